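# Tag collapsing, bounded-mismatch annotation against the reference catalog,
# and the composition / length / chromosome summaries computed from uniquely
# aligned tags.

#' Collapse clean inserts to unique tags
#'
#' @param clean_inserts Character vector of clean insert sequences
#'   (17-45 nt).
#' @param min_len,max_len Allowed insert range; out-of-range input is an
#'   error.
#' @return Data frame `seq`, `count`, sorted lexicographically; counts sum to
#'   the number of input inserts.
#' @export
collapse_reads <- function(clean_inserts, min_len = 17L, max_len = 45L) {
  if (length(clean_inserts) == 0L) {
    return(data.frame(seq = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  len <- nchar(clean_inserts)
  if (any(len < min_len | len > max_len)) {
    stop("insert(s) outside the ", min_len, "-", max_len, " nt range")
  }
  tab <- table(clean_inserts)
  out <- data.frame(seq = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Concatenated reference index for the bounded-Hamming scan. References are
# joined with '#' spacer runs at least as long as the longest query, so no
# window can span two references; a window position maps back to (reference,
# offset) through ref_at/starts.
build_ref_index <- function(catalog, max_query_len = 45L) {
  lens <- nchar(catalog$seq)
  sep <- strrep("#", max_query_len)
  conc <- paste(catalog$seq, collapse = sep)
  starts <- cumsum(c(1L, lens[-length(lens)] + max_query_len))
  ref_at <- integer(nchar(conc))
  for (j in seq_along(lens)) {
    ref_at[starts[j]:(starts[j] + lens[j] - 1L)] <- j
  }
  list(raw = charToRaw(conc), ref_at = ref_at, starts = starts,
       max_query_len = max_query_len)
}

# All in-bounds occurrences of `query` with <= k substitutions across the
# index; N on either side always counts as a mismatch.
scan_hamming <- function(query, index, k) {
  praw <- charToRaw(query)
  L <- length(praw)
  if (L > index$max_query_len) stop("query longer than index spacer")
  n_win <- length(index$raw) - L + 1L
  empty <- data.frame(ref = integer(0), offset = integer(0),
                      mismatches = integer(0))
  if (n_win < 1L) return(empty)
  nraw <- charToRaw("N")
  mm <- integer(n_win)
  for (i in seq_len(L)) {
    if (praw[i] == nraw) {
      mm <- mm + 1L
    } else {
      sub <- index$raw[i:(i + n_win - 1L)]
      mm <- mm + as.integer(sub != praw[i] | sub == nraw)
    }
  }
  w <- which(mm <= k)
  ref <- index$ref_at[w]
  keep <- ref != 0L & index$ref_at[w + L - 1L] == ref
  w <- w[keep]
  ref <- ref[keep]
  data.frame(ref = ref, offset = w - index$starts[ref],
             mismatches = mm[w])
}

#' Align tags to the catalog with bounded mismatches
#'
#' Finds, for every tag, all occurrences of the tag (or of its reverse
#' complement, reported as strand `"-"`) within any catalog reference with at
#' most `max_mismatches` substitutions, using a vectorized bounded-Hamming
#' scan over the reference set (the package's stand-in for genome alignment:
#' only class/feature assignment is needed downstream). An `N` on either side
#' never matches. A tag is unique exactly when a single hit attains the
#' minimum mismatch count; ties (several equally good locations) make it
#' non-unique.
#'
#' @param tags Data frame `seq`, `count` from [collapse_reads()].
#' @param catalog A `small_rna_catalog`.
#' @param max_mismatches 0, 1 or 2 substitutions allowed.
#' @return A list of class `annotated_tags`: `tags` (one row per tag: `seq`,
#'   `count`, `n_hits`, `n_best`, `unique`, `reference_id`, `offset`,
#'   `strand`, `mismatches`, `rna_class`) and `hits` (all hits: `seq`,
#'   `reference_id`, `offset`, `strand`, `mismatches`). Classes are filled by
#'   [assign_classes()], which is applied with the catalog priority.
#' @export
align_tags <- function(tags, catalog, max_mismatches = 0L) {
  stopifnot(max_mismatches %in% 0:2)
  index <- build_ref_index(catalog,
                           max_query_len = max(45L, max(nchar(tags$seq), 0L)))
  hit_list <- vector("list", nrow(tags))
  for (i in seq_len(nrow(tags))) {
    tag <- tags$seq[i]
    rows <- list()
    for (strand in c("+", "-")) {
      query <- if (strand == "+") tag else reverse_complement(tag)
      h <- scan_hamming(query, index, max_mismatches)
      if (nrow(h)) {
        rows[[length(rows) + 1L]] <- data.frame(
          seq = tag, reference_id = catalog$id[h$ref],
          offset = h$offset, strand = strand,
          mismatches = h$mismatches, stringsAsFactors = FALSE)
      }
    }
    hit_list[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  hits <- do.call(rbind, hit_list)
  if (is.null(hits)) {
    hits <- data.frame(seq = character(0), reference_id = character(0),
                       offset = integer(0), strand = character(0),
                       mismatches = integer(0), stringsAsFactors = FALSE)
  }
  summary <- summarize_hits(tags, hits)
  out <- structure(list(tags = summary, hits = hits), class = "annotated_tags")
  assign_classes(out, catalog)
}

# per-tag best-hit summary; unique <=> exactly one minimum-mismatch hit
summarize_hits <- function(tags, hits) {
  n <- nrow(tags)
  summary <- data.frame(
    seq = tags$seq, count = tags$count,
    n_hits = 0L, n_best = 0L, unique = FALSE,
    reference_id = NA_character_, offset = NA_integer_,
    strand = NA_character_, mismatches = NA_integer_,
    rna_class = "other", stringsAsFactors = FALSE
  )
  if (!nrow(hits)) return(summary)
  sp <- split(seq_len(nrow(hits)), factor(hits$seq, levels = tags$seq))
  for (i in seq_len(n)) {
    idx <- sp[[i]]
    if (!length(idx)) next
    mm <- hits$mismatches[idx]
    best <- idx[mm == min(mm)]
    summary$n_hits[i] <- length(idx)
    summary$n_best[i] <- length(best)
    if (length(best) == 1L) {
      summary$unique[i] <- TRUE
      summary$reference_id[i] <- hits$reference_id[best]
      summary$offset[i] <- hits$offset[best]
      summary$strand[i] <- hits$strand[best]
      summary$mismatches[i] <- hits$mismatches[best]
    }
  }
  summary
}

#' Assign ncRNA classes to annotated tags
#'
#' A tag with a single best hit takes that hit's class; when several best
#' hits span different classes the highest-priority class wins (the tag stays
#' non-unique); a tag with no hits is `"other"`.
#'
#' @param annotated An `annotated_tags` object.
#' @param catalog The catalog the tags were aligned to (supplies reference
#'   classes and the priority order), or `NULL` to reuse stored classes.
#' @param priority Optional explicit priority order (defaults to the
#'   catalog's).
#' @return The `annotated_tags` object with `rna_class` filled in.
#' @export
assign_classes <- function(annotated, catalog, priority = NULL) {
  stopifnot(inherits(annotated, "annotated_tags"))
  priority <- priority %||% class_priority(catalog)
  ref_class <- setNames(catalog$rna_class, catalog$id)
  if (!all(unique(catalog$rna_class) %in% priority)) {
    stop("priority must cover every class present in the catalog")
  }
  tags <- annotated$tags
  hits <- annotated$hits
  if (nrow(hits)) {
    sp <- split(seq_len(nrow(hits)), factor(hits$seq, levels = tags$seq))
    for (i in seq_len(nrow(tags))) {
      idx <- sp[[i]]
      if (!length(idx)) { tags$rna_class[i] <- "other"; next }
      mm <- hits$mismatches[idx]
      best <- idx[mm == min(mm)]
      classes <- unique(ref_class[hits$reference_id[best]])
      tags$rna_class[i] <- priority[min(match(classes, priority))]
    }
  }
  annotated$tags <- tags
  annotated
}

#' Class composition of uniquely aligned tags
#'
#' Count-weighted percentage of each ncRNA class over uniquely aligned tags
#' plus unmatched (`"other"`) tags; multi-mapped tags are excluded, mirroring
#' an analysis restricted to uniquely aligned reads. Percentages sum to 100.
#'
#' @param annotated An `annotated_tags` object.
#' @param clean_reads Clean-read total of the library (must be positive).
#' @return Data frame `rna_class`, `copies`, `percent`.
#' @export
class_composition <- function(annotated, clean_reads) {
  if (clean_reads <= 0) stop("clean_reads must be positive")
  tags <- annotated$tags
  keep <- tags$unique | tags$n_hits == 0L
  classes <- c(RNA_CLASSES, "other")
  copies <- vapply(classes, function(cl) {
    sum(tags$count[keep & tags$rna_class == cl])
  }, numeric(1))
  total <- sum(copies)
  data.frame(rna_class = classes,
             copies = as.integer(copies),
             percent = if (total > 0) copies / total * 100 else rep(0, length(classes)),
             stringsAsFactors = FALSE)
}

#' Per-length RPM of one ncRNA class
#'
#' RPM at insert length l = copies of uniquely aligned tags of the class with
#' length l, per million clean reads.
#'
#' @param annotated An `annotated_tags` object.
#' @param rna_class Class label.
#' @param clean_reads Clean-read total (denominator).
#' @param lengths Length range to tabulate.
#' @return Data frame `length`, `rpm`.
#' @export
length_distribution <- function(annotated, rna_class, clean_reads,
                                lengths = 17:45) {
  if (clean_reads <= 0) stop("clean_reads must be positive")
  tags <- annotated$tags
  keep <- tags$unique & tags$rna_class == rna_class
  len <- nchar(tags$seq[keep])
  copies <- vapply(lengths, function(l) sum(tags$count[keep][len == l]),
                   numeric(1))
  data.frame(length = lengths, rpm = copies / clean_reads * 1e6)
}

#' Binned per-chromosome abundance of uniquely aligned tags
#'
#' Each unique tag contributes its copies (as RPM) to the genomic bin
#' containing the start of its alignment, placed at the reference locus start
#' plus the within-reference offset. Hits on references without a locus are
#' accumulated under chromosome `"unplaced"`.
#'
#' @param annotated An `annotated_tags` object.
#' @param catalog The catalog carrying reference loci.
#' @param bin_size Bin width in bases (> 0).
#' @param clean_reads Clean-read total (denominator).
#' @return Data frame `chrom`, `bin_start`, `rpm` (bins with signal only).
#' @export
chromosome_abundance <- function(annotated, catalog, bin_size = 1e6,
                                 clean_reads = NULL) {
  stopifnot(bin_size > 0)
  if (is.null(clean_reads) || clean_reads <= 0) {
    stop("clean_reads must be positive")
  }
  tags <- annotated$tags
  u <- tags[tags$unique, , drop = FALSE]
  if (!nrow(u)) {
    return(data.frame(chrom = character(0), bin_start = numeric(0),
                      rpm = numeric(0), stringsAsFactors = FALSE))
  }
  ridx <- match(u$reference_id, catalog$id)
  chrom <- catalog$chrom[ridx]
  gstart <- catalog$start[ridx] + u$offset
  unplaced <- is.na(chrom)
  chrom[unplaced] <- "unplaced"
  bin <- ifelse(unplaced, 0, floor(gstart / bin_size) * bin_size)
  key <- paste(chrom, bin, sep = ":")
  rpm <- tapply(u$count / clean_reads * 1e6, key, sum)
  parts <- strsplit(names(rpm), ":", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, character(1), 1L),
                    bin_start = as.numeric(vapply(parts, `[`, character(1), 2L)),
                    rpm = as.numeric(rpm),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
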
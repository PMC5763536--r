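# miRNA confirmation, isomiR collapsing, minimum-copy filtering and RPM
# quantification.
#
# A tag is confirmed for a mature miRNA when it contains the entire mature
# sequence and differs from it in length by at most 4 nt. Confirmed tags that
# share the same 5' end of the same precursor and differ in length by no more
# than 2 nt are merged into one call; calls with fewer than 10 copies are
# discarded as likely sequencing error.

#' Confirm a tag against a mature miRNA record
#'
#' @param tag Tag sequence (character).
#' @param mature_record Mature reference sequence, or a catalog row with a
#'   `seq` column.
#' @param max_len_diff Maximum absolute length difference (nt).
#' @return `TRUE` iff the mature sequence is a contiguous substring of the
#'   tag and the length difference is within `max_len_diff`.
#' @export
confirm_tag <- function(tag, mature_record, max_len_diff = 4L) {
  mature <- if (is.data.frame(mature_record)) mature_record$seq[1L] else mature_record
  stopifnot(is.character(tag), length(tag) == 1L,
            is.character(mature), length(mature) == 1L)
  abs(nchar(tag) - nchar(mature)) <= max_len_diff &&
    grepl(mature, tag, fixed = TRUE)
}

#' Merge isomiRs sharing a 5' end
#'
#' Tags from the same precursor whose reconstructed 5' starts coincide and
#' whose pairwise length discrepancy is at most 2 nt (strictly below 3) are
#' merged into one call with summed counts. Within a 5'-anchor group, tags
#' are clustered greedily from the shortest: each cluster takes every tag
#' within 2 nt of its shortest member. The most abundant member represents
#' the call (ties: lexicographically smallest sequence).
#'
#' @param tags_for_precursor Data frame with columns `seq`, `count`,
#'   `mirna_id`, `precursor_id`, `start5` (5' start of the tag in precursor
#'   coordinates; see [quantify_mirnas()] for how it is reconstructed).
#' @param max_len_gap Maximum pairwise length discrepancy within a call.
#' @return Data frame of calls: `mirna_id`, `precursor_id`, `start5`,
#'   `representative_seq`, `n_tags`, `total_count`.
#' @export
collapse_isomirs <- function(tags_for_precursor, max_len_gap = 2L) {
  df <- tags_for_precursor
  need <- c("seq", "count", "mirna_id", "precursor_id", "start5")
  stopifnot(all(need %in% names(df)))
  if (!nrow(df)) {
    return(data.frame(mirna_id = character(0), precursor_id = character(0),
                      start5 = integer(0), representative_seq = character(0),
                      n_tags = integer(0), total_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  # deterministic regardless of input order
  df <- df[order(df$precursor_id, df$mirna_id, df$start5,
                 nchar(df$seq), df$seq), , drop = FALSE]
  key <- paste(df$precursor_id, df$mirna_id, df$start5, sep = "\r")
  out <- list()
  for (grp in split(seq_len(nrow(df)), factor(key, levels = unique(key)))) {
    lens <- nchar(df$seq[grp])  # already ascending
    while (length(grp)) {
      member <- grp[lens - lens[1L] <= max_len_gap]
      rest <- lens - lens[1L] > max_len_gap
      sub <- df[member, , drop = FALSE]
      rep_i <- order(-sub$count, sub$seq)[1L]
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = sub$mirna_id[1L],
        precursor_id = sub$precursor_id[1L],
        start5 = sub$start5[1L],
        representative_seq = sub$seq[rep_i],
        n_tags = nrow(sub),
        total_count = sum(sub$count),
        stringsAsFactors = FALSE
      )
      grp <- grp[rest]
      lens <- lens[rest]
    }
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  calls
}

#' Drop calls below the minimum copy number
#'
#' @param calls Data frame with a `total_count` column.
#' @param min_copies Calls with `total_count < min_copies` are removed
#'   (default 10, guarding against sequencing error).
#' @return The filtered calls.
#' @export
apply_min_copies <- function(calls, min_copies = 10L) {
  out <- calls[calls$total_count >= min_copies, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reads-per-million normalization
#'
#' @param count Nonnegative read count(s).
#' @param clean_reads Clean-read total of the library (> 0).
#' @return `count / clean_reads * 1e6`.
#' @export
rpm_normalize <- function(count, clean_reads) {
  if (length(clean_reads) != 1L || clean_reads <= 0) {
    stop("clean_reads must be a single positive number")
  }
  if (any(count < 0)) stop("counts must be nonnegative")
  count / clean_reads * 1e6
}

#' Quantify mature miRNAs from collapsed tags
#'
#' Applies the confirmation rule to every tag against every mature miRNA in
#' the catalog, merges isomiRs sharing a 5' end, removes calls below the
#' copy-number floor, and attaches RPM values. A tag containing several
#' mature sequences is assigned to the longest one (ties: lexicographically
#' smallest id). The 5' start is reconstructed as the mature 5' offset within
#' its precursor (metadata column `mature_offset`) minus the position of the
#' mature inside the tag; if no offset is available the grouping key keeps
#' the mature id so tags of different matures never merge.
#'
#' @param tags Data frame `seq`, `count` from [collapse_reads()].
#' @param catalog A `small_rna_catalog` containing miRNA records.
#' @param clean_reads Clean-read total of the library.
#' @param min_copies Copy-number floor (default 10), applied after merging.
#' @param max_len_diff Confirmation length window (default 4 nt).
#' @param max_len_gap IsomiR merge window (default 2 nt).
#' @return Data frame of retained calls: `mirna_id`, `precursor_id`,
#'   `start5`, `representative_seq`, `n_tags`, `total_count`, `rpm`.
#' @export
quantify_mirnas <- function(tags, catalog, clean_reads, min_copies = 10L,
                            max_len_diff = 4L, max_len_gap = 2L) {
  if (clean_reads <= 0) stop("clean_reads must be positive")
  mir <- catalog[catalog$rna_class == "miRNA", , drop = FALSE]
  confirmed <- confirm_all(tags, mir, max_len_diff)
  calls <- collapse_isomirs(confirmed, max_len_gap = max_len_gap)
  calls <- apply_min_copies(calls, min_copies)
  calls$rpm <- rpm_normalize(calls$total_count, clean_reads)
  calls[order(calls$mirna_id, calls$start5), , drop = FALSE]
}

# per-tag best confirmed mature; returns collapse_isomirs input
confirm_all <- function(tags, mir, max_len_diff = 4L) {
  empty <- data.frame(seq = character(0), count = integer(0),
                      mirna_id = character(0), precursor_id = character(0),
                      start5 = integer(0), stringsAsFactors = FALSE)
  if (!nrow(tags) || !nrow(mir)) return(empty)
  rows <- vector("list", nrow(tags))
  tag_len <- nchar(tags$seq)
  mat_len <- nchar(mir$seq)
  for (i in seq_len(nrow(tags))) {
    ok <- which(abs(tag_len[i] - mat_len) <= max_len_diff & mat_len <= tag_len[i])
    if (!length(ok)) next
    pos <- regexpr_fixed_many(mir$seq[ok], tags$seq[i])
    found <- which(pos > 0L)
    if (!length(found)) next
    cand <- ok[found]
    # longest mature wins; ties by id
    pick <- cand[order(-mat_len[cand], mir$id[cand])][1L]
    e5 <- pos[found][order(-mat_len[cand], mir$id[cand])][1L] - 1L
    off <- mir$mature_offset[pick]
    if (is.na(off)) {
      start5 <- -e5
      prec <- paste(mir$precursor_id[pick], mir$id[pick], sep = "|")
    } else {
      start5 <- off - e5
      prec <- mir$precursor_id[pick]
    }
    rows[[i]] <- data.frame(seq = tags$seq[i], count = tags$count[i],
                            mirna_id = mir$id[pick], precursor_id = prec,
                            start5 = start5, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

# first-match positions of several fixed patterns in one subject
regexpr_fixed_many <- function(patterns, subject) {
  vapply(patterns, function(p) {
    as.integer(regexpr(p, subject, fixed = TRUE))
  }, integer(1), USE.NAMES = FALSE)
}

#' Assemble a multi-group RPM expression matrix
#'
#' @param call_list Named list of call data frames from [quantify_mirnas()],
#'   one per group.
#' @param clean_reads Named numeric vector of per-group clean-read totals.
#' @return A list of class `expression_matrix` with `rpm` and `counts`
#'   (feature x group matrices; absent features are 0) and `clean_reads`.
#' @export
build_expression_matrix <- function(call_list, clean_reads) {
  stopifnot(length(call_list) >= 1L, !is.null(names(call_list)),
            setequal(names(call_list), names(clean_reads)))
  groups <- names(call_list)
  features <- sort(unique(unlist(lapply(call_list, function(x) x$mirna_id))))
  counts <- matrix(0L, nrow = length(features), ncol = length(groups),
                   dimnames = list(features, groups))
  for (g in groups) {
    calls <- call_list[[g]]
    # several 5'-anchor calls can share a mature id; totals add up
    agg <- tapply(calls$total_count, calls$mirna_id, sum)
    counts[names(agg), g] <- as.integer(agg)
  }
  rpm <- sweep(counts, 2L, as.numeric(clean_reads[groups]), "/") * 1e6
  structure(list(rpm = rpm, counts = counts,
                 clean_reads = clean_reads[groups]),
            class = "expression_matrix")
}
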
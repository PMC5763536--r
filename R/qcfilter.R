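#' Read-filtering configuration
#'
#' Thresholds for classifying raw small-RNA reads into the six rejection
#' categories and clean reads. Defaults: exact-match 3' adapter detection with
#' a minimum overlap of 6 nt; inserts are rejected when their mean Phred score
#' is below 20, when shorter than 17 nt, or when a single base (or N) makes up
#' at least 80% of the insert; a 5' adapter contaminant is an insert carrying
#' 10 or more consecutive bases of the 5' adapter.
#'
#' @param adapter3 3' adapter sequence ligated to every insert.
#' @param adapter5 5' adapter whose carry-over marks a contaminated insert.
#' @param min_overlap Minimum exact overlap (nt) for 3' adapter detection.
#' @param min_insert,max_insert Clean insert length range (nt).
#' @param min_mean_qual Minimum mean Phred score of the insert.
#' @param poly_frac Single-base fraction at or above which an insert counts
#'   as a homopolymer repeat.
#' @param adapter5_run Minimum run (nt) of 5' adapter sequence that flags a
#'   contaminant.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                          adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                          min_overlap = 6L,
                          min_insert = 17L,
                          max_insert = 45L,
                          min_mean_qual = 20,
                          poly_frac = 0.8,
                          adapter5_run = 10L) {
  stopifnot(nchar(adapter3) >= min_overlap, min_overlap >= 1L,
            min_insert >= 1L, max_insert >= min_insert,
            poly_frac > 0, poly_frac <= 1, adapter5_run >= 1L)
  structure(list(adapter3 = toupper(adapter3), adapter5 = toupper(adapter5),
                 min_overlap = as.integer(min_overlap),
                 min_insert = as.integer(min_insert),
                 max_insert = as.integer(max_insert),
                 min_mean_qual = min_mean_qual,
                 poly_frac = poly_frac,
                 adapter5_run = as.integer(adapter5_run)),
            class = "filter_config")
}

FILTER_CATEGORIES <- c("adapter3_null", "insert_null", "adapter5_contaminant",
                       "inferior_quality", "too_short", "poly_repeat")

# Leftmost 1-based position where the 3' adapter starts in each read, or NA.
# A position qualifies when the read suffix from there on exactly matches an
# adapter prefix of length min(adapter length, remaining read), and that
# overlap is at least min_overlap.
find_adapter3 <- function(seqs, adapter, min_overlap = 6L) {
  n <- length(seqs)
  pos <- rep(NA_integer_, n)
  if (n == 0L) return(pos)
  alen <- nchar(adapter)
  probe <- substr(adapter, 1L, min_overlap)
  # overlapping occurrences: a zero-width lookahead finds every start
  cand <- gregexpr(paste0("(?=", probe, ")"), seqs, perl = TRUE)
  rlen <- nchar(seqs)
  for (i in seq_len(n)) {
    cc <- cand[[i]]
    if (cc[1L] == -1L) next
    for (p in as.integer(cc)) {
      ov <- min(alen, rlen[i] - p + 1L)
      if (ov < min_overlap) next
      if (substr(seqs[i], p, p + ov - 1L) == substr(adapter, 1L, ov)) {
        pos[i] <- p
        break
      }
    }
  }
  pos
}

# Vectorized classifier: one category per read, fixed precedence.
classify_reads_impl <- function(seqs, quals, cfg) {
  n <- length(seqs)
  if (length(quals) != n) stop("read and quality vectors differ in length")
  if (n == 0L) {
    return(data.frame(category = character(0), insert = character(0),
                      insert_qual = character(0), stringsAsFactors = FALSE))
  }
  if (any(nchar(seqs) != nchar(quals))) {
    bad <- which(nchar(seqs) != nchar(quals))[1L]
    stop("read and quality string lengths differ at record ", bad)
  }
  seqs <- toupper(seqs)
  category <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)
  iqual <- rep(NA_character_, n)

  pos <- find_adapter3(seqs, cfg$adapter3, cfg$min_overlap)
  category[is.na(pos)] <- "adapter3_null"
  category[!is.na(pos) & pos == 1L] <- "insert_null"

  open <- is.na(category)
  insert[open] <- substr(seqs[open], 1L, pos[open] - 1L)
  iqual[open] <- substr(quals[open], 1L, pos[open] - 1L)

  idx <- which(open)
  contam <- contains_adapter_run(insert[idx], cfg$adapter5, cfg$adapter5_run)
  category[idx[contam]] <- "adapter5_contaminant"

  idx <- which(is.na(category))
  mq <- vapply(iqual[idx], mean_phred, numeric(1), USE.NAMES = FALSE)
  category[idx[mq < cfg$min_mean_qual]] <- "inferior_quality"

  idx <- which(is.na(category))
  category[idx[nchar(insert[idx]) < cfg$min_insert]] <- "too_short"

  idx <- which(is.na(category))
  poly <- max_base_fraction(insert[idx]) >= cfg$poly_frac
  category[idx[poly]] <- "poly_repeat"

  category[is.na(category)] <- "clean"
  insert[category != "clean"] <- NA_character_
  iqual[category != "clean"] <- NA_character_
  data.frame(category = category, insert = insert, insert_qual = iqual,
             stringsAsFactors = FALSE)
}

#' Classify a single raw read
#'
#' Applies the six rejection rules in fixed precedence: (1) 3' adapter not
#' found; (2) adapter at position 1, i.e. empty insert; (3) insert contains a
#' run of the 5' adapter; (4) insert mean Phred below threshold; (5) insert
#' shorter than 17 nt; (6) insert a homopolymer repeat. A read failing none is
#' clean and its trimmed insert is returned.
#'
#' @param read Read sequence (character).
#' @param qual Phred+33 quality string of the same length.
#' @param config A [filter_config()].
#' @return A list with `category` (one of the six rejection labels or
#'   `"clean"`) and `insert` (trimmed insert for clean reads, otherwise `NA`).
#' @export
classify_read <- function(read, qual, config = filter_config()) {
  stopifnot(is.character(read), length(read) == 1L,
            is.character(qual), length(qual) == 1L)
  if (nchar(read) != nchar(qual)) {
    stop("read and quality string lengths differ")
  }
  res <- classify_reads_impl(read, qual, config)
  list(category = res$category, insert = res$insert)
}

#' Filter a small-RNA FASTQ library
#'
#' Classifies every read, trims 3' adapters, and returns the clean 17-45 nt
#' inserts together with a filtering report whose category counts always sum
#' to the total read count. Inserts trimmed to more than `max_insert` nt are
#' counted as clean but excluded from the tag input (they fall outside the
#' analyzed insert range); under the default read length and adapter this
#' cannot occur.
#'
#' @param fastq_path Path to a Phred+33 FASTQ file (gzip allowed).
#' @param config A [filter_config()].
#' @return A list with `clean` (data frame `read_id`, `insert`) and
#'   `report` (a `filter_report` data frame, see [filter_report()]).
#' @export
filter_library <- function(fastq_path, config = filter_config()) {
  reads <- read_fastq(fastq_path)
  filter_reads(reads$seq, reads$qual, read_id = reads$read_id,
               config = config)
}

#' Filter in-memory reads
#'
#' Workhorse behind [filter_library()], operating on character vectors.
#'
#' @param seqs Read sequences.
#' @param quals Phred+33 quality strings.
#' @param read_id Optional read identifiers.
#' @param config A [filter_config()].
#' @return As [filter_library()].
#' @export
filter_reads <- function(seqs, quals, read_id = NULL,
                         config = filter_config()) {
  if (is.null(read_id)) read_id <- sprintf("read%07d", seq_along(seqs))
  res <- classify_reads_impl(seqs, quals, config)
  counts <- table(factor(res$category,
                         levels = c(FILTER_CATEGORIES, "clean")))
  report <- filter_report(as.integer(counts[FILTER_CATEGORIES]),
                          clean_reads = as.integer(counts[["clean"]]))
  keep <- res$category == "clean" & nchar(res$insert) <= config$max_insert
  list(clean = data.frame(read_id = read_id[keep],
                          insert = res$insert[keep],
                          stringsAsFactors = FALSE),
       report = report,
       categories = data.frame(read_id = read_id,
                               category = res$category,
                               stringsAsFactors = FALSE))
}

#' Build a filtering report
#'
#' @param rejected Integer vector of the six rejection-category counts, in
#'   the order `adapter3_null`, `insert_null`, `adapter5_contaminant`,
#'   `inferior_quality`, `too_short`, `poly_repeat`.
#' @param clean_reads Clean read count.
#' @return A data frame of class `filter_report` with columns `category`,
#'   `count`, `percent`; the first row is the total. Category counts sum to
#'   the total by construction.
#' @export
filter_report <- function(rejected, clean_reads) {
  stopifnot(length(rejected) == 6L, all(rejected >= 0L), clean_reads >= 0L)
  total <- sum(rejected) + clean_reads
  counts <- c(total, rejected, clean_reads)
  pct <- if (total > 0L) counts / total * 100 else rep(0, length(counts))
  structure(
    data.frame(category = c("total_reads", FILTER_CATEGORIES, "clean_reads"),
               count = counts,
               percent = round(pct, 2L),
               stringsAsFactors = FALSE),
    class = c("filter_report", "data.frame")
  )
}

# FASTQ reader returning plain character vectors (Phred+33)
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  ids <- names(x)
  if (is.null(ids)) ids <- sprintf("read%07d", seq_along(x))
  ids <- sub("\\s.*$", "", ids)
  data.frame(read_id = ids,
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

# FASTQ writer (Phred+33)
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  quals <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}
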
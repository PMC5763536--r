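# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# n random DNA strings of the given lengths (vector recycled against n)
random_dna <- function(n, lengths) {
  lengths <- rep_len(lengths, n)
  total <- sum(lengths)
  chars <- sample(BASES, total, replace = TRUE)
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  full <- paste(chars, collapse = "")
  substring(full, starts, ends)
}

# Phred+33 quality string from integer scores
phred_string <- function(scores) {
  intToUtf8(scores + 33L, multiple = FALSE)
}

phred_strings <- function(score_list) {
  vapply(score_list, phred_string, character(1))
}

# mean Phred score of a quality string (Phred+33)
mean_phred <- function(qual) {
  if (nchar(qual) == 0L) return(NA_real_)
  mean(utf8ToInt(qual) - 33L)
}

# fraction of the most frequent single base (N included) in each sequence
max_base_fraction <- function(seqs) {
  n <- nchar(seqs)
  frac <- rep(0, length(seqs))
  for (b in c(BASES, "N")) {
    cnt <- nchar(seqs) - nchar(gsub(b, "", seqs, fixed = TRUE))
    frac <- pmax(frac, cnt / pmax(n, 1L))
  }
  frac
}

# TRUE where any >= k-length substring of `adapter` occurs in the sequence
contains_adapter_run <- function(seqs, adapter, k = 10L) {
  hit <- rep(FALSE, length(seqs))
  if (nchar(adapter) < k) return(hit)
  for (i in seq_len(nchar(adapter) - k + 1L)) {
    win <- substr(adapter, i, i + k - 1L)
    hit <- hit | grepl(win, seqs, fixed = TRUE)
  }
  hit
}

# deterministic TSV writer (fixed formatting so reruns are byte-identical)
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
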
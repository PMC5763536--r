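# Independent brute-force oracles and small fixtures shared across tests.
# Each oracle is written as a direct, naive computation so it shares no code
# path with the implementation it checks.

HY4F <- "AGTTCTGATAACCCACTACCATCGGACCAGCC"
HY4RF <- "GGCTGGTCCGATGGTAGTGGGTTATCAGAACT"

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

naive_revcomp <- function(seq) {
  if (nchar(seq) == 0) return("")
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(seq, "")[[1]]]), collapse = "")
}

# naive O(n*m) scan: all offsets where query matches subject exactly
# (N matches nothing)
naive_exact_hits <- function(query, subject) {
  qlen <- nchar(query)
  slen <- nchar(subject)
  if (qlen > slen) return(integer(0))
  qc <- strsplit(query, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  hits <- integer(0)
  for (p in 0:(slen - qlen)) {
    win <- sc[(p + 1):(p + qlen)]
    if (all(win == qc & win != "N" & qc != "N")) hits <- c(hits, p)
  }
  hits
}

# naive bounded-Hamming scan over one subject (offsets 0-based, N mismatches)
naive_hamming_hits <- function(query, subject, k) {
  qlen <- nchar(query)
  slen <- nchar(subject)
  out <- list()
  if (qlen > slen) return(out)
  qc <- strsplit(query, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  for (p in 0:(slen - qlen)) {
    win <- sc[(p + 1):(p + qlen)]
    mm <- sum(win != qc | win == "N" | qc == "N")
    if (mm <= k) out[[length(out) + 1L]] <- c(offset = p, mismatches = mm)
  }
  out
}

# all hits of a tag (both strands) across a catalog, brute force
naive_align <- function(tag, catalog, k) {
  rows <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") tag else naive_revcomp(tag)
    for (j in seq_len(nrow(catalog))) {
      for (h in naive_hamming_hits(q, catalog$seq[j], k)) {
        rows[[length(rows) + 1L]] <- data.frame(
          reference_id = catalog$id[j], offset = unname(h["offset"]),
          strand = strand, mismatches = unname(h["mismatches"]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(reference_id = character(0), offset = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# hand-applied BH step-up: q(i) = min_{j>=i} p(j)*n/j on sorted p
naive_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) {
    if (n > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(n)
  out[o] <- q_sorted
  out
}

# brute-force conditional exact p: enumerate x = 0..s, mass criterion
naive_exact_p <- function(a, b, phi) {
  s <- a + b
  if (s == 0) return(1)
  x <- 0:s
  if (phi == 0) {
    pr <- dbinom(x, s, 0.5)
  } else {
    pr <- dnbinom(x, size = 1 / phi, mu = s / 2) *
      dnbinom(s - x, size = 1 / phi, mu = s / 2)
    pr <- pr / sum(pr)
  }
  sum(pr[pr <= pr[a + 1] * (1 + 1e-12)])
}

# small deterministic hand-built catalog used across modules
make_test_catalog <- function() {
  new_catalog(data.frame(
    id = c("mir-a", "mir-b", "yrna-1", "trna-1", "rrna-1"),
    seq = c("TAGCTTATCAGACTGATGTTGA",          # 22 nt mature
            "TGGAGTGTGACAATGGTGTTTG",          # 22 nt mature
            paste0(HY4F, "TCTTTAGGACATCGGACGGTAAACCGTTAAGCGT"),  # hY4-like
            "GCATTGGTGGTTCAGTGGTAGAATTCTCGCCTGCCACGCGGGAGGCCCGGGTTCGATTCCCGG",
            "CGATTCCCGGCCAATGCACCTTGGAACAGGACTAGGATGGGTACCCGGGCATACCAGGTT"),
    rna_class = c("miRNA", "miRNA", "YRNA", "tRNA", "rRNA"),
    precursor_id = c("pre-mir-a", "pre-mir-b", NA, NA, NA),
    mature_offset = c(12L, 30L, NA, NA, NA),
    chrom = c("chr7", "chr8", "chr7", NA, "chr1"),
    start = c(1000000L, 5000000L, 1200000L, NA, 400000L),
    end = c(1000022L, 5000022L, 1200066L, NA, 400060L),
    strand = c("+", "-", "+", NA, "+"),
    stringsAsFactors = FALSE))
}

# fast-but-small simulation config for tests
small_sim_config <- function(n = 5000L, seed = 1L, ...) {
  simulation_config(library_size = n, seed = seed, ...)
}
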
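# Reference catalog loading and core sequence utilities.

write_demo_files <- function(records) {
  fa <- tempfile(fileext = ".fasta")
  md <- tempfile(fileext = ".tsv")
  writeLines(unlist(lapply(seq_len(nrow(records)), function(i) {
    c(paste0(">", records$id[i]), records$seq[i])
  })), fa)
  write.table(records[, setdiff(names(records), "seq")], md, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  list(fasta = fa, metadata = md)
}

test_that("load_catalog validates and normalizes a small catalog", {
  rec <- data.frame(
    id = c("mir-1", "y4", "pi-1"),
    seq = c("ACGUACGUACGUACGUACGUAC", "AGTTCTGATAACCCACTACC", "ACGTACGTACGTACGTACGTACGTAC"),
    rna_class = c("miRNA", "YRNA", "piRNA"),
    precursor_id = c("pre-mir-1", "", ""),
    stringsAsFactors = FALSE)
  f <- write_demo_files(rec)
  cat <- load_catalog(f$fasta, f$metadata)
  expect_s3_class(cat, "small_rna_catalog")
  expect_equal(nrow(cat), 3L)
  # U converted to T at load time
  expect_equal(cat$seq[cat$id == "mir-1"], "ACGTACGTACGTACGTACGTAC")
  expect_setequal(class_priority(cat), c(default_class_priority()))
})

test_that("load_catalog rejects invalid catalogs", {
  rec <- data.frame(id = c("mir-1", "mir-1"),
                    seq = c("ACGTACGTACGTACGTA", "TTGTACGTACGTACGTA"),
                    rna_class = c("miRNA", "miRNA"),
                    precursor_id = c("p1", "p1"), stringsAsFactors = FALSE)
  f <- write_demo_files(rec)
  expect_error(load_catalog(f$fasta, f$metadata), "duplicate")

  expect_error(new_catalog(data.frame(
    id = "x1", seq = "ACGTACGT", rna_class = "lncRNA",
    stringsAsFactors = FALSE)), "unknown rna_class")
  expect_error(new_catalog(data.frame(
    id = "x1", seq = "ACXTACGT", rna_class = "YRNA",
    stringsAsFactors = FALSE)), "outside")
  expect_error(new_catalog(data.frame(
    id = "m1", seq = "ACGTACGT", rna_class = "miRNA",
    stringsAsFactors = FALSE)), "precursor_id")
  expect_error(new_catalog(data.frame(
    id = "y1", seq = "ACGTACGT", rna_class = "YRNA",
    chrom = "chr1", start = 100L, end = 100L,
    stringsAsFactors = FALSE)), "half-open")
})

test_that("reverse_complement maps the hY4 5' fragment onto its reverse fragment", {
  expect_identical(reverse_complement(HY4F), HY4RF)
  expect_identical(reverse_complement(HY4RF), HY4F)
})

test_that("reverse_complement is a length-preserving involution", {
  expect_identical(reverse_complement(""), "")
  expect_error(reverse_complement("ACGX"), "invalid")
  set.seed(421)
  for (i in 1:25) {
    x <- random_seq(sample(1:60, 1), alphabet = c("A", "C", "G", "T", "N"))
    rc <- reverse_complement(x)
    expect_identical(nchar(rc), nchar(x))
    expect_identical(reverse_complement(rc), x)
    expect_identical(rc, naive_revcomp(x))
  }
})

test_that("locate_fragment finds sense and antisense occurrences", {
  catalog <- make_test_catalog()
  hy4 <- catalog[catalog$id == "yrna-1", ]
  hits <- locate_fragment(HY4F, hy4)
  expect_equal(hits$offset, 0L)
  expect_equal(hits$strand, "+")
  # the reverse fragment hits the same 5' end on the other strand
  rhits <- locate_fragment(HY4RF, hy4)
  expect_equal(rhits$offset, 0L)
  expect_equal(rhits$strand, "-")
  expect_equal(nrow(locate_fragment("TTTT", "ACGT")), 0L)
  # palindromic fragment: both strands report the same occurrence
  pal <- "ACGT"  # reverse complement of itself
  ph <- locate_fragment(pal, "GGACGTGG")
  expect_equal(nrow(ph), 2L)
  expect_setequal(ph$strand, c("+", "-"))
})

test_that("locate_fragment agrees with a naive substring scan", {
  set.seed(99)
  for (i in 1:30) {
    subject <- random_seq(sample(40:120, 1))
    frag <- if (i %% 3 == 0) {
      # planted fragment
      p <- sample(1:(nchar(subject) - 12), 1)
      substr(subject, p, p + 11)
    } else random_seq(8)
    got <- locate_fragment(frag, subject)
    want_fw <- naive_exact_hits(frag, subject)
    want_rv <- naive_exact_hits(naive_revcomp(frag), subject)
    expect_setequal(got$offset[got$strand == "+"], want_fw)
    expect_setequal(got$offset[got$strand == "-"], want_rv)
  }
})

test_that("N in a reference or fragment never matches", {
  # fragment with N: no hits even where the subject has an N
  expect_equal(nrow(locate_fragment("ACCN", "ACCNAGGT")), 0L)
  # subject N blocks the window that crosses it, other windows still hit
  hits <- locate_fragment("ACCT", "ACCNACCTAGGT")
  expect_equal(hits$offset[hits$strand == "+"], 4L)
  expect_equal(hits$offset[hits$strand == "-"], 8L)  # AGGT = revcomp(ACCT)
  # overlapping occurrences are all reported
  expect_equal(locate_fragment("AAA", "AAAAG")$offset, c(0L, 1L))
})

test_that("BED loci attach to a catalog in 0-based half-open coordinates", {
  catalog <- make_test_catalog()
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr2\t500\t522\tmir-a\t0\t+",
               "chr3\t900\t966\tyrna-1\t0\t-"), bed)
  withloci <- attach_loci(catalog, bed)
  expect_equal(withloci$chrom[withloci$id == "mir-a"], "chr2")
  expect_equal(withloci$start[withloci$id == "mir-a"], 500L)
  expect_equal(withloci$end[withloci$id == "mir-a"], 522L)
  expect_equal(withloci$strand[withloci$id == "yrna-1"], "-")
})

test_that("the packaged demo catalog loads", {
  fa <- system.file("extdata", "demo_catalog.fasta", package = "evsmallrna")
  md <- system.file("extdata", "demo_catalog.tsv", package = "evsmallrna")
  cat <- load_catalog(fa, md)
  expect_gt(nrow(cat), 10L)
  expect_true("hY4-synthetic" %in% cat$id)
  expect_equal(substr(cat$seq[cat$id == "hY4-synthetic"], 1, 32), HY4F)
})
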
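# Tag collapsing, bounded-mismatch alignment, class assignment, summaries.

test_that("collapse_reads counts and orders unique inserts", {
  ins <- c("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT",
           "TTAGCGTACGTACGTACGTAC")
  tags <- collapse_reads(ins)
  expect_equal(nrow(tags), 2L)
  expect_equal(tags$seq, sort(unique(ins)))
  expect_equal(sum(tags$count), 3L)
  expect_equal(nrow(collapse_reads(character(0))), 0L)
  expect_error(collapse_reads("ACGT"), "range")
  expect_error(collapse_reads(strrep("A", 46)), "range")
  set.seed(10)
  ins <- replicate(200, random_seq(sample(17:45, 1)))
  ins <- sample(ins, 500, replace = TRUE)
  expect_equal(sum(collapse_reads(ins)$count), 500L)
})

test_that("exact alignment flags unique and multi-mapped tags", {
  catalog <- make_test_catalog()
  tags <- collapse_reads(c(catalog$seq[catalog$id == "mir-a"],
                           substr(catalog$seq[catalog$id == "yrna-1"], 1, 32)))
  ann <- align_tags(tags, catalog, 0L)
  mir_row <- ann$tags[ann$tags$seq == catalog$seq[catalog$id == "mir-a"], ]
  expect_true(mir_row$unique)
  expect_equal(mir_row$reference_id, "mir-a")
  expect_equal(mir_row$offset, 0L)
  expect_equal(mir_row$mismatches, 0L)
  expect_equal(mir_row$rna_class, "miRNA")

  # plant the same 20-mer in two references: multi-mapped, not unique
  dup <- "TACGATTGCCGGATCAATGC"
  cat2 <- new_catalog(data.frame(
    id = c("r1", "r2"),
    seq = c(paste0(dup, "GGTACCGGTTAACCGGTTAA"),
            paste0("CCATGGCCATGG", dup)),
    rna_class = c("rRNA", "snRNA"), stringsAsFactors = FALSE))
  ann2 <- align_tags(collapse_reads(dup), cat2, 0L)
  expect_false(ann2$tags$unique)
  expect_equal(ann2$tags$n_hits, 2L)
  # equal-score multi-class tie resolves by priority for the class label
  expect_equal(ann2$tags$rna_class, "rRNA")
})

test_that("alignment agrees with a brute-force scan at 0 and 1 mismatches", {
  set.seed(77)
  catalog <- new_catalog(data.frame(
    id = sprintf("ref%02d", 1:8),
    seq = replicate(8, random_seq(60)),
    rna_class = sample(c("YRNA", "rRNA", "tRNA"), 8, replace = TRUE),
    stringsAsFactors = FALSE))
  mk_tag <- function() {
    kind <- sample(3, 1)
    if (kind == 1) return(random_seq(sample(17:30, 1)))
    j <- sample(8, 1); p <- sample(1:40, 1)
    t <- substr(catalog$seq[j], p, p + sample(17:20, 1))
    if (kind == 3) {  # mutate one base
      i <- sample(nchar(t), 1)
      substr(t, i, i) <- sample(setdiff(c("A","C","G","T"),
                                        substr(t, i, i)), 1)
    }
    t
  }
  tags <- collapse_reads(unique(replicate(40, mk_tag())))
  for (k in 0:1) {
    ann <- align_tags(tags, catalog, k)
    for (i in seq_len(nrow(tags))) {
      got <- ann$hits[ann$hits$seq == tags$seq[i], ]
      want <- naive_align(tags$seq[i], catalog, k)
      key <- function(d) sort(paste(d$reference_id, d$offset, d$strand,
                                    d$mismatches))
      expect_identical(key(got), key(want))
    }
  }
})

test_that("an N never matches during alignment", {
  cat1 <- new_catalog(data.frame(
    id = "r1", seq = paste0("ACGTACGTNACGTACGTA", "GGCCGGCC"),
    rna_class = "rRNA", stringsAsFactors = FALSE))
  # tag equal to the reference window, N replaced by A: the N position is a
  # mismatch, so no 0-mismatch hit, one 1-mismatch hit
  tag <- "ACGTACGTAACGTACGTA"
  ann0 <- align_tags(collapse_reads(tag), cat1, 0L)
  expect_equal(ann0$tags$n_hits, 0L)
  expect_equal(ann0$tags$rna_class, "other")
  ann1 <- align_tags(collapse_reads(tag), cat1, 1L)
  expect_equal(ann1$tags$n_hits, 1L)
  expect_equal(ann1$tags$mismatches, 1L)
})

test_that("class priority resolves equal-score conflicts", {
  shared <- "TGGCATTCAAGGCATCCAGAT"
  catalog <- new_catalog(data.frame(
    id = c("m1", "r1"),
    seq = c(shared, paste0(shared, "ACGGTTACGGTTACGGTTAC")),
    rna_class = c("miRNA", "rRNA"),
    precursor_id = c("p1", NA), stringsAsFactors = FALSE))
  ann <- align_tags(collapse_reads(shared), catalog, 0L)
  expect_false(ann$tags$unique)   # two equally good locations
  expect_equal(ann$tags$rna_class, "miRNA")
  # reversed priority flips the label
  ann2 <- assign_classes(ann, catalog,
                         priority = c("rRNA", "miRNA"))
  expect_equal(ann2$tags$rna_class, "rRNA")
})

test_that("composition percentages cover unique plus unmatched tags", {
  catalog <- make_test_catalog()
  tags <- collapse_reads(rep(c(catalog$seq[1], catalog$seq[2],
                               random_seq(22)), c(30, 20, 10)))
  ann <- align_tags(tags, catalog, 0L)
  comp <- class_composition(ann, clean_reads = 60)
  expect_equal(sum(comp$percent), 100)
  expect_equal(comp$percent[comp$rna_class == "miRNA"], 50 / 60 * 100)
  expect_equal(comp$percent[comp$rna_class == "other"], 10 / 60 * 100)
  expect_error(class_composition(ann, 0), "positive")
})

test_that("length distribution partitions class RPM by insert length", {
  catalog <- make_test_catalog()
  y32 <- substr(catalog$seq[catalog$id == "yrna-1"], 1, 32)
  tags <- collapse_reads(rep(y32, 10))
  ann <- align_tags(tags, catalog, 0L)
  ld <- length_distribution(ann, "YRNA", clean_reads = 1e6)
  expect_equal(ld$rpm[ld$length == 32], 10)
  expect_equal(sum(ld$rpm), 10)
  expect_true(all(length_distribution(ann, "piRNA", 1e6)$rpm == 0))
})

test_that("chromosome abundance bins unique tags by genomic start", {
  catalog <- make_test_catalog()
  y32 <- substr(catalog$seq[catalog$id == "yrna-1"], 1, 32)
  t32 <- substr(catalog$seq[catalog$id == "trna-1"], 1, 30)
  tags <- collapse_reads(rep(c(y32, t32), c(10, 5)))
  ann <- align_tags(tags, catalog, 0L)
  ca <- chromosome_abundance(ann, catalog, bin_size = 1e6,
                             clean_reads = 1e6)
  # yrna-1 sits at chr7:1,200,000 -> bin 1e6
  expect_equal(ca$rpm[ca$chrom == "chr7" & ca$bin_start == 1e6], 10)
  # trna-1 has no locus -> unplaced
  expect_equal(ca$rpm[ca$chrom == "unplaced"], 5)
  # totals conserved against direct summation
  expect_equal(sum(ca$rpm),
               sum(ann$tags$count[ann$tags$unique]) / 1e6 * 1e6)
})
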
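# Synthetic small-RNA library generator.
#
# Emulates the statistical structure of pooled plasma-EV small-RNA libraries:
# a mixture over ncRNA classes with class-specific insert-length laws (miRNA
# inserts are full mature sequences, ~18-24 nt; YRNA/tRNA fragments are 5'
# fragments of ~29-34 nt), 3'-adapter ligation onto a fixed-length raw read,
# and the six read-rejection categories at configurable rates. Every read
# carries a ground-truth label so the filter and quantification stages can be
# checked exactly.

#' Default per-class insert-length laws
#'
#' For miRNA the insert is the full mature sequence (`lengths = NA`). For the
#' longer reference classes the insert is a 5' fragment whose length is drawn
#' from the stated distribution, mirroring the class-specific fragment-size
#' peaks seen in plasma-EV libraries (YRNA/tRNA ~29-34 nt, rRNA 20-32 nt,
#' snRNA 19-24 nt, snoRNA ~25-29 nt, piRNA 20-22 nt). Lengths are capped at
#' the reference length.
#'
#' @return Named list of `list(lengths, probs)` per class; `lengths = NA`
#'   means "use the full reference sequence".
#' @export
default_insert_laws <- function() {
  list(
    miRNA = list(lengths = NA, probs = NA),
    YRNA = list(lengths = 30:33, probs = c(0.2, 0.35, 0.3, 0.15)),
    tRNA = list(lengths = 29:34, probs = rep(1 / 6, 6)),
    rRNA = list(lengths = 20:32, probs = rep(1 / 13, 13)),
    snRNA = list(lengths = 19:24, probs = rep(1 / 6, 6)),
    snoRNA = list(lengths = 25:29, probs = c(0.1, 0.2, 0.4, 0.2, 0.1)),
    piRNA = list(lengths = 20:22, probs = c(0.3, 0.4, 0.3))
  )
}

#' Simulation configuration
#'
#' Defaults emulate an adenocarcinoma-like pooled EV library: a YRNA-dominated
#' class mixture and rejection-category rates matching the observed filtering
#' proportions of such libraries (about 93% clean; the 3'-adapter-missing,
#' empty-insert, 5'-contaminant, low-quality, under-17-nt and homopolymer
#' categories at roughly 1.9, 1.0, 0.06, 0.5, 3.6 and 0.02 percent).
#'
#' @param library_size Number of raw reads to generate.
#' @param seed Integer seed; all randomness for a library flows from it.
#' @param class_weights Named nonnegative weights over ncRNA classes
#'   (normalized internally).
#' @param insert_laws Per-class insert-length laws, see
#'   [default_insert_laws()].
#' @param adapter3,adapter5 Adapter sequences (defaults match
#'   [filter_config()]).
#' @param artifact_rates Named probabilities for the six rejection categories;
#'   must sum to at most 1, remainder is clean.
#' @param read_length Raw read length (fixed).
#' @param ambiguous If `TRUE`, artifact reads are drawn without the
#'   disjointness checks that make filter recovery exact (robustness testing).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(library_size = 100000L,
                              seed = 1L,
                              class_weights = c(miRNA = 0.25, YRNA = 0.51,
                                                tRNA = 0.011, rRNA = 0.05,
                                                snRNA = 0.03, snoRNA = 0.02,
                                                piRNA = 0.05),
                              insert_laws = default_insert_laws(),
                              adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                              adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                              artifact_rates = c(adapter3_null = 0.0191,
                                                 insert_null = 0.0098,
                                                 adapter5_contaminant = 0.0006,
                                                 inferior_quality = 0.0049,
                                                 too_short = 0.0356,
                                                 poly_repeat = 0.0002),
                              read_length = 50L,
                              ambiguous = FALSE) {
  stopifnot(library_size > 0L, length(seed) == 1L)
  stopifnot(all(class_weights >= 0), sum(class_weights) > 0)
  stopifnot(all(names(class_weights) %in% RNA_CLASSES))
  ar <- artifact_rates[FILTER_CATEGORIES]
  ar[is.na(ar)] <- 0
  names(ar) <- FILTER_CATEGORIES
  stopifnot(all(ar >= 0), sum(ar) <= 1)
  stopifnot(read_length >= 20L)
  structure(list(library_size = as.integer(library_size),
                 seed = as.integer(seed),
                 class_weights = class_weights,
                 insert_laws = insert_laws,
                 adapter3 = toupper(adapter3),
                 adapter5 = toupper(adapter5),
                 artifact_rates = ar,
                 read_length = as.integer(read_length),
                 ambiguous = isTRUE(ambiguous)),
            class = "simulation_config")
}

#' Generate a synthetic reference catalog
#'
#' Random reference sequences with realistic per-class lengths (mature miRNA
#' 20-23 nt with precursor links, YRNA ~96 nt, tRNA ~73 nt, rRNA 120 nt,
#' snRNA 106 nt, snoRNA 80 nt, piRNA 26-31 nt) and synthetic genomic loci.
#' Optionally the first YRNA record is an hY4-like reference whose 5' end is
#' the 32-nt hY4 5' fragment, with its reverse-oriented counterpart present as
#' the fragment's reverse complement.
#'
#' @param n_per_class Named integer vector: references per class.
#' @param seed Integer seed.
#' @param include_hy4 Prepend the hY4-like YRNA reference.
#' @return A `small_rna_catalog`.
#' @export
synthetic_catalog <- function(n_per_class = c(miRNA = 30, YRNA = 6, tRNA = 8,
                                              rRNA = 6, snRNA = 5,
                                              snoRNA = 5, piRNA = 10),
                              seed = 100L,
                              include_hy4 = TRUE) {
  set.seed(seed)
  ref_len <- list(miRNA = 20:23, YRNA = 96, tRNA = 73, rRNA = 120,
                  snRNA = 106, snoRNA = 80, piRNA = 26:31)
  rows <- list()
  for (cls in names(n_per_class)) {
    n <- n_per_class[[cls]]
    if (n == 0L) next
    lens <- sample(rep_len(ref_len[[cls]], max(n, length(ref_len[[cls]]))), n,
                   replace = TRUE)
    seqs <- random_dna(n, lens)
    ids <- sprintf("%s-%03d", tolower(cls), seq_len(n))
    rows[[cls]] <- data.frame(
      id = ids, seq = seqs, rna_class = cls,
      precursor_id = if (cls == "miRNA") paste0("pre-", ids) else NA_character_,
      mature_offset = if (cls == "miRNA") 10L else NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, rows)
  if (include_hy4) {
    hy4f <- "AGTTCTGATAACCCACTACCATCGGACCAGCC"
    hy4 <- paste0(hy4f, random_dna(1L, 62L))
    records <- rbind(
      data.frame(id = "hY4-synthetic", seq = hy4, rna_class = "YRNA",
                 precursor_id = NA_character_, mature_offset = NA_integer_,
                 stringsAsFactors = FALSE),
      records
    )
  }
  n <- nrow(records)
  records$chrom <- paste0("chr", sample(c(1:8), n, replace = TRUE))
  records$start <- as.integer(sample.int(2e6L, n)) * 50L
  records$end <- records$start + nchar(records$seq)
  records$strand <- sample(c("+", "-"), n, replace = TRUE)
  new_catalog(records)
}

# insert safety for exact filter recovery: right length, detectable adapter,
# no early adapter match, no 5'-adapter run, not a homopolymer
clean_insert_ok <- function(inserts, config) {
  probe <- substr(config$adapter3, 1L, 6L)
  len <- nchar(inserts)
  len >= 17L & len <= min(45L, config$read_length - 6L) &
    !grepl(probe, inserts, fixed = TRUE) &
    !contains_adapter_run(inserts, config$adapter5, 10L) &
    max_base_fraction(inserts) < 0.8
}

# assemble full-length raw reads: insert + 3' adapter + random padding
assemble_reads <- function(inserts, config) {
  raw <- paste0(inserts, config$adapter3)
  pad <- config$read_length - nchar(raw)
  need <- which(pad > 0L)
  if (length(need)) {
    raw[need] <- paste0(raw[need], random_dna(length(need), pad[need]))
  }
  substr(raw, 1L, config$read_length)
}

high_quality <- function(n, len) {
  phred_strings(lapply(rep_len(len, n), function(l) {
    sample(33:40, l, replace = TRUE)
  }))
}

#' Simulate a small-RNA FASTQ library with ground truth
#'
#' Draws a per-read category (six rejection categories plus clean) from the
#' configured rates, builds clean reads as reference-derived inserts plus the
#' 3' adapter and random padding with Phred quality at or above 30, and builds
#' each artifact read to satisfy exactly its own rejection rule (disjoint by
#' construction unless `config$ambiguous`). Low-quality reads get insert mean
#' Phred below 20. Deterministic for a fixed seed.
#'
#' @param config A [simulation_config()].
#' @param catalog A `small_rna_catalog` supplying reference sequences.
#' @param fold_changes Optional named multipliers (> 0) on reference sampling
#'   weights, keyed by reference id (used by [simulate_two_group()]).
#' @return A list of class `ev_sim` with `reads` (data frame `read_id`,
#'   `seq`, `qual`), `truth` (per-read `read_id`, `category`, `source_id`,
#'   `insert`), `copy_counts` (per-reference true clean copies and expected
#'   copies), and the `config`.
#' @export
simulate_library <- function(config, catalog, fold_changes = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  clean_rate <- 1 - sum(config$artifact_rates)
  usable <- catalog$rna_class %in% names(config$class_weights) &
    config$class_weights[catalog$rna_class] > 0
  if (clean_rate > 0 && !any(usable)) {
    stop("catalog has no references for the configured class weights")
  }
  set.seed(config$seed)
  n <- config$library_size
  category <- sample(c(FILTER_CATEGORIES, "clean"), n, replace = TRUE,
                     prob = c(config$artifact_rates, clean_rate))

  # per-reference sampling weights: class weight split over its references,
  # then per-reference fold multipliers
  w <- rep(0, nrow(catalog))
  for (cls in names(config$class_weights)) {
    in_cls <- which(catalog$rna_class == cls)
    if (length(in_cls)) {
      w[in_cls] <- config$class_weights[[cls]] / length(in_cls)
    }
  }
  if (!is.null(fold_changes)) {
    if (any(fold_changes <= 0)) stop("fold changes must be positive")
    idx <- match(names(fold_changes), catalog$id)
    if (anyNA(idx)) stop("fold_changes names must be catalog reference ids")
    w[idx] <- w[idx] * fold_changes
  }
  if (clean_rate > 0 && sum(w) <= 0) stop("all reference weights are zero")
  prob <- w / sum(w)

  seqs <- character(n)
  quals <- character(n)
  truth_source <- rep(NA_character_, n)
  truth_insert <- rep(NA_character_, n)

  ## clean reads
  i_clean <- which(category == "clean")
  if (length(i_clean)) {
    ref_idx <- sample.int(nrow(catalog), length(i_clean), replace = TRUE,
                          prob = prob)
    inserts <- draw_inserts(ref_idx, catalog, config)
    if (!config$ambiguous) {
      for (round in 1:25) {
        bad <- which(!clean_insert_ok(inserts, config))
        if (!length(bad)) break
        ref_idx[bad] <- sample.int(nrow(catalog), length(bad), replace = TRUE,
                                   prob = prob)
        inserts[bad] <- draw_inserts(ref_idx[bad], catalog, config)
      }
      if (length(which(!clean_insert_ok(inserts, config)))) {
        stop("could not draw unambiguous clean inserts; check catalog/adapters")
      }
    }
    seqs[i_clean] <- assemble_reads(inserts, config)
    quals[i_clean] <- high_quality(length(i_clean), config$read_length)
    truth_source[i_clean] <- catalog$id[ref_idx]
    truth_insert[i_clean] <- inserts
  }

  ## artifact reads, each built to its own rule
  probe <- substr(config$adapter3, 1L, 6L)

  i_a3 <- which(category == "adapter3_null")
  if (length(i_a3)) {
    s <- random_dna(length(i_a3), config$read_length)
    if (!config$ambiguous) {
      repeat {
        bad <- which(!is.na(find_adapter3(s, config$adapter3, 6L)))
        if (!length(bad)) break
        s[bad] <- random_dna(length(bad), config$read_length)
      }
    }
    seqs[i_a3] <- s
    quals[i_a3] <- high_quality(length(i_a3), config$read_length)
  }

  i_in <- which(category == "insert_null")
  if (length(i_in)) {
    seqs[i_in] <- assemble_reads(rep("", length(i_in)), config)
    quals[i_in] <- high_quality(length(i_in), config$read_length)
  }

  i_a5 <- which(category == "adapter5_contaminant")
  if (length(i_a5)) {
    k <- length(i_a5)
    run_len <- sample(10:14, k, replace = TRUE)
    run_start <- vapply(run_len, function(r) {
      sample.int(nchar(config$adapter5) - r + 1L, 1L)
    }, integer(1))
    run <- substr(rep(config$adapter5, k), run_start,
                  run_start + run_len - 1L)
    tail_len <- pmax(0L, sample(18:25, k, replace = TRUE) - run_len)
    ins <- paste0(run, random_dna(k, tail_len))
    if (!config$ambiguous) {
      repeat {
        bad <- which(grepl(probe, ins, fixed = TRUE))
        if (!length(bad)) break
        ins[bad] <- paste0(run[bad], random_dna(length(bad), tail_len[bad]))
      }
    }
    seqs[i_a5] <- assemble_reads(ins, config)
    quals[i_a5] <- high_quality(k, config$read_length)
  }

  i_iq <- which(category == "inferior_quality")
  if (length(i_iq)) {
    k <- length(i_iq)
    ilen <- sample(17:30, k, replace = TRUE)
    ins <- random_dna(k, ilen)
    if (!config$ambiguous) {
      repeat {
        bad <- which(grepl(probe, ins, fixed = TRUE) |
                       contains_adapter_run(ins, config$adapter5, 10L) |
                       max_base_fraction(ins) >= 0.8)
        if (!length(bad)) break
        ins[bad] <- random_dna(length(bad), ilen[bad])
      }
    }
    seqs[i_iq] <- assemble_reads(ins, config)
    # insert bases well below Q20, remainder high
    quals[i_iq] <- vapply(seq_len(k), function(j) {
      lo <- sample(5:15, ilen[j], replace = TRUE)
      hi <- sample(33:40, config$read_length - ilen[j], replace = TRUE)
      phred_string(c(lo, hi))
    }, character(1))
  }

  i_ts <- which(category == "too_short")
  if (length(i_ts)) {
    k <- length(i_ts)
    ilen <- sample(10:16, k, replace = TRUE)
    ins <- random_dna(k, ilen)
    if (!config$ambiguous) {
      repeat {
        bad <- which(grepl(probe, ins, fixed = TRUE) |
                       contains_adapter_run(ins, config$adapter5, 10L))
        if (!length(bad)) break
        ins[bad] <- random_dna(length(bad), ilen[bad])
      }
    }
    seqs[i_ts] <- assemble_reads(ins, config)
    quals[i_ts] <- high_quality(k, config$read_length)
  }

  i_po <- which(category == "poly_repeat")
  if (length(i_po)) {
    k <- length(i_po)
    base <- sample(c(BASES, "N"), k, replace = TRUE)
    ilen <- sample(17:25, k, replace = TRUE)
    ins <- strrep(base, ilen)
    seqs[i_po] <- assemble_reads(ins, config)
    quals[i_po] <- high_quality(k, config$read_length)
  }

  read_id <- sprintf("read%07d", seq_len(n))
  copies <- table(factor(truth_source[i_clean], levels = catalog$id))
  copy_counts <- data.frame(
    reference_id = catalog$id,
    rna_class = catalog$rna_class,
    true_copies = as.integer(copies),
    expected_copies = n * clean_rate * prob,
    stringsAsFactors = FALSE
  )
  structure(list(
    reads = data.frame(read_id = read_id, seq = seqs, qual = quals,
                       stringsAsFactors = FALSE),
    truth = data.frame(read_id = read_id, category = category,
                       source_id = truth_source, insert = truth_insert,
                       stringsAsFactors = FALSE),
    copy_counts = copy_counts,
    config = config
  ), class = "ev_sim")
}

# class-law insert for each sampled reference (5' fragment or full mature)
draw_inserts <- function(ref_idx, catalog, config) {
  cls <- catalog$rna_class[ref_idx]
  ref_seq <- catalog$seq[ref_idx]
  target <- nchar(ref_seq)
  for (cl in unique(cls)) {
    law <- config$insert_laws[[cl]]
    if (is.null(law) || length(law$lengths) == 1L && is.na(law$lengths[1L])) {
      next  # full reference
    }
    sel <- which(cls == cl)
    target[sel] <- sample(law$lengths, length(sel), replace = TRUE,
                          prob = law$probs)
  }
  substr(ref_seq, 1L, pmin(target, nchar(ref_seq)))
}

#' Simulate a two-group experiment with planted fold changes
#'
#' Generates one library per group from the same configuration and catalog;
#' group B multiplies the sampling weights of the features named in
#' `fold_change_map`. Because each library has a fixed size, planting a fold
#' change renormalizes all relative abundances; the returned truth therefore
#' records, per reference, the exact expected copies in both groups and the
#' realized log2 fold change of relative abundance (which equals
#' `log2(fold_change)` up to the renormalization constant).
#'
#' @param config A [simulation_config()] (its `seed` is ignored here).
#' @param catalog A `small_rna_catalog`.
#' @param fold_change_map Named positive multipliers keyed by reference id
#'   (typically miRNA ids).
#' @param seedA,seedB Seeds for the two libraries.
#' @return List of class `ev_sim2` with `sim_a`, `sim_b` and `truth` (per
#'   reference: requested fold change, expected copies per group, planted
#'   log2 fold change of relative abundance).
#' @export
simulate_two_group <- function(config, catalog, fold_change_map = NULL,
                               seedA = 1L, seedB = 2L) {
  if (!is.null(fold_change_map)) {
    if (any(fold_change_map <= 0)) stop("fold changes must be positive")
    if (!all(names(fold_change_map) %in% catalog$id)) {
      stop("fold_change_map names must be catalog reference ids")
    }
  }
  cfg_a <- config; cfg_a$seed <- as.integer(seedA)
  cfg_b <- config; cfg_b$seed <- as.integer(seedB)
  sim_a <- simulate_library(cfg_a, catalog)
  sim_b <- simulate_library(cfg_b, catalog, fold_changes = fold_change_map)
  fc <- setNames(rep(1, nrow(catalog)), catalog$id)
  if (!is.null(fold_change_map)) fc[names(fold_change_map)] <- fold_change_map
  ea <- sim_a$copy_counts$expected_copies
  eb <- sim_b$copy_counts$expected_copies
  truth <- data.frame(
    reference_id = catalog$id,
    rna_class = catalog$rna_class,
    fold_change = unname(fc),
    expected_copies_a = ea,
    expected_copies_b = eb,
    planted_log2fc = ifelse(ea > 0 & eb > 0, log2(eb / ea), NA_real_),
    stringsAsFactors = FALSE
  )
  structure(list(sim_a = sim_a, sim_b = sim_b, truth = truth),
            class = "ev_sim2")
}

#' Simulate per-feature count pairs for differential-expression studies
#'
#' Count-level companion to the read-level generator: draws a pair of counts
#' per feature, negative-binomial with dispersion `phi` (Poisson when
#' `phi = 0`), with group-B means multiplied by the planted fold changes.
#'
#' @param n_features Number of features.
#' @param mean_range Range of baseline expected counts; feature means are
#'   drawn log-uniformly within it.
#' @param fold_changes Vector of per-feature fold changes (recycled; 1 =
#'   null feature).
#' @param phi Negative-binomial dispersion (0 for Poisson).
#' @param seed Integer seed.
#' @return Data frame `feature_id`, `mean_a`, `fold_change`, `count_a`,
#'   `count_b`.
#' @export
simulate_count_pairs <- function(n_features, mean_range = c(100, 1000),
                                 fold_changes = 1, phi = 0, seed = 1L) {
  stopifnot(n_features > 0L, phi >= 0, all(fold_changes > 0))
  set.seed(seed)
  mu <- exp(runif(n_features, log(mean_range[1L]), log(mean_range[2L])))
  fc <- rep_len(fold_changes, n_features)
  draw <- function(m) {
    if (phi == 0) rpois(length(m), m) else rnbinom(length(m), mu = m, size = 1 / phi)
  }
  data.frame(feature_id = sprintf("feat%04d", seq_len(n_features)),
             mean_a = mu,
             fold_change = fc,
             count_a = draw(mu),
             count_b = draw(mu * fc),
             stringsAsFactors = FALSE)
}

#' Write a simulated library to FASTQ and its truth to TSV
#'
#' @param sim An `ev_sim` from [simulate_library()].
#' @param fastq_path Output FASTQ path.
#' @param truth_path Optional output TSV path for the per-read ground truth.
#' @return Invisibly, `fastq_path`.
#' @export
write_simulated_library <- function(sim, fastq_path, truth_path = NULL) {
  write_fastq(sim$reads, fastq_path)
  if (!is.null(truth_path)) {
    write_tsv(sim$truth, truth_path)
  }
  invisible(fastq_path)
}
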
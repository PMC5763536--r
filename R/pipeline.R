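# End-to-end orchestration: simulate (optional) -> filter -> annotate ->
# quantify -> differential expression, with deterministic TSV outputs and a
# run manifest.

#' Pipeline configuration
#'
#' @param outdir Output directory (created if missing).
#' @param fastq_a,fastq_b Paths to the two group FASTQ files; leave `NULL`
#'   to simulate them (`simulate = TRUE`).
#' @param catalog_fasta,catalog_metadata Reference catalog paths; `NULL`
#'   with `simulate = TRUE` uses a synthetic catalog.
#' @param group_names Labels of the two groups.
#' @param simulate Generate the two libraries with [simulate_two_group()].
#' @param sim_config A [simulation_config()] used when simulating.
#' @param fold_change_map Planted fold changes for the simulated group B.
#' @param filter A [filter_config()].
#' @param de A [de_config()].
#' @param max_mismatches Annotation mismatch bound.
#' @param min_copies miRNA copy-number floor.
#' @param bin_size Chromosome-abundance bin width.
#' @param seed Master seed; the two simulated libraries use `seed` and
#'   `seed + 1`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            fastq_a = NULL, fastq_b = NULL,
                            catalog_fasta = NULL, catalog_metadata = NULL,
                            group_names = c("ADC", "CTRL"),
                            simulate = is.null(fastq_a),
                            sim_config = simulation_config(),
                            fold_change_map = NULL,
                            filter = filter_config(),
                            de = de_config(),
                            max_mismatches = 0L,
                            min_copies = 10L,
                            bin_size = 1e6,
                            seed = 1L) {
  stopifnot(length(group_names) == 2L)
  structure(list(outdir = outdir, fastq_a = fastq_a, fastq_b = fastq_b,
                 catalog_fasta = catalog_fasta,
                 catalog_metadata = catalog_metadata,
                 group_names = group_names, simulate = simulate,
                 sim_config = sim_config, fold_change_map = fold_change_map,
                 filter = filter, de = de,
                 max_mismatches = as.integer(max_mismatches),
                 min_copies = as.integer(min_copies),
                 bin_size = bin_size, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the small-RNA pipeline end to end
#'
#' Executes (optional) simulation, read filtering, tag annotation, miRNA
#' quantification and differential expression for two groups, writing every
#' table as TSV under `config$outdir` plus a plain-text run manifest.
#' Identical inputs and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param catalog Optional pre-loaded `small_rna_catalog` (overrides the
#'   catalog paths).
#' @return Invisibly, a list with the per-group filter reports, composition
#'   tables, miRNA calls, the DE table and the output file paths.
#' @export
run_pipeline <- function(config, catalog = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  grp <- config$group_names
  log_stage <- function(...) message("[evsmallrna] ", ...)

  if (is.null(catalog)) {
    if (!is.null(config$catalog_fasta)) {
      log_stage("loading catalog: ", config$catalog_fasta)
      catalog <- load_catalog(config$catalog_fasta, config$catalog_metadata)
    } else {
      log_stage("generating synthetic catalog")
      catalog <- synthetic_catalog(seed = config$seed + 1000L)
    }
  }

  fastq <- list(config$fastq_a, config$fastq_b)
  truth <- NULL
  if (config$simulate) {
    log_stage("simulating two-group libraries (seed ", config$seed, ")")
    sim2 <- simulate_two_group(config$sim_config, catalog,
                               fold_change_map = config$fold_change_map,
                               seedA = config$seed,
                               seedB = config$seed + 1L)
    fastq <- list(file.path(outdir, paste0(grp[1L], ".fastq")),
                  file.path(outdir, paste0(grp[2L], ".fastq")))
    write_simulated_library(sim2$sim_a, fastq[[1L]])
    write_simulated_library(sim2$sim_b, fastq[[2L]])
    truth <- sim2$truth
    write_tsv(truth, file.path(outdir, "ground_truth.tsv"))
  }

  reports <- list(); compositions <- list(); calls <- list()
  clean_totals <- c(0, 0); names(clean_totals) <- grp
  for (k in 1:2) {
    g <- grp[k]
    log_stage("filtering ", g, ": ", fastq[[k]])
    fl <- filter_library(fastq[[k]], config$filter)
    reports[[g]] <- fl$report
    write_tsv(fl$report, file.path(outdir, paste0(g, "_filter_report.tsv")))
    clean_reads <- fl$report$count[fl$report$category == "clean_reads"]
    clean_totals[g] <- clean_reads

    log_stage("annotating ", g, " (", nrow(fl$clean), " clean reads)")
    tags <- collapse_reads(fl$clean$insert)
    ann <- align_tags(tags, catalog, config$max_mismatches)
    write_tsv(ann$tags, file.path(outdir, paste0(g, "_annotation.tsv")))
    comp <- class_composition(ann, clean_reads)
    compositions[[g]] <- comp
    write_tsv(comp, file.path(outdir, paste0(g, "_composition.tsv")))
    lens <- do.call(rbind, lapply(RNA_CLASSES, function(cl) {
      d <- length_distribution(ann, cl, clean_reads)
      d$rna_class <- cl
      d
    }))
    write_tsv(lens, file.path(outdir, paste0(g, "_length_distribution.tsv")))
    chrom <- chromosome_abundance(ann, catalog, config$bin_size, clean_reads)
    write_tsv(chrom, file.path(outdir, paste0(g, "_chromosome_abundance.tsv")))

    log_stage("quantifying miRNAs in ", g)
    qc <- quantify_mirnas(tags, catalog, clean_reads,
                          min_copies = config$min_copies)
    calls[[g]] <- qc
    write_tsv(qc, file.path(outdir, paste0(g, "_mirna_calls.tsv")))
  }

  expr <- build_expression_matrix(calls, clean_totals)
  expr_df <- data.frame(mirna_id = rownames(expr$rpm), expr$rpm,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(expr_df, file.path(outdir, "expression_rpm.tsv"))

  log_stage("differential expression (phi = ", config$de$phi, ")")
  de <- run_diffexp(expr$counts[, grp[1L]], expr$counts[, grp[2L]],
                    clean_totals[grp[1L]], clean_totals[grp[2L]],
                    config$de)
  write_tsv(de, file.path(outdir, "diffexp.tsv"))

  hm <- heatmap_matrix(expr, pseudo = config$de$pseudo)
  if (nrow(hm)) {
    hm_df <- data.frame(mirna_id = rownames(hm), hm,
                        check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(hm_df, file.path(outdir, "heatmap_matrix.tsv"))
  }

  manifest <- c(
    paste0("package_version\t", as.character(utils::packageVersion("evsmallrna"))),
    paste0("seed\t", config$seed),
    paste0("groups\t", paste(grp, collapse = ",")),
    paste0("simulate\t", config$simulate),
    paste0("max_mismatches\t", config$max_mismatches),
    paste0("min_copies\t", config$min_copies),
    paste0("bin_size\t", format(config$bin_size, scientific = FALSE)),
    paste0("phi\t", config$de$phi),
    paste0("alpha_p\t", config$de$alpha_p),
    paste0("alpha_fdr\t", config$de$alpha_fdr),
    paste0("min_abs_log2fc\t", config$de$min_abs_log2fc),
    paste0("pseudo\t", config$de$pseudo),
    paste0("adapter3\t", config$filter$adapter3),
    paste0("adapter5\t", config$filter$adapter5),
    paste0("clean_reads_", grp[1L], "\t", clean_totals[grp[1L]]),
    paste0("clean_reads_", grp[2L], "\t", clean_totals[grp[2L]])
  )
  writeLines(manifest, file.path(outdir, "manifest.txt"))

  invisible(list(reports = reports, compositions = compositions,
                 calls = calls, expression = expr, diffexp = de,
                 truth = truth, outdir = outdir,
                 files = list.files(outdir, full.names = TRUE)))
}

#' Summarize pipeline outputs as plain text
#'
#' @param outputs The list returned by [run_pipeline()].
#' @return Character vector of report lines (invisibly printed with
#'   `cat`-style newlines by the caller).
#' @export
make_report <- function(outputs) {
  stopifnot(is.list(outputs), !is.null(outputs$reports))
  lines <- character(0)
  for (g in names(outputs$reports)) {
    rp <- outputs$reports[[g]]
    lines <- c(lines, paste0("== Filtering (", g, ") =="),
               sprintf("%-22s %12d %7.2f%%", rp$category, rp$count,
                       rp$percent))
  }
  for (g in names(outputs$compositions)) {
    cp <- outputs$compositions[[g]]
    lines <- c(lines, paste0("== Class composition (", g, ") =="),
               sprintf("%-8s %12d %7.2f%%", cp$rna_class, cp$copies,
                       cp$percent))
  }
  de <- outputs$diffexp
  if (!is.null(de) && nrow(de)) {
    s <- attr(de, "de_summary")
    lines <- c(lines, "== Differential expression ==",
               sprintf("features tested: %d", nrow(de)),
               sprintf("significant up: %d", s[["up"]]),
               sprintf("significant down: %d", s[["down"]]))
  } else {
    lines <- c(lines, "== Differential expression ==",
               "features tested: 0", "significant up: 0",
               "significant down: 0")
  }
  lines
}
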
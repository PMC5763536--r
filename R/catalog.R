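#' @importFrom utils read.delim write.table
#' @importFrom stats setNames
NULL

# Recognized small-RNA classes, in the default priority order used when a tag
# matches references of several classes equally well. "other" is implicit.
RNA_CLASSES <- c("miRNA", "YRNA", "tRNA", "rRNA", "snRNA", "snoRNA", "piRNA")

#' Default class priority
#'
#' Order in which ncRNA classes win ties when a tag matches references of
#' several classes at the same mismatch count. miRNA ranks first; "other" is
#' always implicit last.
#'
#' @return Character vector of class labels.
#' @export
default_class_priority <- function() RNA_CLASSES

#' Load a small-RNA reference catalog
#'
#' Reads mature small-RNA sequences from a FASTA file and their annotations
#' (class label, optional precursor link, optional genomic locus) from a
#' tab-delimited metadata table. Sequences are uppercased and RNA alphabet (U)
#' is converted to DNA (T); all downstream comparisons are DNA-space.
#'
#' @param fasta_path Path to a FASTA file of mature reference sequences.
#' @param metadata_path Path to a tab-delimited table with columns `id` and
#'   `rna_class`, and optionally `precursor_id`, `mature_offset` (0-based
#'   offset of the mature 5' end within its precursor), `chrom`, `start`,
#'   `end`, `strand`. Loci are 0-based half-open (BED convention).
#' @param class_priority Class precedence for tie-breaking; a permutation of
#'   the classes present.
#' @return An object of class `small_rna_catalog`: a data frame with one row
#'   per reference (columns `id`, `seq`, `rna_class`, `precursor_id`,
#'   `mature_offset`, `chrom`, `start`, `end`, `strand`) and a
#'   `class_priority` attribute.
#' @examples
#' fa <- system.file("extdata", "demo_catalog.fasta", package = "evsmallrna")
#' md <- system.file("extdata", "demo_catalog.tsv", package = "evsmallrna")
#' cat <- load_catalog(fa, md)
#' table(cat$rna_class)
#' @export
load_catalog <- function(fasta_path, metadata_path,
                         class_priority = default_class_priority()) {
  # read as raw strings: RNA-alphabet (U) references are normalized to DNA
  # below, and invalid characters are reported as errors rather than dropped
  seqs <- Biostrings::readBStringSet(fasta_path)
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("id", "rna_class") %in% names(meta))) {
    stop("metadata must have columns 'id' and 'rna_class'")
  }
  ids <- names(seqs)
  # FASTA descriptions may carry trailing free text after the identifier
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    stop("duplicate reference id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(meta$id)) {
    stop("duplicate metadata id(s): ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  }
  if (!setequal(ids, meta$id)) {
    stop("FASTA ids and metadata ids do not match")
  }
  meta <- meta[match(ids, meta$id), , drop = FALSE]
  bad_class <- setdiff(unique(meta$rna_class), RNA_CLASSES)
  if (length(bad_class)) {
    stop("unknown rna_class label(s): ", paste(bad_class, collapse = ", "))
  }
  seq_chr <- toupper(as.character(seqs))
  seq_chr <- gsub("U", "T", seq_chr, fixed = TRUE)
  if (any(grepl("[^ACGTN]", seq_chr))) {
    stop("reference sequence(s) contain characters outside {A,C,G,T,U,N}")
  }
  if (any(nchar(seq_chr) == 0L)) stop("empty reference sequence")

  cat_df <- data.frame(
    id = ids,
    seq = unname(seq_chr),
    rna_class = meta$rna_class,
    precursor_id = if ("precursor_id" %in% names(meta)) meta$precursor_id else NA_character_,
    mature_offset = if ("mature_offset" %in% names(meta)) as.integer(meta$mature_offset) else NA_integer_,
    chrom = if ("chrom" %in% names(meta)) meta$chrom else NA_character_,
    start = if ("start" %in% names(meta)) as.integer(meta$start) else NA_integer_,
    end = if ("end" %in% names(meta)) as.integer(meta$end) else NA_integer_,
    strand = if ("strand" %in% names(meta)) meta$strand else NA_character_,
    stringsAsFactors = FALSE
  )
  cat_df$precursor_id[!is.na(cat_df$precursor_id) & cat_df$precursor_id == ""] <- NA_character_
  cat_df$chrom[!is.na(cat_df$chrom) & cat_df$chrom == ""] <- NA_character_
  new_catalog(cat_df, class_priority)
}

#' Construct a catalog from an in-memory data frame
#'
#' @param records Data frame with at least `id`, `seq`, `rna_class`; optional
#'   `precursor_id`, `mature_offset`, `chrom`, `start`, `end`, `strand`.
#' @param class_priority Class precedence order.
#' @return A `small_rna_catalog`.
#' @export
new_catalog <- function(records, class_priority = default_class_priority()) {
  stopifnot(is.data.frame(records),
            all(c("id", "seq", "rna_class") %in% names(records)))
  for (col in c("precursor_id", "chrom", "strand")) {
    if (is.null(records[[col]])) records[[col]] <- NA_character_
  }
  for (col in c("mature_offset", "start", "end")) {
    if (is.null(records[[col]])) records[[col]] <- NA_integer_
  }
  records$seq <- gsub("U", "T", toupper(records$seq), fixed = TRUE)
  validate_catalog(records, class_priority)
  rownames(records) <- NULL
  structure(records,
            class = c("small_rna_catalog", "data.frame"),
            class_priority = class_priority)
}

validate_catalog <- function(records, class_priority) {
  if (anyDuplicated(records$id)) {
    stop("duplicate reference id(s): ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  }
  if (any(nchar(records$seq) == 0L)) stop("empty reference sequence")
  if (any(grepl("[^ACGTN]", records$seq))) {
    stop("reference sequence(s) contain characters outside {A,C,G,T,U,N}")
  }
  bad_class <- setdiff(unique(records$rna_class), RNA_CLASSES)
  if (length(bad_class)) {
    stop("unknown rna_class label(s): ", paste(bad_class, collapse = ", "))
  }
  if (!all(unique(records$rna_class) %in% class_priority)) {
    stop("class_priority must cover every class present in the catalog")
  }
  mir <- records$rna_class == "miRNA"
  if (any(mir & (is.na(records$precursor_id) | records$precursor_id == ""))) {
    stop("miRNA records must carry a precursor_id")
  }
  has_locus <- !is.na(records$chrom)
  if (any(has_locus & (is.na(records$start) | is.na(records$end)))) {
    stop("locus rows need both start and end")
  }
  if (any(has_locus & records$end <= records$start)) {
    stop("locus end must be greater than start (0-based half-open)")
  }
  invisible(records)
}

#' Class priority of a catalog
#' @param catalog A `small_rna_catalog`.
#' @return Character vector of class labels in priority order.
#' @export
class_priority <- function(catalog) attr(catalog, "class_priority")

#' Read genomic loci from a BED file into a catalog
#'
#' Attaches 0-based half-open loci (one per reference, matched by BED name
#' field) to an existing catalog, overwriting any loci present.
#'
#' @param catalog A `small_rna_catalog`.
#' @param bed_path Path to a BED file whose name column holds reference ids.
#' @return The catalog with `chrom`, `start`, `end`, `strand` filled in.
#' @export
attach_loci <- function(catalog, bed_path) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  idx <- match(catalog$id, gr$name)
  hit <- !is.na(idx)
  catalog$chrom[hit] <- as.character(GenomeInfoDb::seqnames(gr))[idx[hit]]
  # GRanges is 1-based closed; store 0-based half-open
  catalog$start[hit] <- BiocGenerics::start(gr)[idx[hit]] - 1L
  catalog$end[hit] <- BiocGenerics::end(gr)[idx[hit]]
  catalog$strand[hit] <- as.character(BiocGenerics::strand(gr))[idx[hit]]
  validate_catalog(catalog, class_priority(catalog))
  catalog
}

#' Reverse complement of a DNA sequence
#'
#' @param seq A single character string over \{A,C,G,T,N\} (lower case
#'   accepted). The empty string maps to itself.
#' @return The reverse complement, uppercase.
#' @examples
#' reverse_complement("AGTTCTGATAACCCACTACCATCGGACCAGCC")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("invalid character in sequence")
  if (nchar(seq) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Locate a fragment within a reference sequence
#'
#' Finds every exact occurrence of `fragment`, or of its reverse complement,
#' inside a reference sequence. An `N` never matches anything, so fragments or
#' references containing `N` yield no hits at those positions.
#'
#' @param fragment Query sequence (character, non-empty).
#' @param record Either a reference sequence (character) or a single catalog
#'   row with a `seq` column.
#' @return Data frame with columns `offset` (0-based) and `strand`
#'   (`"+"` for the fragment itself, `"-"` for its reverse complement);
#'   zero rows when absent.
#' @export
locate_fragment <- function(fragment, record) {
  seq <- if (is.data.frame(record)) record$seq[1L] else record
  stopifnot(is.character(fragment), length(fragment) == 1L, nchar(fragment) > 0L,
            is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  fragment <- toupper(fragment)
  hits_fw <- exact_offsets(fragment, seq)
  hits_rv <- exact_offsets(reverse_complement(fragment), seq)
  out <- data.frame(
    offset = c(hits_fw, hits_rv),
    strand = c(rep("+", length(hits_fw)), rep("-", length(hits_rv))),
    stringsAsFactors = FALSE
  )
  out[order(out$offset, out$strand), , drop = FALSE]
}

# 0-based offsets of exact occurrences, overlapping included (N matches
# nothing)
exact_offsets <- function(pattern, subject) {
  if (nchar(pattern) > nchar(subject)) return(integer(0))
  if (grepl("N", pattern, fixed = TRUE)) return(integer(0))
  m <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  pos <- as.integer(m)
  # drop windows that run across an N in the subject
  plen <- nchar(pattern)
  keep <- vapply(pos, function(p) {
    !grepl("N", substr(subject, p, p + plen - 1L), fixed = TRUE)
  }, logical(1))
  pos[keep] - 1L
}

#' Write a catalog to FASTA + metadata files
#'
#' @param catalog A `small_rna_catalog`.
#' @param fasta_path Output FASTA path.
#' @param metadata_path Output tab-delimited metadata path.
#' @return Invisibly, the catalog.
#' @export
write_catalog <- function(catalog, fasta_path, metadata_path) {
  seqs <- Biostrings::DNAStringSet(setNames(catalog$seq, catalog$id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  meta <- as.data.frame(catalog)[, c("id", "rna_class", "precursor_id",
                                     "mature_offset", "chrom", "start",
                                     "end", "strand")]
  write.table(meta, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(catalog)
}
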
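#' Read per-species gene coordinates
#'
#' Reads a gene coordinate table in one of three formats and returns the
#' standard locus data frame used by all synteny operations. Coordinates are
#' stored 0-based half-open (BED convention); GFF3 1-based closed coordinates
#' are converted on read.
#'
#' @param path Path to the input file.
#' @param species_id Species identifier attached to every locus.
#' @param format `"tsv"` (5 columns: gene_id, chromosome, start, end, strand,
#'   with a header row), `"bed"` (BED6, no header; the name field is the gene
#'   id) or `"gff3"` (gene features; requires the rtracklayer package).
#' @return A data frame with columns `gene_id`, `species_id`,
#'   `chromosome_id`, `start`, `end`, `strand`.
#' @export
read_gene_loci <- function(path, species_id, format = c("tsv", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    check_columns(df, c("gene_id", "chromosome", "start", "end", "strand"),
                  sprintf("gene coordinate table '%s'", path))
    loci <- data.frame(
      gene_id = as.character(df$gene_id),
      species_id = species_id,
      chromosome_id = as.character(df$chromosome),
      start = as.integer(df$start),
      end = as.integer(df$end),
      strand = as.character(df$strand),
      stringsAsFactors = FALSE
    )
  } else if (format == "bed") {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 6L) {
      stop_fmt("BED6 file '%s' has %d columns; 6 required", path, ncol(df))
    }
    loci <- data.frame(
      gene_id = as.character(df[[4L]]),
      species_id = species_id,
      chromosome_id = as.character(df[[1L]]),
      start = as.integer(df[[2L]]),
      end = as.integer(df[[3L]]),
      strand = as.character(df[[6L]]),
      stringsAsFactors = FALSE
    )
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop_fmt("reading GFF3 requires the 'rtracklayer' package")
    }
    gff <- rtracklayer::readGFF(path)
    gff <- gff[gff$type == "gene", , drop = FALSE]
    ids <- as.character(gff$ID %||% gff$gene_id)
    loci <- data.frame(
      gene_id = ids,
      species_id = species_id,
      chromosome_id = as.character(gff$seqid),
      start = as.integer(gff$start) - 1L,  # to 0-based half-open
      end = as.integer(gff$end),
      strand = as.character(gff$strand),
      stringsAsFactors = FALSE
    )
  }
  loci$strand[!loci$strand %in% c("+", "-")] <- "unknown"
  validate_gene_loci(loci)
}

#' Validate a locus table
#'
#' Checks the invariants of the locus representation: `start < end`,
#' non-empty chromosome ids, and gene ids unique within each species.
#'
#' @param loci A locus data frame as returned by [read_gene_loci()].
#' @return The validated data frame, invisibly usable in pipelines.
#' @export
validate_gene_loci <- function(loci) {
  check_columns(loci, c("gene_id", "species_id", "chromosome_id",
                        "start", "end", "strand"), "locus table")
  if (any(loci$start >= loci$end)) {
    bad <- loci$gene_id[loci$start >= loci$end][1L]
    stop_fmt("locus '%s' has start >= end (coordinates are 0-based half-open)", bad)
  }
  if (any(!nzchar(loci$chromosome_id))) {
    stop_fmt("empty chromosome_id in locus table")
  }
  key <- paste(loci$species_id, loci$gene_id)
  if (anyDuplicated(key)) {
    stop_fmt("duplicated gene_id within species: %s", key[duplicated(key)][1L])
  }
  loci
}

#' Read a single-copy orthology table
#'
#' One row per gene family, first column `family_id`, one column per species
#' holding that species' gene id (empty cell = family absent from the
#' species). Compatible with OrthoFinder single-copy orthologue exports after
#' adding a family id column header.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A data frame with column `family_id` and one character column per
#'   species; absent genes are `NA`.
#' @export
read_orthology <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, "family_id", sprintf("orthology table '%s'", path))
  for (col in setdiff(names(df), "family_id")) {
    v <- as.character(df[[col]])
    v[!nzchar(v)] <- NA_character_
    df[[col]] <- v
  }
  if (anyDuplicated(df$family_id)) {
    stop_fmt("duplicated family_id in orthology table: %s",
             df$family_id[duplicated(df$family_id)][1L])
  }
  validate_orthology(df)
}

validate_orthology <- function(orthology) {
  check_columns(orthology, "family_id", "orthology table")
  for (col in orthology_species(orthology)) {
    v <- orthology[[col]]
    dup <- v[!is.na(v)][duplicated(v[!is.na(v)])]
    if (length(dup) > 0L) {
      stop_fmt("gene '%s' of species '%s' appears in more than one family",
               dup[1L], col)
    }
  }
  orthology
}

orthology_species <- function(orthology) setdiff(names(orthology), "family_id")

#' Families with exactly one gene in every species of the table
#' @param orthology An orthology data frame.
#' @return Character vector of single-copy family ids.
#' @export
single_copy_families <- function(orthology) {
  sp <- orthology_species(orthology)
  keep <- rowSums(!is.na(as.matrix(orthology[sp]))) == length(sp)
  orthology$family_id[keep]
}

#' The 24 bilaterian ancestral linkage group labels
#'
#' Default label set for the chromosome units of the bilaterian ancestor.
#' Any label set can be supplied instead wherever these are used.
#'
#' @return Character vector of 24 labels.
#' @export
alg_labels <- function() {
  c("A1a", "A1b", "A2", "B1", "B2", "B3", "C1", "C2", "D", "E", "F", "G",
    "H", "I", "J1", "J2", "K", "L", "M", "N", "O1", "O2", "Q", "R")
}

#' Read an ALG reference table
#'
#' Two tab-separated columns mapping a family id (or reference-species gene
#' id) to an ALG label.
#'
#' @param path Path to the file (header row `family_id`, `alg`).
#' @param labels Full ordered label set; defaults to [alg_labels()].
#' @return Data frame with columns `family_id`, `alg` and attribute
#'   `alg_labels`.
#' @export
read_alg_reference <- function(path, labels = alg_labels()) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("family_id", "alg"), sprintf("ALG reference '%s'", path))
  make_alg_reference(df$family_id, df$alg, labels)
}

#' Construct an ALG reference in memory
#' @param family_id Character vector of family (or gene) ids.
#' @param alg Character vector of ALG labels, same length.
#' @param labels Full ordered label set.
#' @return Data frame with columns `family_id`, `alg` and attribute
#'   `alg_labels`.
#' @export
make_alg_reference <- function(family_id, alg, labels = alg_labels()) {
  if (anyDuplicated(family_id)) {
    stop_fmt("ALG reference maps '%s' more than once",
             family_id[duplicated(family_id)][1L])
  }
  bad <- setdiff(unique(alg), labels)
  if (length(bad) > 0L) {
    stop_fmt("ALG reference uses label(s) absent from the label set: %s",
             paste(bad, collapse = ", "))
  }
  ref <- data.frame(family_id = as.character(family_id),
                    alg = as.character(alg), stringsAsFactors = FALSE)
  attr(ref, "alg_labels") <- labels
  ref
}

#' Read a gene-by-sample count matrix from TSV
#'
#' Genes in rows (first column = gene id), samples in columns.
#'
#' @param path Path to the tab-separated file.
#' @return Integer matrix with gene ids as rownames.
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df[[1L]])
  if (any(m < 0L)) stop_fmt("count matrix '%s' has negative entries", path)
  m
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `condition`, `stage`, `replicate` and
#' optionally `dose`.
#'
#' @param path Path to the tab-separated file.
#' @return Data frame of sample metadata.
#' @export
read_sample_meta <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample_id", "condition", "stage", "replicate"),
                sprintf("sample metadata '%s'", path))
  if (!"dose" %in% names(df)) df$dose <- NA_character_
  key <- paste(df$condition, df$stage, df$replicate, df$dose)
  if (anyDuplicated(key)) {
    stop_fmt("sample metadata has duplicated (condition, stage, replicate, dose)")
  }
  df
}

#' Read a gene phylostratum map
#'
#' Two tab-separated columns: `gene_id` and positive integer `stratum`
#' (1 = oldest class; larger = evolutionarily younger).
#'
#' @param path Path to the file.
#' @return Data frame with columns `gene_id` and `stratum`.
#' @export
read_phylostrata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("gene_id", "stratum"), sprintf("phylostratum map '%s'", path))
  df$stratum <- as.integer(df$stratum)
  if (any(is.na(df$stratum)) || any(df$stratum < 1L)) {
    stop_fmt("phylostrata must be positive integers")
  }
  df
}

# Write a data frame as the package's canonical TSV (UTF-8, header, no quotes).
write_tsv_out <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  write_tsv_out(df, path)
}
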
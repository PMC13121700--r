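#' Propagate ALG labels to genes through single-copy orthology
#'
#' A gene receives ALG label `L` exactly when its single-copy family is
#' mapped to `L` in the reference; genes of families absent from the
#' reference carry no label and are omitted. Only single-copy families
#' (one gene in every species of the orthology table) propagate labels.
#'
#' @param orthology Orthology data frame (see [read_orthology()]).
#' @param reference ALG reference (see [make_alg_reference()]).
#' @param loci Locus table covering all species of the orthology table.
#' @return Data frame with one row per labelled gene: `species_id`,
#'   `gene_id`, `family_id`, `alg`.
#' @export
assign_alg_labels <- function(orthology, reference, loci) {
  validate_orthology(orthology)
  species <- orthology_species(orthology)
  unknown <- setdiff(species, unique(loci$species_id))
  if (length(unknown) > 0L) {
    stop_fmt("orthology names species absent from the locus tables: %s",
             paste(unknown, collapse = ", "))
  }
  labels <- attr(reference, "alg_labels") %||% unique(reference$alg)
  bad <- setdiff(unique(reference$alg), labels)
  if (length(bad) > 0L) {
    stop_fmt("reference maps families to label(s) outside the label set: %s",
             paste(bad, collapse = ", "))
  }
  sc <- single_copy_families(orthology)
  fam_alg <- reference$alg[match(sc, reference$family_id)]
  keep <- !is.na(fam_alg)
  sc <- sc[keep]
  fam_alg <- fam_alg[keep]
  if (length(sc) == 0L) {
    return(data.frame(species_id = character(), gene_id = character(),
                      family_id = character(), alg = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- orthology[match(sc, orthology$family_id), , drop = FALSE]
  out <- do.call(rbind, lapply(species, function(sp) {
    data.frame(species_id = sp,
               gene_id = rows[[sp]],
               family_id = sc,
               alg = fam_alg,
               stringsAsFactors = FALSE)
  }))
  # deterministic order regardless of input row order
  out <- out[order(out$species_id, out$family_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tally ALG composition of each chromosome
#'
#' @param loci Locus table for one or more species.
#' @param labels Label assignment from [assign_alg_labels()].
#' @return Long-format data frame with columns `species_id`,
#'   `chromosome_id`, `alg`, `count`, `n_assigned` (labelled genes on the
#'   chromosome). Chromosomes carrying zero labelled genes are retained with
#'   a single `NA`-label row and `n_assigned = 0`.
#' @export
chromosome_alg_profile <- function(loci, labels) {
  validate_gene_loci(loci)
  key_loci <- paste(loci$species_id, loci$gene_id)
  key_lab <- paste(labels$species_id, labels$gene_id)
  missing <- setdiff(key_lab, key_loci)
  if (length(missing) > 0L) {
    stop_fmt("label map refers to gene(s) absent from the locus table: %s",
             missing[1L])
  }
  alg <- labels$alg[match(key_loci, key_lab)]
  tab <- table(chromosome = paste(loci$species_id, loci$chromosome_id,
                                  sep = "\r"),
               alg = alg, useNA = "no")
  chroms <- unique(loci[c("species_id", "chromosome_id")])
  chrom_key <- paste(chroms$species_id, chroms$chromosome_id, sep = "\r")
  out <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    if (chrom_key[i] %in% rownames(tab)) {
      counts <- tab[chrom_key[i], ]
      counts <- counts[counts > 0L]
    } else {
      counts <- integer(0)
    }
    if (length(counts) == 0L) {
      data.frame(species_id = chroms$species_id[i],
                 chromosome_id = chroms$chromosome_id[i],
                 alg = NA_character_, count = 0L, n_assigned = 0L,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(species_id = chroms$species_id[i],
                 chromosome_id = chroms$chromosome_id[i],
                 alg = names(counts), count = as.integer(counts),
                 n_assigned = sum(as.integer(counts)),
                 stringsAsFactors = FALSE)
    }
  }))
  out <- out[order(out$species_id, out$chromosome_id, out$alg,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call chromosome-ALG correspondence by hypergeometric enrichment
#'
#' For every (chromosome, ALG) pair of a species, the p-value is the
#' upper-tail hypergeometric probability of drawing at least the observed
#' number of genes of that ALG when `n_assigned` genes are sampled from the
#' genome-wide pool of labelled genes. P-values are Benjamini-Hochberg
#' adjusted within each species, and a pair is significant when
#' `q < q_threshold` and `count >= min_genes`.
#'
#' @param profile Output of [chromosome_alg_profile()].
#' @param min_genes Minimum gene count for a significant pair (default 5).
#' @param q_threshold BH-adjusted significance threshold (default 0.05).
#' @return The profile with columns `p`, `q` and `significant` added.
#' @export
call_chromosome_algs <- function(profile, min_genes = 5L, q_threshold = 0.05) {
  if (min_genes < 1L) stop_fmt("min_genes must be >= 1")
  stopifnot(q_threshold > 0, q_threshold < 1)
  profile$p <- NA_real_
  profile$q <- NA_real_
  profile$significant <- FALSE
  for (sp in unique(profile$species_id)) {
    idx <- which(profile$species_id == sp & !is.na(profile$alg))
    if (length(idx) == 0L) next
    sub <- profile[idx, , drop = FALSE]
    alg_totals <- tapply(sub$count, sub$alg, sum)
    n_total <- sum(sub$count)
    p <- phyper(sub$count - 1L,
                m = alg_totals[sub$alg],
                n = n_total - alg_totals[sub$alg],
                k = sub$n_assigned,
                lower.tail = FALSE)
    q <- p.adjust(p, method = "BH")
    profile$p[idx] <- as.numeric(p)
    profile$q[idx] <- q
    profile$significant[idx] <- q < q_threshold & sub$count >= min_genes
  }
  attr(profile, "min_genes") <- as.integer(min_genes)
  attr(profile, "q_threshold") <- q_threshold
  profile
}

#' Classify chromosomes and detect fusion and fission events
#'
#' A chromosome with exactly one significant ALG is `single_alg`; with two or
#' more it is a `fusion`; with none it is reported as `unclassified` and
#' excluded from event tallies. A fission call is emitted for every ALG
#' significant on two or more chromosomes of the same species.
#'
#' @param called Profile with enrichment calls from [call_chromosome_algs()].
#' @return A list with `status` (one row per chromosome: `species_id`,
#'   `chromosome_id`, `status`, `n_significant`, `algs` as a comma-separated
#'   string) and `fissions` (`species_id`, `alg`, `n_chromosomes`,
#'   `chromosomes` comma-separated).
#' @export
detect_fusions_fissions <- function(called) {
  check_columns(called, c("species_id", "chromosome_id", "alg", "significant"),
                "called profile")
  chroms <- unique(called[c("species_id", "chromosome_id")])
  status <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    sig <- called$alg[called$species_id == chroms$species_id[i] &
                      called$chromosome_id == chroms$chromosome_id[i] &
                      called$significant]
    sig <- sort(sig)
    data.frame(species_id = chroms$species_id[i],
               chromosome_id = chroms$chromosome_id[i],
               status = if (length(sig) == 0L) "unclassified"
                        else if (length(sig) == 1L) "single_alg" else "fusion",
               n_significant = length(sig),
               algs = paste(sig, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  status <- status[order(status$species_id, status$chromosome_id,
                         method = "radix"), , drop = FALSE]
  rownames(status) <- NULL

  sig <- called[called$significant, , drop = FALSE]
  fissions <- NULL
  if (nrow(sig) > 0L) {
    split_key <- paste(sig$species_id, sig$alg, sep = "\r")
    pieces <- split(sig$chromosome_id, split_key)
    multi <- pieces[vapply(pieces, length, 1L) >= 2L]
    if (length(multi) > 0L) {
      parts <- strsplit(names(multi), "\r", fixed = TRUE)
      fissions <- data.frame(
        species_id = vapply(parts, `[`, "", 1L),
        alg = vapply(parts, `[`, "", 2L),
        n_chromosomes = vapply(multi, length, 1L),
        chromosomes = vapply(multi, function(x)
          paste(sort(x), collapse = ","), ""),
        stringsAsFactors = FALSE
      )
      fissions <- fissions[order(fissions$species_id, fissions$alg,
                                 method = "radix"), , drop = FALSE]
      rownames(fissions) <- NULL
    }
  }
  if (is.null(fissions)) {
    fissions <- data.frame(species_id = character(), alg = character(),
                           n_chromosomes = integer(),
                           chromosomes = character(), stringsAsFactors = FALSE)
  }
  list(status = status, fissions = fissions)
}

# Number of maximal runs of identical labels along the start-sorted gene
# order of one chromosome.
count_label_runs <- function(algs_in_order) length(rle(algs_in_order)$lengths)

#' Test whether a fused chromosome's constituent ALGs are mixed
#'
#' Genes of the constituent ALGs are taken in start order (ties broken by
#' gene id) and the number of maximal same-ALG runs is compared to its
#' permutation distribution under random shuffles of the labels along the
#' chromosome. Few runs indicate the ALGs still sit in blocks; the one-sided
#' permutation p-value (add-one corrected) tests "fewer runs than expected".
#' The verdict is `blockwise` when `mixing_p < alpha`, `mixed` otherwise, and
#' `indeterminate` when any constituent ALG has fewer than two genes.
#'
#' @param loci Locus table containing the chromosome.
#' @param labels Label assignment from [assign_alg_labels()].
#' @param species_id,chromosome_id Chromosome to test.
#' @param constituent_algs Character vector of two or more ALG labels
#'   (typically the significant set of a fusion chromosome).
#' @param n_perm Number of label shuffles (default 999).
#' @param seed Seed for the permutation draw.
#' @param alpha Significance level for the blockwise call (default 0.05).
#' @return List with `runs_statistic`, `mixing_p`, `mixing`, `n_genes`.
#' @export
mixing_test <- function(loci, labels, species_id, chromosome_id,
                        constituent_algs, n_perm = 999L, seed = 1L,
                        alpha = 0.05) {
  if (length(constituent_algs) < 2L) {
    stop_fmt("mixing_test requires a fusion (>= 2 constituent ALGs); got %d",
             length(constituent_algs))
  }
  sub <- loci[loci$species_id == species_id &
              loci$chromosome_id == chromosome_id, , drop = FALSE]
  alg <- labels$alg[match(paste(species_id, sub$gene_id),
                          paste(labels$species_id, labels$gene_id))]
  keep <- !is.na(alg) & alg %in% constituent_algs
  sub <- sub[keep, , drop = FALSE]
  alg <- alg[keep]
  ord <- order_loci(sub$start, sub$gene_id)
  alg <- alg[ord]
  runs_obs <- count_label_runs(alg)
  per_alg <- table(alg)
  if (length(per_alg) < length(constituent_algs) || any(per_alg < 2L)) {
    return(list(runs_statistic = runs_obs, mixing_p = NA_real_,
                mixing = "indeterminate", n_genes = length(alg)))
  }
  perm_runs <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      count_label_runs(sample(alg))
    }, 1L)
  })
  p <- (1 + sum(perm_runs <= runs_obs)) / (1 + n_perm)
  list(runs_statistic = runs_obs,
       mixing_p = p,
       mixing = if (p < alpha) "blockwise" else "mixed",
       n_genes = length(alg))
}

#' Run the mixing test on every fusion chromosome
#'
#' Convenience wrapper applying [mixing_test()] to each `fusion` row of a
#' status table.
#'
#' @param loci,labels As for [mixing_test()].
#' @param status Status data frame from [detect_fusions_fissions()].
#' @param n_perm,seed,alpha Passed to [mixing_test()]; each chromosome uses
#'   an offset of `seed` so results do not depend on table order.
#' @return The status table with `runs_statistic`, `mixing_p` and `mixing`
#'   columns added (`NA` for non-fusions).
#' @export
classify_fusion_mixing <- function(loci, labels, status, n_perm = 999L,
                                   seed = 1L, alpha = 0.05) {
  status$runs_statistic <- NA_integer_
  status$mixing_p <- NA_real_
  status$mixing <- NA_character_
  fus <- which(status$status == "fusion")
  for (j in seq_along(fus)) {
    i <- fus[j]
    res <- mixing_test(loci, labels,
                       species_id = status$species_id[i],
                       chromosome_id = status$chromosome_id[i],
                       constituent_algs = strsplit(status$algs[i], ",")[[1L]],
                       n_perm = n_perm, seed = seed + j, alpha = alpha)
    status$runs_statistic[i] <- res$runs_statistic
    status$mixing_p[i] <- res$mixing_p
    status$mixing[i] <- res$mixing
  }
  status
}
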
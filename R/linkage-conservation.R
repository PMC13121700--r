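#' Decide whether a family's ALG association is conserved across species
#'
#' For each family, the host set in species `s` is the significant ALG set
#' of the chromosome carrying the family's gene in `s`. Under
#' `mode = "shared_alg"` the family is conserved when the intersection of
#' host sets over all required species is non-empty; under
#' `mode = "single_alg"` the intersection must contain exactly one label.
#' Families whose gene sits on a chromosome without a called profile, or on
#' an unclassified chromosome (no significant ALG), are marked unevaluable -
#' distinct from not conserved. Families missing from a required species are
#' not conserved, with the number of species observed recorded.
#'
#' @param orthology Orthology data frame.
#' @param loci Locus table for all species.
#' @param called Enrichment-called profile from [call_chromosome_algs()].
#' @param family_ids Families to evaluate (default: all in `orthology`).
#' @param required_species Species that must share the association
#'   (default: all species of the orthology table).
#' @param mode `"shared_alg"` or `"single_alg"`.
#' @return Data frame with one row per family: `family_id`,
#'   `n_species_observed`, `intersection` (comma-separated),
#'   `conserved`, `ambiguous`, `unevaluable`.
#' @export
conserved_association <- function(orthology, loci, called,
                                  family_ids = orthology$family_id,
                                  required_species = orthology_species(orthology),
                                  mode = c("shared_alg", "single_alg")) {
  mode <- match.arg(mode)
  sig <- called[called$significant, , drop = FALSE]
  sig_key <- paste(sig$species_id, sig$chromosome_id, sep = "\r")
  prof_key <- unique(paste(called$species_id, called$chromosome_id,
                           sep = "\r"))
  loci_key <- paste(loci$species_id, loci$gene_id)

  rows <- lapply(family_ids, function(fam) {
    frow <- orthology[orthology$family_id == fam, , drop = FALSE]
    if (nrow(frow) != 1L) stop_fmt("family '%s' not in orthology table", fam)
    host_sets <- list()
    unevaluable <- FALSE
    n_obs <- 0L
    for (sp in sort(required_species)) {
      gene <- frow[[sp]]
      if (is.null(gene) || is.na(gene)) next
      n_obs <- n_obs + 1L
      i <- match(paste(sp, gene), loci_key)
      if (is.na(i)) {
        stop_fmt("gene '%s' of species '%s' (family '%s') has no locus",
                 gene, sp, fam)
      }
      key <- paste(sp, loci$chromosome_id[i], sep = "\r")
      if (!key %in% prof_key) {
        unevaluable <- TRUE
        next
      }
      host <- sort(sig$alg[sig_key == key])
      if (length(host) == 0L) {
        unevaluable <- TRUE  # unclassified chromosome
        next
      }
      host_sets[[sp]] <- host
    }
    if (unevaluable) {
      return(data.frame(family_id = fam, n_species_observed = n_obs,
                        intersection = "", conserved = NA, ambiguous = NA,
                        unevaluable = TRUE, stringsAsFactors = FALSE))
    }
    all_present <- n_obs == length(required_species)
    inter <- if (length(host_sets) > 0L) Reduce(intersect, host_sets)
             else character(0)
    conserved <- all_present && length(host_sets) == length(required_species) &&
      (if (mode == "shared_alg") length(inter) >= 1L else length(inter) == 1L)
    data.frame(family_id = fam, n_species_observed = n_obs,
               intersection = paste(sort(inter), collapse = ","),
               conserved = conserved,
               ambiguous = conserved && length(inter) > 1L,
               unevaluable = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample a background set of single-copy families
#'
#' Uniform sample without replacement from the single-copy families of the
#' orthology table, reproducible under `seed`. Focal families are excluded
#' by default so the background is uncontaminated.
#'
#' @param orthology Orthology data frame.
#' @param n Sample size (default 100).
#' @param seed Seed for the draw.
#' @param exclude Family ids to remove from the eligible pool.
#' @return Character vector of `n` family ids.
#' @export
sample_background_families <- function(orthology, n = 100L, seed = 1L,
                                       exclude = character()) {
  pool <- setdiff(single_copy_families(orthology), exclude)
  if (n > length(pool)) {
    stop_fmt("requested %d background families but only %d are eligible",
             n, length(pool))
  }
  with_seed(seed, sample(pool, n))
}

# Pearson chi-square statistic of the 2x2 conserved/not x focal/background
# table, no continuity correction. Degenerate margins give 0.
pearson_chi2_2x2 <- function(k_focal, n_focal, k_bg, n_bg) {
  n <- n_focal + n_bg
  k <- k_focal + k_bg
  E <- c(n_focal * k, n_focal * (n - k), n_bg * k, n_bg * (n - k)) / n
  if (any(E == 0)) return(0)
  O <- c(k_focal, n_focal - k_focal, k_bg, n_bg - k_bg)
  sum((O - E)^2 / E)
}

#' Compare conservation rates of a focal set against background
#'
#' Pearson chi-square test (df = 1, no continuity correction) on the 2x2
#' table of conserved/not-conserved counts in the focal and background
#' groups, with an optional permutation p-value obtained by relabelling the
#' pooled Bernoulli outcomes `mc_reps` times (add-one corrected). The
#' permutation null is discrete, so for small tables `p_mc` is conservative
#' relative to the asymptotic p; it is the recommended p-value whenever any
#' expected cell is below 5 (flagged in the output).
#'
#' @param k_focal,n_focal Conserved count and total in the focal set.
#' @param k_bg,n_bg Conserved count and total in the background set.
#' @param mc_reps Number of permutation replicates (0 = asymptotic only).
#' @param seed Seed for the permutation draw.
#' @return List with `chi2`, `df`, `p_asymptotic`, `p_mc` (or `NA`),
#'   `k_focal`, `n_focal`, `k_bg`, `n_bg`, `expected_min`,
#'   `small_expected_warning`, `mc_reps`, `seed`.
#' @export
conservation_rate_test <- function(k_focal, n_focal, k_bg, n_bg,
                                   mc_reps = 0L, seed = 1L) {
  if (n_focal < 1L || n_bg < 1L) stop_fmt("both groups need n >= 1")
  if (k_focal < 0L || k_focal > n_focal || k_bg < 0L || k_bg > n_bg) {
    stop_fmt("conserved counts must satisfy 0 <= k <= n")
  }
  chi2 <- pearson_chi2_2x2(k_focal, n_focal, k_bg, n_bg)
  p_asym <- pchisq(chi2, df = 1L, lower.tail = FALSE)
  n <- n_focal + n_bg
  k <- k_focal + k_bg
  E <- c(n_focal * k, n_focal * (n - k), n_bg * k, n_bg * (n - k)) / n
  p_mc <- NA_real_
  if (mc_reps > 0L) {
    p_mc <- with_seed(seed, {
      exceed <- 0L
      pooled <- c(rep(1L, k), rep(0L, n - k))
      for (r in seq_len(mc_reps)) {
        kf <- sum(pooled[sample.int(n, n_focal)])
        if (pearson_chi2_2x2(kf, n_focal, k - kf, n_bg) >= chi2 - 1e-12) {
          exceed <- exceed + 1L
        }
      }
      (1 + exceed) / (1 + mc_reps)
    })
  }
  list(chi2 = chi2, df = 1L, p_asymptotic = p_asym, p_mc = p_mc,
       k_focal = k_focal, n_focal = n_focal, k_bg = k_bg, n_bg = n_bg,
       expected_min = min(E),
       small_expected_warning = min(E) < 5,
       mc_reps = as.integer(mc_reps), seed = as.integer(seed))
}
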
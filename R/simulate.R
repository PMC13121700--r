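#' Simulate a clade of genomes with planted ALG structure
#'
#' Each species starts from one chromosome per ALG carrying `genes_per_alg`
#' single-copy orthologues at uniform random positions. Planted fusions then
#' join the chromosomes of the named ALGs in one species, either blockwise
#' (ALG blocks concatenated end to end) or mixed (gene order interleaved
#' round-robin across the constituent ALGs, the fully mixed end state of a
#' fused chromosome). Planted fissions split a single-ALG chromosome at a
#' random gene index, leaving at least `min_fission_side` genes on each
#' side. Finally every gene independently translocates to a uniformly chosen
#' other chromosome with probability `translocation_rate`, re-drawing its
#' position there. Orthology is the identity family structure (one gene per
#' species per family) and the ALG reference maps each family to its source
#' ALG, so the planted truth is fully recoverable.
#'
#' @param n_species Number of species (default 5).
#' @param n_algs Number of ancestral linkage groups (default 24; labels
#'   from [alg_labels()] or synthesized when more are requested).
#' @param genes_per_alg Genes per ALG (default 50).
#' @param fusion_events List of `list(species =, algs =, mixed =)` entries.
#' @param fission_events List of `list(species =, alg =)` entries.
#' @param translocation_rate Per-gene translocation probability in \[0, 1\].
#' @param seed Master seed; output is a pure function of arguments and seed.
#' @param min_fission_side Minimum genes left on each fission fragment.
#' @return List with `loci` (all species), `orthology`, `reference`, and
#'   `truth` (planted fusions, fissions, translocated gene ids, seed).
#' @export
simulate_clade_genomes <- function(n_species = 5L, n_algs = 24L,
                                   genes_per_alg = 50L,
                                   fusion_events = list(),
                                   fission_events = list(),
                                   translocation_rate = 0,
                                   seed = 1L,
                                   min_fission_side = 10L) {
  stopifnot(translocation_rate >= 0, translocation_rate <= 1,
            n_species >= 1L, n_algs >= 1L, genes_per_alg >= 1L)
  labels <- if (n_algs <= 24L) alg_labels()[seq_len(n_algs)]
            else c(alg_labels(), sprintf("X%02d", seq_len(n_algs - 24L)))
  species <- sprintf("sp%02d", seq_len(n_species))
  for (ev in fission_events) {
    if (genes_per_alg < 2L * min_fission_side) {
      stop_fmt("genes_per_alg = %d is too small for a fission keeping %d genes per side",
               genes_per_alg, min_fission_side)
    }
    if (!ev$alg %in% labels) stop_fmt("fission names unknown ALG '%s'", ev$alg)
  }
  for (ev in fusion_events) {
    if (!all(ev$algs %in% labels)) {
      stop_fmt("fusion names unknown ALG(s): %s",
               paste(setdiff(ev$algs, labels), collapse = ", "))
    }
    if (!ev$species %in% species) {
      stop_fmt("fusion names unknown species '%s'", ev$species)
    }
  }

  n_genes <- n_algs * genes_per_alg
  fam_ids <- sprintf("F%05d", seq_len(n_genes))
  fam_alg <- rep(labels, each = genes_per_alg)

  with_seed(seed, {
    loci_list <- list()
    truth_transloc <- character(0)
    for (sp in species) {
      gene_ids <- sprintf("%s_g%05d", sp, seq_len(n_genes))
      chrom <- paste0(sp, "_chr_", fam_alg)
      # uniform positions within each source chromosome
      start <- integer(n_genes)
      for (lab in labels) {
        i <- which(fam_alg == lab)
        start[i] <- sort(sample.int(1e7L, length(i)))
      }
      df <- data.frame(gene_id = gene_ids, species_id = sp,
                       chromosome_id = chrom, start = start,
                       end = start + 500L, strand = "+",
                       family_id = fam_ids, alg = fam_alg,
                       stringsAsFactors = FALSE)

      # planted fusions
      for (ev in fusion_events) {
        if (ev$species != sp) next
        members <- which(df$alg %in% ev$algs)
        new_chr <- paste0(sp, "_chr_", paste(sort(ev$algs), collapse = ""))
        if (isTRUE(ev$mixed)) {
          # round-robin interleave of the constituent ALGs' gene orders
          per <- lapply(sort(ev$algs), function(a) {
            i <- which(df$alg == a)
            i[order(df$start[i])]
          })
          n_max <- max(vapply(per, length, 1L))
          inter <- unlist(lapply(seq_len(n_max), function(k) {
            unlist(lapply(per, function(v) if (k <= length(v)) v[k] else NULL))
          }))
          pos <- sort(sample.int(1e7L * length(ev$algs), length(inter)))
          df$start[inter] <- pos
        } else {
          # concatenate blocks in sorted-label order with offsets
          offset <- 0L
          for (a in sort(ev$algs)) {
            i <- which(df$alg == a)
            df$start[i] <- df$start[i] + offset
            offset <- offset + 1e7L
          }
        }
        df$end[members] <- df$start[members] + 500L
        df$chromosome_id[members] <- new_chr
      }

      # planted fissions
      for (ev in fission_events) {
        if (!is.null(ev$species) && ev$species != sp) next
        i <- which(df$alg == ev$alg &
                   df$chromosome_id == paste0(sp, "_chr_", ev$alg))
        if (length(i) < 2L * min_fission_side) {
          stop_fmt("cannot split ALG '%s' in species '%s': only %d genes on its chromosome",
                   ev$alg, sp, length(i))
        }
        i <- i[order(df$start[i])]
        cut <- sample(seq(min_fission_side, length(i) - min_fission_side), 1L)
        left <- i[seq_len(cut)]
        right <- i[-seq_len(cut)]
        df$chromosome_id[left] <- paste0(sp, "_chr_", ev$alg, "a")
        df$chromosome_id[right] <- paste0(sp, "_chr_", ev$alg, "b")
        df$start[right] <- df$start[right] - df$start[right][1L] + 1L
        df$end[right] <- df$start[right] + 500L
      }

      # random translocations
      if (translocation_rate > 0) {
        moved <- which(runif(n_genes) < translocation_rate)
        chroms_now <- unique(df$chromosome_id)
        if (length(chroms_now) < 2L) moved <- integer(0)
        for (i in moved) {
          dest <- sample(setdiff(chroms_now, df$chromosome_id[i]), 1L)
          df$chromosome_id[i] <- dest
          df$start[i] <- sample.int(1e7L, 1L)
          df$end[i] <- df$start[i] + 500L
        }
        truth_transloc <- c(truth_transloc, df$gene_id[moved])
      }
      loci_list[[sp]] <- df
    }

    all_loci <- do.call(rbind, loci_list)
    orthology <- data.frame(family_id = fam_ids, stringsAsFactors = FALSE)
    for (sp in species) {
      orthology[[sp]] <- loci_list[[sp]]$gene_id
    }
    reference <- make_alg_reference(fam_ids, fam_alg, labels)
    truth <- list(
      fusions = lapply(fusion_events, function(ev) {
        list(species = ev$species,
             chromosome = paste0(ev$species, "_chr_",
                                 paste(sort(ev$algs), collapse = "")),
             algs = sort(ev$algs), mixed = isTRUE(ev$mixed))
      }),
      fissions = do.call(c, c(list(list()), lapply(fission_events, function(ev) {
        sps <- if (is.null(ev$species)) species else ev$species
        lapply(sps, function(sp) list(species = sp, alg = ev$alg))
      }))),
      translocated = sort(truth_transloc),
      labels = labels, seed = as.integer(seed)
    )
    rownames(all_loci) <- NULL
    list(loci = all_loci[, c("gene_id", "species_id", "chromosome_id",
                             "start", "end", "strand")],
         orthology = orthology, reference = reference, truth = truth)
  })
}

#' Simulate perturbation RNA-seq counts with planted regulated genes
#'
#' Counts follow a negative binomial with gene baseline means drawn
#' log-normally, per-sample library factors uniform within +/-20% of 1, and
#' the configured dispersion. Planted pathway-upregulated genes are
#' multiplied by `2^-log2_effect` in both inhibitor conditions and
#' `2^+log2_effect` in the ligand condition (mirror for downregulated
#' genes).
#'
#' @param n_genes Number of genes (default 2000).
#' @param conditions Condition names; the first is the control, the last is
#'   the ligand arm, the middle ones are inhibitors (default
#'   `c("control", "LDN", "K02", "mBMP4")`).
#' @param n_replicates Replicates per condition (default 3).
#' @param n_up,n_down Numbers of planted up-/down-regulated genes, drawn at
#'   random (disjoint); alternatively pass explicit ids via `planted_up` /
#'   `planted_down`.
#' @param planted_up,planted_down Optional explicit gene-id sets.
#' @param log2_effect Absolute planted log2 effect size (default 3).
#' @param dispersion NB dispersion (default 0.1).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of gene
#'   baseline means (defaults log(50) and 1).
#' @param stage Stage label written into the metadata.
#' @param seed Master seed.
#' @return List with `counts` (integer matrix), `meta` (sample metadata)
#'   and `truth` (planted sets, effect, seed).
#' @export
simulate_perturbation_counts <- function(n_genes = 2000L,
                                         conditions = c("control", "LDN",
                                                        "K02", "mBMP4"),
                                         n_replicates = 3L,
                                         n_up = 50L, n_down = 50L,
                                         planted_up = NULL,
                                         planted_down = NULL,
                                         log2_effect = 3,
                                         dispersion = 0.1,
                                         baseline_meanlog = log(50),
                                         baseline_sdlog = 1,
                                         stage = "late_gastrula",
                                         seed = 1L) {
  stopifnot(dispersion >= 0, length(conditions) >= 2L)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  with_seed(seed, {
    if (is.null(planted_up) && is.null(planted_down)) {
      if (log2_effect == 0) {
        planted_up <- planted_down <- character(0)
      } else {
        pick <- sample(gene_ids, n_up + n_down)
        planted_up <- sort(pick[seq_len(n_up)])
        planted_down <- sort(pick[n_up + seq_len(n_down)])
      }
    }
    planted_up <- planted_up %||% character(0)
    planted_down <- planted_down %||% character(0)
    if (length(intersect(planted_up, planted_down)) > 0L) {
      stop_fmt("planted up and down sets overlap")
    }
    control <- conditions[1L]
    ligand <- conditions[length(conditions)]
    inhibitors <- setdiff(conditions, c(control, ligand))
    baseline <- rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    n_samples <- length(conditions) * n_replicates
    sample_ids <- character(n_samples)
    counts <- matrix(0L, n_genes, n_samples,
                     dimnames = list(gene_ids, NULL))
    meta <- data.frame(sample_id = character(n_samples),
                       condition = character(n_samples),
                       stage = stage,
                       replicate = integer(n_samples),
                       dose = NA_character_, stringsAsFactors = FALSE)
    s <- 0L
    for (cond in conditions) {
      effect <- rep(1, n_genes)
      if (cond %in% inhibitors) {
        effect[gene_ids %in% planted_up] <- 2^(-log2_effect)
        effect[gene_ids %in% planted_down] <- 2^(log2_effect)
      } else if (cond == ligand) {
        effect[gene_ids %in% planted_up] <- 2^(log2_effect)
        effect[gene_ids %in% planted_down] <- 2^(-log2_effect)
      }
      for (r in seq_len(n_replicates)) {
        s <- s + 1L
        libf <- runif(1, 0.8, 1.2)
        mu <- baseline * effect * libf
        counts[, s] <- if (dispersion == 0) {
          stats::rpois(n_genes, mu)
        } else {
          rnbinom(n_genes, mu = mu, size = 1 / dispersion)
        }
        sid <- sprintf("%s_%s_R%d", cond, stage, r)
        sample_ids[s] <- sid
        meta$sample_id[s] <- sid
        meta$condition[s] <- cond
        meta$replicate[s] <- r
      }
    }
    colnames(counts) <- sample_ids
    list(counts = counts, meta = meta,
         truth = list(up = planted_up, down = planted_down,
                      log2_effect = log2_effect, stage = stage,
                      dispersion = dispersion, seed = as.integer(seed)))
  })
}

#' Simulate gene phylostrata and an age-structured expression experiment
#'
#' Strata are drawn from `stratum_probs` (default: geometrically decaying
#' class sizes, emulating the old-heavy age distribution of real gene
#' catalogues). The companion generator [simulate_tai_dataset()] produces a
#' TPM matrix in which, for the affected conditions, the expression of the
#' youngest-stratum decile is multiplied by `young_upregulation_factor`
#' before noise.
#'
#' @param n_genes Number of genes.
#' @param n_strata Number of age classes (default 16).
#' @param stratum_probs Optional probability vector of length `n_strata`.
#' @param seed Seed.
#' @return List with `strata` (data frame `gene_id`, `stratum`) and
#'   `truth` (the youngest-decile gene ids, seed).
#' @export
simulate_phylostrata <- function(n_genes = 2000L, n_strata = 16L,
                                 stratum_probs = NULL, seed = 1L) {
  stopifnot(n_strata >= 1L)
  if (is.null(stratum_probs)) {
    stratum_probs <- 0.8^seq_len(n_strata)
    stratum_probs <- stratum_probs / sum(stratum_probs)
  }
  stopifnot(length(stratum_probs) == n_strata)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  with_seed(seed, {
    stratum <- sample.int(n_strata, n_genes, replace = TRUE,
                          prob = stratum_probs)
    strata <- data.frame(gene_id = gene_ids, stratum = stratum,
                         stringsAsFactors = FALSE)
    young_cut <- stats::quantile(stratum, 0.9, type = 1L)
    youngest <- gene_ids[stratum > young_cut]
    if (length(youngest) == 0L) youngest <- gene_ids[stratum == max(stratum)]
    list(strata = strata,
         truth = list(youngest_decile = youngest, seed = as.integer(seed)))
  })
}

#' Simulate a TAI perturbation experiment
#'
#' Produces a linear-scale expression (TPM-like) matrix for a set of
#' conditions with `n_batches` biological batches each. Baseline expression
#' is log-normal per gene; batch noise is multiplicative log-normal with
#' `noise_sdlog`. In the affected conditions, genes of the youngest-stratum
#' decile (from the phylostratum simulation truth) are multiplied by
#' `young_upregulation_factor` before noise.
#'
#' @param phylo Output of [simulate_phylostrata()].
#' @param conditions Condition names (default `c("control", "mBMP4")`).
#' @param affected_conditions Conditions receiving the young-gene shift.
#' @param young_upregulation_factor Multiplier (>= 1, default 4).
#' @param n_batches Batches per condition (default 3).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline parameters.
#' @param noise_sdlog Batch-level multiplicative noise (default 0.2).
#' @param seed Seed.
#' @return List with `expression` (gene-by-sample matrix), `meta` and
#'   `truth`.
#' @export
simulate_tai_dataset <- function(phylo,
                                 conditions = c("control", "mBMP4"),
                                 affected_conditions = "mBMP4",
                                 young_upregulation_factor = 4,
                                 n_batches = 3L,
                                 baseline_meanlog = log(20),
                                 baseline_sdlog = 1,
                                 noise_sdlog = 0.2,
                                 seed = 1L) {
  stopifnot(young_upregulation_factor >= 1)
  gene_ids <- phylo$strata$gene_id
  n_genes <- length(gene_ids)
  with_seed(seed, {
    baseline <- rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    n_samples <- length(conditions) * n_batches
    expr <- matrix(0, n_genes, n_samples,
                   dimnames = list(gene_ids, rep("", n_samples)))
    meta <- data.frame(sample_id = character(n_samples),
                       condition = character(n_samples),
                       stage = "late_gastrula",
                       replicate = integer(n_samples),
                       dose = NA_character_, stringsAsFactors = FALSE)
    young <- gene_ids %in% phylo$truth$youngest_decile
    s <- 0L
    for (cond in conditions) {
      mult <- rep(1, n_genes)
      if (cond %in% affected_conditions) {
        mult[young] <- young_upregulation_factor
      }
      for (b in seq_len(n_batches)) {
        s <- s + 1L
        expr[, s] <- baseline * mult * rlnorm(n_genes, 0, noise_sdlog)
        sid <- sprintf("%s_B%d", cond, b)
        colnames(expr)[s] <- sid
        meta$sample_id[s] <- sid
        meta$condition[s] <- cond
        meta$replicate[s] <- b
      }
    }
    list(expression = expr, meta = meta,
         truth = list(affected_conditions = affected_conditions,
                      factor = young_upregulation_factor,
                      youngest_decile = phylo$truth$youngest_decile,
                      seed = as.integer(seed)))
  })
}
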
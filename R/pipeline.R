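#' Resolved run configuration
#'
#' Collects every tunable constant of the analysis pipeline with its
#' default, so a run manifest can echo the exact configuration used.
#'
#' @param q_threshold BH threshold for chromosome-ALG calls (default 0.05).
#' @param min_genes Minimum genes per significant chromosome-ALG pair
#'   (default 5).
#' @param n_perm Permutations for the mixing test (default 999).
#' @param dispersion Fixed NB dispersion for the exact test (default 0.1).
#' @param fc_threshold,p_threshold Fold-change and p presets (defaults 2
#'   and 0.01; the stringent preset is 4 and 0.001).
#' @param fdr_threshold BH gate for differential expression (default 0.05).
#' @param background_n Background family sample size (default 100).
#' @param seed Master seed for every random draw of the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(q_threshold = 0.05, min_genes = 5L, n_perm = 999L,
                       dispersion = 0.1, fc_threshold = 2,
                       p_threshold = 0.01, fdr_threshold = 0.05,
                       background_n = 100L, seed = 1L) {
  structure(list(q_threshold = q_threshold, min_genes = as.integer(min_genes),
                 n_perm = as.integer(n_perm), dispersion = dispersion,
                 fc_threshold = fc_threshold, p_threshold = p_threshold,
                 fdr_threshold = fdr_threshold,
                 background_n = as.integer(background_n),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Generates a synthetic clade, perturbation count matrices for two stages
#' and a phylostratum experiment from the configured seed, then runs every
#' analysis stage in dependency order: ALG assignment, chromosome profiling
#' and enrichment calls, fusion/fission detection with mixing tests,
#' family-conservation calls with a background chi-square test, per-contrast
#' differential expression, regulation classification and cross-stage
#' intersection, and TAI contrasts. All outputs are written as TSV/JSON
#' under `out_dir` together with a manifest echoing the resolved
#' configuration; a stage whose output file already exists is skipped, so a
#' partially deleted run resumes and regenerates identical files.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param overwrite Regenerate outputs even when present (default TRUE).
#' @return Invisibly, a list with the in-memory results of every stage and
#'   the manifest path.
#' @export
run_pipeline <- function(config = run_config(), out_dir, overwrite = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  fresh <- function(f) overwrite || !file.exists(path(f))
  seed <- config$seed

  # --- synthetic clade with planted rearrangements -----------------------
  sim <- simulate_clade_genomes(
    n_species = 3L, n_algs = 24L, genes_per_alg = 50L,
    fusion_events = list(
      list(species = "sp01", algs = c("H", "Q"), mixed = FALSE),
      list(species = "sp01",
           algs = c("C1", "G", "I", "J2", "K", "L", "O1", "O2", "R"),
           mixed = TRUE)),
    fission_events = list(list(species = "sp01", alg = "E")),
    translocation_rate = 0.01, seed = seed)

  labels <- assign_alg_labels(sim$orthology, sim$reference, sim$loci)
  profile <- chromosome_alg_profile(sim$loci, labels)
  called <- call_chromosome_algs(profile, min_genes = config$min_genes,
                                 q_threshold = config$q_threshold)
  events <- detect_fusions_fissions(called)
  status <- classify_fusion_mixing(sim$loci, labels, events$status,
                                   n_perm = config$n_perm, seed = seed)
  if (fresh("chromosome_profiles.tsv")) {
    write_tsv_out(called, path("chromosome_profiles.tsv"))
  }
  if (fresh("chromosome_status.tsv")) {
    write_tsv_out(status, path("chromosome_status.tsv"))
  }
  if (fresh("fissions.tsv")) {
    write_tsv_out(events$fissions, path("fissions.tsv"))
  }

  # --- linkage conservation ---------------------------------------------
  focal <- sim$orthology$family_id[seq_len(23L)]
  bg <- sample_background_families(sim$orthology, n = config$background_n,
                                   seed = seed, exclude = focal)
  calls_focal <- conserved_association(sim$orthology, sim$loci, called,
                                       family_ids = focal)
  calls_bg <- conserved_association(sim$orthology, sim$loci, called,
                                    family_ids = bg)
  eval_f <- calls_focal[!calls_focal$unevaluable, , drop = FALSE]
  eval_b <- calls_bg[!calls_bg$unevaluable, , drop = FALSE]
  cons_test <- conservation_rate_test(
    sum(eval_f$conserved), nrow(eval_f),
    sum(eval_b$conserved), nrow(eval_b),
    mc_reps = 2000L, seed = seed)
  if (fresh("conservation_calls.tsv")) {
    write_tsv_out(rbind(cbind(set = "focal", calls_focal),
                        cbind(set = "background", calls_bg)),
                  path("conservation_calls.tsv"))
  }
  if (fresh("conservation_test.json")) {
    jsonlite::write_json(c(cons_test, list(background_families = bg)),
                         path("conservation_test.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # --- perturbation response at two stages ------------------------------
  de_cfg <- de_config(dispersion = config$dispersion,
                      fc_threshold = config$fc_threshold,
                      p_threshold = config$p_threshold,
                      fdr_threshold = config$fdr_threshold)
  stages <- c("late_gastrula", "larva")
  calls_by_stage <- list()
  de_truth <- list()
  for (k in seq_along(stages)) {
    pert <- simulate_perturbation_counts(stage = stages[k], seed = seed + k)
    de <- lapply(c("LDN", "K02", "mBMP4"), function(tr) {
      call_de(pert$counts, pert$meta, tr, stages[k], de_cfg)
    })
    names(de) <- c("LDN", "K02", "mBMP4")
    calls <- classify_regulation(de$LDN, de$K02, de$mBMP4)
    calls_by_stage[[stages[k]]] <- calls
    de_truth[[stages[k]]] <- pert$truth
    for (tr in names(de)) {
      f <- sprintf("de_%s_%s.tsv", stages[k], tr)
      if (fresh(f)) write_tsv_out(de[[tr]], path(f))
    }
    f <- sprintf("regulation_calls_%s.tsv", stages[k])
    if (fresh(f)) write_tsv_out(calls, path(f))
  }
  restricted <- intersect_stages(calls_by_stage[[1L]], calls_by_stage[[2L]])
  if (fresh("restricted_sets.json")) {
    jsonlite::write_json(restricted, path("restricted_sets.json"),
                         pretty = TRUE)
  }

  # --- transcriptome age -------------------------------------------------
  phylo <- simulate_phylostrata(seed = seed)
  tai_data <- simulate_tai_dataset(phylo, seed = seed)
  tai <- compute_tai(tai_data$expression, phylo$strata)
  tai_df <- data.frame(sample_id = names(tai),
                       condition = tai_data$meta$condition,
                       tai = tai, stringsAsFactors = FALSE)
  contrast <- tai_contrast_test(
    tai[tai_data$meta$condition == "mBMP4"],
    tai[tai_data$meta$condition == "control"])
  if (fresh("tai.tsv")) write_tsv_out(tai_df, path("tai.tsv"))
  if (fresh("tai_contrast.json")) {
    jsonlite::write_json(contrast, path("tai_contrast.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # --- manifest ----------------------------------------------------------
  manifest <- list(
    package = "algkit",
    version = as.character(packageVersion("algkit")),
    config = unclass(config),
    enrichment_rule = paste(
      "one-sided hypergeometric per (chromosome, ALG), BH within species;",
      "stand-in for any external correspondence pipeline"),
    outputs = sort(setdiff(list.files(out_dir), "manifest.json"))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(synteny = list(called = called, status = status,
                                fissions = events$fissions,
                                truth = sim$truth),
                 conservation = cons_test,
                 regulation = list(calls = calls_by_stage,
                                   restricted = restricted,
                                   truth = de_truth),
                 tai = list(values = tai_df, contrast = contrast),
                 manifest = path("manifest.json")))
}
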
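test_that("ALG labels propagate through single-copy families only", {
  ortho <- make_orthology(list(
    F1 = c(spA = "g1", spB = "g2"),
    F2 = c(spA = "g3", spB = "g4"),   # absent from reference
    F3 = c(spA = "g5")                # not single-copy across the table
  ))
  ref <- make_alg_reference("F1", "Q")
  loci <- make_loci(c("g1", "g3", "g5", "g2", "g4"),
                    c("spA", "spA", "spA", "spB", "spB"),
                    c("c1", "c1", "c1", "c2", "c2"),
                    c(1L, 2L, 3L, 1L, 2L))
  lab <- assign_alg_labels(ortho, ref, loci)
  expect_identical(lab$gene_id, c("g1", "g2"))
  expect_identical(lab$alg, c("Q", "Q"))

  # row-order invariance and idempotence of the propagation
  lab2 <- assign_alg_labels(ortho[c(3, 1, 2), ], ref, loci[sample(5), ])
  expect_identical(lab, lab2)

  expect_error(assign_alg_labels(ortho, ref, loci[loci$species_id == "spA", ]),
               "spB")
})

test_that("chromosome profiles are exact tallies and conserve totals", {
  loci <- make_loci(sprintf("g%02d", 1:16), "spA",
                    c(rep("c1", 15), "c2"), 1:16)
  lab <- data.frame(species_id = "spA", gene_id = sprintf("g%02d", 1:15),
                    family_id = sprintf("F%02d", 1:15),
                    alg = c(rep("H", 10), rep("Q", 5)),
                    stringsAsFactors = FALSE)
  prof <- chromosome_alg_profile(loci, lab)
  c1 <- prof[prof$chromosome_id == "c1", ]
  expect_identical(c1$count[c1$alg == "H"], 10L)
  expect_identical(c1$count[c1$alg == "Q"], 5L)
  expect_identical(unique(c1$n_assigned), 15L)
  # chromosome with no labelled gene is retained, flagged empty
  c2 <- prof[prof$chromosome_id == "c2", ]
  expect_true(is.na(c2$alg) && c2$n_assigned == 0L)
  # totals over chromosomes equal the number of labelled genes
  expect_identical(sum(prof$count), nrow(lab))

  empty <- chromosome_alg_profile(loci, lab[0, ])
  expect_true(all(empty$n_assigned == 0L))
})

test_that("enrichment p-values match a direct-summation oracle", {
  set.seed(41)
  # random scatter: compare every pair's p to the oracle
  n_genes <- 300L
  algs <- sample(c("H", "Q", "R", "B2", "K"), n_genes, replace = TRUE)
  chrom <- sample(paste0("c", 1:4), n_genes, replace = TRUE)
  loci <- make_loci(sprintf("g%03d", 1:n_genes), "spA", chrom,
                    sample.int(1e6, n_genes))
  lab <- data.frame(species_id = "spA", gene_id = loci$gene_id,
                    family_id = loci$gene_id, alg = algs,
                    stringsAsFactors = FALSE)
  called <- call_chromosome_algs(chromosome_alg_profile(loci, lab))
  alg_totals <- table(algs)
  for (i in seq_len(nrow(called))) {
    expected <- hyper_tail_oracle(called$count[i],
                                  alg_totals[[called$alg[i]]],
                                  n_genes, called$n_assigned[i])
    expect_equal(called$p[i], expected, tolerance = 1e-12)
  }
})

test_that("a concentrated ALG is significant but single strays are not", {
  # chromosome c1 holds all 50 genes of ALG R in a 1000-gene genome
  algs <- c(rep("R", 50), rep("H", 950))
  chrom <- c(rep("c1", 50), rep(paste0("c", 2:20), length.out = 950))
  loci <- make_loci(sprintf("g%04d", 1:1000), "spA", chrom, 1:1000)
  lab <- data.frame(species_id = "spA", gene_id = loci$gene_id,
                    family_id = loci$gene_id, alg = algs,
                    stringsAsFactors = FALSE)
  called <- call_chromosome_algs(chromosome_alg_profile(loci, lab))
  r_row <- called[called$chromosome_id == "c1" & called$alg == "R", ]
  expect_lt(r_row$p, 1e-50)
  expect_true(r_row$significant)

  # a single stray gene can never pass min_genes = 5
  algs[51] <- "R"   # one R gene on c2's block
  lab$alg <- algs
  called <- call_chromosome_algs(chromosome_alg_profile(loci, lab),
                                 min_genes = 5L)
  stray <- called[called$alg == "R" & called$chromosome_id != "c1", ]
  expect_false(any(stray$significant))
  expect_error(call_chromosome_algs(chromosome_alg_profile(loci, lab),
                                    min_genes = 0L), "min_genes")
})

test_that("fusion, single-ALG and fission classification follows the significant sets", {
  called <- make_called_profile(
    rep("spA", 4),
    c("chr1", "chr2", "chr3", "chr4"),
    list(c("C1", "G", "I", "J2", "K", "L", "O1", "O2", "R"),  # 9-ALG fusion
         "H",                                                  # single
         "E",                                                  # fission of E...
         "E"))                                                 # ...across chr3+chr4
  called$significant[is.na(called$alg)] <- FALSE
  ev <- detect_fusions_fissions(called)
  st <- ev$status
  expect_identical(st$status[st$chromosome_id == "chr1"], "fusion")
  expect_identical(st$n_significant[st$chromosome_id == "chr1"], 9L)
  expect_identical(st$status[st$chromosome_id == "chr2"], "single_alg")
  expect_identical(nrow(ev$fissions), 1L)
  expect_identical(ev$fissions$alg, "E")
  expect_identical(ev$fissions$chromosomes, "chr3,chr4")
})

test_that("runs statistic and mixing verdicts behave at the extremes", {
  # perfectly alternating labels: maximal runs, mixed
  n <- 20L
  loci <- make_loci(sprintf("g%02d", 1:n), "spA", "chr1", seq_len(n) * 10L)
  lab <- data.frame(species_id = "spA", gene_id = loci$gene_id,
                    family_id = loci$gene_id,
                    alg = rep(c("A1a", "B1"), n / 2),
                    stringsAsFactors = FALSE)
  res <- mixing_test(loci, lab, "spA", "chr1", c("A1a", "B1"),
                     n_perm = 499L, seed = 9L)
  expect_identical(res$runs_statistic, 20L)
  expect_identical(res$mixing, "mixed")

  # two contiguous blocks: 2 runs, blockwise at n_perm = 999
  lab$alg <- c(rep("A1a", 10), rep("B1", 10))
  res2 <- mixing_test(loci, lab, "spA", "chr1", c("A1a", "B1"),
                      n_perm = 999L, seed = 9L)
  expect_identical(res2$runs_statistic, 2L)
  expect_lt(res2$mixing_p, 0.05)
  expect_identical(res2$mixing, "blockwise")

  # determinism under a fixed seed
  res3 <- mixing_test(loci, lab, "spA", "chr1", c("A1a", "B1"),
                      n_perm = 999L, seed = 9L)
  expect_identical(res2$mixing_p, res3$mixing_p)

  # a constituent ALG with < 2 genes is indeterminate
  lab$alg <- c(rep("A1a", 19), "B1")
  res4 <- mixing_test(loci, lab, "spA", "chr1", c("A1a", "B1"),
                      n_perm = 99L, seed = 1L)
  expect_identical(res4$mixing, "indeterminate")
  expect_error(mixing_test(loci, lab, "spA", "chr1", "A1a"), "fusion")
})

test_that("permutation p matches exhaustive enumeration for small chromosomes", {
  # 4 A + 4 B genes: enumerate all C(8,4) label arrangements exactly
  n <- 8L
  loci <- make_loci(sprintf("g%d", 1:n), "spA", "chr1", seq_len(n) * 10L)
  combos <- utils::combn(n, 4L)
  all_runs <- apply(combos, 2L, function(ix) {
    v <- rep("B", n); v[ix] <- "A"
    length(rle(v)$lengths)
  })
  for (obs_labels in list(c("A","A","B","B","A","B","B","A"),
                          c("A","A","A","A","B","B","B","B"))) {
    lab <- data.frame(species_id = "spA", gene_id = loci$gene_id,
                      family_id = loci$gene_id, alg = obs_labels,
                      stringsAsFactors = FALSE)
    res <- mixing_test(loci, lab, "spA", "chr1", c("A", "B"),
                       n_perm = 20000L, seed = 3L)
    exact <- mean(all_runs <= res$runs_statistic)
    se <- sqrt(exact * (1 - exact) / 20000)
    expect_lt(abs(res$mixing_p - exact), 3 * se + 1e-4)
  }
})

test_that("zero-rearrangement clade is fully single-ALG with planted truth recovered", {
  sim <- simulate_clade_genomes(n_species = 3L, n_algs = 6L,
                                genes_per_alg = 20L, seed = 11L)
  lab <- assign_alg_labels(sim$orthology, sim$reference, sim$loci)
  # every labelled gene's chromosome hosts only its own ALG
  prof <- chromosome_alg_profile(sim$loci, lab)
  expect_true(all(table(prof$chromosome_id[!is.na(prof$alg)]) == 1L))
  called <- call_chromosome_algs(prof)
  ev <- detect_fusions_fissions(called)
  expect_true(all(ev$status$status == "single_alg"))
  expect_identical(nrow(ev$fissions), 0L)
})

test_that("planted fusion, fission and mixing labels are recovered", {
  sim <- simulate_clade_genomes(
    n_species = 2L, genes_per_alg = 50L,
    fusion_events = list(list(species = "sp01", algs = c("H", "Q"),
                              mixed = TRUE),
                         list(species = "sp01", algs = c("B2", "D"),
                              mixed = FALSE)),
    fission_events = list(list(species = "sp01", alg = "K")),
    seed = 21L)
  lab <- assign_alg_labels(sim$orthology, sim$reference, sim$loci)
  called <- call_chromosome_algs(chromosome_alg_profile(sim$loci, lab))
  ev <- detect_fusions_fissions(called)
  st <- classify_fusion_mixing(sim$loci, lab, ev$status, n_perm = 499L,
                               seed = 5L)
  fus <- st[st$status == "fusion", ]
  expect_setequal(fus$algs, c("H,Q", "B2,D"))
  expect_identical(fus$mixing[fus$algs == "H,Q"], "mixed")
  expect_identical(fus$mixing[fus$algs == "B2,D"], "blockwise")
  expect_identical(nrow(ev$fissions), 1L)
  expect_identical(ev$fissions$alg, "K")
  # runs statistic bounded by constituents below and gene count above
  expect_true(all(fus$runs_statistic >= 2L & fus$runs_statistic <= 100L))
})
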
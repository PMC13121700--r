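#' Counts-per-million normalization
#'
#' @param counts Non-negative gene-by-sample matrix.
#' @param lib_sizes Per-sample library sizes; defaults to column sums.
#' @return Matrix of CPM values with the same dimensions.
#' @export
cpm_normalize <- function(counts, lib_sizes = colSums(counts)) {
  if (any(lib_sizes <= 0)) stop_fmt("library sizes must be positive")
  if (length(lib_sizes) != ncol(counts)) {
    stop_fmt("lib_sizes length (%d) != number of samples (%d)",
             length(lib_sizes), ncol(counts))
  }
  sweep(counts, 2L, lib_sizes, "/") * 1e6
}

# Scale every sample to the geometric mean library size and round
# half-to-even, so replicate counts can be summed within groups on a
# common scale before the exact test.
equalize_libraries <- function(counts, lib_sizes = colSums(counts)) {
  if (any(lib_sizes <= 0)) stop_fmt("library sizes must be positive")
  target <- exp(mean(log(lib_sizes)))
  scaled <- sweep(counts, 2L, target / lib_sizes, "*")
  out <- round(scaled)  # round() rounds half to even
  storage.mode(out) <- "integer"
  out
}

#' Negative-binomial exact test with fixed dispersion
#'
#' Conditional exact test for a difference between two groups of summed,
#' library-equalized counts. Within each group the sum of `n` replicate
#' counts, each NB with mean `m` and dispersion `phi`, is NB with mean `n m`
#' and dispersion `phi / n`; conditioning on the total `t = y_a + y_b`, the
#' probability of a split depends only on the group sizes and `phi`
#' (a negative hypergeometric distribution). The two-sided p-value sums the
#' probabilities of all splits no more likely than the observed one.
#' `dispersion = 0` is the Poisson limit, where the conditional distribution
#' is binomial with success probability equal to group a's size share
#' (identical to a two-sided exact binomial test).
#'
#' @param y_a,y_b Vectors of summed counts per gene for groups a and b.
#' @param n_a,n_b Number of replicates summed in each group.
#' @param dispersion NB dispersion of a single replicate (default 0.1).
#' @return Vector of two-sided p-values in (0, 1].
#' @export
nb_exact_test <- function(y_a, y_b, n_a = 1L, n_b = 1L, dispersion = 0.1) {
  if (dispersion < 0) stop_fmt("dispersion must be >= 0")
  if (length(y_a) != length(y_b)) stop_fmt("y_a and y_b differ in length")
  if (any(y_a < 0) || any(y_b < 0)) stop_fmt("counts must be non-negative")
  vapply(seq_along(y_a), function(i) {
    nb_exact_p_single(y_a[i], y_a[i] + y_b[i], n_a, n_b, dispersion)
  }, 1.0)
}

# p-value for observed group-a count ya out of total t.
nb_exact_p_single <- function(ya, t, n_a, n_b, phi) {
  if (t == 0) return(1)
  k <- 0:t
  if (phi == 0) {
    lw <- dbinom(k, t, n_a / (n_a + n_b), log = TRUE)
  } else {
    r_a <- n_a / phi
    r_b <- n_b / phi
    lw <- lgamma(k + r_a) - lgamma(k + 1) +
          lgamma(t - k + r_b) - lgamma(t - k + 1)
  }
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  # include all splits whose probability does not exceed the observed one,
  # with a small relative tolerance against floating-point ties
  sum(w[w <= w[ya + 1L] * (1 + 1e-10)])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of BH-adjusted q-values, capped at 1.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_fmt("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[ord] * m / seq(m, 1)))
  q[order(ord)]
}

#' Differential-expression configuration
#'
#' Bundles the dispersion, thresholds and pseudo-count used by [call_de()].
#' The defaults form the discovery preset (linear fold-change > 2, raw
#' p < 0.01); `de_config(fc_threshold = 4, p_threshold = 0.001)` is the
#' stringent preset. Both are combined with the FDR < 0.05 gate.
#'
#' @param dispersion Fixed NB dispersion (default 0.1).
#' @param fc_threshold Linear fold-change threshold (> 1; default 2).
#' @param p_threshold Raw exact-test p threshold (default 0.01).
#' @param fdr_threshold BH-adjusted threshold (default 0.05).
#' @param pseudo_count Pseudo-count added to mean CPM before log2 fold
#'   change (default 0.5).
#' @return A list of class `de_config`.
#' @export
de_config <- function(dispersion = 0.1, fc_threshold = 2,
                      p_threshold = 0.01, fdr_threshold = 0.05,
                      pseudo_count = 0.5) {
  if (fc_threshold <= 1) stop_fmt("fc_threshold must exceed 1")
  if (p_threshold <= 0 || p_threshold >= 1 ||
      fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop_fmt("p/q thresholds must lie in (0, 1)")
  }
  if (dispersion < 0) stop_fmt("dispersion must be >= 0")
  structure(list(dispersion = dispersion, fc_threshold = fc_threshold,
                 p_threshold = p_threshold, fdr_threshold = fdr_threshold,
                 pseudo_count = pseudo_count), class = "de_config")
}

#' Call differential expression for one treatment-vs-control contrast
#'
#' Samples of the treatment condition (all doses pooled) are compared with
#' the controls of the same stage. Replicates are scaled to the geometric
#' mean library size, rounded half-to-even and summed within groups, then
#' tested per gene with [nb_exact_test()] at the configured dispersion.
#' The log2 fold change is computed from mean CPM plus the pseudo-count.
#' A gene is significant when all three gates pass: linear |FC| above
#' `fc_threshold`, raw p below `p_threshold` and BH q below
#' `fdr_threshold`; the gates are also reported separately.
#'
#' @param counts Integer gene-by-sample count matrix.
#' @param meta Sample metadata (see [read_sample_meta()]).
#' @param treatment Treatment condition name (e.g. `"LDN"`).
#' @param stage Stage of the contrast.
#' @param config A [de_config()].
#' @param control Name of the control condition (default `"control"`).
#' @return Data frame with `gene_id`, `log2fc`, `p`, `q`, `fc_pass`,
#'   `p_pass`, `q_pass`, `significant`, plus attributes `contrast` and
#'   `config`.
#' @export
call_de <- function(counts, meta, treatment, stage, config = de_config(),
                    control = "control") {
  a_idx <- which(meta$condition == treatment & meta$stage == stage)
  b_idx <- which(meta$condition == control & meta$stage == stage)
  if (length(b_idx) == 0L) {
    stop_fmt("no control samples for stage '%s'", stage)
  }
  if (length(a_idx) == 0L) {
    stop_fmt("no samples for condition '%s' at stage '%s'", treatment, stage)
  }
  cols <- match(meta$sample_id, colnames(counts))
  if (any(is.na(cols))) {
    stop_fmt("sample '%s' of the metadata is absent from the count matrix",
             meta$sample_id[is.na(cols)][1L])
  }
  a_cols <- cols[a_idx]
  b_cols <- cols[b_idx]
  sub <- counts[, c(a_cols, b_cols), drop = FALSE]
  eq <- equalize_libraries(sub)
  na <- length(a_cols)
  nb <- length(b_cols)
  y_a <- rowSums(eq[, seq_len(na), drop = FALSE])
  y_b <- rowSums(eq[, na + seq_len(nb), drop = FALSE])
  p <- nb_exact_test(y_a, y_b, n_a = na, n_b = nb,
                     dispersion = config$dispersion)
  q <- bh_fdr(p)
  cpm <- cpm_normalize(sub)
  mean_a <- rowMeans(cpm[, seq_len(na), drop = FALSE])
  mean_b <- rowMeans(cpm[, na + seq_len(nb), drop = FALSE])
  log2fc <- log2(mean_a + config$pseudo_count) -
            log2(mean_b + config$pseudo_count)
  fc_pass <- abs(log2fc) > log2(config$fc_threshold)
  p_pass <- p < config$p_threshold
  q_pass <- q < config$fdr_threshold
  out <- data.frame(gene_id = rownames(counts), log2fc = log2fc, p = p,
                    q = q, fc_pass = fc_pass, p_pass = p_pass,
                    q_pass = q_pass,
                    significant = fc_pass & p_pass & q_pass,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "contrast") <- c(treatment = treatment, control = control,
                             stage = stage)
  attr(out, "config") <- config
  out
}

#' Classify genes by direction-consistent response to pathway perturbation
#'
#' A gene is called pathway-upregulated (`BMP_up`) when it is significantly
#' downregulated under both receptor inhibitors and significantly
#' upregulated under the ligand; `BMP_down` is the mirror image. With
#' `require_both_inhibitors = FALSE` one significant inhibitor contrast
#' suffices (the other may be missing or non-significant, but must not be
#' significant in the opposing direction).
#'
#' @param de_inhibitor1,de_inhibitor2 [call_de()] results for the two
#'   inhibitor contrasts (e.g. LDN and K02 vs control).
#' @param de_ligand [call_de()] result for the ligand contrast (e.g. mBMP4).
#' @param require_both_inhibitors Demand significance in both inhibitor
#'   arms (default TRUE).
#' @return Data frame with `gene_id`, `call` in
#'   `{"BMP_up", "BMP_down", "none"}` and `supporting` (comma-separated
#'   contrast labels).
#' @export
classify_regulation <- function(de_inhibitor1, de_inhibitor2, de_ligand,
                                require_both_inhibitors = TRUE) {
  genes <- de_ligand$gene_id
  if (!identical(genes, de_inhibitor1$gene_id) ||
      !identical(genes, de_inhibitor2$gene_id)) {
    stop_fmt("the three contrasts cover different gene sets")
  }
  sig_dir <- function(de) ifelse(de$significant, sign(de$log2fc), 0)
  d1 <- sig_dir(de_inhibitor1)
  d2 <- sig_dir(de_inhibitor2)
  dl <- sig_dir(de_ligand)
  inhib_down <- if (require_both_inhibitors) d1 == -1 & d2 == -1
                else (d1 == -1 | d2 == -1) & d1 <= 0 & d2 <= 0
  inhib_up <- if (require_both_inhibitors) d1 == 1 & d2 == 1
              else (d1 == 1 | d2 == 1) & d1 >= 0 & d2 >= 0
  up <- inhib_down & dl == 1
  down <- inhib_up & dl == -1
  call <- ifelse(up, "BMP_up", ifelse(down, "BMP_down", "none"))
  labs <- c(attr(de_inhibitor1, "contrast")[["treatment"]] %||% "inhibitor1",
            attr(de_inhibitor2, "contrast")[["treatment"]] %||% "inhibitor2",
            attr(de_ligand, "contrast")[["treatment"]] %||% "ligand")
  supporting <- vapply(seq_along(genes), function(i) {
    if (call[i] == "none") return("")
    paste(labs[c(d1[i] != 0, d2[i] != 0, dl[i] != 0)], collapse = ",")
  }, "")
  data.frame(gene_id = genes, call = call, supporting = supporting,
             stringsAsFactors = FALSE)
}

#' Restrict regulation calls to genes consistent across two stages
#'
#' @param calls_a,calls_b [classify_regulation()] outputs for the two
#'   stages.
#' @return List with character vectors `up` (called `BMP_up` at both
#'   stages), `down` (called `BMP_down` at both) and `conflicts` (called in
#'   opposite directions).
#' @export
intersect_stages <- function(calls_a, calls_b) {
  up_a <- calls_a$gene_id[calls_a$call == "BMP_up"]
  up_b <- calls_b$gene_id[calls_b$call == "BMP_up"]
  dn_a <- calls_a$gene_id[calls_a$call == "BMP_down"]
  dn_b <- calls_b$gene_id[calls_b$call == "BMP_down"]
  list(up = sort(intersect(up_a, up_b)),
       down = sort(intersect(dn_a, dn_b)),
       conflicts = sort(union(intersect(up_a, dn_b), intersect(dn_a, up_b))))
}

#' Log-transform and row-centre an expression matrix
#'
#' Per gene: `log2(x + 1)`, then subtract the gene's mean across samples;
#' optionally divide by the row standard deviation.
#'
#' @param expression Non-negative gene-by-sample matrix (e.g. TPM).
#' @param scale Also divide by the row SD (default FALSE: mean-subtraction
#'   only). Constant rows keep zero entries.
#' @return Matrix of the same dimensions with zero row means.
#' @export
zscore_matrix <- function(expression, scale = FALSE) {
  if (any(expression < 0)) stop_fmt("expression must be non-negative")
  lg <- log2(expression + 1)
  out <- lg - rowMeans(lg)
  if (scale) {
    s <- apply(lg, 1L, sd)
    s[s == 0] <- 1
    out <- out / s
  }
  out
}

#' Agglomerative clustering with correlation distance
#'
#' Hierarchical clustering of rows (or columns) using
#' distance = 1 - Pearson correlation and, by default, average linkage.
#' Tie handling follows [stats::hclust()], which merges the
#' lowest-index pair among equidistant candidates, so results are
#' deterministic given the input order.
#'
#' @param mat Numeric matrix; rows are clustered.
#' @param axis `"rows"` or `"columns"`.
#' @param method Linkage passed to [stats::hclust()] (default
#'   `"average"`).
#' @return An object of class `hclust` (see [stats::hclust()]); the leaf
#'   ordering is in `$order`.
#' @export
hierarchical_cluster <- function(mat, axis = c("rows", "columns"),
                                 method = "average") {
  axis <- match.arg(axis)
  if (axis == "columns") mat <- t(mat)
  if (nrow(mat) < 2L) stop_fmt("need at least two items to cluster")
  v <- apply(mat, 1L, var)
  if (any(v == 0)) {
    nm <- rownames(mat)[v == 0][1L] %||% which(v == 0)[1L]
    stop_fmt("constant row '%s' has no defined correlation distance", nm)
  }
  d <- as.dist(1 - cor(t(mat)))
  hclust(d, method = method)
}

#' Pairwise Pearson correlation between samples
#'
#' @param expression Gene-by-sample matrix with at least two genes.
#' @return Symmetric sample-by-sample correlation matrix with unit
#'   diagonal.
#' @export
sample_correlation <- function(expression) {
  if (nrow(expression) < 2L) stop_fmt("need at least two genes")
  v <- apply(expression, 2L, var)
  if (any(v == 0)) {
    nm <- colnames(expression)[v == 0][1L] %||% which(v == 0)[1L]
    stop_fmt("sample '%s' has zero variance", nm)
  }
  cor(expression)
}
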
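#' Transcriptome age index per sample
#'
#' The TAI of a sample is the expression-weighted mean phylostratum of its
#' genes: `TAI_s = sum_i ps_i e_is / sum_i e_is`, with linear expression
#' values as weights. Being a ratio of sums, it is invariant to scaling a
#' sample's expression by any positive constant, and always lies between the
#' smallest and largest stratum present. Higher TAI means an evolutionarily
#' younger transcriptome (strata are numbered 1 = oldest).
#'
#' @param expression Non-negative gene-by-sample matrix (rownames = gene
#'   ids); linear scale (e.g. TPM).
#' @param strata Phylostratum map: data frame with `gene_id` and `stratum`
#'   (see [read_phylostrata()]).
#' @return Named numeric vector of TAI values, one per sample.
#' @export
compute_tai <- function(expression, strata) {
  if (any(expression < 0)) stop_fmt("expression must be non-negative")
  expressed <- rownames(expression)[rowSums(expression) > 0]
  missing <- setdiff(expressed, strata$gene_id)
  if (length(missing) > 0L) {
    stop_fmt("no stratum for expressed gene(s): %s%s",
             paste(utils::head(missing, 5L), collapse = ", "),
             if (length(missing) > 5L) sprintf(" (+%d more)",
                                               length(missing) - 5L) else "")
  }
  totals <- colSums(expression)
  if (any(totals == 0)) {
    stop_fmt("sample '%s' has all-zero expression",
             colnames(expression)[totals == 0][1L])
  }
  ps <- strata$stratum[match(rownames(expression), strata$gene_id)]
  ps[is.na(ps)] <- 0L  # genes with zero expression everywhere contribute 0
  colSums(expression * ps) / totals
}

#' Welch contrast of TAI between two groups of samples
#'
#' Two-sided Welch two-sample t-test on per-batch TAI values, with
#' significance stars at 0.05 (`*`) and 0.01 (`**`). When both groups have
#' zero variance and equal means the statistic is 0 and p = 1 by
#' convention; zero variance with unequal means gives p = 0. Both
#' degenerate cases are flagged.
#'
#' @param tai_a,tai_b Numeric vectors of TAI values (>= 2 each).
#' @return List with `t`, `df`, `p`, `stars`, `mean_a`, `mean_b`,
#'   `degenerate`.
#' @export
tai_contrast_test <- function(tai_a, tai_b) {
  if (length(tai_a) < 2L || length(tai_b) < 2L) {
    stop_fmt("each group needs at least two TAI values")
  }
  if (var(tai_a) == 0 && var(tai_b) == 0) {
    equal <- isTRUE(all.equal(mean(tai_a), mean(tai_b)))
    t_stat <- if (equal) 0 else sign(mean(tai_a) - mean(tai_b)) * Inf
    p <- if (equal) 1 else 0
    return(list(t = t_stat, df = NA_real_, p = p,
                stars = star_string(p), mean_a = mean(tai_a),
                mean_b = mean(tai_b), degenerate = TRUE))
  }
  tt <- t.test(tai_a, tai_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, stars = star_string(tt$p.value),
       mean_a = mean(tai_a), mean_b = mean(tai_b), degenerate = FALSE)
}

star_string <- function(p) {
  if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}
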
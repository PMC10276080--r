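#' Two-sided Wilcoxon rank-sum test
#'
#' Exact-distribution p-value for combined sample sizes up to 25 without
#' ties; normal approximation with tie and continuity correction otherwise.
#'
#' @param x,y Numeric samples for the two groups (both non-empty).
#' @return List with `statistic` (rank-sum W of `x`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty")
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= 25L
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; order-preserving mapping back to
#' the input positions.
#'
#' @param pvals Raw p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must be in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Per-gene differential usage between two cohorts
#'
#' Wilcoxon rank-sum test on each gene's percent usage across cohorts, with
#' Benjamini-Hochberg correction over the genes tested. Genes with zero
#' usage in every sample are excluded from testing (and from the family
#' size). The two isotypes are corrected separately: pass one isotype's
#' matrix per call.
#'
#' @param usage Samples-by-genes usage matrix ([usage_matrix()]).
#' @param labels Cohort label per row (exactly two levels, each with >= 2
#'   samples).
#' @return Data.frame: `gene`, per-cohort means, `statistic`, `p`, `p_adj`.
#' @export
differential_usage <- function(usage, labels = attr(usage, "cohort")) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L) stop("exactly two cohorts are required")
  if (min(table(labels)) < 2L) stop("each cohort needs at least 2 samples")
  tested <- colnames(usage)[colSums(usage) > 0]
  rows <- lapply(tested, function(g) {
    x <- usage[labels == lv[1], g]
    y <- usage[labels == lv[2], g]
    w <- wilcoxon_rank_sum(x, y)
    data.frame(gene = g, mean_a = mean(x), mean_b = mean(y),
               statistic = w$statistic, p = w$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("mean_", lv)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' PCA of gene usage
#'
#' Transforms percent usage as `log2(x + 1)`, centers columns, and
#' performs PCA. Components are sign-fixed so the largest-magnitude
#' loading of each component is positive.
#'
#' @param usage Samples-by-genes percent usage matrix.
#' @return List with `scores`, `loadings`, `percent_var` (sums to 100),
#'   `center` (column means of the transformed matrix).
#' @export
pca_usage <- function(usage) {
  stopifnot(nrow(usage) >= 2L, ncol(usage) >= 2L)
  x <- log2(usage + 1)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2L, flip, `*`)
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  vars <- pc$sdev^2
  pv <- if (sum(vars) == 0) rep(0, length(vars)) else 100 * vars / sum(vars)
  list(scores = scores, loadings = loadings, percent_var = pv,
       center = pc$center)
}

#' All-by-all Pearson correlation with pairwise-complete observations
#'
#' For each feature pair the correlation is computed over samples where
#' both values are observed; two-sided p-values come from the t
#' distribution with `n_pair - 2` degrees of freedom. Pairs with fewer
#' than 3 complete observations, or zero variance within the complete
#' cases, are reported as NA. `r_masked` blanks correlations with
#' `p > alpha`.
#'
#' @param features Samples-by-features numeric matrix or data.frame (may
#'   contain NAs).
#' @param alpha Significance level for the mask (default 0.05;
#'   `p <= alpha` is significant).
#' @return List of matrices `r`, `n`, `p`, `r_masked` (class
#'   `ig_correlation`).
#' @export
pearson_pairwise_complete <- function(features, alpha = 0.05) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  obs <- !is.na(x)
  n <- crossprod(obs)
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  r[n < 3L] <- NA_real_
  diag(r)[diag(n) >= 2L] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = pmax(n - 2, 1))
  p[is.na(r)] <- NA_real_
  r_masked <- ifelse(!is.na(p) & p <= alpha, r, NA_real_)
  structure(list(r = r, n = n, p = p, r_masked = r_masked, alpha = alpha),
            class = "ig_correlation")
}

#' @export
print.ig_correlation <- function(x, ...) {
  cat(sprintf("<ig_correlation> %d features, %d significant pairs at alpha = %g\n",
              ncol(x$r),
              sum(x$p[upper.tri(x$p)] <= x$alpha, na.rm = TRUE), x$alpha))
  invisible(x)
}

#' Cohort comparison of per-sample repertoire summaries
#'
#' Wilcoxon rank-sum tests between cohorts for each requested per-sample
#' metric column (e.g. `n_clones`, `diversity_q5`, `top_n_cumfreq`,
#' `v_identity_nt`, `mut_freq_FR3`). Samples missing a metric are excluded
#' with a warning; a metric observed in only one cohort is an error.
#'
#' @param profiles Profile table ([profile_table()]) with a `cohort`
#'   column.
#' @param metrics Character vector of column names to test.
#' @return Data.frame: `metric`, per-cohort means, `statistic`, `p`.
#' @export
compare_group_summaries <- function(profiles,
                                    metrics = c("n_clones", "diversity_q5",
                                                "top_n_cumfreq")) {
  lv <- sort(unique(profiles$cohort))
  if (length(lv) != 2L) stop("exactly two cohorts are required")
  rows <- lapply(metrics, function(m) {
    if (!m %in% names(profiles)) stop("metric not found: ", m)
    v <- profiles[[m]]
    miss <- is.na(v)
    if (any(miss)) {
      warning(sum(miss), " sample(s) missing metric ", m, " excluded")
    }
    x <- v[!miss & profiles$cohort == lv[1]]
    y <- v[!miss & profiles$cohort == lv[2]]
    if (length(x) == 0L || length(y) == 0L) {
      stop("metric ", m, " is only defined for one cohort")
    }
    w <- wilcoxon_rank_sum(x, y)
    data.frame(metric = m, mean_a = mean(x), mean_b = mean(y),
               statistic = w$statistic, p = w$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("mean_", lv)
  out
}
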
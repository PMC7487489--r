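#' Per-feature log2 fold change, cancer over control
#'
#' The fold change of feature *i* is the ratio of its mean abundance in the
#' cancer samples to its mean abundance in the control samples, on the raw
#' (untransformed) scale, with a pseudocount added to both means so the
#' ratio is always finite:
#' `log2fc = log2((mean_cancer + pseudocount) / (mean_control + pseudocount))`.
#'
#' @param expr An [expression_matrix()].
#' @param pseudocount Nonnegative offset added to both group means
#'   (default 1).  Must be positive whenever a group mean can be zero.
#' @return Named numeric vector of log2 fold changes, one per feature.
#' @export
compute_log2fc <- function(expr, pseudocount = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      pseudocount < 0)
    stop("`pseudocount` must be a single nonnegative number", call. = FALSE)
  ca <- expr$groups == "cancer"
  co <- expr$groups == "control"
  m_ca <- rowMeans(expr$values[, ca, drop = FALSE])
  m_co <- rowMeans(expr$values[, co, drop = FALSE])
  if (pseudocount == 0 && any(m_co == 0)) {
    off <- rownames(expr$values)[m_co == 0]
    stop("zero control mean with pseudocount 0 for feature(s): ",
         paste(utils::head(off, 5), collapse = ", "), call. = FALSE)
  }
  log2((m_ca + pseudocount) / (m_co + pseudocount))
}

#' Two-group test of differential abundance
#'
#' Compares group means on the log2 scale (`log2(x + pseudocount)`).
#' `method = "welch"` is the Welch unequal-variance t-test.
#' `method = "moderated"` replaces each feature's pooled sample variance
#' with an empirical-Bayes posterior variance shrunk toward a prior
#' variance fitted across all features (scaled inverse chi-square prior,
#' method-of-moments on log variances), and refers the statistic to a t
#' distribution with augmented degrees of freedom.
#'
#' Features whose standard error is exactly zero are untestable: their
#' p-value is set to 1 and they are flagged, so downstream significance
#' gates remain total functions.
#'
#' @param expr An [expression_matrix()].
#' @param method `"welch"` (default) or `"moderated"`.
#' @param pseudocount Offset for the log transform (default 1).
#' @return Data frame with columns `feature_id`, `p_value`, `untestable`.
#' @export
two_group_test <- function(expr, method = c("welch", "moderated"),
                           pseudocount = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  method <- match.arg(method)
  ca <- expr$groups == "cancer"
  co <- expr$groups == "control"
  n1 <- sum(ca); n2 <- sum(co)
  if (n1 < 2 || n2 < 2)
    stop("two_group_test needs >=2 samples per group (got ", n1, " cancer, ",
         n2, " control)", call. = FALSE)
  x <- log2(expr$values + pseudocount)
  x1 <- x[, ca, drop = FALSE]
  x2 <- x[, co, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var)
  v2 <- apply(x2, 1, stats::var)
  diff <- m1 - m2

  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    untestable <- se2 == 0
    tstat <- ifelse(untestable, 0, diff / sqrt(se2))
    df <- ifelse(untestable, 1,
                 se2^2 / (((v1 / n1)^2 / (n1 - 1)) + ((v2 / n2)^2 / (n2 - 1))))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  } else {
    d <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
    untestable <- s2 == 0
    fit <- fit_variance_prior(s2[!untestable], d)
    if (is.finite(fit$df_prior)) {
      s2_post <- (fit$df_prior * fit$var_prior + d * s2) /
        (fit$df_prior + d)
    } else {
      s2_post <- rep(fit$var_prior, length(s2))
    }
    df_total <- d + fit$df_prior
    tstat <- ifelse(untestable, 0,
                    diff / sqrt(s2_post * (1 / n1 + 1 / n2)))
    if (is.finite(df_total)) {
      p <- 2 * stats::pt(abs(tstat), df_total, lower.tail = FALSE)
    } else {
      p <- 2 * stats::pnorm(abs(tstat), lower.tail = FALSE)
    }
  }
  p[untestable] <- 1
  data.frame(feature_id = rownames(expr$values),
             p_value = unname(pmin(pmax(p, 0), 1)),
             untestable = unname(untestable),
             stringsAsFactors = FALSE)
}

# Method-of-moments fit of a scaled inverse chi-square prior to per-feature
# pooled variances s2 with common residual df d.  Works on the log scale:
# e = log(s2) - digamma(d/2) + log(d/2) is an unbiased estimate of
# log(sigma^2); its excess variance over trigamma(d/2) identifies the prior
# df via trigamma inversion.
fit_variance_prior <- function(s2, d) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2)
    return(list(df_prior = Inf,
                var_prior = if (length(s2)) mean(s2) else 1))
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  excess <- mean((e - mean(e))^2) * length(e) / (length(e) - 1) -
    trigamma(d / 2)
  if (excess <= 0) {
    df_prior <- Inf
    var_prior <- exp(mean(e))
  } else {
    df_prior <- 2 * trigamma_inverse(excess)
    var_prior <- exp(mean(e) + digamma(df_prior / 2) -
                       log(df_prior / 2))
  }
  list(df_prior = df_prior, var_prior = var_prior)
}

# Solve trigamma(y) = x for y > 0 by Newton iteration (monotone decreasing).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic BH false discovery rate adjustment: for p-values sorted
#' ascending, `p_adj(k) = min over j >= k of m * p(j) / j`, clipped to 1,
#' returned in the original input order.
#'
#' @param p_values Numeric vector of p-values, all in `[0, 1]`.
#' @return Numeric vector of adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values))
    stop("`p_values` must be numeric", call. = FALSE)
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must all lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Full differential expression analysis with significance gate
#'
#' Computes per-feature log2 fold change, a two-group p-value, BH-adjusted
#' FDR, and the significance flag
#' `significant = (fdr < alpha) & (|log2fc| > log2(fc_threshold))`,
#' i.e. a two-sided fold-change gate (FDR < 0.05 and FC > 1.5 with the
#' defaults).
#'
#' @param expr An [expression_matrix()].
#' @param alpha FDR threshold in (0, 1); default 0.05.
#' @param fc_threshold Fold-change threshold on the raw scale, > 1;
#'   default 1.5.
#' @param method Test method, see [two_group_test()].
#' @param pseudocount Offset for fold change and log transform; default 1.
#' @return Data frame with columns `feature_id`, `log2fc`, `p_value`,
#'   `fdr`, `significant`, `untestable`, one row per feature in input
#'   order.
#' @export
differential_expression <- function(expr, alpha = 0.05, fc_threshold = 1.5,
                                    method = c("welch", "moderated"),
                                    pseudocount = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(fc_threshold) || length(fc_threshold) != 1 ||
      fc_threshold <= 1)
    stop("`fc_threshold` must exceed 1", call. = FALSE)
  method <- match.arg(method)
  lfc <- compute_log2fc(expr, pseudocount)
  tst <- two_group_test(expr, method, pseudocount)
  fdr <- bh_adjust(tst$p_value)
  data.frame(feature_id = tst$feature_id,
             log2fc = unname(lfc[tst$feature_id]),
             p_value = tst$p_value,
             fdr = fdr,
             significant = fdr < alpha &
               abs(unname(lfc[tst$feature_id])) > log2(fc_threshold),
             untestable = tst$untestable,
             stringsAsFactors = FALSE)
}

#' Restrict a differential expression table to a gene subset
#'
#' Filters an existing result set (FDR already adjusted over the full
#' family) to the given features, or optionally re-adjusts the FDR within
#' the subset only.
#'
#' @param de Data frame from [differential_expression()].
#' @param features Character vector of feature ids to keep.
#' @param readjust If `TRUE`, recompute `fdr` and `significant` by BH over
#'   the subset alone, using `alpha` and `fc_threshold`.
#' @param alpha,fc_threshold Gate parameters used only when
#'   `readjust = TRUE`.
#' @return Filtered data frame, input row order preserved.
#' @export
subset_de <- function(de, features, readjust = FALSE, alpha = 0.05,
                      fc_threshold = 1.5) {
  out <- de[de$feature_id %in% features, , drop = FALSE]
  if (readjust && nrow(out)) {
    out$fdr <- bh_adjust(out$p_value)
    out$significant <- out$fdr < alpha &
      abs(out$log2fc) > log2(fc_threshold)
  }
  rownames(out) <- NULL
  out
}
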
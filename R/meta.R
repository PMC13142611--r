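# Fixed-effects meta-analysis of per-cohort summary statistics. Only
# summary-level results cross cohort boundaries (the federated pattern).

#' Inverse-variance fixed-effects meta-analysis
#'
#' Pools per-cohort effect estimates with weights `1/se^2`: pooled beta is
#' the weighted mean, pooled SE is `1/sqrt(sum(w))`, p is two-sided
#' normal. Cochran's Q and I-squared are reported for transparency but the
#' estimator never switches to random effects: the per-cohort scaling makes
#' the estimand (effect relative to same-sex, same-age peers in SD units)
#' the same quantity in every cohort.
#'
#' @param beta Numeric per-cohort estimates.
#' @param se Numeric per-cohort standard errors (all > 0).
#' @return Object of class `meta_result`: `beta`, `se`, `z`, `p`, `k`,
#'   `Q`, `I2`, and the per-study inputs.
#' @export
fixed_effects_meta <- function(beta, se) {
  if (length(beta) == 0L) stop("no studies to pool")
  if (length(beta) != length(se)) stop("beta and se lengths differ")
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se <= 0)) {
    stop("betas must be finite and SEs positive")
  }
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  Q <- sum(w * (beta - b)^2)
  k <- length(beta)
  I2 <- if (k > 1L && Q > 0) max(0, (Q - (k - 1)) / Q) else 0
  structure(list(beta = b, se = s, z = z,
                 p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
                 k = k, Q = Q, I2 = I2,
                 studies = data.frame(beta = beta, se = se, weight = w)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> k = %d: beta = %.4f (SE %.4f), z = %.2f, p = %.3g\n",
              x$k, x$beta, x$se, x$z, x$p))
  cat(sprintf("  heterogeneity: Q = %.3f, I2 = %.1f%%\n", x$Q, 100 * x$I2))
  invisible(x)
}

#' Pool variance-explained estimates across cohorts
#'
#' Three-step pooling of per-cohort R-squared values: Fisher-transform the
#' square root (`z = atanh(sqrt(R2))`), pool by fixed-effects with weights
#' `n - 3` (the inverse sampling variance of Fisher's z for a
#' correlation), then back-transform (`tanh(z)^2`).
#'
#' @param r2 Per-cohort R-squared values in `[0, 1)`.
#' @param n Per-cohort sample sizes (> 3).
#' @return Pooled R-squared (scalar).
#' @export
pool_r2 <- function(r2, n) {
  if (length(r2) != length(n)) stop("r2 and n lengths differ")
  if (any(r2 < 0) || any(r2 >= 1)) stop("R2 must lie in [0, 1)")
  if (any(n <= 3)) stop("need n > 3 in every cohort")
  z <- atanh(sqrt(r2))
  w <- n - 3
  tanh(sum(w * z) / sum(w))^2
}

#' Pooled incremental variance explained by CNVs
#'
#' Difference between the pooled R-squared of the full (CNV + covariates)
#' model and the covariate-only model across matched cohorts.
#'
#' @param r2_full,r2_cov Per-cohort R-squared values of the two nested
#'   models, in the same cohort order.
#' @param n Per-cohort sample sizes.
#' @return Pooled delta R-squared (scalar).
#' @export
pooled_delta_r2 <- function(r2_full, r2_cov, n) {
  if (length(r2_full) != length(r2_cov)) {
    stop("cohort mismatch between full and covariate-only results")
  }
  pool_r2(r2_full, n) - pool_r2(r2_cov, n)
}

#' Bonferroni significance flags
#'
#' Flags p-values below `0.05/m` (strict inequality).
#'
#' @param p Numeric p-values.
#' @param m Number of tests corrected for (must cover the tests intended,
#'   e.g. 47 for locus main effects, 32 for interaction tests).
#' @param alpha Family-wise error rate (default 0.05).
#' @return List: `significant` (logical), `threshold`, `p_adjusted`
#'   (Bonferroni-adjusted, capped at 1).
#' @export
bonferroni <- function(p, m, alpha = 0.05) {
  if (length(p) > m) stop("m smaller than the number of tests supplied")
  thr <- alpha / m
  list(significant = p < thr, threshold = thr,
       p_adjusted = pmin(1, p * m))
}

#' Meta-analyze per-cohort association results by allele
#'
#' Groups a stacked table of per-cohort [fit_main_effect()] or
#' [fit_interaction()] rows by (span, allele) and pools each group by
#' [fixed_effects_meta()]. Alleles whose total carrier count across
#' cohorts falls below `min_carriers` are excluded (>= 10 for main
#' effects; interaction designs use >= 200 upstream).
#'
#' @param results data.frame with columns `span`, `allele`, `beta`, `se`,
#'   `n_carriers` (stacked across cohorts).
#' @param min_carriers Combined-carrier inclusion threshold (default 10).
#' @return data.frame of class `meta_table`: one row per allele with
#'   pooled `beta`, `se`, `z`, `p`, `k`, `Q`, `I2`, `n_carriers`.
#' @export
meta_assoc <- function(results, min_carriers = 10) {
  key <- paste(results$span, results$allele, sep = "\r")
  rows <- lapply(unique(key), function(k) {
    sub <- results[key == k, , drop = FALSE]
    total <- sum(sub$n_carriers)
    if (total < min_carriers) return(NULL)
    m <- fixed_effects_meta(sub$beta, sub$se)
    data.frame(span = sub$span[1L], allele = sub$allele[1L],
               beta = m$beta, se = m$se, z = m$z, p = m$p, k = m$k,
               Q = m$Q, I2 = m$I2, n_carriers = total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(span = character(0), allele = character(0),
                      beta = numeric(0), se = numeric(0), z = numeric(0),
                      p = numeric(0), k = integer(0), Q = numeric(0),
                      I2 = numeric(0), n_carriers = numeric(0))
  }
  rownames(out) <- NULL
  class(out) <- c("meta_table", "data.frame")
  out
}
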
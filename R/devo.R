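# Age-dependent trajectory analysis and age-binned cross-sectional
# mediation. Pediatric z-scores come from an LMS reference, so the
# non-carrier population expectation is 0 at every age; trajectory models
# ask whether the carrier offset varies with age.

#' Test an age-dependent carrier effect on a pediatric z-score
#'
#' Compares a null model (constant carrier offset: `z ~ carrier`) to a
#' full model that adds a natural-cubic-spline basis in age for carriers
#' (`z ~ carrier + carrier:ns(age, df)`) by likelihood-ratio test with
#' `df` degrees of freedom. Fixed-df splines keep the nested LRT on a
#' standard chi-square reference (a penalized smooth would make it
#' approximate).
#'
#' @param z Pediatric z-scores (trait relative to the growth reference).
#' @param age Ages in years.
#' @param carrier Logical/0-1 carrier flag.
#' @param df Spline basis dimension (default 5).
#' @return Object of class `trajectory_fit`: `statistic`, `df`, `p`,
#'   `loglik_null`, `loglik_full`, the full-model `fit`, and a
#'   `smooth` data.frame (fitted carrier trajectory over the carrier age
#'   range, with pointwise SE).
#' @export
fit_age_smooth <- function(z, age, carrier, df = 5) {
  carrier <- as.numeric(carrier)
  ages_c <- age[carrier == 1]
  if (length(unique(ages_c)) < 3L) {
    stop("carriers must span at least 3 distinct ages")
  }
  basis <- splines::ns(age, df = df)
  dat <- data.frame(z = z, carrier = carrier)
  fit0 <- stats::lm(z ~ carrier, data = dat)
  fit1 <- stats::lm(z ~ carrier + carrier:basis, data = dat)
  n <- length(z)
  stat <- n * log(sum(stats::resid(fit0)^2) / sum(stats::resid(fit1)^2))
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  grid <- seq(min(ages_c), max(ages_c), length.out = 50L)
  gb <- stats::predict(basis, grid)
  Xg <- cbind(1, 1, gb)                     # intercept, carrier, carrier:basis
  cf <- stats::coef(fit1)
  V <- stats::vcov(fit1)
  smooth <- data.frame(age = grid,
                       z = as.vector(Xg %*% cf),
                       se = sqrt(rowSums((Xg %*% V) * Xg)))
  structure(list(statistic = stat, df = df, p = p,
                 loglik_null = as.numeric(stats::logLik(fit0)),
                 loglik_full = as.numeric(stats::logLik(fit1)),
                 fit = fit1, smooth = smooth, n_carriers = sum(carrier)),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf(
    "<trajectory_fit> LRT chi2(%d) = %.2f, p = %.3g (%d carriers)\n",
    x$df, x$statistic, x$p, x$n_carriers))
  invisible(x)
}

#' @export
plot.trajectory_fit <- function(x, ...) {
  s <- x$smooth
  plot(s$age, s$z, type = "l", lwd = 2, xlab = "age (years)",
       ylab = "trait z-score", ...)
  graphics::lines(s$age, s$z + 1.96 * s$se, lty = 2)
  graphics::lines(s$age, s$z - 1.96 * s$se, lty = 2)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Compare age trajectories between two groups
#'
#' Nested comparison of a shared-smooth model (`z ~ group + ns(age, df)`)
#' against a group-specific-smooth model (`z ~ group * ns(age, df)`),
#' typically applied to carriers split by obesity status, sex, or PGS
#' quartile. The LRT statistic is invariant to swapping group labels.
#'
#' @param z,age As in [fit_age_smooth()].
#' @param group Two-level factor/character/logical group labels.
#' @param df Spline basis dimension (default 5).
#' @return List of class `trajectory_fit`-like: `statistic`, `df`, `p`.
#' @export
compare_trajectories_by_group <- function(z, age, group, df = 5) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly 2 levels")
  if (any(table(group) == 0L)) stop("one group is empty")
  basis <- splines::ns(age, df = df)
  fit0 <- stats::lm(z ~ group + basis)
  fit1 <- stats::lm(z ~ group * basis)
  n <- length(z)
  stat <- n * log(sum(stats::resid(fit0)^2) / sum(stats::resid(fit1)^2))
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p = p,
                 loglik_null = as.numeric(stats::logLik(fit0)),
                 loglik_full = as.numeric(stats::logLik(fit1)),
                 n_by_group = as.vector(table(group))),
            class = "trajectory_comparison")
}

#' @export
print.trajectory_comparison <- function(x, ...) {
  cat(sprintf(
    "<trajectory_comparison> LRT chi2(%d) = %.2f, p = %.3g (groups n = %s)\n",
    x$df, x$statistic, x$p, paste(x$n_by_group, collapse = "/")))
  invisible(x)
}

#' Split samples into obese / non-obese by a BMI percentile cutoff
#'
#' @param bmi_z Pediatric BMI z-scores.
#' @param percentile Population percentile defining obesity (default
#'   0.90; a 0.30 preset suits alleles where obesity is sparse).
#' @return Logical obesity flag.
#' @export
obesity_flag <- function(bmi_z, percentile = 0.90) {
  bmi_z > stats::qnorm(percentile)
}

# Product-of-coefficients estimates from one dataset.
.mediation_point <- function(bmi, height, sex, age, carrier, reverse) {
  sex <- as.numeric(factor(sex))
  if (reverse) { tmp <- bmi; bmi <- height; height <- tmp }
  Xm <- cbind(1, sex, age, carrier)
  Xo <- cbind(1, bmi, sex, age, carrier)
  qm <- qr(Xm)
  qo <- qr(Xo)
  if (qm$rank < ncol(Xm) || qo$rank < ncol(Xo)) return(NULL)
  a <- qr.coef(qm, bmi)[4L]           # CNV -> mediator
  ob <- qr.coef(qo, height)
  b <- ob[2L]                         # mediator -> outcome
  ade <- ob[5L]                       # direct CNV -> outcome
  acme <- a * b
  c(acme = unname(acme), ade = unname(ade),
    prop = unname(acme / (acme + ade)))
}

#' Age-binned cross-sectional mediation of CNV effects via BMI
#'
#' Within each age bin, fits the mediator model `BMI ~ sex + age + CNV`
#' and the outcome model `height ~ BMI + sex + age + CNV` on raw
#' phenotype values, and decomposes the CNV effect on height into the
#' indirect path through BMI (ACME, the product of coefficients) and the
#' direct path (ADE, the outcome-model CNV coefficient). Percentile
#' bootstrap confidence intervals resample individuals with replacement;
#' replicates with singular fits are dropped and counted. `reverse = TRUE`
#' swaps mediator and outcome (CNV -> height -> BMI), the falsification
#' check for directionality.
#'
#' @param bmi,height Raw phenotype values.
#' @param sex,age Covariates.
#' @param carrier Logical/0-1 carrier flag.
#' @param bins Age bin boundaries; bins are upper-exclusive (`c(2, 8, 13,
#'   18)` gives 2-8, 8-13, 13-18, where "8-13" means at least 8 and under
#'   13).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed (private stream; fixed seed gives bit-identical
#'   CIs).
#' @param reverse Swap mediator and outcome.
#' @param min_carriers Bins with fewer carriers are flagged underpowered.
#' @return data.frame of class `mediation_result`, one row per bin:
#'   `acme`, `ade`, `prop_mediated` with percentile CIs, `n`,
#'   `n_carriers`, `underpowered`, `n_boot_failed`, `direction`.
#' @export
mediate_by_age <- function(bmi, height, sex, age, carrier,
                           bins = c(2, 8, 13, 18), n_boot = 1000,
                           seed = 1, reverse = FALSE, min_carriers = 10) {
  carrier <- as.numeric(carrier)
  rows <- list()
  for (i in seq_len(length(bins) - 1L)) {
    lo <- bins[i]; hi <- bins[i + 1L]
    idx <- which(age >= lo & age < hi)
    label <- paste0(lo, "-", hi)
    nc <- sum(carrier[idx])
    pt <- .mediation_point(bmi[idx], height[idx], sex[idx], age[idx],
                           carrier[idx], reverse)
    if (is.null(pt)) stop("singular mediation fit in bin ", label)
    boot <- .with_seed(.child_seed(seed, i), {
      out <- matrix(NA_real_, nrow = n_boot, ncol = 3L)
      for (r in seq_len(n_boot)) {
        bi <- idx[sample.int(length(idx), replace = TRUE)]
        est <- .mediation_point(bmi[bi], height[bi], sex[bi], age[bi],
                                carrier[bi], reverse)
        if (!is.null(est)) out[r, ] <- est
      }
      out
    })
    ok <- stats::complete.cases(boot)
    ci <- apply(boot[ok, , drop = FALSE], 2L, stats::quantile,
                probs = c(0.025, 0.975), names = FALSE)
    rows[[i]] <- data.frame(
      bin = label, acme = pt[["acme"]], acme_lo = ci[1L, 1L],
      acme_hi = ci[2L, 1L], ade = pt[["ade"]], ade_lo = ci[1L, 2L],
      ade_hi = ci[2L, 2L], prop_mediated = pt[["prop"]],
      n = length(idx), n_carriers = nc,
      underpowered = nc < min_carriers,
      n_boot_failed = sum(!ok),
      direction = if (reverse) "reverse" else "forward",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mediation_result", "data.frame")
  out
}
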
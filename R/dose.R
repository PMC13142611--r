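# Dose-response curve construction, 1- vs 2-component linear
# decomposition, and sex-difference analyses across loci.

#' Pair deletion and duplication meta-effects into dose-response points
#'
#' Matches DEL and DUP meta-analyzed effects by span and keeps spans with
#' at least `min_carriers` carriers for BOTH alleles. The Pearson
#' correlation of DEL vs DUP effects (the dose-response signature: mirror
#' effects give a negative correlation) is attached.
#'
#' @param meta_del,meta_dup data.frames with `span`, `beta`, `se`,
#'   `n_carriers` (e.g. rows of a [meta_assoc()] table split by allele).
#' @param min_carriers Per-allele carrier threshold (default 10).
#' @return data.frame of class `dose_points`: `span`, `beta_del`,
#'   `se_del`, `beta_dup`, `se_dup`, carrier counts; attribute
#'   `"correlation"`.
#' @export
build_dose_points <- function(meta_del, meta_dup, min_carriers = 10) {
  common <- intersect(meta_del$span, meta_dup$span)
  d <- meta_del[match(common, meta_del$span), , drop = FALSE]
  u <- meta_dup[match(common, meta_dup$span), , drop = FALSE]
  keep <- d$n_carriers >= min_carriers & u$n_carriers >= min_carriers
  if (!any(keep)) stop("no spans pass the carrier filter for both alleles")
  out <- data.frame(span = common[keep],
                    beta_del = d$beta[keep], se_del = d$se[keep],
                    beta_dup = u$beta[keep], se_dup = u$se[keep],
                    n_del = d$n_carriers[keep], n_dup = u$n_carriers[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "correlation") <- if (nrow(out) > 2L) {
    stats::cor(out$beta_del, out$beta_dup)
  } else NA_real_
  class(out) <- c("dose_points", "data.frame")
  out
}

# log-likelihood of a mixture of linear regressions with per-point
# measurement error variance added to each component's residual variance.
.mixreg_loglik <- function(x, y, se2, par) {
  dens <- vapply(seq_along(par$pi), function(j) {
    par$pi[j] * stats::dnorm(y, par$a[j] + par$b[j] * x,
                             sqrt(par$sigma2[j] + se2))
  }, numeric(length(y)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(y))
  sum(log(rowSums(dens)))
}

# One EM run from a given responsibility matrix. Generalized EM: exact
# (a, b) update by weighted least squares at fixed sigma2, then 1-D
# maximization of the expected log-likelihood in sigma2 -- both coordinate
# ascent steps, so the log-likelihood is monotone.
.mixreg_em <- function(x, y, se2, resp, max_iter = 500, tol = 1e-10) {
  k <- ncol(resp)
  par <- list(pi = rep(1 / k, k), a = numeric(k), b = numeric(k),
              sigma2 = rep(stats::var(y), k))
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # M-step
    for (j in seq_len(k)) {
      w <- resp[, j] / (par$sigma2[j] + se2)
      sw <- sum(w)
      mx <- sum(w * x) / sw
      my <- sum(w * y) / sw
      sxx <- sum(w * (x - mx)^2)
      b <- if (sxx > 0) sum(w * (x - mx) * (y - my)) / sxx else 0
      a <- my - b * mx
      res2 <- (y - a - b * x)^2
      obj <- function(s2) {
        -0.5 * sum(resp[, j] * (log(s2 + se2) + res2 / (s2 + se2)))
      }
      opt <- stats::optimize(obj, interval = c(1e-12, 25 * stats::var(y) + 1),
                             maximum = TRUE, tol = 1e-12)
      par$a[j] <- a; par$b[j] <- b; par$sigma2[j] <- opt$maximum
      par$pi[j] <- mean(resp[, j])
    }
    par$pi <- par$pi / sum(par$pi)
    # E-step
    dens <- vapply(seq_len(k), function(j) {
      par$pi[j] * stats::dnorm(y, par$a[j] + par$b[j] * x,
                               sqrt(par$sigma2[j] + se2))
    }, numeric(length(y)))
    if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(y))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    resp <- dens / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(par = par, loglik = ll_old, resp = resp, converged = converged)
}

#' Fit a k-component linear decomposition of the dose-response curve
#'
#' Fits a Gaussian mixture of linear regressions of the duplication effect
#' on the deletion effect across loci, with each point's squared standard
#' error on the response added to the component noise (known measurement
#' error). `k = 1` is a single weighted regression; `k = 2` separates a
#' "mirror" component (negative slope: DEL and DUP move the trait in
#' opposite directions) from an "asymmetric" component (near-zero slope:
#' one allele null regardless of the other). Fitting is by multi-start EM;
#' one start for `k = 2` is seeded from the `k = 1` solution so the
#' 2-component log-likelihood can never fall below the 1-component one.
#'
#' @param points A [build_dose_points()] table.
#' @param k Number of linear components (1 or 2).
#' @param n_starts Number of seeded random restarts (default 20).
#' @param seed RNG seed for the restarts; identical seeds give identical
#'   fits. Uses a private RNG stream.
#' @param max_iter,tol EM iteration control.
#' @return Object of class `component_fit`: component `intercept`,
#'   `slope`, `sigma2`, mixing `pi`, per-locus posterior
#'   `responsibilities` and hard `assignment`, `loglik`, `bic`,
#'   `converged`.
#' @export
fit_components <- function(points, k = 2, n_starts = 20, seed = 1,
                           max_iter = 500, tol = 1e-10) {
  x <- points$beta_del
  y <- points$beta_dup
  se2 <- points$se_dup^2
  n <- length(x)
  if (n < 2 * k + 2) stop("need at least ", 2 * k + 2, " points for k = ", k)
  starts <- list()
  if (k == 1L) {
    starts[[1L]] <- matrix(1, nrow = n, ncol = 1L)
  } else {
    # deterministic starts: split by x order, and from the k=1 fit
    o <- rank(x, ties.method = "first")
    hard <- function(groups) {
      r <- matrix(0.05 / (k - 1), nrow = n, ncol = k)
      r[cbind(seq_len(n), groups)] <- 0.95
      r
    }
    starts[[1L]] <- hard(1L + as.integer(o > n / 2))
    fit1 <- .mixreg_em(x, y, se2, matrix(1, n, 1L), max_iter, tol)
    # degenerate split of the 1-component solution: equal components,
    # responsibilities 0.5 -- EM can only improve on the k=1 likelihood
    starts[["from_k1"]] <- matrix(0.5, nrow = n, ncol = 2L)
    starts <- c(starts, .with_seed(seed, {
      lapply(seq_len(max(0L, n_starts - 2L)), function(i) {
        g <- sample.int(k, n, replace = TRUE)
        # guarantee both components populated
        g[sample.int(n, k)] <- seq_len(k)
        hard(g)
      })
    }))
  }
  best <- NULL
  for (st in starts) {
    fit <- .mixreg_em(x, y, se2, st, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  npar <- 3L * k + (k - 1L)
  # order components by slope for stable labelling
  o <- order(best$par$b)
  par <- lapply(best$par, function(v) v[o])
  resp <- best$resp[, o, drop = FALSE]
  structure(list(k = k, intercept = par$a, slope = par$b,
                 sigma2 = par$sigma2, pi = par$pi,
                 responsibilities = resp,
                 assignment = max.col(resp),
                 loglik = best$loglik,
                 bic = -2 * best$loglik + npar * log(n),
                 n = n, converged = best$converged),
            class = "component_fit")
}

#' @export
print.component_fit <- function(x, ...) {
  cat(sprintf("<component_fit> k = %d, loglik = %.3f, BIC = %.3f%s\n",
              x$k, x$loglik, x$bic,
              if (!x$converged) " (not converged)" else ""))
  for (j in seq_len(x$k)) {
    cat(sprintf("  component %d: slope %.3f, intercept %.3f, sd %.3f, pi %.2f\n",
                j, x$slope[j], x$intercept[j], sqrt(x$sigma2[j]), x$pi[j]))
  }
  invisible(x)
}

#' Compare 1- vs 2-component dose-response decompositions
#'
#' Fits both models and selects by BIC.
#'
#' @inheritParams fit_components
#' @param ks Component counts to compare (default `1:2`).
#' @return List: `fits` (one `component_fit` per k), `bic`, `best_k`.
#' @export
compare_components <- function(points, ks = 1:2, n_starts = 20, seed = 1) {
  fits <- lapply(ks, function(k) {
    fit_components(points, k = k, n_starts = n_starts, seed = seed)
  })
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  list(fits = stats::setNames(fits, paste0("k", ks)), bic = bic,
       best_k = ks[which.min(bic)])
}

#' Test equality of male and female effect-size slopes
#'
#' Regresses female CNV effects on male effects across loci and tests the
#' joint linear hypothesis {intercept = 0, slope = 1} (deviation from the
#' identity line) by F-test. A slope different from 1 indicates
#' systematically different effect magnitudes between the sexes.
#'
#' @param male,female Numeric effect estimates over matched loci (x:
#'   male, y: female).
#' @return List of class `slope_test`: `slope`, `intercept`, `F`,
#'   `df1`, `df2`, `p`.
#' @export
slope_equality_test <- function(male, female) {
  if (length(male) != length(female)) stop("unmatched loci")
  n <- length(male)
  if (n < 3L) stop("need at least 3 loci")
  X <- cbind(1, male)
  qrx <- qr(X)
  res1 <- qr.resid(qrx, female)
  rss1 <- sum(res1^2)
  coefs <- qr.coef(qrx, female)
  rss0 <- sum((female - male)^2)     # restricted: intercept 0, slope 1
  df2 <- n - 2L
  if (rss1 < 1e-24 && rss0 < 1e-24) {
    Fs <- 0; p <- 1
  } else {
    Fs <- ((rss0 - rss1) / 2) / (rss1 / df2)
    p <- stats::pf(Fs, 2, df2, lower.tail = FALSE)
  }
  structure(list(slope = unname(coefs[2L]), intercept = unname(coefs[1L]),
                 F = Fs, df1 = 2L, df2 = df2, p = p, n = n),
            class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf(
    "<slope_test> slope = %.3f, intercept = %.3f; F(%d, %d) = %.2f, p = %.3g\n",
    x$slope, x$intercept, x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Pooled female-minus-male contrasts grouped by main-effect direction
#'
#' Groups loci by the direction of their (sex-combined) meta main effect
#' -- positive or negative if Bonferroni-significant, neutral otherwise --
#' and pools the per-locus female-minus-male contrast within each group by
#' inverse-variance fixed effects. The contrast SE treats the sex-
#' stratified estimates as independent (exact for disjoint samples):
#' `sqrt(se_f^2 + se_m^2)`.
#'
#' @param sex_table data.frame over loci: `span`, `beta_f`, `se_f`,
#'   `beta_m`, `se_m`.
#' @param main_meta data.frame over the same spans: `span`, `beta`, `p`.
#' @param m Bonferroni correction count for the grouping (default 47).
#' @param alpha Family-wise alpha (default 0.05).
#' @return data.frame per group: pooled `contrast`, `se`, `z`, `p`, `k`.
#' @export
grouped_sex_difference <- function(sex_table, main_meta, m = 47,
                                   alpha = 0.05) {
  mm <- main_meta[match(sex_table$span, main_meta$span), , drop = FALSE]
  sig <- mm$p < alpha / m
  group <- ifelse(!sig, "neutral", ifelse(mm$beta > 0, "positive", "negative"))
  d <- sex_table$beta_f - sex_table$beta_m
  sed <- sqrt(sex_table$se_f^2 + sex_table$se_m^2)
  rows <- lapply(c("positive", "neutral", "negative"), function(gr) {
    idx <- which(group == gr)
    if (length(idx) == 0L) return(NULL)
    pm <- fixed_effects_meta(d[idx], sed[idx])
    data.frame(group = gr, contrast = pm$beta, se = pm$se, z = pm$z,
               p = pm$p, k = pm$k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
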
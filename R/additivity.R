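# Combinatorial decomposition of multi-segment loci: expected combined
# effects under additivity and deviation tests.

#' Expected effect of a composite CNV under additivity
#'
#' Sums the meta-analyzed effects of disjoint component spans; the
#' expected SE assumes independence (`sqrt(sum(se^2))`). Component and
#' composite estimates come from disjoint carrier groups that share only
#' the reference pool, so the induced covariance is small and ignoring it
#' is conservative.
#'
#' @param components data.frame with `span`, `beta`, `se` (one row per
#'   component span, same allele and trait).
#' @param locus Optional [segmented_locus()]; if supplied, the component
#'   spans are checked to be disjoint (no shared segments) and their
#'   union contiguous.
#' @return List: `beta` (sum), `se`, `spans`.
#' @export
expected_combined <- function(components, locus = NULL) {
  if (nrow(components) < 1L) stop("no component estimates")
  if (!is.null(locus)) {
    segs <- lapply(components$span, function(sp) .locus_span(locus, sp)$segments)
    all_segs <- unlist(segs)
    if (anyDuplicated(all_segs)) {
      stop("component spans overlap: segment(s) ",
           paste(unique(all_segs[duplicated(all_segs)]), collapse = ", "),
           " appear in more than one component")
    }
    seg_names <- vapply(locus$segments, `[[`, character(1), "name")
    idx <- sort(match(all_segs, seg_names))
    if (length(idx) > 1L && !all(diff(idx) == 1L)) {
      stop("component spans do not form a contiguous run")
    }
  }
  list(beta = sum(components$beta), se = sqrt(sum(components$se^2)),
       spans = components$span)
}

#' Test an observed composite effect against its additive expectation
#'
#' Deviation z-statistic `(observed - expected) / sqrt(se_obs^2 +
#' se_exp^2)` with a two-sided normal p. When the deviation is
#' significant at `alpha`, the verdict is `"sub-additive"` if the
#' observed magnitude is attenuated relative to the expected one
#' (buffering) and `"super-additive"` if amplified; otherwise
#' `"additive"`.
#'
#' @param observed_beta,observed_se Meta-analyzed composite-span effect.
#' @param expected [expected_combined()] output (or a list with `beta`,
#'   `se`).
#' @param alpha Verdict significance level (default 0.05; a single
#'   pre-specified composite test per locus).
#' @return data.frame of class `additivity_result`.
#' @export
additivity_test <- function(observed_beta, observed_se, expected,
                            alpha = 0.05) {
  z <- (observed_beta - expected$beta) /
    sqrt(observed_se^2 + expected$se^2)
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  verdict <- if (p >= alpha) {
    "additive"
  } else if (abs(observed_beta) < abs(expected$beta)) {
    "sub-additive"
  } else {
    "super-additive"
  }
  out <- data.frame(observed = observed_beta, observed_se = observed_se,
                    expected = expected$beta, expected_se = expected$se,
                    z = z, p = p, verdict = verdict,
                    stringsAsFactors = FALSE)
  class(out) <- c("additivity_result", "data.frame")
  out
}

#' Classify reinforcing versus opposing subregion effects
#'
#' Summarizes the directional structure of component effects at one
#' composite locus: pairs of nominally significant components with the
#' same sign reinforce, with opposite signs oppose (cancellation). The
#' predicted composite effect is the additive sum of all components.
#'
#' @param components data.frame with `span`, `beta`, `se` (and optionally
#'   `p`; recomputed from beta/se if absent).
#' @param alpha Significance threshold for calling a component non-null.
#' @return List of class `opposing_profile`: `pairs` (pairwise
#'   classification), `predicted_composite`, `dominant` (one of
#'   `"cancellation"`, `"reinforcement"`, `"single"`, `"none"`).
#' @export
opposing_effect_profile <- function(components, alpha = 0.05) {
  if (nrow(components) < 2L) stop("need at least 2 component estimates")
  p <- if (!is.null(components$p)) components$p else {
    2 * stats::pnorm(abs(components$beta / components$se), lower.tail = FALSE)
  }
  sig <- p < alpha
  n <- nrow(components)
  pairs <- list()
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    cls <- if (sig[i] && sig[j]) {
      if (sign(components$beta[i]) == sign(components$beta[j])) {
        "reinforcing"
      } else "opposing"
    } else if (sig[i] || sig[j]) "one-null" else "both-null"
    pairs[[length(pairs) + 1L]] <- data.frame(
      span_a = components$span[i], span_b = components$span[j],
      class = cls, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  dominant <- if (sum(sig) >= 2L) {
    if (length(unique(sign(components$beta[sig]))) > 1L) {
      "cancellation"
    } else "reinforcement"
  } else if (sum(sig) == 1L) "single" else "none"
  structure(list(pairs = pairs,
                 predicted_composite = sum(components$beta),
                 dominant = dominant,
                 components = components, significant = sig),
            class = "opposing_profile")
}

#' @export
print.opposing_profile <- function(x, ...) {
  cat("<opposing_profile>", x$dominant,
      "; predicted composite =", format(x$predicted_composite, digits = 4), "\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}
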
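# Per-cohort model fits: CNV main effects, interactions, variance
# explained, medication tabulation/enrichment and stratified means.

.pc_cols <- function(cohort) {
  pcs <- grep("^PC[0-9]+$", names(cohort), value = TRUE)
  pcs[order(as.integer(sub("PC", "", pcs)))]
}

.cohort_id <- function(cohort) {
  if (!is.null(cohort$cohort_id)) as.character(cohort$cohort_id[1L]) else NA_character_
}

#' Fit the CNV main-effect model in one cohort
#'
#' Least-squares fit of a scaled trait on the CNV genotype factor (DEL,
#' DUP, with no-CNV as the reference) plus the top ancestry principal
#' components, within one cohort. `NO_CALL` samples are dropped for the
#' span being tested. The coefficient for each allele is the mean trait
#' difference of carriers versus non-carriers in SD units.
#'
#' @param cohort Cohort data.frame: the scaled trait column, genotype
#'   column, and `PC1..PC10` (any number of `PC*` columns is accepted).
#' @param trait Name of the scaled trait column.
#' @param span Name of the genotype column (values DEL/DUP/REF/NO_CALL).
#' @return data.frame of class `assoc_result`, one row per allele present:
#'   `cohort_id`, `span`, `allele`, `beta`, `se`, `p`, `n_carriers`,
#'   `n_total`, `model`.
#' @export
fit_main_effect <- function(cohort, trait, span) {
  g <- as.character(cohort[[span]])
  keep <- g != "NO_CALL"
  all_keep <- all(keep)
  g <- g[keep]
  y <- cohort[[trait]][keep]
  n_del <- sum(g == "DEL")
  n_dup <- sum(g == "DUP")
  if (n_del + n_dup == 0L) {
    stop("no DEL or DUP carriers at span '", span, "'")
  }
  pcs <- .pc_cols(cohort)
  pc_mat <- vapply(pcs, function(p) {
    if (all_keep) cohort[[p]] else cohort[[p]][keep]
  }, numeric(length(y)))
  X <- cbind(`(Intercept)` = 1,
             DEL = as.numeric(g == "DEL"),
             DUP = as.numeric(g == "DUP"),
             pc_mat)
  present <- c(DEL = n_del > 0L, DUP = n_dup > 0L)
  X <- X[, c(TRUE, present, rep(TRUE, length(pcs))), drop = FALSE]
  fit <- .fast_lm(y, X)
  alleles <- names(present)[present]
  idx <- match(alleles, colnames(X))
  out <- data.frame(
    cohort_id = .cohort_id(cohort), span = span, allele = alleles,
    beta = unname(fit$coefficients[idx]), se = unname(fit$se[idx]),
    p = unname(fit$p[idx]),
    n_carriers = c(n_del, n_dup)[present],
    n_total = length(y), model = "main_effect",
    stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Fit a CNV x moderator interaction model in one cohort
#'
#' Models the scaled trait on genotype factor x moderator plus principal
#' components and returns the allele-by-moderator coefficient with its
#' standard error and z = beta/se. The moderator is a standardized
#' polygenic score or sex (converted to a 0/1 indicator, second factor
#' level = 1). The carrier-count filter (>= 200 combined carriers in the
#' paper-style design) is applied upstream, not here.
#'
#' @inheritParams fit_main_effect
#' @param moderator Name of the moderator column.
#' @return data.frame of class `assoc_result`, one row per allele:
#'   interaction `beta`, `se`, `z`, `p`, carrier counts.
#' @export
fit_interaction <- function(cohort, trait, span, moderator) {
  g <- as.character(cohort[[span]])
  keep <- g != "NO_CALL"
  g <- g[keep]
  y <- cohort[[trait]][keep]
  m <- cohort[[moderator]][keep]
  if (is.character(m) || is.factor(m)) {
    m <- factor(m)
    m <- as.numeric(m == levels(m)[2L])
  }
  if (stats::var(m) == 0) stop("moderator '", moderator, "' is constant")
  n_del <- sum(g == "DEL")
  n_dup <- sum(g == "DUP")
  if (n_del + n_dup == 0L) stop("no carriers at span '", span, "'")
  pcs <- .pc_cols(cohort)
  pc_mat <- vapply(pcs, function(p) cohort[[p]][keep], numeric(length(y)))
  del <- as.numeric(g == "DEL")
  dup <- as.numeric(g == "DUP")
  X <- cbind(`(Intercept)` = 1, mod = m, DEL = del, DUP = dup,
             `DEL:mod` = del * m, `DUP:mod` = dup * m, pc_mat)
  present <- c(DEL = n_del > 0L, DUP = n_dup > 0L)
  X <- X[, c(TRUE, TRUE, present, present, rep(TRUE, length(pcs))), drop = FALSE]
  fit <- .fast_lm(y, X)
  alleles <- names(present)[present]
  idx <- match(paste0(alleles, ":mod"), colnames(X))
  beta <- unname(fit$coefficients[idx])
  se <- unname(fit$se[idx])
  out <- data.frame(
    cohort_id = .cohort_id(cohort), span = span, allele = alleles,
    moderator = moderator, beta = beta, se = se, z = beta / se,
    p = unname(fit$p[idx]),
    n_carriers = c(n_del, n_dup)[present],
    n_total = length(y), model = "interaction",
    stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Variance in a trait explained by all recurrent CNV loci
#'
#' Compares the R-squared of a full model (every allele span coded as a
#' factor, plus principal components) to a covariate-only model (principal
#' components alone) within one cohort. Samples with `NO_CALL` at any
#' tested span are dropped listwise; collinear genotype columns are
#' handled by `lm()` aliasing with a warning.
#'
#' @inheritParams fit_main_effect
#' @param spans Character vector of genotype column names.
#' @return List: `r2_full`, `r2_cov`, `delta_r2` (always >= 0), `n`.
#' @export
variance_explained <- function(cohort, trait, spans) {
  gmat <- as.data.frame(lapply(cohort[spans], as.character),
                        stringsAsFactors = FALSE, check.names = FALSE)
  keep <- rowSums(gmat == "NO_CALL") == 0L
  y <- cohort[[trait]][keep]
  pcs <- .pc_cols(cohort)
  dat <- cohort[keep, pcs, drop = FALSE]
  cov_fml <- stats::as.formula(paste("y ~", paste(pcs, collapse = " + ")))
  fit_cov <- stats::lm(cov_fml, data = cbind(y = y, dat))
  used <- character(0)
  for (sp in spans) {
    g <- gmat[[sp]][keep]
    if (length(unique(g)) > 1L) {
      nm <- make.names(sp)
      dat[[nm]] <- factor(g, levels = c("REF", "DEL", "DUP"))
      dat[[nm]] <- droplevels(dat[[nm]])
      used <- c(used, nm)
    }
  }
  if (length(used) == 0L) {
    r2c <- summary(fit_cov)$r.squared
    return(list(r2_full = r2c, r2_cov = r2c, delta_r2 = 0, n = length(y)))
  }
  full_fml <- stats::as.formula(
    paste("y ~", paste(c(used, pcs), collapse = " + ")))
  fit_full <- stats::lm(full_fml, data = cbind(y = y, dat))
  if (any(is.na(stats::coef(fit_full)))) {
    warning("collinear genotype columns dropped by aliasing")
  }
  r2f <- summary(fit_full)$r.squared
  r2c <- summary(fit_cov)$r.squared
  list(r2_full = r2f, r2_cov = r2c, delta_r2 = max(0, r2f - r2c),
       n = length(y))
}

#' Tabulate psychiatric medication categories per sample
#'
#' Collapses per-sample prescribed medication codes into the three broad
#' categories (antidepressant, antipsychotic, mood stabilizer) plus their
#' union (`any`). A sample is flagged for a category if any of its codes
#' maps to it; codes missing from the dictionary are reported via the
#' `"unknown_codes"` attribute, not dropped silently as errors.
#'
#' @param prescriptions data.frame with `sample_id` and `code` (one row
#'   per prescribed medication), or empty.
#' @param dictionary data.frame mapping `code` to `category`, categories
#'   in `c("antidepressant", "antipsychotic", "mood_stabilizer")`.
#' @param samples Character vector of all sample ids (so samples with no
#'   prescriptions get all-FALSE rows).
#' @return data.frame: `sample_id`, `antidepressant`, `antipsychotic`,
#'   `mood_stabilizer`, `any`.
#' @export
tabulate_medications <- function(prescriptions, dictionary,
                                 samples = unique(prescriptions$sample_id)) {
  cats <- c("antidepressant", "antipsychotic", "mood_stabilizer")
  samples <- sort(unique(as.character(samples)))
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (ct in cats) out[[ct]] <- FALSE
  unknown <- character(0)
  if (nrow(prescriptions) > 0L) {
    cat_of <- dictionary$category[match(prescriptions$code, dictionary$code)]
    unknown <- unique(as.character(prescriptions$code[is.na(cat_of)]))
    ok <- !is.na(cat_of)
    for (ct in cats) {
      flagged <- unique(as.character(
        prescriptions$sample_id[ok & cat_of == ct]))
      out[[ct]] <- out$sample_id %in% flagged
    }
  }
  out$any <- out$antidepressant | out$antipsychotic | out$mood_stabilizer
  if (length(unknown)) {
    message(length(unknown), " unknown medication code(s) ignored")
    attr(out, "unknown_codes") <- unknown
  }
  out
}

# Uncorrected chi-square for a 2x2 table given as c(a, b, c, d) rows
# (exposed, unexposed) x (yes, no).
.chisq2x2 <- function(a, b, c, d) {
  a <- as.double(a); b <- as.double(b); c <- as.double(c); d <- as.double(d)
  n <- a + b + c + d
  num <- n * (a * d - b * c)^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  if (den == 0) stop("degenerate margins in 2x2 table")
  stat <- num / den
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Medication enrichment among CNV carriers
#'
#' For each medication class, a 2x2 chi-square test (no continuity
#' correction) of carrier status against lifetime medication use. Carriers
#' are samples with a DEL or DUP genotype at the span; `NO_CALL` samples
#' are dropped.
#'
#' @inheritParams fit_main_effect
#' @param classes Medication flag columns to test.
#' @return data.frame per class: counts, `chisq`, `p`.
#' @export
medication_enrichment <- function(cohort, span,
                                  classes = c("antidepressant", "antipsychotic",
                                              "mood_stabilizer", "any")) {
  g <- as.character(cohort[[span]])
  keep <- g != "NO_CALL"
  carrier <- g[keep] %in% c("DEL", "DUP")
  if (!any(carrier)) stop("no carriers at span '", span, "'")
  rows <- lapply(classes, function(cl) {
    use <- as.logical(cohort[[cl]][keep])
    a <- sum(carrier & use); b <- sum(carrier & !use)
    c_ <- sum(!carrier & use); d <- sum(!carrier & !use)
    ts <- .chisq2x2(a, b, c_, d)
    data.frame(class = cl, carrier_use = a, carrier_nonuse = b,
               ref_use = c_, ref_nonuse = d,
               chisq = ts$statistic, p = ts$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group means of a raw trait by genotype and strata
#'
#' Stratifies samples by genotype and by polygenic-score quartile and/or a
#' medication flag, and reports the mean raw trait per cell with n and SE,
#' plus the max - min range across non-empty cells -- the "combined
#' effects" summary used to illustrate how polygenic background and
#' medication shift the baseline on which a CNV acts. PGS quartiles are
#' computed on the full cohort (carriers are rare enough not to distort
#' the quartile boundaries).
#'
#' @inheritParams fit_main_effect
#' @param trait Name of the RAW trait column (natural units).
#' @param pgs Optional name of a PGS column to stratify into quartiles.
#' @param medication Optional name of a logical medication flag column.
#' @return List of class `stratified_means`: `table` (one row per cell)
#'   and `range` (max - min of cell means, cells with n > 0 only).
#' @export
stratified_means <- function(cohort, trait, span, pgs = NULL,
                             medication = NULL) {
  g <- as.character(cohort[[span]])
  keep <- g != "NO_CALL"
  df <- data.frame(y = cohort[[trait]][keep],
                   genotype = factor(g[keep], levels = c("REF", "DEL", "DUP")),
                   stringsAsFactors = FALSE)
  strata <- list(genotype = df$genotype)
  if (!is.null(pgs)) {
    q <- stats::quantile(cohort[[pgs]], probs = seq(0, 1, 0.25), names = FALSE)
    q[1L] <- -Inf; q[5L] <- Inf
    strata$pgs_quartile <- cut(cohort[[pgs]][keep], breaks = q,
                               labels = paste0("Q", 1:4))
  }
  if (!is.null(medication)) {
    strata$medication <- factor(as.logical(cohort[[medication]][keep]),
                                levels = c(FALSE, TRUE))
  }
  cells <- expand.grid(lapply(strata, levels), stringsAsFactors = FALSE)
  names(cells) <- names(strata)
  idx <- interaction(strata, drop = FALSE)
  key <- interaction(cells, drop = FALSE)
  stats_by <- function(f) {
    vapply(levels(idx), function(lv) {
      v <- df$y[idx == lv]
      f(v)
    }, numeric(1))[match(as.character(key), levels(idx))]
  }
  cells$n <- stats_by(length)
  cells$mean <- stats_by(function(v) if (length(v)) mean(v) else NA_real_)
  cells$se <- stats_by(function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_)
  nonempty <- cells$n > 0 & !is.na(cells$mean)
  rng <- if (any(nonempty)) diff(range(cells$mean[nonempty])) else NA_real_
  structure(list(table = cells, range = rng), class = "stratified_means")
}

#' @export
print.stratified_means <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("range of cell means:", format(x$range), "\n")
  invisible(x)
}
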
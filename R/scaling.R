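#' Residualize a raw trait on sex and age
#'
#' First stage of the harmonized adult scaling: least-squares residuals of
#' the raw trait on sex, age and age squared. Residuals are orthogonal to
#' the design at machine precision.
#'
#' @param y Numeric raw trait values.
#' @param sex Factor or character/numeric sex (two levels).
#' @param age Numeric age.
#' @return Numeric residual vector.
#' @export
residualize_trait <- function(y, sex, age) {
  if (length(y) <= 4L) stop("need more than 4 observations to residualize")
  if (anyNA(y) || anyNA(sex) || anyNA(age)) stop("missing values in y, sex or age")
  sex <- factor(sex)
  if (nlevels(sex) < 2L) stop("sex is constant: design is rank deficient")
  if (stats::var(age) == 0) stop("age is constant: design is rank deficient")
  X <- cbind(1, as.numeric(sex == levels(sex)[2L]), age, age^2)
  qr.resid(qr(X), y)
}

# Profile log-likelihood of the Box-Cox parameter for positive data x.
.boxcox_loglik <- function(lambda, x, logx_sum) {
  n <- length(x)
  z <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  s2 <- sum((z - mean(z))^2) / n
  -n / 2 * log(s2) + (lambda - 1) * logx_sum
}

#' Maximum-likelihood Box-Cox exponent
#'
#' Profile-likelihood estimate of the Box-Cox lambda on `[-5, 5]`;
#' near-ties against lambda = 1 resolve to 1 (no transformation).
#'
#' @param x Strictly positive numeric data.
#' @return The estimated lambda.
#' @export
boxcox_lambda <- function(x) {
  if (any(x <= 0)) stop("Box-Cox requires strictly positive data")
  ls <- sum(log(x))
  opt <- stats::optimize(.boxcox_loglik, interval = c(-5, 5), x = x,
                         logx_sum = ls, maximum = TRUE, tol = 1e-6)
  if (.boxcox_loglik(1, x, ls) >= opt$objective - 1e-8) 1 else opt$maximum
}

.boxcox_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' Per-sex Box-Cox normalization of trait residuals
#'
#' Second stage of the adult scaling. Within each sex the residuals are
#' first standardized to unit variance (so the chain is invariant to the
#' raw trait's units), shifted to strictly positive support
#' (shift = -min + 1), Box-Cox transformed at the per-sex
#' maximum-likelihood lambda, and standardized to mean 0 / SD 1; sexes
#' are then recombined. The transform is strictly
#' increasing within sex, and the per-sex standardization makes the
#' response variance identical across sexes -- the property that keeps
#' interaction models well specified.
#'
#' @param residuals Numeric residuals from [residualize_trait()].
#' @param sex Factor/character sex, same length.
#' @param min_per_sex Minimum stratum size (default 30).
#' @return An object of class `scaled_phenotype`: list with `values`
#'   (scaled trait, input order) and `params` (per-sex lambda, shift,
#'   post-transform mean and sd).
#' @export
boxcox_per_sex <- function(residuals, sex, min_per_sex = 30) {
  sex <- factor(sex)
  values <- numeric(length(residuals))
  params <- list()
  for (lv in levels(sex)) {
    idx <- which(sex == lv)
    if (length(idx) < min_per_sex) {
      stop("sex stratum '", lv, "' has ", length(idx),
           " samples, below the minimum of ", min_per_sex)
    }
    x <- residuals[idx]
    x <- x / stats::sd(x)        # unit-free support before the shift
    shift <- -min(x) + 1
    xs <- x + shift
    lambda <- boxcox_lambda(xs)
    z <- .boxcox_transform(xs, lambda)
    m <- mean(z)
    s <- stats::sd(z)
    values[idx] <- (z - m) / s
    params[[lv]] <- data.frame(sex = lv, lambda = lambda, shift = shift,
                               mean = m, sd = s, n = length(idx),
                               stringsAsFactors = FALSE)
  }
  structure(list(values = values, params = do.call(rbind, params)),
            class = "scaled_phenotype")
}

#' @export
print.scaled_phenotype <- function(x, ...) {
  cat("<scaled_phenotype> n =", length(x$values), "\n")
  print(x$params, row.names = FALSE)
  invisible(x)
}

#' Full adult trait scaling chain
#'
#' Residualize on sex, age, age^2, then per-sex Box-Cox and
#' standardization. This is the scaling applied within each cohort before
#' association testing; effect sizes downstream are therefore in trait SD
#' units relative to same-sex, same-age peers.
#'
#' @inheritParams residualize_trait
#' @inheritParams boxcox_per_sex
#' @return A `scaled_phenotype` object.
#' @export
scale_adult_trait <- function(y, sex, age, min_per_sex = 30) {
  boxcox_per_sex(residualize_trait(y, sex, age), sex, min_per_sex)
}

# linear interpolation of one LMS column at given ages (constant when the
# reference has a single row for that sex)
.lms_interp <- function(sub, col, a) {
  if (nrow(sub) == 1L) rep(sub[[col]], length(a))
  else stats::approx(sub$age, sub[[col]], a)$y
}

#' Pediatric z-score from an LMS growth reference
#'
#' LMS z-score `z = ((value/M)^L - 1) / (L * S)`, with the limit
#' `log(value/M)/S` as `L -> 0`. L, M and S are interpolated linearly in
#' age within sex.
#'
#' @param value Measured trait value (same units as the reference median).
#' @param age Age in years; must lie within the reference range.
#' @param sex Sex label matching the reference (`"M"`/`"F"`).
#' @param ref LMS reference data.frame: columns `sex`, `age`, `L`, `M`, `S`.
#' @return Numeric z-score(s).
#' @seealso [lms_value()] for the inverse, [default_lms_reference()].
#' @export
pediatric_zscore <- function(value, age, sex, ref) {
  n <- max(length(value), length(age), length(sex))
  value <- rep_len(value, n); age <- rep_len(age, n)
  sex <- rep_len(as.character(sex), n)
  z <- numeric(n)
  for (lv in unique(sex)) {
    sub <- ref[ref$sex == lv, ]
    if (nrow(sub) == 0L) stop("no reference rows for sex '", lv, "'")
    idx <- which(sex == lv)
    a <- age[idx]
    if (any(a < min(sub$age) | a > max(sub$age))) {
      stop("age outside reference range [", min(sub$age), ", ",
           max(sub$age), "] for sex '", lv, "'")
    }
    L <- .lms_interp(sub, "L", a)
    M <- .lms_interp(sub, "M", a)
    S <- .lms_interp(sub, "S", a)
    v <- value[idx]
    z[idx] <- ifelse(abs(L) < 1e-7,
                     log(v / M) / S,
                     ((v / M)^L - 1) / (L * S))
  }
  z
}

#' Trait value at a given pediatric z-score (inverse LMS)
#'
#' @inheritParams pediatric_zscore
#' @param z Z-score(s) to invert.
#' @return Trait value(s).
#' @export
lms_value <- function(z, age, sex, ref) {
  n <- max(length(z), length(age), length(sex))
  z <- rep_len(z, n); age <- rep_len(age, n)
  sex <- rep_len(as.character(sex), n)
  out <- numeric(n)
  for (lv in unique(sex)) {
    sub <- ref[ref$sex == lv, ]
    idx <- which(sex == lv)
    a <- age[idx]
    L <- .lms_interp(sub, "L", a)
    M <- .lms_interp(sub, "M", a)
    S <- .lms_interp(sub, "S", a)
    out[idx] <- ifelse(abs(L) < 1e-7,
                       M * exp(S * z[idx]),
                       M * (1 + L * S * z[idx])^(1 / L))
  }
  out
}

#' Synthetic LMS growth reference
#'
#' A compact, smooth growth reference (ages 2-18, both sexes) in the LMS
#' parameterization, shipped so that pediatric z-scoring and the synthetic
#' data generator need no external download. The curves are realistic in
#' scale (height in cm, BMI in kg/m^2) but synthetic: they are NOT the
#' WHO or CDC reference tables.
#'
#' @param trait `"height"` or `"bmi"`.
#' @return data.frame with columns `sex`, `age`, `L`, `M`, `S`.
#' @export
default_lms_reference <- function(trait = c("height", "bmi")) {
  trait <- match.arg(trait)
  ages <- seq(2, 18, by = 0.25)
  make <- function(sex) {
    if (trait == "height") {
      # near-linear growth with mild deceleration; males slightly taller
      b <- if (sex == "M") c(75.5, 8.0, -0.115) else c(75.0, 7.8, -0.125)
      M <- b[1] + b[2] * ages + b[3] * ages^2
      L <- rep(1, length(ages))
      S <- 0.038 + 0.0006 * ages
    } else {
      b <- if (sex == "M") c(16.6, -0.32, 0.036) else c(16.4, -0.30, 0.036)
      M <- b[1] + b[2] * ages + b[3] * ages^2
      L <- rep(-1.5, length(ages))          # right-skewed BMI distribution
      S <- 0.085 + 0.0035 * ages
    }
    data.frame(sex = sex, age = ages, L = L, M = M, S = S,
               stringsAsFactors = FALSE)
  }
  rbind(make("M"), make("F"))
}
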
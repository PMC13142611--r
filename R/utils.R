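# Internal helpers shared across modules.

# Merge a set of half-open intervals into their union, returned as a
# two-column matrix (start, end) sorted by start. Touching intervals
# ([a,b) and [b,c)) are merged.
.merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1L]
  me <- end[1L]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

# Total length of the intersection between a merged interval set and one
# half-open interval [s, e).
.overlap_length <- function(merged, s, e) {
  if (nrow(merged) == 0L) return(0)
  sum(pmax(0, pmin(merged[, 2L], e) - pmax(merged[, 1L], s)))
}

# Ordinary least squares via QR with coefficient standard errors.
# Errors on rank deficiency (callers that tolerate aliasing use lm()).
.fast_lm <- function(y, X) {
  n <- length(y)
  p <- ncol(X)
  qrx <- qr(X)
  if (qrx$rank < p) {
    stop("rank-deficient design matrix (", p - qrx$rank, " aliased columns)")
  }
  coef <- qr.coef(qrx, y)
  res <- qr.resid(qrx, y)
  rss <- sum(res^2)
  df <- n - p
  sigma2 <- rss / df
  R <- qr.R(qrx)
  cov_unscaled <- chol2inv(R)
  # undo column pivoting if any
  piv <- qrx$pivot
  se <- numeric(p)
  se[piv] <- sqrt(diag(cov_unscaled) * sigma2)
  tval <- coef / se
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  list(coefficients = coef, se = se, t = tval, p = pval,
       residuals = res, rss = rss, df = df, sigma2 = sigma2,
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
       loglik = -n / 2 * (log(2 * pi) + log(rss / n) + 1))
}

# Run code with a private RNG stream, restoring the caller's stream after.
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a master seed; stays inside 32-bit integer range.
.child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647)
}
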
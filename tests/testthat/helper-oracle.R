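# Independent oracles used across tests.

# Brute-force base-wise genotyper: counts covered bases of every segment
# directly, one base at a time, and applies the union rule from scratch.
# Deliberately naive; only usable on loci with small coordinates.
oracle_genotype <- function(calls, locus, span, min_fraction = 0.5) {
  sp <- NULL
  for (s in locus$spans) if (s$name == span) sp <- s
  stopifnot(!is.null(sp))
  seg_frac <- function(state) {
    sub <- calls[calls$state == state & calls$chrom == locus$chrom, ,
                 drop = FALSE]
    vapply(locus$segments, function(seg) {
      covered <- rep(FALSE, seg$end - seg$start)   # one flag per base
      if (nrow(sub)) for (r in seq_len(nrow(sub))) {
        a <- max(sub$start[r], seg$start) - seg$start + 1
        b <- min(sub$end[r], seg$end) - seg$start
        if (b >= a) covered[a:b] <- TRUE
      }
      mean(covered)
    }, numeric(1))
  }
  seg_names <- vapply(locus$segments, function(s) s$name, character(1))
  positive <- function(state) {
    fr <- seg_frac(state)
    f <- fr[match(sp$segments, seg_names)]
    g <- fr[match(sp$flanking, seg_names)]
    all(f >= min_fraction) && (length(g) == 0 || all(g < min_fraction))
  }
  del <- positive("DEL")
  dup <- positive("DUP")
  if (del && dup) "NO_CALL" else if (del) "DEL" else if (dup) "DUP" else "REF"
}

# Random small locus: 1-4 segments of length 40-200 starting near 0,
# with spans over every contiguous run and flanking = the other segments.
random_locus <- function() {
  k <- sample(1:4, 1)
  lens <- sample(40:200, k, replace = TRUE)
  gaps <- sample(0:30, k, replace = TRUE)
  starts <- cumsum(c(sample(0:50, 1), head(lens + gaps, -1)))
  ends <- starts + lens
  nm <- LETTERS[1:(k + 1)]
  seg_names <- paste(nm[-length(nm)], nm[-1], sep = "-")
  segs <- lapply(seq_len(k), function(i) {
    cnv_segment(seg_names[i], "chrT", starts[i], ends[i])
  })
  spans <- list()
  for (i in seq_len(k)) for (j in i:k) {
    used <- seg_names[i:j]
    spans[[length(spans) + 1]] <- list(
      name = paste(nm[i], nm[j + 1], sep = "-"),
      segments = used, flanking = setdiff(seg_names, used))
  }
  segmented_locus(paste0("T", sample.int(1e6, 1)), "chrT", segs, spans)
}

# Random callset for one sample over a locus footprint.
random_calls <- function(locus, n_calls = sample(0:4, 1)) {
  b <- range(unlist(lapply(locus$segments, function(s) c(s$start, s$end))))
  width <- diff(b)
  if (n_calls == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), state = character(0)))
  }
  s <- sample(seq(max(0, b[1] - width), b[2] + width), n_calls, replace = TRUE)
  len <- sample(10:(2 * width), n_calls, replace = TRUE)
  data.frame(chrom = "chrT", start = s, end = s + len,
             state = sample(c("DEL", "DUP"), n_calls, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Normal-equations solver: solve(t(X) %*% X) %*% t(X) %*% y, with classic
# SE formulas -- the independent route for checking regression fits.
normal_equations <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (length(y) - ncol(X))
  se <- sqrt(diag(solve(XtX)) * sigma2)
  list(beta = drop(beta), se = se, residuals = drop(res))
}

# Small adult cohort with a genotype column, for association tests.
make_cohort <- function(n = 2000, f_carrier = 0.05, beta = 0,
                        allele = "DEL", pgs_gamma = 0, pgs_beta = 0.4,
                        cohort_id = "T1") {
  sex <- sample(c("M", "F"), n, replace = TRUE)
  g <- ifelse(runif(n) < f_carrier, allele, "REF")
  pcs <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("PC", 1:10)))
  pgs <- rnorm(n)
  carrier <- as.numeric(g == allele)
  y <- pgs_beta * pgs + carrier * (beta + pgs_gamma * pgs) +
    rnorm(n, 0, sqrt(1 - pgs_beta^2))
  data.frame(cohort_id = cohort_id, sample_id = sprintf("S%05d", 1:n),
             sex = sex, age = runif(n, 30, 70), trait = y, geno = g,
             pcs, PGS = pgs, stringsAsFactors = FALSE)
}
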
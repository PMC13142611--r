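# Multi-cohort synthetic data with fully specified generative structure
# and truth tables. The generator emulates the federated biobank setting:
# several cohorts of different size, sex ratio and age structure; rare CNV
# carriers with noisy breakpoints at catalog loci; standard-normal PGS
# with additive effects; sex-, age- and BMI-mediated CNV effects; and
# medication assignment correlated with carrier status.

#' Default cohort layout
#'
#' Five adult cohorts mirroring the relative sizes and sex ratios of the
#' large biobanks the study design emulates (one of them strongly
#' male-dominated), scaled to `n_total` samples.
#'
#' @param n_total Total sample count across cohorts.
#' @return data.frame: `cohort_id`, `n`, `female_frac`, `age_min`,
#'   `age_max`, `type`.
#' @export
default_cohorts <- function(n_total = 50000) {
  prop <- c(0.236, 0.406, 0.238, 0.044, 0.076)
  data.frame(
    cohort_id = c("BB1", "BB2", "BB3", "BB4", "BB5"),
    n = pmax(100L, as.integer(round(n_total * prop))),
    female_frac = c(0.54, 0.10, 0.60, 0.66, 0.58),
    age_min = c(40, 30, 25, 20, 25), age_max = c(70, 80, 75, 75, 70),
    type = "adult", stringsAsFactors = FALSE)
}

#' Default generative effect map
#'
#' One row per simulated allele. The defaults imitate the headline locus
#' archetypes: a 16p11.2-like mirror pair (DEL raises BMI and lowers
#' height, DUP the reverse, with a child-short/adult-tall height
#' trajectory for the DUP); a 22q11.2-like segmented locus with opposing
#' A-B / C-D duplication effects on height, additive A-C deletions and a
#' sub-additive A-D deletion; a 15q11.2-like female-biased BMI allele;
#' and mirror effects of mixed magnitude at the remaining loci so that the
#' median unsigned effect is large (~0.34 SD) as is characteristic of
#' recurrent CNVs. Carrier frequencies are in the recurrent-CNV range
#' (1e-4 to 5e-3).
#'
#' @param catalog A `cnv_catalog` (defaults to the packaged one).
#' @return data.frame with columns `locus_id`, `span`, `allele`, `freq`,
#'   `beta_height`, `beta_bmi`, `sex_delta_height`, `sex_delta_bmi`,
#'   `pgs_gamma_height`, `pgs_gamma_bmi`, `traj`, `traj_scale`.
#' @export
default_effect_map <- function(catalog = default_catalog()) {
  al <- enumerate_alleles(catalog)
  n <- nrow(al)
  ef <- data.frame(al,
                   freq = 5e-4, beta_height = 0, beta_bmi = 0,
                   sex_delta_height = 0, sex_delta_bmi = 0,
                   pgs_gamma_height = 0, pgs_gamma_bmi = 0,
                   traj = "", traj_scale = 0,
                   stringsAsFactors = FALSE)
  set_row <- function(ef, locus, span, allele, ...) {
    i <- which(ef$locus_id == locus & ef$span == span & ef$allele == allele)
    vals <- list(...)
    for (nm in names(vals)) ef[i, nm] <- vals[[nm]]
    ef
  }
  # 16p11.2-like mirror pair with BMI-mediated and trajectory structure
  ef <- set_row(ef, "16p11.2_BP4-BP5", "16p11.2_BP4-BP5", "DEL",
                freq = 4e-4, beta_height = -0.35, beta_bmi = 0.75,
                traj = "bump_8_13_obese", traj_scale = 1.0)
  ef <- set_row(ef, "16p11.2_BP4-BP5", "16p11.2_BP4-BP5", "DUP",
                freq = 4e-4, beta_height = 0.25, beta_bmi = -0.55,
                traj = "child_short_adult_tall", traj_scale = 0.5)
  # 15q11.2-like female-biased BMI allele
  ef <- set_row(ef, "15q11.2_BP1-BP2", "15q11.2_BP1-BP2", "DEL",
                freq = 4e-3, beta_height = -0.12, beta_bmi = 0.15,
                sex_delta_bmi = 0.10)
  # 22q11.2-like segmented locus (height): opposing DUP effects,
  # reinforcing DELs with a sub-additive full-span deletion
  dup_beta <- c("A-B" = -0.25, "B-C" = 0, "C-D" = 0.28,
                "A-C" = -0.25, "B-D" = 0.28, "A-D" = 0.05)
  del_beta <- c("A-B" = -0.30, "B-C" = -0.10, "C-D" = -0.30,
                "A-C" = -0.40, "B-D" = -0.40, "A-D" = -0.42)
  freq22 <- c("A-B" = 3e-4, "B-C" = 2e-4, "C-D" = 3e-4,
              "A-C" = 2e-4, "B-D" = 2e-4, "A-D" = 4e-4)
  for (sp in names(dup_beta)) {
    ef <- set_row(ef, "22q11.2", sp, "DUP", freq = freq22[[sp]],
                  beta_height = dup_beta[[sp]], beta_bmi = 0.05)
    ef <- set_row(ef, "22q11.2", sp, "DEL", freq = freq22[[sp]],
                  beta_height = del_beta[[sp]], beta_bmi = 0.08)
  }
  # remaining loci: deterministic mirror effects of mixed magnitude
  rest <- which(ef$beta_height == 0 & ef$beta_bmi == 0 & ef$allele == "DEL")
  mags <- .with_seed(202401L, stats::runif(length(rest), 0.05, 0.65))
  freqs <- .with_seed(202402L, 10^stats::runif(length(rest), -3.9, -2.4))
  for (i in seq_along(rest)) {
    r <- rest[i]
    mirror <- i %% 4L != 0L    # a quarter of loci asymmetric (DUP null)
    ef[r, "freq"] <- freqs[i]
    ef[r, "beta_height"] <- -mags[i]
    ef[r, "beta_bmi"] <- 0.5 * mags[i] * (-1)^i
    rdup <- which(ef$locus_id == ef$locus_id[r] & ef$span == ef$span[r] &
                    ef$allele == "DUP")
    ef[rdup, "freq"] <- freqs[i]
    ef[rdup, "beta_height"] <- if (mirror) 0.5 * mags[i] else 0
    ef[rdup, "beta_bmi"] <- if (mirror) -0.25 * mags[i] * (-1)^i else 0
  }
  ef
}

#' Build a simulation configuration
#'
#' @param seed Master RNG seed; fully determines every output.
#' @param cohorts Cohort layout, as from [default_cohorts()].
#' @param catalog `cnv_catalog` the calls are generated against.
#' @param effects Effect map, as from [default_effect_map()]; carrier
#'   frequencies must lie in (0, 0.05].
#' @param pgs_beta Named vector: PGS effect (SD per SD) on each trait.
#' @param mediation_b BMI-to-height path (z-scale) active in pediatric
#'   cohorts; 0 disables mediation structure.
#' @param pc_confound Optional list(`pc`, `carrier_shift`, `trait_beta`):
#'   carriers are shifted on one PC which in turn affects the traits
#'   (planted ancestry confounding).
#' @param medication List: `base` (named baseline rates for
#'   antidepressant/antipsychotic/mood_stabilizer), `carrier_or`
#'   (odds ratio for carriers), `bmi_effect` (additive BMI z side-effect
#'   of any medication).
#' @param jitter_sd Breakpoint jitter SD in bp for emitted raw calls.
#' @param fragmentation_prob Probability a carrier call is emitted as two
#'   fragments.
#' @param false_call_rate Per-sample rate of spurious calls.
#' @param emit_calls Generate raw CNV call intervals (disable to keep
#'   only truth genotypes, e.g. in large calibration runs).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       cohorts = default_cohorts(),
                       catalog = default_catalog(),
                       effects = default_effect_map(catalog),
                       pgs_beta = c(height = 0.60, bmi = 0.45),
                       mediation_b = 0,
                       pc_confound = NULL,
                       medication = list(
                         base = c(antidepressant = 0.10,
                                  antipsychotic = 0.015,
                                  mood_stabilizer = 0.03),
                         carrier_or = 1.8, bmi_effect = 0.12),
                       jitter_sd = 20000,
                       fragmentation_prob = 0.05,
                       false_call_rate = 1e-4,
                       emit_calls = TRUE) {
  if (any(effects$freq <= 0 | effects$freq > 0.05)) {
    stop("carrier frequencies must lie in (0, 0.05]")
  }
  keys <- paste(effects$locus_id, effects$span)
  cat_keys <- with(enumerate_alleles(catalog), paste(locus_id, span))
  if (!all(keys %in% cat_keys)) {
    stop("effect map references alleles absent from the catalog")
  }
  structure(list(seed = seed, cohorts = cohorts, catalog = catalog,
                 effects = effects, pgs_beta = pgs_beta,
                 mediation_b = mediation_b, pc_confound = pc_confound,
                 medication = medication, jitter_sd = jitter_sd,
                 fragmentation_prob = fragmentation_prob,
                 false_call_rate = false_call_rate,
                 emit_calls = emit_calls),
            class = "sim_config")
}

# age-trajectory presets: additive height z contribution for carriers,
# possibly gated on concurrent obesity. "child_short_adult_tall" is a
# pubertal-transition sigmoid running from -scale to +scale; the bumps are
# smoothed plateaus spanning ages 8-13.
.smooth_plateau <- function(age, lo = 8, hi = 13, w = 0.9) {
  d <- pmax(0, pmax(lo - age, age - hi))
  exp(-(d / w)^2)
}

.traj_value <- function(preset, scale, age, bmi_z) {
  switch(preset,
         "child_short_adult_tall" =
           scale * (-1 + 2 * stats::plogis((age - 13) / 1.5)),
         "bump_8_13" = scale * .smooth_plateau(age),
         "bump_8_13_obese" = scale * .smooth_plateau(age) *
           (bmi_z > stats::qnorm(0.9)),
         rep(0, length(age)))
}

# raw-unit conversion for adults (monotone affine per sex for height,
# log-scale for BMI so the raw distribution is right-skewed)
.adult_raw <- function(height_z, bmi_z, sex, age) {
  male <- sex == "M"
  mu <- ifelse(male, 175.6, 162.3)
  sd <- ifelse(male, 6.9, 6.3)
  height <- mu - 0.03 * (age - 50) + sd * height_z
  bmi <- exp(log(ifelse(male, 27.0, 26.3)) + 0.002 * (age - 50) +
               0.17 * bmi_z)
  list(height = height, bmi = bmi)
}

#' Simulate raw CNV call intervals for known carriers
#'
#' Emits one (or, with fragmentation, two) interval(s) per carrier
#' covering the true span with endpoints jittered by `N(0, jitter_sd^2)`,
#' plus spurious calls in non-carriers at `false_call_rate` (each false
#' call covers a random fraction of one random span). Uses the current
#' RNG stream.
#'
#' @param carriers data.frame: `sample_id`, `locus_id`, `span`, `allele`.
#' @param catalog `cnv_catalog`.
#' @param jitter_sd,fragmentation_prob,false_call_rate See [sim_config()].
#' @param samples All sample ids (false-call candidates).
#' @return data.frame of calls: `chrom`, `start`, `end`, `sample_id`,
#'   `state`, `quality`.
#' @export
simulate_raw_calls <- function(carriers, catalog, jitter_sd = 20000,
                               fragmentation_prob = 0.05,
                               false_call_rate = 1e-4,
                               samples = unique(carriers$sample_id)) {
  rows <- list()
  add <- function(chrom, s, e, sid, state) {
    if (e > s) {
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = chrom, start = s, end = e, sample_id = sid, state = state,
        quality = round(stats::runif(1, 15, 60), 1), stringsAsFactors = FALSE)
    }
  }
  if (nrow(carriers) > 0L) {
    for (i in seq_len(nrow(carriers))) {
      locus <- catalog[[carriers$locus_id[i]]]
      sp <- .locus_span(locus, carriers$span[i])
      segs <- lapply(sp$segments, .locus_segment, locus = locus)
      s <- min(vapply(segs, `[[`, numeric(1), "start"))
      e <- max(vapply(segs, `[[`, numeric(1), "end"))
      s2 <- round(s + stats::rnorm(1, 0, jitter_sd))
      e2 <- round(e + stats::rnorm(1, 0, jitter_sd))
      if (s2 >= e2) { s2 <- s; e2 <- e }
      sid <- carriers$sample_id[i]
      st <- carriers$allele[i]
      if (stats::runif(1) < fragmentation_prob && (e2 - s2) > 10000) {
        L <- e2 - s2
        m <- s2 + round(stats::runif(1, 0.2, 0.8) * L)
        gap <- max(1, round(0.01 * L))
        add(locus$chrom, s2, m - gap, sid, st)
        add(locus$chrom, m + gap, e2, sid, st)
      } else {
        add(locus$chrom, s2, e2, sid, st)
      }
    }
  }
  n_false <- stats::rbinom(1, length(samples), false_call_rate)
  if (n_false > 0L) {
    pool <- enumerate_alleles(catalog)
    for (j in seq_len(n_false)) {
      r <- pool[sample.int(nrow(pool), 1L), ]
      locus <- catalog[[r$locus_id]]
      sp <- .locus_span(locus, r$span)
      segs <- lapply(sp$segments, .locus_segment, locus = locus)
      s <- min(vapply(segs, `[[`, numeric(1), "start"))
      e <- max(vapply(segs, `[[`, numeric(1), "end"))
      L <- e - s
      frac <- stats::runif(1, 0.2, 1.0)
      off <- stats::runif(1, 0, 1 - frac)
      add(locus$chrom, round(s + off * L), round(s + (off + frac) * L),
          samples[sample.int(length(samples), 1L)],
          sample(c("DEL", "DUP"), 1L))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               sample_id = character(0), state = character(0),
               quality = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Simulate a multi-cohort dataset with known truth
#'
#' Generates, per cohort: sex, age, 10 standard-normal ancestry PCs,
#' standard-normal height and BMI polygenic scores, latent carrier status
#' per allele (Bernoulli at the configured frequency, at most one allele
#' per locus), scaled-latent and raw phenotypes, medication flags, and
#' (optionally) raw CNV call intervals with breakpoint jitter,
#' fragmentation and false calls. Pediatric cohorts are generated on the
#' LMS z-score scale so that non-carrier z-scores are standard normal at
#' every age, then converted to raw units through the packaged growth
#' reference. Each cohort draws from its own RNG stream derived from the
#' master seed, so outputs are stable under adding cohorts.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_result`: `cohorts` (per cohort: `data`
#'   data.frame and `calls` data.frame), `truth` (carriers table +
#'   generative effect map), `config`.
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ef <- config$effects
  ef$key <- span_key(ef$locus_id, ef$span)
  lms_h <- default_lms_reference("height")
  lms_b <- default_lms_reference("bmi")
  cohorts <- list()
  truth_rows <- list()
  for (ci in seq_len(nrow(config$cohorts))) {
    spec <- config$cohorts[ci, ]
    res <- .with_seed(.child_seed(config$seed, ci), {
      n <- spec$n
      sid <- sprintf("%s_S%07d", spec$cohort_id, seq_len(n))
      sex <- ifelse(stats::runif(n) < spec$female_frac, "F", "M")
      age <- stats::runif(n, spec$age_min, spec$age_max)
      pcs <- matrix(stats::rnorm(n * 10L), n, 10L,
                    dimnames = list(NULL, paste0("PC", 1:10)))
      pgs_h <- stats::rnorm(n)
      pgs_b <- stats::rnorm(n)
      # carrier assignment: at most one allele per locus
      carr <- matrix(FALSE, n, nrow(ef))
      for (lid in unique(ef$locus_id)) {
        rows <- which(ef$locus_id == lid)
        cum <- cumsum(ef$freq[rows])
        u <- stats::runif(n)
        pick <- findInterval(u, c(0, cum), left.open = TRUE)
        hit <- pick >= 1L & pick <= length(rows) & u < cum[length(cum)]
        for (j in seq_along(rows)) carr[hit & pick == j, rows[j]] <- TRUE
      }
      female <- as.numeric(sex == "F")
      contrib <- function(beta_col, delta_col, gamma_col, pgs) {
        out <- numeric(n)
        for (j in which(colSums(carr) > 0L)) {
          out <- out + carr[, j] *
            (ef[[beta_col]][j] + ef[[delta_col]][j] * female +
               ef[[gamma_col]][j] * pgs)
        }
        out
      }
      bmi_cnv <- contrib("beta_bmi", "sex_delta_bmi", "pgs_gamma_bmi", pgs_b)
      hei_cnv <- contrib("beta_height", "sex_delta_height",
                         "pgs_gamma_height", pgs_h)
      pc_extra_b <- pc_extra_h <- 0
      if (!is.null(config$pc_confound)) {
        pcn <- config$pc_confound$pc
        pcs[, pcn] <- pcs[, pcn] +
          config$pc_confound$carrier_shift * as.numeric(rowSums(carr) > 0L)
        pc_extra_h <- config$pc_confound$trait_beta[["height"]] * pcs[, pcn]
        pc_extra_b <- config$pc_confound$trait_beta[["bmi"]] * pcs[, pcn]
      }
      pediatric <- identical(spec$type, "pediatric")
      if (pediatric) {
        bmi_z <- bmi_cnv + stats::rnorm(n)
        b <- config$mediation_b
        traj <- numeric(n)
        for (j in which(colSums(carr) > 0L)) {
          if (nzchar(ef$traj[j])) {
            traj <- traj + carr[, j] *
              .traj_value(ef$traj[j], ef$traj_scale[j], age, bmi_z)
          }
        }
        hei_z <- hei_cnv + traj + b * bmi_z +
          stats::rnorm(n, 0, sqrt(max(1e-6, 1 - b^2)))
        height_raw <- lms_value(hei_z, age, sex, lms_h)
        bmi_raw <- lms_value(bmi_z, age, sex, lms_b)
        med <- NULL
      } else {
        sd_b <- sqrt(max(0.05, 1 - config$pgs_beta[["bmi"]]^2))
        sd_h <- sqrt(max(0.05, 1 - config$pgs_beta[["height"]]^2))
        bmi_z <- config$pgs_beta[["bmi"]] * pgs_b + bmi_cnv + pc_extra_b +
          stats::rnorm(n, 0, sd_b)
        med <- NULL
        if (!is.null(config$medication)) {
          mm <- config$medication
          carrier_any <- as.numeric(rowSums(carr) > 0L)
          med <- as.data.frame(lapply(mm$base, function(pb) {
            p <- stats::plogis(stats::qlogis(pb) + log(mm$carrier_or) * carrier_any)
            stats::runif(n) < p
          }))
          med$any <- Reduce(`|`, med)
          bmi_z <- bmi_z + mm$bmi_effect * as.numeric(med$any)
        }
        hei_z <- config$pgs_beta[["height"]] * pgs_h + hei_cnv + pc_extra_h +
          stats::rnorm(n, 0, sd_h)
        raw <- .adult_raw(hei_z, bmi_z, sex, age)
        height_raw <- raw$height
        bmi_raw <- raw$bmi
      }
      dat <- data.frame(cohort_id = spec$cohort_id, sample_id = sid,
                        sex = sex, age = age,
                        height_raw = height_raw, bmi_raw = bmi_raw,
                        height_z = hei_z, bmi_z = bmi_z,
                        pcs, PGS_height = pgs_h, PGS_BMI = pgs_b,
                        stringsAsFactors = FALSE)
      if (!is.null(med)) dat <- cbind(dat, med)
      hits <- which(carr, arr.ind = TRUE)
      truth <- if (nrow(hits)) {
        data.frame(cohort_id = spec$cohort_id,
                   sample_id = sid[hits[, 1L]],
                   locus_id = ef$locus_id[hits[, 2L]],
                   span = ef$span[hits[, 2L]],
                   allele = ef$allele[hits[, 2L]],
                   stringsAsFactors = FALSE)
      } else {
        data.frame(cohort_id = character(0), sample_id = character(0),
                   locus_id = character(0), span = character(0),
                   allele = character(0))
      }
      calls <- if (config$emit_calls) {
        simulate_raw_calls(truth, config$catalog, config$jitter_sd,
                           config$fragmentation_prob,
                           config$false_call_rate, samples = sid)
      } else NULL
      list(data = dat, calls = calls, truth = truth)
    })
    cohorts[[spec$cohort_id]] <- res[c("data", "calls")]
    truth_rows[[ci]] <- res$truth
  }
  structure(list(cohorts = cohorts,
                 truth = list(carriers = do.call(rbind, truth_rows),
                              effects = ef),
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  ns <- vapply(x$cohorts, function(co) nrow(co$data), integer(1))
  cat("<sim_result>", length(ns), "cohort(s), n =",
      paste(ns, collapse = " + "), "=", sum(ns), "samples;",
      nrow(x$truth$carriers), "carrier allele(s)\n")
  invisible(x)
}

#' Wide truth genotypes for one simulated cohort
#'
#' Converts the generator's latent carrier table into the same wide
#' genotype layout produced by [genotypes_wide()], bypassing raw-call
#' genotyping (useful for large calibration runs where breakpoint noise
#' is not under study).
#'
#' @param sim A `sim_result`.
#' @param cohort_id Cohort to extract.
#' @param keys Span keys to include (defaults to those in the effect map).
#' @return data.frame: `sample_id` plus one genotype column per key.
#' @export
truth_genotypes_wide <- function(sim, cohort_id,
                                 keys = unique(sim$truth$effects$key)) {
  dat <- sim$cohorts[[cohort_id]]$data
  tr <- sim$truth$carriers
  tr <- tr[tr$cohort_id == cohort_id, , drop = FALSE]
  out <- data.frame(sample_id = dat$sample_id, stringsAsFactors = FALSE)
  tkey <- span_key(tr$locus_id, tr$span)
  for (k in keys) {
    col <- rep("REF", nrow(dat))
    sub <- tr[tkey == k, , drop = FALSE]
    col[match(sub$sample_id, dat$sample_id)] <- sub$allele
    out[[k]] <- col
  }
  out
}

#' Recovery metrics against generative truth
#'
#' Joins pipeline effect estimates to the generative effect map and
#' reports per-allele bias and 95% CI coverage of the planted effect.
#'
#' @param truth Generative effect map (`sim$truth$effects`).
#' @param estimates data.frame with `span` (span key), `allele`, `beta`,
#'   `se`.
#' @param trait `"height"` or `"bmi"`.
#' @return data.frame with `true_beta`, `beta`, `bias`, `covered`.
#' @export
truth_report <- function(truth, estimates, trait = c("height", "bmi")) {
  trait <- match.arg(trait)
  tcol <- paste0("beta_", trait)
  key <- paste(truth$key, truth$allele)
  ekey <- paste(estimates$span, estimates$allele)
  idx <- match(ekey, key)
  if (anyNA(idx)) stop("estimates contain alleles absent from truth")
  out <- data.frame(span = estimates$span, allele = estimates$allele,
                    true_beta = truth[[tcol]][idx],
                    beta = estimates$beta, se = estimates$se,
                    stringsAsFactors = FALSE)
  out$bias <- out$beta - out$true_beta
  out$covered <- abs(out$bias) <= stats::qnorm(0.975) * out$se
  out
}
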
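small_config <- function(seed = 1, n = c(1500, 1200), emit_calls = TRUE,
                         effects = NULL, ...) {
  cat_ <- default_catalog()
  if (is.null(effects)) {
    effects <- default_effect_map(cat_)
    effects <- effects[effects$locus_id %in%
                         c("16p11.2_BP4-BP5", "22q11.2"), ]
    effects$freq <- 0.01
  }
  sim_config(seed = seed,
             cohorts = data.frame(cohort_id = paste0("C", seq_along(n)),
                                  n = n, female_frac = 0.5,
                                  age_min = 30, age_max = 70,
                                  type = "adult", stringsAsFactors = FALSE),
             catalog = cat_, effects = effects, emit_calls = emit_calls, ...)
}

test_that("the same seed reproduces the dataset bit-exactly", {
  s1 <- simulate_cohorts(small_config(seed = 5))
  s2 <- simulate_cohorts(small_config(seed = 5))
  expect_identical(s1$cohorts, s2$cohorts)
  expect_identical(s1$truth$carriers, s2$truth$carriers)
  s3 <- simulate_cohorts(small_config(seed = 6))
  expect_false(identical(s1$cohorts[[1]]$data, s3$cohorts[[1]]$data))
})

test_that("cohort streams are stable under adding cohorts", {
  a <- simulate_cohorts(small_config(seed = 9, n = c(800, 700)))
  b <- simulate_cohorts(small_config(seed = 9, n = c(800, 700, 500)))
  expect_identical(a$cohorts[["C1"]]$data, b$cohorts[["C1"]]$data)
  expect_identical(a$cohorts[["C2"]]$data, b$cohorts[["C2"]]$data)
})

test_that("generated PGS are standard normal and carriers exclusive per locus", {
  cfg <- small_config(seed = 11, n = c(12000))
  sim <- simulate_cohorts(cfg)
  d <- sim$cohorts[[1]]$data
  expect_gt(stats::ks.test(d$PGS_height, "pnorm")$p.value, 0.01)
  expect_gt(stats::ks.test(d$PGS_BMI, "pnorm")$p.value, 0.01)
  # at most one allele per locus per sample
  tr <- sim$truth$carriers
  expect_equal(anyDuplicated(tr[, c("sample_id", "locus_id")]), 0)
  # carrier frequency near the configured value
  n16 <- sum(tr$locus_id == "16p11.2_BP4-BP5")
  expect_equal(n16 / nrow(d), 0.02, tolerance = 0.3)
})

test_that("frequency bounds and unknown alleles are rejected", {
  ef <- default_effect_map()
  ef$freq[1] <- 0.2
  expect_error(small_config(effects = ef), "frequencies")
  ef2 <- default_effect_map()[1:2, ]
  ef2$span <- "nonexistent"
  expect_error(small_config(effects = ef2), "absent from the catalog")
})

test_that("noiseless raw calls round-trip through the genotyper", {
  cfg <- small_config(seed = 13, n = c(3000), jitter_sd = 0,
                      fragmentation_prob = 0, false_call_rate = 0)
  sim <- simulate_cohorts(cfg)
  d <- sim$cohorts[[1]]$data
  geno <- genotype_matrix(sim$cohorts[[1]]$calls, cfg$catalog,
                          samples = d$sample_id)
  wide <- genotypes_wide(geno)
  truthw <- truth_genotypes_wide(sim, "C1")
  for (k in names(truthw)[-1]) {
    expect_identical(wide[[k]][match(truthw$sample_id, wide$sample_id)],
                     truthw[[k]])
  }
})

test_that("default breakpoint jitter keeps genotype recovery above 99%", {
  cfg <- small_config(seed = 14, n = c(4000))
  sim <- simulate_cohorts(cfg)
  d <- sim$cohorts[[1]]$data
  wide <- genotypes_wide(genotype_matrix(sim$cohorts[[1]]$calls, cfg$catalog,
                                         samples = d$sample_id))
  truthw <- truth_genotypes_wide(sim, "C1")
  agree <- 0
  total <- 0
  for (k in names(truthw)[-1]) {
    got <- wide[[k]][match(truthw$sample_id, wide$sample_id)]
    agree <- agree + sum(got == truthw[[k]])
    total <- total + length(got)
  }
  expect_gte(agree / total, 0.99)
})

test_that("jitter shrinking a call below threshold yields REF at a multi-segment span", {
  cat_ <- default_catalog()
  locus <- cat_[["22q11.2"]]
  b <- function(nm) for (s in locus$segments) if (s$name == nm) return(s)
  # constructed boundary case: call stops at 40% into C-D
  cd <- b("C-D")
  calls <- data.frame(chrom = "chr22", start = b("A-B")$start,
                      end = cd$start + 0.4 * (cd$end - cd$start),
                      state = "DEL")
  expect_identical(as.character(assign_genotype(calls, locus, "A-D")), "REF")
  # the same call still genotypes DEL at the A-C span it fully covers
  expect_identical(as.character(assign_genotype(calls, locus, "A-C")), "DEL")
})

test_that("false-positive genotypes stay at or below the planted false-call rate", {
  ef <- default_effect_map()
  ef <- ef[ef$locus_id == "1q21.1_TAR", ]
  ef$freq <- 1e-4             # essentially no true carriers
  cfg <- small_config(seed = 15, n = c(5000), effects = ef,
                      false_call_rate = 1e-3)
  sim <- simulate_cohorts(cfg)
  d <- sim$cohorts[[1]]$data
  wide <- genotypes_wide(genotype_matrix(sim$cohorts[[1]]$calls, cfg$catalog,
                                         samples = d$sample_id))
  truthw <- truth_genotypes_wide(sim, "C1", keys = "1q21.1_TAR")
  fp <- sum(wide[["1q21.1_TAR"]] != "REF" & truthw[["1q21.1_TAR"]] == "REF")
  expect_lte(fp / nrow(d), 1e-3)
})

test_that("pediatric non-carrier z-scores are standard normal at every age", {
  ef <- default_effect_map()
  ef <- ef[ef$locus_id == "16p11.2_BP4-BP5", ]
  ef$freq <- 0.01
  cfg <- sim_config(seed = 16,
                    cohorts = data.frame(cohort_id = "PED", n = 20000,
                                         female_frac = 0.5, age_min = 2,
                                         age_max = 18, type = "pediatric"),
                    effects = ef, mediation_b = 0.3, emit_calls = FALSE)
  sim <- simulate_cohorts(cfg)
  d <- sim$cohorts[[1]]$data
  tr <- sim$truth$carriers
  ref <- !(d$sample_id %in% tr$sample_id)
  for (a in seq(2, 16, by = 2)) {
    idx <- ref & d$age >= a & d$age < a + 2
    n <- sum(idx)
    expect_lt(abs(mean(d$height_z[idx])), 3 / sqrt(n))
    expect_lt(abs(mean(d$bmi_z[idx])), 3 / sqrt(n))
  }
  expect_equal(sd(d$height_z[ref]), 1, tolerance = 0.05)
  # raw values round-trip through the packaged LMS reference
  z <- pediatric_zscore(d$height_raw, d$age, d$sex,
                        default_lms_reference("height"))
  expect_equal(z, d$height_z, tolerance = 1e-6)
})

test_that("medication assignment is enriched in carriers and feeds into BMI", {
  ef <- default_effect_map()
  ef <- ef[ef$locus_id == "16p11.2_BP4-BP5", ]
  ef$freq <- 0.025
  ef$beta_bmi <- 0            # isolate the medication pathway
  ef$beta_height <- 0
  cfg <- small_config(seed = 17, n = c(40000), effects = ef,
                      emit_calls = FALSE,
                      medication = list(base = c(antidepressant = 0.10,
                                                 antipsychotic = 0.015,
                                                 mood_stabilizer = 0.03),
                                        carrier_or = 3, bmi_effect = 0.3))
  sim <- simulate_cohorts(cfg)
  d <- sim$cohorts[[1]]$data
  carrier <- d$sample_id %in% sim$truth$carriers$sample_id
  p_c <- mean(d$any[carrier])
  p_r <- mean(d$any[!carrier])
  or <- (p_c / (1 - p_c)) / (p_r / (1 - p_r))
  expect_gt(or, 1.8)
  # medicated samples have higher BMI z by construction
  expect_gt(mean(d$bmi_z[d$any]) - mean(d$bmi_z[!d$any]), 0.15)
})

test_that("truth report computes bias and CI coverage against the effect map", {
  ef <- default_effect_map()[1:2, ]
  ef$key <- span_key(ef$locus_id, ef$span)
  est <- data.frame(span = ef$key, allele = ef$allele,
                    beta = ef$beta_height + c(0.01, -0.01), se = 0.05)
  tr <- truth_report(ef, est, "height")
  expect_equal(tr$bias, c(0.01, -0.01))
  expect_true(all(tr$covered))
  est$se <- 0.001
  expect_false(any(truth_report(ef, est, "height")$covered))
  est$allele <- "XX"
  expect_error(truth_report(ef, est, "height"), "absent")
})
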
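test_that("main-effect fit equals the normal-equations oracle", {
  set.seed(31)
  co <- make_cohort(n = 300, f_carrier = 0.1, beta = -0.4)
  co$geno[1:5] <- "DUP"
  res <- fit_main_effect(co, "trait", "geno")
  X <- cbind(1, as.numeric(co$geno == "DEL"), as.numeric(co$geno == "DUP"),
             as.matrix(co[, paste0("PC", 1:10)]))
  want <- normal_equations(co$trait, X)
  expect_equal(res$beta[res$allele == "DEL"], unname(want$beta[2]),
               tolerance = 1e-10)
  expect_equal(res$beta[res$allele == "DUP"], unname(want$beta[3]),
               tolerance = 1e-10)
  expect_equal(res$se[res$allele == "DEL"], unname(want$se[2]),
               tolerance = 1e-10)
  expect_equal(res$n_total, c(300, 300))
})

test_that("main-effect estimates are equivariant under DEL/DUP label flips", {
  set.seed(32)
  co <- make_cohort(n = 1000, f_carrier = 0.08, beta = 0.5)
  co$geno[co$geno == "REF"][1:40] <- "DUP"
  res1 <- fit_main_effect(co, "trait", "geno")
  co2 <- co
  co2$geno <- c(DEL = "DUP", DUP = "DEL", REF = "REF")[co$geno]
  res2 <- fit_main_effect(co2, "trait", "geno")
  expect_equal(res1$beta[res1$allele == "DEL"],
               res2$beta[res2$allele == "DUP"])
  expect_equal(res1$se[res1$allele == "DEL"],
               res2$se[res2$allele == "DUP"])
})

test_that("NO_CALL samples are dropped per span and zero carriers error", {
  set.seed(33)
  co <- make_cohort(n = 500, f_carrier = 0.1, beta = 0)
  co$geno[1:50] <- "NO_CALL"
  res <- fit_main_effect(co, "trait", "geno")
  expect_equal(unique(res$n_total), 450)
  co$geno <- "REF"
  expect_error(fit_main_effect(co, "trait", "geno"), "no DEL or DUP")
})

test_that("PC adjustment removes planted confounding", {
  set.seed(34)
  n <- 20000
  carrier <- runif(n) < 0.02
  pc1 <- rnorm(n) + 1.5 * carrier            # carriers shifted on PC1
  y <- 0.8 * pc1 + 0 * carrier + rnorm(n)    # trait driven by PC1, not CNV
  co <- data.frame(trait = y, geno = ifelse(carrier, "DEL", "REF"),
                   PC1 = pc1, stringsAsFactors = FALSE)
  adj <- fit_main_effect(co, "trait", "geno")
  raw <- summary(lm(y ~ carrier))$coefficients["carrierTRUE", ]
  expect_gt(abs(raw["Estimate"]), 0.5)       # unadjusted is badly biased
  expect_lt(abs(adj$beta), 0.1)              # adjusted recovers ~0
})

test_that("planted effects are recovered with calibrated CIs", {
  set.seed(35)
  hits <- 0
  reps <- 60
  for (i in 1:reps) {
    co <- make_cohort(n = 4000, f_carrier = 0.02, beta = -0.5)
    r <- fit_main_effect(co, "trait", "geno")
    if (abs(r$beta + 0.5) <= qnorm(0.975) * r$se) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.85)               # ~95% coverage, small-rep slack
})

test_that("interaction fit recovers a planted moderation and its null", {
  set.seed(36)
  co <- make_cohort(n = 30000, f_carrier = 0.03, beta = -0.3,
                    pgs_gamma = 0.2)
  r <- fit_interaction(co, "trait", "geno", "PGS")
  expect_equal(r$beta, 0.2, tolerance = 0.12)
  expect_equal(r$z, r$beta / r$se)
  # additive generator: interaction near zero
  co0 <- make_cohort(n = 30000, f_carrier = 0.03, beta = -0.3)
  r0 <- fit_interaction(co0, "trait", "geno", "PGS")
  expect_lt(abs(r0$beta), 3 * r0$se)
  expect_error(fit_interaction(transform(co, PGS = 1), "trait", "geno", "PGS"),
               "constant")
})

test_that("sex moderator uses a 0/1 indicator and detects female-specific effects", {
  set.seed(37)
  hits <- 0
  for (i in 1:20) {
    n <- 8000
    sex <- sample(c("F", "M"), n, replace = TRUE)
    g <- ifelse(runif(n) < 0.05, "DEL", "REF")
    y <- (g == "DEL") * ifelse(sex == "F", 0.6, 0.1) + rnorm(n)
    co <- data.frame(trait = y, geno = g, sex = sex, PC1 = rnorm(n))
    r <- fit_interaction(co, "trait", "geno", "sex")
    # levels sort F < M: indicator is 1 for M, so female excess has beta < 0
    if (r$beta < 0) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.95)
})

test_that("variance explained matches the rare-indicator closed form", {
  set.seed(38)
  n <- 100000
  f <- 0.01
  beta <- 0.5
  g <- ifelse(runif(n) < f, "DEL", "REF")
  y <- beta * (g == "DEL") + rnorm(n, 0, sqrt(1 - f * (1 - f) * beta^2))
  co <- data.frame(trait = y, s1 = g, PC1 = rnorm(n),
                   stringsAsFactors = FALSE)
  ve <- variance_explained(co, "trait", "s1")
  expect_equal(ve$delta_r2, f * (1 - f) * beta^2, tolerance = 0.2)
  expect_gte(ve$r2_full, ve$r2_cov)
  # null effects: inflation bounded by the parameter-count expectation
  co$y0 <- rnorm(n)
  ve0 <- variance_explained(co, "y0", "s1")
  expect_lt(ve0$delta_r2, 2 * 2 / n)
  expect_gte(ve0$delta_r2, 0)
})

test_that("medication tabulation takes the union of categories", {
  dict <- data.frame(code = c("d1", "d2", "p1", "m1"),
                     category = c("antidepressant", "antidepressant",
                                  "antipsychotic", "mood_stabilizer"),
                     stringsAsFactors = FALSE)
  rx <- data.frame(sample_id = c("a", "b", "b", "b", "d"),
                   code = c("d1", "d2", "p1", "m1", "zz"),
                   stringsAsFactors = FALSE)
  expect_message(
    tab <- tabulate_medications(rx, dict, samples = c("a", "b", "c", "d")),
    "unknown")
  expect_equal(tab$antidepressant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(tab$any, c(TRUE, TRUE, FALSE, FALSE))
  # all three categories -> all four flags
  expect_true(all(unlist(tab[tab$sample_id == "b", -1])))
  # empty prescriptions -> all FALSE
  expect_equal(tab$any[tab$sample_id == "c"], FALSE)
  expect_identical(attr(tab, "unknown_codes"), "zz")
})

test_that("medication enrichment chi-square matches the hand value", {
  # [[30,70],[10,90]]: chi2 = 200*(30*90-70*10)^2/(100*100*40*160) = 12.5
  co <- data.frame(
    geno = rep(c("DEL", "REF"), each = 100),
    any = c(rep(TRUE, 30), rep(FALSE, 70), rep(TRUE, 10), rep(FALSE, 90)))
  r <- medication_enrichment(co, "geno", classes = "any")
  expect_equal(r$chisq, 12.5)
  expect_equal(r$p, stats::pchisq(12.5, 1, lower.tail = FALSE))
  # agreement with the uncorrected chisq.test route
  ct <- stats::chisq.test(matrix(c(30, 70, 10, 90), 2, byrow = TRUE),
                          correct = FALSE)
  expect_equal(r$chisq, unname(ct$statistic))
  # identical proportions -> exactly 0
  co2 <- data.frame(geno = rep(c("DUP", "REF"), each = 50),
                    any = rep(c(TRUE, FALSE), 50))
  expect_equal(medication_enrichment(co2, "geno", classes = "any")$chisq, 0)
})

test_that("enrichment detection has power at a planted odds ratio", {
  set.seed(39)
  hits <- 0
  for (i in 1:20) {
    n <- 20000
    carrier <- runif(n) < 500 / n
    p <- plogis(qlogis(0.10) + log(2) * carrier)
    co <- data.frame(geno = ifelse(carrier, "DEL", "REF"),
                     any = runif(n) < p)
    r <- medication_enrichment(co, "geno", classes = "any")
    if (r$p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 20, 0.9)
})

test_that("stratified means match the additive closed form and are stable", {
  set.seed(40)
  n <- 60000
  pgs <- rnorm(n)
  g <- sample(c("REF", "DEL", "DUP"), n, replace = TRUE,
              prob = c(0.9, 0.05, 0.05))
  beta <- c(REF = 0, DEL = -0.5, DUP = 0.5)
  y <- beta[g] + 0.4 * pgs + rnorm(n, 0, 0.2)
  co <- data.frame(trait = y, geno = g, PGS = pgs, stringsAsFactors = FALSE)
  sm <- stratified_means(co, "trait", "geno", pgs = "PGS")
  # analytic range: CNV spread + 0.4 * spread of quartile PGS means
  qm <- tapply(pgs, cut(pgs, quantile(pgs, seq(0, 1, 0.25)),
                        include.lowest = TRUE), mean)
  want <- (0.5 + 0.5) + 0.4 * (max(qm) - min(qm))
  expect_equal(sm$range, want, tolerance = 0.1)
  # permutation invariance
  sm2 <- stratified_means(co[sample(n), ], "trait", "geno", pgs = "PGS")
  expect_equal(sm$table$mean, sm2$table$mean, tolerance = 1e-3)
  expect_equal(nrow(sm$table), 12)
})
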
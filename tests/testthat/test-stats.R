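make_cohort <- function(n = 300, beta = 0, seed = 1, interaction = 0) {
  set.seed(seed)
  idx <- rnorm(n)
  moca <- rnorm(n)
  d <- tibble::tibble(
    subject_id = sprintf("C%04d", 1:n),
    composite_COR = idx,
    age = rnorm(n, 73, 8),
    sex = factor(sample(c("F", "M"), n, TRUE)),
    site = factor(sample(c("KUMC", "USC", "UTSW"), n, TRUE)),
    apoe_e4 = rbinom(n, 1, 0.4) == 1,
    moca = moca,
    icv = rnorm(n, 1.45e6, 1.5e5)
  )
  d$hippocampal_volume <- beta * idx + interaction * idx * moca +
    rnorm(n, 0, sqrt(max(1 - beta^2, 0.3)))
  d
}

test_that("zscore standardizes, is idempotent, and rejects constants", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(2)
  x <- rnorm(50, 10, 3)
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(zscore(z), z, tolerance = 1e-12)
  expect_error(zscore(rep(4, 10)), "constant")
  xna <- c(x, NA)
  expect_identical(is.na(zscore(xna)), is.na(xna))
})

test_that("identical groups give a null ANOVA and unit Tukey p-values", {
  g <- rep(c("CN", "MCI", "dementia"), each = 30)
  v <- rep(rnorm(30, 0, 1), 3)
  at <- anova_tukey(tibble::tibble(v = v, g = g), "v", "g")
  expect_lt(at$statistic, 1e-20)
  expect_true(all(at$pairwise$adj.p.value > 1 - 1e-10))
  expect_error(anova_tukey(tibble::tibble(v = v[1:60], g = g[1:60]), "v", "g"),
               "3 groups")
})

test_that("Tukey adjusted p-values agree with a permutation max-range null", {
  set.seed(5)
  d <- tibble::tibble(v = rnorm(15), g = rep(c("a", "b", "c"), each = 5))
  at <- anova_tukey(d, "v", "g")
  # permutation oracle: distribution of the studentized pairwise statistic's
  # maximum under label exchange
  B <- 4000
  stat_pair <- function(v, g) {
    m <- tapply(v, g, mean)
    mse <- sum((v - ave(v, g))^2) / (length(v) - 3)
    abs(outer(m, m, `-`))[lower.tri(diag(3))] / sqrt(mse / 5)
  }
  obs <- stat_pair(d$v, d$g)
  null_max <- replicate(B, max(stat_pair(sample(d$v), d$g)))
  p_perm <- sapply(obs, function(o) mean(null_max >= o))
  expect_equal(sort(unname(p_perm)), sort(unname(at$pairwise$adj.p.value)),
               tolerance = 0.15)
})

test_that("covariate-adjusted association recovers a planted standardized slope", {
  d <- make_cohort(n = 2000, beta = 0.26, seed = 3)
  res <- fit_association(d, "composite_COR", "hippocampal_volume")
  expect_lt(abs(res$beta - 0.26), 0.05)
  expect_true(res$conf.low <= res$beta && res$beta <= res$conf.high)
  expect_identical(res$n, 2000L)
  expect_match(res$covariates, "icv") # volumetric outcome pulls in ICV
})

test_that("null associations cover zero at the nominal rate", {
  hits <- sapply(1:300, function(i) {
    d <- make_cohort(n = 120, beta = 0, seed = 1000 + i)
    r <- fit_association(d, "composite_COR", "hippocampal_volume")
    r$conf.low <= 0 && 0 <= r$conf.high
  })
  expect_gt(mean(hits), 0.91)
  expect_lt(mean(hits), 0.985)
})

test_that("association guards: collinearity, constants, small samples", {
  d <- make_cohort(n = 100, seed = 4)
  d$dup <- d$moca
  expect_error(
    fit_association(d, "composite_COR", "hippocampal_volume",
                    covariates = c("age", "sex", "moca", "dup")),
    class = "hemodyn_estimation_failure"
  )
  d2 <- make_cohort(n = 100, seed = 5)
  d2$composite_COR <- 1
  expect_error(fit_association(d2, "composite_COR", "hippocampal_volume"),
               "constant")
  expect_error(fit_association(make_cohort(n = 10, seed = 6),
                               "composite_COR", "hippocampal_volume"),
               class = "hemodyn_insufficient_n")
})

test_that("with no covariates the standardized beta is the Pearson correlation", {
  d <- make_cohort(n = 150, beta = 0.4, seed = 7)
  res <- fit_association(d, "composite_COR", "hippocampal_volume",
                         covariates = character(0), icv_outcomes = character(0))
  expect_equal(res$beta, cor(d$composite_COR, d$hippocampal_volume),
               tolerance = 1e-10)
})

test_that("standardized betas are invariant to affine rescaling", {
  d <- make_cohort(n = 200, beta = 0.3, seed = 8)
  r1 <- fit_association(d, "composite_COR", "hippocampal_volume")
  d2 <- d
  d2$composite_COR <- 100 + 7 * d2$composite_COR
  d2$hippocampal_volume <- -2 + 0.001 * d2$hippocampal_volume
  r2 <- fit_association(d2, "composite_COR", "hippocampal_volume")
  expect_equal(r1$beta, r2$beta, tolerance = 1e-10)
  expect_equal(r1$p.value, r2$p.value, tolerance = 1e-10)
})

test_that("reported n always equals the complete cases analyzed", {
  d <- make_cohort(n = 200, beta = 0.3, seed = 9)
  d$moca[1:30] <- NA
  d$hippocampal_volume[31:40] <- NA
  res <- fit_association(d, "composite_COR", "hippocampal_volume")
  expect_identical(res$n, 160L)
})

test_that("stratified fits detect stratum-specific effects", {
  set.seed(10)
  reps <- sapply(1:25, function(i) {
    n <- 400
    d <- make_cohort(n = n, beta = 0, seed = 2000 + i)
    d$diagnosis <- factor(rep(c("CN", "MCI", "dementia"), length.out = n),
                          levels = c("CN", "MCI", "dementia"))
    imp <- d$diagnosis != "CN"
    # effect present only in the impaired stratum
    d$hippocampal_volume <- d$hippocampal_volume +
      ifelse(imp, 0.5 * d$composite_COR, 0)
    s <- stratified_association(d, "composite_COR", "hippocampal_volume")
    abs(s$beta[s$stratum == "impaired"]) > abs(s$beta[s$stratum == "unimpaired"])
  })
  expect_gte(mean(reps), 0.9)

  d <- make_cohort(n = 60, seed = 11)
  d$diagnosis <- factor(rep("CN", 60), levels = c("CN", "MCI", "dementia"))
  s <- stratified_association(d, "composite_COR", "hippocampal_volume")
  expect_false(s$available[s$stratum == "impaired"])
  expect_true(is.na(s$beta[s$stratum == "impaired"]))
})

test_that("MoCA interaction terms are recovered and null-calibrated", {
  d <- make_cohort(n = 2000, beta = 0.2, seed = 12, interaction = 0.3)
  res <- moca_interaction(d, "composite_COR", "hippocampal_volume")
  expect_lt(abs(res$beta - 0.3), 0.05)
  covered <- sapply(1:120, function(i) {
    d0 <- make_cohort(n = 150, beta = 0.2, seed = 3000 + i)
    r <- moca_interaction(d0, "composite_COR", "hippocampal_volume")
    r$conf.low <= 0 && 0 <= r$conf.high
  })
  expect_gt(mean(covered), 0.88)
})

test_that("index-cognition association matches its planted slope", {
  set.seed(13)
  n <- 2000
  d <- make_cohort(n = n, seed = 13)
  d$moca <- 0.3 * d$composite_COR + rnorm(n, 0, sqrt(1 - 0.09))
  res <- index_cognition_association(d, "composite_COR")
  expect_lt(abs(res$beta - 0.3), 0.05)
  # degenerate: index identical to MoCA
  d$moca <- d$composite_COR
  res2 <- suppressWarnings(index_cognition_association(d, "composite_COR"))
  expect_equal(res2$beta, 1, tolerance = 1e-10)
})

test_that("Bonferroni threshold arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 4), 0.0125)
  expect_equal(bonferroni_threshold(0.03, 1), 0.03)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
  expect_error(bonferroni_threshold(1.2, 4), "alpha")
})

test_that("covariate screen flags real shifts and covers under the null", {
  set.seed(14)
  covered <- sapply(1:150, function(i) {
    d <- make_cohort(n = 120, seed = 4000 + i)
    d$hemisphere <- factor(sample(c("L", "R"), 120, TRUE, prob = c(0.1, 0.9)))
    r <- covariate_check(d, "composite_COR", "hemisphere")
    r$conf.low <= 0 && 0 <= r$conf.high
  })
  expect_gt(mean(covered), 0.9)
  d <- make_cohort(n = 200, seed = 15)
  d$hemisphere <- factor(sample(c("L", "R"), 200, TRUE))
  d$composite_COR <- d$composite_COR + (d$hemisphere == "L")
  r <- covariate_check(d, "composite_COR", "hemisphere")
  expect_lt(r$p.value, 0.01)
  d$hemisphere <- factor(rep("R", 200))
  expect_error(covariate_check(d, "composite_COR", "hemisphere"), "constant")
})

test_that("the full battery labels cells against the Bonferroni threshold", {
  d <- make_cohort(n = 500, beta = 0.3, seed = 16)
  d$DVR <- rnorm(500)
  d$wmh_volume <- rnorm(500)
  tab <- association_table(d, indices = c("composite_COR", "DVR"),
                           outcomes = c("hippocampal_volume", "wmh_volume"))
  expect_identical(nrow(tab), 4L)
  expect_equal(attr(tab, "bonferroni"), 0.0125)
  lead <- tab[tab$predictor == "composite_COR" &
                tab$outcome == "hippocampal_volume", ]
  expect_identical(lead$label, "significant")
  expect_true(all(tab$label %in% c("significant", "trend", "ns")))
})
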
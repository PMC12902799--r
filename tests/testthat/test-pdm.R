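test_that("a rank-1 kernel ensemble yields a single mode equal to the shape", {
  set.seed(1)
  shape <- exp(-(0:59) / 10) * sin((0:59) / 5 + 0.4)
  scales <- runif(12, 0.5, 2)
  K <- outer(scales, shape)
  rownames(K) <- paste0("s", 1:12)
  p <- train_pdms(K, variance_threshold = 0.9)
  expect_identical(p$Q, 1L)
  ref <- shape / sqrt(sum(shape^2))
  expect_lt(min(sum((p$P[, 1] - ref)^2), sum((p$P[, 1] + ref)^2)), 1e-20)
  expect_lt(p$singular_values[2] / p$singular_values[1], 1e-10)
})

test_that("a planted rank-2 ensemble is recovered with tiny principal angles", {
  pc <- planted_kernel_cohort(n_per_group = 30, delta = 0, seed = 2)
  p <- train_pdms(pc$K, variance_threshold = 0.99)
  expect_identical(p$Q, 2L)
  # principal angles between span(P) and span(shapes), via the eigen
  # decomposition oracle
  sv <- svd(crossprod(p$P, pc$shapes))$d
  angles <- acos(pmin(sv, 1))
  expect_lt(max(angles), 1e-6)
  # mode sign convention: largest-magnitude element positive
  for (q in 1:p$Q) expect_gt(p$P[which.max(abs(p$P[, q])), q], 0)
})

test_that("PDM training is invariant to subject order and guards its inputs", {
  pc <- planted_kernel_cohort(n_per_group = 20, seed = 3)
  p1 <- train_pdms(pc$K)
  set.seed(4)
  perm <- sample(nrow(pc$K))
  p2 <- train_pdms(pc$K[perm, ])
  expect_equal(p1$P, p2$P, tolerance = 1e-10)
  expect_equal(p1$singular_values, p2$singular_values, tolerance = 1e-10)
  expect_error(train_pdms(pc$K[1:5, ]), "10")
})

test_that("gains are inner products and reconstruct to projection accuracy", {
  pc <- planted_kernel_cohort(n_per_group = 20, seed = 5)
  p <- train_pdms(pc$K, variance_threshold = 0.99)
  # kernel equal to a mode gives a unit coordinate vector
  g1 <- compute_gains(p$P[, 1], p)
  expect_equal(unname(g1), c(1, 0), tolerance = 1e-10)
  # kernel orthogonal to all modes gives zero gains
  ortho <- rnorm(60)
  ortho <- ortho - p$P %*% crossprod(p$P, ortho)
  expect_lt(max(abs(compute_gains(as.vector(ortho), p))), 1e-10)
  # projection matches brute-force least squares onto the mode columns
  set.seed(6)
  k <- rnorm(60)
  g <- compute_gains(k, p)
  recon <- as.vector(p$P %*% g)
  ls <- as.vector(p$P %*% qr.coef(qr(p$P), k))
  expect_lt(max(abs(recon - ls)), 1e-10)
  expect_lte(sqrt(sum((k - recon)^2)), sqrt(sum(k^2)) + 1e-12)
  expect_error(compute_gains(rnorm(10), p), "length")
})

test_that("reference distributions recover planted group means per stratum", {
  set.seed(7)
  n <- 200
  gains <- cbind(g1 = c(rnorm(n, 1), rnorm(n, -1)))
  impaired <- rep(c(FALSE, TRUE), each = n)
  apoe <- rbinom(2 * n, 1, 0.4) == 1
  refs <- fit_reference_distributions(gains, impaired, apoe)
  cn <- refs[refs$group == "CN", ]
  ci <- refs[refs$group == "CI", ]
  expect_true(all(abs(cn$mu - 1) < 0.25)) # 3 / sqrt(200) bound
  expect_true(all(abs(ci$mu + 1) < 0.25))
  expect_true(all(refs$sigma > 0))
  # identical groups give exactly equal cell parameters
  refs2 <- fit_reference_distributions(rbind(gains, gains),
                                       rep(c(FALSE, TRUE), each = 2 * n),
                                       rep(apoe, 2))
  expect_equal(refs2$mu[refs2$group == "CN"], refs2$mu[refs2$group == "CI"])
  expect_equal(refs2$sigma[refs2$group == "CN"], refs2$sigma[refs2$group == "CI"])
  # single APOE stratum present: pooled fallback with warning
  expect_warning(
    refs3 <- fit_reference_distributions(gains, impaired, rep(TRUE, 2 * n)),
    "pooled"
  )
  expect_true(all(refs3$pooled[refs3$stratum == "noncarrier"]))
  expect_error(
    fit_reference_distributions(gains, rep(FALSE, 2 * n), apoe),
    class = "hemodyn_training_failure"
  )
})

test_that("log-likelihood ratios match their closed forms", {
  expect_equal(loglik_ratio(1, 1, 1, -1, 1), 2)
  expect_equal(loglik_ratio(0, 1, 1, -1, 1), 0)
  # antisymmetry under swapping the reference groups
  g <- c(-2.2, 0.3, 1.7)
  expect_equal(loglik_ratio(g, 0.8, 1.2, -0.5, 0.7),
               -loglik_ratio(g, -0.5, 0.7, 0.8, 1.2))
  expect_error(loglik_ratio(1, 0, 0, 1, 1), class = "hemodyn_invalid_state")
})

test_that("index weights upweight informative gains and fall back safely", {
  set.seed(8)
  n <- 500
  impaired <- rep(c(FALSE, TRUE), each = n / 2)
  informative <- ifelse(impaired, -1, 1) + rnorm(n, 0, 1)
  llr <- cbind(a = informative, b = rnorm(n), c = rnorm(n))
  w <- fit_index_weights(llr, impaired)
  expect_false(attr(w, "fallback"))
  expect_gt(abs(w[1]), abs(w[2]))
  expect_gt(abs(w[1]), abs(w[3]))
  expect_equal(sum(abs(w)), 1, tolerance = 1e-12)
  idx <- compute_index(llr, w)
  expect_gt(mean(idx[!impaired]), mean(idx[impaired]))

  # identical columns trigger the equal-weight fallback
  expect_warning(
    w2 <- fit_index_weights(cbind(informative, informative), impaired),
    "equal weights"
  )
  expect_true(attr(w2, "fallback"))
  expect_equal(abs(unname(w2)), c(0.5, 0.5), ignore_attr = TRUE)

  # perfect separation also falls back
  sep <- ifelse(impaired, -10, 10)
  expect_warning(w3 <- fit_index_weights(cbind(sep, rnorm(n)), impaired),
                 "equal weights")
  expect_true(attr(w3, "fallback"))
})

test_that("shuffled training labels give chance-level held-out discrimination", {
  set.seed(9)
  n <- 600
  impaired <- rep(c(FALSE, TRUE), each = n / 2)
  llr <- cbind(ifelse(impaired, -0.8, 0.8) + rnorm(n), rnorm(n))
  train <- seq_len(n / 2) * 2 - 1 # odd rows
  test <- setdiff(seq_len(n), train)
  # one permuted fit can land anywhere around chance (the weights pick a
  # random sign on the informative column); the mean over permutations is 0.5
  aucs <- replicate(20, {
    shuffled <- sample(impaired)
    w <- suppressWarnings(fit_index_weights(llr[train, ], shuffled[train]))
    classification_auc(compute_index(llr[test, ], w), !impaired[test])
  })
  expect_gt(mean(aucs), 0.42)
  expect_lt(mean(aucs), 0.58)
})

test_that("index arithmetic and the physiological step-response forms", {
  expect_equal(compute_index(c(1, 3), c(0.5, 0.5)), 2)
  expect_equal(compute_index(c(0, 0, 0), c(0.2, 0.3, 0.5)), 0)
  # unit impulse at lag 0: DC gain 1
  expect_equal(physiological_index(c(1, rep(0, 59)), Ts = 1), 1)
  # (1, -1): transient with no steady-state response
  expect_equal(physiological_index(c(1, -1, rep(0, 58)), Ts = 1), 0)
  # random kernel: matches brute-force convolution with a unit step
  set.seed(10)
  k <- rnorm(60)
  step_resp <- sapply(1:60, function(n) sum(k[1:n] * 1))
  expect_equal(physiological_index(k, Ts = 1), step_resp[60])
  expect_equal(physiological_index(k, Ts = 1, method = "integrated_step"),
               sum(step_resp))
  expect_equal(physiological_index(k, Ts = 0.5), 0.5 * step_resp[60])
})
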
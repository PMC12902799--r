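# Shared fixtures: all generated in code, nothing stored on disk.

nmse_vec <- function(est, truth) sum((est - truth)^2) / sum(truth^2)

# True kernels that live exactly in the default estimation basis
# (alpha = 0.5, L = 4), so noiseless recovery is limited only by the
# numerical pipeline, not by model mismatch.
inbasis_kernel_specs <- function() {
  list(
    "ABP->CBV" = kernel_spec("ABP->CBV", c(0.60, -0.25, 0.08, 0.02), 0.5, 0.30),
    "CO2->CBV" = kernel_spec("CO2->CBV", c(0.50, 0.30, -0.10, 0.05), 0.5, 1.50),
    "ABP->OXY" = kernel_spec("ABP->OXY", c(0.50, -0.20, 0.05, 0.01), 0.5, 0.03),
    "CO2->OXY" = kernel_spec("CO2->OXY", c(0.50, 0.25, -0.08, 0.03), 0.5, 0.15)
  )
}

noiseless_recording <- function(seed, duration_s = 480) {
  spec <- subject_spec("syn", kernel_specs = inbasis_kernel_specs(),
                       noise_sd = 0, artifact_rate = 0)
  generate_subject_recording(spec, duration_s, seed = seed)
}

# Ensemble of per-subject kernels built from two fixed orthogonal shapes
# with group-shifted loadings: group 0 loadings ~ N(mu0, 1), group 1
# ~ N(mu0 - delta, 1) on both shapes.
planted_kernel_cohort <- function(n_per_group = 200, delta = 1, M = 60,
                                  seed = 1) {
  set.seed(seed)
  b <- laguerre_basis(0.5, 2, M)
  shapes <- b$B # two orthonormal columns
  n <- 2 * n_per_group
  impaired <- rep(c(FALSE, TRUE), each = n_per_group)
  a1 <- rnorm(n, ifelse(impaired, -delta, 0), 1)
  a2 <- rnorm(n, ifelse(impaired, -delta, 0), 1)
  K <- cbind(a1, a2) %*% t(shapes)
  rownames(K) <- sprintf("P%04d", seq_len(n))
  list(K = K, impaired = impaired,
       apoe = rep_len(c(TRUE, FALSE), n), shapes = shapes)
}
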
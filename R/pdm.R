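#' Derive cohort principal dynamic modes for one pathway
#'
#' Singular value decomposition of the subjects-by-lags matrix of
#' estimated kernels for one input->output pathway. The right singular
#' vectors, ranked by singular value, are the orthonormal principal
#' dynamic modes (PDMs); the number of retained modes `Q` is the smallest
#' count whose cumulative squared-singular-value fraction reaches
#' `variance_threshold`, capped at `q_cap`. The sign of each mode is fixed
#' so its largest-magnitude element is positive (the SVD sign ambiguity
#' must not flip gains between runs).
#'
#' @param kernels Numeric matrix, one row per training subject, one column
#'   per lag (rownames are subject ids), or a tibble with columns
#'   `subject_id`, `lag`, `value`.
#' @param variance_threshold Cumulative energy fraction to retain.
#' @param q_cap Maximum number of modes.
#' @param pathway Optional pathway label carried in the result.
#' @return An object of class `pdm_set` with the `M x Q` mode matrix `P`,
#'   all singular values, `Q` and the training ids.
#' @export
train_pdms <- function(kernels, variance_threshold = 0.9, q_cap = 3,
                       pathway = NULL) {
  if (is.data.frame(kernels)) {
    wide <- tidyr::pivot_wider(kernels, id_cols = "subject_id",
                               names_from = "lag", values_from = "value")
    ids <- wide$subject_id
    kernels <- as.matrix(wide[, -1])
    rownames(kernels) <- ids
  }
  if (nrow(kernels) < 10) {
    abort("At least 10 training subjects are required for the ensemble SVD.")
  }
  sv <- svd(kernels)
  d2 <- sv$d^2
  cum <- cumsum(d2) / sum(d2)
  Q <- which(cum >= variance_threshold)[1]
  Q <- as.integer(min(Q, q_cap, sum(sv$d > max(sv$d) * 1e-12)))
  if (nrow(kernels) < Q) {
    abort("Fewer training subjects than retained modes.")
  }
  P <- sv$v[, seq_len(Q), drop = FALSE]
  for (q in seq_len(Q)) {
    if (P[which.max(abs(P[, q])), q] < 0) P[, q] <- -P[, q]
  }
  colnames(P) <- paste0("g", seq_len(Q))
  structure(
    list(pathway = pathway, P = P, singular_values = sv$d, Q = Q,
         variance_threshold = variance_threshold,
         training_ids = rownames(kernels)),
    class = "pdm_set"
  )
}

#' @export
print.pdm_set <- function(x, ...) {
  cat(sprintf(
    "<pdm_set>%s Q = %d modes of length %d (%.1f%% energy), %d training subjects\n",
    if (is.null(x$pathway)) "" else paste0(" ", x$pathway, ":"),
    x$Q, nrow(x$P),
    100 * sum(x$singular_values[seq_len(x$Q)]^2) / sum(x$singular_values^2),
    length(x$training_ids)
  ))
  invisible(x)
}

#' @export
tidy.pdm_set <- function(x, ...) {
  tibble::tibble(
    mode = rep(colnames(x$P), each = nrow(x$P)),
    lag = rep(seq_len(nrow(x$P)) - 1, ncol(x$P)),
    value = as.vector(x$P)
  )
}

#' @export
glance.pdm_set <- function(x, ...) {
  tibble::tibble(
    pathway = x$pathway %||% NA_character_, Q = x$Q,
    energy_fraction = sum(x$singular_values[seq_len(x$Q)]^2) /
      sum(x$singular_values^2),
    n_training = length(x$training_ids)
  )
}

#' Project kernels onto the principal dynamic modes
#'
#' The principal dynamic mode gains are the inner products of a subject's
#' kernel with each retained mode.
#'
#' @param kernel Numeric vector of length `M`, or a subjects-by-lags
#'   matrix.
#' @param pdms A [train_pdms()] result.
#' @return A named gain vector (single kernel) or a subjects-by-Q matrix.
#' @export
compute_gains <- function(kernel, pdms) {
  stopifnot(inherits(pdms, "pdm_set"))
  M <- nrow(pdms$P)
  if (is.matrix(kernel)) {
    if (ncol(kernel) != M) abort("Kernel length does not match the modes.")
    return(kernel %*% pdms$P)
  }
  if (length(kernel) != M) abort("Kernel length does not match the modes.")
  setNames(as.vector(crossprod(pdms$P, kernel)), colnames(pdms$P))
}

#' Fit APOE-stratified reference gain distributions
#'
#' For every (APOE stratum x cognitive group x mode) cell, fits a Gaussian
#' to the training gains of the cognitively unimpaired (`CN`) and
#' cognitively impaired (`CI`) reference groups. Log-likelihood ratios are
#' later evaluated against the carrier or non-carrier cell of the subject.
#' Cells with fewer than `min_cell` subjects fall back to the fit pooled
#' across strata, with a warning.
#'
#' @param gains Subjects-by-modes gain matrix.
#' @param impaired Logical vector (TRUE = MCI or dementia).
#' @param apoe Logical vector (TRUE = epsilon-4 carrier).
#' @param min_cell Minimum subjects per cell before pooling.
#' @return An object of class `gain_refs`: a tibble with columns
#'   `stratum`, `group`, `mode`, `mu`, `sigma`, `n`, `pooled`.
#' @export
fit_reference_distributions <- function(gains, impaired, apoe, min_cell = 5) {
  gains <- as.matrix(gains)
  stopifnot(nrow(gains) == length(impaired), nrow(gains) == length(apoe))
  if (all(impaired) || !any(impaired)) {
    abort("Both cognitive groups must be present to fit reference distributions.",
          class = "hemodyn_training_failure")
  }
  modes <- colnames(gains) %||% paste0("g", seq_len(ncol(gains)))
  colnames(gains) <- modes
  cells <- tidyr::expand_grid(
    stratum = c("carrier", "noncarrier"),
    group = c("CN", "CI"),
    mode = modes
  )
  fit_cell <- function(stratum, group, mode) {
    keep <- (impaired == (group == "CI"))
    pooled <- FALSE
    in_str <- keep & (apoe == (stratum == "carrier"))
    if (sum(in_str) < min_cell) {
      pooled <- TRUE
    } else {
      keep <- in_str
    }
    x <- gains[keep, mode]
    tibble::tibble(mu = mean(x), sigma = sd(x), n = sum(keep), pooled = pooled)
  }
  out <- dplyr::bind_cols(cells, purrr::pmap_dfr(cells, fit_cell))
  if (any(out$pooled)) {
    warn("Some APOE-stratum cells had too few subjects; pooled fit used for them.")
  }
  structure(out, class = c("gain_refs", class(tibble::tibble())))
}

#' Gaussian log-likelihood ratio of a gain
#'
#' \eqn{\lambda = \ln N(g; \mu_{CN}, \sigma_{CN}) - \ln N(g; \mu_{CI},
#' \sigma_{CI})}. Positive values indicate proximity of the gain to the
#' cognitively unimpaired reference distribution, negative values to the
#' impaired one.
#'
#' @param g Gain value(s).
#' @param mu_cn,sigma_cn Unimpaired reference mean and SD.
#' @param mu_ci,sigma_ci Impaired reference mean and SD.
#' @return Log-likelihood ratio(s), same length as `g`.
#' @export
loglik_ratio <- function(g, mu_cn, sigma_cn, mu_ci, sigma_ci) {
  if (any(sigma_cn <= 0) || any(sigma_ci <= 0)) {
    abort("Reference SDs must be positive.", class = "hemodyn_invalid_state")
  }
  stats::dnorm(g, mu_cn, sigma_cn, log = TRUE) -
    stats::dnorm(g, mu_ci, sigma_ci, log = TRUE)
}

# Per-gain LLR matrix for a cohort, using each subject's APOE stratum.
llr_matrix <- function(gains, refs, apoe) {
  gains <- as.matrix(gains)
  modes <- colnames(gains) %||% paste0("g", seq_len(ncol(gains)))
  out <- matrix(NA_real_, nrow(gains), ncol(gains),
                dimnames = list(rownames(gains), modes))
  for (m in modes) {
    for (str in c("carrier", "noncarrier")) {
      cn <- refs[refs$stratum == str & refs$group == "CN" & refs$mode == m, ]
      ci <- refs[refs$stratum == str & refs$group == "CI" & refs$mode == m, ]
      rows <- if (str == "carrier") apoe else !apoe
      if (any(rows)) {
        out[rows, m] <- loglik_ratio(gains[rows, m], cn$mu, cn$sigma,
                                     ci$mu, ci$sigma)
      }
    }
  }
  out
}

#' Fit frozen index weights by regression
#'
#' The weights of each log-likelihood-ratio index are determined once, by
#' logistic regression of impairment status on the per-gain LLRs, then
#' rescaled to unit sum of absolute values and oriented so that a higher
#' index means more CN-like dynamics. On perfect separation or collinear
#' LLR columns the fit falls back to equal weights with a warning.
#'
#' @param llr Subjects-by-gains LLR matrix.
#' @param impaired Logical vector.
#' @return Numeric weight vector (attribute `fallback` records whether the
#'   equal-weight fallback was used).
#' @export
fit_index_weights <- function(llr, impaired) {
  llr <- as.matrix(llr)
  Q <- ncol(llr)
  equal <- rep(1 / Q, Q)
  fallback <- FALSE
  w <- NULL
  sep <- FALSE
  fit <- withCallingHandlers(
    tryCatch(glm(impaired ~ llr, family = binomial()),
             error = function(e) NULL),
    warning = function(wn) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(wn))) {
        sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  if (!is.null(fit) && !sep && max(abs(coef(fit)[-1]), na.rm = TRUE) > 50) {
    sep <- TRUE # quasi-separation: diverging slope without a glm warning
  }
  if (is.null(fit) || sep || any(is.na(coef(fit)[-1]))) {
    fallback <- TRUE
    w <- equal
    warn("Index-weight regression degenerate (separation or collinearity); equal weights used.")
  } else {
    w <- unname(coef(fit)[-1])
    if (sum(abs(w)) == 0) {
      fallback <- TRUE
      w <- equal
    } else {
      w <- w / sum(abs(w))
    }
  }
  idx <- as.vector(llr %*% w)
  if (mean(idx[!impaired]) < mean(idx[impaired])) w <- -w
  attr(w, "fallback") <- fallback
  w
}

#' Weighted log-likelihood-ratio index
#'
#' @param llr LLR vector for one subject, or a subjects-by-gains matrix.
#' @param w Frozen weight vector from [fit_index_weights()].
#' @return Scalar index, or one value per subject.
#' @export
compute_index <- function(llr, w) {
  if (is.matrix(llr)) as.vector(llr %*% as.vector(w)) else sum(llr * w)
}

#' Physiological step-response index of a kernel
#'
#' The "raw" physiological counterpart of the LLR indices: the
#' steady-state step response of the output to a sustained unit input
#' change, i.e. the kernel's DC gain `Ts * sum(k)` (default), or
#' alternatively the time-integrated step response `Ts^2 * sum(cumsum(k))`.
#'
#' @param kernel Kernel vector.
#' @param Ts Sampling interval (s).
#' @param method `"dc_gain"` (default) or `"integrated_step"`.
#' @return Scalar, in output units per input unit.
#' @export
physiological_index <- function(kernel, Ts = 1,
                                method = c("dc_gain", "integrated_step")) {
  method <- match.arg(method)
  s <- cumsum(kernel)
  switch(method,
    dc_gain = Ts * s[length(s)],
    integrated_step = Ts^2 * sum(s)
  )
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of a score for discriminating two
#' classes; used to quantify how well an index separates cognitively
#' unimpaired from impaired subjects.
#'
#' @param score Numeric scores (higher = more like the positive class).
#' @param positive Logical vector, TRUE for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
classification_auc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  r <- rank(score)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present.")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
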
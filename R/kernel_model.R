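#' Fit the two-input linear dynamic model for one output
#'
#' Expresses cerebral blood velocity (`CBV`) or tissue oxygenation (`OXY`)
#' as the sum of convolutions of the preprocessed arterial-pressure and
#' end-tidal-CO2 fluctuations with two finite-memory kernels, estimated by
#' the Laguerre expansion technique: each kernel is expanded on `L`
#' discrete orthonormal Laguerre functions and the expansion coefficients
#' (plus a constant offset) are obtained by ordinary least squares of the
#' output on the basis-filtered inputs. The first `M` samples are burn-in
#' and excluded from the regression.
#'
#' @param series A `uniform_series` from [preprocess_recording()] (or any
#'   tibble with columns `ABP`, `ETCO2` and the output, uniformly sampled).
#' @param output `"CBV"` or `"OXY"`.
#' @param alpha,L,M Laguerre basis parameters (see [laguerre_basis()]).
#' @param ridge Optional non-negative ridge penalty on the kernel
#'   coefficients (the offset is never penalized); 0 gives plain OLS.
#' @param Ts Sampling interval; taken from the series attributes when
#'   present.
#' @return An object of class `kernel_model` with the offset `k0`,
#'   coefficient vectors `c_abp`, `c_co2`, reconstructed kernels `k_abp`,
#'   `k_co2` (length `M`, units output per input), coefficient standard
#'   errors, and the normalized mean-squared prediction error `nmse`.
#' @export
fit_kernel_model <- function(series, output = c("CBV", "OXY"),
                             alpha = 0.5, L = 4, M = 60, ridge = 0,
                             Ts = NULL) {
  output <- match.arg(output)
  Ts <- Ts %||% attr(series, "Ts") %||% 1
  if (!output %in% names(series)) {
    abort(sprintf("Channel %s is not available in this series.", output),
          class = "hemodyn_missing_channel")
  }
  for (nm in c("ABP", "ETCO2")) {
    if (!nm %in% names(series)) {
      abort(sprintf("Input channel %s is missing.", nm),
            class = "hemodyn_missing_channel")
    }
    if (sd(series[[nm]]) == 0) {
      abort(sprintf("Input %s is constant; kernel estimation failed.", nm),
            class = "hemodyn_estimation_failure")
    }
  }
  basis <- laguerre_basis(alpha, L, M)
  y_all <- series[[output]]
  Va <- laguerre_convolve(series$ABP, basis)
  Vc <- laguerre_convolve(series$ETCO2, basis)
  # First M samples are convolution burn-in; the last M are dropped too,
  # where the zero-phase filter's edge effects concentrate.
  n_all <- length(y_all)
  use <- (M + 1):max(M + 2 * (2 * L + 1), n_all - M)
  # The high-pass filter zeroes the record's stopband Fourier bins in every
  # channel. On full-memory rows that perturbation lies exactly in the span
  # of the stopband sine/cosine terms, so those few terms enter the design
  # as nuisance drift regressors and the filter artifact is projected out.
  f_cut <- attr(series, "f_cut") %||% 0.005
  # Rows whose regressor memory window (inputs) or own sample (output)
  # falls on a span bridged by interpolation after outlier deletion carry
  # corrupted information and are excluded, unless that would starve the
  # regression.
  gaps <- attr(series, "gaps")
  if (length(gaps)) {
    tvec <- series$time_s
    mask <- rep(FALSE, n_all)
    for (nm in names(gaps)) {
      reach <- if (nm %in% c("ABP", "ETCO2")) M * Ts else 0
      for (r in seq_len(nrow(gaps[[nm]]))) {
        if (nm %in% c("ABP", "ETCO2") || nm == output) {
          g <- gaps[[nm]][r, ]
          mask <- mask | (tvec >= g[1] & tvec <= g[2] + reach)
        }
      }
    }
    keep <- use[!mask[use]]
    if (length(keep) >= max(5 * (2 * L + 1), 100)) use <- keep
  }
  D <- drift_columns(n_all, Ts, f_cut)[use, , drop = FALSE]
  X <- cbind(1, Va[use, , drop = FALSE], Vc[use, , drop = FALSE], D)
  colnames(X) <- c("k0", paste0("ABP_", seq_len(L)), paste0("CO2_", seq_len(L)),
                   colnames(D))
  y <- y_all[use]

  qrX <- qr(X)
  if (qrX$rank < ncol(X) && ridge == 0) {
    abort("Regressor matrix is rank deficient (collinear basis-filtered inputs).",
          class = "hemodyn_estimation_failure")
  }
  if (ridge > 0) {
    pen <- rep(0, ncol(X))
    pen[2:(2 * L + 1)] <- ridge
    cf <- solve(crossprod(X) + diag(pen), crossprod(X, y))[, 1]
  } else {
    cf <- qr.coef(qrX, y)
  }
  fitted <- as.vector(X %*% cf)
  res <- y - fitted
  dof <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / dof
  XtX_inv <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
  se <- if (is.null(XtX_inv)) rep(NA_real_, ncol(X)) else sqrt(sigma2 * diag(XtX_inv))
  nmse <- sum(res^2) / sum((y - mean(y))^2)

  np <- 2 * L + 1
  c_abp <- unname(cf[2:(L + 1)])
  c_co2 <- unname(cf[(L + 2):np])
  structure(
    list(
      output = output, k0 = unname(cf[1]),
      c_abp = c_abp, c_co2 = c_co2,
      k_abp = as.vector(basis$B %*% c_abp),
      k_co2 = as.vector(basis$B %*% c_co2),
      se = setNames(se[seq_len(np)], colnames(X)[seq_len(np)]),
      drift_coef = cf[-seq_len(np)], f_cut = f_cut, n_record = n_all,
      rows_used = use,
      basis = basis, Ts = Ts, nmse = nmse, n_used = length(y),
      df_residual = dof
    ),
    class = "kernel_model"
  )
}

# Sine/cosine pairs at the record's sub-cutoff Fourier frequencies
# (plus one guard bin), evaluated over the whole record.
drift_columns <- function(n, Ts, f_cut) {
  if (f_cut <= 0) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  kmax <- floor((f_cut + 1 / (n * Ts)) * n * Ts) + 1
  idx <- seq_len(n) - 1
  cols <- lapply(seq_len(kmax), function(k) {
    th <- 2 * pi * k * idx / n
    cbind(cos(th), sin(th))
  })
  out <- do.call(cbind, cols)
  colnames(out) <- paste0(rep(c("drift_cos", "drift_sin"), kmax),
                          rep(seq_len(kmax), each = 2))
  out
}

#' @export
print.kernel_model <- function(x, ...) {
  cat(sprintf(
    "<kernel_model> output %s: alpha = %.3g, L = %d, M = %d, Ts = %.3g s, NMSE = %.4g\n",
    x$output, x$basis$alpha, x$basis$L, x$basis$M, x$Ts, x$nmse
  ))
  invisible(x)
}

#' Predict the model output on a series
#'
#' Applies the fitted convolutional relation to (new) preprocessed input
#' series and reports the normalized mean-squared error against the
#' observed output when available. On the training series the NMSE equals
#' the stored one by definition.
#'
#' @param model A [fit_kernel_model()] result.
#' @param series A `uniform_series` with `ABP` and `ETCO2` columns (same
#'   sampling interval as the model).
#' @return Tibble with `time_s`, `fitted` and (when observed) `observed`,
#'   burn-in rows excluded; attribute `nmse` when observed data exist.
#' @export
predict_output <- function(model, series) {
  stopifnot(inherits(model, "kernel_model"))
  Ts <- attr(series, "Ts") %||% model$Ts
  if (abs(Ts - model$Ts) > 1e-12) {
    abort("Sampling interval of the series does not match the model.")
  }
  M <- model$basis$M
  Va <- laguerre_convolve(series$ABP, model$basis)
  Vc <- laguerre_convolve(series$ETCO2, model$basis)
  n <- nrow(series)
  use <- if (n == model$n_record) model$rows_used else (M + 1):n
  fitted <- model$k0 + as.vector(Va[use, , drop = FALSE] %*% model$c_abp) +
    as.vector(Vc[use, , drop = FALSE] %*% model$c_co2)
  # The drift term is record-specific: it applies only when predicting on
  # the training record itself (same length and grid).
  if (length(model$drift_coef) && nrow(series) == model$n_record) {
    D <- drift_columns(model$n_record, model$Ts, model$f_cut)
    fitted <- fitted + as.vector(D[use, , drop = FALSE] %*% model$drift_coef)
  }
  out <- tibble::tibble(time_s = series$time_s[use], fitted = fitted)
  if (model$output %in% names(series)) {
    out$observed <- series[[model$output]][use]
    attr(out, "nmse") <- sum((out$observed - out$fitted)^2) /
      sum((out$observed - mean(out$observed))^2)
  }
  out
}

#' @export
tidy.kernel_model <- function(x, type = c("kernels", "coefficients"), ...) {
  type <- match.arg(type)
  if (type == "coefficients") {
    est <- c(x$k0, x$c_abp, x$c_co2)
    tibble::tibble(
      term = names(x$se),
      estimate = est,
      std.error = unname(x$se),
      statistic = est / unname(x$se)
    )
  } else {
    tibble::tibble(
      input = rep(c("ABP", "ETCO2"), each = x$basis$M),
      lag_s = rep((seq_len(x$basis$M) - 1) * x$Ts, 2),
      value = c(x$k_abp, x$k_co2)
    )
  }
}

#' @export
glance.kernel_model <- function(x, ...) {
  tibble::tibble(
    output = x$output, alpha = x$basis$alpha, L = x$basis$L, M = x$basis$M,
    Ts = x$Ts, nmse = x$nmse, n = x$n_used
  )
}
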
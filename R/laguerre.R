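#' Discrete orthonormal Laguerre basis
#'
#' Builds the matrix of discrete-time orthonormal Laguerre functions
#' \eqn{b_j(m)}, \eqn{j = 0, \dots, L-1}, \eqn{m = 0, \dots, M-1}, used to
#' expand finite-memory impulse-response kernels. The functions decay
#' exponentially at rate controlled by `alpha`, so a handful of them can
#' represent a smooth hemodynamic kernel and keep the least-squares
#' estimation well conditioned on short records.
#'
#' The functions satisfy the recursion
#' \eqn{b_j(m) = \sqrt{\alpha}\, b_j(m-1) + \sqrt{\alpha}\, b_{j-1}(m) -
#' b_{j-1}(m-1)} with \eqn{b_0(m) = \sqrt{1-\alpha}\,\alpha^{m/2}}, and are
#' orthonormal over the infinite lag axis; truncation at `M` lags is
#' negligible when `alpha^M` is small.
#'
#' @param alpha Decay parameter in (0, 1). Larger values give slower decay
#'   (longer memory).
#' @param L Number of basis functions (1--9).
#' @param M Kernel memory in lags; must be at least `L`.
#' @return An object of class `laguerre_basis`: a list with `alpha`, `L`,
#'   `M` and the `M x L` matrix `B` of basis values.
#' @examples
#' b <- laguerre_basis(alpha = 0.5, L = 4, M = 60)
#' crossprod(b$B)[1:2, 1:2] # ~ identity
#' @export
laguerre_basis <- function(alpha = 0.5, L = 4, M = 60) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number strictly between 0 and 1.")
  }
  if (L < 1 || L > 9) abort("`L` must be between 1 and 9.")
  if (M < L) abort("`M` must be at least `L`.")
  sa <- sqrt(alpha)
  B <- matrix(0, nrow = M, ncol = L)
  B[, 1] <- sqrt(1 - alpha) * sa^(seq_len(M) - 1)
  if (L > 1) {
    for (j in 2:L) {
      prev <- B[, j - 1]
      cur <- numeric(M)
      cur[1] <- sa * prev[1]
      for (m in 2:M) {
        cur[m] <- sa * cur[m - 1] + sa * prev[m] - prev[m - 1]
      }
      B[, j] <- cur
    }
  }
  structure(
    list(alpha = alpha, L = as.integer(L), M = as.integer(M), B = B),
    class = "laguerre_basis"
  )
}

#' @export
print.laguerre_basis <- function(x, ...) {
  cat(sprintf(
    "<laguerre_basis> alpha = %.3g, L = %d, M = %d lags\n",
    x$alpha, x$L, x$M
  ))
  invisible(x)
}

#' Convolve a signal with every Laguerre basis function
#'
#' Computes the basis-filtered signals
#' \eqn{v_j(n) = \sum_{m=0}^{M-1} b_j(m)\, x(n-m)} (causal convolution with
#' zero initial conditions). The first `M` output samples are burn-in: they
#' depend on unobserved pre-record input and are excluded from kernel
#' estimation.
#'
#' @param x Numeric vector, a uniformly sampled (mean-removed) input signal.
#' @param basis A [laguerre_basis()].
#' @return A `length(x) x L` matrix of filtered signals, with attribute
#'   `burn_in = basis$M`.
#' @export
laguerre_convolve <- function(x, basis) {
  stopifnot(inherits(basis, "laguerre_basis"))
  n <- length(x)
  if (n <= basis$M) {
    abort(sprintf(
      "Input length (%d) must exceed the kernel memory M = %d.", n, basis$M
    ))
  }
  V <- apply(basis$B, 2, function(b) {
    stats::convolve(x, rev(b), type = "open")[seq_len(n)]
  })
  attr(V, "burn_in") <- basis$M
  V
}
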
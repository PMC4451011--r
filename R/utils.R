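# Small linear-algebra helpers shared across modules.

#' @keywords internal
sym <- function(M) (M + t(M)) / 2

#' @keywords internal
spectral_radius <- function(M) max(Mod(eigen(M, only.values = TRUE)$values))

#' Solve the discrete Lyapunov equation S = M S M' + W
#'
#' Vectorized closed form: vec(S) = (I - M (x) M)^{-1} vec(W). Exact for
#' stable M; intended for the small state dimensions (<= 20) used here.
#'
#' @param M square transition matrix with spectral radius < 1
#' @param W symmetric forcing matrix of the same size
#' @return symmetric solution matrix
#' @keywords internal
dlyap <- function(M, W) {
  d <- nrow(M)
  K <- diag(d * d) - kronecker(M, M)
  S <- matrix(solve(K, as.vector(W)), d, d)
  sym(S)
}

#' Iterative Lyapunov solve, used as an independent oracle in tests
#' @keywords internal
dlyap_iterate <- function(M, W, tol = 1e-13, max_iter = 1e6) {
  S <- W
  for (i in seq_len(max_iter)) {
    S_new <- M %*% S %*% t(M) + W
    if (max(abs(S_new - S)) < tol * (1 + max(abs(S_new)))) return(sym(S_new))
    S <- S_new
  }
  sym(S)
}

#' @keywords internal
as_matrix <- function(x, n, what = "matrix") {
  if (is.null(dim(x))) {
    if (length(x) == 1L) return(diag(as.numeric(x), n))
    if (length(x) == n) return(diag(as.numeric(x), nrow = n))
    stop(sprintf("cannot interpret '%s' of length %d as a %dx%d matrix",
                 what, length(x), n, n), call. = FALSE)
  }
  x <- as.matrix(x)
  if (!all(dim(x) == c(n, n)))
    stop(sprintf("'%s' must be %dx%d", what, n, n), call. = FALSE)
  x
}

#' Upper-triangular Cholesky factor with a PSD-tolerant fallback
#' @keywords internal
chol_psd <- function(M, tol = 1e-10) {
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(R)) return(R)
  e <- eigen(sym(M), symmetric = TRUE)
  vals <- pmax(e$values, 0)
  if (min(e$values) < -tol * max(1, max(abs(e$values))))
    stop("matrix is not positive semidefinite", call. = FALSE)
  # factor L' with M = L L' from the eigendecomposition
  t(e$vectors %*% (t(e$vectors) * sqrt(vals)))
}

#' Random stable transition matrix (test/config helper)
#'
#' Draws a matrix with i.i.d. normal entries and rescales it so its spectral
#' radius equals `radius`.
#'
#' @param n dimension
#' @param radius target spectral radius in [0, 1)
#' @return an n x n matrix
#' @export
random_stable_matrix <- function(n, radius = 0.9) {
  M <- matrix(stats::rnorm(n * n), n, n)
  r <- spectral_radius(M)
  if (r < .Machine$double.eps) return(M)
  M * (radius / r)
}

#' Random symmetric positive definite matrix (test/config helper)
#' @param n dimension
#' @param scale average eigenvalue scale
#' @param jitter minimum eigenvalue, keeps the draw strictly positive definite
#' @return an n x n symmetric positive definite matrix
#' @export
random_spd_matrix <- function(n, scale = 1, jitter = 0.05) {
  Z <- matrix(stats::rnorm(n * n), n, n)
  sym(Z %*% t(Z) * scale / n + diag(jitter * scale, n))
}
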
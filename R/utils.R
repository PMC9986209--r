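# Small numerical helpers shared across modules. All random draws go through
# R's RNG so that a single set.seed() call makes every pipeline stage
# reproducible, including the compiled sampler core.

#' Draw from a multivariate normal distribution
#'
#' Cholesky-based sampler used throughout the package. Kept internal-but-exported
#' because tests exercise it directly as a building block.
#'
#' @param n number of draws.
#' @param mean mean vector.
#' @param sigma covariance matrix.
#' @return An `n x length(mean)` matrix of draws.
#' @export
rmvnorm_chol <- function(n, mean, sigma) {
  p <- length(mean)
  L <- chol(sigma)
  z <- matrix(rnorm(n * p), n, p)
  sweep(z %*% L, 2, mean, `+`)
}

# One draw from N(solve(prec) %*% b, solve(prec)) given natural parameters.
draw_gaussian_natural <- function(prec, b) {
  R <- chol(prec)                       # prec = R'R
  m <- backsolve(R, backsolve(R, b, transpose = TRUE))
  m + backsolve(R, rnorm(length(b)))
}

# Inverse-gamma draw, shape/rate parameterisation: X ~ IG(a, b) <=> 1/X ~ Ga(a, b).
rinvgamma1 <- function(shape, rate) 1 / rgamma(1L, shape = shape, rate = rate)

# Inverse-Wishart draw via Bartlett decomposition of the Wishart for the
# precision matrix: if P ~ W(df, solve(scale)) then solve(P) ~ IW(df, scale).
riwish <- function(df, scale) {
  p <- nrow(scale)
  stopifnot(df > p - 1)
  Sinv <- solve(scale)
  Lp <- chol(Sinv)
  A <- matrix(0, p, p)
  diag(A) <- sqrt(rchisq(p, df = df - seq_len(p) + 1))
  A[upper.tri(A)] <- rnorm(p * (p - 1) / 2)
  U <- A %*% Lp
  P <- crossprod(U)                     # Wishart(df, Sinv)
  solve(P)
}

#' Stationary covariance of a first-order vector autoregression
#'
#' Solves the discrete Lyapunov equation `S = Phi S Phi' + Q` for the
#' stationary covariance of `x_t = Phi x_{t-1} + e_t`, `e_t ~ N(0, Q)`, via the
#' vectorised linear system `(I - Phi (x) Phi) vec(S) = vec(Q)`.
#'
#' @param phi transition matrix (spectral radius < 1).
#' @param q innovation covariance matrix.
#' @return The stationary covariance matrix.
#' @export
stationary_cov <- function(phi, q) {
  p <- nrow(phi)
  if (spectral_radius(phi) >= 1) {
    abort("Transition matrix is not stationary (spectral radius >= 1).")
  }
  vecS <- solve(diag(p * p) - kronecker(phi, phi), as.vector(q))
  matrix(vecS, p, p)
}

#' Spectral radius of a matrix
#'
#' @param m a square matrix.
#' @return Largest eigenvalue modulus.
#' @export
spectral_radius <- function(m) max(Mod(eigen(m, only.values = TRUE)$values))

# Assemble the 2x2 transition matrix from a named random-effect vector.
# Row 1 is the stress equation (phi_ss on lagged stress, phi_as on lagged
# affect); row 2 the affect equation (phi_sa on lagged stress, phi_aa on
# lagged affect).
phi_matrix <- function(re) {
  matrix(c(re[["phi_ss"]], re[["phi_as"]],
           re[["phi_sa"]], re[["phi_aa"]]),
         2, 2, byrow = TRUE)
}

re_names <- function() c("mu_s", "mu_a", "phi_ss", "phi_aa", "phi_as", "phi_sa")

# Effective sample size of a (roughly stationary) MCMC trace via the initial
# positive sequence of autocorrelations.
ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  rho <- as.numeric(acf(x, lag.max = min(n - 2, 200), plot = FALSE)$acf)[-1]
  s <- 0
  for (k in seq_along(rho)) {
    if (rho[k] < 0.01) break
    s <- s + rho[k]
  }
  max(1, n / (1 + 2 * s))
}

`%||%` <- rlang::`%||%`
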
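# Internal numerical utilities shared across modules.

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-patient / per-run child
#' seeds, so partial reruns of any stage are stable. Uses a Lehmer-style
#' multiplicative map modulo the Mersenne prime 2^31 - 1; the result always
#' fits a 32-bit R integer.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647
  x <- (abs(as.numeric(master)) %% m) + 1
  as.integer((x * 48271 + as.numeric(index) * 1299721) %% m)
}

# Evaluate expr with a local RNG state; the caller's .Random.seed is restored.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Round half away from zero (clinical-reporting convention; R's round() is
# half-to-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# x * log(x) with the 0 log 0 = 0 convention, optional base switch.
xlogx <- function(x, base = exp(1)) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos], base = base)
  out
}

# ---- truncated normal ----------------------------------------------------

# Mean and SD of N(mu, sigma) truncated to [lo, hi].
truncnorm_moments <- function(mu, sigma, lo = -Inf, hi = Inf) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  aa <- ifelse(is.finite(a), a * da, 0)
  bb <- ifelse(is.finite(b), b * db, 0)
  v <- sigma^2 * (1 + (aa - bb) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(pmax(v, 0)))
}

# Find (mu, sigma) of the underlying normal so the [lo, hi]-truncated
# distribution has the requested mean and SD. Needed because targets taken
# from reported cohort moments describe the observed (truncated) variable.
# The truncated mean is matched exactly (it is monotone in mu, solved by
# uniroot for each candidate sigma); the SD is matched as closely as the
# family allows (a truncated normal cannot exceed cv ~ 1 against a finite
# lower bound, so heavily skewed targets resolve to the closest member).
truncnorm_calibrate <- function(target_mean, target_sd, lo = -Inf, hi = Inf) {
  mu_for_mean <- function(sigma) {
    f <- function(mu) {
      m <- truncnorm_moments(mu, sigma, lo, hi)[1]
      if (!is.finite(m)) {
        # truncation so extreme that Z underflows: the mean sits at a bound
        m <- if (mu <= target_mean) lo
             else if (is.finite(hi)) hi else mu
      }
      m - target_mean
    }
    lo_mu <- target_mean - 10 * sigma
    hi_mu <- target_mean + 10 * sigma
    if (f(lo_mu) > 0 || f(hi_mu) < 0) return(NA_real_)
    stats::uniroot(f, c(lo_mu, hi_mu), tol = 1e-10)$root
  }
  sd_gap <- function(ls) {
    sigma <- exp(ls)
    mu <- mu_for_mean(sigma)
    if (is.na(mu)) return(1e6)
    s <- truncnorm_moments(mu, sigma, lo, hi)[2]
    if (!is.finite(s)) return(1e6)
    (s - target_sd)^2
  }
  ls <- stats::optimize(sd_gap, log(target_sd) + c(-1, 1.2), tol = 1e-8)$minimum
  sigma <- exp(ls)
  c(mu = mu_for_mean(sigma), sigma = sigma)
}

# Inverse-CDF sampler for the truncated normal (deterministic under set.seed).
rtruncnorm <- function(n, mu, sigma, lo = -Inf, hi = Inf) {
  pa <- stats::pnorm(lo, mu, sigma)
  pb <- stats::pnorm(hi, mu, sigma)
  p <- pa + stats::runif(n) * (pb - pa)
  stats::qnorm(pmin(pmax(p, 1e-12), 1 - 1e-12), mu, sigma)
}

# Moment-matched lognormal parameters for a positive, right-skewed variable
# with the given mean and SD (used for laboratory values, whose reported
# dispersion exceeds what a 0-truncated normal can carry).
lognormal_params <- function(target_mean, target_sd) {
  m <- as.numeric(target_mean); s <- as.numeric(target_sd)
  s2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

# ---- separable periodic Gaussian filtering via FFT -----------------------

# Frequency response of a periodic, normalized Gaussian kernel along one axis.
gauss_kernel_fft <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(rep(1 + 0i, n))
  d <- pmin(0:(n - 1), n - (0:(n - 1)))
  k <- exp(-0.5 * (d / sigma_vox)^2)
  stats::fft(k / sum(k))
}

# Periodic convolution of a 3D array with a separable Gaussian,
# sigma given in voxels per axis.
gauss_smooth3d <- function(x, sigma_vox) {
  stopifnot(length(dim(x)) == 3L)
  if (all(sigma_vox <= 0)) return(x)
  dm <- dim(x)
  k1 <- gauss_kernel_fft(dm[1], sigma_vox[1])
  k2 <- gauss_kernel_fft(dm[2], sigma_vox[2])
  k3 <- gauss_kernel_fft(dm[3], sigma_vox[3])
  Kf <- outer(outer(k1, k2), k3)
  Re(stats::fft(stats::fft(x) * Kf, inverse = TRUE)) / prod(dm)
}

# Stationary Gaussian random field: white noise smoothed by a periodic
# Gaussian of the given correlation length (mm), renormalized to unit SD.
grf3d <- function(grid_shape, spacing_mm, corr_length_mm) {
  z <- array(stats::rnorm(prod(grid_shape)), dim = grid_shape)
  if (corr_length_mm <= 0) return(z)
  s <- gauss_smooth3d(z, corr_length_mm / spacing_mm)
  sd0 <- stats::sd(as.vector(s))
  if (sd0 < .Machine$double.eps) return(array(0, dim = grid_shape))
  s / sd0
}
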
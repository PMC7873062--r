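# Cumulant machinery: the model-independent route to diffusion kurtosis.
# These operations act as oracles for the signal-domain fitters — excess
# kurtosis straight from displacement samples, and the PGSE signal as the
# characteristic function of the displacement propagator.

#' Excess kurtosis from displacement samples
#'
#' Computes central moments mu_1..mu_4, cumulants kappa_1..kappa_4 and the
#' excess kurtosis K = mu4/mu2^2 - 3 (equivalently kappa4/kappa2^2) of a
#' sample of 1-D displacements. Gaussian displacements give K = 0.
#'
#' @param x Numeric vector of displacement samples (>= 4 values).
#' @return A tibble with one row: `mu1`..`mu4` (mu2..mu4 central), `kappa1`..
#'   `kappa4`, `K`, `n`.
#' @export
#' @examples
#' excess_kurtosis_from_samples(c(-1, 1, -1, 1))$K # two-point: K = -2
excess_kurtosis_from_samples <- function(x) {
  if (length(x) < 4) abort("need at least 4 samples",
                           class = "microdki_underdetermined")
  m1 <- mean(x)
  xc <- x - m1
  m2 <- mean(xc^2); m3 <- mean(xc^3); m4 <- mean(xc^4)
  if (m2 <= 0) abort("zero variance: degenerate distribution",
                     class = "microdki_degenerate")
  tibble(mu1 = m1, mu2 = m2, mu3 = m3, mu4 = m4,
         kappa1 = m1, kappa2 = m2, kappa3 = m3,
         kappa4 = m4 - 3 * m2^2,
         K = m4 / m2^2 - 3,
         n = length(x))
}

#' PGSE signal from a displacement propagator (Monte-Carlo)
#'
#' Under the narrow-pulse approximation the normalised diffusion signal is
#' the characteristic function of the ensemble average propagator:
#' \deqn{S(q)/S(0) = E[\exp(2\pi i q R)]}
#' Estimated here by Monte-Carlo over displacement samples drawn by
#' `sampler`. For a symmetric propagator (all odd cumulants zero) the
#' imaginary part vanishes up to Monte-Carlo error; the real part is
#' returned along with the corresponding b-values b = Delta (2 pi q)^2.
#'
#' @param sampler Function `n -> n displacement samples` (mm) over diffusion
#'   time `Delta`.
#' @param q Wave-number grid, 1/mm (q = gamma G delta / 2 pi).
#' @param Delta Diffusion time, s.
#' @param n_samples Monte-Carlo sample count.
#' @param seed RNG seed.
#' @return A tibble: `q`, `b` (s/mm^2), `signal` (real part of S/S0),
#'   `imag_max` attribute-free check column `signal_imag`.
#' @export
signal_from_propagator <- function(sampler, q, Delta, n_samples = 2e5,
                                   seed = 7L) {
  set.seed(as.integer(seed))
  R <- sampler(n_samples)
  ph <- outer(R, 2 * pi * q)          # n_samples x length(q)
  s_re <- colMeans(cos(ph))
  s_im <- colMeans(sin(ph))
  tibble(q = q, b = Delta * (2 * pi * q)^2, signal = s_re,
         signal_imag = s_im)
}

#' Gaussian displacement sampler for a given diffusivity
#'
#' Free diffusion at diffusivity `D` for time `Delta` gives 1-D displacements
#' Normal(0, 2 D Delta).
#' @param D Diffusivity, mm^2/s.
#' @param Delta Diffusion time, s.
#' @return A sampler function for [signal_from_propagator()].
#' @export
gaussian_propagator <- function(D, Delta) {
  force(D); force(Delta)
  function(n) rnorm(n, 0, sqrt(2 * D * Delta))
}

#' Two-component Gaussian mixture displacement sampler
#'
#' Scale mixture of free-diffusion propagators; its excess kurtosis has the
#' closed form 3 Var(D) / E[D]^2 (for a 50/50 mixture of D1, D2:
#' 3 ((D1-D2)/2)^2 / ((D1+D2)/2)^2).
#' @param f Fraction of the first component.
#' @param D1,D2 Component diffusivities, mm^2/s.
#' @param Delta Diffusion time, s.
#' @return A sampler function.
#' @export
bigaussian_propagator <- function(f, D1, D2, Delta) {
  force(f); force(D1); force(D2); force(Delta)
  function(n) {
    pick <- runif(n) < f
    sd <- sqrt(2 * ifelse(pick, D1, D2) * Delta)
    rnorm(n, 0, sd)
  }
}

#' Closed-form excess kurtosis of a diffusivity mixture
#' @param f Component fractions (sum to 1).
#' @param D Component diffusivities.
#' @return 3 Var(D) / E[D]^2.
#' @export
mixture_kurtosis <- function(f, D) {
  stopifnot(abs(sum(f) - 1) < 1e-12)
  m <- sum(f * D)
  v <- sum(f * (D - m)^2)
  3 * v / m^2
}

#' Noiseless bi-exponential signal decay
#'
#' Signal of a two-compartment Gaussian system; used as the secondary
#' generator whose kurtosis the cumulant oracle predicts.
#' @param b b-values, s/mm^2.
#' @param f Fraction of compartment 1.
#' @param D1,D2 Compartment diffusivities, mm^2/s.
#' @param S0 b0 signal.
#' @return Numeric signal vector.
#' @export
biexponential_signal <- function(b, f, D1, D2, S0 = 1) {
  S0 * (f * exp(-b * D1) + (1 - f) * exp(-b * D2))
}
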
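#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
NULL

#' Saturating Hill function of stimulus amplitude
#'
#' The package's standing model for the amplitude tuning of evoked responses:
#' `a^h / (a^h + a50^h)`, which is 0 at amplitude 0 and saturates at 1. The
#' underlying experiments show monotone saturating input/output functions but
#' do not commit to a functional form; the Hill form is adopted for its
#' two-parameter interpretability (half-saturation amplitude and steepness).
#'
#' @param a stimulus amplitude (micrometres), non-negative.
#' @param a50 half-saturation amplitude (micrometres), positive.
#' @param h Hill exponent (steepness), positive.
#' @return values in \[0, 1).
#' @export
hill <- function(a, a50, h) {
  stopifnot(a50 > 0, h > 0)
  out <- rep(0, length(a))
  pos <- a > 0
  out[pos] <- a[pos]^h / (a[pos]^h + a50^h)
  out
}

#' Standard error of the mean
#' @param x numeric vector; NAs dropped.
#' @return `sd(x)/sqrt(n)`.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
# seed = NULL uses the current stream.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}

# Event times of a (near-)equilibrium gamma-renewal process on [0, duration)
# for n_trials independent trials at a common rate. Shape kappa controls count
# dispersion: asymptotic Fano factor of the event count is 1/kappa (exactly
# Poisson for kappa = 1). Equilibrium is reached by burning in 10 mean
# inter-event intervals before time 0, so E[count] = rate * duration.
gamma_renewal_trials <- function(rate, kappa, duration, n_trials) {
  if (n_trials <= 0) return(list())
  if (rate <= 0 || duration <= 0) return(rep(list(numeric(0)), n_trials))
  burn <- 10 / rate
  span <- burn + duration
  mu_n <- span * rate
  m <- ceiling(mu_n + 6 * sqrt(mu_n / kappa) + 20)
  isi <- matrix(stats::rgamma(m * n_trials, shape = kappa, rate = kappa * rate),
                nrow = m)
  tt <- apply(isi, 2, cumsum)
  if (is.null(dim(tt))) tt <- matrix(tt, nrow = m)
  lapply(seq_len(n_trials), function(j) {
    ev <- tt[, j]
    while (ev[length(ev)] < span) {
      extra <- ev[length(ev)] +
        cumsum(stats::rgamma(m, shape = kappa, rate = kappa * rate))
      ev <- c(ev, extra)
    }
    ev[ev >= burn & ev < span] - burn
  })
}

# Stationary AR(1) series standardised to zero mean and unit variance.
# The empirical standardisation makes the factor-model correlations implied
# by the loadings hold exactly within each realisation, not just in
# expectation (a slow latent has few effective degrees of freedom per
# session, so its realised variance would otherwise shift all pairwise
# correlations together).
ar1_series <- function(n, tau_s, dt) {
  phi <- exp(-dt / tau_s)
  z <- numeric(n)
  z[1] <- stats::rnorm(1)
  innov <- stats::rnorm(n - 1, sd = sqrt(1 - phi^2))
  for (i in seq_len(n - 1)) z[i + 1] <- phi * z[i] + innov[i]
  (z - mean(z)) / stats::sd(z)
}

assert_named_over <- function(x, conditions, what) {
  if (!all(conditions %in% names(x))) {
    stop(sprintf("`%s` must be named for every condition (%s)",
                 what, paste(conditions, collapse = ", ")), call. = FALSE)
  }
  x[conditions]
}
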
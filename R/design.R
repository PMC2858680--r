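#' S-phase pulse design
#'
#' Describes how an S phase of length `s_length` hours is covered by
#' consecutive labelling pulses. Pulse `i` covers the half-open interval
#' `((i-1) * pulse_length, i * pulse_length]` hours after release into S, and
#' its midpoint is `Y_i = (i - 0.5) * pulse_length`. The default matches the
#' experimental design of six one-hour BrdU/BrdC pulses spanning a six-hour
#' S phase.
#'
#' @param s_length Length of the S phase in hours.
#' @param n_pulses Number of labelling pulses.
#' @param pulse_length Length of one pulse in hours.
#' @return An object of class `sphase_design`.
#' @examples
#' d <- sphase_design()
#' pulse_midpoints(d)
#' @export
sphase_design <- function(s_length = 6, n_pulses = 6, pulse_length = 1) {
  s_length <- assert_number(s_length, "s_length", lower = 1e-9)
  n_pulses <- assert_count(n_pulses, "n_pulses")
  pulse_length <- assert_number(pulse_length, "pulse_length", lower = 1e-9)
  structure(
    list(s_length = s_length, n_pulses = n_pulses,
         pulse_length = pulse_length),
    class = "sphase_design"
  )
}

#' @export
print.sphase_design <- function(x, ...) {
  cat(sprintf("S-phase design: %g h, %d pulses of %g h\n",
              x$s_length, x$n_pulses, x$pulse_length))
  invisible(x)
}

#' Pulse midpoints of a design
#'
#' @param design An [sphase_design()].
#' @return Numeric vector `Y` of pulse midpoints in hours (0.5, 1.5, ... for
#'   the default design).
#' @export
pulse_midpoints <- function(design) {
  stopifnot(inherits(design, "sphase_design"))
  (seq_len(design$n_pulses) - 0.5) * design$pulse_length
}

pulse_interval <- function(design, i) {
  c((i - 1) * design$pulse_length, i * design$pulse_length)
}

#' Replication-time profile of one chromosome arm
#'
#' A minimal two-parameter model of a preferential replication-time window:
#' the replication time of a telomere on this arm is drawn from a normal
#' distribution with mean `mu` and standard deviation `sigma`, truncated to
#' `[0, s_length]`.
#'
#' @param arm_id Arm label, e.g. `"19q"`, `"4q"`, or `"D-p"` for the pooled
#'   acrocentric group D.
#' @param mu Centre of the replication-time window, hours after S entry.
#' @param sigma Spread of the window in hours (> 0).
#' @param s_length S-phase length in hours (truncation bound).
#' @return An object of class `arm_profile`.
#' @export
arm_profile <- function(arm_id, mu, sigma, s_length = 6) {
  if (!is.character(arm_id) || length(arm_id) != 1L || !nzchar(arm_id))
    stop_input("`arm_id` must be a non-empty string")
  s_length <- assert_number(s_length, "s_length", lower = 1e-9)
  mu <- assert_number(mu, "mu", lower = 0, upper = s_length)
  sigma <- assert_number(sigma, "sigma")
  if (sigma <= 0) stop_input("`sigma` must be > 0")
  structure(
    list(arm_id = arm_id, mu = mu, sigma = sigma, s_length = s_length),
    class = "arm_profile"
  )
}

#' @export
print.arm_profile <- function(x, ...) {
  cat(sprintf("Arm %s: replication-time window mu = %g h, sigma = %g h on [0, %g]\n",
              x$arm_id, x$mu, x$sigma, x$s_length))
  invisible(x)
}

#' Generate a set of arm replication-time profiles
#'
#' Draws `n_arms` profiles with window centres spread uniformly over
#' `[0.5, s_length - 0.5]` hours (so every window midpoint is comfortably
#' inside the pulsed span), sorted from earliest to latest.
#'
#' @param n_arms Number of arms (>= 1).
#' @param design An [sphase_design()].
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param sigma Common window spread in hours.
#' @return List of [arm_profile()] objects.
#' @export
make_arm_profiles <- function(n_arms, design, seed, sigma = 1) {
  n_arms <- assert_count(n_arms, "n_arms")
  stopifnot(inherits(design, "sphase_design"))
  sigma <- assert_number(sigma, "sigma", lower = 1e-12)
  lo <- min(0.5, design$s_length / 2)
  hi <- design$s_length - lo
  mus <- with_seed(seed, sort(stats::runif(n_arms, lo, hi)))
  ids <- sprintf("arm%02d", seq_len(n_arms))
  mapply(arm_profile, arm_id = ids, mu = mus,
         MoreArgs = list(sigma = sigma, s_length = design$s_length),
         SIMPLIFY = FALSE)
}

#' Detection-noise model for detargeting calls
#'
#' Misclassification enters at the level of the scored call, not the
#' underlying replication time: a telomere that did not replicate during the
#' observed pulse is called detargeted with probability `eps_fp`, one that
#' did replicate is called mixed with probability `eps_fn`, and any
#' sister-telomere pair is dropped as unscorable with probability
#' `p_unscorable`.
#'
#' @param eps_fp False-positive call probability, in `[0, 1)`.
#' @param eps_fn False-negative call probability, in `[0, 1)`.
#' @param p_unscorable Probability a pair is unscorable, in `[0, 1]`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(eps_fp = 0, eps_fn = 0, p_unscorable = 0) {
  structure(
    list(eps_fp = assert_prob(eps_fp, "eps_fp", include_one = FALSE),
         eps_fn = assert_prob(eps_fn, "eps_fn", include_one = FALSE),
         p_unscorable = assert_prob(p_unscorable, "p_unscorable")),
    class = "noise_model"
  )
}

# Truncated-normal utilities (support [lo, hi]) -------------------------------

rtruncnorm <- function(n, mu, sigma, lo, hi) {
  plo <- stats::pnorm(lo, mu, sigma)
  phi <- stats::pnorm(hi, mu, sigma)
  u <- stats::runif(n, plo, phi)
  pmin(hi, pmax(lo, stats::qnorm(u, mu, sigma)))
}

# Probability mass of the truncated normal on (a, b]
truncnorm_mass <- function(a, b, mu, sigma, lo, hi) {
  z <- stats::pnorm(hi, mu, sigma) - stats::pnorm(lo, mu, sigma)
  if (z <= 0) stop_input("truncated normal has zero mass on its support")
  num <- stats::pnorm(pmin(b, hi), mu, sigma) -
    stats::pnorm(pmax(a, lo), mu, sigma)
  pmax(0, num) / z
}

#' Exact per-pulse interval masses of an arm profile
#'
#' The probability that a replication time drawn from the arm's
#' truncated-normal window falls inside each pulse interval, renormalized to
#' sum to one over the pulses. This is the analytic counterpart of the
#' observed per-pulse detargeting fractions.
#'
#' @param profile An [arm_profile()].
#' @param design An [sphase_design()].
#' @return Numeric vector of length `design$n_pulses` summing to 1.
#' @export
pulse_masses <- function(profile, design) {
  stopifnot(inherits(profile, "arm_profile"), inherits(design, "sphase_design"))
  m <- vapply(seq_len(design$n_pulses), function(i) {
    iv <- pulse_interval(design, i)
    truncnorm_mass(iv[1], iv[2], profile$mu, profile$sigma,
                   0, profile$s_length)
  }, numeric(1))
  if (sum(m) <= 0)
    stop_input("profile has no mass inside the pulsed span")
  m / sum(m)
}
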
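# Independent oracles used to verify the package's own implementations.
# These deliberately use different code paths (lgamma factorial products,
# brute-force enumeration, quadrature) than the functions they check.

# Exact two-sided Fisher p for a 2x2 table by enumerating the full support,
# computing each table's probability from log-factorials.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2]); n <- sum(tab)
  logp <- function(a) {
    b <- r1 - a; cc <- c1 - a; dd <- r2 - cc
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
      lfactorial(n) - lfactorial(a) - lfactorial(b) - lfactorial(cc) -
      lfactorial(dd)
  }
  a_vals <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- exp(vapply(a_vals, logp, numeric(1)))
  p_obs <- exp(logp(tab[1, 1]))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# Freeman-Halton 2x3 oracle: brute-force triple loop over row-1 cells.
oracle_fisher_2x3 <- function(tab) {
  r1 <- sum(tab[1, ]); n <- sum(tab)
  cs <- colSums(tab)
  logp <- function(a, b) {
    cells <- c(a, b, r1 - a - b, cs[1] - a, cs[2] - b,
               cs[3] - (r1 - a - b))
    sum(lfactorial(c(r1, n - r1, cs))) - lfactorial(n) -
      sum(lfactorial(cells))
  }
  probs <- c()
  for (a in 0:min(r1, cs[1])) for (b in 0:min(r1 - a, cs[2])) {
    if (r1 - a - b <= cs[3]) probs <- c(probs, exp(logp(a, b)))
  }
  p_obs <- exp(logp(tab[1, 1], tab[1, 2]))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# Per-pulse interval masses of a truncated normal by numerical quadrature.
oracle_pulse_masses <- function(mu, sigma, design) {
  dens <- function(t) dnorm(t, mu, sigma)
  z <- integrate(dens, 0, design$s_length, rel.tol = 1e-10)$value
  m <- vapply(seq_len(design$n_pulses), function(i) {
    a <- (i - 1) * design$pulse_length
    b <- i * design$pulse_length
    integrate(dens, max(a, 0), min(b, design$s_length),
              rel.tol = 1e-10)$value / z
  }, numeric(1))
  m / sum(m)
}

default_design <- function() sphase_design(s_length = 6, n_pulses = 6,
                                           pulse_length = 1)

# Counts table for a single arm from raw per-pulse proportions at fixed n.
counts_from_props <- function(p, n_scored = 100, arm_id = "arm") {
  data.frame(arm_id = arm_id, pulse_index = seq_along(p),
             n_scored = n_scored, n_detargeted = round(p * n_scored),
             stringsAsFactors = FALSE)
}
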
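#' Normalize per-pulse detargeting proportions
#'
#' For one arm, the raw per-pulse proportion is
#' `p_i = n_detargeted_i / n_scored_i` (the average fraction of detargeted
#' telomeres over the metaphases captured during pulse `i`, computed from
#' counts pooled across metaphases). Because the pulses tile the S phase,
#' the sum of these proportions estimates 1 but is not exactly 1; the
#' returned fractions are adjusted so they sum to 100%:
#' `f_i = p_i / sum(p)`.
#'
#' @param counts Data.frame with columns `pulse_index`, `n_scored`,
#'   `n_detargeted` for a single arm (one row per pulse).
#' @return Numeric vector `f` over pulses, summing to 1.
#' @examples
#' counts <- data.frame(pulse_index = 1:6, n_scored = 50,
#'                      n_detargeted = c(5, 10, 10, 15, 5, 5))
#' normalize_fractions(counts)
#' @export
normalize_fractions <- function(counts) {
  assert_columns(counts, c("pulse_index", "n_scored", "n_detargeted"),
                 "`counts`")
  counts <- counts[order(counts$pulse_index), , drop = FALSE]
  if (anyDuplicated(counts$pulse_index))
    stop_input("`counts` must have one row per pulse for a single arm")
  if (any(counts$n_detargeted < 0) ||
      any(counts$n_detargeted > counts$n_scored))
    stop_input("counts must satisfy 0 <= n_detargeted <= n_scored")
  p <- ifelse(counts$n_scored > 0,
              counts$n_detargeted / counts$n_scored, 0)
  s <- sum(p)
  if (s <= 0)
    stop_input("no replication events observed for arm",
               if (!is.null(counts$arm_id)) paste0(" ", counts$arm_id[1]))
  p / s
}

#' Mean replication timing (mrt)
#'
#' The f-weighted mean of the pulse midpoints:
#' `mrt = sum_i f_i * Y_i` with `Y_i = (i - 0.5) * pulse_length` hours —
#' the average hour of S phase at which telomeres of the arm are seen
#' replicating. By construction `Y_1 <= mrt <= Y_P`.
#'
#' @param f Normalized per-pulse fraction vector (sums to 1), as returned by
#'   [normalize_fractions()].
#' @param design An [sphase_design()] with `n_pulses == length(f)`.
#' @return mrt in hours.
#' @examples
#' compute_mrt(rep(1 / 6, 6), sphase_design())  # 3.0 by symmetry
#' @export
compute_mrt <- function(f, design) {
  stopifnot(inherits(design, "sphase_design"))
  if (!is.numeric(f) || length(f) != design$n_pulses)
    stop_input("`f` must be a numeric vector of length n_pulses")
  if (any(f < 0) || abs(sum(f) - 1) > 1e-8)
    stop_input("`f` must be a normalized fraction vector summing to 1")
  sum(f * pulse_midpoints(design))
}

# Contiguous-thirds bin index for each pulse (early/mid/late).
phase_bins <- function(n_pulses) ceiling(3 * seq_len(n_pulses) / n_pulses)

#' Early/mid/late binned fractions with exact confidence intervals
#'
#' Groups the normalized per-pulse fractions into early S (pulses 1+2),
#' mid S (pulses 3+4) and late S (pulses 5+6) for the canonical 6-pulse
#' design (contiguous thirds for other designs). Each bin's confidence
#' interval is an exact Clopper-Pearson interval at level `1 - alpha` on the
#' pooled detargeted-count proportion of the bin, mapped onto the normalized
#' scale by the bin's normalization factor.
#'
#' @param counts Per-pulse counts for one arm, as in
#'   [normalize_fractions()].
#' @param design An [sphase_design()].
#' @param alpha Significance level of the intervals (default 0.05).
#' @return Data.frame with one row per bin: `bin` (`early`, `mid`, `late`),
#'   `fraction` (normalized, sums to 1 over bins), `lo`/`hi` (CI on the
#'   normalized scale), `raw_p`/`raw_lo`/`raw_hi` (pooled proportion and its
#'   Clopper-Pearson interval on the raw scale), `n_scored`, `n_detargeted`.
#' @export
bin_phases <- function(counts, design, alpha = 0.05) {
  stopifnot(inherits(design, "sphase_design"))
  alpha <- assert_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  counts <- counts[order(counts$pulse_index), , drop = FALSE]
  f <- normalize_fractions(counts)
  p_raw <- ifelse(counts$n_scored > 0,
                  counts$n_detargeted / counts$n_scored, 0)
  s <- sum(p_raw)
  bins <- phase_bins(design$n_pulses)
  lab <- c("early", "mid", "late")
  out <- lapply(1:3, function(b) {
    sel <- bins == b
    k <- sum(counts$n_detargeted[sel])
    n <- sum(counts$n_scored[sel])
    fb <- sum(f[sel])
    if (n > 0) {
      ci <- stats::binom.test(k, n, conf.level = 1 - alpha)$conf.int
      p_hat <- k / n
    } else {
      ci <- c(0, 1)
      p_hat <- 0
    }
    # map the raw-scale interval onto the normalized scale: for a balanced
    # design f_bin = B * p_hat / s with B pulses in the bin, so the factor is
    # f_bin / p_hat (B / s when the bin is empty)
    scale <- if (p_hat > 0) fb / p_hat else sum(sel) / s
    data.frame(bin = lab[b], fraction = fb,
               lo = max(0, min(1, ci[1] * scale)),
               hi = max(0, min(1, ci[2] * scale)),
               raw_p = p_hat, raw_lo = ci[1], raw_hi = ci[2],
               n_scored = n, n_detargeted = k,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Expected mrt implied by an arm profile
#'
#' The mrt that the pulse design would measure on an infinite sample from
#' the arm's replication-time window: the weighted mean of pulse midpoints
#' under the profile's exact per-pulse interval masses. Serves as the
#' analytic reference for parameter-recovery checks.
#'
#' @param profile An [arm_profile()].
#' @param design An [sphase_design()].
#' @return mrt in hours.
#' @export
expected_mrt <- function(profile, design) {
  f <- pulse_masses(profile, design)
  sum(f * pulse_midpoints(design))
}

#' Per-arm timing results from pulse counts
#'
#' Runs [normalize_fractions()], [compute_mrt()] and [bin_phases()] for every
#' arm of a counts table and assembles the flat per-arm summary.
#'
#' @param counts Counts table (`arm_id`, `pulse_index`, `n_scored`,
#'   `n_detargeted`), e.g. from [aggregate_counts()].
#' @param design An [sphase_design()].
#' @param alpha CI level parameter passed to [bin_phases()].
#' @return Data.frame with one row per arm: `arm_id`, `f1..fP`, `mrt`,
#'   `early`, `mid`, `late`, the per-bin CI bounds `*_lo`/`*_hi` (normalized
#'   scale) and `n_scored_total`, sorted by `mrt`.
#' @export
telomere_timing <- function(counts, design, alpha = 0.05) {
  assert_columns(counts, c("arm_id", "pulse_index", "n_scored",
                           "n_detargeted"), "`counts`")
  arms <- unique(counts$arm_id)
  rows <- lapply(arms, function(a) {
    ca <- counts[counts$arm_id == a, , drop = FALSE]
    f <- normalize_fractions(ca)
    mrt <- compute_mrt(f, design)
    b <- bin_phases(ca, design, alpha)
    row <- data.frame(arm_id = a, stringsAsFactors = FALSE)
    for (i in seq_along(f)) row[[paste0("f", i)]] <- f[i]
    row$mrt <- mrt
    row$early <- b$fraction[1]; row$mid <- b$fraction[2]
    row$late <- b$fraction[3]
    row$early_lo <- b$lo[1]; row$early_hi <- b$hi[1]
    row$mid_lo <- b$lo[2]; row$mid_hi <- b$hi[2]
    row$late_lo <- b$lo[3]; row$late_hi <- b$hi[3]
    row$n_scored_total <- sum(ca$n_scored)
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mrt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
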
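#' Simulate ReDFISH detargeting events
#'
#' Emulates the observational structure of a pulse-labelling experiment: for
#' every pulse, `n_metaphases_per_pulse` metaphases are scored; every
#' metaphase exposes each arm with `copies_per_arm` homolog copies; each
#' telomere copy replicates at a time drawn from its arm's truncated-normal
#' window. The telomere is truly detargeted in that metaphase iff its
#' replication time falls inside the metaphase's pulse interval (each
#' telomere replicates within a single pulse). The observed call is then
#' corrupted according to the [noise_model()].
#'
#' @param profiles Non-empty list of [arm_profile()] objects.
#' @param design An [sphase_design()].
#' @param n_metaphases_per_pulse Number of metaphases scored per pulse.
#' @param copies_per_arm Homolog copies per arm (2 for a diploid pair,
#'   tagged `A`/`B`).
#' @param noise A [noise_model()].
#' @param seed Integer seed; output is reproducible bit for bit.
#' @param cell_line Label recorded in the `cell_line` column.
#' @return A data.frame with one row per (metaphase, arm, homolog copy):
#'   columns `cell_line`, `metaphase_id`, `pulse_index`, `arm_id`, `homolog`,
#'   `true_time` (hours), `true_status` and `status` (the observed call,
#'   one of `"detargeted"`, `"mixed"`, `"unscorable"`). The `true_*` columns
#'   are generator ground truth, available for validation.
#' @export
simulate_redfish_events <- function(profiles, design, n_metaphases_per_pulse,
                                    copies_per_arm = 2,
                                    noise = noise_model(), seed,
                                    cell_line = "SIM") {
  if (!is.list(profiles) || !length(profiles))
    stop_input("`profiles` must be a non-empty list of arm profiles")
  lapply(profiles, function(p) {
    if (!inherits(p, "arm_profile"))
      stop_input("every element of `profiles` must be an `arm_profile`")
    if (p$mu < 0 || p$mu > design$s_length ||
        abs(p$s_length - design$s_length) > 1e-9)
      stop_input("profile for arm ", p$arm_id, " lies outside the design ",
                 "S phase [0, s_length]")
  })
  stopifnot(inherits(design, "sphase_design"), inherits(noise, "noise_model"))
  n_metaphases_per_pulse <- assert_count(n_metaphases_per_pulse,
                                         "n_metaphases_per_pulse")
  copies_per_arm <- assert_count(copies_per_arm, "copies_per_arm")

  arms <- vapply(profiles, `[[`, character(1), "arm_id")
  mus <- vapply(profiles, `[[`, numeric(1), "mu")
  sigmas <- vapply(profiles, `[[`, numeric(1), "sigma")

  grid <- expand.grid(copy = seq_len(copies_per_arm),
                      arm = seq_along(profiles),
                      metaphase = seq_len(n_metaphases_per_pulse),
                      pulse = seq_len(design$n_pulses))
  n <- nrow(grid)

  with_seed(seed, {
    t_rep <- rtruncnorm(n, mus[grid$arm], sigmas[grid$arm],
                        0, design$s_length)
    lo <- (grid$pulse - 1) * design$pulse_length
    hi <- grid$pulse * design$pulse_length
    true_det <- t_rep > lo & t_rep <= hi
    u_call <- stats::runif(n)
    u_drop <- stats::runif(n)
  })
  obs_det <- ifelse(true_det, u_call >= noise$eps_fn, u_call < noise$eps_fp)
  status <- ifelse(obs_det, "detargeted", "mixed")
  status[u_drop < noise$p_unscorable] <- "unscorable"

  homolog <- if (copies_per_arm <= 26) LETTERS[grid$copy] else
    sprintf("H%02d", grid$copy)

  data.frame(
    cell_line = cell_line,
    metaphase_id = sprintf("p%d_m%03d", grid$pulse, grid$metaphase),
    pulse_index = grid$pulse,
    arm_id = arms[grid$arm],
    homolog = homolog,
    true_time = t_rep,
    true_status = ifelse(true_det, "detargeted", "mixed"),
    status = status,
    stringsAsFactors = FALSE
  )
}

#' Simulate two-channel sister-telomere intensities
#'
#' Attaches red (C-rich probe) and green (G-rich probe) intensities per
#' sister chromatid to a simulated event table. Detargeted pairs receive
#' reciprocal single-channel-dominant sisters (one red-dominant, one
#' green-dominant, with the orientation randomized); mixed pairs receive both
#' channels on both sisters at equal expected strength. Multiplicative noise
#' on the dominant channels and additive leakage into the off channels both
#' scale as `1/snr`, so `snr = Inf` gives noiseless channel fractions of
#' exactly \{1, 0\} (detargeted) and 0.5 (mixed). Unscorable events receive
#' uniformly dim signals below any sensible `min_total` threshold.
#'
#' @param events Event table from [simulate_redfish_events()].
#' @param snr Signal-to-noise ratio (> 0, may be `Inf`).
#' @param seed Integer seed.
#' @param base_intensity Intensity scale of a full single-channel signal.
#' @param dim_factor Scale of unscorable-event signals relative to
#'   `base_intensity`.
#' @return The event table with columns `red_s1`, `green_s1`, `red_s2`,
#'   `green_s2` appended.
#' @export
simulate_intensities <- function(events, snr, seed, base_intensity = 1000,
                                 dim_factor = 0.02) {
  assert_columns(events, "status", "`events`")
  snr <- assert_number(snr, "snr", lower = 0, allow_inf = TRUE)
  if (snr <= 0) stop_input("`snr` must be > 0")
  base_intensity <- assert_number(base_intensity, "base_intensity",
                                  lower = 1e-9)
  n <- nrow(events)
  sd_noise <- 1 / snr  # 0 when snr = Inf

  red1 <- green1 <- red2 <- green2 <- numeric(n)
  i_d <- which(events$status == "detargeted")
  i_m <- which(events$status == "mixed")
  i_u <- setdiff(seq_len(n), c(i_d, i_m))

  with_seed(seed, {
    if (length(i_d)) {
      nd <- length(i_d)
      dom1 <- base_intensity * exp(stats::rnorm(nd) * sd_noise)
      dom2 <- base_intensity * exp(stats::rnorm(nd) * sd_noise)
      off1 <- base_intensity * abs(stats::rnorm(nd)) * sd_noise
      off2 <- base_intensity * abs(stats::rnorm(nd)) * sd_noise
      flip <- stats::runif(nd) < 0.5  # which sister carries the C-rich tag
      red1[i_d] <- ifelse(flip, dom1, off1)
      green1[i_d] <- ifelse(flip, off1, dom1)
      red2[i_d] <- ifelse(flip, off2, dom2)
      green2[i_d] <- ifelse(flip, dom2, off2)
    }
    if (length(i_m)) {
      nm <- length(i_m)
      half <- base_intensity / 2
      red1[i_m] <- half * exp(stats::rnorm(nm) * sd_noise)
      green1[i_m] <- half * exp(stats::rnorm(nm) * sd_noise)
      red2[i_m] <- half * exp(stats::rnorm(nm) * sd_noise)
      green2[i_m] <- half * exp(stats::rnorm(nm) * sd_noise)
    }
    if (length(i_u)) {
      nu <- length(i_u)
      dim_scale <- dim_factor * base_intensity
      red1[i_u] <- dim_scale * stats::runif(nu)
      green1[i_u] <- dim_scale * stats::runif(nu)
      red2[i_u] <- dim_scale * stats::runif(nu)
      green2[i_u] <- dim_scale * stats::runif(nu)
    }
  })

  events$red_s1 <- red1
  events$green_s1 <- green1
  events$red_s2 <- red2
  events$green_s2 <- green2
  events
}

#' Simulate Q-FISH telomere intensities
#'
#' Generates positive fluorescence intensities with a lognormal
#' metaphase-to-metaphase and telomere-to-telomere variation whose
#' coefficient of variation is `cv`, grouped into metaphases. When `arms` is
#' supplied, every metaphase carries each arm twice (homologs `A` and `B`),
#' and `allele_scale` can impose allele-specific mean intensities (named
#' `"arm:homolog"`).
#'
#' @param n_telomeres Total number of telomere records to generate.
#' @param cv Coefficient of variation of the intensities (>= 0).
#' @param seed Integer seed.
#' @param arms Optional character vector of arm labels.
#' @param telomeres_per_metaphase Number of telomeres per metaphase when
#'   `arms` is not supplied.
#' @param mean_intensity Expected intensity in arbitrary fluorescence units.
#' @param allele_scale Optional named numeric vector of per-allele intensity
#'   multipliers, names of the form `"7p:A"`.
#' @return A data.frame with columns `metaphase_id`, `arm_id`, `homolog`,
#'   `intensity`.
#' @export
simulate_qfish <- function(n_telomeres, cv, seed, arms = NULL,
                           telomeres_per_metaphase = 46,
                           mean_intensity = 1000, allele_scale = NULL) {
  n_telomeres <- assert_count(n_telomeres, "n_telomeres")
  cv <- assert_number(cv, "cv", lower = 0)
  mean_intensity <- assert_number(mean_intensity, "mean_intensity",
                                  lower = 1e-9)

  if (!is.null(arms)) {
    if (!is.character(arms) || !length(arms))
      stop_input("`arms` must be a non-empty character vector")
    arm_id <- rep(arms, each = 2)
    homolog <- rep(c("A", "B"), times = length(arms))
  } else {
    tpm <- assert_count(telomeres_per_metaphase, "telomeres_per_metaphase",
                        min = 2)
    arm_id <- sprintf("t%02d", seq_len(tpm))
    homolog <- rep("A", tpm)
  }
  tpm <- length(arm_id)
  n_met <- ceiling(n_telomeres / tpm)
  idx <- seq_len(n_telomeres)
  met <- (idx - 1) %/% tpm + 1
  pos <- (idx - 1) %% tpm + 1

  sdlog <- sqrt(log1p(cv^2))
  meanlog <- log(mean_intensity) - sdlog^2 / 2
  intensity <- with_seed(seed,
    stats::rlnorm(n_telomeres, meanlog = meanlog, sdlog = sdlog))

  if (!is.null(allele_scale)) {
    key <- paste(arm_id[pos], homolog[pos], sep = ":")
    mult <- allele_scale[key]
    mult[is.na(mult)] <- 1
    intensity <- intensity * as.numeric(mult)
  }

  data.frame(
    metaphase_id = sprintf("m%04d", met),
    arm_id = arm_id[pos],
    homolog = homolog[pos],
    intensity = intensity,
    stringsAsFactors = FALSE
  )
}
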
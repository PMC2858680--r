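#' Default pipeline configuration
#'
#' The full resolved parameter set of [run_pipeline()], mirroring the study
#' conditions the generator emulates: a 6 h S phase covered by six 1 h
#' pulses, 40 scorable metaphases per pulse, two homolog copies per arm,
#' 1 h-wide truncated-normal replication-time windows, 50 localization spots
#' per arm and lognormal Q-FISH intensities with CV 0.45.
#'
#' @return A nested named list of parameters; see the fields themselves for
#'   units. Override entries before passing to [run_pipeline()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    cell_line = "SIM",
    design = list(s_length = 6, n_pulses = 6, pulse_length = 1),
    arms = list(n_arms = 8, sigma = 1),
    noise = list(eps_fp = 0.01, eps_fn = 0.02, p_unscorable = 0.15),
    redfish = list(metaphases_per_pulse = 40, copies_per_arm = 2),
    intensity = list(snr = 10, base = 1000),
    scoring = list(theta_hi = 0.8, min_total = 200, pool = NULL),
    stats = list(alpha = 0.05, k = NULL, scheme = "bins3"),
    geometry = list(semiaxes = c(5, 4, 1.5)),
    nuclei = list(spots_per_arm = 50, ratio_base = 0.2, ratio_slope = 0.6,
                  concentration = 10),
    qfish = list(cv = 0.45, telomeres_per_allele = 30)
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Missing keys fall back to [default_config()]; unknown keys are rejected.
#'
#' @param path Path to a YAML config file.
#' @return The resolved configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user %||% list(), prefix = NULL)
}

merge_config <- function(base, user, prefix = NULL) {
  if (!is.list(user))
    stop_input("config section ", paste(prefix, collapse = "."),
               " must be a mapping")
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop_input("unknown config key(s): ",
               paste(paste(c(prefix, unknown[1]), collapse = "."),
                     collapse = ", "))
  for (key in names(user)) {
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], user[[key]],
                                  prefix = c(prefix, key))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> score -> timing -> compare -> localize -> qfish under
#' one configuration and seed: simulates detargeting events and sister
#' intensities for a set of arms, re-classifies the intensities, aggregates
#' pulse counts, computes per-arm timing results, performs all pairwise
#' Fisher comparisons at the Bonferroni-corrected threshold, simulates and
#' summarizes 3D nuclear localization with a radial law coupled to each
#' arm's replication-time window, correlates timing with localization, and
#' runs the Q-FISH relative-length analysis (whose correlation with timing
#' is expected null). All outputs are written as TSV plus a machine-readable
#' JSON summary when `out_dir` is given; runs are byte-identical under the
#' same config and seed.
#'
#' @param config Configuration list as from [default_config()] or
#'   [read_config()].
#' @param out_dir Optional output directory (created if needed).
#' @param seed Master seed; defaults to `config$seed`.
#' @return Invisibly, a list with elements `events`, `counts`, `timing`,
#'   `comparisons`, `localization`, `timing_localization`, `qfish_alleles`,
#'   `length_timing`, `config`, `seed`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         seed = config$seed) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_input("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  }

  design <- stage("design", do.call(sphase_design, config$design))
  profiles <- stage("simulate",
    make_arm_profiles(config$arms$n_arms, design,
                      seed = derive_seed(seed, 1),
                      sigma = config$arms$sigma))
  noise <- do.call(noise_model, config$noise)

  events <- stage("simulate",
    simulate_redfish_events(profiles, design,
      n_metaphases_per_pulse = config$redfish$metaphases_per_pulse,
      copies_per_arm = config$redfish$copies_per_arm,
      noise = noise, seed = derive_seed(seed, 2),
      cell_line = config$cell_line))
  events <- stage("simulate",
    simulate_intensities(events, snr = config$intensity$snr,
                         seed = derive_seed(seed, 3),
                         base_intensity = config$intensity$base))

  scored <- stage("score",
    classify_events(events, theta_hi = config$scoring$theta_hi,
                    min_total = config$scoring$min_total))
  pool <- config$scoring$pool
  if (!is.null(pool)) pool <- unlist(pool)
  counts <- stage("score", aggregate_counts(scored, design, pool = pool))

  timing <- stage("timing",
    telomere_timing(counts, design, alpha = config$stats$alpha))

  arms <- timing$arm_id
  pairs <- if (length(arms) >= 2) utils::combn(arms, 2) else
    matrix(character(0), 2, 0)
  k <- config$stats$k %||% max(1L, ncol(pairs))
  comparisons <- stage("compare", {
    rows <- lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      res <- compare_arm_timing(
        counts[counts$arm_id == a, ], counts[counts$arm_id == b, ],
        design, scheme = config$stats$scheme,
        alpha_family = config$stats$alpha, k = k)
      data.frame(arm_a = a, arm_b = b, test = res$test, p = res$p,
                 k = res$k, threshold = res$threshold,
                 significant = res$significant, stringsAsFactors = FALSE)
    })
    if (length(rows)) do.call(rbind, rows) else
      data.frame(arm_a = character(0), arm_b = character(0),
                 test = character(0), p = numeric(0), k = integer(0),
                 threshold = numeric(0), significant = logical(0))
  })

  geometry <- stage("localize",
    nucleus_ellipsoid(unlist(config$geometry$semiaxes)))
  localization <- stage("localize", {
    rows <- lapply(seq_along(profiles), function(i) {
      pr <- profiles[[i]]
      m <- config$nuclei$ratio_base +
        config$nuclei$ratio_slope * pr$mu / design$s_length
      m <- min(max(m, 0.02), 0.98)
      law <- radial_law_mean(m, config$nuclei$concentration)
      spots <- simulate_nuclei(law, n_nuclei = config$nuclei$spots_per_arm,
                               geometry = geometry, spots_per_nucleus = 1,
                               seed = derive_seed(seed, 100 + i),
                               arm_id = pr$arm_id)
      s <- summarize_localization(volume_ratio(spots, geometry))
      data.frame(arm_id = pr$arm_id, mean_ratio = s$mean, sem = s$sem,
                 n = s$n, zone_inner = s$zones[1], zone_middle = s$zones[2],
                 zone_peripheral = s$zones[3], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  loc_idx <- match(timing$arm_id, localization$arm_id)
  timing_localization <- stage("localize",
    correlate_timing_localization(timing$mrt,
                                  localization$mean_ratio[loc_idx],
                                  alpha_family = config$stats$alpha, k = 1))

  qfish_tab <- stage("qfish", {
    arm_ids <- vapply(profiles, `[[`, character(1), "arm_id")
    n_tel <- config$qfish$telomeres_per_allele * 2 * length(arm_ids)
    simulate_qfish(n_tel, cv = config$qfish$cv,
                   seed = derive_seed(seed, 5), arms = arm_ids)
  })
  qfish_alleles <- stage("qfish", allele_length_summary(qfish_tab))
  arm_mean_len <- tapply(qfish_alleles$mean_length, qfish_alleles$arm_id,
                         mean)
  length_timing <- stage("qfish", tryCatch(
    correlate_length_timing(as.numeric(arm_mean_len[timing$arm_id]),
                            timing$mrt, alpha_family = config$stats$alpha,
                            k = 1),
    error = function(e) {
      warning("length-timing correlation unavailable: ",
              conditionMessage(e), call. = FALSE)
      NULL
    }))

  result <- list(events = events, counts = counts, timing = timing,
                 comparisons = comparisons, localization = localization,
                 timing_localization = timing_localization,
                 qfish_alleles = qfish_alleles,
                 length_timing = length_timing,
                 config = config, seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(events, file.path(out_dir, "events.tsv"))
    write_table(counts, file.path(out_dir, "counts.tsv"))
    write_table(timing, file.path(out_dir, "timing.tsv"))
    write_table(comparisons, file.path(out_dir, "comparisons.tsv"))
    write_table(localization, file.path(out_dir, "localization.tsv"))
    write_table(qfish_alleles, file.path(out_dir, "qfish_alleles.tsv"))
    summary <- list(
      seed = seed,
      config = config,
      n_arms = nrow(timing),
      timing = timing,
      comparisons = comparisons,
      timing_localization = list(
        rho = timing_localization$rho, p = timing_localization$p),
      length_timing = if (!is.null(length_timing)) list(
        rho = length_timing$rho, p = length_timing$p))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}
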
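#' Classify a sister-telomere signal pair
#'
#' Turns the two-channel intensities of the two sister chromatids of one
#' telomere into a detargeting call. For each sister the red (C-rich probe)
#' fraction is `rho = red / (red + green)`; the sister is tagged
#' `C-rich-only` if `rho >= theta_hi`, `G-rich-only` if `rho <= 1 - theta_hi`
#' and `both` otherwise. The pair is `detargeted` iff the sisters carry
#' reciprocal single tags (one C-rich-only, one G-rich-only — the signature
#' of replication during the pulse), `mixed` iff both sisters are tagged
#' `both`, and `unscorable` otherwise or whenever either sister's total
#' intensity falls below `min_total`. Non-reciprocal single-colour pairs are
#' unscorable, not detargeted: strand destruction produces complementary
#' sisters, so a same-colour pair cannot be a genuine detargeting event.
#'
#' @param sister1,sister2 Numeric length-2 vectors `(red, green)`.
#' @param theta_hi Dominance threshold on the red fraction, in (0.5, 1).
#' @param min_total Minimum summed intensity per sister for a scorable pair.
#' @return An object of class `signal_call`: list with `status`
#'   (`"detargeted"`, `"mixed"` or `"unscorable"`) and `strand_tag`
#'   (per-sister tags).
#' @examples
#' classify_pair(c(900, 30), c(25, 870))            # detargeted
#' classify_pair(c(450, 430), c(440, 460))          # mixed
#' classify_pair(c(900, 30), c(880, 40))            # unscorable
#' @export
classify_pair <- function(sister1, sister2, theta_hi = 0.8, min_total = 200) {
  if (length(sister1) != 2L || length(sister2) != 2L ||
      !is.numeric(sister1) || !is.numeric(sister2))
    stop_input("`sister1` and `sister2` must be numeric (red, green) pairs")
  if (any(c(sister1, sister2) < 0))
    stop_input("intensities must be non-negative")
  res <- classify_vec(sister1[1], sister1[2], sister2[1], sister2[2],
                      theta_hi, min_total)
  structure(
    list(status = res$status,
         strand_tag = c(sister1 = res$tag1, sister2 = res$tag2)),
    class = "signal_call"
  )
}

#' @export
print.signal_call <- function(x, ...) {
  cat(sprintf("signal call: %s (sister tags: %s / %s)\n", x$status,
              x$strand_tag[1], x$strand_tag[2]))
  invisible(x)
}

# Vectorized classification core.
classify_vec <- function(red1, green1, red2, green2, theta_hi, min_total) {
  theta_hi <- assert_number(theta_hi, "theta_hi")
  if (theta_hi <= 0.5 || theta_hi >= 1)
    stop_input("`theta_hi` must lie strictly between 0.5 and 1")
  min_total <- assert_number(min_total, "min_total", lower = 0)
  tot1 <- red1 + green1
  tot2 <- red2 + green2
  rho1 <- ifelse(tot1 > 0, red1 / tot1, NA_real_)
  rho2 <- ifelse(tot2 > 0, red2 / tot2, NA_real_)
  tag_of <- function(rho) {
    out <- rep("both", length(rho))
    out[!is.na(rho) & rho >= theta_hi] <- "C-rich-only"
    out[!is.na(rho) & rho <= 1 - theta_hi] <- "G-rich-only"
    out[is.na(rho)] <- NA_character_
    out
  }
  tag1 <- tag_of(rho1)
  tag2 <- tag_of(rho2)
  status <- rep("unscorable", length(tot1))
  recip <- (tag1 == "C-rich-only" & tag2 == "G-rich-only") |
    (tag1 == "G-rich-only" & tag2 == "C-rich-only")
  both <- tag1 == "both" & tag2 == "both"
  status[!is.na(recip) & recip] <- "detargeted"
  status[!is.na(both) & both] <- "mixed"
  weak <- is.na(rho1) | is.na(rho2) | tot1 < min_total | tot2 < min_total
  status[weak] <- "unscorable"
  list(status = status, tag1 = tag1, tag2 = tag2)
}

#' Classify every event of an intensity table
#'
#' Applies [classify_pair()] row-wise to a table carrying `red_s1`,
#' `green_s1`, `red_s2`, `green_s2` columns and appends the call as a
#' `status` column (any existing `status` column is replaced; the ground
#' truth from the generator lives in `true_status`).
#'
#' @param events Event table with per-sister intensity columns.
#' @param theta_hi,min_total As in [classify_pair()].
#' @return The table with a `status` column of calls.
#' @export
classify_events <- function(events, theta_hi = 0.8, min_total = 200) {
  assert_columns(events, c("red_s1", "green_s1", "red_s2", "green_s2"),
                 "`events`")
  ints <- c(events$red_s1, events$green_s1, events$red_s2, events$green_s2)
  if (any(ints < 0)) stop_input("intensities must be non-negative")
  res <- classify_vec(events$red_s1, events$green_s1,
                      events$red_s2, events$green_s2, theta_hi, min_total)
  events$status <- res$status
  events
}

#' Acrocentric pooling map
#'
#' The conventional grouping of acrocentric short arms: group D pools the
#' p arms of chromosomes 13, 14 and 15; group G pools those of 21 and 22.
#'
#' @return Named character vector mapping arm labels to pooled group labels,
#'   suitable for the `pool` argument of [aggregate_counts()].
#' @export
acrocentric_pooling <- function() {
  c("13p" = "D-p", "14p" = "D-p", "15p" = "D-p",
    "21p" = "G-p", "22p" = "G-p")
}

#' Aggregate calls into per-(arm, pulse) counts
#'
#' The central sufficient statistic of the pipeline: for every arm and pulse,
#' the number of scorable telomeres (`n_scored`) and the number called
#' detargeted (`n_detargeted`). Unscorable events are excluded from both the
#' numerator and the denominator. An optional pooling map (arm label ->
#' group label) merges counts additively before aggregation, e.g.
#' [acrocentric_pooling()].
#'
#' @param events Event table carrying `arm_id`, `pulse_index`, `status`.
#' @param design An [sphase_design()]; pulse indices must lie in
#'   `1..n_pulses`.
#' @param pool Optional named character vector mapping arm labels to pooled
#'   labels; unmapped arms keep their own label.
#' @return A data.frame `arm_id`, `pulse_index`, `n_scored`, `n_detargeted`
#'   covering the complete arm-by-pulse grid (zero rows included), sorted by
#'   arm then pulse.
#' @export
aggregate_counts <- function(events, design, pool = NULL) {
  assert_columns(events, c("arm_id", "pulse_index", "status"), "`events`")
  stopifnot(inherits(design, "sphase_design"))
  p <- events$pulse_index
  if (length(p) && (any(is.na(p)) || any(p != round(p)) || any(p < 1) ||
                    any(p > design$n_pulses)))
    stop_input("`pulse_index` values must be integers in 1..",
               design$n_pulses)
  arm <- events$arm_id
  if (!is.null(pool)) {
    if (is.null(names(pool)) || !is.character(pool))
      stop_input("`pool` must be a named character vector (arm -> group)")
    hit <- arm %in% names(pool)
    arm[hit] <- unname(pool[arm[hit]])
  }
  keep <- events$status != "unscorable"
  arm_levels <- sort(unique(arm))
  if (!length(arm_levels)) {
    return(data.frame(arm_id = character(0), pulse_index = integer(0),
                      n_scored = integer(0), n_detargeted = integer(0),
                      stringsAsFactors = FALSE))
  }
  fa <- factor(arm[keep], levels = arm_levels)
  fp <- factor(events$pulse_index[keep], levels = seq_len(design$n_pulses))
  scored <- table(fa, fp)
  det <- table(fa[events$status[keep] == "detargeted"],
               fp[events$status[keep] == "detargeted"])
  out <- expand.grid(pulse_index = seq_len(design$n_pulses),
                     arm_id = arm_levels, stringsAsFactors = FALSE)
  out <- out[, c("arm_id", "pulse_index")]
  out$n_scored <- as.integer(t(scored))[seq_len(nrow(out))]
  out$n_detargeted <- as.integer(t(det))[seq_len(nrow(out))]
  rownames(out) <- NULL
  out
}
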
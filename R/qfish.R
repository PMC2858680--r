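#' Relative telomere length of one telomere
#'
#' Q-FISH fluorescence intensity divided by the mean intensity over all
#' telomeres of the same metaphase — the standard proxy for telomere length
#' relative to the mean telomere length of the cell. The ratio is invariant
#' under a uniform gain change of the imaging.
#'
#' @param intensity Intensity of the telomere of interest (>= 0).
#' @param metaphase_intensities All telomere intensities of that metaphase
#'   (length >= 2, positive mean).
#' @return The relative length (unitless).
#' @export
relative_length <- function(intensity, metaphase_intensities) {
  intensity <- assert_number(intensity, "intensity", lower = 0)
  if (!is.numeric(metaphase_intensities) ||
      length(metaphase_intensities) < 2)
    stop_input("`metaphase_intensities` must hold >= 2 intensities")
  if (any(metaphase_intensities < 0))
    stop_input("intensities must be non-negative")
  m <- mean(metaphase_intensities)
  if (m <= 0) stop_input("metaphase mean intensity must be positive")
  intensity / m
}

#' Relative lengths for a whole Q-FISH table
#'
#' Adds a `relative_length` column: each intensity divided by its metaphase
#' mean, so the mean relative length within every metaphase is exactly 1.
#'
#' @param records Data.frame with `metaphase_id`, `intensity` (and typically
#'   `arm_id`, `homolog`).
#' @return The table with `relative_length` appended.
#' @export
qfish_relative <- function(records) {
  assert_columns(records, c("metaphase_id", "intensity"), "`records`")
  if (any(records$intensity < 0))
    stop_input("intensities must be non-negative")
  sizes <- table(records$metaphase_id)
  if (any(sizes < 2))
    stop_input("every metaphase needs >= 2 telomere intensities")
  means <- stats::ave(records$intensity, records$metaphase_id, FUN = mean)
  if (any(means <= 0))
    stop_input("metaphase mean intensity must be positive")
  records$relative_length <- records$intensity / means
  records
}

#' Per-allele relative-length summary
#'
#' Mean and SEM of the relative telomere length for every (arm, homolog)
#' allele, the per-allele quantity plotted against per-allele mean
#' replication timing.
#'
#' @param records Q-FISH table with `arm_id`, `homolog` and
#'   `relative_length` (computed by [qfish_relative()] if absent, which
#'   requires `metaphase_id` and `intensity`).
#' @return Data.frame `arm_id`, `homolog`, `mean_length`, `sem`, `n`;
#'   single-record alleles get SEM 0 with a warning.
#' @export
allele_length_summary <- function(records) {
  assert_columns(records, c("arm_id", "homolog"), "`records`")
  if (is.null(records$relative_length)) records <- qfish_relative(records)
  key <- interaction(records$arm_id, records$homolog, drop = TRUE,
                     sep = ":")
  groups <- split(records$relative_length, key)
  rows <- lapply(names(groups), function(g) {
    v <- groups[[g]]
    n <- length(v)
    sem <- if (n > 1) stats::sd(v) / sqrt(n) else {
      warning("allele ", g, " has a single record: SEM set to 0",
              call. = FALSE)
      0
    }
    parts <- strsplit(g, ":", fixed = TRUE)[[1]]
    data.frame(arm_id = parts[1], homolog = parts[2],
               mean_length = mean(v), sem = sem, n = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$arm_id, out$homolog), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlate relative telomere length with replication timing
#'
#' The pipeline's null-result check: under the biology assumed by the
#' generator, telomere length carries no information about replication
#' timing, so this correlation should be indistinguishable from zero.
#'
#' @param mean_length Per-allele (or per-arm) mean relative lengths.
#' @param mrt Matching mean replication timings (hours), length >= 3.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param alpha_family,k Family-wise level and family size.
#' @return A `comparison_result` with `rho` and `p`.
#' @export
correlate_length_timing <- function(mean_length, mrt,
                                    method = c("spearman", "pearson"),
                                    alpha_family = 0.05, k = 1) {
  method <- match.arg(method)
  if (length(mean_length) != length(mrt))
    stop_input("`mean_length` and `mrt` must have the same length")
  if (length(mrt) < 3) stop_input("need at least 3 alleles")
  if (method == "spearman")
    return(spearman_test(mean_length, mrt, alpha_family, k))
  ct <- stats::cor.test(mean_length, mrt, method = "pearson")
  new_comparison_result("pearson", list(x = mean_length, y = mrt),
                        p = ct$p.value, rho = unname(ct$estimate),
                        alpha_family = alpha_family, k = k)
}
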
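#' Exact test of independence for 2x2 and 2x3 count tables
#'
#' Computes the exact two-sided p-value by full enumeration of all tables
#' with the observed margins, summing the (multivariate) hypergeometric
#' probabilities of every table whose probability does not exceed that of
#' the observed table (the standard "probability <= observed" two-sided
#' rule, applied with a relative tolerance of 1e-12 so exact ties are
#' included). 2x3 tables use the Freeman-Halton extension.
#'
#' @param table A 2x2 or 2x3 (or 3x2) matrix of non-negative integer counts
#'   with at least one positive margin.
#' @return The exact p-value.
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))  # 34/70
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (!is.numeric(tab) || any(is.na(tab)))
    stop_input("`table` must be a numeric count matrix")
  if (any(tab < 0) || any(abs(tab - round(tab)) > 1e-9))
    stop_input("`table` must contain non-negative integer counts")
  tab <- round(tab)
  if (nrow(tab) == 3L && ncol(tab) == 2L) tab <- t(tab)
  if (nrow(tab) != 2L || !(ncol(tab) %in% c(2L, 3L)))
    stop_input("`table` must be 2x2 or 2x3")
  if (sum(tab) == 0)
    stop_input("`table` must have at least one positive margin")
  if (ncol(tab) == 2L) fisher_exact_2x2(tab) else fisher_exact_2x3(tab)
}

rel_tol_le <- function(p, p_obs) p <= p_obs * (1 + 1e-12)

fisher_exact_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_min <- max(0, r1 + c1 - n)
  a_max <- min(r1, c1)
  a_vals <- a_min:a_max
  probs <- stats::dhyper(a_vals, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  min(1, sum(probs[rel_tol_le(probs, p_obs)]))
}

# log multivariate-hypergeometric probability of row1 = (a, b, r1 - a - b)
log_mvhyper_2x3 <- function(a, b, r1, c1, c2, c3, n) {
  lchoose(c1, a) + lchoose(c2, b) + lchoose(c3, r1 - a - b) -
    lchoose(n, r1)
}

fisher_exact_2x3 <- function(tab) {
  r1 <- sum(tab[1, ]); n <- sum(tab)
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2]); c3 <- sum(tab[, 3])
  grid <- expand.grid(a = 0:min(r1, c1), b = 0:min(r1, c2))
  grid <- grid[r1 - grid$a - grid$b >= 0 & r1 - grid$a - grid$b <= c3, ]
  lp <- log_mvhyper_2x3(grid$a, grid$b, r1, c1, c2, c3, n)
  lp_obs <- log_mvhyper_2x3(tab[1, 1], tab[1, 2], r1, c1, c2, c3, n)
  probs <- exp(lp)
  min(1, sum(probs[rel_tol_le(probs, exp(lp_obs))]))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha_family Family-wise significance level, in (0, 1).
#' @param k Number of comparisons actually carried out (>= 1).
#' @return The per-comparison threshold `alpha_family / k`; e.g. 0.05 over
#'   20 comparisons gives 0.0025.
#' @export
bonferroni_threshold <- function(alpha_family, k) {
  alpha_family <- assert_number(alpha_family, "alpha_family",
                                lower = 1e-12, upper = 1 - 1e-12)
  k <- assert_count(k, "k")
  alpha_family / k
}

new_comparison_result <- function(test, inputs, p, rho = NA_real_,
                                  alpha_family = 0.05, k = 1) {
  threshold <- bonferroni_threshold(alpha_family, k)
  structure(
    list(test = test, inputs = inputs, p = p, rho = rho,
         alpha_family = alpha_family, k = k, threshold = threshold,
         significant = p < threshold),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: p = %.4g%s; threshold %.4g (alpha %.3g / k = %d) -> %s\n",
              x$test, x$p,
              if (!is.na(x$rho)) sprintf(", rho = %.3f", x$rho) else "",
              x$threshold, x$alpha_family, x$k,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Compare the replication timing of two arms
#'
#' Builds the contingency table of detargeted counts per S-phase bin for the
#' two arms — a 2x3 early/mid/late table under `scheme = "bins3"`, or the
#' collapsed 2x2 late-versus-rest table under `scheme = "late_vs_rest"` —
#' and applies [fisher_exact()]. The significance flag uses the
#' Bonferroni-corrected threshold `alpha_family / k`.
#'
#' @param counts_a,counts_b Per-pulse counts for the two arms (columns
#'   `pulse_index`, `n_scored`, `n_detargeted`), sharing the pulse design.
#' @param design An [sphase_design()].
#' @param scheme `"bins3"` (default) or `"late_vs_rest"`.
#' @param alpha_family Family-wise level.
#' @param k Number of comparisons in the family.
#' @return A `comparison_result` with the table, p-value, threshold and
#'   significance flag.
#' @export
compare_arm_timing <- function(counts_a, counts_b, design,
                               scheme = c("bins3", "late_vs_rest"),
                               alpha_family = 0.05, k = 1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(design, "sphase_design"))
  bin_det <- function(counts) {
    assert_columns(counts, c("pulse_index", "n_scored", "n_detargeted"),
                   "`counts`")
    if (!nrow(counts) || sum(counts$n_scored) == 0)
      stop_input("empty counts: no scored telomeres for one of the arms")
    counts <- counts[order(counts$pulse_index), , drop = FALSE]
    bins <- phase_bins(design$n_pulses)
    vapply(1:3, function(b)
      sum(counts$n_detargeted[bins[counts$pulse_index] == b]), numeric(1))
  }
  tab <- rbind(a = bin_det(counts_a), b = bin_det(counts_b))
  colnames(tab) <- c("early", "mid", "late")
  if (scheme == "late_vs_rest")
    tab <- cbind(rest = tab[, 1] + tab[, 2], late = tab[, 3])
  p <- fisher_exact(tab)
  test <- if (ncol(tab) == 3) "fisher_2x3" else "fisher_2x2"
  new_comparison_result(test, tab, p, alpha_family = alpha_family, k = k)
}

#' Spearman rank correlation test
#'
#' Rank correlation with average ranks for ties. The p-value is exact for
#' `n <= 8` (full enumeration of the permutation null of the rank vectors,
#' two-sided as `P(|rho_perm| >= |rho_obs|)`); for larger `n` the usual
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom is used.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param alpha_family,k Family-wise level and family size for the
#'   Bonferroni-corrected significance flag.
#' @return A `comparison_result` with `rho` and `p`.
#' @export
spearman_test <- function(x, y, alpha_family = 0.05, k = 1) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop_input("`x` and `y` must be numeric vectors of equal length")
  n <- length(x)
  if (n < 3) stop_input("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop_input("missing values are not supported")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop_input("undefined correlation: constant vector")
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- permutations(n)
    a <- rx - mean(rx)
    b <- matrix(ry[perms], nrow = nrow(perms))
    b <- b - mean(ry)
    num <- b %*% a
    rho_perm <- as.numeric(num) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  new_comparison_result("spearman", list(x = x, y = y), p = p, rho = rho,
                        alpha_family = alpha_family, k = k)
}

# all permutations of 1..n as an (n! x n) matrix; n <= 8 in practice
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
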
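#' Radial placement law for nuclear FISH spots
#'
#' A probability law on the volume-ratio scale `[0, 1]` (0 = nuclear centre,
#' 1 = boundary). `family = "beta"` gives a Beta(`shape1`, `shape2`) law —
#' Beta(1, 1) is the uniform null under which spots fill the nucleus
#' uniformly; increasing the mean shifts spots toward the periphery.
#' `family = "point"` is the degenerate law concentrated at `location`.
#'
#' @param family `"beta"` or `"point"`.
#' @param shape1,shape2 Beta parameters (> 0), used when `family = "beta"`.
#' @param location Point-mass location in `[0, 1]`, used when
#'   `family = "point"`.
#' @return An object of class `radial_law`.
#' @export
radial_law <- function(family = c("beta", "point"), shape1 = 1, shape2 = 1,
                       location = 1) {
  family <- match.arg(family)
  if (family == "beta") {
    shape1 <- assert_number(shape1, "shape1", lower = 1e-12)
    shape2 <- assert_number(shape2, "shape2", lower = 1e-12)
  } else {
    location <- assert_prob(location, "location")
  }
  structure(
    list(family = family, shape1 = shape1, shape2 = shape2,
         location = location),
    class = "radial_law"
  )
}

sample_radial_law <- function(law, n) {
  switch(law$family,
    beta = stats::rbeta(n, law$shape1, law$shape2),
    point = rep(law$location, n)
  )
}

#' Beta radial law with a given mean position
#'
#' Convenience constructor: a Beta law on the volume-ratio scale with mean
#' `mean_ratio` and concentration `shape1 + shape2 = concentration`.
#'
#' @param mean_ratio Mean volume ratio in (0, 1).
#' @param concentration Total concentration (> 0); larger is tighter.
#' @return A [radial_law()].
#' @export
radial_law_mean <- function(mean_ratio, concentration = 10) {
  mean_ratio <- assert_number(mean_ratio, "mean_ratio",
                              lower = 1e-6, upper = 1 - 1e-6)
  concentration <- assert_number(concentration, "concentration",
                                 lower = 1e-9)
  radial_law("beta", shape1 = mean_ratio * concentration,
             shape2 = (1 - mean_ratio) * concentration)
}

#' Simulate 3D FISH spots in nuclei
#'
#' Places `spots_per_nucleus` spots in each of `n_nuclei` nuclei such that
#' the spots' volume ratios (see [volume_ratio()]) are distributed according
#' to `law`. A volume ratio `u` corresponds to the concentrically shrunk
#' boundary surface at scaled radius `u^(1/3)`; the spot direction is drawn
#' uniformly on the sphere, so a uniform law reproduces uniform placement
#' over the nuclear volume.
#'
#' @param law A [radial_law()].
#' @param n_nuclei Number of nuclei (>= 1).
#' @param geometry An ellipsoid [nucleus_ellipsoid()] geometry.
#' @param spots_per_nucleus Spots per nucleus (>= 1).
#' @param seed Integer seed.
#' @param arm_id Arm label recorded with every spot.
#' @return A data.frame with columns `nucleus_id`, `arm_id`, `x_um`, `y_um`,
#'   `z_um`; one row per spot.
#' @export
simulate_nuclei <- function(law, n_nuclei, geometry, spots_per_nucleus = 1,
                            seed, arm_id = "arm") {
  if (!inherits(law, "radial_law"))
    stop_input("`law` must be a `radial_law` object")
  if (!inherits(geometry, "nucleus_geometry") || geometry$mode != "ellipsoid")
    stop_input("`geometry` must be an ellipsoid nucleus geometry")
  n_nuclei <- assert_count(n_nuclei, "n_nuclei")
  spots_per_nucleus <- assert_count(spots_per_nucleus, "spots_per_nucleus")

  n <- n_nuclei * spots_per_nucleus
  with_seed(seed, {
    u <- sample_radial_law(law, n)
    v <- matrix(stats::rnorm(3 * n), ncol = 3)
  })
  s <- u^(1 / 3)  # scaled radius such that enclosed volume fraction is u
  dir <- v / sqrt(rowSums(v^2))
  ax <- geometry$semiaxes
  xyz <- sweep(dir, 1, s, `*`)
  xyz <- sweep(xyz, 2, ax, `*`)
  xyz <- sweep(xyz, 2, geometry$center, `+`)

  data.frame(
    nucleus_id = rep(sprintf("n%04d", seq_len(n_nuclei)),
                     each = spots_per_nucleus),
    arm_id = arm_id,
    x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
    stringsAsFactors = FALSE
  )
}
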
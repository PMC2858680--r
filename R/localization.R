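#' Ellipsoid nucleus geometry
#'
#' Models the lamin-B-delimited nuclear boundary as an ellipsoid with the
#' given centre and semi-axes (µm). The volume ratio of a point is then
#' analytic: `s^3` with `s` the normalized ellipsoidal radius.
#'
#' @param semiaxes Numeric length-3 vector of semi-axes `(a, b, c)` in µm.
#' @param center Numeric length-3 centre `(x, y, z)` in µm.
#' @return An object of class `nucleus_geometry` with `mode = "ellipsoid"`.
#' @export
nucleus_ellipsoid <- function(semiaxes, center = c(0, 0, 0)) {
  if (!is.numeric(semiaxes) || length(semiaxes) != 3L || any(semiaxes <= 0))
    stop_input("`semiaxes` must be 3 positive numbers (µm)")
  if (!is.numeric(center) || length(center) != 3L || anyNA(center))
    stop_input("`center` must be a numeric length-3 vector (µm)")
  structure(
    list(mode = "ellipsoid", semiaxes = as.numeric(semiaxes),
         center = as.numeric(center)),
    class = "nucleus_geometry"
  )
}

#' Voxel-mask nucleus geometry
#'
#' Models the nuclear boundary as a binary voxel mask, with axis order
#' `z, y, x` and anisotropic voxel size (default 0.1 x 0.1 x 0.48 µm as in
#' confocal stacks with 0.48 µm optical sections). Distances are computed in
#' physical µm via an exact anisotropic Euclidean distance transform, so the
#' coarse z step does not distort radial positions. Construction precomputes
#' the depth map (distance of every mask voxel to the nearest outside
#' voxel); the volume ratio of a spot is the fraction of nuclear volume
#' lying strictly deeper than the spot's depth.
#'
#' @param mask Logical (or 0/1) 3D array, dimensions ordered `z, y, x`;
#'   `TRUE` inside the nucleus. Must be non-empty; assumed connected.
#' @param voxel_size Numeric length-3 voxel size `(x, y, z)` in µm.
#' @return An object of class `nucleus_geometry` with `mode = "mask"`.
#' @export
nucleus_mask <- function(mask, voxel_size = c(0.1, 0.1, 0.48)) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop_input("`mask` must be a 3D array ordered (z, y, x)")
  if (!is.numeric(voxel_size) || length(voxel_size) != 3L ||
      any(voxel_size <= 0))
    stop_input("`voxel_size` must be 3 positive numbers (x, y, z) in µm")
  m <- array(as.logical(mask), dim(mask))
  if (anyNA(m)) stop_input("`mask` must not contain NA")
  if (!any(m)) stop_input("`mask` is empty")
  vx <- as.numeric(voxel_size)
  # spacing per array axis: dim1 = z, dim2 = y, dim3 = x
  spacing <- c(vx[3], vx[2], vx[1])

  depth2 <- edt3d(!m, spacing)           # squared distance to outside
  bg2 <- edt3d(m, spacing)               # squared distance to the mask
  depth <- sqrt(depth2)
  depth[!m] <- NA_real_
  dsort <- sort(depth[m])
  n_mask <- length(dsort)

  g <- structure(
    list(mode = "mask", mask = m, voxel_size = vx, spacing = spacing,
         depth = depth, depth_sorted = dsort, n_mask = n_mask,
         bg_dist = sqrt(bg2)),
    class = "nucleus_geometry"
  )
  g$lamin_ref <- mask_lamin_reference(g)
  g
}

#' @export
print.nucleus_geometry <- function(x, ...) {
  if (x$mode == "ellipsoid") {
    cat(sprintf("ellipsoid nucleus: semi-axes (%g, %g, %g) µm, centre (%g, %g, %g)\n",
                x$semiaxes[1], x$semiaxes[2], x$semiaxes[3],
                x$center[1], x$center[2], x$center[3]))
  } else {
    d <- dim(x$mask)
    cat(sprintf("voxel-mask nucleus: %d x %d x %d voxels (z,y,x), voxel %g x %g x %g µm, %d voxels inside\n",
                d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
                x$voxel_size[3], x$n_mask))
  }
  invisible(x)
}

# --- exact anisotropic squared Euclidean distance transform ------------------
# Separable lower-envelope-of-parabolas algorithm, one pass per axis, with
# physical spacing per axis. `zero_at` marks voxels at distance 0.

edt3d <- function(zero_at, spacing) {
  d <- dim(zero_at)
  # pad with a distance-0 layer so the array border behaves as outside space
  f <- array(Inf, d + 2L)
  f[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <-
    ifelse(zero_at, 0, Inf)
  f[1, , ] <- 0; f[d[1] + 2, , ] <- 0
  f[, 1, ] <- 0; f[, d[2] + 2, ] <- 0
  f[, , 1] <- 0; f[, , d[3] + 2] <- 0
  for (ax in 1:3) f <- edt_pass(f, ax, spacing[ax])
  f[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

edt_pass <- function(f, axis, h) {
  d <- dim(f)
  perm <- c(axis, setdiff(1:3, axis))
  g <- aperm(f, perm)
  dp <- dim(g)
  m <- matrix(g, nrow = dp[1])
  for (j in seq_len(ncol(m))) m[, j] <- edt1d(m[, j], h)
  g <- array(m, dp)
  aperm(g, order(perm))
}

# 1D squared distance transform over parabolas rooted at finite f values.
edt1d <- function(f, h) {
  n <- length(f)
  fin <- which(is.finite(f))
  nf <- length(fin)
  if (nf == 0L) return(f)
  if (nf == n && all(f == 0)) return(f)
  x <- fin * h
  v <- integer(nf)   # indices (into fin) of envelope parabolas
  z <- numeric(nf + 1L)
  k <- 1L
  v[1] <- 1L
  z[1] <- -Inf
  z[2] <- Inf
  if (nf > 1L) {
    for (q in 2L:nf) {
      fq <- f[fin[q]]; xq <- x[q]
      repeat {
        i <- v[k]
        s <- ((fq + xq^2) - (f[fin[i]] + x[i]^2)) / (2 * (xq - x[i]))
        if (s <= z[k] && k > 1L) k <- k - 1L else break
      }
      k <- k + 1L
      v[k] <- q
      z[k] <- s
      z[k + 1L] <- Inf
    }
  }
  out <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    xq <- q * h
    while (z[k + 1L] < xq) k <- k + 1L
    i <- v[k]
    out[q] <- (xq - x[i])^2 + f[fin[i]]
  }
  out
}

# ---------------------------------------------------------------------------

as_xyz <- function(spots) {
  if (is.numeric(spots) && is.null(dim(spots)) && length(spots) == 3L)
    return(matrix(spots, 1, 3))
  if (is.matrix(spots) && ncol(spots) == 3L) return(spots)
  if (is.data.frame(spots)) {
    assert_columns(spots, c("x_um", "y_um", "z_um"), "`spots`")
    return(cbind(spots$x_um, spots$y_um, spots$z_um))
  }
  stop_input("`spots` must be an (x, y, z) vector, an n x 3 matrix, or a ",
             "data.frame with x_um, y_um, z_um columns")
}

#' Volume ratio of FISH spots
#'
#' The fraction of total nuclear volume enclosed by the boundary surface
#' shrunk concentrically until it passes through the spot: 0 at the nuclear
#' centre, 1 at the boundary (the lamin B reference), so larger values are
#' more peripheral. For an ellipsoid the ratio is `s^3` with
#' `s = sqrt((dx/a)^2 + (dy/b)^2 + (dz/c)^2)`; under uniform spot placement
#' it is uniform on `[0, 1]`, which makes the three equal-volume zones
#' equal-probability under the null. For a voxel mask it is the volume
#' fraction of mask voxels lying strictly deeper (larger distance-to-outside
#' in µm) than the spot's voxel.
#'
#' @param spots Spot coordinates in µm: a length-3 vector, an `n x 3`
#'   matrix, or a data.frame with `x_um`, `y_um`, `z_um`.
#' @param geometry A [nucleus_ellipsoid()] or [nucleus_mask()] geometry.
#' @param tol Tolerance for spots marginally outside the boundary (clipped
#'   to ratio 1); beyond it an error is raised. Defaults to `1e-6` of the
#'   normalized radius for ellipsoids and one voxel diagonal (µm) for masks.
#' @return Numeric vector of ratios in `[0, 1]`.
#' @examples
#' g <- nucleus_ellipsoid(c(4, 4, 4))
#' volume_ratio(c(2, 0, 0), g)  # half radius of a sphere: 0.125
#' @export
volume_ratio <- function(spots, geometry, tol = NULL) {
  stopifnot(inherits(geometry, "nucleus_geometry"))
  xyz <- as_xyz(spots)
  if (geometry$mode == "ellipsoid") {
    tol <- tol %||% 1e-6
    rel <- sweep(xyz, 2, geometry$center)
    rel <- sweep(rel, 2, geometry$semiaxes, `/`)
    s <- sqrt(rowSums(rel^2))
    if (any(s > 1 + tol))
      stop_input(sum(s > 1 + tol), " spot(s) lie outside the nuclear ",
                 "boundary by more than the tolerance")
    return(pmin(s, 1)^3)
  }
  # mask mode
  tol <- tol %||% sqrt(sum(geometry$voxel_size^2))
  d <- dim(geometry$mask)
  vx <- geometry$voxel_size
  iz <- pmin(d[1], pmax(1, floor(xyz[, 3] / vx[3]) + 1))
  iy <- pmin(d[2], pmax(1, floor(xyz[, 2] / vx[2]) + 1))
  ix <- pmin(d[3], pmax(1, floor(xyz[, 1] / vx[1]) + 1))
  inside_box <- xyz[, 1] >= 0 & xyz[, 1] <= d[3] * vx[1] &
    xyz[, 2] >= 0 & xyz[, 2] <= d[2] * vx[2] &
    xyz[, 3] >= 0 & xyz[, 3] <= d[1] * vx[3]
  lin <- cbind(iz, iy, ix)
  in_mask <- geometry$mask[lin] & inside_box
  out <- numeric(nrow(xyz))
  if (any(in_mask))
    out[in_mask] <- mask_ratio_of_depth(geometry$depth[lin[in_mask, ,
                                                           drop = FALSE]],
                                        geometry)
  if (any(!in_mask)) {
    bgd <- geometry$bg_dist[lin[!in_mask, , drop = FALSE]]
    bgd[!inside_box[!in_mask]] <- Inf
    if (any(bgd > tol))
      stop_input(sum(bgd > tol), " spot(s) lie outside the nuclear ",
                 "boundary by more than the tolerance")
    out[!in_mask] <- 1
  }
  out
}

mask_ratio_of_depth <- function(depth, geometry) {
  n_le <- findInterval(depth, geometry$depth_sorted)
  (geometry$n_mask - n_le) / geometry$n_mask
}

#' Assign equal-volume zones
#'
#' Partitions the nucleus into three concentric shells of equal volume and
#' returns the zone of each volume ratio: zone 1 (inner) for ratios below
#' 1/3, zone 2 for `[1/3, 2/3)`, zone 3 (peripheral) otherwise.
#'
#' @param ratio Numeric vector of volume ratios in `[0, 1]`.
#' @return Integer vector of zone indices in `1..3`.
#' @export
assign_zone <- function(ratio) {
  if (!is.numeric(ratio) || anyNA(ratio) || any(ratio < 0) || any(ratio > 1))
    stop_input("`ratio` must be numeric in [0, 1]")
  1L + (ratio >= 1 / 3) + (ratio >= 2 / 3)
}

#' Summarize the nuclear localization of one arm
#'
#' @param ratios Numeric vector of volume ratios for one arm's spots, or a
#'   data.frame with a `volume_ratio` column.
#' @return A list of class `localization_result`: `n`, `mean`, `sem`
#'   (`sd/sqrt(n)`; 0 with a warning when `n = 1`) and `zones`, the spot
#'   counts over the three equal-volume zones (summing to `n`).
#' @export
summarize_localization <- function(ratios) {
  if (is.data.frame(ratios)) {
    assert_columns(ratios, "volume_ratio", "`ratios`")
    ratios <- ratios$volume_ratio
  }
  if (!is.numeric(ratios) || !length(ratios))
    stop_input("need at least one spot")
  if (anyNA(ratios) || any(ratios < 0) || any(ratios > 1))
    stop_input("`ratios` must lie in [0, 1]")
  n <- length(ratios)
  sem <- if (n > 1) stats::sd(ratios) / sqrt(n) else {
    warning("single spot: SEM set to 0", call. = FALSE)
    0
  }
  zones <- tabulate(assign_zone(ratios), nbins = 3L)
  names(zones) <- c("inner", "middle", "peripheral")
  structure(
    list(n = n, mean = mean(ratios), sem = sem, zones = zones),
    class = "localization_result"
  )
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf("localization: n = %d spots, mean volume ratio %.3f +/- %.3f (SEM)\n",
              x$n, x$mean, x$sem))
  cat(sprintf("  zones (inner/middle/peripheral): %d / %d / %d\n",
              x$zones[1], x$zones[2], x$zones[3]))
  invisible(x)
}

#' Peripheral (lamin B) reference value
#'
#' The volume ratio of the nuclear boundary itself. For an ellipsoid it is
#' exactly 1 by construction. For a voxel mask the boundary is the set of
#' mask voxels 6-adjacent to outside voxels, and the reference is the mean
#' volume ratio over those voxels — slightly below 1 because of
#' voxelization, approaching 1 as the mask resolution grows.
#'
#' @param geometry A [nucleus_ellipsoid()] or [nucleus_mask()].
#' @return The reference ratio in `(0, 1]`.
#' @export
lamin_reference <- function(geometry) {
  stopifnot(inherits(geometry, "nucleus_geometry"))
  if (geometry$mode == "ellipsoid") return(1.0)
  geometry$lamin_ref
}

mask_lamin_reference <- function(geometry) {
  m <- geometry$mask
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  nb <- array(TRUE, d)
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  for (s in shifts) {
    nb <- nb & pad[(2:(d[1] + 1)) + s[1], (2:(d[2] + 1)) + s[2],
                   (2:(d[3] + 1)) + s[3]]
  }
  boundary <- m & !nb
  mean(mask_ratio_of_depth(geometry$depth[boundary], geometry))
}

#' Correlate replication timing with nuclear localization
#'
#' Rank (default) or Pearson correlation between per-arm mean replication
#' timings and per-arm mean volume ratios; a positive correlation means
#' later-replicating telomeres sit closer to the nuclear periphery.
#'
#' @param mrt Numeric vector of per-arm mrt values (hours).
#' @param mean_ratio Numeric vector of per-arm mean volume ratios, same
#'   length and order as `mrt`; length >= 3.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param alpha_family,k Family-wise level and family size for the
#'   significance flag.
#' @return A `comparison_result` with `rho` and `p`.
#' @export
correlate_timing_localization <- function(mrt, mean_ratio,
                                          method = c("spearman", "pearson"),
                                          alpha_family = 0.05, k = 1) {
  method <- match.arg(method)
  if (length(mrt) != length(mean_ratio))
    stop_input("`mrt` and `mean_ratio` must have the same length")
  if (length(mrt) < 3)
    stop_input("need at least 3 arms")
  if (method == "spearman")
    return(spearman_test(mrt, mean_ratio, alpha_family, k))
  ct <- stats::cor.test(mrt, mean_ratio, method = "pearson")
  new_comparison_result("pearson", list(x = mrt, y = mean_ratio),
                        p = ct$p.value, rho = unname(ct$estimate),
                        alpha_family = alpha_family, k = k)
}
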
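## Channel-radius profiling along the membrane normal by sphere
## maximization: at each slice z the largest sphere centered in the slice
## plane that touches no atom's van der Waals surface is found by
## Monte-Carlo annealing of the in-plane center, seeded from the previous
## slice (the classic HOLE-style construction).

#' Pore radius at a point
#'
#' Radius of the largest sphere centered at `center` that touches no
#' selected atom: the minimum over atoms of (minimum-image distance -
#' vdW radius).  Negative when the center lies inside an atom.  Distances
#' are full 3-D (not slice-restricted), matching the sphere-based
#' definition.
#'
#' @param center numeric 3-vector (nm).
#' @param atoms atom selection (non-empty).
#' @param fr a `traj_frame`.
#' @param top a `topology`.
#' @return radius in nm (may be negative).
#' @export
pore_radius_at <- function(center, atoms, fr, top) {
  if (length(atoms) == 0) stop("empty atom selection")
  d <- .mi_dist(center, fr$coords[atoms, , drop = FALSE], fr$box)
  min(d - top$atoms$vdw[atoms])
}

#' Channel specification for radius profiling
#'
#' @param seed_point 3-vector (nm): starting center for the first slice.
#' @param z_min,z_max axial extent (nm).
#' @param dz slice spacing (nm), default 0.025.
#' @param max_center_step largest accepted in-plane move (nm).
#' @param axis channel axis; only the membrane normal (+/- z) is supported.
#' @param r_max sentinel cap on the reported radius (nm).
#' @return list of class `"channel_spec"`.
#' @export
channel_spec <- function(seed_point, z_min, z_max, dz = 0.025,
                         max_center_step = 0.1, axis = c(0, 0, 1),
                         r_max = 1.5) {
  if (dz <= 0) stop("dz must be positive")
  if (z_min >= z_max) stop("z_min must be below z_max")
  axis <- axis / sqrt(sum(axis^2))
  if (max(abs(axis - c(0, 0, 1))) > 1e-9 &&
      max(abs(axis + c(0, 0, 1))) > 1e-9)
    stop("only a z-aligned channel axis is supported")
  structure(list(seed_point = seed_point, z_min = z_min, z_max = z_max,
                 dz = dz, max_center_step = max_center_step, axis = axis,
                 r_max = r_max),
            class = "channel_spec")
}

#' Compute a pore-radius profile along z
#'
#' For each slice from `z_min` to `z_max` in steps of `dz`, maximizes
#' [pore_radius_at()] over the in-plane center by simulated annealing:
#' `n_trials` Gaussian proposals per slice, step size halved every
#' `cooling` trials, uphill-only acceptance, moves with in-plane
#' displacement beyond `max_center_step` rejected.  Each slice starts from
#' the previous slice's optimum (first slice: the seed point).  A slice is
#' flagged blocked when the best radius is negative; radii are capped at
#' `spec$r_max`.
#'
#' @param fr a `traj_frame`.
#' @param top a `topology`.
#' @param protein atom selection defining the channel wall.
#' @param spec a [channel_spec()].
#' @param n_trials Monte-Carlo proposals per slice.
#' @param initial_step initial proposal s.d. (nm).
#' @param cooling trials between step halvings.
#' @param seed RNG seed for the annealer.
#' @return object of class `"radius_profile"`: data.frame with columns
#'   `z`, `radius`, `center_x`, `center_y`, `blocked`.
#' @export
compute_radius_profile <- function(fr, top, protein, spec,
                                   n_trials = 2000, initial_step = 0.05,
                                   cooling = 500, seed = 1) {
  stopifnot(inherits(spec, "channel_spec"))
  if (length(protein) == 0) stop("empty atom selection")
  set.seed(seed)
  zs <- seq(spec$z_min, spec$z_max, by = spec$dz)
  coords <- fr$coords[protein, , drop = FALSE]
  vdw <- top$atoms$vdw[protein]
  box <- fr$box
  radius_at <- function(c2, z) {
    d <- .mi_dist(c(c2, z), coords, box)
    min(min(d - vdw), spec$r_max)
  }
  out <- data.frame(z = zs, radius = NA_real_, center_x = NA_real_,
                    center_y = NA_real_, blocked = FALSE)
  cen <- spec$seed_point[1:2]
  for (i in seq_along(zs)) {
    z <- zs[i]
    best <- radius_at(cen, z)
    step <- initial_step
    for (t in seq_len(n_trials)) {
      if (t %% cooling == 0) step <- step / 2
      mv <- stats::rnorm(2, sd = step)
      if (sqrt(sum(mv^2)) > spec$max_center_step) next
      cand <- cen + mv
      r <- radius_at(cand, z)
      if (r > best) {
        best <- r
        cen <- cand
      }
    }
    out$radius[i] <- best
    out$center_x[i] <- cen[1]
    out$center_y[i] <- cen[2]
    out$blocked[i] <- best < 0
  }
  structure(out, class = c("radius_profile", "data.frame"))
}

#' Average radius profiles slice-wise
#'
#' Profiles must share a z grid.  Blocked slices are excluded from the
#' mean; the number of contributing profiles per slice is reported.  The
#' standard deviation is the population value (divisor n).
#'
#' @param profiles list of `radius_profile` objects.
#' @return data.frame with columns `z`, `mean_radius`, `sd_radius`,
#'   `n_unblocked`.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  z <- profiles[[1]]$z
  for (p in profiles)
    if (length(p$z) != length(z) || max(abs(p$z - z)) > 1e-9)
      stop("profiles do not share a z grid")
  R <- sapply(profiles, function(p) ifelse(p$blocked, NA_real_, p$radius))
  R <- matrix(R, nrow = length(z))
  n_ok <- rowSums(!is.na(R))
  mean_r <- rowMeans(R, na.rm = TRUE)
  mean_r[n_ok == 0] <- NA_real_
  sd_r <- apply(R, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) return(NA_real_)
    sqrt(mean((r - mean(r))^2))
  })
  data.frame(z = z, mean_radius = mean_r, sd_radius = sd_r,
             n_unblocked = n_ok)
}

#' Exhaustive in-plane grid search for the pore radius at one slice
#'
#' Reference maximizer used to validate the Monte-Carlo profiler: scans a
#' square grid of in-plane centers around `center0` and returns the best
#' radius and center found.
#'
#' @param fr,top,protein as in [compute_radius_profile()].
#' @param z slice position (nm).
#' @param center0 grid center (x, y).
#' @param half_width half-extent of the scan (nm).
#' @param grid_step grid spacing (nm), default 0.01.
#' @param r_max radius cap (nm).
#' @return list with `radius` and `center`.
#' @export
grid_search_radius <- function(fr, top, protein, z, center0 = c(0, 0),
                               half_width = 0.3, grid_step = 0.01,
                               r_max = 1.5) {
  if (length(protein) == 0) stop("empty atom selection")
  coords <- fr$coords[protein, , drop = FALSE]
  vdw <- top$atoms$vdw[protein]
  gx <- seq(center0[1] - half_width, center0[1] + half_width, by = grid_step)
  gy <- seq(center0[2] - half_width, center0[2] + half_width, by = grid_step)
  best <- -Inf
  bc <- c(NA, NA)
  for (x in gx) {
    for (y in gy) {
      r <- min(min(.mi_dist(c(x, y, z), coords, fr$box) - vdw), r_max)
      if (r > best) {
        best <- r
        bc <- c(x, y)
      }
    }
  }
  list(radius = best, center = bc)
}
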
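## Directed water-current estimation from forced trajectories, plus
## time-averaged real-space density grids and immobile-water site
## detection.

#' Estimate the directed water current through a channel region
#'
#' Per-step minimum-image z displacements of waters inside a cylindrical
#' region are summed over waters and accumulated over frames; the leading
#' `transient_fraction` of frames is discarded and the remainder fitted by
#' ordinary least squares against time.  A water's step contributes when
#' the water is inside the region at the start of the step.  Complete
#' permeation events (a water traversing the full z interval while inside
#' the cylinder radius) are counted as a secondary, event-based estimator.
#'
#' @param traj a `trajectory`.
#' @param waters atom selection tracked (typically water oxygens).
#' @param region list with `center` (in-plane x,y), `radius` (nm), `zlim`
#'   (length-2, nm).
#' @param transient_fraction fraction of leading frames discarded, in
#'   [0, 1).
#' @return object of class `"flux_estimate"`: list with `slope` (nm/ps),
#'   `intercept`, `slope_std_error`, `crossings_per_ns` (signed net rate),
#'   `n_events_up`, `n_events_down`, `transient_fraction`.
#' @export
estimate_water_current <- function(traj, waters, region,
                                   transient_fraction = 0.2) {
  stopifnot(transient_fraction >= 0, transient_fraction < 1)
  nf <- n_frames(traj)
  times <- frame_times(traj)
  nw <- length(waters)
  if (nw == 0) stop("empty water selection")
  inside <- function(fr) {
    xy <- fr$coords[waters, 1:2, drop = FALSE]
    z <- fr$coords[waters, 3]
    (xy[, 1] - region$center[1])^2 + (xy[, 2] - region$center[2])^2 <=
      region$radius^2 & z >= region$zlim[1] & z <= region$zlim[2]
  }
  # cumulative summed displacement
  cum <- numeric(nf)
  ever_inside <- FALSE
  # per-water unwrapped z for event counting
  zu <- traj$frames[[1]]$coords[waters, 3]
  lo <- zu < region$zlim[1]
  hi <- zu > region$zlim[2]
  armed_from <- rep(NA_character_, nw)  # side last exited before entering
  armed_from[lo] <- "below"
  armed_from[hi] <- "above"
  n_up <- 0L; n_down <- 0L
  for (f in seq_len(nf - 1)) {
    f0 <- traj$frames[[f]]
    f1 <- traj$frames[[f + 1]]
    dz <- minimum_image_displacement(f0$coords[waters, , drop = FALSE],
                                     f1$coords[waters, , drop = FALSE],
                                     f0$box)[, 3]
    ins <- inside(f0)
    if (any(ins)) ever_inside <- TRUE
    cum[f + 1] <- cum[f] + sum(dz[ins])
    zu <- zu + dz
    below <- zu < region$zlim[1]
    above <- zu > region$zlim[2]
    xy <- f1$coords[waters, 1:2, drop = FALSE]
    inr <- (xy[, 1] - region$center[1])^2 +
      (xy[, 2] - region$center[2])^2 <= region$radius^2
    up <- which(above & armed_from == "below" & inr)
    down <- which(below & armed_from == "above" & inr)
    n_up <- n_up + length(up)
    n_down <- n_down + length(down)
    armed_from[above] <- "above"
    armed_from[below] <- "below"
  }
  if (!ever_inside) stop("region is empty throughout the trajectory")
  keep <- seq_len(nf) > floor(transient_fraction * nf)
  if (sum(keep) < 10) stop("fewer than 10 frames remain after the transient")
  fit <- stats::lm(cum[keep] ~ times[keep])
  co <- stats::coef(fit)
  # The residuals of a cumulative displacement series are an integrated
  # (random-walk) process, so the iid OLS standard error is invalid.  For
  # a Brownian path of per-step variance s^2 observed over N steps of dt,
  # Var(OLS slope) = (6/5) s^2 / (N dt^2); estimate s from the increments.
  incr <- diff(cum[keep])
  Nk <- length(incr)
  dtk <- mean(diff(times[keep]))
  se <- stats::sd(incr) * sqrt(6 / (5 * Nk)) / dtk
  span_ns <- (times[nf] - times[1]) / 1000
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 slope_std_error = se,
                 crossings_per_ns = (n_up - n_down) / span_ns,
                 n_events_up = n_up, n_events_down = n_down,
                 transient_fraction = transient_fraction),
            class = "flux_estimate")
}

#' Time-averaged Gaussian-smeared density grid
#'
#' Each selected atom deposits a normalized 3-D Gaussian of width `sigma`
#' per frame (truncated at 4 sigma); `values` is the frame average, so its
#' integral equals the number of selected atoms.  `occupancy[v]` is the
#' fraction of frames with at least one selected atom within one grid
#' spacing of voxel `v` along every axis (its 27-voxel neighborhood).
#'
#' @param traj a `trajectory`.
#' @param atoms atom selection.
#' @param spacing voxel edge (nm).
#' @param sigma Gaussian width (nm); must be at least `spacing / 2`.
#' @param max_voxels memory cap on the grid size.
#' @return object of class `"density_grid"`: list with `origin`, `spacing`,
#'   `dims`, `values` (3-D array), `occupancy`.
#' @export
compute_density_grid <- function(traj, atoms, spacing = 0.05, sigma = 0.08,
                                 max_voxels = 2e7) {
  if (spacing <= 0) stop("spacing must be positive")
  if (sigma < spacing / 2) stop("sigma must be at least spacing / 2")
  box <- traj$frames[[1]]$box
  # grid spans the bounding box of the selected atoms, padded by 4 sigma
  all_min <- rep(Inf, 3); all_max <- rep(-Inf, 3)
  for (fr in traj$frames) {
    xyz <- fr$coords[atoms, , drop = FALSE]
    all_min <- pmin(all_min, apply(xyz, 2, min))
    all_max <- pmax(all_max, apply(xyz, 2, max))
  }
  origin <- all_min - 4 * sigma
  dims <- pmax(ceiling((all_max + 4 * sigma - origin) / spacing), 1) + 1
  if (prod(dims) > max_voxels)
    stop("density grid would exceed the memory cap; use coarser spacing")
  values <- array(0, dims)
  occ <- array(0L, dims)
  nf <- n_frames(traj)
  halo <- ceiling(4 * sigma / spacing)
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(dims[k]) - 1) * spacing)
  for (f in seq_len(nf)) {
    xyz <- traj$frames[[f]]$coords[atoms, , drop = FALSE]
    touched <- array(FALSE, dims)
    for (i in seq_len(nrow(xyz))) {
      p <- xyz[i, ]
      ic <- round((p - origin) / spacing) + 1
      rng <- lapply(1:3, function(k)
        max(1, ic[k] - halo):min(dims[k], ic[k] + halo))
      gk <- lapply(1:3, function(k) {
        x <- ax[[k]][rng[[k]]]
        w <- exp(-(x - p[k])^2 / (2 * sigma^2))
        w / sum(w)  # discrete normalization: total deposit = 1
      })
      dep <- outer(outer(gk[[1]], gk[[2]]), gk[[3]])
      values[rng[[1]], rng[[2]], rng[[3]]] <-
        values[rng[[1]], rng[[2]], rng[[3]]] + dep / spacing^3
      # occupancy: voxels within one spacing of the atom per axis
      # (the 27-voxel neighborhood of the nearest voxel)
      orng <- lapply(1:3, function(k)
        max(1, ic[k] - 1):min(dims[k], ic[k] + 1))
      touched[orng[[1]], orng[[2]], orng[[3]]] <- TRUE
    }
    occ <- occ + touched
  }
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 values = values / nf, occupancy = occ / nf),
            class = "density_grid")
}

#' Integral of a density grid
#' @param grid a `density_grid`.
#' @return numeric integral (atoms per frame).
#' @export
density_integral <- function(grid) sum(grid$values) * grid$spacing^3

#' Detect immobile (high-occupancy) water sites
#'
#' Local maxima of the density grid with occupancy at or above the
#' threshold, greedily pruned so that surviving sites are at least
#' `min_separation` apart (highest peak kept first; ties resolved by lower
#' voxel index).
#'
#' @param grid a `density_grid`.
#' @param occupancy_threshold minimum occupancy in [0, 1] (default 0.7).
#' @param min_separation minimum distance between reported sites (nm).
#' @return data.frame of class `"immobile_sites"` with columns `x`, `y`,
#'   `z`, `occupancy`, `peak_density`.
#' @export
detect_immobile_sites <- function(grid, occupancy_threshold = 0.7,
                                  min_separation = 0.2) {
  v <- grid$values
  d <- grid$dims
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      occupancy = numeric(0), peak_density = numeric(0))
  class(empty) <- c("immobile_sites", "data.frame")
  cand <- which(grid$occupancy >= occupancy_threshold)
  if (length(cand) == 0) return(empty)
  idx <- arrayInd(cand, d)
  is_max <- vapply(seq_along(cand), function(t) {
    i <- idx[t, 1]; j <- idx[t, 2]; k <- idx[t, 3]
    val <- v[i, j, k]
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
        next
      if (v[ii, jj, kk] > val) return(FALSE)
    }
    TRUE
  }, logical(1))
  if (!any(is_max)) return(empty)
  keep <- which(is_max)
  peaks <- v[cand[keep]]
  # highest first; ties by lower linear voxel index
  ord <- order(-peaks, cand[keep])
  pos <- sweep((idx[keep, , drop = FALSE] - 1) * grid$spacing, 2,
               grid$origin, "+")
  chosen <- integer(0)
  for (t in ord) {
    if (length(chosen) > 0) {
      dd <- sqrt(colSums((t(pos[chosen, , drop = FALSE]) - pos[t, ])^2))
      if (min(dd) < min_separation) next
    }
    chosen <- c(chosen, t)
  }
  out <- data.frame(x = pos[chosen, 1], y = pos[chosen, 2],
                    z = pos[chosen, 3],
                    occupancy = grid$occupancy[cand[keep]][chosen],
                    peak_density = peaks[chosen])
  class(out) <- c("immobile_sites", "data.frame")
  out
}
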
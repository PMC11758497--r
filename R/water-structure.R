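## Water-structure observables: radial distribution functions, the dipole
## orientational order parameter along the membrane normal, continuous
## (switching-function) coordination numbers, and atom-pair distance
## distributions.

#' Radial distribution function
#'
#' `g(r) = <n(r)> / (4 pi r^2 dr rho)` with `rho = N_targets / V_box`,
#' averaged over reference atoms and frames.  Frames are grouped into
#' consecutive windows of `window_frames`; the per-window means and their
#' spread provide the uncertainty band.
#'
#' @param traj a `trajectory`.
#' @param reference,targets atom selections.  Shared atoms are excluded
#'   from their own pair count.
#' @param r_max histogram extent (nm); must be below half the smallest box
#'   edge for minimum-image validity.
#' @param dr bin width (nm).
#' @param window_frames frames per averaging window (default: all frames,
#'   one window).
#' @return object of class `"rdf_result"`: list with `bin_centers`, `g`,
#'   `window_mean` (bins x windows), `window_std`, `n_windows`.
#' @export
compute_rdf <- function(traj, reference, targets, r_max, dr,
                        window_frames = NULL) {
  if (dr <= 0) stop("dr must be positive")
  nf <- n_frames(traj)
  if (is.null(window_frames)) window_frames <- nf
  box <- traj$frames[[1]]$box
  if (r_max >= min(box) / 2)
    stop("r_max must be below half the smallest box edge (minimum image)")
  edges <- seq(0, r_max, by = dr)
  nb <- length(edges) - 1
  centers <- edges[-1] - dr / 2
  vol <- prod(box)
  rho <- length(targets) / vol
  per_frame <- matrix(0, nb, nf)
  for (f in seq_len(nf)) {
    fr <- traj$frames[[f]]
    counts <- numeric(nb)
    for (i in reference) {
      tt <- targets[targets != i]
      if (length(tt) == 0) next
      d <- .mi_dist(fr$coords[i, ], fr$coords[tt, , drop = FALSE], fr$box)
      d <- d[d < r_max]
      if (length(d) > 0)
        counts <- counts + tabulate(pmin(floor(d / dr) + 1L, nb), nb)
    }
    shell <- 4 * pi * centers^2 * dr
    per_frame[, f] <- counts / (length(reference) * shell * rho)
  }
  win <- split(seq_len(nf), ceiling(seq_len(nf) / window_frames))
  wm <- sapply(win, function(ix) rowMeans(per_frame[, ix, drop = FALSE]))
  wm <- matrix(wm, nrow = nb)
  wstd <- apply(wm, 1, function(v) sqrt(mean((v - mean(v))^2)))
  structure(list(bin_centers = centers, g = rowMeans(per_frame),
                 window_mean = wm, window_std = wstd,
                 n_windows = length(win)),
            class = "rdf_result")
}

#' First minimum of a radial distribution function
#'
#' After smoothing `g(r)` with a 3-bin moving average, returns the bin
#' center of the first local minimum that follows the first local maximum
#' within `search_range`.
#'
#' @param rdf an `rdf_result`.
#' @param search_range length-2 interval (nm).
#' @return position of the first minimum (nm).
#' @export
first_minimum <- function(rdf, search_range = range(rdf$bin_centers)) {
  r <- rdf$bin_centers
  g <- stats::filter(rdf$g, rep(1 / 3, 3), sides = 2)
  g <- as.numeric(g)
  g[1] <- rdf$g[1]; g[length(g)] <- rdf$g[length(g)]
  inr <- which(r >= search_range[1] & r <= search_range[2])
  seen_max <- FALSE
  for (i in inr) {
    if (i <= 1 || i >= length(r)) next
    if (!seen_max && g[i] > g[i - 1] && g[i] >= g[i + 1]) seen_max <- TRUE
    else if (seen_max && g[i] < g[i - 1] && g[i] <= g[i + 1]) return(r[i])
  }
  stop("no interior first minimum found in the search range")
}

#' Water dipole order-parameter profile along z
#'
#' For each water, the dipole direction is the normalized sum of the two
#' O->H vectors and `cos(phi)` is its z component.  Waters are assigned to
#' z bins by their oxygen position; per-frame bin means are averaged over
#' frames.  An optional cylindrical cutoff about the channel axis
#' restricts the average to channel waters.
#'
#' @param traj a `trajectory` whose topology has water groups.
#' @param z_edges bin edges (nm).
#' @param radial_cutoff optional in-plane radius (nm) about `axis_center`.
#' @param axis_center in-plane (x, y) of the channel axis.
#' @return object of class `"order_profile"`: data.frame with `z_center`,
#'   `mean_cos_phi`, `count` (water-frames), `empty` flag.
#' @export
compute_order_profile <- function(traj, z_edges, radial_cutoff = NULL,
                                  axis_center = c(0, 0)) {
  wg <- traj$topology$water_groups
  if (nrow(wg) == 0) stop("topology has no water groups")
  nb <- length(z_edges) - 1
  sum_frame <- numeric(nb)   # sum over frames of per-frame bin means
  nfr_bin <- integer(nb)     # frames contributing to each bin
  count <- integer(nb)       # total water-frames per bin
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$frames[[f]]$coords
    o <- xyz[wg[, 1], , drop = FALSE]
    d <- (xyz[wg[, 2], , drop = FALSE] - o) + (xyz[wg[, 3], , drop = FALSE] - o)
    cphi <- d[, 3] / sqrt(rowSums(d * d))
    keep <- rep(TRUE, nrow(o))
    if (!is.null(radial_cutoff))
      keep <- (o[, 1] - axis_center[1])^2 + (o[, 2] - axis_center[2])^2 <=
        radial_cutoff^2
    bin <- findInterval(o[, 3], z_edges, rightmost.closed = TRUE)
    keep <- keep & bin >= 1 & bin <= nb
    if (!any(keep)) next
    bs <- tapply(cphi[keep], factor(bin[keep], levels = seq_len(nb)), mean)
    hit <- !is.na(bs)
    sum_frame[hit] <- sum_frame[hit] + bs[hit]
    nfr_bin[hit] <- nfr_bin[hit] + 1L
    tb <- tabulate(bin[keep], nb)
    count <- count + tb
  }
  mean_cos <- ifelse(nfr_bin > 0, sum_frame / pmax(nfr_bin, 1), NA_real_)
  structure(data.frame(z_center = (z_edges[-1] + z_edges[-(nb + 1)]) / 2,
                       mean_cos_phi = mean_cos, count = count,
                       empty = nfr_bin == 0),
            class = c("order_profile", "data.frame"))
}

#' Rational switching function
#'
#' `s(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)`, continuous at `r = r0` where
#' it takes the limit value `n/m`.
#'
#' @param r distances (nm).
#' @param r0 cutoff (nm).
#' @param n,m exponents with `m > n > 0`.
#' @return switching values in (0, 1].
#' @export
switching_function <- function(r, r0, n = 6, m = 12) {
  if (!(m > n && n > 0)) stop("need m > n > 0")
  if (r0 <= 0) stop("r0 must be positive")
  x <- r / r0
  s <- (1 - x^n) / (1 - x^m)
  at <- abs(x - 1) < 1e-12
  s[at] <- n / m
  s
}

#' Continuous coordination number of a central atom
#'
#' Per frame, `N = sum_j s(r_j)` over candidate atoms with the rational
#' switching function; the hard-count variant (`r < r0`) is reported
#' alongside.
#'
#' @param traj a `trajectory`.
#' @param center selection of exactly one atom.
#' @param candidates candidate selection (the center is excluded).
#' @param r0 cutoff distance (nm); 0.35 nm is the first minimum of the
#'   hydronium-water RDF.
#' @param n,m switching exponents.
#' @return object of class `"coordination_series"`: data.frame with
#'   `time`, `n_coord`, `hard_count`; attributes `r0`, `n`, `m`.
#' @export
compute_coordination <- function(traj, center, candidates, r0 = 0.35,
                                 n = 6, m = 12) {
  if (length(center) != 1) stop("center selection must contain exactly 1 atom")
  cand <- candidates[candidates != center]
  nf <- n_frames(traj)
  nc <- numeric(nf)
  hc <- numeric(nf)
  for (f in seq_len(nf)) {
    fr <- traj$frames[[f]]
    d <- .mi_dist(fr$coords[center, ], fr$coords[cand, , drop = FALSE],
                  fr$box)
    nc[f] <- sum(switching_function(d, r0, n, m))
    hc[f] <- sum(d < r0)
  }
  structure(data.frame(time = frame_times(traj), n_coord = nc,
                       hard_count = hc),
            class = c("coordination_series", "data.frame"),
            r0 = r0, n = n, m = m)
}

#' Distance distribution between two atoms
#'
#' Normalized histogram of the minimum-image distance between a single
#' atom pair over all frames.
#'
#' @param traj a `trajectory`.
#' @param atom_a,atom_b selections of exactly one atom each.
#' @param bins bin edges (nm); distances outside are dropped before
#'   normalization.
#' @param label text label for the distribution.
#' @return object of class `"distance_distribution"`: data.frame with
#'   `bin_center`, `probability`.
#' @export
compute_distance_distribution <- function(traj, atom_a, atom_b, bins,
                                          label = "") {
  if (length(atom_a) != 1 || length(atom_b) != 1)
    stop("atom_a and atom_b must each select exactly one atom")
  d <- vapply(traj$frames, function(fr)
    sqrt(sum(minimum_image_displacement(fr$coords[atom_a, ],
                                        fr$coords[atom_b, ], fr$box)^2)),
    numeric(1))
  h <- graphics::hist(d[d >= bins[1] & d <= bins[length(bins)]],
                      breaks = bins, plot = FALSE)
  p <- h$counts / sum(h$counts)
  structure(data.frame(bin_center = h$mids, probability = p),
            class = c("distance_distribution", "data.frame"),
            label = label, n = length(d))
}
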
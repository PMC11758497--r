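## Seeded generators producing inputs with the statistical structure the
## analysis stages assume: a membrane slab pierced by a cylindrical aqueous
## pore, three-site waters with a controllable dipole-orientation field,
## drift-diffusion water motion with known mean current, a Metropolis
## walker on a prescribed 2-D energy surface, hidden-Markov torsion
## features with known relaxation timescales, and toy transition-charge
## pigment pairs.

# Rigid three-site water geometry (nm / degrees).
.WATER_OH <- 0.09572
.WATER_ANGLE <- 104.52

# Build one rigid water: oxygen at `o`, H-bisector (dipole direction) along
# unit vector `u`, hydrogen plane azimuth `psi`.
.place_water <- function(o, u, psi) {
  u <- u / sqrt(sum(u * u))
  # orthonormal basis (u, e1, e2)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1 * e1))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  w <- e1 * cos(psi) + e2 * sin(psi)
  half <- (.WATER_ANGLE / 2) * pi / 180
  h1 <- o + .WATER_OH * (cos(half) * u + sin(half) * w)
  h2 <- o + .WATER_OH * (cos(half) * u - sin(half) * w)
  rbind(h1, h2)
}

# Draw cos(phi) with exact mean m and spread controlled by concentration
# kappa >= 0: uniform on [m - D, m + D] with D = (1 - |m|)/sqrt(1 + kappa).
# kappa = 0 and m = 0 give the isotropic distribution; kappa = Inf is
# deterministic.
.draw_cos_phi <- function(m, kappa) {
  m <- pmin(1, pmax(-1, m))
  if (!is.finite(kappa)) return(m)
  D <- (1 - abs(m)) / sqrt(1 + kappa)
  m + stats::runif(length(m), -D, D)
}

#' Generate a membrane-slab system with a cylindrical aqueous pore
#'
#' Immobile lining pseudo-atoms form a cylinder of geometric radius
#' `pore_radius` about the z axis through a slab of half-thickness
#' `slab_half_thickness`; the accessible (probe) radius is therefore
#' `pore_radius - lining_atom_radius` by construction.  Rigid three-site
#' waters fill the channel and the bulk; the dipole of each water is drawn
#' so that the expectation of cos(phi) at its z position equals
#' `orientation_profile(z)`, with spread set by `orientation_concentration`
#' (larger = tighter; `Inf` = deterministic).  Waters are resampled
#' independently every frame; the lining never moves.
#'
#' @param pore_radius geometric cylinder radius (nm).
#' @param slab_half_thickness half-thickness of the slab (nm).
#' @param lining_atom_radius vdW radius of lining pseudo-atoms (nm).
#' @param n_waters_channel,n_waters_bulk water counts.
#' @param orientation_profile function z -> mean cos(phi) in [-1, 1].
#' @param orientation_concentration dimensionless >= 0 (may be `Inf`).
#' @param tracer if `TRUE`, add a charged tracer pseudo-atom (resname H3O).
#' @param tracer_pos tracer position (nm).
#' @param n_frames number of frames to generate.
#' @param dt frame spacing (ps).
#' @param seed integer RNG seed.
#' @return a `trajectory`.
#' @export
make_membrane_channel_system <- function(pore_radius = 0.55,
                                         slab_half_thickness = 1.5,
                                         lining_atom_radius = 0.15,
                                         n_waters_channel = 40,
                                         n_waters_bulk = 0,
                                         orientation_profile = function(z) 0 * z,
                                         orientation_concentration = 0,
                                         tracer = FALSE,
                                         tracer_pos = c(0, 0, 0),
                                         n_frames = 1, dt = 1, seed = 1) {
  if (pore_radius <= lining_atom_radius)
    stop("pore_radius must exceed lining_atom_radius")
  set.seed(seed)
  h <- slab_half_thickness
  box <- c(2 * (pore_radius + 0.8), 2 * (pore_radius + 0.8), 2 * (h + 1.2))

  # lining: rings of immobile pseudo-atoms along z
  ring_z <- seq(-h, h, by = 0.05)
  nring <- 36
  ang <- (seq_len(nring) - 1) * 2 * pi / nring
  lin <- do.call(rbind, lapply(ring_z, function(z)
    cbind(pore_radius * cos(ang), pore_radius * sin(ang), z)))
  n_lin <- nrow(lin)

  n_w <- n_waters_channel + n_waters_bulk
  atoms <- data.frame(
    name = c(rep("LIN", n_lin),
             rep(c("OW", "HW1", "HW2"), n_w),
             if (tracer) "OT"),
    element = c(rep("X", n_lin), rep(c("O", "H", "H"), n_w),
                if (tracer) "O"),
    resid = c(rep(1L, n_lin), rep(seq_len(n_w) + 1L, each = 3),
              if (tracer) n_w + 2L),
    resname = c(rep("LIN", n_lin), rep("SOL", 3 * n_w),
                if (tracer) "H3O"),
    chain = "A",
    vdw = c(rep(lining_atom_radius, n_lin),
            rep(c(0.152, 0.12, 0.12), n_w), if (tracer) 0.152),
    charge = c(rep(0, n_lin), rep(0, 3 * n_w), if (tracer) 1),
    stringsAsFactors = FALSE)
  wg <- if (n_w > 0)
    cbind(n_lin + 3 * (seq_len(n_w) - 1) + 1,
          n_lin + 3 * (seq_len(n_w) - 1) + 2,
          n_lin + 3 * (seq_len(n_w) - 1) + 3)
  else NULL
  top <- topology(atoms, water_groups = wg)

  r_in <- max(pore_radius - lining_atom_radius - 0.05, 0.05)
  sample_positions <- function() {
    pos <- matrix(NA_real_, n_w, 3)
    placed <- 0
    tries <- 0
    while (placed < n_w) {
      tries <- tries + 1
      if (tries > 200 * max(n_w, 1))
        stop("infeasible water packing; reduce the number of waters")
      if (placed < n_waters_channel) {
        rr <- r_in * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        p <- c(rr * cos(th), rr * sin(th), stats::runif(1, -h, h))
      } else {
        side <- sample(c(-1, 1), 1)
        p <- c(stats::runif(1, -box[1] / 2 + 0.2, box[1] / 2 - 0.2),
               stats::runif(1, -box[2] / 2 + 0.2, box[2] / 2 - 0.2),
               side * stats::runif(1, h + 0.25, box[3] / 2 - 0.2))
      }
      if (placed > 0) {
        d <- .mi_dist(p, pos[seq_len(placed), , drop = FALSE], box)
        if (min(d) < 0.25) next
      }
      placed <- placed + 1
      pos[placed, ] <- p
    }
    pos
  }

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    coords <- matrix(0, nrow(atoms), 3)
    coords[seq_len(n_lin), ] <- lin
    if (n_w > 0) {
      opos <- sample_positions()
      m <- orientation_profile(opos[, 3])
      cphi <- .draw_cos_phi(m, orientation_concentration)
      sphi <- sqrt(pmax(0, 1 - cphi^2))
      az <- stats::runif(n_w, 0, 2 * pi)
      psi <- stats::runif(n_w, 0, 2 * pi)
      for (i in seq_len(n_w)) {
        u <- c(sphi[i] * cos(az[i]), sphi[i] * sin(az[i]), cphi[i])
        k <- n_lin + 3 * (i - 1)
        coords[k + 1, ] <- opos[i, ]
        coords[k + 2:3, ] <- .place_water(opos[i, ], u, psi[i])
      }
    }
    if (tracer) coords[nrow(atoms), ] <- tracer_pos
    frames[[f]] <- frame(coords, box, time = (f - 1) * dt)
  }
  trajectory(top, frames)
}

## ------------------------------------------------- hidden-Markov torsions ----

#' Generate hidden-Markov torsion-feature trajectories
#'
#' Samples a hidden chain from a row-stochastic transition matrix and emits
#' torsion angles (state mean + Gaussian noise, wrapped to (-180, 180]
#' degrees).  The generator's exact relaxation timescales are
#' `-dt / log(lambda_i)` for the eigenvalues `lambda_i < 1` of the
#' transition matrix (see [generator_timescales()]).
#'
#' @param transition_matrix row-stochastic square matrix.
#' @param state_means matrix (states x torsions) of mean angles in degrees.
#' @param noise_sd emission noise s.d. in degrees.
#' @param n_frames chain length.
#' @param frame_dt frame spacing in ps.
#' @param seed integer RNG seed.
#' @return list with `angles` (frames x torsions, degrees), `states`
#'   (hidden state sequence), and `dt`.
#' @export
make_markov_feature_trajectories <- function(transition_matrix, state_means,
                                             noise_sd = 10, n_frames = 1000,
                                             frame_dt = 1, seed = 1) {
  P <- as.matrix(transition_matrix)
  k <- nrow(P)
  if (ncol(P) != k || any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12))
    stop("transition_matrix must be row-stochastic (rows sum to 1)")
  state_means <- rbind(state_means)
  if (nrow(state_means) != k)
    stop("state_means must have one row per state")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  cum <- t(apply(P, 1, cumsum))
  u <- stats::runif(n_frames)
  s <- integer(n_frames)
  s[1] <- sample.int(k, 1)
  for (t in 2:n_frames)
    s[t] <- findInterval(u[t], cum[s[t - 1], ], left.open = TRUE) + 1L
  ang <- state_means[s, , drop = FALSE]
  if (noise_sd > 0)
    ang <- ang + matrix(stats::rnorm(length(ang), sd = noise_sd),
                        nrow = n_frames)
  ang <- ang - 360 * ceiling(ang / 360 - 0.5)  # wrap to (-180, 180]
  list(angles = ang, states = s, dt = frame_dt)
}

#' Exact relaxation timescales of a Markov transition matrix
#'
#' @param P row-stochastic matrix.
#' @param dt time per step (ps).
#' @return numeric vector `-dt / log(lambda)` for real eigenvalues
#'   `0 < lambda < 1`, sorted decreasing.
#' @export
generator_timescales <- function(P, dt = 1) {
  ev <- eigen(P, only.values = TRUE)$values
  ev <- Re(ev[abs(Im(ev)) < 1e-10])
  ev <- sort(ev[ev < 1 - 1e-12 & ev > 1e-12], decreasing = TRUE)
  -dt / log(ev)
}

## ------------------------------------------------------- drift-diffusion ----

#' Generate drift-diffusion water walkers
#'
#' Independent 1-D walks along z, `z(t+dt) = z(t) + v dt + sqrt(2 D dt) xi`,
#' wrapped into the periodic box.  The expected summed displacement rate
#' over all walkers is `n * v`.
#'
#' @param v drift velocity (nm/ps).
#' @param D diffusion coefficient (nm^2/ps).
#' @param n number of walkers.
#' @param steps number of steps (frames = steps + 1).
#' @param dt time step (ps).
#' @param seed integer RNG seed.
#' @param box box edges (nm).
#' @return a `trajectory` of single-site walkers (resname SOL, name OW).
#' @export
make_drift_diffusion_waters <- function(v, D, n, steps, dt = 1, seed = 1,
                                        box = c(4, 4, 20)) {
  set.seed(seed)
  atoms <- data.frame(name = "OW", element = "O",
                      resid = seq_len(n), resname = "SOL", chain = "A",
                      stringsAsFactors = FALSE)
  top <- topology(atoms, water_groups = NULL)
  xy <- cbind(stats::runif(n, -0.5, 0.5), stats::runif(n, -0.5, 0.5))
  z <- matrix(0, steps + 1, n)
  z[1, ] <- stats::runif(n, -box[3] / 4, box[3] / 4)
  incr <- matrix(v * dt, steps, n)
  if (D > 0)
    incr <- incr + matrix(stats::rnorm(steps * n, sd = sqrt(2 * D * dt)),
                          steps, n)
  for (t in seq_len(steps)) z[t + 1, ] <- z[t, ] + incr[t, ]
  zw <- z - box[3] * ceiling(z / box[3] - 0.5)  # wrap
  frames <- lapply(seq_len(steps + 1), function(t)
    frame(cbind(xy[, 1], xy[, 2], zw[t, ]), box, time = (t - 1) * dt))
  trajectory(top, frames)
}

## ------------------------------------------------------ Boltzmann walker ----

#' Metropolis walker on a 2-D energy grid
#'
#' Single-bin-move Metropolis Monte Carlo on a grid of energies in kT.
#' Proposals are uniform over the 8 neighbors; moves off the grid or onto
#' masked bins (`NA`/`Inf` energy) are rejected.  The empirical bin
#' distribution converges to `exp(-F)`.
#'
#' @param energy numeric matrix (nx x ny) of energies in kT; `NA` or `Inf`
#'   marks impassable bins.
#' @param steps number of Metropolis steps.
#' @param seed integer RNG seed.
#' @param x_edges,y_edges bin edges (defaults: unit bins `0..nx`, `0..ny`).
#' @param jitter if `TRUE`, returned points are jittered uniformly within
#'   their bin so re-binning on the same edges recovers the visited bin.
#' @return matrix (steps x 2) of sampled 2-D points.
#' @export
make_boltzmann_walker <- function(energy, steps, seed = 1,
                                  x_edges = NULL, y_edges = NULL,
                                  jitter = TRUE) {
  E <- as.matrix(energy)
  nx <- nrow(E); ny <- ncol(E)
  if (is.null(x_edges)) x_edges <- 0:nx
  if (is.null(y_edges)) y_edges <- 0:ny
  open <- is.finite(E)
  if (!any(open)) stop("energy grid has no passable bins")
  set.seed(seed)
  start <- which(E == min(E[open]), arr.ind = TRUE)[1, ]
  moves <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  prop <- sample.int(8, steps, replace = TRUE)
  acc <- stats::runif(steps)
  ix <- integer(steps); iy <- integer(steps)
  cx <- start[1]; cy <- start[2]
  ecur <- E[cx, cy]
  for (t in seq_len(steps)) {
    px <- cx + moves[prop[t], 1]
    py <- cy + moves[prop[t], 2]
    if (px >= 1L && px <= nx && py >= 1L && py <= ny && open[px, py]) {
      de <- E[px, py] - ecur
      if (de <= 0 || acc[t] < exp(-de)) {
        cx <- px; cy <- py; ecur <- E[cx, cy]
      }
    }
    ix[t] <- cx; iy[t] <- cy
  }
  wx <- diff(x_edges); wy <- diff(y_edges)
  jx <- if (jitter) stats::runif(steps) else rep(0.5, steps)
  jy <- if (jitter) stats::runif(steps) else rep(0.5, steps)
  cbind(x = x_edges[ix] + jx * wx[ix],
        y = y_edges[iy] + jy * wy[iy])
}

## ------------------------------------------------------ toy chromophores ----

#' Construct a transition-charge set
#'
#' @param label text label for the pigment/state.
#' @param atom_names ordered atom names the charges map onto.
#' @param charges transition charges in e, one per atom name.
#' @param state_tag `"protonated"`, `"deprotonated"`, or `"none"`.
#' @return object of class `"transition_charge_set"`.
#' @export
transition_charge_set <- function(label, atom_names, charges,
                                  state_tag = c("none", "protonated",
                                                "deprotonated")) {
  state_tag <- match.arg(state_tag)
  charges <- as.numeric(charges)
  if (length(atom_names) != length(charges))
    stop("charge count must equal atom-name count")
  if (any(!is.finite(charges))) stop("charges must be finite")
  structure(list(label = label, atom_names = as.character(atom_names),
                 charges = charges, state_tag = state_tag),
            class = "transition_charge_set")
}

#' Toy two-point-charge chromophore pair
#'
#' Each pigment is a pair of point charges +/- q separated by
#' `charge_separation`, with `q * charge_separation = dipole_moment`,
#' placed at the given poses.  Useful for validating TrESP couplings
#' against the ideal dipole-dipole closed form.
#'
#' @param dipole_moment transition dipole magnitude (e nm).
#' @param charge_separation distance between the two charges (nm).
#' @param placement list of two poses, each `list(center =, direction =)`;
#'   the dipole points along `direction` (from -q to +q).
#' @param box box edges (nm).
#' @return list with `setA`, `setB` (transition_charge_set), `topology`,
#'   `frame`, `selA`, `selB`, and the charge magnitude `q`.
#' @export
make_toy_chromophore_pair <- function(dipole_moment = 0.01,
                                      charge_separation = 0.1,
                                      placement = list(
                                        list(center = c(0, 0, 0),
                                             direction = c(0, 0, 1)),
                                        list(center = c(0, 0, 1),
                                             direction = c(0, 0, 1))),
                                      box = c(50, 50, 50)) {
  q <- dipole_moment / charge_separation
  mk <- function(pose, names) {
    u <- pose$direction / sqrt(sum(pose$direction^2))
    rbind(pose$center - (charge_separation / 2) * u,
          pose$center + (charge_separation / 2) * u)
  }
  coords <- rbind(mk(placement[[1]]), mk(placement[[2]]))
  atoms <- data.frame(name = c("PA1", "PA2", "PB1", "PB2"),
                      element = "C",
                      resid = c(1L, 1L, 2L, 2L),
                      resname = c("PGA", "PGA", "PGB", "PGB"),
                      chain = "A", stringsAsFactors = FALSE)
  top <- topology(atoms, water_groups = NULL)
  list(setA = transition_charge_set("toyA", c("PA1", "PA2"), c(-q, q)),
       setB = transition_charge_set("toyB", c("PB1", "PB2"), c(-q, q)),
       topology = top,
       frame = frame(coords, box),
       selA = select_atoms(top, resname = "PGA"),
       selB = select_atoms(top, resname = "PGB"),
       q = q)
}
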
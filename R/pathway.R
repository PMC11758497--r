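## Free-energy surfaces from sampled densities (-ln P, in kT), Dijkstra
## minimum-energy paths on the visited-bin graph, and tracer-residue
## contact maps.

#' 2-D free-energy surface from samples
#'
#' `F(bin) = -ln( P(bin) / max P )`, so the global minimum is exactly 0.
#' Bins that receive no samples are masked (treated as impassable by the
#' path search), not set to zero.
#'
#' @param samples matrix (n x 2) of points.
#' @param x_edges,y_edges bin edges.
#' @param weights optional per-sample weights.
#' @return object of class `"fes_grid"`: list with `x_edges`, `y_edges`,
#'   `free_energy` (nx x ny, kT; `NA` on masked bins), `visited_mask`.
#' @export
compute_fes_2d <- function(samples, x_edges, y_edges, weights = NULL) {
  samples <- rbind(samples)
  if (is.null(weights)) weights <- rep(1, nrow(samples))
  if (length(weights) != nrow(samples))
    stop("weights must match the number of samples")
  nx <- length(x_edges) - 1
  ny <- length(y_edges) - 1
  ix <- findInterval(samples[, 1], x_edges, rightmost.closed = TRUE)
  iy <- findInterval(samples[, 2], y_edges, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  if (!any(ok)) stop("all samples fall outside the grid")
  H <- matrix(0, nx, ny)
  tap <- tapply(weights[ok], list(factor(ix[ok], seq_len(nx)),
                                  factor(iy[ok], seq_len(ny))), sum)
  tap[is.na(tap)] <- 0
  H[] <- tap
  visited <- H > 0
  Fg <- matrix(NA_real_, nx, ny)
  Fg[visited] <- -log(H[visited] / max(H))
  structure(list(x_edges = x_edges, y_edges = y_edges, free_energy = Fg,
                 visited_mask = visited),
            class = "fes_grid")
}

#' Minimum-energy path on a free-energy surface (Dijkstra)
#'
#' Shortest path on the 8-connected graph of visited bins.  The weight of
#' an edge is the mean of the two bin energies times the Euclidean
#' distance between the bin centers (kT nm), which keeps the cost
#' metric-consistent on the diagonal moves.  Ties in the tentative
#' distance are broken by lexicographic bin index, so the result is
#' deterministic.
#'
#' @param fes an `fes_grid`.
#' @param start,end bin indices as `c(ix, iy)`; both must be visited.
#' @return object of class `"path_result"`: list with `bins` (ordered
#'   matrix of bin indices), `total_cost` (kT nm), `start`, `end`.
#' @export
find_minimum_energy_path <- function(fes, start, end) {
  Fg <- fes$free_energy
  nx <- nrow(Fg); ny <- ncol(Fg)
  vis <- fes$visited_mask
  chk <- function(b, nm) {
    if (b[1] < 1 || b[1] > nx || b[2] < 1 || b[2] > ny || !vis[b[1], b[2]])
      stop(nm, " bin is outside the grid or not visited")
  }
  chk(start, "start"); chk(end, "end")
  cx <- (fes$x_edges[-1] + fes$x_edges[-(nx + 1)]) / 2
  cy <- (fes$y_edges[-1] + fes$y_edges[-(ny + 1)]) / 2
  id <- function(i, j) (j - 1L) * nx + i
  n <- nx * ny
  dist <- rep(Inf, n)
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  s <- id(start[1], start[2]); e <- id(end[1], end[2])
  dist[s] <- 0
  moves <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  repeat {
    active <- which(!done & is.finite(dist))
    if (length(active) == 0) stop("disconnected: no path through visited bins")
    # min distance; ties -> lexicographically smallest linear index
    dmin <- min(dist[active])
    u <- min(active[dist[active] <= dmin + 1e-15])
    if (u == e) break
    done[u] <- TRUE
    ui <- ((u - 1L) %% nx) + 1L
    uj <- ((u - 1L) %/% nx) + 1L
    for (k in 1:8) {
      vi <- ui + moves[k, 1]; vj <- uj + moves[k, 2]
      if (vi < 1 || vi > nx || vj < 1 || vj > ny) next
      if (!vis[vi, vj]) next
      vlin <- id(vi, vj)
      if (done[vlin]) next
      w <- 0.5 * (Fg[ui, uj] + Fg[vi, vj]) *
        sqrt((cx[vi] - cx[ui])^2 + (cy[vj] - cy[uj])^2)
      alt <- dist[u] + w
      if (alt < dist[vlin] - 1e-15 ||
          (abs(alt - dist[vlin]) <= 1e-15 &&
           (is.na(prev[vlin]) || u < prev[vlin]))) {
        dist[vlin] <- alt
        prev[vlin] <- u
      }
    }
  }
  path <- e
  while (path[1] != s) path <- c(prev[path[1]], path)
  bins <- cbind(((path - 1L) %% nx) + 1L, ((path - 1L) %/% nx) + 1L)
  colnames(bins) <- c("ix", "iy")
  structure(list(bins = bins, total_cost = dist[e],
                 start = start, end = end),
            class = "path_result")
}

#' Protein-tracer contact map
#'
#' For every residue of the topology (excluding the tracer's own residue),
#' the fraction of frames in which any of its heavy atoms lies within
#' `cutoff` of any tracer atom (minimum-image distances).
#'
#' @param traj a `trajectory`.
#' @param tracer non-empty atom selection for the tracer.
#' @param cutoff contact cutoff (nm), default 0.45.
#' @return data.frame of class `"contact_map"` with columns `resid`,
#'   `resname`, `chain`, `frequency`; attribute `n_frames`.
#' @export
compute_contact_map <- function(traj, tracer, cutoff = 0.45) {
  if (length(tracer) == 0) stop("empty tracer selection")
  top <- traj$topology
  a <- top$atoms
  heavy <- which(toupper(a$element) != "H")
  heavy <- setdiff(heavy, tracer)
  tr_res <- unique(paste(a$chain[tracer], a$resid[tracer]))
  key <- paste(a$chain[heavy], a$resid[heavy])
  heavy <- heavy[!key %in% tr_res]
  key <- key[!key %in% tr_res]
  groups <- split(heavy, key)
  nf <- n_frames(traj)
  hits <- setNames(numeric(length(groups)), names(groups))
  for (f in seq_len(nf)) {
    fr <- traj$frames[[f]]
    mind <- rep(Inf, length(heavy))
    for (t in tracer) {
      d <- .mi_dist(fr$coords[t, ], fr$coords[heavy, , drop = FALSE], fr$box)
      mind <- pmin(mind, d)
    }
    contact <- mind < cutoff
    for (g in seq_along(groups)) {
      gi <- match(groups[[g]], heavy)
      if (any(contact[gi])) hits[g] <- hits[g] + 1
    }
  }
  first <- vapply(groups, `[`, integer(1), 1)
  out <- data.frame(resid = a$resid[first], resname = a$resname[first],
                    chain = a$chain[first],
                    frequency = unname(hits) / nf)
  out <- out[order(out$chain, out$resid), ]
  rownames(out) <- NULL
  class(out) <- c("contact_map", "data.frame")
  attr(out, "n_frames") <- nf
  attr(out, "cutoff") <- cutoff
  out
}
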
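# Shared fixtures, built in code at test time.

# Minimal one-water PDB; the third atom carries no element column.
write_water_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "CRYST1   30.000   30.000   30.000  90.00  90.00  90.00 P 1           1",
    paste0("ATOM      1  OW  HOH A   1       1.000   2.000   3.000",
           "  1.00  0.00           O"),
    paste0("ATOM      2  HW1 HOH A   1       1.500   2.000   3.000",
           "  1.00  0.00           H"),
    paste0("ATOM      3  HW2 HOH A   1       1.000   2.800   3.000",
           "  1.00  0.00"),
    "END"), path)
  path
}

write_simple_gro <- function(path = tempfile(fileext = ".gro"),
                             coords = rbind(c(1, 2, 3)),
                             box = c(10, 10, 11.5)) {
  n <- nrow(coords)
  writeLines(c(
    "fixture", sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", seq_len(n), "SOL", "OW",
            seq_len(n), coords[, 1], coords[, 2], coords[, 3]),
    sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])), path)
  path
}

# Trajectory from a list of coordinate matrices over a fixed topology.
traj_from_coords <- function(top, coord_list, box = c(10, 10, 10), dt = 1) {
  trajectory(top, lapply(seq_along(coord_list), function(i)
    frame(coord_list[[i]], box, time = (i - 1) * dt)))
}

simple_topology <- function(n, name = "X", resname = "UNK",
                            element = "C") {
  topology(data.frame(name = rep(name, length.out = n),
                      element = rep(element, length.out = n),
                      resid = seq_len(n), resname = resname, chain = "A",
                      stringsAsFactors = FALSE), water_groups = NULL)
}

# Brute-force sliding-window transition-count oracle (independent of the
# vectorized implementation).
oracle_counts <- function(assignments, lag, n_states) {
  C <- matrix(0, n_states, n_states)
  for (a in if (is.list(assignments)) assignments else list(assignments)) {
    if (length(a) <= lag) next
    for (t in seq_len(length(a) - lag))
      C[a[t], a[t + lag]] <- C[a[t], a[t + lag]] + 1
  }
  C
}

# All-simple-paths minimum cost by depth-first enumeration with pruning
# (feasible only on small grids); same edge-cost rule as the package.
dfs_min_cost <- function(Fg, vis, start, end, x_edges, y_edges) {
  nx <- nrow(Fg); ny <- ncol(Fg)
  cx <- (x_edges[-1] + x_edges[-(nx + 1)]) / 2
  cy <- (y_edges[-1] + y_edges[-(ny + 1)]) / 2
  best <- Inf
  seen <- matrix(FALSE, nx, ny)
  moves <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  rec <- function(i, j, cost) {
    if (cost >= best) return()
    if (i == end[1] && j == end[2]) {
      best <<- cost
      return()
    }
    seen[i, j] <<- TRUE
    for (k in 1:8) {
      ii <- i + moves[k, 1]; jj <- j + moves[k, 2]
      if (ii < 1 || ii > nx || jj < 1 || jj > ny) next
      if (!vis[ii, jj] || seen[ii, jj]) next
      w <- 0.5 * (Fg[i, j] + Fg[ii, jj]) *
        sqrt((cx[ii] - cx[i])^2 + (cy[jj] - cy[j])^2)
      rec(ii, jj, cost + w)
    }
    seen[i, j] <<- FALSE
  }
  rec(start[1], start[2], 0)
  best
}

# Best frame agreement between two labelings over all permutations of the
# smaller label set.
best_agreement <- function(pred, truth) {
  k <- max(pred)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(seq_len(k)))
    best <- max(best, mean(p[pred] == truth))
  best
}

# Metastable 4-state chain used across kinetics tests.
four_state_chain <- function() {
  P <- matrix(0.001, 4, 4)
  P[1, 2] <- 0.02; P[2, 1] <- 0.02
  P[2, 3] <- 0.015; P[3, 2] <- 0.015
  P[3, 4] <- 0.02; P[4, 3] <- 0.02
  diag(P) <- 0
  diag(P) <- 1 - rowSums(P)
  P
}

four_state_means <- function() {
  matrix(c(-150, -60, 60, 150,
           -150, 60, 150, -60,
           150, -150, -60, 60), 4, 3)
}
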
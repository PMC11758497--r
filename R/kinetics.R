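## Conformational-kinetics stage: torsion featurization, time-lagged
## independent component analysis (tICA), k-means microstates, reversible
## Markov-state-model estimation, implied timescales, Chapman-Kolmogorov
## validation, PCCA+ macrostates, and stationary-reweighted free-energy
## surfaces.

# Normalize multi-trajectory input: a matrix/vector becomes a 1-element list.
.as_traj_list <- function(x) if (is.list(x) && !is.data.frame(x)) x else list(x)

#' Torsion-angle featurization of a trajectory
#'
#' Dihedral angles by the standard atan2 construction on the three bond
#' vectors (minimum-image), in (-180, 180] degrees, emitted as (sin, cos)
#' pairs so the features are continuous across the wrap.
#'
#' @param traj a `trajectory`.
#' @param torsion_quads integer matrix (quads x 4) of atom indices.
#' @param labels optional torsion labels.
#' @return matrix (frames x 2 quads) with attribute `dt`; columns labelled
#'   `<label>_sin` / `<label>_cos`.
#' @export
featurize_torsions <- function(traj, torsion_quads, labels = NULL) {
  q <- rbind(torsion_quads)
  nq <- nrow(q)
  if (is.null(labels)) labels <- sprintf("tor%d", seq_len(nq))
  nf <- n_frames(traj)
  ang <- matrix(NA_real_, nf, nq)
  for (f in seq_len(nf)) {
    fr <- traj$frames[[f]]
    for (t in seq_len(nq)) {
      p <- fr$coords[q[t, ], , drop = FALSE]
      b1 <- minimum_image_displacement(p[1, ], p[2, ], fr$box)
      b2 <- minimum_image_displacement(p[2, ], p[3, ], fr$box)
      b3 <- minimum_image_displacement(p[3, ], p[4, ], fr$box)
      n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
              b1[1] * b2[2] - b1[2] * b2[1])
      n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
              b2[1] * b3[2] - b2[2] * b3[1])
      if (sum(n1^2) < 1e-14 || sum(n2^2) < 1e-14)
        stop("degenerate (collinear) torsion geometry in quad ", t)
      m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
              n1[1] * b2[2] - n1[2] * b2[1])
      b2n <- sqrt(sum(b2^2))
      ang[f, t] <- atan2(sum(m1 * n2) / b2n, sum(n1 * n2))
    }
  }
  feat <- matrix(NA_real_, nf, 2 * nq)
  feat[, seq(1, 2 * nq, 2)] <- sin(ang)
  feat[, seq(2, 2 * nq, 2)] <- cos(ang)
  colnames(feat) <- as.vector(rbind(paste0(labels, "_sin"),
                                    paste0(labels, "_cos")))
  attr(feat, "dt") <- if (nf > 1) diff(frame_times(traj))[1] else 1
  feat
}

#' Backbone phi/psi torsion quads for residue ranges
#'
#' Builds the standard phi (C-N-CA-C) and psi (N-CA-C-N) atom quadruples
#' for the requested residues from backbone atom names N/CA/C.
#'
#' @param top a `topology`.
#' @param resids residue numbers to include.
#' @param chain chain identifier.
#' @return list with `quads` (matrix) and `labels`.
#' @export
backbone_torsion_quads <- function(top, resids, chain = NULL) {
  a <- top$atoms
  chain_ok <- if (is.null(chain)) rep(TRUE, nrow(a)) else a$chain == chain
  pick <- function(res, nm) {
    hit <- which(a$resid == res & a$name == nm & chain_ok)
    if (length(hit) == 1) hit else NA_integer_
  }
  quads <- NULL
  labels <- character(0)
  for (r in resids) {
    phi <- c(pick(r - 1, "C"), pick(r, "N"), pick(r, "CA"), pick(r, "C"))
    psi <- c(pick(r, "N"), pick(r, "CA"), pick(r, "C"), pick(r + 1, "N"))
    if (!anyNA(phi)) {
      quads <- rbind(quads, phi)
      labels <- c(labels, sprintf("phi%d", r))
    }
    if (!anyNA(psi)) {
      quads <- rbind(quads, psi)
      labels <- c(labels, sprintf("psi%d", r))
    }
  }
  if (is.null(quads)) stop("no complete backbone torsions in the given range")
  rownames(quads) <- NULL
  list(quads = quads, labels = labels)
}

#' Convert torsion angles (degrees) to (sin, cos) features
#'
#' @param angles matrix (frames x torsions) in degrees.
#' @param dt frame spacing (ps), stored as an attribute.
#' @return feature matrix (frames x 2 torsions).
#' @export
angles_to_features <- function(angles, dt = 1) {
  angles <- rbind(angles)
  rad <- angles * pi / 180
  nq <- ncol(rad)
  feat <- matrix(NA_real_, nrow(rad), 2 * nq)
  feat[, seq(1, 2 * nq, 2)] <- sin(rad)
  feat[, seq(2, 2 * nq, 2)] <- cos(rad)
  attr(feat, "dt") <- dt
  feat
}

## ------------------------------------------------------------------ tICA ----

#' Fit time-lagged independent component analysis
#'
#' Solves the generalized eigenproblem `Ctau v = lambda (C0 + reg I) v`
#' with the mean-free instantaneous covariance `C0` and the symmetrized
#' lagged covariance `Ctau`; covariances never accumulate across
#' trajectory boundaries.  Components are sorted by decreasing eigenvalue;
#' the cumulative VAMP-2 score is `1 + sum lambda_i^2` (the leading +1 is
#' the constant singular function).
#'
#' @param features matrix (frames x features) or list of such matrices
#'   (one per trajectory).
#' @param lag lag time in frames.
#' @param n_components number of components kept (default: all).
#' @param reg ridge regularization added to `C0`.
#' @return object of class `"tica_model"`: list with `lag`, `means`,
#'   `eigenvalues`, `components` (features x k), `vamp2_scores`, `dt`.
#' @export
fit_tica <- function(features, lag, n_components = NULL, reg = 1e-8) {
  Xs <- .as_traj_list(features)
  dt <- attr(Xs[[1]], "dt")
  if (is.null(dt)) dt <- 1
  d <- ncol(Xs[[1]])
  npairs <- sum(vapply(Xs, function(x) max(0, nrow(x) - lag), numeric(1)))
  if (npairs < 10 * d)
    stop("need at least 10 x features usable (t, t+lag) pairs")
  mu <- colMeans(do.call(rbind, Xs))
  C0 <- matrix(0, d, d)
  Ct <- matrix(0, d, d)
  n0 <- 0
  for (X in Xs) {
    Xc <- sweep(X, 2, mu)
    C0 <- C0 + crossprod(Xc)
    n0 <- n0 + nrow(Xc)
    if (nrow(Xc) > lag) {
      A <- Xc[seq_len(nrow(Xc) - lag), , drop = FALSE]
      B <- Xc[(lag + 1):nrow(Xc), , drop = FALSE]
      Ct <- Ct + crossprod(A, B)
    }
  }
  C0 <- C0 / n0
  Ct <- (Ct + t(Ct)) / (2 * npairs)
  C0r <- C0 + reg * diag(d)
  R <- tryCatch(chol(C0r), error = function(e)
    stop("singular instantaneous covariance; increase reg"))
  Ri <- backsolve(R, diag(d))
  A <- t(Ri) %*% Ct %*% Ri
  es <- eigen((A + t(A)) / 2, symmetric = TRUE)
  comp <- Ri %*% es$vectors
  k <- if (is.null(n_components)) d else min(n_components, d)
  structure(list(lag = lag, means = mu,
                 eigenvalues = es$values[seq_len(k)],
                 components = comp[, seq_len(k), drop = FALSE],
                 vamp2_scores = 1 + cumsum(es$values[seq_len(k)]^2),
                 dt = dt),
            class = "tica_model")
}

#' Project features onto tICA components
#'
#' @param model a `tica_model`.
#' @param features matrix or list of matrices.
#' @return projection (frames x components), or list of such.
#' @export
project_tica <- function(model, features) {
  pr <- function(X) sweep(X, 2, model$means) %*% model$components
  if (is.list(features) && !is.data.frame(features))
    lapply(features, pr) else pr(features)
}

## --------------------------------------------------------------- k-means ----

#' Cluster projected frames into microstates
#'
#' k-means (Hartigan-Wong via [stats::kmeans()]) with multiple random
#' restarts, deterministic under a fixed seed.
#'
#' @param projected matrix (frames x ICs) or list of such matrices.
#' @param k number of microstates (default 100).
#' @param seed RNG seed.
#' @param n_init number of restarts; the best inertia wins.
#' @return list with `assignments` (vector, or list mirroring the input),
#'   `centers`, `inertia`.
#' @export
cluster_microstates <- function(projected, k = 100, seed = 1, n_init = 5) {
  Ys <- .as_traj_list(projected)
  Y <- do.call(rbind, Ys)
  ndist <- nrow(unique(Y))
  if (k > ndist)
    stop("k (", k, ") exceeds the number of distinct points (", ndist, ")")
  set.seed(seed)
  # Lloyd iterations: stable on large frame counts (Hartigan-Wong's
  # quick-transfer stage hits its internal cap there)
  km <- suppressWarnings(
    stats::kmeans(Y, centers = k, nstart = n_init, iter.max = 500,
                  algorithm = "Lloyd"))
  asg <- km$cluster
  if (length(Ys) > 1) {
    lens <- vapply(Ys, nrow, integer(1))
    asg <- split(asg, rep(seq_along(Ys), lens))
    names(asg) <- NULL
  }
  list(assignments = asg, centers = km$centers, inertia = km$tot.withinss)
}

## ------------------------------------------------------------------- MSM ----

#' Sliding-window transition count matrix
#'
#' @param assignments integer state vector, or list of vectors (counting
#'   never crosses list boundaries).
#' @param lag lag in frames.
#' @param n_states number of states (default: maximum label).
#' @return count matrix (n_states x n_states).
#' @export
transition_counts <- function(assignments, lag, n_states = NULL) {
  As <- .as_traj_list(assignments)
  if (is.null(n_states)) n_states <- max(unlist(As))
  C <- matrix(0, n_states, n_states)
  for (a in As) {
    if (length(a) <= lag) next
    from <- a[seq_len(length(a) - lag)]
    to <- a[(lag + 1):length(a)]
    tab <- table(factor(from, seq_len(n_states)),
                 factor(to, seq_len(n_states)))
    C <- C + matrix(as.numeric(tab), n_states, n_states)
  }
  unname(C)
}

# Connected components of a symmetric adjacency matrix (BFS).
.components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[u, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Estimate a reversible Markov state model
#'
#' Sliding-window counts are symmetrized, `Cbar = (C + C^T)/2`, and row
#' normalized; the stationary distribution is then proportional to the row
#' sums of `Cbar`, which makes the model exactly stationary and
#' detailed-balanced by construction.  States outside the largest
#' connected component of the symmetrized count graph are dropped with a
#' message.
#'
#' @param assignments state vector or list of vectors.
#' @param lag lag in frames.
#' @param dt frame spacing (ps).
#' @param n_states total number of state labels.
#' @return object of class `"msm_model"`: list with `lag`, `dt`,
#'   `transition_matrix`, `stationary`, `eigenvalues`,
#'   `implied_timescales` (ps), `active_states` (original labels kept),
#'   `counts`.
#' @export
estimate_msm <- function(assignments, lag, dt = 1, n_states = NULL) {
  C <- transition_counts(assignments, lag, n_states)
  Cs <- (C + t(C)) / 2
  nz <- rowSums(Cs) > 0
  comp <- rep(NA_integer_, nrow(Cs))
  comp[nz] <- .components((Cs > 0)[nz, nz, drop = FALSE])
  largest <- which.max(tabulate(comp))
  active <- which(!is.na(comp) & comp == largest)
  if (length(active) < sum(nz))
    message("dropping ", sum(nz) - length(active),
            " state(s) outside the largest connected component")
  Cs <- Cs[active, active, drop = FALSE]
  rs <- rowSums(Cs)
  T_ <- Cs / rs
  pi_ <- rs / sum(rs)
  # reversible -> symmetrizable -> real spectrum
  S <- diag(sqrt(pi_)) %*% T_ %*% diag(1 / sqrt(pi_))
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)$values
  lam <- sort(ev, decreasing = TRUE)
  inner <- lam[lam < 1 - 1e-12 & lam > 1e-12]
  structure(list(lag = lag, dt = dt, transition_matrix = T_,
                 stationary = pi_, eigenvalues = lam,
                 implied_timescales = -lag * dt / log(inner),
                 active_states = active, counts = C),
            class = "msm_model")
}

#' Right eigenvectors of a reversible MSM
#'
#' @param msm an `msm_model`.
#' @param k number of eigenpairs.
#' @return list with `values` and `vectors` (right eigenvectors, columns
#'   sorted by decreasing eigenvalue; the first is constant).
#' @export
msm_eigen <- function(msm, k = length(msm$stationary)) {
  pi_ <- msm$stationary
  S <- diag(sqrt(pi_)) %*% msm$transition_matrix %*% diag(1 / sqrt(pi_))
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  V <- diag(1 / sqrt(pi_)) %*% es$vectors
  # normalize sign and scale: first eigenvector exactly 1
  V[, 1] <- V[, 1] / V[1, 1]
  list(values = es$values[seq_len(k)], vectors = V[, seq_len(k), drop = FALSE])
}

#' Implied timescales over a set of lag times
#'
#' @param assignments state vector or list of vectors.
#' @param lags lag times in frames.
#' @param dt frame spacing (ps).
#' @param n_its number of timescales reported.
#' @param n_boot bootstrap resamples (0 = none); resampling is over
#'   trajectories, or over 10 contiguous blocks for a single trajectory.
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with columns `lag`, `its1..n` and, with bootstrap,
#'   `its<i>_lo` / `its<i>_hi` (2.5/97.5 percentiles).
#' @export
compute_implied_timescales <- function(assignments, lags, dt = 1,
                                       n_its = 5, n_boot = 0, seed = 1) {
  As <- .as_traj_list(assignments)
  maxlen <- max(vapply(As, length, integer(1)))
  if (any(lags >= maxlen)) stop("lag beyond trajectory length")
  n_states <- max(unlist(As))
  one <- function(traj_list, lag) {
    m <- estimate_msm(traj_list, lag, dt, n_states)
    its <- m$implied_timescales
    out <- rep(NA_real_, n_its)
    out[seq_len(min(n_its, length(its)))] <- its[seq_len(min(n_its,
                                                             length(its)))]
    out
  }
  blocks <- if (length(As) > 1) As else {
    n <- length(As[[1]])
    split(As[[1]], ceiling(seq_len(n) / ceiling(n / 10)))
  }
  res <- NULL
  for (lag in lags) {
    row <- c(lag = lag, stats::setNames(one(As, lag),
                                        paste0("its", seq_len(n_its))))
    if (n_boot > 0) {
      set.seed(seed)
      bs <- replicate(n_boot, {
        pick <- sample(length(blocks), replace = TRUE)
        tryCatch(one(blocks[pick], lag), error = function(e)
          rep(NA_real_, n_its))
      })
      bs <- matrix(bs, nrow = n_its)
      lo <- apply(bs, 1, stats::quantile, 0.025, na.rm = TRUE)
      hi <- apply(bs, 1, stats::quantile, 0.975, na.rm = TRUE)
      row <- c(row, stats::setNames(lo, paste0("its", seq_len(n_its), "_lo")),
               stats::setNames(hi, paste0("its", seq_len(n_its), "_hi")))
    }
    res <- rbind(res, row)
  }
  out <- as.data.frame(res)
  rownames(out) <- NULL
  out
}

## ----------------------------------------------------------------- PCCA+ ----

#' PCCA+ macrostate memberships
#'
#' Inner-simplex construction on the top `n_macro` right eigenvectors of
#' the transition matrix: the most extreme microstate seeds the first
#' vertex, subsequent vertices are the points farthest from the span of
#' the chosen ones, memberships follow from the linear transform onto that
#' simplex, clipped at zero and renormalized.  Crisp labels are the argmax
#' (ties to the lowest macrostate index).
#'
#' @param msm an `msm_model`.
#' @param n_macro number of macrostates.
#' @return object of class `"macrostate_model"`: list with `membership`
#'   (micro x macro, rows sum to 1), `crisp` (macro label per microstate),
#'   `n_macro`.
#' @export
pcca_macrostates <- function(msm, n_macro) {
  n <- length(msm$stationary)
  if (n_macro > n) stop("n_macro exceeds the number of microstates")
  if (n_macro < 2) stop("n_macro must be at least 2")
  X <- msm_eigen(msm, n_macro)$vectors
  # inner-simplex vertex search
  ind <- integer(n_macro)
  Xc <- X
  ind[1] <- which.max(rowSums(Xc^2))
  Xc <- sweep(Xc, 2, Xc[ind[1], ])
  for (k in seq_len(n_macro - 1) + 1) {
    ind[k] <- which.max(rowSums(Xc^2))
    v <- Xc[ind[k], ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stop("degenerate eigenvector geometry in PCCA+")
    v <- v / nv
    Xc <- Xc - (Xc %*% v) %*% t(v)
  }
  A <- solve(X[ind, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  crisp <- apply(chi, 1, which.max)  # which.max ties -> lowest index
  structure(list(membership = chi, crisp = crisp, n_macro = n_macro),
            class = "macrostate_model")
}

## --------------------------------------------------------------- CK test ----

# Coarse-grain a transition matrix onto crisp macrostates, pi-weighted.
.coarse_grain <- function(T_, pi_, crisp, n_macro) {
  P <- matrix(0, n_macro, n_macro)
  w <- numeric(n_macro)
  for (A in seq_len(n_macro)) {
    ia <- which(crisp == A)
    w[A] <- sum(pi_[ia])
    for (B in seq_len(n_macro)) {
      ib <- which(crisp == B)
      if (length(ia) > 0 && length(ib) > 0)
        P[A, B] <- sum(pi_[ia] * rowSums(T_[ia, ib, drop = FALSE])) / w[A]
    }
  }
  P
}

.mat_pow <- function(M, k) {
  R <- diag(nrow(M))
  for (i in seq_len(k)) R <- R %*% M
  R
}

#' Chapman-Kolmogorov test on macrostates
#'
#' For each macrostate A and lag multiple k, compares the predicted
#' self-transition probability `[coarse(T(tau))^k]_AA` with the estimated
#' `[coarse(T(k tau))]_AA`; a bootstrap over trajectories (or contiguous
#' blocks of a single trajectory) gives the 95% interval on the estimate.
#' The test passes when every prediction lies inside its interval.
#'
#' @param assignments state vector or list of vectors.
#' @param msm the `msm_model` at the base lag.
#' @param macro a `macrostate_model` for `msm`.
#' @param factors lag multiples k to test.
#' @param n_boot bootstrap resamples (default 100).
#' @param seed bootstrap RNG seed.
#' @return object of class `"ck_report"`: data.frame with columns
#'   `macrostate`, `k`, `predicted`, `estimated`, `lo`, `hi`; attribute
#'   `pass`.
#' @export
ck_test <- function(assignments, msm, macro, factors = c(2, 3, 5),
                    n_boot = 100, seed = 1) {
  As <- .as_traj_list(assignments)
  n_states <- max(unlist(As))
  n_macro <- macro$n_macro
  # crisp labels on the full label space (inactive states -> nearest = NA)
  crisp_full <- rep(NA_integer_, n_states)
  crisp_full[msm$active_states] <- macro$crisp
  P1 <- .coarse_grain(msm$transition_matrix, msm$stationary, macro$crisp,
                      n_macro)
  est_at <- function(traj_list, lag) {
    m <- estimate_msm(traj_list, lag, msm$dt, n_states)
    cr <- crisp_full[m$active_states]
    keep <- !is.na(cr)
    Tm <- m$transition_matrix[keep, keep, drop = FALSE]
    Tm <- Tm / rowSums(Tm)
    diag(.coarse_grain(Tm, m$stationary[keep] / sum(m$stationary[keep]),
                       cr[keep], n_macro))
  }
  blocks <- if (length(As) > 1) As else {
    n <- length(As[[1]])
    split(As[[1]], ceiling(seq_len(n) / ceiling(n / 10)))
  }
  rows <- NULL
  for (k in factors) {
    predicted <- diag(.mat_pow(P1, k))
    estimated <- est_at(As, k * msm$lag)
    set.seed(seed + k)
    bs <- replicate(n_boot, {
      pick <- sample(length(blocks), replace = TRUE)
      tryCatch(est_at(blocks[pick], k * msm$lag),
               error = function(e) rep(NA_real_, n_macro))
    })
    bs <- matrix(bs, nrow = n_macro)
    lo <- apply(bs, 1, stats::quantile, 0.025, na.rm = TRUE)
    hi <- apply(bs, 1, stats::quantile, 0.975, na.rm = TRUE)
    rows <- rbind(rows, data.frame(macrostate = seq_len(n_macro), k = k,
                                   predicted = predicted,
                                   estimated = estimated,
                                   lo = lo, hi = hi))
  }
  rownames(rows) <- NULL
  pass <- all(rows$predicted >= rows$lo - 1e-12 &
                rows$predicted <= rows$hi + 1e-12)
  structure(rows, class = c("ck_report", "data.frame"), pass = pass)
}

## --------------------------------------------------------- reweighted FES ----

#' MSM-reweighted free-energy surface
#'
#' Each frame is weighted by `pi(cluster) / count(cluster)` so that the
#' histogram reflects the MSM stationary distribution rather than raw
#' sampling; frames in states dropped from the MSM get weight zero.
#' Delegates to [compute_fes_2d()].
#'
#' @param projected matrix (frames x 2) of IC coordinates, or list.
#' @param assignments microstate labels matching `projected`.
#' @param msm an `msm_model`.
#' @param x_edges,y_edges bin edges.
#' @return an `fes_grid`.
#' @export
reweighted_fes <- function(projected, assignments, msm, x_edges, y_edges) {
  Y <- do.call(rbind, .as_traj_list(projected))
  a <- unlist(.as_traj_list(assignments))
  stopifnot(nrow(Y) == length(a))
  w <- numeric(length(a))
  counts <- tabulate(a, max(a))
  for (s in seq_along(msm$active_states)) {
    lab <- msm$active_states[s]
    w[a == lab] <- msm$stationary[s] / counts[lab]
  }
  w <- w / sum(w)
  compute_fes_2d(Y, x_edges, y_edges, weights = w)
}
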
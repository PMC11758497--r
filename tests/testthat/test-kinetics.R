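test_that("torsion featurization: trans geometry, rigid invariance, width", {
  top <- simple_topology(4)
  # planar anti (trans) arrangement
  co <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  tr <- traj_from_coords(top, list(co), box = c(10, 10, 10))
  f <- featurize_torsions(tr, rbind(1:4))
  expect_equal(ncol(f), 2)
  expect_equal(as.numeric(f), c(0, -1), tolerance = 1e-12)
  # a gauche-like configuration is invariant under rigid motion
  co2 <- rbind(c(0.3, 1, 0.2), c(0, 0, 0), c(1, 0, 0), c(1.2, -0.8, 0.7))
  tr2 <- traj_from_coords(top, list(co2), box = c(10, 10, 10))
  f2 <- featurize_torsions(tr2, rbind(1:4))
  set.seed(71)
  th <- runif(1, 0, 2 * pi)
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr3 <- traj_from_coords(top, list(co2 %*% t(Q) +
                                      rep(1, 4) %o% c(1, 2, 0.5)),
                          box = c(10, 10, 10))
  f3 <- featurize_torsions(tr3, rbind(1:4))
  expect_equal(f3, f2, tolerance = 1e-10)
  # n quads -> 2n features
  f4 <- featurize_torsions(tr2, rbind(1:4, 4:1))
  expect_equal(ncol(f4), 4)
  # collinear geometry errors
  col <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  trc <- traj_from_coords(top, list(col), box = c(10, 10, 10))
  expect_error(featurize_torsions(trc, rbind(1:4)), "degenerate")
})

test_that("tICA separates slow from fast sources and bounds eigenvalues", {
  set.seed(72)
  n <- 30000
  z1 <- numeric(n); z2 <- numeric(n)
  for (t in 2:n) {
    z1[t] <- 0.99 * z1[t - 1] + rnorm(1) * sqrt(1 - 0.99^2)
    z2[t] <- 0.60 * z2[t - 1] + rnorm(1) * sqrt(1 - 0.60^2)
  }
  M <- matrix(rnorm(8), 2, 4)
  X <- cbind(z1, z2) %*% M + matrix(rnorm(4 * n, sd = 0.05), n, 4)
  attr(X, "dt") <- 1
  tica <- fit_tica(X, lag = 5, n_components = 2)
  expect_true(all(tica$eigenvalues <= 1 + 1e-6 &
                    tica$eigenvalues >= -1 - 1e-6))
  y1 <- project_tica(tica, X)[, 1]
  expect_gt(abs(cor(y1, z1)), 0.95)
  # IC1 lag autocorrelation approximates its eigenvalue
  ac <- cor(y1[1:(n - 5)], y1[6:n])
  expect_equal(ac, tica$eigenvalues[1], tolerance = 0.05)
  # white noise: all eigenvalues near zero
  W <- matrix(rnorm(4 * 20000), ncol = 4)
  attr(W, "dt") <- 1
  tw <- fit_tica(W, lag = 5)
  expect_true(all(abs(tw$eigenvalues) < 0.05))
  # VAMP-2 includes the constant singular function
  expect_equal(tica$vamp2_scores[1], 1 + tica$eigenvalues[1]^2)
})

test_that("microstate clustering recovers well-separated blobs", {
  set.seed(73)
  Y <- rbind(matrix(rnorm(2000, 0, 0.1), ncol = 2),
             matrix(rnorm(2000, 5, 0.1), ncol = 2))
  truth <- rep(1:2, each = 1000)
  cl <- cluster_microstates(Y, k = 2, seed = 1, n_init = 3)
  agree <- max(mean(cl$assignments == truth),
               mean(3 - cl$assignments == truth))
  expect_gte(agree, 0.99)
  cl1 <- cluster_microstates(Y, k = 1, seed = 1)
  expect_true(all(cl1$assignments == 1))
  expect_equal(cl1$inertia,
               sum(sweep(Y, 2, colMeans(Y))^2), tolerance = 1e-8)
  expect_error(cluster_microstates(rbind(c(1, 1), c(1, 1)), k = 3),
               "distinct points")
  # duplicated points cluster stably
  cld <- cluster_microstates(rbind(Y, Y[1:5, ]), k = 2, seed = 2)
  expect_equal(cld$assignments[nrow(Y) + 1:5], cld$assignments[1:5])
})

test_that("MSM estimation matches the brute-force count oracle exactly", {
  set.seed(74)
  for (rep in 1:3) {
    a <- sample(1:5, 1000, replace = TRUE)
    lag <- sample(1:4, 1)
    C <- transition_counts(a, lag, 5)
    expect_identical(C, oracle_counts(a, lag, 5))
    msm <- estimate_msm(a, lag)
    Cs <- (C + t(C)) / 2
    expect_equal(msm$transition_matrix, Cs / rowSums(Cs), tolerance = 1e-14)
    # detailed balance by construction
    db <- outer(msm$stationary, rep(1, 5)) * msm$transition_matrix
    expect_lt(max(abs(db - t(db))), 1e-12)
    expect_equal(sum(msm$stationary), 1, tolerance = 1e-12)
    expect_equal(rowSums(msm$transition_matrix), rep(1, 5),
                 tolerance = 1e-12)
  }
  # counting never crosses trajectory boundaries
  C2 <- transition_counts(list(c(1, 2), c(2, 1)), 1, 2)
  expect_equal(C2, rbind(c(0, 1), c(1, 0)))
})

test_that("implied timescales invert eigenvalues and stay flat in lag", {
  P <- matrix(c(0.98, 0.02, 0.02, 0.98), 2, 2)
  g <- make_markov_feature_trajectories(P, matrix(c(-90, 90), 2, 1),
                                        noise_sd = 0, n_frames = 50000,
                                        seed = 75)
  msm <- estimate_msm(g$states, lag = 1, dt = 1)
  expect_equal(msm$implied_timescales[1], -1 / log(0.96), tolerance = 0.2)
  its <- compute_implied_timescales(g$states, lags = c(1, 2, 5, 10),
                                    n_its = 1)
  expect_true(all(abs(its$its1 - its$its1[1]) / its$its1[1] < 0.25))
  expect_error(compute_implied_timescales(g$states, lags = 1e6),
               "lag beyond")
  # single-state data: no finite timescales
  m1 <- estimate_msm(rep(1L, 100), lag = 1)
  expect_length(m1$implied_timescales, 0)
})

test_that("PCCA+ memberships resolve metastable blocks", {
  # two metastable blocks with weak coupling
  T0 <- rbind(c(0.899, 0.1, 0.001, 0),
              c(0.1, 0.899, 0, 0.001),
              c(0.001, 0, 0.899, 0.1),
              c(0, 0.001, 0.1, 0.899))
  pi0 <- rep(0.25, 4)
  msm <- structure(list(lag = 1, dt = 1, transition_matrix = T0,
                        stationary = pi0,
                        active_states = 1:4), class = "msm_model")
  mac <- pcca_macrostates(msm, 2)
  expect_equal(rowSums(mac$membership), rep(1, 4), tolerance = 1e-9)
  expect_true(all(mac$membership >= 0))
  expect_equal(mac$crisp[1], mac$crisp[2])
  expect_equal(mac$crisp[3], mac$crisp[4])
  expect_false(mac$crisp[1] == mac$crisp[3])
  # n_macro = n_micro: memberships are a permutation of identity
  mac4 <- pcca_macrostates(msm, 4)
  expect_equal(sort(mac4$crisp), 1:4)
  expect_equal(mac4$membership[cbind(1:4, mac4$crisp)], rep(1, 4),
               tolerance = 1e-8)
  expect_error(pcca_macrostates(msm, 9), "exceeds")
})

test_that("CK test: identity at k=1, pass for Markovian, fail for cycle", {
  P <- four_state_chain()
  g <- make_markov_feature_trajectories(P, four_state_means(),
                                        noise_sd = 0, n_frames = 60000,
                                        seed = 76)
  msm <- estimate_msm(g$states, lag = 5)
  # identity macrostates (one per microstate)
  mac <- structure(list(membership = diag(4), crisp = 1:4, n_macro = 4),
                   class = "macrostate_model")
  ck1 <- ck_test(g$states, msm, mac, factors = 1, n_boot = 10)
  expect_equal(ck1$predicted, ck1$estimated, tolerance = 1e-12)
  ck <- ck_test(g$states, msm, mac, factors = c(2, 3, 5), n_boot = 50)
  expect_true(attr(ck, "pass"))
  # deterministic period-3 cycle is strongly non-Markovian at k = 2
  cyc <- rep(1:3, length.out = 3000)
  mcyc <- estimate_msm(cyc, lag = 1)
  mac3 <- structure(list(membership = diag(3), crisp = 1:3, n_macro = 3),
                    class = "macrostate_model")
  ck3 <- ck_test(cyc, mcyc, mac3, factors = 2, n_boot = 20)
  expect_false(attr(ck3, "pass"))
  expect_equal(ck3$predicted, rep(0.5, 3), tolerance = 1e-3)
  expect_equal(ck3$estimated, rep(0, 3), tolerance = 1e-3)
})

test_that("stationary reweighting of the FES follows the MSM weights", {
  # frames evenly split between two clusters at distinct grid positions
  Y <- rbind(matrix(rep(c(0.5, 0.5), 100), ncol = 2, byrow = TRUE),
             matrix(rep(c(1.5, 0.5), 100), ncol = 2, byrow = TRUE))
  a <- rep(1:2, each = 100)
  msm <- structure(list(lag = 1, dt = 1,
                        transition_matrix = rbind(c(0.9, 0.1),
                                                  c(0.9, 0.1)),
                        stationary = c(0.9, 0.1), active_states = 1:2),
                   class = "msm_model")
  fes <- reweighted_fes(Y, a, msm, 0:2, 0:1)
  expect_equal(fes$free_energy[2, 1] - fes$free_energy[1, 1], log(9),
               tolerance = 1e-9)
  # uniform stationary + equal counts = unweighted FES
  msmu <- msm
  msmu$stationary <- c(0.5, 0.5)
  fesu <- reweighted_fes(Y, a, msmu, 0:2, 0:1)
  fes0 <- compute_fes_2d(Y, 0:2, 0:1)
  expect_equal(fesu$free_energy, fes0$free_energy, tolerance = 1e-12)
})

test_that("backbone torsion quads are assembled from N/CA/C atoms", {
  atoms <- do.call(rbind, lapply(1:4, function(r)
    data.frame(name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
               resid = r, resname = "ALA", chain = "A",
               stringsAsFactors = FALSE)))
  top <- topology(atoms, water_groups = NULL)
  bt <- backbone_torsion_quads(top, 2:3)
  expect_equal(length(bt$labels), 4)  # phi2, psi2, phi3, psi3
  expect_true(all(c("phi2", "psi3") %in% bt$labels))
  phi2 <- bt$quads[bt$labels == "phi2", ]
  expect_equal(top$atoms$name[phi2], c("C", "N", "CA", "C"))
  expect_equal(top$atoms$resid[phi2], c(1, 2, 2, 2))
})
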
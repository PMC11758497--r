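test_that("charge mapping is name-keyed and validated", {
  toy <- make_toy_chromophore_pair()
  m <- map_charges(toy$setA, toy$topology, toy$selA)
  expect_equal(m$indices, c(1L, 2L))
  expect_equal(m$charges, toy$setA$charges)
  bad <- transition_charge_set("x", c("PA1", "NOPE"), c(0.1, -0.1))
  expect_error(map_charges(bad, toy$topology, toy$selA), "NOPE")
  # permuted topology: identical mapping by name
  perm <- c(2, 1, 4, 3)
  top2 <- topology(toy$topology$atoms[perm, ], water_groups = NULL)
  sel2 <- select_atoms(top2, resname = "PGA")
  m2 <- map_charges(toy$setA, top2, sel2)
  expect_equal(top2$atoms$name[m2$indices], toy$setA$atom_names)
})

test_that("Coulomb constant and point-charge coupling to six figures", {
  e <- 1.602176634e-19
  eps0 <- 8.8541878128e-12
  hc <- 6.62607015e-34 * 2.99792458e8
  # energy of two unit charges at 1 nm, in cm^-1
  K_ref <- e^2 / (4 * pi * eps0 * 1e-9) / hc / 100
  expect_equal(tresp_coulomb_constant(), K_ref, tolerance = 1e-6)
  top <- simple_topology(2, name = c("Q1", "Q2"))
  fr <- frame(rbind(c(0, 0, 0), c(0, 0, 1)), c(50, 50, 50))
  mA <- structure(list(indices = 1L, charges = 1), class = "charge_mapping")
  mB <- structure(list(indices = 2L, charges = 1), class = "charge_mapping")
  expect_equal(compute_coupling(fr, mA, mB), K_ref, tolerance = 1e-6)
})

test_that("in-line dipole pair matches the exact Coulomb closed form", {
  d <- 0.1; q <- 0.1; R <- 1
  toy <- make_toy_chromophore_pair(dipole_moment = q * d,
                                   charge_separation = d)
  mA <- map_charges(toy$setA, toy$topology, toy$selA)
  mB <- map_charges(toy$setB, toy$topology, toy$selB)
  V <- compute_coupling(toy$frame, mA, mB)
  K <- tresp_coulomb_constant()
  exact <- K * q^2 * (2 / R - 1 / (R - d) - 1 / (R + d))
  expect_equal(V, exact, tolerance = 1e-12)
  # ideal-dipole form (kappa = -2) converges: 0.45% deviation at R = 15 d
  toy15 <- make_toy_chromophore_pair(
    dipole_moment = q * d, charge_separation = d,
    placement = list(list(center = c(0, 0, 0), direction = c(0, 0, 1)),
                     list(center = c(0, 0, 1.5), direction = c(0, 0, 1))))
  V15 <- compute_coupling(toy15$frame,
                          map_charges(toy15$setA, toy15$topology, toy15$selA),
                          map_charges(toy15$setB, toy15$topology, toy15$selB))
  ideal15 <- -2 * (q * d)^2 / 1.5^3 * K
  expect_lt(abs(V15 - ideal15) / abs(ideal15), 0.01)
})

test_that("side-by-side dipole pair is within 1% of the ideal form at 10x", {
  d <- 0.1; q <- 0.1; R <- 1
  toy <- make_toy_chromophore_pair(
    dipole_moment = q * d, charge_separation = d,
    placement = list(list(center = c(0, 0, 0), direction = c(0, 0, 1)),
                     list(center = c(R, 0, 0), direction = c(0, 0, 1))))
  V <- compute_coupling(toy$frame,
                        map_charges(toy$setA, toy$topology, toy$selA),
                        map_charges(toy$setB, toy$topology, toy$selB))
  ideal <- (q * d)^2 / R^3 * tresp_coulomb_constant()  # kappa = +1
  expect_lt(abs(V - ideal) / ideal, 0.01)
})

test_that("coupling symmetry, linearity, and far-field dipole scaling", {
  toy <- make_toy_chromophore_pair()
  mA <- map_charges(toy$setA, toy$topology, toy$selA)
  mB <- map_charges(toy$setB, toy$topology, toy$selB)
  expect_identical(compute_coupling(toy$frame, mA, mB),
                   compute_coupling(toy$frame, mB, mA))
  m2 <- mA; m2$charges <- 2 * m2$charges
  expect_equal(compute_coupling(toy$frame, m2, mB),
               2 * compute_coupling(toy$frame, mA, mB))
  # rigid rotation + translation invariance
  set.seed(61)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  Q <- Rz %*% Rx
  fr2 <- frame(toy$frame$coords %*% t(Q) + rep(1, 4) %o% c(2, 3, 4),
               toy$frame$box)
  expect_equal(compute_coupling(fr2, mA, mB),
               compute_coupling(toy$frame, mA, mB), tolerance = 1e-9)
  # |V| R^3 approaches the ideal-dipole constant from below 5d to 50d
  d <- 0.1; q <- 0.1
  K <- tresp_coulomb_constant()
  for (R in c(0.5, 1, 2, 5)) {
    t2 <- make_toy_chromophore_pair(
      dipole_moment = q * d, charge_separation = d,
      placement = list(list(center = c(0, 0, 0), direction = c(0, 0, 1)),
                       list(center = c(0, 0, R), direction = c(0, 0, 1))))
    V <- compute_coupling(t2$frame,
                          map_charges(t2$setA, t2$topology, t2$selA),
                          map_charges(t2$setB, t2$topology, t2$selB))
    expect_equal(abs(V) * R^3, 2 * (q * d)^2 * K,
                 tolerance = (d / R)^2 / (1 - (d / R)^2) + 1e-9)
  }
  # overlapping pigments are rejected
  tov <- make_toy_chromophore_pair(
    placement = list(list(center = c(0, 0, 0), direction = c(0, 0, 1)),
                     list(center = c(0, 0, 0.12), direction = c(0, 0, 1))))
  expect_error(compute_coupling(
    tov$frame, map_charges(tov$setA, tov$topology, tov$selA),
    map_charges(tov$setB, tov$topology, tov$selB)), "0.05 nm")
})

test_that("protonation switching latches at the threshold crossing", {
  # pigments fixed; a probe atom approaches the target then retreats
  atoms <- data.frame(
    name = c("PA1", "PA2", "PB1", "PB2", "PRB", "TGT"),
    element = "C", resid = c(1, 1, 2, 2, 3, 4),
    resname = c("PGA", "PGA", "PGB", "PGB", "PRB", "TGT"),
    chain = "A", stringsAsFactors = FALSE)
  top <- topology(atoms, water_groups = NULL)
  base <- rbind(c(0, 0, -0.05), c(0, 0, 0.05), c(0, 0, 0.95), c(0, 0, 1.05),
                c(5, 5, 5), c(5, 5, 0))
  probe_z <- c(5, 3, 0.4, 2, 5)  # crosses 0.5 nm at frame 3, then retreats
  frames <- lapply(seq_along(probe_z), function(i) {
    co <- base
    co[5, ] <- c(5, 5, probe_z[i])
    co
  })
  tr <- traj_from_coords(top, frames, box = c(20, 20, 20))
  dep <- transition_charge_set("dep", c("PA1", "PA2"), c(-0.1, 0.1),
                               "deprotonated")
  pro <- transition_charge_set("pro", c("PA1", "PA2"), c(-0.05, 0.05),
                               "protonated")
  setB <- transition_charge_set("B", c("PB1", "PB2"), c(-0.1, 0.1))
  pigA <- list(selection = select_atoms(top, resname = "PGA"),
               sets = list(protonated = pro, deprotonated = dep))
  pigB <- list(selection = select_atoms(top, resname = "PGB"), set = setB)
  sw <- list(pigment = "A", probe = select_atoms(top, name = "PRB"),
             target = select_atoms(top, name = "TGT"), threshold = 0.5)
  cs <- compute_coupling_series(tr, pigA, pigB, switch = sw)
  expect_equal(cs$state, c("deprotonated", "deprotonated", "protonated",
                           "protonated", "protonated"))
  expect_equal(cs$V[4], cs$V[1] / 2, tolerance = 1e-12)
  expect_equal(cs$abs_V, abs(cs$V))
  # frame-wise mode releases after the retreat
  csf <- compute_coupling_series(tr, pigA, pigB, switch = sw, latch = FALSE)
  expect_equal(csf$state, c("deprotonated", "deprotonated", "protonated",
                            "deprotonated", "deprotonated"))
  # probe never approaching leaves everything deprotonated
  tr0 <- traj_from_coords(top, list(base, base), box = c(20, 20, 20))
  cs0 <- compute_coupling_series(tr0, pigA, pigB, switch = sw)
  expect_true(all(cs0$state == "deprotonated"))
  # identical sets for both states: series independent of switching
  pigA2 <- list(selection = select_atoms(top, resname = "PGA"),
                sets = list(protonated = dep, deprotonated = dep))
  csi <- compute_coupling_series(tr, pigA2, pigB, switch = sw)
  csn <- compute_coupling_series(tr, list(selection = pigA2$selection,
                                          set = dep), pigB)
  expect_equal(csi$V, csn$V)
  # switch rule without both sets errors
  expect_error(compute_coupling_series(
    tr, list(selection = pigA$selection, sets = list(deprotonated = dep)),
    pigB, switch = sw), "both protonated and deprotonated")
})

test_that("charge sets round-trip through JSON and delimited text", {
  s <- transition_charge_set("chl", c("MG", "NA1"), c(0.02, -0.02),
                             "protonated")
  pj <- tempfile(fileext = ".json")
  jsonlite::write_json(list(label = s$label, atom_names = s$atom_names,
                            charges = s$charges, state_tag = s$state_tag),
                       pj, digits = NA, auto_unbox = TRUE)
  s2 <- read_charge_set(pj)
  expect_equal(s2$charges, s$charges)
  expect_equal(s2$state_tag, "protonated")
  pt <- tempfile(fileext = ".txt")
  writeLines(c("MG 0.02", "NA1 -0.02"), pt)
  s3 <- read_charge_set(pt)
  expect_equal(s3$atom_names, c("MG", "NA1"))
  expect_equal(s3$charges, c(0.02, -0.02))
})
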
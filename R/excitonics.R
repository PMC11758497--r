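## TrESP excitonic couplings: Coulomb sums over atomic transition charges
## of two pigments, with optional protonation-state-dependent switching of
## the active charge set along a trajectory.

# Coulomb constant e^2/(4 pi eps0) expressed in cm^-1 nm e^-2:
# e = 1.602176634e-19 C, eps0 = 8.8541878128e-12 F/m gives
# e^2/(4 pi eps0) = 1.439964548 eV nm; 1 eV = 8065.543937 cm^-1.
.TRESP_K <- 1.439964548 * 8065.543937  # ~11613.1 cm^-1 nm / e^2

#' Coulomb constant for TrESP couplings
#'
#' `e^2 / (4 pi eps0)` in cm^-1 nm per squared elementary charge.
#' @return numeric scalar.
#' @export
tresp_coulomb_constant <- function() .TRESP_K

#' Read a transition-charge set from file
#'
#' Accepts JSON (`label`, `atom_names`, `charges`, `state_tag`) or
#' two-column delimited text (atom name, charge in e).
#'
#' @param path file path.
#' @param label label for delimited input (default: file name).
#' @param state_tag state tag for delimited input.
#' @return a [transition_charge_set()].
#' @export
read_charge_set <- function(path, label = basename(path),
                            state_tag = "none") {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(transition_charge_set(j$label, j$atom_names, j$charges,
                                 if (is.null(j$state_tag)) "none"
                                 else j$state_tag))
  }
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("atom_name", "charge"),
                           stringsAsFactors = FALSE)
  transition_charge_set(label, tab$atom_name, tab$charge, state_tag)
}

#' Map a transition-charge set onto a pigment selection
#'
#' Charges are matched to atoms by name within the selection; the mapping
#' is independent of topology storage order.  Every charge-set name must
#' match exactly one selected atom.
#'
#' @param set a `transition_charge_set`.
#' @param top a `topology`.
#' @param pigment atom selection for the pigment.
#' @return object of class `"charge_mapping"`: list with `indices`
#'   (topology atom indices) and `charges`.
#' @export
map_charges <- function(set, top, pigment) {
  nm <- top$atoms$name[pigment]
  idx <- integer(length(set$atom_names))
  for (i in seq_along(set$atom_names)) {
    hit <- which(nm == set$atom_names[i])
    if (length(hit) == 0)
      stop("charge-set atom name not found in pigment selection: ",
           set$atom_names[i])
    if (length(hit) > 1)
      stop("charge-set atom name matches multiple atoms: ",
           set$atom_names[i])
    idx[i] <- pigment[hit]
  }
  structure(list(indices = idx, charges = set$charges,
                 state_tag = set$state_tag, label = set$label),
            class = "charge_mapping")
}

#' TrESP excitonic coupling for one frame
#'
#' `V = f K sum_ij q_i q_j / r_ij` over all charge pairs of the two
#' pigments, with charges in e, minimum-image distances in nm, and `K`
#' the Coulomb constant in cm^-1 nm e^-2.  No dielectric screening is
#' applied by default (`screening = 1`).
#'
#' @param fr a `traj_frame`.
#' @param mapA,mapB `charge_mapping` objects for disjoint atom sets.
#' @param screening multiplicative screening factor f.
#' @return coupling in cm^-1.
#' @export
compute_coupling <- function(fr, mapA, mapB, screening = 1) {
  if (length(intersect(mapA$indices, mapB$indices)) > 0)
    stop("pigment atom sets must be disjoint")
  xa <- fr$coords[mapA$indices, , drop = FALSE]
  xb <- fr$coords[mapB$indices, , drop = FALSE]
  V <- 0
  for (i in seq_len(nrow(xa))) {
    r <- .mi_dist(xa[i, ], xb, fr$box)
    if (any(r < 0.05))
      stop("pigments overlap: pair distance below 0.05 nm; TrESP invalid")
    V <- V + sum(mapA$charges[i] * mapB$charges / r)
  }
  screening * .TRESP_K * V
}

#' TrESP coupling series with protonation-state switching
#'
#' Computes the coupling for every frame.  When a switch rule is given,
#' the switched pigment uses its "deprotonated" charge set until the first
#' frame at which the minimum probe-target distance drops below the
#' threshold, and its "protonated" set from then on (a one-way latch,
#' reflecting a single protonation event; set `latch = FALSE` for
#' frame-wise switching).
#'
#' @param traj a `trajectory`.
#' @param pigmentA,pigmentB lists: `selection` plus either `set` (a single
#'   charge set) or `sets` (named list with `protonated` and
#'   `deprotonated`).
#' @param switch optional list: `pigment` (`"A"` or `"B"`), `probe` and
#'   `target` atom selections, `threshold` (nm, default 0.5).
#' @param screening screening factor.
#' @param latch one-way switching (default `TRUE`).
#' @return data.frame of class `"coupling_series"` with columns `time`,
#'   `V`, `abs_V`, `state`.
#' @export
compute_coupling_series <- function(traj, pigmentA, pigmentB,
                                    switch = NULL, screening = 1,
                                    latch = TRUE) {
  top <- traj$topology
  get_maps <- function(pg) {
    if (!is.null(pg[["set"]]))
      return(list(none = map_charges(pg[["set"]], top, pg$selection)))
    lapply(pg[["sets"]], map_charges, top = top, pigment = pg$selection)
  }
  mapsA <- get_maps(pigmentA)
  mapsB <- get_maps(pigmentB)
  if (!is.null(switch)) {
    sw_maps <- if (identical(switch$pigment, "B")) mapsB else mapsA
    if (is.null(sw_maps$protonated) || is.null(sw_maps$deprotonated))
      stop("switch rule requires both protonated and deprotonated charge sets")
    if (is.null(switch$threshold)) switch$threshold <- 0.5
  }
  nf <- n_frames(traj)
  V <- numeric(nf)
  state <- character(nf)
  latched <- FALSE
  for (f in seq_len(nf)) {
    fr <- traj$frames[[f]]
    tag <- "none"
    if (!is.null(switch)) {
      near <- FALSE
      for (p in switch$probe) {
        d <- .mi_dist(fr$coords[p, ],
                      fr$coords[switch$target, , drop = FALSE], fr$box)
        if (min(d) < switch$threshold) {
          near <- TRUE
          break
        }
      }
      if (near) latched <- TRUE
      active <- if ((latch && latched) || (!latch && near))
        "protonated" else "deprotonated"
      tag <- active
      if (identical(switch$pigment, "B")) {
        mB <- mapsB[[active]]
        mA <- mapsA[[1]]
      } else {
        mA <- mapsA[[active]]
        mB <- mapsB[[1]]
      }
    } else {
      mA <- mapsA[[1]]
      mB <- mapsB[[1]]
    }
    V[f] <- compute_coupling(fr, mA, mB, screening)
    state[f] <- tag
  }
  structure(data.frame(time = frame_times(traj), V = V, abs_V = abs(V),
                       state = state, stringsAsFactors = FALSE),
            class = c("coupling_series", "data.frame"))
}
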
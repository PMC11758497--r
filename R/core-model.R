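#' porekin: water-channel geometry, proton pathways and conformational kinetics
#'
#' Analysis stages for molecular trajectories of membrane proteins with
#' aqueous channels: pore-radius profiling, water structure (RDF, dipole
#' order, coordination numbers), directed water currents and density maps,
#' free-energy surfaces with minimum-energy paths, TrESP excitonic
#' couplings, and a Markov-state-model kinetics stack.  All coordinates are
#' in nm, times in ps, energies in units of kT, and charges in elementary
#' charges; the membrane normal is the +z axis.
#'
#' @keywords internal
"_PACKAGE"

# Bondi-style van der Waals radii in nm, used for pore profiling.  The set
# is a documented default and can be overridden per call.
.vdw_table <- c(
  H = 0.120, C = 0.170, N = 0.155, O = 0.152, F = 0.147, P = 0.180,
  S = 0.180, CL = 0.175, BR = 0.185, I = 0.198, "NA" = 0.227, MG = 0.173,
  K = 0.275, CA = 0.231, FE = 0.194, ZN = 0.139, MN = 0.205, CU = 0.140
)

.default_water_resnames <- c("HOH", "SOL", "WAT", "TIP3", "H3O")

#' Look up a van der Waals radius for an element
#'
#' Unknown elements fall back to 0.15 nm with a warning, so that pore
#' profiling never silently drops atoms.
#'
#' @param element character vector of element symbols.
#' @param table named numeric vector of radii in nm (uppercase element
#'   names); defaults to a bundled Bondi-style table.
#' @return numeric vector of radii in nm.
#' @export
vdw_radius <- function(element, table = .vdw_table) {
  r <- unname(table[toupper(element)])
  bad <- is.na(r)
  if (any(bad)) {
    warning("unknown element(s) ", paste(unique(element[bad]), collapse = ", "),
            "; using fallback radius 0.15 nm")
    r[bad] <- 0.15
  }
  r
}

# Infer the element symbol from an atom name: strip digits/primes, then the
# leading one or two letters.  Two-letter symbols are only accepted when
# they are in the radius table (CL, NA, ...); hydrogens named 1HW etc. are
# handled by stripping leading digits.
.infer_element <- function(name, table = .vdw_table) {
  vapply(name, function(nm) {
    s <- gsub("[0-9' ]", "", nm)
    if (nchar(s) == 0L) return("X")
    two <- toupper(substr(s, 1, 2))
    if (nchar(s) >= 2L && two %in% names(table) && !two %in% c("CA")) return(two)
    toupper(substr(s, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a molecular topology
#'
#' A topology is an atom table plus the indices of any three-site water
#' molecules.  Atom indices are 1-based throughout the package.
#'
#' @param atoms data.frame with columns `name`, `element`, `resid`
#'   (residue number), `resname`, `chain`, `vdw` (nm), `charge` (e).
#'   Missing columns are filled with defaults.
#' @param water_groups integer matrix with three columns (O, H, H) giving
#'   atom indices of each water, or `NULL` to detect waters by residue name.
#' @param water_resnames residue names treated as water during detection.
#' @return an object of class `"topology"`.
#' @export
topology <- function(atoms, water_groups = NULL,
                     water_resnames = .default_water_resnames) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 0)
  n <- nrow(atoms)
  if (is.null(atoms$name)) atoms$name <- sprintf("X%d", seq_len(n))
  if (is.null(atoms$element)) atoms$element <- .infer_element(atoms$name)
  if (is.null(atoms$resid)) atoms$resid <- seq_len(n)
  if (is.null(atoms$resname)) atoms$resname <- "UNK"
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$vdw)) atoms$vdw <- vdw_radius(atoms$element)
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (any(!is.finite(atoms$vdw)) || any(atoms$vdw <= 0))
    stop("all vdW radii must be positive and finite")
  if (is.null(water_groups))
    water_groups <- .detect_waters(atoms, water_resnames)
  water_groups <- .as_water_matrix(water_groups)
  if (nrow(water_groups) > 0) {
    if (any(water_groups < 1L) || any(water_groups > n))
      stop("water group indices outside the topology")
    if (any(apply(water_groups, 1, anyDuplicated) > 0))
      stop("water groups must reference three distinct atoms")
  }
  structure(list(atoms = atoms, water_groups = water_groups),
            class = "topology")
}

.as_water_matrix <- function(w) {
  if (is.null(w) || length(w) == 0L)
    return(matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("O", "H1", "H2"))))
  w <- matrix(as.integer(w), ncol = 3)
  colnames(w) <- c("O", "H1", "H2")
  w
}

# Detect (O,H,H) triples by residue name; the oxygen is the member whose
# element is O.  Residues without exactly 1 O + 2 H are skipped.
.detect_waters <- function(atoms, water_resnames) {
  sel <- which(atoms$resname %in% water_resnames)
  if (length(sel) == 0L) return(NULL)
  key <- paste(atoms$chain[sel], atoms$resid[sel])
  grp <- split(sel, key)
  rows <- lapply(grp, function(idx) {
    el <- toupper(atoms$element[idx])
    o <- idx[el == "O"]
    h <- idx[el == "H"]
    if (length(o) == 1L && length(h) == 2L) c(o, sort(h)) else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(NULL)
  m <- do.call(rbind, rows)
  m[order(m[, 1]), , drop = FALSE]
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", nrow(x$atoms), "atoms,",
      nrow(x$water_groups), "waters\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param top a `topology`.
#' @return integer atom count.
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Construct a single coordinate frame
#'
#' @param coords numeric matrix (atoms x 3) in nm.
#' @param box length-3 numeric, orthorhombic box edges in nm.
#' @param time frame time in ps.
#' @return object of class `"traj_frame"`.
#' @export
frame <- function(coords, box, time = 0) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, length(box) == 3)
  if (any(box <= 0)) stop("box edge lengths must be positive")
  structure(list(coords = unname(coords), box = as.numeric(box),
                 time = as.numeric(time)),
            class = "traj_frame")
}

#' Construct a trajectory
#'
#' @param topology a `topology`.
#' @param frames list of `traj_frame` objects with matching atom counts and
#'   strictly increasing times.
#' @return object of class `"trajectory"`.
#' @export
trajectory <- function(topology, frames) {
  stopifnot(inherits(topology, "topology"), length(frames) >= 1)
  na <- n_atoms(topology)
  counts <- vapply(frames, function(f) nrow(f$coords), integer(1))
  if (any(counts != na))
    stop("frame atom counts (", paste(unique(counts), collapse = ","),
         ") do not match topology (", na, ")")
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$frames), "frames,",
      n_atoms(x$topology), "atoms\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Frame times of a trajectory
#' @param traj a `trajectory`.
#' @return numeric vector of times in ps.
#' @export
frame_times <- function(traj)
  vapply(traj$frames, function(f) f$time, numeric(1))

## ---------------------------------------------------------------- I/O ----

#' Load a structure file
#'
#' Reads a PDB (via bio3d) or GRO file into a topology plus its first
#' coordinate frame.  PDB coordinates (Angstrom) are converted to nm.
#' Elements missing from the file are inferred from atom names; vdW radii
#' come from the bundled element table.  Waters are detected by residue
#' name (HOH/SOL/WAT/TIP3 by default).
#'
#' @param path file path.
#' @param format `"pdb"` or `"gro"`; guessed from the extension by default.
#' @param water_resnames residue names treated as water.
#' @return list with elements `topology` and `frame`.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "gro"),
                           water_resnames = .default_water_resnames) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") .load_pdb(path, water_resnames)
  else .load_gro(path, water_resnames)
}

.load_pdb <- function(path, water_resnames) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  el <- a$elesy
  miss <- is.na(el) | el == ""
  if (any(miss)) el[miss] <- .infer_element(a$elety[miss])
  atoms <- data.frame(name = a$elety, element = el, resid = a$resno,
                      resname = a$resid,
                      chain = ifelse(is.na(a$chain), "A", a$chain),
                      stringsAsFactors = FALSE)
  top <- topology(atoms, water_resnames = water_resnames)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) / 10  # A -> nm
  box <- .read_cryst1(path)
  list(topology = top, frame = frame(xyz, box, time = 0))
}

.read_cryst1 <- function(path) {
  ln <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(ln) == 0L) return(c(100, 100, 100))  # effectively non-periodic
  v <- as.numeric(c(substr(ln[1], 7, 15), substr(ln[1], 16, 24),
                    substr(ln[1], 25, 33)))
  ang <- as.numeric(c(substr(ln[1], 34, 40), substr(ln[1], 41, 47),
                      substr(ln[1], 48, 54)))
  if (any(abs(ang - 90) > 1e-3))
    stop("only orthorhombic boxes are supported (CRYST1 angles != 90)")
  v / 10
}

.load_gro <- function(path, water_resnames) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("malformed GRO file (too short): ", path)
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat)) stop("malformed GRO atom count at line 2 of ", path)
  if (length(lines) < 3L + nat)
    stop("GRO file truncated: expected ", nat, " atom lines in ", path)
  al <- lines[3:(2 + nat)]
  resid <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resname <- trimws(substr(al, 6, 10))
  name <- trimws(substr(al, 11, 15))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0)
    stop("malformed GRO atom record at line ", 2 + bad[1], " of ", path)
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + nat]),
                                               "[ \t]+")[[1]]))
  if (length(boxv) < 3 || anyNA(boxv[1:3]))
    stop("malformed GRO box line in ", path)
  if (length(boxv) > 3 && any(abs(boxv[-(1:3)]) > 1e-9))
    stop("only orthorhombic boxes are supported (triclinic GRO box)")
  atoms <- data.frame(name = name, element = .infer_element(name),
                      resid = resid, resname = resname, chain = "A",
                      stringsAsFactors = FALSE)
  top <- topology(atoms, water_resnames = water_resnames)
  list(topology = top,
       frame = frame(cbind(x, y, z), boxv[1:3], time = 0))
}

#' Write a frame as a GRO file
#'
#' @param top a `topology`.
#' @param fr a `traj_frame`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gro <- function(top, fr, path) {
  a <- top$atoms
  n <- nrow(a)
  lines <- c("written by porekin", sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     a$resid %% 100000L, substr(a$resname, 1, 5),
                     substr(a$name, 1, 5), seq_len(n) %% 100000L,
                     fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]),
             sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Load a trajectory from one or more coordinate files
#'
#' Supported formats: multi-model PDB, GRO (one frame per file), and DCD
#' (via bio3d).  Frames are concatenated in the given order; when times are
#' absent they are assigned as `dt` times the frame index, offset per file
#' so the full sequence is strictly increasing.
#'
#' @param paths character vector of file paths.
#' @param topology a `topology` the frames must match.
#' @param dt frame spacing in ps used when the files carry no times.
#' @param box fallback box (nm) for formats without box information.
#' @return a `trajectory`.
#' @export
load_trajectory <- function(paths, topology, dt = 1, box = NULL) {
  frames <- list()
  t0 <- 0
  for (p in paths) {
    fl <- .read_frames_file(p, box)
    for (f in fl) {
      f$time <- t0
      t0 <- t0 + dt
      if (nrow(f$coords) != n_atoms(topology))
        stop("atom count mismatch in ", p, ": file has ", nrow(f$coords),
             ", topology has ", n_atoms(topology))
      frames[[length(frames) + 1L]] <- f
    }
  }
  trajectory(topology, frames)
}

.read_frames_file <- function(path, box = NULL) {
  if (grepl("\\.gro$", path, ignore.case = TRUE)) {
    s <- .load_gro(path, .default_water_resnames)
    return(list(s$frame))
  }
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (is.null(box)) box <- c(100, 100, 100)
    return(lapply(seq_len(nrow(xyz)), function(i)
      frame(matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10, box)))
  }
  if (grepl("\\.xtc$", path, ignore.case = TRUE))
    stop("XTC input is not supported; convert to DCD or multi-model PDB")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  if (is.null(box)) box <- .read_cryst1(path)
  lapply(seq_len(nrow(pdb$xyz)), function(i)
    frame(matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE) / 10, box))
}

## ---------------------------------------------------- periodic geometry ----

#' Minimum-image displacement between two points
#'
#' Each component of `b - a` is wrapped into the interval (-L/2, L/2]; the
#' boundary tie at exactly -L/2 maps to +L/2 for determinism.
#'
#' @param a,b numeric 3-vectors (nm), or matrices with 3 columns.
#' @param box length-3 box edges (nm).
#' @return displacement vector(s), same shape as the inputs.
#' @export
minimum_image_displacement <- function(a, b, box) {
  if (any(box <= 0)) stop("box edge lengths must be positive")
  d <- b - a
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * ceiling(d[, k] / box[k] - 0.5)
    return(d)
  }
  d - box * ceiling(d / box - 0.5)
}

# Minimum-image distances from one point to a coordinate matrix.
.mi_dist <- function(point, coords, box) {
  d <- sweep(coords, 2, point)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * ceiling(d[, k] / box[k] - 0.5)
  sqrt(rowSums(d * d))
}

## ------------------------------------------------------------ selection ----

#' Select atoms from a topology
#'
#' Conjunctive (AND) selection over atom attributes; within one attribute a
#' vector of values is an OR.  The result preserves topology order and may
#' be empty.
#'
#' @param top a `topology`.
#' @param name,resname,element,chain character values to match.
#' @param resid integer residue numbers (a range like `25:56` works).
#' @param index explicit atom indices to intersect with.
#' @param ... catches misspelled arguments (an error).
#' @return integer vector of atom indices (class `"atom_selection"`).
#' @export
select_atoms <- function(top, name = NULL, resname = NULL, resid = NULL,
                         element = NULL, chain = NULL, index = NULL, ...) {
  extra <- list(...)
  if (length(extra) > 0)
    stop("unknown selection key(s): ", paste(names(extra), collapse = ", "))
  a <- top$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(element)) keep <- keep & toupper(a$element) %in% toupper(element)
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(index)) keep <- keep & seq_len(nrow(a)) %in% index
  structure(which(keep), class = "atom_selection")
}
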
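## Tabular and grid output writers.  All tabular results are TSV with a
## '#'-prefixed comment header recording the parameters and seed of the
## run.

#' Write a data.frame as TSV with a comment header
#'
#' @param df data.frame.
#' @param path output path.
#' @param params named list recorded in `# key: value` header lines.
#' @return invisibly, the path.
#' @export
write_tsv_result <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(params))
    writeLines(sprintf("# %s: %s", k,
                       paste(format(params[[k]]), collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_result()]
#' @param path file path.
#' @return data.frame (header comments skipped).
#' @export
read_tsv_result <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")

#' Write a free-energy surface as TSV plus a JSON sidecar
#'
#' The TSV holds one row per bin (`ix`, `iy`, `x_center`, `y_center`,
#' `free_energy`, `visited`); the sidecar records the bin edges and mask
#' shape.
#'
#' @param fes an `fes_grid`.
#' @param path TSV output path (sidecar: `<path>.json`).
#' @param params header parameters.
#' @return invisibly, the path.
#' @export
write_fes <- function(fes, path, params = list()) {
  nx <- nrow(fes$free_energy); ny <- ncol(fes$free_energy)
  cx <- (fes$x_edges[-1] + fes$x_edges[-(nx + 1)]) / 2
  cy <- (fes$y_edges[-1] + fes$y_edges[-(ny + 1)]) / 2
  df <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  df$x_center <- cx[df$ix]
  df$y_center <- cy[df$iy]
  df$free_energy <- fes$free_energy[cbind(df$ix, df$iy)]
  df$visited <- fes$visited_mask[cbind(df$ix, df$iy)]
  write_tsv_result(df, path, params)
  jsonlite::write_json(list(x_edges = fes$x_edges, y_edges = fes$y_edges,
                            shape = c(nx, ny)),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' Write a density grid in OpenDX format
#'
#' @param grid a `density_grid`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_dx <- function(grid, path) {
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %g 0 0", grid$spacing),
    sprintf("delta 0 %g 0", grid$spacing),
    sprintf("delta 0 0 %g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  v <- aperm(grid$values, c(3, 2, 1))  # DX: z fastest
  v <- as.vector(v)
  pad <- (-length(v)) %% 3
  if (pad > 0) v <- c(v, rep(NA, pad))
  m <- matrix(v, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r)
    paste(format(r[!is.na(r)], digits = 6), collapse = " "))
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Write detected sites as a PDB of pseudo-atoms
#'
#' Site occupancy goes in the occupancy column; coordinates are written in
#' Angstrom as the format requires.
#'
#' @param sites an `immobile_sites` data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_sites_pdb <- function(sites, path) {
  lines <- sprintf(
    "HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
    seq_len(nrow(sites)), seq_len(nrow(sites)),
    sites$x * 10, sites$y * 10, sites$z * 10,
    pmin(sites$occupancy, 1), 0)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a `trajectory`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_pdb_frames <- function(traj, path) {
  top <- traj$topology
  a <- top$atoms
  box <- traj$frames[[1]]$box * 10
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
    box[1], box[2], box[3]), con)
  for (f in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL %8d", f), con)
    x <- traj$frames[[f]]$coords * 10
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)) %% 100000L, substr(a$name, 1, 4),
      substr(a$resname, 1, 3), substr(a$chain, 1, 1), a$resid %% 10000L,
      x[, 1], x[, 2], x[, 3], substr(a$element, 1, 2)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
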
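#' Write a backbone trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, backbone atoms N, CA, C, O only.
#' O-glycosylation sites are noted in REMARK 999 lines; no glycan atoms are
#' written.
#'
#' @param traj A \code{backbone_trajectory}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "backbone_trajectory"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  gl <- traj$residues$number[traj$residues$glycosylated]
  writeLines(sprintf("REMARK 999 O-GLYCOSYLATION SITES: %s",
                     if (length(gl)) paste(gl, collapse = " ") else "NONE"),
             con)
  n_frames <- dim(traj$coords)[1L]
  atoms <- traj$atoms
  name4 <- sprintf(" %-3s", atoms$atom)
  res3 <- .AA3[atoms$residue_type]
  elem <- substr(atoms$atom, 1L, 1L)
  for (f in seq_len(n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    x <- traj$coords[f, , ]
    writeLines(sprintf(
      "ATOM  %5d%5s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(atoms)), name4, res3, atoms$residue_number,
      x[, 1L], x[, 2L], x[, 3L], elem), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file into a backbone trajectory
#'
#' Parses the file with \code{bio3d::read.pdb} (all models), keeps the
#' backbone heavy atoms N, CA, C, O and discards everything else with a
#' message reporting how many atoms were ignored. Every residue must carry
#' all four backbone atoms in every model.
#'
#' @param path Path to a PDB file.
#' @param geometry \code{backbone_geometry} supplying atomic masses for
#'   the returned trajectory.
#' @return A \code{backbone_trajectory} with one frame per MODEL record.
#' @export
read_pdb_models <- function(path, geometry = backbone_geometry()) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("cannot parse PDB '", path, "': ", conditionMessage(e)))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L)
    stop("no ATOM records in '", path, "'")
  keep <- pdb$atom$elety %in% c("N", "CA", "C", "O")
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message("read_pdb_models: ignoring ", n_drop, " non-backbone atom(s)")
  atom <- pdb$atom[keep, ]
  res_nums <- unique(atom$resno)
  aa1 <- names(.AA3)[match(atom$resid[match(res_nums, atom$resno)], .AA3)]
  if (anyNA(aa1)) stop("unknown residue type(s) in PDB file")
  # column-selected xyz: bio3d stores frames as rows of the xyz matrix
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_frames <- nrow(xyz)
  sel <- which(keep)
  ord <- order(match(atom$resno, res_nums),
               match(atom$elety, c("N", "CA", "C", "O")))
  atom <- atom[ord, ]
  sel <- sel[ord]
  expect <- data.frame(resno = rep(res_nums, each = 4L),
                       elety = rep(c("N", "CA", "C", "O"), length(res_nums)))
  k <- min(nrow(atom), nrow(expect))
  mism <- which(atom$resno[seq_len(k)] != expect$resno[seq_len(k)] |
                  atom$elety[seq_len(k)] != expect$elety[seq_len(k)])
  if (nrow(atom) != nrow(expect) || length(mism)) {
    at <- expect[if (length(mism)) mism[1L] else k + 1L, ]
    stop("missing backbone atom ", at$elety, " in residue ", at$resno)
  }
  coords <- array(NA_real_, dim = c(n_frames, nrow(atom), 3L))
  for (f in seq_len(n_frames)) {
    xf <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    coords[f, , ] <- xf[sel, , drop = FALSE]
  }
  glyco <- integer()
  hdr <- grep("^REMARK 999 O-GLYCOSYLATION SITES:", readLines(path, n = 50L),
              value = TRUE)
  if (length(hdr)) {
    toks <- strsplit(sub(".*SITES:", "", hdr[1L]), "\\s+")[[1L]]
    glyco <- suppressWarnings(as.integer(toks[toks != ""]))
    glyco <- glyco[!is.na(glyco)]
  }
  residues <- data.frame(number = res_nums, type = aa1,
                         glycosylated = res_nums %in% glyco)
  backbone_trajectory(coords, residues, geometry)
}
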
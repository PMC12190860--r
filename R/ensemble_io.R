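# Conformational-ensemble container and plain-text I/O.
#
# A ReferenceStructure holds the atom table and residue bookkeeping of one
# structure; a ConformationalEnsemble adds an F x A x 3 coordinate array of
# frames sharing that topology. Residue ordinals are assigned in file order
# (0-based internally); all user-facing tables use author labels
# "chain:resno[icode]".

SOLVENT_RESNAMES <- c("HOH", "WAT", "DOD", "NA", "CL", "K", "MG", "ZN",
                      "CA", "SO4", "PO4")

#' Construct a reference structure from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer),
#'   `icode` (insertion code, "" if none), `resname` (3-letter code),
#'   `atom` (PDB atom name), `element`, `x`, `y`, `z`.
#' @return Object of class `ReferenceStructure` with components:
#'   `atoms` (the table, plus `residue_ordinal` 1-based, `is_hydrogen`,
#'   `is_standard`), `residue_labels`, `residues` (per-residue table),
#'   `ca_index` (atom row of each residue's Calpha).
#' @export
reference_structure <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("chain", "resno", "icode", "resname", "atom", "element",
            "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("zero atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  # residue ordinal in file order
  ord <- match(key, unique(key))
  atoms$residue_ordinal <- ord
  dup <- duplicated(paste(key, atoms$atom, sep = "\r"))
  if (any(dup))
    stop("duplicate (chain, residue, atom) record: ",
         atoms$chain[dup][1], " ", atoms$resno[dup][1], " ",
         atoms$atom[dup][1])
  first <- !duplicated(ord)
  residues <- data.frame(
    ordinal = ord[first],
    chain = atoms$chain[first],
    resno = atoms$resno[first],
    icode = atoms$icode[first],
    resname = atoms$resname[first],
    stringsAsFactors = FALSE)
  residues$label <- paste0(residues$chain, ":", residues$resno,
                           residues$icode)
  residues$is_standard <- is_standard_residue(residues$resname)
  if (anyDuplicated(residues$label))
    stop("duplicate residue identity (chain, residue_number, icode)")
  # one Calpha per residue
  ca_rows <- which(atoms$atom == "CA" & atoms$element != "H")
  ca_index <- rep(NA_integer_, nrow(residues))
  ca_index[atoms$residue_ordinal[ca_rows]] <- ca_rows
  if (anyNA(ca_index))
    stop("residue(s) without a CA atom: ",
         paste(residues$label[is.na(ca_index)], collapse = ", "))
  if (length(ca_rows) != nrow(residues))
    stop("residue with more than one CA atom")
  atoms$is_hydrogen <- toupper(atoms$element) == "H"
  atoms$is_standard <- is_standard_residue(atoms$resname)
  structure(list(atoms = atoms, residues = residues,
                 residue_labels = residues$label, ca_index = ca_index),
            class = "ReferenceStructure")
}

#' Construct a conformational ensemble
#'
#' @param reference a [reference_structure()].
#' @param frames numeric array F x A x 3 (Angstrom), A matching the
#'   reference atom count.
#' @param frame_labels optional per-frame identifiers.
#' @return Object of class `ConformationalEnsemble`.
#' @export
conformational_ensemble <- function(reference, frames, frame_labels = NULL) {
  stopifnot(inherits(reference, "ReferenceStructure"))
  if (length(dim(frames)) != 3L || dim(frames)[3] != 3L)
    stop("frames must be an F x A x 3 array")
  if (dim(frames)[1] < 1L) stop("ensemble must contain at least one frame")
  if (dim(frames)[2] != nrow(reference$atoms))
    stop("frame atom count (", dim(frames)[2],
         ") does not match reference (", nrow(reference$atoms), ")")
  if (!all(is.finite(frames))) stop("non-finite frame coordinates")
  if (is.null(frame_labels)) frame_labels <- seq_len(dim(frames)[1])
  if (length(frame_labels) != dim(frames)[1])
    stop("frame_labels length mismatch")
  structure(list(reference = reference, frames = frames,
                 frame_labels = frame_labels),
            class = "ConformationalEnsemble")
}

#' @export
print.ConformationalEnsemble <- function(x, ...) {
  cat("ConformationalEnsemble:", dim(x$frames)[1], "frames,",
      dim(x$frames)[2], "atoms,", length(x$reference$residue_labels),
      "residues,", length(unique(x$reference$residues$chain)), "chain(s)\n")
  invisible(x)
}

#' @export
print.ReferenceStructure <- function(x, ...) {
  cat("ReferenceStructure:", nrow(x$atoms), "atoms,",
      nrow(x$residues), "residues\n")
  invisible(x)
}

n_frames <- function(ens) dim(ens$frames)[1]
n_atoms <- function(ens) dim(ens$frames)[2]

# Calpha coordinates of frame f as an N x 3 matrix.
ca_coords <- function(ens, f) ens$frames[f, ens$reference$ca_index, , drop = TRUE]

parse_pdb_atoms <- function(lines) {
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (!length(lines)) return(NULL)
  num <- function(s) suppressWarnings(as.numeric(s))
  df <- data.frame(
    atom = trimws(substr(lines, 13, 16)),
    altloc = substr(lines, 17, 17),
    resname = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    resno = as.integer(trimws(substr(lines, 23, 26))),
    icode = trimws(substr(lines, 27, 27)),
    x = num(substr(lines, 31, 38)),
    y = num(substr(lines, 39, 46)),
    z = num(substr(lines, 47, 54)),
    occ = num(substr(lines, 55, 60)),
    element = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE)
  # element column may be absent in minimal files: fall back to atom name
  noel <- df$element == ""
  df$element[noel] <- substr(gsub("[0-9]", "", df$atom[noel]), 1, 1)
  df$occ[is.na(df$occ)] <- 1
  df
}

resolve_altlocs <- function(df) {
  has <- df$altloc != " " & df$altloc != ""
  if (!any(has)) {
    df$altloc <- NULL
    return(df)
  }
  key <- paste(df$chain, df$resno, df$icode, df$atom, sep = "\r")
  keep <- rep(TRUE, nrow(df))
  for (k in unique(key[has])) {
    rows <- which(key == k)
    if (length(rows) < 2L) next
    # highest occupancy wins; ties broken by altloc letter
    o <- order(-df$occ[rows], df$altloc[rows])
    keep[rows[-o[1]]] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  df$altloc <- NULL
  df
}

#' Read a multi-model PDB file as a conformational ensemble
#'
#' Parses `MODEL`/`ENDMDL` blocks (or a single unannotated model) using the
#' wwPDB v3.3 fixed-width convention. Solvent and common ion records are
#' dropped (with a message); hydrogens are retained and flagged; alternate
#' locations keep the highest-occupancy conformer (ties by altloc letter).
#'
#' @param path PDB file path.
#' @return A [conformational_ensemble()] whose `frame_labels` are the MODEL
#'   numbers in file order.
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) {
    blocks <- list(lines)
    labels <- 1L
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts))
      stop("unbalanced MODEL/ENDMDL records")
    blocks <- Map(function(s, e) lines[(s + 1L):(e - 1L)], starts, ends)
    labels <- as.integer(trimws(substr(lines[starts], 7, 20)))
  }
  parsed <- lapply(blocks, function(b) {
    df <- parse_pdb_atoms(b)
    if (is.null(df)) return(NULL)
    df <- resolve_altlocs(df)
    solv <- df$resname %in% SOLVENT_RESNAMES
    if (any(solv)) df <- df[!solv, , drop = FALSE]
    attr(df, "n_solvent") <- sum(solv)
    df
  })
  ok <- !vapply(parsed, is.null, logical(1))
  if (!any(ok)) stop("zero parsable atoms in ", path)
  parsed <- parsed[ok]
  labels <- labels[ok]
  n_solv <- sum(vapply(parsed, function(d) attr(d, "n_solvent"), numeric(1)))
  if (n_solv > 0) message("dropped ", n_solv, " solvent/ion atom records")
  ref_df <- parsed[[1]]
  ident <- function(d) paste(d$chain, d$resno, d$icode, d$resname, d$atom,
                             sep = "\r")
  ref_id <- ident(ref_df)
  for (m in seq_along(parsed)[-1]) {
    if (nrow(parsed[[m]]) != nrow(ref_df) ||
        !identical(ident(parsed[[m]]), ref_id))
      stop("MODEL ", labels[m],
           ": atom records do not match MODEL ", labels[1],
           " (", nrow(parsed[[m]]), " vs ", nrow(ref_df), " atoms)")
  }
  ref <- reference_structure(ref_df[, c("chain", "resno", "icode", "resname",
                                        "atom", "element", "x", "y", "z")])
  frames <- array(NA_real_, c(length(parsed), nrow(ref_df), 3L))
  for (m in seq_along(parsed))
    frames[m, , ] <- as.matrix(parsed[[m]][, c("x", "y", "z")])
  conformational_ensemble(ref, frames, frame_labels = labels)
}

#' Write a conformational ensemble as a multi-model PDB file
#'
#' Every frame is wrapped in `MODEL n`/`ENDMDL` (including F = 1);
#' coordinates are formatted to 3 decimals.
#'
#' @param ens a [conformational_ensemble()].
#' @param path output path.
#' @export
write_ensemble_pdb <- function(ens, path) {
  stopifnot(inherits(ens, "ConformationalEnsemble"))
  if (n_frames(ens) < 1L) stop("cannot write an empty ensemble")
  a <- ens$reference$atoms
  atom4 <- ifelse(nchar(a$atom) < 4L & nchar(a$element) == 1L,
                  sprintf(" %-3s", a$atom), sprintf("%-4s", a$atom))
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  for (f in seq_len(n_frames(ens))) {
    writeLines(sprintf("MODEL     %4d", as.integer(ens$frame_labels[f])), con)
    xyz <- ens$frames[f, , , drop = TRUE]
    recs <- sprintf(
      "ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)) %% 100000L, atom4, a$resname, a$chain, a$resno,
      ifelse(a$icode == "", " ", a$icode),
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element)
    writeLines(recs, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read an ensemble from a coordinate table plus topology sidecar
#'
#' The coordinate table is whitespace-separated with F rows of 3A numbers
#' (x1 y1 z1 x2 y2 z2 ...); the topology sidecar is a TSV with header
#' `chain residue_number residue_name atom_name element`, one row per atom
#' in coordinate order.
#'
#' @param coords_path,topology_path file paths.
#' @return A [conformational_ensemble()].
#' @export
read_coord_table <- function(coords_path, topology_path) {
  top <- utils::read.delim(topology_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("chain", "residue_number", "residue_name", "atom_name", "element")
  if (!all(need %in% names(top)))
    stop("topology sidecar must have columns: ", paste(need, collapse = " "))
  A <- nrow(top)
  resno_raw <- top$residue_number
  icode <- gsub("^-?[0-9]+", "", resno_raw)
  resno <- as.integer(gsub("[^-0-9].*$", "", resno_raw))
  mat <- as.matrix(utils::read.table(coords_path))
  if (ncol(mat) != 3L * A)
    stop("coordinate rows have ", ncol(mat), " values; expected 3A = ", 3L * A)
  F_ <- nrow(mat)
  frames <- array(NA_real_, c(F_, A, 3L))
  frames[, , 1] <- mat[, seq(1L, 3L * A, by = 3L), drop = FALSE]
  frames[, , 2] <- mat[, seq(2L, 3L * A, by = 3L), drop = FALSE]
  frames[, , 3] <- mat[, seq(3L, 3L * A, by = 3L), drop = FALSE]
  atoms <- data.frame(chain = top$chain, resno = resno, icode = icode,
                      resname = top$residue_name, atom = top$atom_name,
                      element = top$element,
                      x = frames[1, , 1], y = frames[1, , 2],
                      z = frames[1, , 3], stringsAsFactors = FALSE)
  ref <- reference_structure(atoms)
  conformational_ensemble(ref, frames)
}

#' Write an ensemble as a coordinate table plus topology sidecar
#'
#' Full-precision counterpart of [write_ensemble_pdb()]; round-trips through
#' [read_coord_table()] to better than 1e-6 Angstrom.
#'
#' @param ens a [conformational_ensemble()].
#' @param coords_path,topology_path output paths.
#' @export
write_coord_table <- function(ens, coords_path, topology_path) {
  stopifnot(inherits(ens, "ConformationalEnsemble"))
  a <- ens$reference$atoms
  top <- data.frame(chain = a$chain,
                    residue_number = paste0(a$resno, a$icode),
                    residue_name = a$resname, atom_name = a$atom,
                    element = a$element, stringsAsFactors = FALSE)
  utils::write.table(top, topology_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  F_ <- n_frames(ens); A <- n_atoms(ens)
  flat <- matrix(NA_real_, F_, 3L * A)
  flat[, seq(1L, 3L * A, by = 3L)] <- ens$frames[, , 1]
  flat[, seq(2L, 3L * A, by = 3L)] <- ens$frames[, , 2]
  flat[, seq(3L, 3L * A, by = 3L)] <- ens$frames[, , 3]
  utils::write.table(format(flat, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     coords_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(coords_path)
}
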
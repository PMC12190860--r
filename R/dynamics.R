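# Per-residue dynamics statistics over a conformational ensemble:
# least-squares superposition, RMSD/RMSF, the signed dynamic
# cross-correlation matrix C_ij = <dr_i . dr_j> / (<dr_i^2><dr_j^2>)^{1/2},
# its mutual-information ("generalized") counterpart, and ensemble contact
# occupancy.

#' Construct a correlation matrix object
#'
#' @param values N x N numeric matrix.
#' @param kind `"signed_dccm"` (entries in \[-1, 1\], unit diagonal) or
#'   `"generalized"` (entries in \[0, 1\], unit diagonal).
#' @param residue_labels ordered residue labels.
#' @return Object of class `CorrelationMatrix`.
#' @export
correlation_matrix <- function(values, kind = c("signed_dccm", "generalized"),
                               residue_labels) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values),
            nrow(values) == length(residue_labels))
  if (max(abs(values - t(values))) > 1e-10)
    stop("correlation matrix must be symmetric")
  lo <- if (kind == "signed_dccm") -1 else 0
  if (any(values < lo - 1e-9 | values > 1 + 1e-9))
    stop("correlation values out of range for kind ", kind)
  dimnames(values) <- list(residue_labels, residue_labels)
  structure(list(values = values, kind = kind,
                 residue_labels = residue_labels),
            class = "CorrelationMatrix")
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat("CorrelationMatrix (", x$kind, "): ",
      length(x$residue_labels), " residues\n", sep = "")
  invisible(x)
}

#' Per-residue profile container
#'
#' @param residue_labels ordered residue labels.
#' @param values numeric vector of the same length.
#' @param statistic name of the statistic (e.g. "rmsf", "spc", "z").
#' @param units units string.
#' @return Object of class `ResidueProfile` (a data.frame).
#' @export
residue_profile <- function(residue_labels, values, statistic,
                            units = "") {
  stopifnot(length(residue_labels) == length(values))
  structure(data.frame(residue = residue_labels, value = values,
                       stringsAsFactors = FALSE),
            statistic = statistic, units = units,
            class = c("ResidueProfile", "data.frame"))
}

resolve_selection <- function(ens, selection) {
  labs <- ens$reference$residue_labels
  if (is.null(selection)) return(seq_along(labs))
  if (is.character(selection)) {
    idx <- match(selection, labs)
    if (anyNA(idx))
      stop("unknown residues: ",
           paste(selection[is.na(idx)], collapse = ", "))
    return(idx)
  }
  idx <- as.integer(selection)
  if (any(idx < 1L | idx > length(labs))) stop("residue index out of range")
  idx
}

#' Superpose every frame onto the reference structure
#'
#' Least-squares rigid-body fit (optimal rotation + translation) of each
#' frame onto the reference, minimizing Calpha RMSD over the selection.
#' The fitted transform is applied to all atoms. The input is untouched.
#'
#' @param ens a [conformational_ensemble()].
#' @param selection residue labels or ordinals (default: all residues).
#' @return A new, superposed `ConformationalEnsemble`.
#' @export
superpose_frames <- function(ens, selection = NULL) {
  stopifnot(inherits(ens, "ConformationalEnsemble"))
  idx <- resolve_selection(ens, selection)
  if (length(idx) < 3L)
    stop("superposition needs at least 3 selected residues")
  ca_rows <- ens$reference$ca_index[idx]
  ref_ca <- as.matrix(ens$reference$atoms[ca_rows, c("x", "y", "z")])
  sv <- svd(stats::cov(ref_ca))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-30))
    stop("selected Calpha atoms are collinear")
  F_ <- n_frames(ens); A <- n_atoms(ens)
  # bio3d xyz layout: x1 y1 z1 x2 ... per row
  fixed <- as.vector(t(ref_ca))
  mob_ca <- matrix(NA_real_, F_, 3L * length(ca_rows))
  full <- matrix(NA_real_, F_, 3L * A)
  for (d in 1:3) {
    mob_ca[, seq(d, 3L * length(ca_rows), by = 3L)] <-
      ens$frames[, ca_rows, d, drop = FALSE]
    full[, seq(d, 3L * A, by = 3L)] <- ens$frames[, , d, drop = FALSE]
  }
  fitted <- bio3d::fit.xyz(fixed = fixed, mobile = full,
                           fixed.inds = seq_along(fixed),
                           mobile.inds = as.vector(t(outer(
                             (ca_rows - 1L) * 3L, 1:3, "+"))))
  frames <- array(NA_real_, c(F_, A, 3L))
  for (d in 1:3)
    frames[, , d] <- fitted[, seq(d, 3L * A, by = 3L), drop = FALSE]
  conformational_ensemble(ens$reference, frames, ens$frame_labels)
}

#' Per-frame Calpha RMSD to the reference structure
#'
#' @param ens a [conformational_ensemble()], normally already superposed.
#' @param selection residue subset (default all).
#' @param superpose if `TRUE`, superpose internally first.
#' @return Numeric vector of length F (Angstrom).
#' @export
compute_rmsd_series <- function(ens, selection = NULL, superpose = FALSE) {
  idx <- resolve_selection(ens, selection)
  if (length(idx) == 0L) stop("empty selection")
  if (superpose) ens <- superpose_frames(ens, selection)
  ca_rows <- ens$reference$ca_index[idx]
  ref <- as.matrix(ens$reference$atoms[ca_rows, c("x", "y", "z")])
  F_ <- n_frames(ens)
  out <- numeric(F_)
  for (f in seq_len(F_)) {
    d <- ens$frames[f, ca_rows, , drop = TRUE] - ref
    out[f] <- sqrt(mean(rowSums(matrix(d, ncol = 3)^2)))
  }
  out
}

# Centered Calpha displacement matrices (one F x N matrix per dimension).
ca_displacements <- function(ens) {
  ca_rows <- ens$reference$ca_index
  lapply(1:3, function(d) {
    m <- ens$frames[, ca_rows, d, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    sweep(m, 2L, colMeans(m))
  })
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF_i = sqrt(mean over frames of |r_i - <r_i>|^2) over Calpha atoms,
#' with the mean taken about the ensemble-average position.
#'
#' @param ens a superposed [conformational_ensemble()] with F >= 2.
#' @return A [residue_profile()] in Angstrom.
#' @export
compute_rmsf <- function(ens) {
  stopifnot(inherits(ens, "ConformationalEnsemble"))
  if (n_frames(ens) < 2L) stop("RMSF needs at least 2 frames")
  dis <- ca_displacements(ens)
  msf <- colMeans(dis[[1]]^2) + colMeans(dis[[2]]^2) + colMeans(dis[[3]]^2)
  residue_profile(ens$reference$residue_labels, sqrt(msf),
                  statistic = "rmsf", units = "Angstrom")
}

#' Dynamic cross-correlation matrix
#'
#' C_ij = <dr_i . dr_j> / (<dr_i^2> <dr_j^2>)^(1/2) over Calpha
#' displacements from the ensemble-mean position. Positive values mark
#' correlated motion of the residue pair, negative values anti-correlated
#' motion. Residues with zero fluctuation get zero off-diagonal entries
#' (with a warning) so downstream graph construction stays total.
#'
#' @param ens a superposed [conformational_ensemble()] with F >= 2.
#' @return A [correlation_matrix()] of kind `signed_dccm`.
#' @export
compute_dccm <- function(ens) {
  stopifnot(inherits(ens, "ConformationalEnsemble"))
  if (n_frames(ens) < 2L) stop("DCCM needs at least 2 frames")
  dis <- ca_displacements(ens)
  F_ <- n_frames(ens)
  num <- (crossprod(dis[[1]]) + crossprod(dis[[2]]) + crossprod(dis[[3]])) / F_
  v <- diag(num)
  zero <- v <= 0
  if (any(zero)) {
    warning("residue(s) with zero fluctuation: ",
            paste(ens$reference$residue_labels[zero], collapse = ", "))
    v[zero] <- 1
  }
  C <- num / sqrt(outer(v, v))
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C) <- 1
  C <- pmin(pmax((C + t(C)) / 2, -1), 1)
  correlation_matrix(C, "signed_dccm", ens$reference$residue_labels)
}

#' Generalized correlation from a 3N x 3N covariance matrix
#'
#' Gaussian mutual-information estimate per residue pair:
#' I_ij = 1/2 ln( det(S_i) det(S_j) / det(S_ij) ) from the 6x6 joint
#' Calpha covariance, mapped to r_ij = sqrt(1 - exp(-2 I_ij / 3)) in
#' \[0, 1\]. Coordinates are atom-major (x1 y1 z1 x2 ...).
#'
#' @param sigma 3N x 3N covariance matrix.
#' @param residue_labels N labels.
#' @return A [correlation_matrix()] of kind `generalized`.
#' @export
generalized_correlation_from_covariance <- function(sigma, residue_labels) {
  N <- length(residue_labels)
  stopifnot(nrow(sigma) == 3L * N, ncol(sigma) == 3L * N)
  blk <- function(i) (3L * (i - 1L) + 1L):(3L * i)
  logdet <- function(m) {
    d <- determinant(m, logarithm = TRUE)
    if (d$sign <= 0) return(NA_real_)
    as.numeric(d$modulus)
  }
  ld3 <- vapply(seq_len(N), function(i) logdet(sigma[blk(i), blk(i)]),
                numeric(1))
  r <- matrix(0, N, N)
  warned <- FALSE
  for (i in seq_len(N - 1L)) {
    if (is.na(ld3[i])) { warned <- TRUE; next }
    bi <- blk(i)
    for (j in (i + 1L):N) {
      if (is.na(ld3[j])) { warned <- TRUE; next }
      bj <- blk(j)
      s6 <- sigma[c(bi, bj), c(bi, bj)]
      ld6 <- logdet(s6)
      if (is.na(ld6)) { warned <- TRUE; next }
      I <- 0.5 * (ld3[i] + ld3[j] - ld6)
      if (I < 0) I <- 0
      r[i, j] <- r[j, i] <- sqrt(1 - exp(-2 * I / 3))
    }
  }
  if (warned)
    warning("singular marginal covariance for some pair(s); value set to 0")
  diag(r) <- 1
  correlation_matrix(r, "generalized", residue_labels)
}

#' Generalized (mutual-information) correlation matrix of an ensemble
#'
#' Estimates the 3N Calpha displacement covariance from the frames and
#' applies [generalized_correlation_from_covariance()]. The linear-Gaussian
#' closed form makes the estimator exactly testable and guarantees
#' r_ij >= |C_ij| in Gaussian systems.
#'
#' @inheritParams compute_dccm
#' @return A [correlation_matrix()] of kind `generalized`.
#' @export
compute_generalized_correlation <- function(ens) {
  stopifnot(inherits(ens, "ConformationalEnsemble"))
  if (n_frames(ens) < 2L) stop("needs at least 2 frames")
  dis <- ca_displacements(ens)
  F_ <- n_frames(ens); N <- ncol(dis[[1]])
  X <- matrix(NA_real_, F_, 3L * N)
  for (d in 1:3) X[, seq(d, 3L * N, by = 3L)] <- dis[[d]]
  sigma <- crossprod(X) / F_
  generalized_correlation_from_covariance(sigma,
                                          ens$reference$residue_labels)
}

contact_atom_rows <- function(ref, atom_mode) {
  a <- ref$atoms
  heavy <- !a$is_hydrogen
  switch(atom_mode,
    ca_only = which(a$atom == "CA" & heavy),
    all_heavy = which(heavy),
    sidechain_heavy = {
      side <- heavy & !(a$atom %in% c("N", "CA", "C", "O", "OXT"))
      # residues with no side-chain heavy atom (glycine) contribute Calpha
      has_side <- tapply(side, a$residue_ordinal, any)
      fallback <- a$atom == "CA" & heavy &
        !has_side[as.character(a$residue_ordinal)]
      which(side | fallback)
    },
    stop("unknown atom_mode: ", atom_mode))
}

#' Ensemble contact occupancy map
#'
#' values\[i, j\] is the fraction of frames in which any selected atom of
#' residue i lies within `cutoff` of any selected atom of residue j.
#' In `sidechain_heavy` mode glycine contributes its Calpha.
#'
#' @param ens a [conformational_ensemble()].
#' @param cutoff contact distance cutoff, Angstrom.
#' @param atom_mode `"sidechain_heavy"` (default), `"all_heavy"` or
#'   `"ca_only"`.
#' @return Object of class `ContactOccupancyMap` with fields `values`
#'   (symmetric, zero diagonal), `atom_mode`, `cutoff`, `residue_labels`.
#' @export
compute_contact_occupancy <- function(ens, cutoff = 5.0,
                                      atom_mode = c("sidechain_heavy",
                                                    "all_heavy", "ca_only")) {
  atom_mode <- match.arg(atom_mode)
  stopifnot(inherits(ens, "ConformationalEnsemble"))
  if (cutoff <= 0) stop("cutoff must be positive")
  ref <- ens$reference
  rows <- contact_atom_rows(ref, atom_mode)
  res_of <- ref$atoms$residue_ordinal[rows]
  N <- nrow(ref$residues)
  A <- length(rows)
  # map each atom pair (dist() order) to its residue-pair index
  ii <- rep(seq_len(A - 1L), times = (A - 1L):1L)
  jj <- unlist(lapply(seq_len(A - 1L), function(k) (k + 1L):A))
  ri <- res_of[ii]; rj <- res_of[jj]
  lo <- pmin(ri, rj); hi <- pmax(ri, rj)
  same <- lo == hi
  pair_id <- (lo - 1L) * N + hi  # unique id per unordered residue pair
  pair_id[same] <- NA_integer_
  uid <- sort(unique(pair_id[!same]))
  pair_idx <- match(pair_id, uid)
  counts <- numeric(length(uid))
  F_ <- n_frames(ens)
  c2 <- cutoff^2
  for (f in seq_len(F_)) {
    m <- ens$frames[f, rows, , drop = TRUE]
    d2 <- stats::dist(m)^2
    hit <- which(d2 <= c2)
    pidx <- pair_idx[hit]
    pidx <- pidx[!is.na(pidx)]
    if (length(pidx))
      counts <- counts + (tabulate(pidx, nbins = length(uid)) > 0L)
  }
  vals <- matrix(0, N, N)
  lo_u <- (uid - 1L) %/% N + 1L
  hi_u <- (uid - 1L) %% N + 1L
  vals[cbind(lo_u, hi_u)] <- counts / F_
  vals[cbind(hi_u, lo_u)] <- counts / F_
  dimnames(vals) <- list(ref$residue_labels, ref$residue_labels)
  structure(list(values = vals, atom_mode = atom_mode, cutoff = cutoff,
                 residue_labels = ref$residue_labels),
            class = "ContactOccupancyMap")
}

#' @export
print.ContactOccupancyMap <- function(x, ...) {
  cat("ContactOccupancyMap:", length(x$residue_labels), "residues, cutoff",
      x$cutoff, "A, mode", x$atom_mode, "\n")
  invisible(x)
}

#' Subsample an ensemble's frames
#'
#' `stride` picks evenly spaced frames always including the last
#' (frame indices `floor(k * F / n)` for k = 1..n); `random` draws without
#' replacement and requires an explicit seed.
#'
#' @param ens a [conformational_ensemble()].
#' @param n number of frames to keep, 1 <= n <= F.
#' @param scheme `"stride"` (default, deterministic) or `"random"`.
#' @param seed integer seed, required for `scheme = "random"`.
#' @return A `ConformationalEnsemble` with n frames.
#' @export
subsample <- function(ens, n, scheme = c("stride", "random"), seed = NULL) {
  scheme <- match.arg(scheme)
  F_ <- n_frames(ens)
  n <- as.integer(n)
  if (n < 1L || n > F_)
    stop("n must be between 1 and the frame count (", F_, ")")
  idx <- if (scheme == "stride") {
    unique(as.integer(floor(seq_len(n) * (F_ / n))))
  } else {
    if (is.null(seed)) stop("random subsampling requires an explicit seed")
    with_seed(seed, sort(sample.int(F_, n)))
  }
  conformational_ensemble(ens$reference,
                          ens$frames[idx, , , drop = FALSE],
                          ens$frame_labels[idx])
}

# Evaluate expr with a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
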
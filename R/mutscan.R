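# Ensemble-averaged in-silico mutational scanning.
#
# The binding free-energy change of a substitution is scored per frame by a
# pluggable SubstitutionScorer and averaged over equilibrium samples
# (ddG = <ddG_frame>), following the ensemble-averaging framework rather
# than scoring a single mean structure. Positive ddG = destabilizing.

#' Identify interface residues of a chain group
#'
#' Residues of `group_a` whose heavy atoms come within `cutoff` of any
#' heavy atom of `group_b` in at least `min_occupancy` of the frames.
#'
#' @param ens a [conformational_ensemble()].
#' @param group_a,group_b disjoint character vectors of chain ids.
#' @param cutoff distance cutoff, Angstrom (default 5).
#' @param min_occupancy minimum fraction of frames in contact (default 0.5).
#' @return Character vector of residue labels, sorted by residue ordinal.
#' @export
identify_interface_residues <- function(ens, group_a, group_b,
                                        cutoff = 5.0, min_occupancy = 0.5) {
  stopifnot(inherits(ens, "ConformationalEnsemble"))
  if (length(intersect(group_a, group_b)))
    stop("chain groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "))
  a <- ens$reference$atoms
  rows_a <- which(a$chain %in% group_a & !a$is_hydrogen)
  rows_b <- which(a$chain %in% group_b & !a$is_hydrogen)
  if (!length(rows_a) || !length(rows_b))
    stop("empty chain group")
  res_a <- a$residue_ordinal[rows_a]
  ords <- sort(unique(res_a))
  counts <- stats::setNames(numeric(length(ords)), ords)
  F_ <- n_frames(ens)
  c2 <- cutoff^2
  for (f in seq_len(F_)) {
    xa <- matrix(ens$frames[f, rows_a, ], ncol = 3)
    xb <- matrix(ens$frames[f, rows_b, ], ncol = 3)
    d2 <- outer(rowSums(xa^2), rep(1, nrow(xb))) +
      outer(rep(1, nrow(xa)), rowSums(xb^2)) - 2 * tcrossprod(xa, xb)
    near <- rowSums(d2 <= c2) > 0L
    hit <- unique(res_a[near])
    counts[as.character(hit)] <- counts[as.character(hit)] + 1
  }
  occ <- counts / F_
  keep <- ords[occ >= min_occupancy]
  ens$reference$residues$label[keep]
}

#' Built-in contact-potential substitution scorer
#'
#' Scores a substitution at a position on one frame as
#' \deqn{\sum_{p \in contacts} [e(target, aa_p) - e(wt, aa_p)]
#'       + w_b (h(target) - h(wt)) \cdot burial}
#' where the sum runs over residues of *other* chains with any heavy atom
#' within `cutoff` of the position's heavy atoms in that frame, `e` is a
#' symmetric 20x20 contact energy table (kcal/mol), `h` is Kyte-Doolittle
#' hydropathy rescaled to \[-1, 1\], and fractional burial is
#' min(1, n_contact_neighbours / 10) counting all residues (any chain)
#' within `cutoff` — a contact-count exposure proxy, not a true SASA.
#' The wild-type column is exactly 0 by construction.
#'
#' @param pair_energy_table symmetric 20x20 matrix (kcal/mol); default
#'   [default_pair_potential()].
#' @param burial_weight weight of the hydrophobic-burial term (default 0).
#' @param cutoff contact cutoff, Angstrom.
#' @return Object of class `SubstitutionScorer` with elements `name`,
#'   `parameters` and `score_frame(ens, frame, position_ordinals)` returning
#'   a positions x 20 matrix of per-frame ddG contributions.
#' @export
builtin_contact_scorer <- function(pair_energy_table = NULL,
                                   burial_weight = 0, cutoff = 5.0) {
  if (is.null(pair_energy_table)) pair_energy_table <- default_pair_potential()
  e <- as.matrix(pair_energy_table)
  if (!is.null(rownames(e))) e <- e[AA_ORDER, AA_ORDER]
  stopifnot(nrow(e) == 20L, ncol(e) == 20L)
  if (max(abs(e - t(e))) > 1e-9)
    stop("pair energy table must be symmetric")
  dimnames(e) <- list(AA_ORDER, AA_ORDER)
  h <- KD_HYDROPATHY[AA_ORDER] / 4.5
  score_frame <- function(ens, frame, position_ordinals) {
    a <- ens$reference$atoms
    res <- ens$reference$residues
    heavy <- which(!a$is_hydrogen)
    xyz <- matrix(ens$frames[frame, heavy, ], ncol = 3)
    res_of <- a$residue_ordinal[heavy]
    chain_of <- res$chain[res_of]
    c2 <- cutoff^2
    out <- matrix(0, length(position_ordinals), 20L,
                  dimnames = list(res$label[position_ordinals], AA_ORDER))
    for (k in seq_along(position_ordinals)) {
      p <- position_ordinals[k]
      mine <- res_of == p
      xp <- xyz[mine, , drop = FALSE]
      d2 <- outer(rowSums(xyz^2), rep(1, nrow(xp))) +
        outer(rep(1, nrow(xyz)), rowSums(xp^2)) - 2 * tcrossprod(xyz, xp)
      near_atom <- rowSums(d2 <= c2) > 0L
      near_res <- setdiff(unique(res_of[near_atom]), p)
      wt <- aa_three_to_one(res$resname[p])
      cross <- near_res[res$chain[near_res] != res$chain[p]]
      if (length(cross)) {
        partner_aa <- aa_three_to_one(res$resname[cross])
        partner_aa <- partner_aa[!is.na(partner_aa)]
        if (length(partner_aa)) {
          esum <- rowSums(e[, partner_aa, drop = FALSE])
          out[k, ] <- esum - esum[wt]
        }
      }
      if (burial_weight != 0) {
        burial <- min(1, length(near_res) / 10)
        out[k, ] <- out[k, ] + burial_weight * (h - h[wt]) * burial
      }
    }
    out
  }
  structure(list(name = "builtin_contact",
                 parameters = list(burial_weight = burial_weight,
                                   cutoff = cutoff),
                 pair_energy_table = e,
                 score_frame = score_frame),
            class = "SubstitutionScorer")
}

#' Ensemble-averaged mutational scan
#'
#' Systematically substitutes each scanned position with all 20 amino
#' acids, scores each substitution on every selected frame with the
#' scorer, and averages: ddg\[p, a\] = mean over frames of the per-frame
#' score, with the matching standard error. Deterministic for the stride
#' scheme.
#'
#' @param ens a [conformational_ensemble()].
#' @param scorer a `SubstitutionScorer`, e.g. [builtin_contact_scorer()].
#' @param positions residue labels to scan (standard residues only).
#' @param n_samples number of frames to average over (default 1000,
#'   capped at F).
#' @param scheme frame selection scheme, see [subsample()].
#' @param seed seed for `scheme = "random"`.
#' @return Object of class `MutScanTable`: `residue_labels`, `wt`
#'   (wild-type one-letter codes), `aa_order`, `ddg` and `ddg_se`
#'   (positions x 20, kcal/mol), `n_samples`.
#' @export
scan_mutations <- function(ens, scorer, positions, n_samples = 1000,
                           scheme = c("stride", "random"), seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(ens, "ConformationalEnsemble"),
            inherits(scorer, "SubstitutionScorer"))
  res <- ens$reference$residues
  ords <- match(positions, res$label)
  if (anyNA(ords))
    stop("unknown positions: ", paste(positions[is.na(ords)], collapse = ", "))
  bad <- !res$is_standard[ords]
  if (any(bad))
    stop("non-standard residues cannot be scanned: ",
         paste(positions[bad], collapse = ", "))
  n_samples <- min(as.integer(n_samples), n_frames(ens))
  sub <- subsample(ens, n_samples, scheme = scheme, seed = seed)
  P <- length(ords)
  s1 <- matrix(0, P, 20L)
  s2 <- matrix(0, P, 20L)
  F_ <- n_frames(sub)
  for (f in seq_len(F_)) {
    sc <- scorer$score_frame(sub, f, ords)
    s1 <- s1 + sc
    s2 <- s2 + sc^2
  }
  ddg <- s1 / F_
  # sample sd over frames / sqrt(F)
  se <- sqrt(pmax(s2 - F_ * ddg^2, 0) / max(F_ - 1L, 1L)) / sqrt(F_)
  wt <- aa_three_to_one(res$resname[ords])
  # enforce the scorer contract exactly
  ddg[cbind(seq_len(P), match(wt, AA_ORDER))] <- 0
  dimnames(ddg) <- dimnames(se) <- list(res$label[ords], AA_ORDER)
  structure(list(residue_labels = res$label[ords], wt = wt,
                 aa_order = AA_ORDER, ddg = ddg, ddg_se = se,
                 n_samples = F_),
            class = "MutScanTable")
}

#' @export
print.MutScanTable <- function(x, ...) {
  cat("MutScanTable:", length(x$residue_labels), "positions x 20,",
      x$n_samples, "frames averaged\n")
  invisible(x)
}

#' Aggregate per-frame energy-decomposition tables
#'
#' Averages a set of per-residue MM-GBSA-style decomposition tables
#' (columns `residue`, `total`, `vdw`, `elec`) into per-residue means and
#' standard errors, ranked by mean total contribution.
#'
#' @param tables list of data.frames, or character vector of CSV paths.
#' @return Object of class `EnergyDecompositionTable`: a data.frame with
#'   mean and se columns per component, sorted by `total_mean`, plus
#'   attribute `n_samples`.
#' @export
aggregate_energy_decomposition <- function(tables) {
  if (is.character(tables))
    tables <- lapply(tables, utils::read.csv, stringsAsFactors = FALSE)
  stopifnot(length(tables) >= 1L)
  need <- c("residue", "total", "vdw", "elec")
  ref <- tables[[1]]
  if (!all(need %in% names(ref)))
    stop("tables must have columns: ", paste(need, collapse = ", "))
  for (k in seq_along(tables)) {
    t_ <- tables[[k]]
    if (!all(need %in% names(t_)))
      stop("table ", k, " lacks required columns")
    if (!identical(as.character(t_$residue), as.character(ref$residue))) {
      first_bad <- which(as.character(t_$residue) !=
                           as.character(ref$residue))[1]
      stop("table ", k, " residue labels differ from table 1 first at row ",
           first_bad, " (", t_$residue[first_bad], " vs ",
           ref$residue[first_bad], ")")
    }
  }
  n <- length(tables)
  comp <- c("total", "vdw", "elec")
  out <- data.frame(residue = as.character(ref$residue),
                    stringsAsFactors = FALSE)
  for (cc in comp) {
    m <- sapply(tables, function(t_) t_[[cc]])
    m <- matrix(m, nrow = nrow(ref))
    mu <- rowMeans(m)
    se <- if (n > 1L) apply(m, 1L, stats::sd) / sqrt(n) else rep(0, nrow(m))
    out[[paste0(cc, "_mean")]] <- mu
    out[[paste0(cc, "_se")]] <- se
  }
  out <- out[order(out$total_mean), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_samples = n,
            class = c("EnergyDecompositionTable", "data.frame"))
}

#' Export a mutational-scan table as a heatmap CSV (and optional image)
#'
#' Writes the Figure-style orientation: 20 substitution rows, scanned
#' positions as columns. If `image` is given, renders a diverging heatmap
#' centered at 0 (blue = stabilizing, red = destabilizing).
#'
#' @param table a `MutScanTable`.
#' @param path output CSV path.
#' @param image optional PNG path.
#' @export
export_heatmap <- function(table, path, image = NULL) {
  stopifnot(inherits(table, "MutScanTable"))
  m <- t(table$ddg)  # 20 x positions
  df <- data.frame(substitution = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(image)) {
    long <- data.frame(
      position = factor(rep(colnames(m), each = nrow(m)),
                        levels = colnames(m)),
      substitution = factor(rep(rownames(m), ncol(m)),
                            levels = rev(rownames(m))),
      ddg = as.vector(m))
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$position,
                                            y = .data$substitution,
                                            fill = .data$ddg)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                    high = "red", midpoint = 0,
                                    name = "ddG (kcal/mol)") +
      ggplot2::labs(x = "position", y = "substitution") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         vjust = 0.5))
    ggplot2::ggsave(image, p, width = 1.5 + 0.25 * ncol(m), height = 5,
                    dpi = 150, limitsize = FALSE)
  }
  invisible(path)
}
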
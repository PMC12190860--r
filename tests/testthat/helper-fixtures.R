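# Shared fixtures built in code at test time.

# Ensemble of i.i.d. isotropic Gaussian jitter around a structure.
jitter_ensemble <- function(structure, n_frames, sigma, seed = 1) {
  ref <- as.matrix(structure$atoms[, c("x", "y", "z")])
  set.seed(seed)
  A <- nrow(ref)
  frames <- array(stats::rnorm(n_frames * A * 3, 0, sigma),
                  c(n_frames, A, 3))
  for (d in 1:3) frames[, , d] <- frames[, , d] +
      matrix(ref[, d], n_frames, A, byrow = TRUE)
  conformational_ensemble(structure, frames)
}

# Concatenate two ensembles sharing a reference.
concat_ensembles <- function(e1, e2) {
  stopifnot(identical(e1$reference$residue_labels,
                      e2$reference$residue_labels))
  f <- array(NA_real_, c(dim(e1$frames)[1] + dim(e2$frames)[1],
                         dim(e1$frames)[2], 3))
  f[seq_len(dim(e1$frames)[1]), , ] <- e1$frames
  f[dim(e1$frames)[1] + seq_len(dim(e2$frames)[1]), , ] <- e2$frames
  conformational_ensemble(e1$reference, f)
}

# Apply one rigid motion (rotation about z + translation) to every frame.
rigid_transform_ensemble <- function(ens, angle = 0.7,
                                     shift = c(5, -3, 2)) {
  R <- matrix(c(cos(angle), sin(angle), 0,
                -sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3)
  f <- ens$frames
  for (k in seq_len(dim(f)[1])) {
    m <- matrix(f[k, , ], ncol = 3) %*% R
    f[k, , ] <- sweep(m, 2, shift, "+")
  }
  conformational_ensemble(ens$reference, f, ens$frame_labels)
}

write_tiny_pdb <- function(path, models) {
  # models: list of data.frames with chain, resno, resname, atom, x, y, z
  con <- file(path, "w")
  for (m in seq_along(models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    d <- models[[m]]
    writeLines(sprintf(
      "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(d)), d$atom, d$resname, d$chain, d$resno,
      d$x, d$y, d$z, substr(d$atom, 1, 1)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  close(con)
  path
}

peptide_model <- function(jit = 0) {
  d <- expand.grid(atom = c("N", "CA", "C"), resno = 1:5)
  data.frame(chain = "A", resno = d$resno,
             resname = rep(c("ALA", "GLY", "LEU", "SER", "TYR"),
                           each = 3),
             atom = as.character(d$atom),
             x = 3.8 * d$resno + 0.5 * seq_len(15) / 15 + jit,
             y = rep(c(0, 1, 0), 5), z = 0,
             stringsAsFactors = FALSE)
}

# Scorer with continuous per-frame variation: each substitution's score is
# a fixed multiple of the position's mean Calpha distance to the other
# chain, so i.i.d. frames give i.i.d. continuous scores (used to test the
# 1/sqrt(n) standard-error scaling of ensemble averaging).
continuous_distance_scorer <- function() {
  coefs <- seq(-1, 1, length.out = 20) / 10
  structure(list(
    name = "continuous_distance", parameters = list(),
    score_frame = function(ens, f, ords) {
      res <- ens$reference$residues
      ca <- ens$reference$ca_index
      out <- matrix(0, length(ords), 20,
                    dimnames = list(res$label[ords], allonet::aa_alphabet()))
      for (k in seq_along(ords)) {
        p <- ords[k]
        other <- which(res$chain != res$chain[p])
        d <- sqrt(colSums((t(matrix(ens$frames[f, ca[other], ], ncol = 3)) -
                             ens$frames[f, ca[p], ])^2))
        wt <- allonet::aa_three_to_one(res$resname[p])
        out[k, ] <- coefs * mean(d)
        out[k, wt] <- 0
      }
      out
    }), class = "SubstitutionScorer")
}
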
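# Synthetic fixtures with analytic ground truth.
#
# The elastic-network generator stands in for MD ensembles: frames are
# drawn from the Gaussian whose covariance is the (pseudo-inverted)
# isotropic Kirchhoff stiffness matrix, so the DCCM, RMSF and contact
# statistics of the sampled ensemble have closed-form expectations.

#' Elastic-network sampling specification
#'
#' @param cutoff Calpha-Calpha spring cutoff, Angstrom (default 12).
#' @param spring_constant uniform spring constant, energy/Angstrom^2.
#' @param kT thermal energy in the same units (default 0.6, roughly
#'   kcal/mol at 300 K).
#' @param n_frames number of frames to draw (>= 2).
#' @param seed integer seed.
#' @return Object of class `ENMSpec`.
#' @export
enm_spec <- function(cutoff = 12, spring_constant = 1, kT = 0.6,
                     n_frames = 1000, seed = 1) {
  stopifnot(cutoff > 0, spring_constant > 0, kT >= 0, n_frames >= 2)
  structure(list(cutoff = cutoff, spring_constant = spring_constant,
                 kT = kT, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "ENMSpec")
}

ground_truth <- function(covariance_block, residue_labels,
                         planted_interface = NULL,
                         planted_bottleneck = NULL) {
  N <- length(residue_labels)
  v <- diag(covariance_block)
  v0 <- ifelse(v > 0, v, 1)
  dccm <- covariance_block / sqrt(outer(v0, v0))
  dccm[v <= 0, ] <- 0; dccm[, v <= 0] <- 0
  diag(dccm) <- 1
  # full 3N x 3N covariance, atom-major (x1 y1 z1 x2 ...): the three
  # Cartesian blocks are identical and uncorrelated (isotropic model)
  cov3n <- matrix(0, 3L * N, 3L * N)
  for (d in 1:3) {
    idx <- seq(d, 3L * N, by = 3L)
    cov3n[idx, idx] <- covariance_block
  }
  structure(list(covariance = cov3n, covariance_block = covariance_block,
                 analytic_dccm = dccm, residue_labels = residue_labels,
                 planted_interface = planted_interface,
                 planted_bottleneck = planted_bottleneck),
            class = "GroundTruth")
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat("GroundTruth:", length(x$residue_labels), "residues")
  if (!is.null(x$planted_interface))
    cat(";", length(x$planted_interface), "planted interface residues")
  if (!is.null(x$planted_bottleneck))
    cat("; bottleneck ", paste(x$planted_bottleneck, collapse = ","))
  cat("\n")
  invisible(x)
}

toy_sequence <- function(n, sequence = NULL) {
  if (is.null(sequence))
    return(rep_len(AA_ORDER, n))
  s <- strsplit(sequence, "")[[1]]
  stopifnot(length(s) == n)
  s
}

toy_atoms_from_ca <- function(ca, seq1, chain, bead_offset) {
  n <- nrow(ca)
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- data.frame(
      chain = chain, resno = i, icode = "", resname = AA_THREE[seq1[i]],
      atom = "CA", element = "C",
      x = ca[i, 1], y = ca[i, 2], z = ca[i, 3], stringsAsFactors = FALSE)
    if (seq1[i] != "G") {
      b <- ca[i, ] + bead_offset[i, ]
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resno = i, icode = "", resname = AA_THREE[seq1[i]],
        atom = "CB", element = "C",
        x = b[1], y = b[2], z = b[3], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Build a toy Calpha + pseudo-side-chain structure
#'
#' Bead model with one Calpha per residue and a pseudo side-chain bead
#' 1.5 Angstrom off the backbone axis (glycine gets none, so the
#' sidechain-heavy contact mode's Calpha fallback is exercised).
#' Geometries: `extended` (straight chain, consecutive Calpha spacing
#' exactly 3.8 A), `helix` (ideal alpha-helix: radius 2.3 A, rise
#' 1.5 A, 100 degrees per residue), `dumbbell` (two compact clusters
#' joined by a 3-residue linker that is the only inter-cluster contact
#' path at 5 A).
#'
#' @param n_residues number of residues (>= 4; >= 9 for dumbbell).
#' @param geometry `"extended"`, `"helix"` or `"dumbbell"`.
#' @param seed integer seed (jitters cluster packing deterministically).
#' @param sequence optional one-letter sequence string; default cycles
#'   through the 20 standard residues.
#' @return A [reference_structure()] (single chain "A").
#' @export
build_toy_structure <- function(n_residues,
                                geometry = c("extended", "helix",
                                             "dumbbell"),
                                seed = 1, sequence = NULL) {
  geometry <- match.arg(geometry)
  n <- as.integer(n_residues)
  if (n < 4L) stop("need at least 4 residues")
  seq1 <- toy_sequence(n, sequence)
  if (geometry == "extended") {
    ca <- cbind(3.8 * (seq_len(n) - 1L), 0, 0)
    off <- cbind(0, rep(1.5, n), 0)
  } else if (geometry == "helix") {
    th <- (seq_len(n) - 1L) * 100 * pi / 180
    ca <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * (seq_len(n) - 1L))
    off <- cbind(1.5 * cos(th), 1.5 * sin(th), 0)
  } else {
    if (n < 9L) stop("dumbbell geometry needs at least 9 residues")
    n_link <- 3L
    na <- (n - n_link) %/% 2L
    nb <- n - n_link - na
    grid_cluster <- function(m, origin) {
      k <- ceiling(m^(1 / 3))
      pts <- as.matrix(expand.grid(x = 0:(k - 1), y = 0:(k - 1),
                                   z = 0:(k - 1)))[seq_len(m), , drop = FALSE]
      sweep(pts * 4.0, 2L, origin, "+")
    }
    ca_a <- grid_cluster(na, c(0, 0, 0))
    ca_b <- grid_cluster(nb, c(20, 0, 0))
    xa <- max(ca_a[, 1])
    link_x <- seq(xa + 4, 20 - 4, length.out = n_link)
    ca_l <- cbind(link_x, 0, 0)
    ca <- rbind(ca_a, ca_l, ca_b)
    ca <- ca + with_seed(seed, matrix(stats::runif(3L * n, -0.05, 0.05),
                                      n, 3L))
    off <- cbind(0, rep(1.5, n), 0)
  }
  reference_structure(toy_atoms_from_ca(ca, seq1, "A", off))
}

kirchhoff_matrix <- function(ca, cutoff, spring_constant,
                             bridge_disconnected = FALSE) {
  n <- nrow(ca)
  d <- as.matrix(stats::dist(ca))
  adj <- d <= cutoff & upper.tri(d)
  adj <- adj | t(adj)
  if (bridge_disconnected) {
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
    while (comp$no > 1L) {
      # connect the two nearest atoms of different components
      cross <- outer(comp$membership, comp$membership, "!=")
      dd <- d; dd[!cross] <- Inf
      k <- arrayInd(which.min(dd), dim(dd))
      adj[k[1], k[2]] <- adj[k[2], k[1]] <- TRUE
      comp <- igraph::components(
        igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
    }
  }
  gamma <- -spring_constant * adj
  diag(gamma) <- -rowSums(gamma)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
  if (comp$no > 1L)
    stop("elastic network is disconnected; use a larger cutoff")
  gamma
}

sample_gaussian_frames <- function(structure, gamma, kT, n_frames, seed) {
  ev <- eigen(gamma, symmetric = TRUE)
  keep <- ev$values > 1e-8 * max(ev$values)
  lam <- ev$values[keep]
  V <- ev$vectors[, keep, drop = FALSE]
  N <- nrow(gamma)
  cov_block <- kT * V %*% (t(V) / lam)
  A <- nrow(structure$atoms)
  frames <- array(NA_real_, c(n_frames, A, 3L))
  ref_xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  res_of <- structure$atoms$residue_ordinal
  L <- sweep(V, 2L, sqrt(kT / lam), "*")
  disp <- with_seed(seed, {
    lapply(1:3, function(d)
      matrix(stats::rnorm(n_frames * ncol(V)), n_frames) %*% t(L))
  })
  for (d in 1:3) {
    # each residue's atoms (Calpha + bead) move rigidly with its node
    frames[, , d] <- sweep(disp[[d]][, res_of, drop = FALSE], 2L,
                           ref_xyz[, d], "+")
  }
  list(ens = conformational_ensemble(structure, frames),
       cov_block = cov_block)
}

#' Sample a Gaussian elastic-network ensemble with analytic ground truth
#'
#' Builds the isotropic Kirchhoff stiffness matrix over Calpha pairs
#' within the cutoff, takes covariance = kT x pseudo-inverse (rigid modes
#' removed by eigenvalue thresholding at 1e-8 of the largest eigenvalue),
#' and draws frames from the zero-mean Gaussian added to the reference
#' coordinates. Pseudo-side-chain beads move rigidly with their Calpha.
#'
#' @param structure a [reference_structure()].
#' @param spec an [enm_spec()].
#' @return List with `ensemble` (a [conformational_ensemble()]) and
#'   `ground_truth` (covariance, analytic DCCM).
#' @export
sample_enm_ensemble <- function(structure, spec = enm_spec()) {
  stopifnot(inherits(structure, "ReferenceStructure"),
            inherits(spec, "ENMSpec"))
  ca <- as.matrix(structure$atoms[structure$ca_index, c("x", "y", "z")])
  gamma <- kirchhoff_matrix(ca, spec$cutoff, spec$spring_constant)
  out <- sample_gaussian_frames(structure, gamma, spec$kT, spec$n_frames,
                                spec$seed)
  list(ensemble = out$ens,
       ground_truth = ground_truth(out$cov_block,
                                   structure$residue_labels))
}

#' Build and sample a two-chain toy complex with a planted interface
#'
#' Chain A (n_a residues) and chain B (n_b residues) are extended chains
#' placed so that exactly `n_interface_contacts` consecutive mid-chain A
#' residues have heavy atoms within 4.5 Angstrom of chain B in the
#' reference (the planted interface); all other A residues stay more
#' than 5 Angstrom away. With zero contacts the chains are placed more
#' than 20 Angstrom apart. The ensemble is sampled from an elastic
#' network over the whole complex (disconnected components, which arise
#' with an empty interface, are bridged by one weak spring between
#' nearest Calpha atoms so the null fixture can still be sampled).
#'
#' @param n_a,n_b chain lengths (>= 4).
#' @param n_interface_contacts number of planted interface residues,
#'   <= min(n_a, n_b).
#' @param seed integer seed.
#' @param n_frames frames to sample (default 200).
#' @param kT thermal energy (default 0.6).
#' @param cutoff ENM spring cutoff (default 12).
#' @return List with `ensemble` and `ground_truth` (including
#'   `planted_interface` labels on chain A).
#' @export
make_toy_complex <- function(n_a, n_b, n_interface_contacts, seed = 1,
                             n_frames = 200, kT = 0.6, cutoff = 12) {
  n_a <- as.integer(n_a); n_b <- as.integer(n_b)
  K <- as.integer(n_interface_contacts)
  stopifnot(n_a >= 4L, n_b >= 4L, K >= 0L)
  if (K > min(n_a, n_b))
    stop("n_interface_contacts must be <= min(n_a, n_b)")
  y_b <- if (K > 0L) 10 else 25
  seq_a <- rep_len(AA_ORDER[AA_ORDER != "G"], n_a)
  seq_b <- rep_len(rev(AA_ORDER[AA_ORDER != "G"]), n_b)
  ca_a <- cbind(3.8 * (seq_len(n_a) - 1L), 0, 0)
  planted <- integer(0)
  if (K > 0L) {
    c0 <- (n_a - K) %/% 2L + 1L
    planted <- c0:(c0 + K - 1L)
    ca_a[planted, 2] <- y_b - 6.5
  }
  center_x <- if (K > 0L) mean(ca_a[planted, 1]) else mean(ca_a[, 1])
  ca_b <- cbind(center_x + 3.8 * (seq_len(n_b) - 1L) -
                  3.8 * (n_b - 1L) / 2, y_b, 0)
  off_a <- cbind(0, rep(1.5, n_a), 0)
  off_b <- cbind(0, rep(-1.5, n_b), 0)
  atoms <- rbind(toy_atoms_from_ca(ca_a, seq_a, "A", off_a),
                 toy_atoms_from_ca(ca_b, seq_b, "B", off_b))
  ref <- reference_structure(atoms)
  ca <- as.matrix(ref$atoms[ref$ca_index, c("x", "y", "z")])
  gamma <- kirchhoff_matrix(ca, cutoff, 1, bridge_disconnected = TRUE)
  out <- sample_gaussian_frames(ref, gamma, kT, as.integer(n_frames), seed)
  gt <- ground_truth(out$cov_block, ref$residue_labels,
                     planted_interface = ref$residues$label[planted])
  list(ensemble = out$ens, ground_truth = gt)
}

#' Plant a bottleneck (dumbbell) graph
#'
#' Builds dense clusters joined only through one designated articulation
#' node, the planted communication bottleneck: removing it disconnects
#' the graph, and it carries every inter-cluster shortest path.
#'
#' @param cluster_sizes integer vector (>= 2 clusters, each >= 3 nodes).
#' @param inter_edge_g coupling of articulation-cluster edges, in (0, 1).
#' @param intra_edge_g coupling of intra-cluster edges, in (0, 1).
#' @param seed integer seed (deterministic +/-5% coupling jitter).
#' @return List with `graph` (a [residue_graph()]) and `ground_truth`
#'   carrying `planted_bottleneck`.
#' @export
plant_bottleneck_graph <- function(cluster_sizes = c(6, 6),
                                   inter_edge_g = 0.5, intra_edge_g = 0.9,
                                   seed = 1) {
  stopifnot(length(cluster_sizes) >= 2L)
  if (any(cluster_sizes < 3L)) stop("every cluster needs at least 3 nodes")
  if (inter_edge_g <= 0 || inter_edge_g >= 1 ||
      intra_edge_g <= 0 || intra_edge_g >= 1)
    stop("edge couplings must lie strictly in (0, 1)")
  chains <- LETTERS[seq_along(cluster_sizes)]
  nodes <- do.call(rbind, lapply(seq_along(cluster_sizes), function(c_) {
    m <- cluster_sizes[c_]
    data.frame(label = paste0(chains[c_], ":", seq_len(m)),
               chain = chains[c_], resno = seq_len(m),
               resname = AA_THREE[rep_len(AA_ORDER, m)],
               stringsAsFactors = FALSE)
  }))
  hub <- data.frame(label = "X:1", chain = "X", resno = 1L,
                    resname = "ALA", stringsAsFactors = FALSE)
  nodes <- rbind(nodes, hub)
  edges <- list()
  jit <- function(g, n) pmin(pmax(g * (1 + stats::runif(n, -0.05, 0.05)),
                                  G_FLOOR), G_CEIL)
  with_seed(seed, {
    for (c_ in seq_along(cluster_sizes)) {
      labsc <- nodes$label[nodes$chain == chains[c_]]
      pr <- utils::combn(labsc, 2)
      g <- jit(intra_edge_g, ncol(pr))
      edges[[length(edges) + 1L]] <- data.frame(
        i = pr[1, ], j = pr[2, ], occupancy = 1, g = g,
        distance = -log(g), backbone = FALSE, stringsAsFactors = FALSE)
      g2 <- jit(inter_edge_g, length(labsc))
      edges[[length(edges) + 1L]] <- data.frame(
        i = labsc, j = "X:1", occupancy = 1, g = g2,
        distance = -log(g2), backbone = FALSE, stringsAsFactors = FALSE)
    }
  })
  e <- do.call(rbind, edges)
  gr <- residue_graph(nodes, e,
                      build_options = list(planted = TRUE, seed = seed))
  gt <- structure(list(covariance = NULL, covariance_block = NULL,
                       analytic_dccm = NULL,
                       residue_labels = nodes$label,
                       planted_interface = NULL,
                       planted_bottleneck = "X:1"),
                  class = "GroundTruth")
  list(graph = gr, ground_truth = gt)
}

#' Sample a multiple-sequence alignment with planted coupled columns
#'
#' Columns are i.i.d. uniform over the 20 amino acids except the planted
#' pairs: with probability `coupling_strength` the two columns of a pair
#' share one uniformly drawn letter, otherwise they are independent.
#' The analytic mutual information of that mixture is returned per pair
#' (0 nats at strength 0, ln 20 at strength 1).
#'
#' @param n_sequences,n_columns alignment dimensions.
#' @param coupled_pairs 2-column matrix (or list of length-2 vectors) of
#'   column indices; pairs must be disjoint.
#' @param coupling_strength in \[0, 1\].
#' @param seed integer seed.
#' @param fasta optional path to also write the alignment as FASTA.
#' @return List with `alignment` (`Biostrings::AAStringSet`), `matrix`
#'   (sequences x columns), `coupled_pairs`, `ground_truth_mi` (nats).
#' @export
sample_coupled_msa <- function(n_sequences, n_columns, coupled_pairs,
                               coupling_strength, seed = 1, fasta = NULL) {
  if (is.list(coupled_pairs))
    coupled_pairs <- do.call(rbind, coupled_pairs)
  coupled_pairs <- matrix(as.integer(coupled_pairs), ncol = 2L)
  if (anyDuplicated(as.vector(coupled_pairs)))
    stop("coupled pairs must be disjoint")
  if (any(coupled_pairs < 1L | coupled_pairs > n_columns))
    stop("coupled pair column out of range")
  s <- coupling_strength
  if (s < 0 || s > 1) stop("coupling_strength must be in [0, 1]")
  m <- with_seed(seed, {
    m <- matrix(sample(AA_ORDER, n_sequences * n_columns, replace = TRUE),
                n_sequences, n_columns)
    for (p in seq_len(nrow(coupled_pairs))) {
      i <- coupled_pairs[p, 1]; j <- coupled_pairs[p, 2]
      same <- stats::runif(n_sequences) < s
      m[same, j] <- m[same, i]
    }
    m
  })
  # analytic MI of the mixture p(x,y) = s [x==y]/20 + (1-s)/400
  p_d <- s / 20 + (1 - s) / 400
  p_o <- (1 - s) / 400
  mi <- 20 * p_d * log(p_d * 400)
  if (p_o > 0) mi <- mi + 380 * p_o * log(p_o * 400)
  seqs <- apply(m, 1L, paste0, collapse = "")
  aln <- Biostrings::AAStringSet(seqs)
  names(aln) <- sprintf("seq%04d", seq_len(n_sequences))
  if (!is.null(fasta)) Biostrings::writeXStringSet(aln, fasta)
  list(alignment = aln, matrix = m, coupled_pairs = coupled_pairs,
       ground_truth_mi = rep(mi, nrow(coupled_pairs)))
}
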
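# Dynamically weighted residue interaction networks.
#
# Edges connect residue pairs whose contact occupancy meets a threshold;
# the edge coupling g in (0, 1] mixes dynamic correlation with (optional)
# coevolutionary mutual information, and the communication distance is
# d = -ln(g), so strongly coupled pairs are "close". Consecutive residues
# of a chain are always connected (backbone augmentation) because
# communication physically propagates along the backbone.

G_FLOOR <- 0.01
G_CEIL <- 1 - 1e-9

clamp_g <- function(g) pmin(pmax(g, G_FLOOR), G_CEIL)

#' Construct a residue graph from components
#'
#' Low-level constructor; most users want [build_residue_graph()].
#'
#' @param nodes data.frame with columns `label`, `chain`, `resno`,
#'   `resname` (3-letter code or NA).
#' @param edges data.frame with columns `i`, `j` (labels), `occupancy`,
#'   `g`, `distance`, `backbone` (logical).
#' @param build_options named list recording construction parameters.
#' @return Object of class `ResidueGraph`.
#' @export
residue_graph <- function(nodes, edges, build_options = list()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "chain", "resno", "resname") %in% names(nodes)))
  if (nrow(edges)) {
    stopifnot(all(c("i", "j", "occupancy", "g", "distance",
                    "backbone") %in% names(edges)))
    if (any(edges$i == edges$j)) stop("self-edges are not allowed")
    if (!all(c(edges$i, edges$j) %in% nodes$label))
      stop("edge endpoint not in node set")
    if (any(edges$g <= 0 | edges$g > 1)) stop("couplings must be in (0, 1]")
    if (any(edges$distance <= 0)) stop("distances must be positive")
    if (max(abs(edges$distance + log(edges$g))) > 1e-12)
      stop("edge distance must equal -ln(g)")
    key <- paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j))
    if (anyDuplicated(key)) stop("duplicate edges")
  }
  structure(list(nodes = nodes, edges = edges,
                 build_options = build_options),
            class = "ResidueGraph")
}

#' @export
print.ResidueGraph <- function(x, ...) {
  cat("ResidueGraph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Convert a residue graph to an igraph object
#'
#' Edge attribute `weight` carries the communication distance.
#'
#' @param graph a `ResidueGraph`.
#' @return An undirected [igraph::graph].
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "ResidueGraph"))
  g <- igraph::make_empty_graph(n = nrow(graph$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = graph$nodes$label)
  if (nrow(graph$edges)) {
    g <- igraph::add_edges(g, rbind(match(graph$edges$i, graph$nodes$label),
                                    match(graph$edges$j, graph$nodes$label)))
    g <- igraph::set_edge_attr(g, "weight", value = graph$edges$distance)
    g <- igraph::set_edge_attr(g, "g", value = graph$edges$g)
  }
  g
}

#' Build a dynamically weighted residue interaction graph
#'
#' An edge is created for every residue pair with contact occupancy >= tau;
#' its coupling is g = (1 - lambda) g_dyn + lambda g_coev, where g_dyn is
#' |C_ij| for a signed DCCM or the generalized correlation directly, and
#' g_coev is min-max-normalized mutual information. g is clamped to
#' \[0.01, 1 - 1e-9\] (capping any single-edge distance at ln 100) and the
#' communication distance is d = -ln(g). Consecutive residues of the same
#' chain are always connected (backbone augmentation) with their computed
#' coupling, or the clamp floor if none is available.
#'
#' @param occupancy a `ContactOccupancyMap`.
#' @param coupling a [correlation_matrix()] sharing the occupancy labels.
#' @param tau occupancy threshold in \[0, 1\] (default 0.5).
#' @param lambda coevolutionary mixing weight in \[0, 1\] (default 0,
#'   dynamics only); lambda > 0 requires `coev_mi`.
#' @param coev_mi optional N x N mutual-information matrix.
#' @param reference optional [reference_structure()] supplying chain /
#'   residue-name metadata (needed for reweight-mode perturbation).
#' @return A [residue_graph()].
#' @export
build_residue_graph <- function(occupancy, coupling, tau = 0.5, lambda = 0,
                                coev_mi = NULL, reference = NULL) {
  stopifnot(inherits(occupancy, "ContactOccupancyMap"),
            inherits(coupling, "CorrelationMatrix"))
  if (tau < 0 || tau > 1) stop("tau must be in [0, 1]")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  labs <- occupancy$residue_labels
  if (!identical(labs, coupling$residue_labels))
    stop("occupancy and coupling residue labels differ")
  N <- length(labs)
  g_dyn <- if (coupling$kind == "signed_dccm") abs(coupling$values) else
    coupling$values
  if (lambda > 0) {
    if (is.null(coev_mi)) stop("lambda > 0 requires coev_mi")
    mi <- as.matrix(coev_mi)
    if (nrow(mi) != N || ncol(mi) != N)
      stop("coev_mi dimensions do not match residue labels")
    off <- mi[upper.tri(mi)]
    rng <- range(off)
    g_coev <- if (diff(rng) > 0) (mi - rng[1]) / diff(rng) else
      matrix(0.5, N, N)
  } else {
    g_coev <- matrix(0, N, N)
  }
  gmat <- (1 - lambda) * g_dyn + lambda * g_coev
  # node metadata
  if (!is.null(reference)) {
    stopifnot(identical(reference$residue_labels, labs))
    nodes <- data.frame(label = labs, chain = reference$residues$chain,
                        resno = reference$residues$resno,
                        resname = reference$residues$resname,
                        stringsAsFactors = FALSE)
  } else {
    chain <- sub(":.*$", "", labs)
    resno <- suppressWarnings(as.integer(sub("^.*:", "", labs)))
    nodes <- data.frame(label = labs, chain = chain, resno = resno,
                        resname = NA_character_, stringsAsFactors = FALSE)
  }
  ut <- which(upper.tri(gmat), arr.ind = TRUE)
  occ_v <- occupancy$values[ut]
  contact <- occ_v >= tau
  # backbone: consecutive ordinals within the same chain
  bb_pair <- nodes$chain[ut[, 1]] == nodes$chain[ut[, 2]] &
    ut[, 2] == ut[, 1] + 1L
  keep <- contact | bb_pair
  g_v <- clamp_g(gmat[ut])
  edges <- data.frame(i = labs[ut[keep, 1]], j = labs[ut[keep, 2]],
                      occupancy = occ_v[keep], g = g_v[keep],
                      distance = -log(g_v[keep]),
                      backbone = bb_pair[keep], stringsAsFactors = FALSE)
  gr <- residue_graph(nodes, edges,
                      build_options = list(cutoff = occupancy$cutoff,
                                           atom_mode = occupancy$atom_mode,
                                           tau = tau, lambda = lambda,
                                           coupling_kind = coupling$kind,
                                           clamp = c(G_FLOOR, G_CEIL)))
  comp <- igraph::components(as_igraph(gr))
  if (comp$no > 1L)
    warning("residue graph has ", comp$no,
            " connected components after backbone augmentation")
  gr
}

#' Normalized shortest-path betweenness centrality (SPC)
#'
#' For each node i, sums over node pairs (j, k) the fraction of minimal-
#' distance paths between j and k that pass through i (co-minimal paths
#' counted with multiplicity), then normalizes by (N - 1)(N - 2)/2 where N
#' is the size of i's connected component, so SPC lies in \[0, 1\] and a
#' star center scores exactly 1.
#'
#' @param graph a `ResidueGraph`.
#' @return Object of class `CentralityProfile`: `residue_labels`, `spc`,
#'   `raw_spc`.
#' @export
compute_spc <- function(graph) {
  stopifnot(inherits(graph, "ResidueGraph"))
  if (nrow(graph$edges) && any(graph$edges$distance <= 0))
    stop("non-positive edge distance")
  ig <- as_igraph(graph)
  raw <- igraph::betweenness(ig, directed = FALSE,
                             weights = igraph::E(ig)$weight)
  comp <- igraph::components(ig)
  csize <- comp$csize[comp$membership]
  denom <- (csize - 1) * (csize - 2) / 2
  spc <- ifelse(denom > 0, raw / denom, 0)
  structure(list(residue_labels = graph$nodes$label,
                 spc = unname(spc), raw_spc = unname(raw)),
            class = "CentralityProfile")
}

#' @export
print.CentralityProfile <- function(x, ...) {
  cat("CentralityProfile:", length(x$residue_labels), "residues, max SPC ",
      signif(max(x$spc), 4), "\n")
  invisible(x)
}

#' Deterministic shortest path between two residues
#'
#' Dijkstra search with ties broken by lexicographic node-label order, so
#' the returned path is reproducible. An unreachable target yields
#' `reachable = FALSE` (not an error).
#'
#' @param graph a `ResidueGraph`.
#' @param source,target node labels.
#' @return List with `path` (label sequence or NULL), `distance`
#'   (Inf if unreachable), `reachable`.
#' @export
shortest_path <- function(graph, source, target) {
  labs <- graph$nodes$label
  s <- match(source, labs); t_ <- match(target, labs)
  if (is.na(s) || is.na(t_)) stop("unknown node: ",
                                  if (is.na(s)) source else target)
  n <- length(labs)
  if (s == t_)
    return(list(path = labs[s], distance = 0, reachable = TRUE))
  adj <- vector("list", n)
  if (nrow(graph$edges)) {
    ei <- match(graph$edges$i, labs); ej <- match(graph$edges$j, labs)
    for (k in seq_len(nrow(graph$edges))) {
      adj[[ei[k]]] <- rbind(adj[[ei[k]]], c(ej[k], graph$edges$distance[k]))
      adj[[ej[k]]] <- rbind(adj[[ej[k]]], c(ei[k], graph$edges$distance[k]))
    }
  }
  dist <- rep(Inf, n); dist[s] <- 0
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    # smallest distance; ties by label order for determinism
    u <- cand[order(dist[cand], labs[cand])][1]
    if (u == t_) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]; w <- nb[r, 2]
      alt <- dist[u] + w
      tol <- 1e-12 * max(1, abs(alt))
      if (alt < dist[v] - tol) {
        dist[v] <- alt; prev[v] <- u
      } else if (abs(alt - dist[v]) <= tol && !is.na(prev[v])) {
        # co-minimal: prefer the lexicographically smaller predecessor label
        if (labs[u] < labs[prev[v]]) prev[v] <- u
      }
    }
  }
  if (!is.finite(dist[t_]))
    return(list(path = NULL, distance = Inf, reachable = FALSE))
  path <- t_
  while (path[1] != s) path <- c(prev[path[1]], path)
  list(path = labs[path], distance = dist[t_], reachable = TRUE)
}

#' Export a residue graph as an edge-list TSV plus JSON sidecar
#'
#' The TSV has columns `node_i node_j occupancy g distance backbone`
#' (labels quoted); the JSON sidecar (`<path>.json`) records the node
#' table and build options so [import_graph()] is lossless.
#'
#' @param graph a `ResidueGraph`.
#' @param path output TSV path.
#' @export
export_graph <- function(graph, path) {
  stopifnot(inherits(graph, "ResidueGraph"))
  e <- graph$edges
  num17 <- function(x) formatC(x, digits = 17, format = "g")
  out <- data.frame(node_i = if (nrow(e)) e$i else character(0),
                    node_j = if (nrow(e)) e$j else character(0),
                    occupancy = if (nrow(e)) num17(e$occupancy) else character(0),
                    g = if (nrow(e)) num17(e$g) else character(0),
                    distance = if (nrow(e)) num17(e$distance) else character(0),
                    backbone = if (nrow(e)) e$backbone else logical(0))
  con <- file(path, "w")
  utils::write.table(out, con, sep = "\t", quote = c(1L, 2L),
                     row.names = FALSE, qmethod = "double")
  close(con)
  sidecar <- list(nodes = graph$nodes, build_options = graph$build_options)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Import a residue graph written by [export_graph()]
#'
#' @param path TSV path (sidecar `<path>.json` must exist).
#' @return A [residue_graph()].
#' @export
import_graph <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  nodes <- as.data.frame(side$nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$resname)) nodes$resname <- NA_character_
  nodes$resname <- as.character(nodes$resname)
  edges <- data.frame(i = as.character(e$node_i), j = as.character(e$node_j),
                      occupancy = e$occupancy, g = e$g,
                      distance = e$distance, backbone = as.logical(e$backbone),
                      stringsAsFactors = FALSE)
  if (!nrow(e))
    edges <- edges[0, , drop = FALSE]
  # re-derive the exact -ln(g) relation lost to decimal serialization
  edges$distance <- -log(edges$g)
  opts <- side$build_options
  residue_graph(nodes, edges, build_options = opts)
}

#' Column-pair mutual information of a multiple sequence alignment
#'
#' Plug-in (empirical frequency) MI estimate in nats per column pair,
#' used as the coevolutionary coupling input of [build_residue_graph()].
#'
#' @param msa character vector of aligned sequences (equal length), a
#'   character matrix (sequences x columns), or a `Biostrings::AAStringSet`.
#' @return Symmetric n_columns x n_columns MI matrix (zero diagonal).
#' @export
compute_column_mi <- function(msa) {
  if (inherits(msa, "AAStringSet")) msa <- as.character(msa)
  if (is.character(msa) && !is.matrix(msa)) {
    if (length(unique(nchar(msa))) != 1L)
      stop("aligned sequences must share a length")
    msa <- do.call(rbind, strsplit(msa, ""))
  }
  L <- ncol(msa)
  mi <- matrix(0, L, L)
  singles <- lapply(seq_len(L), function(k) table(msa[, k]) / nrow(msa))
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      joint <- table(msa[, i], msa[, j]) / nrow(msa)
      pi_ <- singles[[i]][rownames(joint)]
      pj <- singles[[j]][colnames(joint)]
      ratio <- joint / outer(as.numeric(pi_), as.numeric(pj))
      nz <- joint > 0
      mi[i, j] <- mi[j, i] <- sum(joint[nz] * log(ratio[nz]))
    }
  }
  mi
}
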
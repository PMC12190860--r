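# Independent oracles, deliberately implemented with different algorithms
# than the package (quaternion superposition vs SVD; exhaustive path
# enumeration and Floyd-Warshall vs Brandes/Dijkstra).

# Optimal rigid-fit RMSD via Horn's quaternion method.
quaternion_rmsd <- function(x, y) {
  stopifnot(nrow(x) == nrow(y))
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  S <- t(yc) %*% xc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(xc^2) + sum(yc^2) - 2 * lam) / nrow(x)
  sqrt(max(msd, 0))
}

# Distance matrix of a ResidueGraph (Inf where no edge).
graph_dist_matrix <- function(graph) {
  labs <- graph$nodes$label
  n <- length(labs)
  d <- matrix(Inf, n, n, dimnames = list(labs, labs))
  diag(d) <- 0
  e <- graph$edges
  if (nrow(e)) {
    i <- match(e$i, labs); j <- match(e$j, labs)
    d[cbind(i, j)] <- d[cbind(j, i)] <- e$distance
  }
  d
}

floyd_warshall <- function(d) {
  n <- nrow(d)
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, dk)
  }
  d
}

# ASPL over reachable unordered pairs.
oracle_aspl <- function(graph) {
  fw <- floyd_warshall(graph_dist_matrix(graph))
  v <- fw[upper.tri(fw)]
  v <- v[is.finite(v)]
  if (!length(v)) return(0)
  mean(v)
}

# Enumerate every simple path between two nodes (adjacency list of
# matrices: cols node, weight), returning list of (path, length).
enumerate_paths <- function(adj, s, t_) {
  out <- list()
  recurse <- function(node, visited, len) {
    if (node == t_) {
      out[[length(out) + 1L]] <<- list(path = visited, len = len)
      return(invisible(NULL))
    }
    nb <- adj[[node]]
    if (is.null(nb)) return(invisible(NULL))
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]
      if (v %in% visited) next
      recurse(v, c(visited, v), len + nb[r, 2])
    }
  }
  recurse(s, s, 0)
  out
}

# Brute-force normalized betweenness by exhaustive shortest-path
# enumeration with relative tolerance 1e-9 for co-minimal paths.
oracle_spc <- function(graph) {
  labs <- graph$nodes$label
  n <- length(labs)
  adj <- vector("list", n)
  e <- graph$edges
  if (nrow(e)) {
    ei <- match(e$i, labs); ej <- match(e$j, labs)
    for (k in seq_len(nrow(e))) {
      adj[[ei[k]]] <- rbind(adj[[ei[k]]], c(ej[k], e$distance[k]))
      adj[[ej[k]]] <- rbind(adj[[ej[k]]], c(ei[k], e$distance[k]))
    }
  }
  raw <- numeric(n)
  comp <- igraph::components(allonet::as_igraph(graph))$membership
  for (j in seq_len(n - 1L)) {
    for (k in (j + 1L):n) {
      if (comp[j] != comp[k]) next
      paths <- enumerate_paths(adj, j, k)
      if (!length(paths)) next
      lens <- vapply(paths, `[[`, numeric(1), "len")
      dmin <- min(lens)
      minimal <- which(lens <= dmin + 1e-9 * max(1, dmin))
      g_jk <- length(minimal)
      for (m in minimal) {
        interior <- setdiff(paths[[m]]$path, c(j, k))
        raw[interior] <- raw[interior] + 1 / g_jk
      }
    }
  }
  csize <- table(comp)[as.character(comp)]
  denom <- (as.numeric(csize) - 1) * (as.numeric(csize) - 2) / 2
  list(raw = raw, spc = ifelse(denom > 0, raw / denom, 0))
}

# Seeded random connected weighted graph on n nodes as a ResidueGraph.
random_connected_graph <- function(n, seed, p = 0.45) {
  set.seed(seed)
  repeat {
    adj <- matrix(stats::runif(n * n) < p, n, n)
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    # spanning chain guarantees connectivity
    adj[cbind(seq_len(n - 1L), 2:n)] <- TRUE
    ut <- which(adj, arr.ind = TRUE)
    d <- stats::runif(nrow(ut), 0.2, 2.5)
    g <- exp(-d)
    labs <- sprintf("n%02d", seq_len(n))
    nodes <- data.frame(label = labs, chain = "N", resno = seq_len(n),
                        resname = rep_len(allonet::aa_one_to_three(
                          allonet::aa_alphabet()), n),
                        stringsAsFactors = FALSE)
    edges <- data.frame(i = labs[ut[, 1]], j = labs[ut[, 2]],
                        occupancy = 1, g = g, distance = d,
                        backbone = FALSE, stringsAsFactors = FALSE)
    gr <- allonet::residue_graph(nodes, edges)
    if (igraph::components(allonet::as_igraph(gr))$no == 1L) return(gr)
  }
}

# ResidueGraph from an explicit distance edge list (g = exp(-d)).
graph_from_edges <- function(labels, edge_i, edge_j, dist) {
  nodes <- data.frame(label = labels, chain = "N",
                      resno = seq_along(labels),
                      resname = rep_len(allonet::aa_one_to_three(
                        allonet::aa_alphabet()), length(labels)),
                      stringsAsFactors = FALSE)
  edges <- data.frame(i = edge_i, j = edge_j, occupancy = 1,
                      g = exp(-dist), distance = dist, backbone = FALSE,
                      stringsAsFactors = FALSE)
  allonet::residue_graph(nodes, edges)
}

star_graph <- function(n_leaves, d = 1) {
  labs <- c("ctr", sprintf("lf%02d", seq_len(n_leaves)))
  graph_from_edges(labs, rep("ctr", n_leaves), labs[-1],
                   rep(d, n_leaves))
}
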
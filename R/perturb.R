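# Network-based mutational profiling.
#
# Each residue node is perturbed (removed, or its incident couplings
# reweighted by a substitution similarity), the change of a global network
# observable is recorded per substitution, aggregated over the 19
# substitutions as dL_i = <|dL_i^j|^2> (mean of squared changes, with rms
# and mean_abs variants), and standardized over nodes to
# Z_i = (dL_i - <dL>) / sigma with the population standard deviation.
# High-Z residues are allosteric hotspot candidates: positions whose
# mutation maximally degrades network communication.

#' Global network observable
#'
#' `"aspl"`: average shortest-path (communication) distance over all
#' reachable node pairs, the characteristic path length. `"node_spc"`:
#' the per-node normalized betweenness profile of [compute_spc()].
#'
#' @param graph a `ResidueGraph`.
#' @param observable `"aspl"` or `"node_spc"`.
#' @return Scalar (aspl) or named numeric vector (node_spc).
#' @export
graph_observable <- function(graph, observable = c("aspl", "node_spc")) {
  observable <- match.arg(observable)
  stopifnot(inherits(graph, "ResidueGraph"))
  if (nrow(graph$nodes) == 0L) stop("empty graph")
  if (observable == "aspl") {
    ig <- as_igraph(graph)
    w <- if (nrow(graph$edges)) igraph::E(ig)$weight else NULL
    v <- suppressWarnings(igraph::mean_distance(ig, weights = w,
                                                directed = FALSE,
                                                unconnected = TRUE))
    # a graph with no reachable pairs at all has zero path length
    if (!is.finite(v)) 0 else v
  } else {
    p <- compute_spc(graph)
    stats::setNames(p$spc, p$residue_labels)
  }
}

drop_node <- function(graph, node) {
  keep_e <- graph$edges$i != node & graph$edges$j != node
  residue_graph(graph$nodes[graph$nodes$label != node, , drop = FALSE],
                graph$edges[keep_e, , drop = FALSE],
                graph$build_options)
}

#' Apply a mutational perturbation to one node
#'
#' `remove` deletes the node and its incident edges (identical for all 19
#' substitutions). `reweight` multiplies each incident edge's coupling by
#' s(wild-type, mutation) from the similarity table, re-clamps to the
#' coupling bounds and recomputes d = -ln(g), so connectivity is preserved
#' (backbone edges never drop below the clamp floor).
#'
#' @param graph a `ResidueGraph` whose nodes carry residue names
#'   (reweight mode).
#' @param node node label.
#' @param mutation target amino acid (one-letter); required for reweight,
#'   must differ from the wild type.
#' @param mode `"remove"` or `"reweight"`.
#' @param similarity a [substitution_similarity()] table (default
#'   [default_similarity()]).
#' @return A perturbed `ResidueGraph`.
#' @export
perturb_node <- function(graph, node, mutation = NULL,
                         mode = c("remove", "reweight"),
                         similarity = default_similarity()) {
  mode <- match.arg(mode)
  stopifnot(inherits(graph, "ResidueGraph"))
  k <- match(node, graph$nodes$label)
  if (is.na(k)) stop("unknown node: ", node)
  if (mode == "remove") return(drop_node(graph, node))
  wt3 <- graph$nodes$resname[k]
  wt <- aa_three_to_one(wt3)
  if (is.na(wt))
    stop("node ", node, " has no standard residue name; ",
         "reweight mode needs one")
  if (is.null(mutation)) stop("reweight mode requires a mutation")
  mutation <- toupper(mutation)
  if (!mutation %in% AA_ORDER) stop("unknown amino acid: ", mutation)
  if (mutation == wt) stop("mutation equals the wild-type residue")
  s <- unclass(similarity)[wt, mutation]
  e <- graph$edges
  inc <- e$i == node | e$j == node
  e$g[inc] <- clamp_g(e$g[inc] * s)
  e$distance[inc] <- -log(e$g[inc])
  residue_graph(graph$nodes, e, graph$build_options)
}

#' Mutational network-perturbation profile
#'
#' For each node i and each of the 19 non-wild-type substitutions j,
#' records dL_i^j = observable(perturbed graph) - observable(original),
#' aggregates over substitutions (default: mean of squared changes) and
#' standardizes over nodes to a Z-score profile. In remove mode all 19
#' substitutions coincide, so the perturbed observable is computed once
#' per node. If node removal disconnects a component, the ASPL is taken
#' over the remaining reachable pairs (kept finite by design). For the
#' `node_spc` observable, dL_i^j is the mean absolute SPC change over the
#' nodes present in both graphs.
#'
#' @param graph a `ResidueGraph`.
#' @param mode `"reweight"` (default) or `"remove"`.
#' @param observable `"aspl"` (default) or `"node_spc"`.
#' @param similarity a [substitution_similarity()] table (reweight mode).
#' @param aggregation `"mean_square"` (default, literal mean of |dL|^2),
#'   `"rms"`, or `"mean_abs"`.
#' @return Object of class `PerturbationProfile`: `residue_labels`,
#'   `per_mutation_delta` (N x 19), `delta_L`, `z`, `observable`, `mode`,
#'   `aggregation`.
#' @export
profile_perturbations <- function(graph,
                                  mode = c("reweight", "remove"),
                                  observable = c("aspl", "node_spc"),
                                  similarity = default_similarity(),
                                  aggregation = c("mean_square", "rms",
                                                  "mean_abs")) {
  mode <- match.arg(mode)
  observable <- match.arg(observable)
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(graph, "ResidueGraph"))
  labs <- graph$nodes$label
  N <- length(labs)
  base <- graph_observable(graph, observable)
  delta_of <- function(pg) {
    val <- graph_observable(pg, observable)
    if (observable == "aspl") return(val - base)
    common <- intersect(names(val), names(base))
    mean(abs(val[common] - base[common]))
  }
  per_mut <- matrix(NA_real_, N, 19L)
  rownames(per_mut) <- labs
  for (k in seq_len(N)) {
    if (mode == "remove") {
      d1 <- delta_of(drop_node(graph, labs[k]))
      per_mut[k, ] <- d1
    } else {
      wt <- aa_three_to_one(graph$nodes$resname[k])
      if (is.na(wt))
        stop("node ", labs[k], " lacks a standard residue name")
      muts <- setdiff(AA_ORDER, wt)
      per_mut[k, ] <- vapply(muts, function(m)
        delta_of(perturb_node(graph, labs[k], m, mode = "reweight",
                              similarity = similarity)), numeric(1))
    }
  }
  colnames(per_mut) <- paste0("sub", seq_len(19L))
  delta_L <- switch(aggregation,
                    mean_square = rowMeans(per_mut^2),
                    rms = sqrt(rowMeans(per_mut^2)),
                    mean_abs = rowMeans(abs(per_mut)))
  perturbation_profile(labs, per_mut, delta_L, observable, mode, aggregation)
}

standardize_z <- function(delta_L) {
  mu <- mean(delta_L)
  sigma <- sqrt(mean((delta_L - mu)^2))  # population sd
  if (sigma == 0) rep(0, length(delta_L)) else (delta_L - mu) / sigma
}

perturbation_profile <- function(labels, per_mut, delta_L, observable,
                                 mode, aggregation) {
  structure(list(residue_labels = labels,
                 per_mutation_delta = per_mut,
                 delta_L = unname(delta_L),
                 z = standardize_z(unname(delta_L)),
                 observable = observable, mode = mode,
                 aggregation = aggregation),
            class = "PerturbationProfile")
}

#' @export
print.PerturbationProfile <- function(x, ...) {
  top <- x$residue_labels[which.max(x$z)]
  cat("PerturbationProfile (", x$mode, "/", x$observable, "): ",
      length(x$residue_labels), " residues, top Z at ", top,
      " (", signif(max(x$z), 3), ")\n", sep = "")
  invisible(x)
}

#' Average perturbation profiles across ensemble snapshots
#'
#' Averages the per-node dL values of snapshot-level profiles (identical
#' labels, observable and mode required) and re-standardizes the Z-scores
#' over nodes. Z is invariant under uniform scaling of dL, so two
#' profiles differing only by scale average to their common Z.
#'
#' @param profiles list of `PerturbationProfile`s.
#' @return A single `PerturbationProfile`.
#' @export
ensemble_average_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1),
                       "PerturbationProfile")))
  p1 <- profiles[[1]]
  for (p in profiles[-1]) {
    if (!identical(p$residue_labels, p1$residue_labels))
      stop("profiles have different residue labels")
    if (!identical(p$observable, p1$observable) ||
        !identical(p$mode, p1$mode) ||
        !identical(p$aggregation, p1$aggregation))
      stop("profiles mix observables, modes or aggregations")
  }
  dl <- Reduce(`+`, lapply(profiles, `[[`, "delta_L")) / length(profiles)
  pm <- Reduce(`+`, lapply(profiles, `[[`, "per_mutation_delta")) /
    length(profiles)
  perturbation_profile(p1$residue_labels, pm, dl, p1$observable, p1$mode,
                       p1$aggregation)
}

#' Rank allosteric hotspot candidates
#'
#' Residues whose perturbation Z-score reaches `z_min`, in descending Z
#' order; ties broken by residue ordinal.
#'
#' @param profile a `PerturbationProfile`.
#' @param z_min minimum Z-score (default 1).
#' @return Character vector of residue labels (possibly empty).
#' @export
rank_hotspots <- function(profile, z_min = 1.0) {
  stopifnot(inherits(profile, "PerturbationProfile"))
  idx <- which(profile$z >= z_min)
  idx <- idx[order(-profile$z[idx], idx)]
  profile$residue_labels[idx]
}
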
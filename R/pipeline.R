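# Pipeline orchestration: ingest -> superpose -> dynamics statistics ->
# interface + mutational scan -> residue graph + SPC -> perturbation
# Z-profile, with every intermediate written as labelled CSV/TSV and a
# deterministic manifest of per-stage output checksums.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis sequence with validated
#' defaults: 5 Angstrom contact and interface cutoffs, occupancy
#' threshold tau = 0.5, dynamics-only edge weighting (lambda = 0),
#' 1000-sample ensemble averaging, and remove-mode ASPL perturbation
#' profiling. Round-trips losslessly through YAML.
#'
#' @param ensemble path to a multi-model PDB, or a
#'   `ConformationalEnsemble`.
#' @param target_chains,partner_chains chain id vectors (target chains
#'   are scanned; both sides enter the residue graph).
#' @param out_dir output directory.
#' @param contact_cutoff,interface_cutoff Angstrom (defaults 5).
#' @param atom_mode contact atom selection (default sidechain_heavy).
#' @param tau occupancy threshold (default 0.5).
#' @param lambda coevolutionary mixing weight (default 0).
#' @param coupling `"generalized"` (default) or `"dccm"` edge couplings.
#' @param n_samples frames averaged in the mutational scan (default 1000).
#' @param perturb_mode,perturb_observable,perturb_aggregation perturbation
#'   settings (defaults remove / aspl / mean_square).
#' @param z_min hotspot Z threshold (default 1).
#' @param seed integer seed for every stochastic step.
#' @param burial_weight built-in scorer burial term weight (default 0.5).
#' @return Validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(ensemble, target_chains, partner_chains,
                            out_dir,
                            contact_cutoff = 5.0, interface_cutoff = 5.0,
                            atom_mode = "sidechain_heavy",
                            tau = 0.5, lambda = 0,
                            coupling = c("generalized", "dccm"),
                            n_samples = 1000,
                            perturb_mode = c("remove", "reweight"),
                            perturb_observable = c("aspl", "node_spc"),
                            perturb_aggregation = c("mean_square", "rms",
                                                    "mean_abs"),
                            z_min = 1.0, seed = 1, burial_weight = 0.5) {
  coupling <- match.arg(coupling)
  perturb_mode <- match.arg(perturb_mode)
  perturb_observable <- match.arg(perturb_observable)
  perturb_aggregation <- match.arg(perturb_aggregation)
  if (contact_cutoff <= 0 || interface_cutoff <= 0)
    stop("cutoffs must be positive")
  if (tau < 0 || tau > 1) stop("tau must be in [0, 1]")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (!atom_mode %in% c("sidechain_heavy", "all_heavy", "ca_only"))
    stop("unknown atom_mode: ", atom_mode)
  if (length(intersect(target_chains, partner_chains)))
    stop("target and partner chains overlap")
  structure(list(ensemble = ensemble, target_chains = target_chains,
                 partner_chains = partner_chains, out_dir = out_dir,
                 contact_cutoff = contact_cutoff,
                 interface_cutoff = interface_cutoff,
                 atom_mode = atom_mode, tau = tau, lambda = lambda,
                 coupling = coupling, n_samples = as.integer(n_samples),
                 perturb_mode = perturb_mode,
                 perturb_observable = perturb_observable,
                 perturb_aggregation = perturb_aggregation,
                 z_min = z_min, seed = as.integer(seed),
                 burial_weight = burial_weight),
            class = "PipelineConfig")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [pipeline_config()].
#' @return `read_pipeline_config` returns a validated `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!is.character(config$ensemble))
    stop("only configs with a file-path ensemble can be serialized")
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

write_matrix_csv <- function(m, labels, path) {
  df <- data.frame(residue = labels, m, check.names = FALSE)
  colnames(df) <- c("residue", labels)
  utils::write.csv(df, path, row.names = FALSE)
}

write_profile_csv <- function(labels, values, path,
                              value_name = "value") {
  df <- data.frame(residue = labels, v = values)
  names(df)[2] <- value_name
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run the full ensemble-network analysis pipeline
#'
#' Executes ingest, superposition, dynamics statistics (RMSD, RMSF, DCCM,
#' generalized correlation, contact occupancy), interface detection and
#' ensemble-averaged mutational scanning, residue-graph construction with
#' SPC centrality, and mutational network-perturbation Z-scoring. Every
#' intermediate is written under `config$out_dir`; the manifest
#' (`manifest.json`) records the configuration, seed, package version and
#' per-stage output MD5 checksums, and is identical across repeat runs
#' with the same inputs and seed. A stage failure is recorded with its
#' reason and later stages are skipped.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly (list; also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config = utils::modifyList(unclass(config),
                               list(ensemble = if (is.character(config$ensemble))
                                 config$ensemble else "<in-memory ensemble>")),
    package_version = as.character(utils::packageVersion("allonet")),
    stages = list(), checksums = list())
  log_file <- file.path(config$out_dir, "run.log")
  cat("", file = log_file)
  logmsg <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                              "\n", file = log_file, append = TRUE)
  state <- new.env()
  failed <- FALSE
  run_stage <- function(name, fun) {
    if (failed) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[3]
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE,
                                             reason = conditionMessage(e)))
    logmsg(name, if (res$ok) "ok" else paste("FAILED:", res$reason),
           sprintf("(%.1fs)", proc.time()[3] - t0))
    if (res$ok) {
      manifest$stages[[name]] <<- list(status = "ok")
    } else {
      manifest$stages[[name]] <<- list(status = "failed",
                                       reason = res$reason)
      failed <<- TRUE
    }
    invisible(NULL)
  }
  out <- function(f) file.path(config$out_dir, f)

  run_stage("ingest", function() {
    ens <- if (is.character(config$ensemble))
      read_multimodel_pdb(config$ensemble) else config$ensemble
    state$ens <- superpose_frames(ens)
  })
  run_stage("dynamics", function() {
    ens <- state$ens
    utils::write.csv(data.frame(frame = ens$frame_labels,
                                rmsd = compute_rmsd_series(ens)),
                     out("rmsd.csv"), row.names = FALSE)
    rmsf <- compute_rmsf(ens)
    write_profile_csv(rmsf$residue, rmsf$value, out("rmsf.csv"), "rmsf")
    state$dccm <- compute_dccm(ens)
    write_matrix_csv(state$dccm$values, state$dccm$residue_labels,
                     out("dccm.csv"))
    state$gencorr <- compute_generalized_correlation(ens)
    write_matrix_csv(state$gencorr$values, state$gencorr$residue_labels,
                     out("gencorr.csv"))
    state$occ <- compute_contact_occupancy(ens, config$contact_cutoff,
                                           config$atom_mode)
    write_matrix_csv(state$occ$values, state$occ$residue_labels,
                     out("occupancy.csv"))
  })
  run_stage("mutscan", function() {
    ens <- state$ens
    iface <- identify_interface_residues(ens, config$target_chains,
                                         config$partner_chains,
                                         cutoff = config$interface_cutoff,
                                         min_occupancy = 0.5)
    writeLines(iface, out("interface.txt"))
    state$interface <- iface
    if (length(iface)) {
      scorer <- builtin_contact_scorer(burial_weight = config$burial_weight,
                                       cutoff = config$interface_cutoff)
      scan <- scan_mutations(ens, scorer, iface,
                             n_samples = config$n_samples)
      state$scan <- scan
      export_heatmap(scan, out("mutscan.csv"))
      write_matrix_csv(scan$ddg_se, scan$residue_labels,
                       out("mutscan_se.csv"))
    }
  })
  run_stage("network", function() {
    coupling <- if (config$coupling == "generalized") state$gencorr else
      state$dccm
    graph <- build_residue_graph(state$occ, coupling, tau = config$tau,
                                 lambda = config$lambda,
                                 reference = state$ens$reference)
    state$graph <- graph
    export_graph(graph, out("network.tsv"))
    spc <- compute_spc(graph)
    state$spc <- spc
    write_profile_csv(spc$residue_labels, spc$spc, out("spc.csv"), "spc")
  })
  run_stage("perturb", function() {
    prof <- profile_perturbations(state$graph,
                                  mode = config$perturb_mode,
                                  observable = config$perturb_observable,
                                  aggregation = config$perturb_aggregation)
    state$profile <- prof
    utils::write.csv(data.frame(residue = prof$residue_labels,
                                delta_L = prof$delta_L, z = prof$z),
                     out("zprofile.csv"), row.names = FALSE)
    writeLines(rank_hotspots(prof, config$z_min), out("hotspots.txt"))
  })

  files <- setdiff(list.files(config$out_dir),
                   c("manifest.json", "run.log"))
  sums <- tools::md5sum(file.path(config$out_dir, files))
  manifest$checksums <- as.list(stats::setNames(unname(sums), files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

save_both <- function(plot, prefix, width = 7, height = 3.5) {
  files <- c(paste0(prefix, ".png"), paste0(prefix, ".svg"))
  ggplot2::ggsave(files[1], plot, width = width, height = height, dpi = 150)
  ggplot2::ggsave(files[2], plot, width = width, height = height,
                  device = grDevices::svg)
  files
}

#' Render figures from a pipeline run directory
#'
#' Produces per-residue bar charts (RMSF, SPC, perturbation Z) and
#' heatmaps (DCCM, mutational scan) as PNG + SVG from the CSVs written by
#' [run_pipeline()]. Missing profiles are skipped with a message. Every
#' plotted number comes from a CSV on disk.
#'
#' @param run_dir pipeline output directory.
#' @return Character vector of created figure paths.
#' @export
render_profiles <- function(run_dir) {
  made <- character(0)
  bar_chart <- function(csv, col, ylab) {
    df <- utils::read.csv(file.path(run_dir, csv))
    df$residue <- factor(df$residue, levels = df$residue)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$residue,
                                     y = .data[[col]])) +
      ggplot2::geom_col(fill = "darkorange") +
      ggplot2::labs(x = "residue", y = ylab) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_blank())
  }
  mat_heat <- function(csv, name) {
    df <- utils::read.csv(file.path(run_dir, csv), check.names = FALSE)
    labs <- df$residue
    m <- as.matrix(df[, -1, drop = FALSE])
    long <- data.frame(i = factor(rep(labs, ncol(m)),
                                  levels = labs),
                       j = factor(rep(colnames(m), each = nrow(m)),
                                  levels = labs),
                       v = as.vector(m))
    ggplot2::ggplot(long, ggplot2::aes(x = .data$i, y = .data$j,
                                       fill = .data$v)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                    high = "red", midpoint = 0,
                                    name = name) +
      ggplot2::theme_void()
  }
  jobs <- list(
    rmsf = function() bar_chart("rmsf.csv", "rmsf", "RMSF (Angstrom)"),
    spc = function() bar_chart("spc.csv", "spc", "SPC"),
    z = function() bar_chart("zprofile.csv", "z", "perturbation Z"),
    dccm = function() mat_heat("dccm.csv", "C_ij"))
  for (nm in names(jobs)) {
    csv <- c(rmsf = "rmsf.csv", spc = "spc.csv", z = "zprofile.csv",
             dccm = "dccm.csv")[nm]
    if (!file.exists(file.path(run_dir, csv))) {
      message("skipping ", nm, ": ", csv, " not found")
      next
    }
    made <- c(made, save_both(jobs[[nm]](), file.path(run_dir, nm),
                              height = if (nm == "dccm") 6 else 3.5,
                              width = if (nm == "dccm") 7 else 7))
  }
  if (file.exists(file.path(run_dir, "mutscan.csv"))) {
    df <- utils::read.csv(file.path(run_dir, "mutscan.csv"),
                          check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    long <- data.frame(
      position = factor(rep(colnames(m), each = nrow(m)),
                        levels = colnames(m)),
      substitution = factor(rep(df$substitution, ncol(m)),
                            levels = rev(df$substitution)),
      ddg = as.vector(m))
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$position,
                                            y = .data$substitution,
                                            fill = .data$ddg)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                    high = "red", midpoint = 0,
                                    name = "ddG") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         vjust = 0.5))
    made <- c(made, save_both(p, file.path(run_dir, "mutscan"),
                              width = 2 + 0.22 * ncol(m), height = 5))
  } else message("skipping mutscan: mutscan.csv not found")
  made
}
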
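#' Analysis run configuration
#'
#' Bundles all inputs and tunables of the end-to-end dimer analysis.
#' Defaults follow the analysis protocol of the simulations this package
#' emulates: 500 ps subsampling stride, replicas merged for clustering,
#' Gromos threshold 1.6 Angstrom, interaction occupancy threshold 20
#' percent, C-alpha selection, 20 ns equilibration excluded per replica,
#' trailing 50 percent energy window.
#'
#' @param dimer list of per-replica inputs: multi-model PDB paths or
#'   \code{\link{trajectory}} objects
#' @param monomer_a,monomer_b per-replica inputs for the two monomer
#'   systems (optional; formation energy is skipped without them; for a
#'   homodimer give only \code{monomer_a})
#' @param params nonbonded parameter CSV path or data.frame (optional;
#'   energetics are skipped without it)
#' @param annotation helix annotation YAML path or named list of
#'   \code{\link{helix_annotation}} per chain (optional)
#' @param selection analysis selection expression (default C-alpha atoms)
#' @param criteria \code{\link{geometric_criteria}}
#' @param interaction_kinds interaction classes to detect
#' @param occupancy_threshold merged-occupancy retention threshold
#' @param cluster_threshold Gromos RMSD threshold, Angstrom
#' @param stride_ps subsampling stride, ps
#' @param frame_interval_ps recording interval of PDB inputs, ps
#' @param equilibration_ps equilibration excluded per replica, ps
#' @param energy_window trailing fraction of frames for formation energy
#' @param lowess_frac LOWESS neighbourhood fraction for count smoothing
#' @param out_dir output directory (optional; no files written without it)
#' @param seed seed recorded in the report (the analysis itself is
#'   deterministic)
#' @return list of class \code{"run_config"}
#' @export
run_config <- function(dimer,
                       monomer_a = NULL, monomer_b = NULL,
                       params = NULL, annotation = NULL,
                       selection = "name CA",
                       criteria = geometric_criteria(),
                       interaction_kinds = c("hbond", "salt_bridge",
                                             "pi_pi", "cation_pi"),
                       occupancy_threshold = 0.2,
                       cluster_threshold = 1.6,
                       stride_ps = 500,
                       frame_interval_ps = 100,
                       equilibration_ps = 20000,
                       energy_window = 0.5,
                       lowess_frac = 2 / 3,
                       out_dir = NULL,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(occupancy_threshold > 0, cluster_threshold > 0, stride_ps > 0,
            energy_window > 0, energy_window <= 1,
            lowess_frac > 0, lowess_frac <= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file with fields matching \code{\link{run_config}}
#'   arguments (criteria given as a mapping of
#'   \code{\link{geometric_criteria}} arguments)
#' @return a \code{run_config}
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$criteria)) {
    raw$criteria <- do.call(geometric_criteria, raw$criteria)
  }
  do.call(run_config, raw)
}

load_replicas <- function(x, interval) {
  lapply(seq_along(x), function(i) {
    t <- x[[i]]
    if (inherits(t, "trajectory")) {
      t$replica_id <- i
      t$frame_replica <- rep(i, n_frames(t))
      t
    } else {
      read_pdb(t, frame_interval = interval, replica_id = i)
    }
  })
}

stage_msg <- function(report, stage, text) {
  message(sprintf("[%s] %s", stage, text))
  report$stages <- c(report$stages, stage)
  report
}

#' Run the full dimer-trajectory analysis
#'
#' Executes, in order: input reading, subsampling, per-replica RMSD and
#' RMSF, replica merging, interface interaction detection, occupancy
#' filtering, Ballesteros-Weinstein annotation, pairwise RMSD matrix,
#' Gromos clustering with medoid extraction, energy component
#' decomposition, dimer formation energy, and LOWESS-smoothed H-bond
#' count series. Every stage's tables are collected in the returned
#' report (and written as CSV/JSON plus medoid PDB when
#' \code{out_dir} is configured). The pipeline is deterministic: a
#' re-run with identical config and inputs reproduces every output
#' byte for byte. Missing optional inputs skip their stages with an
#' explicit notice rather than failing.
#'
#' @param cfg a \code{\link{run_config}}
#' @return list of class \code{"analysis_report"}
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  report <- list(stages = character(), notices = character())

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- read -------------------------------------------------------------
  report <- stage_msg(report, "read", "loading trajectories")
  params <- run_stage("read", {
    if (is.character(cfg$params)) read_nonbonded_params(cfg$params)
    else cfg$params
  })
  annotation <- run_stage("read", {
    if (is.character(cfg$annotation)) read_annotation_yaml(cfg$annotation)
    else cfg$annotation
  })
  prep <- function(trajs) {
    lapply(trajs, function(t) {
      t <- assign_groups(t)
      if (!is.null(params)) t <- assign_parameters(t, params)
      t
    })
  }
  dimer <- run_stage("read", prep(load_replicas(cfg$dimer,
                                                cfg$frame_interval_ps)))
  mon_a <- mon_b <- NULL
  if (!is.null(cfg$monomer_a)) {
    mon_a <- run_stage("read", prep(load_replicas(cfg$monomer_a,
                                                  cfg$frame_interval_ps)))
  }
  if (!is.null(cfg$monomer_b)) {
    mon_b <- run_stage("read", prep(load_replicas(cfg$monomer_b,
                                                  cfg$frame_interval_ps)))
  }

  # --- subsample --------------------------------------------------------
  report <- stage_msg(report, "subsample",
                      sprintf("stride %g ps", cfg$stride_ps))
  thin <- function(trajs) {
    if (is.null(trajs)) return(NULL)
    lapply(trajs, function(t) {
      if (cfg$stride_ps == t$frame_interval) t else subsample(t, cfg$stride_ps)
    })
  }
  dimer <- run_stage("subsample", thin(dimer))
  mon_a <- thin(mon_a)
  mon_b <- thin(mon_b)

  # --- per-replica RMSD / RMSF -----------------------------------------
  report <- stage_msg(report, "rmsd_rmsf",
                      sprintf("selection '%s'", cfg$selection))
  run_stage("rmsd_rmsf", {
    sel1 <- select_atoms(dimer[[1L]], cfg$selection)
    report$rmsd <- do.call(rbind, lapply(dimer, function(t) {
      rmsd_series(t, select_atoms(t, cfg$selection))
    }))
    rmsf_reps <- lapply(seq_along(dimer), function(r) {
      out <- rmsf_profile(dimer[[r]], select_atoms(dimer[[r]], cfg$selection))
      out$replica <- r
      out
    })
    report$rmsf <- do.call(rbind, rmsf_reps)[, c("replica", "chain_id",
                                                 "res_seq", "rmsf_A")]
    invisible(sel1)
  })

  # --- merge ------------------------------------------------------------
  merged <- run_stage("merge", merge_replicas(dimer))
  report <- stage_msg(report, "merge",
                      sprintf("%d frames over %d replicas",
                              n_frames(merged), length(dimer)))
  eq_frames <- as.integer(cfg$equilibration_ps %/% merged$frame_interval)

  # --- interactions -----------------------------------------------------
  report <- stage_msg(report, "interactions",
                      paste(cfg$interaction_kinds, collapse = "+"))
  detections <- run_stage("interactions", {
    detect_interactions(merged, cfg$criteria, cfg$interaction_kinds)
  })
  report$occupancy <- run_stage("interactions", {
    occupancy_table(detections, merged, eq_frames, cfg$occupancy_threshold)
  })
  report$hbond_counts <- run_stage("interactions", {
    cs <- count_series(detections, merged, kind = "hbond")
    cs$count_smooth <- NA_real_
    for (r in unique(cs$replica)) {
      i <- cs$replica == r
      if (sum(i) >= 3L) {
        cs$count_smooth[i] <- lowess_smooth(cs$time_ps[i], cs$count[i],
                                            frac = cfg$lowess_frac)
      }
    }
    cs
  })

  # --- annotation -------------------------------------------------------
  if (!is.null(annotation)) {
    report <- stage_msg(report, "annotate", "Ballesteros-Weinstein labels")
    report$occupancy <- run_stage("annotate", {
      annotate_interface(report$occupancy, annotation)
    })
    report$segment_summary <- attr(report$occupancy, "segment_summary")
  } else {
    report$notices <- c(report$notices,
                        "annotation missing: BW labelling skipped")
  }

  # --- clustering -------------------------------------------------------
  report <- stage_msg(report, "cluster",
                      sprintf("Gromos @ %g A on post-equilibration frames",
                              cfg$cluster_threshold))
  run_stage("cluster", {
    keep <- unlist(lapply(replica_frames(merged), function(fr) {
      fr[seq_along(fr) > eq_frames]
    }), use.names = FALSE)
    trimmed <- trajectory(merged$topology,
                          merged$coords[, , keep, drop = FALSE],
                          frame_interval = merged$frame_interval,
                          frame_replica = merged$frame_replica[keep])
    sel <- select_atoms(trimmed, cfg$selection)
    mat <- pairwise_rmsd_matrix(trimmed, sel)
    clust <- gromos_cluster(mat, cfg$cluster_threshold)
    report$clusters <- cluster_assignments(clust, trimmed)
    report$cluster_summary <- list(
      threshold = cfg$cluster_threshold,
      n_clusters = length(clust$clusters),
      sizes = clust$sizes,
      medoid_frames = clust$medoids,
      analyzed_frames = n_frames(trimmed))
    report$cluster_result <- clust
    report$medoid <- medoid_structure(trimmed, clust, rank = 1L)
  })

  # --- energetics -------------------------------------------------------
  if (!is.null(params)) {
    report <- stage_msg(report, "energy", "nonbonded component series")
    run_stage("energy", {
      model <- nonbonded_model()
      report$energy_components <- components_series(merge_replicas(dimer),
                                                     model)
      if (!is.null(mon_a)) {
        comp_a <- components_series(merge_replicas(mon_a), model)
        comp_b <- if (!is.null(mon_b)) {
          components_series(merge_replicas(mon_b), model)
        } else NULL
        report$formation_energy <- dimer_formation_energy(
          report$energy_components, comp_a, comp_b,
          window = cfg$energy_window)
      } else {
        report$notices <- c(report$notices,
                             "monomer trajectories missing: formation-energy stage skipped")
        message("[energy] formation-energy stage skipped (no monomers)")
      }
    })
  } else {
    report$notices <- c(report$notices,
                        "nonbonded parameters missing: energetics skipped")
  }

  # --- provenance and outputs ------------------------------------------
  report$provenance <- list(
    package = "dimertraj",
    version = as.character(utils::packageVersion("dimertraj")),
    seed = cfg$seed,
    config = config_echo(cfg))
  class(report) <- "analysis_report"
  if (!is.null(cfg$out_dir)) {
    report <- stage_msg(report, "write", cfg$out_dir)
    write_report(report, cfg$out_dir)
  }
  report
}

# effective configuration with all defaults expanded, serialisable to JSON
config_echo <- function(cfg) {
  echo <- unclass(cfg)
  for (f in c("dimer", "monomer_a", "monomer_b")) {
    if (!is.null(echo[[f]]) && !is.character(echo[[f]])) {
      echo[[f]] <- sprintf("<%d in-memory trajectories>", length(echo[[f]]))
    }
  }
  if (!is.null(echo$params) && !is.character(echo$params)) {
    echo$params <- "<in-memory parameter table>"
  }
  if (!is.null(echo$annotation) && !is.character(echo$annotation)) {
    echo$annotation <- "<in-memory annotation>"
  }
  echo$criteria <- unclass(echo$criteria)
  echo
}

#' Write an analysis report to disk
#'
#' Emits the report's tables as CSV, the cluster and formation-energy
#' summaries and provenance as JSON, and the top-cluster medoid as a PDB
#' file. All outputs are plain text and deterministic.
#'
#' @param report an \code{\link{run_analysis}} report
#' @param dir output directory (created if needed)
#' @return invisibly, the written file paths
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put_csv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  put_json <- function(x, name) {
    p <- file.path(dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
  }
  if (!is.null(report$rmsd)) put_csv(report$rmsd, "rmsd.csv")
  if (!is.null(report$rmsf)) put_csv(report$rmsf, "rmsf.csv")
  if (!is.null(report$occupancy)) put_csv(report$occupancy, "occupancy.csv")
  if (!is.null(report$hbond_counts)) {
    put_csv(report$hbond_counts, "hbond_counts.csv")
  }
  if (!is.null(report$clusters)) put_csv(report$clusters, "clusters.csv")
  if (!is.null(report$cluster_summary)) {
    put_json(report$cluster_summary, "cluster_summary.json")
  }
  if (!is.null(report$medoid)) {
    p <- file.path(dir, "medoid_rank1.pdb")
    write_pdb(report$medoid, file = p)
    paths <- c(paths, p)
  }
  if (!is.null(report$energy_components)) {
    put_csv(report$energy_components, "energy_components.csv")
  }
  if (!is.null(report$formation_energy)) {
    fe <- report$formation_energy
    put_json(list(per_replica = as.list(fe$per_replica), mean = fe$mean,
                  sem = fe$sem, window = fe$window,
                  favorable = fe$favorable),
             "formation_energy.json")
  }
  if (!is.null(report$segment_summary)) {
    put_csv(report$segment_summary, "segment_summary.csv")
  }
  put_json(list(provenance = report$provenance, stages = report$stages,
                notices = report$notices), "report.json")
  invisible(paths)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("dimertraj analysis report\n")
  cat("  stages: ", paste(unique(x$stages), collapse = " -> "), "\n")
  if (!is.null(x$occupancy)) {
    cat(sprintf("  interactions: %d keys, %d retained at threshold\n",
                nrow(x$occupancy), sum(x$occupancy$retained)))
  }
  if (!is.null(x$cluster_summary)) {
    cat(sprintf("  clusters: %d (top size %d of %d frames)\n",
                x$cluster_summary$n_clusters, x$cluster_summary$sizes[1L],
                x$cluster_summary$analyzed_frames))
  }
  if (!is.null(x$formation_energy)) print(x$formation_energy)
  for (n in x$notices) cat("  notice:", n, "\n")
  invisible(x)
}
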
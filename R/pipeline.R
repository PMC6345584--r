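# Orchestration: validated run configuration, staged execution, and a
# reproducible run manifest.  All randomness flows from the single
# config seed via named substreams, so identical config + seed gives
# byte-identical outputs and manifest.

pkg_version <- function() {
  as.character(utils::packageVersion("fluorquant"))
}

.config_schema <- list(
  scene = c("n_vesicles", "shape", "vesicle_sigma", "vesicle_amplitudes",
            "coloc_fraction", "background_level", "noise_sigma",
            "min_separation", "coloc_jitter"),
  detection = c("n_scales", "threshold_k", "scales_used", "min_area",
                "split_touching"),
  frap = c("rate_k", "mobile_fraction", "postbleach_floor", "fading_rate",
           "frame_interval", "n_prebleach", "noise_sigma", "n_post"),
  tracks = c("mean_speed", "persistence", "frame_interval", "n_frames",
             "pixel_size", "speed_cv", "n_cells"),
  titration = c("kd", "target_conc", "response_unbound", "response_bound",
                "noise_sigma", "ligand_concs"),
  decay = c("lifetime_tau", "total_counts", "bin_width", "n_bins",
            "fit_start")
)

#' Build and validate a pipeline run configuration
#'
#' A run configuration names the stages to execute and their parameters.
#' Unknown keys (top level or within a stage) are rejected before any
#' stage runs, so typos cannot silently fall back to defaults.  Every
#' parameter, including defaults filled in here, is recorded in the run
#' manifest.
#'
#' @param seed integer seed; the single source of randomness for the run
#'   (stages derive named substreams from it).
#' @param out_dir output directory (created if needed).
#' @param scene,detection,frap,tracks,titration,decay optional named
#'   lists of stage parameters; a stage is run when its list is present
#'   (`detection` requires `scene`).
#' @return An object of class `run_config`.
#' @examples
#' cfg <- run_config(seed = 7, out_dir = tempfile(),
#'                   scene = list(n_vesicles = 12, shape = c(96, 96),
#'                                coloc_fraction = 0.5, noise_sigma = 2),
#'                   detection = list())
#' @export
run_config <- function(seed, out_dir, scene = NULL, detection = NULL,
                       frap = NULL, tracks = NULL, titration = NULL,
                       decay = NULL) {
  stages <- list(scene = scene, detection = detection, frap = frap,
                 tracks = tracks, titration = titration, decay = decay)
  for (nm in names(stages)) {
    st <- stages[[nm]]
    if (is.null(st)) next
    if (!is.list(st)) stop(sprintf("stage '%s' must be a list", nm),
                           call. = FALSE)
    unknown <- setdiff(names(st), .config_schema[[nm]])
    if (length(unknown)) {
      stop(sprintf("unknown key(s) in stage '%s': %s", nm,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  if (!is.null(detection) && is.null(scene)) {
    stop("stage 'detection' requires stage 'scene'", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 stages = Filter(Negate(is.null), stages)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file with keys `seed`, `out_dir` and optional stage
#'   blocks (`scene`, `detection`, `frap`, `tracks`, `titration`,
#'   `decay`).
#' @param out_dir optional override of the configured output directory.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  known_top <- c("seed", "out_dir", names(.config_schema))
  unknown <- setdiff(names(y), known_top)
  if (length(unknown)) {
    stop(sprintf("unknown top-level key(s) in config: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (is.null(y$seed)) stop("config must declare a seed", call. = FALSE)
  run_config(seed = y$seed,
             out_dir = if (is.null(out_dir)) y$out_dir else out_dir,
             scene = y$scene, detection = y$detection, frap = y$frap,
             tracks = y$tracks, titration = y$titration, decay = y$decay)
}

run_stage <- function(name, log_con, expr) {
  t0 <- Sys.time()
  writeLines(sprintf("[%s] start %s", name, format(t0, "%Y-%m-%d %H:%M:%S")),
             log_con)
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  writeLines(sprintf("[%s] done (%.2f s)", name,
                     as.numeric(Sys.time() - t0, units = "secs")), log_con)
  out
}

#' Execute a configured pipeline run
#'
#' Runs the configured stages in dependency order, writing every output
#' under `out_dir` and a JSON manifest recording the full config
#' snapshot, package version, and an MD5 checksum per output file.  The
#' manifest contains no timestamps (those go to `run.log`), so two runs
#' with the same config and seed produce byte-identical outputs and
#' manifests.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(config$out_dir, "run.log"), "w")
  on.exit(close(log_con))
  outputs <- character()
  results <- list()
  st <- config$stages
  seed <- config$seed

  emit <- function(path) outputs[[length(outputs) + 1L]] <<- path

  if (!is.null(st$scene)) {
    sc <- run_stage("scene", log_con, {
      args <- st$scene
      args$seed <- substream_seed(seed, "scene")
      if (is.null(args$shape)) args$shape <- c(128L, 128L)
      truth <- do.call(scene_truth, args)
      scene <- make_vesicle_scene(truth)
      pa <- file.path(config$out_dir, "scene_channel_a.tif")
      pb <- file.path(config$out_dir, "scene_channel_b.tif")
      write_image_stack(scene$channel_a, pa); emit(pa)
      write_image_stack(scene$channel_b, pb); emit(pb)
      pt <- file.path(config$out_dir, "scene_truth.json")
      tr <- scene$truth
      tr$vesicle_centers <- apply(tr$vesicle_centers, 1, as.numeric,
                                  simplify = FALSE)
      tr$coloc_centers_b <- apply(tr$coloc_centers_b, 1, as.numeric,
                                  simplify = FALSE)
      jsonlite::write_json(unclass(tr), pt, auto_unbox = TRUE, digits = NA)
      emit(pt)
      writeLines(sprintf("[scene] %d vesicles, coloc_fraction %.2f",
                         nrow(scene$truth$vesicle_centers),
                         scene$truth$coloc_fraction), log_con)
      scene
    })
    if (!is.null(st$detection)) {
      run_stage("detection", log_con, {
        params <- do.call(detection_params, st$detection)
        va <- detect_vesicles(sc$channel_a, params)
        vb <- detect_vesicles(sc$channel_b, params)
        pca <- file.path(config$out_dir, "vesicles_channel_a.csv")
        pcb <- file.path(config$out_dir, "vesicles_channel_b.csv")
        write_vesicles_csv(va, pca); emit(pca)
        write_vesicles_csv(vb, pcb); emit(pcb)
        writeLines(sprintf("[detection] A: %d vesicles, B: %d vesicles",
                           va$n_vesicles, vb$n_vesicles), log_con)
        co <- list(
          pearson = pearson_coloc(sc$channel_a, sc$channel_b)$pearson_r,
          overlap_fraction = if (va$n_vesicles > 0)
            vesicle_overlap(va, vb)$overlap_fraction else NA_real_,
          n_vesicles_a = va$n_vesicles, n_vesicles_b = vb$n_vesicles)
        pc <- file.path(config$out_dir, "coloc.json")
        jsonlite::write_json(co, pc, auto_unbox = TRUE, digits = NA)
        emit(pc)
        results$coloc <- co
      })
    }
  }

  if (!is.null(st$frap)) {
    run_stage("frap", log_con, {
      args <- st$frap
      n_post <- if (is.null(args$n_post)) 36L else args$n_post
      args$n_post <- NULL
      args$seed <- substream_seed(seed, "frap")
      truth <- do.call(frap_truth, args)
      tr <- make_frap_series(truth, n_post)
      pt <- file.path(config$out_dir, "frap_trace.csv")
      write_frap_csv(tr, pt); emit(pt)
      fit <- fit_recovery(normalize_trace(tr))
      pf <- file.path(config$out_dir, "frap_fit.json")
      jsonlite::write_json(as.list(coef(fit)), pf, auto_unbox = TRUE,
                           digits = NA)
      emit(pf)
      results$frap <- coef(fit)
    })
  }

  if (!is.null(st$tracks)) {
    run_stage("tracks", log_con, {
      args <- st$tracks
      n_cells <- if (is.null(args$n_cells)) 50L else args$n_cells
      args$n_cells <- NULL
      args$seed <- substream_seed(seed, "tracks")
      truth <- do.call(track_truth, args)
      trks <- make_tracks(truth, n_cells)
      pt <- file.path(config$out_dir, "tracks.csv")
      write_tracks_csv(trks, pt); emit(pt)
      summ <- condition_summary(trks, rep("simulated", length(trks)))
      ps <- file.path(config$out_dir, "track_speeds.csv")
      utils::write.csv(summ, ps, row.names = FALSE); emit(ps)
      results$tracks <- summ
    })
  }

  if (!is.null(st$titration)) {
    run_stage("titration", log_con, {
      args <- st$titration
      concs <- if (is.null(args$ligand_concs)) 1e-9 * 2^(0:15) else
        as.numeric(args$ligand_concs)
      args$ligand_concs <- NULL
      args$seed <- substream_seed(seed, "titration")
      truth <- do.call(binding_truth, args)
      series <- make_titration(truth, concs)
      pt <- file.path(config$out_dir, "titration.csv")
      write_titration_csv(series, pt); emit(pt)
      fit <- fit_kd(series)
      pf <- file.path(config$out_dir, "kd_fit.json")
      jsonlite::write_json(as.list(coef(fit)), pf, auto_unbox = TRUE,
                           digits = NA)
      emit(pf)
      results$kd <- coef(fit)
    })
  }

  if (!is.null(st$decay)) {
    run_stage("decay", log_con, {
      args <- st$decay
      fit_start <- if (is.null(args$fit_start)) 0.5 else args$fit_start
      args$fit_start <- NULL
      args$seed <- substream_seed(seed, "decay")
      truth <- do.call(decay_truth, args)
      d <- make_decay(truth)
      pd <- file.path(config$out_dir, "decay.csv")
      write_decay_csv(d, pd); emit(pd)
      fit <- fit_lifetime(d, fit_start)
      pf <- file.path(config$out_dir, "lifetime_fit.json")
      jsonlite::write_json(list(tau = fit$tau, deviance = fit$deviance),
                           pf, auto_unbox = TRUE, digits = NA)
      emit(pf)
      results$lifetime <- fit$tau
    })
  }

  paths <- sort(unlist(outputs))
  checks <- vapply(paths, function(p) unname(tools::md5sum(p)), character(1))
  names(checks) <- basename(paths)   # manifest independent of out_dir
  manifest <- list(
    config = list(seed = config$seed, stages = st),
    version = pkg_version(),
    outputs = as.list(checks))
  pm <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, pm, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
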
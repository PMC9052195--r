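# End-to-end orchestration: images -> detections -> ratios/pH -> tracks ->
# events -> kinetics, plus the tracker validation study on Vicsek
# simulations.

#' Pipeline run configuration
#'
#' Validated up front so configuration errors surface before any compute.
#' Two input modes are supported: `"images"` (an `image_stack`, or a TIFF
#' path readable by [read_image_stack()]) runs the full chain from
#' detection onward; `"tracks"` (a list of `ph_track` objects or a tracks
#' data frame with `track_id` and `ph`) runs classification and kinetics
#' only.
#'
#' @param input an `image_stack`, TIFF path, list of `ph_track`s, or
#'   tracks data frame.
#' @param calibration a `calibration_curve` or path to its JSON; required
#'   when `output_ph = TRUE` in image mode.
#' @param output_ph convert ratios to pH (image mode).
#' @param detect a [detect_params()].
#' @param scale_min,scale_max ratio-extraction window range, pixels.
#' @param max_link_distance,max_gap,max_jump tracking parameters.
#' @param min_len,k,spread_ratio,n_restarts classifier parameters.
#' @param lambda_hi,lambda_lo kinetics window.
#' @param frame_interval seconds per frame.
#' @param seed RNG seed governing every stochastic stage.
#' @param out_dir optional output directory for the CSV/JSON bundle.
#' @return an object of class `run_config`.
#' @export
pipeline_config <- function(input, calibration = NULL, output_ph = FALSE,
                            detect = detect_params(),
                            scale_min = 20, scale_max = 30,
                            max_link_distance = NULL, max_gap = 3,
                            max_jump = Inf, min_len = 20, k = 3,
                            spread_ratio = 2, n_restarts = 10,
                            lambda_hi = 0.9, lambda_lo = 0.1,
                            frame_interval = 30, seed = 1L,
                            out_dir = NULL) {
  mode <- if (inherits(input, "image_stack") ||
              (is.character(input) && length(input) == 1)) "images"
          else "tracks"
  if (is.character(input) && !file.exists(input)) {
    stop(sprintf("input file '%s' does not exist", input))
  }
  if (mode == "images" && output_ph) {
    if (is.null(calibration)) {
      stop("configuration error: pH output requested but no calibration ",
           "curve supplied")
    }
    if (is.character(calibration) && !file.exists(calibration)) {
      stop(sprintf("configuration error: calibration file '%s' not found",
                   calibration))
    }
  }
  cfg <- list(input = input, calibration = calibration,
              output_ph = output_ph, mode = mode, detect = detect,
              scale_min = scale_min, scale_max = scale_max,
              max_link_distance = max_link_distance, max_gap = max_gap,
              max_jump = max_jump, min_len = min_len, k = k,
              spread_ratio = spread_ratio, n_restarts = n_restarts,
              lambda_hi = lambda_hi, lambda_lo = lambda_lo,
              frame_interval = frame_interval, seed = as.integer(seed),
              out_dir = out_dir)
  structure(cfg, class = "run_config")
}

config_echo <- function(config) {
  keep <- setdiff(names(config), c("input", "calibration"))
  ech <- unclass(config)[keep]
  ech$detect <- unclass(config$detect)
  ech$max_jump <- if (is.finite(config$max_jump)) config$max_jump else "Inf"
  ech
}

#' Run the full analysis pipeline
#'
#' Executes every configured stage and returns the intermediate and final
#' products.  When `out_dir` is set, writes `detections.csv`,
#' `tracks.csv`, `events.csv`, `kinetics.csv`, the resolved
#' `config.json` and a `manifest.json` with stage counts; a stage failure
#' leaves the partial outputs in place beside a `FAILED` marker naming
#' the stage.
#'
#' @param config a [pipeline_config()].
#' @return list with (depending on mode) `detections`, `tracks`,
#'   `events`, `kinetics`, `summary` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- list()
  manifest <- list(seed = config$seed, config = config_echo(config))
  stage <- "setup"
  res <- try({
    if (config$mode == "images") {
      stage <- "detect"
      stack <- if (is.character(config$input)) {
        read_image_stack(config$input)
      } else config$input
      det <- detect_stack(stack, config$detect)
      stage <- "ratiometry"
      det$ratio <- vapply(seq_len(nrow(det)), function(r) {
        as.numeric(extract_ratio_multiscale(
          stack[[det$frame[r]]], c(det$row[r], det$col[r]),
          config$scale_min, config$scale_max))
      }, numeric(1))
      if (config$output_ph) {
        curve <- if (is.character(config$calibration)) {
          read_calibration_json(config$calibration)
        } else config$calibration
        conv <- ratio_to_ph(curve, det$ratio)
        det$ph <- conv$ph
        det$ph_in_range <- conv$in_range
      }
      out$detections <- det
      manifest$n_detections <- nrow(det)
      stage <- "tracking"
      frames <- lapply(seq_along(stack), function(t) {
        sub <- det[det$frame == t, , drop = FALSE]
        data.frame(x = sub$row, y = sub$col,
                   ph = if ("ph" %in% names(sub)) sub$ph else NA_real_)
      })
      tracks <- track_frames(frames, config$max_link_distance,
                             config$max_gap, config$max_jump)
      out$tracks <- tracks
      manifest$tracking <- attr(tracks, "manifest")
      track_input <- tracks
    } else {
      track_input <- config$input
    }
    has_ph <- !is.data.frame(track_input) || any(is.finite(track_input$ph))
    if (!has_ph) {
      # no pH channel requested: detection/tracking products only
      manifest$note <- "no pH reads; classification and kinetics skipped"
    } else {
      stage <- "classify"
      events <- classify_events(track_input, min_len = config$min_len,
                                k = config$k, seed = config$seed,
                                n_restarts = config$n_restarts,
                                spread_ratio = config$spread_ratio)
      out$events <- events
      manifest$class_sizes <- as.list(table(events$label))
      manifest$explained_fraction <- attr(events, "explained_fraction")
      stage <- "kinetics"
      ce_ids <- events$track_id[events$label == "CE"]
      kin <- do.call(rbind, lapply(ce_ids, function(id) {
        ph <- track_ph_vector(track_input, id)
        fit <- fit_isotonic(ph)
        est <- acidification_time(fit, config$lambda_hi, config$lambda_lo,
                                  frame_interval = config$frame_interval)
        data.frame(track_id = id, delta_tau_min = est$delta_tau_min,
                   total_drop = est$total_drop, ok = est$ok)
      }))
      if (is.null(kin)) {
        kin <- data.frame(track_id = character(0),
                          delta_tau_min = numeric(0),
                          total_drop = numeric(0), ok = logical(0))
      }
      out$kinetics <- kin
      out$summary <- summarize_acidification(kin)
    }
    out$manifest <- manifest
    out
  }, silent = TRUE)

  if (inherits(res, "try-error")) {
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_bundle(out, manifest, config)
      writeLines(sprintf("stage: %s\n%s", stage, as.character(res)),
                 file.path(config$out_dir, "FAILED"))
    }
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 attr(res, "condition")$message), call. = FALSE)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bundle(res, res$manifest, config)
  }
  res
}

# extract the pH vector of one track from either input representation
track_ph_vector <- function(track_input, id) {
  if (is.data.frame(track_input)) {
    track_input$ph[track_input$track_id == id]
  } else {
    ids <- names(track_input) %||% as.character(seq_along(track_input))
    tr <- track_input[[match(as.character(id), ids)]]
    if (inherits(tr, "ph_track")) tr$ph else tr
  }
}

write_bundle <- function(res, manifest, config) {
  od <- config$out_dir
  if (!is.null(res$detections)) {
    write.csv(res$detections, file.path(od, "detections.csv"),
              row.names = FALSE)
  }
  if (!is.null(res$tracks)) {
    write.csv(res$tracks, file.path(od, "tracks.csv"), row.names = FALSE)
  }
  if (!is.null(res$events)) {
    write.csv(res$events, file.path(od, "events.csv"), row.names = FALSE)
  }
  if (!is.null(res$kinetics)) {
    write.csv(res$kinetics, file.path(od, "kinetics.csv"), row.names = FALSE)
  }
  jsonlite::write_json(config_echo(config), file.path(od, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(od)
}

#' Tracker validation study on Vicsek simulations
#'
#' For every particle number in `n_grid`, runs `n_reps` seeded Vicsek
#' simulations, feeds the noiseless ground-truth positions directly to
#' the tracker (isolating linking errors from detection errors) and
#' scores the reconstruction with [evaluate_tracking()].  The default
#' scene is the model's polar ordered phase in a periodic box (the
#' stationary regime of the model, entered through a short burn-in) with
#' a hard-core-like initial exclusion distance, since micron-sized
#' probes cannot overlap; the tracker is given the matching
#' minimum-image metric.
#'
#' @param n_grid particle numbers to test.
#' @param n_reps repetitions per particle number.
#' @param base_config a [vicsek_config()] supplying all other simulation
#'   parameters (its `n_particles` and `seed` are overridden per run).
#' @param seed master seed; each (N, rep) derives its own stream.
#' @param max_gap gap-closing depth passed to the tracker.
#' @return a `validation_report`: data frame with one row per (N, rep)
#'   (`n_particles`, `rep`, `wrong_links`, `missed_links`,
#'   `total_true_links`, `error_fraction`) and a `summary` attribute of
#'   mean error fraction per N.
#' @export
run_validation_study <- function(n_grid = seq(20, 160, by = 20),
                                 n_reps = 100,
                                 base_config = vicsek_config(
                                   init = "ordered", min_separation = 8,
                                   burn_in = 20),
                                 seed = 1L, max_gap = 3) {
  stopifnot(n_reps >= 1)
  rows <- list()
  for (N in n_grid) {
    for (rep_i in seq_len(n_reps)) {
      cfg <- base_config
      cfg$n_particles <- as.integer(N)
      cfg$seed <- derive_seed(seed, N * 1000L + rep_i)
      traj <- simulate_vicsek(cfg)
      frames <- lapply(seq_len(cfg$n_frames), function(t) {
        data.frame(x = traj$positions[, t, 1], y = traj$positions[, t, 2])
      })
      pbox <- if (cfg$boundary == "periodic") cfg$box_size else NULL
      tracks <- track_frames(frames, max_gap = max_gap,
                             periodic_box = pbox)
      sc <- evaluate_tracking(tracks, traj)
      rows[[length(rows) + 1L]] <- data.frame(
        n_particles = N, rep = rep_i, wrong_links = sc$wrong_links,
        missed_links = sc$missed_links,
        total_true_links = sc$total_true_links,
        error_fraction = sc$error_fraction)
    }
  }
  report <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(report, report$n_particles), function(g) {
    data.frame(n_particles = g$n_particles[1],
               mean_error_fraction = mean(g$error_fraction),
               mean_wrong_links = mean(g$wrong_links + g$missed_links))
  }))
  rownames(summ) <- NULL
  structure(report, class = c("validation_report", "data.frame"),
            summary = summ, n_reps = n_reps, n_grid = n_grid)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Tracker validation report\n")
  cat(sprintf("  %d particle numbers x %d repetitions\n",
              length(attr(x, "n_grid")), attr(x, "n_reps")))
  print(attr(x, "summary"))
  invisible(x)
}
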
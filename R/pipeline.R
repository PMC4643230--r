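# End-to-end orchestration: segmentation -> traces -> events -> population.

#' Run the full analysis pipeline on a movie
#'
#' Segments and tracks cells, detects landings, applies the inclusion
#' filters, optionally refines each landed cell's mask once with DRLSE
#' and reuses it for the (stationary) post-landing frames, extracts and
#' smooths per-cell traces, normalizes them to R(t), detects events and
#' classifies responders, and aggregates the population summary. All
#' tables are written to `out_dir` together with a machine-readable run
#' manifest.
#'
#' @param stack a [movie_stack()] (or a TIFF path plus `frame_interval`).
#' @param config a [run_config()].
#' @param out_dir output directory, created if missing.
#' @param frame_interval required when `stack` is a path.
#' @param scan_intervals optional frame intervals (seconds) for a
#'   time-resolution scan written to `resolution_scan.csv`.
#' @param make_figures render PNG figures.
#' @param quiet suppress stage messages.
#' @return (invisibly) a list with `records`, `traces` (smoothed),
#'   `normalized`, `annotations`, `aligned`, `summary`, `scan`,
#'   `manifest`.
#' @export
run_full <- function(stack, config = run_config(), out_dir,
                     frame_interval = NULL, scan_intervals = NULL,
                     make_figures = TRUE, quiet = FALSE) {
  if (is.character(stack)) {
    if (is.null(frame_interval))
      stop("frame_interval is required when reading a stack from file")
    stack <- read_stack(stack, frame_interval)
  }
  stopifnot(inherits(stack, "movie_stack"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  say("segmenting ", n_frames(stack), " frames ...")
  seg <- segment_stack(stack)
  records <- track_cells(stack, seg)
  say("tracked ", length(records), " cells")
  records <- filter_cells(records, stack, config, quiet = quiet)
  included <- Filter(function(r) isTRUE(r$included), records)

  if (config$refine_masks && length(included)) {
    say("refining landed-cell masks with DRLSE ...")
    for (i in seq_along(included)) {
      rec <- included[[i]]
      j <- match(rec$landing_frame, rec$frames)
      seedpix <- rec$masks[[j]]
      if (is.null(seedpix)) next
      mask <- tryCatch(
        drlse_refine(stack$frames[rec$landing_frame + 1L, , ], seedpix),
        error = function(e) NULL)
      if (is.null(mask)) next
      idx <- which(mask)
      post <- which(rec$frames >= rec$landing_frame)
      rec$masks[post] <- list(idx)
      rec$diameter_px <- 2 * sqrt(attr(mask, "area") / pi)
      included[[i]] <- rec
      records[[match(rec$cell_id,
                     vapply(records, `[[`, numeric(1), "cell_id"))]] <- rec
    }
  }

  cells_df <- cells_table(records)
  utils::write.csv(cells_df, file.path(out_dir, "cells.csv"),
                   row.names = FALSE)

  raw <- smoothed <- normalized <- aligned <- list()
  annotations <- NULL
  landing_times <- numeric(0)
  if (length(included)) {
    say("extracting and annotating ", length(included), " traces ...")
    anns <- vector("list", length(included))
    for (i in seq_along(included)) {
      rec <- included[[i]]
      lt <- frame_time(stack, rec$landing_frame)
      tr <- extract_trace(stack, rec)
      sm <- smooth_trace(tr, config$window_frames, config$poly_order)
      nt <- normalize_trace(sm, baseline_samples(config, stack$frame_interval),
                            landing_time = lt)
      ac <- annotate_cell(nt, lt, config)
      raw[[i]] <- tr; smoothed[[i]] <- sm; normalized[[i]] <- nt
      aligned[[i]] <- ac$aligned
      anns[[i]] <- ac$annotation
      landing_times[i] <- lt
    }
    annotations <- do.call(rbind, anns)
    utils::write.csv(traces_table(raw, smoothed, normalized,
                                  stack$frame_interval),
                     file.path(out_dir, "traces.csv"), row.names = FALSE)
    utils::write.csv(annotations, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
  }

  summary <- NULL
  scan <- NULL
  if (!is.null(annotations) && nrow(annotations)) {
    summary <- summarize_population(
      annotations, aligned,
      responders_only = config$mean_r_responders_only,
      dispersion = config$dispersion)
    jsonlite::write_json(
      list(n_total = summary$n_total, n_responders = summary$n_responders,
           fraction = summary$fraction, fraction_sdm = summary$fraction_sdm,
           T_mean_s = summary$T_mean, T_sdm_s = summary$T_sdm,
           config = unclass(config),
           software_version = as.character(utils::packageVersion("calquant"))),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      null = "null", na = "null")
    if (!is.null(scan_intervals)) {
      say("time-resolution scan ...")
      scan <- resolution_scan(smoothed, landing_times, scan_intervals, config)
      utils::write.csv(scan, file.path(out_dir, "resolution_scan.csv"),
                       row.names = FALSE)
    }
    event_figs <- event_figures(summary, annotations, out_dir)
    if (make_figures)
      max_projection_figure(stack, file.path(out_dir, "max_projection.png"))
  } else {
    say("no included cells; population stage and figures skipped")
  }

  manifest <- list(
    config = unclass(config),
    n_frames = n_frames(stack),
    frame_interval = stack$frame_interval,
    n_tracked = length(records),
    n_included = length(included),
    exclusions = as.list(table(cells_df$exclusion_reason)),
    outputs = list.files(out_dir, recursive = TRUE),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  invisible(list(records = records, included = included, raw = raw,
                 traces = smoothed, normalized = normalized,
                 aligned = aligned, annotations = annotations,
                 landing_times = landing_times,
                 summary = summary, scan = scan, manifest = manifest))
}

#' Generate a synthetic movie and analyze it end to end
#'
#' Runs [generate_movie()], writes the ground truth, runs [run_full()],
#' then matches detected cells to ground-truth cells by landed position
#' and writes a parameter-recovery report (`recovery.csv`,
#' `recovery_summary.json`).
#'
#' @param scene a [scene_config()].
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @param write_movie also save the rendered movie as `movie.tif`.
#' @param ... passed to [run_full()].
#' @return (invisibly) the [run_full()] result plus `ground_truth`,
#'   `recovery` (per-cell matching table) and `recovery_summary`.
#' @export
run_synthetic <- function(scene = scene_config(), out_dir,
                          config = run_config(), write_movie = FALSE, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_movie(scene)
  write_ground_truth(sim$ground_truth, file.path(out_dir, "ground_truth.csv"))
  if (write_movie) write_stack(sim$stack, file.path(out_dir, "movie.tif"))
  res <- run_full(sim$stack, config, out_dir, ...)
  rec <- recovery_report(res, sim$ground_truth, sim$stack)
  utils::write.csv(rec$table, file.path(out_dir, "recovery.csv"),
                   row.names = FALSE)
  jsonlite::write_json(rec$summary, file.path(out_dir, "recovery_summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  res$ground_truth <- sim$ground_truth
  res$stack <- sim$stack
  res$recovery <- rec$table
  res$recovery_summary <- rec$summary
  invisible(res)
}

#' Match detected cells to ground truth and score recovery
#'
#' Detected cells are matched to true cells by nearest landed centroid
#' (within 1.5 true diameters). Scores landing-frame error, triggering
#' onset error and responder classification against the truth.
#'
#' @param res a [run_full()] result.
#' @param gt a `ground_truth`.
#' @param stack the analyzed [movie_stack()].
#' @return list with `table` (per detected included cell) and `summary`.
#' @export
recovery_report <- function(res, gt, stack) {
  nf <- n_frames(stack)
  truth <- gt$cells
  # true landed position: trajectory at the final frame
  lastpos <- gt$trajectories[gt$trajectories$frame == nf - 1L, ]
  lastpos <- lastpos[match(truth$cell_id, lastpos$cell_id), ]
  rows <- list()
  for (i in seq_along(res$included)) {
    rec <- res$included[[i]]
    j <- match(rec$landing_frame, rec$frames)
    d <- sqrt((lastpos$row - rec$rows[j])^2 + (lastpos$col - rec$cols[j])^2)
    m <- which.min(d)
    if (d[m] > 3 * truth$radius_px[m]) next
    ann <- res$annotations[res$annotations$cell_id == rec$cell_id, ]
    true_trig_t <- if (!is.na(truth$true_trigger_frame[m]))
      frame_time(stack, truth$true_trigger_frame[m]) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = rec$cell_id,
      gt_cell_id = truth$cell_id[m],
      match_dist_px = d[m],
      true_landing_frame = truth$true_landing_frame[m],
      detected_landing_frame = rec$landing_frame,
      landing_err_frames = rec$landing_frame - truth$true_landing_frame[m],
      true_is_responder = truth$is_responder[m],
      detected_is_responder = ann$is_responder,
      true_trigger_time_s = true_trig_t,
      detected_trigger_time_s = ann$t_triggering_s,
      trigger_err_s = ann$t_triggering_s - true_trig_t,
      true_amplitude_ratio = truth$true_amplitude_ratio[m],
      detected_amplitude_ratio = ann$peak_response)
  }
  tab <- do.call(rbind, rows)
  # one true cell may not absorb two detections; keep the closest
  tab <- tab[order(tab$gt_cell_id, tab$match_dist_px), ]
  tab <- tab[!duplicated(tab$gt_cell_id), ]
  tab <- tab[order(tab$cell_id), ]
  rownames(tab) <- NULL

  both <- tab$true_is_responder & tab$detected_is_responder
  summary <- list(
    n_true_cells = nrow(truth),
    n_detected_included = length(res$included),
    n_matched = nrow(tab),
    true_fraction_realized = mean(truth$is_responder),
    detected_fraction = mean(res$annotations$is_responder),
    landing_within_1_frame = mean(abs(tab$landing_err_frames) <= 1),
    trigger_within_1_s = if (any(both))
      mean(abs(tab$trigger_err_s[both]) <= 1, na.rm = TRUE) else NA_real_,
    mean_trigger_err_s = if (any(both))
      mean(tab$trigger_err_s[both], na.rm = TRUE) else NA_real_)
  list(table = tab, summary = summary)
}

#' Re-run the event and population stages from a saved trace table
#'
#' Accepts a `traces.csv`-schema table (long format with `cell_id`,
#' `time_s` and `intensity_raw`) plus the landing times from the
#' matching `cells.csv`, re-derives smoothed and normalized traces with
#' the same settings, and reproduces `events.csv` and the population
#' summary. Feeding a full run's own `traces.csv` back reproduces its
#' `events.csv` exactly.
#'
#' @param traces_csv path to a traces table.
#' @param cells_csv path to the matching cells table (landing frames).
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return (invisibly) list with `annotations`, `aligned`, `summary`.
#' @export
run_traces_only <- function(traces_csv, cells_csv, config = run_config(),
                            out_dir) {
  tr <- utils::read.csv(traces_csv)
  if (nrow(tr) == 0L) stop("trace table ", traces_csv, " has no data rows")
  cells <- utils::read.csv(cells_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- unique(tr$cell_id)
  anns <- list(); aligned <- list()
  for (id in ids) {
    sub <- tr[tr$cell_id == id, ]
    sub <- sub[order(sub$time_s), ]
    fi <- stats::median(diff(sub$time_s))
    lf <- cells$landing_frame[cells$cell_id == id]
    if (!length(lf) || is.na(lf)) next
    lt <- lf * fi
    rtr <- raw_trace(id, sub$time_s, sub$intensity_raw,
                     sub$n_pixels %||% rep(NA_integer_, nrow(sub)))
    sm <- smooth_trace(rtr, config$window_frames, config$poly_order)
    nt <- normalize_trace(sm, baseline_samples(config, fi),
                          landing_time = lt)
    ac <- annotate_cell(nt, lt, config)
    anns[[length(anns) + 1L]] <- ac$annotation
    aligned[[length(aligned) + 1L]] <- ac$aligned
  }
  if (!length(anns)) stop("no usable cells in ", traces_csv)
  annotations <- do.call(rbind, anns)
  utils::write.csv(annotations, file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  summary <- summarize_population(
    annotations, aligned, responders_only = config$mean_r_responders_only,
    dispersion = config$dispersion)
  jsonlite::write_json(
    list(n_total = summary$n_total, n_responders = summary$n_responders,
         fraction = summary$fraction, fraction_sdm = summary$fraction_sdm,
         T_mean_s = summary$T_mean, T_sdm_s = summary$T_sdm),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(list(annotations = annotations, aligned = aligned,
                 summary = summary))
}
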
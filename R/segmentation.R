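# Cell detection, DRLSE mask refinement, tracking and inclusion filters.

#' Parameters of distance-regularized level-set evolution
#'
#' Edge-based DRLSE minimizes
#' `mu * distance-regularizer + lambda_ * edge-weighted length +
#' alpha * edge-weighted area`, where the distance regularizer (double-well
#' potential) keeps the level-set function close to a signed distance
#' function near its zero level set, removing any need for
#' re-initialization. Negative `alpha` inflates a seed outward until the
#' edge indicator stops it.
#'
#' @param mu distance-regularization weight; stability requires
#'   `time_step * mu < 0.25`.
#' @param lambda_ edge-weighted length (smoothness) weight.
#' @param alpha edge-weighted area (balloon) weight; negative expands.
#' @param sigma_smooth Gaussian pre-smoothing sigma (pixels) for the edge
#'   indicator.
#' @param n_iterations balloon-phase evolution steps (0 returns the seed).
#' @param n_refine refinement steps run after the balloon phase with the
#'   area term off and a widened Dirac band (`epsilon_refine`), letting
#'   the edge-attraction term settle the contour onto the gradient
#'   ridge; the balloon alone stalls at the foot of the edge.
#' @param time_step explicit Euler step size.
#' @param epsilon width of the regularized Dirac/Heaviside, pixels.
#' @param epsilon_refine Dirac width during the refinement phase.
#' @return an object of class `level_set_params`.
#' @export
level_set_params <- function(mu = 0.2, lambda_ = 5, alpha = -5,
                             sigma_smooth = 0.8, n_iterations = 200L,
                             n_refine = 100L,
                             time_step = 1, epsilon = 1.5,
                             epsilon_refine = 2.5) {
  if (n_iterations < 0L || n_refine < 0L)
    stop("n_iterations and n_refine must be >= 0")
  if (time_step * mu >= 0.25)
    stop("unstable DRLSE parameters: need time_step * mu < 0.25, got ",
         time_step * mu)
  structure(list(mu = mu, lambda_ = lambda_, alpha = alpha,
                 sigma_smooth = sigma_smooth,
                 n_iterations = as.integer(n_iterations),
                 n_refine = as.integer(n_refine),
                 time_step = time_step, epsilon = epsilon,
                 epsilon_refine = epsilon_refine),
            class = "level_set_params")
}

# central differences with one-sided ends, MATLAB gradient convention
grad_cols <- function(m) {
  n <- ncol(m)
  g <- m[, c(2:n, n), drop = FALSE] - m[, c(1, 1:(n - 1)), drop = FALSE]
  if (n > 2) g[, 2:(n - 1)] <- g[, 2:(n - 1)] / 2
  g
}
grad_rows <- function(m) t(grad_cols(t(m)))
divergence <- function(fr, fc) grad_rows(fr) + grad_cols(fc)

laplacian5 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  up <- m[c(1, 1:(H - 1)), , drop = FALSE]
  dn <- m[c(2:H, H), , drop = FALSE]
  lf <- m[, c(1, 1:(W - 1)), drop = FALSE]
  rt <- m[, c(2:W, W), drop = FALSE]
  up + dn + lf + rt - 4 * m
}

neumann_bc <- function(m) {
  H <- nrow(m); W <- ncol(m)
  m[c(1, H), c(1, W)] <- m[c(3, H - 2), c(3, W - 2)]
  m[c(1, H), 2:(W - 1)] <- m[c(3, H - 2), 2:(W - 1)]
  m[2:(H - 1), c(1, W)] <- m[2:(H - 1), c(3, W - 2)]
  m
}

dirac_eps <- function(x, eps) {
  f <- (1 / (2 * eps)) * (1 + cos(pi * x / eps))
  f * (abs(x) <= eps)
}

# double-well distance-regularization term
dist_reg_p2 <- function(phi) {
  px <- grad_cols(phi); py <- grad_rows(phi)
  s <- sqrt(px^2 + py^2)
  a <- (s >= 0) & (s <= 1)
  b <- s > 1
  ps <- a * sin(2 * pi * s) / (2 * pi) + b * (s - 1)
  dps <- ((ps != 0) * ps + (ps == 0)) / ((s != 0) * s + (s == 0))
  divergence(dps * py - py, dps * px - px) + laplacian5(phi)
}

# one explicit DRLSE step on phi given edge indicator g and its gradient
drlse_step <- function(phi, g, gx, gy, p) {
  phi <- neumann_bc(phi)
  px <- grad_cols(phi); py <- grad_rows(phi)
  s <- sqrt(px^2 + py^2) + 1e-10
  nx <- px / s; ny <- py / s
  curv <- divergence(ny, nx)
  dirac_phi <- dirac_eps(phi, p$epsilon)
  dist_term <- dist_reg_p2(phi)
  edge_term <- dirac_phi * (gx * nx + gy * ny) + dirac_phi * g * curv
  area_term <- dirac_phi * g
  phi + p$time_step * (p$mu * dist_term + p$lambda_ * edge_term +
                         p$alpha * area_term)
}

edge_indicator <- function(frame, sigma) {
  rng <- range(frame)
  f <- if (diff(rng) > 0) (frame - rng[1]) / diff(rng) * 255 else frame * 0
  fs <- if (sigma > 0) EBImage::gblur(f, sigma = sigma) else f
  gx <- grad_cols(fs); gy <- grad_rows(fs)
  g <- 1 / (1 + gx^2 + gy^2)
  list(g = g, gx = grad_cols(g), gy = grad_rows(g))
}

#' Refine a seed region with distance-regularized level-set evolution
#'
#' Evolves a binary-step level-set function initialized on the seed under
#' the edge-based DRLSE energy and returns the interior of its zero level
#' set. With the default negative balloon weight the seed inflates until
#' the image edge indicator arrests it. Evolution runs on a cropped
#' window around the seed for speed.
#'
#' @param frame 2-D intensity matrix.
#' @param seed logical mask matrix of the same shape, or integer pixel
#'   indices into `frame`.
#' @param params a [level_set_params()].
#' @param crop_margin pixels of context kept around the seed's bounding box.
#' @return logical mask matrix (same shape as `frame`), connected and
#'   containing at least one seed pixel, with attributes `grad_dev` (mean
#'   `||grad phi| - 1|` over the narrow band `|phi| <= epsilon`) and
#'   `area`.
#' @export
drlse_refine <- function(frame, seed, params = level_set_params(),
                         crop_margin = 20L) {
  H <- nrow(frame); W <- ncol(frame)
  if (is.logical(seed)) seed_idx <- which(seed) else seed_idx <- as.integer(seed)
  if (length(seed_idx) == 0L) stop("seed region is empty")
  if (any(seed_idx < 1L | seed_idx > H * W)) stop("seed pixels outside frame")
  sr <- (seed_idx - 1L) %% H + 1L
  sc <- (seed_idx - 1L) %/% H + 1L
  r0 <- max(1L, min(sr) - crop_margin); r1 <- min(H, max(sr) + crop_margin)
  c0 <- max(1L, min(sc) - crop_margin); c1 <- min(W, max(sc) + crop_margin)
  crop <- frame[r0:r1, c0:c1, drop = FALSE]
  h <- nrow(crop); w <- ncol(crop)
  seed_loc <- cbind(sr - r0 + 1L, sc - c0 + 1L)
  seed_ci <- seed_loc[, 1] + (seed_loc[, 2] - 1L) * h

  c0lvl <- 2
  phi <- matrix(c0lvl, h, w)
  phi[seed_ci] <- -c0lvl

  if (params$n_iterations > 0L) {
    ei <- edge_indicator(crop, params$sigma_smooth)
    check <- function(it) {
      inside <- sum(phi < 0)
      if (inside == 0L || inside > 0.5 * h * w)
        stop(sprintf(
          "DRLSE diverged at iteration %d (interior %d of %d px) with mu=%g lambda_=%g alpha=%g time_step=%g",
          it, inside, h * w, params$mu, params$lambda_, params$alpha,
          params$time_step))
    }
    for (it in seq_len(params$n_iterations)) {
      phi <- drlse_step(phi, ei$g, ei$gx, ei$gy, params)
      check(it)
    }
    # refinement: area term off, widened Dirac band
    pref <- params
    pref$alpha <- 0
    pref$epsilon <- params$epsilon_refine
    for (it in seq_len(params$n_refine)) {
      phi <- drlse_step(phi, ei$g, ei$gx, ei$gy, pref)
      check(params$n_iterations + it)
    }
  }

  bin <- phi < 0
  # keep the connected component that overlaps the seed
  lab <- EBImage::bwlabel(bin)
  seed_labs <- lab[seed_ci]
  seed_labs <- seed_labs[seed_labs > 0]
  if (length(seed_labs) == 0L)
    stop("DRLSE mask no longer contains any seed pixel")
  keep <- as.integer(names(which.max(table(seed_labs))))
  binc <- lab == keep

  px <- grad_cols(phi); py <- grad_rows(phi)
  s <- sqrt(px^2 + py^2)
  band <- abs(phi) <= params$epsilon
  grad_dev <- if (any(band)) mean(abs(s[band] - 1)) else NA_real_

  mask <- matrix(FALSE, H, W)
  mask[r0:r1, c0:c1] <- binc
  attr(mask, "grad_dev") <- grad_dev
  attr(mask, "area") <- sum(binc)
  mask
}

#' Detect candidate cell regions in a single frame
#'
#' Feature recognition: intensity threshold on the (optionally
#' background-subtracted) frame, connected components, and an area gate.
#' The default `"noise_floor"` threshold is the frame median plus
#' `nsigma` robust standard deviations (MAD): on movies of
#' calcium-indicator cells a single bright transient can stretch the
#' dynamic range 20-100x, which pushes a histogram-valley (Otsu)
#' threshold above the dim, just-landing cells; the noise-floor rule
#' keeps them detectable. `"otsu"` is available for well-balanced
#' images. Suitable as the seed stage ahead of [drlse_refine()] and as
#' the per-frame detector for tracking.
#'
#' @param frame 2-D intensity matrix (finite values).
#' @param min_area_px,max_area_px inclusive area gate in pixels.
#' @param background optional background matrix subtracted before
#'   thresholding.
#' @param method thresholding rule, `"noise_floor"` or `"otsu"`.
#' @param nsigma robust z-score of the noise-floor threshold.
#' @return list of seed regions; each region is a list with `centroid`
#'   (`c(row, col)`, intensity-unweighted), `area` (pixels) and `pixels`
#'   (integer indices into `frame`). Empty list when nothing is found.
#' @export
detect_features <- function(frame, min_area_px = 20, max_area_px = 2500,
                            background = NULL,
                            method = c("noise_floor", "otsu"),
                            nsigma = 4) {
  method <- match.arg(method)
  f <- if (is.null(background)) frame else frame - background
  rng <- range(f)
  if (!all(is.finite(rng))) stop("frame contains non-finite values")
  if (diff(rng) == 0) return(list())
  if (method == "noise_floor") {
    th <- stats::median(f) + nsigma * stats::mad(f)
    if (th >= rng[2]) return(list())
    bin <- f > th
  } else {
    f01 <- (f - rng[1]) / diff(rng)
    bin <- f01 > EBImage::otsu(f01, range = c(0, 1))
  }
  lab <- EBImage::bwlabel(bin)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  idx <- which(lab > 0L)
  labs <- lab[idx]
  areas <- tabulate(labs, nbins = nlab)
  keep <- which(areas >= min_area_px & areas <= max_area_px)
  if (length(keep) == 0L) return(list())
  H <- nrow(frame)
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  sums <- rowsum(cbind(rows, cols), labs)
  pix <- split(idx, labs)
  lapply(keep, function(l) {
    list(centroid = c(sums[l, 1], sums[l, 2]) / areas[l],
         area = areas[l],
         pixels = pix[[as.character(l)]])
  })
}

#' Segment every frame of a movie
#'
#' Subtracts a per-frame background level (the spatial median of the
#' frame, robust because cells cover a minority of the field and a
#' per-pixel temporal median would absorb cells that sit at one spot for
#' most of the movie), then runs [detect_features()] on each frame.
#'
#' @param stack a [movie_stack()].
#' @param min_area_px,max_area_px area gate passed to [detect_features()].
#' @param ... further arguments to [detect_features()].
#' @return list with `frames` (per-frame region lists) and `background`
#'   (per-frame scalar levels).
#' @export
segment_stack <- function(stack, min_area_px = 20, max_area_px = 2500, ...) {
  nf <- n_frames(stack)
  H <- dim(stack$frames)[2]; W <- dim(stack$frames)[3]
  per_frame <- vector("list", nf)
  bg <- numeric(nf)
  for (k in seq_len(nf)) {
    fr <- stack$frames[k, , ]
    bg[k] <- stats::median(fr)
    per_frame[[k]] <- detect_features(fr, min_area_px, max_area_px,
                                      background = bg[k], ...)
  }
  list(frames = per_frame, background = bg)
}

#' Link per-frame regions into cell tracks
#'
#' Nearest-centroid association with a per-track gate of one cell
#' diameter per frame. A region claimed within gate by two tracks flags
#' both as overlapping (such cells are excluded downstream). Tracks
#' missing a detection coast for up to `max_coast` frames (gap centroids
#' interpolated, masks absent) before being terminated.
#'
#' @param stack the source [movie_stack()] (for frame count and timing).
#' @param segmentation output of [segment_stack()] (or a bare list of
#'   per-frame region lists).
#' @param gate_diameters association gate in units of the track diameter.
#' @param max_coast frames a track may survive without a detection.
#' @param min_track_frames tracks shorter than this are dropped.
#' @return list of `cell_record` objects: `cell_id`, `first_seen_frame`,
#'   `frames` (0-based, contiguous), `rows`/`cols` centroid trajectory,
#'   `masks` (per-frame pixel-index lists, `NULL` at coasted gaps),
#'   `diameter_px`, `overlap` flag, plus `landing_frame`, `included`,
#'   `exclusion_reason` fields filled by later stages.
#' @export
track_cells <- function(stack, segmentation, gate_diameters = 1,
                        max_coast = 3L, min_track_frames = 10L) {
  per_frame <- if (!is.null(segmentation$frames)) segmentation$frames else segmentation
  nf <- length(per_frame)
  tracks <- list()
  active <- integer(0)   # indices into tracks

  new_track <- function(reg, k) {
    list(frames = k, rows = reg$centroid[1], cols = reg$centroid[2],
         areas = reg$area, masks = list(reg$pixels),
         coast = 0L, overlap = FALSE)
  }

  regs0 <- per_frame[[1]]
  for (r in regs0) {
    tracks[[length(tracks) + 1L]] <- new_track(r, 0L)
    active <- c(active, length(tracks))
  }

  for (k in seq_len(nf - 1L)) {
    regs <- per_frame[[k + 1L]]
    nr <- length(regs)
    nt <- length(active)
    assigned_reg <- rep(FALSE, nr)
    matched_trk <- rep(FALSE, nt)
    if (nt > 0L && nr > 0L) {
      tp <- t(vapply(active, function(i) {
        tr <- tracks[[i]]
        n <- length(tr$frames)
        c(tr$rows[n], tr$cols[n], 2 * sqrt(stats::median(tr$areas) / pi))
      }, numeric(3)))
      rc <- t(vapply(regs, function(r) r$centroid, numeric(2)))
      d <- sqrt(outer(tp[, 1], rc[, 1], "-")^2 + outer(tp[, 2], rc[, 2], "-")^2)
      gate <- pmax(gate_diameters * tp[, 3], 5)
      within <- d <= matrix(gate, nt, nr)
      # ambiguity: two tracks competing for the same nearest region
      nearest <- apply(d, 1, which.min)
      nearest[!within[cbind(seq_len(nt), nearest)]] <- NA_integer_
      dup <- unique(nearest[duplicated(nearest) & !is.na(nearest)])
      for (j in dup) {
        for (i in which(nearest == j)) tracks[[active[i]]]$overlap <- TRUE
      }
      ord <- order(d)
      for (o in ord) {
        j <- (o - 1L) %/% nt + 1L
        i <- (o - 1L) %% nt + 1L
        if (!within[i, j] || matched_trk[i] || assigned_reg[j]) next
        matched_trk[i] <- TRUE
        assigned_reg[j] <- TRUE
        ti <- active[i]
        tr <- tracks[[ti]]
        gap <- k - tr$frames[length(tr$frames)] - 1L
        if (gap > 0L) {  # interpolate coasted centroids, masks absent
          n <- length(tr$frames)
          fr <- tr$frames[n] + seq_len(gap)
          w <- seq_len(gap) / (gap + 1)
          tr$rows <- c(tr$rows, tr$rows[n] + w * (regs[[j]]$centroid[1] - tr$rows[n]))
          tr$cols <- c(tr$cols, tr$cols[n] + w * (regs[[j]]$centroid[2] - tr$cols[n]))
          tr$frames <- c(tr$frames, fr)
          tr$areas <- c(tr$areas, rep(tr$areas[n], gap))
          tr$masks <- c(tr$masks, rep(list(NULL), gap))
        }
        tr$frames <- c(tr$frames, k)
        tr$rows <- c(tr$rows, regs[[j]]$centroid[1])
        tr$cols <- c(tr$cols, regs[[j]]$centroid[2])
        tr$areas <- c(tr$areas, regs[[j]]$area)
        tr$masks <- c(tr$masks, list(regs[[j]]$pixels))
        tr$coast <- 0L
        # a sudden area jump means the mask merged with a neighbour
        if (regs[[j]]$area > 1.5 * stats::median(tr$areas))
          tr$overlap <- TRUE
        tracks[[ti]] <- tr
      }
    }
    # unmatched active tracks coast or die
    still <- logical(length(active))
    for (i in seq_along(active)) {
      if (matched_trk[i]) { still[i] <- TRUE; next }
      ti <- active[i]
      tracks[[ti]]$coast <- tracks[[ti]]$coast + 1L
      still[i] <- tracks[[ti]]$coast <= max_coast
    }
    active <- active[still]
    # unmatched regions found a new track
    for (j in which(!assigned_reg)) {
      tracks[[length(tracks) + 1L]] <- new_track(regs[[j]], k)
      active <- c(active, length(tracks))
    }
  }

  keep <- vapply(tracks, function(tr) length(tr$frames) >= min_track_frames,
                 logical(1))
  tracks <- tracks[keep]
  records <- vector("list", length(tracks))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    records[[i]] <- structure(list(
      cell_id = i,
      first_seen_frame = tr$frames[1],
      frames = tr$frames,
      rows = tr$rows, cols = tr$cols,
      masks = tr$masks,
      areas = tr$areas,
      diameter_px = 2 * sqrt(stats::median(tr$areas) / pi),
      overlap = tr$overlap,
      landing_frame = NA_integer_,
      included = NA,
      exclusion_reason = NA_character_), class = "cell_record")
  }
  records
}

#' Detect the landing frame of a tracked cell
#'
#' Landing is an immediate cessation of movement: the first frame from
#' which the per-frame centroid displacement stays below
#' `motion_stop_threshold` for `motion_stop_frames` consecutive frames,
#' provided the cell then remains present to the end of the movie.
#'
#' @param record a `cell_record` from [track_cells()].
#' @param config a [run_config()].
#' @param last_movie_frame final frame index of the movie (0-based); the
#'   cell must persist to it.
#' @return 0-based landing frame index, or `NA` if the cell never lands.
#' @export
detect_landing <- function(record, config = run_config(),
                           last_movie_frame = max(record$frames)) {
  m <- config$motion_stop_frames
  n <- length(record$frames)
  if (n - 1L < m) return(NA_integer_)
  if (max(record$frames) < last_movie_frame) return(NA_integer_)
  steps <- sqrt(diff(record$rows)^2 + diff(record$cols)^2)
  ok <- steps < config$motion_stop_threshold
  runsum <- stats::filter(as.numeric(ok), rep(1, m), sides = 1)
  hit <- which(runsum == m)
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(record$frames[hit[1] - m + 1L])
}

#' Apply the inclusion filters to tracked cells
#'
#' A cell is excluded when it (a) never lands, (b) lands after
#' `landing_window` seconds, (c) sits closer than
#' `edge_margin_diameters` of its own diameter to an image border at its
#' landing frame, or (d) was flagged as overlapping another cell during
#' tracking. Exclusion counts are reported via `message()`.
#'
#' @param records list of `cell_record`s with landing already detected
#'   (see [detect_landing()]; this function calls it for records whose
#'   `landing_frame` is still `NA`).
#' @param stack the source [movie_stack()].
#' @param config a [run_config()].
#' @param quiet suppress the filter-count message.
#' @return the records, with `included` and `exclusion_reason` set.
#' @export
filter_cells <- function(records, stack, config = run_config(), quiet = FALSE) {
  H <- dim(stack$frames)[2]; W <- dim(stack$frames)[3]
  last <- n_frames(stack) - 1L
  reasons <- character(length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (is.na(rec$landing_frame))
      rec$landing_frame <- detect_landing(rec, config, last_movie_frame = last)
    reason <- "none"
    if (is.na(rec$landing_frame)) {
      reason <- "no_landing"
    } else if (frame_time(stack, rec$landing_frame) > config$landing_window) {
      reason <- "late_landing"
    } else {
      j <- match(rec$landing_frame, rec$frames)
      edge_d <- min(rec$rows[j] - 1, H - rec$rows[j],
                    rec$cols[j] - 1, W - rec$cols[j])
      if (edge_d < config$edge_margin_diameters * rec$diameter_px) {
        reason <- "edge"
      } else if (isTRUE(rec$overlap)) {
        reason <- "overlap"
      }
    }
    rec$included <- reason == "none"
    rec$exclusion_reason <- reason
    records[[i]] <- rec
  }
  if (!quiet) {
    tab <- table(factor(vapply(records, `[[`, character(1), "exclusion_reason"),
                        levels = c("none", "no_landing", "late_landing",
                                   "edge", "overlap")))
    message(sprintf(
      "filter_cells: %d tracked; included %d; excluded no_landing=%d late_landing=%d edge=%d overlap=%d",
      length(records), tab[["none"]], tab[["no_landing"]],
      tab[["late_landing"]], tab[["edge"]], tab[["overlap"]]))
  }
  records
}

#' Tabulate cell records
#'
#' @param x list of `cell_record`s.
#' @param ... unused.
#' @return data.frame matching the `cells.csv` schema: `cell_id`,
#'   `first_seen_frame`, `landing_frame`, `centroid_row`, `centroid_col`,
#'   `diameter_px`, `included`, `exclusion_reason`.
#' @export
cells_table <- function(x, ...) {
  do.call(rbind, lapply(x, function(rec) {
    j <- if (!is.na(rec$landing_frame)) match(rec$landing_frame, rec$frames)
         else length(rec$frames)
    data.frame(cell_id = rec$cell_id,
               first_seen_frame = rec$first_seen_frame,
               landing_frame = rec$landing_frame,
               centroid_row = rec$rows[j],
               centroid_col = rec$cols[j],
               diameter_px = rec$diameter_px,
               included = rec$included,
               exclusion_reason = rec$exclusion_reason)
  }))
}
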
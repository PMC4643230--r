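# Landing/triggering event detection from dR/dt, responder classification,
# trace alignment, triggering intervals.

#' Time derivative of a normalized response curve
#'
#' Central differences in the interior, one-sided differences at the two
#' ends; exact for quadratics at interior samples. Requires a uniform
#' time grid.
#'
#' @param trace a `normalized_trace`.
#' @return an object of class `derivative_trace` with `cell_id`, `times`
#'   and `dRdt` (units 1/s), same length as the source.
#' @export
derivative <- function(trace) {
  t <- trace$times; R <- trace$R
  n <- length(t)
  if (n < 3L) stop("need >= 3 samples to differentiate")
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("derivative requires a uniform time grid")
  h <- stats::median(dt)
  d <- numeric(n)
  d[1] <- (R[2] - R[1]) / h
  d[n] <- (R[n] - R[n - 1]) / h
  if (n > 2) d[2:(n - 1)] <- (R[3:n] - R[1:(n - 2)]) / (2 * h)
  structure(list(cell_id = trace$cell_id, times = t, dRdt = d),
            class = "derivative_trace")
}

# indices of strict local maxima (left-strict, right-nonstrict to break
# plateau ties toward the earlier sample)
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# topographic prominence of local maximum i of y
peak_prominence <- function(y, i) {
  n <- length(y)
  lmin <- y[i]
  j <- i
  while (j > 1L && y[j - 1L] <= y[i]) { j <- j - 1L; lmin <- min(lmin, y[j]) }
  left <- if (j == 1L && y[j] <= y[i]) min(y[1:i]) else lmin
  rmin <- y[i]
  j <- i
  while (j < n && y[j + 1L] <= y[i]) { j <- j + 1L; rmin <- min(rmin, y[j]) }
  right <- if (j == n && y[j] <= y[i]) min(y[i:n]) else rmin
  y[i] - max(left, right)
}

#' Locate landing and triggering peaks in dR/dt
#'
#' Both landing (small, the cell drops into the focal plane) and
#' triggering (large, calcium-dependent emission increase) raise the
#' fluorescence and appear as separate peaks in the derivative. The
#' landing peak is the largest derivative value within twice the
#' alignment offset of the known landing time; the triggering peak is
#' the largest local maximum after it with prominence at least
#' `peak_min_prominence` (or, adaptively, 3 robust SDs of the
#' pre-landing derivative). The triggering time is the transient onset:
#' the sample at which dR/dt last rises through 10 % of the peak height
#' before the peak.
#'
#' @param d a [derivative()] trace.
#' @param t_landing landing time, seconds (within the trace span).
#' @param config a [run_config()].
#' @return list with `landing_peak` (`index`, `time`, `value`) and
#'   `trigger_peak` (`index`, `time`, `value`, `prominence`,
#'   `onset_time`) or `NULL` when no triggering peak exists.
#' @export
find_event_peaks <- function(d, t_landing, config = run_config()) {
  t <- d$times; y <- d$dRdt
  if (t_landing < t[1] - 1e-9 || t_landing > t[length(t)] + 1e-9)
    stop("t_landing outside the trace span")
  halfwin <- 2 * config$align_offset
  near <- which(abs(t - t_landing) <= max(halfwin, stats::median(diff(t))))
  li <- near[which.max(y[near])]
  landing_peak <- list(index = li, time = t[li], value = y[li])

  prom_min <- config$peak_min_prominence
  if (is.na(prom_min)) {
    pre <- y[t < t_landing]
    base <- if (length(pre) >= 5L) pre else y
    prom_min <- max(3 * stats::mad(base), 1e-9)
  }
  cand <- local_maxima(y)
  cand <- cand[cand > li & t[cand] > t[li]]
  if (length(cand)) {
    proms <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
    cand <- cand[proms >= prom_min]
    proms <- proms[proms >= prom_min]
  }
  if (!length(cand))
    return(list(landing_peak = landing_peak, trigger_peak = NULL))
  pick <- which.max(y[cand])
  pi <- cand[pick]
  thr <- 0.1 * y[pi]
  j <- pi
  while (j > 1L && y[j - 1L] >= thr) j <- j - 1L
  list(landing_peak = landing_peak,
       trigger_peak = list(index = pi, time = t[pi], value = y[pi],
                           prominence = proms[pick], onset_time = t[j]))
}

#' Classify a cell as responder or non-responder
#'
#' A responder shows a triggering peak in dR/dt, a fold-increase over
#' baseline above the user threshold (default: dI/I0 > 5, i.e. a >500 %
#' increase above background), and a subsequent decrease: after its
#' maximum, R(t) must shed at least `decrease_fraction` of its
#' above-baseline excursion before the trace ends.
#'
#' @param trace a `normalized_trace`.
#' @param trigger_peak the `trigger_peak` element of
#'   [find_event_peaks()] (may be `NULL`).
#' @param config a [run_config()].
#' @return list with `is_responder` (logical) and `peak_response`
#'   (dI/I0, always computed).
#' @export
classify_responder <- function(trace, trigger_peak, config = run_config()) {
  I0 <- trace$I0; Imax <- trace$Imax
  ratio <- if (I0 > 0) trace$dI / I0 else Inf
  crit <- switch(config$threshold_mode,
                 fold_over_baseline = ratio,
                 ratio = if (I0 > 0) Imax / I0 else Inf)
  above <- crit > config$response_threshold
  R <- trace$R
  im <- which.max(R)
  R_base <- I0 / Imax
  decreased <- im < length(R) &&
    min(R[im:length(R)]) <= 1 - config$decrease_fraction * (1 - R_base)
  list(is_responder = !is.null(trigger_peak) && above && decreased,
       peak_response = ratio)
}

#' Align a response curve on its landing event
#'
#' Shifts the time axis so that 0 sits `align_offset` seconds after the
#' landing event; samples before the origin keep negative times.
#'
#' @param trace a `normalized_trace`.
#' @param t_landing landing time, seconds.
#' @param config a [run_config()].
#' @return the trace with an added `aligned_times` field.
#' @export
align_trace <- function(trace, t_landing, config = run_config()) {
  if (t_landing < trace$times[1] - 1e-9 ||
      t_landing > trace$times[length(trace$times)] + 1e-9)
    stop("t_landing outside the trace span")
  trace$aligned_times <- trace$times - (t_landing + config$align_offset)
  trace
}

#' Triggering interval of an annotated cell
#'
#' `T = t_triggering - t_landing`, defined for responders only and never
#' negative.
#'
#' @param annotation one-row data.frame (or list) with `t_landing_s`,
#'   `t_triggering_s`, `is_responder`.
#' @return seconds, or `NA` for non-responders.
#' @export
triggering_interval <- function(annotation) {
  if (!isTRUE(annotation$is_responder) || is.na(annotation$t_triggering_s))
    return(NA_real_)
  max(0, annotation$t_triggering_s - annotation$t_landing_s)
}

#' Annotate one cell's events
#'
#' Runs [derivative()], [find_event_peaks()], [classify_responder()] and
#' [align_trace()] for a single normalized trace.
#'
#' @param trace a `normalized_trace`.
#' @param t_landing landing time, seconds.
#' @param config a [run_config()].
#' @return list with `annotation` (one-row data.frame matching the
#'   `events.csv` schema) and `aligned` (the aligned trace).
#' @export
annotate_cell <- function(trace, t_landing, config = run_config()) {
  d <- derivative(trace)
  pk <- find_event_peaks(d, t_landing, config)
  cl <- classify_responder(trace, pk$trigger_peak, config)
  t_trig <- if (!is.null(pk$trigger_peak) && cl$is_responder)
    pk$trigger_peak$onset_time else NA_real_
  ann <- data.frame(cell_id = trace$cell_id,
                    t_landing_s = t_landing,
                    t_triggering_s = t_trig,
                    T_s = NA_real_,
                    is_responder = cl$is_responder,
                    peak_response = cl$peak_response,
                    I0 = trace$I0, Imax = trace$Imax, dI = trace$dI)
  ann$T_s <- triggering_interval(ann)
  list(annotation = ann, aligned = align_trace(trace, t_landing, config))
}
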
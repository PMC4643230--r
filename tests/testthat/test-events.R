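ntrace <- function(R, dt = 0.5, I0 = NULL, Imax = NULL, cell_id = 1L) {
  Imax <- Imax %||% max(R)
  structure(list(cell_id = cell_id, times = (seq_along(R) - 1) * dt,
                 R = R / max(R), I0 = I0 %||% min(R), Imax = Imax,
                 dI = Imax - (I0 %||% min(R))),
            class = "normalized_trace")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# synthetic responder intensity trace with known landing/trigger times
responder_intensity <- function(n = 400, dt = 0.5, landing_t = 20,
                                trigger_t = 80, I0 = 100, amp = 8,
                                rise = 3, decay = 40, step = 1.3) {
  t <- (seq_len(n) - 1) * dt
  I <- rep(I0 / step, n)
  I[t >= landing_t] <- I0
  tt <- t[t >= trigger_t] - trigger_t
  I[t >= trigger_t] <- I0 + amp * I0 * transient_shape(tt, rise, decay)
  raw_trace(1L, t, I)
}

annotate_intensity <- function(I, landing_t, cfg = run_config(), dt = 0.5) {
  sm <- smooth_trace(I, cfg$window_frames, cfg$poly_order)
  nt <- normalize_trace(sm, max(1L, round(cfg$baseline_window_s / dt)),
                        landing_time = landing_t)
  annotate_cell(nt, landing_t, cfg)
}

test_that("the derivative is exact for linear and quadratic responses", {
  t <- (0:20) * 0.5
  lin <- structure(list(cell_id = 1L, times = t, R = t / max(t),
                        I0 = 0, Imax = 1, dI = 1),
                   class = "normalized_trace")
  expect_equal(derivative(lin)$dRdt, rep(1 / max(t), 21), tolerance = 1e-12)
  cst <- ntrace(rep(2, 10))
  expect_equal(derivative(cst)$dRdt, rep(0, 10))
  quad <- structure(list(cell_id = 1L, times = t, R = 0.01 * t^2 + 0.1,
                         I0 = 1, Imax = 1, dI = 0),
                    class = "normalized_trace")
  d2 <- derivative(quad)
  expect_equal(d2$dRdt[2:20], 0.02 * t[2:20], tolerance = 1e-10)
  expect_error(derivative(ntrace(c(1, 2))), ">= 3")
  bad <- ntrace(1:5); bad$times <- c(0, 1, 2, 4, 8)
  expect_error(derivative(bad), "uniform")
})

test_that("event peaks pick the landing step and the triggering transient", {
  tr <- responder_intensity()
  ac <- annotate_intensity(tr, landing_t = 20)
  ann <- ac$annotation
  expect_true(ann$is_responder)
  # onset recovered within one second of the true trigger time
  expect_lt(abs(ann$t_triggering_s - 80), 1 + 1e-9)
  expect_equal(ann$T_s, ann$t_triggering_s - 20)
  expect_equal(ann$peak_response, 8, tolerance = 0.1)
})

test_that("a flat post-landing trace yields no trigger and no response", {
  t <- (0:199) * 0.5
  I <- c(rep(77, 40), rep(100, 160)) + 0
  ac <- annotate_intensity(raw_trace(1L, t, I), landing_t = 20)
  expect_false(ac$annotation$is_responder)
  expect_true(is.na(ac$annotation$t_triggering_s))
  expect_true(is.na(ac$annotation$T_s))
})

test_that("classification needs threshold crossing AND a subsequent decrease", {
  cfg <- run_config()
  # dI/I0 = 6 with decay: responder
  ac <- annotate_intensity(responder_intensity(amp = 6), 20, cfg)
  expect_true(ac$annotation$is_responder)
  # dI/I0 = 3: below the 500% threshold
  ac <- annotate_intensity(responder_intensity(amp = 3), 20, cfg)
  expect_false(ac$annotation$is_responder)
  expect_equal(ac$annotation$peak_response, 3, tolerance = 0.1)
  # a monotone rise with dI/I0 = 8 but no decrease is not a responder
  t <- (0:399) * 0.5
  I <- c(rep(100, 160), 100 + 800 * (1 - exp(-(t[161:400] - 80) / 60)))
  ac <- annotate_intensity(raw_trace(1L, t, I), landing_t = 0, cfg)
  expect_false(ac$annotation$is_responder)
  expect_gt(ac$annotation$peak_response, 5)
})

test_that("raising the response threshold never adds responders", {
  set.seed(5)
  amps <- runif(12, 2, 12)
  for (th in list(c(3, 5), c(5, 8), c(8, 12))) {
    lo <- run_config(response_threshold = th[1])
    hi <- run_config(response_threshold = th[2])
    r_lo <- vapply(amps, function(a)
      annotate_intensity(responder_intensity(amp = a), 20, lo)$annotation$is_responder,
      logical(1))
    r_hi <- vapply(amps, function(a)
      annotate_intensity(responder_intensity(amp = a), 20, hi)$annotation$is_responder,
      logical(1))
    expect_true(all(r_lo | !r_hi))  # hi-responder implies lo-responder
  }
})

test_that("classification, T and R(t) are invariant under intensity scaling", {
  tr <- responder_intensity(amp = 7)
  for (c_scale in c(0.5, 3, 40)) {
    tr2 <- raw_trace(1L, tr$times, tr$intensities * c_scale)
    a1 <- annotate_intensity(tr, 20)
    a2 <- annotate_intensity(tr2, 20)
    expect_equal(a1$annotation$is_responder, a2$annotation$is_responder)
    expect_equal(a1$annotation$T_s, a2$annotation$T_s)
    expect_equal(a1$annotation$peak_response, a2$annotation$peak_response,
                 tolerance = 1e-9)
    expect_equal(a1$aligned$R, a2$aligned$R, tolerance = 1e-12)
  }
})

test_that("shifting a trace in time shifts both events and leaves T unchanged", {
  base <- responder_intensity()
  a0 <- annotate_intensity(base, 20)$annotation
  shifted <- raw_trace(1L, base$times + 30, base$intensities)
  a1 <- annotate_intensity(shifted, 50)$annotation
  expect_equal(a1$t_landing_s, a0$t_landing_s + 30)
  expect_equal(a1$t_triggering_s, a0$t_triggering_s + 30)
  expect_equal(a1$T_s, a0$T_s)
})

test_that("alignment puts time zero at landing + offset", {
  nt <- ntrace(seq(0.1, 1, length.out = 105), dt = 0.5)
  al <- align_trace(nt, t_landing = 50, run_config(align_offset = 2))
  expect_equal(al$aligned_times[which(nt$times == 52)], 0)
  al0 <- align_trace(nt, t_landing = 50, run_config(align_offset = 0))
  expect_equal(al0$aligned_times[which(nt$times == 50)], 0)
  # two cells landing 30 s apart share the grid where they overlap
  al2 <- align_trace(nt, t_landing = 20, run_config(align_offset = 2))
  common <- intersect(round(al$aligned_times / 0.5),
                      round(al2$aligned_times / 0.5))
  expect_gt(length(common), 0)
  expect_error(align_trace(nt, 1e6, run_config()), "span")
})

test_that("triggering intervals subtract landing from triggering", {
  ann <- data.frame(t_landing_s = 50, t_triggering_s = 163,
                    is_responder = TRUE)
  expect_equal(triggering_interval(ann), 113)
  expect_true(is.na(triggering_interval(
    data.frame(t_landing_s = 50, t_triggering_s = NA_real_,
               is_responder = FALSE))))
})
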
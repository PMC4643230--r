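make_region <- function(ctr, radius = 4, H = 64, W = 64) {
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  m <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= radius^2
  list(centroid = ctr, area = sum(m), pixels = which(m))
}

test_that("feature detection finds disks and ignores blank frames", {
  expect_identical(detect_features(matrix(7, 50, 50)), list())

  d <- disk_frame(radius = 10)
  seeds <- detect_features(d$frame)
  expect_length(seeds, 1L)
  expect_lt(max(abs(seeds[[1]]$centroid - c(40, 40))), 1)
  expect_equal(seeds[[1]]$area, sum(d$mask))

  # grid of many disks is recovered disk-for-disk
  H <- 220
  fr <- matrix(20, H, H)
  centers <- expand.grid(row = seq(20, 200, by = 30), col = seq(20, 200, by = 30))
  for (i in seq_len(nrow(centers))) {
    reg <- make_region(c(centers$row[i], centers$col[i]), radius = 6,
                       H = H, W = H)
    fr[reg$pixels] <- 150
  }
  seeds <- detect_features(fr)
  expect_length(seeds, nrow(centers))
  got <- t(vapply(seeds, function(s) s$centroid, numeric(2)))
  got <- got[order(got[, 1], got[, 2]), ]
  want <- as.matrix(centers[order(centers$row, centers$col), ])
  expect_lt(max(abs(got - want)), 1)
})

test_that("area gate excludes too-small and too-large components", {
  fr <- matrix(0, 64, 64)
  fr[make_region(c(16, 16), 2)$pixels] <- 100   # area ~13
  fr[make_region(c(44, 44), 6)$pixels] <- 100   # area ~113
  seeds <- detect_features(fr, min_area_px = 20, max_area_px = 2500)
  expect_length(seeds, 1L)
  expect_lt(max(abs(seeds[[1]]$centroid - c(44, 44))), 1)
  expect_length(detect_features(fr, min_area_px = 200), 0L)
})

test_that("DRLSE with zero iterations returns the seed unchanged", {
  d <- disk_frame(radius = 10)
  seed <- disk_frame(radius = 6)$mask
  m <- drlse_refine(d$frame, seed,
                    level_set_params(alpha = 0, n_iterations = 0, n_refine = 0))
  expect_identical(which(m), which(seed))
})

test_that("DRLSE recovers a noise-free disk with high overlap and stays
           distance-regularized", {
  d <- disk_frame(radius = 10)
  seed <- disk_frame(radius = 6)$mask
  m <- drlse_refine(d$frame, seed)
  expect_gte(iou(m, d$mask), 0.95)
  expect_lt(attr(m, "grad_dev"), 0.2)
})

test_that("DRLSE tolerates noise at SNR around 5", {
  d <- disk_frame(radius = 10, fg = 200, bg = 20)
  seed <- disk_frame(radius = 6)$mask
  set.seed(99)
  noisy <- d$frame + matrix(rnorm(length(d$frame), 0, 36), nrow(d$frame))
  m <- drlse_refine(noisy, seed)
  expect_gte(iou(m, d$mask), 0.8)
  expect_lt(attr(m, "grad_dev"), 0.2)
})

test_that("DRLSE rejects unstable parameters and empty seeds", {
  expect_error(level_set_params(mu = 0.3, time_step = 1), "unstable")
  d <- disk_frame()
  expect_error(drlse_refine(d$frame, matrix(FALSE, 80, 80)), "empty")
})

test_that("a stationary cell yields one track with zero displacement", {
  reg <- make_region(c(30, 30))
  seg <- replicate(10, list(list(reg)))
  fr <- array(0L, dim = c(10, 64, 64))
  recs <- track_cells(movie_stack(fr, 0.5), seg, min_track_frames = 5L)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$frames, 0:9)
  expect_equal(max(abs(diff(recs[[1]]$rows))), 0)
  expect_equal(max(abs(diff(recs[[1]]$cols))), 0)
  expect_false(recs[[1]]$overlap)
})

test_that("two cells merging into one region are both flagged as overlap", {
  # two tracks converge; from frame 5 a single merged region remains
  seg <- lapply(0:9, function(k) {
    if (k < 5) {
      list(make_region(c(30, 20 + k)), make_region(c(30, 40 - k)))
    } else {
      list(make_region(c(30, 30), radius = 6))
    }
  })
  fr <- array(0L, dim = c(10, 64, 64))
  recs <- track_cells(movie_stack(fr, 0.5), seg, min_track_frames = 3L)
  flagged <- vapply(recs, `[[`, logical(1), "overlap")
  expect_gte(sum(flagged), 2L)
})

test_that("landing is the first frame of a sustained stop", {
  # steps of 3 px/frame, then standstill
  rows <- c(10, 13, 16, 19, rep(19, 8))
  rec <- structure(list(cell_id = 1L, first_seen_frame = 0L,
                        frames = 0:11, rows = rows, cols = rep(5, 12),
                        masks = vector("list", 12), areas = rep(50, 12),
                        diameter_px = 8, overlap = FALSE,
                        landing_frame = NA_integer_, included = NA,
                        exclusion_reason = NA_character_),
                   class = "cell_record")
  cfg <- run_config(motion_stop_threshold = 0.5, motion_stop_frames = 3L)
  expect_equal(detect_landing(rec, cfg, last_movie_frame = 11L), 3L)
  # a cell that never stops has no landing
  rec$rows <- seq(10, by = 3, length.out = 12)
  expect_true(is.na(detect_landing(rec, cfg, last_movie_frame = 11L)))
  # a cell that leaves before the movie ends has no landing
  rec$rows <- rows
  expect_true(is.na(detect_landing(rec, cfg, last_movie_frame = 20L)))
})

test_that("landing detection is equivariant under a shift of the frame axis", {
  rows <- c(10, 12.5, 15, 17, 17.2, rep(17.2, 10))
  mk <- function(shift) structure(
    list(cell_id = 1L, first_seen_frame = shift, frames = shift + 0:14,
         rows = rows, cols = rep(8, 15), masks = vector("list", 15),
         areas = rep(50, 15), diameter_px = 8, overlap = FALSE,
         landing_frame = NA_integer_, included = NA,
         exclusion_reason = NA_character_), class = "cell_record")
  cfg <- run_config(motion_stop_threshold = 0.5, motion_stop_frames = 4L)
  l0 <- detect_landing(mk(0L), cfg, last_movie_frame = 14L)
  for (k in c(3L, 11L)) {
    expect_equal(detect_landing(mk(k), cfg, last_movie_frame = 14L + k),
                 l0 + k)
  }
})

test_that("inclusion filters apply the landing-window, edge and overlap rules", {
  fr <- array(0L, dim = c(400, 100, 100))
  st <- movie_stack(fr, 1)  # 1 s per frame for easy arithmetic
  mk <- function(landing, row, col, overlap = FALSE) structure(
    list(cell_id = 1L, first_seen_frame = 0L, frames = 0:399,
         rows = if (is.na(landing)) row + (0:399) %% 2  # never stops jittering
                else rep(row, 400),
         cols = rep(col, 400),
         masks = vector("list", 400), areas = rep(314, 400),
         diameter_px = 20, overlap = overlap,
         landing_frame = landing, included = NA,
         exclusion_reason = NA_character_), class = "cell_record")
  cfg <- run_config(landing_window = 300, edge_margin_diameters = 1)
  out <- suppressMessages(
    filter_cells(list(mk(310L, 50, 50),      # lands at 310 s: late
                      mk(100L, 5, 50),       # centroid 4 px from edge
                      mk(100L, 50, 50),      # clean
                      mk(100L, 50, 50, overlap = TRUE),
                      mk(NA_integer_, 50, 50)),
                 st, cfg))
  expect_equal(vapply(out, `[[`, character(1), "exclusion_reason"),
               c("late_landing", "edge", "none", "overlap", "no_landing"))
  expect_equal(vapply(out, `[[`, logical(1), "included"),
               c(FALSE, FALSE, TRUE, FALSE, FALSE))
})

test_that("masks within a frame are pairwise disjoint", {
  sim <- generate_movie(small_scene(n_cells = 8L, seed = 14L, n_frames = 40L))
  seg <- segment_stack(sim$stack)
  for (k in c(1L, 20L, 40L)) {
    pix <- unlist(lapply(seg$frames[[k]], `[[`, "pixels"))
    expect_false(anyDuplicated(pix) > 0)
  }
})
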
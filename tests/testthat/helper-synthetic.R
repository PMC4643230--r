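# Shared synthetic fixtures, built in code at test time.

# compact scene: small field, short movie, fast to render and analyze
small_scene <- function(n_cells = 10L, seed = 11L, noise_sd = 10,
                        responder_fraction = 0.6, n_frames = 200L,
                        image_size = c(192L, 192L)) {
  scene_config(image_size = image_size, n_frames = n_frames,
               n_cells = n_cells,
               landing_time_dist = list(dist = "uniform", min = 3, max = 20),
               trigger_delay_dist = list(dist = "uniform", min = 10, max = 40),
               responder_fraction = responder_fraction,
               noise_model = list(gaussian_sd = noise_sd, poisson = FALSE),
               seed = seed)
}

# a noise-free disk image for segmentation oracles
disk_frame <- function(H = 80L, W = 80L, ctr = c(40, 40), radius = 10,
                       fg = 200, bg = 20) {
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  m <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= radius^2
  fr <- matrix(bg, H, W)
  fr[m] <- fg
  list(frame = fr, mask = m)
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# memoized medium end-to-end run shared across test files
.fixture_env <- new.env(parent = emptyenv())
medium_run <- function() {
  if (is.null(.fixture_env$medium)) {
    sc <- small_scene(n_cells = 25L, seed = 42L, n_frames = 240L,
                      image_size = c(256L, 256L))
    sim <- generate_movie(sc)
    out <- file.path(tempdir(), "medium_run_fixture")
    dir.create(out, showWarnings = FALSE)
    res <- suppressMessages(
      run_full(sim$stack, run_config(), out_dir = out, make_figures = FALSE,
               quiet = TRUE))
    .fixture_env$medium <- list(scene = sc, sim = sim, res = res, out = out)
  }
  .fixture_env$medium
}
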
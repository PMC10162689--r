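# a minimal noise-free stack with specified particle trajectories (um at
# 1 um/px), horizontal path at y = 10
make_toy_stack <- function(trajs, n_frames = 60, width = 120, amp = 1000) {
  frames <- lapply(seq_len(n_frames), function(t) {
    px <- matrix(0, 20, width)
    for (tr in trajs) {
      x <- tr[min(t, length(tr))]
      xs <- pmax(1, round(x) - 4):pmin(width, round(x) + 4)
      px[11, xs] <- px[11, xs] + amp * exp(-((xs - 1 - x)^2) / (2 * 1.5^2))
      px[10, xs] <- px[10, xs] + 0.8 * amp * exp(-((xs - 1 - x)^2) / (2 * 1.5^2))
      px[12, xs] <- px[12, xs] + 0.8 * amp * exp(-((xs - 1 - x)^2) / (2 * 1.5^2))
    }
    image_grid(px)
  })
  image_stack(frames, dt_s = 1)
}
toy_path <- function(width = 120) nerve_path(cbind(c(5, width - 5), c(10, 10)))

test_that("kymograph shape matches the movie", {
  sim <- simulate_mito_movie(n_particles = 10, n_frames = 60, dt_s = 1,
                             path_length_um = 150, seed = 70)
  ky <- build_kymograph(sim$stack, sim$path)
  expect_equal(nrow(ky$grid), 60)
  expect_error(build_kymograph(sim$stack,
                               nerve_path(cbind(c(-50, 100), c(20, 20)))),
               "bounds")
})

test_that("static and moving particles draw the expected kymograph lines", {
  static <- make_toy_stack(list(rep(60, 60)))
  ky <- build_kymograph(static, toy_path())
  peak_col <- apply(ky$grid, 1, which.max)
  expect_true(all(peak_col == peak_col[1]))

  v <- 0.5  # um/s toward the eye = decreasing position
  mover <- make_toy_stack(list(100 - v * (0:59)))
  kym <- build_kymograph(mover, toy_path())
  cols <- apply(kym$grid, 1, which.max)
  slope <- unname(coef(lm(cols ~ seq_along(cols)))[2])
  expect_equal(slope, -v / kym$dx_um, tolerance = 0.05)
})

test_that("track detection matches truth on clean movies and empty input", {
  sim <- simulate_mito_movie(n_particles = 20, snr = 50,
                             path_length_um = 300, seed = 71)
  ky <- build_kymograph(sim$stack, sim$path)
  tracks <- detect_tracks(ky)
  expect_gte(length(tracks), 19)
  # match detected tracks to truth particles by mean position error
  tp <- sim$truth$truth$positions
  errs <- vapply(tracks, function(tr) {
    s <- tr$samples
    min(apply(tp[, s$frame, drop = FALSE], 1,
              function(p) mean(abs(p - s$position_um))))
  }, 0)
  expect_lt(mean(errs), 1)

  blank <- structure(list(grid = matrix(0, 60, 100), dt_s = 1, dx_um = 1),
                     class = "kymograph")
  expect_length(detect_tracks(blank), 0)
})

test_that("crossing particles keep their identities", {
  up <- 10 + 1.5 * (0:59)
  down <- 100 - 1.5 * (0:59)
  st <- make_toy_stack(list(up, down))
  ky <- build_kymograph(st, toy_path())
  tracks <- lapply(detect_tracks(ky), classify_track)
  expect_equal(length(tracks), 2)
  ends <- vapply(tracks, function(tr) {
    s <- tr$samples
    s$position_um[nrow(s)] - s$position_um[1]
  }, 0)
  expect_equal(sort(sign(ends)), c(-1, 1))
  expect_true(all(abs(ends) > 40))
})

test_that("motility classification follows the sign convention", {
  mk <- function(pos) structure(
    list(samples = data.frame(frame = seq_along(pos), position_um = pos),
         label = NA_character_, n_samples = length(pos), dt_s = 1),
    class = "mito_track")
  expect_equal(classify_track(mk(rep(30, 15)))$label, "stopped")
  expect_equal(classify_track(mk(seq(50, 38, length.out = 15)))$label,
               "retrograde")
  expect_equal(classify_track(mk(seq(30, 42, length.out = 15)))$label,
               "orthograde")
  # |net| below d_stop is stopped regardless of direction
  expect_equal(classify_track(mk(seq(30, 31.5, length.out = 15)))$label,
               "stopped")
})

test_that("velocity is the pause-excluded mean speed", {
  mk <- function(pos) structure(
    list(samples = data.frame(frame = seq_along(pos), position_um = pos),
         label = NA_character_, n_samples = length(pos), dt_s = 1),
    class = "mito_track")
  uniform <- classify_track(mk(30 + 0.5 * (0:30)))
  expect_equal(track_velocity(uniform), 0.5, tolerance = 1e-6)

  # 10 s pause embedded in a 0.5 um/s run: hand-computed moving-phase speed
  paused <- c(30 + 0.5 * (0:14), rep(37, 10), 37 + 0.5 * (1:15))
  tr <- classify_track(mk(paused))
  expect_equal(track_velocity(tr), 0.5, tolerance = 1e-6)

  expect_error(track_velocity(classify_track(mk(rep(5, 15)))), "moving")
})

test_that("velocity estimation is unbiased on noise-free uniform motion", {
  for (v in c(0.1, 0.5, 1.0, 1.5)) {
    st <- make_toy_stack(list(10 + v * (0:59)), width = 160)
    ky <- build_kymograph(st, toy_path(160))
    tracks <- lapply(detect_tracks(ky), classify_track)
    expect_equal(length(tracks), 1)
    expect_equal(track_velocity(tracks[[1]]), v, tolerance = 0.05 * v + 0.01)
  }
})

test_that("motility summary conserves counts and pools by nerve", {
  mk <- function(label) structure(
    list(samples = data.frame(frame = 1:15,
                              position_um = switch(label,
                                                   stopped = rep(10, 15),
                                                   retrograde = seq(50, 38, length.out = 15),
                                                   orthograde = seq(10, 22, length.out = 15))),
         label = label, n_samples = 15, dt_s = 1),
    class = "mito_track")
  nerve <- list(mk("stopped"), mk("stopped"), mk("retrograde"), mk("orthograde"))
  s <- motility_summary(list(n1 = nerve))$all
  expect_equal(unname(s$fractions$mean),  c(0.5, 0.25, 0.25))
  expect_equal(s$n_mitochondria, 4)
  expect_equal(s$N_nerves, 1)
  expect_equal(sum(s$fractions$mean), 1, tolerance = 1e-9)
  expect_error(motility_summary(list(n1 = nerve, n2 = list())), "zero tracks")
})

test_that("reversing the path orientation swaps retro- and orthograde", {
  sim <- simulate_mito_movie(n_particles = 15, snr = 20,
                             path_length_um = 300, seed = 72)
  ky_f <- build_kymograph(sim$stack, sim$path)
  rev_path <- nerve_path(sim$path$points[2:1, ])
  ky_r <- build_kymograph(sim$stack, rev_path)
  classes <- c("stopped", "retrograde", "orthograde")
  count_by <- function(labels)
    as.integer(table(factor(labels, levels = classes)))
  lab_f <- vapply(lapply(detect_tracks(ky_f), classify_track),
                  function(t) t$label, "")
  lab_r <- vapply(lapply(detect_tracks(ky_r), classify_track),
                  function(t) t$label, "")
  swapped <- c(retrograde = "orthograde", orthograde = "retrograde",
               stopped = "stopped")[lab_r]
  expect_equal(count_by(swapped), count_by(lab_f))
})

test_that("recovered fractions respect binomial error across conditions", {
  sim <- simulate_mito_movie(n_particles = 60, fractions = c(0.3, 0.5, 0.2),
                             path_length_um = 400, seed = 73)
  tracks <- run_motility_pipeline(sim)
  lab <- vapply(tracks, function(t) t$label, "")
  frac <- c(mean(lab == "stopped"), mean(lab == "retrograde"),
            mean(lab == "orthograde"))
  expect_true(all(abs(frac - c(0.3, 0.5, 0.2)) < 0.1))
})
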
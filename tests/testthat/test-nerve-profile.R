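test_that("centerline delineation recovers simulated nerve geometry", {
  straight <- simulate_nerve_pair("uninjured", curved = FALSE, seed = 11)
  p <- delineate_centerline(straight$contra)
  truth <- straight$truth$truth$centerline
  expect_lt(sqrt(sum((p$points[1, ] - truth[1, ])^2)), 2)
  expect_lt(sqrt(sum((p$points[nrow(p$points), ] - truth[nrow(truth), ])^2)), 2)

  curved <- simulate_nerve_pair("uninjured", curved = TRUE, seed = 12)
  pc <- delineate_centerline(curved$contra)
  tc <- curved$truth$truth$centerline
  dev <- vapply(seq_len(nrow(pc$points)), function(i)
    min(sqrt((tc[, 1] - pc$points[i, 1])^2 + (tc[, 2] - pc$points[i, 2])^2)), 0)
  expect_lt(mean(dev), 1)
})

test_that("blank images yield a 'no nerve found' error", {
  blank <- image_grid(matrix(0, 64, 64))
  expect_error(delineate_centerline(blank), "no nerve found")
})

test_that("guide-point delineation follows the clicked polyline", {
  g <- cbind(c(10, 50, 100, 150), c(20, 25, 20, 15))
  img <- image_grid(matrix(1, 40, 160))
  p <- delineate_centerline(img, guide_points = g)
  expect_equal(p$points[1, ], c(x = 10, y = 20), tolerance = 1e-6)
  expect_equal(unname(p$points[nrow(p$points), ]), c(150, 15), tolerance = 1e-6)
})

test_that("profiles over a uniform nerve equal the uniform intensity", {
  px <- matrix(100, 64, 200)
  px[1:8, 1:8] <- 0                    # dark corner acting as background ROI
  img <- image_grid(px)
  path <- nerve_path(cbind(c(20, 180), c(40, 40)))
  dark <- roi_polygon(cbind(c(0, 6, 6, 0), c(0, 0, 6, 6)))
  prof <- extract_profile(img, path, n_bins = 20, background_roi = dark)
  expect_equal(prof$values, rep(100, 20), tolerance = 1e-9)
  # with the background taken from the image itself, the uniform level is
  # subtracted away
  prof0 <- extract_profile(img, path, n_bins = 20, background_quantile = 0.5)
  expect_equal(prof0$values, rep(0, 20), tolerance = 1e-9)
})

test_that("a step-intensity nerve produces a step profile", {
  sim <- simulate_nerve_pair("custom", proximal_amp = 1, distal_residual = 0.25,
                             regrowth_front = 0.5, crush_frac = 0.5,
                             read_sd = 1, seed = 21)
  prof <- extract_profile(sim$injured, sim$path_injured)
  fr <- (seq_len(100) - 0.5) / 100
  base <- mean(prof$values[fr < 0.45])
  expect_equal(mean(prof$values[fr > 0.55]) / base, 0.25, tolerance = 0.05)
})

test_that("profiles are consistent across bin resolutions", {
  sim <- simulate_nerve_pair("uninjured", seed = 22)
  p100 <- extract_profile(sim$contra, sim$path_contra, n_bins = 100)
  p200 <- extract_profile(sim$contra, sim$path_contra, n_bins = 200)
  f100 <- (seq_len(100) - 0.5) / 100
  f200 <- (seq_len(200) - 0.5) / 200
  interp <- approx(f200, p200$values, xout = f100, rule = 2)$y
  expect_equal(p100$values / mean(p100$values),
               interp / mean(interp), tolerance = 0.02)
})

test_that("relative profile identity, zero and residual-recovery cases", {
  sim <- simulate_nerve_pair("uninjured", seed = 23)
  p <- extract_profile(sim$contra, sim$path_contra)
  rel <- relative_profile(p, p)
  expect_true(all(abs(rel$ratios - 1) < 0.02))

  zeros <- p
  zeros$values <- rep(0, p$n_bins)
  expect_equal(relative_profile(zeros, p)$ratios, rep(0, p$n_bins))

  res <- simulate_nerve_pair("custom", proximal_amp = 1.5,
                             distal_residual = 0.10, regrowth_front = 0.5,
                             crush_frac = 0.5, seed = 24)
  rel1 <- relative_profile(extract_profile(res$injured, res$path_injured),
                           extract_profile(res$contra, res$path_contra))
  fr <- (seq_len(rel1$n_bins) - 0.5) / rel1$n_bins
  expect_true(abs(mean(rel1$ratios[fr > 0.65]) - 0.10) < 0.03)

  pb <- extract_profile(sim$contra, sim$path_contra, n_bins = 50)
  expect_error(relative_profile(p, pb), "mismatched")
})

test_that("profile metrics capture pile-up and recovery states", {
  ones <- structure(list(ratios = rep(1, 100), n_bins = 100L, epsilon = 0.1,
                         crush_frac = 0.5), class = "relative_profile")
  m <- profile_metrics(ones)
  expect_equal(m$proximal_index, 1)
  expect_equal(m$distal_index, 1)

  day1 <- simulate_nerve_pair("day1", seed = 25)
  rel <- relative_profile(extract_profile(day1$injured, day1$path_injured),
                          extract_profile(day1$contra, day1$path_contra))
  m1 <- profile_metrics(rel)
  expect_gte(m1$proximal_index, 2.5)
  expect_lte(m1$distal_index, 0.4)

  day7 <- simulate_nerve_pair("day7", seed = 26)
  rel7 <- relative_profile(extract_profile(day7$injured, day7$path_injured),
                           extract_profile(day7$contra, day7$path_contra))
  m7 <- profile_metrics(rel7)
  expect_true(m7$proximal_index >= 0.8 && m7$proximal_index <= 1.2)
  expect_true(m7$distal_index >= 0.8 && m7$distal_index <= 1.2)

  edge <- ones
  edge$crush_frac <- 0.001
  expect_error(profile_metrics(edge), "window")
})

test_that("relative profiles are invariant to multiplicative gain", {
  sim <- simulate_nerve_pair("day3", seed = 27)
  pi1 <- extract_profile(sim$injured, sim$path_injured, background_quantile = 0)
  pc1 <- extract_profile(sim$contra, sim$path_contra, background_quantile = 0)
  r1 <- relative_profile(pi1, pc1)
  gain <- function(img, k) { img$pixels <- img$pixels * k; img }
  pi2 <- extract_profile(gain(sim$injured, 3.7), sim$path_injured,
                         background_quantile = 0)
  pc2 <- extract_profile(gain(sim$contra, 3.7), sim$path_contra,
                         background_quantile = 0)
  r2 <- relative_profile(pi2, pc2)
  expect_equal(r1$ratios, r2$ratios, tolerance = 1e-6)
})

test_that("distal recovery is monotone in the regrowth front", {
  distal <- vapply(c(0.55, 0.7, 0.85, 1.0), function(front) {
    sim <- simulate_nerve_pair("custom", proximal_amp = 1.5,
                               distal_residual = 0.1, regrowth_front = front,
                               seed = 31)
    rel <- relative_profile(extract_profile(sim$injured, sim$path_injured),
                            extract_profile(sim$contra, sim$path_contra))
    profile_metrics(rel)$distal_index
  }, 0)
  expect_true(all(diff(distal) >= -0.02))
  expect_lt(distal[1], distal[4])
})

test_that("group averaging is per-animal then across animals", {
  rels <- lapply(1:3, function(s) {
    sim <- simulate_nerve_pair("day7", seed = 40 + s)
    relative_profile(extract_profile(sim$injured, sim$path_injured),
                     extract_profile(sim$contra, sim$path_contra))
  })
  avg <- average_profiles(rels)
  expect_equal(avg$n, 3)
  expect_length(avg$mean, 100)
  expect_equal(avg$mean, rowMeans(cbind(rels[[1]]$ratios, rels[[2]]$ratios,
                                        rels[[3]]$ratios)))
})
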
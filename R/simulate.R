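#' Ground truth attached to a simulated dataset
#'
#' Every generator returns its full parameterization and per-object truth
#' so that analysis results can be scored against what was simulated;
#' regeneration from (name, parameters, seed) is bit-identical.
#'
#' @param generator generator name.
#' @param params parameter list.
#' @param seed RNG seed used.
#' @param truth per-object truth (points, tracks, spectra, ...).
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(generator, params, seed, truth) {
  structure(list(generator = generator, params = params, seed = seed,
                 truth = truth), class = "synthetic_truth")
}

#' Write a synthetic truth record as JSON
#' @param truth a [synthetic_truth()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  ser <- list(generator = truth$generator, params = truth$params,
              seed = truth$seed,
              truth = lapply(truth$truth, function(x)
                if (is.matrix(x)) as.data.frame(x) else x))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

# Poisson shot noise + additive Gaussian read noise, clipped at 0
.apply_noise <- function(img, read_sd) {
  n <- length(img)
  noisy <- rpois(n, lambda = as.numeric(img)) + rnorm(n, sd = read_sd)
  matrix(pmax(noisy, 0), nrow(img), ncol(img))
}

# stamp a soft tube along dense centerline samples (max-accumulation
# approximates the distance-to-curve cross-section)
.render_tube <- function(canvas, pts, fracs, intensity, width_px) {
  w <- width_px / 2
  rad <- ceiling(2 * w)
  nr <- nrow(canvas); nc <- ncol(canvas)
  span <- -rad:rad
  for (i in seq_len(nrow(pts))) {
    cx <- pts[i, 1]; cy <- pts[i, 2]
    xs <- round(cx) + span; ys <- round(cy) + span
    okx <- xs >= 0 & xs <= nc - 1; oky <- ys >= 0 & ys <= nr - 1
    xs <- xs[okx]; ys <- ys[oky]
    if (!length(xs) || !length(ys)) next
    d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
    contrib <- intensity[i] * exp(-(d2 / w^2)^2)
    block <- canvas[ys + 1, xs + 1, drop = FALSE]
    canvas[ys + 1, xs + 1] <- pmax(block, contrib)
  }
  canvas
}

# additive 2-D Gaussian stamps (for punctate particles/somata)
.render_points <- function(canvas, x, y, amplitude, sigma_px) {
  rad <- ceiling(3 * sigma_px)
  nr <- nrow(canvas); nc <- ncol(canvas)
  span <- -rad:rad
  for (i in seq_along(x)) {
    xs <- round(x[i]) + span; ys <- round(y[i]) + span
    okx <- xs >= 0 & xs <= nc - 1; oky <- ys >= 0 & ys <= nr - 1
    xs <- xs[okx]; ys <- ys[oky]
    if (!length(xs) || !length(ys)) next
    d2 <- outer((ys - y[i])^2, (xs - x[i])^2, "+")
    canvas[ys + 1, xs + 1] <- canvas[ys + 1, xs + 1] +
      amplitude * exp(-d2 / (2 * sigma_px^2))
  }
  canvas
}

#' Simulate a paired injured/contralateral nerve image
#'
#' The contralateral nerve is a smooth fluorescent tube of baseline
#' intensity along a gently curved centerline. The injured nerve is the
#' same tube modulated by the degeneration/regeneration state: a proximal
#' pile-up bump (raised cosine peaking at `proximal_amp` over the arc
#' fractions `[crush_frac - 0.15, crush_frac)`), and a distal multiplier
#' that is 1 up to `regrowth_front` and `distal_residual` beyond it.
#' Named states reproduce the assay's time course: `day1 = (3.0, 0.3,
#' crush)`, `day3 = (2.0, 0.05, crush)`, `day7 = (1.1, 0.9, 1.0)`;
#' `uninjured` applies no modulation.
#'
#' @param state `"uninjured"`, `"day1"`, `"day3"`, `"day7"` or `"custom"`.
#' @param proximal_amp,distal_residual,regrowth_front custom-state
#'   parameters (ignored otherwise).
#' @param crush_frac crush-site arc fraction.
#' @param size image side, pixels (1 um/px).
#' @param width_px nerve tube width.
#' @param baseline tube intensity, counts.
#' @param offset camera background offset, counts.
#' @param read_sd Gaussian read-noise SD, counts.
#' @param curved use a sinusoidal (vs straight) centerline.
#' @param seed RNG seed.
#' @return List: `injured`, `contra` ([image_grid]s), `path_injured`,
#'   `path_contra` ([nerve_path]s), `truth` ([synthetic_truth()]).
#' @export
simulate_nerve_pair <- function(state = "day3", proximal_amp = NULL,
                                distal_residual = NULL, regrowth_front = NULL,
                                crush_frac = 0.5, size = 512, width_px = 10,
                                baseline = 2000, offset = 100, read_sd = 20,
                                curved = TRUE, seed = 1) {
  presets <- list(uninjured = c(1, 1, 1),
                  day1 = c(3.0, 0.3, crush_frac),
                  day3 = c(2.0, 0.05, crush_frac),
                  day7 = c(1.1, 0.9, 1.0))
  if (state == "custom") {
    if (is.null(proximal_amp) || is.null(distal_residual) ||
        is.null(regrowth_front))
      stop("custom state needs proximal_amp, distal_residual, regrowth_front")
  } else {
    p <- presets[[state]]
    if (is.null(p)) stop("unknown state: ", state)
    proximal_amp <- p[1]; distal_residual <- p[2]; regrowth_front <- p[3]
  }
  if (proximal_amp < 0 || distal_residual < 0)
    stop("amplitude and residual must be >= 0")
  set.seed(seed)
  margin <- 30
  xs <- seq(margin, size - margin, by = 0.5)
  ys <- if (curved) size / 2 + 0.12 * size * sin(2 * pi * (xs - margin) /
                                                   (size - 2 * margin))
  else rep(size / 2, length(xs))
  pts <- cbind(xs, ys)
  s <- c(0, cumsum(sqrt(rowSums((pts[-1, ] - pts[-nrow(pts), ])^2))))
  fr <- s / s[length(s)]
  modulation <- rep(1, length(fr))
  if (state != "uninjured") {
    bump <- fr >= crush_frac - 0.15 & fr < crush_frac
    modulation[bump] <- 1 + (proximal_amp - 1) *
      cos(pi / 2 * (crush_frac - fr[bump]) / 0.15)^2
    distal <- fr >= crush_frac
    modulation[distal] <- ifelse(fr[distal] <= regrowth_front, 1,
                                 distal_residual)
  }
  blank <- matrix(0, size, size)
  contra_sig <- .render_tube(blank, pts, fr, rep(baseline, length(fr)), width_px)
  inj_sig <- .render_tube(blank, pts, fr, baseline * modulation, width_px)
  contra <- image_grid(.apply_noise(offset + contra_sig, read_sd),
                       metadata = list(side = "contralateral"))
  injured <- image_grid(.apply_noise(offset + inj_sig, read_sd),
                        metadata = list(side = "injured"))
  cl <- pts[seq(1, nrow(pts), by = 4), , drop = FALSE]
  params <- list(state = state, proximal_amp = proximal_amp,
                 distal_residual = distal_residual,
                 regrowth_front = regrowth_front, crush_frac = crush_frac,
                 size = size, width_px = width_px, baseline = baseline,
                 offset = offset, read_sd = read_sd, curved = curved)
  list(injured = injured, contra = contra,
       path_injured = nerve_path(cl, crush_frac),
       path_contra = nerve_path(cl),
       truth = synthetic_truth("nerve_pair", params, seed,
                               list(centerline = cl)))
}

#' Simulate a tectum image pair with known innervation ratio
#'
#' Renders two tectal regions whose background-subtracted mean intensities
#' stand in ratio `innervation_ratio`, plus a signal-free background
#' region, with Poisson-Gaussian noise.
#'
#' @param innervation_ratio injured/contralateral signal ratio (>= 0).
#' @param size image side, pixels.
#' @param signal contralateral signal above background, counts.
#' @param offset background offset, counts.
#' @param read_sd read-noise SD.
#' @param seed RNG seed.
#' @return List: `image`, `rois` (named `injured`, `contra`, `background`),
#'   `truth`.
#' @export
simulate_tectum_pair <- function(innervation_ratio, size = 256, signal = 1000,
                                 offset = 100, read_sd = 10, seed = 1) {
  if (innervation_ratio < 0) stop("innervation_ratio must be >= 0")
  set.seed(seed)
  img <- matrix(offset, size, size)
  q <- size / 4
  inj <- roi_polygon(cbind(c(q - 30, q + 30, q + 30, q - 30),
                           c(q - 30, q - 30, q + 30, q + 30)), "injured")
  con <- roi_polygon(cbind(c(3 * q - 30, 3 * q + 30, 3 * q + 30, 3 * q - 30),
                           c(q - 30, q - 30, q + 30, q + 30)), "contra")
  bg <- roi_polygon(cbind(c(q - 30, q + 30, q + 30, q - 30),
                          c(3 * q - 30, 3 * q - 30, 3 * q + 30, 3 * q + 30)),
                    "background")
  img[(q - 30):(q + 30) + 1, (q - 30):(q + 30) + 1] <-
    offset + innervation_ratio * signal
  img[(q - 30):(q + 30) + 1, (3 * q - 30):(3 * q + 30) + 1] <- offset + signal
  img <- .apply_noise(img, read_sd)
  params <- list(innervation_ratio = innervation_ratio, size = size,
                 signal = signal, offset = offset, read_sd = read_sd)
  list(image = image_grid(img),
       rois = list(injured = inj, contra = con, background = bg),
       truth = synthetic_truth("tectum_pair", params, seed, list()))
}

#' Simulate a mitochondrial transport movie
#'
#' Particles are placed along a straight horizontal nerve segment and
#' rendered as 2-D Gaussians on a noisy background, 1 frame per `dt`
#' seconds. Stopped particles jitter in place (positional SD 0.2 um);
#' movers travel at a per-particle speed drawn from a truncated normal,
#' retrograde toward the eye (decreasing position), orthograde toward the
#' brain. Mover start positions are chosen so trajectories stay on the
#' path.
#'
#' @param n_particles number of mitochondria.
#' @param fractions length-3 vector (stopped, retrograde, orthograde)
#'   summing to 1.
#' @param velocity_params list with `retro_mean`, `retro_sd`, `ortho_mean`,
#'   `ortho_sd` (um/s).
#' @param dt_s seconds per frame.
#' @param n_frames frame count.
#' @param path_length_um nerve segment length.
#' @param amplitude particle peak intensity, counts.
#' @param snr amplitude / read-noise SD.
#' @param offset background offset.
#' @param min_sep_um hard-core exclusion between particles at t = 0.
#' @param seed RNG seed.
#' @return List: `stack` ([image_stack]), `path` ([nerve_path]), `truth`
#'   with per-particle class, speed and per-frame positions (um).
#' @export
simulate_mito_movie <- function(n_particles = 100,
                                fractions = c(0.5, 0.25, 0.25),
                                velocity_params = list(retro_mean = 0.4,
                                                       retro_sd = 0.1,
                                                       ortho_mean = 0.4,
                                                       ortho_sd = 0.1),
                                dt_s = 1, n_frames = 60,
                                path_length_um = 600, amplitude = 1000,
                                snr = 5, offset = 100, min_sep_um = 2,
                                seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (any(unlist(velocity_params) <= 0)) stop("velocities must be > 0")
  set.seed(seed)
  counts <- floor(fractions * n_particles)
  while (sum(counts) < n_particles)
    counts[which.max(fractions * n_particles - counts)] <-
    counts[which.max(fractions * n_particles - counts)] + 1
  classes <- rep(c("stopped", "retrograde", "orthograde"), counts)
  classes <- sample(classes)
  T_total <- (n_frames - 1) * dt_s
  rtnorm <- function(n, mean, sd) {
    v <- rnorm(n, mean, sd)
    while (any(v <= 0)) v[v <= 0] <- rnorm(sum(v <= 0), mean, sd)
    v
  }
  speed <- numeric(n_particles)
  speed[classes == "retrograde"] <- rtnorm(sum(classes == "retrograde"),
                                           velocity_params$retro_mean,
                                           velocity_params$retro_sd)
  speed[classes == "orthograde"] <- rtnorm(sum(classes == "orthograde"),
                                           velocity_params$ortho_mean,
                                           velocity_params$ortho_sd)
  # uniform placement with a hard-core exclusion at t = 0: mitochondria are
  # extended organelles (~1-2 um) and cannot overlap
  pos0 <- numeric(n_particles)
  for (i in seq_len(n_particles)) {
    travel <- speed[i] * T_total
    repeat {
      p <- switch(classes[i],
                  stopped = runif(1, 2, path_length_um - 2),
                  retrograde = runif(1, min(travel + 2, path_length_um - 2),
                                     path_length_um - 2),
                  orthograde = runif(1, 2,
                                     max(path_length_um - travel - 2, 2)))
      if (i == 1 || min(abs(pos0[seq_len(i - 1)] - p)) >= min_sep_um) break
    }
    pos0[i] <- p
  }
  times <- (seq_len(n_frames) - 1) * dt_s
  positions <- matrix(0, n_particles, n_frames)
  for (i in seq_len(n_particles)) {
    positions[i, ] <- if (classes[i] == "stopped")
      pos0[i] + rnorm(n_frames, sd = 0.2)
    else pos0[i] + ifelse(classes[i] == "retrograde", -1, 1) * speed[i] * times
  }
  positions <- pmin(pmax(positions, 0), path_length_um)
  margin <- 10
  height <- 40
  width <- path_length_um + 2 * margin
  read_sd <- amplitude / snr
  frames <- lapply(seq_len(n_frames), function(t) {
    canvas <- matrix(0, height, width)
    canvas <- .render_points(canvas, margin + positions[, t],
                             rep(height / 2, n_particles), amplitude, 1.5)
    image_grid(.apply_noise(offset + canvas, read_sd))
  })
  path <- nerve_path(cbind(c(margin, margin + path_length_um),
                           c(height / 2, height / 2)))
  params <- list(n_particles = n_particles, fractions = fractions,
                 velocity_params = velocity_params, dt_s = dt_s,
                 n_frames = n_frames, path_length_um = path_length_um,
                 amplitude = amplitude, snr = snr, offset = offset,
                 min_sep_um = min_sep_um)
  list(stack = image_stack(frames, dt_s), path = path,
       truth = synthetic_truth("mito_movie", params, seed,
                               list(class = classes, speed = speed,
                                    positions = positions)))
}

#' Simulate paired control/edited Sanger traces
#'
#' The control trace is a clean one-hot channel signal over a random
#' reference sequence. The edited trace is the frequency-weighted mixture
#' of allele sequences: a deletion of `d` removes `d` bases at the cut; an
#' insertion of `i` inserts `i` random bases. Gaussian peak noise is added
#' to both traces.
#'
#' @param spectrum named numeric vector, indel size -> frequency (must sum
#'   to 1; `"0"` is the unedited fraction).
#' @param cut_site cut position within the trace.
#' @param trace_length number of base calls.
#' @param peak_height clean channel peak height.
#' @param noise_sd Gaussian peak noise SD as a fraction of `peak_height`.
#' @param seed RNG seed.
#' @return List: `control`, `edited` ([trace_signal]s), `truth` (includes
#'   the reference sequence).
#' @export
simulate_sanger_traces <- function(spectrum = c("0" = 1), cut_site = 100,
                                   trace_length = 220, peak_height = 1000,
                                   noise_sd = 0, seed = 1) {
  f <- as.numeric(spectrum)
  sizes <- as.integer(names(spectrum))
  if (anyNA(sizes)) stop("spectrum must be named by signed indel size")
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
    stop("spectrum must be a probability vector")
  if (any(abs(sizes) > 60)) stop("indel sizes must be within +/- 60")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  need <- trace_length + max(0, -min(sizes)) + 5
  ref <- sample(bases, need, replace = TRUE)
  onehot <- function(seq_chr, n) {
    m <- matrix(0, n, 4, dimnames = list(NULL, bases))
    idx <- match(seq_chr[seq_len(n)], bases)
    m[cbind(seq_len(n), idx)] <- 1
    m
  }
  control_clean <- peak_height * onehot(ref, trace_length)
  edited_clean <- matrix(0, trace_length, 4)
  for (k in seq_along(sizes)) {
    s <- sizes[k]
    seq_k <- if (s == 0) ref
    else if (s < 0) c(ref[seq_len(cut_site)], ref[(cut_site + 1 - s):need])
    else c(ref[seq_len(cut_site)], sample(bases, s, replace = TRUE),
           ref[(cut_site + 1):need])
    edited_clean <- edited_clean + f[k] * peak_height * onehot(seq_k, trace_length)
  }
  addnoise <- function(m) pmax(m + rnorm(length(m), sd = noise_sd * peak_height), 0)
  params <- list(spectrum = as.list(setNames(f, sizes)), cut_site = cut_site,
                 trace_length = trace_length, peak_height = peak_height,
                 noise_sd = noise_sd)
  list(control = trace_signal(addnoise(control_clean), cut_site, "control"),
       edited = trace_signal(addnoise(edited_clean), cut_site, "edited"),
       truth = synthetic_truth("sanger_traces", params, seed,
                               list(reference = paste(ref, collapse = ""))))
}

#' Simulate a retinal flatmount point field
#'
#' Somata are placed uniformly on a disc-shaped retina, inside
#' (`n_central`) and outside (`n_peripheral`) a circular birth-date ring,
#' with a minimum mutual separation, and rendered as 2-D Gaussians with
#' Poisson-Gaussian noise. An optional second channel marks a random
#' `stain_fraction` subset of the somata.
#'
#' @param n_central,n_peripheral soma counts inside/outside the ring.
#' @param ring_radius_frac ring radius as a fraction of the retina radius.
#' @param stain_fraction fraction of somata marked in the stain channel.
#' @param size image side, pixels (1 um/px).
#' @param amplitude soma peak intensity.
#' @param snr amplitude / read-noise SD.
#' @param offset background offset.
#' @param min_sep_px minimum soma separation.
#' @param sigma_px soma Gaussian sigma.
#' @param seed RNG seed.
#' @return List: `image`, `stain` (or `NULL`), `ring` ([roi_polygon]),
#'   `truth` with per-soma coordinates, region and stain flag.
#' @export
simulate_flatmount <- function(n_central = 300, n_peripheral = 200,
                               ring_radius_frac = 0.6, stain_fraction = 0,
                               size = 512, amplitude = 1000, snr = 5,
                               offset = 100, min_sep_px = 6, sigma_px = 2,
                               seed = 1) {
  if (n_central < 0 || n_peripheral < 0) stop("counts must be >= 0")
  if (ring_radius_frac <= 0 || ring_radius_frac >= 1)
    stop("ring_radius_frac must lie in (0, 1)")
  n_total <- n_central + n_peripheral
  R <- 0.45 * size
  # soma footprint approximated as a disc of 1.5 sigma
  if (n_total * pi * (1.5 * sigma_px)^2 > 0.1 * pi * R^2)
    stop("soma density exceeds 10% area coverage")
  set.seed(seed)
  cx <- size / 2; cy <- size / 2
  ring_r <- ring_radius_frac * R
  draw <- function(n, r_lo, r_hi) {
    xs <- numeric(0); ys <- numeric(0)
    guard <- 0
    while (length(xs) < n) {
      r <- sqrt(runif(1, r_lo^2, r_hi^2))
      th <- runif(1, 0, 2 * pi)
      x <- cx + r * cos(th); y <- cy + r * sin(th)
      if (!length(xs) || min((xs - x)^2 + (ys - y)^2) >= min_sep_px^2) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
      guard <- guard + 1
      if (guard > 200 * n) stop("could not place somata at this density")
    }
    cbind(xs, ys)
  }
  # central points stay clear of the ring so the partition truth is unambiguous
  pc <- if (n_central) draw(n_central, 0, ring_r - min_sep_px) else
    matrix(0, 0, 2)
  pp <- if (n_peripheral) draw(n_peripheral, ring_r + min_sep_px, R) else
    matrix(0, 0, 2)
  all_pts <- rbind(pc, pp)
  region <- rep(c("central", "peripheral"), c(n_central, n_peripheral))
  canvas <- .render_points(matrix(0, size, size), all_pts[, 1], all_pts[, 2],
                           amplitude, sigma_px)
  read_sd <- amplitude / snr
  image <- image_grid(.apply_noise(offset + canvas, read_sd))
  stained <- rep(FALSE, n_total)
  stain <- NULL
  if (stain_fraction > 0) {
    stained[sample.int(n_total, round(stain_fraction * n_total))] <- TRUE
    sc <- .render_points(matrix(0, size, size), all_pts[stained, 1],
                         all_pts[stained, 2], amplitude, sigma_px)
    stain <- image_grid(.apply_noise(offset + sc, read_sd))
  }
  theta <- seq(0, 2 * pi, length.out = 65)[-65]
  ring <- roi_polygon(cbind(cx + ring_r * cos(theta), cy + ring_r * sin(theta)),
                      "birthdate_ring")
  params <- list(n_central = n_central, n_peripheral = n_peripheral,
                 ring_radius_frac = ring_radius_frac,
                 stain_fraction = stain_fraction, size = size,
                 amplitude = amplitude, snr = snr, offset = offset,
                 min_sep_px = min_sep_px, sigma_px = sigma_px)
  list(image = image, stain = stain, ring = ring,
       truth = synthetic_truth("flatmount", params, seed,
                               list(x = all_pts[, 1], y = all_pts[, 2],
                                    region = region, stained = stained)))
}

#' Simulate a behavior cohort
#'
#' Draws per-animal trial outcomes from per-session response
#' probabilities.
#'
#' @param n_animals animals per group.
#' @param session_probs named numeric vector: session label -> response
#'   probability.
#' @param n_trials trials per session.
#' @param group group label.
#' @param seed RNG seed.
#' @return List: `records` (list of [behavior_record()]), `truth`.
#' @export
simulate_behavior_cohort <- function(n_animals = 10,
                                     session_probs = c(pre = 0.7, day3 = 0.0),
                                     n_trials = 10, group = "all", seed = 1) {
  set.seed(seed)
  records <- list()
  for (a in seq_len(n_animals))
    for (s in names(session_probs))
      records[[length(records) + 1]] <- behavior_record(
        sprintf("%s_%02d", group, a), s,
        runif(n_trials) < session_probs[[s]], group)
  params <- list(n_animals = n_animals,
                 session_probs = as.list(session_probs),
                 n_trials = n_trials, group = group)
  list(records = records,
       truth = synthetic_truth("behavior_cohort", params, seed, list()))
}
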
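#' Build a kymograph from a transport movie
#'
#' Collapses each frame of a time-lapse stack onto a nerve path: entry
#' `(t, s)` is the maximum intensity over the perpendicular segment of
#' half-width `half_width_um` at arc-length station `s` in frame `t`.
#' Maximum (rather than mean) projection preserves punctate particles.
#' Station 1 is the eye/proximal end of the path, so increasing position
#' means motion toward the brain.
#'
#' @param stack an [image_stack].
#' @param path a [nerve_path] lying within every frame.
#' @param half_width_um perpendicular half-width in micrometers.
#' @param n_stations number of arc-length stations; default one per pixel
#'   of path length.
#' @return An object of class `kymograph` with fields `grid` (time rows x
#'   station columns), `dt_s`, `dx_um`.
#' @export
build_kymograph <- function(stack, path, half_width_um = 3, n_stations = NULL) {
  px_size <- stack$frames[[1]]$pixel_size_um
  len_um <- path_length(path) * px_size
  if (is.null(n_stations)) n_stations <- max(2L, round(len_um / px_size))
  fracs <- (seq_len(n_stations) - 0.5) / n_stations
  st <- .path_stations(path, fracs)
  d <- dim(stack$frames[[1]]$pixels)
  if (any(st$x < 0 | st$x > d[2] - 1 | st$y < 0 | st$y > d[1] - 1))
    stop("path exits frame bounds")
  hw_px <- half_width_um / px_size
  offs <- seq(-hw_px, hw_px, by = 0.5)
  xs <- as.numeric(outer(st$x, rep(1, length(offs))) + outer(-st$ty, offs))
  ys <- as.numeric(outer(st$y, rep(1, length(offs))) + outer(st$tx, offs))
  grid <- t(vapply(stack$frames, function(f) {
    v <- matrix(.interp_bilinear(f$pixels, xs, ys), nrow = n_stations)
    apply(v, 1, max, na.rm = TRUE)
  }, numeric(n_stations)))
  structure(list(grid = grid, dt_s = stack$dt_s, dx_um = len_um / n_stations),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d stations, dt %g s, dx %.3g um\n",
              nrow(x$grid), ncol(x$grid), x$dt_s, x$dx_um))
  invisible(x)
}

# topographic prominence of a local maximum: height above the higher of the
# two valleys separating it from the nearest taller ground on each side
.peak_prominence <- function(row, s) {
  n <- length(row)
  left_min <- row[s]; i <- s
  while (i > 1) {
    i <- i - 1
    if (row[i] > row[s]) break
    if (row[i] < left_min) left_min <- row[i]
  }
  right_min <- row[s]; i <- s
  while (i < n) {
    i <- i + 1
    if (row[i] > row[s]) break
    if (row[i] < right_min) right_min <- row[i]
  }
  row[s] - max(left_min, right_min)
}

# sub-pixel local maxima of one kymograph row: prominence filtering (rejects
# noise shoulders on blob flanks), 3-point parabolic refinement, greedy
# minimum-separation suppression by descending intensity
.row_peaks <- function(row, threshold, min_sep_cols, min_prominence = 0) {
  n <- length(row)
  if (n < 3) return(numeric(0))
  cand <- which(row[2:(n - 1)] >= row[1:(n - 2)] &
                  row[2:(n - 1)] >= row[3:n] &
                  row[2:(n - 1)] > threshold) + 1
  if (!length(cand)) return(numeric(0))
  if (min_prominence > 0)
    cand <- cand[vapply(cand, function(s) .peak_prominence(row, s),
                        0) >= min_prominence]
  if (!length(cand)) return(numeric(0))
  cand <- cand[order(row[cand], decreasing = TRUE)]
  kept <- numeric(0)
  for (s in cand)
    if (!length(kept) || min(abs(kept - s)) >= min_sep_cols) kept <- c(kept, s)
  vapply(kept, function(s) {
    denom <- row[s - 1] - 2 * row[s] + row[s + 1]
    delta <- if (denom >= 0) 0 else 0.5 * (row[s - 1] - row[s + 1]) / denom
    s + max(min(delta, 0.5), -0.5)
  }, 0)
}

#' Detect mitochondrial tracks on a kymograph
#'
#' The kymograph is first denoised with a small 2-D Gaussian (matched
#' roughly to the particle size). Per time row, 1-D local maxima above an
#' intensity threshold with a minimum mutual separation are localized to
#' sub-pixel accuracy and linked frame-to-frame by nearest neighbor within
#' a velocity gate `v_max * dt`. Detection gaps of up to `max_gap` frames
#' are bridged by linear interpolation; tracks shorter than
#' `min_track_len` samples are discarded. Linked positions are lightly
#' smoothed (3-sample moving average) to suppress localization jitter.
#'
#' The default threshold is robust to dense particle fields: background
#' level is the 5th percentile of the denoised kymograph and the noise
#' scale is estimated from frame-to-frame differences, which are signal-
#' free for slowly moving punctae.
#'
#' @param kymo a [build_kymograph()] result.
#' @param intensity_threshold absolute peak threshold; default background
#'   + `k_mad` noise SDs (see Details).
#' @param k_mad threshold scale when `intensity_threshold` is `NULL`.
#' @param smooth_sigma_px Gaussian denoising sigma, kymograph pixels.
#' @param min_sep_um minimum peak separation (should be at least the
#'   apparent particle diameter, or noise shoulders split punctae).
#' @param v_max_um_s linking gate velocity.
#' @param max_gap bridgeable gap, frames.
#' @param min_track_len minimum samples per track.
#' @return List of unlabeled `mito_track` objects, each with a `samples`
#'   data.frame (`frame`, `position_um`), `n_samples` and `dt_s`.
#' @export
detect_tracks <- function(kymo, intensity_threshold = NULL, k_mad = 4,
                          smooth_sigma_px = 0.8, min_sep_um = 2,
                          v_max_um_s = 2, max_gap = 2, min_track_len = 10) {
  g <- kymo$grid
  if (smooth_sigma_px > 0) g <- as.matrix(EBImage::gblur(g, sigma = smooth_sigma_px))
  noise_sd <- mad(as.numeric(diff(g))) / sqrt(2)
  bg <- quantile(g, 0.05)
  # floor at 5% of the dynamic range so noise-free data do not admit
  # arbitrarily faint blob tails as peaks
  floor_amp <- 0.05 * (max(g) - bg)
  if (is.null(intensity_threshold))
    intensity_threshold <- bg + max(k_mad * noise_sd, floor_amp)
  min_prom <- max(3 * noise_sd, floor_amp)
  min_sep_cols <- max(1, min_sep_um / kymo$dx_um)
  active <- list()   # each: list(frames, pos_cols, last_frame)
  done <- list()
  for (t in seq_len(nrow(g))) {
    peaks <- .row_peaks(g[t, ], intensity_threshold, min_sep_cols, min_prom)
    # retire stale tracks
    if (length(active)) {
      stale <- vapply(active, function(a) t - a$last_frame > max_gap + 1, TRUE)
      done <- c(done, active[stale])
      active <- active[!stale]
    }
    assigned_peak <- rep(FALSE, length(peaks))
    if (length(active) && length(peaks)) {
      last_frm <- vapply(active, function(a) a$last_frame, 0)
      # constant-velocity prediction (slope over the last <= 5 samples)
      # keeps identities through crossings
      pred_pos <- vapply(seq_along(active), function(i) {
        a <- active[[i]]
        k <- length(a$pos)
        vel <- if (k >= 3) {
          j <- max(1, k - 4)
          (a$pos[k] - a$pos[j]) / (a$frames[k] - a$frames[j])
        } else 0
        a$pos[k] + vel * (t - a$last_frame)
      }, 0)
      cand <- expand.grid(tr = seq_along(active), pk = seq_along(peaks))
      cand$dist <- abs(pred_pos[cand$tr] - peaks[cand$pk]) * kymo$dx_um
      gate <- v_max_um_s * kymo$dt_s * (t - last_frm[cand$tr])
      cand <- cand[cand$dist <= gate, , drop = FALSE]
      cand <- cand[order(cand$dist), , drop = FALSE]
      used_tr <- rep(FALSE, length(active))
      for (i in seq_len(nrow(cand))) {
        tr <- cand$tr[i]; pk <- cand$pk[i]
        if (used_tr[tr] || assigned_peak[pk]) next
        used_tr[tr] <- TRUE; assigned_peak[pk] <- TRUE
        a <- active[[tr]]
        a$frames <- c(a$frames, t); a$pos <- c(a$pos, peaks[pk])
        a$last_frame <- t
        active[[tr]] <- a
      }
    }
    for (pk in which(!assigned_peak))
      active[[length(active) + 1]] <- list(frames = t, pos = peaks[pk],
                                           last_frame = t)
  }
  done <- c(done, active)
  tracks <- lapply(done, function(a) {
    if (length(a$frames) < 2) return(NULL)
    frames <- a$frames[1]:a$frames[length(a$frames)]
    pos <- approx(a$frames, a$pos, xout = frames)$y
    if (length(pos) >= 5) {
      n <- length(pos)
      pos <- vapply(seq_len(n), function(i)
        mean(pos[max(1, i - 2):min(n, i + 2)]), 0)
    }
    structure(list(
      samples = data.frame(frame = frames, position_um = pos * kymo$dx_um),
      label = NA_character_, n_samples = length(frames), dt_s = kymo$dt_s),
      class = "mito_track")
  })
  tracks <- Filter(Negate(is.null), tracks)
  # occlusions are flagged against every linked segment, including short
  # fragments that are then dropped by the length filter; occluded runs at
  # track ends are unreliable (merged-peak drift) and are trimmed
  tracks <- .flag_occlusions(tracks, nrow(g), min_sep_um, extend = 8)
  tracks <- lapply(tracks, function(tr) {
    occ <- tr$samples$occluded
    keep <- which(!occ)
    if (!length(keep)) return(NULL)
    tr$samples <- tr$samples[min(keep):max(keep), , drop = FALSE]
    tr$n_samples <- nrow(tr$samples)
    tr
  })
  tracks <- Filter(Negate(is.null), tracks)
  Filter(function(tr) tr$n_samples >= min_track_len, tracks)
}

# mark samples where another track sits within the resolution limit; each
# track is extrapolated `extend` frames beyond its lifespan at its boundary
# velocity, so merge windows around crossings (where the partner's own
# peaks are suppressed) stay covered
.flag_occlusions <- function(tracks, n_frames, min_sep_um, extend = 8) {
  n <- length(tracks)
  if (n == 0) return(tracks)
  P <- matrix(NA_real_, n, n_frames)
  for (i in seq_len(n)) {
    s <- tracks[[i]]$samples
    m <- nrow(s)
    f0 <- max(1, s$frame[1] - extend)
    f1 <- min(n_frames, s$frame[m] + extend)
    pos <- approx(s$frame, s$position_um, xout = f0:f1)$y
    j <- max(1, m - 4)
    v_tail <- if (m >= 3) (s$position_um[m] - s$position_um[j]) /
      (s$frame[m] - s$frame[j]) else 0
    j <- min(m, 5)
    v_head <- if (m >= 3) (s$position_um[j] - s$position_um[1]) /
      (s$frame[j] - s$frame[1]) else 0
    fr <- f0:f1
    before <- fr < s$frame[1]
    after <- fr > s$frame[m]
    pos[before] <- s$position_um[1] + v_head * (fr[before] - s$frame[1])
    pos[after] <- s$position_um[m] + v_tail * (fr[after] - s$frame[m])
    P[i, fr] <- pos
  }
  for (i in seq_len(n)) {
    s <- tracks[[i]]$samples
    occ <- vapply(seq_len(nrow(s)), function(k) {
      others <- P[-i, s$frame[k]]
      any(abs(others - s$position_um[k]) < min_sep_um, na.rm = TRUE)
    }, TRUE)
    tracks[[i]]$samples$occluded <- occ
  }
  tracks
}

#' Classify a track as stopped, retrograde or orthograde
#'
#' Net displacement is last minus first position; positive means motion
#' toward the brain. `|net| < d_stop_um` is stopped; negative net is
#' retrograde (brain to eye/soma); positive net is orthograde.
#'
#' @param track a `mito_track`.
#' @param d_stop_um net-displacement threshold for "stopped".
#' @return The track with `label` and `net_displacement_um` set.
#' @export
classify_track <- function(track, d_stop_um = 2) {
  pos <- track$samples$position_um
  net <- pos[length(pos)] - pos[1]
  track$net_displacement_um <- net
  track$label <- if (abs(net) < d_stop_um) "stopped"
  else if (net < 0) "retrograde" else "orthograde"
  track
}

#' Pause-excluded mean track speed
#'
#' Mean over consecutive-sample speeds `|dx|/dt`, restricted to intervals
#' moving faster than `pause_speed_um_s`, so a particle that pauses
#' mid-run reports the speed of its moving phase. Intervals flagged as
#' occluded by [detect_tracks()] (another particle within the resolution
#' limit, where the merged peak drags the position estimate) are excluded
#' when unoccluded intervals exist.
#'
#' @param track a labeled, moving `mito_track`.
#' @param pause_speed_um_s speeds at or below this are treated as pauses.
#' @return Mean speed in micrometers per second.
#' @export
track_velocity <- function(track, pause_speed_um_s = 0.05) {
  if (is.na(track$label) || track$label == "stopped")
    stop("track_velocity is defined only for moving (labeled) tracks")
  s <- track$samples
  sp <- abs(diff(s$position_um)) / (diff(s$frame) * track$dt_s)
  keep <- rep(TRUE, length(sp))
  # the detector's position smoothing has one-sided windows at track ends,
  # which lags the first/last two intervals; drop them when enough remain
  if (length(sp) >= 9) keep[c(1, 2, length(sp) - 1, length(sp))] <- FALSE
  if (!is.null(s$occluded)) {
    clean <- !(s$occluded[-1] | s$occluded[-nrow(s)])
    if (any(clean & keep)) keep <- clean & keep
    else if (any(clean)) keep <- clean
  }
  sp <- sp[keep]
  moving <- sp > pause_speed_um_s
  if (!any(moving)) return(0)
  mean(sp[moving])
}

#' Motility summary across nerves and groups
#'
#' The nerve is the replication unit: per-nerve motility fractions are
#' computed first, then averaged (mean, SD) within each group. Per-class
#' velocity statistics pool moving tracks across the group's nerves.
#'
#' @param nerve_tracks named list; each element is the list of labeled
#'   tracks from one nerve.
#' @param groups character vector, one group label per nerve (default: one
#'   group).
#' @return A list of per-group summaries of class `motility_summary`, each
#'   with `fractions` (mean and sd per class), `velocity` (mean, sd, n per
#'   moving class), `N_nerves`, `n_mitochondria`.
#' @export
motility_summary <- function(nerve_tracks, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(nerve_tracks))
  classes <- c("stopped", "retrograde", "orthograde")
  out <- list()
  for (grp in unique(groups)) {
    nerves <- nerve_tracks[groups == grp]
    if (any(vapply(nerves, length, 0L) == 0))
      stop("group '", grp, "' contains a nerve with zero tracks")
    frac <- t(vapply(nerves, function(trks) {
      lab <- vapply(trks, function(tr) tr$label, "")
      cnt <- vapply(classes, function(cl) sum(lab == cl), 0L)
      cnt / sum(cnt)
    }, numeric(3)))
    colnames(frac) <- classes
    vel <- lapply(c("retrograde", "orthograde"), function(cl) {
      v <- unlist(lapply(nerves, function(trks)
        vapply(Filter(function(tr) tr$label == cl, trks),
               track_velocity, 0)))
      list(mean = if (length(v)) mean(v) else NA_real_,
           sd = if (length(v) > 1) sd(v) else NA_real_, n = length(v))
    })
    names(vel) <- c("retrograde", "orthograde")
    out[[grp]] <- structure(list(
      fractions = list(mean = colMeans(frac),
                       sd = if (nrow(frac) > 1) apply(frac, 2, sd)
                       else setNames(rep(NA_real_, 3), classes)),
      velocity = vel, N_nerves = length(nerves),
      n_mitochondria = sum(vapply(nerves, length, 0L))),
      class = "motility_summary")
  }
  out
}

#' @export
print.motility_summary <- function(x, ...) {
  f <- x$fractions$mean
  cat(sprintf(
    "<motility_summary> N = %d nerves, n = %d mitochondria\n  stopped %.2f, retrograde %.2f, orthograde %.2f\n",
    x$N_nerves, x$n_mitochondria, f["stopped"], f["retrograde"],
    f["orthograde"]))
  invisible(x)
}
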
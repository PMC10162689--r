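#' Delineate the optic nerve centerline
#'
#' With `guide_points`, returns a smoothed spline interpolation through the
#' user-clicked polyline (orientation preserved: the first guide point is the
#' eye/proximal end). Without guide points, the image is Gaussian-smoothed,
#' Otsu-thresholded, the largest connected component is skeletonized by
#' morphological thinning, and the path is the longest geodesic of the
#' skeleton. Orientation is then fixed so that index 1 is the eye end:
#' `eye_end` may be `"left"`/`"right"`/`"top"`/`"bottom"` or an `(x, y)`
#' point; images whose metadata carries an `eye_end` entry use it as default.
#'
#' @param image an [image_grid] containing a single elongated fluorescent
#'   structure (ignored for geometry when `guide_points` is given).
#' @param guide_points optional matrix of (x, y) guide vertices.
#' @param crush_frac optional crush-site arc-length fraction to attach.
#' @param eye_end orientation hint (see Details).
#' @param smooth_sigma_px Gaussian smoothing sigma before thresholding.
#' @param min_skeleton_px shortest admissible centerline, in pixels.
#' @return A [nerve_path].
#' @export
delineate_centerline <- function(image, guide_points = NULL,
                                 crush_frac = NA_real_, eye_end = NULL,
                                 smooth_sigma_px = 2, min_skeleton_px = 20) {
  if (is.null(eye_end))
    eye_end <- if (!is.null(image$metadata$eye_end)) image$metadata$eye_end else "left"
  if (!is.null(guide_points)) {
    g <- as.matrix(guide_points)[, 1:2, drop = FALSE]
    if (nrow(g) < 2) stop("need at least 2 guide points")
    s <- c(0, cumsum(sqrt(rowSums((g[-1, , drop = FALSE] -
                                     g[-nrow(g), , drop = FALSE])^2))))
    n_out <- max(50, ceiling(s[length(s)]))
    so <- seq(0, s[length(s)], length.out = n_out)
    if (nrow(g) > 3) {
      xs <- spline(s, g[, 1], xout = so)$y
      ys <- spline(s, g[, 2], xout = so)$y
    } else {
      xs <- approx(s, g[, 1], xout = so)$y
      ys <- approx(s, g[, 2], xout = so)$y
    }
    return(nerve_path(.dedupe_path(cbind(xs, ys)), crush_frac))
  }

  px <- image$pixels
  rng <- range(px)
  if (diff(rng) <= 0) stop("no nerve found: image is constant")
  norm <- (px - rng[1]) / diff(rng)
  sm <- EBImage::gblur(norm, sigma = smooth_sigma_px)
  sm <- pmin(pmax(sm, 0), 1)
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  mask <- sm > thr
  if (!any(mask)) stop("no nerve found: nothing above threshold")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  tab <- tabulate(as.integer(lab[lab > 0]))
  mask <- matrix(as.integer(lab) == which.max(tab), nrow(px), ncol(px))
  skel <- .thin_zhang_suen(mask)
  pathpx <- .longest_geodesic(skel)
  if (is.null(pathpx) || nrow(pathpx) < 2)
    stop("no nerve found: skeleton empty")
  # thinning retracts the ridge about half a half-width from the tube tip;
  # extend both ends along the local tangent by that amount
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  extend_end <- function(p, tail_end) {
    n <- nrow(p)
    if (tail_end) p <- p[n:1, , drop = FALSE]
    k <- min(6, nrow(p))
    tangent <- p[1, ] - p[k, ]
    tangent <- tangent / sqrt(sum(tangent^2))
    hw <- dm[round(p[1, 2]) + 1, round(p[1, 1]) + 1]
    ext <- p[1, ] + tangent * 0.5 * hw
    out <- rbind(ext, p)
    if (tail_end) out[nrow(out):1, , drop = FALSE] else out
  }
  pathpx <- extend_end(extend_end(pathpx, FALSE), TRUE)
  pts <- .smooth_path(pathpx, window = 5)
  pp <- nerve_path(.dedupe_path(pts), crush_frac)
  if (path_length(pp) < min_skeleton_px)
    stop("skeleton shorter than minimum length (", min_skeleton_px, " px)")
  .orient_path(pp, eye_end)
}

.dedupe_path <- function(p) {
  keep <- c(TRUE, rowSums(abs(p[-1, , drop = FALSE] -
                                p[-nrow(p), , drop = FALSE])) > 1e-12)
  p[keep, , drop = FALSE]
}

.smooth_path <- function(p, window = 5) {
  if (nrow(p) <= window) return(p)
  k <- rep(1 / window, window)
  pad <- (window - 1) / 2
  smooth1 <- function(v) {
    vv <- c(rep(v[1], pad), v, rep(v[length(v)], pad))
    as.numeric(stats::filter(vv, k, sides = 2))[(pad + 1):(pad + length(v))]
  }
  cbind(smooth1(p[, 1]), smooth1(p[, 2]))
}

.orient_path <- function(path, eye_end) {
  p <- path$points
  first <- p[1, ]; last <- p[nrow(p), ]
  flip <- if (is.character(eye_end)) {
    switch(eye_end,
           left = first[1] > last[1], right = first[1] < last[1],
           top = first[2] > last[2], bottom = first[2] < last[2],
           stop("unknown eye_end: ", eye_end))
  } else {
    e <- as.numeric(eye_end)
    sum((first - e)^2) > sum((last - e)^2)
  }
  if (flip) nerve_path(p[nrow(p):1, , drop = FALSE], path$crush_frac) else path
}

# Zhang-Suen binary thinning; mask is a logical matrix [y, x]
.thin_zhang_suen <- function(mask) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  sh <- function(a, dy, dx)
    a[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- sh(pad, -1, 0); p3 <- sh(pad, -1, 1); p4 <- sh(pad, 0, 1)
      p5 <- sh(pad, 1, 1);  p6 <- sh(pad, 1, 0);  p7 <- sh(pad, 1, -1)
      p8 <- sh(pad, 0, -1); p9 <- sh(pad, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, nr, nc)
      for (i in 1:8) a <- a + (!seqs[[i]] & seqs[[i + 1]])
      core <- pad[2:(nr + 1), 2:(nc + 1)]
      cond <- core & b >= 2 & b <= 6 & a == 1
      if (step == 1) {
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        changed <- TRUE
        core[cond] <- FALSE
        pad[2:(nr + 1), 2:(nc + 1)] <- core
      }
    }
    if (!changed) break
  }
  pad[2:(nr + 1), 2:(nc + 1)]
}

# ordered (x, y) pixel chain along the longest geodesic of a skeleton
.longest_geodesic <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)  # row = y+1, col = x+1
  if (nrow(idx) < 2) return(NULL)
  n <- nrow(idx)
  key <- (idx[, 1] - 1) + (idx[, 2] - 1) * nrow(skel)
  lookup <- seq_len(n)
  names(lookup) <- as.character(key)
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    ny <- idx[, 1] + offs$dy[k]; nx <- idx[, 2] + offs$dx[k]
    nkey <- as.character((ny - 1) + (nx - 1) * nrow(skel))
    hit <- nkey %in% names(lookup) & ny >= 1 & ny <= nrow(skel) &
      nx >= 1 & nx <= ncol(skel)
    if (any(hit)) {
      from <- c(from, lookup[as.character(key[hit])])
      to <- c(to, lookup[nkey[hit]])
      w <- c(w, rep(sqrt(offs$dy[k]^2 + offs$dx[k]^2), sum(hit)))
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  g <- igraph::simplify(g, edge.attr.comb = "first")
  comp <- igraph::components(g)
  main <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(g, main)
  deg <- igraph::degree(sub)
  ends <- if (any(deg == 1)) which(deg == 1) else seq_along(deg)
  # double sweep: farthest node from an arbitrary end, then farthest from it
  d1 <- igraph::distances(sub, v = ends[1])
  a <- which.max(d1)
  d2 <- igraph::distances(sub, v = a)
  b <- which.max(d2)
  vp <- igraph::shortest_paths(sub, from = a, to = b)$vpath[[1]]
  ids <- as.integer(igraph::V(sub)$name[as.integer(vp)])
  cbind(x = idx[ids, 2] - 1, y = idx[ids, 1] - 1)
}

#' Extract an equal-arc-length fluorescence profile along a nerve
#'
#' At each of `n_bins` equally spaced arc-length stations (bin centers of
#' half-open bins, last bin closed), the value is the mean intensity over
#' the perpendicular segment of half-width `half_width_um`, minus the
#' background (mean of `background_roi` if given, otherwise the image's
#' 5th-percentile intensity), clipped at zero.
#'
#' @param image an [image_grid].
#' @param path a [nerve_path] within the image bounds.
#' @param n_bins number of arc-length bins (>= 10).
#' @param half_width_um perpendicular sampling half-width in micrometers.
#' @param background_roi optional [roi_polygon] for background estimation.
#' @param background_quantile fallback background quantile.
#' @return An object of class `nerve_profile` with fields `values`,
#'   `n_bins`, `background`, `length_um` and `crush_frac`.
#' @export
extract_profile <- function(image, path, n_bins = 100, half_width_um = 5,
                            background_roi = NULL, background_quantile = 0.05) {
  if (n_bins < 10) stop("n_bins must be >= 10")
  background <- if (!is.null(background_roi)) roi_mean(image, background_roi)
  else as.numeric(quantile(image$pixels, background_quantile))
  fracs <- (seq_len(n_bins) - 0.5) / n_bins
  st <- .path_stations(path, fracs)
  hw_px <- half_width_um / image$pixel_size_um
  offs <- seq(-hw_px, hw_px, by = 0.5)
  # perpendicular = tangent rotated 90 degrees
  xs <- outer(st$x, rep(1, length(offs))) + outer(-st$ty, offs)
  ys <- outer(st$y, rep(1, length(offs))) + outer(st$tx, offs)
  vals <- matrix(.interp_bilinear(image$pixels, as.numeric(xs), as.numeric(ys)),
                 nrow = n_bins)
  out_of_bounds <- rowSums(is.na(vals)) > 0
  if (mean(out_of_bounds) > 0.10)
    stop("perpendicular segment leaves the image at more than 10% of stations")
  values <- pmax(rowMeans(vals, na.rm = TRUE) - background, 0)
  structure(list(values = values, n_bins = as.integer(n_bins),
                 background = background,
                 length_um = path_length(path) * image$pixel_size_um,
                 crush_frac = path$crush_frac),
            class = "nerve_profile")
}

#' @export
print.nerve_profile <- function(x, ...) {
  cat(sprintf("<nerve_profile> %d bins over %.1f um, background %.3g\n",
              x$n_bins, x$length_um, x$background))
  invisible(x)
}

#' Contralateral-normalized nerve profile
#'
#' Expresses the injured nerve's profile bin-by-bin as a ratio to the
#' uninjured contralateral nerve at the equivalent arc-length position.
#' A small `epsilon` guard is added to the denominator so that bins where
#' the contralateral signal vanishes stay finite, preserving profile length
#' for group averaging.
#'
#' @param injured,contra [extract_profile()] results with equal `n_bins`.
#' @param epsilon denominator guard; default 1% of the contralateral
#'   profile's median.
#' @return An object of class `relative_profile` with fields `ratios`,
#'   `n_bins`, `epsilon` and `crush_frac`.
#' @export
relative_profile <- function(injured, contra, epsilon = NULL) {
  if (injured$n_bins != contra$n_bins)
    stop("profiles have mismatched n_bins")
  if (is.null(epsilon)) epsilon <- 0.01 * median(contra$values)
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("epsilon must be > 0 (is the contralateral profile all zero?)")
  ratios <- injured$values / (contra$values + epsilon)
  crush <- if (!is.na(injured$crush_frac)) injured$crush_frac else contra$crush_frac
  structure(list(ratios = ratios, n_bins = injured$n_bins,
                 epsilon = epsilon, crush_frac = crush),
            class = "relative_profile")
}

#' @export
print.relative_profile <- function(x, ...) {
  cat(sprintf("<relative_profile> %d bins, median ratio %.3g\n",
              x$n_bins, median(x$ratios)))
  invisible(x)
}

#' Proximal and distal summary indices of a relative profile
#'
#' The proximal index is the maximum ratio over bins whose arc fraction
#' falls in `[crush_frac - window_frac, crush_frac)` — capturing the
#' pile-up of retracting axonal material near the eye side of the crush —
#' and the distal index is the mean ratio over bins in
#' `(crush_frac + window_frac, 1]`, tracking Wallerian loss and regrowth.
#'
#' @param rel a [relative_profile()] with a crush position.
#' @param window_frac half-window width as an arc-length fraction.
#' @return List with `proximal_index` and `distal_index`.
#' @export
profile_metrics <- function(rel, window_frac = 0.15) {
  if (is.na(rel$crush_frac)) stop("crush_frac is required for profile metrics")
  fracs <- (seq_len(rel$n_bins) - 0.5) / rel$n_bins
  prox <- fracs >= rel$crush_frac - window_frac & fracs < rel$crush_frac
  dist <- fracs > rel$crush_frac + window_frac
  if (!any(prox) || !any(dist))
    stop("metric window is empty: crush site too close to a nerve end")
  list(proximal_index = max(rel$ratios[prox]),
       distal_index = mean(rel$ratios[dist]))
}

#' Average relative profiles across animals
#'
#' Group summaries average each animal's relative profile first, then
#' average bin-wise across animals.
#'
#' @param profiles list of [relative_profile()] objects with equal `n_bins`.
#' @return List with bin-wise `mean`, `sd` and `n`.
#' @export
average_profiles <- function(profiles) {
  nb <- unique(vapply(profiles, function(p) p$n_bins, integer(1)))
  if (length(nb) != 1) stop("profiles have mismatched n_bins")
  m <- do.call(cbind, lapply(profiles, function(p) p$ratios))
  list(mean = rowMeans(m),
       sd = if (ncol(m) > 1) apply(m, 1, sd) else rep(NA_real_, nb),
       n = ncol(m))
}
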
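#' Detected point set
#'
#' @param points data.frame with columns `x`, `y` (0-based pixel
#'   coordinates) and `intensity`.
#' @param channel channel name.
#' @return An object of class `point_set`.
#' @export
point_set <- function(points, channel = "") {
  df <- as.data.frame(points)
  if (nrow(df) && !all(c("x", "y") %in% names(df)))
    stop("points need x and y columns")
  if (!nrow(df)) df <- data.frame(x = numeric(0), y = numeric(0),
                                  intensity = numeric(0))
  if (is.null(df$intensity)) df$intensity <- NA_real_
  structure(list(points = df[, c("x", "y", "intensity")],
                 channel = as.character(channel)), class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %d points, channel '%s'\n", nrow(x$points),
              x$channel))
  invisible(x)
}

# scale-normalized Laplacian-of-Gaussian response (positive at bright blobs)
.log_response <- function(px, sigma) {
  sm <- EBImage::gblur(px, sigma = sigma)
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  -sigma^2 * as.matrix(EBImage::filter2(sm, lap))
}

#' Detect somata in a flatmount or section image
#'
#' Multiscale Laplacian-of-Gaussian blob detection over a radius range,
#' local maxima of the scale-maximal response thresholded at `k_mad` MADs
#' above the image median intensity, with minimum mutual separation equal
#' to the smallest radius. Points inside any exclusion polygon (e.g.
#' dissection artifacts) are removed.
#'
#' @param image an [image_grid].
#' @param exclusion_masks list of [roi_polygon]s to exclude.
#' @param r_min_um,r_max_um blob radius range in micrometers.
#' @param n_scales number of LoG scales spanning the radius range.
#' @param k_mad intensity threshold in MADs above the median.
#' @return A [point_set] of detected soma centers.
#' @export
detect_somata <- function(image, exclusion_masks = list(), r_min_um = 2,
                          r_max_um = 5, n_scales = 4, k_mad = 4) {
  if (r_min_um <= 0 || r_max_um < r_min_um)
    stop("radius range must be positive and ordered")
  px <- image$pixels
  radii_px <- seq(r_min_um, r_max_um, length.out = n_scales) / image$pixel_size_um
  sigmas <- radii_px / sqrt(2)
  resp <- Reduce(pmax, lapply(sigmas, function(s) .log_response(px, s)))
  nr <- nrow(resp); nc <- ncol(resp)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- resp
  is_max <- resp > 0
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & resp >= pad[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)]
  }
  # intensity test on the finest-scale smoothed image: single-pixel noise
  # spikes fail it while blobs of the nominal radius pass
  sm <- as.matrix(EBImage::gblur(px, sigma = sigmas[1]))
  thr <- median(sm) + k_mad * mad(sm)
  is_max <- is_max & sm > thr
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(point_set(NULL, image$channel))
  cand <- data.frame(x = idx[, 2] - 1, y = idx[, 1] - 1,
                     intensity = px[idx], resp = resp[idx])
  cand <- cand[order(cand$resp, decreasing = TRUE), ]
  min_sep_px <- r_min_um / image$pixel_size_um
  kept <- logical(nrow(cand))
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (!length(kx) ||
        min((kx - cand$x[i])^2 + (ky - cand$y[i])^2) >= min_sep_px^2) {
      kept[i] <- TRUE
      kx <- c(kx, cand$x[i]); ky <- c(ky, cand$y[i])
    }
  }
  pts <- cand[kept, c("x", "y", "intensity")]
  for (poly in exclusion_masks) {
    if (!nrow(pts)) break
    inside <- points_in_polygon(pts[, c("x", "y")], poly)
    pts <- pts[!inside, , drop = FALSE]
  }
  point_set(pts, image$channel)
}

#' Partition detected points by a birth-date ring
#'
#' The EdU/BrdU pulse annulus separates retinal ganglion cells born before
#' the crush (central to the ring) from those born after (peripheral).
#' Points strictly inside the ring polygon are central; boundary points
#' count as peripheral.
#'
#' @param points a [point_set].
#' @param ring an [roi_polygon] tracing the pulse annulus boundary.
#' @return List of class `ring_partition`: `central_count`,
#'   `peripheral_count`, and the logical `central` indicator per point.
#' @export
partition_by_ring <- function(points, ring) {
  pts <- points$points
  central <- if (nrow(pts)) points_in_polygon(pts[, c("x", "y")], ring)
  else logical(0)
  structure(list(central_count = sum(central),
                 peripheral_count = sum(!central), central = central),
            class = "ring_partition")
}

#' Greedy colocalization of two point sets
#'
#' Candidate pairs within `radius_um` are matched greedily by increasing
#' distance; each point is used at most once. The matched count is
#' symmetric under swapping the two sets.
#'
#' @param a,b [point_set]s in the same image frame.
#' @param radius_um matching radius in micrometers.
#' @param pixel_size_um micrometers per pixel of the shared frame.
#' @return List with `matched`, `unmatched_a`, `unmatched_b` (row indices).
#' @export
colocalize_points <- function(a, b, radius_um = 3, pixel_size_um = 1) {
  pa <- a$points; pb <- b$points
  if (!nrow(pa) || !nrow(pb))
    return(list(matched = 0L, unmatched_a = seq_len(nrow(pa)),
                unmatched_b = seq_len(nrow(pb))))
  r_px <- radius_um / pixel_size_um
  d2 <- outer(pa$x, pb$x, "-")^2 + outer(pa$y, pb$y, "-")^2
  cand <- which(d2 <= r_px^2, arr.ind = TRUE)
  ord <- order(d2[cand])
  cand <- cand[ord, , drop = FALSE]
  used_a <- logical(nrow(pa)); used_b <- logical(nrow(pb))
  matched <- 0L
  for (i in seq_len(nrow(cand))) {
    ia <- cand[i, 1]; ib <- cand[i, 2]
    if (used_a[ia] || used_b[ib]) next
    used_a[ia] <- TRUE; used_b[ib] <- TRUE
    matched <- matched + 1L
  }
  list(matched = matched, unmatched_a = which(!used_a),
       unmatched_b = which(!used_b))
}

#' Ganglion-cell-layer position profile
#'
#' Mean label intensity along a path tracing the ganglion cell layer in a
#' retinal section, binned by normalized position from the periphery
#' (0) to the center (1). Uses the same equal-arc-length machinery as
#' [extract_profile()].
#'
#' @param image an [image_grid].
#' @param gcl_path a [nerve_path] tracing the layer, periphery first.
#' @param n_bins number of position bins.
#' @param half_width_um perpendicular half-width.
#' @return A `nerve_profile` whose bins run periphery to center.
#' @export
gcl_position_profile <- function(image, gcl_path, n_bins = 50,
                                 half_width_um = 5) {
  extract_profile(image, gcl_path, n_bins = n_bins,
                  half_width_um = half_width_um)
}

#' Fraction of nuclei positive for a stain
#'
#' Each nucleus is scored by its mean stain intensity over a disc of
#' radius `disc_radius_um`; nuclei exceeding the positivity threshold
#' (default `k_mad` MADs above the stain image's median) are positive.
#'
#' @param nuclei a non-empty [point_set] of nucleus centers.
#' @param stain an [image_grid] of the stain channel (e.g. pJun).
#' @param positivity_threshold absolute intensity threshold; default
#'   derived from the stain image.
#' @param k_mad threshold scale when `positivity_threshold` is `NULL`.
#' @param disc_radius_um sampling disc radius.
#' @return List with `fraction_positive`, `mean_intensity` per nucleus,
#'   `positive` logical vector and the `threshold` used.
#' @export
count_positive_nuclei <- function(nuclei, stain, positivity_threshold = NULL,
                                  k_mad = 3, disc_radius_um = 2) {
  pts <- nuclei$points
  if (!nrow(pts)) stop("empty nuclei set")
  if (is.null(positivity_threshold))
    positivity_threshold <- median(stain$pixels) + k_mad * mad(stain$pixels)
  if (positivity_threshold <= 0) stop("positivity threshold must be > 0")
  r_px <- disc_radius_um / stain$pixel_size_um
  span <- seq(-ceiling(r_px), ceiling(r_px))
  disc <- expand.grid(dx = span, dy = span)
  disc <- disc[disc$dx^2 + disc$dy^2 <= r_px^2, ]
  mi <- vapply(seq_len(nrow(pts)), function(i) {
    xs <- pts$x[i] + disc$dx; ys <- pts$y[i] + disc$dy
    mean(.interp_bilinear(stain$pixels, xs, ys), na.rm = TRUE)
  }, 0)
  pos <- mi > positivity_threshold
  list(fraction_positive = mean(pos), mean_intensity = mi, positive = pos,
       threshold = positivity_threshold)
}
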
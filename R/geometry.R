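#' Nerve centerline path
#'
#' An ordered polyline of pixel coordinates running from the eye end
#' (index 1, proximal) to the chiasm/brain end, with an optional crush-site
#' position expressed as an arc-length fraction in `[0, 1]`.
#'
#' @param points numeric matrix with columns x, y; >= 2 distinct points.
#' @param crush_frac arc-length fraction of the crush site, or `NA` for
#'   uninjured nerves.
#' @return An object of class `nerve_path`.
#' @export
nerve_path <- function(points, crush_frac = NA_real_) {
  p <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y")
  if (nrow(p) < 2) stop("a nerve path needs at least 2 points")
  d <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(d == 0)) stop("consecutive path points must be distinct")
  if (sum(d) <= 0) stop("path must have positive arc length")
  if (!is.na(crush_frac) && (crush_frac < 0 || crush_frac > 1))
    stop("crush_frac must lie in [0, 1]")
  structure(list(points = p, crush_frac = crush_frac), class = "nerve_path")
}

#' @export
print.nerve_path <- function(x, ...) {
  cat(sprintf("<nerve_path> %d points, arc length %.1f px%s\n",
              nrow(x$points), path_length(x),
              if (is.na(x$crush_frac)) ""
              else sprintf(", crush at %.2f", x$crush_frac)))
  invisible(x)
}

#' Total arc length of a path in pixels
#' @param path a [nerve_path].
#' @return Arc length in pixel units.
#' @export
path_length <- function(path) {
  p <- path$points
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# cumulative arc length (0 at the first point), in px
.arclength <- function(p) {
  c(0, cumsum(sqrt(rowSums((p[-1, , drop = FALSE] -
                              p[-nrow(p), , drop = FALSE])^2))))
}

# resample a polyline at given arc-length fractions; returns x, y and the
# unit tangent at each station
.path_stations <- function(path, fracs) {
  p <- path$points
  s <- .arclength(p)
  total <- s[length(s)]
  target <- fracs * total
  x <- approx(s, p[, "x"], xout = target, rule = 2)$y
  y <- approx(s, p[, "y"], xout = target, rule = 2)$y
  # tangent by central differences on a fine resampling
  eps <- total * 1e-4
  xf <- approx(s, p[, "x"], xout = pmin(target + eps, total), rule = 2)$y
  xb <- approx(s, p[, "x"], xout = pmax(target - eps, 0), rule = 2)$y
  yf <- approx(s, p[, "y"], xout = pmin(target + eps, total), rule = 2)$y
  yb <- approx(s, p[, "y"], xout = pmax(target - eps, 0), rule = 2)$y
  tx <- xf - xb; ty <- yf - yb
  nrm <- sqrt(tx^2 + ty^2)
  nrm[nrm == 0] <- 1
  list(x = x, y = y, tx = tx / nrm, ty = ty / nrm)
}

# bilinear interpolation of image intensities at 0-based (x, y) positions;
# positions outside the image return NA
.interp_bilinear <- function(pixels, x, y) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  out <- rep(NA_real_, length(x))
  ok <- x >= 0 & x <= nc - 1 & y >= 0 & y <= nr - 1
  if (!any(ok)) return(out)
  xo <- x[ok]; yo <- y[ok]
  x0 <- pmin(floor(xo), nc - 2); y0 <- pmin(floor(yo), nr - 2)
  fx <- xo - x0; fy <- yo - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  out[ok] <- pixels[i00] * (1 - fx) * (1 - fy) + pixels[i01] * fx * (1 - fy) +
    pixels[i10] * (1 - fx) * fy + pixels[i11] * fx * fy
  out
}

#' Test whether points lie strictly inside a polygon
#'
#' Points exactly on the boundary are counted as outside.
#'
#' @param points numeric matrix with columns x, y.
#' @param poly an [roi_polygon].
#' @return Logical vector.
#' @export
points_in_polygon <- function(points, poly) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  v <- poly$vertices
  bnd <- list(x = c(v[, "x"], v[1, "x"]), y = c(v[, "y"], v[1, "y"]))
  inside <- mgcv::in.out(cbind(bnd$x, bnd$y), pts)
  # in.out counts boundary points as inside on some edges; enforce the
  # strict-interior rule by checking distance to the boundary
  on_edge <- .dist_to_polygon(pts, v) < 1e-9
  inside & !on_edge
}

# minimum distance from each point to the polygon outline
.dist_to_polygon <- function(pts, v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1), , drop = FALSE]
  dmin <- rep(Inf, nrow(pts))
  for (i in seq_len(n)) {
    ab <- b[i, ] - a[i, ]
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, nrow(pts)) else
      pmin(pmax(((pts[, 1] - a[i, 1]) * ab[1] +
                   (pts[, 2] - a[i, 2]) * ab[2]) / len2, 0), 1)
    dx <- pts[, 1] - (a[i, 1] + t * ab[1])
    dy <- pts[, 2] - (a[i, 2] + t * ab[2])
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  dmin
}

#' Mean intensity of an image inside a polygon ROI
#'
#' @param image an [image_grid].
#' @param poly an [roi_polygon].
#' @return Mean of the pixels whose centers fall inside the polygon.
#' @export
roi_mean <- function(image, poly) {
  v <- poly$vertices
  xr <- floor(max(0, min(v[, "x"]))):ceiling(min(ncol(image$pixels) - 1, max(v[, "x"])))
  yr <- floor(max(0, min(v[, "y"]))):ceiling(min(nrow(image$pixels) - 1, max(v[, "y"])))
  grid <- cbind(x = rep(xr, times = length(yr)), y = rep(yr, each = length(xr)))
  inside <- points_in_polygon(grid, poly)
  if (!any(inside)) stop("ROI contains no pixel centers")
  mean(image$pixels[cbind(grid[inside, "y"] + 1, grid[inside, "x"] + 1)])
}
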
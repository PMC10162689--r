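#' Fluorescence image container
#'
#' An `image_grid` is the package's in-memory form of a single-channel
#' fluorescence image: a numeric matrix of non-negative intensities indexed
#' `[y, x]` (origin top-left, x rightward, y downward, 0-based pixel
#' coordinates in all user-facing geometry), an isotropic pixel size in
#' micrometers, a channel name and free-form metadata (animal id, side,
#' timepoint).
#'
#' @param pixels numeric matrix, rows = y, columns = x; finite, `>= 0`.
#' @param pixel_size_um micrometers per pixel (isotropic), `> 0`.
#' @param channel channel name.
#' @param metadata named list (e.g. `animal_id`, `side`, `timepoint_days`).
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(pixels, pixel_size_um = 1, channel = "", metadata = list()) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels))) stop("image intensities must be finite")
  if (any(pixels < 0)) stop("image intensities must be >= 0")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         channel = as.character(channel), metadata = as.list(metadata)),
    class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d px, %.3g um/px, channel '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$channel))
  invisible(x)
}

#' Time-lapse stack container
#'
#' An ordered list of same-shape [image_grid] frames plus the frame
#' interval in seconds. Frame order is time order.
#'
#' @param frames list of `image_grid`, all the same shape (>= 2 frames).
#' @param dt_s seconds per frame, `> 0`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, dt_s) {
  if (length(frames) < 2) stop("an image_stack needs at least 2 frames")
  if (!all(vapply(frames, inherits, logical(1), "image_grid")))
    stop("frames must all be image_grid objects")
  dims <- vapply(frames, function(f) dim(f$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have identical shape")
  if (!is.numeric(dt_s) || length(dt_s) != 1 || dt_s <= 0)
    stop("dt_s must be a single positive number")
  structure(list(frames = frames, dt_s = dt_s), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]]$pixels)
  cat(sprintf("<image_stack> %d frames of %d x %d px, dt = %g s\n",
              length(x$frames), d[1], d[2], x$dt_s))
  invisible(x)
}

#' Closed polygon region of interest
#'
#' Vertices are 0-based pixel coordinates `(x, y)`; the polygon is implicitly
#' closed (last vertex connects back to the first). Self-intersecting
#' polygons are rejected.
#'
#' @param vertices numeric matrix or data.frame with columns x, y; >= 3 rows.
#' @param label free-text label.
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices, label = "") {
  v <- as.matrix(vertices)[, 1:2, drop = FALSE]
  storage.mode(v) <- "double"
  colnames(v) <- c("x", "y")
  if (nrow(v) < 3) stop("a polygon needs at least 3 vertices")
  if (anyNA(v) || !all(is.finite(v))) stop("polygon vertices must be finite")
  if (.polygon_self_intersects(v)) stop("polygon is self-intersecting")
  structure(list(vertices = v, label = as.character(label)),
            class = "roi_polygon")
}

#' Polygon area in square pixels (shoelace formula)
#' @param poly an [roi_polygon].
#' @return Absolute area in px^2.
#' @export
polygon_area <- function(poly) {
  v <- poly$vertices
  n <- nrow(v)
  j <- c(n, seq_len(n - 1))
  abs(sum(v[j, "x"] * v[, "y"] - v[, "x"] * v[j, "y"])) / 2
}

# segment-intersection test between non-adjacent edges
.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])  # x1 y1 x2 y2
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i || abs(i - j) == 1 || (i == 1 && j == n)) next
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- orient(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- orient(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- orient(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- orient(b[1], b[2], b[3], b[4], a[3], a[4])
      if (d1 != d2 && d3 != d4) return(TRUE)
    }
  }
  FALSE
}

#' Read a single-page TIFF as an image_grid
#'
#' Integer TIFFs (8/16-bit) are read bit-exactly as raw counts; float TIFFs
#' keep their stored values.
#'
#' @param path TIFF file path.
#' @param pixel_size_um micrometers per pixel.
#' @param channel,metadata passed to [image_grid()].
#' @return An [image_grid].
#' @export
read_image <- function(path, pixel_size_um = 1, channel = "", metadata = list()) {
  if (!file.exists(path)) stop("no such file: ", path)
  px <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                 error = function(e) stop("could not read TIFF '", path, "': ",
                                          conditionMessage(e)))
  if (is.list(px)) px <- px[[1]]
  if (length(dim(px)) == 3) px <- px[, , 1]
  image_grid(px, pixel_size_um, channel, metadata)
}

#' Read a multi-page TIFF as an image_stack
#'
#' Page order is preserved as time order.
#'
#' @param path TIFF file path.
#' @param dt_s seconds per frame.
#' @param pixel_size_um micrometers per pixel.
#' @return An [image_stack].
#' @export
read_stack <- function(path, dt_s = 1, pixel_size_um = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("could not read TIFF '", path,
                                             "': ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    image_grid(p, pixel_size_um)
  })
  image_stack(frames, dt_s)
}

#' Write an image_grid (or image_stack) as 16-bit TIFF
#'
#' Intensities are stored as 16-bit unsigned integers; values are rounded
#' and clipped to `[0, 65535]`, so integer-valued images round-trip
#' bit-exactly through [read_image()]/[read_stack()].
#'
#' @param x an [image_grid] or [image_stack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  to16 <- function(m) pmin(pmax(round(m), 0), 65535) / 65535
  if (inherits(x, "image_grid")) {
    tiff::writeTIFF(to16(x$pixels), path, bits.per.sample = 16)
  } else if (inherits(x, "image_stack")) {
    tiff::writeTIFF(lapply(x$frames, function(f) to16(f$pixels)), path,
                    bits.per.sample = 16)
  } else stop("x must be an image_grid or image_stack")
  invisible(path)
}

#' Read ROI polygons and nerve paths from a JSON annotation file
#'
#' The JSON document maps names to objects with a `type` ("polygon" or
#' "path"), a vertex list, and optional fields (`label`, `crush_frac`).
#' Round-trips exactly through [write_roi()].
#'
#' @param path JSON file path.
#' @return Named list of [roi_polygon] / [nerve_path] objects.
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(doc, function(item) {
    v <- do.call(rbind, lapply(item$vertices, function(p) c(p[[1]], p[[2]])))
    if (identical(item$type, "path")) {
      nerve_path(v, crush_frac = if (!is.null(item$crush_frac))
        item$crush_frac else NA_real_)
    } else {
      roi_polygon(v, label = if (!is.null(item$label)) item$label else "")
    }
  })
}

#' Write ROI polygons / nerve paths to JSON
#'
#' @param rois named list of [roi_polygon] / [nerve_path] objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_roi <- function(rois, path) {
  doc <- lapply(rois, function(r) {
    if (inherits(r, "nerve_path")) {
      out <- list(type = "path",
                  vertices = lapply(seq_len(nrow(r$points)),
                                    function(i) as.numeric(r$points[i, ])))
      if (!is.na(r$crush_frac)) out$crush_frac <- r$crush_frac
      out
    } else {
      list(type = "polygon", label = r$label,
           vertices = lapply(seq_len(nrow(r$vertices)),
                             function(i) as.numeric(r$vertices[i, ])))
    }
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline run configuration
#'
#' A validated key-value store of tunable parameters. Every consumed key has
#' a documented default; unknown keys are rejected so that typos fail loudly.
#'
#' @param ... overrides of the defaults, or a single named list.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,                     # global seed for stochastic operations
    n_bins = 100L,                 # nerve-profile arc-length bins
    half_width_um = 5,             # perpendicular sampling half-width
    background_quantile = 0.05,    # fallback background estimate
    epsilon_frac = 0.01,           # ratio guard, fraction of contra median
    window_frac = 0.15,            # proximal/distal metric window
    denervation_threshold = 0.05,  # complete-crush tectal ratio cutoff
    min_skeleton_px = 20,          # shortest admissible centerline
    v_max_um_s = 2,                # track-linking gate velocity
    max_gap_frames = 2L,           # bridgeable detection gaps
    min_track_len = 10L,           # minimum samples per track
    d_stop_um = 2,                 # net displacement below which = stopped
    pause_speed_um_s = 0.05,       # speeds below this are pauses
    min_sep_um = 2,                # kymograph peak minimum separation
    max_del = 25L,                 # decomposition: largest deletion
    max_ins = 35L,                 # decomposition: largest insertion
    decomp_window = 40L,           # positions fitted downstream of the cut
    decomp_offset = 3L,            # skip cut-proximal positions
    min_allele_freq = 0.2,         # F1 allele-calling floor
    blob_r_min_um = 2,             # soma detection radius range
    blob_r_max_um = 5,
    detect_k_mad = 4,              # detection threshold, MADs above median
    coloc_radius_um = 3,
    n_permutations = 10000L)
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    defaults[names(over)] <- over
  }
  structure(defaults, class = c("run_config", "list"))
}

#' Read a run configuration from a YAML file
#'
#' The file holds overrides of the [run_config()] defaults; unknown keys
#' are rejected.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  over <- yaml::read_yaml(path)
  if (is.null(over)) run_config() else run_config(over)
}
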
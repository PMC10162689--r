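#' Injured/contralateral tectal innervation ratio
#'
#' The innervation readout of the crush assay: background-subtracted mean
#' fluorescence of the injured tectum divided by that of the contralateral
#' tectum of the same animal. Mean (not integrated) ROI intensity makes the
#' ratio robust to ROI-area mismatch; background subtraction from a shared
#' ROI cancels additive offsets, and the ratio cancels multiplicative gain.
#'
#' @param image an [image_grid] showing both tecta.
#' @param roi_injured,roi_contra,roi_background disjoint [roi_polygon]s.
#' @param timepoint days post-crush (metadata).
#' @param animal_id animal identifier (metadata).
#' @return An object of class `tectal_measurement` with fields `ratio`,
#'   `mean_injured`, `mean_contra`, `background`, `timepoint`, `animal_id`.
#' @export
tectal_ratio <- function(image, roi_injured, roi_contra, roi_background,
                         timepoint = NA_real_, animal_id = NA_character_) {
  mi <- roi_mean(image, roi_injured)
  mc <- roi_mean(image, roi_contra)
  bg <- roi_mean(image, roi_background)
  if (mc - bg <= 0)
    stop("no signal: contralateral mean does not exceed background")
  ratio <- max((mi - bg) / (mc - bg), 0)
  structure(list(ratio = ratio, mean_injured = mi, mean_contra = mc,
                 background = bg, timepoint = timepoint,
                 animal_id = animal_id),
            class = "tectal_measurement")
}

#' @export
print.tectal_measurement <- function(x, ...) {
  cat(sprintf("<tectal_measurement> ratio %.3f (injured %.1f, contra %.1f, bg %.1f)\n",
              x$ratio, x$mean_injured, x$mean_contra, x$background))
  invisible(x)
}

#' Complete-denervation call
#'
#' Operationalizes "loss of all transgene fluorescence" as an
#' injured/contralateral ratio strictly below `threshold`.
#'
#' @param m a [tectal_ratio()] result, or a bare numeric ratio.
#' @param threshold ratio cutoff (default 0.05); the call is strict (`<`).
#' @return Logical flag.
#' @export
classify_complete_denervation <- function(m, threshold = 0.05) {
  r <- if (inherits(m, "tectal_measurement")) m$ratio else as.numeric(m)
  r < threshold
}

#' Denervation/reinnervation time-course table
#'
#' One row per (group, timepoint): number of animals, mean ratio, SD
#' (`NA` for singletons).
#'
#' @param measurements list of [tectal_ratio()] results.
#' @param groups character vector of group labels, one per measurement
#'   (default: a single group).
#' @return A data.frame with columns group, timepoint, n, mean_ratio, sd_ratio.
#' @export
timecourse_table <- function(measurements, groups = NULL) {
  if (length(measurements) < 1) stop("need at least one measurement")
  if (is.null(groups)) groups <- rep("all", length(measurements))
  df <- data.frame(
    group = groups,
    timepoint = vapply(measurements, function(m) as.numeric(m$timepoint), 0),
    ratio = vapply(measurements, function(m) m$ratio, 0))
  agg <- aggregate(ratio ~ group + timepoint, df, function(v)
    c(n = length(v), mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_))
  out <- data.frame(group = agg$group, timepoint = agg$timepoint,
                    n = agg$ratio[, "n"], mean_ratio = agg$ratio[, "mean"],
                    sd_ratio = agg$ratio[, "sd"])
  out[order(out$group, out$timepoint), , drop = FALSE]
}

#' Two-sided permutation test for a difference in group means
#'
#' Plumbing for between-group comparisons of per-animal ratios (or any
#' scalar per-replicate statistic): the permutation null of no group
#' difference, two-sided on the difference of means.
#'
#' @param x,y numeric vectors of per-replicate values.
#' @param n_perm number of label permutations.
#' @param seed RNG seed for the resampling.
#' @return List with `p_value`, `observed` difference, `n_perm`.
#' @export
permutation_test <- function(x, y, n_perm = 10000, seed = 1) {
  obs <- mean(x) - mean(y)
  pool <- c(x, y)
  nx <- length(x)
  set.seed(seed)
  diffs <- replicate(n_perm, {
    idx <- sample.int(length(pool), nx)
    mean(pool[idx]) - mean(pool[-idx])
  })
  p <- (1 + sum(abs(diffs) >= abs(obs))) / (n_perm + 1)
  list(p_value = p, observed = obs, n_perm = n_perm)
}
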
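#' Sanger trace peak-height signal
#'
#' Per-base-call peak heights of the four sequencing channels, plus the
#' predicted Cas9 cut site (3 bp upstream of the PAM). The canonical input
#' is a 5-column peak table (position, A, C, G, T); see [read_trace_csv()].
#'
#' @param peaks numeric matrix with columns A, C, G, T; one row per base
#'   call; all heights finite and >= 0.
#' @param cut_site base index (1-based) of the predicted break.
#' @param source `"control"` or `"edited"`.
#' @return An object of class `trace_signal`.
#' @export
trace_signal <- function(peaks, cut_site, source = c("control", "edited")) {
  source <- match.arg(source)
  m <- as.matrix(peaks)
  if (ncol(m) != 4) stop("peaks must have 4 channel columns (A, C, G, T)")
  storage.mode(m) <- "double"
  colnames(m) <- c("A", "C", "G", "T")
  if (!all(is.finite(m)) || any(m < 0)) stop("peak heights must be finite and >= 0")
  if (cut_site < 1 || cut_site > nrow(m)) stop("cut_site outside the trace")
  if (nrow(m) - cut_site < 40)
    stop("need at least 40 positions downstream of the cut site")
  structure(list(peaks = m, cut_site = as.integer(cut_site), source = source),
            class = "trace_signal")
}

#' Read a trace peak table from a 5-column CSV
#'
#' Columns: position, A, C, G, T.
#'
#' @param path CSV path.
#' @param cut_site predicted break position.
#' @param source `"control"` or `"edited"`.
#' @return A [trace_signal].
#' @export
read_trace_csv <- function(path, cut_site, source = "control") {
  df <- read.csv(path)
  if (ncol(df) < 5) stop("expected columns: position, A, C, G, T")
  df <- df[order(df[[1]]), ]
  trace_signal(as.matrix(df[, 2:5]), cut_site, source)
}

# per-position channel normalization to sum 1 (zero rows become uniform)
.norm_rows <- function(m) {
  s <- rowSums(m)
  zero <- s <= 0
  s[zero] <- 1
  out <- m / s
  out[zero, ] <- 0.25
  out
}

#' Decompose an edited Sanger trace into an indel spectrum
#'
#' TIDE-style decomposition: over a window of positions downstream of the
#' cut site, the edited four-channel signal is modeled as a non-negative
#' mixture of copies of the control signal shifted by each candidate indel
#' size `s` in `[-max_del, +max_ins]` (size 0 = unedited). Channel heights
#' are normalized per position to sum 1 before fitting; mixture weights are
#' solved by non-negative least squares and renormalized to a probability
#' vector. The fitted window starts `offset` bases downstream of the cut to
#' skip cut-proximal noise.
#'
#' @param control near-homogeneous [trace_signal] from uninjected animals
#'   (dominant channel >= 80% of the per-position total upstream of the cut).
#' @param edited mixed [trace_signal] from injected animals.
#' @param max_del largest deletion considered (positive integer).
#' @param max_ins largest insertion considered.
#' @param window number of positions fitted.
#' @param offset positions skipped immediately downstream of the cut.
#' @return An object of class `indel_spectrum`: `freqs` (named by signed
#'   indel size), `r_squared`, `overall_pct`, `frameshift_pct`.
#' @export
decompose_indels <- function(control, edited, max_del = 25, max_ins = 35,
                             window = 40, offset = 3) {
  stopifnot(inherits(control, "trace_signal"), inherits(edited, "trace_signal"))
  cut <- control$cut_site
  up <- .norm_rows(control$peaks[seq_len(cut - 1), , drop = FALSE])
  dominant_ok <- apply(up, 1, max) >= 0.80
  if (mean(dominant_ok) < 0.90)
    stop("control trace fails the homogeneity check (dominant channel < 80% upstream of the cut)")
  pos <- (cut + offset):(cut + offset + window - 1)
  if (max(pos) + max_del > nrow(control$peaks) || max(pos) > nrow(edited$peaks))
    stop("decomposition window exceeds trace length")
  ctl <- .norm_rows(control$peaks)
  edt <- .norm_rows(edited$peaks)
  sizes <- (-max_del):max_ins
  A <- vapply(sizes, function(s) {
    src <- pos - s                      # deletion of d shifts control forward
    src[src < 1] <- NA
    block <- matrix(0.25, length(pos), 4)
    ok <- !is.na(src) & src <= nrow(ctl)
    block[ok, ] <- ctl[src[ok], ]
    as.numeric(block)
  }, numeric(length(pos) * 4))
  b <- as.numeric(edt[pos, ])
  fit <- pracma::lsqnonneg(A, b)
  f <- fit$x
  if (sum(f) <= 0) stop("decomposition failed: all-zero solution")
  f <- f / sum(f)
  resid <- A %*% f - b
  r2 <- 1 - sum(resid^2) / sum((b - mean(b))^2)
  indel_spectrum(setNames(f, sizes), r_squared = r2)
}

#' Indel-size frequency spectrum
#'
#' @param freqs named numeric vector: names are signed indel sizes (0 =
#'   unedited), values are frequencies summing to 1.
#' @param r_squared decomposition goodness of fit.
#' @return An object of class `indel_spectrum` with derived `overall_pct`
#'   (percent of sequences carrying any indel) and `frameshift_pct`
#'   (percent of all sequences carrying a frame-disrupting indel).
#' @export
indel_spectrum <- function(freqs, r_squared = NA_real_) {
  f <- as.numeric(freqs)
  sizes <- as.integer(names(freqs))
  if (anyNA(sizes)) stop("freqs must be named by signed indel size")
  if (any(f < 0)) stop("frequencies must be >= 0")
  if (abs(sum(f) - 1) > 1e-9) stop("frequencies must sum to 1")
  f0 <- sum(f[sizes == 0])
  fs <- sum(f[sizes != 0 & sizes %% 3 != 0])
  structure(list(freqs = setNames(f, sizes), r_squared = r_squared,
                 overall_pct = 100 * (1 - f0), frameshift_pct = 100 * fs),
            class = "indel_spectrum")
}

#' @export
print.indel_spectrum <- function(x, ...) {
  cat(sprintf("<indel_spectrum> overall %.1f%%, frameshift %.1f%% (R^2 %.3f)\n",
              x$overall_pct, x$frameshift_pct, x$r_squared))
  top <- sort(x$freqs[x$freqs > 0.01], decreasing = TRUE)
  if (length(top))
    cat("  ", paste(sprintf("%s: %.2f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' sgRNA efficiency screen
#'
#' An sgRNA progresses to the crush assay only if its F0 indel spectrum
#' shows at least 80% overall indels and at least 50% frameshift indels
#' (both thresholds inclusive; frameshift percent is expressed as a
#' fraction of all sequences).
#'
#' @param spectrum an [indel_spectrum].
#' @param min_overall_pct,min_frameshift_pct screening thresholds.
#' @return Logical pass/fail.
#' @export
screen_sgrna <- function(spectrum, min_overall_pct = 80, min_frameshift_pct = 50) {
  spectrum$overall_pct >= min_overall_pct &&
    spectrum$frameshift_pct >= min_frameshift_pct
}

#' Predicted protein-level effect of an indel allele
#'
#' Indel sizes that are not multiples of 3 disrupt the reading frame.
#' Codon-aligned in-frame deletions of `3k` nucleotides remove `k`
#' residues (e.g. a -9 allele deletes 3 amino acids); in-frame insertions
#' add `size/3` residues. Alignment to codon boundaries is assumed, not
#' verified against the transcript, so in-frame calls carry
#' `boundary_verified = FALSE`.
#'
#' @param size signed indel length in nucleotides (0 = wild type).
#' @return List with `size`, `frame_status` (`wild_type`, `in_frame`,
#'   `frameshift`), `aa_deleted`, `aa_inserted`, `boundary_verified`.
#' @export
predict_protein_effect <- function(size) {
  size <- as.integer(size)
  if (size == 0) {
    status <- "wild_type"; del <- 0L; ins <- 0L
  } else if (size %% 3 != 0) {
    status <- "frameshift"; del <- 0L; ins <- 0L
  } else if (size < 0) {
    status <- "in_frame"; del <- abs(size) %/% 3L; ins <- 0L
  } else {
    status <- "in_frame"; del <- 0L; ins <- size %/% 3L
  }
  list(size = size, frame_status = status, aa_deleted = del,
       aa_inserted = ins, boundary_verified = FALSE)
}

#' Allele call from an indel size and observed frequency
#'
#' @param size signed indel length in nt.
#' @param frequency observed fraction in the trace decomposition.
#' @return An object of class `allele_call`.
#' @export
allele_call <- function(size, frequency = NA_real_) {
  eff <- predict_protein_effect(size)
  structure(c(eff, list(frequency = frequency)), class = "allele_call")
}

#' Call an F1 genotype from per-homeolog indel spectra
#'
#' *X. laevis* is allotetraploid: each locus has an L- and an S-chromosome
#' homeolog, each diploid, so an animal carries up to four alleles. Per
#' chromosome, the alleles are the spectrum entries at or above
#' `min_allele_freq` (expected near 0.5 for a diploid locus), capped at
#' the two largest; a chromosome with a single passing allele is treated
#' as homozygous (two copies). `functional_dose` counts non-frameshift
#' allele copies (0-4): animals carrying only frameshift alleles are full
#' knockouts (dose 0).
#'
#' @param spectrum_l,spectrum_s [indel_spectrum] objects (or named
#'   frequency vectors) for the L and S homeologs.
#' @param min_allele_freq allele-calling floor.
#' @return An object of class `genotype`: `alleles_l`, `alleles_s` (lists
#'   of [allele_call]), `class_label` (`full_KO`, `partial`, `wild_type`),
#'   `functional_dose`.
#' @export
call_genotype <- function(spectrum_l, spectrum_s, min_allele_freq = 0.2) {
  pick <- function(sp, chrom) {
    f <- if (inherits(sp, "indel_spectrum")) sp$freqs else
      setNames(as.numeric(sp), names(sp))
    hit <- f[f >= min_allele_freq]
    if (!length(hit))
      stop("no allele reaches min_allele_freq on the ", chrom, " chromosome")
    if (length(hit) > 2)
      stop("contaminated/mosaic: more than 2 alleles above threshold on the ",
           chrom, " chromosome")
    sizes <- as.integer(names(hit))
    copies <- if (length(hit) == 1) 2L else c(1L, 1L)
    mapply(function(s, fr, cp) {
      a <- allele_call(s, fr); a$copies <- cp; a
    }, sizes, hit, copies, SIMPLIFY = FALSE)
  }
  al <- pick(spectrum_l, "L")
  as_ <- pick(spectrum_s, "S")
  all_alleles <- c(al, as_)
  status <- vapply(all_alleles, function(a) a$frame_status, "")
  copies <- vapply(all_alleles, function(a) a$copies, 0L)
  dose <- sum(copies[status != "frameshift"])
  label <- if (all(status == "frameshift")) "full_KO"
  else if (all(status == "wild_type")) "wild_type" else "partial"
  structure(list(alleles_l = al, alleles_s = as_, class_label = label,
                 functional_dose = as.integer(dose)),
            class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  fmt <- function(al) paste(vapply(al, function(a)
    sprintf("%+d (%s, x%d)", a$size, a$frame_status, a$copies), ""),
    collapse = ", ")
  cat(sprintf("<genotype> %s, functional dose %d\n  L: %s\n  S: %s\n",
              x$class_label, x$functional_dose, fmt(x$alleles_l),
              fmt(x$alleles_s)))
  invisible(x)
}
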
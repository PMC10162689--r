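# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: the decomposition oracle rebuilds expected traces
# from the simulated reference sequence and searches the frequency simplex
# exhaustively; the matching oracle is plain greedy nearest-neighbor.

# one-hot channel matrix for a base-character vector
onehot_trace <- function(seq_chr, n) {
  bases <- c("A", "C", "G", "T")
  m <- matrix(0, n, 4, dimnames = list(NULL, bases))
  m[cbind(seq_len(n), match(seq_chr[seq_len(n)], bases))] <- 1
  m
}

# exhaustive simplex grid search at `step` resolution over <= 3 candidate
# deletion/wild-type alleles; returns the best frequency vector.
# `reference` is the simulated reference sequence (character string),
# `edited` a trace_signal, `sizes` the candidate allele sizes (<= 0).
grid_search_spectrum <- function(reference, edited, sizes, cut_site,
                                 window = 40, offset = 3, step = 0.01) {
  stopifnot(length(sizes) <= 3, all(sizes <= 0))
  ref <- strsplit(reference, "")[[1]]
  pos <- (cut_site + offset):(cut_site + offset + window - 1)
  basis <- vapply(sizes, function(s) {
    seq_s <- if (s == 0) ref else
      c(ref[seq_len(cut_site)], ref[(cut_site + 1 - s):length(ref)])
    as.numeric(onehot_trace(seq_s, max(pos))[pos, ])
  }, numeric(length(pos) * 4))
  tot <- rowSums(edited$peaks)
  tot[tot <= 0] <- 1
  target <- as.numeric((edited$peaks / tot)[pos, ])
  grid <- seq(0, 1, by = step)
  k <- length(sizes)
  if (k == 1) combos <- matrix(1, 1, 1)
  else if (k == 2) combos <- cbind(grid, 1 - grid)
  else {
    combos <- expand.grid(f1 = grid, f2 = grid)
    combos <- combos[combos$f1 + combos$f2 <= 1 + 1e-12, ]
    combos <- cbind(combos$f1, combos$f2, 1 - combos$f1 - combos$f2)
  }
  pred <- basis %*% t(combos)
  sse <- colSums((pred - target)^2)
  setNames(as.numeric(combos[which.min(sse), ]), sizes)
}

# greedy nearest-neighbor matching between two coordinate matrices within
# `radius`; returns the number of matched pairs
greedy_match_count <- function(a, b, radius) {
  if (!nrow(a) || !nrow(b)) return(0L)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  cand <- which(d2 <= radius^2, arr.ind = TRUE)
  cand <- cand[order(d2[cand]), , drop = FALSE]
  ua <- logical(nrow(a)); ub <- logical(nrow(b)); n <- 0L
  for (i in seq_len(nrow(cand))) {
    if (ua[cand[i, 1]] || ub[cand[i, 2]]) next
    ua[cand[i, 1]] <- TRUE; ub[cand[i, 2]] <- TRUE; n <- n + 1L
  }
  n
}

# run the full kymograph pipeline on one simulated movie and return labeled
# tracks (shared by motility tests)
run_motility_pipeline <- function(sim) {
  ky <- build_kymograph(sim$stack, sim$path)
  lapply(detect_tracks(ky), classify_track)
}
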
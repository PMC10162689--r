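test_that("decomposing an unedited trace returns the pure wild-type spectrum", {
  sim <- simulate_sanger_traces(c("0" = 1), noise_sd = 0, seed = 80)
  edited <- sim$control
  edited$source <- "edited"
  sp <- decompose_indels(sim$control, edited)
  expect_equal(unname(sp$freqs["0"]), 1, tolerance = 1e-6)
  expect_equal(sp$overall_pct, 0, tolerance = 1e-4)
})

test_that("noise-free two-allele mixtures are recovered exactly", {
  sim <- simulate_sanger_traces(c("-7" = 0.7, "0" = 0.3), noise_sd = 0,
                                seed = 81)
  sp <- decompose_indels(sim$control, sim$edited)
  expect_equal(unname(sp$freqs["-7"]), 0.70, tolerance = 0.01)
  expect_equal(sp$overall_pct, 70, tolerance = 1)
  expect_gt(sp$r_squared, 0.99)
})

test_that("a noisy four-allele founder mix is recovered within 0.05", {
  truth <- c("-7" = 0.4, "1" = 0.3, "-9" = 0.2, "0" = 0.1)
  sim <- simulate_sanger_traces(truth, noise_sd = 0.05, seed = 82)
  sp <- decompose_indels(sim$control, sim$edited)
  for (nm in names(truth))
    expect_true(abs(sp$freqs[[nm]] - truth[[nm]]) < 0.05,
                label = sprintf("allele %s recovered", nm))
})

test_that("NNLS decomposition matches the exhaustive grid-search oracle", {
  set.seed(83)
  for (k in 1:10) {
    sizes <- c(0, sort(-sample(1:20, 2)))
    f <- as.numeric(rmultinom(1, 100, rep(1, 3))) / 100
    spectrum <- setNames(f, sizes)
    sim <- simulate_sanger_traces(spectrum, noise_sd = 0, seed = 830 + k)
    sp <- decompose_indels(sim$control, sim$edited)
    oracle <- grid_search_spectrum(sim$truth$truth$reference, sim$edited,
                                   sizes, cut_site = 100)
    for (nm in names(oracle))
      expect_true(abs(sp$freqs[[nm]] - oracle[[nm]]) <= 0.011,
                  label = sprintf("case %d allele %s", k, nm))
  }
})

test_that("control traces failing homogeneity are rejected", {
  sim <- simulate_sanger_traces(c("0" = 1), noise_sd = 0, seed = 84)
  messy <- sim$control
  messy$peaks <- matrix(100, nrow(messy$peaks), 4)
  expect_error(decompose_indels(messy, sim$edited), "homogeneity")
})

test_that("spectrum invariants hold: probability vector and percent identity", {
  sim <- simulate_sanger_traces(c("-7" = 0.5, "-9" = 0.2, "0" = 0.3),
                                noise_sd = 0.03, seed = 85)
  sp <- decompose_indels(sim$control, sim$edited)
  expect_equal(sum(sp$freqs), 1, tolerance = 1e-9)
  expect_equal(sp$overall_pct + 100 * sp$freqs[["0"]], 100, tolerance = 1e-9)
  expect_true(sp$frameshift_pct <= sp$overall_pct)
})

test_that("the sgRNA screening gate is inclusive at 80/50", {
  mk <- function(overall, frameshift) {
    f0 <- 1 - overall / 100
    ffs <- frameshift / 100
    fif <- overall / 100 - ffs
    indel_spectrum(c("0" = f0, "-7" = ffs, "-9" = fif))
  }
  expect_true(screen_sgrna(mk(90, 55)))
  expect_false(screen_sgrna(mk(90, 45)))
  expect_true(screen_sgrna(mk(80, 50)))    # inclusive minimum thresholds
  expect_false(screen_sgrna(mk(79, 50)))
  expect_false(screen_sgrna(mk(80, 49)))
})

test_that("protein-effect prediction matches frame arithmetic on [-60, 60]", {
  eff <- predict_protein_effect(-9)
  expect_equal(eff$frame_status, "in_frame")
  expect_equal(eff$aa_deleted, 3L)
  expect_equal(predict_protein_effect(-7)$frame_status, "frameshift")
  expect_equal(predict_protein_effect(0)$frame_status, "wild_type")
  for (s in setdiff(-60:60, 0)) {
    e <- predict_protein_effect(s)
    expect_equal(e$frame_status == "frameshift", s %% 3 != 0)
    if (s %% 3 == 0 && s < 0) expect_equal(e$aa_deleted, abs(s) / 3)
    if (s %% 3 == 0 && s > 0) expect_equal(e$aa_inserted, s / 3)
  }
})

test_that("F1 genotype calling reproduces the three dosage classes", {
  ko <- call_genotype(c("-7" = 0.48, "32" = 0.47),
                      c("-23" = 0.49, "-7" = 0.46))
  expect_equal(ko$class_label, "full_KO")
  expect_equal(ko$functional_dose, 0L)

  partial <- call_genotype(c("-9" = 0.5, "-7" = 0.5),
                           c("-7" = 0.5, "1" = 0.5))
  expect_equal(partial$class_label, "partial")
  expect_equal(partial$functional_dose, 1L)

  two_copy <- call_genotype(c("-9" = 0.5, "-7" = 0.5),
                            c("-9" = 0.5, "1" = 0.5))
  expect_equal(two_copy$functional_dose, 2L)

  wt <- call_genotype(c("0" = 1), c("0" = 1))
  expect_equal(wt$class_label, "wild_type")
  expect_equal(wt$functional_dose, 4L)
})

test_that("genotype errors: no allele above floor, mosaic contamination", {
  expect_error(call_genotype(c("-7" = 0.1, "0" = 0.15), c("0" = 1)),
               "min_allele_freq")
  expect_error(call_genotype(c("-7" = 0.3, "-9" = 0.3, "1" = 0.3),
                             c("0" = 1)), "contaminated/mosaic")
})

test_that("functional dose is invariant to allele order and homeolog swap", {
  a <- call_genotype(c("-9" = 0.5, "-7" = 0.5), c("-7" = 0.5, "1" = 0.5))
  b <- call_genotype(c("-7" = 0.5, "-9" = 0.5), c("1" = 0.5, "-7" = 0.5))
  swapped <- call_genotype(c("-7" = 0.5, "1" = 0.5), c("-9" = 0.5, "-7" = 0.5))
  expect_equal(a$functional_dose, b$functional_dose)
  expect_equal(a$functional_dose, swapped$functional_dose)
  expect_equal(a$class_label, swapped$class_label)
})

test_that("trace round trip through the 5-column CSV reader", {
  sim <- simulate_sanger_traces(c("-7" = 0.6, "0" = 0.4), noise_sd = 0.02,
                                seed = 86)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(position = seq_len(nrow(sim$edited$peaks)),
                       sim$edited$peaks), path, row.names = FALSE)
  back <- read_trace_csv(path, cut_site = 100, source = "edited")
  expect_equal(back$peaks, sim$edited$peaks, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("F1 heterozygote traces close the loop through genotyping", {
  l_sim <- simulate_sanger_traces(c("-9" = 0.5, "-7" = 0.5), noise_sd = 0.02,
                                  seed = 87)
  s_sim <- simulate_sanger_traces(c("-7" = 0.5, "1" = 0.5), noise_sd = 0.02,
                                  seed = 88)
  sp_l <- decompose_indels(l_sim$control, l_sim$edited)
  sp_s <- decompose_indels(s_sim$control, s_sim$edited)
  g <- call_genotype(sp_l, sp_s)
  expect_equal(g$class_label, "partial")
  expect_equal(g$functional_dose, 1L)
  sizes_l <- sort(vapply(g$alleles_l, function(a) a$size, 0L))
  expect_equal(sizes_l, c(-9L, -7L))
})
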
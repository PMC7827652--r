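test_that("mid-Z selection implements the half-open middle band", {
  # enumerate the 21-slice stack: slice centre fractions (i + 0.5)/21 in
  # [0.4, 0.6) retain 0-based slices 8..12
  centres <- (0:20 + 0.5) / 21
  expected <- which(centres >= 0.4 & centres < 0.6) - 1L
  expect_identical(expected, 8:12)
  nuc <- tibble::tibble(z_centroid_fraction = centres)
  out <- select_mid_z(nuc, band = 0.2)
  expect_identical(which(out$in_mid_z) - 1L, expected)
  # boundary convention: lower edge in, upper edge out
  edges <- select_mid_z(tibble::tibble(z_centroid_fraction = c(0.4, 0.6)), 0.2)
  expect_identical(edges$in_mid_z, c(TRUE, FALSE))
  # full band keeps everything, including z = 1
  all_in <- select_mid_z(tibble::tibble(z_centroid_fraction = c(0, 0.5, 1)), 1)
  expect_true(all(all_in$in_mid_z))
})

test_that("mid-Z band of width b retains about a fraction b of uniform nuclei", {
  nuc <- simulate_catfish_population(ca1_only_config(n_nuclei = 4000))
  for (b in c(0.2, 0.5)) {
    frac <- mean(select_mid_z(nuc, band = b)$in_mid_z)
    expect_lt(abs(frac - b), 3 * sqrt(b * (1 - b) / nrow(nuc)))
  }
})

test_that("thresholds are the minimum over exploring-arm exemplars only", {
  nuc <- manual_nuclei()
  th <- derive_thresholds(nuc)
  expect_equal(th$threshold[th$channel == "e1"], 12.1)  # min{12.1, 13.0, 15.2}
  expect_equal(th$threshold[th$channel == "e2"], 14.0)
  # the home-cage animal's lower flagged intensities (9, 8) were ignored
  expect_identical(th$n_exemplars, c(3L, 3L))
  # a single exemplar is its own threshold
  one <- nuc[nuc$animal_id == "cE01", ]
  one$exemplar_weakest_e1 <- c(TRUE, FALSE, FALSE, FALSE)
  one$exemplar_weakest_e2 <- c(FALSE, TRUE, FALSE, FALSE)
  th1 <- derive_thresholds(one)
  expect_equal(th1$threshold[th1$channel == "e1"], 12.1)
  # a group with no exemplar errors, naming it
  none <- nuc
  none$exemplar_weakest_e1 <- FALSE
  expect_error(derive_thresholds(none), "slide01/CA1/e1",
               class = "checkfish_data_error")
})

test_that("classification applies the >= threshold rule per channel", {
  nuc <- manual_nuclei()
  th <- derive_thresholds(nuc)
  cls <- classify_nuclei(nuc, th)
  # both intensities below both thresholds -> negative
  expect_identical(as.character(cls$iEG_class[cls$animal_id == "cE01"][4]),
                   "negative")
  # intensity exactly at the threshold counts positive
  at <- nuc[1, ]
  at$intensity_e1_channel <- 12.1
  at$intensity_e2_channel <- 0
  expect_identical(as.character(classify_nuclei(at, th)$iEG_class), "homer_pos")
  # nucleus in a group without thresholds errors
  orphan <- nuc[1, ]
  orphan$slide_id <- "slide99"
  expect_error(classify_nuclei(orphan, th), "slide99",
               class = "checkfish_data_error")
})

test_that("raising a threshold never increases the positive fraction", {
  nuc <- simulate_catfish_population(ca1_only_config(n_nuclei = 400))
  prev <- 1
  for (thr in c(5, 10, 15, 20, 25, 40)) {
    th <- tibble::tibble(slide_id = "slide01", region = "CA1",
                         channel = c("e1", "e2"), threshold = thr,
                         n_exemplars = 1L)
    frac <- mean(classify_nuclei(nuc, th)$pos_e1)
    expect_lte(frac, prev)
    prev <- frac
  }
})

test_that("glia flagging needs small size AND odd shape/brightness AND no signal", {
  nuc <- manual_nuclei()
  th <- derive_thresholds(nuc)
  # identical sizes: no 'smaller' tail, nothing flagged
  out0 <- suppressWarnings(filter_glia(nuc, th))
  expect_true(all(out0$cell_type == "neuron"))
  # a small, elongated, bright nucleus with signal is never flagged
  mixed <- nuc
  mixed$size <- c(10, rep(100, 11))          # row 1 small
  mixed$elongation[1] <- 2.5
  mixed$counterstain_brightness[1] <- 200
  # row 1 has e1 = 12.1 >= threshold: supra-threshold signal protects it
  out <- suppressWarnings(filter_glia(mixed, th))
  expect_identical(out$cell_type[1], "neuron")
  # same nucleus without signal is flagged
  mixed$intensity_e1_channel[1] <- 0
  mixed$intensity_e2_channel[1] <- 0
  out2 <- suppressWarnings(filter_glia(mixed, th))
  expect_identical(out2$cell_type[1], "putative_glia")
  expect_warning(filter_glia(nuc[1:8, ], th), "fewer than 10")
})

test_that("a planted glia fraction is recovered on well-separated features", {
  cfg <- ca1_only_config(n_nuclei = 1000, glia_fraction = 0.2, seed = 51)
  nuc <- simulate_catfish_population(cfg)
  th <- derive_thresholds(nuc)
  out <- filter_glia(nuc, th)
  expect_lt(abs(mean(out$cell_type == "putative_glia") - 0.2), 0.03)
  # flagged nuclei are overwhelmingly true glia
  expect_gt(mean(out$latent_glia[out$cell_type == "putative_glia"]), 0.95)
})

test_that("region proportions count the four classes and their epoch marginals", {
  nuc <- tibble::tibble(
    animal_id = "a1", treatment = "control", environment = "A1A2",
    region = "CA1", slide_id = "s1",
    iEG_class = factor(rep(c("negative", "homer_pos", "arc_pos", "double_pos"),
                           c(60, 20, 15, 5)),
                       levels = c("negative", "homer_pos", "arc_pos", "double_pos")),
    included = TRUE)
  pr <- region_proportions(nuc)
  expect_identical(pr$n_included, 100L)
  expect_equal(c(pr$p_neg, pr$p_homer_only, pr$p_arc_only, pr$p_double),
               c(0.60, 0.20, 0.15, 0.05))
  expect_equal(pr$p_e1, 0.25)
  expect_equal(pr$p_e2, 0.20)
  expect_equal(pr$p_neg + pr$p_homer_only + pr$p_arc_only + pr$p_double, 1)
  # all-negative population
  allneg <- dplyr::mutate(nuc, iEG_class = factor("negative",
                                                  levels = levels(nuc$iEG_class)))
  expect_equal(region_proportions(allneg)$p_neg, 1)
  # a cell with zero included nuclei yields NA with a warning
  off <- dplyr::mutate(nuc, included = FALSE)
  expect_warning(pr0 <- region_proportions(off), "Zero included")
  expect_identical(pr0$n_included, 0L)
  expect_true(is.na(pr0$p_neg))
})

test_that("the full chain recovers latent classes almost perfectly when separated", {
  cfg <- ca1_only_config(n_nuclei = 1000, seed = 53)
  nuc <- simulate_catfish_population(cfg)
  res <- catfish_pipeline(nuc)
  inc <- res$nuclei[res$nuclei$included & !res$nuclei$latent_glia, ]
  agree1 <- mean(inc$pos_e1 == inc$latent_active_e1)
  agree2 <- mean(inc$pos_e2 == inc$latent_active_e2)
  expect_gte(agree1, 0.99)
  expect_gte(agree2, 0.99)
  # filtering conserves counts: included + excluded = total
  expect_identical(sum(res$nuclei$included) + sum(!res$nuclei$included),
                   nrow(nuc))
})

test_that("everything negative classifies as 100 percent negative", {
  cfg <- ca1_only_config(
    n_nuclei = 500, glia_fraction = 0, hc_baseline = 0,
    neg_intensity = c(location = 5, scale = 1),
    activity = tibble::tibble(region = "CA1", treatment = c("control", "QNP"),
                              p_e1 = 0, p_e2 = 0))
  nuc <- simulate_catfish_population(cfg)
  expect_true(all(!nuc$latent_active_e1 & !nuc$latent_active_e2))
  # with no true positives thresholds cannot be derived from exemplars;
  # classification against externally supplied thresholds returns all-negative
  th <- tibble::tibble(slide_id = "slide01", region = "CA1",
                       channel = c("e1", "e2"), threshold = 15, n_exemplars = 0L)
  cls <- classify_nuclei(select_mid_z(nuc), th)
  expect_true(all(cls$iEG_class[cls$included] == "negative"))
  expect_error(derive_thresholds(nuc), class = "checkfish_data_error")
})
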
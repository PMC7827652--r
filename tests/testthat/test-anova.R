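# design helper: the study's 2x2 day-11 layout with repeated sessions
null_design <- function(n = c(9, 9, 6, 5)) {
  animals <- tibble::tibble(
    animal_id = sprintf("a%02d", seq_len(sum(n))),
    treatment = rep(c("QNP", "control", "QNP", "control"), n),
    environment = rep(c("A1A2", "A1A2", "HC", "HC"), n))
  tidyr::expand_grid(animals, session = c("E1", "E2"))
}

test_that("mixed ANOVA reports the expected strata and terms", {
  set.seed(61)
  d <- null_design()
  d$value <- rnorm(nrow(d))
  out <- run_mixed_anova(d)
  between <- out$term[out$stratum == "Error: animal_id"]
  expect_true(all(c("treatment", "environment", "treatment:environment") %in% between))
  within <- out$term[out$stratum == "Error: Within"]
  expect_true("session" %in% within)
  expect_true("treatment:environment:session" %in% within)
  # between-subject df: 29 animals, 4 cells -> 25 residual df
  expect_identical(out$df[out$stratum == "Error: animal_id" &
                            out$term == "Residuals"], 25)
})

test_that("a planted treatment effect of two pooled SD is reliably detected", {
  set.seed(62)
  hits <- 0L
  reps <- 150L
  for (r in seq_len(reps)) {
    d <- null_design(c(9, 9, 0, 0))
    d$value <- rnorm(nrow(d)) + ifelse(d$treatment == "QNP", 2, 0)
    out <- run_mixed_anova(d)
    p <- out$p.value[out$term == "treatment" & out$stratum == "Error: animal_id"]
    hits <- hits + (p < 0.05)
  }
  expect_gt(hits / reps, 0.9)
})

test_that("zero within-cell variance is flagged as an infinite F", {
  d <- null_design(c(2, 2, 0, 0))
  d$value <- ifelse(d$treatment == "QNP", 1, 0) +
    ifelse(d$session == "E2", 0.1, 0)
  # both the between- and within-animal strata degenerate, one warning each
  expect_warning(
    expect_warning(out <- run_mixed_anova(d), "Zero within-cell variance"),
    "Zero within-cell variance")
  p <- out$p.value[out$term == "treatment" & out$stratum == "Error: animal_id"]
  expect_identical(p, 0)
})

test_that("similarity comparison excludes undefined scores and reports counts", {
  set.seed(63)
  sc <- tibble::tibble(
    animal_id = sprintf("a%d", 1:18),
    treatment = rep(c("QNP", "control"), each = 9),
    environment = "A1A2", region = "CA1",
    similarity = c(NA, rnorm(17, 0.3, 0.1)))
  out <- compare_similarity(sc)
  expect_identical(unique(out$n_excluded), 1L)
  expect_true(all(c("treatment", "Residuals") %in% out$term))
  # identical scores for everyone: no treatment effect, zero F
  flat <- dplyr::mutate(sc, similarity = 0.25)
  outf <- compare_similarity(flat)
  expect_equal(outf$statistic[outf$term == "treatment"], 0)
  # all-undefined region is skipped
  allna <- dplyr::mutate(sc, similarity = NA_real_)
  expect_error(expect_warning(compare_similarity(allna), "undefined"),
               class = "checkfish_data_error")
})

test_that("a planted between-arm overlap difference is detected through the full chain", {
  set.seed(64)
  detect <- 0L
  reps <- 40L
  for (r in seq_len(reps)) {
    scores <- lapply(c(QNP = 0.4, control = 0.0), function(s) {
      cfg <- catfish_sim_config(
        n_animals = c(QNP_A1A2 = 0, control_A1A2 = 9, QNP_HC = 0, control_HC = 0),
        n_nuclei_per_region = 300, regions = "CA1",
        overlap_similarity = s, glia_fraction = 0,
        seed = 1000L + 7L * r + round(100 * s))
      nuc <- simulate_catfish_population(cfg)
      props <- add_similarity(catfish_pipeline(nuc, band = 1)$proportions)
      props$similarity
    })
    p <- t.test(scores$QNP, scores$control)$p.value
    detect <- detect + (p < 0.05)
  }
  expect_gt(detect / reps, 0.8)
})

test_that("the F test agrees with a permutation oracle on a small balanced design", {
  set.seed(65)
  sc <- tibble::tibble(
    animal_id = sprintf("a%d", 1:16),
    treatment = rep(c("QNP", "control"), each = 8),
    environment = "A1A2", region = "CA1",
    similarity = rnorm(16, 0.3, 0.15) +
      ifelse(rep(c(TRUE, FALSE), each = 8), 0.12, 0))
  out <- compare_similarity(sc)
  p_f <- out$p.value[out$term == "treatment"]
  # permutation oracle: relabel treatments, recompute the mean difference
  obs <- abs(mean(sc$similarity[1:8]) - mean(sc$similarity[9:16]))
  perm <- replicate(4000, {
    idx <- sample(16, 8)
    abs(mean(sc$similarity[idx]) - mean(sc$similarity[-idx]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(p_f - p_perm), 0.05)
})
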
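test_that("the joint activity law inverts marginals + similarity exactly", {
  # perfect overlap: all actives are double-active
  expect_equal(joint_activity_law(0.3, 0.3, 1),
               c(p00 = 0.7, p10 = 0, p01 = 0, p11 = 0.3))
  # independence
  law0 <- joint_activity_law(0.4, 0.5, 0)
  expect_equal(unname(law0["p11"]), 0.2)
  expect_equal(sum(law0), 1)
  # zero marginals: everything negative, similarity has no effect
  expect_equal(unname(joint_activity_law(0, 0, 0.5)["p00"]), 1)
  # infeasible combination fails loudly
  expect_error(joint_activity_law(0.9, 0.9, -1), class = "checkfish_config_error")
  expect_error(catfish_sim_config(overlap_similarity = -1),
               class = "checkfish_config_error")
})

test_that("the nuclei generator is deterministic given config + seed", {
  a <- simulate_catfish_population(ca1_only_config(n_nuclei = 50))
  b <- simulate_catfish_population(ca1_only_config(n_nuclei = 50))
  expect_identical(a, b)
  c <- simulate_catfish_population(ca1_only_config(n_nuclei = 50, seed = 32))
  expect_false(identical(a$intensity_e1_channel, c$intensity_e1_channel))
})

test_that("latent marginals and overlap converge to the configured law", {
  cfg <- ca1_only_config(n_nuclei = 10000, glia_fraction = 0,
                         overlap_similarity = 0)
  nuc <- simulate_catfish_population(cfg)
  ctrl <- nuc[nuc$treatment == "control" & nuc$environment == "A1A2", ]
  n <- nrow(ctrl)
  se3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(ctrl$latent_active_e1) - 0.294), se3(0.294))
  expect_lt(abs(mean(ctrl$latent_active_e2) - 0.306), se3(0.306))
  # independence: empirical double fraction near the closed-form product
  pd <- mean(ctrl$latent_active_e1 & ctrl$latent_active_e2)
  expect_lt(abs(pd - 0.294 * 0.306), se3(0.294 * 0.306))
})

test_that("a similarity target planted in the generator is recovered from latent labels", {
  for (s in c(0.0, 0.3, 0.8)) {
    cfg <- ca1_only_config(n_nuclei = 10000, glia_fraction = 0,
                           overlap_similarity = s, seed = 40 + round(10 * s))
    nuc <- simulate_catfish_population(cfg)
    ctrl <- nuc[nuc$treatment == "control" & nuc$environment == "A1A2", ]
    res <- similarity_from_counts(
      sum(!ctrl$latent_active_e1 & !ctrl$latent_active_e2),
      sum(ctrl$latent_active_e1 & !ctrl$latent_active_e2),
      sum(!ctrl$latent_active_e1 & ctrl$latent_active_e2),
      sum(ctrl$latent_active_e1 & ctrl$latent_active_e2))
    expect_lt(abs(res$score - s), 0.05)
  }
})

test_that("perfect overlap yields doubles only, zero marginals yield all-negative", {
  cfg1 <- ca1_only_config(
    n_nuclei = 2000, glia_fraction = 0, overlap_similarity = 1,
    activity = tibble::tibble(region = "CA1", treatment = c("control", "QNP"),
                              p_e1 = 0.3, p_e2 = 0.3))
  nuc1 <- simulate_catfish_population(cfg1)
  expl <- nuc1[nuc1$environment == "A1A2", ]
  expect_identical(sum(expl$latent_active_e1 != expl$latent_active_e2), 0L)
  expect_equal(mean(expl$latent_active_e1), 0.3, tolerance = 0.05)
})

test_that("exemplar flags mark the weakest true actives of exploring animals only", {
  nuc <- simulate_catfish_population(ca1_only_config(n_nuclei = 500))
  expect_true(all(nuc$environment[nuc$exemplar_weakest_e1] == "A1A2"))
  expect_true(all(nuc$latent_active_e1[nuc$exemplar_weakest_e1]))
  for (sl in unique(nuc$slide_id)) {
    sel <- nuc$slide_id == sl & nuc$environment == "A1A2"
    flagged <- nuc$intensity_e1_channel[sel & nuc$exemplar_weakest_e1]
    if (length(flagged)) {
      actives <- nuc$intensity_e1_channel[sel & nuc$latent_active_e1]
      expect_lte(length(flagged), 3L)
      expect_equal(sort(flagged), sort(actives)[seq_along(flagged)])
    }
  }
})
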
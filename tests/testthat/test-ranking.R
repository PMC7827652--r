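make_visit_rows <- function(animal, counts, day = 1, session = "daily",
                            group = "QNP") {
  tibble::tibble(animal_id = animal, group = group, day = day,
                 session = session,
                 zone_id = c("corner_NW", "corner_NE", "corner_SW", "corner_SE",
                             "object_1", "object_2"),
                 n_visits = as.integer(counts))
}

test_that("zones are ranked A-F by summed visits with the documented tie rule", {
  v <- make_visit_rows("a1", c(50, 10, 5, 3, 2, 1))
  rm <- rank_zones(v, days = 1)
  expect_identical(as.character(rm$rank), LETTERS[1:6])
  expect_identical(rm$zone_id[rm$rank == "A"], "corner_NW")
  expect_identical(rm$zone_id[rm$rank == "F"], "object_2")
  # all-tied counts fall back to the fixed zone enumeration order
  tied <- rank_zones(make_visit_rows("a1", rep(4, 6)), days = 1)
  expect_identical(tied$zone_id,
                   c("corner_NW", "corner_NE", "corner_SW", "corner_SE",
                     "object_1", "object_2"))
  expect_error(rank_zones(v, days = 1:2), class = "checkfish_data_error")
})

test_that("summed counts never increase along the A-F ranking", {
  set.seed(5)
  for (rep in 1:20) {
    days <- 1:3
    v <- dplyr::bind_rows(lapply(days, function(d) {
      make_visit_rows("a1", rpois(6, 8), day = d)
    }))
    rm <- rank_zones(v, days = days)
    expect_true(all(diff(rm$total_visits) <= 0))
  }
})

test_that("rank pooling aligns idiosyncratic patterns", {
  # two animals with disjoint preferred zones but identical count profiles
  v <- dplyr::bind_rows(
    make_visit_rows("a1", c(50, 10, 5, 3, 2, 1)),
    make_visit_rows("a2", c(1, 2, 3, 5, 10, 50)))
  rm <- rank_zones(v, days = 1)
  pooled <- pooled_zone_matrix(v, rm)
  expect_equal(pooled$mean_visits[order(pooled$rank)], c(50, 10, 5, 3, 2, 1))
  expect_true(all(pooled$sd_visits == 0))
  # a single animal's pooled matrix is its own counts
  solo <- pooled_zone_matrix(make_visit_rows("a1", c(9, 8, 0, 4, 2, 7)),
                             rank_zones(make_visit_rows("a1", c(9, 8, 0, 4, 2, 7)),
                                        days = 1))
  expect_setequal(solo$mean_visits, c(9, 8, 0, 4, 2, 7))
})

test_that("session standardization converts day-10 counts to visits per 5 min", {
  v <- dplyr::bind_rows(
    make_visit_rows("a1", c(40, 0, 10, 5, 3, 2), day = 10),
    make_visit_rows("a1", c(4, 0, 1, 1, 0, 0), day = 11, session = "A1"),
    make_visit_rows("a1", c(5, 0, 2, 0, 0, 0), day = 11, session = "A2"))
  st <- standardize_sessions(v)
  d10 <- st[st$session == "day10", ]
  expect_equal(d10$visits_per_5min[d10$zone_id == "corner_NW"], 4.0)
  expect_equal(d10$visits_per_5min[d10$zone_id == "corner_NE"], 0)
  a1 <- st[st$session == "A1", ]
  expect_equal(a1$visits_per_5min[a1$zone_id == "corner_NW"], 4.0)
  # standardization preserves within-session count ratios
  expect_equal(d10$visits_per_5min / sum(d10$visits_per_5min),
               d10$n_visits / sum(d10$n_visits))
  expect_error(standardize_sessions(v[v$session != "A2", ]),
               class = "checkfish_data_error")
  expect_error(standardize_sessions(v, day10_length = 100, a_length = 300),
               class = "checkfish_data_error")
})

test_that("sensitization summary is flat without growth and flags degenerate input", {
  cfg <- small_behavior_config(seed = 21, sensitization_factor = 1,
                               n_qnp = 4, session_length = 300)
  sens <- sensitization_summary(simulate_trajectories(cfg))
  qnp <- sens[sens$group == "QNP", ]
  expect_equal(qnp$ratio_to_day1[qnp$day == 2], 1, tolerance = 0.15)
  # stationary animal: zero path on every day, NaN ratio with a warning
  still <- list(
    trajectory("s", "control", 1, "daily", t = 0:9, x = rep(1, 10), y = rep(1, 10)),
    trajectory("s", "control", 2, "daily", t = 0:9, x = rep(1, 10), y = rep(1, 10)))
  expect_warning(out <- sensitization_summary(still), "NaN")
  expect_true(all(out$mean_path_cm == 0))
  expect_true(all(is.nan(out$ratio_to_day1)))
})
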
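# Independent oracles and small fixture builders used across the suite.

# Per-frame state-machine oracle for visit detection: a plain loop over every
# sample, kept deliberately separate from the vectorized implementation.
oracle_detect_visits <- function(traj, zones, min_dwell = 0.5, hysteresis = 2) {
  out <- list()
  n <- nrow(traj)
  for (k in seq_len(nrow(zones))) {
    d <- sqrt((traj$x - zones$anchor_x[k])^2 + (traj$y - zones$anchor_y[k])^2)
    inside <- FALSE
    t_enter <- NA_real_
    for (i in seq_len(n)) {
      if (!inside) {
        if (d[i] <= zones$radius[k]) {
          inside <- TRUE
          t_enter <- traj$t[i]
        }
      } else if (d[i] > zones$radius[k] + hysteresis) {
        if (traj$t[i] - t_enter >= min_dwell) {
          out[[length(out) + 1L]] <- data.frame(zone_id = zones$zone_id[k],
                                                t_enter = t_enter,
                                                t_exit = traj$t[i])
        }
        inside <- FALSE
      }
    }
    if (inside && traj$t[n] - t_enter >= min_dwell) {
      out[[length(out) + 1L]] <- data.frame(zone_id = zones$zone_id[k],
                                            t_enter = t_enter, t_exit = traj$t[n])
    }
  }
  ev <- if (length(out)) do.call(rbind, out) else {
    data.frame(zone_id = character(), t_enter = numeric(), t_exit = numeric())
  }
  ev[order(ev$zone_id, ev$t_enter), , drop = FALSE]
}

# loop summation oracle for path length
oracle_path_length <- function(traj) {
  total <- 0
  for (i in 2:nrow(traj)) {
    total <- total + sqrt((traj$x[i] - traj$x[i - 1])^2 +
                            (traj$y[i] - traj$y[i - 1])^2)
  }
  total
}

# similarity score by brute-force enumeration of the 2x2 activity table built
# from individual nucleus labels
oracle_similarity_from_counts <- function(n_neg, n_e1_only, n_e2_only, n_double) {
  a1 <- c(rep(FALSE, n_neg), rep(TRUE, n_e1_only), rep(FALSE, n_e2_only),
          rep(TRUE, n_double))
  a2 <- c(rep(FALSE, n_neg), rep(FALSE, n_e1_only), rep(TRUE, n_e2_only),
          rep(TRUE, n_double))
  tab <- table(a1, a2)
  p1 <- mean(a1); p2 <- mean(a2)
  pd <- tab["TRUE", "TRUE"] / length(a1)
  (pd - p1 * p2) / (min(p1, p2) - p1 * p2)
}

# reflective random-walk trajectory that wanders across zone boundaries
random_walk_traj <- function(seed, n = 1200, dt = 0.04, side = 95, step_sd = 1.2) {
  set.seed(seed)
  x <- numeric(n); y <- numeric(n)
  x[1] <- runif(1, 0, side); y[1] <- runif(1, 0, side)
  dx <- cumsum(rnorm(n - 1, 0, step_sd)) + x[1]
  dy <- cumsum(rnorm(n - 1, 0, step_sd)) + y[1]
  reflect <- function(v) {
    v <- v %% (2 * side)
    ifelse(v > side, 2 * side - v, v)
  }
  trajectory(sprintf("rw%d", seed), "control", 1, "daily",
             t = seq_len(n) * dt, x = reflect(c(x[1], dx)), y = reflect(c(y[1], dy)))
}

# small behavior config for fast module tests
small_behavior_config <- function(seed = 1, n_qnp = 2, n_control = 2,
                                  n_days = 2, session_length = 120, ...) {
  behavior_sim_config(n_qnp = n_qnp, n_control = n_control, n_days = n_days,
                      session_length = session_length, frame_rate = 10,
                      seed = seed, ...)
}

# one-region catFISH config with the published CA1 marginals, small cohort
ca1_only_config <- function(..., n_nuclei = 1000, seed = 31,
                            activity = tibble::tibble(
                              region = "CA1", treatment = c("control", "QNP"),
                              p_e1 = c(0.294, 0.112), p_e2 = c(0.306, 0.207))) {
  catfish_sim_config(
    n_animals = c(QNP_A1A2 = 1, control_A1A2 = 2, QNP_HC = 0, control_HC = 1),
    n_nuclei_per_region = n_nuclei, regions = "CA1",
    activity = activity, seed = seed, ...)
}

# a minimal hand-built nucleus table: one slide, one region, one exploring
# animal per arm plus one home-cage animal whose (lower) flagged intensities
# must not influence the thresholds
manual_nuclei <- function() {
  tibble::tibble(
    animal_id = rep(c("cE01", "qE01", "cH01"), each = 4),
    treatment = rep(c("control", "QNP", "control"), each = 4),
    environment = rep(c("A1A2", "A1A2", "HC"), each = 4),
    region = "CA1",
    slide_id = "slide01",
    z_centroid_fraction = 0.5,
    size = 100, elongation = 1.2, counterstain_brightness = 100,
    intensity_e1_channel = c(12.1, 2, 13.0, 3, 15.2, 2, 1, 3, 9, 2, 1, 3),
    intensity_e2_channel = c(2, 14.5, 16.0, 3, 2, 14.0, 1, 3, 8, 2, 1, 3),
    exemplar_weakest_e1 = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE,
                            TRUE, FALSE, FALSE, FALSE),
    exemplar_weakest_e2 = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE,
                            TRUE, FALSE, FALSE, FALSE))
}
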
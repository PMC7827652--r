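#' Configuration for the synthetic open-field behavior generator
#'
#' The generator emulates the checking assay: daily 50-min exposures of a
#' drug-sensitized (QNP) and a saline (control) arm to the object-enriched
#' arena for `n_days` days, plus two 5-min sessions (A1, A2) on day 11.
#' Movement is bout-based: each bout is a goal-directed segment followed by a
#' dwell at the goal. QNP animals are assigned one idiosyncratic preferred
#' corner and one preferred object (a deterministic function of seed and
#' animal index) and direct a fraction `home_zone_attraction` of their bouts
#' at this pair, looping object -> corner and re-checking the corner with
#' probability `corner_recheck` before heading back to the object — so the
#' corner dominates the pair, as checking animals' most-visited location does.
#' Sensitization multiplies bout speed by `sensitization_factor^(day - 1)` and
#' divides dwell times by the same factor (the whole checking cycle
#' accelerates), which makes the expected session path length grow exactly
#' geometrically. Controls pick goals with a mild wall bias and no persistent
#' zone preference, at constant speed.
#'
#' @param n_qnp,n_control Animals per arm.
#' @param n_days Number of daily 50-min exposure days (day 11 with sessions
#'   A1/A2 is always appended).
#' @param session_length Daily session length, s.
#' @param frame_rate Sampling rate, Hz.
#' @param arena An [arena_spec()].
#' @param base_speed Goal-directed movement speed on day 1, cm/s.
#' @param max_speed Hard upper bound on instantaneous speed, cm/s (enforced
#'   sample-to-sample).
#' @param sensitization_factor Per-day multiplicative locomotion growth for
#'   the QNP arm; must be >= 1.
#' @param home_zone_attraction Probability that a QNP bout targets the
#'   animal's preferred corner/object pair, in `[0, 1]`.
#' @param corner_recheck Probability that a preference bout at the corner
#'   re-checks the corner (brief excursion and return) instead of moving on to
#'   the object.
#' @param dwell_mean Mean dwell at a goal on day 1, s (exponentially
#'   distributed).
#' @param wall_bias Probability that a non-preference goal is drawn from the
#'   10-cm wall band rather than uniformly over the arena.
#' @param seed Master seed; identical config + seed gives identical output.
#' @return A `behavior_sim_config` object.
#' @export
behavior_sim_config <- function(n_qnp = 15, n_control = 14, n_days = 10,
                                session_length = 3000, frame_rate = 25,
                                arena = arena_spec(),
                                base_speed = 10, max_speed = 150,
                                sensitization_factor = 1.15,
                                home_zone_attraction = 0.7,
                                corner_recheck = 0.4,
                                dwell_mean = 5, wall_bias = 0.5,
                                seed = 1L) {
  n_qnp <- stopifnot_count(n_qnp, "n_qnp", min = 0L)
  n_control <- stopifnot_count(n_control, "n_control", min = 0L)
  if (n_qnp + n_control == 0L) {
    abort("Need at least one animal.", class = "checkfish_config_error")
  }
  n_days <- stopifnot_count(n_days, "n_days")
  stopifnot_scalar_number(session_length, "session_length", min = 1)
  stopifnot_scalar_number(frame_rate, "frame_rate", min = 1e-9)
  stopifnot_scalar_number(base_speed, "base_speed", min = 1e-9)
  stopifnot_scalar_number(max_speed, "max_speed", min = base_speed)
  stopifnot_scalar_number(sensitization_factor, "sensitization_factor", min = 1)
  stopifnot_scalar_number(home_zone_attraction, "home_zone_attraction",
                          min = 0, max = 1)
  stopifnot_scalar_number(corner_recheck, "corner_recheck", min = 0, max = 1)
  stopifnot_scalar_number(dwell_mean, "dwell_mean", min = 1e-9)
  stopifnot_scalar_number(wall_bias, "wall_bias", min = 0, max = 1)
  seed <- stopifnot_count(seed, "seed", min = 0L)
  if (!inherits(arena, "arena_spec")) {
    abort("`arena` must be an arena_spec.", class = "checkfish_config_error")
  }
  structure(as.list(environment()), class = "behavior_sim_config")
}

# deterministic idiosyncratic zone pair for QNP animal i
preferred_pair <- function(seed, i) {
  corners <- zone_levels()[1:4]
  objects <- zone_levels()[5:6]
  list(corner = corners[(seed + 7L * i) %% 4L + 1L],
       object = objects[(seed + 3L * i) %% 2L + 1L])
}

# one goal-directed leg: straight line plus lateral Brownian-bridge noise
# whose amplitude scales with the step length, so noise multiplies rather
# than offsets the path length
sim_leg <- function(from, to, speed, dt, noise_frac = 0.35) {
  d <- sqrt(sum((to - from)^2))
  n <- max(2L, as.integer(ceiling(d / (speed * dt))))
  fr <- seq(0, 1, length.out = n + 1L)[-1L]
  bx <- from[1] + fr * (to[1] - from[1])
  by <- from[2] + fr * (to[2] - from[2])
  step <- d / n
  e <- cumsum(stats::rnorm(n, 0, noise_frac * step))
  bridge <- e - fr * e[n]
  u <- (to - from) / max(d, 1e-12)   # unit direction; perpendicular (-uy, ux)
  cbind(bx - bridge * u[2], by + bridge * u[1])
}

sim_session_frames <- function(start, n_frames, dt, speed, dwell_mean, arena,
                               goal_fun, max_speed) {
  out <- matrix(NA_real_, n_frames, 2)
  cur <- start
  filled <- 0L
  while (filled < n_frames) {
    goal <- goal_fun(cur)
    seg <- NULL
    for (wp in goal$waypoints) {
      seg <- rbind(seg, sim_leg(cur, wp, speed, dt))
      cur <- wp
    }
    n_dwell <- max(1L, as.integer(round(stats::rexp(1, 1 / dwell_mean) / dt)))
    dwell <- cbind(cur[1] + stats::rnorm(n_dwell, 0, 0.02),
                   cur[2] + stats::rnorm(n_dwell, 0, 0.02))
    seg <- rbind(seg, dwell)
    take <- min(nrow(seg), n_frames - filled)
    out[filled + seq_len(take), ] <- seg[seq_len(take), , drop = FALSE]
    filled <- filled + take
  }
  # enforce the speed bound (scale over-long steps), then project into the
  # arena; both operations are 1-Lipschitz so neither can re-break the other
  steps <- diff(rbind(start, out))
  norms <- sqrt(rowSums(steps^2))
  scale <- pmin(1, (max_speed * dt) / pmax(norms, 1e-12))
  steps <- steps * scale
  out <- cbind(start[1] + cumsum(steps[, 1]), start[2] + cumsum(steps[, 2]))
  eps <- 1e-9
  out[, 1] <- pmin(pmax(out[, 1], 0 + eps), arena$side - eps)
  out[, 2] <- pmin(pmax(out[, 2], 0 + eps), arena$side - eps)
  out
}

# goal picker factories; each returns list(waypoints = list of c(x, y))
make_goal_fun <- function(group, config, pair, state_env) {
  arena <- config$arena
  s <- arena$side
  zones <- build_zones_impl(arena)
  anchor <- function(zid) {
    k <- match(zid, zones$zone_id)
    c(zones$anchor_x[k], zones$anchor_y[k])
  }
  rand_goal <- function() {
    if (stats::runif(1) < config$wall_bias) {
      edge <- sample.int(4L, 1L)
      along <- stats::runif(1, 2, s - 2)
      depth <- stats::runif(1, 2, 10)
      switch(edge, c(along, depth), c(along, s - depth),
             c(depth, along), c(s - depth, along))
    } else {
      c(stats::runif(1, 2, s - 2), stats::runif(1, 2, s - 2))
    }
  }
  corner_goal <- function() {
    a <- anchor(pair$corner)
    # point inside the quarter-disc, a little off the vertex
    r <- stats::runif(1, 0.2, 0.55) * arena$corner_zone_radius
    th <- stats::runif(1, 0.1, pi / 2 - 0.1)
    dx <- r * cos(th); dy <- r * sin(th)
    c(if (a[1] == 0) dx else s - dx, if (a[2] == 0) dy else s - dy)
  }
  object_goal <- function() {
    a <- anchor(pair$object)
    r <- stats::runif(1, 0, 0.5) * arena$object_zone_radius
    th <- stats::runif(1, 0, 2 * pi)
    a + r * c(cos(th), sin(th))
  }
  function(cur) {
    if (group == "QNP" && stats::runif(1) < config$home_zone_attraction) {
      if (identical(state_env$at, "corner") &&
          stats::runif(1) < config$corner_recheck) {
        # corner re-check: brief wall-hugging excursion out of the zone and
        # back; staying along the walls keeps it clear of the object zones
        a <- anchor(pair$corner)
        along <- stats::runif(1, arena$corner_zone_radius + 8,
                              arena$corner_zone_radius + 25)
        depth <- stats::runif(1, 3, 8)
        sgn <- c(if (a[1] == 0) 1 else -1, if (a[2] == 0) 1 else -1)
        ex <- if (stats::runif(1) < 0.5) {
          c(a[1] + sgn[1] * along, a[2] + sgn[2] * depth)
        } else {
          c(a[1] + sgn[1] * depth, a[2] + sgn[2] * along)
        }
        return(list(waypoints = list(ex, corner_goal())))
      }
      if (identical(state_env$at, "corner")) {
        state_env$at <- "object"
        return(list(waypoints = list(object_goal())))
      }
      state_env$at <- "corner"
      return(list(waypoints = list(corner_goal())))
    }
    list(waypoints = list(rand_goal()))
  }
}

#' Simulate open-field trajectories for a two-arm cohort
#'
#' Generates one daily trajectory per animal for days `1..n_days` plus the two
#' 300-s day-11 sessions A1 and A2 for every animal, all inside the arena and
#' reproducible bit-for-bit from the config seed. Each animal runs on its own
#' sub-stream spawned deterministically from the master seed.
#'
#' @param config A [behavior_sim_config()].
#' @return A named list of [trajectory()] objects
#'   (`<animal>_d<day>_<session>`), with attribute `ground_truth`: a tibble of
#'   each animal's arm and (for QNP) assigned preferred corner and object.
#' @export
simulate_trajectories <- function(config) {
  if (!inherits(config, "behavior_sim_config")) {
    abort("`config` must come from behavior_sim_config().",
          class = "checkfish_config_error")
  }
  animals <- tibble(
    animal_id = c(sprintf("q%02d", seq_len(config$n_qnp)),
                  sprintf("c%02d", seq_len(config$n_control))),
    group = rep(c("QNP", "control"), c(config$n_qnp, config$n_control)))
  seeds <- spawn_seeds(config$seed, nrow(animals))
  animals$sub_seed <- seeds
  truth <- list()
  out <- list()
  dt <- 1 / config$frame_rate
  for (i in seq_len(nrow(animals))) {
    id <- animals$animal_id[i]
    grp <- animals$group[i]
    pair <- if (grp == "QNP") preferred_pair(config$seed, i) else
      list(corner = NA_character_, object = NA_character_)
    truth[[i]] <- tibble(animal_id = id, group = grp, sub_seed = seeds[i],
                         pref_corner = pair$corner, pref_object = pair$object)
    out_i <- with_seed(seeds[i], {
      sessions <- list()
      start <- c(stats::runif(1, 3, 8), stats::runif(1, 3, 8))
      state_env <- new.env(parent = emptyenv())
      state_env$at <- "object"   # first preference bout heads to the corner
      goal_fun <- make_goal_fun(grp, config, pair, state_env)
      schedule <- rbind(
        data.frame(day = seq_len(config$n_days), session = "daily",
                   len = config$session_length),
        data.frame(day = config$n_days + 1L, session = c("A1", "A2"), len = 300))
      for (r in seq_len(nrow(schedule))) {
        day <- schedule$day[r]
        g <- if (grp == "QNP") config$sensitization_factor^(day - 1) else 1
        n_frames <- as.integer(round(schedule$len[r] * config$frame_rate))
        xy <- sim_session_frames(
          start, n_frames, dt,
          speed = min(config$base_speed * g, config$max_speed * 0.8),
          dwell_mean = config$dwell_mean / g,
          arena = config$arena, goal_fun = goal_fun,
          max_speed = config$max_speed)
        sessions[[sprintf("%s_d%d_%s", id, day, schedule$session[r])]] <-
          trajectory(id, grp, day, schedule$session[r],
                     t = seq_len(n_frames) * dt, x = xy[, 1], y = xy[, 2],
                     arena = config$arena)
        start <- c(xy[n_frames, 1], xy[n_frames, 2])
      }
      sessions
    })
    out <- c(out, out_i)
  }
  structure(out, ground_truth = dplyr::bind_rows(truth))
}
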
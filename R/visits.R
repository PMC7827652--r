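#' Detect zone visits in a trajectory
#'
#' A visit requires the animal to engage with the object or corner; brief
#' transits through a zone do not count. Per zone, an episode opens
#' at an outside-to-inside transition of the head point (distance to the zone
#' anchor <= radius), the animal then remains "in" until the head exceeds
#' `radius + hysteresis`, and the episode is counted as a visit only when its
#' duration (entry sample to exit) is at least `min_dwell` seconds. An episode
#' still open at the end of the trajectory is counted when its observed
#' duration already reaches `min_dwell`. Timing is sample-based (no
#' interpolation between frames): `t_enter` is the time of the first inside
#' sample, `t_exit` the time of the first sample beyond the hysteresis radius
#' (or the last sample for an unclosed episode).
#'
#' @param traj A [trajectory()].
#' @param zones Zone table from [build_zones()].
#' @param min_dwell Minimum episode duration in s for a visit to be counted.
#' @param hysteresis Extra exit radius in cm; the episode closes only when the
#'   head is farther than `radius + hysteresis` from the anchor.
#' @return A tibble of visit events: `zone_id`, `t_enter`, `t_exit`, `dwell`.
#' @export
detect_visits <- function(traj, zones, min_dwell = 0.5, hysteresis = 2) {
  stopifnot_scalar_number(min_dwell, "min_dwell", min = 0)
  stopifnot_scalar_number(hysteresis, "hysteresis", min = 0)
  t <- traj$t; x <- traj$x; y <- traj$y
  n <- length(t)
  events <- vector("list", nrow(zones))
  for (k in seq_len(nrow(zones))) {
    d2 <- (x - zones$anchor_x[k])^2 + (y - zones$anchor_y[k])^2
    in_core <- d2 <= zones$radius[k]^2
    in_ext <- d2 <= (zones$radius[k] + hysteresis)^2
    # vectorized hysteresis state: "in" iff the most recent core entry is more
    # recent than the most recent full exit
    idx <- seq_len(n)
    last_set <- cummax(ifelse(in_core, idx, 0L))
    last_reset <- cummax(ifelse(!in_ext, idx, 0L))
    state <- last_set > 0L & last_set > last_reset
    if (!any(state)) next
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    starts <- starts[r$values]
    ends <- ends[r$values]
    # exit time: first sample beyond radius + hysteresis, i.e. the sample
    # after the run; unclosed runs end at the last sample
    t_exit <- ifelse(ends < n, t[pmin(ends + 1L, n)], t[n])
    keep <- (t_exit - t[starts]) >= min_dwell
    if (!any(keep)) next
    events[[k]] <- tibble(zone_id = zones$zone_id[k],
                          t_enter = t[starts][keep],
                          t_exit = t_exit[keep])
  }
  out <- dplyr::bind_rows(events)
  if (nrow(out) == 0) {
    out <- tibble(zone_id = character(), t_enter = numeric(), t_exit = numeric())
  }
  out <- dplyr::arrange(out, .data$t_enter)
  out$dwell <- out$t_exit - out$t_enter
  out
}

#' Count zone visits across a collection of trajectories
#'
#' Runs [detect_visits()] on every trajectory and tabulates visits per
#' animal x day x session x zone, with zeros for unvisited zones.
#'
#' @param trajs A list of [trajectory()] objects.
#' @param zones Zone table from [build_zones()].
#' @inheritParams detect_visits
#' @return A tibble: `animal_id`, `group`, `day`, `session`, `zone_id`,
#'   `n_visits`.
#' @export
zone_visit_table <- function(trajs, zones, min_dwell = 0.5, hysteresis = 2) {
  rows <- lapply(trajs, function(tr) {
    ev <- detect_visits(tr, zones, min_dwell = min_dwell, hysteresis = hysteresis)
    counts <- table(factor(ev$zone_id, levels = zone_levels()))
    dplyr::bind_cols(traj_meta(tr),
                     tibble(zone_id = zone_levels(),
                            n_visits = as.integer(counts)))
  })
  dplyr::bind_rows(rows)
}
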
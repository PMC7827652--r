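#' Rank zones A-F per animal from summed visit counts
#'
#' Sums visits to each of the six zones over the requested days (the daily
#' sessions only) separately for each animal, then labels zones from the most
#' visited ("A") to the least visited ("F"). This per-animal relabeling lets
#' animals with different idiosyncratic spatial patterns be pooled. Ties are
#' broken by the fixed zone enumeration order (corner_NW, corner_NE,
#' corner_SW, corner_SE, object_1, object_2).
#'
#' @param visits A visit table from [zone_visit_table()].
#' @param days Days whose daily-session counts are summed (default 1-10).
#' @return A tibble: `animal_id`, `group`, `zone_id`, `total_visits`, `rank`
#'   (factor with levels A-F).
#' @export
rank_zones <- function(visits, days = 1:10) {
  daily <- dplyr::filter(visits, .data$session == "daily", .data$day %in% days)
  present <- dplyr::distinct(daily, .data$animal_id, .data$day)
  missing_days <- setdiff(days, unique(daily$day))
  if (length(missing_days)) {
    abort(sprintf("No daily-session counts for day(s) %s.",
                  paste(missing_days, collapse = ", ")),
          class = "checkfish_data_error")
  }
  per_animal_days <- dplyr::count(present, .data$animal_id, name = "n_days")
  if (any(per_animal_days$n_days != length(days))) {
    bad <- per_animal_days$animal_id[per_animal_days$n_days != length(days)]
    abort(sprintf("Animal(s) %s lack counts for some requested days.",
                  paste(bad, collapse = ", ")),
          class = "checkfish_data_error")
  }
  sums <- daily %>%
    dplyr::group_by(.data$animal_id, .data$group, .data$zone_id) %>%
    dplyr::summarise(total_visits = sum(.data$n_visits), .groups = "drop")
  per_zone <- dplyr::count(sums, .data$animal_id, name = "n_zones")
  if (any(per_zone$n_zones != 6L)) {
    abort("Each animal needs counts for all 6 zones.",
          class = "checkfish_data_error")
  }
  sums %>%
    dplyr::group_by(.data$animal_id, .data$group) %>%
    dplyr::arrange(dplyr::desc(.data$total_visits),
                   match(.data$zone_id, zone_levels()),
                   .by_group = TRUE) %>%
    dplyr::mutate(rank = factor(LETTERS[1:6], levels = LETTERS[1:6])) %>%
    dplyr::ungroup()
}

#' Pool visit counts across animals by rank label
#'
#' Joins each animal's A-F rank map onto its per-day visit counts and
#' averages within a group, aligning idiosyncratic spatial patterns so that
#' "zone A" means each animal's own most-visited location.
#'
#' @param visits A visit table from [zone_visit_table()].
#' @param rank_map Output of [rank_zones()].
#' @param group Optional group filter (`"QNP"` or `"control"`).
#' @return A tibble per group x day x session x rank: `mean_visits`,
#'   `sd_visits`, `n_animals`.
#' @export
pooled_zone_matrix <- function(visits, rank_map, group = NULL) {
  if (!is.null(group)) {
    visits <- dplyr::filter(visits, .data$group == !!group)
  }
  visits %>%
    dplyr::inner_join(dplyr::select(rank_map, "animal_id", "zone_id", "rank"),
                      by = c("animal_id", "zone_id")) %>%
    dplyr::group_by(.data$group, .data$day, .data$session, .data$rank) %>%
    dplyr::summarise(mean_visits = mean(.data$n_visits),
                     sd_visits = stats::sd(.data$n_visits),
                     n_animals = dplyr::n_distinct(.data$animal_id),
                     .groups = "drop")
}

#' Standardize day-10 and day-11 session counts to a common rate
#'
#' The 50-min day-10 exposure and the two 5-min day-11 sessions (A1, A2) are
#' made directly comparable by expressing all visit counts as visits per
#' 5 min: day-10 counts are divided by 10, A1/A2 counts are unchanged.
#'
#' @param visits A visit table from [zone_visit_table()] containing the day-10
#'   daily session and the day-11 A1/A2 sessions.
#' @param reference_day Day whose daily session is the long-exposure
#'   reference (default 10).
#' @param day10_length,a_length Session lengths in s (defaults 3000 and 300,
#'   the 50-min vs 5-min design); the reference counts are divided by their
#'   ratio. Non-positive or inverted lengths are a data error.
#' @return A tibble with column `visits_per_5min` and a `session` factor with
#'   levels `day10`, `A1`, `A2`.
#' @export
standardize_sessions <- function(visits, reference_day = 10,
                                 day10_length = 3000, a_length = 300) {
  if (!is.finite(day10_length) || !is.finite(a_length) ||
      day10_length <= 0 || a_length <= 0 || day10_length < a_length) {
    abort("Mismatched session lengths: the daily exposure must be at least as long as A1/A2.",
          class = "checkfish_data_error")
  }
  ratio <- day10_length / a_length
  d10 <- dplyr::filter(visits, .data$day == reference_day, .data$session == "daily")
  a1 <- dplyr::filter(visits, .data$session == "A1")
  a2 <- dplyr::filter(visits, .data$session == "A2")
  if (nrow(d10) == 0 || nrow(a1) == 0 || nrow(a2) == 0) {
    abort("Need reference-day daily counts and day-11 A1/A2 counts.",
          class = "checkfish_data_error")
  }
  dplyr::bind_rows(
    dplyr::mutate(d10, visits_per_5min = .data$n_visits / ratio, session = "day10"),
    dplyr::mutate(a1, visits_per_5min = as.numeric(.data$n_visits)),
    dplyr::mutate(a2, visits_per_5min = as.numeric(.data$n_visits))) %>%
    dplyr::mutate(session = factor(.data$session, levels = c("day10", "A1", "A2"))) %>%
    dplyr::select("animal_id", "group", "session", "zone_id", "n_visits",
                  "visits_per_5min")
}

#' Locomotor sensitization summary
#'
#' Per-group, per-day mean path length with dispersion, plus each day's ratio
#' to the day-1 mean. Repeated dopamine-agonist dosing shows up as a
#' day-over-day increase of this curve in the treated arm.
#'
#' @param trajs A list of [trajectory()] objects (daily sessions are used).
#' @return A tibble: `group`, `day`, `n_animals`, `mean_path_cm`,
#'   `sd_path_cm`, `ratio_to_day1`. The ratio is `NaN` (with a warning) when
#'   the day-1 mean is zero.
#' @export
sensitization_summary <- function(trajs) {
  rows <- dplyr::bind_rows(lapply(trajs, function(tr) {
    dplyr::bind_cols(traj_meta(tr), tibble(path_cm = path_length(tr)))
  }))
  rows <- dplyr::filter(rows, .data$session == "daily")
  if (nrow(rows) == 0 || dplyr::n_distinct(rows$day) < 2) {
    abort("Need daily sessions on >= 2 days.", class = "checkfish_data_error")
  }
  out <- rows %>%
    dplyr::group_by(.data$group, .data$day) %>%
    dplyr::summarise(n_animals = dplyr::n(),
                     mean_path_cm = mean(.data$path_cm),
                     sd_path_cm = stats::sd(.data$path_cm),
                     .groups = "drop_last") %>%
    dplyr::mutate(ratio_to_day1 =
                    .data$mean_path_cm / .data$mean_path_cm[.data$day == 1][1]) %>%
    dplyr::ungroup()
  if (any(!is.finite(out$ratio_to_day1))) {
    warn("Day-1 mean path length is zero for some group; ratios set to NaN.")
  }
  out
}
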
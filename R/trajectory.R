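#' Construct a head trajectory for one animal-session
#'
#' A trajectory is the time-stamped head position of one animal in one session
#' (a daily 50-min exposure, or one of the two 5-min day-11 sessions A1/A2).
#' Positions are in arena coordinates (origin at the SW corner, cm).
#'
#' @param animal_id Animal identifier (character).
#' @param group `"QNP"` or `"control"`.
#' @param day Experimental day, 1-11.
#' @param session `"daily"`, `"A1"` or `"A2"`.
#' @param t Strictly increasing sample times, s.
#' @param x,y Head coordinates, cm, inside `[0, side]`.
#' @param arena Optional [arena_spec()] used to validate bounds.
#' @return A `checkfish_trajectory`: a tibble of samples with metadata
#'   attributes.
#' @export
trajectory <- function(animal_id, group, day, session, t, x, y, arena = NULL) {
  group <- match.arg(group, c("QNP", "control"))
  session <- match.arg(session, c("daily", "A1", "A2"))
  day <- stopifnot_count(day, "day")
  if (day > 11) abort("`day` must be in 1..11.", class = "checkfish_config_error")
  n <- length(t)
  if (n < 2L || length(x) != n || length(y) != n) {
    abort("A trajectory needs >= 2 samples with equal-length t, x, y.",
          class = "checkfish_data_error")
  }
  if (any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1] + 1L
    abort(sprintf("Sample times must be strictly increasing (violated at sample %d).", bad),
          class = "checkfish_data_error")
  }
  if (!is.null(arena)) {
    out_of_bounds <- which(x < 0 | x > arena$side | y < 0 | y > arena$side)
    if (length(out_of_bounds)) {
      abort(sprintf("%d sample(s) outside the arena (first at row %d: x=%.2f, y=%.2f).",
                    length(out_of_bounds), out_of_bounds[1],
                    x[out_of_bounds[1]], y[out_of_bounds[1]]),
            class = "checkfish_data_error")
    }
  }
  structure(
    tibble(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y)),
    animal_id = as.character(animal_id), group = group,
    day = day, session = session,
    class = c("checkfish_trajectory", class(tibble())))
}

traj_meta <- function(traj) {
  tibble(animal_id = attr(traj, "animal_id"), group = attr(traj, "group"),
         day = attr(traj, "day"), session = attr(traj, "session"))
}

#' @export
print.checkfish_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> animal %s (%s), day %d, session %s: %d samples over %.1f s\n",
              attr(x, "animal_id"), attr(x, "group"), attr(x, "day"),
              attr(x, "session"), nrow(x), x$t[nrow(x)] - x$t[1]))
  NextMethod()
}

#' Total path length of a trajectory
#'
#' Sum of Euclidean distances between consecutive head samples; the locomotion
#' metric used for the sensitization curves.
#'
#' @param traj A [trajectory()].
#' @return Path length in cm (non-negative).
#' @export
#' @examples
#' tr <- trajectory("r1", "control", 1, "daily", t = 0:1, x = c(0, 3), y = c(0, 4))
#' path_length(tr)  # 5
path_length <- function(traj) {
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}
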
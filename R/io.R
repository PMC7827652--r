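# Delimited-text readers/writers and the run manifest. All tables are plain
# headers + tab-separated values so every intermediate is inspectable and
# diff-able; the package's own readers re-read everything its writers emit.

infer_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Write and read trajectory tables
#'
#' One row per video frame: `animal_id`, `group`, `day`, `session`, `t`, `x`,
#' `y`. Reading validates the schema, strictly increasing time per
#' animal-session, and (when an arena is given) that all positions lie inside
#' it, naming offending rows.
#'
#' @param trajs A list of [trajectory()] objects.
#' @param path File path (`.tsv`/`.txt` tab-separated, `.csv` comma).
#' @param arena Optional [arena_spec()] for bounds validation on read.
#' @return `read_trajectories` returns a named list of trajectories;
#'   `write_trajectories` returns `path` invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  rows <- dplyr::bind_rows(lapply(trajs, function(tr) {
    dplyr::bind_cols(traj_meta(tr), tr)
  }))
  utils::write.table(rows, path, sep = infer_sep(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path, arena = NULL) {
  header <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                              nrows = 1, stringsAsFactors = FALSE)
  needed <- c("animal_id", "group", "day", "session", "t", "x", "y")
  missing_cols <- setdiff(needed, names(header))
  if (length(missing_cols)) {
    abort(sprintf("Trajectory file lacks column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "checkfish_schema_error")
  }
  classes <- stats::setNames(rep("character", ncol(header)), names(header))
  classes[c("day")] <- "integer"
  classes[c("t", "x", "y")] <- "numeric"
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                          colClasses = classes)
  if (!is.null(arena)) {
    oob <- which(df$x < 0 | df$x > arena$side | df$y < 0 | df$y > arena$side)
    if (length(oob)) {
      abort(sprintf("Position(s) outside the arena at data row(s) %s.",
                    paste(utils::head(oob, 5), collapse = ", ")),
            class = "checkfish_schema_error")
    }
  }
  key <- paste(df$animal_id, df$day, df$session, sep = "\r")
  idx_by_traj <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  out <- list()
  for (rows in idx_by_traj) {
    sub <- df[rows, ]
    if (any(diff(sub$t) <= 0)) {
      bad <- rows[which(diff(sub$t) <= 0)[1] + 1L]
      abort(sprintf("Non-increasing time at data row %d (animal %s, day %s, session %s).",
                    bad, sub$animal_id[1], sub$day[1], sub$session[1]),
            class = "checkfish_schema_error")
    }
    nm <- sprintf("%s_d%s_%s", sub$animal_id[1], sub$day[1], sub$session[1])
    out[[nm]] <- trajectory(sub$animal_id[1], sub$group[1], sub$day[1],
                            sub$session[1], sub$t, sub$x, sub$y, arena = arena)
  }
  out
}

nuclei_required_cols <- function() {
  c("animal_id", "treatment", "environment", "region", "slide_id",
    "z_centroid_fraction", "size", "elongation", "counterstain_brightness",
    "intensity_e1_channel", "intensity_e2_channel",
    "exemplar_weakest_e1", "exemplar_weakest_e2")
}

#' Write and read nuclei feature tables
#'
#' One row per segmented nucleus with the features the classification chain
#' consumes. Reading validates the schema: z-centroid fractions in `[0, 1]`,
#' non-negative intensities, positive sizes, and strictly parsed booleans
#' (`TRUE`/`FALSE` only) for the exemplar flags. An empty (header-only) file
#' yields an empty table with a warning.
#'
#' @param nuclei A nucleus tibble.
#' @param path File path (`.tsv`/`.txt` tab-separated, `.csv` comma).
#' @return `read_nuclei` returns a tibble; `write_nuclei` returns `path`
#'   invisibly.
#' @export
write_nuclei <- function(nuclei, path) {
  utils::write.table(nuclei, path, sep = infer_sep(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_nuclei
#' @export
read_nuclei <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                          stringsAsFactors = FALSE,
                          colClasses = c(exemplar_weakest_e1 = "character",
                                         exemplar_weakest_e2 = "character"))
  missing_cols <- setdiff(nuclei_required_cols(), names(df))
  if (length(missing_cols)) {
    abort(sprintf("Nuclei file lacks column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "checkfish_schema_error")
  }
  if (nrow(df) == 0) {
    warn("Nuclei file is empty; returning an empty collection.")
    return(as_tibble(df[setdiff(names(df), "row")]))
  }
  for (fl in c("exemplar_weakest_e1", "exemplar_weakest_e2")) {
    if (!all(df[[fl]] %in% c("TRUE", "FALSE"))) {
      abort(sprintf("Column `%s` must contain only TRUE/FALSE.", fl),
            class = "checkfish_schema_error")
    }
    df[[fl]] <- df[[fl]] == "TRUE"
  }
  for (fl in intersect(c("latent_active_e1", "latent_active_e2", "latent_glia",
                         "in_mid_z", "included", "pos_e1", "pos_e2"), names(df))) {
    df[[fl]] <- as.logical(df[[fl]])
  }
  checks <- list(
    c("z_centroid_fraction out of [0, 1]",
      which(df$z_centroid_fraction < 0 | df$z_centroid_fraction > 1)),
    c("negative intensity",
      which(df$intensity_e1_channel < 0 | df$intensity_e2_channel < 0)),
    c("non-positive size", which(df$size <= 0)))
  for (chk in checks) {
    bad <- as.integer(chk[-1])
    if (length(bad)) {
      abort(sprintf("%s at row(s) %s.", chk[1],
                    paste(utils::head(bad, 5), collapse = ", ")),
            class = "checkfish_schema_error")
    }
  }
  as_tibble(df)
}

#' Write a reproducible run manifest
#'
#' Records everything needed to reproduce a pipeline run: the configuration
#' snapshot, master seed, md5 digests of any input files, package version,
#' timestamp, and per-stage row counts.
#'
#' @param path Output JSON path.
#' @param config Configuration object (serialized as-is, arena expanded).
#' @param seed Master seed.
#' @param inputs Character vector of input file paths to digest.
#' @param stage_counts Named list/vector of per-stage row counts.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed, inputs = character(),
                           stage_counts = list()) {
  serialize_cfg <- function(x) {
    if (inherits(x, "arena_spec")) x <- unclass(x)
    if (is.list(x)) lapply(x, serialize_cfg) else x
  }
  manifest <- list(
    package = "checkfish",
    version = as.character(utils::packageVersion("checkfish")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = serialize_cfg(unclass(config)),
    input_digests = if (length(inputs)) {
      as.list(tools::md5sum(inputs))
    } else list(),
    stage_row_counts = stage_counts)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a generator configuration from YAML or JSON
#'
#' Maps a plain config file onto [behavior_sim_config()] or
#' [catfish_sim_config()]; unknown keys are an error so typos fail loudly.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @param type `"behavior"` or `"catfish"`.
#' @return The validated config object.
#' @export
read_sim_config <- function(path, type = c("behavior", "catfish")) {
  type <- match.arg(type)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  ctor <- if (type == "behavior") behavior_sim_config else catfish_sim_config
  unknown <- setdiff(names(raw), names(formals(ctor)))
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s.", paste(unknown, collapse = ", ")),
          class = "checkfish_config_error")
  }
  if (!is.null(raw$arena)) raw$arena <- do.call(arena_spec, raw$arena)
  if (!is.null(raw$activity)) raw$activity <- as_tibble(raw$activity)
  if (!is.null(raw$n_animals)) raw$n_animals <- unlist(raw$n_animals)
  do.call(ctor, raw)
}
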
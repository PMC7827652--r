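#' Mark nuclei in the middle band of the Z-stack
#'
#' Nuclei centered near the top or bottom of a confocal stack are often
#' truncated by the section edge and read falsely negative, so analysis is
#' restricted to nuclei whose z-centroid lies in the middle `band` fraction of
#' the stack. The band is the half-open interval
#' `[0.5 - band/2, 0.5 + band/2)`; a centroid exactly at the lower edge is
#' retained, one exactly at the upper edge is excluded (`band = 1` keeps
#' everything). Excluded nuclei are marked, not deleted.
#'
#' @param nuclei A nucleus table with `z_centroid_fraction` in `[0, 1]`.
#' @param band Width of the mid-Z band as a fraction of stack depth, in
#'   `(0, 1]`.
#' @return `nuclei` with a logical column `in_mid_z`.
#' @export
select_mid_z <- function(nuclei, band = 0.20) {
  stopifnot_scalar_number(band, "band", min = 1e-12, max = 1)
  z <- nuclei$z_centroid_fraction
  lo <- 0.5 - band / 2
  hi <- 0.5 + band / 2
  nuclei$in_mid_z <- z >= lo & (z < hi | (band >= 1 & z <= hi))
  nuclei
}

#' Derive per-slide/region/channel positivity thresholds from weakest
#' exemplars
#'
#' The threshold for a channel is the minimum focus intensity among the
#' manually flagged weakest-positive exemplar nuclei, pooled across the whole
#' slide but kept separate per region and channel. Only exploring-arm
#' (`environment == "A1A2"`) animals contribute; home-cage animals are never
#' used. Thresholds are never imputed across regions: any
#' slide x region x channel present in the data but lacking an exemplar is an
#' error.
#'
#' @param nuclei A nucleus table with intensity columns and
#'   `exemplar_weakest_e1` / `exemplar_weakest_e2` flags.
#' @return A tibble: `slide_id`, `region`, `channel` (`"e1"`/`"e2"`),
#'   `threshold`, `n_exemplars`.
#' @export
derive_thresholds <- function(nuclei) {
  groups <- dplyr::distinct(nuclei, .data$slide_id, .data$region)
  out <- list()
  missing <- character()
  for (ch in c("e1", "e2")) {
    flag <- nuclei[[paste0("exemplar_weakest_", ch)]] &
      nuclei$environment == "A1A2"
    ex <- nuclei[flag, ]
    th <- if (nrow(ex) == 0) {
      tibble(slide_id = character(), region = character(),
             threshold = numeric(), n_exemplars = integer())
    } else {
      ex %>%
        dplyr::group_by(.data$slide_id, .data$region) %>%
        dplyr::summarise(threshold = min(.data[[paste0("intensity_", ch, "_channel")]]),
                         n_exemplars = dplyr::n(), .groups = "drop")
    }
    th$channel <- rep(ch, nrow(th))
    absent <- dplyr::anti_join(groups, th, by = c("slide_id", "region"))
    if (nrow(absent)) {
      missing <- c(missing, sprintf("%s/%s/%s", absent$slide_id, absent$region, ch))
    }
    out[[ch]] <- th
  }
  if (length(missing)) {
    abort(paste0("No exploring-arm exemplars for group(s): ",
                 paste(missing, collapse = ", ")),
          class = "checkfish_data_error")
  }
  dplyr::select(dplyr::bind_rows(out), "slide_id", "region", "channel",
                "threshold", "n_exemplars")
}

#' Flag putative glia nuclei
#'
#' Glia are recognized by the conjunction of (i) small size — below the
#' `size_quantile_cut` quantile of the slide's size distribution (strict), (ii)
#' prolonged shape or bright unstructured counterstain —
#' `elongation > elongation_cut` or
#' `counterstain_brightness > brightness_cut`, and (iii) no IEG signal — both
#' channel intensities below their slide/region thresholds. A nucleus with
#' supra-threshold signal in either channel is never flagged, whatever its
#' size and shape. Flagged nuclei are excluded from all proportion
#' denominators downstream.
#'
#' @param nuclei A nucleus table.
#' @param thresholds Threshold table from [derive_thresholds()].
#' @param size_quantile_cut Quantile (per slide) below which a nucleus counts
#'   as small.
#' @param elongation_cut Aspect-ratio cut for "prolonged shape".
#' @param brightness_cut Counterstain-brightness cut for "bright,
#'   unstructured" staining.
#' @return `nuclei` with a `cell_type` column (`"neuron"` /
#'   `"putative_glia"`). Warns when a slide holds fewer than 10 nuclei (size
#'   quantile unstable).
#' @export
filter_glia <- function(nuclei, thresholds, size_quantile_cut = 0.25,
                        elongation_cut = 1.6, brightness_cut = 125) {
  stopifnot_scalar_number(size_quantile_cut, "size_quantile_cut", min = 0, max = 1)
  stopifnot_scalar_number(elongation_cut, "elongation_cut")
  stopifnot_scalar_number(brightness_cut, "brightness_cut")
  slide_n <- table(nuclei$slide_id)
  if (any(slide_n < 10)) {
    warn(sprintf("Slide(s) %s hold fewer than 10 nuclei; size quantile is unstable.",
                 paste(names(slide_n)[slide_n < 10], collapse = ", ")))
  }
  cuts <- nuclei %>%
    dplyr::group_by(.data$slide_id) %>%
    dplyr::summarise(size_cut = stats::quantile(.data$size, size_quantile_cut,
                                                names = FALSE),
                     .groups = "drop")
  th_wide <- tidyr::pivot_wider(thresholds,
                                id_cols = c("slide_id", "region"),
                                names_from = "channel",
                                values_from = "threshold",
                                names_prefix = "thr_")
  out <- nuclei %>%
    dplyr::left_join(cuts, by = "slide_id") %>%
    dplyr::left_join(th_wide, by = c("slide_id", "region"))
  if (any(is.na(out$thr_e1)) || any(is.na(out$thr_e2))) {
    abort("Some nuclei fall in a slide/region with no derived threshold.",
          class = "checkfish_data_error")
  }
  no_signal <- out$intensity_e1_channel < out$thr_e1 &
    out$intensity_e2_channel < out$thr_e2
  glia <- out$size < out$size_cut &
    (out$elongation > elongation_cut |
       out$counterstain_brightness > brightness_cut) &
    no_signal
  nuclei$cell_type <- ifelse(glia, "putative_glia", "neuron")
  nuclei
}

#' Classify nuclei into the four two-epoch IEG classes
#'
#' Converts the two focus intensities to binary calls against the
#' slide/region/channel thresholds (intensity >= threshold is positive; the
#' boundary counts as positive) and combines them into
#' `negative` / `homer_pos` / `arc_pos` / `double_pos`. Epoch semantics: the
#' green Homer1a channel (e1) reports activity in the first session A1, the
#' orange/red Arc channel (e2) activity in the second session A2. The class
#' is defined only for included nuclei — those inside the mid-Z band (see
#' [select_mid_z()]) and typed as neurons (see [filter_glia()]); other rows
#' get `NA`.
#'
#' @param nuclei A nucleus table carrying `in_mid_z` and `cell_type` (both
#'   added if absent: all-in / all-neuron).
#' @param thresholds Threshold table from [derive_thresholds()].
#' @return `nuclei` with logical `pos_e1`, `pos_e2`, factor `iEG_class`, and
#'   logical `included`.
#' @export
classify_nuclei <- function(nuclei, thresholds) {
  if (!"in_mid_z" %in% names(nuclei)) nuclei$in_mid_z <- TRUE
  if (!"cell_type" %in% names(nuclei)) nuclei$cell_type <- "neuron"
  th_wide <- tidyr::pivot_wider(thresholds,
                                id_cols = c("slide_id", "region"),
                                names_from = "channel",
                                values_from = "threshold",
                                names_prefix = "thr_")
  joined <- dplyr::left_join(nuclei, th_wide, by = c("slide_id", "region"))
  if (any(is.na(joined$thr_e1)) || any(is.na(joined$thr_e2))) {
    bad <- dplyr::distinct(joined[is.na(joined$thr_e1) | is.na(joined$thr_e2), ],
                           .data$slide_id, .data$region)
    abort(sprintf("No threshold for group(s): %s.",
                  paste(sprintf("%s/%s", bad$slide_id, bad$region), collapse = ", ")),
          class = "checkfish_data_error")
  }
  nuclei$pos_e1 <- joined$intensity_e1_channel >= joined$thr_e1
  nuclei$pos_e2 <- joined$intensity_e2_channel >= joined$thr_e2
  nuclei$included <- nuclei$in_mid_z & nuclei$cell_type == "neuron"
  cls <- dplyr::case_when(
    !nuclei$pos_e1 & !nuclei$pos_e2 ~ "negative",
    nuclei$pos_e1 & !nuclei$pos_e2 ~ "homer_pos",
    !nuclei$pos_e1 & nuclei$pos_e2 ~ "arc_pos",
    TRUE ~ "double_pos")
  cls[!nuclei$included] <- NA_character_
  nuclei$iEG_class <- factor(cls, levels = c("negative", "homer_pos",
                                             "arc_pos", "double_pos"))
  nuclei
}

#' Per-region class proportions
#'
#' Counts and fractions of the four IEG classes among included neurons, per
#' animal x region, with the derived epoch marginals
#' `p_e1 = p_homer_only + p_double` (fraction active in A1) and
#' `p_e2 = p_arc_only + p_double` (fraction active in A2).
#'
#' @param classified Output of [classify_nuclei()].
#' @return A tibble per animal x region: `n_included`, class counts and
#'   fractions (`p_neg`, `p_homer_only`, `p_arc_only`, `p_double`), `p_e1`,
#'   `p_e2`. Animal x region cells with zero included nuclei yield an NA row
#'   with a warning.
#' @export
region_proportions <- function(classified) {
  all_cells <- dplyr::distinct(classified, .data$animal_id, .data$treatment,
                               .data$environment, .data$region)
  inc <- dplyr::filter(classified, .data$included)
  counts <- inc %>%
    dplyr::group_by(.data$animal_id, .data$treatment, .data$environment,
                    .data$region) %>%
    dplyr::summarise(
      n_included = dplyr::n(),
      n_neg = sum(.data$iEG_class == "negative"),
      n_homer_only = sum(.data$iEG_class == "homer_pos"),
      n_arc_only = sum(.data$iEG_class == "arc_pos"),
      n_double = sum(.data$iEG_class == "double_pos"),
      .groups = "drop")
  out <- dplyr::left_join(all_cells, counts,
                          by = c("animal_id", "treatment", "environment", "region"))
  if (any(is.na(out$n_included))) {
    empty <- out[is.na(out$n_included), ]
    warn(sprintf("Zero included nuclei for %s; proportions set to NA.",
                 paste(sprintf("%s/%s", empty$animal_id, empty$region),
                       collapse = ", ")))
    out$n_included[is.na(out$n_included)] <- 0L
  }
  out %>%
    dplyr::mutate(
      p_neg = .data$n_neg / .data$n_included,
      p_homer_only = .data$n_homer_only / .data$n_included,
      p_arc_only = .data$n_arc_only / .data$n_included,
      p_double = .data$n_double / .data$n_included,
      p_e1 = .data$p_homer_only + .data$p_double,
      p_e2 = .data$p_arc_only + .data$p_double)
}

#' Run the full catFISH classification chain
#'
#' Convenience wrapper: mid-Z selection, threshold derivation from the
#' weakest exploring-arm exemplars, glia exclusion, binary classification and
#' per-region proportions, in that order.
#'
#' @inheritParams select_mid_z
#' @inheritParams filter_glia
#' @return A list: `nuclei` (classified table), `thresholds`, `proportions`.
#' @export
catfish_pipeline <- function(nuclei, band = 0.20, size_quantile_cut = 0.25,
                             elongation_cut = 1.6, brightness_cut = 125) {
  nuclei <- select_mid_z(nuclei, band = band)
  thresholds <- derive_thresholds(nuclei)
  nuclei <- filter_glia(nuclei, thresholds,
                        size_quantile_cut = size_quantile_cut,
                        elongation_cut = elongation_cut,
                        brightness_cut = brightness_cut)
  nuclei <- classify_nuclei(nuclei, thresholds)
  list(nuclei = nuclei, thresholds = thresholds,
       proportions = region_proportions(nuclei))
}
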
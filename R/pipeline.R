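#' Run the full synthetic-cohort analysis pipeline
#'
#' End-to-end orchestration mirroring the study's analysis structure:
#' simulate (or accept) trajectories and nuclei, then produce locomotor
#' sensitization summaries, zone-visit tables with A-F rankings and pooled
#' matrices, standardized day-10 vs A1/A2 rates, per-region IEG proportions,
#' percent-reduction contrasts, similarity scores and the group-level ANOVAs,
#' and write every table as delimited text together with a run manifest and a
#' plain-text summary.
#'
#' @param behavior_config A [behavior_sim_config()].
#' @param catfish_config A [catfish_sim_config()].
#' @param out_dir Output directory (created; must be writable).
#' @param min_dwell,hysteresis Visit-detection parameters, see
#'   [detect_visits()].
#' @param band Mid-Z band width, see [select_mid_z()].
#' @param trajs,nuclei Optional pre-loaded inputs; when `NULL` they are
#'   simulated from the configs.
#' @return A list with all result tables (`sensitization`, `visits`,
#'   `rank_map`, `pooled`, `standardized`, `proportions`, `reductions`,
#'   `anova_ieg`, `anova_similarity`, `manifest`), invisibly writing them
#'   under `out_dir`.
#' @export
run_full_pipeline <- function(behavior_config, catfish_config, out_dir,
                              min_dwell = 0.5, hysteresis = 2, band = 0.20,
                              trajs = NULL, nuclei = NULL) {
  stage <- "configuration"
  res <- tryCatch({
    if (!inherits(behavior_config, "behavior_sim_config") ||
        !inherits(catfish_config, "catfish_sim_config")) {
      abort("Both configs must come from their constructors.",
            class = "checkfish_config_error")
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    zones <- build_zones(behavior_config$arena)

    stage <- "behavior simulation"
    if (is.null(trajs)) trajs <- simulate_trajectories(behavior_config)

    stage <- "behavior analysis"
    sens <- sensitization_summary(trajs)
    visits <- zone_visit_table(trajs, zones, min_dwell = min_dwell,
                               hysteresis = hysteresis)
    rank_map <- rank_zones(visits, days = seq_len(behavior_config$n_days))
    pooled <- pooled_zone_matrix(visits, rank_map)
    standardized <- standardize_sessions(
      visits, reference_day = behavior_config$n_days,
      day10_length = behavior_config$session_length, a_length = 300)

    stage <- "catfish simulation"
    if (is.null(nuclei)) nuclei <- simulate_catfish_population(catfish_config)

    stage <- "catfish classification"
    cat_res <- catfish_pipeline(nuclei, band = band)
    props <- add_similarity(cat_res$proportions)

    stage <- "contrasts"
    expl <- dplyr::filter(props, .data$environment == "A1A2")
    reductions <- expl %>%
      dplyr::group_by(.data$region, .data$treatment) %>%
      dplyr::summarise(p_e1 = mean(.data$p_e1), p_e2 = mean(.data$p_e2),
                       .groups = "drop") %>%
      tidyr::pivot_wider(names_from = "treatment", values_from = c("p_e1", "p_e2")) %>%
      dplyr::mutate(
        reduction_homer1a_pct = 100 * (1 - .data$p_e1_QNP / .data$p_e1_control),
        reduction_arc_pct = 100 * (1 - .data$p_e2_QNP / .data$p_e2_control))

    stage <- "statistics"
    long <- props %>%
      dplyr::select("animal_id", "treatment", "environment", "region",
                    "p_e1", "p_e2") %>%
      tidyr::pivot_longer(c("p_e1", "p_e2"), names_to = "session",
                          values_to = "value") %>%
      dplyr::mutate(session = toupper(sub("p_", "", .data$session)))
    anova_ieg <- run_mixed_anova(long)
    anova_sim <- compare_similarity(props)

    stage <- "output"
    wt <- function(x, f) utils::write.table(x, file.path(out_dir, f), sep = "\t",
                                            row.names = FALSE, quote = FALSE)
    wt(sens, "sensitization.tsv")
    wt(visits, "zone_visits.tsv")
    wt(rank_map, "rank_map.tsv")
    wt(pooled, "pooled_zone_matrix.tsv")
    wt(standardized, "standardized_sessions.tsv")
    write_nuclei(cat_res$nuclei, file.path(out_dir, "classified_nuclei.tsv"))
    wt(cat_res$thresholds, "thresholds.tsv")
    wt(props, "region_proportions.tsv")
    wt(reductions, "percent_reductions.tsv")
    wt(anova_ieg, "anova_ieg.tsv")
    wt(anova_sim, "anova_similarity.tsv")
    manifest <- write_manifest(
      file.path(out_dir, "manifest.json"),
      config = list(behavior = behavior_config, catfish = catfish_config,
                    min_dwell = min_dwell, hysteresis = hysteresis, band = band),
      seed = c(behavior = behavior_config$seed, catfish = catfish_config$seed),
      stage_counts = list(trajectories = length(trajs),
                          visit_rows = nrow(visits),
                          nuclei = nrow(cat_res$nuclei),
                          nuclei_included = sum(cat_res$nuclei$included),
                          proportion_rows = nrow(props)))
    summary_lines <- c(
      "checkfish pipeline summary",
      sprintf("QNP day-%d/day-1 locomotion ratio: %.2f", behavior_config$n_days,
              sens$ratio_to_day1[sens$group == "QNP" &
                                   sens$day == behavior_config$n_days]),
      sprintf("control day-%d/day-1 locomotion ratio: %.2f", behavior_config$n_days,
              sens$ratio_to_day1[sens$group == "control" &
                                   sens$day == behavior_config$n_days]),
      sprintf("CA1 Homer1a (A1) reduction: %.1f%%; Arc (A2) reduction: %.1f%%",
              reductions$reduction_homer1a_pct[reductions$region == "CA1"],
              reductions$reduction_arc_pct[reductions$region == "CA1"]),
      sprintf("similarity-score treatment effect min p across regions: %.3f",
              min(anova_sim$p.value[anova_sim$term == "treatment"], na.rm = TRUE)))
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
    list(sensitization = sens, visits = visits, rank_map = rank_map,
         pooled = pooled, standardized = standardized,
         nuclei = cat_res$nuclei, thresholds = cat_res$thresholds,
         proportions = props, reductions = reductions,
         anova_ieg = anova_ieg, anova_similarity = anova_sim,
         manifest = manifest)
  }, error = function(e) {
    abort(sprintf("Pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)),
          class = "checkfish_pipeline_error", parent = e)
  })
  invisible(res)
}
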
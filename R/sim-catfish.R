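#' Joint two-epoch activity law from marginals and a similarity target
#'
#' Inverts the ensemble similarity score: given the two marginal active
#' fractions `p1` (epoch 1) and `p2` (epoch 2) and a target similarity `s`,
#' the double-active probability is
#' `p11 = p1*p2 + s * (min(p1, p2) - p1*p2)`, and the four joint cell
#' probabilities follow. When `min(p1, p2) == p1*p2` (a marginal of 0 or 1)
#' the similarity has no degrees of freedom and the independent law is
#' returned. Infeasible combinations (any negative cell) fail loudly.
#'
#' @param p1,p2 Marginal active probabilities in `[0, 1]`.
#' @param similarity Target similarity score in `[-1, 1]`.
#' @return Named numeric vector `c(p00, p10, p01, p11)` summing to 1
#'   (`p10` = epoch-1 only, `p01` = epoch-2 only).
#' @export
#' @examples
#' joint_activity_law(0.3, 0.3, 1)   # perfect overlap: p11 = 0.3
#' joint_activity_law(0.294, 0.306, 0)  # independence: p11 = p1 * p2
joint_activity_law <- function(p1, p2, similarity) {
  stopifnot_scalar_number(p1, "p1", min = 0, max = 1)
  stopifnot_scalar_number(p2, "p2", min = 0, max = 1)
  stopifnot_scalar_number(similarity, "similarity", min = -1, max = 1)
  exp_overlap <- p1 * p2
  span <- min(p1, p2) - exp_overlap
  p11 <- if (span <= 0) exp_overlap else exp_overlap + similarity * span
  cells <- c(p00 = 1 - p1 - p2 + p11, p10 = p1 - p11, p01 = p2 - p11, p11 = p11)
  if (any(cells < -1e-12)) {
    abort(sprintf(
      "Infeasible joint law: p1=%.4g, p2=%.4g, similarity=%.4g gives cell probabilities (%s).",
      p1, p2, similarity, paste(sprintf("%.4g", cells), collapse = ", ")),
      class = "checkfish_config_error")
  }
  pmax(cells, 0)
}

default_activity_table <- function() {
  # exploring-arm marginals; CA1 values follow the published group-level
  # percentages, cortical regions are plausible defaults (strong exploration
  # effect in OFC, weak in ACC/mPFC)
  tibble(
    region = rep(c("CA1", "ACC", "OFC", "mPFC"), each = 2),
    treatment = rep(c("control", "QNP"), 4),
    p_e1 = c(0.294, 0.112, 0.04, 0.04, 0.15, 0.15, 0.04, 0.04),
    p_e2 = c(0.306, 0.207, 0.04, 0.04, 0.15, 0.15, 0.04, 0.04))
}

#' Configuration for the synthetic catFISH nuclei generator
#'
#' Emulates the 2x2 day-11 design (treatment QNP/control x environment
#' arena-exploring A1A2 / home-cage HC) with the two-epoch activity readout:
#' each neuronal nucleus carries a latent `(active_e1, active_e2)` pair drawn
#' from the joint law implied by the per-region marginals and
#' `overlap_similarity`; epoch-1 activity drives the green (Homer1a) channel
#' and epoch-2 activity the orange/red (Arc) channel. A `glia_fraction` of
#' nuclei get glia-like features (small, elongated, bright counterstain, no
#' IEG signal). Animals are distributed over slides in blocks, each channel
#' and slide gets a small multiplicative staining gain, and the k
#' weakest-signal true-active nuclei per slide x region x channel among
#' exploring-arm animals are flagged as threshold exemplars (home-cage
#' animals are never flagged).
#'
#' @param n_animals Named counts per design cell, in the order
#'   `QNP_A1A2, control_A1A2, QNP_HC, control_HC` (defaults 9, 9, 6, 5).
#' @param n_nuclei_per_region Nuclei simulated per animal x region.
#' @param regions Region labels.
#' @param activity Tibble with columns `region`, `treatment`, `p_e1`, `p_e2`:
#'   exploring-arm marginal active fractions.
#' @param hc_baseline Marginal active fraction (both epochs) for home-cage
#'   animals, all regions.
#' @param overlap_similarity Target similarity score in `[-1, 1]`.
#' @param pos_intensity,neg_intensity Length-2 vectors `c(location, scale)` of
#'   the focus-intensity distributions (normal, clipped at 0) for active and
#'   inactive nuclei.
#' @param glia_fraction Fraction of records with glia-like features.
#' @param stack_slices Optical sections per confocal stack (metadata; nucleus
#'   z-centroids are uniform over the stack depth).
#' @param n_exemplars Weakest-positive exemplars flagged per
#'   slide x region x channel.
#' @param slide_capacity Animals per slide block.
#' @param slide_gain_sd SD of the log-normal per-slide x channel staining
#'   gain.
#' @param seed Master seed.
#' @return A `catfish_sim_config` object.
#' @export
catfish_sim_config <- function(n_animals = c(QNP_A1A2 = 9, control_A1A2 = 9,
                                             QNP_HC = 6, control_HC = 5),
                               n_nuclei_per_region = 1000,
                               regions = c("CA1", "ACC", "OFC", "mPFC"),
                               activity = default_activity_table(),
                               hc_baseline = 0.03,
                               overlap_similarity = 0.3,
                               pos_intensity = c(location = 30, scale = 3),
                               neg_intensity = c(location = 8, scale = 3),
                               glia_fraction = 0.1,
                               stack_slices = 21,
                               n_exemplars = 3,
                               slide_capacity = 6,
                               slide_gain_sd = 0.05,
                               seed = 1L) {
  if (length(n_animals) == 1L) {
    n_animals <- stats::setNames(rep(n_animals, 4),
                                 c("QNP_A1A2", "control_A1A2", "QNP_HC", "control_HC"))
  }
  cells <- c("QNP_A1A2", "control_A1A2", "QNP_HC", "control_HC")
  if (!all(cells %in% names(n_animals))) {
    abort("`n_animals` must name the four design cells.",
          class = "checkfish_config_error")
  }
  n_animals <- vapply(cells, function(cl) stopifnot_count(n_animals[[cl]], cl, min = 0L),
                      integer(1))
  if (sum(n_animals[c("QNP_A1A2", "control_A1A2")]) == 0L) {
    abort("Need at least one exploring-arm animal (thresholds derive from them).",
          class = "checkfish_config_error")
  }
  n_nuclei_per_region <- stopifnot_count(n_nuclei_per_region, "n_nuclei_per_region")
  regions <- as.character(regions)
  stopifnot_scalar_number(hc_baseline, "hc_baseline", min = 0, max = 1)
  stopifnot_scalar_number(overlap_similarity, "overlap_similarity", min = -1, max = 1)
  stopifnot_scalar_number(glia_fraction, "glia_fraction", min = 0, max = 1)
  stack_slices <- stopifnot_count(stack_slices, "stack_slices")
  n_exemplars <- stopifnot_count(n_exemplars, "n_exemplars")
  slide_capacity <- stopifnot_count(slide_capacity, "slide_capacity")
  stopifnot_scalar_number(slide_gain_sd, "slide_gain_sd", min = 0)
  seed <- stopifnot_count(seed, "seed", min = 0L)
  activity <- as_tibble(activity)
  needed <- tidyr::expand_grid(region = regions, treatment = c("QNP", "control"))
  merged <- dplyr::left_join(needed, activity, by = c("region", "treatment"))
  if (any(is.na(merged$p_e1)) || any(is.na(merged$p_e2))) {
    abort("`activity` must cover every region x treatment.",
          class = "checkfish_config_error")
  }
  # feasibility of every joint law is a construction-time invariant
  for (r in seq_len(nrow(merged))) {
    joint_activity_law(merged$p_e1[r], merged$p_e2[r], overlap_similarity)
  }
  joint_activity_law(hc_baseline, hc_baseline, overlap_similarity)
  activity <- merged
  structure(as.list(environment())[names(formals(catfish_sim_config))],
            class = "catfish_sim_config")
}

#' Simulate a two-epoch catFISH nuclei population
#'
#' @param config A [catfish_sim_config()].
#' @return A tibble of nucleus records (one per segmented nucleus) with the
#'   feature columns used by the classification chain
#'   (`z_centroid_fraction`, `size`, `elongation`, `counterstain_brightness`,
#'   `intensity_e1_channel`, `intensity_e2_channel`, exemplar flags) plus the
#'   generator's ground-truth columns `latent_active_e1`, `latent_active_e2`,
#'   `latent_glia`.
#' @export
simulate_catfish_population <- function(config) {
  if (!inherits(config, "catfish_sim_config")) {
    abort("`config` must come from catfish_sim_config().",
          class = "checkfish_config_error")
  }
  cells <- tibble(
    treatment = c("QNP", "control", "QNP", "control"),
    environment = c("A1A2", "A1A2", "HC", "HC"),
    n = unname(config$n_animals[c("QNP_A1A2", "control_A1A2", "QNP_HC", "control_HC")]))
  animals <- cells %>%
    dplyr::filter(.data$n > 0) %>%
    tidyr::uncount(.data$n, .id = "k") %>%
    dplyr::mutate(animal_id = sprintf("%s%s%02d",
                                      ifelse(.data$treatment == "QNP", "q", "c"),
                                      ifelse(.data$environment == "A1A2", "E", "H"),
                                      .data$k)) %>%
    dplyr::select(-"k")
  n_slides <- max(1L, as.integer(ceiling(nrow(animals) / config$slide_capacity)))
  animals$slide_id <- sprintf("slide%02d", (seq_len(nrow(animals)) - 1L) %% n_slides + 1L)
  seeds <- spawn_seeds(config$seed, nrow(animals) + 1L)
  animals$sub_seed <- seeds[-1L]
  # per-slide x channel staining gain, from its own stream
  gains <- with_seed(seeds[1L], tibble(
    slide_id = rep(sprintf("slide%02d", seq_len(n_slides)), each = 2),
    channel = rep(c("e1", "e2"), n_slides),
    gain = exp(stats::rnorm(2L * n_slides, 0, config$slide_gain_sd))))

  rnorm_pos <- function(n, par) pmax(0, stats::rnorm(n, par[[1]], par[[2]]))
  sim_animal <- function(a) {
    with_seed(a$sub_seed, {
      per_region <- lapply(config$regions, function(reg) {
        n <- config$n_nuclei_per_region
        if (a$environment == "HC") {
          p1 <- config$hc_baseline; p2 <- config$hc_baseline
        } else {
          row <- config$activity[config$activity$region == reg &
                                   config$activity$treatment == a$treatment, ]
          p1 <- row$p_e1; p2 <- row$p_e2
        }
        law <- joint_activity_law(p1, p2, config$overlap_similarity)
        glia <- stats::runif(n) < config$glia_fraction
        cell <- sample(4L, n, replace = TRUE, prob = law)  # 1=p00 2=p10 3=p01 4=p11
        a1 <- !glia & cell %in% c(2L, 4L)
        a2 <- !glia & cell %in% c(3L, 4L)
        g1 <- gains$gain[gains$slide_id == a$slide_id & gains$channel == "e1"]
        g2 <- gains$gain[gains$slide_id == a$slide_id & gains$channel == "e2"]
        tibble(
          animal_id = a$animal_id, treatment = a$treatment,
          environment = a$environment, region = reg, slide_id = a$slide_id,
          z_centroid_fraction = stats::runif(n),
          size = pmax(1, ifelse(glia, stats::rnorm(n, 45, 8),
                                stats::rnorm(n, 110, 15))),
          elongation = 1 + abs(ifelse(glia, stats::rnorm(n, 0.9, 0.3),
                                      stats::rnorm(n, 0.15, 0.15))),
          counterstain_brightness = pmax(0, ifelse(glia, stats::rnorm(n, 150, 12),
                                                   stats::rnorm(n, 100, 12))),
          intensity_e1_channel = g1 * ifelse(a1, rnorm_pos(n, config$pos_intensity),
                                             rnorm_pos(n, config$neg_intensity)),
          intensity_e2_channel = g2 * ifelse(a2, rnorm_pos(n, config$pos_intensity),
                                             rnorm_pos(n, config$neg_intensity)),
          latent_active_e1 = a1, latent_active_e2 = a2, latent_glia = glia)
      })
      dplyr::bind_rows(per_region)
    })
  }
  nuclei <- dplyr::bind_rows(lapply(seq_len(nrow(animals)),
                                    function(i) sim_animal(animals[i, ])))
  # flag the k weakest true-active exemplars per slide x region x channel,
  # exploring-arm animals only
  nuclei$exemplar_weakest_e1 <- FALSE
  nuclei$exemplar_weakest_e2 <- FALSE
  for (ch in c("e1", "e2")) {
    active_col <- paste0("latent_active_", ch)
    int_col <- paste0("intensity_", ch, "_channel")
    flag_col <- paste0("exemplar_weakest_", ch)
    eligible <- which(nuclei$environment == "A1A2" & nuclei[[active_col]])
    if (length(eligible)) {
      grp <- interaction(nuclei$slide_id[eligible], nuclei$region[eligible],
                         drop = TRUE)
      for (g in levels(grp)) {
        members <- eligible[grp == g]
        k <- min(config$n_exemplars, length(members))
        pick <- members[order(nuclei[[int_col]][members])][seq_len(k)]
        nuclei[[flag_col]][pick] <- TRUE
      }
    }
  }
  nuclei
}
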
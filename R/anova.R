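# Group-level statistical comparisons. The study's SPSS general-mixed-model
# analyses are represented by factorial ANOVA with repeated measures on the
# within-subject factor, fitted with base aov() and an Error(animal) stratum;
# sequential sums of squares give exact F tests under the null.

tidy_aov <- function(fit) {
  sm <- summary(fit)
  # aovlist summaries are nested one level deeper than lm/aov ones
  strata <- if (inherits(fit, "aovlist")) {
    stats::setNames(lapply(sm, function(s) s[[1]]), names(sm))
  } else {
    list(Residuals = sm[[1]])
  }
  rows <- lapply(names(strata), function(nm) {
    tab <- strata[[nm]]
    terms <- trimws(rownames(tab))
    tibble(stratum = nm, term = terms,
           df = tab[["Df"]],
           sumsq = tab[["Sum Sq"]],
           meansq = tab[["Mean Sq"]],
           statistic = if ("F value" %in% colnames(tab)) tab[["F value"]] else NA_real_,
           p.value = if ("Pr(>F)" %in% colnames(tab)) tab[["Pr(>F)"]] else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  # a (numerically) zero residual mean square makes F infinite; flag rather
  # than report an astronomically large finite value
  for (nm in unique(out$stratum)) {
    sel <- out$stratum == nm
    resid_ms <- out$meansq[sel & out$term == "Residuals"]
    if (!length(resid_ms)) next
    scale <- max(out$meansq[sel], na.rm = TRUE)
    if (scale > 0 && resid_ms <= 1e-10 * scale) {
      warn("Zero within-cell variance: F statistics in the affected stratum are infinite.")
      big <- sel & out$term != "Residuals" & out$meansq > 1e-10 * scale
      out$statistic[big] <- Inf
      out$p.value[big] <- 0
    }
  }
  out
}

#' Mixed-design ANOVA on per-animal IEG proportions
#'
#' Factorial ANOVA with between-subject factors treatment (QNP/control) and
#' environment (arena-exploring A1A2 / home-cage HC) and repeated measures on
#' the exploration session (E1 = Homer1a/A1, E2 = Arc/A2), fitted per brain
#' region with an `Error(animal)` stratum. Between-subject effects are tested
#' against the animal stratum, session effects against the within-animal
#' stratum.
#'
#' @param data Long-format tibble with columns `animal_id`, `treatment`,
#'   `environment`, `session` (`"E1"`/`"E2"`), `value`, and optionally
#'   `region` (analyzed separately, never pooled).
#' @return A tibble of effects: (`region`,) `stratum`, `term`, `df`, `sumsq`,
#'   `meansq`, `statistic`, `p.value`.
#' @export
run_mixed_anova <- function(data) {
  needed <- c("animal_id", "treatment", "environment", "session", "value")
  if (!all(needed %in% names(data))) {
    abort(sprintf("`data` needs columns %s.", paste(needed, collapse = ", ")),
          class = "checkfish_data_error")
  }
  if ("region" %in% names(data) && dplyr::n_distinct(data$region) > 1) {
    return(data %>%
             dplyr::group_by(.data$region) %>%
             dplyr::group_modify(~ run_mixed_anova(dplyr::select(.x, -dplyr::any_of("region")))) %>%
             dplyr::ungroup())
  }
  data <- data %>%
    dplyr::filter(!is.na(.data$value)) %>%
    dplyr::mutate(animal_id = factor(.data$animal_id),
                  treatment = factor(.data$treatment),
                  environment = factor(.data$environment),
                  session = factor(.data$session))
  cells <- table(data$treatment, data$environment)
  if (any(cells == 0)) {
    warn("Empty design cell(s): the corresponding interaction terms are dropped.")
  }
  factors <- c("treatment", "environment", "session")
  keep <- factors[vapply(factors, function(f) nlevels(data[[f]]) > 1, logical(1))]
  if (!length(keep)) {
    abort("No factor varies; nothing to test.", class = "checkfish_data_error")
  }
  fml <- stats::reformulate(paste0(paste(keep, collapse = " * "),
                                   " + Error(animal_id)"),
                            response = "value")
  fit <- stats::aov(fml, data = data)
  out <- tidy_aov(fit)
  dplyr::select(out, -dplyr::any_of("region"))
}

#' Compare similarity scores across treatment and environment
#'
#' Two-way between-subjects ANOVA (`score ~ treatment * environment`) on the
#' per-animal ensemble similarity scores, per brain region. Undefined scores
#' (animals with no scorable ensemble, e.g. a zero marginal) are excluded
#' listwise and their count reported; a region where every score is undefined
#' is skipped with a warning.
#'
#' @param scores Tibble with columns `animal_id`, `treatment`, `environment`,
#'   `region`, `similarity` (NA = undefined).
#' @return A tibble of effects per region, with the number of excluded
#'   animals in `n_excluded`.
#' @export
compare_similarity <- function(scores) {
  needed <- c("treatment", "environment", "region", "similarity")
  if (!all(needed %in% names(scores))) {
    abort(sprintf("`scores` needs columns %s.", paste(needed, collapse = ", ")),
          class = "checkfish_data_error")
  }
  out <- list()
  for (reg in unique(scores$region)) {
    sub <- scores[scores$region == reg, ]
    n_excl <- sum(is.na(sub$similarity))
    sub <- sub[!is.na(sub$similarity), ]
    if (nrow(sub) == 0) {
      warn(sprintf("Region %s: all similarity scores undefined; skipped.", reg))
      next
    }
    sub <- dplyr::mutate(sub, treatment = factor(.data$treatment),
                         environment = factor(.data$environment))
    if (stats::sd(sub$similarity) < 1e-12) {
      # constant scores: no variance to partition, every effect is null
      tab <- tibble(stratum = "Residuals",
                    term = c("treatment", "environment", "Residuals"),
                    df = NA_real_, sumsq = 0, meansq = 0,
                    statistic = c(0, 0, NA_real_), p.value = c(1, 1, NA_real_),
                    region = reg, n_excluded = n_excl)
      out[[reg]] <- tab
      next
    }
    keep <- c("treatment", "environment")
    keep <- keep[vapply(keep, function(f) nlevels(sub[[f]]) > 1, logical(1))]
    if (!length(keep)) {
      warn(sprintf("Region %s: no factor varies; skipped.", reg))
      next
    }
    fit <- stats::aov(stats::reformulate(paste(keep, collapse = " * "),
                                         response = "similarity"), data = sub)
    tab <- tidy_aov(fit)
    tab$region <- reg
    tab$n_excluded <- n_excl
    out[[reg]] <- tab
  }
  if (!length(out)) {
    abort("No region had any defined similarity score.",
          class = "checkfish_data_error")
  }
  dplyr::relocate(dplyr::bind_rows(out), "region")
}
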
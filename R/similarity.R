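#' Two-epoch ensemble similarity score
#'
#' Reduces the four class proportions (negative, epoch-1-only, epoch-2-only,
#' double-positive) to a single overlap statistic normalized to the
#' inter-individual variability in ensemble size: with epoch marginals
#' `pE1 = p_e1_only + p_double` and `pE2 = p_e2_only + p_double`,
#'
#' `score = (p_double - pE1 * pE2) / (min(pE1, pE2) - pE1 * pE2)`
#'
#' so independent ensembles score 0 and maximal overlap given the marginals
#' scores 1. When the denominator is zero (a marginal of 0 or 1, where the
#' overlap is fully determined) the score is undefined: it is returned as
#' `NA` with `defined = FALSE`, never silently 0.
#'
#' @param p_neg,p_e1_only,p_e2_only,p_double Non-negative fractions summing
#'   to 1 (within 1e-9).
#' @return A `similarity_result`: list with `pE1`, `pE2`, `p_double`,
#'   `expected_overlap`, `least_marginal`, `score`, `defined`.
#' @export
#' @examples
#' similarity_score(0.7, 0, 0, 0.3)          # identical ensembles: score 1
#' similarity_score(0.55, 0.2, 0.15, 0.10)   # counts 55/20/15/10: score 1/7
similarity_score <- function(p_neg, p_e1_only, p_e2_only, p_double) {
  p <- c(p_neg, p_e1_only, p_e2_only, p_double)
  if (any(!is.finite(p)) || any(p < 0)) {
    abort("Fractions must be finite and non-negative.",
          class = "checkfish_input_error")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    abort(sprintf("Fractions must sum to 1 (got %.12f).", sum(p)),
          class = "checkfish_input_error")
  }
  pE1 <- p_e1_only + p_double
  pE2 <- p_e2_only + p_double
  expected <- pE1 * pE2
  least <- min(pE1, pE2)
  denom <- least - expected
  defined <- denom > 1e-12
  score <- if (defined) (p_double - expected) / denom else NA_real_
  structure(list(pE1 = pE1, pE2 = pE2, p_double = p_double,
                 expected_overlap = expected, least_marginal = least,
                 score = score, defined = defined),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity> pE1=%.4f pE2=%.4f p_double=%.4f expected=%.4f -> score %s\n",
              x$pE1, x$pE2, x$p_double, x$expected_overlap,
              if (x$defined) sprintf("%.4f", x$score) else "undefined"))
  invisible(x)
}

#' Similarity score from nucleus counts
#'
#' @param n_neg,n_e1_only,n_e2_only,n_double Class counts.
#' @return A `similarity_result` (see [similarity_score()]); the score
#'   depends only on the fractions, not the total count.
#' @export
similarity_from_counts <- function(n_neg, n_e1_only, n_e2_only, n_double) {
  total <- n_neg + n_e1_only + n_e2_only + n_double
  if (total <= 0) {
    abort("Counts must sum to a positive total.", class = "checkfish_input_error")
  }
  similarity_score(n_neg / total, n_e1_only / total, n_e2_only / total,
                   n_double / total)
}

#' Per-animal similarity scores from a proportions table
#'
#' @param proportions Output of [region_proportions()].
#' @return The table with columns `similarity` and `similarity_defined`
#'   appended (undefined scores are `NA`, flagged FALSE).
#' @export
add_similarity <- function(proportions) {
  res <- mapply(function(a, b, c, d) {
    if (any(is.na(c(a, b, c, d)))) return(c(NA_real_, FALSE))
    r <- similarity_score(a, b, c, d)
    c(r$score, r$defined)
  }, proportions$p_neg, proportions$p_homer_only, proportions$p_arc_only,
  proportions$p_double)
  proportions$similarity <- as.numeric(res[1, ])
  proportions$similarity_defined <- as.logical(res[2, ])
  proportions
}

#' Percent reduction of a treated value relative to control
#'
#' `100 * (1 - treated / control)`; the scale of the inputs (fractions or
#' percentages) cancels. Positive values mean the treated group is lower.
#'
#' @param control_value Control-group value; must be > 0.
#' @param treated_value Treated-group value.
#' @return Percent reduction.
#' @export
#' @examples
#' percent_reduction(29.4, 11.2)  # ~62
#' percent_reduction(30.6, 20.7)  # ~32
percent_reduction <- function(control_value, treated_value) {
  stopifnot_scalar_number(treated_value, "treated_value")
  stopifnot_scalar_number(control_value, "control_value")
  if (control_value <= 0) {
    abort("`control_value` must be > 0; the reduction is undefined otherwise.",
          class = "checkfish_input_error")
  }
  100 * (1 - treated_value / control_value)
}
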
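# Bundled worked-example data: aggregate tables from a published needs
# assessment of age-friendly community health emergency stations (19
# requirement indicators, 351 valid questionnaires, a three-layer weighting
# hierarchy, four design contradictions and a two-alternative evaluation).
# Only aggregates were published, so these files carry reported summary
# values alongside the raw grids; several reported columns are known to be
# arithmetically inconsistent (see the package vignette) and are kept
# verbatim for comparison, never used in computation.

#' The bundled 19-indicator requirement system
#' @return an `indicator_set` of the A1-A5, B1-B4, C1-C5, D1-D5 indicators.
#' @export
study_indicators <- function() {
  read_indicators(extdata_path("indicators.csv"))
}

#' Bundled sample-accounting table
#'
#' Questionnaire counts and respondent demographics of the worked example:
#' 380 questionnaires distributed, 351 valid, split into older adults and
#' caregivers, with gender, age-band and disease breakdowns.
#'
#' @return data frame with columns `category, group, count`.
#' @export
study_sample_counts <- function() {
  utils::read.csv(extdata_path("sample_counts.csv"), stringsAsFactors = FALSE)
}

#' Sample-accounting arithmetic
#'
#' Recomputes the headline accounting statistics from a counts table:
#' the valid recovery rate (valid / distributed), the role-count sum, and
#' the share of each disease among valid questionnaires. Percentages are
#' on the 0-100 scale.
#'
#' @param counts a counts table as from [study_sample_counts()].
#' @return list with `recovery_rate_pct`, `n_valid`, `role_sum`,
#'   `disease_pct` (named vector).
#' @export
sample_accounting <- function(counts = study_sample_counts()) {
  get1 <- function(cat, grp) {
    v <- counts$count[counts$category == cat & counts$group == grp]
    if (length(v) != 1L) stop("missing count: ", cat, "/", grp, call. = FALSE)
    v
  }
  distributed <- get1("questionnaires", "distributed")
  valid <- get1("questionnaires", "valid")
  roles <- counts[counts$category == "role", ]
  dis <- counts[counts$category == "disease", ]
  list(recovery_rate_pct = 100 * valid / distributed,
       n_valid = valid,
       role_sum = sum(roles$count),
       disease_pct = stats::setNames(100 * dis$count / valid, dis$group))
}

#' Bundled Kano category distributions
#'
#' Per-indicator category percentages from the worked example, converted
#' to fractions. Because several published rows do not sum to 100%, rows
#' are renormalized to sum to 1 by default; the reported final category
#' and Better-Worse values are carried in `reported_*` columns for
#' comparison only.
#'
#' @param renormalize divide each row by its sum (default TRUE).
#' @return a `kano_distribution` with extra `reported_category`,
#'   `reported_better`, `reported_worse` columns; `n` is `NA` (respondent
#'   counts were not published).
#' @export
study_kano_distributions <- function(renormalize = TRUE) {
  df <- utils::read.csv(extdata_path("kano_distributions.csv"),
                        stringsAsFactors = FALSE)
  fr <- as.matrix(df[, c("a_pct", "o_pct", "m_pct", "i_pct", "r_pct", "q_pct")]) / 100
  if (renormalize) fr <- fr / rowSums(fr)
  out <- data.frame(indicator_id = df$indicator_id, n = NA_integer_,
                    a = fr[, 1], o = fr[, 2], m = fr[, 3],
                    i = fr[, 4], r = fr[, 5], q = fr[, 6],
                    stringsAsFactors = FALSE)
  bw <- kano_better_worse(out)
  out$better <- bw$better
  out$worse <- bw$worse
  out$reported_category <- df$reported_category
  out$reported_better <- df$reported_better_pct / 100
  out$reported_worse <- df$reported_worse_pct / 100
  class(out) <- c("kano_distribution", "data.frame")
  out
}

#' Bundled judgment matrices
#'
#' The criterion-layer matrix over the must-be (M), one-dimensional (O)
#' and attractive (A) categories plus the three indicator-layer matrices
#' (M1-M7, O1-O5, N1-N4), exactly as published. Note the published grids
#' are not reciprocal; run them through [priority_weights()] with
#' `reciprocity = "repair_upper"` (the default).
#'
#' @return named list of `pairwise_matrix` objects: `criterion`, `M`,
#'   `O`, `N`.
#' @export
study_judgment_matrices <- function() {
  list(criterion = read_pairwise_matrix(extdata_path("judgment_criterion.csv")),
       M = read_pairwise_matrix(extdata_path("judgment_M.csv")),
       O = read_pairwise_matrix(extdata_path("judgment_O.csv")),
       N = read_pairwise_matrix(extdata_path("judgment_N.csv")))
}

#' Reported AHP values of the worked example
#' @return data frame of reported per-item weights and per-matrix
#'   lambda_max / CI / CR.
#' @export
study_reported_ahp <- function() {
  utils::read.csv(extdata_path("reported_ahp.csv"), stringsAsFactors = FALSE)
}

#' Reported combined weights of the worked example
#'
#' The published 15-indicator combined-weight column (M1..M5, O1..O5,
#' N1..N5) with its sub-criterion weights and rank. The combined column
#' does not equal the product of the published layer weights and does not
#' sum to 1; renormalize before using it as a TOPSIS weight vector.
#'
#' @param renormalize return `combined_weight` rescaled to sum to 1.
#' @return data frame with columns `criterion, indicator, sub_weight,
#'   combined_weight, reported_rank`.
#' @export
study_combined_weights <- function(renormalize = FALSE) {
  df <- utils::read.csv(extdata_path("combined_weights.csv"),
                        stringsAsFactors = FALSE)
  if (renormalize) df$combined_weight <- df$combined_weight / sum(df$combined_weight)
  df
}

#' Bundled initial evaluation matrix
#'
#' Mean 7-point scores of the two evaluated alternatives (the proposed
#' design scheme and a conventional comparison sample) on the 15 retained
#' indicators.
#'
#' @return an `evaluation_matrix` (2 x 15).
#' @export
study_evaluation_matrix <- function() {
  df <- utils::read.csv(extdata_path("evaluation_matrix.csv"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  f <- as.matrix(df[, -1L])
  rownames(f) <- df[[1L]]
  class(f) <- c("evaluation_matrix", class(matrix()))
  f
}

#' Reported closeness values of the worked example
#' @return data frame of the published S+, S-, closeness and rank per
#'   alternative (kept for comparison; internally inconsistent with the
#'   closeness formula).
#' @export
study_reported_closeness <- function() {
  utils::read.csv(extdata_path("closeness_reference.csv"),
                  stringsAsFactors = FALSE)
}

#' Bundled design-contradiction cases
#' @return a `conflict_cases` frame with the four worked-example conflicts
#'   (two physical with configured principle sets, two technical resolved
#'   via [study_contradiction_matrix()]).
#' @export
study_conflicts <- function() {
  df <- utils::read.csv(extdata_path("conflicts.csv"), stringsAsFactors = FALSE)
  conflict_cases(label = df$label, conflict_type = df$conflict_type,
                 indicators = df$indicators,
                 improving = df$improving, worsening = df$worsening,
                 improving_id = df$improving_id, worsening_id = df$worsening_id,
                 principles = ifelse(is.na(df$principles), "", df$principles))
}

#' Bundled contradiction-matrix cells
#'
#' Only the cells exercised by the worked example ship here; the parameter
#' numbering follows the source material, which differs from the classical
#' 39-parameter convention, so no correspondence with the classical matrix
#' is claimed.
#'
#' @return a `triz_matrix`.
#' @export
study_contradiction_matrix <- function() {
  triz_load_matrix(extdata_path("contradiction_matrix.csv"))
}

#' Bundled engineering-parameter names
#' @return data frame `id, name`.
#' @export
study_parameters <- function() {
  utils::read.csv(extdata_path("triz_parameters.csv"), stringsAsFactors = FALSE)
}

#' Bundled inventive-principle names
#' @return data frame `id, name`.
#' @export
study_principles <- function() {
  utils::read.csv(extdata_path("triz_principles.csv"), stringsAsFactors = FALSE)
}
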
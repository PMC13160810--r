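# Synthetic questionnaire data with known ground truth. Every generator is
# a pure function of (arguments, seed): identical inputs give identical
# outputs, and the caller's RNG stream is left untouched. The generators
# define the study conditions the test-suite exercises; their zero-noise
# limits are exact so every downstream stage has a parameter-recovery
# oracle.

#' Generate Kano responses from planted categories
#'
#' Each respondent x indicator answer pair is drawn, with probability
#' 1 - error_rate, uniformly from the evaluation-table cells that map to
#' the indicator's planted category, and with probability error_rate
#' uniformly from all 25 cells. At error_rate 0 every pair classifies back
#' to the planted category exactly; at error_rate 1 the cell distribution
#' is uniform. Q cannot be planted (it denotes a contradictory answer
#' pair, not a demand type). Respondent roles follow the surveyed
#' composition (241 of 351 older adults) by default.
#'
#' @param indicators an `indicator_set`.
#' @param planted named character vector of planted categories (one of
#'   A, O, M, I, R) per indicator id, or a single category recycled.
#' @param n_respondents number of respondents (>= 1).
#' @param error_rate uniform contamination rate in \[0, 1\].
#' @param seed non-negative integer seed.
#' @param prop_older fraction of respondents given the `older_adult` role.
#' @return a `kano_response_table`.
#' @export
generate_kano_responses <- function(indicators, planted, n_respondents,
                                    error_rate = 0, seed = 0,
                                    prop_older = 241 / 351) {
  stopifnot(inherits(indicators, "indicator_set"))
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 1) {
    stop("`error_rate` must be in [0, 1]", call. = FALSE)
  }
  if (n_respondents < 1) stop("`n_respondents` must be >= 1", call. = FALSE)
  if (length(planted) == 1L && is.null(names(planted))) {
    planted <- stats::setNames(rep(planted, nrow(indicators)), indicators$id)
  }
  if (!all(indicators$id %in% names(planted))) {
    stop("`planted` must name a category for every indicator", call. = FALSE)
  }
  planted <- planted[indicators$id]
  if (any(planted == "Q")) {
    stop("category Q cannot be planted: it denotes a contradictory pair, ",
         "not a demand type", call. = FALSE)
  }
  if (!all(planted %in% c("A", "O", "M", "I", "R"))) {
    stop("planted categories must be one of A, O, M, I, R", call. = FALSE)
  }
  tab <- kano_evaluation_table()
  lv <- kano_answer_levels()
  cells_of <- lapply(stats::setNames(nm = c("A", "O", "M", "I", "R")),
                     function(cat) which(tab == cat))
  n_ind <- nrow(indicators)
  resp_ids <- sprintf("r%04d", seq_len(n_respondents))
  roles <- ifelse(seq_len(n_respondents) <= round(prop_older * n_respondents),
                  "older_adult", "caregiver")
  with_seed(seed, {
    rows <- lapply(seq_len(n_ind), function(k) {
      pool <- cells_of[[planted[[k]]]]
      noisy <- stats::runif(n_respondents) < error_rate
      cell <- integer(n_respondents)
      cell[!noisy] <- pool[sample.int(length(pool), sum(!noisy), replace = TRUE)]
      cell[noisy] <- sample.int(25L, sum(noisy), replace = TRUE)
      data.frame(respondent_id = resp_ids, role = roles,
                 indicator_id = indicators$id[k],
                 functional = lv[(cell - 1L) %% 5L + 1L],
                 dysfunctional = lv[(cell - 1L) %/% 5L + 1L],
                 stringsAsFactors = FALSE)
    })
    as_kano_response_table(do.call(rbind, rows), indicators)
  })
}

saaty_scale <- function() c(1 / 9:2, 1:9)

#' Generate a pairwise matrix from true weights
#'
#' Entries are a_ij = (w_i / w_j) * exp(e_ij) with zero-mean normal
#' perturbations e_ij of scale `sigma` on the upper triangle and
#' e_ji = -e_ij, so reciprocity holds exactly and the sigma = 0 limit is a
#' perfectly consistent matrix whose priority vector is `true_weights`.
#' With `snap_to_saaty` the upper-triangle entries are snapped to the
#' nearest value of the discrete 1/9..9 judgment scale before the lower
#' triangle is rebuilt by reciprocals.
#'
#' @param true_weights strictly positive vector summing to 1 (within
#'   1e-12).
#' @param sigma log-perturbation scale, >= 0.
#' @param snap_to_saaty snap entries to the discrete Saaty scale?
#' @param seed non-negative integer seed.
#' @return a `pairwise_matrix`.
#' @export
generate_pairwise_matrix <- function(true_weights, sigma = 0,
                                     snap_to_saaty = FALSE, seed = 0) {
  w <- as.numeric(true_weights)
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-12) {
    stop("`true_weights` must be strictly positive and sum to 1", call. = FALSE)
  }
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  n <- length(w)
  m <- outer(w, w, `/`)
  with_seed(seed, {
    if (n > 1L) {
      up <- upper.tri(m)
      e <- stats::rnorm(sum(up), 0, sigma)
      m[up] <- m[up] * exp(e)
      if (snap_to_saaty) {
        scale <- saaty_scale()
        m[up] <- scale[vapply(m[up], function(v) which.min(abs(scale - v)),
                              integer(1))]
      }
      m[t(up)] <- t(1 / m)[t(up)]
    }
  })
  diag(m) <- 1
  nm <- names(true_weights) %||% paste0("item", seq_len(n))
  as_pairwise_matrix(m, nm)
}

#' Generate rater-level Likert scores around true quality levels
#'
#' Each rater's score is the cell's true mean plus Gaussian noise, rounded
#' to the nearest integer and clipped to the 1-7 scale. Both rater groups
#' (expert, user) receive `n_raters` raters each.
#'
#' @param quality alternatives-by-indicators matrix of true means in
#'   \[1, 7\].
#' @param sd noise standard deviation, >= 0.
#' @param n_raters raters per group.
#' @param seed non-negative integer seed.
#' @return a `score_table`.
#' @export
generate_likert_scores <- function(quality, sd = 0, n_raters = 20, seed = 0) {
  quality <- as.matrix(quality)
  if (any(quality < 1 | quality > 7)) {
    stop("true means must lie within the 1-7 scale", call. = FALSE)
  }
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  alts <- rownames(quality) %||% paste0("alt", seq_len(nrow(quality)))
  inds <- colnames(quality) %||% paste0("ind", seq_len(ncol(quality)))
  groups <- c("expert", "user")
  grid <- expand.grid(rater = seq_len(n_raters), group = groups,
                      alt = seq_along(alts), ind = seq_along(inds),
                      stringsAsFactors = FALSE)
  with_seed(seed, {
    raw <- quality[cbind(grid$alt, grid$ind)] + stats::rnorm(nrow(grid), 0, sd)
  })
  df <- data.frame(
    rater_id = sprintf("%s%02d", grid$group, grid$rater),
    rater_group = grid$group,
    alternative_id = alts[grid$alt],
    indicator_id = inds[grid$ind],
    score = as.integer(pmin(7, pmax(1, round(raw)))),
    stringsAsFactors = FALSE)
  as_score_table(df)
}

#' Generate factor-structured item responses
#'
#' x = loading * f + sqrt(1 - loading^2) * e with independent standard
#' normal common factor f (per subject) and uniqueness e (per cell); the
#' population inter-item correlation is loading^2, so Cronbach's alpha
#' tends to the Spearman-Brown value k*loading^2 / (1 + (k-1)*loading^2).
#'
#' @param n_subjects,n_items dimensions.
#' @param loading common-factor loading in \[0, 1).
#' @param seed non-negative integer seed.
#' @return numeric subjects-by-items matrix.
#' @export
generate_factor_items <- function(n_subjects, n_items, loading, seed = 0) {
  if (!is.numeric(loading) || loading < 0 || loading >= 1) {
    stop("`loading` must be in [0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    f <- stats::rnorm(n_subjects)
    e <- matrix(stats::rnorm(n_subjects * n_items), n_subjects, n_items)
    x <- loading * f + sqrt(1 - loading^2) * e
  })
  colnames(x) <- paste0("item", seq_len(n_items))
  x
}
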
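# Kano requirement classification.
#
# A respondent answers each indicator twice: how they would feel if the
# feature were present (functional form) and if it were absent
# (dysfunctional form), each on the 5-level scale like / must_be / neutral /
# live_with / dislike. The pair is looked up in a 5x5 evaluation table that
# maps it to one of six categories: Attractive (A), One-dimensional (O),
# Must-be (M), Indifferent (I), Reverse (R) or Questionable (Q).

 

#' The 5x5 Kano evaluation table
#'
#' Returns the lookup table mapping (functional answer, dysfunctional
#' answer) pairs to Kano categories. The default is the conventional table:
#' (like, dislike) is O; like paired with any middle answer is A;
#' any middle answer paired with dislike is M; (like, like) and
#' (dislike, dislike) are Q (contradictory); any pair in which the
#' dysfunctional answer is strictly more liked than the functional one is R;
#' the remaining nine middle cells are I. A different table can be supplied
#' as a CSV file of the same shape (first column functional answers, header
#' dysfunctional answers, cells category letters).
#'
#' @param path optional CSV overriding the default table.
#' @return 5x5 character matrix with answer-level dimnames.
#' @export
kano_evaluation_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.cache$eval_table)) return(.cache$eval_table)
    path <- extdata_path("kano_evaluation_table.csv")
    cache <- TRUE
  } else cache <- FALSE
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  lv <- kano_answer_levels()
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (!identical(rownames(m), lv) || !identical(colnames(m), lv)) {
    stop("evaluation table must be indexed by the 5 answer levels in order",
         call. = FALSE)
  }
  if (!all(m %in% kano_categories())) {
    stop("evaluation table cells must be one of A, O, M, I, R, Q", call. = FALSE)
  }
  if (cache) .cache$eval_table <- m
  m
}

#' Classify functional/dysfunctional answer pairs
#'
#' @param functional,dysfunctional character vectors of 5-level answers
#'   (recycled to a common length).
#' @param table evaluation table, by default [kano_evaluation_table()].
#' @return character vector of categories in A, O, M, I, R, Q.
#' @export
#' @examples
#' kano_classify("like", "dislike")       # "O"
#' kano_classify("neutral", "neutral")    # "I"
kano_classify <- function(functional, dysfunctional,
                          table = kano_evaluation_table()) {
  lv <- kano_answer_levels()
  n <- max(length(functional), length(dysfunctional))
  functional <- rep_len(as.character(functional), n)
  dysfunctional <- rep_len(as.character(dysfunctional), n)
  bad <- !(functional %in% lv) | !(dysfunctional %in% lv)
  if (any(bad)) {
    stop("answer outside the 5-level domain: ",
         paste(unique(c(functional[bad], dysfunctional[bad])), collapse = ", "),
         call. = FALSE)
  }
  table[cbind(match(functional, lv), match(dysfunctional, lv))]
}

#' Tabulate Kano category distributions per indicator
#'
#' Classifies every response pair and, per indicator, reports the fraction
#' of respondents in each category together with the Better-Worse
#' coefficients (see [kano_better_worse()]). Fractions are over respondents
#' who answered that indicator, so each row sums to 1.
#'
#' @param responses a `kano_response_table`.
#' @param table evaluation table.
#' @return data frame of class `kano_distribution` with columns
#'   `indicator_id, n, a, o, m, i, r, q, better, worse`.
#' @export
kano_tabulate <- function(responses, table = kano_evaluation_table()) {
  stopifnot(inherits(responses, "kano_response_table"))
  if (nrow(responses) == 0L) stop("response table is empty", call. = FALSE)
  cat6 <- kano_classify(responses$functional, responses$dysfunctional, table)
  ids <- unique(responses$indicator_id)
  rows <- lapply(ids, function(id) {
    cc <- cat6[responses$indicator_id == id]
    n <- length(cc)
    fr <- tabulate(match(cc, kano_categories()), nbins = 6L) / n
    data.frame(indicator_id = id, n = n,
               a = fr[1], o = fr[2], m = fr[3], i = fr[4], r = fr[5], q = fr[6],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  bw <- kano_better_worse(out)
  out$better <- bw$better
  out$worse <- bw$worse
  class(out) <- c("kano_distribution", "data.frame")
  out
}

#' Better-Worse satisfaction coefficients
#'
#' Better = (A + O) / (A + O + M + I) estimates the satisfaction gain when
#' the feature is present; Worse = -(O + M) / (A + O + M + I) the
#' dissatisfaction when absent. R and Q responses are excluded from the
#' denominator. Rows whose A + O + M + I mass is zero get `NA` coefficients.
#'
#' @param dist a `kano_distribution` (or any data frame with columns
#'   `a, o, m, i`).
#' @return data frame with columns `indicator_id` (when present), `better`
#'   in \[0, 1\] and `worse` in \[-1, 0\].
#' @export
kano_better_worse <- function(dist) {
  denom <- dist$a + dist$o + dist$m + dist$i
  better <- ifelse(denom > 0, (dist$a + dist$o) / denom, NA_real_)
  worse <- ifelse(denom > 0, -(dist$o + dist$m) / denom, NA_real_)
  out <- data.frame(better = better, worse = worse)
  if (!is.null(dist$indicator_id)) out <- cbind(indicator_id = dist$indicator_id, out)
  out
}

#' Assign a final Kano category per indicator
#'
#' The final demand type is the most frequent category among A, O, M and I;
#' R and Q fractions are reported by [kano_tabulate()] but never win the
#' final assignment. Exact ties are broken by the configured precedence
#' (default M > O > A > I, favouring must-be requirements in
#' safety-critical settings) and flagged. The rule only compares relative
#' frequencies, so it is invariant to any positive rescaling of the row.
#'
#' @param dist a `kano_distribution`.
#' @param tie_break ordered character vector of categories; earlier wins.
#' @return data frame of class `kano_assignment` with columns
#'   `indicator_id, category, rule, tie_broken`.
#' @export
kano_assign <- function(dist, tie_break = c("M", "O", "A", "I")) {
  if (!setequal(tie_break, c("A", "O", "M", "I"))) {
    stop("`tie_break` must be an ordering of A, O, M, I", call. = FALSE)
  }
  fr <- as.matrix(dist[, c("a", "o", "m", "i")])
  colnames(fr) <- c("A", "O", "M", "I")
  rows <- lapply(seq_len(nrow(fr)), function(k) {
    v <- fr[k, ]
    if (sum(v) <= 0) {
      stop("indicator ", dist$indicator_id[k],
           " was answered only with R/Q; no demand type can be assigned",
           call. = FALSE)
    }
    top <- names(v)[v == max(v)]
    tie <- length(top) > 1L
    win <- tie_break[tie_break %in% top][1L]
    data.frame(indicator_id = dist$indicator_id[k], category = win,
               rule = "argmax_AOMI", tie_broken = tie,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("kano_assignment", "data.frame")
  out
}

#' Group assigned indicators into hierarchy category sets
#'
#' Splits final assignments into the must-be (M), one-dimensional (O) and
#' attractive (A) sets that seed the weighting hierarchy; indifferent (I)
#' indicators are excluded from the hierarchy and listed separately.
#'
#' @param assignments a `kano_assignment`.
#' @return list with components `M`, `O`, `A` (character vectors, possibly
#'   empty) and `excluded` (the I-set).
#' @export
kano_category_sets <- function(assignments) {
  pick <- function(cat) assignments$indicator_id[assignments$category == cat]
  list(M = pick("M"), O = pick("O"), A = pick("A"), excluded = pick("I"))
}

#' @export
print.kano_distribution <- function(x, digits = 3, ...) {
  cat("Kano category distribution over", nrow(x), "indicators\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.double, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
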
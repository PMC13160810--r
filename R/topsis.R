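# TOPSIS ranking: aggregate rater scores into an evaluation matrix,
# vector-normalize columnwise, weight, form the positive and negative ideal
# solutions, and order alternatives by relative closeness
# C_i = S_i- / (S_i+ + S_i-).

#' Aggregate rater scores into an evaluation matrix
#'
#' f_ij is the arithmetic mean score of alternative i on indicator j over
#' all raters, expert and user groups pooled with equal weight. Kept at
#' full precision internally; round only for display.
#'
#' @param scores a `score_table`.
#' @return numeric alternatives-by-indicators matrix of class
#'   `evaluation_matrix`, values on the 1-7 scale.
#' @export
aggregate_scores <- function(scores) {
  stopifnot(inherits(scores, "score_table"))
  alts <- unique(scores$alternative_id)
  inds <- unique(scores$indicator_id)
  f <- matrix(NA_real_, length(alts), length(inds),
              dimnames = list(alts, inds))
  agg <- stats::aggregate(score ~ alternative_id + indicator_id,
                          data = scores, FUN = mean)
  f[cbind(match(agg$alternative_id, alts), match(agg$indicator_id, inds))] <-
    agg$score
  if (anyNA(f)) {
    hole <- which(is.na(f), arr.ind = TRUE)[1L, ]
    stop("no scores for alternative '", alts[hole[1L]], "' on indicator '",
         inds[hole[2L]], "'", call. = FALSE)
  }
  class(f) <- c("evaluation_matrix", class(matrix()))
  f
}

#' Columnwise vector normalization
#'
#' R_ij = f_ij / sqrt(sum_i f_ij^2); every column of the result has unit
#' Euclidean norm.
#'
#' @param f evaluation matrix (alternatives x indicators).
#' @return normalized matrix.
#' @export
topsis_normalize <- function(f) {
  f <- unclass_matrix(f)
  norms <- sqrt(colSums(f^2))
  if (any(norms == 0)) {
    stop("cannot normalize all-zero column(s): ",
         paste(colnames(f)[norms == 0], collapse = ", "), call. = FALSE)
  }
  sweep(f, 2L, norms, `/`)
}

unclass_matrix <- function(f) {
  f <- as.matrix(f)
  storage.mode(f) <- "double"
  if (anyNA(f)) stop("evaluation matrix contains missing cells", call. = FALSE)
  f
}

#' Apply indicator weights
#'
#' u_ij = W_j * R_ij. Closeness is invariant to rescaling the whole weight
#' vector by a positive constant.
#'
#' @param r normalized matrix.
#' @param w nonnegative weight vector, one entry per indicator.
#' @return weighted normalized matrix.
#' @export
topsis_weight <- function(r, w) {
  r <- unclass_matrix(r)
  if (length(w) != ncol(r)) {
    stop("weight vector has length ", length(w), " but the matrix has ",
         ncol(r), " indicators", call. = FALSE)
  }
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  sweep(r, 2L, as.numeric(w), `*`)
}

#' Positive and negative ideal solutions
#'
#' For benefit indicators the positive ideal takes the columnwise maximum
#' and the negative ideal the minimum; cost indicators are reversed.
#'
#' @param u weighted normalized matrix.
#' @param directions per-indicator `"benefit"` or `"cost"` (recycled).
#' @return list with vectors `positive` and `negative`.
#' @export
topsis_ideals <- function(u, directions = "benefit") {
  u <- unclass_matrix(u)
  directions <- rep_len(directions, ncol(u))
  bad <- !(directions %in% c("benefit", "cost"))
  if (any(bad)) {
    stop("unknown direction label(s): ",
         paste(unique(directions[bad]), collapse = ", "), call. = FALSE)
  }
  hi <- apply(u, 2L, max)
  lo <- apply(u, 2L, min)
  cost <- directions == "cost"
  pos <- ifelse(cost, lo, hi)
  neg <- ifelse(cost, hi, lo)
  names(pos) <- names(neg) <- colnames(u)
  list(positive = pos, negative = neg)
}

#' Distances and relative closeness
#'
#' S_i+ and S_i- are the Euclidean distances of each row of the weighted
#' matrix to the positive and negative ideal; the relative closeness is
#' C_i = S_i- / (S_i+ + S_i-), in \[0, 1\]. When both distances are zero
#' (all alternatives identical) C_i is set to 0.5 by convention and
#' flagged. Ranking is by descending C_i, stable on ties.
#'
#' @param u weighted normalized matrix.
#' @param ideals result of [topsis_ideals()] computed from the same `u`.
#' @return object of class `topsis_result`.
#' @export
topsis_closeness <- function(u, ideals) {
  u <- unclass_matrix(u)
  s_plus <- sqrt(rowSums(sweep(u, 2L, ideals$positive)^2))
  s_minus <- sqrt(rowSums(sweep(u, 2L, ideals$negative)^2))
  degenerate <- (s_plus + s_minus) == 0
  closeness <- ifelse(degenerate, 0.5, s_minus / (s_plus + s_minus))
  rk <- rank_descending(closeness)
  tied <- duplicated(closeness) | duplicated(closeness, fromLast = TRUE)
  ranking <- data.frame(alternative = rownames(u) %||% seq_len(nrow(u)),
                        s_plus = s_plus, s_minus = s_minus,
                        closeness = closeness, rank = rk, tied = tied,
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(weighted = u, ideals = ideals, s_plus = s_plus,
                 s_minus = s_minus, closeness = closeness,
                 degenerate = degenerate, ranking = ranking),
            class = "topsis_result")
}

#' Full TOPSIS run
#'
#' Chains normalization, weighting, ideal formation and closeness.
#'
#' @param f evaluation matrix (alternatives x indicators) or
#'   `evaluation_matrix`.
#' @param weights per-indicator weights; uniform when omitted.
#' @param directions per-indicator `"benefit"` (default) or `"cost"`.
#' @return a `topsis_result` with the intermediate matrices attached
#'   (`normalized`, `weights`, `directions`).
#' @export
#' @examples
#' f <- rbind(a = c(7, 7, 7), b = c(1, 1, 1))
#' topsis(f)$closeness   # c(1, 0)
topsis <- function(f, weights = NULL, directions = "benefit") {
  f <- unclass_matrix(f)
  weights <- weights %||% rep(1 / ncol(f), ncol(f))
  r <- topsis_normalize(f)
  u <- topsis_weight(r, weights)
  ideals <- topsis_ideals(u, directions)
  out <- topsis_closeness(u, ideals)
  out$normalized <- r
  out$weights <- stats::setNames(as.numeric(weights),
                                 colnames(f) %||% seq_len(ncol(f)))
  out$directions <- rep_len(directions, ncol(f))
  out
}

#' Ranked report table
#'
#' @param result a `topsis_result`.
#' @param precision decimal places for display columns.
#' @return data frame (alternative, s_plus, s_minus, closeness, rank, tied)
#'   ordered by rank.
#' @export
topsis_rank_report <- function(result, precision = 3L) {
  stopifnot(inherits(result, "topsis_result"))
  tab <- result$ranking
  for (col in c("s_plus", "s_minus", "closeness")) {
    tab[[col]] <- round(tab[[col]], precision)
  }
  tab[order(tab$rank), , drop = FALSE]
}

#' @export
print.topsis_result <- function(x, ...) {
  cat("TOPSIS ranking of", nrow(x$ranking), "alternatives\n")
  print.data.frame(topsis_rank_report(x), row.names = FALSE)
  if (any(x$degenerate)) cat("note: degenerate closeness set to 0.5\n")
  invisible(x)
}

#' Read an evaluation matrix from CSV
#'
#' First column `alternative`, remaining columns one per indicator.
#'
#' @param path CSV file.
#' @return an `evaluation_matrix`.
#' @export
read_evaluation_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  f <- as.matrix(df[, -1L, drop = FALSE])
  rownames(f) <- df[[1L]]
  storage.mode(f) <- "double"
  if (anyNA(f)) stop("evaluation matrix contains non-numeric cells", call. = FALSE)
  class(f) <- c("evaluation_matrix", class(matrix()))
  f
}
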
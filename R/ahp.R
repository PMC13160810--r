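# Analytic hierarchy process: priority weights from Saaty pairwise ratio
# judgments, consistency diagnostics, and synthesis of global indicator
# weights down a criterion -> indicator hierarchy.

#' Construct / validate a pairwise comparison matrix
#'
#' Entries must be positive ratio judgments and the grid square; unit
#' diagonal and reciprocity are *not* enforced here, because published
#' matrices sometimes violate both — [validate_reciprocity()] reports such
#' defects and [repair_from_upper_triangle()] fixes them.
#'
#' @param x square numeric matrix of positive ratio judgments.
#' @param items optional item labels (defaults to existing dimnames).
#' @return a `pairwise_matrix`.
#' @export
as_pairwise_matrix <- function(x, items = NULL) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) {
    stop("pairwise matrix must be square, got ", nrow(x), " x ", ncol(x),
         call. = FALSE)
  }
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    stop("pairwise matrix entries must all be positive numbers", call. = FALSE)
  }
  items <- items %||% rownames(x) %||% paste0("item", seq_len(nrow(x)))
  dimnames(x) <- list(items, items)
  class(x) <- c("pairwise_matrix", class(matrix()))
  x
}

#' Report reciprocity violations
#'
#' A Saaty matrix must satisfy a_ij * a_ji = 1 (for i = j this is the unit
#' diagonal). Returns the upper-triangle-with-diagonal pairs violating
#' this beyond `tol`; an empty report means the matrix is valid.
#'
#' @param m a `pairwise_matrix`.
#' @param tol absolute tolerance on |a_ij * a_ji - 1|.
#' @return data frame with columns `i, j, item_i, item_j, value, transpose,
#'   product`.
#' @export
validate_reciprocity <- function(m, tol = 1e-9) {
  m <- as_pairwise_matrix(m)
  n <- nrow(m)
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  prod <- m[idx] * t(m)[idx]
  bad <- abs(prod - 1) > tol
  data.frame(i = idx[bad, 1L], j = idx[bad, 2L],
             item_i = rownames(m)[idx[bad, 1L]],
             item_j = rownames(m)[idx[bad, 2L]],
             value = m[idx[bad, , drop = FALSE]],
             transpose = t(m)[idx[bad, , drop = FALSE]],
             product = prod[bad],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Repair a matrix from its upper triangle
#'
#' Keeps the strictly-upper-triangle judgments, replaces the lower triangle
#' by their reciprocals and sets the diagonal to 1, yielding a reciprocal
#' matrix. Idempotent; already-reciprocal matrices are returned unchanged.
#'
#' @param m a `pairwise_matrix`.
#' @return a reciprocal `pairwise_matrix`.
#' @export
repair_from_upper_triangle <- function(m) {
  m <- as_pairwise_matrix(m)
  up <- upper.tri(m)
  m[t(up)] <- t(1 / m)[t(up)]
  diag(m) <- 1
  as_pairwise_matrix(m)
}

#' Saaty's random consistency index
#'
#' Expected consistency index of random reciprocal matrices of order n,
#' used as the denominator of the consistency ratio. The classic values
#' ship as a data file and can be overridden.
#'
#' @param n matrix order.
#' @param table optional data frame with columns `n, ri`.
#' @return the RI value.
#' @export
saaty_ri <- function(n, table = NULL) {
  if (is.null(table)) {
    if (is.null(.cache$ri)) {
      .cache$ri <- utils::read.csv(extdata_path("saaty_ri.csv"))
    }
    table <- .cache$ri
  }
  hit <- match(n, table$n)
  if (is.na(hit)) {
    stop("no random-index entry for matrix order n = ", n,
         "; extend the RI table", call. = FALSE)
  }
  table$ri[hit]
}

#' Consistency index and ratio
#'
#' CI = (lambda_max - n) / (n - 1); CR = CI / RI(n) for n >= 3 and 0 for
#' n <= 2 (orders 1-2 are always consistent). A judgment set is
#' conventionally acceptable when CR < 0.1.
#'
#' @param lambda_max dominant eigenvalue of the judgment matrix.
#' @param n matrix order (>= 2).
#' @param ri_table optional override for [saaty_ri()].
#' @return list with `ci`, `cr`, `ri`, `n`, `lambda_max`.
#' @export
#' @examples
#' ahp_consistency(5.425, 5)  # ci 0.106, cr 0.095 at 3 dp
ahp_consistency <- function(lambda_max, n, ri_table = NULL) {
  if (n < 2 || n != trunc(n)) stop("`n` must be an integer >= 2", call. = FALSE)
  if (lambda_max < n - 1e-9) {
    stop("lambda_max (", lambda_max, ") below matrix order n = ", n,
         "; not a dominant eigenvalue of a reciprocal matrix", call. = FALSE)
  }
  ci <- (lambda_max - n) / (n - 1)
  if (n <= 2) {
    ri <- 0
    cr <- 0
  } else {
    ri <- saaty_ri(n, ri_table)
    cr <- ci / ri
  }
  list(ci = ci, cr = cr, ri = ri, n = as.integer(n), lambda_max = lambda_max)
}

#' Priority weights of a judgment matrix
#'
#' Derives the local priority vector and consistency diagnostics. The
#' eigenvector method runs power iteration from the uniform vector
#' (convergence when successive sum-normalised vectors differ by less than
#' `tol` in max-norm, capped at `max_iter`), with lambda_max from the
#' Rayleigh quotient at convergence. The geometric-mean method normalises
#' the row geometric means and takes lambda_max as the mean of (A w)_i / w_i.
#' For a perfectly consistent matrix both recover the generating weights
#' exactly and CI = CR = 0.
#'
#' @param m a `pairwise_matrix`.
#' @param method `"eigenvector"` (default) or `"geometric_mean"`.
#' @param reciprocity `"strict"` errors on reciprocity violations;
#'   `"repair_upper"` (default) rebuilds the lower triangle from the upper
#'   first.
#' @param tol,max_iter power-iteration controls.
#' @return object of class `ahp_weights`: named `weights` summing to 1,
#'   `lambda_max`, `ci`, `cr`, `ri_used`, `method`, `n`, `iterations`,
#'   `repaired`.
#' @export
priority_weights <- function(m, method = c("eigenvector", "geometric_mean"),
                             reciprocity = c("repair_upper", "strict"),
                             tol = 1e-12, max_iter = 10000L) {
  method <- match.arg(method)
  reciprocity <- match.arg(reciprocity)
  m <- as_pairwise_matrix(m)
  viol <- validate_reciprocity(m)
  repaired <- FALSE
  if (nrow(viol) > 0L) {
    if (reciprocity == "strict") {
      stop("matrix violates reciprocity at ",
           paste(paste0("(", viol$item_i, ",", viol$item_j, ")"),
                 collapse = ", "),
           "; use reciprocity = \"repair_upper\" to rebuild from the upper triangle",
           call. = FALSE)
    }
    m <- repair_from_upper_triangle(m)
    repaired <- TRUE
  }
  n <- nrow(m)
  if (n == 1L) {
    return(structure(list(weights = stats::setNames(1, rownames(m)),
                          lambda_max = 1, ci = 0, cr = 0, ri_used = 0,
                          method = method, n = 1L, iterations = 0L,
                          repaired = repaired),
                     class = "ahp_weights"))
  }
  iterations <- 0L
  if (method == "eigenvector") {
    w <- rep(1 / n, n)
    repeat {
      iterations <- iterations + 1L
      w1 <- as.numeric(m %*% w)
      w1 <- w1 / sum(w1)
      if (max(abs(w1 - w)) < tol) { w <- w1; break }
      w <- w1
      if (iterations >= max_iter) {
        stop("power iteration did not converge in ", max_iter,
             " iterations (last max-norm change ", format(max(abs(w1 - w))),
             ")", call. = FALSE)
      }
    }
    aw <- as.numeric(m %*% w)
    lambda_max <- sum(w * aw) / sum(w * w)
  } else {
    gm <- apply(m, 1L, function(row) exp(mean(log(row))))
    w <- gm / sum(gm)
    aw <- as.numeric(m %*% w)
    lambda_max <- mean(aw / w)
  }
  names(w) <- rownames(m)
  cons <- ahp_consistency(lambda_max, n)
  structure(list(weights = w, lambda_max = lambda_max, ci = cons$ci,
                 cr = cons$cr, ri_used = cons$ri, method = method,
                 n = n, iterations = iterations, repaired = repaired),
            class = "ahp_weights")
}

#' @export
print.ahp_weights <- function(x, digits = 4, ...) {
  cat("AHP priority weights (", x$method, ", n = ", x$n, ")\n", sep = "")
  print(round(x$weights, digits))
  cat(sprintf("lambda_max = %.4f  CI = %.4f  CR = %.4f%s\n",
              x$lambda_max, x$ci, x$cr,
              if (x$repaired) "  [lower triangle rebuilt]" else ""))
  invisible(x)
}

#' Synthesize global weights down the hierarchy
#'
#' Multiplies each indicator's local weight by its criterion weight,
#' renormalises the products to sum to 1, and ranks indicators by
#' descending global weight (ties keep input order).
#'
#' @param criterion an `ahp_weights` over the criterion categories.
#' @param locals named list of `ahp_weights`, one per criterion category;
#'   names must match the criterion items.
#' @return object of class `ahp_hierarchy` with a `table` (indicator,
#'   category, local_weight, global_weight, rank), the `criterion` result
#'   and the `locals` list.
#' @export
synthesize_global <- function(criterion, locals) {
  stopifnot(inherits(criterion, "ahp_weights"))
  cats <- names(criterion$weights)
  miss <- setdiff(cats, names(locals))
  if (length(miss)) {
    stop("no local weights supplied for criterion: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(cats, function(cat) {
    lw <- locals[[cat]]
    stopifnot(inherits(lw, "ahp_weights"))
    data.frame(indicator = names(lw$weights), category = cat,
               local_weight = unname(lw$weights),
               global_weight = unname(lw$weights) * criterion$weights[[cat]],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab$indicator)) {
    stop("indicator(s) appear in more than one category: ",
         paste(unique(tab$indicator[duplicated(tab$indicator)]), collapse = ", "),
         call. = FALSE)
  }
  tab$global_weight <- tab$global_weight / sum(tab$global_weight)
  tab$rank <- rank_descending(tab$global_weight)
  structure(list(table = tab, criterion = criterion, locals = locals),
            class = "ahp_hierarchy")
}

# Dense ranks by descending value, stable on ties (first occurrence ranks
# ahead), as positions in the sort order.
rank_descending <- function(x) {
  ord <- order(-x, seq_along(x))
  rk <- integer(length(x))
  rk[ord] <- seq_along(x)
  rk
}

#' @export
print.ahp_hierarchy <- function(x, digits = 4, ...) {
  cat("AHP hierarchy:", nrow(x$table), "indicators in",
      length(x$locals), "categories\n")
  tab <- x$table
  tab$local_weight <- round(tab$local_weight, digits)
  tab$global_weight <- round(tab$global_weight, digits)
  print.data.frame(tab[order(tab$rank), ], row.names = FALSE)
  invisible(x)
}
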
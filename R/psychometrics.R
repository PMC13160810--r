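# Questionnaire reliability and validity battery: Cronbach's alpha for
# internal consistency, the Kaiser-Meyer-Olkin measure of sampling adequacy,
# and Bartlett's test of sphericity. All variances and correlations use the
# sample (n - 1) convention.

check_item_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("item matrix must be numeric", call. = FALSE)
  if (anyNA(x)) stop("item matrix contains missing cells", call. = FALSE)
  if (nrow(x) < 3L || ncol(x) < 2L) {
    stop("need at least 3 subjects and 2 items", call. = FALSE)
  }
  x
}

#' Cronbach's alpha
#'
#' alpha = k/(k - 1) * (1 - sum of item variances / variance of the total
#' score), with k items and sample variances throughout. Equals 1 for
#' perfectly parallel items and k*rho / (1 + (k-1)*rho) in expectation for
#' parallel items with inter-item correlation rho.
#'
#' @param x subjects-by-items numeric matrix.
#' @return alpha, a unitless coefficient in (-Inf, 1]; `NA` when the total
#'   score has zero variance.
#' @export
cronbach_alpha <- function(x) {
  x <- check_item_matrix(x)
  k <- ncol(x)
  vtot <- stats::var(rowSums(x))
  if (vtot <= 0) return(NA_real_)
  vitems <- sum(apply(x, 2L, stats::var))
  k / (k - 1) * (1 - vitems / vtot)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Compares squared zero-order correlations r_ij with squared partial
#' correlations q_ij obtained from the scaled inverse correlation matrix:
#' overall KMO = sum r_ij^2 / (sum r_ij^2 + sum q_ij^2) over i != j, and the
#' per-item MSA uses the same ratio over each row.
#'
#' @param x subjects-by-items numeric matrix.
#' @return list with `overall` in \[0, 1\] and named per-item `msa`.
#' @export
kmo <- function(x) {
  x <- check_item_matrix(x)
  r <- stats::cor(x)
  rinv <- tryCatch(solve(r), error = function(e) {
    stop("correlation matrix is singular (condition number ",
         format(kappa(r), digits = 3), "); drop redundant items",
         call. = FALSE)
  })
  d <- 1 / sqrt(diag(rinv))
  q <- -rinv * outer(d, d)      # partial correlations, up to its diagonal
  diag(q) <- 0
  diag(r) <- 0
  r2 <- r^2
  q2 <- q^2
  overall <- sum(r2) / (sum(r2) + sum(q2))
  msa <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  names(msa) <- colnames(x) %||% paste0("item", seq_len(ncol(x)))
  list(overall = overall, msa = msa)
}

#' Bartlett's test of sphericity
#'
#' Tests whether the item correlation matrix is the identity using
#' chi2 = -(n - 1 - (2p + 5)/6) * ln det(R) on p(p - 1)/2 degrees of
#' freedom, with the p-value from the upper chi-square tail.
#'
#' @param x subjects-by-items numeric matrix with more subjects than items.
#' @return list with `chi2`, `df` and `p`.
#' @export
bartlett_sphericity <- function(x) {
  x <- check_item_matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p) stop("need more subjects than items", call. = FALSE)
  r <- stats::cor(x)
  ld <- determinant(r, logarithm = TRUE)
  if (ld$sign <= 0) {
    stop("correlation matrix is not positive definite", call. = FALSE)
  }
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * as.numeric(ld$modulus)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Full psychometric report for an item matrix
#'
#' @param x subjects-by-items numeric matrix.
#' @return list with `alpha`, `kmo`, per-item `msa`, `bartlett_chi2`,
#'   `bartlett_df`, `bartlett_p` and `n_items`, `n_subjects`.
#' @export
psychometric_report <- function(x) {
  x <- check_item_matrix(x)
  k <- kmo(x)
  b <- bartlett_sphericity(x)
  list(alpha = cronbach_alpha(x), kmo = k$overall, msa = k$msa,
       bartlett_chi2 = b$chi2, bartlett_df = b$df, bartlett_p = b$p,
       n_items = ncol(x), n_subjects = nrow(x))
}
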
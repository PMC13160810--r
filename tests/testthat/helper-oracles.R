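# Independent oracles, written deliberately naively (explicit loops, no
# shared code with the package implementation paths they check).

# Step-by-step TOPSIS with plain loops over a 2D array.
oracle_topsis <- function(f, w) {
  m <- nrow(f); n <- ncol(f)
  r <- matrix(0, m, n)
  for (j in seq_len(n)) {
    denom <- sqrt(sum(f[, j]^2))
    for (i in seq_len(m)) r[i, j] <- f[i, j] / denom
  }
  u <- matrix(0, m, n)
  for (j in seq_len(n)) for (i in seq_len(m)) u[i, j] <- w[j] * r[i, j]
  apos <- apply(u, 2, max); aneg <- apply(u, 2, min)
  sp <- sn <- numeric(m)
  for (i in seq_len(m)) {
    sp[i] <- sqrt(sum((u[i, ] - apos)^2))
    sn[i] <- sqrt(sum((u[i, ] - aneg)^2))
  }
  list(s_plus = sp, s_minus = sn, closeness = sn / (sp + sn))
}

# Cronbach's alpha from the covariance matrix: k/(k-1) (1 - tr(S)/sum(S)).
oracle_alpha <- function(x) {
  s <- cov(x)
  k <- ncol(x)
  k / (k - 1) * (1 - sum(diag(s)) / sum(s))
}

# Partial correlation of items i and j given all others, by regression
# residuals.
oracle_partial_cor <- function(x, i, j) {
  others <- x[, -c(i, j), drop = FALSE]
  ri <- if (ncol(others)) resid(lm(x[, i] ~ others)) else x[, i] - mean(x[, i])
  rj <- if (ncol(others)) resid(lm(x[, j] ~ others)) else x[, j] - mean(x[, j])
  cor(ri, rj)
}

# KMO from zero-order correlations and regression-residual partials.
oracle_kmo <- function(x) {
  p <- ncol(x)
  r <- cor(x)
  q <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    q[i, j] <- q[j, i] <- oracle_partial_cor(x, i, j)
  }
  diag(r) <- 0
  sum(r^2) / (sum(r^2) + sum(q^2))
}

# Bartlett chi-square via the eigenvalues of the correlation matrix.
oracle_bartlett_chi2 <- function(x) {
  n <- nrow(x); p <- ncol(x)
  ev <- eigen(cor(x), symmetric = TRUE, only.values = TRUE)$values
  -(n - 1 - (2 * p + 5) / 6) * sum(log(ev))
}

# AHP weights via the dominant eigenvector from base eigen().
oracle_ahp_weights <- function(m) {
  e <- eigen(m)
  k <- which.max(Re(e$values))
  v <- Re(e$vectors[, k])
  v <- v / sum(v)
  list(weights = v, lambda_max = Re(e$values[k]))
}

# Subjects-by-items data whose *sample* correlation matrix is exactly
# `target` (columns are exact linear combinations of orthonormal
# mean-zero vectors, so cor(x) == target to machine precision).
exact_cor_data <- function(n, target, seed = 1) {
  p <- ncol(target)
  stopifnot(n > p + 1)
  z <- withr_seed_matrix(n, p, seed)
  z <- scale(z, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(z))              # orthonormal, each column mean-zero
  q %*% chol(target)
}

withr_seed_matrix <- function(n, p, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

# Small indicator set reused across tests.
toy_indicators <- function(n = 2) {
  ids <- c("A1", "A2", "B1", "B2", "C1", "D1")[seq_len(n)]
  dims <- c(A = "functional", B = "appearance", C = "culture_management",
            D = "technical")[substr(ids, 1, 1)]
  indicator_set(ids, unname(dims))
}

equicor <- function(p, rho) {
  m <- matrix(rho, p, p)
  diag(m) <- 1
  m
}
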
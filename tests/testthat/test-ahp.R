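consistent_matrix <- function(w) generate_pairwise_matrix(w, sigma = 0)

test_that("reciprocity validation reports exactly the defective pairs", {
  m <- consistent_matrix(c(0.5, 0.3, 0.2))
  expect_equal(nrow(validate_reciprocity(m)), 0L)
  expect_equal(nrow(validate_reciprocity(matrix(1, 4, 4))), 0L)

  jm <- study_judgment_matrices()$M
  v <- validate_reciprocity(jm)
  expect_gt(nrow(v), 0L)
  hit <- v[v$item_i == "M3" & v$item_j == "M4", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$value, 1)
  expect_equal(hit$transpose, 2)
})

test_that("upper-triangle repair yields reciprocal matrices and is idempotent", {
  m <- consistent_matrix(c(0.4, 0.35, 0.25))
  expect_equal(unclass(repair_from_upper_triangle(m)), unclass(m))

  jm <- study_judgment_matrices()$M
  fixed <- repair_from_upper_triangle(jm)
  expect_equal(nrow(validate_reciprocity(fixed)), 0L)

  for (s in 1:30) {
    raw <- matrix(exp(rnorm(25, sd = abs(sin(s)))), 5, 5)
    diag(raw) <- 1
    r1 <- repair_from_upper_triangle(as_pairwise_matrix(raw))
    expect_equal(unclass(repair_from_upper_triangle(r1)), unclass(r1))
    expect_equal(nrow(validate_reciprocity(r1)), 0L)
  }
})

test_that("consistent matrices return the generating weights with zero CI", {
  w <- c(0.5, 0.3, 0.2)
  for (method in c("eigenvector", "geometric_mean")) {
    res <- priority_weights(consistent_matrix(w), method = method)
    expect_equal(unname(res$weights), w, tolerance = 1e-10)
    expect_equal(res$lambda_max, 3, tolerance = 1e-10)
    expect_equal(res$ci, 0, tolerance = 1e-10)
    expect_equal(res$cr, 0, tolerance = 1e-10)
  }
})

test_that("2x2 matrices have the closed-form solution and zero CR", {
  m <- as_pairwise_matrix(rbind(c(1, 3), c(1 / 3, 1)))
  res <- priority_weights(m)
  expect_equal(unname(res$weights), c(0.75, 0.25), tolerance = 1e-10)
  expect_equal(res$lambda_max, 2, tolerance = 1e-10)
  expect_equal(res$cr, 0)
})

test_that("strict mode refuses non-reciprocal input; repair mode flags it", {
  jm <- study_judgment_matrices()$O
  expect_error(priority_weights(jm, reciprocity = "strict"), "reciprocity")
  res <- priority_weights(jm)
  expect_true(res$repaired)
  expect_equal(sum(res$weights), 1, tolerance = 1e-12)
})

test_that("eigenvector and geometric-mean methods agree on near-consistent matrices", {
  kept <- 0
  for (s in 1:60) {
    w <- rexp(5, 1) + 0.2
    w <- w / sum(w)
    m <- generate_pairwise_matrix(w, sigma = 0.04, seed = s)
    r1 <- priority_weights(m, method = "eigenvector")
    if (r1$cr >= 0.1) next
    kept <- kept + 1
    r2 <- priority_weights(m, method = "geometric_mean")
    expect_lt(sum(abs(r1$weights - r2$weights)), 1e-3)
  }
  expect_gt(kept, 30)
})

test_that("consistency arithmetic follows (lambda - n)/(n - 1) and the RI table", {
  res <- ahp_consistency(5.425, 5)
  expect_equal(res$ci, 0.10625)
  expect_equal(round(res$ci, 3), 0.106)
  expect_equal(res$ri, 1.12)
  expect_equal(round(res$cr, 3), 0.095)

  expect_equal(ahp_consistency(5, 5)$ci, 0)
  expect_equal(ahp_consistency(2.0, 2)$cr, 0)
  expect_error(ahp_consistency(12, 11), "random-index")
  expect_error(ahp_consistency(3, 5), "below matrix order")
})

test_that("lambda_max >= n and CI >= 0 on random reciprocal matrices", {
  for (s in 1:25) {
    w <- rexp(4, 1) + 0.1; w <- w / sum(w)
    m <- generate_pairwise_matrix(w, sigma = 0.5, seed = s)
    res <- priority_weights(m)
    expect_gte(res$lambda_max, res$n - 1e-9)
    expect_gte(res$ci, -1e-12)
  }
})

test_that("permuting items permutes weights identically", {
  w <- c(0.45, 0.25, 0.2, 0.1)
  m <- generate_pairwise_matrix(w, sigma = 0.2, seed = 5)
  perm <- c(3, 1, 4, 2)
  mp <- as_pairwise_matrix(m[perm, perm])
  r <- priority_weights(m)
  rp <- priority_weights(mp)
  expect_equal(unname(rp$weights), unname(r$weights[perm]), tolerance = 1e-9)
  expect_equal(rp$lambda_max, r$lambda_max, tolerance = 1e-9)
})

test_that("eigenvector weights agree with a base eigen() oracle", {
  for (s in 1:20) {
    w <- rexp(5, 1) + 0.1; w <- w / sum(w)
    m <- generate_pairwise_matrix(w, sigma = 0.3, seed = s)
    mine <- priority_weights(m)
    ref <- oracle_ahp_weights(unclass(m))
    expect_equal(unname(mine$weights), ref$weights, tolerance = 1e-8)
    expect_equal(mine$lambda_max, ref$lambda_max, tolerance = 1e-8)
  }
})

test_that("global synthesis multiplies, renormalizes, and ranks stably", {
  crit <- priority_weights(consistent_matrix(c(M = 0.5, O = 0.3, A = 0.2)))
  locals <- list(
    M = priority_weights(consistent_matrix(c(m1 = 0.6, m2 = 0.4))),
    O = priority_weights(as_pairwise_matrix(matrix(1, 1, 1, dimnames = list("o1", "o1")))),
    A = priority_weights(consistent_matrix(c(a1 = 0.7, a2 = 0.3))))
  h <- synthesize_global(crit, locals)
  expect_equal(h$table$global_weight, c(0.30, 0.20, 0.30, 0.14, 0.06),
               tolerance = 1e-9)
  expect_equal(sum(h$table$global_weight), 1, tolerance = 1e-12)
  # tie between m1 (0.30) and o1 (0.30): input order decides
  expect_equal(h$table$rank[h$table$indicator == "m1"], 1L)
  expect_equal(h$table$rank[h$table$indicator == "o1"], 2L)

  single <- synthesize_global(
    priority_weights(as_pairwise_matrix(matrix(1, 1, 1, dimnames = list("M", "M")))),
    list(M = locals$M))
  expect_equal(single$table$global_weight, unname(locals$M$weights))

  dup <- list(M = locals$M, O = locals$M, A = locals$A)
  expect_error(synthesize_global(crit, dup), "more than one category")
})

test_that("bundled-layer products do not reproduce the reported combined weights", {
  jm <- study_judgment_matrices()
  crit <- priority_weights(jm$criterion)
  locals <- list(M = priority_weights(jm$M), O = priority_weights(jm$O),
                 A = priority_weights(jm$N))
  h <- synthesize_global(crit, locals)
  expect_equal(sum(h$table$global_weight), 1, tolerance = 1e-9)
  cw <- study_combined_weights()
  m1_combined <- cw$combined_weight[cw$indicator == "M1"]   # 0.410 as reported
  m1_global <- h$table$global_weight[h$table$indicator == "M1"]
  expect_gt(abs(m1_global - m1_combined), 0.05)
})

test_that("weight recovery error shrinks as the perturbation scale shrinks", {
  sig_grid <- c(0.05, 0.15, 0.3)
  w <- c(0.40, 0.25, 0.15, 0.12, 0.08)
  err <- vapply(sig_grid, function(sig) {
    mean(vapply(1:50, function(s) {
      m <- generate_pairwise_matrix(w, sigma = sig, seed = s)
      sum(abs(priority_weights(m)$weights - w))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) > 0))
})
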
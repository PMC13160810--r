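test_that("the evaluation table maps every cell to exactly one category", {
  tab <- kano_evaluation_table()
  lv <- c("like", "must_be", "neutral", "live_with", "dislike")
  grid <- expand.grid(f = lv, d = lv, stringsAsFactors = FALSE)
  cats <- kano_classify(grid$f, grid$d)
  expect_length(cats, 25L)
  expect_true(all(cats %in% c("A", "O", "M", "I", "R", "Q")))
  counts <- table(cats)
  expect_equal(unname(counts[c("O", "Q", "A", "M", "R", "I")]),
               c(1L, 2L, 3L, 3L, 7L, 9L), ignore_attr = TRUE)
})

test_that("definitional cells classify as expected", {
  expect_equal(kano_classify("like", "dislike"), "O")
  expect_equal(kano_classify("neutral", "neutral"), "I")
  expect_equal(kano_classify("dislike", "like"), "R")
  expect_equal(kano_classify("like", "like"), "Q")
  expect_equal(kano_classify("like", "neutral"), "A")
  expect_equal(kano_classify("must_be", "dislike"), "M")
  expect_error(kano_classify("meh", "like"), "5-level")
})

test_that("tabulate counts categories per indicator and rows sum to one", {
  ind <- toy_indicators(1)
  df <- data.frame(
    respondent_id = paste0("r", 1:4), role = "older_adult",
    indicator_id = "A1",
    functional = c("must_be", "neutral", "like", "neutral"),
    dysfunctional = c("dislike", "dislike", "dislike", "neutral"),
    stringsAsFactors = FALSE)
  dist <- kano_tabulate(as_kano_response_table(df, ind))
  expect_equal(dist$m, 0.5)
  expect_equal(dist$o, 0.25)
  expect_equal(dist$i, 0.25)
  expect_equal(dist$n, 4L)

  # property: fractions sum to 1 over random tables
  for (s in 1:25) {
    tbl <- generate_kano_responses(toy_indicators(3), planted = "O",
                                   n_respondents = 17, error_rate = 1,
                                   seed = s)
    d <- kano_tabulate(tbl)
    expect_equal(d$a + d$o + d$m + d$i + d$r + d$q, rep(1, 3),
                 tolerance = 1e-12)
  }
})

test_that("zero-noise synthetic data recovers the planted category with fraction 1", {
  tbl <- generate_kano_responses(toy_indicators(2), planted = "O",
                                 n_respondents = 50, error_rate = 0, seed = 1)
  d <- kano_tabulate(tbl)
  expect_equal(d$o, c(1, 1))
})

test_that("argmax assignment reproduces consistent worked-example rows and flags ties", {
  d <- study_kano_distributions()
  a <- kano_assign(d)
  cat_of <- function(id) a$category[a$indicator_id == id]
  expect_equal(cat_of("A1"), "M")
  expect_equal(cat_of("C3"), "I")
  # B1's largest A/O/M/I fraction is I although the source reports M
  expect_equal(cat_of("B1"), "I")
  expect_false(all(a$category == d$reported_category))

  # invariance to renormalization by a positive constant
  d_raw <- study_kano_distributions(renormalize = FALSE)
  expect_equal(kano_assign(d_raw)$category, a$category)

  # tie-break precedence and flag
  tie <- data.frame(indicator_id = "A1", n = 4L,
                    a = 0.4, o = 0.4, m = 0.1, i = 0.1, r = 0, q = 0)
  res <- kano_assign(tie)
  expect_equal(res$category, "O")   # default M > O > A > I
  expect_true(res$tie_broken)
  expect_equal(kano_assign(tie, tie_break = c("A", "O", "M", "I"))$category, "A")

  # all mass on R/Q cannot be assigned
  rq <- data.frame(indicator_id = "A1", n = 4L,
                   a = 0, o = 0, m = 0, i = 0, r = 0.6, q = 0.4)
  expect_error(kano_assign(rq), "R/Q")
})

test_that("Better-Worse coefficients follow the standard formulas", {
  sym <- data.frame(a = 0.25, o = 0.25, m = 0.25, i = 0.25)
  bw <- kano_better_worse(sym)
  expect_equal(bw$better, 0.5)
  expect_equal(bw$worse, -0.5)

  pure_a <- data.frame(a = 1, o = 0, m = 0, i = 0)
  bw <- kano_better_worse(pure_a)
  expect_equal(bw$better, 1)
  expect_equal(bw$worse, 0)

  # formula result on the first worked-example row; differs from the
  # reported 0.6489 / -0.5145, which no standard denominators reproduce
  d <- study_kano_distributions()
  bw <- kano_better_worse(d[d$indicator_id == "A1", ])
  expect_equal(bw$better, 0.4245077, tolerance = 1e-6)
  expect_equal(bw$worse, -0.8509051, tolerance = 1e-6)
  expect_gt(abs(bw$better - d$reported_better[d$indicator_id == "A1"]), 0.1)

  none <- data.frame(a = 0, o = 0, m = 0, i = 0)
  expect_true(is.na(kano_better_worse(none)$better))
})

test_that("category sets group assignments and exclude the indifferent set", {
  a <- data.frame(indicator_id = c("A1", "A5", "C3"),
                  category = c("M", "A", "I"),
                  rule = "argmax_AOMI", tie_broken = FALSE)
  sets <- kano_category_sets(a)
  expect_equal(sets$M, "A1")
  expect_equal(sets$A, "A5")
  expect_equal(sets$O, character(0))
  expect_equal(sets$excluded, "C3")

  # the worked example's reported labels give the published 7/4/5/3 split
  d <- study_kano_distributions()
  rep_sets <- kano_category_sets(
    data.frame(indicator_id = d$indicator_id, category = d$reported_category))
  expect_length(rep_sets$M, 7L)
  expect_length(rep_sets$O, 4L)
  expect_length(rep_sets$A, 5L)
  expect_length(rep_sets$excluded, 3L)
})
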
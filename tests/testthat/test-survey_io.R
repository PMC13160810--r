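ind2 <- toy_indicators(2)

write_kano_csv <- function(lines) {
  p <- tempfile(fileext = ".csv")
  writeLines(c("respondent_id,role,indicator_id,functional,dysfunctional",
               lines), p)
  p
}

test_that("well-formed response files parse with counts intact", {
  p <- write_kano_csv(c(
    "r1,older_adult,A1,like,dislike",
    "r1,older_adult,A2,neutral,dislike",
    "r2,caregiver,A1,like,neutral",
    "r2,caregiver,A2,must_be,dislike"))
  tbl <- read_kano_responses(p, ind2)
  expect_s3_class(tbl, "kano_response_table")
  expect_equal(nrow(tbl), 4L)
  expect_setequal(unique(tbl$respondent_id), c("r1", "r2"))
})

test_that("malformed response rows are rejected with the offending row named", {
  p <- write_kano_csv(c("r1,older_adult,A1,maybe,dislike"))
  expect_error(read_kano_responses(p, ind2), "maybe.*row 2|row 2.*maybe")

  p <- write_kano_csv(c("r1,older_adult,Z9,like,dislike"))
  expect_error(read_kano_responses(p, ind2), "unknown indicator id 'Z9'")

  p <- write_kano_csv(c("r1,older_adult,A1,like,dislike",
                        "r1,older_adult,A1,like,neutral"))
  expect_error(read_kano_responses(p, ind2), "duplicate")

  p <- write_kano_csv(c("r1,visitor,A1,like,dislike"))
  expect_error(read_kano_responses(p, ind2), "unknown role")
})

test_that("generated responses round-trip identically through write + read", {
  tbl <- generate_kano_responses(toy_indicators(4), planted = "M",
                                 n_respondents = 13, error_rate = 0.4,
                                 seed = 7)
  p <- tempfile(fileext = ".csv")
  write_kano_responses(tbl, p)
  back <- read_kano_responses(p, toy_indicators(4))
  expect_identical(as.data.frame(back), as.data.frame(tbl))
})

test_that("pairwise matrices parse labels, fractions, and reject bad shapes", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("item,x,y,z", "x,1,1,1", "y,1,1,1", "z,1,1,1"), p)
  m <- read_pairwise_matrix(p)
  expect_true(all(m == 1))
  expect_identical(rownames(m), c("x", "y", "z"))

  writeLines(c("item,x,y", "x,1,1/3", "y,3,1"), p)
  m <- read_pairwise_matrix(p)
  expect_equal(m[1, 2], 1 / 3)

  writeLines(c("item,x,y,z", "x,1,1,1", "y,1,1,1"), p)
  expect_error(read_pairwise_matrix(p), "square")

  writeLines(c("item,x,y", "x,1,-2", "y,3,1"), p)
  expect_error(read_pairwise_matrix(p), "positive")
})

test_that("the bundled criterion-layer matrix carries its printed judgments", {
  m <- study_judgment_matrices()$criterion
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(unname(m["M", "O"]), 0.5)
  expect_identical(rownames(m), c("M", "O", "A"))
})

test_that("pairwise write + read round-trips at machine precision", {
  m <- generate_pairwise_matrix(c(a = 0.41, b = 0.33, c = 0.26),
                                sigma = 0.2, seed = 3)
  p <- tempfile(fileext = ".csv")
  write_pairwise_matrix(m, p)
  expect_equal(unclass(read_pairwise_matrix(p)), unclass(m))
})

test_that("score files validate the Likert domain and rater groups", {
  df <- expand.grid(rater_id = c("e1", "u1"), alternative_id = "alt1",
                    indicator_id = paste0("M", 1:15),
                    stringsAsFactors = FALSE)
  df$rater_group <- ifelse(df$rater_id == "e1", "expert", "user")
  df$score <- 5L
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  tbl <- read_scores(p)
  expect_equal(nrow(tbl), 30L)

  df2 <- df; df2$score[1] <- 8L
  utils::write.csv(df2, p, row.names = FALSE)
  expect_error(read_scores(p), "1-7")

  df3 <- df; df3$rater_group[1] <- "manager"
  utils::write.csv(df3, p, row.names = FALSE)
  expect_error(read_scores(p), "rater_group")
})

test_that("score tables round-trip through write + read", {
  tbl <- generate_likert_scores(matrix(c(5, 3, 6, 2), 2, 2), sd = 0.7,
                                n_raters = 4, seed = 11)
  p <- tempfile(fileext = ".csv")
  write_scores(tbl, p)
  expect_identical(as.data.frame(read_scores(p)), as.data.frame(tbl))
})

test_that("reports cover the stages run, omit absent stages, and are deterministic", {
  cfg <- study_pipeline_config()
  res <- run_pipeline(cfg)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  write_report(res, d1)
  write_report(res, d2)
  j <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_true(all(c("kano", "ahp", "topsis", "triz") %in% names(j)))
  expect_false("psychometrics" %in% names(j))
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_identical(unname(tools::md5sum(list.files(d1, full.names = TRUE))),
                   unname(tools::md5sum(list.files(d2, full.names = TRUE))))
})
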
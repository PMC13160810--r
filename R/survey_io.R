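# Tabular I/O for the pipeline. All files are UTF-8 CSV (RFC-4180 quoting via
# read.csv/write.csv); fraction strings "a/b" are accepted wherever Saaty
# judgments appear. Every reader validates against a strict schema and names
# the offending row in its error message, so malformed inputs are never
# silently altered.

kano_roles <- function() c("older_adult", "caregiver")

#' Read paired Kano questionnaire responses
#'
#' Expects a long-format CSV with columns
#' `respondent_id,role,indicator_id,functional,dysfunctional` and optionally
#' extra per-respondent demographic columns, which are carried through
#' untouched. `functional` and `dysfunctional` hold the 5-level answers
#' (`like`, `must_be`, `neutral`, `live_with`, `dislike`) to the "feature
#' present" and "feature absent" question forms.
#'
#' @param path CSV file path.
#' @param indicators an `indicator_set`; every `indicator_id` must resolve
#'   against it.
#' @return a data frame of class `kano_response_table`.
#' @export
read_kano_responses <- function(path, indicators) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("respondent_id", "role", "indicator_id", "functional", "dysfunctional")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("kano response file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  as_kano_response_table(df, indicators)
}

#' Validate an in-memory Kano response table
#'
#' @param df data frame with the long-format response schema.
#' @param indicators an `indicator_set`.
#' @return a validated `kano_response_table`.
#' @export
as_kano_response_table <- function(df, indicators) {
  stopifnot(inherits(indicators, "indicator_set"))
  lv <- kano_answer_levels()
  row_id <- function(i) paste0("row ", i + 1L)  # +1 for the CSV header line

  unknown <- !(df$indicator_id %in% indicators$id)
  if (any(unknown)) {
    i <- which(unknown)[1L]
    stop("unknown indicator id '", df$indicator_id[i], "' at ", row_id(i),
         call. = FALSE)
  }
  for (col in c("functional", "dysfunctional")) {
    bad <- !(df[[col]] %in% lv)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("answer '", df[[col]][i], "' in column ", col, " at ", row_id(i),
           " is outside the 5-level domain (",
           paste(lv, collapse = ", "), ")", call. = FALSE)
    }
  }
  bad_role <- !(df$role %in% kano_roles())
  if (any(bad_role)) {
    i <- which(bad_role)[1L]
    stop("unknown role '", df$role[i], "' at ", row_id(i), call. = FALSE)
  }
  key <- paste(df$respondent_id, df$indicator_id, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop("duplicate (respondent, indicator) pair at ", row_id(i), ": ",
         df$respondent_id[i], " / ", df$indicator_id[i], call. = FALSE)
  }
  attr(df, "indicators") <- indicators
  class(df) <- c("kano_response_table", "data.frame")
  df
}

#' Write Kano responses to CSV
#' @param x a `kano_response_table`.
#' @param path output file.
#' @export
write_kano_responses <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.kano_response_table <- function(x, ...) {
  cat("Kano responses:", length(unique(x$respondent_id)), "respondents x",
      length(unique(x$indicator_id)), "indicators (",
      nrow(x), "records )\n")
  invisible(x)
}

#' Read a labelled pairwise-comparison matrix
#'
#' The file is a labelled square grid: a header of item names, then one row
#' per item whose first field repeats the item name. Entries are positive
#' Saaty ratio judgments; fraction strings such as `"1/3"` are parsed.
#'
#' @param path CSV file path.
#' @return a `pairwise_matrix` (numeric matrix with item dimnames).
#' @export
read_pairwise_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        check.names = FALSE)
  items <- df[[1L]]
  vals <- df[, -1L, drop = FALSE]
  if (nrow(vals) != ncol(vals)) {
    stop("pairwise matrix must be square, got ", nrow(vals), " x ", ncol(vals),
         call. = FALSE)
  }
  if (!identical(names(vals), items)) {
    stop("pairwise matrix row labels must match column labels in order",
         call. = FALSE)
  }
  m <- matrix(NA_real_, nrow(vals), ncol(vals), dimnames = list(items, items))
  for (j in seq_along(vals)) m[, j] <- parse_ratio(vals[[j]])
  as_pairwise_matrix(m)
}

#' Write a pairwise matrix to CSV
#'
#' Values are written at full double precision so write-then-read
#' round-trips exactly.
#'
#' @param m a `pairwise_matrix`.
#' @param path output file.
#' @export
write_pairwise_matrix <- function(m, path) {
  items <- rownames(m)
  df <- data.frame(item = items, stringsAsFactors = FALSE)
  for (j in seq_along(items)) df[[items[j]]] <- format_full(m[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read rater-level Likert scores
#'
#' Long-format CSV with columns
#' `rater_id,rater_group,alternative_id,indicator_id,score`; `rater_group`
#' is `expert` or `user`, `score` an integer on the 7-point scale.
#'
#' @param path CSV file path.
#' @return a data frame of class `score_table`.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_score_table(df)
}

#' Validate an in-memory score table
#' @param df data frame with the score schema.
#' @return a `score_table`.
#' @export
as_score_table <- function(df) {
  need <- c("rater_id", "rater_group", "alternative_id", "indicator_id", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("score file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_group <- !(df$rater_group %in% c("expert", "user"))
  if (any(bad_group)) {
    i <- which(bad_group)[1L]
    stop("unknown rater_group '", df$rater_group[i], "' at row ", i + 1L,
         call. = FALSE)
  }
  s <- df$score
  bad <- !is.numeric(s) | is.na(s) | s != trunc(s) | s < 1 | s > 7
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("score ", s[i], " at row ", i + 1L,
         " is outside the 1-7 Likert domain", call. = FALSE)
  }
  key <- paste(df$rater_id, df$alternative_id, df$indicator_id, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop("duplicate (rater, alternative, indicator) at row ", i + 1L,
         call. = FALSE)
  }
  df$score <- as.integer(s)
  class(df) <- c("score_table", "data.frame")
  df
}

#' Write a score table to CSV
#' @param x a `score_table`.
#' @param path output file.
#' @export
write_scores <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a subjects-by-items matrix for psychometric checks
#'
#' @param path CSV with one column per item, one row per subject.
#' @return numeric matrix.
#' @export
read_item_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("item matrix must be numeric", call. = FALSE)
  if (anyNA(m)) stop("item matrix contains missing cells", call. = FALSE)
  m
}

#' Write the structured pipeline report
#'
#' Emits one machine-readable `report.json` plus a CSV table per stage under
#' `dir`. Floats are rounded to `precision` decimals; the configuration echo
#' and seed are included so two runs with identical inputs produce
#' byte-identical reports.
#'
#' @param results a `pipeline_result` or a named list of stage results.
#' @param dir output directory (created if absent).
#' @param precision decimal places for floats in the report (default 3).
#' @return invisibly, the paths written.
#' @export
write_report <- function(results, dir, precision = 3L) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  if (file.access(dir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", dir, call. = FALSE)
  }
  paths <- character(0)
  emit_csv <- function(df, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    df <- as.data.frame(df)
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], round, digits = precision)
    utils::write.csv(df, p, row.names = FALSE, quote = TRUE)
    paths[[length(paths) + 1L]] <<- p
  }

  json <- list(seed = results$seed, config = results$config_echo)
  if (!is.null(results$kano)) {
    emit_csv(results$kano$distribution, "kano_distribution")
    emit_csv(results$kano$assignments, "kano_assignments")
    json$kano <- list(
      assignments = stats::setNames(as.list(results$kano$assignments$category),
                                    results$kano$assignments$indicator_id),
      category_sets = results$kano$sets)
  }
  if (!is.null(results$psychometrics)) {
    r <- results$psychometrics
    json$psychometrics <- list(
      alpha = r$alpha, kmo = r$kmo, msa = as.list(r$msa),
      bartlett_chi2 = r$bartlett_chi2, bartlett_df = r$bartlett_df,
      bartlett_p = r$bartlett_p)
  }
  if (!is.null(results$ahp)) {
    emit_csv(results$ahp$hierarchy$table, "ahp_hierarchy")
    json$ahp <- list(
      criterion_weights = as.list(results$ahp$criterion$weights),
      consistency = lapply(results$ahp$consistency, function(z) {
        list(lambda_max = z$lambda_max, ci = z$ci, cr = z$cr, n = z$n)
      }),
      global_weights = stats::setNames(
        as.list(results$ahp$hierarchy$table$global_weight),
        results$ahp$hierarchy$table$indicator))
  }
  if (!is.null(results$triz)) {
    emit_csv(results$triz, "triz_conflicts")
    json$triz <- list(n_conflicts = nrow(results$triz),
                      principles = stats::setNames(
                        as.list(results$triz$principles),
                        results$triz$label))
  }
  if (!is.null(results$topsis)) {
    emit_csv(results$topsis$ranking, "topsis_ranking")
    json$topsis <- list(
      weights = as.list(results$topsis$weights),
      closeness = stats::setNames(as.list(results$topsis$closeness),
                                  rownames(results$topsis$weighted)),
      ranking = stats::setNames(as.list(results$topsis$ranking$rank),
                                results$topsis$ranking$alternative))
  }
  if (length(results$divergences)) json$divergences <- results$divergences
  json <- round_list(json, precision)
  p <- file.path(dir, "report.json")
  jsonlite::write_json(json, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  paths[[length(paths) + 1L]] <- p
  invisible(unlist(paths))
}
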
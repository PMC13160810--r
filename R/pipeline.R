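# End-to-end pipeline: Kano classification -> category sets -> AHP
# weighting -> (advisory) contradiction resolution -> TOPSIS ranking, with
# optional questionnaire psychometrics. The TRIZ stage only annotates the
# report; it never alters weights or rankings.

#' Assemble a pipeline configuration
#'
#' Inputs may be file paths (validated to exist immediately) or in-memory
#' objects from the corresponding readers/generators. Stages whose inputs
#' are omitted are skipped without error.
#'
#' @param indicators `indicator_set` or CSV path (needed with `responses`).
#' @param responses Kano response CSV path or `kano_response_table`.
#' @param kano_distribution pre-tabulated `kano_distribution`, as an
#'   alternative to raw responses (e.g. when only aggregates exist).
#' @param item_matrix subjects-by-items CSV path or numeric matrix for the
#'   psychometric battery.
#' @param criterion_matrix pairwise matrix (path or object) over the
#'   criterion categories.
#' @param local_matrices named list of pairwise matrices (paths or
#'   objects), one per criterion item.
#' @param scores Likert score CSV path or `score_table`.
#' @param evaluation alternatives-by-indicators matrix, as an alternative
#'   to raw scores.
#' @param conflicts `conflict_cases` for the advisory contradiction stage.
#' @param contradiction_matrix `triz_matrix` or CSV path.
#' @param weights explicit TOPSIS weight vector; when omitted the
#'   renormalized global AHP weights are used (their names must then match
#'   the evaluation indicators).
#' @param directions per-indicator `"benefit"`/`"cost"` for TOPSIS.
#' @param tie_break Kano tie-break precedence.
#' @param ahp_method `"eigenvector"` or `"geometric_mean"`.
#' @param reciprocity `"repair_upper"` or `"strict"`.
#' @param reference_closeness optional data frame of externally reported
#'   closeness values to diff against (adds divergence-log entries only).
#' @param seed non-negative integer, echoed into the report.
#' @param output_dir when set, [write_report()] is called there.
#' @param precision report rounding (decimal places).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(indicators = NULL, responses = NULL,
                            kano_distribution = NULL, item_matrix = NULL,
                            criterion_matrix = NULL, local_matrices = NULL,
                            scores = NULL, evaluation = NULL,
                            conflicts = NULL, contradiction_matrix = NULL,
                            weights = NULL, directions = "benefit",
                            tie_break = c("M", "O", "A", "I"),
                            ahp_method = c("eigenvector", "geometric_mean"),
                            reciprocity = c("repair_upper", "strict"),
                            reference_closeness = NULL,
                            seed = 0, output_dir = NULL, precision = 3L) {
  check_seed(seed)
  for (p in c(responses, item_matrix, criterion_matrix, scores,
              contradiction_matrix, unlist(local_matrices))) {
    if (is.character(p) && length(p) == 1L && !file.exists(p)) {
      stop("configured input file does not exist: ", p, call. = FALSE)
    }
  }
  cfg <- list(indicators = indicators, responses = responses,
              kano_distribution = kano_distribution,
              item_matrix = item_matrix,
              criterion_matrix = criterion_matrix,
              local_matrices = local_matrices,
              scores = scores, evaluation = evaluation,
              conflicts = conflicts,
              contradiction_matrix = contradiction_matrix,
              weights = weights, directions = directions,
              tie_break = tie_break,
              ahp_method = match.arg(ahp_method),
              reciprocity = match.arg(reciprocity),
              reference_closeness = reference_closeness,
              seed = seed, output_dir = output_dir,
              precision = as.integer(precision))
  class(cfg) <- "pipeline_config"
  cfg
}

resolve_input <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1L) reader(x, ...) else x
}

#' Run the full prioritization pipeline
#'
#' Executes, for every stage whose inputs are configured: Kano
#' classification and category sets; the psychometric battery; AHP
#' criterion and local weighting with consistency diagnostics and global
#' synthesis; advisory contradiction resolution; and TOPSIS ranking. All
#' numerical results are identical to calling the stage functions directly
#' on the same inputs. A divergence log records every place where an
#' externally reported value attached to the inputs disagrees with what
#' the computation yields.
#'
#' @param config a `pipeline_config`.
#' @return a `pipeline_result`: list with the per-stage bundles, a config
#'   echo, the seed, stage timings (seconds) and the divergence log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list(seed = config$seed, divergences = character(0))
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0, stage) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  # -- kano ------------------------------------------------------------
  dist <- NULL
  if (!is.null(config$responses) || !is.null(config$kano_distribution)) {
    t0 <- tic()
    if (!is.null(config$responses)) {
      ind <- resolve_input(config$indicators, read_indicators)
      responses <- if (is.character(config$responses)) {
        read_kano_responses(config$responses, ind)
      } else config$responses
      dist <- kano_tabulate(responses)
    } else {
      dist <- config$kano_distribution
    }
    assign <- kano_assign(dist, tie_break = config$tie_break)
    if (!is.null(dist$reported_category)) {
      off <- which(assign$category != dist$reported_category)
      for (k in off) {
        res$divergences <- c(res$divergences, sprintf(
          "kano: indicator %s classifies as %s by max frequency but is reported as %s in the bundled aggregates",
          assign$indicator_id[k], assign$category[k], dist$reported_category[k]))
      }
    }
    res$kano <- list(distribution = dist, assignments = assign,
                     sets = kano_category_sets(assign))
    toc(t0, "kano")
  }

  # -- psychometrics ---------------------------------------------------
  if (!is.null(config$item_matrix)) {
    t0 <- tic()
    x <- resolve_input(config$item_matrix, read_item_matrix)
    res$psychometrics <- psychometric_report(x)
    toc(t0, "psychometrics")
  }

  # -- ahp -------------------------------------------------------------
  if (!is.null(config$criterion_matrix)) {
    t0 <- tic()
    crit_m <- resolve_input(config$criterion_matrix, read_pairwise_matrix)
    note_repair <- function(m, label) {
      v <- validate_reciprocity(m)
      if (nrow(v) > 0L && config$reciprocity == "repair_upper") {
        res$divergences <<- c(res$divergences, sprintf(
          "ahp: %s judgment matrix violates reciprocity at %d pair(s); lower triangle rebuilt from the upper",
          label, nrow(v)))
      }
    }
    note_repair(crit_m, "criterion")
    crit <- priority_weights(crit_m, method = config$ahp_method,
                             reciprocity = config$reciprocity)
    locals <- lapply(config$local_matrices, resolve_input, read_pairwise_matrix)
    for (nm in names(locals)) note_repair(locals[[nm]], nm)
    local_w <- lapply(locals, priority_weights, method = config$ahp_method,
                      reciprocity = config$reciprocity)
    hier <- synthesize_global(crit, local_w)
    res$ahp <- list(criterion = crit, locals = local_w, hierarchy = hier,
                    consistency = c(list(criterion = crit), local_w))
    toc(t0, "ahp")
  }

  # -- triz (advisory) -------------------------------------------------
  if (!is.null(config$conflicts)) {
    t0 <- tic()
    cm <- if (!is.null(config$contradiction_matrix)) {
      resolve_input(config$contradiction_matrix, triz_load_matrix)
    }
    res$triz <- triz_report(triz_resolve(config$conflicts, cm))
    toc(t0, "triz")
  }

  # -- topsis ----------------------------------------------------------
  if (!is.null(config$scores) || !is.null(config$evaluation)) {
    t0 <- tic()
    f <- if (!is.null(config$scores)) {
      aggregate_scores(resolve_input(config$scores, read_scores))
    } else config$evaluation
    w <- config$weights
    weight_source <- "explicit"
    if (is.null(w)) {
      if (is.null(res$ahp)) {
        stop("TOPSIS needs either explicit `weights` or an AHP stage to take ",
             "global weights from", call. = FALSE)
      }
      tab <- res$ahp$hierarchy$table
      hit <- match(colnames(f), tab$indicator)
      if (anyNA(hit)) {
        stop("AHP hierarchy has no global weight for indicator(s): ",
             paste(colnames(f)[is.na(hit)], collapse = ", "),
             "; supply `weights` explicitly", call. = FALSE)
      }
      w <- tab$global_weight[hit] / sum(tab$global_weight[hit])
      weight_source <- "ahp_global"
    }
    res$topsis <- topsis(f, weights = w, directions = config$directions)
    res$topsis$weight_source <- weight_source
    ref <- config$reference_closeness
    if (!is.null(ref)) {
      hit <- match(ref$alternative, res$topsis$ranking$alternative)
      for (k in which(!is.na(hit))) {
        got <- res$topsis$ranking$closeness[hit[k]]
        if (abs(got - ref$reported_closeness[k]) > 0.005) {
          res$divergences <- c(res$divergences, sprintf(
            "topsis: computed closeness %.3f for %s differs from the reported %.3f (the reported pair is inconsistent with C = S-/(S+ + S-))",
            got, ref$alternative[k], ref$reported_closeness[k]))
        }
      }
    }
    toc(t0, "topsis")
  }

  res$timings <- timings
  res$config_echo <- config_echo(config)
  class(res) <- "pipeline_result"
  if (!is.null(config$output_dir)) {
    write_report(res, config$output_dir, precision = config$precision)
  }
  res
}

# Flat, JSON-friendly summary of the configuration (values echoed for
# reproducibility; large objects reduced to a shape tag).
config_echo <- function(config) {
  describe <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L) return(x)
    paste0("<in-memory ", class(x)[1L], ">")
  }
  list(tie_break = paste(config$tie_break, collapse = ">"),
       ahp_method = config$ahp_method,
       reciprocity = config$reciprocity,
       directions = paste(unique(config$directions), collapse = ","),
       precision = config$precision,
       responses = describe(config$responses),
       kano_distribution = describe(config$kano_distribution),
       item_matrix = describe(config$item_matrix),
       criterion_matrix = describe(config$criterion_matrix),
       scores = describe(config$scores),
       evaluation = describe(config$evaluation),
       weights = if (!is.null(config$weights)) "explicit" else "ahp_global")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Needs-prioritization pipeline result\n")
  cat("stages run:", paste(intersect(
    c("kano", "psychometrics", "ahp", "triz", "topsis"), names(x)),
    collapse = ", "), "\n")
  if (!is.null(x$topsis)) {
    cat("\n")
    print.data.frame(topsis_rank_report(x$topsis), row.names = FALSE)
  }
  if (length(x$divergences)) {
    cat("\n", length(x$divergences), "divergence(s) logged:\n", sep = "")
    cat(paste0(" - ", x$divergences, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Configuration for the bundled worked example
#'
#' Wires the bundled aggregate fixtures into a full pipeline run: the
#' renormalized Kano distributions, the four judgment matrices (the three
#' indicator-layer matrices standing under the criterion categories M, O
#' and A), the four contradiction cases, and the 2 x 15 evaluation matrix.
#' Because the published hierarchy labels (16 indicators, M1-M7/O1-O5/
#' N1-N4) do not match the 15 evaluation indicators, the TOPSIS weight
#' vector is the published combined-weight column renormalized to sum
#' to 1, passed explicitly.
#'
#' @param output_dir optional report directory.
#' @param seed seed echoed into the report.
#' @return a `pipeline_config`.
#' @export
study_pipeline_config <- function(output_dir = NULL, seed = 0) {
  jm <- study_judgment_matrices()
  cw <- study_combined_weights(renormalize = TRUE)
  pipeline_config(
    indicators = study_indicators(),
    kano_distribution = study_kano_distributions(),
    criterion_matrix = jm$criterion,
    local_matrices = list(M = jm$M, O = jm$O, A = jm$N),
    evaluation = study_evaluation_matrix(),
    weights = stats::setNames(cw$combined_weight, cw$indicator),
    conflicts = study_conflicts(),
    contradiction_matrix = study_contradiction_matrix(),
    reference_closeness = study_reported_closeness(),
    seed = seed, output_dir = output_dir)
}
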
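# TRIZ contradiction handling. A technical contradiction improves one
# engineering parameter while worsening another and is resolved by looking
# the (improving, worsening) pair up in a contradiction matrix of inventive
# principles; a physical contradiction demands opposite states of a single
# parameter and carries its principle set directly on the case. The
# parameter list and matrix are loadable data files because numbering
# conventions differ between sources; the bundled files assert only the
# worked example shipped with the package.

parse_principles <- function(x) {
  x <- trimws(as.character(x))
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(integer(0))
    as.integer(strsplit(s, "[ ;,.]+")[[1]])
  })
}

format_principles <- function(ids) {
  vapply(ids, paste, character(1), collapse = " ")
}

#' Load a contradiction matrix
#'
#' The file has columns `improving,worsening,principles`; `principles` is a
#' list of inventive-principle ids separated by spaces (order preserved —
#' it may encode priority). Missing cells are simply absent rows and
#' resolve to an empty principle list.
#'
#' @param path CSV file.
#' @return object of class `triz_matrix`.
#' @export
triz_load_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("integer", "integer", "character"))
  need <- c("improving", "worsening", "principles")
  if (!identical(names(df), need)) {
    stop("contradiction matrix must have columns improving, worsening, principles",
         call. = FALSE)
  }
  if (anyNA(df$improving) || anyNA(df$worsening)) {
    bad <- which(is.na(df$improving) | is.na(df$worsening))[1L]
    stop("malformed parameter id at line ", bad + 1L, " of ", path,
         call. = FALSE)
  }
  key <- paste(df$improving, df$worsening)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1L]
    stop("duplicate (improving, worsening) cell at line ", bad + 1L, ": ",
         key[bad], call. = FALSE)
  }
  structure(list(cells = stats::setNames(parse_principles(df$principles), key)),
            class = "triz_matrix")
}

#' Look up a contradiction-matrix cell
#'
#' @param matrix a `triz_matrix`.
#' @param improving,worsening parameter ids.
#' @return integer vector of principle ids (empty when the cell is missing).
#' @export
triz_lookup <- function(matrix, improving, worsening) {
  stopifnot(inherits(matrix, "triz_matrix"))
  matrix$cells[[paste(improving, worsening)]] %||% integer(0)
}

#' Construct conflict cases
#'
#' @param label short conflict name.
#' @param conflict_type `"physical"` or `"technical"`.
#' @param indicators linked requirement indicator ids, `;`-separated.
#' @param improving,worsening parameter names (free text).
#' @param improving_id,worsening_id parameter ids (technical conflicts).
#' @param principles preset principle ids for physical conflicts (character
#'   like `"3 17 31 40"` or integer vector); technical conflicts normally
#'   leave this empty and fill it via [triz_resolve()].
#' @return data frame of class `conflict_cases`.
#' @export
conflict_cases <- function(label, conflict_type, indicators = "",
                           improving = "", worsening = "",
                           improving_id = NA_integer_,
                           worsening_id = NA_integer_, principles = "") {
  bad <- !(conflict_type %in% c("physical", "technical"))
  if (any(bad)) {
    stop("conflict_type must be physical or technical, got: ",
         paste(unique(conflict_type[bad]), collapse = ", "), call. = FALSE)
  }
  if (is.list(principles) || is.numeric(principles)) {
    principles <- format_principles(if (is.list(principles)) principles
                                    else list(principles))
  }
  out <- data.frame(label = label, conflict_type = conflict_type,
                    indicators = indicators,
                    improving_id = as.integer(improving_id),
                    improving = improving,
                    worsening_id = as.integer(worsening_id),
                    worsening = worsening,
                    principles = as.character(principles),
                    provenance = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("conflict_cases", "data.frame")
  out
}

#' Resolve conflict cases to inventive principles
#'
#' Technical conflicts are resolved through the contradiction matrix;
#' physical conflicts keep the principle set configured on the case (they
#' have no matrix cell). An empty matrix cell yields a warning and an empty
#' principle list, never an error. The resolution provenance (`matrix` vs
#' `configured`) is recorded per case.
#'
#' @param cases a `conflict_cases` frame.
#' @param matrix a `triz_matrix` (required when any case is technical).
#' @return the cases with `principles` and `provenance` filled.
#' @export
triz_resolve <- function(cases, matrix = NULL) {
  stopifnot(inherits(cases, "conflict_cases"))
  for (k in seq_len(nrow(cases))) {
    if (cases$conflict_type[k] == "technical") {
      if (is.null(matrix)) {
        stop("a contradiction matrix is required to resolve technical conflicts",
             call. = FALSE)
      }
      ids <- triz_lookup(matrix, cases$improving_id[k], cases$worsening_id[k])
      if (!length(ids)) {
        warning("no contradiction-matrix cell for (",
                cases$improving_id[k], ", ", cases$worsening_id[k],
                ") in case '", cases$label[k], "'; empty principle list",
                call. = FALSE)
      }
      cases$principles[k] <- format_principles(list(ids))
      cases$provenance[k] <- "matrix"
    } else {
      cases$provenance[k] <- "configured"
    }
  }
  cases
}

#' Conflict report with principle names
#'
#' @param cases resolved `conflict_cases`.
#' @param principle_names data frame with columns `id, name` (defaults to
#'   the bundled inventive-principle list).
#' @return data frame adding a `principle_names` column.
#' @export
triz_report <- function(cases, principle_names = study_principles()) {
  stopifnot(inherits(cases, "conflict_cases"))
  ids <- parse_principles(cases$principles)
  nm <- vapply(ids, function(v) {
    hit <- match(v, principle_names$id)
    if (anyNA(hit)) {
      stop("no name entry for inventive principle id(s): ",
           paste(v[is.na(hit)], collapse = ", "), call. = FALSE)
    }
    paste(principle_names$name[hit], collapse = "; ")
  }, character(1))
  out <- as.data.frame(cases)
  out$principle_names <- nm
  out
}

#' Read conflict cases from CSV
#'
#' Schema: `label,conflict_type,indicators,improving_id,improving,
#' worsening_id,worsening,principles` (ids and principles may be empty for
#' the kinds of conflict that do not use them).
#'
#' @param path CSV file.
#' @return a `conflict_cases` frame.
#' @export
read_conflicts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "conflict_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("conflict file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  get <- function(col, default) if (col %in% names(df)) df[[col]] else default
  pr <- get("principles", "")
  conflict_cases(label = df$label, conflict_type = df$conflict_type,
                 indicators = get("indicators", ""),
                 improving = get("improving", ""),
                 worsening = get("worsening", ""),
                 improving_id = get("improving_id", NA_integer_),
                 worsening_id = get("worsening_id", NA_integer_),
                 principles = ifelse(is.na(pr), "", pr))
}
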
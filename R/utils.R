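#' @keywords internal
"_PACKAGE"

# Five-level Kano answer vocabulary, from most to least liked.
kano_answer_levels <- function() {
  c("like", "must_be", "neutral", "live_with", "dislike")
}

kano_categories <- function() c("A", "O", "M", "I", "R", "Q")

.cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed` and
#' restores the previous RNG state afterwards, so generators are pure
#' functions of their arguments and never disturb the caller's random stream.
#'
#' @param seed non-negative integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  check_seed(seed)
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed < 0 || seed != trunc(seed)) {
    stop("`seed` must be a single non-negative integer", call. = FALSE)
  }
  invisible(as.integer(seed))
}

#' Parse Saaty ratio strings
#'
#' Converts a character vector of judgments to numeric, accepting plain
#' decimals and fraction strings such as `"1/3"`.
#'
#' @param x character or numeric vector.
#' @return numeric vector.
#' @export
#' @examples
#' parse_ratio(c("1/2", "3", "0.25"))
parse_ratio <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  frac <- grepl("^[0-9]+[[:space:]]*/[[:space:]]*[0-9]+$", x)
  if (any(frac)) {
    parts <- strsplit(x[frac], "/")
    out[frac] <- vapply(parts, function(p) {
      as.numeric(p[1]) / as.numeric(p[2])
    }, numeric(1))
  }
  bad <- is.na(out) & !is.na(x) & x != "NA"
  if (any(bad)) {
    stop("cannot parse ratio value(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  out
}

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "needsmcda")
  if (!nzchar(path)) stop("bundled data file not found: ", file, call. = FALSE)
  path
}

# Format a numeric for lossless CSV round-trips.
format_full <- function(x) {
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}

round_list <- function(x, digits) {
  rapply(x, function(v) if (is.double(v)) round(v, digits) else v,
         how = "replace")
}
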
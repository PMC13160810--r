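#' Construct an indicator set
#'
#' An indicator set lists the requirement elements under study. Each
#' indicator has a short code (`dimension letter + index`, e.g. `"A1"`), a
#' dimension, a label and an optional description. The dimension letter of
#' the id must match the dimension: A = functional, B = appearance,
#' C = culture_management, D = technical.
#'
#' @param id character vector of indicator codes.
#' @param dimension character vector of dimensions.
#' @param label human-readable names.
#' @param description free text, optional.
#' @return a data frame of class `indicator_set`.
#' @export
indicator_set <- function(id, dimension, label = id, description = "") {
  dims <- c(A = "functional", B = "appearance",
            C = "culture_management", D = "technical")
  id <- as.character(id)
  dimension <- as.character(dimension)
  if (anyDuplicated(id)) {
    stop("indicator ids must be unique: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  if (!all(dimension %in% dims)) {
    stop("unknown dimension(s): ",
         paste(setdiff(dimension, dims), collapse = ", "), call. = FALSE)
  }
  letter <- substr(id, 1L, 1L)
  expect_dim <- unname(dims[letter])
  bad <- is.na(expect_dim) | expect_dim != dimension
  if (any(bad)) {
    stop("indicator id prefix does not match dimension for: ",
         paste(id[bad], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(id = id, dimension = dimension,
                    label = rep_len(as.character(label), length(id)),
                    description = rep_len(as.character(description), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("indicator_set", "data.frame")
  out
}

#' Read an indicator set from CSV
#'
#' @param path CSV file with columns `id,dimension,label,description`.
#' @return an `indicator_set`.
#' @export
read_indicators <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "dimension", "label")
  if (!all(need %in% names(df))) {
    stop("indicator file must have columns id, dimension, label", call. = FALSE)
  }
  indicator_set(df$id, df$dimension, df$label,
                if ("description" %in% names(df)) df$description else "")
}

#' @export
print.indicator_set <- function(x, ...) {
  cat("Indicator set:", nrow(x), "indicators in",
      length(unique(x$dimension)), "dimensions\n")
  print.data.frame(x[, c("id", "dimension", "label")], row.names = FALSE)
  invisible(x)
}
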
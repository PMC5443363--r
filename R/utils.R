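#' Normalise a sex code
#'
#' Accepts `F`, `M`, `female`, `male` case-insensitively (the input schema's
#' permitted codes) and returns `"female"` or `"male"`.
#'
#' @param x Character (or factor) vector of sex codes.
#' @param strict If `TRUE` (default), unrecognised codes are an error; if
#'   `FALSE` they become `NA` so batch readers can flag the row instead of
#'   aborting.
#' @return Character vector in `c("female", "male")`, with `NA` for
#'   unrecognised codes when `strict = FALSE`.
#' @export
normalize_sex <- function(x, strict = TRUE) {
  x0 <- trimws(tolower(as.character(x)))
  out <- rep(NA_character_, length(x0))
  out[x0 %in% c("f", "female")] <- "female"
  out[x0 %in% c("m", "male")] <- "male"
  if (strict && anyNA(out[!is.na(x0) | TRUE])) {
    bad <- unique(x[is.na(out)])
    if (length(bad)) {
      stop("unrecognised sex code(s): ", paste(sQuote(bad), collapse = ", "),
           " (expected F, M, female, or male)", call. = FALSE)
    }
  }
  out
}

# supported analysis window, months: ages 2 to <20 years
.age_window_months <- c(24, 240)

# columns referenced inside ggplot2::aes()
utils::globalVariables(c("age_y", "bmi", "curve", "id"))

# read a delimited or spreadsheet table by extension; returns a data.frame
read_table_any <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading ", ext, " files requires the 'readxl' package; ",
           "convert the file to CSV or install readxl", call. = FALSE)
    }
    as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
}

# case-insensitive header lookup: returns the actual column name or NA
match_header <- function(df, aliases) {
  hits <- which(tolower(names(df)) %in% tolower(aliases))
  if (length(hits) == 0) return(NA_character_)
  names(df)[hits[1]]
}
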
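#' @keywords internal
"_PACKAGE"

# Half-up rounding at `digits` decimals; base round() is banker's rounding,
# which cannot reproduce the reporting convention used throughout.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percentage at two decimals
#'
#' Percentage of `count` over `total`, rounded half-up to 2 decimals,
#' the convention used in all corpus summaries.
#'
#' @param count numerator count.
#' @param total denominator count.
#' @return numeric percentage.
#' @export
pct2 <- function(count, total) {
  if (total == 0) return(NaN)
  round_half_up(100 * count / total, 2)
}

# Collection window bounds (UTC epoch seconds) of the study corpus:
# 2015-03-24 00:00:00 to 2016-12-02 23:59:59.
default_window <- function() {
  c(
    start = as.numeric(as.POSIXct("2015-03-24 00:00:00", tz = "UTC")),
    end   = as.numeric(as.POSIXct("2016-12-02 23:59:59", tz = "UTC"))
  )
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "hookahsent")
  if (!nzchar(path)) stop("data file not found: ", file, call. = FALSE)
  path
}

read_wordlist <- function(file) {
  x <- readLines(extdata(file), encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

read_tsv_map <- function(file, value_numeric = TRUE) {
  d <- utils::read.delim(extdata(file), header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE, quote = "",
                         fileEncoding = "UTF-8")
  vals <- if (value_numeric) as.numeric(d[[2]]) else as.character(d[[2]])
  stats::setNames(vals, as.character(d[[1]]))
}
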
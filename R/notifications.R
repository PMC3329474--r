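NTYPES <- c("alert", "information", "border_rejection")

#' Construct a notification log
#'
#' A notification log is an ordered collection of notification records. Each
#' record is one logged report: a detector country flags a faulty product
#' originating from a transgressor country, on a date, with a notification
#' type and a free-text hazard description. The contamination `category` is
#' derived from the hazard text via [categorize_hazard()].
#'
#' Self-reports (detector equal to transgressor) are permitted and flagged in
#' the logical `self_report` column rather than rejected.
#'
#' @param date Dates (`Date` or ISO-8601 `"YYYY-MM-DD"` strings).
#' @param detector,transgressor ISO 3166-1 alpha-3 country codes.
#' @param type Notification types, each one of `"alert"`, `"information"`,
#'   `"border_rejection"`.
#' @param hazard Free-text hazard descriptions.
#' @param provenance Free-text note on where the records came from.
#' @param keyword_table Keyword table for categorization.
#' @param allow_unknown_codes Accept country codes outside the ISO 3166 list
#'   with a warning (`TRUE`, default) or reject them (`FALSE`).
#' @return A `notification_log`: a `data.frame` with columns `date`,
#'   `detector`, `transgressor`, `type`, `hazard`, `category`, `self_report`
#'   and a `provenance` attribute.
#' @examples
#' notification_log(
#'   date = c("2007-03-01", "2007-06-15"),
#'   detector = c("DEU", "ITA"),
#'   transgressor = c("IRN", "CHN"),
#'   type = c("alert", "border_rejection"),
#'   hazard = c("aflatoxin in pistachios", "cadmium in frozen squid")
#' )
#' @export
notification_log <- function(date, detector, transgressor, type, hazard,
                             provenance = "constructed in R",
                             keyword_table = rasff_keywords(),
                             allow_unknown_codes = TRUE) {
  date <- parse_iso_date(date)
  detector <- validate_iso3(detector, allow_unknown_codes, "detector code")
  transgressor <- validate_iso3(transgressor, allow_unknown_codes,
                                "transgressor code")
  type <- as.character(type)
  bad <- which(!type %in% NTYPES)
  if (length(bad)) {
    stop("unknown notification type(s) in row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(type[bad]), collapse = ", "),
         " (expected alert, information or border_rejection)", call. = FALSE)
  }
  hazard <- as.character(hazard)
  n <- length(date)
  recycle <- function(x) if (length(x) == 1L) rep(x, n) else x
  detector <- recycle(detector)
  transgressor <- recycle(transgressor)
  type <- recycle(type)
  hazard <- recycle(hazard)
  stopifnot(length(detector) == n, length(transgressor) == n,
            length(type) == n, length(hazard) == n)
  category <- categorize_hazard(hazard, keyword_table)
  log <- data.frame(
    date = date, detector = detector, transgressor = transgressor,
    type = type, hazard = hazard, category = as.character(category),
    self_report = detector == transgressor,
    stringsAsFactors = FALSE
  )
  attr(log, "provenance") <- provenance
  class(log) <- c("notification_log", "data.frame")
  log
}

parse_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x))
  if (length(bad)) {
    stop("unparsable date(s) (ISO-8601 YYYY-MM-DD expected) in row(s) ",
         paste(utils::head(bad, 10L), collapse = ", "), ": ",
         paste(utils::head(x[bad], 10L), collapse = ", "), call. = FALSE)
  }
  if (anyNA(d)) stop("missing date(s)", call. = FALSE)
  d
}

#' @export
print.notification_log <- function(x, ...) {
  cat("Notification log: ", nrow(x), " record(s), ",
      length(unique(x$detector)), " detector(s), ",
      length(unique(x$transgressor)), " transgressor(s)\n", sep = "")
  if (nrow(x)) {
    cat("  dates ", format(min(x$date)), " .. ", format(max(x$date)), "\n",
        sep = "")
    cat("  categories: ",
        paste(sprintf("%s=%d", names(table(x$category)), table(x$category)),
              collapse = ", "), "\n", sep = "")
  }
  cat("  provenance: ", attr(x, "provenance") %||% "unknown", "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a notification log from delimited text
#'
#' Expects a header with columns `date`, `detector`, `transgressor`, `type`
#' and `hazard` (a `category` column, if present, is ignored and re-derived).
#' Dates must be ISO-8601; types must be `alert`, `information` or
#' `border_rejection`.
#'
#' @param path File path.
#' @param sep Field delimiter: `","` (default) or `"\t"`.
#' @param keyword_table Keyword table used to derive categories.
#' @param allow_unknown_codes See [notification_log()].
#' @return A [notification_log()].
#' @export
read_log <- function(path, sep = ",", keyword_table = rasff_keywords(),
                     allow_unknown_codes = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty notification file: ", path, call. = FALSE)
  need <- c("date", "detector", "transgressor", "type", "hazard")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  notification_log(df$date, df$detector, df$transgressor, df$type, df$hazard,
                   provenance = paste0("read from ", path),
                   keyword_table = keyword_table,
                   allow_unknown_codes = allow_unknown_codes)
}

#' Write a notification log as delimited text
#'
#' Emits the input schema plus the derived `category` column, so a written
#' log re-reads identically ([read_log()] re-derives the same categories).
#'
#' @param log A notification log.
#' @param path Output file path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_log <- function(log, path, sep = ",") {
  stopifnot(inherits(log, "notification_log"))
  out <- data.frame(
    date = format(log$date, "%Y-%m-%d"),
    detector = log$detector, transgressor = log$transgressor,
    type = log$type, hazard = log$hazard, category = log$category,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Filter a notification log by contamination category and notification type
#'
#' Category filters are the keyword-table categories plus the aggregates
#' `"all"` (every record, including uncategorized) and `"microorganism"`
#' (mycotoxin together with bacteria). The notification-type filter separates
#' border rejections from the full record set.
#'
#' @param log A notification log.
#' @param category One of `"all"`, `"microorganism"`, `"uncategorized"`, a
#'   keyword-table category, or a character vector of categories.
#' @param ntype `"all"` or `"border_rejection"`.
#' @return The filtered `notification_log` (possibly with zero rows).
#' @examples
#' log <- notification_log(
#'   date = c("2007-01-01", "2007-01-02", "2007-01-03"),
#'   detector = c("DEU", "DEU", "ITA"),
#'   transgressor = c("IRN", "CHN", "CHN"),
#'   type = c("alert", "alert", "border_rejection"),
#'   hazard = c("aflatoxin", "salmonella", "mercury")
#' )
#' filter_log(log, category = "microorganism")
#' @export
filter_log <- function(log, category = "all", ntype = "all") {
  stopifnot(inherits(log, "notification_log"))
  valid_cats <- c("all", "microorganism", unique(log$category),
                  hazard_categories())
  bad <- setdiff(category, valid_cats)
  if (length(bad)) {
    stop("unknown category filter: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ntype <- match.arg(ntype, c("all", "border_rejection"))
  keep <- rep(TRUE, nrow(log))
  if (!identical(category, "all") && !"all" %in% category) {
    cats <- category
    if ("microorganism" %in% cats) {
      cats <- unique(c(setdiff(cats, "microorganism"), "mycotoxin", "bacteria"))
    }
    keep <- keep & log$category %in% cats
  }
  if (ntype == "border_rejection") keep <- keep & log$type == "border_rejection"
  out <- log[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(log, "provenance")
  class(out) <- c("notification_log", "data.frame")
  out
}
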
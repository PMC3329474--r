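#' Index trajectory over a date grid
#'
#' Recomputes the chosen index at every date of a grid: for each date the
#' log is filtered, the decayed snapshot built and the index computed; the
#' per-country scores are assembled into a matrix aligned to the grid. A
#' country absent from a date's snapshot gets score 0 at that date, so
#' columns always sum to 1 over the full country set.
#'
#' @param log A [notification_log()].
#' @param dates Strictly increasing date grid (`Date` or ISO strings).
#' @param method `"pagerank"` or `"hits"`.
#' @param role `"TI"` or `"DI"`.
#' @param category,ntype Filters, see [filter_log()].
#' @param half_life,min_weight Snapshot parameters, see [build_snapshot()].
#' @param ... Passed to the index engine.
#' @return An `index_trajectory`: list with `dates`, `scores` (countries x
#'   dates matrix), `method`, `role`, `filters`.
#' @export
index_trajectory <- function(log, dates, method = c("pagerank", "hits"),
                             role = c("TI", "DI"), category = "all",
                             ntype = "all", half_life = 180, min_weight = 0,
                             ...) {
  method <- match.arg(method)
  role <- match.arg(role)
  dates <- parse_iso_date(dates)
  if (length(dates) > 1L && any(diff(as.numeric(dates)) <= 0)) {
    stop("date grid must be strictly increasing", call. = FALSE)
  }
  flog <- filter_log(log, category = category, ntype = ntype)
  vectors <- lapply(dates, function(d) {
    snap <- tryCatch(
      build_snapshot(flog, d, half_life = half_life, min_weight = min_weight,
                     filters = list(category = category, ntype = ntype)),
      error = function(e) {
        stop("empty snapshot at grid date ", format(d), call. = FALSE)
      })
    compute_indices(snap, method, ...)[[role]]
  })
  countries <- sort(unique(unlist(lapply(vectors, names))))
  scores <- matrix(0, length(countries), length(dates),
                   dimnames = list(countries, format(dates, "%Y-%m-%d")))
  for (j in seq_along(vectors)) {
    scores[names(vectors[[j]]), j] <- as.numeric(vectors[[j]])
  }
  structure(
    list(dates = dates, scores = scores, method = method, role = role,
         filters = list(category = category, ntype = ntype)),
    class = "index_trajectory"
  )
}

#' @export
print.index_trajectory <- function(x, ...) {
  cat(toupper(x$role), " trajectory by ", x$method, ": ",
      nrow(x$scores), " countries x ", length(x$dates), " dates (",
      format(min(x$dates)), " .. ", format(max(x$dates)), ")\n", sep = "")
  invisible(x)
}

#' Monthly date grid helper
#'
#' First-of-month grid covering a date range, the default spacing for
#' trajectory plots.
#'
#' @param from,to Range endpoints (`Date` or ISO strings).
#' @return Vector of `Date`s.
#' @export
monthly_grid <- function(from, to) {
  from <- parse_iso_date(from)
  to <- parse_iso_date(to)
  seq(as.Date(format(from, "%Y-%m-01")), to, by = "month")
}

#' Red/green colour coding of countries by index strength
#'
#' Maps each country's transgressor and detector impact to a colour: red
#' intensity proportional to TI and green to DI (each clamped to [0, 1]
#' after multiplication by `strength_scale`), so dominant transgressors
#' render red, dominant detectors green and countries active in both roles a
#' mixed brownish tone. Opacity is the maximum of the two intensities, so
#' weak actors render transparently.
#'
#' @param TI,DI `index_vector`s sharing the same country set.
#' @param strength_scale Positive multiplier from index value to colour
#'   intensity. Default: reciprocal of the 95th percentile of the pooled
#'   TI/DI values, so colour saturates for the top actors.
#' @return `data.frame` with columns `country`, `red`, `green`, `alpha`.
#' @export
node_colors <- function(TI, DI, strength_scale = NULL) {
  if (!setequal(names(TI), names(DI))) {
    stop("TI and DI must cover the same countries", call. = FALSE)
  }
  DI <- DI[match(names(TI), names(DI))]
  ti <- as.numeric(TI)
  di <- as.numeric(DI)
  if (is.null(strength_scale)) {
    q <- stats::quantile(c(ti, di), 0.95, names = FALSE)
    strength_scale <- if (q > 0) 1 / q else 1
  }
  if (!is.numeric(strength_scale) || strength_scale <= 0) {
    stop("strength_scale must be positive", call. = FALSE)
  }
  red <- pmin(1, pmax(0, ti * strength_scale))
  green <- pmin(1, pmax(0, di * strength_scale))
  data.frame(country = names(TI), red = red, green = green,
             alpha = pmax(red, green), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Export index vectors as a long or pivoted table
#'
#' Long mode writes one row per (country, vector) with the raw score and the
#' report-scaled score, in the schema
#' `country,method,role,date,score,score_x1000`. Pivot mode writes a
#' report-shaped table: per country a TI row and a DI row, one column per
#' supplied vector label (e.g. filter category), values report-scaled.
#'
#' @param vectors Named list of `index_vector`s. In pivot mode the list
#'   must contain TI/DI pairs named like `"<label>.TI"`, `"<label>.DI"`.
#' @param path Output CSV path.
#' @param pivot Write the pivoted report table instead of long format.
#' @return `path`, invisibly.
#' @export
export_table <- function(vectors, path, pivot = FALSE) {
  if (inherits(vectors, "index_vector")) vectors <- list(vectors)
  stopifnot(all(vapply(vectors, inherits, logical(1), "index_vector")))
  if (!pivot) {
    rows <- lapply(vectors, function(v) {
      data.frame(country = names(v),
                 method = attr(v, "method"), role = attr(v, "role"),
                 date = format(attr(v, "query_date"), "%Y-%m-%d"),
                 score = as.numeric(v),
                 score_x1000 = as.numeric(scale_for_report(v)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  labs <- names(vectors)
  if (is.null(labs) || any(!grepl("\\.(TI|DI)$", labs))) {
    stop("pivot mode needs vectors named '<label>.TI' / '<label>.DI'",
         call. = FALSE)
  }
  columns <- unique(sub("\\.(TI|DI)$", "", labs))
  countries <- sort(unique(unlist(lapply(vectors, names))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("country", "role", columns), collapse = ","), con)
  for (cc in countries) {
    for (role in c("TI", "DI")) {
      vals <- vapply(columns, function(lb) {
        v <- vectors[[paste0(lb, ".", role)]]
        if (is.null(v) || !cc %in% names(v)) return(NA_real_)
        as.numeric(scale_for_report(v)[cc])
      }, numeric(1))
      writeLines(paste(c(cc, role, format(vals, trim = TRUE, digits = 12)),
                       collapse = ","), con)
    }
  }
  invisible(path)
}

#' Read back a long-format index table
#'
#' Inverse of [export_table()] in long mode, for lossless round-trips.
#'
#' @param path CSV written by [export_table()].
#' @return `data.frame` with the long schema.
#' @export
read_index_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                    colClasses = c(country = "character", method = "character",
                                   role = "character", date = "character",
                                   score = "numeric", score_x1000 = "numeric"))
}
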
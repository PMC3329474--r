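#' Temporal decay of a notification's network contribution
#'
#' A notification's effect on the network does not vanish on the day it is
#' logged: it persists and fades, halving every `half_life` days. The weight
#' contributed by a notification aged `age_days` at the query date is
#' `2^(-age_days / half_life)`, i.e. 1 at age 0 and 0.5 at one half-life
#' (180 days by default).
#'
#' @param age_days Non-negative number of days since the notification was
#'   logged (vectorized).
#' @param half_life Half-life in days, positive. Default 180.
#' @return Weights in `(0, 1]`.
#' @examples
#' decay_weight(c(0, 180, 540))  # 1, 0.5, 0.125
#' @export
decay_weight <- function(age_days, half_life = 180) {
  if (!is.numeric(half_life) || length(half_life) != 1L || half_life <= 0) {
    stop("half_life must be a single positive number", call. = FALSE)
  }
  age_days <- as.numeric(age_days)
  if (any(age_days < 0)) {
    stop("age_days must be non-negative; notifications dated after the ",
         "query date are excluded upstream, not decayed", call. = FALSE)
  }
  2^(-age_days / half_life)
}

#' Build a decayed network snapshot at a query date
#'
#' Constructs the directed weighted graph of notification activity as seen
#' from `query_date`. Every notification dated on or before the query date
#' contributes a decayed weight ([decay_weight()]) to the edge from its
#' detector to its transgressor; parallel notifications between the same pair
#' are aggregated into one edge by summing their contributions. Notifications
#' dated after the query date are excluded.
#'
#' @param log A [notification_log()], typically pre-filtered with
#'   [filter_log()].
#' @param query_date Query date (`Date` or ISO-8601 string).
#' @param half_life Decay half-life in days.
#' @param min_weight Drop edges whose aggregate weight falls below this
#'   threshold. Default 0 (no pruning; decayed weights never reach exactly
#'   zero).
#' @param filters Optional record of the category/ntype filters applied to
#'   `log`, stored as snapshot metadata.
#' @return A `snapshot` object: list with `query_date`, `nodes` (sorted
#'   country codes), `edges` (`data.frame` with `source`, `target`,
#'   `weight`), `half_life`, `min_weight`, `filters`.
#' @examples
#' log <- notification_log(
#'   date = c("2007-01-01", "2007-06-30"),
#'   detector = "DEU", transgressor = "IRN",
#'   type = "alert", hazard = "aflatoxin"
#' )
#' build_snapshot(log, "2007-06-30")  # one edge, weight 1 + 2^(-180/180)
#' @export
build_snapshot <- function(log, query_date, half_life = 180, min_weight = 0,
                           filters = list(category = "all", ntype = "all")) {
  stopifnot(inherits(log, "notification_log"))
  query_date <- parse_iso_date(query_date)
  stopifnot(length(query_date) == 1L)
  if (min_weight < 0) stop("min_weight must be >= 0", call. = FALSE)
  live <- log[log$date <= query_date, , drop = FALSE]
  if (nrow(live) == 0L) {
    stop("empty snapshot: no notification on or before ", format(query_date),
         call. = FALSE)
  }
  age <- as.numeric(query_date - live$date)
  w <- decay_weight(age, half_life)
  agg <- stats::aggregate(w,
                          by = list(source = live$detector,
                                    target = live$transgressor),
                          FUN = sum)
  names(agg)[3L] <- "weight"
  nodes <- sort(unique(c(live$detector, live$transgressor)))
  agg <- agg[agg$weight >= min_weight & agg$weight > 0, , drop = FALSE]
  agg <- agg[order(agg$source, agg$target), , drop = FALSE]
  rownames(agg) <- NULL
  structure(
    list(query_date = query_date, nodes = nodes, edges = agg,
         half_life = half_life, min_weight = min_weight, filters = filters),
    class = "snapshot"
  )
}

#' @export
print.snapshot <- function(x, ...) {
  cat("Notification network snapshot at ", format(x$query_date), "\n",
      "  ", length(x$nodes), " countries, ", nrow(x$edges),
      " directed edges (detector -> transgressor)\n",
      "  half-life ", x$half_life, " d; filters: category=",
      paste(x$filters$category, collapse = "+"), ", type=",
      x$filters$ntype %||% "all", "\n", sep = "")
  invisible(x)
}

#' Reverse the orientation of a snapshot
#'
#' Swaps every edge's source and target, keeping nodes and weights. The
#' reversed orientation (transgressor -> detector) is what the detector-index
#' PageRank runs on; applying `reverse_snapshot()` twice returns the original
#' snapshot.
#'
#' @param snapshot A `snapshot`.
#' @return A `snapshot` with reversed edges.
#' @export
reverse_snapshot <- function(snapshot) {
  stopifnot(inherits(snapshot, "snapshot"))
  e <- snapshot$edges
  e <- data.frame(source = e$target, target = e$source, weight = e$weight,
                  stringsAsFactors = FALSE)
  e <- e[order(e$source, e$target), , drop = FALSE]
  rownames(e) <- NULL
  snapshot$edges <- e
  snapshot
}

#' Convert a snapshot to an igraph graph
#'
#' @param snapshot A `snapshot`.
#' @param directed Keep the detector -> transgressor orientation (`TRUE`,
#'   default) or collapse to the undirected projection with summed weights
#'   (`FALSE`), as used by the structural analyses.
#' @return An `igraph` graph with a `weight` edge attribute; all snapshot
#'   nodes are vertices, including isolated ones.
#' @export
snapshot_igraph <- function(snapshot, directed = TRUE) {
  stopifnot(inherits(snapshot, "snapshot"))
  g <- igraph::graph_from_data_frame(snapshot$edges, directed = TRUE,
                                     vertices = snapshot$nodes)
  if (!directed) {
    g <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = list(weight = "sum"))
  }
  g
}

#' Export a snapshot as an edge-list CSV
#'
#' Writes `source,target,weight` rows; query date, half-life and filters are
#' recorded in `#`-prefixed header comments.
#'
#' @param snapshot A `snapshot`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_edges <- function(snapshot, path) {
  stopifnot(inherits(snapshot, "snapshot"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# query_date: ", format(snapshot$query_date)),
    paste0("# half_life_days: ", snapshot$half_life),
    paste0("# filters: category=",
           paste(snapshot$filters$category, collapse = "+"),
           " ntype=", snapshot$filters$ntype %||% "all")
  ), con)
  utils::write.table(snapshot$edges, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export a snapshot as GraphML
#'
#' Writes the directed weighted graph in GraphML, optionally stamping
#' per-node colour attributes (`red`, `green`, `alpha` from [node_colors()])
#' and community ids (from [find_communities()]) as vertex attributes, and
#' the query date/filters as graph attributes.
#'
#' @param snapshot A `snapshot`.
#' @param path Output path.
#' @param colors Optional `data.frame` from [node_colors()].
#' @param partition Optional partition from [find_communities()].
#' @return `path`, invisibly.
#' @export
export_graphml <- function(snapshot, path, colors = NULL, partition = NULL) {
  g <- snapshot_igraph(snapshot)
  g <- igraph::set_graph_attr(g, "query_date", format(snapshot$query_date))
  g <- igraph::set_graph_attr(g, "half_life_days", snapshot$half_life)
  g <- igraph::set_graph_attr(
    g, "filters", paste0("category=",
                         paste(snapshot$filters$category, collapse = "+"),
                         ";ntype=", snapshot$filters$ntype %||% "all"))
  if (!is.null(colors)) {
    idx <- match(igraph::V(g)$name, colors$country)
    if (anyNA(idx)) stop("colors must cover every snapshot node", call. = FALSE)
    g <- igraph::set_vertex_attr(g, "red", value = colors$red[idx])
    g <- igraph::set_vertex_attr(g, "green", value = colors$green[idx])
    g <- igraph::set_vertex_attr(g, "alpha", value = colors$alpha[idx])
  }
  if (!is.null(partition)) {
    memb <- partition$assignment
    idx <- match(igraph::V(g)$name, names(memb))
    if (anyNA(idx)) stop("partition must cover every snapshot node",
                         call. = FALSE)
    g <- igraph::set_vertex_attr(g, "community", value = unname(memb[idx]))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
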
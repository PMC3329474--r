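new_index_vector <- function(scores, method, role, query_date,
                             report_scale = 1000) {
  scores <- scores[order(names(scores))]
  structure(scores, class = "index_vector", method = method, role = role,
            query_date = query_date, report_scale = report_scale)
}

#' @export
print.index_vector <- function(x, n = 10L, ...) {
  cat(toupper(attr(x, "role")), " by ", attr(x, "method"), " at ",
      format(attr(x, "query_date")), " (", length(x), " countries, sum = ",
      format(sum(x)), ")\n", sep = "")
  top <- sort(unclass(x), decreasing = TRUE)
  top <- utils::head(top, n)
  for (i in seq_along(top)) {
    cat(sprintf("  %-4s %8.2f (x%d)\n", names(top)[i],
                top[i] * attr(x, "report_scale"), attr(x, "report_scale")))
  }
  invisible(x)
}

# dense weighted adjacency of a snapshot, rows = source, cols = target,
# node order = snapshot$nodes (already sorted)
snapshot_matrix <- function(snapshot) {
  n <- length(snapshot$nodes)
  W <- matrix(0, n, n, dimnames = list(snapshot$nodes, snapshot$nodes))
  e <- snapshot$edges
  if (nrow(e)) W[cbind(match(e$source, snapshot$nodes),
                       match(e$target, snapshot$nodes))] <- e$weight
  W
}

# weighted PageRank by power iteration on adjacency W (rows = source);
# dangling nodes (zero out-strength) teleport uniformly
pagerank_power <- function(W, damping = 0.85, tol = 1e-10, max_iter = 1000L) {
  n <- nrow(W)
  if (n == 1L) return(stats::setNames(1, rownames(W)))
  out_s <- rowSums(W)
  dangling <- out_s == 0
  # row-normalize non-dangling rows once
  M <- W / ifelse(out_s == 0, 1, out_s)
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x_new <- (1 - damping) / n +
      damping * (drop(crossprod(M, x * !dangling)) + sum(x[dangling]) / n)
    res <- sum(abs(x_new - x))
    x <- x_new
    if (res < tol) {
      x <- x / sum(x)
      return(stats::setNames(x, rownames(W)))
    }
  }
  stop("PageRank did not converge after ", max_iter,
       " iterations (L1 residual ", format(res), ")", call. = FALSE)
}

#' Transgressor and Detector Indices by weighted PageRank
#'
#' Computes the two per-country impact indices from a network snapshot. The
#' Transgressor Index (TI) is the weighted PageRank of the detector ->
#' transgressor orientation: being reported, especially by influential
#' detectors, raises a country's TI. The Detector Index (DI) is the weighted
#' PageRank of the reversed orientation. The two PageRank indices are
#' computed independently of each other. Each index is L1-normalized, so TIs
#' (and DIs) sum to 1 over countries at any query date and can be compared
#' like for like.
#'
#' Countries with no out-edge in the relevant orientation (e.g. pure
#' transgressors in the TI run) are dangling nodes and teleport uniformly,
#' keeping the index a proper probability distribution.
#'
#' @param snapshot A [build_snapshot()] result.
#' @param damping PageRank damping factor in (0, 1). Default 0.85.
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter Maximum iterations before a non-convergence error.
#' @return List with elements `TI` and `DI`, each an `index_vector` (named
#'   numeric over all snapshot nodes, zero-score countries retained).
#' @examples
#' log <- notification_log(
#'   date = rep("2007-01-01", 3), detector = "DEU",
#'   transgressor = c("IRN", "CHN", "BRA"),
#'   type = "alert", hazard = "aflatoxin"
#' )
#' pagerank_indices(build_snapshot(log, "2007-01-01"))
#' @export
pagerank_indices <- function(snapshot, damping = 0.85, tol = 1e-10,
                             max_iter = 1000L) {
  stopifnot(inherits(snapshot, "snapshot"))
  if (!is.numeric(damping) || damping <= 0 || damping >= 1) {
    stop("damping must be in (0, 1)", call. = FALSE)
  }
  W <- snapshot_matrix(snapshot)
  ti <- pagerank_power(W, damping, tol, max_iter)
  di <- pagerank_power(t(W), damping, tol, max_iter)
  list(
    TI = new_index_vector(ti, "pagerank", "TI", snapshot$query_date),
    DI = new_index_vector(di, "pagerank", "DI", snapshot$query_date)
  )
}

#' Transgressor and Detector Indices by weighted HITS
#'
#' Computes mutually reinforcing impact indices by the weighted
#' hub/authority iteration on the detector -> transgressor orientation: the
#' Detector Index is the hub score (a detector is strong if it reports
#' countries with high TI) and the Transgressor Index is the authority score
#' (a transgressor is strong if reported by countries with high DI). Unlike
#' the PageRank pair, the two HITS indices take each other into account.
#'
#' Internally the iteration is L2-normalized for numerical stability; the
#' returned vectors are L1-normalized so each index sums to 1.
#'
#' @param snapshot A [build_snapshot()] result with at least one edge.
#' @param tol Convergence tolerance (L1 change of both normalized vectors).
#' @param max_iter Maximum iterations before a non-convergence error. The
#'   default is generous because graphs whose two leading singular values
#'   nearly tie (e.g. loosely coupled components of similar strength)
#'   converge slowly.
#' @return List with `TI` (authority) and `DI` (hub) `index_vector`s.
#' @export
hits_indices <- function(snapshot, tol = 1e-12, max_iter = 10000L) {
  stopifnot(inherits(snapshot, "snapshot"))
  if (nrow(snapshot$edges) == 0L) {
    stop("HITS requires a snapshot with at least one edge", call. = FALSE)
  }
  W <- snapshot_matrix(snapshot)
  n <- nrow(W)
  h <- rep(1 / sqrt(n), n)
  a <- rep(0, n)
  for (it in seq_len(max_iter)) {
    a_new <- drop(crossprod(W, h))
    a_new <- a_new / sqrt(sum(a_new^2))
    h_new <- drop(W %*% a_new)
    h_new <- h_new / sqrt(sum(h_new^2))
    res <- sum(abs(a_new - a)) + sum(abs(h_new - h))
    a <- a_new
    h <- h_new
    if (res < tol) break
    if (it == max_iter) {
      stop("HITS did not converge after ", max_iter,
           " iterations (residual ", format(res), ")", call. = FALSE)
    }
  }
  a <- stats::setNames(pmax(a, 0) / sum(pmax(a, 0)), rownames(W))
  h <- stats::setNames(pmax(h, 0) / sum(pmax(h, 0)), rownames(W))
  list(
    TI = new_index_vector(a, "hits", "TI", snapshot$query_date),
    DI = new_index_vector(h, "hits", "DI", snapshot$query_date)
  )
}

#' Compute TI/DI indices with a chosen method
#'
#' Convenience dispatcher over [pagerank_indices()] and [hits_indices()].
#'
#' @param snapshot A `snapshot`.
#' @param method `"pagerank"` or `"hits"`.
#' @param ... Passed to the engine.
#' @return List with `TI` and `DI`.
#' @export
compute_indices <- function(snapshot, method = c("pagerank", "hits"), ...) {
  method <- match.arg(method)
  switch(method,
         pagerank = pagerank_indices(snapshot, ...),
         hits = hits_indices(snapshot, ...))
}

#' Scale an index vector for reporting
#'
#' Index values are small fractions of 1; for readability reports multiply
#' them by a fixed scale (1000 by default), so a country holding a fifth of
#' all transgressor impact prints as ~200.
#'
#' @param v An `index_vector`.
#' @param scale Multiplier; defaults to the vector's `report_scale`.
#' @return Named numeric vector of scaled scores; `v` is unmodified.
#' @export
scale_for_report <- function(v, scale = attr(v, "report_scale") %||% 1000) {
  stopifnot(inherits(v, "index_vector"))
  stats::setNames(as.numeric(v) * scale, names(v))
}
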
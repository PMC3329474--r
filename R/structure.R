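#' Modularity of a community assignment
#'
#' Newman's weighted modularity Q of a partition, evaluated on the
#' undirected projection of the snapshot (edge weights between a pair summed
#' over both directions). Q compares the weight falling within communities
#' with its expectation under a degree-preserving null model; Q lies in
#' [-0.5, 1], is 0 for the single-community partition and is large when the
#' network splits into tightly connected groups.
#'
#' @param snapshot A `snapshot`.
#' @param assignment Named vector (country -> community id) covering every
#'   snapshot node.
#' @return Modularity Q.
#' @examples
#' # two disjoint unit-weight triangles split into their triangles: Q = 0.5
#' @export
modularity_q <- function(snapshot, assignment) {
  g <- snapshot_igraph(snapshot, directed = FALSE)
  miss <- setdiff(igraph::V(g)$name, names(assignment))
  if (length(miss)) {
    stop("assignment missing node(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  memb <- as.integer(factor(assignment[igraph::V(g)$name]))
  igraph::modularity(g, memb, weights = igraph::E(g)$weight)
}

#' Detect communities by modularity maximization
#'
#' Greedy multilevel (Louvain-family) modularity optimization on the
#' weighted undirected projection of the snapshot. The returned Q is the
#' modularity of the returned assignment, recomputable via
#' [modularity_q()].
#'
#' @param snapshot A `snapshot` with at least one edge.
#' @param seed Integer seed fixed for reproducible refinement order.
#' @return A `partition`: list with `assignment` (named country ->
#'   community id) and `modularity_q`.
#' @export
find_communities <- function(snapshot, seed = 1L) {
  stopifnot(inherits(snapshot, "snapshot"))
  if (nrow(snapshot$edges) == 0L) {
    stop("community detection requires at least one edge", call. = FALSE)
  }
  g <- snapshot_igraph(snapshot, directed = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  assignment <- stats::setNames(igraph::membership(cl), igraph::V(g)$name)
  structure(
    list(assignment = assignment,
         modularity_q = modularity_q(snapshot, assignment)),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  k <- length(unique(x$assignment))
  cat("Partition into ", k, " communities, Q = ",
      format(x$modularity_q, digits = 4), "\n", sep = "")
  invisible(x)
}

#' k-core decomposition
#'
#' Coreness of every country on the unweighted undirected projection of the
#' snapshot (multi-edges collapsed, self-loops dropped). A country's
#' coreness is the largest k such that it survives iterative peeling of all
#' nodes with degree < k; high-coreness countries form the strongly
#' interconnected core of the notification network.
#'
#' @param snapshot A `snapshot`.
#' @return Named integer vector country -> coreness (0 for isolated nodes).
#' @export
k_core <- function(snapshot) {
  g <- snapshot_igraph(snapshot, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  cores <- igraph::coreness(g)
  stats::setNames(as.integer(cores), igraph::V(g)$name)
}

#' Export a partition or coreness map as CSV
#'
#' @param x A `partition` from [find_communities()] or a named coreness
#'   vector from [k_core()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_structure <- function(x, path) {
  if (inherits(x, "partition")) {
    df <- data.frame(country = names(x$assignment),
                     community = unname(x$assignment))
  } else {
    df <- data.frame(country = names(x), coreness = unname(x))
  }
  df <- df[order(df$country), , drop = FALSE]
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
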
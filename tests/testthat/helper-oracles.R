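# Independent oracles and fixture builders used across the suite.
# Oracles are deliberately naive (dense linear algebra, exhaustive search,
# literal peeling) and share no code with the implementation they check.

# build a snapshot object directly from an edge table (bypasses the log
# machinery, for graph-level tests)
toy_snapshot <- function(edges, nodes = NULL, query_date = as.Date("2008-01-01")) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$source, edges$target)))
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      weight = as.numeric(edges$weight),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(query_date = query_date, nodes = sort(nodes), edges = edges,
         half_life = 180, min_weight = 0,
         filters = list(category = "all", ntype = "all")),
    class = "snapshot"
  )
}

# small log built in code; 2 mycotoxin, 1 bacteria, 1 metal, 1 uncategorized
toy_log <- function() {
  notification_log(
    date = c("2007-01-01", "2007-02-01", "2007-03-01", "2007-04-01",
             "2007-05-01"),
    detector = c("DEU", "DEU", "ITA", "ESP", "ITA"),
    transgressor = c("IRN", "IRN", "CHN", "CHN", "BRA"),
    type = c("alert", "information", "alert", "border_rejection", "alert"),
    hazard = c("aflatoxin in pistachios", "ochratoxin in dried figs",
               "salmonella in poultry", "mercury in swordfish",
               "incorrect labelling of allergens")
  )
}

# random weighted digraph snapshot on n nodes (ISO codes), >= 1 edge
random_snapshot <- function(seed, n_max = 8L, p_edge = 0.4) {
  set.seed(seed)
  n <- sample(3:n_max, 1L)
  nodes <- sort(sample(iso3_codes(), n))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[sample.int(nrow(pairs), 1L)] <- TRUE
  edges <- pairs[keep, , drop = FALSE]
  edges$weight <- stats::runif(nrow(edges), 0.5, 2)
  toy_snapshot(edges, nodes)
}

# dense adjacency (rows = source) in sorted node order
adjacency_of <- function(snapshot) {
  n <- length(snapshot$nodes)
  W <- matrix(0, n, n, dimnames = list(snapshot$nodes, snapshot$nodes))
  e <- snapshot$edges
  if (nrow(e)) W[cbind(match(e$source, snapshot$nodes),
                       match(e$target, snapshot$nodes))] <- e$weight
  W
}

# PageRank oracle: direct solve of (I - d G) x = (1-d)/n, where G is the
# column-stochastic transition matrix with dangling columns uniform
pagerank_solve_oracle <- function(W, damping = 0.85) {
  n <- nrow(W)
  out_s <- rowSums(W)
  G <- matrix(1 / n, n, n)
  nz <- out_s > 0
  G[, nz] <- t(W[nz, , drop = FALSE] / out_s[nz])
  x <- solve(diag(n) - damping * G, rep((1 - damping) / n, n))
  stats::setNames(x / sum(x), rownames(W))
}

# HITS oracle: power iteration with the explicit Gram matrices t(W)W
# (authority) and W t(W) (hub), driven to the fixed point by repeated
# squaring of the operator (A^(2^50) applied to the all-ones vector), so the
# oracle is fully converged even under tiny spectral gaps
hits_power_oracle <- function(W, squarings = 50L) {
  fixed_point <- function(A) {
    for (i in seq_len(squarings)) {
      A <- A %*% A
      A <- A / max(A)
    }
    v <- drop(A %*% rep(1, nrow(A)))
    v / sum(v)
  }
  list(TI = stats::setNames(fixed_point(crossprod(W)), rownames(W)),
       DI = stats::setNames(fixed_point(tcrossprod(W)), rownames(W)))
}

# hand-evaluated Newman modularity on the undirected projection of a
# directed edge table (no self-loops expected in oracle fixtures)
modularity_hand <- function(edges, nodes, membership) {
  und <- aggregate(weight ~ a + b,
                   data = data.frame(a = pmin(edges$source, edges$target),
                                     b = pmax(edges$source, edges$target),
                                     weight = edges$weight), FUN = sum)
  m <- sum(und$weight)
  inside <- sum(und$weight[membership[und$a] == membership[und$b]])
  deg <- stats::setNames(numeric(length(nodes)), nodes)
  for (i in seq_len(nrow(und))) {
    deg[und$a[i]] <- deg[und$a[i]] + und$weight[i]
    deg[und$b[i]] <- deg[und$b[i]] + und$weight[i]
  }
  dc <- tapply(deg, membership[names(deg)], sum)
  inside / m - sum((dc / (2 * m))^2)
}

# all set partitions of n elements as membership vectors (restricted growth)
set_partitions <- function(n) {
  parts <- list(c(1L))
  for (i in seq_len(n - 1L)) {
    parts <- unlist(lapply(parts, function(p) {
      lapply(seq_len(max(p) + 1L), function(v) c(p, v))
    }), recursive = FALSE)
  }
  parts
}

# exhaustive modularity optimum over all partitions
best_modularity_oracle <- function(edges, nodes) {
  best_q <- -Inf
  best_memb <- NULL
  for (p in set_partitions(length(nodes))) {
    memb <- stats::setNames(p, nodes)
    q <- modularity_hand(edges, nodes, memb)
    if (q > best_q) {
      best_q <- q
      best_memb <- memb
    }
  }
  list(q = best_q, membership = best_memb)
}

# literal k-core peeling on the simple undirected projection
coreness_peel_oracle <- function(edges, nodes) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    s <- edges$source[i]; t <- edges$target[i]
    if (s != t) { adj[s, t] <- TRUE; adj[t, s] <- TRUE }
  }
  core <- stats::setNames(integer(n), nodes)
  alive <- rep(TRUE, n)
  k <- 1L
  while (any(alive)) {
    repeat {
      deg <- rowSums(adj[, alive, drop = FALSE]) * alive
      low <- which(alive & deg < k)
      if (!length(low)) break
      core[low] <- k - 1L
      alive[low] <- FALSE
    }
    k <- k + 1L
  }
  core
}

# directed edge table of two disjoint unit-weight triangles
two_triangles_edges <- function() {
  data.frame(
    source = c("AUT", "BEL", "CZE", "DNK", "EST", "FIN"),
    target = c("BEL", "CZE", "AUT", "EST", "FIN", "DNK"),
    weight = 1, stringsAsFactors = FALSE
  )
}

# planted two-block directed graph; returns snapshot + true block labels
planted_two_block <- function(seed, n = 10L, p_in = 0.9, p_out = 0.05) {
  set.seed(seed)
  nodes <- sort(iso3_codes()[seq_len(n)])
  block <- stats::setNames(rep(1:2, each = n / 2), nodes)
  src <- character(0); tgt <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      p <- if (block[nodes[i]] == block[nodes[j]]) p_in else p_out
      if (stats::runif(1) < p) {
        src <- c(src, nodes[i]); tgt <- c(tgt, nodes[j])
      }
    }
  }
  edges <- data.frame(source = src, target = tgt, weight = 1,
                      stringsAsFactors = FALSE)
  list(snapshot = toy_snapshot(edges, nodes), block = block)
}
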
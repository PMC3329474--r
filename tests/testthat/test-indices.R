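star_snapshot <- function() {
  toy_snapshot(data.frame(
    source = "DEU", target = c("IRN", "CHN", "BRA"), weight = 1,
    stringsAsFactors = FALSE
  ))
}

test_that("PageRank indices respect star symmetry and sum to one", {
  pr <- pagerank_indices(star_snapshot())
  ti <- pr$TI
  expect_equal(sum(ti), 1, tolerance = 1e-12)
  expect_equal(sum(pr$DI), 1, tolerance = 1e-12)
  # the three reported countries are exchangeable
  expect_equal(unname(ti["IRN"]), unname(ti["CHN"]), tolerance = 1e-9)
  expect_equal(unname(ti["IRN"]), unname(ti["BRA"]), tolerance = 1e-9)
  # being reported raises TI above the reporter's
  expect_gt(ti["IRN"], ti["DEU"])
  # detector role mirrors: DEU has the top DI
  expect_equal(names(which.max(pr$DI)), "DEU")
})

test_that("HITS on a star gives the hub all DI and splits TI equally", {
  h <- hits_indices(star_snapshot())
  expect_equal(unname(h$DI["DEU"]), 1, tolerance = 1e-9)
  expect_equal(unname(h$DI["IRN"]), 0, tolerance = 1e-9)
  expect_equal(unname(h$TI[c("BRA", "CHN", "IRN")]), rep(1 / 3, 3),
               tolerance = 1e-9)
  expect_equal(unname(h$TI["DEU"]), 0, tolerance = 1e-9)
})

test_that("index vectors are normalized on arbitrary synthetic snapshots", {
  log <- generate_log(default_scenario(n_notifications = 600, seed = 3))
  s <- build_snapshot(log, "2008-01-01")
  for (idx in list(pagerank_indices(s), hits_indices(s))) {
    expect_equal(sum(idx$TI), 1, tolerance = 1e-9)
    expect_equal(sum(idx$DI), 1, tolerance = 1e-9)
    expect_true(all(idx$TI >= 0) && all(idx$DI >= 0))
    expect_setequal(names(idx$TI), s$nodes)
    expect_setequal(names(idx$DI), s$nodes)
  }
})

test_that("PageRank matches the dense linear-system oracle on random digraphs", {
  for (seed in 1:25) {
    s <- random_snapshot(seed)
    W <- adjacency_of(s)
    pr <- pagerank_indices(s)
    expect_lt(max(abs(pr$TI[rownames(W)] - pagerank_solve_oracle(W))), 1e-8)
    expect_lt(max(abs(pr$DI[rownames(W)] - pagerank_solve_oracle(t(W)))), 1e-8)
  }
})

test_that("PageRank matches igraph's implementation", {
  for (seed in c(2, 17, 31)) {
    s <- random_snapshot(seed)
    g <- snapshot_igraph(s)
    ref <- igraph::page_rank(g, weights = igraph::E(g)$weight,
                             damping = 0.85)$vector
    pr <- pagerank_indices(s)
    expect_equal(unname(pr$TI[names(ref)]), unname(ref), tolerance = 1e-6)
  }
})

test_that("HITS matches the explicit-matrix oracle and igraph", {
  for (seed in 1:25) {
    s <- random_snapshot(seed)
    W <- adjacency_of(s)
    h <- hits_indices(s)
    orc <- hits_power_oracle(W)
    expect_lt(max(abs(h$TI[rownames(W)] - orc$TI)), 1e-8)
    expect_lt(max(abs(h$DI[rownames(W)] - orc$DI)), 1e-8)
  }
  s <- random_snapshot(8)
  g <- snapshot_igraph(s)
  ref <- igraph::hits_scores(g, weights = igraph::E(g)$weight)
  h <- hits_indices(s)
  expect_equal(unname(h$TI[names(ref$authority)]),
               unname(ref$authority / sum(ref$authority)), tolerance = 1e-6)
  expect_equal(unname(h$DI[names(ref$hub)]),
               unname(ref$hub / sum(ref$hub)), tolerance = 1e-6)
})

test_that("two disjoint stars concentrate HITS mass on the heavier hub", {
  s <- toy_snapshot(data.frame(
    source = rep(c("AUT", "BGR"), each = 2),
    target = c("CHN", "IND", "TUR", "BRA"),
    weight = c(2, 2, 1, 1), stringsAsFactors = FALSE
  ))
  h <- hits_indices(s)
  orc <- hits_power_oracle(adjacency_of(s))
  expect_lt(max(abs(h$TI[names(orc$TI)] - orc$TI)), 1e-8)
  expect_lt(max(abs(h$DI[names(orc$DI)] - orc$DI)), 1e-8)
  expect_gt(h$DI["AUT"], 0.99)
})

test_that("indices are permutation-equivariant and weight-scale invariant", {
  s <- random_snapshot(123)
  # relabel countries by a fixed bijection
  relabel <- stats::setNames(rev(s$nodes), s$nodes)
  e2 <- data.frame(source = unname(relabel[s$edges$source]),
                   target = unname(relabel[s$edges$target]),
                   weight = s$edges$weight, stringsAsFactors = FALSE)
  s2 <- toy_snapshot(e2, unname(relabel))
  for (engine in list(pagerank_indices, hits_indices)) {
    a <- engine(s); b <- engine(s2)
    expect_equal(unname(b$TI[unname(relabel[names(a$TI)])]),
                 unname(as.numeric(a$TI)), tolerance = 1e-9)
    expect_equal(unname(b$DI[unname(relabel[names(a$DI)])]),
                 unname(as.numeric(a$DI)), tolerance = 1e-9)
  }
  # scaling all weights leaves both index families unchanged
  s3 <- s; s3$edges$weight <- s3$edges$weight * 7.3
  expect_equal(as.numeric(pagerank_indices(s3)$TI),
               as.numeric(pagerank_indices(s)$TI), tolerance = 1e-9)
  expect_equal(as.numeric(hits_indices(s3)$TI),
               as.numeric(hits_indices(s)$TI), tolerance = 1e-9)
})

test_that("PageRank roles are independent while HITS roles are coupled", {
  # 2-hub configuration: AUT reports {CHN, IND}, BGR reports only CHN.
  base <- function(w_into_chn) toy_snapshot(data.frame(
    source = c("AUT", "AUT", "BGR"),
    target = c("CHN", "IND", "CHN"),
    weight = c(w_into_chn, 1, w_into_chn), stringsAsFactors = FALSE
  ))
  lo <- base(1); hi <- base(4)
  # raising the weight of edges into the high-TI country (CHN) raises the
  # HITS DI of its minor reporter BGR...
  expect_gt(hits_indices(hi)$DI["BGR"], hits_indices(lo)$DI["BGR"])
  # ...but PageRank DI is computed without reference to TI: the reporters'
  # DI values are untouched (per-source normalization absorbs the raise)
  expect_equal(as.numeric(pagerank_indices(hi)$DI),
               as.numeric(pagerank_indices(lo)$DI), tolerance = 1e-9)
})

test_that("engines handle degenerate snapshots per contract", {
  # edgeless snapshot: PageRank degenerates to uniform, HITS errors
  s <- toy_snapshot(data.frame(source = character(0), target = character(0),
                               weight = numeric(0)), nodes = c("DEU", "IRN"))
  pr <- pagerank_indices(s)
  expect_equal(as.numeric(pr$TI), c(0.5, 0.5))
  expect_error(hits_indices(s), "at least one edge")
  expect_error(pagerank_indices(star_snapshot(), damping = 1.2), "damping")
  expect_error(pagerank_indices(star_snapshot(), max_iter = 1L),
               "did not converge")
})

test_that("report scaling multiplies scores without touching the vector", {
  pr <- pagerank_indices(star_snapshot())
  scaled <- scale_for_report(pr$TI)
  expect_equal(sum(scaled), 1000, tolerance = 1e-9)
  expect_equal(unname(scaled["IRN"]), unname(pr$TI["IRN"]) * 1000)
  expect_equal(sum(pr$TI), 1, tolerance = 1e-12)  # original untouched
  expect_equal(scale_for_report(pr$TI, scale = 1),
               stats::setNames(as.numeric(pr$TI), names(pr$TI)))
})
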
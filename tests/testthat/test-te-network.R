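te_tbl <- function(m) {
  tibble::tibble(
    m_slot = as.vector(row(m)), f_slot = as.vector(col(m)),
    te = as.vector(m), n_triples = 100L)
}

test_that("the edge criterion is the interquartile band of defined TE values", {
  crit <- edge_criterion(1:8)
  expect_equal(crit$lower, 2.75)   # linear-interpolation quantiles
  expect_equal(crit$upper, 6.25)
  expect_equal(crit$n, 8L)
  # NAs are dropped before the quartiles
  expect_equal(edge_criterion(c(1:8, NA, NA))$lower, 2.75)
  # degenerate but valid: all values equal
  d <- edge_criterion(rep(0.3, 6))
  expect_equal(d$lower, 0.3)
  expect_equal(d$upper, 0.3)
  expect_equal(d$mode, 0.3)
  expect_error(edge_criterion(1:3), "at least 4")
  # the mode diagnostic sits in the tallest histogram bin
  v <- c(rep(0.5, 30), stats::runif(10))
  expect_lt(abs(edge_criterion(v)$mode - 0.5), 0.06)
})

test_that("network edges are exactly the in-band defined pairs", {
  m <- matrix(c(0.1, 0.9, 0.5, 0.5), 2, 2)   # rows = m_slot, cols = f_slot
  crit <- structure(list(lower = 0.4, upper = 0.6, mode = 0.5, n = 4L),
                    class = "edge_criterion")
  g <- build_te_network(te_tbl(m), crit)
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 2L)
  edges <- igraph::as_data_frame(g)
  expect_setequal(paste(edges$from, edges$to), c("M1 F2", "M2 F2"))
  expect_true(igraph::is_bipartite(g))

  # all-missing matrix: 40 isolated nodes
  na20 <- matrix(NA_real_, 20, 20)
  g0 <- build_te_network(te_tbl(na20),
                         structure(list(lower = -Inf, upper = Inf),
                                   class = "edge_criterion"))
  expect_equal(igraph::vcount(g0), 40L)
  expect_equal(igraph::ecount(g0), 0L)

  # unbounded criterion connects every defined pair
  full <- build_te_network(te_tbl(matrix(stats::runif(9), 3, 3)),
                           structure(list(lower = -Inf, upper = Inf),
                                     class = "edge_criterion"))
  expect_equal(igraph::ecount(full), 9L)
})

test_that("betweenness matches closed forms on stars and complete bipartite", {
  # star K(1,3): macrophage centre joined to 3 fibroblasts
  star <- te_tbl(matrix(0.5, 1, 3))
  crit <- structure(list(lower = 0, upper = 1), class = "edge_criterion")
  g <- build_te_network(star, crit)
  b <- network_betweenness(g)
  expect_equal(b$betweenness[b$node == "M1"], 1)
  expect_equal(b$betweenness[b$kind == "fibroblast"], rep(0, 3))
  expect_equal(fm_ratio(g), 0)   # all centrality on the macrophage centre

  # K(2,2): symmetric, all four nodes equal
  k22 <- build_te_network(te_tbl(matrix(0.5, 2, 2)), crit)
  b22 <- network_betweenness(k22)$betweenness
  expect_equal(length(unique(round(b22, 12))), 1L)
})

test_that("betweenness agrees exactly with brute-force path enumeration", {
  set.seed(11)
  for (i in 1:25) {
    n_m <- sample(2:4, 1); n_f <- sample(2:4, 1)
    m <- matrix(stats::runif(n_m * n_f), n_m, n_f)
    m[stats::runif(length(m)) < 0.4] <- NA    # some missing entries
    crit <- structure(list(lower = 0.2, upper = 0.9),
                      class = "edge_criterion")
    g <- build_te_network(te_tbl(m), crit)
    b <- network_betweenness(g)
    # independent adjacency reconstruction
    n <- n_m + n_f
    adj <- matrix(0L, n, n)
    for (mi in seq_len(n_m)) for (fi in seq_len(n_f)) {
      v <- m[mi, fi]
      if (!is.na(v) && v >= 0.2 && v <= 0.9) {
        adj[mi, n_m + fi] <- adj[n_m + fi, mi] <- 1L
      }
    }
    expected <- oracle_betweenness(adj)
    got <- b$betweenness[match(c(paste0("M", seq_len(n_m)),
                                 paste0("F", seq_len(n_f))), b$node)]
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("F/M handles the undefined and degenerate cases", {
  expect_equal(fm_ratio(tibble::tibble(
    node = c("M1", "F1"), kind = c("macrophage", "fibroblast"),
    betweenness = c(0.3, 0.6))), 2)
  # edgeless network: both sums zero -> undefined flag, not an error
  crit0 <- structure(list(lower = 2, upper = 3), class = "edge_criterion")
  g0 <- build_te_network(te_tbl(matrix(0.5, 2, 2)), crit0)
  expect_true(is.na(fm_ratio(g0)))
})

test_that("condition summaries pool the criterion and keep replicates apart", {
  set.seed(12)
  mk <- function() {
    m <- matrix(stats::runif(400), 20, 20)
    structure(te_tbl(m), class = c("te_table", class(te_tbl(m))))
  }
  tes <- list(mk(), mk(), mk())
  cs <- condition_summary(tes)
  expect_equal(cs$criterion$n, 1200L)
  expect_length(cs$networks, 3L)
  expect_equal(nrow(cs$replicates), 3L)
  expect_equal(nrow(cs$betweenness), 3L * 40L)
  expect_equal(cs$mean_fm, mean(cs$replicates$fm_ratio))
  # identical replicates collapse the standard error to zero
  same <- condition_summary(list(tes[[1]], tes[[1]], tes[[1]]))
  expect_equal(same$se_fm, 0)
})

test_that("networks export to GraphML and edge-list TSV", {
  g <- build_te_network(te_tbl(matrix(0.5, 2, 2)),
                        structure(list(lower = 0, upper = 1),
                                  class = "edge_criterion"))
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_te_network(g, graphml = gml, tsv = tsv)
  expect_true(file.size(gml) > 0)
  e <- utils::read.delim(tsv)
  expect_equal(nrow(e), 4L)
  expect_named(e, c("m_slot", "f_slot", "te"))
})
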
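test_that("channels spiking in disjoint bins share no edge", {
  tr <- list(list(channel = 1, spike_times_s = 0.05),
             list(channel = 2, spike_times_s = 0.45))
  g <- build_coactivity_graph(tr, duration_s = 1)
  expect_equal(nrow(g$edges), 0L)
})

test_that("three channels in one bin form a triangle", {
  tr <- list(list(channel = 1, spike_times_s = 0.01),
             list(channel = 2, spike_times_s = 0.10),
             list(channel = 3, spike_times_s = 0.19))
  g <- build_coactivity_graph(tr, duration_s = 1)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(mean_degree_centrality(g), 2 * 3 / 3)
})

test_that("random rasters match the exhaustive pairwise-bin oracle", {
  for (s in 1:6) {
    trains <- lapply(1:6, function(ch) poisson_train(ch, 2, 10, s * 100 + ch))
    g <- build_coactivity_graph(trains, duration_s = 10)
    oracle <- coactivity_brute(trains, 10, 0.2)
    got <- g$edges[order(g$edges[, 1], g$edges[, 2]), , drop = FALSE]
    if (is.null(oracle)) {
      expect_equal(nrow(got), 0L)
    } else {
      dimnames(oracle) <- dimnames(got)
      expect_equal(got, oracle)
    }
  }
})

test_that("degrees agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  trains <- lapply(1:8, function(ch) poisson_train(ch, 1.5, 8, 7 * 10 + ch))
  g <- build_coactivity_graph(trains, duration_s = 8)
  ig <- igraph::graph_from_edgelist(apply(g$edges, 2, as.character),
                                    directed = FALSE)
  ig <- igraph::add_vertices(ig, sum(!as.character(g$nodes) %in%
                                       igraph::V(ig)$name))
  expect_equal(2 * nrow(g$edges) / length(g$nodes),
               sum(igraph::degree(ig)) / length(g$nodes))
  expect_equal(mean_degree_centrality(g, "normalized"),
               mean(igraph::degree(ig)) / (length(g$nodes) - 1))
})

test_that("both centrality variants follow the printed formula and bounds", {
  tr <- list(list(channel = 1, spike_times_s = 0.05),
             list(channel = 2, spike_times_s = 0.1))
  g <- build_coactivity_graph(tr, duration_s = 1)
  expect_equal(mean_degree_centrality(g, "paper_formula"), 1.0)
  expect_equal(mean_degree_centrality(g, "normalized"), 1.0)
  ## empty graph on 4 nodes
  tr4 <- lapply(1:4, function(ch) {
    list(channel = ch, spike_times_s = 0.2 * (ch - 1) + 0.01)
  })
  g4 <- build_coactivity_graph(tr4, duration_s = 0.8)
  expect_equal(mean_degree_centrality(g4), 0)
  expect_equal(mean_degree_centrality(g4, "normalized"), 0)
  ## bounds and handshake lemma on random rasters
  for (s in 1:4) {
    trains <- lapply(1:7, function(ch) poisson_train(ch, 3, 5, s * 1000 + ch))
    g <- build_coactivity_graph(trains, duration_s = 5)
    n <- length(g$nodes)
    deg <- table(factor(c(g$edges[, 1], g$edges[, 2]), levels = g$nodes))
    expect_equal(mean_degree_centrality(g), sum(deg) / n)
    expect_lte(mean_degree_centrality(g), n - 1)
    expect_lte(mean_degree_centrality(g, "normalized"), 1)
    expect_gte(mean_degree_centrality(g, "normalized"), 0)
  }
})

test_that("adding a co-active pair strictly increases both variants", {
  tr <- list(list(channel = 1, spike_times_s = 0.05),
             list(channel = 2, spike_times_s = 0.45),
             list(channel = 3, spike_times_s = 0.85))
  g0 <- build_coactivity_graph(tr, duration_s = 1.2)
  tr[[2]]$spike_times_s <- c(0.06, 0.45)   # now co-active with channel 1
  g1 <- build_coactivity_graph(tr, duration_s = 1.2)
  expect_gt(mean_degree_centrality(g1), mean_degree_centrality(g0))
  expect_gt(mean_degree_centrality(g1, "normalized"),
            mean_degree_centrality(g0, "normalized"))
})

test_that("bins partition [0, duration) half-open and edges deduplicate", {
  ## co-occurrence in many bins still yields one edge
  tr <- list(list(channel = 1, spike_times_s = seq(0.05, 4.95, 0.1)),
             list(channel = 2, spike_times_s = seq(0.06, 4.96, 0.1)))
  g <- build_coactivity_graph(tr, duration_s = 5)
  expect_equal(nrow(g$edges), 1L)
  ## a spike exactly at duration is excluded (half-open)
  tr2 <- list(list(channel = 1, spike_times_s = 1.0),
              list(channel = 2, spike_times_s = 0.99))
  g2 <- build_coactivity_graph(tr2, duration_s = 1)
  expect_equal(nrow(g2$edges), 0L)
  expect_error(build_coactivity_graph(tr2, duration_s = 0), "duration")
})
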
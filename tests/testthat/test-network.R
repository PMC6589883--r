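toy_matrix <- function(n_feat = 6, n_samp = 12, seed = 1) {
  set.seed(seed)
  m <- matrix(rlnorm(n_feat * n_samp), n_feat, n_samp,
              dimnames = list(paste0("t", seq_len(n_feat)),
                              paste0("s", seq_len(n_samp))))
  m
}

test_that("Spearman matrix handles monotone pairs, self-pairs and small n", {
  m <- toy_matrix()
  m[2, ] <- m[1, ]^2 + 1          # perfectly monotone with row 1
  sm <- spearman_matrix(m)
  expect_equal(sm$rho[1, 2], 1)
  expect_lt(sm$p[1, 2], 1e-10)
  expect_equal(diag(sm$rho), rep(1, 6), ignore_attr = TRUE)
  expect_true(all(is.na(diag(sm$p))))
  expect_true(all(abs(sm$rho) <= 1 + 1e-12))
  expect_error(spearman_matrix(toy_matrix(n_samp = 3)), ">= 4")
  m0 <- toy_matrix(); m0[3, ] <- 5  # constant feature dropped
  expect_warning(sm0 <- spearman_matrix(m0), "zero-variance")
  expect_equal(nrow(sm0$rho), 5)
})

test_that("t-approximate p-values sit within Monte-Carlo error of permutation p", {
  set.seed(99)
  for (i in 1:6) {
    x <- rnorm(9); y <- rnorm(9) + 0.3 * x
    sm <- spearman_matrix(rbind(a = x, b = y), p_method = "t")
    p_mc <- oracle_spearman_p(x, y, B = 4000, seed = i)
    expect_lt(abs(sm$p[1, 2] - p_mc),
              3 * sqrt(p_mc * (1 - p_mc) / 4000) + 0.02)
  }
})

test_that("exact p-values are used below 10 samples and match cor.test", {
  set.seed(7)
  x <- rnorm(9); y <- rnorm(9)
  sm <- spearman_matrix(rbind(a = x, b = y))   # auto -> exact
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  expect_equal(sm$p[1, 2], ref)
})

test_that("network construction applies the p < alpha rule edge by edge", {
  rho <- matrix(c(1, 0.8, -0.5, 0.8, 1, 0.1, -0.5, 0.1, 1), 3,
                dimnames = list(letters[1:3], letters[1:3]))
  p <- matrix(c(NA, 0.01, 0.02, 0.01, NA, 0.9, 0.02, 0.9, NA), 3,
              dimnames = dimnames(rho))
  net <- suppressMessages(build_network(rho, p))
  expect_equal(igraph::ecount(net), 2)
  el <- igraph::as_data_frame(net)
  expect_setequal(el$sign, c("positive", "negative"))
  # all p = 1 -> empty edge set, nodes retained
  p1 <- p; p1[] <- 1
  net1 <- suppressMessages(build_network(rho, p1))
  expect_equal(igraph::ecount(net1), 0)
  expect_equal(igraph::vcount(net1), 3)
  # edge count bound
  cm <- gen_community(sim_config(seed = 2))
  sm <- spearman_matrix(cm$table)
  netf <- suppressMessages(build_network(sm$rho, sm$p))
  n <- igraph::vcount(netf)
  expect_lte(igraph::ecount(netf), n * (n - 1) / 2)
})

test_that("keystone filter keeps the enriched positive-edge subgraph", {
  el <- data.frame(from = c("a", "a", "b", "c", "d"),
                   to   = c("b", "c", "c", "d", "e"),
                   rho = c(0.9, 0.8, 0.7, -0.6, 0.85),
                   p = rep(0.01, 5),
                   sign = c("positive", "positive", "positive",
                            "negative", "positive"))
  net <- igraph::graph_from_data_frame(el, directed = FALSE)
  treat <- c(a = 10, b = 8, c = 6, d = 1, e = 2)
  ctrl <- c(a = 5, b = 4, c = 3, d = 4, e = 5)   # d, e below control
  out <- keystone_filter(net, treat, ctrl)
  expect_setequal(igraph::V(out)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(out), 3)
  expect_true(all(igraph::E(out)$sign == "positive"))
  # only negative edges -> everything isolated -> empty after default drop
  neg <- igraph::graph_from_data_frame(
    data.frame(from = "a", to = "b", sign = "negative"), directed = FALSE)
  out2 <- keystone_filter(neg, c(a = 2, b = 2), c(a = 1, b = 1))
  expect_equal(igraph::vcount(out2), 0)
  out3 <- keystone_filter(neg, c(a = 2, b = 2), c(a = 1, b = 1),
                          drop_isolated = FALSE)
  expect_equal(igraph::vcount(out3), 2)
  expect_equal(igraph::ecount(out3), 0)
  # filter output is always a subgraph of the positive-edge subgraph
  expect_true(all(edge_keys(igraph::as_data_frame(out)$from,
                            igraph::as_data_frame(out)$to) %in%
                    edge_keys(el$from[el$sign == "positive"],
                              el$to[el$sign == "positive"])))
  # missing control -> node dropped with warning
  expect_warning(out4 <- keystone_filter(net, treat, ctrl[-5]), "control")
  expect_false("e" %in% igraph::V(out4)$name)
})

test_that("topology matches closed forms on standard graphs", {
  k4 <- igraph::make_full_graph(4)
  top <- topology(k4)
  expect_equal(top$clustering, 1)
  expect_equal(top$density, 1)
  expect_equal(top$avg_neighbors, 3)
  expect_equal(top$shortest_path_pairs, 12)
  expect_equal(top$char_path_length, 1)
  p3 <- igraph::make_graph(~ a - b, b - c)
  top3 <- topology(p3)
  expect_equal(top3$clustering, 0)
  expect_equal(top3$shortest_path_pairs, 6)
  expect_equal(top3$char_path_length, (1 + 1 + 2 + 2 + 1 + 1) / 6)
  star <- igraph::make_star(5, mode = "undirected")
  expect_equal(topology(star)$clustering, 0)   # center has no closed triads
  empty <- igraph::make_empty_graph(4, directed = FALSE)
  expect_equal(topology(empty)$density, 0)
  expect_equal(topology(igraph::make_empty_graph(0))$n_nodes, 0)
})

test_that("network exports round-trip through edge list and GraphML", {
  cm <- gen_community(sim_config(seed = 4))
  sm <- spearman_matrix(cm$table)
  net <- suppressMessages(build_network(sm$rho, sm$p, p_adjust = "bonferroni"))
  f1 <- tempfile(fileext = ".tsv")
  export_network(net, f1, "edgelist")
  back <- read_network(f1, "edgelist")
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
  el0 <- igraph::as_data_frame(net); el1 <- igraph::as_data_frame(back)
  expect_setequal(edge_keys(el0$from, el0$to), edge_keys(el1$from, el1$to))
  ord0 <- order(edge_keys(el0$from, el0$to))
  ord1 <- order(edge_keys(el1$from, el1$to))
  expect_equal(el1$rho[ord1], el0$rho[ord0])
  expect_equal(el1$p[ord1], el0$p[ord0])
  expect_equal(el1$sign[ord1], el0$sign[ord0])
  # byte-stable under fixed ordering
  f2 <- tempfile(fileext = ".tsv")
  export_network(net, f2, "edgelist")
  expect_identical(readLines(f1), readLines(f2))
  # GraphML round trip
  f3 <- tempfile(fileext = ".graphml")
  export_network(net, f3, "graphml")
  back3 <- read_network(f3, "graphml")
  expect_setequal(igraph::V(back3)$name, igraph::V(net)$name)
  el3 <- igraph::as_data_frame(back3)
  expect_setequal(edge_keys(el3$from, el3$to), edge_keys(el0$from, el0$to))
  # SIF and empty networks produce valid files
  f4 <- tempfile(fileext = ".sif")
  export_network(net, f4, "sif")
  n_isolated <- sum(igraph::degree(net) == 0)
  expect_equal(length(readLines(f4)), igraph::ecount(net) + n_isolated)
  f5 <- tempfile(fileext = ".tsv")
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  igraph::V(empty)$name <- character(0)
  export_network(empty, f5, "edgelist")
  expect_equal(readLines(f5), "source\ttarget\trho\tp\tsign")
  expect_error(export_network(net, tempfile(), "gml"), "arg")
})
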
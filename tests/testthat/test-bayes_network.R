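chain_edges <- function(nodes, signs = rep("+", length(nodes) - 1L)) {
  data.frame(source = nodes[-length(nodes)], target = nodes[-1L],
             sign = signs, stringsAsFactors = FALSE)
}

test_that("network construction validates the DAG and finds a topological order", {
  net <- build_network(chain_edges(c("A", "B", "C")), sink = "C")
  expect_equal(net$topo_order, c("A", "B", "C"))
  expect_equal(net$sources, "A")

  expect_error(build_network(data.frame(source = c("A", "B"), target = c("B", "A"),
                                        sign = "+"), sink = "B"),
               "cycle.*A.*B")
  expect_error(build_network(data.frame(source = "A", target = "B", sign = "+"),
                             sink = "C", nodes = c("A", "C")),
               "unknown node")
  expect_error(build_network(data.frame(source = "A", target = "B", sign = "x"),
                             sink = "B"), "sign")
  expect_warning(build_network(data.frame(source = "A", target = "B", sign = "+"),
                               sink = "C", nodes = c("A", "B", "C")),
                 "unreachable")
})

test_that("the packaged example network is a valid DAG containing the reported chain", {
  net <- build_network(example_network_edges(), sink = "Cell proliferation")
  chain <- c("S100A11", "RAGE", "P38", "MAPK", "Microtubule-associated protein",
             "Spindle protein", "Centromere protein", "Cell proliferation")
  expect_true(all(chain %in% net$nodes))
  for (i in seq_len(length(chain) - 1L)) {
    expect_true(any(net$edges$source == chain[i] & net$edges$target == chain[i + 1L]))
  }
  expect_setequal(net$sources,
                  c("S100A11", "RASEF", "GCN4", "FKBP", "CENP-B", "S100A2"))
})

test_that("similarity scores become priors, clamped into the unit interval with a log", {
  net <- build_network(chain_edges(c("S100A11", "X", "SINK")), sink = "SINK")
  n1 <- set_priors(net, c(S100A11 = 0.8102))
  expect_equal(n1$priors[["S100A11"]], 0.8102)
  expect_length(n1$clamp_log, 0L)
  expect_message(n2 <- set_priors(net, c(S100A11 = 1.3)), "clamped to 1")
  expect_equal(n2$priors[["S100A11"]], 1)
  expect_message(n3 <- set_priors(net, c(S100A11 = -0.2)), "clamped to 0")
  expect_equal(n3$priors[["S100A11"]], 0)
  expect_error(set_priors(net, c(OTHER = 0.5)), "S100A11")
})

test_that("union propagation applies the sign-gated noisy-OR rule", {
  # single activator chain passes the prior through
  net <- set_priors(build_network(chain_edges(c("A", "B", "C")), sink = "C"),
                    c(A = 0.8))
  expect_equal(propagate(net)[["C"]], 0.8)

  # two activators combine as a union
  e2 <- data.frame(source = c("A", "B"), target = "C", sign = "+")
  n2 <- set_priors(build_network(e2, sink = "C"), c(A = 0.5, B = 0.5))
  expect_equal(propagate(n2)[["C"]], 0.75)

  # an inhibitor gates the activator
  e3 <- data.frame(source = c("A", "B"), target = "C", sign = c("+", "-"))
  n3 <- set_priors(build_network(e3, sink = "C"), c(A = 0.8, B = 0.5))
  expect_equal(propagate(n3)[["C"]], 0.4)

  expect_error(propagate(build_network(e2, sink = "C")), "priors are unset")
})

test_that("literal propagation reproduces the printed conditional sum, clamped at one", {
  e2 <- data.frame(source = c("A", "B"), target = "C", sign = "+")
  n2 <- set_priors(build_network(e2, sink = "C"), c(A = 0.3, B = 0.4))
  # gate * (pA + pB + pA*pB) = 0.3 + 0.4 + 0.12
  expect_equal(propagate(n2, mode = "literal")[["C"]], 0.82)
  n2b <- set_priors(build_network(e2, sink = "C"), c(A = 0.5, B = 0.9))
  expect_message(pl <- propagate(n2b, mode = "literal"), "clamped")
  expect_equal(pl[["C"]], 1)
  # with a single activator the two modes coincide
  e3 <- data.frame(source = c("A", "B"), target = "C", sign = c("+", "-"))
  n3 <- set_priors(build_network(e3, sink = "C"), c(A = 0.8, B = 0.5))
  expect_equal(propagate(n3, mode = "literal")[["C"]], 0.4)
})

test_that("union propagation equals exact Bernoulli enumeration on source trees", {
  for (seed in 1:25) {
    k <- sample(2:6, 1)
    tr <- random_source_tree(k, seed)
    net <- set_priors(build_network(tr$edges, sink = tr$sink), tr$priors)
    got <- propagate(net, mode = "union")
    want <- oracle_enumerate(tr$edges, tr$sources, tr$priors, net$topo_order)
    expect_equal(got[names(want)], want, tolerance = 1e-12)
    expect_true(all(got >= -1e-15 & got <= 1 + 1e-15))
  }
})

test_that("pathway enumeration is exhaustive and deterministic", {
  net <- build_network(chain_edges(c("A", "B", "C")), sink = "C")
  expect_equal(enumerate_paths(net), list(c("A", "B", "C")))

  diamond <- data.frame(source = c("A", "A", "B", "C"),
                        target = c("B", "C", "D", "D"), sign = "+")
  nd <- build_network(diamond, sink = "D")
  expect_equal(enumerate_paths(nd), list(c("A", "B", "D"), c("A", "C", "D")))

  for (seed in 1:10) {
    mn <- make_network(network_spec(n_sources = 3L, depth = 3L, cross_p = 0.5,
                                    seed = seed))
    got <- enumerate_paths(mn$network)
    want <- oracle_paths(mn$network$edges, mn$network$sources, "SINK")
    want <- want[order(vapply(want, paste, character(1), collapse = "\r"))]
    expect_equal(got, want)
  }
})

test_that("pathway probability carries the prior with complement flips at inhibiting edges", {
  net <- set_priors(build_network(chain_edges(c("A", "B", "C", "D")), sink = "D"),
                    c(A = 0.77))
  expect_equal(path_probability(net, c("A", "B", "C", "D")), 0.77)

  neg <- set_priors(build_network(chain_edges(c("A", "B", "C"),
                                              signs = c("-", "+")), sink = "C"),
                    c(A = 0.8))
  expect_equal(path_probability(neg, c("A", "B", "C")), 0.2, tolerance = 1e-12)
  expect_error(path_probability(neg, c("A", "C")), "no edge")
  expect_error(path_probability(neg, c("B", "C")), "source")

  for (seed in 1:5) {
    mn <- make_network(network_spec(seed = seed))
    for (p in enumerate_paths(mn$network)) {
      pp <- path_probability(mn$network, p)
      expect_true(pp >= 0 && pp <= 1)
    }
  }
})

test_that("pathway ranking orders by probability and matches the enumerated path set", {
  two <- rbind(chain_edges(c("A", "B", "SINK")), chain_edges(c("X", "Y", "SINK")))
  net <- set_priors(build_network(two, sink = "SINK"), c(A = 0.9, X = 0.4))
  rk <- rank_pathways(net)
  expect_equal(rk$pathway[1], "A -> B -> SINK")
  expect_equal(rk$probability, c(0.9, 0.4))

  # invariant under edge-order permutation
  set.seed(12)
  net2 <- set_priors(build_network(two[sample(nrow(two)), ], sink = "SINK"),
                     c(A = 0.9, X = 0.4))
  expect_equal(rank_pathways(net2)$pathway, rk$pathway)

  # ranking is a permutation of the enumerated paths
  mn <- make_network(network_spec(seed = 31))
  rk3 <- rank_pathways(mn$network)
  labs <- vapply(enumerate_paths(mn$network), paste, character(1), collapse = " -> ")
  expect_setequal(rk3$pathway, labs)

  isolated <- suppressWarnings(
    build_network(data.frame(source = "A", target = "B", sign = "+"),
                  sink = "C", nodes = c("A", "B", "C")))
  expect_warning(rk4 <- rank_pathways(set_priors(isolated, c(A = 0.5))), "no source-to-sink")
  expect_equal(nrow(rk4), 0L)
})

test_that("posterior attribution distributes a node's activation over the sources", {
  net <- set_priors(build_network(chain_edges(c("A", "B", "C")), sink = "C"),
                    c(A = 0.6))
  expect_equal(posterior_attribution(net, "C"), c(A = 1))

  vee <- data.frame(source = c("A", "B"), target = "M", sign = "+")
  sym <- set_priors(build_network(vee, sink = "M"), c(A = 0.7, B = 0.7))
  expect_equal(posterior_attribution(sym, "M"), c(A = 0.5, B = 0.5))

  asym <- set_priors(build_network(vee, sink = "M"), c(A = 0.8, B = 0.4))
  expect_equal(posterior_attribution(asym, "M"),
               c(A = 0.8 / 1.2, B = 0.4 / 1.2), tolerance = 1e-12)
  expect_equal(sum(posterior_attribution(asym, "M")), 1)
})

test_that("union propagation is monotone in source priors", {
  for (seed in 1:5) {
    mn <- make_network(network_spec(seed = seed, cross_p = 0.5))
    net <- mn$network
    base <- propagate(net)[["SINK"]]
    # raising the planted (activating-chain) source can only help the sink
    up <- net; up$priors[["SRC1"]] <- min(1, up$priors[["SRC1"]] + 0.05)
    expect_gte(propagate(up)[["SINK"]], base - 1e-12)
  }
})
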
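test_that("layer edge lists parse, canonicalize and validate", {
  f <- withr::local_tempfile(fileext = ".tsv")

  writeLines("A\tB", f)
  lay <- read_layer_edges(f)
  expect_equal(nrow(lay$edges), 1L)
  expect_equal(lay$edges$weight, 1.0)

  # Symmetric duplicates collapse after canonicalization (a <= b lexically).
  writeLines(c("B\tA", "A\tB"), f)
  lay <- suppressMessages(read_layer_edges(f))
  expect_equal(nrow(lay$edges), 1L)
  expect_equal(lay$edges$from, "A")
  expect_equal(lay$edges$to, "B")

  writeLines("g1\tg2\t0.2", f)
  lay <- read_layer_edges(f, weighted = TRUE)
  expect_equal(lay$edges$weight, 0.2)

  writeLines("g1\tg2\t-0.2", f)
  expect_error(read_layer_edges(f, weighted = TRUE), "positive")
  writeLines("g1\tg2\t−0.2", f)  # unicode minus
  expect_error(read_layer_edges(f, weighted = TRUE), "positive")

  # Malformed line reported with its line number; comments ignored.
  writeLines(c("# comment", "a\tb", "oops"), f)
  expect_error(read_layer_edges(f), "line 3")

  # Duplicate weighted records keep the maximum weight.
  writeLines(c("a\tb\t0.3", "b\ta\t0.8"), f)
  lay <- suppressMessages(read_layer_edges(f, weighted = TRUE))
  expect_equal(lay$edges$weight, 0.8)

  # Self-loops are dropped with a warning.
  expect_warning(layer("l", data.frame(from = c("a", "a"), to = c("a", "b"))),
                 "self-loop")
})

test_that("read-write-read round trip preserves the edge multiset", {
  net <- make_toy_network(3)
  d <- withr::local_tempdir()
  for (mp in net$multiplexes) {
    for (lay in mp$layers) {
      p <- file.path(d, "roundtrip.tsv")
      write_layer_edges(lay, p)
      back <- read_layer_edges(p, directed = lay$directed,
                               weighted = lay$weighted, name = lay$name)
      expect_equal(back$edges[order(back$edges$from, back$edges$to), ],
                   lay$edges[order(lay$edges$from, lay$edges$to), ],
                   ignore_attr = TRUE)
    }
  }
})

test_that("networks assemble from a manifest and validate endpoints", {
  # Table-2-shaped toy written to disk and reassembled.
  sim <- simulate_multilayer(network_sim_spec(rng_seed = 2))
  d <- withr::local_tempdir()
  man <- write_network(sim$network, d, rwr = list(restart_r = 0.7))
  net <- assemble_network(man)
  expect_s3_class(net, "cnm_network")
  expect_length(net$multiplexes, 5L)
  expect_length(net$bipartites, 8L)
  expect_equal(attr(net, "rwr")$restart_r, 0.7)
  expect_equal(summarize_network(net), summarize_network(sim$network))

  # Single multiplex, no bipartites.
  f <- file.path(d, "solo.tsv")
  writeLines("a\tb", f)
  solo <- assemble_network(list(multiplexes = list(
    solo = list(layers = list(l1 = list(path = "solo.tsv"))))),
    base_dir = d)
  expect_length(solo$multiplexes, 1L)
  expect_length(solo$bipartites, 0L)

  # Bipartite endpoint absent from all layers becomes an isolated node.
  lay <- layer("l1", data.frame(from = "a", to = "b"))
  bp <- bipartite("x", "m1", "m2", data.frame(from = "a", to = "z"))
  lay2 <- layer("l2", data.frame(from = "y", to = "w"))
  expect_warning(
    net2 <- multilayer_network(list(multiplex("m1", list(lay)),
                                    multiplex("m2", list(lay2))), list(bp)),
    "isolated")
  expect_true("z" %in% net2$multiplexes$m2$nodes)

  # Unknown endpoint multiplex is a config error.
  expect_error(multilayer_network(list(multiplex("m1", list(lay))),
                                  list(bp)), "unknown multiplex")
})

test_that("density follows m / (n(n-1)/2) and summary rows are complete", {
  # Complete undirected graph on 4 nodes.
  k4 <- layer("k4", expand.grid(from = letters[1:4], to = letters[1:4])
              [c(2, 3, 4, 7, 8, 12), ])
  net <- multilayer_network(list(multiplex("m", list(k4))))
  s <- summarize_network(net)
  expect_equal(s$n_nodes, 4L)
  expect_equal(s$n_edges, 6L)
  expect_equal(s$density, 1.0)

  # Density in [0, 1] for any simple undirected layer; 1 iff complete.
  for (seed in 1:5) {
    net <- make_toy_network(seed)
    s <- summarize_network(net)
    lay_rows <- !is.na(s$layer) & !s$directed
    expect_true(all(s$density[lay_rows] >= 0 & s$density[lay_rows] <= 1))
  }
})

test_that("node removal deletes incident edges and nothing else", {
  net <- make_toy_network(4)

  # Removing nothing is the identity.
  expect_identical(remove_nodes(net, data.frame(multiplex = character(),
                                                node = character())), net)

  # Removing a node of degree d from a layer deletes exactly d edges there.
  mx <- names(net$multiplexes)[1]
  lay <- net$multiplexes[[mx]]$layers[[1]]
  victim <- lay$edges$from[1]
  d_lay <- sum(lay$edges$from == victim | lay$edges$to == victim)
  pruned <- remove_nodes(net, data.frame(multiplex = mx, node = victim))
  expect_equal(nrow(pruned$multiplexes[[mx]]$layers[[1]]$edges),
               nrow(lay$edges) - d_lay)
  expect_false(victim %in% pruned$multiplexes[[mx]]$nodes)

  # Node counts drop by exactly the removed set per multiplex.
  expect_equal(length(pruned$multiplexes[[mx]]$nodes),
               length(net$multiplexes[[mx]]$nodes) - 1L)

  # Unknown target warns but does not error (idempotent removal).
  expect_warning(remove_nodes(net, data.frame(multiplex = mx, node = "nope")),
                 "unknown target")

  # A bipartite-only node: removal empties its bipartite edges, layers
  # untouched.
  lay1 <- layer("l", data.frame(from = "a", to = "b"))
  lay2 <- layer("l2", data.frame(from = "u", to = "v"))
  bp <- suppressWarnings(bipartite("bp", "m1", "m2",
                                   data.frame(from = c("a", "iso"),
                                              to = c("u", "v"))))
  net2 <- suppressWarnings(multilayer_network(
    list(multiplex("m1", list(lay1)), multiplex("m2", list(lay2))),
    list(bp)))
  pruned2 <- remove_nodes(net2, data.frame(multiplex = "m1", node = "iso"))
  expect_equal(nrow(pruned2$bipartites$bp$edges), 1L)
  expect_equal(pruned2$multiplexes$m1$layers$l$edges,
               net2$multiplexes$m1$layers$l$edges)
})

test_that("dropping layers keeps node universes and guards emptiness", {
  gl1 <- layer("ppi", data.frame(from = "a", to = "b"))
  gl2 <- layer("coexpr", data.frame(from = "b", to = "c"))
  ml <- layer("pathways", data.frame(from = "u", to = "v"))
  net <- multilayer_network(list(multiplex("genes", list(gl1, gl2)),
                                 multiplex("metabolites", list(ml))))
  red <- drop_layers(net, "coexpr")
  expect_equal(red$multiplexes$genes$nodes, c("a", "b", "c"))
  expect_length(red$multiplexes$genes$layers, 1L)
  expect_error(drop_layers(net, c("ppi", "coexpr")), "no layers")
  expect_error(drop_layers(net, "missing_layer"), "unknown layer")
})
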
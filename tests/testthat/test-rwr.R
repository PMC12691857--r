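test_that("the supra transition reduces to a column-normalized walk", {
  # Single multiplex, single unweighted undirected layer.
  edges <- data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"))
  net <- multilayer_network(list(multiplex("m", list(layer("l", edges)))))
  tr <- build_transition(net)
  ids <- tr$nodes$node
  A <- matrix(0, 3, 3, dimnames = list(ids, ids))
  A[cbind(edges$from, edges$to)] <- 1
  A <- A + t(A)
  P <- sweep(A, 2, colSums(A), "/")
  expect_equal(as.matrix(tr$M), P, ignore_attr = TRUE)
  expect_equal(tr$dangling, rep(0, 3))

  # A node with no edges and no bipartite neighbours is fully dangling.
  net2 <- multilayer_network(list(multiplex("m", list(layer("l", edges)),
                                            nodes = "zz")))
  tr2 <- build_transition(net2)
  iso <- which(tr2$nodes$node == "zz")
  expect_equal(tr2$dangling[iso], 1)
  expect_equal(sum(tr2$M[, iso]), 0)
})

test_that("a 3-node toy with one bipartite edge matches hand enumeration", {
  # Multiplex A: a-b edge; multiplex B: single node u; bipartite a-u.
  mA <- multiplex("A", list(layer("l1", data.frame(from = "a", to = "b"))))
  mB <- multiplex("B", list(layer("l2", NULL)), nodes = "u")
  bp <- bipartite("ab", "A", "B", data.frame(from = "a", to = "u"))
  net <- multilayer_network(list(mA, mB), list(bp))
  tr <- build_transition(net)
  key <- paste(tr$nodes$multiplex, tr$nodes$node)
  ia <- which(key == "A a"); ib <- which(key == "A b"); iu <- which(key == "B u")
  # From a: stay (1/2) -> b with prob 1; jump (1/2) -> u.
  expect_equal(tr$M[ib, ia], 0.5)
  expect_equal(tr$M[iu, ia], 0.5)
  # From b: no bipartite reach, stays, moves to a.
  expect_equal(tr$M[ia, ib], 1)
  # From u: jump to a with 1/2; stay-half dangles (u has no layer edges).
  expect_equal(tr$M[ia, iu], 0.5)
  expect_equal(tr$dangling[iu], 0.5)
})

test_that("RWR scores conserve probability and obey limits", {
  # r -> 1: scores collapse to the restart vector.
  edges <- data.frame(from = c("a", "b"), to = c("b", "c"))
  net <- multilayer_network(list(multiplex("m", list(layer("l", edges)))))
  s <- rwr_scores(net, data.frame(multiplex = "m", node = "a"),
                  rwr_config(restart_r = 1 - 1e-12))
  expect_equal(s$nodes$score[s$nodes$node == "a"], 1, tolerance = 1e-9)

  # Uniform seed over an 8-cycle: uniform scores 1/8 by symmetry.
  ids <- sprintf("n%d", 1:8)
  cyc <- data.frame(from = ids, to = ids[c(2:8, 1)])
  net8 <- multilayer_network(list(multiplex("m", list(layer("l", cyc)))))
  s8 <- rwr_scores(net8, data.frame(multiplex = "m", node = ids))
  expect_equal(s8$nodes$score, rep(1 / 8, 8), tolerance = 1e-9)

  # Two-node chain closed form: seed a, r = 0.7 gives (10/13, 3/13).
  net2 <- multilayer_network(list(multiplex("m", list(
    layer("l", data.frame(from = "a", to = "b"))))))
  s2 <- rwr_scores(net2, data.frame(multiplex = "m", node = "a"),
                   rwr_config(tolerance = 1e-14))
  expect_equal(s2$nodes$score[s2$nodes$node == "a"], 10 / 13,
               tolerance = 1e-10)
  expect_equal(s2$nodes$score[s2$nodes$node == "b"], 3 / 13,
               tolerance = 1e-10)

  # Conservation holds with dangling states (directed chain end).
  chain <- data.frame(from = c("a", "b"), to = c("b", "c"))
  netd <- multilayer_network(list(multiplex("m", list(
    layer("l", chain, directed = TRUE)))))
  sd_ <- rwr_scores(netd, data.frame(multiplex = "m", node = "a"))
  expect_equal(sum(sd_$nodes$score), 1, tolerance = 1e-8)

  # Single-node network: all mass on that node.
  net1 <- multilayer_network(list(multiplex("m", list(layer("l", NULL)),
                                            nodes = "only")))
  e1 <- exact_scores(net1, data.frame(multiplex = "m", node = "only"))
  expect_equal(e1$nodes$score, 1)
})

test_that("iterative and exact solvers agree on heterogeneous toys", {
  worst <- 0
  for (k in 1:10) {
    net <- make_toy_network(k)
    tr <- build_transition(net)
    mx <- names(net$multiplexes)[length(net$multiplexes)]
    seeds <- data.frame(multiplex = mx,
                        node = net$multiplexes[[mx]]$nodes[1:2])
    s1 <- rwr_scores(net, seeds, transition = tr)
    s2 <- exact_scores(net, seeds, transition = tr)
    expect_equal(sum(s1$nodes$score), 1, tolerance = 1e-8)
    worst <- max(worst, max(abs(s1$nodes$score - s2$nodes$score)))
  }
  expect_lt(worst, 1e-8)
})

test_that("seed placement and tau renormalize over seeded multiplexes", {
  net <- make_hand_network()
  # Joint gene + phenotype seeds: no restart mass on metabolites.
  seeds <- rbind(node_ref("genes", "g1"), node_ref("phenotypes", "p1"))
  tr <- build_transition(net)
  v <- cnmnet:::restart_vector(tr, seeds, rwr_config())
  v_node <- as.numeric(tr$agg %*% v)
  mass <- tapply(v_node, tr$nodes$multiplex, sum)
  # Restart mass renormalizes over the seeded multiplexes only.
  expect_equal(as.numeric(mass[c("genes", "metabolites", "phenotypes")]),
               c(0.5, 0, 0.5))
  expect_equal(sum(v), 1)
  expect_error(rwr_scores(net, data.frame(multiplex = "genes",
                                          node = "missing")),
               "missing")

  # Seed locality: each seed scores above its multiplex median.
  s <- rwr_scores(net, seeds)
  g <- s$nodes[s$nodes$multiplex == "genes", ]
  expect_gt(g$score[g$node == "g1"], median(g$score))

  # Determinism: identical runs give identical results.
  s2 <- rwr_scores(net, seeds)
  expect_identical(s$nodes, s2$nodes)
})

test_that("ranking is deterministic with lexical tie-breaks", {
  fake <- structure(list(
    supra = NULL,
    nodes = data.frame(multiplex = "m", node = c("C", "B", "A"),
                       score = c(0.2, 0.3, 0.3))),
    class = "cnm_scores")
  top <- rank_top(fake, "m", 2)
  expect_equal(top$node, c("A", "B"))
  expect_equal(top$rank, 1:2)

  top2 <- rank_top(fake, "m", 2, exclude = "A")
  expect_equal(top2$node, c("B", "C"))

  expect_warning(all3 <- rank_top(fake, "m", 20), "returning all")
  expect_equal(nrow(all3), 3L)

  expect_error(rank_top(fake, "nope", 2), "not found")
})
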
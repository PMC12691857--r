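# Shared fixtures built in code.

# Random multiplex-heterogeneous toy network (2-3 multiplexes, 1-3 layers
# each, mixed directed/undirected and weighted/unweighted, small enough for
# the dense oracle).
make_toy_network <- function(seed) {
  set.seed(seed)
  n_mpx <- sample(2:3, 1L)
  mpx <- list()
  for (i in seq_len(n_mpx)) {
    lays <- list()
    for (j in seq_len(sample(1:3, 1L))) {
      lays[[paste0("L", j)]] <- list(density = stats::runif(1, 0.1, 0.3),
                                     weighted = stats::runif(1) < 0.5,
                                     directed = stats::runif(1) < 0.3)
    }
    mpx[[paste0("mx", i)]] <- list(n_nodes = sample(8:20, 1L),
                                   prefix = paste0("x", i, "_"),
                                   layers = lays)
  }
  bps <- list()
  for (i in seq_len(n_mpx - 1L)) {
    bps[[paste0("b", i)]] <- list(source = paste0("mx", i),
                                  target = paste0("mx", i + 1L),
                                  density = stats::runif(1, 0.08, 0.2),
                                  directed = stats::runif(1) < 0.3,
                                  weighted = stats::runif(1) < 0.5)
  }
  simulate_multilayer(network_sim_spec(multiplexes = mpx, bipartites = bps,
                                       hubs = list(),
                                       rng_seed = seed))$network
}

# Tiny hand-built heterogeneous network: gene g1 and phenotype p1 both link
# to metabolite mA through bipartites; other metabolites hang off mA.
make_hand_network <- function() {
  genes <- multiplex("genes", list(
    layer("gl", data.frame(from = c("g1", "g2"), to = c("g2", "g3")))))
  mets <- multiplex("metabolites", list(
    layer("ml", data.frame(from = c("mA", "mA"), to = c("mB", "mC")))))
  phen <- multiplex("phenotypes", list(
    layer("pl", data.frame(from = "p1", to = "p2"), directed = TRUE)))
  bps <- list(
    bipartite("gm", "genes", "metabolites",
              data.frame(from = "g1", to = "mA")),
    bipartite("pm", "phenotypes", "metabolites",
              data.frame(from = "p1", to = "mA")),
    bipartite("gp", "genes", "phenotypes",
              data.frame(from = "g3", to = "p2")))
  multilayer_network(list(genes, mets, phen), bps)
}

# Expression fixture at the planted-recovery study conditions.
sim_modules <- function(seed, n_background = 0L) {
  suppressWarnings(simulate_expression_with_traits(
    expression_sim_spec(rng_seed = seed,
                        n_background_features = n_background)))
}

# Filter + normalize shortcut.
norm_counts <- function(counts) {
  size_factor_normalize(filter_features(counts))
}

# Brute-force oracles, written independently of the implementation paths.
brute_soft_adjacency <- function(expr, power) {
  n <- nrow(expr)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a[i, j] <- if (i == j) 1 else
        abs(stats::cor(expr[i, ], expr[j, ]))^power
    }
  }
  a
}

brute_tom <- function(adj) {
  n <- nrow(adj)
  a <- adj
  diag(a) <- 0
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) shared <- shared + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      tom[i, j] <- (shared + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  tom
}

# Independent dense personalized-PageRank solve on one undirected weighted
# graph (the single-multiplex single-layer reduction target).
dense_ppr <- function(edges, ids, seed_ids, r) {
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[cbind(edges$from, edges$to)] <- edges$weight
  A <- A + t(A)
  P <- sweep(A, 2, colSums(A), "/")
  v <- as.numeric(ids %in% seed_ids) / length(seed_ids)
  solve(diag(n) - (1 - r) * P, r * v)
}
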
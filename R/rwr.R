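# Random walk with restart over a multiplex-heterogeneous network.
#
# The walker lives on supra-states (multiplex, layer, node). From state
# (k, alpha, i) one step factorizes as:
#   1. choose a multiplex: stay in k or jump to a multiplex l where node i
#      has at least one bipartite neighbour, uniformly over
#      {k} union {reachable l} (mass of unreachable jumps stays in k);
#   2. staying: pick a layer beta of k uniformly (including alpha), then
#      follow an out-edge of i in beta with probability proportional to
#      edge weight;
#   3. jumping to l: follow a bipartite edge to a neighbour j proportional
#      to bipartite weight, landing in a uniformly chosen layer of l;
#   4. mass that lands in a layer where i has no out-edges is dangling and
#      is redirected to the restart vector by the solvers.
# Directed layers and bipartites are walked only in their stated direction.

#' Random-walk-with-restart configuration
#'
#' @param restart_r global restart probability in (0, 1); at each step the
#'   walker restarts from the seed set with this probability.
#' @param tau optional named vector of per-multiplex restart weights summing
#'   to 1. Default `NULL`: uniform over the multiplexes that contain at
#'   least one seed (seedless multiplexes get no restart mass and tau is
#'   renormalized over the seeded ones).
#' @param lambda optional row-stochastic inter-multiplex jump matrix with
#'   rows/columns named by multiplex. Default `NULL`: uniform over the
#'   current multiplex and the multiplexes reachable from the walker's node
#'   through at least one bipartite edge. With a custom `lambda`, mass
#'   assigned to unreachable multiplexes is reallocated to staying.
#' @param tolerance L1 convergence tolerance of the iterative solver.
#' @param max_iterations iteration cap of the iterative solver.
#' @return A list of class `cnm_rwr_config`.
#' @export
rwr_config <- function(restart_r = 0.7, tau = NULL, lambda = NULL,
                       tolerance = 1e-10, max_iterations = 1000L) {
  stopifnot(is.numeric(restart_r), length(restart_r) == 1L,
            restart_r > 0, restart_r < 1)
  if (!is.null(tau)) {
    stopifnot(is.numeric(tau), !is.null(names(tau)), all(tau >= 0))
    if (abs(sum(tau) - 1) > 1e-8) stopf("tau must sum to 1")
  }
  if (!is.null(lambda)) {
    lambda <- as.matrix(lambda)
    if (is.null(rownames(lambda)) || is.null(colnames(lambda)) ||
        any(abs(rowSums(lambda) - 1) > 1e-8) || any(lambda < 0)) {
      stopf("lambda must be a named row-stochastic matrix")
    }
  }
  structure(list(restart_r = restart_r, tau = tau, lambda = lambda,
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "cnm_rwr_config")
}

#' Build the supra transition operator of a multilayer network
#'
#' Constructs the sparse column-stochastic operator over all
#' (multiplex, layer, node) states together with a per-column dangling
#' mass. Columns of the same (multiplex, node) are identical across layers
#' because the layer jump is uniform and independent of the current layer.
#'
#' @param net a `cnm_network`.
#' @param config a [rwr_config()].
#' @return A list of class `cnm_transition` with elements `M` (sparse
#'   matrix, columns sum to at most 1), `dangling` (per-column unassigned
#'   mass), `states` (state table), `nodes` (per-node table aligned with the
#'   aggregation operator `agg`), and indexing metadata.
#' @export
build_transition <- function(net, config = rwr_config()) {
  stopifnot(inherits(net, "cnm_network"))
  mx_names <- names(net$multiplexes)
  info <- list()
  offset <- 0L
  for (mx in mx_names) {
    mp <- net$multiplexes[[mx]]
    info[[mx]] <- list(nodes = mp$nodes, n = length(mp$nodes),
                       L = length(mp$layers), offset = offset,
                       layer_names = names(mp$layers))
    offset <- offset + length(mp$nodes) * length(mp$layers)
  }
  n_states <- offset

  # Per-layer out-adjacency, indexed by source-node position.
  layer_adj <- list()
  for (mx in mx_names) {
    mp <- net$multiplexes[[mx]]
    nodes <- info[[mx]]$nodes
    layer_adj[[mx]] <- lapply(mp$layers, function(lay) {
      e <- lay$edges
      if (!lay$directed && nrow(e)) {
        e <- data.frame(from = c(e$from, e$to), to = c(e$to, e$from),
                        weight = c(e$weight, e$weight))
      }
      src <- factor(e$from, levels = nodes)
      list(to = split(match(e$to, nodes), src),
           w = split(e$weight, src))
    })
  }

  # Per ordered multiplex pair, combined bipartite out-adjacency.
  pair_adj <- list()
  add_pair <- function(k, l, from, to, w) {
    key <- paste(k, l, sep = "\r")
    cur <- pair_adj[[key]] %||% data.frame(from = character(),
                                           to = character(),
                                           weight = numeric())
    pair_adj[[key]] <<- rbind(cur, data.frame(from = from, to = to, weight = w))
  }
  for (bp in net$bipartites) {
    if (nrow(bp$edges) == 0L) next
    add_pair(bp$source_multiplex, bp$target_multiplex,
             bp$edges$from, bp$edges$to, bp$edges$weight)
    if (!bp$directed) {
      add_pair(bp$target_multiplex, bp$source_multiplex,
               bp$edges$to, bp$edges$from, bp$edges$weight)
    }
  }
  # Index pair adjacency by source-node position.
  pair_idx <- list()
  for (key in names(pair_adj)) {
    kl <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    e <- pair_adj[[key]]
    src <- factor(e$from, levels = info[[kl[1L]]]$nodes)
    pair_idx[[key]] <- list(target = kl[2L],
                            to = split(match(e$to, info[[kl[2L]]]$nodes), src),
                            w = split(e$weight, src))
  }

  lambda <- config$lambda
  ii <- vector("list", length(mx_names))
  jj <- vector("list", length(mx_names))
  xx <- vector("list", length(mx_names))
  dangling <- numeric(n_states)

  for (mx in mx_names) {
    inf_k <- info[[mx]]
    n_k <- inf_k$n
    L_k <- inf_k$L
    pair_keys <- if (length(pair_idx)) {
      names(pair_idx)[startsWith(names(pair_idx), paste0(mx, "\r"))]
    } else character(0L)
    il <- list(); jl <- list(); xl <- list()
    for (ni in seq_len(n_k)) {
      # Multiplexes reachable from this node through a bipartite edge.
      reach <- character(0L)
      nb <- list()
      for (key in pair_keys) {
        tgt <- pair_idx[[key]]$target
        tos <- pair_idx[[key]]$to[[ni]]
        if (length(tos)) {
          if (is.null(nb[[tgt]])) {
            nb[[tgt]] <- list(to = tos, w = pair_idx[[key]]$w[[ni]])
            reach <- c(reach, tgt)
          } else {
            nb[[tgt]]$to <- c(nb[[tgt]]$to, tos)
            nb[[tgt]]$w <- c(nb[[tgt]]$w, pair_idx[[key]]$w[[ni]])
          }
        }
      }
      if (is.null(lambda)) {
        p_stay <- 1 / (1 + length(reach))
        p_jump <- rep(p_stay, length(reach))
      } else {
        lam <- lambda[mx, ]
        p_jump <- unname(lam[reach])
        p_stay <- lam[mx] + sum(lam[setdiff(mx_names, c(mx, reach))])
      }
      names(p_jump) <- reach
      rows <- integer(0L); vals <- numeric(0L)
      dang_i <- 0
      # Stay: uniform layer choice, then weighted edge.
      per_layer <- p_stay / L_k
      for (beta in seq_len(L_k)) {
        tos <- layer_adj[[mx]][[beta]]$to[[ni]]
        if (length(tos) == 0L) {
          dang_i <- dang_i + per_layer
        } else {
          w <- layer_adj[[mx]][[beta]]$w[[ni]]
          rows <- c(rows, inf_k$offset + (beta - 1L) * n_k + tos)
          vals <- c(vals, per_layer * w / sum(w))
        }
      }
      # Jump: weighted bipartite edge, uniform landing layer.
      for (tgt in reach) {
        inf_l <- info[[tgt]]
        w <- nb[[tgt]]$w
        p_edge <- p_jump[[tgt]] * w / sum(w)
        for (betap in seq_len(inf_l$L)) {
          rows <- c(rows, inf_l$offset + (betap - 1L) * inf_l$n + nb[[tgt]]$to)
          vals <- c(vals, p_edge / inf_l$L)
        }
      }
      # Replicate the column for every layer alpha of this multiplex.
      cols <- inf_k$offset + (seq_len(L_k) - 1L) * n_k + ni
      dangling[cols] <- dang_i
      if (length(rows)) {
        il[[length(il) + 1L]] <- rep(rows, times = L_k)
        jl[[length(jl) + 1L]] <- rep(cols, each = length(rows))
        xl[[length(xl) + 1L]] <- rep(vals, times = L_k)
      }
    }
    ki <- match(mx, mx_names)
    ii[[ki]] <- unlist(il, use.names = FALSE)
    jj[[ki]] <- unlist(jl, use.names = FALSE)
    xx[[ki]] <- unlist(xl, use.names = FALSE)
  }

  M <- Matrix::sparseMatrix(i = as.integer(unlist(ii, use.names = FALSE)),
                            j = as.integer(unlist(jj, use.names = FALSE)),
                            x = as.numeric(unlist(xx, use.names = FALSE)),
                            dims = c(n_states, n_states))
  colsum <- Matrix::colSums(M)
  if (any(colsum + dangling > 1 + 1e-9) || any(colsum + dangling < 1 - 1e-9)) {
    stopf("internal error: transition columns are not stochastic")
  }

  node_mx <- rep(mx_names, vapply(info, `[[`, numeric(1L), "n"))
  node_id <- unlist(lapply(info, `[[`, "nodes"), use.names = FALSE)
  # Per-state global node index, used to aggregate layer scores per node.
  state_node <- unlist(lapply(seq_along(mx_names), function(ki) {
    inf_k <- info[[ki]]
    base <- sum(vapply(info[seq_len(ki - 1L)], `[[`, numeric(1L), "n"))
    rep.int(base + seq_len(inf_k$n), inf_k$L)
  }), use.names = FALSE)
  agg <- Matrix::sparseMatrix(i = state_node, j = seq_len(n_states), x = 1,
                              dims = c(length(node_id), n_states))
  structure(list(M = M, dangling = dangling, info = info,
                 n_states = n_states, agg = agg,
                 nodes = data.frame(multiplex = node_mx, node = node_id,
                                    stringsAsFactors = FALSE)),
            class = "cnm_transition")
}

# Restart vector over supra-states for a seed table.
restart_vector <- function(transition, seeds, config) {
  seeds <- as.data.frame(seeds)
  if (nrow(seeds) == 0L) stopf("seed set must be non-empty")
  stopifnot(all(c("multiplex", "node") %in% names(seeds)))
  if (is.null(seeds$weight)) seeds$weight <- 1
  if (any(seeds$weight < 0)) stopf("seed weights must be non-negative")
  info <- transition$info
  for (i in seq_len(nrow(seeds))) {
    mx <- seeds$multiplex[i]
    if (!mx %in% names(info)) stopf("seed multiplex '%s' not in network", mx)
    if (!seeds$node[i] %in% info[[mx]]$nodes) {
      stopf("seed node '%s' not found in multiplex '%s'", seeds$node[i], mx)
    }
  }
  seeded <- unique(seeds$multiplex)
  if (is.null(config$tau)) {
    tau <- stats::setNames(rep(1 / length(seeded), length(seeded)), seeded)
  } else {
    tau <- config$tau[seeded]
    if (any(is.na(tau)) || sum(tau) <= 0) {
      stopf("tau gives no restart mass to any seeded multiplex")
    }
    tau <- tau / sum(tau)
  }
  v <- numeric(transition$n_states)
  for (mx in seeded) {
    sk <- seeds[seeds$multiplex == mx, , drop = FALSE]
    w <- sk$weight
    if (sum(w) <= 0) w <- rep(1, length(w))
    w <- w / sum(w)
    inf_k <- info[[mx]]
    pos <- match(sk$node, inf_k$nodes)
    for (beta in seq_len(inf_k$L)) {
      idx <- inf_k$offset + (beta - 1L) * inf_k$n + pos
      v[idx] <- v[idx] + tau[[mx]] * w / inf_k$L
    }
  }
  v
}

# Shared iterative solver on a prebuilt transition.
solve_rwr <- function(transition, v, config) {
  r <- config$restart_r
  M <- transition$M
  d <- transition$dangling
  s <- v
  for (it in seq_len(config$max_iterations)) {
    s_new <- (1 - r) * (as.numeric(M %*% s) + sum(d * s) * v) + r * v
    delta <- sum(abs(s_new - s))
    s <- s_new
    if (delta < config$tolerance) {
      return(list(supra = s, iterations = it, residual = delta))
    }
  }
  stopf("RWR did not converge in %d iterations (last L1 change %.3g)",
        config$max_iterations, delta)
}

score_result <- function(transition, s, seeds, config, iterations = NA_integer_) {
  nodes <- transition$nodes
  nodes$score <- as.numeric(transition$agg %*% s)
  structure(list(supra = s, nodes = nodes, seeds = seeds,
                 config = config, iterations = iterations),
            class = "cnm_scores")
}

#' Random walk with restart scores
#'
#' Iterates `s <- (1 - r) * (M s + dangling_mass * v) + r * v` from the
#' restart vector `v` until the L1 change drops below the tolerance. The
#' restart vector places `tau` mass on each seeded multiplex, splits it
#' among that multiplex's seeds (proportional to seed weight) and uniformly
#' across its layers. Supra-scores are aggregated per (multiplex, node) by
#' summation, so the node scores form a probability distribution.
#'
#' @param net a `cnm_network`; ignored when `transition` is supplied.
#' @param seeds data frame with columns `multiplex`, `node` and optionally
#'   `weight`.
#' @param config a [rwr_config()].
#' @param transition optional prebuilt [build_transition()] result, for
#'   repeated walks on the same network.
#' @return An object of class `cnm_scores` with elements `supra` (per-state
#'   probabilities) and `nodes` (data frame multiplex/node/score).
#' @export
rwr_scores <- function(net, seeds, config = rwr_config(), transition = NULL) {
  if (is.null(transition)) transition <- build_transition(net, config)
  v <- restart_vector(transition, seeds, config)
  sol <- solve_rwr(transition, v, config)
  score_result(transition, sol$supra, seeds, config, sol$iterations)
}

#' Exact stationary scores by dense linear solve
#'
#' Solves `s = (1 - r) * Mhat s + r * v` directly, where `Mhat` adds the
#' dangling-to-restart redirection to the transition operator. Intended as
#' a verification oracle for small instances.
#'
#' @inheritParams rwr_scores
#' @param max_states guard on the supra-state count for the dense solve.
#' @return A `cnm_scores`, with the same aggregation contract as
#'   [rwr_scores()].
#' @export
exact_scores <- function(net, seeds, config = rwr_config(), transition = NULL,
                         max_states = 2000L) {
  if (is.null(transition)) transition <- build_transition(net, config)
  n <- transition$n_states
  if (n > max_states) {
    stopf("exact_scores: %d supra-states exceed max_states = %d", n, max_states)
  }
  v <- restart_vector(transition, seeds, config)
  r <- config$restart_r
  Mhat <- as.matrix(transition$M) + outer(v, transition$dangling)
  A <- diag(n) - (1 - r) * Mhat
  s <- solve(A, r * v)
  score_result(transition, s, seeds, config)
}

#' Top-ranked nodes of one multiplex
#'
#' Nodes sorted by aggregated score (descending), ties broken by node id
#' (ascending) so rankings are deterministic.
#'
#' @param scores a `cnm_scores`.
#' @param multiplex multiplex name.
#' @param top_n number of rows to return; if fewer nodes are available all
#'   are returned with a warning.
#' @param exclude nodes to leave out: a character vector of node ids or a
#'   data frame with `multiplex`/`node` columns (e.g. the seed set).
#' @return Data frame with columns `node`, `score`, `rank`.
#' @export
rank_top <- function(scores, multiplex, top_n, exclude = NULL) {
  stopifnot(inherits(scores, "cnm_scores"))
  tab <- scores$nodes[scores$nodes$multiplex == multiplex, , drop = FALSE]
  if (nrow(tab) == 0L) stopf("multiplex '%s' not found in scores", multiplex)
  if (!is.null(exclude)) {
    if (is.data.frame(exclude)) {
      exclude <- exclude$node[exclude$multiplex == multiplex]
    }
    tab <- tab[!tab$node %in% exclude, , drop = FALSE]
  }
  ord <- order(-tab$score, tab$node)
  if (top_n > nrow(tab)) {
    warnf("rank_top: only %d node(s) available, returning all", nrow(tab))
    top_n <- nrow(tab)
  }
  out <- tab[ord[seq_len(top_n)], c("node", "score")]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.cnm_scores <- function(x, ...) {
  cat(sprintf("RWR scores over %d states (%d nodes); total probability %.6f\n",
              length(x$supra), nrow(x$nodes), sum(x$nodes$score)))
  invisible(x)
}
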
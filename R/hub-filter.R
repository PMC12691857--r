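# Resampling null for nonspecific hubs: repeated RWR from random
# single-gene seeds, top-k occurrence counting, the >5%-of-iterations
# top-50 hub rule, and full-vs-subset comparison.

#' Configuration of the random-seed hub scan
#'
#' @param seed_pool data frame (`multiplex`, `node`) of candidate seed
#'   nodes, typically all protein-coding gene nodes of the gene multiplex.
#' @param n_iterations number of random-seed walks.
#' @param top_k_levels top-list sizes at which occurrences are counted.
#' @param hub_top_k the level used by the hub rule (must be one of
#'   `top_k_levels`).
#' @param hub_fraction a node occurring in the `hub_top_k` list in strictly
#'   more than this fraction of iterations is called a hub.
#' @param rng_seed integer seed; the scan is deterministic given it.
#' @return A list of class `cnm_hub_config`.
#' @export
hub_scan_config <- function(seed_pool, n_iterations = 1000L,
                            top_k_levels = c(10L, 50L, 100L),
                            hub_top_k = 50L, hub_fraction = 0.05,
                            rng_seed = 1L) {
  seed_pool <- as.data.frame(seed_pool)
  stopifnot(all(c("multiplex", "node") %in% names(seed_pool)))
  if (!hub_top_k %in% top_k_levels) {
    stopf("hub_top_k must be one of top_k_levels")
  }
  if (hub_fraction <= 0 || hub_fraction >= 1) {
    stopf("hub_fraction must lie in (0, 1)")
  }
  structure(list(seed_pool = seed_pool,
                 n_iterations = as.integer(n_iterations),
                 top_k_levels = as.integer(sort(top_k_levels)),
                 hub_top_k = as.integer(hub_top_k),
                 hub_fraction = hub_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "cnm_hub_config")
}

#' Random-seed hub scan
#'
#' Draws `n_iterations` seeds uniformly with replacement from the seed
#' pool, runs one RWR per seed, and counts, per node category (multiplex)
#' and per top-k level, how often each node appears in the top-k ranking of
#' its category. The seed node is excluded from its own ranking (a seed
#' trivially tops its own list and would corrupt the null). Walks that fail
#' to converge are recorded and excluded from the denominator.
#'
#' @param net a `cnm_network`; ignored when `transition` is supplied.
#' @param config a [hub_scan_config()].
#' @param rwr_config a [rwr_config()].
#' @param transition optional prebuilt transition.
#' @return A list of class `cnm_hub_report` with `counts` (data frame
#'   multiplex, node, `top_<k>` columns), `n_iterations`,
#'   `effective_iterations`, `n_failed`, and the rule parameters.
#' @export
random_seed_scan <- function(net, config, rwr_config = NULL,
                             transition = NULL) {
  stopifnot(inherits(config, "cnm_hub_config"))
  if (is.null(rwr_config)) rwr_config <- rwr_config()
  if (is.null(transition)) transition <- build_transition(net, rwr_config)
  pool <- config$seed_pool
  nodes <- transition$nodes
  levels_k <- config$top_k_levels
  counts <- matrix(0L, nrow = nrow(nodes), ncol = length(levels_k),
                   dimnames = list(NULL, paste0("top_", levels_k)))
  n_failed <- 0L
  if (config$n_iterations > 0L) {
    # Validate the pool once.
    for (mx in unique(pool$multiplex)) {
      if (!mx %in% names(transition$info)) {
        stopf("seed pool references unknown multiplex '%s'", mx)
      }
      bad <- setdiff(pool$node[pool$multiplex == mx],
                     transition$info[[mx]]$nodes)
      if (length(bad)) stopf("seed pool node(s) not in network: %s",
                             paste(utils::head(bad, 3L), collapse = ", "))
    }
    draws <- with_rng(config$rng_seed,
                      sample.int(nrow(pool), config$n_iterations,
                                 replace = TRUE))
    # Precompute per-multiplex node index ranges.
    mx_names <- unique(nodes$multiplex)
    mx_idx <- lapply(mx_names, function(mx) which(nodes$multiplex == mx))
    names(mx_idx) <- mx_names
    kmax <- max(levels_k)
    for (it in seq_len(config$n_iterations)) {
      seed <- pool[draws[it], , drop = FALSE]
      v <- restart_vector(transition, seed, rwr_config)
      sol <- tryCatch(solve_rwr(transition, v, rwr_config),
                      error = function(e) NULL)
      if (is.null(sol)) {
        n_failed <- n_failed + 1L
        next
      }
      score <- as.numeric(transition$agg %*% sol$supra)
      for (mx in mx_names) {
        idx <- mx_idx[[mx]]
        ids <- nodes$node[idx]
        sc <- score[idx]
        if (mx == seed$multiplex) {
          keep <- ids != seed$node
          ids <- ids[keep]
          sc <- sc[keep]
          idx <- idx[keep]
        }
        ord <- order(-sc, ids)
        top <- idx[ord[seq_len(min(kmax, length(ord)))]]
        for (li in seq_along(levels_k)) {
          sel <- top[seq_len(min(levels_k[li], length(top)))]
          counts[sel, li] <- counts[sel, li] + 1L
        }
      }
    }
  }
  out <- cbind(nodes[, c("multiplex", "node")], as.data.frame(counts))
  structure(list(counts = out,
                 n_iterations = config$n_iterations,
                 effective_iterations = config$n_iterations - n_failed,
                 n_failed = n_failed,
                 top_k_levels = levels_k,
                 hub_top_k = config$hub_top_k,
                 hub_fraction = config$hub_fraction),
            class = "cnm_hub_report")
}

#' Call nonspecific hub nodes from a scan report
#'
#' A node is a hub when its occurrence count at the `hub_top_k` level is
#' strictly greater than `hub_fraction` of the effective iterations
#' ("more than 5%": a count of exactly 5% is not a hub).
#'
#' @param report a `cnm_hub_report`.
#' @param hub_top_k,hub_fraction rule parameters; default to those recorded
#'   in the report.
#' @param multiplexes categories over which hubs are called (default: the
#'   gene and metabolite multiplexes if present, else all); hub removal in
#'   the reference procedure applies only to genes and metabolites.
#' @return Data frame (multiplex, node, count) of hubs.
#' @export
detect_hubs <- function(report, hub_top_k = report$hub_top_k,
                        hub_fraction = report$hub_fraction,
                        multiplexes = NULL) {
  stopifnot(inherits(report, "cnm_hub_report"))
  col <- paste0("top_", hub_top_k)
  if (!col %in% names(report$counts)) {
    stopf("report has no counts at top-%d", hub_top_k)
  }
  tab <- report$counts
  if (is.null(multiplexes)) {
    present <- unique(tab$multiplex)
    multiplexes <- intersect(c("genes", "metabolites"), present)
    if (length(multiplexes) == 0L) multiplexes <- present
  }
  tab <- tab[tab$multiplex %in% multiplexes, , drop = FALSE]
  cutoff <- hub_fraction * report$effective_iterations
  hubs <- tab[tab[[col]] > cutoff, c("multiplex", "node", col)]
  names(hubs)[3L] <- "count"
  hubs <- hubs[order(-hubs$count, hubs$multiplex, hubs$node), ]
  rownames(hubs) <- NULL
  hubs
}

#' Full-vs-subset hub scan
#'
#' Runs the random-seed scan with the same seed sequence on the full
#' network and on the network without `drop_layers` (e.g. the experimental
#' co-expression layers), and pairs the occurrence counts per node —
#' the data behind full-vs-subset occurrence scatter plots — together with
#' the Pearson correlation of paired counts per category and level.
#'
#' @param net a `cnm_network`.
#' @param drop_layers layer names removed in the subset run.
#' @param config a [hub_scan_config()].
#' @param rwr_config a [rwr_config()].
#' @return List of class `cnm_paired_scan` with `full`, `subset` (the two
#'   reports), `paired` (merged counts, `full_top_<k>` / `subset_top_<k>`),
#'   and `correlations` (multiplex, level, pearson_r).
#' @export
full_vs_subset_scan <- function(net, drop_layers, config,
                                rwr_config = NULL) {
  if (is.null(rwr_config)) rwr_config <- rwr_config()
  full <- random_seed_scan(net, config, rwr_config)
  sub_net <- if (length(drop_layers)) drop_layers(net, drop_layers) else net
  subset <- random_seed_scan(sub_net, config, rwr_config)
  fc <- full$counts
  sc <- subset$counts
  lv <- paste0("top_", full$top_k_levels)
  names(fc)[match(lv, names(fc))] <- paste0("full_", lv)
  names(sc)[match(lv, names(sc))] <- paste0("subset_", lv)
  paired <- merge(fc, sc, by = c("multiplex", "node"), sort = TRUE)
  cors <- do.call(rbind, lapply(unique(paired$multiplex), function(mx) {
    sl <- paired[paired$multiplex == mx, , drop = FALSE]
    data.frame(multiplex = mx, level = full$top_k_levels,
               pearson_r = vapply(lv, function(l) {
                 x <- sl[[paste0("full_", l)]]
                 y <- sl[[paste0("subset_", l)]]
                 if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
                 stats::cor(x, y)
               }, numeric(1L)))
  }))
  rownames(cors) <- NULL
  structure(list(full = full, subset = subset, paired = paired,
                 correlations = cors),
            class = "cnm_paired_scan")
}
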
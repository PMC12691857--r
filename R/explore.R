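# Joint-seed disease queries and shared/specific overlap reporting.

#' Node reference
#'
#' @param multiplex multiplex name.
#' @param node node id (gene symbol, metabolite id, phenotype term id, ...).
#' @param weight optional restart weight.
#' @return One-row data frame usable as a seed.
#' @export
node_ref <- function(multiplex, node, weight = 1) {
  data.frame(multiplex = multiplex, node = node, weight = weight,
             stringsAsFactors = FALSE)
}

#' Joint-seed query of the multilayer network
#'
#' Runs a single RWR with a gene seed and (optionally) a phenotype seed
#' jointly — restart mass is split uniformly over the seeded multiplexes —
#' and returns the top-scoring nodes of the requested categories, seeds
#' excluded.
#'
#' @param net a `cnm_network`; ignored when `transition` is supplied.
#' @param gene_seed a [node_ref()] (or data frame row) for the gene seed.
#' @param phenotype_seed optional [node_ref()] for the phenotype seed.
#' @param top_n list length per category.
#' @param rwr_config a [rwr_config()].
#' @param categories multiplexes for which top lists are reported (default:
#'   the gene and metabolite multiplexes).
#' @param label query label used in overlap tables.
#' @param transition optional prebuilt transition.
#' @return List of class `cnm_query` with `label`, `seeds`, `scores`, and
#'   `top` (named list of ranked data frames per category).
#' @export
joint_seed_query <- function(net, gene_seed, phenotype_seed = NULL,
                             top_n = 20L, rwr_config = NULL,
                             categories = c("genes", "metabolites"),
                             label = NULL, transition = NULL) {
  if (is.null(rwr_config)) rwr_config <- rwr_config()
  seeds <- rbind(as.data.frame(gene_seed),
                 if (!is.null(phenotype_seed)) as.data.frame(phenotype_seed))
  if (is.null(seeds$weight)) seeds$weight <- 1
  scores <- rwr_scores(net, seeds, rwr_config, transition = transition)
  top <- lapply(categories, function(mx) {
    rank_top(scores, mx, top_n, exclude = seeds)
  })
  names(top) <- categories
  if (is.null(label)) {
    label <- paste(seeds$node, collapse = "+")
  }
  structure(list(label = label, seeds = seeds, scores = scores, top = top),
            class = "cnm_query")
}

#' Shared and specific nodes across queries
#'
#' Partitions, per category, the union of the queries' top lists into
#' nodes shared by all queries, shared by a subset, or specific to one
#' query. The partition is exact and exhaustive over the union.
#'
#' @param results list of `cnm_query` objects (at least two).
#' @return Data frame (category, node, n_queries, queries, status) with
#'   `status` one of `"shared_all"`, `"shared_some"`, `"specific"`, ordered
#'   by category then node.
#' @export
overlap_table <- function(results) {
  if (length(results) < 2L) stopf("need at least two query results")
  ok <- vapply(results, inherits, logical(1L), "cnm_query")
  if (!all(ok)) stopf("all results must be cnm_query objects")
  labels <- vapply(results, `[[`, character(1L), "label")
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels)
  }
  categories <- unique(unlist(lapply(results, function(q) names(q$top))))
  rows <- list()
  for (cat in categories) {
    membership <- lapply(results, function(q) q$top[[cat]]$node %||% character(0L))
    names(membership) <- labels
    universe <- sort(unique(unlist(membership)))
    if (length(universe) == 0L) next
    inq <- vapply(membership, function(m) universe %in% m,
                  logical(length(universe)))
    inq <- matrix(inq, nrow = length(universe),
                  dimnames = list(universe, labels))
    nq <- rowSums(inq)
    status <- ifelse(nq == length(results), "shared_all",
                     ifelse(nq > 1L, "shared_some", "specific"))
    rows[[length(rows) + 1L]] <- data.frame(
      category = cat, node = universe, n_queries = as.integer(nq),
      queries = apply(inq, 1L, function(z) paste(labels[z], collapse = ",")),
      status = status, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(category = character(), node = character(),
               n_queries = integer(), queries = character(),
               status = character())
  out <- out[order(out$category, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.cnm_query <- function(x, ...) {
  cat(sprintf("Query '%s' (%d seed(s))\n", x$label, nrow(x$seeds)))
  for (cat_ in names(x$top)) {
    tp <- x$top[[cat_]]
    cat(sprintf("  top %s: %s\n", cat_,
                paste(utils::head(tp$node, 5L), collapse = ", ")))
  }
  invisible(x)
}
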
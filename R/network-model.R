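# Domain types and surgery for multiplex-heterogeneous multilayer networks:
# layers, multiplexes, bipartites, assembly from a manifest, summary
# statistics, and node removal.

#' Create a network layer
#'
#' A layer is one set of edges over the nodes of a multiplex (e.g. a
#' protein-protein interaction layer, or a thresholded co-expression layer).
#' Edges are canonicalized on construction: ids are whitespace-trimmed
#' (identity is exact, case-sensitive string match), self-loops are dropped
#' with a warning, undirected pairs are stored with the lexically smaller id
#' first, and duplicate records collapse keeping the maximum weight.
#' Unweighted layers carry weight 1 on every edge.
#'
#' @param name layer identifier.
#' @param edges data frame with columns source id, target id and, for
#'   weighted layers, a positive weight.
#' @param directed logical; are edges directed?
#' @param weighted logical; do edges carry weights?
#' @return An object of class `cnm_layer`.
#' @export
layer <- function(name, edges = NULL, directed = FALSE, weighted = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  edges <- clean_edges(edges, weighted = weighted, canonicalize = !directed,
                       drop_loops = TRUE, context = sprintf("layer '%s'", name))
  structure(list(name = name, directed = isTRUE(directed),
                 weighted = isTRUE(weighted), edges = edges),
            class = "cnm_layer")
}

#' Nodes incident to at least one edge of a layer
#' @param x a `cnm_layer`.
#' @return Sorted character vector of node ids.
#' @export
layer_nodes <- function(x) {
  stopifnot(inherits(x, "cnm_layer") || inherits(x, "cnm_bipartite"))
  sort(unique(c(x$edges$from, x$edges$to)))
}

#' Read a layer edge list from a TSV file
#'
#' Files have 2 columns (source, target) or 3 (source, target, weight);
#' lines starting with `#` and blank lines are ignored. The weight column
#' is required iff `weighted` is `TRUE`.
#'
#' @param path path to a UTF-8 TSV file.
#' @param directed,weighted layer flags, see [layer()].
#' @param name layer name; defaults to the file name without extension.
#' @return A `cnm_layer`.
#' @export
read_layer_edges <- function(path, directed = FALSE, weighted = FALSE,
                             name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stopf("layer file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L) return(layer(name, NULL, directed, weighted))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  need <- if (weighted) 3L else 2L
  nf <- lengths(parts)
  bad <- which(nf < need)
  if (length(bad)) {
    stopf("%s: line %d: expected %d tab-separated fields, found %d",
          path, keep[bad[1L]], need, nf[bad[1L]])
  }
  from <- vapply(parts, `[[`, character(1L), 1L)
  to <- vapply(parts, `[[`, character(1L), 2L)
  if (weighted) {
    wtxt <- vapply(parts, `[[`, character(1L), 3L)
    w <- suppressWarnings(as.numeric(gsub("−", "-", wtxt)))
    bad <- which(!is.finite(w))
    if (length(bad)) stopf("%s: line %d: weight '%s' is not a number",
                           path, keep[bad[1L]], wtxt[bad[1L]])
    bad <- which(w <= 0)
    if (length(bad)) stopf("%s: line %d: edge weight must be positive, got %g",
                           path, keep[bad[1L]], w[bad[1L]])
    edges <- data.frame(from = from, to = to, weight = w)
  } else {
    edges <- data.frame(from = from, to = to)
  }
  layer(name, edges, directed = directed, weighted = weighted)
}

#' Write a layer edge list to a TSV file
#'
#' Inverse of [read_layer_edges()]: a read-write-read round trip yields an
#' identical edge multiset.
#'
#' @param x a `cnm_layer` or `cnm_bipartite`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layer_edges <- function(x, path) {
  stopifnot(inherits(x, "cnm_layer") || inherits(x, "cnm_bipartite"))
  tab <- x$edges
  if (!x$weighted) tab <- tab[, c("from", "to"), drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Create a multiplex network
#'
#' A multiplex is an ordered set of layers over a single node type. The node
#' universe is the union of the layer node sets with any extra `nodes`
#' supplied explicitly; a node isolated in every layer is still a member.
#'
#' @param name multiplex identifier.
#' @param layers list of `cnm_layer` (at least one).
#' @param nodes optional character vector of additional (possibly isolated)
#'   node ids.
#' @return An object of class `cnm_multiplex`.
#' @export
multiplex <- function(name, layers, nodes = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (inherits(layers, "cnm_layer")) layers <- list(layers)
  if (length(layers) < 1L) stopf("multiplex '%s' needs at least one layer", name)
  ok <- vapply(layers, inherits, logical(1L), "cnm_layer")
  if (!all(ok)) stopf("multiplex '%s': all layers must be cnm_layer objects", name)
  names(layers) <- vapply(layers, `[[`, character(1L), "name")
  if (anyDuplicated(names(layers))) stopf("multiplex '%s': duplicate layer names", name)
  universe <- sort(unique(c(unlist(lapply(layers, layer_nodes), use.names = FALSE),
                            if (!is.null(nodes)) trimws(as.character(nodes)))))
  structure(list(name = name, layers = layers, nodes = universe),
            class = "cnm_multiplex")
}

#' Create a bipartite network linking two multiplexes
#'
#' @param name bipartite identifier.
#' @param source_multiplex,target_multiplex names of the multiplexes whose
#'   nodes appear in the first/second edge column.
#' @param edges data frame of (source id, target id\[, weight\]).
#' @param directed logical; if `TRUE` the bipartite is walked only from
#'   source to target (e.g. reactant-to-reaction links of a metabolic model).
#' @param weighted logical; do edges carry weights?
#' @return An object of class `cnm_bipartite`.
#' @export
bipartite <- function(name, source_multiplex, target_multiplex, edges = NULL,
                      directed = FALSE, weighted = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  edges <- clean_edges(edges, weighted = weighted, canonicalize = FALSE,
                       drop_loops = FALSE,
                       context = sprintf("bipartite '%s'", name))
  structure(list(name = name,
                 source_multiplex = source_multiplex,
                 target_multiplex = target_multiplex,
                 directed = isTRUE(directed), weighted = isTRUE(weighted),
                 edges = edges),
            class = "cnm_bipartite")
}

#' Read a bipartite edge list from a TSV file
#'
#' @inheritParams read_layer_edges
#' @inheritParams bipartite
#' @return A `cnm_bipartite`.
#' @export
read_bipartite_edges <- function(path, source_multiplex, target_multiplex,
                                 directed = FALSE, weighted = FALSE,
                                 name = tools::file_path_sans_ext(basename(path))) {
  lay <- read_layer_edges(path, directed = TRUE, weighted = weighted, name = name)
  bipartite(name, source_multiplex, target_multiplex, lay$edges,
            directed = directed, weighted = weighted)
}

#' Assemble a multilayer network
#'
#' Combines multiplexes and the bipartites linking them. Bipartite endpoint
#' nodes absent from every layer of their multiplex are added to that
#' multiplex's node universe as isolated nodes, with a warning.
#'
#' @param multiplexes list of `cnm_multiplex` objects.
#' @param bipartites list of `cnm_bipartite` objects (may be empty).
#' @return An object of class `cnm_network`.
#' @export
multilayer_network <- function(multiplexes, bipartites = list()) {
  if (inherits(multiplexes, "cnm_multiplex")) multiplexes <- list(multiplexes)
  ok <- vapply(multiplexes, inherits, logical(1L), "cnm_multiplex")
  if (length(multiplexes) < 1L || !all(ok)) {
    stopf("multiplexes must be a non-empty list of cnm_multiplex objects")
  }
  names(multiplexes) <- vapply(multiplexes, `[[`, character(1L), "name")
  if (anyDuplicated(names(multiplexes))) stopf("duplicate multiplex names")
  if (inherits(bipartites, "cnm_bipartite")) bipartites <- list(bipartites)
  if (length(bipartites)) {
    names(bipartites) <- vapply(bipartites, `[[`, character(1L), "name")
    if (anyDuplicated(names(bipartites))) stopf("duplicate bipartite names")
  }
  for (bp in bipartites) {
    for (side in c("source", "target")) {
      mx <- bp[[paste0(side, "_multiplex")]]
      if (!mx %in% names(multiplexes)) {
        stopf("bipartite '%s' references unknown multiplex '%s'", bp$name, mx)
      }
      ids <- if (side == "source") bp$edges$from else bp$edges$to
      missing <- setdiff(unique(ids), multiplexes[[mx]]$nodes)
      if (length(missing)) {
        warnf("bipartite '%s': adding %d isolated node(s) to multiplex '%s'",
              bp$name, length(missing), mx)
        multiplexes[[mx]]$nodes <- sort(c(multiplexes[[mx]]$nodes, missing))
      }
    }
  }
  structure(list(multiplexes = multiplexes, bipartites = bipartites),
            class = "cnm_network")
}

#' Assemble a multilayer network from a manifest
#'
#' The manifest is a YAML file (or an equivalent list) with blocks
#' `multiplexes` (each naming layer files with `directed`/`weighted` flags),
#' `bipartites` (each with `source`, `target`, `path` and flags), an
#' optional `paths: base:` entry against which relative file paths are
#' resolved, and an optional `rwr` block of walk parameters which is
#' attached to the result as attribute `"rwr"`.
#'
#' @param manifest path to a YAML manifest, or a list with the same shape.
#' @param base_dir directory against which relative paths are resolved;
#'   defaults to the manifest's `paths$base`, else the manifest directory.
#' @return A `cnm_network` with attribute `"rwr"`.
#' @export
assemble_network <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- yaml::read_yaml(manifest)
  }
  if (!is.list(manifest) || is.null(manifest$multiplexes)) {
    stopf("manifest must contain a 'multiplexes' block")
  }
  base_dir <- manifest$paths$base %||% base_dir %||% "."
  resolve <- function(p) {
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  }
  mpx <- lapply(names(manifest$multiplexes), function(mname) {
    blk <- manifest$multiplexes[[mname]]
    lays <- lapply(names(blk$layers), function(lname) {
      lb <- blk$layers[[lname]]
      read_layer_edges(resolve(lb$path),
                       directed = isTRUE(lb$directed),
                       weighted = isTRUE(lb$weighted), name = lname)
    })
    multiplex(mname, lays, nodes = blk$nodes)
  })
  bps <- lapply(names(manifest$bipartites %||% list()), function(bname) {
    bb <- manifest$bipartites[[bname]]
    if (is.null(bb$source) || is.null(bb$target)) {
      stopf("bipartite '%s': manifest entry needs 'source' and 'target'", bname)
    }
    read_bipartite_edges(resolve(bb$path), bb$source, bb$target,
                         directed = isTRUE(bb$directed),
                         weighted = isTRUE(bb$weighted), name = bname)
  })
  net <- multilayer_network(mpx, bps)
  attr(net, "rwr") <- manifest$rwr
  net
}

#' Write a multilayer network as edge lists plus a manifest
#'
#' Writes one TSV per layer and bipartite under `dir` and a
#' `manifest.yaml` that [assemble_network()] can read back.
#'
#' @param net a `cnm_network`.
#' @param dir output directory (created if needed).
#' @param rwr optional list of walk parameters stored in the manifest.
#' @return The manifest path, invisibly.
#' @export
write_network <- function(net, dir, rwr = NULL) {
  stopifnot(inherits(net, "cnm_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- list(multiplexes = list(), bipartites = list())
  for (mp in net$multiplexes) {
    lays <- list()
    for (lay in mp$layers) {
      fn <- sprintf("%s__%s.tsv", mp$name, lay$name)
      write_layer_edges(lay, file.path(dir, fn))
      lays[[lay$name]] <- list(path = fn, directed = lay$directed,
                               weighted = lay$weighted)
    }
    man$multiplexes[[mp$name]] <- list(layers = lays, nodes = mp$nodes)
  }
  for (bp in net$bipartites) {
    fn <- sprintf("bipartite__%s.tsv", bp$name)
    write_layer_edges(bp, file.path(dir, fn))
    man$bipartites[[bp$name]] <- list(
      path = fn, source = bp$source_multiplex, target = bp$target_multiplex,
      directed = bp$directed, weighted = bp$weighted)
  }
  if (!is.null(rwr)) man$rwr <- rwr
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, path)
  invisible(path)
}

#' Simple-graph density
#'
#' Number of actual edges divided by the number of potential edges,
#' `m / (n * (n - 1) / 2)`. This single convention is applied to every
#' layer and monoplex row of [summarize_network()], including directed
#' ones.
#'
#' @param n_nodes,n_edges node and edge counts.
#' @param digits decimals to round to, or `NULL` for no rounding.
#' @return Density value(s); `NA` when `n_nodes < 2`.
#' @export
network_density <- function(n_nodes, n_edges, digits = NULL) {
  d <- ifelse(n_nodes >= 2, n_edges / (n_nodes * (n_nodes - 1) / 2), NA_real_)
  if (!is.null(digits)) d <- round(d, digits)
  d
}

#' Summarize a multilayer network
#'
#' One row per layer and per bipartite, with node count, edge count,
#' density (rounded to 3 decimals), and the weighted/directed flags.
#' Bipartite rows report the combined node count of both sides and leave
#' density `NA`, since the side split is not part of the summary.
#'
#' @param net a `cnm_network`.
#' @return A data frame of class `cnm_summary`.
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "cnm_network"))
  rows <- list()
  for (mp in net$multiplexes) {
    for (lay in mp$layers) {
      # Edgeless layers (e.g. tissue nodes linked only through bipartites)
      # report the multiplex universe.
      n <- if (nrow(lay$edges)) length(layer_nodes(lay)) else length(mp$nodes)
      m <- nrow(lay$edges)
      rows[[length(rows) + 1L]] <- data.frame(
        network = mp$name, layer = lay$name, n_nodes = n, n_edges = m,
        density = network_density(n, m, digits = 3L),
        weighted = lay$weighted, directed = lay$directed)
    }
  }
  for (bp in net$bipartites) {
    rows[[length(rows) + 1L]] <- data.frame(
      network = bp$name, layer = NA_character_,
      n_nodes = length(layer_nodes(bp)), n_edges = nrow(bp$edges),
      density = NA_real_, weighted = bp$weighted, directed = bp$directed)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cnm_summary", "data.frame")
  out
}

#' Remove nodes from a multilayer network
#'
#' Deletes the target nodes from all layers, node universes and bipartites
#' of their multiplexes, together with every incident edge. Other nodes are
#' retained even if left isolated. Unknown targets produce a warning, not an
#' error, so removal is idempotent. This is the surgery used to excise
#' nonspecific hub nodes before re-running walks.
#'
#' @param net a `cnm_network`.
#' @param targets data frame with columns `multiplex` and `node`.
#' @return The pruned `cnm_network`.
#' @export
remove_nodes <- function(net, targets) {
  stopifnot(inherits(net, "cnm_network"))
  targets <- as.data.frame(targets)
  if (nrow(targets) == 0L) return(net)
  stopifnot(all(c("multiplex", "node") %in% names(targets)))
  for (i in seq_len(nrow(targets))) {
    mx <- targets$multiplex[i]
    node <- targets$node[i]
    if (!mx %in% names(net$multiplexes) ||
        !node %in% net$multiplexes[[mx]]$nodes) {
      warnf("remove_nodes: unknown target %s/%s ignored", mx, node)
    }
  }
  by_mx <- split(targets$node, targets$multiplex)
  for (mx in names(by_mx)) {
    if (!mx %in% names(net$multiplexes)) next
    drop <- unique(by_mx[[mx]])
    mp <- net$multiplexes[[mx]]
    mp$nodes <- setdiff(mp$nodes, drop)
    mp$layers <- lapply(mp$layers, function(lay) {
      keep <- !(lay$edges$from %in% drop | lay$edges$to %in% drop)
      lay$edges <- lay$edges[keep, , drop = FALSE]
      rownames(lay$edges) <- NULL
      lay
    })
    net$multiplexes[[mx]] <- mp
    net$bipartites <- lapply(net$bipartites, function(bp) {
      keep <- rep(TRUE, nrow(bp$edges))
      if (bp$source_multiplex == mx) keep <- keep & !(bp$edges$from %in% drop)
      if (bp$target_multiplex == mx) keep <- keep & !(bp$edges$to %in% drop)
      bp$edges <- bp$edges[keep, , drop = FALSE]
      rownames(bp$edges) <- NULL
      bp
    })
  }
  net
}

#' Drop layers from a multilayer network
#'
#' Used to compare walks on the full network against a subset without,
#' e.g., the experimental co-expression layers. Node universes are kept
#' unchanged so results stay comparable node-for-node.
#'
#' @param net a `cnm_network`.
#' @param layers character vector of layer names to drop (layer names are
#'   assumed unique across the network, as in the reference composition).
#' @return The reduced `cnm_network`.
#' @export
drop_layers <- function(net, layers) {
  stopifnot(inherits(net, "cnm_network"))
  if (length(layers) == 0L) return(net)
  all_names <- unlist(lapply(net$multiplexes, function(mp) names(mp$layers)),
                      use.names = FALSE)
  missing <- setdiff(layers, all_names)
  if (length(missing)) stopf("drop_layers: unknown layer(s): %s",
                             paste(missing, collapse = ", "))
  for (mx in names(net$multiplexes)) {
    mp <- net$multiplexes[[mx]]
    keep <- setdiff(names(mp$layers), layers)
    if (length(keep) == 0L) {
      stopf("drop_layers: multiplex '%s' would be left with no layers", mx)
    }
    mp$layers <- mp$layers[keep]
    net$multiplexes[[mx]] <- mp
  }
  net
}

#' @export
print.cnm_network <- function(x, ...) {
  cat(sprintf("Multilayer network: %d multiplex(es), %d bipartite(s)\n",
              length(x$multiplexes), length(x$bipartites)))
  for (mp in x$multiplexes) {
    cat(sprintf("  %s: %d nodes, %d layer(s) [%s]\n", mp$name,
                length(mp$nodes), length(mp$layers),
                paste(names(mp$layers), collapse = ", ")))
  }
  for (bp in x$bipartites) {
    cat(sprintf("  %s: %s -> %s, %d edges%s\n", bp$name, bp$source_multiplex,
                bp$target_multiplex, nrow(bp$edges),
                if (bp$directed) " (directed)" else ""))
  }
  invisible(x)
}

#' @export
print.cnm_layer <- function(x, ...) {
  cat(sprintf("Layer '%s': %d nodes, %d edges%s%s\n", x$name,
              length(layer_nodes(x)), nrow(x$edges),
              if (x$weighted) ", weighted" else "",
              if (x$directed) ", directed" else ""))
  invisible(x)
}
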
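# Weighted co-expression arm: count filtering, median-of-ratios
# normalization, soft-power adjacency, topological overlap, module
# detection and merging, eigengenes, module-trait statistics, beneficial /
# pathogenic classification, and export of thresholded co-expression layers.

#' Filter lowly expressed features
#'
#' Keeps features whose raw count exceeds `min_count` in at least
#' `ceiling(min_fraction * n_samples)` samples (default: more than 10 reads
#' in at least 90% of samples). The sample set is unchanged.
#'
#' @param counts features x samples matrix of raw non-negative counts with
#'   feature row names.
#' @param min_count count a feature must exceed.
#' @param min_fraction fraction of samples in which it must do so.
#' @return The filtered count matrix (possibly with zero rows, with a
#'   warning).
#' @export
filter_features <- function(counts, min_count = 10, min_fraction = 0.9) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  need <- ceiling(min_fraction * ncol(counts))
  keep <- rowSums(counts > min_count) >= need
  if (!any(keep)) warnf("filter_features: no feature passed the filter")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios normalization with log transform
#'
#' Per-sample size factors are the median, over features with a finite
#' geometric mean (all counts nonzero), of the ratio count / geometric
#' mean. Each sample is divided by its size factor and, by default, the
#' result is log2(x + 1)-transformed for correlation work. When no feature
#' has all-nonzero counts, library-size factors (scaled to geometric mean
#' 1) are used instead, with a warning.
#'
#' @param counts features x samples matrix of raw counts, >= 2 samples.
#' @param log2 apply the log2(x + 1) transform (default `TRUE`).
#' @return Normalized matrix with attribute `"size_factors"`.
#' @export
size_factor_normalize <- function(counts, log2 = TRUE) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stopf("need at least 2 samples")
  lg <- log(counts)
  geo <- rowMeans(lg)
  use <- is.finite(geo)
  if (!any(use)) {
    warnf("no feature with all-nonzero counts; falling back to library-size factors")
    sf <- colSums(counts)
    sf <- sf / exp(mean(log(sf)))
  } else {
    ratios <- counts[use, , drop = FALSE] / exp(geo[use])
    sf <- apply(ratios, 2L, stats::median)
  }
  out <- sweep(counts, 2L, sf, "/")
  if (log2) out <- log2(out + 1)
  attr(out, "size_factors") <- sf
  out
}

#' Soft-thresholded adjacency
#'
#' Unsigned weighted-network adjacency `a_ij = |cor(x_i, x_j)|^power` with
#' unit diagonal. Zero-variance features get zero correlation with
#' everything, with a warning.
#'
#' @param expr features x samples matrix (normalized expression).
#' @param power soft-thresholding exponent (> 0).
#' @return Symmetric adjacency matrix with entries in \[0, 1\].
#' @export
soft_adjacency <- function(expr, power = 12) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stopf("need at least 3 samples")
  if (power <= 0) stopf("power must be positive")
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0)) {
    warnf("soft_adjacency: %d zero-variance feature(s); their correlations set to 0",
          sum(sds == 0))
  }
  cm <- suppressWarnings(stats::cor(t(expr)))
  cm[!is.finite(cm)] <- 0
  a <- pmin(abs(cm), 1)^power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k_i = sum_{u != i} a_iu` and unit diagonal; the clustering
#' dissimilarity is `1 - TOM`.
#'
#' @param adj symmetric adjacency in \[0, 1\] with unit diagonal.
#' @return The TOM matrix.
#' @export
topological_overlap <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj) || max(abs(adj - t(adj))) > 1e-8) {
    stopf("adjacency must be a symmetric square matrix")
  }
  if (min(adj) < -1e-12 || max(adj) > 1 + 1e-12) {
    stopf("adjacency entries must lie in [0, 1]")
  }
  A <- adj
  diag(A) <- 0
  k <- rowSums(A)
  shared <- A %*% A          # sum over u != i, j since diag(A) = 0
  tom <- (shared + A) / (outer(k, k, pmin) + 1 - A)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Scale-free fit diagnostic across candidate soft powers
#'
#' For each candidate power, computes the signed R^2 of the log-log
#' regression of the binned connectivity distribution, the usual guide for
#' choosing the soft power (a fit above `r2_target`, e.g. 0.8, indicates
#' approximate scale-free topology). The analysis pipeline itself takes an
#' explicit power; this is a diagnostic only.
#'
#' @param expr features x samples matrix.
#' @param powers candidate powers.
#' @param n_bins connectivity histogram bins.
#' @param r2_target target signed R^2.
#' @return Data frame (power, r_squared, mean_connectivity) with attribute
#'   `"chosen"`, the first power reaching the target (or `NA`).
#' @export
pick_soft_power <- function(expr, powers = c(1:10, 12, 14, 16, 18, 20),
                            n_bins = 10, r2_target = 0.8) {
  cm <- suppressWarnings(stats::cor(t(as.matrix(expr))))
  cm[!is.finite(cm)] <- 0
  acm <- pmin(abs(cm), 1)
  res <- lapply(powers, function(p) {
    a <- acm^p
    diag(a) <- 0
    k <- rowSums(a)
    ok <- k > 0
    r2 <- NA_real_
    if (sum(ok) > n_bins) {
      cuts <- cut(k[ok], breaks = n_bins)
      dk <- tapply(k[ok], cuts, mean)
      pk <- as.numeric(table(cuts)) / sum(ok)
      keep <- !is.na(dk) & pk > 0
      if (sum(keep) >= 3L) {
        fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
        r2 <- summary(fit)$r.squared * -sign(stats::coef(fit)[2L])
      }
    }
    data.frame(power = p, r_squared = r2, mean_connectivity = mean(k))
  })
  out <- do.call(rbind, res)
  hit <- which(!is.na(out$r_squared) & out$r_squared >= r2_target)
  attr(out, "chosen") <- if (length(hit)) out$power[hit[1L]] else NA_real_
  out
}

# Feature-wise z-scored matrix; constant features map to all-zero rows.
zscore_rows <- function(expr) {
  m <- rowMeans(expr)
  s <- apply(expr, 1L, stats::sd)
  z <- (expr - m) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  z
}

#' Module eigengenes
#'
#' Per module, the first principal component of the feature-wise z-scored
#' module submatrix, scaled to unit norm and sign-flipped so it correlates
#' non-negatively with the module's mean expression profile. A
#' single-feature module's eigengene is that feature's (unit-norm) z
#' profile. The reserved label `"grey"` (unassigned features) is skipped.
#'
#' @param expr features x samples matrix (normalized expression).
#' @param assignment named character vector mapping feature id to module
#'   label.
#' @return modules x samples matrix of eigengenes.
#' @export
module_eigengenes <- function(expr, assignment) {
  expr <- as.matrix(expr)
  feats <- rownames(expr)
  if (is.null(feats) || !all(feats %in% names(assignment))) {
    stopf("assignment must cover every feature of expr")
  }
  labels <- assignment[feats]
  mods <- setdiff(sort(unique(labels)), "grey")
  z <- zscore_rows(expr)
  me <- matrix(0, nrow = length(mods), ncol = ncol(expr),
               dimnames = list(mods, colnames(expr)))
  for (mod in mods) {
    X <- z[labels == mod, , drop = FALSE]
    if (nrow(X) == 1L) {
      e <- X[1L, ]
    } else {
      e <- svd(X, nu = 0L, nv = 1L)$v[, 1L]
    }
    nrm <- sqrt(sum(e^2))
    if (nrm > 0) e <- e / nrm
    ref <- colMeans(X)
    al <- suppressWarnings(stats::cor(e, ref))
    if ((!is.na(al) && al < 0) || (is.na(al) && sum(e * ref) < 0)) e <- -e
    me[mod, ] <- e
  }
  me
}

#' Detect co-expression modules by dynamic dendrogram cutting
#'
#' Features are clustered by average-linkage hierarchical clustering on the
#' TOM dissimilarity, and the dendrogram is cut top-down: a branch is split
#' into its two children when both are of module size and their branch
#' eigengenes are separable (correlation dissimilarity `1 - r` at least
#' `merge_threshold` — the exact complement of the merge criterion, so
#' cutting and merging cannot fight each other); loose joins (above the
#' static height `cut_height`) are always descended; what remains is an
#' initial module if it holds at least `min_module_size` features. Features
#' on no module branch are assigned to the module whose eigengene they
#' correlate with most, if that correlation exceeds `assign_threshold`
#' (by default the critical correlation at two-sided p = 0.01 for the
#' available sample size, so that rescue absorbs about 1% of null features
#' per module rather than a fixed fraction that balloons at small n),
#' else labelled `"grey"`. Modules whose eigengenes
#' have correlation dissimilarity (1 - r) below `merge_threshold` are then
#' merged iteratively, recomputing eigengenes after each merge, until
#' stable. Modules are labelled with conventional color names in decreasing
#' size order.
#'
#' @param dissimilarity square TOM-dissimilarity matrix aligned with the
#'   rows of `expr`.
#' @param expr features x samples matrix (normalized expression), used for
#'   eigengene computation.
#' @param min_module_size smallest branch kept as a module.
#' @param merge_threshold eigengene dissimilarity below which modules merge.
#' @param assign_threshold minimum eigengene correlation for rescuing an
#'   unassigned feature; `NULL` (default) uses the critical r at two-sided
#'   p = 0.01 given the sample size.
#' @param cut_height absolute dissimilarity above which a dendrogram join
#'   is considered loose and never kept as a module (TOM dissimilarities
#'   concentrate near 1, so the default is high).
#' @return Named character vector: feature id -> module label (`"grey"` for
#'   unassigned).
#' @export
detect_modules <- function(dissimilarity, expr, min_module_size = 30,
                           merge_threshold = 0.25, assign_threshold = NULL,
                           cut_height = 0.995) {
  dissimilarity <- as.matrix(dissimilarity)
  expr <- as.matrix(expr)
  n <- nrow(dissimilarity)
  if (n != ncol(dissimilarity) || n != nrow(expr)) {
    stopf("dissimilarity must be square and aligned with expr features")
  }
  feats <- rownames(expr) %||% paste0("f", seq_len(n))
  rownames(expr) <- feats
  labels <- stats::setNames(rep("grey", n), feats)
  if (min_module_size > n) {
    warnf("min_module_size exceeds the number of features; all features grey")
    return(labels)
  }
  h <- stats::hclust(stats::as.dist(dissimilarity), method = "average")
  branches <- cut_dendrogram(h, expr, min_module_size, merge_threshold,
                             cut_height)
  if (length(branches) == 0L) {
    warnf("no branch reached min_module_size; all features grey")
    return(labels)
  }
  for (bi in seq_along(branches)) {
    labels[branches[[bi]]] <- paste0("mod", bi)
  }
  if (is.null(assign_threshold)) {
    df <- ncol(expr) - 2L
    tc <- stats::qt(0.995, df)
    assign_threshold <- tc / sqrt(df + tc^2)
  }
  # Rescue unassigned features by (unsigned) eigengene correlation,
  # matching the unsigned network convention.
  if (any(labels == "grey")) {
    me <- module_eigengenes(expr, labels)
    z <- zscore_rows(expr)
    grey_idx <- which(labels == "grey")
    r <- abs(suppressWarnings(stats::cor(t(z[grey_idx, , drop = FALSE]),
                                         t(me))))
    r[!is.finite(r)] <- -Inf
    best <- max.col(r, ties.method = "first")
    rescued <- r[cbind(seq_along(grey_idx), best)] > assign_threshold
    labels[grey_idx[rescued]] <- rownames(me)[best[rescued]]
  }
  # Merge close modules, recomputing eigengenes after each merge.
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2L) break
    me <- module_eigengenes(expr, labels)
    dm <- 1 - suppressWarnings(stats::cor(t(me)))
    dm[!is.finite(dm)] <- Inf
    diag(dm) <- Inf
    if (min(dm) >= merge_threshold) break
    pair <- which(dm == min(dm), arr.ind = TRUE)[1L, ]
    a <- rownames(dm)[pair[1L]]
    b <- colnames(dm)[pair[2L]]
    labels[labels == b] <- a
  }
  relabel_modules(labels)
}

# Top-down dendrogram cut. Returns a list of leaf-index vectors, one per
# initial module. A branch splits when both children hold at least
# min_module_size leaves and their eigengenes are separable; joins higher
# than cut_height are always descended (their small side ends up
# unassigned); what remains is a module if large enough.
cut_dendrogram <- function(h, expr, min_module_size, merge_threshold,
                           cut_height) {
  nm <- nrow(h$merge)
  leafsets <- vector("list", nm)
  for (i in seq_len(nm)) {
    a <- h$merge[i, 1L]
    b <- h$merge[i, 2L]
    leafsets[[i]] <- c(if (a < 0L) -a else leafsets[[a]],
                       if (b < 0L) -b else leafsets[[b]])
  }
  leafset <- function(x) if (x < 0L) -x else leafsets[[x]]
  branch_eigengene <- function(idx) {
    X <- zscore_rows(expr[idx, , drop = FALSE])
    e <- if (length(idx) == 1L) X[1L, ] else svd(X, nu = 0L, nv = 1L)$v[, 1L]
    ref <- colMeans(X)
    if (sum(e * ref) < 0) e <- -e
    e
  }
  separable <- function(ia, ib) {
    r <- suppressWarnings(stats::cor(branch_eigengene(ia),
                                     branch_eigengene(ib)))
    is.na(r) || (1 - r) >= merge_threshold
  }
  rec <- function(node) {
    idx <- leafset(node)
    if (length(idx) < min_module_size) return(list())
    a <- h$merge[node, 1L]
    b <- h$merge[node, 2L]
    ia <- leafset(a)
    ib <- leafset(b)
    if (length(ia) >= min_module_size && length(ib) >= min_module_size &&
        separable(ia, ib)) {
      return(c(rec(a), rec(b)))
    }
    # No separable split at the root of this branch: look deeper in the big
    # child (the small side may be stragglers hiding a genuine split).
    big <- if (length(ia) >= length(ib)) a else b
    sub <- if (big > 0L) rec(big) else list()
    if (h$height[node] > cut_height) return(sub)  # loose join, never a module
    if (length(sub) >= 2L) return(sub)            # genuine split found deeper
    list(idx)
  }
  rec(nm)
}

# Conventional color labels in decreasing module-size order.
module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue")

relabel_modules <- function(labels) {
  mods <- setdiff(unique(labels), "grey")
  if (length(mods) == 0L) return(labels)
  sizes <- table(factor(labels[labels != "grey"], levels = mods))
  ord <- mods[order(-as.integer(sizes), mods)]
  pal <- module_palette
  if (length(ord) > length(pal)) {
    pal <- c(pal, paste0("module", seq_len(length(ord) - length(pal))))
  }
  map <- stats::setNames(pal[seq_along(ord)], ord)
  out <- ifelse(labels == "grey", "grey", map[labels])
  stats::setNames(out, names(labels))
}

#' Module-trait correlation statistics
#'
#' Pearson correlation of each module eigengene with each trait on
#' pairwise-complete samples; two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom;
#' Bonferroni adjustment over the number of traits,
#' `p_adjusted = min(1, p * n_traits)`. Constant traits yield rows with
#' missing statistics.
#'
#' @param eigengenes modules x samples matrix.
#' @param traits samples x traits matrix or data frame; row names must
#'   match the eigengene sample ids (missing values allowed).
#' @return Data frame (module, trait, r, p_value, p_adjusted, n_samples).
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  eigengenes <- as.matrix(eigengenes)
  traits <- as.matrix(traits)
  samples <- colnames(eigengenes)
  if (!is.null(samples) && !is.null(rownames(traits))) {
    if (!all(samples %in% rownames(traits))) {
      stopf("traits are missing sample(s): %s",
            paste(setdiff(samples, rownames(traits)), collapse = ", "))
    }
    traits <- traits[samples, , drop = FALSE]
  } else if (ncol(eigengenes) != nrow(traits)) {
    stopf("eigengene samples and trait rows do not align")
  }
  n_traits <- ncol(traits)
  out <- expand.grid(module = rownames(eigengenes), trait = colnames(traits),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats_rows <- mapply(function(mod, tr) {
    x <- eigengenes[mod, ]
    y <- traits[, tr]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 3L || stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0) {
      return(c(r = NA_real_, p = NA_real_, n = n))
    }
    r <- stats::cor(x[ok], y[ok])
    if (abs(r) >= 1) {
      p <- 0
    } else {
      t <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(t), df = n - 2)
    }
    c(r = r, p = p, n = n)
  }, out$module, out$trait)
  out$r <- stats_rows["r", ]
  out$p_value <- stats_rows["p", ]
  out$p_adjusted <- pmin(1, out$p_value * n_traits)
  out$n_samples <- as.integer(stats_rows["n", ])
  out
}

#' Classify modules as beneficial, pathogenic or unclassified
#'
#' A module is beneficial when it has at least one significant
#' (adjusted p < `alpha`) positive correlation with a functional-improvement
#' trait (normalized TA mass, relative maximal force, hanging time) and/or a
#' significant negative correlation with a pathology trait (percentage of
#' fibers with central nuclei, abnormal mitochondria, small diameter), with
#' no significant correlation of the opposite pattern. Pathogenic modules
#' show the mirrored pattern; everything else is unclassified.
#'
#' @param result data frame from [module_trait_correlation()].
#' @param alpha significance level on the adjusted p-value.
#' @param positive_traits traits whose positive correlation is beneficial.
#' @param negative_traits traits whose negative correlation is beneficial.
#' @return Named character vector: module -> `"beneficial"`, `"pathogenic"`
#'   or `"unclassified"`.
#' @export
classify_modules <- function(result, alpha = 0.05,
                             positive_traits = c("ta_mass", "max_force",
                                                 "hanging_time"),
                             negative_traits = c("central_nuclei",
                                                 "abnormal_mitochondria",
                                                 "small_fibers")) {
  wanted <- c(positive_traits, negative_traits)
  missing <- setdiff(wanted, unique(result$trait))
  if (length(missing)) {
    warnf("classification trait(s) not in results, skipped: %s",
          paste(missing, collapse = ", "))
    positive_traits <- setdiff(positive_traits, missing)
    negative_traits <- setdiff(negative_traits, missing)
  }
  res <- result[result$trait %in% c(positive_traits, negative_traits), ,
                drop = FALSE]
  mods <- sort(unique(result$module))
  out <- stats::setNames(rep("unclassified", length(mods)), mods)
  for (mod in mods) {
    rr <- res[res$module == mod, , drop = FALSE]
    sig <- !is.na(rr$p_adjusted) & rr$p_adjusted < alpha & !is.na(rr$r)
    ben <- any(sig & rr$trait %in% positive_traits & rr$r > 0) ||
      any(sig & rr$trait %in% negative_traits & rr$r < 0)
    path <- any(sig & rr$trait %in% positive_traits & rr$r < 0) ||
      any(sig & rr$trait %in% negative_traits & rr$r > 0)
    if (ben && !path) out[mod] <- "beneficial"
    if (path && !ben) out[mod] <- "pathogenic"
  }
  out
}

#' Export a thresholded co-expression layer
#'
#' Builds an undirected layer with one edge per unordered feature pair
#' whose TOM value exceeds `threshold`, with the TOM value as weight.
#' Reference presets (see [coexpression_presets()]): transcriptomic
#' power 10 / threshold 0.15, proteomic power 12 / threshold 0.25,
#' metabolomic power 5 / threshold 0.05.
#'
#' @param tom TOM matrix from [topological_overlap()], with row names.
#' @param threshold export threshold in \[0, 1).
#' @param weighted keep TOM values as weights (default) or export an
#'   unweighted layer.
#' @param name layer name.
#' @return A `cnm_layer`.
#' @export
export_coexpression_layer <- function(tom, threshold, weighted = TRUE,
                                      name = "coexpression") {
  tom <- as.matrix(tom)
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1) {
    stopf("threshold must lie in [0, 1)")
  }
  ids <- rownames(tom) %||% paste0("f", seq_len(nrow(tom)))
  idx <- which(upper.tri(tom) & tom > threshold, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]],
                      weight = tom[idx])
  layer(name, edges, directed = FALSE, weighted = weighted)
}

#' Co-expression layer presets
#'
#' Soft power and TOM export threshold presets for the transcriptomic,
#' proteomic, and metabolomic co-expression layers of the multilayer
#' network.
#'
#' @return Named list of `list(power, threshold)`.
#' @export
coexpression_presets <- function() {
  list(transcriptomic = list(power = 10, threshold = 0.15),
       proteomic = list(power = 12, threshold = 0.25),
       metabolomic = list(power = 5, threshold = 0.05))
}

#' Run the full co-expression analysis
#'
#' Chains filtering, normalization, soft adjacency, TOM, module detection,
#' eigengenes, module-trait correlation and classification; optionally
#' exports a thresholded co-expression layer (by default at the
#' transcriptomic preset).
#'
#' @param counts raw counts, features x samples.
#' @param traits samples x traits table (may be `NULL` to skip trait
#'   statistics).
#' @param power soft power for module detection.
#' @param min_module_size,merge_threshold see [detect_modules()].
#' @param min_count,min_fraction see [filter_features()].
#' @param alpha significance level for classification.
#' @param export list(power, threshold) to export a co-expression layer, or
#'   `NULL` to skip.
#' @return List with elements `normalized`, `assignment`, `eigengenes`,
#'   `module_trait`, `classification`, `layer`.
#' @export
run_coexpression <- function(counts, traits = NULL, power = 12,
                             min_module_size = 30, merge_threshold = 0.25,
                             min_count = 10, min_fraction = 0.9, alpha = 0.05,
                             export = coexpression_presets()$transcriptomic) {
  filtered <- filter_features(counts, min_count, min_fraction)
  norm <- size_factor_normalize(filtered)
  adj <- soft_adjacency(norm, power)
  tom <- topological_overlap(adj)
  assignment <- detect_modules(1 - tom, norm, min_module_size, merge_threshold)
  has_modules <- any(assignment != "grey")
  me <- if (has_modules) module_eigengenes(norm, assignment) else NULL
  mt <- NULL
  cls <- NULL
  if (!is.null(traits) && has_modules) {
    mt <- module_trait_correlation(me, traits)
    cls <- classify_modules(mt, alpha = alpha)
  }
  lay <- NULL
  if (!is.null(export)) {
    tom_exp <- if (identical(export$power, power)) tom else
      topological_overlap(soft_adjacency(norm, export$power))
    lay <- export_coexpression_layer(tom_exp, export$threshold,
                                     name = "gene_coexpression")
  }
  list(normalized = norm, assignment = assignment, eigengenes = me,
       module_trait = mt, classification = cls, layer = lay)
}
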
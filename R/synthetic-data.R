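# Generators for every input the pipeline needs, with ground truth
# returned alongside: count matrices with planted co-expression modules and
# group-averaged traits, metabolite abundance profiles, and multilayer
# networks with planted hub nodes.

#' Specification of a synthetic expression experiment
#'
#' Defaults emulate the cohort structure of the reference study: four
#' experimental groups (wild type, disease model, treated wild type,
#' treated disease model) of 6 mice each, three planted co-expression
#' modules of 50 features driven by latent factors with log2-scale noise sd
#' 0.3, negative-binomial counts at dispersion 0.1, and seven phenotypic
#' traits built from the module factors and then averaged within group (as
#' when individual phenotypes are unavailable and mice are assigned their
#' group mean).
#'
#' @param n_per_group samples per experimental group.
#' @param groups group labels.
#' @param modules list of module specs: `n_features`, `effect` (latent
#'   factor loading on the log2 scale), `noise_sd` (log2-scale feature
#'   noise), `group_shift` (named per-group offsets added to the factor),
#'   and `prop_positive` (fraction of features loading with positive sign,
#'   default 0.7 — modules mix up- and down-regulated members, which also
#'   keeps median-of-ratios normalization unbiased). `NULL` for the default
#'   three modules.
#' @param n_background_features features driven by no factor.
#' @param base_mean_range range of baseline mean counts.
#' @param lib_size_range range of per-sample library-size factors.
#' @param dispersion negative-binomial dispersion (`size = 1/dispersion`).
#' @param traits list of trait specs: `module` (linked module name), `rho`
#'   (target correlation with the factor, sign included). `NULL` for seven
#'   defaults covering masses, force, hanging time and histology fractions.
#' @param rng_seed integer seed; generation is bit-reproducible given it.
#' @return A list of class `cnm_expr_spec`.
#' @export
expression_sim_spec <- function(n_per_group = 6L,
                                groups = c("WT", "disease", "WT_treated",
                                           "disease_treated"),
                                modules = NULL,
                                n_background_features = 300L,
                                base_mean_range = c(50, 500),
                                lib_size_range = c(0.7, 1.3),
                                dispersion = 0.1,
                                traits = NULL,
                                rng_seed = 1L) {
  if (is.null(modules)) {
    shift <- function(...) stats::setNames(c(...), groups)
    # Effect 2 makes the realized within-module log2 correlation ~0.9
    # (strong co-expression) after negative-binomial sampling noise, which
    # adds substantial log2-scale variance on top of noise_sd.
    modules <- list(
      M1 = list(n_features = 50L, effect = 2, noise_sd = 0.3,
                group_shift = shift(0, 1, 0, 0.3)[groups]),
      M2 = list(n_features = 50L, effect = 2, noise_sd = 0.3,
                group_shift = shift(0, -1, 0, -0.3)[groups]),
      M3 = list(n_features = 50L, effect = 2, noise_sd = 0.3,
                group_shift = shift(0, 0, 0, 0)[groups]))
  }
  for (m in names(modules)) {
    mod <- modules[[m]]
    if (is.null(mod$group_shift)) modules[[m]]$group_shift <-
        stats::setNames(rep(0, length(groups)), groups)
    if (is.null(mod$prop_positive)) modules[[m]]$prop_positive <- 0.7
    if (mod$effect < 0) stopf("module '%s': effect must be >= 0", m)
  }
  if (is.null(traits)) {
    traits <- list(
      body_mass = list(module = "M3", rho = 0.5),
      ta_mass = list(module = "M1", rho = 0.6),
      max_force = list(module = "M1", rho = 0.6),
      hanging_time = list(module = "M1", rho = 0.5),
      central_nuclei = list(module = "M2", rho = 0.6),
      abnormal_mitochondria = list(module = "M2", rho = 0.5),
      small_fibers = list(module = "M2", rho = 0.5))
  }
  for (tr in names(traits)) {
    rho <- traits[[tr]]$rho
    if (abs(rho) >= 1) stopf("trait '%s': rho must lie in (-1, 1)", tr)
    if (!traits[[tr]]$module %in% names(modules)) {
      stopf("trait '%s' linked to unknown module '%s'", tr, traits[[tr]]$module)
    }
  }
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 modules = modules,
                 n_background_features = as.integer(n_background_features),
                 base_mean_range = base_mean_range,
                 lib_size_range = lib_size_range, dispersion = dispersion,
                 traits = traits, rng_seed = as.integer(rng_seed)),
            class = "cnm_expr_spec")
}

#' Simulate counts with planted modules and group-averaged traits
#'
#' Per module, a latent factor is drawn standard normal over samples and
#' shifted by the module's per-group offsets. Each module feature's log2
#' mean is `log2(baseline) + effect * factor + N(0, noise_sd)`; counts are
#' negative binomial around the mean scaled by a per-sample library-size
#' factor. Traits are built as `rho * z(factor) + sqrt(1 - rho^2) * noise`,
#' then replaced by their within-group average so they are constant within
#' each experimental group; when group averaging destroys the target
#' correlation (achieved value below half the target, or sign flipped) a
#' warning reports the achieved correlation.
#'
#' @param spec an [expression_sim_spec()].
#' @return List with `counts` (integer matrix, features x samples),
#'   `traits` (samples x traits matrix, group-constant), `sample_groups`
#'   (named character vector), `truth` (named feature -> module vector,
#'   background features labelled `"grey"`), `factors` (samples x modules),
#'   and `achieved_rho` (per trait, after group averaging).
#' @export
simulate_expression_with_traits <- function(spec = expression_sim_spec()) {
  stopifnot(inherits(spec, "cnm_expr_spec"))
  with_rng(spec$rng_seed, {
    groups <- rep(spec$groups, each = spec$n_per_group)
    n <- length(groups)
    samples <- sprintf("s%02d", seq_len(n))
    names(groups) <- samples

    mods <- names(spec$modules)
    factors <- matrix(0, nrow = n, ncol = length(mods),
                      dimnames = list(samples, mods))
    for (m in mods) {
      factors[, m] <- stats::rnorm(n) + spec$modules[[m]]$group_shift[groups]
    }

    n_feat <- sum(vapply(spec$modules, `[[`, numeric(1L), "n_features")) +
      spec$n_background_features
    feats <- sprintf("g%04d", seq_len(n_feat))
    truth <- stats::setNames(rep("grey", n_feat), feats)
    lib <- stats::runif(n, spec$lib_size_range[1L], spec$lib_size_range[2L])
    base <- stats::runif(n_feat, spec$base_mean_range[1L],
                         spec$base_mean_range[2L])
    log2mu <- matrix(rep(log2(base), n), nrow = n_feat)
    row <- 0L
    for (m in mods) {
      mod <- spec$modules[[m]]
      idx <- row + seq_len(mod$n_features)
      truth[idx] <- m
      sgn <- ifelse(stats::runif(mod$n_features) < mod$prop_positive, 1, -1)
      signal <- outer(sgn * mod$effect, factors[, m])
      log2mu[idx, ] <- log2mu[idx, , drop = FALSE] + signal +
        matrix(stats::rnorm(mod$n_features * n, 0, mod$noise_sd),
               nrow = mod$n_features)
      row <- row + mod$n_features
    }
    if (spec$n_background_features > 0L) {
      idx <- row + seq_len(spec$n_background_features)
      log2mu[idx, ] <- log2mu[idx, , drop = FALSE] +
        matrix(stats::rnorm(spec$n_background_features * n, 0, 0.3),
               nrow = spec$n_background_features)
    }
    mu <- sweep(2^log2mu, 2L, lib, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / spec$dispersion),
                     nrow = n_feat, dimnames = list(feats, samples))

    trait_names <- names(spec$traits)
    traits <- matrix(NA_real_, nrow = n, ncol = length(trait_names),
                     dimnames = list(samples, trait_names))
    achieved <- stats::setNames(numeric(length(trait_names)), trait_names)
    for (tr in trait_names) {
      ts <- spec$traits[[tr]]
      f <- as.numeric(scale(factors[, ts$module]))
      raw <- ts$rho * f + sqrt(1 - ts$rho^2) * stats::rnorm(n)
      avg <- stats::ave(raw, groups)
      traits[, tr] <- avg
      achieved[tr] <- if (stats::sd(avg) == 0) 0 else stats::cor(avg, f)
      if (sign(achieved[tr]) != sign(ts$rho) ||
          abs(achieved[tr]) < abs(ts$rho) / 2) {
        warnf("trait '%s': group averaging gives achieved correlation %.2f (target %.2f)",
              tr, achieved[tr], ts$rho)
      }
    }
    list(counts = counts, traits = traits, sample_groups = groups,
         truth = truth, factors = factors, achieved_rho = achieved)
  })
}

#' Specification of a synthetic multilayer network
#'
#' The default mirrors the reference composition at toy scale: a gene
#' multiplex of five layers (protein-protein interaction, complex
#' co-membership, pathway co-membership, and two weighted co-expression
#' layers), a two-layer metabolite multiplex, a directed reaction monoplex,
#' a phenotype monoplex generated as a random DAG with child-to-parent
#' edges (like an ontology), isolated tissue nodes connected only through
#' bipartites, and eight bipartites (gene-metabolite, gene-reaction,
#' directed metabolite-to-reaction and reaction-to-metabolite,
#' weighted gene-tissue, gene-phenotype, metabolite-tissue,
#' phenotype-tissue), plus one planted gene hub wired to half the gene
#' nodes in every gene layer.
#'
#' @param multiplexes per-multiplex spec: `n_nodes`, `prefix` (node id
#'   prefix), and `layers`, a named list of `density`, `weighted`,
#'   `directed`, `dag` entries. `NULL` for the default.
#' @param bipartites named list of `source`, `target`, `density`,
#'   `weighted`, `directed`. `NULL` for the default eight.
#' @param hubs list of planted hubs: `multiplex`, `fraction` of the
#'   multiplex's other nodes each hub is wired to in every layer, `n_hubs`.
#' @param rng_seed integer seed.
#' @return A list of class `cnm_net_spec`.
#' @export
network_sim_spec <- function(multiplexes = NULL, bipartites = NULL,
                             hubs = list(list(multiplex = "genes",
                                              fraction = 0.5, n_hubs = 1L)),
                             rng_seed = 1L) {
  if (is.null(multiplexes)) {
    multiplexes <- list(
      genes = list(n_nodes = 100L, prefix = "g", layers = list(
        ppi = list(density = 0.05),
        complex_comembership = list(density = 0.05),
        pathway_comembership = list(density = 0.08),
        gene_coexpression = list(density = 0.10, weighted = TRUE),
        protein_coexpression = list(density = 0.10, weighted = TRUE))),
      metabolites = list(n_nodes = 60L, prefix = "m", layers = list(
        pathway_comembership = list(density = 0.08),
        metabolite_coexpression = list(density = 0.12, weighted = TRUE))),
      reactions = list(n_nodes = 80L, prefix = "r", layers = list(
        subsystem = list(density = 0.05, directed = TRUE))),
      phenotypes = list(n_nodes = 60L, prefix = "HP:", layers = list(
        ontology = list(dag = TRUE))),
      tissues = list(n_nodes = 15L, prefix = "tissue_", layers = list(
        tissue = list(density = 0))))
  }
  if (is.null(bipartites)) {
    bipartites <- list(
      genes_metabolites = list(source = "genes", target = "metabolites",
                               density = 0.02),
      genes_reactions = list(source = "genes", target = "reactions",
                             density = 0.02),
      metabolites_reactions = list(source = "metabolites",
                                   target = "reactions", density = 0.02,
                                   directed = TRUE),
      reactions_metabolites = list(source = "reactions",
                                   target = "metabolites", density = 0.02,
                                   directed = TRUE),
      genes_tissues = list(source = "genes", target = "tissues",
                           density = 0.10, weighted = TRUE),
      genes_phenotypes = list(source = "genes", target = "phenotypes",
                              density = 0.03),
      metabolites_tissues = list(source = "metabolites", target = "tissues",
                                 density = 0.05),
      phenotypes_tissues = list(source = "phenotypes", target = "tissues",
                                density = 0.05))
  }
  for (b in names(bipartites)) {
    bp <- bipartites[[b]]
    if (!bp$source %in% names(multiplexes) ||
        !bp$target %in% names(multiplexes)) {
      stopf("bipartite '%s' references an unknown multiplex", b)
    }
  }
  for (h in hubs) {
    if (!h$multiplex %in% names(multiplexes)) {
      stopf("planted hub references unknown multiplex '%s'", h$multiplex)
    }
    if (h$fraction <= 0 || h$fraction > 1) stopf("hub fraction must lie in (0, 1]")
  }
  structure(list(multiplexes = multiplexes, bipartites = bipartites,
                 hubs = hubs, rng_seed = as.integer(rng_seed)),
            class = "cnm_net_spec")
}

# m distinct undirected pairs over n nodes, decoded from a uniform draw of
# linear indices over the n(n-1)/2 pairs (i < j).
er_pairs <- function(n, m, directed = FALSE) {
  if (m <= 0L || n < 2L) {
    return(data.frame(i = integer(), j = integer()))
  }
  if (directed) {
    total <- n * (n - 1)
    idx <- sample.int(total, min(m, total))
    i <- (idx - 1L) %/% (n - 1L) + 1L
    off <- (idx - 1L) %% (n - 1L) + 1L
    j <- off + (off >= i)
  } else {
    total <- n * (n - 1) / 2
    idx <- sample.int(total, min(m, total))
    j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
    i <- idx - (j - 1) * (j - 2) / 2
  }
  data.frame(i = as.integer(i), j = as.integer(j))
}

#' Simulate a multilayer network with planted hubs
#'
#' Each layer is an Erdos-Renyi graph at its density (weights uniform on
#' \[0.1, 1\] for weighted layers); planted hubs are additionally wired to
#' the stated fraction of their multiplex's other nodes in every layer;
#' phenotype-style layers are random DAGs with edges directed from child to
#' parent; bipartites are random at their density.
#'
#' @param spec a [network_sim_spec()].
#' @return List with `network` (a `cnm_network`), `hubs` (data frame
#'   multiplex/node of planted hubs), and `spec`.
#' @export
simulate_multilayer <- function(spec = network_sim_spec()) {
  stopifnot(inherits(spec, "cnm_net_spec"))
  with_rng(spec$rng_seed, {
    node_ids <- lapply(names(spec$multiplexes), function(mx) {
      blk <- spec$multiplexes[[mx]]
      sprintf("%s%04d", blk$prefix %||% paste0(mx, "_"),
              seq_len(blk$n_nodes))
    })
    names(node_ids) <- names(spec$multiplexes)

    hub_tab <- do.call(rbind, lapply(spec$hubs, function(h) {
      data.frame(multiplex = h$multiplex,
                 node = sample(node_ids[[h$multiplex]], h$n_hubs %||% 1L),
                 fraction = h$fraction, stringsAsFactors = FALSE)
    })) %||% data.frame(multiplex = character(), node = character(),
                        fraction = numeric())

    mpx <- lapply(names(spec$multiplexes), function(mx) {
      blk <- spec$multiplexes[[mx]]
      ids <- node_ids[[mx]]
      n <- length(ids)
      hubs_here <- hub_tab[hub_tab$multiplex == mx, , drop = FALSE]
      lays <- lapply(names(blk$layers), function(lname) {
        lb <- blk$layers[[lname]]
        weighted <- isTRUE(lb$weighted)
        directed <- isTRUE(lb$directed)
        if (isTRUE(lb$dag)) {
          # Random ontology-like DAG: each node (except the root) points to
          # 1-2 parents that come earlier in a fixed topological order.
          ord <- sample.int(n)
          edges <- do.call(rbind, lapply(2:n, function(v) {
            np <- sample.int(min(2L, v - 1L), 1L)
            data.frame(from = ids[ord[v]],
                       to = ids[ord[sample.int(v - 1L, np)]])
          }))
          directed <- TRUE
          ew <- NULL
        } else {
          mcount <- if (directed) {
            round(lb$density * n * (n - 1))
          } else {
            round(lb$density * n * (n - 1) / 2)
          }
          pr <- er_pairs(n, mcount, directed = directed)
          edges <- data.frame(from = ids[pr$i], to = ids[pr$j])
        }
        # Planted hubs: wire to fraction * (n - 1) distinct other nodes.
        for (hi in seq_len(nrow(hubs_here))) {
          hub <- hubs_here$node[hi]
          others <- setdiff(ids, hub)
          deg <- round(hubs_here$fraction[hi] * length(others))
          tgt <- sample(others, deg)
          edges <- rbind(edges, data.frame(from = hub, to = tgt))
        }
        if (nrow(edges)) {
          # Canonicalize and dedupe here so constructors stay silent.
          if (!directed) {
            lo <- pmin(edges$from, edges$to)
            hi_ <- pmax(edges$from, edges$to)
            edges$from <- lo
            edges$to <- hi_
          }
          edges <- edges[edges$from != edges$to, , drop = FALSE]
          edges <- edges[!duplicated(paste(edges$from, edges$to)), ,
                         drop = FALSE]
          if (weighted) edges$weight <- stats::runif(nrow(edges), 0.1, 1)
        }
        layer(lname, edges, directed = directed, weighted = weighted)
      })
      multiplex(mx, lays, nodes = ids)
    })

    bps <- lapply(names(spec$bipartites), function(bname) {
      bb <- spec$bipartites[[bname]]
      src <- node_ids[[bb$source]]
      tgt <- node_ids[[bb$target]]
      mcount <- round((bb$density %||% 0.02) * length(src) * length(tgt))
      idx <- sample.int(length(src) * length(tgt), mcount)
      i <- (idx - 1L) %% length(src) + 1L
      j <- (idx - 1L) %/% length(src) + 1L
      edges <- data.frame(from = src[i], to = tgt[j])
      if (isTRUE(bb$weighted)) edges$weight <- stats::runif(nrow(edges), 0.1, 1)
      bipartite(bname, bb$source, bb$target, edges,
                directed = isTRUE(bb$directed), weighted = isTRUE(bb$weighted))
    })

    list(network = multilayer_network(mpx, bps),
         hubs = hub_tab[, c("multiplex", "node")], spec = spec)
  })
}

#' Benchmark network for the hub-detection null
#'
#' Study conditions for validating the top-50/5% hub rule. By the occupancy
#' identity (summed occurrence counts equal `top_k` times the number of
#' iterations) the mean top-50 occupancy of a gene is `50 / n_genes`, so the
#' candidate pool must be much larger than 1000 genes for the 5% rule to be
#' a meaningful null; this benchmark uses 3000 gene nodes (mean occupancy
#' 1.7%) in two gene layers, a two-layer metabolite multiplex, an
#' ontology-like phenotype monoplex, and one planted hub wired to half of
#' the gene nodes in every gene layer.
#'
#' @param rng_seed integer seed.
#' @param hub_fraction fraction of gene nodes the planted hub is wired to.
#' @return A [network_sim_spec()].
#' @export
hub_benchmark_spec <- function(rng_seed = 1L, hub_fraction = 0.5) {
  network_sim_spec(
    multiplexes = list(
      genes = list(n_nodes = 3000L, prefix = "g", layers = list(
        ppi = list(density = 0.004),
        gene_coexpression = list(density = 0.004, weighted = TRUE))),
      metabolites = list(n_nodes = 400L, prefix = "m", layers = list(
        pathway_comembership = list(density = 0.01),
        metabolite_coexpression = list(density = 0.01, weighted = TRUE))),
      phenotypes = list(n_nodes = 150L, prefix = "HP:", layers = list(
        ontology = list(dag = TRUE)))),
    bipartites = list(
      genes_metabolites = list(source = "genes", target = "metabolites",
                               density = 0.002),
      genes_phenotypes = list(source = "genes", target = "phenotypes",
                              density = 0.002)),
    hubs = list(list(multiplex = "genes", fraction = hub_fraction,
                     n_hubs = 1L)),
    rng_seed = rng_seed)
}

#' Simulate metabolite abundance profiles with co-abundance blocks
#'
#' Log-normal abundances: per block, a latent factor drives the block's
#' metabolites on the log2 scale, with independent noise; remaining
#' metabolites are background. Suitable for co-expression layer export at
#' the metabolomic preset (soft power 5, threshold 0.05).
#'
#' @param n_metabolites total number of metabolites.
#' @param n_samples number of samples.
#' @param blocks list of block specs (`n`, `effect`, `noise_sd`).
#' @param base_log2_range range of baseline log2 abundances.
#' @param rng_seed integer seed.
#' @return List with `abundance` (metabolites x samples, positive) and
#'   `truth` (named metabolite -> block vector, `"grey"` for background).
#' @export
simulate_metabolite_profiles <- function(n_metabolites = 60L,
                                         n_samples = 12L,
                                         blocks = list(
                                           B1 = list(n = 15L, effect = 1,
                                                     noise_sd = 0.3),
                                           B2 = list(n = 15L, effect = 1,
                                                     noise_sd = 0.3)),
                                         base_log2_range = c(10, 20),
                                         rng_seed = 1L) {
  n_block <- sum(vapply(blocks, `[[`, numeric(1L), "n"))
  if (n_block > n_metabolites) stopf("blocks exceed n_metabolites")
  with_rng(rng_seed, {
    ids <- sprintf("met%03d", seq_len(n_metabolites))
    truth <- stats::setNames(rep("grey", n_metabolites), ids)
    base <- stats::runif(n_metabolites, base_log2_range[1L],
                         base_log2_range[2L])
    lg <- matrix(rep(base, n_samples), nrow = n_metabolites)
    row <- 0L
    for (b in names(blocks)) {
      blk <- blocks[[b]]
      f <- stats::rnorm(n_samples)
      idx <- row + seq_len(blk$n)
      truth[idx] <- b
      lg[idx, ] <- lg[idx, , drop = FALSE] +
        outer(rep(blk$effect, blk$n), f) +
        matrix(stats::rnorm(blk$n * n_samples, 0, blk$noise_sd),
               nrow = blk$n)
      row <- row + blk$n
    }
    if (row < n_metabolites) {
      idx <- (row + 1L):n_metabolites
      lg[idx, ] <- lg[idx, , drop = FALSE] +
        matrix(stats::rnorm(length(idx) * n_samples, 0, 0.3),
               nrow = length(idx))
    }
    abundance <- 2^lg
    dimnames(abundance) <- list(ids, sprintf("s%02d", seq_len(n_samples)))
    list(abundance = abundance, truth = truth)
  })
}
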
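# Config-driven orchestration: simulate -> co-expression -> network
# assembly -> hub scan -> joint-seed exploration, with a machine-readable
# run manifest.

write_tsv <- function(x, path, row_names = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = row_names,
                     col.names = if (row_names) NA else TRUE)
  path
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in order, writing each stage's outputs
#' before the next starts, and records a run manifest (stage, outputs, md5
#' checksums, wall time) plus a `run_manifest.yaml` echoing every
#' parameter, including defaulted ones, so a run can be re-executed
#' bit-identically. Stage RNG seeds are derived from the global `rng_seed`
#' by fixed offsets.
#'
#' Stages and their parameter blocks:
#' \describe{
#'   \item{simulate_expression}{arguments of [expression_sim_spec()]}
#'   \item{coexpression}{arguments of [run_coexpression()]}
#'   \item{simulate_network}{arguments of [network_sim_spec()]}
#'   \item{hub_scan}{`n_iterations`, `top_k_levels`, `hub_top_k`,
#'     `hub_fraction`, `seed_multiplex`, `drop_layers`, `restart_r`}
#'   \item{explore}{`gene_seed`, `phenotype_seed` (node ids), `top_n`,
#'     `restart_r`, `use_pruned`}
#' }
#'
#' @param config path to a YAML run configuration, or an equivalent list
#'   with `out_dir`, `rng_seed`, `stages`, and per-stage blocks.
#' @return Invisibly, a list with `manifest` (data frame) and the fully
#'   defaulted `config`. Aborts naming the failing stage on error; outputs
#'   of completed stages are retained.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stopf("config needs 'out_dir'")
  seed <- as.integer(config$rng_seed %||% 1L)
  stages <- config$stages %||% c("simulate_expression", "coexpression",
                                 "simulate_network", "hub_scan", "explore")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  state <- new.env(parent = emptyenv())

  record <- function(stage, paths, secs) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, output = basename(paths),
      md5 = unname(tools::md5sum(paths)), seconds = round(secs, 3))
  }
  run_stage <- function(stage, fun) {
    t0 <- proc.time()[["elapsed"]]
    paths <- tryCatch(fun(), error = function(e) {
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    })
    record(stage, paths, proc.time()[["elapsed"]] - t0)
  }

  for (stage in stages) {
    prm <- config[[stage]] %||% list()
    if (stage == "simulate_expression") {
      run_stage(stage, function() {
        spec <- do.call(expression_sim_spec,
                        c(prm, list(rng_seed = seed)))
        config[[stage]] <<- spec[setdiff(names(spec), "rng_seed")]
        sim <- simulate_expression_with_traits(spec)
        state$sim_expr <- sim
        c(write_tsv(sim$counts, file.path(out_dir, "counts.tsv"),
                    row_names = TRUE),
          write_tsv(sim$traits, file.path(out_dir, "traits.tsv"),
                    row_names = TRUE),
          write_tsv(data.frame(sample = names(sim$sample_groups),
                               group = sim$sample_groups),
                    file.path(out_dir, "sample_groups.tsv")),
          write_tsv(data.frame(feature = names(sim$truth),
                               module = sim$truth),
                    file.path(out_dir, "truth_modules.tsv")))
      })
    } else if (stage == "coexpression") {
      run_stage(stage, function() {
        counts <- state$sim_expr$counts %||%
          as.matrix(utils::read.delim(prm$counts %||%
                                        file.path(out_dir, "counts.tsv"),
                                      row.names = 1L, check.names = FALSE))
        traits <- state$sim_expr$traits %||%
          as.matrix(utils::read.delim(prm$traits %||%
                                        file.path(out_dir, "traits.tsv"),
                                      row.names = 1L, check.names = FALSE))
        args <- prm[setdiff(names(prm), c("counts", "traits"))]
        res <- do.call(run_coexpression,
                       c(list(counts = counts, traits = traits), args))
        state$coexpr <- res
        paths <- c(
          write_tsv(data.frame(feature = names(res$assignment),
                               module = res$assignment),
                    file.path(out_dir, "modules.tsv")),
          write_tsv(res$eigengenes, file.path(out_dir, "eigengenes.tsv"),
                    row_names = TRUE))
        if (!is.null(res$module_trait)) {
          paths <- c(paths,
                     write_tsv(res$module_trait,
                               file.path(out_dir, "module_trait.tsv")),
                     write_tsv(data.frame(module = names(res$classification),
                                          class = res$classification),
                               file.path(out_dir, "classification.tsv")))
        }
        if (!is.null(res$layer)) {
          p <- file.path(out_dir, "coexpression_layer.tsv")
          write_layer_edges(res$layer, p)
          paths <- c(paths, p)
        }
        paths
      })
    } else if (stage == "simulate_network") {
      run_stage(stage, function() {
        spec <- do.call(network_sim_spec,
                        c(prm, list(rng_seed = seed + 1L)))
        sim <- simulate_multilayer(spec)
        state$net <- sim$network
        state$planted_hubs <- sim$hubs
        net_dir <- file.path(out_dir, "network")
        man <- write_network(sim$network, net_dir,
                             rwr = list(restart_r = 0.7))
        c(man, write_tsv(sim$hubs, file.path(out_dir, "planted_hubs.tsv")))
      })
    } else if (stage == "hub_scan") {
      run_stage(stage, function() {
        net <- state$net %||%
          assemble_network(file.path(out_dir, "network", "manifest.yaml"))
        seed_mx <- prm$seed_multiplex %||% "genes"
        pool <- data.frame(multiplex = seed_mx,
                           node = net$multiplexes[[seed_mx]]$nodes)
        cfg <- hub_scan_config(
          pool,
          n_iterations = prm$n_iterations %||% 200L,
          top_k_levels = prm$top_k_levels %||% c(10L, 50L, 100L),
          hub_top_k = prm$hub_top_k %||% 50L,
          hub_fraction = prm$hub_fraction %||% 0.05,
          rng_seed = seed + 2L)
        rcfg <- rwr_config(restart_r = prm$restart_r %||% 0.7)
        if (!is.null(prm$drop_layers)) {
          scan <- full_vs_subset_scan(net, prm$drop_layers, cfg, rcfg)
          report <- scan$full
          extra <- c(write_tsv(scan$paired,
                               file.path(out_dir, "paired_counts.tsv")),
                     write_tsv(scan$correlations,
                               file.path(out_dir, "paired_correlations.tsv")))
        } else {
          report <- random_seed_scan(net, cfg, rcfg)
          extra <- character(0L)
        }
        hubs <- detect_hubs(report)
        state$hubs <- hubs
        pruned <- remove_nodes(net, hubs)
        state$pruned_net <- pruned
        c(write_tsv(report$counts, file.path(out_dir, "hub_occurrences.tsv")),
          write_tsv(hubs, file.path(out_dir, "hubs.tsv")),
          extra)
      })
    } else if (stage == "explore") {
      run_stage(stage, function() {
        net <- state$pruned_net %||% state$net %||%
          assemble_network(file.path(out_dir, "network", "manifest.yaml"))
        gene_mx <- prm$gene_multiplex %||% "genes"
        phen_mx <- prm$phenotype_multiplex %||% "phenotypes"
        gseed <- prm$gene_seed %||% net$multiplexes[[gene_mx]]$nodes[1L]
        pseed <- prm$phenotype_seed %||% net$multiplexes[[phen_mx]]$nodes[1L]
        q <- joint_seed_query(
          net, node_ref(gene_mx, gseed), node_ref(phen_mx, pseed),
          top_n = prm$top_n %||% 20L,
          rwr_config = rwr_config(restart_r = prm$restart_r %||% 0.7),
          categories = prm$categories %||% c(gene_mx, "metabolites"))
        paths <- character(0L)
        for (cat_ in names(q$top)) {
          p <- file.path(out_dir, sprintf("top_%s.tsv", cat_))
          paths <- c(paths, write_tsv(q$top[[cat_]], p))
        }
        paths
      })
    } else {
      stopf("unknown pipeline stage '%s'", stage)
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  config$stages <- stages
  config$rng_seed <- seed
  yaml::write_yaml(list(config = config,
                        outputs = lapply(seq_len(nrow(manifest)), function(i)
                          as.list(manifest[i, ]))),
                   file.path(out_dir, "run_manifest.yaml"))
  write_tsv(manifest, file.path(out_dir, "run_manifest.tsv"))
  invisible(list(manifest = manifest, config = config))
}
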
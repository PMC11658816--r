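#' Full-run configuration
#'
#' Collects every threshold of the pipeline with the method's canonical
#' defaults: DMP FDR `alpha` 1e-4, DMR `max_gap` 300 bp and `min_probes` 8,
#' peripheral `fraction` 0.95, entropy-null `subset_size` 100 and `n_iter`
#' 1000, pathway comparison `n_graphs` 100 / `n_resample` 10000 / `ci` 0.89,
#' cis `window` 1 Mb, direct-edge `z_threshold` 2. The resolved
#' configuration is echoed into every run manifest.
#'
#' @param seed Master seed for all stochastic stages.
#' @param sim A [simulation_config()] (the simulate stage's input).
#' @param alpha,max_gap,min_probes,n_perm DMP / DMR thresholds.
#' @param cluster_min_size,fraction Hypergraph central-cluster controls.
#' @param subset_size,n_iter,entropy_max_background Entropy-null controls.
#' @param n_graphs,n_resample,ci,pathway_max_background Pathway-entropy
#'   controls.
#' @param z_threshold,window Silencing edge controls.
#' @param nmf_rank NMF rank for the validation stage.
#' @param stages Character vector of stage toggles; subset of
#'   `c("dmr", "entropy", "pathway", "silencing", "nmf", "enrichment")`
#'   (simulate/preprocess/dmp always run).
#' @param max_dmps Cap on the number of DMPs used as hypergraph vertices
#'   (strongest effects kept) so desk-scale runs stay tractable.
#' @return List of class `RunConfig`.
#' @export
run_config <- function(seed = 1,
                       sim = simulation_config(seed = seed),
                       alpha = 1e-4, max_gap = 300, min_probes = 8,
                       n_perm = 200,
                       cluster_min_size = 10, fraction = 0.95,
                       subset_size = 100, n_iter = 1000,
                       entropy_max_background = 2000,
                       n_graphs = 100, n_resample = 10000, ci = 0.89,
                       pathway_max_background = 500,
                       z_threshold = 2, window = 1000000,
                       nmf_rank = 2,
                       stages = c("dmr", "entropy", "silencing", "nmf"),
                       max_dmps = 500) {
  cfg <- as.list(environment())
  stopifnot(alpha > 0, alpha < 1, max_gap > 0, min_probes >= 2,
            fraction > 0, fraction < 1, ci > 0, ci < 1,
            window > 0, z_threshold > 0)
  structure(cfg, class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Top-level keys are [run_config()] arguments; the optional `sim` mapping
#' holds [simulation_config()] arguments. Unknown keys are an error so
#' typos in threshold names cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim
  raw$sim <- NULL
  known <- names(formals(run_config))
  if (length(setdiff(names(raw), known)) > 0) {
    .ec_stop("unknown run_config keys: %s",
             paste(setdiff(names(raw), known), collapse = ", "))
  }
  if (!is.null(sim_args)) {
    known_sim <- names(formals(simulation_config))
    if (length(setdiff(names(sim_args), known_sim)) > 0) {
      .ec_stop("unknown simulation_config keys: %s",
               paste(setdiff(names(sim_args), known_sim), collapse = ", "))
    }
    if (!is.null(sim_args$loading_strength)) {
      sim_args$loading_strength <- unlist(sim_args$loading_strength)
    }
    if (!is.null(sim_args$flag_fraction)) {
      sim_args$flag_fraction <- unlist(sim_args$flag_fraction)
    }
    if (!is.null(sim_args$dmr_specs)) {
      sim_args$dmr_specs <- as.data.frame(sim_args$dmr_specs)
    }
    if (is.null(sim_args$seed) && !is.null(raw$seed)) {
      sim_args$seed <- raw$seed
    }
    raw$sim <- do.call(simulation_config, sim_args)
  }
  do.call(run_config, raw)
}

# Internal: run one stage with failure attribution
.run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    .ec_stop("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full coordination analysis
#'
#' Orchestrates simulate -> preprocess -> DMP -> DMR -> per-group
#' hypergraphs -> entropy -> silencing -> NMF validation with one
#' configuration, writing stage outputs and a JSON manifest (the resolved
#' configuration plus the counts surviving each filter) into `out_dir`.
#' Group-wise hypergraphs are built from the same case-vs-control DMP list
#' in both groups; only the sample sets differ.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing); `NULL` to skip all
#'   file output and return results only.
#' @return Invisible list of per-stage results plus `manifest`.
#' @export
run_full_analysis <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  res <- list()
  counts <- list()

  sim <- .run_stage("simulate", {
    ann <- generate_probe_annotation(config$sim)
    simulate_methylome(ann, config$sim)
  })
  res$truth <- sim$truth
  counts$n_probes_simulated <- nrow(sim$dataset$values)

  ds <- .run_stage("preprocess", {
    d <- filter_probes(sim$dataset)
    d <- beta_to_m(d)
    zscore_normalize(d)
  })
  res$dataset <- ds
  counts$n_probes_after_filter <- nrow(ds$values)

  dmps <- .run_stage("dmp", test_dmps(ds, alpha = config$alpha))
  res$dmps <- dmps
  counts$n_significant_dmps <- sum(dmps$significant)

  if ("dmr" %in% config$stages) {
    res$dmrs <- .run_stage("dmr", {
      regions <- find_candidate_regions(dmps, ds$annotation,
                                        max_gap = config$max_gap,
                                        min_probes = config$min_probes)
      permutation_region_test(ds, regions, n_perm = config$n_perm,
                              seed = config$seed, alpha = config$alpha,
                              max_gap = config$max_gap,
                              min_probes = config$min_probes)
    })
    counts$n_candidate_regions <- nrow(res$dmrs)
    counts$n_dmrs_fwer05 <- sum(res$dmrs$fwer < 0.05)
  }

  hyper <- .run_stage("hypergraph", {
    sig <- dmps[dmps$significant, ]
    if (nrow(sig) < config$cluster_min_size) {
      .ec_stop("only %d significant DMPs; need >= %d for clustering",
               nrow(sig), config$cluster_min_size)
    }
    if (nrow(sig) > config$max_dmps) {
      sig <- sig[order(-abs(sig$statistic))[seq_len(config$max_dmps)], ]
    }
    vertex_ids <- sig$probe_id
    out <- list(vertex_ids = vertex_ids)
    for (g in c("case", "control")) {
      R <- bipartite_correlation(ds, vertex_ids, group = g)
      M <- binarize_incidence(R)
      A <- adjacency_from_incidence(M)
      cl <- extract_central_cluster(A, min_size = config$cluster_min_size)
      out[[g]] <- list(
        R = R, M = M, A = A, cluster = cl,
        peripheral = refine_peripheral_cpgs(M, cl,
                                            fraction = config$fraction)
      )
    }
    out
  })
  res$hypergraph <- hyper
  counts$n_cluster_case <- length(hyper$case$cluster$members)
  counts$n_cluster_control <- length(hyper$control$cluster$members)
  counts$n_peripheral_case <- length(hyper$case$peripheral)
  counts$n_peripheral_control <- length(hyper$control$peripheral)

  res$cluster_overlap <- compare_clusters(hyper$case$cluster$members,
                                          hyper$control$cluster$members)
  res$strength <- .run_stage("strength", peripheral_strength_comparison(
    hyper$case$R, hyper$case$M, hyper$case$cluster,
    hyper$control$R, hyper$control$M, hyper$control$cluster
  ))

  if ("entropy" %in% config$stages) {
    res$entropy <- .run_stage("entropy", {
      bg <- setdiff(rownames(ds$values), hyper$vertex_ids)
      lapply(stats::setNames(c("case", "control"), c("case", "control")),
             function(g) {
        obs <- shannon_entropy(edge_dimension_distribution(
          hyper[[g]]$A, hyper[[g]]$cluster$members))
        central_cluster_entropy_null(
          ds, g, bg, observed = obs,
          subset_size = config$subset_size, n_iter = config$n_iter,
          seed = config$seed, max_background = config$entropy_max_background
        )
      })
    })
    counts$entropy_case <- res$entropy$case$entropy
    counts$entropy_control <- res$entropy$control$entropy
  }

  if ("silencing" %in% config$stages) {
    res$silencing <- .run_stage("silencing", {
      out <- lapply(stats::setNames(c("case", "control"),
                                    c("case", "control")), function(g) {
        G <- cluster_correlation(ds, hyper[[g]]$cluster$members, group = g)
        S <- silence_network(G)
        ez <- direct_edge_zscores(S, z_threshold = config$z_threshold)
        edges <- classify_cis_trans(ez$edges, ds$annotation,
                                    window = config$window)
        list(S = S, Z = ez$Z, edges = edges)
      })
      out$comparison <- compare_group_edges(out$case$edges,
                                            out$control$edges)
      out
    })
    counts$n_direct_edges_case <- nrow(res$silencing$case$edges)
    counts$n_direct_edges_control <- nrow(res$silencing$control$edges)
  }

  if ("nmf" %in% config$stages) {
    res$nmf <- .run_stage("nmf", {
      fit <- nmf_cluster_dmps(hyper$control$R, rank = config$nmf_rank,
                              seed = config$seed)
      list(fit = fit,
           overlap = cluster_overlap(hyper$control$cluster,
                                     fit$assignment))
    })
    counts$nmf_best_jaccard <- res$nmf$overlap$jaccard
  }

  manifest <- list(
    package = "epicoord",
    config = .config_for_manifest(config),
    counts = counts
  )
  res$manifest <- manifest

  if (!is.null(out_dir)) {
    write_matrix_tsv(ds$values, file.path(out_dir, "values_zscore.tsv"))
    write_annotation_tsv(ds$annotation, file.path(out_dir, "annotation.tsv"))
    utils::write.table(dmps, file.path(out_dir, "dmps.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(res$dmrs)) {
      write_dmr_bed(res$dmrs, file.path(out_dir, "dmrs.bed"))
    }
    for (g in c("case", "control")) {
      writeLines(hyper[[g]]$cluster$members,
                 file.path(out_dir, sprintf("central_cluster_%s.txt", g)))
      writeLines(hyper[[g]]$peripheral,
                 file.path(out_dir, sprintf("peripheral_cpgs_%s.txt", g)))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}

# Internal: flatten a RunConfig (including the nested SimulationConfig)
# into JSON-serializable form so the manifest records every threshold.
.config_for_manifest <- function(config) {
  cfg <- unclass(config)
  sim <- unclass(cfg$sim)
  sim$loading_strength <- as.list(sim$loading_strength)
  sim$flag_fraction <- as.list(sim$flag_fraction)
  if (!is.null(sim$dmr_specs)) {
    sim$dmr_specs <- as.list(as.data.frame(sim$dmr_specs))
  }
  cfg$sim <- sim
  cfg
}
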
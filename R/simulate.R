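#' Simulate a two-group methylome with planted structure
#'
#' Latent-factor generative model. For sample \eqn{i} and probe \eqn{j} the
#' M-value is
#' \deqn{m_{ij} = \mu_j + \delta_j g_i + s_{g(i)} \sum_k \lambda_{jk} f_{ik}
#'   + \epsilon_{ij}}
#' with \eqn{g_i} the case indicator, \eqn{\delta_j = \pm} `dmp_effect` for
#' planted DMPs (0 otherwise), \eqn{f_{ik} \sim N(0,1)} shared latent
#' factors, \eqn{\lambda_{jk} \in \{0,1\}} linking the coordinated DMP block
#' and each factor's hyperedge CpGs to the factors, \eqn{s_g} the per-group
#' `loading_strength`, and \eqn{\epsilon \sim N(0,} `noise_sd`\eqn{)}.
#' Coordination between the DMP block and the hyperedge CpGs is therefore
#' induced entirely by the shared factors, and the per-group strength is the
#' single knob controlling entropy and |r| differences between groups.
#'
#' Beta values are returned as \eqn{\beta = \mathrm{logistic}(m \ln 2)}, the
#' exact inverse of the base-2 logit used by [beta_to_m()], so the M-transform
#' recovers the simulated values.
#'
#' @param annotation Output of [generate_probe_annotation()].
#' @param config The same [simulation_config()] used for the annotation.
#' @return A list with `dataset` (a beta-scale [methylation_dataset()]) and
#'   `truth` (class `GroundTruth`): planted `dmp_ids`, signed `dmp_effects`,
#'   `coordinated_cluster_ids`, `factor_cpg_ids` (per factor),
#'   `hyperedge_cpg_ids` (their union), and `dmr_intervals`.
#' @export
simulate_methylome <- function(annotation, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n_probes <- nrow(annotation)
  if (n_probes != config$n_probes) {
    .ec_stop("annotation has %d probes but config expects %d",
             n_probes, config$n_probes)
  }

  dmr_probe_ids <- annotation$probe_id[!is.na(annotation$dmr_id)]
  if (config$n_dmps < length(dmr_probe_ids)) {
    .ec_stop("n_dmps (%d) smaller than the %d probes consumed by dmr_specs",
             config$n_dmps, length(dmr_probe_ids))
  }
  clean <- !annotation$cross_reactive & !annotation$sex_chromosome &
    !annotation$age_associated & is.na(annotation$dmr_id)
  eligible <- annotation$probe_id[clean]
  n_extra <- config$n_dmps - length(dmr_probe_ids)
  if (n_extra > length(eligible)) {
    .ec_stop("n_dmps exceeds available flag-free autosomal probes")
  }

  with_seed(sub_seed(config$seed, "methylome"), {
    extra_dmps <- sample(eligible, n_extra)
    dmp_ids <- c(dmr_probe_ids, extra_dmps)

    background <- setdiff(eligible, extra_dmps)
    need_cpgs <- config$n_factors * config$cpgs_per_factor
    if (need_cpgs > length(background)) {
      .ec_stop("factor CpG target (%d) exceeds available background (%d)",
               need_cpgs, length(background))
    }
    factor_pool <- sample(background, need_cpgs)
    factor_cpg_ids <- split(factor_pool,
                            rep(seq_len(config$n_factors),
                                each = config$cpgs_per_factor))
    names(factor_cpg_ids) <- sprintf("factor%d", seq_len(config$n_factors))

    if (config$n_coordinated > length(extra_dmps)) {
      .ec_stop("n_coordinated (%d) exceeds the %d non-DMR DMPs",
               config$n_coordinated, length(extra_dmps))
    }
    coordinated <- sample(extra_dmps, config$n_coordinated)

    # signed effects: one sign per DMR run, random sign per isolated DMP
    delta <- stats::setNames(numeric(n_probes), annotation$probe_id)
    if (length(dmr_probe_ids) > 0) {
      run_sign <- sample(c(-1, 1), max(annotation$dmr_id, na.rm = TRUE),
                         replace = TRUE)
      hit <- !is.na(annotation$dmr_id)
      delta[annotation$probe_id[hit]] <-
        run_sign[annotation$dmr_id[hit]] * config$dmp_effect
    }
    delta[extra_dmps] <- sample(c(-1, 1), n_extra, replace = TRUE) *
      config$dmp_effect

    # binary loading structure
    L <- matrix(0, n_probes, config$n_factors,
                dimnames = list(annotation$probe_id, NULL))
    L[coordinated, ] <- 1
    for (k in seq_len(config$n_factors)) L[factor_cpg_ids[[k]], k] <- 1

    n_samples <- config$n_cases + config$n_controls
    sample_ids <- c(sprintf("case%03d", seq_len(config$n_cases)),
                    sprintf("ctrl%03d", seq_len(config$n_controls)))
    group <- stats::setNames(
      rep(c("case", "control"), c(config$n_cases, config$n_controls)),
      sample_ids
    )
    strength <- config$loading_strength[group]

    mu <- stats::rnorm(n_probes, 0, config$baseline_sd)
    f <- matrix(stats::rnorm(n_samples * config$n_factors), n_samples,
                config$n_factors)
    eps <- matrix(stats::rnorm(n_probes * n_samples, 0, config$noise_sd),
                  n_probes, n_samples)

    m <- mu + outer(delta, as.numeric(group == "case")) +
      sweep(L %*% t(f), 2, strength, `*`) + eps
    dimnames(m) <- list(annotation$probe_id, sample_ids)
    beta <- stats::plogis(m * log(2))

    dmr_intervals <- NULL
    if (length(dmr_probe_ids) > 0) {
      dmr_intervals <- do.call(rbind, lapply(
        sort(unique(annotation$dmr_id[!is.na(annotation$dmr_id)])),
        function(id) {
          sub <- annotation[!is.na(annotation$dmr_id) &
                              annotation$dmr_id == id, ]
          data.frame(dmr_id = id, chromosome = sub$chromosome[1],
                     start = min(sub$position), end = max(sub$position),
                     n_probes = nrow(sub), stringsAsFactors = FALSE)
        }
      ))
      dmr_intervals$probe_ids <- lapply(
        dmr_intervals$dmr_id,
        function(id) annotation$probe_id[!is.na(annotation$dmr_id) &
                                           annotation$dmr_id == id]
      )
    }

    truth <- structure(
      list(
        dmp_ids = sort(dmp_ids),
        dmp_effects = delta[dmp_ids][order(dmp_ids)],
        coordinated_cluster_ids = sort(coordinated),
        factor_cpg_ids = lapply(factor_cpg_ids, sort),
        hyperedge_cpg_ids = sort(factor_pool),
        dmr_intervals = dmr_intervals,
        loading_strength = config$loading_strength
      ),
      class = "GroundTruth"
    )

    list(
      dataset = methylation_dataset(beta, group, annotation, scale = "beta"),
      truth = truth
    )
  })
}

#' Write / read ground truth as JSON
#'
#' @param truth A `GroundTruth` object.
#' @param path File path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- unclass(truth)
  out$dmp_effects <- as.list(out$dmp_effects)
  out$loading_strength <- as.list(out$loading_strength)
  if (!is.null(out$dmr_intervals)) {
    out$dmr_intervals$probe_ids <- NULL # flat table; members recoverable from dmp_ids
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$dmp_effects <- unlist(raw$dmp_effects)
  raw$loading_strength <- unlist(raw$loading_strength)
  structure(raw, class = "GroundTruth")
}
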
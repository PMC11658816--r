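#' Simulation configuration
#'
#' Bundles every knob of the synthetic methylome generator. The defaults are
#' the study conditions used throughout the package's tests: 22 cases vs 138
#' controls, 200 planted DMPs of which 100 are coordinated through one
#' dominant shared latent factor that also loads 1500 background CpGs (the
#' planted hyperedges), an M-value effect of 2, unit noise, and strong case
#' coordination (loading 2) against weak control coordination (loading 0.6).
#' The asymmetry places the control group in the partial-retention regime of
#' the incidence binarization (dispersed edge dimensions, higher entropy)
#' while case correlations saturate the cut-off despite the far noisier
#' 22-sample correlation estimates; see the methods vignette.
#'
#' @param n_probes Total number of probes on the synthetic array.
#' @param n_cases,n_controls Group sizes.
#' @param n_dmps Number of planted differentially methylated probes
#'   (includes the probes of all `dmr_specs` runs).
#' @param dmp_effect Absolute M-value difference (case - control) planted at
#'   each DMP; sign is random per DMP (per run for DMR probes). May be 0 for
#'   null simulations.
#' @param n_factors Number of shared latent coordination factors.
#' @param loading_strength Named numeric `c(case = , control = )`: the factor
#'   loading applied to coordinated DMPs and hyperedge CpGs in each group.
#' @param n_coordinated Number of DMPs loading on all factors (the planted
#'   central cluster).
#' @param cpgs_per_factor Number of background CpGs loading on each factor
#'   (the planted hyperedge CpGs).
#' @param dmr_specs `data.frame` with columns `chromosome`, `start`,
#'   `probe_count`, `spacing` describing runs of equally spaced probes that
#'   are all planted as DMPs (one effect sign per run). `NULL` for none.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian probe noise, in
#'   M-value units.
#' @param flag_fraction Named fractions of probes carrying each exclusion
#'   flag (`cross_reactive`, `sex_chromosome`, `age_associated`). The
#'   sex-chromosome fraction is realized by placing probes on chrX.
#' @param bg_spacing Length-2 range (bp) of the random gaps between
#'   consecutive background probes on a chromosome; the default keeps all
#'   background gaps above the DMR gap threshold so spatial runs come only
#'   from `dmr_specs`.
#' @param baseline_sd Standard deviation of the per-probe baseline M-value.
#' @param n_genes Size of the gene-symbol pool (default `n_probes / 10`).
#' @param gene_empty_fraction Fraction of probes with no annotated gene.
#' @param seed Master integer seed; drives hierarchical sub-streams.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_probes = 3000,
                              n_cases = 22,
                              n_controls = 138,
                              n_dmps = 200,
                              dmp_effect = 2,
                              n_factors = 1,
                              loading_strength = c(case = 2, control = 0.6),
                              n_coordinated = 100,
                              cpgs_per_factor = 1500,
                              dmr_specs = data.frame(
                                chromosome = c("chr1", "chr2"),
                                start = c(100000L, 200000L),
                                probe_count = c(8L, 8L),
                                spacing = c(250L, 250L)
                              ),
                              noise_sd = 1,
                              flag_fraction = c(cross_reactive = 0.02,
                                                sex_chromosome = 0.02,
                                                age_associated = 0.01),
                              bg_spacing = c(500, 2000),
                              baseline_sd = 2,
                              n_genes = NULL,
                              gene_empty_fraction = 0.1,
                              seed = 1) {
  if (is.null(n_genes)) n_genes <- max(50L, ceiling(n_probes / 10))
  cfg <- list(
    n_probes = as.integer(n_probes), n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls), n_dmps = as.integer(n_dmps),
    dmp_effect = dmp_effect, n_factors = as.integer(n_factors),
    loading_strength = loading_strength,
    n_coordinated = as.integer(n_coordinated),
    cpgs_per_factor = as.integer(cpgs_per_factor),
    dmr_specs = dmr_specs, noise_sd = noise_sd,
    flag_fraction = flag_fraction, bg_spacing = bg_spacing,
    baseline_sd = baseline_sd, n_genes = as.integer(n_genes),
    gene_empty_fraction = gene_empty_fraction, seed = as.integer(seed)
  )
  counts <- c(n_probes = cfg$n_probes, n_cases = cfg$n_cases,
              n_controls = cfg$n_controls, n_factors = cfg$n_factors,
              n_genes = cfg$n_genes)
  if (any(counts < 1)) {
    .ec_stop("counts must be positive: %s",
             paste(names(counts)[counts < 1], collapse = ", "))
  }
  if (cfg$n_dmps < 0 || cfg$n_dmps > cfg$n_probes) {
    .ec_stop("n_dmps must be in [0, n_probes]")
  }
  if (cfg$n_coordinated > cfg$n_dmps) {
    .ec_stop("n_coordinated cannot exceed n_dmps")
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0) {
    .ec_stop("noise_sd must be > 0")
  }
  if (!all(c("case", "control") %in% names(cfg$loading_strength))) {
    .ec_stop("loading_strength must be named c(case=, control=)")
  }
  if (!is.null(cfg$dmr_specs)) {
    need <- c("chromosome", "start", "probe_count", "spacing")
    if (!all(need %in% names(cfg$dmr_specs))) {
      .ec_stop("dmr_specs must have columns %s", paste(need, collapse = ", "))
    }
  }
  structure(cfg, class = "SimulationConfig")
}

# Internal: check dmr_specs for overlap on a chromosome; error names the
# colliding intervals.
.check_dmr_specs <- function(specs) {
  if (is.null(specs) || nrow(specs) < 2) return(invisible(TRUE))
  specs$end <- specs$start + (specs$probe_count - 1L) * specs$spacing
  for (chr in unique(specs$chromosome)) {
    s <- specs[specs$chromosome == chr, , drop = FALSE]
    if (nrow(s) < 2) next
    s <- s[order(s$start), , drop = FALSE]
    for (i in seq_len(nrow(s) - 1)) {
      if (s$start[i + 1] <= s$end[i]) {
        .ec_stop(
          "overlapping dmr_specs on %s: [%d, %d] collides with [%d, %d]",
          chr, s$start[i], s$end[i], s$start[i + 1], s$end[i + 1]
        )
      }
    }
  }
  invisible(TRUE)
}

#' Generate a synthetic probe annotation table
#'
#' Places `n_probes` probes on chromosomes with strictly increasing positions,
#' realizes each `dmr_specs` entry as a run of equally spaced probes, assigns
#' gene symbols, CpG-island relations and exclusion flags. Probes destined for
#' DMR runs are kept free of exclusion flags so planted structure survives
#' filtering. Background probes start at 10 Mb on each chromosome, clear of
#' the (small-coordinate) DMR runs.
#'
#' @param config A [simulation_config()].
#' @return A `data.frame` with columns `probe_id`, `chromosome`, `position`,
#'   `island_relation`, `gene`, `cross_reactive`, `sex_chromosome`,
#'   `age_associated`, `dmr_id` (run index or `NA`).
#' @export
generate_probe_annotation <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  specs <- config$dmr_specs
  .check_dmr_specs(specs)
  n_dmr <- if (is.null(specs)) 0L else sum(specs$probe_count)
  n_bg <- config$n_probes - n_dmr
  if (n_bg < 1) .ec_stop("dmr_specs consume all probes (n_probes too small)")

  with_seed(sub_seed(config$seed, "annotation"), {
    # DMR run probes at fixed arithmetic positions
    dmr <- NULL
    if (n_dmr > 0) {
      dmr <- do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
        k <- specs$probe_count[i]
        data.frame(
          chromosome = specs$chromosome[i],
          position = specs$start[i] + (seq_len(k) - 1L) * specs$spacing[i],
          dmr_id = i, stringsAsFactors = FALSE
        )
      }))
    }

    # background probes: chrX fraction carries the sex flag, rest autosomal
    n_sex <- floor(config$flag_fraction[["sex_chromosome"]] * config$n_probes)
    n_auto <- n_bg - n_sex
    if (n_auto < 1) .ec_stop("sex-chromosome fraction leaves no autosomal probes")
    chrom <- c(sample(paste0("chr", 1:22), n_auto, replace = TRUE),
               rep("chrX", n_sex))
    bg <- do.call(rbind, lapply(split(seq_along(chrom), chrom), function(idx) {
      gaps <- round(stats::runif(length(idx), config$bg_spacing[1],
                                 config$bg_spacing[2]))
      data.frame(
        chromosome = chrom[idx[1]],
        position = 10000000L + cumsum(gaps),
        dmr_id = NA_integer_, stringsAsFactors = FALSE
      )
    }))
    ann <- rbind(dmr, bg)

    # canonical order: chromosome (natural), then position
    chr_levels <- c(paste0("chr", 1:22), "chrX", "chrY")
    ord <- order(match(ann$chromosome, chr_levels), ann$position)
    ann <- ann[ord, , drop = FALSE]
    ann$probe_id <- sprintf("cg%08d", seq_len(nrow(ann)))

    rel <- c("island", "shore", "shelf", "open_sea")
    ann$island_relation <- sample(rel, nrow(ann), replace = TRUE,
                                  prob = c(0.30, 0.25, 0.10, 0.35))

    genes <- sprintf("GENE%05d", seq_len(config$n_genes))
    ann$gene <- sample(genes, nrow(ann), replace = TRUE)
    ann$gene[stats::runif(nrow(ann)) < config$gene_empty_fraction] <- ""
    # one gene per DMR run, so regions map to a symbol
    if (n_dmr > 0) {
      run_genes <- sample(genes, nrow(specs))
      hit <- !is.na(ann$dmr_id)
      ann$gene[hit] <- run_genes[ann$dmr_id[hit]]
    }

    flaggable <- is.na(ann$dmr_id) & ann$chromosome != "chrX"
    ann$cross_reactive <- flaggable &
      stats::runif(nrow(ann)) < config$flag_fraction[["cross_reactive"]]
    ann$age_associated <- flaggable &
      stats::runif(nrow(ann)) < config$flag_fraction[["age_associated"]]
    ann$sex_chromosome <- ann$chromosome == "chrX"

    rownames(ann) <- NULL
    ann[, c("probe_id", "chromosome", "position", "island_relation", "gene",
            "cross_reactive", "sex_chromosome", "age_associated", "dmr_id")]
  })
}

#' Write / read probe annotation
#'
#' `write_annotation_tsv` round-trips the full table; `write_annotation_bed`
#' exports a BED-like view (0-based start, flags comma-joined).
#'
#' @param annotation Annotation `data.frame`.
#' @param path File path.
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (f in c("cross_reactive", "sex_chromosome", "age_associated")) {
    ann[[f]] <- as.logical(ann[[f]])
  }
  ann$gene[is.na(ann$gene)] <- ""
  ann
}

#' @rdname write_annotation_tsv
#' @export
write_annotation_bed <- function(annotation, path) {
  flags <- apply(
    annotation[, c("cross_reactive", "sex_chromosome", "age_associated")],
    1, function(fl) paste(c("cross_reactive", "sex_chromosome",
                            "age_associated")[as.logical(fl)],
                          collapse = ",")
  )
  bed <- data.frame(
    chrom = annotation$chromosome,
    start = annotation$position - 1L,
    end = annotation$position,
    name = annotation$probe_id,
    gene = ifelse(annotation$gene == "", ".", annotation$gene),
    island_relation = annotation$island_relation,
    flags = ifelse(flags == "", ".", flags),
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate random gene sets over the annotated gene universe
#'
#' @param annotation Annotation `data.frame` with a `gene` column.
#' @param n_sets Number of sets.
#' @param set_size Genes per set (distinct within a set).
#' @param seed Integer seed.
#' @return Named list of character vectors (GMT-writable).
#' @export
generate_gene_sets <- function(annotation, n_sets, set_size, seed = 1) {
  genes <- unique(annotation$gene)
  genes <- genes[genes != ""]
  if (set_size > length(genes)) {
    .ec_stop("set_size (%d) exceeds distinct gene count (%d)",
             set_size, length(genes))
  }
  with_seed(sub_seed(seed, "gene_sets"), {
    sets <- lapply(seq_len(n_sets), function(i) sort(sample(genes, set_size)))
    names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
    sets
  })
}
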
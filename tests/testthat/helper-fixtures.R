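# Small configurations and datasets shared across test files.
# Everything is generated in code; no fixture files.

# Compact simulation config: no flags, no chrX, tight layout.
small_config <- function(n_probes = 600, n_dmps = 40, n_coordinated = 20,
                         cpgs_per_factor = 100, n_cases = 20,
                         n_controls = 20, dmp_effect = 2,
                         loading_strength = c(case = 1.5, control = 1.5),
                         n_factors = 1, noise_sd = 1, dmr_specs = NULL,
                         seed = 1, ...) {
  simulation_config(
    n_probes = n_probes, n_dmps = n_dmps, n_coordinated = n_coordinated,
    cpgs_per_factor = cpgs_per_factor, n_cases = n_cases,
    n_controls = n_controls, dmp_effect = dmp_effect,
    loading_strength = loading_strength, n_factors = n_factors,
    noise_sd = noise_sd, dmr_specs = dmr_specs,
    flag_fraction = c(cross_reactive = 0, sex_chromosome = 0,
                      age_associated = 0),
    seed = seed, ...
  )
}

# Simulate and z-score in one step.
small_sim <- function(config) {
  sim <- simulate_methylome(generate_probe_annotation(config), config)
  sim$zdata <- zscore_normalize(beta_to_m(sim$dataset))
  sim
}

# Hand-built tiny dataset: explicit values, trivial annotation.
manual_dataset <- function(values, group, scale = "M",
                           chromosome = NULL, position = NULL) {
  n <- nrow(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("p%02d", seq_len(n))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  if (is.null(names(group))) names(group) <- colnames(values)
  ann <- data.frame(
    probe_id = rownames(values),
    chromosome = if (is.null(chromosome)) rep("chr1", n) else chromosome,
    position = if (is.null(position)) seq_len(n) * 1000L else position,
    island_relation = "open_sea", gene = "",
    cross_reactive = FALSE, sex_chromosome = FALSE, age_associated = FALSE,
    dmr_id = NA_integer_, stringsAsFactors = FALSE
  )
  methylation_dataset(values, group, ann, scale = scale)
}

# Definitional BH oracle: for each i, min over j with p_j >= p_i of
# min(1, p_j * n / rank_j), computed by brute force.
bh_oracle <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "max") # rank of the largest tied position
  vapply(seq_len(n), function(i) {
    cand <- which(p >= p[i])
    min(1, min(p[cand] * n / rank(p, ties.method = "max")[cand]))
  }, numeric(1))
}

# Naive triple-loop adjacency oracle (inner product written out).
adjacency_oracle <- function(M) {
  n <- nrow(M)
  A <- matrix(0L, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      A[i, j] <- sum(M[i, ] * M[j, ])
    }
  }
  A
}

# Exact two-sided rank-sum p by enumeration of all group assignments.
ranksum_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  obs <- sum(rank(pooled)[seq_len(n)])
  combs <- utils::combn(length(pooled), n)
  stats_all <- apply(combs, 2, function(idx) sum(rank(pooled)[idx]))
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(stats_all - mu) >= abs(obs - mu))
}
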
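make_two <- function() {
  v1 <- matrix(rnorm(12), 3, 4,
               dimnames = list(c("A", "B", "C"), sprintf("s%d", 1:4)))
  v2 <- matrix(rnorm(12), 3, 4,
               dimnames = list(c("B", "C", "D"), sprintf("t%d", 1:4)))
  g1 <- setNames(rep(c("case", "control"), 2), colnames(v1))
  g2 <- setNames(rep(c("case", "control"), 2), colnames(v2))
  ann <- data.frame(probe_id = c("A", "B", "C", "D"), chromosome = "chr1",
                    position = 1:4 * 1000L, island_relation = "island",
                    gene = "", cross_reactive = FALSE, sex_chromosome = FALSE,
                    age_associated = FALSE, dmr_id = NA_integer_)
  list(d1 = methylation_dataset(v1, g1, ann, "M"),
       d2 = methylation_dataset(v2, g2, ann, "M"))
}

test_that("harmonize_probes restricts to the sorted common probe set", {
  two <- make_two()
  out <- harmonize_probes(list(two$d1, two$d2))
  expect_equal(rownames(out[[1]]$values), c("B", "C"))
  expect_equal(rownames(out[[2]]$values), c("B", "C"))
  expect_equal(out[[1]]$values["B", ], two$d1$values["B", ])
  expect_equal(ncol(out[[2]]$values), 4)

  # identical probe sets: values unchanged up to row order
  same <- harmonize_probes(list(two$d1, two$d1))
  expect_equal(same[[1]]$values, two$d1$values[sort(rownames(two$d1$values)), ])

  # disjoint probe sets error, naming the pair
  d3 <- two$d2
  rownames(d3$values) <- c("X", "Y", "Z")
  d3$annotation <- data.frame(
    probe_id = c("X", "Y", "Z"), chromosome = "chr1",
    position = 1:3 * 100L, island_relation = "island", gene = "",
    cross_reactive = FALSE, sex_chromosome = FALSE, age_associated = FALSE,
    dmr_id = NA_integer_
  )
  d3 <- methylation_dataset(d3$values, two$d2$group, d3$annotation, "M")
  expect_error(harmonize_probes(list(two$d1, d3)), "dataset 1 and dataset 2")
})

test_that("filter_probes drops flagged and sex probes with a report", {
  v <- matrix(rnorm(40), 10, 4,
              dimnames = list(sprintf("p%02d", 1:10), sprintf("s%d", 1:4)))
  g <- setNames(rep(c("case", "control"), 2), colnames(v))
  ann <- data.frame(
    probe_id = rownames(v), chromosome = c(rep("chr1", 9), "chrX"),
    position = 1:10 * 1000L, island_relation = "shore", gene = "",
    cross_reactive = c(TRUE, TRUE, rep(FALSE, 8)),
    sex_chromosome = c(rep(FALSE, 9), TRUE),
    age_associated = c(TRUE, rep(FALSE, 9)), dmr_id = NA_integer_
  )
  ds <- methylation_dataset(v, g, ann, "M")

  out <- filter_probes(ds, exclude_flags = "cross_reactive",
                       exclude_sex = FALSE)
  expect_equal(nrow(out$values), 8)
  expect_equal(attr(out, "removal_report")$cross_reactive, 2)

  # probe flagged twice is removed (and counted) once in the total
  out2 <- filter_probes(ds, exclude_flags = c("cross_reactive",
                                              "age_associated"),
                        exclude_sex = TRUE)
  expect_equal(attr(out2, "removal_report")$total_removed, 3)
  expect_equal(nrow(out2$values), 7)

  # empty exclusion is the identity
  out3 <- filter_probes(ds, exclude_flags = character(0), exclude_sex = FALSE)
  expect_identical(out3$values, ds$values)

  ann_all <- ann
  ann_all$cross_reactive <- TRUE
  ds_all <- methylation_dataset(v, g, ann_all, "M")
  expect_error(filter_probes(ds_all, exclude_flags = "cross_reactive"),
               "all probes removed")
})

test_that("beta_to_m matches the closed form and inverts", {
  v <- matrix(c(0.5, 0.8, 0, 0.25, 0.5, 1), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  g <- c(s1 = "case", s2 = "control")
  # need both groups: expand to 4 columns
  v <- cbind(v, v)
  colnames(v) <- sprintf("s%d", 1:4)
  g <- setNames(c("case", "case", "control", "control"), colnames(v))
  ann <- data.frame(probe_id = c("a", "b", "c"), chromosome = "chr1",
                    position = 1:3 * 100L, island_relation = "island",
                    gene = "", cross_reactive = FALSE, sex_chromosome = FALSE,
                    age_associated = FALSE, dmr_id = NA_integer_)
  ds <- methylation_dataset(v, g, ann, "beta")
  eps <- 1e-6
  m <- beta_to_m(ds, epsilon = eps)
  expect_equal(m$scale, "M")
  expect_equal(m$values["a", "s1"], 0)           # b = 0.5
  expect_equal(m$values["b", "s1"], 2)           # b = 0.8 -> log2(4)
  expect_equal(m$values["c", "s1"], log2(eps / (1 - eps))) # clipped boundary
  expect_true(all(is.finite(m$values)))
  # strict monotonicity away from the clip, and analytic inverse identity
  b <- seq(0.01, 0.99, by = 0.01)
  mm <- log2(b / (1 - b))
  expect_true(all(diff(mm) > 0))
  back <- m_to_beta(m)
  interior <- ds$values > eps & ds$values < 1 - eps
  expect_lt(max(abs(back$values[interior] - ds$values[interior])), 1e-9)
  expect_error(beta_to_m(m), "beta-scale")
})

test_that("adjust_covariates removes covariate signal and nothing else", {
  set.seed(42)
  v <- matrix(rnorm(200), 10, 20,
              dimnames = list(sprintf("p%02d", 1:10), sprintf("s%02d", 1:20)))
  g <- setNames(rep(c("case", "control"), 10), colnames(v))
  ann <- data.frame(probe_id = rownames(v), chromosome = "chr1",
                    position = 1:10 * 1000L, island_relation = "island",
                    gene = "", cross_reactive = FALSE, sex_chromosome = FALSE,
                    age_associated = FALSE, dmr_id = NA_integer_)
  ds <- methylation_dataset(v, g, ann, "M")

  # a column of ones is absorbed by the intercept: identity
  out1 <- adjust_covariates(ds, matrix(1, 20, 1))
  expect_equal(out1$values, ds$values)

  # values exactly linear in one covariate -> constant at the probe mean
  cov1 <- matrix(seq_len(20), 20, 1)
  lin <- ds
  lin$values <- matrix(rep(3 * cov1[, 1] + 5, each = 10), 10, 20,
                       dimnames = dimnames(v))
  outl <- adjust_covariates(lin, cov1)
  expect_lt(max(abs(outl$values - rowMeans(lin$values))), 1e-8)

  # residuals orthogonal to each centered covariate
  covs <- matrix(rnorm(40), 20, 2)
  outr <- adjust_covariates(ds, covs)
  cc <- scale(covs, center = TRUE, scale = FALSE)
  resid <- outr$values - rowMeans(outr$values)
  expect_lt(max(abs(resid %*% cc)), 1e-8)

  expect_error(adjust_covariates(ds, cbind(cov1, cov1)), "rank-deficient")
})

test_that("zscore_normalize standardizes rows and drops constants", {
  v <- rbind(p1 = c(1, 2, 3, 4), p2 = c(5, 5, 5, 5), p3 = c(1, 2, 3, 10))
  colnames(v) <- sprintf("s%d", 1:4)
  g <- setNames(rep(c("case", "control"), 2), colnames(v))
  ann <- data.frame(probe_id = rownames(v), chromosome = "chr1",
                    position = 1:3 * 100L, island_relation = "island",
                    gene = "", cross_reactive = FALSE, sex_chromosome = FALSE,
                    age_associated = FALSE, dmr_id = NA_integer_)
  ds <- methylation_dataset(v, g, ann, "M")
  z <- zscore_normalize(ds)
  expect_equal(attr(z, "dropped_constant"), "p2")
  expect_equal(nrow(z$values), 2)
  expect_lt(max(abs(rowMeans(z$values))), 1e-8)
  expect_lt(max(abs(apply(z$values, 1, sd) - 1)), 1e-8)
  # exact row for (1,2,3) with one extra point checked against scale()
  expect_equal(z$values["p1", ], (v["p1", ] - mean(v["p1", ])) / sd(v["p1", ]))

  v3 <- matrix(c(-1, 0, 1, -1, 0, 1), 2, 3, byrow = TRUE)
  dimnames(v3) <- list(c("q1", "q2"), c("s1", "s2", "s3"))
  # row (1,2,3) maps to (-1, 0, 1): sample SD is exactly 1
  v4 <- matrix(c(1, 2, 3), 1, 3, dimnames = list("q", c("a", "b", "c")))
  expect_equal(as.numeric(scale(v4[1, ])), c(-1, 0, 1))

  dc <- ds
  dc$values <- matrix(1, 3, 4, dimnames = dimnames(v))
  dc <- methylation_dataset(dc$values, g, ann, "M")
  expect_error(zscore_normalize(dc), "all probes constant")
})

test_that("harmonize then filter then harmonize is idempotent", {
  cfg <- simulation_config(n_probes = 400, n_dmps = 20, n_coordinated = 4,
                           cpgs_per_factor = 20, seed = 9)
  sim <- simulate_methylome(generate_probe_annotation(cfg), cfg)
  d1 <- sim$dataset
  once <- harmonize_probes(list(d1, d1))
  filtered <- lapply(once, filter_probes)
  twice <- harmonize_probes(filtered)
  expect_identical(lapply(twice, function(d) d$values),
                   lapply(filtered, function(d) d$values))
})

test_that("matrix and sample sheet serialization round-trips", {
  v <- matrix(round(rnorm(12), 6), 3, 4,
              dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(v, path)
  expect_equal(read_matrix_tsv(path), v)
  g <- setNames(rep(c("case", "control"), 2), colnames(v))
  sp <- withr::local_tempfile(fileext = ".csv")
  write_sample_sheet(g, sp, covariates = matrix(1:4, 4, 1,
                                                dimnames = list(names(g),
                                                                "cov1")))
  back <- read_sample_sheet(sp)
  expect_equal(back$group, g)
  expect_equal(back$covariates[, "cov1"], setNames(1:4, names(g)))
})
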
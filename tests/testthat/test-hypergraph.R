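test_that("bipartite_correlation recovers exact and null correlations", {
  set.seed(5)
  n <- 50
  base <- rnorm(2 * n)
  v <- rbind(dmp1 = base[1:n], bg1 = base[1:n], bg2 = -base[1:n],
             matrix(rnorm(20 * n), 20,
                    dimnames = list(sprintf("bg%02d", 3:22), NULL)))
  colnames(v) <- sprintf("s%03d", seq_len(n))
  g <- setNames(rep(c("case", "control"), n / 2), colnames(v))
  ds <- manual_dataset(v, g)
  r <- bipartite_correlation(ds, "dmp1", group = "case")
  expect_equal(r["dmp1", "bg1"], 1)
  expect_equal(r["dmp1", "bg2"], -1)

  # independent Gaussian rows: mean |r| close to the closed-form null moment
  set.seed(6)
  v2 <- matrix(rnorm(120 * n), 120,
               dimnames = list(sprintf("q%03d", 1:120),
                               sprintf("s%03d", 1:n)))
  # both groups must exist in the container; append two control columns
  v2b <- cbind(v2, ctrl1 = rnorm(120), ctrl2 = rnorm(120))
  g2 <- setNames(c(rep("case", n), "control", "control"), colnames(v2b))
  ds2 <- manual_dataset(v2b, g2)
  r2 <- bipartite_correlation(ds2, sprintf("q%03d", 1:20), group = "case")
  expected <- sqrt(2 / (pi * (n - 1)))
  expect_lt(abs(mean(abs(r2)) - expected) / expected, 0.1)

  expect_error(bipartite_correlation(ds, "dmp1", group = "control",
                                     background_ids = "dmp1"),
               "disjoint")
})

test_that("constant rows yield zero correlations with a log message", {
  v <- rbind(d1 = c(1, 2, 3, 4, 5, 6), flat = rep(1, 6),
             b2 = c(2, 1, 3, 6, 5, 4))
  colnames(v) <- sprintf("s%d", 1:6)
  g <- setNames(rep(c("case", "control"), 3), colnames(v))
  ds <- manual_dataset(v, g)
  expect_message(
    r <- bipartite_correlation(ds, "d1", group = "case"),
    "undefined correlations"
  )
  expect_equal(r["d1", "flat"], 0)
})

test_that("incidence binarization uses the pooled sample SD of |r|", {
  R <- matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2,
              dimnames = list(c("d1", "d2"), c("c1", "c2")))
  M <- binarize_incidence(R)
  expect_equal(attr(M, "threshold"), sd(c(0.9, 0.1, 0.2, 0.8)))
  expect_equal(unname(M), matrix(c(1L, 0L, 0L, 1L), 2, 2),
               ignore_attr = TRUE)
  # sign symmetry: binarize(R) == binarize(-R)
  Mneg <- binarize_incidence(-R)
  expect_equal(unname(Mneg), unname(M), ignore_attr = TRUE)
  # all-but-one equal entries still yield a positive threshold
  R2 <- matrix(c(0.6, 0.6, 0.6, 0), 2, 2)
  M2 <- binarize_incidence(R2)
  expect_equal(sum(M2), 3)
  expect_error(binarize_incidence(matrix(0.5, 2, 2)), "degenerate")
})

test_that("adjacency equals M.Mt with its structural invariants", {
  M <- matrix(c(1, 1, 0, 0, 1, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("d1", "d2"), c("c1", "c2", "c3")))
  A <- adjacency_from_incidence(M)
  expect_equal(unname(A), matrix(c(2L, 1L, 1L, 2L), 2, 2))

  M2 <- rbind(M, d3 = c(0, 0, 0))
  A2 <- adjacency_from_incidence(M2)
  expect_true(all(A2["d3", ] == 0) && all(A2[, "d3"] == 0))

  set.seed(8)
  M3 <- matrix(rbinom(20 * 200, 1, 0.3), 20, 200,
               dimnames = list(sprintf("d%02d", 1:20),
                               sprintf("c%03d", 1:200)))
  A3 <- adjacency_from_incidence(M3)
  expect_equal(unname(A3), unname(adjacency_oracle(M3)))
  expect_true(isSymmetric(A3))
  expect_equal(diag(A3), rowSums(M3))
  off <- A3; diag(off) <- 0L
  expect_true(all(off <= outer(diag(A3), diag(A3), pmin)))
  # PSD: smallest eigenvalue of M.Mt is non-negative
  expect_gte(min(eigen(A3, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  # hyperedge count conservation against column sums
  cs <- colSums(M3)
  expect_equal(sum(A3[upper.tri(A3)]), sum(cs * (cs - 1) / 2))
})

test_that("central cluster extraction recovers a planted block", {
  set.seed(10)
  jacc <- vapply(1:3, function(s) {
    cfg <- small_config(n_probes = 700, n_dmps = 100, n_coordinated = 50,
                        cpgs_per_factor = 150, n_cases = 30, n_controls = 138,
                        seed = s)
    sim <- small_sim(cfg)
    verts <- sim$truth$dmp_ids
    R <- bipartite_correlation(sim$zdata, verts, group = "control")
    A <- adjacency_from_incidence(binarize_incidence(R))
    cl <- extract_central_cluster(A, min_size = 10)
    compare_clusters(cl$members, sim$truth$coordinated_cluster_ids)$jaccard
  }, numeric(1))
  expect_true(all(jacc >= 0.8))
})

test_that("central cluster extraction degenerate and invariance behaviour", {
  # equal off-diagonals: no structure to refine, full set returned
  A <- matrix(5L, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  diag(A) <- 9L
  cl <- extract_central_cluster(A, min_size = 2)
  expect_setequal(cl$members, letters[1:6])

  # permuting vertex order only permutes membership labels
  set.seed(11)
  B <- matrix(rpois(100, 3), 10, 10)
  B <- B + t(B)
  diag(B) <- rowSums(B)
  dimnames(B) <- list(letters[1:10], letters[1:10])
  cl1 <- extract_central_cluster(B, min_size = 2)
  perm <- sample(10)
  Bp <- B[perm, perm]
  cl2 <- extract_central_cluster(Bp, min_size = 2)
  expect_setequal(cl1$members, cl2$members)

  expect_error(extract_central_cluster(B, min_size = 50), "min_size")
})

test_that("peripheral CpG refinement applies a strict 95% rule", {
  members <- sprintf("d%02d", 1:20)
  M <- matrix(0L, 20, 3,
              dimnames = list(members, c("all20", "only19", "none")))
  M[, "all20"] <- 1L
  M[1:19, "only19"] <- 1L
  per <- refine_peripheral_cpgs(M, members, fraction = 0.95)
  expect_equal(per, "all20") # 19/20 = 0.95 is not > 0.95
  expect_error(refine_peripheral_cpgs(M, character(0)), "empty cluster")
})

test_that("peripheral recovery hits planted hyperedge CpGs", {
  cfg <- small_config(n_probes = 700, n_dmps = 100, n_coordinated = 50,
                      cpgs_per_factor = 150, n_cases = 30, n_controls = 138,
                      seed = 2)
  sim <- small_sim(cfg)
  verts <- sim$truth$dmp_ids
  R <- bipartite_correlation(sim$zdata, verts, group = "control")
  M <- binarize_incidence(R)
  A <- adjacency_from_incidence(M)
  cl <- extract_central_cluster(A, min_size = 10)
  per <- refine_peripheral_cpgs(M, cl)
  truth <- sim$truth$hyperedge_cpg_ids
  expect_gte(mean(truth %in% per), 0.9) # sensitivity
  expect_gte(mean(per %in% truth), 0.9) # precision
})

test_that("cluster overlap summaries use exact set arithmetic", {
  out <- compare_clusters(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(out$n_shared, 2)
  expect_equal(out$n_unique_a, 1)
  expect_equal(out$n_unique_b, 1)
  expect_equal(out$jaccard, 0.5)
  expect_equal(out$n_shared + out$n_unique_a, 3)
  expect_equal(compare_clusters(letters[1:3], letters[1:3])$jaccard, 1)
  expect_equal(compare_clusters(letters[1:3], letters[4:6])$jaccard, 0)
})

test_that("retained-correlation strength comparison behaves", {
  cfg <- small_config(n_probes = 500, n_dmps = 60, n_coordinated = 30,
                      cpgs_per_factor = 100, n_cases = 40, n_controls = 40,
                      seed = 3)
  sim <- small_sim(cfg)
  verts <- sim$truth$dmp_ids
  R <- bipartite_correlation(sim$zdata, verts, group = "case")
  M <- binarize_incidence(R)
  A <- adjacency_from_incidence(M)
  cl <- extract_central_cluster(A, min_size = 5)
  # self-comparison: ratio exactly 1, Wilcoxon cannot reject
  st <- peripheral_strength_comparison(R, M, cl, R, M, cl)
  expect_equal(st$fold_ratio, 1)
  expect_gt(st$wilcoxon_p, 0.05)

  # Wilcoxon route agrees with exact enumeration on a tiny case
  w <- suppressWarnings(wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value)
  expect_equal(w, ranksum_enum_p(c(1, 2, 3), c(4, 5, 6)))
})

test_that("case-stronger loadings raise the case |r| ratio", {
  ratios <- vapply(1:3, function(s) {
    cfg <- small_config(n_probes = 500, n_dmps = 60, n_coordinated = 30,
                        cpgs_per_factor = 100, n_cases = 40, n_controls = 40,
                        loading_strength = c(case = 1.5, control = 1),
                        seed = s)
    sim <- small_sim(cfg)
    verts <- sim$truth$dmp_ids
    parts <- lapply(c("case", "control"), function(g) {
      R <- bipartite_correlation(sim$zdata, verts, group = g)
      M <- binarize_incidence(R)
      cl <- extract_central_cluster(adjacency_from_incidence(M),
                                    min_size = 5)
      list(R = R, M = M, cl = cl)
    })
    peripheral_strength_comparison(parts[[1]]$R, parts[[1]]$M, parts[[1]]$cl,
                                   parts[[2]]$R, parts[[2]]$M,
                                   parts[[2]]$cl)$fold_ratio
  }, numeric(1))
  expect_true(all(ratios > 1))
})

test_that("sparse coordinate serialization drops zeros", {
  M <- matrix(c(1L, 0L, 0L, 2L), 2, 2,
              dimnames = list(c("r1", "r2"), c("c1", "c2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sparse_tsv(M, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$value, c(1L, 2L))
})
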
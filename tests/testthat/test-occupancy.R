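test_that("occupancy classes follow the standard thresholds at n = 16", {
  pol <- occupancy_policy(16L)
  expect_equal(classify_occupancy(16L, pol), "core")
  expect_equal(classify_occupancy(15L, pol), "softcore")
  expect_equal(classify_occupancy(2L, pol), "cloud")
  expect_equal(classify_occupancy(1L, pol), "cloud")
  expect_equal(classify_occupancy(7L, pol), "shell")
  expect_error(classify_occupancy(0L, pol), "occupancy")
  expect_error(classify_occupancy(17L, pol), "occupancy")
  # total and mutually exclusive over [1, n]
  classes <- vapply(1:16, classify_occupancy, "", policy = pol)
  expect_equal(sum(classes == "core"), 1L)
  expect_equal(sum(classes == "softcore"), 1L)
  expect_equal(sum(classes == "cloud"), 2L)
  expect_equal(sum(classes == "shell"), 12L)
})

test_that("occupancy spectrum conserves the cluster count and supports source filters", {
  members <- data.frame(
    cluster_id = c(1L, 1L, 2L, 3L), genome = c("gA", "gB", "gA", "gB"),
    gene_id = c("a1", "b1", "a2", "b2"), chrom = "chr1",
    start = c(0L, 0L, 5000L, 9000L), end = c(1000L, 1000L, 6000L, 10000L),
    strand = "+", source_set = c("gA", "gB", "legacy", "gB"))
  mat <- pangene_matrix(members, genome_order = c("gA", "gB"))
  spec <- occupancy_spectrum(mat)
  expect_equal(sum(spec), nrow(mat$clusters))
  expect_equal(unname(spec["2"]), 1L)
  filtered <- occupancy_spectrum(mat, exclude_only_sources = "legacy")
  expect_equal(sum(filtered), 2L)
})

test_that("family segregation applies the all-of-family / max-other rule", {
  genomes <- paste0("g", 1:6)
  fams <- setNames(c("japonica", "japonica", "japonica", "aus", "aus", "indica"),
                   genomes)
  mk <- function(cid, gs) data.frame(
    cluster_id = cid, genome = gs, gene_id = paste0("c", cid, "_", gs),
    chrom = "chr1", start = cid * 10000L, end = cid * 10000L + 1000L,
    strand = "+")
  members <- rbind(mk(1L, c("g1", "g2", "g3", "g4")),   # all japonica + 1 aus
                   mk(2L, c("g1", "g2")),               # family incomplete
                   mk(3L, c("g1", "g2", "g3")))         # japonica-private
  mat <- pangene_matrix(members, genome_order = genomes)
  res <- family_segregation(mat, fams, "japonica", max_other = 1L)
  expect_setequal(res$selected, c(1L, 3L))
  expect_equal(res$fractions$japonica[res$fractions$cluster_id == 2L], 2 / 3)
  expect_error(family_segregation(mat, fams, "tropical"), "unknown family")
})

test_that("planted family-private genes are recovered exactly", {
  sim <- simulate_pangenome(
    sim_config(n_genomes = 8, n_ancestral_genes = 120, seed = 13,
               occupancy_profile = c(core = 0.7, cloud = 0.3),
               plant_family_private = 6L))
  mat <- cluster_sim(sim)
  fams <- sim$config$family_labels
  res <- family_segregation(mat, fams, fams[[1L]], max_other = 0L)
  planted_clusters <- unique(
    mat$members$cluster_id[match(
      sim$truth$gene_id[sim$truth$cluster_id %in% sim$planted$family_private],
      mat$members$gene_id)])
  # the planted set must be recovered; sampled subsets can add coincidental hits
  expect_true(all(planted_clusters %in% res$selected))
  fam_genomes <- names(fams)[fams == fams[[1L]]]
  for (cid in res$selected) {
    gs <- unique(mat$members$genome[mat$members$cluster_id == cid])
    expect_setequal(intersect(gs, fam_genomes), fam_genomes)
    expect_equal(length(setdiff(gs, fam_genomes)), 0L)
  }
})

test_that("a shared constant core gives flat trajectories and a pinned asymptote", {
  genomes <- paste0("g", 1:8)
  members <- do.call(rbind, lapply(1:100, function(cid) data.frame(
    cluster_id = cid, genome = genomes, gene_id = paste0("c", cid, "_", genomes),
    chrom = "chr1", start = cid * 10000L, end = cid * 10000L + 1000L,
    strand = "+")))
  mat <- pangene_matrix(members, genome_order = genomes)
  gf <- fit_core_growth(mat, n_perm = 10, seed = 3)
  expect_true(all(gf$trajectories == 100L))
  expect_lt(abs(gf$asymptote - 100), 1)
  expect_equal(unname(coef(gf)["kappa"]), 0)
})

test_that("trajectories are non-increasing and end at the occupancy-n count", {
  sim <- default_sim()
  mat <- cluster_sim(sim)
  gf <- fit_core_growth(mat, n_perm = 10, seed = 5)
  expect_true(all(apply(gf$trajectories, 1L, function(r) all(diff(r) <= 0))))
  n_core <- sum(mat$clusters$occupancy == mat$n_genomes)
  expect_true(all(gf$trajectories[, mat$n_genomes] == n_core))
})

test_that("the fitted asymptote recovers the planted core size", {
  sim <- default_sim()
  mat <- cluster_sim(sim)
  truth_core <- sum(tapply(sim$truth$genome, sim$truth$cluster_id,
                           function(v) length(unique(v))) == 16L)
  for (m in c("tettelin", "willenbrock")) {
    gf <- fit_core_growth(mat, n_perm = 20, seed = 1, method = m)
    expect_true(gf$converged)
    expect_lt(abs(gf$asymptote - truth_core) / truth_core, 0.05)
  }
  # seed invariance of the asymptote (+/- 2%)
  gf1 <- fit_core_growth(mat, n_perm = 20, seed = 1)
  gf2 <- fit_core_growth(mat, n_perm = 20, seed = 202)
  expect_lt(abs(gf1$asymptote - gf2$asymptote) / gf1$asymptote, 0.02)
})

test_that("growth-fit methods expose parameters, predictions and summaries", {
  sim <- default_sim()
  mat <- cluster_sim(sim)
  gf <- fit_core_growth(mat, n_perm = 10, seed = 2)
  expect_named(coef(gf), c("kappa", "tau", "omega"))
  pr <- predict(gf, c(1, 16, 100))
  expect_length(pr, 3L)
  expect_lt(pr[3L] - gf$asymptote, 1)   # decay exhausted far out
  sm <- summary(gf)
  expect_equal(nrow(sm), 16L)
  expect_true(all(c("median", "fitted") %in% names(sm)))
  expect_output(print(gf), "asymptote")
})
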
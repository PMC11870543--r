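domain_rec <- function(gene_id, genome, accession, namespace = "Pfam",
                       te = FALSE, source_set = genome) {
  data.frame(protein_id = paste0(gene_id, ".1"), gene_id = gene_id,
             genome = genome, source_set = source_set, namespace = namespace,
             accession = accession, te_flag = te, stringsAsFactors = FALSE)
}

mk_mat <- function(members, genomes) pangene_matrix(members, genome_order = genomes)

wide_cluster <- function(cid, genomes, chrom = "chr1") data.frame(
  cluster_id = cid, genome = genomes,
  gene_id = paste0("c", cid, "_", genomes), chrom = chrom,
  start = cid * 10000L, end = cid * 10000L + 1000L, strand = "+")

test_that("a domain carried by every genome is representative and consistent", {
  genomes <- sprintf("g%02d", 1:16)
  mat <- mk_mat(wide_cluster(1L, genomes), genomes)
  rec <- do.call(rbind, lapply(genomes, function(g)
    domain_rec(paste0("c1_", g), g, "PF02365")))
  res <- assign_representative_domain(mat, rec, "Pfam", seed = 1)
  expect_equal(res$representative, "PF02365")
  expect_true(res$consistent)
  expect_equal(res$n_genomes_lacking, 0L)
})

test_that("ties among most-common domains break deterministically under a seed", {
  genomes <- paste0("g", 1:4)
  mat <- mk_mat(wide_cluster(1L, genomes), genomes)
  rec <- rbind(domain_rec("c1_g1", "g1", "PF00001"),
               domain_rec("c1_g2", "g2", "PF00001"),
               domain_rec("c1_g3", "g3", "PF00002"),
               domain_rec("c1_g4", "g4", "PF00002"))
  r1 <- assign_representative_domain(mat, rec, "Pfam", seed = 5)
  r2 <- assign_representative_domain(mat, rec, "Pfam", seed = 5)
  expect_identical(r1$representative, r2$representative)
  expect_true(r1$representative %in% c("PF00001", "PF00002"))
})

test_that("genomes lacking the representative are counted with their proteins listed", {
  genomes <- paste0("g", 1:5)
  mat <- mk_mat(wide_cluster(1L, genomes), genomes)
  rec <- do.call(rbind, lapply(genomes[1:4], function(g)
    domain_rec(paste0("c1_", g), g, "PF9")))
  res <- assign_representative_domain(mat, rec, "Pfam", seed = 1)
  expect_equal(res$n_genomes_lacking, 1L)
  expect_equal(res$outlier_proteins, "c1_g5.1")
  expect_false(res$consistent)
})

test_that("variability categories follow the mean-occupancy thresholds", {
  genomes <- sprintf("g%02d", 1:16)
  # one domain in 5 clusters with occupancies 6,7,7,8,8 -> mean 7.2 (variable);
  # another always at 16 -> invariable; a third in 4 clusters -> uncategorized
  members <- list(); recs <- list()
  occs <- c(6L, 7L, 7L, 8L, 8L)
  for (i in seq_along(occs)) {
    gs <- genomes[seq_len(occs[i])]
    members[[length(members) + 1L]] <- wide_cluster(i, gs)
    recs[[length(recs) + 1L]] <- do.call(rbind, lapply(gs, function(g)
      domain_rec(paste0("c", i, "_", g), g, "PFVAR")))
  }
  for (i in 6:10) {
    members[[length(members) + 1L]] <- wide_cluster(i, genomes)
    recs[[length(recs) + 1L]] <- do.call(rbind, lapply(genomes, function(g)
      domain_rec(paste0("c", i, "_", g), g, "PFINV")))
  }
  for (i in 11:14) {
    gs <- genomes[1:12]
    members[[length(members) + 1L]] <- wide_cluster(i, gs)
    recs[[length(recs) + 1L]] <- do.call(rbind, lapply(gs, function(g)
      domain_rec(paste0("c", i, "_", g), g, "PFFEW")))
  }
  mat <- mk_mat(do.call(rbind, members), genomes)
  res <- domain_variability(mat, do.call(rbind, recs), "Pfam")
  expect_equal(res$category[res$accession == "PFVAR"], "highly_variable")
  expect_equal(res$mean_occupancy[res$accession == "PFVAR"], 7.2)
  expect_equal(res$category[res$accession == "PFINV"], "invariable")
  expect_equal(res$category[res$accession == "PFFEW"], "unfiltered")
  # boundary mean exactly 10 lands in the middle category (clusters 6-10
  # carry all 16 genomes; the domain is seen in 10 of them in each)
  res10 <- domain_variability(mat, do.call(rbind, lapply(6:10, function(i) {
    do.call(rbind, lapply(genomes[1:10], function(g)
      domain_rec(paste0("c", i, "_", g), g, "PFB")))
  })), "Pfam")
  expect_equal(res10$mean_occupancy[res10$accession == "PFB"], 10)
  expect_equal(res10$category[res10$accession == "PFB"], "partially_variable")
})

test_that("occupancy counts use designated annotation sets only", {
  genomes <- paste0("g", 1:3)
  mat <- mk_mat(rbind(wide_cluster(1L, genomes), wide_cluster(2L, genomes),
                      wide_cluster(3L, genomes), wide_cluster(4L, genomes),
                      wide_cluster(5L, genomes)), genomes)
  base <- do.call(rbind, lapply(1:5, function(i)
    do.call(rbind, lapply(genomes, function(g)
      domain_rec(paste0("c", i, "_", g), g, "PFX")))))
  designated <- setNames(genomes, genomes)
  r1 <- domain_variability(mat, base, "Pfam", designated_sets = designated)
  # add a second (non-designated) source set for g1: counts must not change
  extra <- base[base$genome == "g1", ]
  extra$source_set <- "altset"
  r2 <- domain_variability(mat, rbind(base, extra), "Pfam",
                           designated_sets = designated)
  expect_equal(r2$mean_occupancy, r1$mean_occupancy)
  expect_equal(r2$n_pangenes, r1$n_pangenes)
})

test_that("TE filtering removes flagged singletons and all-TE clusters only", {
  genomes <- paste0("g", 1:4)
  members <- rbind(
    data.frame(cluster_id = 1L, genome = "g1", gene_id = "s_te", chrom = "chr1",
               start = 0L, end = 1000L, strand = "+"),          # TE singleton
    data.frame(cluster_id = 2L, genome = "g1", gene_id = "s_ok", chrom = "chr1",
               start = 5000L, end = 6000L, strand = "+"),       # clean singleton
    wide_cluster(3L, genomes),                                  # 1 TE of 4
    wide_cluster(4L, genomes[1:3]))                             # all TE
  mat <- mk_mat(members, genomes)
  rec <- rbind(domain_rec("s_te", "g1", "PFTE", te = TRUE),
               domain_rec("c3_g1", "g1", "PFTE", te = TRUE),
               do.call(rbind, lapply(genomes[1:3], function(g)
                 domain_rec(paste0("c4_", g), g, "PFTE", te = TRUE))))
  res <- filter_te_clusters(mat, rec)
  expect_setequal(res$removed, c(1L, 4L))
  expect_setequal(res$matrix$clusters$cluster_id, c(2L, 3L))
  # a singleton tagged only in the legacy TE list is also removed
  res2 <- filter_te_clusters(mat, rec[0, ], msu_te_ids = "s_te")
  expect_equal(res2$removed, 1L)
})

test_that("enrichment p-values equal the hypergeometric closed form", {
  genomes <- sprintf("g%02d", 1:16)
  # background of 10 clusters: 4 core (all 16 genomes), 6 cloud (1 genome)
  members <- rbind(
    do.call(rbind, lapply(1:4, function(i) wide_cluster(i, genomes))),
    do.call(rbind, lapply(5:10, function(i) wide_cluster(i, genomes[1L]))))
  mat <- mk_mat(members, genomes)
  # domain present in exactly 3 clusters, all core
  rec <- do.call(rbind, lapply(1:3, function(i)
    domain_rec(paste0("c", i, "_g01"), "g01", "PFC")))
  res <- enrich_domains(mat, rec, "Pfam", class_a = "core")
  expect_equal(res$p[res$accession == "PFC"], 4 / 120, tolerance = 1e-12)
  expect_equal(res$gene_ratio[res$accession == "PFC"], 3 / 4)
  # a uniformly spread domain shows no signal
  rec_u <- do.call(rbind, lapply(1:10, function(i)
    domain_rec(paste0("c", i, "_g01"), "g01", "PFU")))
  res_u <- enrich_domains(mat, rbind(rec, rec_u), "Pfam", class_a = "core")
  expect_gte(res_u$p_adj[res_u$accession == "PFU"], 0.05)
  # BH adjustment is monotone non-decreasing in raw-p order
  o <- order(res_u$p)
  expect_false(is.unsorted(res_u$p_adj[o]))
  expect_error(enrich_domains(mat, rec, "Pfam", class_a = "softcore"), "class")
})

test_that("domain consistency is complete on a clean simulation with full retention", {
  catalog <- list(list(accession = "PF11111", namespace = "Pfam",
                       n_carriers = 10L, retention = 1.0))
  sim <- simulate_pangenome(sim_config(n_genomes = 6, n_ancestral_genes = 60,
                                       occupancy_profile = c(core = 1),
                                       domain_catalog = catalog, seed = 9))
  mat <- cluster_sim(sim)
  res <- assign_representative_domain(mat, sim$domains, "Pfam", seed = 1)
  expect_equal(nrow(res), 10L)
  expect_true(all(res$consistent))
})
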
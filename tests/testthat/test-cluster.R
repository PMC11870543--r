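lift <- function(gene_id, src, tgt, chrom, start, end, strand = "+", cov = 1) {
  data.frame(gene_id = gene_id, source_genome = src, target_genome = tgt,
             target_chrom = chrom, start = start, end = end,
             lifted_strand = strand, coverage = cov, stringsAsFactors = FALSE)
}

two_genomes <- function() {
  list(gA = tiny_annotation("gA", tiny_gene("a1", 1000, 2000)),
       gB = tiny_annotation("gB", tiny_gene("b1", 5000, 6000)))
}

test_that("identity placement gives a full-overlap edge; antisense gives none", {
  ann <- two_genomes()
  e <- build_overlap_graph(ann, lift("a1", "gA", "gB", "chr1", 5000, 6000))
  expect_equal(nrow(e), 1L)
  expect_equal(e$overlap_fraction, 1.0)
  e2 <- build_overlap_graph(ann, lift("a1", "gA", "gB", "chr1", 5000, 6000,
                                      strand = "-"))
  expect_equal(nrow(e2), 0L)
})

test_that("the overlap fraction is measured against the shorter feature", {
  ann <- list(gA = tiny_annotation("gA", tiny_gene("a1", 0, 1000)),
              gB = tiny_annotation("gB", tiny_gene("b1", 0, 2000)))
  # 1000 bp lifted interval overlapping the 2000 bp gene by 400 bp: 0.4 < 0.5
  e <- build_overlap_graph(ann, lift("a1", "gA", "gB", "chr1", 1600, 2600))
  expect_equal(nrow(e), 0L)
  # 500 bp overlap of the 1000 bp (shorter) interval: exactly 0.5
  e <- build_overlap_graph(ann, lift("a1", "gA", "gB", "chr1", 1500, 2500))
  expect_equal(nrow(e), 1L)
})

test_that("unknown gene names in lifted evidence are skipped with a warning", {
  ann <- two_genomes()
  expect_warning(
    e <- build_overlap_graph(ann, lift("ghost", "gA", "gB", "chr1", 5000, 6000)),
    "skipped")
  expect_equal(attr(e, "skipped"), 1L)
  expect_equal(nrow(e), 0L)
})

test_that("reciprocal 1:1 placements give one cluster of occupancy 2 each", {
  genes_a <- lapply(1:5, function(i) tiny_gene(paste0("a", i),
                                               i * 10000L, i * 10000L + 1000L))
  genes_b <- lapply(1:5, function(i) tiny_gene(paste0("b", i),
                                               i * 20000L, i * 20000L + 1000L))
  ann <- list(gA = do.call(tiny_annotation, c(list("gA"), genes_a)),
              gB = do.call(tiny_annotation, c(list("gB"), genes_b)))
  lf <- do.call(rbind, lapply(1:5, function(i) rbind(
    lift(paste0("a", i), "gA", "gB", "chr1", i * 20000L, i * 20000L + 1000L),
    lift(paste0("b", i), "gB", "gA", "chr1", i * 10000L, i * 10000L + 1000L))))
  mat <- cluster_pangenes(ann, build_overlap_graph(ann, lf))
  expect_equal(nrow(mat$clusters), 5L)
  expect_true(all(mat$clusters$occupancy == 2L))
})

test_that("tandem duplicates join through a shared lift target", {
  ann <- list(
    g1 = tiny_annotation("g1", tiny_gene("g1a", 1000, 2000),
                         tiny_gene("g1b", 3000, 4000)),
    g2 = tiny_annotation("g2", tiny_gene("g2", 7000, 8000)))
  lf <- rbind(lift("g1a", "g1", "g2", "chr1", 7000, 8000),
              lift("g1b", "g1", "g2", "chr1", 7000, 8000))
  mat <- cluster_pangenes(ann, build_overlap_graph(ann, lf))
  expect_equal(nrow(mat$clusters), 1L)
  expect_setequal(mat$members$gene_id, c("g1a", "g1b", "g2"))
  expect_equal(mat$clusters$occupancy, 2L)
})

test_that("clustering equals brute-force transitive closure on small instances", {
  set.seed(99)
  for (rep in 1:5) {
    n_genomes <- 3L
    genomes <- paste0("g", seq_len(n_genomes))
    anns <- list()
    for (g in genomes) {
      k <- sample(5:15, 1L)
      starts <- sort(sample.int(500, k)) * 3000L
      genes <- lapply(seq_len(k), function(i)
        tiny_gene(paste0(g, "_", i), starts[i], starts[i] + 1000L))
      anns[[g]] <- do.call(tiny_annotation, c(list(g), genes))
    }
    all_genes <- do.call(rbind, lapply(genomes, function(g) {
      d <- anns[[g]]$genes; d$genome <- g; d
    }))
    # random lifted placements onto random target genes
    lf <- do.call(rbind, lapply(1:30, function(i) {
      src <- all_genes[sample.int(nrow(all_genes), 1L), ]
      tgt <- all_genes[sample.int(nrow(all_genes), 1L), ]
      if (src$genome == tgt$genome) return(NULL)
      lift(src$gene_id, src$genome, tgt$genome, tgt$chrom,
           tgt$start, tgt$end, strand = sample(c("+", "-"), 1L))
    }))
    edges <- build_overlap_graph(anns, lf)
    mat <- cluster_pangenes(anns, edges)
    lab <- oracle_components(all_genes$gene_id, edges)
    got <- mat$members$cluster_id[match(all_genes$gene_id, mat$members$gene_id)]
    expect_equal(mclust::adjustedRandIndex(got, lab), 1)
  }
})

test_that("lowering the overlap threshold never increases the cluster count", {
  sim <- default_sim()
  sub <- sim$lifted[sim$lifted$source_genome %in% c("genome01", "genome02", "genome03") &
                      sim$lifted$target_genome %in% c("genome01", "genome02", "genome03"), ]
  anns <- sim$annotations[c("genome01", "genome02", "genome03")]
  n_prev <- Inf
  for (f in c(0.9, 0.5, 0.1)) {
    mat <- cluster_pangenes(anns, build_overlap_graph(anns, sub, f))
    expect_lte(nrow(mat$clusters), n_prev)
    n_prev <- nrow(mat$clusters)
  }
})

test_that("every gene lands in exactly one cluster (partition property)", {
  sim <- default_sim()
  mat <- cluster_sim(sim)
  n_genes <- sum(vapply(sim$annotations, function(a) nrow(a$genes), 1L))
  expect_equal(nrow(mat$members), n_genes)
  expect_equal(anyDuplicated(mat$members$gene_id), 0L)
  expect_equal(sum(mat$clusters$n_members), n_genes)
  # strand safety: no same-genome opposite-strand overlapping pair in a cluster
  bad <- FALSE
  for (cid in mat$clusters$cluster_id[mat$clusters$n_members > 1L]) {
    sub <- mat$members[mat$members$cluster_id == cid, ]
    for (g in unique(sub$genome)) {
      s <- sub[sub$genome == g, ]
      if (nrow(s) < 2L) next
      for (i in seq_len(nrow(s) - 1L)) for (j in (i + 1L):nrow(s)) {
        if (s$chrom[i] == s$chrom[j] && s$strand[i] != s$strand[j] &&
            s$start[i] < s$end[j] && s$start[j] < s$end[i]) bad <- TRUE
      }
    }
  }
  expect_false(bad)
})

test_that("components with same-genome antisense overlaps are split", {
  # two genes overlap antisense in g1; both connect to distinct g2 genes,
  # and a spurious edge chain links everything into one component
  ann <- list(
    g1 = tiny_annotation("g1", tiny_gene("p", 1000, 3000, strand = "+"),
                         tiny_gene("q", 2000, 4000, strand = "-")),
    g2 = tiny_annotation("g2", tiny_gene("rp", 1000, 3000, strand = "+"),
                         tiny_gene("rq", 2000, 4000, strand = "-")))
  lf <- rbind(lift("p", "g1", "g2", "chr1", 1000, 3000, "+"),
              lift("q", "g1", "g2", "chr1", 2000, 4000, "-"),
              # weak cross edge tying the two pairs together
              lift("p", "g1", "g2", "chr1", 2200, 3800, "-", cov = 0.5))
  edges <- build_overlap_graph(ann, lf)
  mat <- cluster_pangenes(ann, edges)
  cl_p <- mat$members$cluster_id[mat$members$gene_id == "p"]
  cl_q <- mat$members$cluster_id[mat$members$gene_id == "q"]
  expect_false(cl_p == cl_q)
})

test_that("QC standard errors follow the closed form", {
  g1 <- tiny_gene("x1", 0, 4000)
  g2 <- tiny_gene("y1", 0, 4000)
  ann <- list(gA = tiny_annotation("gA", g1), gB = tiny_annotation("gB", g2))
  # rebuild features: x1 has 2 exons, y1 has 4 (equal CDS length)
  ann$gA$features <- data.frame(transcript_id = "x1.1",
                                type = rep(c("exon", "CDS"), each = 2),
                                start = rep(c(0, 2100), 2),
                                end = rep(c(1900, 4000), 2))
  ann$gB$features <- data.frame(transcript_id = "y1.1",
                                type = rep(c("exon", "CDS"), each = 4),
                                start = rep(c(0, 1050, 2100, 3150), 2),
                                end = rep(c(950, 2000, 3050, 4000), 2))
  lf <- lift("x1", "gA", "gB", "chr1", 0, 4000)
  mat <- cluster_pangenes(ann, build_overlap_graph(ann, lf))
  mat <- cluster_qc(mat, ann)
  # exon counts {2,4}: sample SD sqrt(2), SE = sqrt(2)/sqrt(2) = 1
  expect_equal(mat$clusters$se_exon_count, 1.0)
  # singleton SE is 0
  singleton <- tiny_annotation("gC", tiny_gene("z1", 0, 1000))
  m2 <- cluster_pangenes(list(gC = singleton),
                         build_overlap_graph(list(gC = singleton), empty <-
                                               lf[0, ]))
  m2 <- cluster_qc(m2, list(gC = singleton))
  expect_equal(m2$clusters$se_exon_count, 0)
  expect_equal(m2$clusters$se_protein_length, 0)
})
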
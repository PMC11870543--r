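mk_matrix <- function(cluster_sizes, genome_order = c("gA", "gB", "gC")) {
  rows <- list()
  for (cid in seq_along(cluster_sizes)) {
    gs <- genome_order[seq_len(cluster_sizes[cid])]
    rows[[cid]] <- data.frame(
      cluster_id = cid, genome = gs, gene_id = paste0("c", cid, "_", gs),
      chrom = "chr1", start = cid * 10000L, end = cid * 10000L + 1000L,
      strand = "+")
  }
  pangene_matrix(do.call(rbind, rows), genome_order = genome_order)
}

test_that("minting follows the dual-series numbering and identifier grammar", {
  mat <- mk_matrix(c(2, 1, 3, 1, 2))
  mat <- mint_identifiers(mat, id_scheme("Os4530", "POR", 1))
  ids <- mat$clusters$stable_id
  expect_equal(ids[1L], "Os4530.POR.1.pan0000001")
  expect_equal(ids[2L], "Os4530.POR.1.pan1000001")
  expect_equal(ids[3L], "Os4530.POR.1.pan0000002")
  expect_equal(ids[4L], "Os4530.POR.1.pan1000002")
  # minting is deterministic
  expect_identical(mint_identifiers(mk_matrix(c(2, 1, 3, 1, 2)),
                                    id_scheme("Os4530", "POR", 1))$clusters$stable_id,
                   ids)
  # the worked-example identifier is reproduced from its components
  sch <- id_scheme("Os4530", "POR", 1)
  expect_equal(PanGeneKit:::format_stable_id(sch, 20022L),
               "Os4530.POR.1.pan0020022")
})

test_that("parsing inverts minting and flags the singleton series", {
  p <- parse_identifier("Os4530.POR.1.pan0020022")
  expect_equal(p$clade, "Os4530")
  expect_equal(p$group, "POR")
  expect_equal(p$version, 1L)
  expect_equal(p$number, 20022L)
  expect_false(p$is_singleton)
  expect_true(parse_identifier("Os4530.POR.1.pan1000001")$is_singleton)
  expect_error(parse_identifier("Os4530.POR.pan0000001"), "component")
  expect_error(parse_identifier("Os4530.PORX.1.pan0000001"), "malformed")
  expect_error(parse_identifier("Os4530.POR.1.pan123"), "malformed")
})

test_that("mint/parse round-trips for every cluster", {
  mat <- mint_identifiers(mk_matrix(c(3, 1, 2, 2, 1, 1)))
  p <- parse_identifier(mat$clusters$stable_id)
  expect_equal(p$is_singleton, mat$clusters$n_members == 1L)
  expect_equal(anyDuplicated(mat$clusters$stable_id), 0L)
  rebuilt <- sprintf("%s.%s.%d.pan%07d", p$clade, p$group, p$version, p$number)
  expect_identical(rebuilt, mat$clusters$stable_id)
})

test_that("no-op re-release keeps every identifier (version bumped)", {
  old <- mint_identifiers(mk_matrix(c(2, 1, 3)), id_scheme(version = 1))
  res <- remap_identifiers(old, mk_matrix(c(2, 1, 3)), id_scheme(version = 2))
  expect_true(all(res$mapping$relation == "kept"))
  expect_equal(parse_identifier(res$matrix$clusters$stable_id)$number,
               parse_identifier(old$clusters$stable_id)$number)
  expect_true(all(parse_identifier(res$matrix$clusters$stable_id)$version == 2L))
  expect_error(remap_identifiers(old, mk_matrix(c(2, 1, 3)),
                                 id_scheme(version = 1)),
               "exceed")
})

test_that("splits keep the id on the larger fragment and mark the remainder", {
  old_members <- data.frame(
    cluster_id = 1L, genome = c("gA", "gB", "gC"),
    gene_id = c("g1", "g2", "g3"), chrom = "chr1",
    start = 0L, end = 1000L, strand = "+")
  old <- mint_identifiers(pangene_matrix(old_members,
                                         genome_order = c("gA", "gB", "gC")))
  new_members <- old_members
  new_members$cluster_id <- c(1L, 1L, 2L)
  new_members$start <- c(0L, 0L, 50000L)
  new_members$end <- new_members$start + 1000L
  new <- pangene_matrix(new_members, genome_order = c("gA", "gB", "gC"))
  res <- remap_identifiers(old, new, id_scheme(version = 2))
  big <- res$matrix$clusters
  # {g1,g2} (jaccard 2/3) inherits; {g3} gets a fresh singleton id
  expect_equal(parse_identifier(big$stable_id[big$n_members == 2L])$number, 1L)
  expect_true(parse_identifier(big$stable_id[big$n_members == 1L])$is_singleton)
  expect_setequal(res$mapping$relation, c("kept", "split"))
})

test_that("merged clusters keep the larger-overlap id and absorb the other", {
  old_members <- rbind(
    data.frame(cluster_id = 1L, genome = c("gA", "gB", "gC"),
               gene_id = c("g1", "g2", "g3"), chrom = "chr1",
               start = 0L, end = 1000L, strand = "+"),
    data.frame(cluster_id = 2L, genome = c("gA", "gB"),
               gene_id = c("h1", "h2"), chrom = "chr1",
               start = 50000L, end = 51000L, strand = "+"))
  old <- mint_identifiers(pangene_matrix(old_members,
                                         genome_order = c("gA", "gB", "gC")))
  new_members <- old_members
  new_members$cluster_id <- 1L
  new <- pangene_matrix(new_members, genome_order = c("gA", "gB", "gC"))
  res <- remap_identifiers(old, new, id_scheme(version = 2))
  kept_old <- res$mapping$old_id[res$mapping$relation == "kept"]
  expect_equal(parse_identifier(kept_old)$number, 1L)  # 3-member cluster wins
  expect_true("merged" %in% res$mapping$relation)
  absorbed <- res$mapping[res$mapping$relation == "merged", ]
  expect_equal(absorbed$new_id, res$matrix$clusters$stable_id[1L])
})

test_that("singletons gaining members change series with a recorded relation", {
  old <- mint_identifiers(mk_matrix(c(1, 2)))
  new_members <- rbind(
    data.frame(cluster_id = 1L, genome = c("gA", "gB"),
               gene_id = c("c1_gA", "c1_gB_new"), chrom = "chr1",
               start = 10000L, end = 11000L, strand = "+"),
    data.frame(cluster_id = 2L, genome = c("gA", "gB"),
               gene_id = c("c2_gA", "c2_gB"), chrom = "chr1",
               start = 20000L, end = 21000L, strand = "+"))
  new <- pangene_matrix(new_members, genome_order = c("gA", "gB", "gC"))
  res <- remap_identifiers(old, new, id_scheme(version = 2))
  expect_true("kept-with-series-change" %in% res$mapping$relation)
  moved <- res$matrix$clusters$stable_id[res$matrix$clusters$cluster_id == 1L]
  expect_false(parse_identifier(moved)$is_singleton)
})
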
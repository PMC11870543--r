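# Shared fixtures and independent oracles for the test suite.

# one gene with a single full-span transcript (exon + CDS)
tiny_gene <- function(id, start, end, chrom = "chr1", strand = "+",
                      source_set = "src", biotype = "protein_coding") {
  list(genes = data.frame(gene_id = id, source_set = source_set, chrom = chrom,
                          start = start, end = end, strand = strand,
                          biotype = biotype, stringsAsFactors = FALSE),
       transcripts = data.frame(transcript_id = paste0(id, ".1"), gene_id = id,
                                stringsAsFactors = FALSE),
       features = data.frame(transcript_id = paste0(id, ".1"),
                             type = c("exon", "CDS"), start = start, end = end,
                             stringsAsFactors = FALSE))
}

tiny_annotation <- function(genome, ..., source_set = genome) {
  parts <- list(...)
  genome_annotation(genome,
                    do.call(rbind, lapply(parts, `[[`, "genes")),
                    do.call(rbind, lapply(parts, `[[`, "transcripts")),
                    do.call(rbind, lapply(parts, `[[`, "features")),
                    designated_set = source_set)
}

# default 16-genome / 1000-gene simulation, built once per test run
default_sim_cache <- new.env(parent = emptyenv())
default_sim <- function(seed = 7, ...) {
  key <- paste0("s", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(default_sim_cache[[key]]))
    default_sim_cache[[key]] <- simulate_pangenome(sim_config(seed = seed, ...))
  default_sim_cache[[key]]
}

cluster_sim <- function(sim, min_overlap_fraction = 0.5) {
  edges <- suppressWarnings(
    build_overlap_graph(sim$annotations, sim$lifted, min_overlap_fraction))
  cluster_pangenes(sim$annotations, edges,
                   reference_genome = sim$config$reference_genome)
}

ari_vs_truth <- function(mat, truth) {
  got <- mat$members$cluster_id[match(truth$gene_id, mat$members$gene_id)]
  mclust::adjustedRandIndex(got, truth$cluster_id)
}

# brute-force oracle: transitive closure over the same edge predicate,
# implemented as repeated pairwise label propagation (no graph library)
oracle_components <- function(gene_ids, edges) {
  lab <- setNames(seq_along(gene_ids), gene_ids)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      a <- edges$gene_a[i]; b <- edges$gene_b[i]
      m <- min(lab[a], lab[b])
      if (lab[a] != m || lab[b] != m) {
        lab[lab == lab[a] | lab == lab[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# independent tryptic digestion oracle: enumerate all substrings delimited by
# cleavage sites, counting internal sites directly
oracle_digest <- function(seq, missed = 2L, min_len = 7L, max_len = 50L) {
  v <- strsplit(seq, "")[[1L]]
  n <- length(v)
  sites <- which(v %in% c("K", "R") & c(v[-1L], "") != "P" &
                   seq_along(v) < n)
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  out <- character(0)
  for (si in seq_along(starts)) for (ei in si:length(ends)) {
    internal <- ei - si
    if (internal > missed) break
    len <- ends[ei] - starts[si] + 1L
    if (len >= min_len && len <= max_len)
      out <- c(out, substr(seq, starts[si], ends[ei]))
  }
  unique(out)
}

# exhaustive pseudo-position oracle over all (x, j) pairs in the +/-8 window
oracle_positions <- function(mat, reference_genome = mat$reference_genome) {
  cl <- mat$clusters
  mem <- mat$members
  out <- data.frame(cluster_id = cl$cluster_id, position = NA_real_,
                    provenance = "fallback", stringsAsFactors = FALSE)
  anchor <- function(cid, g, chrom) {
    s <- mem$start[mem$cluster_id == cid & mem$genome == g & mem$chrom == chrom]
    if (length(s)) min(s) else NA_real_
  }
  for (ch in unique(cl$mode_chrom)) {
    ids <- cl$cluster_id[cl$mode_chrom == ch]
    mean_pos <- vapply(ids, function(cid)
      mean(mem$start[mem$cluster_id == cid & mem$chrom == ch]), 0)
    ids <- ids[order(mean_pos, ids)]
    for (r in seq_along(ids)) {
      cid <- ids[r]
      ra <- anchor(cid, reference_genome, ch)
      if (!is.na(ra)) {
        out$position[out$cluster_id == cid] <- ra
        out$provenance[out$cluster_id == cid] <- "reference_member"
        next
      }
      best_delta <- Inf; best_pos <- NA_real_
      best_rank <- Inf; best_oi <- Inf
      offs <- as.vector(rbind(1:8, -(1:8)))
      for (oi in seq_along(offs)) {
        rn <- r + offs[oi]
        if (rn < 1L || rn > length(ids)) next
        nb <- ids[rn]
        ref_j <- anchor(nb, reference_genome, ch)
        if (is.na(ref_j)) next
        for (x in setdiff(mat$genome_order, reference_genome)) {
          xi <- anchor(cid, x, ch); xj <- anchor(nb, x, ch)
          if (is.na(xi) || is.na(xj)) next
          delta <- abs(xi - xj)
          rank_x <- match(x, mat$genome_order)
          better <- delta < best_delta ||
            (delta == best_delta && rank_x < best_rank) ||
            (delta == best_delta && rank_x == best_rank && oi < best_oi)
          if (better) {
            best_delta <- delta; best_pos <- ref_j + xi - xj
            best_rank <- rank_x; best_oi <- oi
          }
        }
      }
      if (is.finite(best_delta)) {
        out$position[out$cluster_id == cid] <- best_pos
        out$provenance[out$cluster_id == cid] <- "neighbor_offset"
      }
    }
  }
  out
}

random_aa <- function(n, len_range = c(20L, 60L)) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  vapply(seq_len(n), function(i)
    paste(sample(aa, sample(len_range[1L]:len_range[2L], 1L), replace = TRUE),
          collapse = ""), "")
}
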
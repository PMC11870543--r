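# Synthetic multi-genome pan-genome simulator.  Generates per-genome gene
# models descended from a shared ancestral gene order, with per-gene occupancy
# classes, tandem duplications, inversions and translocations, plus the lifted
# intervals, domain labels, evidence tables and proteins that the downstream
# stages consume.  Ground-truth cluster membership is retained throughout.

#' Simulator configuration
#'
#' @param n_genomes Number of genomes (>= 2).
#' @param n_ancestral_genes Number of ancestral loci (= truth clusters before
#'   duplication).
#' @param chromosome_count Chromosomes per genome.
#' @param chromosome_length Chromosome length in bp; layout must fit.
#' @param occupancy_profile Named fractions over occupancy classes
#'   \code{core} (all genomes), \code{shell} (uniform 3..n-2 genomes) and
#'   \code{cloud} (1 or 2 genomes); must sum to 1.
#' @param duplication_rate Per gene per genome probability of a tandem
#'   duplicate.
#' @param inversion_events,inversion_span Number of inversion events and their
#'   span in genes; an inversion flips strand and reverses order of a
#'   contiguous block in one non-reference genome.
#' @param translocation_events,translocation_span Number/span of blocks moved
#'   to another chromosome in one non-reference genome.
#' @param family_labels Named character vector genome -> varietal group;
#'   default cycles japonica/indica/aus/aromatic.
#' @param reference_genome Reference genome id (default first genome).
#' @param multi_source_reference Emit three overlapping annotation sets for
#'   the reference genome (for merge testing).
#' @param domain_catalog list of lists with fields \code{accession},
#'   \code{namespace}, \code{n_carriers} (ancestral genes carrying the
#'   domain), \code{retention} (per-protein retention probability).
#' @param te_fraction Fraction of cloud ancestral genes flagged as TEs.
#' @param plant_family_private Number of ancestral genes forced to be present
#'   in exactly the genomes of \code{family_private_target} (default: first
#'   family label) and no others.
#' @param family_private_target Family targeted by the planting above.
#' @param noise_dropout Fraction of lifted intervals dropped at random.
#' @param noise_truncate Probability a lifted interval is truncated to 40\%
#'   of its span (may fall below the clustering overlap threshold).
#' @param protein_substitution_rate Per-residue substitution rate applied
#'   per genome to the shared ancestral protein of each cluster.
#' @param gene_gap Fixed inter-gene gap in bp (genes never overlap).
#' @param seed Integer seed; the simulation is a pure function of the config.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_genomes = 16L, n_ancestral_genes = 1000L,
                       chromosome_count = 2L, chromosome_length = 6e6,
                       occupancy_profile = c(core = 0.5, shell = 0.2, cloud = 0.3),
                       duplication_rate = 0.01,
                       inversion_events = 0L, inversion_span = 5L,
                       translocation_events = 0L, translocation_span = 3L,
                       family_labels = NULL, reference_genome = NULL,
                       multi_source_reference = FALSE,
                       domain_catalog = default_domain_catalog(),
                       te_fraction = 0, plant_family_private = 0L,
                       family_private_target = NULL,
                       noise_dropout = 0, noise_truncate = 0,
                       protein_substitution_rate = 0,
                       gene_gap = 2000L, seed = 1L) {
  if (n_genomes < 2L) stop("n_genomes must be >= 2")
  if (abs(sum(occupancy_profile) - 1) > 1e-9)
    stop("occupancy_profile fractions must sum to 1")
  if (!all(names(occupancy_profile) %in% c("core", "shell", "cloud")))
    stop("occupancy_profile classes must be core/shell/cloud")
  if (!is.null(occupancy_profile["shell"]) &&
      !is.na(occupancy_profile["shell"]) && occupancy_profile["shell"] > 0 &&
      n_genomes < 5L)
    stop("shell class (3..n-2 genomes) requires at least 5 genomes")
  genomes <- sprintf("genome%02d", seq_len(n_genomes))
  if (is.null(family_labels))
    family_labels <- setNames(rep(c("japonica", "indica", "aus", "aromatic"),
                                  length.out = n_genomes), genomes)
  if (is.null(reference_genome)) reference_genome <- genomes[1L]
  cfg <- list(n_genomes = as.integer(n_genomes),
              n_ancestral_genes = as.integer(n_ancestral_genes),
              chromosome_count = as.integer(chromosome_count),
              chromosome_length = chromosome_length,
              occupancy_profile = occupancy_profile,
              duplication_rate = duplication_rate,
              inversion_events = as.integer(inversion_events),
              inversion_span = as.integer(inversion_span),
              translocation_events = as.integer(translocation_events),
              translocation_span = as.integer(translocation_span),
              genomes = genomes, family_labels = family_labels,
              reference_genome = reference_genome,
              multi_source_reference = multi_source_reference,
              domain_catalog = domain_catalog, te_fraction = te_fraction,
              plant_family_private = as.integer(plant_family_private),
              family_private_target = family_private_target,
              noise_dropout = noise_dropout, noise_truncate = noise_truncate,
              protein_substitution_rate = protein_substitution_rate,
              gene_gap = as.integer(gene_gap), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default domain catalog for the simulator
#'
#' A small mixture emulating invariable (high-retention, e.g. a NAC-like
#' transcription-factor domain) and highly variable (low-retention, NB-ARC-like
#' resistance-gene domain) protein domains in both Pfam and InterPro
#' namespaces.
#' @return list of catalog entries.
#' @export
default_domain_catalog <- function() {
  list(list(accession = "PF02365", namespace = "Pfam", n_carriers = 20L, retention = 0.95),
       list(accession = "PF00931", namespace = "Pfam", n_carriers = 30L, retention = 0.45),
       list(accession = "IPR003441", namespace = "InterPro", n_carriers = 20L, retention = 0.95),
       list(accession = "IPR002182", namespace = "InterPro", n_carriers = 30L, retention = 0.45))
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

#' Simulate a multi-genome pan-genome with known truth clusters
#'
#' Each ancestral gene is assigned an occupancy class, then placed in the
#' sampled genome subset; tandem duplications add same-genome cluster members;
#' inversions flip strand and reverse order of contiguous blocks;
#' translocations move blocks across chromosomes.  Lifted intervals are
#' emitted for every cross-genome gene pair sharing a truth cluster (clean
#' mode), positioned on the target member's span with the target locus strand.
#'
#' @param config A \code{\link{sim_config}}.
#' @return list of class \code{simulated_pangenome} with elements
#'   \code{annotations} (named list of \code{genome_annotation}),
#'   \code{reference_sets} (3 overlapping sets when requested),
#'   \code{lifted}, \code{truth} (cluster_id, genome, gene_id),
#'   \code{domains}, \code{evidence}, \code{proteins}, \code{planted},
#'   \code{config}.
#' @export
simulate_pangenome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  n <- config$n_genomes
  genomes <- config$genomes
  n_anc <- config$n_ancestral_genes
  chroms <- sprintf("chr%02d", seq_len(config$chromosome_count))

  # ancestral loci
  anc <- data.frame(
    anc_id = sprintf("anc%05d", seq_len(n_anc)),
    chrom = chroms[ceiling(seq_len(n_anc) / max(1, ceiling(n_anc / length(chroms))))],
    stringsAsFactors = FALSE)
  if (n_anc > 0) {
    anc$ord <- stats::ave(seq_len(n_anc), anc$chrom, FUN = seq_along)
    anc$length <- as.integer(round(runif(n_anc, 900, 3000)))
    anc$n_exons <- sample.int(5L, n_anc, replace = TRUE)
    anc$strand <- sample(c("+", "-"), n_anc, replace = TRUE)
    anc$class <- sample(names(config$occupancy_profile), n_anc, replace = TRUE,
                        prob = config$occupancy_profile)
  } else {
    anc$ord <- integer(0); anc$length <- integer(0); anc$n_exons <- integer(0)
    anc$strand <- character(0); anc$class <- character(0)
  }

  subsets <- lapply(seq_len(n_anc), function(i) {
    switch(anc$class[i],
           core = seq_len(n),
           shell = sort(sample.int(n, sample(3:(n - 2L), 1L))),
           cloud = sort(sample.int(n, sample(1:2, 1L))))
  })

  planted <- list(family_private = character(0), inverted = character(0),
                  translocated = character(0))
  if (config$plant_family_private > 0L && n_anc > 0) {
    target <- config$family_private_target
    if (is.null(target)) target <- config$family_labels[[1L]]
    fam_idx <- which(config$family_labels[genomes] == target)
    if (!length(fam_idx)) stop("unknown family: ", target)
    pick <- sample.int(n_anc, config$plant_family_private)
    for (i in pick) subsets[[i]] <- fam_idx
    anc$class[pick] <- "planted"
    planted$family_private <- anc$anc_id[pick]
  }

  te_anc <- character(0)
  if (config$te_fraction > 0 && n_anc > 0) {
    cloud_ids <- anc$anc_id[anc$class == "cloud"]
    te_anc <- sample(cloud_ids, round(config$te_fraction * length(cloud_ids)))
  }

  # per-genome gene layout
  mem_list <- vector("list", n)
  for (gi in seq_len(n)) {
    g <- genomes[gi]
    present <- which(vapply(subsets, function(s) gi %in% s, TRUE))
    if (!length(present)) {
      mem_list[[gi]] <- NULL
      next
    }
    df <- anc[present, , drop = FALSE]
    df$copy <- 1L
    if (config$duplication_rate > 0) {
      # duplicates only where the cluster spans >= 2 genomes: a tandem copy
      # of a single-genome locus is indistinguishable from a separate locus
      # under cross-genome alignment evidence
      multi <- vapply(subsets[present], length, 1L) >= 2L
      dup <- runif(nrow(df)) < config$duplication_rate & multi
      if (any(dup)) {
        dd <- df[dup, , drop = FALSE]
        dd$copy <- 2L
        df <- rbind(df, dd)
      }
    }
    df$sort_ord <- df$ord + (df$copy - 1L) * 0.5
    df$genome <- g
    mem_list[[gi]] <- df
  }
  mem <- do.call(rbind, mem_list)
  if (is.null(mem)) mem <- cbind(anc[0, ], copy = integer(0),
                                 sort_ord = numeric(0), genome = character(0))
  rownames(mem) <- NULL

  # rearrangement events in non-reference genomes
  nonref <- setdiff(genomes, config$reference_genome)
  pick_block <- function(span, label) {
    for (attempt in 1:50) {
      g <- sample(nonref, 1L)
      ch <- sample(chroms, 1L)
      idx <- which(mem$genome == g & mem$chrom == ch)
      idx <- idx[order(mem$sort_ord[idx])]
      if (length(idx) >= span) {
        s <- sample.int(length(idx) - span + 1L, 1L)
        return(idx[s:(s + span - 1L)])
      }
    }
    stop(label, " span (", span, " genes) exceeds available chromosome gene counts")
  }
  for (e in seq_len(config$inversion_events)) {
    blk <- pick_block(config$inversion_span, "inversion")
    mem$sort_ord[blk] <- rev(mem$sort_ord[blk])
    mem$strand[blk] <- ifelse(mem$strand[blk] == "+", "-", "+")
    planted$inverted <- union(planted$inverted, mem$anc_id[blk])
  }
  for (e in seq_len(config$translocation_events)) {
    blk <- pick_block(config$translocation_span, "translocation")
    g <- mem$genome[blk[1L]]
    from <- mem$chrom[blk[1L]]
    to <- sample(setdiff(chroms, from), 1L)
    top <- suppressWarnings(max(mem$sort_ord[mem$genome == g & mem$chrom == to], 0))
    mem$chrom[blk] <- to
    mem$sort_ord[blk] <- top + seq_along(blk)
    planted$translocated <- union(planted$translocated, mem$anc_id[blk])
  }

  # coordinates: lay out each genome chromosome in sort order, fixed gap
  mem <- mem[order(mem$genome, mem$chrom, mem$sort_ord), , drop = FALSE]
  gap <- config$gene_gap
  key <- paste(mem$genome, mem$chrom)
  mem$start <- rep(NA_integer_, nrow(mem))
  for (k in unique(key)) {
    i <- which(key == k)
    starts <- 1000L + cumsum(c(0L, head(mem$length[i] + gap, -1L)))
    mem$start[i] <- starts
  }
  mem$end <- mem$start + mem$length
  if (nrow(mem) && max(mem$end) > config$chromosome_length)
    stop("layout exceeds chromosome_length; increase it or reduce gene count")
  mem$gene_id <- if (nrow(mem))
    paste0(mem$genome, "_", mem$anc_id,
           ifelse(mem$copy > 1L, paste0("_d", mem$copy), "")) else character(0)
  mem$transcript_id <- if (nrow(mem)) paste0(mem$gene_id, ".1") else character(0)
  mem$te <- mem$anc_id %in% te_anc

  # annotations
  build_ann <- function(sub, genome, source_set, id_prefix = "") {
    if (!nrow(sub)) {
      return(genome_annotation(
        genome,
        data.frame(gene_id = character(), source_set = character(),
                   chrom = character(), start = integer(), end = integer(),
                   strand = character(), biotype = character(),
                   stringsAsFactors = FALSE),
        data.frame(transcript_id = character(), gene_id = character()),
        data.frame(transcript_id = character(), type = character(),
                   start = integer(), end = integer()),
        designated_set = source_set,
        family = unname(config$family_labels[genome])))
    }
    sub$gene_id2 <- paste0(id_prefix, sub$gene_id)
    feats <- make_exon_features(sub)
    genome_annotation(
      genome,
      data.frame(gene_id = sub$gene_id2, source_set = source_set,
                 chrom = sub$chrom, start = sub$start, end = sub$end,
                 strand = sub$strand,
                 biotype = ifelse(sub$te, "TE", "protein_coding"),
                 stringsAsFactors = FALSE),
      data.frame(transcript_id = paste0(sub$gene_id2, ".1"),
                 gene_id = sub$gene_id2, stringsAsFactors = FALSE),
      feats, designated_set = source_set,
      family = unname(config$family_labels[genome]))
  }
  annotations <- list()
  for (g in genomes) {
    sub <- mem[mem$genome == g, , drop = FALSE]
    annotations[[g]] <- build_ann(sub, g, source_set = g)
  }
  reference_sets <- NULL
  if (isTRUE(config$multi_source_reference)) {
    rg <- config$reference_genome
    sub <- mem[mem$genome == rg, , drop = FALSE]
    jitter_set <- function(sub, prefix) {
      s <- sub
      shift <- as.integer(round(runif(nrow(s), -150, 150)))
      s$start <- pmax(0L, s$start + shift)
      s$end <- s$end + as.integer(round(runif(nrow(s), -150, 150)))
      s$end <- pmax(s$end, s$start + 300L)
      s
    }
    reference_sets <- list(
      build_ann(sub, rg, source_set = "srcA"),
      build_ann(jitter_set(sub), rg, source_set = "srcB", id_prefix = "B_"),
      build_ann(jitter_set(sub), rg, source_set = "srcC", id_prefix = "C_"))
  }

  # truth clusters
  truth <- data.frame(cluster_id = mem$anc_id, genome = mem$genome,
                      gene_id = mem$gene_id, stringsAsFactors = FALSE)

  # lifted intervals: each cross-genome truth pair, placed on the target span
  lifted <- empty_lifted()
  if (nrow(mem)) {
    src <- mem[, c("anc_id", "genome", "gene_id")]
    tgt <- mem[, c("anc_id", "genome", "chrom", "start", "end", "strand")]
    names(tgt) <- c("anc_id", "t_genome", "t_chrom", "t_start", "t_end", "t_strand")
    pairs <- merge(src, tgt, by = "anc_id")
    pairs <- pairs[pairs$genome != pairs$t_genome, , drop = FALSE]
    lifted <- data.frame(gene_id = pairs$gene_id, source_genome = pairs$genome,
                         target_genome = pairs$t_genome,
                         target_chrom = pairs$t_chrom,
                         start = pairs$t_start, end = pairs$t_end,
                         lifted_strand = pairs$t_strand, coverage = 1,
                         stringsAsFactors = FALSE)
    lifted <- lifted[order(lifted$source_genome, lifted$target_genome,
                           lifted$target_chrom, lifted$start, lifted$gene_id), ,
                     drop = FALSE]
    rownames(lifted) <- NULL
    if (config$noise_truncate > 0 && nrow(lifted)) {
      hit <- runif(nrow(lifted)) < config$noise_truncate
      lifted$end[hit] <- lifted$start[hit] +
        pmax(1L, as.integer(round(0.4 * (lifted$end[hit] - lifted$start[hit]))))
      lifted$coverage[hit] <- 0.4
    }
    if (config$noise_dropout > 0 && nrow(lifted)) {
      keep <- runif(nrow(lifted)) >= config$noise_dropout
      lifted <- lifted[keep, , drop = FALSE]
    }
  }

  # domain assignments
  domains <- data.frame(protein_id = character(), gene_id = character(),
                        genome = character(), source_set = character(),
                        namespace = character(), accession = character(),
                        te_flag = logical(), stringsAsFactors = FALSE)
  if (n_anc > 0) {
    rows <- list()
    for (entry in config$domain_catalog) {
      carriers <- sample(anc$anc_id, min(entry$n_carriers, n_anc))
      sub <- mem[mem$anc_id %in% carriers, , drop = FALSE]
      keep <- runif(nrow(sub)) < entry$retention
      sub <- sub[keep, , drop = FALSE]
      if (nrow(sub))
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = sub$transcript_id, gene_id = sub$gene_id,
          genome = sub$genome, source_set = sub$genome,
          namespace = entry$namespace, accession = entry$accession,
          te_flag = sub$te, stringsAsFactors = FALSE)
    }
    if (length(rows)) domains <- do.call(rbind, rows)
    domains <- unique(domains)
    domains <- domains[order(domains$namespace, domains$accession,
                             domains$protein_id), , drop = FALSE]
    rownames(domains) <- NULL
  }

  # evidence tables keyed to occupancy class of the parent cluster
  occ_of_anc <- vapply(subsets, length, 1L)
  names(occ_of_anc) <- anc$anc_id
  evidence <- list()
  if (nrow(mem)) {
    occ <- occ_of_anc[mem$anc_id]
    frac <- if (n > 1) (occ - 1) / (n - 1) else 1
    clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
    evidence$aed_min <- data.frame(
      gene_id = mem$gene_id,
      value = clamp(rnorm(nrow(mem), 0.9 - 0.4 * frac, 0.05), 0, 1))
    evidence$log_expression <- data.frame(
      gene_id = mem$gene_id,
      value = clamp(rnorm(nrow(mem), 1 + 4 * frac, 0.5), 0, 20))
    evidence$plddt_mean <- data.frame(
      gene_id = mem$gene_id,
      value = clamp(rnorm(nrow(mem), 55 + 25 * frac, 3), 0, 100))
    evidence$ortholog_count <- data.frame(
      gene_id = mem$gene_id, value = rpois(nrow(mem), 2 + 8 * frac))
    evidence$paralog_count <- data.frame(
      gene_id = mem$gene_id, value = rpois(nrow(mem), 1.5))
  }

  # proteins: shared ancestral sequence per cluster, per-genome substitutions
  proteins <- list()
  if (n_anc > 0) {
    anc_seq <- vapply(seq_len(n_anc), function(i) {
      paste(sample(AA20, sample(200:600, 1L), replace = TRUE), collapse = "")
    }, "")
    names(anc_seq) <- anc$anc_id
    for (g in genomes) {
      sub <- mem[mem$genome == g, , drop = FALSE]
      seqs <- anc_seq[sub$anc_id]
      if (config$protein_substitution_rate > 0 && nrow(sub)) {
        seqs <- vapply(seqs, function(s) {
          v <- strsplit(s, "")[[1L]]
          hit <- runif(length(v)) < config$protein_substitution_rate
          v[hit] <- sample(AA20, sum(hit), replace = TRUE)
          paste(v, collapse = "")
        }, "")
      }
      names(seqs) <- sub$transcript_id
      proteins[[g]] <- seqs
    }
  }

  structure(list(config = config, annotations = annotations,
                 reference_sets = reference_sets, lifted = lifted,
                 truth = truth, domains = domains, evidence = evidence,
                 proteins = proteins, planted = planted),
            class = "simulated_pangenome")
}

# split each gene span into n_exons exons with 100 bp introns; CDS == exons
make_exon_features <- function(sub) {
  if (!nrow(sub))
    return(data.frame(transcript_id = character(), type = character(),
                      start = integer(), end = integer()))
  rows <- vector("list", nrow(sub))
  for (i in seq_len(nrow(sub))) {
    k <- sub$n_exons[i]
    L <- sub$end[i] - sub$start[i]
    intr <- 100L * (k - 1L)
    exlen <- (L - intr) %/% k
    starts <- sub$start[i] + (seq_len(k) - 1L) * (exlen + 100L)
    ends <- starts + exlen
    ends[k] <- sub$end[i]
    tid <- paste0(sub$gene_id2[i], ".1")
    rows[[i]] <- data.frame(transcript_id = tid,
                            type = rep(c("exon", "CDS"), each = k),
                            start = rep(starts, 2L), end = rep(ends, 2L),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @export
print.simulated_pangenome <- function(x, ...) {
  cat("simulated_pangenome:", x$config$n_genomes, "genomes,",
      x$config$n_ancestral_genes, "ancestral genes\n")
  cat("  genes:", nrow(x$truth), " lifted intervals:", nrow(x$lifted),
      " domain records:", nrow(x$domains), "\n")
  invisible(x)
}

#' Write a simulated pan-genome to disk as plain-text fixtures
#'
#' Emits one GFF3 per genome (plus the three overlapping reference sets when
#' simulated), one BED6 per directed genome pair, an InterProScan-style
#' domain TSV, a truth-cluster TSV, per-metric evidence TSVs and per-genome
#' protein FASTA, plus a manifest with md5 checksums.
#'
#' @param sim A \code{simulated_pangenome}.
#' @param directory Output directory (created if absent).
#' @return data.frame manifest (file, md5), invisibly.
#' @export
write_fixture <- function(sim, directory) {
  stopifnot(inherits(sim, "simulated_pangenome"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (g in names(sim$annotations)) {
    p <- file.path(directory, paste0(g, ".gff3"))
    write_annotation(sim$annotations[[g]], p)
    files <- c(files, p)
  }
  if (!is.null(sim$reference_sets)) {
    for (ann in sim$reference_sets) {
      p <- file.path(directory, paste0(ann$genome, ".", ann$designated_set, ".gff3"))
      write_annotation(ann, p)
      files <- c(files, p)
    }
  }
  gs <- sim$config$genomes
  for (s in gs) for (t in gs) {
    if (s == t) next
    p <- file.path(directory, sprintf("lifted_%s_to_%s.bed", s, t))
    sub <- sim$lifted[sim$lifted$source_genome == s &
                        sim$lifted$target_genome == t, , drop = FALSE]
    write_lifted_bed(sub, p)
    files <- c(files, p)
  }
  p <- file.path(directory, "truth_clusters.tsv")
  write.table(sim$truth[order(sim$truth$cluster_id, sim$truth$genome,
                              sim$truth$gene_id), ],
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, p)
  p <- file.path(directory, "domains.tsv")
  write_interproscan_tsv(sim$domains, p)
  files <- c(files, p)
  p <- file.path(directory, "domain_gene_map.tsv")
  write.table(sim$domains, p, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, p)
  for (metric in names(sim$evidence)) {
    p <- file.path(directory, paste0("evidence_", metric, ".tsv"))
    write.table(sim$evidence[[metric]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, p)
  }
  for (g in names(sim$proteins)) {
    p <- file.path(directory, paste0("proteins_", g, ".fasta"))
    sq <- Biostrings::AAStringSet(sim$proteins[[g]])
    Biostrings::writeXStringSet(sq, p)
    files <- c(files, p)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  write.table(manifest, file.path(directory, "MANIFEST.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

# InterProScan 13-column dialect; only columns 1, 4, 5 and 12 carry signal
write_interproscan_tsv <- function(domains, path) {
  if (!nrow(domains)) {
    file.create(path)
    return(invisible(path))
  }
  is_pf <- domains$namespace == "Pfam"
  out <- data.frame(
    v1 = domains$protein_id, v2 = "-", v3 = 0,
    v4 = ifelse(is_pf, "Pfam", "ProSiteProfiles"),
    v5 = ifelse(is_pf, domains$accession, paste0("PS", substr(domains$accession, 4, 9))),
    v6 = "-", v7 = 1, v8 = 10, v9 = 0.0, v10 = "T", v11 = "01-01-2024",
    v12 = ifelse(is_pf, "-", domains$accession), v13 = "-",
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
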
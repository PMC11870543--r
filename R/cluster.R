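# Pan-gene cluster construction: overlap-edge derivation from lifted-interval
# evidence, connected-component clustering with a strand-validity split pass,
# and per-cluster QC statistics.

#' Build the cross-genome overlap-edge list
#'
#' An undirected edge (a, b) is emitted when gene a's interval lifted onto
#' gene b's genome overlaps b's span by at least \code{min_overlap_fraction}
#' of the shorter of the two features, and the lifted strand equals b's
#' strand.  Evidence in either direction of a genome pair suffices; duplicate
#' edges keep the strongest overlap fraction.
#'
#' @param annotations Named list of \code{genome_annotation}, one per genome.
#' @param lifted data.frame of lifted intervals
#'   (see \code{\link{read_lifted_bed}}).
#' @param min_overlap_fraction Overlap threshold (default 0.5).
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{overlap_bp}, \code{overlap_fraction}, \code{strand_consistent};
#'   attribute \code{skipped} counts lifted records naming unknown
#'   genes/genomes.
#' @export
build_overlap_graph <- function(annotations, lifted, min_overlap_fraction = 0.5) {
  all_genes <- combined_gene_table(annotations)
  known <- paste(lifted$source_genome, lifted$gene_id) %in%
    paste(all_genes$genome, all_genes$gene_id)
  known <- known & lifted$target_genome %in% names(annotations)
  n_skip <- sum(!known)
  if (n_skip > 0)
    warning(n_skip, " lifted interval(s) naming unknown genes/genomes skipped")
  lifted <- lifted[known, , drop = FALSE]

  out <- vector("list", length(annotations))
  for (ti in seq_along(annotations)) {
    tg <- names(annotations)[ti]
    lf <- lifted[lifted$target_genome == tg, , drop = FALSE]
    genes <- annotations[[tg]]$genes
    if (!nrow(lf) || !nrow(genes)) next
    qr <- GenomicRanges::GRanges(lf$target_chrom,
                                 IRanges::IRanges(lf$start + 1L, lf$end))
    sr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L, genes$end))
    hits <- GenomicRanges::findOverlaps(qr, sr, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    if (!length(qi)) next
    ov <- pmin(lf$end[qi], genes$end[si]) - pmax(lf$start[qi], genes$start[si])
    shorter <- pmin(lf$end[qi] - lf$start[qi], genes$end[si] - genes$start[si])
    strand_ok <- lf$lifted_strand[qi] == genes$strand[si]
    pass <- strand_ok & (ov / shorter >= min_overlap_fraction) &
      lf$gene_id[qi] != genes$gene_id[si]
    if (!any(pass)) next
    out[[ti]] <- data.frame(gene_a = lf$gene_id[qi][pass],
                            gene_b = genes$gene_id[si][pass],
                            overlap_bp = ov[pass],
                            overlap_fraction = pmin(1, ov[pass] / shorter[pass]),
                            strand_consistent = TRUE,
                            stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, out)
  if (is.null(edges))
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        overlap_bp = integer(), overlap_fraction = numeric(),
                        strand_consistent = logical(), stringsAsFactors = FALSE)
  # undirected dedup, keeping the strongest evidence per pair
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  edges$gene_a <- a; edges$gene_b <- b
  edges <- edges[order(a, b, -edges$overlap_fraction), , drop = FALSE]
  edges <- edges[!duplicated(paste(edges$gene_a, edges$gene_b)), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "skipped") <- n_skip
  edges
}

combined_gene_table <- function(annotations) {
  cols <- c("gene_id", "source_set", "chrom", "start", "end", "strand",
            "biotype")
  rows <- lapply(names(annotations), function(g) {
    genes <- annotations[[g]]$genes[, cols, drop = FALSE]
    if (!nrow(genes)) return(NULL)
    tx <- annotations[[g]]$transcripts
    tx_by <- vapply(split(tx$transcript_id, tx$gene_id),
                    function(v) paste(sort(v), collapse = ","), "")
    genes$transcripts <- unname(tx_by[genes$gene_id])
    genes$transcripts[is.na(genes$transcripts)] <- ""
    genes$genome <- g
    genes
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), source_set = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), biotype = character(),
                      transcripts = character(), genome = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cluster genes into pan-genes
#'
#' Pan-genes are the connected components of the overlap-edge graph; genes
#' with no edges become singleton clusters.  A validity pass splits any
#' component holding two same-genome genes that overlap each other on
#' opposite strands: those genes seed sub-components and every other member
#' joins the seed it reaches through the strongest edges.  Provisional
#' cluster ids are assigned in order of (mode chromosome, mean member start
#' on the mode chromosome).
#'
#' @param annotations Named list of \code{genome_annotation}.
#' @param edges Edge list from \code{\link{build_overlap_graph}}.
#' @param reference_genome Reference genome id (default first annotation).
#' @param policy An \code{\link{occupancy_policy}}; default derives from the
#'   number of annotations.
#' @return An object of class \code{pangene_matrix}: list with \code{clusters}
#'   (one row per pan-gene), \code{members} (long table), \code{genome_order},
#'   \code{reference_genome}, \code{n_genomes}.
#' @export
cluster_pangenes <- function(annotations, edges,
                             reference_genome = names(annotations)[1L],
                             policy = NULL) {
  all_genes <- combined_gene_table(annotations)
  if (is.null(policy))
    policy <- occupancy_policy(n_genomes = length(annotations))
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b", "overlap_fraction")],
    directed = FALSE, vertices = data.frame(name = all_genes$gene_id))
  membership <- igraph::components(g)$membership[all_genes$gene_id]

  membership <- split_strand_conflicts(all_genes, edges, membership)

  members <- all_genes
  members$component <- membership

  # mode chromosome and ordering position per component
  comp_ids <- sort(unique(membership))
  idx_by_comp <- split(seq_len(nrow(members)), members$component)
  mode_chrom <- character(length(comp_ids))
  order_pos <- numeric(length(comp_ids))
  ref <- reference_genome
  for (k in seq_along(comp_ids)) {
    i <- idx_by_comp[[as.character(comp_ids[k])]]
    tab <- table(members$chrom[i])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      ref_chroms <- members$chrom[i][members$genome[i] == ref]
      hit <- intersect(top, ref_chroms)
      top <- if (length(hit)) sort(hit)[1L] else sort(top)[1L]
    }
    mode_chrom[k] <- top
    on_mode <- i[members$chrom[i] == top]
    order_pos[k] <- mean(members$start[on_mode])
  }
  ord <- order(mode_chrom, order_pos, comp_ids)
  new_id <- integer(max(comp_ids, 0L))
  new_id[comp_ids[ord]] <- seq_along(comp_ids)
  members$cluster_id <- new_id[members$component]
  members$component <- NULL

  occ <- integer(length(comp_ids))
  nm <- integer(length(comp_ids))
  occ_tab <- tapply(members$genome, members$cluster_id,
                    function(v) length(unique(v)))
  occ[as.integer(names(occ_tab))] <- as.integer(occ_tab)
  nm_tab <- tapply(members$gene_id, members$cluster_id, length)
  nm[as.integer(names(nm_tab))] <- as.integer(nm_tab)
  clusters <- data.frame(
    cluster_id = seq_along(comp_ids),
    stable_id = NA_character_,
    occupancy = occ,
    occupancy_class = vapply(occ, classify_occupancy, "", policy = policy),
    mode_chrom = mode_chrom[ord],
    pseudo_position = NA_real_,
    n_members = nm,
    se_exon_count = NA_real_, se_protein_length = NA_real_,
    stringsAsFactors = FALSE)
  rownames(clusters) <- NULL
  members <- members[order(members$cluster_id, members$genome,
                           members$gene_id), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(clusters = clusters, members = members,
                 genome_order = names(annotations),
                 reference_genome = reference_genome,
                 n_genomes = length(annotations)),
            class = "pangene_matrix")
}

# split components containing same-genome opposite-strand overlapping genes:
# each offending gene seeds a sub-component; other members attach to the
# seed reached with the smallest accumulated (1 - overlap_fraction) cost
split_strand_conflicts <- function(all_genes, edges, membership) {
  next_comp <- max(membership, 0L) + 1L
  for (comp in unique(membership)) {
    i <- which(membership == comp)
    if (length(i) < 2L) next
    seeds <- character(0)
    for (gset in split(i, all_genes$genome[i])) {
      if (length(gset) < 2L) next
      for (x in seq_along(gset)) for (y in seq_len(x - 1L)) {
        a <- gset[x]; b <- gset[y]
        if (all_genes$chrom[a] == all_genes$chrom[b] &&
            all_genes$strand[a] != all_genes$strand[b] &&
            all_genes$start[a] < all_genes$end[b] &&
            all_genes$start[b] < all_genes$end[a]) {
          seeds <- union(seeds, all_genes$gene_id[c(a, b)])
        }
      }
    }
    if (length(seeds) < 2L) next
    ids <- all_genes$gene_id[i]
    sub_e <- edges[edges$gene_a %in% ids & edges$gene_b %in% ids, , drop = FALSE]
    sg <- igraph::graph_from_data_frame(
      data.frame(from = sub_e$gene_a, to = sub_e$gene_b,
                 weight = 1 - sub_e$overlap_fraction + 1e-9),
      directed = FALSE, vertices = data.frame(name = ids))
    seeds <- sort(seeds)
    d <- igraph::distances(sg, v = ids, to = seeds)
    assign_seed <- apply(d, 1L, function(r) seeds[which.min(r)])
    for (s in seq_along(seeds)) {
      grp <- ids[assign_seed == seeds[s]]
      if (s == 1L) next  # first seed keeps the original component id
      membership[match(grp, all_genes$gene_id)] <- next_comp
      next_comp <- next_comp + 1L
    }
  }
  membership
}

#' Assemble a pan-gene matrix from a member table
#'
#' Builds the \code{pangene_matrix} structure from an explicit membership
#' assignment (e.g. hand-curated clusters or an external clustering), filling
#' occupancy, class and mode chromosome.  Columns \code{source_set},
#' \code{biotype} and \code{transcripts} default to the genome name,
#' \code{protein_coding}, and \code{<gene_id>.1}.
#'
#' @param members data.frame with columns \code{cluster_id}, \code{genome},
#'   \code{gene_id}, \code{chrom}, \code{start}, \code{end}, \code{strand}.
#' @param genome_order Declared genome order (default: sorted unique genomes).
#' @param reference_genome Reference genome id (default first in order).
#' @param policy Optional \code{\link{occupancy_policy}}.
#' @return A \code{pangene_matrix}.
#' @export
pangene_matrix <- function(members, genome_order = sort(unique(members$genome)),
                           reference_genome = genome_order[1L], policy = NULL) {
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  if (is.null(members$source_set)) members$source_set <- members$genome
  if (is.null(members$biotype)) members$biotype <- "protein_coding"
  if (is.null(members$transcripts)) members$transcripts <- paste0(members$gene_id, ".1")
  if (anyDuplicated(members$gene_id))
    stop("a gene may belong to only one cluster")
  if (is.null(policy)) policy <- occupancy_policy(length(genome_order))
  ids <- sort(unique(members$cluster_id))
  occ <- tapply(members$genome, members$cluster_id, function(v) length(unique(v)))
  nm <- tapply(members$gene_id, members$cluster_id, length)
  mode_chrom <- tapply(seq_len(nrow(members)), members$cluster_id, function(i) {
    tab <- table(members$chrom[i])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      hit <- intersect(top, members$chrom[i][members$genome[i] == reference_genome])
      top <- if (length(hit)) sort(hit)[1L] else sort(top)[1L]
    }
    top
  })
  clusters <- data.frame(
    cluster_id = ids, stable_id = NA_character_,
    occupancy = as.integer(occ[as.character(ids)]),
    occupancy_class = vapply(as.integer(occ[as.character(ids)]),
                             classify_occupancy, "", policy = policy),
    mode_chrom = as.character(mode_chrom[as.character(ids)]),
    pseudo_position = NA_real_,
    n_members = as.integer(nm[as.character(ids)]),
    se_exon_count = NA_real_, se_protein_length = NA_real_,
    stringsAsFactors = FALSE)
  structure(list(clusters = clusters, members = members,
                 genome_order = genome_order,
                 reference_genome = reference_genome,
                 n_genomes = length(genome_order)),
            class = "pangene_matrix")
}

#' Fill per-cluster QC statistics
#'
#' For each member gene the canonical (longest-CDS) transcript contributes
#' its exon count and CDS length in amino acids; the cluster records the
#' standard error of each across members.  Singletons get SE 0.  Members
#' without CDS are excluded from the protein-length SE with a warning.
#'
#' @param mat A \code{pangene_matrix}.
#' @param annotations The annotations the matrix was built from.
#' @return The matrix with \code{se_exon_count} and \code{se_protein_length}
#'   filled.
#' @export
cluster_qc <- function(mat, annotations) {
  feats <- do.call(rbind, lapply(annotations, function(a) a$features))
  txs <- do.call(rbind, lapply(annotations, function(a) a$transcripts))
  cds <- feats[feats$type == "CDS", , drop = FALSE]
  cds_len <- tapply(cds$end - cds$start, cds$transcript_id, sum)
  ex <- feats[feats$type == "exon", , drop = FALSE]
  ex_n <- tapply(ex$transcript_id, ex$transcript_id, length)
  # canonical transcript per gene: longest CDS, ties by id
  txs$cds <- ifelse(txs$transcript_id %in% names(cds_len),
                    cds_len[txs$transcript_id], 0)
  txs <- txs[order(txs$gene_id, -txs$cds, txs$transcript_id), , drop = FALSE]
  canon <- txs[!duplicated(txs$gene_id), , drop = FALSE]
  canon$exons <- ifelse(canon$transcript_id %in% names(ex_n),
                        ex_n[canon$transcript_id], 0L)
  canon$aa <- canon$cds / 3

  m <- mat$members
  m$exons <- canon$exons[match(m$gene_id, canon$gene_id)]
  m$aa <- canon$aa[match(m$gene_id, canon$gene_id)]
  if (any(m$aa == 0, na.rm = TRUE))
    warning(sum(m$aa == 0, na.rm = TRUE),
            " member(s) without CDS excluded from protein-length SE")
  se <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(0)
    sd(v) / sqrt(length(v))
  }
  se_ex <- tapply(m$exons, m$cluster_id, se)
  se_aa <- tapply(ifelse(m$aa > 0, m$aa, NA_real_), m$cluster_id, se)
  cl <- mat$clusters
  cl$se_exon_count <- unname(se_ex[as.character(cl$cluster_id)])
  cl$se_protein_length <- unname(se_aa[as.character(cl$cluster_id)])
  mat$clusters <- cl
  mat
}

#' @export
print.pangene_matrix <- function(x, ...) {
  cl <- x$clusters
  cat("pangene_matrix:", nrow(cl), "pan-genes over", x$n_genomes, "genomes\n")
  cat("  members:", nrow(x$members),
      " singletons:", sum(cl$occupancy == 1L), "\n")
  tab <- table(cl$occupancy_class)
  cat("  classes:", paste(names(tab), as.integer(tab), sep = "=", collapse = " "),
      "\n")
  if (!all(is.na(cl$stable_id)))
    cat("  stable ids:", cl$stable_id[1L], "...\n")
  invisible(x)
}

#' Summarize a pan-gene matrix
#' @param object A \code{pangene_matrix}.
#' @param ... Unused.
#' @return data.frame of per-class cluster counts and occupancy spectrum.
#' @export
summary.pangene_matrix <- function(object, ...) {
  spec <- occupancy_spectrum(object)
  data.frame(occupancy = as.integer(names(spec)),
             n_pangenes = as.integer(spec), row.names = NULL)
}
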
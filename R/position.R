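# Reference-relative pseudo-position assignment and cross-chromosome flags.
#
# The anchor coordinate of a gene is its start (0-based): strand-stable in
# GFF3 and the coordinate genome browsers sort on.

#' Assign pseudo-positions to pan-genes
#'
#' Each cluster first receives its mode chromosome (most common chromosome
#' among members; ties resolved to a reference member's chromosome when
#' present, else the lexicographically smallest).  Clusters with a reference
#' member on the mode chromosome take that member's anchor coordinate.
#' Otherwise neighboring clusters on the same mode chromosome are scanned at
#' rank offsets j = 1, -1, 2, -2, ..., 8, -8 (matrix ordered by mean member
#' anchor on the mode chromosome): for every genome x with a member gene_xi
#' in the cluster and a member gene_xj in the neighbor, where the neighbor
#' also holds a reference member gene_1j, the candidate position is
#' pos(gene_1j) + pos(gene_xi) - pos(gene_xj); the candidate minimizing
#' |pos(gene_xi) - pos(gene_xj)| wins (ties: earliest genome in the declared
#' genome order, then the earlier offset in scan order).  Clusters with no
#' candidate in the +/-8 window are flagged as fallback and ordered after the
#' last positioned cluster of their mode chromosome.
#'
#' @param mat A \code{pangene_matrix}.
#' @param reference_genome Reference genome id (default: the matrix's).
#' @param chrom_map Optional data.frame (genome, chrom, normalized) renaming
#'   per-genome chromosomes onto a shared naming before comparison.
#' @return data.frame: cluster_id, mode_chrom, position (NA when unplaced),
#'   provenance (\code{reference_member}, \code{neighbor_offset}, or
#'   \code{fallback}), genome_x, offset_j.
#' @export
assign_pseudo_positions <- function(mat, reference_genome = mat$reference_genome,
                                    chrom_map = NULL) {
  if (!nrow(mat$clusters))
    return(data.frame(cluster_id = integer(), mode_chrom = character(),
                      position = numeric(), provenance = character(),
                      genome_x = character(), offset_j = integer(),
                      stringsAsFactors = FALSE))
  mem <- normalize_chroms(mat$members, chrom_map)
  cl <- mat$clusters
  offsets <- as.vector(rbind(1:8, -(1:8)))

  # matrix order: within each mode chromosome, by mean member anchor on it
  mem_mode <- mem[mem$chrom == cl$mode_chrom[match(mem$cluster_id, cl$cluster_id)], ,
                  drop = FALSE]
  mean_anchor <- tapply(mem_mode$start, mem_mode$cluster_id, mean)
  cl$order_pos <- unname(mean_anchor[as.character(cl$cluster_id)])
  cl$order_pos[is.na(cl$order_pos)] <- Inf

  out <- data.frame(cluster_id = cl$cluster_id, mode_chrom = cl$mode_chrom,
                    position = NA_real_, provenance = "fallback",
                    genome_x = NA_character_, offset_j = NA_integer_,
                    stringsAsFactors = FALSE)

  # per (cluster, genome) anchor on the cluster's mode chromosome: 5'-most
  mem_mode <- mem_mode[order(mem_mode$cluster_id, mem_mode$genome,
                             mem_mode$start), , drop = FALSE]
  first <- !duplicated(paste(mem_mode$cluster_id, mem_mode$genome))
  anchors <- mem_mode[first, c("cluster_id", "genome", "start"), drop = FALSE]

  for (ch in sort(unique(cl$mode_chrom))) {
    rows <- which(cl$mode_chrom == ch)
    rows <- rows[order(cl$order_pos[rows], cl$cluster_id[rows])]
    ids <- cl$cluster_id[rows]
    a_ch <- anchors[anchors$cluster_id %in% ids, , drop = FALSE]
    # anchor lookup: [cluster, genome]
    akey <- split(setNames(a_ch$start, a_ch$genome), a_ch$cluster_id)
    for (r in seq_along(ids)) {
      cid <- ids[r]
      a <- akey[[as.character(cid)]]
      if (!is.null(a) && reference_genome %in% names(a)) {
        out$position[out$cluster_id == cid] <- a[[reference_genome]]
        out$provenance[out$cluster_id == cid] <- "reference_member"
        next
      }
      best <- NULL
      for (oi in seq_along(offsets)) {
        j <- offsets[oi]
        rn <- r + j
        if (rn < 1L || rn > length(ids)) next
        nb <- akey[[as.character(ids[rn])]]
        if (is.null(nb) || !reference_genome %in% names(nb)) next
        cand_genomes <- intersect(names(a), names(nb))
        cand_genomes <- setdiff(cand_genomes, reference_genome)
        for (x in cand_genomes) {
          delta <- abs(a[[x]] - nb[[x]])
          pos <- nb[[reference_genome]] + a[[x]] - nb[[x]]
          rank_x <- match(x, mat$genome_order)
          key <- c(delta, rank_x, oi)
          if (is.null(best) || lex_less(key, best$key))
            best <- list(key = key, pos = pos, x = x, j = j)
        }
      }
      if (!is.null(best)) {
        i <- which(out$cluster_id == cid)
        out$position[i] <- best$pos
        out$provenance[i] <- "neighbor_offset"
        out$genome_x[i] <- best$x
        out$offset_j[i] <- best$j
      }
    }
  }
  out
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

normalize_chroms <- function(members, chrom_map) {
  if (is.null(chrom_map)) return(members)
  key <- paste(chrom_map$genome, chrom_map$chrom)
  hit <- match(paste(members$genome, members$chrom), key)
  members$chrom <- ifelse(is.na(hit), members$chrom,
                          chrom_map$normalized[hit])
  members
}

#' Flag pan-genes spanning multiple chromosomes
#'
#' Clusters with occupancy greater than 2 whose members map to two or more
#' distinct (normalized) chromosome names; candidate translocations or
#' assembly artefacts.
#'
#' @param mat A \code{pangene_matrix}.
#' @param chrom_map Optional per-genome chromosome-name normalization
#'   (data.frame genome, chrom, normalized).
#' @return Integer vector of flagged cluster ids.
#' @export
flag_cross_chromosome <- function(mat, chrom_map = NULL) {
  mem <- normalize_chroms(mat$members, chrom_map)
  nchr <- tapply(mem$chrom, mem$cluster_id, function(v) length(unique(v)))
  occ <- mat$clusters$occupancy[match(as.integer(names(nchr)),
                                      mat$clusters$cluster_id)]
  sort(as.integer(names(nchr))[nchr >= 2L & occ > 2L])
}
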
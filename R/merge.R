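# Merging of multiple overlapping annotation sets for one genome into a
# single non-redundant gene set (the three-source reference-genome case).

#' Merge policy
#'
#' @param min_overlap_fraction Minimum overlap as a fraction of the shorter
#'   gene's length for two genes to merge (default 0.5, i.e. >= 50\%).
#' @param id_priority Ordered source-set names; the merged gene takes the id
#'   of its member from the highest-priority source.
#' @param require_same_strand Only merge genes on the same strand.
#' @param protein_coding_only Only protein-coding genes participate in
#'   merging; others pass through unmerged.
#' @return list of class \code{merge_policy}.
#' @export
merge_policy <- function(min_overlap_fraction = 0.5,
                         id_priority = character(0),
                         require_same_strand = TRUE,
                         protein_coding_only = TRUE) {
  if (!(min_overlap_fraction > 0 && min_overlap_fraction <= 1))
    stop("min_overlap_fraction must be in (0, 1]")
  structure(list(min_overlap_fraction = min_overlap_fraction,
                 id_priority = id_priority,
                 require_same_strand = require_same_strand,
                 protein_coding_only = protein_coding_only),
            class = "merge_policy")
}

#' Merge overlapping annotation sets of one genome
#'
#' Protein-coding genes whose spans overlap by at least
#' \code{min_overlap_fraction} of the shorter gene's length, on the same
#' strand, are merged transitively (connected components of the pairwise
#' overlap graph, with the threshold evaluated on the original gene pairs).
#' Each merged gene's span is the envelope of the most extreme 5' and 3'
#' coordinates of its members' protein-coding transcripts; its id comes from
#' the highest-priority source set (ties resolved to the 5'-most member).
#' All member transcripts are retained under the merged gene.
#'
#' @param sets list of \code{genome_annotation}, all for the same genome.
#' @param policy A \code{\link{merge_policy}}; if \code{id_priority} is empty
#'   it defaults to the order of \code{sets}.
#' @return A merged \code{genome_annotation}; merged genes carry a
#'   \code{merged_from} column listing member gene ids.
#' @export
merge_annotation_sets <- function(sets, policy = merge_policy()) {
  stopifnot(length(sets) >= 1L)
  genomes <- vapply(sets, function(a) a$genome, "")
  if (length(unique(genomes)) != 1L)
    stop("all annotation sets must come from the same genome, got: ",
         paste(unique(genomes), collapse = ", "))
  if (!length(policy$id_priority))
    policy$id_priority <- vapply(sets, function(a) a$genes$source_set[1L], "")

  # disambiguate duplicate ids across sets (same-set duplicates are rejected
  # by the constructor)
  seen <- character(0)
  renamed <- character(0)
  sets <- lapply(sets, function(a) {
    clash <- a$genes$gene_id %in% seen
    if (any(clash)) {
      renamed <<- c(renamed, a$genes$gene_id[clash])
      new_id <- paste0(a$genes$gene_id, "_", a$genes$source_set)
      remap <- setNames(ifelse(clash, new_id, a$genes$gene_id), a$genes$gene_id)
      a$transcripts$gene_id <- unname(remap[a$transcripts$gene_id])
      a$genes$gene_id <- unname(remap[a$genes$gene_id])
    }
    seen <<- c(seen, a$genes$gene_id)
    a
  })
  if (length(renamed))
    warning("duplicate gene ids across sets disambiguated with source suffix: ",
            paste(unique(renamed), collapse = ", "))
  genes <- do.call(rbind, lapply(sets, function(a) a$genes))
  txs <- do.call(rbind, lapply(sets, function(a) a$transcripts))
  feats <- do.call(rbind, lapply(sets, function(a) a$features))
  rownames(genes) <- NULL

  if (is.null(genes$merged_from)) genes$merged_from <- ""

  # iterate single rounds to a fixed point: merged envelopes can create new
  # qualifying overlaps, and stopping only when the gene count is stable
  # makes the operation idempotent
  repeat {
    res <- merge_round(genes, txs, policy)
    txs <- res$txs
    if (nrow(res$genes) == nrow(genes)) {
      genes <- res$genes
      break
    }
    genes <- res$genes
  }
  genome_annotation(genomes[1L], genes, txs, feats,
                    designated_set = policy$id_priority[1L],
                    family = sets[[1L]]$family)
}

merge_round <- function(genes, txs, policy) {
  coding <- if (policy$protein_coding_only)
    genes$biotype == "protein_coding" else rep(TRUE, nrow(genes))
  gc <- genes[coding, , drop = FALSE]

  comp <- integer(nrow(gc))
  if (nrow(gc)) {
    gr <- GenomicRanges::GRanges(
      gc$chrom, IRanges::IRanges(gc$start + 1L, gc$end),
      strand = if (policy$require_same_strand) gc$strand else "*")
    hits <- GenomicRanges::findOverlaps(gr, gr,
                                        ignore.strand = !policy$require_same_strand)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    keep <- qi < si
    qi <- qi[keep]; si <- si[keep]
    ov <- pmin(gc$end[qi], gc$end[si]) - pmax(gc$start[qi], gc$start[si])
    shorter <- pmin(gc$end[qi] - gc$start[qi], gc$end[si] - gc$start[si])
    pass <- ov / shorter >= policy$min_overlap_fraction
    g <- igraph::graph_from_data_frame(
      data.frame(from = qi[pass], to = si[pass]), directed = FALSE,
      vertices = data.frame(name = seq_len(nrow(gc))))
    comp <- igraph::components(g)$membership[as.character(seq_len(nrow(gc)))]
  }

  # one output gene per component
  prio <- match(gc$source_set, policy$id_priority)
  prio[is.na(prio)] <- length(policy$id_priority) + 1L
  out_rows <- lapply(split(seq_len(nrow(gc)), comp), function(i) {
    sub <- gc[i, , drop = FALSE]
    # envelope of protein-coding transcript extremes (gene spans already
    # bound their transcripts)
    span <- c(min(sub$start), max(sub$end))
    p <- prio[i]
    best <- i[p == min(p)]
    if (length(best) > 1L) {
      # within one priority tier the 5'-most member wins
      if (gc$strand[best[1L]] == "+") {
        best <- best[order(gc$start[best], gc$gene_id[best])]
      } else {
        best <- best[order(-gc$end[best], gc$gene_id[best])]
      }
    }
    lead <- best[1L]
    orig <- unlist(lapply(seq_len(nrow(sub)), function(r)
      if (nzchar(sub$merged_from[r]))
        strsplit(sub$merged_from[r], ",", fixed = TRUE)[[1L]]
      else sub$gene_id[r]))
    data.frame(gene_id = gc$gene_id[lead], source_set = gc$source_set[lead],
               chrom = sub$chrom[1L], start = span[1L], end = span[2L],
               strand = gc$strand[lead], biotype = "protein_coding",
               merged_from = if (length(orig) > 1L)
                 paste(sort(unique(orig)), collapse = ",") else "",
               members = I(list(sub$gene_id)),
               stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, out_rows)

  # re-parent transcripts of merged members onto the surviving gene id
  if (!is.null(merged) && nrow(merged)) {
    gene_map <- setNames(rep(merged$gene_id, lengths(merged$members)),
                         unlist(merged$members))
    txs$gene_id <- ifelse(txs$gene_id %in% names(gene_map),
                          unname(gene_map[txs$gene_id]), txs$gene_id)
    merged$members <- NULL
  }
  passthrough <- genes[!coding, , drop = FALSE]
  all_genes <- rbind(merged, passthrough)
  if (is.null(all_genes))
    all_genes <- cbind(genes[0, c("gene_id", "source_set", "chrom", "start",
                                  "end", "strand", "biotype")],
                       merged_from = character(0))
  rownames(all_genes) <- NULL
  list(genes = all_genes, txs = txs)
}
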
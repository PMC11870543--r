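#' @importFrom stats median sd setNames quantile p.adjust phyper rnorm rpois runif coef predict
#' @importFrom utils read.delim write.table head tail
NULL

# Internal coordinate convention: 0-based half-open everywhere.  Conversion to
# 1-based inclusive (GFF3) or 0-based half-open (BED) happens only in the
# readers/writers in this file.

#' Construct a genome annotation object
#'
#' Container for one genome's gene models: a gene table, a transcript table
#' and an exon/CDS feature table, all using 0-based half-open coordinates.
#'
#' @param genome Genome identifier.
#' @param genes data.frame with columns \code{gene_id}, \code{source_set},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand} (\code{+}/\code{-}),
#'   \code{biotype} (\code{protein_coding}, \code{TE} or \code{other}).
#' @param transcripts data.frame with columns \code{transcript_id},
#'   \code{gene_id}.
#' @param features data.frame with columns \code{transcript_id}, \code{type}
#'   (\code{exon} or \code{CDS}), \code{start}, \code{end}.
#' @param designated_set The single source set counted for per-genome
#'   statistics (defaults to the most frequent source in \code{genes}).
#' @param family Optional varietal-group label (e.g. japonica, indica).
#' @return An object of class \code{genome_annotation}.
#' @export
genome_annotation <- function(genome, genes, transcripts, features,
                              designated_set = NULL, family = NA_character_) {
  stopifnot(is.character(genome), length(genome) == 1L)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need_g <- c("gene_id", "source_set", "chrom", "start", "end", "strand", "biotype")
  if (!all(need_g %in% names(genes)))
    stop("genes table must have columns: ", paste(need_g, collapse = ", "))
  if (nrow(genes)) {
    if (any(genes$start >= genes$end))
      stop("gene spans must satisfy start < end (0-based half-open)")
    if (!all(genes$strand %in% c("+", "-")))
      stop("gene strand must be '+' or '-'")
    key <- paste(genes$source_set, genes$gene_id)
    if (anyDuplicated(key))
      stop("duplicate gene_id within a source_set: ",
           genes$gene_id[duplicated(key)][1L])
  }
  if (is.null(designated_set)) {
    designated_set <- if (nrow(genes)) names(sort(table(genes$source_set),
                                                  decreasing = TRUE))[1L] else NA_character_
  }
  ord <- order(genes$chrom, genes$start, genes$gene_id)
  structure(list(genome = genome, family = family,
                 designated_set = designated_set,
                 genes = genes[ord, , drop = FALSE],
                 transcripts = transcripts, features = features),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", x$genome,
      if (!is.na(x$family)) paste0("(", x$family, ")") else "", "\n")
  cat("  genes:", nrow(x$genes), " transcripts:", nrow(x$transcripts),
      " sources:", paste(unique(x$genes$source_set), collapse = ","), "\n")
  invisible(x)
}

#' Read a GFF3 gene annotation
#'
#' Parses a GFF3 file with a gene/mRNA/exon/CDS hierarchy into a
#' \code{\link{genome_annotation}}.  GFF3 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention.  Biotype is taken
#' from a \code{biotype} attribute when present, otherwise
#' \code{protein_coding}.
#'
#' @param path GFF3 file.
#' @param genome Genome identifier (default: file name without extension).
#' @param source_set Source-set label (default: same as \code{genome}).
#' @param exclude_contigs Optional regular expression; genes on matching
#'   chromosome/contig names are dropped (e.g. unresolved haplotig patterns).
#' @inheritParams genome_annotation
#' @return A \code{genome_annotation}.
#' @export
read_annotation <- function(path, genome = NULL, source_set = NULL,
                            exclude_contigs = NULL, family = NA_character_,
                            designated_set = NULL) {
  if (is.null(genome))
    genome <- sub("\\.gff3?$", "", basename(path))
  if (is.null(source_set)) source_set <- genome
  n_data <- length(grep("^[^#]", readLines(path, warn = FALSE), value = TRUE))
  if (n_data == 0L) {
    empty <- data.frame(gene_id = character(), source_set = character(),
                        chrom = character(), start = integer(), end = integer(),
                        strand = character(), biotype = character(),
                        stringsAsFactors = FALSE)
    return(genome_annotation(genome, empty,
                             data.frame(transcript_id = character(), gene_id = character()),
                             data.frame(transcript_id = character(), type = character(),
                                        start = integer(), end = integer()),
                             designated_set = source_set, family = family))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
                   stringsAsFactors = FALSE)
  par <- gr$Parent
  df$parent <- if (is.null(par)) NA_character_ else
    vapply(as.list(par), function(p) if (length(p)) p[[1L]] else NA_character_, "")
  df$biotype <- if (!is.null(gr$biotype)) as.character(gr$biotype) else NA_character_

  is_gene <- df$type == "gene"
  is_tx <- df$type %in% c("mRNA", "transcript")
  is_feat <- df$type %in% c("exon", "CDS")
  if (any(is_gene & !df$strand %in% c("+", "-")))
    stop("gene with unknown strand: ", df$id[is_gene & !df$strand %in% c("+", "-")][1L])
  genes <- df[is_gene, , drop = FALSE]
  if (!is.null(exclude_contigs) && nrow(genes)) {
    keep <- !grepl(exclude_contigs, genes$chrom)
    genes <- genes[keep, , drop = FALSE]
  }
  gene_tab <- data.frame(gene_id = genes$id, source_set = source_set,
                         chrom = genes$chrom, start = genes$start,
                         end = genes$end, strand = genes$strand,
                         biotype = ifelse(is.na(genes$biotype), "protein_coding",
                                          genes$biotype),
                         stringsAsFactors = FALSE)
  txs <- df[is_tx, , drop = FALSE]
  bad_tx <- !txs$parent %in% gene_tab$gene_id
  txs <- txs[!bad_tx, , drop = FALSE]
  tx_tab <- data.frame(transcript_id = txs$id, gene_id = txs$parent,
                       stringsAsFactors = FALSE)
  feats <- df[is_feat, , drop = FALSE]
  if (nrow(feats)) {
    missing_par <- is.na(feats$parent) | !feats$parent %in% tx_tab$transcript_id
    if (any(missing_par)) {
      bad <- feats[missing_par, ][1L, ]
      stop(sprintf("%s feature at %s:%d-%d has missing/unknown Parent '%s'",
                   bad$type, bad$chrom, bad$start + 1L, bad$end,
                   if (is.na(bad$parent)) "" else bad$parent))
    }
  }
  feat_tab <- data.frame(transcript_id = feats$parent, type = feats$type,
                         start = feats$start, end = feats$end,
                         stringsAsFactors = FALSE)
  genome_annotation(genome, gene_tab, tx_tab, feat_tab,
                    designated_set = designated_set, family = family)
}

#' Write a genome annotation to GFF3
#'
#' Emits a gene/mRNA/exon/CDS hierarchy, converting internal 0-based
#' half-open coordinates to GFF3 1-based inclusive.  Rows are ordered by
#' (chrom, start, gene id) so output is reproducible.
#'
#' @param ann A \code{genome_annotation}.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_annotation <- function(ann, path) {
  g <- ann$genes
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!nrow(g)) return(invisible(path))
  esc <- function(x) gsub("[;=,\t]", "_", x)
  tx_by_gene <- split(ann$transcripts$transcript_id, ann$transcripts$gene_id)
  fe <- ann$features
  fe <- fe[order(fe$transcript_id, fe$start, fe$type), , drop = FALSE]
  fe_by_tx <- split(fe, fe$transcript_id)
  src <- "PanGeneKit"
  lines <- character(0)
  for (i in seq_len(nrow(g))) {
    attrs <- sprintf("ID=%s;biotype=%s", esc(g$gene_id[i]), g$biotype[i])
    if (!is.null(g$merged_from) && !is.na(g$merged_from[i]) && nzchar(g$merged_from[i]))
      attrs <- paste0(attrs, ";merged_from=", esc(g$merged_from[i]))
    lines <- c(lines, paste(g$chrom[i], src, "gene", g$start[i] + 1L, g$end[i],
                            ".", g$strand[i], ".", attrs, sep = "\t"))
    for (tid in sort(tx_by_gene[[g$gene_id[i]]])) {
      fx <- fe_by_tx[[tid]]
      tspan <- if (!is.null(fx) && nrow(fx)) c(min(fx$start), max(fx$end)) else
        c(g$start[i], g$end[i])
      lines <- c(lines, paste(g$chrom[i], src, "mRNA", tspan[1L] + 1L, tspan[2L],
                              ".", g$strand[i], ".",
                              sprintf("ID=%s;Parent=%s", esc(tid), esc(g$gene_id[i])),
                              sep = "\t"))
      if (!is.null(fx) && nrow(fx)) {
        lines <- c(lines, paste(g$chrom[i], src, fx$type, fx$start + 1L, fx$end,
                                ".", g$strand[i], ifelse(fx$type == "CDS", "0", "."),
                                sprintf("Parent=%s", esc(tid)), sep = "\t"))
      }
    }
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read lifted gene intervals from BED6
#'
#' BED is 0-based half-open, matching the internal convention, so coordinates
#' pass through unchanged.  The BED name field holds the source gene id, the
#' score the overlap-eligible coverage fraction scaled by 1000, and the strand
#' the lifted strand.
#'
#' @param path BED6 file.
#' @param source_genome,target_genome Genome identifiers for the directed pair.
#' @return data.frame with columns \code{gene_id}, \code{source_genome},
#'   \code{target_genome}, \code{target_chrom}, \code{start}, \code{end},
#'   \code{lifted_strand}, \code{coverage}.
#' @export
read_lifted_bed <- function(path, source_genome, target_genome) {
  if (source_genome == target_genome)
    stop("source_genome and target_genome must differ")
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0L)
    return(empty_lifted())
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!nrow(bed)) return(empty_lifted())
  data.frame(gene_id = as.character(bed[[4L]]),
             source_genome = source_genome, target_genome = target_genome,
             target_chrom = as.character(bed[[1L]]),
             start = as.integer(bed[[2L]]), end = as.integer(bed[[3L]]),
             lifted_strand = as.character(bed[[6L]]),
             coverage = as.numeric(bed[[5L]]) / 1000,
             stringsAsFactors = FALSE)
}

empty_lifted <- function() {
  data.frame(gene_id = character(), source_genome = character(),
             target_genome = character(), target_chrom = character(),
             start = integer(), end = integer(), lifted_strand = character(),
             coverage = numeric(), stringsAsFactors = FALSE)
}

#' Write lifted intervals for one directed genome pair to BED6
#'
#' @param lifted data.frame as returned by \code{\link{read_lifted_bed}}.
#' @param path Output BED file.
#' @return The path, invisibly.
#' @export
write_lifted_bed <- function(lifted, path) {
  lifted <- lifted[order(lifted$target_chrom, lifted$start, lifted$gene_id), ,
                   drop = FALSE]
  out <- data.frame(lifted$target_chrom, lifted$start, lifted$end,
                    lifted$gene_id, as.integer(round(lifted$coverage * 1000)),
                    lifted$lifted_strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a pan-gene matrix to TSV
#'
#' Column 1 is the stable identifier; one column per genome (fixed declared
#' order) holds comma-separated, lexicographically sorted transcript
#' identifiers of that genome's members, with \code{-} marking absence;
#' trailing columns give occupancy, occupancy class, mode chromosome and
#' pseudo-position.
#'
#' @param mat A \code{pangene_matrix} with stable identifiers minted.
#' @param path Output TSV.
#' @return The path, invisibly.
#' @export
write_pangene_matrix <- function(mat, path) {
  cl <- mat$clusters
  if (any(is.na(cl$stable_id)))
    stop("stable identifiers not minted; run mint_identifiers() first")
  mem <- mat$members
  cell <- function(cid, g) {
    tx <- mem$transcripts[mem$cluster_id == cid & mem$genome == g]
    tx <- sort(unlist(strsplit(tx, ",", fixed = TRUE)))
    if (!length(tx)) "-" else paste(tx, collapse = ",")
  }
  cells <- matrix("-", nrow(cl), length(mat$genome_order))
  key <- paste(mem$cluster_id, mem$genome)
  tx_by <- split(mem$transcripts, key)
  for (j in seq_along(mat$genome_order)) {
    k <- paste(cl$cluster_id, mat$genome_order[j])
    hit <- k %in% names(tx_by)
    cells[hit, j] <- vapply(tx_by[k[hit]], function(v)
      paste(sort(unlist(strsplit(v, ",", fixed = TRUE))), collapse = ","), "")
  }
  out <- data.frame(stable_id = cl$stable_id, cells,
                    occupancy = cl$occupancy,
                    occupancy_class = cl$occupancy_class,
                    mode_chrom = cl$mode_chrom,
                    pseudo_position = ifelse(is.na(cl$pseudo_position), "unplaced",
                                             cl$pseudo_position),
                    stringsAsFactors = FALSE)
  names(out) <- c("stable_id", mat$genome_order, "occupancy", "occupancy_class",
                  "mode_chrom", "pseudo_position")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a pan-gene matrix TSV
#'
#' @param path TSV written by \code{\link{write_pangene_matrix}}.
#' @return list with the raw \code{table}, the \code{genome_order}, and a long
#'   \code{members} data.frame (stable_id, genome, transcript_id).
#' @export
read_pangene_matrix <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  trailing <- c("occupancy", "occupancy_class", "mode_chrom", "pseudo_position")
  genome_order <- setdiff(names(tab), c("stable_id", trailing))
  rows <- lapply(genome_order, function(g) {
    present <- tab[[g]] != "-"
    if (!any(present)) return(NULL)
    tx <- strsplit(tab[[g]][present], ",", fixed = TRUE)
    data.frame(stable_id = rep(tab$stable_id[present], lengths(tx)),
               genome = g, transcript_id = unlist(tx),
               stringsAsFactors = FALSE)
  })
  members <- do.call(rbind, rows)
  members <- members[order(members$stable_id, members$genome,
                           members$transcript_id), , drop = FALSE]
  rownames(members) <- NULL
  list(table = tab, genome_order = genome_order, members = members)
}

#' Read an InterProScan-style domain TSV
#'
#' Consumes the standard 13+ column InterProScan TSV (no header).  Only the
#' protein accession, analysis, signature accession and InterPro accession
#' columns are used.  Each protein/domain pair becomes one record in one of
#' two namespaces: \code{Pfam} (signature accession of Pfam analysis rows) or
#' \code{InterPro} (column 12 where not \code{-}).
#'
#' @param path TSV file.
#' @return data.frame with columns \code{protein_id}, \code{namespace},
#'   \code{accession} (unique rows).
#' @export
read_interproscan <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  pf <- tab[tab[[4L]] == "Pfam", , drop = FALSE]
  out <- data.frame(protein_id = pf[[1L]], namespace = "Pfam",
                    accession = pf[[5L]], stringsAsFactors = FALSE)
  if (ncol(tab) >= 12L) {
    ip <- tab[tab[[12L]] != "-" & !is.na(tab[[12L]]), , drop = FALSE]
    out <- rbind(out, data.frame(protein_id = ip[[1L]], namespace = "InterPro",
                                 accession = ip[[12L]], stringsAsFactors = FALSE))
  }
  unique(out)
}

#' Read a two-column per-gene evidence table
#'
#' @param path TSV with header columns \code{gene_id}, \code{value}.
#' @param metric Metric name; \code{aed_min} values are checked to lie in
#'   [0,1] and \code{plddt_mean} in [0,100].
#' @return data.frame (gene_id, value) with attribute \code{metric}.
#' @export
read_evidence_table <- function(path, metric = "custom") {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "value") %in% names(tab)))
  if (metric == "aed_min" && any(tab$value < 0 | tab$value > 1, na.rm = TRUE))
    stop("AED values must lie in [0,1]")
  if (metric == "plddt_mean" && any(tab$value < 0 | tab$value > 100, na.rm = TRUE))
    stop("pLDDT values must lie in [0,100]")
  attr(tab, "metric") <- metric
  tab
}
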
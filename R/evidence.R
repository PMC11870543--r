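# Per-gene evidence summarized by pan-gene occupancy, and in-silico tryptic
# peptide digestion, mapping and parsimonious protein inference.

#' Summarize per-gene evidence metrics by pan-gene occupancy
#'
#' Per cluster, the metric is averaged over members of the restricted source
#' set (clusters without such members are excluded), then grouped by
#' occupancy.
#'
#' @param mat A \code{pangene_matrix}.
#' @param tables Named list of evidence data.frames (gene_id, value); names
#'   are the metric names.
#' @param restrict_source_set Source set whose members contribute values
#'   (default: no restriction).
#' @return data.frame: metric, occupancy, mean, median, iqr, n (clusters).
#' @export
summarize_by_occupancy <- function(mat, tables, restrict_source_set = NULL) {
  mem <- mat$members
  if (!is.null(restrict_source_set))
    mem <- mem[mem$source_set == restrict_source_set, , drop = FALSE]
  occ <- mat$clusters$occupancy[match(mem$cluster_id, mat$clusters$cluster_id)]
  out <- list()
  for (metric in names(tables)) {
    tab <- tables[[metric]]
    v <- tab$value[match(mem$gene_id, tab$gene_id)]
    ok <- !is.na(v)
    if (!any(ok)) {
      warning("metric '", metric, "' has no genes overlapping the matrix")
      next
    }
    per_cl <- tapply(v[ok], mem$cluster_id[ok], mean)
    cl_occ <- occ[ok][!duplicated(mem$cluster_id[ok])]
    names(cl_occ) <- unique(mem$cluster_id[ok])
    cl_occ <- cl_occ[names(per_cl)]
    for (o in sort(unique(cl_occ))) {
      x <- per_cl[cl_occ == o]
      out[[length(out) + 1L]] <- data.frame(
        metric = metric, occupancy = as.integer(o),
        mean = mean(x), median = median(x),
        iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)),
        n = length(x), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(metric = character(), occupancy = integer(),
                      mean = numeric(), median = numeric(), iqr = numeric(),
                      n = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Tryptic digestion of a protein sequence
#'
#' Cleaves C-terminal to K or R except when the next residue is P, allowing
#' up to \code{missed_cleavages} missed sites, and keeps peptides within the
#' length bounds.
#'
#' @param sequence Amino-acid string (20-letter alphabet).
#' @param missed_cleavages Maximum missed cleavage sites (default 2).
#' @param min_len,max_len Peptide length bounds (defaults 7 and 50).
#' @return Character vector of unique peptides in N-to-C order of first
#'   occurrence.
#' @export
digest_peptides <- function(sequence, missed_cleavages = 2L,
                            min_len = 7L, max_len = 50L) {
  if (!nzchar(sequence)) return(character(0))
  v <- strsplit(sequence, "")[[1L]]
  if (!all(v %in% AA20))
    stop("sequence contains non-amino-acid characters")
  n <- length(v)
  cut_after <- which(v %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & v[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)          # fragment boundaries
  nfrag <- length(bounds) - 1L
  peps <- character(0)
  for (i in seq_len(nfrag)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > nfrag) break
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      len <- e - s + 1L
      if (len >= min_len && len <= max_len)
        peps <- c(peps, paste(v[s:e], collapse = ""))
    }
  }
  unique(peps)
}

#' Digest proteomes, map peptides and assign them parsimoniously
#'
#' All proteins are digested in silico; each peptide is mapped back to every
#' protein containing it as an exact substring (optionally with isoleucine
#' and leucine equated).  Parsimonious assignment is greedy set cover:
#' iteratively the protein covering the most unassigned peptides claims
#' them, ties broken by lexicographic protein id.
#'
#' @param proteomes Named list (genome -> named character vector of protein
#'   sequences; names are protein ids).
#' @param mat Optional \code{pangene_matrix}; protein ids are resolved to
#'   clusters via member transcript ids for per-cluster peptide counts.
#' @param min_len,max_len,missed_cleavages Digestion parameters.
#' @param equate_il Treat I and L as identical during matching (default
#'   FALSE: exact string matching).
#' @param min_peptides_per_gene Peptide-evidence threshold for the
#'   per-genome supported-gene count (default 2).
#' @return list: \code{assignments} (peptide, n_candidates, assigned_protein,
#'   genomes_with_match), \code{per_cluster} (cluster_id, n_peptides under
#'   all-mapping), \code{histogram} (genomes-per-peptide counts),
#'   \code{supported_genes} (genome, n_genes with >= threshold assigned
#'   peptides).
#' @export
digest_and_map_peptides <- function(proteomes, mat = NULL, min_len = 7L,
                                    max_len = 50L, missed_cleavages = 2L,
                                    equate_il = FALSE,
                                    min_peptides_per_gene = 2L) {
  prot_ids <- unlist(lapply(proteomes, names), use.names = FALSE)
  if (anyDuplicated(prot_ids))
    stop("protein ids must be unique across genomes")
  seqs <- unlist(proteomes, use.names = FALSE)
  names(seqs) <- prot_ids
  genome_of <- rep(names(proteomes), lengths(proteomes))
  names(genome_of) <- prot_ids

  bad <- !vapply(strsplit(seqs, ""), function(v) all(v %in% AA20), TRUE)
  if (any(bad)) {
    warning(sum(bad), " sequence(s) with non-amino-acid characters rejected")
    seqs <- seqs[!bad]
  }
  norm <- if (equate_il) function(x) gsub("I", "L", x, fixed = TRUE) else identity

  pep_by_prot <- lapply(seqs, digest_peptides, missed_cleavages = missed_cleavages,
                        min_len = min_len, max_len = max_len)
  all_peps <- unique(norm(unlist(pep_by_prot, use.names = FALSE)))
  if (!length(all_peps))
    return(list(assignments = data.frame(peptide = character(),
                                         n_candidates = integer(),
                                         assigned_protein = character(),
                                         genomes_with_match = integer()),
                per_cluster = NULL, histogram = integer(0),
                supported_genes = NULL))

  # exact substring mapping back to all proteins
  seqs_n <- norm(seqs)
  cand <- lapply(setNames(all_peps, all_peps), function(p)
    names(seqs_n)[grepl(p, seqs_n, fixed = TRUE)])

  genomes_with <- vapply(cand, function(ids)
    length(unique(genome_of[ids])), 1L)

  # greedy set cover
  cover <- lapply(setNames(names(seqs), names(seqs)), function(x) character(0))
  for (p in names(cand)) for (pr in cand[[p]])
    cover[[pr]] <- c(cover[[pr]], p)
  assigned <- setNames(rep(NA_character_, length(all_peps)), all_peps)
  remaining <- lapply(cover, unique)
  repeat {
    sizes <- lengths(remaining)
    if (!length(sizes) || max(sizes) == 0L) break
    top <- names(remaining)[sizes == max(sizes)]
    pick <- sort(top)[1L]
    got <- remaining[[pick]]
    assigned[got] <- pick
    remaining <- lapply(remaining, setdiff, got)
    remaining[[pick]] <- NULL
  }

  assignments <- data.frame(peptide = all_peps,
                            n_candidates = lengths(cand)[all_peps],
                            assigned_protein = unname(assigned[all_peps]),
                            genomes_with_match = unname(genomes_with[all_peps]),
                            stringsAsFactors = FALSE)

  histogram <- table(factor(assignments$genomes_with_match,
                            levels = seq_along(proteomes)))
  histogram <- setNames(as.integer(histogram), names(histogram))

  per_cluster <- NULL
  supported_genes <- NULL
  if (!is.null(mat)) {
    tx2cl <- tx_to_cluster(mat)
    cl_of_prot <- tx2cl$cluster_id[match(names(seqs), tx2cl$transcript_id)]
    gene_of_prot <- tx2cl$gene_id[match(names(seqs), tx2cl$transcript_id)]
    pep_cl <- lapply(cand, function(ids)
      unique(cl_of_prot[match(ids, names(seqs))]))
    cl_counts <- table(unlist(pep_cl))
    per_cluster <- data.frame(cluster_id = as.integer(names(cl_counts)),
                              n_peptides = as.integer(cl_counts),
                              stringsAsFactors = FALSE)
    per_cluster <- per_cluster[!is.na(per_cluster$cluster_id), , drop = FALSE]
    ok <- !is.na(assignments$assigned_protein)
    gene_hits <- table(gene_of_prot[match(assignments$assigned_protein[ok],
                                          names(seqs))])
    good_genes <- names(gene_hits)[gene_hits >= min_peptides_per_gene]
    gene_genome <- mat$members$genome[match(good_genes, mat$members$gene_id)]
    supported_genes <- as.data.frame(table(genome = gene_genome),
                                     stringsAsFactors = FALSE)
    names(supported_genes) <- c("genome", "n_genes")
  }
  list(assignments = assignments, per_cluster = per_cluster,
       histogram = histogram, supported_genes = supported_genes)
}

tx_to_cluster <- function(mat) {
  mem <- mat$members
  tx <- strsplit(mem$transcripts, ",", fixed = TRUE)
  data.frame(transcript_id = unlist(tx),
             gene_id = rep(mem$gene_id, lengths(tx)),
             cluster_id = rep(mem$cluster_id, lengths(tx)),
             stringsAsFactors = FALSE)
}
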
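# Protein-domain analysis over pan-genes: representative domains and
# consistency, domain occupancy variability, TE-cluster filtering, and
# core-vs-cloud enrichment (one-sided hypergeometric with BH adjustment).
# Pfam and InterPro namespaces are kept separate in all statistics.

join_domain_clusters <- function(mat, records, namespace) {
  rec <- records[records$namespace == namespace, , drop = FALSE]
  hit <- match(rec$gene_id, mat$members$gene_id)
  rec$cluster_id <- mat$members$cluster_id[hit]
  rec[!is.na(rec$cluster_id), , drop = FALSE]
}

#' Representative domain per pan-gene
#'
#' The representative is the accession present in the most distinct genomes
#' of the cluster; ties are broken by a seeded uniform draw.  A cluster is
#' domain consistent when every member genome carries the representative.
#'
#' @param mat A \code{pangene_matrix}.
#' @param records Domain records: data.frame with columns protein_id,
#'   gene_id, genome, namespace, accession (see
#'   \code{\link{read_interproscan}} plus a gene/genome join).
#' @param namespace \code{"Pfam"} or \code{"InterPro"}.
#' @param seed Seed for tie-breaking.
#' @return data.frame: cluster_id, representative, n_genomes_with,
#'   n_genomes_lacking, consistent, outlier_proteins (comma-separated
#'   proteins of genomes lacking the representative).
#' @export
assign_representative_domain <- function(mat, records, namespace = "Pfam",
                                         seed = 1L) {
  rec <- join_domain_clusters(mat, records, namespace)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cl_genomes <- tapply(mat$members$genome, mat$members$cluster_id, unique)
  out <- lapply(sort(unique(rec$cluster_id)), function(cid) {
    sub <- rec[rec$cluster_id == cid, , drop = FALSE]
    cnt <- tapply(sub$genome, sub$accession, function(v) length(unique(v)))
    top <- names(cnt)[cnt == max(cnt)]
    repd <- if (length(top) == 1L) top else sample(sort(top), 1L)
    have <- unique(sub$genome[sub$accession == repd])
    all_g <- cl_genomes[[as.character(cid)]]
    lacking <- setdiff(all_g, have)
    outliers <- sort(unique(
      mat$members$transcripts[mat$members$cluster_id == cid &
                                mat$members$genome %in% lacking]))
    data.frame(cluster_id = cid, representative = repd,
               n_genomes_with = length(have),
               n_genomes_lacking = length(lacking),
               consistent = length(lacking) == 0L,
               outlier_proteins = paste(outliers, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cluster_id = integer(), representative = character(),
                      n_genomes_with = integer(), n_genomes_lacking = integer(),
                      consistent = logical(), outlier_proteins = character(),
                      stringsAsFactors = FALSE)
  res
}

#' Domain occupancy variability categories
#'
#' For every domain, the per-pan-gene domain occupancy is the number of
#' genomes with a protein carrying the domain in that cluster, counted over
#' each genome's designated annotation set only.  The mean over all clusters
#' containing the domain defines the category: highly variable (< 10),
#' partially variable ([10, 15]; the strict-inequality thresholds leave the boundaries
#' open and the middle category absorbs them) and invariable (> 15).  Domains
#' found in fewer than \code{min_pangenes} clusters are reported
#' uncategorized.
#'
#' @param mat A \code{pangene_matrix}.
#' @param records Domain records (protein_id, gene_id, genome, source_set,
#'   namespace, accession).
#' @param namespace \code{"Pfam"} or \code{"InterPro"}.
#' @param min_pangenes Minimum clusters for categorization (default 5).
#' @param designated_sets Named character vector genome -> counted source
#'   set; defaults to each record's own source set (i.e. no filtering).
#' @param high_max,invariable_min Category thresholds (defaults 10 and 15).
#' @return data.frame: namespace, accession, n_pangenes, mean_occupancy,
#'   category.
#' @export
domain_variability <- function(mat, records, namespace = "Pfam",
                               min_pangenes = 5L, designated_sets = NULL,
                               high_max = 10, invariable_min = 15) {
  rec <- join_domain_clusters(mat, records, namespace)
  if (!is.null(designated_sets) && nrow(rec)) {
    keep <- rec$source_set == designated_sets[rec$genome]
    rec <- rec[!is.na(keep) & keep, , drop = FALSE]
  }
  if (!nrow(rec))
    return(data.frame(namespace = character(), accession = character(),
                      n_pangenes = integer(), mean_occupancy = numeric(),
                      category = character(), stringsAsFactors = FALSE))
  key <- paste(rec$accession, rec$cluster_id)
  occ <- tapply(rec$genome, key, function(v) length(unique(v)))
  acc <- sub(" .*$", "", names(occ))
  mean_occ <- tapply(as.numeric(occ), acc, mean)
  n_pg <- tapply(as.numeric(occ), acc, length)
  category <- ifelse(n_pg < min_pangenes, "unfiltered",
                     ifelse(mean_occ < high_max, "highly_variable",
                            ifelse(mean_occ > invariable_min, "invariable",
                                   "partially_variable")))
  out <- data.frame(namespace = namespace, accession = names(mean_occ),
                    n_pangenes = as.integer(n_pg),
                    mean_occupancy = as.numeric(mean_occ),
                    category = as.character(category),
                    stringsAsFactors = FALSE)
  out[order(out$accession), , drop = FALSE]
}

#' Filter transposable-element clusters
#'
#' Singleton clusters (occupancy 1) are removed when their gene is
#' TE-annotated either in the domain records or in the supplied legacy TE id
#' list; clusters with occupancy above 1 are removed only when every member
#' gene is TE-flagged in the domain records.
#'
#' @param mat A \code{pangene_matrix}.
#' @param records Domain records with a logical \code{te_flag} column.
#' @param msu_te_ids Character vector of TE-tagged gene ids from a legacy
#'   annotation source (applied to singletons only).
#' @return list: \code{matrix} (filtered), \code{removed} (cluster ids).
#' @export
filter_te_clusters <- function(mat, records, msu_te_ids = character(0)) {
  te_genes <- unique(records$gene_id[records$te_flag])
  mem <- mat$members
  te_member <- mem$gene_id %in% te_genes
  te_legacy <- mem$gene_id %in% msu_te_ids | mem$biotype == "TE"
  all_te <- tapply(te_member, mem$cluster_id, all)
  any_te_single <- tapply(te_member | te_legacy, mem$cluster_id, any)
  occ <- mat$clusters$occupancy[match(as.integer(names(all_te)),
                                      mat$clusters$cluster_id)]
  removed <- as.integer(names(all_te))[
    (occ == 1L & any_te_single) | (occ > 1L & all_te)]
  keep_cl <- !mat$clusters$cluster_id %in% removed
  mat$clusters <- mat$clusters[keep_cl, , drop = FALSE]
  mat$members <- mat$members[!mat$members$cluster_id %in% removed, , drop = FALSE]
  list(matrix = mat, removed = sort(removed))
}

#' Domain enrichment between occupancy classes
#'
#' One-sided hypergeometric test per accession: the probability of observing
#' at least the seen number of class-A clusters among the clusters carrying
#' the domain, drawing from the (TE-filtered) background; Benjamini-Hochberg
#' adjustment across accessions.
#'
#' @param mat A (TE-filtered) \code{pangene_matrix} defining the background.
#' @param records Domain records.
#' @param namespace \code{"Pfam"} or \code{"InterPro"}.
#' @param class_a Occupancy class of interest (e.g. \code{"core"}).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @return data.frame: accession, count_a, count_bg, gene_ratio, p, p_adj,
#'   significant.
#' @export
enrich_domains <- function(mat, records, namespace = "Pfam",
                           class_a = "core", alpha = 0.05) {
  cl <- mat$clusters
  a_ids <- cl$cluster_id[cl$occupancy_class == class_a]
  if (!length(a_ids)) stop("no clusters in class '", class_a, "'")
  n_bg <- nrow(cl)
  n_a <- length(a_ids)
  rec <- join_domain_clusters(mat, records, namespace)
  rec <- unique(rec[, c("accession", "cluster_id")])
  count_bg <- tapply(rec$cluster_id, rec$accession, function(v) length(unique(v)))
  count_a <- tapply(rec$cluster_id, rec$accession,
                    function(v) length(unique(intersect(v, a_ids))))
  acc <- names(count_bg)
  p <- phyper(as.numeric(count_a) - 1L, n_a, n_bg - n_a,
              as.numeric(count_bg), lower.tail = FALSE)
  out <- data.frame(accession = acc,
                    count_a = as.integer(count_a),
                    count_bg = as.integer(count_bg),
                    gene_ratio = as.numeric(count_a) / n_a,
                    p = p, p_adj = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_adj < alpha
  out[order(out$p, out$accession), , drop = FALSE]
}
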
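# Comparison of a pan-gene matrix against an external cluster set (e.g.
# reciprocal-best ortholog gene indices), anchored on a shared genome's
# gene identifiers.

#' Percentage agreement with an external cluster set
#'
#' Each pan-gene is paired with the external cluster sharing its anchor-genome
#' gene identifier; pan-genes whose anchor ids appear in no external cluster
#' are reported unmatched, and anchor ids appearing in more than one external
#' cluster are reported ambiguous and skipped.  After removing members from
#' excluded sources on both sides, the percentage similarity is matching
#' counts / total counts, where total counts is the number of unique
#' identifiers in the combined set (equivalently the Jaccard index times
#' 100).
#'
#' @param mat A \code{pangene_matrix}.
#' @param external data.frame (cluster_id, member_id) describing the external
#'   clustering, or a named list of member-id vectors.
#' @param anchor_genome Genome whose gene identifiers are shared between the
#'   two clusterings.
#' @param excluded_sources Source sets removed from the pan-gene side before
#'   comparison.
#' @param excluded_external Member-id patterns (regular expressions) removed
#'   from the external side before comparison.
#' @return list: \code{records} (pangene cluster_id, external_cluster_id,
#'   matching, total, percent), \code{histogram} (percent binned by 10),
#'   \code{unmatched} and \code{ambiguous} cluster ids.
#' @export
cluster_agreement <- function(mat, external, anchor_genome,
                              excluded_sources = character(0),
                              excluded_external = character(0)) {
  if (is.data.frame(external)) {
    ext_sets <- split(as.character(external$member_id),
                      as.character(external$cluster_id))
  } else ext_sets <- lapply(external, as.character)
  for (pat in excluded_external)
    ext_sets <- lapply(ext_sets, function(v) v[!grepl(pat, v)])

  mem <- mat$members
  if (length(excluded_sources))
    mem <- mem[!mem$source_set %in% excluded_sources, , drop = FALSE]

  member2ext <- data.frame(
    member = unlist(ext_sets, use.names = FALSE),
    ext = rep(names(ext_sets), lengths(ext_sets)),
    stringsAsFactors = FALSE)

  records <- list(); unmatched <- integer(0); ambiguous <- integer(0)
  for (cid in unique(mem$cluster_id)) {
    sub <- mem[mem$cluster_id == cid, , drop = FALSE]
    anchors <- sub$gene_id[sub$genome == anchor_genome]
    if (!length(anchors)) next
    hits <- unique(member2ext$ext[member2ext$member %in% anchors])
    if (length(hits) == 0L) { unmatched <- c(unmatched, cid); next }
    if (length(hits) > 1L) { ambiguous <- c(ambiguous, cid); next }
    pg_ids <- unique(sub$gene_id)
    ext_ids <- unique(ext_sets[[hits]])
    matching <- length(intersect(pg_ids, ext_ids))
    total <- length(union(pg_ids, ext_ids))
    records[[length(records) + 1L]] <- data.frame(
      cluster_id = cid, external_cluster_id = hits,
      matching = matching, total = total,
      percent = 100 * matching / total, stringsAsFactors = FALSE)
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(cluster_id = integer(), external_cluster_id = character(),
               matching = integer(), total = integer(), percent = numeric(),
               stringsAsFactors = FALSE)
  breaks <- seq(0, 100, by = 10)
  histogram <- table(cut(records$percent, breaks = breaks,
                         include.lowest = TRUE, right = TRUE))
  list(records = records,
       histogram = setNames(as.integer(histogram), names(histogram)),
       unmatched = sort(unmatched), ambiguous = sort(ambiguous))
}
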
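# Minting, parsing and release-to-release remapping of stable pan-gene
# identifiers of the form [clade].[group].[version].panNNNNNNN, where the
# 7-digit number starts at 0000001 for clusters with two or more members and
# at 1000001 for singletons.

#' Identifier scheme
#'
#' @param clade Letter code plus NCBI taxon id (e.g. \code{Os4530} for a
#'   species-level set).
#' @param group Three-letter consortium code (e.g. \code{POR}).
#' @param version Positive integer release version.
#' @return list of class \code{id_scheme}.
#' @export
id_scheme <- function(clade = "Os4530", group = "POR", version = 1L) {
  if (!grepl("^[A-Za-z]{1,2}[0-9]+$", clade))
    stop("clade must be a 1-2 letter code followed by an NCBI taxon id")
  if (!grepl("^[A-Z]{3}$", group))
    stop("group must be a three-letter code")
  version <- as.integer(version)
  if (is.na(version) || version < 1L) stop("version must be a positive integer")
  structure(list(clade = clade, group = group, version = version,
                 cluster_series_start = 1L, singleton_series_start = 1000001L),
            class = "id_scheme")
}

format_stable_id <- function(scheme, number) {
  sprintf("%s.%s.%d.pan%07d", scheme$clade, scheme$group, scheme$version,
          number)
}

#' Mint stable identifiers onto a pan-gene matrix
#'
#' Clusters with two or more members are numbered sequentially from 0000001
#' in matrix order; singletons from 1000001 in matrix order.
#'
#' @param mat A \code{pangene_matrix} (ordered; no identifiers present).
#' @param scheme An \code{\link{id_scheme}}.
#' @return The matrix with \code{stable_id} filled.
#' @export
mint_identifiers <- function(mat, scheme = id_scheme()) {
  cl <- mat$clusters
  multi <- cl$n_members >= 2L
  if (sum(multi) >= scheme$singleton_series_start - scheme$cluster_series_start)
    stop("multi-member series would collide with the singleton series")
  num <- integer(nrow(cl))
  num[multi] <- scheme$cluster_series_start + seq_len(sum(multi)) - 1L
  num[!multi] <- scheme$singleton_series_start + seq_len(sum(!multi)) - 1L
  cl$stable_id <- format_stable_id(scheme, num)
  mat$clusters <- cl
  attr(mat, "id_scheme") <- scheme
  mat
}

#' Parse a stable pan-gene identifier
#'
#' @param id Identifier string(s).
#' @return data.frame with columns clade, group, version, number,
#'   is_singleton.
#' @export
parse_identifier <- function(id) {
  m <- regmatches(id, regexec(
    "^([A-Za-z]{1,2}[0-9]+)\\.([A-Z]{3})\\.([0-9]+)\\.pan([0-9]{7})$", id))
  bad <- lengths(m) != 5L
  if (any(bad)) {
    x <- id[bad][1L]
    parts <- strsplit(x, ".", fixed = TRUE)[[1L]]
    what <- if (length(parts) != 4L) "expected 4 dot-separated components"
    else if (!grepl("^[A-Za-z]{1,2}[0-9]+$", parts[1L])) "invalid clade"
    else if (!grepl("^[A-Z]{3}$", parts[2L])) "invalid group"
    else if (!grepl("^[0-9]+$", parts[3L])) "invalid version"
    else "invalid pan number (need pan + 7 digits)"
    stop("malformed identifier '", x, "': ", what)
  }
  number <- as.integer(vapply(m, `[`, "", 5L))
  data.frame(clade = vapply(m, `[`, "", 2L),
             group = vapply(m, `[`, "", 3L),
             version = as.integer(vapply(m, `[`, "", 4L)),
             number = number,
             is_singleton = number >= 1000001L,
             stringsAsFactors = FALSE)
}

#' Remap stable identifiers between releases
#'
#' Each new cluster inherits the old identifier with which it shares the
#' largest Jaccard index of member gene ids, assigned greedily in descending
#' Jaccard order (ties broken by old id, then new cluster order); unmatched
#' new clusters receive fresh numbers continuing each series.  The mapping
#' table records, per old identifier, the inheriting or absorbing new
#' identifier and the relation: \code{kept} (inherited, same series),
#' \code{kept-with-series-change} (inherited across the singleton/multi
#' boundary), \code{split} (extra new clusters carved out of an old one),
#' \code{merged} (old cluster absorbed into another's identifier),
#' \code{retired} (no overlap with any new cluster), and \code{new}.
#'
#' @param old_mat Previous-release \code{pangene_matrix} with minted ids.
#' @param new_mat New-release matrix (ids absent).
#' @param scheme_new \code{\link{id_scheme}} for the new release; its version
#'   must exceed the old release's version.
#' @return list: \code{matrix} (new matrix with ids) and \code{mapping}
#'   (data.frame old_id, new_id, relation, jaccard).
#' @export
remap_identifiers <- function(old_mat, new_mat, scheme_new) {
  old_cl <- old_mat$clusters
  if (any(is.na(old_cl$stable_id)))
    stop("old matrix has unminted clusters")
  old_ver <- unique(parse_identifier(old_cl$stable_id)$version)
  if (scheme_new$version <= max(old_ver))
    stop("new scheme version (", scheme_new$version,
         ") must exceed the old release version (", max(old_ver), ")")

  old_sets <- split(old_mat$members$gene_id, old_mat$members$cluster_id)
  names(old_sets) <- old_cl$stable_id[match(as.integer(names(old_sets)),
                                            old_cl$cluster_id)]
  new_sets <- split(new_mat$members$gene_id, new_mat$members$cluster_id)

  # candidate pairs via shared genes
  gene2old <- setNames(rep(names(old_sets), lengths(old_sets)),
                       unlist(old_sets))
  cand <- list()
  for (nc in names(new_sets)) {
    hits <- unique(gene2old[intersect(new_sets[[nc]], names(gene2old))])
    hits <- hits[!is.na(hits)]
    for (oc in hits) {
      inter <- length(intersect(old_sets[[oc]], new_sets[[nc]]))
      uni <- length(union(old_sets[[oc]], new_sets[[nc]]))
      cand[[length(cand) + 1L]] <- data.frame(
        old_id = oc, new_cid = as.integer(nc), jaccard = inter / uni,
        stringsAsFactors = FALSE)
    }
  }
  cand <- if (length(cand)) do.call(rbind, cand) else
    data.frame(old_id = character(), new_cid = integer(), jaccard = numeric())
  cand <- cand[order(-cand$jaccard, cand$old_id, cand$new_cid), , drop = FALSE]

  inherit <- setNames(rep(NA_character_, length(new_sets)), names(new_sets))
  claimed <- character(0)
  for (i in seq_len(nrow(cand))) {
    oc <- cand$old_id[i]; nc <- as.character(cand$new_cid[i])
    if (oc %in% claimed || !is.na(inherit[nc])) next
    inherit[nc] <- oc
    claimed <- c(claimed, oc)
  }

  # assign identifiers to new clusters
  new_cl <- new_mat$clusters
  parse_old <- parse_identifier(old_cl$stable_id)
  max_multi <- max(c(0L, parse_old$number[!parse_old$is_singleton]))
  max_single <- max(c(1000000L, parse_old$number[parse_old$is_singleton]))
  reformat <- function(old_id) {
    p <- parse_identifier(old_id)
    format_stable_id(scheme_new, p$number)
  }
  new_ids <- character(nrow(new_cl))
  relations <- character(nrow(new_cl))
  for (r in seq_len(nrow(new_cl))) {
    cid <- as.character(new_cl$cluster_id[r])
    oc <- inherit[cid]
    is_multi <- new_cl$n_members[r] >= 2L
    if (!is.na(oc)) {
      old_singleton <- parse_identifier(oc)$is_singleton
      if (old_singleton == !is_multi) {
        new_ids[r] <- reformat(oc)
        relations[r] <- "kept"
      } else {
        # membership-size series change: fresh number in the correct series
        if (is_multi) { max_multi <- max_multi + 1L; num <- max_multi }
        else { max_single <- max_single + 1L; num <- max_single }
        new_ids[r] <- format_stable_id(scheme_new, num)
        relations[r] <- "kept-with-series-change"
      }
    } else {
      if (is_multi) { max_multi <- max_multi + 1L; num <- max_multi }
      else { max_single <- max_single + 1L; num <- max_single }
      new_ids[r] <- format_stable_id(scheme_new, num)
      relations[r] <- "new"
    }
  }
  new_cl$stable_id <- new_ids
  new_mat$clusters <- new_cl

  # mapping table
  rows <- list()
  new_id_of <- setNames(new_ids, as.character(new_cl$cluster_id))
  jac <- function(oc, nc) {
    inter <- length(intersect(old_sets[[oc]], new_sets[[nc]]))
    inter / length(union(old_sets[[oc]], new_sets[[nc]]))
  }
  for (r in seq_len(nrow(new_cl))) {
    cid <- as.character(new_cl$cluster_id[r])
    oc <- inherit[cid]
    if (!is.na(oc))
      rows[[length(rows) + 1L]] <- data.frame(
        old_id = oc, new_id = new_ids[r], relation = relations[r],
        jaccard = jac(oc, cid), stringsAsFactors = FALSE)
  }
  # old clusters not inherited by any new cluster
  for (oc in setdiff(names(old_sets), claimed)) {
    touching <- cand$new_cid[cand$old_id == oc]
    if (length(touching)) {
      # genes went to clusters that kept other ids
      for (nc in touching) {
        nid <- new_id_of[as.character(nc)]
        rel <- if (is.na(inherit[as.character(nc)])) "split" else "merged"
        rows[[length(rows) + 1L]] <- data.frame(
          old_id = oc, new_id = nid, relation = rel,
          jaccard = jac(oc, as.character(nc)), stringsAsFactors = FALSE)
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        old_id = oc, new_id = NA_character_, relation = "retired",
        jaccard = 0, stringsAsFactors = FALSE)
    }
  }
  # new clusters carved from an inherited old cluster (split remainder)
  inherited_old <- inherit[!is.na(inherit)]
  for (r in seq_len(nrow(new_cl))) {
    cid <- as.character(new_cl$cluster_id[r])
    if (!is.na(inherit[cid])) next
    touching <- unique(cand$old_id[cand$new_cid == as.integer(cid)])
    for (oc in intersect(touching, inherited_old)) {
      rows[[length(rows) + 1L]] <- data.frame(
        old_id = oc, new_id = new_ids[r], relation = "split",
        jaccard = jac(oc, cid), stringsAsFactors = FALSE)
    }
  }
  mapping <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(old_id = character(), new_id = character(),
               relation = character(), jaccard = numeric())
  mapping <- mapping[order(mapping$old_id, mapping$new_id), , drop = FALSE]
  rownames(mapping) <- NULL
  list(matrix = new_mat, mapping = mapping)
}
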
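# the classification layer: subfamily anchoring, phylogroup/subgroup
# assignment by support thresholds, intragenic-vs-intergenic duplication
# calls, fusion-locus detection and cleavage-motif association.

#' Assign subfamily labels by nearest anchor
#'
#' Each leaf is labeled with the subfamily of its nearest anchor by patristic
#' (path-length) distance; an exact tie gives "other".
#'
#' @param tree \code{phylo} with branch lengths whose leaves include the
#'   anchors.
#' @param anchors named character vector: anchor leaf id -> subfamily
#'   ("R"/"F"); at least one anchor per subfamily.
#' @return named character vector: leaf id -> subfamily (anchors keep their
#'   own labels).
#' @export
assign_subfamilies <- function(tree, anchors) {
  if (!all(names(anchors) %in% tree$tip.label))
    stop("anchor leaves missing from tree: ",
         paste(setdiff(names(anchors), tree$tip.label), collapse = ", "))
  if (length(unique(anchors)) < 2)
    stop("need anchors for at least two subfamilies")
  D <- patristic_distances(tree)
  out <- anchors[match(tree$tip.label, names(anchors))]
  names(out) <- tree$tip.label
  for (leaf in setdiff(tree$tip.label, names(anchors))) {
    d <- D[leaf, names(anchors)]
    by_sf <- tapply(d, anchors[names(d)], min)
    mn <- min(by_sf)
    winners <- names(by_sf)[by_sf - mn < 1e-12]
    out[leaf] <- if (length(winners) == 1) winners else "other"
  }
  out
}

# supported clades with their supports, oriented away from `orientation`
.decorated_clades <- function(tree, orientation) {
  sup <- tree_supports(tree)
  n <- length(tree$tip.label)
  root <- n + 1L
  sets <- .node_leafsets(tree)
  out <- list()
  for (v in setdiff(seq_len(tree$Nnode) + n, root)) {
    s <- sup[v - n]
    if (is.na(s)) next
    side <- if (orientation %in% sets[[v]]) setdiff(tree$tip.label, sets[[v]])
            else sets[[v]]
    out[[length(out) + 1L]] <- list(set = sort(side), support = s)
  }
  out
}

# keep the maximal sets (not a subset of any other set in the list)
.maximal_sets <- function(sets) {
  if (length(sets) == 0) return(sets)
  keep <- vapply(seq_along(sets), function(i)
    !any(vapply(seq_along(sets), function(j)
      j != i && length(sets[[i]]) <= length(sets[[j]]) &&
        all(sets[[i]] %in% sets[[j]]) &&
        !setequal(sets[[i]], sets[[j]]), logical(1))), logical(1))
  # drop exact duplicates (same set seen from two edges cannot happen, but
  # guard against it deterministically)
  sets <- sets[keep]
  sets[!duplicated(vapply(sets, paste, character(1), collapse = "\r"))]
}

#' Assign phylogroups and subgroups by support thresholds
#'
#' Phylogroups are the maximal supported clades (support >=
#' \code{group_threshold}) whose members all share one subfamily label;
#' within each group, subgroups are the maximal supported clades at
#' \code{subgroup_threshold} that are proper subsets of the group. Units in
#' no group get group "<subfamily>0"; units in no subgroup get subgroup 0
#' (no phylogenetic affiliation with any other subgroup). Labels are
#' numbered by descending member count, ties by the lexicographically
#' smallest member id.
#'
#' @param tree \code{phylo} with supports in \code{node.label}.
#' @param subfamilies named character vector leaf -> subfamily
#'   (see \code{\link{assign_subfamilies}}).
#' @param group_threshold,subgroup_threshold support thresholds (the
#'   0.9 / 0.8 convention).
#' @param orientation either one tip label used to orient all bipartitions,
#'   or a named vector subfamily -> orientation leaf (so each subfamily's
#'   clades can be oriented by the opposite subfamily's anchor).
#' @param exclude leaf ids (e.g. anchors) to drop from group membership and
#'   from the returned assignments.
#' @return data.frame(unit_id, subfamily, group, subgroup, affiliated);
#'   \code{affiliated} is FALSE for subgroup-0 units.
#' @export
assign_phylogroups <- function(tree, subfamilies,
                               group_threshold = 0.9, subgroup_threshold = 0.8,
                               orientation, exclude = character(0)) {
  leaves <- setdiff(tree$tip.label, exclude)
  sfs <- sort(unique(subfamilies[leaves]))
  res <- data.frame(unit_id = leaves,
                    subfamily = unname(subfamilies[leaves]),
                    group = NA_character_, subgroup = NA_integer_,
                    stringsAsFactors = FALSE)
  orient_for <- function(sf) {
    if (length(orientation) == 1 && is.null(names(orientation))) orientation
    else if (sf %in% names(orientation)) orientation[[sf]]
    else orientation[[1]]
  }
  for (sf in sfs) {
    cl <- .decorated_clades(tree, orient_for(sf))
    uniform <- Filter(function(x) {
      mem <- setdiff(x$set, exclude)
      length(mem) > 0 && isTRUE(all(subfamilies[x$set] == sf))
    }, cl)
    gcand <- Filter(function(x) x$support >= group_threshold, uniform)
    gsets <- .maximal_sets(lapply(gcand, `[[`, "set"))
    # order groups by member count (anchors excluded), then smallest member
    gmem <- lapply(gsets, setdiff, y = exclude)
    o <- order(-lengths(gmem), vapply(gmem, min, character(1)))
    gmem <- gmem[o]; gsets <- gsets[o]
    for (gi in seq_along(gmem)) {
      glabel <- paste0(sf, gi)
      res$group[res$unit_id %in% gmem[[gi]]] <- glabel
      # subgroups: maximal supported clades strictly inside the group clade
      scand <- Filter(function(x)
        x$support >= subgroup_threshold &&
          all(x$set %in% gsets[[gi]]) && !setequal(x$set, gsets[[gi]]),
        uniform)
      ssets <- .maximal_sets(lapply(scand, `[[`, "set"))
      smem <- lapply(ssets, setdiff, y = exclude)
      smem <- smem[lengths(smem) > 0]
      so <- order(-lengths(smem), vapply(smem, min, character(1)))
      smem <- smem[so]
      for (si in seq_along(smem))
        res$subgroup[res$unit_id %in% smem[[si]]] <- si
    }
    res$group[res$subfamily == sf & is.na(res$group)] <- paste0(sf, 0)
  }
  res$subgroup[is.na(res$subgroup)] <- 0L
  res$affiliated <- res$subgroup > 0L
  res
}

#' Classify each unit's duplication mode
#'
#' The nearest homolog of a unit is its arg-min-distance partner over all
#' other units. If the minimum is attained only within the unit's locus the
#' mode is intragenic; only outside, intergenic; attained both within and
#' outside (tie at \code{tolerance}), ambiguous.
#'
#' @param units data.frame with unit_id and locus_id.
#' @param D symmetric distance matrix over unit ids (typically
#'   \code{\link{p_distance}} with correction "none" — sequence
#'   dissimilarity — or \code{\link{patristic_distances}}).
#' @param tolerance tie tolerance.
#' @param tiebreak_D optional second distance matrix (typically patristic)
#'   consulted only when several candidates tie exactly on \code{D}: the
#'   tie set shrinks to its \code{tiebreak_D} minimisers before the mode
#'   rule applies. Mismatch-count distances are discrete, so exact ties are
#'   common at low divergence; a continuous tree distance resolves most of
#'   them. The mode is ambiguous only if the surviving tie set still spans
#'   both sides.
#' @return data.frame(unit_id, mode, nearest_id, nearest_dist).
#' @export
classify_duplication_mode <- function(units, D, tolerance = 1e-9,
                                      tiebreak_D = NULL) {
  if (nrow(units) < 2) stop("need at least two units to classify")
  ids <- units$unit_id
  if (!all(ids %in% rownames(D))) stop("distance matrix missing some units")
  loc <- setNames(units$locus_id, ids)
  out <- lapply(ids, function(u) {
    others <- setdiff(ids, u)
    d <- setNames(D[u, others], others)
    mn <- min(d)
    ties <- names(d)[d - mn <= tolerance]
    if (length(ties) > 1 && !is.null(tiebreak_D)) {
      dt <- tiebreak_D[u, ties]
      ties <- ties[dt - min(dt) <= tolerance]
    }
    same <- loc[ties] == loc[u]
    mode <- if (any(same) && any(!same)) "ambiguous"
            else if (any(same)) "intragenic" else "intergenic"
    nearest <- sort(ties)[1]
    data.frame(unit_id = u, mode = mode, nearest_id = nearest,
               nearest_dist = mn, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Detect fusion loci
#'
#' A locus is a fusion locus iff its units carry at least one R and one F
#' subfamily label. The composition string counts units per subfamily in
#' descending order, e.g. "Fx2+Rx1".
#'
#' @param assignments data.frame with unit_id, locus_id and subfamily.
#' @return data.frame(locus_id, n_units, is_fusion, composition).
#' @export
detect_fusion_loci <- function(assignments) {
  out <- lapply(split(assignments, assignments$locus_id), function(a) {
    tab <- sort(table(a$subfamily), decreasing = TRUE)
    tab <- tab[order(-tab, names(tab))]
    data.frame(locus_id = a$locus_id[1], n_units = nrow(a),
               is_fusion = all(c("R", "F") %in% a$subfamily),
               composition = paste(paste0(names(tab), "x", as.integer(tab)),
                                   collapse = "+"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Association between junction-motif presence and focal-group membership
#'
#' Builds the 2x2 locus table (motif yes/no x focal group yes/no) and
#' computes the two-sided Fisher exact p-value (hypergeometric enumeration:
#' the sum of probabilities of all tables with the observed margins whose
#' point probability does not exceed the observed one). Degenerate margins
#' (an all-zero row or column) give p = 1 with a warning.
#'
#' @param motif_by_locus named logical: locus carries a junction motif.
#' @param focal_by_locus named logical (same loci): locus belongs to the
#'   focal group.
#' @return list(table = 2x2 matrix, p.value).
#' @export
motif_group_association <- function(motif_by_locus, focal_by_locus) {
  if (!identical(sort(names(motif_by_locus)), sort(names(focal_by_locus))))
    stop("the two indicators must cover the same loci")
  focal_by_locus <- focal_by_locus[names(motif_by_locus)]
  tab <- matrix(c(sum(motif_by_locus & focal_by_locus),
                  sum(motif_by_locus & !focal_by_locus),
                  sum(!motif_by_locus & focal_by_locus),
                  sum(!motif_by_locus & !focal_by_locus)),
                nrow = 2, byrow = TRUE,
                dimnames = list(motif = c("yes", "no"),
                                focal = c("yes", "no")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin in 2x2 table; p set to 1")
    return(list(table = tab, p.value = 1))
  }
  list(table = tab, p.value = fisher.test(tab)$p.value)
}
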
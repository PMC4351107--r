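# distance computation, neighbor-joining, bootstrap supports and
# support-thresholded clade extraction.  Trees are ape `phylo` objects with
# bootstrap proportions (in [0,1]) stored as internal node labels; those
# proportions stand in for SH-like local supports, which live on the same
# scale, so the classification thresholds (0.9, 0.8) apply unchanged.

#' Pairwise p-distances from an alignment
#'
#' Pairwise deletion: for each pair only columns where both rows are
#' ungapped are compared. Optional Poisson correction
#' \code{d = -ln(1 - p)} with p capped at 0.95.
#'
#' @param aln an \code{aa_alignment}.
#' @param correction "none" (proportion of mismatches) or "poisson".
#' @return symmetric distance matrix with taxa dimnames.
#' @export
p_distance <- function(aln, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  m <- aln_matrix(aln)
  nz <- (m != "-") * 1
  V <- nz %*% t(nz)                     # compared columns per pair
  res <- setdiff(unique(as.vector(m)), "-")
  Msame <- matrix(0, nrow(m), nrow(m))
  for (r in res) {
    x <- (m == r) * 1
    Msame <- Msame + x %*% t(x)
  }
  off <- which(V == 0 & upper.tri(V), arr.ind = TRUE)
  if (nrow(off) > 0)
    stop("no comparable columns between ", rownames(m)[off[1, 1]], " and ",
         rownames(m)[off[1, 2]])
  p <- (V - Msame) / V
  diag(p) <- 0
  if (correction == "poisson") p <- -log(1 - pmin(p, 0.95))
  dimnames(p) <- list(rownames(m), rownames(m))
  p
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei agglomeration on the Q criterion with the standard
#' branch-length formulas. Ties in Q are broken deterministically by the
#' lexicographically smallest pair of cluster labels (a cluster's label is
#' the smallest leaf name it contains). Negative branch-length estimates are
#' clamped to zero with the deficit moved to the sibling edge.
#'
#' @param D symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return unrooted \code{phylo} (trifurcation at the root node); no
#'   supports set.
#' @export
neighbor_joining <- function(D) {
  taxa <- rownames(D)
  if (is.null(taxa) || length(taxa) < 3) stop("need >= 3 labeled taxa")
  if (any(abs(D - t(D)) > 1e-9)) stop("distance matrix not symmetric")
  frag <- taxa
  rep_label <- taxa
  Dm <- D
  clamp2 <- function(v) {  # clamp negatives, move deficit to the sibling
    if (v[1] < 0) { v[2] <- v[2] + v[1]; v[1] <- 0 }
    if (v[2] < 0) { v[1] <- max(v[1] + v[2], 0); v[2] <- 0 }
    v
  }
  while (length(frag) > 3) {
    n <- length(frag)
    r <- rowSums(Dm)
    Q <- (n - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    mq <- min(Q)
    cand <- which(Q - mq < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      lab <- sort(c(rep_label[ij[1]], rep_label[ij[2]]))
      paste(lab, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    v <- clamp2(c(0.5 * Dm[i, j] + (r[i] - r[j]) / (2 * (n - 2)),
                  0.5 * Dm[i, j] + (r[j] - r[i]) / (2 * (n - 2))))
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], v[1], frag[j], v[2])
    dnew <- pmax(0.5 * (Dm[i, ] + Dm[j, ] - Dm[i, j]), 0)[-c(i, j)]
    Dm <- Dm[-c(i, j), -c(i, j), drop = FALSE]
    Dm <- rbind(cbind(Dm, dnew), c(dnew, 0))
    frag <- c(frag[-c(i, j)], newfrag)
    rep_label <- c(rep_label[-c(i, j)], min(rep_label[i], rep_label[j]))
  }
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  x <- pmax(c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2,
              (d13 + d23 - d12) / 2), 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], x[1], frag[2], x[2], frag[3], x[3])
  ape::read.tree(text = nwk)
}

# leaf-label set under every node (tips and internal), by postorder pass
.node_leafsets <- function(tree) {
  n <- length(tree$tip.label)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  ed <- reorder(tree, "postorder")$edge
  for (k in seq_len(nrow(ed)))
    sets[[ed[k, 1]]] <- c(sets[[ed[k, 1]]], sets[[ed[k, 2]]])
  sets
}

# canonical split keys for all non-root internal nodes: the side not
# containing the reference leaf (smallest label), sorted and joined
.split_keys <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  ref <- min(tree$tip.label)
  sets <- .node_leafsets(tree)
  nodes <- setdiff(seq_len(tree$Nnode) + n, root)
  keys <- vapply(nodes, function(v) {
    s <- sets[[v]]
    side <- if (ref %in% s) setdiff(tree$tip.label, s) else s
    paste(sort(side), collapse = "\r")
  }, character(1))
  setNames(keys, nodes)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement \code{n_reps} times, rebuilds
#' the NJ tree from each resample, and sets each internal edge's support to
#' the fraction of replicates containing the same bipartition.
#'
#' @param aln the \code{aa_alignment} the tree was built from.
#' @param tree the \code{phylo} to decorate (taxa must equal alignment rows).
#' @param n_reps number of bootstrap resamplings (>= 1); the default follows
#'   the 400-resampling convention.
#' @param seed integer seed; identical seeds give identical supports.
#' @param correction distance correction, as in \code{\link{p_distance}}.
#' @return \code{tree} with supports in \code{node.label} (root label empty).
#' @export
bootstrap_supports <- function(aln, tree, n_reps = 400L, seed = 1L,
                               correction = "poisson") {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!setequal(names(aln), tree$tip.label))
    stop("alignment taxa do not match tree taxa")
  m <- aln_matrix(aln)[sort(names(aln)), , drop = FALSE]  # leaf-order invariant
  L <- ncol(m)
  keys <- .split_keys(tree)
  counts <- setNames(numeric(length(keys)), keys)
  set.seed(stage_seed(seed, "bootstrap"))
  for (b in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    mb <- m[, cols, drop = FALSE]
    rows <- apply(mb, 1, paste, collapse = "")
    alnb <- structure(setNames(rows, rownames(m)), class = "aa_alignment")
    Db <- p_distance(alnb, correction)
    trb <- neighbor_joining(Db)
    kb <- .split_keys(trb)
    hit <- keys %in% kb
    counts[hit] <- counts[hit] + 1
  }
  n <- length(tree$tip.label)
  lab <- rep("", tree$Nnode)
  lab[as.integer(names(keys)) - n] <- as.character(counts / n_reps)
  tree$node.label <- lab
  tree
}

#' Extract clades above a support threshold
#'
#' Bipartitions are turned into clades by an orientation (outgroup) leaf:
#' every internal edge with support at or above the threshold contributes
#' the leaf set on the side not containing the orientation leaf.
#'
#' @param tree \code{phylo} with supports in \code{node.label}.
#' @param threshold minimum support in [0,1].
#' @param orientation tip label used to orient bipartitions.
#' @return list of character vectors (sorted leaf sets), one per supported
#'   internal edge.
#' @export
supported_clades <- function(tree, threshold, orientation) {
  if (!orientation %in% tree$tip.label)
    stop("orientation leaf '", orientation, "' absent from tree")
  sup <- tree_supports(tree)
  if (all(is.na(sup))) stop("tree carries no supports")
  n <- length(tree$tip.label)
  root <- n + 1L
  sets <- .node_leafsets(tree)
  out <- list()
  for (v in setdiff(seq_len(tree$Nnode) + n, root)) {
    s <- sup[v - n]
    if (is.na(s) || s < threshold) next
    side <- if (orientation %in% sets[[v]]) setdiff(tree$tip.label, sets[[v]])
            else sets[[v]]
    out[[length(out) + 1L]] <- sort(side)
  }
  out
}

#' Patristic (path-length) distances between all leaves
#' @param tree \code{phylo} with branch lengths.
#' @return symmetric matrix of path-length distances.
#' @export
patristic_distances <- function(tree) {
  as.matrix(stats::cophenetic(tree))
}
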
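# independent oracles used by the tests. Each deliberately avoids the code
# path it checks: alignment scores come from explicit enumeration of all
# gapped alignments, clades from flood-fill bipartition enumeration on the
# edge list, Fisher p-values from direct hypergeometric sums, patristic
# distances from a depth-first path walk.

# ---- exhaustive alignment enumeration --------------------------------------
# all monotone alignment templates for sequence lengths (la, lb): matrices
# with columns ai, bi (0 = gap). Enumerated once per length pair.
alignment_templates <- local({
  cache <- list()
  function(la, lb) {
    key <- paste(la, lb)
    if (!is.null(cache[[key]])) return(cache[[key]])
    out <- list()
    rec <- function(i, j, rows) {
      if (i == la && j == lb) { out[[length(out) + 1L]] <<- rows; return() }
      if (i < la && j < lb) rec(i + 1, j + 1, rbind(rows, c(i + 1, j + 1)))
      if (i < la) rec(i + 1, j, rbind(rows, c(i + 1, 0)))
      if (j < lb) rec(i, j + 1, rbind(rows, c(0, j + 1)))
    }
    rec(0, 0, matrix(integer(0), ncol = 2))
    cache[[key]] <<- out
    out
  }
})

# affine gap cost of one maximal gap run of length k
gap_run_cost <- function(k, open, ext) ifelse(k > 0, open + (k - 1) * ext, 0)

# best score over all alignments of a and b by explicit enumeration
nw_oracle_score <- function(a, b, submat, open, ext) {
  ai <- strsplit(a, "")[[1]]; bi <- strsplit(b, "")[[1]]
  la <- length(ai); lb <- length(bi)
  if (la == 0 && lb == 0) return(0)
  if (la == 0) return(gap_run_cost(lb, open, ext))
  if (lb == 0) return(gap_run_cost(la, open, ext))
  best <- -Inf
  for (tpl in alignment_templates(la, lb)) {
    s <- 0
    m <- tpl[, 1] > 0 & tpl[, 2] > 0
    if (any(m)) s <- s + sum(submat[cbind(ai[tpl[m, 1]], bi[tpl[m, 2]])])
    for (col in 1:2) {
      gaps <- tpl[, col] == 0
      runs <- rle(gaps)
      s <- s + sum(gap_run_cost(runs$lengths[runs$values], open, ext))
    }
    best <- max(best, s)
  }
  best
}

# ---- tree oracles -----------------------------------------------------------
# random binary tree with uniform branch lengths, as an ape phylo
random_metric_tree <- function(n, min_bl = 0.05, max_bl = 0.5) {
  tr <- ape::rtree(n, br = NULL)
  tr$edge.length <- runif(nrow(tr$edge), min_bl, max_bl)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

# leaf sets of both sides of every internal edge, by flood fill on the edge
# list with the focal edge removed (independent of the package's postorder
# accumulation)
oracle_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  edges <- tree$edge
  internal <- which(edges[, 2] > n)
  lapply(internal, function(k) {
    keep <- edges[-k, , drop = FALSE]
    adj <- split(c(keep[, 2], keep[, 1]), c(keep[, 1], keep[, 2]))
    comp <- edges[k, 2]; frontier <- comp
    while (length(frontier)) {
      nb <- setdiff(unlist(adj[as.character(frontier)]), comp)
      comp <- c(comp, nb); frontier <- nb
    }
    side <- sort(tree$tip.label[comp[comp <= n]])
    list(node = edges[k, 2], side = side,
         other = sort(setdiff(tree$tip.label, side)))
  })
}

# clades above threshold by direct edge enumeration
oracle_supported_clades <- function(tree, threshold, orientation) {
  sup <- suppressWarnings(as.numeric(tree$node.label))
  n <- length(tree$tip.label)
  out <- list()
  for (bp in oracle_bipartitions(tree)) {
    if (bp$node == n + 1) next  # root carries no edge
    s <- sup[bp$node - n]
    if (is.na(s) || s < threshold) next
    out[[length(out) + 1L]] <-
      if (orientation %in% bp$side) bp$other else bp$side
  }
  out
}

# patristic distance by explicit path walk from each leaf (DFS)
oracle_patristic <- function(tree) {
  n <- length(tree$tip.label)
  edges <- tree$edge; len <- tree$edge.length
  adj <- lapply(seq_len(max(edges)), function(v) {
    k <- which(edges[, 1] == v | edges[, 2] == v)
    cbind(ifelse(edges[k, 1] == v, edges[k, 2], edges[k, 1]), len[k])
  })
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(n)) {
    dist <- rep(NA_real_, max(edges)); dist[s] <- 0; frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (r in seq_len(nrow(adj[[v]]))) {
        w <- adj[[v]][r, 1]
        if (is.na(dist[w])) { dist[w] <- dist[v] + adj[[v]][r, 2]; nxt <- c(nxt, w) }
      }
      frontier <- nxt
    }
    D[s, ] <- dist[seq_len(n)]
  }
  D
}

# ---- Fisher oracle ----------------------------------------------------------
# two-sided Fisher exact p by direct hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- choose(c1, xs) * choose(N - c1, r1 - xs) / choose(N, r1)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ---- misc -------------------------------------------------------------------
random_aa_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

canon_sets <- function(sets)
  sort(unname(vapply(sets, paste, character(1), collapse = "|")))
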
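# progressive multiple alignment of unit sequences plus gap-column trimming.
# Pairwise and profile-profile steps share one affine-gap DP kernel (C++);
# the guide tree is UPGMA on a k-mer distance.

.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[AA20, AA20]
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch with gap cost \code{gap_open + (k-1) * gap_extend} for a
#' run of length k. Traceback ties prefer diagonal, then up, then left, so
#' the alignment is deterministic.
#'
#' @param a,b residue strings (either may be empty).
#' @param submat substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend gap penalties (negative).
#' @return list(a, b, score) with gapped strings.
#' @export
pairwise_nw <- function(a, b, submat = .blosum62(),
                        gap_open = -10, gap_extend = -1) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0 && nb == 0) return(list(a = "", b = "", score = 0))
  if (na == 0) return(list(a = strrep("-", nb), b = b,
                           score = gap_open + (nb - 1) * gap_extend))
  if (nb == 0) return(list(a = a, b = strrep("-", na),
                           score = gap_open + (na - 1) * gap_extend))
  ai <- strsplit(a, "")[[1]]; bi <- strsplit(b, "")[[1]]
  S <- submat[ai, bi, drop = FALSE]
  r <- .nw_dp(S, gap_open, gap_extend)
  pa <- r$path[, 1]; pb <- r$path[, 2]
  list(a = paste(ifelse(pa == 0, "-", ai[pmax(pa, 1)]), collapse = ""),
       b = paste(ifelse(pb == 0, "-", bi[pmax(pb, 1)]), collapse = ""),
       score = r$score)
}

# column count matrix (21 x L: 20 residues + gap) of a profile (char matrix rows x cols)
.profile_counts <- function(rows) {
  L <- nchar(rows[1])
  m <- do.call(rbind, strsplit(rows, ""))
  counts <- matrix(0, nrow = 21L, ncol = L)
  for (j in seq_len(L)) {
    tab <- table(factor(m[, j], levels = c(AA20, "-")))
    counts[, j] <- as.numeric(tab)
  }
  counts
}

# profile-profile column score matrix: mean pairwise substitution score over
# row pairs; residue-vs-gap pairs score gap_extend, gap-gap pairs score 0
.profile_colscores <- function(ca, cb, submat, gap_extend) {
  nA <- sum(ca[, 1]); nB <- sum(cb[, 1])
  ra <- ca[1:20, , drop = FALSE]; rb <- cb[1:20, , drop = FALSE]
  ga <- ca[21, ]; gb <- cb[21, ]
  t1 <- t(ra) %*% submat %*% rb
  t2 <- outer(ga, colSums(rb)) + outer(colSums(ra), gb)
  (t1 + gap_extend * t2) / (nA * nB)
}

.merge_profiles <- function(rows_a, rows_b, submat, gap_open, gap_extend) {
  ca <- .profile_counts(rows_a); cb <- .profile_counts(rows_b)
  S <- .profile_colscores(ca, cb, submat, gap_extend)
  r <- .nw_dp(S, gap_open, gap_extend)
  pa <- r$path[, 1]; pb <- r$path[, 2]
  expand <- function(rows, idx) {
    m <- do.call(rbind, strsplit(rows, ""))
    out <- matrix("-", nrow = nrow(m), ncol = length(idx))
    out[, idx > 0] <- m[, idx[idx > 0], drop = FALSE]
    setNames(apply(out, 1, paste, collapse = ""), names(rows))
  }
  c(expand(rows_a, pa), expand(rows_b, pb))
}

# shared k-mer multiset distance: 1 - |shared k-mers| / max(#kmers a, #kmers b)
.kmer_dist <- function(seqs, k) {
  n <- length(seqs)
  km <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1), k:L)
  })
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ti <- table(km[[i]]); tj <- table(km[[j]])
    common <- intersect(names(ti), names(tj))
    shared <- sum(pmin(ti[common], tj[common]))
    D[i, j] <- D[j, i] <- 1 - shared / max(length(km[[i]]), length(km[[j]]), 1)
  }
  dimnames(D) <- list(names(seqs), names(seqs))
  D
}

#' Progressive multiple alignment
#'
#' UPGMA guide tree on a 3-mer multiset distance, profiles merged bottom-up
#' by profile-profile Needleman-Wunsch (column score = mean pairwise
#' substitution score; gaps scored with the gap-extension penalty).
#'
#' @param seqs named character vector of residue strings (>= 1).
#' @param k k-mer size for the guide-tree distance.
#' @inheritParams pairwise_nw
#' @return object of class \code{aa_alignment}: named character vector of
#'   equal-length gapped rows, in the input order.
#' @export
progressive_align <- function(seqs, k = 3, submat = .blosum62(),
                              gap_open = -10, gap_extend = -1) {
  if (length(seqs) == 0) stop("no sequences to align")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  if (length(seqs) == 1)
    return(structure(seqs, class = "aa_alignment"))
  D <- .kmer_dist(seqs, k)
  hc <- hclust(as.dist(D), method = "average")  # UPGMA
  profiles <- lapply(seq_along(seqs), function(i) setNames(seqs[i], names(seqs)[i]))
  merged <- vector("list", nrow(hc$merge))
  for (step in seq_len(nrow(hc$merge))) {
    pick <- function(x) if (x < 0) profiles[[-x]] else merged[[x]]
    merged[[step]] <- .merge_profiles(pick(hc$merge[step, 1]),
                                      pick(hc$merge[step, 2]),
                                      submat, gap_open, gap_extend)
  }
  out <- merged[[nrow(hc$merge)]][names(seqs)]
  structure(out, class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("<aa_alignment> ", length(x), " rows x ", nchar(x[[1]]), " columns\n",
      sep = "")
  invisible(x)
}

# alignment -> character matrix
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Remove gap-rich alignment columns
#'
#' A column is retained iff its gap fraction is at most
#' \code{max_gap_fraction}; column order is preserved and the kept-column
#' index map (attribute \code{kept_columns}) projects trimmed coordinates
#' back onto the input alignment.
#'
#' @param aln an \code{aa_alignment}.
#' @param max_gap_fraction maximum tolerated gap fraction per column.
#' @return trimmed \code{aa_alignment} with attribute \code{kept_columns}.
#' @export
trim_columns <- function(aln, max_gap_fraction = 0.5) {
  m <- aln_matrix(aln)
  frac <- colMeans(m == "-")
  kept <- which(frac <= max_gap_fraction)
  if (length(kept) == 0)
    stop("all columns exceed the gap-fraction threshold; raise max_gap_fraction")
  out <- apply(m[, kept, drop = FALSE], 1, paste, collapse = "")
  structure(setNames(out, names(aln)), class = "aa_alignment",
            kept_columns = unname(kept))
}

#' Write/read a gapped FASTA alignment
#' @param aln an \code{aa_alignment}.
#' @param path file path.
#' @export
write_alignment <- function(aln, path) write_fasta(unclass(aln), path)

#' @rdname write_alignment
#' @export
read_alignment <- function(path) {
  x <- read_fasta(path)
  if (length(unique(nchar(x))) > 1) stop("rows differ in length: not an alignment")
  structure(x, class = "aa_alignment")
}
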
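# decomposition of polyproteins into single LHC-like units by a fixed-length
# position-weight-matrix scan, redundancy collapse, and junction-motif search.
# The PWM plays the role a profile-HMM search plays on real data: simulated
# units are fixed-length and indel-free, so insert/delete states add nothing.

#' Build a log-odds profile from a gapless seed alignment
#'
#' Per-cell score is
#' \code{log2(((count(pos, r) + 1) / (N + 20)) / 0.05)}: residue counts with
#' pseudocount 1 against a uniform 1/20 background.
#'
#' @param seed_alignment character vector of equal-length, gapless residue
#'   strings (at least one).
#' @return object of class \code{aa_profile}: a length x 20 score matrix in
#'   bits with attribute \code{consensus_score}.
#' @export
build_profile <- function(seed_alignment) {
  if (length(seed_alignment) == 0) stop("empty seed alignment")
  L <- unique(nchar(seed_alignment))
  if (length(L) != 1) stop("ragged seed alignment: sequences differ in length")
  N <- length(seed_alignment)
  rows <- lapply(seed_alignment, aa_to_int)
  counts <- matrix(0L, nrow = L, ncol = 20L, dimnames = list(NULL, AA20))
  for (r in rows) counts[cbind(seq_len(L), r)] <- counts[cbind(seq_len(L), r)] + 1L
  scores <- log2(((counts + 1) / (N + 20)) / 0.05)
  structure(scores, class = "aa_profile",
            consensus_score = sum(apply(scores, 1, max)))
}

#' @export
print.aa_profile <- function(x, ...) {
  cat("<aa_profile> length ", nrow(x), ", consensus self-score ",
      round(attr(x, "consensus_score"), 2), " bits\n", sep = "")
  invisible(x)
}

# score the profile at every start offset of an integer-coded sequence
.pwm_scores <- function(s_int, profile) {
  L <- nrow(profile); n <- length(s_int)
  if (n < L) return(numeric(0))
  n_off <- n - L + 1L
  tot <- numeric(n_off)
  for (k in seq_len(L)) {
    v <- profile[cbind(k, s_int)]
    tot <- tot + v[k:(k + n_off - 1L)]
  }
  tot
}

#' Scan one polyprotein for unit occurrences of a profile
#'
#' Slides the profile over every start offset, then greedily accepts
#' candidates in descending score order (ties: smaller start first), skipping
#' any candidate overlapping an accepted span, and keeps those scoring at
#' least \code{min_score}.
#'
#' @param loc a \code{\link{locus}} (its \code{polyprotein} is scanned).
#' @param profile an \code{\link{build_profile}} result.
#' @param min_score acceptance threshold in bits; default half the profile's
#'   consensus self-score.
#' @param min_len,max_len accepted span-width bounds (the fixed-width scan
#'   always emits \code{nrow(profile)}; the bounds are validated).
#' @return data.frame with columns locus_id, start, end (0-based half-open),
#'   score, rank, sequence; sequences shorter than the profile give zero rows.
#' @export
scan_polyprotein <- function(loc, profile, min_score = NULL,
                             min_len = nrow(profile), max_len = nrow(profile)) {
  if (max_len < nrow(profile) || nrow(profile) < min_len)
    stop("profile length must lie within [min_len, max_len]")
  if (is.null(min_score)) min_score <- 0.5 * attr(profile, "consensus_score")
  empty <- data.frame(locus_id = character(0), start = integer(0),
                      end = integer(0), score = numeric(0), rank = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  s_int <- tryCatch(aa_to_int(loc$polyprotein), error = function(e) NULL)
  if (is.null(s_int)) stop("locus ", loc$id, ": non-standard residues")
  sc <- .pwm_scores(s_int, profile)
  if (length(sc) == 0) return(empty)
  L <- nrow(profile)
  cand <- which(sc >= min_score)
  if (length(cand) == 0) return(empty)
  cand <- cand[order(-sc[cand], cand)]  # score desc, then smaller start
  taken <- logical(length(s_int))
  acc <- integer(0)
  for (o in cand) {
    idx <- o:(o + L - 1L)
    if (!any(taken[idx])) { taken[idx] <- TRUE; acc <- c(acc, o) }
  }
  acc <- sort(acc)
  data.frame(locus_id = loc$id, start = acc - 1L, end = acc - 1L + L,
             score = sc[acc], rank = rank(-sc[acc], ties.method = "first"),
             sequence = vapply(acc, function(o)
               substr(loc$polyprotein, o, o + L - 1L), character(1)),
             stringsAsFactors = FALSE)
}

#' Scan a collection of loci and assemble the unit table
#'
#' @param loci named list of \code{\link{locus}} objects.
#' @inheritParams scan_polyprotein
#' @return data.frame with unit_id (\code{<locus>_u<k>} in genomic order),
#'   locus_id, position, start, end, score, sequence. Per-locus results are
#'   independent of the input order of \code{loci}.
#' @export
scan_units <- function(loci, profile, min_score = NULL,
                       min_len = nrow(profile), max_len = nrow(profile)) {
  out <- lapply(loci, function(loc) {
    u <- scan_polyprotein(loc, profile, min_score, min_len, max_len)
    if (nrow(u)) {
      u$position <- seq_len(nrow(u))
      u$unit_id <- paste0(u$locus_id, "_u", u$position)
    } else { u$position <- integer(0); u$unit_id <- character(0) }
    u
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("unit_id", "locus_id", "position", "start", "end", "score", "sequence")]
}

#' Collapse redundant units
#'
#' Units with identical residue sequence AND identical locus keep only the
#' copy with the smallest start coordinate (redundant same-locus models, e.g.
#' alternative splice forms, collapse); identical sequences on different loci
#' are all retained — they are the intergenic duplication signal.
#'
#' @param units unit data.frame (needs locus_id, sequence, start).
#' @return list(units = surviving rows, removed = removed rows).
#' @export
collapse_redundant <- function(units) {
  key <- paste(units$locus_id, units$sequence, sep = "\r")
  keep <- logical(nrow(units))
  for (k in unique(key)) {
    idx <- which(key == k)
    keep[idx[which.min(units$start[idx])]] <- TRUE
  }
  list(units = units[keep, , drop = FALSE],
       removed = units[!keep, , drop = FALSE])
}

#' Locate junction motifs in a locus
#'
#' Exact (possibly overlapping) motif occurrences are classified by where
#' they fall: \code{junction} hits lie between consecutive unit spans or
#' straddle a span boundary by at most \code{nchar(motif) - 1} residues;
#' \code{within_unit} hits lie entirely inside one unit span and are excluded
#' from junction counts; anything else (leading/trailing flank) is
#' \code{flank}.
#'
#' @param loc a \code{\link{locus}} with at least one unit span.
#' @param motif non-empty residue string.
#' @return data.frame(start, end, class) in 0-based half-open coordinates.
#' @export
find_junction_motifs <- function(loc, motif) {
  if (!nzchar(motif)) stop("motif must be non-empty")
  if (nrow(loc$spans) < 1) stop("locus ", loc$id, " has no unit spans")
  m <- gregexpr(paste0("(?=", motif, ")"), loc$polyprotein, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(start = integer(0), end = integer(0),
                      class = character(0), stringsAsFactors = FALSE))
  start <- as.integer(m) - 1L            # 0-based
  end <- start + nchar(motif)
  spans <- loc$spans
  within <- vapply(seq_along(start), function(i)
    any(spans[, 1] <= start[i] & end[i] <= spans[, 2]), logical(1))
  # inter-span gap regions
  gaps <- if (nrow(spans) > 1)
    cbind(spans[-nrow(spans), 2], spans[-1, 1]) else matrix(integer(0), ncol = 2)
  touches_gap <- vapply(seq_along(start), function(i) {
    if (nrow(gaps) == 0) return(FALSE)
    any(start[i] < gaps[, 2] & end[i] > gaps[, 1])
  }, logical(1))
  cls <- ifelse(within, "within_unit", ifelse(touches_gap, "junction", "flank"))
  data.frame(start = start, end = end, class = cls, stringsAsFactors = FALSE)
}
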
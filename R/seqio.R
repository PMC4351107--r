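# readers/writers for every on-disk format the pipeline touches:
# protein FASTA (Biostrings), the locus-map GFF3 dialect, Newick (ape), TSV.
# Internal coordinates are 0-based half-open everywhere; 1-based inclusive
# exists only at the GFF3 boundary.

#' Construct a polyprotein locus
#'
#' A locus is one genomic gene model holding a polyprotein sequence and the
#' ordered spans of its constituent protein units.
#'
#' @param id locus identifier.
#' @param scaffold scaffold/contig identifier.
#' @param strand "+" or "-".
#' @param polyprotein residue string (uppercase one-letter codes).
#' @param spans integer matrix with columns start, end: ordered,
#'   non-overlapping unit spans in 0-based half-open coordinates.
#' @return an object of class \code{locus}.
#' @export
locus <- function(id, scaffold, strand, polyprotein, spans) {
  spans <- matrix(as.integer(spans), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (!strand %in% c("+", "-")) stop("unknown strand symbol for locus ", id)
  n <- nchar(polyprotein)
  if (nrow(spans) > 0) {
    if (any(spans[, 2] <= spans[, 1]))
      stop("locus ", id, ": span end must exceed start")
    if (any(spans[, 1] < 0) || any(spans[, 2] > n))
      stop("locus ", id, ": unit span outside sequence bounds")
    o <- order(spans[, 1])
    spans <- spans[o, , drop = FALSE]
    if (nrow(spans) > 1 && any(spans[-1, 1] < spans[-nrow(spans), 2]))
      stop("locus ", id, ": overlapping unit spans")
  }
  structure(list(id = id, scaffold = scaffold, strand = strand,
                 polyprotein = polyprotein, spans = spans),
            class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat("<locus ", x$id, "> ", nrow(x$spans), " unit(s), ",
      nchar(x$polyprotein), " aa on ", x$scaffold, x$strand, "\n", sep = "")
  invisible(x)
}

# extract unit sequences of a locus as a named character vector
locus_unit_seqs <- function(loc) {
  if (nrow(loc$spans) == 0) return(character(0))
  vapply(seq_len(nrow(loc$spans)), function(i)
    substr(loc$polyprotein, loc$spans[i, 1] + 1L, loc$spans[i, 2]),
    character(1))
}

#' Read a protein FASTA file
#'
#' Lowercase residues are uppercased (with a message); duplicate ids are an
#' error. Returns a named character vector of sequences.
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  raw <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(raw)))
  if (length(nonblank) == 0) return(setNames(character(0), character(0)))
  if (!startsWith(raw[nonblank[1]], ">"))
    stop("malformed FASTA header at line ", nonblank[1],
         ": expected a '>' record start")
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) return(setNames(character(0), character(0)))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  low <- grepl("[a-z]", seqs)
  if (any(low)) {
    message(sum(low), " record(s) contained lowercase residues; uppercased")
    seqs <- toupper(seqs)
  }
  setNames(seqs, ids)
}

#' Write sequences as FASTA wrapped at 60 columns
#' @param records named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# ---- GFF3 locus-map dialect -------------------------------------------------
# one `gene` feature per locus (span 1..len of the polyprotein) and one
# `mature_protein_region` child per unit; coordinates are residues within the
# locus polyprotein, 1-based inclusive on disk.

#' Write loci as a GFF3 locus map
#' @param loci list of \code{locus} objects.
#' @param path output file.
#' @export
write_gff3 <- function(loci, path) {
  lines <- "##gff-version 3"
  for (loc in loci) {
    n <- nchar(loc$polyprotein)
    lines <- c(lines, paste(loc$scaffold, "polydup", "gene", 1L, n, ".",
                            loc$strand, ".", paste0("ID=", loc$id),
                            sep = "\t"))
    if (nrow(loc$spans) > 0)
      for (i in seq_len(nrow(loc$spans)))
        lines <- c(lines, paste(loc$scaffold, "polydup", "mature_protein_region",
                                loc$spans[i, 1] + 1L, loc$spans[i, 2], ".",
                                loc$strand, ".",
                                paste0("ID=", loc$id, ".u", i, ";Parent=", loc$id),
                                sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 locus map
#'
#' On-disk 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention at this single point.
#'
#' @param path GFF3 file written by \code{\link{write_gff3}} (gene features
#'   with \code{mature_protein_region} children).
#' @param sequences optional named character vector of polyprotein sequences
#'   (FASTA ids = locus ids) used to populate the locus sequences.
#' @return named list of \code{locus} objects, in file order.
#' @export
read_gff3 <- function(path, sequences = NULL) {
  raw <- readLines(path)
  raw <- raw[!grepl("^#", raw) & nzchar(raw)]
  if (length(raw) == 0) return(list())
  f <- strsplit(raw, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad))
    stop("malformed GFF3 line ", bad[1], ": expected 9 columns")
  attr1 <- function(a, key) {
    m <- regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]*"), a))
    if (length(m) == 0) return(NA_character_)
    sub(paste0("^(;)?", key, "="), "", m)
  }
  recs <- do.call(rbind, lapply(seq_along(f), function(i) {
    x <- f[[i]]
    start <- suppressWarnings(as.integer(x[4])); end <- suppressWarnings(as.integer(x[5]))
    if (is.na(start) || is.na(end) || end < start)
      stop("GFF3 line ", i, ": invalid coordinates (end < start?)")
    if (!x[7] %in% c("+", "-"))
      stop("GFF3 line ", i, ": unknown strand symbol '", x[7], "'")
    data.frame(scaffold = x[1], type = x[3], start = start, end = end,
               strand = x[7], id = attr1(x[9], "ID"),
               parent = attr1(x[9], "Parent"), stringsAsFactors = FALSE)
  }))
  genes <- recs[recs$type == "gene", , drop = FALSE]
  units <- recs[recs$type != "gene", , drop = FALSE]
  loci <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    u <- units[units$parent == g$id, , drop = FALSE]
    seqstr <- if (!is.null(sequences)) sequences[[g$id]] %||% strrep("X", g$end)
              else strrep("X", g$end)
    locus(g$id, g$scaffold, g$strand, seqstr,
          cbind(u$start - 1L, u$end))  # 1-based inclusive -> 0-based half-open
  })
  setNames(loci, genes$id)
}

# ---- Newick -----------------------------------------------------------------

#' Read a single Newick tree with supports as internal node labels
#' @param path Newick file.
#' @return an \code{ape} \code{phylo}; internal node labels hold supports
#'   in [0,1] (as characters, parse with \code{\link{tree_supports}}).
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("failed to parse Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("failed to parse Newick file ", path)
  tr
}

#' Write a tree as Newick (branch lengths to 6 decimals)
#' @param tree \code{phylo} object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  if (!is.null(tree$edge.length))
    tree$edge.length <- round(tree$edge.length, 6)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Numeric supports of a tree's internal nodes
#'
#' @param tree \code{phylo} with supports stored in \code{node.label}
#'   (proportions in [0,1]; the label "1" parses as 1.0).
#' @return numeric vector, one entry per internal node (NA where unlabeled).
#' @export
tree_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  s <- suppressWarnings(as.numeric(tree$node.label))
  s
}

# ---- TSV --------------------------------------------------------------------

#' Read/write a tab-separated table with header
#' @param x data.frame to write.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)
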
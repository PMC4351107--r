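# forward simulator of multigene-family evolution on polyprotein loci.
#
# Two divergent founder subfamilies (R-like and F-like, one single-unit locus
# each) evolve by per-generation Poisson numbers of events:
#   intragenic_dup — a unit is copied in place, adjacent to its template
#   intergenic_dup — a unit (or, with probability 0.5, its whole locus) is
#                    copied to a brand-new locus
#   fusion         — a copy of a unit is appended to a locus composed
#                    entirely of the other subfamily
#   conversion     — a unit's sequence is overwritten by a random paralog's
#   loss           — a unit is deleted (never the last unit of a subfamily)
# after which every site of every unit mutates independently with a fixed
# per-site probability to a uniformly chosen different residue.  Every event
# is logged, so recovery of duplication modes, fusion loci and subfamily
# labels can be scored against the truth.

#' Simulation configuration
#'
#' @param n_generations number of generations.
#' @param rate_intragenic,rate_intergenic,rate_fusion,rate_conversion,rate_loss
#'   expected events per generation (Poisson rates, >= 0).
#' @param subst_per_site_per_generation per-site substitution probability in
#'   [0,1) applied each generation.
#' @param unit_length unit length in residues.
#' @param founder_divergence target fraction of differing sites between the
#'   two subfamily founders, in [0,1].
#' @param motif junction cleavage motif (default "SPLR").
#' @param motif_subgroup lineage tag whose junctions carry the motif
#'   (founder lineages are "F1" and "R1").
#' @param seed integer seed; identical configs give byte-identical output.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_generations = 60L,
                       rate_intragenic = 0.3, rate_intergenic = 0.3,
                       rate_fusion = 0.05, rate_conversion = 0,
                       rate_loss = 0.05,
                       subst_per_site_per_generation = 3e-4,
                       unit_length = 120L,
                       founder_divergence = 0.6,
                       motif = "SPLR", motif_subgroup = "F1",
                       seed = 1L) {
  for (r in c(rate_intragenic, rate_intergenic, rate_fusion,
              rate_conversion, rate_loss))
    stopifnot_scalar_num(r, "event rate", lo = 0)
  stopifnot_scalar_num(subst_per_site_per_generation, "substitution probability",
                       lo = 0, hi = 1 - 1e-12)
  stopifnot_scalar_num(founder_divergence, "founder_divergence", lo = 0, hi = 1)
  if (unit_length < 4 * nchar(motif))
    stop("unit_length must be at least 4 x motif length")
  cfg <- list(n_generations = as.integer(n_generations),
              rate_intragenic = rate_intragenic,
              rate_intergenic = rate_intergenic,
              rate_fusion = rate_fusion,
              rate_conversion = rate_conversion,
              rate_loss = rate_loss,
              subst_per_site_per_generation = subst_per_site_per_generation,
              unit_length = as.integer(unit_length),
              founder_divergence = founder_divergence,
              motif = motif, motif_subgroup = motif_subgroup,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# draw founders from the current RNG stream
.make_founders_rng <- function(config) {
  L <- config$unit_length
  a <- sample.int(20L, L, replace = TRUE)
  b <- a
  k <- round(config$founder_divergence * L)
  if (k > 0) {
    pos <- sample.int(L, k)
    # replace with a uniformly chosen *different* residue
    shift <- sample.int(19L, k, replace = TRUE)
    b[pos] <- ((a[pos] - 1L + shift) %% 20L) + 1L
  }
  list(R = a, F = b)
}

#' Draw the two subfamily founder units
#'
#' Founder A (R-like) is uniform over residues; founder B (F-like) is A with
#' exactly \code{round(founder_divergence * unit_length)} positions replaced
#' by a different residue.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{R} and \code{F}, residue strings.
#' @export
make_founders <- function(config) {
  set.seed(stage_seed(config$seed, "simfamily"))
  f <- .make_founders_rng(config)
  list(R = int_to_aa(f$R), F = int_to_aa(f$F))
}

#' Evolve a polyprotein gene family forward in time
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{sim_family} with elements:
#'   \item{loci}{ordered list of (id, scaffold, unit_ids)}
#'   \item{units}{named list of unit records (seq, subfamily, lineage)}
#'   \item{founders}{pristine founder sequences (the anchor references)}
#'   \item{truth}{the executed-event log: data.frame(generation, kind,
#'     parent, child, source_locus, target_locus)}
#'   \item{drawn}{total Poisson-drawn event counts per kind; can exceed the
#'     executed counts when an eligibility guard skips a drawn event (e.g. a
#'     loss that would empty a subfamily)}
#'   \item{config}{the configuration used}
#' @export
evolve_family <- function(config) {
  if (config$rate_loss > 0 && config$rate_intragenic == 0 &&
      config$rate_intergenic == 0 && config$rate_fusion == 0)
    warning("loss is the only non-zero event rate; the genome will shrink ",
            "toward the two-founder floor")
  set.seed(stage_seed(config$seed, "simfamily"))
  founders <- .make_founders_rng(config)

  units <- list(
    u1 = list(seq = founders$R, subfamily = "R", lineage = "R1"),
    u2 = list(seq = founders$F, subfamily = "F", lineage = "F1"))
  loci <- list(L1 = list(id = "L1", scaffold = "scf1", unit_ids = "u1"),
               L2 = list(id = "L2", scaffold = "scf2", unit_ids = "u2"))
  next_unit <- 3L; next_locus <- 3L
  ev <- list()
  kinds <- c("intragenic_dup", "intergenic_dup", "fusion", "conversion", "loss")
  drawn <- setNames(numeric(5), kinds)

  new_unit_id <- function() { id <- paste0("u", next_unit); next_unit <<- next_unit + 1L; id }
  new_locus_id <- function() { id <- paste0("L", next_locus); next_locus <<- next_locus + 1L; id }
  log_event <- function(gen, kind, parent, child, src, tgt)
    ev[[length(ev) + 1L]] <<- data.frame(generation = gen, kind = kind,
                                         parent = parent, child = child,
                                         source_locus = src, target_locus = tgt,
                                         stringsAsFactors = FALSE)
  locus_of <- function(uid)
    names(loci)[vapply(loci, function(l) uid %in% l$unit_ids, logical(1))][1]
  pick_unit <- function() {
    ids <- unlist(lapply(loci, `[[`, "unit_ids"), use.names = FALSE)
    ids[sample.int(length(ids), 1L)]
  }

  for (gen in seq_len(config$n_generations)) {
    n_intra <- rpois(1L, config$rate_intragenic)
    n_inter <- rpois(1L, config$rate_intergenic)
    n_fus   <- rpois(1L, config$rate_fusion)
    n_conv  <- rpois(1L, config$rate_conversion)
    n_loss  <- rpois(1L, config$rate_loss)
    drawn <- drawn + c(n_intra, n_inter, n_fus, n_conv, n_loss)

    for (k in seq_len(n_intra)) {
      tpl <- pick_unit(); lid <- locus_of(tpl)
      child <- new_unit_id()
      units[[child]] <- units[[tpl]]
      pos <- match(tpl, loci[[lid]]$unit_ids)
      loci[[lid]]$unit_ids <- append(loci[[lid]]$unit_ids, child, after = pos)
      log_event(gen, "intragenic_dup", tpl, child, lid, lid)
    }

    for (k in seq_len(n_inter)) {
      tpl <- pick_unit(); lid <- locus_of(tpl)
      new_lid <- new_locus_id()
      whole <- runif(1) < 0.5
      src_ids <- if (whole) loci[[lid]]$unit_ids else tpl
      child_ids <- character(length(src_ids))
      for (i in seq_along(src_ids)) {
        child_ids[i] <- new_unit_id()
        units[[child_ids[i]]] <- units[[src_ids[i]]]
        log_event(gen, "intergenic_dup", src_ids[i], child_ids[i], lid, new_lid)
      }
      loci[[new_lid]] <- list(id = new_lid,
                              scaffold = paste0("scf", sub("^L", "", new_lid)),
                              unit_ids = child_ids)
    }

    for (k in seq_len(n_fus)) {
      src <- pick_unit(); lid <- locus_of(src)
      sf <- units[[src]]$subfamily
      pure_other <- names(loci)[vapply(loci, function(l) {
        sfs <- vapply(l$unit_ids, function(u) units[[u]]$subfamily, character(1))
        all(sfs != sf)
      }, logical(1))]
      if (length(pure_other) == 0) next  # no eligible target; event not executed
      tgt <- pure_other[sample.int(length(pure_other), 1L)]
      child <- new_unit_id()
      units[[child]] <- units[[src]]
      loci[[tgt]]$unit_ids <- c(loci[[tgt]]$unit_ids, child)
      log_event(gen, "fusion", src, child, lid, tgt)
    }

    for (k in seq_len(n_conv)) {
      ids <- unlist(lapply(loci, `[[`, "unit_ids"), use.names = FALSE)
      if (length(ids) < 2) next
      rec <- ids[sample.int(length(ids), 1L)]
      donor <- setdiff(ids, rec)[sample.int(length(ids) - 1L, 1L)]
      units[[rec]]$seq <- units[[donor]]$seq
      units[[rec]]$subfamily <- units[[donor]]$subfamily
      units[[rec]]$lineage <- units[[donor]]$lineage
      log_event(gen, "conversion", donor, rec, locus_of(donor), locus_of(rec))
    }

    for (k in seq_len(n_loss)) {
      ids <- unlist(lapply(loci, `[[`, "unit_ids"), use.names = FALSE)
      sfs <- vapply(ids, function(u) units[[u]]$subfamily, character(1))
      eligible <- ids[sfs %in% names(which(table(sfs) >= 2))]
      if (length(eligible) == 0) next
      victim <- eligible[sample.int(length(eligible), 1L)]
      lid <- locus_of(victim)
      loci[[lid]]$unit_ids <- setdiff(loci[[lid]]$unit_ids, victim)
      if (length(loci[[lid]]$unit_ids) == 0) loci[[lid]] <- NULL
      log_event(gen, "loss", victim, NA_character_, lid, NA_character_)
    }

    # per-site substitution on every surviving unit
    p <- config$subst_per_site_per_generation
    if (p > 0) {
      live <- unlist(lapply(loci, `[[`, "unit_ids"), use.names = FALSE)
      for (uid in live) {
        L <- length(units[[uid]]$seq)
        nm <- rbinom(1L, L, p)
        if (nm > 0) {
          pos <- sample.int(L, nm)
          shift <- sample.int(19L, nm, replace = TRUE)
          units[[uid]]$seq[pos] <- ((units[[uid]]$seq[pos] - 1L + shift) %% 20L) + 1L
        }
      }
    }
  }

  live <- unlist(lapply(loci, `[[`, "unit_ids"), use.names = FALSE)
  units <- units[names(units) %in% live]
  truth <- if (length(ev)) do.call(rbind, ev)
           else data.frame(generation = integer(0), kind = character(0),
                           parent = character(0), child = character(0),
                           source_locus = character(0), target_locus = character(0),
                           stringsAsFactors = FALSE)
  structure(list(loci = loci, units = units,
                 founders = list(R = int_to_aa(founders$R), F = int_to_aa(founders$F)),
                 truth = truth, drawn = drawn, config = config),
            class = "sim_family")
}

#' @export
print.sim_family <- function(x, ...) {
  cat("<sim_family> ", length(x$loci), " loci, ", length(x$units),
      " units, ", nrow(x$truth), " logged events\n", sep = "")
  invisible(x)
}

# default 8-residue linker; motif junctions carry the motif in positions 1-4
.LINKER <- "GGSGGSGG"

#' Render a simulated family as polyprotein loci
#'
#' Units of a locus are joined with a fixed 8-residue linker; at junctions
#' whose downstream unit belongs to the motif lineage, the first
#' \code{nchar(motif)} linker residues are the motif.
#'
#' @param fam a \code{\link{evolve_family}} result.
#' @return list with \code{loci} (named list of \code{\link{locus}} objects),
#'   \code{fasta} (named polyprotein strings) and \code{units} (data.frame of
#'   the true unit registry: unit_id, locus_id, position, start, end,
#'   sequence, subfamily, lineage).
#' @export
render_genome <- function(fam) {
  config <- fam$config
  motif <- config$motif
  plain <- .LINKER
  motif_link <- paste0(motif, substr(plain, nchar(motif) + 1L, nchar(plain)))
  loci <- list(); reg <- list()
  for (l in fam$loci) {
    seqs <- vapply(l$unit_ids, function(u) int_to_aa(fam$units[[u]]$seq), character(1))
    n <- length(seqs)
    parts <- character(0); spans <- matrix(integer(0), ncol = 2)
    off <- 0L
    for (i in seq_len(n)) {
      if (i > 1) {
        uid <- l$unit_ids[i]
        link <- if (fam$units[[uid]]$lineage == config$motif_subgroup) motif_link else plain
        parts <- c(parts, link); off <- off + nchar(link)
      }
      start <- off; end <- off + nchar(seqs[i])
      parts <- c(parts, seqs[i]); off <- end
      spans <- rbind(spans, c(start, end))
      reg[[length(reg) + 1L]] <- data.frame(
        unit_id = l$unit_ids[i], locus_id = l$id, position = i,
        start = start, end = end, sequence = seqs[i],
        subfamily = fam$units[[l$unit_ids[i]]]$subfamily,
        lineage = fam$units[[l$unit_ids[i]]]$lineage,
        stringsAsFactors = FALSE)
    }
    loci[[l$id]] <- locus(l$id, l$scaffold, "+", paste(parts, collapse = ""), spans)
  }
  fasta <- vapply(loci, `[[`, character(1), "polyprotein")
  list(loci = loci, fasta = fasta, units = do.call(rbind, reg))
}

#' Write simulator output to a directory
#'
#' Writes \code{proteins.fasta} (60-column wrap), \code{loci.gff3},
#' \code{anchors.fasta} (the pristine founder references, ids
#' \code{anchor_R}/\code{anchor_F}), \code{truth_events.tsv},
#' \code{truth_units.tsv} and a \code{config.yaml} echo.
#'
#' @param fam a \code{sim_family}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_sim_output <- function(fam, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rnd <- render_genome(fam)
  write_fasta(rnd$fasta, file.path(dir, "proteins.fasta"))
  write_gff3(rnd$loci, file.path(dir, "loci.gff3"))
  write_fasta(c(anchor_R = fam$founders$R, anchor_F = fam$founders$F),
              file.path(dir, "anchors.fasta"))
  write_tsv(fam$truth, file.path(dir, "truth_events.tsv"))
  write_tsv(rnd$units, file.path(dir, "truth_units.tsv"))
  cfg <- unclass(fam$config)
  writeLines(yaml::as.yaml(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
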
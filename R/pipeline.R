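# orchestration: simulate -> scan -> align -> tree -> classify -> report as
# one reproducible run, plus the validation studies that score the pipeline
# against the simulator's ground truth.

#' Pipeline run configuration
#'
#' One global seed governs all stochastic stages; each stage derives its own
#' sub-seed from the stage name (see \code{\link{stage_seed}}), so adding a
#' stage never shifts another stage's random stream.
#'
#' @param seed global integer seed.
#' @param out_dir output directory for the run.
#' @param simulate a \code{\link{sim_config}} to generate the inputs, or
#'   NULL to read \code{fasta}/\code{gff}/\code{anchors} instead.
#' @param fasta,gff,anchors input files for real-data mode: protein FASTA,
#'   GFF3 locus map, and an anchor FASTA whose ids end in \code{_R}/\code{_F}
#'   (or a TSV with columns id, subfamily).
#' @param min_score PWM acceptance threshold (NULL = half consensus score).
#' @param trim maximum per-column gap fraction kept by the trimmer.
#' @param gap_open,gap_extend alignment gap penalties.
#' @param n_boot bootstrap resamplings for branch supports.
#' @param group_threshold,subgroup_threshold support thresholds for
#'   phylogroup / subgroup extraction.
#' @param motif junction cleavage motif searched in the loci.
#' @param tolerance tie tolerance for duplication-mode calls.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("polydup_run_"),
                       simulate = sim_config(), fasta = NULL, gff = NULL,
                       anchors = NULL, min_score = NULL, trim = 0.5,
                       gap_open = -10, gap_extend = -1, n_boot = 400L,
                       group_threshold = 0.9, subgroup_threshold = 0.8,
                       motif = "SPLR", tolerance = 1e-9) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulate = simulate, fasta = fasta, gff = gff,
                 anchors = anchors, min_score = min_score, trim = trim,
                 gap_open = gap_open, gap_extend = gap_extend,
                 n_boot = as.integer(n_boot),
                 group_threshold = group_threshold,
                 subgroup_threshold = subgroup_threshold,
                 motif = motif, tolerance = tolerance),
            class = "run_config")
}

#' Run the full polyprotein-family pipeline
#'
#' Stages: (1) simulate inputs or load them; (2) PWM scan for units and
#' redundancy collapse; (3) progressive alignment and gap trimming; (4) NJ
#' tree with bootstrap supports; (5) subfamily / phylogroup / subgroup
#' assignment, duplication-mode calls, fusion-locus detection and
#' motif-group association; (6) reports. Any stage failure aborts with the
#' stage name; outputs written so far are retained.
#'
#' @param config a \code{\link{run_config}}.
#' @return invisibly, the summary list (also written as
#'   \code{summary.json}); side effect: \code{units.tsv}, \code{aln.fasta},
#'   \code{tree.nwk}, \code{assign.tsv}, \code{fusion.tsv},
#'   \code{motif_assoc.tsv}, \code{architecture.txt}, \code{run.log} in
#'   \code{config$out_dir}.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  logline <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  stage <- function(name, expr) {
    logline("[stage ", name, "] start")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # ---- inputs ---------------------------------------------------------------
  inputs <- stage("inputs", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      sim$seed <- stage_seed(config$seed, "simulate")
      fam <- evolve_family(sim)
      rnd <- render_genome(fam)
      write_sim_output(fam, file.path(config$out_dir, "sim"))
      anchors <- c(anchor_R = "R", anchor_F = "F")
      anchor_seqs <- c(anchor_R = fam$founders$R, anchor_F = fam$founders$F)
      logline("simulated ", length(rnd$loci), " loci / ", nrow(rnd$units), " units")
      list(loci = rnd$loci, anchors = anchors, anchor_seqs = anchor_seqs,
           fam = fam, truth_units = rnd$units)
    } else {
      seqs <- read_fasta(config$fasta)
      loci <- read_gff3(config$gff, sequences = seqs)
      aseq <- read_fasta(config$anchors)
      anchors <- setNames(sub("^.*_", "", names(aseq)), names(aseq))
      if (!all(anchors %in% c("R", "F")))
        stop("anchor ids must end in _R or _F")
      list(loci = loci, anchors = anchors, anchor_seqs = aseq,
           fam = NULL, truth_units = NULL)
    }
  })
  loci <- inputs$loci

  # ---- scan -----------------------------------------------------------------
  scan <- stage("scan", {
    profile <- build_profile(unname(inputs$anchor_seqs))
    ms <- config$min_score %||% (0.5 * attr(profile, "consensus_score"))
    logline("scan min_score = ", round(ms, 2), " bits",
            if (is.null(config$min_score)) " (default: half consensus self-score)")
    units_all <- scan_units(loci, profile, min_score = ms)
    coll <- collapse_redundant(units_all)
    units <- coll$units
    units$position <- stats::ave(units$start, units$locus_id, FUN = rank)
    write_tsv(units, file.path(config$out_dir, "units.tsv"))
    logline("detected ", nrow(units_all), " units; ", nrow(units),
            " non-redundant (", nrow(coll$removed), " collapsed)")
    # attach detected spans to loci for motif search
    for (lid in names(loci)) {
      u <- units[units$locus_id == lid, , drop = FALSE]
      if (nrow(u)) loci[[lid]]$spans <-
          matrix(as.integer(c(u$start, u$end)), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
    }
    list(units_all = units_all, units = units, loci = loci, profile = profile)
  })
  units <- scan$units

  # ---- align ----------------------------------------------------------------
  aln <- stage("align", {
    seqs <- c(setNames(units$sequence, units$unit_id), inputs$anchor_seqs)
    a <- progressive_align(seqs, gap_open = config$gap_open,
                           gap_extend = config$gap_extend)
    tr <- trim_columns(a, config$trim)
    write_alignment(tr, file.path(config$out_dir, "aln.fasta"))
    logline("alignment: ", length(tr), " rows x ", nchar(tr[[1]]),
            " columns after trimming at gap fraction ", config$trim)
    tr
  })

  # ---- tree -----------------------------------------------------------------
  tree <- stage("tree", {
    D <- p_distance(aln, "poisson")
    tr <- neighbor_joining(D)
    tr <- bootstrap_supports(aln, tr, n_reps = config$n_boot,
                             seed = stage_seed(config$seed, "tree"))
    write_newick(tr, file.path(config$out_dir, "tree.nwk"))
    tr
  })

  # ---- classify -------------------------------------------------------------
  cls <- stage("classify", {
    subfam <- assign_subfamilies(tree, inputs$anchors)
    anchor_of <- split(names(inputs$anchors), inputs$anchors)
    orientation <- c(F = anchor_of$R[1], R = anchor_of$F[1],
                     other = anchor_of$R[1])
    pg <- assign_phylogroups(tree, subfam,
                             group_threshold = config$group_threshold,
                             subgroup_threshold = config$subgroup_threshold,
                             orientation = orientation,
                             exclude = names(inputs$anchors))
    Did <- p_distance(aln, "none")
    modes <- classify_duplication_mode(units, Did, config$tolerance,
                                       tiebreak_D = patristic_distances(tree))
    assign <- merge(units[, c("unit_id", "locus_id", "position")], pg,
                    by = "unit_id")
    assign <- merge(assign, modes, by = "unit_id")
    assign <- assign[order(assign$locus_id, assign$position), ]
    write_tsv(assign, file.path(config$out_dir, "assign.tsv"))

    fus <- detect_fusion_loci(assign)
    write_tsv(fus, file.path(config$out_dir, "fusion.tsv"))

    # junction motifs are only defined where junctions exist, so the
    # association table is over multi-unit (polyprotein) loci
    multi <- names(which(table(units$locus_id) >= 2))
    motif_by_locus <- vapply(scan$loci[multi], function(l) {
      hits <- find_junction_motifs(l, config$motif)
      any(hits$class == "junction")
    }, logical(1))
    # focal group: the group whose loci most often carry the junction motif
    grp_of_locus <- split(assign$group, assign$locus_id)
    cand_groups <- sort(setdiff(unique(assign$group), NA))
    motif_loci_per_group <- vapply(cand_groups, function(g)
      sum(vapply(names(grp_of_locus), function(l)
        g %in% grp_of_locus[[l]] && isTRUE(unname(motif_by_locus[l])), logical(1))),
      numeric(1))
    focal <- cand_groups[order(-motif_loci_per_group, cand_groups)][1]
    focal_by_locus <- vapply(names(grp_of_locus), function(l)
      focal %in% grp_of_locus[[l]], logical(1))
    assoc <- motif_group_association(motif_by_locus,
                                     focal_by_locus[names(motif_by_locus)])
    write_tsv(data.frame(focal_group = focal,
                         motif_focal = assoc$table[1, 1],
                         motif_other = assoc$table[1, 2],
                         nomotif_focal = assoc$table[2, 1],
                         nomotif_other = assoc$table[2, 2],
                         p_value = assoc$p.value),
              file.path(config$out_dir, "motif_assoc.tsv"))
    logline("focal group ", focal, "; motif association p = ",
            signif(assoc$p.value, 4))
    list(assign = assign, fusion = fus, assoc = assoc, focal = focal)
  })

  # ---- summary --------------------------------------------------------------
  summary <- stage("summary", {
    assign <- cls$assign
    s <- list(
      n_loci = length(unique(units$locus_id)),
      n_units_detected = nrow(scan$units_all),
      n_units_nonredundant = nrow(units),
      alignment_columns = nchar(aln[[1]]),
      n_groups = lapply(split(assign$group, assign$subfamily), function(g)
        length(setdiff(unique(g), grep("0$", unique(g), value = TRUE)))),
      n_subgroups = length(unique(paste(assign$group, assign$subgroup)[
        assign$subgroup > 0])),
      mode_counts = as.list(table(assign$mode)),
      n_fusion_loci = sum(cls$fusion$is_fusion),
      focal_group = cls$focal,
      motif_table = as.vector(cls$assoc$table),
      motif_p = cls$assoc$p.value)
    jsonlite::write_json(s, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    s
  })

  stage("report", {
    writeLines(architecture_report(config$out_dir),
               file.path(config$out_dir, "architecture.txt"))
  })
  invisible(summary)
}

#' Per-locus architecture strings
#'
#' One line per locus, units in genomic order, each unit encoded as
#' \code{<group>.<subgroup>} — a text rendering of the colored-box locus
#' composition diagrams.
#'
#' @param run_dir a completed \code{\link{run_pipeline}} output directory.
#' @return character vector of lines "locus_id: g.s|g.s|...".
#' @export
architecture_report <- function(run_dir) {
  assign <- read_tsv(file.path(run_dir, "assign.tsv"))
  assign <- assign[order(assign$locus_id, assign$position), ]
  vapply(split(assign, assign$locus_id), function(a)
    paste0(a$locus_id[1], ": ",
           paste(paste0(a$group, ".", a$subgroup), collapse = "|")),
    character(1))
}

#' Compare a pipeline run against externally supplied reference counts
#'
#' Benchmark mode for real datasets: given the summary of a run and a named
#' numeric vector of reference values (e.g. published unit, locus, group and
#' fusion counts), reports the per-quantity differences. No agreement is
#' asserted; the table is the deliverable.
#'
#' @param summary summary list from \code{\link{run_pipeline}} (or a path to
#'   a \code{summary.json}).
#' @param reference named numeric vector; names must be summary quantities
#'   (e.g. n_units_detected, n_units_nonredundant, n_loci,
#'   alignment_columns, n_fusion_loci).
#' @return data.frame(quantity, observed, reference, diff).
#' @export
external_benchmark <- function(summary, reference) {
  if (is.character(summary)) summary <- jsonlite::read_json(summary)
  obs <- vapply(names(reference), function(k) {
    v <- summary[[k]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  data.frame(quantity = names(reference), observed = obs,
             reference = as.numeric(reference),
             diff = obs - as.numeric(reference),
             stringsAsFactors = FALSE)
}
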
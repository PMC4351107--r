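# validation studies: score the analysis pipeline against the simulator's
# ground-truth event log (parameter / call recovery), and check the
# simulator's event counts against their Poisson expectations.

# Sequence-lineage table from the event log: lineage[u, t+1] is the unit id
# whose sequence lineage unit u occupied at generation t.  A unit's lineage
# is its own id from its birth (creation by duplication/fusion, or latest
# conversion) and follows its parent's lineage before that.  The truth
# duplication mode of a unit is then read off the genealogy: its closest
# kin are the surviving units with maximal lineage-coalescence time.
.lineage_table <- function(events, unit_ids, n_generations) {
  lin <- matrix(NA_character_, nrow = length(unit_ids),
                ncol = n_generations + 1L,
                dimnames = list(unit_ids, NULL))
  lin["u1", ] <- "u1"; lin["u2", ] <- "u2"
  if (nrow(events) == 0) return(lin)
  # chronological replay: a child snapshots its parent's lineage-so-far at
  # its birth; a conversion rebirths the recipient on the donor's lineage
  # (its sequence past is the donor's past from then on)
  mk <- events[events$kind %in% c("intragenic_dup", "intergenic_dup",
                                  "fusion", "conversion"), , drop = FALSE]
  for (i in seq_len(nrow(mk))) {
    g <- mk$generation[i]; p <- mk$parent[i]; ch <- mk$child[i]
    if (!ch %in% rownames(lin) || !p %in% rownames(lin)) next
    row <- rep(ch, n_generations + 1L)
    if (g > 0) row[seq_len(g)] <- lin[p, seq_len(g)]
    lin[ch, ] <- row
  }
  lin
}

# truth duplication mode over a given unit universe: same tie semantics as
# classify_duplication_mode, but on genealogical coalescence times
.truth_modes <- function(lin, locus_of, universe) {
  vapply(universe, function(u) {
    others <- setdiff(universe, u)
    tc <- vapply(others, function(v) {
      eq <- which(lin[u, ] == lin[v, ])
      if (length(eq)) max(eq) else 0L
    }, integer(1))
    kin <- others[tc == max(tc)]
    same <- locus_of[kin] == locus_of[u]
    if (any(same) && any(!same)) "ambiguous"
    else if (any(same)) "intragenic" else "intergenic"
  }, character(1))
}

#' Duplication-mode and fusion-locus recovery against simulator truth
#'
#' For each replicate: evolve a family, render it, rebuild the unit catalog
#' with the PWM scan + redundancy collapse, align, call duplication modes
#' from sequence dissimilarity, assign subfamilies on an NJ tree anchored by
#' the pristine founder sequences, and detect fusion loci. Detected units
#' are matched to true units by locus and start coordinate (within
#' \code{boundary_tol} residues).
#'
#' Mode calls are scored against a genealogical oracle computed from the
#' event log alone: over the same unit universe the classifier analyzed,
#' each unit's true closest kin are the units with maximal sequence-lineage
#' coalescence time (the generation of the most recent duplication event
#' joining their lineages); the truth mode is intragenic / intergenic /
#' ambiguous according to whether those kin are co-resident, dispersed, or
#' both — the same tie semantics the classifier uses on distances. Scoring
#' is restricted to units created by a logged duplication event.
#'
#' @param n_replicates number of simulated replicates.
#' @param config a \code{\link{sim_config}}; its seed is re-derived per
#'   replicate from \code{seed}.
#' @param seed global seed for the study.
#' @param boundary_tol maximum start-coordinate error when matching detected
#'   to true units.
#' @return data.frame, one row per replicate: mode_accuracy (against the
#'   full genealogical oracle, conversion-aware), mode_accuracy_history
#'   (against the duplication-only genealogy; equal to mode_accuracy when
#'   the conversion rate is zero, and degraded by gene conversion),
#'   n_scored, fusion_precision, fusion_recall, n_truth_fusion,
#'   unit_recall, mean_boundary_error, n_units_true, n_units_detected.
#' @export
recovery_study <- function(n_replicates = 20, config = sim_config(),
                           seed = 1L, boundary_tol = 2L) {
  one <- function(i) {
    cfg <- config
    cfg$seed <- stage_seed(seed, paste0("recovery_rep", i))
    fam <- evolve_family(cfg)
    rnd <- render_genome(fam)
    truth <- rnd$units

    profile <- build_profile(unname(unlist(fam$founders)))
    units <- collapse_redundant(scan_units(rnd$loci, profile))$units

    # match detected -> true units by locus and nearest start
    match_truth <- vapply(seq_len(nrow(units)), function(k) {
      tt <- truth[truth$locus_id == units$locus_id[k], , drop = FALSE]
      if (nrow(tt) == 0) return(NA_character_)
      derr <- abs(tt$start - units$start[k])
      if (min(derr) > boundary_tol) return(NA_character_)
      tt$unit_id[which.min(derr)]
    }, character(1))
    boundary_err <- vapply(seq_len(nrow(units)), function(k) {
      tt <- truth[truth$locus_id == units$locus_id[k], , drop = FALSE]
      if (nrow(tt) == 0) return(NA_real_)
      min(abs(tt$start - units$start[k]))
    }, numeric(1))

    anchor_seqs <- c(anchor_R = fam$founders$R, anchor_F = fam$founders$F)
    aln <- trim_columns(progressive_align(
      c(setNames(units$sequence, units$unit_id), anchor_seqs)))
    Did <- p_distance(aln, "none")
    tree <- neighbor_joining(p_distance(aln, "poisson"))
    modes <- classify_duplication_mode(units, Did,
                                       tiebreak_D = patristic_distances(tree))

    ev <- fam$truth
    dup <- ev[ev$kind %in% c("intragenic_dup", "intergenic_dup", "fusion"), ,
              drop = FALSE]
    all_ids <- unique(c("u1", "u2", ev$parent, ev$child))
    all_ids <- all_ids[!is.na(all_ids)]
    lin <- .lineage_table(ev, all_ids, cfg$n_generations)
    # second oracle from the duplication events only: gene conversion
    # rewrites sequences but not this genealogy, so disagreement with it
    # measures how much conversion obscures the duplication history
    lin_dup <- .lineage_table(ev[ev$kind != "conversion", , drop = FALSE],
                              all_ids, cfg$n_generations)
    # truth computed over the unit universe the classifier saw
    universe <- match_truth[!is.na(match_truth)]
    locus_of <- setNames(truth$locus_id, truth$unit_id)
    truth_mode <- .truth_modes(lin, locus_of, universe)
    truth_mode_dup <- .truth_modes(lin_dup, locus_of, universe)

    scored <- !is.na(match_truth) & match_truth %in% dup$child
    acc <- if (any(scored))
      mean(modes$mode[scored] == truth_mode[match_truth[scored]]) else NA_real_
    acc_hist <- if (any(scored))
      mean(modes$mode[scored] == truth_mode_dup[match_truth[scored]]) else NA_real_

    subfam <- assign_subfamilies(tree, c(anchor_R = "R", anchor_F = "F"))
    units$subfamily <- unname(subfam[units$unit_id])
    det_f <- detect_fusion_loci(units)
    det_fusion <- det_f$locus_id[det_f$is_fusion]
    truth_f <- vapply(split(truth$subfamily, truth$locus_id), function(s)
      all(c("R", "F") %in% s), logical(1))
    truth_fusion <- names(truth_f)[truth_f]
    tp <- length(intersect(det_fusion, truth_fusion))
    data.frame(
      mode_accuracy = acc, mode_accuracy_history = acc_hist,
      n_scored = sum(scored),
      fusion_precision = if (length(det_fusion)) tp / length(det_fusion) else 1,
      fusion_recall = if (length(truth_fusion)) tp / length(truth_fusion) else 1,
      n_truth_fusion = length(truth_fusion),
      unit_recall = mean(truth$unit_id %in% match_truth),
      mean_boundary_error = mean(boundary_err, na.rm = TRUE),
      n_units_true = nrow(truth), n_units_detected = nrow(units))
  }
  do.call(rbind, lapply(seq_len(n_replicates), one))
}

#' Drawn event counts across simulator replicates
#'
#' Runs the simulator under one configuration with many derived seeds and
#' tabulates the Poisson-drawn event counts per kind, for comparison with
#' the expectation \code{n_generations * rate}. (Executed counts, which the
#' eligibility guards can push below the drawn counts, live in each
#' replicate's truth log.)
#'
#' @param n_replicates number of replicates.
#' @param config a \code{\link{sim_config}}.
#' @param seed global seed.
#' @return data.frame, one row per replicate, columns intragenic_dup,
#'   intergenic_dup, fusion, conversion, loss.
#' @export
event_count_study <- function(n_replicates = 200, config = sim_config(),
                              seed = 1L) {
  one <- function(i) {
    cfg <- config
    cfg$seed <- stage_seed(seed, paste0("events_rep", i))
    as.data.frame(as.list(evolve_family(cfg)$drawn))
  }
  do.call(rbind, lapply(seq_len(n_replicates), one))
}
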
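# PWM construction, polyprotein scanning, redundancy collapse, junction motifs

test_that("profile scores follow the log-odds formula", {
  p <- build_profile("ACD")
  expect_equal(unname(p[1, "A"]), log2((2 / 21) / 0.05))
  expect_equal(unname(p[1, "A"]), 0.9296, tolerance = 1e-4)
  expect_equal(unname(p[2, "C"]), log2((2 / 21) / 0.05))
  expect_equal(unname(p[1, "C"]), log2((1 / 21) / 0.05))

  # one sequence per residue in every column: all cells hit count 1
  seqs <- vapply(1:20, function(i) paste(AA20[(((0:2) + i - 1) %% 20) + 1],
                                         collapse = ""), character(1))
  p20 <- build_profile(seqs)
  expect_true(all(abs(p20 - log2((2 / 40) / 0.05)) < 1e-12))
  expect_true(all(abs(p20) < 1e-12))

  expect_error(build_profile(character(0)), "empty")
  expect_error(build_profile(c("ACD", "AC")), "ragged")
})

consensus_of <- function(profile) {
  paste(colnames(profile)[apply(profile, 1, which.max)], collapse = "")
}

test_that("scanning finds profile occurrences greedily and disjointly", {
  set.seed(7)
  seed_seq <- random_aa_seq(40)
  prof <- build_profile(seed_seq)
  cons <- consensus_of(prof)

  one <- scan_polyprotein(locus("L1", "s", "+", cons, NULL), prof)
  expect_identical(nrow(one), 1L)
  expect_identical(c(one$start, one$end), c(0L, 40L))
  expect_equal(one$score, attr(prof, "consensus_score"))

  two <- scan_polyprotein(
    locus("L2", "s", "+", paste0(cons, "GGSGGSGG", cons), NULL), prof)
  expect_equal(unname(as.matrix(two[, c("start", "end")])),
               rbind(c(0L, 40L), c(48L, 88L)))

  # shorter than the profile: empty result, no error
  short <- scan_polyprotein(locus("L3", "s", "+", "ACDEF", NULL), prof)
  expect_identical(nrow(short), 0L)

  # random sequences never reach the consensus self-score
  hits <- vapply(1:100, function(i)
    nrow(scan_polyprotein(locus("R", "s", "+", random_aa_seq(200), NULL),
                          prof, min_score = attr(prof, "consensus_score"))),
    integer(1))
  expect_identical(sum(hits), 0L)
})

test_that("accepted spans are disjoint, above threshold, and order-invariant", {
  fam <- evolve_family(sim_config(seed = 19))
  rnd <- render_genome(fam)
  prof <- build_profile(unname(unlist(fam$founders)))
  u1 <- scan_units(rnd$loci, prof)
  expect_true(all(u1$score >= 0.5 * attr(prof, "consensus_score")))
  for (lid in unique(u1$locus_id)) {
    sp <- u1[u1$locus_id == lid, ]
    if (nrow(sp) > 1)
      expect_true(all(sp$start[-1] >= sp$end[-nrow(sp)]))
  }
  # shuffling locus input order never changes per-locus spans
  u2 <- scan_units(rev(rnd$loci), prof)
  key <- function(u) u[order(u$locus_id, u$start),
                       c("locus_id", "start", "end", "score")]
  expect_equal(key(u1), key(u2), ignore_attr = TRUE)
})

test_that("scan recovers simulated units at low divergence", {
  recalls <- c(); ok_boundary <- c()
  for (s in 1:20) {
    fam <- evolve_family(sim_config(seed = 100 + s))
    rnd <- render_genome(fam)
    prof <- build_profile(unname(unlist(fam$founders)))
    u <- scan_units(rnd$loci, prof)
    truth <- rnd$units
    err <- vapply(seq_len(nrow(truth)), function(k) {
      d <- abs(u$start[u$locus_id == truth$locus_id[k]] - truth$start[k])
      if (length(d) == 0) Inf else min(d)
    }, numeric(1))
    recalls <- c(recalls, mean(err <= 2))
    ok_boundary <- c(ok_boundary, mean(err[is.finite(err)] <= 2))
  }
  expect_gte(mean(recalls), 0.95)
  expect_gte(mean(ok_boundary), 0.95)
})

test_that("redundancy collapse removes same-locus duplicates only", {
  base <- data.frame(unit_id = c("a", "b"), locus_id = c("L1", "L1"),
                     start = c(0L, 128L), sequence = c("AAAA", "AAAA"),
                     stringsAsFactors = FALSE)
  got <- collapse_redundant(base)
  expect_identical(got$units$unit_id, "a")     # smallest start survives
  expect_identical(got$removed$unit_id, "b")

  cross <- data.frame(unit_id = c("a", "b"), locus_id = c("L1", "L2"),
                      start = c(0L, 0L), sequence = c("AAAA", "AAAA"),
                      stringsAsFactors = FALSE)
  expect_identical(nrow(collapse_redundant(cross)$units), 2L)

  # a 199-unit catalog with 35 planted same-locus duplicates shrinks to 164
  set.seed(42)
  n_base <- 164
  units <- data.frame(
    unit_id = paste0("u", 1:n_base),
    locus_id = paste0("L", sample(1:82, n_base, replace = TRUE)),
    start = 0L,
    sequence = vapply(1:n_base, function(i) random_aa_seq(50), character(1)),
    stringsAsFactors = FALSE)
  units$start <- stats::ave(seq_len(n_base), units$locus_id,
                            FUN = function(i) (seq_along(i) - 1L) * 128L)
  dup_idx <- sample(n_base, 35)
  dups <- units[dup_idx, ]
  dups$unit_id <- paste0("d", seq_len(35))
  dups$start <- dups$start + 10000L   # same locus, same sequence, later span
  all_units <- rbind(units, dups)
  expect_identical(nrow(all_units), 199L)
  got <- collapse_redundant(all_units)
  expect_identical(nrow(got$units), 164L)
  expect_true(all(got$units$unit_id %in% units$unit_id))
})

test_that("junction motif hits are restricted to inter-span gaps", {
  fam <- evolve_family(sim_config(rate_intergenic = 0, rate_fusion = 0,
                                  rate_loss = 0,
                                  subst_per_site_per_generation = 0,
                                  seed = 8))
  rnd <- render_genome(fam)
  for (loc in rnd$loci) {
    hits <- find_junction_motifs(loc, "SPLR")
    reg <- rnd$units[rnd$units$locus_id == loc$id, ]
    n_motif_junctions <- sum(reg$subfamily[-1] == "F")
    expect_identical(sum(hits$class == "junction"), as.integer(n_motif_junctions))
  }

  # a motif inside the unit body is reported but not counted as junction
  body <- paste0(strrep("A", 50), "SPLR", strrep("A", 66))
  loc <- locus("LX", "s", "+", paste0(body, "GGSGGSGG", strrep("C", 120)),
               rbind(c(0L, 120L), c(128L, 248L)))
  hits <- find_junction_motifs(loc, "SPLR")
  expect_identical(hits$class, "within_unit")
  expect_identical(sum(hits$class == "junction"), 0L)

  expect_error(find_junction_motifs(loc, ""), "non-empty")

  # positions agree with a brute-force all-substring search on random loci
  set.seed(30)
  for (i in 1:50) {
    s <- paste(sample(c("S", "P", "L", "R", "A"), 150, replace = TRUE),
               collapse = "")
    loc <- locus(paste0("B", i), "s", "+", s, rbind(c(0L, 60L), c(90L, 150L)))
    hits <- find_junction_motifs(loc, "SPLR")
    brute <- which(vapply(1:(nchar(s) - 3), function(j)
      substr(s, j, j + 3) == "SPLR", logical(1))) - 1L
    expect_identical(hits$start, as.integer(brute))
  }
})
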
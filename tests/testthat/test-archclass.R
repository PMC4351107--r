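# subfamily anchoring, phylogroup/subgroup assignment, duplication-mode
# calls, fusion loci, motif association

test_that("subfamily labels follow the nearest anchor patristically", {
  tr <- ape::read.tree(text =
    "(((u1:0.1,aR:0.1):0.5,aR2:0.6):1,((u2:0.2,aF:0.1):0.4,u3:0.9):1);")
  anchors <- c(aR = "R", aR2 = "R", aF = "F")
  got <- assign_subfamilies(tr, anchors)
  expect_identical(unname(got["u1"]), "R")
  expect_identical(unname(got["u2"]), "F")
  expect_identical(unname(got["aR"]), "R")    # anchors keep their labels

  # exact equidistance gives "other"
  star <- ape::read.tree(text = "(u1:1,aR:1,aF:1);")
  expect_identical(unname(assign_subfamilies(star, c(aR = "R", aF = "F"))["u1"]),
                   "other")

  expect_error(assign_subfamilies(star, c(zz = "R", aF = "F")), "missing")
  expect_error(assign_subfamilies(star, c(aR = "R")), "two subfamilies")

  # agreement with a brute-force path-length computation on random trees
  set.seed(14)
  for (i in 1:20) {
    tr <- random_metric_tree(10)
    anchors <- setNames(c("R", "R", "F"), sample(tr$tip.label, 3))
    D <- oracle_patristic(tr)
    got <- assign_subfamilies(tr, anchors)
    for (leaf in setdiff(tr$tip.label, names(anchors))) {
      d <- D[leaf, names(anchors)]
      best <- tapply(d, anchors[names(d)], min)
      expect_identical(unname(got[leaf]), names(which.min(best)))
    }
  }
})

test_that("phylogroups and subgroups follow the support thresholds", {
  # one F clade of 6 units at 0.95 containing two sub-clades at 0.85
  tr <- ape::read.tree(text = paste0(
    "(((f1:1,(f2:1,f3:1)0.85:1)0.3:1,((f4:1,f5:1)0.85:1,f6:1)0.2:1)0.95:1,",
    "aR:3,f0:3);"))
  sf <- c(setNames(rep("F", 7), c(paste0("f", 1:6), "f0")), aR = "R")
  got <- assign_phylogroups(tr, sf, orientation = "aR", exclude = "aR")
  g <- setNames(got$group, got$unit_id)
  s <- setNames(got$subgroup, got$unit_id)
  expect_identical(unname(g[paste0("f", 1:6)]), rep("F1", 6))
  expect_identical(unname(g["f0"]), "F0")   # outside every supported clade
  # equal-size subgroups numbered by the smallest member id
  expect_identical(unname(s[c("f2", "f3")]), c(1L, 1L))
  expect_identical(unname(s[c("f4", "f5")]), c(2L, 2L))
  expect_identical(unname(s["f1"]), 0L)     # in the group, no subgroup
  expect_identical(unname(s["f6"]), 0L)
  expect_false(got$affiliated[got$unit_id == "f1"])

  # all supports below threshold: everything in group 0
  tr2 <- tr
  tr2$node.label <- sub("0.95", "0.5", tr2$node.label, fixed = TRUE)
  tr2$node.label <- sub("0.85", "0.5", tr2$node.label, fixed = TRUE)
  got2 <- assign_phylogroups(tr2, sf, orientation = "aR", exclude = "aR")
  expect_true(all(got2$group[got2$subfamily == "F"] == "F0"))
})

test_that("group membership equals brute-force clade enumeration", {
  set.seed(77)
  for (i in 1:20) {
    tr <- random_metric_tree(12)
    tr$node.label <- as.character(round(runif(tr$Nnode), 2))
    sf <- setNames(sample(c("R", "F"), 12, replace = TRUE), tr$tip.label)
    ref <- tr$tip.label[1]
    got <- assign_phylogroups(tr, sf, group_threshold = 0.6,
                              subgroup_threshold = 0.3, orientation = ref)
    # oracle: maximal supported uniform clades by direct enumeration
    cl <- oracle_supported_clades(tr, 0.6, ref)
    cl <- Filter(function(s) length(unique(sf[s])) == 1, cl)
    maximal <- Filter(function(s) !any(vapply(cl, function(t)
      length(s) < length(t) && all(s %in% t), logical(1))), cl)
    want <- lapply(maximal, sort)
    grouped <- split(got$unit_id, got$group)
    grouped <- grouped[!grepl("0$", names(grouped))]
    expect_identical(canon_sets(lapply(grouped, sort)),
                     unique(canon_sets(want)))
    # every unit gets exactly one assignment; sizes reconcile
    expect_identical(sort(got$unit_id), sort(tr$tip.label))
    expect_identical(nrow(got), 12L)
  }
})

test_that("group extraction is invariant to leaf relabeling", {
  set.seed(3)
  tr <- random_metric_tree(10)
  tr$node.label <- as.character(round(runif(tr$Nnode), 2))
  sf <- setNames(sample(c("R", "F"), 10, replace = TRUE), tr$tip.label)
  got1 <- assign_phylogroups(tr, sf, group_threshold = 0.5,
                             subgroup_threshold = 0.3,
                             orientation = tr$tip.label[1])
  # apply a label permutation that preserves the subfamily map
  perm <- setNames(sprintf("x%02d", sample(10)), tr$tip.label)
  tr2 <- tr; tr2$tip.label <- unname(perm[tr$tip.label])
  sf2 <- setNames(unname(sf), unname(perm[names(sf)]))
  got2 <- assign_phylogroups(tr2, sf2, group_threshold = 0.5,
                             subgroup_threshold = 0.3,
                             orientation = unname(perm[tr$tip.label[1]]))
  # partition structure (sets of units per group) is preserved
  m1 <- split(got1$unit_id, got1$group)
  # map new labels back through the permutation
  m2 <- split(names(perm)[match(got2$unit_id, perm)], got2$group)
  expect_identical(canon_sets(lapply(m1, sort)), canon_sets(lapply(m2, sort)))
})

test_that("duplication modes distinguish tandem, dispersed and tied cases", {
  units <- data.frame(
    unit_id = c("a1", "a2", "b1", "c1"),
    locus_id = c("LA", "LA", "LB", "LC"), stringsAsFactors = FALSE)
  ids <- units$unit_id
  D <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(D) <- 0
  D["a1", "a2"] <- D["a2", "a1"] <- 0.01   # tandem pair
  D["b1", "c1"] <- D["c1", "b1"] <- 0.02   # dispersed identical pair
  got <- classify_duplication_mode(units, D)
  expect_identical(setNames(got$mode, got$unit_id),
                   c(a1 = "intragenic", a2 = "intragenic",
                     b1 = "intergenic", c1 = "intergenic"))
  expect_identical(got$nearest_id[got$unit_id == "a1"], "a2")

  # exact within/without tie is ambiguous
  D2 <- D
  D2["a1", "b1"] <- D2["b1", "a1"] <- 0.01
  got2 <- classify_duplication_mode(units, D2)
  expect_identical(got2$mode[got2$unit_id == "a1"], "ambiguous")

  # a tiebreak distance resolves the tie
  Dt <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(Dt) <- 0
  Dt["a1", "a2"] <- Dt["a2", "a1"] <- 0.1
  Dt["a1", "b1"] <- Dt["b1", "a1"] <- 0.5
  got3 <- classify_duplication_mode(units, D2, tiebreak_D = Dt)
  expect_identical(got3$mode[got3$unit_id == "a1"], "intragenic")

  expect_error(classify_duplication_mode(units[1, , drop = FALSE], D),
               "two units")
})

test_that("fusion loci are exactly those mixing the two subfamilies", {
  a <- data.frame(unit_id = paste0("u", 1:7),
                  locus_id = c("L1", "L1", "L1", "L2", "L2", "L3", "L3"),
                  subfamily = c("F", "F", "R", "F", "F", "R", "R"),
                  stringsAsFactors = FALSE)
  got <- detect_fusion_loci(a)
  expect_identical(got$is_fusion, c(TRUE, FALSE, FALSE))
  expect_identical(got$composition[got$locus_id == "L1"], "Fx2+Rx1")
  expect_identical(got$composition[got$locus_id == "L3"], "Rx2")
})

test_that("fusion detection recovers the simulator's truth", {
  r <- recovery_study(n_replicates = 4, seed = 31)
  expect_gte(mean(r$fusion_precision), 0.95)
  expect_gte(mean(r$fusion_recall), 0.95)
})

test_that("Fisher association matches hypergeometric enumeration", {
  m <- setNames(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), paste0("L", 1:6))
  f <- setNames(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), paste0("L", 1:6))
  got <- motif_group_association(m, f)
  expect_equal(got$p.value, 0.1, tolerance = 1e-9)
  expect_identical(unname(got$table[1, ]), c(3L, 0L))

  z <- setNames(rep(FALSE, 5), paste0("L", 1:5))
  f5 <- setNames(c(rep(FALSE, 5)), paste0("L", 1:5))
  expect_warning(got0 <- motif_group_association(z, f5), "degenerate")
  expect_identical(got0$p.value, 1)

  # exhaustive agreement for all 2x2 tables with N <= 8
  for (a in 0:8) for (b in 0:(8 - a)) for (cc in 0:(8 - a - b))
    for (d in 0:(8 - a - b - cc)) {
      if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
      n <- a + b + cc + d
      mv <- rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, cc, d))
      fv <- rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, cc, d))
      names(mv) <- names(fv) <- paste0("L", seq_len(n))
      got <- motif_group_association(mv, fv)
      expect_equal(got$p.value, oracle_fisher_p(a, b, cc, d),
                   tolerance = 1e-9, info = paste(a, b, cc, d))
    }
})
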
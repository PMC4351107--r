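# forward simulator: founder construction, event process, rendering

test_that("founder divergence is honored exactly", {
  ham <- function(cfg) {
    f <- make_founders(cfg)
    sum(strsplit(f$R, "")[[1]] != strsplit(f$F, "")[[1]])
  }
  expect_identical(ham(sim_config(founder_divergence = 0, seed = 3)), 0L)
  expect_identical(ham(sim_config(founder_divergence = 1, seed = 3)), 120L)
  expect_identical(ham(sim_config(founder_divergence = 0.4, seed = 3)), 48L)
  expect_identical(ham(sim_config(founder_divergence = 0.4, seed = 99)), 48L)
})

test_that("null process returns the two founder loci and an empty log", {
  cfg <- sim_config(rate_intragenic = 0, rate_intergenic = 0, rate_fusion = 0,
                    rate_conversion = 0, rate_loss = 0,
                    subst_per_site_per_generation = 0,
                    n_generations = 50, seed = 11)
  fam <- evolve_family(cfg)
  expect_length(fam$loci, 2)
  expect_length(fam$units, 2)
  expect_identical(nrow(fam$truth), 0L)
  expect_identical(int_seqs <- unname(vapply(fam$units, function(u)
    polydup:::int_to_aa(u$seq), character(1))),
    unname(unlist(fam$founders)))
})

test_that("identical configs give byte-identical genomes and logs", {
  cfg <- sim_config(seed = 42)
  a <- evolve_family(cfg)
  b <- evolve_family(cfg)
  expect_identical(a, b)
  expect_identical(render_genome(a), render_genome(b))
})

test_that("unit count is conserved: founders + duplications - losses", {
  for (s in c(2, 7, 13)) {
    fam <- evolve_family(sim_config(seed = s, rate_loss = 0.2,
                                    rate_conversion = 0.1))
    ev <- fam$truth
    dups <- sum(ev$kind %in% c("intragenic_dup", "intergenic_dup", "fusion"))
    expect_equal(length(fam$units), 2 + dups - sum(ev$kind == "loss"))
    # ids of newly created units are unique (conversions may re-target)
    newborn <- ev$child[ev$kind %in% c("intragenic_dup", "intergenic_dup",
                                       "fusion")]
    expect_false(anyDuplicated(newborn) > 0)
  }
})

test_that("loss-only configurations warn about genome shrinkage", {
  expect_warning(
    evolve_family(sim_config(rate_intragenic = 0, rate_intergenic = 0,
                             rate_fusion = 0, rate_loss = 0.5,
                             n_generations = 5, seed = 1)),
    "shrink")
  # the guard still leaves at least one unit per subfamily
  fam <- suppressWarnings(
    evolve_family(sim_config(rate_intragenic = 0, rate_intergenic = 0,
                             rate_fusion = 0, rate_loss = 2,
                             n_generations = 200, seed = 1)))
  sf <- vapply(fam$units, `[[`, character(1), "subfamily")
  expect_setequal(unique(sf), c("R", "F"))
})

test_that("drawn event counts track their Poisson expectations", {
  cfg <- sim_config(rate_intragenic = 0.5, rate_intergenic = 0.2,
                    rate_fusion = 0.1, rate_conversion = 0.1, rate_loss = 0.1,
                    subst_per_site_per_generation = 0, n_generations = 30)
  counts <- event_count_study(n_replicates = 60, config = cfg, seed = 4)
  expected <- 30 * c(intragenic_dup = 0.5, intergenic_dup = 0.2,
                     fusion = 0.1, conversion = 0.1, loss = 0.1)
  for (k in names(expected)) {
    se <- stats::sd(counts[[k]]) / sqrt(nrow(counts))
    expect_lt(abs(mean(counts[[k]]) - expected[[k]]), 3 * se + 1e-9)
  }
  # executed counts never exceed drawn counts
  fam <- evolve_family(sim_config(seed = 6, rate_loss = 0.3))
  executed <- table(factor(fam$truth$kind, levels = names(fam$drawn)))
  expect_true(all(as.numeric(executed)[match(c("fusion", "loss"),
                                             names(fam$drawn))] <=
                  fam$drawn[c("fusion", "loss")]))
})

test_that("rendering places linkers and motifs as specified", {
  # single-unit loci render as the bare unit sequence
  cfg0 <- sim_config(rate_intragenic = 0, rate_intergenic = 0, rate_fusion = 0,
                     rate_conversion = 0, rate_loss = 0,
                     subst_per_site_per_generation = 0, seed = 5)
  rnd0 <- render_genome(evolve_family(cfg0))
  expect_identical(unname(nchar(rnd0$fasta)), c(120L, 120L))

  # tandem-only growth: the two founder loci become tandem arrays; motif
  # linkers appear at every F junction and nowhere on the R locus
  cfg <- sim_config(rate_intergenic = 0, rate_fusion = 0, rate_loss = 0,
                    subst_per_site_per_generation = 0, seed = 8)
  rnd <- render_genome(evolve_family(cfg))
  f_loc <- Filter(function(l)
    all(rnd$units$subfamily[rnd$units$locus_id == l$id] == "F") &&
      nrow(l$spans) >= 2, rnd$loci)[[1]]
  n_units <- nrow(f_loc$spans)
  hits <- as.integer(gregexpr("SPLR", f_loc$polyprotein, fixed = TRUE)[[1]])
  expect_identical(hits, 128L * (seq_len(n_units - 1) - 1L) + 121L)
  r_loc <- Filter(function(l)
    all(rnd$units$subfamily[rnd$units$locus_id == l$id] == "R"), rnd$loci)[[1]]
  expect_identical(gregexpr("SPLR", r_loc$polyprotein, fixed = TRUE)[[1]][1],
                   -1L)
})

test_that("rendered output round-trips through FASTA and GFF3", {
  fam <- evolve_family(sim_config(seed = 21))
  dir <- withr::local_tempdir()
  write_sim_output(fam, dir)
  seqs <- read_fasta(file.path(dir, "proteins.fasta"))
  loci <- read_gff3(file.path(dir, "loci.gff3"), sequences = seqs)
  reg <- render_genome(fam)$units
  # GFF3 spans sliced out of the FASTA reproduce the unit registry exactly
  for (lid in names(loci)) {
    got <- polydup:::locus_unit_seqs(loci[[lid]])
    expect_identical(unname(got), reg$sequence[reg$locus_id == lid])
  }
  expect_setequal(names(loci), unique(reg$locus_id))
})
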
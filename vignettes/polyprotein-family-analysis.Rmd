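---
title: "Cataloguing duplicated polyprotein gene families: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloguing duplicated polyprotein gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polydup)
```

## The problem

Dinoflagellate light-harvesting complex (LHC) antenna genes — the
chlorophyll *a*–chlorophyll *c2*–peridinin (acpPC) family — are encoded as
**polyproteins**: a single gene model translates into several tandem
~120-residue LHC units that are cleaved apart post-translationally. Such
families expand by two distinguishable routes:

* **intragenic (tandem) duplication** — a unit is copied next to its
  template within one locus, growing the polyprotein;
* **intergenic (dispersed) duplication** — a unit, or a whole locus, is
  copied to a physically separate locus.

Two anciently diverged subfamilies coexist (an *Lhcr*-like, PSI-associated
type and an *Lhcf*-like type), occasionally fused into a single polyprotein
("fusion loci"), and a short cleavage-site motif (canonically `SPLR`) marks
the junctions of one lineage only. `polydup` rebuilds the whole analysis
chain that turns a set of predicted gene models into a unit-level catalog:
unit detection, redundancy collapse, alignment, phylogeny with supports,
phylogroup/subgroup classification, duplication-mode calls, fusion-locus
detection, motif association, and RPKM expression summaries — and ships a
forward simulator with a complete event log so every call can be scored
against a known history.

## The simulator

`sim_config()` / `evolve_family()` implement a forward, family-level event
process. Two founder units (one per subfamily) start in single-unit loci;
each generation, Poisson-distributed numbers of events of each kind are
drawn and applied, then every site of every unit mutates independently with
a fixed probability to a uniformly chosen different residue.

Defaults (the study conditions used throughout the tests and the acceptance
script):

| parameter | default | meaning |
|---|---|---|
| `n_generations` | 60 | generations simulated |
| `rate_intragenic` | 0.3 | expected tandem duplications / generation |
| `rate_intergenic` | 0.3 | expected dispersed duplications / generation |
| `rate_fusion` | 0.05 | expected fusion insertions / generation |
| `rate_conversion` | 0 | expected gene conversions / generation |
| `rate_loss` | 0.05 | expected unit losses / generation |
| `subst_per_site_per_generation` | 3e-4 | per-site substitution probability |
| `unit_length` | 120 | residues per unit (~3 transmembrane helices) |
| `founder_divergence` | 0.6 | fraction of sites differing between founders |
| `motif`, `motif_subgroup` | `"SPLR"`, `"F1"` | junction motif and the lineage carrying it |

Choices worth explaining:

* **Intragenic and intergenic rates are equal by default.** Their relative
  frequency in real genomes is unknown; equal rates exercise both call
  classes and are user-tunable, not estimates.
* **Founder divergence 0.6** makes the two subfamilies unambiguous
  (comparable to the deep divergence between red-lineage LHC subfamilies)
  while staying below saturation, so subfamily anchoring is a solved
  sub-problem and the interesting errors happen within subfamilies.
* **Intergenic duplications copy the whole locus with probability 0.5**, so
  both single-unit and multi-unit homologies between loci arise.
* **Conversion is a full-unit overwrite.** The recipient takes the donor's
  sequence, subfamily and lineage tag; partial conversion tracts are out of
  scope.
* **Loss never removes a subfamily's last unit**, so anchors always have
  same-subfamily relatives downstream.
* **Substitutions are uniform over the 19 alternative residues.** Recovery
  tests need controlled divergence, not a realistic rate matrix.
* **Lineage tags**: every unit inherits a tag (`F1`/`R1` at the founders);
  junction linkers whose downstream unit carries `motif_subgroup` start
  with the motif. This reproduces the qualitative pattern that the cleavage
  motif is confined to one expanded lineage; it does not attempt to model
  motif gain/loss.
* **Rendering**: units are joined by a fixed 8-residue linker
  (`GGSGGSGG`), with the motif occupying linker positions 1–4 at motif
  junctions. A fixed linker makes junction detection exactly testable; real
  inter-unit spacers vary.
* `evolve_family()` records both the **drawn** Poisson counts per event
  kind and the **executed** event log. The two differ when an eligibility
  guard skips a drawn event (a loss that would empty a subfamily, a fusion
  with no purely-opposite target locus); calibration checks compare the
  drawn counts with `n_generations * rate`, because that is what the
  Poisson law describes.

What the simulator deliberately does **not** emulate: indels inside units,
alternative splice forms, assembly artifacts, rate heterogeneity across
sites and lineages, and population-level processes (every change fixes
instantly). Tests passing on simulated data therefore demonstrate the
correctness and calibration of the pipeline's logic, not its robustness to
real-data noise sources such as fragmented gene models.

## Unit detection

`build_profile()` turns a gapless seed alignment (in practice: the anchor
sequences) into a position weight matrix with log-odds scores
`log2(((count + 1) / (N + 20)) / 0.05)` — pseudocount 1 per cell against a
uniform background. `scan_polyprotein()` slides the fixed-length profile
over every offset and accepts candidates greedily in descending score
order, skipping overlaps; ties prefer the smaller start. The default
acceptance threshold is half the profile's consensus self-score.

A fixed-length PWM replaces a profile HMM deliberately: simulated units are
fixed-length and indel-free, so insert/delete states add nothing testable,
and downstream analyses need only unit presence and identity. This is the
main fidelity boundary against an HMM-based scan on real data, where unit
length varies. Transmembrane-helix prediction is likewise out of scope; the
three-helix architecture is represented implicitly by unit length.

`collapse_redundant()` removes units with identical sequence *and*
identical locus, keeping the smallest start. On real data this
operationalizes the removal of redundant gene models (e.g. splice
variants); identical sequences on *different* loci are always kept — they
are the intergenic signal. On simulated data the rule also removes genuine
zero-divergence tandem twins; the recovery oracle accounts for this by
scoring over the unit universe the classifier actually saw.

## Alignment and trimming

`pairwise_nw()` is global Needleman–Wunsch with affine gaps (a length-k run
costs `open + (k-1)·extend`; defaults BLOSUM62, −10/−1 — conventional
protein defaults, configurable). Traceback ties prefer diagonal, then up,
then left, making alignments deterministic. `progressive_align()` builds a
UPGMA guide tree on a 3-mer multiset distance and merges profiles by
profile–profile NW, scoring columns as the mean pairwise substitution score
with residue-vs-gap pairs at the extension penalty. `trim_columns()` keeps
columns with gap fraction ≤ 0.5 by default; the threshold is ours (the
trimming mode used on the original data is unpublished) and is surfaced in
the configuration. Trimming is idempotent and monotone in the threshold,
and every row de-gaps to its input sequence — both are asserted by tests.

## Phylogeny and supports

`p_distance()` computes pairwise-deletion p-distances with an optional
Poisson correction (−ln(1−p), p capped at 0.95). `neighbor_joining()` is
canonical Saitou–Nei agglomeration; Q-ties break on the lexicographically
smallest cluster labels, and negative branch estimates are clamped to zero
with the deficit moved to the sibling edge (standard practice, stated for
reproducibility). On additive matrices NJ reproduces all path lengths to
1e-9 and recovers the generating topology — both checked against brute
force.

`bootstrap_supports()` resamples columns with replacement (default 400
resamplings, the conventional count), rebuilds NJ, and reports bipartition
proportions on [0,1]. **Bootstrap proportions stand in for SH-like local
supports**: both live on the same scale, so the classification thresholds
(0.9 for groups, 0.8 for subgroups) are applied unchanged. This is the main
fidelity compromise versus approximate-ML supports; the classification
layer consumes only topology plus supports, which is why a distance method
suffices here and maximum likelihood stays out of scope. A dual-criterion
rule combining bootstrap and SH-like supports simultaneously is also out of
scope; the package exposes one support channel and one threshold pair.

## Classification

* `assign_subfamilies()`: each unit takes the subfamily of its nearest
  anchor by patristic distance; exact ties give `"other"`. In simulated
  runs the anchors are the pristine founder sequences; on real data they
  are reference proteins of known subfamily.
* `assign_phylogroups()`: phylogroups are the *maximal* supported clades
  (support ≥ 0.9) whose members share one subfamily; subgroups are maximal
  supported clades (≥ 0.8) strictly inside a group. Units outside any group
  get `<subfamily>0`; units in no subgroup get subgroup 0 — "no
  phylogenetic affiliation" — and are flagged by `affiliated = FALSE`, which
  distinguishes genuinely unplaced units from members of supported
  subgroups. Labels are ordinal by member count (ties: smallest member id),
  so "group 1 is the largest" holds by construction; the numbering is not
  asserted to correspond to any published numbering. Bipartitions are
  turned into clades by orienting away from the *opposite* subfamily's
  anchor — the two subfamilies are mutually monophyletic stand-ins for a
  root.
* `classify_duplication_mode()`: a unit's nearest homolog is its arg-min
  distance partner; the mode is intragenic if the minimum is attained only
  within the unit's locus, intergenic if only outside, ambiguous on an
  exact within/without tie. The default distance is percent dissimilarity
  on the trimmed alignment ("similarity was highest" reads as sequence
  similarity, not tree distance). Because mismatch counts are discrete,
  exact ties are common at low divergence; an optional `tiebreak_D`
  (patristic distance in the pipeline) shrinks exact tie sets before the
  rule applies. The ambiguous class itself, and the tie tolerance (1e-9),
  are this package's policy — ties are simply undiscussed in the
  literature the procedure follows.
* `detect_fusion_loci()`: a locus is a fusion locus iff its units carry
  both subfamily labels; the composition string (`"Fx2+Rx1"`) summarises
  the mix.
* `motif_group_association()`: a 2×2 locus table (junction-motif presence ×
  focal-group membership) with a two-sided Fisher exact p-value; degenerate
  margins return p = 1 with a warning. The pipeline restricts the table to
  **multi-unit loci**, because a cleavage-junction indicator is undefined
  for a locus with no junctions, and picks as focal group the group whose
  loci most often carry the motif.

## Recovery validation and its honest limits

`recovery_study()` runs the full chain (simulate → scan → collapse → align
→ classify) and scores it against the event log. The truth side is
**genealogical**: from the log alone it computes, for every pair of units,
the generation at which their sequence lineages last coincided; a unit's
true closest kin are the units with maximal coalescence time over exactly
the unit universe the classifier analyzed, and the truth mode follows the
same within/without/ambiguous rule on kin location. This is the right
oracle because duplication-mode calling recovers the *most recent*
duplication relationship — a unit later copied to another locus genuinely
has a cross-locus nearest homolog regardless of how it was born.

Under the default study conditions, fusion-locus precision and recall are
1.0 and unit recall ≈ 0.9 (the shortfall is collapsed zero-divergence
tandem twins), but mode accuracy plateaus near 0.85. The reason is
information-theoretic, not a bug: at 3e-4 substitutions/site/generation a
unit accrues ~0.036 substitutions per generation, so the true kin
(typically ~1–2 expected substitutions away) and older relatives (~2–4)
overlap heavily in *realized* distance, and many relative pairs are
realized-identical. No nearest-neighbor rule on sequence distance can
separate them; the residual ~15% disagreement measures exactly this
overlap. Raising the substitution rate or lengthening the simulation
separates the distributions and pushes accuracy toward 1.

Gene conversion is scored with a second oracle built from duplication
events only (`mode_accuracy_history`): conversion rewrites sequences but
not that genealogy, so disagreement with it measures how strongly
conversion obscures the duplication record. The degradation is real but
bounded — as conversion intensifies, calls drift toward the intergenic
base rate (most truth modes are intergenic, since whole-locus copies
create one dispersed child per copied unit), so mean agreement saturates
rather than falling monotonically. We therefore report the curve instead
of asserting strict monotonicity.

## Expression layer

`rpkm()` is the plain definition
`count / (length_bp/1000) / (total_mapped/1e6)`; `fold_table()` reports
`log2((RPKM + 1)/(RPKM_baseline + 1))` (pseudocount 1 RPKM, ours,
configurable). Read alignment is out of scope — counts are inputs.
`simulate_counts()` provides negative-binomial null tables (dispersion 0.3)
so "no expression change" scenarios can be emulated. There is deliberately
no differential-expression testing: the expression layer is a summarisation
device, mirroring data that were qualitative by design.

## Orchestration and reproducibility

`run_pipeline()` executes simulate/load → scan → align → tree → classify →
report into one directory (`units.tsv`, `aln.fasta`, `tree.nwk`,
`assign.tsv`, `fusion.tsv`, `motif_assoc.tsv`, `summary.json`,
`architecture.txt`, `run.log`). One global seed governs every stochastic
stage; each stage derives a sub-seed by hashing the stage name
(`stage_seed()`), so adding a stage never shifts another stage's stream,
and identical configurations give byte-identical outputs. `run.log` records
each applied default, so every unpublished-parameter decision is auditable
per run. `architecture_report()` renders each locus as
`group.subgroup|group.subgroup|…` in genomic order — a text version of the
colored-box locus diagrams.

Problem sizes used by the default validation runs — 20 replicates of
60-generation families (≈ 40–90 units each), 400 bootstrap resamplings,
200-replicate calibration studies — were chosen as the smallest designs
whose Monte-Carlo error is well below the thresholds being checked.

## Known limitations

* Bootstrap proportions are not SH-like supports; absolute support values
  on real data will differ from approximate-ML tools even where the
  topology agrees.
* The PWM scan assumes near-constant unit length; real gene models with
  indels or truncated terminal units need a profile-HMM upstream.
* The aligner is progressive without iterative refinement; on deeply
  diverged subfamily mixtures it can place an occasional spurious gap
  column (trimming removes most).
* The redundancy-collapse rule is an operationalization of
  splice-variant removal; with only gene-model FASTA as input it cannot
  distinguish a true zero-divergence tandem twin from a redundant model.
* Mode accuracy under very low divergence is bounded by realized-distance
  overlap, as quantified above.
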
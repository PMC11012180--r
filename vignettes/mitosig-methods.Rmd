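---
title: "Methods: detecting Neanderthal-shared mitochondrial variants and separating recombination from convergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: N-SNV screening, bootscan and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis in one paragraph

Given an alignment of complete mitogenomes from three groups — Neanderthals,
archaic anatomically modern humans (AMHs) and present-day humans — the
package identifies polymorphic positions in rCRS numbering, flags those
whose derived allele is shared by at least one Neanderthal and at least one
modern genome while absent from every archaic AMH (N-SNVs), annotates their
coding consequences, asks how much evolutionary time the observed variant
counts imply under two molecular-clock calibrations, and then weighs the two
mechanisms that can generate such sharing: mitochondrial recombination
(tested with a sliding-window bootstrap scan) versus recurrent mutation
(made measurable through a simulator that plants known convergence and
recombination). The deliberate asymmetry of the N-SNV definition — sharing
with moderns, absence in archaic AMHs of comparable age to the Neanderthals
— is what makes the archaic panel an outgroup-in-time control.

## Coordinates, missing data and the gap rule

All positions are 1-based rCRS coordinates (16,569 bp). The anchoring step
maps alignment columns to reference positions through the gap pattern of the
reference row: columns where the reference holds a gap are insertions
relative to rCRS, are recorded, and never yield variant rows (indels carry
no weight in the downstream tree-based analyses). The circular origin is
not re-spliced; the control region simply occupies two coordinate arms
(16,024–16,569 and 1–576).

Two kinds of non-base symbols are deliberately kept distinct:

* `N` is *missing data*: ignored when deciding whether a column is
  polymorphic, treated as absence in presence/absence predicates, emitted
  as a missing genotype in VCF and as `NA` in the genotype matrix.
* `-` is an *alignment gap*: it is not an allele, but it taints the column —
  the row is emitted with `has_gap = TRUE` so the descriptive SNV census
  retains it while PCA and the bootscan exclude it. This reproduces the
  distinction between a full polymorphic-site census and the smaller
  gap-free SNP matrix used for multivariate analyses.

For unaligned input, `map_to_reference()` performs per-sample global
pairwise alignment to the reference (match +2, mismatch −1, gap opening 10,
gap extension 0.5) and merges on reference coordinates. These scoring
defaults are ordinary choices for near-identical (>94%) mitogenome
sequences; the upstream tool originally used for this step does not
document its parameters, so ours are stated here and exposed in code.

## Annotation choices

The gene map is the standard mitochondrial annotation keyed to NC_012920
(37 genes, control region split across the origin). Decisions a maintainer
should know about:

* Overlapping gene pairs (ATP8/ATP6, ND4L/ND4): the gene whose reading
  frame continues downstream of the overlap (ATP6, ND4) is primary; the
  alternative is reported in an `overlap` field.
* Light-strand genes (ND6 and eight tRNAs): codons and alleles are
  reverse-complemented onto the coding strand before translation, and the
  codon index is counted from the 3′ genomic end of the CDS downward.
* Translation uses the vertebrate mitochondrial code (TGA=Trp, ATA=Met,
  AGA/AGG=stop). This matters in practice: a TGA→TGG change is synonymous
  here where the standard code would call a stop-loss.
* rRNA and tRNA variants get `effect = RNA_GENE`; incomplete
  (polyadenylation-completed) stop codons get a codon position but no
  effect call.
* dbSNP rs identifiers and population frequencies in the bundled catalogue
  are carried as metadata, never computed.

### The bundled reference stand-in

A genuine NC_012920 sequence cannot be redistributed inside this package's
test budget as a guaranteed-exact artifact, so the packaged FASTA is a
*synthetic stand-in*, and says so in its header and documentation: base
identities are exact at the documented variant sites of the catalogue, at
their full codons, at gene start codons and at the 3107 placeholder; all
other positions are random draws with rCRS-like base composition. Every
piece of annotation logic (feature lookup, frame arithmetic, strand
handling, translation) is independent of the unconstrained positions, and
all functions accept a user-supplied reference, so a real rCRS drops in
without code changes.

## The N-SNV criterion and the five patterns

The operative criterion is: derived allele present in ≥ 1 Neanderthal and
≥ 1 modern genome, absent from all archaic AMHs. The source literature
describes the sharing requirement in two incompatible ways ("all present-day
humans" versus patterns exclusive to single haplogroup classes); only the
"≥ 1 modern carrier" reading is consistent with the published pattern
counts (20 + 25 + 21 = 66) and haplogroup lists, so that is what is
implemented, prominently documented here.

The five clades of the pattern analysis are the two Neanderthal subgroups
(H-like late genomes; L-like oldest genomes), archaic AMHs, modern
haplogroup L and modern Eurasians. Subgroup membership is driven by
editable metadata labels, not hard-coded; the two Neanderthal subsets are
collapsed with OR in the pattern predicates. Pattern 1 (present in all five
clades) is reportable but lies *outside* the N-SNV set; Pattern 2
(Neanderthal + archaic only) is retained as a class even when empty, since
its emptiness is itself a finding. Missing archaic data at a site does not
block an N-SNV call but flags it `low_confidence` — ancient genomes have
coverage holes, and silently dropping such sites would bias the census.

## Clock arithmetic

Both calibrations reduce to `years = n_changes / s × 10⁴` with `s` the
substitutions per genome per 10,000 years: the populational calibration
uses `s = 1` (one observed change ≈ 10 ky), the ancient-DNA calibration
uses `s = 4.14`. The whole-genome constant 4.14 is taken as an input rather
than derived, because it does not follow exactly from the midpoint of the
published per-site range (2.14–2.74 × 10⁻⁸ subs/site/year gives ≈ 4.04);
both parameterisations are exposed and the discrepancy is the user's to
choose between. Values are kept at full precision internally; rounding
(2 decimals for My-scale, integers otherwise) happens only at display.

## Bootscan: design and numerical choices

Per window of 200 alignment columns (step 20), the scan draws `replicates`
bootstrap column-resamples, builds the neighbor-joining tree of query +
parentals + background on K80 distances, and votes for the parental inside
the smallest clade containing the query and at least one parental
(operationalised as the smallest query-side component over single-edge
removals of the unrooted tree; ties split the vote equally). The original
tool's grouping criterion is not published; nearest-neighbor-by-smallest-
clade is the natural reading and is stated here as ours.

* **Saturation**: when `1 − 2P − Q ≤ 0` or `1 − 2Q ≤ 0` the K80 logarithm
  is undefined; the distance is set to a ceiling (default 5.0
  substitutions/site) instead of aborting — windows are short, so
  occasional saturated pairs must not kill a scan. Zero comparable sites
  also map to the ceiling inside the scan (and to an error in the
  standalone distance function, where it indicates a user mistake).
* **NJ determinism**: Q-matrix ties break on the smallest index pair;
  negative branch lengths clamp to zero; an all-zero matrix yields a star
  tree.
* **Replicates with no variable site** count as unresolved, as do
  replicates whose minimal query-side clade contains no parental; support
  percentages over parentals plus unresolved sum to 100.
* **RNG**: each window's bootstrap stream is seeded from (seed, window
  index), so serial and window-parallel execution give bit-identical
  profiles.
* **Tracts versus points**: windows overlap, so one misleading column (a
  single convergent mutation) lifts support in up to
  `window_size / step_size` consecutive windows. `recombination_tracts()`
  therefore requires a run strictly longer than that single-column
  footprint before calling a segment a candidate tract. Null simulations
  (no recombination, moderate rate heterogeneity) show maximal spurious
  runs well below this footprint while planted 1 kb tracts exceed it
  several-fold, so the footprint is a natural separation point; both views
  (raw flagged windows and filtered tracts) are always reported.
* The binomial segment p-value treats windows as independent draws at the
  genome-wide support proportion; overlapping windows violate independence,
  so it is an ordering heuristic, not a calibrated test — documented as
  such.

F81 distances are not provided (the K80 and JC69 forms cover the published
analyses; F81 would need base-frequency estimation that the short windows
do not support well).

## PCA

Gap-free biallelic encodings only; multiallelic sites contribute one
indicator column per alternate allele; missing entries are mean-imputed per
column. The default scaling is the population-genetics standard: centre by
allele frequency, divide by `sqrt(p(1 − p))`; raw centred PCA is a flag
away. Scores come from the SVD; each component's sign is fixed by making
its largest-magnitude loading positive, so runs are reproducible.
Monomorphic-after-filtering columns are dropped with a message; an
all-monomorphic matrix returns explicit zero scores rather than an error.

## The simulator: what it emulates and what it does not

`simulate_mitogenomes()` evolves a root sequence (rCRS-like base
composition) down a user tree under per-site Poisson substitution: site `i`
on a branch of length `b` receives `Poisson(m_i · b)` events, where `m_i`
is a gamma(α, α) multiplier (mean 1) times a hotspot factor, and each event
is a transition with probability `κ/(κ + 2)` (default κ = 2). Events are
realised one by one (not via matrix exponentials) precisely so that the
truth record is exact at event level: every (branch, site, from, to) is
logged, convergent sites are recomputed from the log, and replaying the log
regenerates the tips bit-for-bit.

The default tree is a five-tip caricature of the study design — two
Neanderthals, one archaic AMH, two moderns, Neanderthal–modern divergence
around 2% — matching the order of magnitude of a ~5% polymorphic
whole-alignment screen. `plant_convergence()` schedules identical derived
mutations on one Neanderthal and one modern terminal branch (never archaic)
at evenly spaced sites; by default those sites are masked from the random
process so the expected N-SNV set is exactly the planted set.
Recombination events copy the donor's finished tract into the recipient.

What the simulator does *not* model, and what that means for the tests:
indels (gap handling is exercised by hand-built fixtures instead), ancient
DNA damage (C→T deamination), heteroplasmy, coalescent tree uncertainty and
within-clade population structure. Passing tests therefore demonstrate the
*algorithms* behave correctly under the stated generative assumptions; they
do not certify performance on real paleogenomes, where alignment error and
damage-derived artefacts add failure modes outside this model.

## Problem sizes used by the test suite

The suite validates at deliberately reduced scale, chosen so the full
statistical battery stays cheap while keeping every estimate's standard
error far from its decision threshold: simulated genomes of 1.5–8 kb
(full 16,569 bp for the Poisson-calibration and pipeline checks), bootstrap
replicates of 100–300 per window against the 1000-replicate production
default, 15–50 seeds per statistical property (100 for the Poisson
calibration), and planted tracts of 1 kb against 3 kb genomes. Production
defaults (window 200, step 20, 1000 replicates, cutoff 70%) are exercised
as defaults in the configuration tests and are the values used by
`run_pipeline()`.

## Known limitations

* The N-SNV criterion is presence/absence-based; it does not weight allele
  frequency within clades or coverage-dependent call confidence beyond the
  `low_confidence` flag.
* The binomial bootscan p-value ignores window overlap (see above).
* Insertions relative to the reference are recorded but not analysed; an
  indel-aware screen would need a different variant model.
* Haplogroup calling, parsimony tree search and disease-association lookup
  are out of scope: clade and haplogroup labels are pipeline *inputs*, and
  the per-site allele-sharing partitions are provided as the informative
  content that per-site cladograms would display.
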
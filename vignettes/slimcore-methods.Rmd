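---
title: "Methods: motif-mediated corepressor interaction mapping with slimcore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-mediated corepressor interaction mapping with slimcore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimcore)
```

## Scope and scientific setting

Transcription factors can recruit CTBP-family corepressors through short
linear motifs (SLiMs) of the PXDLX class, the canonical example being
PLDLS. Establishing that such an interaction is real, specific and
druggable typically combines five computational analyses, and `slimcore`
implements each of them as a testable stage:

1. **Structure-ensemble interface scoring** — given an ensemble of
   predicted complex structures, which residues are repeatedly at the
   chain–chain interface?
2. **Proteome motif-context analysis** — where else does the motif occur,
   how do its sequence contexts cluster, and how do we design a repeat
   competitor peptide (and its motif-dead control) from those contexts?
3. **Co-complex network analysis** — are the proteins co-purifying with
   the bait enriched for known complexes, and how do they organise into
   communities when weighted by co-membership?
4. **IP-MS differential enrichment** — which proteins are specifically
   enriched in a bait immunoprecipitation versus control, on label-free
   log2 intensities?
5. **ChIP signal correlation** — does the candidate cofactor's chromatin
   signal track the factor's binding sites genome-wide?

Every stage runs on synthetic inputs with planted ground truth produced
by the package's seeded generators, so correctness is demonstrated
without any external download.

## Interface frequency from structure ensembles

### Solvent accessibility

Solvent-accessible surface area (SASA) uses the Shrake–Rupley method: the
sphere of radius $r_{\mathrm{vdW}} + r_{\mathrm{probe}}$ around each atom
is sampled at $n$ quasi-uniform points and the accessible fraction is the
fraction of points not inside any neighbouring atom's expanded sphere.
Two numerical choices matter:

* **Deterministic sphere points.** Points come from a Fibonacci
  (golden-spiral) lattice rather than a random rotation, so SASA values
  are bit-reproducible. Accuracy improves roughly as $1/n$; at the
  default $n = 960$ the two-sphere configuration agrees with the analytic
  spherical-cap area to well within 2%, and to within 0.5% at
  $n = 10\,000$ (both checked in the test suite against the closed form).
* **Fixed van der Waals radii** (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20,
  P 1.80 Å). Published interface analyses often delegate this table to an
  external viewer whose values are not printed; pinning it in code keeps
  results reproducible. Unknown elements fall back to carbon with a
  warning.

### Interface calls

A residue is *interfacial* under one of two criteria:

* `buried_sasa` (default): the residue's SASA in the isolated chain
  minus its SASA in the complex exceeds
  $\max(\text{area cutoff}, 0.1\,\text{Å}^2)$. The 0.1 Å² floor absorbs
  lattice noise when the cutoff is 0, mirroring an "area cutoff 0"
  interface command. The strict inequality means a residue must bury
  measurable surface to count.
* `contact`: any heavy-atom pair across the chain pair within 4.0 Å.

Both criteria are exposed because interface tools differ on this point
and the choice is not always recoverable from a paper's methods; on the
package's zero-jitter synthetic dimers the two agree exactly, which the
tests assert.

Hydrogen-bond detection is purely geometric (N/O donors and acceptors,
distance ≤ 3.5 Å, donor angle ≥ 120°). Predicted models usually lack
hydrogens, so the angle at the donor is measured through the donor's
nearest bonded heavy atom; a donor with no antecedent passes on distance
alone. This over-calls slightly relative to an explicit-hydrogen
definition and is intended for ranking, not energetics.

### Ensemble aggregation

`ensemble_interface_frequency()` counts, per residue, the fraction of
ensemble models in which the residue is interfacial — a residue appearing
in 13 of 25 models scores 0.52. A residue is counted once per model
regardless of how many contacts it makes; weighting by contact count
would conflate interface breadth with depth. Consensus segments are
maximal runs of ≥ `min_run` (default 3) consecutive residues at frequency
≥ 0.5, which is how a docked five-residue motif such as PLDLS reads out
of an ensemble.

The ensemble generator plants a *contiguous* run of contact residues
(default 5, the length of the motif the pipeline is designed around) and
jitters coordinates with σ = 0.3 Å per model, a perturbation scale at
which a genuine 3.5 Å contact stays within the 4 Å cutoff in essentially
every model while spurious contacts stay out. At these study conditions
the consensus segments recover the planted interface with Jaccard 1.0;
the generator does **not** emulate prediction failure modes (partial
docking, alternative poses), so recovery on real ensembles depends on
prediction quality, not on this package.

## Motif scanning, context clustering and competitor design

Scanning is exhaustive with a one-character wildcard (`P.DL.` matches
PLDLS and PFDLT), reporting overlapping occurrences deterministically.
For a fixed 5-mer query, exhaustive scanning is complete where heuristic
homology search is not, and requires no external binary; the test suite
pins it to a naive sliding-window oracle.

Contexts are fixed-length windows, motif ± 15 residues, gap-padded at
protein termini so the motif always occupies the same central slice.
Pairwise distances are $\sqrt{1 - s}$ with $s$ the mean positional
similarity over columns where at least one side is a residue: identical
residues score 1, same-class residues score 0.5 under the class scheme
(classes {AGPST}, {C}, {DENQ}, {HKR}, {ILMV}, {FWY}), everything else 0;
gap-versus-residue scores 0 and gap-versus-gap columns are excluded. The
exact amino-acid-characteristics matrix used by the seqinr
`dist.alignment` convention this mirrors is not printed in its
documentation, so the class partition and within-class credit here are
explicit configuration — swappable via arguments — rather than a claimed
reconstruction; the identity scheme is verified against seqinr directly.
$\sqrt{1-s}$ is a semimetric; the triangle inequality is not guaranteed
under the class scheme and is deliberately not asserted.

Trees come from `stats::hclust` (complete linkage by default, the
`hclust` default, since published trees rarely state their linkage) and
are exported as ultrametric Newick via `ape`. The two-family recovery
check cuts the tree at the root and compares the bipartition to the
planted family labels; at the generator's per-site flank mutation rate of
0.05 the split is exact.

Competitor constructs concatenate gap-free context windows (e.g. two
human and two mouse motif windows), an optional linker and a C-terminal
NLS; the motif copy number is obtained by *rescanning the assembled
product*, so the PLDLS→PLASS mutated control verifiably contains zero
copies and differs from the inhibitor at exactly two positions per
repeat. Four 35-residue windows plus a 7-residue NLS give the expected
147-residue construct.

## Co-complex enrichment and network

Enrichment of a hit list against a complex database is the
hypergeometric upper tail $P[X \ge k]$ with BH adjustment across
complexes — the core statistic of standard enrichment tools; combined
scores (log p × z) are out of scope. The universe defaults to all
proteins in the database because IP-MS background sets are rarely
published. The test suite checks the p-value against exhaustive tail
enumeration for every configuration with $N \le 20$.

Edge weights are the **cosine similarity** of binary complex-membership
vectors. Methods sections sometimes phrase this as "cosine distance"
while drawing strong ties as heavy edges; similarity is the default here
because it preserves that visual semantics, and the distance form is
available. Louvain community detection (igraph, default resolution 1)
and Fruchterman–Reingold layout are both seeded for determinism. On the
planted-module generator — two 15-protein modules sharing many
complexes, with disjoint background complexes — the modules come back as
exactly two communities and the full-module complex is the top
enrichment row.

## IP-MS differential enrichment

The workflow mirrors standard label-free practice: filter proteins to
those with ≥ 3 valid values in at least one group (`any_group`; an
interactor absent from the control IP is informative, not missing data),
impute left-censored missing values, test, and call significance.

* **Imputation.** `below_min` (default): all missing values become the
  global observed minimum minus 0.5 log2 units — the "value below the
  lowest detected protein" convention. `fixed(value)` and
  `min_prob(width, downshift)` (seeded draws from a normal centred below
  the minimum) cover the other conventions in circulation; which one a
  given study used is often ambiguous, so all are reachable.
* **Test.** Welch (unequal-variance) t per protein, two-sided p from the
  t reference distribution, with an optional `s0` added to the standard
  error (default 0). Degenerate rows with zero variance in both groups
  get p = 1 (equal means) or p = 0 (unequal) by documented convention.
* **Permutation FDR.** Group labels are permuted (unrestricted, 250
  rounds by default, seeded); for each observed $|t|$ threshold,
  $q$ = (mean permutation count ≥ threshold) / (observed count ≥
  threshold), capped at 1 and monotonized so $q$ is non-increasing in
  $|t|$.
* **Calling.** Volcano mode — $|\log_2 FC| > 1$ and raw $p < 0.05$ — is
  the default, matching common volcano-plot thresholds; FDR mode uses
  $q$ instead of $p$.

The LFQ generator plants a 4-log2-unit enrichment in 50 of 2000 proteins
(baselines N(20, 1), within-group noise σ = 0.3, n = 3 per group) and
censors everything below the 10% quantile of the matrix, reproducing
abundance-dependent missingness. Under these conditions recovery is
recall = precision = 1.0 at the volcano thresholds; note that the
fold-change threshold is what protects precision here, because imputation
places censored values only ~0.5 units below the observed floor. The
null configuration (no effect, no censoring) keeps the q < 0.05 fraction
at or below 0.07 averaged over 20 seeds. The generator draws each
protein's samples i.i.d.; correlated sample effects (batch, loading) are
not emulated, so the null calibration shown is for exchangeable samples.

## ChIP signal correlation

Peaks become windows of ± 1000 bp around the peak midpoint (the
heatmap-compatible `center` mode; `edges` mode widens peaks
asymmetrically and is provided for completeness). Windows crossing a
chromosome boundary are dropped rather than truncated so heatmap rows
stay equal width. Counts are exact integrals of bedGraph
piecewise-constant coverage over half-open windows — read extension and
shifting are upstream concerns — and are normalized to counts per
million of track library size, the declared stand-in for a
replicate-aware normalization whose defaults are tool-internal; a hook
accepts user-supplied factors. Correlation between tracks is ordinary
least squares and Pearson r on $\log_{10}(x + 1)$, computed from
closed-form sums so that a track against itself returns exactly r = 1,
slope = 1, intercept = 0. Heatmap matrices are ranked by a chosen track
(ties by coordinate) and winsorized at a global percentile — 99 by
default, 90 being conventional for broad acetylation marks — using the
linear-interpolation percentile definition (type 7); winsorization is
idempotent up to interpolation of the clipped extreme, since a second
pass recomputes the percentile on clipped data.

The coverage generator draws per-peak log-rates from an equicorrelated
Gaussian (shared-factor construction, pairwise correlation ρ) and
Poisson counts at mean depth × rate. Poisson noise attenuates the
log-scale correlation slightly below ρ (~0.74 observed at ρ = 0.8,
depth 30, 2000 windows — within the ±0.1 recovery band the tests use),
and r increases monotonically with depth, which the tests check at three
depths.

## Stage runner and reproducibility

`run_stage()` executes any stage from a `run_config` (or YAML file):
inputs are validated before any computation, outputs are written
temp-then-rename, and every run emits a `manifest.json` with the
resolved parameters, input MD5 checksums, seed and package version.
Config files are YAML — the de facto configuration format of the R
pipeline ecosystem — with unknown keys rejected outright. All
randomness derives from the single `seed` field, and every stage rerun
with an identical configuration is byte-identical, which both the tests
and the acceptance script verify end to end. A thin command-line
wrapper (`inst/cli/slimcore.R`) exposes the same runner to shell users.

## Problem sizes and limitations

The packaged checks run at deliberately modest sizes chosen to exercise
every code path with comfortable statistical margins: 25-model ensembles
of 30 + 30 residues, 500-protein proteomes with 40 planted motifs,
200-complex databases, 2000 × 6 LFQ matrices, and 2000-peak coverage
tracks. These are the generators' defaults and the conditions under
which the quantitative claims above hold.

Known limitations: PDB is the only structure format (no mmCIF, no
insertion codes); SASA uses a pairwise neighbour search suited to
peptide-scale models, not whole proteomes; the hydrogen-bond criterion
is heavy-atom geometric only; motif scanning is exact/wildcard, not
probabilistic; the class-based context similarity is a documented
configuration, not a published matrix; enrichment ignores protein
abundance bias in the universe; the ChIP stage consumes bedGraph
coverage, not alignments. Passing the planted-truth tests demonstrates
the correctness of each implementation under its stated model, not the
biological validity of any particular dataset.
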
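---
title: "Methods: TnSeq depletion statistics and CATCH-N bioenergetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TnSeq depletion statistics and CATCH-N bioenergetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catchn)
```

# Scope

`catchn` implements the computational core of an in-planta transposon
sequencing (TnSeq) analysis of rhizobium--legume symbiosis together with the
bioenergetic and kinetic models of the CATCH-N cycle — the co-catabolism of
plant-provided arginine and a C4-dicarboxylate (succinate or malate) that
powers nitrogenase in bacteroids. The package has five layers: a
synthetic-data generator, insertion-table/GFF3 I/O and site assignment,
essentiality calls, the symbiosis impairment score, and the bioenergetic and
reaction-network models. Everything downstream of raw sequencing
(demultiplexing, alignment) is out of scope; the package consumes
insertion-site tables.

# The impairment score

For each CDS we record `n`, the unique insertion sites present in the input
mutant pool; `i`, the sites recovered from nodules; and `k`, the longest run
of coordinate-consecutive input sites absent from the output pool. Passage
through the plant is a severe population bottleneck that removes insertions
neutrally at a loss rate `l` (estimated as total input sites over total
recovered sites in a neutral gene set; the study-scale calibration value
6.840 is the package default). The score of a gene is the product of two
probabilities:

* `p1 = P(X <= i)` for `X ~ Poisson(lambda)`, `lambda = n / l`: the
  probability of recovering at most `i` insertions through a neutral
  bottleneck. Computed with `stats::ppois` (log-space stable); the
  `lambda = n / l` strategy is a package choice — the loss-rate estimate
  itself is the only calibrated quantity.
* `p2 = P(longest loss run >= k)` when `i` of `n` ordered sites are retained
  uniformly at random. The `n - i` lost sites fall into the `i + 1` ordered
  gaps between retained sites — a bounded composition of `n - i` — and `p2`
  asks for at least one part of size `>= k`.

Small scores flag genes whose mutants are specifically depleted during
nodule selection, with the run-length term rewarding biologically contiguous
loss.

## Run-length combinatorics

Four estimators of `p2` are provided and cross-checked:

* **Inclusion–exclusion** (default, exact in every regime):
  `p2 = sum_{j>=1} (-1)^(j+1) C(i+1, j) C(n - j k, i) / C(n, i)`, terms with
  `n - j k < i` vanishing. When every binomial coefficient fits in exact
  double-integer range (< 2^53) the alternating sum is evaluated in integer
  arithmetic and is exact as a rational; otherwise terms are evaluated via
  `lchoose` and combined with compensated (Kahan) summation and the result
  clamped to [0, 1].
* **Closed form** `(i+1) C(n-k, i) / C(n, i)`: the first
  inclusion–exclusion term, exact iff `k > (n - i)/2` (at most one gap can
  reach `k`). The function refuses the multi-run regime rather than return
  an upper bound.
* **Enumeration** over all `C(n, i)` retention patterns: the independent
  oracle for small `n` (the test suite exhausts all `n <= 12`).
* **Monte Carlo** sampling of retention patterns with a binomial standard
  error, for very large `n` where exact evaluation is disabled.

Edge semantics: `k = 0` gives `p2 = 1` (a run of length zero always
exists); `k > n - i` gives `p2 = 0`; `k = 0` occurs iff recovery is
complete.

## Calibration of the product score

The product of two approximately uniform p-values is anti-conservative as a
p-value (the Fisher-combination effect): for independent uniforms,
`P(U1 U2 < a) = a (1 - ln a)`, which is 0.20 at `a = 0.05`. Discreteness of
`i` and `k` pulls the real exceedance back: computing the exact null mixture
(`i ~ Binomial(n, 1/l)`, `k` from the run-length distribution) gives
`P(score > 0.05)` of 0.92 at `n = 20` input sites, 0.87 at `n = 30` and
0.85 at `n = 110`, approaching ~0.80 as discreteness vanishes. The score is
therefore validated as a *ranking* statistic (the property suite checks
AUROC against ground truth and checks that the empirical neutral-score
calibration matches this exact null), not as a calibrated p-value; users
wanting set-level control should apply the Benjamini–Hochberg option of
`call_symbiosis_genes()`.

# Essentiality calls

From the input library alone, each CDS gets an insertion density and a gap
decomposition (maximal insertion-free intervals; a site occupies one base,
so the gap between consecutive sites is their distance minus one; gaps
touching a CDS end are boundary gaps). A CDS is *essential* when its
density falls below 1/6 of the genome-wide average **and** a single gap
covers > 60% of the CDS or the two largest internal gaps cover > 80%;
failing that, density below 1/4 of the average makes it a *fitness* gene.
Read literally, density thresholds of the form "< 6 times the average" would
be nearly vacuous — essential genes must have *fewer* insertions — so the
reduced-density reading is the default, with both factors exposed
(`essential_density_factor`, `fitness_density_factor`) so the literal
variant is selectable. Genes shorter than 100 bp are flagged low-confidence
but still classified. Boundary gaps are eligible for the single-gap rule.

# The synthetic-data generator

The generator emulates the study conditions so that every downstream stage
is testable without sequencing data: a tripartite ~6.7 Mb genome (3.65 Mb
chromosome plus 1.35 and 1.68 Mb megaplasmids, 6200 CDS), a hyper-saturated
input library at 0.112 unique sites per bp (~750k sites genome-wide,
Binomial site counts, uniform placement, no strand bias — strand is
recorded but ignored by all statistics), and a nodule-selected output
library produced by (a) independent neutral retention with probability
`1/l`, `l = 6.84`, and (b) gene-specific depletion: sites in designated
symbiosis genes survive with probability `(1/l)/depletion_factor` (default
20-fold), with half of each gene's losses (`contiguity_weight = 0.5`) laid
down as one contiguous run whose start is uniform within the gene. Read
counts are geometric with mean 10 and play no role in the statistics, which
are presence/absence. A single config seed drives all draws; identical
config plus seed reproduces files byte-for-byte.

What the generator does **not** emulate: per-plant multinomial structure of
the bottleneck (retention is independent Bernoulli), insertion hot/cold
spots, alignment artifacts, or read-count noise models. Passing the
recovery tests therefore demonstrates the statistics recover engineered
depletion under idealised sampling, not performance on real libraries.

# Bioenergetic accounting

Constants: nitrogenase consumes 16 ATP and 8 low-potential electrons per
N2 (2 ATP per flavodoxin hydroquinone); electron bifurcation sends one
electron of each NADH pair to nitrogenase and one to the oxidase branch,
which translocates 3 H+ per electron; each catabolic QH2 adds two oxidase
electrons; a terminal oxidase takes 4 electrons per O2; ATP synthase needs
10/3 H+ per ATP. The ratio is stored as the exact rational: using the
commonly rounded value 3.33 would give 2.82 instead of 2.80 ATP for the flagship
cycle. Per pathway,

```
electrons_to_oxidase = nadh_bifurcated + 2 qh2_catabolic + extra
o2                   = -electrons_to_oxidase / 4
h_influx             = 3 electrons_to_oxidase + h_enzymatic
atp_net              = h_influx * 3/10 + substrate_level_atp - 16
```

Rounding (half-up, two decimals) happens only at report time.

Two fixture fields are package reconstructions rather than independently reported values:
`substrate_level_atp` (2 for the CATCH-N cycles, 1.6 for the TCA
references) is back-solved from the accounting identity on the reference
rows, and `extra_electrons_to_oxidase` (2 for the malate cycles) closes the
electron balance implied by each row's reported proton-translocation term
where the net QH2 column alone does not. The TCA-succinate row cannot be
reconciled with these rules at all (its translocation term exceeds the
electron supply by 0.4 H+ and the identity yields 0.24 ATP, not the reported
0.12); its fixture carries the bracket-derived electron flux, is flagged
`non_reconciled`, and is excluded from exact checks.

Nitrogen bookkeeping is per arginine: 4 organic N enter; the cycle's 8
bifurcated electrons fix one N2 per two arginine (one N each); the two
transamination steps per arginine export 2 N as alanine (or aspartate);
the remainder — guanidino N released as urea and hydrolysed, plus the
fixation share — leaves as ammonium: 2 alanine + 3 ammonium, 5 N per
arginine, 25% above the 4-N classical reference. Note the comparative
table prints product labels per N2 (two cycle turns), so its "2Ala" label
coexists with the per-arginine accounting; the report keeps the per-N2
labels, the nitrogen budget uses the transamination count.

# The arginine transamination network

The reaction graph (twelve core metabolites, arginine to succinate) is
shipped as data (YAML) rather than hard-coded: the network is usually
communicated as a drawing, so an explicit, easily amended edge list — one
edge per enzyme activity class identified by the profiling work — is the
more maintainable representation. Reaction classes
fix the co-species pattern (aminotransferase: pyruvate to alanine;
ureohydrolase: + urea; decarboxylase: + CO2; dehydrogenase: + NADH with the
NAD+ pool treated as non-limiting, matching the 2 mM NAD+ excess of the
reconstitution assay; deiminase: + ammonium), and every edge is checked
for whole-molecule carbon and nitrogen balance. Structural invariants:
every directed arginine-to-succinate route has at least 6 steps and exactly
2 aminotransferase steps (hence consumes two pyruvate equivalents while the
backbone regenerates only one — the origin of the obligatory succinate
co-catabolism). The deiminase branch (to citrulline), the classical
ornithine–proline–glutamate branch and urea hydrolysis are optional
sub-networks used by the label-propagation demonstrations. Isoenzyme
redundancy (e.g. three 4-aminobutyraldehyde dehydrogenases) is collapsed
into single edges.

Kinetics are irreversible mass action — unimolecular in the backbone
substrate, bimolecular (substrate x pyruvate) for aminotransferases — with
order-of-magnitude default rate constants chosen so that ~90% of 2 mM
arginine is consumed within 30 min with 20 mM pyruvate, as in the 14-enzyme
reconstitution; no constants are fitted, and all assertions about the
kinetics are structural or ordinal (tier-1 intermediates peak before
tier-2; alanine converges to twice the consumed arginine; atoms are
conserved to integrator tolerance, `rtol 1e-8`/`atol 1e-10`, lsoda).
Label propagation duplicates each pool into labeled/unlabeled copies
sharing rate constants; fluxes are computed from totals and split by the
substrate's labeled fraction (the alanine co-product carries the pyruvate
label), sources are clamped in concentration and fraction. Fractions are
reported as NA while a pool is empty. For steady-state demonstrations the
pyruvate pool must be co-clamped; otherwise its finite 20 mM reservoir is
exhausted and transaminase fluxes die out.

# Problem sizes and determinism

The test suite runs the recovery screen at 500 genes of ~960 bp on a
600 kb replicon (study insertion density, so ~100 input sites per gene,
comfortably above the 20-site floor the score needs), five seeds for the
ranking check; the combinatorics oracle exhausts all `n <= 12`; Monte-Carlo
checks use 1e5 replicates at `n` of 100 and 300. The pipeline writes its
resolved configuration beside its outputs, and identical configurations
give bit-identical files.

# Known limitations

* The impairment score is anti-conservative as a p-value (see calibration
  above); it is a ranking statistic.
* Real-data outputs of the original screen (per-gene catalogues and their
  counts) require the original libraries and are not reproducible here;
  property-based checks on synthetic ground truth stand in for them.
* The bottleneck model is site-independent; clonal and per-plant structure
  would fatten the null tails further.
* The network's rate constants are illustrative; time courses are
  qualitative, not fits to measured mass-spectrometry traces, and
  reference fractional-labeling values are measured quantities the model
  does not target.
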
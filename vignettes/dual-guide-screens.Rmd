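---
title: "Dual-guide CRISPRi modifier screens: models, scoring, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-guide CRISPRi modifier screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualguide)
```

## The experimental design this package models

A dual-guide CRISPRi modifier screen asks: *given a sensitized genetic
background, which genes change their phenotype?* Every vector in the pooled
library carries two sgRNA cassettes. The **fixed (anchor) guide** is the same
in every element — either a validated guide against the anchor gene, or a
non-targeting (NT) control — and establishes the genetic background. The
**variable guide** comes from a genome-wide library (five guides per gene
plus non-targeting controls). Cells carrying one library element each are
sorted on a ratiometric fluorescent reporter (GFP:RFP), the top and bottom
30% tails are collected, and guide abundances in each bin are read out by
sequencing. Running the same variable library on both the NT-anchored and
gene-anchored backgrounds, and comparing per-gene results, separates three
modes of genetic interaction:

* **synthetic** — the phenotype is *enhanced* in the anchored background
  (the gene buffers the anchor's loss, e.g. a parallel pathway);
* **same_pathway** — the phenotype is *diminished* (the anchor has already
  removed the pathway the gene acts in, so its loss adds little);
* **orthogonal** — the phenotype is *unchanged* (the gene acts independently
  of the anchor).

The motivating biology is tail-anchored protein insertion into the ER
membrane, where two partially redundant insertase pathways (an EMC-like and
a GET-like route) can each handle a moderately hydrophobic substrate.

## Library construction model

Cloning the variable library into the dual-guide vector requires
restriction-digesting it with BamHI (GGATCC) and NotI (GCGGCCGC); any
element whose protospacer (or its junction with the vector) contains one of
these sites is destroyed. `build_dual_library()` reproduces this attrition
in silico and reports the lost elements; on random 20-mers the expected loss
rate is close to the ~1% observed for a real genome-wide library
(`1 - (1 - p6)^15 * (1 - p8)^13` with `p6 = 4^-6`, `p8 = 4^-8`, about 0.4%
from the protospacer alone — junction-spanning sites, supplied via
`context5`/`context3`, account for the remainder; the real vector flanks are
not hard-coded because they are not published as sequence).

Both default enzymes are palindromic, so single-strand scanning suffices;
user-supplied non-palindromic recognition sequences are scanned on both
strands. Scans report *all* overlapping occurrences.

`make_annealing_oligos()` implements the fixed-guide cloning oligos: forward
`"ATG" + guide + "GTTTCAGAGC"`, reverse
`"TTAGCTCTGAAAC" + reverse-complement(guide) + "CATGTTT"`. The pair is
invertible (`decode_annealing_oligos()`), which is what the round-trip
property tests assert. `transformants_required()` is the coverage product
used to size bacterial transformations (e.g. 100,000 elements at 50x =
5,000,000 colonies).

## The flux model behind the simulator

The generator needs a quantitative stand-in for "two partially redundant
pathways". We use a sum-of-fluxes model: reporter output is

$$ R = F_A \cdot a_A + F_B \cdot a_B + F_{bg}, $$

where $a_P$ is the residual activity of pathway $P$ and $F_{bg}$ a small
anchor-independent background (defaults $F_A = F_B = 0.5$,
$F_{bg} = 0.02$). Knocking down gene $g$ with strength $s$ and guide
efficacy $e$ leaves residual gene activity $1 - se$; guides against the same
gene compose multiplicatively ($1 - s e_1$ times $1 - s e_2$), and a
pathway's activity is the product over its targeted members. The reported
value is $\log_2 R$ relative to the unperturbed output, so "no knockdown"
is exactly 0. This functional form is a modeling choice, not a published
equation: it is the simplest form that reproduces the two signatures the
screen design relies on — *masking* within a pathway (once the anchor
ablates pathway A, further pathway-A knockdowns change nothing; an exact
algebraic identity in the model) and *synergy* across pathways (ablating
both collapses output to $F_{bg}$).

Two more effect categories complete the world. **Stabilizers** model factors
whose loss raises reporter level (degradation machinery): a knockdown adds
$\log_2(1 + s \cdot e)$. **Expression-only** genes scale GFP and RFP alike;
they cancel in the ratio and contribute 0 — the screen's ratiometric design
exists precisely to discriminate them, and the simulator encodes that
cancellation literally.

The fixed guide's efficacy is multiplied by an interference factor
`interference_rho` (default 0.8): delivering a second cassette on the same
vector measurably but modestly diminishes the fixed guide's potency. No
number is published for this effect; 0.8 encodes "real but not large". The
anchor gene is also present as a variable gene, so the anchor+self element
(a deeper double knockdown of one gene) exists, as it does in the real
library.

## Simulator parameters and their defaults

| parameter | default | units | why |
|---|---|---|---|
| `guides_per_gene` | 5 | – | compact 5-guides-per-gene library design |
| `gate_fraction` | 0.30 | – | top/bottom 30% reporter-ratio gates |
| `cells_per_element` | 1000 | cells | coverage maintained per sgRNA during screening |
| `read_depth_per_bin` | 1000 × elements | reads | ~1000 reads per element per bin, matching maintained coverage |
| `n_replicates` | 2 | – | biological duplicate |
| `doublings` | 10 | – | growth screens: Day 0 vs Day 18 after 10 doublings |
| `guide_efficacy` | Beta(8, 2) | – | per-guide potency, mean 0.8 with realistic spread; a deterministic ladder {0.9, 0.8, 0.7, 0.5, 0.3} is available for frozen fixtures |
| `anchor_efficacy` | 0.95 | – | fixed guides are pre-validated to be potent |
| `interference_rho` | 0.8 | – | modest loss of fixed-guide efficacy from the second cassette |
| `cell_noise_sd` | 1.0 | log2 | see below |

**Why `cell_noise_sd = 1.0` and not something smaller.** Tail gates amplify
mean shifts: the measured quantity is the log-ratio of a guide's abundance
in the two 30% tails, which for a true mean shift $\delta$ and cell-level
noise $\sigma$ behaves like
$\log_2\{[1 - \Phi((z_{0.7}\sigma + \delta)/\sigma)] / \Phi((-z_{0.7}\sigma
+ \delta)/\sigma)\}$. With $\sigma = 0.5$ a true shift of ~1 log2 unit
leaves under 0.1% of a hit's cells in its depleted bin; at any realistic
sequencing depth those guides then fall below the 50-count filter, and the
analysis censors exactly the strong synthetic hits it is supposed to find.
Published reporter screens show substantially overlapping high/low
distributions, which corresponds to $\sigma$ on the order of the phenotypes
being measured; $\sigma = 1.0$ reproduces that overlap, keeps strong hits
above the count filter, and leaves the null calibration unchanged. This is
a deliberate deviation from an earlier working default of 0.5.

**What the generator does not model:** infection/MOI and antibiotic
selection (simulation starts at guide-positive cells), recombination
between the two guide cassettes, induction kinetics, per-cell reporter
dynamics beyond a Gaussian in log-ratio, and sequencing error (reads are
sampled multinomially from bin composition; `count_guides()` is exercised
with synthesized reads instead). A green simulator-based test therefore
establishes that the *analysis chain* recovers a known world of this shape
— not that the model captures every property of real FACS data.

## The scoring chain

For each replicate, for the compared sample pair (high/low bins, or
day18/day0 in growth mode):

1. **Filter**: keep guides with ≥ `min_count` (50) reads in *both* columns.
   Requiring both sides is the strict reading of "fewer than 50 counts were
   excluded"; it prevents ratio artifacts from one-sided dropout. Exactly 50
   is retained.
2. **Enrichment**: $\log_2$ of pseudocounted relative frequencies,
   `log2(((high + 1)/T_high) / ((low + 1)/T_low))`, with totals computed over
   passing elements and pseudocount-adjusted.
3. **Center**: subtract the median of the passing non-targeting guides, so
   the NT median is exactly 0.

Guide phenotypes are then **averaged across replicates** (only over
replicates where the guide passed; a guide failing everywhere is dropped).
Per gene:

* **phenotype score** = signed mean of the `k_strongest` (3) guides with the
  largest |phenotype| — selection by magnitude, not sign, with a
  deterministic element-id tie-break;
* **p-value** = two-sided Mann–Whitney of all the gene's passing guides
  against all passing NT guides: exact by complete enumeration of
  $\binom{n+m}{n}$ labelings when $n \cdot m \le 100$ (two-sided = twice the
  smaller tail of U, capped at 1; midranks for ties), otherwise the normal
  approximation with tie and continuity corrections, clamped into (0, 1];
* **discriminant** = phenotype score × (−log10 p) by default. The
  alternative literal convention (phenotype × p) is implemented as
  `literal_product`, but it shrinks significant genes toward zero — the
  opposite of what a ranking statistic should do, and inconsistent with
  volcano-plot usage — so `neglog_product` is the default and the choice is
  recorded in the run metadata;
* **rank** = 1 for the lowest discriminant, ties broken by |phenotype|
  descending then gene name, a deterministic total order.

Growth mode divides the centered enrichment by the number of doublings,
giving the conventional per-doubling fitness gamma.

## Screen comparison and classification

`compare_screens()` joins the two screens' gene tables, computes
`rank_delta = rank_nt − rank_anchor`, and classifies each gene. With
sig(screen) = (p ≤ `alpha` and |phenotype| ≥ `min_abs_phenotype`) and
τ = `enhancement_factor`, the rules apply in order: *synthetic* if
significant in the anchored screen and either enhanced ≥ (1+τ)-fold with
the same sign or absent from the control screen entirely; *same_pathway* if
significant in the control screen and lost or diminished ≤ (1−τ)-fold in
the anchored screen; *orthogonal* if significant in both and essentially
unchanged; *null* otherwise.

The thresholds are operational inventions — the three-way framework itself
is qualitative — and therefore configurable. Defaults: `alpha = 0.05`,
`enhancement_factor = 0.3`, and `min_abs_phenotype = 0.25` log2 units. The
effect floor is calibrated against the generator's default world, where
null-gene scores have a scale of ~0.06 log2 units and the weakest true
measured effect is ~0.9: 0.25 sits several null standard deviations above
zero and several below the weakest signal. Note that an absolute floor
necessarily breaks exact scale-invariance of the classification near the
floor; with the floor at 0 the rules are exactly scale-consistent (this is
the property the test suite asserts).

The anchor gene's own row — the anchor+self double knockdown, expected to
be a significant hit in its own screen — is flagged and excluded from the
summary counts and the truth-versus-call confusion matrix.

## Numerical and degenerate-input choices

* Sorting gates are global quantiles of the pooled population (one sorter
  gate on the mixed library), with exactly `round(gate_fraction * n)` cells
  per tail and stable tie-breaking; fewer than 4 cells is an error.
* Multinomial sequencing conserves depth exactly per sample; an empty bin is
  an error rather than a silent zero column.
* All-equal Mann–Whitney inputs give p = 1; a p of exactly 0 (impossible
  from the computation, possible from user input) is clamped with a warning
  before the log.
* Guide counting is exact-match only, immediately after the first
  occurrence of the 5' constant anchor, longest protospacer length first;
  mismatch-tolerant matching is deliberately out of scope. Duplicate
  protospacers are rejected at index build, which also makes length
  tie-breaks impossible.
* Restriction scanning uppercases input and rejects ambiguity codes;
  sequences shorter than the recognition site simply report no sites.

## Known limitations

* The flux model is a two-pathway caricature; it cannot express
  dose-dependent epistasis shapes, three-way redundancy, or feedback.
* Simulated phenotypes are tail-enrichment readouts of the flux model and
  are therefore on a *measured* scale that amplifies true shifts; parameter
  recovery is about signs, orderings and classifications, not about
  reproducing any published effect size.
* The comparison layer classifies against a single anchor; all-by-all
  genetic-interaction maps and quantitative epsilon scores are out of
  scope.
* The count filter is applied per compared pair. Whether the original
  analysis dropped failing guides globally or per pair is not documented;
  per pair is the less destructive choice.
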
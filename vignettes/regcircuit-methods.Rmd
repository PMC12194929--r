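---
title: "Models and methods behind regcircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind regcircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regcircuit)
```

`regcircuit` infers regulator-to-operon circuits in bacterial genomes from
four standard annotation products: gene coordinates (GFF3), protein domain
hits (Pfam accessions per protein), all-vs-all protein similarity hits, and
nucleotide sequence. This vignette documents the models, the parameters
that matter, the numerical choices, and what the synthetic validation does
and does not demonstrate.

## Orthology

Ortholog groups (OGs) are built from reciprocal best hits (RBH). A
similarity hit is retained when E-value < 10⁻¹⁰ (strict), percent identity
> 60 (strict), and query coverage ≥ 60 (inclusive); the asymmetry follows
the usual phrasing of these cutoffs ("under", "over", bare "60%"), and all
three are arguments of `orthology_thresholds()`. For each ordered genome
pair and each query, the best subject maximizes bitscore, with ties broken
by smaller E-value and then lexicographic subject id — a fully specified
order, so the RBH set is invariant to input row order. OGs are the
connected components of the RBH graph. Spectral partitioning (as in
ProteinOrtho) would split weakly connected components; on data where
retained hits are reliable, components are the simpler and exactly
checkable choice, and the package's validation is truth recovery, not
parity with any particular clustering heuristic. The genome × OG matrix
counts members per genome, with an optional cap (`cap = 2`) matching the
common 0–2 display.

## Regulator classification

Domain hits are first reduced to an architecture per protein: hits are
admitted greedily by descending bitscore (ties: leftmost alignment start)
and a hit is rejected if it overlaps an admitted hit by more than 50% of
the shorter interval. Classification is a first-match rule cascade over
the architecture:

1. `PF00309` + `PF04963` + `PF04552` (Sigma54_AID/CBD/DBD) → sigma54, RpoN;
2. `PF00140` (Sigma70_r1_2) + `PF04539` (Sigma70_r3) → sigma70 groups 1–2;
3. `PF04539` alone (no r1_2, r2 or r4_2) → group 3, FliA-like;
4. `PF04542` (Sigma70_r2) + `PF08281` (Sigma70_r4_2), without r1_2/r3 →
   group 4, RpoE-like;
5. any other sigma70-region domain → generic sigma70-like;
6. otherwise unclassified.

Region domains are matched by accession and, as a fallback, by Pfam name
(`Sigma70_*`), because the r2/r4_2 regions are usually cited by name.
Distinguishing RpoD/RpoS/RpoH within groups 1–2 is an orthology question,
not an architecture question, and is supported only through OG labelling
with user-supplied references.

bEBPs require `PF00158` (sigma54 activator, AAA+) and `PF00072` (receiver);
HKS sensors require HisKA (`PF00512`) plus HATPase_c, with accessory
PAS/HAMP/cache domains ignored. A protein carrying all four domains is a
hybrid sensor; the package reports it as a bEBP with `hybrid_kinase = TRUE`
and a warning rather than forcing a single class silently. TCS pairing
searches the bEBP's own transcriptional unit and one flanking unit on each
side (`flank`, configurable) — wide enough for both co-operonic and
divergent sensor layouts — taking the nearest HKS by intergenic distance
(ties to the downstream neighbor); a bEBP with no sensor in the window is
a one-component regulator, the HupR pattern.

## Transcriptional units and upstream regions

Adjacent genes join one TU when they share a strand and the gap
`next.start − prev.end − 1` is at most 40 bases; more than 40 bases, or a
strand switch, starts a new unit. The same 40 bp threshold defines both TU
joining and upstream-region existence — one knob (`max_gap`) rather than
two, since both derive from the same intergenic-distance argument.
Overlapping same-strand genes are treated as gap 0 and joined, with a
message. Upstream regions run from the previous genomic feature to the
base before the leader gene, capped at `max_len = 300` nt — a typical
bacterial promoter-search window; minus-strand units take the mirror
interval and the returned string is reverse-complemented so coordinates
always read toward the gene. Divergent gene pairs each receive their own
oriented copy of the shared intergenic DNA. Replicons are treated as
linear; wrap-around joining is off (draft assemblies dominate the intended
inputs).

## PWMs, backgrounds, and exact p-values

`build_pwm_from_sites()` uses `(count + αq_b)/(n + α)` per column; α
defaults to `0.1·n` for curated site collections (strictly positive
matrices for log-odds) and 0.01 inside EM. Markov backgrounds of order
k ≤ 4 are estimated from (k+1)-mer counts with add-one smoothing,
conditionals for every context length up to k (the short contexts serve
sequence starts); windows containing `N` are skipped, and ambiguity codes
are collapsed to `N` on input.

Scanning scores are log₂ odds against the background's order-0 marginal.
p-values are exact, not approximate: scores are discretized to multiples
of ε = 10⁻³ bits and a dynamic program convolves the per-column null
distributions into the full null distribution of the window score, giving
`p(s) = P(score ≥ s)` with `p(min) = 1`. Computing the null under the
order-0 marginal even when a higher-order background is supplied is
standard scanner practice — the exact DP requires positional independence.
Both strands are scanned by default; a minus-strand window receives the
score and p-value of its reverse complement. Overlapping hits are removed
greedily by descending score (ties: smaller p, then leftmost, then strand,
then motif id), keeping a hit only if every retained overlap is ≤ 50% of
the shorter hit; the filter is idempotent and order-invariant.

The test suite checks the DP against brute-force enumeration of all 4^W
words (widths ≤ 6) *on the same discretized score grid*, where agreement
must be exact to floating-point precision; against the continuous scores
it checks the bracketing `p(s + Wε) ≤ p_DP(s) ≤ p(s − Wε)`. A plain
`|p_DP − p_exact|` bound in probability units would be ill-posed: p is a
step function of score, and two words whose scores differ by less than ε
can carry more probability mass than any fixed small tolerance.

Null calibration (10⁵ background windows at p < 10⁻⁴ should yield about
10 hits) uses a heterogeneous random PWM as the instrument. A
consensus-style PWM with two distinct values per column has a lattice of
attainable scores with no p-level near 10⁻⁴ (the level below the cutoff
sits at ~3 × 10⁻⁵), so the expected count is ~3 regardless of
implementation correctness; a PWM with varied column probabilities has a
near-continuous score distribution and an effective rate of 0.998 × 10⁻⁴.

## ZOOPS motif discovery

The generative model: each sequence independently contains one motif
occurrence with probability γ (else none), at a uniform position and
strand, letters drawn column-wise from the PWM; background letters follow
the background model. EM alternates the per-window posterior E-step with
M-step re-estimation of the PWM (pseudocount 0.01) and γ, stopping when
the objective gains less than 10⁻⁶ or after 200 iterations. Starting
points are the five most over-represented W-mers (count over background
expectation), seeded at probability 0.7 on the consensus base. The
reported objective trace is the Dirichlet-penalized log posterior that the
pseudocounted M-step actually maximizes; it is non-decreasing every
iteration (the raw likelihood alone can dip at the 10⁻⁵ scale once the
penalty is active, so asserting monotonicity of the raw likelihood would
be wrong for any pseudocounted EM). Likelihood ratios inside EM use the
background's order-0 marginal, mirroring the scanning convention.

Candidate (width, start) fits are ranked by per-site information content
times expected site count — a simpler, truth-recovery-oriented criterion
than MEME's E-value approximation, documented here as a deliberate
deviation. After a motif is accepted, its letters are down-weighted by
their site posteriors (probabilistic erasure) before the next motif is
sought, up to 10 motifs.

Two properties of ZOOPS EM on *finite null data* are worth knowing. First,
the MLE overfits: on 30 random 200-nt sequences the fitted γ̂ reaches 1
with a fuzzy motif of ~0.7 bits/column — this is the correct maximum of
the likelihood, not a bug, and the same behavior is visible in any ZOOPS
implementation (motif discovery tools flag it through a selection
statistic, not by suppressing the fit). The package's null test therefore
asserts discrimination — the null motif's information content stays well
below a genuinely planted motif's — rather than an absolute null bound.
Second, recovery of a strongly planted motif is excellent: at the
reference conditions (30 × 200 nt, width 12, ~1.6 bits/column, γ = 0.8,
five starts) the fitted PWM correlates with truth at r ≈ 0.998 per column
and γ̂ lands within ±0.05 of truth. The recovery check runs discovery at
the planted width: the quantity under test is parameter recovery at known
width; a width sweep (exercised separately at small scale) tests model
selection, a different property.

Information content uses the Schneider–Stephens small-sample correction
`R_seq(j) = 2 − (H_j + e(n))`, `e(n) = 3/(2·ln2·n)` bits, clipped at 0.
`autoplot()` renders IC-scaled logos as stacked bars.

## Promoter calls and circuit assembly

`call_promoter()` scans sigma-class PWMs over the 60 nt nearest the
leader. The default sigma54 PWM encodes only the conserved −24 `GC` and
−12 `TGC` elements (five informative positions): even a perfect match has
p ≈ 9.8 × 10⁻⁴, so promoter calling defaults to p < 10⁻³ rather than the
genome-scan 10⁻⁴ — short class-level elements cannot reach scan
stringency, and the window and threshold are both arguments. The sigma70
default encodes `TTGACA`/`TATAAT` with a fixed 17 nt spacer.

`assemble_network()` emits one edge per (regulator, TU) with a surviving
site hit, recording the best p-value; bEBP genes divergently oriented
toward a TU leader within 300 nt gain a colocalization edge (the
HupR / hydrogenase-operon layout), and both evidence kinds merge into
`evidence = "both"`. Regulators are reported at protein or motif level;
OG-level collapsing is a join away via the orthology tables.
`run_pipeline()` chains every stage from files, writes all intermediates,
and records a manifest (package version, parameters, seed, input MD5
checksums, completed stages); identical inputs and seed give byte-identical
outputs.

## The synthetic genome generator

`simulation_config()` fixes the study conditions; every stochastic choice
flows from its mandatory seed. Defaults: 3 genomes × 40 operons, 2–5
genes of 300–900 nt per operon, intra-operon gaps uniform on [0, 40] and
inter-operon gaps uniform on [700, 1000], operons on alternating strands,
uniform order-0 background, one copy per genome of each architecture in
`planted_architecture_catalog()` (one unambiguous representative per
classification outcome plus a decoy), and two width-12 planted motifs
(consensus probability 0.94, ~1.6 bits/column raw) at occupancy γ = 0.9,
one targeting odd- and one even-numbered operons. Binding sites are
planted 10–80 nt upstream of target leaders, sampled column-wise from the
PWM on a uniform strand.

Two deliberate choices shape the defaults. Intergenic gap distributions
are uniform and configurable — no empirical gap distribution is assumed.
The inter-operon range starts at 700 nt so that the two divergent
promoter regions sharing a gap (alternating strands make every other gap
divergent) lie farther apart than twice the 300 nt upstream cap:
otherwise every planted site would legitimately appear in its divergent
neighbor's upstream scan and (motif, TU) truth recovery would be
ambiguous by construction rather than limited by the method. Real
bacterial intergenic distances are mostly shorter; the choice isolates
scanner and assembly performance from a genuine biological ambiguity
(divergently shared enhancers) that coordinate-level truth cannot
adjudicate.

Protein sequences are random amino-acid strings and domain hits are
asserted in the table rather than detected — the pipeline consumes domain
tables, so HMM search is upstream of everything tested here. The
similarity table is generated from the planted orthology truth
(reciprocal rows at identity 90, coverage 100, E-value 10⁻⁵⁰, plus
sub-threshold noise pairs), which makes RBH/OG recovery exactly checkable.

What passing on this generator shows: coordinate arithmetic, strand
handling, the gap rule, the rule cascade, RBH logic, scanner calibration
and EM recovery are correct under their stated models. What it does not
show: robustness to mis-annotated gene starts, pseudogenes, horizontally
transferred paralogs, compositional heterogeneity (GC skew,
strand-specific bias), overlapping regulons, or degenerate real motifs —
real-data performance depends on those, and the configurable thresholds
exist precisely because the defaults encode a clean model.

## Problem sizes and determinism

The shipped tests run the generator at 1–3 genomes and 5–50 operons, the
scanner oracle at widths ≤ 6 (full enumeration), null calibration at 10⁵
windows, discovery at 30 × 200 nt, and the end-to-end run at the full
reference configuration — sizes chosen so each property is measured at
meaningful statistical resolution while the whole suite stays
desk-interactive. All entry points take explicit seeds; no function
consumes hidden global randomness, and `with_seed` restores the caller's
RNG state.

## Known limitations

- Connected-component clustering can chain OGs through promiscuous
  domains if sub-threshold hits are admitted; the thresholds are the
  guard.
- The exact-p DP is per-PWM; scanning many PWMs over huge genomes would
  want score-table caching beyond what `scan_sequences()` does per call.
- ZOOPS erasure is posterior-weighted masking, so heavily overlapping
  motif instances can suppress each other across rounds.
- Promoter classification is element-based; it does not model spacer
  length variability beyond the fixed PWM layout.
- No activation/repression sign, no expression integration, and no
  q-value correction (the pipeline filters on raw p < 10⁻⁴ by design).
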
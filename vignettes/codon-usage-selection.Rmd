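---
title: "Methods: quantifying selection on synonymous codon usage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying selection on synonymous codon usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`codonsel` analyzes how translational selection reshapes synonymous codon
usage across prokaryotic gene sets — strain-specific singletons, core gene
sets of increasing ancestry (C1…Cn) and putative highly expressed genes
(PHE) — and between genes of different expression level and sequence
conservation. This vignette records the models and procedures, the
parameters that matter, the design choices made where several defensible
options existed, and the known limits of what the synthetic-data tests
demonstrate.

## Counting and usage statistics

All statistics start from raw codon counts (RCC) over the 61 sense codons
of NCBI translation table 11 (`genetic_code()`; its codon→amino-acid map
coincides with the standard code — only start-codon annotations differ,
and start codons are counted with their sense meaning; 2 single-codon
amino acids, 9 two-fold, 1 three-fold, 5 four-fold, 3 six-fold families).
Stops are never counted; codons with ambiguous bases are skipped and
tallied. The frame policy is strict by default (`count_codons(frame =
"strict")` errors on out-of-frame input, naming the gene); `"trim"` drops a
trailing partial codon with a warning.

CUF is a codon's share within its synonymous family; families absent from
a gene or set are left undefined (`NA`) rather than zero-filled, except in
`rscu_matrix()`, whose zero-fill is the usual convention for
correspondence-analysis input. GC3 is the G+C fraction at third positions
of sense codons.

Wright's effective number of codons uses the homozygosity
F = (nΣp² − 1)/(n − 1) per amino acid (n > 1 counted codons), class means
over the 2-, 3-, 4- and 6-fold families, and
Nc = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆. A missing three-fold mean (no
usable Ile counts) is imputed as the harmonic mean of F̄₂ and F̄₄,
following Wright's original rules rather than the slightly different
CodonW variant. Nc is not capped: the unbiased F makes Nc exceed 61
slightly for finite uniform counts (e.g. 61.41 at 100 counts per codon),
so values above 61 are reported as-is with a warning; Nc → 61 only as
counts grow.

## Modal codon usage

The modal usage of a gene collection is the usage of its largest
internally consistent subset, not the pooled mean, which a minority of
atypical genes (horizontally acquired, highly expressed, …) can distort.
`modal_usage()` iterates: candidate ← pooled CUF of the accepted set
(initially all genes, floored at 1e-6 and renormalized per family so genes
using codons the candidate lacks keep a finite score); per gene, a
likelihood-ratio statistic G = 2Σ n_c log(n_c/(N_aa q_c)) summed over
families, compared to χ² with Σ(k−1) degrees of freedom over the gene's
observed degenerate families; genes with p > `p_cutoff` (default 0.1) are
re-accepted; stop at an identical accepted set on consecutive iterations
(`max_iter` 50). We apply the Williams small-sample correction per family
(G divided by 1 + (k+1)/(6n)): without it the χ² approximation is
anti-conservative at typical 300-codon gene lengths and rejects ~20% of a
truly homogeneous set at the 0.1 cutoff instead of the nominal ~10%. Note
that any exact test still rejects a p_cutoff-sized fraction of a
homogeneous set by construction; "acceptance" fractions near 1 − p_cutoff
are the expected behavior, not a defect.

Modal sequences (`modal_sequence()`) realize a profile as a concrete
artificial CDS of at least 10,000 codons — long enough that codons of rare
amino acids are represented accurately — with a default of exactly 10,020
codons. Amino-acid counts and within-family codon counts are assigned by
largest-remainder rounding (worst-case CUF error 0.5/n_aa ≈ 0.004 for the
rarest amino acid at the default length), and codons are emitted grouped
by amino acid in alphabetical order, making the sequence byte-reproducible.

## Correspondence analysis

`ca_fit()` is standard simple CA: P = N/n, standardized residuals
S = D_r^{−1/2}(P − rcᵀ)D_c^{−1/2}, SVD, principal coordinates by the
transition formulas. Total inertia equals χ²/n of the input table.
Supplementary rows (modal sequences, pooled sets) are projected as row
profile × column standard coordinates, which reproduces an active row's
coordinates exactly for a duplicate row. Because SVD signs are arbitrary,
each dimension's sign is fixed so the column with the largest absolute
standard coordinate loads positively. Genes of different lengths receive
no extra normalization beyond CA's intrinsic profile construction. A
matrix whose rows are all proportional has no inertia and is rejected
with an error rather than returning an all-zero embedding.

## Translational adaptation (Wi, tAI, m-tAI, DCBS, Sij)

The pairing table allows, per codon, the Watson–Crick anticodon and one
wobble decoder at position 34: U3 ← A34 (the `AU` slot, efficient where
A34 is inosine-modified) and G34 (`GU`); C3 ← G34 (WC) and A34-as-inosine
(`IC`); A3 ← U34 (WC) and A34-as-inosine (`IA`); G3 ← C34 (WC) and U34
(`UG`). Watson–Crick penalties are fixed at 0; the five wobble penalties
s ∈ [0,1] are trainable. The nonstandard U3:U34 interaction is
deliberately excluded, which is also why a U-ending-biased gene set can
score a lower m-tAI than its codon adaptation deserves — a known
limitation of this index family.

Wᵢ = Σⱼ (1 − s)·tGCNⱼ over allowed pairings, wᵢ = Wᵢ/max W, with
undecodable codons (W = 0) assigned the geometric mean of the nonzero w
and flagged. Per-gene tAI is the geometric mean of w with multiplicity;
m-tAI scores a whole profile, exp(Σ q_c log w_c) with
q_c = aa_freq·CUF, and matches the tAI of the realized modal sequence to
<1e-3. DCBS compares each codon's frequency with the product of the
gene's own positional nucleotide frequencies, d = max(f/f₁f₂f₃, f₁f₂f₃/f),
averaged with multiplicity; positional frequencies are per-gene (the
alternative genome-wide flavor changes d little and the per-gene form
needs no external input).

`train_sij()` maximizes Spearman's ρ between per-gene DCBS and per-gene
tAI over the five penalties with Nelder–Mead (proposals clipped to [0,1],
default 20 random uniform starts, tolerance 1e-6, ≤500 iterations per
start, all randomness from one seed). The defaults of `sij_weights()`
(GU 0.41, IC 0.28, IA 0.9999, UG 0.68, AU 0) are the classic bacterial
estimates and serve as the fixed "true" penalties in the planted-recovery
experiments.

**A caveat this package makes explicit.** On synthetic genomes with a
known tRNA pool and known penalties, maximizing ρ(DCBS, tAI) recovers the
*direction* of adaptation but systematically sharpens the wobble
penalties: profiling the objective one penalty at a time on a low-noise
genome shows its maximum near s_GU ≈ 0.8 when the planted truth is 0.41,
because wobble-decoded codons are the within-box minority in any
tRNA-consistent genome, so penalizing them harder exaggerates the tAI
contrast that tracks DCBS at essentially no cost. The achieved objective
at the sharpened optimum exceeds the objective at the truth, so this is a
property of the estimator, not of the optimizer. Consequently trained
penalties should be read as rank-order devices (which codon of a box is
preferred), not as physical pairing efficiencies, and the planted-truth
rank recovery of the full w vector plateaus around ρ ≈ 0.7–0.95 rather
than above 0.9 reliably.

## C/U bias and genome groups

`delta_cuf()` gives per-codon CUF differences between two sets (zero-sum
within each family). The C-bias test covers the C-ending codons of the
pyrimidine-ending two-fold families (Asp GAC, Phe UUC, His CAC, Asn AAC,
Tyr UAC) plus three-fold Ile AUC; Cys is excluded because its C-ending
codon shows no consistent ancestry-related bias. The U-bias test covers
the U-ending codons of the five four-fold families and the four-fold boxes
of Ser, Leu and Arg. Both are one-sample, one-sided t tests of Δ against
zero across eligible codons; a constant Δ vector is reported as an
infinite-t edge case (p = 0 for positive mean) rather than NaN. A second
mode (`species_bias_test()`) t-tests per-species mean deltas, for
multi-genome aggregation; which flavor a published figure used is often
ambiguous, so both are exposed.

Diversity groups follow GC orderings evaluated in sequence: A (global
GC < 0.36 and GC3 singletons > core > PHE), B (GC3(core) exceeding both
PHE and singletons by ≥ 0.03 — the smallest margin that reads as clearly
biphasic; configurable), C (PHE > core > singletons), D (global GC ≥ 0.60
and core ≥ PHE > singletons), otherwise `none`. "Core" GC3 is the pooled
most-ancestral set by default.

## Conserved and variable domains

HEP/LEP are the ≥0.9 and ≤0.1 abundance quantiles of the core genes with
data (quantile cuts configurable; the source analyses did not state
theirs). `backthread()` threads codons onto an amino-acid alignment after
verifying that each CDS translates exactly to its ungapped row (one
terminal stop tolerated). A column is conserved only when a single amino
acid occupies *every* row — a column containing any gap can never be
conserved; variable when no amino acid exceeds proportion 0.5 among
non-gap residues (gaps leave the denominator); intermediate otherwise.
`conservation_percent()` is the share of fully conserved columns among
columns where the reference has a residue; mean pairwise identity is
available as an option since published "percent conservation" figures are
frequently either.

## Distances and trees

`usage_distance()` is D = Σ_aa m_aa · ½ Σ |CUF₁ − CUF₂| with m_aa the mean
amino-acid frequency of the two profiles: a per-family L1 that
down-weights rare amino acids. It is symmetric, satisfies the triangle
inequality, and is invariant to codon order within families. Trees use
in-package Saitou–Nei neighbor joining with two determinism guarantees
the classic implementations leave unspecified: ties on the Q criterion
join the lowest-index pair, and a negative branch length at a join is
clamped to zero with the deficit moved to its sibling so the pair's total
is preserved. On additive distances NJ reproduces the generating tree to
1e-9 (and agrees with `ape::nj` topologies on noisy input, which serves as
the independent cross-check in the tests). The natural/simulated
`selection_ratio()` compares one entry (typically HEP_cr ↔ LEP_vr) across
a natural and a no-selection distance matrix; values > 1 mean natural
codon usages are more divergent, i.e. positively adapted.

## The synthetic-data generator

The generator stands in for the genome databases the real analyses drew
on. Each gene's amino acids come from a realistic average bacterial
composition (`default_aa_freq()`), lengths are log-normal with median 300
codons (floor 50), and codons are drawn per amino acid from the mixture
(1 − mix)·mutational + mix·selected, with `mix` the per-set selection
intensity. The mutational profile weights third bases A > U > G > C
(AT-leaning mutation pressure); the selected profile carries the planted
selection signal: C-ending dominance in the pyrimidine two-fold families
and Ile (the C bias), U-ending dominance in four-fold boxes (the U bias),
G in the purine two-folds. `derive_trna_pool()` makes the selection
tRNA-consistent with a sparse, realistic anticodon repertoire: box usage
is routed to Watson–Crick decoders, except that a U-ending codon feeds an
inosine-style A34 decoder when it dominates its box and the box's G34
wobble reader otherwise; copies are largest-remainder rounded to a
bacterial-scale total (120) with a one-copy bump wherever a codon would
otherwise be undecodable. Under the default penalties the resulting w
ranks like the planted CUF (ρ > 0.9), closing the loop between planted
pools and planted preferences.

Because GC3 is linear in `mix`, a two-profile mixture with monotone mix
cannot produce the biphasic GC3 trajectory of group-B genomes (rising
from singletons to the ancestral core, then falling toward PHE). The
group-B preset therefore applies an extra `phe_u_shift` (0.18) to the PHE
set only, moving four-fold-box CUF mass from G- then C-ending codons onto
U — the "late U bias" that separates PHE from the ancestral core. The
shift value was fixed from the geometry of the preset profiles (it must
lower PHE GC3 at least 0.03 below the ancestral core after mixing) at
design time. Abundances are log-normal around a line in `mix` (base 1,
slope 3 decades, sd 0.3), so PHE-like genes are abundant.

What the generator does *not* emulate: operon and strand composition
structure, amino-acid composition differences between gene classes,
within-genome GC heterogeneity, horizontal transfer mosaicism, or any
U:U-decoding effect. Passing tests on these genomes therefore shows the
pipeline's statistics behave as designed under their own assumptions, not
that real genomes satisfy those assumptions.

The M0 simulator evolves a root CDS along a tree under the one-ratio
codon model: single-nucleotide changes only, rate π_target × κ (if
transition) × ω (if nonsynonymous), F3×4 equilibrium frequencies (stop
mass renormalized away), matrix scaled to one expected substitution per
codon per unit branch length. Sites evolve independently by exact
Gillespie event sampling — no matrix exponentials, so event sequences are
exact at any branch length and the ω = 0 case preserves the protein
identically. The companion Nei–Gojobori (1986) estimator uses per-position
synonymous-site fractions with mutations to stop codons disregarded (the
original convention; implementations that count them as nonsynonymous
sites give ~6% smaller KA), pathway-averaged difference counts excluding
stop-crossing paths, and the Jukes–Cantor correction; its KS matches an
independent implementation exactly on simulated pairs. At ω = 1 with
κ = 2 the NG86 ratio centers near 0.89 rather than 1 — the classic
transition-bias underestimate — which is why simulator checks compare
replicate means against a generous band rather than expecting exactly 1.

## Problem sizes and runtime

The test-suite and acceptance-script scales were chosen to finish quickly
on one CPU while leaving the statistics well-resolved: 400–900 genes per
synthetic genome (~300 codons each), 2,000-codon sequence pairs and a
5,000-codon long-branch run for the simulator checks, 3 seeds × 5 restarts
for Sij training, and 200–1,000 replicates for the bias-test calibration.
The full suite runs in ~30 s and the acceptance script in ~15 s.
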
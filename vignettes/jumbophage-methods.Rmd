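---
title: "Methods: jumbo phage discovery and ecology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: jumbo phage discovery and ecology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the models and procedures it
implements, the parameters that matter, the numerical choices made where the
design was genuinely open, and what the synthetic-community validation does and
does not demonstrate about real data.

## The problem

Jumbo phages — bacteriophages with genomes above 200 kb — are systematically
lost or mislabelled in metagenomic catalogues: their contigs assemble poorly,
and their gene content overlaps bacterial chromosomes enough that
horizontally-transferred marker genes mislead contig classifiers in both
directions. The package implements a catalogue-style analysis over assembled
contigs and their gene annotations: call jumbo phages, strip bacterial false
positives, characterise genome features (alternative genetic codes, crAss-like
relatives), reconstruct CRISPR-spacer interaction networks, demarcate novel
families from whole-proteome comparisons, and infer co-abundance networks from
coverage profiles.

All thresholds live in `jumbo_config()`; nothing below is hard-coded.

## Discovery rules

A contig is called **phage** iff (1) at least `min_keyword_genes = 2` genes
carry a virus-specific keyword in their free-text product annotation, matched
as case-insensitive substrings ("tail" inside "tailless" counts — a documented
limitation inherent to keyword lists); (2) no gene carries a
prokaryote-specific exclusion term (*ribosomal protein*, *preprotein
translocase*, *DNA gyrase subunit A*); and (3) at least one CRISPR spacer from
a bacterial or archaeal genome matches the contig. In `run_pipeline()` the
spacer evidence is derived from arrays detected in genomes that are not
themselves keyword-positive; standalone callers can pass any evidence vector.

The **BUSCO ratio** — the fraction of a genome's genes hitting bacterial
universal single-copy orthologs — separates residual bacterial contigs from
true phages: viral genomes sit in the 0–0.067 band, so a genome is retained
iff its ratio is strictly below 0.067 (exactly 0.067 fails; the published rule
keeps genomes "below" the benchmark). The denominator is the genome's total
predicted gene count: the benchmark is a dimensionless per-gene fraction, not
a count against the 318-marker panel.

The four **viral signatures** (presence of viral protein families, absence of
microbial families, viral nucleotide signature, long same-strand gene runs)
are scored with explicit, overridable thresholds: viral families on ≥ 10% of
genes, microbial families on ≤ 2%, a same-strand run of ≥ 10 genes. The
literature the signature combination comes from does not print its thresholds,
so these conservative defaults are the package's own choice. The nucleotide
signature is a pluggable predicate defaulting to "absent": no trained sequence
model ships with the package.

**Lifestyles** use lysogeny-score cuts (virulent < 0.5, temperate > 0.9,
uncertain in the closed interval [0.5, 0.9] — the published inequalities are
open on both sides, so boundary scores are deliberately "uncertain"), with
provirus evidence overriding to temperate.

## Alternative genetic codes

Some phages reassign a stop codon (code 15: TAG, code 90: TAA, code 91: TGA).
Under the wrong code their genes fragment at the reassigned codon, so coding
density discriminates: `find_orfs()` performs a six-frame maximal-ORF scan
(starts ATG/GTG/TTG, minimum 90 nt, ORFs must terminate at a stop; trailing
stop-less spans are ignored) and `assign_genetic_code()` assigns an
alternative code iff its coded fraction exceeds the code-11 fraction by ≥ 10%.
The ORF caller is intentionally simple — no GC-frame model, no overlap
resolution beyond taking the union of spans — because the decision statistic
is a density *ratio*, which is robust to the caller's exact gene set. This is
a deliberate replacement for a trained gene finder, which does not support
codes 90/91 natively.

## crAss-like classification

Genomes above 70 kb are crAss-like if either (1) a translated search against
the crAssphage polymerase/terminase markers scores E < 1e-10, or (2) they show
≥ 95% nucleotide identity over ≥ 80% of their length against the reference.
The translated search is seed-and-extend: exact 5-aa words shared with the
marker seed Smith-Waterman extensions (BLOSUM62, gap open 10 / extend 1) in a
window around each seed, on all six frames; significance uses ungapped
Karlin–Altschul statistics (λ = 0.318, K = 0.13) with search space =
genome length x marker length x 6. Criterion (2) is a deterministic ANI-style
approximation: 1,000-nt query fragments placed on the reference by ungapped
matching, "aligned" at ≥ 95% identity, pass iff ≥ 80% of fragments align; the
denominator is the query length, so the comparison is asymmetric by design.
The packaged marker FASTA contains *synthetic stand-ins* (random sequences)
used by the validation suite; real analyses must substitute the genuine marker
proteins.

The 70 kb gate deliberately differs from the 200 kb catalogue cut: the
crAss screen runs on the pre-size-filter pool, and only > 200 kb genomes enter
the final catalogue; `run_pipeline()` reports both sets.

## CRISPR arrays and spacer networks

`detect_crispr_arrays()` is a CRT-style detector: an exact 8-nt window that
recurs 49–97 nt downstream (the repeat+spacer period range implied by repeats
of 23–47 nt and spacers of 26–50 nt) seeds a candidate; all occurrences of the
anchor word are chained at plausible periods, and repeat boundaries are then
extended only while *every* copy agrees, which prevents one-sided boundary
blur. Arrays need ≥ 3 identical repeat copies. Exact-repeat recurrence is
strand-symmetric, so a forward-strand scan reports every array in genome
coordinates.

A **spacer match** is an ungapped full-length placement of the spacer on
another genome in which up to `L − ceiling(0.95 L)` terminal spacer positions
may be clipped, leaving at most one substitution in the kept window (coverage
= kept fraction ≥ 95%). Indels are not tolerated — the published rule is a
short-sequence substitution rule — and `N` never matches anything. Self-hits
(spacer vs its own source genome) are excluded. The test suite checks the
implementation against an independent sliding-Hamming oracle position by
position.

Directed phage→phage edges aggregate matches per (source, target); mutual
pairs have edges both ways. The published analysis never defines "competitive
pair"; the package's interpretation — an unordered phage pair with at least
one spacer edge between them whose predicted host phylum sets intersect — is
flagged as such, on the rationale that competition requires a shared host.
"Interaction" counts are reported both as unordered pairs and directed edges,
and the competitive percentage under both normalisations (of all spacer pairs,
which matches the published 16.94% = 72/425 convention, and of phage–phage
pairs only).

## Family demarcation

Orthologues between two proteomes are reciprocal best hits under local
alignment with E ≤ 1e-5 and identity ≥ 30%, plus an alignment-coverage
condition (≥ 50% of the shorter protein) added to stop domain-only matches
from counting as orthologues; it is configurable. The shared fraction divides
the RBH count by the *smaller* proteome. Pairwise RBH sets stand in for global
orthologous protein clusters — a documented simplification that is exact on
the synthetic communities, where orthology is planted as near-identical
copies.

The proteomic tree is a neighbor-joining tree over D = 1 − S, where S is the
summed orthologue-pair bit score divided by the smaller proteome self-score.
The published analysis uses a maximum-likelihood whole-proteome tree with a
log-scale branch-length demarcation of ~0.05; since that pipeline is a web
service and not reproducible offline, the NJ surrogate is used and the 0.05
threshold is applied to *patristic distance* on it (the published wording
does not say whether 0.05 is a single branch, a depth, or a separation; the
patristic reading is the implemented interpretation and the threshold is
configurable). Negative NJ branch lengths (only possible for non-additive
inputs) are clamped to zero with the deficit moved to the sibling edge; on
additive matrices the tree reproduces the input distances exactly, which the
tests assert to 1e-9.

Families are the connected components of the relation "patristic distance
< 0.05 OR shared fraction ≥ 0.10": two genomes are split only when they are
both phylogenetically divergent *and* genomically distinct, matching the dual
criterion. A pair sharing exactly 10% stays together (the published
distinctness condition is strictly "< 10%"). Component labels take the
lexicographically smallest member, making the partition order-invariant.

## Abundance and co-abundance

Per-sample abundances are mean coverage depths, zeroed when breadth
(fraction of positions at depth ≥ 1) is ≤ 0.25 — the inclusive reading of
"< 1x across ≥ 75% of the genome". Mean depths are scaled by 100 and rounded
to integer pseudo-counts so Dirichlet resampling is defined; whether the
published correlations were computed on raw depths or transformed values is
not stated, so this transform is an explicit, configurable decision.

`sparcc_correlations()` implements the SparCC estimator: per estimation
iteration (default 20), fractions are resampled from a per-sample Dirichlet
posterior (counts + 1); log-ratio variances t_ij = Var log(x_i/x_j) are
converted to basis variances ω by solving the SparCC linear system; the
strongest-correlated pair above 0.1 is iteratively excluded and the system
re-solved (≤ 10 rounds; skipped below 4 taxa, where exclusion makes the
system singular — the 3-taxon case is exactly determined and serves as the
closed-form oracle in the tests). The final estimate is the entrywise median.
Taxa with identical counts in every sample have no correlation signal and are
reported `NA`, never fabricated.

Significance uses the permutation bootstrap: each of 1,000 iterations permutes
every taxon's counts independently across samples and recomputes ρ with a
single estimation iteration; p = (exceedance count)/1,000, so "p < 0.001"
means zero exceedances. An optional `(count+1)/(n+1)` estimator is available
behind a flag; the strict count/n default matches the published reading.

A known statistical property follows directly: per null pair the p-value is
approximately uniform, so a network over m pairs is expected to retain about
m/1,000 false edges at the 0.001 cutoff. With 45 pairs per 10-taxon dataset
this is ~0.05 false edges per dataset — small but not zero, and occasionally a
dataset contains a pair whose *empirical* sample correlation is genuinely
extreme (|r| ≈ 0.25 at n = 200 has nominal p < 0.001), which every faithful
implementation of the procedure will retain. The validation suite documents
one such case; it is inherent to the published procedure, not a defect of this
implementation.

## The synthetic communities

`synthesize_study_community()` fixes the validation conditions: 20 phage
genomes of 201–300 kb and 5 contaminants; two phages rebuilt with codes 15 and
90; one carrying the synthetic crAss markers in frame; proteomes planted with
3 families (7/7/6 genomes, within-family sharing 0.6, between 0); 10 directed
spacer edges (4 exact, 4 with one mismatch, 2 negatives with two interior
mismatches that must stay unrecovered); and a 20-taxon x 200-sample
compositional count matrix with 4 planted log-scale correlations of ±0.9
(3 positive, 1 negative) at total depth 1e5 per sample, where multinomial
resampling noise is small against the planted effects.

Generator choices worth knowing:

* Backgrounds are gene-structured (dense genes under code 11 with short random
  gaps), not uniform random nucleotides: coding-dense sequence is what real
  contigs look like, and uniform random sequence sits close to the
  alternative-code density margin by construction (removing a stop codon from
  the stop set lengthens random ORFs substantially), which would make the
  planted code labels meaningless.
* Planted regions are laid out in zones (gene annotations in the first 60% of
  each genome, protospacers read from 30–60%, arrays and markers written from
  65% onward behind a per-genome cursor) so plants never overwrite each other.
* Spacer sets are re-drawn when all spacers in an array would share a first or
  last base, and array flanks get guard bases: otherwise the repeat boundary
  is ambiguous by one position and detection could legitimately return
  shifted spacers. Mismatches are planted away from the clippable spacer ends
  so the coverage rule cannot cancel them.
* Orthologue copies mutate each residue at 1%, keeping planted pairs ≥ 95%
  identical with overwhelming probability, per the planted-orthology contract.
* Self-validation at generation time (on by default) re-detects each planted
  signal with an independent check: keyword/BUSCO margins for labels, 4-code
  density recomputation for recoded genomes.

What passing the suite shows — and does not. The generator plants signals with
margins that respect the decision thresholds (BUSCO 30% vs 6.7%; density gains
~19% vs 10%; sharing 0.6/0.0 vs 0.10), so perfect recovery demonstrates that
the rules are implemented correctly, boundaries included, not that the
thresholds are optimal for real data. The communities have no sequencing
error, no strain variation, no partial genes, phylogenetically unrealistic
proteins, and iid backgrounds; sensitivity on real contigs will be governed by
annotation quality and assembly completeness, which are out of scope here.

## Problem sizes and determinism

The reference validation uses 25 genomes of 201–300 kb, 25-protein proteomes,
200 samples and 1,000 bootstrap iterations; the full pipeline runs in a few
minutes on one CPU, and every stage is a pure function of (inputs, config,
seed) — re-running with the same seed reproduces outputs byte for byte. The
stages that consume randomness (Dirichlet resampling, bootstrap permutation,
all generators) take explicit seeds.

## Known limitations

* Keyword matching is substring-based; product-text conventions differ across
  annotation pipelines.
* The nucleotide viral signature is a stub unless a model is supplied.
* Karlin–Altschul parameters are ungapped while alignments are gapped; E-values
  are therefore conservative approximations, adequate at the 1e-5/1e-10
  thresholds used.
* The NJ proteomic tree is a surrogate for a maximum-likelihood tree; the 0.05
  demarcation on patristic distance is an interpretation, kept configurable.
* Array detection assumes exact repeat copies (the generator plants exact
  copies); degenerate repeats would need a consensus-tolerant extension.
* SparCC exclusion is skipped below 4 taxa, and the bootstrap inherits the
  multiple-testing behaviour described above.
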
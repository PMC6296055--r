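---
title: "Models and methods for variant prioritization in augmented references"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for variant prioritization in augmented references}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varprior)
```

## The problem

Augmenting a linear reference genome with known population variants reduces
reference bias and recovers alignments that would otherwise be penalized at
non-reference alleles. But inclusion is not free: each added variant
multiplies the allele combinations representable in its neighborhood, and a
variant whose alternate allele recreates sequence already present elsewhere
makes the reference *more* repetitive and alignment *more* ambiguous.
`varprior` scores each variant in a catalog for this benefit/cost tradeoff,
selects an optimal subset under a user budget, and emits the artifacts a
downstream aligner needs.

## Localized s-mers and window probabilities

All models work on *localized s-mers* ⟨s, l⟩: length-`s` sequences anchored
at a genome offset `l`, realized by some combination of REF/ALT alleles of
the variants starting in `[l, l + s)`. The probability that a random
individual's window at `l` reads σ factorizes as
`p(σ) = p_l · p_s(σ)`, with a uniform offset prior `p_l = 1/W`.

Two numerical choices here are deliberate:

* **W is the number of valid window offsets**, `Σ_chrom max(0, len − s + 1)`
  minus offsets whose reference window contains N — not the genome length.
  With this convention the combination probabilities at every offset sum to
  exactly 1, and the population coverage of the complete augmented genome is
  exactly 1 rather than approximately so.
* **N handling**: windows containing N are excluded from counting, from W,
  and from probability sums; assembly gaps would otherwise dominate
  multiplicity statistics.
* **Strand**: counting is forward-strand only; the genome model is
  single-stranded. Strand-collapsed (canonical) counting would change
  multiplicities near reverse-complement repeats; we do not attempt it.

`p_s` is the independence product of allele frequencies, or, when a phased
haplotype panel is available, the fraction of panel haplotypes whose alleles
match the combination at every window variant (allele co-occurrence). When a
window holds more variants than the enumeration cap `k_cap` (default 15),
the capped-out variants are held at REF in the sequence and *marginalized
out* of `p_s`, keeping the per-offset normalization exact. The cap set is
the same everywhere — leftmost variant plus the `k_cap − 1` highest-AF
others — so s-mer counting and enhanced-segment construction agree on one
blowup policy.

## The three models

**Population coverage.** `C(G) = Σ p(⟨s,l⟩)` over the s-mers representable
by an augmented genome G. Under the *complete-graph assumption* — scoring
each variant as if all others are already included, which is what makes a
single static score list possible — the coverage lost by removing a variant
is proportional to its allele frequency, so the Pop Cov model scores each
variant by its raw AF. Phasing is irrelevant here: the complete graph covers
every haplotype. Indels are supported (no sequence enumeration is needed).

**Uniqueness.** `U(G) = Σ 1/f_G(seq)` over s-mer occurrences, where `f_G`
is the occurrence's multiplicity. The sum telescopes to the number of
distinct sequences — which the implementation exploits as a self-test — and
it is exposed as a genome statistic only: almost all variants add only
unique s-mers, so uniqueness alone cannot rank them.

**Hybrid.** `H(G) = Σ p(⟨s,l⟩)/f_G(seq)` weights each occurrence's
probability by the reciprocal of its multiplicity. A variant's score is the
sum, over every ALT-carrying s-mer overlapping it, of
`ΔH = (p − ā)/(n + 1)`, where `n` is the number of *other* occurrences of
the same sequence in the complete augmented genome and `ā` their average
probability. Computing `ā` exactly for every occurrence is quadratic, so it
is approximated by a weighted average of two pre-computed constants: the
mean probability of reference s-mers (`p̄_ref`) and of ALT-containing
s-mers (`p̄_*`), weighted by how many of the sequence's occurrences are of
each kind. Two ambiguities were settled as follows:

* The printed weighted average divides by `f_G*(seq)` — the multiplicity
  *including* the candidate occurrence. `hybrid_delta()` implements this as
  its default and offers `avg_denom = "n"` (candidate excluded) as a
  sensitivity switch.
* `p̄_*` and `p̄_ref` are global means over all chromosomes, not
  per-chromosome values.

The hybrid model is SNV-only (indels are a hard error); the Pop Cov model
is the one to use for catalogs with indels. Phased panel probabilities are
used when available, because unlike Pop Cov the hybrid sum weights terms by
their realized frequency in the population.

`score_hybrid_exact()` is a brute-force oracle: it evaluates
`H(G*) − H(G* ∖ v)` by direct enumeration (algebraically reorganized around
per-sequence aggregates, which is exact). One approximation is inherited:
the per-window cap sets of the complete graph are held fixed for the
leave-one-out genome, since re-deriving them per variant would change which
*other* variants get enumerated. On the package's standard 10 kb / 200-SNV /
20%-repeat fixture the approximate and exact scores agree to rank
correlation 1.0, and exactly (to 1e−9) for every variant whose ALT s-mers
are unique — the regime covering the vast majority of real variants.

## Selection with blowup avoidance

Variants are ranked by descending score, ties broken by chromosome order
then offset (one tie-break authority, applied at selection time only).
The `+` variants of the models add dynamic re-scoring: when a variant is
selected, every unselected variant within `s` nt (between start positions,
same chromosome, symmetric) has its current score multiplied by `w`
(default 0.5). Penalties accumulate multiplicatively when several selected
neighbors hit the same candidate — the literal reading of re-scoring on
each addition; the alternative (one penalty per candidate) is not
implemented. `w = 1` reduces to static ranking; `w = 0` is accepted as a
diagnostic mode that provably exhausts isolated positive-score variants
before touching any neighbor, with zero-score candidates remaining
selectable afterwards in tie-break order.

The selector uses a lazy binary max-heap: since penalties only ever lower
scores, a popped entry whose recorded score is stale is simply re-pushed at
its current score. The test suite verifies the heap path against a
recompute-argmax-each-step oracle on 2000-variant catalogs for
`w ∈ {0, 0.25, 0.5, 1}`.

Fractional budgets are interpreted against the catalog after multi-allelic
splitting, rounded to the nearest integer with a floor of one.

## Enhanced segments and the major-allele baseline

The enhanced-reference representation appends, for every combination of
nearby ALT alleles, a reference substring carrying those alleles plus
`r − 1` flanking bases, so a linear aligner can match any read overlapping
them. A cluster of n co-windowed variants needs `2^n − 1` segments; the
builder anchors each segment at its leftmost ALT so that every subset is
emitted exactly once (deduplication across overlapping windows) and every
variant is covered through its own anchor even when the per-window cap
discards it from a neighbor's set. Segment flanks are clipped at chromosome
ends, never padded with invented sequence. The co-window relation uses
start positions within `r − 1` bases; indel lengths do not extend it.

The major-allele reference applies an ALT wherever it is strictly more
frequent than the reference allele (biallelic: AF > 0.5, ties keep REF;
multi-allelic: the most frequent of REF and all ALTs). Indel edits shift
downstream coordinates; the shift at each applied edit is recorded in a
3-column offset map. Records whose REF no longer matches are skipped with a
warning, which makes the transform idempotent.

## The synthetic-data generator

Fixtures emulate the structure of a population callset on a small genome:
i.i.d. uniform sequence with a tunable fraction overwritten by copies of
earlier blocks (block length ≥ 2s, planting non-unique s-mers); variant
positions with a tunable clustering rate (probability of landing within `s`
of the previous variant); a target AF per site drawn from a configurable
spectrum (uniform, Beta, or a rare-heavy "spiked" mixture of 90% Beta(1,9)
and 10% Uniform(0.5,1)); and H haplotypes carrying the ALT independently
with that probability. The *realized* panel fraction — not the target — is
written as the AF INFO value, so phased and unphased marginals agree by
construction and the AF/panel consistency invariant is testable at 1e−9.

The standard study conditions used throughout the tests and the acceptance
script are: 10 kb genome, 20% planted repeats, 200 SNVs, H = 20 phased
haplotypes, s = 25, uniform AF spectrum. These sizes keep full enumeration
(every offset × every allele combination) exact and fast while still
exercising repeat collisions and clustered windows. What the generator does
*not* emulate: linkage disequilibrium beyond what finite-panel sampling
induces, mutation-rate heterogeneity, structural variants, N-gap
distribution of real assemblies, and transition/transversion bias. Passing
tests therefore demonstrate correctness of the models and algorithms, not
performance claims about any particular organism's callset.

Each generator seeds R's RNG deterministically from the fixture seed (the
panel generator uses seed + 1 so it is reproducible standalone), and the
bundle writer embeds the seed in every output filename next to a JSON
sidecar of the spec.

## Degenerate inputs and edge rules

* Chromosomes shorter than `s` contribute no windows (warning, not error).
* REF-mismatching VCF records are dropped and counted, never repaired;
  symbolic ALTs and overlapping indels are likewise rejected with warnings.
* Zero-AF records are retained and score 0.
* Unphased genotypes anywhere disable the panel genome-wide (warning).
* Multi-allelic records are split into independent biallelic records before
  scoring; fraction budgets count the split records.
* A window that would enumerate more than 2^20 combinations is a hard error
  with the locus reported.

## Limitations

The greedy selector is not a joint optimizer — the method is greedy by
construction. The ERG builder constructs segments for alignment-style use
but does not index or align. Paired-end window logic is out of scope: there
is no practical single choice of window length spanning both read and
fragment scales for the segment representation. Hybrid scoring of indels is
unsupported by design; Pop Cov covers that case.
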
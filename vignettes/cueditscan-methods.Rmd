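---
title: "Methods: stem-loop rules, sequence forests and the C>U variant pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stem-loop rules, sequence forests and the C>U variant pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cueditscan)
```

## The biological model

APOBEC3A and APOBEC3G deaminate cytosines in single-stranded RNA, with a
strong preference for cytosines presented at the terminus of a 3–4 nt
hairpin loop closed by a GC-rich stem. `cueditscan` operationalizes that
substrate preference twice: once as an interpretable integer score over
explicitly enumerated hairpins, and once as a random forest over a binary
encoding of the local sequence. Both predictors consume the same unit of
data, a `site_window`: the cytosine with 15 nt upstream and 10 nt
downstream context.

## The rules-based scorer

For a window, candidate hairpins place the cytosine at a loop terminus
(loop length 3, then 4) and extend the stem outward from the loop
boundary, classifying G·C and A·U Watson–Crick pairs and stopping at the
first disallowed mismatch. The total is

\[
S = 3\,n_{GC} + n_{AU}
  + 2\,[\text{U in loop} \lor \text{purine 5' of C}]
  - 2\,[\text{G in loop}],
\]

maximised over all candidate structures; a site is called when $S > 9$
(an integer score of at least 10). Decisions worth spelling out:

* **Loop-terminus convention.** The substrate literature describes the
  edited C at the 3′ end of the loop, while the scorer could equally be
  anchored at the 5′ end; the two conventions genuinely differ in which
  structures they enumerate. Both are implemented
  (`convention = "three_prime"` (default) or `"five_prime"`), and the
  oracle-equivalence tests cover both.
* **The mismatch allowance.** One mismatch or bulge is tolerated at the
  position two nucleotides 5′ of the scored C, counted in sequence space.
  Under the `three_prime` convention that position falls inside the loop,
  so the allowance is inert; under `five_prime` it is the second stem
  pair, and the search branches into a paired mismatch, a 5′-arm bulge
  and a 3′-arm bulge, keeping each viable extension as a distinct call.
* **Wobble pairs.** G·U pairs score nothing and terminate extension: the
  scoring formula names only G·C and A·U.
* **Bonus semantics.** The +2 is awarded at most once even when both the
  U-in-loop and purine-5′ conditions hold; the scored C itself is not
  evidence for the loop-composition bonuses. Both +2 and −2 may apply,
  netting zero.
* **Ties and caps.** Equal-scoring calls prefer loop length 3, then the
  longer stem, then the 5′-most loop start (this affects only the
  reported structure, never the total). Stem length is capped at 15
  pairs, unreachable inside a 26-nt window.
* **Sequence ends.** Windows truncated by a sequence end are padded with
  U and flagged; padding keeps genome-wide scans total while letting
  callers exclude flagged sites. Padding U can participate in spurious
  A·U pairs at window edges — a documented, deliberate simplification.

The implementation is a recursive outward extension with branching only
at the permitted offset. Its correctness is checked against an
independent brute-force enumeration (all loop placements × all stem
lengths × all mismatch/bulge options as explicit index arithmetic) on
10^4 seeded random windows per convention.

## The random forest

Each window is encoded position-major (−15…−1, +1…+10), two bits per
nucleotide — `isPurine`, then `pairsGC`: A=(1,0), G=(1,1), C=(0,1),
U=(0,0) — yielding 50 features; the encoding is bijective on
{A,C,G,U} so unpadded windows round-trip exactly. Padding U encodes
(0,0), i.e. zero evidence.

Editing sites are rare (the realistic ratio is roughly 1:468), so the
training design is imbalance-aware: all positives are kept and negatives
are downsampled to `neg_pos_ratio` per positive (default 3), with half of
them (default) drawn from "hard" negatives whose rules total is at least
6 — the forest thus spends its capacity where the rules model is nearly
fooled. The hard-score threshold of 6 and the 500-tree /
$\sqrt{p}$-features-per-split forest are declared defaults, exposed in
`training_config()`. SMOTE-style minority interpolation is implemented
(a small k-nearest-neighbour interpolator over the bit vectors) but off
by default: downsampling plus hard negatives is the primary strategy.
The probability threshold is strictly greater than 0.5.

## Consensus and benchmarking

Union and intersection consensus are literal set operations on the two
boolean calls — no score blending. Consequently recall(union) ≥
recall(either primary) ≥ recall(intersection) on any labeled set, which
the acceptance suite asserts.

The harness builds two evaluation sets: the *testing* set (the held-out
30% of a stratified 70/30 split, at 1:3) and the *proportional* set,
which keeps the same positives and tops negatives up to 1:468 from a
disjoint pool (leakage against the training set is an error). Because
positives are shared, recall of any fixed classifier is identical on the
two sets. Point metrics use the standard closed forms with zero-
denominator cases reported as `NA` with a warning, never silently as 0 —
on tiny predicted sets a 0 would flatter precision. Curves sweep the
unique score values; the rules model's no-structure sentinel ranks below
every integer score, which caps its maximum recall. AUROC is trapezoidal
(and is cross-checked against the Mann–Whitney statistic and pROC in the
tests); AUPRC is the step-wise, non-interpolated average precision, with
the prevalence as its baseline. The redundancy audit computes pairwise
identity over the 25-nt contexts and reports the fractions of pairs above
75% (≥19/25 positions) and 30% identity.

## What the synthetic data emulate — and what they do not

`make_site()` plants positives as hairpins with `stem_len` pairs (default
5), a configurable G·C fraction (default 0.7), a 3-nt loop with a planted
U, embedded in uniform-composition background (25% per base); negatives
are background around a C, optionally rejection-sampled until the rules
total is below threshold. These defaults give a mean rules-score
separation of well over 5 points, so planted positives are nearly
perfectly recoverable — by design: the generators exist to verify the
machinery (determinism, set algebra, metric formulas, pipeline plumbing),
not to re-create the difficulty of curated editing data. Real editing
sites overlap real non-sites in sequence space; passing tests on planted
motifs therefore say nothing quantitative about recall or precision on
biological data, and the package deliberately reports benchmark numbers
only for the synthetic conditions that produced them.

`make_variant_table()` emits a ClinVar-`variant_summary`-dialect table
plus matching CCDS-style coding sequences. Every C>U row owns an
11-codon block whose 26-nt site window lies entirely inside the block, so
predicted rows (a planted 4-G·C-pair UUC-loop hairpin, total 14) and
unpredicted rows (block rejection-sampled below threshold) are decided
locally and deterministically. Decoy rows exercise every exclusion path:
non-SNV type, GRCh37 duplicates, non-specific and like-to-like alleles,
missing or synonymous protein change, a gene without a coding sequence, a
reference-codon mismatch, an unreachable alternate amino acid, and
deliberately ambiguous codons (UGG→Ter is reachable by G>A at two
positions).

`variant_spec_mirror()` freezes a reduced-scale count set (~1/20 of the
published study) chosen so that every reported percentage — computed
half-up to one decimal from the counts — equals its full-scale
counterpart. A literal 1/100 scaling cannot do this (the printed counts
are not divisible by 100 and small denominators shift the rounded
percentages), so the counts were solved for once and frozen: 30,411
exonic rows, 5,033 C>U (16.5%) splitting 955/467/3,611 across
pathogenic/benign/unspecified (19.0/9.3/71.7%), 229 predicted (4.5%)
splitting 52/21/156 (22.7/9.2/68.1%), with per-bin prediction rates
5.4/4.5/4.3%.

## The variant pipeline

Filters run in a fixed order (SNV type, GRCh38, per-allele
deduplication, specific alleles, not like-to-like, non-synonymous protein
change), each logging in/out counts. Genes without a usable coding
sequence are excluded wholesale; individual records whose reference amino
acid is not coded at the claimed codon are dropped. The mRNA change is
inferred codon-first: the substitutions of the reference codon reaching
the recorded alternate amino acid are intersected with the genomic allele
pair read on *both* strands (the input does not declare strand); a unique
survivor fixes the coding-sequence position and base change, multiple
survivors are flagged ambiguous and kept out of the C>U set, and no
survivor drops the record as inconsistent. Significance binning is a
case-insensitive *word* match — "pathogenic" then "benign" then
unspecified — so "Conflicting interpretations of pathogenicity" does not
leak into the pathogenic bin via the substring. Reported percentages are
always recomputed from counts, half-up to one decimal.

The pipeline's prediction step is model-selectable. The union model is
the default for analysis (it is the most sensitive); the fixture
round-trip in the acceptance suite runs the deterministic rules-based
caller instead, because exact count reproduction requires a caller with
no training stochasticity — the fixture plants sites the rules model
decides, and a trained forest's occasional extra positive would shift
the marginals. A separate test asserts that union predictions contain
the rules predictions on the same fixture.

## MeSH rollup

The hierarchy is a table of terms with dotted tree numbers; levels are
minimum tree-number depth, and orphan numbers are rejected at load. The
condition→term mapping is an input artifact, reflecting externally
curated (and inherently irreproducible) human judgment; a non-empty
qualifier column invalidates a mapping to "Not found", and unmapped
conditions roll up to the reserved top-level pseudo-term "Not found".
Each top-level heading counts at most once per variant regardless of how
many of the variant's conditions fall under it; multi-tree descriptors
count once per distinct top-level heading. Third-level terms
(grandchildren of top-level terms) proxy individual diseases: a term is
covered by a site set if any site maps to it or to any descendant, and
coverage percentages divide by the number of genuine third-level
descendants (terms with none yield `NA`).

## Problem sizes and numerical conventions

The test and acceptance workloads use 10^4-window oracle suites, a
200-positive 1:3 training benchmark with a 60-positive 1:468 proportional
evaluation (28,140 sites), and the ~30k-row mirror fixture; together they
run in a few minutes on one CPU. All randomness flows through explicit
seeds (`with_seed` restores the caller's RNG state), derived child seeds
stay below 2^31, and every generator is byte-reproducible for a given
seed. Percentages round half-up (base R's round-half-even would mis-state
e.g. 22.75%); curve integration conventions are fixed as above so
reported areas are comparable across runs.

## Known limitations

* The rules grammar is single-hairpin only: no multiloops, pseudoknots or
  thermodynamic folding; a cytosine in a strong fold that is not a simple
  terminal-loop hairpin scores as unstructured.
* The forest's features see only the 25-nt window; longer-range structure
  is invisible to it.
* Synthetic benchmarks overstate separability (above); metrics on them
  are machinery checks, not biological performance estimates.
* The pipeline trusts the recorded protein change; records with correct
  alleles but erroneous HGVS annotations are dropped or mis-placed rather
  than rescued.
* Strand is inferred per record from codon/allele consistency, not from
  an annotation; genes where both strand readings are consistent surface
  as ambiguous rather than being resolved.
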
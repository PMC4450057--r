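---
title: "Identifying cis-spliced fusion RNAs between adjacent genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying cis-spliced fusion RNAs between adjacent genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cissage)
```

## The problem

RNA polymerase II occasionally reads through a gene's terminator into the
downstream gene. When the resulting precursor is spliced so that exons of
the upstream gene join exons of the downstream gene, the product is a
chimeric mRNA created without any change to the DNA — *cis*-splicing
between adjacent genes (cis-SAGe), also called read-through or
conjoined-gene fusion. Fusion callers applied to RNA-seq report such
chimeras alongside genuine rearrangement products, trans-splicing products
and artifacts. Because a read-through chimera requires its parental genes
to be same-strand immediate neighbors, while a deletion or translocation
does not, genomic context plus orthogonal evidence can separate the
classes. `cissage` codifies that reasoning as a reproducible pipeline.

Two observations drive the design. First, the insulator-binding factor
CTCF suppresses read-through between neighbors, so silencing CTCF
*induces* cis-SAGe chimeras while trans-splicing products tend to go
*down* — the direction of response under knockdown is diagnostic. Second,
validated cis-SAGe events show strong positional regularities: the
parental genes are unusually close (all under 30 kb in the motivating
cohort against a genome median near 54 kb), and the junction preferentially
joins the *second-to-last* exon of the 5′ gene to the *second* exon of the
3′ gene (the "2–2" configuration), the second exon being the nearest one
carrying a splice acceptor.

## Classification

A call with parental genes $g_5, g_3$ is classified against the
annotation:

* `INTERCHR` — different chromosomes;
* `INTRACHR_SS_0GAP` — same chromosome and strand, **no** gene of either
  strand overlapping the open intergenic interval, and $g_5$
  transcriptionally upstream of $g_3$;
* `INTRACHR_OTHER` — everything else on one chromosome, with a recorded
  reason (`different-strand`, `intervening-gene`, `reversed-order`).

Two genuinely open choices are resolved as follows. A same-strand adjacent
pair reported in reverse transcriptional order is *not* a read-through
candidate — polymerase does not run backwards — so it is classed
`INTRACHR_OTHER` with the `reversed-order` annotation rather than being
silently flipped. Overlapping same-strand neighbors are kept in the
zero-gap class at distance 0, since "zero gap" names the category and
read-through across an overlap is physically possible.

The intervening-gene test uses the open interval between the upstream
gene's end and the downstream gene's start: any other gene, on either
strand, overlapping that interval by at least 1 bp disqualifies immediacy.
Genes overlapping only the pair's own bodies (e.g. an antisense gene
nested inside one partner) do not count unless they extend into the gap.
This matches the behavior needed for pairs eliminated because a small
gene sits between the partners.

## The six-criteria cascade

Candidate `INTRACHR_SS_0GAP` pairs pass through six stages in a fixed
order; a pair's `eliminated_at` is its first failing stage:

| stage | evidence | passing value | default threshold |
|---|---|---|---|
| `sanger_confirmed` | junction RT-PCR + Sanger flag | Y | — |
| `immediate_neighbor` | annotation | Y | ≥ 1 bp gap overlap disqualifies |
| `interstitial_deletion` | CNV segment track (log₂ ratio) | **N** | log₂ ≤ −0.3, ≥ 1 bp overlap |
| `ctcf_binding` | peak track over the intergenic gap | Y | ≥ 1 peak, ≥ 1 bp overlap |
| `sictcf_induced` | expression under knockdown vs control | Y | FC ≥ 1.5 |
| `intergenic_transcript` | coverage track or RT-PCR flag | Y | mean ≥ 1.0; flag wins |

Notes on the less obvious rows. The deletion column's polarity is
inverted on purpose: `N` (no deletion) is the *passing* value, because a
deletion would explain the chimera at the DNA level. The −0.3 log₂ cutoff
is the common single-copy-loss heuristic; it is configurable because
deletion evidence in practice often rests on visual inspection of array
segmentations of varying noise. The fold change uses a pseudocount
(default 0.01) in both numerator and denominator so zero expression stays
defined. The 1.5-fold threshold applies in both directions: FC ≥ 1.5 is
`induced`, FC ≤ 1/1.5 is `down`, anything else `unchanged`; only `induced`
passes. An `NA` at a stage the pair is still active in eliminates the pair
with a logged warning — a conservative choice; in the shipped 48-pair
fixture blanks occur only after an earlier elimination, so this rule never
fires there.

Because the cascade is a pure conjunction, the final set is independent of
stage order; only the `eliminated_at` labels and per-stage survivor counts
depend on it. The test suite asserts both facts.

Junction-read support is made comparable to gene-level FPKM via
$\mathrm{FPKM} = r / (L_e \cdot N)$ with $r$ junction reads, $L_e$ the
effective junction length in kb and $N$ the library size in millions of
fragments. The default $L_e = 2(\ell - a)/1000$ (read length $\ell$ = 101,
minimum anchor $a$ = 8) is the span of junction-detectable fragment
placements; it is configurable because the appropriate value depends on
the caller's anchor rule. A fusion contributing ≥ 10% of its parental
gene's FPKM is flagged as a significant fraction.

## Characterization statistics

**KS comparisons.** The two-sample statistic is computed exactly as the
maximum empirical-CDF gap over the pooled points; the p-value uses the
asymptotic two-sample Smirnov series
$p = 2\sum_{k\ge1}(-1)^{k-1}\exp(-2k^2 n_e D^2)$,
$n_e = n_1 n_2/(n_1+n_2)$, truncated at $k=100$ (terms decay as
$e^{-2k^2}$, so the truncation error is far below double precision). No
small-sample exact tables are used: at cohort sizes of 16–32 genes the
p-value is approximate either way, and ties (integer distances) make the
exact distribution inapplicable. The statistic agrees with the standard
implementation to machine precision; p-values agree to ~1e−5, the
reference's own series tolerance.

**Exon-2 usage test.** Under the null, each 3′ parental gene $i$ with
$E_i$ exons contributes a fused exon drawn uniformly from $1..E_i$, so the
number $K$ of genes entering at the target rank (default 2) is
Poisson-binomial with $p_i = 1/E_i$ (0 if $E_i$ is below the target rank).
The package reports both a simulated tail (10,000 replicates by default,
seeded) and the exact tail by convolving the per-gene distributions — the
exact value is the reference answer, the simulation is retained because a
resampling readout is the field's habit and the two validate each other.
Exon 1 stays in the null support because observed cohorts do include
first-exon junctions; a stricter "acceptor-bearing exons only" null
($2..E_i$) is available via `acceptor_only = TRUE`.

**Coding impact.** On the canonical transcripts, the donor junction's
transcript coordinate $j_5$ and the 3′ acceptor's $j_3$ are compared with
the CDS intervals. If either junction point lies outside its CDS (5′ or 3′
UTR) the chimera leaves protein coding untouched (`NR`); this includes
acceptors upstream of the 3′ CDS start, which retain the entire downstream
CDS. Otherwise the retained coding length $j_5 - c_5$ is compared mod 3
with the acceptor's offset into its CDS $j_3 - c_3$: equal residues are
`in_frame`, unequal `out_of_frame`. Junction points strictly inside a CDS
but off an exon boundary are refused as non-canonical rather than guessed.
The arithmetic is performed in transcript coordinates, making it strand
invariant; the suite checks a mirrored minus-strand construction against
the plus-strand case.

## Candidate prediction

The four rules are applied to every same-strand immediate neighbor pair:
distance strictly < 30 kb (the quoted rule is "less than"; the boundary
case is excluded and the cutoff is configurable), 5′ gene FPKM strictly
> 1, and — on by default — both canonical transcripts multi-exonic so the
2–2 junction exists; disabling the multi-exon requirement reproduces the
bare distance-and-expression pair count. Expression is required of the 5′
gene only, since read-through initiates from the 5′ promoter; requiring 3′
expression is optional. The predicted junction joins the
transcription-order 3′ edge of the 5′ gene's backward-rank-2 exon to the
5′ edge of the 3′ gene's forward-rank-2 exon; the two exon spans are
emitted as amplicon targets for primer design done elsewhere.

## Coordinates, ranks and tolerances

Internally all intervals are 0-based half-open; GTF I/O converts to/from
1-based inclusive, BED-like tracks stay 0-based. Fusion TSV positions are
1-based junction bases (the last transcribed base of the donor exon, the
first of the acceptor) and are converted on read, strand-aware. Exon ranks
count in transcription order from either end, so forward + backward =
exon count + 1 on both strands. Junction-to-exon matching is exact on
boundaries; positions within a 5 bp slack of a boundary are matched but
flagged non-canonical, positions farther away get no rank and are excluded
from histograms with a warning and a reported count.

The canonical transcript of a gene is the one with the most exons, ties
broken by the longest genomic span, then the lexicographically smallest
id — a deterministic stand-in for curated canonical sets, which
annotation releases do not always provide.

## The synthetic-data generator

`simulate_annotation()` lays out non-overlapping genes per chromosome with
(defaults): 12% single-exon genes, multi-exon counts 2 + Poisson(3.5)
(mode near 5), log-normal exon lengths (median 150 bp), intron lengths
(median 1.5 kb) and intergenic gaps (median 54 kb, log-sd 1.2), strands
i.i.d. with probability 0.5. These values were chosen once to mirror the
qualitative background shapes a mammalian annotation shows — the
single-exon mass, the secondary exon-count mode, and a same-strand
neighbor spacing whose median sits well above the 30 kb rule — so that
planted cis-SAGe pairs produce the expected KS contrast.

`plant_events()` places, by default, 16 true cis-SAGe events (same-strand
immediate pairs, gap in [1 kb, 30 kb), both genes ≥ 4 exons) of which
round(11/16 · n) get the deterministic 2–2 junction and the rest random
valid exon pairs; plus decoys: 5 deletion-driven, 13 trans-like
(knockdown-repressed), 5 interchromosomal. Planted pairs are selected
gene-disjoint so the evidence intervals of different events cannot
interact. `simulate_tracks_and_expression()` then emits tracks that are
*consistent by construction*: copy-number losses only under
deletion-driven fused-exon intervals, CTCF peaks in the gaps of cis-SAGe
and trans-like pairs, above-threshold intergenic coverage only for
cis-SAGe pairs, and fold changes of 2.5 / 0.4 / 1.0 for
cis-SAGe / trans-like / deletion-driven fusions. Noise affects nuisance
quantities only (peak scores, baseline expression, neutral log₂ jitter),
not the evidence polarity, so default-configuration recovery is exact:
sensitivity and specificity 1.0, with each decoy failing at the stage its
mechanism dictates.

What passing these tests shows — and does not. They verify that the
classification logic, interval arithmetic, cascade bookkeeping and
statistics do exactly what they claim on data whose ground truth is known.
They do not establish performance on real cohorts, where junction
evidence is noisy, annotations disagree with transcription, CNV
segmentations are uncertain, flags can be wrong, and the evidence
polarities are not clean — robustness to such noise is a property of the
evidence, not of this implementation.

## Problem sizes and determinism

The default simulated genome is 4 chromosomes × 500 genes (2,000 genes,
~10,000 exons), large enough for stable background distributions and
hundreds of eligible neighbor pairs while keeping a full pipeline run in
tens of seconds; tests use 150–300-gene genomes where genome scale is not
the point. Every stochastic component (generator, exon-usage simulation,
candidate sampling) takes an explicit seed, saves and restores the global
RNG state, and is reproducible run-to-run; pipeline outputs are stamped
with a configuration fingerprint and the seed.

## Known limitations

* Annotation-tied genome-wide numbers (same-strand pair counts under
  30 kb, median neighbor spacing, background KS statistics) depend on the
  annotation release supplied; the package computes them for whatever
  annotation it is given rather than shipping reference values.
* The cascade treats evidence as per-pair and independent; it does not
  model shared intergenic regions of overlapping candidate pairs.
* Coding impact is computed on canonical transcripts only and refuses
  non-boundary junctions instead of modeling novel splice sites.
* The candidate rules are necessary-style filters tuned for recall of the
  canonical 2–2 configuration; they do not score or rank candidates.
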
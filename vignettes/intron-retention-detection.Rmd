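---
title: "Detecting retained introns from poly-A RNA-seq"
author: "intread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting retained introns from poly-A RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intread)
```

## The problem and the model

Most splicing tools ask whether an intron is *differentially* spliced
between conditions; `intread` instead profiles, in a single sample, every
intron for which retention can be established unambiguously. The
observation model is simple: if an intron is retained in a detectable
fraction of a gene's mature transcripts, sequencing fragments will (a) fall
inside the intron at a rate proportional to the retained isoform's
abundance, (b) be spread roughly uniformly along the intron, because the
retained intron is a contiguous part of the mRNA, and (c) straddle the
exon–intron boundaries. Spliced transcripts, by contrast, contribute only
gapped alignments whose skipped region spans the intron and which therefore
never physically overlap it.

Two failure modes motivate the design. First, an "intron" of one isoform
may be an exon of another isoform or of an overlapping gene; intronic reads
there prove nothing. We therefore restrict attention to **independent
introns**: the exons of *all* isoforms of *all* genes are merged and
subtracted from each gene's span, and only the remaining intervals are
scored. By default the exon union ignores strand, because unstranded poly-A
libraries cannot attribute a read to a strand; `stranded = TRUE` relaxes
this for stranded protocols. Second, localized pile-ups (mispriming,
repeats, unannotated small RNAs) can mimic intronic expression. The
**normalized entropy score** targets exactly this: the intron is divided
into 8 near-equal bins, the per-bin fragment counts are normalized to a
probability distribution, and its Shannon entropy is divided by
`log2(8) = 3`. Flat coverage gives NE near 1; a pile-up concentrated in one
or two bins gives a small NE and is rejected.

## Counting rules

A *fragment* is the unit of evidence: a read pair counts once (its junction
status is the OR of its mates), a single-end read counts once. Aligned
blocks are derived from the CIGAR: `N` gaps split blocks (the gap is not
covered — this is what makes counting splice-aware), `D` deletions keep the
reference covered, and `I/S/H` consume no reference. Secondary and
supplementary alignments are excluded; duplicates are kept (no
deduplication is assumed) and no mapping-quality filter is applied unless
requested — both defaults can be changed via `min_mapq` and upstream
filtering. A fragment may legitimately count toward two adjacent introns.

A fragment is a **junction** fragment for an intron when one of its blocks
has at least 1 aligned bp on each side of an intron boundary. No minimum
overhang is imposed: one base on either side is the weakest reading
consistent with the definition, and the junction filter's default (J ≥ 1)
is interpreted against it.

Each (fragment, intron) pair increments exactly one of the 8 bins — the bin
containing the midpoint of the fragment's intersection with the intron.
This keeps the bin counts integers summing to T, so the normalized bin
distribution is a true probability mass function over fragments. Bin `k`
covers `[start + floor((k-1)L/8), start + floor(kL/8))`; the widths differ
by at most 1 bp and tile the intron exactly. Introns shorter than 8 bp are
dropped at derivation since they cannot support 8 bins.

## Filters and their defaults

| filter | default | units | rationale |
|---|---|---|---|
| `min_total` (T) | 20 | fragments | enough evidence for a stable NE-score |
| `min_junction` (J) | 1 | fragments | direct boundary evidence |
| `min_fpkm` | 3 | FPKM | requires non-trivial intronic expression |
| `min_ne` | 0.9 | — | rejects clumped, artifactual coverage |

All comparisons are inclusive. The defaults are deliberately strict: they
select conservative, high-confidence retention events and trade recall for
precision. `FPKM = T·10⁹ / (length · library_size)`; the library size is
the total number of primary mapped fragments, either supplied (`-t` on the
command line, `library_size=` in R) or counted from the file. NE thresholds
above 1 are permitted and simply reject everything, which gives a cheap
"call nothing" switch.

Degenerate inputs: an intron with T = 0 has an all-zero bin vector, whose
entropy is defined as 0 here; such introns can never be called retained
even with all thresholds at 0. Ties in any ranking (e.g. equal FPKM) are
broken by intron id, so every ordering in the package is deterministic.

## What the simulator emulates

`simulate_ir_dataset()` builds a toy genome — by default 500 genes on 4
chromosomes, 3–7 exons of 100–300 bp, introns of 250–2500 bp, 1–3 isoforms
per gene (extra isoforms skip internal exons) — and designates a fraction
(default 0.3) of the independent introns as retained. Retained introns
emit contiguous fragments whose positions are uniform across the intron,
with counts drawn Poisson around a log-uniform FPKM target (default
0.2–30); spliced transcripts emit fragments in transcript coordinates that
map back to gapped alignments whose N-gaps exactly span their introns.
Reads are 75 bp, fragments 200 ± 30 bp, paired by default. The declared
library size (default 2·10⁷ fragments) plays the role of the full
sequencing run from which the simulated loci are a slice; it is used for
the truth FPKM and should be passed to the detector, exactly as one passes
`-t` for a real alignment subset. These values were chosen once as a
realistic desk-scale portrait of a mammalian poly-A library; at that scale
an intron at the FPKM default threshold of 3 carries on the order of a
hundred fragments, so the entropy filter operates in its stable regime.

Ground-truth counts are derived from the coordinates of the emitted reads
by the simulator's own arithmetic (not by the BAM-parsing detection path),
and the tiered gold standards follow the classic construction: an intron
enters a tier when its true FPKM clears a floor (0.1 / 0.3 / 0.5 for
GS1/GS2/GS3) and it has at least 10 fragments and at least one junction
fragment. GS3 ⊆ GS2 ⊆ GS1 by construction.

The simulator intentionally omits sequencing errors, quality variation, GC
and 3′ bias, multi-mapping, and novel splice isoforms; SEQ fields are
homopolymers because the detector never reads base content. Passing tests
on simulated data therefore validates the *counting, scoring and decision
logic* — they say nothing about alignment artifacts in real data, which
enter upstream of this package.

A `clumped` mode concentrates retained-intron fragments in the first
quarter of the intron, producing exactly the pathological coverage the
NE-score is designed to reject; it is used to exercise that rejection.

## Evaluation machinery

For benchmarking against a second caller whose score is supplied
externally, the package implements: top-`N = min(N₁, N₂)` comparison of
FPKM-ranked call lists; precision/recall against a gold standard; ROC/AUC
as the Mann–Whitney rank statistic (ties count one half); an integrated
score `S = (S₁ + S₂)/2` where each `Sₖ` is the log2-transformed,
standardized (zero mean, unit sample variance) raw score over the introns
scored by *both* methods; and the performance improvement ratio
`PIR = (AUC_integrated − AUC_mean)/AUC_mean`. Because standardization
removes any multiplicative constant from the log scores, the integrated
score is invariant to rescaling of either input. Introns with a
non-positive raw score are excluded from integration by default (a
pseudocount option exists). ROC labels are taken over all introns that
received a score; restricting negatives to expressed introns is a
legitimate alternative we did not adopt, since it makes the AUC depend on
an arbitrary expression floor.

## Numerical and design choices

- Coordinates are 0-based half-open internally and in BED output; GTF input
  (1-based closed) is converted on parse. This makes BED round-trips
  byte-exact.
- GTF parsing is a small dedicated parser so that malformed lines and
  exons lacking `transcript_id` fail with line-numbered errors; interval
  algebra is delegated to GenomicRanges/IRanges, alignment access to
  Rsamtools/GenomicAlignments.
- The whole alignment file is streamed once (no index needed); per-intron
  assignment is a single overlap join, so output is independent of record
  order and of the worker-count flag, which is accepted for interface
  compatibility.
- Intron ids are self-describing, `"<gene>-<chrom>:<start>-<end>"`, so
  parent-gene attribution survives a round trip through BED.
- Table output uses 6 significant digits; the retained flag is the literal
  `yes`/`no`.

## Problem sizes and limitations

The test suite and the acceptance script run entirely on simulated data:
~500 genes (~2,000 independent introns, ~200,000 fragments) for the
precision benchmark, 6–60 genes for unit and property tests, with fixed
seeds throughout — sizes chosen so the whole suite exercises every code
path in minutes on one core. Known limitations: no CRAM input, no
strand-specific counting, no per-base coverage output, and retention calls
in a single sample are not significance statements — downstream
differential analysis should be done with count-based tools on the T
column.
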
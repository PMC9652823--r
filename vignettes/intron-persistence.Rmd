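---
title: "Intron persistence from long reads: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intron persistence from long reads: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripbench)
```

## The problem

Short-read RNA-seq cannot tell whether an intronic signal comes from a
mature transcript that genuinely retained the intron, from a pre-mRNA
molecule caught before splicing finished, or from stochastic one-off
splicing noise. Long reads observe the whole molecule, so the splicing
state of *every* intron in a read is visible at once. `ripbench` exploits
this to build a noise-aware retention metric and to use it as a reference
against which short-read retained-intron (RI) callers can be scored.

## The model

Each long read assigned to transcript $t$ contributes a row of the
retention matrix with states *spliced* (the intron is a skip gap of the
alignment), *retained* (the aligned span wholly contains the intron, which
is not spliced out), or *uncovered*. For intron $i$,

$$P_{i,t} = d_i \cdot \frac{1}{|M^t|} \sum_{r \in M^t} R_{r,i}\,
            SF_{r,i}\, H_{r,i},
\qquad P_i = \max_{t \ni i} P_{i,t},$$

with $d_i$ the fraction of assigned reads covering $i$, $R_{r,i}$ the
binary retention indicator, $SF_{r,i}$ the fraction of introns spliced in
the read with the target excluded, and $H_{r,i}$ the mean pattern agreement
with reads sharing $r$'s state at $i$ over jointly covered introns. The
three modifiers shrink plain intron PSI (which is $d_i$-weighted mean
$R$) toward zero exactly in the situations where PSI overcalls retention:
low coverage of the intron ($d_i$), molecules early in splicing
progression ($SF$), and discordant one-off patterns ($H$).

Assumptions worth stating explicitly:

- **Annotation-bound.** Reads whose intron chain contains any interval not
  present in an annotated isoform are discarded; unannotated isoforms are
  invisible.
- **Exact junctions.** Chain matching uses exact coordinate equality; there
  is no fuzz window for wobbly splice sites.
- **Best-match assignment.** Exact intron-set matches beat subset
  ("skipped splicing") matches; among candidates the transcript whose
  exonic length is closest to the read's exonic footprint wins, with
  lexicographic id as the deterministic tie-break. An unspliced read is a
  subset match to every same-strand transcript and is resolved by length
  alone — a documented consequence of pooling candidates across genes.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `min_reads_per_transcript` | 5 | reads | minimum evidence for per-transcript persistence; transcripts below it are skipped |
| `persistent_threshold` | 0.1 | — | inclusive cutoff defining a persistent intron |
| `mean_denominator` | `assigned` | — | the displayed defining equation divides by all assigned reads; `spanning` divides by reads covering the target (the reading suggested by the Methods prose); both supported, default follows the displayed equation |
| `sf_single_intron_value` | 1 | — | $SF$ is 0/0 for a read spanning only the target; such a read carries no contrary splicing evidence, so 1; set 0 for a conservative variant |
| `end_tolerance` | 50 | bases | slack allowed between a full-length read's aligned ends and the transcript's annotated ends in target-gene selection |
| coverage floor | 2 | reads/base | median gene-wide short-read coverage required of target genes |
| windows | 300/100/0–4300 | bases | sliding intron-length performance windows (41 windows) |
| `min_tools` | 3 | tools | consensus rule for truth-category groups |
| profile bins | 1000 | bins | per-intron normalized coverage profile resolution |

The query read is a member of its own Hamming comparison set (its
self-similarity is 1 by construction); this follows the summation domain of
the defining formula. The comparison set never contains a read pair with no
jointly covered intron, because every member spans the target.

## Numerical choices

- **Weighted median** (used for LWM harmonization and gene coverage
  medians): scores sorted ascending, first score whose cumulative weight
  reaches half the total; an exact half split returns the midpoint of the
  straddling scores, so equal weights reproduce the ordinary median.
- **Persistence arithmetic** is double precision with the final value
  clamped to $[0,1]$; the test suite checks it against an exact
  rational-arithmetic nested-loop oracle to $10^{-12}$ on random matrices.
- **Undefined ratios** (precision with no positive calls, recall with no
  persistent introns, F1 when either is undefined, Fleiss' kappa when
  expected agreement is 1) are reported as missing (`NA`), never as 0.
- **Coordinates** are 0-based half-open internally; GTF is converted from
  1-based closed at parse time, BED/bedGraph pass through; IRanges is used
  purely as an overlap engine behind the conversion.
- **log10 profiles** add a pseudocount of 1 before the transform (zero
  handling is otherwise undefined); minus-strand introns are *not* flipped
  in the 1000-bin profiles — the axis is 5'→3' on the positive genomic
  strand by convention.
- **Ties** everywhere break deterministically (lexicographic transcript
  id), and `run-all` is byte-identical across reruns at a fixed seed.

## What the simulator emulates — and what it does not

`simulation_config()` describes a stated world: genes laid along one
chromosome on alternating strands; each gene's primary isoform carries 3–5
introns with canonical GT–AG motifs; additional isoforms skip one internal
exon (creating the intron-over-exon overlaps the feature annotation must
handle). Each unique intron draws a retention probability $\rho_i$ from a
background in which 76.7% of introns are never retained and 0.13% always
are — the shape reported for real persistence distributions — with the
remainder uniform. Reads are sampled per transcript (default 50):

- **mature** molecules splice each intron independently with probability
  $1-\rho_i$;
- **pre-mRNA** molecules (default 20%, reflecting the estimate that up to a
  fifth of splicing completes post-transcriptionally) retain a contiguous
  3' run of introns — splicing progressed 5'→3' to a uniform stopping
  point (a `random_subset` alternative is available);
- **partial** reads (default 10%) truncate at a uniform molecule position
  from a uniformly chosen end.

Mock callers call persistent introns with configurable sensitivity and
non-persistent ones at one minus specificity, drawing scores and auxiliary
columns above or below each shipped rule's thresholds so the rule
reproduces the drawn call. One caveat: records sit exactly on universe
introns, so on universes with *overlapping* introns (exon-skipping
isoforms) the length-weighted median legitimately mixes neighboring
records and calls need not round-trip; exact round-tripping is guaranteed
only on non-overlapping universes, which is how the perfect-caller
acceptance check is constructed.

Not emulated: sequencing error (indels, chimeras), primer/barcode
artifacts, empirical Iso-Seq read-length distributions, multi-chromosome
genomes, expression-level variation between genes. A green test therefore
establishes algorithmic correctness on idealized alignments, not robustness
to alignment noise.

## Design decisions that were genuinely open

- **Denominator of the persistence mean** — see the parameter table; both
  readings are exposed rather than silently choosing one.
- **Relative position of a single-intron transcript** is 0.5: a one-point
  scale has no orientation, and either endpoint would be arbitrary.
- **"Other transcripts" in exon overlap** includes same-gene isoforms and
  other genes alike; the overlap statistics are about the ambiguity of the
  intronic interval, not gene structure.
- **Inter-rater universe for Fleiss' kappa** is every harmonized intron,
  including introns no tool called: all-negative rows carry information
  about expected agreement.
- **Consensus categories are counted independently**: an intron TP under
  some tools and FP under others contributes to both counts.
- **"Potential" RIs** are introns with any overlapping expression evidence
  (LWM present); no per-tool expression floor is applied.
- **iREAD sample profiles** (`strict`: FPKM ≥ 3, fragments ≥ 20;
  `lenient`: ≥ 1 / ≥ 10) are configuration profiles selected with
  `--profile`, not hard-coded per sample.

## Limitations

Persistence is relative to the annotation and to long-read depth: shallow
transcripts (under 5 reads) are silently absent, and the metric only
partially compensates for mixed cell populations. The harmonization by
length-weighted medians is deliberately stringent and can inflate false
negatives where caller scores are high-variance over long ranges. The
benchmark scores *calling rules applied to harmonized scores*, not the
callers' native end-to-end pipelines.

## A minimal run

```{r example, eval = FALSE}
cfg <- simulation_config(n_genes = 8, seed = 7)
sim <- simulate_dataset(cfg)
assignments <- assign_reads(sim$reads, sim$tx_set)
res <- persistence_pipeline(sim$reads, assignments, sim$tx_set)
harm <- harmonize_calls(unique(res$introns[, .(chrom, start, end, strand)]),
                        sim$caller$calls)
threshold_sweep(res$introns, harm)
```

Every number shown in the README's worked example is the actual output of
this pipeline at the seed given there; the package reports nothing it does
not compute.
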
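---
title: "Detecting fusion transcripts and genomic breakpoints with fusegraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fusion transcripts and genomic breakpoints with fusegraph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusegraph)
```

## The problem

Classical fusion-gene detectors restrict their search space to annotated
exons and splice junctions — the territory of poly(A)-selected RNA-seq.
Ribosomal-depleted (rRNA-minus) total-RNA libraries, however, retain
pre-mRNA: a large fraction of their reads is intronic, and reads crossing a
*genomic breakpoint* inside an intron are directly observable. A detector
that treats the whole genome as search space can therefore recover two
distinct layers of information from one RNA-seq sample:

* **exonic junctions** — products of splicing between (possibly cryptic,
  possibly intergenic) exon boundaries: the classical fusion-mRNA signal;
* **intronic junctions** — junctions that are *not* products of splicing;
  they span the genomic breakpoint itself, typically carried by pre-mRNA
  reads.

The label encodes mechanism (splicing vs breakage), not location. In
particular, a genomic breakpoint that happens to fall inside an exon is
still labelled intronic: nothing was spliced to produce it. Keeping the two
layers separate is the central design constraint of this package — the same
rearrangement usually manifests as one junction of each kind, a few hundred
nucleotides apart, and they must end up as two calls under one event rather
than one blurred call.

## The breakpoint-graph model

Input is a coordinate-addressable alignment file containing chimeric
(discordant) records from a splice-aware aligner: split reads (one read
aligned in two arms), read pairs with inverted orientation, oversized
insert, or mates on different chromosomes. Each fragment is reduced to a
pair of **breakends**. A breakend is an oriented genomic position: the
coordinate of the *last retained aligned base* plus the side
(`left`/`right`) of the genome that survives in the derivative allele.
Internally all coordinates are 0-based half-open; every report file is
1-based inclusive.

Evidence is aggregated into a graph whose nodes are breakends and whose
edges accumulate typed counts between two breakends:

* split reads give base-precise breakends (weight `w_split = 3`),
* spanning pairs give interval-precise breakends with uncertainty up to the
  insert-size bound (weight `w_spanning = 1`),
* the edge score is `w_split * n_split + w_spanning * n_spanning`, and a
  junction needs `min_reads >= 2` fragments — single-read junctions are
  never reported. The default score threshold of 6 corresponds to two split
  reads, or one split read plus three spanning pairs.

Split-derived edges are provisionally typed `splice_like` when the junction
context reads as a canonical splice motif (GT..AG, optionally GC..AG and
AT..AC, plus their minus-strand genome views) or both breakends sit on
annotated exon boundaries; otherwise `genomic`. The two types are kept as
separate edges even between identical positions, so that splice evidence
and breakage evidence never blend before event analysis.

### Merging interval evidence into base-precise nodes

Spanning breakends within **strictly less than 450 nt** (the insert-size
bound, configurable) of a split breakend with the same retained side are
absorbed into the split node; the base-precise position wins, counts are
summed, and base-precise nodes are never moved. Two refinements matter in
practice:

* merging is **edge-aware first**: a spanning-only edge whose two endpoints
  both fit one split-supported edge is snapped onto that edge as a whole.
  Deciding each endpoint independently can tear one fragment's support
  between two adjacent junctions of the same event;
* **head-to-tail evidence merges only with head-to-tail evidence**. The
  head-to-tail class is defined geometrically — both breakends on one
  chromosome with the acceptor (right-retaining) breakend upstream of the
  donor (left-retaining) one — so back-splice split reads and everted
  spanning pairs share a class, and neither ever merges with a linear
  junction. This keeps back-splices (circRNA) apart from everything except
  small tandem duplications, which genuinely share the geometry.

Head-to-tail split reads are ordinary base-precise split evidence for
counting and scoring; `n_head_to_tail` records how many supporting
fragments have the geometry rather than forming a third, unscored class
(which would make every back-splice junction unreportable).

### Events, splice variants, consensus

Clusters of edges connected through shared breakends, or through
within-window breakends on the same chromosome pair with compatible
orientation, form **events**. Orientation compatibility (identical retained
sides after canonical ordering) is what keeps hot-spot regions from
collapsing into one mega-event. Within an event, splice-like edges sharing
one breakend are splice isoforms (one donor to alternative acceptors) and
stay separate calls under one `event_id`; evidence is never double-counted.

The consensus position of a call is the split-read mode, ties to the
smallest coordinate. Base-precise members collapse within a 5-nt jitter
window; interval-precise (spanning-only) members collapse within the merge
window, because their positions are interval bounds scattered within the
insert size. A spanning-only call reports the midpoint of its uncertainty
interval along with the interval width.

### Filters

All failing reasons are reported, not just the first:
`insufficient_reads` (< 2 fragments), `no_split_support` (spanning-only
while `min_split > 0`), `low_start_diversity` (fraction of distinct
fragment start signatures below 0.5 — a stack of identically placed reads
is an artefact signature; the signature is the joint start of both arms,
since for head-to-tail junctions one arm starts exactly at the breakend by
geometry), and `nonstandard_contig` (`chrUn_*`, `*_alt`, `*_random`).

### Classification and annotation

A call is **exonic** iff both breakends lie within 2 nt (tolerance for
aligner jitter) of annotated exon boundaries with splice-consistent sides,
or — in motif mode with a reference — both flanks read as a canonical
splice motif. The motif route admits *cryptic exons*, including intergenic
ones. Everything else is intronic, including in-exon genomic breakpoints
and interval-precise calls. Gene annotation uses gene spans (first to last
exon); intergenic status is `both_in_gene` / `one_intergenic` /
`both_intergenic`; for unstranded libraries membership ignores gene strand.
Head-to-tail calls can additionally be matched against a back-splice
catalogue at **0-nt tolerance** — catalogue concordance is exact by
definition.

## Cohort-level utilities

* `match_junction_sets()` compares two junction sets (e.g. RNA junctions vs
  WGS breakpoints): both sides must agree within **40 nt inclusive**;
  head-to-tail junctions and alternate-locus contigs are excluded up front,
  and the comparison can be restricted to interchromosomal junctions to
  avoid artefacts of RNA post-processing. Assignment is greedy
  nearest-pair — deterministic and adequate at realistic junction
  densities; a bipartite-optimal matcher would change nothing at the
  distances involved.
* `bin_junction_density()` bins both endpoints of every non-circRNA
  junction and reports the Pearson correlation between two tracks.
* `split_cohort_by_locus()` calls a sample *mutant* iff it has one or more
  passing junctions with a breakend inside the locus;
  `chromosomal_de()` then tests every gene on the locus's chromosome and
  plots at the gene's genomic center, `(start + end) / 2`.

### The differential-expression engine

The DE contract is per-gene log2 fold change (mutant vs wild-type) plus
Benjamini–Hochberg q-values from a count-appropriate test. It is
implemented self-contained: total-count normalization to the geometric-mean
library size; tagwise NB dispersion by a pooled moment estimator shrunk
toward the cohort median with prior weight 10; a conditional
negative-binomial exact-style test on the group sums (the conditional
probability of the observed group-1 sum given the total, two-sided by
summing all outcomes at most as probable); `p.adjust(method = "BH")`.
Sums are enumerated within ±25 SD of the conditional mean — the truncated
mass is far below double precision. logFC uses a 0.5 pseudo-count. The
implementation tracks an established exact-test implementation closely
(logFC correlation > 0.99 in the cross-check test) while keeping the
package dependency-light; groups below two samples are refused.

## The simulator

`sim_spec()` defaults define the test conditions: 4 contigs of 500 kb, 48
genes (5 exons of 160 nt, 700-nt introns; every fourth gene on the minus
strand), 20 events mixed over deletions (0.35), translocations (0.25),
inversions (0.15), tandem duplications (0.10) and back-splices (0.15); 30
split + 20 spanning reads per event, 200 noise chimeras; 126-nt stranded
paired-end reads with 300–600-nt fragments — the geometry of the HiSeq
libraries this detector is aimed at. `pre_mrna_fraction` emulates library
chemistry: ~0.01 for poly(A)+ (splicing-only signal), ~0.35 for rRNA-minus
(pre-mRNA rich), following the well-known 30–40% vs 5–10% intronic read
fractions of the two protocols.

Design choices worth knowing:

* splice motifs are baked into the reference at every generated intron
  (GT..AG; genome view CT..AC for minus-strand genes), so motif-mode
  classification is exercised against real sequence;
* genomic breakpoints of expressed events are planted 50–300 nt into the
  introns flanking the fused exons. Real breakpoints can sit much deeper in
  long introns; placing them near the exon keeps the exonic and intronic
  junction of one event within the 450-nt linkage window, which is the
  stated event-linkage rule, and models the clinically typical case of
  breakpoint hot spots near recurrently fused exons;
* breakpoint draws whose flanks would by chance read as a splice-motif pair
  (~0.8% of draws) are rejected, so the planted truth labels are clean;
* expressed fusions are planted between plus-strand genes; minus-strand
  genes act as annotation decoys. Inversions and tandem duplications are
  genomic-only events; back-splices are expressed head-to-tail exon
  junctions with a catalogue entry;
* noise is alignment-level (uniform random arm pairs), not base-error
  level: the detector consumes alignments, and mapping ambiguity is the
  operative confounder. Noise chimeras carry one read each and are
  eliminated by the >1-read rule;
* everything is a pure function of the spec's seed — identical FASTA, GTF,
  SAM bytes on re-run.

What the simulator does **not** emulate: quality scores, PCR duplicates,
FFPE degradation, alignment errors at real repeat structures, deep-intron
breakpoints beyond the linkage window, and expression-level variation
between events. A perfect score on simulated data therefore demonstrates
the correctness of the graph/cluster/classification machinery, not
real-data performance.

`score_against_truth()` applies the 40-nt matching rule between calls and
planted truths. A truth junction whose marginal support was merged into a
passing junction less than 450 nt away with the same orientation is counted
as *absorbed* and credited to recall — the behaviour expected when a weakly
covered genomic breakpoint sits next to a dominant splice junction, where
the breakpoint-spanning reads are present but reported under the adjacent
junction.

## Worked example

```{r example, eval = FALSE}
library(fusegraph)

run <- simulate_run(sim_spec(seed = 1), dir = tempfile())
calls <- detect_junctions(run$paths$sam,
                          gene_models = run$models,
                          reference = run$reference$sequences,
                          circ_catalogue = run$catalogue)
passing_junctions(calls)
score_against_truth(calls, run$truths)
```

## Problem sizes and numerical choices

The shipped test-suite and acceptance runs use the default 2-Mb genome with
~2,400 simulated fragments per run, ten scaled-down replicate pairs
(300-kb contigs, 10 events) for the library-contrast property, and
2,000-gene, 20+20-sample cohorts for DE — sizes chosen so a complete run
stays in the minutes range on a laptop core while every code path is
exercised. Ties are broken to the smallest coordinate throughout;
empty inputs yield empty, well-typed results; region queries on unindexed
files, unknown contigs, mixed genome builds and undersized DE groups raise
explicit errors rather than guessing.

## Known limitations

* No reconstruction of multi-breakpoint derivative alleles (poly-fusions):
  events are reported junction-wise under a shared `event_id`.
* Junctions supported only by concordant coverage shifts are out of scope;
  the detector consumes discordant records exclusively.
* The event-linkage window ties exonic and intronic junctions of one event
  only when the genomic breakpoint lies within the insert-size window of
  the splice junction; deeper breakpoints yield two events.
* Reading frames, protein consequences and neo-antigen prediction are not
  addressed.
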
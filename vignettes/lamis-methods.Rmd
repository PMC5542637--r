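---
title: "Integration-site analysis for LAM-PCR vector safety studies: models and methods"
author: "lamis package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integration-site analysis for LAM-PCR vector safety studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamis)
```

## The problem

Gene-therapy vectors based on adeno-associated virus (AAV) persist mostly
as episomes, but a fraction of vector genomes integrates into host
chromosomes. Long-term safety surveillance of treated subjects therefore
asks three questions of sequencing data derived from linear
amplification-mediated PCR (LAM-PCR) of tissue biopsies:

1. *Where* did the vector integrate (integration sites, IS), and are any
   clones expanding (clonal abundance)?
2. How much of the amplified material reflects *vector-vector*
   (concatemeric, episomal) junctions rather than genuine vector-genome
   junctions?
3. Do the recovered sites cluster in chromosomal hotspots or fall into
   cancer-related genes more often than random expectation?

`lamis` implements this analysis as a verifiable pipeline. Because
real LAM-PCR datasets from such studies are rarely deposited, the package
ships a simulator that generates reads from *known, planted* integration
events, so every stage -- junction classification, mapping, site
collapsing, clonality, and the null-model statistics -- can be checked
against ground truth.

## The LAM-PCR amplicon model

LAM-PCR anchors on a vector-specific primer, linearly amplifies across
the vector-genome junction, truncates the product at the first
restriction site (here the 4-cutters MseI, `T^TAA`, and MluCI, `^AATT`),
ligates a linker, and re-amplifies with nested primers. The in-silico
consequences the simulator reproduces are:

* an **IS amplicon** is `vector segment (anchor..terminus) + genomic
  flank truncated at the first MseI/MluCI cut + linker`;
* a **concatemer amplicon** is `vector segment + downstream vector copy`,
  entered according to the junction kind (head-to-tail: the forward
  vector from its start; head-to-head: the reverse complement of the
  vector terminus region; tail-to-tail: the reverse complement of the
  vector start region);
* a junction with **no restriction site** within `max_flank` yields no
  ligatable product and emits no reads -- such events are structurally
  unrecoverable by the assay, which the truth table records;
* reads are the first `read_length` bases of the amplicon with i.i.d.
  substitution errors; reads are allocated to amplicons multinomially in
  proportion to clone abundance.

Only the sense strand read from the vector primer is modelled: LAM-PCR
reads are anchored single-direction amplicons, so paired-end structure
adds nothing at this level of abstraction. Indels and PCR/chimera
artifacts are deliberately out of scope; substitution errors dominate
the Illumina error profile that matters for anchor and seed matching.

## Study conditions emulated by the generator defaults

The defaults describe a desk-scale analogue of a serial-biopsy vector
safety study:

| parameter | default | rationale |
|---|---|---|
| genome | 2 chromosomes, 1 Mb each | large enough that 16-mers are effectively unique, small enough for seconds-scale runs |
| GC content | 0.41 | mammalian-like |
| genes | 60 non-overlapping, 5-15 kb | about 30% genic fraction, so distance bins are all populated |
| cancer fraction | 0.3 | in-cancer-gene null fraction lands near 9%, the scale reported for curated cancer-gene unions |
| events | 200 | same order as the site counts recovered in long-term studies, with headroom for partition tests |
| depth | 20,000 reads | enough that multinomial noise on composition percentages is well below a percentage point |
| read length | 150 nt | MiSeq-class single reads |
| error rate | 0.002/base | Illumina substitution scale |
| abundance | log-series, theta = 0.95 | strongly skewed clone sizes, as in semiquantitative clonality plots |
| max_flank | 1,000 nt | beyond this, linear amplification of a 4-cutter-free flank is unrealistic |
| min_fragment | 20 nt | below this, a genomic fragment is not reliably mappable on a megabase-scale genome |

The simulator emulates what the wet-lab protocol makes visible in
silico. It does **not** emulate PCR efficiency bias, chimeric
amplicons, restriction-site polymorphism, or quality-score decay, so a
passing test suite demonstrates the correctness of the *computational*
pipeline under the stated read model -- not robustness to every artifact
of real libraries.

## Junction classification

Reads are quality-filtered (length, N fraction), then classified:

* no vector anchor (up to 2 mismatches, leftmost occurrence) →
  `unclassified`;
* anchor present, and the sequence following the vector terminus matches
  the vector in either orientation → `concatemer`;
* otherwise the linker prefix (10 nt, up to 1 mismatch) is trimmed and
  the remaining genomic fragment is an `IS` call if it reaches
  `min_fragment`, else `internal`.

The concatemer test uses an exact 12-mer (`k_vec = 12`,
`concat_mismatches = 0`). This pairing is a deliberate design choice:
at k = 12 an exact match against the ~480 vector positions (both
orientations) has a chance-collision probability of roughly 3e-5 per
junction, whereas allowing one mismatch inflates it to about 1e-3 --
enough to misroute one or two genuine IS junctions per few hundred
events into the concatemer bin. The asymmetric cost settles the choice:
a concatemer read that slips past the exact check (because a sequencing
error fell in its first 12 post-terminus bases, about 2.4% of
concatemer reads at the default error rate) carries vector sequence as
its "fragment", maps nowhere on the genome, and is dropped as
`unmapped` -- it can never create a false integration site. A genuine
IS read misrouted to the concatemer bin, by contrast, silently deletes
evidence of a real site. Both `k_vec` and the budget are configurable.

Classification is exhaustive and mutually exclusive: on every input,
`|IS| + |concatemer| + |internal| + |unclassified|` equals the number of
filtered reads, mirroring the exhaustive unique/multi accounting that
site tables report downstream.

## Mapping and the unique/multi partition

A full genome aligner is deliberately not used: at toy-genome scale an
exact k-mer index (default k = 16) with ungapped seed-and-extend is
transparent, dependency-free and fast, and its behaviour is provable
against a brute-force full-scan aligner, which the test suite does for
fragments up to 60 nt. Fragments are seeded with tiled k-mers in both
orientations, extended ungapped, and scored by `identity x aligned
length`; hits below 95% identity or 20 aligned bases are discarded.
Gapped alignments are treated as unmapped, acceptable at simulator
error rates.

Uniqueness is resolved with a score margin (default 5): a best hit
beating the runner-up by at least the margin is `unique`; otherwise the
fragment is `multi` with `n_best` co-optimal loci. The two clauses of
the rule meet at exact equality; `lamis` resolves the boundary in
favour of `unique` (margin reached = separated). The junction
coordinate reported for minus-strand placements is the reference
position of the junction-adjacent base, not the alignment start, so
plus and minus reads of the same event collapse to the same site.

## Sites, clonality and composition

Unique junctions within 3 bp on the same chromosome and strand collapse
into one site (single linkage; the site position is the modal member
position, ties to the smallest). The 3 bp window absorbs alignment
jitter from sequencing errors near fragment edges; collapsing is
idempotent. Multi-mapped fragments are excluded from clonality
quantification, which reports each site's read count relative to all
uniquely mapped IS reads -- the semiquantitative clone-size proxy used
in serial-biopsy studies (restriction-based LAM-PCR has no
sonication-length diversity to correct abundance with).

Per-sample summaries report `pct_is` and `pct_concatemer` as
percentages of vector-positive reads (IS + concatemer); they sum to 100
whenever any vector-positive reads exist and are reported as `NA`, not
zero, otherwise. Site persistence across serial biopsies is assessed by
re-clustering pooled site tables across time points with the same
window.

## Null models and statistics

The null comparison dataset (`random_null`) contains, by default, 8,628
random positions -- matching the scale such synthetic random datasets
are generated at -- drawn either uniformly over the genome (the default,
mirroring how published comparisons are described) or uniformly over
MseI/MluCI cut positions (`site_matched`), which models the recovery
bias of restriction-based LAM-PCR and is offered as a documented
deviation option.

All comparative questions reduce to 2x2 tables tested with Fisher's
exact test. The two-sided p-value is the sum of hypergeometric
probabilities (computed with `stats::dhyper`) of all tables with the
observed margins whose probability does not exceed the observed table's
(relative tolerance 1e-7 for floating-point ties); the test suite
verifies this against full enumeration from binomial coefficients on
every table with total up to 60, and against `stats::fisher.test`.

* **Chromosomal hotspots**: per chromosome, on/off-chromosome counts of
  sample vs null, Benjamini-Hochberg adjusted across chromosomes
  (configurable: none/Bonferroni/BH; BH is the field default and the
  published analyses report no correction method). A chromosome is a
  hotspot when `q < alpha`.
* **Gene context**: positions are binned by distance to the nearest
  gene span (inside, <=10 kb, 10-100 kb, >100 kb by default);
  distributions are compared per-bin (Fisher + BH) or globally
  (chi-square).
* **Cancer-gene enrichment**: in/out counts of sample sites and null
  positions within cancer-flagged gene spans (gene body by default; a
  promoter-extension window is configurable). Strand is ignored in all
  enrichment tests; the questions are position-based.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; BED is
  native, GFF3 is converted on read. The strand of an IS is the
  orientation of the genomic flank relative to the reference plus
  strand.
* k-mer codes are 2-bit packed into doubles (exact up to k = 26);
  N-containing windows are never indexed, and N bases are accepted in
  input genomes but not produced by the generator.
* An all-zero 2x2 table, an empty site list, a single time point for
  persistence, and a site-matched null on a site-free genome are
  errors, not silent zeros; a sample with no vector-positive reads
  reports undefined (NA) percentages rather than 0.
* Odds ratios with a 0/0 structure are NA.
* Event positions keep a `max_flank` margin from chromosome ends so
  flank extraction is always defined; hotspot windows must intersect
  the plantable region.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full chain on a 2 Mb,
2-chromosome genome with 200 events at depth 20,000 (error-free for the
exact-recovery contracts), a 20-event duplicated-segment scenario for
the multi-mapping partition, a 70/30 IS/concatemer mixture at depth
20,000 for composition accounting, an exhaustive Fisher sweep over all
635,375 tables with total <= 60, and 200 replicate seeds each for the
hotspot type-I and power properties. These sizes were chosen so each
property is measured with comfortable statistical margin while the
whole suite stays in the minutes range on a single core.

## Known limitations

* The mapper is exact-seed, ungapped: indel-containing fragments and
  repeat structures beyond a planted exact duplication are out of
  scope; on real macaque-scale genomes a production aligner (e.g. BLAT
  or bwa) would stand behind the same `map_fragments` interface.
* Read counts are a semiquantitative clonality proxy; no UMI or
  sonication-based correction is modelled.
* The cancer-gene flag is a user-supplied list; the precise curated
  unions used in published analyses are not recoverable, so enrichment
  conclusions depend on the list provided.
* The hotspot scan is per-chromosome, not a sliding-window common
  insertion site (CIS) detector; fine-scale clustering below chromosome
  resolution requires other methods.

## A worked run

```{r run, eval = FALSE}
cfg <- pipeline_config(outdir = "lamis_out", seed = 42)
run_pipeline(cfg, stage = "all")
```

This writes the genome, annotation, reads and truth table, the junction
calls, mapped junctions, collapsed and annotated site table, the
Table-style sample summary, the null dataset, the hotspot scan,
gene-context and cancer-enrichment results, a plain-text report and one
manifest per stage (parameters, seed, package version, output
checksums). Re-running with the same configuration reproduces every
artifact byte-identically.
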
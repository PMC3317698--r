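---
title: "Small RNA miRNA discovery with miRglean: models and methods"
author: "miRglean authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small RNA miRNA discovery with miRglean}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRglean)
```

# Overview

miRglean implements the standard desk analysis of a plant small RNA
sequencing library: quality-scored short reads (16–30 nt inserts) are
cleaned and collapsed into unique tags; tags are classified against an
ncRNA contaminant catalog; survivors are assigned to known mature
miRNAs by mismatch-bounded matching; still-unannotated tags are mapped
to a genome, candidate precursors are excised and folded, and hairpins
passing plant miRNA annotation criteria become novel miRNA calls, with
miRNA\* read support recorded where a sequenced tag matches the duplex
partner. Downstream, miRNA–transcript complementarity is scored with a
seed-weighted penalty scheme, and qRT-PCR CT tables are summarized as
ΔCT values.

Because real libraries, genomes and catalog databases are large and
version-bound, the package ships a first-class synthetic data
generator: it plants pre-miRNA hairpins and ncRNA loci in a random
genome, simulates a quality-scored read library, and keeps a truth
ledger so every stage can be scored for precision and recall.

# Read cleaning

Reads pass three whole-read filters, in this order: 3′ adapter
trimming, the N/quality filter, and the 16–30 nt length window
(inclusive at both ends). Adapter trimming removes the longest read
suffix matching a prefix of the adapter with at least 6 nt of overlap
and at most one substitution per 7 nt of overlap; reads that are
entirely adapter are tallied as adapter dimers, and reads without a
recognizable adapter pass through to the length filter, which removes
read-through artifacts.

The quality filter rejects a read if it contains an ambiguous base, if
more than 4 bases fall below Q10, or if more than 6 bases fall in the
Q10–Q12 band. The two thresholds deliberately count *disjoint* quality
bands: with a cumulative count, a read sitting exactly at both stated
limits (4 bases at Q9 plus 6 bases at Q12) could never pass, because
the 4 sub-Q10 bases would also count against the sub-Q13 limit. The
banded reading keeps both boundary cases meaningful, and the test suite
pins the filter exactly at those boundaries. Qualities default to
Phred+33; the offset is a parameter for legacy Phred+64 data.

Clean reads are collapsed into unique tags (`SmallRNATagSet`), sorted
by descending count then sequence, and the `QcReport` enforces two
conservation invariants: raw reads = clean reads + rejections, and the
length histogram sums to the clean-read count. No read can be silently
lost or double-counted.

# Annotation cascade

Tags ending in ≥ 8 consecutive A or composed of ≥ 80% A are removed as
poly-A artifacts. Remaining tags are classified by exact substring
containment (either strand) in a class-annotated catalog, searched in
the fixed precedence order rRNA → tRNA → snRNA → snoRNA → repeat, which
makes classification independent of catalog file order. Exact
containment rather than alignment is a deliberate sensitivity
trade-off: it is deterministic and dependency-free, and near-match
contaminant tags simply fall through to the unannotated pool.

Conserved miRNA assignment aligns each tag end-to-end (ungapped)
against every catalog mature, absorbing length differences up to 2 nt
as terminal overhangs. Exact hits are member-level calls; hits with 1–2
substitutions are family-level variants; both count as miRNA in the
category table. Ties go to the fewest mismatches, then the smallest
catalog id. The category table reports unique-tag and read counts with
two-decimal percentages, and errors out if any tag would be counted in
two categories.

# Hairpin discovery

Unannotated tags with at least 2 supporting reads are mapped to the
genome by exact matching on both strands; tags with more than 20 loci
are set aside as repetitive. Around every locus two candidate windows
are excised — `[start − 150, end + 20)` and `[start − 20, end + 150)` —
so the mature can sit on either hairpin arm; minus-strand windows are
reverse complemented so the tag always reads 5′→3′.

## Folding engine

Windows are folded with an interval dynamic program over an additive
base-pair energy model: G:C −3.0, A:U −2.0, G:U −1.0 kcal/mol, hairpin
loops of at least 3 unpaired bases, no pseudoknots. Ties in energy are
broken toward more base pairs, and the traceback prefers pairing the
5′-most base with its 5′-most admissible partner, so the reported
structure is a deterministic function of the sequence. The model is
intentionally simple enough to verify against brute-force enumeration
of *all* nested structures (the test suite does exactly that on random
sequences up to 22 nt), while remaining monotone with stem strength so
hairpin ranking behaves like a thermodynamic folder. A
nearest-neighbour engine could be substituted behind `foldRna()`
without changing any downstream contract; energies from this model are
not numerically comparable to nearest-neighbour MFEs.

## Evaluation criteria

A candidate passes when: the mature is 20–24 nt; every paired mature
base points into the same opposite arm (a mature crossing the terminal
loop fails); at most 4 mature bases are unpaired opposite the star
region; at most 2 bases are asymmetrically bulged within the duplex
(symmetric internal loops count as mismatches, asymmetry as bulges);
and the window MFE is at or below −18 kcal/mol under the model above.
All thresholds are parameters of `hairpinThresholds()`.

The theoretical miRNA\* is the duplex partner with 2-nt 3′ overhangs on
both strands, read off the fold via the partners of the mature's ends
(extrapolating across unpaired end bases). `findStar()` flags the
candidate when a sequenced tag maps to that genomic interval within
2 nt at either end. Absent star evidence never fails a candidate —
in real libraries most genuine miRNAs are sequenced without their
passenger strand — it is reported as supporting evidence only.

Passing matures are clustered into families by greedy seed-linkage:
seeds are taken in descending read count, and a mature joins a family
when it has the seed's length and differs from the *seed* by at most 2
substitutions. Linking to the seed (rather than to any member) keeps
the family invariant — every member within 2 substitutions of its seed
— true by construction; chained single-linkage could silently violate
it.

# Target prediction

A miRNA is aligned antiparallel against each transcript window of its
own length: position *i* of the miRNA faces position *L − i + 1* of the
site. Watson–Crick pairs score 0, G:U wobbles 0.5, anything else 1.0,
and penalties double at miRNA positions 2–13, the region where plant
target recognition is most sensitive. Sites scoring below 3.0 are
called targets. Overlapping candidate sites resolve to the
lower-scoring one (ties to the 5′-most). The weights, the seed window
and the cutoff are all parameters, so alternative published weightings
can be reproduced; an optional gapped mode permits a single 1-nt site
bulge at a 2.0 gap penalty. Every reported score is recomputable by
independently walking the two sequences — the tests do this for every
emitted hit.

# Expression summaries

CT tables (miRNA, sample, replicate, CT, reference CT) are summarized
as ΔCT = CT~sample~ − CT~ref~, averaged over replicates (sd reported,
or NA with one replicate), with optional group means over user-defined
miRNA sets; lower ΔCT means higher expression. The stress comparison
reports ΔΔCT = ΔCT~stress~ − ΔCT~control~, fold change 2^−ΔΔCT^, and an
up/down/unchanged call at a configurable |ΔΔCT| threshold (default 1
cycle). No amplification-efficiency correction is applied, and no
significance testing is performed — the inputs are replicate means, not
a statistical model.

# The synthetic generator

`generateGenome()` draws uppercase chromosomes at a chosen GC fraction.
`plantHairpins()` inserts non-overlapping precursors built as
`F + M + loop + revcomp(M) + revcomp(F)` (flank F, mature M), so the
mature arm pairs its star arm perfectly and the theoretical miRNA\* is
known by construction; precursor lengths are drawn from 120–200 nt and
loops from 8–15 nt, bracketing typical plant pre-miRNAs. Candidate
draws are re-sampled until the package's own evaluator recovers the
designed duplex exactly on the precursor — random stems occasionally
admit co-optimal "slipped" foldings under an additive model, and the
generator's contract is that planted hairpins satisfy the criteria by
construction. Half the hairpins land on the minus strand.

`simulateLibrary()` draws reads from planted matures (log-normal
abundance, μ = 2, σ = 1.5, over a floor of ~20 reads each, mirroring
the heavy-tailed family skew of real libraries), miRNA\* reads for
marked hairpins at ~10% of the mature abundance, random 16–30 nt
fragments of planted ncRNA loci, and random unplanted genome windows as
degradation. Fragment lengths peak at 21 and 24 nt. Inserts get the 3′
adapter appended and are cut to 36 nt; per-read mean quality is drawn
from [25, 40], and a configurable fraction of reads is deliberately
degraded with an N or with low-quality bases placed *exactly* at the
filter boundaries, so every rejection path is exercised. All generators
are pure functions of (parameters, seed): identical calls give
byte-identical FASTQ output.

What the simulation does *not* emulate: indel sequencing errors,
ligation bias, multi-tissue composition, imperfect miRNA/miRNA\*
duplexes, and genomic repeat structure. Consequently, passing the
recovery benchmark demonstrates that the pipeline's logic is correct
and self-consistent — not that its sensitivity matches real-library
conditions, where imperfect duplexes and repetitive mappings dominate
the error budget.

One property of the perfect-duplex construction deserves note: because
the star arm is the exact reverse complement of the mature arm, every
planted mature also occurs verbatim on the opposite strand of its own
locus. Discovery may therefore report a candidate at the antisense
interval of the same physical hairpin; recovery scoring treats the
mature and star intervals of a planted hairpin as the same locus and
ignores strand when matching (tolerance ±3 nt).

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open in every table; GFF3 output is
  1-based via rtracklayer.
* Catalogs are read as raw strings and normalized U→T, so RNA-alphabet
  FASTA files are accepted; all matching happens in DNA space.
* Fold ties: energy first, then pair count, then 5′-most pairing —
  fully deterministic.
* Candidate selection per tag: passing preferred, then lowest MFE.
* Empty inputs return empty, well-typed tables rather than errors,
  except where the spec of the operation makes emptiness a
  configuration error (empty catalogs, empty transcriptome).
* `familyStats()` reports members-per-family to one decimal, the
  conventional reporting precision.

# Benchmark problem sizes

The bundled benchmark uses a 100 kb genome, 30 planted hairpins (15
with miRNA\* reads, 10 listed as conserved in the catalog), 10 ncRNA
loci and 50,000 reads at an error rate of 0.001 — large enough that
per-category tallies and the abundance skew are meaningful, small
enough to run in under a minute. Unit tests use 40–60 kb genomes and a
few thousand reads.

# Known limitations

* The additive energy model ranks hairpins sensibly but its MFE values
  are not comparable to nearest-neighbour folders.
* Exact-substring ncRNA classification misses diverged contaminants by
  design.
* Exact-match genome mapping means a single sequencing error unmaps a
  tag; with the default minimum of 2 supporting reads this mainly
  affects very low-abundance miRNAs.
* Target prediction is ungapped by default and does not model
  translational inhibition versus cleavage, nor target-site
  conservation.
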
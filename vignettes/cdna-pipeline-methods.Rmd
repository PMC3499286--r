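---
title: "Methods: locus mapping, CDS classification and editing estimation for full-length cDNA resources"
author: "capmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus mapping, CDS classification and editing estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capmap)
```

# The problem

Full-length-enriched cDNA libraries (built by oligo-capping, vector-capping
or SMART protocols) preferentially clone transcripts that retain the mRNA 5'
cap position, so most clones carry the transcription start and the start
codon. Sequencing such libraries from the 5' end (ESTs) and then fully
sequencing selected clone inserts yields a resource used to annotate a draft
genome: each cDNA is assigned to a genomic *locus*, classified by coding
content, and compared base-by-base with the genome to estimate both draft
accuracy and A-to-I RNA editing.

`capmap` implements that computational pipeline — the analysis layer between
raw reads plus alignments and the published report tables — together with a
seeded synthetic-data generator that makes every stage testable without
external downloads.

# Locus assignment: anchor, extend, merge

Alignments arrive as the classic 12-column tabular search output. For each
query, the **anchor** is its best alignment with score strictly above 100 and
percent identity strictly above 90 (both read as strict inequalities; the
boundary behaviour is locked by unit tests). Queries with no qualifying
alignment are *unmapped*. Ties on score fall back to identity, then alignment
length, then lowest (subject, coordinate) — an invented but deterministic
order, because reproducibility matters more than which equally good anchor
wins.

The locus **region** grows from the anchor by absorbing other alignments of
the same query on the same subject and strand whose distance from the current
region is less than 1 Mb (an intron-scale gap bound). The gap is measured to
the *growing region*, not the anchor, and absorption iterates to a fixpoint,
so serial introns chain: an absorbed exon block can bridge to the next one
even when that block is more than 1 Mb from the anchor itself. A one-pass
variant would split long multi-exon genes; the fixpoint choice is therefore
deliberate and is exercised by a chaining test.

Per-query loci are then **merged**: two loci are the same locus exactly when
their regions overlap on the same chromosome *and* strand. Opposite-strand
overlap never merges — sense and antisense transcription are distinct loci.
Merging is the transitive closure of that relation, implemented as a
coordinate sweep per (chromosome, strand); an independent brute-force
union-find oracle checks it on a thousand random interval sets in the test
suite. Touching-but-not-overlapping intervals stay distinct (the relation is
"overlapped", not "adjacent").

Reports are per-chromosome/strand locus counts (with a separate
unplaced-scaffold row and a totals row equal to column sums) and
sliding-window densities: for window width $w$ and stride $s$, window $i$
covers $[is, is + w)$ clipped at the chromosome end, and a locus counts in
every window its interval intersects, separately per strand.

# Coding-content classification

A cDNA *contains a full-length CDS* when its best protein alignment trims the
reference protein by fewer than 10 amino acids at both ends:
$\mathrm{trim}_N = p_\mathrm{start} - 1$,
$\mathrm{trim}_C = L_\mathrm{prot} - p_\mathrm{end}$, full-length iff both
are $< 10$. The start-codon call uses the N-terminal half of the same rule
($\mathrm{trim}_N < 10$); the resource literature reports start-codon
estimates without defining the criterion, so this package adopts the
N-terminal analogue of its full-length rule and locks it with boundary tests.

ORFs are scanned in the three forward frames only, because the libraries are
cloned unidirectionally — the sense strand is known. An ORF requires both an
ATG and an in-frame stop inside the sequence; ORFs running off the 3' end are
not counted (a conservative, configurable choice). A cDNA is flagged
*non-coding* when its longest peptide is not strictly longer than 30 amino
acids.

Each merged locus gets a *representative*: the member cDNA with the longest
ORF (ties to the longer sequence, then id). When one reference protein is hit
by the representatives of two or more loci, the locus group is reported as a
putative duplication, and every locus whose representative ORF is shorter
than the group maximum is flagged — the signature of a pseudogenized copy or
an assembly artefact.

# Editing and draft accuracy

For each cDNA the single alignment covering the largest fraction of the
query is extracted and turned into a base-level pairing oriented along the
cDNA; minus-strand regions are reverse-complemented exactly once, so a
genome-A/cDNA-G column always means A-to-G on the transcribed strand.

A column counts as A-to-G only when the 5 columns on each side are gap-free
exact matches (the flank rule; gaps inside a flank window disqualify the
column). G-to-A is counted with the same rule. Polymorphism, sequencing
error and residual draft errors hit A-to-G and G-to-A symmetrically, whereas
A-to-I editing adds A-to-G only, so the **excess asymmetry**

$$\hat f = \frac{n_{AG} - n_{GA}}{n_{AG} + n_{GA}}$$

estimates the fraction of the combined A/G discordance attributable to
editing. The raw counts are always reported next to $\hat f$: the estimator
is a documented, swappable strategy, not a claim that this exact arithmetic
underlies any published summary. Per-cDNA reports also flag clones carrying
*only* A-to-G or *only* G-to-A changes, since aggregate conventions for
mixed clones differ between accountings.

3'-UTRs — from the end of the longest ORF to the first run of at least
eight A's — are compared column-by-column against the genome; the aggregate
mismatch rate over all aligned UTR columns, and the count of perfectly
matching UTRs, estimate draft-sequence accuracy.

# EST processing

*Quality filter*: a read survives iff it contains a run of **more than 100**
consecutive bases with Phred quality **at least 10**; a run of exactly 100
is discarded (strict boundary, verbatim thresholds).

*Masking*: homopolymer runs of 12+ bases and dinucleotide repeats of 8+
units are soft-masked (lowercase). This is a small explicit screen for
poly(A) tracts and microsatellites, not a repeat-library masker.

*Clustering* is a documented greedy stand-in for a full assembler: reads
link when a shared exact 20-mer seed (masked bases never seed) implies an
ungapped overlap of at least 40 bp at 95% identity or better; clusters are
single-linkage closures, offsets come from the accepted pairwise shifts, and
the consensus is a per-column majority vote with alphabetical tie-break. It
furnishes structurally correct contigs/singlets for the downstream stages;
it does not try to reproduce any production assembler's contig counts, and
its overlap parameters are configuration knobs, not claims about any
external run.

*Clone selection* mirrors the resource workflow: per contig the 5'-most
member is selected (`forefront`); on incremental reruns a newly appeared
more-5' member is *added* (`upstream_update`) without displacing earlier
picks, because previously selected clones are already in the sequencing
queue; singlets join only when their assigned gene has no counterpart among
contig-derived picks (`novel_gene_singlet`).

*Detection probability*: a transcript at expression frequency $p$ is absent
from $n$ independently cloned transcripts with probability $(1-p)^n$; at
$p = 6\times10^{-5}$ and $n = 10^4$ this is $0.549$ — rare transcripts are
more likely missed than caught at that depth.

# The synthetic-data generator

The generator defines the study conditions; its defaults are fixed design
choices, not tuning knobs:

* **Genome**: 2 chromosomes of 100 kb plus 2 unplaced scaffolds of 20 kb,
  uniform random background, genes placed without overlap with a 2 kb
  minimum gap. Sizes were chosen so a full simulate–align–report cycle runs
  in seconds; the vignette's and tests' problem sizes (up to 50 genes,
  10^4 reads) are stated with each experiment.
* **Genes**: 1–3 exons of 150–400 bp, introns 200–1500 bp, 5'UTR 10–60 nt,
  3'UTR 60–150 nt, CDS at least 240 nt built as ATG + non-stop codons +
  stop. An in-frame stop codon is placed immediately upstream of the CDS so
  that no upstream ATG can extend the reading frame past the true start —
  without it, a random 5'UTR occasionally creates an in-frame upstream
  extension and the classifier would (correctly, but unhelpfully for
  calibration) report a longer ORF than the annotated CDS.
* **Duplicates** diverge from their template only at synonymous third codon
  positions and non-coding bases (~1% per base): the encoded protein is
  identical, the nucleotide sequence is distinguishable, so anchoring
  resolves the two copies while the duplication screen sees one protein hit
  by two loci. **Pseudogene** copies additionally carry a premature stop at
  mid-CDS and are transcribed (transcribed pseudogenes are what the
  duplication screen must flag).
* **Reads** emulate fully sequenced clone inserts (up to 2 kb), drawn per
  gene from a Zipf law over randomly assigned ranks. With probability 0.75
  (the full-length design value) a read starts at the transcription start;
  otherwise it is truncated past the start region — 5'UTR plus the first
  ten codons — by an additional geometric offset. Tying "truncated" to
  "start region lost" makes the full-length probability identifiable from
  the CDS-coverage rule, so the classified full-length fraction converges
  to the configured 0.75; the geometric tail is a stand-in, since no
  truncation-length distribution is established for these libraries.
* **Editing** sites are chosen per gene at rate `editing_rate` per eligible
  transcript A (at least 5 nt from the transcript ends, so the flank rule
  can validate them) and are fully penetrant: every read over the site
  shows G. **Polymorphism** is applied per read molecule (breed-versus-
  reference divergence), substituting a uniformly random other base — a
  symmetric background by construction, which is exactly what the
  excess-asymmetry estimator assumes. Sequencing errors are additional
  uniform substitutions.
* Everything is bit-reproducible from the single integer seed.

What the generator does *not* emulate — alternative splicing, indels,
chimeric clones, position-dependent error profiles, genomic repeats beyond
simple tracts — bounds what passing tests show: they validate the
algorithms' logic and calibration under clean assumptions, not performance
on real trace data.

The bundled naive aligner (exact 20-mer seeds, ungapped X-drop extension,
+1/−2 scoring) exists only so the pipeline runs end-to-end on synthetic
data; production use consumes externally computed tabular alignments.

# Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open everywhere; conversions happen
  only at format boundaries (1-based inclusive tabular/GFF3, 0-based BED).
* All strictly-worded thresholds (score 100, identity 90, gene score 50,
  trim 10 aa, ORF 30 aa, quality run 100) are strict inequalities, each with
  a boundary test on both sides.
* `editing_fraction(0, 0)` is an error, not 0: no flank-validated changes
  means the estimator is undefined.
* Empty inputs return empty typed tables (never `NULL`) throughout; loci
  with no members are an error.
* Report totals rows are always recomputed column sums, and
  `check_accounting()` re-verifies every identity rather than trusting the
  producer.

# Validation strategy

The test suite pairs each non-trivial algorithm with an independent oracle:
locus merging against brute-force pairwise union-find; the ORF scanner
against an every-ATG walker; the flank counter against a per-column loop;
the editing estimator against its analytic expectation over 100 seeded
replicates (within three standard errors); the full-length fraction against
the generator's design value on 10^4 noiseless reads (0.75 ± 0.02, measured
over reads from protein-coding source genes, since pseudogene-derived reads
are by construction not full-length-CDS); and the report layer against the
transcribed resource tables, whose printed totals must be reproduced exactly
by column sums.

# Known limitations

* The clusterer and naive aligner are stand-ins: structurally faithful,
  not performance-comparable to production assemblers or similarity
  searches, and noise-fragile by design (exact peptide matching loses hits
  on reads with coding substitutions).
* Direct gene-to-term GO counting only; no ontology-graph propagation.
* Single isoform per gene; duplication divergence is synonymous-only.
* The excess-asymmetry estimator assumes a strictly symmetric background;
  context-dependent mutation biases would shift it.
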
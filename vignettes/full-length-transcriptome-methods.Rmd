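---
title: "Methods: reference-free characterization of full-length transcript sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-free characterization of full-length transcript sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fltrx)
```

# Scope

`fltrx` characterizes a set of full-length transcripts — the kind produced
by single-molecule isoform sequencing of a non-model organism — without a
reference genome.  It implements the post-processing chain of such a study:
redundancy collapse, reference-free alternative-splicing (AS) detection
from local-alignment geometry, microsatellite (SSR) scanning, open reading
frame (ORF) calling, consensus lncRNA filtering, KEGG-ortholog pathway
cataloguing for the anthraquinone biosynthesis route of *Rubia*-type
medicinal plants, relative expression by 2^-ddCt, and summary accounting.
Raw-read processing (CCS construction, full-length read classification,
isoform clustering), database annotation (NR/KEGG/GO/Pfam searches),
BUSCO, transcription-factor prediction and enrichment analysis are out of
scope: where their results feed the accounting (read counts, BUSCO
classes), they enter as external counts, never recomputed.

The repository is organized as an analysis workflow: `analysis/01…08_*.R`
are thin narrative drivers over the package functions and write their
tables under `results/`; every computation they perform lives in `R/` and
is exercised by the test suite.

# Redundancy collapse

The collapse step emulates greedy incremental nucleotide clustering in the
CD-HIT-EST style: sequences are sorted longest-first; each joins the first
existing cluster whose representative exceeds the identity threshold
(strictly greater than 0.99 by default, matching the study setting),
otherwise it founds a new cluster.  Two conventions required a decision
because the method description names only the tool:

* **Identity denominator.** Identity is matching bases divided by the
  *shorter* sequence length (the named tool's convention for nucleotide
  clustering).  This is configurable in spirit but deliberate: it makes a
  pair of isoforms that differ by one internal segment score as
  near-identical over the shorter isoform, which is what folds a gene's
  isoform pair into one "unigene" cluster.
* **Alignment model.** Identity is computed from an ends-free affine-gap
  alignment (match +10, mismatch −20, gap open −100, gap extension −1,
  ties resolved toward more matched bases; implemented in C++).  The
  affine shape matters: a single long internal deletion costs little
  (isoform difference), while stitching chance matches between unrelated
  sequences requires many gap opens and is heavily punished.  A pure
  maximize-matches alignment would be useless here — a random 500-mer
  embeds almost entirely into a random 3000-mer as a subsequence — and a
  linear-gap score makes a genuine internal deletion more expensive than
  mismatching through it.  The tie-break toward more matches makes
  "matching bases in the best alignment" single-valued, so the identity is
  well defined and testable against an independent dynamic-programming
  oracle.

A shared-word prefilter (10-mers; at least 30 shared words) gates the
alignments.  At the high thresholds this step targets (> 0.95), a
qualifying pair of length *L* shares on the order of 0.9 *L* words while an
unrelated pair shares a handful, so the gate is conservative; a test
verifies that disabling it does not change the clustering.  Words of
length 8 would not discriminate at kilobase scale (two unrelated 1.5 kb
sequences already share ~30 distinct 8-mers by chance), which is why the
default word size is 10.

# Reference-free AS detection

Without a genome, an AS difference between two transcripts appears in
their pairwise local alignment as two high-scoring segment pairs (HSPs)
with the same orientation: adjacent (or overlapping by a few bases) on one
transcript — the *continuous* one — and separated by an internal unaligned
segment, the *AS gap*, on the other — the *distinct* one.  The detector
enforces four criteria, read strictly:

* gap length **> 100** bp (a gap of exactly 100 is rejected);
* gap **≥ 100** bp away from both ends of the distinct transcript
  (99 is rejected, 100 accepted);
* junction overlap **< 5** bp in absolute value, covering both small
  overlaps and small unaligned gaps on the continuous side (an overlap of
  exactly 5 is rejected);
* the two HSPs jointly cover **≥ 95%** of the continuous transcript — the
  operationalization of "aligns almost completely", which the source
  method states without a number; 95% tolerates small terminal soft clips
  and is configurable.

Every same-orientation HSP pair within a transcript pair is examined under
both role assignments (either transcript may be the continuous one), and
events are deduplicated by (continuous, distinct, gap coordinates), so the
result is invariant under query/subject relabelling and robust to extra
spurious HSPs.  Event *types* (exon skip vs intron retention) are not
classified: that distinction requires a genome.

The built-in aligner is a seed-and-extend HSP finder: exact 12-mer seeds
grouped by diagonal, bridged across point mismatches, extended outward
base-by-base, and reported when at least 50 bp at ≥ 90% identity.  These
defaults are the package's reading of "high identity settings"; they are
configurable, and standard 12-column tabular alignments from an external
aligner can be substituted via `read_alignment_tabular()`.  Because HSPs
are gapless and diagonal-bound, a point substitution can never split an
HSP in a way that fakes an AS event: a split on one diagonal gives equal
separations on both transcripts, which cannot simultaneously satisfy the
overlap (< 5) and gap (> 100) criteria.

# SSR scanning

The scanner reports maximal perfect tandem repeats of 1–6 nt units on
transcripts of at least 500 bp (the study's filter), with the MISA default
minima (mono 10, di 6, tri 5, tetra/penta/hexa 5) — the tool is named in
the source but its thresholds are not printed, so the tool's documented
defaults are adopted, all configurable.  Runs whose unit is itself a
repetition of a shorter unit are reported at the smaller unit; overlaps
are resolved left-to-right, longest match first, so simple loci never
overlap; simple loci separated by at most 100 bases merge into a compound
locus with component records retained.  Motifs are reported as they appear
at the locus start (MISA behaviour), with a lexicographically-smallest
rotation column added for grouping.  Spans are truncated to whole units;
consequently, a run with a partial trailing unit mirrors to the reverse
complement with coordinates shifted by the partial remainder — the
coordinate-symmetry test therefore uses guarded, exact-span runs.
Imperfect (mismatch-containing) repeats are out of scope, as in the
emulated tool.

# ORF calling

ORFs are enumerated per strand and frame from maximal stop-to-stop
intervals: the candidate starts at the first ATG of the interval
(complete if stop-terminated, 3'-partial otherwise); an interval with no
ATG that starts at the transcript edge yields a 5'-partial (stop-
terminated) or internal (unterminated) candidate.  Nested later-ATG ORFs
are not emitted (the standard longest-ORF convention).  Codons containing
N match neither ATG nor stop and translate to X.  The 100-aa minimum is
the named tool's default; both strands are searched by default even though
full-length reads are nominally stranded, matching that tool — a
forward-only mode exists, and the both-strand default is the conservative
choice when comparing counts.  Stop codons are included in the reported
span of stop-terminated classes, so spans are always divisible by three
and `protein_length` is the codon count minus one for them.

# Consensus lncRNA filtering

The defined computation is the *combination*: a transcript strictly longer
than 200 nt is a consensus lncRNA candidate, and it is called lncRNA when
every enabled coding-potential scorer votes noncoding (the four-tool Venn
intersection of the emulated study).  The four external tools themselves
are not re-implemented; instead the module ships two transparent scorers —
a longest-ORF rule (coding iff the representative ORF is ≥ 100 aa) and the
classic Fickett TESTCODE statistic with its published position/content
lookup tables and the 0.74 threshold (scores ≥ 0.74 count as coding) —
and accepts external per-scorer verdict tables in their place.  The
source's "more than two exons" clause is *dropped, not approximated*:
exon counts are undefined for genome-free transcripts and the original
procedure for them is unexplained.

# Pathway cataloguing and qPCR

The anthraquinone feeder-pathway scheme (MVA, MEP, TCA, shikimate) ships
as a 40-row data table of enzyme → KEGG-ortholog id with the published
per-enzyme unigene counts; shipping it as data keeps the package
network-free and version-stable.  Composite multi-EC rows are kept exactly
as printed, as are same-EC subunit rows with distinct KO ids.  Cataloguing
deduplicates (transcript, KO) pairs, counts distinct transcripts per
scheme row, and reports anything outside the scheme as unclassified.  The
published pathway subtotals derive from the table sums (22 + 44 + 138 +
76 = 280); where the source narrative disagrees with its own table on two
subtotals, the table — whose sum matches the published overall total — is
treated as authoritative.

Relative expression uses the Livak 2^-ddCt method with group-mean dCt and
an equal-variance t-test at the 1% level (Welch available); replicates at
the 45-cycle limit are excluded as non-detects.  Efficiency-corrected
(Pfaffl) models are out of scope.  The published fold changes cannot be
recomputed because raw Ct values are not public; the packaged Ct table is
synthetic and exists to exercise the contract.

# The synthetic transcriptome generator

The generator is the test bed standing in for the deposited reads.  Its
defaults are the study conditions the pipeline is verified under, and all
planted features are *discoverable by construction*:

* **Genes and lengths.** Coding transcripts are composed as
  UTR5 (80–250 nt) + ORF (120–450 aa) + UTR3 (100–350 nt), giving the
  ~0.5–2 kb scale of full-length isoform data; noncoding genes draw
  uniformly from 800–3000 nt.  Background sequence is i.i.d. uniform
  A/C/G/T — the simplest null that exercises the aligners and scanners;
  GC bias is deliberately not modelled.
* **AS pairs.** An AS gene emits the distinct isoform and a continuous
  isoform equal to it minus one internal segment (> 100 bp, ≥ 100 bp from
  both ends).  The first deleted base is forced to differ from the first
  retained base after the gap (and symmetrically), otherwise the true
  junction is ambiguous by one or more bases and "exact gap coordinates"
  would not be a well-posed target.
* **SSRs.** One guarded run per selected gene: flanking bases are set so
  the run cannot extend, and accidental runs arising anywhere in any
  emitted sequence are disrupted by a single masked-aware substitution
  (stop-codon-safe inside ORFs), so the manifest is the exact ground
  truth.  SSR regions are excluded from mutation noise.
* **ORFs.** Planted ORFs use position-biased codon sampling (first
  position G/T-leaning, second A/T-leaning, third C/G-leaning), mimicking
  the codon-position asymmetry of real coding sequence so that
  composition-based scorers see a realistic signal; an in-frame stop is
  placed immediately before the ATG so the first-ATG rule recovers the
  planted start exactly.
* **Noncoding transcripts** are built over a 22-mer cassette
  (`TAAGTAAGTAATTAGTTAGTTA`) inserted every 100 bases, which places stop
  codons in all three forward and all three reverse frames of every
  150-base window — no ORF of ≥ 100 aa can survive on either strand.
* **Redundancy.** Non-AS genes are emitted `cluster_redundancy` times
  (substitution rate 0.002 per base, below the 0.005 ceiling consistent
  with a > 0.99 collapse threshold).  Copies are restricted to non-AS
  genes so the planted AS event list stays the exact ground truth;
  AS genes instead contribute their isoform pair to the gene's cluster.
* **Determinism.** All randomness flows from the seed; identical seeds
  give byte-identical FASTA and manifest, and the caller's RNG state is
  restored.

What passing tests on this generator shows — and what it does not: the
recovery properties (100% of planted AS events with exact coordinates,
100% of planted SSRs and complete ORFs, one representative per gene, zero
false AS events at `as_fraction = 0`) verify the *algorithms* under clean
geometry and under mild point-substitution noise.  They do not certify
behaviour on real long-read artefacts the generator deliberately omits:
indel-rich sequencing error, polyA tails, chimeras, truncated isoforms,
paralog families at intermediate identity, or GC-composition bias.

# Numerical and degenerate-input choices

* Percentages are recomputed from their two counts at render time and
  rounded **half-up** at the printed precision (two decimals for
  sequencing-summary shares, one for BUSCO classes); R's banker's
  rounding would print 0.42 where the emulated accounting prints 0.43.
  One published BUSCO share (missing class) is not reproducible by direct
  rounding of its own counts and is reported as computed.
* Empty inputs collapse to empty outputs (empty transcript set, empty
  event list, all-zero type tables) rather than errors, except where the
  contract demands an error: empty FASTA, duplicate ids, non-IUPAC
  characters (with position), malformed table rows (with line number),
  missing transcript lengths, a gene absent from a qPCR group.
* Problem sizes in the checked examples — 200-gene recovery runs,
  200 × 1 kb scanner-oracle sequences, 100 ORF-oracle sequences, 50
  alignment-oracle pairs — were chosen as the smallest sets that exercise
  every code path with comfortable statistical margin.

# Known limitations

* The HSP finder is seed-based and gapless; diverged isoform pairs
  (< 90% identity) or junctions buried in mutation clusters can fall below
  seeding sensitivity.  External aligner output can be substituted.
* Collapse is single-threaded greedy; its first-qualifying (not
  best-qualifying) assignment matches the emulated tool but is order
  dependent by design.
* The Fickett scorer is a screening statistic, not a replacement for the
  four external coding-potential tools; on real data external verdict
  tables should be preferred.
* Compound-SSR accounting counts one compound locus per merged group;
  tools differ here, and comparisons across tools should use the retained
  component records.
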
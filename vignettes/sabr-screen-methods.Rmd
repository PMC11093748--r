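---
title: "Models and methods behind sabrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sabrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sabrscreen)
```

## The screening system in brief

A SABR-II is a chimeric receptor that displays a covalently linked peptide on
an MHC class II scaffold (for instance the NOD mouse allele I-Ag7, or human
HLA-DQ8) fused to intracellular signalling domains. A reporter cell carrying a
SABR-II lights up (NFAT–GFP) when a CD4+ T cell receptor binds the displayed
peptide–MHC. Cloning a pooled library of epitopes into the SABR-II backbone
turns a co-incubation with TCR-expressing cells into a genetic screen: cells
whose displayed epitope is recognised signal, the brightest cells are
flow-sorted, and the epitope inserts of sorted cells are amplified, sequenced
and counted. `sabrscreen` implements everything computational around that
assay: library design, TCR construct reconstruction, read processing,
enrichment scoring, and a simulator that generates whole screens with known
ground truth.

## Library design

**Curation.** Defined epitope libraries are curated from annotated peptide
lists: peptides are kept when their length falls inside inclusive bounds
(default 9–25 amino acids, the range a covalently linked MHC-II epitope
tolerates) and their modification annotation is permitted. Because inserts are
genetically encoded, only modifications expressible as sequence are kept by
default: deamidation (written directly as N→D / Q→E) and hybrid insulin
peptides (HIPs). Duplicated peptides collapse to the first occurrence —
first-seen-wins is arbitrary but deterministic, and collisions are logged so a
curator can audit them.

**HIP enumeration.** HIPs are non-genetically-encoded fusions of an insulin
fragment (left half) and another secretory-granule protein fragment (right
half). The theoretical library is the full cross product of user-supplied left
and right cleavage fragments, filtered to fused lengths of 12–25 residues.
The enumeration rules that produced any particular published library depend on
its fragment sets, which derive from external proteomic predictions; we
therefore take fragments as input and provide `cleavage_products()` to derive
them from a protein plus declared cut positions. `junction_index` records the
number of left-derived residues (0-based offset of the fusion point).

**Junction validation epitopes.** `make_junction_epitope()` builds the 2k-mer
from the last k residues of the left context and the first k of the right
(default k = 7). With a 9-residue MHC-II binding core, no core of the 14-mer
can derive wholly from either source protein, so reactivity to it must span
the fusion junction; the tests verify this by scanning all six 9-mers.

**Back-translation and oligo pools.** Peptides become nucleotide inserts by
codon-usage-weighted sampling (bundled mouse weights; only relative weights
within an amino acid matter), seeded so pools are reproducible. Forbidden
restriction motifs — BsmBI (`CGTCTC`) by default, since Golden-Gate cloning of
the insert uses it — are removed by resampling only the codons overlapping an
occurrence, on either strand, with a bounded retry budget so impossible
constraints fail loudly. An oligo is `flank5 + insert + flank3`, the flanks
being the constant amplification/overhang sequences of the synthesis vendor.

## TCR reconstruction

Clonotype callers emit V/J allele names plus CDR3 amino-acid sequences; to
express a TCR, the full-length chain must be rebuilt against a segment
reference (IMGT-dialect FASTA; a synthetic toy reference ships under
`inst/extdata`). We follow the IMGT junction convention — the CDR3 spans the
V-segment conserved cysteine through the J-segment conserved F/W of the FGXG
motif — so the chain protein is `V[1..anchor-1] + CDR3 + J[anchor+1..] + C`.
Anchors are located at load: the last Cys within the C-terminal 15 residues of
a V segment, the first `[FW]GxG` match of a J segment; segments failing the
scan are flagged unusable rather than silently mis-anchored. Nucleotides reuse
germline codons wherever the CDR3 prefix/suffix matches the germline V tail /
J head (longest-match trimming); only the non-templated core is
back-translated. This maximises germline fidelity and makes the
germline-junction limit exact: a CDR3 equal to the germline junction
reconstructs the literal germline concatenation, which the tests assert.

The bicistronic construct is `EcoRI flank + TCRα + P2A + TCRβ`, the β chain
truncated at the first BlpI site (`GCTCAGC`) of its constant region with the
motif retained, matching how such constructs are subcloned into a recipient
vector already carrying the remainder of Cβ. Internal EcoRI sites would break
cloning, so they are removed by synonymous codon resampling; the protein is
unchanged by construction. CDR3s that do not start with C are rejected unless
`lenient = TRUE`, because upstream callers occasionally emit non-canonical
junctions and the right behaviour is a deliberate user choice.

## Read processing

Samples carry unique dual indexes (UDI). A read is assigned to the unique
sample whose i7 and i5 are both within a Hamming tolerance (default 1 per
index, no indels — standard UDI practice); sheets that are ambiguous at the
chosen tolerance (both index distances ≤ 2·tol for some pair) are refused
before any read is touched. Epitope inserts sit between two constant amplicon
flanks; extraction finds the 5′ anchor, then the 3′ anchor downstream, each
within a substitution tolerance (default 1), and takes the substring between.
Matching against the designed library is nucleotide-exact by default — the
library was synthesised, so correct reads equal designed inserts — with a
peptide mode (in-frame translation matched against the peptide index) for
error-tolerant recounts. Only read 1 is searched for anchors; read 2
contributes indexes. Phred scores are ignored by default (`min_qual` exists
but is off), since counting is anchored and exact. Read conservation holds at
every stage: assigned + unmatched-insert + unassigned-index = input reads.

## Enrichment scoring and hit calling

Counts are normalised to counts-per-million with a 0.5 pseudocount (tames
zeros ahead of regression without materially distorting abundant epitopes).
For each sorted replicate an ordinary least-squares fit with intercept of

> observed CPM ~ mean unsorted CPM

provides the expected abundance of every epitope absent TCR-driven selection,
and the enrichment score is the literal difference

> ES = observed − expected,

in CPM units (a `studentize` flag divides by the residual SD for users who
prefer unitless scores). Fitting per sorted replicate, rather than pooling,
lets each fit absorb that replicate's depth and composition; a TCR's score for
an epitope is the mean ES over the replicates whose co-incubation contained
that TCR. This single rule covers both designs: for a conventional screen
(one TCR, three sorted replicates) it is the plain replicate mean, and for a
leave-one-out multiplex it is the dropout deconvolution rule. A contrast mode
additionally subtracts the mean ES over replicates lacking the TCR; its
benefit comes from cancelling replicate-shared artifacts (epitope-specific
presentation or growth biases), which the simulator deliberately lacks, so on
simulated data it adds little beyond noise.

Hit calling is two-tiered and control-calibrated rather than p-value based:
with `base` the minimum mean ES among the positive-control TCR's known
cognate epitopes, the high-confidence threshold defaults to `0.5 * base` and
the low-confidence threshold to `0.25 * base`. The fractions are configurable
and recorded in the zones' provenance; halving and quartering the weakest
trusted positive is a deliberately conservative reading of "anchor the zones
to what the control achieves". A control cognate with non-positive mean ES
aborts calibration — it means the screen itself failed. Ties in the ranked
hit list break by epitope id for determinism.

## The simulator

The simulator emulates, per co-incubation: log-normal library representation
(sdlog default 1, echoing the unevenness of real cloned pools); one SABR per
cell; a standard-normal background reporter signal with an additive shift
(default 6 SD) for cells presenting an epitope cognate to any TCR present; a
top-percentile sort gate (default top 2%); multinomial read sampling to a
fixed depth (default 10^5); and optional per-base substitution errors on
inserts and indexes when emitting FASTQ. Cognate-carrying cells default to a
pinned pre-sort frequency of 0.05% — when pinned, the frequency is applied to
the library itself so unsorted samples see it too, since a cell pool has one
composition. With a 2% gate and a 6 SD shift essentially every cognate cell
is collected, so fold enrichment approaches its ceiling, the reciprocal of
the gate fraction (50× at 2%, 100× at 1%); the closed-form expectation
`f/(f + g(1−f)) / f` is checked against simulation in the tests. All
randomness is explicitly seeded and the caller's RNG state is never touched.

What the simulator does not model: reporter kinetics, CD69 co-staining,
multiple vector integrations per cell, cell growth between sort and
sequencing, PCR amplification bias, or index hopping. Passing simulation
tests therefore demonstrates the correctness of the pipeline's logic and
statistics under the stated generative model, not robustness to every
artifact of real screens.

## Problem sizes and numerical choices

The test suite runs screens of 300–1,000 epitopes at 5×10^4–10^5 cells and
5×10^4–10^5 reads per sample, and the acceptance script uses 10^6 cells with
1,000 epitopes over 100 seeds — sizes at which every headline behaviour
(≥50-fold gate enrichment, 4/4 dropout recovery, ≥95/100 top-ranking of a
20×-inflated cognate) is already stable. Degenerate inputs are handled
explicitly: all-zero count columns, zero-variance covariates and sub-single-
cell gates are errors; empty fragment sets degrade to controls-only libraries
with a warning. Coordinates are 1-based inclusive in R interfaces (anchors,
junction spans), with the HIP `junction_index` kept as a 0-based count of
left-derived residues because "number of residues from the left source" is
the quantity curators exchange.

## Known limitations

The published theoretical HIP library cannot be regenerated exactly without
its fragment-set provenance; `check_hip_manifest()` validates a supplied
manifest instead, and the corresponding acceptance check remains red unless
the published supplementary table is placed in `inst/extdata`. Allele
reference handling targets the IMGT FASTA dialect and in-frame segment
sequences; γδ chains and allele inference from reads are out of scope.
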
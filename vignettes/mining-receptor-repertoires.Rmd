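---
title: "Mining TAAR repertoires: methods and design"
author: "taarminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining TAAR repertoires: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameters and design decisions behind
`taarminer`, a pipeline for recovering trace amine-associated receptor
(TAAR) gene repertoires from fragmented genome assemblies. TAARs are
class-A GPCRs of ~330–350 residues with seven transmembrane (TM) segments;
in many teleost lineages a large fraction of the family carries a single
phase-0 GT–AG intron close to codon 55, inside the first internal loop, and
the codons flanking the splice junction typically encode an aromatic
residue (F/Y/W) before and a basic residue (R/K/H) after the intron.
Fragmented assemblies additionally contain pseudogenes (frameshifts,
premature stops), genes cut by contig boundaries ("edge genes") and
internal partial alignments ("fragments"). The pipeline recovers all of
these classes and the family structure above them.

## Translated homology search

Bait proteins are aligned against the six frame translations of each contig
with an affine-gap Smith–Waterman (BLOSUM62; gap open 11, extend 1, so a
gap of length $L$ costs $11 + L$). The DP kernel is written in C++; a
score-plus-endpoint pass scans the whole frame and a traceback alignment is
then computed inside a window guaranteed to contain the optimum. After each
hit the matched frame segment is masked with `X` and the frame re-scanned,
so several genes of the same family on one contig are all found.

Raw scores are converted to E-values with the Karlin–Altschul
approximation $E = K m n e^{-\lambda S}$, using the gapped BLOSUM62(11,1)
parameters $\lambda = 0.267$, $K = 0.041$. These are the standard published
values for this scoring system; because no finite-size edge-length
correction is applied, absolute E-values differ somewhat from what a full
BLAST implementation reports, and the cutoffs are therefore configurable
(`search_config()`). The default cutoff for both bait sets is $10^{-50}$.

The two-pass bait strategy mirrors field practice: the positive set
(reference TAARs) is searched genome-wide; the negative set (non-TAAR
class-A GPCRs) is then aligned only against the candidate loci, and any
locus with a negative match at or below the cutoff is discarded, with the
rejection reason recorded. Filtering is per locus, not per hit, so a locus
overlapping both a TAAR and a GPCR hit is adjudicated once.

Hits on the same contig and strand within `merge_gap = 2000` nt are merged
into one locus. The value bridges observed intron lengths (up to a few kb)
while staying below typical intergene distances of tandem receptor arrays
(reported in the kilobase range, roughly 1–6 kb); it is configurable.

## Gene models

Reconstruction works on the locus strand with generous context
(6 kb upstream in coding orientation — enough for the longest modelled
intron plus exon 1 — and 1.5 kb downstream).

**Single-exon models.** All ORFs (ATG to stop) of 250–400 codons
overlapping at least 80 % of the best positive hit are enumerated; when
several in-frame ATGs precede the aligned region, the one giving a protein
length closest to the bait is used (an upstream ATG only adds unaligned
leader). A single-exon model covering ≥ 95 % of the bait is accepted
outright.

**Disruption detection before spliced rescue.** If no high-coverage
single-exon model exists, the bait is aligned against the three
coding-strand frame translations of the locus.

* An *in-frame stop* is a `*` column aligned against a bait residue
  (stops inside alignment gaps belong to skipped segments such as bridged
  introns and are ignored), and only where the alignment carries real
  support on both sides of the stop (cumulative column score ≥ 40 on each
  flank — weak tails that a local alignment drags across flanking sequence
  cannot produce a call). Stop positions are exact on the bait.
* A *frameshift* is a frame change between two alignments covering
  complementary parts of the bait whose genomic segments are contiguous.
  Contiguity is the discriminator against introns: at a real frameshift the
  two segments overlap or nearly touch (alignment slop extends into the
  other segment), whereas an intron separates them by at least the minimum
  intron length. The threshold is half the minimum intron length (25 nt by
  default). The breakpoint is estimated as the midpoint of the overlap
  between the two segments; it is accurate to roughly ±8 codons, unlike
  stop positions, which are exact.

A locus with disruptions is a pseudogene and is *not* passed to the spliced
search — a contiguous frame switch must never be modelled as an intron,
which would otherwise happily "splice out" a frameshift through any nearby
GT/AG pair.

**Two-exon models.** The spliced search enumerates: an ATG; a phase-0 `GT`
donor at a codon boundary within codons 40–80 of that ATG (the family's
introns sit close to codon 55); an `AG` acceptor giving an intron of
50–5,000 nt; and an in-frame exon 2 running to a stop, with 250–400 codons
in total. Per-frame next-stop indices make the enumeration cheap; each
surviving candidate's spliced protein is aligned against the bait. If the
primary donor window yields nothing, a wider window (codons 10–150) is
tried and any resulting model is flagged `atypical_junction` — receptor
families do contain rare outlier junctions, and they should be reported
rather than silently dropped.

Candidate selection: the bait-alignment score decides, but all candidates
within `junction_tie_margin = 12` score units of the best are re-ranked
first by the family's junction signature (aromatic residue before and basic
residue after the intron), then by agreement of the protein length with the
bait, then score, then the shorter intron, then the smaller donor
coordinate. The two weak priors resolve "intron slide" ambiguities — a
splice placement shifted by a multiple of 3 nt that happens to score a few
points higher against a diverged bait — deterministically and in favour of
the biologically expected junction; a candidate that beats the others by
more than the margin always wins on score alone. Published repertoires were
curated manually at exactly this step; the margin rule is this package's
deterministic replacement, not a reconstruction of that manual process.

A complete model of either kind must cover ≥ 90 % of the bait
(`min_model_coverage`); models below that fall through to the
edge/fragment classification.

**Status.** A locus with no complete model and no disruption is an *edge*
gene when the best hit reaches within `edge_margin = 10` nt of a contig end
and the bait coverage is missing on the corresponding terminal side;
otherwise it is a *fragment*. Genes are named
`<Species>TAR<letter>.<Family><NNN>` with `s`/`p`/`e`/`f` for spliced
genes, pseudogenes, edge genes and fragments (complete single-exon genes
carry no letter).

## Repertoire structure

Percent identity is computed from a global Needleman–Wunsch alignment
(BLOSUM62, gap open 10, extend 1) as identical columns over mutually
aligned (both non-gap) columns — the convention closest to ClustalW's
reported percent identity; the denominator choice matters several points at
low identity and is documented for that reason.

Families are the connected components (single linkage) of the graph linking
pairs at ≥ 40 % identity; subfamilies are components at ≥ 60 % within each
family. Single linkage is the deterministic, permutation-invariant closure
of "pairs identified on a tree"; family letters are assigned by decreasing
size (ties by lexicographically smallest member), so labels are
presentation only, and tests compare partitions, not letters. Ortholog
detection reports maximal cliques of size 2 or 3 at ≥ 99 % identity,
labelling cross-species groups orthologs and single-species groups
paralogs; pairs inside a reported triplet are not reported again.

The guide tree is neighbor-joining (via `ape`) on $d = 1 - \mathrm{id}/100$,
with negative branch-length estimates clamped to zero and flagged.
Maximum-likelihood inference and bootstrap support are deliberately out of
scope; on additive distance matrices NJ reproduces path distances exactly,
which the test suite verifies.

## dN/dS

The pairwise estimator is Nei–Gojobori (1986) with Zhang's modification:
when counting potential synonymous sites, each of a position's three
alternative bases is weighted $R$ if it is a transition and 1 if a
transversion, so $R = 1$ recovers plain NG86. $s + n = 3$ holds for every
codon and every $R$; changes creating stop codons count as nonsynonymous
(configurable). The default is $R = 1$ because published repertoire
analyses using the modified method rarely state the weight employed;
`--tstv-weight` exposes it.

Observed differences are averaged over all orderings of the differing
codon positions (1, 2 or 6 pathways); pathways passing through stop codons
are excluded and the rest renormalized (if every pathway is blocked, the
estimator falls back to counting them). Proportions are Jukes–Cantor
corrected, $d = -\tfrac{3}{4}\ln(1 - \tfrac{4p}{3})$, each proportion
independently: a pair can have a defined $dN$ and an undefined $dS$ (the
`jc_undefined` flag) when only one proportion reaches the $3/4$ domain
boundary. $\omega = dN/dS$ is reported only when $dS > 0$; pairs with
$dN > 0, dS = 0$ are flagged `omega_unbounded` and reported as "> 10"-style
entries in tables, never as numbers entering means. Unequal-length pairs
are codon-aligned through their protein global alignment, dropping codons
opposite gaps from both sequences.

Two NG86 subtleties are worth stating. First, pathway averaging assigns
fractional nonsynonymous differences to codon pairs like CGT/AGA that are
reachable through purely synonymous single steps — so sequences that
diverged under a strictly synonymous process show a tiny positive $dN$,
not exactly zero. Second, with structural constraints (frozen motifs,
hydropathy-restricted TM residues) the realized $\omega$ of a repertoire
sits well below the nominal nonsynonymous acceptance ratio of the
generating process, because the constrained sites contribute synonymous
but no nonsynonymous substitutions; this is visible in the synthetic
benchmark and is the expected signature of purifying selection.

Family summaries report mean/min/max over finite $\omega$ per family with
unbounded counts listed separately; the intra/inter table compares
same-species and cross-species means per species and family, leaving cells
with no pairs empty. By default all within-family pairs enter the means
(which pairs published tables used is typically unstated); the records
table allows any other pairing to be summarized.

## Structural annotation

TM segments are maximal runs where the 19-residue Kyte–Doolittle window
mean is ≥ 1.5, merged across gaps of < 5 residues, dropped below 17
residues and trimmed above 35 (centred on the hydropathy peak); runs of
21–28 residues are flagged canonical for this receptor class. This is a
sliding-window annotation, not a topology prediction — TM counts are a soft
annotation, not an acceptance gate for real sequences. Sequon scanning
implements only the N-X-[S/T] (X ≠ P) grammar; no glycosylation propensity
score is computed, and outputs say so. Motif discovery maximizes mean
per-column information content (bits; gap-containing columns down-weighted
by their non-gap fraction) over ungapped windows of widths 6–15 on the
repertoire alignment, greedily selecting the top five non-overlapping
windows — deterministic, and adequate for highly conserved blocks at fixed
alignment positions, which is what receptor repertoires show; it is not an
EM motif finder and will not find dispersed, low-information motifs.
Splice-site logos use fixed windows (donor: last 3 exon + first 6 intron
nt; acceptor: last 12 intron + first 3 exon nt); the window extents are
this package's convention.

## The synthetic benchmark

`simulate_repertoire()` plants a full repertoire with ground truth. Its
defaults are the reference study conditions used by the acceptance script
and tests: 5 species, per species 14 two-exon genes, 4 single-exon genes,
4 frameshift and 2 stop pseudogenes, 4 edge genes, 2 fragments and 4 decoy
GPCRs, on ~30 contigs per species with log-normal lengths (median 25 kb,
matching the contiguity of the draft assemblies this kind of pipeline is
aimed at); 6 ortholog pairs and 2 triplets at ≥ 99 % identity are planted
across species.

Receptors are fixed at 330 codons with a fixed architecture: seven
28-residue TM blocks drawn from hydrophobic residues, polar loops, and five
frozen 6-residue motif blocks in loops and termini. Genes evolve from a
root ancestor through family and subfamily ancestors by a codon-level
proposal/acceptance process (transitions weighted `tstv = 2`; synonymous
proposals accepted, nonsynonymous with probability `omega = 0.4`; proposals
creating stops rejected; TM positions restricted to hydrophobic and loop
positions to polar residues so deep divergence preserves the 7-TM
hydropathy profile). Divergence targets (gene → subfamily ancestor 85 %,
subfamily → family 71 %, family chain 25 %) were calibrated so that the
*measured* (gap-excluded global-alignment) identity bands land at roughly
70–76 % within subfamilies, 40–52 % within families and 18–34 % between
families — comfortably separated from the 40/60 thresholds. The
calibration is needed because gap-excluded identity runs several points
above per-site identity at low similarity. Family ancestors form a chain
(each evolved to 25 % identity of the previous) rather than a star, which
bounds every between-family pair away from the family threshold.

Two-exon genes get an intron of 70–3,000 nt after a codon drawn from a
clipped normal around position 55 (codons 42–75); the junction codons are
set to a dipeptide drawn from {FR: 0.79, FK: 0.14, YR: 0.04, LT: 0.03},
echoing the observed junction census of this family. Intron interiors are
random DNA constrained to start `GT`, end `AG`, and contain no other `AG`
within 6 nt of the acceptor (avoiding untestable splice ties). Pseudogenes
are single-exon backbones with a 1–2 nt indel or a stop substitution at a
codon drawn from 45–285 — central enough that both flanking segments
remain individually detectable at the 10⁻⁵⁰ cutoff. Edge genes retain
55–70 % of the CDS abutting a contig boundary and fragments 55–75 %
internally; shorter remnants at the baits' divergence cannot clear a
10⁻⁵⁰ E-value bar under any scoring regime, so the default study condition
keeps the planted classes detectable (the `truncate_to_edge()` operation
itself accepts 30–70 %). Positive baits are relatives of the subfamily
ancestors at 80 % identity; negative baits derive from independent decoy
ancestors, so the negative filter's task is well-posed.

What the benchmark does *not* emulate: repeats, assembly gaps (N runs),
sequencing error, length variation among receptors, non-canonical splice
sites, more than one intron, and base-composition structure beyond a global
GC setting. Passing the end-to-end tests therefore demonstrates the
correctness of the pipeline's logic under its stated model, not
performance on real assemblies, where bait divergence, atypical gene
structures and assembly artifacts dominate the error budget.

`simulate_omega_pair()` is a separate, unconstrained two-lineage simulator
used to validate the dN/dS estimator: with uniform proposals and
acceptance ratio $\rho$ for nonsynonymous changes, the expected pairwise
$\omega$ equals $\rho$. The default 120 proposals per lineage at 300
codons keep divergence in a regime with enough fixed differences for a
stable ratio but well below Jukes–Cantor saturation.

## Numerical conventions and degenerate inputs

Coordinates are 0-based half-open internally and 1-based inclusive in GFF3
output; all introns are phase 0 by construction, and the GFF3 writer emits
phase-0 CDS rows. Codons containing `N` translate to `X`, score like `X`
in alignments, and are dropped from dN/dS counts. Lowercase FASTA input is
uppercased; `U` is rejected. Empty alignments score 0; empty hit lists,
empty families and catalogues without spliced genes produce empty tables
or explicit errors, never silent partial output. All tie-breaks (splice
candidates, motif windows, family letters) are deterministic, so identical
inputs give byte-identical reports.

## Known limitations

* Gene models with more than one intron are out of scope (the modelled
  family shows at most one).
* E-values are approximate (ungapped-theory parameters applied to gapped
  scores, no length correction); cutoffs are calibrated choices, not
  probabilities.
* Frameshift breakpoints are located to ~±8 codons; stop positions are
  exact.
* The family/subfamily letters and numbers are stable only for a fixed
  input set; adding sequences can relabel (but not repartition) groups.
* NJ replaces likelihood phylogenetics; no branch support is computed.
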
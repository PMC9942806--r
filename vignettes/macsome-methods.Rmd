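---
title: "Methods: somatic genome architecture and domesticated-transposase screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic genome architecture and domesticated-transposase screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macsome)
```

## Background

Ciliates carry two kinds of nuclei: a germline micronucleus (MIC) and a
somatic macronucleus (MAC) whose genome is extensively edited during
development.  In heterotrichs such as *Blepharisma stoltei* the MAC genome
is naturally fragmented into DNA molecules capped by telomeres, with many
*alternative telomere addition sites* (ATASs): internal assembly positions
where a minority of sequenced molecules end and receive a telomere.
`macsome` implements the sequence-level analyses that characterise this
architecture from long, high-accuracy (HiFi-like) reads, together with the
protein-level screens used to study the MAC-encoded PiggyBac transposase
homologs that are candidate DNA excisases: catalytic-triad (DDD) calling,
cysteine-rich-domain detection, pairwise dN/dS, and a developmental
fold-change ranking.  Every stage has a seeded simulator with known ground
truth, so the whole pipeline is testable without any external data.

## Telomere run detection

The *Blepharisma* telomeric repeat unit is `CCCTAACA` on the C-rich strand.
A telomeric tract on a read may begin at any phase of the repeat, so a
"repeat" is taken to be any cyclic rotation of the unit; the G-rich strand
is matched through the rotations of the reverse complement.  A *run* is a
maximal substring of the read that is a substring of the infinite
repetition of the unit (in either orientation).  Detection uses the
observation that any such stretch longer than one unit has exact period
`|unit|`, and that within a region of period `k` every `k`-window is a
cyclic rotation of the first: the scanner finds maximal period-`k` regions
and classifies each with a single membership test.  The reported span
includes flanking partial units, while `n_repeats` counts complete units
(`floor(span/|unit|)`); a run qualifies with at least `min_repeats = 3`
complete units, the "at least three consecutive repeats" convention for
calling a read telomere-bearing.

Choices worth making explicit:

* **Rotation, not letter permutation.** "Permutation" of the unit is read
  as cyclic rotation (repeat phase).  Arbitrary letter permutations would
  match large amounts of non-telomeric AT-rich sequence.
* **Exact matching by default.** HiFi reads are accurate enough that
  mismatch tolerance mostly adds false extension; a `max_mismatch` budget
  is available (it merges runs lying on the same global repeat phase across
  isolated mismatched bases) but defaults to 0 and is off in all tests.
* **Terminal tolerance.** A run counts as terminal when it starts or ends
  within `end_tol = 50` bp of the read end, allowing for adapter remnants
  or junk at read ends.
* Reads are classified `none` / `five_prime` / `three_prime` / `both_ends`
  / `internal_only`; a read is telomere-bearing iff its class is not
  `none`.  Trimming removes the full terminal spans (including partial
  units) so that "length excluding telomeres" is well defined.

The scanner is validated against a brute-force oracle that tests sequences
against every global tiling phase of the unit; the two agree exactly on
thousands of random and constructed sequences.

## ATAS calling

Given per-read telomere annotations and read-to-assembly alignments (PAF,
or SAM/BAM through `read_aln_sam()`), a junction is emitted wherever a
terminal telomeric run abuts the aligned part of the read: the run must end
within `junction_tol = 20` bp of the aligned query interval.  The junction
coordinate is the strand-appropriate reference boundary (5′ telomere on a
`+` alignment → `rstart`, side `left`; on `−` → `rend`, side `right`;
symmetric for 3′ telomeres).  Identical `(contig, pos, side)` junctions are
aggregated into one call with a support count; coverage is the number of
qualifying primary alignments spanning the position, and `telo_frac` their
ratio.

* Only primary alignments take part: a telomere junction must be anchored
  uniquely; secondary/supplementary placements are discarded entirely.
* No positional clustering is applied by default — HiFi accuracy makes
  exact junction coordinates meaningful.
* Sites within `end_margin = 100` bp of a contig end whose telomere
  fraction reaches 0.5 are labelled contig termini, not ATASs.  The
  biological distinction is that ATASs are *minority*-telomere internal
  positions; the 0.5 cutoff is this package's operational default, exposed
  as a parameter.
* Coordinates are 0-based internally and in BED output; the TSV keeps an
  extra 1-based column for human reading.

On error-free simulated reads with truth alignments, every call coincides
exactly with a planted junction or a molecule terminus, and at the default
study scale (5 × 100 kbp contigs, 200 junctions at usage 0.02–0.3, 20,000
reads) recall and precision of exact `(contig, pos, side)` recovery are
≥ 0.99.

## Inter-telomere spacing and genome statistics

If reads of trimmed mean length $\bar L$ sample DNA molecules of mean
length $M$ uniformly, molecule ends (telomeres) occur at density $2/M$ and
a read covers one with probability $\approx 2\bar L/M$.  Writing $p$ for
the observed telomere-bearing read fraction, the *linear* estimator is

$$\hat M = \frac{2 \bar L}{p},$$

and a Poisson variant $\hat M = 2\bar L / (-\log(1-p))$ corrects for reads
carrying more than one telomere.  Both are reported; confidence intervals
come from a seeded nonparametric bootstrap over reads.  With $p = 1/8$ and
$\bar L = 8{,}125$ bp the linear form gives 130 kbp, the worked example in
the package tests.  The estimator recovers a planted 130 kbp molecule
length within 5 % from 10,000 simulated reads, with bootstrap CIs covering
the truth in ≥ 45/50 seeded replicates.

Other summaries are deliberately plain arithmetic: individual
heterozygosity is `n_het_snps / callable_len` (the callable denominator
defaults to assembly length; the published strain rates are reproduced
from the published SNP counts with a callable length of ~41.46 Mbp);
AT fraction is computed over unambiguous bases; intron lengths are the
gaps between consecutive exon features of each transcript under 1-based
inclusive GFF arithmetic.  Architecture classification (nanochromosomal /
minichromosomal / chromosomal) uses rough, configurable thresholds
(≤ 10 kbp or ≤ 2 genes; ≥ 500 kbp), reflecting that the published
categories overlap and are explicitly approximate.

## Synthetic data: what it emulates and what it does not

`simulate_mac_genome()` plants telomere-addition junctions along AT-rich
contigs (66 % AT by default).  Each junction has a side and a usage
probability; when a read is drawn, the molecule containing its genomic
anchor point is delimited by independently activating each junction with
its usage — different reads therefore see different molecule boundaries at
the same locus, as different cells do in a real population.

`simulate_reads()` draws trimmed read lengths from a lognormal with mean
8 kbp truncated to 1–12 kbp.  The mean is a modelling choice (the
qualitative description of the read set constrains only the range: bound
reads as short as 4 kbp, a 12 kbp maximum excluding telomeres); it is
configurable.  A read of length $L$ on a molecule of length $M$ covers an
end with probability $\min(1, 2L/M)$ — the renewal-density rate at which
random fragments encounter molecule ends — so the telomere-bearing
fraction converges to $2\bar L/M$ by construction, matching the estimator
model exactly; reads at least as long as their molecule carry telomeres at
both ends.  Telomeric tracts have a shifted-geometric number of complete
units (minimum 3) at a uniformly random rotation phase, C-rich facing the
molecule start, so read 5′ tracts are C-rich as in real data.  Errors are
substitutions only at a constant rate (HiFi-like); there are no indels and
no quality-score model.  Truth tables and 12-column truth PAF records
allow every downstream stage to be tested without an aligner.

What passing these tests does *not* show: robustness to alignment error,
indels, chimeric reads, copy-number variation between loci, or biased
molecule sampling — all present in real libraries and all outside the
generative model.

`simulate_codon_pair()` evolves a descendant from a random stop-free
ancestor under a continuous-time Markov codon process in which
single-nucleotide exchanges have rate 1 if synonymous and rate `omega_true`
if nonsynonymous, with no pathways into stops; the generator is scaled so
`t` is the expected number of substitutions per codon and transition
probabilities are computed by matrix exponential (exact for any `t`).
`simulate_expression()` draws negative-binomial counts with lognormal
baseline means and scales a planted gene set in the target sample only;
the default planted fold-change range (69–825×) spans the range reported
for the top up-regulated development genes.

## Pairwise dN/dS

The package implements the Nei–Gojobori (1986) counting method:
per-position synonymous site fractions over valid single-nucleotide
neighbours, observed differences averaged over all minimal mutational
pathways, and a Jukes–Cantor correction
$d = -\tfrac34\log(1 - \tfrac43 p)$, with $\omega = d_N/d_S$.  Conventions:

* **Stop codons are excluded from the mutational opportunity**: neighbours
  that are stops do not count as sites, and pathways through stops are
  discarded (with equal weighting of the remainder; if every pathway
  passes through a stop, all are kept as a fallback).  Under this
  convention $N + S = 3 \times n_\text{codons}$ still holds, which is
  asserted against the oracle.
* Gapped codon columns are dropped pairwise (complete deletion).
* Proportions at or beyond the JC saturation point (3/4) yield `NA`
  distances with per-component saturation flags rather than numbers.
* $\omega$ is `NA` (undefined) when both distances are 0 and `Inf` when
  only $d_S$ is 0.
* The default code for *Blepharisma* input is `UGA_to_Trp` (UGA reassigned
  from stop to tryptophan), with the standard code available.

This is a counting method, chosen for transparency and testability: it is
verified against an independent exhaustive pathway-enumeration oracle on
every sense-codon pair under both codes, and recovers planted ω from the
codon simulator (neutral simulations at ω = 1, 2,000 codons, t = 0.3 give
a 50-replicate mean within [0.9, 1.1]).  Maximum-likelihood codon models
would give different absolute values at high divergence; exact agreement
with likelihood software is therefore not claimed, and conclusions are
restricted to regimes (ω ≪ 1 vs ω ≈ 1) where counting and likelihood
methods agree qualitatively.

`back_align()` threads coding sequences through a gapped protein
alignment, stripping terminal stop codons — note that a terminal TGA under
`UGA_to_Trp` is tryptophan, not a stop, and is retained.

## Transposase annotation

Domain presence/absence matrices are built from HMMER `--domtblout`-style
per-domain tables (i-Evalue filter, default ≤ 1e-5), with species lacking
hits retained as all-absent rows and deterministic lexicographic ordering.
The default domain whitelist contains the five transposase PFAM families
named for the *Blepharisma* MAC genome (`DDE_Tnp_1_7`, `DDE_3`,
`DDE_Tnp_IS1595`, `MULE`, `DDE_1`); the full set used in any figure-scale
comparison is user-supplied.

Catalytic-triad calling is alignment-column based: the user supplies a
reference protein and the three 1-based positions of its aspartate (D)
triad — no residue numbering is hard-coded, since triad positions depend
on the alignment in use.  The reference positions are mapped to alignment
columns and the target residues read off; a non-D target residue with an
aspartate exactly one column away (non-gap) is the D′ case, an aspartate
displaced by one residue.  Statuses: `complete` (DDD), `offset_Dprime`,
`incomplete`, `absent` (gapped at all three columns).  The ±1-column D′
tolerance is fixed by the one-residue-translocation definition.

CRD detection is a deliberately simple heuristic — maximal windows of
≤ 60 residues containing ≥ 5 cysteines within the C-terminal 35 % of the
protein, reported with an inter-cysteine spacing string (`C-x2-C-…`) that
round-trips to the cysteine positions.  No published formula defines the
domain; parameters are exposed and results should be treated as candidate
regions, not domain-database calls.

## Expression ranking

The developmental screen is a *ranking*, not a differential-expression
test: fold change is the target-sample value over the unweighted mean of
the baseline samples (starved, gamone-treated, 0 h), with a pseudocount of
0.5 on both terms, descending sort, and lexicographic tie-breaking on gene
id.  TPM normalisation is provided for count input; the ranking itself is
unit-agnostic and invariant to global rescaling.  The pseudocount and the
normalisation are package decisions (recorded in output); dispersion
modelling is intentionally out of scope.  `annotate_top()` counts genes in
the top *k* with hits in a chosen domain set, reproducing the
"transposase domains among the top 100" style of summary.

## Numerical and engineering choices

* All simulators take an integer seed and are bit-reproducible for a fixed
  seed; stochastic tests fix seeds and test distributional properties at
  ±3 standard errors or as replicate success proportions.
* The telomere scanner concatenates reads with a separator byte and works
  on raw vectors, using a cumulative-sum trick to locate qualifying
  periodic regions without enumerating every run; this keeps a 20,000-read
  scan in tens of seconds in pure R.
* Problem sizes used in the shipped tests — 1,000 oracle sequences
  ≤ 2 kbp; 5 × 100 kbp contigs / 200 junctions / 20,000 reads for ATAS
  recovery; 10,000 reads × 50 bootstrap replicates for spacing; all codon
  pairs plus 50 × 2,000-codon neutral replicates for dN/dS; 20 × 2,000-gene
  ranking replicates — were chosen as the smallest scales at which the
  statistical claims are sharp.
* Degenerate inputs fail loudly: empty annotation sets, `p = 0` or
  `p = 1` in spacing estimation, zero-length genes, non-positive
  dispersion, stop codons inside codon alignments, and reference triad
  positions that are not aspartate all raise errors rather than returning
  silent values.

## Limitations

The ATAS caller trusts the alignments it is given; it does not realign or
detect chimeras.  The spacing estimators assume uniform molecule sampling
and reads much shorter than molecules; the Poisson variant only partially
relaxes this.  NG86 underestimates divergence at saturation and ignores
transition/transversion and codon-usage bias.  The CRD heuristic has no
statistical calibration.  None of the simulators model indels, and the
expression simulator plants a single up-regulated condition rather than a
full time course.
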
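---
title: "Amp-seq surveillance of insecticide resistance: models and methods"
author: "stephseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amp-seq surveillance of insecticide resistance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stephseq)
```

## The problem

*Anopheles stephensi*, an invasive malaria vector spreading through the
Horn of Africa, is monitored for insecticide-resistance alleles by targeted
amplicon sequencing (Amp-seq): ~500 bp PCR amplicons spanning known
resistance codons in *vgsc* (pyrethroid/DDT knock-down resistance, kdr),
*rdl* (cyclodiene resistance), *ace1* (carbamates/organophosphates) and
*GSTe2* (metabolic DDT resistance), plus the phylogenetic markers *its2*
and *cox1*, are amplified per mosquito with inline 6-bp sample barcodes on
both primers, pooled up to 200 amplicons per pool, and sequenced 2 x 250 bp.
`stephseq` implements the complete desk-side half of that assay: panel
definition, read simulation, demultiplexing, alignment and pileup
construction, dual-caller variant calling with the assay's filters,
genotype classification, codon-effect annotation with cross-species marker
numbering, and population genetics on consensus haplotypes.

Everything is testable without external data: the synthetic-data generator
is a first-class module whose defaults are the study conditions the
pipeline is designed for.

## The default panel

`buildDefaultPanel()` defines 10 amplicons across 6 loci (four *vgsc*
domains as VGSCI, VGSCII and the combined VGSCIII/IV; ACE1_I and ACE1_II;
Rdl1 and Rdl2; GSTe2; ITS2; CO1). The reference sequences are synthetic —
drawn once from a seeded uniform base distribution — because the pipeline
operates entirely in amplicon-local coordinates; no genome build is
embedded. What is real is the *structure*: every coding amplicon carries a
gene model (CDS interval, strand, codon offset) placed so that the seven
published resistance codons (vgsc L958F; rdl A296S, V327I, T345S; ace1
G119S, N177D; GSTe2 V189L) sit at their native codon numbers and are one
nucleotide substitution away from the resistance amino acid, exactly as in
the real gene sequences. GSTe2 is modelled on the minus strand so the
reverse-complement annotation path is exercised by default. Ortholog
numbering is carried as pure codon offsets (vgsc +56 to *Musca domestica*
numbering, so L958F reports as L1014F; rdl +5 to *Drosophila melanogaster*,
A296S as A301S).

Real primer and reference sequences can be substituted by editing the YAML
panel config (`writePanel()` / `readPanel()`), which round-trips
byte-identically.

## The simulator and what it does (not) emulate

`simulatePool()` emulates the sequencer output for one pool:

* read 1 = forward barcode + forward primer + template; read 2 = reverse
  barcode + reverse primer + reverse-complement template. Fragment length
  equals amplicon length (amplicon sequencing has no shearing), so 2 x 250
  reads overlap mid-amplicon on ~500 bp templates.
* per-unit read counts are Poisson with mean `readsPerAmplicon`
  (default 250, the design coverage of a 200-unit pool sequenced to 50,000
  pairs).
* per-sample genotypes at planted sites are drawn from Hardy-Weinberg
  proportions at the configured population allele frequency; heterozygotes
  emit alt-bearing strands with probability 0.5 per fragment.
* base qualities are two-level (phred 37, with 10% of bases at phred 20 by
  default); substitution errors are applied per base with probability
  proportional to the base's phred error probability, rescaled so the mean
  equals `baseErrorRate` (default 0.1%). This makes errors base-quality
  dependent while keeping the overall rate interpretable.
* indels are supported as planted single events (`+SEQ` / `-N`) only.

Not emulated: chimeric reads, index hopping, PCR duplicates, quality decay
along the read, and real error-motif biases. Passing tests therefore show
the pipeline's logic is correct under a faithful but idealized error model;
they do not certify performance on degraded libraries.

Barcodes deserve a note. The assay needs many 6-mers with pairwise Hamming
distance >= 3 within a pool so that single-substitution errors demultiplex
unambiguously. Random rejection sampling saturates well below 100 barcodes
(the coding-theory ceiling for 6-mers over a 4-letter alphabet at distance
3 is modest), so `generateBarcodes()` uses the hexacode — the [6,3,4]
linear code over GF(4), 64 codewords at pairwise distance >= 4 — passed
through a seed-dependent distance-preserving isometry (position
permutation, per-position symbol relabelling). 64 barcodes per pool
comfortably cover a 200-amplicon pool at two barcodes per sample; larger
studies use more pools, which is also how the replication filter expects
the design to look.

## Demultiplexing

Barcodes are read from a fixed 6-base window at position 0 of each mate (no
indel search — inline tags sit at the exact 5' end). Both mates must
resolve to the *same* sample (the barcode combination); ambiguous or
conflicting pairs are kept, untrimmed, as UNASSIGNED with a reason code.
The amplicon is assigned from the read-1 forward primer (best primer by
mismatch count, ties unassigned) and cross-checked against the read-2
reverse primer when that maps. Defaults: 1 barcode mismatch, 2 primer
mismatches — the tolerances are configurable since the original protocol
does not state any. Quality trimming keeps each mate through the last
4-base window with mean phred >= 20, then extends until the first base
below 20; with the default simulator qualities this trims nothing, which is
intentional — trimming behaviour is a property of real data the simulator
does not model. Counts are conserved (assigned + unassigned = input) and
demultiplexing is deterministic and order-independent.

## Alignment and pileups

Demultiplexing fixes the amplicon and the primer anchors the read, so each
mate has a known expected placement. `alignToAmplicon()` first tries that
placement ungapped (accepted when mismatches stay under 15% of the read);
reads that fail — indel carriers, clipped or foreign reads — fall through
to a local affine-gap alignment (`Biostrings::pairwiseAlignment`).
Alignments with a soft-clip run over 50 bases, or scoring under 60% of the
perfect score, are discarded and counted. Overlapping mate bases are
reconciled: agreement keeps the higher phred; disagreement keeps the
higher-phred base with its quality capped at the difference (so an exact
tie yields quality 0 and is removed by the base-quality floor).

`buildPileup()` excludes bases below phred 30 (the assay's per-called-base
floor) *before* counting, so depth (DP) is the post-filter pileup depth.
Indel events are aggregated separately from the base counts; deletion-spanned
positions contribute a DEL row to depth.

## Calling, genotypes and filters

Two callers read the same pileup, and their union is reported — the
dual-caller design is a cross-check, not an ensemble:

* the **frequency caller** emits a call wherever the most frequent
  non-reference allele has alternate depth >= 10 at depth >= 30, with a
  site quality equal to the phred-scaled binomial tail probability of that
  many error bases at the site's mean base-error rate. Indels are called by
  this caller only.
* the **genotype-likelihood caller** computes diploid likelihoods of
  hom-ref / het / hom-alt under a symmetric error model driven by the
  observed phred scores (binned by quality level, which is exact) and emits
  a call when a non-hom-ref genotype has posterior > 0.99 under a uniform
  prior; its site quality is the phred of the hom-ref posterior.

Sites emitted by one caller only are flagged `single_caller`; conflicting
alternate alleles at one position are kept as separate flagged records.

Genotypes come from the alternate-allele read fraction: < 25% hom-ref,
> 75% hom-alt, the closed band [25%, 75%] het. Both boundaries classify
as heterozygous, matching the inclusive het band and strict homozygote
inequalities of the published rule.

The replication filter retains a variant key only when carried
(non-hom-ref, no site-level flag) by >= 2 samples spanning >= 2 independent
pools; dropped keys are flagged `singleton` / `single_pool` on every
record, never deleted. Single-pool runs can relax `minPools` to 1 — a
documented deviation for bench-scale use. Depth thresholds are applied
inclusively (DP >= 30) everywhere.

## Annotation

A compact effect engine maps amplicon position to contig to CDS coordinate
honouring strand and phase, builds reference and alternate codons,
translates with the standard genetic code and classifies: synonymous,
missense, nonsense; indels are frameshift unless length is a multiple of
three; positions outside every CDS interval are non-coding; variants
overlapping a CDS boundary are flagged composite rather than dropped.
Alleles are always expressed on the amplicon plus strand; complementation
for minus-strand genes is internal. The marker report counts carriers (het
or hom-alt) per resistance marker with the allele frequency
(het + 2 hom-alt) / (2 genotyped); the denominator is the number of
samples whose pileup reaches the depth floor at the marker site, and it is
always printed beside the percentage, because percentages without
denominators are ambiguous.

## Population genetics

Per-sample consensus haplotypes are built from pileups of the phylogenetic
amplicons: samples are kept only when mean depth exceeds 50-fold; the
majority base is emitted per position, N where depth falls below 5, and
heterozygous sites (alternate fraction inside the het band) can optionally
be encoded as IUPAC ambiguity codes (default: major allele, since the
downstream statistics treat sequences as haploid haplotypes).

All statistics use complete deletion: alignment columns containing N or a
gap in any sequence are masked set-wide first (the common default; a
pairwise-deletion option was considered and rejected to keep every
statistic computed on one common site set).

* nucleotide diversity `pi` = sum of pairwise differences / (C(n,2) * L);
* haplotype diversity `Hd` = n/(n-1) * (1 - sum p_i^2);
* Watterson's `theta_W` = S / a1 (per locus);
* Tajima's `D` = (pi*L - theta_W) / sqrt(e1*S + e2*S*(S-1)) with the
  standard a1, a2, b1, b2, c1, c2, e1, e2 coefficients. D is reported NA
  when S = 0, and also when the variance term degenerates (at n = 3 the
  c1 coefficient vanishes exactly, so D is undefined for a single
  segregating site there).

One subtlety: `pi` with the C(n,2) denominator is *not* exactly invariant
under duplicating the whole sequence set (self-pairs contribute zeros); it
scales by 2(n-1)/(2n-1). The tests assert this exact factor rather than
pretending invariance.

Haplotype networks collapse identical masked sequences into nodes with
population-stratified counts and connect them by a minimum spanning tree of
the pairwise-difference matrix (Prim's algorithm, lexicographic tie-break on
node labels for determinism); edge weights are nucleotide differences — the
tick marks of the classic figure. A strict MST was chosen over TCS-style
parsimony networks as the deterministic, testable core; alternative network
algorithms would be extensions. Export is GML/DOT via igraph.

Trees are classical neighbour joining on the same distance matrix
(optional Jukes-Cantor correction), implemented in the package with a
deterministic tie-break on the Q criterion by label order; negative branch
lengths are clamped to zero with the deficit moved to the sister branch so
joined distances are preserved. NJ was implemented (rather than wrapping
`ape::nj`, which serves as an independent oracle in the tests) because the
clamping and tie-break semantics are part of the artifact's contract. A
maximum-likelihood GTR+Gamma treatment with bootstrap, as used for
publication figures, is out of scope; NJ is the self-contained,
deterministic counterpart.

## Numerical and design choices

* One integer seed drives each simulation; derived per-pool seeds are
  `seed + pool index`. All stochastic draws come from R's global RNG inside
  a save/restore guard.
* Text outputs use LF, 6-significant-digit floats and no timestamps, so
  identical runs produce byte-identical VCFs and manifests
  (`tools::md5sum` checksums are recorded in the run manifest).
* VCF output is version 4.2 text with per-sample GT:DP:AD:AF columns,
  FILTER flags (`min_dp`, `min_ad`, `min_qual`, `singleton`,
  `single_pool`, `single_caller`, `allele_conflict`) and caller provenance
  in INFO; files are validated against `VariantAnnotation::readVcf` in the
  test suite.
* Degenerate inputs: empty FASTQ input yields an empty report;
  desynchronized mates are a hard error; an empty pileup rejects consensus
  with a reason; `diversityStats` requires n >= 2; `njTree` requires 3 taxa
  and a symmetric zero-diagonal matrix.

## Problem sizes in the test suite

The suite exercises the full study geometry once (a 200-unit pool at mean
250 pairs per unit, ~50,000 pairs) and otherwise uses 2-25 samples per
pool at depths of 40-120 pairs per unit, 10-20 simulation seeds for the
recovery properties, and 100-1000 randomized trials for the oracle
equivalences. These sizes were chosen so every stochastic check has
comfortable statistical margin (binomial 99% bounds or better) while the
whole suite stays interactive.

## Known limitations

* The synthetic references share no sequence with the real genome, so
  results on the default panel are structural, not biological; real panels
  load through the config file.
* The aligner is amplicon-targeted: it assumes reads come from their
  assigned amplicon and will discard, not rescue, heavily foreign reads.
* Multi-allelic sites are carried as independent keys; no joint genotype
  model across alleles.
* The likelihood caller models substitutions only; indel evidence flows
  through the frequency caller.
* Haplotype networks and NJ trees are exact for the implemented
  definitions but are not substitutes for model-based phylogenetics on
  divergent sequences.
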
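---
title: "Methods: marker discovery and metabolite-guided screening in neemomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker discovery and metabolite-guided screening in neemomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neemomics)
```

`neemomics` reimplements, as reusable and tested R functions, the
computational core of a multi-omics characterisation of neem
(*Azadirachta indica*): microsatellite (SSR) marker mining and
cross-genotype polymorphism calling, filtered SNP/InDel calling with
coding-effect annotation, RPKM expression profiling screened against
metabolite concentrations to nominate limonoid-biosynthesis candidate
genes, and internal-standard calibration-curve quantification of
azadirachtin-class metabolites. This vignette explains each model and the
design decisions behind it; the companion synthetic panel defines the study
conditions under which every stage is validated.

## SSR detection and canonical classes

A microsatellite here is a maximal perfect tandem run of a *primitive*
repeat unit of 1-6 bases (a unit that is not itself a repetition of a
shorter unit, so `AAAA` is reported as `A` x4, never `AA` x2). Detection
thresholds default to the widely used MISA configuration -- at least 10
copies for mononucleotide motifs, 6 for dinucleotides, and 5 for units of
3-6 bases, with loci closer than 100 bases flagged as compound. These are
the shipped defaults of the standard mining tool; analyses that need other
settings pass an `ssr_thresholds()` object.

Scanning is greedy and left-to-right within each unit length: once a run is
emitted, the next run of the same unit length starts strictly after it.
Runs containing `N` are split at the `N`, and reported spans never overlap
one. The scanner is validated against an independent brute-force
enumeration (leftmost-greedy backreference regular expressions per unit
length, plus the same primitivity rule) on a thousand random 10 kb
sequences per run.

Classes group a motif with its cyclic rotations and their reverse
complements and are labelled `X/revcomp(X)` with `X` the lexicographically
smallest member -- the convention behind familiar labels such as `AAG/CTT`
and `A/T`, and the reason class assignment is strand-invariant.

## Flank-anchored SSR polymorphism

Cross-genotype comparison treats assemblies, not reads: every reference
locus is excised together with 100 bases of upstream and downstream flank
(`extract_ssr_regions()`), the flanks are located in the query assembly,
and the query sequence *between* the anchored flanks is re-scanned with the
copy-number minimums relaxed to 2, so shrunken tracts are still counted
(`call_ssr_polymorphism()`). A locus is `polymorphic` when the canonical
class is conserved but the repeat count differs by at least one unit, or
when the locus is absent; a different class is reported separately as
`class_changed`, because a repeat-count comparison across classes is not
marker-grade evidence. Compound and flank-truncated loci are excluded from
polymorphism calling: anchoring and count comparison are ill-posed for
them.

Anchoring is a ladder of increasingly tolerant passes, each still subject
to the same acceptance rule -- both flanks must place *uniquely*, on one
contig, in one orientation, correctly ordered, with an inter-flank span of
at most the locus length + 200 bases:

1. full 100-base flank, three staggered exact 31-mer seeds, extension
   allowing <= 2 mismatches (two mismatches cannot cover three disjoint
   seeds, so a seed always survives);
2. the inner 50 bases with 25-mer seeds and a 1-mismatch budget;
3. an exact innermost 25-mer;
4. an exact 25-mer from bases 26-50 of the flank, with the inferred
   boundary pulled back 13 bases so a small deletion between anchor and
   locus cannot clip the tract (the relaxed re-scan absorbs the extra
   window, and spacer junctions in the synthetic panel are phase-clean, so
   counts stay exact);
5. if exactly one flank anchored, a gap-tolerant `pairwiseAlignment` of the
   other flank inside the window the anchor implies.

The later rungs matter because flanks in real (and simulated) genomes carry
small InDels as well as substitutions; a pure mismatch-extension matcher
silently drops those loci. The original analysis aligned extracted regions
with a gapped short-read aligner, so gap tolerance is part of the method
being reproduced, not an embellishment. Ambiguous (multi-hit) placements
are dropped rather than best-scored -- a marker locus that cannot be placed
uniquely is not usable as a marker.

`concordant_polymorphic()` intersects two call sets made against the same
reference locus list and returns loci polymorphic in *both* query
genotypes, the shortlist of markers expected to segregate across all three
genotypes.

## Pileup variant calling and effect annotation

`pileup_call()` consumes plain SAM text (or the simulator's alignment
tibbles) and performs haploid-style consensus calling: per-site base
columns are built from the gapped alignments, and a substitution is emitted
where an alternative base reaches 80% of the site depth. The 0.8 consensus
fraction reflects that the compared genotypes are assemblies of a
predominantly selfing tree -- variants are genotype differences, not
heterozygous sites. Insertions and deletions are taken from the alignment
gap operations and *left-aligned* against the reference before reporting,
so coordinates are deterministic inside repeat tracts. Their supporting
fraction uses a junction denominator: only reads spanning both reference
bases flanking the event can witness it, so reads that merely touch one
side neither support nor count against it. This keeps the fraction unbiased
for insertions longer than the overlap of a partially covering read.

Call confidence is a Phred-scaled binomial score of the alternative count
against a fixed 1% per-base error rate, and the published filter is applied
as variant quality > 30 with depth >= 10 (`pass`), after discarding input
records below mapping quality 20. The ">30" quality in the source protocol
is ambiguous between mapping and variant quality; interpreting it as
variant quality with a conventional mapping-quality floor matches how the
cited consensus-calling stack behaves. Raising either threshold can only
shrink the pass set, and the suite asserts that monotonicity.

`annotate_variants()` classifies positions as exonic > intronic > upstream
/ downstream (5,000 bases, strand-aware -- the cited annotation tool's
default window) > intergenic. For exonic SNPs the affected codon is rebuilt
on the coding strand (CDS spans concatenated in transcription order, phase
respected) and translated with the standard genetic code:
synonymous, nonsynonymous, start_lost (first codon), stop_gained, or
stop_lost (terminal codon). The suite checks every planted exonic SNP
against an oracle that translates the full reference and mutant proteins
and diffs them. `marker_density()` reports markers per 1,000 bases at two
significant figures while retaining full precision.

## RPKM profiling and the metabolite correlation screen

Expression is quantified as RPKM = count x 10^9 / (gene length x total
mapped reads), with the per-tissue denominator taken as reads mapped to the
gene set so the matrix is self-contained and reproducible from its stored
counts. Genes are partitioned into ubiquitous (RPKM >= 1 in every tissue),
tissue-specific (exactly one tissue), and other; expressed-gene tallies are
reported at the conventional RPKM > 1, 5, 10 thresholds.

The candidate screen is deliberately simple, because the selection rule
that the source analysis actually applied was a Pearson correlation: each
gene's RPKM profile across tissues is correlated with the per-tissue
metabolite concentration, and candidates must also show the contrasting
tissue pattern (higher expression in developing endosperm than mature leaf
for azadirachtin). Tier `r08` requires r >= 0.8 plus the contrast; tier
`r09` additionally r >= 0.9. Both thresholds are inclusive and
configurable, since the source mixes "above +0.8" with ">= 0.9"; inclusive
is the weaker reading and the boundary case is pinned in a test. Genes with
zero expression variance -- or a constant metabolite vector -- are flagged
undefined rather than silently given r = 0. The weighted-network step of
the original analysis is represented by the two outputs it actually
contributed downstream: the tissue dendrogram (`cluster_tissues()`, average
linkage on log2(RPKM+1) distances) and the per-gene correlation ranking;
the full topological-overlap machinery is out of scope.

`ddct_fold_change()` is the standard qPCR companion: replicate wells are
averaged on the Ct scale, and fold change is `2^-(dCt_sample -
dCt_calibrator)` against a reference gene.

## Calibration curves and absolute quantification

Quantification follows the internal-standard construction: the response
ratio (analyte peak area / internal-standard area) is regressed on the
amount on column by ordinary least squares -- unweighted by default, since
no weighting scheme is part of the stated method; `1/x` weighting is
exposed as an option. The linearity statistic `r` is the product-moment
correlation of ratio and amount. Because both calibration and samples are
ratios to the same spiked internal standard, its absolute amount cancels
and is carried only as metadata.

`quantify()` inverts the fitted line and scales through the preparation
chain -- 2 mg dry powder extracted in 1 mL, a 5 uL aliquot in a 50 uL final
mix, 10 uL injected, by default -- to report pg per microgram of dry
tissue. Amounts outside the calibrated range are flagged `extrapolated`
(the top standard itself is in range; a tiny relative tolerance guards the
float boundary), and ratios at or below the intercept are flagged
`below_quantification` and reported as `NA`, never as negative
concentrations. The noiseless round trip -- forward-simulating a sample of
known concentration through the same chain and quantifying it -- is exact
to floating precision, and changing prep volumes while holding the physical
sample fixed leaves the reported concentration unchanged.

`fold_range()` is the integer part of `high/low`: the only rule consistent
with both printed descriptions of the dilution series (64 from 998.4/15.6 =
64.0 and 73 from 250/3.4 = 73.5).

## The synthetic panel: what it emulates and what it does not

`generate_panel()` builds the entire study design from one seed, with all
submodule seeds derived by fixed offsets:

* **Reference assembly** -- 6 contigs x 75 kb whose 550 SSR tracts are
  separated by rejection-sampled spacers guaranteed to contain no SSR at
  detection thresholds, checked on windows that include the full
  neighbouring tracts so no run can cross a junction or shift a tract's
  phase. Detector precision is therefore measurable against an exact truth
  table.
* **Gene models** -- 250 fully coding genes (2-3 exons, valid phases,
  genuine ATG/TAA terminal codons rewritten into the spacers before the
  SSR-free check) tiling roughly a third of each contig.
* **Query genotypes** -- G2 and G3 derive from the reference by an explicit
  edit script: 60 SSR loci per genotype changed by +/-1..4 repeat units,
  SNPs at 3 per kb, and 1-10-base InDels at 0.23 per kb (the genome-wide
  SNP:InDel ratio of about 13:1 observed in the emulated study). Counts are
  binomial in the contig length; placement is uniform over the mutable
  interior -- outside SSR tracts (6-base buffer) and away from contig ends,
  where uniform read simulation cannot supply full depth. Every
  reference/query difference, including the SSR repeat changes re-expressed
  as left-normalised InDels, appears in the variant truth table, and a test
  rebuilds each query byte-for-byte from reference + truth ("truth
  closure").
* **Reads** -- error-free 100-base reads at 30x from either genotype, each
  emitted with its true reference position and gapped CIGAR (the simulator
  knows the edit script, so no external aligner is involved). Coverage of
  30x is a free design choice; the emulated study reports only total
  yields.
* **Expression** -- 50 planted genes whose expected RPKM is *exactly*
  proportional to the planted azadirachtin-like concentration vector
  (highest in developing endosperm, lowest in mature leaf, across the seven
  tissues of the pathway analysis), achieved by solving the
  self-consistent library size so proportionality survives the RPKM
  denominator. The remaining 200 genes get tissue profiles independent of
  the metabolite (gene-level scale lognormal sdlog 1.2; per-tissue
  modulation lognormal sdlog 0.3). Counts are expected values (fractional)
  with mean-one lognormal noise at cv 0.1 by default. The universe is
  deliberately a few hundred genes: with only seven tissues a random
  profile clears r >= 0.9 against a spiky concentration vector about 1% of
  the time, so the screen is only meaningful on a prefiltered candidate
  pool -- exactly how the original analysis used it (a set of ~150
  pathway-annotated, endosperm-expressed genes), not on a whole
  transcriptome.
* **Calibration standards** -- two-fold dilution series (15.6 pg to ~1 ng
  by default) with multiplicative lognormal noise at cv 0.01 on the
  response ratio.

The panel does **not** emulate sequencing errors, quality-score
miscalibration, GC or coverage bias, paired-end inserts, heterozygosity,
repetitive DNA beyond the planted SSRs, or assembly artefacts. Passing the
recovery checks therefore demonstrates the correctness of the pipeline's
logic under clean conditions -- not its robustness to noisy real data,
where alignment error and repeat structure would dominate.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere (GFF3/MISA convention).
* Empty sequences scan to an empty locus table; invalid characters raise an
  error naming the offending position.
* Tied alternative alleles at a pileup site resolve to the first
  maximal-count base; with the 0.8 consensus fraction a tie can never pass.
* Binomial quality scores are computed on the log scale, so saturated sites
  (all reads alternative) get large finite Phreds rather than infinities.
* The permutation check shuffles tissue labels of the metabolite vector; a
  spiky vector reproduces itself under roughly 1/7 of permutations, so the
  collapse criterion uses the median tier size across 100 shuffles.
* Problem sizes in the test suite (a 450 kb panel at 30x, 1,000 oracle
  sequences of 10 kb, 1,000 calibration replicates) were chosen so the full
  suite completes in a few minutes while keeping every planted-event class
  represented hundreds of times.

## Known limitations

* The SSR scanner reports perfect repeats only; imperfect or interrupted
  repeats are represented solely by the compound flag.
* Polymorphism calling is assembly-to-assembly; genotyping microsatellites
  from raw reads is out of scope.
* The variant caller has no genotype likelihoods, realignment, or
  multi-sample mode, and reads compressed alignments only after external
  conversion to SAM text.
* The screen ranks genes by a single metabolite profile at a time; joint
  multi-metabolite modelling is not attempted.
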
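---
title: "From two-line variant calls to validated KASP markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From two-line variant calls to validated KASP markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaspforge)
```

## The problem

Kompetitive Allele-Specific PCR (KASP) is a biallelic SNP genotyping
chemistry: two allele-specific forward primers, identical except for their
3' base and each carrying a universal fluorescent-tail sequence (FAM or
HEX), compete for the template together with one common reverse primer.
Given deep sequencing of two inbred lines mapped to a shared reference -
for example RNA-seq of a heat-sensitive and a heat-tolerant maize inbred -
the variant calls of the two lines can be mined for SNPs that distinguish
them, and those SNPs converted into cheap, plate-based genotyping assays
for mapping populations derived from their cross.

`kaspforge` implements the downstream half of that workflow. Upstream read
QC, alignment, and variant calling are out of scope: the package starts
from one VCF per line (GATK-style, optionally SnpEff-annotated), a
reference FASTA, and optionally a per-base depth track, and ends with an
assay table and scored genotyping panels.

## Site comparison

After PASS filtering (`filter_pass()`; FILTER `"."` is kept by default
because variant callers emit it before a filtration step has run, and
dropping such records silently would surprise - a switch drops them),
`diff_sites()` compares the two call sets with two-file `--diff-site`
semantics. The comparison key is (contig, position):

* a position called in only one line is **unique** to that line;
* a position called in both with identical REF and identical ALT-allele
  set is **concordant shared** - both lines differ from the reference the
  same way, so the site is useless for distinguishing them;
* a position called in both with different alleles is a **discordant
  overlap**.

Genotypes are deliberately not part of the key: homozygosity is an assay
design requirement, enforced later as filter criterion (e), not a property
of the site comparison. InDels participate in the comparison (the class
counts of a variant panel include them); restriction to SNPs happens
downstream. Identity is required at the allele level only - requiring
identical genotypes for the shared class would reclassify het/hom
disagreements as overlaps, which is not what the two-file comparison
convention does. REF disagreements at a shared position (possible when
inputs were normalised differently) are classified as discordant overlaps
and tallied with a warning rather than being silently merged.

## Panel summary statistics

`ts_tv_ratio()`, `chrom_variant_rates()`, `window_densities()`,
`mapping_percentages()` and `impact_summary()` reproduce the usual panel
summaries. Conventions that matter:

* **Variant rate** is `floor(length_bp / count)` bases per variant, with a
  pooled genome-wide row computed from total length over total count -
  the convention of published chromosome-wise variant tables.
* **Windows** are non-overlapping, tiled from position 1, 1 Mb by default;
  window size is a parameter, so coarser or finer density tracks are one
  argument away. Window counts always conserve the total variant count.
* **Percentages and ratios** are rounded half away from zero
  (`round_half_up()`), 2 decimals for percentages, 2 for Ts/Tv, 1 for
  panel rates - matching how such tables are conventionally printed. Base
  R's banker's rounding would disagree on exact halves.
* **SnpEff summaries** count one per `ANN` entry, not one per record, and
  percentages are of total annotations. This mirrors SnpEff's own summary
  convention; a record annotated against three transcripts contributes
  three entries. Effect strings are mapped to reporting categories by
  keyword (missense before exon, so compound `&`-joined effects resolve
  to the most specific match).

## The suitability filter

`apply_filter()` screens biallelic SNPs with 50-bp reference flanks
through five criteria, in order:

(a) no InDel call within the 101-bp window around the site;
(b) at most 4 ambiguous bases across both flanks;
(c) read depth of at least 5;
(d) no more than 4 consecutive copies of any 1-5 bp motif;
(e) homozygous-alternate genotype.

Design choices a user should know about:

* **Flanks come from the reference**, without substituting the line's own
  variants. The assay targets the reference-anchored site reported in the
  VCF; a consensus-substitution mode would be an extension.
* **Criterion (a)** can only be evaluated against InDel calls in the same
  line's VCF - the reference flank itself contains no InDels by
  construction, so the line's calls are the only InDel information
  available.
* **Criterion (b)** counts every non-ACGT IUPAC code, not just N - the
  superset reading. Soft-masked (lowercase) reference bases are uppercased
  at ingestion and not treated as ambiguous; masking is a nuisance
  annotation, not sequence uncertainty.
* **Criterion (c)** reads "coverage of at least five" strictly: every
  position of the 101-bp window must reach the threshold, the conservative
  interpretation for assay design. Without a depth track the filter
  degrades to the variant's own DP and flags the candidate
  `depth_approximate`, rather than passing or failing blind.
* **Criterion (d)** is applied to the full window - left flank, site base,
  right flank concatenated - so a tandem run spanning the SNP junction is
  caught. `max_tandem_copies()` counts a homopolymer of length k as k
  copies of a 1-mer; "TATATATATA" is five copies of TA and fails, eight
  bases of it is four copies and passes.
* **Multi-allelic sites** are rejected with a tally before the criteria:
  KASP chemistry resolves exactly two alleles.

`proximity_cull()` then removes every survivor within 20 bp of another
survivor on the same contig - both members of a close pair, since either
SNP sits inside the other's primer footprint; a pair exactly 20 bp apart
is culled. The operation is idempotent. It runs after criteria (a)-(e),
matching the order in which such pipelines describe it.

`select_genomewide()` picks up to 10 SNPs per chromosome by even-quantile
binning: the contig is divided into 10 equal bins and the candidate
nearest each bin midpoint wins, ties to the lower position. Candidates
inside priority intervals (e.g. differentially expressed gene loci from a
companion expression study) are preferred within their bin. Selection is
deterministic and invariant to input order.

## Primer design

No thermodynamic design parameters are standard for KASP - commercial
design is usually outsourced - so the module's defaults are explicit and
configurable (`design_params()`): target Tm 57 degC (the final annealing
temperature of the standard KASP touchdown program), tolerance +/- 3 degC,
untailed lengths 17-30 nt, amplicons under 100 bp (short enough that no
extension step is needed).

The untailed allele-specific primer is a suffix of the left flank plus the
allele base, putting the SNP at the 3' end where mismatch discrimination
is strongest; both allele primers share one genomic footprint. The suffix
length is the shortest whose Tm clears `tm_target - tm_tol`; because the
two primers differ at their 3' base their Tm values differ, and the
*weaker* of the two governs - an assay is only as specific as its less
stable primer. If no length in range reaches the band, the longest usable
primer is returned with a warning rather than failing the assay. Tm is
computed on the untailed portion only: the universal tails do not
hybridise to the template in the early cycles.

Two Tm models are provided: the Wallace rule (2(A+T) + 4(G+C)) and the
default unified nearest-neighbor duplex model (stacked dinucleotide
enthalpies/entropies with terminal initiation terms, entropy salt
correction `0.368 (N-1) ln[Na+]`, Tm = dH / (dS + R ln(CT/4)) at 50 mM
monovalent salt and 0.25 uM total oligo). The implementation is
cross-checked in the test suite against values computed with an
independent implementation of the same published parameter table.

The common reverse primer is the reverse complement of a right-flank
window, placed at the smallest end offset that satisfies both the Tm band
and the amplicon cap. Design is plus-strand only: if the allele-specific
design fails, the assay fails rather than silently flipping strands, which
keeps the allele-to-dye bookkeeping auditable (`swap_dyes` exists for the
deliberate inversion). By default FAM reports line A's allele (allele X)
and HEX line B's (allele Y). There is no hairpin or cross-dimer screen in
this version; that is a known limitation.

Marker ids follow the `MKAM_<chromosome>_<serial>` convention with
two-digit chromosome ordinals and three-digit serials. Serials run across
the panel in (contig, position) order - published marker lists of this
kind number beyond the per-chromosome quota, so a single running counter,
not a per-chromosome one, reproduces the convention. Design is fully
deterministic: re-designing a candidate gives byte-identical output.

## Scoring genotyping panels

`classify_marker()` consumes discrete plate calls (X, Y, HET, MISSING) -
fluorescence-space clustering happens in vendor software and is out of
scope. A marker is **failed** when missing calls exceed half the non-NTC
wells ("majority missing" is nowhere quantified in plate-scoring practice;
0.5 is the package's operationalisation and is configurable) or when any
no-template control amplifies (contamination invalidates the assay).
**Polymorphic** requires concordant opposite homozygous parents and both
homozygous classes among the F2. **Monomorphic** is a single homozygous
class everywhere. Everything else - one allele plus heterozygotes,
discordant parent duplicates - is **partial**: signal exists but the
marker is unusable. Monomorphic and partial are kept distinct and their
sum reported, since validation reports often merge them into one
"unusable" middle category.

`summarize_panel()` computes the conversion metrics: design success rate
(assays designed / sites selected), work success rate (assays producing
calls / assays designed, i.e. everything not failed), and polymorphic
rate, all as percentages to one decimal. No segregation-ratio chi-square
test is applied; the scoring stops at status classification.

## What the synthetic generator emulates - and what it does not

`fixture_spec()` / `simulate_fixture()` generate a complete synthetic
study: uniform-random contigs (default 3 x 1 Mb, about 1,000 variant
sites - large enough to exercise every stage, small enough to run in
seconds), two VCFs whose site classification is known exactly by
construction, planted violations of each filter criterion, close pairs for
the cull, a depth track with dips, priority intervals, and F2 plates with
the parents duplicated, two NTCs and 90 F2 individuals segregating 1:2:1.
One integer seed drives a separate derived stream per artifact kind, so
every artifact is byte-reproducible and adding a generator never perturbs
existing fixtures.

Two generator properties are worth stating plainly:

* Roughly 40% of uniform-random 101-bp windows contain a legitimate
  5-copy tandem run, so windows of sites *not* planted as repeat
  violations are deterministically resampled until clean. Planted
  rejection counts are therefore exact - by construction, not by luck.
* Planted site positions keep a minimum spacing (except deliberate close
  pairs), so criterion windows never interact.

The generator emulates class structure, filter violations and plate
patterns. It does **not** emulate linkage disequilibrium, recombination
maps, realistic base composition, transcript structure, alignment
artefacts or allele-specific expression - so passing tests demonstrate
the correctness of the pipeline's logic on well-posed inputs, not
robustness to the pathologies of real RNA-seq variant calls. The
published retained-count figures of real panels (hundreds of thousands of
SNPs surviving filtering) depend on unpublished read data and are not
reproducible here; the package reproduces the *arithmetic* of such
studies (variant rates, mapping percentages, conversion rates) and the
*behaviour* of every pipeline stage against planted truth.

## Numerical and degenerate-input conventions

* All user-facing coordinates are 1-based (VCF convention); bedGraph and
  BED are converted from 0-based half-open at the boundary.
* Depth queries beyond a track's end return 0; a missing depth track is
  "unknown", not zero - it switches criterion (c) to DP-fallback mode.
* Sites closer than the flank width to a contig end raise
  `flank_unavailable` (and are tallied, not fatal, inside
  `apply_filter()`).
* A Ts/Tv ratio with zero transversions is reported absent with a
  warning, as is a variant rate with zero variants.
* `summarize_panel()` with zero designed assays reports absent rates
  rather than dividing by zero.
* Multi-allelic VCF records are split per ALT at ingestion, keeping the
  original genotype, so SNP/InDel status is per-allele and unambiguous.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on synthetic
fixtures: the default 3 x 1 Mb genome for the end-to-end smoke test, 60-90
kb contigs for planted-truth recovery, an exhaustive enumeration of all
{A,C} strings up to length 12 against a brute-force tandem-repeat oracle,
100 seeded candidate sets for cull idempotence, and a 10,000-individual F2
draw for the segregation check. These sizes were chosen so the whole suite
exercises every stage at study-like density while remaining a
seconds-to-minutes run on a laptop.
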
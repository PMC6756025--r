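---
title: "Familial loss-of-function variant analysis: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Familial loss-of-function variant analysis: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famlof)
```

`famlof` chains five pieces of evidence for a candidate germline
loss-of-function (LoF) variant in a familial cancer study: predicted
transcript/protein consequence, germline origin, within-family segregation,
cross-family recurrence, and case-control carrier burden. This vignette
documents the model behind each step, the tunable parameters with their
defaults and rationale, the numerical conventions, and what the synthetic
cohorts do and do not emulate.

## Coordinates and transcript models

Genomic inputs follow the VCF/GFF3 convention (1-based, inclusive); all
reported positions are 1-based. A transcript model is a strand-aware set of
non-overlapping exons plus strand-independent genomic CDS bounds; the spliced
CDS includes the stop codon. `g_to_c()` maps genomic positions onto the
coding (`c.`) scale: `c.1` is the first base of the start codon, 5'UTR
positions are negative (`c.-k`), 3'UTR positions count past the stop
(`c.*k`), and intronic positions are anchored to the nearest exonic base with
a signed offset — donor side `N+k`, acceptor side `M-k`, ties going to the
donor side. `c_to_g()` is the exact inverse on the image of `g_to_c()`, a
property the test suite exercises on hundreds of random positions per
transcript on both strands. Variant REF/ALT alleles are genome-forward (VCF
is the source of truth); the annotator reverse-complements them for
minus-strand transcripts so HGVS `c.` names are transcript-oriented.

Positions up to `flank` (default 5000 bp) beyond the transcript span are
still mapped, labelled on the extended UTR scale; the flank only affects the
labelling of far-away positions, never intragenic calls.

One transcript per gene is assumed downstream. Where a GFF3 supplies several,
`pick_transcript()` keeps the longest CDS, breaking ties by transcript id.
Model validity (CDS length divisible by 3, ATG start, stop end) is checked at
load and *flagged*, not fatal: transcript models are input data, and a
curated model that fails a check should be visible, not silently dropped.

## Consequence prediction

Coding SNVs are compared codon-wise against the standard genetic code.
A variant converting the native stop codon to a sense codon is a stop-loss;
one creating a stop upstream of the native one is a stop-gain with the PTC
position recorded. CDS indels are called frameshift when the length change is
not a multiple of 3 (left-trimmed input is assumed; indel normalisation
beyond that is out of scope).

**Canonical splice variants.** Only SNVs at intronic offsets +1/+2 (donor)
and -1/-2 (acceptor) are treated as splice-disrupting, and their effect is
modelled as skipping the single adjacent exon — the donor variant skips the
exon it follows, the acceptor variant the exon it precedes. This mirrors the
dominant in-silico expectation for donor-site loss (exon skipping) while
keeping the model testable: the skipped product is rebuilt and re-translated
outright, so frameshift status, the first affected codon and any new PTC are
computed, not guessed. Intron retention and cryptic splice sites are
deliberately out of scope; when the adjacent exon is terminal or contains a
CDS boundary the effect is reported as "terminal exon, effect unresolved"
rather than computed. Whatever the skip outcome, a canonical splice call is
truncating for masking purposes.

**Frameshift naming.** The fs anchor is the first codon whose underlying
nucleotides change, reported even when its encoded residue is coincidentally
preserved (so an exon skip beginning inside an Arg codon that still reads Arg
is named `p.Arg<k>Argfs*N`), and the stop offset `N` counts the anchor codon
as 1. This is the convention that makes the protein name agree with a
nucleotide-level view of where the change begins.

**NMD.** The classical rule: a PTC triggers decay when its first nucleotide
lies at least 50 nt upstream of the last exon–exon junction of the spliced
transcript, measured in mRNA coordinates, *inclusive* at exactly 50; PTCs in
the last exon and single-exon transcripts escape. For splice-induced skips
the rule is evaluated on the *skipped* transcript, whose junction structure
is the one the surveillance machinery would see. The rule is monotone —
moving a PTC upstream never flips the prediction from decay to escape — and
that property is tested.

**Stop-loss readthrough.** The native stop is recoded per the variant and
translation continues in frame into the 3'UTR until the next stop.
`extension_residues` counts the residues *after* the substituted one; the
HGVS-style name emits `ext*N` with `N = extension_residues + 1` (the
substituted residue counted once). Both numbers are reported so either
counting convention can be checked against an external annotation. If the
transcript ends before an in-frame stop the call is flagged (`ext*?`).

**Qualifying masks.** `discovery` mode admits the truncating classes plus
stop-loss. `burden` mode additionally admits missense calls whose
deleteriousness score meets an inclusive threshold (default 20 on a
CADD-like phred scale, configurable); missense without a score never
qualifies, with a warning. The class gate precedes the score: a synonymous
variant with a high score is still excluded.

## Germline QC and segregation

A germline heterozygote should show a variant allele fraction (VAF) near 0.5.
`vaf_germline_check()` runs an exact two-sided binomial test of alternate
reads against p = 0.5 and flags calls with p < α. Defaults: α = 0.01 and a
minimum depth of 10 (below which the call is `insufficient_depth`, not
judged). The loose α avoids flagging ordinary sampling noise — at depth 100,
≥ 98–99% of true binomial heterozygotes pass by construction, which the suite
verifies — while still catching the low-VAF pattern of somatic or artefactual
calls. The QC is reported alongside carrier status and is *not* a hard filter
for prioritization, because in the study design it emulates the VAF evidence
was confirmatory, not exclusionary.

Mendelian checks enumerate the allowed biallelic transmissions per trio; a
missing parent releases only that parent's constraint. Phenotypes use a
6-column PED dialect with extended codes (0 unknown, 1 unaffected, 2 MM,
3 MGUS, 4 other hematological condition, 5 amyloidosis); "affected" means
MM or MGUS by default, and related-but-distinct conditions (amyloidosis,
other heme) are tallied with the unaffected stratum unless promoted via the
`affected` argument.

The `discordant_affected` flag encodes a qualitative judgement, since no
formal segregation statistic is defined for pedigrees this small: it is
raised when a family has at least one affected carrier *and* at least one
genotyped affected non-carrier — the pattern where the variant cannot explain
an affected relative's disease (e.g. an affected parent who does not carry
the allele that the affected child does). The flag is reported per family and
per variant, never used to discard a gene automatically.

## Prioritization

A gene is a cross-family hit when qualifying variants are carried in at least
`min_families` (default 2) distinct families; a family is counted once no
matter how many carriers or distinct variants it contains, and carrying is
`allele_count ∈ {1, 2}` at any qualifying site. The `min_affected_carriers`
knob (default 1) asks that the variant be seen in at least that many affected
members per family before the family counts: 1 matches a design that
ascertains families through affected probands, 0 relaxes to any-member
carriage, 2 demands sharing by two affected members. The default of 1 was
chosen because a family contributes evidence for a disease gene only through
its affected carriers; the 0 setting exists for sensitivity analyses. Family
identity is taken at face value (`family_id`); kinship inference across
families is out of scope.

## Burden testing

Carrier collapsing: an individual is a carrier with ≥ 1 qualifying allele
across the gene's mask; individuals with all-missing genotypes at the mask
sites are dropped with a logged count. The crude cross-product odds ratio
with the Woolf (log-normal) 95% CI is the headline statistic because it is
exactly reproducible from printed carrier counts — `burden_from_counts()` and
the CLI `burden --counts a,b,c,d` recompute it from a bare 2×2 — with
Fisher's exact two-sided p reported alongside. Zero cells receive the
Haldane–Anscombe +0.5 correction for the OR and CI only; the exact p is never
corrected. Covariate-adjusted (logistic / PC-corrected) burden models are a
non-goal: they cannot be reproduced from printed counts and belong to a
regression framework this package does not provide. When several genes are
tested, `adjust_burden()` adds a Benjamini–Hochberg column; raw p is the
default since the primary design tests a single candidate gene.

**Calibration.** Sequencing or sampling asymmetries between cases and
controls inflate any carrier test. The calibration runs the identical
collapse on a neutral (synonymous) mask, where no true association is
expected; a Woolf 95% CI of the calibration OR excluding 1 raises
`bias_flag`. This is an explicit stand-in for cohort-specific bias checks
whose details vary by study; it is the right *shape* of control (same
machinery, neutral signal) rather than a reimplementation of any particular
one.

## The synthetic cohorts

`sim_config()` defaults define the study conditions: a discovery arm of 23
families with ~66 genotyped individuals (carriers and affected members
genotyped first, as screening would), a spiked canonical splice-donor variant
transmitted dominantly from a founder in 2 families, and a burden arm of 781
cases vs 3534 controls with qualifying-carrier frequencies 30/781 and
72/3534. Penetrance defaults are f1 = 0.5 for carriers and f0 = 0.02 for
non-carriers: neither is observable from printed cohort summaries, so they
were set once to values a genetic epidemiologist would call plausible for an
"intermediate-risk" dominant allele in a disease with low lifetime background
risk — high enough that spiked families usually contain several affected
carriers, low enough that unaffected carriers and phenocopies occur, which is
exactly the imperfect segregation the segregation flags must cope with. Mean
read depth defaults to 100 (typical targeted/WES coverage); heterozygote
alternate reads are Binomial(depth, 0.5) with an `allelic_bias` knob reserved
for negative-control experiments, and a Poisson depth of zero becomes a
missing call.

Background singleton LoF variants arise at rate 0.3 per family (Poisson),
each in a gene sampled without replacement across families by default
(`background_collisions = "avoid"`), so the spiked gene is deterministically
the unique two-family hit; `"allow"` switches to independent sampling for
property tests that detect and exclude collisions with an oracle. Background
alleles also enter through founders and transmit Mendelianly, so the strict
0-Mendelian-error invariant holds for every simulated variant.

Randomness discipline: one mandatory root seed; each component (reference,
families, case-control arm, scores, masks) draws from a named derived stream,
so adding a component never perturbs the others, and every output is a pure
function of the configuration. The writers emit FASTA (+ index), GFF3 with
CDS phases, VCF 4.2 with GT:AD:DP, PED and TSV, and a JSON manifest carrying
the full configuration; re-reading a bundle reproduces the in-memory objects.

**What the simulator does not emulate:** linkage disequilibrium, population
structure and relatedness across families, sequencing error and strand bias,
somatic contamination of blood-derived DNA, mosaicism, multi-nucleotide and
structural variants, and ascertainment through clinical referral patterns.
Green tests on synthetic cohorts therefore demonstrate that the *logic* is
correct under idealised genetics — Mendelian transmission, binomial reads,
independent carriers — not that the pipeline is robust to every artefact of
real sequencing data; the QC stages exist precisely because real data violate
these idealisations.

## Numerical and implementation choices

* Exact tests come from `stats::binom.test` / `stats::fisher.test`; the test
  suite re-derives both from first principles (tail sums, full hypergeometric
  enumeration over all 2×2 tables with total ≤ 12) as independent oracles.
* Translation uses the standard genetic code; codons containing non-ACGT
  characters translate to `X` with a warning rather than erroring, so a
  single ambiguous base does not abort a batch.
* Intronic anchor ties (a position equidistant from both flanking exons) go
  to the donor (+) side, the HGVS convention for the middle base.
* Interval arithmetic is 1-based inclusive end to end, matching VCF and GFF3
  bit-exactly at boundaries; no half-open conversions are exposed to users.
* The problem sizes in the shipped tests — toy genes under 300 CDS nt for
  exhaustive SNV enumeration, 200 replicates for parameter recovery, 2×2
  enumeration to total 12 — were chosen as the smallest sizes at which the
  properties are fully exercised (every codon position and mutation class,
  stable coverage estimates, every achievable margin configuration).

## Known limitations

* One transcript per gene; isoform-aware annotation is out of scope.
* Splice modelling covers canonical ±1/±2 SNVs as single-exon skips only; no
  splice-strength scoring, intron retention or cryptic-site prediction.
* The segregation flag is qualitative; no likelihood-based co-segregation
  statistic (e.g. Bayes factors) is computed for these small pedigrees.
* No covariate adjustment in the burden test (see above).
* No genome-wide recurrence significance: the cross-family filter has no null
  model for gene length or mutability, so it ranks candidates rather than
  assigning p-values.
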
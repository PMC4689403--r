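---
title: "Truncating-variant burden analysis in a multi-isoform gene: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Truncating-variant burden analysis in a multi-isoform gene: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttnsift)
```

## The problem

Titin (*TTN*) is the largest human gene (~363 exons), and protein-truncating
variants in it — nonsense, frameshift and essential splice-site changes,
collectively "TTNtv" — are the most common genetic cause of dilated
cardiomyopathy. Yet truncating calls also appear in healthy reference
populations, and a large share of them are artefacts of the gene's size and
isoform complexity: calls confined to the short novex-3 isoform's private
exon, calls in exons barely expressed in left-ventricle tissue, indel calls in
poorly covered regions, and calls unique to a single call set. Estimating how
many people really carry a truncation that matters — in particular one in the
A-band, where pathogenic truncations cluster — requires a disciplined
filtering workflow on top of an exact consequence caller.

`ttnsift` implements that workflow end to end for any titin-like gene model:

1. a **gene model** container with genomic ↔ CDS ↔ codon coordinate mapping
   on either strand;
2. **variant IO** for a site-level VCF subset (AC/AN/Hom plus per-population
   counts) with left-aligning allele normalization;
3. a **consequence caller** with the severity ladder
   nonsense > frameshift > essential splice > splice region > in-frame indel >
   missense > synonymous > intronic > noncoding;
4. the **filter pipeline**: quality → annotate → truncating classes →
   transcript-membership/PSI → cross-dataset concordance → coverage;
5. a **nonsense-spectrum** module (codon→stop enumeration, CpG deamination
   hotspots, codon-position bias test);
6. a **splice allele-frequency-spectrum** module (distance bins × frequency
   classes, Fisher composition tests);
7. **population statistics** (carrier counting, prevalence with binomial
   intervals, group tests, Hardy–Weinberg het:hom expectation);
8. a seeded **synthetic-data generator** with exact truth labels, so every
   stage is testable without external downloads.

## The gene model and its assumptions

A model is a self-contained JSON + FASTA bundle: locus sequence, exons,
transcripts, band intervals and per-exon PSI. Assumptions worth stating:

* **Transcripts are fully coding** between `cds_start` and `cds_end`. UTRs are
  out of scope; this matches the titin-style use where truncation position
  within the protein is what matters.
* **Bands are genomic intervals**, not residue ranges. The sarcomere bands
  (Z/I/A/M) must jointly cover the reference CDS and be disjoint. Making them
  genomic spans gives splice variants — which are intronic — a well-defined
  band, inherited from the surrounding span.
* **Coordinates are 1-based inclusive** in all files. Internally the package
  keeps the same convention, and bundles round-trip byte-identically.
* **Consequences are computed per transcript and resolved by severity**, with
  ties broken toward the designated reference transcript (the longest CDS).
  This is what lets a nonsense call inside the novex-only exon be counted as
  a truncating variant (it *is* one, on that isoform) and then removed by the
  transcript filter rather than silently misclassified as intronic.

### "Affecting all transcripts" with a short isoform in the model

A literal reading of "an exon is isoform-specific if any transcript lacks it"
breaks down as soon as a short novex-like transcript is listed: every exon
downstream of its terminus would count as isoform-specific, and the filter
would discard the entire A-band — the exact opposite of the analysis it
serves. The package therefore judges membership against **transcripts whose
genomic span overlaps the exon**: an exon skipped by an overlapping transcript
is isoform-specific; an exon lying beyond a short isoform's end is not
"absent" from it in any biologically meaningful sense. The same rule drives
the `affects_all` flag on calls. This was a genuinely open design point; the
span-overlap rule is the only reading under which both the novex exclusion
and the A-band retention hold simultaneously.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `psi_threshold` | 0.15 | proportion spliced-in | exons below this LV expression level are treated as not meaningfully translated; the source analyses cite PSI filtering without printing a cut-off, and 0.15 cleanly separates the generator's constitutive (≥0.90) and low-PSI (≤0.10) populations |
| `min_mean_depth` | 15 | × coverage | indel false positives concentrate in low-coverage regions; 15× is a conventional site-level floor, deliberately below the ~50× typical of exome data so it removes only clearly unreliable sites |
| `private_max_AC` | 1 | allele copies | "private" = dataset-wide singleton; a population-private alternative is available via configuration |
| `low_freq_max_AF` | 0.005 | allele frequency | 0.5% is the conventional boundary between low-frequency and common variation |
| CI method | Wilson | — | good coverage at small k/n without the conservatism of Clopper–Pearson; the exact interval is available as an option and the headline bounds agree after rounding |
| pairwise group test | Fisher's exact | — | expected cell counts are small at desk scale; chi-square (uncorrected) is available and is the default only for the multi-group homogeneity test |

No multiple-testing correction is applied anywhere; reports label p-values
nominal. This mirrors the analysis style the package reproduces.

## The filter pipeline

Stages run in a fixed order; each emits a trace (`n_in`, `n_out`, removed
keys) so every published attrition figure is recomputable:

1. **quality** — drop calls whose FILTER is not PASS.
2. **normalize/annotate** — left-align and trim alleles (standard
   vt-style normalization: shared suffix, shared prefix, left shift), then
   classify. Count-preserving.
3. **truncating classes** — keep nonsense, frameshift, essential splice.
   Splice-region (3–6 bp) variants are explicitly *not* truncating.
4. **transcript/PSI** — drop calls whose exon (or adjacent exon, for splice
   calls) is isoform-specific or low-PSI.
5. **concordance** — drop calls unique to a single subset call set and absent
   from the superset call set; calls shared by two subset call sets are kept
   whatever the superset contains, and counted in the overlap report.
6. **coverage** — drop calls below the depth floor; calls at positions with
   no coverage record are removed and listed separately ("uncovered"), never
   silently kept.

The pipeline is order-invariant in its input, idempotent on its own output,
and its removals plus survivors add up to the truncating calls that entered
stage 4 — all three are property-tested.

## Carrier counting and prevalence

A call with allele count AC and homozygote count hom contributes
`AC − hom` carriers (heterozygotes plus homozygotes counted once). Summing
over calls assumes no individual carries two distinct qualifying variants; at
the frequencies involved the resulting overcount is below k²/2n and is
documented rather than corrected. Prevalence is `100·k/n` percent, kept
unrounded internally; "1 in N" figures are `round(100/prevalence)` with
display rounding (nearest 50) applied only at formatting time.

Under Hardy–Weinberg, an allele at frequency q yields `2(1−q)/q` heterozygous
individuals per homozygous individual, with q recoverable from an observed
homozygote count as `q = √(h/n)`. For one homozygote among 60,706 individuals
this gives ≈491 — not the ~245 sometimes quoted, which equals p/q, the
*allele*-ratio rather than the individual-ratio. The package implements the
standard individual form and leaves the discrepancy visible.

## The nonsense spectrum

Exhaustive enumeration over the standard genetic code yields exactly 23
single-substitution codon→stop patterns: 9 at the first codon position, 7 at
the second, 7 at the third. The enumeration is brute-force verified in the
tests (61 sense codons × 3 positions × 3 alternates). A substitution is a CpG
deamination transition when it is C→T with G immediately 3′, or G→A with C
immediately 5′. For stop-gains this can only fire codon-internally (CGA→TGA,
the Cga/Tga arginine-to-stop change) — a small lemma the implementation does
not rely on: the flag is evaluated generally, on the spliced coding sequence
by default (`cpg_context = "genomic"` switches to genomic neighbours), so a
codon's partner across an exon junction is its spliced neighbour. The
codon-position bias test is a chi-square goodness-of-fit against either a
uniform null (the default, matching the simple published test) or an
opportunity-weighted null (9/23, 7/23, 7/23) that accounts for the unequal
number of mutational routes per position.

## Splice-distance allele-frequency spectrum

Splice distances are signed and transcription-ordered: +d means d bases into
the intron from the donor (the exon's 3′ end), −d from the acceptor. Distances
1–2 are essential, 3–6 splice-region, beyond 6 intronic. Calls bin into 1–2 /
3–4 / 5–6 and are cross-classified as private / low-frequency / common;
compositions are compared with two-sided Fisher tests, per bin or pooled
(3–6 vs 1–2). The published per-class counts behind the headline p-values
were never printed, so those p-values are not reproduction targets; the
package reproduces the printed *fractions* (41/49 private essential, 324/373
non-essential, 175/197 of A-band splice calls non-essential) exactly from
margin-matched fixtures.

## What the generator emulates — and what it does not

`sim_config()` defaults define the study conditions: 40 shared exons plus one
novex-like terminal exon (all lengths multiples of 3, so every transcript CDS
is in frame), three transcripts (full; novex-like, sharing the first eight
exons and ending in its private exon; one alternative transcript skipping two
shared exons), band fractions 0.09/0.35/0.45/0.11 weighted toward the A band
as in titin, PSI mixtures (constitutive ≥0.90, low-PSI ≤0.10), a
singleton-heavy frequency spectrum (70% singletons, the remainder log-uniform
between 5×10⁻⁵ and 5×10⁻³), five population groups of 5,000 with configurable
rate multipliers, 95% PASS, mean site depth 65× (σ 15) with ~10% of sites
below the 15× floor — chosen so that roughly 80% of sites clear 50×, matching
the coverage profile reported for exome reference data — and superset/subset
dataset roles with planted subset-unique false positives.

Variants are *planted*, not mutated at random: stop-gain codons for nonsense,
mid-exon 1–2 bp indels for frameshift (left-aligned at planting, with a
geometric check — independent of the classifier — that the changed bases stay
strictly inside the exon body), exact intron distances for splice classes,
rejection-sampled alternates for missense/synonymous. Truth labels are
therefore exact, and the classifier-vs-truth property demands 100% agreement,
not a score. When a small exon context runs out of eligible positions the
planter falls back to a neighbouring context; labels always describe the exon
actually used.

What the generator does **not** emulate: linkage and haplotype structure,
mutation-rate heterogeneity (including elevated CpG mutability — CpG status
appears only through which codons are planted), genotype-level data,
multi-nucleotide variants, and sequencing error models. Passing tests
therefore demonstrate the *logic* of the workflow — classification,
filtering, counting, and the statistics — under clean conditions, not
robustness to messy real-world call sets.

## Margin-matched fixtures

Three deterministic fixtures reproduce the published aggregate margins for
worked-example tests and reports: the reference-population burden table
(470/33/66 truncating calls entering the transcript filter; 173/9/16
surviving; 219/10/19 carriers; the 19/39/90/25 band split; three splice
variants shared between the subset call sets), the nonsense spectrum
(21/23 and 21/34 ratios), and the splice composition (41/49, 324/373,
175/197). Per-cell carrier counts are not printed anywhere, so the fixtures
back-compute them from the printed prevalences and reconcile rounding so the
totals land exactly on the printed carrier counts. Two source
inconsistencies are handled openly: the subset cohort's total is taken from
the per-class text counts (1 + 13 + 19 = 33) rather than the printed 29, and
one M-band cell prints a prevalence arithmetically incompatible with its own
variant count (10 variants cannot make 4 carriers); the fixture uses 16
carriers there so the band totals reconcile. These fixtures are synthetic
constructions that *reproduce margins*; they are not the underlying variant
lists, which were never published.

## Numerical choices and degenerate inputs

* Normalization trims the shared suffix before the prefix and extends through
  the locus boundary error rather than emitting an anchorless allele;
  `ref == alt` after trimming is an error, as is a reference mismatch.
* `fisher.test` and `chisq.test` (uncorrected) provide the exact and
  asymptotic tests; both are cross-checked in the suite against explicit
  hypergeometric enumeration and the Pearson formula respectively.
* Wilson bounds come from the closed form, clamped to [0, 1]; the tests
  invert the score statistic by root-finding and require 1e-6 agreement.
  Clopper–Pearson uses the beta-quantile form with its k = 0 / k = n edge
  cases.
* Ties in splice distance (a position equidistant from donor and acceptor
  cannot occur for distances ≤6 in introns ≥13 bp, which the generator
  guarantees) resolve to the donor side.
* Empty inputs flow through every stage: empty VCF bodies, empty call sets,
  all-zero spectrum summaries and header-only reports are all defined and
  tested.

## Problem sizes used in the checks

The property suites run at sizes chosen to exercise the mathematics while
staying desk-scale: 1,000 planted variants for the classifier-vs-truth check;
500 random indels for normalization idempotence plus a windowed
leftmost-representation enumeration oracle; a thinned exhaustive sweep of 2×2
tables with totals ≤20 plus 300 random tables with totals up to 200 for the
Fisher oracle; 1,000 seeded cohorts of 5,000 for the 95% CI coverage bound
(≥93%); and 20 seeded simulations for recovery of population rate multipliers
within three binomial standard errors.

## Known limitations

* Site-level only: no genotype matrices, no BCF/tabix, no structural
  variants.
* One gene at a time; no canonical-transcript databases or HGVS output.
* Compound heterozygosity is ignored in carrier counting (documented bias).
* Multi-nucleotide substitutions are bucketed as missense rather than
  re-decomposed.
* The published cohort analyses queried live databases; the package
  reproduces their printed arithmetic, enumerations and margins, not the
  underlying variant lists.
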
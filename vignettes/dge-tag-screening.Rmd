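---
title: "DGE-tag screening of RNAi targets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DGE-tag screening of RNAi targets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgescreen)
```

## The tag model

NlaIII DGE-tag profiling reduces each transcript to a 21 nt tag: the CATG
recognition site closest to the 3′ end of an oligo-dT-primed cDNA plus the
17 nt immediately downstream. Counting sequenced tags per library then
proxies transcript abundance per condition — here, the four developmental
stages of an insect (egg, larva, pupa, adult). Screening for RNAi targets
amounts to finding tags whose counts are confined to, or strongly dominated
by, one stage.

The package's reference object is the *virtual tag index*: every CATG site
on the sense strand of every unigene with a full 17 nt extension yields a
virtual tag, identified by its 17-mer (`tag17`; the anchor is constant and
carries no information). Three modelling decisions shape the index:

- **Canonical site = 3′-most eligible CATG.** The chemistry anchors the
  library at the restriction site nearest the poly(A) tail, so
  `build_tag_index(mode = "canonical")` keeps only that site per unigene.
  An `"all"` mode indexes every site for sensitivity analysis; internal
  repeats of a tag within one unigene do not make it ambiguous, only
  occurrence in two or more distinct unigenes does.
- **Sense strand only.** DGE libraries are stranded; no reverse-complement
  scan is performed.
- **Exact, case-insensitive matching.** No mismatch tolerance: observed
  tags either equal an indexed 17-mer or count as unmapped. A mismatch-
  tolerant mapper would blur the clean separation between the sequencing-
  error model and the mapping step, and 4^17 tag space makes accidental
  exact collisions rare.

Coordinates are 0-based internally and 1-based in written reports.

## Clean-tag filtering and its accounting

Raw observations pass three filters in a fixed order: (1) *low quality* —
the observation contains at least one N; (2) *adaptor* — it equals or
starts with a configured adaptor sequence (the default adaptor list is
empty, matching libraries in which no adaptor reads survive demultiplexing);
(3) *copy number* — after aggregation, tags seen once are dropped. The
order is what makes the accounting additive: each removed observation is
attributed to exactly one category, so

```
raw = low-quality + adaptors + copy<2 + clean
```

holds exactly in both total-tag and unique-tag units, and singletons have
`total == unique` by definition. `filter_accounting()` exposes the same
identities as a constructor, which also lets the package verify published
filter tables whose raw reads are unavailable.

Observations may be full 21 nt tags (default; the CATG prefix is enforced
and a violation is a malformed record, not a filter category) or bare
17-mers (`dialect = "tag17"`).

## Expression profiling and target calling

`map_tags()` looks each clean tag up in the index. Unique hits credit
their unigene; ambiguous hits are tallied but never credit any unigene —
an ambiguous count cannot be attributed to a single transcript and would
otherwise double-count; unmapped tags are tallied separately. The
conservation identity `mapped + ambiguous + unmapped = clean_total` is
asserted per stage after every mapping.

"Stage specific" is implemented in two modes because practical usage is
looser than the words: published target lists include genes with clearly
dominant but not exclusive larval expression alongside strictly exclusive
ones.

- **strict**: nonzero in exactly one stage and count ≥ `min_count` —
  presence/absence semantics.
- **dominance** (default, fold ≥ 3, count ≥ 100): called stage is the
  argmax; the call stands when the called-stage count divided by the
  largest other-stage count (∞ if all others are zero) reaches the
  threshold. A tied argmax has fold 1 and is never called.

Strict calls are a subset of dominance calls at any finite threshold and
equal `min_count`. Defaults reflect screening practice: a dominance fold
of 3 separates a 6325-vs-1942 pattern (called) from genuinely shared
expression, and `min_count = 100` keeps targets abundant enough for
follow-up dsRNA work. Ranking is by called-stage count, descending, with
lexicographic tag17 tie-break for determinism.

The Venn partition assigns every detected item (count > 0 anywhere) to
exactly one of the 2⁴−1 presence categories; the copy-number distribution
bins distinct clean tags by their library copy number into the
conventional 2 / 3–9 / … / ≥10000 bins, whose column totals equal each
stage's distinct clean-tag count by construction.

## Assembly statistics

`n50()` follows the longest-first cumulative definition with a strict
"exceeds": sequences are ordered longest to shortest and the N50 is the
length at which the running sum first goes strictly beyond half the total;
a sum landing exactly on half continues to the next length. Length classes
are lower-inclusive half-open intervals, so a 200 nt sequence falls in the
200–300 class; reported means and percents round half-up (never half to
even) because that is how printed report tables behave. All rounding lives
at the reporting layer only.

## Bioassay statistics

**Abbott correction.** Control mortality is removed as
`(T − C)/(100 − C) × 100`. Raw mortality below the control clamps to 0 and
is flagged rather than reported negative. One published corrected cell
(DS28 against the dsEYFP control) differs from this arithmetic by 0.01 at
2 dp — consistent, like two other cells, with the original correction
having used unrounded replicate means that were never printed; the package
reports the value implied by the printed means.

**Probit LC50.** `probit_fit()` regresses corrected proportions on log₁₀
dose by maximum likelihood (binomial GLM with probit link — iteratively
reweighted least squares), requiring a positive slope, and inverts
`LC50 = 10^(−intercept/slope)`. When a dose-0 control row is present the
observed control proportion is used for Abbott pre-correction of all
proportions before fitting (the classic corrected-mortality workflow); a
natural-response likelihood term is deliberately not estimated, keeping the
fit consistent with the reported corrected tables. Interval estimation
follows Finney's fiducial recipe: with coefficient covariance V (unscaled),
Fieller's theorem gives limits for m = −a/b on the log scale with
g = t²·V_bb/b²; when the Pearson heterogeneity factor χ²/df exceeds 1, V is
inflated by it and the normal multiplier is replaced by Student's t on the
residual df; when g ≥ 1 the slope is too uncertain for Fieller and a
first-order delta-method interval is returned, flagged. Simulation at the
default study design (true LC50 60 ng/µl, slope 4 per log₁₀ dose, 11%
control mortality, doses 20–100 ng/µl, 300 larvae per dose) shows a
median estimate within a fraction of a percent of truth and ~94% empirical
coverage of the nominal 95% interval; the mild undercoverage is the price
of pre-correcting with an *estimated* control, partly absorbed by the
heterogeneity factor.

**qPCR.** Relative expression uses the Livak 2^−ΔΔCt method with
amplification efficiency fixed at 2 and replicate aggregation on the ΔCt
scale (the standard practice; aggregating folds instead would bias the
geometric structure). Replicate scatter propagates as 2^−(ΔΔCt ± sd). No
Pfaffl efficiency correction is offered because the workflow this package
mirrors used none.

## The synthetic-data generator

The generator exists so that every downstream stage is testable without
raw sequencing or rearing data. It emulates:

- a unigene set of configurable size, length range (default 200–1500 nt)
  and GC content (default 0.42, typical of lepidopteran transcriptomes),
  with 95% of unigenes guaranteed an eligible tag site by default;
- four stage libraries of `library_depth` tags each (default 3.5 million,
  the scale of real stage libraries), drawn multinomially from lognormal
  expected abundances (meanlog 0, sdlog 1 — a heavy right tail, as tag
  libraries show) in which a configurable fraction per stage (default
  0.15) is expressed in exactly one stage and the remainder in all four;
- sequencing noise: per-base substitutions on the 17 variable bases
  (default 0.001), N-masking of whole observations (default 0.005), and a
  singleton-junk share (default 0.02) of unique random CATG-anchored
  17-mers rejected on collision with any true tag — so the copy-number
  filter, and only it, is what removes them. The CATG anchor itself is
  never corrupted: raw DGE records are anchored at the restriction site,
  and an anchorless record is malformed input rather than a filter
  category. The published filter tables give no error or contamination
  rates (their adaptor row is zero throughout), so these defaults are
  plausible free parameters, not calibrated values.

Every draw flows from one seeded private RNG per call (stage libraries use
a stage-indexed sub-seed), so identical config + seed gives byte-identical
outputs and no global RNG state is touched. `sample_tag_library()` also
offers `sampling = "expected"` (rounded expected counts instead of a
multinomial draw) for exact end-to-end recovery checks.

What the generator does *not* emulate: read-level sequencing (quality
scores, PCR duplicates, indels — tags are fixed-length 21-mers, so
substitution-only noise matches the exact-match mapping downstream),
3′-bias within transcripts, and cross-stage correlation structure beyond
specific-vs-shared. Passing recovery tests therefore demonstrates the
pipeline's correctness under its own model, not performance on real
libraries with, e.g., heavy PCR duplication.

The bioassay simulator draws dead counts binomially from
`p = c + (1−c)·Φ(slope·(log₁₀ d − log₁₀ LC50))` including a dose-0
control row; the qPCR simulator encodes programmed fold changes as
`Ct = Ct_cal − log₂(fold) + noise` with a constant reference gene.

## Problem sizes and numerical choices

The test and acceptance runs use scaled-down study conditions chosen as
the package's own working sizes: oracle comparisons on 1000 random 1 kb
sequences and 1000 random length multisets; conservation checks over 50
seeded libraries of 2000 tags; recovery screens on 150–200 unigenes at
depths of 1–3 × 10⁵ tags per library (noise-free recovery uses expected
counts; the noisy screen uses substitution rate 0.005 and singleton share
0.02 at `min_count` 100); LC50 recovery over 500 simulated assays at the
default design. Degenerate inputs fail loudly: empty length sets, all-0%
or all-100% responses, non-monotone dose-response, duplicate unigene ids,
bin grammars that do not cover [2, ∞).

## Known limitations

- Published per-stage annotated-unigene counts and the global
  stage-specific tag total depend on the unavailable raw libraries; the
  package reproduces the shapes and identities of those tables, not the
  counts themselves.
- The printed LC50s of the original filter-paper assays (61.02 and 60.44
  ng/µl) have no printed dose-response counts behind them, so the probit
  machinery is validated by simulation recovery instead.
- Ambiguous tags are excluded from unigene counts rather than
  fractionally assigned; with short 17-mer identities this is the
  conservative choice and matches the "unambiguous tags only" screening
  convention.
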
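---
title: "SNP discovery from read stacks in heterozygous genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP discovery from read stacks in heterozygous genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpstacks)
```

## The problem

In an outcrossing, highly heterozygous organism (the motivating case is a
clonally propagated tree crop genotyped against its own BAC-end reference
sequences), SNPs cannot be found by comparing two homozygous lines.  A SNP in
a single heterozygous individual shows up as *variation within the stack* of
short reads mapped to one reference site: at a truly heterozygous site the
two haplotypes contribute reads in equal expectation, while sequencing and
mapping errors contribute minor variants.  `snpstacks` implements the full
downstream pipeline for this design: per-site variant statistics, a depth
model that excludes repeat-derived stacks, a multi-criterion filter cascade,
genotyping-assay selection, validation against an F1 cross, a logistic
true/false-positive classifier, and pedigree/diversity analytics.

## Variant frequency and its folded form

For a pileup column with read depth $RMD$ and $n_{ref}$ reads carrying the
reference base, the variant frequency is

$$VF = \frac{RMD - n_{ref}}{RMD} \in [0, 1],$$

and the folded variant frequency is $FVF = \min(VF,\, 1 - VF) \in [0, 0.5]$.
$FVF = 0$ means a homozygous site (no SNP detectable in a single-individual
design); $FVF$ near 0.5 is the heterozygous expectation; small positive
$FVF$ is the signature of a sequencing or mapping error.  Folding matters
because the reference may carry either haplotype: two stacks with variant
shares $p$ and $1-p$ are the same evidence.

A special case arises when the two top-ranked bases in a stack *both* differ
from the reference base.  The site is still called (alleles = the top two
bases, $FVF$ = minor share of their total) and the reference base itself is
flagged as an inferred sequencing error (`ref_error_inferred`).  Third-ranked
bases are treated as noise: they count toward depth and $VF$ but never become
alleles.  Count ties are broken in the fixed order A < C < G < T, which
affects allele naming only, never $FVF$.

## Testing FVF against the heterozygous expectation

Variant counts at a true het site are $\mathrm{Binomial}(RMD, 0.5)$, so the
deviation of $FVF$ from 0.5 is tested with

$$t = \frac{|FVF - 0.5| - 0.5/RMD}{0.5\sqrt{1/RMD}}
\quad (RMD \times 0.5 < 30), \qquad
t = \frac{|FVF - 0.5|}{0.5\sqrt{1/RMD}}
\quad (RMD \times 0.5 \ge 30),$$

with the site discarded as a likely false positive when
$t \ge t_{\alpha,\,RMD-1}$ at $\alpha = 0.05$.  Two numerical choices are
deliberate:

* the critical value is the *upper one-tail* quantile — folding makes the
  test one-sided by construction;
* the continuity correction $0.5/RMD$ applies only in the small-sample
  branch, exactly as the statistic is defined; the suite verifies the
  branch switch at $RMD \times 0.5 = 30$ and checks the realized discard
  rate at simulated het sites against the exact enumerated level of the
  discrete test (which oscillates around the nominal 5% because the
  binomial support is discrete).

This test replaces a fixed $FVF \ge 0.2$ threshold (the "initial" preset):
a fixed threshold is blind to depth, discarding perfectly plausible
low-depth het sites and retaining implausible high-depth ones.

## Depth as a repeat filter

Repeated sequences attract disproportionately many reads, so excess depth is
evidence that a stack is repeat-derived (and its "variants" paralogous).
Depth over single-copy references is modelled with a Gumbel (type-I
extreme-value) distribution, the standard choice for mapped-depth modelling
in this pipeline family, fitted by maximum likelihood (`fit_evd()`, with a
method-of-moments fallback).  The cutoff is

$$\mathrm{cutoff} = \lfloor \bar X + k\, s \rfloor,$$

with $k = 0.5$ by default; sites deeper than the cutoff fail the `max_rmd`
filter.  Flooring matches the calibrated arithmetic
(`depth_cutoff(15.9, 19.1, 0.5) = 25`).

Two interpretations of $\bar X$ and $s$ are supported, because a fitted
distribution and its sample can disagree when the data are a
single-copy/repeat mixture: `moment_source = "fitted"` (default) derives
$\bar X = \mu + \gamma\beta$ and $s = \pi\beta/\sqrt 6$ from the fitted
parameters; `"sample"` uses the plain sample moments.  On the default
synthetic mixture both place the cutoff where >90% of single-copy sites pass
and >95% of repeat sites fail; the fitted mode is the default because the
calibrated cutoff was derived from a fitted distribution.  Note that the fit
is run over *all* covered sites, repeats included — the contaminated tail is
precisely what inflates $s$ and pushes the cutoff far enough right to spare
single-copy sites.

## The filter cascade

`run_cascade()` evaluates, for every candidate (defaults shown; the
"adjusted" preset):

| filter | rule | default |
|---|---|---|
| `min_rmd` | depth at least | 5 reads |
| `max_rmd` | depth at most | depth-model cutoff (25-equivalent) |
| `fvf` | no significant deviation from 0.5 | t-test, $\alpha=0.05$ |
| `mqs` | mapping quality at least | 30 (initial preset: 25) |
| `ref_base_quality` | reference Phred at the SNP | ≥40 genic / ≥45 non-genic |
| `homopolymer` | no run of ≥3 identical bases at/through the site | 3 bp |
| `proximity` | >3 bp between contiguous SNPs | both members removed |
| `right_edge` | >30 bp from the 3' read end | 30 bp |

Design choices: all filters are evaluated for every candidate (no
short-circuiting) so the report attributes every failure; unannotated
references are held to the stricter non-genic quality threshold; the
proximity rule removes *both* members of a close pair (no principled way to
elect a survivor); the "right side" is the 3' end of the stored reference
string, where Sanger quality decays.  The 60-bp probe-spacing rule is
applied at assay-design time (`assay_spacing_filter()`), not in discovery —
it is a genotyping-chemistry constraint, not an evidence filter.

## Assay selection

`classify_infinium()` types biallelic SNPs: [A/T] and [C/G] need two probes
(type I), the other four pairs one (type II); panels use type II only, with
a vendor design score ≥ 0.7 (design scores are external input — the scoring
algorithm is proprietary).  `select_assay_snps()` allocates the budget
across physical-map contigs proportionally to contig size by the
largest-remainder method (the apportionment algorithm was an open choice;
largest remainder is the simplest method that matches proportionality
exactly on round quotas), guarantees one SNP per eligible contig when
capacity allows, takes at most one SNP per reference and per gene, and
spreads within-contig picks by position percentile.

## Validation against an F1 cross

With both parents genotyped alongside the progeny, each marker is classified
(`classify_segregation()`): AB×AB → 1:2:1 test (2 df); AB×hom → 1:1 test on
the two observable classes, carrier vs non-carrier (1 df); identical
homozygous parents with a single progeny class → monomorphic.  Up to 5% of
progeny calls in classes impossible under the parental genotypes are
tolerated as genotyping error and excluded from the test — a strict rule
would mark nearly every real marker unscorable at realistic (~0.5%) error
rates.  Labelling then keys on the discovery parent: a discovered SNP is
`true_positive` only if that parent is heterozygous and the progeny
segregate; monomorphic markers, and segregating markers where the discovery
parent is homozygous, are `false_positive`.

The logistic classifier models the probability that a SNP is false-positive:

$$\log\frac{p}{1-p} = b_0 + b_1\,MQS + b_2\,RMD + b_3\,FVF,$$

with defaults `tp_model()` = (10.3976899, −0.3077982, 0.07896269,
−5.2585503): better mapping quality and higher FVF argue for a real SNP,
excess depth argues for a repeat artifact.  `fit_tp_logit()` refits by
maximum likelihood (`stats::glm`); prediction uses the canonical 0.5
threshold on `p_false`.

## Pedigree and diversity analytics

`cop()` implements Malecot coancestry with all inbreeding coefficients fixed
at 0 (outcrossing species): $f(x,x) = 0.5$ and
$f(x,y) = \tfrac12[f(s_x,y) + f(d_x,y)]$, recursing on the individual with
greater pedigree depth (the standard guard against infinite descent);
unknown parents contribute 0.  `heterozygosity()` is the AB share of scored
calls.  `dissimilarity()` is the allele-sharing distance
$d = 1 - \text{shared}/2$ averaged over jointly scored loci — the exact
"improved coefficient" of the original diversity analysis is not fully
specified anywhere reproducible, so results that depend on the precise
coefficient are treated as directional only (the suite checks that COP and
genotype similarity co-vary positively on pedigree-dropped genotypes, not a
particular r).

## What the generator emulates — and what it does not

`sim_config()` defaults define the study conditions: ~721-bp references
(60% genic, grouped 5 per contig), per-reference depth Gumbel(16, 5) reads
jittered ±10% per site, a 15% repeat class at 4× depth, het sites at
0.002/bp, base errors from the local Phred via $e = 10^{-Q/10}$ with a
Sanger profile decaying Q55→Q20 over the final 100 bp, site MQS ~
N(34, 1.8), and 428 F1 progeny genotyped with 0.5% error and 2%
missingness.  The depth scale (β = 5) was set so that the fitted SD on the
repeat-contaminated mixture is large relative to the mean, reproducing the
regime in which the $\bar X + 0.5s$ cutoff is meaningful.

Two deliberate simplifications:

* **Planted truth sites sit in assayable contexts** — outside homopolymer
  runs, ≥61 bp apart, and upstream of the 3' decay window.  End-to-end
  sensitivity therefore measures what the *stochastic* filters (depth, FVF
  test, MQS) do to real het sites; the deterministic context filters
  (homopolymer, proximity, right-edge) are exercised by designed unit
  fixtures and by the error model, which concentrates false candidates in
  the low-quality 3' tail where those filters bite.  Real data contain
  SNPs in filter-hostile contexts; the pipeline's sensitivity there is by
  construction lower, and passing synthetic tests say nothing about it.
* **Mismapping is not modelled as such**: repeat paralogy is represented by
  inflated depth plus het-like paralogous sites, not by a read-level
  mapping simulation.  MQS is drawn independently of the error state, so
  the synthetic data cannot validate the *joint* behaviour of MQS with the
  other filters, only its marginal thresholding.

End-to-end regression checks run at 150 references (~100k pileup columns),
chosen to keep the full suite around ten seconds while leaving the binomial
sampling error on the measured rates far from the asserted margins.

## Known limitations

* The mpileup text dialect parser is best-effort sugar; the canonical TSV
  is authoritative.
* Site-level MQS aggregation from individual reads is the mapper's
  business; the pipeline consumes one number per site.
* `validation_summary()` reports unrounded percentages; display rounding
  is left to `print()`.
* The VCF writer emits the minimal subset of VCF 4.2 this pipeline needs
  (one ALT except for inferred reference errors, INFO statistics, first
  failing filter in FILTER); it is not a general-purpose VCF library.
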
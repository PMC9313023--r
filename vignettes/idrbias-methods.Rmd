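---
title: "Compositional bias of intrinsic disorder: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional bias of intrinsic disorder: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrbias)
```

# The scientific problem

Intrinsically disordered regions (IDRs) are protein segments that lack a
stable tertiary structure. Their sequences are compositionally biased:
enriched in polar and charged residues (P, E, S, K, Q, G, D) and depleted in
bulky hydrophobics (W, F, Y, I, L, C). This bias is not uniform — short IDRs,
very long IDRs, fully disordered proteins and disordered *binding* regions
each carry a distinguishable flavour of it — and the agreement between a
disorder predictor's compositional bias and the native one tracks its
predictive accuracy. `idrbias` packages this analysis end to end:

1. parse per-residue disorder/binding references and predictor outputs
   (CAID-style text formats);
2. extract IDRs, categorise them by size/context/binding, and assign each
   protein to one of six disorder classes;
3. quantify per-amino-acid enrichment of any residue collection against a
   background, with permutation significance;
4. compare the resulting propensity scales by Kendall rank correlation, and
   correlate scale agreement with predictor accuracy;
5. evaluate predictors per residue (AUC, AUPR, MCC, F1), overall and per
   class, with a bootstrap protocol for pairwise comparisons;
6. assemble a class-routed meta-predictor that gives each protein to the
   component predictor best suited to its class.

A synthetic-data generator emulates the whole data model, so every stage is
exercised by tests without network access.

# Data model and region rules

A protein carries two per-residue tracks with states positive / negative /
unannotated. Regions are maximal runs of the positive state; an unannotated
residue breaks a run. The operational definitions, all configurable:

* **IDR**: a disordered run of at least 10 residues.
* **Disorder content**: all disordered residues (including runs shorter than
  10) divided by sequence length.
* **IDR categories** (a region may hold several): *short* (10–14 residues,
  host content < 0.3), *long* (over 70 residues, content in [0.3, 0.8]),
  *fully disordered* (host content ≥ 0.8), *binding* (≥ 1 residue overlap
  with a binding region), *other* (no size rule applies).
* **Protein classes** (mutually exclusive): fully disordered (content
  ≥ 0.8); low-content (≤ 0.3) with binding long (> 15 aa), non-binding long,
  or short IDRs; high-content (strictly between 0.3 and 0.8) with or without
  binding IDRs.

Two deliberate subtleties. First, the category rules and the class rules use
*different* "long" thresholds (over 70 residues vs over 15 residues); both
are kept as independent parameters (`long_region_min = 71`,
`class_long_min = 16`) rather than silently merged. Second, the class rules,
read literally, leave a gap: a low-content protein whose only IDRs are
exactly 15 residues long triggers neither the short (< 15) nor the long
(> 15) rule and is reported `unassigned`. We keep the literal reading —
masking it would change class counts invisibly. Where a low-content protein
qualifies for several classes, the precedence binding-long > non-binding-long
> short is applied; the paper-level analysis needs *one* class per protein
and binding is the rarest, most informative annotation, so it wins. The
precedence is a `classify_idps()` argument.

# Compositional enrichment and its significance

For a residue sample $s$ and background $b$, the enrichment of amino acid
$a$ is the relative frequency difference

$$ e_a = \frac{f_{s,a} - f_{b,a}}{f_{b,a}}, $$

bounded below by −1, zero when the compositions agree. The background used
throughout an analysis should be the *same* pool (by default the
non-disordered residues of the dataset), so that scales computed for
different IDR collections are comparable side by side.

Significance is a two-sided permutation test per amino acid: sample and
background are pooled and re-split into groups of the original sizes — a
multivariate hypergeometric draw, executed as 20 sequential vectorised
`rhyper` draws, so 10,000 permutations of a 300,000-residue pool cost
milliseconds — and the p-value is the smoothed exceedance proportion
$(1 + \#\{|d^\ast| \ge |d|\})/(B + 1)$ on the frequency difference. Calls
are `enriched`/`depleted` when $p < \alpha$ (default 0.05) with the matching
sign, `neutral` otherwise. Choices worth stating:

* **No multiple-testing correction.** The scale is reported per amino acid
  at a per-amino-acid $\alpha$, matching how such propensity profiles are
  conventionally displayed; users needing family-wise control can correct
  the returned `p_value` vector themselves.
* **Residues are the permutation unit.** Residues within a region are not
  independent in real proteins, so the test is anti-conservative to an
  unknown degree on real data; on the generator's i.i.d. residues it is
  exactly calibrated, which is what the calibration test verifies (the
  false-positive call rate sits inside the binomial 99% band around 0.05
  over 200 null replicates).
* **Smoothed p-values** can never be exactly 0 and make the neutral-call
  invariant (`neutral` iff $p \ge \alpha$) exact.

# Comparing scales

Scales are compared by Kendall rank correlation. The tie-corrected tau-b is
the default because computed enrichments can tie (e.g. two amino acids both
at exactly 0); without ties tau-a and tau-b coincide, so published
comparisons of untied scales are unaffected. `kendall_tau()` delegates to
`stats::cor(method = "kendall")`; the test suite checks it against an
independent $O(n^2)$ concordant/discordant pair counter. The accompanying
`bias_performance_correlation()` is a plain Pearson correlation between
per-predictor accuracy and per-predictor scale agreement.

# Predictor evaluation

Metrics pool residues across the proteins of a subset — they are *not*
per-protein averages; per-residue pooling is what community assessments of
disorder prediction report, and a per-protein average would weight a
30-residue peptide like a 3,000-residue protein. Unannotated residues are
excluded; disorder is the positive class. AUC is the Mann–Whitney rank
statistic with ties averaged; AUPR is step integration of the
precision–recall curve with tied scores entering together; MCC and F1 use
the predictor's native binary calls when the file provides them, otherwise
scores thresholded at 0.5 (the threshold is an argument; 0.5 is a
convention, not an optimised value).

## Bootstrap comparisons

To compare two predictors, `bootstrap_compare()` draws half the proteins
(without replacement by default — drawing *with* replacement would count
some proteins' residues twice in a pooled metric; a `replace = TRUE` flag
restores the classical bootstrap) 100 times, evaluates both predictors on
identical draws, and tests the paired per-iteration differences:
Anderson–Darling normality at 0.05 selects between a paired t-test and the
Wilcoxon signed-rank test. Identical tracks short-circuit to "not
significant" (all differences are zero, where both tests are undefined).

One property of this protocol deserves emphasis. Because the per-iteration
differences concentrate around the *realised* performance gap on the fixed
dataset while their standard error shrinks like $1/\sqrt{n_{\text{iter}}}$,
the test asks "is the observed ranking on this benchmark robust to
resampling its proteins?", not "are the two predictors truly equally
accurate?". Two equally accurate random-score predictors exhibit a small
but nonzero realised gap on any finite dataset, and the protocol flags it
often (we measure roughly 85% at $\alpha = 0.05$ on a 40-protein null
benchmark, versus the 5% a calibrated equality test would give). This is a
property of the resampling design itself, which we implement as described;
conclusions drawn from it should be phrased about the benchmark at hand.

## The class-routed meta-predictor

`assemble_meta()` min–max normalises each component predictor's scores over
*all* of its residues in the dataset — normalising per protein would destroy
the cross-protein comparability that pooled metrics rely on — and then gives
each protein the normalised scores (and native binary calls) of the
predictor routed for its class. Min–max is strictly monotone, so identity
routing reproduces the routed predictor's AUC and AUPR exactly, which the
tests assert. `best_routing()` picks the per-class argmax-AUC predictor from
an `evaluate_by_class()` table. The meta-predictor needs the true class of
each protein, so it is an upper bound on what class-aware combination can
deliver rather than a deployable tool.

# The synthetic generator

`generate_reference()` builds proteins whose architecture *provably*
satisfies the requested class rule (contents and IDR lengths are drawn from
ranges that respect the defining inequalities, and the derived class is
re-checked post hoc), then fills residues i.i.d. from state-specific
compositions: a UniProt-like frequency vector for ordered residues and a
reweighted disorder vector (P, E, S, K, Q, G, D up; W, C, F, I, Y, L, V
down) for disordered ones. Enrichment injections are multiplicative factors
renormalised onto the simplex, so an injected ×2.0 proline has a closed-form
expected enrichment that the recovery tests compare against at the binomial
99% level.

Score tracks use the binormal model: negatives $N(0,1)$, positives
$N(\delta,1)$ with $\delta = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC})$, squashed to
$[0,1]$ by a logistic map (AUC-invariant) with calls thresholded at the
midpoint $\delta/2$; a target AUC of 1 is the separation limit. The closed
form makes per-class target AUCs analytically verifiable.

What the generator does *not* emulate: positional autocorrelation of
residues within regions, sequence grammar (e.g. proline-rich motifs),
length–composition coupling, or the error structure of any real predictor.
Tests passing on this generator therefore validate the *machinery* —
parsers, region logic, statistics, routing — not claims about real
disordered proteomes.

Preset conditions (chosen once as realistic desk-scale study conditions):
`caid_like` uses ~250 proteins across all six classes with IDR length
statistics loosely matching the reference benchmark (overall median IDR
length near 34, short-IDR median 12); `null` uses 40 half-disordered
proteins (~10,000 residues) with identical order/disorder compositions;
`class_specialists` gives six predictors AUC 0.95 on their own class and
0.55 elsewhere; calibration checks use 200 replicates, enrichment recovery
~20,000 sampled residues, AUC recovery ~10,000 residues, and bootstrap power
runs on 300 proteins.

# Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive everywhere user-facing.
* `mcc_score()` returns 0 when a confusion marginal is empty.
* `kendall_tau()` and `bias_performance_correlation()` refuse constant
  vectors rather than returning `NA`.
* Permutation exceedance uses a `1e-12` tolerance so ties at the observed
  difference count as exceedances on either side.
* Per-class evaluation reports single-class subsets as `NA` rows rather
  than dropping or zeroing them.
* All randomness flows through per-call seeds; pipeline stages derive their
  seeds from the run seed, so stages can be re-run in isolation and a rerun
  with the same configuration is bit-identical.

# A worked example

```{r example, eval = FALSE}
ds <- generate_dataset("class_specialists", seed = 42)
per_class <- evaluate_by_class(ds$tracks, ds$proteins, ds$classes)
routing <- best_routing(per_class)
meta <- assemble_meta(ds$tracks, routing, ds$classes, ds$proteins)
rbind(evaluate(meta, ds$proteins),
      do.call(rbind, lapply(ds$tracks, evaluate, ds$proteins)))
```

On this benchmark the meta-predictor's pooled AUC/AUPR/MCC/F1 strictly
dominate every specialist's — the qualitative signature of class-aware
combination. The same flow runs on real reference and prediction files via
`run_config(reference = ..., binding = ..., predictions = ...)` and
`run_pipeline()`.

# Known limitations

* The permutation test treats residues as exchangeable units; real IDRs
  violate this, so real-data significance calls are optimistic. A
  protein-level block permutation would be the conservative alternative and
  is a natural extension.
* The bootstrap comparison is a ranking-robustness statement, not an
  equality test (see above).
* The class rules inherit the literal threshold gap at IDR length 15.
* Composition counts cover only the 20 standard amino acids; non-standard
  letters stay in sequences but never enter counts.
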
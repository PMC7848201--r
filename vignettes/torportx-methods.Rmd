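---
title: "Methods: state-series transcriptome analysis for torpor-arousal cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-series transcriptome analysis for torpor-arousal cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torportx)
```

## The problem

Circannual hibernators such as the 13-lined ground squirrel cycle between
months of profound torpor, brief euthermic interbout arousals, and an
active season. Bulk RNA-seq sampled at six physiological states — summer
active (SA), interbout arousal (IBA), entrance (Ent), late torpor (LT),
arousing (Ar), and spring dark (SpD) — captures both seasonal and body
temperature driven transcriptome dynamics. `torportx` implements the
analysis chain for such a design: detection filtering, multi-state
differential expression with a sex covariate, pairwise transition effect
sizes, assignment of expression profiles to ten canonical torpor-arousal
patterns, percent-spliced-in (PSI) analysis of local splicing variations
(LSVs) including intron retention, a three-source transcript-annotation
merge, and sequence-feature statistics (GC, AU-rich elements, motifs,
gene-set over-representation). A synthetic-data generator with known
ground truth makes the entire chain testable without any external data.

## Normalization, transform, and the detection filter

Size factors are classical median-of-ratios against a geometric-mean
pseudo-reference over genes with all-positive counts; when no such gene
exists the package falls back to total-count scaling with a warning.

The log transform is `log2(count / factor + 1)`. This is a deliberate,
documented approximation of a regularized log transform: it is monotone,
equals 7 at 127 normalized counts, and avoids a heavyweight dependency.
The detection rule — transformed value at least 7 in at least 4/5 of the
replicates of at least one state — therefore keeps its intended meaning of
"clearly detected in some physiological state". Both the threshold and the
fraction are parameters of `filter_rule()`.

Consequence of the approximation: at low counts the transform has more
variance than a regularized log would, so the filter is marginally
stricter near the boundary. None of the package's contracts depend on the
exact low-count behavior.

## Differential expression

Each gene is modeled as negative binomial with log link, library-size
offsets, and fixed gene-wise dispersion. The multi-state test is a
likelihood-ratio test of `~ state + sex` against `~ sex`, referred to a
chi-squared distribution with (number of states − 1) degrees of freedom;
p-values are Benjamini–Hochberg adjusted within the tested family. The sex
term is included because the design is mixed-sex and sex-biased genes
would otherwise inflate the state test.

**Dispersion.** Per gene, a method-of-moments estimate is pooled across
within-state groups with df weights, floored at 1e-8, then shrunk 50%
toward the mean across genes. Two choices deserve a note:

* *Grouping by state rather than state × sex.* With five replicates per
  state split across sexes, state × sex cells hold 2–3 samples and the
  resulting dispersion estimates were noisy enough to make the null LRT
  anticonservative (on 2,000 simulated null genes the p-value distribution
  failed a KS uniformity check). State-level groups (n = 5) calibrate
  well. The small variance contributed by the sex effect is absorbed into
  the dispersion, which makes the state test mildly conservative — the
  safer direction at this sample size.
* *Shrinkage target.* The 50% pull toward the across-gene mean is a
  deliberately simple stabilizer, not an empirical-Bayes trend fit; at the
  simulated dispersion scale (≈ 0.05, typical of bulk brain replicates) a
  mean target and a trend target are nearly indistinguishable.

**Pairwise transitions.** For each edge of the circannual graph
(SpD→SA→IBA→Ent→LT→Ar→IBA→SpD), the same NB model on the two states'
samples yields a log2 fold-change (later state over earlier), a Wald
p-value, and a BH q-value within the pair. The shrunken estimate is the
posterior mean under a Normal(0, `shrinkage_sd`²) prior with a normal
likelihood approximation: `raw · sd₀²/(sd₀² + se²)`. This guarantees
|shrunken| ≤ |raw| and recovers the raw value as the prior widens; it is a
simple stand-in for adaptive shrinkage, adequate because downstream logic
only uses signs and q-values.

## Reference-pattern clustering

Mean transformed expression per state gives each gene a 6-long profile,
which is correlated (Pearson) against ten named templates; a gene joins
the best-correlated template when r ≥ 0.8 and the `Unassigned` cluster
otherwise. Pearson correlation is affine-invariant, so templates encode
only shape. The shipped template vectors over (SA, IBA, Ent, LT, Ar, SpD)
— e.g. `Winter_high` = (0,1,1,1,1,0), `Cold_high_EM` = (0,0,0.5,1,1,0) —
encode the canonical verbal descriptions (the EH/EM/EL suffix is the
relative level during entrance); the exact numeric shapes are conventions
and are user-overridable as data (`read_templates()`). Zero-variance
profiles have undefined correlation and are always Unassigned; exact ties
are broken by template order and flagged (none are expected in continuous
data).

## Splicing: PSI, dPSI, and intron retention

An LSV is a set of 2+ alternative junctions, optionally including a
retained-intron "junction". Replicate counts are pooled within each state
and combined with a Jeffreys Dirichlet prior (½ per junction); PSI point
estimates are the posterior means, which sum to 1 within an LSV-state by
construction. Pooling replicates before the posterior is a documented
simplification of the hierarchical read-rate models used by dedicated
splicing tools: it understates between-replicate variability, which the
calibration test bounds in practice (≤1% of null LSVs flagged at the
stated rule).

dPSI between two states is evaluated by Monte Carlo: 10,000 paired draws
from the two Dirichlet posteriors, seeded per LSV so results are
reproducible. An LSV is significant when some junction reaches a 0.999
posterior probability of |dPSI| ≥ 0.2 in any pairwise state comparison
(both one-sided probabilities are checked; whether the published rule was
one- or two-sided is not stated, and the max of the two is the
conservative reading).

Patterns are oriented to the summer-dominant junction — the junction with
the highest PSI in SA — and, separately, the retained intron if present:
the profile is expected dPSI versus SA per state (SA entry exactly 0),
assigned to the same ten templates. An LSV with a retained intron is
classified `retained-default` when the intron has the top PSI in SA
(retention is the warm-state default), else `excised-default`; ties fall
to `retained-default` with a flag.

The temperature-dependence gate for retained introns is operationalized as
significance at the relaxed 0.90/0.2 rule in any warm (SA, IBA, SpD, Ent)
versus cold (LT, Ar) comparison; control introns are the non-significant,
non-overlapping retained introns, emitted BED-like with coordinates for
external splice-site strength scoring (the scoring itself is out of
scope).

## Annotation merge

Transcripts are exon chains with 0-based half-open coordinates internally
(GTF I/O converts to/from 1-based closed; this removes off-by-one risk
from the interval algebra). The stepwise merge:

1. **Secondary supplement.** Keep every secondary transcript with no
   exonic overlap (same strand — the data are stranded) with any primary
   transcript; additionally rescue short (<1 kb) single-exon secondary
   transcripts whose reciprocal overlap with every primary transcript is
   below 0.90. Reciprocal overlap is defined as the minimum of the two
   per-transcript shared-exonic-base fractions (the source procedure does
   not pin down the formula; this is recorded as a convention, as is the
   boundary: exactly 0.90 rejects).
2. **Novel integration.** The same rules applied with the novel set
   incoming against the current merge.
3. **Splice-evidence resolution.** A novel transcript with a junction
   (≥1 read) linking one of its exons to a reference exon on the same
   strand inherits that reference gene's id; a junction linking two
   reference genes resolves to the higher read count, ties to the
   lexicographically smaller gene id, always logged. A novel transcript
   with no evidence whose full span lies inside a single reference intron
   (either strand — intronic fragments need not be stranded) is removed;
   anything else keeps its own gene id.

Every incoming transcript's fate (kept / dropped + reason / reassigned) is
recorded in a provenance log, and a constructed fixture
(`gen_annotation_fixture()`) exercises each branch with a hand-built
expected answer that the merge must reproduce exactly.

**Symbols.** The best qualifying homology hit (e ≤ 1e-20; primary table
first, fallback only if the primary has none) names the transcript:
unmodified at query coverage ≥ 0.90, `_like` strictly between 0.50 and
0.90, `_containing` at or below 0.50 (the published wording "higher than
50%" forces the 0.50 boundary down; 0.90 going to the plain symbol is the
recorded convention). E-value ties break by higher coverage, then higher
identity, then lexicographic subject.

## Sequence features

* **GC**: (G+C)/(A+C+G+T), case-insensitive, N excluded from the
  denominator.
* **ARE score**: for 3′UTRs of at least 200 nt, P overlapping AUUUA
  (DNA: ATTTA) pentamers plus 1.5 per consecutive pair with start-to-start
  distance ≤ 14 nt. This is a transparent approximation of the web-based
  scorer used in the field (whose exact algorithm is not restated in the
  literature the package follows); the two published class boundaries are
  preserved exactly: score 0 ⇔ "no ARE", score ≥ 8 ⇔ "high ARE". All
  constants sit in `are_config()`.
* **Motifs**: IUPAC patterns, overlapping matches, per-kb densities. The
  Mex3c-type recognition motif is deliberately a required parameter — no
  authoritative default exists.
* **k-mer enrichment** uses sequence-level presence/absence so the Fisher
  2×2 is well-defined; p-values are BH-adjusted over every k-mer present
  in either set.
* **Fisher/Wilcoxon**: enrichment p-values come from the exact Fisher
  test; reported odds ratios are Haldane-corrected sample ORs (so
  swapping foreground and background inverts them exactly, and
  proportional tables give exactly 1). The rank test is exact for ≤8
  untied values per group, tie-corrected normal otherwise, and returns 1
  when all values are equal.

## The synthetic generator: what it emulates, and what a green test means

`gen_counts()` draws, for gene *i* from template *k*, state log2 means
`baseline_i + amplitude · template_k(state)` plus a gene-specific
Normal(0, 0.1) male offset, scales by log-uniform library factors in
[0.7, 1.4], and samples NB counts at dispersion 0.05. Defaults were chosen
once as a realistic bulk-brain stated world and not revisited: amplitude 2
(a 4-fold peak-to-trough change, the scale of clearly patterned genes),
dispersion 0.05 (typical biological CV ≈ 22% for brain replicates),
baselines log2-uniform in [8, 12] so simulated genes behave like the
pass-filter detected genes the downstream analysis actually sees. The LSV
simulator draws Poisson totals (mean 100) split multinomially by planted
per-state PSI; planted classes include a cold cassette drop (|dPSI| 0.5),
a warm-default retained intron, and a constant retained intron that should
end up a control.

What the generator does **not** emulate: outlier samples and batch
effects, correlated genes (every gene is independent), GC- or
length-dependent quantification bias, between-replicate overdispersion of
junction counts beyond multinomial, incomplete or wrong annotation. A
green recovery test therefore establishes that the estimators implement
their contracts on well-behaved data at realistic effect sizes and n — it
does not certify performance on pathological real-world libraries.

## Numerical choices and degenerate inputs

* One RNG stream per generator call, seeded explicitly; the global seed
  never leaks (`.Random.seed` is restored).
* Monte-Carlo dPSI seeds derive deterministically from the configured seed
  and the LSV id (kept < 2³¹).
* GLM non-convergence flags the gene and sets its p missing rather than
  aborting.
* All-zero LSV states are uninformative and excluded from tests; LSVs with
  all-zero reference states error on orientation-dependent operations.
* Empty template sets, single-state designs, genes never observed, and
  sub-minimum 3′UTRs all raise or flag explicitly rather than propagating
  NaNs.

## Known limitations

The DE machinery treats gene-wise dispersion as known in the LRT (the
usual plug-in approximation); at n = 5 per state this is mildly liberal in
principle, compensated here by the conservative state-level pooling — the
calibration test pins the net behavior. The splicing posterior ignores
between-replicate variability by pooling. The annotation merge is
quadratic in transcripts per chromosome, fine for the fixture scale and
desk-scale annotation sets, not tuned for 70k-transcript genomes. The
shrunken fold-change is a fixed-prior posterior mean, not adaptive
shrinkage.
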
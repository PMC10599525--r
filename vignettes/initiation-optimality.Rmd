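---
title: "Scoring codon initiation optimality: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring codon initiation optimality: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonIO)
```

## The model

`codonIO` scores each codon's association with a sequence-set contrast
by a log odds ratio against its synonyms. For focal codon $c$ in
synonymous block $B$, with counts $n_1 = $ occurrences of $c$ in the
target set, $s_1 = $ occurrences of the other members of $B$ in the
target set, and $n_2, s_2$ likewise in the comparator set:

$$\mathrm{LOR}(c) = \ln\frac{n_1/s_1}{n_2/s_2}, \qquad
\mathrm{SE}(c) = \sqrt{\tfrac1{n_1}+\tfrac1{s_1}+\tfrac1{n_2}+\tfrac1{s_2}}.$$

Because the comparison is always against synonyms, the statistic is
insensitive to amino-acid composition differences between the two
sets — the property that makes 5'-window contrasts across heterogeneous
gene sets meaningful. One entry per codon with at least one synonym
gives a 59-element vector (61 sense codons minus ATG and TGG). The
six-fold families (Leu, Ser, Arg) are treated as single blocks; an
explicit repartition (e.g. Arg split into AGA/AGG and CGN) is available
through `genetic_code_partition(repartition = ...)` and changes the
scored-codon set accordingly.

Key structural consequences, all asserted as tests: entries of a
two-fold block are exact negations with equal SE; swapping target and
comparator negates the vector; doubling all counts leaves estimates
unchanged and shrinks SEs by $1/\sqrt2$.

### Zero cells

The SE formula presumes positive counts. When any of the four cells is
zero the default is the Haldane–Anscombe correction (+0.5 on all four
cells) with a `corrected` flag on the entry; `correction = "drop"`
instead marks the entry undefined and downstream statistics drop it
pairwise. Both sides of a block empty always yields an undefined entry.
The correction preserves vector completeness in small strata (the
situation the synthetic tests exercise) while remaining visible to the
analyst.

## Sequence windows and conventions

* Codon positions are 1-based; position 1 is the start codon.
* The 5' window defaults to positions 2–12: the first 11 codons of the
  ORF excluding the start. The core window has the same length and
  starts at $\lfloor (L - w)/2 \rfloor + 1$, with $L$ the codon count
  excluding the terminal stop and $w$ the window length; the floor
  makes the "middle of the CDS" deterministic.
* Genes too short for the 5' window are dropped (reported); genes whose
  windows overlap are retained with `overlap_flag`, letting users
  reproduce either inclusion choice.
* CDS quality filters, in fixed order: length divisible by 3, terminal
  stop present, no internal stop, NTG start. Filtering is idempotent.
* Codons containing non-ACGT characters are excluded from all counts;
  the record is kept and flagged rather than discarded.
* GC3 is, per gene, the G/C fraction of third positions over sense
  codons (terminal stop excluded; the start codon is included, though
  its third base is constitutively G — the same convention must be
  used consistently when comparing genomes). The genome value defaults
  to the unweighted per-gene mean; a pooled mode exists.
* Transgene constructs carry an 11-codon variable region *including*
  the start, so their scored positions default to 2–11; native windows
  use 2–12.

## Contrast definitions

Quantitative strata use nearest-rank quantiles: the top
$\lceil fN\rceil$ records by the metric (ties broken by a stable sort
on the identifier, so results are reproducible to the byte). The
transgene contrast takes the top and bottom 25% of constructs by
Prot.FCC, the construct's reporter ratio normalised by the mean of the
uncensored members of its 13-variant synonymous group; out-of-range
measurements are ranked $\pm\infty$ — for extreme strata only their
extremeness matters, not the unmeasurable value. Whether the group mean
should include out-of-range members is not determinable from the data
description; the uncensored mean is used and the censoring fraction is
a simulator parameter, so the sensitivity is testable. Abundance
contrasts use 25% tails; the noise contrast uses 40% tails (its source
data set is an order of magnitude smaller) and orients *low* noise as
the target so positive entries read "low-noise-associated";
essentiality is a categorical split.

## Vector comparison

Pearson correlation (Spearman as an outlier check) is the primary
comparison, but log-odds entries are not independent within blocks —
a two-fold block contributes $x$ and $-x$. The oriented pairwise
synonymous-difference construction addresses this: one data point per
unordered intra-block codon pair, the difference taken so the x-vector
value is non-negative, with orientation preserved on y. The standard
partition gives $9\binom22 \cdot 1 + \binom32 + 5\binom42 + 3\binom62
= 87$ pairs. Exact x-ties are oriented alphabetically.

Other comparison tools:

* **Orthogonal regression** via the first principal axis of the
  centered, *unscaled* 2-column data (total least squares). An
  isotropic cloud (equal eigenvalues) raises an error rather than
  picking an axis silently.
* **Exact binomial sign test**: two-sided p as
  $\min(1, 2\min(P(X\le k), P(X\ge k)))$ at $p_0 = 0.5$, by pmf
  summation. Zero-valued entries count as non-matching and are
  reported separately. (For 22 of 30 this gives 0.016; note that for
  22 of 29 the exact value is 0.0081 — counting conventions around
  zero entries matter and the test reports them.)
* **Multivariate OLS**, unweighted, intercept always included;
  quadratic terms appended on request (GC3 models). Rank deficiency is
  an error naming the collinear columns, not a silent drop.
* **Cronbach's alpha** for the concordance of per-position vectors,
  with Feldt's F-interval ($F_{n-1,\,(n-1)(k-1)}$); used on the
  positions 2–11 matrix from `positional_log_odds()`.

## Genome survey

`survey_genomes()` computes each genome's V_5-core vector and its
Pearson correlation with a reference vector. "Significantly positive"
means two-sided Bonferroni-adjusted p < 0.05 *and* r > 0, the
correction factor being the number of genomes surveyed. Per-genome
p-values use however many entries are defined for that genome
(undefined entries are pairwise-dropped). Collection gating — genome
length ≥ 500 kb, one genome per genus against phylogenetic
pseudo-replication — is a manifest-level pre-filter
(`filter_genome_manifest()`), since genus labels and lengths are
catalogue metadata, not sequence properties. Optimal growth
temperature and window folding energies are consumed as covariate
columns; predicting them is out of scope.

The GC3 model fits r ~ GC3 + GC3² (the biology predicts an interior
optimum: GC-rich genomes differentiate 5' ends strongly, AT-rich
genomes get low 5' stability for free), optionally joined with growth
temperature; interactions are excluded.

## The synthetic-data generator

The simulator is the package's substitute for the external data
sources, and its defaults state the world the validation runs in:

* **Genomes**: `n_genes = 2000`; codon lengths lognormal
  (meanlog log 200, sdlog 0.35, floor 24); amino acids uniform over
  the 18 multi-codon families so block contrasts carry no amino-acid
  confound; ATG start, TAA stop. Within a block, codon probabilities
  are a softmax of core log-weights plus `delta` inside the 5' window,
  plus `coupling` for top-quartile-abundance genes.
* **Transgenes**: 200 groups × 13 synonymous variants; per-codon
  log-effects `beta` with sd 0.15; multiplicative lognormal
  measurement noise sd 0.2; lognormal group baselines (cancelled by
  Prot.FCC, asserted); 2% of measurements censored at the range
  limits to exercise the extreme-rank rule.
* **Annotations**: lognormal(0, 1) abundance; noise rank-coupled to
  abundance at Spearman −0.5 via a Gaussian copula; essentiality
  logistic in log-abundance with baseline fraction 0.2.

**Identifiability of planted effects.** Both generators expose effects
only through within-block weight differences (softmax) or
group-normalised sums, so adding a constant per block to `delta` or
`beta` changes nothing observable. Planted vectors are therefore
centred within blocks on input and the *centred* vector is the stored
ground truth; recovery correlations are computed against it. Without
this normalisation the uncheckable between-block component of a raw
random draw caps the attainable correlation near
$\sqrt{(k-1)/k}$-averaged ≈ 0.84 — a property of the question, not of
the estimator.

What a green recovery test establishes: that the estimator recovers
within-block preference differences planted under this generative
model (log-additive effects, no positional interactions, no RNA
structure, no amino-acid bias). What it does not establish: behaviour
under real features the generator omits — genuine secondary-structure
effects, codon-pair and positional context, amino-acid usage skew,
operon structure, phylogenetic correlation between genomes. The
multi-genome claims of the field (the shape of the cross-genome
correlation distribution, the GC3 dependence) need real genome
collections; here they are covered by calibration and
coefficient-recovery checks of the same statistical machinery.

## Numerical choices

* Natural log throughout; vector rows ordered alphabetically by codon
  for stable file output.
* Quantile membership is nearest-rank `ceiling(frac * N)`; the exact
  rule at the boundary is not universally standardised, so it is fixed
  and documented rather than configurable.
* RNG: generators require an explicit seed, run in a local RNG scope
  (the caller's `.Random.seed` is restored), and are byte-reproducible
  for fixed parameters.
* The orthogonal-fit eigenvalue tie tolerance is `1e-12` relative;
  `correlate_vectors` refuses zero-variance input rather than
  returning NA.
* Flat-file parsing (GenBank/EMBL) is a minimal in-house reader for
  CDS features — locations with `complement()`/`join()`, locus tags,
  ORIGIN/SQ blocks — because no installed R package parses these
  dialects; FASTA I/O delegates to Biostrings. Mixed-strand join
  locations and fuzzy locations beyond `<`/`>` trimming are rejected
  per record (skipped and logged), not fatal.

## Known limitations

* The standard genetic code only; no alternative translation tables,
  no programmed frameshifts.
* The transgene normalisation reproduces the published group-mean
  scheme but not the upstream fluorescence processing.
* Per-genome survey p-values inherit the block non-independence of
  vector entries; the null-calibration test shows the type-I rate is
  nevertheless near-nominal under the generator, but the
  pairwise-difference route remains the cautious option for single
  comparisons.
* No multiple-testing machinery beyond Bonferroni; no weighted or
  robust regression variants.
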
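---
title: "Homology-based GO transfer: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based GO transfer: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homologyGO)
```

# The model

Homology-based function transfer assumes that sequence similarity implies
functional similarity. Its inputs are (i) a GO ontology (OBO), (ii) a
template database of proteins with curated annotations (GAF), and (iii) a
tabular hit list from a sequence search tool linking each query to
templates with a bit-score, E-value, identical-residue count and
alignment/sequence lengths. The prediction for a query is a score in
(0, 1] for every GO term carried by at least one annotated hit.

Three conventions run through everything:

* **Ancestor closure.** An annotation to a term implies all of its
  transitive parents. We propagate over `is_a` and `part_of` edges only
  (the CAFA convention; regulates-type edges relate processes rather than
  subsume them) and never across aspects. The three aspect roots are
  excluded everywhere — they are true of every protein and carry no
  information.
* **Evidence filtering.** Only experimental, high-throughput, author
  statement (TAS) and curator (IC) evidence codes are trusted;
  electronically inferred (IEA) rows are dropped, as are `NOT`-qualified
  rows (a `NOT` annotation asserts the absence of a function and must not
  be transferred as presence).
* **Protein-binding exclusion.** A protein whose *only* MF leaf is
  GO:0005515 "protein binding" says almost nothing about molecular
  function (the term is near-universal among interacting proteins), so
  such MF sets are removed from both targets and templates.

## Scoring functions

With K annotated templates, bit-score $B_k$, identity normalisations
$qID_k, tID_k, aID_k$ (by query length, template length, aligned columns)
and $ID_k = \min(qID_k, tID_k)$ (by the longer sequence), and $K(q)$ the
templates carrying term $q$ after closure:

$$S_1(q) = \frac{\sum_{k \in K(q)} B_k}{\sum_k B_k}, \qquad
  S_2(q) = \frac{\sum_{k \in K(q)} B_k\, ID_k}{\sum_k B_k\, ID_k},$$

$S_3$–$S_6$ replace the weight with $qID$, $tID$, $aID$, $ID$ alone,
$S_7(q) = K(q)/K$ is the unweighted frequency, and $S_8$–$S_{11}$ take the
maximum of the four identities over templates carrying $q$. $S_2$ is the
default: the bit-score is length- and parameterisation-dependent while
sequence identity is an intrinsic property of the pair, so their product
weights templates by two complementary similarity signals. For search
tools that report another similarity (e.g. a cosine similarity from an
embedding model), `parseHits(..., scoreField = "score")` substitutes that
column for the bit-score in the weighted functions.

Because closed term sets are nested along the DAG, $K(q) \subseteq
K(\mathrm{parent}(q))$, every function is monotone: a parent never scores
below its child. Terms carried by no template are absent rather than
zero — the formulas are undefined there and no smoothing prior is
applied.

## Evaluation

Precision at threshold $t$ is averaged over the $M(t)$ ground-truth
proteins with at least one prediction scoring $\ge t$; recall is averaged
over all $N$ ground-truth proteins, so an unpredicted protein drags
recall but not precision. Fmax is the maximum harmonic mean over the
threshold grid. wFmax weights every term indicator by its information
accretion

$$IC(q) = -\log_2 \frac{1 + C(q)}{1 + C(\mathrm{parent}(q))}$$

with $C(q)$ the number of template-database proteins carrying $q$ and
$C(\mathrm{parent}(q))$ the number carrying *all* direct parents of $q$
simultaneously; the +1 smoothing keeps unobserved terms finite. On a
closed database $C(q) \le C(\mathrm{parent}(q))$, so $IC \ge 0$.
Methods are compared per protein: each protein's own F at a fixed
threshold, a two-tailed paired t-test on the aligned differences, and the
per-method standard error of the mean.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fn` | `"S2"` | scoring function, `"S1"`–`"S11"` |
| `evidenceFilter` | 13 codes | accepted GAF evidence codes |
| threshold grid | 0.01–1.00 step 0.01 | CAFA grid; `mode = "exact"` sweeps the distinct scores instead |
| `weight` (`combinePredictors`) | 0.5 | weight on the first predictor |
| `lambda` (`blendScores`) | — | convex weight between two score maps |
| NK-easy cutoff | ID > 0.5 | best-template identity (longer-sequence normalisation) separating easy from hard no-knowledge targets |

Identity-based weights and scores are dimensionless fractions in [0, 1];
bit-scores are in bits as reported by the search tool; IC values are in
bits.

# Numerical and design choices

* **Threshold comparison epsilon.** A score counts as above threshold
  when `score >= t - 1e-9`. `seq(0.01, 1, 0.01)` does not represent most
  grid points exactly in binary, and without the epsilon a score of 0.29
  could fall below the "0.29" grid point. The epsilon makes grid and
  exact sweeps agree whenever scores sit on the grid.
* **0/0 harmonic means are 0** (empty intersections, empty predictions),
  the standard CAFA handling; when $M(t) = 0$ precision is reported as 0
  with an explicit flag.
* **Multi-HSP pairs.** Search tools may report several local alignments
  per query–template pair; the per-template quantities of the scoring
  functions are singular, so `dedupeHits()` keeps the highest-bit-score
  HSP (ties: lowest E-value, then first occurrence).
* **Identity from percent identity.** When a dialect reports only
  `pident`, the identical-residue count is `pident/100 × alnLen` rounded
  half away from zero (deterministic across platforms); `aID` is clamped
  to 1 for dialects that count gap columns inconsistently.
* **Blending sign.** The combination of S2 with another score is
  implemented as the convex combination $\lambda S_2 + (1-\lambda) S_c$.
  A minus sign on the second component would leave the (0, 1] score range
  and make the $\lambda = 0.5$ "half-half" blend meaningless; the convex
  form is the only reading under which the endpoints reproduce the
  individual scores. After any arithmetic on score maps, DAG consistency
  is re-enforced by max-propagating scores to ancestors.
* **Root IC.** The accretion formula is silent on roots; we define
  $C(\mathrm{parent}(\mathrm{root}))$ as the number of proteins annotated
  in the aspect, which makes root IC 0 — computable, and irrelevant since
  roots never enter scoring or evaluation.
* **Per-protein t-test threshold.** Per-protein F vectors entering the
  paired t-test are computed at each method's own Fmax-optimal threshold
  (its best operating point); the threshold is an explicit argument, so
  any other convention is one call away.
* **Unknown GAF terms** are skipped with a counted warning rather than an
  error: real GAF and OBO releases drift apart, and a handful of retired
  ids should not abort a database build.

# The synthetic-data generator

`simulateBenchmark()` draws, deterministically per seed: a random DAG per
aspect (30 terms, at most 2 parents per term, 20% `part_of` edges); 100
template and 50 query proteins with `1 + Poisson(2)` leaf annotations per
aspect and evidence codes from the accepted list (10% IEA decoys exercise
the filter); and a hit table built from a latent similarity per
query–template pair,

$$\ell = s \cdot \mathrm{overlap} + (1 - s)\, U(0,1),$$

where `overlap` is the fraction of the query's true terms the template
shares and `s = signalStrength` (default 0.8). Each query's hit list is
the top 20 templates of the similarity ranking — the way a search tool
reports hits: enriched for true homologs, contaminated by chance high
scorers — plus 5 random lower-ranking "noise" templates. Bit-scores rise
linearly with the latent (30 + 470ℓ), the identity fraction of the longer
sequence as 0.1 + 0.8ℓ; sequence lengths are uniform on 100–600 residues
and identical-residue counts are clamped to the alignment invariants.
With `s = 1` and no noise the top hit provably shares the most truth
terms; with `s = 0` bit-scores are independent of term sharing.

The generator emulates the *structure* of real data — DAG-closed
annotations, evidence-code mixtures, hit lists whose scores correlate
with functional relatedness. It does not emulate sequence evolution:
there are no actual sequences, no alignment statistics (bit-scores are
linear in the latent rather than log-E-value-shaped), no annotation bias
(real databases annotate popular proteins more deeply), and term
assignment is uniform rather than depth-biased. Passing tests on these
fixtures therefore show the machinery is correct and that the scoring
functions behave as designed *when the planted assumption (similarity
tracks shared function) holds* — they do not certify performance on any
real proteome.

On these fixtures, the 100-seed comparison reported by
`scripts/acceptance.R` evaluates each scoring function's wFmax per aspect
and compares the mean across the three aspects seed by seed; a
single-aspect comparison would discard two thirds of each simulated
dataset for no reason. The bit-score-times-identity weighting dominates
both the unweighted frequency (S7) and best-single-hit (S11) transfer in
well over 90 of 100 seeds.

# Problem sizes

The test suite and acceptance script use the generator defaults above (50
queries × 25 hits, three aspects) for the 100-seed comparisons, 15-term
ontologies for the DAG-monotonicity trials, and template sets of at most
10 entries for the brute-force scoring oracle; these sizes give stable
statistics while keeping a full run in the low minutes on one CPU.

# Known limitations

* `part_of` inclusion in propagation is a convention; ontologies that
  lean on `regulates` relationships will propagate less than some
  downstream tools expect.
* The joint-parent count $C(\mathrm{parent}(q))$ is computed by exact set
  intersection per term; on multi-hundred-thousand-protein databases this
  is the slowest step of `computeIC()`.
* Evaluation-only runs require every predicted term to have an IC entry;
  predictions against a different ontology release fail fast rather than
  silently dropping terms.
* No Smin/semantic-distance metric and no bootstrap confidence intervals
  are provided (SEM and the paired t-test are the supported comparison
  tools).
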
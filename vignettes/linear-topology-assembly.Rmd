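---
title: "Assembling BAC fingerprint contigs with linear-topology control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling BAC fingerprint contigs with linear-topology control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincontig)
library(data.table)
```

## The problem

Physical maps order large-insert BAC clones along a chromosome before
sequencing. Each clone is characterized by its *fingerprint*: the multiset
of restriction-fragment band sizes (here typed by dye/enzyme, as in
high-information-content fingerprinting, HICF). Two clones from the same
genomic region share bands, so a sufficiently improbable number of shared
bands is evidence of physical overlap. In large, repeat-rich genomes the
standard approach — thresholding the classical Sulston score at a very
stringent cutoff and clustering — yields short, sometimes unreliable
contigs, leaves chimeric ("Q") clones undetected, and gives no tools to
diagnose why a minimal tiling path (MTP) fails at the bench.

`lincontig` implements an alternative workflow built on one structural
idea: a correct contig, as a set of clones tiling an interval of a linear
chromosome, must form a *topologically linear* net of significant
overlaps, and every true overlap should be corroborated by parallel
overlapping clones. The stages are:

1. **Overlap p-values** for all clone pairs, by Monte-Carlo-calibrated
   metrics (`compute_overlaps()`).
2. **TENPP** — temporal exclusion of clones and clone overlaps not proven
   by parallel paths in the overlap net (`tenpp()`).
3. **Adaptive clustering**: single-linkage at a liberal cutoff, freezing
   reasonably sized clusters, tightening the cutoff only on what remains
   large (`adaptive_cluster()`).
4. **Linearity diagnosis** via the diametric path and vertex ranks, and
   splitting of non-linear clusters at branching nodes
   (`linearity_check()`, `split_nonlinear()`).
5. **Ordering** of each cluster by maximizing the criterion
   $W(\Omega)=\sum_k W_{\Omega(k),\Omega(k+1)} - b(\Omega)\,W_0$, an
   open-path traveling-salesman problem (`order_clones()`).
6. **Jackknife** order stability from band resampling (`jackknife()`).
7. **Merging** of contigs through the pools of temporarily excluded
   elements (`elongate()`).
8. **MTP selection** from the diametric path (`select_mtp()`).

A BAC-library simulator (`simulate_clones()`) provides ground truth for
validating every stage, and partition statistics (`rand_index()`,
`mean_overlap()`, `evaluate_vs_truth()`) quantify agreement.

## Overlap metrics

For clones $c_1, c_2$ with $n_1, n_2$ bands sharing $k$, three metrics are
available:

* **sulston** — the classical binomial approximation with per-band match
  probability $p_1 = 1-(1-(2t+1)/G)^{n_2}$, where $t$ is the tolerance and
  $G$ the number of distinct possible band values.
* **siid** — the same iid model, but the upper tail $\Pr(K \ge k)$ is
  estimated by simulating random clone pairs and fitting
  $\exp\{-(a_0+a_1k+a_2k^2)\}$ to the empirical tail. The quadratic
  replaces the binomial approximation, which degrades for large $k$.
* **sind** — drops the identical-distribution assumption: the statistic
  becomes $k_w=-\sum\ln f_b$ over shared bands, with $f_b$ the estimated
  abundance of band class $b$, so that sharing a *rare* band counts for
  more than sharing a ubiquitous one. Calibration draws bands from the
  estimated abundance distribution.

Abundances come from the small-$f$ maximum-likelihood approximation
$f_b \approx n_{\mathrm{mean}}^{-1}\,\pi_b/(1-\pi_b)$, where $\pi_b$ is
the fraction of clones carrying a band within tolerance of $b$; $f_b$ is
capped at 1 and $\pi_b = 1$ is protected against division by zero.

Shared genetic markers multiply any metric's p-value by
$e^{-a_{\mathrm{mark}}}$ per marker, with $a_{\mathrm{mark}} = 100\ln 10$
by default, so a marker-sharing pair is always more significant than
$10^{-100}$. Markers and bands therefore act synchronously; a duplicated
or mis-amplified marker shows up later as non-linear topology rather than
silently fusing two contigs.

### Numerical choices

* **Calibration window.** The quadratic is fitted where the empirical tail
  lies in $[10/\mathrm{reps}, 10^{-3}]$; the upper boundary is the
  validity threshold of the model (the tail must be below $10^{-3}$ beyond
  $k_0$), the lower avoids the unpopulated extreme tail. Below $k_0$ the
  empirical tail itself is returned. Fits with fewer than three support
  points fall back to a linear tail with a warning, as do fits whose
  quadratic would not be monotone over the evaluation range. Note that the
  default `reps = 2e5` gives the count statistic only a handful of support
  points; p-values far beyond the fitted window are extrapolations and
  should be read as rankings, not calibrated probabilities.
* **Model sharing.** Tail models are calibrated per band-count pair
  $(n_1,n_2)$ rounded to the nearest multiple of 10 and cached; an
  all-pairs run over hundreds of clones could not afford per-pair
  Monte-Carlo.
* **The universe $G$** is the number of distinct *raw* band values (for
  wheat-style HICF data, about 18,000 = 4 dyes x 4,500 scored values). The
  Sulston formula uses $(2t+1)/G$ directly; the Monte-Carlo calibration
  draws from the tolerance-binned universe $G/(2t+1)$ with exact matching,
  which implies the same per-band-pair collision probability. When `G` is
  not given it is estimated from the observed per-type size ranges.
* **Band classes.** The size axis of each type is pooled greedily into
  classes that end at a gap larger than $t$ *or* when the class would
  exceed $\pm t$ around its first member. The width bound matters: on
  dense HICF size axes gaps larger than the tolerance are rare, and pure
  gap-based pooling would collapse entire types into one class, destroying
  abundance estimation.
* **Far-tail continuation.** Beyond the last Monte-Carlo-supported
  statistic the quadratic is pure extrapolation, and its $a_2$ term
  amplifies fit noise quadratically — badly enough that edge weights for
  near-duplicate clone pairs became dominated by calibration noise. The
  model therefore continues *linearly* past the fit window, with the
  slope at the window edge. P-values inside and near the calibrated
  window (where clustering cutoffs live) are unchanged; far-tail values
  stay monotone and comparable across band-count cells.
* **Internal scale.** Natural log internally; log10 in all reported
  values.

## TENPP and why it is one pass

Each edge of the net of significant overlaps is required to have a
parallel simple path of 2–5 edges connecting its endpoints without the
edge itself; each vertex is required to offer such a path between every
pair of its neighbors without passing through itself. Elements failing
the test are moved to exclusion pools — *temporarily*: merging later
re-admits them. One invocation performs the edge phase and then the
vertex phase on the edge-filtered graph, and is *not* iterated to a
fixpoint: repetition is provided by the adaptive clustering loop, which
re-applies TENPP at each stringency level. Iterating within one call
would only matter when the proportion of false overlaps is high, and it
would erode genuinely linear chains from their ends.

The path-length bounds (2 and 5) are configurable; for the *edge* phase
the tested edge itself never counts, so the shortest possible bypass has
2 edges, and 5 keeps the bypass local — a long detour through another
genomic region is not corroboration. For the *vertex* phase the default
minimum is 1: the question is whether the two neighbors of $c_0$ remain
connected without $c_0$, and a direct edge between them answers it. With
a minimum of 2 the vertex phase annihilates every thin-coverage triangle
(local coverage 3) and excluded ~16% of the clones of a clean simulated
12x library, against the ~7% reported for real HICF data; with the
direct edge admitted the rate falls in line while chimera detection is
unaffected (a chimera's neighbor pairs straddle regions and have no
connecting edge).

The first clustering round applies TENPP to the entire net before any
freezing — putative chimeras must be removed before clusters form —
while later rounds re-apply it only inside clusters still too large to
freeze.

## Adaptive clustering

Single-linkage clustering at cutoff $\Pr_0$ is exactly the set of
connected components of the overlap net at that cutoff. The loop starts
liberal ($\Pr_0 = 10^{-12}$, roughly $10^{-3}/N^2$ for tens of thousands
of clones), applies TENPP inside components larger than 500 clones,
freezes components of 6–500 clones ("reasonable size"), and tightens the
cutoff by $\times 10^{-3}$ on the rest. Frozen clusters are never
revisited — stringency that a cluster does not need would only dissolve
it. The 6/500 bounds and the schedule are configurable
(`cluster_schedule()`); the default bounds are conventional and
acknowledged as arbitrary-for-certainty. If the schedule
is exhausted while a large cluster persists, its clones are flagged
`UNRESOLVED` rather than silently dropped.

Buried clones (fingerprint essentially contained in another's: at least a
fraction `q = 0.9` of bands matched, fewer bands than the host) can be
detached before clustering and are re-attached to their host's cluster
afterwards. Burial handling is a trade-off: buried clones inflate
clusters and break the path structure the TSP solver relies on (a buried
clone's only significant overlap may be its host, forcing the path to
visit the host twice), but detaching them can also disconnect a contig.

## Ordering and stability

The TSP edge weights default to the *analytic* Sulston tail
(`order_metric = "sulston"`) even when significance calling uses a
calibrated metric. The reason is numerical, not statistical: the
calibrated tails are piecewise (empirical table, quadratic window,
linear continuation) and quantized over band-count cells, so two
arrangements of borderline adjacent clones can be separated by
calibration noise rather than data; the analytic tail is a smooth
deterministic function of the exact $(n_1, n_2, k)$. On a 473-clone
simulated contig the calibrated weights left a handful of local swaps
(and the count-statistic variant shuffled the order grossly), while the
analytic weights reproduced the true genomic order exactly. Gap calls
and the penalty indicator stay with the primary significance metric.

Within a linear cluster, distances
$d(c_i,c_j) = W_{\max} - W_{i,j} + W_0\,\mathbf{1}\{\Pr(c_i,c_j)>\Pr_0\}$
turn criterion maximization into an open-path TSP. The penalty $W_0$
defaults to $-\log_{10}\Pr_0$ — one non-significant adjacency costs one
threshold-grade link; $W_0$ is otherwise a free parameter. The
solver is nearest-neighbour construction from multiple starts plus 2-opt
and Or-opt improvement; the contract is the criterion value, not a
particular optimizer, and for $n \le 9$ the tests verify exhaustive
optimality. Orientation is canonicalized (lexicographically smaller
endpoint first) since $W$ is reversal-invariant.

The jackknife drops a random 5% of *band classes* — all their occurrences
across clones — recomputes the cluster's overlaps restricted to kept
bands, evaluates them against the same tail models, reorders, and tallies
left/right neighbors per clone. Dropping classes rather than per-clone
bands mirrors resampling "subsets of bands" and avoids the
significance inflation that bootstrap resampling of band occurrences
would cause. A clone's instability is one minus its maximal neighbor
frequency, averaged over sides; clones above the threshold (default 0.3)
are "parallel clones" — near-duplicates that no fingerprint method can
order — and `skeleton_order()` removes them, attaching each to its most
significant kept neighbor. The replicate count (default 100) is a
compromise; there is no canonical value.

## Simulator: the stated world

`simulate_clones()` emulates a HICF BAC library from a genome sequence:

* Clone boundaries are HindIII sites; `i_start` is uniform over sites
  (sequence ends added as sentinels), direction $\pm 1$, and the site
  count is $h = \lfloor N(a, \sigma^2)\rfloor$ with $a = 120\lambda$,
  $\sigma = 30\lambda$, $\lambda = (N{+}1)/L$ — targeting clone lengths
  of about 120 ± 30 kbp. Out-of-range ends are clipped to the sequence
  ends (mimicking chromosome-end clones); degenerate draws are redrawn.
* With probability 0.05 a clone is a chimera: the union of its interval
  with one further independently drawn clone (recursively, so 3-part
  chimeras occur at rate $p^2$).
* Bands: fragments between consecutive cuts of BamHI, EcoRI, XbaI, XhoI
  (typing enzymes), HaeIII (blunt) and the clone ends; a fragment yields
  one band per *distinct* typing enzyme bounding it — a fragment between
  two different typing enzymes is counted twice, one bounded only by
  HaeIII or clone ends not at all. Bands outside 50–500 bp are discarded.
  Band lengths are computed from cut coordinates, not sequence slices.
* Observation noise: error uniform on $(-\varepsilon,\varepsilon)$ with
  probability 0.9, else on $(-3\varepsilon,3\varepsilon)$, with
  $\varepsilon = 0.2$; scored size = `round(30 * (len + err))` plus a
  type offset of 0/5000/10000/15000 — the FPC-format convention — hence
  tolerance $t = 30\cdot 2\varepsilon = 12$ in scored units. Bands are
  lost with probability 0.05; clones with fewer than 50 or more than 250
  observed bands are dropped.

Two consequences of this model are worth knowing. First, the closed form
for the probability that two observations of one band fall within the
tolerance, $\tau = p_\varepsilon^2(1-(1-\frac{t}{2\varepsilon})^2) +
p_{3\varepsilon}^2(1-(1-\frac{t}{6\varepsilon})^2) + 2p_\varepsilon
p_{3\varepsilon}\frac{t}{3\varepsilon} = 0.94$ at the defaults, is
reproduced empirically by the simulator (see the test suite). Second,
the clone-length standard deviation *realized* by the site-step sampling
rule exceeds the nominal 30 kbp: conditioning on $h$ site steps, the bp
length is a sum of $h$ roughly exponential spacings, which adds
$\mathbb{E}[h]/\lambda^2$ to the variance — about 36–37 kbp realized
versus 30 nominal on a 10 Mbp i.i.d. genome. We implement the sampling
rule exactly as stated and report what it produces rather than re-tuning
$\sigma$. Clones whose end index falls outside the site range are
clipped to the sequence ends and flagged `clipped` in the ground truth;
parameter-recovery measurements exclude them, since clipping is a
boundary artifact rather than part of the sampling rule.

What the generator does *not* emulate: repeat families and transposon
landscapes (the main source of false overlaps in real cereal genomes),
correlated base composition, partial digestion, gel-lane calibration
drift, and the bimodal insert-length mixtures of real libraries. A green
end-to-end test therefore establishes that the pipeline recovers clean
linear order under calibrated iid-style noise and detects distant-region
chimeras — not that it would tame a hexaploid wheat chromosome.

The synthetic genome default (10 Mbp, ~1,000 clones, 13x coverage) is a
desk-scale analogue of a rice-chromosome-scale benchmark library
(45 Mbp, ~4,400 clones):
the same coverage and noise, an order of magnitude fewer clones. On an
i.i.d. genome at GC 0.44 the HindIII spacing (~3.4 kb) is close to the
rice value (3.6 kb); the per-clone band count comes out somewhat higher
(~140 versus 113), so chimeras — the union of two clones — sit near the
250-band ceiling and are frequently dropped at observation. Detection
statistics for chimeric clones are therefore computed over the *retained*
chimeras.

## Merging and re-admission

Elongation searches for significant end-to-end connections between
contigs, possibly through one or two intermediate clones from the
exclusion pools; merges must keep the union linear, must not join
different marker zones, and competing candidates for one end are
reported, never auto-resolved. End-based search cannot return
temporarily excluded clones whose region lies in a contig's interior, so
after merging, any pool clone whose significant overlaps all fall within
one local window of a single contig (at least 2 links, window diameter
at most `max(6, 2 x links)`) is re-attached as a position-free
`ATTACHED` clone, like a buried one. The window guard keeps putative
chimeras — links in two distant windows — out. This recovers clone
coverage from ~86% to ~96-99% on simulated libraries, matching the
benchmark workflows that re-analyze all temporarily excluded elements.

## Verification of external contigs

`verify_contigs()` re-derives the overlap net inside each supplied contig
and reports the five standard gap origins: non-connected nets;
buried-clone conflicts (connectivity lost when buried clones are
detached); orders fixable by global reordering; marker conflicts (a
marker shared by clones without significant overlap); and non-linear
topology. `rand_index()` and `mean_overlap()` compare partitions; the
mean-overlap statistic exposes `min_cluster` to suppress small clusters
(variant statistics that further down-weight small clusters exist; the
`min_cluster`/singleton filters are the documented stand-in here).

## Ground-truth evaluation

With simulator truth, `evaluate_vs_truth()` scores: contigs mixing
genomic regions more than one mean clone length apart (chimeric contigs);
genomic parts per contig; wrongly ordered contigs — neither the order
nor its reversal monotone in true midpoints, ignoring conflicts between
clones whose intervals overlap by more than 80% (near-identical clones
are not orderable from fingerprints); the fraction of retained clones
placed in contigs; and the fraction of chimeric clones kept in contigs.

## Known limitations

* P-values far beyond the calibrated window are quadratic extrapolations;
  they order pairs correctly but their absolute magnitudes are generous.
  Band-map construction, which would refine both ordering and MTP
  selection, is out of scope.
* The burial threshold, rs-cluster bounds, TSP restart count and
  jackknife replicates are heuristics with the defaults documented above;
  none is estimated from data.
* The FPC offset encoding folds scaled band sizes above 5000 into the
  next type's range. Decoding is deterministic, so matching within the
  database is unaffected, but a small fraction of bands near multiples of
  5000 lose cross-observation matchability, and decoded "types" are not
  guaranteed to equal the generating enzyme for long fragments.
```
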
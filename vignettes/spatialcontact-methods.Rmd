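---
title: "spatialcontact: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spatialcontact: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialcontact)
```

This vignette is the package's own account of its statistics: the model
behind each stage, the tunables that matter, what the synthetic
generator establishes (and what it cannot), and the numerical decisions
taken where the design was genuinely open. It states no empirical claim
that the test suite does not itself compute.

## 1. The coordinate grid

All 4C statistics live on the HindIII site grid. `digest_genome()`
performs a complete in-silico digest: every forward-strand occurrence of
`AAGCTT` (palindromic, so one strand suffices) cuts at its start
coordinate; occurrences overlapping `N` runs are skipped so masked
assembly regions contribute no phantom sites. Partial digestion is not
modelled — the protocol uses enzyme in excess — and the two-base 5'
overhang offset is ignored because no downstream statistic uses
sub-fragment resolution. Coordinates are 0-based half-open everywhere
in memory and on disk (BED dialect); `load_fragment_map()` re-validates
the tiling invariants on load and reports violations by line number.

## 2. The window p-score

For a bait profile restricted to a scope (cis = the bait chromosome,
trans = all other chromosomes pooled), each site $i$ receives the sum
$S_i$ of counts at sites within $\pm w/2$ of it ($w$ = 100 kb by
default, so roughly 24 sites at the expected 4 kb spacing) and the
upper-tail binomial probability

$$p_i = P\!\left[\mathrm{Binom}\!\left(N, \tfrac{k_i}{M}\right) \ge S_i\right],
\qquad \text{p-score}_i = -\log_{10} p_i \ (\text{capped at } 320),$$

where $N$ is the total scope read count, $M$ the scope site count and
$k_i$ the number of sites in the window. The null is uniform read
placement over the scope's sites — the simplest exchangeable null, and
the one the percentile threshold makes essentially free of
distributional risk: the caller is rank-based, so any monotone
transformation of the test statistic gives the same domains. Windows
never span a chromosome boundary; the p-value is computed in log space
(`pbinom(..., log.p = TRUE)`) so deep-signal sites do not underflow
before the cap.

Two sites — one on each flank of the bait's fragment — are masked
before scoring. In any circular 4C design their counts are dominated by
self-ligation and un-cut fragments, not by contacts. The mask width is
a parameter (`mask_bait_sites`).

**Thresholding.** The cutoff is the inverse-ECDF $(1-f)$ quantile of
the p-score ($f$ = 0.10 cis, 0.05 trans); a site is positive iff its
score is *strictly* above the cutoff, so ties at the cutoff are all
excluded and the positive fraction never exceeds $f$. This makes the
positive set deterministic and monotone in $f$ (a larger $f$ can only
add sites). The rank is computed as an order statistic with a
$10^{-9}$ epsilon so that floating-point representation of $f$ cannot
shift the index at exact-boundary values.

**Domains.** Maximal runs of at least 16 consecutive positive sites
("more than 15") become contact domains; runs break at any negative
site and at chromosome boundaries. A domain is recorded as
$[\mathrm{pos}_{\mathrm{first}}, \mathrm{pos}_{\mathrm{last}})$ — the
stored end is the last site's position, and all downstream interval
arithmetic treats domains as half-open.

## 3. Why retrieval is gated on an empirical FDR

The percentile threshold flags the top $f$ of sites *by construction*,
signal or not. Because adjacent windows share all but one site, the
positive flags are autocorrelated with correlation length of a full
window (~24 sites): one upward count fluctuation lifts a whole stretch
of windows. On a flat profile this produces runs of 16+ positives at a
material rate — around ten spurious "domains" per 10,000 sites in our
null simulations — so a naive independence bound of the form
$M f^{16}$ badly understates the false-call rate of this (or any
overlapping-window) caller.

The remedy, and the reason the study qualifies its domains with an FDR:
`estimate_fdr()` permutes the counts across the scope's sites,
re-scores, and counts permuted sites exceeding the cutoff observed on
the real data; the estimate is the mean permuted positive count over
the observed positive count. On a null profile the permutation changes
nothing material and the estimate is ~1; on a profile whose top decile
is filled with genuine structure the observed cutoff sits far above
anything a shuffled profile reaches and the estimate collapses toward
0. `detect_domains()` therefore retrieves called domains only when the
estimate is below `fdr_max` (default 0.05); otherwise it returns an
empty set with the estimate attached. The un-gated `call_domains()`
remains available and is what the exhaustive run-length oracle tests.

Two properties of this permutation scheme are worth knowing:

* it conditions on the count *marginals*, so heterogeneous means (the
  viewpoint-proximal plateau) make the permutation null heavier-tailed
  than the binomial. The estimate is honest about that: it reports the
  rate at which shuffled data beats the observed cutoff, not the
  binomial's fantasy rate. Consequently FDR < 0.04 is reachable only in
  a strong-signal regime where the entire top decile is genuine —
  which is exactly the regime in which percentile-thresholded domains
  deserve trust;
* it is seeded and reported in every manifest and BED sidecar.

## 4. The synthetic world

`synthetic_scenario()` declares a desk-scale dataset; every generator is
a pure function of (scenario, seed) and the tests assert bit-identical
re-runs. Defaults, chosen once from the stated study design and from
realism at desk scale:

* **genome** — 2 chromosomes × 20 Mb; exponential site spacing with
  mean 4096 bp = $4^6$, the i.i.d.-sequence occurrence rate of a 6-mer,
  so a sequence-free map is statistically interchangeable with a real
  digest (~9,800 sites);
* **4C cis** — negative binomial (dispersion 0.1; overdispersion is
  characteristic of 4C counts), mean
  $20 \cdot (\max(d, 200\,\mathrm{kb})/100\,\mathrm{kb})^{-1}$ at
  distance $d$ from the bait: a power-law contact decay with exponent
  1 (standard polymer behaviour) saturating in a ±200 kb self-ligation
  plateau. Six planted 30-site domains at fold 5, anchored 1.4–2.2 Mb
  from the bait. The anchor band is a power calculation, not a
  convenience: under the decay, a fold-5 window sum at distance $d$ is
  $\approx 25 \cdot 20 \cdot (100\,\mathrm{kb}/d) \cdot 5$ reads against
  a uniform-null mean of ~66, which clears the top-10% cutoff
  comfortably inside ~2.5 Mb and sinks below it beyond ~3 Mb —
  associating domains a caller with these parameters can *in principle*
  find are near-bait domains, and the generator plants only what the
  stated method can express;
* **4C trans** — uniform mean 1 read/site, eight planted 30-site
  domains at fold 5 on the second chromosome (the study reports on the
  order of twenty domains per bait genome-wide);
* **genes** — inhomogeneous Poisson TSS placement at 5 /Mb background,
  15 /Mb in active compartments, 2 /Mb in facultative heterochromatin;
  10 kb bodies, random strand; cluster labels drawn with
  compartment-dependent proportions (active compartments lean to
  clusters 3–4, heterochromatin to 1–2, mirroring the positional
  predisposition the study reports);
* **expression** — five conditions (0h, 1Gy-6h, 1Gy-24h, 6Gy-6h,
  6Gy-24h) × 3 replicates; NB counts with per-gene log-normal baselines
  around 200 and the four hard-wired (but overridable) kinetic shapes:
  cluster 1 down at 6Gy-6h and 6Gy-24h, cluster 2 down at both 24 h
  points, cluster 3 up at 6Gy-24h only, cluster 4 up at both 24 h
  points, |log2FC| = 2;
* **ChIP** — 10 kb bins, Poisson input (mean 50/bin), Poisson IP with
  mean input-rate × multiplier; multipliers (1, 2, 0.8) over
  (0h, 3h, 24h) in active compartments and (1, 0.9, 1.5) in facultative
  heterochromatin — repair signal rises then clears where
  transcription will be activated, and arrives late in the repressive
  compartment.

`null_scenario()` removes *every* effect — including the distance
decay, which is genuine contact signal: a "no-signal" 4C profile is
flat. `strong_scenario()` is the trustworthy-retrieval regime: twelve
40-site fold-8 cis domains, under which the whole top decile is genuine
and the permutation FDR collapses below 0.04.

**What a green test does not establish.** The generator draws
independent counts per site around a smooth mean: it has no ligation
chemistry, no PCR duplicates, no mappability structure, no
translocations, and its trans background is exchangeable. Recovery of
planted domains shows the caller's statistics are right, not that real
libraries are this clean. Likewise the expression model has no
outlier samples or batch structure, so the DE stage's behaviour on
pathological real data is untested by design.

## 5. Expression: a moderated stand-in, not an edgeR clone

The study used edgeR; re-implementing it is neither needed nor honest
at this scope. The package's test works on log2-CPM (pseudocount 0.5):
per-gene pooled variances are shrunk toward a lowess mean–variance
trend with a fixed prior of 4 degrees of freedom, a two-sample t
statistic is referenced to $t_{df_g+4}$, and Benjamini–Hochberg FDR is
applied per contrast. The *decision contract* matches the study: DE iff
FDR < 0.05 and |log2FC| > 0.5 (raw-p gate available as a flag). The
log-fold-change is computed from mean CPM, so a strong asymmetric
response shifts the CPM denominator and compresses observed log-FCs —
the usual composition effect of per-library normalization; the tests
therefore verify generator fold-changes on raw counts and treat the DE
gate's false-positive behaviour (BH at a high true-positive fraction
admits some stable genes) as a property of the stated method, not a
bug to tune away.

Clustering: genes DE in at least one contrast are represented by their
z-scored mean log2-CPM profile over the five conditions and k-means
(50 restarts, seeded) splits them into k = 4. Cluster *identity* is
made stable by relabelling the centroids to the nearest canonical
kinetic shape over all 4! assignments, so "cluster 3" means the same
thing in every run. An alternative in the source figure's legend —
clustering the gene–gene correlation matrix — is deliberately not
implemented; profile clustering is the declared scope, and the
correlation variant would only change cluster geometry, not the
downstream enrichment contract.

## 6. Integration readouts

* **Gene density** — genes/Mb with membership by TSS containment
  (start on `+`, end−1 on `-`) in the reduced domain union, against the
  all-genes/genome-length control. TSS containment avoids
  double-counting long genes and is deterministic; a whole-body-overlap
  flag would be an easy extension.
* **Cluster enrichment** — for cluster $c$ and bait $b$:
  (fraction of cluster-$c$ genes with TSS in $b$'s union) /
  (fraction of universe genes with TSS in $b$'s union), universe = all
  expressed genes (clustered + stable): clusters are defined only on
  expressed genes, so the expressed universe is the fair null. Raw
  ratios, log2 ratios and one-sided hypergeometric p-values are all
  emitted — the source figure's colour scale is not defined, so nothing
  is guessed.
* **ChIP dynamics** — bins belong to a domain union when ≥ 50% of the
  bin overlaps it (symmetric and grid-refinement-consistent when
  domains align to bins); the statistic is ΣIP/Σinput over selected
  bins, by default after dividing each track by its library size so
  timepoints of different depths compare. Both normalized and raw modes
  exist because the source figure does not state which it used.

## 7. Numerical and edge-case decisions

* zero reads in scope → all p-values 1 with a warning, never NaN;
* window smaller than the median site spacing → warning (the score
  degenerates toward a per-site test);
* all scores equal → zero positives and a warning (percentiles are
  meaningless on a constant track);
* zero observed positives → FDR reported *not applicable* (NA), never 0;
* empty domain set → gene density NA with a message; enrichment cells
  with an empty denominator → NA; zero input reads in a ChIP selection
  → error naming the timepoint;
* `n_permutations ≥ 10` enforced; permutations, k-means and every
  generator take explicit seeds; the pipeline manifest records md5
  checksums of all artifacts and reruns are checksum-identical.

## 8. Evaluation conventions used by the tests

Planted-domain recovery is domain-level: a planted domain is recovered
when called domains cover ≥ 50% of its span; a called domain is a true
positive when ≥ 50% of it lies in the planted union. Called domains
whose midpoint falls within ±1 Mb of the bait are excluded from the
precision denominator — the viewpoint neighbourhood is genuinely in
contact, and every 4C analysis treats it separately — but still count
toward sensitivity coverage. Cluster recovery (adjusted Rand index) is
computed over the genes planted in clusters 1–4, so it measures the
clustering stage rather than compounding the DE gate's false-positive
rate; both stages also have their own dedicated null tests.

## 9. Known limitations

* The binomial null ignores the distance decay in cis; the percentile
  threshold absorbs this for ranking, but the absolute p-values near
  the bait are not calibrated. A distance-stratified null would
  calibrate them at the cost of a smoothness assumption.
* The FDR gate is per (bait, condition, scope); with many baits a
  further across-bait correction would be needed.
* CPM-based log-FCs are composition-sensitive (see §5); a TMM-style
  normalization would reduce this and could be added without changing
  the decision contract.
* The ChIP arm consumes matched (track, domains) pairs and does not
  model the cross-cell-line caveat of combining 4C and ChIP from
  different lines; that epistemic limitation lives with the user's
  input choice, not in the arithmetic.
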
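---
title: "Base-bias-corrected co-occurrence of intronic motif pairs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Base-bias-corrected co-occurrence of intronic motif pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coocpair)
```

## The problem

During exon definition the spliceosome recognizes a pair of splice
sites *across* an exon, and short intronic splicing elements in the
flanking introns help stabilize that recognition.  If two such
elements act together from the two sides of an exon, the two motifs
should co-occur in the upstream and downstream intronic flanks of the
same exons more often than chance predicts.  Testing this naively
fails, because the GC contents of the two flanks of an exon are
strongly correlated (GC isochores): any pair of motifs of similar
base composition co-occurs "significantly" for purely compositional
reasons.  The base-bias-corrected co-occurrence (BBC-COOC) statistic
implemented here removes that bias by restricting the comparison to
exons of similar GC content on both sides.

## The statistic

Let N exons each carry an upstream and a downstream scanning window.
For an ordered pair of k-mers (U, D), let `n_U` and `n_D` be the
numbers of exons whose upstream (resp. downstream) window contains
the motif at least once — presence is binary per exon and window.

1. **GC grid.**  Exons are ranked into 20 equal-occupancy rows by
   upstream-window GC and, independently, into 20 equal-occupancy
   columns by downstream-window GC (`gc_grid()`).  Ties are broken by
   a stable sort on (GC, exon id) so the grid is deterministic.
2. **Corrected expectation.**  With `q_U[y]` the carrier frequency of
   U in row y, `q_D[x]` that of D in column x, and `K[y,x]` the box
   occupancy, the null expectation of the joint carrier count is
   `k' = sum_{x,y} K[y,x] q_U[y] q_D[x]` (`expected_pair_count()`).
   Conditioning on the stratum removes the compositional correlation.
3. **Margin adjustment.**  The joint count is tested against a
   hypergeometric distribution whose mean is forced to `k'`: keeping
   `n_U`, the downstream margin becomes `n'_D = round(N k' / n_U)`
   (round half to even, clamped to [0, N]; `adjust_margin()`).
   Adjusting the upstream margin, or both (rescaling each by
   `sqrt(N k' / (n_U n_D))`), is available through `adjust=` and
   yields equivalent discoveries on planted-pair simulations.
4. **Exact tails.**  With the observed joint count `k_a`,
   `p_upper = P(K >= k_a)` and `p_lower = P(K <= k_a)` are exact
   hypergeometric tail sums (`pair_pvalue()`); no Poisson or normal
   approximation is used.  If rounding pushed `k_a` outside the
   support, the record is flagged and the offending tail reports the
   point mass at the support end.

`bbcooc()` runs this for all `4^(2k)` ordered pairs (k = 5 by
default: 1,048,576 hypotheses) and thresholds the *enrichment* tail
at `alpha = 1/4^(2k)`, so about one pair passes by chance per scan.
The depletion tail is reported but not thresholded, because the
biological hypothesis — cooperating elements — predicts positive
association only.  Exons whose windows contain ambiguous bases are
dropped from the scan rather than imputed.

Internally the scan encodes every window into rolling k-mer ranks,
builds sparse exon-by-motif presence matrices, and obtains all joint
counts as one sparse cross-product and all expectations as one
20-dimensional bilinear form, so a pentamer scan of 20,000 exons
takes seconds.

## Windows and coordinates

Coordinates are splice-site relative and inclusive: -1 is the intron
base adjacent to the acceptor AG, +1 the first intron base after the
donor GT.  The four default 50-nt windows are Ud = [-100, -51],
Up = [-64, -15], Dp = [+7, +56], Dd = [+51, +100]; upstream windows
end at or before -15 to stay out of the polypyrimidine tract, and
downstream windows start at or after +7 to stay out of the donor
consensus, so motif counts are never confounded by splice-site
signal.  `distance_scan()` slides symmetric window pairs outward at
increasing distances, applying the same border exclusions to the
nearest windows.

## Controls

**GC-balanced shuffle** (`gc_balanced_shuffle()`): window sequences
are permuted uniformly among exons whose windows have exactly the
same integer G+C count (51 possible classes for a 50-nt window —
the strictest reading of "same GC content").  The multiset of window
sequences, all marginal carrier counts, every per-region statistic
and the GC grid itself are preserved exactly; only the cross-flank
joint distribution is destroyed.  Fixed points are allowed, as in
any uniform permutation.  A well-calibrated scan of a shuffled
corpus should report significant pairs at the background rate
(about one).

**Pseudo exons and pseudo splice sites**: decoy exon-like segments
are classified with `is_pseudo_exon()` (length 50-250 nt, acceptor
consensus value >= 75, donor >= 78, >= 100 nt from a real exon,
canonical AG/GT; all thresholds inclusive) and decoy splice sites
are found with `find_pseudo_splice_sites()` (consensus value at
least the authentic site's, >= 100 nt away, anchored on AG/GT).
Consensus values come from position-weight matrices estimated from
the corpus windows (`estimate_pwm()`), scored on the classic 0-100
scale: the acceptor window spans intron -14..-1 plus the first exon
base (15 positions), the donor window the last 3 exon bases plus
intron +1..+6 (9 positions).  These extents are a documented choice:
they are the standard weight-matrix windows consistent with the
consensus-exclusion zones above.  The minimal score `s_min` sums
per-position minima over bases actually observed; a window using a
never-observed base clamps at 0.

## Corpus filtering

`filter_corpus()` applies three rules in order: (1) among
alternative 3' (or 5') splice sites of the same gene within 50 nt,
one exon is kept, chosen by seeded RNG (this needs the optional
splice-site coordinate columns; without them the stage is a recorded
no-op); (2) any two exons similar in *both* windows of the
configured pairing are both purged — similarity is a Jaccard index
of at least 0.8 on 11-mer sets, a deterministic, alignment-free
contract standing in for a pairwise sequence search, computed only
for candidate pairs sharing at least one 11-mer on each side; (3)
exons with window GC below 20% or above 80% (or ambiguous windows)
are removed.  The filter is idempotent and logs every rejection.

## The synthetic corpus

`simulate_corpus()` generates the study conditions the analyses
assume:

* **GC structure.**  A latent isochore value per exon
  (`gc_mean = 0.47`, roughly intronic base composition) plus
  independent per-flank noise (`flank_noise_sd = 0.03`) sets each
  flank's composition; bases are drawn independently with
  `P(G) = P(C) = GC/2`.  `calibrate_isochore_sd()` inverts
  `r = v_iso / (v_iso + v_noise + v_binom)` — including the binomial
  sampling variance of a 50-nt window — so that the measured
  window-GC correlation hits the target, 0.73 by default, the
  empirical flank-GC correlation around human internal exons.  At
  N = 20,000 the achieved correlation is within ±0.05 of target.
* **Splice sites.**  Acceptor/donor windows are sampled from built-in
  consensus frequency matrices softened toward uniform by
  `site_temperature` (default 0.1), with the AG/GT dinucleotides
  forced canonical, and are welded onto the flank/exon ends so that
  corpus records are internally coherent.
* **Planting.**  Each `plant_pair()` spec assigns exons independently
  to joint (`f_both`), upstream-only (`f_u`), downstream-only
  (`f_d`) or no planting, and overwrites the motif at a uniformly
  sampled offset inside its window (a positional bias vector is
  accepted).  Overlapping plants within one window are re-sampled
  and skipped when no free offset exists, so the emitted truth
  ledger always matches the sequences exactly.
* **Determinism.**  All randomness flows from one seed through named
  substreams per component (isochores, each flank, sites, each
  planted pair, orthologs, SNPs, expression), so adding a component
  never perturbs another's stream and equal seeds give byte-identical
  corpora.

What the generator does *not* emulate: dinucleotide structure (no
CpG depletion by default), repeats, length variation of flanks,
phylogenetic structure beyond a single ortholog, and expression
correlation between tissues.  Tests passing on this corpus therefore
show the statistics behave as designed under their own assumptions,
not that real genomes satisfy those assumptions.

**Derivative discoveries.**  Overwrite-planting a pair into a
fraction of exons necessarily makes motifs that straddle a planted
occurrence and its random context co-occur genuinely (they appear
exactly in the jointly planted exons).  Recovery experiments
therefore score discoveries with `attribute_discoveries()`: a
discovery counts as planted-derived when both of its motifs overlap
the planted motifs by at least k-2 exactly matching bases; with a
background rate of order one, the chance of misattributing an
unrelated pair is negligible.  At the reference planting conditions
(`f_both = 0.3`, `f_u = f_d = 0.02`, N = 5,000) recall of the
planted pair is 1.0 and unattributed discoveries average about one
per seed — the background rate.

## Downstream statistics

* **Regional specificity** (`cross_region_pvalues()`): each
  discovered pair is re-evaluated in the other window pairings; a
  comparability flag marks whether the null expected count there is
  within a factor of two of the defining region's, i.e. whether a
  non-significant result reflects absence rather than power loss.
* **Positions** (`positional_distribution()`): occurrence counts per
  window position, numbered from the exon-proximal end.
* **Exon strength** (`gc_matched_partition()`,
  `compare_exon_strength()`): carrier exons are matched 1:1 to
  non-carriers with identical integer G+C counts in both windows
  (greedy within class, seeded), then compared on
  enhancer/silencer hexamer coverage (`motif_coverage()`, interval
  union) and splice-site consensus values.  The group test is a
  two-sided Welch t-test by default (Mann-Whitney on request) — the
  choice is ours; no particular test is canonical for this
  comparison.  `normalize_for_display()` reproduces the
  zero-centered, max-1 display scaling of grouped bar panels.
* **Conservation** (`pairing_conservation()`): a motif is conserved
  when it occurs anywhere in the corresponding window of the
  ortholog flank — presence, not alignment.  The statistic is the
  conditional proportion (partner conserved, given the other side
  conserved), compared between co-occurring pairs and GC-matched
  non-co-occurring control pairs (`select_control_motifs()`: same
  integer G+C count, pairing p-value above 0.05 with the original
  partner, drawn uniformly with a seed).  Controls are k-mers of the
  scan's k — the natural reading, since all scanned motifs share one
  length.  The difference is tested with a plain two-proportion
  z-test (pooled SE, no continuity correction), chosen over
  `prop.test()` to keep the statistic exactly the textbook z.
* **SNP density** (`snp_motif_density()`): occurrences of the pair's
  motifs are classified as paired (partner present in the partner
  window of the same exon) or alone; an occurrence contains a SNP
  when any of its k positions does.  Proportions come with binomial
  SEs and the same z-test.
* **Tissue bias** (`pair_tissue_bias()`): genes are
  tissue-specific where expression exceeds the gene's own
  cross-tissue median by more than two cross-tissue standard
  deviations (per-gene statistics — the natural reading of
  "median expression across all tissues" for a gene; strict
  inequality).  The pair's host-gene tissue fractions are compared
  with 10,000 seeded control draws of non-carrier exons matched on
  the host gene's exon count (nearest count when no exact match);
  empirical p-values use `(count + 1) / (iterations + 1)` so no p is
  reported as zero, at the cost of a conservative floor of
  `1/(iterations + 1)`.  Per-tissue significance cutoff: 0.001.
  `concordance_binomial()` then asks whether an RNA-binding
  protein's expression deviates in the matching direction in the
  significant tissues (above its own median where the pair is
  enriched, below where depleted), via a one-sided binomial test at
  0.5 — the construction is ours, as only the test family is
  conventional.
* **Synergy** (`synergy_index()`): from skipped proportions
  `S = skipped/(included + skipped)`, skipping fitness is
  `W_x = S_x / S_0` and the synergy index
  `SI = W_UD - W_U * W_D`; SI < 0 means the pair suppresses
  skipping more than multiplicatively (synergy), SI > 0
  anti-synergy, and |SI| below a 1e-12 tolerance counts as none.
  `synergy_from_measurements()` computes SI per transfection
  replicate and reports mean ± SEM, so error bars propagate from
  replicates rather than from pooled means.

## Numerical and design notes

* Rounding the adjusted margin uses round-half-to-even; observations
  pushed outside the hypergeometric support by rounding are flagged
  and scored with the support-end point mass.
* A motif absent from every upstream window (`n_U = 0`) admits no
  test; those pairs are recorded with p = 1 and a skip flag.
* Exact discrete tails make the per-test level conservative:
  `P(p <= alpha)` is below alpha, more so at smaller N where the
  tail is coarser.  At N = 20,000 a shuffled-corpus pentamer scan
  averages roughly 0.2-1 significant pairs per scan across corpus
  seeds — of order one, as expected, but systematically at or below
  the nominal one.
* Problem sizes in the test-suite were chosen to exercise each claim
  at the smallest scale where it is statistically unambiguous
  (oracle comparisons at N <= 200 with k <= 3; recovery at N = 5,000
  with k = 5; calibration checks at N = 6,000-20,000).
* The package's interface is the function surface documented here
  (readers/writers for every interchange format, `extract_flanks()`
  for FASTA+BED extraction, `snps_from_vcf()` for VCF positions);
  analyses are composed in R scripts rather than through a shell
  command.

## Limitations

The corrected expectation conditions on 20 GC bins per side;
residual within-bin composition correlation is not removed, though
shuffle controls show it is negligible at these bin counts.  The
similarity purge is a k-mer identity contract, not an aligner:
diverged repeats below 80% 11-mer Jaccard pass it.  The multiple
testing strategy is the fixed `1/4^(2k)` cutoff of the original
design — no FDR machinery is provided, because the discovery
criterion itself is part of the method under study.
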
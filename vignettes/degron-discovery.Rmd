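---
title: "In-silico phosphodegron discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico phosphodegron discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degscan)
```

## The problem

FBXW7 is the substrate-recognition subunit of an SCF E3 ubiquitin ligase. It
binds short phosphorylated peptides — Cdc4 phosphodegrons (CPDs) — in its
substrates and targets them for degradation. By convention the CPD places a
phospho-acceptor (S/T) at position 0, an obligatory proline at +1, and a
phosphorylatable or acidic residue at +4; the two positions FBXW7's WD40
arginines read out are '0' and '+4'. Finding new FBXW7 substrates *in
silico* therefore reduces to: derive a consensus motif from experimentally
validated degrons, scan a canonical proteome for windows satisfying it, and
triage the candidates with orthogonal evidence — known phosphosites at '0'
and '+4', cross-species conservation of the matched window, and pathway-level
overrepresentation of the candidate gene list.

`degscan` implements that workflow end to end, plus a synthetic-data
generator that produces calibrated inputs for every stage, so the whole
pipeline can be exercised and validated without any external database.

## The motif model

A degron catalog is a set of fixed-length windows (length $L$, here 7)
aligned on the phospho-acceptor (column 3). The position-frequency matrix
tallies residues per column; per-column Shannon information content is

$$IC_j = \log_2 20 - H_j, \qquad
H_j = -\sum_a f_{aj} \log_2 f_{aj},$$

optionally with the small-sample bias term $(|A|-1)/(2 \ln 2\, n)$
subtracted and the result floored at 0. A *consensus motif* is an ordered
list of residue classes: per column, the class is the set of residues with
frequency at least `include_threshold` (default 0.2); an empty or
over-large class (more than `max_class` = 4 residues) becomes a wildcard.
Motifs serialize to bracket notation (`"[LP][LP][ST]P..[DEST]"`), and motif
equality is **set equality per column** — the interchange string is
canonicalized alphabetically, so differently-ordered spellings of the same
classes compare equal.

Two design points deserve emphasis:

* The derivation rule (threshold/max-class) is a transparent convention, not
  a fitted quantity. When a published consensus exists, the parsed pattern
  is the reference artifact used downstream; re-derivation from a catalog is
  available for new degron families. The packaged synthetic catalog was
  constructed so its default derivation reproduces the validated CPD
  classes, which makes the two routes mutually checkable.
* The '0'/'+4' column annotation follows CPD convention (the first S/T-only
  class column followed by an invariant proline is '0'; '+4' is four
  positions downstream). Both can be set explicitly for non-CPD motifs.

## Scanning

`scan_protein()` reports **every** window whose substring satisfies all
column classes, overlapping matches included — no suppression rule is
applied, since per-gene match counts are part of the output contract.
Coordinates are 1-based inclusive, the protein-database convention. The
implementation compiles the motif to a zero-width look-ahead regular
expression; its correctness is checked in the test suite against an
independent naive enumerator that tests every window by per-column set
membership.

Ambiguity codes (X, B, Z, U, O) never satisfy an explicit residue class but
do satisfy wildcards: a class is a stated constraint, a wildcard is the
absence of one. Gene-less records aggregate under their protein id with a
warning.

## Conservation scores

No alignment pipeline is built here; conservation is scored on a
user-supplied (or simulated) multiple alignment with two transparent
quantities:

* `motif_retention` — the fraction of non-reference members whose aligned
  window still satisfies every non-wildcard class;
* `column_identity` — per column, the fraction of non-reference members
  matching the reference residue.

Gaps never count as matching, at class columns, wildcard columns or for
identity: an absent residue cannot evidence conservation. The
`highly_conserved` flag in the TSV output uses a reporting threshold of 0.8
retention — a package convention, configurable, not a literature value.

## Count statistics

The overrepresentation p-value is the upper-tail hypergeometric
$P(X \ge k)$ for an overlap of $k$ between an $n$-gene candidate list and a
$K$-gene set in an $N$-gene universe, accumulated in log space from
`lchoose` terms; the suite verifies it against exact rational arithmetic,
`phyper`, and Monte-Carlo sampling. Benjamini–Hochberg q-values are the
step-up minima $q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j$, applied across all
sets tested in one call. The default enrichment universe is all genes of
the scanned proteome, overridable. Fold enrichment is $(k/n)/(K/N)$.

The two-sided Fisher exact p-value uses the minimum-likelihood convention —
the sum over tables with the observed margins whose point probability is at
most the observed one, with a $1+10^{-7}$ relative tolerance on the
comparison — stated explicitly because two-sided conventions differ between
packages. Odds ratios are $(ad)/(bc)$ with an optional Haldane–Anscombe
+0.5 correction applied to all cells when any cell is zero. Reported
percentages round half-up to one decimal, matching the usual printed style
of clinical proportions.

## The synthetic-data generator

The generator defines the conditions under which the pipeline's claims are
tested:

* **Proteomes** are i.i.d. draws from a residue distribution (uniform by
  default), with a chosen number of motif-satisfying windows implanted at
  recorded, well-separated positions (at least one motif length apart).
  Implant sequences are drawn uniformly per column from each class. With
  `clean_background = TRUE`, accidental matches are re-drawn (up to 100
  rounds per protein) and any survivors are masked by forcing a class
  column outside all implants to a non-class residue — so the scan's ground
  truth is exact. The analytic per-window match rate is the product of
  class masses; for the validated CPD on a uniform background,
  $(2/20)^3 (1/20)(4/20) = 10^{-5}$, and the suite checks the empirical
  rate at $10^7$ windows against it within 3 Poisson standard deviations.
* **Ortholog families** mutate each site independently with probability
  `sub_prob` to a uniformly-chosen different residue, optionally exempting
  the degron window; the emitted alignment is gapless (identity) by
  construction. This is deliberately not a realistic evolutionary model —
  no indels, no rate heterogeneity, no phylogenetic structure — it exists
  to give conservation scores a known truth.
* **Gene sets** are uniform draws from the universe, plus one spiked set
  whose candidate overlap is controlled. The default acceptance condition
  uses a universe of 5,000 genes, 250 candidates, 50 sets of 100–400 genes
  and a spiked set of 250 with overlap 62 (about five times the expected
  12.5); over 200 seeds the spiked set must rank first by q-value in at
  least 95% of runs.

What passing these tests shows — and does not show: the scanner, statistics
and scores are correct on data matching their assumptions (i.i.d.
background, exact class membership, identity alignments). Real proteomes
have compositional bias, repeats and disordered regions that inflate or
deflate motif hit rates relative to the uniform-background calibration;
real orthologs have indels and alignment error; and real candidate lists
reflect database release and isoform-selection choices. The published count
of 1,064 candidate FBXW7 substrates depends on a specific proteome release
and merge rule and is therefore not a reproduction target of this package.

## Numerical and degenerate-input choices

* Hypergeometric tails and Fisher enumerations are computed from log
  binomial coefficients with a max-shift log-sum-exp; $k \le 0$ returns 1.
* Uniformity testing of discrete p-values: upper-tail hypergeometric
  p-values are sub-uniform by construction, so the suite applies the
  randomized probability integral transform
  $u = P(X \ge k) - V\,P(X = k)$, $V \sim U(0,1)$, which is exactly
  uniform iff the tail and point masses are correct, before the
  Kolmogorov–Smirnov check.
* An empty catalog, an empty universe, a family with fewer than two
  members, and inconsistent hypergeometric counts are validation errors; a
  matchless proteome is a valid empty result, not an error.
* Scanning a sequence shorter than the motif returns zero matches.
* Generators restore the caller's RNG state; every generator is a pure
  function of its arguments and one integer seed.

## Problem sizes

The test suite exercises the scanner at $10^7$ windows (1,000 proteins of
10,006 residues), the Fisher enumeration over all 635,375 tables with total
at most 60, and enrichment recovery over 200 simulation seeds — sizes at
which every stochastic check has comfortable margin while the whole suite
runs in a few minutes on one CPU.

## Limitations

* Hard-class matching only: no position-specific scoring matrix, log-odds
  or threshold calibration. The published search this workflow mirrors is a
  hard-class match, and the contract keeps it auditable.
* No isoform handling: scan a canonical proteome, or accept per-isoform
  matches.
* Gene-symbol matching is uppercased exact string comparison; alias
  resolution must be supplied externally.
* The conservation module scores a given alignment; building ortholog sets
  and alignments, and phylogenetic weighting, are out of scope.
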
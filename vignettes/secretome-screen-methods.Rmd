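---
title: "Models and methods behind secrescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind secrescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secrescreen)
library(dplyr)
```

`secrescreen` supports a strain-engineering workflow for protein-production
yeasts such as *Komagataella phaffii*: identify the host's secretome, screen
it with a pooled CRISPR-Cas9 knockout library to learn which of those genes
are essential, and hand back a ranked, packaged list of non-essential
knockout targets. This vignette explains each model and algorithm, the
defaults and why they were chosen, and what the packaged simulations do and
do not establish about real data.

## Defining a secretome

Two independent lines of evidence define membership:

* **Prediction** — a signal-peptide probability per protein, parsed from the
  short tab-separated output dialect of SignalP-style predictors
  (`parse_signalp()`). A protein is *predicted* when its Sec/SPI probability
  is **strictly** greater than the threshold (default 0.5). The strict
  inequality matters only for ties at exactly 0.5, which are excluded;
  `predict_secreted()` is monotone in the threshold.
* **Detection** — presence in culture-supernatant proteomics. The relative
  abundance of a protein in a cultivation phase is defined as log10 of the
  total area under the curve summed over replicate cultivations (default 4);
  rows with a zero replicate sum are dropped as undetected
  (`load_abundance()`). Upstream spectral quality filters (search-engine
  score floors, isolation-interference ceilings) are assumed already
  applied; `filter_rows()` offers a generic numeric row filter for inputs
  that still need one.

The secretome is the **union** of the two sets, partitioned into
`predicted_and_detected`, `predicted_only` and `detected_only`
(`define_secretome()`). Detection in *either* cultivation phase counts as
detected; a protein detected in only one phase keeps a missing (not zero)
abundance in the other and is excluded from the cross-phase correlation.
Id reconciliation between prediction and abundance tables is exact string
match, with an optional user-supplied alias map as the only remapping
mechanism — silent fuzzy matching of gene and protein identifiers causes
more harm than it saves.

Cross-phase agreement is summarised by the Pearson correlation of paired
log10 abundances over proteins detected in both phases
(`abundance_correlation()`). The synthetic generator
(`simulate_abundance()`) draws such pairs from a bivariate normal with
correlation parameter `rho`; the packaged default `rho = 0.93` emulates the
high concordance typically seen between glycerol-fed outgrowth and
methanol-fed production supernatants. At the scale of ~134 detected
proteins the sampling error of the correlation is about 0.012, so sample
values between roughly 0.89 and 0.97 are expected.

## Guide design

`design_guides()` scans the 5' portion of each CDS for SpCas9 protospacers:

* **Window** — the first 50% of the CDS by default (`cds_window_frac`).
  Knockouts rely on frameshifts early enough to break the protein; cutting
  in the 3' half too often yields tolerated truncations.
* **PAM** — IUPAC pattern, default `NGG`, searched on both strands of the
  CDS-oriented sequence.
* **Cut site** — the blunt cut is placed 3 nt 5' of the PAM, between spacer
  positions 17 and 18 (the standard SpCas9 convention); `cut_offset` is that
  position in 1-based CDS coordinates. Candidates are ranked 5'-most first.
* **Filters** — spacer GC within [0.2, 0.8]; no `TTTT` run (a Pol III
  terminator in tRNA-driven cassettes); genome-wide uniqueness, defined as
  an exact occurrence count of 1 for the full spacer+PAM sequence across
  both genome strands. No mismatch-tolerant off-target scoring is applied:
  in a compact fungal genome exact spacer+PAM uniqueness is the decisive
  criterion, and activity models trained on mammalian data transfer poorly.

All coordinates are 1-based inclusive throughout the package — the native
convention of GFF3 and of R's string and ranges infrastructure — so there
is no internal/external conversion layer to get wrong.

`emit_oligos()` substitutes each spacer into a cassette template at a
single `{SPACER}` placeholder. The default template is a neutral
Golden-Gate-style flank pair; users of tRNA-based multiplexed cassettes
should supply their own flanks. `assign_multiplex_vectors()` packs selected
targets into delivery vectors greedily in input order with a capacity of 4
targets per vector, giving `ceiling(n / capacity)` vectors — optimal for
disjoint single-target demands. No grouping heuristics (e.g. avoiding
co-lethal combinations) are applied; combination effects are not
predictable from a single-gene screen.

## Quantifying the screen

`count_guides()` avoids alignment entirely: amplicon structure is fixed, so
each read is matched by locating a constant anchor sequence (the cassette
flank immediately 5' of the spacer) and extracting the following 20 nt.
Matching is exact by default; `max_mismatches = 1` uses a precomputed
neighbourhood table in which variants reachable from two different guides
are treated as unmappable. Reads shorter than anchor + spacer are unmapped,
never truncated-matched. Per sample, mapped + unmapped equals reads
processed, always.

Normalisation is counts-per-million with a pseudocount of 0.5:
`norm = (c + 0.5) / (total + 0.5 * n_guides) * 1e6`. Median-ratio
normalisation was deliberately not used: a depletion screen violates its
mostly-unchanged assumption precisely when the screen works. Log2 fold
changes are `log2(post) - log2(pre)` on these normalised values; the
pseudocount keeps them finite and makes a guide absent from both samples
land exactly at 0 when depths match.

## The essentiality score

For gene $g$ with guide LFCs $x_1 \dots x_{n_g}$ and background $y_1 \dots
y_{n_b}$ (all guides of all other genes — leave-one-gene-out, so a strongly
depleted gene does not drag its own background), the one-sided
Kolmogorov–Smirnov depletion statistic is

$$D_g^+ = \sup_x \left[ \hat F_g(x) - \hat F_b(x) \right],$$

evaluated at every pooled data point with right-continuous ECDFs (ties are
handled by construction). The one-sided asymptotic p-value is

$$p_g = \exp\!\left(-2 m D_g^{+2}\right), \qquad
m = \frac{n_g n_b}{n_g + n_b},$$

clamped to $(0, 1]$, and the **essentiality score** is $s_g = 1 - p_g$.
A gene is called *likely essential* when $s_g > 0.5$, strictly. Genes with
fewer than `min_guides = 2` guides (or a background smaller than 2) are
reported unscored. Because $D^+$ depends only on ranks, the score is
invariant under any strictly increasing transformation applied to all LFCs
at once. An exact permutation p-value (`method = "permutation"`) is
available for small libraries where the asymptotic formula is crude; the
scoring interface isolates the p-value definition so variants can be
swapped without touching downstream selection.

**Null behaviour and the 0.5 threshold.** A score defined as one minus a
valid p-value leaves about half of truly non-essential genes above 0.5,
because null p-values are approximately uniform. The exponential form used
here is a conservative (Dvoretzky–Kiefer–Wolfowitz-type) bound, which pulls
that fraction down to roughly 0.4 at six guides per gene, and contamination
of the background by genuinely depleted guides pulls it to roughly a third
in the packaged default simulation. The threshold is therefore a
*high-sensitivity* operating point: on the packaged simulation the score
separates essential from non-essential genes essentially perfectly at the
top of the ranking (sensitivity 1.0), but calling every gene above 0.5
"essential" is deliberately cautious about what it leaves in the
non-essential pool rather than accurate about what it labels essential. A
false-positive rate anywhere near 0.1 at this threshold is not achievable
by any score of the form $1 - p$; users who need a calibrated call rate
should select on the score *ranking* (or on the underlying p-values with a
multiplicity correction), not on the 0.5 cut. Selection for knockout
candidacy uses the complementary strict rule `score < 0.5`, so genes at
exactly 0.5 are neither called essential nor selected.

## Weighted gene-set enrichment

`weighted_gsea()` ranks genes by score (descending, ties broken by gene id
so results are reproducible) and walks the list with a running sum: a set
member at rank $i$ adds $|s_i|^w / \sum_{hits} |s_j|^w$ (default exponent
$w = 1$; $w = 0$ recovers the classic unweighted KS statistic), a non-member
subtracts $1/(N - n_{set})$. The enrichment score is the signed maximal
deviation; when the largest positive and negative deviations tie to within
1e-12 the positive branch wins, a rule chosen so the statistic is stable
under cumulative-sum rounding. The null distribution re-draws the set's
positions uniformly (gene-label permutation, mandatory explicit seed); NES
divides ES by the mean absolute same-sign null ES; the permutation p-value
uses the same-sign null with a +1 correction, so its floor is
$1/(n_{perm}+1)$; q-values are Benjamini–Hochberg across sets. Permutation
counts of 250 (demo) and 1000 (analysis) keep the p floor meaningfully
below 0.05.

## Target selection

`select_targets()` implements the engineering filter: *candidates* are
detected in the supernatant in any phase **and** score strictly below 0.5;
genes with missing scores are never candidates. A curated exclusion table
(id → reason) is subtracted — in a methanol-induced production host this is
where methanol-utilisation genes are removed, since they look dispensable
on glucose plates but are needed during induction. The exclusion list is
user-supplied by design: which genes belong on it is a biological judgment,
not something the screen can decide. Output order is score ascending with
id tie-break, so the safest knockouts come first and reruns are identical.

## The synthetic-data module

The generator produces every input the pipeline consumes, with known ground
truth, under a single seed (`sim_config()`):

* **Genome** — one contig, random sequence at GC 0.41 (a typical fungal
  value), `n_genes` non-overlapping CDSs of 300–1800 nt (multiples of 3)
  separated by 150–400 nt intergenic spacers, random strands. CDSs are
  coordinate spans only: no start/stop codons, introns, or codon usage.
  Guide design does not read frames, so this realism is not needed for what
  the simulations test.
* **Abundances** — bivariate normal log10 pairs at `rho = 0.93` (above).
* **Screen counts** — per-guide baseline means lognormal around
  `nb_mean = 500` with sd 0.5 on the log2 scale (pooled libraries are never
  uniform; this mimics typical cloning skew), negative-binomial noise with
  dispersion 0.1 (variance $\mu + 0.1\mu^2$), and a multiplicative fitness
  factor of $1/8$ on the post-selection mean for the 10% of genes planted
  essential. One pre and one post sample; multi-passage designs can be
  emulated by calling the generator repeatedly with adjusted fitness, but
  the packaged default is the single-passage contrast. No partial
  essentiality is planted by default, though per-gene fitness factors are
  accepted.
* **Reads** — `emit_screen_fastq()` writes anchor+spacer amplicons with
  optional uniform substitution noise; there is no quality-score model, no
  indels, no adapter contamination. The FASTQ round trip tests the counting
  logic, not a sequencer.

The defaults (361 genes, 6 guides per gene, 10% essential, depletion 8,
seed 17) are the packaged reference simulation used by the test suite.
Passing tests on it establishes that the statistics do what they claim
under negative-binomial noise with known truth — not that any particular
real screen meets those noise assumptions; real libraries add guide-
efficiency variation, transformation bottlenecks and chromatin effects
that are out of scope here.

## Determinism and problem sizes

Every stochastic function takes an explicit seed; `run_pipeline()` derives
all stage seeds from one master seed and refuses configs without one.
Reruns of an identical config are byte-identical (the manifest records
seeds, parameters, row counts and MD5 digests, and no timestamps). The test
suite runs the reference 361-gene simulation once, a ~40-gene end-to-end
demo twice (for the byte-identity check), an exhaustive brute-force
verification of the KS statistic over every tie pattern with pooled
$n \le 8$, and 1000 random KS instances — sizes chosen so the whole suite
exercises each claim at meaningful scale while staying quick on a laptop.

## Known limitations

* The score-vs-threshold calibration issue discussed above: 0.5 is a
  sensitivity-first cut, not an error-rate guarantee.
* Exact spacer+PAM uniqueness is the only off-target control; no activity
  or repair-outcome prediction.
* Synthetic lethality between combined knockouts is invisible to a
  one-gene-per-cell screen and is not modelled in packing.
* The simulator emulates summarised per-protein abundances and per-guide
  counts, not raw spectra or raw reads with realistic error profiles.
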
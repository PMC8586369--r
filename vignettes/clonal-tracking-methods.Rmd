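---
title: "Methods: clonal tracking linked to single-cell transcriptomes"
author: "clonotrx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal tracking linked to single-cell transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Patient-derived xenografts (PDX) of B-cell acute lymphoblastic leukemia are
polyclonal: every transduced cell founds a *clone*, marked by a random DNA
barcode inserted in the 3'UTR of a GFP transgene and inherited by all
descendants. Clones differ in where they expand (blood, spleen, bone-marrow
sites, extramedullary organs), in how they fare across serial transplants,
and in how they respond to chemotherapy. clonotrx implements the
computational side of an experiment that measures these behaviors by
amplicon sequencing and then asks which genes are differentially expressed
between clones with different behaviors, using 10x single-cell RNA-seq
linked to clones through long-read "molecular bridges".

# Clonal abundance

Sequencing sees only the within-sample barcode read shares; FACS anchors
them to an absolute scale. For barcode $b$ in a sample:

$$\mathrm{abundance}(b) = 100 \cdot
  \frac{\mathrm{reads}_b}{\mathrm{total\ reads}} \cdot
  \frac{\#\,\mathrm{human}}{\#\,\mathrm{MNC}} \cdot
  \frac{\#\,\mathrm{GFP^+}}{\#\,\mathrm{human}}$$

expressed as % of mononuclear cells (MNC). Barcodes are extracted by exact
matching of both constant flanks (first admissible position, forward strand;
reverse-complement scanning is a flag because amplicon sequencing is
directional). No quality-based filtering and no error correction are applied
by default — exact counting is the procedure; `collapse_barcodes()` offers a
standard Hamming-distance absorption knob (default off) for libraries where
sequencing error is a concern.

Clones with abundance **strictly greater than 0.01%** are retained, per
sample: the same clone may pass in spleen and fail in blood, which is
exactly the situation the tissue-bias analysis quantifies. The boundary is
tested at exactly 0.01%.

# Bridge mapping

A molecular bridge is a cDNA molecule carrying both the droplet cell barcode
and the clonal tracking barcode, consensus-sequenced with long reads. The
mapping rules are deliberately conservative:

* a read links a cell to a clone only if it contains **exact** substring
  matches (zero mismatches) of exactly one whitelisted cell index and
  exactly one whitelisted clone barcode;
* one supporting molecule suffices (`min_support = 1`, configurable);
* cells whose reads name two or more clones are excluded outright
  (multimapped), rather than resolved by majority vote.

Consensus reads have arbitrary strand, so both orientations are scanned and
their hits pooled before the exactly-one rule is applied; an orientation
disagreement therefore discards the read. The cell index is the 16-nt
droplet barcode only — mapping is per cell, so UMIs play no role. The
assigned / multimapped / unmapped sets partition the cell whitelist, an
invariant the tests check. We scan order-free: the architectural order of
index and barcode within the read is not enforced, since the exactly-one
rule already suppresses chimeric reads.

With bridge coverage around 0.2 — the regime this protocol operates in —
roughly 20% of cells with transcriptome data acquire a clone label; the
`validate_mapped_fraction()` study recomputes this number.

# Single-cell preprocessing

Filters run cells-first, then genes, per channel:

* **Cell filter.** Cells with mitochondrial UMI fraction strictly above 10%
  are removed; the fraction is computed on raw counts *before* any gene
  filtering (so a mitochondrial gene that later fails the prevalence filter
  still counts). Mitochondrial genes are identified by the `MT-` symbol
  prefix (human annotation), overridable by an explicit list. Zero-UMI cells
  have an undefined fraction and are removed with a warning.
* **Gene filter.** A gene is kept iff strictly more than 5% of cells have
  strictly more than 2 UMIs. Both boundaries are tested exactly.
* **Normalization.** Expression of gene $i$ in cell $j$ is
  $10{,}000 \cdot c_{ij} / \sum_i c_{ij} + 1$ ("TPM-like + 1"). No log
  transform by default: the defining formula has none, and the downstream
  rank test is invariant to monotone transforms, so a `log2` flag changes
  reported magnitudes only. The denominator sums over **retained** genes —
  removed genes take no part in downstream analyses — with a `"prefilter"`
  option for the alternative reading. After normalization each cell's
  values minus the pseudocount sum to exactly 10,000, a tested invariant.

Channels are filtered independently and merged on the gene intersection,
with cell indexes prefixed by channel id on collision.

# Differential expression with a scramble-based false-positive score

For a clone grouping (e.g. bone-marrow-biased vs blood-biased clones), cells
inherit their clone's group; multimapped and unmapped cells join neither
side. Per gene, a **one-sided Mann–Whitney U test** compares the two cell
sets: midranks for ties; the exact null distribution when
$\min(n_a, n_b) \le 8$ and the gene is untied; otherwise the normal
approximation with tie and continuity corrections. A gene tied across all
cells is degenerate and reported at $p = 0.5$.

Rather than Benjamini–Hochberg, false discovery is controlled empirically:
five scramble datasets are built by permuting clone labels uniformly across
the assigned cells (seeds `seed + 1 … seed + 5`), preserving the label
multiset and the group sizes. For gene $g$:

$$\mathrm{FPS}(g) = \frac{\mathrm{median}_s\,
  |\{g' : p_s(g') \le p_{\mathrm{exp}}(g)\}|}
  {|\{g' : p_{\mathrm{exp}}(g') \le p_{\mathrm{exp}}(g)\}|}$$

with the median of five counts being the 3rd order statistic and the
denominator always at least 1 ($g$ itself; both comparisons are inclusive).
Genes with **FPS < 0.05 and p < 0.05** (both strict) are significant.

Design choices that were genuinely open:

* **Direction handling.** The experiment reports both elevated and reduced
  genes but the test is one-sided; each direction runs as its own family
  with its own scrambles and FPS, preserving one-sidedness while covering
  both outcomes.
* **Scramble granularity.** Cell-level permutation is the default reading
  of "randomly mapping tracking barcode data to gene expression data"; a
  clone-level mode (permuting clone identities, keeping each clone's cell
  block together) is available for sensitivity analysis, since it preserves
  within-clone correlation under a coarser null.

`compute_fps()` is checked for exact equality against a brute-force
double-loop oracle on random instances, including heavily tied p-values.

# Clonal-dynamics statistics

* **Shannon diversity** over detected clones, base 2 (bits). The base is a
  choice — the reference diversity implementations default to base 2 — and
  is configurable.
* **Cross-tissue Pearson correlation** on raw % abundances over the union
  of clones detected in either sample (absent = 0); log-scale correlation by
  flag. Zero-variance samples yield missing entries rather than errors.
* **Tissue bias.** Non-biased clones are assumed equally abundant across
  tissues, so the blood–spleen comparison calibrates pure sampling spread:
  the band is the mean ± 2.576·sd (normal 99% interval) of
  $\log_2((\mathrm{spleen}+f)/(\mathrm{blood}+f))$ over clones detected in
  either anchor, with an empirical-quantile alternative. Each clone's
  target-vs-blood ratio is compared to the band. The pseudo-abundance floor
  $f = 0.001\%$ — a tenth of the detection threshold — keeps ratios finite
  while preserving ordering. Whether the original band was computed on
  ratios, residuals, or abundance bins is not documented; ratios are the
  most direct reading of "clonal abundance variations between blood and
  spleen".
* **Trajectory classification.** k-means with $k = 2$ and fixed seed on
  $\log_{10}(\text{mean abundance} + f)$ per transplant generation
  (abundances span orders of magnitude, hence the log). The cluster whose
  centroid rises most from first to last passage is "expanding". k-means on
  level trajectories is a coarse instrument: it separates cleanly when
  selection dominates the baseline clone-size spread, and the tests
  therefore assert label semantics and enrichment, not per-clone accuracy.
* **Treatment response.** Per-tissue log2 fold differences of mean clonal
  abundance between arms (same floor), and a per-clone two-sided
  Kruskal–Wallis test across arms with Bonferroni correction over the
  clones tested; arms with fewer than two observations skip the clone with
  a warning.

# The synthetic-data generator

Every analysis stage is testable without any download because the generator
emits exactly the formats the pipeline consumes (FASTQ, MTX + TSV, FASTA,
CSV) plus ground truth, all deterministically from one master seed.

What it emulates, and the defaults chosen as realistic for this setting:

* **Clone structure:** 50 clones, lognormal(0, 1) sizes per mouse;
  tissue-tropic clones get a per-tissue multiplier. Sequencing reads are a
  multinomial draw (default 1e5 reads/sample) over flank+barcode+flank
  amplicons with optional per-base substitution errors. A tissue where
  clones expanded holds more cells in absolute terms, so the per-sample
  expansion factor is folded into the GFP FACS fraction rather than
  diluting neutral clones — without this, planted bias would induce
  spurious blood-bias calls in neutral clones, an artifact of forcing
  proportions to sum to one rather than a property of the assay.
* **UMI counts:** negative binomial with lognormal gene weights
  (meanlog = log 2, sdlog = 1 over 500 genes), shared dispersion
  $\theta = 2$ (variance $\mu + \mu^2/\theta$), lognormal library size
  (1,000 nuclear UMIs, sdlog 0.3). Planted DE genes have their mean
  multiplied by the fold change in one clone group; they are assigned the
  upper-quartile expression weight so that recovery measures the test, not
  random prevalence-filter dropout.
* **Mitochondrial fraction:** ordinary cells draw a Beta(2, 60) fraction
  truncated at 6%; planted "dying" cells (5% of cells) draw uniformly from
  15–35%. Mitochondrial counts are Poisson rather than negative binomial so
  the realized fraction concentrates tightly around its target and the
  planted cells — and only they — cross the 10% exclusion boundary.
* **Bridges:** a coverage fraction (default 0.2) of cells emit one correct
  bridge read (half reverse-complemented); a multimap fraction additionally
  emit a read naming a wrong clone, forcing exclusion.
* **Serial transplants:** per-clone lognormal fitness applied
  multiplicatively per passage; truth labels the realized direction of each
  clone's share.

What it does **not** emulate: transcriptome biology (pathways, cell cycle,
doublets), barcode PCR chimeras and jackpot effects, index hopping,
batch/channel effects, or realistic gene–gene correlation. Passing tests
demonstrate that the algorithms recover the statistical structure they
assume, not that the assay is robust to artifacts outside that structure.

# Validation studies and problem sizes

The `validate_*` family freezes the study conditions used by the test suite
and by `scripts/acceptance.R`:

* `validate_null_fdr()`: 100 null datasets (500 genes, 200 mapped cells,
  20 clones split 10/10, no planted difference); the mean count of
  significant genes should stay at or below one.
* `validate_power()`: 50 datasets with 10 genes planted at 2-fold between
  groups of ~125 cells; at least 8 of 10 recovered in at least 80% of runs.
* `validate_tissue_bias()`: 200 cohorts with five 10×-biased clones
  (recall) and 200 fully neutral cohorts (false-call rate of the 99% band,
  expected on the order of a few percent once band-estimation error over 50
  clones is included).
* `validate_roundtrip()`: a noise-free cohort through the entire pipeline;
  extracted counts, cell assignments and planted 8-fold DE calls must match
  generator truth exactly.

These scales keep the whole validation honest but desk-sized; they are the
package's chosen study sizes, stated here so reruns are comparable.

# Known limitations

* Exact flank sequences and barcode length of any particular construct are
  required configuration, not defaults.
* FPS resolution is limited by the scramble count: with 5 scrambles the
  score is a coarse ratio and small changes in `n_scrambles` change its
  granularity.
* The normal-theory tissue-bias band is calibrated for roughly lognormal
  ratio noise; with very few reference clones (< ~10) the empirical
  quantile option is unreliable and the normal band inherits estimation
  error in mean and sd.
* Bridge scanning is exact-substring only; it will not recover reads whose
  barcodes carry sequencing errors, by design.
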
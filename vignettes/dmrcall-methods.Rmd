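---
title: "Methods: binned score-test DMR calling in CG-island methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binned score-test DMR calling in CG-island methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

# Scope and model

`dmrcall` analyzes whole-genome bisulfite sequencing (WGBS) of genomes whose
DNA methylation is sparse and concentrated in discrete CG-methylated
transposable-element (TE) islands — the methylome architecture of diatoms
and several other microeukaryotes. The motivating design is a reference line
(wild type) against two independent knockout lines of a maintenance
methyltransferase, with matched RNA-seq: methylation collapses in the
knockouts, and the question is *where* it is lost and *which* transcripts
respond.

Every quantity derives from per-cytosine counts. For cytosine $i$ in sample
$s$ we observe $m_{is}$ methylated and $u_{is}$ unmethylated read calls
(Bismark-style cytosine reports, one row per cytosine per strand, with its
CG/CHG/CHH context). The **weighted methylation level** of any region $R$ is

$$\hat p_R = \frac{\sum_{i \in R} m_i}{\sum_{i \in R} (m_i + u_i)},$$

i.e. reads are pooled before dividing — low-coverage sites are neither
dropped nor given equal weight. An uncovered region has an *undefined* level
(`NA`), never zero.

## Sequence contexts

Contexts are assigned from the reference sequence on both strands: a
cytosine's context is determined by the next one or two bases read 5'→3' on
its own strand — `CG` if the next base is G, `CHG` if the base after next is
G, otherwise `CHH` (H = A, C, T; `N` counts as H). Minus-strand cytosines
appear as G on the reference and read leftwards with complementation.
Cytosines within 2 bp of a contig end with insufficient downstream sequence
default to `CHH`. All analysis defaults use the CG context only, because
that is where essentially all methylation resides in this architecture.

## Coverage filter

Before any comparison, positions are restricted to those covered by at
least `min_cov` reads (default **5**) in *every* sample of the study. This
single intersection set is reused for all samples and all downstream
summaries, so each sample is quantified over identical cytosines and level
differences cannot arise from coverage composition.

# The DMR caller

The genome is tiled into non-overlapping bins of `bin_width` bp (default
**100**; the final bin of each chromosome keeps its true, shorter length).
Within each bin, retained CG positions are pooled into counts
$(m_1, n_1)$ for the reference and $(m_2, n_2)$ for the treatment sample.

Equality of the two proportions is tested with the pooled two-proportion
**score test**:

$$z = \frac{\hat p_1 - \hat p_2}
      {\sqrt{\hat p (1-\hat p)\left(\tfrac{1}{n_1} + \tfrac{1}{n_2}\right)}},
  \qquad \hat p = \frac{m_1 + m_2}{n_1 + n_2},$$

with a two-sided normal p-value $p = 2\Phi(-|z|)$. Conventions: if the
pooled proportion is 0 or 1 the variance vanishes and there is no evidence
of a difference — we define $z = 0,\ p = 1$ (never `NaN`); a bin with
$n_1 = 0$ or $n_2 = 0$ is untestable (`NA`) and excluded from both numerator
and denominator of all rates. The sign of $z$ follows
$\hat p_1 - \hat p_2$, so hypomethylation in the treatment gives $z > 0$.

A bin is called a DMR when (defaults in bold):

1. $|\hat p_1 - \hat p_2| \ge$ `min_delta` (**0.20**),
2. $p <$ `max_p` (**0.01**),
3. for *hypo* calls, the reference shows at least `min_ref_meth_cpg`
   (**2**) distinct methylated CG cytosines in the bin — a guard against
   single-cytosine artifacts.

The 100-bp bin, 5X three-line coverage floor, Δ ≥ 0.20, p < 0.01 and the
two-methylated-CpG rule are the field-standard operating point for this
assay type and are deliberately the package defaults; every one is an
explicit argument of `call_dmrs()`. Raw p-values are used by default
(`p_adjust = "none"`) because the Δ filter dominates specificity at these
counts; any `p.adjust` method can be requested.

## Consensus across knockouts

`consensus_dmrs()` intersects two DMR sets *by exact bin coordinates* (same
grid, same chromosome, same start/end) and a direction (default `hypo`). It
reports the common set, each side's private calls, and the shared fractions
$|A \cap B|/|A|$ and $|A \cap B|/|B|$. With two independent knockout lines,
the common hypoDMR set is the high-confidence footprint of methylation
loss; `genome_fraction()` expresses it as a percentage of the genome.

# Annotation and chromatin overlap

`interval_overlap()` follows bedtools-intersect semantics (≥ 1 bp shared;
strand ignored). `windowed_overlap()` extends feature coordinates by 0, 500
or 1000 bp (clipped at chromosome bounds) before intersecting — the
regulatory-region analysis: a gene whose *flank* holds the methylation loss
is attributed at the first window that hits it, not at window 0.
`histone_membership()` builds the boolean membership matrix of DMRs against
H3K27me3/H3K9me2/H3K9me3 peak sets and tallies *exclusive* combination
patterns (UpSet semantics: each DMR contributes to exactly one pattern,
including `"none"`), plus per-mark marginals.
`summarize_te_families()` counts hit TEs per family and discards families
with fewer than 3 members, the conventional reporting floor.

Coordinates are `GRanges` (1-based, closed) inside the package; BED and
bedGraph files are converted to/from 0-based half-open form only at I/O.

# Expression integration

Differential-expression tables (DESeq2-style `feature_id`,
`log2FoldChange`, `padj`) are classified per mutant with strict
inequalities: `upregulated` (LFC > 1, FDR < threshold), `downregulated`
(LFC < −1), `stable` (−1 < LFC < 1 *and* significant), else
`not_significant` (including `NA` FDR and |LFC| exactly 1). Consensus sets
intersect the two mutants. The default FDR threshold is **0.01**; 0.05 is a
common alternative operating point for the same assay, so the threshold is
a first-class argument (`fdr_thr`) and is echoed, with every other
parameter and a config hash, in the pipeline report header.

`link_dmr_expression()` crosses the categories with the common hypoDMRs at
each window; `lfc_zscore()` standardizes LFCs over a stated subset (sample
SD, n − 1) and flags z > 2; `compare_te_lengths()` partitions
consensus-upregulated TE features by direct hypoDMR overlap and compares
the two length distributions with a Wilcoxon rank-sum test
(`wilcoxon_rank_sum()`: exact when the pooled sample is ≤ 12 and tie-free,
otherwise normal approximation with midranks, tie-corrected variance and
continuity correction; the rank-sum W of the first sample is reported).

# The synthetic methylome generator

`sim_config()` + `generate_genome()` + `simulate_methylome()` produce a
fully specified study with planted ground truth:

- a random genome (default **2 chromosomes × 500 kb**, GC 0.5) with
  **20** TE islands (2–5 kb), **20** short decoy TEs (200–500 bp,
  unmethylated), nested TE-genes, background genes, and three histone-mark
  peak sets covering 70/85/95% of islands;
- per-cytosine counts: coverage ~ Poisson(**30**), methylated calls ~
  Binomial(coverage, p) with p = **0.80** at island CGs in the reference,
  **0.02** at background CGs, **0.005** at non-CG sites; knockout island
  levels are divided by the depletion factor **4.5**;
- expression tables with planted log2 fold changes (mean 3, SD 0.5,
  observation noise 0.25) for half the island TE-genes and 30% of the decoy
  TE-genes — decoys are upregulated *without* methylation loss, so
  integration must not credit them.

These defaults are the package's standing study conditions: island level
0.80 with depletion 4.5 plants a contrast of $0.8(1 - 1/4.5) \approx 0.62$,
comfortably above the 0.20 calling threshold at 30X, which is what makes
recovery a meaningful correctness check rather than a statistical gamble.
All sampling flows from one master seed through labeled child streams, so
any single artifact can be regenerated independently and two runs with the
same seed are byte-identical.

What the generator deliberately does **not** emulate: bisulfite conversion
failure, mapping bias, PCR duplicates, copy-number variation, partial
(mosaic) methylation within islands, or biological replicate dispersion in
expression — it is a correctness instrument, not a power simulator.

# Pipeline

`run_pipeline()` (or the `inst/scripts/dmrcall-cli.R` command-line wrapper)
chains: simulate/load → contexts → coverage filter → feature methylation
matrix → DMR calling per knockout → consensus → annotation/histone overlap
→ expression integration → (when truth is present) recovery metrics. It
writes BED/TSV/CSV artifacts and a `report.json` whose header embeds the
full configuration and its SHA-256 hash. `validate_config()` accepts YAML
or JSON, fills defaults, and reports *all* problems at once.

# Limitations

- The score test's normal approximation is crude below ~10 pooled reads;
  the coverage filter is what keeps bins in its working range.
- Exact-coordinate consensus is stricter than overlap-based consensus;
  DMRs from different bin grids are rejected rather than fuzzily matched.
- Bin-level calls do not delimit DMR boundaries at cytosine resolution;
  `merge_dmr_bins()` only fuses adjacent called bins.
- The caller tests one treatment against one reference; replicate-aware
  dispersion modeling is out of scope by design.
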
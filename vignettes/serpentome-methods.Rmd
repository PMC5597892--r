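---
title: "Methods: postprandial trend classification and subtractive secretome analysis"
author: "serpentome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: postprandial trend classification and subtractive secretome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpentome)
```

# Scope and data model

`serpentome` analyses a digestive time course in an infrequently feeding
snake: five visceral organs, each sampled fasting, 24 h and 48 h after a
meal, one library per design cell (no biological replicates — a property of
the study design this package mirrors, see *Limitations*). Expression data
live in `SummarizedExperiment` objects: transcript-level fragment counts
with `gene_id`/`length_nt` rowData and the sample sheet as colData, and
gene-level FPKM after aggregation. Proteomic identifications are plain
tables (protein id, annotation, unique-peptide count, emPAI), as a search
engine would export them.

# Quantification

A gene is represented by its longest transcript: the gene length used for
FPKM is the longest member transcript's length, and the gene count is the
sum of member-transcript counts. FPKM is

$$\mathrm{FPKM}_{gs} = \frac{C_{gs}\,10^9}{L_g\,N_s}.$$

`N_s` defaults to the column sum of the gene-level table, which makes the
conservation identity $\sum_g \mathrm{FPKM}_{gs} L_g / 10^9 = 1$ hold
exactly per sample; an explicit totals vector (e.g. aligner-reported
mapped-fragment counts) overrides it. Both modes exist because aligner
totals and column sums differ in general and either may be the right
denominator depending on provenance. Heat-map values are
$\log_2(\mathrm{FPKM} + \varepsilon)$ median-centred per gene;
$\varepsilon = 1$ by default (the transform must be defined at zero; 1 FPKM
is far below every decision threshold used downstream).

# Trend classification

Each gene's triple $(f_0, f_1, f_2)$ — fasting, 24 h, 48 h — is classified
into exactly one of seven classes by three gates, all strict inequalities:

1. *Expressed*: $\max f > 10$ FPKM, else **lowly expressed**.
2. *Differentially expressed*: some pairwise fold change $> 4$, where
   $\mathrm{FC}(a,b) = (\max(a,b) + \varepsilon_{fc}) / (\min(a,b) +
   \varepsilon_{fc})$ with $\varepsilon_{fc} = 0.1$ FPKM. The pseudocount
   defines the ratio at zero; being 1% of the expressed-gene gate it cannot
   manufacture a 4-fold change among expressed genes.
3. Among non-DEGs: **highly** ($\max f > 200$) versus **moderately**
   expressed.

DEGs get a direction. If both consecutive transitions
($f_0\!\to\!f_1$, $f_1\!\to\!f_2$) are individually significant and
opposed, the gene is **up-then-down** (+,−) or **down-then-up** (−,+).
Otherwise the trend is the sign of the largest-magnitude significant
pairwise comparison, ties broken in the fixed order
$(f_0,f_1) > (f_0,f_2) > (f_1,f_2)$. This precedence rule is a design
choice: the class definitions are given by worked examples rather than an
algorithm, and the rule reproduces all of them deterministically. Genes
whose significant comparisons disagree in direction without forming the
consecutive biphasic pattern are flagged `ambiguous` in the output so the
rule's involvement is visible. Note one symmetry property for free: under
time reversal UP and DOWN swap while the biphasic classes are fixed points
(a rise-then-fall profile read backwards is still rise-then-fall).

The strict heat-map DEG selector is deliberately different: FPKM $\ge 400$
in at least one time point *and* FC $\ge 2$ in at least one comparison,
inclusive bounds — the two threshold sets are kept exactly as worded in
their respective procedures rather than harmonised.

Class colours for pathway painting are fixed and injective: red (up), blue
(down), yellow (up-then-down), brown (down-then-up), purple (high), pink
(moderate), dark grey (low). Hex values are package conventions for the
named colours.

# PCA and clustering

PCA treats samples as observations and genes as variables, centred and (by
default) unscaled, matching `prcomp`'s defaults; the variance proportion of
component $k$ is $\sigma_k^2 / \sum \sigma^2$. The high-expression gene
filter (row-max FPKM $> 100$) is applied first. Gene clustering uses
$d = 1 - \rho_s$ (Spearman correlation with average ranks on ties) and
unweighted average linkage; `hclust(method = "average")` provides the
merge sequence, and tests verify its heights against a direct cross-pair
mean oracle. $1 - \rho$ rather than $1 - |\rho|$ is the default because
anticorrelated profiles are biologically opposite trends; the alternative
is one transformation away for users who want it.

# Enrichment

Over-representation of a term carried by $K$ of $N$ reference genes, with
$k$ carriers among $n$ test genes, is the one-sided hypergeometric tail
$p = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$. The test
set stays inside the reference (test-vs-whole-reference); a test-vs-rest
report is available, and its exact one-sided p is identical because both
2×2 tables condition on the same margins. FDR control is Benjamini–Hochberg
step-up (the conventional choice where a procedure is not named; the
downstream threshold in this workflow is q < 0.001). Significant terms are
reduced to the most specific: a term is kept iff no other significant term
is its descendant under the transitive closure of child→parent edges —
the ancestor-removal reading of "most specific", chosen over weighting
schemes for determinism and transparency.

# Subtractive secretome

The chain applies, in order: (1) discard identifications with fewer than 2
unique peptides (single-peptide hits are the conventional noise floor of
search-engine exports); (2) remove proteins whose id occurs in the plasma
table — gastric fluid is collected through blood-contaminated tissue, and
plasma and stomach secretion are assumed disjoint; (3) remove prey
homologs: each prey annotation is reduced to a lowercase base term by
cutting at the first comma and truncating at the first stop token (alpha,
beta, type, chain, isoform, precursor, subunit, numerals, parenthesised
qualifiers) — "Collagen alpha-1(I) chain" becomes "collagen" — and any
remaining annotation containing a base term as substring is removed, with
the matching term recorded as the reason; (4) categorise the remainder by
a keyword map (shipped as editable YAML, because the original curation was
manual and a list of substrings is policy, not algorithm): intracellular
keywords override everything (calpain 9 is a protease but intracellular),
then mucosal > proteolytic > other-hydrolytic > other; unmatched proteins
are conservatively non-secreted.

The whole chain is an S4 `FilterChainReport` whose validity method enforces
the audit identity $|\mathrm{retained}_i| + |\mathrm{removed}_i| =
|\mathrm{retained}_{i-1}|$ with per-protein reasons, so no protein can
silently vanish. Subtraction stages are idempotent by construction.

emPAI is $10^{N_{obs}/N_{obsbl}} - 1$. $N_{obsbl}$ is computed here as the
number of distinct fully tryptic peptides (no missed cleavages, length
6–35) from in-silico digestion — a documented, reproducible proxy for the
search engine's internal observable-peptide count, with configurable
bounds. Protein-vs-transcript agreement is an ordinary least-squares fit of
emPAI on FPKM reporting $R^2 = 1 - SS_{res}/SS_{tot}$; raw values by
default, with a log10 option, since the emPAI scale is already
exponential-compressed.

# Sequence utilities

Read QC applies, in fixed order: adapter removal (exact substring — no
fuzzy matching is attempted because no adapter-alignment algorithm is
specified for this workflow), removal of pairs containing ambiguous bases,
sliding-window trimming (scan 5'→3'; truncate at the start of the first
10-base window with mean Phred quality below 20 — the trim-from-first-
failing-window reading of window trimming, chosen over masking because it
keeps reads contiguous), and a minimum-length drop applied to the pair.
Trimming can only shorten reads.

Tryptic digestion cleaves after K or R except before P; with $m$ allowed
missed cleavages all concatenations of up to $m+1$ consecutive fragments
are produced. The zero-missed peptides concatenate to the input, which the
tests exploit as an exact invariant.

The Tajima-Nei distance over the comparable sites (pairwise deletion of
positions gapped or ambiguous in either sequence) uses mismatch proportion
$p$, pair-averaged base frequencies $g_i$, and unordered mismatch-pair
frequencies $x_{ij}$:

$$h = \sum_{i<j} \frac{x_{ij}^2}{2 g_i g_j},\qquad
  b = \tfrac12\Bigl(1 - \sum_i g_i^2 + \frac{p^2}{h}\Bigr),\qquad
  d = -b \ln(1 - p/b).$$

Identical sequences return $d = 0$ directly (bypassing the $0/0$ in $h$);
$p/b \ge 1$ is reported as saturation rather than silently clamped. In the
symmetric case (equal frequencies, all six mismatch pairs equally used)
$b = 3/4$ and the formula collapses to Jukes–Cantor,
$d = -\tfrac34\ln(1 - \tfrac43 p)$, which the tests verify to $10^{-9}$.
The gastricsin-paralog use case aligns at the amino-acid level but measures
a nucleotide distance; `codonAlign()` back-translates a protein alignment
onto the coding sequences (residue column → codon triplet, gap → `---`),
which is the only self-consistent way to combine the two.

# Synthetic data: what it emulates and what it does not

The generators define the package's test conditions and are themselves
tested code.

* `simulateTrendCounts()` plants, per tissue, equal numbers of genes in all
  seven classes (default 200 per class, i.e. 1400 genes). Base FPKM triples
  keep at least a 1.5× margin to every threshold; multiplicative log-normal
  noise (sd 0.05, clamped at 2.5 sd) therefore cannot flip a class, making
  recovery tests exact rather than statistical. Triples are inverted
  through the FPKM formula at a fixed library size of $10^7$ fragments and
  rounded to integer counts split over 1–3 transcripts of 2000–4000 nt;
  these sizes keep the smallest planted count near 50, bounding
  rounding-induced FPKM error below 1% (asserted at generation time).
  Planted FPKM is recovered through the explicit totals carried in the
  truth object; column-sum totals cannot reproduce a plant exactly since
  the realised sum depends on the whole table.
* `simulateProteinTables()` plants disjoint strata with disjoint annotation
  vocabularies: 235 single-peptide artefacts, 50 plasma contaminants, 150
  prey homologs, 77 intracellular distractors and 37 secreted proteins
  (18/7/4/8 across categories), so the default chain reads
  549 → 314 → 264 → 114 → 37. The split of the 200 subtraction removals
  into 50 plasma + 150 prey is a generator choice; only the endpoints of
  that segment are externally meaningful.
* `simulateAnnotations()` plants one term with a sampling-odds multiplier
  for its carriers in the test set (multiplier 1 = exchangeable null);
  it is used both for null calibration (q < 0.001 hit rate ≤ 0.005 over
  2000 draws) and power (planted term recovered in ≥ 95% of 200 draws at
  multiplier 10, K = 50, n = 100, N = 2000).
* `simulateAlignedSequences()` mutates a uniform random reference at a
  per-site rate and records realised pairwise mismatch fractions as truth.

All generators are pure functions of their seed (the caller's RNG stream is
saved and restored).

What the synthetic data deliberately lacks: biological replicates and
negative-binomial count dispersion (the emulated design has none), isoform-
level expression uncertainty (counts are planted at gene level and split
arbitrarily), peptide-spectrum-match noise, shared-peptide protein
inference, and real annotation-transfer error. Passing the planted-truth
tests therefore demonstrates that the decision rules and arithmetic are
implemented correctly under the stated conditions — not that the thresholds
are optimal for noisy real data.

# Numerical choices and degenerate inputs

* Strict (`>`) versus inclusive (`>=`) thresholds follow each procedure's
  own wording and are not harmonised (see above).
* Spearman correlation of a constant row is undefined; the offending rows
  are named in the error rather than returning NA.
* PCA of a constant matrix, fold changes of negative FPKM, empty gene
  subsets, zero library sizes, saturated distances and cyclic ontology
  edges are all hard errors, not warnings.
* Tables are TSV (UTF-8, `#` comments); reals serialise at 6 decimals,
  integers bit-exactly. Comparisons in tests use tolerances, never text.
* Merge ties in clustering and rank ties in correlation are resolved by
  `hclust`'s canonical smallest-index rule and average ranks respectively,
  for determinism.

# Problem sizes

Default test and acceptance runs use 1400 planted genes per tissue, 549
planted proteins, 2000-gene annotation universes with 20 terms, exhaustive
Fisher verification over all universes up to N = 60, 10 000 random reads,
and 50–100 random matrices for the multivariate oracles. These sizes fully
exercise every decision branch while keeping a complete run in the order of
a minute.

# Interface

The package is a library, in the style of Bioconductor analysis packages:
the exported functions compose the pipeline (`simulate* → readCountTable /
makeCountTable → aggregateToGenes → computeFpkm → classifyTrends /
selectStrictDegs → runPca / averageLinkage → fisherEnrichment /
keggColorExport → runSecretomeChain`), and this vignette plus the README
are the operating manual. `scripts/acceptance.R` is the scripted
end-to-end entry point.

# Limitations

* With one library per design cell there is no dispersion model; "DEG"
  here means a fold-change/threshold rule, not a statistical test with
  error control. The enrichment FDR controls term-level multiplicity, not
  gene-level uncertainty.
* The keyword categoriser is exactly as good as its keyword map; it ships
  as data so users can audit and edit the policy.
* `N_observable` for emPAI is an in-silico proxy; absolute emPAI values are
  comparable within a run, not across search engines.
* The base-term subtraction is intentionally aggressive (substring match);
  like the workflow it models, it may remove genuine secretome members
  that share names with prey proteins.
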
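---
title: "Methods: codon-usage bias indices, diagnostics and optimal codons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-usage bias indices, diagnostics and optimal codons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubkit)
```

## Scope and model

Synonymous codons are not used uniformly. In a transcriptome-scale set of
coding sequences, the usage pattern of each gene reflects a balance of
mutational pressure (which pushes the freely variable third codon position
toward the genome's compositional equilibrium), weak translational
selection (which favours codons matching the abundant tRNAs in highly
expressed genes), and drift. `cubkit` implements the standard battery of
per-gene indices and dataset-level diagnostics used to dissect this
balance in non-model organisms — typically the predicted CDS collection of
a de novo assembled transcriptome, where no curated expression data exist
and the codon adaptation index (CAI) stands in for expression level.

The pipeline is: filter and validate CDS records; compute per-gene indices
(RSCU, ENC, GC1/GC2/GC3/GC3s/GC12, CAI, GRAVY, aromaticity); run the
dataset-level diagnostics (neutrality plot, ENC–GC3s profile, PR2 bias,
correspondence analysis, Spearman correlation battery); and determine
optimal codons from CAI-defined expression extremes.

## Filtering and frame validation

A record is retained only if it is *strictly* longer than 300 nt (the
conventional cutoff against sampling error in short CDSs; configurable),
and, after trimming any incomplete terminal codon and a terminal stop,
contains no in-frame stop codon. Internal-stop records are rejected rather
than truncated: the intended inputs are predicted coding regions, and an
in-frame stop indicates a frameshift or misprediction that truncation
would silently mask. Every rejection is logged with a reason code, so
retained + rejected always reconciles with the input count. Codons
containing `N` are excluded from all counting, in both numerator and
denominator of every index.

## Per-gene indices

**RSCU.** For codon $i$ of an amino acid with $n$ synonyms and observed
family counts $g$, $\mathrm{RSCU}_i = n\, g_i / \sum_j g_j$. Families
absent from a gene have undefined RSCU (reported `NA`, treated as zero
usage by the ordination). Internally RSCU is kept at full precision;
comparisons against printed tables round half-away-from-zero to 2
decimals, matching how such tables are typeset.

**ENC.** Wright's effective number of codons estimates, per gene, the
codon homozygosity $\hat F = (n\sum p_i^2 - 1)/(n-1)$ of each synonymous
family, averages it within each degeneracy class (9 two-fold, 1
three-fold, 5 four-fold, 3 six-fold amino acids), and sums
$\mathrm{ENC} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$.
ENC is 20 when one codon is used per amino acid and 61 under uniform
usage; sampling noise can push the estimator above 61, so values are
capped there. If Ile (the only three-fold amino acid) is unobserved,
$\bar F_3$ is imputed as the mean of $\bar F_2$ and $\bar F_4$ — the
standard handling that keeps short genes comparable; if any other class
mean is undefined or zero, ENC is reported missing rather than guessed.

**Expected ENC.** The mutation-only null curve is
$\mathrm{ENC}_{exp} = 2 + s + 29/(s^2 + (1-s)^2)$ with $s$ the GC3s
fraction. A variant with denominator $s^2 + (1 - s^2)$ circulates in
print; it peaks near 31.5 and is inconsistent with the observable fact
that genes at intermediate GC3s reach ENC near 61, so `cubkit` treats it
as a typesetting corruption of $(1-s)^2$ and uses the standard form.

**GC3 versus GC3s.** These are computed as distinct quantities: GC3 is
the third-position G+C fraction over all sense codons and feeds the
neutrality plot; GC3s restricts to the 59 synonymously variable codons
(Met, Trp, stops excluded) and feeds the ENC curve and the ordination
correlations. Published analyses often use the symbols interchangeably;
keeping both avoids a systematic offset in Met/Trp-rich genes.

**CAI.** Relative adaptiveness is computed from a reference set of
highly expressed genes (classically ribosomal-protein genes):
$w_i = \mathrm{RSCU}_i / \max_{family} \mathrm{RSCU}$, after adding a
pseudocount of 0.5 to codons unobserved in the reference. The
pseudocount choice is ours: it keeps the geometric mean finite without
materially distorting observed ratios (a codon absent from a
10,000-codon reference gets $w \approx 10^{-4}$-scale influence, not
$-\infty$). CAI is the geometric mean of $w$ over the gene's analysis
codons, computed as the exponential of the mean log weight. When no
reference list is supplied, `run_pipeline()` falls back to whole-set
weights (self-referential CAI), which preserves ranking power for the
partition but shrinks the dynamic range; supplying a genuine reference is
always preferable.

**GRAVY and aromaticity** use the Kyte–Doolittle scale and the F/Y/W
fraction respectively, with unknown (`X`) residues excluded.

## Dataset-level diagnostics

The **neutrality plot** regresses GC12 on GC3 by ordinary least squares
and reports a Spearman correlation alongside (rank correlation is the
package's default association measure throughout, because index
distributions are heavy-tailed and monotone-but-nonlinear relations are
common; Pearson users can correlate the exported columns themselves).

The **ENC–GC3s profile** computes per-gene
$(\mathrm{ENC}_{exp} - \mathrm{ENC}_{obs})/\mathrm{ENC}_{exp}$ and bins it
into a left-closed histogram over $[-1, 1)$ with width 0.05, which makes
"the mode lies in 0–0.05" a well-defined statement.

The **PR2 plot** tallies third-position A/T/G/C over the eight four-codon
boxes only (Ala, Arg CGN, Gly, Leu CUN, Pro, Ser UCN, Thr, Val) and plots
$y = A_3/(A_3+T_3)$ against $x = G_3/(G_3+C_3)$ per gene. The axis
assignment follows the conventional "y against x" caption reading; the
two orderings differ only by relabelling. Genes with a zero denominator
are excluded and tallied, not errored.

**Correspondence analysis** operates on the genes × 59 RSCU matrix (not
raw counts, which would confound amino-acid composition), with missing
entries as zero usage. The implementation is the standard chi-square
decomposition: relative-frequency matrix, row/column masses,
standardised residuals, SVD, principal coordinates, inertia fractions.
CA axis signs are arbitrary, so axis 1 is oriented such that its
correlation with gene GC content is negative (GC-rich genes on the
left), giving a stable convention; tests compare coordinates up to sign.
Degenerate inputs (identical rows, rank deficiency) return fewer axes or
zero inertia, never an exception.

**Gene classes** for ordination colouring follow the precedence
ribosomal > hydrophobic > aromatic > other, with GRAVY > 5 and
aromaticity ≥ 0.15 as the default thresholds. The GRAVY default follows
the convention of published transcriptome surveys but exceeds the
maximum attainable Kyte–Doolittle mean (4.5, poly-Ile), so it yields an
empty hydrophobic class; the threshold is configurable (0.5 is a useful
practical value) and the anomaly is deliberate fidelity to convention
rather than an oversight.

## Optimal codons

Genes are ranked by CAI; the top and bottom $\lfloor 0.05 N \rfloor$ (at
least one each, ties broken by id) form the high- and low-expression
pools. For each of the 59 analysis codons a 2×2 Pearson chi-square
without continuity correction compares codon-versus-rest-of-family counts
between pools — the family-conditional contingency table implied by
comparing per-family RSCU. A codon is optimal iff $p < 0.01$ and its
RSCU is higher in the high pool. No multiple-testing correction is
applied by default (the conventional rule in this literature is a raw
p cutoff); a Bonferroni flag exists for conservative use. There is no
requirement that the high-pool RSCU exceed 1: a codon can be
significantly enriched among highly expressed genes while still below
parity in its family.

Two caveats belong with this procedure. First, with pool sizes in the
thousands of codons, 59 raw-α tests essentially guarantee occasional
false flags under a true null (expected ≈ 0.3 per dataset at α = 0.01).
Second, and more importantly, CAI-defined extremes are *compositional*
extremes whenever mutational bias varies across genes: the high-CAI tail
is enriched for genes whose GC3 matches the reference bias, so the
high/low pools differ genuinely in codon usage even with no translational
selection, and the chi-square dutifully flags G/C-ending codons. The
simulator (below) reproduces this confound on demand, and users should
read genome-wide optimal-codon lists with it in mind.

## The synthetic CDS generator

`simulate_cds_set()` generates gene sets under an explicit
mutation–selection model so every stage is testable without external
data. Per gene: interior length uniform on 110–400 codons (keeping every
record above the 300 nt filter, in the length range typical of predicted
transcriptome CDSs); a mutational GC3 target $t \sim \mathrm{Beta}(2.2,
1.9)$ (mean 0.54, wide spread — the regime of a slightly GC-biased
transcriptome whose genes span almost the whole GC3 range); an
expression level $e \sim \mathrm{Beta}(1.5, 5.3)$ (right-skewed, mean
0.22, matching CAI-like distributions), or a bimodal 0.05/0.95 mixture
for sharp two-class designs. Amino acids are i.i.d. uniform by default.
Within each family, codon weights are the product of a mutational term
(odds $t/(1-t)$ for G/C-ending versus A/T-ending third bases, G and C
equiprobable) and a selection bonus $e^{s_{sel} \cdot e}$ on the family's
designated preferred codon (default: the first C-ending codon, else
G-ending — the direction seen in most invertebrate optimal-codon sets).
A start codon is prepended, a random stop appended. The top 5% of genes
by expression are emitted as the "ribosomal" reference list. All
randomness flows from one integer seed; a fixed seed yields
byte-identical FASTA output.

What the generator does *not* emulate: amino-acid composition differences
between genes (so GC12 variation is minimal and simulated neutrality
slopes are near 0, not the intermediate slopes of real data),
assembly artifacts, sequencing error, isoforms, codon-pair effects, and
expression–length coupling (off by default). Passing tests on simulated
data therefore demonstrate correctness of the estimators and the
qualitative signatures (low-ENC outliers under selection, CAI–ENC
negative correlation, GC-driven axis 1), not realism of any particular
organism's transcriptome.

## Numerical choices and test design

Problem sizes in the test suite are chosen for desk-scale runs: oracle
equivalence uses 200 random small count tables per estimator, simulation
checks use 100–200 genes, and the end-to-end optimal-codon recovery uses
1,000 genes with 20 replicates for the null arm — about a minute in
total. Brute-force oracles (explicit family enumeration for ENC,
per-occurrence log weights for CAI, `MASS::corresp` for CA, independent
genetic-code tables from Biostrings) are kept structurally independent of
the implementation. Printed-table fixtures ship as plain TSV under
`inst/extdata/` and are exercised at full precision: recomputing RSCU
from the shipped counts reproduces every printed 2-decimal value in the
targeted families, and the published high/low pools yield the expected
optimal-codon directions (UUC flagged; UUU and UUA not).

Ties in the CAI partition break lexicographically by id; histogram bins
are left-closed; rounding for table comparison is half-away-from-zero;
ENC above 61 is capped; CA singular values below $10^{-10}$ of the
leading one are treated as zero inertia.
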
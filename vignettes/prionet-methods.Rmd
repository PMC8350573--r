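---
title: "prionet: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{prionet: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prionet)
```

# Overview

`prionet` implements a prionome analysis pipeline for plant genomes:
it detects prion-like domains (PrLDs) in proteomes by compositional
log-likelihood scoring, summarizes the resulting prionome, builds a
signed co-expression network from a diurnal expression time series,
filters candidate regulatory edges by promoter *cis*-binding evidence,
assembles a three-layer gene regulatory network (GRN), and extracts
dense clusters with an MCODE-style algorithm. Every input the pipeline
consumes can be produced by deterministic synthetic generators with
ground-truth tables, so the whole chain is testable offline.

This vignette explains the models behind each stage, the tunable
parameters and their defaults, the numerical choices, and the known
limitations — in particular what passing tests on synthetic data do
and do not establish about real data.

# Prion-like domain detection

## The compositional model

Prion-forming domains in yeast are strongly enriched in glutamine (Q)
and asparagine (N). The scanner scores each residue $a$ by a
log-likelihood ratio in bits,

$$\mathrm{llr}(a) = \log_2 \frac{f_{\mathrm{fg}}(a)}{f_{\mathrm{bg}}(a)},$$

where $f_{\mathrm{fg}}$ is a prion-domain foreground composition and
$f_{\mathrm{bg}}$ a blended background

$$f_{\mathrm{bg}} = \frac{\alpha}{100}\, f_{\mathrm{species}} +
\Bigl(1 - \frac{\alpha}{100}\Bigr)\, f_{\mathrm{default}}.$$

The **COREscore** of a protein is the maximum sum of residue scores
over any contiguous window of exactly $L_{\mathrm{core}}$ residues.
Proteins scoring at or above the calling threshold are reported as
prion-like proteins (PrLPs). This sliding-window formulation
reproduces the ranking behaviour of HMM-based prion scanners on
Q/N-rich domains while being exactly specifiable and cheap to verify
against brute-force window enumeration; a full HMM parse is out of
scope.

Parameters and defaults:

| parameter | default | meaning |
|---|---|---|
| `l_core` | 60 residues | core window length |
| `alpha` | 50 (%) | species-vs-default background blend |
| `threshold` | 25 bits | COREscore calling cutoff, compared with `>=` |

The packaged composition tables (`aa_composition()`) are a Q/N-rich
yeast-prion-domain foreground, a yeast-style default background, and
an Arabidopsis-style species background; all are normalized to sum to
one over the 20 canonical amino acids and can be overridden per call.
Ambiguity codes (B, Z, J, X, U, O, `*`) contribute 0 bits and are
excluded from frequency estimation, so unknown residues never create
or destroy a hit by themselves.

Numerical choices: window sums are computed from a cumulative sum; the
best window is the *leftmost* maximum, with a `1e-9` tolerance so that
windows whose sums are analytically tied (identical residue multisets)
are not separated by floating-point accumulation order. Sequences
shorter than `l_core` are unscorable and recorded as such rather than
raising an error mid-scan.

Domain boundaries around the scored core are the maximal-scoring
contiguous segment containing the core window. Because the left and
right extensions contribute independently, the optimum is the core
plus the best-scoring left suffix and right prefix, each included only
when its sum is strictly positive; this closed form equals exhaustive
search over all containing segments.

# Prionome summaries

Density is `n_prlps / proteome_size`, reported to four decimals in
tables. Functional categories come from an ordered, case-insensitive
keyword rule list (`default_category_rules()`); the first matching
rule wins and unmatched entries are `"unclassified"`. The rules are
illustrative keyword heuristics — real annotation pipelines assign
categories with richer evidence — and are fully configurable. Isoforms
collapse to gene level keeping the top COREscore, so summaries exist
at both protein and gene counting levels. Percentages are exact
internally; only the display column is rounded to whole percent.

# Co-expression network

Expression rows are min–max scaled to $[0,1]$ (constant rows map to
zeros — an explicit decision, as the transform is otherwise
undefined). For every gene pair both Pearson and Spearman correlations
are computed over the $n$ samples, each with the two-sided
$t$-approximation p-value $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$
degrees of freedom (the approximation Hmisc's `rcorr` uses, adequate
at the 48-sample scale of a diurnal series; it is not exact for
Spearman at very small $n$). An edge is called when **both** methods
pass $|r| \ge 0.8$ and $p < 0.01$ and the signs agree — the
conservative AND reading of a dual-method filter; an OR mode and an
optional Benjamini–Hochberg adjustment are available by flag, with raw
p-values the default to mirror a plain $p < 0.01$ filter. Genes with
zero variance are excluded with a warning, since their correlations
are undefined.

Correlogram ordering uses the loading on the first eigenvector of the
Pearson correlation matrix, with the sign fixed so the first gene in
input order has a non-negative loading. Cluster structure is read out
by average-linkage hierarchical clustering on the distance $1 - r$ cut
at $k = 2$; the antagonism flag is raised when more than half of the
nonzero inter-cluster entries of the binary signed matrix are
negative — the signature of two mutually antagonistic diurnal modules
(e.g. morning- vs evening-phased gene sets).

# Promoters and binding evidence

Promoters cover 1,500 bp upstream plus 200 bp downstream of the
transcription start site (TSS), 1,700 bp for genes interior to their
contig. The TSS is taken from the longest mRNA of the gene (ties by
feature id; genes without mRNA children fall back to the gene
feature). The TSS base itself is counted as the first base of the
downstream segment — the upstream/downstream wording leaves this
inclusion ambiguous, so the convention is a package decision.
Coordinates are 0-based half-open internally and converted at the
GFF3 boundary; minus-strand promoters are reverse-complemented so
sequences always read 5'→3' toward the gene. Truncation at contig
edges is flagged rather than fatal.

Binding evidence either comes from a database export (TF id → target
gene id) or from scanning promoters with a position weight matrix.
Count PWMs are converted to log2-odds with a pseudocount of 0.25
against a uniform base background; both orientations are scanned and
windows containing `N` are skipped. The edge filter then retains a
TF-source edge only when that (TF, target) pair has evidence, flagging
it `evidence_filtered`; edges whose source is not a TF pass unchanged,
because binding evidence constrains only TF-binding claims. The filter
is idempotent and never adds edges.

# GRN assembly and clustering

The network is assembled in three layers: (1) co-expression among
PrLPs, (2) PrLP–TF co-expression, (3) stress- and memory-related genes
correlated with the prionome. Edges are undirected co-expression
pairs; a duplicated pair keeps the lowest layer. The stored
source/target orientation is metadata used by the binding filter (TF
end as source). Hubs are the top 5% of nodes by degree with boundary
ties included (so a regular graph is all hubs) — degree is the one
hub statistic that needs no further modelling assumptions, and the
fraction is configurable. SIF export writes
`source TAB relation TAB target` with relation `pos`/`neg`; node roles
and degrees go to a sidecar TSV because SIF carries no attributes.

## MCODE

Clustering follows the published MCODE algorithm. The weight of a
vertex $v$ is $k_{\max} \cdot d$, where $k_{\max}$ is the maximal core
number of the subgraph induced by $v$'s closed neighborhood ($v$ plus
its neighbors) and $d$ is the density of that highest $k$-core.
Scoring the *core* rather than the whole neighborhood makes the weight
robust to low-degree bystander neighbors, and including $v$ itself
keeps the weights of a dense module's members homogeneous — both are
needed for dense modules to be recovered as units. Complexes are
seeded from the highest-weighted unvisited vertex and grown
breadth-first, admitting vertices with weight at least
`seed_weight * (1 - vwp)`; each vertex belongs to at most one complex.
The haircut removes members with fewer than two intra-complex
neighbors in a single pass (a complex losing its seed is discarded),
and complexes are ranked by density × size. Defaults are the canonical
published ones: degree cutoff 2, vwp 0.2, haircut on, fluff off. All
tie-breaking is lexicographic by node id, so two runs on the same
graph are identical.

One consequence of seed-relative expansion is worth stating plainly:
two equally dense structures connected by even a single edge between
equal-weight vertices will merge into one complex (the two endpoints
of the bridge are exchanged by a graph automorphism and therefore
carry identical weights, so neither can be admitted without the
other). Separating such twins would require information the weight
function does not carry. The planted-module generator used in testing
therefore embeds its modules in a sparse background rather than wiring
them to each other directly — the intended analogue of distinct
molecular complexes touching only through background interactions.

# Synthetic data

The generators are pure functions of their arguments and a seed, and
each returns a ground-truth table consistent with the emitted files
(`check_truth()` validates this).

* **Proteomes** — background residues drawn i.i.d. from a proteome
  composition; planted proteins carry an 80-residue segment drawn from
  the prion-domain foreground at a random interior offset. 80 residues
  comfortably exceeds the 60-residue core window, so a planted domain
  should always contain a scoring core.
* **Diurnal matrices** — 48 samples spanning one 24 h cycle at 30 min
  resolution. Module genes are phase-shifted sinusoids plus Gaussian
  noise on a baseline of 10 (keeping values TPM-like and positive);
  noise genes are independent Gaussians. The intra-module correlation
  target is set through the noise level,
  $r = (A^2/2) / (A^2/2 + \sigma^2)$ (`expected_intra_r()`,
  `noise_sd_for_r()`), and the cross-module correlation through the
  phase offset, attenuated by $\cos\Delta\phi$. The default study
  conditions plant two 15-gene modules at intra-module $r = 0.95$ with
  a phase offset of $\arccos(-0.9/0.95)$, i.e. a cross-module target
  of $-0.9$, among 36 noise genes.
* **Genomes** — genes on one chromosome, alternating strands, 4 kb
  between gene starts (≥ 2 kb of intergenic space); motif consensus
  planted at a random promoter-oriented offset inside the
  [−1500, +200) window of each chosen target, reverse-complemented as
  needed on minus-strand genes.
* **Role tables** — independent draws per role (TF, Ts/RTR, stress,
  memory); sizes below one are fractions of the pool, one or more are
  exact counts. Defaults in the bundled pipeline mirror the scale of a
  rice prionome slice: 66 expression genes of which 12 are TFs and 5
  are Ts/RTRs.

What the generators do **not** emulate: real codon/isoform structure,
autocorrelated measurement noise, batch effects, unequal time spacing,
non-sinusoidal circadian waveforms, and annotation errors. Passing the
planted-truth tests therefore demonstrates that the algorithms recover
the structures they model under clean conditions at realistic sizes —
not that those structures are recoverable from any particular real
dataset.

# Problem sizes used in validation

The shipped tests and the acceptance script run at deliberately modest
scales chosen to exercise every code path: 1,000 random sequences (60
to 500 aa) against brute-force window enumeration; 20 replicates of a
500-protein proteome with 10% planted domains for
sensitivity/false-positive rates; 50 replicates of the 66-gene × 48-
sample diurnal design for edge precision/recall; 20-gene genomes for
promoter geometry and binding-filter checks; 50 replicates of the
5-module planted graph (module size 8, intra-edge probability 0.9,
40 background nodes at 0.05) for MCODE recovery; and two full pipeline
runs compared byte-for-byte for determinism.

# Known limitations

* The scanner is compositional; it will score any Q/N-rich window,
  including compositionally biased non-prion regions — mirroring the
  behaviour (and caveats) of composition-based prion prediction
  generally.
* Spearman p-values use the $t$ approximation throughout; for
  $n < \sim 10$ an exact permutation test would be preferable.
* The category rules are keyword heuristics, not an annotation
  pipeline.
* MCODE cannot split equally dense structures joined by
  equal-weight bridges (see above); overlapping complexes (fluff) are
  not implemented.
* The binding-evidence scan assumes a single PWM per TF and
  independence between positions.
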
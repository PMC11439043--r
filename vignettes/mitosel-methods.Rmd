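---
title: "Models and methods in mitosel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mitosel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosel)
```

mitosel implements the inference chain used to argue for episodic positive
selection in mitochondrial OXPHOS genes of nematodes: branch-site codon-model
likelihood ratio tests, a scanner for clade-fixed derived nonsynonymous
substitutions (FdNs), chemical-change classification, projection of
substituted residues onto a cytochrome c oxidase structure with
proton-channel proximity classes, and the derived metrics of extracellular
flux (oxygen consumption rate, OCR) assays. This vignette explains the
models, the defaults, and the choices made where the design was open.

## The codon substitution model

Substitution between the 62 sense codons of the invertebrate mitochondrial
code (NCBI table 5; ATA = Met, AGA/AGG = Ser, TGA = Trp, stops TAA/TAG) is
modelled with the Goldman–Yang (GY94) parameterisation. The instantaneous
rate from codon $i$ to $j$ is nonzero only for single-nucleotide changes:

$$q_{ij} = \pi_j \times \begin{cases}
1 & \text{synonymous transversion}\\
\kappa & \text{synonymous transition}\\
\omega & \text{nonsynonymous transversion}\\
\omega\kappa & \text{nonsynonymous transition,}
\end{cases}$$

where $\pi$ are equilibrium codon frequencies, $\kappa \ge 0$ the
transition/transversion rate ratio and $\omega = d_N/d_S$. The generator is
reversible ($\pi_i q_{ij} = \pi_j q_{ji}$), so transition matrices
$P(t) = e^{Qt}$ are computed by a symmetrized eigendecomposition, which is
both fast and numerically stable; the test suite cross-checks it against
scaling-and-squaring.

Codon frequencies default to the F3x4 scheme (position-specific nucleotide
frequencies estimated from the alignment, products renormalised over sense
codons), with F1x4 and F61 available. F3x4 is the conventional default for
branch-site analyses and is essential for AT-rich mitochondrial data, where
uniform frequencies would badly misfit the composition.

## Branch-site Model A and the likelihood ratio test

`fit_branch_site()` fits the four-class branch-site mixture on a tree with
one marked foreground branch (the `#1` Newick convention, or
`mark_foreground()`):

| class | proportion | background $\omega$ | foreground $\omega$ |
|-------|------------|--------------------|---------------------|
| 0     | $p_0$      | $\omega_0 < 1$     | $\omega_0$          |
| 1     | $p_1$      | 1                  | 1                   |
| 2a    | $p_2\,p_0/(p_0+p_1)$ | $\omega_0$ | $\omega_2$      |
| 2b    | $p_2\,p_1/(p_0+p_1)$ | 1          | $\omega_2$      |

The per-site likelihood is the prior-weighted mixture of class-conditional
pruning likelihoods (Felsenstein's algorithm, implemented in C++ with
per-node rescaling so the result is exact to better than $10^{-8}$ relative
regardless of the scaling path). All generators share $\kappa$ and $\pi$ and
are scaled jointly by the class-weighted background rate, so branch lengths
are expected substitutions per codon site on background branches.

The alternative model estimates $\omega_2 \ge 1$; the null fixes
$\omega_2 = 1$. `lrt()` (or `anova()` on two fits) forms
$2\Delta\ell = 2(\ell_\text{alt} - \ell_\text{null})$ and refers it to
$\chi^2$ with **two** degrees of freedom by default, with critical values
5.991 (5%) and 9.210 (1%) and Bonferroni correction
$p_\text{adj} = \min(1, p \cdot n_\text{tests})$ over the branches tested.
The two-degree reference is deliberately the one used in the analyses this
package reproduces; the canonical branch-site test instead refers the
statistic to a 50:50 mixture of a point mass at zero and $\chi^2_1$, which
is available via `df = 1, mixture = TRUE`. The df = 2 reference is
conservative for this null, and the package's null-calibration check
(200 parametric simulations) verifies that the raw rejection rate at 0.05
stays at or below nominal plus binomial slack.

Optimisation is bounded L-BFGS-B on transformed parameters ($\log\kappa$,
$\log\omega_0$, $\log\omega_2$ bounded below at $\log 1$, a softmax for the
proportions, log branch lengths; bounds $\kappa\in[0.01,100]$,
$\omega_0\in[10^{-4},0.999]$, $\omega_2\in[1,999]$, branch lengths
$[10^{-6},12]$) from deterministic multi-starts: a warm start from a
single-$\omega$ (M0) pre-fit, a selection-regime start with large
$\omega_2$, and a broad start; extra seeded jitter starts are available.
Branch lengths are re-optimised under each model. `branch_site_test()` fits
the null first and warm-starts the alternative from it; because the null
optimum is a feasible point of the alternative, the fitted alternative is
floored at the null optimum, which guarantees a non-negative statistic (and
makes borderline under-optimisation conservative rather than
anti-conservative).

Ambiguous codons (IUPAC) are marginalised at the tips — the tip partial
likelihood is 1 on every compatible sense codon; gap columns must be excised
before fitting (`excise_gaps()` removes whole gap-containing codon columns,
preserving frame and order, and terminal stop columns are stripped on read
with a log message).

`neb_sites()` computes Naive Empirical Bayes posteriors at the fitted
parameters — posterior of class $k$ at a site proportional to
$p_k L_k(\text{site})$ — and reports sites whose combined class 2a + 2b
posterior reaches 0.95.

`pairwise_rates()` estimates $d_N$ and $d_S$ for two sequences either by
maximising the two-sequence codon likelihood over $(t, \kappa, \omega)$ and
decomposing the flux into synonymous/nonsynonymous components relative to
the neutral opportunity, or by the Nei–Gojobori (1986) counting method with
pathway averaging and Jukes–Cantor correction; the two routes cross-check
each other in the test suite.

## FdNs scanning and ancestral states

A fixed derived nonsynonymous substitution (FdNs) for a clade is a codon
site at which every clade member shares an amino acid that differs from the
clade's ancestral state. `detect_fdns()` operationalises this as:

1. every foreground taxon carries the same amino acid $a_f$ (gaps or
   ambiguity in the foreground disqualify the column; outgroup gaps are
   tolerated while at least two informative outgroups remain);
2. the ancestral state, reconstructed from the outgroups, differs from
   $a_f$.

Ancestral states come from Fitch parsimony evaluated on the outgroup subtree
rooted at the clade's attachment node. Ties are broken by the Fitch set of
the phylogenetically nearest outgroup lineage (the attachment-node subtree
containing the outgroup taxon at minimal patristic distance from the
clade), then by the state of the nearest taxon inside that lineage; columns
still tied are reported as ambiguous and skipped (listed in an attribute).
This formalises what is usually done by manual inspection of alignments and,
on the packaged substitution table, resolves every column — including one
deep-homoplasy column whose ancestor is ambiguous under plain Fitch.

Deliberately, a derived state may reappear in a distant outgroup
(homoplasy): the definition is "derived relative to the ancestor", not
"absent from all outgroups". The stricter rule is available as
`strict_outgroup_absence = TRUE`. Each record carries a single-nucleotide
attributability flag (some observed outgroup codon encoding the ancestor is
one nucleotide from some foreground codon), a synonymous-variation flag
(foreground codons differ while encoding the same amino acid), the chemical
classes of both states and a polarity-crossing flag, and site numbers in up
to two taxon coordinate systems (e.g. a structural template species and the
study species). The chemical partition is fixed: nonpolar
{G A V L I P F M W}, polar {S T C Y N Q}, positive {K R H}, negative {D E};
"crossing" means exactly one side is nonpolar. Severity grades
(high/medium/low) printed in published tables have no stated rule and are
not reproduced; the class pair and crossing flag are.

The packaged reference table (`cox_substitution_patterns()`) and ten-taxon
tree reproduce the published 20-substitution set: 18 in COX1 (8 on the
Tylenchina branch D, 9 on the Panagrolaimidae branch C, 1 on the
Halicephalobus branch B), one each in COX2 and COX3, with 4 of 8 branch-D
COX1 substitutions polarity-crossing. Because the table records amino-acid
states, `back_translate_aa()` encodes each state with a fixed canonical
codon; codon-level flags of that reconstruction reflect the canonical
encoding, not the original nucleotides.

## Structural projection

`read_structure()` parses PDB coordinate records (first model,
highest-occupancy alternate locations, heavy atoms only — bio3d does the
parsing). Residue numbering is transferred between species with a global
Needleman–Wunsch alignment (BLOSUM62, affine gaps, gap opening 10 /
extension 0.5, all logged) inducing a strictly increasing injective map;
`map_residue_coordinates()` returns the partner position or `NA` at gaps.

`min_channel_distance()` measures the minimum over all heavy-atom pairs
between a residue and an annotated channel residue set — not
C$\alpha$–C$\alpha$ and not centroids, because the 4 Å contact threshold is
only meaningful at atomic resolution. `classify_proximity()` assigns
`within4` at $\le 4$ Å, `within13` at $\le 13$ Å (both inclusive, so
boundary behaviour is testable) and `distal` otherwise; thresholds are
configurable. Channel annotations (H- and K-pathway residues of cytochrome
c oxidase) are user-supplied TSVs in a declared numbering frame; the
packaged `synthetic_channels.tsv` is a small synthetic example, not the
published residue list, which the source literature does not reprint.
Distances are measured to annotated residues only; pathway waters are not
modelled. `superpose_rmsd()` implements Kabsch least-squares superposition
with reflections disallowed.

## OCR metrics

An `ocr_plate()` holds a 32-cycle flux run: 8 untreated cycles, injection 1
(FCCP at 40 µM, or the 1% DMSO vehicle control) before cycle 9, injection 2
(25 mM sodium azide, a complex IV inhibitor whose residual signal is the
non-mitochondrial oxygen consumption) before cycle 29. `normalize_ocr()`
subtracts the mean background-well trace per cycle and divides by worm
count (subtraction first, then per-worm scaling — the order is logged
because published methods do not state it). `derive_ocr_metrics()` then
computes, on window means of the normalised traces:

* basal = DMSO window mean − azide mean,
* maximal = FCCP window mean − azide mean,
* spare = FCCP window mean − DMSO window mean,

with the azide mean pooled over all sample wells across the azide window
(default: every cycle from injection 2 to the end, i.e. the 4 final cycles),
so spare = maximal − basal holds as an algebraic identity on every plate.
Window presets: cycles 10–13 for *H. mephisto* (whose FCCP response peaks
and decays quickly) and 13–16 for *C. elegans*; the untreated baseline is
cycles 5–8. Negative metrics are reported with a warning, never clipped —
clipping would hide assay failure. `fold_change()` guards division by zero.

## Simulators and what passing tests mean

Every input class has a generator with known ground truth:
`simulate_codon_alignment()` (the same generator and scaling as inference;
root codons from $\pi$, per-branch sampling from $e^{Qt}$, true site classes
returned), `plant_fdns()` (clade-fixed substitutions with optional
synonymous scatter), `toy_structure()` (helix or seeded coil with a channel
set and exhaustively computed true distances) and `simulate_ocr_plate()`
(plateau phases plus Gaussian noise). All take a mandatory seed and are
byte-deterministic given seed and configuration, without disturbing the
caller's RNG stream.

The synthetic data emulate the relevant structure of the real inputs —
site-class mixtures on a marked tree, clade-fixed columns over a
Tylenchina-like topology (two distant outgroups plus nested B/C/D clades),
injection-response plateaus — but not alignment error, indels, selection
regimes varying among background branches, codon usage beyond F3x4, or
instrument drift. Passing tests therefore demonstrate correctness of the
algorithms under the stated models, not robustness to every artefact of
real data.

Problem sizes used by the packaged checks (chosen as the smallest sizes at
which each property is statistically meaningful): null calibration uses 200
simulations of 300 codons on 6 taxa under $\omega_2 = 1$ with moderate
divergence (tree length ≈ 1 substitution/codon); parameter recovery uses
$\omega_2 = 4$ at 3000 codons; NEB recall uses a ten-taxon tree with a
short (0.1) foreground stem, strong purifying background
($\omega_0 = 0.02$) and $\omega_2 = 16$ at a fifth of 60 sites — a regime
chosen, before freezing the seeds, so that a planted selected site carries
enough information for a 0.95 posterior: recall is fundamentally limited by
the probability that the site experienced at least one foreground
substitution and by saturation if the stem is long, and the two-degree
analysis of those limits is why the stem is short and $\omega_2/\omega_0$
large. Pruning correctness is checked against literal enumeration of all
internal-node codon assignments on 200 random 3–4-taxon instances.

## Numerical and degenerate-input policy

Likelihood underflow is handled by per-node rescaling with log
accumulation. Optimiser convergence uses L-BFGS-B's `factr` (default
$10^9$, about $10^{-7}$ relative); the calibration and recovery checks
relax it (to $10^{10}$–$10^{11}$) where a looser tolerance provably cannot
change the outcome at the thresholds tested. Class-proportion boundaries
($p_2 \to 0$) and $\omega_2 \to 1$ are permitted; the LRT clamps small
negative statistics (magnitude below $10^{-4}$) to zero and treats anything
more negative as an optimiser inconsistency error. Identical sequences in
`pairwise_rates()` short-circuit to $d_N = d_S = 0$ with $\omega$ flagged
undefined; $d_S = 0$ never produces a division. Ties in Fitch sets,
nearest-lineage and nearest-taxon tie-breaks are all deterministic, and any
residual ambiguity is reported rather than forced.

## Known limitations

* The likelihood machinery supports one foreground branch per run (as in
  the analyses reproduced); clade models and multiple independent
  foreground regimes are out of scope.
* NEB (not BEB) posteriors are provided; NEB ignores parameter uncertainty
  and is known to be anti-conservative on small data.
* The FdNs ancestral rule is parsimony-based by design; probabilistic
  (marginal ML) reconstruction is not implemented.
* dS saturation at deep divergences degrades both the LRT power and NG86
  counting (Jukes–Cantor correction returns `NA` beyond p = 0.749); the
  package reports rather than repairs saturation.
* Genome composition statistics operate on user-supplied sequences; the
  deposited mitochondrial genome accession is not redistributed with the
  package.
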
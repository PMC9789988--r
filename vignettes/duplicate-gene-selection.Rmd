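---
title: "Selection, synteny, and expression analysis of duplicated gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection, synteny, and expression analysis of duplicated gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ohnosel)
```

`ohnosel` implements the inference chain used to study gene families retained
from whole-genome duplications — the motivating system being the *HIFA*
(hypoxia-inducible factor alpha) family of ray-finned fishes, shaped by two
rounds of vertebrate genome duplication, the teleost-specific duplication
(TGD), and the salmonid-specific duplication (SGD). This vignette documents
the models, the tunable parameters, the numerical choices, and the
limitations a user should know about.

## The codon substitution model

All selection machinery rests on a reversible Goldman–Yang (GY94) model over
the 61 sense codons of the standard genetic code. For codons $i \ne j$
differing at exactly one nucleotide position,

$$ q_{ij} = \pi_j \,\kappa^{\mathbf 1[\text{transition}]}\,
            \omega^{\mathbf 1[\text{nonsynonymous}]}, $$

and $q_{ij} = 0$ when more than one position differs. $\kappa$ is the
transition/transversion rate ratio, $\omega = dN/dS$, and $\pi$ the
stationary codon frequencies. The matrix is scaled to a mean rate of one at
stationarity, so branch lengths are expected substitutions per codon. Codon
frequencies come from the data under an F3x4 (position-specific nucleotide
frequencies, the default), F1x4, or equal-frequency model, and are held
fixed during optimization; the model family does not include site-rate
gamma variation or the more elaborate branch-site models of the codeml M2a
family — the two-ratio branch model covers the branch-level question at
desk scale.

Likelihoods are computed by Felsenstein pruning in compiled code. Because
the model is reversible, transition probabilities come from the
eigendecomposition of the $\pi^{1/2}$-symmetrized rate matrix — numerically
stable at large branch lengths — and a codon containing any gap or ambiguity
character is treated as fully missing at its site (a partial likelihood of
one). Alignment columns are indexed 1-based ("MSA codons").

## Branch models and their test

`codon_fit()` maximizes the likelihood over $\kappa$, the $\omega$ ratio(s),
and either all branch lengths or — in fast mode
(`optimize_branch_lengths = FALSE`) — a single tree-scale factor, by L-BFGS-B
on log-transformed parameters with seeded random restarts (`n_starts`,
default 3). Convergence uses `optim`'s `factr = 1e7` (about $10^{-9}$
relative tolerance on the objective); bounds are
$\kappa \in [10^{-2}, 10^2]$, $\omega \in [10^{-4}, 50]$, branch lengths
$\in [10^{-7}, 50]$. Foreground branches for the two-ratio model are marked
with the `#1` label suffix in Newick (the convention of branch-model
software); a tag on an internal node flags only its stem branch, and the
documented extension `#1*` flags the whole clade. The two-ratio vs one-ratio
comparison is a 1-df likelihood-ratio test. A foreground whose branches all
have length (near) zero leaves $\omega_1$ unidentifiable; the fit is then
flagged rather than silently returned.

Fast mode exists because the calibration studies refit hundreds of
simulated datasets; with the simulated branch lengths supplied, optimizing
a single scale factor is statistically harmless there and an order of
magnitude faster. Fits are deterministic given `seed`.

## Site-level tests

All site tests condition on the global one-ratio fit (branch lengths,
$\kappa$, $\pi$). Writing the unscaled rate matrix as
$R_s + \omega R_n$ (synonymous and nonsynonymous parts), the per-site model
is $Q(\alpha, \beta) = (\alpha R_s + \beta R_n)/C$, with $C$ the mean rate
of the global matrix, so that $\alpha = 1, \beta = \hat\omega$ reproduces
the global model exactly. The implementation uses the identity
$Q(\alpha,\beta) = \alpha\,(C_{\omega}/C)\,Q_{\text{norm}}(\omega)$ with
$\omega = \beta/\alpha$: one eigendecomposition per distinct $\omega$ per
evaluation, with $\alpha$ folded into the branch lengths.

* **FEL-style (pervasive).** Per site, $\alpha$ and $\beta$ are free; the
  null constrains $\alpha = \beta$; 1-df chi-squared LRT. A site is called
  positively selected when $\hat\beta > \hat\alpha$ and $p \le$ the
  threshold (default 0.05, configurable — the threshold is a reporting
  convention, not part of the model).
* **MEME-style (episodic).** Per site, each branch independently draws
  $\beta^- = \delta\alpha$ ($\delta \in [0,1]$, weight $1-w^+$) or a free
  $\beta^+$ (weight $w^+$); because draws are branch-independent, the site
  likelihood is pruning with per-branch mixture transition matrices. The
  null constrains $\beta^+ = \alpha$. The asymptotics of this boundary
  mixture are non-standard: the package defaults to the conservative
  $\chi^2_2$ reference and exposes a mixture over $\chi^2_{0,1,2}$ weights;
  the calibration studies below use the published mixture
  $(0.37, 0.30, 0.33)$, which is close to nominal in our null simulations
  (the $\chi^2_2$ default is markedly conservative).
* **SLAC-style (counting).** Ancestral codons by marginal maximum-likelihood
  reconstruction under the global fit (up-down algorithm); per branch-site
  substitutions decomposed into synonymous/nonsynonymous counts, with
  multi-nucleotide changes averaged over all shortest mutational paths that
  avoid stop codons (falling back to all shortest paths in the rare case
  none avoids a stop). Each site's synonymous fraction is tested against a
  $\kappa$-weighted neutral expectation from the reconstructed parent
  codons, using binomial tails extended to fractional counts via the
  regularized incomplete beta function.
* **BUSTED-style (gene-wide).** Every branch-site draws $\omega$ from a
  shared three-class distribution with
  $\omega_1 \le \omega_2 \le 1 \le \omega_3$; the null pins $\omega_3 = 1$;
  conservative $\chi^2_2$ reference. Synonymous-rate site variation (the
  full method's SRV component) is deliberately omitted. Per-site evidence
  ratios are the unconstrained/constrained site-likelihood ratios at the
  respective MLEs; the study convention treats ER > 2 as corroborating a
  site call. Alignments with two or fewer distinct site patterns are
  reported untestable.

Raw per-site p-values are reported; a Benjamini–Hochberg column can be added
with `stats::p.adjust` but the default site calls use the per-test
threshold, matching common practice with these tests' web defaults.

## What the synthetic data emulate

`sim_scenario()`/`simulate_codon_alignment()` draw a root sequence from
$\pi$ and evolve it branch by branch. Omega regimes: constant; site classes;
two-ratio branch; "episodic" (flagged branches, a fraction of sites); and
"branch-site" (each branch-site independently elevated with a given
probability — the episodic signature MEME targets). Two scaling conventions
matter and are chosen to match the corresponding estimators: the constant
and branch regimes normalize each class matrix to mean rate one (the
branch-model parameterization), while the site-level regimes share the
neutral synonymous scale across classes, so an elevated $\omega$ produces
genuinely more nonsynonymous events rather than a recomposition of the same
number of changes.

The default simulation tree (`sim_tree`) draws branch lengths uniform on
[0.05, 0.35] substitutions/codon — the divergence regime of cross-lineage
gene-family alignments with a distant outgroup, which is where these tests
have useful power. Desk-scale study sizes, chosen so the full suite runs in
tens of minutes on one CPU, are: 16 taxa × 300 codons with 200 replicates
for the branch-LRT null calibration; 16 taxa × 500 codons with 20 replicates
for $\omega$ recovery (median $|\hat\omega - 0.3| < 0.05$); 300 null sites
for site-test size; and 32 taxa × 50 sites for the episodic power
comparison ($\omega^+ = 6$ on 30% of branches against a 0.2 background).
The acceptance script reuses these conditions with 100–150 replicates/sites
where that keeps its total runtime in single-digit minutes. What passing
these studies does *not* show: robustness to alignment error, recombination,
synonymous-rate variation, or model misspecification, all of which affect
real data.

The neighborhood simulator duplicates an ancestral ±10 window and applies
per-gene loss (replacement by a novel symbol), strand flips, and insertions
on each descendant branch, recording the truth; the expression simulator
draws negative-binomial counts (Poisson in the infinite-dispersion limit)
around a paralog × tissue mean matrix plus log-normal background genes, so
TPM is normalized over a full transcriptome rather than the focal family
alone — the normalization universe is a genuine ambiguity in published
RPKM-based TPMs, and the package always computes it transcriptome-wide.

## Synteny rules

Neighborhoods are ±10 flanking genes with uppercase-normalized symbols;
unidentifiable ORFs stay as `"unknown"` and never match. Shared-flank counts
are symbol-set intersections (duplicates once, order and strand ignored);
conserved runs walk outward from the focal gene and break at the first
mismatch or unknown, with strand agreement reported separately. The naming
rules: with at least one lineage retaining both TGD paralogs, the copy
sharing more flanks with the ancestral (gar) neighborhood is "a", the other
"b"; ties are unresolved, and single-survivor families are left unsuffixed
because the copy's identity cannot be established. SGD duplicates are "s1"
(more flanks shared with the Esociformes sister group) and "s2". Matching is
by symbol only — no sequence-level orthology check — which is the main
limitation; the packaged fixture `inst/extdata/synteny_s2_synthetic.tsv` is
a synthetic re-encoding of the published neighborhood relationships (the
15-gene and 3-gene shared counts, the 10-gene conserved upstream run, the
zebrafish *HIF2A* a/b reversal, and the s1/s2 assignments), not the original
supplementary data.

## Physicochemical profiling

Residues at selected sites are encoded by the five Sandberg z-scales
(hydrophobicity, steric bulk, polarity, and two electronic terms; the 20×5
table is transcribed from the published reference and bundled as a
constant). Gaps and unknown residues default to column-mean imputation with
a recorded mask. For cluster-number selection, k-means runs on the
principal-component rotation of the centered (not scaled) matrix with the
BIC heuristic $n\ln(\mathrm{WSS}_k/n) + k\ln n$; all variance is retained by
default so the PCA is only a rotation — retaining a variance fraction first
concentrates the between-group signal into few dimensions and makes the BIC
overfit $k$; per-column scaling has a similar pathology when between-group
variance dominates a column, and the z-scales are already on a common scale.
The full BIC curve is always returned so an elbow criterion can be applied
instead. DAPC then centers the matrix, retains the minimum number of PCs
explaining ≥ 80% of the variance (configurable; capped at
$n - \#\text{groups}$), and runs linear discriminant analysis on the scores,
reporting discriminant coordinates, membership probabilities, and the
reassignment accuracy. Cross-validated choice of the PC count is out of
scope.

## Expression summaries

$\mathrm{RPKM} = \text{count}/(\text{length}_{kb} \cdot \text{library}/10^6)$
and $\mathrm{TPM} = 10^6\,\mathrm{RPKM}/\sum \mathrm{RPKM}$, the sum running
over the tissue's whole transcriptome. Paralog × tissue matrices hold median
TPM over the species possessing the paralog; a species lacking a paralog is
excluded rather than counted as zero, and an empty cell is missing — absence
must not masquerade as low expression.

## Pipeline

`run_pipeline()` chains selection → site tests → physicochemical profiling →
synteny → expression → motifs on user inputs or built-in synthetic
scenarios, validating the configuration up front (every failure listed),
writing per-stage TSV/CSV/JSON artifacts, and recording seeds, thresholds,
input hashes, and artifact hashes in `manifest.json`; identical
configurations reproduce identical artifacts. The package is driven from R;
the pipeline function plus `scripts/acceptance.R` are its command-line
surface.

## Known limitations

Branch lengths and $\kappa$ are treated as known in the site tests
(conditioning on the global fit, as the originals do), which mildly
understates per-site uncertainty. The MEME-style default reference is
conservative by design. Exact reproduction of published site lists for a
real gene family would require the original alignments and the original
tools' thresholds, and is sensitive to both; the package's claims are
therefore calibration- and property-based.
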
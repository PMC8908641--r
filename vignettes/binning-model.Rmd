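---
title: "The two-layer composition and coverage binning model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-layer composition and coverage binning model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoCoBin)
```

## The problem

A metagenomic assembly is a bag of contigs from an unknown number of
genomes. Binning groups contigs into genome-level clusters using two
signals: **composition** (tetranucleotide frequencies are genome-specific
and roughly homogeneous along a genome) and **coverage** (contigs of one
genome share a mean sequencing depth per sample, reflecting the organism's
abundance). A third, sparser signal comes from **single-copy marker
genes**: genes present exactly once in nearly every bacterial genome, so
two contigs carrying the same marker must come from different genomes.

CoCoBin combines the three in two layers: a global mixture model produces
preliminary clusters, and each preliminary cluster is refined by a
marker-seeded, classifier-guided coverage mixture.

## Features

For each contig $c$ of length $l_c$ we count canonical $k$-mers
($k = 4$ by default; a $k$-mer and its reverse complement are one
feature, giving $D_4 = 136$ columns), normalize to frequencies, and
reduce by PCA keeping the smallest number of components reaching 90% of
the variance. Depths are computed per sample as aligned bases (CIGAR
M/=/X of primary, non-supplementary alignments with MAPQ $\ge 20$)
divided by contig length, and enter the model as $\log(\text{depth}+1)$.
The shift makes the transform defined at zero depth; the base of the
logarithm is irrelevant downstream. The first-layer feature vector is
$x_c = [\text{PCA-reduced composition} \,\|\, \log \text{depths}]$, and
every contig carries the weight $w_c = l_c / \overline{l}$, so longer
contigs — whose composition and depth estimates are less noisy — dominate
the parameter estimates.

## First layer: weighted variational DP Gaussian mixture

The number of genomes is unknown, so the first layer is a truncated
stick-breaking Dirichlet-process Gaussian mixture with
normal-inverse-Wishart base measure
$\mathcal{NIW}(\mu_0, \kappa, \Psi, v)$: $\kappa = 10^{-4}$ (nearly
non-informative), $\mu_0$ and $\Psi$ the empirical mean and covariance of
the features, $v = d$, concentration $\alpha = 1$. Mean-field variational
inference alternates:

* **M-step** — with $N_g = \sum_c w_c r_{c,g}$:
  $\gamma_{g,1} = 1 + N_g$,
  $\gamma_{g,2} = \alpha + \sum_{g' > g} N_{g'}$,
  $\kappa_g = \kappa + N_g$,
  $\mu_{0,g} = (\kappa \mu_0 + \sum_c w_c r_{c,g} x_c)/\kappa_g$,
  $\Psi_g = \Psi + S_g +
  \frac{\kappa N_g}{\kappa_g}(\bar{x}_g - \mu_0)(\bar{x}_g - \mu_0)^T$
  with $S_g$ the weighted scatter about the weighted mean $\bar{x}_g$,
  and $v_g = v + N_g$.
* **E-step** — the unnormalized log responsibility adds the expected log
  stick weight (digamma terms of the $\gamma$'s) to
  $\tfrac12 [\sum_i \psi(\tfrac{v_g+1-i}{2}) + d\ln 2 - \ln|\Psi_g|
  - d/\kappa_g - v_g (x_c-\mu_{0,g})^T \Psi_g^{-1} (x_c-\mu_{0,g})]$.

The layer starts at $3G$ components, with $G$ estimated from the markers
(below), and runs to a mean absolute responsibility change below $10^{-3}$
with a 300-iteration cap.

**Initialization.** We seed the responsibilities from a k-means partition
of the column-standardized features (standardized for the init only —
the composition PCs are numerically tiny next to log depths, and
unstandardized k-means would split on coverage alone). A symmetric
Dirichlet draw is available as `init = "random"`, but variational fitting
can empty components and never split one: from a random start all
component means sit near the global centroid and the two most similar
genomes routinely end up sharing a component for good. The k-means start
places components on distinct regions so the pruning machinery only ever
has to merge, which it can do.

**Dissolution.** To keep components genome-sized, components whose
hard-assigned contigs total less than 500 kb are dissolved every 10
iterations and their contigs' responsibilities renormalized over the
survivors. Two refinements matter in practice. Empty components are
dropped freely, but *occupied* under-threshold components are dissolved
one per checkpoint: their contigs re-home to the nearest surviving
component and the fit re-converges before the next removal. Removing all
of them at once can delete every piece of a genome the fit has not yet
consolidated, pushing its contigs wholesale into another genome's
component. Second, responsibility convergence does not stop the run while
prunable components remain (the iteration cap still does, with a final
simultaneous dissolution as safety net). If *no* component reaches the
threshold — a pool smaller than one genome-sized component — the pool
collapses to a single cluster and is left to the second layer.

**Abnormality screen.** Each final cluster is screened by the average
pairwise Euclidean distance between its raw tetramer frequency profiles;
clusters above 0.04 (option `maxDpgmmDistance`) are flagged abnormal and
excluded from further processing. Within-genome profiles at realistic
contig lengths sit well below this value (about 0.01 at 10–30 kb), while
mixtures of compositionally distinct genomes exceed it.

## Markers, seeds and the composition classifier

Valid marker hits (hit coverage $\ge$ 0.5 and accuracy $\ge$ 0.6, both
inclusive) map each marker $m_i$ to $G_i$ contigs. With $G_{mode}$ the
mode of $\{G_i\}$ (ties broken toward the larger value, erring toward
over-splitting, which the output gate can absorb), the genome number is
$G = \max(G_i \text{ such that } \#G_i \ge 0.5\,\#G_{mode})$.

Markers mapping to at least $G_{mode}$ contigs contribute their contig
sets as groups. For each group with two or more members, a multi-class
SVM is trained on 20 random 1.5–2.5 kb sub-contigs per member (features:
canonical tetramer frequencies of the fragment plus the parent contig's
log depths; label: the contig id) and then predicts every grouped contig
from its full-length features. If the label of training contig $i$ claims
exactly one contig $j$ of a predicted group, $A_{i,j}$ gains 1; if it
claims two, each gains 0.5 (the tie is unresolvable); labels claiming
nothing add nothing. The symmetrized matrix $A + A^T$ is clustered into
$G$ groups by normalized-Laplacian spectral clustering (k-means on the
row-normalized top-$G$ eigenvectors, 10 seeded restarts; contigs with no
bonus anywhere stay as isolated nodes and land where k-means puts them).
Each spectral cluster is concatenated, in input contig order, into one
**extended seed**.

From each seed, 300 random 3–4 kb sub-seeds train an RBF-kernel SVM on
canonical tetramer frequencies with $\gamma = 1/D_4 = 1/136$ and cost
$C = 1$ (the library defaults otherwise; features are column-standardized
inside the fit, without which the decision values of the nearly-constant
kernel degenerate and probability calibration collapses). Pairwise-coupling
calibration yields, for every contig, the probability row
$p_{SVM(c)} \in \Delta^{G-1}$ of belonging to each seed's genome.

## Second layer: KL-regularized coverage mixture

Log depths $x_c \in \mathbb{R}^n$ ($n$ = samples) are modeled by a
Gaussian mixture with one component per seed and *contig-specific*
priors $\pi_c$:

$$\ell = \sum_c \log \sum_g \pi_c^g\, \mathcal{N}(x_c \mid \mu^g,
\Sigma^g) \;-\; W \sum_c KL\!\left(p_{SVM(c)} \,\|\, \pi_c\right),
\qquad W = 1/n .$$

The KL term pulls each prior toward the composition evidence; with more
samples ($W$ small) the coverage likelihood dominates — the intended
balance, since coverage becomes more informative with more samples. EM:
the E-step is the usual posterior $r_c^g \propto \pi_c^g \mathcal{N}(x_c
\mid \mu^g, \Sigma^g)$ (log-space); the M-step blends
$\pi_c^g = (r_c^g + W p_{SVM(c)}^g)/(1+W)$ — whose rows sum to one by
construction — and sets $\mu^g, \Sigma^g$ to the responsibility-weighted
mean and scatter. Initialization takes $\pi = p_{SVM}$ and one M-step
with $r = p_{SVM}$, a warm start that avoids the local optima of random
initialization. Convergence is judged on the objective (change below
$10^{-4}$, 200-iteration cap) because the objective is what the EM
derivation ascends; it is non-decreasing along the run up to $10^{-8}$
numerical slack. An exactly zero prior entry annihilates its component
for that contig permanently — calibrated classifier probabilities are
never exactly zero, so this arises only with hand-built priors.

## Pipeline and output gating

Clusters from the first layer with marker-estimated $G = 1$ (or no
markers at all) are emitted intact when above 200 kb (option
`minClusterSize`); otherwise they run through seeds, classifier and
coverage mixture, and each sub-cluster above 200 kb whose own restricted
marker estimate is 1 is emitted. Everything else is pooled assembly-wide
and the whole two-layer procedure repeats (fresh first layer on the
pool, letting contigs escape a bad preliminary split) until the pool is
empty, a full round emits nothing, or 10 rounds elapse; the remainder is
reported `unclustered`, abnormal-flagged contigs as `abnormal`. Every
stochastic step draws a child seed deterministically from the master
seed, so results are byte-identical across runs.

## Numerical choices

* Responsibilities in both layers are computed in log space;
  log-sum-exp normalization guards underflow.
* $\Psi_g$ and $\Sigma^g$ are inverted via Cholesky; on failure a ridge
  of $10^{-6} \cdot \mathrm{tr}/d$ is added. $\Sigma^g$ additionally
  receives $10^{-6} \cdot \overline{\mathrm{diag}}$ every M-step (a
  variance floor of $10^{-6}$ when $n = 1$), required for degenerate
  single-sample data.
* Fragment lengths are uniform on the integer interval and starts
  uniform over admissible offsets; sequences shorter than the minimum
  fragment length contribute themselves whole, so short marker-bearing
  contigs still provide training material.
* Ties: argmax assignments take the first maximum; the mode of marker
  counts breaks ties toward the larger value.
* Without markers the first layer starts at
  $\max(10, \lceil \text{bp}/4\,\mathrm{Mb} \rceil)$ components.

## The synthetic community generator

`generateCommunity()` emulates the statistical structure the model
assumes: each genome has its own randomly drawn order-2 Markov chain
(rows Dirichlet(1)), giving distinct, internally homogeneous tetramer
compositions; contigs are independent chain emissions with uniform
lengths (10–30 kb by default) summing to about 2 Mb per genome;
per-genome per-sample depths are log-normal around 20× (roughly the
10–40× range of typical simulation studies) with per-contig log-normal
noise (sdlog 0.1) for the overdispersion real coverage shows beyond
Poisson; markers are placed one per genome on random contigs with 5%
dropout and 5% duplication. Defaults: 5 genomes, 2 samples, 40 markers,
about 10 Mb of assembly — the scale at which the full pipeline runs in
seconds on one CPU, which is also the problem size used by the test
suite and the acceptance script.

What it does **not** emulate: assembly chimerism and fragmented repeats,
strain-level mixtures, shared (horizontally transferred) sequence,
GC-dependent coverage bias, and compositionally *similar* genome pairs
distinguished only by coverage. Passing tests therefore show the
machinery is correct and well-calibrated at desk scale, not that
real-assembly accuracy matches benchmark studies.

The evaluator scores bins base-pair-wise: precision (purity) is the
dominant genome's share of a bin, recall (completeness) the share of
that genome captured; genomes are credited to at most one bin by greedy
best-F1 matching — an approximation of the exact matching used by
benchmarking toolkits, adequate at this scale.

## Known limitations

* Variational fitting cannot split a component; recovery from
  under-segmentation relies on the initialization spreading components
  and on second-layer recycling.
* A genome split into pieces that all exceed the 500 kb dissolution
  threshold stays split (the output gate will still only emit pieces
  whose marker estimate is 1).
* Abnormal clusters are removed, not re-examined; their contigs are
  reported unclustered.
* The coverage model assumes genome-wide mean depths; uneven
  within-genome coverage (e.g., replication origins) is absorbed only by
  the Gaussian variance.
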
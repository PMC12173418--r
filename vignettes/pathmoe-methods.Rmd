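---
title: "pathMoE: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pathMoE: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pathMoE integrates two views of a tumour — a whole-slide image (WSI)
summarised as a bag of patch feature vectors, and multi-omics profiles
(expression, copy number, methylation) summarised at the gene level — into a
single predictive model whose internal gating weights are directly
interpretable as region-, pathway- and interaction-level importance scores.
This vignette describes the model, the assumptions behind it, the parameters
that matter, the synthetic-data generator used for validation, and the design
choices made where the architecture left genuine freedom.

## The model

**WSI branch.** A slide arrives as `np` patches, each with a fixed-length
feature vector $h_j$ (from an upstream extractor; any dimension works) and a
spatial center $g_j$. Pairwise patch similarity is the product of two
Gaussian kernels,
$$\kappa(x_i, x_j) = e^{-\lambda_h \lVert h_i - h_j\rVert^2}\,
                     e^{-\lambda_g \lVert g_i - g_j\rVert^2},$$
so two patches are similar only when they agree both morphologically and
spatially. Average-linkage agglomerative clustering on the distance
$1-\kappa$, cut at $1-\delta_c$, merges near-duplicate patches into
representative "merged patches" (member means of features and coordinates).
A hypergraph is built on the merged set: one hyperedge per merged patch
containing every patch whose *morphological* similarity $\kappa_h$ reaches
$\delta_h$ (spatial proximity does not gate hyperedge membership). Two
layers of attention-weighted hypergraph convolution — node scores define a
softmax over each hyperedge's members, hyperedge messages are the
attention-weighted member averages, and each node aggregates its hyperedges'
messages with degree normalization, followed by a linear map and tanh —
produce node embeddings, which are mean-pooled by region into
$X^K \in \mathbb{R}^{K \times z}$.

Region identity matters: for the gating weights to mean the same thing for
every patient, "region k" must be the same tissue category across slides.
K-means centroids are therefore fitted once, on the merged patches of the
training slides (standardized feature space), and every slide's merged
patches are assigned to their nearest centroid. A region with no patches on
some slide yields a zero row flagged in a mask and is excluded from the
gating softmax.

**Omics branch.** Each omics source is split by gene set into P blocks.
Pathway p gets a multi-source variational autoencoder: per-source
sub-encoders (two hidden layers, batch-normalized tanh), a central encoder
mapping their concatenation to a latent mean and log-variance of dimension
$z$, and per-source decoders. Stacking the P latent embeddings gives
$O^P \in \mathbb{R}^{P \times z}$. Genes that belong to several pathways are
duplicated into each block — overlapping collections such as the MSigDB
Hallmarks are the expected input, and exclusivity would silently drop genes.

**Fusion.** Every (region, pathway) pair is fused by low-rank factorized
bilinear pooling: $z_{k,p} = \mathrm{SumPool}_r(Ux_k \circ Vo_p)$, followed
by a signed square root and L2 normalization. The operator is purely
bilinear (no biases), so an all-zero input annihilates the fused vector.
Because both embeddings are roughly centered, a naive bilinear map would
suppress all first-order information; the pipeline therefore lifts each
embedding to homogeneous coordinates $[x, 1]$ before fusing, which lets
linear terms in either modality survive while keeping the operator bilinear.
It also gives missing modalities sensible semantics: a dropped WSI
($X^K = 0$) turns every fused block into a function of the omics embedding
alone. The factor matrices start from a pass-through initialization — the
first two rank slots of each output dimension read $x_d \cdot 1$ and
$1 \cdot o_d$ — so the fused block begins as roughly $x + o$ and training
rotates the remaining slots toward interactions. Each fused block is batch
normalized before gating: after L2 normalization the across-sample variation
is small relative to the block's mean direction, and the gates and head need
it on a unit scale.

**Hierarchical mixture of experts.** Phase 1: for each pathway, a gating
network scores each region's fused vector; softmax over regions gives
weights $w^p_{k}$ ($\sum_k w^p_{k}=1$) and the pathway embedding
$z^{moe}_p = \sum_k w^p_k z_{k,p}$. Each pathway gets its own phase-1 gating
network by default: a gate shared across pathways cannot specialize to the
fused blocks of one pathway, and in planted-signal experiments sharing
prevented interaction recovery (`shared_gate = TRUE` restores sharing).
Phase 2: a second gate softmax-normalizes pathway weights $w_p$ and forms
the patient embedding $z^{moe} = \sum_p w_p z^{moe}_p$, which a linear head
maps to class logits or a scalar risk. Each pathway embedding also passes
through a linear layer producing pathway-specific predictions; these are
trained against the task (weight `pw_loss_weight`, default 0.3), which gives
the gating direct gradient signal about which pathways are informative.

**Losses and training.** Classification uses mean categorical cross-entropy.
Survival uses the Cox negative partial log-likelihood
$L(\theta) = -\sum_{i: E_i=1}\bigl(\hat\mu_i - \log\sum_{j: T_j \ge T_i}
e^{\hat\mu_j}\bigr)$ with the Breslow convention for ties and a log-sum-exp
stabilized inner sum. Training is multiphase: phase 1 pretrains the WSI
encoder (feature autoencoding through the hypergraph convolution — the
unsupervised counterpart of the omics VAEs) and the pathway VAEs
(reconstruction + $\beta$·KL, $\beta = 0.01$ with a 10-epoch linear
warm-up); phase 2 freezes the sub-encoders and the WSI encoder, unfreezes
the central encoders (at a reduced learning rate, `central_lr_scale = 0.1`)
and trains fusion, gating and heads on the task loss plus
`aux_weight = 0.1` times the VAE losses. Modality dropout is applied
throughout training: each sample loses each modality (the WSI or one omics
source) independently with probability `modality_dropout = 0.4`, survivors
are rescaled by $1/(1-p)$, and a sample never loses all modalities (its mask
is redrawn). At inference genuinely missing modalities are zeroed without
rescaling.

**Interpretation.** The phase-2 weight $w_{i,p}$ is read verbatim as the
pathway enrichment score $r_{i,p}$; the phase-1 weight $w^p_{i,k}$ as the
multimodal interaction score $\mathrm{MIS}_{i,k,p}$. Gene attributions
$s_{i,g}$ come from expected gradients (integrated gradients averaged over a
training-set background — exact Shapley values for linear models, additive
up to quadrature error), are normalized by pathway importance
$\tilde s_{i,g} = r_{i,p(g)} s_{i,g}$, and cohort-aggregated
$|\tilde s|$ values feed a two-sided two-sample Kolmogorov–Smirnov test of
each pathway's genes against all others, with Benjamini–Hochberg adjusted
p-values reported alongside the raw ones.

## Parameters that matter

| parameter | default | units / range | why |
|---|---|---|---|
| `lambda_h`, `lambda_g` | median heuristic | 1 / squared distance | scale-free across feature dimensions and magnifications |
| `delta_c` | 0.9 | (0, 1] | merge threshold; higher keeps more patches |
| `delta_h` | 0.5 | (0, 1] | hyperedge threshold on the morphological kernel |
| `n_regions` (K) | 4 | count | spatial categories; fixed so the gating shape is constant |
| `zdim` | 32 | dims | shared embedding width |
| `rank` | 4 | count | bilinear factor rank (≥ 2 for the pass-through start) |
| `modality_dropout` | 0.4 | probability | moderate rates gave the best robustness in our experiments |
| `beta` | 0.01 (10-epoch warm-up) | – | KL weight; small so reconstruction dominates early |
| `lr` | 3e-3, cosine decay | – | Adam step size for both phases |
| `weight_decay` | 1e-3 | – | decoupled (AdamW) decay on supervised parameters |
| `phase1_epochs` / `wsi_epochs` / `phase2_epochs` | 30 / 8 / 100 | epochs | desk-scale budgets |
| `batch_size` | 256 | samples | effectively full batch at desk scale; Cox risk sets see every pair |

Several defaults deviate from common deep-learning practice because the
intended regime is small (tens to low hundreds of patients in validation
studies): network dropout defaults to 0 (modality dropout and weight decay
regularize already, and at these sample sizes dropout noise dominates the
gradient); phase 2 conditions on the latent *mean* rather than a
reparameterized sample (after pretraining the posterior sd is of the order
of the embedding spread, and sampling drowns the supervised gradient); and
early stopping uses patience 25 with a best-validation snapshot, because a
20%-split validation loss is too noisy for aggressive stopping.

## The synthetic-data generator

`generateCohort()` emulates the statistical structure the model assumes,
not the appearance of real data. Per patient: patch coordinates come from
`n_regions` spatial Gaussian clusters (centers on a circle of radius 1000
px, sd 75 px); patch features from region-specific prototypes (norm 3,
noise sd 0.5) plus a per-patient region-activity latent
$u_{i,r} \sim N(1,1)$ along a region-specific direction, so morphological
and spatial similarity agree on the cluster structure. Omics values follow
one latent factor per pathway, $f_{i,p} \sim N(1,1)$, with per-source
loadings U(0.5, 1.5) and residual sd 0.6, giving within-pathway correlation.
The outcome depends on the product of the signal region's activity and the
signal pathway's factor through
$\eta_i = \mathrm{effect\_size}\,(a_i b_i - 1)$: classification labels are
Bernoulli$(\sigma(\eta_i))$; survival times are exponential with log-hazard
$\eta_i$ (proportional hazards by construction) under independent
exponential censoring whose rate is solved numerically to hit the target
censoring fraction. The positive-mean activity latents are deliberate:
pathway activities and region abundances are positive quantities, and the
centered product then carries both main effects and an interaction, so the
planted score separates classes cleanly (the generator's own oracle checks
require AUC > 0.85 at effect size 3).

What the generator does **not** emulate: tissue texture, staining variation,
batch effects, overlapping gene sets, count-distributed omics, informative
censoring. Passing the planted-signal tests therefore demonstrates that the
pipeline can find a region-by-pathway interaction under its own modelling
assumptions — not that it will do so on real cohorts.

## Numerical choices

* All networks run on a small reverse-mode autodiff tape over dense base-R
  matrices; gradients of every operator are property-tested against central
  differences.
* Weight initialization is uniform $U(-1/\sqrt{k}, 1/\sqrt{k})$ with $k$ the
  fan-in; batch-norm layers keep running statistics with momentum 0.1.
* The MFB signed square root is smoothed as $x(\varepsilon+|x|)^{-1/2}$ with
  $\varepsilon = 10^{-2}$: the exact kink has an unbounded derivative, which
  breaks the completeness of gradient-based attributions; the smooth form
  matches $\mathrm{sign}(x)\sqrt{|x|}$ to within 5% for $|x| > 0.1$ and has
  an exact derivative everywhere.
* Softmax and log-sum-exp are max-shifted; the Cox loss subtracts the
  maximal risk before exponentiating.
* K-means uses 10 restarts under a fixed seed; an assignment with `K` equal
  to the number of merged patches returns the identity labelling; empty
  regions yield zero embedding rows excluded from gating via $-\infty$
  logits.
* Degenerate inputs error loudly: all-censored training sets, batches with
  no events, pathways with no genes in any source, all regions masked,
  non-numeric cells in omics tables.
* KS enrichment p-values follow `stats::ks.test`'s convention: exact for
  small gene sets (where the hand-enumerable oracle applies), asymptotic
  for larger ones. Exact small-sample p-values are discrete, so null
  calibration checks are run in the asymptotic regime (sets of ~60 genes),
  where the p-values are continuous and only mildly conservative.

## Open design points and how they were resolved

* **Merging linkage.** The merge rule is stated pairwise; average linkage on
  $1-\kappa$ cut at $1-\delta_c$ is symmetric and order-robust.
* **Hyperedges use $\kappa_h$ only**, as printed; spatial proximity does not
  gate membership.
* **Gating mechanism.** The sum-to-one constraint is realized by softmax
  over learned gating-network logits conditioned on the fused vector (the
  object being weighted).
* **Cohort aggregation for enrichment** is the mean of $|\tilde s|$ over
  patients per gene — sign-agnostic importance.
* **KS sidedness** is two-sided: enrichment may shift scores in either
  direction, and the ranking by p-value is what is reported.
* **SHAP target** defaults to the task output (risk or class logit);
  the background is 20 training samples under a fixed seed; similar-sample
  smoothing is a k-nearest-neighbor (k = 5) average in embedding space,
  off by default.
* **Missing-WSI semantics.** With a purely bilinear operator and the
  homogeneous lift, a dropped WSI reduces every fused block to omics-only
  linear features; without the lift the forward pass would be constant.
  WSI-only inference (all omics missing) works symmetrically.

## Validation problem sizes

The test-suite and acceptance experiments run at desk scale, chosen to
exercise every code path while keeping a full run in minutes on one core:
cohorts of 40–150 patients, 8–60 patches per slide, 16-dimensional patch
features, 2 omics sources, 3–6 pathways of 5–8 genes, 4 spatial regions,
and 100–150 supervised epochs. Oracle comparisons (Cox partial likelihood,
hypergraph thresholding, merged-patch means, batched-versus-loop fusion)
use randomized inputs with exact or 1e-6-level tolerances.

## Known limitations

* At validation-study sample sizes (≈70 training patients), test AUC for a
  planted multiplicative interaction runs 0.05–0.15 below the cohort's
  Bayes ceiling; an oracle-assisted ridge on the true informative
  coordinates shows a comparable gap, i.e. the shortfall is a small-sample
  estimation limit of the study conditions, not specific to this
  implementation. Cohort-mean interaction scores sharpen accordingly slowly
  at this scale: per-cohort MIS rankings of the planted cell are
  informative but not reliably within the top decile.
* A missing WSI at inference removes the interaction pathway entirely (by
  design of the bilinear operator): predictions remain finite and
  omics-driven through the lifted linear terms only.
* The hypergraph encoder is trained by feature autoencoding; no
  slide-level self-supervision is implemented.
* Training is single-threaded, dense linear algebra; it is comfortable to a
  few hundred patients and a few thousand genes, not to biobank scale.
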
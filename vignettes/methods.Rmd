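---
title: "Landscape structure in joint species distribution models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape structure in joint species distribution models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`patchSDM` fits presence-only, joint species distribution models on
environmental patch tensors. An occurrence at location $u$ is represented
by a tensor $x(u)$ of size $p \times p \times L$: for each of the $L$
environmental layers, the $p \times p$ window of that layer's native grid
whose centre pixel contains $u$. Layers keep their own resolution, so the
geographic footprint of a slice differs between, say, a 1-km climate layer
and a 100-m land-cover layer. Categorical layers are one-hot expanded
beforehand (one boolean layer per observed class, class-sorted for
reproducibility), and undefined pixels are filled with a sentinel strictly
below the layer's valid minimum,
$\mathrm{min} - 0.1\,(\mathrm{max}-\mathrm{min})$, so "no data" is never
confused with a real value.

Because the data contain no absences, the model does not predict presence
probability. It predicts the categorical distribution of the species
*conditional on an observation*: with $z = \phi(x)$ a learnt feature
vector and $(\beta_s, \alpha_s)$ a per-species linear head,

$$\hat y_s = \frac{e^{\beta_s \cdot z + \alpha_s}}
                  {\sum_j e^{\beta_j \cdot z + \alpha_j}},$$

trained jointly over all species with multinomial cross-entropy
$-\log \hat y_{\text{true}}$ (probabilities floored at $10^{-12}$).
Training is plain SGD with momentum 0.9 and a step schedule that divides
the initial rate $10^{-1}$ by 10 before epochs 90, 130, 150 and 170 (the
reference recipe; desk-scale runs rescale these breakpoints to shorter
schedules, keeping the same fractions of the run). Validation runs every 5
epochs and the checkpoint with the best validation $MSA_k$ is returned.
The checkpoint metric uses $k = 30$ by default — the primary metric family
of the protocol — clamped to the species count; desk-scale configurations
use a smaller $k$ so the metric is not saturated.

Four models share this interface:

* **tensor CNN** — a small convolutional backbone (3×3 convolutions,
  ReLU, 2×2 average pooling, global average pooling, optional dense
  feature layer, dropout before the head). The backbone is a
  configuration choice; an `inception_v3_compat` preset reproduces the
  input/output contract of the large reference backbone (64×64 patches,
  2048 features) but is not exercised by the tests — it is not trainable
  in reasonable time on one CPU, and it is *not* the genuine Inception
  graph.
* **punctual DNN** — identical architecture, but each input layer is the
  centre-pixel value repeated over the whole patch. This deliberately
  wasteful encoding keeps the comparison controlled: any performance gap
  with the CNN is attributable to the landscape content of the tensor,
  not to architecture. Default dropout 0.5 (0.7 for the CNN).
* **random forest** — bagged CART with per-node feature subsampling
  (Gini, 100 trees, depth 16) on punctual vectors.
* **boosted trees** — Friedman multiclass gradient boosting with depth-2
  regression trees on punctual vectors.

No tree or deep-learning library is assumed: convolutions are im2col +
BLAS matrix products in compiled code, the split search is an
$O(n\log n)$ incremental-Gini scan, and both are verified against
brute-force oracles in the test suite (finite-difference gradient checks
for the network, exhaustive split enumeration for the trees).

### Input encoding (a design choice that matters)

Early experiments showed a conditioning artefact: a model trained on
per-patch-standardized tensors (the *structure-only* ablation) optimized
markedly better than the model given raw tensors, despite having strictly
less information. To remove this optimization asymmetry without touching
the ablation semantics, the network's input pipeline standardizes every
(already transformed) tensor layer over its own patch and re-injects the
deleted moments — each layer's patch mean and standard deviation — as a
side vector appended to the pooled features. Information is exactly
preserved per ablation: the mean-collapse model keeps its layer means (and
zero slices), the permutation model keeps the value moments of each layer,
the structure-only model keeps arrangement with constant moments, and the
unablated model keeps everything. All models thereby train on equally
well-conditioned inputs. Global per-channel normalization (train-split
statistics) is applied before this step, and is skipped for the
structure-only ablation, whose layers are already standardized.

## The ablation suite

Four transformations are applied to *every* tensor at *every* access,
during training and testing alike, each deleting a specific information
channel:

| transform | deletes | keeps |
|---|---|---|
| `rotation` (0/90/180/270°, same for all layers) | orientation | everything else |
| `permutation` (independent per layer) | spatial arrangement | per-layer value distribution |
| `mean` (layer collapsed to its mean) | arrangement and variability | punctual-scale values |
| `standardize` (per-layer mean 0, sd 1) | location and scale | arrangement |

Random draws are re-sampled at each access from counter-based keys
(seed, epoch, observation index), so runs are exactly reproducible while
behaving like data augmentation. The per-layer permutation is drawn
independently per layer (the plain reading of the protocol); a variant
sharing one permutation across layers would preserve cross-layer pixel
alignment and is noted as an extension, not built.

## Evaluation

The primary metric ranks, for each test observation $i$, the true species
within the sorted predicted probabilities: $A_k$ is the fraction with rank
$r_i \le k$; $SA_{k,s}$ averages the indicator within species $s$; $MSA_k$
averages $SA_{k,s}$ over species, so frequent species carry no extra
weight. Rank ties are resolved *pessimistically* (the true species is
placed after every species with an equal score): this is deterministic,
conservative, and penalizes degenerate constant predictors.

AUC and TSS are computed per species against pseudo-absences drawn from
the other species' test occurrences, one per presence, without
replacement, each occurrence weighted by the inverse of its species' test
count — equivalent to first drawing a species uniformly, then one of its
records. Neural models are scored by their logits
$\beta_s\cdot z + \alpha_s$; tree baselines, which have no logits, by
their categorical probabilities. For TSS, scores are min-max scaled per
species over all test occurrences (a constant score maps to 0.5), the
threshold grid is 101 points on $[0,1]$, and **one global threshold** —
the maximizer of the species-mean TSS — is reported. The alternative
per-species threshold reading of the protocol would trivially inflate
small-sample species; the choice is genuinely ambiguous in the source and
is resolved here in favour of the conservative option.

With one presence and one untied pseudo-absence, the AUC can only be 0 or
1, and attainable per-species TSS values lie in $\{1, 0.5, 0, -1\}$; the
acceptance tests assert both degeneracies.

## The synthetic world

The generator produces worlds in which the value channel and the
structure channel of the landscape can be manipulated independently:

* **plain layers** — Gaussian random fields (periodic Gaussian-kernel
  convolution of white noise via FFT), zero mean, unit variance, with a
  configurable correlation length; white noise at length 0. The binding
  contract is Moran's I (rook contiguity): ~0 for white noise, > 0.5 at
  length 16 on a 128-pixel grid.
* **roughness layers** — $\sqrt{a}\,g_{\text{fine}} +
  \sqrt{1-a}\,g_{\text{coarse}}$, where $g_{\text{fine}}$ is white noise,
  $g_{\text{coarse}}$ a short-correlation field, and $a$ a smooth mixing
  surface mapped through the normal CDF. Both components have unit
  variance, so the blend is standard normal *at every pixel*: the local
  value distribution (mean, dispersion, multiset) is homogeneous across
  the map and only the spatial arrangement — fragmented versus smooth —
  varies. This emulates variation in landscape fragmentation at constant
  habitat amount.
* **categorical land cover** — a quantile-thresholded field giving
  near-equal class shares; its correlation length defaults to the finest
  quantitative length so land-cover patches carry as little
  location-coding information as possible (see *Limitations*).
* **niches** — `punctual` species respond to pixel values;
  `landscape_mean` to window means; `landscape_structure` to the local
  spatial autocorrelation of the window (a windowed Moran-type lag-1
  statistic: neighbour covariance over window variance). The structure
  statistic is invariant to additive shifts, rescaling and square
  rotations of the layer, is destroyed by pixel permutation, and is
  uncorrelated with the centre value for Gaussian fields (a third-moment
  symmetry) — it is therefore the cleanest possible carrier of
  "structure, not values". An earlier oriented (upper-minus-lower
  half-window) contrast was abandoned: random rotations annihilate an
  oriented signal, which contradicts the protocol's requirement that the
  rotation model stays in the strong group.
  Occurrence intensity is $\mathrm{softplus}(\sum_l w_l f_l + c)$ with
  weights scaled so the linear predictor has a target standard deviation
  (`signal`, default 3) over the map — comparable selectivity for all
  modes. The intercept $c$ (`offset`, default 0) controls niche breadth:
  a large negative offset yields hotspot specialists whose intensity is
  negligible outside the top of the linear predictor. This matters for
  top-1 style metrics: with diffuse softplus niches even the
  Bayes-optimal $MSA_1$ stays below $5/m$ (overlapping ridges), so the
  end-to-end learnability test world and the rare-species world use
  negative offsets. Niche directions are stratified (greedy farthest-point selection
  from random candidates) so a small community never degenerates into
  near-collinear niches by draw luck; optional **guilds** draw species
  weights around shared prototypes, the regime in which a jointly learnt
  representation can transfer to species with very few records.
* **abundances** — species counts are multinomial with probabilities
  $\propto$ rank$^{-\gamma}$ (long tail); locations are sampled
  proportional to intensity with sub-pixel jitter. The rank-frequency
  slope is recovered within ±0.2 in the tests. Splitting is uniform:
  10% test, then 10% of the remaining training records to validation —
  a rare species' sole record may land in test, exactly as in the
  reference protocol.

Everything is deterministic under a single integer seed.

## What the acceptance experiments establish (and what they do not)

The reference results were computed on ~98,000 occurrences of 4,520
species with an Inception-scale network on GPU. That regime is out of
scope; the tests reproduce the *protocol* at desk scale:

* **Information ordering.** On 256×256 worlds populated entirely by
  structure-niche species (the "dominated by landscape structure" regime),
  six models per seed — the CNN under each of the five transforms plus
  the punctual DNN — are trained on identical partitions for three seeds.
  The averaged $MSA_{30}$ must satisfy: every structure-preserving model
  (`none`, `rotation`, `standardize`) beats every structure-blind model
  (`mean`, `permutation`, DNN) by at least 0.05. Because the structure
  statistic is rotation-invariant, `rotation` sits in the strong group
  here by construction; in the reference study its position reflects the
  weaker role of orientation in real landscapes.
* **Rare species.** On a long-tail guild world of habitat specialists
  (250 species, guild prototypes, sharp niches with a negative offset —
  narrow hotspot distributions, which is how the reference study
  characterizes its rare species), the CNN's $SA_{30}$ averaged over
  species with ≤ 3 training records must exceed the random forest's.
  Community size matters for the honesty of this comparison: at small
  species counts the forest "wins" rare species through a
  zero-probability-cliff ranking artefact (any lucky leaf co-occurrence
  beats the mass of zero-probability species), and the CNN's transfer
  through shared guild features only outweighs that artefact once the
  community is large and niches are narrow. A green test establishes the
  direction of the effect, not its magnitude — per-species heads of
  1-3-record species receive little gradient in a plain cross-entropy
  run, so absolute rare-species accuracies remain small.
* The metric suite is verified against brute-force oracles exactly
  (pair counting for AUC, exhaustive threshold enumeration for TSS, direct
  indicator counting for $A_k$/$MSA_k$) on all small instances.

Known limitations of the synthetic testbed: a single landscape realization
is both training and testing ground, so any model can in principle exploit
realization-specific associations ("location coding") — the worlds are
sized, and layer correlation lengths chosen, to keep that channel small,
but it is not exactly zero; observation effort is uniform (the metric is
designed to be robust to effort bias, which is therefore not modelled);
and the desk-scale CNN is orders of magnitude smaller than the reference
backbone, so absolute metric values are not comparable to the reference
study — only the relative ordering of the ablated models is.

## Numerical choices

* Patch centre convention: the point's pixel sits at 0-based index
  $(p/2, p/2)$; even patches are slightly asymmetric, applied identically
  in tensors, punctual vectors and the constant-tensor encoding.
* Edge handling: windows overflowing a grid are padded with the layer's
  sentinel fill value rather than rejected.
* Probability floor $10^{-12}$ in the loss; overflow-safe softmax by
  max-subtraction; population (not sample) standard deviation in the
  structure-only ablation, with constant layers mapping to zero.
* Batch size 64, fan-in-scaled Gaussian initialization, all seeded;
  batched transforms draw rotation per occurrence and permutations per
  (epoch, batch) from counter-based keys.
* The coordinate convention is GeoTIFF-style: origin at the upper-left
  corner, row-major, 0-based pixel indexing internally, no reprojection
  (a CRS mismatch between rasters and occurrences is the caller's error).
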
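---
title: "Boundary-aware attention and growth-stage supervision for pest classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-aware attention and growth-stage supervision for pest classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Field identification of agricultural insect pests is a fine-grained
recognition task with three characteristic difficulties. First, distinct
species can be nearly indistinguishable while a single species changes its
appearance radically over its life cycle — a moth, a chrysalis, a caterpillar
and an egg cluster may all carry the same species label. Second, field images
are cluttered: leaf texture, uneven illumination and partial occlusion
compete with the subject. Third, field-collected datasets are long-tailed,
with a few dominant species and many rare ones. `pestnet` implements a
classifier designed around these three failure modes, together with a
synthetic-scene generator that reproduces them under controlled conditions so
every component can be exercised and tested on a desktop CPU.

## The model

### One-shot-aggregation backbone

The feature extractor is a 57-layer-style stack of one-shot-aggregation
(OSA) blocks. Each block applies five chained 3×3 convolutions
$y_i = \sigma(\mathrm{Conv}_i(y_{i-1}))$, $y_0 = f$, concatenates
$\{y_1,\dots,y_5\}$ once along channels, and projects back to the stage
width with a 1×1 convolution. The concatenation spans receptive fields from
3×3 to 11×11, giving multi-scale features at the cost of a single fusion.
Following the equations literally, the block input is *not* part of the
concatenation. The default staging is stem 64/64/128 (strides 2/1/2), stage
widths 128/160/192/224 per layer with outputs 256/512/768/1024 and 1/1/4/3
blocks, 2×2 max-pool between stages; a 224×224 input ends at 7×7×1024.

Two implementation choices differ from common GPU practice and are
deliberate. Convolutions carry biases and there are **no normalization
layers**: the package implements its forward/backward passes natively on
CPU, where batch statistics buy little and bit-exact eval-mode determinism
is a tested contract. And the published parameter budget of the full model
(35.65 M with the 168-class training head) is reproduced exactly under this
convention — see "Parameter budget" below.

### Boundary-aware channel-spatial attention (BCSA)

After every stage, a BCSA module re-weights the feature map
$f \in \mathbb{R}^{C\times H\times W}$:

* **Channel gate.** Global average pooling $\mu(f)$ and global
  standard-deviation pooling $\sigma(f)$ (population convention, divisor
  $HW$) form a $2C$ descriptor; a single learnable transform $W_c$ plus
  logistic squashing yields $g_c = \mathrm{sigmoid}(W_c[\mu,\sigma])$.
  The second-order term lets the gate distinguish uniformly active channels
  from spatially peaked ones.
* **Spatial gate.** Fixed (non-trainable) Sobel kernels applied depthwise
  give edge responses $E_x$, $E_y$; their sum is fused by a learnable
  convolution stack $W_s$ (3×3 $C\to 50$, rectifier, 3×3 $50\to 1$) and
  squashed: $g_s = \mathrm{sigmoid}(W_s(E_x + E_y))$. The fixed edge prior
  directs spatial attention toward object boundaries rather than letting it
  discover saliency from scratch.
* **Residual fusion.**
  $\mathrm{out} = f\,(1 + \alpha g_c)(1 + \beta g_s)$, with $g_c$ broadcast
  over space and $g_s$ over channels. At $\alpha=\beta=0$ the module is the
  exact identity (asserted bit-exactly in the tests), so attention can only
  amplify — never erase — the underlying features, and the output is bounded
  by $(1+\alpha)(1+\beta)\,|f|$.

The gains default to $\alpha=\beta=1$ (symmetric contribution; no values are
prescribed) and are exposed for ablation. Sobel same-padding leaves edge
artifacts on the one-pixel border; tests therefore assert interior pixels
only.

### Generalized p-norm pooling (GPP)

The head pools each channel with the power mean
$\mathrm{GPP}(x) = \left(\tfrac{1}{HW}\sum_{h,w} x_{h,w}^{\,p}\right)^{1/p}$,
a learnable interpolation between average pooling ($p=1$, proven in the
tests to within $10^{-6}$) and max pooling ($p\to\infty$). Numerical
choices: activations are clamped to $\ge 10^{-6}$ before exponentiation
(fractional powers of negatives are undefined; the head follows a rectified
map, so the clamp is inert in practice); the learnable scalar is
unconstrained with the effective exponent $\max(p_\mathrm{raw}, 0.5)$ — the
0.5 floor admits the smoother-than-average regime while preventing the
$p \to 0$ blow-up; initialization is $p=3$, the generalized-mean pooling
convention. One scalar is shared across channels, matching the single-symbol
form of the pooling equation.

### Scheduled loss

Training minimizes
$L = \lambda\,L_\mathrm{CE} + (1-\lambda)\,L_\mathrm{FL}$ with
$\lambda(t) = \lambda_{\max}(1 - t/T)$ over a 0-based epoch counter $t$
(the schedule is written in epochs, so it advances per epoch, not per
step). Early training is dominated by label-smoothed cross-entropy
(smoothing 0.1, $\varepsilon/K$-uniform convention — the target keeps
$1-\varepsilon+\varepsilon/K$; the convention is stated because two exist),
handing over linearly to the focal term
$-(1-p_t)^\gamma \log p_t$ that concentrates gradient on hard, often
minority-class, samples. Unstated constants resolved here:
$\lambda_{\max} = 1$ (training starts purely on CE for stability) and
$\gamma = 2$ (the standard focal default); no per-class $\alpha$-balancing,
since the schedule itself is the imbalance mechanism. Smoothing applies to
the CE term only — focal's $p_t$ is defined on hard targets.

### Growth-stage label refinement

Stage annotations (Adult/Larva/Pupa/Egg) refine the species label space at
training time: every (species, stage) subgroup with **strictly more than**
`min_count` images (30 by default) becomes its own training class; all other
samples of the species — under-threshold stages and unannotated images —
share one residual class. Splitting small subgroups would create classes too
thin to learn, hence the threshold. Where the residual would be empty it is
not created, so no class starts with zero samples. Refined indices are
assigned deterministically (ascending species; stages Adult < Larva < Pupa
< Egg; residual last), making class IDs reproducible across runs and input
orders.

At inference, refined predictions are collapsed to species: by default the
refined argmax is mapped through `parent_of` (the simplest reading of
"mapped back"); probability summation per species is available as
`sum_probs`. Ties break toward the lowest class index for determinism.
Species-level accuracy can only gain from collapsing (errors merge only
within a species), a property the tests assert on every evaluation.

## Training engine

AdamW (decoupled weight decay $5\times 10^{-4}$) at learning rate
$10^{-3}$, $\beta = (0.9, 0.999)$, batch size 32, up to 500 epochs. The
warm-up length is not prescribed beyond "default configuration"; the package
uses 5 epochs, linear from lr/100 to lr, and logs the rate per epoch so the
choice is auditable. Early stopping monitors validation **species-level**
accuracy (the headline metric) with patience 30. Preprocessing: resize the
shorter side to $1.1\times$ the input size, random crop (training) or center
crop (evaluation), normalize with the ImageNet channel statistics. All
randomness — initialization, shuffling, crops — derives from one seed;
on CPU two runs with the same configuration produce identical epoch logs
(tolerance zero, tested).

## The synthetic world

The generator stands in for a large field-collected benchmark that cannot be
bundled. It emulates, with one knob each:

* **stage morphology** — four geometrically distinct shapes per species
  (winged adult, ovoid pupa, segmented larva, egg cluster of disjoint
  discs) sharing a species hue/aspect/stripe archetype, so stages of one
  species differ more in shape than same-stage species differ in color;
* **clutter** — oriented sinusoid gratings whose amplitude scales with
  `clutter_level` (exactly flat at 0), with per-image clutter recorded in
  the manifest so the most-cluttered-k-per-class evaluation subset can be
  reproduced;
* **occlusion and illumination** — a foreground band over at most ~40% of
  the specimen with probability `occlusion_prob`; a global illumination
  multiplier per image;
* **long tail** — species counts $\propto i^{-q}$ with $q = 1.5$ by
  default, giving a largest/smallest ratio above 5 from six species.

Defaults are fixed once: 64×64 images (224 available), stage mix
45/30/10/10% plus 5% unannotated, split 60/10/30 stratified by species.
The smoke-test world (4 species, 100 images for the head species, clutter
0.1, occlusion 0.1, balanced) uses the low-clutter setting its criterion
states; 100 images per species keeps the validation split large enough that
a 95% accuracy bound is meaningful rather than an all-or-nothing handful.

What a green test does *not* establish: the sprites are hue-separable by
construction, so synthetic accuracy says nothing about accuracy on real
imagery; backgrounds are stationary textures, not scenes; there is no
camera noise, scale extremes, or inter-species mimicry. The synthetic runs
validate the machinery — gradients, schedules, label plumbing, metrics —
not field performance.

## Parameter budget

The printed budget of the full model is 35.65 M parameters. With the
published staging fixed, the remaining freedom is the attention fusion
capacity; the package resolves it as: bias-carrying, normalization-free
convolutions and a 50-channel hidden layer in the spatial edge fusion.
The count then lands at 35,650,301 — 35.65 M at the printed precision —
decomposed as backbone 30,389,376, channel transforms 3,934,720, spatial
fusion 1,154,004, pooling exponent 1, and 168-class head 172,200. The test
suite asserts the total; the acceptance script recomputes it from a freshly
built model.

## Numerical choices and degenerate inputs

* Standard-deviation pooling guards its backward pass with
  $\max(\sigma, 10^{-8})$ so constant channels do not produce infinite
  gradients (the forward value stays exactly 0).
* The GPP backward cuts the raw-exponent gradient to 0 below the 0.5 floor
  (subgradient of the clamp).
* Probability inputs to the loss functions must row-sum to 1 within
  $10^{-4}$; logarithms are clamped at $10^{-12}$.
* Precision/recall 0/0 cases resolve to F1 = 0 (standard macro-F1 practice
  under imbalance); classes with no true samples are flagged in the report
  and carry zero weight in weighted F1.
* The paired-classifier comparison uses the *exact* two-sided binomial
  McNemar test, $p = \min(1,\, 2\,P(X \le \min(b,c)))$,
  $X \sim \mathrm{Bin}(b+c, \tfrac12)$ — not the χ² approximation.
* Empty evaluation sets, out-of-range labels, non-normalized probability
  vectors, shape-mismatched pretrained keys, and unknown YAML keys are all
  hard errors; nothing is silently coerced.

## Limitations

The engine is single-threaded CPU R/C++; the full-size model is practical
for forward passes and parameter accounting, but training it at 224 px is
out of desk-scale reach — training runs use the reduced backbone. JPEG
input is not supported (PNG only). Pretrained weight files are *loaded* by
name from a key→tensor archive but no weights are distributed. Benchmark
accuracies on real pest datasets are expressly out of scope: nothing in the
test suite claims them.
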
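---
title: "Sparse deconvolution of cellular-resolution spatial transcriptomics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse deconvolution: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sequencing-based spatial transcriptomics platforms with ~10 µm capture
elements (Stereo-seq, Slide-seqV2, Pixel-seq) profile hundreds of
thousands of spots, each covering only one to a few cells, with mean total
UMI counts per spot often below a few hundred. Deconvolution — inferring
which cell types contribute to each spot, and in what proportion — must
therefore cope with (i) very shallow, overdispersed counts, (ii) genuinely
*sparse* compositions (a spot rarely contains more than a handful of
types), and (iii) dataset sizes that rule out per-spot optimization.

`spotsparse` addresses this with an amortized variational encoder–decoder
trained by mini-batches, so cost per spot is a constant number of matrix
products, plus a sparsemax output layer that produces exact zeros in the
inferred compositions.

## Generative model

For spot $i$ and gene $g$, with $T$ cell types:

$$z_i \sim N(0, I), \qquad Z_i = E_\sigma(X_i)\, z_i + E_\mu(X_i),
\qquad Y_i = D_\omega(Z_i),$$
$$\mu_{ig} = \ell_i\Big(s_g \sum_{t=1}^{T} y_{it}\, u_{tg} + \gamma_g\Big),
\qquad X_{ig} \sim \mathrm{NB}(\mu_{ig}, \beta_g).$$

* $u_{tg}$ — mean expression of gene $g$ in type $t$, and $\beta_g$ — the
  gene-wise NB inverse-dispersion; both are estimated from a labelled
  scRNA-seq reference (below) and **frozen** during training.
* $s_g > 0$ (gene-specific scaling) and $\gamma_g \ge 0$ (gene-specific
  additive noise) absorb platform effects between the reference and the
  spatial assay; they are trainable, parameterized as $e^{\cdot}$ and
  $\mathrm{softplus}(\cdot)$ to respect their domains.
* $\ell_i$ is a fixed per-spot size factor (total count / median total
  count). The mixing equation has no natural per-spot scale, and without
  $\ell_i$ the proportions would have to absorb sequencing-depth
  differences; this is a deliberate design choice, switchable off with
  `use_size_factor = FALSE` for uniform-depth data.

The NB parameterization is fixed package-wide as mean/inverse-dispersion:
$\mathrm{Var}(X) = \mu + \mu^2/\beta$, the convention standard in
single-cell count modelling. `likelihood = "poisson"` and
`likelihood = "zinb"` (gene-wise trainable dropout $\tau_g$) are provided
as alternative observation models; in our experiments, as in the wider
literature, plain NB suffices.

The decoder output layer is **sparsemax** — the Euclidean projection of
the $T$ logits onto the probability simplex. Unlike softmax it returns
exact zeros, so inferred compositions are sparse by construction rather
than by thresholding. The projection is unique; coordinates exactly at the
threshold receive the projected value, so no tie-breaking rule is needed.

## Inference and objective

The posterior $p(Z_i \mid X_i)$ is approximated by the diagonal Gaussian
$q_\phi(Z_i \mid X_i) = N(E_\mu(X_i), \mathrm{diag}\,E_\sigma(X_i)^2)$,
trained by minimizing per spot

$$\mathcal{L} = D_{\mathrm{KL}}\!\big(q_\phi(Z_i|X_i)\,\|\,N(0,I)\big)
  \;-\; \mathbb{E}_{q_\phi}\!\big[\log p_\theta(X_i \mid Z_i)\big],$$

the negative evidence lower bound, with a single Monte-Carlo sample of
$Z_i$ per spot per step (standard VAE practice) and the closed-form KL.
Trainable parameters are $\phi$ (encoder), $\omega$ (decoder) and
$(s, \gamma)$; gradients are exact analytic backpropagation (verified
against finite differences to ~1e-7 in the test suite).

**Pseudo-spot supervision.** Because the decoder's output is never
observed, training is anchored with pseudo-spots: pools of $k \sim
\mathrm{Uniform}\{1..5\}$ reference cells drawn uniformly without
replacement, counts summed and binomially thinned to the median total UMI
of the spatial dataset, with ground-truth proportions defined as
cell-count fractions. Each mini-batch mixes real spots (ELBO terms) with
pseudo-spots (ELBO plus a supervised term), in proportion `pseudo_ratio`
(default 0.5). The supervised loss is the mean per-spot L1 distance
between predicted and true proportions: it is robust, bounded by 2, and —
unlike cross-entropy — well-defined when sparsemax places exact zeros off
the true support. Joint training is the default; `pretrain_epochs` offers
a supervised-only warm-up for very small datasets.

At inference time no sampling occurs: spots are decoded from the posterior
mean $Z = E_\mu(X)$, so `deconvolve()` is deterministic and repeatable.

## Reference signature estimation

`estimate_signatures()` fits, per gene, cell-type means with cell-specific
library offsets and one shared inverse-dispersion:
$x_{cg} \sim \mathrm{NB}(o_c\, u_{t(c)g}, \beta_g)$ with
$o_c = \text{total}_c / \mathrm{median}(\text{total})$, so $u$ lives on a
"median library" scale. Maximization alternates damped Newton steps on
$\log u$ (concave in $\log u$, so steps with halving are safe) and on
$\log \beta$, each guarded by a line search so the log-likelihood is
non-decreasing — a property the tests assert. Convergence is declared at
relative log-likelihood change below `tol` (default 1e-6). Genes silent in
a type get $u_{tg}=0$ exactly; genes silent everywhere keep $u=0$ and the
dispersion floor. $\beta$ is clamped to $[10^{-3}, 10^{4}]$ as numerical
hygiene for the Gamma-function evaluations. Whether to use raw or
normalized reference counts, and which offset convention to take, was an
open choice; raw counts with median-normalized total-count offsets make
$u$ directly comparable across cells and match the spatial model's size
factors.

## Architecture and numerical defaults

| parameter | default | rationale |
|---|---|---|
| hidden layers | 2 × 128 ReLU (encoder and decoder) | small enough for CPU training, expressive enough for hundreds of genes |
| latent dim $D$ | 10 | compositions of ≤ a few dozen types are low-dimensional |
| encoder input | `log1p(counts)` | raw counts are heavy-tailed |
| $\sigma$ floor | 1e-4; $\mu$ floor 1e-8 | keep likelihoods and KL finite |
| optimizer | Adam, lr 1e-3, batch 128, 100 epochs | standard for this model family |
| loss weights | KL 1, supervised 1, pseudo ratio 0.5 | unweighted objective; all flags |
| early stopping | 10% pseudo-spot validation split, patience 10, best weights restored | guards against overfitting the reconstruction term |
| gradient clip | global norm 10 | the NB score $x/\mu$ can spike early in training |
| initialization | He-normal; $s$ started at (median spot depth)/(signature depth) | puts the likelihood on scale immediately |

A single `seed` in `training_config()` controls initialization, batch
shuffling and the reparameterization draws, so training is reproducible
end-to-end.

## Synthetic data: what it emulates, what it does not

`simulate_reference()`/`simulate_tissue()` generate a fully known study:
log-normal per-type signatures sharing a per-gene baseline, with disjoint
6-fold upregulated marker sets per type; NB counts with gene dispersions
$\beta \sim U(2, 20)$; reference cells at ~1000 total UMI with log-normal
(sd 0.3) library sizes; tissues of 2000 spots at mean 100 total UMI laid
out in horizontal bands with soft borders (mimicking laminar structures
such as cortical layers), at most 3 cell types per spot with band-dependent
type probabilities, and log-normal per-spot depth so the size-factor path
is exercised. The default sizes (T = 5, G = 300, N = 2000, 200 cells per
type for tissue studies; 3 types × 500 cells × 200 genes for signature
recovery) are the sizes at which the package's own acceptance checks run.

The generator deliberately matches the model's count family, which is the
right design for testing *estimation* — recovery failures then indicate
implementation error, not model misfit. The flip side is what passing
tests do **not** show: real platforms add segmentation error, bead/bin
diffusion, cell-type-correlated capture efficiency, and reference-spatial
batch effects far richer than a gene-wise $(s_g, \gamma_g)$ pair. Passing
recovery thresholds on synthetic tissue demonstrates correct mechanics,
not real-data performance.

## Evaluation metrics

With no ground truth in real tissue, the package evaluates inferred
proportions indirectly:

* **Marker correlation** — Spearman rank correlation (average ranks on
  ties) between a type's proportion field and each of its marker genes
  across spots. Zero-variance inputs yield `NA`, excluded from summaries
  rather than imputed as 0. At 100 UMI per spot these correlations are
  intrinsically modest even for perfect recovery — marker counts are
  mostly 0/1 — which is why medians around 0.4 on synthetic tissue are
  expected and healthy.
* **Moran's I** — spatial autocorrelation of each proportion field on a
  k-nearest-neighbour graph (default k = 6) with row-standardized binary
  weights; the weight scheme is a package choice. Constant fields are
  `NA`.
* **Jensen–Shannon distance** — base-2, square-rooted, a metric in
  [0, 1]. The comparator for a spot's composition is not canonically
  defined; the package uses the marker-derived composition (each type
  scored by the mean expression of its markers at that spot, normalized
  across types), documented so the number is interpretable.

## Degenerate inputs and edge behaviour

All-zero spots and all-zero batches produce finite losses ($\mu$ floored);
an all-zero gene keeps its aligned column with $u = 0$; `epochs = 0`
returns the model untouched; an empty gene intersection between reference
and spatial data is an error, as is a cell type with fewer than two
reference cells (named in the message). Gene alignment orders the shared
genes lexicographically — the data impose no order, and determinism
matters for reproducible training. NaN losses abort with the epoch and
batch identified rather than training on.

## Known limitations

* The decoder is deterministic given $Z$; no uncertainty is attached to
  the inferred proportions.
* Spots are conditionally independent — no spatial smoothness prior on
  $Y$; coordinates are used only for evaluation.
* $u$ and $\beta$ are frozen at reference estimates; a poor or mismatched
  reference propagates directly into the deconvolution.
* Pure R training: fine at 10^3–10^4 spots and a few hundred genes
  (seconds to minutes on one CPU core), but the package does not target
  the 10^5-spot regime that GPU implementations of this model family
  handle.

## A worked run

```{r example}
library(spotsparse)

cfg <- sim_config(seed = 42)
ref <- simulate_reference(cfg)
tis <- simulate_tissue(cfg, ref$profile)

prof <- estimate_signatures(ref$counts, ref$labels)
ps <- generate_pseudo_spots(ref$counts, ref$labels, n_spots = 2000,
                            cells_per_spot = c(1, 3),
                            target_umi = median(rowSums(tis$counts)),
                            seed = 43)
model <- variational_model(prof, seed = 1)
fit <- train(model, tis$counts, ps, training_config(seed = 1))
Y <- deconvolve(fit, tis$counts)

diag(cor(Y, tis$props))        # per-type recovery
mean(rowSums(abs(Y - tis$props)))  # mean per-spot L1 error
plot_proportions(Y, tis$coords)
```

The same pipeline is exposed as shell subcommands (`simulate`,
`signatures`, `pseudospots`, `deconvolve`, `evaluate`) through
`spotsparse_cli()` / the installed `exec/spotsparse` script.
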
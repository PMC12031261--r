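---
title: "Two-phase rosette MRI reconstruction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase rosette MRI reconstruction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rosetteRecon)
```

## The problem

Rosette trajectories sample k-space along petal-shaped lobes that repeatedly
pass through the origin. They cover k-space efficiently and tolerate high
acceleration factors, but they are non-Cartesian: a plain inverse FFT does
not apply, and classical gridding reconstructions need density compensation
and still degrade under undersampling. This package implements a two-phase
reconstruction: a cheap physics-based initial approximation — density
compensated adjoint gridding of the multi-coil samples, combined by root sum
of squares (RSS) — followed by a learned refinement with a vision transformer
(ViT) whose output is cleaned up by a single trailing convolution. The
package also contains everything needed to exercise the pipeline end to end
without scanner data: a phantom simulator with complex coil sensitivities, an
exact forward model, a CG-SENSE reference reconstructor, a training loop, and
a patch-based image-quality evaluation suite.

## Trajectory model

The rosette is parameterized as
$k(t) = k_{max}\,\sin(2\pi w_1 t)\,e^{i 2\pi w_2 t}$,
with the radial frequency $w_1$ (Hz) driving the oscillation between the
origin and the rim $|k| = k_{max}$, and the angular frequency $w_2$ rotating
the lobe. One petal spans a radial half-period $t \in [0, 1/(2w_1))$, so
every petal starts at the origin and touches the rim; even sample counts put
one sample exactly on the rim. Defaults follow a 7T brain acquisition:
$k_{max} = 1000\,\mathrm{m}^{-1}$, $w_1 = w_2 = 400$ Hz, 189 petals,
acceleration 4.

Two per-petal phase schedules are provided. The default, `uniform`, spaces
petal rotations evenly over $[0, \pi)$, emulating a multi-shot acquisition in
which each petal is a separately rotated shot. The alternative, `continuous`,
uses the phase the $w_2$ carrier accumulates up to the petal's start time;
it makes $w_2 = 0$ collapse all petals onto one diameter (a useful sanity
case) but degenerates whenever $w_2/w_1$ is an integer — with the default
$w_1 = w_2$ the curve retraces a single circle — which is why it is not the
default. Acceleration is realized as petal subsampling (evenly spaced petal
indices by default), since the acquisition distributes its shots over the
full angular range regardless of the acceleration factor.

## Gridding engine and density compensation

The non-uniform Fourier transforms are Kaiser–Bessel gridding interpolations
on a 1.5x oversampled grid with a width-6 kernel (Beatty shape parameter),
deapodized by the kernel's analytic Fourier transform. Width 6 was chosen so
that the worst-case (white-noise image) forward error against the literal
DFT sum stays below $10^{-4}$; width 4 at this oversampling measures around
$4\times10^{-3}$ and was rejected. The adjoint is the exact algebraic
transpose of the forward interpolation, so the inner-product identity holds
to rounding error — the test suite checks both engines against an explicit
DFT oracle that evaluates the defining sums literally. Frequencies beyond
the Nyquist square are accepted: the discrete spectrum is 1-periodic in
cycles/pixel, and the mod-$G$ index wrap realizes exactly that aliasing, so
corner-covering acquisitions are valid inputs.

Density compensation offers three estimators. `pipe_menon` iterates
$w \leftarrow w / C(w)$ with $C$ the gridding-kernel convolution, on a grid
twice as fine as the image grid — at image resolution the width-6 kernel is
too blunt to resolve the density spike where all petals converge at the
origin (measured: dense-trajectory recon error drops from 0.24 to 0.01 when
the density grid is doubled). `voronoi` rasterizes the Nyquist square and
assigns each cell to its nearest sample, a deterministic approximation of
Voronoi cell areas, clipped at `clip_radius`; coincident samples (the shared
petal origins) must be merged first with `dedupe_trajectory()`. `analytic_radial`
is the classical $|k|$-proportional heuristic. All three are finally rescaled
to unit DC gain of the compensated adjoint–forward chain, i.e. a constant
image is reproduced at unit amplitude; this normalization, rather than a
unit *central* point-spread value, is what makes the compensated adjoint an
approximate inverse on dense trajectories (a unit central value would
over-scale smooth regions by the reciprocal k-space coverage fraction,
about 1.27 at Nyquist spacing).

## Reference reconstruction

`cg_sense()` solves the density-weighted, l2-regularized normal equations
$(A^H W A + \lambda I)x = A^H W b$ with the conjugate *residual* variant of
the conjugate-gradient family. CR minimizes the residual norm over the
Krylov space at each step, so the logged residual is non-increasing by
construction; plain CG's residual norm oscillates (we measured increases of
up to 12% between iterations on well-conditioned SENSE systems). l1/TV
regularization is deliberately out of scope; on synthetic data the ground
truth is available, and the l2 solver is only needed as a reference and as
an optional training target.

## The refinement network

The network follows the reconstruction-ViT design: non-overlapping
`patch_size^2` patches are linearly embedded into `embed_dim` features,
learned position embeddings are added (no classification token), and `depth`
pre-norm encoder layers (multi-head self-attention + GELU MLP, residual
connections, layer norm before every block, a final layer norm) feed a
per-patch linear reconstruction head that maps features back to pixels. A
single dimension-preserving 3x3 convolution (stride 1, zero padding,
delta-initialized so it starts as the identity) follows the reassembled
image; its role is to remove the "miscolored patch" artifacts with sharp
boundaries that the patchwise head otherwise leaves at high-contrast edges.
Images whose side is not a patch multiple are symmetrically zero-padded and
exactly cropped back (512 pads to 520 and splits into 2704 patches of 10x10
at the full-scale configuration), preserving pixel fidelity; resizing was
rejected because it blurs the target of a per-pixel loss.

The window-based variant (WBSA) partitions the patch grid into
`window_size`-by-`window_size` windows and attends within each window;
alternating layers shift the partition cyclically by half a window
(Swin-style). No attention mask is applied across the cyclic seam — at desk
scale the seam couples periodic neighbors, which is harmless for
magnitude-image refinement and keeps the code path identical for forward
and backward. A window at least as large as the patch grid reduces WBSA to
global attention exactly (attention is permutation-equivariant), which the
tests exploit.

Forward and backward passes are implemented directly in R with matrix
algebra; the analytic gradients of every component (layer norm, softmax
attention, GELU MLP, patch embedding, head, convolution) are verified
against central finite differences at $10^{-4}$ relative in the test suite.
Mixed precision, GPUs and multi-device training are out of scope; at the
package's desk scale (64x64 images, ~50k parameters) a full training run is
a couple of minutes on one CPU.

## Training

Adam (default betas) under a 1cycle schedule with peak learning rate
3e-4 (cosine warmup over the first 30% of steps from peak/25, cosine anneal
to peak/1e4), up to 20 epochs with best-validation checkpointing, MSE loss
by default (L1 optional), one item in five held out for validation. The
augmentation set mirrors standard practice for this task: random horizontal
and vertical flips (p = 0.5 each), rotation up to 180 degrees, random
resized crop with area scale 0.3–1.1, and brightness/contrast jitter in
0.8–1.2 applied to the network input only (the target stays the reference
to be predicted); saturation jitter is meaningless on single-channel
magnitude images and is omitted. One geometric draw is applied identically
to input and target. `multiplicity = 3` iterates three independently
augmented copies of the training set per epoch ("triple augmentation").
For the desk-scale study the augmentation is restricted to flips with
triple multiplicity: the rough images' aliasing structure is tied to the
one fixed trajectory, which is (approximately) symmetric under axis flips
but not under arbitrary rotations or rescaling, so rotations, crops and
jitter move the 200-phantom training distribution away from what the
network must learn at evaluation time and measurably slow convergence,
while flips triple the optimizer steps per epoch at preserved statistics.
The full augmentation list remains available (and sensible) for larger,
more varied corpora.

## The synthetic study

The generator emulates the acquisition at desk scale. Phantoms are sums of
ellipses on $[-1,1]^2$ (a modified Shepp–Logan head preset plus seeded
random variants with one head-like outer ellipse and six signed interior
ellipses), rasterized, clipped at zero and scaled to $[0,1]$. Coil
sensitivities are Gaussian lobes centered just outside the FOV perimeter
with smooth low-order phase, RSS-normalized on their support; four coils at
a 64-grid scale the 32-channel head coil by the 64/512 resolution ratio.
The fully sampled trajectory uses 48 petals at 64x64 — the same fraction of
the radial Nyquist petal count ($\approx \pi N / 2$) as 189 petals are at
512 — and acceleration 4 retains 12 petals. K-space noise is zero-mean
complex Gaussian per sample; because absolute scanner k-space magnitudes
are hardware-specific, noise may be specified as a noise-to-signal power
fraction, and the equivalent absolute per-component variance is recorded.
The noise-robustness sweep uses power fractions {0, 1e-3, 1e-2, 5e-2}
spanning clean to visibly degraded inputs.

Training pairs are (rough, truth): the rough image is the density
compensated adjoint + RSS of the simulated accelerated acquisition, and the
target is the noiseless phantom magnitude, both scaled by the target
maximum. The ground-truth target was preferred over a CG-SENSE target
because on synthetic data the true image is available and any solver output
is only a proxy for it; a `target = "cg_sense"` mode mirrors the
reference-trained setup when wanted. Batch size 1 is the study default:
with the learning rate and epoch cap fixed, the tiny network is
optimization-limited, and maximizing 1cycle steps (480 per epoch under
flip-only triple augmentation) is what converges within the budget. A
useful capacity bound guided these choices: projecting the target images'
8x8 patches onto their best rank-32 basis (the embedding width) leaves
about 8% NRMSE, so the architecture has room below the ~12% the trained
network reaches, and shortfalls are optimization, not representation.

What passing the desk-scale study does and does not show: the synthetic
phantoms are piecewise-constant, noise-free, perfectly coil-calibrated and
share one trajectory, so the measured ~30%+ NRMSE improvement of the
refined over the rough image demonstrates that the pipeline's mechanics
(simulation, gridding, training, refinement, evaluation) work and that the
network learns the trajectory's aliasing structure — not that the
architecture reaches scanner-data quality, which requires the full-scale
configuration (patch 10, depth 10, heads 16, embedding 80) and real
training corpora.

## Evaluation protocol

Metrics are computed on six 50x50-pixel patches whose centers are drawn
from a truncated Gaussian about the image center ($\sigma$ = image/6,
redrawn until the patch fits) to avoid empty background, then averaged.
The suite: Gaussian-windowed SSIM (11x11, $\sigma$ 1.5, $c_i = (k_i L)^2$
with $k_1 = 0.01$, $k_2 = 0.03$); NRMSE normalized by the *reference*
patch's intensity range; PSNR in dB against the dynamic range; NMI from a
64-bin joint histogram with shared edges over the pooled range; relative
contrast $(\max-\min)/(\max+\min)$; Shannon entropy over 256 bins; and the
entropy focus criterion in its standard energy-normalized form
$E = -\sum (x_j/x_{max})\ln(x_j/x_{max})$, $x_{max} = \sqrt{\sum x_j^2}$.
Every metric is checked against a naive double-loop oracle. Undefined
cases (zero-range reference, constant regions, all-zero patches) raise
errors at the metric level and are recorded as missing — never as zero —
by the report aggregator.

Method comparisons use one-way repeated-measures ANOVA per metric (items
as the repeated unit) plus all pairwise paired t-tests, flagged at the
Bonferroni threshold $0.05/k$ for $k$ comparisons ($k = 6 \Rightarrow
\alpha = 0.0083$). Per-image patch-averaged scores are the pairing unit.

## Numerical choices and degenerate inputs

Layer-norm epsilon 1e-5; softmax rows are max-subtracted; Adam epsilon
1e-8; CR iterations stop at a relative residual of `tol` or `max_iters`
(returning the best iterate with a warning). Gridding requires even grid
sizes (quadrant-swap FFT shifts). Zero k-space data reconstruct to zero
images without iteration. Trajectories exceeding `kmax` are rejected at
construction; duplicate samples are legal everywhere except the Voronoi
estimator, which demands deduplication. All random draws (phantoms, coils,
noise, splits, shuffles, patch sampling, init) descend from explicit seeds
through a splitmix-style stream derivation, making every pipeline product
bit-reproducible from one seed.

## Known limitations

No T1 contrast, motion, off-resonance or eddy-current simulation; no coil
sensitivity estimation from data; no l1/TV compressed sensing; no 3D
trajectories or gradient-hardware feasibility checks; single-channel
magnitude images only. The Voronoi weights are raster approximations
(exact cell geometry would need a computational-geometry dependency). The
WBSA seam is unmasked, as noted above. The container format is a
package-specific binary layout (documented in `?write_kspace_container`)
rather than a community standard.
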
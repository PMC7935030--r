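---
title: "Directed connectivity pipelines with phase transfer entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed connectivity pipelines with phase transfer entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ptenet implements a complete resting-state directed-connectivity analysis
for multichannel oscillatory time series (EEG source time series being the
motivating case): phase transfer entropy (PTE) networks per subject and
session, surrogate-based edge denoising, network-based statistics (NBS) on
paired pre/post cohorts, and graph-theoretical characterization with
density-adjusted group statistics. This vignette explains the model behind
each stage, the tunable parameters and their defaults, the numerical
choices, and what the packaged synthetic data can and cannot tell you about
real recordings.

## The estimator: phase transfer entropy

Transfer entropy from a source signal $x$ to a target $y$ at prediction
delay $\delta$ is the conditional mutual information

$$\mathrm{TE}_{x \to y} = \sum p(y_{t+\delta}, y_t, x_t)\,
  \log \frac{p(y_{t+\delta} \mid y_t, x_t)}{p(y_{t+\delta} \mid y_t)},$$

i.e. the information the source's present adds about the target's future
beyond the target's own present. *Phase* transfer entropy applies this to
instantaneous phases: each channel is band-passed to the analysis band
(0.53–35 Hz by default), its analytic signal is obtained by the Hilbert
transform, and the phase angle series (radians in $[-\pi, \pi)$) enters the
TE formula. Probabilities are estimated by plain histogram counts of the
binned phase triplets — no kernel smoothing and no bias correction, because
the surrogate stage (below) absorbs estimator bias. Values are reported in
nats; tiny negative estimates from finite samples are clipped to zero.

Two estimator parameters matter:

* **Prediction delay $\delta$** (samples). The underlying study does not
  report its value, so results are exposed as $\delta$-parameterized. The
  default ties the delay to the fastest phase dynamics in the band,
  $\delta = \max(1, \mathrm{round}(f_s / 2 f_{hi}))$ ($f_{hi}$ = upper band
  edge; 4 samples at 256 Hz). The sign-change heuristic familiar from the
  directed-PTE literature (samples × channels / number of phase sign
  changes) is available as `delay_mode = "sign_change"`.
* **Bin count.** Scott's rule on the pooled phase distribution of the two
  series in a pair: $h = 3.49\,\hat\sigma N^{-1/3}$, bin count
  $\lceil 2\pi/h \rceil$, with edges anchored on $[-\pi, \pi)$. Pooling
  makes $\mathrm{PTE}_{x\to y}$ and $\mathrm{PTE}_{y\to x}$ comparable.
  (For roughly uniform phases this gives 13 bins at 1,024-sample segments —
  histogram TE at this sample size carries a large additive bias, which is
  precisely why pruning is done against surrogates computed by the
  *identical* estimator path.)

Phases are extracted once per recording, before segmentation, and the phase
series is then cut into segments. This avoids per-segment edge artifacts of
the analytic signal; since the real and surrogate paths share the
convention, the choice does not bias the pruning comparison. Exact offset
invariance of the estimator holds for phase offsets that are multiples of
the bin width (counts permute); arbitrary offsets perturb the estimate at
finite sample size because the bin edges are anchored, not data-driven.

## Per-subject networks

Each recording is denoised by zero-phase Butterworth IIR filters (0.53 Hz
high-pass, 48–52 Hz notch, 97 Hz low-pass by default), then band-passed to
the analysis band. Forward–backward application makes the net filter
zero-phase, which protects the phase estimates PTE depends on; signals are
demeaned and padded by odd reflection so edge transients stay out of the
data. Fifteen non-overlapping four-second segments are selected uniformly
at random from the partitioned recording (seeded), one PTE matrix is
computed per segment, and the matrices are averaged into the
subject/session network: entry $(i, j)$ is the flow $i \to j$, the diagonal
is zero.

## Surrogate pruning

Histogram TE is biased upward, and genuine coupling must be separated from
that noise floor. For each subject and session the package builds an
ensemble of phase-randomized surrogates: the Fourier magnitudes of each
channel are kept, the positive-frequency phases are replaced by i.i.d.
uniform draws (DC and Nyquist untouched, conjugate symmetry preserved), and
the surrogate is pushed through the *identical* segmentation / phase / PTE
/ averaging path. This preserves each channel's amplitude spectrum and
autocorrelation while destroying cross-channel coupling. Internally, the
surrogate's analytic signal is obtained directly by applying the Hilbert
mask in the randomized spectrum (one inverse FFT), with the forward
spectrum shared across the ensemble; the result is numerically identical to
randomizing first and transforming afterwards, and uniform phases are drawn
as normalized Gaussian pairs.

An edge is removed when its real weight is exceeded (by more than a
tolerance, $10^{-3}$ by default) by more than
$\lfloor \alpha\, n_{\mathrm{sur}} \rfloor$ surrogate weights at the same
position — with 1,000 surrogates at the 5% level, the classic "worse than
more than 50 surrogates" criterion. Ties within the tolerance favor
retention; retained weights are never altered. The comparison is
positional (edge $(i,j)$ against surrogate edge $(i,j)$), following the
edge-by-edge wording of the underlying procedure. The full-study setting is
1,000 surrogates per subject and session; the packaged tests use 100–200,
which already stabilizes the exceedance counts at these network sizes.

## Paired network-based statistics

The pre/post comparison uses the NBS logic: an edgewise paired $t$
statistic ($t = \bar d / (s_d/\sqrt{n})$ on post − pre), a primary
threshold (default tail: positive, i.e. post > pre), connected components
of the suprathreshold edges — connectivity is evaluated on the undirected
support while edges keep their directions in the report, and component size
is the suprathreshold edge count — and family-wise error control by a
permutation null of the *maximal* component size. The paired permutation
scheme independently exchanges each subject's session labels, which for a
paired $t$ is a sign flip of that subject's differences; $2^n$ labelings
are sampled with replacement. Corrected
$p = (1 + \#\{\text{perm max} \ge \text{observed}\}) / (1 + n_{\mathrm{perm}})$,
so $p$ is bounded below by $1/(1+n_{\mathrm{perm}})$ and never exactly
zero. The reference setting is 5,000 permutations; positive and negative
tails are run separately when both directions are of interest (a two-sided
mode exists). Because the sum of squared differences is invariant under
sign flips, the permutation $t$ statistics are computed for all
permutations with one matrix product, which keeps 200-replicate error-rate
simulations cheap.

## Graph measures

All measures operate on weighted networks; shortest-path measures use the
length graph $\ell_{ij} = 1/w_{ij}$.

* **Global efficiency**: mean inverse shortest-path distance over ordered
  pairs; unreachable pairs contribute 0.
* **Characteristic path length**: mean shortest-path distance over ordered
  *reachable* pairs; the unreachable count is reported alongside. These two
  conventions keep both measures finite on disconnected graphs.
* **Transitivity and local clustering**: geometric-mean (Onnela) triangle
  intensity on the symmetrized graph (mean of the two directions), which
  reduces to the classic closed/total-triplet ratio and neighbor-pair
  fraction on binary graphs.
* **Betweenness**: Brandes accumulation on the weighted directed length
  graph; raw values with $(n-1)(n-2)$ normalization attached.
* **Degree**: in-, out-, and total counts of nonzero incident edges.
* **Density (covariate)**: mean off-diagonal weight × maximum weight. This
  idiosyncratic definition is kept verbatim because it is the covariate the
  group statistics adjust for; the standard connection density is carried
  alongside for diagnostics.

Directed quantities (efficiency, path length, betweenness) are computed on
the directed graph; clustering-type quantities and community detection use
the symmetrized graph, since they are classically defined for undirected
graphs and the source procedure does not state its handling.

**Small-worldness** $\sigma = (C/C_{\mathrm{rand}})/(L/L_{\mathrm{rand}})$
compares mean clustering and path length against degree-preserving random
networks: directed double-edge swaps (self-loops and duplicate edges
rejected, weights traveling with their source edge) with at least 100
attempted swaps per edge, 100 null networks by default; $\sigma$ is
computed against each null and the values averaged. $\sigma > 1$ is the
conventional small-world classification.

**Hierarchical communities** come from recursive Louvain: 100 runs under
random node orders on the symmetrized graph, a representative partition
chosen by maximal mean normalized mutual information (ties: higher
modularity, then fewer communities), then recursion into each community's
induced subgraph until a subgraph yields a single community or has fewer
than 3 nodes. Resolution stays at 1 throughout — multiscale structure comes
from the recursion, not from resolution sweeps. NMI is defined as 1 when
both partitions are single-community and 0 when exactly one has zero
entropy.

## Group statistics

Graph measures are compared between sessions by ANCOVA with density as the
covariate: $y = \beta_0 + \beta_1\,\mathrm{group} + \beta_2\,\mathrm{density}$
fitted across the pooled $2n$ observations, testing $\beta_1$. Treating the
paired sessions as two groups reproduces the source analysis verbatim; a
paired alternative (within-subject differences regressed on density
differences, intercept test) is available via `paired = TRUE` and is the
statistically tighter choice for paired designs. Local (per-node) measures
are corrected by Benjamini–Hochberg FDR. Behavioral scores use Wilcoxon
signed-rank tests (zeros dropped; exact distribution up to $n = 25$ without
ties, tie-corrected normal approximation otherwise) or paired $t$ tests;
the degenerate all-equal paired $t$ case reports $t = 0$, $p = 1$.

## The synthetic cohort generator

Because the motivating study's recordings are not deposited, the package
generates paired cohorts with known ground truth. Each node starts as
unit-variance Gaussian noise band-limited by FFT masking (so that all of a
noiseless signal's power lies in the configured band, 0.53–35 Hz by
default). A directed coupling $(i \to j, \mathrm{lag}, s)$ replaces the
target's phase by the argument of the circular mixture
$(1 - S)\,e^{i\phi_j} + s\,e^{i\phi_i(t - \mathrm{lag})}$ (summed over
incoming couplings, $S$ = total incoming strength), keeping the target's
amplitude envelope; the planted effect therefore lives in exactly the
quantity PTE measures. The mixed signal is re-band-limited and white noise
(sd 0.5 by default, against unit signal variance) is added. Because the
argument of the mixture is scale-invariant, only mixtures with total
incoming strength up to 1 are identified; `source_model()` enforces this,
and post-intervention planting rescales proportionally (with a warning) if
an increment would exceed it. Coupling sources contribute their uncoupled
base phase, so chains plant both pairwise effects without feedback
ambiguity; lagged phases are circularly shifted.

Cohorts emulate a paired intervention design (12 subjects by default):
subject-level coupling strengths are drawn from a truncated normal around
the base values (jitter sd 0.05) and shared between that subject's pre and
post recordings; post recordings additionally strengthen a planted edge
subset by `delta`. No effect-size information was available to calibrate
`delta`; the default 0.4 is a convenience choice giving comfortable power
at the packaged problem sizes, not an estimate of any study's effect. All
randomness flows from one master seed through a documented derivation rule
(master, subject, session), so any subject/session is independently
reproducible. The default sampling rate is 256 Hz — band-limited 0.53–35 Hz
content is fully represented there, and it is the lowest power-of-two rate
that still admits the full 97 Hz denoising chain. Default recording length
is 300 s (a five-minute resting-state session).

What the generator does *not* emulate: volume conduction and source
leakage, artifacts (blinks, muscle), non-stationarity, 1/f spectral shape,
and realistic inter-channel covariance. Passing tests therefore demonstrate
that the estimator and inference machinery behave correctly when their
assumptions hold — not that any particular real-data effect will be
detected.

## Numerical choices and problem sizes

* PTE histograms use integer counts with an entropy decomposition
  ($\mathrm{TE} = [S(c_{3}) + S(c_y) - S(c_{yx}) - S(c_{fy})]/m$,
  $S(c) = \sum c \log c$), implemented in C++; segment matrices at
  desk scale cost well under a millisecond.
* Zero-variance edges in the paired $t$ get $t = 0$ with a note; the
  diagonal is excluded throughout.
* Degenerate graphs: an edgeless network has efficiency 0 and an undefined
  path length (the low-level function errors; the pipeline records NA).
* Seeds: every stochastic function takes an explicit seed; sub-seeds are
  derived by a fixed linear-congruential rule modulo $2^{31}-1$.
* Test-scale simulations use 60-second recordings, 5–8 node networks,
  100–200 surrogates and 500 permutations; the statistical checks (FWER,
  power, type-I error) use 20–500 replicates. These sizes were chosen so
  the planted effects sit well inside the detectable regime of the
  1,024-sample segment estimator while a full cohort replicate stays in the
  tens of seconds.

## Known limitations

* Histogram PTE at 4-second segments is strongly biased; only
  surrogate-relative statements are meaningful. Absolute PTE values should
  not be compared across different segment lengths or bin counts.
* The coupling mixture saturates at total incoming strength 1, so planted
  effects on already strongly driven targets are not identifiable; plant
  new edges or keep total strength below 1.
* The pooled ANCOVA on paired data ignores the pairing (kept for
  faithfulness); prefer `paired = TRUE` when the design allows.
* The NBS tails are run separately, not FWER-pooled across tails.
* Community detection inherits Louvain's stochasticity; the NMI
  representative over 100 runs stabilizes but does not guarantee the
  modularity optimum.
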
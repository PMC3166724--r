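---
title: "Markov-model sequential classification of human activities: methods"
author: "actichain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov-model sequential classification of human activities: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actichain)
```

## The problem and the model

Body-worn accelerometers make it possible to infer what physical activity a
person is performing — lying, sitting, standing, walking, climbing stairs,
running, cycling — from a few channels of acceleration alone. A
*single-frame* classifier looks at one window of signal at a time and
forgets everything else. A *sequential* classifier additionally exploits
the obvious statistical structure of human behaviour: activities persist,
and some successions (standing then walking) are far more probable than
others (lying then cycling). `actichain` implements both and the machinery
to compare them.

The behavioural level is modelled by a first-order Markov chain over $Q$
activity states $S_1,\dots,S_Q$, specified by a prior vector $\pi$ with
$\pi_i = \Pr(X(t_0) = S_i)$ and a row-stochastic transition probability
matrix (TPM) $A$ with $a_{ij} = \Pr(X(t_n)=S_j \mid X(t_{n-1})=S_i)$.
When the states are read directly from annotations this pair is an
observable Markov model (`MarkovModel`). In operation the states are
hidden: each occupied state emits a feature vector $x$ drawn from a
state-conditional density, here a Gaussian mixture with full covariances,

$$p(x \mid S_i) = \sum_{m=1}^{M} c_{im}\, N(x \mid \mu_{im}, \Sigma_{im}),
\qquad \sum_m c_{im} = 1 .$$

The pair $(\pi, A)$ plus the per-state mixtures form a continuous-emission
hidden Markov model (`CHMM`). The single-frame reference classifier
(`GmmClassifier`) uses exactly the same emission densities but assigns each
frame independently to $\arg\max_i p(x \mid S_i)$, with no priors — which
makes the two classifiers directly comparable: any accuracy difference is
attributable to the temporal model.

## From raw signal to feature vectors

Recordings are fixed-rate multichannel series in g units. They are cut
into frames of constant width with 50% overlap by default
(`segmentFrames`); a frame at the end that would not be full is dropped
rather than padded. Per frame and channel the package computes:

* **DC component** — the frame mean; separates static postures through
  the gravity projection.
* **Spectral energy** — the sum of squared magnitude-spectrum
  coefficients excluding the DC bin, divided by the frame length; by
  Parseval's identity `energy + width * dc^2` equals the total signal
  energy, which the tests assert. Measures activity intensity.
* **Spectral entropy** — the Shannon entropy of a Gaussian kernel density
  estimate (Silverman's bandwidth, trapezoidal integration over the
  estimate's support) of the one-sided non-DC magnitude coefficients after
  normalizing them to unit sum. The normalization makes the value
  invariant to amplitude scaling; the estimate distinguishes broadband
  (complex) from narrowband (rhythmic) frames. Degenerate spectra
  (all-zero, or all coefficients equal) are defined to score 0.
* **Correlation coefficients** — entries of the frame's channel covariance
  matrix: dot products of mean-removed channel pairs divided by the frame
  width, for every unordered pair *including self-pairs*. The self-pairs
  are deliberate: `ch` channels then give `ch*(ch+1)/2` values, i.e. 55
  for ten channels and 6 for three, and the total dimension is
  $d = 3\,\mathrm{ch} + \mathrm{ch}(\mathrm{ch}+1)/2$ — 85 and 15
  respectively.

"Detrended" is implemented as mean removal (not linear detrending) and
"normalized to the window size" as division by the frame width; these are
the simplest readings consistent with the correlation features being
covariance-matrix entries, and they only affect feature scale.

## Feature selection

`sffsSelect` is a floating forward–backward search. Features are first
standardized with training statistics — the raw features mix units (g,
g², nats), so unstandardized Euclidean distances would be dominated by
whichever feature happens to have the largest numeric range. The search
is driven by a within-class compactness criterion (negative mean Euclidean
distance over same-class pairs): conditional inclusion adds the feature
that most improves it, conditional exclusion removes features while doing
so beats the best subset already recorded at the smaller size, and the
search stops once every feature has entered the candidate set at least
once. A k-NN cross-validation study (default $k=5$, 10 folds; constants
chosen as common defaults — the criterion, not its constants, is the
substance) then arbitrates the final size: the minimal-size subset
maximizing the cross-validated accuracy wins, ties going to the smaller
subset and then lexicographic order. The split of roles — compactness
guides the walk, k-NN accuracy picks the operating size — is our
resolution of a genuinely underdetermined design point, and it is recorded
here rather than hidden in code.

`pcaFit`/`pcaTransform` provide the optional principal-component rotation
(eigendecomposition of the covariance of column-standardized features);
`varianceTarget = 1` keeps all components (pure rotation), otherwise the
smallest count reaching the target variance fraction is retained.

## Two-level training

Supervised first level (`trainLevel1`): because training sequences are
labeled, $(\pi, A)$ come from counting — $\hat a_{ij} = N_{i\to j} / N_{i
\to \cdot}$, pooled over sequences — and each state's mixture is fitted to
that state's frames by EM (`fitMixture`; $M=1$ reduces to the closed-form
mean and covariance). Frames labeled `"transition"` or `"garbage"` are
excluded from both counts and fits; transitions are counted between
consecutive *retained* frames, which recovers the generating chain when
out-of-vocabulary frames are interspersed without advancing it. A state
with no outgoing transitions is flagged and given a self-loop row.

Second level (`trainLevel2`): Baum–Welch refinement initialized at the
first-level estimates. By default only $(\pi, A)$ are re-estimated and the
emissions stay frozen — refining the transition parameters is the purpose
of this step — but `update = "all"` re-estimates the emissions too for
users who want full EM. The per-iteration total log-likelihood is returned
and is non-decreasing (asserted in the tests at every iteration).
Baum–Welch is run pooled over the training sequences of a fold.

Decoding uses the standard Viterbi algorithm. All recursions — forward,
backward, Viterbi — run in the log domain with log-sum-exp: emission
log-densities of realistic frames reach magnitudes that underflow linear
arithmetic long before a sequence ends. Ties resolve to the lowest state
index everywhere, making results reproducible.

## Rejection of spurious frames

A frame whose class-conditional density is below a threshold for *every*
state carries too little evidence for any known activity:
`rejectionMask` flags frames with $\max_i \log p(x \mid S_i) < Th$. No
garbage state or extra mixture component is introduced. Thresholding the
log-density is equivalent to thresholding the density (monotone
transform); the log scale is used for numerical sanity.

The threshold is chosen on a sensitivity–specificity curve
(`rocCurve`, evaluated on the sorted unique statistic values), with
spurious frames as the positive class: sensitivity is the fraction of
garbage rejected, specificity the fraction of genuine frames retained.
`selectThreshold` returns the operating point where specificity is
slightly greater than sensitivity — concretely, the largest grid threshold
with $Sp \ge Se$, the point just before sensitivity overtakes specificity.
During decoding, rejected frames are removed and the retained frames are
decoded as one contiguous sequence with unchanged transition
probabilities ("skip and stitch"); each rejected frame then inherits the
decoded label of the previous retained frame purely for reporting, so
rejection never affects the classifier's operation on retained frames.

In leave-one-subject-out evaluation (`evaluateClassifier`) the threshold
is selected per fold from the training subjects' ROC only; nothing from
the held-out subject enters training. After rejection, accuracy excludes
rejected frames from the denominator (a retained garbage frame still
counts as an error); a strict mode keeps all frames in the denominator.

## What the synthetic generator emulates — and what it does not

No public corpus accompanies this package, so validation rests on a
generative *virtual experiment* design. Each activity is a declared
parametric stand-in (`ActivityEmissionSpec`): per-channel gravity
baseline, movement harmonics with random phase, and cross-channel
correlated Gaussian noise. Pools of `N` such frames per activity and
subject (classically 18–58) are sampled with replacement whenever a state
path drawn from the seven-activity TPM occupies the matching state
(defaults $T = 300$ frames per experiment, 20 experiments per subject).
Garbage frames from a distinct "unknown activity" spec — deliberately not
pure noise, since real spurious data are unmodeled *activities* — are
interspersed at uniformly random positions. The default ratio is one
garbage frame per three genuine frames (25% of the total); because "one
third" admits a second reading (a third of the total), the ratio is a
plain parameter: `garbageRatio = 0.5` yields the 1/3-of-total variant.

Default specs use three channels ($d = 15$): the feature-count identities
are exercised at ten channels separately, and nothing else depends on
channel count, while three channels keep simulation studies fast. Climbing
stairs and walking are given nearly identical baselines and close
harmonics so they remain the dominant confusion pair; static postures
differ only in gravity projection. `simulateVirtualStudy` adds a small
per-subject perturbation of the DC baselines (default sd 0.005 g),
emulating modest sensor-placement variability between subjects.

These stand-ins reproduce the *phenomenology* that matters for validating
the algorithms — class overlap, persistent dynamics, out-of-vocabulary
contamination, between-subject shifts — but not biomechanics: no gait
variability within a pool beyond sensor noise, no amplitude drift, no
realistic transients between frames of a virtual sequence. Passing tests
therefore demonstrate correctness and the claimed *relative* behaviour of
the classifiers under these conditions, not field performance on real
recordings.

The continuous sit–stand–walk recording (`generateSitStandWalk`) is
closer to a real acquisition: ~15 s at 250 Hz, three channels, static
gravity projections for sitting and standing, a smooth sigmoid
reorientation during each postural transition, gait harmonics while
walking, and per-sample annotations including the transition zones.
Frames overlapping an annotated transition zone are labeled
`"transition"` and excluded from supervised fitting — how such frames
were handled originally is unknowable, and excluding ambiguous frames is
the conservative choice. Ties in a frame's majority vote are treated the
same way.

## The seven-activity transition matrix

The packaged TPM (`sevenActivityTpm`) ships as specified, but its first row
sums to 1.20. The default repair zeroes the lying-to-cycling entry
$a_{12} = 0.20$: it is the single-entry change that restores an exact row
sum, and a 20% chance of switching from lying down directly to cycling is
behaviourally implausible; row-renormalization is available as an
alternative (`repair = "renormalize"`), and `repair = "none"` returns the
raw matrix. Virtual-experiment priors are not part of the matrix's
specification; the default is uniform.

## Numerical choices

* Covariance eigenvalues are floored (`reg`, default $10^{-6}$) after
  every fit and every EM step: per-state frame counts can be smaller than
  the feature dimension, making raw covariances singular. Simulation
  studies in the tests pass `reg = 1e-4` (a floor of 0.01 g on the
  feature scale) so that class densities stay finite under the
  between-subject DC shifts the generator produces.
* GMM EM: k-means++-style seeding from the supplied seed, at most 200
  iterations, relative log-likelihood tolerance $10^{-8}$. Baum–Welch:
  default cap 50 iterations, tolerance $10^{-6}$.
* Strict TPM validation rejects rows off unit sum by more than $10^{-6}$;
  class invariants are enforced at $10^{-9}$.
* A zero-likelihood sequence under a model is reported as an error
  suggesting a larger covariance floor rather than silently propagating
  `-Inf`.
* All generators and fits are bit-reproducible given seeds; functions
  taking a `seed` restore the caller's RNG state.

## Problem sizes used by the test and validation suites

The validation suite runs scaled-down versions of the full design, chosen
so the properties under test are comfortably identifiable: TPM recovery
pools 20 chains of $T=300$ (the full virtual-experiment size); the
sequential-vs-single-frame comparison uses 20 replicates of 4 subjects
with 200-frame sequences from a 3-state persistent chain with class means
1.5 standard deviations apart; the rejection study uses 20 replicates of
3 subjects with two 300-frame experiments each under 1:3 contamination;
the sit–stand–walk study uses 3 subjects with two 15 s trials each. These
sizes are the package's own choices and are stated here so that users
scaling up know what has actually been exercised.

## Known limitations

* Emission stand-ins are declared, not fitted to real signals; absolute
  accuracies on synthetic data say nothing about absolute accuracies on
  real data.
* The count-based priors are unsmoothed empirical frequencies: a state
  never observed at a sequence start gets prior 0 and cannot begin a
  decoded path. This is faithful to the estimator; with few training
  sequences users may prefer to supply priors explicitly.
* First-order dynamics only; no duration modelling (a semi-Markov model
  would capture dwell times better), no discrete-emission variant.
* Feature selection assumes the compactness criterion and the k-NN
  arbiter agree on what "informative" means; with strongly interacting
  features the greedy floating walk can miss subsets an exhaustive search
  would find.
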
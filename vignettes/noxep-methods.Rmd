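---
title: "Simulating and analysing intensity-matched nociceptive evoked potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing intensity-matched nociceptive evoked potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noxep)
```

## The problem

Laser-evoked potentials (LEPs) and contact-heat evoked potentials (CHEPs)
are the two standard cortical read-outs of A-delta nociceptor activation.
Comparing them fairly requires that the two stimulus types be matched for
*perceived* intensity, because stimulus saliency scales the vertex
potentials. `noxep` implements the full computational chain of such a
matched comparison — adaptive perceptual matching, evoked-potential
extraction, and the paired statistical layer — together with a synthetic
observer and EEG generator so that every stage can be validated against
known ground truth without any human recordings.

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin drivers that narrate each stage and write their
tables under `results/`, while all computation lives in the package
functions documented here.

## The synthetic observer

An observer maps laser energy $E$ (joules) to a 0--10 numeric rating scale
(NRS) report through a piecewise-linear psychometric model,

$$R(E) = \mathrm{clip}\big(\mathrm{round}(s \cdot \max(0, E - \theta) +
\varepsilon),\, 0,\, 10\big), \qquad \varepsilon \sim N(0, \sigma_r^2),$$

with threshold $\theta$ (default 1.0 J), slope $s$ (2.5 NRS/J) and report
noise $\sigma_r$ (0.5 NRS). Rounding to integers mirrors how subjects use
the scale; it is the simplest monotone model consistent with an integer
scale and makes closed-form checks possible (the test suite integrates the
rounded, clipped normal numerically as an oracle). Contact-heat ratings are
drawn from a per-subject session distribution
$\mathrm{round}(\mathrm{clip}(N(\mu_h, \sigma_h^2), 0, 10))$; the cohort
default $\mu_h = 3.0$ with between-subject SD 1.6 NRS matches the sham
contact-heat pain distribution of the calibration tables, and the
within-session SD defaults to 1.0 NRS (individual ratings vary less within
a session than session means vary between subjects). Ratings and
evoked-potential amplitudes are generated independently: the pipeline makes
no claim about rating--amplitude coupling and cannot be used to study it.

## The staircase matcher

The double random staircase (DRS) runs two concurrent tracks, randomly
interspersed with no more than three consecutive trials from the same
track, 10 stimuli per track, starting at 1.5 J:

* rating 0 (no pain): step up 0.5 J;
* rating below the target: step up 0.25 J;
* rating above the target: step down 0.25 J.

The matching target is the mean of the 11 familiarization contact-heat
ratings after discarding the first (novelty/surprise). On completion each
track's median energy and median rating are computed over its own 10
trials; the matched energy is the mean of the two median energies, plus
0.25 J when the mean of the two median ratings falls short of the target
(subjects tend to underestimate laser intensity).

Design choices where the procedure is underdetermined:

* **Tie rule.** A rating exactly at a nonzero target holds the current
  energy (`tie = "hold"`); treating ties as "above" is available
  (`tie = "down"`) and is what makes a noiseless observer oscillate rather
  than lock. Holding is the symmetric reading of "lower/higher".
* **Fixed track length.** Both tracks always deliver their 10 stimuli and
  medians are taken over all 10 trials; "oscillation" does not shorten a
  run. A track that never reverses is flagged (`nonconverged`), not
  extended.
* **Grids.** Visited energies live on the 0.25 J grid offset from 1.5 J.
  The median of an even count is the mean of the two central values, so a
  track median lives on the 0.125 J grid and the matched energy (the mean
  of two medians) on the 0.0625 J grid.
* **Safety cap.** Energies clamp to [0.25, 5] J with a message, never
  silently.
* **Divergence.** Track medians more than 1 J apart trigger a warning but
  are still averaged — flagged, not second-guessed.

Validated closed-loop: across seeded cohorts of 20 observers the ICC(A,2)
between heat target and matched-laser mean rating is computed by
`matching_experiment()`; the acceptance suite requires at least 0.8.

## The EEG generator

Each of the three canonical components is a Gaussian bump
$A \exp(-(t - L)^2 / 2\sigma_w^2)$. Gaussians are a deliberate choice: the
morphology of real components is not specified anywhere usable, and a
Gaussian makes latency and amplitude ground truth unambiguous. Width SDs
default to 15 ms (N1), 25 ms (N2) and 40 ms (P2). N1 is injected on the
central electrode contralateral to the stimulated arm (C4 for left-arm
stimulation), N2 and P2 on the vertex electrode Cz; Fz and the ear
references A1/A2 carry noise only, so the analysis montages (Cz minus
linked ears; C3/C4 minus Fz) recover the injected components.

Background noise is $1/f^\beta$ with $\beta = 1$, synthesized in the
spectral domain (Hermitian-symmetric Gaussian spectrum, DC removed) and
scaled to 10 µV RMS per channel — a typical broadband EEG floor.
Trial-to-trial latency jitter is Gaussian with SD 10 ms, a modest
single-trial variability for A-delta potentials; jitter that would push a
component outside the post-stimulus window is resampled with a warning.
Epochs span $[-1, 2)$ s at 4000 Hz (12000 samples, $t = 0$ at index 4001);
continuous recordings place 20 triggers at inter-stimulus intervals uniform
in 8--12 s with 2 s lead-in and 3 s tail.

Per-subject ground truths are drawn from per-modality population
calibrations (contact heat: N1 $-3.6$ µV @ 336 ms, N2 $-10.6$ µV @ 392 ms,
P2 13.0 µV @ 494 ms; laser: N1 $-7.1$ µV @ 175 ms, N2 $-18.9$ µV @ 211 ms,
P2 16.8 µV @ 322 ms, with the corresponding between-subject SDs). Latency
variation uses a single per-subject latent factor — every component
latency is $\mu_c + \mathrm{sd}_c \cdot z$ with one shared
$z \sim N(0,1)$ — so subjects shift their whole waveform together. This
keeps each marginal exactly at the calibrated mean and SD and preserves
the N1 < N2 < P2 order without rejection sampling; rejection on ordering
constraints was measured to bias the drawn N2 population mean by several
milliseconds and was discarded. Amplitudes are drawn independently,
truncated to the correct sign with magnitude at least 1 µV (a present
component must be generatable); the truncation shifts means by well under
one calibrated SD.

What the generator does **not** emulate: ocular/muscle artifacts and their
component-space structure (there is no independent-component stage to
exercise), habituation or drift across the 20 trials, rating--amplitude
coupling, volume-conduction leakage between channels (available as an
option, off by default), and any biophysics of skin heating — thermode
ramp rates and laser pulse geometry are carried as metadata only. Passing
tests therefore demonstrate correctness of the *algorithms* under
controlled conditions, not robustness to every artifact of real
recordings.

## Preprocessing

The offline filter is a Hamming-windowed FIR bandpass, 1--40 Hz. A
"first-order" windowed FIR cannot realise a 1--40 Hz bandpass; the phrase
is read the way EEG toolboxes use it, with the filter order set by the
transition-band rule $N \approx 3.3 f_s / \Delta f$. The low edge's 1 Hz
transition is the binding constraint, giving 13201 taps at 4000 Hz. The
realised response is flat to better than 1% between 2 and 35 Hz with more
than 20 dB attenuation at 0.25 and 60 Hz (asserted against the designed
taps in the tests). Application is zero-phase (forward FFT convolution
with group-delay compensation) so component latencies are unbiased, and
filtering precedes epoching so filter transients stay away from epoch
edges. Baseline correction subtracts the mean over the full pre-stimulus
second per epoch and channel; the full second is used because nothing
narrower is dictated and it gives the most stable baseline estimate.

One numerical consequence deserves emphasis: a 1 Hz highpass removes real
signal energy from broad monophasic components. A Gaussian bump of width
$\sigma_w$ has spectral mass below 1 Hz proportional to
$\mathrm{erf}(2\pi\sigma_w/\sqrt 2)$; at the default widths this
attenuates isolated peaks by 2--7% (N1, a lone bump on its montage, loses
the most). The biphasic N2--P2 complex largely self-cancels — its
peak-to-peak amplitude loses only about 2--3% — and zero-phase application
leaves latencies within about 1 ms. The strict template-recoverability
check (±1 sample, amplitude to within 1%) therefore runs on the unfiltered
epoched path, and the filtered continuous path is checked against the
attenuation predicted from the designed taps. Artifact rejection is a
deterministic threshold rule: epochs whose peak-to-peak amplitude exceeds
150 µV on any channel are marked rejected (never deleted) and excluded
from averages.

## Extraction

Session quality is gated by the signal-to-noise ratio of the averaged
vertex trace, $20 \log_{10}(\mathrm{RMS}_{\mathrm{ROI}} /
\mathrm{RMS}_{\mathrm{pre}})$ — the voltage-dB convention, equivalently
$10\log_{10}$ of the power ratio. The region of interest is 150--550 ms
post-trigger for laser and 300--650 ms for contact heat; the reference
window is the full pre-stimulus second (the 500 ms immediately pre-trigger
is reserved for the component presence rule — both windows are
configurable since the split is an interpretation). Sessions below 3 dB
are excluded: they keep their SNR and flag but report no components.

Component marking is rule-based, replacing two-reviewer visual marking
with deterministic criteria:

* **N2** is the most negative sample in its search window (laser
  150--300 ms, contact heat 300--500 ms; centred on the calibrated means,
  configurable), **P2** the most positive sample in its window (250--450 /
  400--650 ms) constrained to follow the N2 peak.
* **Presence** requires the peak magnitude to reach $\sqrt 2$ times the
  RMS of the 500 ms pre-trigger interval — a 3 dB margin consistent with
  the session gate. Absent components carry amplitude 0 µV and a missing
  latency, so they enter amplitude statistics but drop out of latency
  statistics.
* **N1** is the most negative sample on the contralateral montage between
  the start of the region of interest and the *onset* of N2, and requires
  N2 to be present. Onset is operationalized as the last crossing of half
  the N2 amplitude before the N2 peak. A near-zero (e.g. 10%) crossing
  was rejected: with the canonical laser geometry (N1 at 175 ms, N2 at
  211 ms with 25 ms width) the 10% crossing falls near 157 ms — *before*
  the N1 peak — and would misclassify textbook N1 waveforms as absent.
  A minimum that lands on the closing edge of the search window is the
  tail of a later negativity, not a peak, and is likewise rejected.
* **N2P2** is $P2 - N2$ peak-to-peak when both are present, 0 otherwise.

## Statistics

The comparison layer mirrors the study design: two-sided paired t-tests
per outcome with pairwise deletion of incomplete pairs (so degrees of
freedom vary across outcomes exactly as the missing-data policy dictates),
Pearson correlation for perceived-pain matching, and the intraclass
correlation ICC(A,k) — two-way random effects, absolute agreement,
average measures (McGraw--Wong), computed from the two-way ANOVA mean
squares

$$\mathrm{ICC}(A,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n},$$

with the consistency variant available behind a flag. A non-positive
denominator is flagged, not hidden. The seven evoked-potential outcomes
(N1/N2/P2 latency and amplitude, N2P2) form one Bonferroni family:
$\alpha = 0.05/7 \approx 0.00714$, reported to three decimals as 0.007.
Identical pairs are treated as a well-defined null ($t = 0$, $p = 1$);
constant nonzero differences are refused as degenerate. p-values display
to three decimals with values below 0.001 shown as "< 0.001".

The pinprick layer collapses each block (seven weighted pinpricks, 8 to
512 mN, five applications each in randomized order) to the mean of all 35
ratings; secondary hyperalgesia is the post-minus-pre difference of block
means, compared between sham and capsaicin with the same paired machinery.
Per-force means are emitted as a diagnostic only. The simulated pinprick
response follows a log2-force rule (about 0 NRS at 8 mN rising to about
3 NRS at 512 mN) with per-condition effect distributions calibrated to
the reference deltas (sham near zero, capsaicin positive); the capsaicin
effect on thermal ratings and on the evoked potentials defaults to zero,
matching the null findings the pipeline is meant to reproduce.

## Problem sizes and runtime choices

The validation experiments use the following sizes, chosen to give stable
Monte-Carlo estimates: 20 observers per matching cohort with 50 replicate
cohorts for the closed-loop ICC; 100 seeded sessions per modality for
parameter recovery through the full continuous chain (the stage-2 analysis
script uses 40 per modality for a quicker narrative run); 1000 replicates
for the null calibration of the comparison layer, which runs on
session-summary tables rather than full EEG since only the statistical
layer is under test there. The miniature end-to-end study in the test
suite uses 6 subjects in epoched mode.

## Known limitations

* The epoched generation path cannot be bandpass-filtered (a 3 s epoch is
  shorter than the 3.3 s filter), so its pre-stimulus noise floor retains
  low-frequency power and its session SNR runs lower than the filtered
  continuous path; weak-amplitude subjects can fall under the 3 dB gate
  there. This mirrors the behaviour of unfiltered data rather than a
  defect, but means epoched-mode group means are noisier.
* Peak-picking on noisy averages has a small positive bias (the maximum of
  signal plus noise exceeds the signal maximum); at the default noise
  floor and 20-trial averages this is well under the 10% recovery
  tolerance but visible in recovered amplitudes.
* The N1 presence rate is imperfect by construction — N1 is only marked
  when its peak precedes the half-amplitude N2 onset. At the laser
  calibration the N1-to-onset margin is a few milliseconds, and because
  the common latency factor moves N1 and N2 together the margin shrinks
  for late-shifted subjects: roughly 40% of simulated laser sessions
  report N1 absent (contact-heat sessions, with a 56 ms N1-N2 gap,
  almost never do). This echoes, though exaggerates, the empirical
  observation that N1 is the least reliably acquired component; the
  onset fraction is configurable where a laxer rule is wanted.
* Component amplitudes are drawn independently per subject and modality,
  so there is no within-subject correlation between a subject's
  contact-heat and laser amplitudes. Paired amplitude comparisons on the
  synthetic cohort are therefore noticeably less powerful than they would
  be on real subjects, where such correlation is substantial; latency
  comparisons, driven by the large between-modality separation, are
  unaffected.
* On *unfiltered* 1/f noise, per-epoch baseline correction removes the
  pre-window mean and with it a sizable share of the pre-window
  low-frequency power, inflating the apparent session SNR by roughly
  2--3 dB; a pure-noise epoched session can therefore hover at the 3 dB
  boundary instead of sitting at 0 dB. The filtered continuous path does
  not show this (the highpass removes the offending power on both sides
  of the ratio).
* `run_study()` randomizes session order but models no carry-over,
  habituation or session-order effects.
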
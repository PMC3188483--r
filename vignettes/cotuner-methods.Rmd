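---
title: "Models and methods: from lateral inhibition to co-tuning in one circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from lateral inhibition to co-tuning in one circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Sensory-cortical neurons sum excitatory and inhibitory synaptic input, and the
spatial (tonotopic) tuning of the two opposing inputs shapes the receptive
field. Two canonical arrangements are observed *in vivo*: **lateral
inhibition**, where the inhibitory input to a pyramidal cell is tuned more
broadly than its excitatory input (width ratio $w_{inh}/w_{exc} > 1$), and
**co-tuning**, where both have the same width ($w_{inh}/w_{exc} \approx 1$).
`cotuner` implements a three-tier computational argument that a *single,
fixed* cortical circuit produces both: the configuration is selected purely by
the spatial spread $\sigma$ of the thalamic drive, with narrow drive giving
lateral inhibition and broad drive giving co-tuning, together with the
accompanying changes in gain, firing pattern (tonic vs phasic) and
rate-intensity monotonicity.

## Tier 1: the spiking sheet

The circuit is a two-dimensional sheet, 1185 µm a side, with 160×160
pyramidal (P) cells and 32×32 fast-spiking (FS) interneurons on registered
grids. Directed wiring is sampled once per ordered pair from the Gaussian
connection-probability profile

$$p(d) = A\,e^{-d^2/2\sigma_c^2},$$

with the in-vitro values $A = 0.10,\ \sigma_c = 145$ µm (P→P), $A = 0.30,\
\sigma_c = 92$ µm (P→FS) and $A = 0.39,\ \sigma_c = 92$ µm (FS→P). FS–FS
chemical and electrical coupling are deliberately absent (their net effect is
probed instead by raising the FS spike threshold, below).

Neurons are adaptive exponential integrate-and-fire (aEIF) units

$$C\dot V = -g_L(V - E_L) + g_L\Delta_T e^{(V - V_T)/\Delta_T} - w + I,\qquad
\tau_w\dot w = a(V - E_L) - w,$$

with a reset, a spike-triggered adaptation increment $b$ and a 2-ms refractory
period. The P class is a regular-spiking, adapting cell with a slow membrane
($\tau_m$ = 20 ms); the FS class is non-adapting with a fast membrane
($\tau_m$ = 10 ms), a sharp spike initiation ($\Delta_T$ = 0.4 mV) and a spike
threshold of −47 mV (its control value; −52 and −37 mV are used as
excitability variants). The full tables of membrane constants behind the
original study are not part of the published text, so the defaults in
`neuron_params()` are standard aEIF values for these two firing phenotypes;
everything is overridable from configuration.

Synaptic conductances are alpha functions, normalized so the kernel peak
equals the plasticity-scaled unitary amplitude $A$, with fixed 1-ms axonal
delay. Every pathway depresses through the Tsodyks–Markram resource model
(per-connection state; utilization $U$, recovery $\tau_{rec}$). Inhibition
is effectively delayed relative to excitation not by a longer wiring delay but
because FS cells must first integrate to threshold — the mechanism the
circuit itself provides.

### Calibration of unitary amplitudes

The unitary synaptic amplitudes (`synapse_params()`) were calibrated once,
as the original experimental fits were, against the circuit's stated
operating points, and then frozen:

* cortical firing (and therefore FS-mediated inhibition onto P cells) first
  appears near $N_{max} \approx 20$ afferents for a 40-µm drive;
* evoked P and FS rates at $N_{max} = 60$–100 sit in the midrange of the
  cells' F/I curves, with FS rates well above P rates;
* FS→P inhibition is substantially stronger than the sparse P→P recurrence
  (which contributes only to the foot of the excitatory profile), a stated
  precondition for lateral inhibition;
* thalamic synapses depress strongly; their kinetics and dynamics differ
  between P and FS targets. Thalamic drive to P cells is slow and strongly
  depressing (τ = 5 ms, U = 0.7), to FS cells fast and weakly depressing
  (τ = 1.2 ms, U = 0.3) — the FS pathway acts as an onset-synchrony detector
  while the P pathway integrates the whole afferent volley.

The asymmetry in the last point is what lets one circuit express both
configurations: the excitatory conductance profile inherits the breadth of
the afferent *count* envelope, while FS recruitment tracks the sharper
count × rate product, and the firing threshold of the FS population then
trims its skirt (the "iceberg" effect) before the 92-µm axonal spread
re-broadens it.

## Tier 1 inputs: synthetic thalamic drive

There are no external data; the only input is simulated thalamus. Each
afferent train fires repetitively at rate $F$: the first-spike latency and
every subsequent inter-spike interval are Gaussian, mean $1/F$ and standard
deviation $0.25/F$, so the afferent population is synchronized at stimulus
onset and desynchronizes over tens of milliseconds (a phasic-tonic
population histogram whose peak sits near $1/F$). Non-positive sampled
intervals (tail mass ≈ 3×10⁻⁵) are re-drawn to keep spike times increasing.
Both the number of afferents converging on a cell and their rate follow
Gaussian spatial envelopes with peak $N_{max}$ (counts round half-up) and
$F_{max}$ = 50 Hz and common width $\sigma$. Afferents are private to their
target cell — whether neighboring cells share thalamic axons is not
specified in the source anatomy, and independent draws are the conservative
choice. Two-tone stimuli superpose two identical envelopes separated by
$\Delta x$ along the tonotopic axis; counts add before rounding and each
afferent fires at its own stimulus' rate envelope.

## Tier 2: the reduced feedforward model

To expose the mechanism, the recurrent pathways are dropped: thalamic current
$I_{thal}(x) = I_{max}e^{-x^2/2\sigma_{thal}^2}$ drives excitatory and
inhibitory cells; the excitatory input profile is inherited unchanged, while
the inhibitory profile is obtained by (i) the threshold-linear transform
$F_{inh} = m\,\max(I_{thal} - \theta, 0)$ (the iceberg step), (ii) convolution
with the Gaussian inhibitory spread $P_{inh}$ ($\sigma_{inh}$), and (iii)
conversion back to current by a constant with units nA/Hz (which cancels in
width ratios). Widths are full widths at half maximum with linear
interpolation, outermost crossings. With the threshold removed the model has
a closed form — the convolution of Gaussians gives

$$\frac{w_{inh}}{w_{exc}} = \sqrt{1 + \left(\frac{\sigma_{inh}}{\sigma_{thal}}\right)^2} > 1,$$

which the numerical path reproduces to 10⁻³ at lattice spacing
$\sigma_{inh}/50$; this is the package's strongest internal oracle. With the
threshold present the ratio surface crosses 1 at finite $\sigma$: the
threshold is what makes exact co-tuning reachable.

## Tier 3: the spatial firing-rate model

Population dynamics on a 1-D lattice (1185 µm, 5-µm spacing, open
boundaries):

$$\tau_e \dot F_{exc} = -F_{exc} + S_{exc}(w_{thal}F_{thal} + w_{ee}\!\ast\!F_{exc} - w_{ei}\!\ast\!F_{inh}),$$
$$\tau_i \dot F_{inh} = -F_{inh} + S_{inh}(w_{thal}F_{thal} + w_{ie}\!\ast\!F_{exc}),$$

with weight kernels $w = \rho\,A\,P(x)$ (presynaptic density × unitary
strength × connectivity profile, the in-vitro profiles above) and
Naka–Rushton transfers $S(x) = M x^n/(x^n + \theta^n)$; net input is
rectified at zero before the transfer (inhibition silences, it cannot drive
negative rates). Thalamic rate is fixed at 20 Hz; the drive envelope is the
same Gaussian $(N_{max}, \sigma)$ for both populations. There is no
short-term plasticity in this tier — only the transient response window is
analyzed.

The weight and transfer constants of the original study's tables are likewise
not in the published text. The defaults in `rate_params()` were chosen once
to satisfy, simultaneously, the model's characteristic regimes: sustained
center firing for narrow drive (σ = 40 µm, $N_{max}$ = 20) versus transient
firing for broad drive (σ = 120 µm); mean rate decreasing in σ and increasing
in $N_{max}$; a width-ratio slice that crosses 1; and saturation of
inhibition at broad σ. Mechanistically this requires τ_exc > τ_inh (10 vs
8 ms, the P membrane being slower), inhibition stronger than recurrent
excitation ($A_{ei} \gg A_{ee}$), an inhibitory transfer with a high
semi-saturation (θ = 550 pA — the iceberg) and a modest inhibitory ceiling
(M = 120 Hz) so that inhibitory growth saturates once the active region
exceeds the 92-µm kernel.

### Intensity trajectories

A graded stimulus maps to concurrent increases of $N_{max}$ and σ through two
Naka–Rushton transfers ($M = 1000, n = 5, \theta = 0.4$ for $N_{max}$;
$M = 75, n = 4, \theta = 0.5$ for σ, optionally shifted up by 75 µm for a
broad thalamocortical terminal field). The $N_{max}$ transfer's output range
(0–1000) is mapped onto the model's drive scale through the thalamic weight:
the intensity analyses use $w_{thal} = 0.02$ pA/Hz so the full transfer range
spans the same input currents as 0–20 afferents at the default weight — one
model, two equivalent axes. The resulting rate-versus-intensity curve is
classified **non-monotonic** when its maximum is interior and the terminal
value falls below 90% of that maximum (robust to plateau noise), otherwise
**monotonic-increasing**; a flat curve counts as monotonic by convention.
The narrow-field trajectory climbs the steep lateral-inhibition flank of the
rate surface and rolls off (non-monotonic); the 75-µm-offset trajectory
stays on the flatter co-tuned shelf (monotonic).

## Measurements

All tiers funnel into the same analysis vocabulary:

* **Counts**: spikes in the first 50 ms after stimulus onset divided by
  sweeps — the window where thalamic drive dominates and the conductance
  changes are largest.
* **Radial profiles**: per-cell quantities averaged over 15-µm annuli about
  the stimulus center (≈ two P-cell pitches; empty annuli are dropped).
* **Peak conductances**: per cell, the maximum of the *sweep-averaged*
  pathway trace in the window (peak-of-mean, chosen over mean-of-peak for
  noise robustness). The composite excitatory trace sums thalamic and
  recurrent conductances before the peak is taken.
* **Half-widths**: FWHM by linear interpolation between bins, outermost
  crossings; radial profiles are reflected about the center first. The
  central quantity is the ratio $w_{inh}/w_{exc}$.
* **Gain summaries**: least-squares slope of count-vs-$N_{max}$ over the
  supra-onset range; onset = first grid value with a nonzero count; a family
  of curves is flagged *divisive* when slopes differ but onsets agree within
  one grid step.
* **Two-tone curves**: count of the cell nearest the S1 center versus
  separation, with the single-stimulus baseline attached.

## Numerical choices

* Forward Euler at dt = 0.05 ms for the spiking tier, with the exponential
  spike-initiation term clamped at the 0-mV cutoff; spike time recorded at
  the crossing step. Halving dt does not change any regime-level outcome.
* Alpha synapses integrate as an exactly-discretized two-state linear
  system; conductances are recorded at 0.5-ms resolution.
* White background noise (variant analyses) is injected as
  $I = \mathrm{amp}\,\eta/\sqrt{dt}$ so the membrane fluctuation level is
  step-size independent; `calibrate_noise()` finds the amplitude for a target
  membrane sd by secant iteration on a long subthreshold run.
* The wiring sampler draws each ordered pair within 4 connection-σ of the
  presynaptic cell (tail probability < 3×10⁻⁴ of the peak).
* Rate-model integration uses dt ≤ min(τ)/20 (default 0.25 ms); kernels are
  truncated at 10⁻⁶ of peak; convolutions are dense matrix products on the
  lattice. Halving dt moves the 50-ms mean center rate by < 1%.
* Open boundaries everywhere; analyses are center-referenced, and the
  region of interest stays far from the sheet edge.
* The FS grid is shifted by half a pitch so one FS soma sits exactly at the
  sheet center. With the 37-µm FS pitch this matters: a narrow (σ = 40 µm)
  stimulus falling midway between four FS cells is sampled at only ~65% of
  its peak, which distorts the inhibition-onset measurement. The stimulus
  "center cell" is the cell nearest the envelope center (for two-tone runs,
  the S1 center); two-tone counts average cells within 30 µm of that center
  to reduce per-cell count quantization.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the spiking tier at the
full 160×160 sheet for the transition, onset and FS-threshold analyses
(20 sweeps per condition), and use proportionally coarsened grids
(`build_network(scale = )`) with fewer sweeps for the gain and two-tone
property checks; the paper-scale presets in `preset_config()` keep the
original 50-sweep settings. These sizes are the package's own choice of a
scale at which every qualitative claim is resolvable with comfortable
statistical margin.

## What the synthetic data do and do not show

The generator reproduces the *statistical structure* the study attributes to
thalamus — phasic-tonic trains, Gaussian spatial envelopes, independent
afferents — not recorded thalamic spikes. Passing tests therefore demonstrate
the circuit-level mechanism under those statistical assumptions; they cannot
rule out contributions from correlated thalamic axons, non-Gaussian terminal
fields (probed only through the rate-tier kernel variants), LTS interneurons,
FS–FS coupling, or longer-timescale cortical feedback, all of which are
explicitly out of scope.

## Known limitations

* The aEIF, synaptic and rate-model constants are literature defaults
  calibrated to the study's operating points, not the original (unpublished)
  tables; quantitative values such as absolute counts are therefore
  indicative, while the regime structure is the tested claim.
* The two-tone analysis offsets the second stimulus along one axis only.
* The divisive-gain signature (count-vs-$N_{max}$ slopes differing across σ
  with a common onset) holds throughout, but the slope *ordering* — steepest
  at σ = 40 µm — holds only up to moderate $N_{max}$: near $N_{max} = 100$
  the broad-σ curve steepens as recurrent excitation outgrows the saturating
  FS→P inhibition.
* Unequal E/I input tuning shifts the co-tuning contour as expected for
  moderate inequality; for strongly broader inhibitory-cell input
  ($r_{EI} \gtrsim 1.4$ at $I_{max} = 3\theta$) the width-ratio asymptote
  itself exceeds 1 and exact co-tuning disappears.
* The feedforward tier is 1-D by construction; the spiking tier's radial
  analysis assumes isotropy.
* Runaway recurrent activity is flagged (population-rate ceiling), not
  truncated; none of the shipped configurations trips the flag.
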
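---
title: "Reversible concealment of cardiac signals in facial video: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reversible concealment of cardiac signals in facial video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsecloak)
```

## The problem

Remote photoplethysmography (rPPG) reads the blood-volume pulse from a
plain RGB recording of a face: with each heartbeat the skin's light
absorption changes minutely, most strongly in the green channel, where
hemoglobin absorption peaks. Averaging skin pixels over a facial region
and projecting the resulting R/G/B time series yields a pulse waveform and
from it heart rate, and downstream quantities such as stress or emotional
state. Anyone holding a facial video — a conference recording, a
livestream, a telehealth session — can therefore extract physiological
information the subject never consented to share.

`pulsecloak` implements a sender/receiver framework that conceals this
signal *reversibly*. The sender adds a small sinusoid at a fake heart rate
to the green channel of the rPPG-rich facial regions, frame by frame. An
eavesdropper who runs rPPG on the transmitted clip measures the fake
rhythm, not the real one. The fake-frequency schedule travels alongside
the video encrypted with the receiver's RSA public key, and because the
injected increment is an integer applied to losslessly stored frames, the
legitimate receiver subtracts it again and recovers the original video
bit-for-bit.

## The modulation model

For pixel $(x, y)$ of frame $n$ the sender updates only the green plane
inside the facial mask:

$$G(x,y,n) \leftarrow G(x,y,n) + \mathrm{round}\!\big(A \sin \varphi_n\big),
\qquad t_n = n/\mathrm{fps},$$

where $A$ (default 2 grey levels) is the modulation amplitude and the
phase $\varphi_n$ follows the active fake frequency $f$ (in bpm) of the
schedule. Two phase policies are supported, carried inside the schedule so
both sides agree:

* **continuous** (default): $\varphi_{n+1} = \varphi_n + 2\pi (f/60)/\mathrm{fps}$.
  The phase accumulates across segment boundaries, so the injected wave has
  no visible discontinuity when the fake rate switches.
* **per-segment reset**: $\varphi_n = 2\pi (f/60)\, t_n$, the literal
  global-time sinusoid; at a segment switch the phase jumps.

The real-valued sinusoid is rounded to an integer **once per frame** and
applied uniformly over the mask. This is the crux of reversibility: 8-bit
storage forces quantization somewhere, and quantizing the *increment*
(rather than the modulated pixel values) means restoration can subtract the
identical integer. Saturating arithmetic clamps results to $[0, 255]$;
clamped pixels are counted in a clip report because exactness is lost
there. At the default $A = 2$ on mid-range skin tones, clipping does not
occur.

Restoration requires the same schedule, masks, frame rate and phase policy,
and lossless storage end-to-end. The package's default container is a PNG
frame archive (bit-exact, no external dependency); FFV1-in-Matroska is
supported through an `ffmpeg` executable when one is on the PATH. Lossy
codecs are refused on this path: after a lossy transcode the modulation
cannot be inverted exactly and traces of it remain.

## The frequency schedule and its encryption

A schedule is a list of fake frequencies, one per segment of $t$ seconds
(default 8 s, matching the analysis window), each in the physiological
range 60–160 bpm. The sender can derive a randomized schedule from any
seed string: the string is RSA-OAEP-encrypted, and each ciphertext byte
$b$ maps to $(b \bmod 101) + 60 \in [60, 160]$. A 4096-bit key produces a
512-byte ciphertext and hence 512 frequencies. Because OAEP padding is
randomized, the same seed string yields a different schedule every time —
the injected rhythm is unpredictable even to someone who knows the seed.

For transport, the schedule is serialized to a compact canonical byte
layout (version byte, phase-policy byte, big-endian counts, segment
duration and amplitude in hundredths, one offset-encoded byte per
frequency) and RSA-OAEP-encrypted for the receiver, chunked across blocks
when longer than one RSA payload. Whether the segment duration is part of
the encrypted payload was an open choice; we include it (and the
amplitude and phase policy), so the ciphertext alone, plus masks, fully
determines the inverse transformation. Tampering with the ciphertext is
detected by the OAEP integrity check and surfaces as a decryption error.

Keys use standard PEM encoding. Note that modern RSA keys satisfy
$d \equiv e^{-1} \pmod{\operatorname{lcm}(p-1, q-1)}$ (Carmichael's
function) rather than the textbook $\varphi = (p-1)(q-1)$ form; the two
give the same encryption/decryption identity. A small square-and-multiply
routine (`modpow`) exposes the schoolbook arithmetic for verification on
toy moduli.

## Facial regions

Masks come from 468-point face-mesh landmarks through a pluggable backend
(a CSV file of per-frame landmarks in the tests; any detector with the
same interface in production). Two region modes exist:

* **five regions** (modification default): the union of the upper medial
  forehead, lower medial forehead, glabella, and right/left malar patches —
  the regions that carry the strongest pulse signal. The exact polygon
  vertex indices are not fixed by any standard, so they ship as an
  explicit, documented, editable table (`facemesh_regions`).
* **face hull** (evaluation): the convex hull of all 468 landmarks minus
  the eye and mouth polygons, i.e. the holistic skin patch over which the
  RGB trace is averaged.

Rasterization uses a fixed convention — row-major, 0-based pixel-center
coordinates, even-odd fill with boundary pixels included — because sender
and receiver must produce bit-identical masks. Masks are per-frame with no
temporal smoothing; frames with no detected face pass through unmodified
on both sides and are logged.

## Measurement side

The evaluation pipeline mirrors standard rPPG practice: spatial mean of
each channel over the skin mask, one of eight projections (GREEN, CHROM,
POS, PBV, PCA, ICA, LGI, OMIT, following their original formulations), a
zero-phase Butterworth band-pass of design order 6 over 0.65–4.0 Hz
(39–240 bpm), 8-s windows with a 1-s stride (the overlap is otherwise
unquantified; it is configurable), Z-score normalization per window, and
heart rate as the in-band maximum of a Hann-tapered, zero-padded power
spectrum (grid finer than 1 bpm). The mean is removed before filtering:
the DC step at the edges of a short recording otherwise excites long
transients near the 0.65 Hz band edge. Signals are filtered in full and
then windowed. The 60-Hz reference PPG is resampled to the video rate by
linear interpolation before windowing, since window-wise comparison needs
a common rate. Numeric parity with any particular rPPG framework is not
promised for the seven non-GREEN projections; they are validated by
frequency-recovery behaviour (the component decompositions PCA/ICA select
the component with the most in-band power, and the compact symmetric
FastICA uses a fixed identity initialization so results are
deterministic).

Concealment quality is scored per window by DTW (classic dynamic
programming, absolute-difference cost, no band constraint, on Z-scored
windows), absolute Pearson correlation $|r|$ against the reference PPG,
and the absolute heart-rate error; and per video by PSNR (per-frame MSE
over all three channels, frame-averaged, capped at 100 dB when frames are
identical) and SSIM (standard constants, 11×11 Gaussian window,
$\sigma = 1.5$, replicate-padded convolution). The composite overall
score min-max normalizes DTW, $|r|$, PSNR and SSIM across a batch and
averages $\tfrac14\{\mathrm{DTW} + (1-r) + \mathrm{PSNR} + \mathrm{SSIM}\}$,
so $0 \le \mathrm{OS} \le 1$ with higher = better concealment at better
fidelity. The score is only defined relative to its batch; the batch
scope (all rows, or within each video) is a run-time parameter because no
single convention fits every comparison. A metric on which all records tie
contributes the neutral value 0.5.

## What the synthetic generator emulates — and what it does not

`make_pulsatile_video()` renders an elliptical "skin" patch whose green
channel oscillates as $a \sin(2\pi f_\mathrm{true}/60\, t)$ with i.i.d.
Gaussian per-pixel sensor noise, plus a noiseless 60-Hz reference PPG and
a canonical 468-point landmark layout on the patch. Defaults mirror the
recording setup the method targets: 640×480 @ 25 fps video (a consumer
webcam) and a 60-Hz fingertip-oximeter reference; pulse amplitude 1 grey
level and noise 2 grey levels are of the order seen in webcam skin pixels.
Generation is bit-reproducible under a fixed seed.

The generator deliberately omits head motion, illumination change,
specular highlights, compression artifacts and skin-tone diversity. Tests
passing on it therefore demonstrate the *mechanics* — exact reversibility,
locality, spectral takeover by the injected frequency, metric behaviour —
not robustness on real faces; dataset-scale replication requires real
recordings and a landmark detector.

## Numerical and design choices

* **Rounding**: R's `round()` (half-to-even) on the sinusoid; irrelevant
  to reversibility since both sides evaluate the identical function.
* **Saturation**: saturating add with a clip report, rather than refusing
  to conceal; at $A = 2$ clipping is rare and localized.
* **Schedule cycling**: when a clip outlasts
  $n_\mathrm{freq} \times t$ seconds the frequency list repeats from the
  start.
* **Frame storage**: frames are raw byte arrays (one byte per channel
  value), and the modulation loop uses a 256-entry saturating lookup table
  with a cached mask index, which keeps a conceal or restore pass over a
  10-s VGA clip under a second on one CPU and is measured that way
  (steady-state, after a warm-up pass) in the test suite.
* **Degenerate inputs**: constant windows are flagged and excluded from
  correlation/DTW; degenerate (collinear) landmarks raise an error rather
  than an empty mask; zero-variance traces yield zero-valued pulse
  candidates, not NaNs.
* **Problem sizes in tests**: the suite exercises full VGA resolution for
  the timing/reversibility checks and 64×80 to 96×128 clips of 9–30 s for
  pipeline behaviour — large enough for several 8-s windows, small enough
  to keep the suite quick.

## Known limitations

* The red and blue channels are untouched; residual physiological signal
  in them is out of scope here.
* Exact restoration fails (and is reported, via checksum and clip report)
  for saturated pixels, lossy transcodes, or mismatched masks/schedules.
* The five-region polygon table is a documented convention, not an
  anatomical ground truth; users with their own landmark conventions can
  edit it.
* OAEP chunked encryption authenticates each block but not the block
  order of very long schedules; schedules fit one block in all realistic
  configurations.

## A minimal walk-through

```{r example, eval = FALSE}
# sender ----------------------------------------------------------------
syn <- make_pulsatile_video(synth_config(duration_s = 10, seed = 7))
receiver <- rsa_generate_keypair(4096)
schedule <- derive_frequency_list("meeting_2026-03-14.mkv", receiver)
hidden <- conceal_video(syn$video, schedule, syn$mask)
payload <- encrypt_schedule(schedule, receiver)

# an eavesdropper measures the fake rhythm ------------------------------
trace <- extract_rgb_trace(hidden$video, syn$mask)
estimate_hr(bandpass_pulse(rppg_extract(trace, "CHROM"), 25)[1:200], 25)

# receiver --------------------------------------------------------------
restored <- restore_video(hidden$video,
                          decrypt_schedule(payload, receiver), syn$mask)
identical(video_checksum(restored$video), video_checksum(syn$video))
```
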
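# pcgsnr

Signal-to-noise-ratio quality assessment for phonocardiographic (PCG)
recordings, and determination of the minimum SNR a recording needs before
heart-valve-closure timing can be trusted.

## The problem

The four components of the two heart sounds mark the closures of the heart
valves: the first sound (S1) carries the mitral and tricuspid closures, the
second (S2) the aortic and pulmonary ones. The latencies from the ECG R-peak
to these components — R-S1,M, R-S1,T, R-S2,A, R-S2,P — index the heart's
electromechanical coupling and lengthen when ventricular function
deteriorates, which makes them attractive for home telemonitoring of
patients at risk of heart failure. But home-recorded PCG is noisy, and a
latency estimated from a poor recording is clinically misleading. Two
questions follow:

1. How should the quality of a PCG recording be quantified automatically,
   per heartbeat, without features that a pathology could distort?
2. Below which quality does the latency estimate stop being trustworthy at a
   given acceptable uncertainty?

## The method

**Per-beat SNR.** Cardiac cycles are delimited by the R-peaks of a
simultaneous ECG. For each beat and each heart sound,

    SNR = 20 log10( A_S / (4 sigma_N) )   [dB]

where `A_S` is the peak-to-peak amplitude of the sound inside its search
window and `4 sigma_N` is the 95% band of the noise, whose standard
deviation is measured in the 70–85% span of the cycle, where no heart sound
occurs. The recording-level SNR is the median over beats, separately for S1
and S2, computed on the raw signal.

**Calibrated degradation.** White Gaussian noise with standard deviation
`sigma_i = sigma0 * sqrt(10^(0.1 i / 10) - 1)` added to the original
recording (original noise sd `sigma0`) lowers the SNR by exactly `0.1 i` dB,
so stepping `i = 1, 2, ...` sweeps recording quality downward on a 0.1 dB
schedule. At every step the SNR and the four latencies are recomputed; the
loop stops when the measured SNR fails to decrease twice in a row (the
metric itself has broken down). Ten runs per recording are resampled onto a
common 0.1 dB grid and reduced to a median latency-versus-SNR curve.

**Minimum acceptable SNR.** Scanning that curve in decreasing SNR order, the
minimum acceptable SNR is the first grid point where the latency both (a)
shows a trend (exact Wald–Wolfowitz runs test on the signs of the trailing
deviations, alpha = 0.05) and (b) deviates from its high-SNR reference by
more than the acceptable uncertainty — either 1 ms (acquisition-system
resolution) or a percentage (2.5–20%) of the population median latency.
Curves that never leave the band yield "N/A". Population tables take the
worst case (maximum) over subjects.

Everything is testable without clinical data: the package ships a synthetic
PCG+ECG cohort generator with known ground truth (Gaussian-enveloped
component transients, QRS/T-wave ECG, calibrated noise) emulating the
population statistics the method was built on.

## Worked example

```r
library(pcgsnr)

rec <- generate_recording(60, fs_hz = 2000, heart_rate_bpm = 62,
                          target_snr_db = 22, seed = 2024, label = "demo")
seg <- segment_recording(rec)
snr <- compute_recording_snr(rec, seg)
agg <- aggregate_latencies(estimate_latencies(rec, seg))
norm <- test_noise_normality(rec, seg)

print(rec); print(seg); print(snr)
print(round(agg$latencies_ms, 1))
cat(sprintf("noise windows consistent with Gaussian: %.0f%%\n",
            100 * norm$fraction_non_rejected))
```

prints

```
<pcg_recording> demo
  120000 samples @ 2000 Hz (60.0 s)
  synthetic, target S1 SNR 22.0 dB, sigma0 0.0304, 61 beats
<beat_segmentation> 61 R-peaks, 60 cycles (60 retained)
<recording_snr> 60 beats, S1 22.2 dB, S2 18.9 dB
rs1m_ms rs1t_ms rs2a_ms rs2p_ms
   44.3    77.0   368.2   392.0
noise windows consistent with Gaussian: 95%
```

The recording was synthesized with a 22 dB S1 target and true mean latencies
near 44 / 77 / 368 / 392 ms; the pipeline measures 22.2 dB and recovers the
latencies within a fraction of a millisecond. From here,
`run_sensitivity(rec)` produces the median latency-vs-SNR curve,
`find_min_acceptable_snr()` / `subject_threshold_table()` /
`threshold_vs_uncertainty()` derive the minimum acceptable SNR tables, and
`select_validation_recordings()` + `compute_validation_sensitivity()`
implement the external-validation stage. `read_recording()` /
`write_recording()` handle CSV, WAV and WFDB-style records.

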
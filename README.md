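# laminocular

Laminar fMRI and EEG frequency-tagging analysis of monocular processing
and binocular interactions in human visual cortex, with a ground-truthed
synthetic-data generator so that every stage is verifiable by parameter
recovery.

## Who this is for

Researchers analysing cortical-depth-resolved BOLD responses and/or
steady-state visually evoked potentials (SSVEPs) under dichoptic
stimulation — typically in amblyopia or other binocular-vision studies —
who need the bespoke computations between standard preprocessing and
standard inferential statistics:

* **Laminar fMRI**: equivolume cortical depth from paired pial/white
  meshes, equal-volume layer compartments, vein-column exclusion
  (intensity < 0.70 × average, or response > 10% signal change), block
  GLM in percent signal change, ocular-bias ROIs (10% per side of the
  AE−FE distribution), and laminar profiles of the amblyopic deficit
  index.
* **Inverted encoding model (IEM)**: per-voxel non-negative monocular
  channel weights (Y = WC, non-negative least squares), OLS inversion of
  the binocular condition per depth bin, and the per-eye binocular
  suppression index.
* **EEG SSVEP**: zero-phase band-pass, surface Laplacian over an
  occipito-parietal montage, trial averaging, exact-bin amplitude
  spectra with first+second harmonic summation, intermodulation
  amplitude at f1+f2, least-squares phase with millisecond delay
  conversion.
* **Group statistics**: chi-squared Mahalanobis outlier flagging,
  percentile bootstrap CIs, circular means, one-sample and
  Watson–Williams mean-direction tests, and the ADI–BSI Pearson
  correlation.

The two headline indices, in the field's notation:

* ADI = (R_FE − R_AE) / R_FE — proportional response loss of the
  amblyopic eye;
* BSI = 1 − R_bino / R_mono — fraction of one eye's response suppressed
  under binocular viewing (per eye; via the IEM channel responses in
  fMRI, via tagged amplitudes in EEG).

## Worked example

Simulate a submillimeter run on a curved-wedge ribbon with a flat
planted ADI of 0.3 and planted suppression (BSI 0.40 for the amblyopic
eye, 0.05 for the fellow eye), then recover both through the full
pipeline:

```r
library(laminocular)

mesh  <- make_cortical_ribbon("wedge", n_vertices = 400, thickness = 2, ratio = 2)
truth <- laminar_truth(adi = 0.3, bsi_AE = 0.4, bsi_FE = 0.05)
ev    <- make_block_design(3, 18, 12, seed = 0)   # 282-s run
bold  <- simulate_bold_run(mesh, truth, ev, noise_sd = 0, spacing = 0.4,
                           partial_volume = 0.4)

glm   <- fit_block_glm(bold)
depth <- equivolume_depth(mesh, spacing = 0.4)
adi_profile(laminar_profile(glm, depth = depth))
#>   bin  depth_lo  depth_hi adi n_voxels
#> 1   1 0.0000000 0.3333333 0.3      800
#> 2   2 0.3333333 0.6666667 0.3     1050
#> 3   3 0.6666667 1.0000000 0.3      950

iem_bsi_profile(glm, depth = depth)[, c("bin", "bsi_AE", "bsi_FE")]
#>   bin bsi_AE bsi_FE
#> 1   1    0.4   0.05
#> 2   2    0.4   0.05
#> 3   3    0.4   0.05
```

The flat ADI of exactly 0.3 in all three compartments is the feedforward
signature (ratios cancel the depth gain), and the IEM returns the
planted suppression exactly despite 40% partial-volume mixing — the
naive binocular/monocular ratio would underestimate it.

On the EEG side:

```r
rec <- simulate_ssvep_recording(ssvep_truth(noise_sd = 3), n_trials = 6, seed = 1)
res <- analyze_ssvep_recording(rec)
res$indices        # per-SF ADI_mono, ADI_bino, BSI_AE, BSI_FE
res$delay_AE_FE_ms # planted 12.81 ms AE-vs-FE delay, recovered
```

End-to-end orchestration with provenance (config hash + seed stamped on
every table) is available through `run_fmri_arm()` / `run_eeg_arm()`
with `pipeline_config()`.

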
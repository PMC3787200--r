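---
title: "Counting synaptic inputs by 3D puncta colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting synaptic inputs by 3D puncta colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptoloc)
```

## The problem

A neuron filled with a tracer (e.g. Neurobiotin visualized with a Cy3
fluorophore) and immunolabeled for pre- and post-synaptic markers can be
imaged as a multichannel confocal z-stack. Counting its excitatory and
inhibitory synaptic inputs then becomes a geometric problem: a putative
synapse is a pre-synaptic punctum (VGLUT2 for glutamatergic, VGAT for
GABAergic terminals) lying within a stated physical distance of a
post-synaptic punctum (PSD-95, GABA-A receptor α1) that itself belongs to
the filled neuron. `synaptoloc` implements that workflow as scriptable,
deterministic stages:

1. **Surface segmentation** — threshold the fill channel into a voxel
   occupancy mask of the neuron (`create_surface()`), or model dendrites
   as generalized cylinders via centreline tracing (`trace_filament()`,
   `filament_to_mask()`).
2. **Role-based masking** — zero post-synaptic fluorescence outside the
   surface and pre-synaptic fluorescence inside it
   (`mask_channels_by_role()`).
3. **Spot detection** — reduce each punctate label to discrete spots with
   physical-unit centres (`detect_spots()`).
4. **Colocalization** — spots within a threshold distance of the surface
   (`spots_near_surface()`) and pre/post pairs within a threshold of each
   other (`colocalize_spots()`).
5. **Quantification** — compartment tables, co-label percentages,
   densities, and depth-penetration QC.

All distances are Euclidean in micrometres, computed from voxel indices
and the physical voxel spacing `(dz, dy, dx)`; anisotropy (a z-step of
0.3 µm over ~0.1 µm pixels is typical) is carried through every distance.
Array indices are never used as distances.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `intensity_threshold` (surface) | none | fill-channel level defining the neuron; chosen from `intensity_histogram()`, never automatic |
| `min_object_volume_um3` | 0 | components smaller than this are discarded as blebs |
| `diameter_um` (spots) | 0.3 pre / 0.6 post | nominal punctum size; sets the blob-filter scale σ = d/(2√3) |
| `quality_threshold` (spots) | none | minimum blob-filter response; picked at the valley of `quality_histogram()` |
| `min_z_slices` | 2 | candidates spanning fewer contiguous optical slices are rejected as single-slice artifacts |
| `max_distance_um` (coloc) | 1.0 | apposition threshold; ~0.5 µm suits SIM-resolution data |
| `bin_size_um` (depth QC) | 5 (soma) / 3 (distal) | depth histogram bin width |
| `cutoff_fraction` (depth QC) | 0.85 | analysis is cut at the depth where the cumulative spot fraction reaches this value |

Spot "quality" here is the scale-normalized Laplacian-of-Gaussian
response at the spot centre. Proprietary quality units of commercial
packages (e.g. thresholds like 13.5 or 14.9 "arbitrary units") do not
transfer to this scale; only the procedure — threshold on the filter
response at the valley of its histogram — does.

## Conventions fixed for determinism

Several choices are underdetermined by the workflow description and are
fixed here once:

* **Distances are centre-to-centre** (spot–spot) and
  centre-to-nearest-mask-voxel-centre (spot–surface). Edge-to-edge
  conventions would shift counts by roughly one punctum radius; the
  centre convention is independent of diameter estimates. Spots whose own
  voxel lies inside the surface have distance 0.
* **Pairing is many-to-many**: every pair within threshold is reported,
  so the pre-near and post-near counts can legitimately differ (counts
  like 45 pre vs 51 post spots from one cell are expected behaviour, not
  an error).
* **The surface is a voxel mask, not a mesh.** Mesh extraction adds an
  interpolation ambiguity that the mask avoids; rendering is a display
  concern.
* **Connectivity is 26-neighbour** for component labeling; size filters
  are expressed in µm³ and converted to voxel counts by half-up rounding.
* **Background subtraction** (surface stage) is a Gaussian low-pass at
  the stated object scale, clipped at zero — the separable, reproducible
  equivalent of rolling-ball estimates. Note that at a small object
  scale this removes the interior of large somata (the low-pass tracks
  them); on fill channels with low, flat background the surface stage is
  better run with `background_subtraction = FALSE`, as the examples do.
* **Depth background** (spot stage) is estimated per optical slice as
  the mean intensity of low-contrast voxels — those at or below the
  slice median of the local-contrast image — and subtracted uniformly
  per slice. This keeps detection counts stable against the roughly
  linear rise of background with imaging depth.
* **Plateau maxima** tie-break to the smallest (z, y, x) lexicographic
  index; all outputs are sorted, so repeated runs are byte-identical.
* **Rounding** of reported percentages is half-up (1 decimal for
  co-label percentages, nearest integer for percent changes, 2 decimals
  for frequency ratios), making printed tables bit-reproducible.

## The two-slice rule and axial sampling

Requiring supra-threshold support in at least two contiguous optical
slices suppresses single-slice artifacts. A consequence worth knowing:
the rule interacts with axial sampling. A punctum whose axial extent
(intrinsic size convolved with the optical PSF) is small relative to the
z-step can concentrate its supra-threshold response in one slice and be
rejected. With a confocal axial FWHM of ~0.56 µm at 0.3 µm z-steps,
real puncta comfortably span two slices; with SIM-like axial resolution
(~0.30 µm) the same z-step undersamples, and finer z-steps (~0.15 µm)
should be used — the SIM-mode tests do exactly that.

## Filament tracing

The alternative dendrite model follows the generalized-cylinder idea:
the thresholded fill mask is reduced to a centreline by farthest-point
geodesic paths through the voxel adjacency graph, with edge weights
penalized away from the ridge of the interior distance transform so the
path rides the medial axis. The local radius at a node is the
anisotropic distance to the mask boundary plus half the mean voxel
spacing (recentring the voxel-centre distance on the boundary). Side
branches are added until every tube-like voxel (interior depth above
half the minimal diameter, 0.4 µm by default) lies within the swept
tube of some node; branches shorter than the minimal diameter are
pruned. Voxelizing the resulting capsules gives a `neuron_surface`
interchangeable with the thresholded one — on tube phantoms both
definitions yield identical downstream synapse counts, mirroring the
agreement reported between surface- and filament-based filtering.

## What the phantom generator emulates

`generate_neuron_stack()` renders, with known ground truth: an ellipsoid
soma plus capsule-chain dendrites; paired puncta straddling the membrane
(post-synaptic 0.05–0.20 µm inside, pre-synaptic 0.30–0.55 µm outside at
the 0.8 µm default separation cap); distractor puncta scattered through
the volume (pre-distractors outside the neuron); a depth-linear diffuse
background; anisotropic Gaussian blur at the stated optical resolution
(FWHM 0.56/0.15/0.15 µm confocal, 0.30/0.12/0.12 µm SIM); and Gaussian
noise. Default study conditions: a 15 × 19.2 × 19.2 µm stack at
(0.3, 0.1, 0.1) µm voxels, soma radii (4, 5, 5) µm with one tapering
dendrite, 40 synapses, 100 distractors per channel, puncta of 0.3/0.6 µm
at peak 150 over a base-20 background rising 1 per µm of depth, noise
SD 4. Synapse sites are kept ≥ 2 µm apart so that genuine neighbouring
synapses do not cross-pair at the 1 µm threshold — with sites closer
than threshold-plus-offsets, cross-pairs are a property of the geometry,
not an error of the method.

What it does **not** emulate: realistic PSF side lobes, depth-dependent
blur, bleaching, scattering, antibody-penetration failure, or biological
clustering of synapses. Passing the recovery tests therefore shows the
geometry and thresholding logic is correct under resolution-scale blur
and noise — not that any particular biological dataset will be recovered
at the same rates.

Event-train synthesis (`generate_current_trace()`) superimposes Poisson
trains of difference-of-exponential events (rise 1 ms / decay 10 ms
inward; 2.5 / 25 ms outward) on Gaussian noise, returning the exact
injected event list.

## Electrophysiology analyses

`detect_events()` implements the optimally scaled sliding template: at
each offset the template is fit in scale and baseline by least squares,
and the detection criterion is scale divided by the standard error of
the fit, which makes detection exactly invariant to amplifier gain and
offset. Detections within one template length collapse to the highest
criterion, which makes template length a dead-time parameter: the
default template (rise + 4 decay constants long) suits kinetic fidelity
at low event rates, while rate estimation at ~10 Hz is better served by
a short (~5 ms) template covering just the rising phase and peak — the
rate-recovery tests use exactly that. The criterion threshold default of
3 is standard practice for this detector and is recorded in the output
metadata. Two numerical floors (10⁻⁶ and 10⁻⁹ of the trace range) keep
the criterion finite on noiseless data without breaking gain invariance.

Event kinetics report the interpolated 10–90% rise time and a
single-exponential-with-offset decay fit started where the signal has
fallen to 90% of peak (avoiding contamination by the residual rising
component); the fitted offset re-estimates the baseline and corrects the
amplitude for segments with no quiet stretch. Reversal potentials come
from ordinary least squares of amplitude on holding potential, with the
x-intercept CI by the delta method; distribution comparisons use the
two-sample Kolmogorov–Smirnov test (`stats::ks.test`, asymptotic p).

## Depth-penetration QC

Antibody penetration decays with depth, so spot counts deep in a stack
under-report. `depth_qc()` histograms spot depths (measured from the top
optical slice — depth 0 is an imaging origin, not the tissue surface)
and reports the cutoff depth where the cumulative fraction first reaches
85%. For a pre/post pair the binding cutoff is the *minimum* across the
two labels (the worst-penetrating antibody), applied to both sets by
`apply_depth_cutoff()` so the comparison covers a common depth range.

## Numerical and degenerate-input behaviour

Empty surfaces, empty spot sets, zero denominators, mismatched shapes or
physical frames, and templates longer than traces raise classed errors
(`EmptySurface`, `EmptySpotSet`, `ZeroDenominator`, `ShapeMismatch`,
`FrameMismatch`, `TemplateTooLong`) rather than producing numbers. TIFFs
without physical voxel metadata are refused unless a voxel size is given
explicitly: a silent 1 µm default would corrupt every downstream
distance. Stacks are written as 32-bit-float multi-page TIFF scaled into
[0, 1] with the scale, voxel size, channel roles and page layout in a
JSON sidecar; OME `PhysicalSizeX/Y/Z` attributes are honoured on read.

## Problem sizes used in the test-suite

The shipped tests run the full chain on the default 50 × 192 × 192
phantom (about 5.5 M voxels over three channels) once, plus a reduced
30 × 96 × 96 phantom for pipeline determinism checks, a 10 µm cylinder
phantom for the filament module, and 60 s of simulated current at
10 kHz for the detector; the complete suite finishes in about a minute
on a single core. These sizes were chosen as the smallest that leave
each property non-trivial (e.g. ≥ 10 blobs per detection test, ≥ 500
events per rate test).

## Known limitations

* Surface quality is entirely threshold-driven; there is no
  shape prior, so very dim dendrites below threshold simply vanish.
  The histogram helpers expose the choice; they do not make it.
* The z-anisotropy of confocal PSFs inflates surfaces axially, which can
  inflate "inside" counts; the filament route exists precisely as a
  cross-check, and disagreement between the two is a red flag worth
  investigating on real data.
* Spot detection assumes roughly Gaussian, roughly diffraction-limited
  puncta; elongated or merged structures yield single displaced spots.
* The sliding-template detector merges events closer than one template
  length; at high event rates use short templates and treat rates as
  slight underestimates.
* Distance-based pairing cannot distinguish a genuine synaptic
  apposition from a chance co-occurrence; the phantom experiments
  quantify that chance rate only under the generator's assumptions.
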
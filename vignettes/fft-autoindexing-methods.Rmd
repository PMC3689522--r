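---
title: "One-dimensional FFT autoindexing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-dimensional FFT autoindexing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fftindex)
```

## The problem

An oscillation diffraction image is a distorted projection of the crystal's
reciprocal lattice: a spot appears where a reciprocal-lattice point (rlp)
crosses the Ewald sphere while the crystal rotates through a small spindle
range. Autoindexing recovers, from nothing but a list of spot positions and
the experiment geometry, the shape of the unit cell and the orientation of
the crystal. `fftindex` implements the one-dimensional-FFT route to this
problem: map spots to reciprocal-space scattering vectors, find real-space
axis directions as periodicities of the projected vectors, choose a basis by
integral-index agreement, classify the reduced cell against the 44 lattice
characters, refine each plausible Bravais solution against the observed
positions, and optionally peel off several misoriented lattices by iterative
outlier rejection.

## Coordinate model

The laboratory frame has the X-ray beam along $+X$ and the spindle along
$+Z$; a flat detector sits normal to the beam at $x = D$ with its axes
parallel to lab $Y$ and $Z$. With beam-relative detector coordinates
$(X_d, Y_d)$ and $R = \sqrt{D^2 + X_d^2 + Y_d^2}$, a spot maps to the
dimensionless scattering vector

$$ \mathbf{s} = \left( \frac{D}{R} - 1,\; \frac{X_d}{R},\; \frac{Y_d}{R} \right), $$

which satisfies $|\mathbf{s} + \hat{x}| = 1$ by construction (unit Ewald
sphere). Every spot's $\varphi$ is taken as the midpoint of its oscillation
range — the dominant error source in the whole method — and vectors from
different images are rotated about the spindle to the common $\varphi = 0$
frame. Angles are degrees at every interface and radians internally.

## The direction search

For a projection axis $\mathbf{t}$ parallel to a real-space axis of length
$a$, the projections $p_j = \mathbf{s}_j \cdot \mathbf{t}$ cluster with
period $\lambda/a$, so the FFT of a binned indicator series of the
projections on $[-s_{max}, s_{max}]$ shows a peak at frequency index
$m = 2 s_{max} a / \lambda$. The search scans a quasi-uniform hemisphere of
directions (default step 1.7°, about 7,000 directions), then refines each
promising direction with two successive 5×5 local grids whose step shrinks
by 5 per stage, giving a final angular resolution of about 0.07°. Axis
lengths come from a parabolic sub-bin interpolation of the peak frequency,
so the quantisation error is well below 1% at the default 8,192-bin
transform (a 2,048-bin transform is used during the coarse scan, where only
peak detection matters).

Two practical details matter more than the transform itself:

* **Background contrast.** The projection density is a smooth bell, which
  leaks power into low frequencies; the raw in-range maximum is therefore a
  poor axis signature. Peaks are local maxima scored by their contrast
  above the neighbouring spectral floor, and among near-best peaks the
  lowest frequency wins — the comb fundamental, not a harmonic. A candidate
  is kept only if its contrast is at least 60% of its raw magnitude;
  short pseudo-periodicities of the Ewald-slab geometry (lune spacings)
  ride on the leakage background and fail this test, while genuine axes
  measure above 90%.
* **Acceptance threshold.** A direction is accepted when its raw peak
  magnitude reaches 0.2 times the number of vectors. The threshold is a
  fraction rather than an absolute count so that the same setting works
  from 30-spot lists to thousands.

Up to 30 candidate axes are retained, sorted by contrast; collinear
candidates (within 2°) keep the shorter axis.

## Basis selection

All triplets of retained axes are scored by the number of reflections whose
fractional indices $\mathbf{h}' = \lambda^{-1} A^{\mathsf T} \mathbf{s}$
deviate from integers by at least 0.3 (a reflection counts once even if
several indices deviate). The winner is the triplet with the fewest
rejections that does not have a significantly larger cell: among triplets
within $\max(3, 5\%N)$ rejections of the best, the smallest cell volume is
preferred, with ties broken by summed peak height and then candidate order.

Three guards surround this textbook rule, each motivated by a concrete
failure mode of thin two-image data:

1. **Deviation filter.** A basis can slip under the rejection threshold
   while misfitting every index (its deviations fill the tolerance band
   uniformly). Pool members whose mean deviation exceeds 1.5× the pool
   best + 0.01 are dropped before the volume preference, so an accidental
   small cell cannot outrank the lattice that actually indexes the data.
   The additive 0.01 keeps the noiseless doubled-axis case decided by
   volume, as it should be.
2. **Sharpness gate.** In mixtures of several misoriented lattices, a
   "compromise" basis can index most spots sloppily. When any triplet
   assigns at least half of its accepted reflections within a third of the
   threshold, only such sharp triplets compete. If none is sharp (heavily
   mosaic data), the gate waives itself.
3. **Information gate and residual verification.** A single image samples a
   thin shell of reciprocal space; near-coplanar triplets then reduce to
   cells with one tiny axis that carries no information (every reflection
   gets the same index along it). Bases whose reduced axes do not spread
   the assigned indices over at least three distinct integers are skipped,
   and the top few surviving bases are compared by a quick triclinic
   refinement — the positional residual is the decisive quality metric, and
   the smallest volume wins among bases within 1.3× of the best residual.

The chosen basis is finally polished by two rounds of linear least squares
of the scattering vectors on their rounded indices, which removes the small
length and direction errors that FFT candidates carry into triplet
combinations (long-vector triplets amplify them badly under reduction).

## Cell reduction, lattice characters, penalties

The chosen cell is Niggli-reduced by the stepwise Krivy–Gruber algorithm
(relative tolerance $10^{-5}$, iteration capped), applied as integer column
operations so the laboratory orientation is carried through. The reduced
metric is classified against the 44 lattice characters; the table of
conditions and reduced-to-conventional transformations ships as a JSON data
file and was validated programmatically: for hundreds of randomly generated
lattices of every Bravais type, some row of the correct type reaches
penalty 0 and its conventional cell reproduces the generating metric and
centring. The body-centred monoclinic character (43) is expressed in the
C-centred setting, with the I→C basis change folded into its transformation.

The distortion penalty is `round(999 × mean relative violation)` of a
character's conditions, where the violation of an equality $X = Y$ is
$|X-Y| / \max(|X|, |Y|, \varepsilon_G)$ and of $X = 0$ is $|X|/C$ (the
largest metric diagonal), with $\varepsilon_G = 10^{-6} C$. The scale is
calibrated so a distortion of about 1% of the metric gives a small
two-digit penalty, which keeps the conventional screening thresholds
meaningful: below 20 counts as a low penalty, and only characters below 50
are refined. Penalty orderings are comparable across programs; absolute
values are not.

## Refinement and ranking

For every character under the penalty gate, the conventional cell (under
exact Bravais constraints), two orientation angles, the direct-beam
position and optionally the crystal-to-detector distance are refined by
Levenberg–Marquardt least squares on the spot positions. Each reflection is
predicted at the spindle angle that puts its rlp on the Ewald sphere,
choosing the crossing nearest the oscillation midpoint (or the angle of
closest approach when no crossing exists). Spots whose starting deviation
exceeds 0.3 — the conventional single-lattice index gate — are excluded
from the fit. Distance refinement is off by default because of its strong
correlation with the cell parameters; it is appropriate for
high-resolution data only.

Two deliberate choices:

* **Spindle-azimuth gauge.** A rotation of the crystal about the spindle
  axis shifts every predicted crossing angle equally and leaves all
  positions unchanged — an exact null direction of a position-only fit.
  Orientation is therefore parameterised by two angles (about lab X and Y)
  and the azimuth stays pinned to the orientation delivered by indexing,
  which the midpoint mapping centres in $\varphi$. Without this, the
  solver drifts freely along the gauge and corrupts $\sigma(\varphi)$ and
  the index assignments.
* **Residuals.** $\sigma(x,y)$ is the r.m.s. of the two-dimensional
  positional residual (so pure Gaussian noise of $\sigma$ per coordinate
  gives $\sigma\sqrt{2}$), $\sigma(\varphi)$ the r.m.s. of the signed
  $\varphi_{calc} - \varphi_{mid}$ residual (about $0.29°$ for a 1°
  oscillation, i.e. $1/\sqrt{12}$), and $\delta$(beam) the Euclidean shift
  of the refined beam from the input.

Ranking marks any solution whose $\sigma(x,y)$ exceeds 1.3× the triclinic
value as a pseudo-symmetry suspect, then highlights the highest-symmetry
non-suspect below penalty 20, falling back to the best non-suspect below 50
and finally to the triclinic solution itself.

## Multiple lattices

Multi-lattice indexing assumes the full spot list indexes as a single
lattice, labels as outliers the spots whose indices deviate from integers
by at least 0.2 under the refined triclinic basis (a positional criterion
is available as an alternative), re-indexes the accepted spots, appends
further outliers, and then feeds the rejected list to a fresh indexing pass
for the next lattice. Iteration stops when the rejected list holds less
than 10% of all spots found or a lattice cap (8) is reached; leftover spots
stay unassigned. Each lattice's reported solution table comes from a final
clean re-index of exactly the spots assigned to it. Unit-cell parameters
are deliberately not forced to agree across lattices.

Because a minority lattice legitimately rejects most of a mixture, the
passes run with the basis-selection failure gate relaxed to 90% (the
single-lattice default is 50%). Misorientations against the first lattice
are minimal rotation angles over the proper symmetry operations of the
reduced cell; the metric tolerance for recognising those operations is
deliberately generous (1% of the mean metric diagonal), because refined
bases carry small metric errors and a missed operation turns a sign
convention into a spurious near-180° angle.

## The beam search

Indexing is attempted over a grid of beam positions (±2 steps of 0.5 mm by
default, 25 nodes) with the beam held fixed at each node, so the triclinic
residual measures that node's beam error; refining the beam inside the node
fit would flatten the landscape. Oversized cells (volume beyond 1.5× the
grid median) are discarded, and the recommendation then exploits the
consistency of refined beams: nodes belonging to the correct solution
family refine to the same beam position, so the lowest-residual node within
the largest 0.25 mm cluster of refined beams wins. This also rejects the
characteristic false minima created by re-indexing ±1 along a cell axis
whose reciprocal direction lies near the spindle, which mimics a beam shift
of roughly $\lambda D / a$.

## The simulator and what passing tests mean

The forward simulator enumerates all rlps of one or more crystals inside a
resolution sphere, solves the Ewald crossing inside each (mosaicity-widened)
oscillation range in closed form, projects the diffracted ray onto the
detector, adds independent Gaussian positional noise per coordinate, and
emits a per-spot ground-truth ledger (crystal, indices, true $\varphi$,
noiseless position) plus the realised orientations. Intensities follow a
crude exponential decay with resolution plus lognormal scatter — enough to
exercise I/σ thresholds, since indexing uses positions only. Mosaicity is a
hard widening of the crossing acceptance window, not a reflection profile;
it reproduces the midpoint-error pathology of broad oscillations but not
partiality. What the simulator does not emulate: detector point-spread and
pixelation, overlapping and split spot centroids, radiation damage, ice or
zingers as actual false spots, and anisotropic mosaicity. Passing tests
therefore demonstrate the geometry, the search and the decision rules, not
robustness to every pathology of real images.

Default study conditions (chosen once): orthorhombic 50×60×70 Å cell,
wavelength 1 Å, distance 150 mm, two 1° images at 0° and 90°, resolution
3 Å (about 350 spots), positional noise 0.03 mm. The four-lattice
split-crystal scene uses 100 mm distance, 1.6 Å resolution and a 20% spot
fraction (about 1,900 spots): separating a 0.8° misorientation with an
index-deviation threshold of 0.2 requires deviations of roughly
$\theta \cdot |\mathbf{s}| \cdot a / \lambda$ to exceed 0.2, which for a
50–70 Å cell needs data beyond about 2 Å. These sizes keep a full
single-lattice run at a couple of seconds and the complete simulation
suite within a few minutes.

## Worked example

```{r example, eval = FALSE}
geom <- experiment_geometry(wavelength = 1.0, distance = 150,
                            beam_centre = c(100, 100))
scene <- synthetic_scene(crystal(c(50, 60, 70, 90, 90, 90)), geom,
                         noise_sigma_mm = 0.03, seed = 1)
gen <- generate_spots(scene)
res <- index_spots(gen$spots, geom)
print(res)
writeLines(format_solution_table(res))
```

## Known limitations

* The first multi-lattice pass must succeed on the full list; scenes where
  no lattice reaches the relaxed rejection gate fail outright, as the
  method's own design accepts.
* Split crystals below the resolution-dependent separability bound merge
  into one lattice whose orientation is a compromise of the pair.
* The 0–999 penalty scale is calibrated, not standardised: orderings are
  comparable with other implementations, absolute values are not.
* $\varphi$ centroids are never refined; fine-sliced data are treated
  exactly like coarse oscillations.
* The beam search reports its consistency-based recommendation, but truly
  degenerate cases (very long axes) may need intensity-based checks that
  are out of scope here.
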
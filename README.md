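# fftindex

Autoindexing of macromolecular diffraction spot lists by the
one-dimensional fast-Fourier-transform method, in R.

Given spot positions from one or more oscillation images plus the basic
experiment geometry (wavelength, crystal-to-detector distance, direct-beam
position, spindle sense), `fftindex` determines the shape of the crystal's
unit cell and its orientation — with no prior knowledge of either — and
can peel apart several misoriented lattices recorded in the same images.
It is aimed at crystallographers and methods developers who want an
inspectable, scriptable implementation of the classic autoindexing chain,
plus a forward simulator that makes every stage testable without real
detector data.

## The method

1. **Ewald mapping.** Beam-relative spot coordinates $(X_d, Y_d)$ map to
   dimensionless reciprocal-space scattering vectors
   $\mathbf{s} = (D/R - 1,\ X_d/R,\ Y_d/R)$ with
   $R = \sqrt{D^2+X_d^2+Y_d^2}$, so the Ewald sphere has unit radius; each
   spot is assigned the midpoint of its oscillation range and all vectors
   are rotated about the spindle to a common $\varphi$ origin.
2. **Direction search.** For every direction $\mathbf{t}$ on a sampled
   hemisphere, the projections $\mathbf{s}_j \cdot \mathbf{t}$ are binned
   and Fourier-transformed; a real-space axis of length $a$ parallel to
   $\mathbf{t}$ produces a peak at frequency index
   $m = 2 s_{max} a/\lambda$. Promising directions are refined on
   successively finer grids; up to 30 non-collinear axes are retained.
3. **Basis selection.** Axis triplets are scored by how many reflections
   receive integral indices
   $\mathbf{h}' = \lambda^{-1} A^{\mathsf{T}}\mathbf{s}$ within a 0.3
   deviation; the best-scoring triplet without a significantly larger cell
   becomes the orientation matrix $[A]$.
4. **Reduction and classification.** The cell is Niggli-reduced and
   compared against the 44 lattice characters; each gets a 0–999
   distortion penalty and a conventional cell.
5. **Refinement and ranking.** Every character with penalty below 50 is
   refined (cell under exact Bravais constraints, orientation, beam,
   optionally distance) against the observed spot positions; solutions
   whose positional residual exceeds 1.3× the triclinic residual are
   flagged as pseudo-symmetric, and the best plausible solution is
   highlighted.
6. **Multiple lattices.** Spots whose indices deviate by ≥ 0.2 from
   integers are moved to a rejected list, the remainder re-indexed, and the
   rejected list fed to a fresh pass for the next lattice, until fewer
   than 10% of all spots remain unexplained.

## Worked example

```r
library(fftindex)

geom  <- experiment_geometry(wavelength = 1.0, distance = 150,
                             beam_centre = c(100, 100))
scene <- synthetic_scene(crystal(c(50, 60, 70, 90, 90, 90)), geom,
                         noise_sigma_mm = 0.03, seed = 1)
gen   <- generate_spots(scene)      # 371 spots on two 1-degree images
res   <- index_spots(gen$spots, geom)
print(res)
#> FFT autoindexing: 371 spots, 371 vectors, 0 rejected (0.0%)
#> Highlighted: oP (character 32, penalty 0)
#>   cell 50.00 60.00 69.99 A  90.00 90.00 90.00 deg
#>   sigma(x,y) 0.0432 mm  sigma(phi) 0.282 deg  delta(beam) 0.001 mm
```

The highlighted row says the data index on a primitive orthorhombic
lattice whose refined cell matches the generating 50×60×70 Å cell to a few
hundredths of an angstrom; `sigma(x,y)` = 0.043 mm is the r.m.s. spot
position residual (the simulated noise was 0.03 mm per coordinate, and
0.03·√2 ≈ 0.042), `sigma(phi)` ≈ 0.28° reflects the 1° oscillation width,
and the refined direct beam moved only 0.001 mm from the input. The full
44-row solution table, with per-character penalties and pseudo-symmetry
flags, is in `solution_table(res)` or `format_solution_table(res)`.

Two lattices in the same images:

```r
scene2 <- multilattice_scene(c(50, 60, 70, 90, 90, 90),
                             misorientations_deg = c(0, 10),
                             shares = c(0.6, 0.4), geom = geom, seed = 5)
ml <- index_multilattice(generate_spots(scene2)$spots, geom)
print(ml)
#> Multi-lattice indexing: 2 lattice(s), 53 of 609 spots unassigned
#>   lattice 1:  323 spots, oP cell 50.00 60.00 70.00 ... misorientation 0.00 deg
#>   lattice 2:  233 spots, oP cell 49.99 60.00 69.99 ... misorientation 9.97 deg
```

A thin command-line front end ships in `inst/cli/fftindex.R`
(subcommands `simulate`, `index`, `index-multi`, `beam-search`).

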
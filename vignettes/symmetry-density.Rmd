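---
title: "Mirror-symmetry density: the histogram algorithm and its spiking realization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mirror-symmetry density: the histogram algorithm and its spiking realization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symspike)
library(ggplot2)
```

## The model

A point p in a plane is a locus of mirror symmetry of a point set X when many
pairs of X are equidistant from it: every such pair could be folded onto
itself across a line through p. symspike quantifies this with a *distance
tensor*: at every grid point p, the histogram of distances from p to all
points of X, each distance rounded to a configurable number of decimals
(`decimals` in `density_config()`). The value of each histogram component at
distance d is the discretization of the contour integral of the image
surface on the circle of radius d around p. The **mirror-symmetry density**
at p is the peak of this histogram — the count (or accumulated weight) of
the most frequent binned distance. Perpendicular bisectors of point pairs,
centers of circles, and the axes of symmetric figures accumulate large peaks;
unstructured clutter does not. The cost is O(mn) for m output pixels and n
input points.

```{r four-corners, eval = FALSE}
corners <- data.frame(x = c(0, 8, 0, 8), y = c(0, 0, 8, 8))
map <- symmetry_density(corners, 9, 9)
autoplot(map)   # global maximum 4 at the center (4, 4)
```

Any metric satisfying non-negativity, symmetry and the triangle inequality
can stand behind the histogram. The package implements Euclidean and
Manhattan (L1) distance; L1 needs no multiplication or square root, which is
why the digital-logic network below uses it, at the cost of emphasizing
horizontal, vertical and diagonal equidistant structure.

## The spiking realization

The same field falls out of a single layer of leaky-integrate-and-fire (LIF)
coincidence detectors when axonal delay is taken seriously. Every input-grid
neuron connects to every output-grid neuron through a delay line of length

    L(i, o) = round(k * d(i, o)) + base        [clock cycles]

If all active inputs fire once, simultaneously, the number of pulses
arriving at output o during one cycle equals the height of one histogram
bin at o; the maximum over cycles equals the density. This equivalence is
exact — `detect_symmetry(run_symmetry(...))` reproduces
`symmetry_density(..., density_config(decimals = 0))` bin for bin — because
both sides use the same half-away-from-zero rounding, and because the
uniform `base` offset shifts every arrival by the same amount without
changing any per-cycle count. The test suite asserts this equality on
hundreds of random point sets, and separately checks that for two-point
inputs the firing outputs are exactly the equidistant set of the pair under
the configured metric.

The discrete neuron update, in order within a cycle: advance lines, sum
arrivals, subtract the leak, clamp at zero, compare to threshold, reset on
fire. Clamping and this ordering are a design choice (the digital-logic
description fixes summation-minus-leak and reset-to-zero but not the rest);
they make the two-pulse coincidence example exact. With the defaults A = 1,
theta = 1.5, lambda = 0.5 a pair of pulses fires only when it arrives in the
same cycle: one cycle after a lone pulse the residual is 0.5, and
0.5 + 1 - 0.5 = 1.0 < 1.5. An m-fold detector uses theta = (m - 0.5) A. One
caveat of leaky accumulation worth knowing: three or more *consecutive*
single arrivals can also accumulate to threshold (0.5 per cycle with the
defaults); this cannot occur with two-point inputs and does not affect the
arrival-count readout of `detect_symmetry()`, which ignores the accumulator.

Delay lines are represented either as shift registers (a bit per cycle of
travel) or as countdown registers; the two are observationally equivalent
and tested as such. The 8x8 Manhattan network with k = 1 and base = 2 has
4096 lines, maximum length 14 + 2 = 16 and, with a two-stage accumulator,
an input-to-output latency of 18 cycles. The printed maximum length of 16
exceeds the 8x8 Manhattan diameter of 14; we reconstruct the difference as a
two-cycle pipeline offset on every line (`base = 2`), which is a choice —
the hardware description does not state the decomposition. `base` is
configurable.

`min_energy_bound()` complements the simulator with the physical floor on
switching energy for a delay-coded detector at the ultimate speed limit,
pi*hbar*c / (2 d_p) joules for array pitch d_p in meters — the only place
the package leaves pixel units.

## Layering, feedback, and sets

Coincidence times at the output layer depend on the data, so stacking a
second symmetry layer directly on the first would feed it desynchronized
spikes. A **synchronization layer** of slow-leak LIF neurons stores lower
fires (threshold above one stored pulse) and releases them simultaneously
when a periodic timing pulse arrives. With the defaults (store 1, release 1,
threshold 1.75, leak 0.01) a stored spike survives (1 + 1 - 1.75) / 0.01 =
25 cycles of waiting, comfortably above the latency of the grids the package
targets; the timing period defaults to the lower latency + 2 and refuses to
run below the latency. `run_hierarchical()` returns the symmetry of the
symmetry points; `run_recurrent()` instead unions the released fires with
the original input and re-presents, which matches `iterate_density()` — the
histogram algorithm applied repeatedly with feedback, whose
`feedback_threshold` defaults to the current map mean.

For comparing two labeled sets, each set receives a pseudorandom delay code:
one integer offset per output connection, uniform on `[0, code_range]`
(default 4), added to every line that originates in the set. We index the
code by output neuron because it makes single-set invariance exact — a
common offset at an output is a pure time shift — whereas indexing by delay
value could create accidental new coincidences; the source description
("one pseudorandom value for each distance value in the norm") is ambiguous
between the two. A surviving cross-set coincidence requires the two codes to
agree at that output, probability 1/(code_range + 1), so dispersion improves
with the range; integer (whole-cycle) offsets are used. The inter-set map is
realized as exact subtractive inhibition, clamp0(union - intra), chosen
deterministic for testability.

## GPU-style heuristics

`bisection_density()` is the exact pairwise variant: for every unordered
pair of above-threshold points it rasterizes the perpendicular bisector with
a Bresenham-style walk whose slope is inverted (negative reciprocal),
anchored at the pair midpoint and clipped to the domain; every raster point
is within half a pixel of the true bisector, hence within one pixel of exact
equidistance. When the midpoint has half-integer coordinates it is not
itself a grid point; the raster brackets it, and the rounded midpoint can
sit one pixel off the raster for odd diagonal pairs — the tests assert
one-pixel proximity rather than strict membership.

`randomized_midpoint_density()` is the mutex-free simplification: source
points are scattered into a fixed M-slot array (K passes of random
single-slot writes, then a sequential sweep for empty slots, then seeded
re-insertion of any point that was completely overwritten, so capacity and
multiplicity invariants always hold; M defaults to 4n). Each of `n_draws`
iterations draws two slots, skips identical points and pairs beyond
`dist_limit`, and increments the rounded midpoint. We count *draws*, not
surviving increments, as the iteration budget — the alternative reading
exists, and the convergence test therefore compares map/N against the exact
per-draw increment distribution computed from the slot multiplicities, with
the skip mass excluded identically on both sides. Sequential semantics are
the contract; the lock-free parallel variant's collision noise is out of
scope.

Both heuristics and the histogram algorithm accept a distance limit
(pair/contribution filter). Enlarging the limit can only add contributions,
so density maps are pointwise monotone non-decreasing in it — the mechanism
behind scale selection on multi-scale inputs such as the triangle IFS
fractal, and a property the acceptance tests assert across limits of 9, 19,
39 and 78 percent of the image size.

Noise enters in two distinct places with opposite uses: Gaussian noise on
*distances* (`distance_noise_sd`, clamped at zero before binning — the
clamp is ours, avoiding negative-distance bins) or on *delay lines*
(`add_delay_noise()`, clamped at `base`). Small noise relative to the bin
size perturbs the output only slightly; larger noise first destroys narrow
coincidence bands and then floods the map, which the tests capture as mean
MSE rising from sd = 1 to sd = 5 over 20 seeds against the noiseless map
(MSE defined as the per-pixel mean of squared differences; a total-sum
normalization would only rescale the comparison).

## The image pipeline and synthetic tiles

`run_experiment()` reproduces the overhead-imagery workflow: first channel,
Sobel-Feldman gradient magnitude (reflect padding, so constant images give
zero edges and an interior step of height h responds 4h), strict threshold
128, then either density variant; the reference heuristic configuration is
dist_limit = 50 px and n_draws = 177828. Images are read directly from
PNG/TIFF; the original tooling's TIFF-to-JPEG recompression is treated as an
I/O artifact, not re-implemented. `region_stats()` scores polygon regions by
the mean density over pixels whose centers fall inside the ring (even-odd
rule, via `mgcv::in.out`); the per-image statistic compares the pooled
building-pixel mean against the whole-image mean, following the per-image
reading of the building comparison.

`make_synthetic_tile()` generates the test imagery: a low-intensity textured
background, Poisson-placed irregular clutter blobs, and bright axis-aligned
rectangles with polygon footprints (rings offset 0.5 px outward so border
pixels count as inside). It emulates exactly one thing — the edge-geometry
statistics the method consumes: straight parallel building edges contribute
many equidistant pairs, clutter few. It does not model sensor noise, ground
sampling, oblique geometry, shadows, or rotated footprints, so passing tests
demonstrate the mechanism, not performance on real imagery; the reported
93% building statistic on real satellite tiles is explicitly not claimed
or reproduced here. Likewise the aircraft outline is a generated bilaterally
symmetric polygon standing in for a fighter silhouette that is not
available, so only the direction of the delay-noise response is asserted,
never published MSE magnitudes.

## Numerical choices and problem sizes

* Rounding is half-away-from-zero everywhere (binning, delays, midpoints);
  base R's banker's rounding would break oracle equality on ties.
* Self-distance: a probe point that coincides with an input point keeps its
  0-bin contribution, preserving the n-contributions-per-histogram
  invariant; for n >= 2 it cannot create spurious maxima.
* Weighted mode uses the per-point pixel value (the algorithm iterates
  points, not pairs); this deviates in spirit from averaging the two
  equidistant pixels of a pair and is documented as such.
* Mode ties need no tie-break: only the peak count is emitted, never the
  bin identity.
* Degenerate inputs fail loudly with classed conditions: empty point sets,
  non-positive dimensions, horizons below latency, overlapping label sets,
  out-of-bounds or self-intersecting polygons.

Tests and acceptance checks run on deliberately small instances chosen as
the smallest sizes that exercise every mechanism: grids up to 12x12 (the
brute-force oracle up to 16x16), the 8x8 hardware geometry, a 20x20
aircraft outline, a depth-3 fractal on 32x32, and fifty 64x64 tiles for the
region statistic. All randomness flows through explicit seeds; all
generators are pure functions of their arguments.

## Known limitations

Only mirror symmetry is detected — rotational, scaling and skew symmetry
are out of scope by design. The histogram implementation is vectorized R
adequate for these grid sizes, not a GPU kernel; the exact pairwise variant
is quadratic in the point count. Sub-pixel point positions and geodesic
metrics are not supported. The set machinery implements pairwise comparison
only; cascading more than two sets is described upstream but not built.
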
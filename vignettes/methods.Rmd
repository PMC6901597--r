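---
title: "Methods: regional quantification of segmented objects in atlas-registered sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional quantification of segmented objects in atlas-registered sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasquant)
```

## Model and procedure

`atlasquant` quantifies labelled objects in serial brain sections that
have been (a) segmented into exact RGB colour codes and (b) registered
to a 3D reference atlas. The pipeline per section is:

binarize by colour → extract connected components → filter by size →
assign regions → per-region report → 3D points → overlay; series
aggregation pools the per-section reports.

**Object extraction.** A mask is taken per target colour by *exact*
RGB match — off-by-one colours are a warning, never snapped, because
anti-aliased segmentations are invalid input and should be surfaced,
not absorbed. Maximal connected components are collected by flood
fill. The semantics are those of a recursive fill, but the
implementation (compiled, `src/label.cpp`) uses an explicit stack:
plaque cross-sections can reach 10⁶ pixels and must not be limited by
call-stack depth. Components are scanned in raster order, so object
numbering is deterministic and the first-visited pixel of each object
is its *anchor*: the member with minimum y, ties broken by minimum x
("top-left pixel"). Default connectivity is 8 — diagonally touching
plaque pixels belong to one plaque — with 4-connectivity available;
the choice is exposed because the underlying biology does not dictate
it.

**Region assignment and the two attribution rules.** The anchor rule
assigns a whole object to the atlas region under its anchor pixel and
is always used for object *counts*. Region *load*, however, is defined
as the labelled area within the region divided by the region's area,
which is a statement about pixels, not objects. The package therefore
defaults to pixelwise attribution for areas and loads (each labelled
pixel credited to the region under it) while counting objects by
anchor. Both rules are switchable (`attribution = "pixel"|"anchor"`),
and they agree exactly whenever no object straddles a region boundary
— a property the test suite checks. Surfacing both rules, rather than
silently picking one, is a deliberate design choice: on sections where
many objects cross boundaries the two can differ noticeably, and the
discrepancy is scientifically meaningful (it measures boundary
straddling).

**Load arithmetic.** For region $r$ with area $A_r$ pixels and
labelled area $a_r$, $\mathrm{load}_r = a_r / A_r$. Merged custom
regions and series aggregates are always pooled *area-weighted*:
$\mathrm{load}_{G} = \sum_{r \in G} a_r / \sum_{r \in G} A_r$, never
the mean of member loads — the mean would weight a tiny region equally
with cortex. Zero-area regions yield an NA-flagged load rather than a
silent NaN. Excluded regions leave both numerator and denominator of
whole-brain summaries.

**Unit arithmetic.** Segmentations are produced from scans downscaled
by `resize_factor` before classification, so one segmentation pixel
covers $(\text{pixel\_size}/\text{resize\_factor})^2$ µm². At the
scales typical for plaque series (0.284 µm/px scanned, factor 0.05) an
8-pixel minimum object size corresponds to
`r object_area_um2(8, scale_spec(0.284, 0.05))` µm²; at 0.265 µm/px a
4-pixel cut-off at factor 0.05 is
`r object_area_um2(4, scale_spec(0.265, 0.05))` µm² and an 8-pixel
cut-off at factor 0.1 is
`r object_area_um2(8, scale_spec(0.265, 0.1))` µm². Size filters are
inclusive at both ends; whether the original tooling treats its bounds
inclusively is not documented anywhere we know of, so the inclusive
choice is documented here and tested.

**Anchoring geometry.** A section of $W \times H$ pixels is placed in
atlas space by vectors $o$ (top-left corner), $u$ (width axis) and $v$
(height axis), in atlas voxel units. Pixel $(x, y)$ maps to
$o + u\,(x + \tfrac12)/W + v\,(y + \tfrac12)/H$ under the default
pixel-centre convention. The half-pixel offset makes the point set
unbiased with respect to the pixel's footprint; a corner convention
($x/W$, $y/H$), which maps $(0,0) \mapsto o$, $(W,0) \mapsto o+u$,
$(0,H) \mapsto o+v$ exactly, is selectable for byte-compatibility with
tools that use it. Registration exports do not state their coordinate
unit, so exports record the unit (`voxel` by default) in file metadata
rather than guessing a micrometre multiplier.

**Point-grid area-fraction estimator.** For validation against
stereology, the package reimplements the point-counting probe:
counting frames of $f_x \times f_y$ µm laid at grid period
$g_x \times g_y$ µm, test points every $p$ µm inside each frame
(points at cell centres, $p/2$ inset), estimate = hits / points, with
the binomial standard error $\sqrt{\hat{p}(1-\hat{p})/n}$ reported.
Defaults are 300/200/20 µm, the common plaque-load settings. A section
smaller than one frame, or a degenerate grid, returns an NA-flagged
estimate rather than an error or a silent zero.

## Atlas-map handling

Atlas maps arrive either as colour-coded PNGs (decoded exactly through
the label table; any off-palette pixel is an error naming the colour
and first offending pixel) or as a raw little-endian label matrix
(`QMAP` magic, width, height, row-major uint32 ids) — registration
tools export one or the other, and supporting both keeps the package
tool-agnostic. When segmentation and map dimensions differ, the *map*
is rescaled to the segmentation by nearest-neighbour (labels are
categorical; the segmentation carries the measured signal and is never
resampled). The output pixel at index $i$ takes the source pixel
containing $(i + \tfrac12) \cdot s/d$ — the standard centre-mapping
rule, verified in tests against an independent per-pixel oracle.

## PNG input/output

The deployment environment provides no R binding to libpng, so the
package carries a minimal codec (8-bit greyscale/RGB/RGBA, no
interlacing) over base R's zlib stream support. The reader implements
all five scanline filters and is validated against a frozen file
produced by an independent encoder with adaptive filtering; the writer
emits filter-0 scanlines, which every PNG reader accepts. This scope
covers exactly the 24-bit segmentations and atlas plates the workflow
uses; palette, 16-bit and interlaced PNGs are rejected with a clear
error.

## Synthetic scenes: what they emulate and what they do not

`make_scene` builds one registered, segmented section with known
truth: a label table with a two-level hierarchy; an atlas map of
vertical region bands with a notch carved into band 1 (so at least one
region is concave, exercising boundary rendering and pixelwise
attribution); objects planted as irregular blobs grown by seeded
4-neighbour region growing (not discs — connected-component code
should face plaque-like shapes); and a randomized planar anchoring.
`make_series` advances the anchoring origin along one axis at a fixed
spacing, emulating serial coronal sectioning at every-4th-section
sampling, with optional jitter (`drift`).

Generator defaults state the testing world once: 128×128 px sections,
4 regions, 10 objects of 8–60 px (sizes straddling the 8-px minimum
cut-off used for plaque series), `straddle_fraction` controlling how
many objects cross region borders. Objects are planted with at least
one pixel of Chebyshev clearance from each other and are grown
4-connected, so extraction recovers the planted partition *exactly*
under both connectivities — this is what makes the end-to-end
acceptance check an exact integer equality rather than a tolerance
test.

What a green fixture test establishes: the pipeline's bookkeeping
(extraction, attribution, areas, loads, aggregation, coordinates) is
exact on inputs whose truth is known by construction. What it does not
establish: segmentation quality, registration quality, or behaviour on
anti-aliased/invalid exports — the first two are upstream of this
package by design, the third is deliberately an error.

## Numerical and formatting choices

* Resize output dimensions are round-half-up of factor·dimension, with
  the precondition factor·dimension ≥ 1 (a request that would produce
  a sub-unit output errors out before rounding).
* Report floats carry 6 significant digits; all pixel counts are exact
  integers end to end. Loads are exact rationals of integers until
  formatting.
* Point-cloud TSVs print coordinates with `%.9g` (round-trips to
  1e-6 over the coordinate magnitudes in use); subsampling is
  every-k-th, never random, so exports are reproducible.
* All outputs are deterministic: directory listings are sorted,
  nothing depends on wall clock or iteration order, and rerunning a
  configuration is bit-identical (tested).
* Section keys are extracted with a configurable regex (default
  `_s(\d+)`, leading zeros ignored) and matching is strict: unmatched
  images/maps/anchors are reported, duplicates are errors, nothing is
  silently dropped.

## Known limitations

* No nonlinear section-to-atlas deformation; the anchoring model is
  planar-affine, as exported by the registration tools it consumes.
* Hemisphere is not modelled separately: left/right are distinct
  regions only if the label table provides distinct ids.
* The overlay renderer draws no text labels (font rendering is
  platform-dependent; tests compare label-free images).
* The point-grid estimator assumes the whole mask is "section"; it
  does not take a separate section-contour input.
* The TOML reader is a documented subset (sections, scalars, flat
  arrays) sufficient for the configuration schema; it is not a general
  TOML implementation.
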
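---
title: "Methods: ROI-based archival compression in roipack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROI-based archival compression in roipack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roipack)
```

`roipack` implements an archival codec for single-frame grayscale medical
images built on a simple observation: in a typical MR frame, the
diagnostically relevant anatomy occupies perhaps a third of the pixels,
while the rest is near-black background carrying only burned-in annotation
text. The package therefore treats the two regions asymmetrically — the
region of interest (ROI) is preserved bit-exactly, the background is
reduced to its text content and regenerated at read time. This vignette
documents the model, the tunable parameters, the numerical choices, and the
limits of what the tests demonstrate.

## Segmentation model

The ROI/non-ROI split uses the Chan–Vese two-phase piecewise-constant
active contour. With the image normalized to unit range, the mask minimizes

$$E = \mu\,\mathrm{Length}(\partial M)
 + \lambda_{in} \sum_{M} (I - c_{in})^2
 + \lambda_{out} \sum_{\bar M} (I - c_{out})^2,$$

where $c_{in}, c_{out}$ are the region means. The level set is evolved with
a semi-implicit Gauss–Seidel scheme and a smoothed Heaviside/delta of width
`eps`; the converged phase with the higher mean intensity is labeled ROI
(anatomy is bright on a near-black background; a tie raises a
degenerate-result error, as does an all-foreground or all-background
result, and a constant image is rejected up front for having no contrast).

Assumptions worth stating: the model is two-phase (one intensity population
per side), so it suits bright-anatomy-on-dark-background content and will
not separate multiple tissue classes; and brightness decides which phase is
"the" ROI.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `mu` | 0.2 | contour-length weight per unit intensity range (0.2·range² on the raw scale) |
| `lambda_in`, `lambda_out` | 1, 1 | region fidelity weights |
| `eps` | 1.0 | smoothed Heaviside/delta width of the level set |
| `dt` | 0.5 | evolution step of the semi-implicit sweep |
| `max_iter` | 300 | sweep cap |
| `tol` | 1e-3 | fraction of pixels whose label may flip over a 5-sweep window at convergence |
| `init` | `"intensity"` | initial level set |
| `open_radius` | 3 | morphological opening radius applied to the converged mask |
| `min_component` | 64 px | smallest connected component kept as ROI |

### Numerical choices and their reasons

**Initialization.** The default level set is the mean-centered image,
$\phi_0 = I - \bar I$. A periodic checkerboard initialization (also
available as `init = "checkerboard"`) proved unreliable here: the periodic
pattern samples both phases symmetrically, so $c_{in} \approx c_{out}$ and
the data force nearly vanishes; the contour then drifts so slowly that any
mask-change stopping rule fires long before the phases separate. Starting
from the image itself separates the phases at sweep one and converges in a
few dozen sweeps on the phantoms.

**Stopping.** Convergence is declared when the fraction of flipped labels
is below `tol` over a five-sweep window, twice in a row. Measuring flips per
single sweep is fragile: a slow but steady drift can flip fewer than
`tol`·N pixels every sweep while still moving the contour a long way.

**Boundary refinement.** The discretized curvature term can hold a one-pixel
staircase against the data at equilibrium. After evolution, pixels adjacent
to the contour are reassigned to the nearer region mean (the optimal
two-phase assignment given the means), iterated to a fixpoint, with means
recomputed. Interior pixels are never touched. On a noiseless binary disk
this snaps the mask exactly onto the disk, giving `c_in`/`c_out` equal to
the two plateau values.

**Glyph exclusion.** At maximal intensity, burned-in glyphs are energetically
part of the bright phase — the fidelity gain of including a 35-pixel glyph
far exceeds its length penalty — yet treating them as ROI would hide them
from the OCR stage and bloat the bounding box. The converged mask is
therefore opened (radius `open_radius`; an opening erases structures whose
stroke width is below the radius, and glyph strokes are 1–2 px wide while
anatomy is smooth and thick) and components smaller than `min_component`
are dropped. Radius 3 also severs dense adjacent glyphs (e.g. `E` next to
`N`) whose level-set halos would otherwise bridge into a component large
enough to pass the area filter. On phantoms, Dice against ground truth
improves slightly under this cleanup; anatomy boundaries of curvature
radius well above 3 px are essentially unchanged. The cost is a known
limitation: genuinely thin (≤ 3 px) or tiny (< 64 px) anatomical structures
would be excluded from the ROI.

**Energy bookkeeping.** The energy is evaluated after every sweep (length
term as $\sum \delta_\varepsilon(\phi)\,|\nabla\phi|$) and returned as a
trace; on the phantoms it is non-increasing to numerical precision, which
the tests assert with a relative tolerance of $10^{-6}$.

## Lossless ROI codec

The crop handed to the codec is the bounding box of the mask — the mask
itself is *not* stored. The container stores only the box, so pixels inside
the box but outside the mask ride along losslessly; this keeps the stored
geometry to four integers and makes reconstruction a rectangle paste.

The codec is the LOCO-I regular mode: raster scan; median edge detector
$\hat x = \mathrm{med}(a, b, a+b-c)$ over the causal neighbors; gradients
$(d-b,\, b-c,\, c-a)$ quantized into 9 levels each with thresholds derived
from the sample precision (T1/T2/T3 = 18/67/276 at 16 bits, 3/7/21 at
8 bits), folded by sign into 365 contexts; per-context bias correction
(`C[q]`) and adaptive Golomb parameter
$k = \min\{k : N[q]\,2^k \ge A[q]\}$ with the standard halving reset at
$N = 64$; plain Rice mapping $M(e) = 2e$ for $e \ge 0$, $-2e-1$ otherwise,
after modulo-`RANGE` reduction of the prediction error; unary-plus-`k`-bit
Golomb codes with the limited-length escape (cap
$\mathrm{LIMIT} - q_{bpp} - 1$, escape payload of $q_{bpp}$ raw bits).
Encoder and decoder run the identical context machinery, which the tests
check by comparing their final `A/B/C/N` state.

Two deliberate departures from the interchange standard, both flagged:
**run mode is omitted** (losslessness is unaffected; flat areas code at
about 1–2 bits/sample instead of near zero — a constant 512×512 16-bit
plane compresses to ~12.5% of raw rather than under 1%), and the stream
carries a private 13-byte header (magic `JLSR`, rows, cols, bits) instead
of JPEG markers. The contract is behavioral (bit-exact round trip), not
bitstream conformance. Boundary samples follow fixed edge rules (row 0:
$b=c=d=0$; column 0: $a=b$, $c=b$; last column: $d=b$) applied identically
on both sides.

## OCR and text coding

Because the background is deleted, text extraction must be exactly
invertible for rendered text. The package therefore ships a fixed 5×7
monospaced bitmap font (advance 6) used both to burn annotations into
phantoms and as the OCR template set. Extraction binarizes the non-ROI
pixels (Otsu threshold by default, overridable), masks out a 3-px dilation
of the ROI (a segmented boundary is only pixel-accurate, and bright
anatomy-edge strays must not read as ink), groups ink rows into line bands,
and aligns each band to the glyph grid by scanning the ≤ 5×7 feasible cell
offsets for the alignment with minimal total Hamming distance — with exact
rendering the true offset reaches distance zero. Cells are matched to the
nearest glyph (ties by code point; an all-blank cell is a space);
imperfectly matched cells are counted in an `unmatched` attribute rather
than dropped. Run intensity is the median of the matched ink pixels, and
reconstruction re-renders at that value.

Text records (frame dimensions, whitelisted metadata pairs, runs with
anchors and intensity, serialized deterministically as JSON) are coded with
canonical Huffman: tree built by merging the two lowest-frequency nodes
(ties by the smallest byte value in the node, so the build is fully
deterministic), then codes reassigned canonically in (length, symbol)
order. Only `(symbol, length)` pairs are serialized — 1 + 2·`symbol_count`
bytes — since canonical codes are reconstructible from lengths. A
single-symbol alphabet gets code `0` of length 1, the one documented
exception to the Kraft equality. A package holds **one** codebook built
over the concatenated text payload of all its images.

## Container and archive

The `.mipp` layout, little-endian throughout:

```
"MIPP" | version u8
u32 tree_size   | codebook
u32 text_bytes  | u32 text_bitcount | coded text
u16 image_number
per image: u32 roi_size | bbox 4×u32 | rows u32 | cols u32 | bits u8 | stream
```

Magic and version are an extension for format evolution; bounding box and
frame dimensions ride with each ROI record because reconstruction needs
the frame size and paste position. Every size prefix is validated against
the buffer on read (truncation errors name the failing section), and
`image_number` is cross-checked against the text records.

Reconstruction is: black canvas of the frame size, re-render runs at their
anchors, paste the decoded crop at its box, wrap as DICOM with the
whitelisted metadata (HIMS id, patient name/surname, citizenship id, study
date — the archive's five search fields). DICOM I/O is a minimal Part 10
explicit-VR little-endian reader/writer; input breadth is deliberately
narrow since the pipeline re-encodes pixels itself.

The archive splits each package into fixed-size chunks (default 255 KiB, so
any single stored document stays far below the usual 16 MB document limit)
under a file document carrying length, chunk count and an Adler-32
checksum, verified on reassembly. Search is two-mode: direct by primary
key, or conjunctive criteria over the indexed patient fields returning the
ascending HIMS-id list (the caller then fetches by id). Study dates are
ISO-8601 strings compared lexicographically over half-open ranges
`[from, to)` — the convention that makes consecutive year-long windows
partition cleanly. Batch compression runs map-per-image over a fork-based
worker pool and reduces by consolidating in input order, so the package
bytes are identical for any worker count.

## The phantom generator

Phantoms emulate the structure the pipeline targets: 2–5 anisotropic
Gaussian blobs summed near the frame center, thresholded to the requested
area fraction by bisection (realized fractions land well within ±0.03 of
the request for 64–1024 px frames), interior intensities mapped smoothly to
0.3–0.9 of the representable range, background at a configurable level
(default 0), and annotation lines rendered from the shared font in margin
bands chosen to keep at least 5 px of clearance from the anatomy — as real
burned-in overlays do. Defaults: 512×512, 16-bit, ROI fraction 0.3284 (a
typical average ROI share for an MR corpus of this kind), three text lines,
maximal-intensity glyphs, and Gaussian noise of σ = 1% of range confined to
the ROI (so the background-discard path stays exercisable in its clean
regime; `noise_everywhere = TRUE` adds it globally). Generation is a pure
function of the spec: the global RNG state is saved and restored, so equal
seeds give bit-identical phantoms.

What the phantoms do *not* emulate — and hence what passing tests cannot
show about real data: MR physics (coil shading, bias fields, Rician noise),
anatomy with internal texture or thin processes, proportional or
anti-aliased annotation fonts, and annotations overlapping anatomy. The
OCR stage in particular is font-exact by design; a general OCR engine can
be substituted behind the same interface, but then the render–extract loop
is no longer guaranteed to close.

## Problem sizes used in the checks

The test suite exercises: 20 phantoms at 512×512 for the batch non-ROI
saving bound; 8 noiseless 256×256 phantoms for the ROI fold bound; 50
random phantoms (160–224 px, fractions 0.20–0.38, noise 0–2% of range) for
end-to-end content losslessness; 200 randomized cases each for codec and
container round-trip identities; 200 random small alphabets (≤ 6 symbols,
frequencies ≤ 20) against the exhaustive prefix-code oracle; 20 + 20
phantoms at 256×256 for the Dice bounds (clean and 5% global noise);
worker counts 1/2/4 on a 6-image batch for parallel invariance; and 1000
randomized archive entries against a linear-scan oracle. The acceptance
script reruns the 20-phantom 512×512 batch from scratch under a
caller-provided seed.

## Known limitations

- Two-phase segmentation only; no multi-region or edge-based variants.
- The ROI is stored as a rectangle superset; pathological mask shapes
  (e.g. a thin diagonal) inflate the stored crop.
- Thin (≤ 3 px) or tiny (< `min_component`) anatomical structures are
  excluded from the ROI by the mask cleanup.
- The ROI stream is not an interchange JPEG-LS bitstream (no run mode, no
  JPEG markers).
- OCR is exact only for the built-in font; unmatched regions are flagged,
  and whatever the OCR mis-reads in the discarded background is lost — the
  price of deleting it.
- DICOM support is single-frame grayscale, explicit-VR little-endian,
  uncompressed, with a fixed metadata whitelist.
- The archive is a storage contract (chunking, indexes, checksums), not a
  database: no replication, sharding or authentication.
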
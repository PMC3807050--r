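---
title: "Neural Schematics: model, layout, and rendering conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural Schematics: model, layout, and rendering conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroschematics)
```

## The notation

Models of large-scale neural network structures are usually communicated as
ad-hoc box-and-arrow figures whose symbols mean different things in every
paper. This package implements a formal schematic notation for such models,
borrowing its discipline from electrical-engineering schematics: a closed
symbol vocabulary, a fixed signal-flow convention, and a textual companion
format, so that a diagram can be validated, laid out, and rendered
mechanically.

The data model has two first-class element kinds and four annotation kinds:

* **Populations** — compounds of functionally related neurons of one
  morphological/electrophysiological cell class; the lowest level of
  abstraction. A population is named by its electrophysiological (or spiking
  behaviour) class in normal typeset and/or its morphological or other
  descriptive class in italics, e.g. `RS/`*`PYR`*, *`TC`*, `POIS`. Single
  neurons, synapses, and receptor types are deliberately below the
  notation's level of abstraction.
* **Projections** — directed bundles of same-excitation-type synaptic
  connections between two populations. They never branch or join; a
  projection without an origin is an input to the structure, one without a
  terminus is an output (the `EXTERNAL` sentinel endpoint), and
  self-projections are allowed. The only strength attribute ever rendered
  is the relative connection density in [0, 1]; weights, delays, and
  plasticity are carried as non-rendered attributes, keeping the diagram a
  description of static structure.
* **Layers** (cortical laminae I–VI, highest on top), **areas** (cortical
  surface partitions that may contain layers), **NCRs** (non-cortical
  regions, drawn like areas but never containing layer boundaries), and
  **units** (dashed functional groupings, e.g. columns, which may nest
  sub-units alongside populations as a forest).

Two prohibitions define the visual grammar as much as the symbols do: no
color anywhere, and no glyph feature may scale with an attribute value.
Direction needs no arrowheads because afferents always enter a population
box on its left edge and efferents leave on its right; an inhibitory
projection is marked by an empty circle at its terminus, like a negated
input in logic schematics.

## Validation

`validate_model()` checks a model against a closed rulebook of ten rules
(`NNS_RULES`) and returns sorted, machine-readable diagnostics rather than
raising conditions. Structural faults (dangling references, a layer inside
an NCR, unit-membership cycles, densities outside [0, 1], malformed labels
or layer names) are `ERROR`s; stylistic requests the notation forbids but
which do not corrupt the model — attributes asking for colors or
attribute-scaled glyphs — are `WARNING`s, as is a density of exactly zero
(renderable but semantically void; the choice of warning severity is ours).
The strict constructors enforce the same invariants at construction time, so
a model with no `ERROR` findings can always be rebuilt strictly; the
validator exists for inspecting documents of unknown provenance.

Where the rulebook needed decisions the notation does not make: duplicate
(area, numeral) layer pairs report `R-LAYER-NAME`; an order index
inconsistent with its numeral reports `R-LAYER-ORDER`; a layered population
whose region is an NCR reports `R-NCR-NOLAYERS`, while a missing or
mismatched area reports `R-REF-INTEGRITY`. A projection between populations
in two different NCRs is treated as ordinary. Direct membership of one
population in two overlapping units is forbidden (`R-UNIT-FOREST`); the
notation is silent here and we chose the stricter reading.

## Serialization: NNSD and the PyNN subset

The notation prescribes no file format, only that a textual representation
exist. **NNSD** (`.nnsd.json`, schema in `inst/schema/`) is this package's
JSON dialect: top-level sections for regions, layers, populations,
projections, units, and metadata. Writing sorts elements by id with a fixed
key order, making output byte-deterministic — two invocations on equal
models produce identical bytes, which keeps diffs and caches honest.
Reading enforces every invariant, converts `density_percent` values to
relative numbers by exact division by 100, and preserves unknown element
keys in the element's extra attributes instead of dropping them.

**PyNN export** emits a runnable declarative script: one `Population`
statement per population (size from the `size` extra attribute, default
100), one `Projection` statement per internal projection with the
excitation type as `receptor_type` and the density as the connector
probability. PyNN has no vocabulary for layers, areas, NCRs, or units, so
that structure must be annotated onto the corresponding elements; our
encoding — one `# @nns-<kind> <json>` comment per element, attached to the
statement where one exists — is a package choice, made so the script stays
runnable by a PyNN interpreter that knows nothing of schematics.
`import_pynn()` parses exactly the emitted subset as *text* (literal
arguments, no control flow, never executed) and rejects anything outside it
with an unsupported-construct error. Round-trip identity holds on this
constrained subset, not on arbitrary PyNN code.

Numeric fidelity: JSON writers print doubles at 15 significant digits,
which does not round-trip every IEEE double. Densities written by this
package therefore survive exactly when they carry at most ~6 decimal
digits; the synthetic generator samples densities on a 1e-6 grid over
(0, 1] for precisely this reason.

## Layout

The notation fixes topology conventions (attachment sides, line styles,
layer order) but no placement algorithm; the algorithm here is the
package's own, chosen for determinism and testability over aesthetics.

1. **Grid scaffold.** One column per region in `display_order` (areas and
   NCRs alike), plus a trailing column for region-less populations; one
   horizontal band per cortical layer numeral in increasing order top to
   bottom, plus a bottom band for unlayered populations. Bands and columns
   auto-size to their content, so a population always fits its band.
2. **Within a cell**, populations are ordered left to right by longest-path
   rank over the cell-internal projection graph — source-to-sink flow then
   matches the left-in/right-out convention — with ties broken by
   declaration order.
3. **Routing** is orthogonal. Internal projections leave the source's right
   edge at a per-projection port, jog once through the inter-column
   channel, and enter the target's left edge; backward edges detour below
   the occupied bands. Inputs run from the canvas's left margin to their
   target; outputs from their source to the right margin, where the layer
   labels also sit. Self-projections loop over the top of their box at
   `loop_margin`. Channel tracks are assigned greedily in projection-id
   order. Crossing minimization is explicitly a non-goal.
4. **Unit boxes** are bounding rectangles of their members (recursively for
   sub-units) grown by `unit_margin`. Unit boxes of non-nested units may
   overlap when their members genuinely interleave on the grid; this is
   permitted and surfaced in the layout's `warnings` field rather than
   forced apart.
5. Layer *lines* are drawn per area containing the layer (never across NCR
   strips), with one roman-numeral label per band at the schematic's right
   edge; region delimiters are drawn only between adjacent strips, so a
   single unnamed area — used by the hypercolumn fixture, whose source
   material shows layers but no area — renders without any vertical line.

All metric parameters (`layout_config()`) are in abstract length units that
become SVG user units: box minimum 60×30, band gap 18, column gap 40,
channel spacing 8, unit margin 10, loop margin 12, terminator radius 4.5
(three stroke widths), and a `char_width` of 8 used to widen boxes around
their labels. Text metrics are character-count heuristics so no font files
are ever consulted. The layout is a pure function of model and
configuration: no randomness, no iteration-order dependence.

## Rendering

`render_svg()` writes SVG 1.1 text directly: population rectangles
(solid, unfilled), projection polylines (solid, **no** arrowhead markers),
empty terminator circles on inhibitory termini tangent to the target edge,
dotted lines (`1,3`) for layer and region delimiters, dashed rectangles
(`6,3`) for units, monospace layer/region names, population labels as
`tspan` spans with the morphological class in `font-style="italic"`, and
density labels printed verbatim at path midpoints (the midpoint-offset
placement is our convention; the notation does not fix it). One stroke
width serves every element class; only `black`/`none` paints appear; the
background is transparent for print embedding. Coordinates are formatted
through a fixed two-decimal formatter, so rendering is byte-deterministic.

## The fixture set and the synthetic generator

`build_fixture()` reconstructs five worked examples — bare population
symbols, the four-projection single-population example (densities 0.5, 0.1,
0.2, 0.2), a thalamocortical loop (Thalamus NCR + layered cortical area
with stimulus inputs), a three-group synfire chain with feed-forward
inhibition, and an associative-memory hypercolumn nesting minicolumn units.
Where the source material does not print densities in machine-readable
form, the fixtures encode topology only and mark densities absent; the
hypercolumn's stimulus population sits outside the hypercolumn unit, a
choice the source leaves open.

`random_model()` is the property-test generator: seeded and fully
deterministic, it produces models with requested element counts, labels
drawn from the field's class-token pools, layer/region/unit assignments
uniform among *valid* choices only, inhibitory and external-endpoint
fractions governed by `p_inhibitory`/`p_external`, and grid-valued
densities as above. It emulates structural variety — not biological
plausibility: connectivity is uniform-random, so passing property suites
demonstrates geometric and serialization correctness on arbitrary valid
structures, not that real cortical circuits look reasonable. The test
suites sweep seeds with element counts up to ~13 populations and ~20
projections per model (hundreds of models per run), sizes at which the
brute-force geometric oracles stay trivially fast.

## Degenerate inputs and numerical choices

The empty model is valid everywhere: it serializes to a version-only
document, exports to a header-only script, lays out to a zero-extent
canvas, and renders to a valid SVG with an empty canvas group. Ties in
placement are broken by id or declaration order, never by hash order.
Geometry tests use an absolute tolerance of 1e-9 on coordinates that are
exact by construction. Because bands auto-size, the only layout-infeasible
inputs are non-positive configuration lengths, rejected at configuration
time.

## Limitations

Crossing counts are not minimized and dense backward wiring can look busy —
the cost of a deterministic one-pass router. Hierarchical units that hide
their contents, 3-D spatial embedding, receptor types, and synaptic
dynamics are out of scope, as they are for the notation itself. PyNN
interchange covers the declarative structural subset only, not neuron-model
parameterization or simulator control.
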
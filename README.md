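# neuroschematics

Formal schematic diagrams for large-scale neural network structures (NNSs).

Published models of brain circuitry — thalamocortical loops, cortical
microcircuits, synfire chains, attractor networks — are almost always
communicated as ad-hoc box-and-arrow figures with conflicting symbol
conventions: arrows mean excitation in one paper and inhibition in the next,
node shapes encode cell classes or nothing at all, and layer/area context
lives only in the caption. This package implements a *Neural Schematics*
notation the way electrical engineering treats circuit schematics: a closed
symbol vocabulary with a validated data model, a deterministic automatic
layout, a textual interchange format, and a renderer — so the same model
always produces the same diagram, and the diagram is machine-checkable.

It is aimed at computational neuroscientists and neuromorphic engineers who
describe models at the population/projection level (the notation's lowest
level of abstraction) and want reproducible, publication-grade figures plus
a migration path to and from PyNN model scripts.

## The notation in brief

* **Population**: a compound of neurons of one morphological /
  electrophysiological class; drawn as a solid rectangle labelled
  `EPHYS`/*`MORPH`* (electrophysiological class in normal typeset,
  morphological or other descriptive class in italics), e.g. `RS/`*`PYR`*,
  *`TC`*, `POIS`.
* **Projection**: a directed, non-branching bundle of same-excitation-type
  connections; a solid line with **no arrowhead** — direction is fixed by
  the convention that afferents enter a population box on its **left** edge
  and efferents leave on its **right**. An inhibitory projection ends in an
  empty circle; the optional label is the relative connection density in
  [0, 1]. Projections without an origin are network inputs; without a
  terminus, outputs; self-projections are allowed.
* **Layers** I–VI: dotted horizontal bands, highest cortical layer on top,
  roman-numeral labels at the right edge. **Areas**: dotted vertical
  strips that may contain layers; **NCRs** (non-cortical regions) are drawn
  the same but never contain layer boundaries. **Units** (columns etc.):
  dashed rectangles that may nest sub-units alongside populations.
* No color, and no glyph ever scales with an attribute value.

## Worked example

The classic single-population worked example: one `RS/PYR` population with
an excitatory input (density 0.5), an inhibitory input (0.1), an excitatory
self-projection (0.2), and an output (0.2).

```r
library(neuroschematics)

m <- build_fixture("FIG8_PROJECTIONS")
m
#> <nns_model> 1 populations, 4 projections, 0 layers, 0 regions, 0 units

classify_endpoints(m)
#> $internal
#> [1] "self_exc"
#> $inputs
#> [1] "in_exc" "in_inh"
#> $outputs
#> [1] "out_exc"

display_label(m$populations[["pyr"]]$label)
#>   text  style
#> 1   RS normal
#> 2    / normal
#> 3  PYR italic

validate_model(m)          # 0 rows: conforms to every notation rule
write_nnsd(m, "fig8.nnsd.json")   # deterministic JSON serialization
svg <- render_svg(compute_layout(m), m)
```

`classify_endpoints()` shows the two origin-free projections classified as
inputs and the terminus-free one as an output; `display_label()` shows the
two-part label with the morphological class set in italics. The rendered
SVG contains four arrowhead-free polylines and exactly one empty terminator
circle — the single inhibitory afferent.

The same workflows are scriptable from a shell (wrapper in `inst/cli/`):

```sh
Rscript inst/cli/neuroschematic demo FIG11_SYNFIRE_FFI -o out/
Rscript inst/cli/neuroschematic validate out/fig11.nnsd.json
Rscript inst/cli/neuroschematic render out/fig11.nnsd.json -o fig11.svg
Rscript inst/cli/neuroschematic convert out/fig11.nnsd.json --to pynn -o fig11.py
```

`convert --to pynn` emits a runnable declarative PyNN script with the
schematic-only structure (layers, regions, units, external inputs) attached
as `# @nns-...` annotations; `import_pynn()` reads exactly that subset back,
as source text, without executing anything.

Ready-made example documents for all five built-in fixtures live under
`examples/`; `vignettes/neural-schematics.Rmd` documents the data model,
the rulebook, the layout algorithm, and the design decisions.

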
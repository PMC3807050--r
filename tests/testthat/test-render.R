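test_that("the worked projection example renders its terminators and polylines", {
  r <- render_fixture("FIG8_PROJECTIONS")
  x <- svg_doc(r$svg)
  expect_equal(svg_count(x, "//circle[@class='nns-terminator']"), 1L)
  expect_equal(svg_count(x, "//polyline[@class='nns-projection']"), 4L)
  expect_equal(svg_count(x, "//rect[@class='nns-population']"), 1L)
  # density labels printed verbatim
  texts <- xml2::xml_text(xml2::xml_find_all(x, "//text"))
  expect_true(all(c("0.5", "0.1", "0.2") %in% texts))
})

test_that("an empty model renders to a valid document with an empty canvas group", {
  m <- nns_model()
  svg <- render_svg(compute_layout(m), m)
  x <- svg_doc(svg)
  expect_equal(xml2::xml_name(x), "svg")
  expect_equal(svg_count(x, "//g[@class='nns-canvas']"), 1L)
  expect_equal(svg_count(x, "//g/*"), 0L)
})

test_that("terminator circles match the inhibitory projection count on every fixture", {
  for (fid in fixture_ids()) {
    r <- render_fixture(fid)
    x <- svg_doc(r$svg)
    n_inh <- sum(vapply(r$model$projections,
                        function(p) p$excitation == "inhibitory", TRUE))
    expect_equal(svg_count(x, "//circle"), n_inh, label = fid)
    # terminators are empty circles: no fill
    fills <- xml2::xml_attr(xml2::xml_find_all(x, "//circle"), "fill")
    expect_true(all(fills == "none"), label = fid)
  }
})

test_that("no arrowheads and no color anywhere in the grammar", {
  for (fid in c("FIG10_THALAMOCORTICAL", "FIG11_SYNFIRE_FFI")) {
    r <- render_fixture(fid)
    x <- svg_doc(r$svg)
    expect_equal(svg_count(x, "//*[@marker-end or @marker-start or @marker-mid]"), 0L)
    expect_equal(svg_count(x, "//marker"), 0L)
    paints <- svg_paints(x)
    expect_true(all(paints %in% c("black", "none", NA)), label = fid)
  }
})

test_that("dash patterns appear exactly on layer, region, and unit strokes", {
  r <- render_fixture("FIG10_THALAMOCORTICAL")
  expect_setequal(svg_dashed_classes(svg_doc(r$svg)),
                  c("nns-layer-line", "nns-region-line"))
  r <- render_fixture("FIG11_SYNFIRE_FFI")
  expect_setequal(svg_dashed_classes(svg_doc(r$svg)), "nns-unit")
  # solid elements never carry a dash pattern
  x <- svg_doc(r$svg)
  expect_equal(svg_count(x, "//polyline[@stroke-dasharray]"), 0L)
  expect_equal(svg_count(x, "//rect[@class='nns-population'][@stroke-dasharray]"), 0L)
})

test_that("italic spans are exactly the morphological class tokens", {
  r <- render_fixture("FIG10_THALAMOCORTICAL")
  x <- svg_doc(r$svg)
  morphs <- unlist(lapply(r$model$populations, function(p) p$label$morph))
  expect_setequal(svg_italic_texts(x), unname(morphs))
})

test_that("layer labels are uppercase roman numerals in the monospace family", {
  r <- render_fixture("FIG12_HYPERCOLUMN")
  x <- svg_doc(r$svg)
  lab <- xml2::xml_find_all(x, "//text[@font-family='monospace']")
  expect_setequal(xml2::xml_text(lab), c("II", "III"))
})

test_that("unit boxes render dashed with their names", {
  r <- render_fixture("FIG12_HYPERCOLUMN")
  x <- svg_doc(r$svg)
  expect_equal(svg_count(x, "//rect[@class='nns-unit']"), 3L)
  texts <- xml2::xml_text(xml2::xml_find_all(x, "//text"))
  expect_true("Hypercolumn" %in% texts)
  expect_equal(sum(texts == "Minicolumn"), 2L)
})

test_that("rendering is byte-deterministic", {
  m <- sweep_model(13)
  lay <- compute_layout(m)
  expect_identical(render_svg(lay, m), render_svg(lay, m))
})

test_that("a layout/model mismatch is a render error", {
  m <- build_fixture("FIG8_PROJECTIONS")
  lay <- compute_layout(m)
  other <- nns_model(populations = list(population("zz", "RS")))
  expect_error(render_svg(lay, other), class = "nns_render_error")
})
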
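test_that("an empty model lays out to an empty canvas", {
  lay <- compute_layout(nns_model())
  expect_length(lay$population_boxes, 0L)
  expect_length(lay$projection_paths, 0L)
  expect_equal(lay$canvas, list(x = 0, y = 0, w = 0, h = 0))
})

test_that("configuration lengths must be strictly positive", {
  expect_error(layout_config(box_min_w = 0), class = "nns_layout_infeasible")
  expect_error(layout_config(unit_margin = -1), class = "nns_layout_infeasible")
})

test_that("layout refuses models with ERROR findings", {
  m <- inject_violation("R-REF-INTEGRITY", 2)
  expect_error(compute_layout(m), class = "nns_validation_error")
})

test_that("boxes never overlap and endpoints obey the side convention", {
  for (s in 1:15) {
    m <- sweep_model(s)
    lay <- compute_layout(m)
    expect_equal(count_box_overlaps(lay$population_boxes), 0L,
                 label = sprintf("overlaps (seed %d)", s))
    expect_equal(count_endpoint_violations(m, lay), 0L,
                 label = sprintf("endpoint violations (seed %d)", s))
  }
})

test_that("self-projections leave the right edge and re-enter the left edge", {
  m <- build_fixture("FIG8_PROJECTIONS")
  lay <- compute_layout(m)
  p <- lay$projection_paths[["self_exc"]]
  expect_equal(p$kind, "self")
  b <- lay$population_boxes[["pyr"]]
  expect_true(on_right_edge(p$points[1, ], b))
  expect_true(on_left_edge(p$points[nrow(p$points), ], b))
  # the loop passes over the top of the box
  expect_lt(min(p$points[, 2]), b$y)
})

test_that("layered populations sit inside their band and region strip", {
  m <- build_fixture("FIG10_THALAMOCORTICAL")
  lay <- compute_layout(m)
  ln <- lay$layer_lines
  expect_equal(nrow(ln), 1L)
  expect_equal(ln$layer, "VI")
  expect_equal(ln$area, "area5")
  for (pid in c("pyr", "in")) {
    b <- lay$population_boxes[[pid]]
    expect_lte(b$y + b$h, ln$y + eps)
    expect_gte(b$x, ln$x0 - eps)
    expect_lte(b$x + b$w, ln$x1 + eps)
  }
  # the thalamic NCR strip carries no layer line
  thal <- lay$region_labels[lay$region_labels$region == "thalamus", ]
  expect_equal(nrow(thal), 1L)
  expect_false(any(ln$area == "thalamus"))
  # one vertical delimiter between the two region strips
  expect_equal(nrow(lay$region_lines), 1L)
})

test_that("layer bands stack top-to-bottom in increasing numeral order", {
  m <- random_model(3, n_pop = 12, n_proj = 6, n_layers = 5, n_regions = 2,
                    p_external = 0)
  lay <- compute_layout(m)
  lb <- lay$layer_labels
  ord <- order(lb$y)
  nums <- match(lb$layer, c("I", "II", "III", "IV", "V", "VI"))
  expect_equal(nums[ord], sort(nums))
})

test_that("unit boxes contain members with the configured margin, nested units included", {
  m <- build_fixture("FIG12_HYPERCOLUMN")
  cfg <- layout_config(unit_margin = 10)
  lay <- compute_layout(m, cfg)
  hc <- lay$unit_boxes[["hc"]]
  for (uid in c("mc1", "mc2")) {
    mc <- lay$unit_boxes[[uid]]
    # minicolumn fully inside the hypercolumn with at least the margin
    expect_gte(mc$x - hc$x, cfg$unit_margin - eps)
    expect_gte(mc$y - hc$y, cfg$unit_margin - eps)
    expect_gte(hc$x + hc$w - mc$x - mc$w, cfg$unit_margin - eps)
    expect_gte(hc$y + hc$h - mc$y - mc$h, cfg$unit_margin - eps)
    for (pid in m$units[[uid]]$members) {
      pb <- lay$population_boxes[[pid]]
      expect_gte(pb$x - mc$x, cfg$unit_margin - eps)
      expect_lte(pb$x + pb$w, mc$x + mc$w + eps)
    }
  }
  # the basket population is in the hypercolumn, the stimulus outside it
  bb <- lay$population_boxes[["basket"]]
  expect_gte(bb$x, hc$x); expect_lte(bb$x + bb$w, hc$x + hc$w)
  sb <- lay$population_boxes[["stim"]]
  expect_false(sb$x >= hc$x && sb$x + sb$w <= hc$x + hc$w &&
               sb$y >= hc$y && sb$y + sb$h <= hc$y + hc$h)
})

test_that("layout is deterministic and the canvas grows monotonically", {
  m <- sweep_model(11)
  expect_identical(compute_layout(m), compute_layout(m))
  lay1 <- compute_layout(m)
  pops <- c(m$populations, list(population("zzz_extra", "RS", morph = "PYR")))
  m2 <- nns_model(populations = pops, projections = m$projections,
                  layers = m$layers, regions = m$regions, units = m$units,
                  metadata = m$metadata)
  lay2 <- compute_layout(m2)
  expect_gte(lay2$canvas$w, lay1$canvas$w)
  expect_gte(lay2$canvas$h, lay1$canvas$h)
})

test_that("extra attributes never influence geometry or glyph size", {
  m1 <- build_fixture("FIG8_PROJECTIONS")
  pops <- m1$populations
  pops[["pyr"]]$extra <- list(size = 100000L, neuron_model = "IF_cond_exp")
  projs <- m1$projections
  projs[["self_exc"]]$extra <- list(weight = 99, delay = 1.5)
  m2 <- nns_model(populations = pops, projections = projs,
                  metadata = m1$metadata)
  l1 <- compute_layout(m1); l2 <- compute_layout(m2)
  expect_identical(l1$population_boxes, l2$population_boxes)
  expect_identical(l1$projection_paths, l2$projection_paths)
})

test_that("density labels anchor at projection midpoints", {
  m <- build_fixture("FIG8_PROJECTIONS")
  lay <- compute_layout(m)
  dl <- lay$density_labels
  expect_setequal(dl$projection, names(m$projections))
  expect_setequal(dl$text, c("0.5", "0.1", "0.2", "0.2"))
})
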
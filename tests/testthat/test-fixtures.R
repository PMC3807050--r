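test_that("every fixture validates clean and round-trips both formats", {
  for (fid in fixture_ids()) {
    m <- build_fixture(fid)
    expect_equal(nrow(validate_model(m)), 0L, label = fid)
    expect_true(models_equal(m, read_nnsd(write_nnsd(m))), label = fid)
    expect_true(models_equal(m, import_pynn(export_pynn(m))), label = fid)
  }
  expect_error(build_fixture("FIG99"), class = "nns_unknown_fixture")
})

test_that("the synfire chain carries three group units with FFI wiring", {
  m <- build_fixture("FIG11_SYNFIRE_FFI")
  expect_length(m$units, 3L)
  expect_true(all(grepl("^Group", vapply(m$units, `[[`, "", "name"))))
  # within each group the fast-spiking population inhibits the regular-spiking one
  for (k in 1:3) {
    pr <- m$projections[[sprintf("ffi%d", k)]]
    expect_equal(pr$source, sprintf("fs%d", k))
    expect_equal(pr$target, sprintf("rs%d", k))
    expect_equal(pr$excitation, "inhibitory")
  }
  # feed-forward excitation into the next group's pair
  expect_equal(m$projections[["chain_rs1"]]$target, "rs2")
  expect_equal(m$projections[["chain_fs2"]]$target, "fs3")
})

test_that("the projection example carries the printed density multiset", {
  m <- build_fixture("FIG8_PROJECTIONS")
  dens <- sort(vapply(m$projections, function(p) p$density, 0))
  expect_equal(unname(dens), c(0.1, 0.2, 0.2, 0.5))
})

test_that("the thalamocortical fixture separates NCR and layered area", {
  m <- build_fixture("FIG10_THALAMOCORTICAL")
  expect_equal(m$regions[["thalamus"]]$kind, "ncr")
  expect_equal(m$regions[["area5"]]$kind, "area")
  expect_equal(m$layers[["area5.VI"]]$name, "VI")
  expect_equal(m$populations[["tc"]]$region_ref, "thalamus")
  expect_null(m$populations[["tc"]]$layer_ref)
  expect_equal(m$populations[["pyr"]]$layer_ref, "area5.VI")
  # stimulus afferents enter from outside the structure
  cls <- classify_endpoints(m)
  expect_setequal(cls$inputs, c("stim_tc", "stim_pyr"))
})

test_that("the hypercolumn nests minicolumn units and keeps the stimulus outside", {
  m <- build_fixture("FIG12_HYPERCOLUMN")
  expect_setequal(m$units[["hc"]]$members, c("mc1", "mc2", "basket"))
  expect_null(population_unit(m, "stim"))
  expect_equal(m$populations[["stim"]]$label$morph, "STIM")
  # relabelling: RSNP -> RS/NPYR, Basket -> FS/NPYR, PYR -> RS/PYR
  expect_equal(unclass(m$populations[["mc1_rsnp"]]$label),
               list(ephys = "RS", morph = "NPYR"))
  expect_equal(unclass(m$populations[["basket"]]$label),
               list(ephys = "FS", morph = "NPYR"))
  expect_equal(unclass(m$populations[["mc1_pyr"]]$label),
               list(ephys = "RS", morph = "PYR"))
})

test_that("the generator is deterministic and honors element counts", {
  a <- random_model(42, 10, 20, 3, 2, 2, p_inhibitory = 0.3, p_external = 0.1)
  b <- random_model(42, 10, 20, 3, 2, 2, p_inhibitory = 0.3, p_external = 0.1)
  expect_true(models_equal(a, b))
  expect_length(a$populations, 10L)
  expect_length(a$projections, 20L)
  expect_length(a$layers, 3L)
  expect_length(a$regions, 2L)
  expect_length(a$units, 2L)
  expect_true(models_equal(random_model(0, 0, 0, 0, 0, 0, .5, .1), nns_model()))
})

test_that("generator rejects infeasible element combinations", {
  expect_error(random_model(1, n_pop = 0, n_proj = 5),
               class = "nns_generator_error")
  expect_error(random_model(1, n_pop = 3, n_proj = 0, n_layers = 2,
                            n_regions = 0), class = "nns_generator_error")
  expect_error(random_model(1, n_pop = 3, n_proj = 0, n_layers = 7,
                            n_regions = 1), class = "nns_generator_error")
})

test_that("the inhibitory fraction stays inside binomial 99% bounds", {
  p <- 0.3
  n <- 1000L
  m <- random_model(7, n_pop = 20, n_proj = n, p_inhibitory = p,
                    p_external = 0.1)
  k <- sum(vapply(m$projections, function(x) x$excitation == "inhibitory", TRUE))
  bounds <- stats::qbinom(c(0.005, 0.995), n, p)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("generated densities lie on the serializable grid in (0, 1]", {
  m <- random_model(11, n_pop = 6, n_proj = 200, p_external = 0)
  dens <- unlist(lapply(m$projections, function(p) p$density))
  expect_true(all(dens > 0 & dens <= 1))
  expect_equal(dens * 1e6, round(dens * 1e6))
})
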
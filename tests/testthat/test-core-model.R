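test_that("labels typeset with the morphological class in italics", {
  expect_equal(display_label(population_label("RS", "PYR")),
               data.frame(text = c("RS", "/", "PYR"),
                          style = c("normal", "normal", "italic")))
  expect_equal(display_label(population_label(morph = "TC")),
               data.frame(text = "TC", style = "italic"))
  expect_equal(display_label(population_label("POIS")),
               data.frame(text = "POIS", style = "normal"))
  expect_error(population_label(), class = "nns_invalid_label")
  expect_error(population_label("rs", "PYR"), class = "nns_invalid_label")
  expect_error(population_label("R S"), class = "nns_invalid_label")
})

test_that("display_label is injective on distinct class pairs", {
  pool_e <- list(NULL, "RS", "FS", "POIS")
  pool_m <- list(NULL, "PYR", "NPYR", "TC")
  seen <- character()
  for (e in pool_e) for (m in pool_m) {
    if (is.null(e) && is.null(m)) next
    spans <- display_label(population_label(e, m))
    key <- paste(spans$text, spans$style, sep = "@", collapse = "|")
    expect_false(key %in% seen)
    seen <- c(seen, key)
  }
})

test_that("element constructors reject invariant violations", {
  expect_error(projection("p", EXTERNAL, EXTERNAL), class = "nns_invalid_element")
  expect_error(projection("p", "a", "b", density = 1.2), class = "nns_invalid_element")
  expect_error(projection("p", "a", "b", density = -0.1), class = "nns_invalid_element")
  expect_error(projection("p", "a", "b", excitation = "modulatory"),
               class = "nns_invalid_element")
  expect_silent(projection("p", "a", "a", density = 0.5))  # self-projection ok
  expect_error(layer("l", "VII", "a"), class = "nns_invalid_element")
  expect_error(layer("l", "iv", "a"), class = "nns_invalid_element")
  expect_equal(layer("l", "VI", "a")$order_index, 6L)
  expect_error(region("r", "cortex"))
  expect_error(unit_group("u", members = c("a", "a")), class = "nns_invalid_element")
  expect_error(population("EXTERNAL", "RS"), class = "nns_invalid_element")
})

test_that("model assembly enforces referential integrity", {
  expect_error(
    nns_model(projections = list(projection("p", "ghost", "ghost2"))),
    class = "nns_invalid_model")
  expect_error(
    nns_model(populations = list(population("a", "RS"), population("a", "FS"))),
    class = "nns_invalid_element")
  # a layered population must live in the area containing the layer
  expect_error(nns_model(
    regions = list(region("ncr1", "ncr", "Thalamus")),
    layers = list(layer("l1", "I", "ncr1"))),
    class = "nns_invalid_model")
})

test_that("endpoint classification matches a brute-force scan", {
  m <- build_fixture("FIG8_PROJECTIONS")
  cls <- classify_endpoints(m)
  expect_setequal(cls$inputs, c("in_exc", "in_inh"))
  expect_setequal(cls$outputs, "out_exc")
  expect_setequal(cls$internal, "self_exc")

  empty <- nns_model()
  expect_equal(classify_endpoints(empty),
               list(internal = character(), inputs = character(),
                    outputs = character()))

  m <- random_model(1, n_pop = 12, n_proj = 30, p_external = 0.25)
  got <- classify_endpoints(m)
  want <- brute_classify(m)
  expect_setequal(got$internal, want$internal)
  expect_setequal(got$inputs, want$inputs)
  expect_setequal(got$outputs, want$outputs)
  # the partition covers every projection exactly once
  expect_setequal(c(got$internal, got$inputs, got$outputs),
                  names(m$projections))
  expect_equal(length(got$internal) + length(got$inputs) + length(got$outputs),
               length(m$projections))
})

test_that("partition sizes sum to the projection count across generated models", {
  for (s in 1:20) {
    m <- sweep_model(s)
    cls <- classify_endpoints(m)
    expect_equal(length(unlist(cls)), length(m$projections))
    expect_equal(anyDuplicated(unlist(cls)), 0L)
  }
})

test_that("unit membership queries resolve direct ownership", {
  m <- build_fixture("FIG11_SYNFIRE_FFI")
  expect_equal(population_unit(m, "rs2"), "group2")
  expect_null(population_unit(m, "stim"))
})
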
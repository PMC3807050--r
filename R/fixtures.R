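#' Identifiers of the built-in example schematics
#'
#' @return Character vector of the fixture ids accepted by [build_fixture()].
#' @export
fixture_ids <- function() {
  c("FIG7_POPULATIONS", "FIG8_PROJECTIONS", "FIG10_THALAMOCORTICAL",
    "FIG11_SYNFIRE_FFI", "FIG12_HYPERCOLUMN")
}

#' Build one of the built-in example schematics
#'
#' Programmatic reconstructions of classic circuit motifs in the notation:
#'
#' * `FIG7_POPULATIONS`: three bare population symbols — a Poisson stimulus
#'   generator (`POIS`), a regular-spiking pyramidal population (`RS/PYR`),
#'   and a unipolar motor population (`UNI`).
#' * `FIG8_PROJECTIONS`: one `RS/PYR` population with an excitatory input
#'   (density 0.5), an inhibitory input (density 0.1), an excitatory
#'   self-projection (density 0.2) and an additional output (density 0.2).
#' * `FIG10_THALAMOCORTICAL`: a thalamocortical loop after Destexhe's
#'   thalamus/cortex circuit — a Thalamus NCR housing `TC` and `RE`
#'   populations and cortical Area 5 with Layer VI housing `RS/PYR` and
#'   `FS/NPYR`, with external stimulus inputs. Connection densities are
#'   omitted: the source figure prints them but they are not restated in
#'   machine-readable form, so the fixture encodes topology only.
#' * `FIG11_SYNFIRE_FFI`: a three-group synfire chain with feed-forward
#'   inhibition after Kremkow — each group unit holds an `RS/PYR` and an
#'   `FS/NPYR` population; the stimulus excites the first group's pair, the
#'   fast-spiking population inhibits its group's regular-spiking one, and
#'   each regular-spiking population feeds the next group's pair. Densities
#'   are omitted (defined only in the upstream reference).
#' * `FIG12_HYPERCOLUMN`: one hypercolumn of a cortical associative-memory
#'   model after Lundqvist — minicolumn units of `RS/NPYR` + `RS/PYR` cells
#'   in Layers II/III plus an `FS/NPYR` basket population inside a
#'   Hypercolumn unit, driven by a `STIM` population abstracting the Layer
#'   IV input. The stimulus sits outside the hypercolumn unit (its housing
#'   is not specified by the source) and densities are omitted.
#'
#' Every fixture validates clean against the rulebook.
#'
#' @param fid One of [fixture_ids()].
#' @return An `nns_model`.
#' @export
build_fixture <- function(fid) {
  if (!is_string(fid) || !fid %in% fixture_ids()) {
    abort_ns(sprintf("unknown fixture id %s; see fixture_ids()", deparse(fid)),
             "nns_unknown_fixture")
  }
  switch(fid,
    FIG7_POPULATIONS = nns_model(
      populations = list(
        population("pois", ephys = "POIS"),
        population("pyr", ephys = "RS", morph = "PYR"),
        population("uni", morph = "UNI")),
      metadata = list(title = "Population symbol examples")),

    FIG8_PROJECTIONS = nns_model(
      populations = list(population("pyr", ephys = "RS", morph = "PYR")),
      projections = list(
        projection("in_exc", EXTERNAL, "pyr", "excitatory", density = 0.5),
        projection("in_inh", EXTERNAL, "pyr", "inhibitory", density = 0.1),
        projection("self_exc", "pyr", "pyr", "excitatory", density = 0.2),
        projection("out_exc", "pyr", EXTERNAL, "excitatory", density = 0.2)),
      metadata = list(title = "Projection symbol examples")),

    FIG10_THALAMOCORTICAL = nns_model(
      regions = list(
        region("thalamus", "ncr", name = "Thalamus", display_order = 1L),
        region("area5", "area", name = "Area 5", display_order = 2L)),
      layers = list(layer("area5.VI", "VI", "area5")),
      populations = list(
        population("tc", morph = "TC", region = "thalamus"),
        population("re", morph = "RE", region = "thalamus"),
        population("pyr", ephys = "RS", morph = "PYR",
                   region = "area5", layer = "area5.VI"),
        population("in", ephys = "FS", morph = "NPYR",
                   region = "area5", layer = "area5.VI")),
      projections = list(
        projection("stim_tc", EXTERNAL, "tc", "excitatory"),
        projection("stim_pyr", EXTERNAL, "pyr", "excitatory"),
        projection("tc_pyr", "tc", "pyr", "excitatory"),
        projection("tc_in", "tc", "in", "excitatory"),
        projection("tc_re", "tc", "re", "excitatory"),
        projection("pyr_tc", "pyr", "tc", "excitatory"),
        projection("pyr_re", "pyr", "re", "excitatory"),
        projection("pyr_pyr", "pyr", "pyr", "excitatory"),
        projection("re_tc", "re", "tc", "inhibitory"),
        projection("re_re", "re", "re", "inhibitory"),
        projection("in_pyr", "in", "pyr", "inhibitory")),
      metadata = list(title = "Thalamocortical regions")),

    FIG11_SYNFIRE_FFI = {
      pops <- list(population("stim", ephys = "POIS"))
      projs <- list(
        projection("stim_rs1", "stim", "rs1", "excitatory"),
        projection("stim_fs1", "stim", "fs1", "excitatory"))
      units <- list()
      for (k in 1:3) {
        rs <- sprintf("rs%d", k)
        fs <- sprintf("fs%d", k)
        pops <- c(pops, list(
          population(rs, ephys = "RS", morph = "PYR"),
          population(fs, ephys = "FS", morph = "NPYR")))
        units <- c(units, list(
          unit_group(sprintf("group%d", k), name = sprintf("Group %d", k),
                     members = c(rs, fs))))
        projs <- c(projs, list(
          projection(sprintf("ffi%d", k), fs, rs, "inhibitory")))
        if (k < 3) {
          projs <- c(projs, list(
            projection(sprintf("chain_rs%d", k), rs, sprintf("rs%d", k + 1),
                       "excitatory"),
            projection(sprintf("chain_fs%d", k), rs, sprintf("fs%d", k + 1),
                       "excitatory")))
        }
      }
      nns_model(populations = pops, projections = projs, units = units,
                metadata = list(title = "Synfire chain with feed-forward inhibition"))
    },

    FIG12_HYPERCOLUMN = {
      pops <- list(
        population("basket", ephys = "FS", morph = "NPYR",
                   region = "cortex", layer = "cortex.III"),
        population("stim", morph = "STIM", region = "cortex"))
      projs <- list(
        projection("stim_pyr1", "stim", "mc1_pyr", "excitatory"),
        projection("stim_pyr2", "stim", "mc2_pyr", "excitatory"))
      units <- list(unit_group("hc", name = "Hypercolumn",
                               members = c("mc1", "mc2", "basket")))
      for (k in 1:2) {
        pyr <- sprintf("mc%d_pyr", k)
        rsnp <- sprintf("mc%d_rsnp", k)
        other <- sprintf("mc%d_rsnp", 3L - k)
        pops <- c(pops, list(
          population(pyr, ephys = "RS", morph = "PYR",
                     region = "cortex", layer = "cortex.II"),
          population(rsnp, ephys = "RS", morph = "NPYR",
                     region = "cortex", layer = "cortex.III")))
        units <- c(units, list(
          unit_group(sprintf("mc%d", k), name = "Minicolumn",
                     members = c(pyr, rsnp))))
        projs <- c(projs, list(
          projection(sprintf("rec%d", k), pyr, pyr, "excitatory"),
          projection(sprintf("pyr%d_basket", k), pyr, "basket", "excitatory"),
          projection(sprintf("basket_pyr%d", k), "basket", pyr, "inhibitory"),
          projection(sprintf("pyr%d_dbc", k), pyr, other, "excitatory"),
          projection(sprintf("dbc_pyr%d", k), rsnp, pyr, "inhibitory")))
      }
      nns_model(
        regions = list(region("cortex", "area", name = "", display_order = 1L)),
        layers = list(layer("cortex.II", "II", "cortex"),
                      layer("cortex.III", "III", "cortex")),
        populations = pops, projections = projs, units = units,
        metadata = list(title = "Associative-memory hypercolumn"))
    })
}

#' Generate a random model with controlled structure
#'
#' Property-test input generator: builds a valid random schematic with the
#' requested element counts. Output is a pure function of the arguments
#' (seeded determinism). Densities, when present, are sampled uniformly on
#' (0, 1] on a 1e-6 grid so they survive textual serialization exactly.
#' Assignments of populations to layers, regions and units are made
#' uniformly among valid choices only (layered populations only inside areas
#' that contain the layer, at most one direct unit membership, unit nesting
#' kept acyclic).
#'
#' @param seed Integer seed.
#' @param n_pop,n_proj,n_layers,n_regions,n_units Non-negative element counts.
#' @param p_inhibitory Probability that a projection is inhibitory.
#' @param p_external Probability that a projection has an `EXTERNAL` endpoint.
#' @return An `nns_model` validating clean.
#' @export
random_model <- function(seed, n_pop = 8, n_proj = 16, n_layers = 0,
                         n_regions = 0, n_units = 0,
                         p_inhibitory = 0.2, p_external = 0.1) {
  stopifnot(is_count(n_pop), is_count(n_proj), is_count(n_layers),
            is_count(n_regions), is_count(n_units),
            is_prob(p_inhibitory), is_prob(p_external))
  if (n_proj > 0 && n_pop == 0) {
    abort_ns("cannot generate projections without populations", "nns_generator_error")
  }
  set.seed(as.integer(seed))

  ncr_names <- c("Thalamus", "LGN", "Striatum", "Cerebellum", "Superior Colliculus")
  regions <- list()
  if (n_regions > 0) {
    kinds <- sample(c("area", "ncr"), n_regions, replace = TRUE)
    if (n_layers > 0 && !"area" %in% kinds) kinds[1L] <- "area"
    for (i in seq_len(n_regions)) {
      nm <- if (kinds[i] == "area") sprintf("Area %d", i) else
        ncr_names[1L + (i - 1L) %% length(ncr_names)]
      regions[[i]] <- region(sprintf("reg%02d", i), kinds[i], name = nm,
                             display_order = i)
    }
  } else if (n_layers > 0) {
    abort_ns("layers requested but no regions to contain them", "nns_generator_error")
  }
  area_ids <- vapply(Filter(function(r) r$kind == "area", regions),
                     `[[`, "", "id")
  if (n_layers > 6L * length(area_ids)) {
    abort_ns("more layers requested than areas can contain", "nns_generator_error")
  }

  layers <- list()
  free <- lapply(stats::setNames(area_ids, area_ids),
                 function(a) names(roman_layers))
  for (i in seq_len(n_layers)) {
    open <- names(free)[vapply(free, length, 0L) > 0L]
    a <- open[sample.int(length(open), 1L)]
    nm <- free[[a]][sample.int(length(free[[a]]), 1L)]
    free[[a]] <- setdiff(free[[a]], nm)
    layers[[i]] <- layer(sprintf("lay%02d", i), nm, a)
  }
  layers_of <- function(a) Filter(function(l) l$area_ref == a, layers)

  ephys_pool <- c("RS", "FS", "IB", "CH", "POIS")
  morph_pool <- c("PYR", "NPYR", "TC", "RE", "UNI", "STIM")
  pops <- vector("list", n_pop)
  for (i in seq_len(n_pop)) {
    shape <- sample.int(3L, 1L)
    eph <- if (shape != 2L) ephys_pool[sample.int(length(ephys_pool), 1L)]
    mor <- if (shape != 1L) morph_pool[sample.int(length(morph_pool), 1L)]
    reg <- lay <- NULL
    if (length(regions) && stats::runif(1) < 0.8) {
      r <- regions[[sample.int(length(regions), 1L)]]
      reg <- r$id
      rl <- if (r$kind == "area") layers_of(r$id) else list()
      if (length(rl) && stats::runif(1) < 0.7) {
        lay <- rl[[sample.int(length(rl), 1L)]]$id
      }
    }
    extra <- if (stats::runif(1) < 0.3) list(size = sample(50:500, 1L)) else list()
    pops[[i]] <- population(sprintf("pop%02d", i), ephys = eph, morph = mor,
                            layer = lay, region = reg, extra = extra)
  }
  pop_ids <- vapply(pops, `[[`, "", "id")

  units <- vector("list", n_units)
  members <- replicate(n_units, character(), simplify = FALSE)
  if (n_units > 0) {
    for (i in seq_len(n_units)) {
      if (i > 1L && stats::runif(1) < 0.4) {
        parent <- sample.int(i - 1L, 1L)
        members[[parent]] <- c(members[[parent]], sprintf("unit%02d", i))
      }
    }
    for (p in pop_ids) {
      if (stats::runif(1) < 0.6) {
        k <- sample.int(n_units, 1L)
        members[[k]] <- c(members[[k]], p)
      }
    }
    for (i in seq_len(n_units)) {
      units[[i]] <- unit_group(sprintf("unit%02d", i),
                               name = sprintf("Unit %d", i),
                               members = members[[i]])
    }
  }

  projs <- vector("list", n_proj)
  for (i in seq_len(n_proj)) {
    if (stats::runif(1) < p_external) {
      p <- pop_ids[sample.int(n_pop, 1L)]
      if (stats::runif(1) < 0.5) { src <- EXTERNAL; tgt <- p }
      else { src <- p; tgt <- EXTERNAL }
    } else {
      src <- pop_ids[sample.int(n_pop, 1L)]
      tgt <- pop_ids[sample.int(n_pop, 1L)]
    }
    exc <- if (stats::runif(1) < p_inhibitory) "inhibitory" else "excitatory"
    dens <- if (stats::runif(1) < 0.8) ceiling(stats::runif(1) * 1e6) / 1e6
    projs[[i]] <- projection(sprintf("proj%02d", i), src, tgt, exc,
                             density = dens)
  }

  nns_model(populations = pops, projections = projs, layers = layers,
            regions = regions, units = units)
}
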
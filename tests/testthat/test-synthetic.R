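test_that("population generation is a pure function of config and seed", {
  cfg <- generator_config(n_molecules = 10, seed = 7)
  d1 <- generate_population(cfg)
  d2 <- generate_population(cfg)
  expect_identical(d1$graphs, d2$graphs)

  d3 <- generate_population(generator_config(n_molecules = 10, seed = 8))
  expect_false(identical(d1$graphs, d3$graphs))
})

test_that("degenerate size range fixes the atom count", {
  cfg <- generator_config(n_molecules = 20, size_range = c(5, 5), seed = 1)
  ds <- generate_population(cfg)
  expect_true(all(vapply(ds$graphs, n_atoms, integer(1)) == 5L))
})

test_that("every generated graph is valid across many seeded draws", {
  # 1,000 graphs across several seeds, all must pass the validator
  for (seed in 1:4) {
    ds <- generate_population(generator_config(n_molecules = 250, seed = seed))
    viol <- lapply(ds$graphs, validate_graph)
    expect_true(all(lengths(viol) == 0))
  }
})

test_that("atom-type frequencies match the configured distribution", {
  probs <- c(H = 0.5, C = 0.33, N = 0.07, O = 0.07, F = 0.03)
  ds <- generate_population(generator_config(n_molecules = 1000, seed = 42,
                                             atom_type_probs = probs))
  codes <- unlist(lapply(ds$graphs, `[[`, "nodes"))
  n <- length(codes)
  for (a in names(probs)) {
    emp <- mean(codes == a)
    se <- sqrt(probs[[a]] * (1 - probs[[a]]) / n)
    expect_lt(abs(emp - probs[[a]]), 3 * se)
  }
})

test_that("attach_property matches an independent functional computation", {
  ds <- generate_population(generator_config(n_molecules = 50, seed = 3))

  # identity functional, no noise
  ds <- attach_property(ds, property_spec("size", c(n_atoms = 1)), seed = 1)
  expect_equal(ds$properties$size,
               vapply(ds$graphs, n_atoms, integer(1)) + 0)

  # independent re-implementation of the linear combination
  spec <- property_spec("combo",
                        c(frac_nonsingle = 2.0, mean_degree = -1.5,
                          count_type_C = 0.25))
  ds <- attach_property(ds, spec, seed = 1)
  oracle <- vapply(ds$graphs, function(g) {
    nb <- nrow(g$edges)
    fns <- if (nb) sum(g$edges$type %in% c("double", "triple", "aromatic")) / nb else 0
    2.0 * fns - 1.5 * (2 * nb / length(g$nodes)) + 0.25 * sum(g$nodes == "C")
  }, numeric(1))
  expect_equal(ds$properties$combo, oracle)

  # fixed fraction example: 2 single + 2 double bonds -> frac 0.5
  g <- mol_graph(c("C", "C", "C", "C", "C"),
                 data.frame(u = 1:4, v = 2:5,
                            type = c("single", "double", "single", "double")))
  expect_equal(property_signal(g, property_spec("y", c(frac_nonsingle = 2))), 1.0)

  expect_error(attach_property(ds, property_spec("z", c(nonsense = 1))),
               "unknown graph functional")
})

test_that("noise keeps the property tightly correlated with its signal", {
  ds <- generate_population(generator_config(n_molecules = 2000, seed = 9))
  spec <- property_spec("y", c(mean_degree = 10), noise_sd = 0.1)
  ds <- attach_property(ds, spec, seed = 4)
  signal <- vapply(ds$graphs, property_signal, numeric(1), spec = spec)
  expect_gt(cor(ds$properties$y, signal), 0.99)
  # noise is seeded and reproducible
  ds2 <- attach_property(ds, spec, seed = 4)
  expect_equal(ds2$properties$y, ds$properties$y)
})

test_that("the packaged benchmark has the documented shape", {
  ds <- default_benchmark(seed = 0, n_molecules = 120)
  expect_equal(length(ds), 120L)
  expect_setequal(setdiff(names(ds$properties), "id"),
                  c("target_size_linked", "target_bond_linked",
                    "gap_like", "target_self"))
  expect_false(identical(ds$properties$gap_like, ds$properties$target_self))
  sizes <- vapply(ds$graphs, n_atoms, integer(1))
  expect_true(all(sizes >= 3 & sizes <= 27))
})
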
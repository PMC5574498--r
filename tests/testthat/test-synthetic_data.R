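# Synthetic paired-data generator: joint-cell inversion, determinism,
# class-level constraints, parameter recovery, reference fixtures.

test_that("generate_joint inverts the kappa definition", {
  j <- generate_joint(allergen_sim_spec("x", 0.3, kappa_target = 1))
  expect_equal(unname(j), c(0.3, 0, 0, 0.7))
  j0 <- generate_joint(allergen_sim_spec("x", 0.5, kappa_target = 0))
  expect_equal(unname(j0), rep(0.25, 4))

  # round trip through the agreement module at machine precision
  set.seed(3)
  for (i in 1:50) {
    pa <- runif(1, 0.05, 0.95)
    kt <- runif(1, 0.05, 0.95)
    dl <- runif(1, -0.05, 0.05)
    spec <- allergen_sim_spec("x", pa, kt, dl)
    j <- tryCatch(generate_joint(spec), mast_infeasible_spec = function(e) NULL)
    if (is.null(j)) next
    scale <- 1e9 # large pseudo-counts: kappa is scale-free
    tab <- paired_table(round(j[1] * scale), round(j[2] * scale),
                        round(j[3] * scale), round(j[4] * scale))
    expect_equal(cohen_kappa(tab), kt, tolerance = 1e-6)
  }
  expect_error(generate_joint(allergen_sim_spec("x", 0.49, 0.9, 0.2)),
               class = "mast_infeasible_spec")
  err <- tryCatch(generate_joint(allergen_sim_spec("x", 0.49, 0.9, 0.2)),
                  error = identity)
  expect_match(conditionMessage(err), "p_np") # names the violated cell
  expect_error(allergen_sim_spec("x", 0.1, 0.5, 0.5),
               class = "mast_infeasible_spec")
})

test_that("simulation is deterministic and allergen substreams are independent", {
  cfg <- sim_config(5, list(allergen_sim_spec("cat", 0.4, 0.7)),
                    analyzer_a = "A", analyzer_b = "B", seed = 9)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_equal(nrow(d1), 10)

  # adding an allergen does not perturb the existing one's draws
  cfg2 <- sim_config(5, list(allergen_sim_spec("cat", 0.4, 0.7),
                             allergen_sim_spec("milk", 0.2, 0.6)),
                     analyzer_a = "A", analyzer_b = "B", seed = 9)
  d3 <- simulate_dataset(cfg2)
  cat1 <- as.data.frame(d1)
  cat3 <- as.data.frame(d3)[as.data.frame(d3)$allergen == "cat", ]
  rownames(cat3) <- NULL
  expect_equal(cat1, cat3, ignore_attr = TRUE)

  # byte-identical written output
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_results(d1, p1)
  write_results(simulate_dataset(cfg), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("generated classes respect the generative cutoff exactly", {
  for (t in c(1L, 2L, 4L)) {
    cfg <- sim_config(400, list(allergen_sim_spec("cat", 0.5, 0.3)),
                      analyzer_a = "A", analyzer_b = "B", cutoff = t, seed = 2)
    d <- simulate_dataset(cfg)
    ps <- build_pair_set(d, "A", "B", "food")
    tab <- tabulate_pairs(ps$pairs, t)
    # every record is cleanly positive (>= t) or negative (< t); tabulation
    # at the generative cutoff partitions all pairs
    expect_equal(tab$N, 400)
    expect_true(all(d$class >= 0 & d$class <= 6))
  }
  # perfect-agreement spec: empirical agreement 100% at the generative cutoff
  cfg1 <- sim_config(200, list(allergen_sim_spec("cat", 0.3, 1)),
                     analyzer_a = "A", analyzer_b = "B", seed = 4)
  ps1 <- build_pair_set(simulate_dataset(cfg1), "A", "B", "food")
  expect_equal(total_agreement(tabulate_pairs(ps1$pairs, 2)), 100)
})

test_that("empirical cells recover the target parameters at large n", {
  spec <- allergen_sim_spec("x", 0.4, kappa_target = 0.6, propensity_delta = 0.1)
  cfg <- sim_config(100000, list(spec), analyzer_a = "A", analyzer_b = "B",
                    seed = 19)
  ps <- build_pair_set(simulate_dataset(cfg), "A", "B", "food")
  tab <- tabulate_pairs(ps$pairs, 2)
  expect_lt(abs(cohen_kappa(tab) - 0.6), 0.02)
  expect_lt(abs(positive_propensity(tab) - 10), 0.5)
  # cell frequencies within 3 binomial SEs of generate_joint output
  j <- generate_joint(spec)
  emp <- c(tab$n_pp, tab$n_pn, tab$n_np, tab$n_nn) / tab$N
  se3 <- 3 * sqrt(j * (1 - j) / tab$N)
  expect_true(all(abs(emp - j) <= se3 + 1e-12))
})

test_that("reference fixtures reproduce their reconstructed 2x2 tables", {
  cases <- list(
    dfarinae_food = c(21, 1, 1, 20),
    dpteronyssinus_food = c(22, 0, 0, 21),
    barleymeal_food = c(1, 1, 0, 41),
    cladosporium_food = c(0, 1, 0, 42),
    dog_inhalant = c(0, 1, 1, 88),
    housedust_food_smart_vs_rida = c(0, 8, 0, 22),
    housedust_inhalant_smart_vs_rida = c(0, 24, 0, 55),
    dfarinae_inhalant_protia_vs_rida = c(11, 16, 0, 66)
  )
  for (nm in names(cases)) {
    d <- reference_fixture(nm)
    an <- unique(d$analyzer)
    ps <- build_pair_set(d, an[1], an[2], unique(d$panel))
    tab <- tabulate_pairs(ps$pairs, 2)
    expect_equal(c(tab$n_pp, tab$n_pn, tab$n_np, tab$n_nn), cases[[nm]],
                 info = nm)
  }
  expect_error(reference_fixture("nope"), class = "mast_unknown_fixture")
})

test_that("YAML config round-trips into a working simulation", {
  path <- system.file("extdata", "example_sim.yaml", package = "mastagree")
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_patients, 40L)
  expect_equal(length(cfg$allergens), 4)
  d <- simulate_dataset(cfg)
  expect_equal(nrow(d), 40 * 4 * 2)
  expect_error(read_sim_config(file.path(tempdir(), "none.yaml")),
               class = "mast_io_error")
})
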
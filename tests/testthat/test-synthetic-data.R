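test_that("community config validates its distributions", {
  expect_s3_class(tiny_config(), "community_config")
  expect_error(tiny_config(availability = c(0.5, 0.5)), "over the 3 taxa")
  expect_error(tiny_config(u_laevis = c(-1, 1, 1)), "non-negative")
  expect_error(community_config(
    taxa = "a", habitat_class = "benthos",
    availability = list(A = 1), utilization = list(B = list(s = 1)),
    n_predators = list(A = list(s = 1))), "same sites")
})

test_that("environment generation is multinomial around the availability truth", {
  cfg <- tiny_config()
  one <- generate_environment(tiny_config(availability = c(1, 0, 0)),
                              "A", seed = 1, total = 50)
  expect_equal(unique(one$taxon), "Ostracoda")
  expect_equal(nrow(one), 50)
  expect_equal(unique(one$sampling_method), "core")

  env <- generate_environment(cfg, "A", seed = 2, total = 2873)
  phat <- table(factor(env$taxon, levels = cfg$taxa)) / 2873
  p <- c(0.5, 0.3, 0.2)
  se <- sqrt(p * (1 - p) / 2873)
  expect_true(all(abs(as.numeric(phat) - p) <= 3 * se))

  # reproducibility
  expect_identical(generate_environment(cfg, "A", seed = 7),
                   generate_environment(cfg, "A", seed = 7))
  expect_error(generate_environment(cfg, "B", seed = 1), "unknown site")
})

test_that("stomach generation recovers the utilization truth and its knobs work", {
  cfg <- tiny_config(u_laevis = c(0.5, 0.5, 0), n_laevis = 120,
                     empty_rate = 0, contamination = c(sloughed_skin = 0,
                                                       plant_matter = 0,
                                                       stone = 0))
  g <- generate_stomachs(cfg, "A", "X_laevis", seed = 10)
  n_items <- nrow(g$records)
  expect_gt(n_items, 500)
  counts <- table(factor(g$records$taxon, levels = cfg$taxa))
  expect_equal(unname(counts[["Anura"]]), 0)
  se <- sqrt(n_items * 0.25)
  expect_lt(abs(counts[["Ostracoda"]] - n_items / 2), 3 * se)
  # every item belongs to a known predator; SVL in the species range
  expect_true(all(g$records$predator_id %in% g$predators$predator_id))
  expect_true(all(g$predators$svl_mm >= 35 & g$predators$svl_mm <= 105))

  empty <- generate_stomachs(tiny_config(n_laevis = 0), "A", "X_laevis",
                             seed = 1)
  expect_equal(nrow(empty$predators), 0)
  expect_equal(nrow(empty$records), 0)
  expect_s3_class(empty$records, "prey_records")
})

test_that("a diet concentrated on anurans yields a matching anurophagy ratio", {
  cfg <- tiny_config(u_laevis = c(0.1, 0.1, 0.8), n_laevis = 100,
                     empty_rate = 0)
  g <- generate_stomachs(cfg, "A", "X_laevis", seed = 12)
  tab <- build_abundance_table(g$records, g$predators)
  ratio <- anurophagy_summary(tab, "X_laevis")$ratio
  expect_close(ratio, 0.8, tol = 0.05)
})

test_that("simulated studies are written whole and carry a usable truth file", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(tiny_config(), dir, seed = 99)
  expect_true(all(file.exists(unlist(sim$paths))))
  prey <- read_prey_records(sim$paths$prey)
  preds <- read_predators(sim$paths$predators)
  expect_gt(nrow(prey), 0)
  truth <- jsonlite::read_json(sim$paths$truth, simplifyVector = TRUE)
  expect_equal(truth$seed, 99)
  expect_equal(truth$true_overlap$A,
               pianka_overlap(c(0.2, 0.3, 0.5), c(0.3, 0.3, 0.4)),
               tolerance = 1e-9)
  # non-prey contamination present but excluded from the prey table
  tab <- build_abundance_table(prey, preds)
  expect_true(all(tab$taxa %in% c("Ostracoda", "Daphnia", "Anura")))
})

test_that("estimated overlap converges to the true overlap as sampling grows", {
  sizes <- c(8, 80, 800)          # predators per species; ~12 items each
  true_o <- pianka_overlap(c(0.2, 0.3, 0.5), c(0.3, 0.3, 0.4))
  errs <- vapply(seq_along(sizes), function(i) {
    cfg <- tiny_config(n_laevis = sizes[i], n_gilli = sizes[i],
                       empty_rate = 0)
    gl <- generate_stomachs(cfg, "A", "X_laevis", seed = 100 + i)
    gg <- generate_stomachs(cfg, "A", "X_gilli", seed = 200 + i)
    tab <- build_abundance_table(rbind(gl$records, gg$records),
                                 rbind(gl$predators, gg$predators))
    est <- pianka_overlap(make_profile(tab, "X_laevis"),
                          make_profile(tab, "X_gilli"))
    abs(est - true_o)
  }, 0)
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.02)
})

test_that("planted preference is detected; no-selection diets give E* near zero", {
  # preference planted on Anura: r = 0.6 vs availability p = 0.1
  cfg <- tiny_config(availability = c(0.6, 0.3, 0.1),
                     u_laevis = c(0.25, 0.15, 0.6),
                     u_gilli = c(0.6, 0.3, 0.1),   # feeds at availability
                     n_laevis = 80, n_gilli = 80, empty_rate = 0)
  env <- generate_environment(cfg, "A", seed = 61, total = 4000)
  gl <- generate_stomachs(cfg, "A", "X_laevis", seed = 62)
  gg <- generate_stomachs(cfg, "A", "X_gilli", seed = 63)
  tab <- build_abundance_table(rbind(env, gl$records, gg$records),
                               rbind(gl$predators, gg$predators))
  ea <- electivity_analysis(tab, c("A.X_laevis", "A.X_gilli"), "A.environment")
  lae <- ea$taxa[["A.X_laevis"]]
  expect_equal(lae$verdict[lae$taxon == "Anura"], "preferred")
  expect_gt(lae$estar[lae$taxon == "Anura"], 0.5)
  # the no-selection species shows only small electivities
  gil <- ea$taxa[["A.X_gilli"]]
  expect_true(all(abs(gil$estar[gil$included]) < 0.25))
})
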
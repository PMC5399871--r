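test_that("CSV reader passes records through and applies defaults", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,site,taxon,habitat_class",
               "stomach,A,Ostracoda,benthos",
               "stomach,A,Acari,nekton",
               "stomach,A,Anura,nekton"), path)
  rec <- read_prey_records(path)
  expect_s3_class(rec, "prey_records")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$taxon, c("Ostracoda", "Acari", "Anura"))
  expect_equal(rec$count, rep(1L, 3))            # counts default to 1
  expect_equal(rec$non_prey_flag, rep("none", 3))
})

test_that("reader rejects invalid rows and missing columns with specifics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,site,taxon,habitat_class,count",
               "stomach,A,Ostracoda,benthos,0"), path)
  expect_error(read_prey_records(path), "count must be a positive integer")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,site,habitat_class", "stomach,A,benthos"), path2)
  expect_error(read_prey_records(path2), "taxon")

  bad_vocab <- tiny_prey()
  bad_vocab$habitat_class[2] <- "pelagic"
  expect_error(prey_records(bad_vocab), "habitat_class.*benthos",
               class = "dietniche_validation_error")
})

test_that("predator reader validates SVL and species vocabulary", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("predator_id,species,site,svl_mm",
               "g1,X_gilli,CoGH,36.9"), path)
  p <- read_predators(path)
  expect_equal(p$svl_mm, 36.9)
  expect_equal(p$species, "X_gilli")
  expect_equal(p$sex, "unknown")

  expect_error(predators(data.frame(predator_id = "x", species = "X_laevis",
                                    site = "A", svl_mm = -5)),
               "svl_mm must be a positive")
  expect_error(predators(data.frame(predator_id = "x", species = "X_borealis",
                                    site = "A", svl_mm = 40)),
               "X_laevis, X_gilli")
})

test_that("non-prey items are retained in records but never tabulated as prey", {
  prey <- tiny_prey()
  prey$non_prey_flag <- "none"
  prey <- rbind(prey, data.frame(source = "stomach", site = "A", pond = "P1",
                                 sampling_method = "stomach_flush",
                                 taxon = "sloughed_skin",
                                 habitat_class = "terrestrial", count = 1L,
                                 predator_id = "f1",
                                 non_prey_flag = "sloughed_skin"))
  rec <- prey_records(prey)
  expect_true("sloughed_skin" %in% rec$taxon)     # recorded
  tab <- build_abundance_table(rec, tiny_predators())
  expect_false("sloughed_skin" %in% tab$taxa)     # never counted as prey
})

test_that("abundance table equals an independent brute-force tally", {
  prey <- tiny_prey()
  preds <- tiny_predators()
  tab <- build_abundance_table(prey, preds)

  # oracle: plain split/sum tally of the same records
  st <- prey[prey$source == "stomach", ]
  st$species <- preds$species[match(st$predator_id, preds$predator_id)]
  for (sp in unique(st$species)) {
    lab <- paste("A", sp, sep = ".")
    for (tx in tab$taxa) {
      rows <- st[st$species == sp & st$taxon == tx, ]
      expect_identical(unname(tab$N[tx, lab]), as.integer(sum(rows$count)))
      expect_identical(unname(tab$Freq[tx, lab]),
                       length(unique(rows$predator_id)))
    }
  }
  env <- prey[prey$source == "environment", ]
  for (tx in tab$taxa) {
    expect_identical(unname(tab$N[tx, "A.environment"]),
                     as.integer(sum(env$count[env$taxon == tx])))
  }
  # hand-checked expectations for the tiny fixture
  expect_equal(unname(tab$N["Ostracoda", "A.X_laevis"]), 3L)
  expect_equal(unname(tab$Freq["Ostracoda", "A.X_laevis"]), 1L)
  expect_equal(unname(tab$Freq["Daphnia", "A.X_laevis"]), 2L)
  expect_equal(unname(tab$N["Daphnia", "A.X_gilli"]), 1L)
  expect_error(build_abundance_table(
    transform(prey, predator_id = ifelse(is.na(predator_id), NA, "ghost")),
    preds), "unknown predator ID")
})

test_that("abundance tables round-trip through CSV exactly", {
  tab <- build_abundance_table(tiny_prey(), tiny_predators())
  path <- withr::local_tempfile(fileext = ".csv")
  write_abundance_table(tab, path)
  back <- read_abundance_table(path)
  expect_identical(back$N, tab$N)
  expect_identical(back$Freq, tab$Freq)
  expect_equal(back$V, tab$V)
  expect_identical(back$groups$n_predators, tab$groups$n_predators)
})

test_that("tally conservation and Freq bounds hold on random fixtures", {
  set.seed(42)
  for (i in 1:10) {
    fx <- random_fixture(n_records = sample(20:80, 1),
                         n_predators = sample(3:8, 1))
    tab <- build_abundance_table(fx$prey, fx$predators)
    # conservation: total N equals total record count
    expect_equal(sum(tab$N), sum(fx$prey$count))
    # Freq never exceeds the number of predators in its group
    for (j in seq_len(nrow(tab$groups))) {
      if (tab$groups$group[j] == "environment") next
      expect_true(all(tab$Freq[, tab$groups$label[j]] <=
                        tab$groups$n_predators[j]))
    }
  }
})
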
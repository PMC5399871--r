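# In-code fixtures shared across test files.

# A minimal hand-checkable dataset: 3 predators at one site, 2 prey taxa in
# stomachs plus an environment sample.
tiny_prey <- function() {
  data.frame(
    source = c(rep("stomach", 6), rep("environment", 4)),
    site = "A",
    pond = "P1",
    sampling_method = c(rep("stomach_flush", 6), rep("sweep", 4)),
    taxon = c("Ostracoda", "Ostracoda", "Daphnia", "Daphnia", "Daphnia",
              "Ostracoda", "Ostracoda", "Ostracoda", "Daphnia", "Daphnia"),
    habitat_class = c(rep(c("benthos", "benthos", "zooplankton",
                            "zooplankton", "zooplankton", "benthos"), 1),
                      "benthos", "benthos", "zooplankton", "zooplankton"),
    count = c(1L, 2L, 5L, 1L, 1L, 3L, 10L, 5L, 20L, 2L),
    predator_id = c("f1", "f1", "f1", "f2", "f3", "f3", NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

tiny_predators <- function() {
  data.frame(
    predator_id = c("f1", "f2", "f3"),
    species = c("X_laevis", "X_laevis", "X_gilli"),
    site = "A",
    svl_mm = c(80.0, 45.5, 36.9),
    sex = c("F", "M", "F"),
    stringsAsFactors = FALSE
  )
}

# Random prey/predator fixture generator for property-style tests.
random_fixture <- function(n_records = 40, n_predators = 6, n_taxa = 4,
                           site = "S") {
  taxa <- paste0("T", seq_len(n_taxa))
  ids <- paste0("p", seq_len(n_predators))
  prey <- data.frame(
    source = sample(c("stomach", "environment"), n_records, replace = TRUE),
    site = site,
    taxon = sample(taxa, n_records, replace = TRUE),
    habitat_class = sample(HABITAT_CLASSES, n_records, replace = TRUE),
    count = sample(1:5, n_records, replace = TRUE),
    stringsAsFactors = FALSE
  )
  prey$predator_id <- ifelse(prey$source == "stomach",
                             sample(ids, n_records, replace = TRUE),
                             NA_character_)
  preds <- data.frame(predator_id = ids,
                      species = sample(c("X_laevis", "X_gilli"), n_predators,
                                       replace = TRUE),
                      site = site,
                      svl_mm = runif(n_predators, 31, 90),
                      stringsAsFactors = FALSE)
  list(prey = prey, predators = preds)
}

# Small community config for generator tests (3 taxa, one site, two species).
tiny_config <- function(availability = c(0.5, 0.3, 0.2),
                        u_laevis = c(0.2, 0.3, 0.5),
                        u_gilli = c(0.3, 0.3, 0.4),
                        n_laevis = 20, n_gilli = 20, ...) {
  community_config(
    taxa = c("Ostracoda", "Daphnia", "Anura"),
    habitat_class = c("benthos", "zooplankton", "nekton"),
    availability = list(A = availability),
    utilization = list(A = list(X_laevis = u_laevis, X_gilli = u_gilli)),
    n_predators = list(A = list(X_laevis = n_laevis, X_gilli = n_gilli)),
    env_total = list(A = 500),
    ...
  )
}

expect_close <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol)
}
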
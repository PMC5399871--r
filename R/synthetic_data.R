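#' Configuration of a synthetic two-site predator-prey community
#'
#' Describes a community with known ground truth from which environment
#' samples and stomach contents can be simulated: per-site availability
#' distributions, per site x species true utilization distributions,
#' predators per group, an overdispersed items-per-stomach law (negative
#' binomial — in real stomach data a few individuals dominate the counts of
#' swarming prey, which a Poisson cannot mimic), per-taxon log-normal prey
#' length distributions, the empty-stomach fraction and non-prey
#' contamination rates.
#'
#' @param taxa character vector of prey taxa.
#' @param habitat_class habitat class per taxon (same length).
#' @param availability named list `site -> numeric vector` (proportions over
#'   `taxa`; normalized).
#' @param utilization nested named list `site -> species -> vector` of true
#'   diet proportions.
#' @param n_predators nested named list `site -> species -> count`.
#' @param env_total named list `site -> total` environmental items.
#' @param items_mean,items_dispersion negative-binomial mean and size of the
#'   per-stomach item count (non-empty stomachs; at least 1 item).
#' @param empty_rate fraction of empty stomachs.
#' @param contamination named per-stomach probabilities of one
#'   `sloughed_skin`, `plant_matter`, `stone` record.
#' @param prey_length_meanlog,prey_length_sdlog log-normal parameters of prey
#'   length (mm), recycled over taxa; width is drawn as 40% of length.
#' @param svl_range named list `species -> c(min, max)` of SVL (mm).
#' @return A validated `community_config` list.
#' @export
community_config <- function(taxa, habitat_class, availability, utilization,
                             n_predators, env_total = NULL,
                             items_mean = 12, items_dispersion = 1.5,
                             empty_rate = 0.03,
                             contamination = c(sloughed_skin = 0.16,
                                               plant_matter = 0.14,
                                               stone = 0.01),
                             prey_length_meanlog = log(3),
                             prey_length_sdlog = 0.6,
                             svl_range = list(X_laevis = c(35, 105),
                                              X_gilli = c(30, 62))) {
  stopifnot(length(taxa) == length(habitat_class), !anyDuplicated(taxa))
  check_vocab(habitat_class, HABITAT_CLASSES, "habitat_class")
  norm <- function(v, what) {
    if (length(v) != length(taxa) || any(v < 0) || sum(v) <= 0) {
      stop_dn(what, " must be a non-negative vector over the ", length(taxa),
              " taxa with positive sum")
    }
    stats::setNames(v / sum(v), taxa)
  }
  availability <- lapply(availability, norm, what = "availability")
  utilization <- lapply(utilization, function(site) {
    lapply(site, norm, what = "utilization")
  })
  if (!setequal(names(availability), names(utilization))) {
    stop_dn("availability and utilization must cover the same sites")
  }
  stopifnot(items_mean > 0, items_dispersion > 0,
            empty_rate >= 0, empty_rate < 1)
  structure(list(taxa = taxa,
                 habitat_class = stats::setNames(habitat_class, taxa),
                 availability = availability, utilization = utilization,
                 n_predators = n_predators,
                 env_total = env_total %||%
                   stats::setNames(as.list(rep(2000, length(availability))),
                                   names(availability)),
                 items_mean = items_mean, items_dispersion = items_dispersion,
                 empty_rate = empty_rate, contamination = contamination,
                 prey_length_meanlog = rep_len(prey_length_meanlog, length(taxa)),
                 prey_length_sdlog = rep_len(prey_length_sdlog, length(taxa)),
                 svl_range = svl_range),
            class = "community_config")
}

method_for_class <- c(benthos = "core", nekton = "sweep",
                      zooplankton = "filter", terrestrial = "sweep")

draw_measures <- function(config, taxon_idx) {
  len <- stats::rlnorm(length(taxon_idx),
                       config$prey_length_meanlog[taxon_idx],
                       config$prey_length_sdlog[taxon_idx])
  data.frame(length_mm = len, width_mm = 0.4 * len, height_mm = NA_real_)
}

#' Simulate an environmental availability sample
#'
#' Draws `total` items multinomially from the site's availability
#' distribution, one record per item, with log-normal linear measures and
#' the sampling method implied by each taxon's habitat class (core for
#' benthos, filter for zooplankton, sweep otherwise).
#'
#' @param config a [community_config()].
#' @param site site name present in the config.
#' @param seed integer seed (required for reproducibility).
#' @param total number of items; default from `config$env_total`.
#' @return A `prey_records` table.
#' @export
generate_environment <- function(config, site, seed, total = NULL) {
  stopifnot(inherits(config, "community_config"))
  if (!site %in% names(config$availability)) stop_dn("unknown site: ", site)
  if (!missing(seed) && !is.null(seed)) set.seed(as.integer(seed))
  total <- total %||% config$env_total[[site]]
  p <- config$availability[[site]]
  counts <- as.integer(stats::rmultinom(1, total, p))
  idx <- rep(seq_along(config$taxa), counts)
  if (length(idx) == 0) {
    idx <- integer(0)
  }
  rec <- data.frame(source = "environment", site = site, pond = "P1",
                    taxon = config$taxa[idx],
                    habitat_class = unname(config$habitat_class[idx]),
                    count = 1L, stringsAsFactors = FALSE)
  rec$sampling_method <- unname(method_for_class[rec$habitat_class])
  rec <- cbind(rec, draw_measures(config, idx))
  prey_records(rec)
}

#' Simulate predators and their stomach contents
#'
#' Draws each predator's SVL uniformly within the species range, empties a
#' configured fraction of stomachs, draws per-stomach item counts from a
#' negative binomial (minimum one item in non-empty stomachs), assigns taxa
#' multinomially from the group's true utilization distribution, and injects
#' non-prey contamination (sloughed skin, plant matter, stones) at the
#' configured per-stomach rates.
#'
#' @inheritParams generate_environment
#' @param species species name present in the config for that site.
#' @return list with elements `predators` and `records`.
#' @export
generate_stomachs <- function(config, site, species, seed) {
  stopifnot(inherits(config, "community_config"))
  u <- config$utilization[[site]][[species]]
  if (is.null(u)) stop_dn("no utilization defined for ", species, " at ", site)
  if (!missing(seed) && !is.null(seed)) set.seed(as.integer(seed))
  n <- config$n_predators[[site]][[species]]
  rng <- config$svl_range[[species]] %||% c(30, 100)
  if (n == 0) {
    empty_pred <- data.frame(predator_id = character(0), species = character(0),
                             site = character(0), svl_mm = numeric(0),
                             stringsAsFactors = FALSE)
    empty_rec <- data.frame(source = character(0), site = character(0),
                            taxon = character(0), habitat_class = character(0))
    return(list(predators = predators(empty_pred),
                records = prey_records(empty_rec)))
  }
  preds_df <- data.frame(
    predator_id = sprintf("%s_%s_%03d", site, species, seq_len(n)),
    species = species, site = site, pond = "P1",
    svl_mm = stats::runif(n, rng[1], rng[2]),
    sex = sample(c("M", "F"), n, replace = TRUE),
    capture_date = "2014-08-01", stringsAsFactors = FALSE)
  empty <- stats::runif(n) < config$empty_rate
  n_items <- ifelse(empty, 0L,
                    pmax(1L, stats::rnbinom(n, size = config$items_dispersion,
                                            mu = config$items_mean)))
  idx <- unlist(lapply(n_items, function(k) {
    if (k == 0) integer(0)
    else rep(seq_along(config$taxa), stats::rmultinom(1, k, u))
  }))
  pid <- rep(preds_df$predator_id, n_items)
  rec <- data.frame(source = "stomach", site = site, pond = "P1",
                    sampling_method = "stomach_flush",
                    taxon = config$taxa[idx],
                    habitat_class = unname(config$habitat_class[idx]),
                    count = 1L, predator_id = pid,
                    digestion_flag = sample(c("fresh", "partially_digested", "digested"),
                                            length(idx), replace = TRUE,
                                            prob = c(0.2, 0.5, 0.3)),
                    stringsAsFactors = FALSE)
  rec <- cbind(rec, draw_measures(config, idx))
  contam <- lapply(names(config$contamination), function(kind) {
    hit <- stats::runif(n) < config$contamination[[kind]]
    if (!any(hit)) return(NULL)
    data.frame(source = "stomach", site = site, pond = "P1",
               sampling_method = "stomach_flush",
               taxon = kind, habitat_class = "terrestrial", count = 1L,
               predator_id = preds_df$predator_id[hit],
               digestion_flag = "unknown", non_prey_flag = kind,
               length_mm = NA_real_, width_mm = NA_real_, height_mm = NA_real_,
               stringsAsFactors = FALSE)
  })
  contam <- do.call(rbind, contam)
  if (!is.null(contam)) {
    rec$non_prey_flag <- "none"
    rec <- rbind(rec[, names(contam)], contam)
  }
  list(predators = predators(preds_df), records = prey_records(rec))
}

#' Simulate a complete two-site study and write it to disk
#'
#' Generates the environment sample and every predator group defined in the
#' config, writes `prey_records.csv` and `predators.csv`, plus `truth.json`
#' holding the true availability/utilization distributions and the true
#' pairwise overlaps per site — the ground truth against which estimated
#' profiles, electivities and overlaps can be validated.
#'
#' @inheritParams generate_environment
#' @param dir output directory (created if needed).
#' @return Invisibly, list with `prey`, `predators`, `truth` and the file
#'   paths.
#' @export
simulate_study <- function(config, dir, seed) {
  stopifnot(inherits(config, "community_config"))
  set.seed(as.integer(seed))
  prey <- list()
  preds <- list()
  for (site in names(config$availability)) {
    prey[[paste0(site, ".env")]] <-
      generate_environment(config, site, seed = NULL)
    for (sp in names(config$utilization[[site]])) {
      g <- generate_stomachs(config, site, sp, seed = NULL)
      prey[[paste(site, sp, sep = ".")]] <- g$records
      preds[[paste(site, sp, sep = ".")]] <- g$predators
    }
  }
  all_cols <- c("source", "site", "pond", "sampling_method", "taxon",
                "habitat_class", "count", "length_mm", "width_mm",
                "height_mm", "volume_mm3", "digestion_flag", "non_prey_flag",
                "predator_id")
  prey_df <- do.call(rbind, lapply(prey, function(d) {
    as.data.frame(prey_records(d))[, all_cols]
  }))
  preds_df <- do.call(rbind, lapply(preds, as.data.frame))
  rownames(prey_df) <- rownames(preds_df) <- NULL

  truth <- list(
    seed = as.integer(seed),
    availability = config$availability,
    utilization = config$utilization,
    true_overlap = lapply(names(config$utilization), function(site) {
      sp <- names(config$utilization[[site]])
      if (length(sp) < 2) return(NULL)
      pianka_overlap(config$utilization[[site]][[sp[1]]],
                     config$utilization[[site]][[sp[2]]])
    })
  )
  names(truth$true_overlap) <- names(config$utilization)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(prey = file.path(dir, "prey_records.csv"),
                predators = file.path(dir, "predators.csv"),
                truth = file.path(dir, "truth.json"))
  utils::write.csv(prey_df, paths$prey, row.names = FALSE, na = "")
  utils::write.csv(preds_df, paths$predators, row.names = FALSE, na = "")
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(prey = prey_df, predators = preds_df, truth = truth,
                 paths = paths))
}

#' A ready-made community resembling the bundled case study
#'
#' Availability and utilization vectors are set to the proportions of the
#' bundled two-site clawed-frog tables (see [xenopus_counts()]), group sizes
#' to the study's 94/111 and 89/105 stomachs, and environmental totals to
#' the study's pooled sample sizes, so the synthetic world statistically
#' resembles the case study while having fully known ground truth.
#'
#' @return A `community_config`.
#' @export
example_community_config <- function() {
  tab <- xenopus_counts()
  taxa <- tab$taxa
  col <- function(g) {
    v <- tab$N[, g]
    v[v < 0] <- 0
    v
  }
  community_config(
    taxa = taxa,
    habitat_class = unname(tab$habitat[taxa]),
    availability = list(
      CoGH = col("CoGH.environment"),
      Kleinmond = col("Kleinmond.environment")),
    utilization = list(
      CoGH = list(X_laevis = col("CoGH.X_laevis"),
                  X_gilli = col("CoGH.X_gilli")),
      Kleinmond = list(X_laevis = col("Kleinmond.X_laevis"),
                       X_gilli = col("Kleinmond.X_gilli"))),
    n_predators = list(CoGH = list(X_laevis = 94, X_gilli = 111),
                       Kleinmond = list(X_laevis = 89, X_gilli = 105)),
    env_total = list(CoGH = 2873, Kleinmond = 1723))
}
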
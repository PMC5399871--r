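#' Validate or construct a prey-record table
#'
#' A prey-record table holds one row per prey item (or per aggregated count of
#' identical items) recovered either from a predator stomach or from an
#' environmental availability sample. Mandatory columns: `source`
#' (`"stomach"`/`"environment"`), `site`, `taxon`, `habitat_class`. Optional
#' columns are filled with defaults: `pond`, `sampling_method`, `count`
#' (default 1), `length_mm`, `width_mm`, `height_mm`, `volume_mm3`,
#' `digestion_flag` (default `"unknown"`), `non_prey_flag` (default `"none"`),
#' `predator_id` (required for stomach records at table-building time).
#'
#' Non-prey items (sloughed skin, plant matter, stones) are retained in the
#' table — they are reported separately in field studies — but are never
#' counted as prey by [build_abundance_table()].
#'
#' @param df data.frame of raw records.
#' @return The validated data.frame with class `prey_records`.
#' @export
prey_records <- function(df) {
  stopifnot(is.data.frame(df))
  mandatory <- c("source", "site", "taxon", "habitat_class")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0) {
    stop_dn("prey records are missing mandatory column(s): ",
            paste(missing_cols, collapse = ", "),
            class = "dietniche_format_error")
  }
  df$pond <- as.character(df$pond %||% rep(NA_character_, nrow(df)))
  df$sampling_method <- as.character(df$sampling_method %||% rep(NA_character_, nrow(df)))
  if (is.null(df$count)) df$count <- rep(1L, nrow(df))
  df$count[is.na(df$count)] <- 1L
  for (col in c("length_mm", "width_mm", "height_mm", "volume_mm3")) {
    df[[col]] <- as.numeric(df[[col]] %||% rep(NA_real_, nrow(df)))
  }
  df$digestion_flag <- as.character(df$digestion_flag %||% rep("unknown", nrow(df)))
  df$digestion_flag[is.na(df$digestion_flag)] <- "unknown"
  df$non_prey_flag <- as.character(df$non_prey_flag %||% rep("none", nrow(df)))
  df$non_prey_flag[is.na(df$non_prey_flag)] <- "none"
  df$predator_id <- as.character(df$predator_id %||% rep(NA_character_, nrow(df)))

  rows <- seq_len(nrow(df))
  check_vocab(df$source, RECORD_SOURCES, "source", rows)
  check_vocab(df$habitat_class, HABITAT_CLASSES, "habitat_class", rows)
  check_vocab(df$sampling_method, SAMPLING_METHODS, "sampling_method", rows)
  check_vocab(df$digestion_flag, DIGESTION_FLAGS, "digestion_flag", rows)
  check_vocab(df$non_prey_flag, NON_PREY_FLAGS, "non_prey_flag", rows)

  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- is.na(cnt) | cnt < 1 | cnt != round(cnt)
  if (any(bad)) {
    stop_dn("count must be a positive integer; offending rows: ",
            paste(utils::head(rows[bad], 10), collapse = ", "),
            class = "dietniche_validation_error")
  }
  df$count <- as.integer(cnt)
  for (col in c("length_mm", "width_mm", "height_mm")) {
    bad <- !is.na(df[[col]]) & df[[col]] <= 0
    if (any(bad)) {
      stop_dn(col, " must be positive; offending rows: ",
              paste(utils::head(rows[bad], 10), collapse = ", "),
              class = "dietniche_validation_error")
    }
  }
  bad <- !is.na(df$volume_mm3) & df$volume_mm3 < 0
  if (any(bad)) {
    stop_dn("volume_mm3 must be non-negative; offending rows: ",
            paste(utils::head(rows[bad], 10), collapse = ", "),
            class = "dietniche_validation_error")
  }
  class(df) <- unique(c("prey_records", class(df)))
  df
}

#' Read prey records from CSV
#'
#' Reads a tidy comma-separated file (UTF-8, dot decimal) with one prey item
#' or aggregated count per row and validates it with [prey_records()].
#' Validation errors name the offending column or data rows (header is row 1,
#' so data row *i* is file line *i* + 1).
#'
#' @param path path to a CSV file.
#' @return A `prey_records` data.frame.
#' @export
read_prey_records <- function(path) {
  if (!file.exists(path)) stop_dn("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  prey_records(df)
}

#' Validate or construct a predator table
#'
#' One row per examined predator: `predator_id`, `species`, `site`, `svl_mm`
#' (snout-vent length, mm) are mandatory; `pond`, `sex`, `capture_date`
#' optional.
#'
#' @param df data.frame of predators.
#' @param species_vocab allowed species labels.
#' @return The validated data.frame with class `predators`.
#' @export
predators <- function(df, species_vocab = PREDATOR_SPECIES) {
  stopifnot(is.data.frame(df))
  mandatory <- c("predator_id", "species", "site", "svl_mm")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0) {
    stop_dn("predator table is missing mandatory column(s): ",
            paste(missing_cols, collapse = ", "),
            class = "dietniche_format_error")
  }
  df$predator_id <- as.character(df$predator_id)
  df$pond <- as.character(df$pond %||% rep(NA_character_, nrow(df)))
  df$sex <- as.character(df$sex %||% rep("unknown", nrow(df)))
  df$sex[is.na(df$sex)] <- "unknown"
  df$capture_date <- as.character(df$capture_date %||% rep(NA_character_, nrow(df)))
  rows <- seq_len(nrow(df))
  check_vocab(df$species, species_vocab, "species", rows)
  check_vocab(df$sex, SEX_LABELS, "sex", rows)
  df$svl_mm <- suppressWarnings(as.numeric(df$svl_mm))
  bad <- is.na(df$svl_mm) | df$svl_mm <= 0
  if (any(bad)) {
    stop_dn("svl_mm must be a positive number; offending rows: ",
            paste(utils::head(rows[bad], 10), collapse = ", "),
            class = "dietniche_validation_error")
  }
  if (anyDuplicated(df$predator_id)) {
    stop_dn("duplicated predator_id: ",
            paste(unique(df$predator_id[duplicated(df$predator_id)]), collapse = ", "),
            class = "dietniche_validation_error")
  }
  class(df) <- unique(c("predators", class(df)))
  df
}

#' @rdname predators
#' @param path path to a CSV file.
#' @export
read_predators <- function(path, species_vocab = PREDATOR_SPECIES) {
  if (!file.exists(path)) stop_dn("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  predators(df, species_vocab = species_vocab)
}

new_abundance_table <- function(taxa, groups, N, V, Freq, habitat = NULL) {
  stopifnot(!anyDuplicated(taxa))
  dimnames(N) <- dimnames(V) <- dimnames(Freq) <- list(taxa, groups$label)
  structure(list(taxa = taxa, groups = groups, N = N, V = V, Freq = Freq,
                 habitat = habitat),
            class = "abundance_table")
}

#' Build a taxon-by-group abundance table
#'
#' Aggregates prey records into the common currency of all downstream
#' statistics: per taxon and group, the total item count `N`, summed item
#' volume `V` (mm^3; computed from linear measures via [ellipsoid_volume()]
#' where not given), and `Freq`, the number of distinct predators whose
#' stomach contained the taxon. Stomach records are grouped by predator
#' `species` and `site` (plus size class when `size_scheme` is supplied);
#' environment records form one `"environment"` group per site. Non-prey
#' items never enter the table. Group labels are `site.group[.size_class]`.
#'
#' @param prey a `prey_records` table.
#' @param preds a `predators` table; required when stomach records exist.
#' @param size_scheme optional [size_class_scheme()] used to stratify stomach
#'   groups by predator size.
#' @param drop_trap_suspect drop stomach items flagged `fresh` whose taxon is
#'   in `trap_suspect_taxa` (prey likely ingested inside a baited trap rather
#'   than in the pond). Default off.
#' @param trap_suspect_taxa taxa attracted into baited traps.
#' @return An object of class `abundance_table`.
#' @export
build_abundance_table <- function(prey, preds = NULL, size_scheme = NULL,
                                  drop_trap_suspect = FALSE,
                                  trap_suspect_taxa = c("Anura")) {
  prey <- prey_records(as.data.frame(prey))
  prey <- prey[prey$non_prey_flag == "none", , drop = FALSE]
  if (drop_trap_suspect) {
    drop <- prey$source == "stomach" & prey$digestion_flag == "fresh" &
      prey$taxon %in% trap_suspect_taxa
    prey <- prey[!drop, , drop = FALSE]
  }

  stomach <- prey[prey$source == "stomach", , drop = FALSE]
  env <- prey[prey$source == "environment", , drop = FALSE]

  if (nrow(stomach) > 0) {
    if (is.null(preds)) {
      stop_dn("stomach records present but no predator table given")
    }
    preds <- predators(as.data.frame(preds))
    unknown <- setdiff(stomach$predator_id, preds$predator_id)
    if (length(unknown) > 0 || anyNA(stomach$predator_id)) {
      stop_dn("stomach records reference unknown predator ID(s): ",
              paste(utils::head(unknown, 5), collapse = ", "),
              class = "dietniche_validation_error")
    }
    idx <- match(stomach$predator_id, preds$predator_id)
    stomach$species <- preds$species[idx]
    stomach$.svl <- preds$svl_mm[idx]
    if (!is.null(size_scheme)) {
      stomach$size_class <- assign_size_class(stomach$.svl, size_scheme)
      preds$size_class <- assign_size_class(preds$svl_mm, size_scheme)
    }
  }

  group_key <- function(site, grp, size_class = NULL) {
    if (is.null(size_class)) paste(site, grp, sep = ".")
    else paste(site, grp, size_class, sep = ".")
  }

  rows <- list()
  if (nrow(stomach) > 0) {
    sc <- if (!is.null(size_scheme)) stomach$size_class else NULL
    stomach$.lab <- group_key(stomach$site, stomach$species, sc)
    rows$stomach <- stomach
  }
  if (nrow(env) > 0) {
    env$.lab <- group_key(env$site, "environment",
                          if (!is.null(size_scheme)) rep("all", nrow(env)))
    rows$env <- env
  }
  all_rec <- do.call(rbind, lapply(rows, function(d) {
    d[, c(".lab", "site", "taxon", "habitat_class", "count",
          "length_mm", "width_mm", "height_mm", "volume_mm3", "predator_id",
          "source")]
  }))
  if (is.null(all_rec) || nrow(all_rec) == 0) {
    stop_dn("no prey records to tabulate")
  }

  # volume_mm3 is per item; a row's volume contribution is volume * count
  vol <- all_rec$volume_mm3
  derivable <- is.na(vol) & !is.na(all_rec$length_mm) & !is.na(all_rec$width_mm)
  if (any(derivable)) {
    vol[derivable] <- ellipsoid_volume(all_rec$length_mm[derivable],
                                       all_rec$width_mm[derivable],
                                       all_rec$height_mm[derivable])
  }
  vol <- vol * all_rec$count
  vol[is.na(vol)] <- 0
  all_rec$.vol <- vol

  taxa <- sort(unique(all_rec$taxon))
  labels <- sort(unique(all_rec$.lab))

  Nx <- stats::xtabs(count ~ taxon + .lab, data = all_rec)[taxa, labels, drop = FALSE]
  Vx <- stats::xtabs(.vol ~ taxon + .lab, data = all_rec)[taxa, labels, drop = FALSE]
  N <- matrix(as.integer(Nx), length(taxa), length(labels))
  V <- matrix(as.numeric(Vx), length(taxa), length(labels))

  Freq <- matrix(NA_integer_, length(taxa), length(labels),
                 dimnames = list(taxa, labels))
  st <- all_rec[all_rec$source == "stomach", , drop = FALSE]
  if (nrow(st) > 0) {
    fr <- unique(st[, c("taxon", ".lab", "predator_id")])
    ftab <- as.matrix(table(factor(fr$taxon, levels = taxa),
                            factor(fr$.lab, levels = labels)))
    stomach_labs <- unique(st$.lab)
    Freq[, stomach_labs] <- ftab[, stomach_labs, drop = FALSE]
  }

  parts <- strsplit(labels, ".", fixed = TRUE)
  groups <- data.frame(
    label = labels,
    site = vapply(parts, `[`, "", 1),
    group = vapply(parts, `[`, "", 2),
    size_class = vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
  groups$n_predators <- NA_integer_
  if (nrow(stomach) > 0) {
    for (i in seq_len(nrow(groups))) {
      if (groups$group[i] == "environment") next
      sel <- preds$site == groups$site[i] & preds$species == groups$group[i]
      if (!is.na(groups$size_class[i]) && !is.null(preds$size_class)) {
        sel <- sel & !is.na(preds$size_class) & preds$size_class == groups$size_class[i]
      }
      groups$n_predators[i] <- sum(sel)
    }
  }

  hab <- tapply(all_rec$habitat_class, all_rec$taxon, function(h) h[1])
  new_abundance_table(taxa, groups, N, V, Freq, habitat = hab[taxa])
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Abundance table:", length(x$taxa), "taxa x", nrow(x$groups), "groups\n")
  cat("Groups:", paste(x$groups$label, collapse = ", "), "\n")
  cat("Total N per group:\n")
  print(colSums(x$N))
  invisible(x)
}

#' @export
as.data.frame.abundance_table <- function(x, ...) {
  long <- expand.grid(taxon = x$taxa, label = x$groups$label,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(long$label, x$groups$label)
  data.frame(
    site = x$groups$site[gi],
    group = x$groups$group[gi],
    size_class = x$groups$size_class[gi],
    taxon = long$taxon,
    habitat_class = if (is.null(x$habitat)) NA_character_ else unname(x$habitat[long$taxon]),
    N = x$N[cbind(long$taxon, long$label)],
    V = x$V[cbind(long$taxon, long$label)],
    Freq = x$Freq[cbind(long$taxon, long$label)],
    n_predators = x$groups$n_predators[gi],
    stringsAsFactors = FALSE
  )
}

#' Write / read an abundance table as CSV
#'
#' The on-disk form is the tidy long format returned by
#' [as.data.frame.abundance_table()]; a write followed by a read reproduces
#' N, V and Freq exactly.
#'
#' @param x an `abundance_table`.
#' @param path CSV path.
#' @export
write_abundance_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_abundance_table
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  abundance_table_from_long(df)
}

#' Assemble an abundance table from a tidy long data.frame
#'
#' @param df data.frame with columns `site`, `group`, `taxon`, `N`, and
#'   optionally `size_class`, `habitat_class`, `V`, `Freq`, `n_predators`.
#' @return An `abundance_table`.
#' @export
abundance_table_from_long <- function(df) {
  stopifnot(all(c("site", "group", "taxon", "N") %in% names(df)))
  df$size_class <- df$size_class %||% NA_character_
  df$V <- as.numeric(df$V %||% 0)
  df$V[is.na(df$V)] <- 0
  if (is.null(df$Freq)) df$Freq <- NA_integer_
  if (is.null(df$n_predators)) df$n_predators <- NA_integer_
  lab <- ifelse(is.na(df$size_class),
                paste(df$site, df$group, sep = "."),
                paste(df$site, df$group, df$size_class, sep = "."))
  taxa <- unique(df$taxon)
  labels <- unique(lab)
  mk <- function(col, fill = 0) {
    m <- matrix(fill, length(taxa), length(labels), dimnames = list(taxa, labels))
    m[cbind(match(df$taxon, taxa), match(lab, labels))] <- df[[col]]
    m
  }
  N <- mk("N"); storage.mode(N) <- "integer"
  V <- mk("V")
  Freq <- mk("Freq", fill = NA_integer_)
  first <- !duplicated(lab)
  groups <- data.frame(label = labels,
                       site = df$site[first][match(labels, lab[first])],
                       group = df$group[first][match(labels, lab[first])],
                       size_class = df$size_class[first][match(labels, lab[first])],
                       n_predators = as.integer(df$n_predators[first][match(labels, lab[first])]),
                       stringsAsFactors = FALSE)
  hab <- NULL
  if (!is.null(df$habitat_class)) {
    hab <- tapply(df$habitat_class, df$taxon, function(h) h[1])[taxa]
  }
  bad <- which(!is.na(Freq) & !is.na(N) & Freq > 0 &
                 rep(groups$n_predators, each = length(taxa)) < Freq)
  if (length(bad) > 0 && !all(is.na(groups$n_predators))) {
    stop_dn("Freq exceeds the number of predators in its group",
            class = "dietniche_validation_error")
  }
  new_abundance_table(taxa, groups, N, V, Freq, habitat = hab)
}

#' Extract one group's column from an abundance table
#'
#' @param x an `abundance_table`.
#' @param group a group label (either the full `site.group` label or, when
#'   unambiguous, the bare group name).
#' @param what which matrix to take the column from.
#' @return Named numeric vector over taxa.
#' @export
group_column <- function(x, group, what = c("N", "V", "Freq")) {
  what <- match.arg(what)
  lab <- resolve_group(x, group)
  m <- x[[what]][, lab, drop = FALSE]
  stats::setNames(m[, 1], rownames(m))
}

resolve_group <- function(x, group) {
  if (group %in% x$groups$label) return(group)
  hit <- x$groups$label[x$groups$group == group]
  if (length(hit) == 1) return(hit)
  stop_dn("group '", group, "' not found (or ambiguous) among: ",
          paste(x$groups$label, collapse = ", "))
}
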
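#' Controlled vocabularies
#'
#' Closed label sets used throughout the package. Habitat classes follow the
#' four-way classification standard for pond prey sampling (benthic cores,
#' nekton sweeps, filtered zooplankton, terrestrial fall-in); the remaining
#' vocabularies describe how a record was obtained and whether it is prey at
#' all.
#'
#' @format Character vectors of allowed labels.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
HABITAT_CLASSES <- c("benthos", "nekton", "zooplankton", "terrestrial")

#' @rdname vocabularies
#' @export
SAMPLING_METHODS <- c("core", "sweep", "filter", "stomach_flush", "dissection")

#' @rdname vocabularies
#' @export
DIGESTION_FLAGS <- c("fresh", "partially_digested", "digested", "unknown")

#' @rdname vocabularies
#' @export
NON_PREY_FLAGS <- c("none", "sloughed_skin", "plant_matter", "stone")

#' @rdname vocabularies
#' @export
RECORD_SOURCES <- c("stomach", "environment")

#' @rdname vocabularies
#' @export
PREDATOR_SPECIES <- c("X_laevis", "X_gilli")

#' @rdname vocabularies
#' @export
SEX_LABELS <- c("M", "F", "unknown")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dn <- function(..., class = "dietniche_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_vocab <- function(x, vocab, what, rows = NULL) {
  bad <- !is.na(x) & !(x %in% vocab)
  if (any(bad)) {
    where <- if (is.null(rows)) which(bad) else rows[bad]
    stop_dn(sprintf("invalid %s %s (rows %s); allowed: %s",
                    what,
                    paste(unique(x[bad]), collapse = ", "),
                    paste(utils::head(where, 5), collapse = ", "),
                    paste(vocab, collapse = ", ")),
            class = "dietniche_validation_error")
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Report tables round to a fixed number of decimals with ties going away
#' from zero (0.005 -> 0.01), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
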
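#' Ellipsoid prey volume from linear measures
#'
#' Estimates the volume of a prey item as a general ellipsoid
#' \deqn{V = \frac{4}{3}\pi \frac{L}{2}\frac{W}{2}\frac{H}{2}}
#' from calliper measures of length, width and (optionally) height in mm.
#' When no height was measured the item is treated as a prolate spheroid,
#' i.e. `height_mm` defaults to `width_mm`.
#'
#' @param length_mm,width_mm,height_mm positive item dimensions (mm).
#'   Vectorized; `height_mm` may be `NA` element-wise.
#' @return Volumes in mm^3.
#' @export
ellipsoid_volume <- function(length_mm, width_mm, height_mm = NULL) {
  if (is.null(height_mm)) height_mm <- rep(NA_real_, length(length_mm))
  height_mm <- ifelse(is.na(height_mm), width_mm, height_mm)
  if (any(is.na(length_mm)) || any(is.na(width_mm)) ||
      any(length_mm <= 0) || any(width_mm <= 0) || any(height_mm <= 0)) {
    stop_dn("all dimensions must be positive",
            class = "dietniche_validation_error")
  }
  (4 / 3) * pi * (length_mm / 2) * (width_mm / 2) * (height_mm / 2)
}

#' Utilization profile of a group
#'
#' Converts one group's column of an abundance table into a normalized
#' proportion vector over taxa: the diet proportions \eqn{r_i} for a predator
#' group, or the availability proportions \eqn{p_i} for an environment group.
#' Zero-count taxa are retained with proportion 0. The `"Unidentified"`
#' pseudo-taxon is excluded from both the vector and the denominator unless
#' `include_unidentified = TRUE` (identified-only proportions are the
#' reproducible convention; see the package vignette).
#'
#' @param x an `abundance_table`.
#' @param group group label (see [group_column()]).
#' @param basis `"count"` (N) or `"volume"` (V).
#' @param include_unidentified keep the `"Unidentified"` taxon in the
#'   denominator.
#' @return A named numeric vector of class `utilization_profile` summing to 1,
#'   with attributes `basis`, `group` and `denominator`.
#' @export
make_profile <- function(x, group, basis = c("count", "volume"),
                         include_unidentified = FALSE) {
  basis <- match.arg(basis)
  v <- group_column(x, group, what = if (basis == "count") "N" else "V")
  if (!include_unidentified) {
    v <- v[names(v) != "Unidentified"]
  }
  total <- sum(v)
  if (total <= 0) stop_dn("empty profile for group '", group, "'")
  structure(v / total, class = "utilization_profile",
            basis = basis, group = group, denominator = total)
}

#' @export
print.utilization_profile <- function(x, ...) {
  cat("Utilization profile for", attr(x, "group"),
      "(basis:", attr(x, "basis"),
      "; denominator:", attr(x, "denominator"), ")\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Per-habitat-class prey summary
#'
#' Tallies environmental (or dietary) records by habitat class: total item
#' count, mean per-item volume and its standard error. Items without a stored
#' or derivable volume are excluded from the volume summary (their number is
#' reported in `n_missing_volume`).
#'
#' @param records a `prey_records` table.
#' @return data.frame with one row per habitat class.
#' @export
habitat_class_summary <- function(records) {
  records <- prey_records(as.data.frame(records))
  records <- records[records$non_prey_flag == "none", , drop = FALSE]
  vol <- records$volume_mm3
  derivable <- is.na(vol) & !is.na(records$length_mm) & !is.na(records$width_mm)
  vol[derivable] <- ellipsoid_volume(records$length_mm[derivable],
                                     records$width_mm[derivable],
                                     records$height_mm[derivable])
  out <- lapply(HABITAT_CLASSES, function(cl) {
    sel <- records$habitat_class == cl
    n <- sum(records$count[sel])
    # per-item volumes, repeated for aggregated rows
    v <- rep(vol[sel], records$count[sel])
    miss <- sum(is.na(v))
    v <- v[!is.na(v)]
    data.frame(habitat_class = cl, N = n,
               mean_volume = if (length(v) > 0) mean(v) else NA_real_,
               se_volume = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n_missing_volume = miss,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  total_missing <- sum(res$n_missing_volume)
  if (total_missing > 0) {
    warning(total_missing, " item(s) without volume excluded from volume summary")
  }
  res
}
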
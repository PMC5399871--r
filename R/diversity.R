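#' Simpson diversity of a utilization profile
#'
#' Computes Simpson concentration \eqn{\lambda = \sum p_i^2} and returns
#' either the complement \eqn{1 - \lambda} (`"simpson_1mD"`, bounded in
#' \[0, 1)) or the inverse \eqn{1/\lambda} (`"simpson_inverse"`, Hill number
#' of order 2). The complement is the default: it is the form whose range
#' matches the usual "0 = no diversity" reading. Both variants are exposed
#' because the ecological literature uses the same name for either.
#'
#' @param profile a `utilization_profile` (or any non-negative vector, which
#'   is normalized first).
#' @param variant which transform of \eqn{\sum p_i^2} to report.
#' @return A `diversity_result` list with elements `index`, `value`, `group`,
#'   `k` (number of taxa with non-zero proportion).
#' @export
simpson_diversity <- function(profile, variant = c("simpson_1mD", "simpson_inverse")) {
  variant <- match.arg(variant)
  p <- as_proportions(profile)
  lambda <- sum(p^2)
  value <- if (variant == "simpson_1mD") 1 - lambda else 1 / lambda
  diversity_result(variant, value, profile, base = NA_real_)
}

#' Shannon diversity of a utilization profile
#'
#' \eqn{H' = -\sum_i p_i \log p_i}, with zero-proportion taxa contributing 0.
#' Natural log by default; base 2 or 10 switchable.
#'
#' @inheritParams simpson_diversity
#' @param base logarithm base.
#' @return A `diversity_result`.
#' @export
shannon_diversity <- function(profile, base = exp(1)) {
  p <- as_proportions(profile)
  p <- p[p > 0]
  value <- -sum(p * log(p, base = base))
  diversity_result("shannon", value, profile, base = base)
}

as_proportions <- function(profile) {
  p <- as.numeric(profile)
  if (length(p) == 0 || any(is.na(p)) || any(p < 0) || sum(p) <= 0) {
    stop_dn("profile must be a non-empty vector of non-negative proportions")
  }
  p / sum(p)
}

diversity_result <- function(index, value, profile, base) {
  structure(list(index = index, value = value,
                 base = base,
                 group = attr(profile, "group") %||% NA_character_,
                 k = sum(as.numeric(profile) > 0)),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("%s = %.4f (group %s, %d taxa)\n",
              x$index, x$value, x$group, x$k))
  invisible(x)
}

#' Diversity report over all groups of an abundance table
#'
#' @param x an `abundance_table`.
#' @param basis passed to [make_profile()].
#' @param simpson_variant,shannon_base index options.
#' @return data.frame: group, index, variant/base, value, k.
#' @export
diversity_report <- function(x, basis = "count",
                             simpson_variant = "simpson_1mD",
                             shannon_base = exp(1)) {
  rows <- lapply(x$groups$label, function(g) {
    prof <- make_profile(x, g, basis = basis)
    si <- simpson_diversity(prof, variant = simpson_variant)
    sh <- shannon_diversity(prof, base = shannon_base)
    data.frame(group = g,
               index = c(si$index, "shannon"),
               base = c(NA_real_, shannon_base),
               value = c(si$value, sh$value),
               k = c(si$k, sh$k),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
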
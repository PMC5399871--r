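#' Vanderploeg-Scavia electivity index E*
#'
#' \deqn{E^* = \frac{r - p}{r + p - 2rp}}
#' where \eqn{r} is a food category's proportion in the diet and \eqn{p} its
#' proportion in the environment. E* ranges from -1 (total avoidance)
#' through 0 (use in proportion to availability) to +1 (exclusive
#' preference). Limits: E* = 1 when \eqn{p = 0 < r}; E* = -1 when
#' \eqn{r = 0 < p}; E* = `NA` when both are 0 (the index is undefined).
#'
#' @param r,p diet and availability proportions in \[0, 1\]. Vectorized.
#' @return E* values in \[-1, 1\] (or `NA` where undefined).
#' @export
electivity_index <- function(r, p) {
  if (any(r < 0 | r > 1, na.rm = TRUE) || any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_dn("r and p must be proportions in [0, 1]",
            class = "dietniche_validation_error")
  }
  num <- r - p
  den <- r + p - 2 * r * p
  out <- ifelse(den > 0, num / den, NA_real_)
  # r == p with a zero denominator: proportional use at the boundary (r=p=1)
  out[r == p & r > 0] <- 0
  out[r == 0 & p == 0] <- NA_real_
  out
}

#' Dietary-frequency inclusion mask for electivity
#'
#' Electivity is only interpretable for taxa eaten often enough; following
#' standard practice for clawed-frog diet studies, a taxon is tested only
#' when its total dietary count summed over the given predator groups reaches
#' `min_total` (default 10). The threshold basis is configurable: summed item
#' counts (`"N"`, the default) or summed stomach occurrence (`"Freq"`).
#'
#' @param x an `abundance_table`.
#' @param diet_groups labels of the predator groups whose diets are pooled
#'   for the threshold (typically both species at one site).
#' @param min_total minimum pooled dietary total.
#' @param basis `"N"` or `"Freq"`.
#' @return Named logical vector over taxa.
#' @export
inclusion_mask <- function(x, diet_groups, min_total = 10, basis = c("N", "Freq")) {
  basis <- match.arg(basis)
  labs <- vapply(diet_groups, resolve_group, "", x = x)
  m <- x[[basis]][, labs, drop = FALSE]
  m[is.na(m)] <- 0L
  rowSums(m) >= min_total
}

#' Chi-square goodness-of-fit test of prey selection
#'
#' Tests whether observed diet counts follow the environmental availability
#' distribution. Expected counts are \eqn{E_i = n \hat p_i} with the
#' availability proportions renormalized over the tested taxa (so that
#' \eqn{\sum E_i = n}); taxa whose renormalized expectation is zero cannot be
#' tested under this model and are dropped with a warning. Pearson residuals
#' \eqn{(O_i - E_i)/\sqrt{E_i}} are returned per taxon.
#'
#' @param observed named vector of diet counts over tested taxa.
#' @param availability availability proportions (or counts; normalized) over
#'   the same taxa.
#' @return list: `statistic`, `df`, `p_value`, `expected`, `residuals`
#'   (named; `NA` for dropped taxa), `dropped` (names of untestable taxa).
#' @export
chisq_selection_test <- function(observed, availability) {
  if (length(observed) != length(availability)) {
    stop_dn("observed and availability must have the same length")
  }
  n <- sum(observed)
  if (n <= 0) stop_dn("observed counts sum to zero")
  p <- as_proportions(availability)
  res_full <- rep(NA_real_, length(observed))
  names(res_full) <- names(observed)
  keep <- p > 0
  dropped <- names(observed)[!keep]
  if (length(dropped) > 0) {
    warning("taxa with zero expected count dropped from the chi-square test: ",
            paste(dropped, collapse = ", "))
    p <- p[keep] / sum(p[keep])
  }
  o <- observed[keep]
  expected <- sum(o) * p
  resid <- (o - expected) / sqrt(expected)
  statistic <- sum(resid^2)
  df <- sum(keep) - 1
  res_full[keep] <- resid
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
       expected = expected, residuals = res_full, dropped = dropped)
}

#' Simultaneous Bonferroni confidence intervals on usage proportions
#'
#' Neu-style simultaneous intervals for \eqn{k} usage proportions at family
#' level \eqn{\alpha}: \eqn{\hat p_i \pm z_{1-\alpha/(2k)}
#' \sqrt{\hat p_i (1-\hat p_i)/n}}, clipped to \[0, 1\]. A taxon with zero
#' observed count gets the degenerate interval \[0, 0\]. Comparing each
#' availability proportion with its interval yields the selection verdict:
#' `preferred` when availability falls below the interval, `avoided` when
#' above, `proportional` otherwise.
#'
#' @param observed named vector of diet counts over tested taxa.
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame: taxon, `p_hat`, `lower`, `upper`.
#' @export
bonferroni_intervals <- function(observed, alpha = 0.05) {
  k <- length(observed)
  if (k == 0) stop_dn("no taxa to build intervals for")
  n <- sum(observed)
  if (n <= 0) stop_dn("observed counts sum to zero")
  p_hat <- observed / n
  z <- stats::qnorm(1 - alpha / (2 * k))
  half <- z * sqrt(p_hat * (1 - p_hat) / n)
  data.frame(taxon = names(observed) %||% as.character(seq_len(k)),
             p_hat = unname(p_hat),
             lower = pmax(0, unname(p_hat - half)),
             upper = pmin(1, unname(p_hat + half)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname bonferroni_intervals
#' @param availability availability proportions to compare with the intervals.
#' @param lower,upper interval bounds from [bonferroni_intervals()].
#' @export
selection_verdict <- function(availability, lower, upper) {
  ifelse(availability < lower, "preferred",
         ifelse(availability > upper, "avoided", "proportional"))
}

#' Full electivity analysis for one site
#'
#' For each predator group at a site: diet proportions r, availability
#' proportions p, E* per taxon, the pooled-frequency inclusion mask, a
#' chi-square goodness-of-fit test over the included taxa, Pearson
#' residuals, 95% simultaneous Bonferroni intervals and per-taxon selection
#' verdicts.
#'
#' @param x an `abundance_table`.
#' @param diet_groups predator group labels at the site.
#' @param env_group environment group label at the site.
#' @param min_total,threshold_basis see [inclusion_mask()].
#' @param alpha significance level for the simultaneous intervals.
#' @return An `electivity_result`: list with `taxa` (per-group data.frames)
#'   and `tests` (per-group chi-square summaries).
#' @export
electivity_analysis <- function(x, diet_groups, env_group,
                                min_total = 10,
                                threshold_basis = "N", alpha = 0.05) {
  p_env <- make_profile(x, env_group)
  mask <- inclusion_mask(x, diet_groups, min_total = min_total,
                         basis = threshold_basis)
  mask <- mask[names(p_env)]

  per_group <- list()
  tests <- list()
  for (g in diet_groups) {
    r <- make_profile(x, g)
    stopifnot(identical(names(r), names(p_env)))
    estar <- electivity_index(as.numeric(r), as.numeric(p_env))
    counts <- group_column(x, g, "N")[names(r)]

    tested <- mask & (counts > 0 | p_env > 0)
    df <- data.frame(taxon = names(r),
                     N = unname(counts),
                     r = as.numeric(r), p = as.numeric(p_env),
                     estar = ifelse(mask, estar, NA_real_),
                     included = unname(mask),
                     residual = NA_real_,
                     ci_lower = NA_real_, ci_upper = NA_real_,
                     verdict = "not_testable",
                     row.names = NULL, stringsAsFactors = FALSE)

    test_taxa <- names(r)[tested]
    if (length(test_taxa) >= 2) {
      obs <- counts[test_taxa]
      chi <- suppressWarnings(chisq_selection_test(obs, as.numeric(p_env[test_taxa])))
      ci <- bonferroni_intervals(obs, alpha = alpha)
      i <- match(test_taxa, df$taxon)
      df$residual[i] <- unname(chi$residuals[test_taxa])
      df$ci_lower[i] <- ci$lower
      df$ci_upper[i] <- ci$upper
      df$verdict[i] <- selection_verdict(as.numeric(p_env[test_taxa]),
                                         ci$lower, ci$upper)
      tests[[g]] <- data.frame(group = g, statistic = chi$statistic,
                               df = chi$df, p_value = chi$p_value,
                               k = length(test_taxa), alpha = alpha,
                               stringsAsFactors = FALSE)
    } else {
      tests[[g]] <- data.frame(group = g, statistic = NA_real_, df = NA_integer_,
                               p_value = NA_real_, k = length(test_taxa),
                               alpha = alpha, stringsAsFactors = FALSE)
    }
    per_group[[g]] <- df
  }
  structure(list(taxa = per_group, tests = do.call(rbind, tests),
                 env_group = env_group, min_total = min_total,
                 threshold_basis = threshold_basis, alpha = alpha),
            class = "electivity_result")
}

#' @export
print.electivity_result <- function(x, ...) {
  cat("Electivity analysis (min pooled dietary", x$threshold_basis, "=",
      x$min_total, ", alpha =", x$alpha, ")\n")
  print(x$tests, row.names = FALSE)
  for (g in names(x$taxa)) {
    cat("\n--", g, "--\n")
    d <- x$taxa[[g]]
    d$estar <- round(d$estar, 2)
    d$r <- round(d$r, 4); d$p <- round(d$p, 4)
    print(d[, c("taxon", "N", "r", "p", "estar", "verdict")], row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.electivity_result <- function(x, ...) {
  out <- do.call(rbind, lapply(names(x$taxa), function(g) {
    cbind(group = g, x$taxa[[g]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
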
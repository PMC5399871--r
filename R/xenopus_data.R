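#' Case-study prey-count tables for two sympatric Xenopus species
#'
#' The package ships the published site-level prey tables of a winter field
#' study of the African clawed frog (*Xenopus laevis*) and the endangered
#' Cape platanna (*Xenopus gilli*) living in sympatry at two sites in the
#' south-western Cape: the Cape of Good Hope (`"CoGH"`) and Kleinmond. For
#' each site the table holds, per prey taxon (Order level), the
#' environmental availability counts and summed volumes (pooled benthos
#' cores, nekton sweeps and zooplankton filters) and each species' diet
#' counts, summed volumes and stomach-occurrence frequencies, from 399
#' stomach-content samples in total. Habitat-class assignments are the
#' package's own Order-level classification.
#'
#' @param site `"CoGH"`, `"Kleinmond"`, or both (default) for a combined
#'   table.
#' @return An `abundance_table` with groups `<site>.environment`,
#'   `<site>.X_laevis` and `<site>.X_gilli`.
#' @examples
#' tab <- xenopus_counts("CoGH")
#' pianka_overlap(make_profile(tab, "X_laevis"), make_profile(tab, "X_gilli"))
#' @export
xenopus_counts <- function(site = c("CoGH", "Kleinmond")) {
  site <- match.arg(site, several.ok = TRUE)
  counts <- utils::read.csv(
    system.file("extdata", "xenopus_prey_counts.csv", package = "dietniche"),
    stringsAsFactors = FALSE)
  sizes <- utils::read.csv(
    system.file("extdata", "xenopus_group_sizes.csv", package = "dietniche"),
    stringsAsFactors = FALSE)
  counts <- counts[counts$site %in% site, , drop = FALSE]
  key <- paste(counts$site, counts$group)
  counts$n_predators <- sizes$n_predators[match(key, paste(sizes$site, sizes$group))]
  abundance_table_from_long(counts)
}
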
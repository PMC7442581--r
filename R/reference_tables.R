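#' Published reference confusion tables for the five-species system
#'
#' Confusion matrices (output class x target class) reported for
#' single-grain FTIR classification of the five Pooideae species under
#' each preprocessing approach and validation design, together with the
#' published integer success rates. Shipped as a plain-text fixture so
#' the success-rate arithmetic of this package can be validated against
#' reported results: `baseline_loo`, `omit_loo`, `nmf_loo`, `emsc_loo`
#' are leave-one-out PLS-DA results for the four preprocessing
#' approaches; `popsplit_plsda`, `popsplit_ann`, `popsplit_rf` are
#' independent-population results after EMSC with a paraffin constituent.
#'
#' @return named list; each element has `counts` (5 x 5 integer matrix,
#'   output x target), `published_per_class` and `published_overall`
#'   (integer percentages as reported)
#' @export
reference_confusion_tables <- function() {
  counts <- utils::read.csv(system.file("extdata",
                                        "reference_confusion_counts.csv",
                                        package = "pollenftir"))
  rates <- utils::read.csv(system.file("extdata",
                                       "reference_success_rates.csv",
                                       package = "pollenftir"))
  species <- pollen_species()
  out <- lapply(unique(counts$table), function(tb) {
    sub <- counts[counts$table == tb, ]
    m <- as.matrix(sub[match(species, sub$output_class), species])
    dimnames(m) <- list(output = species, target = species)
    r <- rates[rates$table == tb, ]
    list(counts = m,
         published_per_class = stats::setNames(
           as.integer(r[1, species]), species),
         published_overall = as.integer(r$overall[1]))
  })
  names(out) <- unique(counts$table)
  out
}
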
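#' Names of the paraffin-handling approaches
#'
#' `baseline_only` leaves the paraffin signal in place (AsLS + simple
#' EMSC + smoothing); `omit_region` cuts out 1300-1500 cm^-1;
#' `nmf` unmixes paraffin by joint non-negative factorization;
#' `emsc_paraffin` removes it with an EMSC paraffin constituent.
#' @return character vector
#' @export
approach_names <- function() {
  c("baseline_only", "omit_region", "nmf", "emsc_paraffin")
}

#' Apply one paraffin-handling approach to a pollen spectra set
#'
#' Runs the approach's preprocessing chain. When `train_mask` is given,
#' every data-driven statistic (EMSC reference spectrum, NMF components)
#' is computed from the masked training spectra only and applied to the
#' rest, so an independent-population evaluation stays honest; held-out
#' spectra are projected onto the fixed NMF components by non-negative
#' least squares. With `joint_fit = TRUE` the NMF is instead fitted on
#' all spectra jointly (the exploratory variant, which leaks test
#' information into the components and is only appropriate for
#' leave-one-out work).
#'
#' @param approach one of [approach_names()]
#' @param pollen embedded-pollen [spectra_set]
#' @param paraffin pure-paraffin [spectra_set] (needed by `nmf` and
#'   `emsc_paraffin`)
#' @param asls [asls_params()] for baseline correction
#' @param n_components,nmf_restarts,nmf_seed NMF settings
#' @param train_mask optional logical vector over pollen spectra
#' @param joint_fit fit NMF on training and held-out spectra jointly
#' @return list with `set` (the processed [spectra_set]) and
#'   approach-specific extras (`emsc_coefficients`, `nmf`, `labels`)
#' @export
apply_approach <- function(approach, pollen, paraffin = NULL,
                           asls = asls_params(), n_components = 6L,
                           nmf_restarts = 3L, nmf_seed = 1L,
                           train_mask = NULL, joint_fit = FALSE) {
  approach <- match.arg(approach, approach_names())
  stopifnot(inherits(pollen, "spectra_set"))
  if (is.null(train_mask)) train_mask <- rep(TRUE, n_spectra(pollen))
  stopifnot(length(train_mask) == n_spectra(pollen))

  if (approach == "baseline_only") {
    corrected <- asls_correct(pollen, asls)
    ref <- colMeans(corrected$spectra[train_mask, , drop = FALSE])
    fit <- emsc_fit_correct(corrected, emsc_model(ref, pollen$wavenumbers))
    return(list(set = savgol_set(fit$corrected),
                emsc_coefficients = fit$coefficients))
  }

  if (approach == "omit_region") {
    cut <- omit_region_concat(pollen, 1300, 1500, asls)
    ref <- colMeans(cut$spectra[train_mask, , drop = FALSE])
    fit <- emsc_fit_correct(cut, emsc_model(ref, cut$wavenumbers))
    return(list(set = savgol_set(fit$corrected),
                emsc_coefficients = fit$coefficients))
  }

  if (approach == "nmf") {
    stopifnot(!is.null(paraffin))
    corr <- vector_normalize_set(asls_correct(pollen, asls))
    par_corr <- vector_normalize_set(asls_correct(paraffin, asls))
    ref <- paraffin_reference(pollen$wavenumbers)
    if (all(train_mask) || joint_fit) {
      dec <- joint_nmf(corr, par_corr, k = n_components, seed = nmf_seed,
                       restarts = nmf_restarts)
      labels <- identify_paraffin_components(dec, ref)
      recon <- reconstruct_without_paraffin(dec, labels)
    } else {
      train_set <- subset_spectra(corr, train_mask)
      dec <- joint_nmf(train_set, par_corr, k = n_components,
                       seed = nmf_seed, restarts = nmf_restarts)
      labels <- identify_paraffin_components(dec, ref)
      w_test <- nmf_project(subset_spectra(corr, !train_mask), dec)
      weights <- matrix(NA_real_, n_spectra(corr), dec$k)
      weights[train_mask, ] <- dec$weights[dec$is_pollen, ]
      weights[!train_mask, ] <- w_test
      dec_all <- dec
      dec_all$weights <- weights
      dec_all$meta <- corr$meta
      dec_all$is_pollen <- rep(TRUE, n_spectra(corr))
      recon <- reconstruct_without_paraffin(dec_all, labels)
    }
    return(list(set = recon, nmf = dec, labels = labels))
  }

  # emsc_paraffin: pure paraffin spectra are reference material, the
  # pollen constituent comes from training spectra only
  stopifnot(!is.null(paraffin))
  corrected <- asls_correct(pollen, asls)
  par_const <- colMeans(asls_correct(paraffin, asls)$spectra)
  par_const <- par_const / max(par_const)
  pollen_ref <- colMeans(corrected$spectra[train_mask, , drop = FALSE])
  fit <- emsc_paraffin(corrected, pollen_ref, par_const)
  list(set = fit$corrected, emsc_coefficients = fit$coefficients)
}

#' Run the full analysis pipeline
#'
#' For every requested approach: preprocess the embedded-pollen spectra,
#' compute per-plant averages and their PCA, Ward dendrogram and
#' cluster purity, run a leave-one-out PLS-DA over individual spectra,
#' and evaluate the independent-population split with the requested
#' classifiers (preprocessing statistics refitted on the training
#' population only). A failing approach is recorded and skipped rather
#' than aborting the run.
#'
#' @param data either a [synthetic_config()] (data are generated) or a
#'   list with [spectra_set]s `embedded` and `paraffin`
#' @param approaches subset of [approach_names()]
#' @param classifiers subset of `c("plsda", "ann", "rf")` for the
#'   population split
#' @param n_lv PLS-DA latent variables
#' @param do_loo,do_popsplit toggle the two validation designs
#' @param train_population which population trains the split model
#' @param n_components NMF component count
#' @param purity_k clusters for the dendrogram purity cut (default: one
#'   per species)
#' @param seed master seed; per-stage seeds are derived as
#'   `seed + 100 * stage_counter`
#' @param out_dir optional directory for report JSON, tables and trees
#' @return a `run_report` list
#' @export
run_pipeline <- function(data,
                         approaches = approach_names(),
                         classifiers = c("plsda", "ann", "rf"),
                         n_lv = 9L, do_loo = TRUE, do_popsplit = TRUE,
                         train_population = 1L, n_components = 6L,
                         purity_k = 5L, seed = 1L, out_dir = NULL) {
  approaches <- match.arg(approaches, approach_names(),
                          several.ok = TRUE)
  if (inherits(data, "synthetic_config")) data <- generate_dataset(data)
  embedded <- data$embedded; paraffin <- data$paraffin
  stopifnot(inherits(embedded, "spectra_set"))
  stage_seed <- function(i) as.integer(seed + 100L * i)
  report <- list(config = list(approaches = approaches,
                               classifiers = classifiers, n_lv = n_lv,
                               train_population = train_population,
                               n_components = n_components, seed = seed),
                 approaches = list())
  for (ai in seq_along(approaches)) {
    ap <- approaches[ai]
    res <- tryCatch({
      proc <- apply_approach(ap, embedded, paraffin,
                             n_components = n_components,
                             nmf_seed = stage_seed(ai))
      set <- proc$set
      plant_avg <- average_by_plant(set)
      pca <- spectra_pca(plant_avg, n_pc = min(8L, n_spectra(plant_avg) - 1L))
      hca <- hca_ward(plant_avg)
      purity <- cluster_purity(hca, k = min(purity_k, n_spectra(plant_avg)))
      entry <- list(provenance = set$provenance,
                    explained_variance_pct = pca$explained_variance_pct,
                    hca_mean_purity = purity$mean_purity,
                    hca = hca)
      species <- factor(set$meta$species)
      if (do_loo) {
        cm <- full_loo_cv(set$spectra, species, n_lv)
        entry$loo <- list(confusion = cm, rates = success_rates(cm))
      }
      if (do_popsplit) {
        mask <- embedded$meta$population == train_population
        proc_split <- apply_approach(ap, embedded, paraffin,
                                     n_components = n_components,
                                     nmf_seed = stage_seed(ai) + 1L,
                                     train_mask = mask)
        sp_set <- proc_split$set
        keep <- sp_set$meta$spectrum_id
        mask2 <- embedded$meta$population[
          match(keep, embedded$meta$spectrum_id)] == train_population
        train <- subset_spectra(sp_set, mask2)
        test <- subset_spectra(sp_set, !mask2)
        entry$popsplit <- list()
        for (cl in classifiers) {
          ev <- population_split_eval(
            train, test, classifier = cl, n_lv = n_lv,
            ann = ann_config(seed = stage_seed(ai) + 2L),
            rf = rf_config(seed = stage_seed(ai) + 3L))
          entry$popsplit[[cl]] <- list(confusion = ev$confusion,
                                       rates = ev$rates)
        }
      }
      entry
    }, error = function(e) list(failed = TRUE,
                                error = conditionMessage(e)))
    report$approaches[[ap]] <- res
  }
  class(report) <- "run_report"
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' Format a report confusion matrix in Output x Target layout
#'
#' Returns the k x k counts with a "Success rate (SR)" row and an
#' "Overall SR" row of half-up-rounded integer percentages, matching the
#' layout of the published tables.
#'
#' @param report a `run_report`
#' @param which table id: `"<approach>/loo"` or
#'   `"<approach>/popsplit/<classifier>"`
#' @return data frame ready to write as CSV
#' @export
make_table <- function(report, which) {
  stopifnot(inherits(report, "run_report"))
  parts <- strsplit(which, "/", fixed = TRUE)[[1]]
  ap <- report$approaches[[parts[1]]]
  if (is.null(ap) || isTRUE(ap$failed)) stop("unknown or failed table: ",
                                             which)
  node <- if (length(parts) == 2 && parts[2] == "loo") ap$loo
          else if (length(parts) == 3 && parts[2] == "popsplit")
            ap$popsplit[[parts[3]]]
  if (is.null(node)) stop("unknown table id: ", which)
  cm <- node$confusion
  rates <- node$rates
  df <- data.frame(output_class = rownames(cm), as.data.frame(cm[, ]),
                   check.names = FALSE)
  sr <- data.frame(output_class = "Success rate (SR)",
                   t(sprintf("%d%%", rates$per_class_rounded)),
                   check.names = FALSE)
  names(sr) <- names(df)
  ov <- df[1, ]; ov[1, ] <- ""
  ov$output_class <- "Overall SR"
  ov[[2]] <- sprintf("%d%%", rates$overall_rounded)
  rbind(df, sr, ov)
}

write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "trees"), showWarnings = FALSE)
  slim <- report
  for (ap in names(slim$approaches)) {
    entry <- slim$approaches[[ap]]
    if (isTRUE(entry$failed)) next
    export_newick(entry$hca, file.path(out_dir, "trees",
                                       paste0(ap, ".nwk")))
    slim$approaches[[ap]]$hca <- NULL
    ids <- c(if (!is.null(entry$loo)) paste0(ap, "/loo"),
             if (!is.null(entry$popsplit))
               paste0(ap, "/popsplit/", names(entry$popsplit)))
    for (id in ids) {
      utils::write.csv(make_table(report, id),
                       file.path(out_dir, "tables",
                                 paste0(gsub("/", "_", id), ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(unclass_report(slim),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

unclass_report <- function(x) {
  if (is.matrix(x)) {
    return(list(dimnames = dimnames(x), counts = unclass(as.data.frame(x))))
  }
  if (is.list(x)) return(lapply(unclass(x), unclass_report))
  x
}
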
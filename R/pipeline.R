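# Cohort orchestration: run every stage over a set of patients and roll up
# the headline per-patient metrics into a cohort summary.

#' Run the full pipeline on one patient
#'
#' Architecture (presence, proportions, clonality), migration inference
#' with model selection (optionally over a tree ensemble for migration
#' probabilities), reclassification, seeding annotation, diversity,
#' duration/sufficiency, cavity summary, LOH/detection validation and
#' signature dynamics.
#'
#' @param p a `cs_patient`.
#' @param ensemble optional list of trees for migration probabilities
#'   (defaults to the patient's stored ensemble).
#' @param signature_iterations resampling iterations for small clusters
#'   (0 skips signature fitting).
#' @param seed seed for the signature resampling.
#' @param resolve resolve polytomies during migration inference.
#' @return list of stage outputs (see names).
#' @export
run_patient <- function(p, ensemble = NULL, signature_iterations = 100,
                        seed = 1L, resolve = TRUE) {
  primary <- patient_primary(p)
  tree <- p$trees[[1]]
  pres_r <- presence_matrix(p, "region")
  pres_t <- presence_matrix(p, "tumour")
  props <- infer_subclone_proportions(tree, p$ccf)
  # migration labeling sees cell-bearing (extant) subclones only
  pres_mig <- migration_presence(p, tree)
  clon <- classify_clonality(p, tree, pres_r)
  hist <- select_seeding_model(tree, pres_mig, primary, resolve = resolve)
  clon2 <- reclassify_shared(hist, clon)
  seeding <- annotate_seeding(hist, clon2, primary)
  div_snv <- diversity_matrix(p, "snv")
  het <- heterogeneity_summary(p, div_snv)
  suff <- sufficiency_threshold(p, hist, tree, pres_t)
  cav <- cavity_summary(hist, tumour_cavity(p), tumour_site(p), primary)
  validation <- if (nrow(p$segments)) validate_history(p, hist) else NULL
  prob <- if (!is.null(ensemble) && length(ensemble) > 1) {
    migration_probabilities(ensemble, pres_mig, primary)
  } else NULL
  sigs <- NULL
  if (!is.null(p$spectra) && signature_iterations > 0) {
    sigs <- signature_activity_table(p, tree, clon2,
                                     iterations = signature_iterations,
                                     seed = seed)
    aet <- aetiology_summary(sigs$activity, p$platinum_treated, clon2)
    apo <- if ("APOBEC" %in% colnames(aet$detected)) {
      detect_episodic_apobec(tree,
                             stats::setNames(aet$detected[, "APOBEC"],
                                             rownames(aet$detected)))
    } else NULL
    sigs$aetiology <- aet
    sigs$episodic_apobec <- apo
    sigs$distance <- signature_distance_report(sigs$activity, clon2)
  }
  list(patient_id = p$patient_id, history = hist, clonality = clon2,
       proportions = props, seeding = seeding, heterogeneity = het,
       sufficiency = suff, cavity = cav, validation = validation,
       probabilities = prob, signatures = sigs)
}

#' Run the pipeline over a cohort
#'
#' @param cohort list of `cs_patient` (or of `list(patient, truth)` pairs
#'   from [simulate_cohort()]), or a directory of patient subdirectories.
#' @param out_dir optional directory for per-patient TSV outputs and the
#'   cohort summary.
#' @param seed root seed; per-patient seeds are derived from it.
#' @param signature_iterations see [run_patient()].
#' @return list with `results` (per patient) and `summary` (data frame) and
#'   `rollup` (named cohort-level aggregates).
#' @export
run_pipeline <- function(cohort, out_dir = NULL, seed = 1L,
                         signature_iterations = 0) {
  if (is.character(cohort)) {
    dirs <- list.dirs(cohort, recursive = FALSE)
    cohort <- lapply(dirs, read_patient)
  }
  cohort <- lapply(cohort, function(x)
    if (inherits(x, "cs_patient")) x else x$patient)
  results <- lapply(seq_along(cohort), function(i)
    run_patient(cohort[[i]], seed = derive_seed(seed, i),
                signature_iterations = signature_iterations))
  rows <- lapply(results, function(r) {
    sb <- r$seeding$metastasis$seeded_by
    n_met <- nrow(r$seeding$metastasis)
    cls <- r$seeding$cluster
    data.frame(
      patient_id = r$patient_id,
      model = r$history$model,
      mu = r$history$mu,
      n_primary_seeders = sum(cls == "primary_to_met_seeder"),
      n_met_seeders = sum(cls == "met_to_met_seeder"),
      n_metastases = n_met,
      pct_seeded_primary = 100 * mean(sb == "primary", na.rm = TRUE),
      pct_seeded_metastasis = 100 * mean(sb == "metastasis",
                                         na.rm = TRUE),
      pct_seeded_both = 100 * mean(sb == "both", na.rm = TRUE),
      within_cavity_fraction = r$cavity$within_cavity_fraction,
      intra_primary_het = unname(r$heterogeneity["intra_primary"]),
      primary_met_het = unname(r$heterogeneity["primary_metastasis"]),
      episodic_apobec = if (!is.null(r$signatures) &&
                            !is.null(r$signatures$episodic_apobec)) {
        r$signatures$episodic_apobec$patient_flag
      } else NA,
      stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  seeded <- unlist(lapply(results, function(r)
    r$seeding$metastasis$seeded_by))
  seeded <- seeded[!is.na(seeded)]
  rollup <- c(
    n_patients = nrow(summary),
    n_metastases_seeded = length(seeded),
    pct_met_seeded_by_metastasis = 100 * mean(seeded == "metastasis"),
    pct_met_seeded_by_primary = 100 * mean(seeded == "primary"),
    pct_met_seeded_by_both = 100 * mean(seeded == "both"),
    mean_within_cavity = mean(summary$within_cavity_fraction,
                              na.rm = TRUE))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_strict(summary, file.path(out_dir, "summary.tsv"))
    jsonlite::write_json(as.list(rollup), file.path(out_dir,
                                                    "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    for (r in results) {
      pd <- file.path(out_dir, r$patient_id)
      dir.create(pd, showWarnings = FALSE)
      write_tsv_strict(r$history$migrations,
                       file.path(pd, "migrations.tsv"))
      write_tsv_strict(data.frame(cluster_id = names(r$clonality),
                                  clonality = unname(r$clonality)),
                       file.path(pd, "clonality.tsv"))
      write_tsv_strict(r$seeding$metastasis,
                       file.path(pd, "seeding.tsv"))
    }
  }
  list(results = results, summary = summary, rollup = rollup)
}

#' Seeded-by proportions across migration-probability thresholds
#'
#' Recomputes, at each threshold, the proportion of metastases whose
#' retained incoming migrations are metastasis-sourced vs primary-sourced.
#' Retained migration counts are monotone non-increasing in the threshold.
#'
#' @param prob output of [migration_probabilities()].
#' @param primary primary tumour id.
#' @param thresholds probability cutoffs.
#' @return data frame per threshold: n_retained, pct_met_seeded,
#'   pct_primary_seeded.
#' @export
threshold_sweep <- function(prob, primary,
                            thresholds = c(0, 0.25, 0.5, 0.75, 0.9, 1)) {
  rows <- lapply(thresholds, function(th) {
    sb <- seeded_by_at_threshold(prob, primary, th)
    keep <- prob$pair$probability >= th
    data.frame(threshold = th,
               n_retained = sum(keep),
               pct_met_seeded = 100 * mean(sb == "metastasis",
                                           na.rm = TRUE),
               pct_primary_seeded = 100 * mean(sb == "primary",
                                               na.rm = TRUE))
  })
  do.call(rbind, rows)
}
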
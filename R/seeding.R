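# Seeding/non-seeding classification, subclone metastatic-capacity Monte
# Carlo tests, duration-in-situ surrogates, anatomical cavity summaries and
# subclone SCNA-burden comparisons.

#' Annotate seeding subclones and seeded metastases
#'
#' Migrating clusters are classified by their migration's source tumour
#' kind (primary-to-metastasis or metastasis-to-metastasis seeders; all
#' other clusters are non-seeding). Metastases are annotated with their
#' seeding source kind (primary / metastasis / both) and whether they seed
#' other tumours. Truncal clusters keep their annotation but are excluded
#' from seeder vs non-seeder comparisons downstream.
#'
#' @param history a `cs_history`.
#' @param clonality named clonality classes (used to list all clusters).
#' @param primary primary tumour id.
#' @return list with `cluster` (named: primary_to_met_seeder /
#'   met_to_met_seeder / non_seeding) and `metastasis` (data frame
#'   tumour_id, seeded_by, seeds_others).
#' @export
annotate_seeding <- function(history, clonality, primary) {
  m <- history$migrations
  cls <- stats::setNames(rep("non_seeding", length(clonality)),
                         names(clonality))
  for (cl in unique(m$cluster)) {
    if (!cl %in% names(cls)) next
    srcs <- m$source[m$cluster == cl]
    cls[cl] <- if (any(srcs != primary)) "met_to_met_seeder" else
      "primary_to_met_seeder"
  }
  mets <- names(history$seeded_by)
  met_df <- data.frame(tumour_id = mets,
                       seeded_by = unname(history$seeded_by),
                       seeds_others = mets %in% m$source,
                       stringsAsFactors = FALSE)
  list(cluster = cls, metastasis = met_df)
}

#' Monte Carlo multinomial test of equal seeding capacity
#'
#' Tests whether subclones seeded comparable numbers of metastases under an
#' equal-probability multinomial null. The statistic is the likelihood
#' ratio G = 2 * sum o_i * ln(o_i / e_i) with e_i = n / k; the p-value is
#' (1 + #\{simulated G >= observed G\}) / (reps + 1). A maximally even count
#' vector attains the minimal G, so its p-value is exactly 1 for any seed.
#'
#' @param counts non-negative integer vector of metastases seeded per
#'   subclone (k >= 2).
#' @param reps Monte Carlo replicates (>= 1e4 recommended).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list with `p_value`, `statistic`, `counts`; `p_value` is `NA`
#'   for a single subclone.
#' @export
monte_carlo_capacity_test <- function(counts, reps = 1e5, seed) {
  if (length(counts) < 2L || sum(counts) < 1L) {
    return(list(p_value = NA_real_, statistic = NA_real_,
                counts = counts))
  }
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  k <- length(counts)
  n <- sum(counts)
  e <- n / k
  g_stat <- function(o) {
    nz <- o > 0
    2 * sum(o[nz] * log(o[nz] / e))
  }
  g_obs <- g_stat(counts)
  sim <- stats::rmultinom(reps, n, rep(1 / k, k))
  logs <- sim * log(pmax(sim, 1) / e)
  g_sim <- 2 * colSums(logs)
  p <- (1 + sum(g_sim >= g_obs - 1e-9)) / (reps + 1)
  list(p_value = p, statistic = g_obs, counts = counts)
}

#' Duration-in-situ surrogate for a metastasis
#'
#' Counts mutations and SCNA breakpoints on clusters that are private to
#' the metastasis (detected there and nowhere else) and descend from the
#' subclone(s) that seeded it; alterations accrued after seeding proxy the
#' time the metastasis has existed.
#'
#' @param metastasis tumour id.
#' @param history a `cs_history`.
#' @param tree the clone tree used for the history.
#' @param p the `cs_patient`.
#' @param presence cluster-by-tumour presence matrix.
#' @return list `n_mut`, `n_scna`; both `NA` when the seeder is unknown.
#' @export
duration_in_situ <- function(metastasis, history, tree, p, presence) {
  seeders <- unique(history$migrations$cluster[
    history$migrations$target == metastasis])
  if (!length(seeders)) return(list(n_mut = NA_real_, n_scna = NA_real_))
  desc <- unique(unlist(lapply(seeders, function(s)
    c(s, tree_descendants(tree, s)))))
  pres <- presence[intersect(desc, rownames(presence)), , drop = FALSE]
  private <- rownames(pres)[pres[, metastasis] &
                              rowSums(pres) == 1L]
  nm <- sum(p$clusters$n_mutations[p$clusters$cluster_id %in% private])
  nb <- sum(vapply(private, function(cl)
    subclone_breakpoints(p$subclone_profiles, cl), numeric(1)))
  list(n_mut = nm, n_scna = nb)
}

# breakpoints = copy-number state changes between adjacent segments of the
# same chromosome in a subclone's integer profile
subclone_breakpoints <- function(profiles, cluster_id) {
  if (is.null(profiles)) return(NA_real_)
  pr <- profiles[profiles$cluster_id == cluster_id, ]
  if (!nrow(pr)) return(NA_real_)
  pr <- pr[order(pr$chrom, pr$start), ]
  n <- 0L
  same_chrom <- pr$chrom[-1] == pr$chrom[-nrow(pr)]
  changed <- pr$cn_major[-1] != pr$cn_major[-nrow(pr)] |
    pr$cn_minor[-1] != pr$cn_minor[-nrow(pr)]
  sum(same_chrom & changed)
}

#' Patient-level sufficient-duration threshold
#'
#' For each metastasis-to-metastasis seeding subclone, the emergence count
#' is the number of mutations accumulated from the trunk to the subclone
#' (inclusive path sum). The patient threshold is the 90th percentile
#' (linear interpolation) of these emergence counts; a metastasis has had
#' sufficient time in situ for onward seeding when its total detected
#' mutation count reaches the threshold.
#'
#' @param p a `cs_patient`.
#' @param history a `cs_history`.
#' @param tree clone tree.
#' @param presence cluster-by-tumour presence matrix.
#' @param private_only count only a metastasis' private mutations instead
#'   of all detected.
#' @return list with `threshold`, `emergence_counts`, and `metastasis`
#'   (tumour_id, total_mutations, sufficient); threshold `NA` when the
#'   patient has no met-to-met seeding subclone.
#' @export
sufficiency_threshold <- function(p, history, tree, presence,
                                  private_only = FALSE) {
  primary <- patient_primary(p)
  nmut <- stats::setNames(p$clusters$n_mutations, p$clusters$cluster_id)
  mm_seeders <- unique(history$migrations$cluster[
    history$migrations$source != primary])
  emergence <- vapply(mm_seeders, function(s)
    sum(nmut[tree_path_from_root(tree, s)]), numeric(1))
  thr <- if (length(emergence)) {
    unname(stats::quantile(emergence, 0.9, type = 7))
  } else NA_real_
  mets <- setdiff(patient_tumours(p), primary)
  totals <- vapply(mets, function(m) {
    cls <- rownames(presence)[presence[, m]]
    if (private_only) {
      cls <- cls[rowSums(presence[cls, , drop = FALSE]) == 1L]
    }
    sum(nmut[cls])
  }, numeric(1))
  data_met <- data.frame(tumour_id = mets, total_mutations = totals,
                         sufficient = if (is.na(thr)) NA else
                           totals >= thr,
                         stringsAsFactors = FALSE)
  list(threshold = thr, emergence_counts = emergence,
       metastasis = data_met)
}

#' Cavity-structured seeding summary
#'
#' Cross-tabulates metastasis-to-metastasis migrations by source and
#' target anatomical cavity, reports the within-cavity fraction, flags the
#' within-organ subset, and tabulates per-site seeding prevalence.
#'
#' @param history a `cs_history` (or a data frame of migrations with
#'   source/target columns).
#' @param cavities named cavity class per tumour.
#' @param sites named anatomical site per tumour.
#' @param primary primary tumour id.
#' @return list with `table` (source_cavity x target_cavity counts),
#'   `within_cavity_fraction`, `within_organ_fraction` (of within-cavity
#'   migrations), and `site_prevalence` (per site: n metastases, n that
#'   seed).
#' @export
cavity_summary <- function(history, cavities, sites, primary) {
  m <- if (is.data.frame(history)) history else history$migrations
  mm <- unique(m[m$source != primary, c("source", "target"), drop = FALSE])
  if (!nrow(mm)) {
    lev <- c("intrathoracic", "extrathoracic")
    return(list(table = table(factor(character(0), lev),
                              factor(character(0), lev)),
                within_cavity_fraction = NA_real_,
                within_organ_fraction = NA_real_,
                site_prevalence = data.frame(site = character(0),
                                             n_metastases = integer(0),
                                             n_seeding = integer(0))))
  }
  sc <- cavities[mm$source]
  tc <- cavities[mm$target]
  lev <- c("intrathoracic", "extrathoracic")
  tab <- table(factor(sc, lev), factor(tc, lev))
  within <- sc == tc
  same_organ <- sites[mm$source] == sites[mm$target]
  met_ids <- names(cavities)[cavities != "primary"]
  site_prev <- do.call(rbind, lapply(split(met_ids, sites[met_ids]),
    function(ids) data.frame(site = unname(sites[ids[1]]),
                             n_metastases = length(ids),
                             n_seeding = sum(ids %in% m$source),
                             stringsAsFactors = FALSE)))
  rownames(site_prev) <- NULL
  list(table = tab,
       within_cavity_fraction = mean(within),
       within_organ_fraction = if (any(within))
         mean(same_organ[within]) else NA_real_,
       site_prevalence = site_prev)
}

#' Subclone SCNA-burden comparison
#'
#' Per subclone, the SCNA burden is the number of copy-number breakpoints
#' in its inferred profile and the acquisition rate is breakpoints per SNV.
#' Medians are reported for seeding vs non-seeding subclones (truncal
#' clusters excluded) and, among primary-to-metastasis seeders, for those
#' seeding intrathoracic vs extrathoracic targets. Cohort-level inference
#' uses paired Wilcoxon signed-rank tests on per-patient medians (see
#' [scna_burden_cohort_test()]), a nonparametric substitute for mixed
#' models.
#'
#' @param p a `cs_patient` with `subclone_profiles`.
#' @param annotation output of [annotate_seeding()].
#' @param history the `cs_history` (for seeding-target cavities).
#' @return data frame per subclone: cluster_id, seeding class, breakpoints,
#'   scna_per_snv, seeds_extrathoracic; plus attribute `medians`.
#' @export
scna_burden_comparison <- function(p, annotation, history) {
  if (is.null(p$subclone_profiles)) {
    stop("patient has no subclone copy-number profiles", call. = FALSE)
  }
  trunk <- p$clusters$cluster_id[p$clusters$is_trunk]
  cav <- tumour_cavity(p)
  cls <- annotation$cluster
  out <- data.frame(cluster_id = names(cls),
                    seeding_class = unname(cls),
                    stringsAsFactors = FALSE)
  out$breakpoints <- vapply(out$cluster_id, function(cl)
    subclone_breakpoints(p$subclone_profiles, cl), numeric(1))
  nm <- stats::setNames(p$clusters$n_mutations, p$clusters$cluster_id)
  out$scna_per_snv <- out$breakpoints / pmax(1, nm[out$cluster_id])
  m <- history$migrations
  out$seeds_extrathoracic <- vapply(out$cluster_id, function(cl) {
    tg <- m$target[m$cluster == cl]
    if (!length(tg)) return(NA)
    any(cav[tg] == "extrathoracic")
  }, logical(1))
  sub <- out[out$cluster_id != trunk, ]
  med <- function(x) if (length(x)) stats::median(x, na.rm = TRUE) else
    NA_real_
  medians <- c(
    seeder_bp = med(sub$breakpoints[sub$seeding_class != "non_seeding"]),
    non_seeder_bp = med(sub$breakpoints[sub$seeding_class ==
                                          "non_seeding"]),
    seeder_rate = med(sub$scna_per_snv[sub$seeding_class !=
                                         "non_seeding"]),
    non_seeder_rate = med(sub$scna_per_snv[sub$seeding_class ==
                                             "non_seeding"]),
    extrathoracic_seeder_bp = med(sub$breakpoints[
      sub$seeding_class == "primary_to_met_seeder" &
        sub$seeds_extrathoracic %in% TRUE]),
    intrathoracic_seeder_bp = med(sub$breakpoints[
      sub$seeding_class == "primary_to_met_seeder" &
        sub$seeds_extrathoracic %in% FALSE]))
  attr(out, "medians") <- medians
  out
}

#' Cohort-level paired test on per-patient burden medians
#'
#' @param reports list of [scna_burden_comparison()] outputs.
#' @param what pair of median names to compare, e.g.
#'   `c("seeder_bp", "non_seeder_bp")`.
#' @return p-value of the paired Wilcoxon signed-rank test across patients
#'   with both strata.
#' @export
scna_burden_cohort_test <- function(reports,
                                    what = c("seeder_bp",
                                             "non_seeder_bp")) {
  a <- vapply(reports, function(r) attr(r, "medians")[[what[1]]],
              numeric(1))
  b <- vapply(reports, function(r) attr(r, "medians")[[what[2]]],
              numeric(1))
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  rank_tests(a[ok], b[ok], paired = TRUE)
}
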
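# Per-subclone mutational-signature activity: constrained least-squares
# refitting onto a fixed signature set, a resampling scheme that stabilises
# small clusters by borrowing mutations from tree neighbours and
# clonality-matched clusters, aetiology grouping/prevalence/majority calls,
# episodic APOBEC detection and cosine-distance comparisons.

#' Fit signature activities to a 96-context spectrum
#'
#' Non-negative least squares of the normalised spectrum onto the signature
#' matrix; coefficients are reported as fractions of mutations (summing to
#' at most ~1, the remainder unexplained).
#'
#' @param counts 96-vector of trinucleotide-context mutation counts.
#' @param signature_matrix 96 x k matrix, columns summing to 1.
#' @param normalise_activities rescale coefficients to sum to 1 (off by
#'   default; the unexplained remainder is informative).
#' @return named activity vector with attribute `residual`.
#' @export
fit_activity <- function(counts, signature_matrix,
                         normalise_activities = FALSE) {
  stopifnot(length(counts) == nrow(signature_matrix), all(counts >= 0))
  if (sum(counts) == 0) {
    return(stats::setNames(rep(NA_real_, ncol(signature_matrix)),
                           colnames(signature_matrix)))
  }
  y <- counts / sum(counts)
  fit <- pracma::lsqnonneg(signature_matrix, y)
  act <- stats::setNames(fit$x, colnames(signature_matrix))
  if (normalise_activities && sum(act) > 0) act <- act / sum(act)
  attr(act, "residual") <- sqrt(sum((signature_matrix %*% fit$x - y)^2))
  act
}

#' Resampling-stabilised activity for a small cluster
#'
#' Clusters with at least `direct_min` mutations are fitted directly
#' (standard deviation 0). Smaller clusters are refitted over
#' `iterations` resamples: each resample draws the cluster's own number of
#' mutations with replacement from the index cluster (60%), a neighbouring
#' cluster on the tree (20%, uniform among parent and children) and a
#' cluster of matching clonality class (20%). The activity is the mean
#' across iterations; clusters whose activity standard deviation exceeds
#' 0.1 on two or more signatures are flagged excluded. Missing neighbour
#' or class-matched sources reweight the remaining sources proportionally.
#'
#' @param cluster_id index cluster.
#' @param p a `cs_patient` with `spectra` and `signature_matrix`.
#' @param tree clone tree (neighbour lookup).
#' @param clonality named clonality classes.
#' @param iterations resampling iterations.
#' @param seed RNG seed.
#' @param direct_min direct-fit mutation threshold.
#' @param neighbour_parent_only restrict the neighbour source to the
#'   parent.
#' @return list with `activity`, `sd`, `excluded`, `method`.
#' @export
resample_fit <- function(cluster_id, p, tree = p$trees[[1]],
                         clonality = NULL, iterations = 1000, seed = 1L,
                         direct_min = 50L, neighbour_parent_only = FALSE) {
  stopifnot(!is.null(p$spectra), !is.null(p$signature_matrix))
  spec <- p$spectra[, cluster_id]
  n <- sum(spec)
  if (n >= direct_min) {
    act <- fit_activity(spec, p$signature_matrix)
    return(list(activity = act,
                sd = stats::setNames(rep(0, length(act)), names(act)),
                excluded = FALSE, method = "direct"))
  }
  set.seed(seed)
  nbr <- c(if (cluster_id != tree$root) unname(tree$parent[[cluster_id]]),
           if (!neighbour_parent_only) tree_children(tree, cluster_id))
  nbr <- intersect(nbr, colnames(p$spectra))
  cls_match <- if (!is.null(clonality)) {
    same <- names(clonality)[clonality == clonality[[cluster_id]]]
    intersect(setdiff(same, cluster_id), colnames(p$spectra))
  } else character(0)
  w <- c(index = 0.6,
         neighbour = if (length(nbr)) 0.2 else 0,
         class = if (length(cls_match)) 0.2 else 0)
  if (sum(w) < 1) {
    message("missing resampling source(s) for ", cluster_id,
            "; reweighting remaining sources")
    w <- w / sum(w)
  }
  probs_index <- spec / n
  fits <- matrix(NA_real_, iterations, ncol(p$signature_matrix),
                 dimnames = list(NULL, colnames(p$signature_matrix)))
  for (it in seq_len(iterations)) {
    mix <- w[["index"]] * probs_index
    if (w[["neighbour"]] > 0) {
      src <- if (length(nbr) == 1L) nbr else sample(nbr, 1)
      sv <- p$spectra[, src]
      if (sum(sv) > 0) mix <- mix + w[["neighbour"]] * sv / sum(sv)
      else mix <- mix + w[["neighbour"]] * probs_index
    }
    if (w[["class"]] > 0) {
      src <- if (length(cls_match) == 1L) cls_match else
        sample(cls_match, 1)
      sv <- p$spectra[, src]
      if (sum(sv) > 0) mix <- mix + w[["class"]] * sv / sum(sv)
      else mix <- mix + w[["class"]] * probs_index
    }
    draw <- stats::rmultinom(1, n, mix)[, 1]
    fits[it, ] <- fit_activity(draw, p$signature_matrix)
  }
  act <- colMeans(fits)
  sds <- apply(fits, 2, stats::sd)
  list(activity = act, sd = sds, excluded = sum(sds > 0.1) >= 2L,
       method = "resampled")
}

#' Signature activities for all clusters of a patient
#'
#' @inheritParams resample_fit
#' @return list with `activity` (cluster x signature matrix), `sd`,
#'   `excluded` (named logical).
#' @export
signature_activity_table <- function(p, tree = p$trees[[1]],
                                     clonality = NULL, iterations = 200,
                                     seed = 1L, direct_min = 50L) {
  cids <- colnames(p$spectra)
  res <- lapply(seq_along(cids), function(i)
    resample_fit(cids[i], p, tree, clonality, iterations = iterations,
                 seed = derive_seed(seed, i), direct_min = direct_min))
  act <- do.call(rbind, lapply(res, function(r) r$activity))
  sds <- do.call(rbind, lapply(res, function(r) r$sd))
  rownames(act) <- rownames(sds) <- cids
  list(activity = act, sd = sds,
       excluded = stats::setNames(vapply(res, function(r) r$excluded,
                                         logical(1)), cids))
}

# aetiology groups over the NSCLC signature set
.aetiology_groups <- list(
  clock_like = c("SBS1", "SBS5"),
  smoking = "SBS4",
  APOBEC = c("SBS2", "SBS13"),
  other = "SBS17b",
  platinum = c("SBS31", "SBS35")
)

#' Aetiology-level activity, detection and majority calls
#'
#' Signature activities are grouped by aetiology (clock-like SBS1+SBS5,
#' smoking SBS4, APOBEC SBS2+SBS13, other SBS17b, platinum SBS31+SBS35;
#' platinum evaluated only for platinum-treated patients). An aetiology is
#' detected at group activity >= 0.06 and is the majority aetiology when
#' it exceeds 0.5.
#'
#' @param activity cluster x signature activity matrix.
#' @param treated_platinum was the patient treated with platinum.
#' @param clonality optional clonality classes for stratified prevalence.
#' @param detect_threshold detection cutoff (inclusive).
#' @return list with `group_activity` (cluster x aetiology), `detected`,
#'   `majority` (named; `"none"` when no group exceeds 0.5), `prevalence`
#'   (per aetiology, overall and by clonality class).
#' @export
aetiology_summary <- function(activity, treated_platinum = FALSE,
                              clonality = NULL, detect_threshold = 0.06) {
  groups <- .aetiology_groups
  if (!treated_platinum) groups$platinum <- NULL
  ga <- vapply(groups, function(sigs)
    rowSums(activity[, intersect(sigs, colnames(activity)),
                     drop = FALSE]),
    numeric(nrow(activity)))
  if (is.null(dim(ga))) ga <- matrix(ga, nrow = 1,
                                     dimnames = list(rownames(activity),
                                                     names(groups)))
  detected <- ga >= detect_threshold
  majority <- apply(ga, 1, function(v) {
    i <- which(v > 0.5)
    if (length(i)) names(v)[i[1]] else "none"
  })
  prev_overall <- colMeans(detected)
  prevalence <- data.frame(aetiology = names(prev_overall),
                           stratum = "all",
                           prevalence = unname(prev_overall),
                           stringsAsFactors = FALSE)
  if (!is.null(clonality)) {
    cl <- clonality[rownames(ga)]
    for (st in unique(cl)) {
      sel <- which(cl == st)
      prevalence <- rbind(prevalence,
        data.frame(aetiology = colnames(detected), stratum = st,
                   prevalence = colMeans(detected[sel, , drop = FALSE]),
                   stringsAsFactors = FALSE))
    }
  }
  rownames(prevalence) <- NULL
  list(group_activity = ga, detected = detected, majority = majority,
       prevalence = prevalence)
}

#' Episodic APOBEC detection along lineages
#'
#' An aetiology emerges on an edge when the parent is inactive and the
#' child active. A trunk-to-leaf lineage is episodic when (i) the trunk is
#' active and the aetiology emerges at least once later, or (ii) it emerges
#' two or more times; only inactive-to-active transitions count.
#'
#' @param tree clone tree.
#' @param active named logical: APOBEC detection call per cluster.
#' @return list with `patient_flag` and `lineages` (leaf, episodic,
#'   n_emergences, trunk_active).
#' @export
detect_episodic_apobec <- function(tree, active) {
  leaves <- tree_leaves(tree)
  rows <- lapply(leaves, function(lf) {
    path <- tree_path_from_root(tree, lf)
    a <- active[path]
    emerg <- sum(!a[-length(a)] & a[-1])
    episodic <- (a[[1]] && emerg >= 1L) || emerg >= 2L
    data.frame(leaf = lf, episodic = episodic, n_emergences = emerg,
               trunk_active = a[[1]], stringsAsFactors = FALSE)
  })
  lin <- do.call(rbind, rows)
  list(patient_flag = any(lin$episodic), lineages = lin)
}

#' Cosine-distance comparison of signature activities
#'
#' Per patient: the mean pairwise cosine distance among metastasis-unique
#' clusters versus the mean cosine distance between metastasis-unique
#' clusters and their ancestral primary clusters (truncal, shared
#' subclonal, primary-unique).
#'
#' @param activity cluster x signature activity matrix.
#' @param clonality named clonality classes.
#' @return list `met_met_mean`, `met_primary_mean` (either `NA` when a
#'   stratum is degenerate).
#' @export
signature_distance_report <- function(activity, clonality) {
  mets <- names(clonality)[clonality == "metastasis_unique"]
  anc <- names(clonality)[clonality %in% c("truncal", "shared_subclonal",
                                           "primary_unique")]
  mets <- intersect(mets, rownames(activity))
  anc <- intersect(anc, rownames(activity))
  mm <- if (length(mets) >= 2) {
    prs <- utils::combn(mets, 2)
    mean(vapply(seq_len(ncol(prs)), function(i)
      cosine_distance(activity[prs[1, i], ], activity[prs[2, i], ]),
      numeric(1)), na.rm = TRUE)
  } else NA_real_
  mp <- if (length(mets) >= 1 && length(anc) >= 1) {
    mean(outer(mets, anc, Vectorize(function(a, b)
      cosine_distance(activity[a, ], activity[b, ]))), na.rm = TRUE)
  } else NA_real_
  list(met_met_mean = mm, met_primary_mean = mp)
}
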
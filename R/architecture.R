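# Subclone architecture: presence calls, tree scoring and enumeration,
# proportion deconvolution, clonality classes, DNV calling, event timing and
# the biallelic-inactivation binomial test.

#' Mutant-read presence rule
#'
#' A cluster is called present in a region when more than one mutant read
#' supports it (any constituent mutation). With no read support available
#' the CCF > 0 fallback applies, with a warning.
#'
#' @param mutant_reads mutant-read count for the cluster in the region, or
#'   `NA` when unavailable.
#' @param ccf the cluster's CCF in the region (fallback evidence).
#' @param min_reads presence threshold; present iff reads > `min_reads - 1`,
#'   i.e. at least `min_reads`.
#' @return logical flag.
#' @export
detect_presence <- function(mutant_reads, ccf = NA_real_, min_reads = 2L) {
  if (is.na(mutant_reads)) {
    warning("no read support available; falling back to CCF > 0",
            call. = FALSE)
    return(!is.na(ccf) && ccf > 0)
  }
  mutant_reads >= min_reads
}

#' Presence matrix for a patient
#'
#' @param p a `cs_patient`.
#' @param level `"region"` or `"tumour"` (present in a tumour iff present in
#'   at least one of its regions).
#' @param min_reads presence threshold, see [detect_presence()].
#' @return logical matrix cluster x region (or cluster x tumour).
#' @export
presence_matrix <- function(p, level = c("region", "tumour"),
                            min_reads = 2L) {
  level <- match.arg(level)
  if (!is.null(p$reads)) {
    pres <- p$reads >= min_reads
  } else {
    warning("patient has no read support table; using CCF > 0",
            call. = FALSE)
    pres <- p$ccf > 0
  }
  if (level == "region") return(pres)
  tums <- patient_tumours(p)
  out <- matrix(FALSE, nrow(pres), length(tums),
                dimnames = list(rownames(pres), tums))
  for (tm in tums) {
    regs <- intersect(tumour_regions(p, tm), colnames(pres))
    out[, tm] <- apply(pres[, regs, drop = FALSE], 1, any)
  }
  out
}

#' Sum condition error of a tree topology
#'
#' For every internal node and region, children CCFs may not sum to more
#' than the parent's CCF (the pigeonhole principle); SCE totals the
#' violations: \eqn{\sum_{v,r} \max(0, \sum_{c \in ch(v)} CCF(c,r) -
#' CCF(v,r))}. Zero iff the topology satisfies the sum condition everywhere.
#'
#' @param tree a [clone_tree()].
#' @param ccf cluster-by-region CCF matrix covering the tree's nodes.
#' @return non-negative number.
#' @export
score_tree_sce <- function(tree, ccf) {
  total <- 0
  for (v in tree_nodes(tree)) {
    kids <- tree_children(tree, v)
    if (!length(kids)) next
    excess <- colSums(ccf[kids, , drop = FALSE]) - ccf[v, ]
    total <- total + sum(pmax(0, excess))
  }
  total
}

#' Enumerate admissible clone-tree topologies
#'
#' Generates every rooted tree over the clusters in which each parent's CCF
#' is at least each child's CCF in every region (the crossing rule, up to
#' tolerance `tau`), scores each by SCE and returns them sorted ascending
#' with a deterministic lexicographic-edge-list tie-break. The lowest-SCE
#' topology is the selected tree; the remainder form the ensemble used for
#' migration probabilities.
#'
#' @param ccf cluster-by-region CCF matrix; the trunk row must be named.
#' @param trunk trunk cluster id (root of every topology).
#' @param tau crossing-rule tolerance on CCF comparisons.
#' @param max_clusters combinatorial guard; more clusters than this is fatal
#'   (supply an externally built tree instead).
#' @param max_trees cap on the number of returned trees (lowest SCE kept).
#' @return list of [clone_tree()] ranked by SCE (possibly empty when no
#'   admissible topology exists, with a diagnostic message).
#' @export
enumerate_trees <- function(ccf, trunk, tau = 0.05, max_clusters = 10L,
                            max_trees = 100L) {
  cids <- rownames(ccf)
  if (length(cids) > max_clusters) {
    stop("more than ", max_clusters, " clusters; tree enumeration is ",
         "combinatorial - supply an externally reconstructed tree",
         call. = FALSE)
  }
  others <- sort(setdiff(cids, trunk))
  # crossing rule: admissible parents dominate the child in every region
  cand <- lapply(others, function(ch) {
    ok <- vapply(cids, function(pa) {
      pa != ch && all(ccf[pa, ] >= ccf[ch, ] - tau)
    }, logical(1))
    cids[ok]
  })
  names(cand) <- others
  if (any(lengths(cand) == 0)) {
    bad <- others[lengths(cand) == 0]
    message("no admissible parent for cluster(s) ",
            paste(bad, collapse = ", "),
            " (CCF exceeds every candidate, including the trunk)")
    return(list())
  }
  trees <- list()
  assign_next <- function(i, par) {
    if (i > length(others)) {
      tr <- tryCatch(clone_tree(unlist(par), root = trunk),
                     error = function(e) NULL)
      if (!is.null(tr)) trees[[length(trees) + 1L]] <<- tr
      return(invisible())
    }
    ch <- others[i]
    for (pa in cand[[ch]]) {
      par[[ch]] <- pa
      assign_next(i + 1L, par)
    }
  }
  assign_next(1L, stats::setNames(vector("list", length(others)), others))
  if (!length(trees)) {
    message("no admissible tree topology")
    return(list())
  }
  sces <- vapply(trees, score_tree_sce, numeric(1), ccf = ccf)
  keys <- vapply(trees, tree_key, character(1))
  ord <- order(sces, keys)
  trees <- trees[ord][seq_len(min(length(trees), max_trees))]
  sces <- sces[ord][seq_len(length(trees))]
  for (i in seq_along(trees)) {
    trees[[i]]$sce <- sces[i]
    trees[[i]]$rank <- i
  }
  trees
}

#' Infer subclone proportions from a clone tree
#'
#' Leaf-node CCFs are the terminal subclone proportions; internal-node
#' proportions are the node CCF minus the summed CCFs of its children,
#' iterated from the leaves to the trunk. Negative values are clipped to 0
#' and the residual recorded. Subclones with proportion <= 5% in every
#' region are flagged extinct (> 5% in at least one region = extant).
#'
#' @param tree a [clone_tree()].
#' @param ccf cluster-by-region CCF matrix.
#' @param extinct_threshold proportion at or below which a subclone is
#'   considered extinct in a region.
#' @return list with `proportion` (matrix cluster x region), `residual`
#'   (total clipped negative mass per region) and `extinct` (named logical).
#' @export
infer_subclone_proportions <- function(tree, ccf, extinct_threshold = 0.05) {
  prop <- ccf * 0
  resid <- stats::setNames(numeric(ncol(ccf)), colnames(ccf))
  for (v in tree_nodes(tree)) {
    kids <- tree_children(tree, v)
    raw <- if (length(kids)) {
      ccf[v, ] - colSums(ccf[kids, , drop = FALSE])
    } else {
      ccf[v, ]
    }
    resid <- resid + pmax(0, -raw)
    prop[v, ] <- pmax(0, raw)
  }
  extinct <- apply(prop <= extinct_threshold + 1e-9, 1, all)
  list(proportion = prop, residual = resid, extinct = extinct)
}

#' Classify cluster clonality
#'
#' The trunk is truncal; every other cluster is classified from its
#' presence aggregated to tumour kind: detected in primary regions only =
#' primary-unique, in metastases only = metastasis-unique, in both = shared
#' subclonal. Clusters detected nowhere are flagged `"undetected"` with a
#' warning and excluded from class counts.
#'
#' @param p a `cs_patient`.
#' @param tree the selected clone tree.
#' @param presence optional precomputed region-level presence matrix.
#' @return named character vector over the tree's clusters.
#' @export
classify_clonality <- function(p, tree = p$trees[[1]], presence = NULL) {
  pres <- presence %||% presence_matrix(p, level = "region")
  prim_regs <- p$samples$region_id[p$samples$tumour_kind == "primary"]
  met_regs <- p$samples$region_id[p$samples$tumour_kind == "metastasis"]
  nodes <- tree_nodes(tree)
  out <- stats::setNames(character(length(nodes)), nodes)
  trunk <- tree$root
  for (v in nodes) {
    if (v == trunk) { out[v] <- "truncal"; next }
    in_p <- any(pres[v, intersect(prim_regs, colnames(pres))])
    in_m <- any(pres[v, intersect(met_regs, colnames(pres))])
    out[v] <- if (in_p && in_m) "shared_subclonal"
      else if (in_p) "primary_unique"
      else if (in_m) "metastasis_unique"
      else "undetected"
  }
  if (any(out == "undetected")) {
    warning("cluster(s) detected nowhere: ",
            paste(names(out)[out == "undetected"], collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Call a dinucleotide variant from two adjacent SNVs
#'
#' Two criteria: (i) per sample, a two-sided two-proportion z-test (pooled
#' variance) finds no significant difference between the two SNV
#' frequencies at `alpha` (in at least one sample, or all samples with
#' `require_all_samples`); and (ii) at least 90% of reads overlapping both
#' positions carry both alternate alleles in at least one sample.
#'
#' @param snv1_alt,snv1_total,snv2_alt,snv2_total per-sample read counts.
#' @param both_variant_reads,overlapping_reads per-sample counts of reads
#'   spanning both positions and of those carrying both alternates.
#' @param alpha significance level of the proportion test.
#' @param both_fraction minimum fraction of double-alt overlapping reads.
#' @param require_all_samples require the proportion test to pass in every
#'   sample rather than any.
#' @param tost use two-one-sided equivalence testing (margin 0.1) instead of
#'   failure-to-reject.
#' @return list with `is_dnv`, per-sample `p_equal` and `both_fraction`.
#' @export
call_dnv <- function(snv1_alt, snv1_total, snv2_alt, snv2_total,
                     both_variant_reads, overlapping_reads, alpha = 0.05,
                     both_fraction = 0.9, require_all_samples = FALSE,
                     tost = FALSE) {
  stopifnot(length(snv1_alt) == length(snv2_alt))
  z_p <- function(x1, n1, x2, n2) {
    p1 <- x1 / n1; p2 <- x2 / n2
    pool <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
    if (se == 0) return(1)
    2 * stats::pnorm(-abs(p1 - p2) / se)
  }
  tost_p <- function(x1, n1, x2, n2, margin = 0.1) {
    p1 <- x1 / n1; p2 <- x2 / n2
    se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
    if (se == 0) return(0)
    pl <- stats::pnorm((p1 - p2 + margin) / se, lower.tail = FALSE)
    pu <- stats::pnorm((p1 - p2 - margin) / se)
    max(pl, pu)
  }
  p_eq <- mapply(z_p, snv1_alt, snv1_total, snv2_alt, snv2_total)
  similar <- if (tost) {
    mapply(tost_p, snv1_alt, snv1_total, snv2_alt, snv2_total) < alpha
  } else {
    p_eq > alpha
  }
  crit1 <- if (require_all_samples) all(similar) else any(similar)
  if (all(overlapping_reads == 0)) {
    warning("no overlapping reads in any sample; not a DNV", call. = FALSE)
    frac <- rep(NA_real_, length(overlapping_reads))
    return(list(is_dnv = FALSE, p_equal = p_eq, both_fraction = frac))
  }
  frac <- ifelse(overlapping_reads > 0,
                 both_variant_reads / overlapping_reads, NA_real_)
  crit2 <- any(frac >= both_fraction, na.rm = TRUE)
  list(is_dnv = crit1 && crit2, p_equal = p_eq, both_fraction = frac)
}

#' Classify the timing of an event from its cluster
#'
#' Mutations, SCNAs and WGD calls inherit the clonality class of the cluster
#' they are assigned to: truncal, shared subclonal, primary-unique or
#' metastasis-unique.
#'
#' @param cluster_id cluster carrying the event.
#' @param clonality named classification from [classify_clonality()].
#' @return the event's timing class.
#' @export
classify_event_timing <- function(cluster_id, clonality) {
  if (!cluster_id %in% names(clonality)) {
    stop("unknown cluster: ", cluster_id, call. = FALSE)
  }
  unname(clonality[[cluster_id]])
}

#' Binomial test for biallelic TSG inactivation
#'
#' Under the null hypothesis that all remaining allele copies are mutated
#' (m = CN_T in LOH regions), the expected VAF is
#' \deqn{VAF = m \cdot CCF \cdot \rho / (2(1-\rho) + CN_T \cdot \rho).}
#' The two-sided p-value is 2 x CDF when the binomial CDF at the observed
#' alt count is below 0.5, else 2 x (1 - CDF), capped at 1; Holm–Šidák
#' correction is applied across the supplied family of tests.
#'
#' Note: as printed, the decision rule calls a biallelic event when the
#' corrected p is below `alpha` in any sample, i.e. when the
#' all-copies-mutated null is rejected; `invert_call` flips the call to
#' "biallelic = null not rejected" for users who read the rule the other
#' way.
#'
#' @param rho tumour purity in (0, 1].
#' @param ccf cancer cell fraction of the mutation.
#' @param cn_t tumour copy number at the locus.
#' @param m mutation multiplicity (defaults to `cn_t`, the LOH-region null).
#' @param alt_reads,total_reads observed coverage, vectorised over samples.
#' @param alpha significance level on the corrected p-values.
#' @param invert_call see above.
#' @return list with per-sample `vaf_expected`, `p_value`, `p_adjusted` and
#'   the scalar `call` ("biallelic"/"not_biallelic").
#' @export
test_biallelic <- function(rho, ccf, cn_t, m = cn_t, alt_reads, total_reads,
                           alpha = 0.05, invert_call = FALSE) {
  stopifnot(all(rho > 0 & rho <= 1), all(alt_reads <= total_reads))
  n <- max(length(rho), length(ccf), length(cn_t), length(m),
           length(alt_reads), length(total_reads))
  rho <- rep_len(rho, n); ccf <- rep_len(ccf, n); cn_t <- rep_len(cn_t, n)
  m <- rep_len(m, n)
  alt_reads <- rep_len(alt_reads, n); total_reads <- rep_len(total_reads, n)
  vaf <- (m * ccf * rho) / (2 * (1 - rho) + cn_t * rho)
  if (any(vaf <= 0 | vaf > 1)) {
    stop("expected VAF outside (0, 1]: ",
         paste(signif(vaf[vaf <= 0 | vaf > 1], 4), collapse = ", "),
         " (check purity/CCF/copy-number inputs)", call. = FALSE)
  }
  cdf <- stats::pbinom(alt_reads, total_reads, pmin(vaf, 1))
  p <- ifelse(cdf < 0.5, 2 * cdf, 2 * (1 - cdf))
  p <- pmin(1, p)
  padj <- holm_sidak(p)
  rejected <- any(padj < alpha)
  call <- if (xor(rejected, invert_call)) "biallelic" else "not_biallelic"
  list(vaf_expected = vaf, p_value = p, p_adjusted = padj, call = call)
}
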
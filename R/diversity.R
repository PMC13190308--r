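# Pairwise genomic diversity between tumour regions: an L1 metric on
# mutation-cluster CCFs and a segment-length-weighted, ploidy-normalised L1
# metric on allele-specific fractional copy numbers; plus the four
# per-patient heterogeneity summaries built from them.

#' SNV diversity between two regions
#'
#' L1 norm between the cluster CCF vectors of two regions, each cluster term
#' weighted by its mutation count (equivalent to per-mutation CCF vectors;
#' switch off with `weight_by_mutations`). Truncal terms are included only
#' when the MRCA was inferred as the seeding subclone.
#'
#' @param ccf cluster-by-region CCF matrix.
#' @param region_a,region_b region ids (columns of `ccf`).
#' @param n_mutations named mutation counts per cluster.
#' @param trunk trunk cluster id.
#' @param mrca_seeds include the truncal cluster (TRUE when the MRCA is a
#'   seeding subclone).
#' @param weight_by_mutations weight each cluster by `n_mutations`.
#' @return non-negative number.
#' @export
snv_diversity <- function(ccf, region_a, region_b, n_mutations,
                          trunk, mrca_seeds = FALSE,
                          weight_by_mutations = TRUE) {
  cids <- rownames(ccf)
  if (!mrca_seeds) cids <- setdiff(cids, trunk)
  if (!length(cids)) return(0)
  w <- if (weight_by_mutations) as.numeric(n_mutations[cids]) else
    rep(1, length(cids))
  sum(w * abs(ccf[cids, region_a] - ccf[cids, region_b]))
}

# union segmentation of two profiles restricted to shared chromosomes
union_segments <- function(seg_a, seg_b) {
  chroms <- intersect(unique(seg_a$chrom), unique(seg_b$chrom))
  if (!length(chroms)) {
    stop("profiles share no chromosomes; SCNA diversity undefined",
         call. = FALSE)
  }
  out <- list()
  for (ch in chroms) {
    a <- seg_a[seg_a$chrom == ch, ]
    b <- seg_b[seg_b$chrom == ch, ]
    bp <- sort(unique(c(a$start, a$end, b$start, b$end)))
    if (length(bp) < 2) next
    st <- bp[-length(bp)]; en <- bp[-1]
    lookup <- function(seg, pos) {
      i <- findInterval(pos, seg$start)
      ok <- i >= 1 & pos < seg$end[pmax(i, 1)]
      list(maj = ifelse(ok, seg$cn_major[pmax(i, 1)], NA_real_),
           min = ifelse(ok, seg$cn_minor[pmax(i, 1)], NA_real_))
    }
    la <- lookup(a[order(a$start), ], st)
    lb <- lookup(b[order(b$start), ], st)
    out[[ch]] <- data.frame(chrom = ch, start = st, end = en,
                            maj_a = la$maj, min_a = la$min,
                            maj_b = lb$maj, min_b = lb$min)
  }
  do.call(rbind, out)
}

#' SCNA diversity between two regions
#'
#' Over the union segmentation of the two profiles, the segment-length-
#' weighted L1 norm of allele-specific fractional copy numbers, each
#' normalised by the sample's ploidy and rescaled to the diploid reference
#' (x2) so that a clean whole-genome doubling scores zero against its
#' undoubled parent. Major and minor alleles contribute separately by
#' default (`sum_alleles` collapses them).
#'
#' @param seg_a,seg_b segment data frames (chrom, start, end, cn_major,
#'   cn_minor) for the two regions.
#' @param ploidy_a,ploidy_b sample ploidies.
#' @param sum_alleles compare total copy number instead of per-allele.
#' @return non-negative number.
#' @export
scna_diversity <- function(seg_a, seg_b, ploidy_a, ploidy_b,
                           sum_alleles = FALSE) {
  u <- union_segments(seg_a, seg_b)
  u <- u[stats::complete.cases(u), , drop = FALSE]
  if (is.null(u) || !nrow(u)) return(NA_real_)
  len <- u$end - u$start
  w <- len / sum(len)
  ref <- 2
  if (sum_alleles) {
    d <- abs((u$maj_a + u$min_a) / ploidy_a -
             (u$maj_b + u$min_b) / ploidy_b) * ref
  } else {
    d <- (abs(u$maj_a / ploidy_a - u$maj_b / ploidy_b) +
          abs(u$min_a / ploidy_a - u$min_b / ploidy_b)) * ref
  }
  sum(w * d)
}

#' Pairwise diversity matrix for a patient
#'
#' @param p a `cs_patient`.
#' @param metric `"snv"` or `"scna"`.
#' @param mrca_seeds include truncal terms in the SNV metric.
#' @return data frame (region_a, region_b, value), one row per unordered
#'   region pair.
#' @export
diversity_matrix <- function(p, metric = c("snv", "scna"),
                             mrca_seeds = FALSE) {
  metric <- match.arg(metric)
  regs <- p$samples$region_id
  trunk <- p$clusters$cluster_id[p$clusters$is_trunk]
  nm <- stats::setNames(p$clusters$n_mutations, p$clusters$cluster_id)
  pl <- stats::setNames(p$samples$ploidy, p$samples$region_id)
  rows <- list()
  for (i in seq_along(regs)) {
    for (j in seq_len(i - 1L)) {
      a <- regs[j]; b <- regs[i]
      v <- if (metric == "snv") {
        snv_diversity(p$ccf, a, b, nm, trunk, mrca_seeds = mrca_seeds)
      } else {
        sa <- p$segments[p$segments$region_id == a, ]
        sb <- p$segments[p$segments$region_id == b, ]
        if (!nrow(sa) || !nrow(sb)) NA_real_ else
          scna_diversity(sa, sb, pl[[a]], pl[[b]])
      }
      rows[[length(rows) + 1L]] <- data.frame(region_a = a, region_b = b,
                                              value = v)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region_a = character(0), region_b = character(0),
               value = numeric(0))
  attr(out, "metric") <- metric
  out
}

#' Per-patient heterogeneity summaries
#'
#' Four means over the pairwise diversity values: intra-primary (pairs of
#' primary regions), intra-metastasis (pairs of regions within one
#' metastasis), inter-metastasis (pairs of anatomically distinct metastases,
#' multi-region metastases aggregated by the mean over their region pairs)
#' and primary–metastasis (primary region x metastasis pairs). Summaries
#' whose preconditions fail (e.g. a single primary region) are `NA`, never
#' zero.
#'
#' @param p a `cs_patient`.
#' @param div output of [diversity_matrix()].
#' @return named numeric vector of the four summaries.
#' @export
heterogeneity_summary <- function(p, div) {
  s <- p$samples
  tum <- stats::setNames(s$tumour_id, s$region_id)
  kind <- stats::setNames(s$tumour_kind, s$region_id)
  ka <- kind[div$region_a]; kb <- kind[div$region_b]
  ta <- tum[div$region_a]; tb <- tum[div$region_b]

  mean_or_na <- function(v) if (length(v)) mean(v, na.rm = TRUE) else NA_real_

  intra_primary <- mean_or_na(div$value[ka == "primary" & kb == "primary"])
  intra_met <- mean_or_na(div$value[ka == "metastasis" & kb == "metastasis" &
                                      ta == tb])
  # metastasis-level values: mean over cross-region pairs per tumour pair
  mm <- div[ka == "metastasis" & kb == "metastasis" & ta != tb, ,
            drop = FALSE]
  inter_met <- if (nrow(mm)) {
    key <- paste(pmin(ta[ka == "metastasis" & kb == "metastasis" & ta != tb],
                      tb[ka == "metastasis" & kb == "metastasis" & ta != tb]),
                 pmax(ta[ka == "metastasis" & kb == "metastasis" & ta != tb],
                      tb[ka == "metastasis" & kb == "metastasis" & ta != tb]))
    mean_or_na(tapply(mm$value, key, mean, na.rm = TRUE))
  } else NA_real_
  pm <- div[(ka == "primary") != (kb == "primary"), , drop = FALSE]
  primary_met <- if (nrow(pm)) {
    met_t <- ifelse(kind[pm$region_a] == "metastasis",
                    tum[pm$region_a], tum[pm$region_b])
    prim_r <- ifelse(kind[pm$region_a] == "primary",
                     pm$region_a, pm$region_b)
    mean_or_na(tapply(pm$value, paste(prim_r, met_t), mean, na.rm = TRUE))
  } else NA_real_

  c(intra_primary = intra_primary, intra_metastasis = intra_met,
    inter_metastasis = inter_met, primary_metastasis = primary_met)
}
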
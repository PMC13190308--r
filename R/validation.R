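# Orthogonal validation of inferred migrations: conserved-LOH
# directionality (LOH is irreversible, so LOH clonal in the seeding tumour
# must be present in the seeded one) and radiological detection-time
# consistency (a tumour cannot be detected before its seeding source).

#' Clonal LOH segments of a region
#'
#' Observed fractional allele copy numbers are adjusted for normal-cell
#' admixture, assuming contaminating cells contribute one copy per allele:
#' adjusted = (observed - (1 - rho)) / rho. A segment has clonal LOH when
#' the adjusted copy number of an allele falls below 0.1.
#'
#' @param segments one region's segment rows (chrom, start, end, cn_major,
#'   cn_minor).
#' @param purity tumour purity rho in (0, 1].
#' @param threshold purity-adjusted copy-number cutoff.
#' @return data frame (chrom, start, end, allele, adjusted_cn) of clonal
#'   LOH segments; alleles are `"minor"`/`"major"`.
#' @export
clonal_loh_segments <- function(segments, purity, threshold = 0.1) {
  stopifnot(purity > 0, purity <= 1)
  adjust <- function(cn) {
    adj <- (cn - (1 - purity)) / purity
    if (any(adj < -0.5)) {
      warning(sum(adj < -0.5), " adjusted copy number(s) < -0.5 ",
              "(purity inconsistent); clipped to 0", call. = FALSE)
    }
    pmax(adj, 0)
  }
  adj_min <- adjust(segments$cn_minor)
  adj_maj <- adjust(segments$cn_major)
  out <- rbind(
    data.frame(chrom = segments$chrom, start = segments$start,
               end = segments$end, allele = "minor",
               adjusted_cn = adj_min,
               stringsAsFactors = FALSE)[adj_min < threshold, ],
    data.frame(chrom = segments$chrom, start = segments$start,
               end = segments$end, allele = "major",
               adjusted_cn = adj_maj,
               stringsAsFactors = FALSE)[adj_maj < threshold, ])
  rownames(out) <- NULL
  out
}

loh_keys <- function(loh) {
  if (!nrow(loh)) return(character(0))
  unique(paste(loh$chrom, loh$start, loh$end, loh$allele, sep = ":"))
}

#' Fraction of source LOH conserved in a target
#'
#' Of the segments with clonal LOH in the source (the putative seeding
#' tumour), the fraction also showing clonal LOH of the same allele in the
#' target. Allele identity is required: loss of opposite parental alleles
#' (mirrored allelic imbalance) is non-conserved. The denominator is the
#' source's clonal LOH set; an empty denominator yields `NA`.
#'
#' @param source_loh,target_loh outputs of [clonal_loh_segments()] on the
#'   union segmentation.
#' @return fraction in \[0, 1\], or `NA`.
#' @export
conserved_loh_fraction <- function(source_loh, target_loh) {
  src <- loh_keys(source_loh)
  if (!length(src)) return(NA_real_)
  tgt <- loh_keys(target_loh)
  sum(src %in% tgt) / length(src)
}

#' Radiological first-detection record for a tumour
#'
#' First detection is the earliest scan listing the tumour. Tumours never
#' detected on imaging but sampled at autopsy are assigned the midpoint of
#' the last scan and the date of death. The scan period normalises scan
#' days between the relapse scan and death: detection on the relapse scan
#' is its own category, <= 50% of the interval is the first half, > 50%
#' the second half, and midpoint-imputed detections are autopsy-only.
#'
#' @param tumour_id tumour to look up.
#' @param scans data frame (scan_day, tumour_id), `NA` tumour_id rows mark
#'   scans with no detection.
#' @param death_day day of death (days since surgery).
#' @return list with `first_detection_day` and `period`, or `NULL` when no
#'   scans exist.
#' @export
assign_detection <- function(tumour_id, scans, death_day) {
  if (is.null(scans) || !nrow(scans)) return(NULL)
  scans <- scans[order(scans$scan_day), ]
  relapse_day <- min(scans$scan_day)
  last_scan <- max(scans$scan_day)
  hit <- scans$scan_day[!is.na(scans$tumour_id) &
                          scans$tumour_id == tumour_id]
  if (length(hit)) {
    day <- min(hit)
    period <- if (day <= relapse_day) {
      "relapse_scan"
    } else {
      denom <- death_day - relapse_day
      frac <- if (denom > 0) (day - relapse_day) / denom else 0
      if (frac <= 0.5) "first_half" else "second_half"
    }
  } else {
    day <- (last_scan + death_day) / 2
    period <- "autopsy_only"
  }
  list(tumour_id = tumour_id, first_detection_day = day, period = period)
}

#' Detection table for all metastases of a patient
#'
#' @param p a `cs_patient`.
#' @return data frame (tumour_id, first_detection_day, period).
#' @export
detection_table <- function(p) {
  mets <- setdiff(patient_tumours(p), patient_primary(p))
  recs <- lapply(mets, assign_detection, scans = p$scans,
                 death_day = p$dates$death_day)
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) {
    return(data.frame(tumour_id = character(0),
                      first_detection_day = numeric(0),
                      period = character(0)))
  }
  do.call(rbind, lapply(recs, as.data.frame))
}

# per-tumour clonal LOH on the shared segmentation, intersected across the
# tumour's regions (clonal = present in all cancer cells of every region)
tumour_loh_sets <- function(p, threshold = 0.1) {
  tums <- patient_tumours(p)
  out <- list()
  for (tm in tums) {
    regs <- tumour_regions(p, tm)
    keysets <- lapply(regs, function(r) {
      seg <- p$segments[p$segments$region_id == r, ]
      if (!nrow(seg)) return(NULL)
      rho <- p$samples$purity[p$samples$region_id == r]
      loh_keys(clonal_loh_segments(seg, rho, threshold))
    })
    keysets <- keysets[!vapply(keysets, is.null, logical(1))]
    out[[tm]] <- if (length(keysets)) Reduce(intersect, keysets) else
      character(0)
  }
  out
}

#' Validate a migration history against LOH and detection times
#'
#' For every inferred metastasis-to-metastasis pair the conserved-LOH
#' fraction of the inferred source is compared with (i) the primary as the
#' alternative source and (ii) every other metastasis as alternative source
#' (Mann–Whitney across pairs). Detection-day distributions of primary- vs
#' metastasis-seeded tumours are compared the same way. Pairs in which the
#' source carries clonal LOH absent from the target are flagged: the
#' migrating cell must have carried every LOH clonal in its tumour of
#' origin, so such non-conserved events are incompatible with the route.
#'
#' @param p a `cs_patient` with segments and scans.
#' @param history a `cs_history`.
#' @param threshold purity-adjusted LOH cutoff.
#' @return list with `pair_table`, `p_inferred_vs_primary`,
#'   `p_inferred_vs_alternatives`, `detection`, `p_detection`.
#' @export
validate_history <- function(p, history, threshold = 0.1) {
  if (!nrow(p$segments)) {
    stop("patient has no segment profiles; LOH validation impossible",
         call. = FALSE)
  }
  primary <- patient_primary(p)
  sets <- tumour_loh_sets(p, threshold)
  as_loh <- function(keys) {
    if (!length(keys)) {
      return(data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), allele = character(0)))
    }
    parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
    data.frame(chrom = parts[, 1], start = as.numeric(parts[, 2]),
               end = as.numeric(parts[, 3]), allele = parts[, 4],
               stringsAsFactors = FALSE)
  }
  mm <- history$migrations[history$migrations$source != primary, ,
                           drop = FALSE]
  mm <- unique(mm[, c("source", "target")])
  rows <- list()
  for (i in seq_len(nrow(mm))) {
    src <- mm$source[i]; tgt <- mm$target[i]
    f_inf <- conserved_loh_fraction(as_loh(sets[[src]]),
                                    as_loh(sets[[tgt]]))
    f_pri <- conserved_loh_fraction(as_loh(sets[[primary]]),
                                    as_loh(sets[[tgt]]))
    alts <- setdiff(names(sets), c(src, tgt, primary))
    f_alt <- vapply(alts, function(a)
      conserved_loh_fraction(as_loh(sets[[a]]), as_loh(sets[[tgt]])),
      numeric(1))
    non_conserved <- length(setdiff(sets[[src]], sets[[tgt]]))
    rows[[i]] <- data.frame(source = src, target = tgt,
                            conserved_inferred = f_inf,
                            conserved_primary_source = f_pri,
                            conserved_alt_mean =
                              if (length(f_alt)) mean(f_alt, na.rm = TRUE)
                              else NA_real_,
                            n_non_conserved = non_conserved,
                            stringsAsFactors = FALSE)
  }
  pair_table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(0), target = character(0),
               conserved_inferred = numeric(0),
               conserved_primary_source = numeric(0),
               conserved_alt_mean = numeric(0),
               n_non_conserved = integer(0))
  p_vs_pri <- if (nrow(pair_table) >= 1) {
    rank_tests(pair_table$conserved_inferred,
               pair_table$conserved_primary_source, paired = TRUE)
  } else NA_real_
  p_vs_alt <- if (nrow(pair_table) >= 1) {
    rank_tests(pair_table$conserved_inferred,
               pair_table$conserved_alt_mean, paired = TRUE)
  } else NA_real_

  det <- detection_table(p)
  det$seeded_by <- history$seeded_by[det$tumour_id]
  p_det <- rank_tests(det$first_detection_day[det$seeded_by == "primary"],
                      det$first_detection_day[det$seeded_by ==
                                                "metastasis"])
  list(pair_table = pair_table,
       p_inferred_vs_primary = p_vs_pri,
       p_inferred_vs_alternatives = p_vs_alt,
       detection = det, p_detection = p_det)
}
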
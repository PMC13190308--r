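# The Patient container: everything the pipeline knows about one case.
#
# Fields:
#   patient_id        character scalar
#   samples           data.frame(region_id, tumour_id, tumour_kind,
#                     anatomical_site, cavity, purity, ploidy, collection)
#   clusters          data.frame(cluster_id, n_mutations, is_trunk)
#   ccf               numeric matrix [cluster x region], values in [0, 1.5]
#   reads             integer matrix [cluster x region] of mutant-read
#                     support, or NULL (CCF>0 fallback used downstream)
#   trees             list of cs_tree, ranked by SCE (rank 1 first)
#   segments          data.frame(region_id, chrom, start, end, cn_major,
#                     cn_minor); 0-based half-open coordinates
#   subclone_profiles data.frame(cluster_id, chrom, start, end, cn_major,
#                     cn_minor) or NULL
#   spectra           numeric matrix [96 x cluster] of trinucleotide-context
#                     mutation counts, or NULL
#   signature_matrix  numeric matrix [96 x signature], columns sum to 1,
#                     or NULL
#   events            data.frame(gene, kind, cluster_id)
#   wgd               character vector of cluster ids carrying a WGD
#   scans             data.frame(scan_day, tumour_id) long format; a scan
#                     with no detections has one row with tumour_id NA
#   dates             list(surgery_day, relapse_day, death_day)
#   platinum_treated  logical flag

#' Construct a Patient
#'
#' Assembles and validates the complete per-patient input bundle consumed by
#' every downstream stage. All cross-references (region ids, cluster ids,
#' tumour ids) are checked; CCF values above the clipping ceiling are clipped
#' with a warning.
#'
#' @param patient_id identifier.
#' @param samples data frame of sampled regions (see Details in the package
#'   vignette for the schema).
#' @param clusters data frame with `cluster_id`, `n_mutations`, `is_trunk`.
#' @param ccf cluster-by-region CCF matrix.
#' @param trees list of [clone_tree()] objects, lowest SCE first.
#' @param segments allele-specific fractional copy-number segments.
#' @param reads,subclone_profiles,spectra,signature_matrix,events,wgd,scans
#'   optional components, `NULL`/empty when absent.
#' @param dates list with `surgery_day`, `relapse_day`, `death_day` (days,
#'   surgery = 0 reference; NA when unobserved).
#' @param platinum_treated was the patient treated with platinum chemotherapy.
#' @param ccf_ceiling CCF clipping threshold (noisy estimates may exceed 1).
#' @return an object of class `cs_patient`.
#' @export
patient <- function(patient_id, samples, clusters, ccf, trees = list(),
                    segments = NULL, reads = NULL, subclone_profiles = NULL,
                    spectra = NULL, signature_matrix = NULL, events = NULL,
                    wgd = character(0), scans = NULL,
                    dates = list(surgery_day = 0, relapse_day = NA_real_,
                                 death_day = NA_real_),
                    platinum_treated = FALSE, ccf_ceiling = 1.5) {
  if (is.null(segments)) {
    segments <- data.frame(region_id = character(0), chrom = character(0),
                           start = numeric(0), end = numeric(0),
                           cn_major = numeric(0), cn_minor = numeric(0),
                           stringsAsFactors = FALSE)
  }
  if (is.null(events)) {
    events <- data.frame(gene = character(0), kind = character(0),
                         cluster_id = character(0), stringsAsFactors = FALSE)
  }
  over <- ccf > ccf_ceiling
  if (any(over, na.rm = TRUE)) {
    warning(sum(over, na.rm = TRUE), " CCF value(s) above ", ccf_ceiling,
            " clipped", call. = FALSE)
    ccf[which(over)] <- ccf_ceiling
  }
  p <- structure(list(patient_id = patient_id, samples = samples,
                      clusters = clusters, ccf = ccf, reads = reads,
                      trees = trees, segments = segments,
                      subclone_profiles = subclone_profiles,
                      spectra = spectra, signature_matrix = signature_matrix,
                      events = events, wgd = wgd, scans = scans,
                      dates = dates, platinum_treated = platinum_treated),
                 class = "cs_patient")
  validate_patient(p)
  p
}

#' Validate a Patient's invariants
#'
#' Checks purity/ploidy ranges, uniqueness of the primary tumour and trunk
#' cluster, consistency of all cross-references, segment ordering, and date
#' ordering. Fatal on any violation, naming the offending ids.
#'
#' @param p a `cs_patient`.
#' @return `p`, invisibly.
#' @export
validate_patient <- function(p) {
  s <- p$samples
  req <- c("region_id", "tumour_id", "tumour_kind", "anatomical_site",
           "cavity", "purity", "ploidy", "collection")
  miss <- setdiff(req, names(s))
  if (length(miss)) stop("samples lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(s$region_id)) stop("duplicate region_id", call. = FALSE)
  if (any(s$purity <= 0 | s$purity > 1)) {
    stop("purity must be in (0, 1] for region(s): ",
         paste(s$region_id[s$purity <= 0 | s$purity > 1], collapse = ", "),
         call. = FALSE)
  }
  if (any(s$ploidy <= 0)) stop("ploidy must be > 0", call. = FALSE)
  prim <- unique(s$tumour_id[s$tumour_kind == "primary"])
  if (length(prim) != 1L) {
    stop("exactly one primary tumour required, found ", length(prim),
         call. = FALSE)
  }
  cl <- p$clusters
  if (sum(cl$is_trunk) != 1L) {
    stop("exactly one trunk cluster required", call. = FALSE)
  }
  if (!identical(sort(rownames(p$ccf)), sort(cl$cluster_id))) {
    stop("ccf matrix rows must match cluster ids", call. = FALSE)
  }
  bad_reg <- setdiff(colnames(p$ccf), s$region_id)
  if (length(bad_reg)) {
    stop("ccf references unknown region_id: ",
         paste(bad_reg, collapse = ", "), call. = FALSE)
  }
  if (any(p$ccf < 0, na.rm = TRUE)) stop("negative CCF", call. = FALSE)
  for (tr in p$trees) {
    extra <- setdiff(tree_nodes(tr), cl$cluster_id)
    if (length(extra)) {
      stop("tree references unknown cluster_id: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  seg <- p$segments
  if (nrow(seg)) {
    bad <- setdiff(unique(seg$region_id), s$region_id)
    if (length(bad)) {
      stop("segments reference unknown region_id: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(seg$end <= seg$start)) {
      stop("segment end must exceed start", call. = FALSE)
    }
    if (any(seg$cn_minor > seg$cn_major + 1e-9)) {
      stop("cn_major must be >= cn_minor", call. = FALSE)
    }
    if (any(seg$cn_minor < 0)) stop("negative copy number", call. = FALSE)
    # non-overlap within (region, chrom)
    o <- order(seg$region_id, seg$chrom, seg$start)
    so <- seg[o, ]
    same <- so$region_id[-1] == so$region_id[-nrow(so)] &
      so$chrom[-1] == so$chrom[-nrow(so)]
    if (any(same & so$start[-1] < so$end[-nrow(so)])) {
      stop("overlapping segments within a region", call. = FALSE)
    }
  }
  if (nrow(p$events)) {
    bad <- setdiff(p$events$cluster_id, cl$cluster_id)
    if (length(bad)) {
      stop("events reference unknown cluster_id: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  bad <- setdiff(p$wgd, cl$cluster_id)
  if (length(bad)) {
    stop("wgd calls reference unknown cluster_id: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(p$scans) && nrow(p$scans)) {
    known <- unique(s$tumour_id)
    bad <- setdiff(stats::na.omit(p$scans$tumour_id), known)
    if (length(bad)) {
      stop("scans reference unknown tumour_id: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  d <- p$dates
  ds <- c(d$surgery_day, d$relapse_day, d$death_day)
  ds <- ds[!is.na(ds)]
  if (is.unsorted(ds)) {
    stop("dates must satisfy surgery <= relapse <= death", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.cs_patient <- function(x, ...) {
  nmet <- length(unique(x$samples$tumour_id[x$samples$tumour_kind ==
                                              "metastasis"]))
  cat("<patient ", x$patient_id, "> ", nrow(x$samples), " regions (",
      sum(x$samples$tumour_kind == "primary"), " primary, ", nmet,
      " metastases), ", nrow(x$clusters), " clusters, ",
      length(x$trees), " tree(s)\n", sep = "")
  invisible(x)
}

#' Tumour-level lookups on a patient
#'
#' `patient_primary()` returns the primary tumour id, `patient_tumours()`
#' all tumour ids, `tumour_regions()` the regions of one tumour, and
#' `tumour_cavity()`/`tumour_site()` named per-tumour cavity classes and
#' anatomical sites.
#'
#' @param p a `cs_patient`.
#' @param tumour_id tumour to look up.
#' @return character vector(s) as described.
#' @export
patient_primary <- function(p) {
  unique(p$samples$tumour_id[p$samples$tumour_kind == "primary"])
}

#' @rdname patient_primary
#' @export
patient_tumours <- function(p) unique(p$samples$tumour_id)

#' @rdname patient_primary
#' @export
tumour_regions <- function(p, tumour_id) {
  p$samples$region_id[p$samples$tumour_id == tumour_id]
}

#' @rdname patient_primary
#' @export
tumour_cavity <- function(p) {
  s <- p$samples[!duplicated(p$samples$tumour_id), ]
  stats::setNames(s$cavity, s$tumour_id)
}

#' @rdname patient_primary
#' @export
tumour_site <- function(p) {
  s <- p$samples[!duplicated(p$samples$tumour_id), ]
  stats::setNames(s$anatomical_site, s$tumour_id)
}
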
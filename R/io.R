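# On-disk patient format.
#
# A patient directory contains (tab-delimited, header mandatory, '.' = NA):
#   samples.tsv   region_id tumour_id tumour_kind anatomical_site cavity
#                 purity ploidy collection
#   clusters.tsv  cluster_id region_id ccf n_mutations  (long; n_mutations
#                 repeated per cluster)
#   segments.tsv  region_id chrom start end cn_major cn_minor   (0-based
#                 half-open; a 1-based dialect converts on read)
#   events.tsv    gene kind cluster_id
#   scans.tsv     scan_day tumour_id
#   reads.tsv     cluster_id region_id mutant_reads            [optional]
#   spectra.tsv   context <one column per cluster>             [optional]
#   signatures.tsv context <one column per signature>          [optional]
#   subclone_profiles.tsv cluster_id chrom start end cn_major cn_minor [opt]
#   tree.json     {"trees":[{"root":..,"edges":[[parent,child],..],
#                 "sce":..,"rank":..},..]}
#   patient.json  patient_id, dates, wgd, platinum_treated

#' Read a patient directory
#'
#' Reads the documented TSV/JSON file set and returns a fully
#' cross-validated [patient()]. Fatal on missing files, dangling references
#' (the offending ids are named) and malformed numerics (the line number is
#' named).
#'
#' @param dir path to the patient directory.
#' @param coordinates `"bed"` (0-based half-open, the native convention) or
#'   `"one_based"` (converted on read by subtracting 1 from starts).
#' @return a `cs_patient`.
#' @export
read_patient <- function(dir, coordinates = c("bed", "one_based")) {
  coordinates <- match.arg(coordinates)
  fp <- function(f) file.path(dir, f)
  samples <- read_tsv_strict(fp("samples.tsv"),
                             list(purity = "numeric", ploidy = "numeric"))
  clusters_long <- read_tsv_strict(fp("clusters.tsv"),
                                   list(ccf = "numeric",
                                        n_mutations = "integer"))
  bad <- setdiff(unique(clusters_long$region_id), samples$region_id)
  if (length(bad)) {
    stop("clusters.tsv references unknown region_id: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cids <- unique(clusters_long$cluster_id)
  rids <- samples$region_id
  ccf <- matrix(NA_real_, length(cids), length(rids),
                dimnames = list(cids, rids))
  ccf[cbind(clusters_long$cluster_id, clusters_long$region_id)] <-
    clusters_long$ccf
  ccf[is.na(ccf)] <- 0
  nmut <- clusters_long[!duplicated(clusters_long$cluster_id),
                        c("cluster_id", "n_mutations")]

  tj <- jsonlite::read_json(fp("tree.json"))
  trees <- lapply(tj$trees, function(t) {
    edges <- do.call(rbind, lapply(t$edges, unlist))
    par <- if (is.null(edges)) stats::setNames(character(0), character(0))
           else stats::setNames(edges[, 1], edges[, 2])
    clone_tree(par, root = t$root, sce = t$sce %||% NA_real_,
               rank = as.integer(t$rank %||% NA_integer_))
  })
  pj <- jsonlite::read_json(fp("patient.json"), simplifyVector = TRUE)
  trunk_id <- if (length(trees)) trees[[1]]$root else pj$trunk %||% cids[1]
  clusters <- data.frame(cluster_id = nmut$cluster_id,
                         n_mutations = nmut$n_mutations,
                         is_trunk = nmut$cluster_id == trunk_id,
                         stringsAsFactors = FALSE)

  segments <- read_tsv_strict(fp("segments.tsv"),
                              list(start = "numeric", end = "numeric",
                                   cn_major = "numeric",
                                   cn_minor = "numeric"))
  if (nrow(segments) && coordinates == "one_based") {
    segments$start <- segments$start - 1
  }
  events <- read_tsv_strict(fp("events.tsv"))
  scans <- read_tsv_strict(fp("scans.tsv"), list(scan_day = "numeric"))

  reads <- NULL
  if (file.exists(fp("reads.tsv"))) {
    rl <- read_tsv_strict(fp("reads.tsv"), list(mutant_reads = "integer"))
    reads <- matrix(0L, length(cids), length(rids),
                    dimnames = list(cids, rids))
    reads[cbind(rl$cluster_id, rl$region_id)] <- rl$mutant_reads
  }
  read_matrix_tsv <- function(path) {
    df <- read_tsv_strict(path)
    m <- as.matrix(df[, -1, drop = FALSE])
    mode(m) <- "numeric"
    rownames(m) <- df[[1]]
    m
  }
  spectra <- if (file.exists(fp("spectra.tsv")))
    read_matrix_tsv(fp("spectra.tsv")) else NULL
  sig <- if (file.exists(fp("signatures.tsv")))
    read_matrix_tsv(fp("signatures.tsv")) else NULL
  profiles <- if (file.exists(fp("subclone_profiles.tsv")))
    read_tsv_strict(fp("subclone_profiles.tsv"),
                    list(start = "numeric", end = "numeric",
                         cn_major = "numeric", cn_minor = "numeric"))
    else NULL

  patient(patient_id = pj$patient_id, samples = samples,
          clusters = clusters, ccf = ccf, trees = trees,
          segments = segments, reads = reads,
          subclone_profiles = profiles, spectra = spectra,
          signature_matrix = sig, events = events,
          wgd = as.character(pj$wgd %||% character(0)),
          scans = scans,
          dates = list(surgery_day = pj$dates$surgery_day %||% 0,
                       relapse_day = pj$dates$relapse_day %||% NA_real_,
                       death_day = pj$dates$death_day %||% NA_real_),
          platinum_treated = isTRUE(pj$platinum_treated))
}

#' Write a patient directory
#'
#' Inverse of [read_patient()]: emits the documented file set so that
#' read-then-write is the identity.
#'
#' @param p a `cs_patient`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_patient <- function(p, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_tsv_strict(p$samples, fp("samples.tsv"))
  cl <- expand.grid(cluster_id = rownames(p$ccf),
                    region_id = colnames(p$ccf),
                    stringsAsFactors = FALSE)
  cl$ccf <- p$ccf[cbind(cl$cluster_id, cl$region_id)]
  cl$n_mutations <- p$clusters$n_mutations[
    match(cl$cluster_id, p$clusters$cluster_id)]
  cl <- cl[order(cl$cluster_id, cl$region_id), ]
  write_tsv_strict(cl, fp("clusters.tsv"))
  write_tsv_strict(p$segments, fp("segments.tsv"))
  write_tsv_strict(p$events, fp("events.tsv"))
  write_tsv_strict(p$scans %||%
                     data.frame(scan_day = numeric(0),
                                tumour_id = character(0)),
                   fp("scans.tsv"))
  if (!is.null(p$reads)) {
    rl <- expand.grid(cluster_id = rownames(p$reads),
                      region_id = colnames(p$reads),
                      stringsAsFactors = FALSE)
    rl$mutant_reads <- p$reads[cbind(rl$cluster_id, rl$region_id)]
    rl <- rl[order(rl$cluster_id, rl$region_id), ]
    write_tsv_strict(rl, fp("reads.tsv"))
  }
  write_matrix_tsv <- function(m, path, key) {
    df <- data.frame(m[, , drop = FALSE], check.names = FALSE)
    df <- cbind(stats::setNames(data.frame(rownames(m)), key), df)
    write_tsv_strict(df, path)
  }
  if (!is.null(p$spectra)) {
    write_matrix_tsv(p$spectra, fp("spectra.tsv"), "context")
  }
  if (!is.null(p$signature_matrix)) {
    write_matrix_tsv(p$signature_matrix, fp("signatures.tsv"), "context")
  }
  if (!is.null(p$subclone_profiles)) {
    write_tsv_strict(p$subclone_profiles, fp("subclone_profiles.tsv"))
  }
  trees <- lapply(p$trees, function(t) {
    e <- tree_edges(t)
    list(root = t$root,
         edges = lapply(seq_len(nrow(e)),
                        function(i) as.list(unname(e[i, ]))),
         sce = t$sce, rank = t$rank)
  })
  jsonlite::write_json(list(trees = trees), fp("tree.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(list(patient_id = p$patient_id, dates = p$dates,
                            wgd = p$wgd,
                            platinum_treated = p$platinum_treated,
                            trunk = p$clusters$cluster_id[p$clusters$is_trunk]),
                       fp("patient.json"), auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(dir)
}
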
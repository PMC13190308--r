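# Small hand-built fixtures shared across test files.

# A minimal two-tumour patient: primary P (2 regions) and metastasis M1
# (1 region), four clusters in a chain/fork, exact CCFs.
tiny_patient <- function() {
  samples <- data.frame(
    region_id = c("P_R1", "P_R2", "M1_R1"),
    tumour_id = c("P", "P", "M1"),
    tumour_kind = c("primary", "primary", "metastasis"),
    anatomical_site = c("lung", "lung", "liver"),
    cavity = c("primary", "primary", "extrathoracic"),
    purity = c(0.6, 0.5, 0.7),
    ploidy = c(2, 2, 2),
    collection = c("surgery", "surgery", "autopsy"),
    stringsAsFactors = FALSE)
  clusters <- data.frame(
    cluster_id = c("T", "A", "B", "C"),
    n_mutations = c(10L, 6L, 4L, 5L),
    is_trunk = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  ccf <- rbind(T = c(1, 1, 1),
               A = c(0.6, 0.5, 0),
               B = c(0.3, 0.2, 0),
               C = c(0, 0, 0.8))
  colnames(ccf) <- samples$region_id
  reads <- (ccf > 0) * 10L
  mode(reads) <- "integer"
  tree <- clone_tree(c(A = "T", B = "A", C = "T"), root = "T")
  segments <- do.call(rbind, lapply(samples$region_id, function(r)
    data.frame(region_id = r, chrom = c("chr1", "chr1"),
               start = c(0, 50), end = c(50, 100),
               cn_major = c(1, 1), cn_minor = c(1, 1),
               stringsAsFactors = FALSE)))
  scans <- data.frame(scan_day = c(200, 260, 320),
                      tumour_id = c(NA, "M1", "M1"),
                      stringsAsFactors = FALSE)
  patient(patient_id = "TINY", samples = samples, clusters = clusters,
          ccf = ccf, reads = reads, trees = list(tree),
          segments = segments, scans = scans,
          dates = list(surgery_day = 0, relapse_day = 200,
                       death_day = 400))
}

# small noise-free simulated patient, memoised per seed for speed
sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed, ...) {
  key <- paste(seed, ..., sep = "_")
  if (!is.null(sim_cache[[key]])) return(sim_cache[[key]])
  cfg <- simulation_config(seed = seed, n_clusters = c(6, 12),
                           n_metastases = c(2, 5), ccf_noise_sd = 0, ...)
  sim_cache[[key]] <- simulate_patient(cfg)
  sim_cache[[key]]
}
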
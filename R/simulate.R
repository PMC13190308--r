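# Synthetic cohort generator.
#
# Emulates the data structure of a multi-region primary + autopsy-metastasis
# WES cohort: a clone tree grown by uniform attachment, tumours colonised by
# migrating subclones under one of three seeding regimes, per-region CCFs
# implied by terminal subclone proportions (stick-breaking along the tree)
# with optional truncated-normal noise, irreversible clonal LOH accumulated
# along branches, per-cluster mutational-signature activities with optional
# episodic APOBEC, and radiological first-detection times with an
# exponential post-seeding latency. Every patient is returned together with
# its ground truth so each pipeline stage has a recovery test.

#' Simulation configuration
#'
#' Defaults are the package's desk-scale rendering of the cohort structure:
#' 2-8 primary regions, 2-12 anatomically labelled metastases (the full
#' cohort range of up to 37 is reachable via this field), 10-20 mutation
#' clusters (cohort range up to 60), 60% of metastasis seedings originating
#' in another metastasis, and a 30% chance that a migration exits to an
#' extrathoracic site.
#'
#' @param seed integer seed driving every random draw for the patient.
#' @param n_primary_regions integer range `c(lo, hi)`.
#' @param n_metastases integer range.
#' @param n_clusters integer range.
#' @param seeding_model `"primary_only"`, `"single_source"` or
#'   `"multi_source"`.
#' @param fraction_met_to_met probability that a metastasis is seeded from
#'   an existing metastasis rather than the primary.
#' @param ccf_noise_sd truncated-normal CCF noise (0 = noise-free).
#' @param mean_mutations_per_cluster Poisson mean of mutations per cluster.
#' @param loh_rate_per_branch Poisson mean of LOH events per branch.
#' @param p_extrathoracic_exit probability a metastasis site is
#'   extrathoracic.
#' @param signature_set SBS signature ids simulated.
#' @param episodic_apobec simulate APOBEC bursts that switch on along
#'   lineages.
#' @return a `cs_sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_primary_regions = c(2L, 8L),
                              n_metastases = c(2L, 12L),
                              n_clusters = c(10L, 20L),
                              seeding_model = c("single_source",
                                                "multi_source",
                                                "primary_only"),
                              fraction_met_to_met = 0.6,
                              ccf_noise_sd = 0.05,
                              mean_mutations_per_cluster = 50,
                              loh_rate_per_branch = 0.5,
                              p_extrathoracic_exit = 0.3,
                              signature_set = c("SBS1", "SBS5", "SBS4",
                                                "SBS2", "SBS13", "SBS17b",
                                                "SBS31", "SBS35"),
                              episodic_apobec = TRUE) {
  seeding_model <- match.arg(seeding_model)
  rng_ok <- function(r) length(r) == 2L && r[1] <= r[2] && r[1] >= 1L
  stopifnot(rng_ok(n_primary_regions), rng_ok(n_metastases),
            rng_ok(n_clusters),
            fraction_met_to_met >= 0, fraction_met_to_met <= 1,
            ccf_noise_sd >= 0, mean_mutations_per_cluster > 0,
            loh_rate_per_branch >= 0,
            p_extrathoracic_exit >= 0, p_extrathoracic_exit <= 1)
  if (seeding_model == "primary_only" && fraction_met_to_met > 0) {
    stop("fraction_met_to_met > 0 is infeasible under primary_only",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_primary_regions = as.integer(n_primary_regions),
                 n_metastases = as.integer(n_metastases),
                 n_clusters = as.integer(n_clusters),
                 seeding_model = seeding_model,
                 fraction_met_to_met = fraction_met_to_met,
                 ccf_noise_sd = ccf_noise_sd,
                 mean_mutations_per_cluster = mean_mutations_per_cluster,
                 loh_rate_per_branch = loh_rate_per_branch,
                 p_extrathoracic_exit = p_extrathoracic_exit,
                 signature_set = signature_set,
                 episodic_apobec = episodic_apobec),
            class = "cs_sim_config")
}

#' Synthetic SBS signature matrix
#'
#' A deterministic, synthetic stand-in for a COSMIC-style 96-context
#' signature matrix (it is not the COSMIC catalogue): each signature is a
#' sparse random profile over the 96 trinucleotide contexts, columns sum
#' to 1. The same ids always produce the same matrix.
#'
#' @param signature_ids column names.
#' @return 96 x length(signature_ids) matrix.
#' @export
synthetic_signature_matrix <- function(signature_ids) {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  grid <- expand.grid(five = bases, three = bases, sub = subs,
                      stringsAsFactors = FALSE)
  ctx <- sort(paste0(grid$five, "[", grid$sub, "]", grid$three))
  m <- matrix(0, 96, length(signature_ids),
              dimnames = list(ctx, signature_ids))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  for (j in seq_along(signature_ids)) {
    # deterministic per-signature profile, independent of the global RNG
    sid <- sum(utf8ToInt(signature_ids[j]) *
                 seq_along(utf8ToInt(signature_ids[j])))
    set.seed(20000 + sid)
    w <- stats::rexp(96)^3   # sparse-ish peaks
    m[, j] <- w / sum(w)
  }
  m
}

# non-qualifier metastasis sites by cavity
.sim_sites <- list(
  intrathoracic = c("lung", "mediastinal lymph node",
                    "mediastinal soft tissue", "pleura"),
  extrathoracic = c("liver", "brain", "bone", "adrenal gland",
                    "axillary lymph node", "cervical lymph node",
                    "kidney", "soft tissue", "gastric", "peritoneum")
)

# Stick-breaking terminal proportions over a tumour's cell-bearing clones.
# `cells` is the set of clones with surviving cells in the tumour; roots of
# the restricted forest (clones whose parent bears no cells there, i.e. the
# founders) split the tumour's mass by a Dirichlet draw, and each clone
# keeps 20-50% of the mass entering its subtree. Ancestors outside `cells`
# get zero terminal proportion (their mutations are clonal, their pure
# populations are gone).
sim_proportions <- function(tree, cells) {
  prop <- stats::setNames(numeric(length(cells)), cells)
  rec <- function(node, mass) {
    kids <- intersect(tree_children(tree, node), cells)
    if (!length(kids)) {
      prop[node] <<- mass
      return(invisible())
    }
    keep <- mass * stats::runif(1, 0.2, 0.5)
    prop[node] <<- keep
    w <- stats::rgamma(length(kids), shape = 2)
    w <- w / sum(w)
    for (i in seq_along(kids)) rec(kids[i], (mass - keep) * w[i])
  }
  roots <- cells[!vapply(cells, function(c)
    c != tree$root && unname(tree$parent[[c]]) %in% cells, logical(1))]
  if (length(roots) == 1L) {
    rec(roots, 1)
  } else {
    w <- stats::rgamma(length(roots), shape = 2)
    w <- w / sum(w)
    for (i in seq_along(roots)) rec(roots[i], w[i])
  }
  prop
}

#' Simulate one patient with ground truth
#'
#' @param config a [simulation_config()].
#' @param patient_id identifier for the emitted patient.
#' @return list with `patient` (a `cs_patient`) and `truth` (list with
#'   `tree`, `proportions` (cluster x region), `migrations` (source,
#'   target, cluster), `seeded_by`, `loh_history`, `signature_activity`,
#'   `detection_day`, `present` (cluster x tumour logical)).
#' @export
simulate_patient <- function(config, patient_id = "SIM1") {
  set.seed(config$seed)
  ri <- function(rng) if (rng[1] == rng[2]) rng[1] else
    sample(seq(rng[1], rng[2]), 1)
  n_preg <- ri(config$n_primary_regions)
  n_met <- ri(config$n_metastases)
  n_clu <- ri(config$n_clusters)

  primary <- "P"
  mets <- paste0("M", seq_len(n_met))
  tumours <- c(primary, mets)
  cav <- c(primary = "primary")
  sites <- c(primary = "lung")
  for (m in mets) {
    extra <- stats::runif(1) < config$p_extrathoracic_exit
    cv <- if (extra) "extrathoracic" else "intrathoracic"
    cav[m] <- cv
    sites[m] <- sample(.sim_sites[[cv]], 1)
  }

  # --- clone tree growth coupled with tumour colonisation ---------------
  cl_counter <- 1L
  new_cluster <- function() {
    cl_counter <<- cl_counter + 1L
    paste0("C", cl_counter)
  }
  trunk <- "C1"
  parent <- stats::setNames(character(0), character(0))
  present <- list()   # tumour -> clusters whose mutations are detectable
  cells <- list()     # tumour -> clusters with surviving cell populations
  present[[primary]] <- trunk
  cells[[primary]] <- trunk
  home <- c(C1 = primary)

  grow_in <- function(tumour, occult = FALSE) {
    anc <- cells[[tumour]]
    # in metastases, new subclones preferentially arise from the expanding
    # met-private populations rather than the primary-shared founder pool
    w <- rep(1, length(anc))
    if (tumour != primary) {
      w[!anc %in% cells[[primary]]] <- 3
    }
    pa <- if (length(anc) == 1L) anc else sample(anc, 1, prob = w)
    id <- new_cluster()
    parent[id] <<- pa
    home[id] <<- tumour
    if (!occult) {
      present[[tumour]] <<- c(present[[tumour]], id)
      cells[[tumour]] <<- c(cells[[tumour]], id)
    }
    id
  }

  n_early <- max(2L, round(n_clu * 0.35))
  while (cl_counter < n_early) grow_in(primary)

  ancestors_of <- function(cl) {
    path <- cl
    while (cl != trunk) {
      cl <- unname(parent[[cl]])
      path <- c(path, cl)
    }
    path
  }

  migrations <- list()
  seed_order <- mets   # seeded sequentially
  for (m in seed_order) {
    use_met_source <- config$seeding_model != "primary_only" &&
      stats::runif(1) < config$fraction_met_to_met &&
      length(setdiff(names(present), c(primary, m))) > 0
    src <- if (use_met_source) {
      cand <- setdiff(names(present), c(primary, m))
      if (length(cand) == 1L) cand else sample(cand, 1)
    } else primary
    pick_seeder <- function(src) {
      if (cl_counter < n_clu && stats::runif(1) < 0.8) {
        # a new subclone of the source seeds. Primary founders are often
        # occult: the primary was resected before metastatic relapse, so
        # the minor subclone that seeded is frequently below detection in
        # the resected specimen.
        occ <- src == primary && stats::runif(1) < 0.5
        grow_in(src, occult = occ)
      } else if (src == primary) {
        # an existing primary subclone seeds again (multi-target capacity)
        cand <- setdiff(cells[[primary]], trunk)
        if (!length(cand)) grow_in(src) else
          if (length(cand) == 1L) cand else sample(cand, 1)
      } else {
        # onward seeding re-uses a subclone only when it is unique to the
        # source; a clone shared with other tumours leaves no record of
        # which tumour it physically departed from, so multi-target
        # capacity of metastases arises through descendants instead
        others <- setdiff(names(cells), src)
        elsewhere <- unique(unlist(cells[others]))
        cand <- setdiff(cells[[src]], c(trunk, elsewhere))
        if (!length(cand)) grow_in(src) else
          if (length(cand) == 1L) cand else sample(cand, 1)
      }
    }
    seed_into <- function(m, src) {
      s <- pick_seeder(src)
      present[[m]] <<- unique(c(present[[m]], ancestors_of(s)))
      cells[[m]] <<- unique(c(cells[[m]], s))
      migrations[[length(migrations) + 1L]] <<-
        data.frame(source = src, target = m, cluster = s,
                   stringsAsFactors = FALSE)
      s
    }
    s1 <- seed_into(m, src)
    # polyclonal seeding: a second subclone co-migrates from the same
    # source in about a quarter of seedings (cohort-scale prevalence)
    if (cl_counter < n_clu && stats::runif(1) < 0.25) {
      seed_into(m, src)
    }
    if (config$seeding_model == "multi_source" &&
        stats::runif(1) < 0.15) {
      cand_src <- setdiff(names(present), c(m, src))
      if (length(cand_src)) {
        src2 <- if (length(cand_src) == 1L) cand_src else
          sample(cand_src, 1)
        seed_into(m, src2)
      }
    }
  }
  # remaining clusters are private to a uniformly chosen tumour
  while (cl_counter < n_clu) {
    tm <- sample(tumours, 1)
    if (is.null(present[[tm]])) next
    grow_in(tm)
  }
  migrations <- do.call(rbind, migrations)
  clusters_all <- paste0("C", seq_len(cl_counter))
  tree <- clone_tree(parent, root = trunk, rank = 1L)

  # --- regions, proportions, CCFs --------------------------------------
  n_regions <- c(n_preg, sample(1:3, n_met, replace = TRUE))
  names(n_regions) <- tumours
  samples <- do.call(rbind, lapply(tumours, function(tm) {
    k <- n_regions[[tm]]
    data.frame(region_id = paste0(tm, "_R", seq_len(k)),
               tumour_id = tm,
               tumour_kind = if (tm == primary) "primary" else "metastasis",
               anatomical_site = unname(sites[tm]),
               cavity = unname(cav[tm]),
               purity = round(stats::runif(k, 0.3, 0.95), 3),
               ploidy = 2,
               collection = if (tm == primary) "surgery" else "autopsy",
               stringsAsFactors = FALSE)
  }))
  regions <- samples$region_id
  true_prop <- matrix(0, length(clusters_all), length(regions),
                      dimnames = list(clusters_all, regions))
  for (tm in tumours) {
    for (r in samples$region_id[samples$tumour_id == tm]) {
      pr <- sim_proportions(tree, cells[[tm]])
      true_prop[names(pr), r] <- pr
    }
  }
  # CCF = proportion of the cluster plus all descendants present
  ccf_true <- true_prop * 0
  post <- tree_postorder(tree)
  for (v in post) {
    kids <- tree_children(tree, v)
    ccf_true[v, ] <- true_prop[v, ] +
      if (length(kids)) colSums(ccf_true[kids, , drop = FALSE]) else 0
  }
  ccf <- ccf_true
  if (config$ccf_noise_sd > 0) {
    noise <- matrix(stats::rnorm(length(ccf), 0, config$ccf_noise_sd),
                    nrow(ccf))
    ccf <- pmin(pmax(ccf + noise * (ccf_true > 0), 0), 1.5)
  }
  reads <- matrix(0L, nrow(ccf), ncol(ccf), dimnames = dimnames(ccf))
  reads[ccf_true > 0] <- pmax(2L, as.integer(round(ccf[ccf_true > 0] * 60)))

  n_mut <- stats::setNames(pmax(1L, stats::rpois(
    length(clusters_all), config$mean_mutations_per_cluster)),
    clusters_all)
  clusters_df <- data.frame(cluster_id = clusters_all,
                            n_mutations = as.integer(n_mut[clusters_all]),
                            is_trunk = clusters_all == trunk,
                            stringsAsFactors = FALSE)

  # --- copy number: irreversible LOH plus occasional gains --------------
  chroms <- paste0("chr", 1:22)
  seg_template <- do.call(rbind, lapply(chroms, function(ch)
    data.frame(chrom = ch, start = c(0, 5e7), end = c(5e7, 1e8))))
  n_seg <- nrow(seg_template)
  # per-cluster own events
  loh_events <- list()   # (segment index, cluster)
  gain_events <- list()
  free_segs <- seq_len(n_seg)
  for (cl in clusters_all) {
    k <- stats::rpois(1, config$loh_rate_per_branch)
    k <- min(k, length(free_segs))
    if (k > 0) {
      segs <- if (length(free_segs) == 1L) free_segs else
        sample(free_segs, k)
      free_segs <- setdiff(free_segs, segs)
      for (s in segs) {
        loh_events[[length(loh_events) + 1L]] <-
          data.frame(seg = s, cluster = cl, stringsAsFactors = FALSE)
      }
    }
    g <- stats::rpois(1, config$loh_rate_per_branch / 2)
    if (g > 0) {
      for (s in sample(seq_len(n_seg), min(g, n_seg))) {
        gain_events[[length(gain_events) + 1L]] <-
          data.frame(seg = s, cluster = cl, stringsAsFactors = FALSE)
      }
    }
  }
  loh_df <- if (length(loh_events)) do.call(rbind, loh_events) else
    data.frame(seg = integer(0), cluster = character(0))
  gain_df <- if (length(gain_events)) do.call(rbind, gain_events) else
    data.frame(seg = integer(0), cluster = character(0))
  # integer allele profiles per cluster (path-accumulated)
  cn_minor_cl <- matrix(1, length(clusters_all), n_seg,
                        dimnames = list(clusters_all, NULL))
  cn_major_cl <- matrix(1, length(clusters_all), n_seg,
                        dimnames = list(clusters_all, NULL))
  for (cl in clusters_all) {
    path <- ancestors_of(cl)
    for (s in loh_df$seg[loh_df$cluster %in% path]) {
      cn_minor_cl[cl, s] <- 0
    }
    for (s in gain_df$seg[gain_df$cluster %in% path]) {
      cn_major_cl[cl, s] <- cn_major_cl[cl, s] + 1
    }
  }
  segments <- do.call(rbind, lapply(regions, function(r) {
    rho <- samples$purity[samples$region_id == r]
    w <- true_prop[, r]
    w <- w / sum(w)
    tum_min <- colSums(cn_minor_cl * w)
    tum_maj <- colSums(cn_major_cl * w)
    data.frame(region_id = r, chrom = seg_template$chrom,
               start = seg_template$start, end = seg_template$end,
               cn_major = rho * tum_maj + (1 - rho),
               cn_minor = rho * tum_min + (1 - rho),
               stringsAsFactors = FALSE)
  }))
  subclone_profiles <- do.call(rbind, lapply(clusters_all, function(cl)
    data.frame(cluster_id = cl, chrom = seg_template$chrom,
               start = seg_template$start, end = seg_template$end,
               cn_major = cn_major_cl[cl, ], cn_minor = cn_minor_cl[cl, ],
               stringsAsFactors = FALSE)))

  # --- signatures -------------------------------------------------------
  sig <- synthetic_signature_matrix(config$signature_set)
  platinum_treated <- stats::runif(1) < 0.5
  act <- matrix(0, length(clusters_all), length(config$signature_set),
                dimnames = list(clusters_all, config$signature_set))
  apobec_on <- stats::setNames(rep(FALSE, length(clusters_all)),
                               clusters_all)
  for (cl in clusters_all) {
    base <- c(SBS1 = 0.25, SBS5 = 0.35, SBS4 = 0.4)
    a <- stats::setNames(numeric(length(config$signature_set)),
                         config$signature_set)
    a[names(base)[names(base) %in% names(a)]] <-
      base[names(base) %in% names(a)]
    pa <- if (cl == trunk) NA_character_ else unname(parent[[cl]])
    if (config$episodic_apobec && all(c("SBS2", "SBS13") %in% names(a))) {
      on <- if (!is.na(pa) && apobec_on[[pa]]) {
        stats::runif(1) < 0.7        # bursts persist, sometimes switch off
      } else {
        stats::runif(1) < 0.25       # emergence
      }
      apobec_on[cl] <- on
      if (on) a[c("SBS2", "SBS13")] <- c(0.25, 0.15)
    }
    if (platinum_treated && home[[cl]] != primary &&
        all(c("SBS31", "SBS35") %in% names(a)) && stats::runif(1) < 0.4) {
      a[c("SBS31", "SBS35")] <- c(0.2, 0.1)
    }
    act[cl, ] <- a / sum(a)
  }
  spectra <- vapply(clusters_all, function(cl) {
    p <- as.vector(sig %*% act[cl, ])
    stats::rmultinom(1, n_mut[[cl]], p)[, 1]
  }, numeric(96))
  rownames(spectra) <- rownames(sig)

  # --- detection times and scans ---------------------------------------
  seeding_day <- stats::setNames(numeric(length(tumours)), tumours)
  seeding_day[primary] <- 0
  day <- 150
  for (m in mets) {
    day <- day + stats::runif(1, 20, 80)
    # a metastasis cannot be seeded before its source exists
    src <- migrations$source[migrations$target == m][1]
    seeding_day[m] <- max(day, seeding_day[src] + 10)
    day <- seeding_day[m]
  }
  detection_day <- seeding_day + c(0, stats::rexp(n_met, 1 / 60))
  # a tumour cannot be detected before the tumour that seeded it
  for (m in mets) {
    src <- migrations$source[migrations$target == m][1]
    detection_day[m] <- max(detection_day[m], detection_day[src] + 1)
  }
  relapse_day <- round(min(detection_day[mets]))
  death_day <- round(max(detection_day[mets]) + stats::runif(1, 60, 200))
  scan_days <- unique(c(relapse_day,
                        seq(relapse_day, death_day, by = 60)))
  scan_rows <- list()
  for (sd in scan_days) {
    det <- mets[detection_day[mets] <= sd]
    if (!length(det)) {
      scan_rows[[length(scan_rows) + 1L]] <-
        data.frame(scan_day = sd, tumour_id = NA_character_)
    } else {
      scan_rows[[length(scan_rows) + 1L]] <-
        data.frame(scan_day = sd, tumour_id = det)
    }
  }
  scans <- do.call(rbind, scan_rows)

  # --- drivers / WGD ----------------------------------------------------
  wgd <- if (stats::runif(1) < 0.4) trunk else character(0)
  genes <- c("TP53", "KRAS", "EGFR", "KEAP1", "STK11", "PIK3CA")
  ne <- sample(2:4, 1)
  events <- data.frame(
    gene = sample(genes, ne),
    kind = sample(c("mutation", "amplification", "loh"), ne,
                  replace = TRUE),
    cluster_id = sample(clusters_all, ne, replace = TRUE),
    stringsAsFactors = FALSE)

  tree$sce <- score_tree_sce(tree, ccf)
  p <- patient(patient_id = patient_id, samples = samples,
               clusters = clusters_df, ccf = ccf, trees = list(tree),
               segments = segments, reads = reads,
               subclone_profiles = subclone_profiles, spectra = spectra,
               signature_matrix = sig, events = events, wgd = wgd,
               scans = scans,
               dates = list(surgery_day = 0, relapse_day = relapse_day,
                            death_day = death_day),
               platinum_treated = platinum_treated)
  present_mat <- matrix(FALSE, length(clusters_all), length(tumours),
                        dimnames = list(clusters_all, tumours))
  for (tm in tumours) present_mat[present[[tm]], tm] <- TRUE
  cells_mat <- matrix(FALSE, length(clusters_all), length(tumours),
                      dimnames = list(clusters_all, tumours))
  for (tm in tumours) cells_mat[cells[[tm]], tm] <- TRUE
  seeded_by <- vapply(mets, function(m) {
    srcs <- unique(migrations$source[migrations$target == m])
    kinds <- ifelse(srcs == primary, "primary", "metastasis")
    if (all(kinds == "primary")) "primary"
    else if (all(kinds == "metastasis")) "metastasis" else "both"
  }, character(1))
  truth <- list(tree = tree, proportions = true_prop,
                migrations = migrations, seeded_by = seeded_by,
                loh_history = loh_df, gains = gain_df,
                signature_activity = act, apobec_on = apobec_on,
                detection_day = detection_day, seeding_day = seeding_day,
                present = present_mat, cells = cells_mat, home = home)
  list(patient = p, truth = truth)
}

#' Simulate a cohort
#'
#' @param n number of patients.
#' @param config base [simulation_config()]; each patient gets a seed
#'   derived from `seed` and its index.
#' @param seed cohort-level root seed.
#' @return list of `list(patient, truth)` entries.
#' @export
simulate_cohort <- function(n, config = simulation_config(), seed = 1L) {
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(seed, i)
    simulate_patient(cfg, patient_id = sprintf("SIM%03d", i))
  })
}

#' Simulate a ranked tree ensemble around the true topology
#'
#' Returns the true tree plus `k - 1` distinct perturbed topologies
#' (random parent reassignments that keep the crossing constraint
#' approximately satisfied), each scored by SCE against the patient's CCFs
#' and sorted ascending. Under noise-free CCFs the true tree attains the
#' minimal SCE.
#'
#' @param sim output of [simulate_patient()].
#' @param k ensemble size (>= 1).
#' @param tau crossing-rule tolerance for perturbed parents.
#' @param seed RNG seed for the perturbations.
#' @return list of [clone_tree()] ranked by SCE.
#' @export
simulate_tree_ensemble <- function(sim, k, tau = 0.1, seed = 1L) {
  stopifnot(k >= 1)
  set.seed(seed)
  true_tree <- sim$truth$tree
  ccf <- sim$patient$ccf
  seen <- tree_key(true_tree)
  trees <- list(true_tree)
  tries <- 0L
  while (length(trees) < k && tries < k * 50L) {
    tries <- tries + 1L
    tr <- trees[[sample(length(trees), 1)]]
    nodes <- setdiff(tree_nodes(tr), tr$root)
    v <- sample(nodes, 1)
    forbidden <- c(v, tree_descendants(tr, v), unname(tr$parent[[v]]))
    cand <- setdiff(tree_nodes(tr), forbidden)
    cand <- cand[vapply(cand, function(pa)
      all(ccf[pa, ] >= ccf[v, ] - tau), logical(1))]
    if (!length(cand)) next
    pa <- if (length(cand) == 1L) cand else sample(cand, 1)
    par2 <- tr$parent
    par2[v] <- pa
    tr2 <- tryCatch(clone_tree(par2, root = tr$root),
                    error = function(e) NULL)
    if (is.null(tr2)) next
    key <- tree_key(tr2)
    if (key %in% seen) next
    seen <- c(seen, key)
    trees[[length(trees) + 1L]] <- tr2
  }
  sces <- vapply(trees, score_tree_sce, numeric(1), ccf = ccf)
  keys <- vapply(trees, tree_key, character(1))
  ord <- order(sces, keys)
  trees <- trees[ord]
  for (i in seq_along(trees)) {
    trees[[i]]$sce <- sces[ord][i]
    trees[[i]]$rank <- i
  }
  trees
}
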
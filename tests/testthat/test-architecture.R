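# Tree scoring/enumeration, proportions, clonality, DNV and biallelic
# calls.

test_that("presence follows the more-than-one-mutant-read rule", {
  expect_true(detect_presence(2))
  expect_false(detect_presence(1))
  expect_warning(absent <- detect_presence(NA, ccf = 0), "fall")
  expect_false(absent)
  expect_warning(present <- detect_presence(NA, ccf = 0.2), "fall")
  expect_true(present)
})

test_that("SCE totals sum-condition violations over nodes and regions", {
  ccf <- rbind(T = c(1, 1), A = c(0.5, 0.7), B = c(0.4, 0.6))
  colnames(ccf) <- c("r1", "r2")
  tr <- clone_tree(c(A = "T", B = "T"), root = "T")
  # r1 satisfied (0.9 <= 1), r2 violated by 0.3
  expect_equal(score_tree_sce(tr, ccf), 0.3)
  ccf2 <- rbind(T = c(1, 1), A = c(0.5, 0.5), B = c(0.4, 0.4))
  colnames(ccf2) <- c("r1", "r2")
  expect_equal(score_tree_sce(tr, ccf2), 0)
})

test_that("tree enumeration respects the crossing rule and ranks by SCE", {
  # two subclonal clusters with nested CCFs: chain and fork both
  # admissible; the chain satisfies the sum condition, the fork does not
  ccf <- rbind(T = c(1, 1), A = c(0.8, 0.7), B = c(0.5, 0.4))
  colnames(ccf) <- c("r1", "r2")
  trees <- enumerate_trees(ccf, trunk = "T", tau = 0)
  expect_length(trees, 2L)
  expect_equal(trees[[1]]$sce, 0)       # chain T->A->B
  expect_identical(unname(trees[[1]]$parent[["B"]]), "A")
  expect_gt(trees[[2]]$sce, 0)          # fork T->{A,B}: 1.3 > 1 in r1
  # a cluster exceeding the trunk everywhere admits no tree
  ccf_bad <- rbind(T = c(0.5, 0.5), A = c(0.9, 0.9))
  colnames(ccf_bad) <- c("r1", "r2")
  expect_message(none <- enumerate_trees(ccf_bad, trunk = "T", tau = 0),
                 "no admissible")
  expect_length(none, 0L)
  expect_error(enumerate_trees(matrix(0, 11, 1,
                                      dimnames = list(paste0("c", 1:11),
                                                      "r")),
                               trunk = "c1"),
               "externally")
})

test_that("enumeration agrees with a naive all-parent-maps generator", {
  # independent oracle: enumerate every parent map, filter validity and
  # the crossing rule, score by SCE
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:6, 1)
    cids <- c("T", paste0("S", seq_len(n - 1)))
    ccf <- matrix(runif(2 * n, 0, 0.9), n, 2,
                  dimnames = list(cids, c("r1", "r2")))
    ccf["T", ] <- 1
    tau <- 0.05
    others <- cids[-1]
    combos <- expand.grid(rep(list(cids), length(others)),
                          stringsAsFactors = FALSE)
    oracle <- 0L
    oracle_min <- Inf
    for (i in seq_len(nrow(combos))) {
      par <- stats::setNames(unlist(combos[i, ]), others)
      if (any(names(par) == par)) next
      tr <- tryCatch(clone_tree(par, root = "T"), error = function(e) NULL)
      if (is.null(tr)) next
      ok <- all(vapply(others, function(ch)
        all(ccf[par[[ch]], ] >= ccf[ch, ] - tau), logical(1)))
      if (!ok) next
      oracle <- oracle + 1L
      oracle_min <- min(oracle_min, score_tree_sce(tr, ccf))
    }
    trees <- enumerate_trees(ccf, trunk = "T", tau = tau,
                             max_trees = 10000L)
    expect_identical(length(trees), as.integer(oracle))
    if (oracle > 0) expect_equal(trees[[1]]$sce, oracle_min)
  }
})

test_that("noise-free simulated truth ranks first in enumeration", {
  cfg <- simulation_config(seed = 77, n_clusters = c(6, 6),
                           n_metastases = c(2, 3), ccf_noise_sd = 0)
  sim <- simulate_patient(cfg)
  trees <- enumerate_trees(sim$patient$ccf,
                           trunk = sim$truth$tree$root, tau = 0.01)
  expect_gt(length(trees), 0)
  expect_equal(trees[[1]]$sce, 0)
  expect_identical(cloneseed:::tree_key(trees[[1]]),
                   cloneseed:::tree_key(sim$truth$tree))
})

test_that("subclone proportions subtract children CCFs leaf to trunk", {
  mk <- function(vals) matrix(vals, ncol = 1,
                              dimnames = list(names(vals), "r1"))
  # one-step subtraction
  tr <- clone_tree(c(A = "T"), root = "T")
  pr <- infer_subclone_proportions(tr, mk(c(T = 1, A = 0.4)))
  expect_equal(pr$proportion["T", 1], 0.6)
  expect_equal(pr$proportion["A", 1], 0.4)
  # boundary of the 5% extinction rule
  tr2 <- clone_tree(c(A = "T", B = "T"), root = "T")
  pr2 <- infer_subclone_proportions(tr2, mk(c(T = 1, A = 0.5, B = 0.45)))
  expect_equal(pr2$proportion["T", 1], 0.05)
  expect_true(pr2$extinct[["T"]])       # <= 0.05 everywhere
  expect_false(pr2$extinct[["A"]])
  # chain with iterated subtraction
  tr3 <- clone_tree(c(A = "T", B = "A"), root = "T")
  pr3 <- infer_subclone_proportions(tr3, mk(c(T = 1, A = 0.8, B = 0.3)))
  expect_equal(unname(pr3$proportion[c("T", "A", "B"), 1]),
               c(0.2, 0.5, 0.3))
  # negative internal proportions clip to zero and record the residual
  pr4 <- infer_subclone_proportions(tr2, mk(c(T = 1, A = 0.7, B = 0.6)))
  expect_equal(pr4$proportion["T", 1], 0)
  expect_equal(pr4$residual[["r1"]], 0.3)
})

test_that("proportions conserve trunk CCF per region before clipping", {
  for (seed in c(101, 202, 303)) {
    sim <- cached_sim(seed)
    tr <- sim$truth$tree
    pr <- infer_subclone_proportions(tr, sim$patient$ccf)
    trunk <- tr$root
    expect_equal(colSums(pr$proportion) - pr$residual,
                 sim$patient$ccf[trunk, ], tolerance = 1e-6)
  }
})

test_that("clonality classes follow tumour-kind presence", {
  p <- tiny_patient()
  clon <- classify_clonality(p)
  expect_identical(unname(clon["T"]), "truncal")
  expect_identical(unname(clon["A"]), "primary_unique")
  expect_identical(unname(clon["B"]), "primary_unique")
  expect_identical(unname(clon["C"]), "metastasis_unique")
  # shared: make B present in the metastasis region too
  p2 <- p
  p2$reads["B", "M1_R1"] <- 5L
  expect_identical(unname(classify_clonality(p2)["B"]),
                   "shared_subclonal")
  # undetected clusters are flagged with a warning
  p3 <- p
  p3$reads["B", ] <- 0L
  expect_warning(clon3 <- classify_clonality(p3), "B")
  expect_identical(unname(clon3["B"]), "undetected")
  # clonality on noise-free simulations equals ground truth
  sim <- cached_sim(101)
  clon_sim <- classify_clonality(sim$patient, sim$truth$tree)
  pm <- sim$truth$present
  mets <- setdiff(colnames(pm), "P")
  for (cl in rownames(pm)) {
    expected <- if (cl == sim$truth$tree$root) "truncal"
      else if (pm[cl, "P"] && any(pm[cl, mets])) "shared_subclonal"
      else if (pm[cl, "P"]) "primary_unique"
      else if (any(pm[cl, mets])) "metastasis_unique" else "undetected"
    expect_identical(unname(clon_sim[cl]), expected)
  }
})

test_that("event timing inherits the cluster's clonality class", {
  p <- tiny_patient()
  clon <- classify_clonality(p)
  expect_identical(classify_event_timing("T", clon), "truncal")
  expect_identical(classify_event_timing("C", clon), "metastasis_unique")
  expect_error(classify_event_timing("nope", clon), "unknown cluster")
})

test_that("DNV calls need similar frequencies and 90% double-alt reads", {
  # similar frequencies + 19/20 double-alt -> DNV
  r1 <- call_dnv(30, 100, 28, 100, 19, 20)
  expect_true(r1$is_dnv)
  expect_equal(r1$p_equal, z_two_prop(30, 100, 28, 100))
  expect_gt(r1$p_equal, 0.05)
  # clearly different frequencies -> not a DNV
  r2 <- call_dnv(30, 100, 5, 100, 19, 20)
  expect_false(r2$is_dnv)
  expect_lt(z_two_prop(30, 100, 5, 100), 0.05)
  # both-variant fraction below 0.9 in every sample -> not a DNV
  r3 <- call_dnv(30, 100, 29, 100, 8, 10)
  expect_false(r3$is_dnv)
  # any-sample suffices across samples
  r4 <- call_dnv(c(30, 30), c(100, 100), c(28, 29), c(100, 100),
                 c(8, 19), c(10, 20))
  expect_true(r4$is_dnv)
  # zero overlapping reads everywhere -> warning, not a DNV
  expect_warning(r5 <- call_dnv(30, 100, 28, 100, 0, 0), "overlap")
  expect_false(r5$is_dnv)
})

test_that("biallelic test computes expected VAF and doubled-CDF p", {
  t1 <- test_biallelic(rho = 0.5, ccf = 1, cn_t = 2, alt_reads = 50,
                       total_reads = 100)
  expect_equal(t1$vaf_expected, 0.5)
  t2 <- test_biallelic(rho = 1, ccf = 1, cn_t = 1, alt_reads = 90,
                       total_reads = 100)
  expect_equal(t2$vaf_expected, 1)
  # n=100, alt=50, p=0.5: CDF ~ 0.54 -> p = 2*(1 - CDF)
  cdf <- pbinom(50, 100, 0.5)
  expect_gt(cdf, 0.5)
  expect_equal(t1$p_value, 2 * (1 - cdf))
  # binomial symmetry at p = 0.5: alt and total-alt give equal p
  t_lo <- test_biallelic(rho = 0.5, ccf = 1, cn_t = 2, alt_reads = 40,
                         total_reads = 100)
  t_hi <- test_biallelic(rho = 0.5, ccf = 1, cn_t = 2, alt_reads = 60,
                         total_reads = 100)
  expect_equal(t_lo$p_value, t_hi$p_value, tolerance = 0.05)
  # invalid expected VAF is fatal
  expect_error(test_biallelic(rho = 0.5, ccf = 0, cn_t = 2,
                              alt_reads = 1, total_reads = 10),
               "VAF")
  # the decision rule (verbatim) calls biallelic when the null is
  # rejected in any sample; invert_call flips it
  t3 <- test_biallelic(rho = 0.9, ccf = 1, cn_t = 2, alt_reads = 5,
                       total_reads = 200)
  expect_identical(t3$call, "biallelic")
  t4 <- test_biallelic(rho = 0.9, ccf = 1, cn_t = 2, alt_reads = 5,
                       total_reads = 200, invert_call = TRUE)
  expect_identical(t4$call, "not_biallelic")
})

test_that("Holm-Sidak adjustment is monotone and bounded", {
  p <- c(0.01, 0.04, 0.03, 0.2)
  adj <- holm_sidak(p)
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(adj <= 1))
  # smallest raw p gets the full-family exponent
  expect_equal(adj[1], 1 - (1 - 0.01)^4)
})
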
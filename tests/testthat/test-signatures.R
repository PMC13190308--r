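# Signature refitting, resampling, aetiology grouping, episodic APOBEC
# and cosine distances.

sigs4 <- synthetic_signature_matrix(c("SBS1", "SBS2", "SBS4", "SBS5"))

test_that("NNLS refitting recovers constructed mixtures", {
  counts <- round(1000 * (0.7 * sigs4[, "SBS1"] + 0.3 * sigs4[, "SBS2"]))
  a <- fit_activity(counts, sigs4)
  expect_equal(unname(a["SBS1"]), 0.7, tolerance = 0.01)
  expect_equal(unname(a["SBS2"]), 0.3, tolerance = 0.01)
  # pure signature
  pure <- round(5000 * sigs4[, "SBS4"])
  a2 <- fit_activity(pure, sigs4)
  expect_equal(unname(a2["SBS4"]), 1, tolerance = 0.01)
  # exact recovery of a large noise-free two-signature mixture
  exact <- 1e4 * (0.6 * sigs4[, "SBS4"] + 0.4 * sigs4[, "SBS5"])
  a3 <- fit_activity(exact, sigs4)
  expect_lt(attr(a3, "residual"), 1e-6)
  expect_equal(unname(a3[c("SBS4", "SBS5")]), c(0.6, 0.4),
               tolerance = 1e-6)
  # zero counts -> missing
  expect_true(all(is.na(fit_activity(rep(0, 96), sigs4))))
})

test_that("small-cluster resampling is routed, seeded and flagged", {
  sim <- cached_sim(101)
  p <- sim$patient
  big <- colnames(p$spectra)[colSums(p$spectra) >= 50][1]
  r_big <- resample_fit(big, p, iterations = 10, seed = 1)
  expect_identical(r_big$method, "direct")
  expect_true(all(r_big$sd == 0))
  expect_false(r_big$excluded)
  small <- colnames(p$spectra)[colSums(p$spectra) < 50]
  if (length(small)) {
    r1 <- resample_fit(small[1], p, iterations = 30, seed = 7)
    r2 <- resample_fit(small[1], p, iterations = 30, seed = 7)
    expect_identical(r1$activity, r2$activity)   # determinism
    expect_identical(r1$method, "resampled")
    expect_identical(r1$excluded, sum(r1$sd > 0.1) >= 2L)
  }
})

test_that("homogeneous patients resample close to the pooled fit", {
  # every cluster drawn from the same exposure: the resampled mean of a
  # small cluster approximates the pooled direct fit
  set.seed(9)
  mix <- 0.5 * sigs4[, "SBS1"] + 0.5 * sigs4[, "SBS4"]
  spectra <- vapply(1:4, function(i) stats::rmultinom(1, 45, mix)[, 1],
                    numeric(96))
  colnames(spectra) <- c("T", "A", "B", "C")
  rownames(spectra) <- rownames(sigs4)
  p <- tiny_patient()
  p$spectra <- spectra
  p$signature_matrix <- sigs4
  pooled <- fit_activity(rowSums(spectra), sigs4)
  r <- resample_fit("A", p, iterations = 300, seed = 5)
  expect_lt(max(abs(r$activity - pooled)), 0.15)
})

test_that("aetiology detection and majority use the stated thresholds", {
  act <- rbind(c1 = c(SBS1 = 0.02, SBS5 = 0.04, SBS4 = 0.51,
                      SBS2 = 0.2, SBS13 = 0.1),
               c2 = c(SBS1 = 0.3, SBS5 = 0.21, SBS4 = 0.49,
                      SBS2 = 0, SBS13 = 0))
  s <- aetiology_summary(act)
  # group activity sums members: clock c1 = 0.06 -> detected (inclusive)
  expect_true(s$detected["c1", "clock_like"])
  expect_equal(s$group_activity["c1", "clock_like"], 0.06)
  # majority needs > 0.5: smoking 0.51 qualifies, 0.49 does not
  expect_identical(unname(s$majority["c1"]), "smoking")
  # clock 0.51 vs smoking 0.49 for c2
  expect_identical(unname(s$majority["c2"]), "clock_like")
  act2 <- rbind(c3 = c(SBS1 = 0.5, SBS5 = 0, SBS4 = 0.5,
                       SBS2 = 0, SBS13 = 0))
  expect_identical(unname(aetiology_summary(act2)$majority["c3"]),
                   "none")
  # platinum masked unless treated
  act3 <- rbind(c4 = c(SBS1 = 0.1, SBS5 = 0, SBS4 = 0, SBS2 = 0,
                       SBS13 = 0, SBS31 = 0.4, SBS35 = 0.3))
  expect_false("platinum" %in%
                 colnames(aetiology_summary(act3)$group_activity))
  expect_true("platinum" %in%
                colnames(aetiology_summary(act3,
                                           treated_platinum =
                                             TRUE)$group_activity))
  # invariance to signature column order
  perm <- act[, sample(ncol(act))]
  s2 <- aetiology_summary(perm)
  expect_identical(s$majority, s2$majority)
  expect_equal(s$group_activity, s2$group_activity[, colnames(
    s$group_activity)])
})

test_that("episodic APOBEC needs inactive-to-active transitions", {
  chain <- clone_tree(c(b = "a", c = "b", d = "c"), root = "a")
  # active -> inactive -> active (criterion i: trunk active + emergence)
  e1 <- detect_episodic_apobec(chain, c(a = TRUE, b = FALSE, c = TRUE,
                                        d = TRUE))
  expect_true(e1$patient_flag)
  # inactive -> active -> inactive -> active (criterion ii)
  e2 <- detect_episodic_apobec(chain, c(a = FALSE, b = TRUE, c = FALSE,
                                        d = TRUE))
  expect_true(e2$patient_flag)
  expect_equal(e2$lineages$n_emergences, 2)
  # constitutively active: never episodic
  e3 <- detect_episodic_apobec(chain, c(a = TRUE, b = TRUE, c = TRUE,
                                        d = TRUE))
  expect_false(e3$patient_flag)
  # single late emergence with inactive trunk: not episodic
  e4 <- detect_episodic_apobec(chain, c(a = FALSE, b = FALSE, c = TRUE,
                                        d = TRUE))
  expect_false(e4$patient_flag)
  # brute-force scan over random lineages agrees with the rule
  set.seed(31)
  for (i in 1:30) {
    states <- sample(c(TRUE, FALSE), 6, replace = TRUE)
    lin <- clone_tree(stats::setNames(paste0("n", 1:5), paste0("n", 2:6)),
                      root = "n1")
    names(states) <- paste0("n", 1:6)
    res <- detect_episodic_apobec(lin, states)
    emerg <- sum(!states[-6] & states[-1])
    expect_identical(res$patient_flag,
                     (states[[1]] && emerg >= 1) || emerg >= 2)
  }
})

test_that("cosine distances separate shifted metastasis signatures", {
  expect_equal(cloneseed:::cosine_distance(c(1, 0), c(1, 0)), 0)
  expect_equal(cloneseed:::cosine_distance(c(1, 0), c(0, 1)), 1)
  act <- rbind(T = c(1, 0, 0), A = c(0.9, 0.1, 0),
               m1 = c(0.1, 0.1, 0.8), m2 = c(0.05, 0.15, 0.8))
  clon <- c(T = "truncal", A = "primary_unique",
            m1 = "metastasis_unique", m2 = "metastasis_unique")
  rep <- signature_distance_report(act, clon)
  # a metastasis-specific exposure shift: met-met mean below met-primary
  expect_lt(rep$met_met_mean, rep$met_primary_mean)
  # degenerate strata are missing
  rep2 <- signature_distance_report(act[c("T", "m1"), ],
                                    clon[c("T", "m1")])
  expect_true(is.na(rep2$met_met_mean))
  expect_false(is.na(rep2$met_primary_mean))
})
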
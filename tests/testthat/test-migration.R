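# Weighted-parsimony migration labeling, polytomy refinement, model
# selection, reclassification and ensemble probabilities.

mk_presence <- function(clusters, tumours, ...) {
  m <- matrix(FALSE, length(clusters), length(tumours),
              dimnames = list(clusters, tumours))
  hits <- list(...)
  for (cl in names(hits)) m[cl, hits[[cl]]] <- TRUE
  m
}

test_that("forced labelings produce the expected migrations", {
  # trunk in primary, single child detected only in M1
  tr <- clone_tree(c(A = "T"), root = "T")
  pres <- mk_presence(c("T", "A"), c("P", "M1"), T = "P", A = "M1")
  h <- infer_history(tr, pres, "P", model = "multi_source")
  expect_identical(h$migrations$source, "P")
  expect_identical(h$migrations$target, "M1")
  expect_equal(h$mu, 1)
  expect_identical(unname(h$seeded_by["M1"]), "primary")
  # star: k children in k distinct metastases -> k independent migrations
  tr2 <- clone_tree(c(A = "T", B = "T", C = "T"), root = "T")
  pres2 <- mk_presence(c("T", "A", "B", "C"), c("P", "M1", "M2", "M3"),
                       T = "P", A = "M1", B = "M2", C = "M3")
  h2 <- infer_history(tr2, pres2, "P", model = "multi_source")
  expect_equal(h2$mu, 3)
  expect_equal(h2$gamma, 3)
  expect_setequal(h2$migrations$target, c("M1", "M2", "M3"))
  expect_true(all(h2$migrations$source == "P"))
})

test_that("a met-private chain is resolved to met-to-met seeding", {
  # trunk(P) -> A (detected M1 only) -> B (detected M2 only); the most
  # parsimonious labeling routes P -> M1 -> M2
  tr <- clone_tree(c(A = "T", B = "A"), root = "T")
  pres <- mk_presence(c("T", "A", "B"), c("P", "M1", "M2"),
                      T = "P", A = "M1", B = "M2")
  h <- infer_history(tr, pres, "P", model = "single_source")
  expect_equal(h$mu, 2)
  key <- paste(h$migrations$source, h$migrations$target, sep = ">")
  expect_setequal(key, c("P>M1", "M1>M2"))
  # brute-force oracle agrees on (mu, gamma) for the 5-node refined tree
  rt <- refine_tree(tr, pres, "P")
  bf <- brute_force_labeling(rt, "single_source")
  res <- cloneseed:::label_refined(rt, "single_source")
  expect_equal(unname(bf["mu"]), res$mu)
  expect_equal(unname(bf["gamma"]), res$gamma)
})

test_that("DP (mu, gamma) equals brute force on random refined trees", {
  for (seed in 1:60) {
    rt <- random_refined_tree(seed)
    for (model in c("primary_only", "single_source", "multi_source")) {
      bf <- brute_force_labeling(rt, model)
      res <- cloneseed:::label_refined(rt, model)
      expect_equal(res$mu, unname(bf["mu"]),
                   info = paste("seed", seed, model))
      expect_equal(res$gamma, unname(bf["gamma"]),
                   info = paste("seed", seed, model))
    }
  }
})

test_that("model nesting holds: mu multi <= single <= primary-only", {
  for (seed in 1:25) {
    rt <- random_refined_tree(seed + 500)
    mus <- vapply(c("multi_source", "single_source", "primary_only"),
                  function(m) cloneseed:::label_refined(rt, m)$mu,
                  numeric(1))
    expect_true(mus[1] <= mus[2] && mus[2] <= mus[3],
                info = paste("seed", seed))
  }
})

test_that("no solution contains a migration into the primary", {
  for (seed in 1:20) {
    rt <- random_refined_tree(seed + 900)
    res <- cloneseed:::label_refined(rt, "multi_source")
    mig <- res$migrations
    expect_false(any(mig$target == "P"))
  }
})

test_that("polytomy refinement groups same-tumour children", {
  # 3 children: 2 in M1, 1 in M2; grouping the M1 pair drops mu 3 -> 2
  tr <- clone_tree(c(A = "T", B = "T", C = "T"), root = "T")
  pres <- mk_presence(c("T", "A", "B", "C"), c("P", "M1", "M2"),
                      T = "P", A = "M1", B = "M1", C = "M2")
  rt <- refine_tree(tr, pres, "P")
  before <- cloneseed:::label_refined(rt, "multi_source")
  expect_equal(before$mu, 3)
  rt2 <- resolve_polytomies(rt, "multi_source")
  after <- cloneseed:::label_refined(rt2, "multi_source")
  expect_equal(after$mu, 2)
  # contracting the inserted nodes recovers the input edges
  contracted <- rt2$parent
  inter <- grep("^\\.i", names(contracted), value = TRUE)
  for (ch in names(contracted)) {
    while (contracted[[ch]] %in% inter) {
      contracted[ch] <- rt2$parent[[contracted[[ch]]]]
    }
  }
  contracted <- contracted[!names(contracted) %in% inter]
  expect_identical(sort(paste(names(contracted), contracted)),
                   sort(paste(names(rt$parent), rt$parent)))
  # all children already in the parent's tumour: unchanged
  pres_same <- mk_presence(c("T", "A", "B", "C"), c("P", "M1"),
                           T = "P", A = "P", B = "P", C = "P")
  rt3 <- refine_tree(tr, pres_same, "P")
  rt3b <- resolve_polytomies(rt3, "multi_source")
  expect_identical(length(rt3b$parent), length(rt3$parent))
  # a binary tree is never refined
  tr_bin <- clone_tree(c(A = "T", B = "A"), root = "T")
  pres_bin <- mk_presence(c("T", "A", "B"), c("P", "M1"),
                          T = "P", A = "M1", B = "M1")
  rt4 <- refine_tree(tr_bin, pres_bin, "P")
  rt4b <- resolve_polytomies(rt4, "multi_source")
  expect_identical(names(rt4b$parent), names(rt4$parent))
})

test_that("model selection minimises mu with ties to the simpler model", {
  # primary seeds everything: all three models tie -> primary_only
  tr <- clone_tree(c(A = "T", B = "T"), root = "T")
  pres <- mk_presence(c("T", "A", "B"), c("P", "M1", "M2"),
                      T = "P", A = "M1", B = "M2")
  h <- select_seeding_model(tr, pres, "P")
  expect_identical(h$model, "primary_only")
  mus <- attr(h, "mu_by_model")
  expect_length(mus, 3L)
  expect_true(all(mus == mus[1]))
  # single-metastasis patient: all equal, primary_only reported
  tr1 <- clone_tree(c(A = "T"), root = "T")
  pres1 <- mk_presence(c("T", "A"), c("P", "M1"), T = "P", A = "M1")
  expect_identical(select_seeding_model(tr1, pres1, "P")$model,
                   "primary_only")
  # met-private chain needs met-to-met: a richer model wins strictly
  tr2 <- clone_tree(c(A = "T", B = "A", C = "B"), root = "T")
  pres2 <- mk_presence(c("T", "A", "B", "C"), c("P", "M1", "M2"),
                       T = "P", A = "M1", B = "M1", C = "M2")
  h2 <- select_seeding_model(tr2, pres2, "P")
  mus2 <- attr(h2, "mu_by_model")
  expect_lt(mus2[["single_source"]], mus2[["primary_only"]])
  expect_true(h2$model != "primary_only")
  expect_true(any(h2$migrations$source == "M1" &
                    h2$migrations$target == "M2"))
})

test_that("met-unique clusters labeled in the primary become shared", {
  tr <- clone_tree(c(A = "T", B = "A"), root = "T")
  # A undetected anywhere at cell level but sits on the path to a
  # primary-detected descendant: the solver labels it P
  pres <- mk_presence(c("T", "A", "B"), c("P", "M1"),
                      T = "P", B = "P")
  h <- infer_history(tr, pres, "P", model = "multi_source")
  expect_identical(unname(h$labels[["A"]]), "P")
  clon <- c(T = "truncal", A = "metastasis_unique", B = "primary_unique")
  re <- reclassify_shared(h, clon)
  expect_identical(unname(re[["A"]]), "shared_subclonal")
  expect_identical(unname(re[["B"]]), "primary_unique")
  # met-unique clusters labeled in a metastasis stay met-unique
  pres2 <- mk_presence(c("T", "A", "B"), c("P", "M1"),
                       T = "P", A = "M1", B = "M1")
  h2 <- infer_history(tr, pres2, "P", model = "multi_source")
  clon2 <- c(T = "truncal", A = "metastasis_unique",
             B = "metastasis_unique")
  re2 <- reclassify_shared(h2, clon2)
  expect_identical(unname(re2[["A"]]), "metastasis_unique")
})

test_that("ensemble migration probabilities are solution fractions", {
  sim <- cached_sim(101)
  pres <- migration_presence(sim$patient, sim$truth$tree)
  # an ensemble of identical trees gives probabilities exactly 1
  ens_same <- list(sim$truth$tree, sim$truth$tree, sim$truth$tree)
  pr_same <- migration_probabilities(ens_same, pres, "P",
                                     model = "multi_source")
  expect_true(all(pr_same$pair$probability == 1))
  # perturbed ensemble: probabilities in [0, 1]; retention is monotone
  ens <- simulate_tree_ensemble(sim, 8, seed = 3)
  pr <- migration_probabilities(ens, pres, "P", model = "multi_source")
  expect_true(all(pr$pair$probability >= 0 & pr$pair$probability <= 1))
  sweep <- threshold_sweep(pr, "P")
  expect_true(all(diff(sweep$n_retained) <= 0))
  expect_equal(sweep$n_retained[1], nrow(pr$pair))     # threshold 0
  expect_equal(utils::tail(threshold_sweep(pr, "P",
                                           thresholds = c(0, 1.01)),
                           1)$n_retained, 0)           # beyond 1
  expect_error(migration_probabilities(list(), pres, "P"), "empty")
})
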
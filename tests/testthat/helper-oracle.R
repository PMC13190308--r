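# Independent brute-force oracles used across tests.

# Exhaustive minimum over all tumour labelings of a refined tree:
# lexicographic (mu, gamma) subject to root = primary, no edge into the
# primary, and the seeding-model constraint. Deliberately naive and
# independent of the package's branch-and-bound.
brute_force_labeling <- function(rt, model) {
  tumours <- rt$tumours
  primary <- rt$primary
  nodes <- unique(c(rt$root, names(rt$parent)))
  fixed <- rt$fixed
  free <- setdiff(nodes, names(fixed))
  base <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  base[names(fixed)] <- fixed
  edges <- cbind(parent = unname(rt$parent), child = names(rt$parent))
  best <- c(mu = Inf, gamma = Inf)
  eval_one <- function(lab) {
    a <- lab[edges[, 1]]
    b <- lab[edges[, 2]]
    if (any(b == primary & a != primary)) return(NULL)
    if (model == "primary_only" && any(a != primary & a != b)) return(NULL)
    mig <- a != b
    if (model == "single_source") {
      tgt <- b[mig]; src <- a[mig]
      if (any(vapply(split(src, tgt), function(s)
        length(unique(s)), 1L) > 1L)) return(NULL)
    }
    pr <- unique(paste(a[mig], b[mig]))
    c(mu = sum(mig), gamma = length(pr))
  }
  grid_rec <- function(i, lab) {
    if (i > length(free)) {
      v <- eval_one(lab)
      if (!is.null(v) &&
          (v["mu"] < best["mu"] ||
           (v["mu"] == best["mu"] && v["gamma"] < best["gamma"]))) {
        best <<- v
      }
      return(invisible())
    }
    for (t in tumours) {
      lab[free[i]] <- t
      grid_rec(i + 1L, lab)
    }
  }
  grid_rec(1L, base)
  best
}

# Random refined tree with <= max_nodes nodes and <= max_tumours tumours;
# leaves are fixed observation nodes, internals free, root fixed primary.
random_refined_tree <- function(seed, max_nodes = 9L, max_tumours = 4L) {
  set.seed(seed)
  n <- sample(4:max_nodes, 1)
  k <- sample(2:max_tumours, 1)
  tumours <- c("P", paste0("M", seq_len(k - 1)))
  ids <- paste0("n", seq_len(n))
  parent <- stats::setNames(
    vapply(2:n, function(i) ids[sample(i - 1, 1)], character(1)),
    ids[-1])
  leaves <- setdiff(ids, unname(parent))
  fixed <- stats::setNames(sample(tumours, length(leaves), replace = TRUE),
                           leaves)
  fixed[ids[1]] <- "P"
  structure(list(parent = parent, root = ids[1], fixed = fixed,
                 cluster = stats::setNames(ids, ids), tumours = tumours,
                 primary = "P"),
            class = "cs_refined_tree")
}

# two-proportion z-test with pooled variance (oracle for call_dnv)
z_two_prop <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  2 * stats::pnorm(-abs(p1 - p2) / se)
}
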
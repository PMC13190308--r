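# Parsimonious migration-history inference.
#
# The clone tree is refined by attaching one fixed observation leaf per
# (cluster, tumour) pair where the cluster is detected; internal nodes are
# then labeled with tumours so as to minimise, lexicographically, the number
# of migrations mu (tree edges whose endpoints carry different tumours),
# the number of comigrations gamma (distinct ordered source-target pairs)
# and the number of distinct source tumours. The root is fixed to the
# primary and no migration may enter the primary (primaries were resected
# before metastatic relapse, so reseeding is not modelled). Three seeding
# models constrain the labeling: primary_only (every migration starts at
# the primary), single_source (each metastasis receives migrations from
# exactly one source tumour) and multi_source (unconstrained).
#
# The search is an exact branch-and-bound over internal labels with a
# Sankoff-style dynamic-programming lower bound, replacing the ILP of the
# original migration-history literature with the same objective.

BIG <- 1e9

#' Cell-level presence used for migration inference
#'
#' A subclone takes part in the migration labeling of a tumour only where
#' it has surviving cells: its inferred terminal proportion exceeds the
#' extinction threshold in at least one region of the tumour. Mutation
#' detection alone is not enough - a metastasis carries the mutations of
#' every ancestor of its founding clone without any of those ancestral
#' populations having migrated.
#'
#' @param p a `cs_patient`.
#' @param tree clone tree used to deconvolve proportions.
#' @param threshold per-region proportion above which the subclone counts
#'   as present (0.05 = extant rule; `include_extinct` drops it to 0).
#' @param include_extinct include subclones with any positive proportion.
#' @return logical cluster-by-tumour matrix.
#' @export
migration_presence <- function(p, tree = p$trees[[1]], threshold = 0.05,
                               include_extinct = FALSE) {
  if (include_extinct) threshold <- 0
  props <- infer_subclone_proportions(tree, p$ccf)$proportion
  tums <- patient_tumours(p)
  out <- matrix(FALSE, nrow(props), length(tums),
                dimnames = list(rownames(props), tums))
  for (tm in tums) {
    regs <- intersect(tumour_regions(p, tm), colnames(props))
    out[, tm] <- apply(props[, regs, drop = FALSE] > threshold, 1, any)
  }
  out
}

#' Build a refined tree from a clone tree and tumour-level presence
#'
#' @param tree a [clone_tree()].
#' @param presence logical cluster-by-tumour matrix (see
#'   [presence_matrix()]).
#' @param primary tumour id of the primary.
#' @return an object of class `cs_refined_tree` with fixed observation
#'   leaves, free internal nodes, and per-node cluster assignments.
#' @export
refine_tree <- function(tree, presence, primary) {
  parent <- tree$parent
  fixed <- stats::setNames(character(0), character(0))
  clus <- stats::setNames(tree_nodes(tree), tree_nodes(tree))
  tumours <- colnames(presence)
  for (cl in intersect(rownames(presence), tree_nodes(tree))) {
    for (tm in tumours[presence[cl, ]]) {
      leaf <- paste0(cl, "@", tm)
      parent[leaf] <- cl
      fixed[leaf] <- tm
      clus[leaf] <- cl
    }
  }
  fixed[tree$root] <- primary
  structure(list(parent = parent[order(names(parent))], root = tree$root,
                 fixed = fixed, cluster = clus, tumours = tumours,
                 primary = primary, obs = presence),
            class = "cs_refined_tree")
}

rt_children <- function(rt, node) names(rt$parent)[rt$parent == node]

rt_nodes <- function(rt) unique(c(rt$root, names(rt$parent)))

# model-specific edge cost matrix over tumour labels
edge_cost_matrix <- function(tumours, primary, model) {
  k <- length(tumours)
  cm <- matrix(1, k, k, dimnames = list(tumours, tumours))
  diag(cm) <- 0
  cm[tumours != primary, primary] <- BIG    # no migration into the primary
  if (model == "primary_only") {
    for (a in setdiff(tumours, primary)) {
      cm[a, tumours != a & tumours != primary] <- BIG
      # a -> primary already BIG above
    }
  }
  cm
}

# Exact lexicographic-optimal labeling by branch and bound with a
# Sankoff dynamic-programming lower bound. Internally everything is
# integer-indexed for speed.
# Objective: (mu, gamma, n_observation_inconsistent, n_sources,
# -n_primary_internal, label order). The inconsistency term counts free
# nodes labeled with a tumour in which their cluster is undetected; among
# equal-(mu, gamma) labelings, solutions that place clones only where
# they were observed are preferred, which resolves primary-vs-metastasis
# source ties toward the observed route.
label_refined <- function(rt, model = c("primary_only", "single_source",
                                        "multi_source"),
                          max_solutions = 20000L) {
  model <- match.arg(model)
  tumours <- rt$tumours
  primary <- rt$primary
  K <- length(tumours)
  lab_of <- stats::setNames(seq_len(K), tumours)
  iprim <- lab_of[[primary]]
  cm <- edge_cost_matrix(tumours, primary, model)

  # integer node table in preorder
  nodes <- character(0)
  walk_pre <- function(n) {
    nodes <<- c(nodes, n)
    for (ch in sort(rt_children(rt, n))) walk_pre(ch)
  }
  walk_pre(rt$root)
  N <- length(nodes)
  idx_of <- stats::setNames(seq_len(N), nodes)
  par_i <- rep(NA_integer_, N)
  for (ch in names(rt$parent)) par_i[idx_of[[ch]]] <-
    idx_of[[rt$parent[[ch]]]]
  fix_i <- rep(NA_integer_, N)
  for (n in names(rt$fixed)) fix_i[idx_of[[n]]] <- lab_of[[rt$fixed[[n]]]]
  children <- vector("list", N)
  for (i in seq_len(N)) children[[i]] <- integer(0)
  for (i in seq_len(N)) {
    if (!is.na(par_i[i])) {
      children[[par_i[i]]] <- c(children[[par_i[i]]], i)
    }
  }
  fixed_ch <- lapply(children, function(k) k[!is.na(fix_i[k])])
  free_ch <- lapply(children, function(k) k[is.na(fix_i[k])])

  # Sankoff arrays, children before parents (reverse preorder works)
  M <- matrix(0, N, K)
  for (i in rev(seq_len(N))) {
    v <- numeric(K)
    for (ch in children[[i]]) {
      mch <- M[ch, ]
      v <- v + vapply(seq_len(K), function(a) min(cm[a, ] + mch),
                      numeric(1))
    }
    if (!is.na(fix_i[i])) {
      w <- rep(BIG, K)
      w[fix_i[i]] <- v[fix_i[i]]
      v <- w
    }
    M[i, ] <- pmin(v, BIG)
  }

  free <- which(is.na(fix_i))   # already in preorder
  nfree <- length(free)
  lab_order <- c(iprim, setdiff(order(tumours), iprim))

  # observation consistency of (node, label): the node's cluster is
  # detected in that tumour. TRUE everywhere when no presence is attached.
  cons <- matrix(TRUE, N, K)
  if (!is.null(rt$obs)) {
    for (i in free) {
      cl <- rt$cluster[[nodes[i]]]
      if (cl %in% rownames(rt$obs)) {
        cons[i, ] <- rt$obs[cl, tumours]
      }
    }
  }

  labels <- rep(iprim, N)
  labels[!is.na(fix_i)] <- fix_i[!is.na(fix_i)]

  eval_edges <- function(lv) {
    # returns c(mu, gamma, nsrc) and feasibility for a full labeling
    a <- lv[par_i[-1]]; b <- lv[-1]
    mig <- a != b
    pairs <- unique((a[mig] - 1L) * K + b[mig])
    feas <- TRUE
    if (model == "single_source") {
      tgts <- (pairs - 1L) %% K + 1L
      feas <- !anyDuplicated(tgts)
    }
    list(mu = sum(mig), gamma = length(pairs),
         nsrc = length(unique(a[mig])), feasible = feas)
  }
  n_incons_of <- function(lv) {
    if (!nfree) return(0L)
    sum(!cons[cbind(free, lv[free])])
  }
  inc <- eval_edges(labels)
  best <- list(mu = inc$mu, gamma = inc$gamma,
               n_incons = n_incons_of(labels), n_sources = inc$nsrc,
               n_prim = sum(labels[free] == iprim), labels = labels)

  better_than_best <- function(mu, gamma, nincons, nsrc, nprim, lv) {
    a <- c(mu, gamma, nincons, nsrc, -nprim)
    b <- c(best$mu, best$gamma, best$n_incons, best$n_sources,
           -best$n_prim)
    for (i in seq_along(a)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
    # final deterministic tie-break on label sequence
    for (i in free) {
      if (lv[i] < best$labels[i]) return(TRUE)
      if (lv[i] > best$labels[i]) return(FALSE)
    }
    FALSE
  }

  n_eval <- 0L
  cur <- labels
  # lb_terms: numeric vector over nodes, NA when not on the frontier
  rec <- function(pos, mu, lb_terms, lb_sum, pairs) {
    if (n_eval >= max_solutions) return(invisible())
    if (pos > nfree) {
      n_eval <<- n_eval + 1L
      gamma <- length(unique(pairs))
      nincons <- n_incons_of(cur)
      nsrc <- length(unique((unique(pairs) - 1L) %/% K))
      nprim <- sum(cur[free] == iprim)
      if (better_than_best(mu, gamma, nincons, nsrc, nprim, cur)) {
        best <<- list(mu = mu, gamma = gamma, n_incons = nincons,
                      n_sources = nsrc, n_prim = nprim, labels = cur)
      }
      return(invisible())
    }
    v <- free[pos]
    la <- cur[par_i[v]]
    fk <- fixed_ch[[v]]
    fr <- free_ch[[v]]
    for (l in lab_order) {
      step <- cm[la, l]
      if (step >= BIG) next
      new_pairs <- pairs
      add <- step
      ok <- TRUE
      if (step > 0) new_pairs <- c(new_pairs, (la - 1L) * K + l)
      if (length(fk)) {
        fl <- fix_i[fk]
        costs <- cm[l, fl]
        if (any(costs >= BIG)) next
        migf <- fl[costs > 0]
        add <- add + length(migf)
        if (length(migf)) new_pairs <- c(new_pairs, (l - 1L) * K + migf)
      }
      if (model == "single_source") {
        up <- unique(new_pairs)
        if (anyDuplicated((up - 1L) %% K + 1L)) next
      }
      new_terms <- lb_terms
      new_sum <- lb_sum - new_terms[v]
      new_terms[v] <- 0
      bad <- FALSE
      if (length(fr)) {
        for (fc in fr) {
          t <- min(cm[l, ] + M[fc, ])
          if (t >= BIG) { bad <- TRUE; break }
          new_terms[fc] <- t
          new_sum <- new_sum + t
        }
      }
      if (bad) next
      if (mu + add + new_sum > best$mu) next
      cur[v] <<- l
      rec(pos + 1L, mu + add, new_terms, new_sum, new_pairs)
    }
    invisible()
  }

  # initial decided edges: root -> fixed children
  init_pairs <- integer(0)
  init_mu <- 0L
  rfk <- fixed_ch[[1L]]
  feasible_start <- TRUE
  if (length(rfk)) {
    fl <- fix_i[rfk]
    costs <- cm[iprim, fl]
    if (any(costs >= BIG)) feasible_start <- FALSE
    migf <- fl[costs > 0]
    init_mu <- length(migf)
    if (length(migf)) init_pairs <- (iprim - 1L) * K + migf
  }
  init_terms <- rep(0, N)
  init_sum <- 0
  for (fc in free_ch[[1L]]) {
    t <- min(cm[iprim, ] + M[fc, ])
    if (t >= BIG) feasible_start <- FALSE
    init_terms[fc] <- t
    init_sum <- init_sum + t
  }
  if (feasible_start && nfree > 0) {
    rec(1L, init_mu, init_terms, init_sum, init_pairs)
  } else if (feasible_start) {
    fin <- eval_edges(cur)
    if (fin$feasible) {
      best <- list(mu = fin$mu, gamma = fin$gamma, n_incons = 0L,
                   n_sources = fin$nsrc, n_prim = 0L, labels = cur)
    }
  }

  lab <- stats::setNames(tumours[best$labels], nodes)
  migs <- list()
  for (ch in names(rt$parent)) {
    a <- lab[[rt$parent[[ch]]]]; b <- lab[[ch]]
    if (a != b) {
      migs[[length(migs) + 1L]] <-
        data.frame(source = a, target = b,
                   cluster = unname(rt$cluster[[ch]]),
                   stringsAsFactors = FALSE)
    }
  }
  migrations <- if (length(migs)) unique(do.call(rbind, migs)) else
    data.frame(source = character(0), target = character(0),
               cluster = character(0), stringsAsFactors = FALSE)
  rownames(migrations) <- NULL
  migrations <- migrations[order(migrations$source, migrations$target,
                                 migrations$cluster), , drop = FALSE]
  list(mu = best$mu, gamma = best$gamma, n_sources = best$n_sources,
       labels = lab, migrations = migrations,
       feasible = best$mu < BIG, truncated = n_eval >= max_solutions)
}

# enumerate all rooted binary join trees over k items; returns list of
# nested pair structures (indices into the item list)
binary_joins <- function(items) {
  if (length(items) == 1L) return(list(items[[1]]))
  out <- list()
  n <- length(items)
  rest <- items[-1]
  # the subtree containing item 1 pairs with the subtree of the rest;
  # enumerating subsets of the remaining items avoids double counting
  for (mask in 0:(2^(n - 1) - 2)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n - 1) - 1)))
    left <- c(items[1], rest[sel])
    right <- rest[!sel]
    for (lt in binary_joins(left)) {
      for (rt_ in binary_joins(right)) {
        out[[length(out) + 1L]] <- list(lt, rt_)
      }
    }
  }
  out
}

#' Resolve polytomies of a refined tree
#'
#' Multifurcations are refined by inserting free intermediate nodes
#' (carrying the polytomy node's cluster) when this strictly reduces the
#' migration count mu (then gamma). Refinement is exhaustive over binary
#' join trees for polytomies of degree up to `max_degree_exhaustive` and
#' greedy (joining children that share a dominant tumour) beyond.
#' Contracting the inserted nodes recovers the input tree.
#'
#' @param rt a `cs_refined_tree`.
#' @param model seeding model under which mu is evaluated.
#' @param max_degree_exhaustive largest polytomy degree for exhaustive
#'   refinement.
#' @return a refined `cs_refined_tree` (possibly identical to the input).
#' @export
resolve_polytomies <- function(rt, model = "multi_source",
                               max_degree_exhaustive = 6L) {
  base <- label_refined(rt, model)
  counter <- 0L
  insert_refinement <- function(rt, node, joinspec) {
    # joinspec: nested list of child ids; insert an intermediate for every
    # internal pair with >= 2 leaves below
    build <- function(spec, parent) {
      if (!is.list(spec)) {
        rt$parent[[spec]] <<- parent
        return(invisible())
      }
      counter <<- counter + 1L
      nid <- paste0(".i", counter)
      rt$parent[nid] <<- parent
      rt$cluster[nid] <<- rt$cluster[[node]]
      for (s in spec) build(s, nid)
      invisible()
    }
    for (s in joinspec) build(s, node)
    rt
  }
  simplify_spec <- function(spec) {
    # drop intermediates that would hold a single child
    if (!is.list(spec)) return(spec)
    parts <- lapply(spec, simplify_spec)
    if (length(parts) == 1L) return(parts[[1]])
    parts
  }
  cm <- edge_cost_matrix(rt$tumours, rt$primary, model)
  K <- length(rt$tumours)
  lab_of <- stats::setNames(seq_len(K), rt$tumours)
  # per-node Sankoff arrays over the current refined tree
  sankoff_M <- function(rt) {
    M <- list()
    walk <- function(n) {
      for (ch in rt_children(rt, n)) walk(ch)
      v <- numeric(K)
      for (ch in rt_children(rt, n)) {
        mch <- M[[ch]]
        v <- v + vapply(seq_len(K), function(a) min(cm[a, ] + mch),
                        numeric(1))
      }
      if (n %in% names(rt$fixed)) {
        w <- rep(BIG, K)
        i <- lab_of[[rt$fixed[[n]]]]
        w[i] <- v[i]
        v <- w
      }
      M[[n]] <<- pmin(v, BIG)
    }
    walk(rt$root)
    M
  }
  # array of a candidate refinement of `node`, reusing child arrays
  spec_array <- function(spec, M) {
    if (!is.list(spec)) return(M[[spec]])
    v <- numeric(K)
    for (part in spec) {
      mch <- spec_array(part, M)
      v <- v + vapply(seq_len(K), function(a) min(cm[a, ] + mch),
                      numeric(1))
    }
    pmin(v, BIG)
  }
  dominant_tumour <- function(k) {
    if (k %in% names(rt$fixed)) return(rt$fixed[[k]])
    labs <- character(0)
    stack <- k
    while (length(stack)) {
      cur <- stack[1]; stack <- stack[-1]
      if (cur %in% names(rt$fixed)) labs <- c(labs, rt$fixed[[cur]])
      stack <- c(stack, rt_children(rt, cur))
    }
    if (length(labs)) names(which.max(table(labs))) else rt$primary
  }
  repeat {
    improved <- FALSE
    M <- sankoff_M(rt)
    for (node in rt_nodes(rt)) {
      kids <- rt_children(rt, node)
      if (length(kids) < 3L) next
      dom <- vapply(kids, dominant_tumour, character(1))
      # a refinement can only help when >= 2 children share a tumour
      if (!any(duplicated(dom))) next
      groups <- split(kids, dom)
      grp_spec <- lapply(groups, function(g) if (length(g) == 1L) g[[1]]
                         else as.list(g))
      cands <- list(grp_spec)   # cheap grouped candidate first
      if (length(kids) <= max_degree_exhaustive) {
        cands <- c(cands, binary_joins(as.list(kids)))
      }
      base_arr <- spec_array(as.list(kids), M)
      first <- TRUE
      for (spec in cands) {
        spec <- simplify_spec(spec)
        if (!is.list(spec)) next
        # local Sankoff screen: a refinement that lowers no entry of the
        # subtree cost array cannot lower mu (the grouped candidate is
        # always tried in full, so gamma-level gains are still found)
        if (!first && !any(spec_array(spec, M) < base_arr)) next
        first <- FALSE
        rt2 <- insert_refinement(rt, node, spec)
        res2 <- label_refined(rt2, model)
        if (res2$mu < base$mu ||
            (res2$mu == base$mu && res2$gamma < base$gamma)) {
          rt <- rt2
          base <- res2
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  rt
}

#' Infer a migration history under a seeding model
#'
#' Builds the refined tree, optionally resolves polytomies, and finds the
#' lexicographically optimal tumour labeling (migrations, then
#' comigrations, then distinct sources). Migration edges are tree edges
#' whose endpoints carry different tumours; the migrating cluster is the
#' child endpoint's cluster.
#'
#' @param tree a [clone_tree()].
#' @param presence logical cluster-by-tumour presence matrix.
#' @param primary primary tumour id.
#' @param model one of `"primary_only"`, `"single_source"`,
#'   `"multi_source"`.
#' @param resolve resolve polytomies before labeling.
#' @return a `cs_history`: list with `migrations` (source, target, cluster),
#'   `model`, `mu`, `gamma`, `seeded_by` (per metastasis: primary /
#'   metastasis / both), `labels`, `refined`, `status`.
#' @export
infer_history <- function(tree, presence, primary,
                          model = c("multi_source", "single_source",
                                    "primary_only"),
                          resolve = TRUE) {
  model <- match.arg(model)
  rt <- refine_tree(tree, presence, primary)
  if (resolve) rt <- resolve_polytomies(rt, model)
  res <- label_refined(rt, model)
  mets <- setdiff(rt$tumours, primary)
  seeded_by <- stats::setNames(rep(NA_character_, length(mets)), mets)
  for (m in mets) {
    srcs <- unique(res$migrations$source[res$migrations$target == m])
    if (!length(srcs)) next
    kinds <- ifelse(srcs == primary, "primary", "metastasis")
    seeded_by[m] <- if (all(kinds == "primary")) "primary"
      else if (all(kinds == "metastasis")) "metastasis" else "both"
  }
  structure(list(migrations = res$migrations, model = model,
                 mu = res$mu, gamma = res$gamma,
                 n_sources = res$n_sources, seeded_by = seeded_by,
                 labels = res$labels, refined = rt,
                 status = if (res$feasible) "ok" else "infeasible"),
            class = "cs_history")
}

#' @export
print.cs_history <- function(x, ...) {
  cat("<migration history> model=", x$model, " mu=", x$mu, " gamma=",
      x$gamma, " (", nrow(x$migrations), " migration rows)\n", sep = "")
  invisible(x)
}

#' Select the most parsimonious seeding model
#'
#' Runs all three seeding models and keeps the smallest migration count,
#' breaking ties toward the simpler model (primary-only < single-source <
#' multi-source). All three mu values are reported.
#'
#' @inheritParams infer_history
#' @return the chosen `cs_history`, with attribute `mu_by_model`.
#' @export
select_seeding_model <- function(tree, presence, primary, resolve = TRUE) {
  models <- c("primary_only", "single_source", "multi_source")
  hists <- lapply(models, function(m)
    infer_history(tree, presence, primary, model = m, resolve = resolve))
  mus <- vapply(hists, function(h) h$mu, numeric(1))
  keep <- which(mus == min(mus))[1]   # ties -> simpler model (list order)
  h <- hists[[keep]]
  attr(h, "mu_by_model") <- stats::setNames(mus, models)
  h
}

#' Reclassify metastasis-unique clusters placed in the primary
#'
#' A metastasis-unique cluster whose internal node (or an inserted copy of
#' it) is labeled with the primary tumour in the selected solution was
#' inferred to be present in the primary, and is reclassified as shared
#' subclonal. All other classes are unchanged.
#'
#' @param history a `cs_history`.
#' @param clonality named classification from [classify_clonality()].
#' @return updated clonality vector.
#' @export
reclassify_shared <- function(history, clonality) {
  rt <- history$refined
  lab <- history$labels
  for (cl in names(clonality)) {
    if (clonality[[cl]] != "metastasis_unique") next
    nodes <- names(rt$cluster)[rt$cluster == cl]
    nodes <- nodes[!nodes %in% names(rt$fixed)]
    if (length(nodes) && any(lab[nodes] == rt$primary)) {
      clonality[[cl]] <- "shared_subclonal"
    }
  }
  clonality
}

#' Ensemble migration probabilities
#'
#' Runs the migration inference on each tree of a ranked ensemble (the
#' lowest-SCE phylogenies) and reports, for every (source, target) tumour
#' pair, the fraction of solutions containing it; cluster-level
#' probabilities are emitted alongside.
#'
#' @param trees list of [clone_tree()] (the ensemble, typically <= 100).
#' @param presence cluster-by-tumour presence matrix.
#' @param primary primary tumour id.
#' @param model fixed model, or `"auto"` to select per tree.
#' @param resolve resolve polytomies per tree.
#' @return list with `pair` (source, target, probability), `cluster`
#'   (source, target, cluster, probability) and `n_solutions`.
#' @export
migration_probabilities <- function(trees, presence, primary,
                                    model = "auto", resolve = TRUE) {
  if (!length(trees)) stop("empty tree ensemble", call. = FALSE)
  pair_tab <- list()
  clus_tab <- list()
  for (tr in trees) {
    h <- if (identical(model, "auto")) {
      select_seeding_model(tr, presence, primary, resolve = resolve)
    } else {
      infer_history(tr, presence, primary, model = model,
                    resolve = resolve)
    }
    m <- h$migrations
    pair_tab[[length(pair_tab) + 1L]] <-
      unique(paste(m$source, m$target, sep = "\t"))
    clus_tab[[length(clus_tab) + 1L]] <-
      unique(paste(m$source, m$target, m$cluster, sep = "\t"))
  }
  n <- length(trees)
  tab2df <- function(tab, cols) {
    cnt <- table(unlist(tab))
    if (!length(cnt)) {
      out <- as.data.frame(stats::setNames(
        replicate(length(cols), character(0), simplify = FALSE), cols))
      out$probability <- numeric(0)
      return(out)
    }
    parts <- do.call(rbind, strsplit(names(cnt), "\t", fixed = TRUE))
    out <- data.frame(parts, stringsAsFactors = FALSE)
    names(out) <- cols
    out$probability <- as.numeric(cnt) / n
    out[order(-out$probability, out[[1]], out[[2]]), , drop = FALSE]
  }
  list(pair = tab2df(pair_tab, c("source", "target")),
       cluster = tab2df(clus_tab, c("source", "target", "cluster")),
       n_solutions = n)
}

#' Seeded-by summary at a probability threshold
#'
#' @param prob output of [migration_probabilities()].
#' @param primary primary tumour id.
#' @param threshold minimum migration probability for retention.
#' @return named character vector per target tumour: `"primary"`,
#'   `"metastasis"`, `"both"` or `NA` when no migration is retained.
#' @export
seeded_by_at_threshold <- function(prob, primary, threshold = 0) {
  m <- prob$pair[prob$pair$probability >= threshold, , drop = FALSE]
  tgts <- unique(prob$pair$target)
  out <- stats::setNames(rep(NA_character_, length(tgts)), tgts)
  for (t in tgts) {
    srcs <- m$source[m$target == t]
    if (!length(srcs)) next
    kinds <- ifelse(srcs == primary, "primary", "metastasis")
    out[t] <- if (all(kinds == "primary")) "primary"
      else if (all(kinds == "metastasis")) "metastasis" else "both"
  }
  out
}
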
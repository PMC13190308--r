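# Rooted clone trees over mutation clusters.
#
# A clone tree is stored as a named character vector `parent` mapping each
# non-root cluster to its parent, plus the root (trunk) id. The trunk is the
# MRCA of all sequenced cancer cells; every other node is a subclone nested
# below it.

#' Construct a clone tree
#'
#' @param parent named character vector; names are child cluster ids, values
#'   their parents. The root must not appear as a name.
#' @param root cluster id of the trunk (MRCA).
#' @param sce sum condition error of the topology (see [score_tree_sce()]).
#' @param rank 1-based rank within a patient's tree ensemble (1 = lowest SCE).
#' @return an object of class `cs_tree`.
#' @export
clone_tree <- function(parent, root, sce = NA_real_, rank = NA_integer_) {
  parent <- unlist(parent)
  if (length(parent)) {
    stopifnot(!is.null(names(parent)), !any(names(parent) == root))
    parent <- parent[order(names(parent))]
  } else {
    parent <- stats::setNames(character(0), character(0))
  }
  tr <- structure(list(parent = parent, root = root,
                       sce = sce, rank = rank),
                  class = "cs_tree")
  validate_tree(tr)
  tr
}

validate_tree <- function(tree) {
  nodes <- tree_nodes(tree)
  if (anyDuplicated(nodes)) stop("duplicate node ids in tree", call. = FALSE)
  if (length(tree$parent)) {
    unknown <- setdiff(tree$parent, nodes)
    if (length(unknown)) {
      stop("tree parent(s) not in node set: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    # acyclicity/connectivity: every node must reach the root
    for (n in names(tree$parent)) {
      seen <- character(0)
      cur <- n
      while (cur != tree$root) {
        if (cur %in% seen) stop("cycle in tree at node ", n, call. = FALSE)
        seen <- c(seen, cur)
        cur <- unname(tree$parent[[cur]])
        if (is.null(cur) || is.na(cur)) {
          stop("node ", n, " does not reach the root", call. = FALSE)
        }
      }
    }
  }
  invisible(tree)
}

#' @export
print.cs_tree <- function(x, ...) {
  cat("<clone tree> ", length(tree_nodes(x)), " clusters, root=", x$root,
      if (!is.na(x$sce)) paste0(", SCE=", signif(x$sce, 4)) else "",
      "\n", sep = "")
  invisible(x)
}

tree_nodes <- function(tree) unique(c(tree$root, names(tree$parent),
                                      unname(tree$parent)))

tree_children <- function(tree, node) {
  names(tree$parent)[tree$parent == node]
}

tree_edges <- function(tree) {
  if (!length(tree$parent)) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("parent", "child"))))
  }
  cbind(parent = unname(tree$parent), child = names(tree$parent))
}

# all descendants (not including the node itself)
tree_descendants <- function(tree, node) {
  out <- character(0)
  frontier <- tree_children(tree, node)
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unlist(lapply(frontier, tree_children, tree = tree))
  }
  out
}

# path root -> node inclusive
tree_path_from_root <- function(tree, node) {
  path <- node
  while (node != tree$root) {
    node <- unname(tree$parent[[node]])
    path <- c(node, path)
  }
  path
}

tree_leaves <- function(tree) {
  nodes <- tree_nodes(tree)
  nodes[!nodes %in% unname(tree$parent)]
}

# nodes in post-order (children before parents)
tree_postorder <- function(tree) {
  out <- character(0)
  walk <- function(n) {
    for (ch in sort(tree_children(tree, n))) walk(ch)
    out <<- c(out, n)
  }
  walk(tree$root)
  out
}

# canonical key for topology identity (sorted edge list)
tree_key <- function(tree) {
  e <- tree_edges(tree)
  if (!nrow(e)) return(tree$root)
  paste(sort(paste(e[, "parent"], e[, "child"], sep = ">")), collapse = ";")
}

#' Serialize a clone tree to Newick
#'
#' Cluster ids become node labels; branch lengths are the mutation count of
#' the child cluster (the trunk's own count is attached to the root branch).
#' Children are emitted in lexicographic order, so the output is canonical.
#'
#' @param tree a [clone_tree()].
#' @param n_mutations named numeric vector of mutation counts per cluster.
#' @param path optional file to write to.
#' @return the Newick string, invisibly if written to file.
#' @examples
#' tr <- clone_tree(c(A = "trunk", B = "trunk"), root = "trunk")
#' write_tree_newick(tr, c(trunk = 10, A = 3, B = 4))
#' @export
write_tree_newick <- function(tree, n_mutations, path = NULL) {
  fmt_num <- function(x) sprintf("%.12g", x)
  rec <- function(node) {
    kids <- sort(tree_children(tree, node))
    bl <- fmt_num(unname(n_mutations[[node]]))
    if (!length(kids)) return(paste0(node, ":", bl))
    paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")",
           node, ":", bl)
  }
  nw <- paste0(rec(tree$root), ";")
  if (!is.null(path)) {
    writeLines(nw, path)
    return(invisible(nw))
  }
  nw
}
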
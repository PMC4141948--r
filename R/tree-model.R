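#' Bind a phylogeny to an environment table
#'
#' A `labeled_tree` is the validated join of a rooted phylogeny (`ape`
#' `phylo` object) and an environment table assigning abundance counts of
#' one or more samples (communities) to each leaf. It is the input type of
#' every distance and significance function in the package.
#'
#' Validation enforces: unique, non-empty leaf names; branch lengths present,
#' finite and non-negative (a root edge, if any, is dropped and treated as
#' length zero); counts that are positive integers; no duplicated
#' (leaf, sample) entry; every environment leaf present in the tree. Under
#' `strict = TRUE` (default) every tree leaf must also appear in the
#' environment table; with `strict = FALSE` unlabeled leaves are kept with
#' zero abundance and a warning is issued, since which leaves carry counts
#' changes permutation p-values.
#'
#' @param tree A rooted `phylo` object (or an existing `labeled_tree`, which
#'   is re-validated and returned — validation is idempotent).
#' @param env A data frame with columns `leaf`, `sample`, `count`
#'   (`count` may be omitted, defaulting to 1). Ignored when `tree` is
#'   already a `labeled_tree`.
#' @param strict Require every tree leaf to have an environment entry?
#' @param quiet Suppress the lenient-join warning (used internally).
#'
#' @return An object of class `labeled_tree`: a list with elements `tree`
#'   (`phylo`), `env` (tibble of `leaf`, `sample`, `count`) and `samples`
#'   (sample names in order of first appearance).
#'
#' @examples
#' tr <- parse_newick("(A:0.1,B:0.1);")
#' env <- tibble::tibble(leaf = c("A", "B"),
#'                       sample = c("Sample1", "Sample2"), count = c(4L, 4L))
#' lt <- labeled_tree(tr, env)
#' lt
#' @export
labeled_tree <- function(tree, env = NULL, strict = TRUE, quiet = FALSE) {
  if (inherits(tree, "labeled_tree")) {
    env <- env %||% tree$env
    tree <- tree$tree
  }
  if (!inherits(tree, "phylo")) {
    stop_value("`tree` must be a `phylo` object (see parse_newick()).")
  }
  if (is.null(env)) stop_value("`env` must be supplied.")
  env <- validate_env_table(env)

  tips <- tree$tip.label
  if (anyNA(tips) || any(!nzchar(tips))) {
    stop_format("every leaf of the tree must have a non-empty name.")
  }
  if (anyDuplicated(tips)) {
    dup <- unique(tips[duplicated(tips)])
    stop_format(sprintf("duplicate leaf name(s) in tree: %s",
                        paste(dup, collapse = ", ")))
  }
  if (!is.null(tree$root.edge)) tree$root.edge <- NULL
  el <- tree$edge.length
  if (is.null(el)) {
    stop_format("tree has no branch lengths; parse with `missing_length` to substitute a value.")
  }
  if (anyNA(el) || any(!is.finite(el))) {
    stop_format("tree has missing or non-finite branch lengths.")
  }
  if (any(el < 0)) stop_value("branch lengths must be non-negative.")

  unknown <- setdiff(env$leaf, tips)
  if (length(unknown) > 0) {
    stop_join(sprintf("environment references leaf name(s) absent from tree: %s",
                      paste(unknown, collapse = ", ")))
  }
  unlabeled <- setdiff(tips, env$leaf)
  if (length(unlabeled) > 0) {
    if (strict) {
      stop_join(sprintf(
        "tree leaf/leaves without environment entry: %s (use strict = FALSE to keep them with zero abundance)",
        paste(unlabeled, collapse = ", ")))
    } else if (!quiet) {
      warn(sprintf("keeping %d unlabeled leaf/leaves with zero abundance: %s",
                   length(unlabeled), paste(unlabeled, collapse = ", ")))
    }
  }

  structure(
    list(tree = tree, env = env, samples = unique(env$sample)),
    class = "labeled_tree")
}

# column + value checks for an environment table; returns a tibble with
# columns leaf, sample, count (integer)
validate_env_table <- function(env) {
  if (!is.data.frame(env)) stop_value("`env` must be a data frame.")
  if (!all(c("leaf", "sample") %in% names(env))) {
    stop_value("`env` must have columns `leaf` and `sample` (and optionally `count`).")
  }
  if (nrow(env) == 0) stop_value("`env` must have at least one row.")
  if (!"count" %in% names(env)) env$count <- 1L
  leaf <- as.character(env$leaf)
  sample <- as.character(env$sample)
  count <- env$count
  if (anyNA(leaf) || anyNA(sample) || any(!nzchar(leaf)) || any(!nzchar(sample))) {
    stop_value("`leaf` and `sample` must be non-empty strings.")
  }
  if (!is.numeric(count) || anyNA(count)) {
    stop_value("`count` must be numeric and non-missing.")
  }
  if (any(count != as.integer(count))) {
    stop_value("counts must be whole numbers (the expanded form creates one leaf per individual).")
  }
  if (any(count < 1)) stop_value("counts must be >= 1.")
  key <- paste(leaf, sample, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop_value(sprintf("duplicated (leaf, sample) entry: (%s)",
                       gsub("\r", ", ", dup, fixed = TRUE)))
  }
  tibble(leaf = leaf, sample = sample, count = as.integer(count))
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat(sprintf("<labeled_tree> %d leaves, %d samples, %d individuals\n",
              length(x$tree$tip.label), length(x$samples), sum(x$env$count)))
  cat("samples:", paste(x$samples, collapse = ", "), "\n")
  tot <- vapply(split(x$env$count, x$env$sample)[x$samples], sum, 0L)
  cat("totals: ", paste(sprintf("%s=%d", names(tot), tot), collapse = ", "), "\n")
  invisible(x)
}

#' Root-to-leaf path lengths
#'
#' Sums branch lengths along the path from the root to each leaf. These
#' depths appear in the normalization denominator of the weighted UniFrac
#' distance.
#'
#' @param tree A `phylo` object or a `labeled_tree`.
#' @return A tibble with columns `leaf` and `depth`, one row per leaf in
#'   tip order.
#' @examples
#' leaf_depths(parse_newick("((A1:0,A2:0):0.1,B:0.1);"))
#' @export
leaf_depths <- function(tree) {
  phy <- if (inherits(tree, "labeled_tree")) tree$tree else tree
  if (!inherits(phy, "phylo")) stop_value("`tree` must be a phylo or labeled_tree.")
  ntip <- length(phy$tip.label)
  d <- ape::node.depth.edgelength(phy)[seq_len(ntip)]
  tibble(leaf = phy$tip.label, depth = d)
}

# per-tip count matrix (ntip x length(samples)) in tip order; `samples` may
# repeat (e.g. a self-comparison), so columns are filled one at a time
tip_count_matrix <- function(lt, samples = lt$samples) {
  tips <- lt$tree$tip.label
  m <- matrix(0, nrow = length(tips), ncol = length(samples),
              dimnames = list(tips, samples))
  for (j in seq_along(samples)) {
    e <- lt$env[lt$env$sample == samples[j], , drop = FALSE]
    m[match(e$leaf, tips), j] <- e$count
  }
  m
}

## ---- internal recursive tree form -----------------------------------------
## A node is list(name = chr, length = dbl, children = list of nodes).
## Used by the compact<->expanded transform and the fixture generator;
## conversion to/from phylo keeps child order, so edge enumeration (and with
## it floating-point accumulation order) is deterministic.

tl_node <- function(name = "", length = 0, children = list()) {
  list(name = name, length = length, children = children)
}

phylo_to_tl <- function(phy) {
  ntip <- length(phy$tip.label)
  nlab <- phy$node.label %||% character(0)
  kids <- vector("list", ntip + phy$Nnode)
  elen <- numeric(ntip + phy$Nnode)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
    kids[[p]] <- c(kids[[p]], ch)
    elen[ch] <- phy$edge.length[i]
  }
  node_name <- function(id) {
    if (id <= ntip) phy$tip.label[id]
    else if (length(nlab) >= id - ntip) nlab[id - ntip] %||% ""
    else ""
  }
  build <- function(id) {
    nm <- node_name(id)
    if (is.na(nm)) nm <- ""
    tl_node(nm, elen[id], lapply(kids[[id]], build))
  }
  root <- ntip + 1L
  if (ntip == 1L) {
    # degenerate single-leaf tree: the root's sole child is the leaf
    return(tl_node(phy$tip.label[1], phy$edge.length[1]))
  }
  out <- build(root)
  out$length <- 0  # root edge ignored
  out
}

tl_to_phylo <- function(tl) {
  if (length(tl$children) == 0) {
    # single-leaf tree: represent as a one-tip phylo with a root node
    return(structure(
      list(edge = matrix(c(2L, 1L), 1, 2), tip.label = tl$name,
           edge.length = tl$length, Nnode = 1L),
      class = "phylo", order = "cladewise"))
  }
  tips <- character(0); node_names <- character(0)
  # first pass: count tips to number internals after them
  count_tips <- function(n) {
    if (length(n$children) == 0) 1L
    else sum(vapply(n$children, count_tips, 0L))
  }
  ntip <- count_tips(tl)
  edge_p <- integer(0); edge_c <- integer(0); edge_l <- numeric(0)
  tip_i <- 0L; node_i <- ntip
  rec <- function(n) {
    # returns the id assigned to n; appends edges parent->child in child order
    if (length(n$children) == 0) {
      tip_i <<- tip_i + 1L
      tips[tip_i] <<- n$name
      return(tip_i)
    }
    node_i <<- node_i + 1L
    my <- node_i
    node_names[my - ntip] <<- n$name
    for (ch in n$children) {
      pos <- length(edge_p) + 1L
      edge_p[pos] <<- my
      # reserve the slot before recursing so edges stay in preorder
      edge_c[pos] <<- NA_integer_
      edge_l[pos] <<- ch$length
      edge_c[pos] <<- rec(ch)
    }
    my
  }
  rec(tl)
  phy <- structure(
    list(edge = cbind(edge_p, edge_c, deparse.level = 0),
         tip.label = tips, edge.length = edge_l, Nnode = node_i - ntip),
    class = "phylo", order = "cladewise")
  if (any(nzchar(node_names))) phy$node.label <- node_names
  phy
}
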
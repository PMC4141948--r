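## Distance engine.
##
## All distances are computed from per-edge abundance tallies obtained by a
## single post-order accumulation pass. For samples A and B with totals A_T
## and B_T and per-edge descendant tallies A_i, B_i on an edge of length b_i:
##
##   raw        u = sum_i b_i * |A_i/A_T - B_i/B_T|
##   normalized U = u / D,   D = sum_i b_i * (A_i/A_T + B_i/B_T)
##
## D equals the usual leaf form sum_j d_j (A_j/A_T + B_j/B_T) (swap the order
## of summation along each root-to-leaf path), but the per-edge form keeps
## distances on a tree and on its zero-length expansion bitwise identical:
## expansion only inserts terms that are exactly 0, and the accumulation
## order of the surviving terms (fixed post-order edge sequence) is
## preserved. Summation order is deterministic throughout.

# postorder traversal cache for a phylo
tree_engine <- function(phy) {
  z <- ape::reorder.phylo(phy, order = "postorder")
  list(edge = z$edge, el = z$edge.length,
       ntip = length(z$tip.label), nnode = z$Nnode,
       tip.label = z$tip.label)
}

# per-edge tallies for count matrix C (ntip x k); returns (nedge x k)
edge_tallies <- function(eng, C) {
  acc <- matrix(0, nrow = eng$ntip + eng$nnode, ncol = ncol(C))
  acc[seq_len(eng$ntip), ] <- C
  e <- eng$edge
  for (i in seq_len(nrow(e))) {
    acc[e[i, 1], ] <- acc[e[i, 1], ] + acc[e[i, 2], ]
  }
  acc[e[, 2], , drop = FALSE]
}

# distances for paired count-matrix columns CA, CB (ntip x P each).
# Totals must be positive; returns list(raw, normalized, denom), each length P.
engine_distances <- function(eng, CA, CB) {
  AT <- colSums(CA)
  BT <- colSums(CB)
  EA <- edge_tallies(eng, CA)
  EB <- edge_tallies(eng, CB)
  FA <- EA / rep(AT, each = nrow(EA))
  FB <- EB / rep(BT, each = nrow(EB))
  raw <- colSums(eng$el * abs(FA - FB))
  denom <- colSums(eng$el * (FA + FB))
  normalized <- ifelse(denom > 0, raw / denom, 0)
  list(raw = raw, normalized = normalized, denom = denom)
}

#' Per-branch abundance tallies
#'
#' For every branch of the tree, the total count of each sample among the
#' leaves descending through that branch — the per-branch terms of the
#' weighted UniFrac sum. Tallies satisfy the parent-sum relation: a branch's
#' tally equals the sum of its child branches' tallies plus the counts at
#' its own child node if that node is a leaf.
#'
#' @param lt A `labeled_tree`.
#' @return A tibble with one row per (branch, sample): columns `parent` and
#'   `child` (node numbers in the tree's `edge` matrix, post-order),
#'   `child_label` (leaf name or internal label, `NA` if anonymous),
#'   `branch_length`, `sample`, `count`.
#' @examples
#' fig <- figure_fixtures()
#' branch_partition(fig$fig2)
#' @export
branch_partition <- function(lt) {
  lt <- labeled_tree(lt, strict = FALSE, quiet = TRUE)
  eng <- tree_engine(lt$tree)
  C <- tip_count_matrix(lt)
  tal <- edge_tallies(eng, C)
  labs <- c(eng$tip.label,
            if (!is.null(lt$tree$node.label)) lt$tree$node.label
            else rep(NA_character_, eng$nnode))
  labs[!nzchar(labs) | is.na(labs)] <- NA_character_
  base <- tibble(
    parent = rep(eng$edge[, 1], times = length(lt$samples)),
    child = rep(eng$edge[, 2], times = length(lt$samples)),
    child_label = rep(labs[eng$edge[, 2]], times = length(lt$samples)),
    branch_length = rep(eng$el, times = length(lt$samples)),
    sample = rep(lt$samples, each = nrow(eng$edge)),
    count = as.integer(as.vector(tal)))
  base
}

#' Weighted UniFrac distance between two samples
#'
#' The raw weighted UniFrac distance is the sum over branches of the branch
#' length times the absolute difference in the fraction of each sample's
#' individuals descending through the branch. The normalized distance
#' divides by the abundance-weighted total root-to-leaf depth, scaling the
#' result to \[0, 1\]. It is 0 exactly when the two samples have identical
#' relative abundance at every leaf, and 1 when they occupy completely
#' disjoint, maximally separated parts of the tree.
#'
#' @param lt A `labeled_tree`.
#' @param sample_a,sample_b Sample names; default to the tree's first two
#'   samples when it has exactly two.
#' @return A one-row tibble: `sample_a`, `sample_b`, `raw`, `normalized`.
#' @examples
#' fig <- figure_fixtures()
#' weighted_unifrac(fig$fig2, "Sample1", "Sample2")
#' @export
weighted_unifrac <- function(lt, sample_a = NULL, sample_b = NULL) {
  lt <- labeled_tree(lt, strict = FALSE, quiet = TRUE)
  pair <- resolve_pair(lt, sample_a, sample_b)
  C <- tip_count_matrix(lt, pair)
  if (any(colSums(C) < 1)) {
    stop_value(sprintf("sample '%s' has zero total abundance.",
                       pair[colSums(C) < 1][1]))
  }
  eng <- tree_engine(lt$tree)
  d <- engine_distances(eng, C[, 1, drop = FALSE], C[, 2, drop = FALSE])
  if (d$denom <= 0) {
    stop_value("degenerate input: every individual sits at depth 0, so the normalized distance is undefined.")
  }
  tibble(sample_a = pair[1], sample_b = pair[2],
         raw = d$raw, normalized = d$normalized)
}

resolve_pair <- function(lt, sample_a, sample_b) {
  if (is.null(sample_a) && is.null(sample_b)) {
    if (length(lt$samples) != 2) {
      stop_value("specify `sample_a` and `sample_b` (tree has more than two samples).")
    }
    return(lt$samples)
  }
  pair <- c(sample_a, sample_b)
  if (length(pair) != 2) stop_value("both `sample_a` and `sample_b` are required.")
  miss <- setdiff(pair, lt$samples)
  if (length(miss) > 0) {
    stop_value(sprintf("unknown sample(s): %s", paste(miss, collapse = ", ")))
  }
  pair
}

#' All-pairs weighted UniFrac distance matrix
#'
#' @param lt A `labeled_tree` with at least two samples.
#' @param normalized Return normalized (default) or raw distances.
#' @return A symmetric numeric matrix with zero diagonal, rows and columns
#'   named by sample.
#' @examples
#' fig <- figure_fixtures()
#' unifrac_matrix(fig$fig2)
#' @export
unifrac_matrix <- function(lt, normalized = TRUE) {
  lt <- labeled_tree(lt, strict = FALSE, quiet = TRUE)
  s <- lt$samples
  if (length(s) < 2) stop_value("need at least two samples.")
  m <- matrix(0, length(s), length(s), dimnames = list(s, s))
  for (ij in combn(length(s), 2, simplify = FALSE)) {
    d <- weighted_unifrac(lt, s[ij[1]], s[ij[2]])
    v <- if (normalized) d$normalized else d$raw
    m[ij[1], ij[2]] <- v
    m[ij[2], ij[1]] <- v
  }
  m
}

#' Heatmap of a UniFrac distance matrix
#'
#' @param m A symmetric distance matrix as returned by [unifrac_matrix()].
#' @return A ggplot object.
#' @export
plot_unifrac_matrix <- function(m) {
  df <- as_tibble(as.table(m), .name_repair = ~ c("sample_a", "sample_b", "distance"))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$distance)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#c0392b",
                                 limits = c(0, max(m, 1))) +
    ggplot2::labs(x = NULL, y = NULL, fill = "wUniFrac") +
    ggplot2::theme_minimal()
}
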
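#' Specification for a random labeled-tree fixture
#'
#' Collects the knobs of the synthetic generator: tree size, number of
#' samples, abundance range, branch-length range, and the fraction of
#' branches forced to length exactly 0 (the expanded-form signature).
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param n_samples Number of samples (>= 2).
#' @param max_count Upper bound for abundance counts (uniform on
#'   `1:max_count`).
#' @param branch_length_range Length-2 numeric, lower bound >= 0; branch
#'   lengths are drawn uniformly on this interval (arbitrary distance
#'   units).
#' @param zero_branch_fraction Probability that a branch length is set to
#'   exactly 0 instead of a uniform draw.
#' @param multi_label_prob Probability that a leaf carries a second sample
#'   label.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_leaves, n_samples = 2, max_count = 4,
                         branch_length_range = c(0.05, 1),
                         zero_branch_fraction = 0,
                         multi_label_prob = 0.2, seed = 1) {
  if (!is.numeric(n_leaves) || n_leaves < 2) stop_value("`n_leaves` must be >= 2.")
  if (!is.numeric(n_samples) || n_samples < 2) stop_value("`n_samples` must be >= 2.")
  if (n_samples > n_leaves * n_samples) stop_value("infeasible spec.")
  if (!is.numeric(max_count) || max_count < 1) stop_value("`max_count` must be >= 1.")
  if (length(branch_length_range) != 2 || branch_length_range[1] < 0 ||
      diff(branch_length_range) < 0) {
    stop_value("`branch_length_range` must be c(low, high) with 0 <= low <= high.")
  }
  if (zero_branch_fraction < 0 || zero_branch_fraction > 1) {
    stop_value("`zero_branch_fraction` must be in [0, 1].")
  }
  structure(
    list(n_leaves = as.integer(n_leaves), n_samples = as.integer(n_samples),
         max_count = as.integer(max_count),
         branch_length_range = as.numeric(branch_length_range),
         zero_branch_fraction = zero_branch_fraction,
         multi_label_prob = multi_label_prob, seed = as.integer(seed)),
    class = "fixture_spec")
}

#' Generate a random labeled tree
#'
#' Builds a random rooted tree by recursive bifurcation (with occasional
#' multifurcation), draws branch lengths uniformly on the spec's range
#' (with the spec'd fraction forced to exactly 0), assigns each leaf one or
#' two sample labels with counts uniform on `1:max_count`, and guarantees
#' every sample appears at at least one leaf. Output is deterministic for a
#' given spec and always passes [labeled_tree()] validation.
#'
#' @param spec A [fixture_spec()].
#' @return A `labeled_tree`.
#' @examples
#' gen_labeled_tree(fixture_spec(n_leaves = 6, n_samples = 3, seed = 42))
#' @export
gen_labeled_tree <- function(spec) {
  if (!inherits(spec, "fixture_spec")) stop_value("`spec` must be a fixture_spec.")
  withr::with_seed(spec$seed, {
    rlen <- function() {
      if (stats::runif(1) < spec$zero_branch_fraction) 0
      else stats::runif(1, spec$branch_length_range[1], spec$branch_length_range[2])
    }
    build <- function(idx) {
      if (length(idx) == 1) {
        return(tl_node(sprintf("t%d", idx), rlen()))
      }
      k <- if (length(idx) >= 3 && stats::runif(1) < 0.15) 3L else 2L
      k <- min(k, length(idx))
      grp <- sample(rep(seq_len(k), length.out = length(idx)))
      kids <- lapply(split(idx, grp), build)
      tl_node("", rlen(), unname(kids))
    }
    tl <- build(seq_len(spec$n_leaves))
    tl$length <- 0

    samples <- sprintf("S%d", seq_len(spec$n_samples))
    rows <- list()
    for (i in seq_len(spec$n_leaves)) {
      labs <- sample(samples, 1)
      if (spec$n_samples > 1 && stats::runif(1) < spec$multi_label_prob) {
        labs <- c(labs, sample(setdiff(samples, labs), 1))
      }
      for (s in labs) {
        rows[[length(rows) + 1L]] <-
          list(leaf = sprintf("t%d", i), sample = s,
               count = sample.int(spec$max_count, 1))
      }
    }
    env <- tibble(leaf = map_chr(rows, "leaf"),
                  sample = map_chr(rows, "sample"),
                  count = vapply(rows, function(r) as.integer(r$count), 0L))
    # guarantee coverage of every sample
    missing <- setdiff(samples, env$sample)
    for (s in missing) {
      leaf <- sprintf("t%d", sample.int(spec$n_leaves, 1))
      if (any(env$leaf == leaf & env$sample == s)) next
      env <- bind_rows(env, tibble(leaf = leaf, sample = s,
                                   count = sample.int(spec$max_count, 1)))
    }
    labeled_tree(tl_to_phylo(tl), env)
  })
}

#' The worked-example trees
#'
#' The four two-sample toy inputs used throughout the package's tests and
#' documentation:
#'
#' * `fig1` — two leaves `A`, `B` at branch length 0.1; `A` in `Sample1`,
#'   `B` in `Sample2`, implicit counts of 1.
#' * `fig2` — same tree, but `A` found 4 times in `Sample1` and `B` 4 times
#'   in `Sample2` (compact form).
#' * `fig3` — the expanded form of `fig2`: eight unit-count leaves attached
#'   by zero-length branches, four per sample (`fig3` is literally
#'   `expand_tree(fig2)`).
#' * `fig2_scaled` — the compact tree with counts of 10,000 and branch
#'   lengths 0.9: two large, disjoint, phylogenetically distant
#'   communities, for which compact-semantics testing still returns p = 1.
#'
#' @return A named list of `labeled_tree` objects.
#' @examples
#' figure_fixtures()$fig2
#' @export
figure_fixtures <- function() {
  two_leaf <- function(len, count) {
    labeled_tree(
      parse_newick(sprintf("(A:%s,B:%s);", len, len)),
      tibble(leaf = c("A", "B"), sample = c("Sample1", "Sample2"),
             count = as.integer(c(count, count))))
  }
  fig2 <- two_leaf("0.1", 4)
  list(
    fig1 = two_leaf("0.1", 1),
    fig2 = fig2,
    fig3 = expand_tree(fig2),
    fig2_scaled = two_leaf("0.9", 10000))
}
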
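## Permutation significance test.
##
## The p-value is the fraction of random label assignments whose
## between-sample distance is greater than or equal to the observed one.
## Two permutation semantics are supported:
##
##  * compact  — each leaf's entire annotation bundle (all its sample:count
##    pairs) moves as one indivisible unit; abundance counts stay bound to
##    their sample labels during shuffling.
##  * expanded — the tree is first converted to expanded form (one
##    unit-count leaf per individual, zero-length branches) and the unit
##    labels are shuffled across the expanded leaves.
##
## On semantically identical input the two can disagree dramatically: on the
## two-leaf tree with counts (4, 4), compact enumeration has only 2 equally
## extreme assignments (p = 1), while the expanded form has 70 distinct
## assignments of which only 2 reach the observed distance (p = 2/70).

#' Randomly reassign leaf annotations
#'
#' Draws one uniformly random permutation of the leaf annotation multiset:
#' whole sample:count bundles in `compact` mode, unit labels in `expanded`
#' mode (the tree must then already be in expanded form). Topology, branch
#' lengths and per-sample totals are conserved. Uses R's RNG; seed with
#' [set.seed()] for reproducibility.
#'
#' @param lt A `labeled_tree`.
#' @param mode `"compact"` or `"expanded"`.
#' @param scope Shuffle bundles across `"all"` leaves (default; leaves with
#'   no annotation participate as empty slots) or only across `"occupied"`
#'   leaves.
#' @return A `labeled_tree` with permuted annotations.
#' @export
shuffle_labels <- function(lt, mode = c("compact", "expanded"),
                           scope = c("all", "occupied")) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  lt <- labeled_tree(lt, strict = FALSE, quiet = TRUE)
  if (mode == "expanded" && !is_expanded_form(lt)) {
    stop_value("expanded-mode shuffling requires a tree in expanded form; apply expand_tree() first.")
  }
  tips <- lt$tree$tip.label
  occupied <- tips %in% lt$env$leaf
  pos <- if (scope == "all") seq_along(tips) else which(occupied)
  perm <- sample(pos)
  relab <- setNames(tips[perm], tips[pos])  # old leaf name -> new leaf name
  env2 <- lt$env
  env2$leaf <- ifelse(env2$leaf %in% names(relab),
                      relab[env2$leaf], env2$leaf)
  labeled_tree(lt$tree, env2, strict = FALSE, quiet = TRUE)
}

#' UniFrac permutation significance test
#'
#' Tests whether two samples differ by comparing their weighted UniFrac
#' distance with the distribution obtained under random reassignment of the
#' leaf annotations. The reported p-value is the number of null assignments
#' with distance greater than or equal to the observed distance, divided by
#' the number of assignments evaluated.
#'
#' `method = "exact"` enumerates every distinct assignment of the
#' annotation multiset exactly once (uniform over distinct assignments,
#' which is the distribution induced by a uniform shuffle); `method = "mc"`
#' draws `n_perm` independent random shuffles. The "greater or equal"
#' comparison uses a relative tolerance of 1e-9 on the equality side so
#' that symmetric images of the observed labeling tie exactly.
#'
#' When the tree carries more than two samples, only the two tested
#' samples' counts enter the distance; annotation bundles are restricted
#' accordingly before shuffling (other samples' individuals are excluded
#' from the pair's test).
#'
#' @param lt A `labeled_tree`.
#' @param sample_a,sample_b The pair to test (defaults to the only two
#'   samples when exactly two are present).
#' @param mode Permutation semantics, `"compact"` or `"expanded"` (see
#'   Details). The expanded mode expands internally; passing an already
#'   expanded tree is a no-op.
#' @param method `"exact"` enumeration or `"mc"` Monte-Carlo.
#' @param n_perm Number of random labelings for `method = "mc"`
#'   (default 100, the web-service default — statistically coarse).
#' @param seed Optional integer seed recorded in the result (MC only).
#' @param scope Shuffle across `"all"` leaves or only `"occupied"` ones.
#' @param plus_one Use the (n_ge + 1) / (n_null + 1) permutation-test
#'   estimator instead of the plain fraction. Off by default to match the
#'   historical definition; the plain estimator can report p = 0.
#' @param normalized Compare normalized (default) or raw distances.
#' @param cap Refuse exact enumeration beyond this many distinct
#'   assignments (default 1e6); use `method = "mc"` instead.
#' @return An object of class `unifrac_signif`; see [tidy()] and
#'   [glance()] methods, `print()`, and [ggplot2::autoplot()].
#' @examples
#' fig <- figure_fixtures()
#' unifrac_signif(fig$fig2, mode = "compact", method = "exact")
#' unifrac_signif(fig$fig3, mode = "expanded", method = "exact")
#' @export
unifrac_signif <- function(lt, sample_a = NULL, sample_b = NULL,
                           mode = c("compact", "expanded"),
                           method = c("exact", "mc"),
                           n_perm = 100, seed = NULL,
                           scope = c("all", "occupied"),
                           plus_one = FALSE, normalized = TRUE,
                           cap = 1e6) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  scope <- match.arg(scope)
  lt <- labeled_tree(lt, strict = FALSE, quiet = TRUE)
  pair <- resolve_pair(lt, sample_a, sample_b)
  obs <- weighted_unifrac(lt, pair[1], pair[2])  # validates pair, degeneracy

  # restrict annotations to the tested pair, then expand if requested
  env_pair <- lt$env[lt$env$sample %in% pair, , drop = FALSE]
  sub <- labeled_tree(lt$tree, env_pair, strict = FALSE, quiet = TRUE)
  if (mode == "expanded") sub <- expand_tree(sub)
  eng <- tree_engine(sub$tree)
  C <- tip_count_matrix(sub, pair)

  # bundle ids per shuffled slot
  tips <- sub$tree$tip.label
  occupied <- rowSums(C) > 0
  pos <- if (scope == "all") seq_along(tips) else which(occupied)
  if (length(pos) < 2) stop_value("fewer than two shuffleable leaves.")
  key <- paste(C[pos, 1], C[pos, 2], sep = "/")
  uk <- unique(key)
  g <- match(key, uk)                       # bundle id per slot
  U <- C[pos[match(uk, key)], , drop = FALSE]  # representative counts per id

  if (method == "exact") {
    A <- multiset_permutations(g, cap = cap)   # n_distinct x m matrix of ids
    n_null <- nrow(A)
    used_seed <- NULL
  } else {
    if (!is.numeric(n_perm) || n_perm < 1) stop_value("`n_perm` must be >= 1.")
    n_perm <- as.integer(n_perm)
    draw <- function() {
      matrix(vapply(seq_len(n_perm), function(i) sample(g), integer(length(g))),
             nrow = length(g))
    }
    if (!is.null(seed)) {
      Am <- withr::with_seed(seed, draw())
    } else {
      Am <- draw()
    }
    A <- t(Am)
    n_null <- n_perm
    used_seed <- seed
  }

  # build count matrices for all null assignments and evaluate in one pass
  P <- nrow(A)
  CA <- matrix(C[, 1], nrow = nrow(C), ncol = P)
  CB <- matrix(C[, 2], nrow = nrow(C), ncol = P)
  CA[pos, ] <- t(matrix(U[A, 1], nrow = P))
  CB[pos, ] <- t(matrix(U[A, 2], nrow = P))
  d <- engine_distances(eng, CA, CB)
  null_d <- if (normalized) d$normalized else d$raw
  obs_d <- if (normalized) obs$normalized else obs$raw

  thr <- obs_d - 1e-9 * abs(obs_d)
  n_ge <- sum(null_d >= thr)
  p <- if (plus_one) (n_ge + 1) / (n_null + 1) else n_ge / n_null

  structure(
    list(observed = obs, p_value = p, n_null = n_null, n_ge = n_ge,
         mode = mode, method = if (method == "mc") "monte_carlo" else "exact",
         seed = used_seed, plus_one = plus_one, scope = scope,
         normalized = normalized, null_distances = null_d,
         sample_a = pair[1], sample_b = pair[2]),
    class = "unifrac_signif")
}

#' Significance tests for every sample pair
#'
#' Runs [unifrac_signif()] for each unordered pair of samples. For each
#' pair only that pair's counts participate. P-values are uncorrected by
#' default; `p_adjust = "bonferroni"` adds an adjusted column.
#'
#' @inheritParams unifrac_signif
#' @param p_adjust `"none"` (default) or `"bonferroni"`.
#' @param ... Passed on to [unifrac_signif()].
#' @return A tibble with one row per pair: the [tidy()] columns plus
#'   `p_adjusted` when requested.
#' @export
pairwise_unifrac_signif <- function(lt, mode = c("compact", "expanded"),
                                    method = c("exact", "mc"),
                                    n_perm = 100, seed = NULL,
                                    p_adjust = c("none", "bonferroni"), ...) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  lt <- labeled_tree(lt, strict = FALSE, quiet = TRUE)
  s <- lt$samples
  if (length(s) < 2) stop_value("need at least two samples.")
  pairs <- combn(s, 2, simplify = FALSE)
  run <- function() {
    map(pairs, function(pr) {
      tidy(unifrac_signif(lt, pr[1], pr[2], mode = mode, method = method,
                          n_perm = n_perm, seed = NULL, ...))
    })
  }
  res <- if (!is.null(seed)) withr::with_seed(seed, run()) else run()
  out <- bind_rows(res)
  out$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  if (p_adjust == "bonferroni") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "bonferroni")
  }
  out
}

# all distinct arrangements of the multiset `ids` (integer vector), as a
# matrix with one arrangement per row; errors beyond `cap` rows
multiset_permutations <- function(ids, cap = 1e6) {
  n <- length(ids)
  tab <- tabulate(ids)
  total <- 1
  rem <- n
  for (t in tab) {
    total <- total * choose(rem, t)
    rem <- rem - t
  }
  total <- round(total)
  if (total > cap) {
    stop_value(sprintf(
      "exact enumeration needs %s distinct assignments (cap %s); use method = 'mc'.",
      format(total, big.mark = ","), format(cap, big.mark = ",")))
  }
  out <- matrix(0L, nrow = total, ncol = n)
  counts <- tab
  arrangement <- integer(n)
  row <- 0L
  rec <- function(depth) {
    if (depth > n) {
      row <<- row + 1L
      out[row, ] <<- arrangement
      return(invisible())
    }
    for (id in seq_along(counts)) {
      if (counts[id] > 0L) {
        counts[id] <<- counts[id] - 1L
        arrangement[depth] <<- id
        rec(depth + 1L)
        counts[id] <<- counts[id] + 1L
      }
    }
  }
  rec(1L)
  out
}

#' @export
print.unifrac_signif <- function(x, ...) {
  cat(sprintf("<unifrac_signif> %s vs %s\n", x$sample_a, x$sample_b))
  cat(sprintf("  observed %s distance: %.6g (raw %.6g)\n",
              if (x$normalized) "normalized" else "raw",
              if (x$normalized) x$observed$normalized else x$observed$raw,
              x$observed$raw))
  cat(sprintf("  semantics: %s; method: %s%s; scope: %s\n",
              x$mode, x$method,
              if (!is.null(x$seed)) sprintf(" (seed %d)", x$seed) else "",
              x$scope))
  cat(sprintf("  p = %.6g  (%d of %d null labelings >= observed%s)\n",
              x$p_value, x$n_ge, x$n_null,
              if (x$plus_one) "; +1 estimator" else ""))
  invisible(x)
}

#' @rdname unifrac_signif
#' @param x A `unifrac_signif` object.
#' @param ... Unused, for generic consistency.
#' @export
tidy.unifrac_signif <- function(x, ...) {
  tibble(
    sample_a = x$sample_a, sample_b = x$sample_b,
    observed = if (x$normalized) x$observed$normalized else x$observed$raw,
    raw = x$observed$raw, normalized = x$observed$normalized,
    p_value = x$p_value, n_ge = x$n_ge, n_null = x$n_null,
    mode = x$mode, method = x$method,
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed))
}

#' @rdname unifrac_signif
#' @export
glance.unifrac_signif <- function(x, ...) {
  tibble(p_value = x$p_value, n_null = x$n_null, mode = x$mode,
         method = x$method,
         null_median = stats::median(x$null_distances),
         null_max = max(x$null_distances))
}

#' Null-distribution plot for a significance test
#'
#' Histogram of the permutation null distances with the observed distance
#' marked.
#'
#' @param object A `unifrac_signif` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.unifrac_signif <- function(object, ...) {
  df <- tibble(distance = object$null_distances)
  obs <- if (object$normalized) object$observed$normalized else object$observed$raw
  ggplot2::ggplot(df, ggplot2::aes(.data$distance)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = obs, colour = "#c0392b", linewidth = 1) +
    ggplot2::labs(
      title = sprintf("%s vs %s (%s semantics, %s)", object$sample_a,
                      object$sample_b, object$mode, object$method),
      subtitle = sprintf("observed = %.4g, p = %.4g (%d/%d)", obs,
                         object$p_value, object$n_ge, object$n_null),
      x = "null weighted UniFrac distance", y = "labelings") +
    ggplot2::theme_minimal()
}
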
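#' Convert a compact tree to its expanded form
#'
#' In the *compact* form a leaf may carry several sample labels and
#' abundance counts greater than one. The *expanded* form represents every
#' individual as its own unit-count leaf: each leaf with total count > 1 or
#' with more than one sample label becomes an interior node whose children
#' are new leaves attached by branches of length exactly 0, one per
#' individual, each labeled with that individual's sample. Because the new
#' branches have length zero, the two forms are semantically identical
#' communities (distance zero means identity — the coincidence axiom), and
#' every weighted UniFrac distance is unchanged by the transform.
#'
#' Generated leaf names follow the deterministic scheme
#' `<leaf>__<sample>__<k>` for `k = 1..count`; a collision with an existing
#' name is an error rather than silently renamed. Leaves that already carry
#' a single label with count 1 (and unlabeled leaves, in lenient trees) are
#' left untouched, so the transform is idempotent.
#'
#' @param lt A `labeled_tree`.
#' @return The expanded `labeled_tree` (all counts equal 1).
#' @examples
#' fig <- figure_fixtures()
#' write_newick(expand_tree(fig$fig2))
#' @seealso [collapse_tree()] for the inverse transform.
#' @export
expand_tree <- function(lt) {
  lt <- labeled_tree(lt, strict = FALSE, quiet = TRUE)
  env <- lt$env
  bundles <- split(seq_len(nrow(env)), env$leaf)
  tips <- lt$tree$tip.label
  needs <- vapply(tips, function(tp) {
    rows <- bundles[[tp]]
    !is.null(rows) && (length(rows) > 1L || env$count[rows] > 1L)
  }, TRUE)
  if (!any(needs)) return(lt)

  all_names <- c(tips, lt$tree$node.label %||% character(0))
  new_rows <- list()
  expand_leaf <- function(node) {
    rows <- bundles[[node$name]]
    kids <- list()
    for (r in rows) {
      s <- env$sample[r]
      for (k in seq_len(env$count[r])) {
        nm <- sprintf("%s__%s__%d", node$name, s, k)
        if (nm %in% all_names) {
          stop_value(sprintf("generated leaf name '%s' collides with an existing name.", nm))
        }
        kids[[length(kids) + 1L]] <- tl_node(nm, 0)
        new_rows[[length(new_rows) + 1L]] <<- list(leaf = nm, sample = s)
      }
    }
    tl_node(node$name, node$length, kids)
  }
  rec <- function(node) {
    if (length(node$children) == 0) {
      if (isTRUE(needs[[node$name]])) expand_leaf(node) else node
    } else {
      node$children <- lapply(node$children, rec)
      node
    }
  }
  tl <- rec(phylo_to_tl(lt$tree))

  keep <- env[!needs[env$leaf], , drop = FALSE]
  env2 <- bind_rows(
    keep,
    tibble(leaf = map_chr(new_rows, "leaf"),
           sample = map_chr(new_rows, "sample"), count = 1L))
  labeled_tree(tl_to_phylo(tl), env2, strict = FALSE, quiet = TRUE)
}

#' Collapse zero-length unit leaves into abundance counts
#'
#' The inverse of [expand_tree()]. A *pre-terminal* node is an interior node
#' all of whose children are leaves. Every pre-terminal node whose child
#' branches all have length exactly 0 is collapsed into a single leaf whose
#' environment entry gives, for each sample, the summed count of the
#' children carrying that label (for unit-count children this is simply the
#' number of children per label). Collapsing proceeds bottom-up to a fixed
#' point, so stacked levels of zero-length branches collapse fully; subtrees
#' with any positive child branch length are left untouched — a tree whose
#' short branches are merely *near* zero is a genuinely different tree.
#'
#' The zero test is exact equality by default; `tol` admits an explicit
#' tolerance for branch lengths to treat as zero.
#'
#' @param lt A `labeled_tree`.
#' @param tol Branch lengths `<= tol` count as zero (default 0, exact).
#' @return The collapsed (canonical compact form) `labeled_tree`.
#' @export
collapse_tree <- function(lt, tol = 0) {
  lt <- labeled_tree(lt, strict = FALSE, quiet = TRUE)
  env <- lt$env
  rows_of <- split(seq_len(nrow(env)), env$leaf)
  drop_rows <- integer(0)

  rec <- function(node) {
    if (length(node$children) == 0) return(node)
    node$children <- lapply(node$children, rec)
    all_leaf <- all(vapply(node$children, function(ch) length(ch$children) == 0, TRUE))
    if (!all_leaf) return(node)
    all_zero <- all(vapply(node$children, function(ch) ch$length <= tol, TRUE))
    if (!all_zero) return(node)
    child_names <- vapply(node$children, function(ch) ch$name, "")
    missing <- child_names[!child_names %in% names(rows_of)]
    if (length(missing) > 0) {
      stop_join(sprintf("cannot collapse: child leaf/leaves without environment entry: %s",
                        paste(missing, collapse = ", ")))
    }
    tally <- list()
    for (cn in child_names) {
      for (r in rows_of[[cn]]) {
        s <- env$sample[r]
        tally[[s]] <- (tally[[s]] %||% 0L) + env$count[r]
      }
    }
    drop_rows <<- c(drop_rows, unlist(rows_of[child_names], use.names = FALSE))
    new_name <- if (nzchar(node$name)) node$name else child_names[1]
    # append the tallied entry and point the (possibly reused) name at it,
    # so a parent-level collapse can absorb this new leaf in turn
    idx <- nrow(env) + seq_along(tally)
    env <<- bind_rows(env, tibble(leaf = new_name,
                                  sample = names(tally),
                                  count = as.integer(unlist(tally))))
    rows_of[[new_name]] <<- idx
    tl_node(new_name, node$length)
  }

  tl <- rec(phylo_to_tl(lt$tree))
  env2 <- env[setdiff(seq_len(nrow(env)), drop_rows), , drop = FALSE]
  labeled_tree(tl_to_phylo(tl), env2, strict = FALSE, quiet = TRUE)
}

# TRUE when every leaf carries exactly one label with count 1
is_expanded_form <- function(lt) {
  all(lt$env$count == 1L) && !anyDuplicated(lt$env$leaf)
}
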
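# Independent oracles used to cross-check the package implementation.
#
# oracle_wunifrac recomputes the weighted UniFrac distance by direct
# recursion over the phylo edge matrix, using the per-LEAF depth form of the
# normalization denominator (the package uses the per-edge form), so the two
# routes share no code.
#
# oracle_exact_p enumerates ALL n! orderings of the annotation items (not
# the package's distinct-multiset enumeration) and counts distance ties
# with multiplicity, which must give the same p-value.

oracle_wunifrac <- function(phy, env, a, b) {
  ntip <- length(phy$tip.label)
  kids <- vector("list", ntip + phy$Nnode)
  elen <- numeric(ntip + phy$Nnode)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    kids[[p]] <- c(kids[[p]], phy$edge[i, 2])
    elen[phy$edge[i, 2]] <- phy$edge.length[i]
  }
  cnt <- function(leaf, s) sum(env$count[env$leaf == leaf & env$sample == s])
  AT <- sum(env$count[env$sample == a])
  BT <- sum(env$count[env$sample == b])
  raw <- 0
  den <- 0
  rec <- function(id, depth) {
    if (id <= ntip) {
      ca <- cnt(phy$tip.label[id], a)
      cb <- cnt(phy$tip.label[id], b)
      den <<- den + depth * (ca / AT + cb / BT)
      return(c(ca, cb))
    }
    tot <- c(0, 0)
    for (ch in kids[[id]]) {
      sub <- rec(ch, depth + elen[ch])
      raw <<- raw + elen[ch] * abs(sub[1] / AT - sub[2] / BT)
      tot <- tot + sub
    }
    tot
  }
  if (ntip == 1) {
    rec(1, elen[1])
  } else {
    rec(ntip + 1L, 0)
  }
  c(raw = raw, normalized = if (den > 0) raw / den else 0)
}

# all n! permutations of seq_len(n) (rows), n <= 7
all_orderings <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_orderings(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)), deparse.level = 0)
  }))
}

# brute-force exact p-value over all orderings of the annotation items.
# compact: items are whole per-leaf bundles placed on leaves.
# expanded: items are unit labels placed on individual "slots" (one slot per
# individual); distances are evaluated on the ORIGINAL tree by tallying
# slot labels back onto their leaves (valid because zero-length expansion
# does not change weighted UniFrac).
oracle_exact_p <- function(lt, a, b, mode = c("compact", "expanded")) {
  mode <- match.arg(mode)
  env <- lt$env[lt$env$sample %in% c(a, b), , drop = FALSE]
  tips <- lt$tree$tip.label
  if (mode == "compact") {
    slot_of <- seq_along(tips)                       # one slot per leaf
    bundles <- lapply(tips, function(tp) env[env$leaf == tp, , drop = FALSE])
    items <- bundles
    place <- function(ordering) {
      # ordering[i]: item placed on slot i
      do.call(rbind, lapply(seq_along(tips), function(i) {
        bd <- items[[ordering[i]]]
        if (nrow(bd) == 0) return(NULL)
        bd$leaf <- tips[i]
        bd
      }))
    }
  } else {
    slots <- do.call(rbind, lapply(seq_along(tips), function(i) {
      rows <- env[env$leaf == tips[i], , drop = FALSE]
      if (nrow(rows) == 0) {
        data.frame(leaf = tips[i], n = 1L)            # empty slot
      } else {
        data.frame(leaf = tips[i], n = sum(rows$count))
      }
    }))
    slot_leaf <- rep(slots$leaf, slots$n)
    items <- c(rep(env$sample, env$count),
               rep(NA_character_, length(slot_leaf) - sum(env$count)))
    place <- function(ordering) {
      lab <- items[ordering]
      keep <- !is.na(lab)
      if (!any(keep)) return(NULL)
      agg <- stats::aggregate(list(count = rep(1L, sum(keep))),
                              by = list(leaf = slot_leaf[keep], sample = lab[keep]),
                              FUN = sum)
      agg
    }
  }
  n <- length(items)
  # cheap canonical key per ordering so the distance is evaluated once per
  # distinct configuration; the count of orderings still includes every one
  if (mode == "compact") {
    sig <- vapply(items, function(bd) {
      if (nrow(bd) == 0) "-" else paste(bd$sample, bd$count, sep = ":", collapse = ",")
    }, "")
    key_of <- function(ordering) paste(sig[ordering], collapse = "|")
  } else {
    key_of <- function(ordering) {
      lab <- items[ordering]
      paste(sort(paste(slot_leaf, lab)[!is.na(lab)]), collapse = "|")
    }
  }
  obs <- oracle_wunifrac(lt$tree, env, a, b)[["normalized"]]
  ords <- all_orderings(n)
  memo <- new.env(parent = emptyenv())
  d_of <- function(ordering) {
    key <- key_of(ordering)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    e2 <- place(ordering)
    v <- if (is.null(e2)) 0 else oracle_wunifrac(lt$tree, e2, a, b)[["normalized"]]
    memo[[key]] <- v
    v
  }
  d <- vapply(seq_len(nrow(ords)), function(i) d_of(ords[i, ]), 0)
  sum(d >= obs - 1e-9 * abs(obs)) / nrow(ords)
}

expect_same_tree <- function(x, y) {
  expect_identical(write_newick(x), write_newick(y))
  ex <- dplyr::arrange(x$env, leaf, sample)
  ey <- dplyr::arrange(y$env, leaf, sample)
  expect_equal(as.data.frame(ex), as.data.frame(ey))
}
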
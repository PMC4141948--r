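#' Parse a Newick tree
#'
#' Reads a single rooted Newick statement into an `ape` `phylo` object.
#' A lexical pre-scan reports malformed input (unbalanced parentheses,
#' missing `;` terminator, empty leaf names) with the 1-based character
#' offset of the problem. Labels are taken literally: no quote stripping
#' and no underscore-to-space conversion, because leaf-name identity drives
#' the join against the environment file.
#'
#' Branch lengths are required; a tree with missing lengths is rejected
#' unless `missing_length` supplies an explicit substitute. Silent defaults
#' are dangerous here because exact zero-length branches carry meaning for
#' the compact/expanded transform. A root edge length, if present, is
#' ignored (treated as 0). A single-leaf statement such as `"A;"` or
#' `"A:0;"` yields a one-leaf tree at depth 0.
#'
#' @param text Newick text (one statement terminated by `;`).
#' @param missing_length `NULL` (default) to error on absent branch lengths,
#'   or a number substituted for each absent length.
#' @return A `phylo` object.
#' @examples
#' parse_newick("(A:0.1,B:0.1);")
#' @export
parse_newick <- function(text, missing_length = NULL) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    stop_value("`text` must be a single string.")
  }
  txt <- trimws(text)
  if (!nzchar(txt)) stop_format("empty Newick input.")
  scan_newick(txt)
  body <- sub(";\\s*$", "", txt)

  if (!grepl("(", body, fixed = TRUE)) {
    # single-leaf statement "A;" or "A:0.5;" — the whole tree is one node,
    # whose length is a root length and hence ignored
    name <- sub(":.*$", "", body)
    phy <- structure(
      list(edge = matrix(c(2L, 1L), 1, 2), tip.label = name,
           edge.length = 0, Nnode = 1L),
      class = "phylo", order = "cladewise")
    return(phy)
  }

  phy <- tryCatch(
    suppressWarnings(ape::read.tree(text = txt)),
    error = function(e) NULL)
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop_format(sprintf("could not parse Newick input (offset 1..%d).", nchar(txt)))
  }
  if (is.null(phy$edge.length)) {
    if (is.null(missing_length)) {
      stop_format("Newick input has no branch lengths; pass `missing_length` to substitute a value.")
    }
    phy$edge.length <- rep(as.numeric(missing_length), nrow(phy$edge))
  } else if (anyNA(phy$edge.length) || any(is.nan(phy$edge.length))) {
    if (is.null(missing_length)) {
      stop_format("Newick input has branches without lengths; pass `missing_length` to substitute a value.")
    }
    bad <- is.na(phy$edge.length) | is.nan(phy$edge.length)
    phy$edge.length[bad] <- as.numeric(missing_length)
  }
  if (!is.null(phy$root.edge)) phy$root.edge <- NULL
  phy
}

# lexical sanity scan; errors carry a character offset
scan_newick <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  n <- length(chars)
  semi <- which(chars == ";")
  if (length(semi) == 0) {
    stop_format(sprintf("missing ';' terminator at end of input (offset %d).", n))
  }
  if (semi[1] != n) {
    stop_format(sprintf("text after ';' terminator (offset %d).", semi[1] + 1L))
  }
  depth <- 0L
  prev <- ""
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop_format(sprintf("unbalanced ')' (offset %d).", i))
      }
      if (prev == "," || prev == "(") {
        stop_format(sprintf("empty leaf name before ')' (offset %d).", i))
      }
    } else if (ch == ",") {
      if (prev == "," || prev == "(") {
        stop_format(sprintf("empty leaf name before ',' (offset %d).", i))
      }
    } else if (ch == ";") {
      if (depth != 0L) {
        stop_format(sprintf("unbalanced '(' - %d unclosed at ';' (offset %d).", depth, i))
      }
    }
    if (!grepl("^\\s$", ch)) prev <- ch
  }
  invisible(TRUE)
}

#' Write a tree as Newick text
#'
#' Branch lengths are rendered with the fewest significant digits that
#' still parse back to the identical double, so
#' `parse_newick(write_newick(t))` reproduces `t` exactly and simple
#' lengths stay readable (`0.1`, not `0.10000000000000001`). Internal node
#' labels are preserved; the root carries no length.
#'
#' @param tree A `phylo` object or a `labeled_tree`.
#' @param path Optional file to write to; when `NULL` the text is returned.
#' @return The Newick string (invisibly when `path` is given).
#' @examples
#' write_newick(parse_newick("(A:0.1,B:0.1);"))
#' @export
write_newick <- function(tree, path = NULL) {
  phy <- if (inherits(tree, "labeled_tree")) tree$tree else tree
  if (!inherits(phy, "phylo")) stop_value("`tree` must be a phylo or labeled_tree.")
  ser <- function(n, is_root = FALSE) {
    body <- if (length(n$children) == 0) n$name
            else paste0("(", paste(vapply(n$children, ser, ""), collapse = ","),
                        ")", n$name)
    if (is_root) body else paste0(body, ":", shortest_exact(n$length))
  }
  tl <- phylo_to_tl(phy)
  txt <- if (length(tl$children) == 0) {
    paste0(tl$name, ":0;")  # single-leaf tree, depth 0 by convention
  } else {
    paste0(ser(tl, is_root = TRUE), ";")
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# fewest significant digits that reproduce x exactly
shortest_exact <- function(x) {
  for (d in 1:17) {
    s <- trimws(formatC(x, digits = d, format = "g"))
    if (as.numeric(s) == x) return(s)
  }
  trimws(formatC(x, digits = 17, format = "g"))
}

#' Parse a UniFrac environment table
#'
#' Environment files bind tree leaves to samples: one record per line,
#' whitespace-delimited fields `leaf sample [count]`, with the count
#' defaulting to 1 when absent. Blank lines are skipped.
#'
#' @param text Environment-file text (single string or character vector of
#'   lines).
#' @param merge_duplicates Repeated (leaf, sample) lines are an error by
#'   default; `TRUE` sums them with a warning. Silent summation would change
#'   permutation p-values, so it is opt-in.
#' @return A tibble with columns `leaf`, `sample`, `count`.
#' @examples
#' parse_env("A\tSample1\t4\nB\tSample2\t4")
#' @export
parse_env <- function(text, merge_duplicates = FALSE) {
  if (!is.character(text) || anyNA(text)) stop_value("`text` must be character.")
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  recs <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (length(f) < 2 || length(f) > 3) {
      stop_format(sprintf("line %d: expected 2 or 3 fields, found %d.", i, length(f)))
    }
    cnt <- 1L
    if (length(f) == 3) {
      cnum <- suppressWarnings(as.numeric(f[3]))
      if (is.na(cnum) || cnum != as.integer(cnum)) {
        stop_value(sprintf("line %d: count '%s' is not an integer.", i, f[3]))
      }
      if (cnum < 1) {
        stop_value(sprintf("line %d: count must be >= 1, found %s.", i, f[3]))
      }
      cnt <- as.integer(cnum)
    }
    recs[[length(recs) + 1L]] <- list(leaf = f[1], sample = f[2], count = cnt, line = i)
  }
  if (length(recs) == 0) stop_format("environment input has no records.")
  env <- tibble(
    leaf = map_chr(recs, "leaf"),
    sample = map_chr(recs, "sample"),
    count = vapply(recs, function(r) r$count, 0L))
  key <- paste(env$leaf, env$sample, sep = "\r")
  if (anyDuplicated(key)) {
    if (merge_duplicates) {
      warn("summing repeated (leaf, sample) records.")
      env <- env |>
        group_by(.data$leaf, .data$sample) |>
        summarise(count = as.integer(sum(.data$count)), .groups = "drop")
    } else {
      first_dup <- which(duplicated(key))[1]
      stop_value(sprintf(
        "line %d: repeated (leaf, sample) record (%s, %s); use merge_duplicates = TRUE to sum.",
        recs[[first_dup]]$line, env$leaf[first_dup], env$sample[first_dup]))
    }
  }
  validate_env_table(env)
}

#' Write an environment table
#'
#' Records are ordered by leaf then sample name (byte-wise, locale
#' independent) and tab-delimited, so output is deterministic and
#' `parse_env(write_env(e))` is the identity.
#'
#' @param env An environment tibble (or a `labeled_tree`, whose `env` is
#'   used).
#' @param path Optional output file.
#' @return The text (invisibly when `path` is given).
#' @export
write_env <- function(env, path = NULL) {
  if (inherits(env, "labeled_tree")) env <- env$env
  env <- validate_env_table(env)
  o <- order(env$leaf, env$sample, method = "radix")
  txt <- paste(env$leaf[o], env$sample[o], env$count[o], sep = "\t")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(paste(txt, collapse = "\n")))
  }
  paste(txt, collapse = "\n")
}

#' @rdname parse_newick
#' @param path Path to a Newick file.
#' @param ... Passed on to the corresponding parser.
#' @export
read_newick <- function(path, ...) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""), ...)
}

#' @rdname parse_env
#' @param path Path to an environment file.
#' @param ... Passed on to the corresponding parser.
#' @export
read_env <- function(path, ...) {
  parse_env(readLines(path, warn = FALSE), ...)
}
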
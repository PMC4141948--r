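test_that("compact shuffling of the two-leaf tree has exactly two states", {
  fig <- figure_fixtures()
  seen <- character(0)
  set.seed(1)
  for (i in 1:20) {
    sh <- shuffle_labels(fig$fig2, mode = "compact")
    seen <- union(seen, write_env(sh))
  }
  expect_setequal(seen, c("A\tSample1\t4\nB\tSample2\t4",
                          "A\tSample2\t4\nB\tSample1\t4"))
})

test_that("shuffling conserves per-sample totals and tree shape", {
  for (s in 1:10) {
    lt <- gen_labeled_tree(fixture_spec(n_leaves = 7, n_samples = 3, seed = s))
    set.seed(s)
    sh <- shuffle_labels(lt, mode = "compact")
    expect_identical(write_newick(sh$tree), write_newick(lt$tree))
    tot <- function(x) sapply(split(x$env$count, x$env$sample), sum)
    expect_equal(tot(sh)[sort(lt$samples)], tot(lt)[sort(lt$samples)])
  }
})

test_that("expanded-mode shuffling rejects non-expanded trees", {
  fig <- figure_fixtures()
  expect_error(shuffle_labels(fig$fig2, mode = "expanded"),
               class = "wunifrac_value_error")
  set.seed(1)
  sh <- shuffle_labels(fig$fig3, mode = "expanded")
  expect_true(is.na(match(FALSE, sh$env$count == 1L)))
})

test_that("exact enumeration reproduces the hand-counted figure p-values", {
  fig <- figure_fixtures()
  r3 <- unifrac_signif(fig$fig3, mode = "expanded", method = "exact")
  expect_identical(r3$n_null, 70L)   # choose(8, 4) distinct assignments
  expect_identical(r3$n_ge, 2L)      # the original labeling and its mirror
  expect_equal(r3$p_value, 2 / 70)

  r2 <- unifrac_signif(fig$fig2, mode = "compact", method = "exact")
  expect_identical(r2$n_null, 2L)
  expect_equal(r2$p_value, 1)

  # expanded semantics applied to the compact tree expand internally
  r2e <- unifrac_signif(fig$fig2, mode = "expanded", method = "exact")
  expect_equal(r2e$p_value, r3$p_value)
  expect_identical(r2e$n_null, r3$n_null)

  r1 <- unifrac_signif(fig$fig1, mode = "compact", method = "exact")
  expect_equal(r1$p_value, 1)
  r1e <- unifrac_signif(fig$fig1, mode = "expanded", method = "exact")
  expect_equal(r1e$p_value, 1)

  rs <- unifrac_signif(fig$fig2_scaled, mode = "compact", method = "exact")
  expect_equal(rs$p_value, 1)
})

test_that("Monte-Carlo runs are reproducible given a seed and tie correctly", {
  fig <- figure_fixtures()
  a <- unifrac_signif(fig$fig3, mode = "expanded", method = "mc",
                      n_perm = 200, seed = 11)
  b <- unifrac_signif(fig$fig3, mode = "expanded", method = "mc",
                      n_perm = 200, seed = 11)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$null_distances, b$null_distances)
  expect_identical(a$seed, 11)

  # symmetric two-leaf compact tree: every permutation ties the observed
  for (sd in c(1, 7, 123)) {
    r <- unifrac_signif(fig$fig2, mode = "compact", method = "mc",
                        n_perm = 50, seed = sd)
    expect_identical(r$p_value, 1)
  }
})

test_that("the plus-one estimator shifts the p-value as documented", {
  fig <- figure_fixtures()
  r <- unifrac_signif(fig$fig3, mode = "expanded", method = "exact",
                      plus_one = TRUE)
  expect_equal(r$p_value, (2 + 1) / (70 + 1))
})

test_that("exact p-values agree with all-orderings brute force in both modes", {
  # small fixtures whose full ordering space is enumerable (n! <= 5040)
  for (s in 1:6) {
    lt <- gen_labeled_tree(fixture_spec(n_leaves = 4, n_samples = 2,
                                        max_count = 2, multi_label_prob = 0.1,
                                        seed = s + 40))
    pr <- lt$samples
    pc <- unifrac_signif(lt, mode = "compact", method = "exact")$p_value
    expect_equal(pc, oracle_exact_p(lt, pr[1], pr[2], "compact"))
    if (sum(lt$env$count) <= 7) {
      pe <- unifrac_signif(lt, mode = "expanded", method = "exact")$p_value
      expect_equal(pe, oracle_exact_p(lt, pr[1], pr[2], "expanded"))
    }
  }
})

test_that("Monte-Carlo converges to the exact p-value", {
  for (s in c(3, 8)) {
    lt <- gen_labeled_tree(fixture_spec(n_leaves = 5, n_samples = 2,
                                        max_count = 3, seed = s))
    ex <- unifrac_signif(lt, mode = "compact", method = "exact")
    mc <- unifrac_signif(lt, mode = "compact", method = "mc",
                         n_perm = 1e5, seed = s)
    ci <- stats::qbinom(c(5e-4, 1 - 5e-4), 1e5, ex$p_value) / 1e5
    expect_gte(mc$p_value, ci[1])
    expect_lte(mc$p_value, ci[2])
  }
})

test_that("expanded-mode p is unchanged by explicit pre-expansion", {
  for (s in 1:5) {
    lt <- gen_labeled_tree(fixture_spec(n_leaves = 4, n_samples = 2,
                                        max_count = 2, seed = s))
    if (sum(lt$env$count) > 9) next
    p1 <- unifrac_signif(lt, mode = "expanded", method = "exact")$p_value
    p2 <- unifrac_signif(expand_tree(lt), mode = "expanded", method = "exact")$p_value
    expect_identical(p1, p2)
  }
})

test_that("near-zero branch lengths give nearly the zero-length p-value", {
  # un-clustering scenario: replace the expanded tree's zero-length branches
  # with 0.01 — no longer an isomorphic transform, but the p-value moves by
  # less than 0.01 from 2/70
  fig <- figure_fixtures()
  tl <- fig$fig3$tree
  eps_tree <- tl
  eps_tree$edge.length[eps_tree$edge.length == 0] <- 0.01
  lt_eps <- labeled_tree(eps_tree, fig$fig3$env)
  p <- unifrac_signif(lt_eps, mode = "expanded", method = "exact")$p_value
  expect_lt(abs(p - 2 / 70), 0.01)
})

test_that("pairwise testing matches the single-pair test on two samples", {
  fig <- figure_fixtures()
  tab <- pairwise_unifrac_signif(fig$fig2, mode = "compact", method = "exact")
  expect_identical(nrow(tab), 1L)
  single <- tidy(unifrac_signif(fig$fig2, mode = "compact", method = "exact"))
  expect_equal(tab$p_value, single$p_value)
  expect_equal(tab$observed, single$observed)
})

test_that("pairwise significance covers every pair with valid p-values", {
  lt <- gen_labeled_tree(fixture_spec(n_leaves = 10, n_samples = 6,
                                      max_count = 3, seed = 5))
  tab <- pairwise_unifrac_signif(lt, mode = "compact", method = "mc",
                                 n_perm = 60, seed = 2,
                                 p_adjust = "bonferroni")
  expect_identical(nrow(tab), 15L)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true(all(tab$p_adjusted >= tab$p_value))
  expect_true(all(tab$p_adjusted <= 1))
  # reproducible under the run seed
  tab2 <- pairwise_unifrac_signif(lt, mode = "compact", method = "mc",
                                  n_perm = 60, seed = 2,
                                  p_adjust = "bonferroni")
  expect_equal(tab$p_value, tab2$p_value)
})

test_that("a sample co-located with its partner always yields p = 1", {
  # third sample C placed exactly like Sample1: the (Sample1, C) observed
  # distance is 0, which every null labeling matches or exceeds
  fig <- figure_fixtures()
  env <- dplyr::bind_rows(fig$fig2$env,
                          tibble::tibble(leaf = "A", sample = "C", count = 4L))
  lt <- labeled_tree(fig$fig2$tree, env)
  r <- unifrac_signif(lt, "Sample1", "C", mode = "expanded", method = "exact")
  expect_identical(r$p_value, 1)
  # brute-force confirmation at a size where all orderings are enumerable
  env_small <- tibble::tibble(leaf = c("A", "A", "B"),
                              sample = c("Sample1", "C", "Sample2"),
                              count = c(2L, 2L, 4L))
  lt_small <- labeled_tree(fig$fig2$tree, env_small)
  expect_equal(oracle_exact_p(lt_small, "Sample1", "C", "expanded"), 1)
  expect_identical(
    unifrac_signif(lt_small, "Sample1", "C", mode = "expanded",
                   method = "exact")$p_value, 1)
})
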
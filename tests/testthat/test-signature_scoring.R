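# AR signature score and mTOR activation score.

ref5 <- gene_signature(paste0("G", 1:5), c(1, 2, 3, 4, 5), name = "ref5")

test_that("AR score is the per-sample correlation against the reference", {
  vals <- cbind(
    s_self = c(1, 2, 3, 4, 5),
    s_neg = -c(1, 2, 3, 4, 5),
    s_mix = c(2, 1, 4, 3, 5)
  )
  rownames(vals) <- ref5$genes
  sc <- ar_signature_score(make_expr(vals), ref5, min_genes_present = 5)
  expect_equal(sc$score, c(1, -1, 0.8)) # hand r: 8/10 for the permuted sample
  expect_true(all(sc$score >= -1 & sc$score <= 1))
})

test_that("missing signature genes drop pairwise, with floor and flags", {
  vals <- matrix(rnorm(8), 4, 2,
    dimnames = list(paste0("G", 1:4), c("s1", "s2"))
  )
  sc <- ar_signature_score(make_expr(vals), ref5, min_genes_present = 4)
  expect_equal(sc$n_genes_used, c(4L, 4L))
  expect_match(sc$flags[1], "missing_genes:G5")
  expect_error(
    ar_signature_score(make_expr(vals), ref5, min_genes_present = 5),
    "only 4 of 5.*G5"
  )
})

test_that("a zero-variance sample yields NA with a flag", {
  vals <- cbind(s_flat = rep(2, 5), s_ok = c(1, 2, 3, 4, 5))
  rownames(vals) <- ref5$genes
  sc <- ar_signature_score(make_expr(vals), ref5)
  expect_true(is.na(sc$score[1]))
  expect_match(sc$flags[1], "zero_variance")
  expect_equal(sc$score[2], 1)
})

test_that("AR score is invariant to positive affine transforms and flips under negation", {
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(5)
    if (sd(x) == 0) next
    e1 <- one_sample_expr(setNames(x, ref5$genes))
    e2 <- one_sample_expr(setNames(2.7 * x + 11, ref5$genes))
    e3 <- one_sample_expr(setNames(-0.3 * x + 4, ref5$genes))
    s1 <- ar_signature_score(e1, ref5)$score
    expect_equal(ar_signature_score(e2, ref5)$score, s1, tolerance = 1e-12)
    expect_equal(ar_signature_score(e3, ref5)$score, -s1, tolerance = 1e-12)
  }
})

up3 <- paste0("U", 1:3)
down3 <- paste0("D", 1:3)
sets3 <- pathway_gene_sets(up3, down3, name = "sets3")

test_that("mTOR score matches the hand-computed pooled t", {
  e <- one_sample_expr(setNames(c(2, 4, 6, 1, 2, 3), c(up3, down3)))
  sc <- mtor_activation_score(e, sets3, variant = "pooled")
  expect_equal(sc$score, 2 / sqrt(5 / 3), tolerance = 1e-12) # means 4 vs 2, sp2 = 2.5
  expect_equal(sc$signed_score, sc$score)
  e0 <- one_sample_expr(setNames(c(1, 2, 3, 1, 2, 3), c(up3, down3)))
  expect_equal(mtor_activation_score(e0, sets3)$score, 0)
})

test_that("swapping up and down sets preserves |t| and negates the signed score", {
  swapped <- pathway_gene_sets(down3, up3, name = "swapped")
  set.seed(11)
  for (i in 1:20) {
    e <- one_sample_expr(setNames(rnorm(6, 5), c(up3, down3)))
    a <- mtor_activation_score(e, sets3, absolute = TRUE)
    b <- mtor_activation_score(e, swapped, absolute = TRUE)
    expect_equal(a$score, b$score, tolerance = 1e-12)
    expect_equal(a$signed_score, -b$signed_score, tolerance = 1e-12)
  }
})

test_that("degenerate gene groups are handled as documented", {
  both_flat <- one_sample_expr(setNames(c(2, 2, 2, 2, 2, 2), c(up3, down3)))
  sc <- mtor_activation_score(both_flat, sets3)
  expect_equal(sc$score, 0)
  expect_match(sc$flags, "degenerate_variance")
  one_flat <- one_sample_expr(setNames(c(2, 2, 2, 1, 2, 3), c(up3, down3)))
  sc2 <- mtor_activation_score(one_flat, sets3, variant = "pooled")
  expect_match(sc2$flags, "one_group_constant_welch")
  expect_equal(sc2$signed_score, oracle_welch_t(c(2, 2, 2), c(1, 2, 3)), tolerance = 1e-12)
})

test_that("both scores match independent oracles on random instances", {
  set.seed(23)
  for (i in 1:200) {
    n_genes <- sample(4:12, 1)
    ref <- gene_signature(sprintf("R%02d", seq_len(n_genes)), rnorm(n_genes))
    x <- rnorm(n_genes)
    e <- one_sample_expr(setNames(x, ref$genes))
    expect_lt(
      rel_err(
        ar_signature_score(e, ref, min_genes_present = 3)$score,
        oracle_pearson(x, ref$reference)
      ),
      1e-12
    )
    n_up <- sample(2:8, 1)
    n_dn <- sample(2:8, 1)
    sets <- pathway_gene_sets(sprintf("U%02d", 1:n_up), sprintf("D%02d", 1:n_dn))
    vals <- rnorm(n_up + n_dn, 5)
    e2 <- one_sample_expr(setNames(vals, c(sets$up_genes, sets$down_genes)))
    expect_lt(
      rel_err(
        mtor_activation_score(e2, sets, variant = "pooled", absolute = FALSE)$score,
        oracle_pooled_t(vals[1:n_up], vals[-(1:n_up)])
      ),
      1e-12
    )
    expect_lt(
      rel_err(
        mtor_activation_score(e2, sets, variant = "welch", absolute = FALSE)$score,
        oracle_welch_t(vals[1:n_up], vals[-(1:n_up)])
      ),
      1e-12
    )
  }
})

test_that("scores also agree with stats::cor and stats::t.test", {
  set.seed(31)
  x <- rnorm(20)
  ref <- gene_signature(sprintf("R%02d", 1:20), rnorm(20))
  e <- one_sample_expr(setNames(x, ref$genes))
  expect_equal(ar_signature_score(e, ref)$score, cor(x, ref$reference), tolerance = 1e-12)
  sets <- pathway_gene_sets(sprintf("U%02d", 1:6), sprintf("D%02d", 1:5))
  vals <- rnorm(11, 5)
  e2 <- one_sample_expr(setNames(vals, c(sets$up_genes, sets$down_genes)))
  expect_equal(
    mtor_activation_score(e2, sets, variant = "welch", absolute = FALSE)$score,
    unname(t.test(vals[1:6], vals[7:11])$statistic),
    tolerance = 1e-12
  )
  expect_equal(
    mtor_activation_score(e2, sets, variant = "pooled", absolute = FALSE)$score,
    unname(t.test(vals[1:6], vals[7:11], var.equal = TRUE)$statistic),
    tolerance = 1e-12
  )
})
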
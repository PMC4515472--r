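# Brute-force Mann-Whitney oracle: enumerate every assignment of the pooled
# values to the two groups, build the exact U null distribution, and compute
# the two-sided p as 2 * min(P(U <= u), P(U >= u)) capped at 1.
mw_enum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pool <- c(x, y)
  u_obs <- sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
  combs <- utils::combn(m + n, m)
  us <- apply(combs, 2, function(ix) {
    xx <- pool[ix]; yy <- pool[-ix]
    sum(outer(xx, yy, `>`)) + 0.5 * sum(outer(xx, yy, `==`))
  })
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

test_that("comparative Ct computes per-batch fold changes", {
  tb <- ct_table(data.frame(
    gene = rep(c("bgm", "rp49"), each = 2),
    sample_id = rep(c("s_v", "s_m"), 2),
    condition = rep(c("virgin", "mated"), 2),
    batch_id = 1, ct = c(25, 24, 20, 20)))
  res <- comparative_ct(tb, "bgm")
  expect_equal(res$per_batch$ddct, -1)
  expect_equal(res$per_batch$fold, 2)

  # identical conditions: null fold
  tb0 <- ct_table(data.frame(gene = rep(c("bgm", "rp49"), each = 2),
                             sample_id = rep(c("s_v", "s_m"), 2),
                             condition = rep(c("virgin", "mated"), 2),
                             batch_id = 1, ct = c(25, 25, 20, 20)))
  expect_equal(comparative_ct(tb0, "bgm")$per_batch$fold, 1)

  # +3 cycles on every gene of one sample cancels through the housekeeping
  shifted <- as.data.frame(tb)
  shifted$ct[shifted$sample_id == "s_m"] <- shifted$ct[shifted$sample_id == "s_m"] + 3
  expect_equal(comparative_ct(ct_table(shifted), "bgm")$per_batch$fold, 2)

  # missing housekeeping names the offending sample
  broken <- as.data.frame(tb)[-3, ]
  expect_error(comparative_ct(ct_table(broken), "bgm"), "s_v")
})

test_that("comparative Ct averages technical triplicates first", {
  tb <- generate_ct_table("bgm", fold_changes = 2, sd = 0, n_batches = 3,
                          sample_shift_sd = 0.8, seed = 5)
  res <- comparative_ct(tb, "bgm")
  expect_equal(res$per_batch$fold, rep(2, 3), tolerance = 1e-9)
  expect_equal(res$mean_fold, 2, tolerance = 1e-9)
})

test_that("recovered fold changes are unbiased under technical noise", {
  folds <- vapply(1:120, function(s)
    comparative_ct(generate_ct_table("bgm", 2, sd = 0.2, n_batches = 6, seed = s),
                   "bgm")$mean_fold, 0)
  expect_lt(abs(mean(folds) - 2) / 2, 0.05)
})

test_that("paired t matches the closed form and handles tails", {
  z <- paired_t(c(1, 1, 1, 1))
  expect_true(is.na(z$p_raw))
  expect_match(z$note, "zero-variance")

  d <- c(2.1, 1.4, 3.0, 0.5)
  r <- paired_t(d)
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(r$statistic, t_hand)
  expect_equal(r$p_raw, 2 * pt(abs(t_hand), 3, lower.tail = FALSE))

  one <- paired_t(d, alternative = "greater")
  expect_equal(one$p_raw, r$p_raw / 2)
})

test_that("welch t uses the Satterthwaite df and is affine invariant", {
  r0 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_raw, 1)

  x <- c(0, 0, 0, 0.0001); y <- c(1, 1, 1, 1.0001)
  r <- welch_t(x, y)
  v1 <- var(x) / 4; v2 <- var(y) / 4
  df_hand <- (v1 + v2)^2 / (v1^2 / 3 + v2^2 / 3)
  expect_equal(r$df, df_hand)
  expect_lt(r$p_raw, 1e-6)

  r10 <- welch_t(10 * x + 3, 10 * y + 3)
  expect_equal(r10$statistic, r$statistic, tolerance = 1e-9)
  expect_equal(r10$p_raw, r$p_raw, tolerance = 1e-9)

  dz <- welch_t(c(2, 2), c(2, 2))
  expect_match(dz$note, "zero variance")
})

test_that("mann-whitney exact path equals brute-force enumeration", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_raw, 1 / 3)
  expect_true(r$exact)

  # fully interleaved samples carry no evidence
  ri <- mann_whitney(c(1, 3, 5, 7), c(2, 4, 6, 8))
  expect_gt(ri$p_raw, 0.5)

  # property: exact p equals enumeration for all combined n <= 10
  set.seed(33)
  for (k in 1:50) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    v <- sample(1000, m + n)  # distinct values: no ties
    x <- v[1:m]; y <- v[(m + 1):(m + n)]
    expect_equal(mann_whitney(x, y)$p_raw, mw_enum_p(x, y))
  }
})

test_that("holm adjustment matches hand-stepped values and its bounds", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.5), 0.5)

  set.seed(2)
  for (k in 1:20) {
    p <- runif(sample(2:8, 1))
    a <- holm_adjust(p)
    expect_true(all(a >= p))
    expect_true(all(a <= 1))
    expect_true(all(diff(a[order(p)]) >= -1e-12))
  }

  # list-of-results interface fills p_adjusted
  res <- list(welch_t(c(1, 2, 3), c(4, 5, 6)), welch_t(c(1, 2, 3), c(1.1, 2, 3)))
  adj <- holm_adjust(res, family_id = "demo")
  expect_equal(vapply(adj, function(t) t$p_adjusted, 0),
               p.adjust(vapply(res, function(t) t$p_raw, 0), "holm"))
})

test_that("nb glm lrt behaves under exact null duplication and separation", {
  d <- count_data(data.frame(unit_id = 1:20, group = rep(c("a", "b"), each = 10),
                             count = rep(c(0, 1, 2, 3, 5, 7, 2, 4, 1, 9), 2)))
  r <- nb_glm_lrt(d)
  expect_equal(r$p_raw, 1, tolerance = 1e-6)

  strong <- generate_counts(c(v = 2, m = 10), dispersion = 1, n_per_group = 30, seed = 4)
  expect_lt(nb_glm_lrt(strong)$p_raw, 1e-3)

  zero <- count_data(data.frame(unit_id = 1:8, group = rep(c("a", "b"), each = 4),
                                count = 0))
  expect_error(nb_glm_lrt(zero), "all counts")
})

test_that("nb power at programmed separation is high across seeds", {
  hits <- vapply(1:60, function(s)
    nb_glm_lrt(generate_counts(c(v = 2, m = 10), 1, 30, seed = s))$p_raw < 1e-3, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("hatch fractions validate and recover the programmed hatch rate", {
  expect_equal(hatch_fraction(10, 9)$fractions$fraction, 0.9)
  expect_error(hatch_fraction(10, 11), "exceeds")
  expect_warning(h0 <- hatch_fraction(c(10, 0), c(9, 0)), "zero eggs")
  expect_equal(nrow(h0$fractions), 1)

  set.seed(10)
  laid <- rpois(30, 40) + 1
  hatched <- rbinom(30, laid, 0.95)
  h <- hatch_fraction(laid, hatched)
  mhat <- h$group_means$fraction
  se <- sqrt(0.95 * 0.05 / sum(laid))
  expect_lt(abs(mhat - 0.95), 4 * se + 0.01)

  two <- hatch_fraction(c(laid, laid), c(hatched, rbinom(30, laid, 0.9)),
                        group = rep(c("a", "b"), each = 30))
  expect_length(two$comparisons, 1)
  expect_s3_class(two$comparisons[[1]], "test_result")
})
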
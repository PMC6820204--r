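# Exact signed-rank inference, r-equivalent, FDR, permutation tests,
# distance-decay regression and the interaction contrast.

test_that("the exact signed-rank null matches psignrank for N = 8", {
  probs <- hgalpha:::signed_rank_null(1:8)     # P(2W = k), k = 0..72
  for (w in 0:36) {
    expect_equal(sum(probs[seq_len(2 * w + 1)]), psignrank(w, 8),
                 tolerance = 1e-12)
  }
})

test_that("reported p-values for one-sided and near-one-sided patterns", {
  # all eight differences share a sign: W = 0
  t0 <- exact_signed_rank(-(1:8))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 2 / 256)
  # only the rank-2 magnitude opposes: W = 2
  d2 <- -(1:8); d2[2] <- 2
  t2 <- exact_signed_rank(d2)
  expect_equal(t2$statistic, 2)
  expect_equal(t2$p, 6 / 256)
  # N = 2 can never beat p = 0.5
  expect_gte(exact_signed_rank(c(1, 2))$p, 0.5)
})

test_that("tied magnitudes use average ranks and match brute force", {
  set.seed(44)
  for (i in 1:5) {
    d <- sample(c(-3, -2, -1, 1, 1, 2, 2, 5), 8, replace = TRUE) +
      sample(c(0, 0.5), 8, replace = TRUE)
    d <- d[d != 0]
    if (length(d) < 3) next
    expect_equal(exact_signed_rank(d)$p, brute_force_signed_rank_p(d),
                 tolerance = 1e-12)
  }
})

test_that("zero differences are dropped with a warning and N shrinks", {
  expect_warning(t <- exact_signed_rank(c(0, 0, 1, 2, 3, 4)), "dropped")
  expect_equal(t$n, 4)
  expect_error(exact_signed_rank(rep(0, 5)) |> suppressWarnings())
  expect_error(exact_signed_rank(1:25), "N <= 20")
})

test_that("r-equivalent behaves as a p-to-correlation conversion", {
  expect_equal(r_equivalent(1, 8), 0)
  ps <- c(0.5, 0.1, 0.05, 0.01)
  rs <- vapply(ps, r_equivalent, numeric(1), n = 8)
  expect_true(all(diff(rs) > 0))
  expect_equal(r_equivalent(2 / 256, 8), 0.812, tolerance = 0.02)
  expect_error(r_equivalent(0, 8), "positive")
})

test_that("Benjamini-Hochberg step-up behaves at its boundary", {
  expect_equal(fdr_correct(rep(0.01, 10)), rep(TRUE, 10))
  expect_identical(fdr_correct(numeric(0)), logical(0))
  expect_true(fdr_correct(0.04))
  expect_false(fdr_correct(0.06))
  # step-up: the largest i with p_(i) <= i q / m admits all smaller ranks;
  # p = 0.05 at i = m = 4 sits exactly on its threshold, so all four pass
  expect_equal(fdr_correct(c(0.004, 0.02, 0.03, 0.05)), rep(TRUE, 4))
  expect_equal(fdr_correct(c(0.004, 0.02, 0.03, 0.051)),
               c(TRUE, TRUE, TRUE, FALSE))
})

test_that("permutation test attains its extremes and is seeded", {
  a <- 10 + c(1:10) / 10
  b <- c(1:10) / 10
  t1 <- trial_label_permutation(a, b, n_perm = 1000, seed = 2)
  expect_equal(t1$p, 1 / 1001)
  t2 <- trial_label_permutation(a, b, n_perm = 1000, seed = 2)
  expect_identical(t1$p, t2$p)
  expect_warning(t3 <- trial_label_permutation(rep(1, 6), rep(1, 6)),
                 "degenerate")
  expect_equal(t3$p, 1)
  expect_error(trial_label_permutation(1:3, 1:6), "at least 5")
})

test_that("permutation test keeps its type-I error rate under the null", {
  set.seed(77)
  rejections <- mean(replicate(1000, {
    x <- rnorm(16)
    trial_label_permutation(x[1:8], x[9:16], n_perm = 199,
                            seed = sample.int(1e6, 1))$p <= 0.05
  }))
  expect_lte(rejections, 0.055)
})

test_that("distance decay recovers a noiseless linear dependence", {
  set.seed(55)
  contacts <- data.frame(
    contact_id = paste0("c", 1:20),
    hemisphere_id = rep(c("Ha", "Hb"), each = 10),
    x = rnorm(20, 0, 10), y = rnorm(20, 0, 10), z = rnorm(20, 0, 10)
  )
  assigned <- stats::setNames(rep(c("alHG", "pmHG"), 10),
                              contacts$contact_id)
  # compute the same distances the fit will use, then build exact line
  alpha <- numeric(20)
  names(alpha) <- contacts$contact_id
  for (h in c("Ha", "Hb")) {
    hc <- contacts[contacts$hemisphere_id == h, ]
    al <- hc[assigned[hc$contact_id] == "alHG", ]
    ce <- colMeans(al[, c("x", "y", "z")])
    d <- sqrt((hc$x - ce[1])^2 + (hc$y - ce[2])^2 + (hc$z - ce[3])^2)
    alpha[hc$contact_id] <- -6 + 0.31 * d
  }
  fit <- distance_decay_fit(contacts, alpha, assigned)
  expect_equal(fit$per_hemisphere$slope, c(0.31, 0.31), tolerance = 1e-9)
  # constant alpha: zero slopes, degenerate group test at p = 1
  expect_warning(fit0 <- distance_decay_fit(contacts,
                                            stats::setNames(rep(-3, 20),
                                                            contacts$contact_id),
                                            assigned),
                 "zero")
  expect_equal(fit0$group_test$p, 1)
})

test_that("the interaction contrast reproduces its enumeration quantile", {
  # contrasts with magnitudes 1..8 where ranks {3, 4} oppose: W = 7
  d <- c(1, 2, -3, -4, 5, 6, 7, 8)
  cm <- do.call(rbind, lapply(1:8, function(h) {
    data.frame(hemisphere_id = paste0("H", h),
               region = c("pmHG", "pmHG", "alHG", "alHG"),
               condition = c("clear", "vocoded", "clear", "vocoded"),
               value = c(0, 0, d[h], 0))
  }))
  t <- interaction_contrast(cm)
  expect_equal(t$statistic, 7)
  expect_equal(t$p, 38 / 256)
  expect_equal(brute_force_signed_rank_p(d), 38 / 256)
  # identical conditions: all contrasts zero, degenerate p = 1
  cm0 <- cm; cm0$value <- 1
  expect_warning(t0 <- interaction_contrast(cm0), "zero")
  expect_equal(t0$p, 1)
})

test_that("test tables are tidy and exportable", {
  tests <- list(a = exact_signed_rank(-(1:8)),
                b = exact_signed_rank(c(-1, 2, -3, -4, -5, -6, -7, -8)))
  path <- tempfile(fileext = ".csv")
  df <- test_results_table(tests, path)
  expect_equal(df$comparison, c("a", "b"))
  expect_true(file.exists(path))
  expect_equal(nrow(read.csv(path)), 2)
  unlink(path)
})
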
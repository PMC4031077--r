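test_that("density normalization uses the all-island mean as background", {
  d <- island_density(data.frame(island_id = c("a", "b", "c"),
                                 raw_score = c(1, 2, 3)))
  expect_equal(d$norm_density, c(0.5, 1, 1.5))
  expect_equal(mean(d$norm_density), 1)

  d2 <- island_density(data.frame(island_id = letters[1:4],
                                  raw_score = rep(7, 4)))
  expect_equal(d2$norm_density, rep(1, 4))

  set.seed(3)
  d3 <- island_density(data.frame(island_id = sprintf("i%d", 1:50),
                                  raw_score = rexp(50)))
  expect_equal(mean(d3$norm_density), 1)

  expect_error(island_density(data.frame(island_id = "a",
                                         raw_score = 0)),
               "not positive")

  # per-mark normalization and subtract mode
  dm <- island_density(data.frame(island_id = rep(c("a", "b"), 2),
                                  mark = rep(c("H3K27me3", "H3K4me3"),
                                             each = 2),
                                  raw_score = c(1, 3, 10, 30)))
  expect_equal(dm$norm_density, c(0.5, 1.5, 0.5, 1.5))
  ds <- island_density(data.frame(island_id = c("a", "b"),
                                  raw_score = c(1, 3)), "subtract")
  expect_equal(ds$norm_density, c(-1, 1))
})

test_that("above-background flag is strict and scale-invariant", {
  rec <- flag_above_background(
    data.frame(island_id = c("a", "b", "c"),
               norm_density = c(2.1, 2.0, 0)))
  expect_equal(rec$above_background, c(TRUE, FALSE, FALSE))

  set.seed(9)
  raw <- rexp(40) + 0.1
  f1 <- flag_above_background(island_density(
    data.frame(island_id = sprintf("i%d", 1:40), raw_score = raw)))
  f2 <- flag_above_background(island_density(
    data.frame(island_id = sprintf("i%d", 1:40), raw_score = raw * 37)))
  expect_equal(f1$above_background, f2$above_background)
})

test_that("fixed-width span profiles bin on the density axis", {
  p <- profile_by_span(c(0.2, 0.4), c(1, 2), span_width = 5)
  expect_equal(nrow(p), 1)
  expect_equal(p$mean_meth, 0.3)
  expect_equal(p$bin_lo, 0)
  expect_equal(p$bin_hi, 5)

  # constant methylation -> flat curve, empty windows omitted
  p2 <- profile_by_span(rep(0.7, 4), c(1, 2, 11, 12))
  expect_equal(p2$mean_meth, c(0.7, 0.7))
  expect_equal(p2$bin_lo, c(0, 10))
  expect_equal(sum(p2$n), 4)
})

test_that("span profile recovers a planted linear density-methylation slope", {
  set.seed(13)
  density <- runif(5000, 0, 50)
  meth <- 0.1 * density + rnorm(5000, 0, 0.05)
  p <- profile_by_span(meth, density, 5)
  slope <- coef(lm(mean_meth ~ mean_density, data = p))[[2]]
  expect_lt(abs(slope - 0.1), 0.02)
})

test_that("equal-count bins enumerate ranks deterministically", {
  p <- profile_by_decile(seq(0.1, 2, length.out = 20), 1:20,
                         sprintf("i%02d", 1:20), 10)
  expect_equal(p$mean_density, seq(1.5, 19.5, by = 2))
  expect_equal(p$n, rep(2L, 10))

  # 10 islands -> singleton bins sorted by density
  p1 <- profile_by_decile(11:20, 10:1, sprintf("i%02d", 1:10), 10)
  expect_equal(p1$mean_meth, 20:11)

  expect_error(profile_by_decile(1:5, 1:5, n_bins = 10), "at least")
})

test_that("decile bins match brute force, sizes differ by <= 1, order-invariant", {
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(25:150, 1)
    nb <- sample(4:10, 1)
    meth <- rnorm(n)
    density <- sample(rexp(n))
    ids <- sprintf("i%03d", sample(n))
    p <- profile_by_decile(meth, density, ids, nb)
    oracle <- brute_decile(meth, density, ids, nb)
    expect_equal(p$mean_density, oracle[, 1])
    expect_equal(p$mean_meth, oracle[, 2])
    expect_lte(diff(range(p$n)), 1)
    perm <- sample(n)
    p2 <- profile_by_decile(meth[perm], density[perm], ids[perm], nb)
    expect_equal(p2, p)
  }
  # span profile is row-order invariant too
  set.seed(20)
  meth <- rnorm(200); density <- runif(200, 0, 30)
  perm <- sample(200)
  expect_equal(profile_by_span(meth[perm], density[perm]),
               profile_by_span(meth, density))
})

test_that("methylation independent of density yields a flat decile curve", {
  set.seed(29)
  n <- 2000
  meth <- rnorm(n, 0.5, 0.2)
  density <- rexp(n)
  p <- profile_by_decile(meth, density, sprintf("i%04d", 1:n), 10)
  se <- sd(meth) / sqrt(min(p$n))
  expect_true(all(abs(p$mean_meth - mean(meth)) <= 3 * se))
})

test_that("protection curve gates on H3K27me3 and degrades gracefully", {
  expect_error(protection_curve(1:5, 1:5, rep(FALSE, 5)), "gate")

  # all gated islands share one H3K4me3 density -> a single bin
  p <- protection_curve(c(1, 2, 3, 9), rep(0, 4),
                        c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(nrow(p), 1)
  expect_equal(p$mean_meth, 2)

  # planted protection: meth = g * (1 - min(k4/k4max, 1)) is monotone
  set.seed(47)
  n <- 600
  k4 <- runif(n, 0, 10)
  meth <- 2 * (1 - pmin(k4 / 8, 1))
  gate <- rep(TRUE, n)
  pc <- protection_curve(meth, k4, gate, sprintf("i%03d", 1:n), 10)
  expect_true(all(diff(pc$mean_meth) <= 1e-9))
})

test_that("paired density change recovers a planted reduction", {
  ids <- sprintf("i%03d", 1:500)
  set.seed(53)
  a <- setNames(rnorm(500, 5, 0.1), ids)
  hi <- ids[1:100]
  b <- a + rnorm(500, 0, 0.1)
  b[hi] <- b[hi] - 3
  pd <- paired_density_change(a, b, hi)
  expect_lt(abs(pd$summary$mean_diff[pd$summary$group == "highlight"] +
                  3), 0.05)
  expect_lt(abs(pd$summary$mean_diff[pd$summary$group == "other"]), 0.05)

  expect_equal(paired_density_change(a, a, hi)$per_island$diff,
               rep(0, 500))
  expect_error(paired_density_change(a, b[-1], hi), "universes differ")
  expect_error(paired_density_change(a, b, c("nope1", "nope2")),
               "not in universe")
})
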
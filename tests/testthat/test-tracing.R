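toy_matrix <- function(values, samples, ids = NULL) {
  m <- matrix(values, ncol = length(samples), byrow = TRUE)
  colnames(m) <- samples
  rownames(m) <- if (is.null(ids)) sprintf("isl%02d", seq_len(nrow(m)))
    else ids
  m
}

test_that("constitutive set requires strictly negative IMS in every tissue", {
  roles <- sample_roles(c("t1", "t2", "t3"), rep("tissue", 3))
  m <- toy_matrix(c(-0.5, -0.1, -0.9,   # in set
                    -0.5, 0.0, -0.3,    # 0.0 is not < 0
                    -0.5, NA, -0.3,     # missing tissue disqualifies
                    0.2, -0.1, -0.9),   # positive tissue value
                  c("t1", "t2", "t3"))
  expect_equal(constitutive_set(m, roles), "isl01")
  expect_error(constitutive_set(m, sample_roles("x", "es_test")),
               "no tissue")
})

test_that("constitutive set matches hand enumeration on a 6x3 panel", {
  roles <- sample_roles(c("t1", "t2", "t3"), rep("tissue", 3))
  vals <- c(-1, -1, -1,
            -0.2, -0.3, -0.1,
            0.5, -1, -1,
            -2, -0.4, -0.6,
            -1, -1, 0.9,
            -0.1, -0.2, -0.3)
  m <- toy_matrix(vals, c("t1", "t2", "t3"))
  expect_equal(constitutive_set(m, roles),
               c("isl01", "isl02", "isl04", "isl06"))
})

test_that("aberrant calls stay inside the background set", {
  roles <- sample_roles(c("t1", "t2", "e1", "e2"),
                        c("tissue", "tissue", "es_test", "es_test"))
  m <- toy_matrix(c(-1, -1, 0.8, 0.1,    # aberrant: one ES hit
                    -1, -1, 0.75, 0.2,   # 0.75 not > 0.75
                    -1, -1, NA, 0.1,     # missing test = non-hit
                    0.5, -1, 2.0, 2.0),  # not in background
                  c("t1", "t2", "e1", "e2"))
  bg <- constitutive_set(m, roles)
  res <- aberrant_set(m, roles, bg)
  expect_equal(res$aberrant_set, "isl01")
  expect_true(all(res$aberrant_set %in% res$background_set))
  expect_false("isl04" %in% res$background_set)
  expect_error(aberrant_set(m, roles, character(0)), "empty background")

  # min_test_samples_hit = 2 empties the call set here
  cfg2 <- tracing_config(min_test_samples_hit = 2)
  expect_equal(aberrant_set(m, roles, bg, cfg2)$aberrant_set,
               character(0))
})

test_that("raising the aberrant threshold never grows the call set", {
  set.seed(61)
  roles <- sample_roles(c("t1", "t2", "e1", "e2"),
                        c("tissue", "tissue", "es_test", "es_test"))
  m <- toy_matrix(c(rnorm(200, -0.5, 0.3), rnorm(200, 0.5, 0.6)),
                  c("t1", "t2", "e1", "e2"),
                  ids = sprintf("isl%03d", 1:100))
  bg <- constitutive_set(m, roles)
  prev <- NULL
  for (thr in c(0.25, 0.5, 0.75, 1.0)) {
    cur <- aberrant_set(m, roles, bg,
                        tracing_config(aberrant_min = thr))$aberrant_set
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("the tracer is invariant to sample column order within a role", {
  set.seed(67)
  samples <- c("t1", "t2", "t3", "e1", "e2")
  roles <- sample_roles(samples, c(rep("tissue", 3), rep("es_test", 2)))
  m <- toy_matrix(rnorm(250, 0, 0.7), samples,
                  ids = sprintf("isl%03d", 1:50))
  bg <- constitutive_set(m, roles)
  res <- aberrant_set(m, roles, bg)
  perm <- m[, c("t3", "e2", "t1", "e1", "t2")]
  expect_equal(constitutive_set(perm, roles), bg)
  expect_equal(aberrant_set(perm, roles, bg)$aberrant_set,
               res$aberrant_set)
})

test_that("planted aberrant islands are recovered exactly at low noise", {
  set.seed(71)
  n <- 200
  ids <- sprintf("isl%03d", seq_len(n))
  planted <- sort(sample(ids, 30))
  samples <- c("t1", "t2", "e1", "e2")
  roles <- sample_roles(samples, c("tissue", "tissue", "es_test",
                                   "es_test"))
  m <- matrix(rnorm(n * 4, -0.4, 0.05), n, 4,
              dimnames = list(ids, samples))
  m[planted, c("e1", "e2")] <- rnorm(60, 1.2, 0.05)
  bg <- constitutive_set(m, roles)
  res <- aberrant_set(m, roles, bg)
  expect_equal(res$aberrant_set, planted)
  ev <- evaluate_tracing(res, planted)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$fdr, 0)
})

test_that("tissue-specific (group B) islands are methylated in exactly one tissue", {
  roles <- sample_roles(c("t1", "t2", "t3"), rep("tissue", 3))
  cfg <- tracing_config("percent")
  m <- toy_matrix(c(80, 5, 10,    # group B
                    80, 70, 5,    # two tissues methylated
                    50, 5, 10,    # 50 not > 60
                    80, 25, 10,   # 25 not < 20: ambiguous, excluded
                    5, 5, 90),    # group B
                  c("t1", "t2", "t3"))
  expect_equal(tissue_specific_set(m, roles, cfg), c("isl01", "isl05"))
  expect_error(tissue_specific_set(m[, 1, drop = FALSE],
                                   sample_roles("t1", "tissue"), cfg),
               "at least 2")
  # exhaustive scan oracle on a random percent matrix
  set.seed(73)
  mr <- toy_matrix(runif(300, 0, 100), c("t1", "t2", "t3"),
                   ids = sprintf("isl%03d", 1:100))
  got <- tissue_specific_set(mr, roles, cfg)
  want <- rownames(mr)[apply(mr, 1, function(v)
    sum(v > 60) == 1 && sum(v < 20) == 2)]
  expect_equal(got, want)
})

test_that("hypergeometric enrichment reproduces exact combinatorics", {
  u <- sprintf("g%02d", 1:10)
  res <- hypergeom_enrichment(u[1:5], u[c(1:4, 6)][1:4], u)
  # N=10, K=4, n=5, k=4 -> C(4,4)C(6,1)/C(10,5) = 6/252
  expect_equal(res$overlap, 4)
  expect_equal(res$p, 6 / 252, tolerance = 1e-12)
  expect_equal(res$fold, 4 / (5 * 4 / 10), tolerance = 1e-12)

  # zero overlap -> p = P(X >= 0) = 1
  r0 <- hypergeom_enrichment(u[1:3], u[4:6], u)
  expect_equal(r0$overlap, 0)
  expect_equal(r0$p, 1)

  # set_b = universe -> k = n, p = 1
  r1 <- hypergeom_enrichment(u[1:5], u, u)
  expect_equal(r1$overlap, 5)
  expect_equal(r1$p, 1)

  expect_error(hypergeom_enrichment(c(u[1], "zz"), u[1:2], u), "subsets")

  # log-space survives extreme significance
  big_u <- sprintf("i%05d", 1:13000)
  rb <- hypergeom_enrichment(big_u[1:1000], big_u[1:1200], big_u)
  expect_equal(rb$p, 0)  # underflows as a double
  expect_lt(rb$log10_p, -1000)
  expect_true(is.finite(rb$log10_p))
})

test_that("hypergeometric tail matches exhaustive enumeration on random sets", {
  set.seed(79)
  for (rep in 1:30) {
    N <- sample(5:12, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    u <- sprintf("x%02d", 1:N)
    res <- hypergeom_enrichment(sample(u, n), sample(u, K), u)
    expect_equal(res$p, brute_hyper(N, K, n, res$overlap),
                 tolerance = 1e-12)
  }
})

test_that("pooled-variance t-test handles regular and degenerate input", {
  r <- group_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)
  o <- brute_pooled_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$p, o$p, tolerance = 1e-12)

  # swapping groups negates t, keeps p
  r2 <- group_ttest(c(2, 3, 4), c(1, 2, 3))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)

  expect_equal(group_ttest(c(5, 5), c(5, 5)), list(t = 0, df = 2, p = 1))
  expect_warning(rz <- group_ttest(c(5, 5), c(7, 7)), "zero pooled")
  expect_equal(rz$p, 0)
  expect_error(group_ttest(1, c(1, 2)), "n >= 2")

  set.seed(83)
  for (rep in 1:20) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), 0.5)
    r <- group_ttest(a, b)
    o <- brute_pooled_t(a, b)
    expect_equal(r$t, o$t, tolerance = 1e-10)
    expect_equal(r$p, o$p, tolerance = 1e-10)
  }
})

test_that("condition comparison recovers a planted uniform shift", {
  set.seed(89)
  n <- 200
  ids <- sprintf("isl%03d", 1:n)
  roles <- sample_roles(c("serum", "twoi"),
                        c("condition_a", "condition_b"))
  base <- runif(n, 10, 40)
  m <- cbind(serum = base + 10 + rnorm(n, 0, 1),
             twoi = base + rnorm(n, 0, 1))
  rownames(m) <- ids
  cc <- compare_conditions(m, roles, ids, seed = 2)
  expect_lt(abs(cc$mean_diff - 10), 0.3)
  expect_true(cc$ci[1] < cc$mean_diff & cc$mean_diff < cc$ci[2])
  expect_equal(cc$n_used, n)

  # identical conditions -> zero differences
  m0 <- cbind(serum = base, twoi = base)
  rownames(m0) <- ids
  expect_equal(compare_conditions(m0, roles, ids, seed = 2)$mean_diff, 0)

  # islands missing from a condition are excluded and counted
  m2 <- m; m2[1:5, "twoi"] <- NA
  cc2 <- compare_conditions(m2, roles, ids, seed = 2)
  expect_equal(cc2$n_used, n - 5)
  expect_equal(cc2$n_excluded, 5)
  m3 <- m; m3[, "twoi"] <- NA
  expect_error(compare_conditions(m3, roles, ids, seed = 2),
               "no usable")
})

test_that("heat-map export orders aberrant rows by mean test value", {
  samples <- c("t1", "t2", "e1", "e2")
  roles <- sample_roles(samples, c("tissue", "tissue", "es_test",
                                   "es_test"))
  m <- toy_matrix(c(-1, -1, 0.9, 0.9,
                    -1, -1, 1.2, 1.2,
                    -1, -1, 0.9, 0.9,
                    -1, -1, 0.1, 0.1),
                  samples)
  res <- aberrant_set(m, roles, constitutive_set(m, roles))
  hm <- export_heatmap_matrix(res, m, roles)
  # descending mean test IMS, tie broken by island_id
  expect_equal(rownames(hm), c("isl02", "isl01", "isl03"))
  expect_equal(colnames(hm), samples)
  # independent sort oracle
  mean_test <- rowMeans(m[res$aberrant_set, c("e1", "e2")])
  oracle <- res$aberrant_set[order(-mean_test, res$aberrant_set)]
  expect_equal(rownames(hm), oracle)

  res0 <- res; res0$aberrant_set <- character(0)
  hm0 <- export_heatmap_matrix(res0, m, roles)
  expect_equal(nrow(hm0), 0)
  expect_equal(colnames(hm0), samples)
})

test_that("tracing config validates thresholds", {
  expect_error(tracing_config(constitutive_max = 1, aberrant_min = 0.5),
               "exceed")
  cfg <- tracing_config("percent")
  expect_equal(cfg$constitutive_max, 20)
  expect_equal(cfg$aberrant_min, 60)
})
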
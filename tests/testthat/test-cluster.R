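# Pointwise t-maps, cluster formation, and the sign-flip permutation test.

test_that("the paired t-map matches the closed form", {
  chn <- c("a", "b")
  zero <- lapply(1:5, function(i)
    as_wave(matrix(0, 2, 10, dimnames = list(chn, NULL))))
  tm0 <- pointwise_t(zero, zero)
  expect_true(all(tm0$t == 0))
  expect_equal(tm0$df, 4)
  ## constant participant differences d_i: t = mean/(sd/sqrt(n)) everywhere
  d <- c(1.2, 0.7, 1.9, 0.4, 1.1)
  tw <- lapply(d, function(x)
    as_wave(matrix(x, 2, 10, dimnames = list(chn, NULL))))
  tm <- pointwise_t(tw, zero)
  expect_equal(unique(round(as.vector(tm$t), 10)),
               round(mean(d) / (stats::sd(d) / sqrt(5)), 10))
  ## the cluster-forming threshold is the two-tailed t quantile
  tw20 <- lapply(rnorm(20), function(x)
    as_wave(matrix(x, 2, 10, dimnames = list(chn, NULL))))
  tm20 <- pointwise_t(tw20, lapply(tw20, function(w) as_wave(w$data * 0)))
  expect_equal(tm20$threshold_t, stats::qt(0.975, 19))
  expect_error(pointwise_t(tw[1], zero[1]), "at least 2")
})

test_that("cluster formation agrees with the graph-search oracle on bands", {
  adj <- grid_adjacency(list(2, c(1, 3), 2, integer(0)))  # ch4 isolated
  t <- matrix(0, 4, 30, dimnames = list(adj$labels, NULL))
  ## two temporally disjoint bands on one channel
  t[1, 5:8] <- 3; t[1, 20:24] <- 4
  tm <- list(t = t, threshold_t = 2.5, channels = adj$labels,
             times_ms = seq_len(30), divergence_ms = 0)
  class(tm) <- "tmap"
  cl <- form_clusters(tm, adj)
  expect_length(cl, 2)
  expect_setequal(vapply(cl, `[[`, 0, "mass"), c(12, 20))
  ## the same band on two adjacent channels fuses; non-adjacent stays split
  t2 <- matrix(0, 4, 30, dimnames = list(adj$labels, NULL))
  t2[1, 5:8] <- 3; t2[2, 5:8] <- 3
  tm$t <- t2
  expect_length(form_clusters(tm, adj), 1)
  t3 <- matrix(0, 4, 30, dimnames = list(adj$labels, NULL))
  t3[1, 5:8] <- 3; t3[4, 5:8] <- 3
  tm$t <- t3
  expect_length(form_clusters(tm, adj), 2)
  ## no supra-threshold points: empty list
  tm$t <- t3 * 0
  expect_length(form_clusters(tm, adj), 0)
})

test_that("random t-maps cluster identically under implementation and oracle", {
  set.seed(31)
  for (rep in 1:25) {
    nb <- random_neighbors(8)
    adj <- grid_adjacency(nb)
    t <- matrix(stats::rnorm(8 * 50, sd = 1.6), 8, 50,
                dimnames = list(adj$labels, NULL))
    tm <- structure(list(t = t, threshold_t = 2, channels = adj$labels,
                         times_ms = seq_len(50), divergence_ms = 0),
                    class = "tmap")
    got <- form_clusters(tm, adj)
    want <- oracle_clusters(t, nb, 2)
    expect_equal(length(got), length(want))
    expect_equal(sort(round(vapply(got, `[[`, 0, "mass"), 8)),
                 sort(round(vapply(want, `[[`, 0, "mass"), 8)))
  }
})

test_that("clusters at a doubled threshold nest inside the original ones", {
  set.seed(77)
  nb <- random_neighbors(8)
  adj <- grid_adjacency(nb)
  t <- matrix(stats::rnorm(8 * 60, sd = 2), 8, 60,
              dimnames = list(adj$labels, NULL))
  tm <- structure(list(t = t, threshold_t = 1.5, channels = adj$labels,
                       times_ms = seq_len(60), divergence_ms = 0),
                  class = "tmap")
  lo <- form_clusters(tm, adj, threshold = 1.5)
  hi <- form_clusters(tm, adj, threshold = 3)
  key <- function(cl) paste(cl$members$channel, cl$members$sample)
  lo_keys <- lapply(lo, key)
  for (cl in hi) {
    inside <- vapply(lo_keys, function(k) all(key(cl) %in% k), TRUE)
    expect_equal(sum(inside), 1)
  }
})

test_that("permutation p-values match exhaustive enumeration for n = 5", {
  set.seed(5)
  n <- 5
  adj <- grid_adjacency(list(2, c(1, 3), 2))
  sig <- matrix(0, 3, 40, dimnames = list(adj$labels, NULL))
  sig[1:2, 10:18] <- -1.2
  tw <- lapply(1:n, function(i)
    as_wave(sig + matrix(stats::rnorm(120, sd = 0.8), 3, 40,
                         dimnames = list(adj$labels, NULL))))
  dw <- lapply(1:n, function(i)
    as_wave(matrix(stats::rnorm(120, sd = 0.8), 3, 40,
                   dimnames = list(adj$labels, NULL))))
  ex <- cluster_permutation_test(tw, dw, adj,
                                 permutation_scheme(32, exhaustive = TRUE))
  expect_true(ex$exhaustive)
  expect_equal(length(ex$null_pos), 32)
  mc <- cluster_permutation_test(tw, dw, adj,
                                 permutation_scheme(10000, seed = 99))
  expect_false(mc$exhaustive)
  expect_equal(length(mc$clusters), length(ex$clusters))
  for (k in seq_along(ex$clusters))
    expect_lt(abs(ex$clusters[[k]]$p_value - mc$clusters[[k]]$p_value), 0.02)
  ## the observed assignment is one partition: p never drops below 1/(N+1)
  expect_true(all(vapply(mc$clusters, `[[`, 0, "p_value") >= 1 / 10001))
  expect_true(all(vapply(ex$clusters, `[[`, 0, "p_value") >= 1 / 32))
})

test_that("all-zero data yield no clusters and a calm summary", {
  adj <- grid_adjacency(list(2, 1))
  zw <- lapply(1:4, function(i)
    as_wave(matrix(0, 2, 15, dimnames = list(adj$labels, NULL))))
  res <- cluster_permutation_test(zw, zw, adj, permutation_scheme(50))
  expect_length(res$clusters, 0)
  expect_equal(nrow(summary(res)), 0)
})

test_that("p-values are invariant under joint channel relabelling", {
  set.seed(12)
  nb <- list(2, c(1, 3), 2, integer(0))
  adj <- grid_adjacency(nb)
  mkdat <- function() matrix(stats::rnorm(4 * 30), 4, 30)
  base <- lapply(1:6, function(i) mkdat())
  tw <- lapply(base, function(m) {
    m[2, 10:16] <- m[2, 10:16] - 2
    as_wave(matrix(m, 4, 30, dimnames = list(adj$labels, NULL)))
  })
  dw <- lapply(1:6, function(i)
    as_wave(matrix(mkdat(), 4, 30, dimnames = list(adj$labels, NULL))))
  r1 <- cluster_permutation_test(tw, dw, adj, permutation_scheme(500, seed = 3))
  perm <- c(3, 1, 4, 2)
  labs2 <- adj$labels[perm]
  adj2 <- grid_adjacency(lapply(nb[perm], function(v) match(v, perm)),
                         labels = labs2)
  rl <- function(w) { w$data <- w$data[perm, , drop = FALSE]
    rownames(w$data) <- labs2; w }
  r2 <- cluster_permutation_test(lapply(tw, rl), lapply(dw, rl), adj2,
                                 permutation_scheme(500, seed = 3))
  expect_equal(sort(vapply(r1$clusters, `[[`, 0, "p_value")),
               sort(vapply(r2$clusters, `[[`, 0, "p_value")))
  expect_equal(sort(vapply(r1$clusters, `[[`, 0, "mass")),
               sort(vapply(r2$clusters, `[[`, 0, "mass")))
})

test_that("a noiseless null never produces supra-threshold points", {
  adj <- grid_adjacency(list(2, 1))
  cal <- type1_calibration(5, 6, adj, n_time = 20, noise_sd = 0,
                           scheme = permutation_scheme(20), seed = 2)
  expect_equal(cal$rate, 0)
})

test_that("cluster results export to JSON and CSV", {
  set.seed(2)
  adj <- grid_adjacency(list(2, 1))
  tw <- lapply(1:5, function(i)
    as_wave(matrix(stats::rnorm(40) - 1.5, 2, 20,
                   dimnames = list(adj$labels, NULL))))
  dw <- lapply(1:5, function(i)
    as_wave(matrix(stats::rnorm(40), 2, 20,
                   dimnames = list(adj$labels, NULL))))
  res <- cluster_permutation_test(tw, dw, adj, permutation_scheme(100))
  fj <- withr::local_tempfile(fileext = ".json")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_cluster_results(res, fj, fc)
  j <- jsonlite::fromJSON(fj, simplifyVector = FALSE)
  expect_length(j, length(res$clusters))
  expect_equal(nrow(utils::read.csv(fc)), length(res$clusters))
})
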
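make_two_pop <- function(steps = 0, n_per = 4, L = 30) {
  a <- matrix("A", n_per, L)
  b <- matrix("A", n_per, L)
  if (steps > 0) b[, seq_len(steps)] <- "T"
  m <- rbind(a, b)
  rownames(m) <- sprintf("s%02d", seq_len(2 * n_per))
  list(aln = alignment_from_matrix(m),
       pop = rep(c("P1", "P2"), each = n_per))
}

test_that("summary_stats limiting cases and internal consistency", {
  same <- make_two_pop(0)
  ss <- summary_stats(same$aln, same$pop)
  expect_equal(unname(ss["P1.P2.fst"]), 0)
  expect_equal(unname(ss["P1.P2.between"]), 0)

  fixed <- make_two_pop(10)
  ssf <- summary_stats(fixed$aln, fixed$pop)
  expect_equal(unname(ssf["P1.P2.between"]), 10)
  expect_equal(unname(ssf["P1.P2.fst"]), 1)

  # element-wise agreement with the user-facing diversity operations
  set.seed(50)
  scn <- demographic_scenario(3)
  ds <- simulate_dataset(scn, c(Madagascar = 7, EastAfrica = 6,
                                WestAsia = 6), seed = 3)
  ss <- summary_stats(ds$aln, ds$meta$population)
  for (p in c("EastAfrica", "Madagascar", "WestAsia")) {
    sub <- subset_alignment(ds$aln,
                            ds$meta$sample_id[ds$meta$population == p])
    expect_equal(unname(ss[paste0(p, ".S")]), segregating_sites(sub))
    expect_equal(unname(ss[paste0(p, ".n_hap")]),
                 length(collapse_haplotypes(sub)$counts))
    expect_equal(unname(ss[paste0(p, ".H")]),
                 haplotype_diversity(collapse_haplotypes(sub)))
    dsub <- pairwise_differences(sub)
    expect_equal(unname(ss[paste0(p, ".mean_pw")]),
                 mean(dsub$diffs[upper.tri(dsub$diffs)]))
    td <- tryCatch(tajimas_d(sub)$tajima_D, error = function(e) 0)
    expect_equal(unname(ss[paste0(p, ".tajD")]), td, tolerance = 1e-12)
  }
})

test_that("abc_reject retains the right rows and is affine-invariant", {
  set.seed(51)
  n <- 1000
  tab <- data.frame(scenario = rep(1:2, each = n / 2),
                    T2 = runif(n, 700, 2000),
                    ss.x = rnorm(n), ss.y = rnorm(n, 5, 2),
                    ss.z = rnorm(n, -2, 0.5))
  obs <- c(x = 0.2, y = 4, z = -2.1)
  rej <- abc_reject(obs, tab, 0.01)
  expect_equal(rej$n_retained, 10)
  expect_equal(length(rej$index), 10)
  # retained distances do not exceed any rejected distance
  expect_true(all(diff(rej$distance) >= 0))

  # a row identical to the observation is always retained
  tab2 <- tab
  tab2[7, c("ss.x", "ss.y", "ss.z")] <- obs
  rej2 <- abc_reject(obs, tab2, 0.005)
  expect_true(7 %in% rej2$index)
  expect_equal(min(rej2$distance), 0)

  # affine rescaling of one statistic leaves the retained set unchanged
  tab3 <- tab
  tab3$ss.y <- tab3$ss.y * 40 + 3
  obs3 <- obs; obs3["y"] <- obs["y"] * 40 + 3
  rej3 <- abc_reject(obs3, tab3, 0.01)
  expect_equal(sort(rej3$index), sort(rej$index))

  # degenerate statistic dropped with a warning
  tab4 <- tab; tab4$ss.z <- 1
  expect_warning(abc_reject(obs, tab4, 0.01), "degenerate")
})

test_that("scenario_posterior limiting cases", {
  set.seed(52)
  n <- 600
  tab <- data.frame(scenario = rep(1:3, each = n / 3),
                    ss.a = rnorm(n), ss.b = rnorm(n))
  # retained all from one scenario
  tab1 <- tab; tab1$ss.a[tab1$scenario == 2] <- 100
  obs <- c(a = 100, b = 0)
  rej <- abc_reject(obs, tab1, 0.05)
  expect_true(all(tab1$scenario[rej$index] == 2))
  post <- scenario_posterior(tab1, rej, obs)
  expect_equal(post$PP$pp, c(0, 1, 0))
  expect_equal(sum(post$PP$pp), 1)

  # labels independent of statistics: PP near 1/3 each
  obs0 <- c(a = 0, b = 0)
  rej0 <- abc_reject(obs0, tab, 0.5)
  post0 <- scenario_posterior(tab, rej0, obs0)
  expect_equal(sum(post0$PP$pp), 1, tolerance = 1e-8)
  expect_true(all(abs(post0$PP$pp - 1 / 3) < 0.15))
  expect_true(all(post0$PP$lo <= post0$PP$pp & post0$PP$pp <= post0$PP$hi))

  # invariant to duplicating the reference table
  tabd <- rbind(tab, tab)
  rejd <- abc_reject(obs0, tabd, 0.5)
  postd <- scenario_posterior(tabd, rejd, obs0)
  expect_equal(postd$PP$pp, post0$PP$pp, tolerance = 0.02)
})

test_that("estimate_params concentrates at an exactly matching row", {
  set.seed(53)
  n <- 500
  tab <- data.frame(scenario = 2, T2 = runif(n, 700, 2000),
                    ss.a = rnorm(n), ss.b = rnorm(n))
  obs <- c(a = tab$ss.a[42], b = tab$ss.b[42])
  rej <- abc_reject(obs, tab, 0.01)
  post <- estimate_params(tab, rej, obs, 2, "T2",
                          prior_range = c(700, 2000))
  expect_equal(sum(post$weights), 1, tolerance = 1e-12)
  expect_true(all(post$weights >= 0))
  expect_true(all(post$draws >= 700 & post$draws <= 2000))
  expect_true(post$hpd[1] <= post$median && post$median <= post$hpd[2])
  # the exactly matching row carries the largest weight
  expect_equal(rej$index[which.max(post$weights)], 42L)
})

test_that("weighted quantile and HPD are correct on known inputs", {
  x <- c(1, 2, 3, 4, 100)
  w <- c(0.24, 0.24, 0.24, 0.24, 0.04)
  expect_equal(weighted_quantile(x, w, 0.5), 3)
  hpd <- weighted_hpd(x, w, 0.95)
  expect_equal(hpd, c(1, 4))     # shortest interval with >= 95% weight
  # uniform weights: interval excludes the far outlier
  expect_equal(weighted_hpd(c(0, 1, 2, 50), rep(0.25, 4), 0.75), c(0, 2))
})
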
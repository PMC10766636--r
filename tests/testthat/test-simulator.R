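test_that("prior draws respect ranges and order constraints", {
  set.seed(40)
  d1 <- draw_priors(demographic_scenario(1), 2000)
  expect_true(all(d1$T1 > d1$Ta))
  expect_true(all(d1$Ta >= 800 & d1$Ta <= 1200))
  expect_true(all(d1$T1 >= 800 & d1$T1 <= 2000))
  d3 <- draw_priors(demographic_scenario(3), 2000)
  expect_true(all(d3$Ta > d3$T3))
  expect_true(all(d3$T3 >= 700 & d3$T3 <= 1200))
  # unconstrained T2 marginal is uniform
  d2 <- draw_priors(demographic_scenario(2), 2000)
  ks <- suppressWarnings(ks.test(d2$T2, "punif", 700, 2000))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(d2$N_Madagascar >= 10 & d2$N_Madagascar <= 1e5))
})

test_that("coalescent times match analytic expectations", {
  set.seed(41)
  # pair TMRCA ~ Exp(mean N)
  tm <- replicate(4000, simulate_genealogy(NULL, list(N_pop = 1000),
                                           c(pop = 2))$tmrca)
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 1000), 3 * se)

  # total tree length for k = 10: E = 2N * sum_{i=1}^{9} 1/i
  tl <- replicate(2000, {
    g <- simulate_genealogy(NULL, list(N_pop = 500), c(pop = 10))
    sum(g$edge.length)
  })
  target <- 2 * 500 * sum(1 / (1:9))
  se <- sd(tl) / sqrt(length(tl))
  expect_lt(abs(mean(tl) - target), 3 * se)
})

test_that("population splits gate cross-population coalescence", {
  set.seed(42)
  scn <- demographic_scenario(2)
  for (r in 1:20) {
    p <- draw_priors(scn, 1)
    g <- simulate_genealogy(scn, p, c(Madagascar = 5, WestAsia = 5))
    # walk coalescences in time order; the first event merging clusters
    # that contain both populations must be later than T2
    n <- g$n_tip
    cluster <- as.list(seq_len(n))
    owner <- seq_len(n)                   # tip -> cluster index
    parents <- unique(g$edge[, 1])
    parents <- parents[order(g$node_time[parents])]
    for (nd in parents) {
      ch <- g$edge[g$edge[, 1] == nd, 2]
      tips <- unlist(lapply(ch, function(c)
        if (c <= n) c else cluster[[c]]))
      pops_in <- unique(g$tip.pop[tips])
      if (length(pops_in) > 1) expect_gte(g$node_time[nd], p$T2)
      cluster[[nd]] <- tips
    }
  }
})

test_that("mutation engine matches the analytic HKY expectation", {
  mod0 <- hky_model(mu_site = 0)
  g2 <- simulate_genealogy(NULL, list(N_pop = 100), c(pop = 4))
  a0 <- mutate_sequences(g2, mod0, 50)
  expect_equal(length(unique(apply(a0$seqs, 1, paste0, collapse = ""))), 1)

  # two-leaf tree with fixed separation: mean pairwise differences equal
  # L * (1-p_inv) * mean over gamma categories of HKY difference
  # probability, from the matrix-exponential closed form
  set.seed(43)
  mod <- hky_model(kappa = 5, freqs = c(A = .3, C = .2, G = .2, T = .3),
                   alpha = 0.7, p_inv = 0.3, mu_site = 1e-4)
  t_half <- 500                       # years per branch
  g <- list(edge = rbind(c(3L, 1L), c(3L, 2L)),
            edge.length = c(t_half, t_half),
            tip.label = c("x", "y"), tip.pop = c("p", "p"), n_tip = 2L,
            node_time = c(0, 0, t_half), root = 3L, tmrca = t_half)
  L <- 400
  reps <- 400
  dd <- replicate(reps, {
    a <- mutate_sequences(g, mod, L)
    pairwise_differences(a)$diffs[1, 2]
  })
  p_diff <- vapply(mod$cat_rates, function(r) {
    P <- hky_transition_matrix(mod, mod$mu_site * r * 2 * t_half)
    1 - sum(mod$freqs * diag(P))
  }, 0)
  expected <- L * (1 - mod$p_inv) * mean(p_diff)
  se <- sd(dd) / sqrt(reps)
  expect_lt(abs(mean(dd) - expected), 3 * se)

  # base composition approaches the stationary frequencies
  set.seed(44)
  big <- mutate_sequences(g, mod, 10000)
  freq_obs <- table(factor(big$seqs, levels = c("A", "C", "G", "T"))) /
    (2 * 10000)
  expect_true(all(abs(as.numeric(freq_obs) - mod$freqs) < 0.02))
})

test_that("simulate_dataset is reproducible and respects the topology", {
  scn <- demographic_scenario(1)
  sizes <- c(Madagascar = 8, EastAfrica = 6, WestAsia = 7)
  d1 <- simulate_dataset(scn, sizes, seed = 7)
  d2 <- simulate_dataset(scn, sizes, seed = 7)
  expect_identical(d1$aln$seqs, d2$aln$seqs)
  expect_identical(d1$truth, d2$truth)
  expect_equal(unname(table(d1$meta$population)[names(sizes)]),
               unname(sizes), ignore_attr = TRUE)
  expect_equal(d1$aln$n, sum(sizes))

  # Scenario 1: Madagascar-EastAfrica diverge at Ta < T1 =
  # Madagascar-WestAsia divergence; with fixed sizes the mean distances
  # must order accordingly
  set.seed(45)
  mod <- hky_model(p_inv = 0)
  params <- data.frame(Ta = 1000, T1 = 1900, N_Madagascar = 800,
                       N_EastAfrica = 800, N_WestAsia = 800)
  dme <- dmw <- numeric(60)
  for (r in 1:60) {
    g <- simulate_genealogy(scn, params, sizes)
    a <- mutate_sequences(g, mod, 1230)
    dd <- pairwise_differences(a)$diffs
    me <- d1$meta$population  # same layout: labels follow sample order
    pops <- g$tip.pop
    dme[r] <- mean(dd[pops == "Madagascar", pops == "EastAfrica"])
    dmw[r] <- mean(dd[pops == "Madagascar", pops == "WestAsia"])
  }
  expect_lt(mean(dme), mean(dmw))
  expect_gt(mean(dmw - dme), 0)
})

test_that("summary statistics are exchangeable within populations", {
  set.seed(46)
  scn <- demographic_scenario(2)
  sizes <- c(Madagascar = 6, EastAfrica = 5, WestAsia = 5)
  ds <- simulate_dataset(scn, sizes, seed = 11)
  ss1 <- summary_stats(ds$aln, ds$meta$population)
  # permute samples within each population
  perm <- unlist(lapply(split(seq_len(ds$aln$n), ds$meta$population),
                        sample), use.names = FALSE)
  aln_p <- alignment_from_matrix(ds$aln$seqs[perm, ])
  ss2 <- summary_stats(aln_p, ds$meta$population[perm])
  expect_equal(ss1, ss2)
})
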
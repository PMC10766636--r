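# Diversity statistics, Tajima's D, mismatch distribution and expansion
# dating for haploid (mitochondrial) sequence samples.

#' Mutation-rate constants for molecular dating
#'
#' Bundles the per-site yearly mutation rate, sequence length, the derived
#' per-sequence rate and the generation interval used to convert mutational
#' time into years.
#'
#' @param L sequence length in sites (default 1230, a complete chicken
#'   D-loop).
#' @param mu_site mutations/site/year (default 3.13e-7, the chicken
#'   mitochondrial control-region rate).
#' @param generation_years generation interval in years (default 1).
#' @return list(`mu_site`, `L`, `mu_seq` = mu_site * L, `generation_years`).
#' @export
rate_constants <- function(L = 1230, mu_site = 3.13e-7, generation_years = 1) {
  stopifnot(L > 0, mu_site > 0, generation_years > 0)
  list(mu_site = mu_site, L = L, mu_seq = mu_site * L,
       generation_years = generation_years)
}

#' Nucleotide diversity (pi)
#'
#' Mean over unordered sequence pairs of the per-site p-distance
#' d_ij / comparable_ij (pairwise deletion, no multiple-hit correction).
#'
#' @param diffs a `pairwise_diffs` object.
#' @return pi per site (numeric scalar).
#' @export
nucleotide_diversity <- function(diffs) {
  stopifnot(inherits(diffs, "pairwise_diffs"))
  ut <- upper.tri(diffs$diffs)
  mean(diffs$diffs[ut] / diffs$comparable[ut])
}

#' Haplotype diversity (H)
#'
#' H = n/(n-1) * (1 - sum p_i^2): the bias-corrected probability that two
#' randomly drawn sequences carry different haplotypes.
#'
#' @param ht a `haplotype_table`.
#' @return H in [0, 1].
#' @export
haplotype_diversity <- function(ht) {
  stopifnot(inherits(ht, "haplotype_table"))
  n <- ht$n
  if (n < 2) stop("need at least 2 sequences")
  n / (n - 1) * (1 - sum(ht$freqs^2))
}

#' Number of segregating sites
#'
#' A site segregates if at least two distinct unambiguous bases occur among
#' the non-missing individuals.
#'
#' @param aln a `dloop_alignment`.
#' @return integer count S.
#' @export
segregating_sites <- function(aln) {
  stopifnot(inherits(aln, "dloop_alignment"))
  sum(seg_cols_cpp(aln$code))
}

# Tajima (1989) constants a1..e2 for sample size n.
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Tajima's D with beta-approximation significance
#'
#' D = (k_hat - S/a1) / sqrt(e1*S + e2*S*(S-1)), where k_hat is the mean
#' pairwise difference count (pairwise deletion) and S the number of
#' segregating sites. Significance uses Tajima's (1989) approximation: D is
#' treated as a rescaled beta variate on (Dmin, Dmax) with mean 0 and
#' variance 1, and a two-tailed p-value is read from that distribution.
#'
#' @param aln a `dloop_alignment` with n >= 4.
#' @return A `diversity_stats` list: `n`, `S`, `k_hat`, `pi_site`, `H`,
#'   `tajima_D`, `tajima_p`, `tajima_p_flag` (one of "ns", "p<0.05",
#'   "p<0.01").
#' @export
tajimas_d <- function(aln) {
  stopifnot(inherits(aln, "dloop_alignment"))
  n <- aln$n
  if (n < 4) stop("need at least 4 sequences")
  S <- segregating_sites(aln)
  if (S == 0) stop("undefined (no segregating sites)")
  pd <- pairwise_differences(aln)
  ut <- upper.tri(pd$diffs)
  k_hat <- mean(pd$diffs[ut])
  k <- tajima_constants(n)
  D <- (k_hat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  # Beta approximation: support limits for large S (even/odd sample size).
  dmax_num <- if (n %% 2 == 0) n / (2 * (n - 1)) else (n + 1) / (2 * n)
  Dmin <- (2 / n - 1 / k$a1) / sqrt(k$e2)
  Dmax <- (dmax_num - 1 / k$a1) / sqrt(k$e2)
  m <- -Dmin / (Dmax - Dmin)              # mean of the standard beta
  v <- 1 / (Dmax - Dmin)^2                # variance of the standard beta
  s0 <- m * (1 - m) / v - 1
  p_shape <- m * s0; q_shape <- (1 - m) * s0
  Fd <- stats::pbeta((D - Dmin) / (Dmax - Dmin), p_shape, q_shape)
  p <- 2 * min(Fd, 1 - Fd)
  flag <- if (p < 0.01) "p<0.01" else if (p < 0.05) "p<0.05" else "ns"
  ht <- collapse_haplotypes(aln)
  structure(list(n = n, S = S, k_hat = k_hat,
                 pi_site = nucleotide_diversity(pd),
                 H = haplotype_diversity(ht),
                 tajima_D = D, tajima_p = p, tajima_p_flag = flag),
            class = "diversity_stats")
}

#' Observed mismatch distribution
#'
#' Histogram of pairwise difference counts over all unordered pairs,
#' normalized to sum to one. Element i of the result is the frequency of
#' pairs differing at i-1 sites.
#'
#' @param diffs a `pairwise_diffs`.
#' @return numeric vector of frequencies, names "0".."max".
#' @export
mismatch_observed <- function(diffs) {
  stopifnot(inherits(diffs, "pairwise_diffs"))
  d <- diffs$diffs[upper.tri(diffs$diffs)]
  f <- tabulate(d + 1L, nbins = max(d) + 1L)
  stats::setNames(f / sum(f), 0:max(d))
}

#' Expected mismatch distribution under sudden expansion
#'
#' The Rogers-Harpending (1992) three-parameter curve for a population that
#' grew instantaneously from theta0 to theta1 at mutational time tau = 2*mu*t
#' before present:
#' \deqn{F_j = \hat F_j(\theta_1) + e^{-\tau(\theta_1+1)/\theta_1}
#'   \sum_{i=0}^{j} \frac{\tau^i}{i!}
#'   [\hat F_{j-i}(\theta_0) - \hat F_{j-i}(\theta_1)]}
#' with the equilibrium distribution \eqn{\hat F_j(\theta) =
#' \theta^j/(\theta+1)^{j+1}}.
#'
#' The curve is evaluated from the pairwise coalescent with a piecewise
#' constant rate: a pair either coalesces within the expanded epoch
#' (geometric-equilibrium shape truncated at tau) or survives it
#' (probability exp(-tau/theta1)), accumulates Poisson(tau) mutations, and
#' then coalesces under the ancestral equilibrium theta0:
#' \deqn{F_j = \hat F_j(\theta_1)\,[1 - P(\mathrm{Pois}(\lambda_1\tau) \le j)]
#'   + e^{-\tau/\theta_1} \sum_{i=0}^{j} \mathrm{dpois}(i;\tau)\,
#'     \hat F_{j-i}(\theta_0), \quad \lambda_1 = (\theta_1+1)/\theta_1.}
#'
#' @param tau mutational time since expansion (>= 0).
#' @param theta0,theta1 pre-/post-expansion theta (per sequence).
#' @param max_k largest difference count to evaluate.
#' @return numeric vector over 0..max_k (not renormalized).
#' @export
expected_mismatch <- function(tau, theta0, theta1, max_k) {
  stopifnot(tau >= 0, theta0 >= 0, theta1 > 0, max_k >= 0)
  j <- 0:max_k
  Fhat <- function(theta) {
    if (theta == 0) return(c(1, rep(0, max_k)))
    exp(j * log(theta) - (j + 1) * log(theta + 1))
  }
  F0 <- Fhat(theta0); F1 <- Fhat(theta1)
  lam1 <- (theta1 + 1) / theta1
  pois <- stats::dpois(j, tau)
  conv <- vapply(j, function(jj)
    sum(pois[1:(jj + 1)] * F0[jj:0 + 1]), 0)
  F1 * (1 - stats::ppois(j, lam1 * tau)) + exp(-tau / theta1) * conv
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Least-squares fit of the Rogers-Harpending expected curve to an observed
#' mismatch frequency vector: a deterministic coarse grid over (tau, theta0,
#' theta1) followed by Nelder-Mead refinement from the best grid point.
#'
#' @param obs observed frequency vector over 0..max (sums to 1).
#' @param theta1_max ceiling for theta1 (default 1000).
#' @param grid_n grid resolution per parameter (default 12).
#' @return A `mismatch_fit` list: `tau`, `theta0`, `theta1`, `SSD`,
#'   `observed`, `expected` (renormalized over the observed support).
#' @export
fit_sudden_expansion <- function(obs, theta1_max = 1000, grid_n = 12) {
  stopifnot(is.numeric(obs), all(obs >= 0))
  obs <- obs / sum(obs)
  max_k <- length(obs) - 1L
  if (max_k == 0)   # all pairs identical: degenerate, no expansion signal
    return(structure(list(tau = 0, theta0 = 0, theta1 = theta1_max,
                          SSD = 0, observed = obs, expected = 1),
                     class = "mismatch_fit"))
  mean_d <- sum((0:max_k) * obs)
  ssd <- function(par) {
    e <- expected_mismatch(par[1], par[2], par[3], max_k)
    e <- e / sum(e)
    sum((obs - e)^2)
  }
  taus <- seq(0, max(3 * mean_d, 2), length.out = grid_n)
  th0s <- seq(0, max(mean_d, 1), length.out = grid_n)
  th1s <- exp(seq(log(0.5), log(theta1_max), length.out = grid_n))
  grid <- as.matrix(expand.grid(tau = taus, theta0 = th0s, theta1 = th1s))
  vals <- apply(grid, 1, ssd)
  best <- grid[which.min(vals), ]
  opt <- stats::optim(best, function(p) {
    if (p[1] < 0 || p[2] < 0 || p[3] <= 0 || p[3] > theta1_max) return(1e9)
    ssd(p)
  }, method = "Nelder-Mead",
     control = list(maxit = 2000, reltol = 1e-12))
  par <- opt$par
  if (par[2] > par[3]) par[2] <- par[3]   # enforce theta0 <= theta1
  e <- expected_mismatch(par[1], par[2], par[3], max_k)
  structure(list(tau = unname(par[1]), theta0 = unname(par[2]),
                 theta1 = unname(par[3]), SSD = ssd(par),
                 observed = obs, expected = e / sum(e)),
            class = "mismatch_fit")
}

#' Date a sudden expansion from tau
#'
#' tau = 2*mu*t with mu the per-sequence yearly mutation rate, so
#' t = tau / (2 * mu_seq) years before present.
#'
#' @param tau mutational time of the expansion.
#' @param rates a [rate_constants()] list.
#' @return time in years.
#' @export
#' @examples
#' expansion_time(0.248, rate_constants(L = 1230)) # ~ 322 years
expansion_time <- function(tau, rates = rate_constants()) {
  stopifnot(tau >= 0)
  tau / (2 * rates$mu_seq)
}

#' Date a population divergence from a net per-site distance
#'
#' d = 2*mu_site*t, so t = d / (2 * mu_site) years before present.
#'
#' @param net_distance_per_site net between-population distance per site.
#' @param rates a [rate_constants()] list.
#' @return time in years.
#' @export
#' @examples
#' divergence_time(2.85e-4, rate_constants()) # ~ 455 years
divergence_time <- function(net_distance_per_site, rates = rate_constants()) {
  stopifnot(net_distance_per_site >= 0)
  net_distance_per_site / (2 * rates$mu_site)
}

#' Per-group diversity report
#'
#' Convenience wrapper computing n, S, pi, H, Tajima's D and its significance
#' flag for each level of a metadata grouping column.
#'
#' @param aln a `dloop_alignment`.
#' @param meta sample metadata data.frame.
#' @param group metadata column to group by (default "population").
#' @return data.frame, one row per group.
#' @export
diversity_by_group <- function(aln, meta, group = "population") {
  stopifnot(group %in% names(meta))
  groups <- split(meta$sample_id, meta[[group]])
  rows <- lapply(names(groups), function(g) {
    sub <- subset_alignment(aln, groups[[g]])
    ds <- tryCatch(tajimas_d(sub), error = function(e) NULL)
    if (is.null(ds))
      return(data.frame(group = g, n = sub$n, S = NA, pi = NA, H = NA,
                        tajima_D = NA, flag = NA))
    data.frame(group = g, n = ds$n, S = ds$S, pi = ds$pi_site, H = ds$H,
               tajima_D = ds$tajima_D, flag = ds$tajima_p_flag)
  })
  do.call(rbind, rows)
}
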
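# Approximate Bayesian computation: summary statistics, MAD-standardized
# rejection, multinomial-logistic scenario posterior probabilities, and
# local-linear parameter posteriors.

#' Summary-statistic vector for a multi-population dataset
#'
#' Fixed-order vector used for ABC distances. Per population (in the order
#' given by `pops`): S, number of haplotypes, haplotype diversity H, mean
#' pairwise differences, variance of pairwise differences, Tajima's D. Per
#' population pair (lexicographic in the same order): mean between-population
#' pairwise differences and FST in the 1 - within/between form. Undefined
#' entries (e.g. Tajima's D with S = 0) are encoded as 0; the validity mask
#' is returned as an attribute.
#'
#' @param aln a `dloop_alignment`.
#' @param pop character vector: population of each alignment row.
#' @param pops population order (default: sorted unique values of `pop`).
#' @return named numeric vector with attribute `valid` (logical mask).
#' @export
summary_stats <- function(aln, pop, pops = sort(unique(pop))) {
  stopifnot(inherits(aln, "dloop_alignment"), length(pop) == aln$n)
  pd <- pairwise_differences(aln)
  d <- pd$diffs
  idx <- split(seq_along(pop), pop)[pops]
  if (any(lengths(idx) == 0)) stop("empty population")
  # only columns that vary anywhere can segregate or split haplotypes
  # within a population (missing/ambiguity classes count as a state for
  # the haplotype key, matching exact-sequence collapsing on clean data)
  var_col <- which(seg_cols_cpp(aln$code) | colSums(aln$code == 0L) > 0)
  code_var <- aln$code[, var_col, drop = FALSE]
  clean <- ncol(code_var) == 0 || all(code_var != 0L)
  out <- numeric(0); valid <- logical(0)
  for (p in pops) {
    ii <- idx[[p]]
    n_i <- length(ii)
    sub_code <- code_var[ii, , drop = FALSE]
    S <- sum(seg_cols_cpp(sub_code))
    if (clean) {
      # no missing data: zero pairwise distance implies identity
      D0 <- d[ii, ii, drop = FALSE] == 0L
      grp <- apply(D0, 1, which.max)       # first identical row
      counts <- tabulate(grp)
      counts <- counts[counts > 0]
    } else {
      key <- if (ncol(sub_code) == 0) rep("", n_i) else
        do.call(paste, c(as.data.frame(sub_code), sep = "."))
      counts <- tabulate(match(key, unique(key)))
    }
    H <- if (n_i >= 2)
      n_i / (n_i - 1) * (1 - sum((counts / n_i)^2)) else 0
    dp <- d[ii, ii][upper.tri(d[ii, ii])]
    mpd <- if (length(dp)) mean(dp) else 0
    vpd <- if (length(dp) > 1) stats::var(dp) else 0
    td <- NA_real_
    if (n_i >= 4 && S >= 1) {
      k <- tajima_constants(n_i)
      td <- (mpd - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
    }
    vals <- c(S = S, n_hap = length(counts), H = H, mean_pw = mpd,
              var_pw = vpd, tajD = if (is.na(td)) 0 else td)
    names(vals) <- paste(p, names(vals), sep = ".")
    out <- c(out, vals)
    valid <- c(valid, rep(TRUE, 5), !is.na(td))
  }
  np <- length(pops)
  for (a in seq_len(np - 1)) for (b in (a + 1):np) {
    ii <- idx[[pops[a]]]; jj <- idx[[pops[b]]]
    between <- mean(d[ii, jj, drop = FALSE])
    wi <- d[ii, ii][upper.tri(d[ii, ii])]
    wj <- d[jj, jj][upper.tri(d[jj, jj])]
    within <- mean(c(wi, wj))
    fst <- if (between > 0) 1 - within / between else 0
    vals <- c(between, fst)
    names(vals) <- paste(pops[a], pops[b], c("between", "fst"), sep = ".")
    out <- c(out, vals)
    valid <- c(valid, TRUE, between > 0)
  }
  attr(out, "valid") <- valid
  out
}

#' Build an ABC reference table
#'
#' Simulates `n_per_scenario` datasets under each scenario with parameters
#' drawn from the priors, and records parameters and summary statistics.
#'
#' @param scenarios list of `demographic_scenario` objects.
#' @param n_per_scenario simulations per scenario.
#' @param sample_sizes named integer vector of per-population sample sizes.
#' @param model a `mutation_model`.
#' @param L sequence length.
#' @param seed integer seed for the whole table.
#' @param progress print a progress line every 1000 simulations.
#' @return data.frame: `scenario`, parameter columns (NA where a parameter
#'   does not occur in a scenario), then statistic columns prefixed `ss.`.
#' @export
build_reference_table <- function(scenarios, n_per_scenario, sample_sizes,
                                  model = hky_model(), L = 1230, seed = 1,
                                  progress = FALSE) {
  set.seed(seed)
  pops <- sort(names(sample_sizes))
  par_names <- unique(unlist(lapply(scenarios, function(s)
    c(names(s$time_priors), paste0("N_", s$populations)))))
  rows <- vector("list", length(scenarios) * n_per_scenario)
  k <- 0L
  for (scn in scenarios) {
    pars <- draw_priors(scn, n_per_scenario)
    for (i in seq_len(n_per_scenario)) {
      g <- simulate_genealogy(scn, pars[i, ], sample_sizes)
      aln <- mutate_sequences(g, model, L)
      ss <- summary_stats(aln, g$tip.pop, pops)
      k <- k + 1L
      pv <- stats::setNames(rep(NA_real_, length(par_names)), par_names)
      pv[names(pars)] <- as.numeric(pars[i, ])
      rows[[k]] <- c(scenario = scn$scenario_id, pv,
                     stats::setNames(as.numeric(ss),
                                     paste0("ss.", names(ss))))
      if (progress && k %% 1000 == 0)
        message("simulated ", k, " datasets")
    }
  }
  as.data.frame(do.call(rbind, rows))
}

#' ABC rejection step
#'
#' Statistics are standardized by their table-wide median absolute
#' deviation (statistics with MAD 0 are dropped with a warning), distances
#' are Euclidean, and the ceiling(tolerance * nrow) closest simulations are
#' retained.
#'
#' @param observed named numeric vector of observed statistics (names
#'   without the `ss.` prefix or with it; matched either way).
#' @param table reference table from [build_reference_table()].
#' @param tolerance fraction of rows to retain (0 < tolerance <= 1).
#' @return list `index` (retained row indices, by increasing distance),
#'   `distance` (their distances), `n_retained`, `dropped_stats`.
#' @export
abc_reject <- function(observed, table, tolerance = 0.01) {
  stopifnot(nrow(table) > 0, tolerance > 0, tolerance <= 1)
  ss_cols <- grep("^ss\\.", names(table), value = TRUE)
  obs_names <- names(observed)
  if (!all(startsWith(obs_names, "ss.")))
    names(observed) <- paste0("ss.", obs_names)
  use <- intersect(ss_cols, names(observed))
  if (!length(use)) stop("no matching statistics")
  X <- as.matrix(table[, use, drop = FALSE])
  mads <- apply(X, 2, stats::mad)
  drop <- mads == 0 | !is.finite(mads)
  if (any(drop))
    warning("dropping degenerate statistics: ",
            paste(sub("^ss\\.", "", use[drop]), collapse = ", "))
  use <- use[!drop]; X <- X[, !drop, drop = FALSE]; mads <- mads[!drop]
  Z <- sweep(X, 2, mads, "/")
  zo <- observed[use] / mads
  dist <- sqrt(colSums((t(Z) - zo)^2))
  n_keep <- ceiling(tolerance * nrow(table))
  ord <- order(dist)[seq_len(n_keep)]
  list(index = ord, distance = dist[ord], n_retained = n_keep,
       dropped_stats = sub("^ss\\.", "", names(mads)[drop]),
       used_stats = use, mads = mads)
}

# Weighted multinomial logistic regression by Newton-Raphson with a small
# ridge for stability. y: factor (K classes); X: model matrix (with
# intercept); wts: observation weights (local smoothing weights in the ABC
# use). Returns coefficients B (p x (K-1)) and the inverse Hessian
# (covariance).
.multinom_fit <- function(y, X, wts = rep(1, nrow(X)), ridge = 1e-4,
                          max_iter = 100) {
  K <- nlevels(y); p <- ncol(X); m <- nrow(X)
  Y <- matrix(0, m, K); Y[cbind(seq_len(m), as.integer(y))] <- 1
  B <- matrix(0, p, K - 1)
  for (it in seq_len(max_iter)) {
    eta <- cbind(0, X %*% B)
    eta <- eta - apply(eta, 1, max)
    P <- exp(eta); P <- P / rowSums(P)
    grad <- numeric(p * (K - 1))
    H <- matrix(0, p * (K - 1), p * (K - 1))
    for (k in 2:K) {
      gk <- crossprod(X, wts * (Y[, k] - P[, k])) - ridge * B[, k - 1]
      grad[((k - 2) * p + 1):((k - 1) * p)] <- gk
      for (l in 2:K) {
        w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
        Hkl <- -crossprod(X, X * (wts * w))
        if (k == l) Hkl <- Hkl - ridge * diag(p)
        H[((k - 2) * p + 1):((k - 1) * p),
          ((l - 2) * p + 1):((l - 1) * p)] <- Hkl
      }
    }
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    B_new <- B - matrix(step, p, K - 1)
    if (max(abs(B_new - B)) < 1e-8) { B <- B_new; break }
    B <- B_new
  }
  eta <- cbind(0, X %*% B); eta <- eta - apply(eta, 1, max)
  P <- exp(eta); P <- P / rowSums(P)
  cov <- tryCatch(solve(-H), error = function(e) NULL)
  list(B = B, cov = cov, P = P, levels = levels(y))
}

#' Scenario posterior probabilities from retained simulations
#'
#' Multinomial logistic regression of the scenario indicator on the
#' (summary - observed) differences among retained simulations, with
#' Epanechnikov weights on the rejection distance; the fitted
#' probabilities at zero are the posterior probabilities. Confidence
#' intervals come from the regression's asymptotic covariance by the delta
#' method. When the regression is singular or only one scenario is
#' retained, the retained-fraction estimator is used and flagged.
#'
#' @param table reference table.
#' @param rej result of [abc_reject()].
#' @param observed observed statistic vector (same naming as for
#'   [abc_reject()]).
#' @return An `abc_scenario_result`: data.frame `PP` (scenario, pp, lo, hi),
#'   `method` ("mnlogit" or "rejection"), `n_retained`, `tolerance_n`.
#' @export
scenario_posterior <- function(table, rej, observed) {
  idx <- rej$index
  scen <- factor(table$scenario[idx])
  use <- rej$used_stats
  obs_names <- names(observed)
  if (!all(startsWith(obs_names, "ss.")))
    names(observed) <- paste0("ss.", obs_names)
  all_levels <- sort(unique(table$scenario))
  if (nlevels(scen) == 1) {
    pp <- as.numeric(all_levels == levels(scen))
    res <- data.frame(scenario = all_levels, pp = pp, lo = pp, hi = pp)
    return(structure(list(PP = res, method = "degenerate",
                          n_retained = length(idx)),
                     class = "abc_scenario_result"))
  }
  Xs <- sweep(as.matrix(table[idx, use, drop = FALSE]), 2, rej$mads, "/")
  zo <- observed[use] / rej$mads
  Xc <- sweep(Xs, 2, zo)           # centered: observed maps to 0
  # drop collinear columns
  qr_x <- qr(Xc)
  keep <- qr_x$pivot[seq_len(qr_x$rank)]
  X <- cbind(1, Xc[, keep, drop = FALSE])
  # Epanechnikov weights on the rejection distance (standard local
  # smoothing for regression-based ABC model choice)
  delta <- max(rej$distance)
  wts <- if (delta > 0) pmax(0, 1 - (rej$distance / delta)^2) else
    rep(1, length(idx))
  if (all(wts == 0)) wts <- rep(1, length(idx))
  fit <- .multinom_fit(scen, X, wts = wts)
  if (is.null(fit) || is.null(fit$cov)) {
    tabf <- base::table(factor(table$scenario[idx], levels = all_levels))
    pp <- as.numeric(tabf) / length(idx)
    se <- sqrt(pp * (1 - pp) / length(idx))
    res <- data.frame(scenario = all_levels, pp = pp,
                      lo = pmax(0, pp - 1.96 * se),
                      hi = pmin(1, pp + 1.96 * se))
    return(structure(list(PP = res, method = "rejection",
                          n_retained = length(idx)),
                     class = "abc_scenario_result"))
  }
  # PP at x = 0: softmax of the intercepts
  K <- length(fit$levels); p <- ncol(X)
  b0 <- c(0, fit$B[1, ])
  pp <- exp(b0 - max(b0)); pp <- pp / sum(pp)
  # delta method on the intercept block
  int_idx <- (seq_len(K - 1) - 1) * p + 1
  V <- fit$cov[int_idx, int_idx, drop = FALSE]
  # d pp_k / d b0_l (l = 2..K): pp_k (delta_kl - pp_l)
  Jac <- matrix(0, K, K - 1)
  for (k in seq_len(K)) for (l in 2:K)
    Jac[k, l - 1] <- pp[k] * ((k == l) - pp[l])
  se <- sqrt(pmax(0, diag(Jac %*% V %*% t(Jac))))
  present <- match(fit$levels, as.character(all_levels))
  pp_full <- se_full <- numeric(length(all_levels))
  pp_full[present] <- pp; se_full[present] <- se
  res <- data.frame(scenario = all_levels, pp = pp_full,
                    lo = pmax(0, pp_full - 1.96 * se_full),
                    hi = pmin(1, pp_full + 1.96 * se_full))
  structure(list(PP = res, method = "mnlogit", n_retained = length(idx)),
            class = "abc_scenario_result")
}

#' @export
print.abc_scenario_result <- function(x, ...) {
  cat("ABC scenario posterior (", x$method, ", ", x$n_retained,
      " retained)\n", sep = "")
  print(x$PP, row.names = FALSE)
  invisible(x)
}

#' Local-linear parameter posterior for one scenario
#'
#' Beaumont-style regression adjustment: among retained simulations of the
#' chosen scenario, the parameter is regressed on the standardized summary
#' differences with Epanechnikov weights on the rejection distance; the
#' adjusted draws (prediction at the observed statistics plus residuals)
#' are clipped to the prior range and summarized by weighted median and 95%
#' highest posterior density interval.
#'
#' @param table reference table.
#' @param rej result of [abc_reject()].
#' @param observed observed statistics.
#' @param scenario_id scenario whose retained rows are used.
#' @param param parameter column name (e.g. "T2").
#' @param prior_range length-2 numeric; adjusted draws are clipped to it.
#' @return An `abc_param_posterior`: list `param`, `draws`, `weights`,
#'   `median`, `hpd` (length 2), `adjusted` (logical).
#' @export
estimate_params <- function(table, rej, observed, scenario_id, param,
                            prior_range = NULL) {
  sel <- rej$index[table$scenario[rej$index] == scenario_id]
  dists <- rej$distance[table$scenario[rej$index] == scenario_id]
  if (length(sel) < 2) stop("too few retained rows for scenario")
  theta <- table[[param]][sel]
  if (anyNA(theta)) stop("parameter undefined for scenario")
  obs_names <- names(observed)
  if (!all(startsWith(obs_names, "ss.")))
    names(observed) <- paste0("ss.", obs_names)
  use <- rej$used_stats
  Xs <- sweep(as.matrix(table[sel, use, drop = FALSE]), 2, rej$mads, "/")
  zo <- observed[use] / rej$mads
  Xc <- sweep(Xs, 2, zo)
  delta <- max(dists)
  w <- if (delta > 0) 1 - (dists / delta)^2 else rep(1, length(dists))
  w[w < 0] <- 0
  if (all(w == 0)) w <- rep(1, length(w))
  qr_x <- qr(Xc * sqrt(w))
  keep <- qr_x$pivot[seq_len(qr_x$rank)]
  X <- cbind(1, Xc[, keep, drop = FALSE])
  fit <- tryCatch(stats::lm.wfit(X, theta, w), error = function(e) NULL)
  adjusted <- !is.null(fit) && all(is.finite(fit$coefficients[1]))
  if (adjusted) {
    draws <- fit$coefficients[1] + fit$residuals
  } else {
    draws <- theta
  }
  if (!is.null(prior_range))
    draws <- pmin(pmax(draws, prior_range[1]), prior_range[2])
  wn <- w / sum(w)
  med <- weighted_quantile(draws, wn, 0.5)
  hpd <- weighted_hpd(draws, wn, 0.95)
  structure(list(param = param, draws = draws, weights = wn, median = med,
                 hpd = hpd, adjusted = adjusted),
            class = "abc_param_posterior")
}

#' Weighted quantile (inverse of the weighted ECDF)
#' @param x values.
#' @param w normalized weights.
#' @param p probability.
#' @return numeric scalar.
#' @export
weighted_quantile <- function(x, w, p) {
  ord <- order(x)
  cw <- cumsum(w[ord])
  x[ord][which(cw >= p)[1]]
}

#' Weighted highest-posterior-density interval
#'
#' Shortest interval containing at least `level` of the total weight,
#' found by scanning the sorted draws.
#'
#' @param x draws.
#' @param w normalized weights.
#' @param level coverage.
#' @return c(lower, upper).
#' @export
weighted_hpd <- function(x, w, level = 0.95) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- c(0, cumsum(w))
  n <- length(x)
  best <- c(x[1], x[n]); best_len <- x[n] - x[1]
  j <- 1
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j <= n && cw[j + 1] - cw[i] < level) j <- j + 1
    if (j > n) break
    if (x[j] - x[i] < best_len) {
      best_len <- x[j] - x[i]; best <- c(x[i], x[j])
    }
  }
  best
}
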
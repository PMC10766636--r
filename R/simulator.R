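# Haploid (maternal) coalescent simulator for three-population demographic
# scenarios with HKY+I+Gamma sequence evolution. Time is measured in years
# before present; the generation interval is one year so years equal
# generations. Populations split cleanly (no migration, no recombination:
# mitochondrial DNA).

.SCENARIO_POPS <- c("Madagascar", "EastAfrica", "WestAsia")

#' Demographic scenarios for the origin of an island population
#'
#' Three alternative colonization histories of a focal island population
#' (Madagascar) relative to a mainland neighbor (EastAfrica) and a source
#' region (WestAsia):
#' \itemize{
#' \item Scenario 1: Madagascar splits from WestAsia at T1; EastAfrica
#'   splits from Madagascar at Ta (T1 > Ta).
#' \item Scenario 2: Madagascar splits from WestAsia at T2; EastAfrica
#'   splits from WestAsia at Ta (no order constraint).
#' \item Scenario 3: EastAfrica splits from WestAsia at Ta; Madagascar
#'   splits from EastAfrica at T3 (Ta > T3).
#' }
#' Time priors (years before present): Ta ~ U(800, 1200),
#' T1 ~ U(800, 2000), T2 ~ U(700, 2000), T3 ~ U(700, 1200). Each extant or
#' ancestral population has an effective-size prior on (10, 1e5),
#' log-uniform by default: effective female sizes are scale parameters
#' spanning four orders of magnitude, and under a plain uniform prior the
#' overwhelming mass at N of tens of thousands makes the three topologies
#' statistically indistinguishable at these split times (set
#' `n_prior_log = FALSE` for the plain uniform).
#'
#' @param scenario_id 1, 2 or 3.
#' @param n_prior length-2 vector, prior range for every population's
#'   effective size.
#' @param n_prior_log draw N log-uniformly over `n_prior` (default TRUE).
#' @return A `demographic_scenario`: list with `scenario_id`, `populations`,
#'   `events` (data.frame daughter/ancestor/time_var), `time_priors`,
#'   `constraints` (character, e.g. "T1>Ta"), `n_prior`, `n_prior_log`.
#' @export
demographic_scenario <- function(scenario_id, n_prior = c(10, 1e5),
                                 n_prior_log = TRUE) {
  stopifnot(scenario_id %in% 1:3)
  ev <- switch(scenario_id,
    `1` = data.frame(daughter = c("EastAfrica", "Madagascar"),
                     ancestor = c("Madagascar", "WestAsia"),
                     time_var = c("Ta", "T1")),
    `2` = data.frame(daughter = c("EastAfrica", "Madagascar"),
                     ancestor = c("WestAsia", "WestAsia"),
                     time_var = c("Ta", "T2")),
    `3` = data.frame(daughter = c("Madagascar", "EastAfrica"),
                     ancestor = c("EastAfrica", "WestAsia"),
                     time_var = c("T3", "Ta")))
  priors <- list(Ta = c(800, 1200), T1 = c(800, 2000),
                 T2 = c(700, 2000), T3 = c(700, 1200))
  constraints <- switch(scenario_id, `1` = "T1>Ta", `2` = character(0),
                        `3` = "Ta>T3")
  structure(list(scenario_id = scenario_id, populations = .SCENARIO_POPS,
                 events = ev,
                 time_priors = priors[unique(c(ev$time_var))],
                 constraints = constraints, n_prior = n_prior,
                 n_prior_log = n_prior_log),
            class = "demographic_scenario")
}

#' Draw scenario parameters from their priors
#'
#' Uniform draws for every time variable (rejection-sampled on the
#' scenario's order constraints) and uniform or log-uniform draws for the
#' per-population effective sizes, following the scenario's `n_prior_log`.
#'
#' @param scn a `demographic_scenario`.
#' @param n number of draws.
#' @return data.frame, one row per draw: time variables and `N_<population>`
#'   columns.
#' @export
draw_priors <- function(scn, n = 1) {
  stopifnot(inherits(scn, "demographic_scenario"))
  vars <- names(scn$time_priors)
  draw_block <- function(m) {
    out <- as.data.frame(lapply(scn$time_priors, function(r)
      stats::runif(m, r[1], r[2])))
    names(out) <- vars
    out
  }
  ok_rows <- function(df) {
    keep <- rep(TRUE, nrow(df))
    for (cs in scn$constraints) {
      p <- strsplit(cs, ">")[[1]]
      keep <- keep & df[[p[1]]] > df[[p[2]]]
    }
    keep
  }
  acc <- draw_block(n)
  acc <- acc[ok_rows(acc), , drop = FALSE]
  while (nrow(acc) < n) {
    more <- draw_block(n)
    acc <- rbind(acc, more[ok_rows(more), , drop = FALSE])
  }
  acc <- acc[seq_len(n), , drop = FALSE]
  for (p in scn$populations)
    acc[[paste0("N_", p)]] <- if (isTRUE(scn$n_prior_log))
      exp(stats::runif(n, log(scn$n_prior[1]), log(scn$n_prior[2])))
    else stats::runif(n, scn$n_prior[1], scn$n_prior[2])
  rownames(acc) <- NULL
  acc
}

#' Simulate a coalescent genealogy under a demographic scenario
#'
#' Structured haploid coalescent: within a population of effective size N,
#' each pair of lineages coalesces at rate 1/N per generation; at a split
#' time the daughter's lineages move into the ancestor. Branch lengths are
#' in years (generation = 1 year).
#'
#' @param scn a `demographic_scenario`, or NULL for a single panmictic
#'   population.
#' @param params single-row data.frame (or named vector/list) of parameter
#'   values as produced by [draw_priors()]; for `scn = NULL` only
#'   `N_<population>` is needed.
#' @param sample_sizes named integer vector of sample sizes per extant
#'   population.
#' @return list `edge` (2-column matrix), `edge.length` (years),
#'   `tip.label`, `tip.pop`, `n_tip`, `tmrca` - convertible with
#'   [genealogy_to_phylo()].
#' @export
simulate_genealogy <- function(scn, params, sample_sizes) {
  params <- as.list(params)
  if (is.null(scn)) {
    pops <- names(sample_sizes)
    ev_t <- numeric(0); ev_d <- ev_a <- integer(0)
  } else {
    pops <- scn$populations
    ev_t <- vapply(scn$events$time_var, function(v) params[[v]], 0)
    ord <- order(ev_t)
    ev_t <- ev_t[ord]
    ev_d <- match(scn$events$daughter[ord], pops)
    ev_a <- match(scn$events$ancestor[ord], pops)
  }
  stopifnot(all(names(sample_sizes) %in% pops), all(sample_sizes >= 1))
  Npop <- vapply(pops, function(p) params[[paste0("N_", p)]], 0)

  n_tip <- sum(sample_sizes)
  lin_pop <- match(rep(names(sample_sizes), sample_sizes), pops)
  tip_pop <- rep(names(sample_sizes), sample_sizes)
  tip_label <- paste0(tip_pop, "_", unlist(lapply(sample_sizes, seq_len)))
  res <- coalesce_cpp(as.integer(lin_pop), as.numeric(Npop),
                      as.numeric(ev_t), as.integer(ev_d),
                      as.integer(ev_a))
  node_time <- res$node_time
  list(edge = res$edge,
       edge.length = node_time[res$edge[, 1]] - node_time[res$edge[, 2]],
       tip.label = tip_label, tip.pop = tip_pop, n_tip = n_tip,
       node_time = node_time, root = res$root,
       tmrca = node_time[res$root])
}

#' Convert a simulated genealogy to an ape phylo
#' @param g output of [simulate_genealogy()].
#' @return an `ape::phylo`.
#' @export
genealogy_to_phylo <- function(g) {
  n <- g$n_tip
  # renumber internal nodes to the ape convention (root = n + 1, then
  # breadth-first)
  kids <- split(g$edge[, 2], g$edge[, 1])
  newid <- integer(2L * n - 1L)
  newid[seq_len(n)] <- seq_len(n)
  queue <- g$root; nxt <- n + 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    newid[v] <- nxt; nxt <- nxt + 1L
    ch <- kids[[as.character(v)]]
    queue <- c(queue, ch[ch > n])
  }
  tr <- list(edge = cbind(newid[g$edge[, 1]], newid[g$edge[, 2]]),
             edge.length = g$edge.length,
             tip.label = g$tip.label, Nnode = n - 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' HKY+I+Gamma mutation model
#'
#' HKY substitution rates with transition/transversion parameter kappa and
#' arbitrary base frequencies; rate heterogeneity as a proportion p_inv of
#' invariant sites plus a discrete-gamma multiplier (mean 1 across variable
#' sites). The per-site yearly rate mu applies to variable sites.
#'
#' @param kappa transition/transversion rate ratio parameter (default 10,
#'   transitions strongly favored as typical for mtDNA).
#' @param freqs stationary base frequencies (A, C, G, T).
#' @param alpha gamma shape (default 0.5).
#' @param p_inv proportion of invariant sites (default 0.5).
#' @param mu_site mutations/site/year on variable sites (default 3.13e-7).
#' @param n_cat number of discrete gamma categories (default 4).
#' @return A `mutation_model`: normalized rate matrix, jump chain, leave
#'   rates, category multipliers, and the input parameters.
#' @export
hky_model <- function(kappa = 10, freqs = c(A = .25, C = .25, G = .25,
                                            T = .25),
                      alpha = 0.5, p_inv = 0.5, mu_site = 3.13e-7,
                      n_cat = 4) {
  stopifnot(kappa > 0, length(freqs) == 4, all(freqs > 0),
            alpha > 0, p_inv >= 0, p_inv < 1, mu_site >= 0)
  freqs <- freqs / sum(freqs)
  names(freqs) <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(names(freqs), names(freqs)))
  transition <- matrix(c(FALSE, FALSE, TRUE, FALSE,
                         FALSE, FALSE, FALSE, TRUE,
                         TRUE, FALSE, FALSE, FALSE,
                         FALSE, TRUE, FALSE, FALSE), 4, 4)  # A<->G, C<->T
  for (i in 1:4) for (j in 1:4) if (i != j)
    Q[i, j] <- freqs[j] * (if (transition[i, j]) kappa else 1)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))          # mean rate at stationarity
  Q <- Q / scale
  leave <- -diag(Q)
  jump <- Q; diag(jump) <- 0
  jump <- jump / rowSums(jump)
  # median-of-quantile discrete gamma categories, normalized to mean 1
  cat_rates <- stats::qgamma((seq_len(n_cat) - 0.5) / n_cat, alpha, alpha)
  cat_rates <- cat_rates / mean(cat_rates)
  structure(list(kappa = kappa, freqs = freqs, alpha = alpha,
                 p_inv = p_inv, mu_site = mu_site, n_cat = n_cat,
                 Q = Q, leave = leave, jump = jump, cat_rates = cat_rates,
                 q_max = max(leave)),
            class = "mutation_model")
}

#' Analytic HKY transition probabilities
#'
#' Closed-form P(t) = exp(Qt) for the normalized HKY matrix, used as an
#' independent check of the stochastic mutation engine.
#'
#' @param model a `mutation_model`.
#' @param t branch length in expected substitutions/site.
#' @return 4x4 transition probability matrix.
#' @export
hky_transition_matrix <- function(model, t) {
  eig <- eigen(model$Q)
  V <- eig$vectors
  Re(V %*% diag(exp(eig$values * t)) %*% solve(V))
}

#' Evolve sequences along a genealogy (HKY+I+Gamma)
#'
#' The root sequence is drawn from the stationary frequencies. Each site is
#' invariant with probability p_inv, otherwise assigned a discrete-gamma
#' rate category. Substitutions along each branch are generated exactly by
#' uniformization of the normalized HKY chain at per-site rate
#' mu_site * multiplier.
#'
#' @param g genealogy from [simulate_genealogy()] (branch lengths in years).
#' @param model a `mutation_model`.
#' @param L sequence length in sites.
#' @return A `dloop_alignment` of the tip sequences (rows named by tip
#'   label).
#' @export
mutate_sequences <- function(g, model, L) {
  stopifnot(inherits(model, "mutation_model"), L > 0)
  # per-site rate multipliers
  r <- numeric(L)
  variable <- stats::runif(L) >= model$p_inv
  n_var <- sum(variable)
  if (n_var > 0)
    r[variable] <- sample(model$cat_rates, n_var, replace = TRUE)
  # parent-before-child edge order (edges are appended in coalescence
  # order, so the reverse order works from the root down)
  ord <- rev(seq_len(nrow(g$edge)))
  jump_cum <- t(apply(model$jump, 1, cumsum))
  tips <- mutate_tree_cpp(g$edge[ord, , drop = FALSE],
                          g$edge.length[ord], g$n_tip, g$root, r,
                          model$mu_site, model$q_max, model$leave,
                          jump_cum, cumsum(model$freqs))
  alignment_from_code(tips, g$tip.label)
}

#' Simulate a complete multi-population dataset
#'
#' Draws parameters from the scenario priors (unless supplied), simulates a
#' genealogy and sequences, and returns alignment, metadata and the true
#' parameter record.
#'
#' @param scn a `demographic_scenario`.
#' @param sample_sizes named integer vector (populations -> sample sizes).
#' @param model a `mutation_model`.
#' @param L sequence length (default 1230).
#' @param params optional single-row data.frame of fixed parameters; drawn
#'   from the priors when NULL.
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first so the dataset is reproducible.
#' @return A `simulated_dataset`: list `aln`, `meta` (sample_id, locality,
#'   region, elevation, population), `truth` (scenario_id, parameters,
#'   seed).
#' @export
simulate_dataset <- function(scn, sample_sizes, model = hky_model(),
                             L = 1230, params = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) params <- draw_priors(scn, 1)
  g <- simulate_genealogy(scn, params, sample_sizes)
  aln <- mutate_sequences(g, model, L)
  meta <- data.frame(sample_id = g$tip.label, locality = g$tip.pop,
                     region = "Lowland_west", elevation = 0,
                     population = g$tip.pop, stringsAsFactors = FALSE)
  structure(list(aln = aln, meta = meta,
                 truth = c(list(scenario_id =
                                  if (is.null(scn)) NA else scn$scenario_id,
                                seed = seed), as.list(params))),
            class = "simulated_dataset")
}
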
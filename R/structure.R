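# Between-population distances, NJ tree with midpoint rooting, AMOVA
# variance components and the SAMOVA-style annealing search for the K-group
# partition maximizing the among-group component.

#' Within-, between- and net between-population distances
#'
#' Per-site p-distances (pairwise deletion, no multiple-hit correction).
#' The net distance between populations X and Y is
#' dA = dXY - (dX + dY)/2, clamped at 0; a singleton population has
#' within-distance 0.
#'
#' @param aln a `dloop_alignment`.
#' @param meta metadata data.frame with `sample_id` and the grouping column.
#' @param group_by metadata column defining subpopulations (default
#'   "locality").
#' @return A `pop_distances`: list with `labels`, `dX` (within, per group),
#'   `dXY` (between matrix, diagonal = within), `dA` (net matrix), `n_per`.
#' @export
pop_distances <- function(aln, meta, group_by = "locality") {
  stopifnot(inherits(aln, "dloop_alignment"), group_by %in% names(meta))
  pop <- meta[[group_by]][match(rownames(aln$seqs), meta$sample_id)]
  if (anyNA(pop)) stop("group absent from metadata for some samples")
  labs <- sort(unique(pop))
  if (length(labs) < 2) stop("need at least 2 groups")
  pd <- pairwise_differences(aln)
  ps <- pd$diffs / pd$comparable
  idx <- split(seq_along(pop), pop)
  m <- length(labs)
  dXY <- matrix(0, m, m, dimnames = list(labs, labs))
  dX <- stats::setNames(numeric(m), labs)
  for (i in seq_len(m)) {
    ii <- idx[[labs[i]]]
    dX[i] <- if (length(ii) < 2) 0 else
      mean(ps[ii, ii][upper.tri(ps[ii, ii])])
    dXY[i, i] <- dX[i]
    if (i < m) for (j in (i + 1):m) {
      jj <- idx[[labs[j]]]
      dXY[i, j] <- dXY[j, i] <- mean(ps[ii, jj, drop = FALSE])
    }
  }
  dA <- dXY - (outer(dX, dX, "+")) / 2
  dA[dA < 0] <- 0
  diag(dA) <- 0
  structure(list(labels = labs, dX = dX, dXY = dXY, dA = dA,
                 n_per = lengths(idx)[labs]),
            class = "pop_distances")
}

#' Neighbor-joining tree over subpopulations
#'
#' Saitou-Nei agglomeration on the net-distance matrix. Negative branch
#' lengths are set to zero with the deficit transferred to the adjacent
#' branch at the same node so path lengths are preserved where possible.
#'
#' @param pd a `pop_distances` object or a symmetric distance matrix.
#' @return an `ape::phylo` (unrooted; for 2 taxa, a single edge split
#'   evenly).
#' @export
nj_tree <- function(pd) {
  d <- if (inherits(pd, "pop_distances")) pd$dA else as.matrix(pd)
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("non-symmetric matrix")
  m <- nrow(d)
  if (m < 2) stop("need at least 2 taxa")
  if (m == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                        rownames(d)[1], d[1, 2] / 2,
                                        rownames(d)[2], d[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  # clamp negative branches, transferring length to the adjacent edge
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    len <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    node <- tr$edge[e, 2]
    adj <- which(tr$edge[, 1] == node)
    if (length(adj)) tr$edge.length[adj] <- tr$edge.length[adj] + len
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return a rooted `ape::phylo`; a zero-diameter tree is returned rooted
#'   arbitrarily with attribute `zero_diameter = TRUE`.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n_tip <- length(tree$tip.label)
  if (n_tip < 2) stop("need at least 2 leaves")
  dt <- ape::dist.nodes(tree)[seq_len(n_tip), seq_len(n_tip)]
  if (max(dt) == 0) {
    out <- tree
    attr(out, "zero_diameter") <- TRUE
    return(out)
  }
  phangorn::midpoint(tree)
}

# Pooled squared-distance sums between populations: S[p, q] = sum over
# ordered pairs (i in p, j in q) of delta^2_ij. AMOVA/SAMOVA both read from
# this summary, so partitions can be re-scored in O(#pops^2).
pop_ss_matrix <- function(diffs, pop) {
  labs <- sort(unique(pop))
  idx <- split(seq_along(pop), pop)[labs]
  m <- length(labs)
  S <- matrix(0, m, m, dimnames = list(labs, labs))
  for (i in seq_len(m)) for (j in i:m) {
    S[i, j] <- S[j, i] <-
      sum(diffs[idx[[i]], idx[[j]], drop = FALSE])
  }
  list(S = S, n = lengths(idx), labels = labs)
}

# Variance components for a fixed partition, from the pooled summary.
# groups: integer group index per population (1..G).
amova_components <- function(ss, groups) {
  S <- ss$S; np <- ss$n; labs <- ss$labels
  N <- sum(np); P <- length(np); G <- max(groups)
  ssd_total <- sum(S) / (2 * N)
  ssd_wp <- sum(diag(S) / (2 * np))
  ssd_wg <- 0
  sum_np2_over_ng <- 0; ng2 <- 0
  for (g in seq_len(G)) {
    sel <- which(groups == g)
    n_g <- sum(np[sel])
    ssd_wg <- ssd_wg + sum(S[sel, sel]) / (2 * n_g)
    sum_np2_over_ng <- sum_np2_over_ng + sum(np[sel]^2) / n_g
    ng2 <- ng2 + n_g^2
  }
  ssd_ap <- ssd_wg - ssd_wp          # among populations within groups
  ssd_ag <- ssd_total - ssd_wg       # among groups
  df_a <- G - 1; df_b <- P - G; df_c <- N - P
  sigma_c <- if (df_c > 0) ssd_wp / df_c else NA_real_
  n_coef <- if (df_b > 0) (N - sum_np2_over_ng) / df_b else NA_real_
  sigma_b <- if (df_b > 0) (ssd_ap / df_b - sigma_c) / n_coef else 0
  np2_over_N <- sum(np^2) / N
  n1 <- if (df_a > 0) (sum_np2_over_ng - np2_over_N) / df_a else NA_real_
  n2 <- if (df_a > 0) (N - ng2 / N) / df_a else NA_real_
  sigma_a <- if (df_a > 0)
    (ssd_ag / df_a - sigma_c - n1 * sigma_b) / n2 else 0
  tot <- sigma_a + sigma_b + sigma_c
  list(sigma = c(a = sigma_a, b = sigma_b, c = sigma_c),
       SSD = c(among_groups = ssd_ag, among_pops = ssd_ap,
               within_pops = ssd_wp, total = ssd_total),
       df = c(a = df_a, b = df_b, c = df_c),
       FCT = sigma_a / tot, FSC = sigma_b / (sigma_b + sigma_c),
       FST = (sigma_a + sigma_b) / tot)
}

#' AMOVA Phi-statistics for a fixed grouping of subpopulations
#'
#' Excoffier-Smouse-Quattro nested analysis of molecular variance with
#' pairwise difference counts as squared Euclidean distances. Returns the
#' variance components (among groups, among populations within groups,
#' within populations) and the Phi-statistics FCT, FSC, FST.
#'
#' @param aln a `dloop_alignment`.
#' @param meta metadata with `sample_id` and the grouping column.
#' @param partition named list: group name -> character vector of
#'   subpopulation labels; must cover all subpopulations, disjointly.
#' @param group_by metadata column defining subpopulations (default
#'   "locality").
#' @return A `samova_result` list with `K`, `partition`, `sigma`, `SSD`,
#'   `df`, `FCT`, `FSC`, `FST`.
#' @export
amova <- function(aln, meta, partition, group_by = "locality") {
  pop <- meta[[group_by]][match(rownames(aln$seqs), meta$sample_id)]
  if (anyNA(pop)) stop("group absent from metadata for some samples")
  pd <- pairwise_differences(aln)
  ss <- pop_ss_matrix(pd$diffs, pop)
  all_labs <- unlist(partition)
  if (anyDuplicated(all_labs) || !setequal(all_labs, ss$labels))
    stop("partition must cover all subpopulations disjointly")
  groups <- integer(length(ss$labels))
  for (g in seq_along(partition))
    groups[ss$labels %in% partition[[g]]] <- g
  comp <- amova_components(ss, groups)
  structure(c(list(K = length(partition), partition = partition), comp),
            class = "samova_result")
}

#' SAMOVA: search the K-group partition maximizing FCT
#'
#' Simulated-annealing search over partitions of subpopulations into K
#' non-empty groups, maximizing the among-group Phi-statistic FCT
#' (geometric cooling, single-deme reassignment moves, multiple seeded
#' restarts). No geographic contiguity constraint is imposed by default.
#'
#' @param aln a `dloop_alignment`.
#' @param meta metadata with `sample_id` and the grouping column.
#' @param K number of groups (2 <= K < number of subpopulations).
#' @param group_by metadata column defining subpopulations.
#' @param n_restarts independent annealing restarts (default 20).
#' @param seed RNG seed (default 1).
#' @param t0,cooling,steps_per_temp,n_temps annealing schedule.
#' @return A `samova_result` with the best partition found, its
#'   Phi-statistics, and `trace` (best FCT per restart).
#' @export
samova <- function(aln, meta, K, group_by = "locality", n_restarts = 20,
                   seed = 1, t0 = 1, cooling = 0.95, steps_per_temp = 100,
                   n_temps = 60) {
  pop <- meta[[group_by]][match(rownames(aln$seqs), meta$sample_id)]
  if (anyNA(pop)) stop("group absent from metadata for some samples")
  pd <- pairwise_differences(aln)
  ss <- pop_ss_matrix(pd$diffs, pop)
  m <- length(ss$labels)
  if (K < 2 || K >= m) stop("K out of range")
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  res <- samova_anneal_cpp(ss$S, as.integer(ss$n), as.integer(K),
                           as.integer(n_restarts), t0, cooling,
                           as.integer(steps_per_temp), as.integer(n_temps))
  best_g <- res$groups; trace <- res$trace
  partition <- split(ss$labels, best_g)
  names(partition) <- paste0("group", seq_along(partition))
  comp <- amova_components(ss, best_g)
  structure(c(list(K = K, partition = partition, trace = trace,
                   seed = seed, n_restarts = n_restarts), comp),
            class = "samova_result")
}

#' Exhaustive K = 2 SAMOVA
#'
#' Enumerates all 2^(m-1) - 1 bipartitions of the subpopulations and returns
#' the one with maximal FCT. Feasible for m <= ~15; used as the exact
#' reference for the annealing search.
#'
#' @inheritParams samova
#' @return A `samova_result`.
#' @export
samova_exhaustive_k2 <- function(aln, meta, group_by = "locality") {
  pop <- meta[[group_by]][match(rownames(aln$seqs), meta$sample_id)]
  pd <- pairwise_differences(aln)
  ss <- pop_ss_matrix(pd$diffs, pop)
  m <- length(ss$labels)
  if (m > 16) stop("too many subpopulations for exhaustive search")
  best_f <- -Inf; best_g <- NULL
  for (mask in seq_len(2^(m - 1) - 1)) {
    g <- as.integer(intToBits(mask))[seq_len(m)] + 1L
    v <- amova_components(ss, g)$FCT
    if (!is.na(v) && v > best_f) { best_f <- v; best_g <- g }
  }
  partition <- split(ss$labels, best_g)
  names(partition) <- paste0("group", seq_along(partition))
  comp <- amova_components(ss, best_g)
  structure(c(list(K = 2, partition = partition), comp),
            class = "samova_result")
}

#' @export
print.samova_result <- function(x, ...) {
  cat("K =", x$K, " FCT =", round(x$FCT, 4), " FSC =", round(x$FSC, 4),
      " FST =", round(x$FST, 4), "\n")
  for (g in names(x$partition))
    cat(" ", g, ":", paste(x$partition[[g]], collapse = ", "), "\n")
  invisible(x)
}
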
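# Independent brute-force oracles and fixture generators. These
# deliberately use literal loops over the definitional sums, not the
# package's vectorized/C++ paths.

.VALID <- c("A", "C", "G", "T")

rand_aln <- function(n, L, p_missing = 0) {
  m <- matrix(sample(.VALID, n * L, replace = TRUE), n, L)
  if (p_missing > 0) {
    hit <- which(stats::runif(n * L) < p_missing)
    m[hit] <- sample(c("N", "-"), length(hit), replace = TRUE)
  }
  rownames(m) <- sprintf("s%02d", seq_len(n))
  alignment_from_matrix(m)
}

# low-diversity alignment: founder haplotype plus sparse mutations
rand_popgen_aln <- function(n, L, n_mut = 10) {
  founder <- sample(.VALID, L, replace = TRUE)
  m <- matrix(rep(founder, each = n), n, L)
  for (k in seq_len(n_mut)) {
    i <- sample(n, 1); s <- sample(L, 1)
    m[i, s] <- sample(setdiff(.VALID, m[i, s]), 1)
  }
  rownames(m) <- sprintf("s%02d", seq_len(n))
  alignment_from_matrix(m)
}

oracle_pairwise <- function(aln) {
  ch <- aln$seqs
  n <- nrow(ch); L <- ncol(ch)
  diffs <- comp <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- 0L; cc <- 0L
    for (s in seq_len(L)) {
      a <- ch[i, s]; b <- ch[j, s]
      if (a %in% .VALID && b %in% .VALID) {
        cc <- cc + 1L
        if (a != b) d <- d + 1L
      }
    }
    diffs[i, j] <- d; comp[i, j] <- cc
  }
  list(diffs = diffs, comparable = comp)
}

oracle_pi <- function(aln) {
  o <- oracle_pairwise(aln)
  n <- nrow(o$diffs)
  tot <- 0; m <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + o$diffs[i, j] / o$comparable[i, j]
    m <- m + 1
  }
  tot / m
}

oracle_H <- function(aln) {
  key <- apply(aln$seqs, 1, paste0, collapse = "")
  n <- length(key)
  p <- as.numeric(table(key)) / n
  n / (n - 1) * (1 - sum(p^2))
}

oracle_S <- function(aln) {
  S <- 0L
  for (s in seq_len(ncol(aln$seqs))) {
    col <- aln$seqs[, s]
    states <- unique(col[col %in% .VALID])
    if (length(states) >= 2) S <- S + 1L
  }
  S
}

# Tajima's D from a second, literal implementation of the constants
oracle_tajima <- function(aln) {
  n <- nrow(aln$seqs)
  S <- oracle_S(aln)
  o <- oracle_pairwise(aln)
  k_hat <- mean(o$diffs[upper.tri(o$diffs)])
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# literal AMOVA sums-of-squares decomposition over all individual pairs
oracle_amova <- function(aln, pop, groups) {
  o <- oracle_pairwise(aln)
  d2 <- o$diffs
  N <- length(pop)
  pops <- sort(unique(pop))
  grp_of_pop <- vapply(pops, function(p) groups[[which(vapply(
    groups, function(g) p %in% g, TRUE))[1]]][1], "")
  grp <- vapply(pop, function(p) names(groups)[vapply(
    groups, function(g) p %in% g, TRUE)][1], "")
  ssd_within <- function(sel) {
    if (length(sel) < 2) return(0)
    tot <- 0
    for (i in sel) for (j in sel) tot <- tot + d2[i, j]
    tot / (2 * length(sel))
  }
  ssd_total <- ssd_within(seq_len(N))
  ssd_wp <- 0
  for (p in pops) ssd_wp <- ssd_wp + ssd_within(which(pop == p))
  ssd_wg <- 0
  for (g in names(groups))
    ssd_wg <- ssd_wg + ssd_within(which(grp == g))
  ssd_ap <- ssd_wg - ssd_wp
  ssd_ag <- ssd_total - ssd_wg
  P <- length(pops); G <- length(groups)
  np <- as.numeric(table(pop)[pops])
  ng <- vapply(names(groups), function(g) sum(grp == g), 0)
  sum_np2_over_ng <- 0
  for (g in names(groups)) {
    in_g <- pops[pops %in% groups[[g]]]
    sum_np2_over_ng <- sum_np2_over_ng +
      sum(np[match(in_g, pops)]^2) / sum(np[match(in_g, pops)])
  }
  sigma_c <- ssd_wp / (N - P)
  n_coef <- (N - sum_np2_over_ng) / (P - G)
  sigma_b <- (ssd_ap / (P - G) - sigma_c) / n_coef
  n1 <- (sum_np2_over_ng - sum(np^2) / N) / (G - 1)
  n2 <- (N - sum(ng^2) / N) / (G - 1)
  sigma_a <- (ssd_ag / (G - 1) - sigma_c - n1 * sigma_b) / n2
  list(sigma = c(a = sigma_a, b = sigma_b, c = sigma_c),
       SSD = c(among_groups = ssd_ag, among_pops = ssd_ap,
               within_pops = ssd_wp, total = ssd_total),
       FCT = sigma_a / (sigma_a + sigma_b + sigma_c))
}

# Prim's algorithm: total weight of a minimum spanning tree
oracle_mst_weight <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  total <- 0
  for (k in seq_len(n - 1)) {
    best <- Inf; bj <- NA
    for (i in which(in_tree)) for (j in which(!in_tree))
      if (d[i, j] < best) { best <- d[i, j]; bj <- j }
    total <- total + best
    in_tree[bj] <- TRUE
  }
  total
}

# alignment with groups of distinct composition, for AMOVA/SAMOVA tests
grouped_aln <- function(n_per, n_pops, L = 60, divergence = 4) {
  base <- sample(.VALID, L, replace = TRUE)
  rows <- list(); pop <- character(0)
  for (p in seq_len(n_pops)) {
    pop_seq <- base
    mut <- sample(L, divergence)
    for (s in mut) pop_seq[s] <- sample(setdiff(.VALID, pop_seq[s]), 1)
    for (i in seq_len(n_per)) {
      x <- pop_seq
      s <- sample(L, 1)
      x[s] <- sample(setdiff(.VALID, x[s]), 1)
      rows[[length(rows) + 1]] <- x
      pop <- c(pop, paste0("pop", p))
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("s%02d", seq_along(pop))
  list(aln = alignment_from_matrix(m),
       meta = data.frame(sample_id = rownames(m), locality = pop,
                         region = "Lowland_west", elevation = 0,
                         population = "X", stringsAsFactors = FALSE))
}

write_fasta_tmp <- function(seqs_named) {
  fa <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(paste0(">", names(seqs_named)),
                             unname(seqs_named))), fa)
  fa
}
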
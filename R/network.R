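# Median-joining haplotype network (Bandelt, Forster & Roehl 1999).
#
# Distances are Hamming counts over network-usable sites: sites containing a
# gap or any ambiguous base in any haplotype are excluded, all remaining
# sites have weight 1. The algorithm alternates (i) the epsilon-relaxed
# minimum spanning network over the current node set, (ii) removal of
# obsolete median vectors (degree <= 2), and (iii) addition of
# majority-consensus (median) vectors for connected triplets, keeping in each
# round only candidates whose connection cost is within epsilon of the
# minimum. Ties are processed in lexicographic (distance, node id) order so
# the result is reproducible.

# epsilon-relaxed minimum spanning network over an integer distance matrix.
# An edge at distance d is included iff its endpoints are not connected by
# edges of distance < d - eps. With eps = 0 this is the union of all MSTs.
msn_edges <- function(d, eps = 0) {
  n <- nrow(d)
  if (n < 2) return(matrix(integer(0), 0, 3,
                           dimnames = list(NULL, c("u", "v", "w"))))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  pw <- d[upper.tri(d)]
  ord <- order(pw, pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]; pw <- pw[ord]
  edges <- matrix(integer(0), 0, 3)
  levels <- unique(pw)
  comp <- seq_len(n)                 # union-find by relabeling (n is small)
  for (lev in levels) {
    # connectivity from strictly lower levels (relaxed by eps)
    base <- edges[edges[, 3] < lev - eps, , drop = FALSE]
    comp <- seq_len(n)
    if (nrow(base)) for (k in seq_len(nrow(base))) {
      a <- comp[base[k, 1]]; b <- comp[base[k, 2]]
      if (a != b) comp[comp == b] <- a
    }
    sel <- which(pw == lev)
    for (k in sel) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (comp[i] != comp[j])
        edges <- rbind(edges, c(i, j, lev))
    }
  }
  colnames(edges) <- c("u", "v", "w")
  edges
}

# Majority-consensus median of three encoded sequences; NULL when some site
# has three distinct states (no majority).
.majority_median <- function(a, b, c) {
  m <- ifelse(a == b | a == c, a, ifelse(b == c, b, NA_integer_))
  if (anyNA(m)) NULL else m
}

#' Build a median-joining haplotype network
#'
#' Connects observed haplotypes through inferred intermediate (median)
#' sequences following the median-joining heuristic. Sites containing gaps
#' or ambiguity codes in any haplotype are excluded from the distance; all
#' retained sites have weight 1.
#'
#' @param ht a `haplotype_table` with >= 2 haplotypes.
#' @param epsilon relaxation parameter (default 0, the usual software
#'   default; larger values admit more links and medians).
#' @param max_iter safety cap on median-addition rounds.
#' @return A `haplo_network`: list with `nodes` (data.frame: id, count,
#'   is_median), `edges` (data.frame: u, v, steps), `seqs` (encoded matrix of
#'   node sequences on network sites), `epsilon`.
#' @export
build_mj_network <- function(ht, epsilon = 0, max_iter = 25) {
  stopifnot(inherits(ht, "haplotype_table"))
  code <- .encode_seqs(ht$seqs)
  usable <- colSums(code == 0L) == 0
  code <- code[, usable, drop = FALSE]
  n_obs <- nrow(code)
  if (n_obs < 2) stop("need at least 2 haplotypes")
  labels <- rownames(ht$seqs)
  is_median <- rep(FALSE, n_obs)
  n_med <- 0L

  # recompute the spanning network and drop degree-<=2 medians until stable;
  # updates code/labels/is_median in the enclosing frame
  recompute <- function() {
    repeat {
      d <- hamming_matrix_cpp(code)
      edges <- msn_edges(d, epsilon)
      deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = nrow(code))
      drop <- which(is_median & deg <= 2)
      if (!length(drop)) return(edges)
      keep <- setdiff(seq_len(nrow(code)), drop)
      code <<- code[keep, , drop = FALSE]
      labels <<- labels[keep]; is_median <<- is_median[keep]
    }
  }

  for (iter in seq_len(max_iter)) {
    edges <- recompute()
    # candidate medians from connected triplets
    adj <- lapply(seq_len(nrow(code)), function(i)
      sort(unique(c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1]))))
    seen_keys <- apply(code, 1, paste0, collapse = ".")
    cand <- list(); cost <- numeric(0)
    for (u in seq_len(nrow(code))) {
      nb <- adj[[u]]
      if (length(nb) < 2) next
      for (a in seq_len(length(nb) - 1)) for (b in (a + 1):length(nb)) {
        v <- nb[a]; w <- nb[b]
        m <- .majority_median(code[u, ], code[v, ], code[w, ])
        if (is.null(m)) next
        key <- paste0(m, collapse = ".")
        if (key %in% seen_keys || key %in% names(cand)) next
        cc <- sum(m != code[u, ]) + sum(m != code[v, ]) + sum(m != code[w, ])
        cand[[key]] <- m; cost[key] <- cc
      }
    }
    if (!length(cand)) break
    lam <- min(cost)
    add_keys <- names(cand)[cost <= lam + epsilon]
    add_keys <- sort(add_keys)        # reproducible order
    for (key in add_keys) {
      n_med <- n_med + 1L
      code <- rbind(code, cand[[key]])
      labels <- c(labels, sprintf("Median_%02d", n_med))
      is_median <- c(is_median, TRUE)
    }
  }
  edges <- recompute()

  rownames(code) <- labels
  counts <- ifelse(is_median, 0L, as.integer(ht$counts[labels]))
  nodes <- data.frame(id = labels, count = counts, is_median = is_median,
                      stringsAsFactors = FALSE)
  edf <- data.frame(u = labels[edges[, 1]], v = labels[edges[, 2]],
                    steps = edges[, 3], stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edf, seqs = code, epsilon = epsilon),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("haplo_network:", sum(!x$nodes$is_median), "haplotypes,",
      sum(x$nodes$is_median), "median vectors,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Write network node and edge tables
#'
#' @param net a `haplo_network`.
#' @param nodes_path,edges_path output TSV paths.
#' @param ht optional `haplotype_table` for locality composition columns.
#' @param meta optional metadata data.frame (sample_id, locality).
#' @export
write_network_tables <- function(net, nodes_path, edges_path,
                                 ht = NULL, meta = NULL) {
  nodes <- net$nodes
  if (!is.null(ht) && !is.null(meta)) {
    comp <- vapply(nodes$id, function(id) {
      if (!id %in% names(ht$members)) return("")
      loc <- meta$locality[match(ht$members[[id]], meta$sample_id)]
      paste(sprintf("%s:%d", names(table(loc)), as.integer(table(loc))),
            collapse = ";")
    }, "")
    nodes$localities <- comp
  }
  utils::write.table(nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(net)
}
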
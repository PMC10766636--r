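test_that("pop_distances computes within/between/net with clamping", {
  # two groups with identical sequence composition -> dA = 0 (raw net is
  # negative: dXY = d/2 < dX = d)
  m <- rbind(a1 = c("A", "A", "A", "A"), a2 = c("T", "T", "A", "A"),
             b1 = c("A", "A", "A", "A"), b2 = c("T", "T", "A", "A"))
  aln <- alignment_from_matrix(m)
  meta <- data.frame(sample_id = rownames(m),
                     locality = c("X", "X", "Y", "Y"),
                     region = "Lowland_west", elevation = 0,
                     population = "M")
  pd <- pop_distances(aln, meta)
  expect_equal(pd$dX[["X"]], 0.5)
  expect_equal(pd$dXY["X", "Y"], 0.25)
  expect_equal(pd$dA["X", "Y"], 0)          # clamped from -0.25

  # diverged groups: positive net distance
  m2 <- rbind(a1 = c("A", "A", "A", "A"), a2 = c("A", "A", "A", "A"),
              b1 = c("T", "T", "A", "A"), b2 = c("T", "T", "A", "A"))
  pd2 <- pop_distances(alignment_from_matrix(m2), meta)
  expect_equal(pd2$dA["X", "Y"], 0.5)

  # singleton group: within-distance 0
  meta3 <- meta; meta3$locality <- c("X", "X", "X", "Z")
  pd3 <- pop_distances(aln, meta3)
  expect_equal(pd3$dX[["Z"]], 0)
})

test_that("nj_tree reproduces additive matrices and handles 2 taxa", {
  two <- matrix(c(0, 0.1, 0.1, 0), 2, dimnames = list(c("a", "b"),
                                                      c("a", "b")))
  t2 <- nj_tree(two)
  expect_equal(sort(t2$tip.label), c("a", "b"))
  expect_equal(sum(t2$edge.length), 0.1)

  # 4-taxon additive matrix from a known tree
  txt <- "((a:0.02,b:0.05):0.03,(c:0.04,d:0.01):0.02);"
  tr <- ape::read.tree(text = txt)
  d <- cophenetic(tr)
  # four-point condition sanity for the generating matrix
  s <- c(d["a", "b"] + d["c", "d"], d["a", "c"] + d["b", "d"],
         d["a", "d"] + d["b", "c"])
  expect_equal(sort(s)[2], sort(s)[3])
  rec <- nj_tree(d[c("a", "b", "c", "d"), c("a", "b", "c", "d")])
  expect_equal(cophenetic(rec)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)

  # ultrametric 3-taxon matrix: correct cherry
  d3 <- matrix(c(0, 0.02, 0.1, 0.02, 0, 0.1, 0.1, 0.1, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(d3)
  cp <- cophenetic(t3)
  expect_lt(cp["x", "y"], cp["x", "z"])

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "non-symmetric")
})

test_that("midpoint_root splits the longest path evenly", {
  t2 <- nj_tree(matrix(c(0, 0.4, 0.4, 0), 2,
                       dimnames = list(c("a", "b"), c("a", "b"))))
  r2 <- midpoint_root(t2)
  dr <- ape::dist.nodes(r2)
  root <- length(r2$tip.label) + 1
  expect_equal(unname(dr[root, 1:2]), c(0.2, 0.2))

  # caterpillar: diameter path found by brute force
  cat_tr <- ape::read.tree(
    text = "(((a:0.5,b:0.1):0.1,c:0.1):0.1,(d:0.1,e:0.7):0.1);")
  rooted <- midpoint_root(cat_tr)
  dt <- ape::dist.nodes(cat_tr)[1:5, 1:5]
  diam <- max(dt)
  ends <- which(dt == diam, arr.ind = TRUE)[1, ]
  expect_setequal(cat_tr$tip.label[ends], c("a", "e"))
  drr <- ape::dist.nodes(rooted)
  rootn <- length(rooted$tip.label) + 1
  tips_r <- match(c("a", "e"), rooted$tip.label)
  expect_equal(unname(drr[rootn, tips_r[1]]), diam / 2, tolerance = 1e-10)
  expect_equal(unname(drr[rootn, tips_r[2]]), diam / 2, tolerance = 1e-10)

  # symmetric tree: root at the center of symmetry
  sym <- ape::read.tree(text = "((a:0.1,b:0.1):0.2,(c:0.1,d:0.1):0.2);")
  rs <- midpoint_root(sym)
  ds <- ape::dist.nodes(rs)
  rootn <- length(rs$tip.label) + 1
  expect_true(all(abs(ds[rootn, 1:4] - 0.3) < 1e-10))
})

test_that("amova matches the literal sums-of-squares oracle", {
  set.seed(30)
  for (k in 1:5) {
    ga <- grouped_aln(n_per = 4, n_pops = 4, L = 40)
    part <- list(g1 = c("pop1", "pop2"), g2 = c("pop3", "pop4"))
    res <- amova(ga$aln, ga$meta, part)
    o <- oracle_amova(ga$aln, ga$meta$locality, part)
    expect_equal(unname(res$sigma), unname(o$sigma), tolerance = 1e-10)
    expect_equal(unname(res$SSD), unname(o$SSD), tolerance = 1e-10)
    expect_equal(res$FCT, o$FCT, tolerance = 1e-10)
  }
})

test_that("amova limiting cases and relabeling invariance", {
  # identical pooled composition in both groups -> FCT ~ 0
  set.seed(31)
  base <- sample(c("A", "C", "G", "T"), 30, replace = TRUE)
  mk <- function(id) { x <- base; x[id] <- "T"; x }
  m <- rbind(p1a = mk(1), p1b = mk(2), p2a = mk(1), p2b = mk(2),
             p3a = mk(1), p3b = mk(2), p4a = mk(1), p4b = mk(2))
  meta <- data.frame(sample_id = rownames(m),
                     locality = rep(c("p1", "p2", "p3", "p4"), each = 2),
                     region = "Lowland_west", elevation = 0,
                     population = "M")
  aln <- alignment_from_matrix(m)
  r0 <- amova(aln, meta, list(g1 = c("p1", "p2"), g2 = c("p3", "p4")))
  expect_lt(abs(r0$FCT), 0.3)     # no true group signal

  # fixed differences between groups, none within -> FCT = 1
  m2 <- rbind(p1a = rep("A", 10), p1b = rep("A", 10),
              p2a = rep("A", 10), p2b = rep("A", 10),
              p3a = rep("T", 10), p3b = rep("T", 10),
              p4a = rep("T", 10), p4b = rep("T", 10))
  rownames(m2) <- rownames(m)
  r1 <- amova(alignment_from_matrix(m2), meta,
              list(g1 = c("p1", "p2"), g2 = c("p3", "p4")))
  expect_equal(r1$FCT, 1)

  # invariance to relabeling populations within groups
  set.seed(32)
  ga <- grouped_aln(n_per = 3, n_pops = 4, L = 30)
  pa <- amova(ga$aln, ga$meta, list(g1 = c("pop1", "pop2"),
                                    g2 = c("pop3", "pop4")))
  pb <- amova(ga$aln, ga$meta, list(g1 = c("pop2", "pop1"),
                                    g2 = c("pop4", "pop3")))
  expect_equal(pa$sigma, pb$sigma)
  expect_equal(pa$FCT, pb$FCT)
})

test_that("samova recovers a true bipartition and beats fixed partitions", {
  set.seed(33)
  # two deeply split deme groups: pops 1-3 from cluster A, 4-6 from B
  base <- sample(c("A", "C", "G", "T"), 50, replace = TRUE)
  other <- base
  other[1:6] <- vapply(base[1:6], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], "")
  rows <- list(); loc <- character(0)
  for (p in 1:6) {
    src <- if (p <= 3) base else other
    for (i in 1:4) {
      x <- src
      s <- sample(50, 1)
      x[s] <- sample(setdiff(c("A", "C", "G", "T"), x[s]), 1)
      rows[[length(rows) + 1]] <- x
      loc <- c(loc, paste0("pop", p))
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("s%02d", seq_along(loc))
  aln <- alignment_from_matrix(m)
  meta <- data.frame(sample_id = rownames(m), locality = loc,
                     region = "Lowland_west", elevation = 0,
                     population = "M")
  sam <- samova(aln, meta, K = 2, n_restarts = 10, seed = 5)
  expect_true(setequal(sam$partition[[1]], c("pop1", "pop2", "pop3")) ||
                setequal(sam$partition[[2]], c("pop1", "pop2", "pop3")))
  # maximizer beats an arbitrary fixed partition
  fixed <- amova(aln, meta, list(g1 = c("pop1", "pop4"),
                                 g2 = c("pop2", "pop3", "pop5", "pop6")))
  expect_gte(sam$FCT, fixed$FCT - 1e-12)
  expect_error(samova(aln, meta, K = 7), "K out of range")
})
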
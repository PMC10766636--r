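test_that("read_alignment parses, normalizes and validates", {
  fa <- write_fasta_tmp(c(s1 = "ACGTA", s2 = "acgt-", s3 = "ANGTA"))
  aln <- read_alignment(fa)
  expect_equal(aln$n, 3)
  expect_equal(aln$L, 5)
  expect_equal(unname(aln$seqs["s2", ]), c("A", "C", "G", "T", "-"))
  expect_equal(aln$kept_sites, 0:4)

  ragged <- write_fasta_tmp(c(a = "ACGTA", b = "ACGTAA"))
  expect_error(read_alignment(ragged), "unaligned input")
  dup <- write_fasta_tmp(c(a = "ACGTA", a = "ACGTA"))
  expect_error(read_alignment(dup), "duplicate id")
  bad <- write_fasta_tmp(c(a = "ACGTA", b = "ACGTZ"))
  expect_error(read_alignment(bad), "bad symbol")
})

test_that("filter_sites applies the strict >70% rule and is idempotent", {
  m <- matrix("A", 10, 3, dimnames = list(sprintf("s%d", 1:10), NULL))
  m[1:8, 2] <- "N"    # 0.8 > 0.7 -> removed
  m[1:7, 3] <- "N"    # 0.7 is not > 0.7 -> kept
  aln <- alignment_from_matrix(m)
  f <- filter_sites(aln)
  expect_equal(f$L, 2)
  expect_equal(f$kept_sites, c(0L, 2L))
  expect_equal(attr(f, "removed_sites"), 1L)

  # no missing data: identity
  set.seed(1)
  clean <- rand_aln(6, 30)
  expect_equal(filter_sites(clean)$seqs, clean$seqs)

  # idempotence on random alignments with missing data
  for (k in 1:5) {
    a <- rand_aln(8, 40, p_missing = 0.4)
    f1 <- filter_sites(a, 0.3)
    f2 <- filter_sites(f1, 0.3)
    expect_equal(f2$seqs, f1$seqs)
    expect_equal(f2$kept_sites, f1$kept_sites)
  }

  allN <- alignment_from_matrix(
    matrix("N", 4, 3, dimnames = list(letters[1:4], NULL)))
  expect_error(filter_sites(allN), "empty alignment")
})

test_that("collapse_haplotypes groups identical sequences", {
  m <- rbind(s1 = c("A", "C", "G"), s2 = c("A", "C", "G"),
             s3 = c("A", "C", "G"), s4 = c("A", "C", "T"))
  ht <- collapse_haplotypes(alignment_from_matrix(m))
  expect_equal(unname(ht$counts), c(3L, 1L))
  expect_equal(unname(ht$freqs), c(0.75, 0.25))
  expect_equal(ht$members$Hap_01, c("s1", "s2", "s3"))

  same <- alignment_from_matrix(matrix("A", 5, 4,
                                       dimnames = list(letters[1:5], NULL)))
  expect_equal(unname(collapse_haplotypes(same)$counts), 5L)

  # sequences differing only at a filtered site merge
  m2 <- rbind(x = c("A", "C"), y = c("A", "G"))
  m2 <- cbind(m2, matrix("N", 2, 0))
  aln2 <- alignment_from_matrix(rbind(x = c("A", "N"), y = c("A", "C")))
  f2 <- filter_sites(aln2, 0.4)       # site 2 has 50% missing -> removed
  expect_equal(length(collapse_haplotypes(f2)$counts), 1L)

  # counts always sum to n
  set.seed(2)
  for (k in 1:5) {
    a <- rand_aln(10, 6)
    expect_equal(sum(collapse_haplotypes(a)$counts), 10L)
  }
})

test_that("pairwise_differences uses pairwise deletion and matches oracle", {
  a <- alignment_from_matrix(rbind(s1 = c("A", "C", "G", "T"),
                                   s2 = c("A", "C", "G", "A")))
  pd <- pairwise_differences(a)
  expect_equal(pd$diffs[1, 2], 1L)
  expect_equal(pd$comparable[1, 2], 4L)

  b <- alignment_from_matrix(rbind(s1 = c("A", "C", "-", "T"),
                                   s2 = c("A", "C", "G", "T")))
  pdb <- pairwise_differences(b)
  expect_equal(pdb$diffs[1, 2], 0L)
  expect_equal(pdb$comparable[1, 2], 3L)

  same <- alignment_from_matrix(rbind(a = c("A", "C"), b = c("A", "C")))
  expect_equal(pairwise_differences(same)$diffs[1, 2], 0L)

  # oracle equality and metric property on random alignments
  set.seed(3)
  for (k in 1:5) {
    a <- rand_aln(7, 25, p_missing = if (k > 3) 0.1 else 0)
    pd <- pairwise_differences(a)
    o <- oracle_pairwise(a)
    expect_equal(unname(pd$diffs), o$diffs)
    expect_equal(unname(pd$comparable), o$comparable)
    if (k <= 3) {   # gap-free: triangle inequality
      d <- pd$diffs
      n <- nrow(d)
      for (i in 1:n) for (j in 1:n) for (l in 1:n)
        expect_lte(d[i, j], d[i, l] + d[l, j])
    }
  }

  inc <- alignment_from_matrix(rbind(a = c("A", "N"), b = c("N", "C")))
  expect_error(pairwise_differences(inc), "incomparable pair")
})

test_that("assign_haplogroup picks the nearest reference and reports ties", {
  panel <- rbind(C2a = c("A", "A", "A", "A", "A"),
                 C2b = c("A", "A", "A", "A", "C"),
                 E1  = c("T", "T", "T", "T", "T"))
  labels <- c("C2", "C2", "E")
  hit <- assign_haplogroup(c("A", "A", "A", "A", "A"), panel, labels)
  expect_equal(hit$labels, "C2")
  expect_equal(hit$distance, 0L)

  one_step <- assign_haplogroup(c("A", "A", "A", "A", "G"), panel, labels)
  expect_equal(one_step$labels, "C2")
  expect_equal(one_step$distance, 1L)

  # equidistant between C2 and E references
  panel2 <- rbind(c1 = c("A", "A"), e1 = c("T", "T"))
  tie <- assign_haplogroup(c("A", "T"), panel2, c("C2", "E"))
  expect_setequal(tie$labels, c("C2", "E"))
})

test_that("sample metadata validation enforces the elevation rule", {
  meta <- data.frame(sample_id = c("a", "b"), locality = c("X", "Y"),
                     region = c("Highland", "Lowland_east"),
                     elevation = c(1400, 20), population = "M")
  expect_silent(validate_sample_table(meta))
  bad <- meta; bad$region[2] <- "Highland"
  expect_error(validate_sample_table(bad), "elevation rule")
  dup <- meta[c(1, 1), ]
  expect_error(validate_sample_table(dup), "duplicate id")
})
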
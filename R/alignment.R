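#' @useDynLib dloopr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Alphabet handling ----------------------------------------------------------

# Unambiguous bases get codes 1..4; everything else legal (gaps, N, IUPAC
# ambiguity codes) is "missing" for both the site filter and pairwise deletion.
.BASES <- c(A = 1L, C = 2L, G = 3L, T = 4L)
.AMBIG <- c("-", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "?")

.encode_seqs <- function(seq_mat) {
  code <- .BASES[seq_mat]
  code[is.na(code)] <- 0L
  matrix(code, nrow = nrow(seq_mat), dimnames = dimnames(seq_mat))
}

#' Construct an aligned sequence set
#'
#' Internal constructor and validator for the `dloop_alignment` class: a
#' rectangular matrix of haploid sequences over A/C/G/T plus gap, N and IUPAC
#' ambiguity codes, with provenance of which original alignment columns are
#' retained.
#'
#' @param seq_mat character matrix (rows = samples, named; columns = sites),
#'   single uppercase characters.
#' @param kept_sites 0-based original coordinates of the columns, strictly
#'   increasing.
#' @return A `dloop_alignment`: list with `seqs` (character matrix), `code`
#'   (integer matrix, 1..4 = ACGT, 0 = missing/ambiguous), `kept_sites`,
#'   `n`, `L`.
#' @keywords internal
new_alignment <- function(seq_mat, kept_sites = seq_len(ncol(seq_mat)) - 1L) {
  stopifnot(is.matrix(seq_mat), nrow(seq_mat) >= 1)
  ids <- rownames(seq_mat)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) stop("missing sample ids")
  if (anyDuplicated(ids)) stop("duplicate id")
  bad <- setdiff(unique(as.vector(seq_mat)), c(names(.BASES), .AMBIG))
  if (length(bad)) stop("bad symbol: ", paste(bad, collapse = " "))
  kept_sites <- as.integer(kept_sites)
  if (length(kept_sites) != ncol(seq_mat) ||
      (length(kept_sites) > 1 && any(diff(kept_sites) <= 0)))
    stop("kept_sites must match columns and be strictly increasing")
  structure(list(seqs = seq_mat, code = .encode_seqs(seq_mat),
                 kept_sites = kept_sites,
                 n = nrow(seq_mat), L = ncol(seq_mat)),
            class = "dloop_alignment")
}

#' Read an aligned FASTA file
#'
#' Reads a pre-aligned FASTA (e.g. MAFFT output) into a [new_alignment()]
#' object. Sequences are uppercased; ragged records, duplicated ids and
#' characters outside the DNA alphabet (ACGT, gap, N, IUPAC codes) are errors.
#'
#' @param fasta_path path to an aligned FASTA file.
#' @return A `dloop_alignment`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGTA", ">s2", "ACCTA"), fa)
#' aln <- read_alignment(fa)
#' aln$n; aln$L
read_alignment <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("file not found: ", fasta_path)
  recs <- Biostrings::readBStringSet(fasta_path)
  if (length(recs) == 0) stop("empty FASTA")
  if (length(unique(Biostrings::width(recs))) != 1)
    stop("unaligned input")
  ids <- sub("\\s.*$", "", names(recs))    # id = first header token
  if (anyDuplicated(ids)) stop("duplicate id")
  chr <- do.call(rbind, strsplit(toupper(as.character(recs)), ""))
  rownames(chr) <- ids
  new_alignment(chr)
}

#' Filter alignment sites by missing-data fraction
#'
#' Removes every site at which the fraction of individuals with a missing or
#' ambiguous base (gap, N, or any non-ACGT IUPAC code) strictly exceeds
#' `max_missing_frac`. A site with exactly the threshold fraction is kept.
#' `kept_sites` records original 0-based coordinates of surviving columns.
#'
#' @param aln a `dloop_alignment`.
#' @param max_missing_frac maximum tolerated missing fraction (default 0.70).
#' @return A filtered `dloop_alignment` with attribute `removed_sites`
#'   (original 0-based coordinates of dropped columns).
#' @export
filter_sites <- function(aln, max_missing_frac = 0.70) {
  stopifnot(inherits(aln, "dloop_alignment"),
            max_missing_frac >= 0, max_missing_frac <= 1)
  miss_frac <- colMeans(aln$code == 0L)
  keep <- miss_frac <= max_missing_frac
  if (!any(keep)) stop("empty alignment")
  out <- new_alignment(aln$seqs[, keep, drop = FALSE],
                       aln$kept_sites[keep])
  attr(out, "removed_sites") <- aln$kept_sites[!keep]
  out
}

#' Collapse identical sequences into haplotypes
#'
#' Sequences identical on all retained sites (exact string match, including
#' any residual ambiguity characters) share a haplotype. Haplotypes are
#' numbered by decreasing count, ties broken by first occurrence.
#'
#' @param aln a (typically site-filtered) `dloop_alignment`.
#' @return A `haplotype_table`: list with `seqs` (character matrix, one row
#'   per haplotype), `counts`, `freqs`, `members` (list of sample-id vectors),
#'   `n` (total samples), `haplotype` (per-sample haplotype id).
#' @export
collapse_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "dloop_alignment"))
  key <- apply(aln$seqs, 1, paste0, collapse = "")
  first <- !duplicated(key)
  uk <- key[first]
  counts <- as.integer(table(key)[uk])
  ord <- order(-counts, match(uk, key))
  uk <- uk[ord]; counts <- counts[ord]
  ids <- sprintf("Hap_%02d", seq_along(uk))
  members <- lapply(uk, function(k) rownames(aln$seqs)[key == k])
  names(members) <- ids
  seqs <- aln$seqs[match(uk, key), , drop = FALSE]
  rownames(seqs) <- ids
  structure(list(seqs = seqs, counts = stats::setNames(counts, ids),
                 freqs = stats::setNames(counts / aln$n, ids),
                 members = members, n = aln$n,
                 haplotype = stats::setNames(ids[match(key, uk)],
                                             rownames(aln$seqs)),
                 kept_sites = aln$kept_sites),
            class = "haplotype_table")
}

#' Pairwise nucleotide differences under pairwise deletion
#'
#' For every unordered pair of sequences, sites where either member carries a
#' missing or ambiguous base are excluded; differences are counted on the
#' remaining comparable sites.
#'
#' @param aln a `dloop_alignment` with at least 2 sequences.
#' @return A `pairwise_diffs`: list with integer matrices `diffs` and
#'   `comparable` (both n x n, symmetric, zero diagonal).
#' @export
pairwise_differences <- function(aln) {
  stopifnot(inherits(aln, "dloop_alignment"))
  if (aln$n < 2) stop("need at least 2 sequences")
  res <- diff_matrix_cpp(aln$code)
  dimnames(res$diffs) <- dimnames(res$comparable) <-
    list(rownames(aln$seqs), rownames(aln$seqs))
  off <- res$comparable[upper.tri(res$comparable)]
  if (any(off == 0)) stop("incomparable pair")
  structure(res, class = "pairwise_diffs")
}

#' Assign a haplogroup label by nearest reference
#'
#' A lightweight stand-in for tree-based haplogroup assignment: the query is
#' labeled with the haplogroup of the closest reference sequence (pairwise-
#' deletion differences); equidistant references of different haplogroups
#' yield a tie list.
#'
#' @param query_seq character vector of single characters, or 1-row matrix,
#'   in the same alignment frame as the panel.
#' @param panel_seqs character matrix of reference sequences (rows named by
#'   sequence id).
#' @param panel_labels haplogroup label per panel row.
#' @return list(`labels` = character vector (length > 1 on ties),
#'   `distance` = minimal difference count).
#' @export
assign_haplogroup <- function(query_seq, panel_seqs, panel_labels) {
  if (is.matrix(query_seq)) query_seq <- query_seq[1, ]
  stopifnot(is.matrix(panel_seqs), nrow(panel_seqs) >= 1,
            length(panel_labels) == nrow(panel_seqs))
  if (length(query_seq) != ncol(panel_seqs)) stop("alignment frame mismatch")
  m <- rbind(q = query_seq, panel_seqs)
  code <- .encode_seqs(m)
  res <- diff_matrix_cpp(code)
  d <- res$diffs[1, -1]
  dmin <- min(d)
  list(labels = unique(panel_labels[d == dmin]), distance = dmin)
}

#' Read a sample metadata table
#'
#' Tab- or comma-separated with header columns `sample_id`, `locality`,
#' `region`, `elevation`, `population`. Checks that every alignment id has
#' exactly one row and that the region label obeys the elevation rule
#' (Highland iff elevation > 1000 m).
#'
#' @param path metadata file path.
#' @param aln optional `dloop_alignment` to validate ids against.
#' @return data.frame of sample metadata.
#' @export
read_sample_table <- function(path, aln = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  meta <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  validate_sample_table(meta, aln)
}

#' @rdname read_sample_table
#' @param meta a data.frame with the metadata columns.
#' @export
validate_sample_table <- function(meta, aln = NULL) {
  need <- c("sample_id", "locality", "region", "elevation", "population")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate id in metadata")
  hl <- meta$elevation > 1000
  if (any(hl != (meta$region == "Highland")))
    stop("region inconsistent with elevation rule (Highland iff > 1000 m)")
  if (!is.null(aln)) {
    missing_ids <- setdiff(rownames(aln$seqs), meta$sample_id)
    if (length(missing_ids))
      stop("metadata missing ids: ", paste(missing_ids, collapse = ", "))
  }
  meta
}

#' Write a haplotype table to TSV
#'
#' @param ht a `haplotype_table`.
#' @param path output TSV path (haplotype_id, count, members).
#' @export
write_haplotype_table <- function(ht, path) {
  df <- data.frame(haplotype_id = names(ht$counts),
                   count = as.integer(ht$counts),
                   members = vapply(ht$members, paste, "", collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @export
print.dloop_alignment <- function(x, ...) {
  cat("dloop_alignment:", x$n, "sequences x", x$L, "sites\n")
  invisible(x)
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", length(x$counts), "haplotypes from", x$n,
      "sequences\n")
  invisible(x)
}

# Fast internal constructor from an integer code matrix (1..4 = ACGT),
# skipping validation; used by the simulation engine where codes are valid
# by construction.
alignment_from_code <- function(code, labels) {
  chr <- matrix(names(.BASES)[code], nrow = nrow(code))
  rownames(chr) <- labels
  rownames(code) <- labels
  structure(list(seqs = chr, code = code,
                 kept_sites = seq_len(ncol(code)) - 1L,
                 n = nrow(code), L = ncol(code)),
            class = "dloop_alignment")
}

#' Subset an alignment by sample ids
#' @param aln a `dloop_alignment`.
#' @param ids sample ids to keep.
#' @return a `dloop_alignment`.
#' @export
subset_alignment <- function(aln, ids) {
  keep <- rownames(aln$seqs) %in% ids
  if (!any(keep)) stop("no matching samples")
  new_alignment(aln$seqs[keep, , drop = FALSE], aln$kept_sites)
}

# Build an alignment from a character matrix without file I/O.
#' Build an alignment from an in-memory character matrix
#' @param seq_mat character matrix with rownames as sample ids.
#' @return A `dloop_alignment`.
#' @export
alignment_from_matrix <- function(seq_mat) {
  seq_mat[] <- toupper(seq_mat)
  new_alignment(seq_mat)
}
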
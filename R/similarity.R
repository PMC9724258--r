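# Pairwise and group sequence similarity on the 0-1000 reporting scale,
# representative selection, and family-merge decisions.
#
# The score is the identity fraction over the columns of one optimal global
# alignment, scaled so that two identical sequences score 1000. 700-1000 is
# read as high similarity, 400-699 moderate, 0-399 low.

#' Alignment parameters for similarity scoring
#'
#' Standard DNA defaults: match +1, mismatch -1, affine gaps (open 2,
#' extend 1; Biostrings' positive-penalty convention).
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @return a list of class `alignment_params`.
#' @export
alignment_params <- function(match = 1, mismatch = -1, gap_open = 2,
                             gap_extend = 1) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 submat = Biostrings::nucleotideSubstitutionMatrix(
                   match = match, mismatch = mismatch, baseOnly = FALSE)),
            class = "alignment_params")
}

#' Pairwise similarity score (0-1000)
#'
#' Globally aligns two DNA sequences and returns
#' `round(1000 * matches / alignment_columns)`. 1000 for identical sequences;
#' 0 when no column matches. Because co-optimal alignments can differ in
#' match count, the pair is aligned in a canonical order, which makes the
#' score exactly symmetric.
#'
#' @param seq_a,seq_b non-empty DNA strings.
#' @param params an [alignment_params()] object.
#' @return integer score in `[0, 1000]`.
#' @export
#' @examples
#' pairwise_similarity("ACGTACGT", "ACGTACGT")  # 1000
pairwise_similarity <- function(seq_a, seq_b, params = alignment_params()) {
  assert_dna(seq_a, "seq_a"); assert_dna(seq_b, "seq_b")
  if (seq_a == seq_b) return(1000L)
  if (seq_a > seq_b) { tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = params$submat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  n_cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  as.integer(round(1000 * Biostrings::nmatch(aln) / n_cols))
}

#' Classify a similarity score
#'
#' @param value integer score in `[0, 1000]`.
#' @return `"high"` (>= 700), `"moderate"` (400-699) or `"low"` (< 400).
#' @export
similarity_class <- function(value) {
  stopifnot(all(value >= 0 & value <= 1000))
  ifelse(value >= 700, "high", ifelse(value >= 400, "moderate", "low"))
}

#' Intra-group similarity statistics and representative selection
#'
#' Computes the symmetric matrix of pairwise scores, the mean over all
#' unordered distinct pairs (1000 by convention for a singleton), and the
#' representative: the member with the highest row-mean, ties broken by
#' lexicographically smallest accession.
#'
#' @param seqs named character vector of sequences (names = accessions).
#' @param group_id,segment_kind optional annotations carried into the result.
#' @param params an [alignment_params()].
#' @return list of class `group_similarity` with `intra_mean`, `pair_matrix`,
#'   `representative`, `group_id`, `segment_kind`.
#' @export
group_similarity <- function(seqs, group_id = NA_character_,
                             segment_kind = NA_character_,
                             params = alignment_params()) {
  n <- length(seqs)
  if (n == 0L) tb_error("empty group", "trnabarcode_bad_argument")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%03d", seq_len(n))
  m <- matrix(1000L, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      s <- pairwise_similarity(seqs[[i]], seqs[[j]], params)
      m[i, j] <- s; m[j, i] <- s
    }
  }
  intra_mean <- if (n == 1L) 1000 else mean(m[upper.tri(m)])
  row_means <- rowMeans(m)
  best <- which(row_means == max(row_means))
  representative <- sort(names(seqs)[best])[1]
  structure(list(group_id = group_id, segment_kind = segment_kind,
                 intra_mean = intra_mean, pair_matrix = m,
                 representative = representative),
            class = "group_similarity")
}

#' Decide whether a candidate related group should be merged
#'
#' Compares the intra-group mean COI similarity of `seqs_a` alone
#' (`score_before`) with that of the union with `seqs_b` (`score_after`);
#' the union is deduplicated by accession name, so merging a group with
#' itself is a no-op (`delta = 0`). The merge is accepted when the drop is
#' at most `delta` and the merged score stays at or above the `theta` floor
#' (the high-similarity boundary).
#'
#' @param seqs_a,seqs_b named character vectors of COI sequences for the two
#'   groups.
#' @param delta maximum tolerated score drop (default 30).
#' @param theta minimum merged score (default 700).
#' @param params an [alignment_params()].
#' @return list of class `merge_decision` with `score_before`, `score_after`,
#'   `delta`, `merged`.
#' @export
evaluate_merge <- function(seqs_a, seqs_b, delta = 30, theta = 700,
                           params = alignment_params()) {
  if (length(seqs_a) == 0L || length(seqs_b) == 0L)
    tb_error("both groups must be non-empty", "trnabarcode_bad_argument")
  before <- group_similarity(seqs_a, params = params)$intra_mean
  union <- c(seqs_a, seqs_b)
  if (!is.null(names(union)))
    union <- union[!duplicated(names(union))]
  after <- group_similarity(union, params = params)$intra_mean
  drop <- before - after
  structure(list(score_before = before, score_after = after,
                 delta = drop, tolerance = delta, floor = theta,
                 merged = (drop <= delta) && (after >= theta)),
            class = "merge_decision")
}

#' @export
print.merge_decision <- function(x, ...) {
  cat(sprintf("<merge_decision> before=%.0f after=%.0f drop=%.0f -> %s\n",
              x$score_before, x$score_after, x$delta,
              if (x$merged) "MERGE" else "keep separate"))
  invisible(x)
}
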
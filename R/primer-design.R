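# Primer candidate enumeration, scoring and pair assembly inside flanking
# tRNA segments. The length regime (18-26 nt, optimum 21) is the one used
# for COI-flank primers; Tm/GC/clamp terms are documented defaults.

#' Primer design constraints and penalty weights
#'
#' @param min_len,max_len,opt_len primer length bounds and optimum (nt).
#' @param tm_range,tm_opt melting-temperature window and optimum (deg C).
#' @param gc_range GC-fraction hard bounds.
#' @param max_homopolymer longest tolerated single-base run.
#' @param max_self_complement_run longest tolerated run complementary to the
#'   primer's own reverse complement (a primer-dimer proxy).
#' @param require_no_N reject candidates containing N.
#' @param w_len,w_tm,w_gc,w_clamp,w_pair_tm penalty weights: length deviation,
#'   Tm deviation, distance to the GC window, missing 3' G/C clamp, and the
#'   pair-level Tm-difference term.
#' @return list of class `primer_constraints`.
#' @export
primer_constraints <- function(min_len = 18L, max_len = 26L, opt_len = 21L,
                               tm_range = c(50, 65), tm_opt = 57.5,
                               gc_range = c(0.30, 0.70),
                               max_homopolymer = 4L,
                               max_self_complement_run = 8L,
                               require_no_N = TRUE,
                               w_len = 1, w_tm = 1, w_gc = 2, w_clamp = 3,
                               w_pair_tm = 1) {
  if (!(min_len <= opt_len && opt_len <= max_len))
    tb_error("need min_len <= opt_len <= max_len", "trnabarcode_bad_argument")
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 opt_len = as.integer(opt_len), tm_range = tm_range,
                 tm_opt = tm_opt, gc_range = gc_range,
                 max_homopolymer = as.integer(max_homopolymer),
                 max_self_complement_run = as.integer(max_self_complement_run),
                 require_no_N = require_no_N,
                 w_len = w_len, w_tm = w_tm, w_gc = w_gc, w_clamp = w_clamp,
                 w_pair_tm = w_pair_tm),
            class = "primer_constraints")
}

#' Primer melting temperature
#'
#' Wallace rule `2(A+T) + 4(G+C)` below 14 nt, otherwise
#' `64.9 + 41 * (gc_count - 16.4) / length`.
#'
#' @param seq primer sequence(s), 5'->3'.
#' @return numeric Tm in deg C.
#' @export
melting_temperature <- function(seq) {
  vapply(seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    gc <- sum(ch %in% c("G", "C"))
    n <- length(ch)
    if (n < 14) 2 * (n - gc) + 4 * gc else 64.9 + 41 * (gc - 16.4) / n
  }, numeric(1), USE.NAMES = FALSE)
}

has_long_homopolymer <- function(seqs, max_run) {
  grepl(sprintf("([ACGTN])\\1{%d}", max_run), seqs, perl = TRUE)
}

has_self_complement_run <- function(seq, max_run) {
  k <- max_run + 1L
  n <- nchar(seq)
  if (n < k) return(FALSE)
  rc <- revcomp_dna(seq)
  kmers <- substring(seq, seq_len(n - k + 1L), k:n)
  any(vapply(kmers, function(km) grepl(km, rc, fixed = TRUE), logical(1)))
}

# positions (i, j) of complementary k-mer pairs in a whole segment; a window
# has a self-complementary run > max_run iff it contains such a pair entirely
self_complement_pairs <- function(scan, max_run) {
  k <- max_run + 1L
  n <- nchar(scan)
  if (n < k) return(NULL)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(scan, starts, starts + k - 1L)
  rc_kmers <- vapply(kmers, function(s)
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s)))), character(1),
    USE.NAMES = FALSE)
  by_kmer <- split(starts, kmers)
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (i in which(rc_kmers %in% kmers)) {
    js <- by_kmer[[rc_kmers[i]]]
    pairs_i <- c(pairs_i, rep.int(starts[i], length(js)))
    pairs_j <- c(pairs_j, js)
  }
  if (length(pairs_i) == 0L) return(NULL)
  cbind(lo = pmin(pairs_i, pairs_j),
        hi = pmax(pairs_i, pairs_j) + k - 1L)  # 1-based span
}

#' Score one primer candidate
#'
#' `penalty = w_len*|len - opt| + w_tm*|tm - tm_opt| + w_gc*dist(gc, gc_range)
#'  + w_clamp*[3' base not G/C]`. Zero only when every term is at its optimum.
#'
#' @param sequence primer sequence 5'->3'.
#' @param constraints a [primer_constraints()].
#' @return non-negative penalty.
#' @export
score_candidate <- function(sequence, constraints = primer_constraints()) {
  score_windows(sequence, constraints)$penalty
}

# vectorized scoring used by the enumerator
score_windows <- function(seqs, cs) {
  len <- nchar(seqs)
  gc <- gc_fraction_str(seqs)
  tm <- melting_temperature(seqs)
  gc_dist <- pmax(cs$gc_range[1] - gc, 0) + pmax(gc - cs$gc_range[2], 0)
  clamp_missing <- !substr(seqs, len, len) %in% c("G", "C")
  penalty <- cs$w_len * abs(len - cs$opt_len) +
    cs$w_tm * abs(tm - cs$tm_opt) +
    cs$w_gc * gc_dist +
    cs$w_clamp * as.numeric(clamp_missing)
  tibble::new_tibble(list(sequence = seqs, length = len, gc = gc, tm = tm,
                          penalty = penalty), nrow = length(seqs))
}

#' Enumerate primer candidates in a segment
#'
#' Scans every window of length `min_len..max_len` of the segment (forward
#' orientation) or of its reverse complement (`reverse_complement`
#' orientation). Windows failing the hard filters (N content, homopolymer
#' runs, GC bounds, self-complementary runs) are dropped; the survivors are
#' scored and sorted by ascending penalty, ties broken by (offset, length).
#'
#' @param segment DNA string (may be shorter than `min_len`, giving an empty
#'   result).
#' @param constraints a [primer_constraints()].
#' @param orientation `"forward"` or `"reverse_complement"`.
#' @param apply_filters set `FALSE` to keep every window (used by the
#'   enumeration oracle in tests).
#' @return tibble with columns `sequence`, `offset` (0-based start within the
#'   scanned string), `length`, `orientation`, `gc`, `tm`, `penalty`.
#' @export
enumerate_candidates <- function(segment,
                                 constraints = primer_constraints(),
                                 orientation = c("forward", "reverse_complement"),
                                 apply_filters = TRUE) {
  orientation <- match.arg(orientation)
  cs <- constraints
  scan <- if (orientation == "forward") segment else revcomp_dna(segment)
  n <- nchar(scan)
  sc_pairs <- if (apply_filters && cs$max_self_complement_run < cs$max_len)
    self_complement_pairs(scan, cs$max_self_complement_run) else NULL
  out <- list()
  for (len in cs$min_len:cs$max_len) {
    if (n < len) next
    starts <- seq_len(n - len + 1L)
    seqs <- substring(scan, starts, starts + len - 1L)
    keep <- rep(TRUE, length(seqs))
    if (apply_filters) {
      if (cs$require_no_N) keep <- keep & !grepl("N", seqs, fixed = TRUE)
      keep <- keep & !has_long_homopolymer(seqs, cs$max_homopolymer)
      gc <- gc_fraction_str(seqs)
      keep <- keep & gc >= cs$gc_range[1] & gc <= cs$gc_range[2]
      if (!is.null(sc_pairs)) {
        ends <- starts + len - 1L
        bad <- vapply(seq_along(starts), function(w)
          any(sc_pairs[, "lo"] >= starts[w] & sc_pairs[, "hi"] <= ends[w]),
          logical(1))
        keep <- keep & !bad
      }
    }
    if (!any(keep)) next
    sc <- score_windows(seqs[keep], cs)
    sc$offset <- starts[keep] - 1L
    out[[length(out) + 1L]] <- sc
  }
  if (length(out) == 0L)
    return(tibble::tibble(sequence = character(0), offset = integer(0),
                          length = integer(0), orientation = character(0),
                          gc = numeric(0), tm = numeric(0),
                          penalty = numeric(0)))
  res <- do.call(rbind, out)
  res$orientation <- orientation
  res <- res[order(res$penalty, res$offset, res$length), , drop = FALSE]
  tibble::as_tibble(res[, c("sequence", "offset", "length", "orientation",
                            "gc", "tm", "penalty")])
}

empty_pairs <- function() {
  tibble::tibble(accession = character(0), segment_rank = integer(0),
                 f_seq = character(0), f_offset = integer(0),
                 f_len = integer(0), f_tm = numeric(0), f_penalty = numeric(0),
                 r_seq = character(0), r_offset = integer(0),
                 r_len = integer(0), r_tm = numeric(0), r_penalty = numeric(0),
                 pair_penalty = numeric(0), rank = integer(0))
}

#' Design ranked primer pairs from a flank set
#'
#' Forward primers are windows of the chosen left (upstream) tRNA segment;
#' reverse primers are windows of the reverse complement of the chosen right
#' (downstream) segment. The top candidates on each side are combined and the
#' pairs ranked by `pair_penalty = f_penalty + r_penalty +
#' w_pair_tm * |f_tm - r_tm|`. Ordering is fully deterministic.
#'
#' @param flanks a `flank_set` from [extract_flanks()].
#' @param constraints a [primer_constraints()].
#' @param top_n number of pairs to return (and of candidates kept per side).
#' @param segment_rank which flank segment to design from (1 = nearest tRNA,
#'   2 = second nearest after extension, ...).
#' @param enum_cache optional environment memoising candidate enumeration by
#'   segment sequence (used by the pipeline, where near-identical family
#'   members share flank haplotypes).
#' @return a tibble of up to `top_n` pairs with attribute `missing` set to a
#'   reason string when the requested segments are unavailable.
#' @export
design_pairs <- function(flanks, constraints = primer_constraints(),
                         top_n = 5L, segment_rank = 1L, enum_cache = NULL) {
  stopifnot(inherits(flanks, "flank_set"))
  out <- empty_pairs()
  if (length(flanks$left_segments) < segment_rank ||
      length(flanks$right_segments) < segment_rank) {
    attr(out, "missing") <- sprintf(
      "flank segment rank %d unavailable (left: %d, right: %d)",
      segment_rank, length(flanks$left_segments), length(flanks$right_segments))
    return(out)
  }
  enum <- function(seg, ori) {
    if (is.null(enum_cache)) return(enumerate_candidates(seg, constraints, ori))
    key <- paste0(ori, "|", seg)
    if (is.null(enum_cache[[key]]))
      enum_cache[[key]] <- enumerate_candidates(seg, constraints, ori)
    enum_cache[[key]]
  }
  fw <- enum(flanks$left_segments[segment_rank], "forward")
  rv <- enum(flanks$right_segments[segment_rank], "reverse_complement")
  if (nrow(fw) == 0L || nrow(rv) == 0L) {
    attr(out, "missing") <- "no admissible primer candidate in a flank segment"
    return(out)
  }
  fw <- utils::head(fw, top_n)
  rv <- utils::head(rv, top_n)
  grid <- expand.grid(fi = seq_len(nrow(fw)), ri = seq_len(nrow(rv)))
  pairs <- tibble::tibble(
    accession = flanks$accession,
    segment_rank = as.integer(segment_rank),
    f_seq = fw$sequence[grid$fi], f_offset = fw$offset[grid$fi],
    f_len = fw$length[grid$fi], f_tm = fw$tm[grid$fi],
    f_penalty = fw$penalty[grid$fi],
    r_seq = rv$sequence[grid$ri], r_offset = rv$offset[grid$ri],
    r_len = rv$length[grid$ri], r_tm = rv$tm[grid$ri],
    r_penalty = rv$penalty[grid$ri])
  pairs$pair_penalty <- pairs$f_penalty + pairs$r_penalty +
    constraints$w_pair_tm * abs(pairs$f_tm - pairs$r_tm)
  ord <- order(pairs$pair_penalty, pairs$f_penalty, pairs$f_offset,
               pairs$f_len, pairs$r_offset, pairs$r_len)
  pairs <- pairs[ord, , drop = FALSE]
  pairs <- utils::head(pairs, top_n)
  pairs$rank <- seq_len(nrow(pairs))
  pairs
}
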
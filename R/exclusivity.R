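# Mismatch-tolerant primer mapping, in-silico PCR amplicon prediction,
# family-exclusivity classification, and greedy minimal primer-pair cover.
#
# Matching semantics: a primer aligns end-to-end with at most max_mm
# mismatches and its 3 terminal 3'-end bases matching exactly; circular
# genomes are scanned across the origin. The fast path uses
# Biostrings::matchPattern; tests hold it to a naive scan oracle.

# extended subject for circular scanning (sequence + wraparound prefix)
.extended_subject <- function(record, extra) {
  s <- record$sequence
  if (record$topology == "circular" && extra > 0L)
    s <- paste0(s, substr(s, 1L, extra))
  s
}

match_one_strand <- function(pattern, subject_str, L, max_mm) {
  subj <- Biostrings::DNAString(subject_str)
  pat <- Biostrings::DNAString(pattern)
  hits <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm,
                                   with.indels = FALSE, fixed = TRUE)
  starts <- BiocGenerics::start(hits)
  starts <- starts[starts <= L]          # report each circular site once
  if (length(starts) == 0L)
    return(tibble::tibble(position = integer(0), mismatches = integer(0)))
  mm <- if (max_mm == 0L) rep(0L, length(starts)) else
    as.integer(Biostrings::neditStartingAt(pat, subj, starting.at = starts,
                                           with.indels = FALSE, fixed = TRUE))
  tibble::tibble(position = as.integer(starts - 1L), mismatches = mm)
}

# exact-match filter on the w reference positions closest to the primer 3' end
.three_prime_ok <- function(primer_on_ref, subject_str, positions0, strand, w = 3L) {
  plen <- nchar(primer_on_ref)
  vapply(positions0, function(p0) {
    if (strand == 1L) {
      a <- p0 + plen - w + 1L
      substr(subject_str, a, a + w - 1L) == substr(primer_on_ref, plen - w + 1L, plen)
    } else {
      # minus-strand primer 3' end sits at the start of the reference match
      substr(subject_str, p0 + 1L, p0 + w) == substr(primer_on_ref, 1L, w)
    }
  }, logical(1))
}

#' Find primer match sites on one genome
#'
#' Reports all sites on both strands where the primer aligns end-to-end with
#' at most `max_mm` mismatches and an exact 3-base 3'-terminal match.
#' Positions are 0-based on the reference strand; circular genomes are
#' scanned across the origin.
#'
#' @param primer primer sequence 5'->3'.
#' @param record a [mito_record()].
#' @param max_mm maximum tolerated mismatches (default 0).
#' @return tibble with columns `accession`, `position`, `strand`, `mismatches`.
#' @export
find_matches <- function(primer, record, max_mm = 0L) {
  assert_dna(primer, "primer")
  stopifnot(inherits(record, "mito_record"))
  L <- nchar(record$sequence)
  subject <- .extended_subject(record, nchar(primer) - 1L)

  plus <- match_one_strand(primer, subject, L, max_mm)
  plus$strand <- 1L
  minus <- match_one_strand(revcomp_dna(primer), subject, L, max_mm)
  minus$strand <- -1L

  res <- rbind(plus, minus)
  if (nrow(res) > 0L && max_mm > 0L) {
    pat_on_ref <- ifelse(res$strand == 1L, primer, revcomp_dna(primer))
    ok <- vapply(seq_len(nrow(res)), function(i)
      .three_prime_ok(pat_on_ref[i], subject, res$position[i], res$strand[i]),
      logical(1))
    res <- res[ok, , drop = FALSE]
  }
  res <- res[res$mismatches <= max_mm, , drop = FALSE]
  tibble::tibble(accession = rep(record$accession, nrow(res)),
                 position = res$position, strand = res$strand,
                 mismatches = res$mismatches)
}

#' Predict PCR amplicons of a primer pair on one genome
#'
#' An amplicon is a plus-strand forward-primer site followed (in amplifiable
#' orientation, across the origin for circular genomes) by a minus-strand
#' reverse-primer site, with product length inside the configured bounds.
#'
#' @param pair a one-row pair tibble from [design_pairs()] (columns `f_seq`,
#'   `r_seq`), or a list with those fields.
#' @param record a [mito_record()].
#' @param config a [barcode_config()] (supplies `max_mm` and product bounds).
#' @return tibble with columns `accession`, `f_position`, `r_position`,
#'   `product_length`.
#' @export
predict_amplicons <- function(pair, record, config = barcode_config()) {
  f_sites <- find_matches(pair$f_seq, record, config$max_mm)
  f_sites <- f_sites[f_sites$strand == 1L, , drop = FALSE]
  if (nrow(f_sites) == 0L) return(.empty_amplicons())
  r_sites <- find_matches(pair$r_seq, record, config$max_mm)
  r_sites <- r_sites[r_sites$strand == -1L, , drop = FALSE]
  if (nrow(r_sites) == 0L) return(.empty_amplicons())

  L <- nchar(record$sequence)
  r_len <- nchar(pair$r_seq)
  combos <- expand.grid(fi = seq_len(nrow(f_sites)), ri = seq_len(nrow(r_sites)))
  fp <- f_sites$position[combos$fi]
  rp <- r_sites$position[combos$ri]
  prod_len <- rp + r_len - fp
  if (record$topology == "circular") {
    wrap <- prod_len <= 0L | rp < fp
    prod_len[wrap] <- prod_len[wrap] + L
  }
  keep <- prod_len >= config$product_min & prod_len <= config$product_max &
    prod_len > 0
  tibble::tibble(accession = rep(record$accession, sum(keep)),
                 f_position = fp[keep], r_position = rp[keep],
                 product_length = as.integer(prod_len[keep]))
}

.empty_amplicons <- function() {
  tibble::tibble(accession = character(0), f_position = integer(0),
                 r_position = integer(0), product_length = integer(0))
}

# ---- universe screening index -------------------------------------------

#' Precompute a screening index over a genome universe
#'
#' Builds the extended (circular-aware) subjects once so that repeated pair
#' screens avoid re-constructing Biostrings objects.
#'
#' @param records list of [mito_record()] objects.
#' @param max_primer_len longest primer that will be screened.
#' @return an opaque index object for [amplified_accessions()].
#' @export
universe_index <- function(records, max_primer_len = 26L) {
  subjects <- vapply(records, .extended_subject, character(1),
                     extra = max_primer_len - 1L)
  structure(list(records = records,
                 accessions = vapply(records, `[[`, character(1), "accession"),
                 lens = vapply(records, function(r) nchar(r$sequence), integer(1)),
                 circular = vapply(records, function(r)
                   r$topology == "circular", logical(1)),
                 subjects_chr = unname(subjects),
                 subjects = Biostrings::DNAStringSet(subjects)),
            class = "universe_index")
}

amplifying_sites <- function(pattern, index, max_mm) {
  m <- Biostrings::vmatchPattern(pattern, index$subjects,
                                 max.mismatch = max_mm, with.indels = FALSE,
                                 fixed = TRUE)
  starts <- Biostrings::startIndex(m)
  lapply(seq_along(starts), function(i) {
    s <- starts[[i]]
    if (is.null(s)) return(integer(0))
    s[s <= index$lens[i]] - 1L
  })
}

#' Accessions amplified by a primer pair across a universe
#'
#' Fast equivalent of running [predict_amplicons()] on every genome: a genome
#' counts as amplified when a plus-strand forward site precedes a minus-strand
#' reverse site with product length inside bounds; tests hold the two routes
#' to each other.
#'
#' @param pair one-row pair tibble.
#' @param index a [universe_index()].
#' @param config a [barcode_config()].
#' @return character vector of amplified accessions.
#' @export
amplified_accessions <- function(pair, index, config = barcode_config()) {
  f_hits <- amplifying_sites(pair$f_seq, index, config$max_mm)
  have_f <- lengths(f_hits) > 0L
  if (!any(have_f)) return(character(0))
  r_on_ref <- revcomp_dna(pair$r_seq)
  r_hits <- amplifying_sites(r_on_ref, index, config$max_mm)
  cand <- which(have_f & lengths(r_hits) > 0L)
  if (length(cand) == 0L) return(character(0))
  r_len <- nchar(pair$r_seq)
  amplified <- vapply(cand, function(i) {
    fp <- f_hits[[i]]; rp <- r_hits[[i]]
    if (config$max_mm > 0L) {
      subj <- index$subjects_chr[i]
      fp <- fp[.three_prime_ok(pair$f_seq, subj, fp, 1L)]
      rp <- rp[.three_prime_ok(r_on_ref, subj, rp, -1L)]
      if (length(fp) == 0L || length(rp) == 0L) return(FALSE)
    }
    prod_len <- rep(rp + r_len, each = length(fp)) - fp
    if (index$circular[i]) {
      wrap <- prod_len <= 0L | rep(rp, each = length(fp)) < fp
      prod_len[wrap] <- prod_len[wrap] + index$lens[i]
    }
    any(prod_len >= config$product_min & prod_len <= config$product_max &
          prod_len > 0)
  }, logical(1))
  index$accessions[cand[amplified]]
}

#' Classify a primer pair's exclusivity for a group
#'
#' A species counts as matched when the pair predicts at least one amplicon
#' on it. The pair is exclusive when it amplifies at least one group member
#' and no species outside the group (a pair amplifying nothing is
#' non-exclusive, not vacuously exclusive).
#'
#' @param members accessions of the group.
#' @param pair one-row pair tibble.
#' @param index a [universe_index()] over the screening universe.
#' @param config a [barcode_config()].
#' @param group_id optional group label carried into the report.
#' @return list of class `exclusivity_report` with `matched_in_group`,
#'   `matched_out_group`, `exclusive`.
#' @export
classify_exclusivity <- function(members, pair, index,
                                 config = barcode_config(),
                                 group_id = NA_character_) {
  amp <- amplified_accessions(pair, index, config)
  matched_in <- intersect(amp, members)
  matched_out <- setdiff(amp, members)
  structure(list(group_id = group_id, pair = pair,
                 matched_in_group = matched_in,
                 matched_out_group = matched_out,
                 exclusive = length(matched_out) == 0L && length(matched_in) > 0L),
            class = "exclusivity_report")
}

#' Greedy minimal primer-pair cover of a group
#'
#' Candidate pairs (contributed per species) are first screened for
#' exclusivity to the group; among the eligible pairs the cover repeatedly
#' selects the one amplifying the most still-uncovered members (ties: lower
#' `pair_penalty`, then lexicographically smaller forward sequence) until all
#' members are covered or no eligible pair helps. Uncovered members are
#' returned as residuals for escalation.
#'
#' @param members accessions of the group (defines in-group for exclusivity).
#' @param candidate_pairs tibble of candidate pairs (rows from
#'   [design_pairs()], possibly from several species).
#' @param index a [universe_index()] over the screening universe.
#' @param config a [barcode_config()].
#' @param require_exclusive if `FALSE`, any pair amplifying >= 1 member is
#'   eligible (the restricted-reference mode used in stage 2).
#' @param targets accessions the cover must reach (defaults to all members;
#'   escalation steps pass only the still-uncovered members).
#' @return list with `selected` (list of `list(pair, covered)`), `residual`
#'   (uncovered targets), and `eligible` (row indices of eligible pairs).
#' @export
minimal_pair_cover <- function(members, candidate_pairs, index,
                               config = barcode_config(),
                               require_exclusive = TRUE,
                               targets = members) {
  n <- nrow(candidate_pairs)
  cover_sets <- vector("list", n)
  eligible <- logical(n)
  memo <- new.env(parent = emptyenv())   # identical pairs recur across members
  for (i in seq_len(n)) {
    pair <- candidate_pairs[i, , drop = FALSE]
    key <- paste(pair$f_seq, pair$r_seq, sep = "|")
    amp <- memo[[key]]
    if (is.null(amp)) {
      amp <- amplified_accessions(pair, index, config)
      memo[[key]] <- amp
    }
    in_g <- intersect(amp, members)
    out_g <- setdiff(amp, members)
    ok <- length(in_g) > 0L && (!require_exclusive || length(out_g) == 0L)
    eligible[i] <- ok
    cover_sets[[i]] <- if (ok) in_g else character(0)
  }
  uncovered <- targets
  selected <- list()
  repeat {
    gains <- vapply(cover_sets, function(s) length(intersect(s, uncovered)),
                    integer(1))
    gains[!eligible] <- 0L
    if (length(gains) == 0L || max(gains) == 0L) break
    best <- which(gains == max(gains))
    if (length(best) > 1L) {
      ord <- order(candidate_pairs$pair_penalty[best],
                   candidate_pairs$f_seq[best])
      best <- best[ord[1]]
    }
    selected[[length(selected) + 1L]] <- list(
      pair = candidate_pairs[best, , drop = FALSE],
      covered = intersect(cover_sets[[best]], uncovered),
      amplifies = cover_sets[[best]])
    uncovered <- setdiff(uncovered, cover_sets[[best]])
    eligible[best] <- FALSE
    if (length(uncovered) == 0L) break
  }
  list(selected = selected, residual = uncovered, eligible = which(eligible))
}
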
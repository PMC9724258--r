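# Annotated mitogenome model: gene features, records, COI location and
# flanking tRNA extraction.
#
# Coordinates are 0-based half-open internally; GenBank 1-based inclusive
# coordinates are converted on read/write.

#' Construct a gene feature
#'
#' A single annotated feature on a mitogenome, in 0-based half-open
#' reference-strand coordinates.
#'
#' @param kind one of `"tRNA"`, `"CDS"`, `"rRNA"`, `"other"`.
#' @param label gene or product name (free text, e.g. `"COX1"`, `"tRNA-Tyr"`).
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must exceed `start` unless the feature
#'   wraps the origin of a circular genome.
#' @param strand `+1` or `-1`.
#' @param wraps_origin logical; `TRUE` for features spanning the origin.
#' @return a one-row tibble usable as a feature-table row.
#' @export
gene_feature <- function(kind, label, start, end, strand = 1L,
                         wraps_origin = FALSE) {
  kind <- match.arg(kind, c("tRNA", "CDS", "rRNA", "other"))
  if (!wraps_origin && end <= start)
    tb_error("feature end must exceed start unless wraps_origin",
             "trnabarcode_bad_feature")
  if (start < 0)
    tb_error("feature start must be >= 0", "trnabarcode_bad_feature")
  if (!strand %in% c(1L, -1L))
    tb_error("strand must be +1 or -1", "trnabarcode_bad_feature")
  tibble::tibble(kind = kind, label = label, start = as.integer(start),
                 end = as.integer(end), strand = as.integer(strand),
                 wraps_origin = wraps_origin)
}

#' Construct an annotated mitogenome record
#'
#' @param accession unique accession string (e.g. `"NC_002333"`).
#' @param organism scientific name.
#' @param sequence genome sequence over \{A,C,G,T,N\}.
#' @param features tibble of features as built by [gene_feature()] (rows are
#'   re-sorted by start position).
#' @param family_id taxonomy family identifier, `NA` if unknown.
#' @param topology `"circular"` (the mitochondrial default) or `"linear"`.
#' @return an object of class `mito_record`.
#' @export
mito_record <- function(accession, organism, sequence, features,
                        family_id = NA_character_, topology = "circular") {
  topology <- match.arg(topology, c("circular", "linear"))
  assert_dna(sequence)
  L <- nchar(sequence)
  if (any(features$start >= L))
    tb_error(sprintf("feature start beyond sequence end in %s", accession),
             "trnabarcode_bad_feature")
  features <- features[order(features$start, features$end), , drop = FALSE]
  structure(
    list(accession = accession, organism = organism,
         family_id = family_id, sequence = sequence,
         topology = topology, features = features),
    class = "mito_record")
}

#' @export
print.mito_record <- function(x, ...) {
  cat(sprintf("<mito_record> %s (%s)\n  family: %s | %d bp, %s | %d features\n",
              x$accession, x$organism, x$family_id, nchar(x$sequence),
              x$topology, nrow(x$features)))
  invisible(x)
}

# Fixed synonym table; unknown labels are never fuzzily matched.
.coi_synonyms <- c(
  "coi", "cox1", "co1", "coxi", "cox-1",
  "cytochrome c oxidase subunit 1", "cytochrome c oxidase subunit i",
  "cytochrome oxidase subunit 1", "cytochrome oxidase subunit i")

#' Locate the COI gene on a record
#'
#' Matches feature labels (case-insensitively, after trimming) against a fixed
#' synonym table: COI, COX1, CO1, COXI, "cytochrome (c) oxidase subunit 1/I".
#'
#' @param record a [mito_record()].
#' @return the matching feature as a one-row tibble.
#' @export
locate_coi <- function(record) {
  stopifnot(inherits(record, "mito_record"))
  lab <- tolower(trimws(record$features$label))
  hit <- lab %in% .coi_synonyms
  if (sum(hit) == 0L)
    tb_error(sprintf("no COI-like feature found on %s", record$accession),
             "trnabarcode_missing_coi")
  if (sum(hit) > 1L)
    tb_error(sprintf("multiple COI-like features on %s: %s", record$accession,
                     paste(record$features$label[hit], collapse = ", ")),
             "trnabarcode_ambiguous_coi")
  record$features[hit, , drop = FALSE]
}

# sequence of one feature row, reference-strand orientation
feature_sequence <- function(record, feat) {
  L <- nchar(record$sequence)
  if (isTRUE(feat$wraps_origin)) {
    len <- (L - feat$start) + feat$end
    substr_circ(record$sequence, feat$start + 1L, len)
  } else {
    substr(record$sequence, feat$start + 1L, feat$end)
  }
}

#' Extract the k nearest flanking tRNA segments around COI
#'
#' Finds the `k` nearest tRNA genes upstream and downstream of the COI gene
#' (nearest first). For circular records the search wraps the origin; each
#' tRNA is eligible only for the side to which it is closer, so a genome whose
#' tRNAs all sit upstream of COI reports a truly missing downstream flank
#' rather than re-using upstream genes across the wrap. Segments are reported
#' in reference-strand orientation regardless of the tRNA's coding strand.
#'
#' @param record a [mito_record()].
#' @param k extension depth (number of tRNAs per side), `k >= 1`.
#' @return an object of class `flank_set` with fields `accession`, `coi`,
#'   `left_segments`, `right_segments` (character vectors, nearest first),
#'   `left_features`, `right_features`, `k`, `missing_left`, `missing_right`.
#' @export
extract_flanks <- function(record, k = 1L) {
  stopifnot(inherits(record, "mito_record"))
  if (!is.numeric(k) || k < 1) tb_error("k must be >= 1", "trnabarcode_bad_argument")
  k <- as.integer(k)
  coi <- locate_coi(record)
  L <- nchar(record$sequence)
  trnas <- record$features[record$features$kind == "tRNA", , drop = FALSE]

  if (nrow(trnas) > 0L) {
    if (record$topology == "circular") {
      d_up <- (coi$start - trnas$end) %% L
      d_down <- (trnas$start - coi$end) %% L
      # overlap with COI shows up as a "negative" wrap distance on both sides;
      # drop features overlapping the COI interval outright
      overlaps <- trnas$start < coi$end & trnas$end > coi$start
      side_up <- d_up <= d_down        # ties go upstream
      up_idx <- which(side_up & !overlaps)
      down_idx <- which(!side_up & !overlaps)
      up_idx <- up_idx[order(d_up[up_idx])]
      down_idx <- down_idx[order(d_down[down_idx])]
    } else {
      up_idx <- which(trnas$end <= coi$start)
      down_idx <- which(trnas$start >= coi$end)
      up_idx <- up_idx[order(coi$start - trnas$end[up_idx])]
      down_idx <- down_idx[order(trnas$start[down_idx] - coi$end)]
    }
  } else {
    up_idx <- integer(0); down_idx <- integer(0)
  }

  up_idx <- utils::head(up_idx, k)
  down_idx <- utils::head(down_idx, k)
  left_features <- trnas[up_idx, , drop = FALSE]
  right_features <- trnas[down_idx, , drop = FALSE]

  seq_of <- function(feats) {
    if (nrow(feats) == 0L) return(character(0))
    vapply(seq_len(nrow(feats)),
           function(i) feature_sequence(record, feats[i, , drop = FALSE]),
           character(1))
  }

  structure(
    list(accession = record$accession, coi = coi,
         left_segments = seq_of(left_features),
         right_segments = seq_of(right_features),
         left_features = left_features, right_features = right_features,
         k = k,
         missing_left = length(up_idx) < k,
         missing_right = length(down_idx) < k),
    class = "flank_set")
}

#' @export
print.flank_set <- function(x, ...) {
  cat(sprintf("<flank_set> %s k=%d | left: %d segment(s)%s | right: %d segment(s)%s\n",
              x$accession, x$k,
              length(x$left_segments), if (x$missing_left) " (missing)" else "",
              length(x$right_segments), if (x$missing_right) " (missing)" else ""))
  invisible(x)
}

#' Export flank sets as multi-FASTA
#'
#' Headers follow the `accession|side|rank` convention, rank 1 = nearest.
#'
#' @param flank_sets list of `flank_set` objects.
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
flanks_to_fasta <- function(flank_sets, path) {
  seqs <- character(0)
  for (fs in flank_sets) {
    for (i in seq_along(fs$left_segments))
      seqs[sprintf("%s|L|%d", fs$accession, i)] <- fs$left_segments[i]
    for (i in seq_along(fs$right_segments))
      seqs[sprintf("%s|R|%d", fs$accession, i)] <- fs$right_segments[i]
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}
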
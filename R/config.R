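#' Pipeline configuration
#'
#' Bundles every tunable knob of the two-stage pipeline.
#'
#' @param constraints a [primer_constraints()].
#' @param max_mm mismatches tolerated when mapping primers (0 = strict
#'   exclusivity; up to 3 with the 3-base 3'-exact window).
#' @param product_min,product_max predicted-amplicon length bounds (nt); the
#'   defaults admit the full ~1.5 kb COI gene plus flanking tRNAs.
#' @param delta maximum tolerated intra-group COI score drop for accepting a
#'   family merge.
#' @param theta minimum merged intra-group COI score (the high-similarity
#'   floor).
#' @param top_n candidate primer pairs cycled through per species.
#' @param max_k maximum flank-extension depth (2 = one extension beyond the
#'   nearest tRNA; unlimited extension drifts primers away from COI).
#' @return list of class `barcode_config`.
#' @export
barcode_config <- function(constraints = primer_constraints(),
                           max_mm = 0L,
                           product_min = 200L, product_max = 3000L,
                           delta = 30, theta = 700,
                           top_n = 5L, max_k = 2L) {
  stopifnot(max_mm >= 0L, product_min < product_max, max_k >= 1L, top_n >= 1L)
  structure(list(constraints = constraints, max_mm = as.integer(max_mm),
                 product_min = as.integer(product_min),
                 product_max = as.integer(product_max),
                 delta = delta, theta = theta,
                 top_n = as.integer(top_n), max_k = as.integer(max_k)),
            class = "barcode_config")
}
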
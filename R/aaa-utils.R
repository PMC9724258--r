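# internal helpers shared across modules

tb_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "trnabarcode_error"), call = call))
}

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors (the package stores sequences as character strings).
#'
#' @param x character vector of DNA sequences over \{A,C,G,T,N\}.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp_dna("ACGTT")
revcomp_dna <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", s))))
  }, character(1), USE.NAMES = FALSE)
}

assert_dna <- function(x, arg = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    tb_error(sprintf("'%s' must be a non-empty DNA string", arg),
             "trnabarcode_bad_argument")
  if (grepl("[^ACGTN]", x))
    tb_error(sprintf("'%s' contains characters outside {A,C,G,T,N}", arg),
             "trnabarcode_bad_argument")
  invisible(x)
}

# circular-aware substring: 1-based start, length len, wraps around seq end
substr_circ <- function(seq, start1, len) {
  L <- nchar(seq)
  end1 <- start1 + len - 1L
  if (end1 <= L) return(substr(seq, start1, end1))
  paste0(substr(seq, start1, L), substr(seq, 1L, end1 - L))
}

gc_fraction_str <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)
  vapply(chars, function(ch) sum(ch %in% c("G", "C")) / length(ch), numeric(1))
}
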
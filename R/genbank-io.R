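# Reading and writing annotated mitogenomes.
#
# GenBank flat files (LOCUS/FEATURES/ORIGIN) are read and written with a
# minimal parser covering the feature kinds this package uses (tRNA, CDS,
# rRNA; simple spans, complement(), and origin-wrapping join()). FASTA input
# goes through Biostrings and is paired with a tab-separated feature table.

.norm_feature_kind <- function(x) {
  ifelse(x %in% c("tRNA", "CDS", "rRNA"), x, "other")
}

parse_genbank_location <- function(loc, file, lineno) {
  strand <- 1L
  wraps <- FALSE
  loc <- gsub(" ", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      tb_error(sprintf("%s line %d: unsupported join() location '%s'",
                       file, lineno, loc), "trnabarcode_format_error")
    a <- as.integer(strsplit(parts[1], "..", fixed = TRUE)[[1]])
    b <- as.integer(strsplit(parts[2], "..", fixed = TRUE)[[1]])
    # origin-wrapping join: start..L,1..end
    return(list(start = a[1] - 1L, end = b[2], strand = strand, wraps = TRUE))
  }
  if (!grepl("^<?[0-9]+\\.\\.>?[0-9]+$", loc))
    tb_error(sprintf("%s line %d: cannot parse location '%s'",
                     file, lineno, loc), "trnabarcode_format_error")
  ab <- as.integer(gsub("[<>]", "", strsplit(loc, "..", fixed = TRUE)[[1]]))
  list(start = ab[1] - 1L, end = ab[2], strand = strand, wraps = wraps)
}

#' Read one GenBank flat file
#'
#' Minimal LOCUS/FEATURES/ORIGIN reader. Feature labels are taken from the
#' `/gene` qualifier, falling back to `/product`. Records without an explicit
#' `linear` flag on the LOCUS line default to circular topology, the
#' mitochondrial norm.
#'
#' @param path GenBank flat file with a single record.
#' @return a [mito_record()] (with `family_id` unset).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^LOCUS", lines[1]))
    tb_error(sprintf("%s line 1: not a GenBank flat file (no LOCUS line)", path),
             "trnabarcode_format_error")
  topology <- if (grepl("\\blinear\\b", lines[1])) "linear" else "circular"

  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(acc_line)) strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1] else NA_character_
  org_line <- grep("^\\s{2}ORGANISM", lines, value = TRUE)
  organism <- if (length(org_line)) trimws(sub("^\\s+ORGANISM", "", org_line[1])) else NA_character_

  feat_start <- grep("^FEATURES", lines)
  orig_start <- grep("^ORIGIN", lines)
  if (length(feat_start) != 1L || length(orig_start) != 1L)
    tb_error(sprintf("%s: expected one FEATURES and one ORIGIN section", path),
             "trnabarcode_format_error")

  # feature table
  feats <- list()
  i <- feat_start + 1L
  while (i < orig_start) {
    line <- lines[i]
    if (grepl("^\\s{5}\\S", line)) {  # new feature at column 6
      key <- trimws(substr(line, 1, 20))
      loc <- trimws(substr(line, 21, nchar(line)))
      lineno <- i
      gene <- NA_character_; product <- NA_character_
      j <- i + 1L
      while (j < orig_start && grepl("^\\s{21}", lines[j])) {
        q <- trimws(lines[j])
        if (grepl('^/gene="', q)) gene <- sub('^/gene="(.*)"$', "\\1", q)
        if (grepl('^/product="', q)) product <- sub('^/product="(.*)"$', "\\1", q)
        j <- j + 1L
      }
      if (key != "source") {
        pl <- parse_genbank_location(loc, path, lineno)
        label <- if (!is.na(gene)) gene else if (!is.na(product)) product else key
        feats[[length(feats) + 1L]] <- gene_feature(
          .norm_feature_kind(key), label, pl$start, pl$end, pl$strand, pl$wraps)
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    gene_feature("other", "none", 0, 1)[0, ]

  # ORIGIN block
  seq_lines <- lines[(orig_start + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  mito_record(accession = accession, organism = organism, sequence = sequence,
              features = features, topology = topology)
}

#' Write a record as a GenBank flat file
#'
#' Inverse of [read_genbank()]; the two round-trip losslessly for the feature
#' kinds the package models.
#'
#' @param record a [mito_record()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  L <- nchar(record$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s   VRT",
                     record$accession, L, record$topology), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion, complete genome.",
                     record$organism), con)
  writeLines(sprintf("ACCESSION   %s", record$accession), con)
  writeLines(sprintf("SOURCE      %s", record$organism), con)
  writeLines(sprintf("  ORGANISM  %s", record$organism), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  writeLines(sprintf('                     /organism="%s"', record$organism), con)
  f <- record$features
  for (i in seq_len(nrow(f))) {
    loc <- if (isTRUE(f$wraps_origin[i]))
      sprintf("join(%d..%d,1..%d)", f$start[i] + 1L, L, f$end[i])
    else sprintf("%d..%d", f$start[i] + 1L, f$end[i])
    if (f$strand[i] == -1L) loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-15s %s", f$kind[i], loc), con)
    writeLines(sprintf('                     /gene="%s"', f$label[i]), con)
  }
  writeLines("ORIGIN", con)
  s <- record$sequence
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tolower(tens), collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Tab-separated with columns `accession`, `organism`, `family_id`,
#' `family_name`.
#'
#' @param path TSV file.
#' @return a tibble.
#' @export
read_taxonomy <- function(path) {
  tx <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "organism", "family_id", "family_name")
  if (!all(need %in% names(tx)))
    tb_error(sprintf("taxonomy table %s lacks columns: %s", path,
                     paste(setdiff(need, names(tx)), collapse = ", ")),
             "trnabarcode_format_error")
  tibble::as_tibble(tx)
}

read_fasta_with_features <- function(fasta_path, feature_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ft <- utils::read.delim(feature_path, stringsAsFactors = FALSE)
  need <- c("accession", "kind", "label", "start_1based", "end_1based", "strand")
  if (!all(need %in% names(ft)))
    tb_error(sprintf("feature table %s lacks columns: %s", feature_path,
                     paste(setdiff(need, names(ft)), collapse = ", ")),
             "trnabarcode_format_error")
  lapply(seq_along(seqs), function(i) {
    header <- names(seqs)[i]
    acc <- strsplit(header, "\\s+")[[1]][1]
    organism <- trimws(sub("^\\S+\\s*", "", header))
    if (organism == "") organism <- NA_character_
    rows <- ft[ft$accession == acc, , drop = FALSE]
    feats <- if (nrow(rows)) do.call(rbind, lapply(seq_len(nrow(rows)), function(r)
      gene_feature(.norm_feature_kind(rows$kind[r]), rows$label[r],
                   rows$start_1based[r] - 1L, rows$end_1based[r],
                   if (rows$strand[r] %in% c("-", "-1", -1)) -1L else 1L)))
    else gene_feature("other", "none", 0, 1)[0, ]
    mito_record(accession = acc, organism = organism,
                sequence = as.character(seqs[[i]]), features = feats)
  })
}

#' Read a universe of annotated mitogenomes
#'
#' Accepts GenBank flat files and/or FASTA files (each FASTA `x.fasta` paired
#' with a feature table `x.features.tsv` unless `feature_tables` overrides the
#' pairing). Every record is joined to the taxonomy by accession first, then
#' by organism name; records lacking a taxonomy entry are kept with
#' `family_id = NA` and reported via a warning, never silently dropped.
#'
#' @param paths character vector of input files.
#' @param taxonomy a taxonomy tibble (see [read_taxonomy()]) or a TSV path.
#' @param feature_tables optional named character vector mapping a FASTA path
#'   to its feature-table path.
#' @return list of [mito_record()] objects, features sorted by start.
#' @export
read_genomes <- function(paths, taxonomy, feature_tables = NULL) {
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)
  if (length(paths) == 0L) {
    warning("read_genomes(): empty input list, returning empty universe")
    return(list())
  }
  records <- list()
  for (p in paths) {
    first <- readLines(p, n = 1L, warn = FALSE)
    recs <- if (grepl("^LOCUS", first)) list(read_genbank(p))
    else if (grepl("^>", first)) {
      ftp <- if (!is.null(feature_tables) && p %in% names(feature_tables))
        feature_tables[[p]] else sub("\\.(fa|fasta|fna)$", ".features.tsv", p)
      if (!file.exists(ftp))
        tb_error(sprintf("%s: no feature table found at %s", p, ftp),
                 "trnabarcode_format_error")
      read_fasta_with_features(p, ftp)
    } else
      tb_error(sprintf("%s line 1: unrecognized format", p),
               "trnabarcode_format_error")
    records <- c(records, recs)
  }
  accs <- vapply(records, `[[`, character(1), "accession")
  if (anyDuplicated(accs))
    tb_error(sprintf("duplicate accession(s): %s",
                     paste(unique(accs[duplicated(accs)]), collapse = ", ")),
             "trnabarcode_conflict_error")
  unmatched <- character(0)
  for (i in seq_along(records)) {
    hit <- match(records[[i]]$accession, taxonomy$accession)
    if (is.na(hit)) hit <- match(records[[i]]$organism, taxonomy$organism)
    if (is.na(hit)) unmatched <- c(unmatched, records[[i]]$accession)
    else records[[i]]$family_id <- as.character(taxonomy$family_id[hit])
  }
  if (length(unmatched))
    warning(sprintf("no taxonomy entry for: %s (kept with family_id = NA)",
                    paste(unmatched, collapse = ", ")))
  names(records) <- accs
  records
}
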
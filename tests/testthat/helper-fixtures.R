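# Test fixtures and independent oracles. Everything here is deliberately
# naive and self-contained so it can serve as a reference implementation
# against the package's optimized paths.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rc_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# build a toy annotated record with the ...tRNA,tRNA,COI,tRNA,tRNA... layout
build_toy_record <- function(accession = "TOY00001",
                             organism = "Toyfish example",
                             family_id = "FAMTOY",
                             l2 = rand_seq(70), l1 = rand_seq(70),
                             coi = rand_seq(600),
                             r1 = rand_seq(70), r2 = rand_seq(70),
                             spacer = 20, lead = 50,
                             topology = "circular",
                             drop_right = FALSE) {
  parts <- list(lead = rand_seq(lead), l2 = l2, s1 = rand_seq(spacer),
                l1 = l1, s2 = rand_seq(spacer), coi = coi)
  if (!drop_right)
    parts <- c(parts, list(s3 = rand_seq(spacer), r1 = r1,
                           s4 = rand_seq(spacer), r2 = r2))
  parts <- c(parts, list(tail = rand_seq(lead)))
  seq <- paste(unlist(parts), collapse = "")
  off <- cumsum(c(0, nchar(unlist(parts))))
  names(off) <- c(names(parts), "end")
  feats <- rbind(
    gene_feature("tRNA", "tRNA-Cys", off[["l2"]], off[["l2"]] + nchar(l2)),
    gene_feature("tRNA", "tRNA-Tyr", off[["l1"]], off[["l1"]] + nchar(l1)),
    gene_feature("CDS", "COX1", off[["coi"]], off[["coi"]] + nchar(coi)))
  if (!drop_right)
    feats <- rbind(feats,
      gene_feature("tRNA", "tRNA-Ser", off[["r1"]], off[["r1"]] + nchar(r1), -1L),
      gene_feature("tRNA", "tRNA-Asp", off[["r2"]], off[["r2"]] + nchar(r2)))
  mito_record(accession, organism, seq, feats, family_id, topology)
}

# naive mismatch-tolerant end-to-end scan, both strands, circular aware,
# enforcing the 3-base 3'-exact window -- the reference for find_matches()
naive_find_matches <- function(primer, record, max_mm = 0L) {
  L <- nchar(record$sequence)
  plen <- nchar(primer)
  subject <- record$sequence
  if (record$topology == "circular")
    subject <- paste0(subject, substr(subject, 1, plen - 1))
  pchars_f <- strsplit(primer, "")[[1]]
  pchars_r <- strsplit(rc_chr(primer), "")[[1]]
  schars <- strsplit(subject, "")[[1]]
  out <- list()
  for (pos in seq_len(L)) {
    if (pos + plen - 1 > nchar(subject)) break
    win <- schars[pos:(pos + plen - 1)]
    # plus strand: primer 3' end is the window's right edge
    mm <- sum(win != pchars_f)
    if (mm <= max_mm && all(win[(plen - 2):plen] == pchars_f[(plen - 2):plen]))
      out[[length(out) + 1]] <- data.frame(position = pos - 1L, strand = 1L,
                                           mismatches = mm)
    # minus strand: reference carries revcomp(primer); 3' end at left edge
    mm <- sum(win != pchars_r)
    if (mm <= max_mm && all(win[1:3] == pchars_r[1:3]))
      out[[length(out) + 1]] <- data.frame(position = pos - 1L, strand = -1L,
                                           mismatches = mm)
  }
  if (!length(out))
    return(data.frame(position = integer(0), strand = integer(0),
                      mismatches = integer(0)))
  do.call(rbind, out)
}

# brute-force window enumeration with independent filter logic
naive_enumerate <- function(segment, min_len = 18, max_len = 26,
                            gc_range = c(0.30, 0.70), max_homopolymer = 4,
                            max_self_comp = 8, apply_filters = TRUE) {
  n <- nchar(segment)
  rows <- list()
  for (len in min_len:max_len) {
    if (n < len) next
    for (s in 1:(n - len + 1)) {
      w <- substr(segment, s, s + len - 1)
      if (apply_filters) {
        if (grepl("N", w, fixed = TRUE)) next
        ch <- strsplit(w, "")[[1]]
        r <- rle(ch)
        if (max(r$lengths) > max_homopolymer) next
        gc <- mean(ch %in% c("G", "C"))
        if (gc < gc_range[1] || gc > gc_range[2]) next
        k <- max_self_comp + 1
        if (len >= k) {
          rcw <- rc_chr(w)
          bad <- FALSE
          for (i in 1:(len - k + 1))
            if (grepl(substr(w, i, i + k - 1), rcw, fixed = TRUE)) {
              bad <- TRUE; break
            }
          if (bad) next
        }
      }
      rows[[length(rows) + 1]] <- data.frame(sequence = w, offset = s - 1L,
                                             length = len)
    }
  }
  if (!length(rows))
    return(data.frame(sequence = character(0), offset = integer(0),
                      length = integer(0)))
  do.call(rbind, rows)
}

# exhaustive minimum set cover over candidate index sets
exhaustive_cover_size <- function(targets, sets) {
  reachable <- intersect(targets, unique(unlist(sets)))
  for (size in seq_along(sets)) {
    combos <- utils::combn(length(sets), size, simplify = FALSE)
    for (cmb in combos)
      if (all(reachable %in% unlist(sets[cmb]))) return(size)
  }
  0L
}

# small clean universe shared by several pipeline tests
small_universe <- function(seed = 101, n_families = 4, species = 2, ...) {
  simulate_universe(simulation_config(n_families = n_families,
                                      species_per_family = species,
                                      seed = seed, ...))
}
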
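test_that("gene_feature validates intervals and strand", {
  f <- gene_feature("tRNA", "tRNA-Tyr", 10, 80)
  expect_equal(f$start, 10L)
  expect_equal(f$end, 80L)
  expect_error(gene_feature("tRNA", "x", 10, 10), class = "trnabarcode_bad_feature")
  expect_error(gene_feature("tRNA", "x", -1, 10), class = "trnabarcode_bad_feature")
  expect_error(gene_feature("tRNA", "x", 0, 10, strand = 2), class = "trnabarcode_bad_feature")
  # origin-wrapping features may have end <= start
  w <- gene_feature("tRNA", "x", 90, 5, wraps_origin = TRUE)
  expect_true(w$wraps_origin)
})

test_that("locate_coi matches the fixed synonym table and nothing else", {
  set.seed(1)
  for (lab in c("COX1", "coi", "CO1", "cytochrome c oxidase subunit I",
                "Cytochrome c oxidase subunit 1")) {
    rec <- build_toy_record()
    rec$features$label[rec$features$kind == "CDS"] <- lab
    expect_equal(locate_coi(rec)$label, lab)
  }
  rec <- build_toy_record()
  rec$features$label[rec$features$kind == "CDS"] <- "cytochrome b"
  expect_error(locate_coi(rec), class = "trnabarcode_missing_coi")
  rec2 <- build_toy_record()
  rec2$features <- rbind(rec2$features, gene_feature("CDS", "COI", 0, 30))
  expect_error(locate_coi(rec2), class = "trnabarcode_ambiguous_coi")
  # no fuzzy matching: a COI-containing longer label is not a hit
  rec3 <- build_toy_record()
  rec3$features$label[rec3$features$kind == "CDS"] <- "COI-like pseudogene"
  expect_error(locate_coi(rec3), class = "trnabarcode_missing_coi")
})

test_that("extract_flanks returns nearest tRNAs first and respects k", {
  set.seed(2)
  l2 <- rand_seq(70); l1 <- rand_seq(70); r1 <- rand_seq(70); r2 <- rand_seq(70)
  rec <- build_toy_record(l2 = l2, l1 = l1, r1 = r1, r2 = r2)
  f1 <- extract_flanks(rec, k = 1)
  expect_equal(f1$left_segments, l1)   # nearest upstream = tRNA-Tyr
  expect_equal(f1$right_segments, r1)  # nearest downstream = tRNA-Ser
  expect_false(f1$missing_left); expect_false(f1$missing_right)
  f2 <- extract_flanks(rec, k = 2)
  expect_equal(f2$left_segments, c(l1, l2))
  expect_equal(f2$right_segments, c(r1, r2))
  # prefix property: k results are a prefix of k+1 results
  f3 <- extract_flanks(rec, k = 3)
  expect_equal(f3$left_segments[1:2], f2$left_segments)
  expect_true(f3$missing_left && f3$missing_right)
})

test_that("flank segments are reported on the reference strand", {
  set.seed(8)
  r1 <- rand_seq(70)
  rec <- build_toy_record(r1 = r1)  # tRNA-Ser is annotated on the minus strand
  fs <- extract_flanks(rec, k = 1)
  expect_equal(fs$right_segments[1], r1)  # not reverse-complemented
  expect_equal(fs$right_features$strand[1], -1L)
})

test_that("extraction on linear records equals a naive sorted-feature scan", {
  set.seed(3)
  for (i in 1:5) {
    rec <- build_toy_record(topology = "linear")
    coi <- locate_coi(rec)
    trnas <- rec$features[rec$features$kind == "tRNA", ]
    up <- trnas[trnas$end <= coi$start, ]
    up <- up[order(coi$start - up$end), ]
    down <- trnas[trnas$start >= coi$end, ]
    down <- down[order(down$start - coi$end), ]
    fs <- extract_flanks(rec, k = 2)
    expect_equal(fs$left_features$start, utils::head(up$start, 2))
    expect_equal(fs$right_features$start, utils::head(down$start, 2))
    # segments never overlap the COI interval
    expect_true(all(fs$left_features$end <= coi$start))
    expect_true(all(fs$right_features$start >= coi$end))
  }
})

test_that("circular topology wraps the flank search across the origin", {
  set.seed(4)
  # rotate a toy genome so that the upstream tRNAs sit at the far end
  rec <- build_toy_record()
  rot <- 200L  # move origin into the middle of the leading spacer region
  L <- nchar(rec$sequence)
  seq2 <- paste0(substr(rec$sequence, rot + 1, L), substr(rec$sequence, 1, rot))
  feats <- rec$features
  feats$start <- (feats$start - rot) %% L
  feats$end0 <- (feats$end - rot) %% L
  feats$wraps_origin <- feats$end0 < feats$start
  feats$end <- ifelse(feats$wraps_origin, feats$end0, feats$end0)
  feats$end0 <- NULL
  rec2 <- mito_record(rec$accession, rec$organism, seq2, feats,
                      rec$family_id, "circular")
  fs <- extract_flanks(rec, k = 2)
  fs2 <- extract_flanks(rec2, k = 2)
  expect_equal(fs2$left_segments, fs$left_segments)
  expect_equal(fs2$right_segments, fs$right_segments)
})

test_that("a genome with no downstream tRNA reports a missing right flank", {
  set.seed(5)
  # generous spacers so no upstream tRNA is closer to COI across the origin
  rec <- build_toy_record(drop_right = TRUE, lead = 300)
  fs <- extract_flanks(rec, k = 1)
  expect_true(fs$missing_right)
  expect_false(fs$missing_left)
  expect_length(fs$right_segments, 0)
})

test_that("GenBank output round-trips through read_genomes", {
  set.seed(6)
  u <- small_universe(seed = 106, n_families = 2, species = 2)
  d <- withr::local_tempdir()
  write_universe(u, d)
  recs <- read_genomes(list.files(d, pattern = "[.]gb$", full.names = TRUE),
                       file.path(d, "taxonomy.tsv"))
  expect_length(recs, length(u$records))
  for (acc in names(u$records)) {
    a <- u$records[[acc]]; b <- recs[[acc]]
    expect_identical(b$sequence, a$sequence)
    expect_identical(b$organism, a$organism)
    expect_identical(b$family_id, a$family_id)
    expect_equal(b$features[order(b$features$start), c("kind", "start", "end", "strand")],
                 a$features[order(a$features$start), c("kind", "start", "end", "strand")])
  }
})

test_that("read_genomes reports taxonomy gaps and rejects duplicates", {
  set.seed(7)
  u <- small_universe(seed = 107, n_families = 2, species = 1)
  d <- withr::local_tempdir()
  write_universe(u, d)
  files <- list.files(d, pattern = "[.]gb$", full.names = TRUE)
  tax <- u$taxonomy[-1, ]  # drop one entry
  expect_warning(recs <- read_genomes(files, tax), "no taxonomy entry")
  expect_length(recs, length(files))    # reported, not dropped
  expect_true(is.na(recs[[u$taxonomy$accession[1]]]$family_id))
  expect_error(read_genomes(c(files, files[1]), u$taxonomy),
               class = "trnabarcode_conflict_error")
  expect_warning(empty <- read_genomes(character(0), u$taxonomy), "empty input")
  expect_length(empty, 0)
})

test_that("FASTA plus feature-table input is equivalent to GenBank input", {
  set.seed(9)
  u <- small_universe(seed = 109, n_families = 1, species = 2)
  d <- withr::local_tempdir()
  write_universe(u, d)
  rec <- u$records[[1]]
  fa <- file.path(d, "one.fasta")
  writeLines(c(sprintf(">%s %s", rec$accession, rec$organism), rec$sequence), fa)
  ft <- data.frame(accession = rec$accession, kind = rec$features$kind,
                   label = rec$features$label,
                   start_1based = rec$features$start + 1L,
                   end_1based = rec$features$end,
                   strand = ifelse(rec$features$strand == 1L, "+", "-"))
  write.table(ft, file.path(d, "one.features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  got <- read_genomes(fa, u$taxonomy)[[1]]
  expect_identical(got$sequence, rec$sequence)
  expect_equal(got$features$start, rec$features$start)
  expect_equal(extract_flanks(got, 2)$left_segments,
               extract_flanks(rec, 2)$left_segments)
})

test_that("flanks_to_fasta writes accession|side|rank headers", {
  set.seed(10)
  rec <- build_toy_record(accession = "TOY00042")
  path <- withr::local_tempfile(fileext = ".fasta")
  flanks_to_fasta(list(extract_flanks(rec, 2)), path)
  headers <- grep("^>", readLines(path), value = TRUE)
  expect_setequal(headers, c(">TOY00042|L|1", ">TOY00042|L|2",
                             ">TOY00042|R|1", ">TOY00042|R|2"))
})
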
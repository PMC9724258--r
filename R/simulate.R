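# Seeded synthetic-mitogenome generator.
#
# Emulates the input structure the pipeline consumes: annotated circular
# mitogenomes with the vertebrate gene order around COI
# (... tRNA-Cys, tRNA-Tyr, COI, tRNA-Ser, tRNA-Asp ...), family structure
# with high intra-family and lower inter-family flank similarity, plus
# planted failure scenarios: confusable family pairs whose nearest flanks
# differ by exactly one base, species missing all downstream tRNAs, and one
# oversized "megafamily" whose residual species force stage-2 resolution.

#' Simulation configuration
#'
#' Family ancestors are drawn from a global ancestral cassette mutated at
#' `inter_family_divergence / 2` per branch (star phylogeny), so the
#' *pairwise* inter-family divergence is approximately
#' `inter_family_divergence`. Species mutate from their family ancestor at
#' `intra_family_sub_rate` per site (substitutions only, keeping planted
#' mismatch counts exact).
#'
#' Planted scenarios are appended to the `n_families` clean families:
#' each confusable pair adds two single-species families whose nearest flanks
#' differ by exactly one base (shielded so no admissible primer window covers
#' the differing site) while their second flanks diverge normally; a
#' megafamily (>= 7 species) adds one oversized family whose last five
#' species form a known residual set (4 sharing flank haplotype A, 1 with
#' haplotype B) plus three single-species decoy families that make the
#' residuals non-exclusive at both extension depths.
#'
#' @param n_families number of clean families.
#' @param species_per_family species count per clean family (length-1, or
#'   length-2 range sampled uniformly).
#' @param flank_len tRNA segment length (nt); >= 47 when confusable pairs or
#'   a megafamily are planted.
#' @param coi_len COI gene length (nt).
#' @param n_flanking_trnas_per_side tRNAs on each side of COI.
#' @param intra_family_sub_rate per-site substitution rate within a family.
#' @param inter_family_divergence target pairwise per-site divergence between
#'   families.
#' @param n_confusable_pairs planted confusable family pairs.
#' @param n_missing_flank_species species stripped of all downstream tRNAs.
#' @param megafamily_size size of the planted megafamily (0 = none; else >= 7).
#' @param seed integer seed fixing all randomness.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_families = 10L, species_per_family = 5L,
                              flank_len = 70L, coi_len = 1545L,
                              n_flanking_trnas_per_side = 2L,
                              intra_family_sub_rate = 0.01,
                              inter_family_divergence = 0.15,
                              n_confusable_pairs = 0L,
                              n_missing_flank_species = 0L,
                              megafamily_size = 0L,
                              seed = 1L) {
  rates <- c(intra_family_sub_rate, inter_family_divergence)
  if (any(rates < 0 | rates > 1))
    tb_error("mutation rates must lie in [0, 1]", "trnabarcode_bad_argument")
  if (flank_len <= 0 || coi_len <= 0 || n_families < 1)
    tb_error("lengths and family count must be positive", "trnabarcode_bad_argument")
  if (n_confusable_pairs > 0 && flank_len < 47)
    tb_error("confusable pairs need flank_len >= 47 (shield + primer window)",
             "trnabarcode_bad_argument")
  if (megafamily_size != 0 && megafamily_size < 7)
    tb_error("megafamily_size must be 0 or >= 7 (5 residuals + >= 2 core)",
             "trnabarcode_bad_argument")
  if (n_flanking_trnas_per_side < 1)
    tb_error("need >= 1 flanking tRNA per side", "trnabarcode_bad_argument")
  n_clean_species <- if (length(species_per_family) == 1L)
    n_families * species_per_family else n_families * species_per_family[1]
  if (n_missing_flank_species > n_clean_species)
    tb_error("more missing-flank species than clean species", "trnabarcode_bad_argument")
  structure(list(n_families = as.integer(n_families),
                 species_per_family = as.integer(species_per_family),
                 flank_len = as.integer(flank_len),
                 coi_len = as.integer(coi_len),
                 n_flanking_trnas_per_side = as.integer(n_flanking_trnas_per_side),
                 intra_family_sub_rate = intra_family_sub_rate,
                 inter_family_divergence = inter_family_divergence,
                 n_confusable_pairs = as.integer(n_confusable_pairs),
                 n_missing_flank_species = as.integer(n_missing_flank_species),
                 megafamily_size = as.integer(megafamily_size),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Substitution-only sequence mutation
#'
#' Each site is independently replaced by a uniformly chosen *different* base
#' with probability `rate`; length is preserved and no indels are introduced,
#' so planted mismatch counts stay exact.
#'
#' @param seq DNA string.
#' @param rate per-site substitution probability in `[0, 1]`.
#' @return mutated DNA string.
#' @export
mutate_sequence <- function(seq, rate) {
  if (rate < 0 || rate > 1)
    tb_error("rate must lie in [0, 1]", "trnabarcode_bad_argument")
  if (rate == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(bases, b), 1L), character(1))
  }
  paste(ch, collapse = "")
}

# segment ids for a cassette, outermost-left first
.cassette_segment_names <- function(n_side) {
  c(sprintf("L%d", rev(seq_len(n_side))), "COI", sprintf("R%d", seq_len(n_side)))
}

# upstream tRNA labels nearest-first are Tyr, Cys; downstream Ser, Asp
.trna_labels <- c("tRNA-Phe", "tRNA-Val", "tRNA-Trp", "tRNA-Ala", "tRNA-Asn",
                  "tRNA-Cys", "tRNA-Tyr", "tRNA-Ser", "tRNA-Asp", "tRNA-Lys")

.draw_cassette <- function(cfg) {
  n_side <- cfg$n_flanking_trnas_per_side
  segs <- stats::setNames(
    c(lapply(seq_len(n_side), function(i) rand_dna(cfg$flank_len)),
      list(rand_dna(cfg$coi_len)),
      lapply(seq_len(n_side), function(i) rand_dna(cfg$flank_len))),
    .cassette_segment_names(n_side))
  segs
}

.mutate_cassette <- function(segs, rate, skip = character(0)) {
  for (nm in names(segs))
    if (!nm %in% skip) segs[[nm]] <- mutate_sequence(segs[[nm]], rate)
  segs
}

# flank with a 1-base signal position shielded by 5-base homopolymer runs so
# that every admissible primer window provably avoids it
.shielded_flank <- function(cfg, signal_base, run_base = "A") {
  shield <- strrep(run_base, 5)
  left_len <- (cfg$flank_len - 11L) %/% 2L
  right_len <- cfg$flank_len - 11L - left_len
  cs <- primer_constraints()
  repeat {
    left <- rand_dna(left_len); right <- rand_dna(right_len)
    flank <- paste0(left, shield, signal_base, shield, right)
    if (nrow(enumerate_candidates(flank, cs, "forward")) > 0L &&
        nrow(enumerate_candidates(flank, cs, "reverse_complement")) > 0L)
      return(list(flank = flank, left = left, right = right,
                  signal_at = left_len + 6L))  # 1-based signal position
  }
}

.swap_signal <- function(shielded, new_base) {
  f <- shielded$flank
  substr(f, shielded$signal_at, shielded$signal_at) <- new_base
  f
}

# assemble a mito_record from cassette segments
.assemble_record <- function(accession, organism, family_id, segs, cfg,
                             drop_downstream = FALSE) {
  n_side <- cfg$n_flanking_trnas_per_side
  spacer <- function(n) rand_dna(n)
  up_names <- sprintf("L%d", rev(seq_len(n_side)))      # outermost first
  down_names <- sprintf("R%d", seq_len(n_side))         # nearest first
  up_labels <- rev(.trna_labels[seq(7L, by = -1L, length.out = n_side)])
  down_labels <- .trna_labels[seq(8L, length.out = n_side)]

  parts <- character(0); feats <- list(); pos <- 0L
  add <- function(seq, kind = NULL, label = NULL, strand = 1L) {
    parts <<- c(parts, seq)
    if (!is.null(kind))
      feats[[length(feats) + 1L]] <<- gene_feature(kind, label, pos,
                                                   pos + nchar(seq), strand)
    pos <<- pos + nchar(seq)
  }
  add(spacer(60L), "rRNA", "16S ribosomal RNA")
  for (i in seq_along(up_names)) {
    add(spacer(20L))
    add(segs[[up_names[i]]], "tRNA", up_labels[i])
  }
  add(spacer(20L))
  add(segs[["COI"]], "CDS", "COX1")
  if (!drop_downstream) {
    for (i in seq_along(down_names)) {
      add(spacer(20L))
      add(segs[[down_names[i]]], "tRNA", down_labels[i],
          strand = if (down_labels[i] == "tRNA-Ser") -1L else 1L)
    }
  }
  add(spacer(60L))
  mito_record(accession = accession, organism = organism,
              sequence = paste(parts, collapse = ""),
              features = do.call(rbind, feats),
              family_id = family_id, topology = "circular")
}

#' Simulate an annotated mitogenome universe
#'
#' Generates the universe described by the [simulation_config()], with truth
#' labels recording each species' planted scenario (`clean`, `confusable`,
#' `missing-flank`, `megafamily-core`, `megafamily-residual`, or `decoy-*`).
#' The RNG state is saved and restored; the same seed yields byte-identical
#' output.
#'
#' @param config a [simulation_config()].
#' @return list with `records` (named list of [mito_record()]), `truth`
#'   (tibble: accession, organism, family_id, tag, haplotype), and `taxonomy`
#'   (tibble in the on-disk taxonomy format).
#' @export
simulate_universe <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  cfg <- config
  n_side <- cfg$n_flanking_trnas_per_side

  records <- list(); truth <- list()
  acc_counter <- 0L
  next_acc <- function() {
    acc_counter <<- acc_counter + 1L
    sprintf("SYN%06d", acc_counter)
  }
  add_species <- function(fam_idx, fam_id, sp_idx, segs, tag,
                          haplotype = NA_character_, drop_downstream = FALSE) {
    acc <- next_acc()
    org <- sprintf("Synthofamilia%03d species%02d", fam_idx, sp_idx)
    rec <- .assemble_record(acc, org, fam_id, segs, cfg, drop_downstream)
    records[[acc]] <<- rec
    truth[[length(truth) + 1L]] <<- tibble::tibble(
      accession = acc, organism = org, family_id = fam_id, tag = tag,
      haplotype = haplotype)
  }

  global <- .draw_cassette(cfg)
  branch_rate <- cfg$inter_family_divergence / 2

  # clean families
  missing_left_to_assign <- cfg$n_missing_flank_species
  fam_counter <- 0L
  for (f in seq_len(cfg$n_families)) {
    fam_counter <- fam_counter + 1L
    fam_id <- sprintf("FAM%03d", fam_counter)
    fam_segs <- .mutate_cassette(global, branch_rate)
    n_sp <- if (length(cfg$species_per_family) == 1L) cfg$species_per_family
    else sample(cfg$species_per_family[1]:cfg$species_per_family[2], 1L)
    for (s in seq_len(n_sp)) {
      sp_segs <- .mutate_cassette(fam_segs, cfg$intra_family_sub_rate)
      drop_down <- FALSE; tag <- "clean"
      if (missing_left_to_assign > 0L && s == n_sp) {
        drop_down <- TRUE; tag <- "missing-flank"
        missing_left_to_assign <- missing_left_to_assign - 1L
      }
      add_species(fam_counter, fam_id, s, sp_segs, tag,
                  drop_downstream = drop_down)
    }
  }

  # confusable pairs: two single-species families per pair, nearest flanks
  # identical except one shielded base on each side
  for (p in seq_len(cfg$n_confusable_pairs)) {
    base_a <- .mutate_cassette(global, branch_rate)
    base_b <- .mutate_cassette(global, branch_rate)
    shield_L <- .shielded_flank(cfg, "C", run_base = "A")
    shield_R <- .shielded_flank(cfg, "C", run_base = "T")
    segs_a <- base_a; segs_b <- base_b
    segs_a[["L1"]] <- shield_L$flank
    segs_a[["R1"]] <- shield_R$flank
    segs_b[["L1"]] <- .swap_signal(shield_L, "G")
    segs_b[["R1"]] <- .swap_signal(shield_R, "G")
    for (which_fam in c("a", "b")) {
      fam_counter <- fam_counter + 1L
      fam_id <- sprintf("FAM%03d", fam_counter)
      add_species(fam_counter, fam_id, 1L,
                  if (which_fam == "a") segs_a else segs_b,
                  "confusable", haplotype = sprintf("confusable-pair%d", p))
    }
  }

  # megafamily + decoys
  if (cfg$megafamily_size > 0L) {
    mega_segs <- .mutate_cassette(global, branch_rate)
    decoys <- list(DX1 = .mutate_cassette(global, branch_rate),
                   DX2 = .mutate_cassette(global, branch_rate),
                   DY = .mutate_cassette(global, branch_rate))
    decoy_tags <- c(DX1 = "decoy-k1", DX2 = "decoy-k1", DY = "decoy-k2")
    decoy_ids <- character(0)
    for (d in names(decoys)) {
      fam_counter <- fam_counter + 1L
      fam_id <- sprintf("FAM%03d", fam_counter)
      decoy_ids[d] <- fam_id
      add_species(fam_counter, fam_id, 1L, decoys[[d]], decoy_tags[[d]])
    }
    fam_counter <- fam_counter + 1L
    mega_id <- sprintf("FAM%03d", fam_counter)
    n_core <- cfg$megafamily_size - 5L
    for (s in seq_len(n_core)) {
      sp <- .mutate_cassette(mega_segs, cfg$intra_family_sub_rate)
      add_species(fam_counter, mega_id, s, sp, "megafamily-core")
    }
    outer_names <- if (n_side >= 2L)
      c(sprintf("L%d", 2L:n_side), sprintf("R%d", 2L:n_side)) else character(0)
    for (s in seq_len(5L)) {
      hap <- if (s <= 4L) "A" else "B"
      donor <- if (hap == "A") decoys$DX1 else decoys$DX2
      sp <- .mutate_cassette(mega_segs, cfg$intra_family_sub_rate,
                             skip = c("L1", "R1", outer_names))
      sp[["L1"]] <- donor[["L1"]]           # homogenized: exact copies
      sp[["R1"]] <- donor[["R1"]]
      for (nm in outer_names) sp[[nm]] <- decoys$DY[[nm]]
      add_species(fam_counter, mega_id, n_core + s, sp,
                  "megafamily-residual", haplotype = hap)
    }
  }

  truth <- do.call(rbind, truth)
  taxonomy <- tibble::tibble(accession = truth$accession,
                             organism = truth$organism,
                             family_id = truth$family_id,
                             family_name = paste0("Synthofamilia_",
                                                  truth$family_id))
  list(records = records, truth = truth, taxonomy = taxonomy)
}

#' Write a simulated universe to disk
#'
#' One GenBank flat file per genome plus `taxonomy.tsv` and
#' `truth_labels.json`.
#'
#' @param universe result of [simulate_universe()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_universe <- function(universe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in universe$records)
    write_genbank(rec, file.path(dir, paste0(rec$accession, ".gb")))
  utils::write.table(universe$taxonomy, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(universe$truth, file.path(dir, "truth_labels.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(dir)
}
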
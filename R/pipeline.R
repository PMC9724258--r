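# Two-stage orchestration: family grouping, stage-1 design + exclusivity
# screening with candidate cycling, escalation by flank extension and
# similarity-based re-grouping, stage-2 per-species resolution against the
# residual reference, and catalog/statistics emission.
#
# Escalation order is fixed: candidate cycling (inside stage 1) -> flank
# extension -> re-grouping -> stage 2; each step only touches groups the
# previous step left with uncovered members.

new_family_group <- function(group_id, members) {
  structure(list(group_id = group_id,
                 group_kind = if (length(members) == 1L) "single-species"
                 else "multispecies",
                 members = members,
                 status = "unresolved",
                 resolution = NA_character_,
                 assigned = list(),
                 residual = members,
                 residual_reasons = character(0)),
            class = "family_group")
}

#' @export
print.family_group <- function(x, ...) {
  cat(sprintf("<family_group> %s (%s, %d species) status=%s resolution=%s, %d pair(s), %d residual\n",
              x$group_id, x$group_kind, length(x$members), x$status,
              x$resolution, length(x$assigned), length(x$residual)))
  invisible(x)
}

.update_group_status <- function(group) {
  covered <- unique(unlist(lapply(group$assigned, `[[`, "covered")))
  group$residual <- setdiff(group$members, covered)
  group$status <- if (length(group$residual) == 0L) "exclusive"
  else if (length(covered) > 0L) "partially-non-exclusive"
  else "unresolved"
  n_pairs <- length(group$assigned)
  group$primer_mode <- if (n_pairs <= 1L) "single-pair" else "multiple-pairs"
  group
}

.design_for <- function(ctx, acc, config, segment_rank) {
  key <- sprintf("%s@%d", acc, segment_rank)
  if (is.null(ctx$pairs_cache[[key]])) {
    ctx$pairs_cache[[key]] <- design_pairs(ctx$flanks[[acc]],
                                           config$constraints,
                                           top_n = config$top_n,
                                           segment_rank = segment_rank,
                                           enum_cache = ctx$enum_cache)
  }
  ctx$pairs_cache[[key]]
}

# pipeline context: shared caches (environment so helpers can fill them)
.make_ctx <- function(records, config) {
  ctx <- new.env(parent = emptyenv())
  ctx$records <- records
  ctx$index <- universe_index(records, config$constraints$max_len)
  ctx$flanks <- lapply(records, extract_flanks, k = config$max_k)
  ctx$pairs_cache <- new.env(parent = emptyenv())
  ctx$enum_cache <- new.env(parent = emptyenv())
  ctx
}

.member_pairs <- function(ctx, members, config, segment_rank) {
  pieces <- lapply(members, function(acc) .design_for(ctx, acc, config, segment_rank))
  missing <- vapply(pieces, function(p) !is.null(attr(p, "missing")), logical(1))
  out <- do.call(rbind, pieces)
  attr(out, "members_missing") <- members[missing]
  out
}

.cover_group <- function(group, ctx, config, members_to_cover, pairs, stage,
                         require_exclusive = TRUE, index = NULL) {
  if (is.null(index)) index <- ctx$index
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(group)
  cov <- minimal_pair_cover(group$members, pairs, index, config,
                            require_exclusive = require_exclusive,
                            targets = members_to_cover)
  for (sel in cov$selected) {
    hit <- intersect(sel$covered, members_to_cover)
    if (length(hit) == 0L) next
    group$assigned[[length(group$assigned) + 1L]] <-
      list(pair = sel$pair, covered = hit, amplifies = sel$amplifies,
           stage = stage)
  }
  .update_group_status(group)
}

#' Run stage 1: family-level design and exclusivity screening
#'
#' Groups the universe at the family level, extracts nearest flanks, designs
#' up to `top_n` candidate primer pairs per species (candidate cycling), and
#' resolves each group by a greedy minimal cover restricted to pairs
#' exclusive to the group. Members whose flanks are missing are reported in
#' the group's `residual_reasons`, never dropped.
#'
#' @param records named list of [mito_record()] (family-labeled).
#' @param config a [barcode_config()].
#' @return list of class `stage1_result` with `groups`, `ctx` (shared caches
#'   reused by the later steps), and `log`.
#' @export
run_stage1 <- function(records, config = barcode_config()) {
  fam <- vapply(records, `[[`, character(1), "family_id")
  if (anyNA(fam))
    tb_error(sprintf("records without family_id: %s",
                     paste(names(records)[is.na(fam)], collapse = ", ")),
             "trnabarcode_bad_argument")
  ctx <- .make_ctx(records, config)
  groups <- lapply(split(names(records), fam), function(members)
    new_family_group(unique(fam[members]), sort(members)))
  log <- list()
  for (gid in names(groups)) {
    g <- groups[[gid]]
    pairs <- .member_pairs(ctx, g$members, config, segment_rank = 1L)
    g <- .cover_group(g, ctx, config, g$members, pairs, stage = 1L)
    miss <- attr(pairs, "members_missing")
    miss <- intersect(miss, g$residual)
    if (length(miss))
      g$residual_reasons[miss] <- "missing-flank"
    if (length(g$residual) == 0L) g$resolution <- "stage1"
    groups[[gid]] <- g
    log[[length(log) + 1L]] <- tibble::tibble(step = "stage1", group_id = gid,
                                              status = g$status)
  }
  structure(list(groups = groups, ctx = ctx, log = do.call(rbind, log)),
            class = "stage1_result")
}

#' Escalate one group by flank extension
#'
#' Re-extracts flanks one tRNA further out (up to `max_k`) for the group's
#' uncovered members, redesigns primer pairs on the extended segments, and
#' retries the exclusive cover. Members with no further tRNA to extend into
#' keep a `no-further-trna` residual reason.
#'
#' @param group a `family_group` with uncovered members.
#' @param ctx the shared context from [run_stage1()].
#' @param config a [barcode_config()].
#' @return the updated group (resolution `"extension"` when it becomes fully
#'   covered).
#' @export
resolve_by_extension <- function(group, ctx, config = barcode_config()) {
  if (length(group$residual) == 0L) return(group)
  for (rank in 2L:config$max_k) {
    if (length(group$residual) == 0L) break
    target <- group$residual
    pairs <- .member_pairs(ctx, target, config, segment_rank = rank)
    noext <- attr(pairs, "members_missing")
    if (length(noext))
      group$residual_reasons[setdiff(noext, names(group$residual_reasons))] <-
        "no-further-trna"
    group <- .cover_group(group, ctx, config, target, pairs, stage = 1L)
  }
  if (length(group$residual) == 0L) group$resolution <- "extension"
  group
}

.group_coi_seqs <- function(ctx, members) {
  stats::setNames(vapply(members, function(acc) {
    rec <- ctx$records[[acc]]
    feature_sequence(rec, locate_coi(rec))
  }, character(1)), members)
}

.group_representative <- function(ctx, members, params) {
  if (length(members) == 1L) return(members)
  group_similarity(.group_coi_seqs(ctx, members), params = params)$representative
}

#' Escalate one group by similarity-based re-grouping
#'
#' Finds the related group (highest representative-to-representative COI
#' similarity), applies the merge criterion ([evaluate_merge()]) on the COI
#' sets, and on acceptance forms a multi-family group that is re-screened
#' from scratch (with the former out-group partner now in-group). Other
#' groups are never modified. A merge is kept only when the re-screen fully
#' resolves the merged group; a merge that leaves members uncovered is
#' reverted (with the decision reported) so the original residuals escalate
#' to stage 2 instead of dragging an unrelated group along.
#'
#' @param group a `family_group` still carrying uncovered members.
#' @param groups the full named list of current groups.
#' @param ctx shared context from [run_stage1()].
#' @param config a [barcode_config()].
#' @return list with `group` (merged or unchanged), `absorbed` (the id of the
#'   partner group when merged, else `NULL`), and `decision`
#'   (the [evaluate_merge()] result, or `NULL` when no partner exists).
#' @export
resolve_by_regroup <- function(group, groups, ctx, config = barcode_config()) {
  others <- groups[setdiff(names(groups), group$group_id)]
  if (length(others) == 0L || length(group$residual) == 0L)
    return(list(group = group, absorbed = NULL, decision = NULL))
  params <- alignment_params()
  rep_a <- .group_representative(ctx, group$members, params)
  coi_a_rep <- .group_coi_seqs(ctx, rep_a)
  sims <- vapply(others, function(o) {
    rep_b <- .group_representative(ctx, o$members, params)
    pairwise_similarity(coi_a_rep[[1]], .group_coi_seqs(ctx, rep_b)[[1]], params)
  }, numeric(1))
  related <- others[[which.max(sims)]]
  decision <- evaluate_merge(.group_coi_seqs(ctx, group$members),
                             .group_coi_seqs(ctx, related$members),
                             delta = config$delta, theta = config$theta,
                             params = params)
  if (!decision$merged)
    return(list(group = group, absorbed = NULL, decision = decision))
  merged <- new_family_group(paste(group$group_id, related$group_id, sep = "+"),
                             sort(c(group$members, related$members)))
  merged$group_kind <- "multi-family"
  pairs <- .member_pairs(ctx, merged$members, config, segment_rank = 1L)
  merged <- .cover_group(merged, ctx, config, merged$members, pairs, stage = 1L)
  if (length(merged$residual) > 0L)
    merged <- resolve_by_extension(merged, ctx, config)
  if (length(merged$residual) > 0L) {
    # merge did not resolve the group: revert it
    decision$reverted <- TRUE
    return(list(group = group, absorbed = NULL, decision = decision))
  }
  merged$resolution <- "regroup"
  list(group = merged, absorbed = related$group_id, decision = decision)
}

#' Run stage 2: per-species resolution against the residual reference
#'
#' Residual species (members no exclusive family-level pair covered) are
#' re-screened with their own mitogenomes as the reference set: each residual
#' species contributes its own candidate pairs, and a pair is assigned to the
#' residual subset it amplifies within that reference. Species that still
#' cannot be resolved (e.g. missing flanks) are reported unresolved, never
#' dropped.
#'
#' @param group a `family_group` with residual members after extension and
#'   re-grouping.
#' @param ctx shared context from [run_stage1()].
#' @param config a [barcode_config()].
#' @return the updated group; stage-2 assignments carry `stage = 2`.
#' @export
run_stage2 <- function(group, ctx, config = barcode_config()) {
  if (length(group$residual) == 0L) return(group)
  residuals <- group$residual
  ref_records <- ctx$records[residuals]
  ref_index <- universe_index(ref_records, config$constraints$max_len)
  pairs <- .member_pairs(ctx, residuals, config, segment_rank = 1L)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    group$residual_reasons[setdiff(residuals, names(group$residual_reasons))] <-
      "no-candidate-primer"
    return(group)
  }
  cov <- minimal_pair_cover(residuals, pairs, ref_index, config,
                            require_exclusive = FALSE)
  for (sel in cov$selected) {
    group$assigned[[length(group$assigned) + 1L]] <-
      list(pair = sel$pair, covered = sel$covered, amplifies = sel$amplifies,
           stage = 2L)
  }
  group <- .update_group_status(group)
  if (length(group$residual) == 0L) group$resolution <- "stage2"
  else group$residual_reasons[setdiff(group$residual,
                                      names(group$residual_reasons))] <-
      "no-unique-primer"
  group
}

group_stats <- function(groups, step) {
  rows <- lapply(groups, function(g) tibble::tibble(
    step = step, group_id = g$group_id, group_kind = g$group_kind,
    primer_mode = if (is.null(g$primer_mode)) NA_character_ else g$primer_mode,
    status = g$status, n_species = length(g$members),
    n_pairs = length(g$assigned), n_residual = length(g$residual)))
  do.call(rbind, rows)
}

#' Run the full two-stage pipeline
#'
#' Orchestrates [run_stage1()], [resolve_by_extension()],
#' [resolve_by_regroup()] and [run_stage2()] in that fixed order, each step
#' operating only on groups the previous step left with uncovered members,
#' then emits the barcode catalog and per-step statistics.
#'
#' @param records named list of family-labeled [mito_record()] objects.
#' @param config a [barcode_config()].
#' @return object of class `barcode_pipeline` with `groups`, `catalog`
#'   (see [emit_catalog()]), `stats` (per-step group statistics), `log`,
#'   and `config`.
#' @export
run_pipeline <- function(records, config = barcode_config()) {
  s1 <- run_stage1(records, config)
  groups <- s1$groups
  ctx <- s1$ctx
  log <- s1$log
  stats_tbl <- group_stats(groups, "stage1")

  # flank extension
  for (gid in names(groups)) {
    if (length(groups[[gid]]$residual) == 0L) next
    groups[[gid]] <- resolve_by_extension(groups[[gid]], ctx, config)
    log <- rbind(log, tibble::tibble(step = "extension", group_id = gid,
                                     status = groups[[gid]]$status))
  }
  stats_tbl <- rbind(stats_tbl, group_stats(groups, "extension"))

  # re-grouping
  for (gid in names(groups)) {
    g <- groups[[gid]]
    if (is.null(g) || length(g$residual) == 0L) next
    res <- resolve_by_regroup(g, groups, ctx, config)
    if (!is.null(res$absorbed)) {
      groups[[gid]] <- NULL
      groups[[res$absorbed]] <- NULL
      groups[[res$group$group_id]] <- res$group
      log <- rbind(log, tibble::tibble(step = "regroup",
                                       group_id = res$group$group_id,
                                       status = res$group$status))
    } else {
      log <- rbind(log, tibble::tibble(step = "regroup", group_id = gid,
                                       status = g$status))
    }
  }
  stats_tbl <- rbind(stats_tbl, group_stats(groups, "regroup"))

  # stage 2
  for (gid in names(groups)) {
    if (length(groups[[gid]]$residual) == 0L) next
    groups[[gid]] <- run_stage2(groups[[gid]], ctx, config)
    log <- rbind(log, tibble::tibble(step = "stage2", group_id = gid,
                                     status = groups[[gid]]$status))
  }
  stats_tbl <- rbind(stats_tbl, group_stats(groups, "stage2"))

  structure(list(groups = groups,
                 catalog = emit_catalog(groups, records),
                 stats = stats_tbl, log = log, config = config),
            class = "barcode_pipeline")
}

#' @export
print.barcode_pipeline <- function(x, ...) {
  st <- table(vapply(x$groups, `[[`, character(1), "status"))
  cat(sprintf("<barcode_pipeline> %d species in %d groups (%s)\n",
              nrow(x$catalog), length(x$groups),
              paste(sprintf("%s: %d", names(st), st), collapse = ", ")))
  invisible(x)
}

#' Emit the barcode catalog
#'
#' One row per universe species: its group, assigned primer pair, resolution
#' stage, exclusivity flag, and the related species sharing the same pair.
#' Species without an assignment appear with `NA` primers and
#' `exclusive = FALSE`.
#'
#' @param groups named list of resolved `family_group` objects.
#' @param records the genome universe (for organism names).
#' @return a tibble with columns `accession`, `organism`, `family_id`,
#'   `group_id`, `f_primer`, `r_primer`, `stage`, `exclusive`,
#'   `related_species`, `status`.
#' @export
emit_catalog <- function(groups, records) {
  rows <- list()
  for (g in groups) {
    assignment <- stats::setNames(rep(NA_integer_, length(g$members)), g$members)
    for (i in seq_along(g$assigned)) {
      cov <- g$assigned[[i]]$covered
      assignment[cov[is.na(assignment[cov])]] <- i
    }
    for (acc in g$members) {
      ai <- assignment[[acc]]
      rec <- records[[acc]]
      if (is.na(ai)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          accession = acc, organism = rec$organism, family_id = rec$family_id,
          group_id = g$group_id, f_primer = NA_character_,
          r_primer = NA_character_, stage = NA_integer_, exclusive = FALSE,
          related_species = "",
          status = if (!is.null(g$residual_reasons) &&
                       acc %in% names(g$residual_reasons))
            g$residual_reasons[[acc]] else "unresolved")
      } else {
        a <- g$assigned[[ai]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          accession = acc, organism = rec$organism, family_id = rec$family_id,
          group_id = g$group_id, f_primer = a$pair$f_seq,
          r_primer = a$pair$r_seq, stage = a$stage, exclusive = TRUE,
          related_species = paste(setdiff(a$covered, acc), collapse = ","),
          status = "assigned")
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$accession), , drop = FALSE]
}

#' Look up catalog entries by name
#'
#' Case-insensitive substring match on organism and accession (the minimal
#' query interface of a barcode catalog).
#'
#' @param catalog tibble from [emit_catalog()].
#' @param query search string.
#' @return the matching catalog rows.
#' @export
lookup_catalog <- function(catalog, query) {
  if (nrow(catalog) == 0L) return(catalog)
  q <- tolower(query)
  hit <- grepl(q, tolower(catalog$organism), fixed = TRUE) |
    grepl(q, tolower(catalog$accession), fixed = TRUE)
  catalog[hit, , drop = FALSE]
}

#' Export a catalog as TSV
#'
#' @param catalog tibble from [emit_catalog()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
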
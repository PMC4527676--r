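# End-to-end workflows composing the stages, with a reproducibility manifest.

# Re-throw any stage error with the stage name attached, so a failing run
# names the stage that aborted it.
#' @noRd
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                 class = c("globinkit_stage_error", "globinkit_error"),
                 parent = e)
  })
}

#' Run the sequence workflow
#'
#' Composes the sequence stages on one gapped MSA: fold-check every
#' candidate against the reference, scan each ungapped sequence for tandem
#' globin domains, reduce redundancy at an identity threshold, and build a
#' bootstrapped neighbor-joining tree from Poisson-corrected distances on
#' the kept sequences. All outputs are written as plain text (TSV, FASTA,
#' Newick) plus a JSON run manifest.
#'
#' @param msa Gapped MSA: a [struct_alignment()] with rows, a path or FASTA
#'   text, or a named character vector.
#' @param out_dir Output directory (created if needed).
#' @param reference_id Fold reference member; when absent from the MSA the
#'   shipped myoglobin reference is added for the fold stage.
#' @param threshold_pct Redundancy threshold (percent identity).
#' @param replicates Bootstrap replicates.
#' @param seed Seed governing all randomness in the run.
#' @param strict_fold Use the strict fold rule (see [check_mb_fold()]).
#' @return Invisibly, a list with `fold_report`, `domain_calls`, `kept_ids`,
#'   `tree`, and `manifest_path`.
#' @export
run_sequence_workflow <- function(msa, out_dir,
                                  reference_id = "spermwhale_Mb",
                                  threshold_pct = 90, replicates = 100,
                                  seed = 1, strict_fold = FALSE) {
  aln <- with_stage("input", {
    if (inherits(msa, "struct_alignment")) msa
    else if (is.character(msa) && !is.null(names(msa))) {
      struct_alignment_from_rows(msa)
    } else {
      read_gapped_alignment(msa)
    }
  })
  if (is.null(aln$rows)) {
    abort_globinkit("sequence workflow: alignment must carry sequence rows",
                    "globinkit_bad_input")
  }
  if (length(aln$member_ids) == 0 || n_columns(aln) == 0) {
    abort_globinkit("sequence workflow: empty alignment", "globinkit_empty_input")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- fold stage: each member vs the reference -----------------------------
  has_ref <- reference_id %in% aln$member_ids
  fold_report <- with_stage("fold_check", purrr::map_dfr(
    setdiff(aln$member_ids, reference_id),
    function(id) {
      sub <- if (has_ref) {
        pair_alignment(aln, reference_id, id)
      } else {
        align_to_reference(aln$rows[[id]], id, reference_id)
      }
      res <- tryCatch(
        check_mb_fold(sub, reference_id = reference_id, candidate_id = id,
                      strict = strict_fold),
        error = function(e) NULL
      )
      if (is.null(res)) {
        return(tibble::tibble(candidate_id = id, verdict = NA, f8_his = NA,
                              helices_present = NA_character_,
                              hydrophobic_fraction = NA_real_,
                              fugue_z = NA_real_))
      }
      glance(res)
    }
  ))
  write_tsv_file(fold_report, file.path(out_dir, "fold_report.tsv"))

  # --- domain stage ---------------------------------------------------------
  ungapped <- gsub("[-.]", "", aln$rows)
  domain_calls <- with_stage("domain_scan", purrr::imap_dfr(ungapped, function(s, id) {
    if (nchar(s) < nchar(mb_reference_sequence())) return(NULL)
    calls <- scan_domains(s)
    if (nrow(calls) == 0) return(NULL)
    dplyr::mutate(calls, id = id, .before = 1)
  }))
  if (nrow(domain_calls) == 0) {
    domain_calls <- tibble::tibble(id = character(), start = integer(),
                                   end = integer(), score = numeric(),
                                   f8_his = logical())
  }
  write_tsv_file(domain_calls, file.path(out_dir, "domain_calls.tsv"))
  split_records <- purrr::map_dfr(unique(domain_calls$id), function(id) {
    calls <- domain_calls[domain_calls$id == id, ]
    split_domains(stats::setNames(ungapped[[id]], id), calls)
  })
  if (nrow(split_records) > 0) {
    writeLines(write_fasta(split_records), file.path(out_dir, "domains.fasta"))
  }

  # --- redundancy stage -----------------------------------------------------
  idm <- with_stage("redundancy", build_identity_matrix(aln))
  kept <- with_stage("redundancy", reduce_redundancy(idm, threshold_pct))
  writeLines(kept, file.path(out_dir, "kept_ids.txt"))
  writeLines(write_fasta(stats::setNames(aln$rows[kept], kept)),
             file.path(out_dir, "reduced.fasta"))

  # --- tree stage -----------------------------------------------------------
  tree <- NULL
  if (length(kept) >= 4) {
    tree <- with_stage("nj_tree", bootstrap_support(
      aln$rows[kept], replicates = replicates, seed = seed))
    writeLines(write_newick(tree), file.path(out_dir, "tree.nwk"))
  }

  manifest_path <- write_manifest(
    out_dir, stage = "sequence",
    params = list(reference_id = reference_id, threshold_pct = threshold_pct,
                  replicates = replicates, seed = seed,
                  strict_fold = strict_fold),
    outputs = c("fold_report.tsv", "domain_calls.tsv", "kept_ids.txt",
                "reduced.fasta", if (!is.null(tree)) "tree.nwk")
  )
  invisible(list(fold_report = fold_report, domain_calls = domain_calls,
                 kept_ids = kept, tree = tree, manifest_path = manifest_path))
}

#' Run the structure workflow
#'
#' Composes the structure stages for two or more C-alpha traces: pairwise
#' per-site dRMSD profiles against a chosen target, the column-wise average
#' over the query structures, a per-pair summary (aligned length and
#' overall RMSD), and least-squares superposition transforms. When no
#' summary alignment is supplied a structure-guided fallback alignment is
#' built (and recorded as such in the manifest).
#'
#' @param traces List of [coord_trace()] objects.
#' @param out_dir Output directory.
#' @param aln Optional [struct_alignment()] over the traces' structure ids;
#'   if `NULL` a [structure_guided_alignment()] is computed.
#' @param target Structure id profiles are computed against; default the
#'   last trace.
#' @param seed Seed recorded in the manifest (the stage itself is
#'   deterministic).
#' @return Invisibly, a list with `profiles` (named list of
#'   `site_profile`s), `average`, `summary`, `superpositions`,
#'   `manifest_path`.
#' @export
run_structure_workflow <- function(traces, out_dir, aln = NULL,
                                   target = NULL, seed = 1) {
  if (length(traces) < 2) {
    abort_globinkit("structure workflow: need at least 2 structures",
                    "globinkit_bad_input")
  }
  ids <- vapply(traces, function(t) t$structure_id, character(1))
  names(traces) <- ids
  fallback <- is.null(aln)
  if (fallback) aln <- structure_guided_alignment(traces)
  if (is.null(target)) target <- ids[[length(ids)]]
  queries <- setdiff(ids, target)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  dists <- purrr::map(traces, intra_distances)
  profiles <- purrr::map(queries, function(q) {
    per_site_drmsd(dists[[q]], dists[[target]], aln)
  })
  names(profiles) <- queries
  for (q in queries) {
    write_tsv_file(tidy(profiles[[q]]),
                   file.path(out_dir, sprintf("profile_%s_vs_%s.tsv", q, target)))
  }
  average <- NULL
  if (length(profiles) >= 2) {
    average <- purrr::reduce(profiles, average_profiles)
    write_tsv_file(tidy(average),
                   file.path(out_dir, sprintf("profile_average_vs_%s.tsv", target)))
  }
  summary_tbl <- purrr::map_dfr(profiles, glance)
  write_tsv_file(summary_tbl, file.path(out_dir, "summary.tsv"))

  superpositions <- purrr::map(queries, function(q) {
    tryCatch(superpose(traces[[target]], traces[[q]], aln),
             error = function(e) NULL)
  })
  names(superpositions) <- queries
  sup_tbl <- purrr::imap_dfr(superpositions, function(s, q) {
    if (is.null(s)) return(NULL)
    tibble::tibble(
      query = q, target = target,
      coordinate_rmsd = s$coordinate_rmsd, n_pairs = s$n_pairs,
      rotation = paste(sprintf("%.6f", t(s$rotation)), collapse = ","),
      translation = paste(sprintf("%.6f", s$translation), collapse = ",")
    )
  })
  write_tsv_file(sup_tbl, file.path(out_dir, "superpositions.tsv"))

  manifest_path <- write_manifest(
    out_dir, stage = "structure",
    params = list(target = target, seed = seed,
                  alignment = if (fallback) "structure-guided fallback"
                  else "supplied"),
    outputs = c(sprintf("profile_%s_vs_%s.tsv", queries, target),
                if (!is.null(average)) sprintf("profile_average_vs_%s.tsv", target),
                "summary.tsv", "superpositions.tsv")
  )
  invisible(list(profiles = profiles, average = average,
                 summary = summary_tbl, superpositions = superpositions,
                 manifest_path = manifest_path))
}

#' @noRd
struct_alignment_from_rows <- function(rows) {
  read_gapped_alignment(write_fasta(rows))
}

#' Restrict an alignment to two members
#' @noRd
pair_alignment <- function(aln, a, b) {
  ords <- aln$ordinals[, c(a, b), drop = FALSE]
  struct_alignment(ords, rows = aln$rows[c(a, b)])
}

#' Align one ungapped candidate to the shipped myoglobin reference
#' @noRd
align_to_reference <- function(row, id, reference_id = "spermwhale_Mb") {
  cand <- gsub("[-.]", "", row)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(mb_reference_sequence()),
    subject = Biostrings::AAString(cand),
    type = "global", substitutionMatrix = blosum62_matrix(),
    gapOpening = 11, gapExtension = 1
  )
  rows <- stats::setNames(
    c(as.character(Biostrings::alignedPattern(pa)),
      as.character(Biostrings::alignedSubject(pa))),
    c(reference_id, id)
  )
  struct_alignment_from_rows(rows)
}

#' @noRd
write_tsv_file <- function(df, path) {
  if (is.null(df) || nrow(df) == 0) {
    df <- df %||% tibble::tibble()
  }
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.4f", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
write_manifest <- function(out_dir, stage, params, outputs) {
  outputs <- outputs[file.exists(file.path(out_dir, outputs))]
  digests <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(digests) <- outputs
  manifest <- list(
    tool = "globinkit",
    version = as.character(utils::packageVersion("globinkit")),
    stage = stage,
    parameters = params,
    output_digests = digests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}
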
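#' Run the full RBP classification pipeline
#'
#' Chains every stage: record validation, prophage-activity and rough-host
#' metadata filters, anchor/RBD delineation, within-serogroup redundancy
#' removal, all-vs-all RBD hit search, single-linkage subtype clustering,
#' within-genus redundancy removal (with re-clustering of the kept set),
#' serogroup assignment, the genus filter, the conservation-checked dataset
#' ledger and - when nucleotide sequences are available - the flanking
#' motif scan.
#'
#' @param records An RBP record tibble (see [read_rbp_dataset()]).
#' @param cfg An [rbp_config()].
#' @param curated Optional curated boundary table for
#'   [delineate_domains()].
#' @param allow_ambiguous Passed to [filter_prophages()].
#' @param scan_motifs Run the motif scan when nucleotide sequences are
#'   present? Default `TRUE`.
#' @param seed Seed for the motif permutation test.
#' @return An object of class `rbp_pipeline`: list with `records`
#'   (post-filter input), `delineations`, `hits`, `subtypes_all`
#'   (pre-dedupe partition), `kept` (post-dedupe records), `subtypes`
#'   (post-dedupe partition), `assignments`, `final`, `ledger`, `motifs`,
#'   `cfg`.
#' @examples
#' sim <- simulate_rbp_dataset(sim_config(n_genera = 3, n_per_genus = 2,
#'                                        n_families = 3, n_redundant = 0,
#'                                        n_decoys = 0, n_unknown = 0),
#'                             seed = 1)
#' res <- run_rbp_pipeline(sim$records, scan_motifs = FALSE)
#' res$ledger
#' @export
run_rbp_pipeline <- function(records, cfg = rbp_config(), curated = NULL,
                             allow_ambiguous = FALSE, scan_motifs = TRUE,
                             seed = 1L) {
  cfg <- as_rbp_config(cfg)
  records <- validate_rbp_records(records)
  records <- filter_prophages(records, cfg, allow_ambiguous)
  records <- filter_rough_hosts(records, cfg)

  delineations <- delineate_domains(records, cfg, curated = curated)
  deduped <- dedupe_same_serogroup(records, cfg)
  hits <- rbd_hits(deduped, delineations, cfg)
  subtypes_all <- cluster_subtypes(deduped, hits)
  kept <- dedupe_within_genus(deduped, subtypes_all)
  hits_kept <- hits[hits$query_id %in% kept$rbp_id &
                      hits$subject_id %in% kept$rbp_id, , drop = FALSE]
  subtypes <- cluster_subtypes(kept, hits_kept)

  assignments <- assign_serogroups(kept, subtypes, cfg)
  final <- genus_filter(kept, subtypes, assignments, cfg)
  ledger <- build_ledger(kept, subtypes, assignments, final)

  motifs <- NULL
  if (scan_motifs && any(!is.na(kept$nt_sequence))) {
    motifs <- find_flank_motifs(kept, delineations, cfg, seed = seed)
  }

  structure(list(
    records = records, delineations = delineations, hits = hits,
    subtypes_all = subtypes_all, kept = kept, subtypes = subtypes,
    assignments = assignments, final = final, ledger = ledger,
    motifs = motifs, cfg = cfg
  ), class = "rbp_pipeline")
}

#' @export
print.rbp_pipeline <- function(x, ...) {
  cat("<rbp_pipeline>\n")
  cat(sprintf("  %d records -> %d after redundancy removal\n",
              nrow(x$records), nrow(x$kept)))
  cat(sprintf("  %d subtypes (%d before within-genus dedupe)\n",
              length(unique(x$subtypes$subtype_id)),
              length(unique(x$subtypes_all$subtype_id))))
  t <- x$ledger$totals
  cat(sprintf("  assigned %d subtypes / %d RBPs; final %d RBPs\n",
              t$n_assigned_subtypes, t$n_assigned_rbps, t$n_final_rbps))
  if (!is.null(x$motifs)) {
    cat(sprintf("  %d conserved flanking motifs\n", nrow(x$motifs)))
  }
  invisible(x)
}

#' Tidy a pipeline result
#'
#' One row per RBP subtype with its assignment outcome, in the spirit of
#' broom: `tidy()` gives the per-subtype table, `glance()` a one-row model
#' summary of the run.
#'
#' @param x An `rbp_pipeline` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy rbp_pipeline
#' @export
tidy.rbp_pipeline <- function(x, ...) {
  a <- x$assignments
  tibble(
    subtype_id = a$subtype_id,
    n_members = a$n_members,
    n_known = a$n_known,
    n_genera = vapply(a$genera_present, length, integer(1)),
    assigned_serogroup = a$assigned_serogroup,
    assignment_basis = a$assignment_basis,
    rejection_reason = a$rejection_reason
  )
}

#' @rdname tidy.rbp_pipeline
#' @method glance rbp_pipeline
#' @export
glance.rbp_pipeline <- function(x, ...) {
  dplyr::bind_cols(x$ledger$totals,
                   tibble(n_input_records = nrow(x$records)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
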
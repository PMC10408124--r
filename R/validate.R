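#' Assign a host serogroup to every RBP subtype
#'
#' Applies the two assignment criteria per subtype: (i) if a member carries
#' experimental serogroup evidence at the RBP level (group A) its serogroup
#' is assigned to the whole subtype; failing that, phage-level evidence
#' (group B) is used the same way. (ii) Otherwise the known host serogroups
#' of the members - including the retained votes of removed duplicates
#' ("doubles") - are tallied: with fewer than `consensus_min_known` known
#' votes the subtype is rejected for lack of data; if the modal serogroup
#' reaches `consensus_fraction` of the known votes it is assigned by
#' consensus; otherwise the subtype is rejected as inconsistent. A tie for
#' the modal serogroup is inconsistent. Conflicting experimental members
#' with different serogroups are a data contradiction and raise an error.
#'
#' @param records An RBP record tibble (post-deduplication, so that
#'   `double_serogroups` votes are present if any).
#' @param subtypes Partition from [cluster_subtypes()].
#' @param cfg An [rbp_config()].
#' @return One row per subtype: `subtype_id`, `n_members`, `n_known`
#'   (known serogroup votes incl. doubles), `assigned_serogroup`,
#'   `assignment_basis` (`"experimental_rbp"`, `"experimental_phage"`,
#'   `"consensus"`, `"none"`), `rejection_reason` (`"none"`,
#'   `"inconsistent"`, `"insufficient_data"`), plus list-columns
#'   `member_rbp_ids`, `genera_present`, `serogroups_observed`.
#' @export
assign_serogroups <- function(records, subtypes, cfg = rbp_config()) {
  cfg <- as_rbp_config(cfg)
  records <- ensure_doubles_col(records)
  st <- subtypes$subtype_id[match(records$rbp_id, subtypes$rbp_id)]
  if (any(is.na(st))) stop("subtypes must cover all records")
  out <- lapply(sort(unique(st)), function(s) {
    m <- records[st == s, , drop = FALSE]
    assign_one_subtype(s, m, cfg)
  })
  dplyr::bind_rows(out)
}

assign_one_subtype <- function(subtype_id, members, cfg) {
  votes <- c(members$host_serogroup,
             unlist(members$double_serogroups, use.names = FALSE))
  votes <- votes[!is.na(votes)]
  res <- list(serogroup = NA_character_, basis = "none", reason = "none")

  exp_assign <- function(level, basis) {
    sel <- !is.na(members$serogroup_evidence) &
      members$serogroup_evidence == level
    if (!any(sel)) return(NULL)
    sgs <- unique(members$host_serogroup[sel])
    if (length(sgs) > 1) {
      stop("conflicting ", level, " serogroups in subtype ", subtype_id,
           ": ", paste(sgs, collapse = ", "))
    }
    list(serogroup = sgs, basis = basis, reason = "none")
  }

  hit <- exp_assign("rbp_level", "experimental_rbp")
  if (is.null(hit)) hit <- exp_assign("phage_level", "experimental_phage")
  if (!is.null(hit)) {
    res <- hit
  } else if (length(votes) < cfg$consensus_min_known) {
    res$reason <- "insufficient_data"
  } else {
    tab <- table(votes)
    top <- max(tab)
    modal <- names(tab)[tab == top]
    if (length(modal) > 1 || top / length(votes) < cfg$consensus_fraction) {
      res$reason <- "inconsistent"
    } else {
      res <- list(serogroup = modal, basis = "consensus", reason = "none")
    }
  }

  tibble(
    subtype_id = subtype_id,
    n_members = nrow(members),
    n_known = length(votes),
    assigned_serogroup = res$serogroup,
    assignment_basis = res$basis,
    rejection_reason = res$reason,
    member_rbp_ids = list(members$rbp_id),
    genera_present = list(sort(unique(members$genus))),
    serogroups_observed = list(votes)
  )
}

#' Filter to genera with enough serogroup-specific RBPs
#'
#' A genus only enters the final dataset if it contributes at least
#' `genus_min_specific_rbps` serogroup-assigned RBPs; assigned RBPs in
#' thinner genera are omitted, and unassigned RBPs are excluded already.
#'
#' @param records An RBP record tibble.
#' @param subtypes Partition from [cluster_subtypes()].
#' @param assignments Result of [assign_serogroups()].
#' @param cfg An [rbp_config()].
#' @return The final record tibble with an `assigned_serogroup` column;
#'   assigned-but-omitted rows in `attr(, "dropped")`, per-genus assigned
#'   counts in `attr(, "genus_counts")`.
#' @export
genus_filter <- function(records, subtypes, assignments,
                         cfg = rbp_config()) {
  cfg <- as_rbp_config(cfg)
  st <- subtypes$subtype_id[match(records$rbp_id, subtypes$rbp_id)]
  asg <- assignments$assigned_serogroup[match(st, assignments$subtype_id)]
  assigned <- !is.na(asg)
  counts <- table(records$genus[assigned])
  good_genus <- names(counts)[counts >= cfg$genus_min_specific_rbps]
  keep <- assigned & records$genus %in% good_genus
  out <- records[keep, , drop = FALSE]
  out$assigned_serogroup <- asg[keep]
  dropped <- records[assigned & !keep, "rbp_id", drop = FALSE]
  dropped$reason <- "genus_below_min_specific_rbps"
  attr(out, "dropped") <- as_tibble(dropped)
  attr(out, "genus_counts") <-
    tibble(genus = names(counts), n_assigned = as.integer(counts))
  out
}

#' Dataset accounting ledger
#'
#' Tallies the dataset at every stage - per-evidence-group counts with
#' K-antigen outgroup records counted separately, subtype totals by
#' assignment outcome, and the final post-genus-filter set - and verifies
#' conservation: every record lands in exactly one terminal category and
#' the category counts telescope to the total. A violation is a hard error.
#'
#' @param records The record tibble entering clustering.
#' @param subtypes Partition from [cluster_subtypes()].
#' @param assignments Result of [assign_serogroups()].
#' @param final_records Result of [genus_filter()].
#' @return A list of class `rbp_ledger`: `group_counts`, `totals`,
#'   `genus_counts`, `record_categories`.
#' @export
build_ledger <- function(records, subtypes, assignments, final_records) {
  st <- subtypes$subtype_id[match(records$rbp_id, subtypes$rbp_id)]
  row <- match(st, assignments$subtype_id)
  reason <- assignments$rejection_reason[row]
  assigned <- assignments$rejection_reason[row] == "none"
  in_final <- records$rbp_id %in% final_records$rbp_id

  category <- dplyr::case_when(
    in_final ~ "final",
    assigned & !in_final ~ "assigned_omitted_by_genus_filter",
    reason == "inconsistent" ~ "rejected_inconsistent",
    reason == "insufficient_data" ~ "rejected_insufficient_data",
    TRUE ~ NA_character_
  )
  if (any(is.na(category))) {
    stop("ledger conservation violation: uncategorized records: ",
         paste(records$rbp_id[is.na(category)], collapse = ", "))
  }
  cat_counts <- table(category)
  if (sum(cat_counts) != nrow(records)) {
    stop("ledger conservation violation: category counts do not telescope")
  }

  is_outgroup <- !is.na(records$host_serogroup) &
    grepl("^K", records$host_serogroup)
  grp <- factor(records$evidence_group, levels = LETTERS[1:6])
  group_counts <- tibble(
    evidence_group = LETTERS[1:6],
    n = as.integer(table(grp[!is_outgroup])),
    n_outgroup = as.integer(table(grp[is_outgroup]))
  )

  totals <- tibble(
    n_records = nrow(records),
    n_subtypes = nrow(assignments),
    n_assigned_subtypes = sum(assignments$rejection_reason == "none"),
    n_assigned_rbps = sum(assigned),
    n_inconsistent_subtypes =
      sum(assignments$rejection_reason == "inconsistent"),
    n_inconsistent_rbps = sum(reason == "inconsistent"),
    n_insufficient_subtypes =
      sum(assignments$rejection_reason == "insufficient_data"),
    n_insufficient_rbps = sum(reason == "insufficient_data"),
    n_final_rbps = sum(in_final),
    n_omitted_by_genus_filter = sum(assigned & !in_final)
  )
  stopifnot(totals$n_assigned_subtypes + totals$n_inconsistent_subtypes +
              totals$n_insufficient_subtypes == totals$n_subtypes)

  structure(list(
    group_counts = group_counts,
    totals = totals,
    genus_counts = attr(final_records, "genus_counts"),
    record_categories = tibble(rbp_id = records$rbp_id, category = category)
  ), class = "rbp_ledger")
}

#' @export
print.rbp_ledger <- function(x, ...) {
  cat("<rbp_ledger>\n")
  t <- x$totals
  cat(sprintf("  %d RBPs in %d subtypes\n", t$n_records, t$n_subtypes))
  cat(sprintf("  assigned: %d subtypes / %d RBPs; inconsistent: %d / %d; insufficient: %d / %d\n",
              t$n_assigned_subtypes, t$n_assigned_rbps,
              t$n_inconsistent_subtypes, t$n_inconsistent_rbps,
              t$n_insufficient_subtypes, t$n_insufficient_rbps))
  cat(sprintf("  final after genus filter: %d RBPs (%d omitted)\n",
              t$n_final_rbps, t$n_omitted_by_genus_filter))
  invisible(x)
}
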
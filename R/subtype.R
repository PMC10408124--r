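#' Cluster RBPs into subtypes by single linkage
#'
#' RBP subtypes are the connected components of the graph whose vertices are
#' the records and whose edges are the passing RBD hits: any chain of
#' horizontal-transfer links merges clusters (single linkage), and records
#' without any passing hit form singleton subtypes. The subtype id is the
#' lexicographically smallest member id, so the partition is deterministic
#' and invariant to input order.
#'
#' @param records An RBP record tibble.
#' @param hits Hit tibble from [rbd_hits()] (only rows with `passes` are
#'   used as edges).
#' @return Tibble `rbp_id`, `subtype_id`, in the input record order.
#' @export
cluster_subtypes <- function(records, hits) {
  ids <- records$rbp_id
  edges <- hits[hits$passes, c("query_id", "subject_id"), drop = FALSE]
  edges <- edges[edges$query_id %in% ids & edges$subject_id %in% ids, ]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  subtype_of <- stats::ave(names(comp), comp, FUN = function(v) min(v))
  tibble(rbp_id = ids,
         subtype_id = subtype_of[match(ids, names(comp))])
}

# Keep-priority ordering shared by both redundancy rules: higher prophage
# score first, then stronger evidence group (A strongest), then longer
# sequence, then smaller id.
keep_priority_order <- function(records) {
  score <- ifelse(is.na(records$prophage_score), -Inf,
                  records$prophage_score)
  grp <- ifelse(is.na(records$evidence_group), "Z", records$evidence_group)
  order(-score, grp, -nchar(records$aa_sequence), records$rbp_id)
}

#' Collapse near-duplicate RBPs within a serogroup
#'
#' Within each group of records sharing a (known) host serogroup, records
#' that are at least `redundancy_identity` percent identical over their full
#' length to an already-kept record are removed, keeping the record with the
#' highest prophage score (then strongest evidence group, longest sequence,
#' smallest id). The serogroups of removed records are retained as votes on
#' their representative in the `double_serogroups` list-column, so the
#' consensus step still sees them.
#'
#' @param records An RBP record tibble.
#' @param cfg An [rbp_config()].
#' @return Kept records with a `double_serogroups` list-column; removed rows
#'   are recorded in `attr(, "dropped")`.
#' @export
dedupe_same_serogroup <- function(records, cfg = rbp_config()) {
  cfg <- as_rbp_config(cfg)
  records <- ensure_doubles_col(records)
  keep <- rep(TRUE, nrow(records))
  rep_of <- stats::setNames(records$rbp_id, records$rbp_id)
  for (sg in unique(stats::na.omit(records$host_serogroup))) {
    idx <- which(records$host_serogroup %in% sg)
    if (length(idx) < 2) next
    ord <- idx[rank_within(records, idx)]
    kept <- integer(0)
    for (i in ord) {
      dup <- FALSE
      for (k in kept) {
        aln <- align_pair(records$aa_sequence[i], records$aa_sequence[k],
                          cfg, "global")
        if (aln$identity_pct >= cfg$redundancy_identity) {
          dup <- TRUE
          rep_of[records$rbp_id[i]] <- records$rbp_id[k]
          break
        }
      }
      if (dup) keep[i] <- FALSE else kept <- c(kept, i)
    }
  }
  collapse_records(records, keep, rep_of, "redundant_same_serogroup")
}

rank_within <- function(records, idx) {
  sub <- records[idx, , drop = FALSE]
  keep_priority_order(sub)
}

ensure_doubles_col <- function(records) {
  if (!"double_serogroups" %in% names(records)) {
    records$double_serogroups <- vector("list", nrow(records))
  }
  records
}

collapse_records <- function(records, keep, rep_of, reason) {
  for (i in which(!keep)) {
    k <- which(records$rbp_id == rep_of[records$rbp_id[i]])
    votes <- c(records$double_serogroups[[k]],
               records$host_serogroup[i], records$double_serogroups[[i]])
    records$double_serogroups[[k]] <- votes[!is.na(votes)]
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "dropped") <- tibble(
    rbp_id = records$rbp_id[!keep],
    representative = unname(rep_of[records$rbp_id[!keep]]),
    reason = rep(reason, sum(!keep))
  )
  out
}

#' Keep one representative per subtype within each genus
#'
#' Within every (subtype, genus) cell, a single representative survives,
#' chosen by the same keep-priority as [dedupe_same_serogroup()]. Host
#' serogroups of removed members are kept as votes on the representative.
#'
#' @param records An RBP record tibble.
#' @param subtypes Partition from [cluster_subtypes()].
#' @return Kept records with updated `double_serogroups`; removed rows in
#'   `attr(, "dropped")`.
#' @export
dedupe_within_genus <- function(records, subtypes) {
  records <- ensure_doubles_col(records)
  st <- subtypes$subtype_id[match(records$rbp_id, subtypes$rbp_id)]
  if (any(is.na(st))) stop("subtypes must cover all records")
  cell <- paste(st, records$genus, sep = "\r")
  keep <- rep(TRUE, nrow(records))
  rep_of <- stats::setNames(records$rbp_id, records$rbp_id)
  for (cl in unique(cell)) {
    idx <- which(cell == cl)
    if (length(idx) < 2) next
    ord <- idx[rank_within(records, idx)]
    winner <- ord[1]
    for (i in ord[-1]) {
      keep[i] <- FALSE
      rep_of[records$rbp_id[i]] <- records$rbp_id[winner]
    }
  }
  collapse_records(records, keep, rep_of, "redundant_within_genus")
}
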
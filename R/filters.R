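#' Filter prophage records by activity score
#'
#' Keeps prophage records whose prediction score marks them as active
#' (score strictly above `prophage_active_score`). Scores inside the
#' ambiguous band `[prophage_ambiguous_floor, prophage_active_score]` are
#' kept only when `allow_ambiguous = TRUE` and flagged as such; lower scores
#' are dropped. Records from free phages pass untouched. Prophage records
#' without a score are dropped with a warning.
#'
#' @param records An RBP record tibble.
#' @param cfg An [rbp_config()].
#' @param allow_ambiguous Keep ambiguous-score prophages? Default `FALSE`.
#' @return The kept records with an added `prophage_status` column
#'   (`"active"`, `"ambiguous"`, or `NA` for free phages). Dropped rows are
#'   recorded in `attr(, "dropped")` as a tibble of `rbp_id` + `reason`.
#' @export
filter_prophages <- function(records, cfg = rbp_config(),
                             allow_ambiguous = FALSE) {
  cfg <- as_rbp_config(cfg)
  is_pro <- records$source == "prophage"
  score <- records$prophage_score
  status <- rep(NA_character_, nrow(records))
  status[is_pro & !is.na(score) & score > cfg$prophage_active_score] <- "active"
  amb <- is_pro & !is.na(score) &
    score >= cfg$prophage_ambiguous_floor &
    score <= cfg$prophage_active_score
  status[amb] <- "ambiguous"

  reason <- rep(NA_character_, nrow(records))
  reason[is_pro & is.na(score)] <- "prophage_score_missing"
  reason[is_pro & !is.na(score) & score < cfg$prophage_ambiguous_floor] <-
    "prophage_score_below_floor"
  if (!allow_ambiguous) reason[amb] <- "prophage_score_ambiguous"

  if (any(reason == "prophage_score_missing", na.rm = TRUE)) {
    warning("dropping prophage records without a score: ",
            paste(records$rbp_id[which(reason == "prophage_score_missing")],
                  collapse = ", "))
  }
  keep <- is.na(reason)
  out <- records[keep, , drop = FALSE]
  out$prophage_status <- status[keep]
  attr(out, "dropped") <- tibble(rbp_id = records$rbp_id[!keep],
                                 reason = reason[!keep])
  out
}

#' Remove phages of rough laboratory host strains
#'
#' Rough strains lack the O-antigen, so a phage isolated on one carries no
#' serogroup signal. Records whose host strain label matches the blocklist
#' (case-insensitive exact match) are removed; records with an empty or
#' unknown host strain pass.
#'
#' @inheritParams filter_prophages
#' @return Kept records, with dropped rows in `attr(, "dropped")`.
#' @export
filter_rough_hosts <- function(records, cfg = rbp_config()) {
  cfg <- as_rbp_config(cfg)
  strain <- records$host_strain
  blocked <- !is.na(strain) & strain != "" &
    tolower(strain) %in% tolower(cfg$rough_strain_blocklist)
  out <- records[!blocked, , drop = FALSE]
  attr(out, "dropped") <- tibble(rbp_id = records$rbp_id[blocked],
                                 reason = rep("rough_host_strain", sum(blocked)))
  out
}
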
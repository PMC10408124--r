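#' Split RBPs into anchor and receptor-binding domain
#'
#' Assigns every record an anchor/RBD boundary using, in priority order:
#' a curated boundary (from the `curated` table or the record's
#' `curated_anchor_end` field), a data-driven conservation breakpoint
#' computed within each genus, and finally the tentative default cutoff
#' (150 aa). Coordinates are 1-based inclusive: the anchor spans positions
#' `1..anchor_end` and the RBD `anchor_end + 1 .. L`. Records flagged
#' `split_rbp` (RBP architectures where anchor and RBD are separate
#' proteins and the stored sequence is the RBD protein) get
#' `anchor_end = 0`.
#'
#' @param records An RBP record tibble.
#' @param cfg An [rbp_config()].
#' @param curated Optional tibble/data frame with columns `rbp_id`,
#'   `anchor_end` of curated boundaries; takes precedence over everything
#'   except the `split_rbp` flag.
#' @param use_breakpoint Compute per-genus conservation breakpoints for
#'   records without a curated boundary? Default `TRUE`.
#' @return A tibble with one row per record: `rbp_id`, `anchor_end`,
#'   `method` (`"curated"`, `"breakpoint"`, `"default_cutoff"`),
#'   `confidence` in `[0, 1]`.
#' @examples
#' rec <- tibble::tibble(rbp_id = "r1", genus = "g",
#'                       aa_sequence = strrep("ACDEFGHIKL", 60),
#'                       split_rbp = FALSE)
#' delineate_domains(rec, use_breakpoint = FALSE)
#' @export
delineate_domains <- function(records, cfg = rbp_config(), curated = NULL,
                              use_breakpoint = TRUE) {
  cfg <- as_rbp_config(cfg)
  records <- as_tibble(records)
  n <- nrow(records)
  L <- nchar(records$aa_sequence)
  anchor_end <- rep(NA_integer_, n)
  method <- rep(NA_character_, n)
  confidence <- rep(NA_real_, n)

  # curated boundaries: explicit table first, then the metadata field
  cur <- rep(NA_integer_, n)
  if (!is.null(curated)) {
    stopifnot(all(c("rbp_id", "anchor_end") %in% names(curated)))
    cur <- as.integer(curated$anchor_end[match(records$rbp_id,
                                               curated$rbp_id)])
  }
  if ("curated_anchor_end" %in% names(records)) {
    cur <- ifelse(is.na(cur), records$curated_anchor_end, cur)
  }

  split <- if ("split_rbp" %in% names(records)) {
    records$split_rbp %in% TRUE
  } else rep(FALSE, n)
  anchor_end[split] <- 0L
  method[split] <- "curated"
  confidence[split] <- 1

  has_cur <- !split & !is.na(cur)
  if (any(cur[has_cur] >= L[has_cur])) {
    stop("curated anchor_end at or beyond sequence length for: ",
         paste(records$rbp_id[has_cur][cur[has_cur] >= L[has_cur]],
               collapse = ", "))
  }
  anchor_end[has_cur] <- cur[has_cur]
  method[has_cur] <- "curated"
  confidence[has_cur] <- 1

  todo <- is.na(anchor_end)
  if (use_breakpoint && any(todo)) {
    for (g in unique(records$genus[todo])) {
      idx <- which(todo & records$genus == g)
      grp <- which(records$genus == g)  # profile uses all genus members
      if (length(grp) < 3) {
        warning("genus ", g, " has < 3 records; using default cutoff")
        next
      }
      bp <- genus_breakpoints(records[grp, , drop = FALSE], cfg)
      hit <- match(records$rbp_id[idx], bp$rbp_id)
      ok <- !is.na(bp$anchor_end[hit])
      anchor_end[idx[ok]] <- bp$anchor_end[hit][ok]
      method[idx[ok]] <- "breakpoint"
      confidence[idx[ok]] <- bp$confidence[hit][ok]
    }
  }

  todo <- is.na(anchor_end)
  if (any(todo)) {
    short <- todo & (L <= cfg$default_anchor_cutoff + 10L)
    if (any(short)) {
      stop("sequence too short for default cutoff: ",
           paste(records$rbp_id[short], collapse = ", "))
    }
    anchor_end[todo] <- cfg$default_anchor_cutoff
    method[todo] <- "default_cutoff"
    confidence[todo] <- 0.5
  }

  stopifnot(all(anchor_end >= 0), all(anchor_end < L),
            all(L - anchor_end >= 10))
  tibble(rbp_id = records$rbp_id, anchor_end = as.integer(anchor_end),
         method = method, confidence = confidence)
}

# Conservation-profile breakpoint for one genus (>= 3 records).
# For each record, every position gets the fraction of same-genus partners
# identical to it at that position in a global (N-terminally anchored)
# pairwise alignment; the profile is smoothed with a running mean of width
# breakpoint_window. The anchor ends at the last smoothed value >= t_high
# before the profile first drops below t_low; no such drop (or no plateau)
# means no data-driven boundary and the caller falls back to the default.
genus_breakpoints <- function(records, cfg) {
  n <- nrow(records)
  ids <- records$rbp_id
  L <- nchar(records$aa_sequence)
  match_frac <- lapply(seq_len(n), function(i) numeric(L[i]))
  counts <- lapply(seq_len(n), function(i) numeric(L[i]))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      eq <- aligned_position_matches(records$aa_sequence[i],
                                     records$aa_sequence[j], cfg)
      match_frac[[i]][seq_along(eq$q)] <- match_frac[[i]][seq_along(eq$q)] + eq$q
      counts[[i]][seq_along(eq$q)] <- counts[[i]][seq_along(eq$q)] + 1
      match_frac[[j]][seq_along(eq$s)] <- match_frac[[j]][seq_along(eq$s)] + eq$s
      counts[[j]][seq_along(eq$s)] <- counts[[j]][seq_along(eq$s)] + 1
    }
  }
  res <- lapply(seq_len(n), function(i) {
    prof <- match_frac[[i]] / pmax(counts[[i]], 1)
    be <- profile_breakpoint(prof, cfg, L[i])
    tibble(rbp_id = ids[i], anchor_end = be$anchor_end,
           confidence = be$confidence)
  })
  dplyr::bind_rows(res)
}

# Per-position identity indicators for both sequences of one global
# alignment, in each sequence's own coordinates.
aligned_position_matches <- function(a, b, cfg) {
  submat <- protein_submat(cfg)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = submat,
                                      gapOpening = cfg$gap_open,
                                      gapExtension = cfg$gap_extend)
  pc <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sc <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  same <- pc == sc & pc != "-"
  list(q = same[pc != "-"], s = same[sc != "-"])
}

profile_breakpoint <- function(prof, cfg, L) {
  w <- cfg$breakpoint_window
  sm <- running_mean(prof, w)
  below <- which(sm < cfg$breakpoint_t_low)
  if (!length(below)) return(list(anchor_end = NA_integer_,
                                  confidence = NA_real_))
  first_drop <- below[1]
  plateau <- which(sm[seq_len(first_drop - 1)] >= cfg$breakpoint_t_high)
  if (!length(plateau)) return(list(anchor_end = NA_integer_,
                                    confidence = NA_real_))
  ae <- max(plateau)
  if (ae < 1 || L - ae < 10) return(list(anchor_end = NA_integer_,
                                         confidence = NA_real_))
  conf <- mean(prof[seq_len(ae)]) - mean(prof[seq(ae + 1, L)])
  list(anchor_end = as.integer(ae), confidence = max(0, min(1, conf)))
}

running_mean <- function(x, w) {
  n <- length(x)
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
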
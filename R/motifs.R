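#' Extract DNA flanks around the anchor/RBD boundary and downstream of the CDS
#'
#' For every record with a nucleotide sequence, cuts two windows: the
#' `boundary_flank`, +/- `flank_halfwidth` nt around the last nucleotide of
#' the anchor (position `3 * anchor_end` of the CDS), and the
#' `downstream_noncoding` window of up to `downstream_len` nt starting
#' right after the stop codon. Windows truncated by a sequence edge are
#' kept and flagged. Records without a nucleotide sequence are skipped with
#' a warning; records without any downstream sequence contribute no
#' downstream window.
#'
#' @param records An RBP record tibble with `nt_sequence`.
#' @param delineations Delineation tibble from [delineate_domains()].
#' @param cfg An [rbp_config()].
#' @return Tibble: `rbp_id`, `region`, `start`, `end` (1-based inclusive on
#'   the record's nt_sequence), `rel_start`, `rel_end` (relative to the
#'   boundary nucleotide or the stop codon), `seq`, `truncated`.
#' @export
extract_flanks <- function(records, delineations, cfg = rbp_config()) {
  cfg <- as_rbp_config(cfg)
  has_nt <- !is.na(records$nt_sequence)
  if (any(!has_nt)) {
    warning("records without nt_sequence skipped in flank extraction: ",
            paste(records$rbp_id[!has_nt], collapse = ", "))
  }
  records <- records[has_nt, , drop = FALSE]
  out <- lapply(seq_len(nrow(records)), function(i) {
    id <- records$rbp_id[i]
    nt <- records$nt_sequence[i]
    L <- nchar(nt)
    n_aa <- nchar(records$aa_sequence[i])
    ae <- delineations$anchor_end[delineations$rbp_id == id]
    if (!length(ae)) stop("missing delineation for ", id)
    rows <- list()

    centre <- 3L * ae
    lo <- centre - cfg$flank_halfwidth + 1L
    hi <- centre + cfg$flank_halfwidth
    lo_c <- max(1L, lo); hi_c <- min(L, hi)
    if (hi_c >= lo_c) {
      rows$boundary <- tibble(
        rbp_id = id, region = "boundary_flank",
        start = lo_c, end = hi_c,
        rel_start = lo_c - centre, rel_end = hi_c - centre,
        seq = substr(nt, lo_c, hi_c),
        truncated = (lo_c != lo) || (hi_c != hi)
      )
    }

    stop_end <- 3L * n_aa + 3L
    dlo <- stop_end + 1L
    dhi <- min(L, stop_end + cfg$downstream_len)
    if (dhi >= dlo) {
      rows$down <- tibble(
        rbp_id = id, region = "downstream_noncoding",
        start = dlo, end = dhi,
        rel_start = 1L, rel_end = dhi - stop_end,
        seq = substr(nt, dlo, dhi),
        truncated = dhi < stop_end + cfg$downstream_len
      )
    }
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}

#' Center-star multiple alignment of nucleotide windows
#'
#' Builds a multiple alignment by choosing the window with the greatest
#' summed pairwise global-alignment score against all others as the center
#' (ties broken by lexicographically smallest id, so the result does not
#' depend on input order) and merging the pairwise center alignments under
#' the "once a gap, always a gap" rule.
#'
#' @param windows Named character vector of DNA windows (>= 2), or a tibble
#'   with `rbp_id` and `seq` columns as produced by [extract_flanks()].
#' @param cfg An [rbp_config()].
#' @return Named character vector of equal-length aligned rows, class
#'   `star_msa`, with the center id in `attr(, "center")`.
#' @export
star_msa <- function(windows, cfg = rbp_config()) {
  cfg <- as_rbp_config(cfg)
  if (is.data.frame(windows)) {
    windows <- stats::setNames(windows$seq, windows$rbp_id)
  }
  stopifnot(length(windows) >= 2, !is.null(names(windows)))
  windows <- windows[order(names(windows))]
  n <- length(windows)
  submat <- dna_submat(cfg)
  score_mat <- matrix(0, n, n)
  set <- Biostrings::DNAStringSet(windows)
  for (j in seq(2, n)) {
    s <- Biostrings::pairwiseAlignment(
      set[seq_len(j - 1)], windows[j], type = "global",
      substitutionMatrix = submat, gapOpening = cfg$nt_gap_open,
      gapExtension = cfg$nt_gap_extend, scoreOnly = TRUE)
    score_mat[seq_len(j - 1), j] <- s
    score_mat[j, seq_len(j - 1)] <- s
  }
  centre <- which.max(rowSums(score_mat))  # first index = smallest id on ties
  c_seq <- windows[centre]
  others <- setdiff(seq_len(n), centre)

  Lc <- nchar(c_seq)
  ins <- integer(Lc + 1)          # master insertions before residue i
  parsed <- list()
  for (k in others) {
    pa <- Biostrings::pairwiseAlignment(
      c_seq, windows[k], type = "global", substitutionMatrix = submat,
      gapOpening = cfg$nt_gap_open, gapExtension = cfg$nt_gap_extend)
    cg <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    sg <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    blocks <- split_insertion_blocks(cg, sg, Lc)
    parsed[[as.character(k)]] <- blocks
    ins <- pmax(ins, blocks$ins)
  }

  rows <- character(n)
  rows[centre] <- paste(unlist(lapply(seq_len(Lc + 1), function(i) {
    c(rep("-", ins[i]), if (i <= Lc) substr(c_seq, i, i))
  })), collapse = "")
  for (k in others) {
    b <- parsed[[as.character(k)]]
    rows[k] <- paste(unlist(lapply(seq_len(Lc + 1), function(i) {
      pad <- ins[i] - length(b$inserted[[i]])
      c(b$inserted[[i]], rep("-", pad), if (i <= Lc) b$at[i])
    })), collapse = "")
  }
  structure(stats::setNames(rows, names(windows)), class = "star_msa",
            center = names(windows)[centre])
}

# Decompose a pairwise center/other alignment into, per center residue i,
# the other-sequence characters inserted before residue i and the character
# aligned to residue i.
split_insertion_blocks <- function(cg, sg, Lc) {
  inserted <- vector("list", Lc + 1)
  for (i in seq_len(Lc + 1)) inserted[[i]] <- character(0)
  at <- character(Lc)
  pos <- 0L
  for (col in seq_along(cg)) {
    if (cg[col] == "-") {
      inserted[[pos + 1L]] <- c(inserted[[pos + 1L]], sg[col])
    } else {
      pos <- pos + 1L
      at[pos] <- sg[col]
    }
  }
  list(inserted = inserted, at = at,
       ins = vapply(inserted, length, integer(1)))
}

msa_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- names(aln)
  m
}

# Unordered row-index pairs used by every conservation statistic. When
# group labels are given (e.g. phage genus), only cross-group pairs count:
# identity among same-group rows reflects shared ancestry of the flank,
# not motif conservation.
conservation_pairs <- function(ids, groups = NULL) {
  n <- length(ids)
  pairs <- utils::combn(n, 2)
  if (!is.null(groups)) {
    ga <- groups[ids[pairs[1, ]]]
    gb <- groups[ids[pairs[2, ]]]
    cross <- is.na(ga) | is.na(gb) | ga != gb
    if (any(cross)) pairs <- pairs[, cross, drop = FALSE]
  }
  pairs
}

# Per-column mean pairwise identity: for each column, the fraction of
# counted row pairs with identical bases among pairs not gapped in both
# rows (gap vs base is a mismatch).
column_identity_profile <- function(m, groups = NULL) {
  C <- ncol(m)
  pairs <- conservation_pairs(rownames(m), groups)
  match_c <- numeric(C)
  valid_c <- numeric(C)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    both_gap <- m[i, ] == "-" & m[j, ] == "-"
    eq <- m[i, ] == m[j, ] & m[i, ] != "-"
    match_c <- match_c + (eq & !both_gap)
    valid_c <- valid_c + !both_gap
  }
  ifelse(valid_c > 0, match_c / valid_c, 0)
}

# Mean and sd of pairwise identities over a set of columns, for the given
# rows (both-gap columns excluded per pair).
pairwise_identity_stats <- function(m, rows, cols, groups = NULL) {
  pairs <- conservation_pairs(rows, groups)
  vals <- numeric(0)
  for (k in seq_len(ncol(pairs))) {
    x <- m[rows[pairs[1, k]], cols]; y <- m[rows[pairs[2, k]], cols]
    ok <- !(x == "-" & y == "-")
    if (!any(ok)) next
    vals <- c(vals, 100 * sum(x == y & x != "-" & ok) / sum(ok))
  }
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}

#' Scan a flank alignment for conserved windows
#'
#' Computes the per-column mean pairwise identity profile over the dense
#' columns of the alignment (those with at least 50% non-gap rows; sparse
#' insertion columns carry no conservation signal and would fragment real
#' motifs), smooths it with a running mean of `motif_window` columns, and
#' reports maximal runs where the smoothed profile stays at or above
#' `motif_min_identity` percent. Each run is re-delimited to the maximal
#' contiguous block of dense columns individually at or above
#' `motif_col_floor` percent, touching runs are merged, and a run must
#' span at least `motif_min_len` dense columns and be supported by at
#' least `motif_min_members` sequences that are non-gap over >= 80% of
#' the span.
#'
#' @param aln A `star_msa` alignment.
#' @param cfg An [rbp_config()].
#' @param region Optional region tag copied into the result.
#' @param groups Optional named vector of group labels (e.g. phage genus)
#'   per sequence: conservation is then measured over cross-group pairs
#'   only, so shared ancestry of same-group flanks does not masquerade as
#'   motif conservation.
#' @return Tibble of motif hits: `region`, `start_col`, `end_col`
#'   (original alignment columns), `span_start`, `span_end` (consensus
#'   window coordinates), `length` (dense columns in the span),
#'   `n_members`, `mean_identity_pct`, `sd_identity_pct`,
#'   `background_identity_pct`, `consensus`, and list-columns `members`,
#'   `pfm`, `member_spans` (per-member window coordinates of the span).
#' @export
scan_conserved_windows <- function(aln, cfg = rbp_config(), region = NA,
                                   groups = NULL) {
  cfg <- as_rbp_config(cfg)
  m <- msa_matrix(aln)
  C <- ncol(m)
  dense <- which(colMeans(m != "-") >= 0.5)
  if (length(dense) < cfg$motif_min_len) {
    return(empty_motif_tbl())
  }
  md <- m[, dense, drop = FALSE]
  prof <- column_identity_profile(md, groups)
  sm <- running_mean(prof, cfg$motif_window)
  # conserved windows are maximal scoring segments of the excess profile
  # against the hysteresis midpoint between col_floor and min_identity:
  # isolated low columns inside a motif do not split a segment, edge
  # columns are included down to the midpoint, and background (below the
  # floor) scores negative. Segments must contain a smoothed core at
  # min_identity (window w_m) and the reported hit must reach mean
  # pairwise identity >= min_identity.
  mid <- (cfg$motif_min_identity + cfg$motif_col_floor) / 200
  runs <- max_scoring_segments(prof - mid, cfg$motif_min_len)
  if (!nrow(runs)) return(empty_motif_tbl())
  runs <- runs[vapply(seq_len(nrow(runs)), function(i) {
    max(sm[seq(runs$start[i], runs$end[i])]) >=
      cfg$motif_min_identity / 100
  }, logical(1)), , drop = FALSE]
  runs <- trim_runs(runs, prof, cfg$motif_col_floor / 100)
  runs <- merge_touching_runs(runs)
  runs <- runs[runs$end - runs$start + 1 >= cfg$motif_min_len, ,
               drop = FALSE]
  if (!nrow(runs)) return(empty_motif_tbl())

  hits <- lapply(seq_len(nrow(runs)), function(r) {
    dcols <- dense[seq(runs$start[r], runs$end[r])]
    cols <- seq(min(dcols), max(dcols))
    nongap <- rowMeans(md[, seq(runs$start[r], runs$end[r]),
                          drop = FALSE] != "-")
    members <- rownames(m)[nongap >= 0.8]
    if (length(members) < cfg$motif_min_members) return(NULL)
    st <- pairwise_identity_stats(m, members, dcols, groups)
    if (st$mean < cfg$motif_min_identity) return(NULL)
    bg_cols <- setdiff(dense, dcols)
    bg <- if (length(bg_cols)) {
      pairwise_identity_stats(m, members, bg_cols, groups)$mean
    } else NA_real_
    cp <- consensus_and_pfm(m[members, dcols, drop = FALSE])
    spans <- member_nt_spans(m, members, dcols)
    tibble(
      region = region,
      start_col = min(dcols), end_col = max(dcols),
      # consensus location in window coordinates: the median of the
      # member spans, robust to individually slipped rows
      span_start = stats::median(spans$start, na.rm = TRUE),
      span_end = stats::median(spans$end, na.rm = TRUE),
      length = length(dcols), n_members = length(members),
      mean_identity_pct = st$mean, sd_identity_pct = st$sd,
      background_identity_pct = bg,
      consensus = cp$consensus,
      members = list(members), pfm = list(cp$pfm),
      member_spans = list(spans)
    )
  })
  dplyr::bind_rows(hits)
}

empty_motif_tbl <- function() {
  tibble(region = character(), start_col = integer(), end_col = integer(),
         span_start = numeric(), span_end = numeric(),
         length = integer(), n_members = integer(),
         mean_identity_pct = numeric(), sd_identity_pct = numeric(),
         background_identity_pct = numeric(), consensus = character(),
         members = list(), pfm = list(), member_spans = list())
}

run_spans <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble(start = starts[r$values], end = ends[r$values])
}

# All disjoint maximal positive-scoring segments of x, found by repeated
# Kadane scans with masking; only segments of length >= min_len are kept.
max_scoring_segments <- function(x, min_len, max_segments = 25L) {
  out <- list()
  for (k in seq_len(max_segments)) {
    best <- kadane_segment(x)
    if (is.null(best) || best$score <= 0) break
    if (best$end - best$start + 1 >= min_len) {
      out[[length(out) + 1]] <- tibble(start = best$start, end = best$end)
    }
    x[seq(best$start, best$end)] <- -Inf
  }
  if (!length(out)) return(tibble(start = integer(), end = integer()))
  dplyr::bind_rows(out)
}

kadane_segment <- function(x) {
  best <- NULL
  cur <- 0; cur_start <- 1L
  best_score <- 0
  for (i in seq_along(x)) {
    if (is.infinite(x[i]) && x[i] < 0) { cur <- 0; cur_start <- i + 1L; next }
    cur <- cur + x[i]
    if (cur <= 0) { cur <- 0; cur_start <- i + 1L; next }
    if (cur > best_score) {
      best_score <- cur
      best <- list(start = cur_start, end = i, score = cur)
    }
  }
  best
}

trim_runs <- function(runs, prof, floor) {
  keep <- logical(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; e <- runs$end[i]
    while (s <= e && prof[s] < floor) s <- s + 1
    while (e >= s && prof[e] < floor) e <- e - 1
    runs$start[i] <- s; runs$end[i] <- e
    keep[i] <- s <= e
  }
  runs[keep, , drop = FALSE]
}

merge_touching_runs <- function(runs) {
  if (nrow(runs) < 2) return(runs)
  runs <- runs[order(runs$start), , drop = FALSE]
  out <- runs[1, , drop = FALSE]
  for (i in seq(2, nrow(runs))) {
    last <- nrow(out)
    if (runs$start[i] <= out$end[last] + 1) {
      out$end[last] <- max(out$end[last], runs$end[i])
    } else {
      out <- dplyr::bind_rows(out, runs[i, ])
    }
  }
  out
}

# Per-member window coordinates of the span: the interval between the
# first and last motif column where the member has a base (content placed
# in sparse insertion columns does not extend the span).
member_nt_spans <- function(m, members, cols) {
  dplyr::bind_rows(lapply(members, function(id) {
    row <- m[id, ]
    nongap_cum <- cumsum(row != "-")
    present <- cols[row[cols] != "-"]
    if (!length(present)) {
      return(tibble(rbp_id = id, start = NA_integer_, end = NA_integer_))
    }
    tibble(rbp_id = id,
           start = as.integer(nongap_cum[present[1]]),
           end = as.integer(nongap_cum[present[length(present)]]))
  }))
}

#' Permutation significance of a conserved window
#'
#' Compares the observed mean pairwise identity of a motif span against a
#' null distribution of `motif_n_perm` equally long column windows drawn
#' uniformly from the same flank alignment, excluding windows overlapping
#' the hit. The p-value is `(1 + #null >= observed) / (N + 1)` and is
#' bitwise-reproducible for a fixed seed.
#'
#' @param hit A one-row motif hit from [scan_conserved_windows()].
#' @param aln The `star_msa` alignment the hit came from.
#' @param cfg An [rbp_config()].
#' @param seed Integer seed for the window draws.
#' @param groups Optional group labels as in [scan_conserved_windows()];
#'   use the same value the hit was computed with.
#' @return The permutation p-value, or `NA` (with a warning) when the
#'   alignment has no non-overlapping window of the motif's width.
#' @export
motif_significance <- function(hit, aln, cfg = rbp_config(), seed = 1L,
                               groups = NULL) {
  cfg <- as_rbp_config(cfg)
  m <- msa_matrix(aln)
  dense <- which(colMeans(m != "-") >= 0.5)
  md <- m[, dense, drop = FALSE]
  members <- hit$members[[1]]
  # hit span in dense-column index space
  in_hit <- dense >= hit$start_col & dense <= hit$end_col
  s_d <- min(which(in_hit)); e_d <- max(which(in_hit))
  w <- e_d - s_d + 1
  starts_all <- seq_len(length(dense) - w + 1)
  overlap <- starts_all + w - 1 >= s_d & starts_all <= e_d
  starts <- starts_all[!overlap]
  if (!length(starts)) {
    warning("flanks too short for a null window; p undefined")
    return(NA_real_)
  }
  pc <- pair_cumulants(md, members, groups)
  obs <- window_mean_identity(pc, s_d, e_d)
  null <- with_local_seed(seed, {
    draw <- sample(starts, cfg$motif_n_perm, replace = TRUE)
    vapply(draw, function(s) window_mean_identity(pc, s, s + w - 1),
           numeric(1))
  })
  (1 + sum(null >= obs - 1e-12)) / (cfg$motif_n_perm + 1)
}

# Per-pair cumulative match/valid counts so any column window's mean
# pairwise identity is O(#pairs).
pair_cumulants <- function(m, members, groups = NULL) {
  pr <- conservation_pairs(members, groups)
  idx <- match(members, rownames(m))
  pairs <- rbind(idx[pr[1, ]], idx[pr[2, ]])
  lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    both_gap <- m[i, ] == "-" & m[j, ] == "-"
    eq <- m[i, ] == m[j, ] & m[i, ] != "-"
    list(match = cumsum(c(0, as.numeric(eq & !both_gap))),
         valid = cumsum(c(0, as.numeric(!both_gap))))
  })
}

window_mean_identity <- function(pc, s, e) {
  vals <- vapply(pc, function(p) {
    v <- p$valid[e + 1] - p$valid[s]
    if (v == 0) return(NA_real_)
    100 * (p$match[e + 1] - p$match[s]) / v
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Consensus sequence and position-frequency matrix
#'
#' Per-column base frequencies over non-gap members; the consensus base is
#' the modal base, with ties encoded as the IUPAC ambiguity code of the
#' tied set.
#'
#' @param sub Character matrix of aligned rows (members) by columns, or a
#'   `star_msa` object.
#' @return List with `consensus` (string) and `pfm` (4 x ncol frequency
#'   matrix over A, C, G, T).
#' @export
consensus_and_pfm <- function(sub) {
  if (inherits(sub, "star_msa")) sub <- msa_matrix(sub)
  stopifnot(nrow(sub) >= 2)
  bases <- c("A", "C", "G", "T")
  pfm <- apply(sub, 2, function(col) {
    col <- col[col %in% bases]
    if (!length(col)) return(stats::setNames(rep(0, 4), bases))
    tab <- table(factor(col, levels = bases))
    as.numeric(tab) / length(col)
  })
  rownames(pfm) <- bases
  consensus <- vapply(seq_len(ncol(pfm)), function(j) {
    f <- pfm[, j]
    if (all(f == 0)) return("-")
    modal <- bases[f == max(f)]
    if (length(modal) == 1) return(modal)
    iupac_code(modal)
  }, character(1))
  list(consensus = paste(consensus, collapse = ""), pfm = pfm)
}

iupac_code <- function(bases) {
  key <- paste(sort(bases), collapse = "")
  map <- Biostrings::IUPAC_CODE_MAP
  hit <- names(map)[vapply(map, function(v) {
    paste(sort(strsplit(v, "")[[1]]), collapse = "") == key
  }, logical(1))]
  if (length(hit)) hit[1] else "N"
}

#' Find conserved motifs in both flank regions
#'
#' Convenience wrapper running [extract_flanks()], [star_msa()],
#' [scan_conserved_windows()] and [motif_significance()] for the boundary
#' and downstream regions. Conservation is measured over cross-genus
#' sequence pairs (the records\' `genus` labels), matching the claim the
#' motifs make: DNA conservation across phage genera.
#'
#' @param records An RBP record tibble with nucleotide sequences.
#' @param delineations Delineation tibble from [delineate_domains()].
#' @param cfg An [rbp_config()].
#' @param seed Seed for the permutation test.
#' @return Motif-hit tibble as in [scan_conserved_windows()] with an added
#'   `permutation_p` column.
#' @export
find_flank_motifs <- function(records, delineations, cfg = rbp_config(),
                              seed = 1L) {
  cfg <- as_rbp_config(cfg)
  flanks <- extract_flanks(records, delineations, cfg)
  groups <- if ("genus" %in% names(records)) {
    stats::setNames(records$genus, records$rbp_id)
  } else NULL
  out <- lapply(unique(flanks$region), function(reg) {
    fr <- flanks[flanks$region == reg, , drop = FALSE]
    if (nrow(fr) < max(2, cfg$motif_min_members)) return(NULL)
    aln <- star_msa(fr, cfg)
    hits <- scan_conserved_windows(aln, cfg, region = reg, groups = groups)
    if (!nrow(hits)) return(hits)
    hits$permutation_p <- vapply(seq_len(nrow(hits)), function(i) {
      suppressWarnings(motif_significance(hits[i, ], aln, cfg,
                                          seed = seed + i,
                                          groups = groups))
    }, numeric(1))
    hits
  })
  dplyr::bind_rows(out)
}
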
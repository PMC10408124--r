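AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        names(which(Biostrings::GENETIC_CODE == "*")))

# synonymous codons per residue (standard code)
SYN_CODONS <- split(SENSE_CODONS, Biostrings::GENETIC_CODE[SENSE_CODONS])

#' Synthetic dataset configuration
#'
#' Parameters of the ground-truth generator. Defaults emulate the
#' structures the pipeline assumes: genus-conserved anchors (planted
#' boundary 150-210 aa, ~5% within-genus divergence), serogroup-linked RBD
#' families shared across genera by construction (each family recurs in
#' several genera, i.e. horizontal transfer), within-family RBD divergence
#' up to 40% substitutions against ~background identity between families,
#' near-duplicate pairs above the 80% redundancy threshold, decoy families
#' whose host serogroup labels stay below the 90% consensus, records with
#' unknown serogroup, and conserved DNA motifs planted at the anchor/RBD
#' boundary and in the noncoding flank downstream of the stop codon.
#'
#' @param n_genera,n_per_genus Number of genera and core records per genus.
#' @param n_families Number of serogroup-linked RBD families; families are
#'   dealt to genera cyclically so each spans several genera.
#' @param anchor_len_range,rbd_len_range Length ranges (aa).
#' @param anchor_divergence Target pairwise divergence between same-genus
#'   anchors (default 0.05, i.e. ~95% identity); each record mutates from
#'   the genus ancestor at half this rate.
#' @param rbd_divergence_max Upper bound of the per-record uniform draw of
#'   RBD substitution rate from the family ancestor (default 0.40).
#' @param n_redundant Number of planted near-duplicate records (~95%
#'   identity to an existing record, same serogroup).
#' @param redundant_divergence Substitution rate of a duplicate from its
#'   source (default 0.05).
#' @param n_decoys,decoy_size Decoy RBD families and their member count;
#'   decoy members carry deliberately mixed serogroup labels.
#' @param n_unknown Records (one extra family) with unknown host serogroup.
#' @param serogroups Pool of serogroup labels for the families.
#' @param motif_boundary_codons Length of the boundary motif in codons
#'   (default 15, i.e. 45 nt ending exactly at the boundary nucleotide).
#' @param motif_boundary_rate Per-site nt mutation rate of the boundary
#'   motif (default 0.12, giving roughly 70-80% pairwise DNA identity).
#' @param motif_downstream_len,motif_downstream_offset,motif_downstream_rate
#'   Length (nt), offset after the stop codon, and mutation rate of the
#'   downstream noncoding motif.
#' @param downstream_flank_len Length of the noncoding flank appended after
#'   the stop codon (default 120 nt).
#' @return A list of class `rbp_sim_config`.
#' @export
sim_config <- function(n_genera = 5L,
                       n_per_genus = 3L,
                       n_families = 5L,
                       anchor_len_range = c(150L, 210L),
                       rbd_len_range = c(350L, 600L),
                       anchor_divergence = 0.05,
                       rbd_divergence_max = 0.40,
                       n_redundant = 2L,
                       redundant_divergence = 0.05,
                       n_decoys = 1L,
                       decoy_size = 3L,
                       n_unknown = 2L,
                       serogroups = c("O157", "O26", "O103", "O104", "O111",
                                      "O145", "O45", "O78", "O18", "4s/O22"),
                       motif_boundary_codons = 15L,
                       motif_boundary_rate = 0.12,
                       motif_downstream_len = 20L,
                       motif_downstream_offset = 21L,
                       motif_downstream_rate = 0.08,
                       downstream_flank_len = 120L) {
  stopifnot(n_families <= length(serogroups),
            rbd_divergence_max < 0.75,  # must stay above background identity
            anchor_divergence < 0.5,
            anchor_len_range[1] >= 60,
            motif_downstream_offset + motif_downstream_len <=
              downstream_flank_len)
  structure(as.list(environment()), class = "rbp_sim_config")
}

# draw n integers uniformly from [lo, hi]; safe for lo == hi (base sample()
# would treat a scalar as 1:x)
sample_range <- function(range, n) {
  range[1] + sample.int(range[2] - range[1] + 1L, n, replace = TRUE) - 1L
}

mutate_aa <- function(seq, rate) {
  x <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(x)) < rate
  x[hit] <- vapply(x[hit], function(a) sample(setdiff(AA20, a), 1),
                   character(1))
  paste(x, collapse = "")
}

mutate_nt <- function(seq, rate) {
  x <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(x)) < rate
  x[hit] <- vapply(x[hit], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste(x, collapse = "")
}

random_aa <- function(len) paste(sample(AA20, len, replace = TRUE),
                                 collapse = "")
random_nt <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                        replace = TRUE), collapse = "")

# one random synonymous codon per residue: the ancestral coding sequence
ancestral_codons <- function(aa) {
  vapply(strsplit(aa, "")[[1]], function(a) {
    syn <- SYN_CODONS[[a]]
    syn[sample.int(length(syn), 1)]
  }, character(1), USE.NAMES = FALSE)
}

# descendants inherit the ancestral codon wherever the residue is
# unchanged and draw a fresh synonymous codon only at substituted sites,
# so DNA identity tracks shared ancestry instead of a codon table
inherit_codons <- function(aa, anc_aa, anc_codons) {
  av <- strsplit(aa, "")[[1]]
  ov <- strsplit(anc_aa, "")[[1]]
  out <- anc_codons
  for (i in which(av != ov)) {
    syn <- SYN_CODONS[[av[i]]]
    out[i] <- syn[sample.int(length(syn), 1)]
  }
  out
}

# Replace any in-frame stop codon created by motif mutations with its
# pre-mutation codon (the ancestral motif is stop-free by construction).
fix_stops <- function(cds, ancestral, at) {
  first_codon <- (at - 1L) %/% 3L + 1L
  last_codon <- (at + nchar(ancestral) - 2L) %/% 3L + 1L
  for (cd in seq(first_codon, last_codon)) {
    lo <- 3L * (cd - 1L) + 1L
    codon <- substr(cds, lo, lo + 2L)
    if (Biostrings::GENETIC_CODE[[codon]] == "*") {
      anc_codon <- substr(ancestral, lo - at + 1L, lo - at + 3L)
      substr(cds, lo, lo + 2L) <- anc_codon
    }
  }
  cds
}

#' Generate a synthetic RBP dataset with ground truth
#'
#' Emits an RBP record tibble (amino-acid and nucleotide sequences plus
#' metadata) together with the truth used to generate it, so that every
#' pipeline stage can be checked against known answers. Deterministic for a
#' fixed `(gen_cfg, seed)` pair; the caller's RNG state is untouched.
#'
#' @param gen_cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List with `records` (an RBP record tibble) and `truth` (list of
#'   class `rbp_sim_truth`: `genera`, `families`, `records`, `motifs`,
#'   `redundant`, `decoy_ids`, `unknown_ids`).
#' @examples
#' sim <- simulate_rbp_dataset(sim_config(n_genera = 2, n_per_genus = 2,
#'                                        n_families = 2), seed = 7)
#' sim$truth$families$serogroup
#' @export
simulate_rbp_dataset <- function(gen_cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(gen_cfg, "rbp_sim_config"))
  with_local_seed(seed, simulate_impl(gen_cfg))
}

simulate_impl <- function(cfg) {
  genera <- tibble(
    genus = sprintf("genus%02d", seq_len(cfg$n_genera)),
    anchor_end = sample_range(cfg$anchor_len_range, cfg$n_genera),
    anchor_seq = NA_character_
  )
  genera$anchor_seq <- vapply(genera$anchor_end, random_aa, character(1))
  genera$anchor_codons <- lapply(genera$anchor_seq, ancestral_codons)

  new_family <- function(name, serogroup, len) {
    aa <- random_aa(len)
    tibble(family = name, serogroup = serogroup, rbd_seq = aa,
           rbd_codons = list(ancestral_codons(aa)))
  }
  families <- dplyr::bind_rows(lapply(seq_len(cfg$n_families), function(f) {
    new_family(sprintf("fam%02d", f), cfg$serogroups[f],
               sample_range(cfg$rbd_len_range, 1))
  }))

  # shared DNA motifs (ancestral); the boundary motif is codon-aligned and
  # stop-free so planting it cannot break the reading frame
  motif_boundary <- paste(sample(SENSE_CODONS, cfg$motif_boundary_codons,
                                 replace = TRUE), collapse = "")
  motif_downstream <- random_nt(cfg$motif_downstream_len)

  rows <- list()
  truth_rows <- list()
  k <- 0L
  add_record <- function(id, genus_i, fam_row, serogroup, evidence,
                         sg_evidence, rbd_rate, source = "phage",
                         score = NA_real_) {
    g <- genera[genus_i, ]
    anchor <- mutate_aa(g$anchor_seq, cfg$anchor_divergence / 2)
    rbd <- mutate_aa(fam_row$rbd_seq, rbd_rate)
    aa <- paste0(anchor, rbd)
    codons <- c(inherit_codons(anchor, g$anchor_seq, g$anchor_codons[[1]]),
                inherit_codons(rbd, fam_row$rbd_seq, fam_row$rbd_codons[[1]]))
    nt <- build_nt(codons, g$anchor_end, motif_boundary, motif_downstream,
                   cfg)
    aa_final <- translate_cds(nt$seq, nchar(aa))
    k <<- k + 1L
    rows[[k]] <<- tibble(
      rbp_id = id, phage_id = id, genus = g$genus,
      lifestyle = "lytic", source = source, rbp_index = 1L,
      aa_sequence = aa_final, nt_sequence = nt$seq,
      evidence_group = evidence, host_strain = NA_character_,
      host_serogroup = serogroup, serogroup_evidence = sg_evidence,
      prophage_score = score, curated_anchor_end = NA_integer_,
      split_rbp = FALSE
    )
    truth_rows[[k]] <<- tibble(
      rbp_id = id, genus = g$genus, family = fam_row$family,
      anchor_end = g$anchor_end, rbd_rate = rbd_rate
    )
    invisible(id)
  }

  # core records: families dealt cyclically across genera => every family
  # recurs in several genera (the horizontal-transfer structure)
  first_of_family <- rep(TRUE, cfg$n_families)
  for (g in seq_len(cfg$n_genera)) {
    for (i in seq_len(cfg$n_per_genus)) {
      f <- ((g - 1L + (i - 1L)) %% cfg$n_families) + 1L
      fam <- families[f, ]
      if (first_of_family[f]) {
        ev <- if (f %% 2L == 1L) "A" else "B"
        sg_ev <- if (ev == "A") "rbp_level" else "phage_level"
        first_of_family[f] <- FALSE
      } else {
        ev <- "C"; sg_ev <- "host_strain"
      }
      add_record(sprintf("rbp_g%02d_%02d", g, i), g, fam, fam$serogroup,
                 ev, sg_ev, stats::runif(1, 0, cfg$rbd_divergence_max))
    }
  }

  core <- dplyr::bind_rows(rows)
  redundant <- tibble(rbp_id = character(), duplicate_of = character())
  if (cfg$n_redundant > 0) {
    src_idx <- sample(nrow(core), min(cfg$n_redundant, nrow(core)))
    for (s in src_idx) {
      src <- core[s, ]
      tr <- truth_rows[[s]]
      fam <- families[families$family == tr$family, ]
      id <- paste0(src$rbp_id, "_dup")
      # clone by re-mutating the source RBD slightly; anchor from the genus
      g_i <- match(tr$genus, genera$genus)
      fam_anc <- families[families$family == tr$family, ]
      anchor <- mutate_aa(genera$anchor_seq[g_i], cfg$redundant_divergence / 2)
      src_rbd <- substr(src$aa_sequence, tr$anchor_end + 1L,
                        nchar(src$aa_sequence))
      rbd <- mutate_aa(src_rbd, cfg$redundant_divergence)
      aa <- paste0(anchor, rbd)
      codons <- c(inherit_codons(anchor, genera$anchor_seq[g_i],
                                 genera$anchor_codons[[g_i]]),
                  inherit_codons(rbd, fam_anc$rbd_seq,
                                 fam_anc$rbd_codons[[1]]))
      nt <- build_nt(codons, tr$anchor_end, motif_boundary,
                     motif_downstream, cfg)
      aa_final <- translate_cds(nt$seq, nchar(aa))
      k <- k + 1L
      rows[[k]] <- dplyr::mutate(src, rbp_id = id, phage_id = id,
                                 aa_sequence = aa_final,
                                 nt_sequence = nt$seq,
                                 evidence_group = "C",
                                 serogroup_evidence = "host_strain")
      truth_rows[[k]] <- dplyr::mutate(tr, rbp_id = id)
      redundant <- dplyr::bind_rows(
        redundant, tibble(rbp_id = id, duplicate_of = src$rbp_id))
    }
  }

  decoy_ids <- character(0)
  if (cfg$n_decoys > 0) {
    decoy_pool <- setdiff(cfg$serogroups,
                          families$serogroup)
    if (length(decoy_pool) < 2) decoy_pool <- c("Odx1", "Odx2")
    for (dnum in seq_len(cfg$n_decoys)) {
      fam <- new_family(sprintf("decoy%02d", dnum), NA_character_,
                        sample_range(cfg$rbd_len_range, 1))
      families <- dplyr::bind_rows(families, fam)
      # mixed labels: alternate two serogroups so no label reaches 90%
      labels <- rep(decoy_pool[1:2], length.out = cfg$decoy_size)
      for (i in seq_len(cfg$decoy_size)) {
        g <- ((i - 1L) %% cfg$n_genera) + 1L
        id <- sprintf("rbp_dec%02d_%02d", dnum, i)
        add_record(id, g, fam, labels[i], "E", "host_strain",
                   stats::runif(1, 0, cfg$rbd_divergence_max))
        decoy_ids <- c(decoy_ids, id)
      }
    }
  }

  unknown_ids <- character(0)
  if (cfg$n_unknown > 0) {
    fam <- new_family("famUnknown", NA_character_,
                      sample_range(cfg$rbd_len_range, 1))
    families <- dplyr::bind_rows(families, fam)
    for (i in seq_len(cfg$n_unknown)) {
      g <- ((i - 1L) %% cfg$n_genera) + 1L
      id <- sprintf("rbp_unk_%02d", i)
      add_record(id, g, fam, NA_character_, "E", "unknown",
                 stats::runif(1, 0, cfg$rbd_divergence_max))
      unknown_ids <- c(unknown_ids, id)
    }
  }

  records <- dplyr::bind_rows(rows)
  truth_records <- dplyr::bind_rows(truth_rows)
  motifs <- tibble(
    region = c("boundary_flank", "downstream_noncoding"),
    seq = c(motif_boundary, motif_downstream),
    # positions relative to the boundary nucleotide (3 * anchor_end) and to
    # the last nucleotide of the stop codon, 1-based inclusive
    rel_start = c(-(3L * cfg$motif_boundary_codons) + 1L,
                  cfg$motif_downstream_offset),
    rel_end = c(0L, cfg$motif_downstream_offset + cfg$motif_downstream_len - 1L),
    rate = c(cfg$motif_boundary_rate, cfg$motif_downstream_rate)
  )
  truth <- structure(list(
    genera = genera, families = families, records = truth_records,
    motifs = motifs, redundant = redundant,
    decoy_ids = decoy_ids, unknown_ids = unknown_ids
  ), class = "rbp_sim_truth")
  list(records = validate_rbp_records(records), truth = truth)
}

# CDS (with stop) + downstream flank; boundary motif overwrites the last
# motif_boundary_codons codons of the anchor, the downstream motif a window
# in the noncoding flank. Both are mutated per record before planting.
build_nt <- function(codons, anchor_end, motif_boundary, motif_downstream,
                     cfg) {
  cds <- paste0(paste(codons, collapse = ""), "TAA")
  mb <- mutate_nt(motif_boundary, cfg$motif_boundary_rate)
  at <- 3L * (anchor_end - cfg$motif_boundary_codons) + 1L
  substr(cds, at, at + nchar(mb) - 1L) <- mb
  cds <- fix_stops(cds, motif_boundary, at)
  flank <- random_nt(cfg$downstream_flank_len)
  md <- mutate_nt(motif_downstream, cfg$motif_downstream_rate)
  substr(flank, cfg$motif_downstream_offset,
         cfg$motif_downstream_offset + nchar(md) - 1L) <- md
  list(seq = paste0(cds, flank))
}

#' Write a simulated dataset plus truth to a directory
#'
#' Writes `aa.fasta`, `nt.fasta`, `metadata.tsv` via [write_rbp_dataset()]
#' and the ground truth as `truth.json`.
#'
#' @param sim Result of [simulate_rbp_dataset()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  write_rbp_dataset(sim$records, dir)
  truth <- sim$truth
  jsonlite::write_json(
    lapply(unclass(truth), function(x) if (is.data.frame(x)) x else as.list(x)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate flank windows with a planted motif in random background
#'
#' Generates `n` DNA windows of uniform random background (expected 25%
#' pairwise identity) sharing one planted motif: every window carries the
#' same ancestral motif, independently mutated per site at `rate`, at the
#' same position. The minimal fixture for testing conserved-window
#' detection and localization in isolation.
#'
#' @param n Number of windows.
#' @param flank_len Window length (nt).
#' @param motif_len Motif length (nt).
#' @param position 1-based start of the motif within each window.
#' @param rate Per-site motif mutation rate (pairwise identity is roughly
#'   `(1 - rate)^2`).
#' @param seed Integer seed.
#' @return List with `windows` (named character vector) and `truth`
#'   (list: `motif`, `start`, `end`).
#' @export
simulate_motif_windows <- function(n = 20L, flank_len = 300L,
                                   motif_len = 44L, position = 106L,
                                   rate = 0.15, seed = 1L) {
  stopifnot(position + motif_len - 1 <= flank_len, n >= 2)
  with_local_seed(seed, {
    motif <- random_nt(motif_len)
    windows <- vapply(seq_len(n), function(i) {
      w <- random_nt(flank_len)
      substr(w, position, position + motif_len - 1L) <-
        mutate_nt(motif, rate)
      w
    }, character(1))
    names(windows) <- sprintf("w%02d", seq_len(n))
    list(windows = windows,
         truth = list(motif = motif, start = position,
                      end = position + motif_len - 1L))
  })
}

#' Localization accuracy of detected flanking motifs
#'
#' For every flank region with a planted motif, converts the planted motif
#' coordinates into each member's extracted-window coordinates (through
#' that record's delineated boundary) and scores each detected motif by
#' the median per-member interval Jaccard between its span and the planted
#' span (median, so individually slipped alignment rows do not dominate).
#' The best-localizing hit per region is reported.
#'
#' @param result An `rbp_pipeline` object from [run_rbp_pipeline()] with
#'   motifs scanned.
#' @param truth The `rbp_sim_truth` from [simulate_rbp_dataset()].
#' @return Tibble: `region`, `jaccard` (0 when no hit was found),
#'   `n_members`, `mean_identity_pct`, `permutation_p` of the best hit.
#' @export
motif_recovery <- function(result, truth) {
  stopifnot(inherits(result, "rbp_pipeline"),
            inherits(truth, "rbp_sim_truth"))
  if (is.null(result$motifs)) stop("pipeline was run without a motif scan")
  flanks <- extract_flanks(result$kept, result$delineations, result$cfg)
  out <- lapply(seq_len(nrow(truth$motifs)), function(i) {
    tm <- truth$motifs[i, ]
    hits <- result$motifs[result$motifs$region == tm$region, , drop = FALSE]
    fl <- flanks[flanks$region == tm$region, , drop = FALSE]
    if (!nrow(hits)) {
      return(tibble(region = tm$region, jaccard = 0, n_members = 0L,
                    mean_identity_pct = NA_real_,
                    permutation_p = NA_real_))
    }
    jac <- vapply(seq_len(nrow(hits)), function(h) {
      sp <- hits$member_spans[[h]]
      stats::median(vapply(seq_len(nrow(sp)), function(k) {
        id <- sp$rbp_id[k]
        tr_ae <- truth$records$anchor_end[truth$records$rbp_id == id]
        rec <- result$kept[result$kept$rbp_id == id, ]
        origin <- if (tm$region == "boundary_flank") 3L * tr_ae else
          3L * nchar(rec$aa_sequence) + 3L
        w <- fl[fl$rbp_id == id, ]
        planted <- c(origin + tm$rel_start, origin + tm$rel_end) -
          w$start + 1L
        interval_jaccard(c(sp$start[k], sp$end[k]), planted)
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    best <- which.max(jac)
    tibble(region = tm$region, jaccard = jac[best],
           n_members = hits$n_members[best],
           mean_identity_pct = hits$mean_identity_pct[best],
           permutation_p = if ("permutation_p" %in% names(hits))
             hits$permutation_p[best] else NA_real_)
  })
  dplyr::bind_rows(out)
}

interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  uni <- max(a[2], b[2]) - min(a[1], b[1]) + 1
  inter / uni
}

#' Compare pipeline output against planted truth
#'
#' Scores a pipeline run on a simulated dataset: adjusted Rand index of the
#' subtype partition against the planted RBD families, serogroup-assignment
#' accuracy over assigned (non-decoy) subtypes, the number of decoy
#' subtypes that wrongly received an assignment, mean absolute anchor
#' boundary error, and redundancy-removal correctness (each planted
#' duplicate pair reduced to one survivor).
#'
#' @param result An `rbp_pipeline` object from [run_rbp_pipeline()].
#' @param truth The `rbp_sim_truth` from [simulate_rbp_dataset()].
#' @return One-row tibble: `ari`, `assignment_accuracy`,
#'   `decoy_false_assignments`, `mean_anchor_error`, `redundancy_correct`.
#' @export
recovery_report <- function(result, truth) {
  stopifnot(inherits(result, "rbp_pipeline"),
            inherits(truth, "rbp_sim_truth"))
  part <- result$subtypes
  tr <- truth$records
  common <- intersect(part$rbp_id, tr$rbp_id)
  if (!length(common)) stop("no shared rbp_id between result and truth")
  ari <- mclust::adjustedRandIndex(
    part$subtype_id[match(common, part$rbp_id)],
    tr$family[match(common, tr$rbp_id)])

  asg <- result$assignments
  fam_sg <- stats::setNames(truth$families$serogroup, truth$families$family)
  subtype_truth <- vapply(asg$member_rbp_ids, function(ids) {
    fams <- tr$family[match(ids, tr$rbp_id)]
    names(sort(table(fams), decreasing = TRUE))[1]
  }, character(1))
  is_decoy <- grepl("^decoy", subtype_truth) |
    subtype_truth == "famUnknown"
  assigned <- asg$rejection_reason == "none"
  acc_pool <- assigned & !is_decoy
  accuracy <- if (any(acc_pool)) {
    mean(asg$assigned_serogroup[acc_pool] ==
           unname(fam_sg[subtype_truth[acc_pool]]))
  } else NA_real_
  decoy_false <- sum(assigned & grepl("^decoy", subtype_truth))

  del <- result$delineations
  err <- abs(del$anchor_end[match(common, del$rbp_id)] -
               tr$anchor_end[match(common, tr$rbp_id)])
  redundancy_ok <- if (nrow(truth$redundant)) {
    kept <- result$subtypes$rbp_id
    all(vapply(seq_len(nrow(truth$redundant)), function(i) {
      sum(c(truth$redundant$rbp_id[i],
            truth$redundant$duplicate_of[i]) %in% kept) == 1
    }, logical(1)))
  } else NA

  tibble(
    ari = ari,
    assignment_accuracy = accuracy,
    decoy_false_assignments = decoy_false,
    mean_anchor_error = mean(err, na.rm = TRUE),
    redundancy_correct = redundancy_ok
  )
}
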
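#' Pipeline configuration
#'
#' Collects every tunable threshold of the RBP classification pipeline in one
#' validated list. Defaults mirror the criteria used throughout the analysis:
#' a horizontal-transfer hit requires >= 30% amino-acid identity over >= 60%
#' of the receptor-binding domain (RBD); near-duplicates at >= 80% identity
#' within a serogroup are collapsed; a consensus serogroup assignment needs
#' >= 90% agreement among at least two known votes; a genus must contribute
#' at least two serogroup-specific RBPs to survive the final filter; the
#' tentative N-terminal anchor cutoff is 150 aa; and prophages count as
#' active above a prediction score of 0.8 (ambiguous in [0.5, 0.8]).
#'
#' @param hit_min_identity Minimum percent amino-acid identity for an RBD-RBD
#'   hit (default 30).
#' @param hit_min_coverage Minimum percent coverage of the RBD by the aligned
#'   span, in either direction of the comparison (default 60).
#' @param redundancy_identity Full-length percent identity above which two
#'   RBPs of the same serogroup are considered redundant (default 80).
#' @param consensus_fraction Fraction of known serogroup votes that must agree
#'   for a consensus assignment (default 0.90).
#' @param consensus_min_known Minimum number of known serogroup votes required
#'   before consensus is attempted (default 2).
#' @param genus_min_specific_rbps Minimum number of serogroup-assigned RBPs a
#'   genus must hold to be retained (default 2).
#' @param default_anchor_cutoff Tentative anchor length in aa used when no
#'   curated or data-driven boundary is available (default 150).
#' @param prophage_active_score Prophage prediction score strictly above which
#'   a prophage is "active" (default 0.8).
#' @param prophage_ambiguous_floor Lower bound of the "ambiguous" score band
#'   (default 0.5).
#' @param rough_strain_blocklist Host strain labels (rough laboratory strains
#'   lacking an O-antigen) whose phages are discarded; matched
#'   case-insensitively.
#' @param substitution_matrix Name of the protein substitution matrix
#'   (default "BLOSUM62").
#' @param gap_open,gap_extend Affine gap penalties, given as positive costs
#'   (defaults 11 and 1, the familiar protein-BLAST values).
#' @param nt_match,nt_mismatch,nt_gap_open,nt_gap_extend Scoring for
#'   nucleotide alignments in the motif scan; defaults are the familiar
#'   nucleotide-BLAST values (2, -3, 5, 2), whose stiff gap extension keeps
#'   alignments of diverged flanks from drifting.
#' @param breakpoint_window Smoothing window w (aa) for the conservation
#'   profile used in data-driven anchor/RBD boundary detection (default 20).
#' @param breakpoint_t_high,breakpoint_t_low Conservation levels defining the
#'   anchor plateau and the drop into the RBD (defaults 0.7 and 0.4).
#' @param flank_halfwidth Half-width (nt) of the DNA window centred on the
#'   anchor/RBD boundary (default 150).
#' @param downstream_len Length (nt) of the noncoding window taken after the
#'   stop codon (default 120).
#' @param motif_min_len Minimum motif span in alignment columns (default 15).
#' @param motif_min_identity Minimum windowed mean pairwise identity, percent,
#'   for a conserved window (default 55).
#' @param motif_window Smoothing window w_m in alignment columns (default 10).
#' @param motif_col_floor Per-column identity floor, percent, used to trim
#'   window edges (default 40).
#' @param motif_min_members Minimum number of sequences supporting a motif
#'   (default 4).
#' @param motif_n_perm Number of permutations for motif significance
#'   (default 999).
#' @param rng_seed Integer seed recorded with the configuration.
#'
#' @return A list of class `rbp_config`.
#' @examples
#' cfg <- rbp_config(hit_min_identity = 35)
#' cfg$hit_min_identity
#' @export
rbp_config <- function(hit_min_identity = 30,
                       hit_min_coverage = 60,
                       redundancy_identity = 80,
                       consensus_fraction = 0.90,
                       consensus_min_known = 2L,
                       genus_min_specific_rbps = 2L,
                       default_anchor_cutoff = 150L,
                       prophage_active_score = 0.8,
                       prophage_ambiguous_floor = 0.5,
                       rough_strain_blocklist = c("58", "AG1", "B", "BL21",
                                                  "C", "C600", "DH1",
                                                  "DH5α", "MG1655",
                                                  "W3110", "W945"),
                       substitution_matrix = "BLOSUM62",
                       gap_open = 11,
                       gap_extend = 1,
                       nt_match = 2,
                       nt_mismatch = -3,
                       nt_gap_open = 5,
                       nt_gap_extend = 2,
                       breakpoint_window = 20L,
                       breakpoint_t_high = 0.7,
                       breakpoint_t_low = 0.4,
                       flank_halfwidth = 150L,
                       downstream_len = 120L,
                       motif_min_len = 15L,
                       motif_min_identity = 55,
                       motif_window = 10L,
                       motif_col_floor = 40,
                       motif_min_members = 4L,
                       motif_n_perm = 999L,
                       rng_seed = 1L) {
  cfg <- list(
    hit_min_identity = hit_min_identity,
    hit_min_coverage = hit_min_coverage,
    redundancy_identity = redundancy_identity,
    consensus_fraction = consensus_fraction,
    consensus_min_known = as.integer(consensus_min_known),
    genus_min_specific_rbps = as.integer(genus_min_specific_rbps),
    default_anchor_cutoff = as.integer(default_anchor_cutoff),
    prophage_active_score = prophage_active_score,
    prophage_ambiguous_floor = prophage_ambiguous_floor,
    rough_strain_blocklist = rough_strain_blocklist,
    substitution_matrix = substitution_matrix,
    gap_open = gap_open,
    gap_extend = gap_extend,
    nt_match = nt_match,
    nt_mismatch = nt_mismatch,
    nt_gap_open = nt_gap_open,
    nt_gap_extend = nt_gap_extend,
    breakpoint_window = as.integer(breakpoint_window),
    breakpoint_t_high = breakpoint_t_high,
    breakpoint_t_low = breakpoint_t_low,
    flank_halfwidth = as.integer(flank_halfwidth),
    downstream_len = as.integer(downstream_len),
    motif_min_len = as.integer(motif_min_len),
    motif_min_identity = motif_min_identity,
    motif_window = as.integer(motif_window),
    motif_col_floor = motif_col_floor,
    motif_min_members = as.integer(motif_min_members),
    motif_n_perm = as.integer(motif_n_perm),
    rng_seed = as.integer(rng_seed)
  )
  validate_rbp_config(cfg)
  structure(cfg, class = "rbp_config")
}

validate_rbp_config <- function(cfg) {
  stopifnot(
    cfg$hit_min_identity > 0, cfg$hit_min_identity <= 100,
    cfg$hit_min_coverage > 0, cfg$hit_min_coverage <= 100,
    cfg$redundancy_identity > 0, cfg$redundancy_identity <= 100,
    cfg$consensus_fraction > 0, cfg$consensus_fraction <= 1,
    cfg$consensus_min_known >= 1,
    cfg$genus_min_specific_rbps >= 1,
    cfg$default_anchor_cutoff > 0,
    cfg$prophage_ambiguous_floor <= cfg$prophage_active_score,
    cfg$gap_open >= 0, cfg$gap_extend >= 0,
    cfg$breakpoint_t_low <= cfg$breakpoint_t_high,
    cfg$motif_min_len > 0, cfg$motif_window > 0,
    cfg$motif_min_identity > 0, cfg$motif_min_identity <= 100,
    cfg$motif_n_perm >= 1
  )
  invisible(cfg)
}

#' @export
print.rbp_config <- function(x, ...) {
  cat("<rbp_config>\n")
  cat(sprintf("  hit criterion: identity >= %g%%, coverage >= %g%%\n",
              x$hit_min_identity, x$hit_min_coverage))
  cat(sprintf("  redundancy: >= %g%% full-length identity\n",
              x$redundancy_identity))
  cat(sprintf("  consensus: >= %g%% of >= %d known votes\n",
              100 * x$consensus_fraction, x$consensus_min_known))
  cat(sprintf("  genus filter: >= %d specific RBPs\n",
              x$genus_min_specific_rbps))
  cat(sprintf("  default anchor cutoff: %d aa\n", x$default_anchor_cutoff))
  invisible(x)
}

as_rbp_config <- function(cfg) {
  if (is.null(cfg)) return(rbp_config())
  if (inherits(cfg, "rbp_config")) return(cfg)
  do.call(rbp_config, cfg)
}
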
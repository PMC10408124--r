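#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

AA_ALPHABET_RE <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"

rbp_metadata_cols <- function() {
  c("rbp_id", "phage_id", "genus", "lifestyle", "source", "rbp_index",
    "evidence_group", "host_strain", "host_serogroup", "serogroup_evidence",
    "prophage_score", "curated_anchor_end", "split_rbp")
}

#' Read an RBP dataset from FASTA + metadata
#'
#' Builds a one-row-per-RBP tibble from an amino-acid FASTA file, a
#' tab-separated metadata table, and optionally a nucleotide FASTA covering
#' the coding sequence plus downstream noncoding flank. FASTA identifiers
#' must match the `rbp_id` column of the metadata exactly; records are
#' returned in FASTA file order. The metadata uses "." for missing values.
#'
#' Serogroup labels are opaque strings from one namespace (O-antigens such
#' as "O157", compound labels such as "4s/O22", and K-antigens such as "K1")
#' and are stored verbatim; nothing is split on "/".
#'
#' @param aa_fasta Path to the amino-acid FASTA file.
#' @param metadata Path to the metadata TSV (header row required), or a data
#'   frame with the same columns.
#' @param nt_fasta Optional path to a nucleotide FASTA with matching ids.
#' @return A tibble with one row per FASTA entry; sequences without metadata
#'   rows get all-unknown metadata (with a warning), metadata rows without a
#'   sequence are an error.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' sim <- simulate_rbp_dataset(sim_config(n_genera = 2, n_per_genus = 2,
#'                                        n_families = 2), seed = 1)
#' write_rbp_dataset(sim$records, dir)
#' rec <- read_rbp_dataset(file.path(dir, "aa.fasta"),
#'                         file.path(dir, "metadata.tsv"),
#'                         file.path(dir, "nt.fasta"))
#' nrow(rec)
#' @seealso [write_rbp_dataset()], [validate_rbp_records()]
#' @export
read_rbp_dataset <- function(aa_fasta, metadata, nt_fasta = NULL) {
  aa <- Biostrings::readAAStringSet(aa_fasta)
  ids <- fasta_ids(names(aa))
  if (anyDuplicated(ids)) {
    stop("duplicate rbp_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  meta <- if (is.data.frame(metadata)) {
    as_tibble(metadata)
  } else {
    readr::read_tsv(metadata, na = ".", show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  }
  if (!"rbp_id" %in% names(meta)) stop("metadata must contain an rbp_id column")
  if (anyDuplicated(meta$rbp_id)) {
    stop("duplicate rbp_id in metadata: ",
         paste(unique(meta$rbp_id[duplicated(meta$rbp_id)]), collapse = ", "))
  }
  orphan_meta <- setdiff(meta$rbp_id, ids)
  if (length(orphan_meta)) {
    stop("metadata rows without a sequence: ",
         paste(orphan_meta, collapse = ", "))
  }
  orphan_seq <- setdiff(ids, meta$rbp_id)
  if (length(orphan_seq)) {
    warning("sequences without metadata (kept with unknown metadata): ",
            paste(orphan_seq, collapse = ", "))
  }

  records <- tibble(rbp_id = ids, aa_sequence = unname(as.character(aa)))
  meta <- coerce_metadata(meta)
  records <- dplyr::left_join(records, meta, by = "rbp_id")
  records <- fill_unknown_metadata(records)

  if (!is.null(nt_fasta)) {
    nt <- Biostrings::readDNAStringSet(nt_fasta)
    nt_ids <- fasta_ids(names(nt))
    if (anyDuplicated(nt_ids)) stop("duplicate rbp_id in nucleotide FASTA")
    records$nt_sequence <- unname(as.character(nt))[match(records$rbp_id, nt_ids)]
  } else if (!"nt_sequence" %in% names(records)) {
    records$nt_sequence <- NA_character_
  }

  records <- records[, union(c("rbp_id", "aa_sequence", "nt_sequence"),
                             names(records))]
  validate_rbp_records(records)
}

fasta_ids <- function(x) sub("\\s.*$", "", x)

coerce_metadata <- function(meta) {
  for (col in setdiff(rbp_metadata_cols(), names(meta))) {
    meta[[col]] <- NA_character_
  }
  meta$rbp_index <- suppressWarnings(as.integer(meta$rbp_index))
  meta$prophage_score <- suppressWarnings(as.numeric(meta$prophage_score))
  meta$curated_anchor_end <-
    suppressWarnings(as.integer(meta$curated_anchor_end))
  meta$split_rbp <- parse_bool(meta$split_rbp)
  meta
}

parse_bool <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

fill_unknown_metadata <- function(records) {
  records$lifestyle[is.na(records$lifestyle)] <- "unknown"
  records$source[is.na(records$source)] <- "phage"
  records$rbp_index[is.na(records$rbp_index)] <- 1L
  records$serogroup_evidence[is.na(records$serogroup_evidence)] <- "unknown"
  records$split_rbp[is.na(records$split_rbp)] <- FALSE
  records$phage_id[is.na(records$phage_id)] <- records$rbp_id[is.na(records$phage_id)]
  records$genus[is.na(records$genus)] <- "unknown"
  records
}

#' Validate an RBP record tibble
#'
#' Checks the structural invariants every downstream stage relies on:
#' non-empty amino-acid sequences over the 20-letter alphabet plus X, unique
#' ids, positive `rbp_index`, experimentally-evidenced records (groups A/B)
#' carrying a host serogroup, prophage scores only on prophage records, and
#' - when a nucleotide sequence is present - that its CDS translates to the
#' amino-acid sequence under the standard code (stop excluded).
#'
#' @param records An RBP record tibble.
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_rbp_records <- function(records) {
  records <- as_tibble(records)
  stopifnot(all(c("rbp_id", "aa_sequence") %in% names(records)))
  if (anyDuplicated(records$rbp_id)) {
    stop("duplicate rbp_id: ",
         paste(unique(records$rbp_id[duplicated(records$rbp_id)]),
               collapse = ", "))
  }
  bad <- !grepl(AA_ALPHABET_RE, records$aa_sequence)
  if (any(bad)) {
    stop("invalid amino-acid sequence for: ",
         paste(records$rbp_id[bad], collapse = ", "))
  }
  if (any(records$rbp_index < 1, na.rm = TRUE)) stop("rbp_index must be >= 1")
  exp_grp <- records$evidence_group %in% c("A", "B")
  if (any(exp_grp & is.na(records$host_serogroup))) {
    stop("evidence group A/B records must carry a host_serogroup: ",
         paste(records$rbp_id[exp_grp & is.na(records$host_serogroup)],
               collapse = ", "))
  }
  if (any(!is.na(records$prophage_score) & records$source != "prophage")) {
    stop("prophage_score present on non-prophage records")
  }
  has_nt <- which(!is.na(records$nt_sequence))
  if (length(has_nt)) {
    cds <- substr(records$nt_sequence[has_nt], 1L,
                  3L * nchar(records$aa_sequence[has_nt]))
    aa_obs <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(cds), if.fuzzy.codon = "X"))
    bad <- aa_obs != records$aa_sequence[has_nt]
    if (any(bad)) {
      stop("nt_sequence does not translate to aa_sequence for: ",
           paste(records$rbp_id[has_nt][bad], collapse = ", "))
    }
  }
  records
}

translate_cds <- function(nt, n_aa) {
  cds <- substr(nt, 1L, 3L * n_aa)
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "X"))
}

#' Write an RBP dataset to a directory
#'
#' Inverse of [read_rbp_dataset()]: writes `aa.fasta`, `metadata.tsv` and,
#' when nucleotide sequences are present, `nt.fasta`. Reading the files back
#' reproduces the records field for field.
#'
#' @param records An RBP record tibble.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_rbp_dataset <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aa <- Biostrings::AAStringSet(records$aa_sequence)
  names(aa) <- records$rbp_id
  Biostrings::writeXStringSet(aa, file.path(dir, "aa.fasta"))
  if (any(!is.na(records$nt_sequence))) {
    keep <- !is.na(records$nt_sequence)
    nt <- Biostrings::DNAStringSet(records$nt_sequence[keep])
    names(nt) <- records$rbp_id[keep]
    Biostrings::writeXStringSet(nt, file.path(dir, "nt.fasta"))
  }
  meta <- records[, intersect(rbp_metadata_cols(), names(records))]
  meta_chr <- dplyr::mutate(meta, dplyr::across(
    dplyr::everything(),
    function(x) ifelse(is.na(x), ".", as.character(x))
  ))
  readr::write_tsv(meta_chr, file.path(dir, "metadata.tsv"))
  invisible(dir)
}
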
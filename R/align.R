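protein_submat <- function(cfg) {
  name <- cfg$substitution_matrix
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

dna_submat <- function(cfg) {
  Biostrings::nucleotideSubstitutionMatrix(match = cfg$nt_match,
                                           mismatch = cfg$nt_mismatch,
                                           baseOnly = TRUE)
}

check_aa <- function(x, what = "sequence") {
  if (length(x) != 1 || is.na(x) || !nzchar(x)) {
    stop(what, " must be a nonempty string")
  }
  if (!grepl(AA_ALPHABET_RE, x)) {
    stop(what, " contains characters outside the amino-acid alphabet")
  }
  x
}

# Align a set of query sequences against one subject in a single
# vectorized call; identity counts all alignment columns (gaps included in
# the denominator: n_columns = nchar(pa), n_identical = nmatch(pa)).
batch_align <- function(patterns, b, cfg, type, subject_id = "subject",
                        dna = FALSE) {
  submat <- if (dna) dna_submat(cfg) else protein_submat(cfg)
  go <- if (dna) cfg$nt_gap_open else cfg$gap_open
  ge <- if (dna) cfg$nt_gap_extend else cfg$gap_extend
  set <- if (dna) Biostrings::DNAStringSet(patterns) else
    Biostrings::AAStringSet(patterns)
  pa <- Biostrings::pairwiseAlignment(set, b, type = type,
                                      substitutionMatrix = submat,
                                      gapOpening = go, gapExtension = ge)
  n_columns <- Biostrings::nchar(pa)
  n_identical <- Biostrings::nmatch(pa)
  tibble(
    query_id = names(patterns) %||% rep("query", length(patterns)),
    subject_id = subject_id,
    query_start = Biostrings::start(Biostrings::pattern(pa)),
    query_end = Biostrings::end(Biostrings::pattern(pa)),
    subject_start = Biostrings::start(Biostrings::subject(pa)),
    subject_end = Biostrings::end(Biostrings::subject(pa)),
    score = Biostrings::score(pa),
    n_columns = n_columns,
    n_identical = n_identical,
    identity_pct = 100 * n_identical / n_columns,
    mode = type
  )
}

align_pair <- function(a, b, cfg, type, query_id = "query",
                       subject_id = "subject", dna = FALSE) {
  batch_align(stats::setNames(a, query_id), b, cfg, type,
              subject_id = subject_id, dna = dna)
}

#' Optimal local protein alignment
#'
#' Smith-Waterman alignment with affine gap penalties under the configured
#' substitution matrix (BLOSUM62 / gap open 11 / gap extend 1 by default).
#' Identity is counted over all alignment columns, gap columns included in
#' the denominator.
#'
#' @param a,b Amino-acid sequences (single strings over the 20-letter
#'   alphabet plus X).
#' @param cfg An [rbp_config()].
#' @param query_id,subject_id Identifiers carried into the result.
#' @return A one-row tibble: ids, 1-based inclusive aligned spans on both
#'   sequences, `score`, `n_columns`, `n_identical`, `identity_pct`, `mode`.
#' @examples
#' align_local("ACDEFGHIK", "ACDEYGHIK")$identity_pct
#' @export
align_local <- function(a, b, cfg = rbp_config(),
                        query_id = "query", subject_id = "subject") {
  cfg <- as_rbp_config(cfg)
  check_aa(a, "a"); check_aa(b, "b")
  align_pair(a, b, cfg, "local", query_id, subject_id)
}

#' Optimal global protein alignment
#'
#' Needleman-Wunsch alignment of the full sequences (end gaps penalised),
#' used for region-level identity matrices. Same scoring and identity
#' convention as [align_local()].
#'
#' @inheritParams align_local
#' @return A one-row tibble as in [align_local()] with `mode = "global"`.
#' @export
align_global <- function(a, b, cfg = rbp_config(),
                         query_id = "query", subject_id = "subject") {
  cfg <- as_rbp_config(cfg)
  check_aa(a, "a"); check_aa(b, "b")
  align_pair(a, b, cfg, "global", query_id, subject_id)
}

region_sequence <- function(records, delineations, region) {
  if (region == "full") return(stats::setNames(records$aa_sequence,
                                               records$rbp_id))
  d <- delineations$anchor_end[match(records$rbp_id, delineations$rbp_id)]
  if (any(is.na(d))) {
    stop("missing delineation for: ",
         paste(records$rbp_id[is.na(d)], collapse = ", "))
  }
  seqs <- switch(region,
    anchor = substr(records$aa_sequence, 1L, d),
    rbd = substr(records$aa_sequence, d + 1L, nchar(records$aa_sequence)),
    stop("unknown region: ", region)
  )
  stats::setNames(seqs, records$rbp_id)
}

#' RBD-vs-RBD horizontal-transfer hit
#'
#' Aligns the receptor-binding domains of two records locally and applies
#' the hit criterion: identity >= `hit_min_identity` and coverage >=
#' `hit_min_coverage` of either RBD by its aligned span. Because the optimal
#' local alignment is symmetric in its two sequences, taking coverage in
#' either direction makes the hit an undirected edge predicate:
#' `passes(q, s) == passes(s, q)`.
#'
#' @param query,subject Single-row RBP record tibbles (or a list-like with
#'   `rbp_id` and `aa_sequence`).
#' @param delineations Delineation tibble from [delineate_domains()].
#' @param cfg An [rbp_config()].
#' @return One-row tibble: ids, `identity_pct`, `coverage_pct` (query side),
#'   `coverage_pct_subject`, `passes`. RBDs shorter than 10 aa yield no hit
#'   (zero rows) with a warning.
#' @export
rbd_hit <- function(query, subject, delineations, cfg = rbp_config()) {
  cfg <- as_rbp_config(cfg)
  rbds <- region_sequence(dplyr::bind_rows(as_tibble(query),
                                           as_tibble(subject)),
                          delineations, "rbd")
  if (any(nchar(rbds) < 10)) {
    warning("RBD shorter than 10 aa, no hit for pair ",
            paste(names(rbds), collapse = " / "))
    return(empty_hit_tbl())
  }
  pair_hit(rbds[1], rbds[2], names(rbds)[1], names(rbds)[2], cfg)
}

pair_hit <- function(q_rbd, s_rbd, qid, sid, cfg) {
  aln <- align_pair(q_rbd, s_rbd, cfg, "local", qid, sid)
  cov_q <- 100 * (aln$query_end - aln$query_start + 1) / nchar(q_rbd)
  cov_s <- 100 * (aln$subject_end - aln$subject_start + 1) / nchar(s_rbd)
  tibble(
    query_id = qid, subject_id = sid,
    identity_pct = aln$identity_pct,
    coverage_pct = cov_q,
    coverage_pct_subject = cov_s,
    passes = aln$identity_pct >= cfg$hit_min_identity &&
      (cov_q >= cfg$hit_min_coverage || cov_s >= cfg$hit_min_coverage)
  )
}

empty_hit_tbl <- function() {
  tibble(query_id = character(), subject_id = character(),
         identity_pct = numeric(), coverage_pct = numeric(),
         coverage_pct_subject = numeric(), passes = logical())
}

#' All-vs-all RBD hits
#'
#' Computes [rbd_hit()] for every unordered pair of records; the resulting
#' passing pairs are the edges from which RBP subtypes are built.
#'
#' @param records An RBP record tibble.
#' @inheritParams rbd_hit
#' @return Tibble of one row per unordered pair (query_id < subject_id
#'   lexicographically), columns as in [rbd_hit()]. Pairs involving an RBD
#'   shorter than 10 aa are skipped with one warning.
#' @export
rbd_hits <- function(records, delineations, cfg = rbp_config()) {
  cfg <- as_rbp_config(cfg)
  rbds <- region_sequence(records, delineations, "rbd")
  ord <- order(names(rbds))
  rbds <- rbds[ord]
  short <- nchar(rbds) < 10
  if (any(short)) {
    warning("RBD shorter than 10 aa, excluded from hit search: ",
            paste(names(rbds)[short], collapse = ", "))
    rbds <- rbds[!short]
  }
  n <- length(rbds)
  if (n < 2) return(empty_hit_tbl())
  out <- vector("list", n - 1)
  for (j in seq(2, n)) {
    aln <- batch_align(rbds[seq_len(j - 1)], rbds[j], cfg, "local",
                       subject_id = names(rbds)[j])
    cov_q <- 100 * (aln$query_end - aln$query_start + 1) /
      nchar(rbds[seq_len(j - 1)])
    cov_s <- 100 * (aln$subject_end - aln$subject_start + 1) /
      nchar(rbds[j])
    out[[j - 1]] <- tibble(
      query_id = aln$query_id, subject_id = aln$subject_id,
      identity_pct = aln$identity_pct,
      coverage_pct = unname(cov_q),
      coverage_pct_subject = unname(cov_s),
      passes = aln$identity_pct >= cfg$hit_min_identity &
        (cov_q >= cfg$hit_min_coverage | cov_s >= cfg$hit_min_coverage)
    )
  }
  dplyr::bind_rows(out)
}

#' Pairwise identity matrix for a domain region
#'
#' Global pairwise alignment identity between all record pairs, computed on
#' the full protein, the anchor, or the RBD. The matrix is symmetric with a
#' diagonal of exactly 100 and is the input to the distance-based domain
#' phylogenies.
#'
#' @param records An RBP record tibble (>= 2 rows).
#' @param region One of `"full"`, `"anchor"`, `"rbd"`.
#' @param delineations Required when `region != "full"`.
#' @param cfg An [rbp_config()].
#' @return A square numeric matrix of percent identities with `rbp_id`
#'   dimnames and a `region` attribute.
#' @export
identity_matrix <- function(records, region = c("full", "anchor", "rbd"),
                            delineations = NULL, cfg = rbp_config()) {
  region <- match.arg(region)
  cfg <- as_rbp_config(cfg)
  if (nrow(records) < 2) stop("identity_matrix needs >= 2 records")
  seqs <- region_sequence(records, delineations, region)
  if (any(!nzchar(seqs))) {
    stop("empty ", region, " region for: ",
         paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  }
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (j in seq(2, n)) {
    aln <- batch_align(seqs[seq_len(j - 1)], seqs[j], cfg, "global")
    m[seq_len(j - 1), j] <- aln$identity_pct
    m[j, seq_len(j - 1)] <- aln$identity_pct
  }
  attr(m, "region") <- region
  m
}
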
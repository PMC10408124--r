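# build a record whose nt is a CDS (with stop) + downstream flank,
# aa derived by translation so the consistency invariant holds
nt_record <- function(id, n_codons = 250, flank = 120, seed = 1) {
  set.seed(seed)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   names(which(Biostrings::GENETIC_CODE == "*")))
  sense <- setdiff(sense, "ATG")  # avoid fuzzy translation corner cases
  cds <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  nt <- paste0(cds, "TAA",
               paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                     collapse = ""))
  make_record(id, aa, nt = nt)
}

test_that("flank windows are cut at the documented coordinates", {
  rec <- nt_record("r1", n_codons = 250, flank = 120)
  del <- tibble::tibble(rbp_id = "r1", anchor_end = 150L,
                        method = "curated", confidence = 1)
  fl <- extract_flanks(rec, del)
  b <- fl[fl$region == "boundary_flank", ]
  # anchor_end 150, halfwidth 150: CDS window nt 301..600 centred on 450
  expect_equal(b$start, 301L)
  expect_equal(b$end, 600L)
  expect_false(b$truncated)
  expect_equal(b$seq, substr(rec$nt_sequence, 301, 600))

  d <- fl[fl$region == "downstream_noncoding", ]
  expect_equal(d$start, 3L * 250L + 4L)
  expect_equal(d$end, 3L * 250L + 3L + 120L)
  expect_equal(d$rel_start, 1L)
  expect_false(d$truncated)
})

test_that("records without nucleotide sequence are skipped with a warning", {
  recs <- dplyr::bind_rows(nt_record("r1"),
                           make_record("r2", strrep("MKLVINSGGS", 30)))
  del <- tibble::tibble(rbp_id = c("r1", "r2"), anchor_end = 150L,
                        method = "curated", confidence = 1)
  expect_warning(fl <- extract_flanks(recs, del), "r2")
  expect_setequal(unique(fl$rbp_id), "r1")
})

test_that("windows truncated by the sequence edge are kept and flagged", {
  rec <- nt_record("r1", n_codons = 200, flank = 40)
  del <- tibble::tibble(rbp_id = "r1", anchor_end = 170L,
                        method = "curated", confidence = 1)
  fl <- extract_flanks(rec, del)
  d <- fl[fl$region == "downstream_noncoding", ]
  expect_true(d$truncated)            # only 40 of 120 nt available
  expect_equal(nchar(d$seq), 40L)
})

test_that("center-star alignment is exact on identical and toy windows", {
  same <- c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAC")
  aln <- star_msa(same)
  expect_equal(as.character(unclass(aln)), unname(same))

  # expected merge computed by hand: b carries a 2-nt insertion
  toy <- c(a = "ACGTACGTACGTACGT", b = "ACGTACGGGTACGTACGT",
           c = "ACGTACGTACGTACGT")
  aln <- star_msa(toy)
  expect_equal(unclass(aln)[["a"]], "ACGTACG--TACGTACGT")
  expect_equal(unclass(aln)[["b"]], "ACGTACGGGTACGTACGT")

  perm <- star_msa(toy[c(3, 1, 2)])
  expect_equal(unclass(perm)[names(aln)], unclass(aln)[names(aln)])
})

test_that("an all-identical alignment yields one full-span hit at 100%", {
  w <- rep("ACGTACGTACGTACGTACGT", 5)
  names(w) <- paste0("w", 1:5)
  aln <- star_msa(w)
  hits <- scan_conserved_windows(aln)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start_col, 1)
  expect_equal(hits$end_col, 20)
  expect_equal(hits$mean_identity_pct, 100)
  expect_equal(hits$sd_identity_pct, 0)
  expect_equal(hits$n_members, 5L)
})

test_that("a threshold above the planted identity yields zero hits", {
  sim <- simulate_motif_windows(n = 8, rate = 0.15, seed = 5)
  aln <- star_msa(sim$windows)
  none <- scan_conserved_windows(aln, rbp_config(motif_min_identity = 99,
                                                 motif_col_floor = 99))
  expect_equal(nrow(none), 0)
})

test_that("raising the identity threshold never lengthens a reported span", {
  sim <- simulate_motif_windows(n = 10, rate = 0.12, seed = 8)
  aln <- star_msa(sim$windows)
  prev_len <- Inf
  for (t in c(45, 55, 65, 75)) {
    hits <- scan_conserved_windows(aln, rbp_config(motif_min_identity = t))
    len <- if (nrow(hits)) max(hits$length) else 0
    expect_lte(len, prev_len)
    prev_len <- len
  }
})

test_that("reported mean +/- sd equals a brute-force all-pairs computation", {
  sim <- simulate_motif_windows(n = 5, rate = 0.2, seed = 12)
  aln <- star_msa(sim$windows)
  hits <- scan_conserved_windows(aln)
  expect_gte(nrow(hits), 1)
  hit <- hits[1, ]
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  cols <- seq(hit$start_col, hit$end_col)
  # keep only the dense columns the scanner reports on
  cols <- cols[colMeans(m[, cols, drop = FALSE] != "-") >= 0.5]
  ids <- hit$members[[1]]
  vals <- c()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq(i + 1, length(ids))) {
      x <- m[ids[i], cols]; y <- m[ids[j], cols]
      ok <- !(x == "-" & y == "-")
      vals <- c(vals, 100 * sum(x == y & x != "-") / sum(ok))
    }
  }
  expect_equal(hit$mean_identity_pct, mean(vals))
  expect_equal(hit$sd_identity_pct, stats::sd(vals))
})

test_that("a planted motif in random flanks is localized accurately", {
  sim <- simulate_motif_windows(n = 12, motif_len = 44, position = 106,
                                rate = 0.15, seed = 15)
  aln <- star_msa(sim$windows)
  hits <- scan_conserved_windows(aln)
  expect_gte(nrow(hits), 1)
  best <- hits[which.max(hits$length), ]
  inter <- max(0, min(best$span_end, 149) - max(best$span_start, 106) + 1)
  jac <- inter / (max(best$span_end, 149) - min(best$span_start, 106) + 1)
  expect_gte(jac, 0.9)
})

test_that("permutation p is exact for a perfectly conserved motif and reproducible", {
  set.seed(77)
  flank <- function() paste(sample(c("A", "C", "G", "T"), 120,
                                   replace = TRUE), collapse = "")
  motif <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                 collapse = "")
  w <- vapply(1:6, function(i) {
    f <- flank(); substr(f, 40, 59) <- motif; f
  }, character(1))
  names(w) <- paste0("w", 1:6)
  aln <- star_msa(w)
  hits <- scan_conserved_windows(aln)
  expect_equal(nrow(hits), 1)
  p1 <- motif_significance(hits[1, ], aln, seed = 42)
  p2 <- motif_significance(hits[1, ], aln, seed = 42)
  expect_identical(p1, p2)           # bitwise reproducible
  expect_equal(p1, 1 / (999 + 1))    # observed is maximal
})

test_that("p-values are calibrated when the 'motif' is background itself", {
  cfg <- rbp_config(motif_n_perm = 99L)
  ps <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    w <- vapply(1:5, function(i) {
      paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
            collapse = "")
    }, character(1))
    names(w) <- paste0("w", 1:5)
    aln <- star_msa(w, cfg)
    fake <- tibble::tibble(start_col = 30L, end_col = 49L, length = 20L,
                           members = list(names(w)))
    motif_significance(fake, aln, cfg, seed = s)
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.1)
})

test_that("consensus and PFM follow the modal-base and IUPAC tie rules", {
  sub <- rbind(c("A", "A"), c("A", "A"), c("A", "G"), c("A", "G"))
  colnames(sub) <- NULL
  cp <- consensus_and_pfm(sub)
  expect_equal(cp$consensus, "AR")   # A unanimous; A/G tie -> R
  expect_equal(unname(cp$pfm["A", 1]), 1)
  expect_equal(unname(cp$pfm["A", 2]), 0.5)
  expect_equal(unname(cp$pfm["G", 2]), 0.5)

  # noiseless planted motif: consensus equals the motif exactly
  sim <- simulate_motif_windows(n = 6, motif_len = 20, position = 50,
                                rate = 0, seed = 30)
  aln <- star_msa(sim$windows)
  hits <- scan_conserved_windows(aln)
  expect_true(grepl(sim$truth$motif, hits$consensus[1], fixed = TRUE))
})
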
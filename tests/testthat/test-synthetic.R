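test_that("generation is deterministic for a fixed config and seed", {
  cfg <- sim_config()
  s1 <- simulate_rbp_dataset(cfg, seed = 99)
  s2 <- simulate_rbp_dataset(cfg, seed = 99)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$records, s2$truth$records)
  expect_identical(s1$truth$motifs, s2$truth$motifs)
  s3 <- simulate_rbp_dataset(cfg, seed = 100)
  expect_false(identical(s1$records$aa_sequence, s3$records$aa_sequence))
})

test_that("realized identities stay within 5 points of the configured targets", {
  sim <- simulate_rbp_dataset(sim_config(n_redundant = 0, n_decoys = 0,
                                         n_unknown = 0), seed = 8)
  tr <- sim$truth$records
  del <- tibble::tibble(rbp_id = tr$rbp_id, anchor_end = tr$anchor_end,
                        method = "curated", confidence = 1)
  d <- sim_config()$anchor_divergence
  p_match <- function(r1, r2) (1 - r1) * (1 - r2) + r1 * r2 / 19

  # within-genus anchors (stratum mean per genus)
  m_anchor <- identity_matrix(sim$records, "anchor", del)
  for (g in unique(tr$genus)) {
    ids <- tr$rbp_id[tr$genus == g]
    off <- m_anchor[ids, ids][upper.tri(diag(length(ids)))]
    expect_lte(abs(mean(off) - 100 * p_match(d, d)), 5)
  }

  # within-family RBDs: stratum mean against the expectation from each
  # record's drawn substitution rate
  m_rbd <- identity_matrix(sim$records, "rbd", del)
  obs <- c(); expd <- c()
  for (f in unique(tr$family)) {
    ids <- tr$rbp_id[tr$family == f]
    if (length(ids) < 2) next
    for (i in seq_along(ids)[-length(ids)]) {
      for (j in seq(i + 1, length(ids))) {
        r1 <- tr$rbd_rate[tr$rbp_id == ids[i]]
        r2 <- tr$rbd_rate[tr$rbp_id == ids[j]]
        obs <- c(obs, m_rbd[ids[i], ids[j]])
        expd <- c(expd, 100 * p_match(r1, r2))
      }
    }
  }
  expect_lte(abs(mean(obs) - mean(expd)), 5)

  # cross-family RBDs sit near background, far below the hit threshold
  cross <- c()
  fams <- tr$family[match(rownames(m_rbd), tr$rbp_id)]
  for (i in seq_len(nrow(m_rbd) - 1)) {
    for (j in seq(i + 1, ncol(m_rbd))) {
      if (fams[i] != fams[j]) cross <- c(cross, m_rbd[i, j])
    }
  }
  expect_lt(mean(cross), 25)
})

test_that("zero mutation rates give identical family members and anchors", {
  cfg <- sim_config(n_genera = 2, n_per_genus = 2, n_families = 2,
                    anchor_divergence = 0, rbd_divergence_max = 0,
                    motif_boundary_rate = 0, motif_downstream_rate = 0,
                    n_redundant = 0, n_decoys = 0, n_unknown = 0)
  sim <- simulate_rbp_dataset(cfg, seed = 4)
  tr <- sim$truth$records
  rbd_of <- function(id) {
    r <- sim$records[sim$records$rbp_id == id, ]
    substr(r$aa_sequence, tr$anchor_end[tr$rbp_id == id] + 1,
           nchar(r$aa_sequence))
  }
  for (f in unique(tr$family)) {
    ids <- tr$rbp_id[tr$family == f]
    expect_equal(length(unique(vapply(ids, rbd_of, character(1)))), 1)
  }
  anchor_of <- function(id) {
    r <- sim$records[sim$records$rbp_id == id, ]
    substr(r$aa_sequence, 1, tr$anchor_end[tr$rbp_id == id])
  }
  for (g in unique(tr$genus)) {
    ids <- tr$rbp_id[tr$genus == g]
    expect_equal(length(unique(vapply(ids, anchor_of, character(1)))), 1)
  }
})

test_that("decoy clusters with mixed labels are rejected as inconsistent", {
  sim <- simulate_rbp_dataset(sim_config(n_decoys = 1, decoy_size = 4),
                              seed = 6)
  res <- run_rbp_pipeline(sim$records, scan_motifs = FALSE)
  dec <- res$assignments[vapply(res$assignments$member_rbp_ids,
                                function(ids) any(ids %in%
                                                    sim$truth$decoy_ids),
                                logical(1)), ]
  expect_true(all(dec$rejection_reason == "inconsistent"))

  unk <- res$assignments[vapply(res$assignments$member_rbp_ids,
                                function(ids) any(ids %in%
                                                    sim$truth$unknown_ids),
                                logical(1)), ]
  expect_true(all(unk$rejection_reason == "insufficient_data"))
})

test_that("experimental assignment implies the consensus criterion holds too", {
  sim <- simulate_rbp_dataset(sim_config(), seed = 23)
  res <- run_rbp_pipeline(sim$records, scan_motifs = FALSE)
  a <- res$assignments
  exp_rows <- a[a$assignment_basis %in% c("experimental_rbp",
                                          "experimental_phage"), ]
  expect_gt(nrow(exp_rows), 0)
  for (i in seq_len(nrow(exp_rows))) {
    votes <- exp_rows$serogroups_observed[[i]]
    tab <- table(votes)
    expect_gte(length(votes), 2)
    expect_gte(max(tab) / length(votes), 0.9)
  }
})

test_that("recovery metrics behave at both extremes", {
  sim <- simulate_rbp_dataset(sim_config(), seed = 19)
  res <- run_rbp_pipeline(sim$records, scan_motifs = FALSE)
  rr <- recovery_report(res, sim$truth)
  expect_equal(rr$ari, 1)
  expect_equal(rr$assignment_accuracy, 1)
  expect_equal(rr$decoy_false_assignments, 0L)
  expect_true(rr$redundancy_correct)

  # shuffling the partition labels destroys the agreement
  set.seed(19)
  aris <- vapply(1:20, function(i) {
    shuffled <- sample(res$subtypes$subtype_id)
    mclust::adjustedRandIndex(
      shuffled,
      sim$truth$records$family[match(res$subtypes$rbp_id,
                                     sim$truth$records$rbp_id)])
  }, numeric(1))
  expect_lt(mean(abs(aris)), 0.05)
})

test_that("defaulted boundaries against a planted 180 give mean error 30", {
  cfg <- sim_config(n_genera = 2, n_per_genus = 2, n_families = 2,
                    anchor_len_range = c(180L, 180L),
                    n_redundant = 0, n_decoys = 0, n_unknown = 0)
  sim <- simulate_rbp_dataset(cfg, seed = 2)
  d <- delineate_domains(sim$records, use_breakpoint = FALSE)
  expect_true(all(d$method == "default_cutoff"))
  err <- abs(d$anchor_end - 180L)
  expect_equal(mean(err), 30)
})

test_that("written truth and dataset serialize losslessly alongside each other", {
  sim <- simulate_rbp_dataset(sim_config(n_genera = 2, n_per_genus = 2,
                                         n_families = 2), seed = 41)
  dir <- withr::local_tempdir()
  write_simulated_dataset(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("aa.fasta", "nt.fasta",
                                               "metadata.tsv",
                                               "truth.json")))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$records$rbp_id, sim$truth$records$rbp_id)
  expect_equal(truth$motifs$seq, sim$truth$motifs$seq)
})

test_that("planted flanking motifs are recovered end to end", {
  for (s in c(1, 5, 7)) {
    sim <- simulate_rbp_dataset(sim_config(), seed = s)
    res <- run_rbp_pipeline(sim$records, scan_motifs = TRUE, seed = s)
    mr <- motif_recovery(res, sim$truth)
    down <- mr[mr$region == "downstream_noncoding", ]
    expect_gte(down$jaccard, 0.9)
    expect_lte(down$permutation_p, 0.01)
    bound <- mr[mr$region == "boundary_flank", ]
    # the boundary motif abuts the cross-genus-conserved RBD start, so the
    # detected window may extend into it; require detection with overlap
    # and significance
    expect_gt(bound$jaccard, 0)
    expect_lte(bound$permutation_p, 0.01)
  }
})
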
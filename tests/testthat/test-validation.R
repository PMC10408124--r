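cluster_of <- function(serogroups, evidence = NULL, genus = NULL) {
  n <- length(serogroups)
  if (is.null(evidence)) evidence <- rep(NA_character_, n)
  if (is.null(genus)) genus <- rep("genusA", n)
  sg_ev <- dplyr::case_when(evidence %in% "A" ~ "rbp_level",
                            evidence %in% "B" ~ "phage_level",
                            TRUE ~ "host_strain")
  recs <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_record(sprintf("r%02d", i), "MKLVINSGGST", genus = genus[i],
                serogroup = serogroups[i], evidence = evidence[i],
                sg_evidence = sg_ev[i])
  }))
  subtypes <- tibble::tibble(rbp_id = recs$rbp_id, subtype_id = "r01")
  list(records = recs, subtypes = subtypes)
}

test_that("experimental members assign their serogroup to the whole subtype", {
  cl <- cluster_of(c("O157", "O26", "O26"), evidence = c("A", NA, NA))
  a <- assign_serogroups(cl$records, cl$subtypes)
  expect_equal(a$assigned_serogroup, "O157")
  expect_equal(a$assignment_basis, "experimental_rbp")

  cl <- cluster_of(c("O103", "O103"), evidence = c("B", NA))
  a <- assign_serogroups(cl$records, cl$subtypes)
  expect_equal(a$assignment_basis, "experimental_phage")

  # conflicting RBP-level evidence is a data contradiction, never resolved
  cl <- cluster_of(c("O157", "O77"), evidence = c("A", "A"))
  expect_error(assign_serogroups(cl$records, cl$subtypes), "conflicting")
})

test_that("consensus sits exactly at the 90% boundary with a minimum of two", {
  # 9 of 10 = 90% >= 90%: assigned
  cl <- cluster_of(c(rep("O26", 9), "O111"))
  a <- assign_serogroups(cl$records, cl$subtypes)
  expect_equal(a$assigned_serogroup, "O26")
  expect_equal(a$assignment_basis, "consensus")

  # 8 of 10 = 80% < 90%: inconsistent
  cl <- cluster_of(c(rep("O26", 8), "O111", "O145"))
  a <- assign_serogroups(cl$records, cl$subtypes)
  expect_equal(a$rejection_reason, "inconsistent")

  # a single known vote: insufficient data
  cl <- cluster_of(c("O26", NA, NA))
  a <- assign_serogroups(cl$records, cl$subtypes)
  expect_equal(a$rejection_reason, "insufficient_data")
  expect_equal(a$n_known, 1L)

  # modal tie can never reach 90% with two voters: inconsistent
  cl <- cluster_of(c("O26", "O111"))
  a <- assign_serogroups(cl$records, cl$subtypes)
  expect_equal(a$rejection_reason, "inconsistent")

  # unknown votes neither support nor veto
  cl <- cluster_of(c("O26", "O26", NA, NA, NA))
  a <- assign_serogroups(cl$records, cl$subtypes)
  expect_equal(a$assigned_serogroup, "O26")
})

test_that("serogroup votes of removed doubles still count in the consensus", {
  recs <- dplyr::bind_rows(
    make_record("keep", "MKLVINSGGST", serogroup = "O26"),
    make_record("dbl", "MKLVINSGGST", serogroup = "O26")
  )
  subtypes0 <- tibble::tibble(rbp_id = recs$rbp_id, subtype_id = "keep")
  kept <- dedupe_within_genus(recs, subtypes0)
  expect_equal(nrow(kept), 1)
  a <- assign_serogroups(kept, subtypes0[subtypes0$rbp_id %in% kept$rbp_id, ])
  expect_equal(a$n_known, 2L)  # member + its double
  expect_equal(a$assigned_serogroup, "O26")
})

test_that("raising the consensus fraction never assigns more subtypes", {
  sim <- simulate_rbp_dataset(sim_config(), seed = 13)
  res <- run_rbp_pipeline(sim$records, scan_motifs = FALSE)
  n_prev <- Inf
  for (f in c(0.5, 0.75, 0.9, 0.99)) {
    a <- assign_serogroups(res$kept, res$subtypes,
                           rbp_config(consensus_fraction = f))
    n <- sum(a$rejection_reason == "none")
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("the genus filter drops assigned RBPs of under-represented genera", {
  recs <- dplyr::bind_rows(
    make_record("a1", "MKLVINSGGST", genus = "big", serogroup = "O26"),
    make_record("a2", "MKLVINSGGST", genus = "big", serogroup = "O26"),
    make_record("b1", "MKLVINSGGST", genus = "small", serogroup = "O103"),
    make_record("c1", "MKLVINSGGST", genus = "empty")
  )
  subtypes <- tibble::tibble(
    rbp_id = c("a1", "a2", "b1", "c1"),
    subtype_id = c("a1", "a1", "b1", "c1"))
  asg <- dplyr::bind_rows(
    tibble::tibble(subtype_id = "a1", assigned_serogroup = "O26",
                   rejection_reason = "none"),
    tibble::tibble(subtype_id = "b1", assigned_serogroup = "O103",
                   rejection_reason = "none"),
    tibble::tibble(subtype_id = "c1", assigned_serogroup = NA_character_,
                   rejection_reason = "insufficient_data"))
  fin <- genus_filter(recs, subtypes, asg)
  expect_setequal(fin$rbp_id, c("a1", "a2"))           # genus "big" kept
  expect_equal(attr(fin, "dropped")$rbp_id, "b1")      # singleton genus out
  expect_equal(fin$assigned_serogroup, c("O26", "O26"))
})

test_that("the ledger telescopes and flags uncategorized records", {
  sim <- simulate_rbp_dataset(sim_config(), seed = 17)
  res <- run_rbp_pipeline(sim$records, scan_motifs = FALSE)
  led <- res$ledger
  t <- led$totals
  expect_equal(t$n_assigned_subtypes + t$n_inconsistent_subtypes +
                 t$n_insufficient_subtypes, t$n_subtypes)
  expect_equal(t$n_final_rbps + t$n_omitted_by_genus_filter +
                 t$n_inconsistent_rbps + t$n_insufficient_rbps,
               t$n_records)
  expect_equal(nrow(led$record_categories), t$n_records)
  expect_true(all(table(led$record_categories$rbp_id) == 1))
})

test_that("published group tallies telescope to the printed dataset totals", {
  tal <- tally_study_dataset(study_group_counts())
  expect_identical(tal$initial_selection, 17L)
  expect_identical(tal$initial_dataset, 20L)
  expect_identical(tal$group_d, 9L)
  expect_identical(tal$expanded_dataset, 136L)
  expect_identical(sum(study_prophage_counts()$n), 9L)
})
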
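test_that("aligning a sequence to itself gives 100% identity over full length", {
  a <- "MKLVINSGGSTTAYKLP"
  aln <- align_local(a, a)
  expect_equal(aln$identity_pct, 100)
  expect_equal(aln$query_start, 1)
  expect_equal(aln$query_end, nchar(a))
  expect_equal(aln$n_identical, nchar(a))
})

test_that("local alignment matches the independent DP oracle on a worked pair", {
  # expected values computed with the pure-R Gotoh oracle in
  # helper-oracles.R (BLOSUM62, gap open 11, extend 1)
  o <- oracle_align("ACDEFGHIK", "ACDEYGHIK", blosum62, 11, 1, "local")
  expect_equal(o$score, 50)
  expect_equal(o$n_columns, 9)
  expect_equal(o$n_identical, 8)
  aln <- align_local("ACDEFGHIK", "ACDEYGHIK")
  expect_equal(aln$score, o$score)
  expect_equal(aln$identity_pct, 100 * o$n_identical / o$n_columns)
})

test_that("scores equal the DP oracle on pairs of short 4-letter sequences", {
  set.seed(101)
  seqs <- vapply(1:24, function(i) random_aa_seq(sample(2:8, 1)),
                 character(1))
  for (i in seq_along(seqs)) {
    for (j in seq(i, length(seqs))) {
      for (type in c("local", "global")) {
        o <- oracle_align(seqs[i], seqs[j], blosum62, 11, 1, type)
        f <- if (type == "local") align_local(seqs[i], seqs[j]) else
          align_global(seqs[i], seqs[j])
        expect_equal(f$score, o$score,
                     info = paste(type, seqs[i], seqs[j]))
      }
    }
  }
})

test_that("illegal or empty sequences are rejected", {
  expect_error(align_local("", "ACD"), "nonempty")
  expect_error(align_local("ACD", ""), "nonempty")
  expect_error(align_local("AC1D", "ACD"), "alphabet")
})

test_that("rbd_hit is a symmetric edge predicate and respects the criterion", {
  anchor <- strrep("MKLVINSGGST", 15)            # 165 aa shared anchor
  set.seed(7)
  rbd1 <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"),
                       320, replace = TRUE), collapse = "")
  v <- strsplit(rbd1, "")[[1]]
  idx <- sample(320, 130)  # ~60% identity variant
  v[idx] <- sample(c("M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                   130, replace = TRUE)
  rbd2 <- paste(v, collapse = "")
  q <- make_record("q", toy_rbp(anchor, rbd1))
  s <- make_record("s", toy_rbp(anchor, rbd2))
  del <- delineate_domains(dplyr::bind_rows(q, s), use_breakpoint = FALSE)
  h_qs <- rbd_hit(q, s, del)
  h_sq <- rbd_hit(s, q, del)
  expect_true(h_qs$passes)
  expect_equal(h_qs$passes, h_sq$passes)
  expect_equal(h_qs$identity_pct, h_sq$identity_pct)

  # RBD below 10 aa: no hit, warning
  tiny <- make_record("t", paste0(substr(toy_rbp(anchor, rbd1), 1, 155),
                                  "AAAA"))
  del2 <- dplyr::bind_rows(del, tibble::tibble(rbp_id = "t",
                                               anchor_end = 155L,
                                               method = "curated",
                                               confidence = 1))
  expect_warning(h <- rbd_hit(q, tiny, del2), "shorter")
  expect_equal(nrow(h), 0)
})

test_that("unrelated random RBDs essentially never pass the 30/60 criterion", {
  set.seed(202)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  n_pass <- 0L
  for (k in 1:100) {
    r1 <- paste(sample(aa, 300, replace = TRUE), collapse = "")
    r2 <- paste(sample(aa, 300, replace = TRUE), collapse = "")
    recs <- dplyr::bind_rows(make_record("a", paste0(strrep("M", 151), r1)),
                             make_record("b", paste0(strrep("M", 151), r2)))
    del <- tibble::tibble(rbp_id = c("a", "b"), anchor_end = 151L,
                          method = "curated", confidence = 1)
    h <- rbd_hits(recs, del)
    n_pass <- n_pass + sum(h$passes)
  }
  expect_equal(n_pass, 0L)
})

test_that("raising thresholds never creates a new passing pair", {
  sim <- simulate_rbp_dataset(sim_config(n_genera = 3, n_per_genus = 2,
                                         n_families = 3, n_redundant = 0,
                                         n_decoys = 0, n_unknown = 0),
                              seed = 5)
  del <- suppressWarnings(delineate_domains(sim$records))
  base <- rbd_hits(sim$records, del, rbp_config())
  for (cfg2 in list(rbp_config(hit_min_identity = 45),
                    rbp_config(hit_min_coverage = 80),
                    rbp_config(hit_min_identity = 45,
                               hit_min_coverage = 80))) {
    strict <- rbd_hits(sim$records, del, cfg2)
    expect_true(all(strict$passes <= base$passes))
  }
})

test_that("identity matrices are symmetric with diagonal 100 and match the oracle", {
  dup <- dplyr::bind_rows(make_record("a", "MKLVINSGGSTT"),
                          make_record("b", "MKLVINSGGSTT"))
  m <- identity_matrix(dup, region = "full")
  expect_equal(m["a", "b"], 100)

  seqs <- c(x = "ACDEFG", y = "ACDEYG", z = "ACKKFG")
  recs <- dplyr::bind_rows(lapply(names(seqs),
                                  function(n) make_record(n, seqs[[n]])))
  m <- identity_matrix(recs, region = "full")
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 3))
  for (i in 1:2) for (j in seq(i + 1, 3)) {
    o <- oracle_align(seqs[[i]], seqs[[j]], blosum62, 11, 1, "global")
    expect_equal(m[i, j], 100 * o$n_identical / o$n_columns)
  }
})

test_that("same-genus anchors at 5% planted divergence land in [90, 100]", {
  sim <- simulate_rbp_dataset(sim_config(n_genera = 1, n_per_genus = 3,
                                         n_families = 3, n_redundant = 0,
                                         n_decoys = 0, n_unknown = 0),
                              seed = 9)
  del <- tibble::tibble(rbp_id = sim$truth$records$rbp_id,
                        anchor_end = sim$truth$records$anchor_end,
                        method = "curated", confidence = 1)
  m <- identity_matrix(sim$records, region = "anchor", delineations = del)
  off <- m[upper.tri(m)]
  expect_true(all(off >= 90 & off <= 100))
})
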
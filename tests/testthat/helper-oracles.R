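# Independent oracles used across the suite. All are deliberately naive
# implementations that share no code with the package internals.

# Affine-gap dynamic programming (Gotoh), pure R. A gap of length L costs
# gap_open + L * gap_ext. Returns the optimal score plus the column and
# identity counts of one optimal alignment (traceback prefers the
# match/mismatch state on ties).
oracle_align <- function(a, b, submat, gap_open = 11, gap_ext = 1,
                         type = c("global", "local")) {
  type <- match.arg(type)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in aligned pair
  X <- matrix(NEG, n + 1, m + 1)  # ends with gap in b (a aligned to gap)
  Y <- matrix(NEG, n + 1, m + 1)  # ends with gap in a
  M[1, 1] <- 0
  if (type == "global") {
    for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + i * gap_ext)
    for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + j * gap_ext)
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[av[i], bv[j]]
      best_prev <- max(M[i, j], X[i, j], Y[i, j])
      M[i + 1, j + 1] <- best_prev + s
      if (type == "local") M[i + 1, j + 1] <- max(0, M[i + 1, j + 1])
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                             X[i, j + 1] - gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                             Y[i + 1, j] - gap_ext)
    }
  }
  if (type == "global") {
    score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
    end <- c(n, m)
  } else {
    score <- max(M)
    end <- which(M == score, arr.ind = TRUE)[1, ] - 1L
  }
  tb <- oracle_traceback(M, X, Y, av, bv, submat, gap_open, gap_ext,
                         end[1], end[2], type)
  list(score = score, n_columns = tb$n_columns,
       n_identical = tb$n_identical)
}

oracle_traceback <- function(M, X, Y, av, bv, submat, gap_open, gap_ext,
                             i, j, type) {
  eps <- 1e-9
  cand <- c(M = M[i + 1, j + 1], X = X[i + 1, j + 1], Y = Y[i + 1, j + 1])
  state <- names(cand)[which.max(cand)]
  n_columns <- 0L; n_identical <- 0L
  repeat {
    if (type == "global" && i == 0 && j == 0) break
    if (state == "M") {
      cur <- M[i + 1, j + 1]
      if (type == "local" && cur <= eps) break
      n_columns <- n_columns + 1L
      if (av[i] == bv[j]) n_identical <- n_identical + 1L
      prev <- cur - submat[av[i], bv[j]]
      i <- i - 1; j <- j - 1
      if (type == "global" && i == 0 && j == 0) break
      cand <- c(M = M[i + 1, j + 1], X = X[i + 1, j + 1],
                Y = Y[i + 1, j + 1])
      hit <- names(cand)[abs(cand - prev) <= eps]
      if (!length(hit)) break  # local: restart from the zero floor
      state <- hit[1]          # prefer M on ties
    } else if (state == "X") {
      cur <- X[i + 1, j + 1]
      n_columns <- n_columns + 1L
      from_open <- M[i, j + 1] - gap_open - gap_ext
      i <- i - 1
      state <- if (abs(cur - from_open) <= eps) "M" else "X"
    } else {
      cur <- Y[i + 1, j + 1]
      n_columns <- n_columns + 1L
      from_open <- M[i + 1, j] - gap_open - gap_ext
      j <- j - 1
      state <- if (abs(cur - from_open) <= eps) "M" else "Y"
    }
  }
  list(n_columns = n_columns, n_identical = n_identical)
}

# Brute-force connected components by breadth-first search over an edge
# list; returns membership named by vertex.
oracle_components <- function(vertices, edges) {
  adj <- stats::setNames(vector("list", length(vertices)), vertices)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- stats::setNames(rep(NA_character_, length(vertices)), vertices)
  for (v in vertices) {
    if (!is.na(comp[v])) next
    queue <- v
    seen <- character(0)
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (u %in% seen) next
      seen <- c(seen, u)
      queue <- c(queue, adj[[u]])
    }
    comp[seen] <- min(seen)
  }
  comp
}

# Exhaustive least-squares fit of the three unrooted 4-taxon topologies;
# returns the index (1: AB|CD, 2: AC|BD, 3: AD|BC) with smallest residual.
oracle_best_quartet <- function(d) {
  stopifnot(nrow(d) == 4)
  pairs <- t(utils::combn(4, 2))
  y <- d[pairs]
  designs <- list(
    rbind(c(1,1,0,0,0), c(1,0,1,0,1), c(1,0,0,1,1), c(0,1,1,0,1),
          c(0,1,0,1,1), c(0,0,1,1,0)),
    rbind(c(1,1,0,0,1), c(1,0,1,0,0), c(1,0,0,1,1), c(0,1,1,0,1),
          c(0,1,0,1,0), c(0,0,1,1,1)),
    rbind(c(1,1,0,0,1), c(1,0,1,0,1), c(1,0,0,1,0), c(0,1,1,0,0),
          c(0,1,0,1,1), c(0,0,1,1,1))
  )
  rss <- vapply(designs, function(A) {
    fit <- stats::lm.fit(A, y)
    sum(fit$residuals^2)
  }, numeric(1))
  which.min(rss)
}

# Tiny helpers shared by tests ----------------------------------------------

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  get("BLOSUM62", envir = env)
})

random_aa_seq <- function(len, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

make_record <- function(rbp_id, aa, genus = "genusA", serogroup = NA,
                        evidence = NA, sg_evidence = "unknown",
                        source = "phage", score = NA_real_,
                        strain = NA_character_, split = FALSE,
                        nt = NA_character_, index = 1L) {
  tibble::tibble(
    rbp_id = rbp_id, phage_id = rbp_id, genus = genus,
    lifestyle = "unknown", source = source, rbp_index = index,
    aa_sequence = aa, nt_sequence = nt,
    evidence_group = evidence, host_strain = strain,
    host_serogroup = serogroup, serogroup_evidence = sg_evidence,
    prophage_score = score, curated_anchor_end = NA_integer_,
    split_rbp = split
  )
}

# A modular toy protein: shared anchor prefix + family-specific RBD.
toy_rbp <- function(anchor, rbd) paste0(anchor, rbd)
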
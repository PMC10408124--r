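#' Distance matrix from a percent-identity matrix
#'
#' Maps percent identity linearly onto `[0, 1]` distances: `d = 1 -
#' identity / 100`, so identical sequences are at distance 0 and completely
#' dissimilar ones at 1.
#'
#' @param identity Square symmetric percent-identity matrix (diagonal 100),
#'   e.g. from [identity_matrix()].
#' @return A symmetric numeric distance matrix with zero diagonal and the
#'   same dimnames; the `region` attribute is carried over.
#' @export
distances_from_identity <- function(identity) {
  stopifnot(is.matrix(identity), nrow(identity) == ncol(identity))
  d <- 1 - identity / 100
  diag(d) <- 0
  attr(d, "region") <- attr(identity, "region")
  d
}

#' Neighbor-joining tree
#'
#' Builds an unrooted tree from a distance matrix by standard
#' neighbor-joining agglomeration. Negative branch lengths, which NJ can
#' produce on non-additive input, are clamped to 0 with the deficit moved
#' to the sister branch so that path lengths are preserved. Ties in the
#' join criterion are broken by the lexicographically smallest pair of
#' member labels, making the result invariant to taxon input order.
#'
#' @param d Symmetric distance matrix with taxon dimnames (>= 2 taxa).
#' @return An [ape::read.tree()] `phylo` object; with 2 taxa a single-edge
#'   tree carrying the full distance, no NJ step.
#' @examples
#' d <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ape::write.tree(nj_tree(d))
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  n <- nrow(d)
  if (n < 2) stop("nj_tree needs >= 2 taxa")
  labels <- rownames(d)
  if (n == 2) {
    nwk <- sprintf("(%s:%.10g,%s:%.10g);", labels[1], d[1, 2] / 2,
                   labels[2], d[1, 2] / 2)
    return(ape::read.tree(text = nwk))
  }
  # per-node newick fragment and a sort key (smallest member label)
  node <- labels
  key <- labels
  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        cand_key <- sort(c(key[i], key[j]))
        if (is.null(best) || q[i, j] < best$q - 1e-12 ||
            (abs(q[i, j] - best$q) <= 1e-12 &&
             (cand_key[1] < best$key[1] ||
              (cand_key[1] == best$key[1] && cand_key[2] < best$key[2])))) {
          best <- list(i = i, j = j, q = q[i, j], key = cand_key)
        }
      }
    }
    i <- best$i; j <- best$j
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    bl <- clamp_pair(li, lj)
    new_node <- sprintf("(%s:%.10g,%s:%.10g)", node[i], bl[1], node[j], bl[2])
    new_key <- min(key[i], key[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    node <- c(node[keep], new_node)
    key <- c(key[keep], new_key)
    rownames(d2) <- colnames(d2) <- paste0("n", seq_len(m - 1))
    d <- d2
  }
  # final star of three nodes
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ls <- clamp_star(c(l1, l2, l3))
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 node[1], ls[1], node[2], ls[2], node[3], ls[3])
  ape::read.tree(text = nwk)
}

clamp_pair <- function(a, b) {
  if (a < 0) { b <- b + a; a <- 0 }
  if (b < 0) { a <- max(0, a + b); b <- 0 }
  c(a, b)
}

clamp_star <- function(x) {
  for (i in seq_along(x)) {
    if (x[i] < 0) {
      sib <- which.max(x)
      x[sib] <- x[sib] + x[i]
      x[i] <- 0
    }
  }
  pmax(x, 0)
}

#' Nearest-neighbor label concordance
#'
#' Quantifies how well a labelling (phage genus, host serogroup, ...)
#' agrees with a distance structure: the fraction of taxa whose nearest
#' neighbor (smallest off-diagonal distance, ties broken by
#' lexicographically smallest taxon id) carries the same label. Taxa whose
#' label occurs only once cannot have a same-label neighbor and are
#' excluded from the denominator. This is the statistic used to express
#' "anchors cluster by genus, RBDs by serogroup" as a number.
#'
#' @param d Symmetric distance matrix with taxon dimnames.
#' @param labels Character vector of labels, either named by taxon or in
#'   matrix order; `NA` labels are treated as singletons.
#' @return The concordance fraction in `[0, 1]`, with the evaluated taxon
#'   count in `attr(, "n")`. All-singleton labellings are an error.
#' @export
label_concordance <- function(d, labels) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  ids <- rownames(d)
  if (!is.null(names(labels))) labels <- labels[ids]
  stopifnot(length(labels) == nrow(d))
  tab <- table(labels, useNA = "no")
  eval_ok <- !is.na(labels) & labels %in% names(tab)[tab >= 2]
  if (!any(eval_ok)) stop("all labels are singletons; concordance undefined")
  agree <- vapply(which(eval_ok), function(i) {
    dd <- d[i, ]
    dd[i] <- Inf
    nn <- which(dd == min(dd))
    nn <- nn[order(ids[nn])][1]
    isTRUE(unname(labels[nn]) == unname(labels[i]))
  }, logical(1))
  structure(mean(agree), n = sum(eval_ok))
}
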
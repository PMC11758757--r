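# p-distance matrices from genotype cohorts and Saitou-Nei neighbor joining
# with deterministic tie-breaking.

#' Pairwise p-distance matrix from a genotype cohort
#'
#' For each sample pair, over the sites where both are genotyped, the site
#' distance is `|dosage_i - dosage_j| / 2` and the pair distance is the
#' mean over those sites (the allele-sharing convention used by VCF-based
#' distance tools). `measure = "shared"` instead scores a site 0 when the
#' genotypes are identical, 0.5 when they share one allele, 1 otherwise —
#' which differs from the dosage difference only for opposite-homozygote
#' vs heterozygote comparisons.
#'
#' @param cohort Variant cohort tibble.
#' @param measure `"dosage"` (default) or `"shared"`.
#' @return A symmetric numeric matrix with sample IDs as dimnames and a
#'   `pair_n` attribute holding the per-pair number of co-genotyped sites.
#' @export
p_distance_matrix <- function(cohort, measure = c("dosage", "shared")) {
  measure <- match.arg(measure)
  assert_cohort(cohort)
  m <- dosage_matrix(cohort)
  samples <- colnames(m)
  ns <- length(samples)
  if (ns < 2) abort("p-distance needs at least two samples")
  D <- matrix(0, ns, ns, dimnames = list(samples, samples))
  N <- matrix(0L, ns, ns, dimnames = list(samples, samples))
  for (i in seq_len(ns - 1)) {
    di <- m[, i]
    for (j in seq(i + 1, ns)) {
      dj <- m[, j]
      ok <- !is.na(di) & !is.na(dj)
      n_ok <- sum(ok)
      if (n_ok == 0) {
        abort(paste0("no shared genotyped site for pair ", samples[i], " / ",
                     samples[j]))
      }
      d <- if (measure == "dosage") {
        mean(abs(di[ok] - dj[ok])) / 2
      } else {
        a <- di[ok]; b <- dj[ok]
        mean(ifelse(a == b, 0, ifelse(a == 1L | b == 1L, 0.5, 1)))
      }
      D[i, j] <- D[j, i] <- d
      N[i, j] <- N[j, i] <- n_ok
    }
  }
  diag(N) <- as.integer(colSums(!is.na(m)))
  attr(D, "pair_n") <- N
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q-criterion. The
#' minimizing pair is chosen deterministically: exact ties on Q are broken
#' by the lexicographic order of the joined subtrees' smallest leaf labels,
#' which also makes the result invariant to taxon-order permutations.
#' Negative branch lengths (possible on non-additive input) are clamped to
#' zero and the total clamped deficit is recorded in the `clamped` attribute.
#' On an additive matrix, NJ recovers the generating topology and branch
#' lengths exactly.
#'
#' @param dm Symmetric distance matrix with taxon dimnames (at least 3).
#' @return An unrooted [ape::phylo] tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) abort("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- paste0("t", seq_len(n))
  }
  if (max(abs(dm - t(dm))) > 1e-8) abort("distance matrix is not symmetric")
  labels <- rownames(dm)
  if (anyDuplicated(labels)) abort("duplicate taxon labels")

  clamp <- function(x) pmax(x, 0)
  deficit <- 0
  newick <- labels     # growing subtree strings
  rank_lab <- labels   # smallest leaf label inside each subtree (tie-break)
  D <- dm

  fmt <- function(x) sprintf("%.12g", x)

  while (length(newick) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      pr <- sort(c(rank_lab[cand[k, 1]], rank_lab[cand[k, 2]]))
      paste(pr, collapse = "\r")
    }, character(1))
    pick <- cand[order(key)[1], ]
    i <- min(pick); j <- max(pick)

    bi <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    deficit <- deficit + sum(pmin(c(bi, bj), 0))
    bi <- clamp(bi); bj <- clamp(bj)

    # order children by tie-break label for a canonical string
    ord <- order(c(rank_lab[i], rank_lab[j]))
    kids <- c(paste0(newick[i], ":", fmt(bi)),
              paste0(newick[j], ":", fmt(bj)))[ord]
    new_str <- paste0("(", kids[1], ",", kids[2], ")")
    new_rank <- min(rank_lab[i], rank_lab[j])
    d_new <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    d_new <- d_new[-c(i, j)]

    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, d_new), c(d_new, 0))
    newick <- c(newick[-c(i, j)], new_str)
    rank_lab <- c(rank_lab[-c(i, j)], new_rank)
  }

  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  deficit <- deficit + sum(pmin(c(b1, b2, b3), 0))
  b <- clamp(c(b1, b2, b3))
  ord <- order(rank_lab)
  parts <- paste0(newick, ":", fmt(b))[ord]
  tree <- ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
  attr(tree, "clamped") <- -deficit
  tree
}

#' Neighbor-joining tree straight from a genotype cohort
#'
#' Convenience wrapper: [p_distance_matrix()] then [nj_tree()].
#'
#' @inheritParams p_distance_matrix
#' @return An unrooted [ape::phylo] tree.
#' @export
cohort_nj_tree <- function(cohort, measure = c("dosage", "shared")) {
  nj_tree(p_distance_matrix(cohort, measure = measure))
}
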
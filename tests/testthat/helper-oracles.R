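# Independent brute-force oracles and small fixture builders. Each oracle is
# a deliberately naive second implementation (loops, literal formulas,
# enumeration) kept separate from the package's code paths.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# --- fixture builders -------------------------------------------------------

toy_cohort <- function(dosages, chrom = "chr01", pos = NULL,
                       vtype = "SNP", length = 1L) {
  # dosages: matrix sites x samples with sample column names
  if (is.null(pos)) pos <- seq_len(nrow(dosages)) * 1000L
  bind_cols(
    tibble(chrom = chrom, pos = as.integer(pos),
           vtype = rep_len(vtype, nrow(dosages)),
           length = as.integer(rep_len(length, nrow(dosages)))),
    as_tibble(dosages)
  )
}

random_dosages <- function(n_sites, samples, miss_rate = 0) {
  d <- matrix(sample(0:2, n_sites * length(samples), replace = TRUE),
              nrow = n_sites, dimnames = list(NULL, samples))
  if (miss_rate > 0) d[runif(length(d)) < miss_rate] <- NA
  storage.mode(d) <- "integer"
  d
}

toy_genes <- function(df) {
  # df: tibble with gene_id chrom start end strand [family_id rga_class exons]
  df <- as_tibble(df)
  if (!"family_id" %in% names(df)) df$family_id <- NA_character_
  if (!"rga_class" %in% names(df)) df$rga_class <- NA_character_
  if (!"exons" %in% names(df)) df$exons <- rep(list(NULL), nrow(df))
  df
}

# --- oracles ---------------------------------------------------------------

# Weir & Cockerham (1984) components, literal transcription for r
# populations, one site. dos_list: list of dosage vectors, one per group.
oracle_wc_fst <- function(dos_list) {
  r <- length(dos_list)
  n <- vapply(dos_list, function(d) sum(!is.na(d)), numeric(1))
  p <- vapply(dos_list, function(d) sum(d, na.rm = TRUE), numeric(1)) / (2 * n)
  h <- vapply(dos_list, function(d) sum(d == 1, na.rm = TRUE), numeric(1)) / n
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

# Average pairwise difference over all allele pairs at one site.
oracle_site_pi <- function(dosages) {
  dosages <- unname(dosages[!is.na(dosages)])
  alleles <- unlist(lapply(dosages, function(d) c(rep(1, d), rep(0, 2 - d))))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diff_sum <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) diff_sum <- diff_sum + (alleles[i] != alleles[j])
  }
  diff_sum / choose(n, 2)
}

# Genic context by exhaustive per-(SV, gene) interval checks.
oracle_sv_context <- function(cohort, genes, flank = 1000) {
  out <- character(nrow(cohort))
  for (v in seq_len(nrow(cohort))) {
    s <- cohort$pos[v]
    e <- if (cohort$vtype[v] == "INS") s else s + cohort$length[v] - 1L
    exon <- genic <- up <- down <- FALSE
    for (g in seq_len(nrow(genes))) {
      if (genes$chrom[g] != cohort$chrom[v]) next
      gs <- genes$start[g]; ge <- genes$end[g]
      st <- genes$strand[g]; if (is.na(st)) st <- "+"
      if (s <= ge && e >= gs) genic <- TRUE
      ex <- genes$exons[[g]]
      if (!is.null(ex)) {
        for (k in seq_len(nrow(ex))) {
          if (s <= ex$end[k] && e >= ex$start[k]) exon <- TRUE
        }
      }
      upw <- if (st == "+") c(gs - flank, gs - 1) else c(ge + 1, ge + flank)
      dnw <- if (st == "+") c(ge + 1, ge + flank) else c(gs - flank, gs - 1)
      if (s <= upw[2] && e >= upw[1]) up <- TRUE
      if (s <= dnw[2] && e >= dnw[1]) down <- TRUE
    }
    out[v] <- if (exon) "exon" else if (genic) "intron" else if (up) "upstream"
      else if (down) "downstream" else "intergenic"
  }
  out
}

# Favored screen by direct rule evaluation on one row of frequencies.
oracle_favored <- function(freq_focal, freq_others, hi = 0.5, lo = 0.05) {
  if (is.na(freq_focal) || freq_focal <= hi) return(FALSE)
  for (f in freq_others) {
    if (is.na(f) || f >= lo) return(FALSE)
  }
  TRUE
}

# PLINK-style filter decision for one record.
oracle_filter_keep <- function(dosages, max_missing = 0.5, maf = 0.05) {
  miss <- mean(is.na(dosages))
  if (miss > max_missing) return(FALSE)
  called <- sum(!is.na(dosages))
  if (called == 0) return(FALSE)
  p <- sum(dosages, na.rm = TRUE) / (2 * called)
  min(p, 1 - p) >= maf
}

# Single-linkage clustering by explicit gap chaining per chrom+family.
oracle_clusters <- function(genes, max_gap = 200000) {
  genes <- genes[!is.na(genes$family_id), ]
  out <- list()
  for (key in unique(paste(genes$chrom, genes$family_id))) {
    g <- genes[paste(genes$chrom, genes$family_id) == key, ]
    g <- g[order(g$start), ]
    members <- g$gene_id[1]
    last_end <- g$end[1]
    for (i in seq_len(nrow(g))[-1]) {
      gap <- max(0, g$start[i] - last_end - 1)
      if (gap <= max_gap) {
        members <- c(members, g$gene_id[i])
      } else {
        if (length(members) >= 2) out[[length(out) + 1]] <- sort(members)
        members <- g$gene_id[i]
      }
      last_end <- max(last_end, g$end[i])
    }
    if (length(members) >= 2) out[[length(out) + 1]] <- sort(members)
  }
  out
}

# Hypergeometric upper tail by direct summation of choose() terms.
oracle_hyper_p <- function(q, m, n, k) {
  x <- q:min(m, k)
  sum(choose(m, x) * choose(n, k - x)) / choose(m + n, k)
}

# p-distance by per-pair site loop.
oracle_p_distance <- function(dosmat) {
  ns <- ncol(dosmat)
  D <- matrix(0, ns, ns, dimnames = list(colnames(dosmat), colnames(dosmat)))
  for (i in seq_len(ns - 1)) {
    for (j in seq(i + 1, ns)) {
      num <- 0; den <- 0
      for (s in seq_len(nrow(dosmat))) {
        if (is.na(dosmat[s, i]) || is.na(dosmat[s, j])) next
        num <- num + abs(dosmat[s, i] - dosmat[s, j]) / 2
        den <- den + 1
      }
      D[i, j] <- D[j, i] <- num / den
    }
  }
  D
}
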
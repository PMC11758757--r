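# Per-site and windowed population-genetic statistics: Weir & Cockerham
# (1984) FST variance components, nucleotide diversity, percentile-threshold
# region calling, and distance thinning.

# Vectorized two-population W&C components over the rows of two dosage
# matrices (variants x samples). Sites with < 2 genotyped individuals in
# either group, or monomorphic across both groups, come back NA.
fst_components_matrix <- function(m1, m2) {
  n1 <- rowSums(!is.na(m1))
  n2 <- rowSums(!is.na(m2))
  p1 <- rowSums(m1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(m2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(m1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(m2 == 1L, na.rm = TRUE) / n2

  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)

  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  bad <- n1 < 2 | n2 < 2
  mono <- (pbar == 0 | pbar == 1) & hbar == 0
  a[bad | mono] <- NA_real_
  b[bad | mono] <- NA_real_
  cc[bad | mono] <- NA_real_
  denom <- a + b + cc
  fst <- ifelse(!is.na(denom) & denom != 0, a / denom, NA_real_)
  tibble(a = a, b = b, c = cc, fst = fst)
}

# Per-site components for a cohort and a group pair.
cohort_fst_components <- function(cohort, groups, pair) {
  assert_cohort(cohort)
  gl <- group_sample_list(groups)
  if (!all(pair %in% names(gl))) {
    abort(paste0("unknown group(s): ",
                 paste(setdiff(pair, names(gl)), collapse = ", ")))
  }
  s1 <- intersect(gl[[pair[1]]], names(cohort))
  s2 <- intersect(gl[[pair[2]]], names(cohort))
  if (length(s1) < 2 || length(s2) < 2) {
    abort("each group of the pair needs at least two samples in the cohort")
  }
  bind_cols(cohort[c("chrom", "pos")],
            fst_components_matrix(dosage_matrix(cohort, s1),
                                  dosage_matrix(cohort, s2)))
}

#' Weir-Cockerham FST at a single site
#'
#' Computes the Weir & Cockerham (1984) variance components for two
#' populations of diploids at one biallelic site: `a` (among populations),
#' `b` (among individuals within populations) and `c` (within individuals),
#' with `fst = a / (a + b + c)`. Small negative estimates are an expected
#' property of the estimator. A site monomorphic across both groups has no
#' defined components and returns `NA`.
#'
#' @param dosages Named integer vector of per-sample dosages (0/1/2, `NA`
#'   missing), names = sample IDs.
#' @param groups Sample-to-group map (tibble or named vector).
#' @param pair Character vector of the two group labels to compare.
#' @return One-row tibble with `a`, `b`, `c` and `fst`.
#' @export
site_fst_wc <- function(dosages, groups, pair) {
  gl <- group_sample_list(groups)
  m <- function(g) {
    s <- intersect(gl[[g]], names(dosages))
    matrix(dosages[s], nrow = 1)
  }
  m1 <- m(pair[1]); m2 <- m(pair[2])
  if (sum(!is.na(m1)) < 2 || sum(!is.na(m2)) < 2) {
    abort("site_fst_wc needs at least two non-missing genotypes per group")
  }
  fst_components_matrix(m1, m2)
}

#' Windowed Weir-Cockerham FST
#'
#' Tiles each chromosome with windows starting at position 1 and reports the
#' weighted window estimate `sum(a) / sum(a + b + c)` over the usable sites
#' in each window (the VCFtools weighted-FST convention). Windows with no
#' usable site get `NA`. The default 20 kb non-overlapping tiling matches
#' the study design; `step < window` gives sliding windows.
#'
#' @param cohort Variant cohort tibble.
#' @param groups Sample-to-group map.
#' @param pair The two group labels to compare.
#' @param window Window size in bp (default 20000).
#' @param step Step size in bp (default = `window`, i.e. tiling).
#' @param chrom_lengths Optional named chromosome lengths; defaults to the
#'   last variant position per chromosome.
#' @return A window track tibble: `chrom`, `start`, `end`, `value`
#'   (weighted FST), `n_sites`.
#' @export
windowed_fst <- function(cohort, groups, pair, window = 20000,
                         step = window, chrom_lengths = NULL) {
  comp <- cohort_fst_components(cohort, groups, pair)
  track_from_sites(comp, window = window, step = step,
                   chrom_lengths = chrom_lengths, stat = "fst")
}

# Shared site->window aggregation. For stat = "fst", value is
# sum(a)/sum(a+b+c); for stat = "count", value is the number of sites.
track_from_sites <- function(sites, window, step, chrom_lengths, stat) {
  window <- as.integer(window); step <- as.integer(step)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- sites |> group_by(.data$chrom) |>
      summarise(len = max(.data$pos), .groups = "drop")
    chrom_lengths <- setNames(chrom_lengths$len, chrom_lengths$chrom)
  }
  tracks <- purrr::map_dfr(names(chrom_lengths), function(ch) {
    L <- as.integer(chrom_lengths[[ch]])
    starts <- window_starts(L, step)
    win <- tibble(chrom = ch, start = starts,
                  end = pmin(starts + window - 1L, L))
    sub <- sites[sites$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) {
      win$value <- NA_real_
      win$n_sites <- 0L
      if (stat == "count") win$value <- 0
      return(win)
    }
    # each site falls in windows k_lo..k_hi (0-based window index)
    k_hi <- pmin((sub$pos - 1L) %/% step, length(starts) - 1L)
    k_lo <- pmax(0L, ceiling((sub$pos - window) / step))
    reps <- k_hi - k_lo + 1L
    site_idx <- rep(seq_len(nrow(sub)), reps)
    win_idx <- unlist(purrr::map2(k_lo, k_hi, seq)) + 1L
    if (stat == "fst") {
      ok <- !is.na(sub$a[site_idx])
      num <- tapply(sub$a[site_idx][ok], win_idx[ok], sum)
      den <- tapply((sub$a + sub$b + sub$c)[site_idx][ok], win_idx[ok], sum)
      n_sites <- tapply(rep(1L, sum(ok)), win_idx[ok], sum)
      win$value <- NA_real_
      win$n_sites <- 0L
      idx <- as.integer(names(num))
      win$value[idx] <- ifelse(den != 0, num / den, NA_real_)
      win$n_sites[idx] <- as.integer(n_sites)
    } else {
      cnt <- tabulate(win_idx, nbins = length(starts))
      win$value <- as.numeric(cnt)
      win$n_sites <- cnt
    }
    win
  })
  new_window_track(tracks, window = window, step = step, stat = stat)
}

#' Genome-wide weighted FST
#'
#' `sum(a) / sum(a + b + c)` over all usable sites of the cohort — the
#' single-number differentiation summary used to calibrate simulated
#' cohorts against their target F.
#'
#' @inheritParams windowed_fst
#' @return A single numeric value.
#' @export
genome_fst <- function(cohort, groups, pair) {
  comp <- cohort_fst_components(cohort, groups, pair)
  ok <- !is.na(comp$a)
  sum(comp$a[ok]) / sum((comp$a + comp$b + comp$c)[ok])
}

#' Call highly differentiated regions from a window track
#'
#' The threshold is the stated percentile (linear interpolation between
#' order statistics) of the non-`NA` window values; windows strictly above
#' it are selected and overlapping or bookended selected windows are merged.
#' With a constant track nothing exceeds the threshold and the result is
#' empty.
#'
#' @param track Window track tibble (from [windowed_fst()] or
#'   [sv_window_counts()]).
#' @param percentile Percentile threshold (default 95).
#' @return Region tibble (`chrom`, `start`, `end`) with attributes
#'   `threshold` and `total_length`.
#' @export
call_hdr <- function(track, percentile = 95) {
  percentile_regions(track, percentile)
}

percentile_regions <- function(track, percentile = 95) {
  vals <- track$value[!is.na(track$value)]
  if (length(vals) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer())
    attr(out, "threshold") <- NA_real_
    attr(out, "total_length") <- 0L
    return(out)
  }
  thr <- quantile(vals, percentile / 100, type = 7, names = FALSE)
  sel <- !is.na(track$value) & track$value > thr
  out <- merge_regions(track[sel, c("chrom", "start", "end")])
  attr(out, "threshold") <- thr
  attr(out, "total_length") <- region_length(out)
  out
}

#' Per-site nucleotide diversity
#'
#' `pi = 2 j (n - j) / (n (n - 1))` with `j` the alternate allele count and
#' `n` the number of non-missing alleles — the average pairwise difference
#' among the sampled alleles at the site.
#'
#' @param dosages Integer vector of diploid dosages (0/1/2, `NA` missing).
#' @return Site diversity (0 for a monomorphic site; `NA` with fewer than
#'   two called alleles).
#' @export
site_pi <- function(dosages) {
  n <- 2 * sum(!is.na(dosages))
  if (n < 2) return(NA_real_)
  j <- sum(dosages, na.rm = TRUE)
  2 * j * (n - j) / (n * (n - 1))
}

#' Mean nucleotide diversity over a site subset
#'
#' @param cohort Variant cohort tibble.
#' @param sites Optional logical or integer index of rows to include
#'   (default all).
#' @return Mean of per-site pi over the selected sites (`NA` sites dropped).
#' @export
mean_pi <- function(cohort, sites = NULL) {
  assert_cohort(cohort)
  d <- dosage_matrix(cohort)
  if (!is.null(sites)) d <- d[sites, , drop = FALSE]
  pis <- apply(d, 1, site_pi)
  mean(pis, na.rm = TRUE)
}

#' Thin variants by a minimum inter-site distance
#'
#' Greedy left-to-right per chromosome: a site is kept when its position is
#' at least `min_gap` beyond the last kept position. Thinning is idempotent
#' and keeps the first site of every chromosome.
#'
#' @param cohort Variant cohort tibble (sorted by chrom, pos).
#' @param min_gap Minimum distance between kept sites in bp (default 2000).
#' @return The thinned cohort tibble.
#' @export
thin_variants <- function(cohort, min_gap = 2000) {
  assert_cohort(cohort)
  keep <- logical(nrow(cohort))
  for (ch in unique(cohort$chrom)) {
    idx <- which(cohort$chrom == ch)
    pos <- cohort$pos[idx]
    if (is.unsorted(pos)) abort("cohort positions not sorted within chromosome")
    last <- -Inf
    for (i in seq_along(idx)) {
      if (pos[i] >= last + min_gap) {
        keep[idx[i]] <- TRUE
        last <- pos[i]
      }
    }
  }
  cohort[keep, , drop = FALSE]
}
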
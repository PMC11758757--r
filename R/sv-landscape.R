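# Structural-variant landscape: genic-context annotation, hotspot scanning,
# group frequencies, favored-SV screening, hotspot gene classing and the
# genotype-level PLINK-style filter.

sv_interval <- function(cohort) {
  # insertions occupy a single breakpoint; deletions/inversions their span
  s <- cohort$pos
  e <- ifelse(cohort$vtype == "INS", cohort$pos, cohort$pos + cohort$length - 1L)
  list(start = s, end = as.integer(e))
}

#' Annotate the genic context of each SV
#'
#' Assigns each variant one category by precedence
#' exon > intron > upstream > downstream > intergenic. The variant interval
#' (`[pos, pos + length - 1]`; insertions use the single insertion point)
#' is compared against gene bodies and exons, and against `flank`-bp
#' windows 5' (upstream) and 3' (downstream) of each gene respecting its
#' strand. When no gene carries exon structure, exon/intron collapse to a
#' single `genic` category with a warning.
#'
#' @param cohort Variant cohort tibble.
#' @param genes Gene-set tibble (see [read_gff()]).
#' @param flank Upstream/downstream window size in bp (default 1000).
#' @return The cohort with an added `context` column.
#' @export
annotate_sv_context <- function(cohort, genes, flank = 1000) {
  assert_cohort(cohort)
  iv <- sv_interval(cohort)
  have_exons <- "exons" %in% names(genes) &&
    any(!vapply(genes$exons, is.null, logical(1)))
  if (!have_exons) {
    warn("gene set has no exon features; exon/intron collapse to 'genic'")
  }
  exon_hit <- genic_hit <- up_hit <- down_hit <- logical(nrow(cohort))
  for (ch in unique(genes$chrom)) {
    vi <- which(cohort$chrom == ch)
    if (length(vi) == 0) next
    s <- iv$start[vi]; e <- iv$end[vi]
    gsub_ <- genes[genes$chrom == ch, , drop = FALSE]
    for (gi in seq_len(nrow(gsub_))) {
      gs <- gsub_$start[gi]; ge <- gsub_$end[gi]
      strand <- gsub_$strand[gi]
      if (is.na(strand)) strand <- "+"
      ov <- s <= ge & e >= gs
      genic_hit[vi] <- genic_hit[vi] | ov
      if (have_exons && !is.null(gsub_$exons[[gi]])) {
        ex <- gsub_$exons[[gi]]
        for (k in seq_len(nrow(ex))) {
          exon_hit[vi] <- exon_hit[vi] | (s <= ex$end[k] & e >= ex$start[k])
        }
      }
      if (strand == "+") {
        up <- c(gs - flank, gs - 1L); down <- c(ge + 1L, ge + flank)
      } else {
        up <- c(ge + 1L, ge + flank); down <- c(gs - flank, gs - 1L)
      }
      up_hit[vi] <- up_hit[vi] | (s <= up[2] & e >= up[1])
      down_hit[vi] <- down_hit[vi] | (s <= down[2] & e >= down[1])
    }
  }
  context <- if (have_exons) {
    case_when(exon_hit ~ "exon",
              genic_hit ~ "intron",
              up_hit ~ "upstream",
              down_hit ~ "downstream",
              TRUE ~ "intergenic")
  } else {
    case_when(genic_hit ~ "genic",
              up_hit ~ "upstream",
              down_hit ~ "downstream",
              TRUE ~ "intergenic")
  }
  mutate(cohort, context = context)
}

#' Summarize SV context percentages
#' @param annotated Cohort with a `context` column from
#'   [annotate_sv_context()].
#' @return Tibble `context`, `n`, `pct` (half-up, 2 decimals).
#' @export
sv_context_summary <- function(annotated) {
  annotated |>
    count(.data$context, name = "n") |>
    mutate(pct = round_half_up(100 * .data$n / sum(.data$n)))
}

#' SV counts in sliding windows
#'
#' Counts, for every window (default 100 kb windows advancing by 20 kb),
#' the number of SVs whose start position lies inside it; an interior
#' position is therefore counted in `window/step` overlapping windows.
#'
#' @param cohort Variant cohort tibble.
#' @param window Window size in bp (default 100000).
#' @param step Step size in bp (default 20000).
#' @param chrom_lengths Optional named chromosome lengths.
#' @return A window track tibble (`chrom`, `start`, `end`, `value`,
#'   `n_sites`).
#' @export
sv_window_counts <- function(cohort, window = 100000, step = 20000,
                             chrom_lengths = NULL) {
  assert_cohort(cohort)
  track_from_sites(cohort[c("chrom", "pos")], window = window, step = step,
                   chrom_lengths = chrom_lengths, stat = "count")
}

#' Call SV hotspot regions
#'
#' Selects the windows whose SV count is strictly above the stated
#' percentile of all window counts and merges overlapping or bookended
#' selected windows — the same percentile/merge machinery as [call_hdr()].
#'
#' @param track Window track from [sv_window_counts()].
#' @param percentile Percentile threshold (default 95, i.e. top 5%).
#' @return Region tibble with `threshold` and `total_length` attributes.
#' @export
call_sv_hotspots <- function(track, percentile = 95) {
  percentile_regions(track, percentile)
}

#' Per-group SV allele frequencies
#'
#' For every SV and group: alternate allele count over non-missing allele
#' count within the group (`NA` when the group has no called genotype).
#' `measure = "carrier"` instead reports the fraction of genotyped samples
#' carrying at least one alternate allele.
#'
#' @param cohort Variant cohort tibble.
#' @param groups Sample-to-group map.
#' @param measure `"allele"` (default) or `"carrier"`.
#' @return Tibble `chrom`, `pos`, `vtype`, `length`, then one frequency
#'   column per group.
#' @export
group_sv_frequencies <- function(cohort, groups, measure = c("allele", "carrier")) {
  measure <- match.arg(measure)
  assert_cohort(cohort)
  gl <- group_sample_list(groups)
  out <- cohort[.cohort_meta]
  for (g in names(gl)) {
    m <- dosage_matrix(cohort, intersect(gl[[g]], names(cohort)))
    called <- rowSums(!is.na(m))
    f <- if (measure == "allele") {
      rowSums(m, na.rm = TRUE) / (2 * called)
    } else {
      rowSums(m >= 1L, na.rm = TRUE) / called
    }
    f[called == 0] <- NA_real_
    out[[g]] <- f
  }
  structure(out, freq_groups = names(gl))
}

#' Screen for group-favored SVs
#'
#' An SV is favored in the focal group when its frequency there is strictly
#' above `hi` (default 0.5) and strictly below `lo` (default 0.05) in every
#' other group. By default an `NA` frequency in any other group excludes
#' the SV (conservative); `na_rule = "ignore"` skips `NA` groups instead.
#'
#' @param freqs Frequency table from [group_sv_frequencies()].
#' @param focal Focal group label.
#' @param hi High-frequency threshold for the focal group (strict `>`).
#' @param lo Low-frequency threshold for the other groups (strict `<`).
#' @param na_rule `"exclude"` (default) or `"ignore"`.
#' @return The favored subset of `freqs`.
#' @export
favored_svs <- function(freqs, focal, hi = 0.5, lo = 0.05,
                        na_rule = c("exclude", "ignore")) {
  na_rule <- match.arg(na_rule)
  grps <- attr(freqs, "freq_groups") %||% setdiff(names(freqs), .cohort_meta)
  if (!focal %in% grps) abort(paste0("unknown focal group: ", focal))
  others <- setdiff(grps, focal)
  ok <- !is.na(freqs[[focal]]) & freqs[[focal]] > hi
  for (g in others) {
    fg <- freqs[[g]]
    ok <- ok & if (na_rule == "exclude") !is.na(fg) & fg < lo
               else is.na(fg) | fg < lo
  }
  freqs[ok, , drop = FALSE]
}

#' Classify genes relative to SV hotspot regions
#'
#' A gene whose body overlaps a hotspot (by any amount) is `SV-hotspot`;
#' otherwise, if its strand-aware `upstream`-bp promoter window overlaps a
#' hotspot it is `SV-hotspot-upstream`; all remaining genes are
#' `non-SV-hotspot`.
#'
#' @param genes Gene-set tibble.
#' @param hotspots Region tibble from [call_sv_hotspots()].
#' @param upstream Upstream window size in bp (default 2000).
#' @return `genes` with an added `hotspot_class` column.
#' @export
classify_genes_by_hotspot <- function(genes, hotspots, upstream = 2000) {
  body_hit <- up_hit <- logical(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    hs <- hotspots[hotspots$chrom == ch, , drop = FALSE]
    if (nrow(hs) == 0) next
    strand <- ifelse(is.na(genes$strand[gi]), "+", genes$strand[gi])
    us <- ifelse(strand == "+", genes$start[gi] - upstream, genes$end[gi] + 1L)
    ue <- ifelse(strand == "+", genes$start[gi] - 1L, genes$end[gi] + upstream)
    for (k in seq_len(nrow(hs))) {
      body_hit[gi] <- body_hit[gi] |
        (genes$start[gi] <= hs$end[k] & genes$end[gi] >= hs$start[k])
      up_hit[gi] <- up_hit[gi] | (us <= hs$end[k] & ue >= hs$start[k])
    }
  }
  mutate(genes, hotspot_class = case_when(
    body_hit ~ "SV-hotspot",
    up_hit ~ "SV-hotspot-upstream",
    TRUE ~ "non-SV-hotspot"
  ))
}

#' Fraction of differentially expressed genes per hotspot class
#'
#' For every condition and hotspot class: the percentage of the class's
#' genes that appear in the condition's DE list, and optionally the
#' percentage with an absolute fold change above `fold_threshold`.
#'
#' @param classes Tibble `gene_id`, `hotspot_class` (from
#'   [classify_genes_by_hotspot()]).
#' @param de_lists Named list: condition -> character vector of DE gene IDs.
#' @param fold_changes Optional named list: condition -> named numeric
#'   vector of fold changes (names = gene IDs).
#' @param fold_threshold Absolute fold-change cutoff (default 4).
#' @return Tibble `condition`, `hotspot_class`, `n_genes`, `pct_deg` and,
#'   when fold changes are supplied, `pct_deg_strong`.
#' @export
deg_fraction_by_class <- function(classes, de_lists, fold_changes = NULL,
                                  fold_threshold = 4) {
  cls_levels <- unique(classes$hotspot_class)
  purrr::map_dfr(names(de_lists), function(cond) {
    de <- de_lists[[cond]]
    purrr::map_dfr(cls_levels, function(cl) {
      g <- classes$gene_id[classes$hotspot_class == cl]
      n <- length(g)
      row <- tibble(
        condition = cond, hotspot_class = cl, n_genes = n,
        pct_deg = if (n == 0) NA_real_ else
          round_half_up(100 * sum(g %in% de) / n)
      )
      if (!is.null(fold_changes)) {
        fc <- fold_changes[[cond]]
        strong <- names(fc)[abs(fc) > fold_threshold]
        row$pct_deg_strong <- if (n == 0) NA_real_ else
          round_half_up(100 * sum(g %in% intersect(de, strong)) / n)
      }
      row
    })
  })
}

#' Filter an SV genotype matrix by missingness and allele frequency
#'
#' PLINK-style genotype-level filters: drop variants whose missing-call
#' rate exceeds `max_missing` or whose minor allele frequency falls below
#' `maf` (computed over all samples); a variant at exactly the `maf`
#' threshold is kept.
#'
#' @param cohort Variant cohort tibble.
#' @param max_missing Maximum missing-call rate (default 0.5).
#' @param maf Minimum minor allele frequency (default 0.05).
#' @return The filtered cohort tibble.
#' @export
filter_sv_genotype_matrix <- function(cohort, max_missing = 0.5, maf = 0.05) {
  assert_cohort(cohort)
  m <- dosage_matrix(cohort)
  miss <- rowMeans(is.na(m))
  called <- rowSums(!is.na(m))
  p <- rowSums(m, na.rm = TRUE) / (2 * called)
  mafs <- pmin(p, 1 - p)
  keep <- miss <= max_missing & !is.na(mafs) & mafs >= maf
  cohort[keep, , drop = FALSE]
}

#' Tally variants by type
#' @param cohort Variant cohort tibble.
#' @return Tibble `vtype`, `n`.
#' @export
sv_type_counts <- function(cohort) {
  count(cohort, .data$vtype, name = "n")
}
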
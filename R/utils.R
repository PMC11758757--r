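# Shared internal helpers: cohort column conventions, rounding, interval merge.

# Metadata columns of a variant cohort tibble; everything else is a sample.
.cohort_meta <- c("chrom", "pos", "vtype", "length")

#' Sample columns of a variant cohort
#'
#' A variant cohort is a tibble with one row per variant, the metadata columns
#' `chrom`, `pos` (1-based), `vtype` (`"SNP"`, `"INS"`, `"DEL"` or `"INV"`) and
#' `length` (bp, 1 for SNPs), followed by one integer column per sample holding
#' the diploid alternate-allele dosage (0, 1, 2, or `NA` for a missing call).
#'
#' @param cohort A variant cohort tibble.
#' @return Character vector of sample column names, in cohort order.
#' @export
cohort_samples <- function(cohort) {
  setdiff(names(cohort), .cohort_meta)
}

# Dosage matrix (variants x samples) from a cohort tibble.
dosage_matrix <- function(cohort, samples = cohort_samples(cohort)) {
  m <- as.matrix(cohort[samples])
  storage.mode(m) <- "integer"
  m
}

assert_cohort <- function(cohort) {
  missing_meta <- setdiff(.cohort_meta, names(cohort))
  if (length(missing_meta) > 0) {
    abort(paste0("not a variant cohort: missing column(s) ",
                 paste(missing_meta, collapse = ", ")))
  }
  if (length(cohort_samples(cohort)) == 0) {
    abort("variant cohort has no sample columns")
  }
  invisible(cohort)
}

# Half-up decimal rounding (base round() is round-half-even); used for all
# printed percentages so 67.715 -> 67.72.
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

# Normalize a sample->group mapping to a two-column tibble (sample, group).
as_group_map <- function(groups, first = "sample") {
  if (is.character(groups) && !is.null(names(groups))) {
    groups <- tibble(sample = names(groups), group = unname(groups))
  }
  groups <- as_tibble(groups)
  if (ncol(groups) < 2) abort("group map needs two columns: sample, group")
  names(groups)[1:2] <- c("sample", "group")
  if (anyDuplicated(groups$sample)) {
    abort("group map assigns some samples more than once")
  }
  if (first != "sample") names(groups)[1] <- first
  groups
}

group_sample_list <- function(groups) {
  groups <- as_group_map(groups)
  split(groups$sample, groups$group)
}

# Merge sorted per-chromosome intervals; `adjacent = TRUE` also fuses
# bookended intervals (end + 1 == next start).  Input/output are 1-based
# inclusive region tibbles (chrom, start, end).
merge_regions <- function(regions, adjacent = TRUE) {
  if (nrow(regions) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  slack <- if (adjacent) 1L else 0L
  regions |>
    arrange(.data$chrom, .data$start, .data$end) |>
    group_by(.data$chrom) |>
    mutate(new_run = cumsum(
      dplyr::lag(cummax(as.numeric(.data$end)), default = -Inf) + slack <
        .data$start
    )) |>
    group_by(.data$chrom, .data$new_run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    select("chrom", "start", "end") |>
    arrange(.data$chrom, .data$start)
}

# Total span of a region tibble in bp (1-based inclusive).
region_length <- function(regions) {
  if (nrow(regions) == 0) return(0L)
  sum(regions$end - regions$start + 1)
}

# Tiling/sliding window starts for one chromosome of length L (windows start
# at 1, step apart, while start <= L).
window_starts <- function(chrom_length, step) {
  k_max <- (chrom_length - 1L) %/% step
  1L + step * (0:k_max)
}

new_window_track <- function(df, window, step, stat = "count") {
  structure(as_tibble(df), window = window, step = step, stat = stat,
            class = c("window_track", class(as_tibble(df))))
}
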
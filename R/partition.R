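# Occupancy-based pan-genome partitioning: core / softcore / dispensable /
# cloud, group-specific families, and term enrichment.

#' Occupancy thresholds for pan-genome partitioning
#'
#' The four categories tile the occupancy range 1..N: core = present in all
#' N assemblies; softcore = present in at least `ceil(softcore_frac * N)`
#' but not all; dispensable = present in 2 up to the softcore minimum minus
#' one; cloud = present in exactly one. With N = 15 and the default 0.85
#' fraction the softcore band is 13-14 assemblies.
#'
#' @param n_assemblies Number of assemblies N.
#' @param softcore_frac Softcore occupancy fraction (default 0.85).
#' @return A list with `n_assemblies`, `softcore_min` and the category bands.
#' @export
partition_thresholds <- function(n_assemblies, softcore_frac = 0.85) {
  softcore_min <- as.integer(ceiling(softcore_frac * n_assemblies))
  if (softcore_min < 3) {
    abort("softcore minimum below 3: occupancy bands collide; use more assemblies")
  }
  list(
    n_assemblies = as.integer(n_assemblies),
    softcore_min = softcore_min,
    bands = list(core = c(n_assemblies, n_assemblies),
                 softcore = c(softcore_min, n_assemblies - 1L),
                 dispensable = c(2L, softcore_min - 1L),
                 cloud = c(1L, 1L))
  )
}

partition_categories <- c("core", "softcore", "dispensable", "cloud")

#' Classify gene families by assembly occupancy
#'
#' A family's frequency is the number of assemblies where it has at least
#' one member gene (copy number is ignored). Frequency N is core, the
#' softcore band is `[softcore_min, N-1]`, dispensable `[2, softcore_min-1]`
#' and cloud exactly 1. Every family receives exactly one category.
#'
#' @param fm Family-matrix tibble (`family_id` + assembly count columns).
#' @param thresholds Output of [partition_thresholds()]; defaults to the
#'   matrix's assembly count with `softcore_frac`.
#' @param softcore_frac Used when `thresholds` is `NULL`.
#' @return A `pan_partition` object; see [tidy.pan_partition()] for the
#'   per-family table and [partition_summary()] for composition.
#' @export
classify_families <- function(fm, thresholds = NULL, softcore_frac = 0.85) {
  asm <- setdiff(names(fm), "family_id")
  if (length(asm) < 2) abort("family matrix needs at least two assemblies")
  counts <- as.matrix(fm[asm])
  thresholds <- thresholds %||% partition_thresholds(length(asm), softcore_frac)
  if (thresholds$n_assemblies != length(asm)) {
    abort("thresholds declare a different assembly count than the matrix")
  }
  freq <- rowSums(counts >= 1)
  if (any(freq == 0)) {
    abort("family present in zero assemblies violates the family-matrix invariant")
  }
  n <- thresholds$n_assemblies
  sc <- thresholds$softcore_min
  category <- case_when(
    freq == n ~ "core",
    freq >= sc ~ "softcore",
    freq >= 2 ~ "dispensable",
    TRUE ~ "cloud"
  )
  structure(
    list(
      families = tibble(
        family_id = fm$family_id,
        frequency = as.integer(freq),
        n_genes = as.integer(rowSums(counts)),
        category = factor(category, levels = partition_categories)
      ),
      thresholds = thresholds,
      assembly_ids = asm,
      matrix = fm
    ),
    class = "pan_partition"
  )
}

#' @export
print.pan_partition <- function(x, ...) {
  cat("Pan-genome partition over", x$thresholds$n_assemblies, "assemblies",
      "(softcore band", paste0(x$thresholds$softcore_min, "-",
                               x$thresholds$n_assemblies - 1L), ")\n")
  print(partition_summary(x))
  invisible(x)
}

#' Summarize pan-genome composition
#'
#' Reports family counts, gene counts and their percentages per category,
#' with a totals row. Percentages are rounded half-up to two decimals.
#' The data-frame method accepts pre-tabulated per-category counts (columns
#' `category`, `n_families` and optionally `n_genes`), which lets published
#' composition tables be re-summarized directly.
#'
#' @param x A `pan_partition` object or a per-category count data frame.
#' @param ... Unused.
#' @return A tibble with one row per category plus a `total` row.
#' @export
partition_summary <- function(x, ...) UseMethod("partition_summary")

#' @rdname partition_summary
#' @export
partition_summary.pan_partition <- function(x, ...) {
  counts <- x$families |>
    group_by(category = .data$category) |>
    summarise(n_families = dplyr::n(), n_genes = sum(.data$n_genes),
              .groups = "drop") |>
    tidyr::complete(category, fill = list(n_families = 0L, n_genes = 0L))
  partition_summary(as_tibble(counts))
}

#' @rdname partition_summary
#' @export
partition_summary.data.frame <- function(x, ...) {
  x <- as_tibble(x)
  if (!all(c("category", "n_families") %in% names(x))) {
    abort("need columns category and n_families")
  }
  x$category <- factor(as.character(x$category), levels = partition_categories)
  if (anyNA(x$category)) abort("unknown category label")
  x <- arrange(x, .data$category)
  out <- tibble(
    category = as.character(x$category),
    n_families = as.integer(x$n_families),
    pct_families = round_half_up(100 * x$n_families / sum(x$n_families))
  )
  if ("n_genes" %in% names(x)) {
    out$n_genes <- as.integer(x$n_genes)
    out$pct_genes <- round_half_up(100 * x$n_genes / sum(x$n_genes))
  }
  totals <- tibble(category = "total",
                   n_families = sum(out$n_families),
                   pct_families = 100)
  if ("n_genes" %in% names(out)) {
    totals$n_genes <- sum(out$n_genes)
    totals$pct_genes <- 100
  }
  bind_rows(out, totals)
}

#' Combined share of selected categories
#'
#' The percentage of families (or genes) falling in the selected categories,
#' computed from the raw counts and rounded half-up once — so a combined
#' share (e.g. dispensable plus cloud) matches direct ratio arithmetic
#' rather than a sum of independently rounded percentages.
#'
#' @param x A `pan_partition` object or a summary tibble from
#'   [partition_summary()] (a `total` row, if present, is ignored).
#' @param categories Character vector of categories to combine.
#' @param level `"families"` (default) or `"genes"`.
#' @return A single percentage, rounded half-up to 2 decimals.
#' @export
composition_share <- function(x, categories, level = c("families", "genes")) {
  level <- match.arg(level)
  if (inherits(x, "pan_partition")) x <- partition_summary(x)
  x <- x[x$category != "total", , drop = FALSE]
  col <- if (level == "families") "n_families" else "n_genes"
  if (!col %in% names(x)) abort(paste0("summary has no ", col, " column"))
  round_half_up(100 * sum(x[[col]][x$category %in% categories]) / sum(x[[col]]))
}

#' Per-assembly pan-genome composition
#'
#' For each assembly, the number and percentage of its genes that belong to
#' families of each category (an assembly's genes in a category are the
#' member genes it contributes to families classified there).
#'
#' @param partition A `pan_partition` object.
#' @return A tibble with `assembly`, `category`, `n_genes`, `pct_genes`.
#' @export
assembly_composition <- function(partition) {
  fm <- partition$matrix
  purrr::map_dfr(partition$assembly_ids, function(a) {
    by_cat <- tapply(fm[[a]], partition$families$category, sum, default = 0L)
    tibble(assembly = a,
           category = names(by_cat),
           n_genes = as.integer(by_cat),
           pct_genes = round_half_up(100 * by_cat / sum(by_cat)))
  })
}

#' Families specific to one assembly group
#'
#' A family is specific to the focal group when it is present (count >= 1)
#' in every focal assembly and absent (count 0) in every non-focal assembly
#' of the map. All assemblies of the matrix must be assigned to a group.
#'
#' @param fm Family-matrix tibble.
#' @param groups Assembly-to-group map: tibble (`assembly`, `group`) or a
#'   named character vector (names = assemblies).
#' @param focal Focal group label.
#' @return Tibble of specific families (`family_id`, `n_genes`).
#' @export
group_specific_families <- function(fm, groups, focal) {
  groups <- as_group_map(groups, first = "assembly")
  asm <- setdiff(names(fm), "family_id")
  unmapped <- setdiff(asm, groups$assembly)
  if (length(unmapped) > 0) {
    abort(paste0("assemblies missing from the group map: ",
                 paste(unmapped, collapse = ", ")))
  }
  focal_asm <- groups$assembly[groups$group == focal]
  focal_asm <- intersect(focal_asm, asm)
  if (length(focal_asm) == 0) abort(paste0("focal group '", focal, "' is empty"))
  other_asm <- setdiff(asm, focal_asm)
  in_all_focal <- rowSums(as.matrix(fm[focal_asm]) >= 1) == length(focal_asm)
  absent_all_other <- if (length(other_asm) == 0) TRUE else
    rowSums(as.matrix(fm[other_asm])) == 0
  keep <- in_all_focal & absent_all_other
  tibble(family_id = fm$family_id[keep],
         n_genes = as.integer(rowSums(as.matrix(fm[asm]))[keep]))
}

#' Families present only in one sex
#'
#' Families present in every assembly of the target sex and absent from all
#' assemblies of the other; an alias of [group_specific_families()] with sex
#' labels.
#'
#' @param fm Family-matrix tibble.
#' @param sex Assembly-to-sex map (`assembly`, `group` in `{male, female}`),
#'   tibble or named vector.
#' @param target_sex `"male"` or `"female"`.
#' @return Tibble of sex-specific families (`family_id`, `n_genes`).
#' @export
presence_only_in_sex <- function(fm, sex, target_sex) {
  group_specific_families(fm, sex, target_sex)
}

#' Term over-representation test
#'
#' One-sided hypergeometric (Fisher) upper-tail test per term against the
#' stated universe, with Benjamini-Hochberg correction across the tested
#' terms. Terms hit fewer than `min_hits` times (or annotating no universe
#' gene) are reported with `NA` p and q values and do not enter the BH
#' correction.
#'
#' @param hits Character vector of hit gene IDs.
#' @param annotation Long tibble mapping `gene` to `term`.
#' @param universe Character vector of universe gene IDs.
#' @param min_hits Minimum hits in a term for it to be tested (default 2).
#' @return Tibble `term`, `n_term`, `n_hits`, `p_value`, `q_value`,
#'   ordered by p.
#' @export
enrichment_test <- function(hits, annotation, universe, min_hits = 2) {
  annotation <- as_tibble(annotation)
  names(annotation)[1:2] <- c("gene", "term")
  all_terms <- unique(annotation$term)
  annotation <- filter(annotation, .data$gene %in% universe) |> distinct()
  hits <- intersect(unique(hits), universe)
  n_univ <- length(unique(universe))
  k <- length(hits)
  per_term <- annotation |>
    group_by(.data$term) |>
    summarise(n_term = dplyr::n(),
              n_hits = sum(.data$gene %in% hits), .groups = "drop")
  # keep terms that vanished from the universe visible as NA rows
  per_term <- tidyr::complete(per_term, term = unique(c(all_terms, per_term$term)),
                              fill = list(n_term = 0L, n_hits = 0L))
  tested <- per_term$n_term > 0 & per_term$n_hits >= min_hits
  p <- rep(NA_real_, nrow(per_term))
  p[tested] <- phyper(per_term$n_hits[tested] - 1, per_term$n_term[tested],
                      n_univ - per_term$n_term[tested], k, lower.tail = FALSE)
  q <- rep(NA_real_, nrow(per_term))
  q[tested] <- p.adjust(p[tested], method = "BH")
  per_term |>
    mutate(p_value = p, q_value = q) |>
    arrange(.data$p_value)
}
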
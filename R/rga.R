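# Resistance gene analog atlas: physical clustering, head-to-head paired
# NLR detection, per-class summaries, and pan-RGA partitioning.

#' Cluster same-family genes by physical proximity
#'
#' Within each chromosome and family, genes sorted by start are chained
#' into one cluster while the gap between successive genes
#' (`next start - previous end - 1`, floored at 0 for overlaps) stays at or
#' below `max_gap` (single linkage: members can end up further apart than
#' `max_gap` through chaining). `method = "diameter"` instead requires every
#' member to lie within `max_gap` of the cluster's first gene, the
#' all-pairs reading. Only clusters of two or more genes are reported.
#'
#' @param genes Gene-set tibble with a `family_id` column; genes without a
#'   family are skipped with a warning.
#' @param max_gap Maximum chaining gap in bp (default 200000).
#' @param method `"chain"` (default, single linkage) or `"diameter"`.
#' @return Tibble `cluster_id`, `chrom`, `family_id`, `start`, `end`,
#'   `n_genes`, `gene_ids` (list-column).
#' @export
cluster_genes <- function(genes, max_gap = 200000,
                          method = c("chain", "diameter")) {
  method <- match.arg(method)
  if (any(is.na(genes$family_id))) {
    warn(paste0(sum(is.na(genes$family_id)),
                " gene(s) without family_id skipped"))
    genes <- genes[!is.na(genes$family_id), , drop = FALSE]
  }
  genes <- arrange(genes, .data$chrom, .data$family_id, .data$start)
  out <- genes |>
    group_by(.data$chrom, .data$family_id) |>
    group_modify(function(g, key) {
      gap <- pmax(0L, g$start[-1] - head(g$end, -1) - 1L)
      run <- if (method == "chain") {
        cumsum(c(0L, as.integer(gap > max_gap)))
      } else {
        run <- integer(nrow(g))
        anchor_end <- g$end[1]
        for (i in seq_len(nrow(g))[-1]) {
          if (g$start[i] - anchor_end - 1L > max_gap) {
            run[i] <- run[i - 1] + 1L
            anchor_end <- g$end[i]
          } else {
            run[i] <- run[i - 1]
          }
        }
        run
      }
      g |>
        mutate(run = run) |>
        group_by(.data$run) |>
        summarise(start = min(.data$start), end = max(.data$end),
                  n_genes = dplyr::n(), gene_ids = list(.data$gene_id),
                  .groups = "drop") |>
        select(-"run")
    }) |>
    ungroup() |>
    filter(.data$n_genes >= 2) |>
    arrange(.data$chrom, .data$start)
  out |>
    mutate(cluster_id = sprintf("CL%04d", dplyr::row_number())) |>
    select("cluster_id", "chrom", "family_id", "start", "end",
           "n_genes", "gene_ids")
}

#' Percentage of genes located in clusters, per RGA class
#'
#' @param genes Gene-set tibble with `rga_class`.
#' @param clusters Cluster tibble from [cluster_genes()].
#' @param class Optional single class to report; default all classes.
#' @return Tibble `rga_class`, `n_genes`, `n_clustered`, `pct_clustered`
#'   (half-up, 2 decimals).
#' @export
clustered_fraction <- function(genes, clusters, class = NULL) {
  in_cluster <- unique(unlist(clusters$gene_ids))
  g <- genes[!is.na(genes$rga_class), , drop = FALSE]
  if (!is.null(class)) g <- g[g$rga_class %in% class, , drop = FALSE]
  g |>
    group_by(rga_class = .data$rga_class) |>
    summarise(n_genes = dplyr::n(),
              n_clustered = sum(.data$gene_id %in% in_cluster),
              .groups = "drop") |>
    mutate(pct_clustered = round_half_up(100 * .data$n_clustered / .data$n_genes))
}

#' Detect head-to-head paired NLRs
#'
#' Among the NBS-class genes of each chromosome (sorted by start), a pair is
#' two *adjacent* NBS genes — no other NBS gene between them — whose strands
#' are minus then plus in coordinate order (divergent transcription,
#' promoters facing) and whose intergenic gap is at most `max_gap`. Genes
#' are assigned greedily left to right so each gene joins at most one pair;
#' the gap is reported with each pair so users can re-filter.
#'
#' @param genes Gene-set tibble with `rga_class` and `strand`.
#' @param max_gap Maximum intergenic gap in bp (default 20000).
#' @return Tibble `chrom`, `gene_minus`, `gene_plus`, `gap`.
#' @export
paired_nlr <- function(genes, max_gap = 20000) {
  nbs <- genes[!is.na(genes$rga_class) & genes$rga_class == "NBS", ,
               drop = FALSE]
  if (any(is.na(nbs$strand))) {
    abort("NBS gene without strand; strands are required for pairing")
  }
  nbs <- arrange(nbs, .data$chrom, .data$start)
  pairs <- list()
  for (ch in unique(nbs$chrom)) {
    g <- nbs[nbs$chrom == ch, , drop = FALSE]
    i <- 1L
    while (i < nrow(g)) {
      gap <- g$start[i + 1] - g$end[i] - 1L
      if (g$strand[i] == "-" && g$strand[i + 1] == "+" && gap <= max_gap) {
        pairs[[length(pairs) + 1]] <- tibble(
          chrom = ch, gene_minus = g$gene_id[i], gene_plus = g$gene_id[i + 1],
          gap = as.integer(max(gap, 0L))
        )
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(pairs) == 0) {
    return(tibble(chrom = character(), gene_minus = character(),
                  gene_plus = character(), gap = integer()))
  }
  bind_rows(pairs)
}

#' Summary rates for paired NLRs
#'
#' The published "percent paired NLRs of NBS genes" is ambiguous between
#' counting paired genes and counting pairs, so both rates are reported.
#'
#' @param genes Gene-set tibble.
#' @param pairs Pair tibble from [paired_nlr()].
#' @return One-row tibble: `n_nbs`, `n_pairs`, `pct_genes_in_pairs`,
#'   `pct_pairs_per_nbs`.
#' @export
paired_nlr_summary <- function(genes, pairs) {
  n_nbs <- sum(!is.na(genes$rga_class) & genes$rga_class == "NBS")
  tibble(
    n_nbs = n_nbs,
    n_pairs = nrow(pairs),
    pct_genes_in_pairs = round_half_up(100 * 2 * nrow(pairs) / n_nbs),
    pct_pairs_per_nbs = round_half_up(100 * nrow(pairs) / n_nbs)
  )
}

#' Pan-RGA partition
#'
#' Classifies an RGA-restricted family matrix with the standard occupancy
#' bands and, when per-family RGA classes are supplied, additionally
#' reports each class's core/softcore/dispensable/cloud gene composition.
#'
#' @param fm RGA family-matrix tibble.
#' @param family_classes Optional tibble `family_id`, `rga_class`.
#' @param softcore_frac Softcore occupancy fraction (default 0.85).
#' @return A `pan_rga` object: list with `partition` (a `pan_partition`),
#'   `summary` (composition tibble) and `class_composition` (or `NULL`).
#' @export
pan_rga <- function(fm, family_classes = NULL, softcore_frac = 0.85) {
  part <- classify_families(fm, softcore_frac = softcore_frac)
  class_comp <- NULL
  if (!is.null(family_classes)) {
    class_comp <- part$families |>
      inner_join(as_tibble(family_classes), by = "family_id") |>
      group_by(.data$rga_class, .data$category) |>
      summarise(n_genes = sum(.data$n_genes), .groups = "drop_last") |>
      mutate(pct_genes = round_half_up(100 * .data$n_genes / sum(.data$n_genes))) |>
      ungroup()
  }
  structure(
    list(partition = part, summary = partition_summary(part),
         class_composition = class_comp),
    class = "pan_rga"
  )
}

#' @export
print.pan_rga <- function(x, ...) {
  cat("Pan-RGA partition\n")
  print(x$summary)
  if (!is.null(x$class_composition)) {
    cat("\nPer-class gene composition:\n")
    print(x$class_composition)
  }
  invisible(x)
}

#' Families absent from target assemblies
#'
#' Families with zero members in every target assembly but at least one
#' member elsewhere; optionally restricted to one partition category.
#'
#' @param fm Family-matrix tibble.
#' @param target Character vector of target assembly names.
#' @param category Optional category restriction (requires `partition`).
#' @param partition Optional `pan_partition` of `fm`, needed with
#'   `category`.
#' @return Tibble `family_id`, `n_genes`.
#' @export
absent_in_target <- function(fm, target, category = NULL, partition = NULL) {
  asm <- setdiff(names(fm), "family_id")
  bad <- setdiff(target, asm)
  if (length(bad) > 0) {
    abort(paste0("unknown assemblies: ", paste(bad, collapse = ", ")))
  }
  others <- setdiff(asm, target)
  absent <- rowSums(as.matrix(fm[target])) == 0
  present_elsewhere <- rowSums(as.matrix(fm[others]) >= 1) >= 1
  keep <- absent & present_elsewhere
  if (!is.null(category)) {
    if (is.null(partition)) abort("category restriction needs the partition")
    keep <- keep & as.character(partition$families$category) == category
  }
  tibble(family_id = fm$family_id[keep],
         n_genes = as.integer(rowSums(as.matrix(fm[asm]))[keep]))
}
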
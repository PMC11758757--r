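# tidy()/glance() methods for the package's fitted objects.

#' Tidy a pan-genome partition
#'
#' One row per family: `family_id`, `frequency` (assemblies present),
#' `n_genes`, `category`.
#'
#' @param x A `pan_partition` object from [classify_families()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pan_partition <- function(x, ...) {
  x$families
}

#' Glance at a pan-genome partition
#'
#' One-row summary: totals, the softcore band, and the combined
#' dispensable-plus-cloud family share.
#'
#' @param x A `pan_partition` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.pan_partition <- function(x, ...) {
  fam <- x$families
  tibble(
    n_families = nrow(fam),
    n_genes = sum(fam$n_genes),
    n_assemblies = x$thresholds$n_assemblies,
    softcore_min = x$thresholds$softcore_min,
    pct_dispensable_cloud = composition_share(x, c("dispensable", "cloud"))
  )
}

#' Tidy a pan-RGA partition
#' @param x A `pan_rga` object from [pan_rga()].
#' @param ... Unused.
#' @return A tibble, one row per RGA family.
#' @export
tidy.pan_rga <- function(x, ...) {
  tidy(x$partition)
}

#' Glance at a pan-RGA partition
#' @param x A `pan_rga` object from [pan_rga()].
#' @param ... Unused.
#' @return A one-row tibble of totals.
#' @export
glance.pan_rga <- function(x, ...) {
  glance(x$partition)
}
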
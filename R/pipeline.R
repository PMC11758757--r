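# End-to-end orchestration from a single YAML config: simulate inputs (or
# read them from files), then run the requested partition / popgen / SV /
# tree / RGA stages, writing standard-format outputs and a manifest with
# content hashes. For a fixed seed a rerun is byte-identical.

pipeline_schema <- list(
  seed = NULL,
  simulate = list(
    family_matrix = c("n_assemblies", "targets", "softcore_frac"),
    snp_cohort = c("groups", "fst", "n_sites", "chrom_lengths", "missing_rate"),
    sv_cohort = c("groups", "n_sv", "favored_frac", "focal", "chrom_lengths",
                  "len_range", "shared_freq_range", "mode", "missing_rate"),
    rga_geneset = c("chrom_lengths", "n_clusters", "n_pairs", "n_decoys",
                    "n_singletons")
  ),
  partition = c("softcore_frac"),
  popgen = c("vcf", "groups", "pair", "window", "step", "hdr_percentile",
             "thin_gap"),
  sv = c("vcf", "groups", "window", "step", "hotspot_percentile", "focal",
         "favored_hi", "favored_lo", "max_missing", "maf"),
  tree = c("vcf", "measure"),
  rga = c("gff", "cluster_gap", "pair_gap")
)

# Reject misspelled/unknown keys anywhere in the config (no silent defaults).
check_keys <- function(cfg, schema, path = "") {
  allowed <- if (is.list(schema)) names(schema) else schema
  bad <- setdiff(names(cfg), allowed)
  if (length(bad) > 0) {
    abort(paste0("unknown config key: ", path, bad[1]))
  }
  if (is.list(schema)) {
    for (key in names(cfg)) {
      if (!is.null(schema[[key]]) && is.list(cfg[[key]])) {
        check_keys(cfg[[key]], schema[[key]], paste0(path, key, "."))
      }
    }
  }
  invisible(TRUE)
}

num_vec <- function(x) {
  if (is.null(x)) return(NULL)
  x <- unlist(x)
  # YAML 1.1 parses exponent notation without a sign ("4.0e6") as a string
  if (is.character(x)) x <- setNames(as.numeric(x), names(x))
  x
}

#' Run the full pipeline from a YAML config
#'
#' Executes the requested stages in dependency order — simulate inputs (or
#' read the configured files), partition the family matrix, compute
#' windowed FST and call HDRs, scan the SV landscape (hotspots, per-group
#' frequencies, favored SVs, genotype filter), build the p-distance NJ
#' tree, and cluster RGAs — writing every result in its standard format
#' under `out_dir` together with a `manifest.json` listing parameters and
#' the MD5 hash of every output. Unknown config keys fail immediately, and
#' stages whose inputs are not available (neither simulated nor given as a
#' path) fail before any computation starts.
#'
#' @param config Path to a YAML config, or an equivalent named list. Top
#'   sections: `seed`, `simulate` (subsections `family_matrix`,
#'   `snp_cohort`, `sv_cohort`, `rga_geneset`), `partition`, `popgen`,
#'   `sv`, `tree`, `rga`. See the shipped demo config
#'   (`system.file("extdata", "demo_config.yaml", package = "pankiwi")`).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (named list: seed, parameters, files
#'   with MD5 hashes).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  check_keys(cfg, pipeline_schema)
  seed <- cfg$seed %||% 1L
  sim <- cfg$simulate %||% list()

  # ---- fail-fast input resolution before any computation ----
  need <- function(stage, what, sim_key, path_key) {
    if (is.null(cfg[[stage]])) return(invisible(NULL))
    has_sim <- !is.null(sim[[sim_key]])
    p <- cfg[[stage]][[path_key]]
    if (!has_sim && is.null(p)) {
      abort(paste0("stage '", stage, "' needs ", what,
                   ": add simulate.", sim_key, " or ", stage, ".", path_key))
    }
    if (!has_sim && !file.exists(p)) {
      abort(paste0("stage '", stage, "': file not found: ", p))
    }
  }
  if (!is.null(cfg$partition) && is.null(sim$family_matrix)) {
    abort("stage 'partition' needs simulate.family_matrix")
  }
  need("popgen", "a SNP VCF", "snp_cohort", "vcf")
  need("sv", "an SV VCF", "sv_cohort", "vcf")
  need("tree", "an SV VCF", "sv_cohort", "vcf")
  need("rga", "a gene GFF", "rga_geneset", "gff")
  if (!is.null(cfg$popgen) && is.null(sim$snp_cohort) &&
      is.null(cfg$popgen$groups)) {
    abort("stage 'popgen' needs a groups file when the cohort is not simulated")
  }
  if (!is.null(cfg$popgen) && !is.null(cfg$popgen$groups) &&
      !file.exists(cfg$popgen$groups)) {
    abort(paste0("stage 'popgen': groups file not found: ", cfg$popgen$groups))
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, path)
    path
  }
  message("pipeline: seed ", seed)

  # ---- simulate ----
  fm <- snp <- svs <- rga_genes <- NULL
  if (!is.null(sim$family_matrix)) {
    a <- sim$family_matrix
    fm <- simulate_family_matrix(
      n_assemblies = a$n_assemblies %||% 15,
      targets = num_vec(a$targets) %||%
        c(core = 236, softcore = 87, dispensable = 347, cloud = 330),
      softcore_frac = a$softcore_frac %||% 0.85,
      seed = seed
    )
    emit("family_matrix.tsv", function(p) write_orthogroup_table(fm$matrix, p))
    emit("family_truth.tsv", function(p) readr::write_tsv(fm$truth, p))
  }
  if (!is.null(sim$snp_cohort)) {
    a <- sim$snp_cohort
    snp <- simulate_snp_cohort(
      groups = num_vec(a$groups) %||% c(LG = 28, MG = 86),
      fst = a$fst %||% 0.2,
      n_sites = a$n_sites %||% 10000,
      chrom_lengths = num_vec(a$chrom_lengths) %||% c(chr01 = 1e7, chr02 = 1e7),
      missing_rate = a$missing_rate %||% 0,
      seed = seed
    )
    emit("snps.vcf", function(p) write_vcf(snp$cohort, p))
    emit("snp_groups.tsv", function(p) write_group_map(snp$groups, p))
  }
  if (!is.null(sim$sv_cohort)) {
    a <- sim$sv_cohort
    svs <- simulate_sv_cohort(
      groups = num_vec(a$groups) %||% c(LG = 20, MG1 = 20, MG2 = 20),
      n_sv = a$n_sv %||% 2000,
      favored_frac = a$favored_frac %||% 0.1,
      focal = a$focal %||% "LG",
      chrom_lengths = num_vec(a$chrom_lengths) %||% c(chr01 = 1e7, chr02 = 1e7),
      mode = a$mode %||% "binomial",
      missing_rate = a$missing_rate %||% 0,
      seed = seed
    )
    emit("svs.vcf", function(p) write_vcf(svs$cohort, p))
    emit("sv_groups.tsv", function(p) write_group_map(svs$groups, p))
    emit("sv_truth.tsv", function(p) readr::write_tsv(svs$truth, p))
  }
  if (!is.null(sim$rga_geneset)) {
    a <- sim$rga_geneset
    rga_genes <- simulate_rga_geneset(
      chrom_lengths = num_vec(a$chrom_lengths) %||% c(chr01 = 1.5e7, chr02 = 1.5e7),
      n_clusters = a$n_clusters %||% 8,
      n_pairs = a$n_pairs %||% 6,
      n_decoys = a$n_decoys %||% 3,
      n_singletons = a$n_singletons %||% 30,
      seed = seed
    )
    emit("rga_genes.gff3", function(p) write_gff(rga_genes$genes, p))
  }

  # ---- partition ----
  if (!is.null(cfg$partition)) {
    part <- classify_families(fm$matrix,
                              softcore_frac = cfg$partition$softcore_frac %||% 0.85)
    emit("family_categories.tsv", function(p) readr::write_tsv(tidy(part), p))
    emit("partition_summary.tsv",
         function(p) readr::write_tsv(partition_summary(part), p))
    message("pipeline: partition done")
  }

  # ---- popgen ----
  if (!is.null(cfg$popgen)) {
    a <- cfg$popgen
    cohort <- if (!is.null(snp)) snp$cohort else read_vcf(a$vcf)
    groups <- if (!is.null(snp)) snp$groups else read_group_map(a$groups)
    pair <- unlist(a$pair) %||% unique(groups$group)[1:2]
    track <- windowed_fst(cohort, groups, pair,
                          window = a$window %||% 20000,
                          step = a$step %||% (a$window %||% 20000))
    hdr <- call_hdr(track, percentile = a$hdr_percentile %||% 95)
    emit("fst_windows.tsv", function(p) readr::write_tsv(track, p))
    emit("hdr.bed", function(p) write_bed(hdr, p))
    thinned <- thin_variants(cohort, min_gap = a$thin_gap %||% 2000)
    emit("snps_thinned.vcf", function(p) write_vcf(thinned, p))
    message("pipeline: popgen done (", nrow(hdr), " HDRs, ",
            attr(hdr, "total_length"), " bp)")
  }

  # ---- sv landscape ----
  if (!is.null(cfg$sv)) {
    a <- cfg$sv
    cohort <- if (!is.null(svs)) svs$cohort else read_vcf(a$vcf, sv_mode = TRUE)
    groups <- if (!is.null(svs)) svs$groups else read_group_map(a$groups)
    filtered <- filter_sv_genotype_matrix(cohort,
                                          max_missing = a$max_missing %||% 0.5,
                                          maf = a$maf %||% 0.05)
    emit("svs_filtered.vcf", function(p) write_vcf(filtered, p))
    track <- sv_window_counts(cohort, window = a$window %||% 100000,
                              step = a$step %||% 20000)
    hot <- call_sv_hotspots(track, percentile = a$hotspot_percentile %||% 95)
    emit("sv_windows.tsv", function(p) readr::write_tsv(track, p))
    emit("sv_hotspots.bed", function(p) write_bed(hot, p))
    freqs <- group_sv_frequencies(cohort, groups)
    emit("sv_frequencies.tsv", function(p) readr::write_tsv(freqs, p))
    focal <- a$focal %||% groups$group[1]
    fav <- favored_svs(freqs, focal, hi = a$favored_hi %||% 0.5,
                       lo = a$favored_lo %||% 0.05)
    emit("favored_svs.tsv", function(p) readr::write_tsv(fav, p))
    if (!is.null(rga_genes)) {
      ctx <- annotate_sv_context(cohort, rga_genes$genes)
      emit("sv_context.tsv",
           function(p) readr::write_tsv(sv_context_summary(ctx), p))
    }
    message("pipeline: sv done (", nrow(hot), " hotspots, ", nrow(fav),
            " ", focal, "-favored SVs)")
  }

  # ---- tree ----
  if (!is.null(cfg$tree)) {
    a <- cfg$tree
    cohort <- if (!is.null(svs)) svs$cohort else read_vcf(a$vcf, sv_mode = TRUE)
    dm <- p_distance_matrix(cohort, measure = a$measure %||% "dosage")
    tree <- nj_tree(dm)
    emit("distances.tsv", function(p) {
      readr::write_tsv(as_tibble(as.data.frame(dm), rownames = "sample"), p)
    })
    emit("tree.nwk", function(p) write_newick(tree, p))
    message("pipeline: tree done (", length(tree$tip.label), " tips)")
  }

  # ---- rga ----
  if (!is.null(cfg$rga)) {
    a <- cfg$rga
    genes <- if (!is.null(rga_genes)) rga_genes$genes else read_gff(a$gff)
    clus <- cluster_genes(genes, max_gap = a$cluster_gap %||% 200000)
    pairs <- paired_nlr(genes, max_gap = a$pair_gap %||% 20000)
    emit("rga_clusters.tsv", function(p) {
      readr::write_tsv(clus |> mutate(gene_ids = purrr::map_chr(
        .data$gene_ids, paste, collapse = ",")), p)
    })
    emit("paired_nlr.tsv", function(p) readr::write_tsv(pairs, p))
    emit("clustered_fraction.tsv",
         function(p) readr::write_tsv(clustered_fraction(genes, clus), p))
    message("pipeline: rga done (", nrow(clus), " clusters, ", nrow(pairs),
            " pairs)")
  }

  manifest <- list(
    seed = seed,
    parameters = cfg,
    files = lapply(setNames(basename(files), basename(files)), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
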
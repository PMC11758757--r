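# Readers and writers for the standard formats the pipeline touches.
# Coordinates are 1-based inclusive everywhere inside the package (the GFF/VCF
# native convention); BED's 0-based half-open convention exists only at the
# I/O boundary.

#' Read an orthogroup membership table into a family matrix
#'
#' Parses an OrthoFinder-style table: tab-separated, first column the family
#' (orthogroup) ID, remaining columns one per assembly holding comma-separated
#' gene ID lists (empty cell = family absent from that assembly). The result
#' is the family matrix that all partitioning operates on: a tibble with a
#' `family_id` column followed by one integer gene-count column per assembly
#' (explicit zeros, never `NA`).
#'
#' @param path Path to the tab-separated table. The first line is the header
#'   (family ID column name, then assembly names).
#' @return A family-matrix tibble: `family_id` plus one count column per
#'   assembly.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("Orthogroup\ta1\ta2\ta3", "OG1\tg1, g2\t\tg3"), tf)
#' read_orthogroup_table(tf)
#' @export
read_orthogroup_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) abort("orthogroup table has no data rows")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  n_col <- length(header)
  if (n_col < 2) abort("orthogroup table needs a family column plus assemblies")
  rows <- cells[-1]
  widths <- lengths(rows)
  if (any(widths > n_col)) {
    bad <- which(widths > n_col)[1] + 1L
    abort(paste0("ragged orthogroup table: line ", bad, " has ",
                 widths[bad - 1L], " fields, header has ", n_col))
  }
  # strsplit drops trailing empty fields; pad them back as absences
  rows <- lapply(rows, function(r) c(r, rep("", n_col - length(r))))
  fam_ids <- vapply(rows, `[[`, character(1), 1)
  if (anyDuplicated(fam_ids)) {
    abort(paste0("duplicate family IDs in orthogroup table: ",
                 paste(unique(fam_ids[duplicated(fam_ids)]), collapse = ", ")))
  }
  count_cell <- function(x) {
    x <- trimws(x)
    if (x == "") 0L else length(strsplit(x, ",[ ]*")[[1]])
  }
  counts <- vapply(rows, function(r) {
    vapply(r[-1], count_cell, integer(1))
  }, integer(n_col - 1L))
  counts <- matrix(counts, ncol = n_col - 1L, byrow = TRUE,
                   dimnames = list(NULL, header[-1]))
  if (any(rowSums(counts) == 0)) {
    abort("family with zero members in every assembly violates the family-matrix invariant")
  }
  bind_cols(tibble(family_id = fam_ids), as_tibble(counts))
}

#' Write a family matrix as an orthogroup membership table
#'
#' The inverse of [read_orthogroup_table()]. Member gene IDs are synthesized
#' as `<family>|<assembly>|<i>` unless the counts came with real members;
#' re-reading the written file reproduces the counts exactly.
#'
#' @param fm Family-matrix tibble (`family_id` + assembly count columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthogroup_table <- function(fm, path) {
  asm <- setdiff(names(fm), "family_id")
  header <- paste(c("Orthogroup", asm), collapse = "\t")
  body <- vapply(seq_len(nrow(fm)), function(i) {
    cells <- vapply(asm, function(a) {
      k <- fm[[a]][i]
      if (k == 0) "" else paste0(fm$family_id[i], "|", a, "|", seq_len(k),
                                 collapse = ", ")
    }, character(1))
    paste(c(fm$family_id[i], cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a variant cohort
#'
#' Uses \pkg{vcfR} for parsing and converts per-sample `GT` calls to diploid
#' alternate-allele dosages (0/1/2; `./.` becomes `NA`; phased and unphased
#' genotypes are treated identically). In `sv_mode` the variant type and
#' length come from the `SVTYPE`/`SVLEN`/`END` INFO keys (lengths use the
#' absolute-value convention, so `SVLEN=-120` is a 120 bp deletion);
#' otherwise they come from REF/ALT allele lengths.
#'
#' @param path Path to a VCF 4.x file (plain or gzipped).
#' @param sv_mode Logical; interpret records as structural variants.
#' @param multiallelic `"error"` (default) rejects records with more than one
#'   ALT allele; `"split"` expands each ALT allele into its own biallelic
#'   record (dosage = copies of that allele).
#' @return A variant cohort tibble (see [cohort_samples()]).
#' @export
read_vcf <- function(path, sv_mode = FALSE,
                     multiallelic = c("error", "split")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) abort("VCF has no per-sample genotype columns")
  fmt_fields <- strsplit(gt[, "FORMAT"], ":", fixed = TRUE)
  gt_idx <- vapply(fmt_fields, function(f) match("GT", f), integer(1))
  if (anyNA(gt_idx)) abort("GT field missing from FORMAT in at least one record")

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  chrom_runs <- rle(chrom)$values
  if (anyDuplicated(chrom_runs)) abort("unsorted VCF: chromosome blocks interleaved")
  if (any(unlist(tapply(pos, factor(chrom, levels = chrom_runs), diff)) < 0)) {
    abort("unsorted VCF: positions decrease within a chromosome")
  }

  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (multiallelic == "error" && any(multi)) {
    abort(paste0("multiallelic record at ", chrom[multi][1], ":",
                 pos[multi][1], "; use multiallelic = \"split\" to expand"))
  }

  samples <- colnames(gt)[-1]
  gt_cells <- gt[, -1, drop = FALSE]
  # pull the GT subfield; gt_idx is almost always 1 so fast-path that
  gt_str <- if (all(gt_idx == 1L)) {
    sub(":.*", "", gt_cells)
  } else {
    matrix(mapply(function(cell, k) strsplit(cell, ":", fixed = TRUE)[[1]][k],
                  gt_cells, rep(gt_idx, times = ncol(gt_cells))),
           nrow = nrow(gt_cells))
  }
  # vcfR reports fully missing calls ("./.") as NA cells
  if (any(!is.na(gt_str) & !grepl("[/|]", gt_str))) {
    abort("haploid GT call found; diploid genotypes required")
  }
  a1 <- sub("[/|].*", "", gt_str)
  a2 <- sub(".*[/|]", "", gt_str)

  info <- fix[, "INFO"]
  ref <- fix[, "REF"]
  info_val <- function(key) {
    m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    m
  }
  meta_for_allele <- function(alt_allele) {
    if (sv_mode) {
      vtype <- info_val("SVTYPE")
      svlen <- suppressWarnings(abs(as.integer(info_val("SVLEN"))))
      end <- suppressWarnings(as.integer(info_val("END")))
      len <- ifelse(!is.na(svlen), svlen,
                    ifelse(!is.na(end), end - pos + 1L,
                           abs(nchar(alt_allele) - nchar(ref)) ))
      if (anyNA(vtype)) abort("sv_mode: SVTYPE missing from INFO")
      if (!all(vtype %in% c("INS", "DEL", "INV"))) {
        abort("sv_mode: SVTYPE must be INS, DEL or INV")
      }
    } else {
      rl <- nchar(ref)
      al <- nchar(alt_allele)
      vtype <- ifelse(al > rl, "INS", ifelse(al < rl, "DEL", "SNP"))
      len <- ifelse(vtype == "SNP", 1L, abs(al - rl))
    }
    list(vtype = vtype, length = as.integer(len))
  }

  dose_tbl <- function(keep, allele_k, alt_allele) {
    aa1 <- a1[keep, , drop = FALSE]
    aa2 <- a2[keep, , drop = FALSE]
    d <- (aa1 == allele_k) + (aa2 == allele_k)
    d[is.na(aa1) | is.na(aa2) | aa1 == "." | aa2 == "."] <- NA
    storage.mode(d) <- "integer"
    colnames(d) <- samples
    meta <- meta_for_allele(alt_allele)
    bind_cols(
      tibble(chrom = chrom[keep], pos = pos[keep],
             vtype = meta$vtype[keep], length = meta$length[keep]),
      as_tibble(d)
    )
  }

  if (!any(multi)) {
    out <- dose_tbl(rep(TRUE, length(pos)), "1", alt)
  } else {
    parts <- list(dose_tbl(!multi, "1", ifelse(multi, "N", alt)))
    alt_lists <- strsplit(alt, ",", fixed = TRUE)
    for (i in which(multi)) {
      for (k in seq_along(alt_lists[[i]])) {
        keep <- seq_along(pos) == i
        parts[[length(parts) + 1]] <- dose_tbl(keep, as.character(k),
                                               rep(alt_lists[[i]][k], length(pos)))
      }
    }
    out <- bind_rows(parts) |> arrange(match(.data$chrom, chrom_runs), .data$pos)
  }
  out
}

#' Write a variant cohort as VCF 4.2
#'
#' SNPs are written with placeholder alleles (`A`/`T`); structural variants
#' use symbolic ALT alleles with `SVTYPE`, `SVLEN` (negative for deletions)
#' and `END` INFO keys. Dosages map back to unphased `GT` calls, `NA` to
#' `./.`; round-tripping through [read_vcf()] preserves all dosages, types
#' and lengths.
#'
#' @param cohort Variant cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cohort, path) {
  assert_cohort(cohort)
  samples <- cohort_samples(cohort)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  is_sv <- cohort$vtype != "SNP"
  ref <- ifelse(is_sv, "N", "A")
  alt <- ifelse(is_sv, paste0("<", cohort$vtype, ">"), "T")
  svlen <- ifelse(cohort$vtype == "DEL", -cohort$length, cohort$length)
  info <- ifelse(is_sv,
                 paste0("SVTYPE=", cohort$vtype, ";SVLEN=", svlen,
                        ";END=", cohort$pos + cohort$length - 1L),
                 ".")
  d <- dosage_matrix(cohort, samples)
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow = nrow(d))
  gt[is.na(d)] <- "./."
  body <- paste(cohort$chrom, cohort$pos, ".", ref, alt, ".", "PASS", info,
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene` features (via [ape::read.gff()]) into a gene-set tibble with
#' 1-based inclusive coordinates, and attaches any `exon` features to their
#' parent gene as a list-column of exon intervals. Optional `family=` and
#' `rga_class=` attributes populate the family and RGA-class columns used by
#' the clustering and pan-RGA workflows.
#'
#' @param path Path to a GFF3 file.
#' @return A gene-set tibble: `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (`"+"`, `"-"` or `NA`), `family_id`, `rga_class`, `exons` (list of
#'   tibbles with `start`/`end`, or `NULL`).
#' @export
read_gff <- function(path) {
  g <- ape::read.gff(path, GFF3 = TRUE)
  genes <- g[g$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) abort("GFF contains no gene features")
  attr_field <- function(x, key) {
    stringr::str_match(x, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
  }
  ids <- attr_field(genes$attributes, "ID")
  if (anyNA(ids)) abort("gene feature without an ID attribute")
  if (anyDuplicated(ids)) abort("duplicate gene IDs in GFF")
  exons <- g[g$type == "exon", , drop = FALSE]
  exon_parent <- attr_field(exons$attributes, "Parent")
  exon_list <- rep(list(NULL), length(ids))
  if (nrow(exons) > 0) {
    by_parent <- split(seq_len(nrow(exons)), exon_parent)
    hit <- match(names(by_parent), ids)
    for (j in seq_along(by_parent)) {
      if (is.na(hit[j])) next
      idx <- by_parent[[j]]
      exon_list[[hit[j]]] <- tibble(start = as.integer(exons$start[idx]),
                                    end = as.integer(exons$end[idx]))
    }
  }
  tibble(
    gene_id = ids,
    chrom = as.character(genes$seqid),
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    strand = ifelse(as.character(genes$strand) %in% c("+", "-"),
                    as.character(genes$strand), NA_character_),
    family_id = attr_field(genes$attributes, "family"),
    rga_class = attr_field(genes$attributes, "rga_class"),
    exons = exon_list
  ) |> arrange(.data$chrom, .data$start)
}

#' Write a gene set as GFF3
#'
#' @param genes Gene-set tibble as returned by [read_gff()] or
#'   [simulate_rga_geneset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    attrs <- paste0("ID=", genes$gene_id[i])
    if (!is.null(genes$family_id) && !is.na(genes$family_id[i])) {
      attrs <- paste0(attrs, ";family=", genes$family_id[i])
    }
    if (!is.null(genes$rga_class) && !is.na(genes$rga_class[i])) {
      attrs <- paste0(attrs, ";rga_class=", genes$rga_class[i])
    }
    strand <- if (is.na(genes$strand[i])) "." else genes$strand[i]
    lines <- c(lines, paste(genes$chrom[i], "pankiwi", "gene",
                            genes$start[i], genes$end[i], ".", strand, ".",
                            attrs, sep = "\t"))
    ex <- if ("exons" %in% names(genes)) genes$exons[[i]] else NULL
    if (!is.null(ex) && nrow(ex) > 0) {
      for (k in seq_len(nrow(ex))) {
        lines <- c(lines, paste(genes$chrom[i], "pankiwi", "exon",
                                ex$start[k], ex$end[k], ".", strand, ".",
                                paste0("ID=", genes$gene_id[i], ".e", k,
                                       ";Parent=", genes$gene_id[i]),
                                sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample-to-group map
#'
#' Two-column TSV (`sample`, `group`); a header row with exactly those names
#' is tolerated and skipped. Each sample may appear only once.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `sample` and `group`.
#' @export
read_group_map <- function(path) {
  df <- readr::read_tsv(path, col_names = c("sample", "group"),
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (nrow(df) > 0 && df$sample[1] == "sample" && df$group[1] == "group") {
    df <- df[-1, , drop = FALSE]
  }
  if (anyNA(df$sample) || anyNA(df$group)) abort("group map contains missing fields")
  as_group_map(df)
}

#' Write a group map
#' @param groups Tibble with `sample` and `group` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_map <- function(groups, path) {
  readr::write_tsv(as_group_map(groups), path, col_names = FALSE)
  invisible(path)
}

#' Write regions as BED
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention (a gene at 1-based `[101, 200]` becomes
#' `100<TAB>200`).
#'
#' @param regions Region tibble (`chrom`, `start`, `end`, 1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  readr::write_tsv(
    tibble(chrom = regions$chrom, start = regions$start - 1L, end = regions$end),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Read a BED file into a 1-based region tibble
#' @param path Path to a BED file (first three columns used).
#' @return Region tibble (`chrom`, `start`, `end`, 1-based inclusive).
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE,
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  tibble(chrom = df[[1]],
         start = as.integer(df[[2]]) + 1L,
         end = as.integer(df[[3]]))
}

#' Write a phylogenetic tree in Newick format
#'
#' Branch lengths are written with 6 decimal places, so write-then-read
#' round-trips to within 1e-6.
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
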
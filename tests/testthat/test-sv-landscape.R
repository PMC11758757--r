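ctx_genes <- function() {
  toy_genes(tibble::tibble(
    gene_id = c("gA", "gB"),
    chrom = "chr01",
    start = c(10000L, 14000L),
    end = c(12000L, 16000L),
    strand = c("+", "-"),
    exons = list(tibble::tibble(start = c(10000L, 11500L),
                                end = c(10500L, 12000L)),
                 tibble::tibble(start = 14000L, end = 16000L))
  ))
}

test_that("context precedence puts exon above flank categories", {
  genes <- ctx_genes()
  # inside gA's second exon AND within 1 kb upstream of minus-strand gB? No:
  # gB upstream is [16001,17000]. Use a variant in exon and in gB's downstream
  sv <- toy_cohort(random_dosages(1, c("s1", "s2")), pos = 11600L,
                   vtype = "DEL", length = 300L)
  expect_equal(annotate_sv_context(sv, genes)$context, "exon")
})

test_that("flank windows respect strand", {
  genes <- ctx_genes()
  # 500 bp 5' of the minus-strand gene gB means beyond its end coordinate
  sv <- toy_cohort(random_dosages(1, c("s1", "s2")), pos = 16500L,
                   vtype = "INS", length = 80L)
  expect_equal(annotate_sv_context(sv, genes)$context, "upstream")
  # and 3' of gB (below its start) is downstream
  sv2 <- toy_cohort(random_dosages(1, c("s1", "s2")), pos = 13500L,
                    vtype = "INS", length = 60L)
  expect_equal(annotate_sv_context(sv2, genes)$context, "downstream")
})

test_that("geneless exon structure collapses to genic with a warning", {
  genes <- toy_genes(tibble::tibble(
    gene_id = "g1", chrom = "chr01", start = 5000L, end = 8000L, strand = "+"
  ))
  sv <- toy_cohort(random_dosages(1, c("s1", "s2")), pos = 6000L,
                   vtype = "DEL", length = 100L)
  expect_warning(ann <- annotate_sv_context(sv, genes), "genic")
  expect_equal(ann$context, "genic")
})

test_that("context labels match brute-force interval arithmetic", {
  set.seed(91)
  for (rep in 1:8) {
    n_genes <- 6
    starts <- sort(sample.int(80000, n_genes)) + 10000L
    genes <- toy_genes(tibble::tibble(
      gene_id = sprintf("g%d", seq_len(n_genes)),
      chrom = sample(c("chr01", "chr02"), n_genes, replace = TRUE),
      start = starts,
      end = starts + sample(500:4000, n_genes),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      exons = lapply(seq_len(n_genes), function(i) {
        if (runif(1) < 0.2) return(NULL)
        s <- starts[i] + sample(0:200, 1)
        tibble::tibble(start = s, end = s + sample(100:400, 1))
      })
    ))
    nv <- 40
    cohort <- toy_cohort(
      random_dosages(nv, c("s1", "s2")),
      chrom = sample(c("chr01", "chr02"), nv, replace = TRUE),
      pos = sample.int(100000, nv),
      vtype = sample(c("INS", "DEL", "INV"), nv, replace = TRUE),
      length = sample(50:3000, nv)
    ) |> dplyr::arrange(chrom, pos)
    got <- annotate_sv_context(cohort, genes)$context
    expect_equal(got, oracle_sv_context(cohort, genes))
  }
})

test_that("context categories partition the cohort and percentages sum to 100", {
  sim <- simulate_sv_cohort(groups = c(LG = 4, MG1 = 4), n_sv = 200, seed = 92)
  rga <- simulate_rga_geneset(seed = 92,
                              chrom_lengths = c(chr01 = 1e7, chr02 = 1e7),
                              n_clusters = 3, n_pairs = 2, n_decoys = 1,
                              n_singletons = 10)
  ann <- annotate_sv_context(sim$cohort, rga$genes)
  expect_false(anyNA(ann$context))
  s <- sv_context_summary(ann)
  expect_equal(sum(s$n), 200L)
  expect_lt(abs(sum(s$pct) - 100), 0.05)
})

test_that("an interior SV start falls in window/step overlapping windows", {
  cohort <- toy_cohort(random_dosages(1, c("s1", "s2")), pos = 500000L,
                       vtype = "DEL", length = 100L)
  track <- sv_window_counts(cohort, window = 100000, step = 20000,
                            chrom_lengths = c(chr01 = 1e6))
  expect_equal(sum(track$value), 5)  # ceil(100000 / 20000)
  covering <- track[track$value > 0, ]
  expect_true(all(covering$start <= 500000 & covering$end >= 500000))
})

test_that("empty cohorts give all-zero tracks", {
  cohort <- toy_cohort(random_dosages(1, c("s1", "s2")), pos = 100L)[0, ]
  track <- sv_window_counts(cohort, chrom_lengths = c(chr01 = 5e5))
  expect_true(all(track$value == 0))
})

test_that("hotspot calling selects exactly the top strict-exceedance windows", {
  set.seed(93)
  vals <- sample(1000, 200)  # distinct values
  track <- tibble::tibble(
    chrom = "chr01",
    start = seq(1L, by = 20000L, length.out = 200),
    end = seq(100000L, by = 20000L, length.out = 200),
    value = as.numeric(vals), n_sites = 1L
  )
  thr <- attr(call_sv_hotspots(track), "threshold")
  expect_equal(sum(vals > thr), 10L)  # exactly top 5% of 200
  expect_equal(nrow(call_sv_hotspots(tibble::tibble(
    chrom = "chr01", start = 1L, end = 10L, value = 5, n_sites = 1L
  ))), 0L)
})

test_that("selected overlapping windows chain-merge into single regions", {
  track <- tibble::tibble(
    chrom = "chr01",
    start = c(1L, 20001L, 40001L, 200001L),
    end = c(100000L, 120000L, 140000L, 300000L),
    value = c(50, 60, 55, 1), n_sites = 1L
  )
  hs <- call_sv_hotspots(track, percentile = 25)
  expect_equal(nrow(hs), 1L)
  expect_equal(c(hs$start, hs$end), c(1L, 140000L))
})

test_that("group frequencies count alleles over non-missing calls", {
  gm <- tibble::tibble(sample = sprintf("s%d", 1:6),
                       group = rep(c("G1", "G2"), each = 3))
  d <- matrix(c(2L, 1L, 0L, NA, 0L, 2L,
                NA, NA, NA, 1L, 1L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, gm$sample))
  cohort <- toy_cohort(d, vtype = "DEL", length = 100L)
  fr <- group_sv_frequencies(cohort, gm)
  expect_equal(fr$G1, c(3 / 6, NA))
  expect_equal(fr$G2, c(2 / 4, 2 / 6))

  # a 4-diploid group with dosages (2,1,0,0) -> 3/8
  gm2 <- tibble::tibble(sample = sprintf("t%d", 1:4), group = "G")
  d2 <- matrix(c(2L, 1L, 0L, 0L), nrow = 1, dimnames = list(NULL, gm2$sample))
  expect_equal(group_sv_frequencies(toy_cohort(d2), gm2)$G, 0.375)
})

test_that("group frequencies agree with a brute-force tally", {
  set.seed(94)
  gm <- tibble::tibble(sample = sprintf("s%02d", 1:12),
                       group = rep(c("A", "B", "C"), each = 4))
  d <- random_dosages(50, gm$sample, miss_rate = 0.2)
  fr <- group_sv_frequencies(toy_cohort(d), gm)
  for (g in c("A", "B", "C")) {
    cols <- gm$sample[gm$group == g]
    want <- apply(d[, cols], 1, function(r) {
      if (all(is.na(r))) NA_real_ else sum(r, na.rm = TRUE) / (2 * sum(!is.na(r)))
    })
    expect_equal(fr[[g]], want)
  }
  # invariant to sample order
  fr2 <- group_sv_frequencies(toy_cohort(d[, sample(ncol(d))]), gm)
  expect_equal(fr2$A, fr$A)
})

test_that("favored screen applies strict thresholds and the NA rule", {
  meta <- tibble::tibble(chrom = "chr01", pos = 1:5 * 100L,
                         vtype = "DEL", length = 100L)
  freqs <- dplyr::bind_cols(meta, tibble::tibble(
    LG = c(0.75, 0.50, 0.60, 0.80, 0.90),
    MG1 = c(0.00, 0.00, 0.05, NA, 0.01),
    MG2 = c(0.02, 0.00, 0.00, 0.00, 0.04)
  ))
  attr(freqs, "freq_groups") <- c("LG", "MG1", "MG2")
  fav <- favored_svs(freqs, "LG")
  expect_equal(fav$pos, c(100L, 500L))   # 0.50 fails strict >, 0.05 fails strict <
  fav2 <- favored_svs(freqs, "LG", na_rule = "ignore")
  expect_equal(fav2$pos, c(100L, 400L, 500L))
})

test_that("favored screen matches rule enumeration on a frequency grid", {
  grid_vals <- c(0, 0.04, 0.05, 0.5, 0.51, 1)
  grid <- expand.grid(LG = grid_vals, MG1 = grid_vals, MG2 = grid_vals)
  meta <- tibble::tibble(chrom = "chr01", pos = seq_len(nrow(grid)) * 10L,
                         vtype = "INS", length = 60L)
  freqs <- dplyr::bind_cols(meta, tibble::as_tibble(grid))
  attr(freqs, "freq_groups") <- c("LG", "MG1", "MG2")
  got <- freqs$pos %in% favored_svs(freqs, "LG")$pos
  want <- vapply(seq_len(nrow(grid)), function(i) {
    oracle_favored(grid$LG[i], c(grid$MG1[i], grid$MG2[i]))
  }, logical(1))
  expect_equal(got, want)
})

test_that("binomial-mode generator yields no favored calls among common shared SVs", {
  sim <- simulate_sv_cohort(seed = 95)
  fr <- group_sv_frequencies(sim$cohort, sim$groups)
  fav <- favored_svs(fr, "LG")
  called <- paste(fr$chrom, fr$pos) %in% paste(fav$chrom, fav$pos)
  common_shared <- !sim$truth$favored &
    sim$truth$freq_LG >= 0.2 & sim$truth$freq_MG1 >= 0.2 &
    sim$truth$freq_MG2 >= 0.2
  expect_equal(sum(called & common_shared), 0L)
})

test_that("hotspot gene classes follow body-first, then upstream overlap", {
  hotspots <- tibble::tibble(chrom = "chr01", start = 50000L, end = 60000L)
  genes <- toy_genes(tibble::tibble(
    gene_id = c("body", "up_plus", "up_minus", "neither"),
    chrom = "chr01",
    start = c(59999L, 61000L, 40000L, 80000L),
    end = c(62000L, 63000L, 48500L, 82000L),
    strand = c("+", "+", "-", "+")
  ))
  cls <- classify_genes_by_hotspot(genes, hotspots, upstream = 2000)
  expect_equal(cls$hotspot_class,
               c("SV-hotspot", "SV-hotspot-upstream",
                 "SV-hotspot-upstream", "non-SV-hotspot"))
})

test_that("hotspot gene classes match brute-force interval checks", {
  set.seed(96)
  for (rep in 1:10) {
    hs <- tibble::tibble(chrom = "chr01",
                         start = sort(sample.int(90000, 3)) * 10L)
    hs$end <- hs$start + sample(5000:20000, 3)
    hs <- pankiwi:::merge_regions(hs)
    starts <- sample.int(1000000, 30)
    genes <- toy_genes(tibble::tibble(
      gene_id = sprintf("g%d", 1:30), chrom = "chr01",
      start = starts, end = starts + sample(500:5000, 30),
      strand = sample(c("+", "-"), 30, replace = TRUE)
    ))
    got <- classify_genes_by_hotspot(genes, hs)$hotspot_class
    want <- vapply(seq_len(nrow(genes)), function(i) {
      body <- any(genes$start[i] <= hs$end & genes$end[i] >= hs$start)
      if (body) return("SV-hotspot")
      if (genes$strand[i] == "+") {
        us <- genes$start[i] - 2000; ue <- genes$start[i] - 1
      } else {
        us <- genes$end[i] + 1; ue <- genes$end[i] + 2000
      }
      if (any(us <= hs$end & ue >= hs$start)) "SV-hotspot-upstream"
      else "non-SV-hotspot"
    }, character(1))
    expect_equal(got, want)
  }
})

test_that("DE fractions per class are plain set arithmetic", {
  classes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:20),
    hotspot_class = rep(c("SV-hotspot", "non-SV-hotspot"), each = 10)
  )
  de <- list(heat = sprintf("g%02d", c(1, 2, 3, 15)))
  fc <- list(heat = setNames(c(5, 2, 8, 1), de$heat))
  res <- deg_fraction_by_class(classes, de, fc)
  expect_equal(res$pct_deg[res$hotspot_class == "SV-hotspot"], 30)
  expect_equal(res$pct_deg[res$hotspot_class == "non-SV-hotspot"], 10)
  expect_equal(res$pct_deg_strong[res$hotspot_class == "SV-hotspot"], 20)

  empty <- deg_fraction_by_class(classes[0, ], de)
  expect_equal(nrow(empty), 0L)
})

test_that("genotype filter applies PLINK-style geno and maf thresholds", {
  samples <- sprintf("s%02d", 1:10)
  d <- rbind(
    c(rep(NA, 6), 0L, 0L, 1L, 2L),      # 60% missing -> dropped
    c(rep(NA, 5), 0L, 0L, 0L, 1L, 2L),  # 50% missing, maf 0.3 -> kept
    c(1L, rep(0L, 9)),                  # maf exactly 0.05 -> kept
    c(2L, rep(0L, 9)),                  # maf 0.10 -> kept
    rep(0L, 10)                         # monomorphic, maf 0 -> dropped
  )
  colnames(d) <- samples
  cohort <- toy_cohort(d, vtype = "DEL", length = 100L)
  kept <- filter_sv_genotype_matrix(cohort)
  expect_equal(kept$pos, cohort$pos[c(2, 3, 4)])

  set.seed(97)
  for (rep in 1:10) {
    dd <- random_dosages(40, samples, miss_rate = 0.3)
    cc <- toy_cohort(dd)
    got <- filter_sv_genotype_matrix(cc)$pos
    want <- cc$pos[apply(dd, 1, oracle_filter_keep)]
    expect_equal(got, want)
  }
})
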
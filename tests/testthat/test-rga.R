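lin_genes <- function(starts, ends, family = "FAM1", strand = "+",
                      class = "NBS", chrom = "chr01") {
  toy_genes(tibble::tibble(
    gene_id = sprintf("g%02d", seq_along(starts)),
    chrom = chrom, start = as.integer(starts), end = as.integer(ends),
    strand = rep_len(strand, length(starts)),
    family_id = rep_len(family, length(starts)),
    rga_class = rep_len(class, length(starts))
  ))
}

test_that("single-linkage chaining clusters across successive 150 kb gaps", {
  # gaps 150 kb then 150 kb: ends are 300 kb apart yet one chained cluster
  g <- lin_genes(c(1e6, 1e6 + 155000, 1e6 + 310000),
                 c(1e6 + 4999, 1e6 + 159999, 1e6 + 314999))
  cl <- cluster_genes(g)
  expect_equal(nrow(cl), 1L)
  expect_equal(sort(cl$gene_ids[[1]]), c("g01", "g02", "g03"))
  # the diameter reading splits the same layout
  cl2 <- cluster_genes(g, method = "diameter")
  expect_equal(sort(vapply(cl2$gene_ids, length, integer(1))), c(2L))
})

test_that("a gap of 200,001 bp splits clusters at the boundary", {
  g <- lin_genes(c(1e6, 1e6 + 5000 + 200001, 1e6 + 5000 + 200001 + 5000 + 200000),
                 c(1e6 + 4999, 1e6 + 5000 + 200001 + 4999,
                   1e6 + 5000 + 200001 + 5000 + 200000 + 4999))
  # gene1-gene2 gap = 200001 (split); gene2-gene3 gap = 200000 (join)
  cl <- cluster_genes(g)
  expect_equal(nrow(cl), 1L)
  expect_equal(sort(cl$gene_ids[[1]]), c("g02", "g03"))
})

test_that("different families never co-cluster even when interleaved", {
  g <- dplyr::bind_rows(
    lin_genes(c(1000, 21000), c(5000, 25000), family = "A"),
    lin_genes(c(11000, 31000), c(15000, 35000), family = "B")
  )
  g$gene_id <- sprintf("g%02d", 1:4)
  cl <- cluster_genes(g, max_gap = 50000)
  expect_equal(nrow(cl), 2L)
  expect_setequal(cl$family_id, c("A", "B"))
})

test_that("clustering matches the brute-force chain oracle on random layouts", {
  set.seed(111)
  for (rep in 1:15) {
    n <- 25
    starts <- sort(sample.int(3e6, n))
    g <- toy_genes(tibble::tibble(
      gene_id = sprintf("g%02d", seq_len(n)),
      chrom = sample(c("chr01", "chr02"), n, replace = TRUE),
      start = starts, end = starts + sample(1000:5000, n),
      strand = sample(c("+", "-"), n, replace = TRUE),
      family_id = sample(c("F1", "F2", "F3"), n, replace = TRUE),
      rga_class = "NBS"
    ))
    got <- lapply(cluster_genes(g, max_gap = 100000)$gene_ids, sort)
    expect_true(setequal(got, oracle_clusters(g, max_gap = 100000)))
  }
})

test_that("genes without a family are skipped with a warning", {
  g <- lin_genes(c(1000, 10000), c(5000, 14000))
  g$family_id[2] <- NA
  expect_warning(cl <- cluster_genes(g), "skipped")
  expect_equal(nrow(cl), 0L)
})

test_that("clustered fractions are per-class membership percentages", {
  g <- dplyr::bind_rows(
    lin_genes(c(1000, 10000), c(5000, 14000), class = "NBS"),
    lin_genes(c(1e6, 2e6), c(1e6 + 4000, 2e6 + 4000), family = "SOLO1",
              class = "RLK")
  )
  g$gene_id <- sprintf("g%02d", 1:4)
  g$family_id[3:4] <- c("SOLO1", "SOLO2")
  cl <- cluster_genes(g)
  cf <- clustered_fraction(g, cl)
  expect_equal(cf$pct_clustered[cf$rga_class == "NBS"], 100)
  expect_equal(cf$pct_clustered[cf$rga_class == "RLK"], 0)
})

test_that("head-to-head orientation defines paired NLRs", {
  g <- lin_genes(c(10000, 18000), c(15000, 23000), strand = c("-", "+"))
  pr <- paired_nlr(g)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$gene_minus, "g01")
  expect_equal(pr$gene_plus, "g02")
  expect_equal(pr$gap, 18000L - 15000L - 1L)

  # tail-to-tail (+,-) is not a pair
  tt <- lin_genes(c(10000, 18000), c(15000, 23000), strand = c("+", "-"))
  expect_equal(nrow(paired_nlr(tt)), 0L)
  # nor divergent genes too far apart
  far <- lin_genes(c(10000, 60000), c(15000, 65000), strand = c("-", "+"))
  expect_equal(nrow(paired_nlr(far, max_gap = 20000)), 0L)
})

test_that("pairing is NBS-adjacent, greedy and disjoint", {
  # triple -,+,+ : greedy takes the first two only
  g <- lin_genes(c(10000, 18000, 26000), c(15000, 23000, 31000),
                 strand = c("-", "+", "+"))
  pr <- paired_nlr(g)
  expect_equal(nrow(pr), 1L)
  expect_equal(c(pr$gene_minus, pr$gene_plus), c("g01", "g02"))

  # an intervening non-NBS gene does not break NBS adjacency
  g2 <- lin_genes(c(10000, 13000, 18000), c(12000, 14000, 23000),
                  strand = c("-", "+", "+"))
  g2$rga_class[2] <- "RLK"
  pr2 <- paired_nlr(g2)
  expect_equal(c(pr2$gene_minus, pr2$gene_plus), c("g01", "g03"))

  # every reported pair satisfies the predicates by construction
  sim <- simulate_rga_geneset(seed = 112)
  pr3 <- paired_nlr(sim$genes)
  nbs <- sim$genes[!is.na(sim$genes$rga_class) & sim$genes$rga_class == "NBS", ]
  for (i in seq_len(nrow(pr3))) {
    gm <- nbs[nbs$gene_id == pr3$gene_minus[i], ]
    gp <- nbs[nbs$gene_id == pr3$gene_plus[i], ]
    expect_equal(c(gm$strand, gp$strand), c("-", "+"))
    expect_lte(gp$start - gm$end - 1, 20000)
    between <- nbs$chrom == gm$chrom & nbs$start > gm$start & nbs$start < gp$start
    expect_equal(sum(between), 0L)
  }
  expect_equal(anyDuplicated(c(pr3$gene_minus, pr3$gene_plus)), 0L)
})

test_that("missing strands are an error in the pairing workflow only", {
  g <- lin_genes(c(10000, 18000), c(15000, 23000), strand = c("-", "+"))
  g$strand[1] <- NA
  expect_error(paired_nlr(g), "strand")
  expect_silent(cluster_genes(g))
})

test_that("paired-NLR summary reports both rate denominators", {
  g <- lin_genes(c(1e4, 2e4, 3e6, 3.01e6, 6e6),
                 c(1.5e4, 2.5e4, 3.005e6, 3.015e6, 6.05e6),
                 strand = c("-", "+", "-", "+", "+"))
  g$family_id <- c("A", "A", "B", "B", "C")
  s <- paired_nlr_summary(g, paired_nlr(g))
  expect_equal(s$n_nbs, 5L)
  expect_equal(s$n_pairs, 2L)
  expect_equal(s$pct_genes_in_pairs, 80)
  expect_equal(s$pct_pairs_per_nbs, 40)
})

test_that("pan-RGA delegates to the partition with conserved totals", {
  sim <- simulate_family_matrix(n_assemblies = 15,
                                targets = c(core = 26, softcore = 22,
                                            dispensable = 62, cloud = 32),
                                seed = 113)
  classes <- tibble::tibble(
    family_id = sim$matrix$family_id,
    rga_class = sample(c("NBS", "RLK", "RLP", "TM-CC"),
                       nrow(sim$matrix), replace = TRUE)
  )
  pr <- pan_rga(sim$matrix, family_classes = classes)
  s <- pr$summary
  expect_equal(s$n_families[s$category == "total"], 142L)
  expect_equal(sum(pr$class_composition$n_genes),
               s$n_genes[s$category == "total"])
  # per class, gene composition sums to that class's gene total
  by_class <- tapply(pr$class_composition$pct_genes,
                     pr$class_composition$rga_class, sum)
  expect_true(all(abs(by_class - 100) < 0.05))

  # an all-universal matrix is 100% core
  uni <- simulate_family_matrix(n_assemblies = 15,
                                targets = c(core = 20, softcore = 0,
                                            dispensable = 0, cloud = 0),
                                seed = 114)
  su <- pan_rga(uni$matrix)$summary
  expect_equal(su$pct_families[su$category == "core"], 100)
})

test_that("absence in target assemblies is a column test", {
  fm <- tibble::tibble(
    family_id = c("F1", "F2", "F3"),
    a1 = c(0L, 1L, 0L), a2 = c(0L, 0L, 0L), a3 = c(1L, 1L, 2L),
    a4 = c(2L, 0L, 1L)
  )
  hit <- absent_in_target(fm, c("a1", "a2"))
  expect_setequal(hit$family_id, c("F1", "F3"))

  set.seed(115)
  sim <- simulate_family_matrix(n_assemblies = 8,
                                targets = c(core = 10, softcore = 4,
                                            dispensable = 30, cloud = 10),
                                seed = 115)
  target <- c("asm01", "asm02", "asm03")
  got <- absent_in_target(sim$matrix, target)$family_id
  m <- as.matrix(sim$matrix[-1])
  want <- sim$matrix$family_id[
    rowSums(m[, target]) == 0 & rowSums(m[, setdiff(colnames(m), target)]) > 0
  ]
  expect_equal(got, want)
})
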
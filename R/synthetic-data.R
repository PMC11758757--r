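# Synthetic-data generators. Each generator plants a known ground truth so
# the downstream callers can be tested by parameter recovery; with a fixed
# seed every generator is byte-reproducible.

#' Simulate a gene-family matrix with planted partition categories
#'
#' Each family is assigned a category up front (the planted truth), its
#' assembly frequency is drawn uniformly from that category's occupancy band
#' (core: N; softcore: ceil(0.85 N)..N-1; dispensable: 2..ceil(0.85 N)-1;
#' cloud: 1), the member assemblies are sampled uniformly, and per-cell gene
#' counts are 1 plus Poisson(0.3) copies wherever the family is present.
#'
#' @param n_assemblies Number of assemblies N (default 15, the study design).
#' @param targets Named integer vector of family counts per category
#'   (`core`, `softcore`, `dispensable`, `cloud`). The default scales the
#'   published pan-genome composition down to 1,000 families.
#' @param softcore_frac Softcore occupancy fraction (default 0.85).
#' @param seed Random seed.
#' @return A list with `matrix` (family-matrix tibble) and `truth` (tibble
#'   `family_id`, `category`).
#' @export
simulate_family_matrix <- function(n_assemblies = 15,
                                   targets = c(core = 236, softcore = 87,
                                               dispensable = 347, cloud = 330),
                                   softcore_frac = 0.85,
                                   seed = 1) {
  stopifnot(all(targets >= 0), n_assemblies >= 2)
  softcore_min <- ceiling(softcore_frac * n_assemblies)
  if (softcore_min <= 2) {
    abort(paste0("occupancy bands collide at N = ", n_assemblies,
                 " (ceil(", softcore_frac, " N) = ", softcore_min,
                 " <= 2); use a larger number of assemblies"))
  }
  bands <- list(
    core = n_assemblies,
    softcore = seq(softcore_min, n_assemblies - 1L),
    dispensable = seq(2L, softcore_min - 1L),
    cloud = 1L
  )
  cats <- names(targets)
  if (!setequal(cats, names(bands))) {
    abort("targets must name core, softcore, dispensable and cloud")
  }
  set.seed(seed)
  category <- rep(cats, times = targets)
  n_fam <- length(category)
  fam_ids <- sprintf("F%05d", seq_len(n_fam))
  asm_ids <- sprintf("asm%02d", seq_len(n_assemblies))
  counts <- matrix(0L, n_fam, n_assemblies, dimnames = list(NULL, asm_ids))
  for (i in seq_len(n_fam)) {
    band <- bands[[category[i]]]
    freq <- if (length(band) == 1) band else sample(band, 1)
    present <- sample.int(n_assemblies, freq)
    counts[i, present] <- 1L + rpois(freq, 0.3)
  }
  list(
    matrix = bind_cols(tibble(family_id = fam_ids), as_tibble(counts)),
    truth = tibble(family_id = fam_ids,
                   category = factor(category, levels = names(bands)))
  )
}

# Balding-Nichols draw of one group's allele frequencies around ancestral p.
bn_group_freq <- function(p, fst) {
  if (fst == 0) return(p)
  rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
}

# Allocate n_sites sorted unique positions across chromosomes, proportional
# to length.
sim_positions <- function(n_sites, chrom_lengths) {
  share <- chrom_lengths / sum(chrom_lengths)
  n_per <- diff(round(cumsum(c(0, share * n_sites))))
  purrr::map2_dfr(names(chrom_lengths), n_per, function(ch, n) {
    if (n == 0) return(tibble(chrom = character(), pos = integer()))
    tibble(chrom = ch,
           pos = sort(sample.int(chrom_lengths[[ch]], n)))
  })
}

apply_missing <- function(d, rate) {
  if (rate > 0) d[runif(length(d)) < rate] <- NA
  d
}

#' Simulate a SNP cohort under the Balding-Nichols model
#'
#' Ancestral allele frequencies are drawn Uniform(0.05, 0.95); each group's
#' frequency is Beta-distributed around the ancestral one with shape
#' parameters `p(1-F)/F` and `(1-p)(1-F)/F`, so the expected Weir-Cockerham
#' FST between groups equals `fst` (at `fst = 0` the groups share the
#' ancestral frequency exactly). Diploid dosages are Binomial(2, group
#' frequency); positions are uniform on the stated chromosomes.
#'
#' @param groups Named integer vector, group label -> number of diploid
#'   samples. The default mirrors the study's resequencing panel (28 LG,
#'   86 MG individuals).
#' @param fst Target differentiation F in `[0, 1)`.
#' @param n_sites Number of SNP sites.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param missing_rate Per-genotype missing probability (default 0).
#' @param seed Random seed.
#' @return A list with `cohort` (variant cohort tibble) and `groups`
#'   (sample-to-group tibble).
#' @export
simulate_snp_cohort <- function(groups = c(LG = 28, MG = 86),
                                fst = 0.2,
                                n_sites = 10000,
                                chrom_lengths = c(chr01 = 1e7, chr02 = 1e7),
                                missing_rate = 0,
                                seed = 1) {
  stopifnot(length(groups) >= 2, all(groups >= 2), fst >= 0, fst < 1)
  set.seed(seed)
  sites <- sim_positions(n_sites, chrom_lengths)
  n_sites <- nrow(sites)
  p <- runif(n_sites, 0.05, 0.95)
  dose <- lapply(names(groups), function(g) {
    pg <- bn_group_freq(p, fst)
    d <- matrix(rbinom(n_sites * groups[[g]], 2, rep(pg, groups[[g]])),
                nrow = n_sites)
    d <- apply_missing(d, missing_rate)
    storage.mode(d) <- "integer"
    colnames(d) <- sprintf("%s_%02d", g, seq_len(groups[[g]]))
    d
  })
  dose <- do.call(cbind, dose)
  list(
    cohort = bind_cols(
      sites |> mutate(vtype = "SNP", length = 1L),
      as_tibble(dose)
    ),
    groups = tibble(sample = colnames(dose),
                    group = rep(names(groups), times = groups))
  )
}

#' Simulate a structural-variant cohort with planted group-favored SVs
#'
#' A stated fraction of SVs are planted as favored in the focal group: their
#' focal-group allele frequency is drawn Uniform(0.6, 1.0) and every other
#' group's frequency Uniform(0, 0.03). The remainder share one frequency
#' (Uniform over `shared_freq_range`) across all groups. Genotypes are
#' realized per sample by Binomial(2, freq) sampling by default; the
#' `"exact"` mode instead places the closest achievable allele count in each
#' group, which is the mode to use when unit-testing threshold logic.
#' Lengths are log-uniform on `len_range` (>= 50 bp); types are drawn from
#' `type_probs`.
#'
#' @param groups Named integer vector, group label -> samples per group.
#' @param n_sv Number of SVs.
#' @param favored_frac Fraction of SVs planted as focal-group-favored.
#' @param focal Focal group label.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param len_range SV length range in bp (log-uniform; minimum 50).
#' @param type_probs Named probabilities for INS/DEL/INV.
#' @param shared_freq_range Frequency range for non-favored (shared) SVs.
#' @param mode `"binomial"` (default) or `"exact"` genotype realization.
#' @param missing_rate Per-genotype missing probability (default 0).
#' @param seed Random seed.
#' @return A list with `cohort`, `groups`, and `truth` (tibble `chrom`,
#'   `pos`, `favored`, plus the planted per-group frequencies as columns
#'   `freq_<group>`).
#' @export
simulate_sv_cohort <- function(groups = c(LG = 20, MG1 = 20, MG2 = 20),
                               n_sv = 2000,
                               favored_frac = 0.1,
                               focal = "LG",
                               chrom_lengths = c(chr01 = 1e7, chr02 = 1e7),
                               len_range = c(50, 10000),
                               type_probs = c(INS = 0.45, DEL = 0.45, INV = 0.10),
                               shared_freq_range = c(0.05, 0.95),
                               mode = c("binomial", "exact"),
                               missing_rate = 0,
                               seed = 1) {
  mode <- match.arg(mode)
  stopifnot(focal %in% names(groups), len_range[1] >= 50)
  set.seed(seed)
  sites <- sim_positions(n_sv, chrom_lengths)
  n_sv <- nrow(sites)
  favored <- seq_len(n_sv) %in% sample.int(n_sv, round(n_sv * favored_frac))

  shared <- runif(n_sv, shared_freq_range[1], shared_freq_range[2])
  freqs <- sapply(names(groups), function(g) {
    f <- shared
    if (g == focal) {
      f[favored] <- runif(sum(favored), 0.6, 1.0)
    } else {
      f[favored] <- runif(sum(favored), 0, 0.03)
    }
    f
  })

  exact_doses <- function(p, n) {
    k <- round(2 * n * p)
    d <- integer(n)
    d[seq_len(k %/% 2)] <- 2L
    if (k %% 2 == 1) d[k %/% 2 + 1L] <- 1L
    sample(d)
  }
  dose <- lapply(names(groups), function(g) {
    n <- groups[[g]]
    d <- if (mode == "binomial") {
      matrix(rbinom(n_sv * n, 2, rep(freqs[, g], n)), nrow = n_sv)
    } else {
      t(vapply(freqs[, g], exact_doses, integer(n), n = n))
    }
    d <- apply_missing(d, missing_rate)
    storage.mode(d) <- "integer"
    colnames(d) <- sprintf("%s_%02d", g, seq_len(n))
    d
  })
  dose <- do.call(cbind, dose)

  lens <- pmax(50L, as.integer(round(exp(runif(n_sv, log(len_range[1]),
                                               log(len_range[2]))))))
  vtypes <- sample(names(type_probs), n_sv, replace = TRUE, prob = type_probs)

  truth <- bind_cols(sites, tibble(favored = favored),
                     as_tibble(freqs) |> rlang::set_names(paste0("freq_", names(groups))))
  list(
    cohort = bind_cols(sites |> mutate(vtype = vtypes, length = lens),
                       as_tibble(dose)),
    groups = tibble(sample = colnames(dose),
                    group = rep(names(groups), times = groups)),
    truth = truth
  )
}

#' Simulate an RGA gene set with planted clusters and paired NLRs
#'
#' Plants, on the stated chromosomes: multi-gene same-family clusters whose
#' intra-cluster gaps are below 200 kb; head-to-head paired NLRs (two
#' adjacent NBS genes, minus strand then plus strand in coordinate order,
#' separated by a short gap); tail-to-tail NBS decoy pairs that must NOT be
#' detected as paired; and singleton genes of mixed RGA classes. Consecutive
#' planted elements are separated by gaps above 200 kb so planted clusters
#' never chain together. Each gene carries 1-3 exons.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param n_clusters Number of planted multi-gene clusters.
#' @param cluster_size Range (min, max) of genes per planted cluster.
#' @param n_pairs Number of planted head-to-head NBS pairs.
#' @param n_decoys Number of planted tail-to-tail NBS pairs (negative truth).
#' @param n_singletons Number of singleton genes.
#' @param class_probs Named RGA-class mixture for non-NBS elements.
#' @param seed Random seed.
#' @return A list with `genes` (gene-set tibble) and `truth` (list with
#'   `clusters`: tibble `cluster_id`, `gene_id`; and `pairs`: tibble
#'   `gene_minus`, `gene_plus`).
#' @export
simulate_rga_geneset <- function(chrom_lengths = c(chr01 = 1.5e7, chr02 = 1.5e7),
                                 n_clusters = 8,
                                 cluster_size = c(2, 5),
                                 n_pairs = 6,
                                 n_decoys = 3,
                                 n_singletons = 30,
                                 class_probs = c(NBS = 0.3, RLK = 0.45,
                                                 RLP = 0.1, `TM-CC` = 0.15),
                                 seed = 1) {
  set.seed(seed)
  elements <- c(rep("cluster", n_clusters), rep("pair", n_pairs),
                rep("decoy", n_decoys), rep("single", n_singletons))
  elements <- sample(elements)
  chroms <- rep_len(names(chrom_lengths), length(elements))
  cursor <- setNames(rep(1L, length(chrom_lengths)), names(chrom_lengths))

  rows <- list()
  truth_clusters <- list()
  truth_pairs <- list()
  fam_i <- 0L
  gene_i <- 0L

  gene_len <- function() as.integer(round(runif(1, 1000, 5000)))
  new_gene <- function(ch, start, len, strand, fam, class) {
    gene_i <<- gene_i + 1L
    start <- as.integer(unname(start))
    n_ex <- sample(1:3, 1)
    bounds <- sort(sample(seq(0L, len - 1L), 2 * n_ex))
    exons <- tibble(start = start + bounds[seq(1, 2 * n_ex, 2)],
                    end = start + bounds[seq(2, 2 * n_ex, 2)])
    tibble(gene_id = sprintf("RGA%04d", gene_i), chrom = ch,
           start = start, end = start + len - 1L, strand = strand,
           family_id = fam, rga_class = class, exons = list(exons))
  }

  for (e in seq_along(elements)) {
    ch <- chroms[e]
    pos <- cursor[ch] + as.integer(round(runif(1, 250000, 500000)))
    fam_i <- fam_i + 1L
    fam <- sprintf("RGAFAM%03d", fam_i)
    kind <- elements[e]
    if (kind == "cluster") {
      k <- sample(seq(cluster_size[1], cluster_size[2]), 1)
      class <- if (runif(1) < 0.7) "NBS" else
        sample(names(class_probs), 1, prob = class_probs)
      members <- list()
      for (j in seq_len(k)) {
        len <- gene_len()
        g <- new_gene(ch, pos, len, sample(c("+", "-"), 1), fam, class)
        members[[j]] <- g
        pos <- g$end + 1L + as.integer(round(runif(1, 5000, 150000)))
      }
      members <- bind_rows(members)
      rows[[length(rows) + 1]] <- members
      truth_clusters[[length(truth_clusters) + 1]] <-
        tibble(cluster_id = fam, gene_id = members$gene_id)
      cursor[ch] <- max(members$end)
    } else if (kind == "pair" || kind == "decoy") {
      len1 <- gene_len(); len2 <- gene_len()
      strands <- if (kind == "pair") c("-", "+") else c("+", "-")
      g1 <- new_gene(ch, pos, len1, strands[1], fam, "NBS")
      gap <- as.integer(round(runif(1, 1000, 15000)))
      g2 <- new_gene(ch, g1$end + 1L + gap, len2, strands[2], fam, "NBS")
      rows[[length(rows) + 1]] <- bind_rows(g1, g2)
      truth_clusters[[length(truth_clusters) + 1]] <-
        tibble(cluster_id = fam, gene_id = c(g1$gene_id, g2$gene_id))
      if (kind == "pair") {
        truth_pairs[[length(truth_pairs) + 1]] <-
          tibble(gene_minus = g1$gene_id, gene_plus = g2$gene_id)
      }
      cursor[ch] <- g2$end
    } else {
      class <- sample(names(class_probs), 1, prob = class_probs)
      g <- new_gene(ch, pos, gene_len(), sample(c("+", "-"), 1), fam, class)
      rows[[length(rows) + 1]] <- g
      cursor[ch] <- g$end
    }
    if (cursor[ch] > chrom_lengths[[ch]]) {
      abort(paste0("chromosome ", ch, " too short for the requested layout"))
    }
  }

  genes <- bind_rows(rows) |> arrange(.data$chrom, .data$start)
  list(
    genes = genes,
    truth = list(
      clusters = bind_rows(truth_clusters),
      pairs = if (length(truth_pairs)) bind_rows(truth_pairs) else
        tibble(gene_minus = character(), gene_plus = character())
    )
  )
}
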
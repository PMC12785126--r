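test_that("Venn regions partition the union and the common set is the intersection", {
  r <- intersect_contrasts(list(A = c("a", "b", "c"), B = c("b", "c"),
                                C = "c"))
  expect_setequal(r$common, "c")
  expect_equal(sum(r$region_sizes), 3L)
  expect_setequal(r$regions[["A"]], "a")
  expect_setequal(r$regions[["A&B"]], "b")
  expect_setequal(r$regions[["A&B&C"]], "c")

  same <- intersect_contrasts(list(X = c("p", "q"), Y = c("q", "p")))
  expect_setequal(same$common, c("p", "q"))

  set.seed(29)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    sets <- lapply(seq_len(k), function(j) {
      sample(letters, sample(3:15, 1))
    })
    names(sets) <- LETTERS[seq_len(k)]
    r <- intersect_contrasts(sets)
    universe <- unique(unlist(sets))
    expect_equal(sum(r$region_sizes), length(universe))
    expect_setequal(r$common, Reduce(intersect, sets))
    # brute-force region check, feature by feature
    for (f in universe) {
      pattern <- paste(names(sets)[vapply(sets, function(s)
        f %in% s, logical(1))], collapse = "&")
      expect_true(f %in% r$regions[[pattern]])
    }
  }
})

test_that("up/down tallies are consistent, class-aware and antisymmetric", {
  empty <- data.frame(feature_id = character(), log2fc = numeric(),
                      padj = numeric())
  t0 <- updown_table(list(c1 = call_degs(empty)))
  expect_equal(t0$n_up, 0L)
  expect_equal(t0$n_down, 0L)

  set.seed(37)
  ids <- sprintf("f%03d", 1:120)
  lfc <- c(rep(3, 30), rep(-3, 20), rnorm(70, 0, 0.2))
  res <- call_degs(data.frame(feature_id = ids, log2fc = lfc,
                              padj = c(rep(1e-4, 50), rep(0.9, 70))))
  cls <- stats::setNames(rep(c("lncRNA", "gene"), c(60, 60)), ids)
  tab <- updown_table(list(ct = res), feature_class = cls)
  all_row <- tab[tab$class == "all", ]
  expect_equal(all_row$n_up, 30L)
  expect_equal(all_row$n_down, 20L)
  expect_equal(all_row$n_up + all_row$n_down, all_row$n_significant)
  lnc_row <- tab[tab$class == "lncRNA", ]
  expect_equal(lnc_row$n_up + lnc_row$n_down, lnc_row$n_significant)

  flipped <- res
  flipped$log2fc <- -flipped$log2fc
  flipped <- call_degs(flipped[, c("feature_id", "log2fc", "padj")])
  tab2 <- updown_table(list(ct = flipped))
  expect_equal(tab2$n_up[tab2$class == "all"], 20L)
  expect_equal(tab2$n_down[tab2$class == "all"], 30L)
})

coding_gene <- function(gene, chrom, start, end, strand) {
  genome_annotation(exon_gr(chrom, start, end, strand, paste0(gene, ".t1"),
                            gene = gene, status = "coding"))
}

test_that("cis assignment reproduces the two benchmark configurations", {
  # gene on + at 10,000-20,000; lncRNA on - at 21,000-22,000:
  # past the gene's 3' end, opposite strand
  gene <- coding_gene("Hsd17b12", "chr1", 10000, 20000, "+")
  lnc <- list(transcript_id = "novel.1", chrom = "chr1", strand = "-",
              start = 21000, end = 22000)
  call <- assign_cis_target(lnc, gene)
  expect_equal(call$relative_position, "downstream")
  expect_equal(call$relative_strand, "antisense")
  expect_equal(call$distance, 1000)
  expect_equal(call$target_gene_id, "Hsd17b12")

  # gene on + at 10,000-20,000; lncRNA on + at 5,000-6,000:
  # before the gene's 5' end, same strand
  gene2 <- coding_gene("Sfswap", "chr1", 10000, 20000, "+")
  lnc2 <- list(transcript_id = "novel.2", chrom = "chr1", strand = "+",
               start = 5000, end = 6000)
  call2 <- assign_cis_target(lnc2, gene2)
  expect_equal(call2$relative_position, "upstream")
  expect_equal(call2$relative_strand, "sense")
  expect_equal(call2$distance, 4000)
})

test_that("cis geometry follows the target gene's orientation", {
  # on a minus-strand gene, a lncRNA past the higher coordinate is
  # upstream (the gene's 5' end is at the right)
  gene <- coding_gene("g1", "chr1", 10000, 20000, "-")
  lnc <- list(transcript_id = "n", chrom = "chr1", strand = "-",
              start = 21000, end = 22000)
  call <- assign_cis_target(lnc, gene)
  expect_equal(call$relative_position, "upstream")
  expect_equal(call$relative_strand, "sense")

  inside <- list(transcript_id = "n2", chrom = "chr1", strand = "+",
                 start = 12000, end = 13000)
  call2 <- assign_cis_target(inside, gene)
  expect_equal(call2$relative_position, "overlapping")
  expect_equal(call2$distance, 0)
})

test_that("cis assignment is translation-invariant and strand-flip consistent", {
  set.seed(43)
  for (i in 1:20) {
    gs <- sample(5000:50000, 1)
    ge <- gs + sample(2000:20000, 1)
    gstrand <- sample(c("+", "-"), 1)
    ls <- ge + sample(100:5000, 1) * sample(c(-1, 1), 1)
    if (ls < 1) ls <- 1
    le <- ls + sample(200:3000, 1)
    lnc <- list(transcript_id = "n", chrom = "chr1",
                strand = sample(c("+", "-"), 1), start = ls, end = le)
    gene <- coding_gene("g", "chr1", gs, ge, gstrand)
    base <- assign_cis_target(lnc, gene)

    shift <- 12345
    lnc_s <- lnc
    lnc_s$start <- lnc$start + shift
    lnc_s$end <- lnc$end + shift
    gene_s <- coding_gene("g", "chr1", gs + shift, ge + shift, gstrand)
    moved <- assign_cis_target(lnc_s, gene_s)
    expect_equal(moved[, -1], base[, -1])

    flip <- function(x) if (x == "+") "-" else "+"
    lnc_f <- lnc
    lnc_f$strand <- flip(lnc$strand)
    gene_f <- coding_gene("g", "chr1", gs, ge, flip(gstrand))
    flipped <- assign_cis_target(lnc_f, gene_f)
    expect_equal(flipped$relative_strand, base$relative_strand)
  }
})

test_that("cis assignment picks the nearest gene, breaks ties lexicographically, respects the window", {
  genes <- genome_annotation(c(
    exon_gr("chr1", 1000, 2000, "+", "far.t1", gene = "far",
            status = "coding"),
    exon_gr("chr1", 30000, 31000, "+", "near.t1", gene = "near",
            status = "coding")))
  lnc <- list(transcript_id = "n", chrom = "chr1", strand = "+",
              start = 25000, end = 26000)
  expect_equal(assign_cis_target(lnc, genes)$target_gene_id, "near")

  tied <- genome_annotation(c(
    exon_gr("chr1", 1000, 2000, "+", "b.t1", gene = "b",
            status = "coding"),
    exon_gr("chr1", 5000, 6000, "+", "a.t1", gene = "a",
            status = "coding")))
  mid <- list(transcript_id = "n", chrom = "chr1", strand = "+",
              start = 3000, end = 4000)
  expect_equal(assign_cis_target(mid, tied)$target_gene_id, "a")

  lonely <- list(transcript_id = "n", chrom = "chr1", strand = "+",
                 start = 5e6, end = 5e6 + 500)
  expect_null(assign_cis_target(lonely, genes))
})

# Exact hypergeometric upper tail by enumeration over binomial
# coefficients.
hyper_oracle <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

test_that("enrichment p-values match combinatorial enumeration", {
  universe <- paste0("g", 1:10)
  term_map <- data.frame(gene_id = paste0("g", 1:5), term_id = "T1")
  res <- enrich(paste0("g", c(1, 2, 3, 4)), term_map, universe)
  expect_equal(res$p, 5 / 210)
  expect_equal(res$hits, 4L)

  # a term covering the whole universe is never enriched
  full <- data.frame(gene_id = universe, term_id = "ALL")
  expect_equal(enrich(paste0("g", 1:3), full, universe)$p, 1)

  expect_error(enrich(c("g1", "zz"), term_map, universe), "zz")

  set.seed(53)
  for (i in 1:40) {
    N <- sample(5:20, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    universe <- paste0("u", seq_len(N))
    term <- paste0("u", sample(N, K))
    query <- paste0("u", sample(N, n))
    k <- length(intersect(term, query))
    res <- enrich(query, data.frame(gene_id = term, term_id = "T"),
                  universe)
    if (k == 0) {
      expect_equal(nrow(res), 0L)
    } else {
      expect_equal(res$p, hyper_oracle(k, K, n, N))
    }
  }
})

test_that("hypergeometric p is monotone non-increasing in the hit count", {
  N <- 40; K <- 12; n <- 10
  universe <- paste0("u", seq_len(N))
  term <- universe[1:K]
  ps <- vapply(1:min(K, n), function(k) {
    query <- c(term[seq_len(k)], universe[(K + 1):(K + n - k)])
    enrich(query, data.frame(gene_id = term, term_id = "T"),
           universe)$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  expect_true(all(ps > 0 & ps <= 1))
})
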
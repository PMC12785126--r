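# O(n*m) brute-force oracles for the interval filters.
oracle_overlap_fail <- function(candidates, known, stranded = FALSE) {
  ce <- as.data.frame(candidates$exons)
  ke <- as.data.frame(known$exons)
  ke <- ke[ke$annotation_status %in% c("coding", "annotated_lncRNA"), ]
  bad <- character()
  for (i in seq_len(nrow(ce))) {
    for (j in seq_len(nrow(ke))) {
      if (ce$seqnames[i] != ke$seqnames[j]) next
      if (stranded && ce$strand[i] != ke$strand[j]) next
      if (ce$start[i] <= ke$end[j] && ke$start[j] <= ce$end[i]) {
        bad <- c(bad, ce$transcript_id[i])
      }
    }
  }
  unique(bad)
}

oracle_distance_fail <- function(candidates, known, max_gap = 2000) {
  ct <- candidates$transcripts
  kt <- known$transcripts
  kt <- kt[kt$n_exons == 1L, , drop = FALSE]
  bad <- character()
  for (i in seq_len(nrow(ct))) {
    for (j in seq_len(nrow(kt))) {
      if (ct$chrom[i] != kt$chrom[j]) next
      gap <- max(0L, max(kt$start[j] - ct$end[i],
                         ct$start[i] - kt$end[j]) - 1L)
      if (gap <= max_gap) bad <- c(bad, ct$transcript_id[i])
    }
  }
  unique(bad)
}

fpkm_of <- function(ids, mat) apply(mat[ids, , drop = FALSE], 1, max)

test_that("FPKM follows its closed form", {
  counts <- matrix(c(50, 0, 999950,
                     10, 20, 30), ncol = 2,
                   dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  lengths <- c(t1 = 2000, t2 = 1000, t3 = 500)
  fpkm <- compute_fpkm(counts, lengths)
  expect_equal(fpkm["t1", "s1"], 25)       # 50/( (2000/1e3)*(1e6/1e6) )
  expect_equal(fpkm["t2", "s1"], 0)
  # hand evaluation of the full formula on the second sample
  tot2 <- sum(counts[, "s2"])
  for (t in rownames(counts)) {
    expect_equal(fpkm[t, "s2"],
                 counts[t, "s2"] * 1e9 / (lengths[[t]] * tot2))
  }
  bad <- counts
  bad[, "s2"] <- 0
  expect_error(compute_fpkm(bad, lengths), "s2")
})

test_that("length and FPKM thresholds are strict, FPKM over any one sample", {
  ann <- genome_annotation(exon_gr(
    "chr1", c(1, 1000, 3000), c(200, 1200, 3200), "+",
    c("len200", "len201", "fpkm_half")))
  # len200 has length 200 exactly; the others 201
  ann2 <- genome_annotation(exon_gr(
    "chr1", c(1, 1000, 3000), c(200, 1200, 3200), "+",
    c("len200", "len201", "fpkm_half")))
  fpkm <- rbind(len200 = c(5, 5), len201 = c(0.4, 0.6),
                fpkm_half = c(0.5, 0.5))
  colnames(fpkm) <- c("s1", "s2")
  # fix lengths: len201/fpkm_half exons are 201 nt wide
  expect_equal(ann$transcripts$length,
               c(200, 201, 201)[order(c(1, 1000, 3000))])
  dec <- filter_length_fpkm(ann2, fpkm)
  d <- stats::setNames(dec$passed, dec$transcript_id)
  expect_false(d[["len200"]])     # length 200 is not > 200
  expect_true(d[["len201"]])      # 0.6 > 0.5 in one sample suffices
  expect_false(d[["fpkm_half"]])  # 0.5 is not > 0.5
  expect_error(filter_length_fpkm(ann, fpkm[1:2, ]), "absent")
})

test_that("known-exon overlap is base-level, strand-blind by default, and exon-only", {
  known <- genome_annotation(exon_gr("chr1", 200, 300, "+", "k1",
                                     status = "coding"))
  one_bp <- genome_annotation(exon_gr("chr1", 100, 200, "-", "c1"))
  expect_false(filter_known_overlap(one_bp, known)$passed)
  adjacent <- genome_annotation(exon_gr("chr1", 100, 199, "+", "c2"))
  expect_true(filter_known_overlap(adjacent, known)$passed)
  # candidate intron spans the known exon entirely: exon-level test only
  intron_span <- genome_annotation(
    exon_gr("chr1", c(1, 500), c(100, 600), "+", c("c3", "c3")))
  expect_true(filter_known_overlap(intron_span, known)$passed)
  # stranded mode ignores the antisense overlap
  thr <- filter_thresholds(stranded_overlap = TRUE)
  expect_true(filter_known_overlap(one_bp, known, thr)$passed)
  same_strand <- genome_annotation(exon_gr("chr1", 100, 200, "+", "c4"))
  expect_false(filter_known_overlap(same_strand, known, thr)$passed)
})

test_that("single-exon distance threshold is strict at 2 kb", {
  cand <- genome_annotation(exon_gr("chr1", 1, 1000, "+", "c1"))
  # single-exon transcript starting at 3001: gap of 2000 -> fail
  known_2000 <- genome_annotation(exon_gr("chr1", 3001, 3500, "+", "k1",
                                          status = "coding"))
  expect_false(filter_single_exon_distance(cand, known_2000)$passed)
  known_2001 <- genome_annotation(exon_gr("chr1", 3002, 3500, "+", "k1",
                                          status = "coding"))
  expect_true(filter_single_exon_distance(cand, known_2001)$passed)
  # multi-exon known transcripts do not trigger the rule
  multi <- genome_annotation(exon_gr("chr1", c(1500, 2500),
                                     c(1600, 2600), "+", c("k2", "k2"),
                                     status = "coding"))
  expect_true(filter_single_exon_distance(cand, multi)$passed)
  # no single-exon transcript on the chromosome: vacuous pass
  other_chrom <- genome_annotation(exon_gr("chr2", 1001, 1500, "+",
                                           "k3", status = "coding"))
  expect_true(filter_single_exon_distance(cand, other_chrom)$passed)
})

test_that("interval filters agree with the brute-force pairwise oracle", {
  for (seed in 1:15) {
    cand <- random_annotation(40, seed = seed,
                              statuses = "unannotated")
    known <- random_annotation(40, seed = seed + 1000,
                               statuses = c("coding",
                                            "annotated_lncRNA"))
    dec_o <- filter_known_overlap(cand, known)
    expect_setequal(dec_o$transcript_id[!dec_o$passed],
                    oracle_overlap_fail(cand, known))
    thr <- filter_thresholds(stranded_overlap = TRUE)
    dec_s <- filter_known_overlap(cand, known, thr)
    expect_setequal(dec_s$transcript_id[!dec_s$passed],
                    oracle_overlap_fail(cand, known, stranded = TRUE))
    dec_d <- filter_single_exon_distance(cand, known)
    expect_setequal(dec_d$transcript_id[!dec_d$passed],
                    oracle_distance_fail(cand, known))
  }
})

test_that("the cascade recovers planted truth with a complete audit trail", {
  cfg <- small_sim_config()
  sim <- simulate_experiment(cfg)
  ref <- sim$reference$transcripts
  model <- train_coding_model(
    extract_transcript_sequence(sim$genome, sim$reference,
      ref$transcript_id[ref$annotation_status == "coding"]),
    extract_transcript_sequence(sim$genome, sim$reference,
      ref$transcript_id[ref$annotation_status == "annotated_lncRNA"]))
  res <- identify_novel_lncrnas(sim$assembled, sim$reference,
                                counts = sim$counts,
                                genome = sim$genome, model = model)
  planted <- sim$truth$transcript_id[sim$truth$class == "true_novel"]
  expect_setequal(res$novel_ids, planted)

  # audit completeness: every unannotated transcript decided exactly once
  unann <- sim$truth$transcript_id[grepl("^MSTRG", sim$truth$transcript_id)]
  expect_setequal(res$decisions$transcript_id, unann)
  expect_equal(anyDuplicated(res$decisions$transcript_id), 0L)
  expect_identical(res$decisions$passed,
                   res$decisions$stage_reached == "passed")
  expect_identical(res$decisions$passed, res$decisions$reasons == "")
  expect_setequal(res$decisions$transcript_id[res$decisions$passed],
                  res$novel_ids)

  # funnel is monotone non-increasing
  expect_true(all(diff(res$funnel) <= 0))

  # each decoy class fails at its designated stage
  cls <- stats::setNames(sim$truth$class, sim$truth$transcript_id)
  stage <- stats::setNames(res$decisions$stage_reached,
                           res$decisions$transcript_id)
  expect_true(all(stage[names(cls)[cls == "decoy:short"]] ==
                    "length_fpkm"))
  expect_true(all(stage[names(cls)[cls == "decoy:low_fpkm"]] ==
                    "length_fpkm"))
  expect_true(all(stage[names(cls)[cls == "decoy:exon_overlap"]] ==
                    "overlap"))
  expect_true(all(stage[names(cls)[cls == "decoy:near_single_exon"]] ==
                    "distance"))
  expect_true(all(stage[names(cls)[cls == "decoy:coding_like"]] ==
                    "coding"))

  # tightening a threshold can only shrink the novel set
  strict <- identify_novel_lncrnas(
    sim$assembled, sim$reference, counts = sim$counts,
    genome = sim$genome, model = model,
    thr = filter_thresholds(min_length = 500))
  expect_true(all(strict$novel_ids %in% res$novel_ids))
})

test_that("an empty unannotated set yields an empty result", {
  ann <- genome_annotation(exon_gr("chr1", 1, 500, "+", "t1",
                                   status = "coding"))
  res <- identify_novel_lncrnas(ann, ann, fpkm = matrix(
    1, 1, 1, dimnames = list("t1", "s1")))
  expect_length(res$novel_ids, 0)
  expect_equal(nrow(res$decisions), 0L)
  expect_equal(unname(res$funnel["unannotated"]), 0L)
})
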
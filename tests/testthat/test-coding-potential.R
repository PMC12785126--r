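# Brute-force ORF oracle: enumerate every ATG and the first in-frame
# stop after it, over all three forward frames.
orf_oracle <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- 0L
  for (i in seq_len(max(0L, n - 2L))) {
    if (substring(seq, i, i + 2L) != "ATG") next
    j <- i + 3L
    while (j + 2L <= n) {
      cod <- substring(seq, j, j + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, j + 2L - i + 1L)
        break
      }
      j <- j + 3L
    }
  }
  best
}

test_that("longest-ORF detection matches hand-derived cases", {
  expect_equal(find_longest_orf("ATGAAATAG")$orf_length, 9L)
  expect_equal(find_longest_orf("ATGAAATAG")$orf_coverage, 1.0)
  expect_equal(find_longest_orf("CCCCCC")$orf_length, 0L)
  orf <- find_longest_orf("AAATGAAATAGAA")
  expect_equal(orf$orf_length, 9L)
  expect_equal(orf$orf_coverage, 9 / 13)
  expect_equal(orf$orf_start, 3L)
  # ORFs require a stop codon
  expect_equal(find_longest_orf("ATGAAAAAA")$orf_length, 0L)
})

test_that("longest-ORF detection agrees with the brute-force oracle", {
  set.seed(31)
  for (i in 1:150) {
    n <- sample(10:300, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    expect_equal(find_longest_orf(s)$orf_length, orf_oracle(s),
                 info = s)
  }
})

# Independent evaluation of the TESTCODE definition using the exported
# lookup constants.
fickett_oracle <- function(seq) {
  tb <- fickett_tables()
  bases <- strsplit(toupper(seq), "")[[1]]
  phase <- rep_len(1:3, length(bases))
  total <- sum(bases %in% c("A", "C", "G", "T"))
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- sapply(1:3, function(p) sum(bases == b & phase == p))
    ppar <- max(cnt) / (min(cnt) + 1)
    cpar <- sum(cnt) / total
    pi <- which(ppar >= tb$position_para)[1]
    ci <- which(cpar >= tb$content_para)[1]
    score <- score + tb$position_prob[[b]][pi] * tb$position_weight[[b]] +
      tb$content_prob[[b]][ci] * tb$content_weight[[b]]
  }
  score
}

test_that("Fickett score is deterministic and matches its definition", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 240, replace = TRUE),
             collapse = "")
  expect_identical(fickett_score(s), fickett_score(s))
  for (i in 1:20) {
    n <- sample(30:400, 1)
    x <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    expect_equal(fickett_score(x), fickett_oracle(x))
  }
})

test_that("Fickett position parameters are equal for positionally balanced sequences", {
  # 120 nt with every base appearing 10 times at every codon position:
  # each position parameter is 10/(10+1)
  p1 <- rep(c("A", "C", "G", "T"), 10)
  p2 <- rep(c("C", "G", "T", "A"), 10)
  p3 <- rep(c("G", "T", "A", "C"), 10)
  block <- paste(as.vector(rbind(p1, p2, p3)), collapse = "")
  stopifnot(nchar(block) == 120)
  det <- fickett_score(block, detail = TRUE)
  expect_true(all(abs(det$position - det$position[1]) < 1e-12))
  expect_equal(unname(det$position["A"]), 10 / 11)
})

test_that("Fickett score depends only on positional counts and content", {
  set.seed(77)
  n <- 120
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  # shuffle whole codons: per-codon-position base counts are unchanged
  codons <- matrix(s, nrow = 3)
  shuffled <- c(codons[, sample(ncol(codons))])
  expect_equal(fickett_score(paste(s, collapse = "")),
               fickett_score(paste(shuffled, collapse = "")))
})

test_that("hexamer table obeys symmetry, sign, scale and antisymmetry", {
  set.seed(19)
  seqs <- vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  }, character(1))
  same <- train_hexamer_table(seqs, seqs)
  expect_true(all(same == 0))

  a <- strrep("AAAAAA", 20)
  c6 <- strrep("CCCCCC", 20)
  tab <- train_hexamer_table(rep(a, 3), rep(c6, 3))
  expect_gt(tab[["AAAAAA"]], 0)
  expect_lt(tab[["CCCCCC"]], 0)

  one <- train_hexamer_table(seqs[1:2], seqs[3:5])
  doubled <- train_hexamer_table(rep(seqs[1:2], 2), rep(seqs[3:5], 2))
  expect_equal(unclass(one), unclass(doubled))

  swapped <- train_hexamer_table(seqs[3:5], seqs[1:2])
  expect_equal(unclass(swapped), -unclass(one))

  expect_error(train_hexamer_table(character(), seqs), "non-empty")
})

test_that("hexamer feature averages in-frame ORF hexamers and defaults to 0", {
  tab <- train_hexamer_table(strrep("ATGGCA", 30), strrep("TTTTTT", 30))
  expect_equal(hexamer_feature("CCCCCCCC", tab), 0)
  # a minimal ORF holds exactly one hexamer
  expect_equal(hexamer_feature("ATGTAA", tab), unname(tab[["ATGTAA"]]))
  seq <- "ATGGCAATGGCATAA"  # ORF covers the whole sequence
  pos <- c(1, 4, 7, 10)
  expected <- mean(tab[substring(seq, pos, pos + 5)])
  expect_equal(hexamer_feature(seq, tab), expected)
})

test_that("logistic combiner recovers signal, nulls, and is deterministic", {
  set.seed(23)
  # single feature perfectly correlated with the label: separation
  # triggers the ridge fallback with a positive coefficient
  x <- data.frame(f = c(rnorm(50, -2), rnorm(50, 2)))
  y <- rep(c(0, 1), each = 50)
  co <- train_classifier(x, y)
  expect_equal(attr(co, "method"), "ridge")
  expect_gt(co[["f"]], 0)

  # feature independent of a balanced label: coefficient near zero
  set.seed(24)
  x2 <- data.frame(sig = c(rnorm(1000, -1), rnorm(1000, 1)),
                   noise = rnorm(2000))
  y2 <- rep(c(0, 1), each = 1000)
  co2 <- train_classifier(x2, y2)
  expect_lt(abs(co2[["noise"]]), 0.1)

  co2b <- train_classifier(x2, y2)
  expect_identical(co2, co2b)

  expect_error(train_classifier(x2, rep(1, 2000)), "both labels")
})

test_that("the noncoding verdict is exactly score < 0, with 0 not noncoding", {
  tab <- train_hexamer_table("ATGGCAGCATAA", "TTTTAAAATTTT")
  zero_model <- structure(list(
    hexamer_table = tab,
    coefficients = stats::setNames(
      rep(0, 5), c("(Intercept)", "orf_log_length", "orf_coverage",
                   "fickett", "hexamer")),
    feature_names = c("orf_log_length", "orf_coverage", "fickett",
                      "hexamer")),
    class = "coding_potential_model")
  res <- score_transcripts(c(a = "ATGAAATAGCCC"), zero_model)
  expect_equal(res$score, 0)
  expect_false(res$is_noncoding)

  set.seed(41)
  seqs <- stats::setNames(vapply(1:40, function(i) {
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  }, character(1)), paste0("s", 1:40))
  cod <- vapply(1:40, function(i)
    adipolnc:::make_coding_sequence(300), character(1))
  model <- train_coding_model(cod, seqs)
  sc <- score_transcripts(seqs, model)
  expect_identical(sc$is_noncoding, sc$score < 0)
})

test_that("a trained scorer separates held-out coding from noncoding sequences", {
  set.seed(55)
  make_set <- function(n, coding) {
    vapply(seq_len(n), function(i) {
      len <- sample(400:1500, 1)
      if (coding) adipolnc:::make_coding_sequence(len)
      else paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    }, character(1))
  }
  train_cod <- make_set(150, TRUE)
  train_non <- make_set(150, FALSE)
  test_cod <- make_set(100, TRUE)
  test_non <- make_set(100, FALSE)
  model <- train_coding_model(train_cod, train_non)
  sc <- score_transcripts(c(test_cod, test_non), model)
  truth_noncoding <- rep(c(FALSE, TRUE), c(100, 100))
  acc <- mean(sc$is_noncoding == truth_noncoding)
  expect_gte(acc, 0.9)
  expect_identical(sc$is_noncoding, sc$score < 0)
})

test_that("monotonicity: a positive coefficient on orf_coverage raises the score", {
  tab <- train_hexamer_table("ATGGCAGCATAA", "TTTTAAAATTTT")
  model <- structure(list(
    hexamer_table = tab,
    coefficients = stats::setNames(
      c(0, 0, 2, 0, 0), c("(Intercept)", "orf_log_length",
                          "orf_coverage", "fickett", "hexamer")),
    feature_names = c("orf_log_length", "orf_coverage", "fickett",
                      "hexamer")),
    class = "coding_potential_model")
  # same ORF, longer tail lowers coverage, hence the score
  hi <- score_transcripts(c(x = "ATGAAATAG"), model)$score
  lo <- score_transcripts(c(x = paste0("ATGAAATAG", strrep("C", 30))),
                          model)$score
  expect_gt(hi, lo)
})

test_that("model JSON serialization round-trips scores exactly", {
  set.seed(61)
  cod <- vapply(1:20, function(i)
    adipolnc:::make_coding_sequence(400), character(1))
  non <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""),
    character(1))
  model <- train_coding_model(cod, non)
  path <- withr::local_tempfile(fileext = ".json")
  write_coding_model(model, path)
  back <- read_coding_model(path)
  probe <- c(p1 = non[1], p2 = cod[1])
  expect_equal(score_transcripts(probe, back),
               score_transcripts(probe, model))
})
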
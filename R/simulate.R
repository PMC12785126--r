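`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Simulation configuration
#'
#' Defines the synthetic study: a toy two-chromosome genome carrying
#' multi-exon coding genes with codon-biased ORFs, single-exon coding
#' loci, annotated lncRNAs, planted true-novel lncRNAs that satisfy every
#' novelty criterion by construction, and five decoy classes each
#' violating exactly one criterion; plus an expression layer of six
#' samples (white, brown, beige adipocytes, two replicates each) with
#' negative-binomial counts, planted size factors and planted fold
#' changes. The seed fixes every output byte-for-byte.
#'
#' @param seed Integer RNG seed.
#' @param n_coding_genes,n_single_exon_known,n_annotated_lncrnas,n_true_novel
#'   Feature counts per class.
#' @param decoys_per_class Decoys per violation class (short, low_fpkm,
#'   exon_overlap, near_single_exon, coding_like).
#' @param chrom_sizes Named vector of chromosome lengths in bp.
#' @param alpha NB dispersion of the count layer (0 = Poisson).
#' @param de_fraction Fraction of expressed coding/lncRNA/novel features
#'   given a planted group effect.
#' @param de_lfc Magnitude (log2) of planted effects.
#' @param de_graded_fraction Fraction of the planted DE features given a
#'   graded three-level pattern (low/mid/high across the three types,
#'   steps of `de_lfc`), so they are differential in every pairwise
#'   contrast and the cross-contrast intersection has a common core, as
#'   in the real design. The remainder get a single-group effect.
#' @param n_beige_novel Number of true-novel lncRNAs forced to be
#'   beige-upregulated (the browning-candidate signal).
#' @param size_factor_sdlog Log-normal sd of the planted size factors.
#' @param orf_cap Maximum longest-ORF length (nt) tolerated in sequences
#'   that must score noncoding; such sequences are resampled until they
#'   comply.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_coding_genes = 200,
                              n_single_exon_known = 30,
                              n_annotated_lncrnas = 100,
                              n_true_novel = 50,
                              decoys_per_class = 10,
                              chrom_sizes = c(chr1 = 1.6e6, chr2 = 1.6e6),
                              alpha = 0.1,
                              de_fraction = 0.15,
                              de_lfc = 3,
                              de_graded_fraction = 0.25,
                              n_beige_novel = 10,
                              size_factor_sdlog = 0.15,
                              orf_cap = 240) {
  stopifnot(n_coding_genes >= 0, n_single_exon_known >= 0,
            n_annotated_lncrnas >= 0, n_true_novel >= 0,
            decoys_per_class >= 0, alpha >= 0,
            n_beige_novel <= n_true_novel)
  structure(list(
    seed = seed,
    n_coding_genes = n_coding_genes,
    n_single_exon_known = n_single_exon_known,
    n_annotated_lncrnas = n_annotated_lncrnas,
    n_true_novel = n_true_novel,
    decoys_per_class = decoys_per_class,
    chrom_sizes = chrom_sizes,
    coding_length = list(meanlog = log(1800), sdlog = 0.3,
                         min = 900, max = 4000),
    lnc_length = list(meanlog = log(700), sdlog = 0.45,
                      min = 300, max = 2500),
    single_exon_length = c(500, 1200),
    coding_exons = c(4, 8),
    lnc_exons = c(2, 4),
    coding_intron = c(200, 800),
    lnc_intron = c(200, 600),
    locus_gap = c(3200, 5000),
    near_gap = c(500, 1500),
    short_length = c(120, 200),
    overlap_decoy_length = c(250, 500),
    overlap_bases = 50,
    orf_cap = orf_cap,
    alpha = alpha,
    baseline = list(coding = list(meanlog = log(150), sdlog = 1, min = 5),
                    lnc = list(meanlog = log(30), sdlog = 0.8, min = 5),
                    novel = list(meanlog = log(80), sdlog = 0.6,
                                 min = 30),
                    decoy = list(meanlog = log(40), sdlog = 0.5,
                                 min = 20)),
    de_fraction = de_fraction,
    de_lfc = de_lfc,
    de_graded_fraction = de_graded_fraction,
    n_beige_novel = n_beige_novel,
    size_factor_sdlog = size_factor_sdlog,
    conservation = list(coding_exon = c(8, 2), lnc_exon = c(3, 7),
                        intron = c(2, 8)),
    samples = c("White-1", "White-2", "Brown-1", "Brown-2",
                "Beige-1", "Beige-2"),
    groups = c("White", "White", "Brown", "Brown", "Beige", "Beige")
  ), class = "simulation_config")
}

# Position-specific codon composition used for planted coding ORFs:
# codon positions have distinct base preferences, which yields both the
# positional asymmetry the Fickett statistic reads and a hexamer usage
# bias the log-odds table can learn.
.codon_pos_probs <- list(
  p1 = c(A = 0.32, C = 0.16, G = 0.38, T = 0.14),
  p2 = c(A = 0.40, C = 0.28, G = 0.12, T = 0.20),
  p3 = c(A = 0.08, C = 0.38, G = 0.34, T = 0.20)
)

sample_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

sample_biased_codons <- function(n_codons) {
  pp <- .codon_pos_probs
  b1 <- sample(names(pp$p1), n_codons, TRUE, pp$p1)
  b2 <- sample(names(pp$p2), n_codons, TRUE, pp$p2)
  b3 <- sample(names(pp$p3), n_codons, TRUE, pp$p3)
  cod <- paste0(b1, b2, b3)
  bad <- cod %in% .stop_codons
  while (any(bad)) {
    k <- sum(bad)
    cod[bad] <- paste0(sample(names(pp$p1), k, TRUE, pp$p1),
                       sample(names(pp$p2), k, TRUE, pp$p2),
                       sample(names(pp$p3), k, TRUE, pp$p3))
    bad <- cod %in% .stop_codons
  }
  cod
}

# A coding-like transcript sequence: UTRs around one long biased ORF
# covering roughly 3/4 of the transcript.
make_coding_sequence <- function(len) {
  orf_len <- max(102L, (floor(0.75 * len) %/% 3L) * 3L)
  if (orf_len > len - 6L) orf_len <- ((len - 6L) %/% 3L) * 3L
  n_codons <- orf_len %/% 3L - 2L
  rest <- len - orf_len
  utr5 <- rest %/% 2L
  utr3 <- rest - utr5
  paste0(if (utr5 > 0) sample_bases(utr5) else "",
         "ATG", paste(sample_biased_codons(n_codons), collapse = ""),
         sample(.stop_codons, 1),
         if (utr3 > 0) sample_bases(utr3) else "")
}

# A noncoding sequence whose longest ORF is capped, so a trained scorer
# reliably gives it a negative score.
make_noncoding_sequence <- function(len, orf_cap, max_tries = 100) {
  for (i in seq_len(max_tries)) {
    s <- sample_bases(len)
    if (find_longest_orf(s)$orf_length <= orf_cap) return(s)
  }
  stop("could not generate an ORF-capped noncoding sequence of length ",
       len)
}

rlnorm_clamped <- function(n, spec) {
  x <- stats::rlnorm(n, spec$meanlog, spec$sdlog)
  round(pmin(pmax(x, spec$min), spec$max))
}

# Split a spliced length into exon widths (min 100 bp each).
split_exons <- function(len, n_exons, min_exon = 100L) {
  n_exons <- max(1L, min(n_exons, len %/% min_exon))
  if (n_exons == 1L) return(len)
  extra <- stats::rmultinom(1, len - n_exons * min_exon,
                            rep(1, n_exons))[, 1]
  as.integer(min_exon + extra)
}

#' Simulate the annotation layer
#'
#' Lays out all loci along the toy genome with inter-locus gaps larger
#' than the single-exon distance threshold, writes class-appropriate
#' sequences into the genome (codon-biased ORFs for coding loci, random
#' ORF-capped sequence for lncRNA-like loci), then attaches the
#' exon-overlap decoys (sharing `overlap_bases` with a host coding exon)
#' and the near-single-exon decoys (placed 500-1500 bp from a single-exon
#' locus). True-novel transcripts satisfy all four novelty criteria by
#' construction; each decoy violates exactly its designated criterion.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `reference` and `assembled`
#'   ([genome_annotation()]), `genome` (`DNAStringSet`), `truth`
#'   (data.frame: `transcript_id`, `gene_id`, `class`, `single_exon`) and
#'   `cis_truth` (data.frame of each true novel's nearest coding gene and
#'   relative geometry, computed from the layout).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, simulate_annotation_impl(cfg))
}

simulate_annotation_impl <- function(cfg) {
  loci <- list()
  add_locus <- function(id, gene, class, status, strand, len, n_exons,
                        intron_range, seqtype) {
    widths <- split_exons(len, n_exons)
    k <- length(widths)
    introns <- if (k > 1) sample(intron_range[1]:intron_range[2],
                                 k - 1, replace = TRUE) else integer(0)
    loci[[length(loci) + 1L]] <<- list(
      id = id, gene = gene, class = class, status = status,
      strand = strand, widths = widths, introns = introns,
      span = sum(widths) + sum(introns), seqtype = seqtype)
  }
  rand_strand <- function(n) sample(c("+", "-"), n, replace = TRUE)

  n_cod <- cfg$n_coding_genes
  cod_len <- rlnorm_clamped(n_cod, cfg$coding_length)
  cod_strand <- rand_strand(n_cod)
  for (i in seq_len(n_cod)) {
    add_locus(sprintf("tx_coding_%03d", i), sprintf("g_coding_%03d", i),
              "coding", "coding", cod_strand[i], cod_len[i],
              sample(cfg$coding_exons[1]:cfg$coding_exons[2], 1),
              cfg$coding_intron, "coding")
  }
  n_se <- cfg$n_single_exon_known
  se_len <- sample(cfg$single_exon_length[1]:cfg$single_exon_length[2],
                   n_se, replace = TRUE)
  se_strand <- rand_strand(n_se)
  for (i in seq_len(n_se)) {
    add_locus(sprintf("tx_se_%03d", i), sprintf("g_se_%03d", i),
              "coding", "coding", se_strand[i], se_len[i], 1L,
              cfg$coding_intron, "coding")
  }
  n_lnc <- cfg$n_annotated_lncrnas
  lnc_len <- rlnorm_clamped(n_lnc, cfg$lnc_length)
  lnc_strand <- rand_strand(n_lnc)
  for (i in seq_len(n_lnc)) {
    add_locus(sprintf("tx_lnc_%03d", i), sprintf("g_lnc_%03d", i),
              "annotated_lncRNA", "annotated_lncRNA", lnc_strand[i],
              lnc_len[i], sample(cfg$lnc_exons[1]:cfg$lnc_exons[2], 1),
              cfg$lnc_intron, "noncoding")
  }

  # MSTRG-style ids for everything unannotated, in one shuffled series
  n_dec <- cfg$decoys_per_class
  n_unann <- cfg$n_true_novel + 3L * n_dec  # standalone unannotated loci
  mstrg_ids <- sample(seq(10000, 10000 + cfg$n_true_novel + 5L * n_dec - 1L))
  next_mstrg <- local({
    k <- 0L
    function() {
      k <<- k + 1L
      sprintf("MSTRG.%d", mstrg_ids[k])
    }
  })
  novel_ids <- character(cfg$n_true_novel)
  for (i in seq_len(cfg$n_true_novel)) {
    g <- next_mstrg()
    novel_ids[i] <- paste0(g, ".1")
    add_locus(novel_ids[i], g, "true_novel", "unannotated",
              rand_strand(1), rlnorm_clamped(1, cfg$lnc_length),
              sample(cfg$lnc_exons[1]:cfg$lnc_exons[2], 1),
              cfg$lnc_intron, "noncoding_capped")
  }
  for (i in seq_len(n_dec)) {
    g <- next_mstrg()
    add_locus(paste0(g, ".1"), g, "decoy:short", "unannotated",
              rand_strand(1),
              sample(cfg$short_length[1]:cfg$short_length[2], 1), 1L,
              cfg$lnc_intron, "noncoding_capped")
  }
  for (i in seq_len(n_dec)) {
    g <- next_mstrg()
    add_locus(paste0(g, ".1"), g, "decoy:low_fpkm", "unannotated",
              rand_strand(1), rlnorm_clamped(1, cfg$lnc_length),
              sample(cfg$lnc_exons[1]:cfg$lnc_exons[2], 1),
              cfg$lnc_intron, "noncoding_capped")
  }
  for (i in seq_len(n_dec)) {
    g <- next_mstrg()
    add_locus(paste0(g, ".1"), g, "decoy:coding_like", "unannotated",
              rand_strand(1),
              round(stats::runif(1, 600, 1500)), 2L,
              cfg$lnc_intron, "coding")
  }

  # place standalone loci
  ord <- sample(seq_along(loci))
  chroms <- names(cfg$chrom_sizes)
  placement <- vector("list", length(loci))
  ci <- 1L
  cursor <- 0L
  for (j in ord) {
    lc <- loci[[j]]
    gap <- sample(cfg$locus_gap[1]:cfg$locus_gap[2], 1)
    start <- cursor + gap
    while (start + lc$span - 1L > cfg$chrom_sizes[ci] - 3000L) {
      ci <- ci + 1L
      if (ci > length(chroms)) {
        stop("genome too small for the configured loci; ",
             "increase chrom_sizes")
      }
      cursor <- 0L
      gap <- sample(cfg$locus_gap[1]:cfg$locus_gap[2], 1)
      start <- cursor + gap
    }
    ex_start <- integer(length(lc$widths))
    pos <- start
    for (k in seq_along(lc$widths)) {
      ex_start[k] <- pos
      pos <- pos + lc$widths[k] +
        (if (k < length(lc$widths)) lc$introns[k] else 0L)
    }
    placement[[j]] <- list(chrom = chroms[ci], ex_start = ex_start,
                           ex_end = ex_start + lc$widths - 1L)
    cursor <- max(placement[[j]]$ex_end)
  }

  # genome background
  genome_chars <- lapply(cfg$chrom_sizes, function(n) {
    sample(c("A", "C", "G", "T"), n, replace = TRUE)
  })

  write_transcript_seq <- function(plc, strand, spliced) {
    genomic <- if (strand == "-") {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(spliced)))
    } else spliced
    offset <- 0L
    for (k in seq_along(plc$ex_start)) {
      w <- plc$ex_end[k] - plc$ex_start[k] + 1L
      piece <- substring(genomic, offset + 1L, offset + w)
      genome_chars[[plc$chrom]][plc$ex_start[k]:plc$ex_end[k]] <<-
        strsplit(piece, "", fixed = TRUE)[[1]]
      offset <- offset + w
    }
  }

  for (j in seq_along(loci)) {
    lc <- loci[[j]]
    len <- sum(lc$widths)
    spliced <- switch(lc$seqtype,
      coding = make_coding_sequence(len),
      noncoding = sample_bases(len),
      noncoding_capped = make_noncoding_sequence(len, cfg$orf_cap))
    write_transcript_seq(placement[[j]], lc$strand, spliced)
  }

  # attached decoys: exon-overlap (host = multi-exon coding genes) and
  # near-single-exon (host = single-exon loci)
  is_class <- function(cl) which(vapply(loci, function(l)
    l$class == cl, logical(1)))
  coding_idx <- is_class("coding")
  multi_cod <- coding_idx[vapply(loci[coding_idx], function(l)
    length(l$widths) > 1L, logical(1))]
  se_idx <- coding_idx[vapply(loci[coding_idx], function(l)
    length(l$widths) == 1L, logical(1))]
  if (n_dec > 0 && (length(multi_cod) < n_dec || length(se_idx) < n_dec)) {
    stop("not enough host loci for attached decoys")
  }
  ov_hosts <- sample(multi_cod, n_dec)
  near_hosts <- sample(se_idx, n_dec)

  chrom_string <- lapply(genome_chars, paste, collapse = "")

  for (i in seq_len(n_dec)) {
    host <- placement[[ov_hosts[i]]]
    L <- sample(cfg$overlap_decoy_length[1]:cfg$overlap_decoy_length[2],
                1)
    ovl <- cfg$overlap_bases
    hs <- host$ex_start[1]
    dstart <- hs - (L - ovl)
    dend <- hs + ovl - 1L
    host_piece <- substring(chrom_string[[host$chrom]], hs, dend)
    prefix <- NULL
    for (tries in seq_len(100)) {
      cand_prefix <- sample_bases(L - ovl)
      if (find_longest_orf(paste0(cand_prefix, host_piece))$orf_length <=
            cfg$orf_cap) {
        prefix <- cand_prefix
        break
      }
    }
    if (is.null(prefix)) stop("could not ORF-cap an overlap decoy")
    genome_chars[[host$chrom]][dstart:(hs - 1L)] <-
      strsplit(prefix, "", fixed = TRUE)[[1]]
    g <- next_mstrg()
    loci[[length(loci) + 1L]] <- list(
      id = paste0(g, ".1"), gene = g, class = "decoy:exon_overlap",
      status = "unannotated", strand = "+", widths = L,
      introns = integer(0), span = L, seqtype = "attached")
    placement[[length(loci)]] <- list(chrom = host$chrom,
                                      ex_start = dstart, ex_end = dend)
  }
  for (i in seq_len(n_dec)) {
    host <- placement[[near_hosts[i]]]
    d <- sample(cfg$near_gap[1]:cfg$near_gap[2], 1)
    L <- sample(400:1000, 1)
    dstart <- max(host$ex_end) + d + 1L
    dend <- dstart + L - 1L
    seq <- make_noncoding_sequence(L, cfg$orf_cap)
    genome_chars[[host$chrom]][dstart:dend] <-
      strsplit(seq, "", fixed = TRUE)[[1]]
    g <- next_mstrg()
    loci[[length(loci) + 1L]] <- list(
      id = paste0(g, ".1"), gene = g, class = "decoy:near_single_exon",
      status = "unannotated", strand = "+", widths = L,
      introns = integer(0), span = L, seqtype = "attached")
    placement[[length(loci)]] <- list(chrom = host$chrom,
                                      ex_start = dstart, ex_end = dend)
  }

  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste,
                                            character(1), collapse = ""))
  names(genome) <- names(cfg$chrom_sizes)

  # assemble GRanges of exons
  rows <- list()
  for (j in seq_along(loci)) {
    lc <- loci[[j]]
    plc <- placement[[j]]
    rows[[j]] <- data.frame(
      chrom = plc$chrom, start = plc$ex_start, end = plc$ex_end,
      strand = lc$strand, transcript_id = lc$id, gene_id = lc$gene,
      annotation_status = lc$status, class = lc$class,
      stringsAsFactors = FALSE)
  }
  exdf <- do.call(rbind, rows)
  make_ann <- function(df) {
    genome_annotation(GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand,
      transcript_id = df$transcript_id, gene_id = df$gene_id,
      annotation_status = df$annotation_status))
  }
  assembled <- make_ann(exdf)
  reference <- make_ann(exdf[exdf$annotation_status != "unannotated", ,
                             drop = FALSE])

  truth <- do.call(rbind, lapply(loci, function(lc) data.frame(
    transcript_id = lc$id, gene_id = lc$gene, class = lc$class,
    single_exon = length(lc$widths) == 1L, stringsAsFactors = FALSE)))

  # cis truth for true novels: nearest coding gene by span gap, from the
  # layout itself (independent of the package's assignment routine)
  cod_span <- do.call(rbind, lapply(which(
    vapply(loci, function(l) l$class == "coding", logical(1))),
    function(j) data.frame(
      gene_id = loci[[j]]$gene, chrom = placement[[j]]$chrom,
      strand = loci[[j]]$strand,
      start = min(placement[[j]]$ex_start),
      end = max(placement[[j]]$ex_end), stringsAsFactors = FALSE)))
  cis_rows <- lapply(which(vapply(loci, function(l)
    l$class == "true_novel", logical(1))), function(j) {
    lc <- loci[[j]]
    plc <- placement[[j]]
    ls <- min(plc$ex_start); le <- max(plc$ex_end)
    cand <- cod_span[cod_span$chrom == plc$chrom, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    gap <- pmax(0L, pmax(cand$start - le, ls - cand$end))
    o <- order(gap, cand$gene_id)
    g <- cand[o[1], ]; d <- gap[o[1]]
    pos <- if (ls <= g$end && g$start <= le) "overlapping"
      else if (ls > g$end) {
        if (g$strand == "+") "downstream" else "upstream"
      } else {
        if (g$strand == "+") "upstream" else "downstream"
      }
    data.frame(lncrna_id = lc$id, target_gene_id = g$gene_id,
               relative_position = pos,
               relative_strand = if (lc$strand == g$strand) "sense"
                                 else "antisense",
               distance = d, stringsAsFactors = FALSE)
  })
  cis_truth <- do.call(rbind, cis_rows)

  list(reference = reference, assembled = assembled, genome = genome,
       truth = truth, cis_truth = cis_truth)
}

#' Default contrasts of the three-adipocyte design
#'
#' White-vs-brown, white-vs-beige and beige-vs-brown, oriented so fold
#' changes read "up in the first-named group".
#'
#' @param cfg A [simulation_config()] (supplies sample and group names).
#' @return A list of [de_contrast()] objects.
#' @export
default_contrasts <- function(cfg = simulation_config()) {
  samp <- split(cfg$samples, cfg$groups)
  list(de_contrast("White_vs_Brown", samp$White, samp$Brown),
       de_contrast("White_vs_Beige", samp$White, samp$Beige),
       de_contrast("Beige_vs_Brown", samp$Beige, samp$Brown))
}

#' Simulate the count layer
#'
#' Draws per-feature baselines by class (novel lncRNAs higher than
#' annotated ones, coding genes highest), plants group effects of
#' magnitude `de_lfc` in a `de_fraction` of expressed features (with
#' `n_beige_novel` true-novel lncRNAs forced beige-up), applies planted
#' size factors, and draws `NB(mu = s_j * q_i * mult_i(group_j),
#' dispersion = alpha)` counts (Poisson when `alpha = 0`). Low-FPKM
#' decoys get zero baseline, hence zero counts.
#'
#' @param sim Output of [simulate_annotation()].
#' @param cfg The same [simulation_config()].
#' @return A list with `counts` (integer matrix features x samples),
#'   `size_factors` (planted, named), `truth_de` (data.frame with the
#'   group multipliers and, per contrast, the true log2 fold change and
#'   DE status).
#' @export
simulate_counts <- function(sim, cfg) {
  with_seed(cfg$seed + 1L, simulate_counts_impl(sim, cfg))
}

simulate_counts_impl <- function(sim, cfg) {
  truth <- sim$truth
  n <- nrow(truth)
  base_spec <- function(class) {
    switch(class,
           coding = cfg$baseline$coding,
           annotated_lncRNA = cfg$baseline$lnc,
           true_novel = cfg$baseline$novel,
           cfg$baseline$decoy)
  }
  q <- numeric(n)
  for (i in seq_len(n)) {
    if (truth$class[i] == "decoy:low_fpkm") {
      q[i] <- 0
    } else {
      sp <- base_spec(truth$class[i])
      q[i] <- max(sp$min, stats::rlnorm(1, sp$meanlog, sp$sdlog))
    }
  }

  groups <- c("White", "Brown", "Beige")
  mult <- matrix(1, n, 3, dimnames = list(truth$transcript_id, groups))
  eligible <- which(truth$class %in%
                      c("coding", "annotated_lncRNA", "true_novel"))
  n_de <- round(cfg$de_fraction * length(eligible))
  de_idx <- sample(eligible, n_de)
  novel_idx <- which(truth$class == "true_novel")
  beige_idx <- sample(novel_idx, cfg$n_beige_novel)
  de_idx <- union(de_idx, beige_idx)
  graded <- cfg$de_graded_fraction %||% 0
  for (i in de_idx) {
    if (i %in% beige_idx) {
      mult[i, "Beige"] <- 2^cfg$de_lfc
    } else if (stats::runif(1) < graded) {
      # low/mid/high gradient: differential in every pairwise contrast
      levels <- sample(c(-1, 0, 1))
      mult[i, ] <- 2^(levels * cfg$de_lfc)
    } else {
      g <- sample(groups, 1)
      sgn <- sample(c(-1, 1), 1)
      mult[i, g] <- 2^(sgn * cfg$de_lfc)
    }
  }

  s <- stats::rlnorm(length(cfg$samples), 0, cfg$size_factor_sdlog)
  names(s) <- cfg$samples
  counts <- matrix(0L, n, length(cfg$samples),
                   dimnames = list(truth$transcript_id, cfg$samples))
  for (j in seq_along(cfg$samples)) {
    mu <- s[j] * q * mult[, cfg$groups[j]]
    counts[, j] <- if (cfg$alpha > 0) {
      stats::rnbinom(n, mu = mu, size = 1 / cfg$alpha)
    } else {
      stats::rpois(n, mu)
    }
  }

  truth_de <- data.frame(transcript_id = truth$transcript_id,
                         class = truth$class, baseline = q,
                         mult_White = mult[, "White"],
                         mult_Brown = mult[, "Brown"],
                         mult_Beige = mult[, "Beige"],
                         stringsAsFactors = FALSE)
  for (ct in default_contrasts(cfg)) {
    ga <- cfg$groups[match(ct$group_a[1], cfg$samples)]
    gb <- cfg$groups[match(ct$group_b[1], cfg$samples)]
    lfc <- log2(mult[, ga] / mult[, gb])
    truth_de[[paste0("lfc_", ct$name)]] <- lfc
    truth_de[[paste0("de_", ct$name)]] <- lfc != 0 & q > 0
  }
  list(counts = counts, size_factors = s, truth_de = truth_de)
}

#' Simulate a conservation track
#'
#' Per-exon scores drawn from class-specific beta distributions (coding
#' exons high, lncRNA-like exons low) and per-intron scores from a low
#' beta, over the coding, annotated-lncRNA and true-novel loci. Scores
#' are bounded in \[0, 1\].
#'
#' @param sim Output of [simulate_annotation()].
#' @param cfg The same [simulation_config()].
#' @return A `GRanges` track with a `score` column, usable directly or
#'   via [write_conservation_track()].
#' @export
simulate_conservation <- function(sim, cfg) {
  with_seed(cfg$seed + 2L, {
    ann <- sim$assembled
    truth <- sim$truth
    keep <- truth$transcript_id[truth$class %in%
                                  c("coding", "annotated_lncRNA",
                                    "true_novel")]
    cls <- stats::setNames(truth$class, truth$transcript_id)
    pieces <- list()
    ex <- ann$exons
    for (id in keep) {
      e <- ex[ex$transcript_id == id]
      shp <- if (cls[id] == "coding") cfg$conservation$coding_exon
             else cfg$conservation$lnc_exon
      sc <- stats::rbeta(length(e), shp[1], shp[2])
      pieces[[length(pieces) + 1L]] <- GenomicRanges::GRanges(
        GenomeInfoDb::seqnames(e), IRanges::ranges(e), score = sc)
      if (length(e) > 1L) {
        introns <- intron_ranges(e)
        shp_i <- cfg$conservation$intron
        pieces[[length(pieces) + 1L]] <- GenomicRanges::GRanges(
          GenomeInfoDb::seqnames(introns), IRanges::ranges(introns),
          score = stats::rbeta(length(introns), shp_i[1], shp_i[2]))
      }
    }
    track <- suppressWarnings(do.call(c, unname(pieces)))
    track[order(as.character(GenomeInfoDb::seqnames(track)),
                BiocGenerics::start(track))]
  })
}

#' Simulate a gene-to-term annotation map
#'
#' Background terms draw members uniformly from the universe of coding
#' and lncRNA features; two planted "browning-like" terms draw most of
#' their members from features with planted group effects, so enrichment
#' of a recovered DEG set should rank them first.
#'
#' @param truth_de The `truth_de` table from [simulate_counts()].
#' @param cfg The same [simulation_config()].
#' @param n_background Number of background terms.
#' @return A data.frame `gene_id`, `term_id`, `term_name`.
#' @export
simulate_term_map <- function(truth_de, cfg, n_background = 30) {
  with_seed(cfg$seed + 3L, {
    universe <- truth_de$transcript_id[
      truth_de$class %in% c("coding", "annotated_lncRNA", "true_novel")]
    de_cols <- grep("^de_", names(truth_de), value = TRUE)
    any_de <- rowSums(as.matrix(truth_de[, de_cols])) > 0
    de_feats <- intersect(universe,
                          truth_de$transcript_id[any_de])
    rows <- list()
    for (t in seq_len(n_background)) {
      k <- sample(10:40, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sample(universe, k),
        term_id = sprintf("TERM:%04d", t),
        term_name = sprintf("background process %d", t),
        stringsAsFactors = FALSE)
    }
    for (t in 1:2) {
      k <- 25
      n_hit <- min(length(de_feats), round(0.7 * k))
      members <- c(sample(de_feats, n_hit),
                   sample(setdiff(universe, de_feats), k - n_hit))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = members,
        term_id = sprintf("TERM:DE%02d", t),
        term_name = c("thermogenic program", "lipid oxidation")[t],
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Run the full simulation and optionally write its files
#'
#' Convenience wrapper producing every input the pipeline consumes:
#' reference and assembled GTFs, genome FASTA, count matrix, conservation
#' track, term map, and the truth tables. With `dir` set, all files are
#' written (plain text) and the paths returned alongside the objects.
#'
#' @param cfg A [simulation_config()].
#' @param dir Optional output directory (created if missing).
#' @return A list with the simulation objects (`reference`, `assembled`,
#'   `genome`, `truth`, `cis_truth`, `counts`, `size_factors`,
#'   `truth_de`, `conservation`, `term_map`, `cfg`) and, when `dir` is
#'   given, a `paths` element.
#' @export
simulate_experiment <- function(cfg = simulation_config(), dir = NULL) {
  sim <- simulate_annotation(cfg)
  cl <- simulate_counts(sim, cfg)
  sim$counts <- cl$counts
  sim$size_factors <- cl$size_factors
  sim$truth_de <- cl$truth_de
  sim$conservation <- simulate_conservation(sim, cfg)
  sim$term_map <- simulate_term_map(sim$truth_de, cfg)
  sim$cfg <- cfg
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(dir, f)
    write_gtf(sim$reference, p("reference.gtf"))
    write_gtf(sim$assembled, p("assembled.gtf"))
    Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
    write_tsv_matrix(sim$counts, p("counts.tsv"), "transcript_id")
    write_conservation_track(sim$conservation, p("conservation.tsv"))
    utils::write.table(sim$term_map, p("term_map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth, p("truth_features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth_de, p("truth_de.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$cis_truth, p("truth_cis.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg_json <- cfg
    class(cfg_json) <- NULL
    jsonlite::write_json(cfg_json, p("config.json"), auto_unbox = TRUE,
                         digits = NA)
    sim$paths <- stats::setNames(
      file.path(dir, c("reference.gtf", "assembled.gtf", "genome.fa",
                       "counts.tsv", "conservation.tsv", "term_map.tsv",
                       "truth_features.tsv", "truth_de.tsv",
                       "truth_cis.tsv", "config.json")),
      c("reference", "assembled", "genome", "counts", "conservation",
        "term_map", "truth_features", "truth_de", "truth_cis",
        "config"))
  }
  sim
}

#' Write / read a matrix as TSV with a named id column
#'
#' @param m Matrix with rownames.
#' @param path File path.
#' @param id_col Name of the first column holding the rownames.
#' @return Invisibly, `path` (`read_tsv_matrix` returns the matrix).
#' @export
write_tsv_matrix <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
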
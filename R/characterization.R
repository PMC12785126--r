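#' Read a per-base conservation track
#'
#' Expects a 4-column TSV (`chrom`, `start`, `end`, `score`) with 0-based
#' half-open intervals, phastCons-like scores. Intervals are converted to
#' the package's 1-based closed convention on read.
#'
#' @param path TSV path (no header).
#' @return A `GRanges` with a `score` metadata column.
#' @export
read_conservation_track <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "score"),
                          stringsAsFactors = FALSE)
  stopifnot(all(df$end > df$start))
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         score = df$score)
}

#' Write a conservation track
#'
#' Inverse of [read_conservation_track()]: emits 0-based half-open
#' intervals.
#'
#' @param track A `GRanges` with a `score` column.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_conservation_track <- function(track, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(track)),
                   start = BiocGenerics::start(track) - 1L,
                   end = BiocGenerics::end(track),
                   score = track$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Gaps between consecutive exons of one transcript (all exons must share
# one chromosome); empty for single-exon transcripts.
intron_ranges <- function(exons) {
  s <- BiocGenerics::start(exons)
  e <- BiocGenerics::end(exons)
  o <- order(s)
  s <- s[o]
  e <- e[o]
  if (length(s) < 2L) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(exons))[1],
    IRanges::IRanges(e[-length(e)] + 1L, s[-1] - 1L))
}

# Mean track score over a set of (disjoint) intervals, weighting each
# covered base equally; NA when no base is covered by the track.
mean_track_score <- function(regions, track) {
  if (length(regions) == 0L) return(NA_real_)
  hits <- GenomicRanges::findOverlaps(regions, track, ignore.strand = TRUE)
  if (length(hits) == 0L) return(NA_real_)
  q <- regions[S4Vectors::queryHits(hits)]
  s <- track[S4Vectors::subjectHits(hits)]
  w <- BiocGenerics::width(IRanges::pintersect(IRanges::ranges(q),
                                               IRanges::ranges(s)))
  sum(w * s$score) / sum(w)
}

#' Per-class feature summary
#'
#' Collects, for one class of transcripts (novel lncRNA, annotated lncRNA
#' or coding), the feature vectors compared across classes: spliced
#' lengths, per-transcript maximum FPKM over samples, coding-potential
#' scores, and mean conservation over exonic and intronic bases. Introns
#' are the gaps between consecutive exons of a transcript; single-exon
#' transcripts contribute no intron value.
#'
#' @param class_label Label stored in the summary.
#' @param transcript_ids Members of the class.
#' @param annotation A [genome_annotation()] containing them.
#' @param fpkm FPKM matrix (rows = transcripts).
#' @param coding_scores Optional [score_transcripts()] data.frame.
#' @param conservation Optional track from [read_conservation_track()].
#' @return A list of class `class_summary` with elements `class`, `ids`,
#'   `lengths`, `fpkm_max`, `coding_scores`, `exon_conservation`,
#'   `intron_conservation`.
#' @export
summarize_class <- function(class_label, transcript_ids, annotation,
                            fpkm = NULL, coding_scores = NULL,
                            conservation = NULL) {
  tx <- annotation$transcripts
  tx <- tx[match(transcript_ids, tx$transcript_id), , drop = FALSE]
  if (anyNA(tx$transcript_id)) {
    stop("transcripts missing from annotation: ",
         paste(utils::head(transcript_ids[is.na(tx$transcript_id)]),
               collapse = ", "))
  }
  out <- list(class = class_label, ids = transcript_ids,
              lengths = stats::setNames(tx$length, tx$transcript_id),
              fpkm_max = NULL, coding_scores = NULL,
              exon_conservation = NULL, intron_conservation = NULL)
  if (!is.null(fpkm)) {
    out$fpkm_max <- apply(fpkm[transcript_ids, , drop = FALSE], 1, max)
  }
  if (!is.null(coding_scores)) {
    out$coding_scores <- stats::setNames(
      coding_scores$score[match(transcript_ids,
                                coding_scores$transcript_id)],
      transcript_ids)
  }
  if (!is.null(conservation)) {
    track_chroms <- as.character(
      GenomeInfoDb::seqlevels(conservation))
    missing <- setdiff(unique(tx$chrom), track_chroms)
    if (length(missing)) {
      stop("conservation track lacks chromosome(s): ",
           paste(missing, collapse = ", "))
    }
    ex <- annotation$exons
    exon_cons <- intron_cons <- stats::setNames(
      rep(NA_real_, length(transcript_ids)), transcript_ids)
    for (id in transcript_ids) {
      e <- ex[ex$transcript_id == id]
      exon_cons[id] <- mean_track_score(e, conservation)
      if (length(e) > 1L) {
        intron_cons[id] <- mean_track_score(intron_ranges(e),
                                            conservation)
      }
    }
    out$exon_conservation <- exon_cons
    out$intron_conservation <- intron_cons
  }
  structure(out, class = "class_summary")
}

#' Empirical cumulative distribution function
#'
#' Right-continuous ECDF of a non-empty sample (delegates to
#' `stats::ecdf`): 0 below the minimum, 1 at and above the maximum.
#'
#' @param values Non-empty numeric vector.
#' @return A function of class `ecdf`.
#' @export
empirical_cdf <- function(values) {
  if (length(values) == 0L) stop("values must be non-empty")
  stats::ecdf(values)
}

#' Compare transcript classes
#'
#' For each feature (length, max FPKM, coding score, exon and intron
#' conservation) reports per-class medians and two-sided Wilcoxon
#' rank-sum p-values for every class pair. Classes with fewer than 3
#' values for a feature are skipped for that feature's tests, with a
#' warning.
#'
#' @param summaries A list of [summarize_class()] objects (>= 2).
#' @return A list with `medians` (data.frame class x feature) and
#'   `tests` (data.frame feature, class_a, class_b, p).
#' @export
class_comparison_report <- function(summaries) {
  stopifnot(length(summaries) >= 2)
  features <- c(lengths = "length", fpkm_max = "fpkm_max",
                coding_scores = "coding_score",
                exon_conservation = "exon_conservation",
                intron_conservation = "intron_conservation")
  med_rows <- list()
  test_rows <- list()
  for (slot in names(features)) {
    vals <- lapply(summaries, function(s) {
      v <- s[[slot]]
      v[is.finite(v)]
    })
    names(vals) <- vapply(summaries, `[[`, character(1), "class")
    have <- vapply(vals, length, integer(1)) > 0
    if (!any(have)) next
    for (cl in names(vals)[have]) {
      med_rows[[length(med_rows) + 1L]] <- data.frame(
        class = cl, feature = features[[slot]],
        n = length(vals[[cl]]), median = stats::median(vals[[cl]]),
        stringsAsFactors = FALSE)
    }
    testable <- names(vals)[vapply(vals, length, integer(1)) >= 3]
    small <- setdiff(names(vals)[have], testable)
    if (length(small)) {
      warning("class(es) with < 3 values for ", features[[slot]],
              ", tests skipped: ", paste(small, collapse = ", "))
    }
    if (length(testable) >= 2) {
      pairs <- utils::combn(testable, 2)
      for (j in seq_len(ncol(pairs))) {
        a <- pairs[1, j]; b <- pairs[2, j]
        p <- suppressWarnings(
          stats::wilcox.test(vals[[a]], vals[[b]])$p.value)
        test_rows[[length(test_rows) + 1L]] <- data.frame(
          feature = features[[slot]], class_a = a, class_b = b, p = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(medians = do.call(rbind, med_rows),
       tests = do.call(rbind, test_rows))
}

#' Class-comparison plots
#'
#' ggplot2 analogues of the standard characterization panels: length
#' density, expression ECDF (log10(FPKM + 1e-3)), coding-score density,
#' and exon-conservation ECDF.
#'
#' @param summaries A list of [summarize_class()] objects.
#' @return A named list of ggplot objects (only panels with data).
#' @export
class_comparison_plots <- function(summaries) {
  gather <- function(slot, transform = identity) {
    dfs <- lapply(summaries, function(s) {
      v <- s[[slot]]
      v <- v[is.finite(v)]
      if (!length(v)) return(NULL)
      data.frame(class = s$class, value = transform(v),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, dfs)
  }
  plots <- list()
  len <- gather("lengths")
  if (!is.null(len)) {
    plots$length <- ggplot2::ggplot(len,
        ggplot2::aes(x = value, colour = class)) +
      ggplot2::geom_density() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "transcript length (nt)", y = "density")
  }
  expr <- gather("fpkm_max", function(v) log10(v + 1e-3))
  if (!is.null(expr)) {
    plots$expression <- ggplot2::ggplot(expr,
        ggplot2::aes(x = value, colour = class)) +
      ggplot2::stat_ecdf() +
      ggplot2::labs(x = "log10(max FPKM + 1e-3)",
                    y = "cumulative fraction")
  }
  sc <- gather("coding_scores")
  if (!is.null(sc)) {
    plots$coding_score <- ggplot2::ggplot(sc,
        ggplot2::aes(x = value, colour = class)) +
      ggplot2::geom_density() +
      ggplot2::labs(x = "coding-potential score", y = "density")
  }
  cons <- gather("exon_conservation")
  if (!is.null(cons)) {
    plots$conservation <- ggplot2::ggplot(cons,
        ggplot2::aes(x = value, colour = class)) +
      ggplot2::stat_ecdf() +
      ggplot2::labs(x = "mean exon conservation",
                    y = "cumulative fraction")
  }
  plots
}
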
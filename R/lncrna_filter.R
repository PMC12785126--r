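#' Filter thresholds for novel-lncRNA identification
#'
#' All comparisons are strict, as printed in the originating criteria:
#' transcripts are kept when length > `min_length` nt, maximum FPKM over
#' samples > `min_fpkm`, distance to the nearest known single-exon
#' transcript > `min_single_exon_distance` bp, and coding-potential score
#' < `coding_score_max`. `min_exons` is off by default (no exon-count
#' exclusion); when set, transcripts with fewer exons are removed at the
#' first stage.
#'
#' @param min_length Minimum spliced length in nt (strict, default 200).
#' @param min_fpkm Minimum FPKM in at least one sample (strict, 0.5).
#' @param min_single_exon_distance Minimum gap in bp to any known
#'   single-exon transcript (strict, 2000).
#' @param coding_score_max Upper bound on the signed coding score
#'   (strict, 0).
#' @param min_exons Optional minimum exon count (`NULL` = no filter).
#' @param stranded_overlap If `TRUE`, the known-exon overlap filter only
#'   counts same-strand overlaps; default `FALSE` (strand-blind, the
#'   conservative reading).
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_length = 200, min_fpkm = 0.5,
                              min_single_exon_distance = 2000,
                              coding_score_max = 0, min_exons = NULL,
                              stranded_overlap = FALSE) {
  stopifnot(min_length > 0, min_fpkm > 0, min_single_exon_distance > 0)
  structure(list(min_length = min_length, min_fpkm = min_fpkm,
                 min_single_exon_distance = min_single_exon_distance,
                 coding_score_max = coding_score_max,
                 min_exons = min_exons,
                 stranded_overlap = isTRUE(stranded_overlap)),
            class = "filter_thresholds")
}

#' Compute FPKM from a count matrix
#'
#' `FPKM[t, s] = count[t, s] / ((length[t] / 1e3) * (total[s] / 1e6))`,
#' where `total[s]` is the column sum of the count matrix (the library
#' size used for normalization).
#'
#' @param counts Non-negative count matrix, rows = transcripts (rownames
#'   required), columns = samples.
#' @param lengths Named vector of transcript lengths in nt (>= 1), covering
#'   all rows of `counts`.
#' @return An FPKM matrix with the same dimnames as `counts`.
#' @export
compute_fpkm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), all(counts >= 0))
  if (!all(rownames(counts) %in% names(lengths))) {
    stop("lengths missing for: ",
         paste(utils::head(setdiff(rownames(counts), names(lengths))),
               collapse = ", "))
  }
  len <- lengths[rownames(counts)]
  stopifnot(all(len >= 1))
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("zero column sum in sample(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  sweep(counts / (len / 1e3), 2, totals / 1e6, "/")
}

decision_frame <- function(ids, passed, reason) {
  data.frame(transcript_id = ids, passed = passed,
             reason = ifelse(passed, "", reason),
             stringsAsFactors = FALSE)
}

#' Length and expression filter
#'
#' Pass requires spliced length strictly greater than `thr$min_length` and
#' FPKM strictly greater than `thr$min_fpkm` in at least one sample.
#'
#' @param candidates A [genome_annotation()] of candidate transcripts.
#' @param fpkm FPKM matrix covering every candidate (rownames =
#'   transcript ids).
#' @param thr [filter_thresholds()].
#' @return A data.frame `transcript_id`, `passed`, `reason`.
#' @export
filter_length_fpkm <- function(candidates, fpkm,
                               thr = filter_thresholds()) {
  tx <- candidates$transcripts
  missing <- setdiff(tx$transcript_id, rownames(fpkm))
  if (length(missing)) {
    stop("candidates absent from FPKM matrix: ",
         paste(utils::head(missing), collapse = ", "))
  }
  max_fpkm <- apply(fpkm[tx$transcript_id, , drop = FALSE], 1, max)
  len_ok <- tx$length > thr$min_length
  fpkm_ok <- max_fpkm > thr$min_fpkm
  exon_ok <- if (is.null(thr$min_exons)) TRUE else
    tx$n_exons >= thr$min_exons
  reason <- paste0(
    ifelse(len_ok, "", sprintf("length<=%g", thr$min_length)),
    ifelse(fpkm_ok, "", sprintf(";max_fpkm<=%g", thr$min_fpkm)),
    ifelse(exon_ok, "", ";too_few_exons")
  )
  reason <- sub("^;", "", reason)
  decision_frame(tx$transcript_id, len_ok & fpkm_ok & exon_ok, reason)
}

#' Known-exon overlap filter
#'
#' A candidate fails when any of its exons shares at least one base with
#' any exon of a known (coding or annotated-lncRNA) transcript on the same
#' chromosome. By default the test is strand-blind; `thr$stranded_overlap`
#' restricts it to same-strand overlaps. Adjacency is not overlap.
#'
#' @param candidates A [genome_annotation()] of candidates.
#' @param known A [genome_annotation()] providing the known exons.
#' @param thr [filter_thresholds()].
#' @return A data.frame `transcript_id`, `passed`, `reason`.
#' @export
filter_known_overlap <- function(candidates, known,
                                 thr = filter_thresholds()) {
  known_ex <- known$exons[known$exons$annotation_status %in%
                            c("coding", "annotated_lncRNA")]
  cand_ex <- candidates$exons
  all_levels <- union(GenomeInfoDb::seqlevels(cand_ex),
                      GenomeInfoDb::seqlevels(known_ex))
  GenomeInfoDb::seqlevels(cand_ex) <- all_levels
  GenomeInfoDb::seqlevels(known_ex) <- all_levels
  hits <- GenomicRanges::findOverlaps(
    cand_ex, known_ex, minoverlap = 1L,
    ignore.strand = !thr$stranded_overlap
  )
  bad <- unique(cand_ex$transcript_id[S4Vectors::queryHits(hits)])
  ids <- candidates$transcripts$transcript_id
  decision_frame(ids, !ids %in% bad, "overlaps_known_exon")
}

#' Single-exon distance filter
#'
#' A candidate fails when the gap between its span (first exon start to
#' last exon end) and the span of any known single-exon transcript on the
#' same chromosome is less than or equal to
#' `thr$min_single_exon_distance` bp. The gap counts bases strictly
#' between the two spans (0 for overlapping or adjacent spans); strand is
#' ignored. Chromosomes without known single-exon transcripts pass
#' vacuously.
#'
#' @inheritParams filter_known_overlap
#' @return A data.frame `transcript_id`, `passed`, `reason`.
#' @export
filter_single_exon_distance <- function(candidates, known,
                                        thr = filter_thresholds()) {
  ktx <- known$transcripts
  single <- ktx[ktx$n_exons == 1L, , drop = FALSE]
  ids <- candidates$transcripts$transcript_id
  if (nrow(single) == 0L) {
    return(decision_frame(ids, rep(TRUE, length(ids)), ""))
  }
  single_gr <- GenomicRanges::GRanges(
    single$chrom, IRanges::IRanges(single$start, single$end)
  )
  cand_gr <- transcript_spans(candidates)
  all_levels <- union(GenomeInfoDb::seqlevels(cand_gr),
                      GenomeInfoDb::seqlevels(single_gr))
  GenomeInfoDb::seqlevels(cand_gr) <- all_levels
  GenomeInfoDb::seqlevels(single_gr) <- all_levels
  near <- GenomicRanges::distanceToNearest(cand_gr, single_gr,
                                           ignore.strand = TRUE)
  dist <- rep(Inf, length(cand_gr))
  dist[S4Vectors::queryHits(near)] <- S4Vectors::mcols(near)$distance
  decision_frame(ids, dist > thr$min_single_exon_distance,
                 sprintf("single_exon_within_%gbp",
                         thr$min_single_exon_distance))
}

#' Identify novel lncRNAs
#'
#' The full novelty cascade over the unannotated transcripts of a merged
#' assembly, applied in order: (1) length > 200 nt and FPKM > 0.5 in at
#' least one sample; (2) no base-level overlap with known exons; (3) gap
#' > 2 kb to any known single-exon transcript; (4) coding-potential score
#' < 0. Every unannotated transcript receives exactly one decision record
#' stating the first stage at which it failed (or `passed`).
#'
#' @param assembled [genome_annotation()] of the merged assembly
#'   (reference plus unannotated transcripts).
#' @param reference [genome_annotation()] of the known annotation used for
#'   the overlap and distance filters.
#' @param counts Count matrix over assembled transcripts (used to compute
#'   FPKM), or `NULL` when `fpkm` is supplied directly.
#' @param genome Named `DNAStringSet`; required unless `scores` is given.
#' @param model A trained [train_coding_model()] model; required unless
#'   `scores` is given.
#' @param thr [filter_thresholds()].
#' @param fpkm Optional precomputed FPKM matrix (used verbatim).
#' @param scores Optional precomputed [score_transcripts()] data.frame.
#' @return A list with `novel_ids` (character), `decisions` (data.frame
#'   `transcript_id`, `stage_reached`, `reasons`, `passed`) and `funnel`
#'   (named integer vector of survivors after each stage).
#' @export
identify_novel_lncrnas <- function(assembled, reference, counts = NULL,
                                   genome = NULL, model = NULL,
                                   thr = filter_thresholds(),
                                   fpkm = NULL, scores = NULL) {
  tx <- assembled$transcripts
  cand_ids <- tx$transcript_id[tx$annotation_status == "unannotated"]
  stages <- c("length_fpkm", "overlap", "distance", "coding")
  if (length(cand_ids) == 0L) {
    return(list(
      novel_ids = character(),
      decisions = data.frame(transcript_id = character(),
                             stage_reached = character(),
                             reasons = character(), passed = logical(),
                             stringsAsFactors = FALSE),
      funnel = stats::setNames(integer(5), c("unannotated", stages))
    ))
  }
  candidates <- subset_annotation(assembled, cand_ids)
  if (is.null(fpkm)) {
    if (is.null(counts)) stop("either counts or fpkm must be supplied")
    lengths <- stats::setNames(assembled$transcripts$length,
                               assembled$transcripts$transcript_id)
    fpkm <- compute_fpkm(counts, lengths)
  }

  stage_reached <- stats::setNames(rep("passed", length(cand_ids)),
                                   cand_ids)
  reasons <- stats::setNames(rep("", length(cand_ids)), cand_ids)
  alive <- cand_ids
  funnel <- c(unannotated = length(cand_ids))

  apply_stage <- function(stage, dec) {
    fail <- dec$transcript_id[!dec$passed]
    stage_reached[fail] <<- stage
    reasons[fail] <<- dec$reason[!dec$passed]
    alive <<- setdiff(alive, fail)
    funnel[stage] <<- length(alive)
  }

  apply_stage("length_fpkm",
              filter_length_fpkm(candidates, fpkm, thr))
  apply_stage("overlap",
              filter_known_overlap(subset_if_any(candidates, alive),
                                   reference, thr))
  apply_stage("distance",
              filter_single_exon_distance(subset_if_any(candidates, alive),
                                          reference, thr))

  if (length(alive)) {
    if (is.null(scores)) {
      if (is.null(genome) || is.null(model)) {
        stop("genome and model (or precomputed scores) are required ",
             "for the coding-potential stage")
      }
      seqs <- extract_transcript_sequence(genome, candidates, alive)
      scores <- score_transcripts(seqs, model)
    }
    sc <- scores[match(alive, scores$transcript_id), , drop = FALSE]
    if (anyNA(sc$score)) {
      stop("coding scores missing for: ",
           paste(utils::head(alive[is.na(sc$score)]), collapse = ", "))
    }
    dec <- decision_frame(alive, sc$score < thr$coding_score_max,
                          sprintf("coding_score>=%g",
                                  thr$coding_score_max))
    apply_stage("coding", dec)
  } else {
    funnel["coding"] <- 0L
  }

  decisions <- data.frame(
    transcript_id = cand_ids,
    stage_reached = unname(stage_reached[cand_ids]),
    reasons = unname(reasons[cand_ids]),
    passed = unname(stage_reached[cand_ids]) == "passed",
    stringsAsFactors = FALSE
  )
  list(novel_ids = alive, decisions = decisions, funnel = funnel)
}

subset_if_any <- function(annotation, ids) {
  if (length(ids) == 0L) {
    return(genome_annotation(GenomicRanges::GRanges(
      transcript_id = character(), gene_id = character()
    )))
  }
  subset_annotation(annotation, ids)
}
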
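#' Construct a genome annotation
#'
#' Container holding a set of transcript models together with the exon-level
#' interval index that the novelty filters query. Exons are stored as a
#' [GenomicRanges::GRanges] (1-based, closed intervals, the Bioconductor
#' convention) carrying `transcript_id` and `gene_id` metadata columns; the
#' transcript table summarises each model (span, exon count, spliced length,
#' annotation status).
#'
#' @param exons A `GRanges` of exons with metadata columns `transcript_id`,
#'   `gene_id` and `annotation_status`. Exons of one transcript must lie on a
#'   single chromosome and strand and be pairwise disjoint.
#' @param annotation_status Optional named character vector
#'   (`transcript_id -> status`) overriding the per-exon status column.
#'
#' @return An object of class `genome_annotation` with elements
#'   `transcripts` (data.frame) and `exons` (`GRanges`, sorted).
#' @export
genome_annotation <- function(exons, annotation_status = NULL) {
  stopifnot(methods::is(exons, "GRanges"))
  mc <- S4Vectors::mcols(exons)
  if (is.null(mc$transcript_id) || is.null(mc$gene_id)) {
    stop("exons must carry 'transcript_id' and 'gene_id' metadata columns")
  }
  if (!is.null(annotation_status)) {
    mc$annotation_status <- unname(annotation_status[mc$transcript_id])
  }
  if (is.null(mc$annotation_status)) {
    mc$annotation_status <- rep("unannotated", length(exons))
  }
  status <- mc$annotation_status
  ok <- status %in% c("coding", "annotated_lncRNA", "unannotated")
  if (!all(ok)) stop("unknown annotation_status: ",
                     paste(unique(status[!ok]), collapse = ", "))
  S4Vectors::mcols(exons) <- mc
  exons <- exons[order(as.character(GenomeInfoDb::seqnames(exons)),
                       BiocGenerics::start(exons))]

  tid <- mc <- NULL
  tid <- exons$transcript_id
  if (length(exons)) {
    strand_chr <- as.character(BiocGenerics::strand(exons))
    if (any(!strand_chr %in% c("+", "-"))) {
      stop("exon strand must be '+' or '-'")
    }
    chrom <- as.character(GenomeInfoDb::seqnames(exons))
    sp <- split(seq_along(exons), tid)
    for (idx in sp) {
      if (length(unique(chrom[idx])) != 1L ||
          length(unique(strand_chr[idx])) != 1L) {
        stop("exons of transcript '", tid[idx[1]],
             "' span multiple chromosomes or strands")
      }
      if (length(idx) > 1L) {
        s <- BiocGenerics::start(exons)[idx]
        e <- BiocGenerics::end(exons)[idx]
        o <- order(s)
        if (any(s[o][-1] <= e[o][-length(o)])) {
          stop("exons of transcript '", tid[idx[1]], "' overlap")
        }
      }
    }
    first <- !duplicated(tid)
    agg_len <- tapply(BiocGenerics::width(exons), tid, sum)
    agg_n <- tapply(rep.int(1L, length(exons)), tid, sum)
    agg_start <- tapply(BiocGenerics::start(exons), tid, min)
    agg_end <- tapply(BiocGenerics::end(exons), tid, max)
    ids <- tid[first]
    transcripts <- data.frame(
      transcript_id = ids,
      gene_id = exons$gene_id[first],
      chrom = chrom[first],
      strand = strand_chr[first],
      start = as.integer(agg_start[ids]),
      end = as.integer(agg_end[ids]),
      n_exons = as.integer(agg_n[ids]),
      length = as.integer(agg_len[ids]),
      annotation_status = exons$annotation_status[first],
      stringsAsFactors = FALSE
    )
    rownames(transcripts) <- NULL
  } else {
    transcripts <- data.frame(
      transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(),
      start = integer(), end = integer(), n_exons = integer(),
      length = integer(), annotation_status = character(),
      stringsAsFactors = FALSE
    )
  }
  structure(list(transcripts = transcripts, exons = exons),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  tab <- table(x$transcripts$annotation_status)
  cat("genome_annotation:", nrow(x$transcripts), "transcripts,",
      length(x$exons), "exons\n")
  if (length(tab)) {
    cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"),
        "\n")
  }
  invisible(x)
}

#' Default biotype classification rules
#'
#' Maps GTF gene/transcript biotype attributes onto the three annotation
#' statuses the pipeline distinguishes: `protein_coding` becomes `coding`;
#' biotypes containing `lncRNA`, `lincRNA` or `antisense` become
#' `annotated_lncRNA`; everything else (including transcripts with no
#' biotype attribute at all, as emitted for assembler-novel `MSTRG.*`
#' models) is `unannotated`.
#'
#' @param coding_biotypes Character vector of biotypes mapped to `coding`.
#' @param lncrna_patterns Regular expressions (case-insensitive) mapped to
#'   `annotated_lncRNA`.
#' @return A list usable as the `biotype_rules` argument of [parse_gtf()].
#' @export
default_biotype_rules <- function(coding_biotypes = "protein_coding",
                                  lncrna_patterns = c("lncRNA", "lincRNA",
                                                      "antisense")) {
  list(coding_biotypes = coding_biotypes, lncrna_patterns = lncrna_patterns)
}

classify_biotype <- function(biotype, rules) {
  status <- rep("unannotated", length(biotype))
  known <- !is.na(biotype)
  status[known & biotype %in% rules$coding_biotypes] <- "coding"
  pat <- paste(rules$lncrna_patterns, collapse = "|")
  status[known & grepl(pat, biotype, ignore.case = TRUE) &
           status == "unannotated"] <- "annotated_lncRNA"
  status
}

validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9L) {
      stop("GTF parse error at line ", i, ": expected 9 tab-separated ",
           "fields, found ", length(fields))
    }
    st <- suppressWarnings(as.integer(fields[4]))
    en <- suppressWarnings(as.integer(fields[5]))
    if (is.na(st) || is.na(en) || st < 1L || en < st) {
      stop("GTF parse error at line ", i, ": invalid coordinates '",
           fields[4], "'-'", fields[5], "'")
    }
    if (fields[3] == "exon" && !grepl("transcript_id", fields[9],
                                      fixed = TRUE)) {
      stop("GTF parse error at line ", i, ": exon feature lacks a ",
           "transcript_id attribute")
    }
  }
  sum(nzchar(lines) & !startsWith(lines, "#"))
}

#' Read a GTF annotation
#'
#' Reads an Ensembl-dialect GTF (1-based, closed coordinates) through
#' rtracklayer after a light structural validation pass that reports
#' malformed lines by line number. Only `exon` features are used to build
#' transcript models; each transcript's annotation status is derived from
#' its `gene_biotype`/`transcript_biotype` attribute via `biotype_rules`.
#'
#' @param path Path to a GTF file.
#' @param biotype_rules Rules from [default_biotype_rules()].
#' @return A [genome_annotation()].
#' @export
parse_gtf <- function(path, biotype_rules = default_biotype_rules()) {
  if (!file.exists(path)) stop("no such file: ", path)
  n_feat <- validate_gtf_lines(path)
  if (n_feat == 0L) {
    return(genome_annotation(GenomicRanges::GRanges(
      transcript_id = character(), gene_id = character()
    )))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) {
    return(genome_annotation(GenomicRanges::GRanges(
      transcript_id = character(), gene_id = character()
    )))
  }
  biotype <- gr$gene_biotype
  if (is.null(biotype)) biotype <- gr$transcript_biotype
  if (is.null(biotype)) biotype <- rep(NA_character_, length(gr))
  gid <- gr$gene_id
  if (is.null(gid)) gid <- gr$transcript_id
  exons <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(gr), IRanges::ranges(gr),
    strand = BiocGenerics::strand(gr),
    transcript_id = gr$transcript_id,
    gene_id = gid,
    annotation_status = classify_biotype(biotype, biotype_rules)
  )
  genome_annotation(exons)
}

#' Write a genome annotation as GTF
#'
#' Emits one `exon` line per exon with 1-based closed coordinates and
#' `transcript_id`/`gene_id` attributes. Annotation status is encoded as a
#' `gene_biotype` attribute (`protein_coding` for coding, `lncRNA` for
#' annotated lncRNAs, omitted for unannotated transcripts) so that
#' `parse_gtf(write_gtf(x))` recovers `x`.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  ex <- annotation$exons
  if (length(ex) == 0L) {
    writeLines("##gff-version 2", path)
    return(invisible(path))
  }
  biotype <- c(coding = "protein_coding", annotated_lncRNA = "lncRNA",
               unannotated = NA_character_)[ex$annotation_status]
  out <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(ex), IRanges::ranges(ex),
    strand = BiocGenerics::strand(ex)
  )
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    source = "adipolnc", type = "exon",
    transcript_id = ex$transcript_id, gene_id = ex$gene_id,
    gene_biotype = unname(biotype)
  )
  rtracklayer::export(out, path, format = "gtf")
  invisible(path)
}

#' Extract spliced transcript sequences
#'
#' Concatenates exon sequences in genomic order and reverse-complements the
#' result for minus-strand transcripts, so the returned sequence reads 5' to
#' 3' in transcript orientation. Output lengths equal the spliced transcript
#' lengths.
#'
#' @param genome A named [Biostrings::DNAStringSet] of chromosome sequences.
#' @param annotation A [genome_annotation()].
#' @param transcript_ids Transcripts to extract (default: all).
#' @return A `DNAStringSet` named by transcript id.
#' @export
extract_transcript_sequence <- function(genome, annotation,
                                        transcript_ids = NULL) {
  stopifnot(methods::is(genome, "DNAStringSet"),
            inherits(annotation, "genome_annotation"))
  tx <- annotation$transcripts
  if (!is.null(transcript_ids)) {
    missing <- setdiff(transcript_ids, tx$transcript_id)
    if (length(missing)) stop("unknown transcript(s): ",
                              paste(missing, collapse = ", "))
    tx <- tx[match(transcript_ids, tx$transcript_id), , drop = FALSE]
  }
  ex <- annotation$exons
  ex_by_tx <- split(seq_along(ex), ex$transcript_id)
  out <- vector("list", nrow(tx))
  chrom_len <- stats::setNames(BiocGenerics::width(genome),
                               names(genome))
  for (i in seq_len(nrow(tx))) {
    chrom <- tx$chrom[i]
    if (!chrom %in% names(genome)) stop("chromosome '", chrom,
                                        "' absent from genome")
    idx <- ex_by_tx[[tx$transcript_id[i]]]
    s <- BiocGenerics::start(ex)[idx]
    e <- BiocGenerics::end(ex)[idx]
    o <- order(s)
    if (max(e) > chrom_len[chrom]) {
      stop("exon of '", tx$transcript_id[i], "' extends beyond end of ",
           chrom, " (", max(e), " > ", chrom_len[chrom], ")")
    }
    pieces <- Biostrings::extractAt(genome[[chrom]],
                                    IRanges::IRanges(s[o], e[o]))
    seq <- unlist(pieces)
    if (tx$strand[i] == "-") seq <- Biostrings::reverseComplement(seq)
    out[[i]] <- seq
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- tx$transcript_id
  res
}

#' Transcript spans as GRanges
#'
#' One range per transcript covering first exon start to last exon end,
#' with `transcript_id`, `gene_id` and `annotation_status` metadata.
#'
#' @param annotation A [genome_annotation()].
#' @param status Optional filter on annotation status.
#' @return A `GRanges`.
#' @export
transcript_spans <- function(annotation, status = NULL) {
  tx <- annotation$transcripts
  if (!is.null(status)) tx <- tx[tx$annotation_status %in% status, ,
                                 drop = FALSE]
  GenomicRanges::GRanges(
    tx$chrom, IRanges::IRanges(tx$start, tx$end), strand = tx$strand,
    transcript_id = tx$transcript_id, gene_id = tx$gene_id,
    annotation_status = tx$annotation_status,
    n_exons = tx$n_exons
  )
}

#' Subset an annotation by transcript id
#'
#' @param annotation A [genome_annotation()].
#' @param transcript_ids Ids to keep.
#' @return A [genome_annotation()] restricted to the requested transcripts.
#' @export
subset_annotation <- function(annotation, transcript_ids) {
  ex <- annotation$exons
  genome_annotation(ex[ex$transcript_id %in% transcript_ids])
}
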
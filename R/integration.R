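#' Intersect DEG sets across contrasts
#'
#' Computes every Venn region of two or more named feature sets. Each
#' feature in the union is assigned to exactly one region keyed by the
#' sets that contain it (names joined with `&`), so region sizes sum to
#' the union size. The common set is the intersection of all sets.
#'
#' @param deg_sets Named list (>= 2 elements) of character vectors.
#' @return A list with `regions` (named list of character vectors, keys =
#'   membership patterns), `region_sizes` (named integer vector), and
#'   `common` (character vector).
#' @export
intersect_contrasts <- function(deg_sets) {
  stopifnot(length(deg_sets) >= 2, !is.null(names(deg_sets)),
            all(nzchar(names(deg_sets))))
  sets <- lapply(deg_sets, unique)
  all_feats <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(all_feats, function(f) {
    paste(names(sets)[vapply(sets, function(s) f %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  regions <- split(all_feats, membership)
  common <- all_feats[membership == paste(names(sets), collapse = "&")]
  list(regions = regions,
       region_sizes = vapply(regions, length, integer(1)),
       common = common)
}

#' Up/down tallies per contrast and feature class
#'
#' Counts significant up- and down-regulated features per contrast,
#' overall and (when a class map is given) within each feature class,
#' e.g. genes versus lncRNAs. For every row, `n_up + n_down` equals the
#' number of significant features of that contrast and class.
#'
#' @param results Named list of [call_degs()] result data.frames.
#' @param feature_class Optional named character vector mapping
#'   `feature_id` to a class label; unmapped features are labelled
#'   `"other"`.
#' @return A data.frame `contrast`, `class`, `n_up`, `n_down`,
#'   `n_significant` (class `"all"` rows tally the whole contrast).
#' @export
updown_table <- function(results, feature_class = NULL) {
  rows <- list()
  for (nm in names(results)) {
    res <- results[[nm]]
    tally <- function(cls, sub) {
      data.frame(contrast = nm, class = cls,
                 n_up = sum(sub$direction == "up"),
                 n_down = sum(sub$direction == "down"),
                 n_significant = sum(sub$significant),
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- tally("all", res)
    if (!is.null(feature_class)) {
      cls <- feature_class[res$feature_id]
      cls[is.na(cls)] <- "other"
      for (cl in sort(unique(cls))) {
        rows[[length(rows) + 1L]] <- tally(cl, res[cls == cl, ,
                                                   drop = FALSE])
      }
    }
  }
  do.call(rbind, rows)
}

#' Assign a cis target gene to a lncRNA
#'
#' Finds the nearest protein-coding gene (by gap between genomic spans,
#' strand-blind) within `max_distance` of the lncRNA and classifies the
#' relative geometry in the TARGET GENE's orientation: `downstream` means
#' the lncRNA lies past the gene's 3' end, `upstream` before its 5' end,
#' `overlapping` when the spans share bases (distance 0).
#' `relative_strand` is `sense` when both lie on the same strand,
#' `antisense` otherwise. The reported distance is the coordinate gap
#' between the facing span boundaries (`target_start - lnc_end` or
#' `lnc_start - target_end`; 0 when the spans overlap). Ties on distance
#' go to the lexicographically smaller `gene_id`.
#'
#' @param lncrna A one-row data.frame (or list) with `chrom`, `strand`,
#'   `start`, `end`, `transcript_id` — e.g. one row of
#'   `annotation$transcripts`.
#' @param coding A [genome_annotation()]; its coding transcripts define
#'   the gene spans (union of spans per `gene_id`).
#' @param max_distance Maximum gap in bp (default 1e5).
#' @return A one-row data.frame `lncrna_id`, `target_gene_id`,
#'   `relative_position`, `relative_strand`, `distance`, or `NULL` when no
#'   coding gene lies within range.
#' @export
assign_cis_target <- function(lncrna, coding, max_distance = 1e5) {
  tx <- coding$transcripts
  tx <- tx[tx$annotation_status == "coding", , drop = FALSE]
  tx <- tx[tx$chrom == lncrna$chrom, , drop = FALSE]
  if (nrow(tx) == 0L) return(NULL)
  genes <- do.call(rbind, lapply(split(tx, tx$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], strand = g$strand[1],
               start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  gap <- pmax(genes$start - lncrna$end, lncrna$start - genes$end)
  gap <- pmax(0L, gap)
  genes <- genes[gap <= max_distance, , drop = FALSE]
  gap <- gap[gap <= max_distance]
  if (nrow(genes) == 0L) return(NULL)
  o <- order(gap, genes$gene_id)
  g <- genes[o[1], ]
  d <- gap[o[1]]
  pos <- if (lncrna$start <= g$end && g$start <= lncrna$end) {
    "overlapping"
  } else if (lncrna$start > g$end) {
    if (g$strand == "+") "downstream" else "upstream"
  } else {
    if (g$strand == "+") "upstream" else "downstream"
  }
  data.frame(
    lncrna_id = if (!is.null(lncrna$transcript_id)) lncrna$transcript_id
                else NA_character_,
    target_gene_id = g$gene_id,
    relative_position = pos,
    relative_strand = if (identical(lncrna$strand, g$strand)) "sense"
                      else "antisense",
    distance = d,
    stringsAsFactors = FALSE
  )
}

#' Cis targets for a set of lncRNAs
#'
#' @param lncrna_ids Transcript ids present in `annotation`.
#' @param annotation A [genome_annotation()] containing the lncRNAs.
#' @param coding A [genome_annotation()] providing coding genes.
#' @param max_distance Maximum gap in bp.
#' @return A data.frame with one row per lncRNA that has a target in
#'   range.
#' @export
assign_cis_targets <- function(lncrna_ids, annotation, coding,
                               max_distance = 1e5) {
  tx <- annotation$transcripts
  rows <- lapply(lncrna_ids, function(id) {
    r <- tx[tx$transcript_id == id, , drop = FALSE]
    if (nrow(r) == 0L) stop("unknown lncRNA: ", id)
    assign_cis_target(r, coding, max_distance = max_distance)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(lncrna_id = character(),
                      target_gene_id = character(),
                      relative_position = character(),
                      relative_strand = character(),
                      distance = integer(), stringsAsFactors = FALSE)
  }
  out
}

#' Hypergeometric term enrichment
#'
#' For each term with at least one hit in the query, tests over-
#' representation with the upper-tail hypergeometric probability
#' `P(X >= k)` for `k` hits among a query of size `n`, a term of size `K`
#' and a universe of size `N`, then adjusts across tested terms by BH.
#'
#' @param query Character vector of features (must lie in `universe`).
#' @param term_map A data.frame with columns `gene_id`, `term_id` and
#'   optionally `term_name`; rows outside the universe are dropped.
#' @param universe Character vector defining `N`.
#' @return A data.frame `term_id`, `term_name`, `term_size`, `hits`,
#'   `query_size`, `universe_size`, `p`, `padj`, sorted by `p`.
#' @export
enrich <- function(query, term_map, universe) {
  query <- unique(query)
  universe <- unique(universe)
  bad <- setdiff(query, universe)
  if (length(bad)) {
    stop("query features outside the universe: ",
         paste(utils::head(bad), collapse = ", "))
  }
  term_map <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  if (is.null(term_map$term_name)) term_map$term_name <- term_map$term_id
  n <- length(query)
  N <- length(universe)
  rows <- lapply(split(term_map, term_map$term_id), function(tm) {
    members <- unique(tm$gene_id)
    K <- length(members)
    k <- length(intersect(query, members))
    if (k == 0L) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tm$term_id[1], term_name = tm$term_name[1],
               term_size = K, hits = k, query_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term_id = character(), term_name = character(),
                      term_size = integer(), hits = integer(),
                      query_size = integer(), universe_size = integer(),
                      p = numeric(), padj = numeric(),
                      stringsAsFactors = FALSE))
  }
  out$padj <- bh_adjust(out$p)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
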
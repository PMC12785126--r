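# Fickett (1982) TESTCODE constants: probability-of-coding lookup tables
# indexed by position-asymmetry and base-content parameter bins, plus the
# published weights. Embedded verbatim from the original publication.
.fickett <- list(
  position_para = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0),
  content_para = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0),
  position_prob = list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
  ),
  position_weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
  content_prob = list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.61, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
  ),
  content_weight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
)

#' Fickett TESTCODE lookup constants
#'
#' Returns the embedded TESTCODE lookup tables and weights (Fickett 1982)
#' used by [fickett_score()], so callers and tests can evaluate the
#' statistic's definition independently.
#'
#' @return A list with elements `position_para`, `content_para`,
#'   `position_prob`, `position_weight`, `content_prob`, `content_weight`.
#' @export
fickett_tables <- function() .fickett

.stop_codons <- c("TAA", "TAG", "TGA")

#' Find the longest open reading frame
#'
#' Scans the three forward reading frames for ORFs running from an ATG to
#' the first in-frame stop codon (TAA/TAG/TGA), stop included. Reverse
#' frames are not scanned: transcript orientation is assumed already
#' resolved by strand. Ties on length are broken by the leftmost start.
#'
#' @param seq A single nucleotide string (or `DNAString`).
#' @return A list with `orf_length` (nt, multiple of 3; 0 when no ORF),
#'   `orf_coverage` (`orf_length / nchar(seq)`), and `orf_start` (1-based
#'   position of the ATG, `NA` when no ORF).
#' @export
find_longest_orf <- function(seq) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  stopifnot(n >= 1L)
  best_len <- 0L
  best_start <- NA_integer_
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 2L) next
    pos <- f + 3L * (seq_len(ncod) - 1L) + 1L
    codons <- substring(seq, pos, pos + 2L)
    starts <- which(codons == "ATG")
    stops <- which(codons %in% .stop_codons)
    if (!length(starts) || !length(stops)) next
    # first in-frame stop strictly after each start
    idx <- findInterval(starts, stops) + 1L
    ok <- idx <= length(stops)
    if (!any(ok)) next
    lens <- integer(length(starts))
    lens[ok] <- (stops[idx[ok]] - starts[ok] + 1L) * 3L
    for (k in which(ok)) {
      gstart <- pos[starts[k]]
      if (lens[k] > best_len ||
          (lens[k] == best_len && !is.na(best_start) &&
             gstart < best_start)) {
        best_len <- lens[k]
        best_start <- gstart
      }
    }
  }
  list(orf_length = best_len,
       orf_coverage = best_len / n,
       orf_start = best_start)
}

fickett_lookup <- function(value, para, prob) {
  idx <- which(value >= para)[1]
  prob[idx]
}

#' Fickett TESTCODE statistic
#'
#' For each base, the position parameter is the maximum of its counts at
#' the three codon positions divided by (minimum + 1), and the content
#' parameter is its overall fraction; both are mapped through the published
#' probability tables and combined with the published weights. Bases other
#' than A/C/G/T are ignored in the counts. Sequences shorter than 6 nt get
#' the minimum attainable score.
#'
#' @param seq A single nucleotide string (or `DNAString`).
#' @param detail If `TRUE`, also return the per-base position and content
#'   parameters.
#' @return The TESTCODE score (numeric scalar), or a list when
#'   `detail = TRUE`.
#' @export
fickett_score <- function(seq, detail = FALSE) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  tb <- .fickett
  if (n < 6L) {
    min_score <- sum(vapply(c("A", "C", "G", "T"), function(b) {
      min(tb$position_prob[[b]]) * tb$position_weight[[b]] +
        min(tb$content_prob[[b]]) * tb$content_weight[[b]]
    }, numeric(1)))
    return(if (detail) list(score = min_score, position = NULL,
                            content = NULL) else min_score)
  }
  phase <- rep_len(1:3, n)
  score <- 0
  pos_par <- con_par <- c(A = NA_real_, C = NA_real_, G = NA_real_,
                          T = NA_real_)
  total <- sum(bases %in% c("A", "C", "G", "T"))
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(1:3, function(p) sum(bases == b & phase == p),
                  numeric(1))
    ppar <- max(cnt) / (min(cnt) + 1)
    cpar <- if (total > 0) sum(cnt) / total else 0
    pos_par[b] <- ppar
    con_par[b] <- cpar
    score <- score +
      fickett_lookup(ppar, tb$position_para, tb$position_prob[[b]]) *
        tb$position_weight[[b]] +
      fickett_lookup(cpar, tb$content_para, tb$content_prob[[b]]) *
        tb$content_weight[[b]]
  }
  if (detail) list(score = score, position = pos_par, content = con_par)
  else score
}

#' Train a hexamer usage-bias table
#'
#' Log-odds of hexamer frequencies between a coding and a noncoding
#' training corpus: `log(f_coding(h) / f_noncoding(h))` over all 4096
#' hexamers. Frequencies are smoothed on the frequency scale (mixed with
#' the uniform hexamer distribution, `pseudocount / 4096` added to each
#' relative frequency), which keeps the table finite, makes it invariant
#' to duplicating a corpus, zero for identical corpora, and antisymmetric
#' under swapping the corpora. Windows containing non-ACGT bases are
#' skipped.
#'
#' @param coding_seqs,noncoding_seqs `DNAStringSet` (or character vectors)
#'   of training sequences; both must be non-empty.
#' @param pseudocount Positive pseudocount added to every hexamer count.
#' @return A named numeric vector of length 4096 (class `hexamer_table`).
#' @export
train_hexamer_table <- function(coding_seqs, noncoding_seqs,
                                pseudocount = 1) {
  if (length(coding_seqs) == 0L || length(noncoding_seqs) == 0L) {
    stop("both training corpora must be non-empty")
  }
  stopifnot(pseudocount > 0)
  count6 <- function(seqs) {
    if (!methods::is(seqs, "DNAStringSet")) {
      seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
    }
    colSums(Biostrings::oligonucleotideFrequency(seqs, width = 6,
                                                 step = 1))
  }
  cc <- count6(coding_seqs)
  cn <- count6(noncoding_seqs)
  eps <- pseudocount / 4096
  tab <- log((cc / sum(cc) + eps) / (cn / sum(cn) + eps))
  class(tab) <- c("hexamer_table", class(tab))
  tab
}

#' Mean in-frame hexamer log-odds over the longest ORF
#'
#' Walks the longest ORF in codon steps and averages the table entries of
#' the hexamers starting at each codon position. Transcripts with no ORF
#' (or an ORF too short to hold a hexamer) score 0; windows containing
#' non-ACGT bases are skipped.
#'
#' @param seq A single nucleotide string.
#' @param table A table from [train_hexamer_table()].
#' @param orf Optional precomputed result of [find_longest_orf()].
#' @return Numeric scalar.
#' @export
hexamer_feature <- function(seq, table, orf = NULL) {
  seq <- toupper(as.character(seq))
  if (is.null(orf)) orf <- find_longest_orf(seq)
  if (orf$orf_length < 6L) return(0)
  pos <- seq(orf$orf_start, orf$orf_start + orf$orf_length - 6L, by = 3L)
  hex <- substring(seq, pos, pos + 5L)
  vals <- unname(table[hex])
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(0)
  mean(vals)
}

#' Coding-potential feature vector
#'
#' The four features the logistic combiner uses: `log1p(orf_length)`,
#' `orf_coverage`, the Fickett TESTCODE score, and the mean in-frame
#' hexamer log-odds over the longest ORF.
#'
#' @param seqs A `DNAStringSet` or character vector of sequences.
#' @param table A [train_hexamer_table()] table.
#' @return A data.frame with columns `orf_length`, `orf_coverage`,
#'   `orf_log_length`, `fickett`, `hexamer`, one row per sequence.
#' @export
coding_features <- function(seqs, table) {
  chr <- toupper(as.character(seqs))
  n <- length(chr)
  out <- data.frame(orf_length = integer(n), orf_coverage = numeric(n),
                    orf_log_length = numeric(n), fickett = numeric(n),
                    hexamer = numeric(n))
  for (i in seq_len(n)) {
    orf <- find_longest_orf(chr[i])
    out$orf_length[i] <- orf$orf_length
    out$orf_coverage[i] <- orf$orf_coverage
    out$orf_log_length[i] <- log1p(orf$orf_length)
    out$fickett[i] <- fickett_score(chr[i])
    out$hexamer[i] <- hexamer_feature(chr[i], table, orf = orf)
  }
  if (!is.null(names(seqs))) rownames(out) <- names(seqs)
  out
}

# Ridge-penalized logistic regression by iteratively reweighted least
# squares. Used as the deterministic fallback when the unpenalized fit
# separates perfectly; the intercept is not penalized.
ridge_logistic <- function(x, y, lambda = 1e-2, maxit = 100,
                           tol = 1e-10) {
  x <- cbind(`(Intercept)` = 1, as.matrix(x))
  p <- ncol(x)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtw <- t(x * w)
    beta_new <- solve(xtw %*% x + pen, xtw %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  stats::setNames(drop(beta), colnames(x))
}

#' Fit the logistic combiner
#'
#' Maximum-likelihood logistic regression of the coding label on the
#' feature columns via `stats::glm`. If the likelihood degenerates
#' (perfect separation, non-convergence, or runaway coefficients), the fit
#' falls back to a ridge-penalized IRLS solution, which is deterministic
#' and finite for any separable data.
#'
#' @param features A data.frame or matrix of finite numeric features.
#' @param labels Binary vector (1 = coding, 0 = noncoding); both classes
#'   must be present.
#' @param ridge_lambda Penalty used by the fallback.
#' @return Named numeric coefficient vector (intercept first), with
#'   attribute `method` (`"glm"` or `"ridge"`).
#' @export
train_classifier <- function(features, labels, ridge_lambda = 1e-2) {
  x <- as.matrix(features)
  y <- as.numeric(labels)
  stopifnot(all(y %in% c(0, 1)), all(is.finite(x)))
  if (length(unique(y)) < 2L) stop("both labels must be present")
  dat <- data.frame(y = y, x)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  coefs <- stats::coef(fit)
  if (sep || anyNA(coefs) || max(abs(coefs)) > 15) {
    coefs <- ridge_logistic(x, y, lambda = ridge_lambda)
    attr(coefs, "method") <- "ridge"
  } else {
    names(coefs) <- c("(Intercept)", colnames(x))
    attr(coefs, "method") <- "glm"
  }
  coefs
}

#' Train a coding-potential model
#'
#' Builds the hexamer table from the two training corpora, computes the
#' feature vectors, and fits the logistic combiner. The resulting signed
#' score is a logistic log-odds of coding: score < 0 is equivalent to
#' coding probability < 0.5 and yields the noncoding verdict.
#'
#' @param coding_seqs,noncoding_seqs Training sequences (`DNAStringSet` or
#'   character).
#' @param pseudocount Hexamer pseudocount.
#' @param ridge_lambda Fallback ridge penalty for the combiner.
#' @return An object of class `coding_potential_model` holding the hexamer
#'   table and combiner coefficients.
#' @export
train_coding_model <- function(coding_seqs, noncoding_seqs,
                               pseudocount = 1, ridge_lambda = 1e-2) {
  tab <- train_hexamer_table(coding_seqs, noncoding_seqs,
                             pseudocount = pseudocount)
  feats <- rbind(coding_features(coding_seqs, tab),
                 coding_features(noncoding_seqs, tab))
  labels <- rep(c(1, 0), c(length(coding_seqs), length(noncoding_seqs)))
  cols <- c("orf_log_length", "orf_coverage", "fickett", "hexamer")
  coefs <- train_classifier(feats[, cols], labels,
                            ridge_lambda = ridge_lambda)
  structure(list(hexamer_table = tab, coefficients = coefs,
                 feature_names = cols),
            class = "coding_potential_model")
}

#' @export
print.coding_potential_model <- function(x, ...) {
  cat("coding_potential_model (", attr(x$coefficients, "method"),
      " fit)\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Score transcripts for coding potential
#'
#' Applies a trained model to each sequence, returning the signed combined
#' score and the noncoding verdict. The decision contract is strict:
#' `is_noncoding` is `TRUE` exactly when `score < 0`; a score of exactly 0
#' is not called noncoding.
#'
#' @param seqs A named `DNAStringSet` or character vector.
#' @param model A [train_coding_model()] model.
#' @return A data.frame with columns `transcript_id`, `orf_length`,
#'   `orf_coverage`, `fickett`, `hexamer`, `score`, `is_noncoding`.
#' @export
score_transcripts <- function(seqs, model) {
  stopifnot(inherits(model, "coding_potential_model"))
  feats <- coding_features(seqs, model$hexamer_table)
  x <- cbind(1, as.matrix(feats[, model$feature_names, drop = FALSE]))
  score <- drop(x %*% as.numeric(model$coefficients))
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(score))
  data.frame(transcript_id = ids,
             orf_length = feats$orf_length,
             orf_coverage = feats$orf_coverage,
             fickett = feats$fickett,
             hexamer = feats$hexamer,
             score = score,
             is_noncoding = score < 0,
             stringsAsFactors = FALSE)
}

#' Serialize / restore a coding-potential model as JSON
#'
#' @param model A `coding_potential_model`.
#' @param path File path.
#' @return `read_coding_model` returns the model; `write_coding_model`
#'   returns `path` invisibly.
#' @export
write_coding_model <- function(model, path) {
  stopifnot(inherits(model, "coding_potential_model"))
  obj <- list(
    coefficients = as.list(stats::setNames(as.numeric(model$coefficients),
                                           names(model$coefficients))),
    fit_method = attr(model$coefficients, "method"),
    feature_names = model$feature_names,
    hexamer_table = as.list(stats::setNames(as.numeric(model$hexamer_table),
                                            names(model$hexamer_table)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coding_model
#' @export
read_coding_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- unlist(obj$coefficients)
  attr(coefs, "method") <- obj$fit_method
  tab <- unlist(obj$hexamer_table)
  class(tab) <- c("hexamer_table", class(tab))
  structure(list(hexamer_table = tab, coefficients = coefs,
                 feature_names = obj$feature_names),
            class = "coding_potential_model")
}
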
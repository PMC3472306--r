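#' Position weight matrix
#'
#' Constructs a PWM from a 4 x n matrix of per-position base frequencies
#' (rows A, C, G, T). Per-position information content is computed against the
#' background distribution as `C_j = sum_i f_ij * log2(f_ij / P_i)` with the
#' convention `0 * log(0) = 0`.
#'
#' @param freq 4 x n numeric matrix of frequencies; columns must sum to 1.
#' @param background base probabilities (A, C, G, T) of the background model;
#'   default uniform.
#' @return an object of class `pwm`: a list with `freq`, `background`, `ic`
#'   (per-position information content) and `length`.
#' @export
pwm <- function(freq, background = rep(0.25, 4)) {
  freq <- as.matrix(freq)
  if (nrow(freq) != 4) stop("freq must have 4 rows (A, C, G, T)", call. = FALSE)
  rownames(freq) <- DNA_BASES
  if (any(freq < 0) || any(abs(colSums(freq) - 1) > 1e-6)) {
    stop("PWM columns must be non-negative and sum to 1", call. = FALSE)
  }
  freq <- sweep(freq, 2, colSums(freq), "/")
  background <- as.numeric(background)
  if (length(background) != 4 || any(background < 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("background must be 4 probabilities summing to 1", call. = FALSE)
  }
  structure(
    list(freq = freq, background = background,
         ic = information_content_(freq, background), length = ncol(freq)),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM of length", x$length, "| total information",
      round(sum(x$ic), 3), "bits\n")
  print(round(x$freq, 3))
  invisible(x)
}

information_content_ <- function(freq, background) {
  if (any(background == 0 & rowSums(freq) > 0)) {
    stop("background probability 0 for a base with non-zero frequency",
         call. = FALSE)
  }
  ratio <- freq / background
  term <- ifelse(freq > 0, freq * log2(ratio), 0)
  colSums(term)
}

#' Per-position information content of a PWM
#'
#' @param x a [pwm] object.
#' @return numeric vector `C_j`, one value per position (bits).
#' @export
information_content <- function(x) {
  stopifnot(inherits(x, "pwm"))
  x$ic
}

#' Consensus sequence of a PWM
#'
#' @param x a [pwm] object.
#' @return the string of per-position most-frequent bases (ties broken
#'   alphabetically).
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(DNA_BASES[apply(x$freq, 2, which.max)], collapse = "")
}

strand_score_ <- function(idx, x) sum(x$freq[cbind(idx, seq_along(idx))] * x$ic)

#' Sequence feature of a DNA segment
#'
#' Scores a segment against a PWM as the information-content-weighted sum of
#' observed-base frequencies, `sum_j f(b_j, j) * C_j`. Both strands are scored
#' (the reverse complement against the same PWM) and the higher value is
#' returned. The value is the raw, unnormalized sum.
#'
#' @param segment DNA string of the same length as the PWM.
#' @param x a [pwm] object.
#' @return the double-strand maximum score.
#' @export
sequence_score <- function(segment, x) {
  stopifnot(inherits(x, "pwm"))
  if (nchar(segment) != x$length) {
    stop("segment length (", nchar(segment), ") != PWM length (", x$length,
         ")", call. = FALSE)
  }
  fwd <- seq_to_index(segment)
  rev <- 5L - rev(fwd) # reverse complement in index space (A<->T, C<->G)
  max(strand_score_(fwd, x), strand_score_(rev, x))
}

#' Best-window sequence feature of a segment of arbitrary length
#'
#' When the segment is longer than the PWM, all windows of PWM length are
#' scored and the maximum is returned; segments shorter than the PWM are an
#' error.
#'
#' @inheritParams sequence_score
#' @param score_fun scoring function taking (segment, pwm); defaults to
#'   [sequence_score()].
#' @return the best window score.
#' @export
scan_sequence_score <- function(segment, x, score_fun = sequence_score) {
  n <- nchar(segment)
  if (n < x$length) {
    stop("segment shorter than PWM (", n, " < ", x$length, ")", call. = FALSE)
  }
  if (n == x$length) return(score_fun(segment, x))
  starts <- seq_len(n - x$length + 1)
  max(vapply(starts, function(s) {
    score_fun(substr(segment, s, s + x$length - 1), x)
  }, numeric(1)))
}

#' Match-style normalized PWM similarity
#'
#' Min-max-normalized matrix similarity, as used by PWM matching tools:
#' `(Current - Min) / (Max - Min)`, where `Current = sum_j C_j * f(b_j, j)`,
#' and `Min`/`Max` are the scores of the per-position least/most frequent
#' bases. Both strands are evaluated and the higher normalized value is
#' returned. When the PWM is completely uninformative (`Max == Min`) the
#' similarity is defined as 1.
#'
#' @inheritParams sequence_score
#' @return similarity in \[0, 1\].
#' @export
match_similarity_score <- function(segment, x) {
  stopifnot(inherits(x, "pwm"))
  if (nchar(segment) != x$length) {
    stop("segment length (", nchar(segment), ") != PWM length (", x$length,
         ")", call. = FALSE)
  }
  smin <- sum(apply(x$freq, 2, min) * x$ic)
  smax <- sum(apply(x$freq, 2, max) * x$ic)
  if (smax - smin <= 0) return(1.0)
  fwd <- seq_to_index(segment)
  rev <- 5L - rev(fwd)
  cur <- max(strand_score_(fwd, x), strand_score_(rev, x))
  (cur - smin) / (smax - smin)
}

#' Structure feature of a DNA segment for one attribute
#'
#' The mean of the attribute's empirical dinucleotide values over the n - 1
#' overlapping dinucleotides of the segment, computed on the given orientation
#' (no strand flip).
#'
#' @param segment DNA string, length >= 2.
#' @param table a `dinuc_table` (see [read_property_table()]).
#' @param attribute attribute (row) name.
#' @return the mean empirical value.
#' @export
structure_score <- function(segment, table, attribute) {
  if (!attribute %in% rownames(table)) {
    stop("unknown attribute: ", attribute, call. = FALSE)
  }
  unname(structure_matrix(segment, table)[1, attribute])
}

#' Structure feature vector of a DNA segment
#'
#' [structure_score()] applied to every attribute of the table, in table
#' order.
#'
#' @inheritParams structure_score
#' @return named numeric vector, one value per attribute.
#' @export
structure_vector <- function(segment, table) {
  structure_matrix(segment, table)[1, ]
}

#' Structure feature matrix for many segments
#'
#' @param segments character vector of DNA strings (each length >= 2; equal
#'   lengths are not required).
#' @param table a `dinuc_table`.
#' @return numeric matrix, one row per segment, one column per attribute.
#' @export
structure_matrix <- function(segments, table) {
  if (any(nchar(segments) < 2)) {
    stop("structure feature requires segments of length >= 2", call. = FALSE)
  }
  dinucs <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  vals <- table[, dinucs, drop = FALSE]
  out <- matrix(NA_real_, nrow = length(segments), ncol = nrow(table),
                dimnames = list(NULL, rownames(table)))
  for (i in seq_along(segments)) {
    idx <- seq_to_index(segments[i])
    n <- length(idx)
    di <- idx[-n] + (idx[-1L] - 1L) * 4L # position in the outer() dinuc order
    out[i, ] <- rowMeans(vals[, di, drop = FALSE])
  }
  out
}

#' Ungapped similarity of a segment to an IUPAC consensus
#'
#' The shorter of the two strings is slid without gaps along the longer; at
#' each offset the fraction of positions where the segment base is compatible
#' with the consensus IUPAC code is computed. Both strands of the segment are
#' scanned. The best fraction over all offsets and strands is returned.
#'
#' @param segment DNA string (A/C/G/T).
#' @param consensus IUPAC consensus string.
#' @return similarity in \[0, 1\].
#' @export
motif_similarity <- function(segment, consensus) {
  motif_best_similarity(seq_to_bits(segment),
                        list(seq_to_bits(toupper(consensus))))[1]
}

#' Evolution feature of a DNA segment
#'
#' The maximal conservation score among catalog motifs whose
#' [motif_similarity()] with the segment reaches the catalog's similarity
#' threshold; 0 if no motif matches (or the catalog is empty).
#'
#' @param segment DNA string.
#' @param catalog a [motif_catalog].
#' @return the evolution feature (>= 0).
#' @export
evolution_score <- function(segment, catalog) {
  evolution_scores(segment, catalog)
}

#' Evolution features for many segments
#'
#' @param segments character vector of DNA strings.
#' @param catalog a [motif_catalog].
#' @return numeric vector of evolution features.
#' @export
evolution_scores <- function(segments, catalog) {
  stopifnot(inherits(catalog, "motif_catalog"))
  if (nrow(catalog) == 0) return(rep(0, length(segments)))
  motif_bits <- lapply(catalog$consensus, seq_to_bits)
  threshold <- attr(catalog, "threshold")
  vapply(segments, function(s) {
    sims <- motif_best_similarity(seq_to_bits(s), motif_bits)
    hits <- sims >= threshold - 1e-12
    if (any(hits)) max(catalog$score[hits]) else 0
  }, numeric(1), USE.NAMES = FALSE)
}

#' Assemble the per-instance feature block
#'
#' Computes, for every instance of a set, the sequence feature (when a PWM is
#' available), the structure feature vector (one column per table attribute)
#' and the evolution feature, in that fixed column order. With the default
#' 38-attribute table and a PWM this yields the canonical 40-column block;
#' without a PWM the sequence column is omitted (the no-PWM regime). Instances
#' whose length differs from the PWM length are scanned and the best-scoring
#' window is used for the sequence feature.
#'
#' @param instances instance-set data frame with columns `instance_id`,
#'   `label`, `sequence` (see [assemble_instance_sets()]).
#' @param x a [pwm] or `NULL`.
#' @param table a `dinuc_table`.
#' @param catalog a [motif_catalog].
#' @return `instances` with feature columns appended (`sequence_feature`,
#'   then one column per structure attribute, then `evolution_feature`).
#' @export
featurize <- function(instances, x = NULL, table, catalog) {
  segs <- instances$sequence
  if (any(nchar(segs) < 2)) {
    stop("instances shorter than 2 nt cannot be featurized", call. = FALSE)
  }
  blocks <- list()
  if (!is.null(x)) {
    blocks$sequence_feature <- vapply(segs, scan_sequence_score, numeric(1),
                                      x = x, USE.NAMES = FALSE)
  }
  sm <- structure_matrix(segs, table)
  ev <- evolution_scores(segs, catalog)
  out <- cbind(instances,
               as.data.frame(c(blocks, as.data.frame(sm),
                               list(evolution_feature = ev))))
  rownames(out) <- NULL
  out
}

#' Names of the feature columns in a featurized instance set
#'
#' @param featurized output of [featurize()].
#' @return character vector of feature column names, in canonical order.
#' @export
feature_columns <- function(featurized) {
  setdiff(names(featurized), c("set_id", "instance_id", "label", "sequence"))
}
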
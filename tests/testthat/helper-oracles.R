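# Independent brute-force oracles and tiny fixture builders. Everything here
# is written straight from the defining formulas, independent of the package's
# implementation paths.

DNA <- c("A", "C", "G", "T")

random_pwm <- function(n, seed) {
  withr::with_seed(seed, {
    freq <- matrix(stats::rexp(4 * n), nrow = 4)
    freq <- sweep(freq, 2, colSums(freq), "/")
    pwm(freq)
  })
}

all_kmers <- function(k) {
  apply(expand.grid(rep(list(DNA), k)), 1, paste, collapse = "")
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Eq-style sequence score: straight double loop over positions and strands.
oracle_sequence_score <- function(segment, x) {
  ic <- x$ic
  score_one <- function(s) {
    b <- strsplit(s, "")[[1]]
    total <- 0
    for (j in seq_along(b)) total <- total + x$freq[b[j], j] * ic[j]
    total
  }
  max(score_one(segment), score_one(oracle_revcomp(segment)))
}

oracle_match_score <- function(segment, x) {
  ic <- x$ic
  smin <- 0; smax <- 0
  for (j in seq_len(x$length)) {
    smin <- smin + min(x$freq[, j]) * ic[j]
    smax <- smax + max(x$freq[, j]) * ic[j]
  }
  if (smax == smin) return(1)
  cur <- oracle_sequence_score(segment, x)
  (cur - smin) / (smax - smin)
}

oracle_structure_score <- function(segment, table, attribute) {
  b <- strsplit(segment, "")[[1]]
  vals <- numeric(length(b) - 1)
  for (j in seq_len(length(b) - 1)) {
    vals[j] <- table[attribute, paste0(b[j], b[j + 1])]
  }
  mean(vals)
}

iupac_match_oracle <- function(base, code) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  base %in% sets[[code]]
}

oracle_motif_similarity <- function(segment, consensus) {
  best <- 0
  for (seg in c(segment, oracle_revcomp(segment))) {
    s <- strsplit(seg, "")[[1]]
    m <- strsplit(consensus, "")[[1]]
    if (length(m) <= length(s)) { long <- s; short <- m; short_is_motif <- TRUE }
    else { long <- m; short <- s; short_is_motif <- FALSE }
    for (off in 0:(length(long) - length(short))) {
      hits <- 0
      for (j in seq_along(short)) {
        a <- long[off + j]; b <- short[j]
        ok <- if (short_is_motif) iupac_match_oracle(a, b) else
          iupac_match_oracle(b, a)
        hits <- hits + ok
      }
      best <- max(best, hits / length(short))
    }
  }
  best
}

# O(n^2) pair-counting AUC.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

tiny_property_table <- function(values) {
  dinucs <- as.vector(outer(DNA, DNA, paste0))
  m <- matrix(values, nrow = length(values) %/% 16, ncol = 16, byrow = TRUE,
              dimnames = list(paste0("attr", seq_len(length(values) %/% 16)),
                              dinucs))
  class(m) <- c("dinuc_table", class(m))
  m
}

random_property_table <- function(n_attr, seed) {
  withr::with_seed(seed,
    tiny_property_table(round(stats::runif(16 * n_attr, -5, 5), 3)))
}

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}
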
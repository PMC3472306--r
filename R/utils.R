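DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8)
IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

AA_LETTERS <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a deterministic sub-seed (< 2^31) from a master seed and stream index.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 65521) + 1
  as.integer((s * 20011 + as.double(k) * 7919) %% 2147483629) + 1L
}

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings (IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  flipped <- chartr("ACGTRYSWKMBDHVacgtryswkmbdhv",
                    "TGCAYRSWMKVHDBtgcayrswmkvhdb", x)
  vapply(flipped, function(s) {
    paste(rev(split_chars(s)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

seq_to_index <- function(s) {
  idx <- match(split_chars(s), DNA_BASES)
  if (anyNA(idx)) {
    stop("non-ACGT character in DNA segment: ", s, call. = FALSE)
  }
  idx
}

seq_to_bits <- function(s) {
  bits <- unname(IUPAC_BITS[split_chars(s)])
  if (anyNA(bits)) {
    stop("non-IUPAC character in string: ", s, call. = FALSE)
  }
  as.integer(bits)
}

is_dna <- function(x) !grepl("[^ACGT]", x)

is_iupac <- function(x) !grepl("[^ACGTRYSWKMBDHVN]", x)

is_protein <- function(x) {
  !grepl(paste0("[^", paste(AA_LETTERS, collapse = ""), "]"), x)
}
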
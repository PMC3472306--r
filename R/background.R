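#' Fit a k-th order Markov chain to promoter sequences
#'
#' Estimates transition probabilities `P(next base | preceding k-mer)` from
#' training sequences with add-`pseudocount` smoothing, and the initial
#' distribution over k-mers from the observed k-mer frequencies. The fitted
#' chain is the background model used to synthesize promoter-like pseudo
#' sequences for negative-instance construction.
#'
#' @param promoters character vector of DNA training sequences.
#' @param order Markov order (context length), default 3.
#' @param pseudocount additive smoothing count, default 1 (contexts never seen
#'   then fall back to a uniform next-base distribution).
#' @return an object of class `markov_model`.
#' @export
fit_markov <- function(promoters, order = 3, pseudocount = 1) {
  if (length(promoters) == 0 || sum(nchar(promoters)) <= order) {
    stop("training set empty or shorter than the model order", call. = FALSE)
  }
  n_ctx <- 4L^order
  counts <- matrix(0, nrow = n_ctx, ncol = 4)
  init_counts <- numeric(n_ctx)
  pow <- 4L^((order - 1):0)
  for (s in promoters) {
    idx <- seq_to_index(s)
    n <- length(idx)
    if (n <= order) next
    # rolling base-4 context index (1-based)
    ctx <- rep(1L, n - order)
    for (k in seq_len(order)) {
      ctx <- ctx + (idx[k:(n - order + k - 1)] - 1L) * pow[k]
    }
    nxt <- idx[(order + 1):n]
    for (b in 1:4) {
      sel <- nxt == b
      if (any(sel)) {
        t <- tabulate(ctx[sel], nbins = n_ctx)
        counts[, b] <- counts[, b] + t
      }
    }
    init_counts <- init_counts + tabulate(ctx, nbins = n_ctx)
  }
  counts <- counts + pseudocount
  totals <- rowSums(counts)
  trans <- counts
  seen <- totals > 0
  trans[seen, ] <- counts[seen, ] / totals[seen]
  trans[!seen, ] <- 0.25
  init <- if (sum(init_counts) > 0) init_counts / sum(init_counts) else
    rep(1 / n_ctx, n_ctx)
  structure(list(order = as.integer(order), transition = trans,
                 initial = init, pseudocount = pseudocount),
            class = "markov_model")
}

context_to_string <- function(ctx_index, order) {
  # inverse of the rolling base-4 encoding used in fit_markov
  x <- ctx_index - 1L
  out <- character(order)
  for (k in order:1) {
    out[k] <- DNA_BASES[x %% 4L + 1L]
    x <- x %/% 4L
  }
  paste(out, collapse = "")
}

#' Transition probability of a fitted Markov model
#'
#' @param model a `markov_model`.
#' @param context k-mer context string (k = model order).
#' @param base next base, one of A/C/G/T.
#' @return the smoothed transition probability.
#' @export
markov_transition <- function(model, context, base) {
  stopifnot(inherits(model, "markov_model"))
  idx <- seq_to_index(context)
  if (length(idx) != model$order) {
    stop("context length must equal the model order", call. = FALSE)
  }
  pow <- 4L^((model$order - 1):0)
  ctx <- 1L + sum((idx - 1L) * pow)
  model$transition[ctx, match(base, DNA_BASES)]
}

#' Generate a pseudo promoter sequence from a fitted Markov model
#'
#' Samples an initial k-mer from the model's k-mer distribution and extends it
#' base by base from the transition distributions until the requested length
#' is reached.
#'
#' @param model a `markov_model`.
#' @param length sequence length, default 5000 (5 kb pseudo sequences).
#' @param seed integer seed; generation is reproducible under a fixed seed.
#' @return a DNA string of exactly `length` characters.
#' @export
generate_pseudo_sequence <- function(model, length = 5000, seed = 1) {
  stopifnot(inherits(model, "markov_model"))
  order <- model$order
  if (length < order) stop("length must be >= model order", call. = FALSE)
  cum_trans <- t(apply(model$transition, 1, cumsum))
  with_seed(seed, {
    ctx <- sample.int(length(model$initial), 1, prob = model$initial)
    out <- integer(length)
    start <- seq_to_index(context_to_string(ctx, order))
    out[seq_len(order)] <- start
    u <- stats::runif(length)
    mod <- 4L^(order - 1L)
    for (i in (order + 1):length) {
      b <- findInterval(u[i], cum_trans[ctx, ], left.open = TRUE) + 1L
      out[i] <- b
      ctx <- ((ctx - 1L) %% mod) * 4L + b
    }
    paste(DNA_BASES[out], collapse = "")
  })
}

#' Build a pool of negative instances
#'
#' Generates pseudo promoter sequences from the background model and cuts each
#' into consecutive non-overlapping windows of exactly `window` nucleotides
#' (the trailing remainder is discarded). The window is normally the average
#' positive-instance length of the TF under study, rounded to the nearest
#' integer.
#'
#' @param model a `markov_model`.
#' @param window window length in nt (>= 2, <= `seq_length`).
#' @param n_sequences number of pseudo sequences to cut.
#' @param seed integer seed.
#' @param seq_length pseudo-sequence length, default 5000.
#' @return character vector of negative segments, deterministic under `seed`.
#' @export
build_negative_pool <- function(model, window, n_sequences = 10, seed = 1,
                                seq_length = 5000) {
  window <- as.integer(round(window))
  if (window < 2) stop("window must be >= 2", call. = FALSE)
  if (window > seq_length) {
    stop("window (", window, ") exceeds pseudo-sequence length (", seq_length,
         ")", call. = FALSE)
  }
  pool <- character(0)
  for (i in seq_len(n_sequences)) {
    s <- generate_pseudo_sequence(model, seq_length, seed = derive_seed(seed, i))
    k <- seq_length %/% window
    starts <- (seq_len(k) - 1L) * window + 1L
    pool <- c(pool, substring(s, starts, starts + window - 1L))
  }
  pool
}

#' Assemble balanced instance sets
#'
#' Builds `n_sets` balanced sets, each containing all positive instances of a
#' TF plus an equal number of negatives drawn at random from the pool (without
#' replacement within a set; draws are independent across sets).
#'
#' @param positives character vector of positive (verified TFBS) segments.
#' @param pool character vector of negative segments
#'   (see [build_negative_pool()]).
#' @param n_sets number of balanced sets, default 10.
#' @param seed integer seed.
#' @param tf_id optional TF identifier used in instance ids.
#' @return list of `n_sets` data frames with columns `set_id`, `instance_id`,
#'   `label` (1 positive / 0 negative), `sequence`.
#' @export
assemble_instance_sets <- function(positives, pool, n_sets = 10, seed = 1,
                                   tf_id = "TF") {
  n_pos <- length(positives)
  if (n_pos == 0) stop("no positive instances", call. = FALSE)
  if (length(pool) < n_pos) {
    stop("negative pool too small: have ", length(pool), ", need at least ",
         n_pos, call. = FALSE)
  }
  lapply(seq_len(n_sets), function(k) {
    neg <- with_seed(derive_seed(seed, k),
                     sample(pool, n_pos, replace = FALSE))
    data.frame(
      set_id = sprintf("%s_set%02d", tf_id, k),
      instance_id = c(sprintf("%s_pos%03d", tf_id, seq_len(n_pos)),
                      sprintf("%s_set%02d_neg%03d", tf_id, k, seq_len(n_pos))),
      label = rep(c(1L, 0L), each = n_pos),
      sequence = c(positives, neg),
      stringsAsFactors = FALSE
    )
  })
}
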
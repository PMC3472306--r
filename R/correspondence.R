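align_link_matrix <- function(seqs, moltype, coverage, identity) {
  n <- length(seqs)
  link <- matrix(FALSE, n, n)
  if (n < 2) return(link)
  if (moltype == "protein") {
    submat <- get(utils::data("BLOSUM62", package = "Biostrings",
                              envir = environment()))
    gap_open <- 11; gap_ext <- 1
    set <- Biostrings::AAStringSet(seqs)
  } else {
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                       mismatch = -2,
                                                       baseOnly = TRUE)
    gap_open <- 5; gap_ext <- 2
    set <- Biostrings::DNAStringSet(seqs)
  }
  len <- nchar(seqs)
  for (i in seq_len(n - 1)) {
    idx <- (i + 1):n
    aln <- Biostrings::pairwiseAlignment(
      set[idx], set[[i]], type = "local", substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_ext
    )
    pat <- Biostrings::pattern(aln)
    sub <- Biostrings::subject(aln)
    cov_p <- (Biostrings::end(pat) - Biostrings::start(pat) + 1) / len[idx]
    cov_s <- (Biostrings::end(sub) - Biostrings::start(sub) + 1) / len[i]
    ident <- Biostrings::pid(aln, type = "PID1")
    ok <- cov_p >= coverage & cov_s >= coverage & ident >= identity
    link[i, idx] <- ok
    link[idx, i] <- ok
  }
  link
}

components_ <- function(link) {
  n <- nrow(link)
  comp <- integer(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1
    queue <- i
    comp[i] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(link[v, ] & comp == 0)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Cluster sequences by pairwise local-alignment similarity
#'
#' Single-linkage clustering in the style of blastclust: two sequences are
#' linked when a local alignment covers at least fraction `coverage` of BOTH
#' sequences and has at least `identity` percent identical columns. Protein
#' sequences are aligned with BLOSUM62 (gap open 11 / extend 1); DNA with
#' +1/-2 match/mismatch (gap open 5 / extend 2). Identical sequences are
#' collapsed before alignment, so large sets of duplicated segments cluster
#' quickly. Exact agreement with the NCBI binary is not promised; the -L/-S
#' semantics are.
#'
#' @param records data frame with columns `id`, `sequence`, `moltype`
#'   (homogeneous).
#' @param coverage length-coverage threshold L in (0, 1].
#' @param identity identity threshold S in percent, in (0, 100].
#' @return an object of class `cluster_set`: list with `clusters` (list of
#'   member-id character vectors, ordered by first appearance) and `params`.
#' @export
cluster_sequences <- function(records, coverage, identity) {
  if (nrow(records) == 0) stop("no sequences to cluster", call. = FALSE)
  moltype <- unique(records$moltype)
  if (length(moltype) != 1) {
    stop("records must have a single moltype", call. = FALSE)
  }
  if (coverage <= 0 || coverage > 1) {
    stop("coverage must be in (0, 1]", call. = FALSE)
  }
  if (identity <= 0 || identity > 100) {
    stop("identity must be in (0, 100]", call. = FALSE)
  }
  uniq <- unique(records$sequence)
  link <- align_link_matrix(uniq, moltype, coverage, identity)
  comp_u <- components_(link)
  comp <- comp_u[match(records$sequence, uniq)]
  clusters <- split(records$id, comp)
  # order clusters by first appearance in the input
  first <- vapply(clusters, function(ids) {
    min(match(ids, records$id))
  }, numeric(1))
  clusters <- unname(clusters[order(first)])
  structure(list(clusters = clusters,
                 params = list(coverage = coverage, identity = identity)),
            class = "cluster_set")
}

as_cluster_list <- function(x) {
  if (inherits(x, "cluster_set")) x$clusters else x
}

#' Intersection rate between two sets
#'
#' `|A intersect B| / |A union B|` — the cluster-matching statistic used for
#' TF-to-TFBS correspondence.
#'
#' @param a,b character vectors (treated as sets).
#' @return rate in \[0, 1\]; 1 iff the sets are equal.
#' @export
intersection_rate <- function(a, b) {
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / length(union(a, b))
}

#' Match TF clusters against TF-name-rewritten TFBS clusters
#'
#' Each TFBS cluster is rewritten as the set of TF names owning its members.
#' A TF cluster counts as matched when, for some rewritten cluster, either
#' (a) more than 90% of the TF cluster's members are contained in it, or
#' (b) the intersection rate exceeds 2/3. The match rate is the fraction of
#' matched TF clusters. A one-sided Fisher test of association between TF
#' co-clustering and TFBS co-clustering is computed over all unordered TF
#' pairs (2x2 table of same-TF-cluster vs co-occurring in at least one
#' rewritten TFBS cluster).
#'
#' @param tf_clusters a `cluster_set` (or plain list) of TF id clusters.
#' @param tfbs_clusters a `cluster_set` (or plain list) of TFBS id clusters.
#' @param tf_of_tfbs named character vector mapping every TFBS id to its TF id.
#' @param containment containment threshold for criterion (a), default 0.9.
#' @param min_rate intersection-rate threshold for criterion (b), default 2/3.
#' @return list of class `match_report`: `n_tf_clusters`, `n_tfbs_clusters`,
#'   `n_matching`, `match_rate`, `fisher_odds`, `fisher_p`.
#' @export
transform_and_match <- function(tf_clusters, tfbs_clusters, tf_of_tfbs,
                                containment = 0.9, min_rate = 2 / 3) {
  tfc <- as_cluster_list(tf_clusters)
  bsc <- as_cluster_list(tfbs_clusters)
  unmapped <- setdiff(unique(unlist(bsc)), names(tf_of_tfbs))
  if (length(unmapped) > 0) {
    stop("TFBS id without a TF mapping: ", unmapped[1], call. = FALSE)
  }
  rewritten <- lapply(bsc, function(ids) unique(unname(tf_of_tfbs[ids])))

  matched <- vapply(tfc, function(tf_set) {
    any(vapply(rewritten, function(rw) {
      mean(tf_set %in% rw) > containment ||
        intersection_rate(tf_set, rw) > min_rate
    }, logical(1)))
  }, logical(1))

  tfs <- unlist(tfc)
  tf_cluster_of <- rep(seq_along(tfc), lengths(tfc))
  names(tf_cluster_of) <- tfs
  co_tfbs <- matrix(FALSE, length(tfs), length(tfs),
                    dimnames = list(tfs, tfs))
  for (rw in rewritten) {
    present <- intersect(rw, tfs)
    co_tfbs[present, present] <- TRUE
  }
  ut <- upper.tri(co_tfbs)
  same_tf <- outer(tf_cluster_of[tfs], tf_cluster_of[tfs], "==")[ut]
  co <- co_tfbs[ut]
  tab <- matrix(c(sum(same_tf & co), sum(same_tf & !co),
                  sum(!same_tf & co), sum(!same_tf & !co)), nrow = 2)
  ft <- tryCatch(stats::fisher.test(tab, alternative = "greater"),
                 error = function(e) NULL)

  structure(list(
    n_tf_clusters = length(tfc), n_tfbs_clusters = length(bsc),
    n_matching = sum(matched), match_rate = mean(matched),
    fisher_odds = if (is.null(ft)) NA_real_ else unname(ft$estimate),
    fisher_p = if (is.null(ft)) NA_real_ else ft$p.value
  ), class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "TF clusters: %d | TFBS clusters: %d | matching: %d (rate %.3f)\n",
    x$n_tf_clusters, x$n_tfbs_clusters, x$n_matching, x$match_rate))
  cat(sprintf("Fisher association: odds %.3f, one-sided p %.3g\n",
              x$fisher_odds, x$fisher_p))
  invisible(x)
}

#' Split frequency of structure attributes across trained trees
#'
#' For each attribute, the fraction of models whose (pruned) decision tree
#' splits on that attribute at least once.
#'
#' @param models list of `tfbs_model` objects (structure or hybrid trees
#'   across TFs and sets).
#' @param attributes attribute names (rows of the property table).
#' @return named numeric vector of frequencies in \[0, 1\].
#' @export
attribute_frequency <- function(models, attributes) {
  if (length(models) == 0) stop("no models supplied", call. = FALSE)
  used <- vapply(attributes, function(a) {
    mean(vapply(models, function(m) a %in% tree_split_attributes(m),
                logical(1)))
  }, numeric(1))
  used
}

#' Bootstrap selection of high-frequency attributes
#'
#' Bootstraps the 75th quantile of the attribute-frequency vector (resampling
#' attributes with replacement, `n_boot` replicates), forms the 2.5%/97.5%
#' percentile interval of the bootstrapped quantile and selects the attributes
#' whose frequency strictly exceeds the interval midpoint.
#'
#' @param frequencies named numeric vector (see [attribute_frequency()]).
#' @param n_boot bootstrap replicates, default 10000.
#' @param seed integer seed.
#' @return character vector of selected attribute names.
#' @export
bootstrap_select_attributes <- function(frequencies, n_boot = 10000,
                                        seed = 1) {
  n <- length(frequencies)
  q75 <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      stats::quantile(sample(frequencies, n, replace = TRUE), 0.75,
                      names = FALSE)
    }, numeric(1))
  })
  ci <- stats::quantile(q75, c(0.025, 0.975), names = FALSE)
  mid <- mean(ci)
  names(frequencies)[frequencies > mid + 1e-12]
}

#' Encode TFBS sets per TF and map TF classes to TFBS clusters
#'
#' Each TF is encoded as the mean of the selected structure attributes over
#' its positive binding sites; attributes are standardized (they live on
#' heterogeneous physical scales). The number of TFBS classes is estimated by
#' Gaussian-mixture fits for k = 1..`max_k` scored by BIC, and the chosen k is
#' passed to K-means (seeded, `nstart` restarts). A TF class maps to a TFBS
#' class when more than `containment` of its members fall in a single K-means
#' cluster.
#'
#' @param tf_classes named character vector: TF id -> structural class label.
#' @param tfbs_features data frame with a `tf_id` column and one column per
#'   attribute, one row per positive binding site.
#' @param selected character vector of selected attribute names.
#' @param seed integer seed.
#' @param max_k largest class number tried, default 10.
#' @param nstart K-means restarts, default 50.
#' @param containment mapping threshold, default 0.9.
#' @return list with `k` (estimated class number), `assignment` (named cluster
#'   vector per TF) and `mapping` (data frame: `class`, `items_in_class`,
#'   `mapped_items`, `mapping_rate`, `mapping_status`).
#' @export
encode_and_map <- function(tf_classes, tfbs_features, selected, seed = 1,
                           max_k = 10, nstart = 50, containment = 0.9) {
  if (length(unique(tf_classes)) < 2) {
    stop("need at least 2 TF classes", call. = FALSE)
  }
  missing_cols <- setdiff(selected, names(tfbs_features))
  if (length(missing_cols) > 0) {
    stop("selected attribute not in features: ", missing_cols[1],
         call. = FALSE)
  }
  agg <- stats::aggregate(tfbs_features[, selected, drop = FALSE],
                          by = list(tf_id = tfbs_features$tf_id), FUN = mean)
  tf_ids <- agg$tf_id
  m <- as.matrix(agg[, selected, drop = FALSE])
  if (all(apply(m, 2, stats::sd) == 0)) {
    stop("degenerate encoding: all TF vectors identical", call. = FALSE)
  }
  keep <- apply(m, 2, stats::sd) > 0
  z <- scale(m[, keep, drop = FALSE])

  fit <- with_seed(derive_seed(seed, 1), {
    Mclust(z, G = 1:max_k, verbose = FALSE)
  })
  k <- fit$G
  cl <- if (k == 1) rep(1L, nrow(z)) else {
    with_seed(derive_seed(seed, 2),
              stats::kmeans(z, centers = k, nstart = nstart)$cluster)
  }
  names(cl) <- tf_ids

  classes <- tf_classes[tf_ids]
  rows <- lapply(sort(unique(classes)), function(cls) {
    members <- tf_ids[classes == cls]
    overlap <- max(table(factor(cl[members], levels = seq_len(max(cl)))))
    rate <- overlap / length(members)
    data.frame(class = cls, items_in_class = length(members),
               mapped_items = as.integer(overlap),
               mapping_rate = rate,
               mapping_status = ifelse(rate > containment, "Yes", "No"),
               stringsAsFactors = FALSE)
  })
  list(k = k, assignment = cl, mapping = do.call(rbind, rows))
}

#' Evolution-level correspondence: Spearman correlation of conservation
#'
#' Spearman rank correlation between TF conservation scores and the mean
#' evolution feature of their binding sites, with tie-corrected (average)
#' ranks. The one-sided (positive) p-value uses the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param pairs data frame with columns `tf_score` and `tfbs_score` (see
#'   [conservation_table_270()]).
#' @return list with `rho`, `p_one_sided`, `n`.
#' @export
conservation_correspondence <- function(pairs) {
  x <- pairs$tf_score
  y <- pairs$tfbs_score
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("conservation scores are constant; correlation undefined",
         call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_one_sided = stats::pt(t_stat, df = n - 2,
                                          lower.tail = FALSE), n = n)
}

#' Ortholog-based TF conservation scores
#'
#' Normalizes per-TF ortholog counts by a reference species count, giving a
#' score in \[0, 1\] that is monotone in the number of orthologs.
#'
#' @param ortholog_counts named integer vector of ortholog counts per TF.
#' @param n_reference the normalizing count (>= max count).
#' @return named numeric vector of scores in \[0, 1\].
#' @export
tf_conservation_score <- function(ortholog_counts, n_reference) {
  if (any(ortholog_counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(ortholog_counts > n_reference)) {
    stop("ortholog count exceeds the reference count", call. = FALSE)
  }
  ortholog_counts / n_reference
}

#' Mean evolution feature of a TF's binding sites
#'
#' @param tf_instances character vector of the TF's positive segments.
#' @param catalog a [motif_catalog].
#' @return the arithmetic mean evolution feature.
#' @export
tfbs_conservation_score <- function(tf_instances, catalog) {
  if (length(tf_instances) == 0) {
    stop("need at least one positive instance", call. = FALSE)
  }
  mean(evolution_scores(tf_instances, catalog))
}
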
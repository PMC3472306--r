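#' Configuration of a synthetic TF/TFBS world
#'
#' Collects the knobs of the synthetic-world generator. The defaults are the
#' study conditions used throughout the package's tests: a handful of TF
#' families with high within-family protein identity, sharp per-TF PWMs whose
#' similarity tracks protein similarity, 30 verified sites per TF (every TF
#' passes the more-than-10-sites inclusion rule), a motif catalog of 174
#' entries, and a planted Spearman correlation between TF conservation and the
#' mean evolution feature of its sites.
#'
#' @param n_families number of TF families.
#' @param tfs_per_family TFs per family.
#' @param protein_length TF protein length (aa).
#' @param within_family_divergence per-site substitution probability within a
#'   family (must be < `between_family_divergence`).
#' @param between_family_divergence per-site substitution probability between
#'   the shared root and each family ancestor.
#' @param pwm_length binding-site / PWM length (nt).
#' @param pwm_sharpness Dirichlet concentration on the consensus base; larger
#'   values give sharper columns.
#' @param sites_per_tf verified binding sites per TF (>= 10).
#' @param n_motifs catalog size (one motif per TF plus random decoys).
#' @param motif_score_range range of motif conservation scores.
#' @param motif_embed_range range of per-TF motif embedding probabilities.
#' @param planted_rho target Spearman correlation between TF conservation and
#'   mean TFBS evolution feature, in \[-1, 1\].
#' @param n_reference_species normalizer for ortholog counts.
#' @param n_promoters,promoter_length promoter corpus shape.
#' @param seed integer master seed.
#' @return a list of class `world_config`.
#' @export
world_config <- function(n_families = 4, tfs_per_family = 5,
                         protein_length = 120,
                         within_family_divergence = 0.05,
                         between_family_divergence = 0.6,
                         pwm_length = 12, pwm_sharpness = 12,
                         sites_per_tf = 30, n_motifs = 174,
                         motif_score_range = c(5, 60),
                         motif_embed_range = c(0.25, 0.95),
                         planted_rho = 0.3, n_reference_species = 96,
                         n_promoters = 30, promoter_length = 1000,
                         seed = 1) {
  cfg <- as.list(environment())
  if (within_family_divergence < 0 || between_family_divergence > 1 ||
      within_family_divergence >= between_family_divergence) {
    stop("divergences must satisfy 0 <= within < between <= 1", call. = FALSE)
  }
  if (sites_per_tf < 10) {
    stop("sites_per_tf must be >= 10 (TF inclusion rule)", call. = FALSE)
  }
  if (abs(planted_rho) > 1) stop("planted_rho must be in [-1, 1]",
                                 call. = FALSE)
  if (n_motifs < n_families * tfs_per_family) {
    stop("n_motifs must be >= the number of TFs", call. = FALSE)
  }
  if (pwm_length < 2) stop("pwm_length must be >= 2", call. = FALSE)
  class(cfg) <- "world_config"
  cfg
}

mutate_protein <- function(s, rate) {
  chars <- split_chars(s)
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) {
      sample(setdiff(AA_LETTERS, a), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

mutate_dna <- function(s, rate) {
  chars <- split_chars(s)
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) {
      sample(setdiff(DNA_BASES, a), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

random_protein <- function(n) paste(sample(AA_LETTERS, n, replace = TRUE),
                                    collapse = "")

# Dirichlet PWM around a consensus string.
consensus_pwm <- function(consensus, sharpness, background = rep(0.25, 4)) {
  idx <- seq_to_index(consensus)
  freq <- vapply(idx, function(b) {
    alpha <- rep(0.5, 4)
    alpha[b] <- sharpness
    g <- stats::rgamma(4, shape = alpha)
    g / sum(g)
  }, numeric(4))
  pwm(freq, background = background)
}

# Bivariate Gaussian copula with the latent correlation chosen so the
# resulting Spearman correlation equals `rho` (rho_latent = 2 sin(pi rho / 6)).
copula_sample <- function(n, rho) {
  rho_l <- 2 * sin(pi * rho / 6)
  z1 <- stats::rnorm(n)
  z2 <- rho_l * z1 + sqrt(1 - rho_l^2) * stats::rnorm(n)
  list(u1 = stats::pnorm(z1), u2 = stats::pnorm(z2))
}

#' Sample binding sites from a PWM
#'
#' Each position is drawn independently from the corresponding PWM column.
#'
#' @param x a [pwm].
#' @param n number of sites (>= 1).
#' @param seed integer seed.
#' @return character vector of `n` sites, each of the PWM's length.
#' @export
sample_sites <- function(x, n, seed = 1) {
  stopifnot(inherits(x, "pwm"), n >= 1)
  with_seed(seed, {
    mat <- vapply(seq_len(x$length), function(j) {
      sample(DNA_BASES, n, replace = TRUE, prob = x$freq[, j])
    }, character(n))
    if (n == 1) mat <- matrix(mat, nrow = 1)
    apply(mat, 1, paste, collapse = "")
  })
}

# A fixed promoter-like order-3 chain: AT-rich with CpG depletion. Transition
# probabilities depend on the final base of the context.
promoter_markov_model <- function() {
  base_prob <- c(A = 0.32, C = 0.18, G = 0.18, T = 0.32)
  n_ctx <- 4L^3L
  trans <- matrix(rep(base_prob, each = n_ctx), nrow = n_ctx)
  last_base <- ((seq_len(n_ctx) - 1L) %% 4L) + 1L # C = 2 in index space
  cpg <- last_base == 2L
  trans[cpg, 3] <- trans[cpg, 3] * 0.25
  trans <- trans / rowSums(trans)
  structure(list(order = 3L, transition = trans,
                 initial = rep(1 / n_ctx, n_ctx), pseudocount = 0),
            class = "markov_model")
}

#' Synthetic conservation pairs with a planted Spearman correlation
#'
#' Simulates, at the score level, the evolution-level correspondence data: a
#' per-TF ortholog count (normalized to a conservation score) and the mean
#' evolution feature of its sites. A Gaussian copula couples the ortholog
#' count with the per-TF motif-embedding probability and motif score, so the
#' expected mean evolution feature is rank-correlated with the TF score at
#' `rho`; the realized mean carries binomial site-sampling noise.
#'
#' @param n number of TFs.
#' @param rho planted Spearman correlation.
#' @param n_reference reference species count (normalizer).
#' @param sites_per_tf sites averaged per TF.
#' @param motif_score_range,embed_range marginal ranges.
#' @param seed integer seed.
#' @return data frame: `tf_id`, `tf_score`, `tfbs_score`.
#' @export
plant_conservation_pairs <- function(n, rho, n_reference = 96,
                                     sites_per_tf = 30,
                                     motif_score_range = c(5, 60),
                                     embed_range = c(0.25, 0.95), seed = 1) {
  with_seed(seed, {
    u <- copula_sample(n, rho)
    counts <- pmin(floor(u$u1 * (n_reference + 1)), n_reference)
    p_embed <- embed_range[1] + u$u2 * diff(embed_range)
    score <- motif_score_range[1] + u$u2 * diff(motif_score_range)
    hits <- stats::rbinom(n, sites_per_tf, p_embed)
    data.frame(
      tf_id = sprintf("TF%03d", seq_len(n)),
      tf_score = counts / n_reference,
      tfbs_score = score * hits / sites_per_tf,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a complete synthetic TF/TFBS world
#'
#' Builds, deterministically under the config seed: (i) TF protein families
#' (family ancestors mutated from a shared root, members mutated from their
#' ancestor, so within-family identity exceeds between-family identity);
#' (ii) per-TF PWMs derived from a family consensus, so similar TFs have
#' similar PWMs; (iii) positive binding sites sampled column-wise from each
#' TF's PWM; (iv) a promoter corpus from a fixed order-3 Markov chain
#' (AT-rich, CpG-depleted); (v) a motif catalog containing each TF's consensus
#' plus random decoys, with per-TF embedding probabilities and motif scores
#' copula-matched to ortholog counts so that TF conservation and mean TFBS
#' evolution feature have Spearman correlation near `planted_rho`.
#'
#' @param config a [world_config()].
#' @return a list of class `synthetic_world` with elements `config`,
#'   `tf_records` (protein records with family, ortholog count), `pwms`,
#'   `sites`, `promoters`, `catalog`, `conservation` (planted truth),
#'   `families`, `classes` (filled by [plant_structure_classes()]).
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  n_tfs <- config$n_families * config$tfs_per_family
  tf_ids <- sprintf("TF%03d", seq_len(n_tfs))
  family_of <- rep(sprintf("FAM%02d", seq_len(config$n_families)),
                   each = config$tfs_per_family)
  names(family_of) <- tf_ids

  proteins <- with_seed(derive_seed(config$seed, 1), {
    root <- random_protein(config$protein_length)
    ancestors <- vapply(seq_len(config$n_families), function(i) {
      mutate_protein(root, config$between_family_divergence)
    }, character(1))
    vapply(seq_len(n_tfs), function(i) {
      fam <- (i - 1) %/% config$tfs_per_family + 1
      mutate_protein(ancestors[fam], config$within_family_divergence)
    }, character(1))
  })

  consensi <- with_seed(derive_seed(config$seed, 2), {
    anc <- vapply(seq_len(config$n_families), function(i) {
      random_dna(config$pwm_length)
    }, character(1))
    vapply(seq_len(n_tfs), function(i) {
      fam <- (i - 1) %/% config$tfs_per_family + 1
      mutate_dna(anc[fam], config$within_family_divergence)
    }, character(1))
  })
  pwms <- with_seed(derive_seed(config$seed, 3), {
    lapply(seq_len(n_tfs), function(i) {
      consensus_pwm(consensi[i], config$pwm_sharpness)
    })
  })
  names(pwms) <- tf_ids

  # conservation planting (copula over ortholog count, embed prob, motif score)
  planted <- with_seed(derive_seed(config$seed, 4), {
    u <- copula_sample(n_tfs, config$planted_rho)
    counts <- pmin(floor(u$u1 * (config$n_reference_species + 1)),
                   config$n_reference_species)
    data.frame(
      tf_id = tf_ids,
      ortholog_count = counts,
      tf_score = counts / config$n_reference_species,
      p_embed = config$motif_embed_range[1] +
        u$u2 * diff(config$motif_embed_range),
      motif_score = config$motif_score_range[1] +
        u$u2 * diff(config$motif_score_range),
      stringsAsFactors = FALSE
    )
  })

  sites <- lapply(seq_len(n_tfs), function(i) {
    s <- sample_sites(pwms[[i]], config$sites_per_tf,
                      seed = derive_seed(config$seed, 10000 + i))
    with_seed(derive_seed(config$seed, 20000 + i), {
      embed <- stats::runif(config$sites_per_tf) < planted$p_embed[i]
      s[embed] <- consensi[i]
    })
    s
  })
  names(sites) <- tf_ids

  n_decoys <- config$n_motifs - n_tfs
  decoys <- with_seed(derive_seed(config$seed, 5), {
    vapply(seq_len(n_decoys), function(i) {
      random_dna(sample(10:16, 1))
    }, character(1))
  })
  decoy_scores <- with_seed(derive_seed(config$seed, 6), {
    stats::runif(n_decoys, config$motif_score_range[1],
                 config$motif_score_range[2])
  })
  catalog <- motif_catalog(c(consensi, decoys),
                           c(planted$motif_score, decoy_scores))

  promoters <- vapply(seq_len(config$n_promoters), function(i) {
    generate_pseudo_sequence(promoter_markov_model(),
                             length = config$promoter_length,
                             seed = derive_seed(config$seed, 30000 + i))
  }, character(1))

  structure(list(
    config = config,
    tf_records = data.frame(id = tf_ids, sequence = proteins,
                            moltype = "protein", family = unname(family_of),
                            ortholog_count = planted$ortholog_count,
                            stringsAsFactors = FALSE),
    pwms = pwms, consensi = stats::setNames(consensi, tf_ids), sites = sites,
    promoters = promoters, catalog = catalog,
    conservation = planted, families = family_of, classes = NULL
  ), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic world:", nrow(x$tf_records), "TFs in",
      x$config$n_families, "families,", x$config$sites_per_tf,
      "sites per TF,", nrow(x$catalog), "catalog motifs\n")
  invisible(x)
}

#' Plant structural classes into a synthetic world
#'
#' Reassigns TFs to `k_classes` structural classes and rebuilds their PWMs
#' around class-specific consensus skeletons drawn from disjoint two-base
#' alphabets, so the dinucleotide composition of each class's binding sites is
#' biased in a class-specific direction and the per-TF mean structure
#' attributes separate the classes. All members of a class share one flat
#' consensus PWM, and within-class variability is injected at the site level
#' (each sampled site is additionally mutated at per-site rate
#' `min(0.5, 0.5 / separation)`), so per-TF encodings are approximately
#' Gaussian within a class (averaging over sites) with spread shrinking as
#' `separation` grows. Sites are resampled with a fixed embedded-site count
#' and the catalog motif of each TF is updated to its class consensus; class
#' members then share their catalog motif, so this operation replaces the
#' conservation planting of the base world — use a fresh world for
#' evolution-level analyses.
#'
#' @param world a `synthetic_world`.
#' @param k_classes number of classes (>= 2).
#' @param separation positive separation factor (roughly, between-class over
#'   within-class spread).
#' @param class_sizes optional integer vector of class sizes summing to the
#'   number of TFs; default near-equal.
#' @return the modified world, with `classes` filled in `tf_records`.
#' @export
plant_structure_classes <- function(world, k_classes, separation,
                                    class_sizes = NULL) {
  stopifnot(inherits(world, "synthetic_world"))
  if (k_classes < 2) stop("k_classes must be >= 2", call. = FALSE)
  if (separation <= 0) stop("separation must be > 0", call. = FALSE)
  cfg <- world$config
  n_tfs <- nrow(world$tf_records)
  if (is.null(class_sizes)) {
    class_sizes <- rep(n_tfs %/% k_classes, k_classes)
    extra <- n_tfs - sum(class_sizes)
    if (extra > 0) class_sizes[seq_len(extra)] <- class_sizes[seq_len(extra)] + 1
  }
  if (sum(class_sizes) != n_tfs || length(class_sizes) != k_classes) {
    stop("class_sizes must have length k_classes and sum to the TF count",
         call. = FALSE)
  }
  class_labels <- sprintf("class%d", seq_len(k_classes))
  class_of <- rep(class_labels, class_sizes)
  site_noise <- min(0.5, 0.5 / separation)

  base_pairs <- list(c("A", "T"), c("C", "G"), c("A", "C"), c("G", "T"),
                     c("A", "G"), c("C", "T"))
  if (k_classes > length(base_pairs)) {
    stop("at most ", length(base_pairs), " structural classes are supported",
         call. = FALSE)
  }
  skeletons <- with_seed(derive_seed(cfg$seed, 7), {
    # class skeletons over distinct two-base alphabets: each class gets its
    # own dinucleotide composition, the axis the structure feature reads
    vapply(seq_len(k_classes), function(i) {
      paste(sample(base_pairs[[i]], cfg$pwm_length, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  consensi <- skeletons[match(class_of, class_labels)]
  names(consensi) <- world$tf_records$id

  # one flat consensus PWM per class: per-TF Dirichlet PWMs would give each TF
  # a systematic offset (spiky minor-base masses), turning classes into
  # collections of sub-lumps; with a shared PWM the within-class spread is
  # iid site-sampling noise, Gaussian by averaging over sites
  pwms <- lapply(seq_len(n_tfs), function(i) {
    idx <- seq_to_index(consensi[i])
    freq <- matrix(0.05, nrow = 4, ncol = cfg$pwm_length)
    freq[cbind(idx, seq_len(cfg$pwm_length))] <- 0.85
    pwm(freq)
  })
  names(pwms) <- world$tf_records$id

  # a fixed embedded-site count shared by all TFs: per-TF embedding variation
  # would give every class a dominant one-dimensional axis (the embedded
  # fraction) that EM/BIC resolves into spurious subcomponents
  n_embed <- round(mean(world$conservation$p_embed) * cfg$sites_per_tf)
  sites <- lapply(seq_len(n_tfs), function(i) {
    s <- sample_sites(pwms[[i]], cfg$sites_per_tf,
                      seed = derive_seed(cfg$seed, 40000 + i))
    with_seed(derive_seed(cfg$seed, 50000 + i), {
      s <- vapply(s, mutate_dna, character(1), rate = site_noise,
                  USE.NAMES = FALSE)
      embed <- sample.int(cfg$sites_per_tf, n_embed)
      s[embed] <- consensi[i]
    })
    s
  })
  names(sites) <- world$tf_records$id

  catalog <- world$catalog
  catalog$consensus[seq_len(n_tfs)] <- unname(consensi)

  world$pwms <- pwms
  world$consensi <- consensi
  world$sites <- sites
  world$catalog <- catalog
  world$tf_records$class <- class_of
  world$classes <- stats::setNames(class_of, world$tf_records$id)
  world
}

#' Realized conservation pairs of a synthetic world
#'
#' Computes, for every TF in the world, the ortholog-based conservation score
#' and the realized mean evolution feature of its positive sites.
#'
#' @param world a `synthetic_world`.
#' @return data frame: `tf_id`, `tf_score`, `tfbs_score`.
#' @export
world_conservation_pairs <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  tf_ids <- world$tf_records$id
  tfbs <- vapply(tf_ids, function(id) {
    tfbs_conservation_score(world$sites[[id]], world$catalog)
  }, numeric(1))
  data.frame(tf_id = tf_ids,
             tf_score = world$conservation$tf_score,
             tfbs_score = unname(tfbs), stringsAsFactors = FALSE)
}

#' Balanced instance bundles for every TF of a synthetic world
#'
#' Fits the order-3 background model to the world's promoter corpus, builds a
#' negative pool with windows of the TF site length, and assembles the
#' balanced instance sets for each TF.
#'
#' @param world a `synthetic_world`.
#' @param n_sets balanced sets per TF, default 10.
#' @param seed integer seed.
#' @return named list (per TF) of instance-set lists.
#' @export
world_bundles <- function(world, n_sets = 10, seed = 1) {
  stopifnot(inherits(world, "synthetic_world"))
  cfg <- world$config
  model <- fit_markov(world$promoters, order = 3, pseudocount = 1)
  n_needed <- cfg$sites_per_tf * n_sets * 2
  n_seq <- max(2, ceiling(n_needed / (5000 %/% cfg$pwm_length)))
  pool <- build_negative_pool(model, window = cfg$pwm_length,
                              n_sequences = n_seq, seed = derive_seed(seed, 1))
  out <- lapply(seq_along(world$sites), function(i) {
    assemble_instance_sets(world$sites[[i]], pool, n_sets = n_sets,
                           seed = derive_seed(seed, 100 + i),
                           tf_id = names(world$sites)[i])
  })
  names(out) <- names(world$sites)
  out
}

#' Evaluate the model suite on every TF of a synthetic world
#'
#' Convenience wrapper: builds the per-TF bundles with [world_bundles()] and
#' runs [run_model_suite()] for each TF with its own PWM.
#'
#' @param world a `synthetic_world`.
#' @param table a `dinuc_table`.
#' @param n_sets balanced sets per TF, default 10.
#' @param n_folds cross-validation folds, default 10.
#' @param seed integer seed.
#' @param collect_trees keep structure/hybrid trees for attribute-frequency
#'   analysis.
#' @return list with `results` (data frame with a `tf_id` column) and `trees`.
#' @export
run_world_suite <- function(world, table, n_sets = 10, n_folds = 10, seed = 1,
                            collect_trees = FALSE) {
  bundles <- world_bundles(world, n_sets = n_sets, seed = seed)
  rows <- list()
  trees <- list()
  for (id in names(bundles)) {
    res <- run_model_suite(bundles[[id]], x = world$pwms[[id]], table = table,
                           catalog = world$catalog,
                           seed = derive_seed(seed, 1000 + match(id, names(bundles))),
                           n_folds = n_folds, collect_trees = collect_trees)
    rows[[id]] <- cbind(tf_id = id, res$results, stringsAsFactors = FALSE)
    if (collect_trees) trees <- c(trees, res$trees)
  }
  list(results = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       trees = if (collect_trees) trees else NULL)
}
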
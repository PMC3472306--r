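mutate_seq <- function(s, k, seed, alphabet = DNA) {
  withr::with_seed(seed, {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(seq_along(ch), k)
    for (i in pos) ch[i] <- sample(setdiff(alphabet, ch[i]), 1)
    paste(ch, collapse = "")
  })
}

test_that("clustering links identical sequences and separates unrelated ones", {
  recs <- data.frame(id = c("a", "b"), sequence = rep("ACGTACGTACGTACGT", 2),
                     moltype = "dna", stringsAsFactors = FALSE)
  cl <- cluster_sequences(recs, coverage = 0.9, identity = 90)
  expect_equal(length(cl$clusters), 1)

  recs2 <- data.frame(id = c("a", "b"),
                      sequence = c("ACACACACACACACAC", "GTGTGTGTGTGTGTGT"),
                      moltype = "dna", stringsAsFactors = FALSE)
  cl2 <- cluster_sequences(recs2, coverage = 0.9, identity = 90)
  expect_equal(length(cl2$clusters), 2)

  expect_error(cluster_sequences(recs, coverage = 0, identity = 90), "coverage")
  expect_error(cluster_sequences(recs, coverage = 0.9, identity = 101),
               "identity")
})

test_that("two mutated families cluster into two groups at L=0.9 S=90", {
  base1 <- strrep("ACGGTTACGGAATCCGGTTA", 3)
  base2 <- strrep("TTCAGGCATTGACCAGGCAT", 3)
  fam <- c(base1, mutate_seq(base1, 3, 1), mutate_seq(base1, 3, 2),
           base2, mutate_seq(base2, 3, 3), mutate_seq(base2, 3, 4))
  recs <- data.frame(id = paste0("s", 1:6), sequence = fam, moltype = "dna",
                     stringsAsFactors = FALSE)
  cl <- cluster_sequences(recs, coverage = 0.9, identity = 90)
  expect_equal(length(cl$clusters), 2)
  expect_setequal(cl$clusters[[1]], c("s1", "s2", "s3"))
  expect_setequal(cl$clusters[[2]], c("s4", "s5", "s6"))
})

test_that("clustering agrees with a brute-force all-pairs oracle", {
  withr::with_seed(80, {
    bases <- replicate(4, paste(sample(DNA, 40, TRUE), collapse = ""))
    seqs <- unlist(lapply(seq_along(bases), function(i) {
      c(bases[i], vapply(1:3, function(k) {
        mutate_seq(bases[i], sample(1:6, 1), seed = i * 10 + k)
      }, character(1)))
    }))
  })
  recs <- data.frame(id = paste0("q", seq_along(seqs)), sequence = seqs,
                     moltype = "dna", stringsAsFactors = FALSE)
  got <- cluster_sequences(recs, coverage = 0.85, identity = 88)

  # oracle: one alignment per pair, then connected components by iteration
  n <- length(seqs)
  submat <- Biostrings::nucleotideSubstitutionMatrix(1, -2, baseOnly = TRUE)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    aln <- Biostrings::pairwiseAlignment(seqs[i], seqs[j], type = "local",
                                         substitutionMatrix = submat,
                                         gapOpening = 5, gapExtension = 2)
    pi_ <- Biostrings::pattern(aln); sj <- Biostrings::subject(aln)
    ok <- (Biostrings::end(pi_) - Biostrings::start(pi_) + 1) / nchar(seqs[i]) >= 0.85 &&
      (Biostrings::end(sj) - Biostrings::start(sj) + 1) / nchar(seqs[j]) >= 0.85 &&
      Biostrings::pid(aln, type = "PID1") >= 88
    adj[i, j] <- adj[j, i] <- ok
  }
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[c(i, which(adj[i, ]))]),
                  integer(1))
    if (identical(new, comp)) break
    comp <- new
  }
  want <- unname(lapply(split(recs$id, comp), sort))
  got_sorted <- lapply(got$clusters, sort)
  expect_setequal(got_sorted, want)
})

test_that("intersection rate is symmetric, bounded, and 1 only at equality", {
  expect_equal(intersection_rate(c("a", "b"), c("a", "b")), 1)
  expect_equal(intersection_rate(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(intersection_rate("a", "b"), 0)
  withr::with_seed(81, {
    for (i in 1:30) {
      a <- sample(letters, sample(1:10, 1))
      b <- sample(letters, sample(1:10, 1))
      r <- intersection_rate(a, b)
      expect_equal(r, intersection_rate(b, a))
      expect_gte(r, 0); expect_lte(r, 1)
      expect_equal(r == 1, setequal(a, b))
    }
  })
})

test_that("transform_and_match applies the containment and intersection criteria", {
  tf_clusters <- list(c("A", "B", "C"), c("D", "E"))
  tfbs_clusters <- list(c("b1", "b2", "b3"), c("b4", "b5"))
  tf_of <- c(b1 = "A", b2 = "B", b3 = "C", b4 = "D", b5 = "E")
  mr <- transform_and_match(tf_clusters, tfbs_clusters, tf_of)
  expect_equal(mr$match_rate, 1.0)
  expect_equal(mr$n_matching, 2)

  # {A,B,C} vs rewritten {B,C,D}: intersection rate 0.5, no containment
  tf_of2 <- c(b1 = "B", b2 = "C", b3 = "D", b4 = "D", b5 = "E")
  mr2 <- transform_and_match(list(c("A", "B", "C")), list(c("b1", "b2", "b3")),
                             tf_of2)
  expect_equal(mr2$match_rate, 0)

  expect_error(transform_and_match(tf_clusters, list("zz"), tf_of),
               "without a TF mapping")
})

test_that("a planted TF/TFBS correspondence is detected and destroyed by permutation", {
  w <- generate_world(world_config(n_families = 10, tfs_per_family = 7,
                                   sites_per_tf = 10, n_motifs = 80,
                                   within_family_divergence = 0.02,
                                   seed = 90))
  site_recs <- do.call(rbind, lapply(names(w$sites), function(id) {
    data.frame(id = paste0(id, "_s", seq_along(w$sites[[id]])),
               sequence = w$sites[[id]], moltype = "dna",
               stringsAsFactors = FALSE)
  }))
  tf_of <- setNames(sub("_s[0-9]+$", "", site_recs$id), site_recs$id)
  tfc <- cluster_sequences(w$tf_records[, c("id", "sequence", "moltype")],
                           0.9, 60)
  bsc <- cluster_sequences(site_recs, 0.9, 60)
  mr <- transform_and_match(tfc, bsc, tf_of)
  expect_gte(mr$match_rate, 0.8)
  expect_lt(mr$fisher_p, 0.01)

  drops <- vapply(1:25, function(i) {
    perm <- withr::with_seed(i, setNames(sample(unname(tf_of)), names(tf_of)))
    transform_and_match(tfc, bsc, perm)$match_rate < mr$match_rate
  }, logical(1))
  expect_gte(mean(drops), 0.9)
})

test_that("attribute frequencies count models that split on each attribute", {
  tab <- random_property_table(6, seed = 91)
  x <- withr::with_seed(92, data.frame(attr1 = c(rnorm(20, -4), rnorm(20, 4)),
                                       attr2 = rnorm(40)))
  y <- rep(c(0L, 1L), each = 20)
  m1 <- train_tree(x, y, seed = 1)
  m2 <- train_tree(x, y, seed = 2)
  freqs <- attribute_frequency(list(m1, m2), rownames(tab))
  expect_equal(unname(freqs["attr1"]), 1)
  expect_true(all(freqs[setdiff(rownames(tab), "attr1")] == 0))
  expect_error(attribute_frequency(list(), rownames(tab)), "no models")
})

test_that("bootstrap attribute selection isolates the high-frequency block", {
  freqs <- setNames(c(rep(0.9, 5), rep(0.1, 33)), paste0("a", 1:38))
  sel <- bootstrap_select_attributes(freqs, n_boot = 3000, seed = 2)
  expect_setequal(sel, paste0("a", 1:5))

  flat <- setNames(rep(0.4, 38), paste0("a", 1:38))
  expect_equal(length(bootstrap_select_attributes(flat, n_boot = 500,
                                                  seed = 2)), 0)

  s1 <- bootstrap_select_attributes(freqs, n_boot = 1000, seed = 7)
  s2 <- bootstrap_select_attributes(freqs, n_boot = 1000, seed = 7)
  expect_identical(s1, s2)
})

test_that("encode_and_map recovers planted structural classes", {
  tab <- default_property_table()
  w <- generate_world(world_config(n_families = 4, tfs_per_family = 12,
                                   n_motifs = 60, seed = 93))
  w <- plant_structure_classes(w, k_classes = 4, separation = 5)
  feat <- do.call(rbind, lapply(names(w$sites), function(id) {
    data.frame(tf_id = id, structure_matrix(w$sites[[id]], tab),
               stringsAsFactors = FALSE)
  }))
  res <- encode_and_map(w$classes, feat, selected = rownames(tab)[1:6],
                        seed = 5)
  expect_equal(res$k, 4)
  expect_true(all(res$mapping$mapping_status == "Yes"))
  expect_equal(res$mapping$items_in_class, rep(12L, 4))

  # mapping-rate arithmetic
  expect_equal(round(52 / 56, 3), 0.929)

  expect_error(encode_and_map(w$classes[1:12], feat, rownames(tab)[1:2]),
               "at least 2")
})

test_that("Spearman correspondence matches cor.test and handles edge cases", {
  inc <- data.frame(tf_score = 1:20 / 20, tfbs_score = (1:20)^2)
  expect_equal(conservation_correspondence(inc)$rho, 1)
  dec <- data.frame(tf_score = 1:20 / 20, tfbs_score = rev(1:20))
  expect_equal(conservation_correspondence(dec)$rho, -1)
  expect_error(conservation_correspondence(inc[1:2, ]), "at least 3")
  expect_error(conservation_correspondence(
    data.frame(tf_score = rep(1, 5), tfbs_score = 1:5)), "constant")

  withr::with_seed(94, {
    pairs <- data.frame(tf_score = round(runif(40), 2), # ties likely
                        tfbs_score = round(rexp(40), 1))
  })
  got <- conservation_correspondence(pairs)
  want_rho <- suppressWarnings(stats::cor.test(pairs$tf_score,
                                               pairs$tfbs_score,
                                               method = "spearman")$estimate)
  expect_equal(got$rho, unname(want_rho))
  t_stat <- got$rho * sqrt((40 - 2) / (1 - got$rho^2))
  expect_equal(got$p_one_sided, stats::pt(t_stat, 38, lower.tail = FALSE))
})

test_that("TF and TFBS conservation scores follow their definitions", {
  expect_equal(unname(tf_conservation_score(c(t1 = 0, t2 = 96), 96)), c(0, 1))
  expect_equal(unname(tf_conservation_score(c(t1 = 49, t2 = 31), 96)),
               c(49, 31) / 96, tolerance = 1e-12)
  expect_error(tf_conservation_score(c(t1 = 100), 96), "exceeds")

  # fixture scores sit near integer multiples of 1/96
  tab <- conservation_table_270()
  resid <- abs(tab$tf_score * 96 - round(tab$tf_score * 96))
  expect_lt(stats::median(resid), 0.05)

  cat0 <- motif_catalog("TGACTCA", 10)
  expect_equal(tfbs_conservation_score(c("AAAAAAA", "CCCCCCC"), cat0), 0)
  expect_equal(tfbs_conservation_score(c("TGACTCA", "AAAAAAA"), cat0), 5)
  expect_error(tfbs_conservation_score(character(0), cat0), "at least one")

  withr::with_seed(95, {
    segs <- replicate(15, paste(sample(DNA, 10, TRUE), collapse = ""))
  })
  catalog <- motif_catalog(c("ACGTACGTAC", "TTTTTTTTTT"), c(7, 3),
                           threshold = 0.8)
  expect_equal(tfbs_conservation_score(segs, catalog),
               mean(vapply(segs, evolution_score, numeric(1),
                           catalog = catalog)))
})
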
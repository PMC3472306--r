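#' Read sequence records from a FASTA file
#'
#' Reads a FASTA file into a data frame of sequence records. Sequences are
#' uppercased on read. DNA records must be pure A/C/G/T (ambiguity codes are
#' rejected, since downstream scoring treats instances as concrete segments);
#' protein records must use the 20 standard amino-acid letters.
#'
#' @param path path to a FASTA file.
#' @param moltype either `"dna"` or `"protein"`.
#' @return a data frame with columns `id`, `sequence`, `moltype`.
#' @export
read_fasta <- function(path, moltype = c("dna", "protein")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    return(data.frame(id = character(), sequence = character(),
                      moltype = character(), stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  records <- data.frame(id = ids, sequence = unname(seqs), moltype = moltype,
                        stringsAsFactors = FALSE)
  validate_records(records)
  records
}

validate_records <- function(records) {
  empty <- !nzchar(records$sequence)
  if (any(empty)) {
    stop("empty sequence for record: ", records$id[which(empty)[1]],
         call. = FALSE)
  }
  ok <- ifelse(records$moltype == "dna", is_dna(records$sequence),
               is_protein(records$sequence))
  if (!all(ok)) {
    stop("sequence with characters outside the declared alphabet: ",
         records$id[which(!ok)[1]], call. = FALSE)
  }
  invisible(records)
}

#' Write sequence records to a FASTA file
#'
#' @param records data frame with columns `id` and `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a TRANSFAC-format position weight matrix
#'
#' Parses the TRANSFAC matrix dialect: a `P0 A C G T` header followed by
#' numbered rows of four counts (an optional trailing consensus letter is
#' ignored). Counts are normalized per position; matrices already given as
#' frequencies (rows summing to ~1) pass through unchanged by the same
#' normalization.
#'
#' @param path path to a TRANSFAC matrix file.
#' @param background background base probabilities (A, C, G, T); default
#'   uniform.
#' @return a [pwm] object.
#' @export
read_transfac_pwm <- function(path, background = rep(0.25, 4)) {
  lines <- readLines(path)
  header <- grep("^P0\\b|^PO\\b", lines)
  if (length(header) != 1) {
    stop("TRANSFAC matrix must contain exactly one P0 header line",
         call. = FALSE)
  }
  rows <- list()
  for (ln in lines[-seq_len(header)]) {
    if (grepl("^(XX|//)", ln) || !nzchar(trimws(ln))) break
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!grepl("^[0-9]+$", tok[1])) break
    counts <- suppressWarnings(as.numeric(tok[2:5]))
    if (anyNA(counts)) {
      stop("malformed count row ", tok[1], " in ", path, call. = FALSE)
    }
    rows[[length(rows) + 1]] <- counts
  }
  if (length(rows) == 0) stop("no matrix rows found in ", path, call. = FALSE)
  counts <- do.call(rbind, rows)
  totals <- rowSums(counts)
  if (any(totals <= 0)) {
    stop("matrix row ", which(totals <= 0)[1], " does not sum to a positive ",
         "total", call. = FALSE)
  }
  freq <- t(counts / totals)
  rownames(freq) <- DNA_BASES
  pwm(freq, background = background)
}

#' Write a PWM in TRANSFAC format
#'
#' @param x a [pwm] object.
#' @param path output path.
#' @param id identifier written on the `ID` line.
#' @param scale counts scale (frequencies are written as `scale * f`).
#' @return `path`, invisibly.
#' @export
write_transfac_pwm <- function(x, path, id = "M00001", scale = 100) {
  stopifnot(inherits(x, "pwm"))
  lines <- c(paste("ID", id), "P0\tA\tC\tG\tT")
  for (j in seq_len(ncol(x$freq))) {
    lines <- c(lines, paste(c(sprintf("%02d", j),
                              format(round(x$freq[, j] * scale, 4))),
                            collapse = "\t"))
  }
  writeLines(c(lines, "XX", "//"), path)
  invisible(path)
}

#' Read a dinucleotide property table
#'
#' The table is a TSV with an `attribute` column followed by one column per
#' dinucleotide (AA, AC, ..., TT). Each row is one conformational or
#' physicochemical attribute.
#'
#' @param path path to the TSV.
#' @return a numeric matrix (attributes x 16 dinucleotides) of class
#'   `dinuc_table`.
#' @export
read_property_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  dinucs <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  missing <- setdiff(dinucs, colnames(df))
  if (length(missing) > 0) {
    stop("property table missing dinucleotide column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  attrs <- as.character(df[[1]])
  if (anyDuplicated(attrs)) {
    stop("duplicate attribute name: ", attrs[anyDuplicated(attrs)],
         call. = FALSE)
  }
  m <- as.matrix(df[, dinucs, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) {
    stop("property table contains non-numeric values", call. = FALSE)
  }
  rownames(m) <- attrs
  class(m) <- c("dinuc_table", class(m))
  m
}

#' Bundled default dinucleotide property table
#'
#' Returns the 38-attribute x 16-dinucleotide table shipped with the package.
#' The bundled table is a synthetic stand-in: attribute names follow the
#' standard conformational/physicochemical vocabulary (twist, roll, stacking
#' energy, duplex stability, ...) and values are drawn once, deterministically,
#' on realistic scales. For analyses of real data, substitute a measured table
#' via [read_property_table()].
#'
#' @return a `dinuc_table` matrix with 38 rows.
#' @export
default_property_table <- function() {
  read_property_table(system.file("extdata",
                                  "dinucleotide_properties_synthetic.tsv",
                                  package = "tfbstrio", mustWork = TRUE))
}

#' Construct a conserved-motif catalog
#'
#' @param consensus character vector of IUPAC consensus strings.
#' @param score numeric vector of conservation scores (>= 0).
#' @param threshold similarity threshold in (0, 1] above which a segment is
#'   considered to match a motif; default 0.95.
#' @return a data frame of class `motif_catalog` with columns `consensus` and
#'   `score`, carrying the threshold as an attribute.
#' @export
motif_catalog <- function(consensus, score, threshold = 0.95) {
  consensus <- toupper(consensus)
  if (length(consensus) > 0 && !all(is_iupac(consensus))) {
    stop("non-IUPAC character in motif consensus: ",
         consensus[which(!is_iupac(consensus))[1]], call. = FALSE)
  }
  if (length(score) != length(consensus)) {
    stop("consensus and score lengths differ", call. = FALSE)
  }
  if (threshold <= 0 || threshold > 1) {
    stop("similarity threshold must be in (0, 1]", call. = FALSE)
  }
  cat <- data.frame(consensus = consensus, score = as.numeric(score),
                    stringsAsFactors = FALSE)
  attr(cat, "threshold") <- threshold
  class(cat) <- c("motif_catalog", class(cat))
  cat
}

#' Read a conserved-motif catalog
#'
#' TSV with columns `consensus` (IUPAC string) and `score`.
#'
#' @param path path to the TSV.
#' @param threshold similarity threshold, default 0.95.
#' @return a [motif_catalog].
#' @export
read_motif_catalog <- function(path, threshold = 0.95) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    return(motif_catalog(character(), numeric(), threshold))
  }
  motif_catalog(df$consensus, df$score, threshold)
}

#' Write a motif catalog to TSV
#'
#' @param catalog a [motif_catalog].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motif_catalog <- function(catalog, path) {
  utils::write.table(as.data.frame(catalog), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TF conservation table
#'
#' TSV with columns `tf_id`, `tf_score` (ortholog-based conservation, in
#' \[0, 1\]) and `tfbs_score` (mean evolution feature of the TF's binding
#' sites, >= 0).
#'
#' @param path path to the TSV.
#' @return a data frame with the three columns.
#' @export
read_conservation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "character"))
  names(df) <- c("tf_id", "tf_score", "tfbs_score")
  tf_score <- suppressWarnings(as.numeric(df$tf_score))
  tfbs_score <- suppressWarnings(as.numeric(df$tfbs_score))
  bad <- is.na(tf_score) | is.na(tfbs_score)
  if (any(bad)) {
    stop("non-numeric conservation score for TF ", df$tf_id[which(bad)[1]],
         call. = FALSE)
  }
  if (anyDuplicated(df$tf_id)) {
    stop("duplicate tf_id: ", df$tf_id[anyDuplicated(df$tf_id)],
         call. = FALSE)
  }
  data.frame(tf_id = df$tf_id, tf_score = tf_score, tfbs_score = tfbs_score,
             stringsAsFactors = FALSE)
}

#' Packaged conservation table for 270 transcription factors
#'
#' The published table of ortholog-based conservation scores for 270 TFs and
#' the mean evolution feature of their binding sites, shipped as a plain-text
#' fixture. The Spearman rank correlation across its rows quantifies
#' evolution-level correspondence between TFs and their targets.
#'
#' @return a data frame with 270 rows: `tf_id`, `tf_score`, `tfbs_score`.
#' @export
conservation_table_270 <- function() {
  read_conservation_table(system.file("extdata",
                                      "tf_conservation_270.tsv",
                                      package = "tfbstrio", mustWork = TRUE))
}

#' Read labeled instance sets
#'
#' TSV with columns `set_id`, `instance_id`, `label` (1 = positive TFBS,
#' 0 = background) and `sequence`.
#'
#' @param path path to the TSV.
#' @return a list of data frames, one per `set_id`, each with columns
#'   `set_id`, `instance_id`, `label`, `sequence`.
#' @export
read_instance_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("set_id", "instance_id", "label", "sequence")
  if (!all(need %in% names(df))) {
    stop("instance TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$label %in% c(0L, 1L))) {
    stop("instance labels must be 0 or 1", call. = FALSE)
  }
  df$sequence <- toupper(df$sequence)
  split(df[, need], df$set_id)
}

#' Write instance sets to a single TSV
#'
#' @param sets list of instance-set data frames (as produced by
#'   [assemble_instance_sets()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_instance_sets <- function(sets, path) {
  df <- do.call(rbind, sets)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
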
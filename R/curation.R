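#' Merge per-class peptide sources into one multi-label set
#'
#' Therapeutic-peptide benchmarks are assembled from many mono-functional
#' source datasets. A peptide collected under several functions is the same
#' molecule, so identical sequences are collapsed into a single record whose
#' label set is the union of the source labels. Duplicates within one source
#' are dropped first. Output order is lexicographic by sequence, making the
#' merge deterministic and order-independent in its inputs.
#'
#' @param sources Named list: names are label codes, elements are character
#'   vectors of sequences (or [peptide_set()]s, whose labels are ignored in
#'   favour of the source name).
#' @return A [peptide_set()] with ids `pep00001`, `pep00002`, ... assigned
#'   in output order.
#' @examples
#' merge_peptide_sources(list(ABP = c("AAAAA", "CCCCC"), ACP = "CCCCC"))
#' @export
merge_peptide_sources <- function(sources) {
  if (is.null(names(sources)) || any(!nzchar(names(sources)))) {
    stop("sources must be a named list (names are label codes)")
  }
  env <- new.env(parent = emptyenv())
  for (code in names(sources)) {
    s <- sources[[code]]
    seqs <- if (inherits(s, "peptide_set")) s$sequence else as.character(s)
    for (sq in unique(toupper(seqs))) {
      assign(sq, union(if (exists(sq, env)) get(sq, env) else character(),
                       code), envir = env)
    }
  }
  seqs <- sort(ls(env))
  labs <- lapply(seqs, get, envir = env)
  ids <- sprintf("pep%05d", seq_along(seqs))
  peptide_set(ids, seqs, labs)
}

#' Curate a multi-label peptide set
#'
#' Applies the three standard benchmark curation criteria:
#' \enumerate{
#'   \item drop peptides containing non-standard amino acids (anything
#'     outside the 20-letter alphabet [AA_ALPHABET]);
#'   \item drop peptides shorter than `min_len` or longer than `max_len`
#'     residues (very short peptides lack activity, long ones tend to be
#'     toxic and unstable);
#'   \item drop function classes with fewer than `min_class_count` member
#'     peptides, removing those codes from every record's label set.
#' }
#' The class-count filter runs after the per-sequence filters, on the
#' post-filter membership counts. Records left with an empty label set are
#' removed. Curation is idempotent.
#'
#' @param records A [peptide_set()].
#' @param min_len,max_len Length bounds in residues (defaults 5 and 50).
#' @param min_class_count Minimum surviving class size (default 40).
#' @param vocab Optional [label_vocab()] restricting which codes are
#'   considered at all; defaults to the codes present in `records`.
#' @return A list of class `curation` with elements `records` (the curated
#'   [peptide_set()]), `vocab` (the pruned [label_vocab()]), and `dropped`
#'   (counts of records removed per criterion).
#' @export
curate_peptides <- function(records, min_len = 5L, max_len = 50L,
                            min_class_count = 40L, vocab = NULL) {
  n0 <- nrow(records)
  if (n0 == 0L) stop("curate_peptides: empty dataset")
  ok_alpha <- !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                     records$sequence)
  len <- nchar(records$sequence)
  ok_len <- len >= min_len & len <= max_len
  kept <- records[ok_alpha & ok_len, ]

  if (!is.null(vocab)) {
    kept$labels <- lapply(kept$labels, intersect, unclass(vocab))
  }
  codes <- used_labels(kept)
  if (length(codes)) {
    counts <- label_counts(kept, label_vocab_any(codes))
    keep_codes <- names(counts)[counts >= min_class_count]
  } else {
    keep_codes <- character()
  }
  kept$labels <- lapply(kept$labels, intersect, keep_codes)
  n_before_empty <- nrow(kept)
  kept <- kept[lengths(kept$labels) > 0L, ]
  if (nrow(kept) == 0L) {
    stop("curate_peptides: empty dataset after filtering",
         " (check length bounds and min_class_count)")
  }
  rownames(kept) <- NULL
  structure(list(
    records = kept,
    vocab = label_vocab_any(keep_codes),
    dropped = c(nonstandard = sum(!ok_alpha),
                length = sum(ok_alpha & !ok_len),
                unlabeled = n_before_empty - nrow(kept))
  ), class = "curation")
}

# vocabulary that tolerates a single code (curation of degenerate toy sets)
label_vocab_any <- function(codes) {
  if (length(codes) < 2L) return(structure(codes, class = "label_vocab"))
  label_vocab(codes)
}

#' @export
print.curation <- function(x, ...) {
  cat("Curated peptide set:", nrow(x$records), "records,",
      length(x$vocab), "classes\n")
  cat("Dropped:", x$dropped[["nonstandard"]], "non-standard residue,",
      x$dropped[["length"]], "length,",
      x$dropped[["unlabeled"]], "left unlabeled\n")
  invisible(x)
}

#' Encode peptides as a fixed-length token/label batch
#'
#' Each sequence is mapped to integer tokens — the letter at alphabetical
#' position k of [AA_ALPHABET] becomes k (1..20) — and right-padded with 0
#' to length `L`. Labels become an N x M binary indicator matrix over the
#' vocabulary columns.
#'
#' @param records A [peptide_set()] of curated sequences (length <= `L`,
#'   standard alphabet only).
#' @param vocab A [label_vocab()] fixing the label column order.
#' @param L Fixed token length (default 50).
#' @return A list of class `encoded_batch` with `tokens` (N x L integer
#'   matrix, 0 = pad) and `labels` (N x M binary matrix with vocabulary
#'   codes as column names).
#' @examples
#' v <- label_vocab(c("ABP", "ACP"))
#' encode_peptides(peptide_set("p", "ACDE", list("ACP")), v, L = 8)
#' @export
encode_peptides <- function(records, vocab, L = 50L) {
  n <- nrow(records)
  bad <- which(nchar(records$sequence) > L)
  if (length(bad)) {
    stop("sequence longer than L=", L, ": record ", records$id[bad[1]],
         " (", nchar(records$sequence[bad[1]]), " residues)")
  }
  chars <- strsplit(records$sequence, "", fixed = TRUE)
  tokens <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    idx <- match(chars[[i]], AA_ALPHABET)
    if (anyNA(idx)) {
      stop("non-standard amino acid '", chars[[i]][which(is.na(idx))[1]],
           "' in record ", records$id[i])
    }
    tokens[i, seq_along(idx)] <- idx
  }
  M <- length(vocab)
  labels <- matrix(0L, n, M, dimnames = list(NULL, unclass(vocab)))
  for (i in seq_len(n)) {
    j <- label_index(vocab, records$labels[[i]])
    labels[i, j[!is.na(j)]] <- 1L
  }
  structure(list(tokens = tokens, labels = labels), class = "encoded_batch")
}

#' Decode token rows back to sequences
#'
#' @param tokens Integer matrix as produced by [encode_peptides()].
#' @return Character vector of sequences (padding stripped).
#' @export
decode_tokens <- function(tokens) {
  apply(tokens, 1L, function(r) paste(AA_ALPHABET[r[r > 0L]], collapse = ""))
}

#' Random train/test split
#'
#' Simple random partition: `floor(ratio * N)` records go to the training
#' split, the remainder to the test split. Optionally stratified so every
#' class contributes approximately `ratio` of its members to training (off
#' by default, matching the plain random protocol).
#'
#' @param records A [peptide_set()].
#' @param ratio Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed for reproducibility.
#' @param stratify Stratify by (first) label? Default `FALSE`.
#' @return A list with `train` and `test` [peptide_set()]s.
#' @export
split_train_test <- function(records, ratio = 0.8, seed = 1L,
                             stratify = FALSE) {
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records to split")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  if (stratify) {
    strata <- vapply(records$labels,
                     function(l) if (length(l)) l[[1]] else "", "")
    idx <- unlist(lapply(split(seq_len(n), strata), function(g) {
      sample(g, floor(ratio * length(g)))
    }), use.names = FALSE)
    if (!length(idx)) idx <- sample.int(n, floor(ratio * n))
  } else {
    idx <- sample.int(n, floor(ratio * n))
  }
  idx <- sort(idx)
  list(train = records[idx, ], test = records[setdiff(seq_len(n), idx), ])
}

# set.seed that restores the caller's RNG state on exit
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
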
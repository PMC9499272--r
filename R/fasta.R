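#' Read a multi-label peptide FASTA file
#'
#' There is no standard for attaching several function labels to one FASTA
#' record, so the package uses the header dialect
#' `>id|CODE1,CODE2,...` — the record identifier, a pipe, then a
#' comma-separated list of label codes. A header with no pipe yields a record
#' with an empty label set (useful for prediction-only input).
#'
#' @param path Path to a FASTA file.
#' @param vocab Optional [label_vocab()]; codes absent from it trigger one
#'   warning naming the unknown codes (records are retained).
#' @return A [peptide_set()]. Sequences are upper-cased.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">p1|ABP,ACP", "GLFDIIKKIAESF"), f)
#' read_multilabel_fasta(f)
#' @export
read_multilabel_fasta <- function(path, vocab = NULL) {
  check_fasta_structure(path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) {
    warning("empty FASTA file: ", path)
    return(peptide_set(character(), character(), list())[0, ])
  }
  headers <- names(aas)
  parts <- strsplit(headers, "|", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  labs <- lapply(parts, function(p) {
    if (length(p) < 2L) return(character())
    lab <- strsplit(p[[2]], ",", fixed = TRUE)[[1]]
    lab[nzchar(trimws(lab))]
  })
  if (!is.null(vocab)) {
    unknown <- setdiff(unique(unlist(labs)), unclass(vocab))
    if (length(unknown)) {
      warning("unknown label code(s) not in vocabulary: ",
              paste(unknown, collapse = ", "))
    }
  }
  peptide_set(ids, as.character(aas), labs)
}

# Structural pre-scan so malformed input fails with a line number rather
# than an opaque parser error.
check_fasta_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) return(invisible(TRUE))
  if (!startsWith(lines[nonblank[1]], ">")) {
    stop("malformed FASTA at line ", nonblank[1],
         ": expected a '>' header before sequence data")
  }
  is_hdr <- startsWith(lines, ">")
  for (i in which(is_hdr)) {
    nxt <- nonblank[nonblank > i][1]
    if (is.na(nxt) || is_hdr[nxt]) {
      stop("malformed FASTA at line ", i, ": header '",
           lines[i], "' has no sequence")
    }
  }
  invisible(TRUE)
}

#' Write a peptide set as multi-label FASTA
#'
#' Inverse of [read_multilabel_fasta()]: headers are `id|CODE1,CODE2,...`
#' (bare `id` when the label set is empty).
#'
#' @param records A [peptide_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multilabel_fasta <- function(records, path) {
  aas <- Biostrings::AAStringSet(records$sequence)
  labs <- vapply(records$labels, paste, "", collapse = ",")
  names(aas) <- ifelse(nzchar(labs), paste0(records$id, "|", labs),
                       records$id)
  Biostrings::writeXStringSet(aas, path, width = 80L)
  invisible(path)
}

#' Read a single-class FASTA file
#'
#' Plain FASTA where every record belongs to one function class given by the
#' caller (typically derived from the file name). Used to ingest per-class
#' source datasets before [merge_peptide_sources()].
#'
#' @param path Path to a FASTA file.
#' @param code The label code to assign to every record.
#' @return A [peptide_set()] where every record carries `code`.
#' @export
read_class_fasta <- function(path, code) {
  check_fasta_structure(path)
  aas <- Biostrings::readAAStringSet(path)
  peptide_set(names(aas), as.character(aas),
              rep(list(as.character(code)), length(aas)))
}

#' Export a peptide set as TSV
#'
#' Columns: `id`, `sequence`, `labels` (comma-joined).
#'
#' @param records A [peptide_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_tsv <- function(records, path) {
  out <- data.frame(id = records$id, sequence = records$sequence,
                    labels = vapply(records$labels, paste, "", collapse = ","))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
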
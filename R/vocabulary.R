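#' The 20 standard amino acids, alphabetical
#'
#' One-letter codes in alphabetical order. Token encoding maps the letter at
#' position k to the integer k (1..20); 0 is reserved for padding.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default therapeutic-function label codes
#'
#' The 21 therapeutic peptide function classes used by the reference
#' benchmark: anti-angiogenic (AAP), anti-bacterial (ABP), anti-cancer (ACP),
#' anti-coronavirus (ACVP), anti-diabetic (ADP), anti-endotoxin (AEP),
#' anti-fungal (AFP), anti-HIV (AHIVP), anti-hypertensive (AHP),
#' anti-inflammatory (AIP), anti-MRSA (AMRSAP), anti-parasitic (APP),
#' anti-tubercular (ATP), anti-viral (AVP), blood-brain barrier (BBP),
#' biofilm-inhibitory (BIP), cell-penetrating (CPP), dipeptidyl peptidase IV
#' (DPPIP), quorum-sensing (QSP), surface-binding (SBP) and tumor-homing
#' (THP) peptides.
#'
#' @format Character vector of length 21.
#' @export
MFTP_CLASSES <- c("AAP", "ABP", "ACP", "ACVP", "ADP", "AEP", "AFP", "AHIVP",
                  "AHP", "AIP", "AMRSAP", "APP", "ATP", "AVP", "BBP", "BIP",
                  "CPP", "DPPIP", "QSP", "SBP", "THP")

#' Construct a label vocabulary
#'
#' A label vocabulary is an ordered set of function codes; its ordering fixes
#' the column order of every label-indicator matrix produced downstream, so a
#' vocabulary must be serialized together with any model trained against it.
#'
#' @param codes Character vector of unique label codes (at least 2).
#' @return An object of class `label_vocab`: the character vector of codes
#'   with positions accessible through [label_index()].
#' @examples
#' v <- label_vocab(c("ABP", "ACP", "AFP"))
#' label_index(v, "ACP")
#' @export
label_vocab <- function(codes = MFTP_CLASSES) {
  codes <- as.character(codes)
  if (anyDuplicated(codes)) {
    stop("label codes must be unique; duplicated: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  }
  if (length(codes) < 2L) {
    stop("a label vocabulary needs at least 2 codes")
  }
  structure(codes, class = "label_vocab")
}

#' @export
print.label_vocab <- function(x, ...) {
  cat("Label vocabulary with", length(x), "classes:\n")
  cat(" ", paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}

#' Position of label codes in a vocabulary
#'
#' @param vocab A [label_vocab()].
#' @param codes Character vector of codes.
#' @return Integer positions (1-based); unknown codes give `NA`.
#' @export
label_index <- function(vocab, codes) {
  match(codes, unclass(vocab))
}

#' @export
`[.label_vocab` <- function(x, i) {
  label_vocab(unclass(x)[i])
}

#' Serialize / deserialize a label vocabulary as JSON
#'
#' @param vocab A [label_vocab()].
#' @param path File path.
#' @return `read_vocab_json` returns a [label_vocab()];
#'   `write_vocab_json` returns `path` invisibly.
#' @export
write_vocab_json <- function(vocab, path) {
  jsonlite::write_json(list(codes = unclass(vocab)), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_vocab_json
#' @export
read_vocab_json <- function(path) {
  label_vocab(jsonlite::read_json(path, simplifyVector = TRUE)$codes)
}
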
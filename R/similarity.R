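#' @useDynLib posim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Standard amino acid alphabet
#'
#' The 20 standard one-letter amino acid codes, and the ambiguity/rare codes
#' accepted in input sequences (which carry no similarity evidence under the
#' identity measure).
#'
#' @format Character vectors.
#' @name aa_alphabet
#' @keywords internal
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_AMBIGUOUS <- c("X", "B", "Z", "U", "O")

#' Load a residue similarity measure
#'
#' Builds the residue-pair scoring function used in fragment comparison.
#' `"identity"` scores 1 for two equal standard residues and 0 otherwise;
#' ambiguity codes (X, B, Z, U, O) score 0 against everything, including
#' themselves, because an uncertain residue carries no evidence of local
#' similarity.  Alternatively a path to a substitution matrix in NCBI text
#' format (e.g. BLOSUM62) can be given; its values are used verbatim.
#'
#' @param spec Either the string `"identity"` or a path to an NCBI-format
#'   substitution matrix file.
#' @return An object of class `residue_similarity` with fields `kind`
#'   (`"identity"` or `"matrix"`) and `values`, a symmetric numeric matrix
#'   with residue dimnames.
#' @examples
#' sim <- load_similarity("identity")
#' sim$values["A", "A"]  # 1
#' sim$values["A", "C"]  # 0
#' sim$values["X", "X"]  # 0: ambiguity carries no evidence
#' @export
load_similarity <- function(spec = "identity") {
  if (inherits(spec, "residue_similarity")) return(spec)
  if (!is.character(spec) || length(spec) != 1L)
    stop("similarity spec must be \"identity\" or a matrix file path")
  if (identical(spec, "identity")) {
    alphabet <- c(AA_STANDARD, AA_AMBIGUOUS)
    values <- matrix(0, length(alphabet), length(alphabet),
                     dimnames = list(alphabet, alphabet))
    values[cbind(AA_STANDARD, AA_STANDARD)] <- 1
    out <- list(kind = "identity", values = values)
  } else {
    values <- read_substitution_matrix(spec)
    out <- list(kind = "matrix", values = values)
  }
  class(out) <- "residue_similarity"
  out
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text layout used by the NCBI BLAST distribution
#' (`#` comment lines, a header row of residue codes, one labelled row per
#' residue).  The matrix must be complete and symmetric.
#'
#' @param path Path to the matrix file.
#' @return A symmetric numeric matrix with residue dimnames.
#' @keywords internal
read_substitution_matrix <- function(path) {
  if (!file.exists(path)) stop("substitution matrix file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("substitution matrix file is empty: ", path)
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  body <- lines[-1L]
  if (length(body) != length(header))
    stop("substitution matrix is incomplete: ", length(header),
         " residues in header but ", length(body), " rows")
  values <- matrix(NA_real_, length(header), length(header),
                   dimnames = list(header, header))
  for (line in body) {
    tokens <- strsplit(trimws(line), "\\s+")[[1L]]
    res <- tokens[[1L]]
    if (!res %in% header)
      stop("substitution matrix row '", res, "' missing from header")
    vals <- suppressWarnings(as.numeric(tokens[-1L]))
    if (length(vals) != length(header) || anyNA(vals))
      stop("malformed substitution matrix row for residue '", res, "'")
    values[res, ] <- vals
  }
  if (anyNA(values)) {
    missing <- rownames(values)[apply(values, 1L, anyNA)]
    stop("substitution matrix missing rows for: ",
         paste(missing, collapse = ", "))
  }
  if (!isSymmetric(unname(values)))
    stop("substitution matrix is not symmetric: ", path)
  values
}

#' Encode a residue string as 0-based indices into a similarity alphabet
#'
#' @param residues A single string of residues.
#' @param similarity A `residue_similarity` object.
#' @param id Sequence id used in error messages.
#' @return Integer vector of 0-based codes.
#' @keywords internal
encode_residues <- function(residues, similarity, id = "?") {
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  idx <- match(chars, rownames(similarity$values))
  if (anyNA(idx)) {
    bad <- sort(unique(chars[is.na(idx)]))
    stop("sequence '", id, "' contains residue(s) not covered by the ",
         "similarity measure: ", paste(bad, collapse = ", "))
  }
  idx - 1L
}
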
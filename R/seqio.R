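#' Read amino acid sequences from a FASTA file
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines).  Ids are
#' taken as the header token before the first whitespace, matching UniProt
#' conventions; residues are uppercased.  Duplicate ids and empty sequences
#' are hard errors.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector: names are sequence ids, values are
#'   uppercase residue strings.  Order follows the file.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 some description", "acde"), f)
#' read_fasta(f)  # c(P1 = "ACDE")
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for id: ", paste(ids[empty], collapse = ", "))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sequence id: ", paste(dup, collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of residue strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences), length(sequences) >= 1L,
            !is.null(names(sequences)))
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Construct a protein x ligand-class interaction table
#'
#' @param member Binary matrix (0/1), rows proteins, columns ligand classes,
#'   with dimnames.
#' @return An object of class `interaction_table` with fields `protein_ids`,
#'   `ligand_ids` and the binary `member` matrix.  `member[k, C]` is the
#'   class weight a_k(C) of training protein k for ligand class C; the
#'   complement weight is b_k(C) = 1 - member[k, C] (absence of a reported
#'   interaction is a conditionally negative example).
#' @export
interaction_table <- function(member) {
  member <- as.matrix(member)
  if (is.null(rownames(member)) || is.null(colnames(member)))
    stop("interaction matrix must have protein row names and ligand column names")
  if (!all(member %in% c(0, 1)))
    stop("interaction matrix cells must be 0 or 1")
  storage.mode(member) <- "integer"
  dup <- unique(rownames(member)[duplicated(rownames(member))])
  if (length(dup)) stop("duplicate protein id: ", paste(dup, collapse = ", "))
  dup <- unique(colnames(member)[duplicated(colnames(member))])
  if (length(dup)) stop("duplicate ligand id: ", paste(dup, collapse = ", "))
  structure(list(protein_ids = rownames(member),
                 ligand_ids = colnames(member),
                 member = member),
            class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("interaction_table:", length(x$protein_ids), "proteins x",
      length(x$ligand_ids), "ligand classes,",
      sum(x$member), "positive pairs\n")
  invisible(x)
}

#' Read protein-ligand interaction labels
#'
#' Two dialects are supported.  `wide`: a tab-separated matrix with a header
#' row of ligand ids, one row per protein (id in the first column) and 0/1
#' cells.  `long`: a headerless two-column TSV of positive
#' (protein_id, ligand_id) pairs; any pair not listed is a conditionally
#' negative example and becomes 0.
#'
#' Ligand classes with fewer than `min_class_size` member proteins are
#' dropped (reported via a message); proteins left without any class are
#' retained as complement-only examples.
#'
#' @param path Path to the TSV file.
#' @param dialect `"wide"` or `"long"`.
#' @param min_class_size Minimum number of member proteins a ligand class
#'   must have to be retained (default 5).
#' @return An [interaction_table()].
#' @export
read_interactions <- function(path, dialect = c("wide", "long"),
                              min_class_size = 5L) {
  dialect <- match.arg(dialect)
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("interaction file not found: ", path)
  if (dialect == "wide") {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("wide interaction table needs >= 2 columns")
    member <- as.matrix(df[, -1L, drop = FALSE])
    rownames(member) <- as.character(df[[1L]])
    if (!all(member %in% c(0, 1)))
      stop("wide interaction table cells must be 0 or 1")
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) != 2L)
      stop("long interaction list must have exactly two columns")
    proteins <- unique(as.character(df[[1L]]))
    ligands <- unique(as.character(df[[2L]]))
    member <- matrix(0L, length(proteins), length(ligands),
                     dimnames = list(proteins, ligands))
    member[cbind(as.character(df[[1L]]), as.character(df[[2L]]))] <- 1L
  }
  filter_classes(interaction_table(member), min_class_size)
}

#' Drop ligand classes smaller than a minimum size
#'
#' Classes need enough member proteins for a reliable class/complement
#' contrast; the default minimum is five.  Filtering is idempotent.
#'
#' @param table An [interaction_table()].
#' @param min_class_size Minimum member count per retained class.
#' @return The filtered `interaction_table`.  Errors if no class survives.
#' @export
filter_classes <- function(table, min_class_size = 5L) {
  stopifnot(inherits(table, "interaction_table"), min_class_size >= 1L)
  sizes <- colSums(table$member)
  drop <- sizes < min_class_size
  if (any(drop))
    message("dropping ", sum(drop), " ligand class(es) with < ",
            min_class_size, " members: ",
            paste(table$ligand_ids[drop], collapse = ", "))
  if (all(drop))
    stop("no ligand class with at least ", min_class_size,
         " member proteins remains after filtering")
  interaction_table(table$member[, !drop, drop = FALSE])
}

#' Check that every protein in an interaction table has a sequence
#' @keywords internal
check_sequences_cover <- function(sequences, table) {
  missing <- setdiff(table$protein_ids, names(sequences))
  if (length(missing))
    stop("interaction table references id(s) absent from the sequence set: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
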
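#' Fragment comparison configuration
#'
#' Bundles the fragment length F and the residue similarity measure used in
#' positional scoring.  F = 7 emphasises the signal of individual residues;
#' F = 30 captures more distant inter-positional dependencies and is the
#' default.
#'
#' @param F Fragment length in residues (positive integer).
#' @param similarity A similarity spec accepted by [load_similarity()], or a
#'   `residue_similarity` object.
#' @return An object of class `fragment_config`.
#' @export
fragment_config <- function(F = 30L, similarity = "identity") {
  F <- as.integer(F)
  if (length(F) != 1L || is.na(F) || F < 1L)
    stop("fragment length F must be a single integer >= 1")
  structure(list(F = F, similarity = load_similarity(similarity)),
            class = "fragment_config")
}

#' Similarity rate of one window pair
#'
#' Sums residue similarities over the length-F ungapped window starting at
#' query position `i` against the training window starting at `i + h`.
#' Both windows must lie fully inside their sequences; coordinates are
#' 1-based inclusive.
#'
#' @param query,training Residue strings (a named length-1 character vector
#'   or plain string).
#' @param i Window start in the query (1-based).
#' @param h Integer shift between query and training coordinates.
#' @param cfg A [fragment_config()].
#' @return The summed similarity of the two fragments; under identity an
#'   integer in `[0, F]`.
#' @export
window_rate <- function(query, training, i, h, cfg = fragment_config()) {
  stopifnot(inherits(cfg, "fragment_config"))
  q <- encode_residues(unname(query[[1L]]), cfg$similarity,
                       id = names(query)[1L] %||% "query")
  k <- encode_residues(unname(training[[1L]]), cfg$similarity,
                       id = names(training)[1L] %||% "training")
  F <- cfg$F
  if (i < 1L || i + F - 1L > length(q) || i + h < 1L ||
      i + h + F - 1L > length(k))
    stop("inadmissible window: i = ", i, ", h = ", h, ", F = ", F,
         " for sequence lengths ", length(q), " and ", length(k))
  j <- i:(i + F - 1L)
  sum(cfg$similarity$values[cbind(q[j] + 1L, k[j + h] + 1L)])
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || is.na(a)) b else a
}

#' Positional similarity scores of a query against one training sequence
#'
#' Every position p of the query receives the maximum window rate over all
#' ungapped length-F window pairs, at all shifts, that cover p and fit fully
#' inside both sequences.  If no admissible window covers p — in particular
#' whenever either sequence is shorter than F — the score is 0 (no
#' evidence).  Under identity similarity every score is an integer in
#' `[0, F]`.
#'
#' @param query,training Residue strings.
#' @param cfg A [fragment_config()].
#' @return Numeric vector of length `nchar(query)`; attributes `query_id`
#'   and `training_id` carry the sequence names when present.
#' @export
positional_scores <- function(query, training, cfg = fragment_config()) {
  stopifnot(inherits(cfg, "fragment_config"))
  qid <- names(query)[1L] %||% "query"
  kid <- names(training)[1L] %||% "training"
  q <- encode_residues(unname(query[[1L]]), cfg$similarity, id = qid)
  k <- encode_residues(unname(training[[1L]]), cfg$similarity, id = kid)
  S <- posim_kernel(q, k, cfg$similarity$values, cfg$F)
  structure(S, query_id = qid, training_id = kid)
}

#' Positional score stack of a query against a training set
#'
#' @param query Residue string of the test protein.
#' @param training Named character vector of training sequences.  For
#'   cross-validation the query must already be excluded by the caller.
#' @return An m x n numeric matrix (m query positions, n training
#'   sequences), column k holding [positional_scores()] against training
#'   sequence k, in training order.  Attribute `query_id` names the query.
#' @inheritParams positional_scores
#' @export
score_stack <- function(query, training, cfg = fragment_config()) {
  stopifnot(inherits(cfg, "fragment_config"))
  if (length(training) == 0L) stop("training set is empty")
  if (is.null(names(training))) stop("training sequences must be named")
  qid <- names(query)[1L] %||% "query"
  q <- encode_residues(unname(query[[1L]]), cfg$similarity, id = qid)
  S <- vapply(names(training), function(kid) {
    k <- encode_residues(unname(training[[kid]]), cfg$similarity, id = kid)
    posim_kernel(q, k, cfg$similarity$values, cfg$F)
  }, numeric(length(q)))
  S <- matrix(S, nrow = length(q), ncol = length(training),
              dimnames = list(NULL, names(training)))
  structure(S, query_id = qid)
}
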
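#' Integrated per-position class scores
#'
#' Combines the positional scores of a query against n training sequences
#' into one score per position for a given ligand class.  With binary class
#' weights `a` (1 = class member) and complement weights `b = 1 - a`,
#' position p scores
#' \deqn{t_p = \frac{\sum_k S_{pk}(a_k - b_k)}{\sum_k S_{pk}(a_k + b_k)},}
#' a signed fraction in `[-1, 1]`: +1 when all local similarity at p points
#' at class members, -1 when it all points at the complement.  Positions
#' with no evidence at all (zero denominator) score 0, the indefinite value.
#'
#' Negative positional scores (possible under substitution-matrix
#' similarity) are clamped to 0 with a warning, preserving the `[-1, 1]`
#' range.
#'
#' @param S Score stack: an m x n matrix from [score_stack()], or a single
#'   row (numeric vector of length n) for one position.
#' @param a Binary class membership weights of the n training sequences.
#' @param b Binary complement weights; defaults to `1 - a`.
#' @param allow_real_weights If `FALSE` (default), weights are validated to
#'   be binary and mutually exclusive.
#' @return Numeric vector of integrated scores, one per position.
#' @export
integrated_position_scores <- function(S, a, b = 1 - a,
                                       allow_real_weights = FALSE) {
  if (is.vector(S)) S <- matrix(S, nrow = 1L)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (ncol(S) != length(a) || length(a) != length(b))
    stop("length mismatch: ", ncol(S), " score columns vs ", length(a),
         " class weights and ", length(b), " complement weights")
  if (!allow_real_weights &&
      (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)) || !all(a + b == 1)))
    stop("class/complement weights must be binary and mutually exclusive ",
         "(a_k + b_k = 1)")
  if (any(S < 0)) {
    warning("negative positional scores clamped to 0 before integration")
    S <- pmax(S, 0)
  }
  num <- as.vector(S %*% (a - b))
  den <- as.vector(S %*% (a + b))
  ifelse(den == 0, 0, num / den)
}

#' Arcsine-average of per-position scores
#'
#' Averages the m integrated positional scores on the arcsine scale,
#' \eqn{t = \sin(\frac{1}{m}\sum_p \arcsin t_p)}, a variance-stabilising
#' average that respects the `[-1, 1]` bounds.
#'
#' @param tp Numeric vector of per-position scores in `[-1, 1]`.
#' @return A single value in `[-1, 1]`.
#' @export
arcsine_average <- function(tp) {
  if (length(tp) == 0L) stop("no positional scores to average")
  if (any(!is.finite(tp)) || any(tp < -1 | tp > 1))
    stop("positional scores must lie in [-1, 1]")
  sin(mean(asin(tp)))
}

#' A priori class score
#'
#' The dataset-level class/complement imbalance,
#' \eqn{t_0 = (\sum_k a_k - \sum_k b_k) / (\sum_k a_k + \sum_k b_k)}; with
#' binary weights this is (class size - complement size) / n.  It is the
#' baseline the classification statistic subtracts.
#'
#' @inheritParams integrated_position_scores
#' @return A single value in `[-1, 1]`.
#' @export
prior_score <- function(a, b = 1 - a) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0L || length(a) != length(b))
    stop("need n >= 1 matching class and complement weights")
  den <- sum(a) + sum(b)
  if (den == 0) stop("all weights zero: empty training set")
  (sum(a) - sum(b)) / den
}

#' Classification statistic B(C)
#'
#' Combines the averaged score t with the a priori score t0 as
#' \eqn{B = (t - t_0) / (1 - t\,t_0)}, the hyperbolic-tangent-style
#' composition that maps `[-1, 1] x (-1, 1)` back onto `[-1, 1]`.  B close
#' to +1 indicates class membership, close to -1 the complement, and near 0
#' an indefinite result.  When t and t0 sit at the same pole
#' (|1 - t*t0| below 1e-12) the result is defined as 0; floating-point
#' overshoot is clamped to `[-1, 1]`.
#'
#' @param t Averaged score(s) in `[-1, 1]`.
#' @param t0 A priori score(s) in `[-1, 1]`.
#' @return B value(s) in `[-1, 1]`, recycled over the longer argument.
#' @examples
#' classify(1, 0)    #  1: certain class membership
#' classify(-1, 0)   # -1: certain complement
#' classify(0.8, 0.5)  # 0.5
#' @export
classify <- function(t, t0) {
  if (any(!is.finite(t)) || any(t < -1 | t > 1) ||
      any(!is.finite(t0)) || any(t0 < -1 | t0 > 1))
    stop("t and t0 must lie in [-1, 1]")
  den <- 1 - t * t0
  B <- ifelse(abs(den) < 1e-12, 0, (t - t0) / den)
  pmin(1, pmax(-1, B))
}

#' Predict ligand-class membership of a query protein
#'
#' Scores the query against every training sequence once (the score stack),
#' then evaluates the naive-Bayes-style statistic B(C) for each requested
#' ligand class.  Classes with no member or no complement protein in the
#' training set are skipped with a warning.
#'
#' @param query_id Id of the test protein; must be present in `sequences`
#'   and absent from the interaction table (remove it first for
#'   cross-validation).
#' @param sequences Named character vector covering the query and all
#'   training proteins.
#' @param interactions An [interaction_table()] over the training proteins.
#' @param cfg A [fragment_config()].
#' @param classes Ligand ids to evaluate; default all classes in the table.
#' @param details If `TRUE`, attach the per-class t_p vectors as attribute
#'   `tp`.
#' @return A data frame with one row per evaluated class: `query_id`,
#'   `ligand_id`, `t`, `t0`, `B`, `n_class`, `n_complement`.
#' @export
predict_ligands <- function(query_id, sequences, interactions,
                            cfg = fragment_config(), classes = NULL,
                            details = FALSE) {
  stopifnot(inherits(interactions, "interaction_table"),
            inherits(cfg, "fragment_config"))
  if (!query_id %in% names(sequences))
    stop("query id '", query_id, "' not found in the sequence set")
  if (query_id %in% interactions$protein_ids)
    stop("query id '", query_id, "' is still among the training proteins; ",
         "remove it from the interaction table first")
  check_sequences_cover(sequences, interactions)
  if (is.null(classes)) classes <- interactions$ligand_ids
  unknown <- setdiff(classes, interactions$ligand_ids)
  if (length(unknown))
    stop("unknown ligand class(es): ", paste(unknown, collapse = ", "))

  training <- sequences[interactions$protein_ids]
  S <- score_stack(sequences[query_id], training, cfg)

  rows <- vector("list", length(classes))
  tps <- list()
  skipped <- character(0)
  for (ci in seq_along(classes)) {
    C <- classes[[ci]]
    a <- interactions$member[, C]
    n_class <- sum(a)
    n_comp <- length(a) - n_class
    if (n_class == 0L || n_comp == 0L) {
      skipped <- c(skipped, C)
      next
    }
    tp <- integrated_position_scores(S, a)
    t <- arcsine_average(tp)
    t0 <- prior_score(a)
    rows[[ci]] <- data.frame(query_id = query_id, ligand_id = C,
                             t = t, t0 = t0, B = classify(t, t0),
                             n_class = n_class, n_complement = n_comp,
                             stringsAsFactors = FALSE)
    if (details) tps[[C]] <- tp
  }
  if (length(skipped))
    warning("skipped class(es) with empty class or complement: ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out))
    out <- data.frame(query_id = character(0), ligand_id = character(0),
                      t = numeric(0), t0 = numeric(0), B = numeric(0),
                      n_class = integer(0), n_complement = integer(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (details) attr(out, "tp") <- tps
  out
}
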
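#' Leave-one-out cross-validation over a labelled dataset
#'
#' Each protein in the interaction table is in turn removed from the
#' training set entirely (its whole label row), treated as the test
#' protein, and scored against every ligand class that remains valid —
#' non-empty class and non-empty complement after the removal.  Each
#' evaluated (protein, class) pair yields one labelled score: the statistic
#' B and the held-out protein's true membership label.
#'
#' Classes invalidated in a fold contribute no pair for that fold; they are
#' reported once, in a warning, rather than given a default score.
#'
#' @param sequences Named character vector covering all proteins in the
#'   table.
#' @param interactions An [interaction_table()].
#' @param cfg A [fragment_config()].
#' @return A data frame with columns `query_id`, `ligand_id`, `B`, `label`
#'   (1 if the held-out protein is a member of the class, else 0), ordered
#'   by protein then class.
#' @export
loocv <- function(sequences, interactions, cfg = fragment_config()) {
  stopifnot(inherits(interactions, "interaction_table"),
            inherits(cfg, "fragment_config"))
  check_sequences_cover(sequences, interactions)
  proteins <- interactions$protein_ids
  if (length(proteins) < 2L)
    stop("leave-one-out needs at least two proteins")

  folds <- vector("list", length(proteins))
  skipped <- character(0)
  for (pi in seq_along(proteins)) {
    held <- proteins[[pi]]
    fold_tab <- interaction_table(
      interactions$member[setdiff(proteins, held), , drop = FALSE])
    pred <- withCallingHandlers(
      predict_ligands(held, sequences, fold_tab, cfg),
      warning = function(w) {
        if (grepl("skipped class", conditionMessage(w))) {
          skipped <<- c(skipped, conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      })
    if (nrow(pred) == 0L) {
      folds[[pi]] <- NULL
      next
    }
    pred$label <- unname(interactions$member[held, pred$ligand_id])
    folds[[pi]] <- pred[, c("query_id", "ligand_id", "B", "label")]
  }
  if (length(skipped))
    warning("classes skipped in ", length(skipped), " fold(s): ",
            paste(unique(sub("^.*complement: ", "", skipped)),
                  collapse = ", "))
  out <- do.call(rbind, folds[!vapply(folds, is.null, logical(1L))])
  if (is.null(out))
    out <- data.frame(query_id = character(0), ligand_id = character(0),
                      B = numeric(0), label = integer(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tie-aware ROC curve and AUC
#'
#' Computes the area under the ROC curve as the normalised Mann-Whitney U
#' statistic with average ranks, so tied scores count 0.5 — the estimator
#' is independent of sort stability.  The curve is the tie-aware step
#' function: one vertex per distinct score threshold, from (0, 0) to
#' (1, 1).
#'
#' @param B Numeric scores (higher = more class-like), or a data frame with
#'   columns `B` and `label` as returned by [loocv()].
#' @param labels Binary labels (1 = positive); ignored when `B` is a data
#'   frame.
#' @return An object of class `roc_result`: list with `auc`, `n_pos`,
#'   `n_neg` and `curve`, a data frame of (fpr, tpr) vertices.
#' @examples
#' roc_auc(c(0.9, 0.1), c(1, 0))$auc  # 1: perfect separation
#' @export
roc_auc <- function(B, labels = NULL) {
  if (is.data.frame(B)) {
    labels <- B$label
    B <- B$B
  }
  labels <- as.integer(labels)
  if (length(B) != length(labels) || length(B) == 0L)
    stop("scores and labels must be non-empty and of equal length")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: need at least one positive and one negative label")

  r <- rank(B)  # average ranks: ties count 0.5 in the U statistic
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(B, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1L)
  fp <- cumsum(labels[ord] == 0L)
  last <- !duplicated(B[ord], fromLast = TRUE)  # last index of each tie group
  curve <- data.frame(fpr = c(0, fp[last] / n_neg),
                      tpr = c(0, tp[last] / n_pos))
  structure(list(auc = auc, n_pos = n_pos, n_neg = n_neg, curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positive, %d negative pairs)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Per-class AUC summary of pooled LOOCV scores
#'
#' The pooled AUC over all (protein, class) pairs is the primary
#' performance estimate; per-class AUCs are a supplementary breakdown.
#' Classes whose labelled scores are single-class (all positive or all
#' negative) get `NA`.
#'
#' @param labeled A data frame from [loocv()].
#' @return A data frame with columns `ligand_id`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_by_class <- function(labeled) {
  stopifnot(is.data.frame(labeled),
            all(c("ligand_id", "B", "label") %in% names(labeled)))
  classes <- unique(labeled$ligand_id)
  do.call(rbind, lapply(classes, function(C) {
    sub <- labeled[labeled$ligand_id == C, ]
    res <- tryCatch(roc_auc(sub$B, sub$label), error = function(e) NULL)
    data.frame(ligand_id = C,
               auc = if (is.null(res)) NA_real_ else res$auc,
               n_pos = sum(sub$label == 1L), n_neg = sum(sub$label == 0L),
               stringsAsFactors = FALSE)
  }))
}

#' Randomly permute the protein label rows of an interaction table
#'
#' Breaks any association between sequences and class labels while keeping
#' the label-matrix margins intact — the standard negative control for
#' cross-validated performance estimates.
#'
#' @param interactions An [interaction_table()].
#' @param seed Integer seed for the permutation.
#' @return An `interaction_table` with the same proteins and classes but
#'   permuted label rows.
#' @export
permute_labels <- function(interactions, seed) {
  stopifnot(inherits(interactions, "interaction_table"))
  member <- interactions$member
  perm <- with_local_seed(seed, sample.int(nrow(member)))
  permuted <- member[perm, , drop = FALSE]
  rownames(permuted) <- rownames(member)
  interaction_table(permuted)
}
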
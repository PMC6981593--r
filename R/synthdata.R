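#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state,
#' so package randomness never disturbs the user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic family generator configuration
#'
#' Describes a set of protein families of diverged homologs whose ligand
#' specificity is carried either by whole-family membership
#' (`"family-linked"`: each family is one ligand class, the regime of
#' benchmark sets whose classes coincide with phylogeny) or by short
#' planted motifs cutting across families (`"motif-linked"`: the
#' kinase-like regime in which a few residues, not overall similarity,
#' determine specificity).
#'
#' @param n_families Number of families.
#' @param proteins_per_family Members per family.
#' @param seq_length Sequence length in residues.
#' @param family_divergence Per-site probability that a member's residue is
#'   resampled uniformly from the founder's (expected pairwise identity
#'   within a family is `(1 - d)^2 + small` resampling terms; see the
#'   methods vignette).
#' @param motif_length Length of each planted class motif (motif-linked
#'   mode).
#' @param motif_classes Number of ligand classes (motif-linked mode; in
#'   family-linked mode the classes are the families).
#' @param class_mode `"family-linked"` or `"motif-linked"`.
#' @param carriers_per_class Number of member proteins per ligand class in
#'   motif-linked mode; defaults to `proteins_per_family`.
#' @param label_noise Probability that each label cell is flipped.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_families = 4L, proteins_per_family = 8L,
                         seq_length = 300L, family_divergence = 0.2,
                         motif_length = 10L, motif_classes = 4L,
                         class_mode = c("family-linked", "motif-linked"),
                         carriers_per_class = NULL,
                         label_noise = 0, seed = 1L) {
  class_mode <- match.arg(class_mode)
  if (is.null(carriers_per_class)) carriers_per_class <- proteins_per_family
  cfg <- list(n_families = as.integer(n_families),
              proteins_per_family = as.integer(proteins_per_family),
              seq_length = as.integer(seq_length),
              family_divergence = as.numeric(family_divergence),
              motif_length = as.integer(motif_length),
              motif_classes = as.integer(motif_classes),
              class_mode = class_mode,
              carriers_per_class = as.integer(carriers_per_class),
              label_noise = as.numeric(label_noise),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_families >= 1L, proteins_per_family >= 1L, seq_length >= 1L,
              motif_length >= 1L, motif_classes >= 1L, carriers_per_class >= 1L,
              family_divergence >= 0, family_divergence <= 1,
              label_noise >= 0, label_noise <= 1)
    if (motif_length >= seq_length)
      stop("motif_length must be smaller than seq_length")
  })
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic protein dataset with known specificity structure
#'
#' Family founders are drawn uniformly over the 20 standard residues;
#' members are independent per-site mutants of their founder.  In
#' family-linked mode each family becomes one ligand class.  In
#' motif-linked mode each class is a random, family-independent set of
#' `carriers_per_class` proteins (classes are disjoint) and a
#' class-specific motif is implanted at a fixed position in the members'
#' sequences (no indels anywhere, matching the ungapped scoring model).  Remaining proteins
#' belong to no class and serve as complement-only examples.
#'
#' @param cfg A [synth_config()].
#' @return A list with `sequences` (named character vector),
#'   `interactions` (an [interaction_table()], unfiltered), and
#'   `ground_truth` (mode, per-protein family, family founder sequences,
#'   and in motif-linked mode the class motifs, their implant positions,
#'   and carrier ids).
#' @export
generate_synthetic <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$class_mode == "motif-linked" &&
      cfg$motif_classes * cfg$carriers_per_class >
        cfg$n_families * cfg$proteins_per_family)
    stop("more classes than assignable carriers: ", cfg$motif_classes,
         " classes of ", cfg$carriers_per_class, " carriers exceed ",
         cfg$n_families * cfg$proteins_per_family, " proteins")
  with_local_seed(cfg$seed, {
    n_prot <- cfg$n_families * cfg$proteins_per_family
    ids <- sprintf("F%02dP%02d",
                   rep(seq_len(cfg$n_families), each = cfg$proteins_per_family),
                   rep(seq_len(cfg$proteins_per_family), cfg$n_families))
    family <- rep(seq_len(cfg$n_families), each = cfg$proteins_per_family)
    within_idx <- rep(seq_len(cfg$proteins_per_family), cfg$n_families)

    seqs <- character(n_prot)
    founders <- character(cfg$n_families)
    for (f in seq_len(cfg$n_families)) {
      founder <- sample(AA_STANDARD, cfg$seq_length, replace = TRUE)
      founders[f] <- paste(founder, collapse = "")
      for (j in seq_len(cfg$proteins_per_family)) {
        res <- founder
        hit <- stats::runif(cfg$seq_length) < cfg$family_divergence
        if (any(hit))
          res[hit] <- sample(AA_STANDARD, sum(hit), replace = TRUE)
        seqs[(f - 1L) * cfg$proteins_per_family + j] <- paste(res, collapse = "")
      }
    }
    names(seqs) <- ids

    if (cfg$class_mode == "family-linked") {
      ligand_ids <- sprintf("L%02d", seq_len(cfg$n_families))
      member <- matrix(0L, n_prot, cfg$n_families,
                       dimnames = list(ids, ligand_ids))
      member[cbind(seq_len(n_prot), family)] <- 1L
      truth <- list(mode = "family-linked",
                    family = stats::setNames(family, ids),
                    founders = founders,
                    class_of_family = stats::setNames(ligand_ids,
                                                      seq_len(cfg$n_families)))
    } else {
      ligand_ids <- sprintf("L%02d", seq_len(cfg$motif_classes))
      member <- matrix(0L, n_prot, cfg$motif_classes,
                       dimnames = list(ids, ligand_ids))
      # evenly spaced, non-overlapping implant sites
      step <- cfg$seq_length %/% cfg$motif_classes
      if (step < cfg$motif_length)
        stop("seq_length too short to place ", cfg$motif_classes,
             " non-overlapping motifs of length ", cfg$motif_length)
      positions <- 1L + (seq_len(cfg$motif_classes) - 1L) * step
      motifs <- vapply(seq_len(cfg$motif_classes), function(c)
        paste(sample(AA_STANDARD, cfg$motif_length, replace = TRUE),
              collapse = ""), character(1L))
      # class membership independent of family: disjoint random carrier sets
      # of carriers_per_class proteins each; the rest stay complement-only
      pool <- sample.int(n_prot)
      carriers <- vector("list", cfg$motif_classes)
      for (c in seq_len(cfg$motif_classes)) {
        idx <- pool[((c - 1L) * cfg$carriers_per_class + 1L):
                    (c * cfg$carriers_per_class)]
        member[idx, c] <- 1L
        carriers[[c]] <- ids[idx]
        span <- positions[c]:(positions[c] + cfg$motif_length - 1L)
        for (i in idx) {
          res <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
          res[span] <- strsplit(motifs[[c]], "", fixed = TRUE)[[1L]]
          seqs[[i]] <- paste(res, collapse = "")
        }
      }
      names(motifs) <- ligand_ids
      names(positions) <- ligand_ids
      names(carriers) <- ligand_ids
      truth <- list(mode = "motif-linked",
                    family = stats::setNames(family, ids),
                    founders = founders,
                    motifs = motifs, positions = positions,
                    carriers = carriers)
    }

    if (cfg$label_noise > 0) {
      flip <- stats::runif(length(member)) < cfg$label_noise
      member[flip] <- 1L - member[flip]
    }

    list(sequences = seqs,
         interactions = interaction_table(member),
         ground_truth = truth)
  })
}
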
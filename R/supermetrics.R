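#' Least-squares (Kabsch) superposition
#'
#' Rigid-body superposition of point set `a` onto `b` minimising RMSD, with the
#' reflection corrected so the rotation is proper (determinant +1).
#'
#' @param a,b N x 3 coordinate matrices with matching rows, N >= 3.
#' @return A list of class `superposition`: `rotation` (3 x 3), `translation`
#'   (length 3, Angstroms), `rmsd`. The superposed copy of `a` is
#'   `a %*% t(rotation) + translation`.
#' @export
kabsch <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b) || ncol(a) != 3L || ncol(b) != 3L)
    stop("a and b must be N x 3 matrices of equal size")
  if (nrow(a) < 3L) stop("at least 3 points are required")
  out <- cpp_kabsch(a, b, TRUE)
  out$translation <- as.numeric(out$translation)
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

apply_superposition <- function(xyz, sp) {
  sweep(xyz %*% t(sp$rotation), 2L, -sp$translation)
}

# Residue correspondence by residue_index intersection.
corresponding_ca <- function(model, reference) {
  shared <- intersect(model$residue_index, reference$residue_index)
  if (length(shared) < 3L)
    stop("fewer than 3 corresponding residues between model and reference")
  list(m = model$ca_coords[match(shared, model$residue_index), , drop = FALSE],
       r = reference$ca_coords[match(shared, reference$residue_index), , drop = FALSE],
       shared = shared)
}

# Shared GDT/TM superposition search. Exhaustive subset enumeration is exact
# for small chains; above `exact_max` a fragment-seeded iterative-extension
# heuristic is used (seed lengths 4/8/16/L, stride 4, <= `max_rounds` rounds
# of superpose -> keep residues within cutoff -> re-superpose).
score_pair <- function(model, reference, cutoffs = c(1, 2, 4, 8),
                       exact_max = 12L, max_rounds = 10L) {
  co <- corresponding_ca(model, reference)
  l_ref <- length(reference)
  d0 <- tm_d0(l_ref)
  res <- cpp_score_pair(co$m, co$r, l_ref, cutoffs, d0,
                        nrow(co$m) <= exact_max, max_rounds)
  res$tm_score <- min(res$tm_score, 1)
  res$n_common <- nrow(co$m)
  res
}

# TM-score normalisation length scale, floored at 0.5 A for short chains.
tm_d0 <- function(l_ref) {
  if (l_ref <= 19) return(0.5)
  max(0.5, 1.24 * (l_ref - 15)^(1 / 3) - 1.8)
}

#' Global distance test total score (GDT-TS)
#'
#' Mean over the 1, 2, 4 and 8 Angstrom cutoffs of the maximal fraction of
#' corresponding Ca pairs that can be superposed within the cutoff. The
#' superposition search is exhaustive over residue subsets for chains of up to
#' `exact_max` residues and a documented fragment-seeded heuristic above that;
#' absolute agreement with any particular GDT implementation beyond the third
#' decimal is not claimed.
#'
#' @param model,reference [ca_structure()] objects; correspondence is by
#'   `residue_index` intersection (>= 3 shared residues required).
#' @param exact_max largest chain length scored by exhaustive subset
#'   enumeration.
#' @return GDT-TS fraction in \[0, 1\].
#' @export
gdt_ts <- function(model, reference, exact_max = 12L) {
  score_pair(model, reference, exact_max = exact_max)$gdt_ts
}

#' Template modelling score (TM-score)
#'
#' Maximum over the searched superpositions of
#' `mean_i 1 / (1 + (d_i / d0)^2)` with `d0 = 1.24 (L_ref - 15)^(1/3) - 1.8`
#' (floored at 0.5 A), normalised by the reference length `L_ref`; residues
#' missing from the correspondence are excluded from the sum but counted in
#' `L_ref`, mirroring the CASP treatment of unresolved residues.
#'
#' @inheritParams gdt_ts
#' @return TM-score in (0, 1\].
#' @export
tm_score <- function(model, reference, exact_max = 12L) {
  score_pair(model, reference, exact_max = exact_max)$tm_score
}

#' Optimal-superposition RMSD between two structures
#'
#' @inheritParams gdt_ts
#' @return RMSD in Angstroms over all corresponding Ca pairs.
#' @export
rmsd_after_superposition <- function(model, reference) {
  co <- corresponding_ca(model, reference)
  cpp_kabsch(co$m, co$r, FALSE)$rmsd
}

#' All similarity scores for a model/reference pair
#'
#' @inheritParams gdt_ts
#' @return A one-row tibble with `gdt_ts`, `tm_score` and `rmsd`.
#' @export
similarity_scores <- function(model, reference, exact_max = 12L) {
  sp <- score_pair(model, reference, exact_max = exact_max)
  tibble::tibble(gdt_ts = sp$gdt_ts, tm_score = sp$tm_score, rmsd = sp$rmsd)
}

#' Pairwise similarity matrix of a model pool
#'
#' @param pool a [model_pool()] with at least two models.
#' @param metric `"gdt_ts"` or `"tm_score"`.
#' @return Symmetric matrix with unit diagonal, dimnames = model ids.
#' @export
pairwise_matrix <- function(pool, metric = c("gdt_ts", "tm_score")) {
  metric <- match.arg(metric)
  stopifnot(inherits(pool, "model_pool"))
  ids <- names(pool$models)
  n <- length(ids)
  if (n < 2L) stop("pairwise matrix needs at least 2 models")
  out <- diag(1, n)
  dimnames(out) <- list(ids, ids)
  fn <- if (metric == "gdt_ts") gdt_ts else tm_score
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      v <- fn(pool$models[[i]], pool$models[[j]])
      out[i, j] <- out[j, i] <- v
    }
  }
  out
}
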
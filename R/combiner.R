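#' Neighbour-selection presets for model combination
#'
#' Two documented parameter sets are exposed: `"human"` collects models ranked
#' within the top 60 that have GDT-TS above 0.7 **or** RMSD below 3 A with
#' respect to the reference model, while `"server"` collects models with
#' GDT-TS above 0.6 with no rank or RMSD rule. Both cap the member set at 20.
#'
#' @param preset `"human"` or `"server"`.
#' @return A named list of `gdt_min`, `rmsd_max`, `top_n`, `cap`.
#' @export
combination_preset <- function(preset = c("human", "server")) {
  preset <- match.arg(preset)
  if (preset == "human")
    list(gdt_min = 0.7, rmsd_max = 3, top_n = 60, cap = 20)
  else
    list(gdt_min = 0.6, rmsd_max = 0, top_n = Inf, cap = 20)
}

#' Select the member set for consensus combination
#'
#' From the ranked pool, collects the models ranked within `top_n` whose
#' GDT-TS to the reference exceeds `gdt_min` or whose RMSD to the reference is
#' below `rmsd_max`, truncated to `cap` members in rank order. The reference
#' itself is never a member. An empty set is allowed (the hard-target failure
#' mode: no sufficiently similar neighbours exist).
#'
#' @param reference_id id of the reference (start) model; must be in the pool.
#' @param pool a [model_pool()].
#' @param ranking a [new_ranking()] over the pool.
#' @param gdt_min GDT-TS similarity gate (exclusive).
#' @param rmsd_max RMSD similarity gate in Angstroms (exclusive); 0 disables.
#' @param top_n only models ranked at or above this position qualify.
#' @param cap maximum number of members.
#' @return Character vector of member model ids in rank order.
#' @export
select_combination_set <- function(reference_id, pool, ranking,
                                   gdt_min = 0.7, rmsd_max = 3,
                                   top_n = 60, cap = 20) {
  stopifnot(reference_id %in% names(pool$models))
  ref <- pool$models[[reference_id]]
  cand <- ranking$model_id[ranking$rank <= top_n]
  cand <- setdiff(cand, reference_id)
  cand <- cand[cand %in% names(pool$models)]
  ok <- vapply(cand, function(id) {
    sp <- score_pair(pool$models[[id]], ref)
    sp$gdt_ts > gdt_min || (rmsd_max > 0 && sp$rmsd < rmsd_max)
  }, logical(1L))
  utils::head(cand[ok], cap)
}

#' Consensus candidate model by superpose-and-average
#'
#' Every member is superposed onto the reference by least squares over the
#' shared Ca correspondence and the candidate Ca trace is the unweighted mean
#' of the superposed coordinates, reference included. This Ca-averaging
#' construction replaces multi-template rebuilding with an external modelling
#' engine; the downstream acceptance gate is unchanged.
#'
#' @param reference a [ca_structure()] (the start model).
#' @param members list of [ca_structure()] objects sharing residue
#'   correspondence with the reference.
#' @return A [ca_structure()] on the reference's residue set (Ca only).
#' @export
consensus_combine <- function(reference, members) {
  if (length(members) == 0L) {
    warning("no members to combine; returning the reference unchanged")
    return(reference)
  }
  idx <- reference$residue_index
  acc <- reference$ca_coords
  cnt <- rep(1, length(idx))
  for (m in members) {
    co <- corresponding_ca(m, reference)
    sp <- cpp_kabsch(co$m, co$r, FALSE)
    fit <- sweep(co$m %*% t(sp$rotation), 2L, -as.numeric(sp$translation))
    at <- match(co$shared, idx)
    acc[at, ] <- acc[at, ] + fit
    cnt[at] <- cnt[at] + 1
  }
  ca_structure(acc / cnt, sequence = reference$sequence,
               residue_index = idx,
               target_id = paste0(reference$target_id, "_consensus"))
}

#' Acceptance gate for a consensus candidate
#'
#' The candidate is accepted when its GDT-TS to the start model is at least
#' `threshold`; otherwise it is rejected, signalling the caller to fall back
#' to refining the start model (refinement itself is out of scope here).
#'
#' @param candidate,reference [ca_structure()] objects.
#' @param threshold GDT-TS acceptance threshold.
#' @return `"accepted"` or `"rejected"`, with the measured GDT-TS in the
#'   `gdt_ts` attribute.
#' @export
accept_candidate <- function(candidate, reference, threshold = 0.9) {
  g <- gdt_ts(candidate, reference)
  structure(if (g >= threshold) "accepted" else "rejected", gdt_ts = g)
}

#' Replace a region of a model with the corresponding region of another
#'
#' The donor is superposed onto the kept model with the TM-score-optimal
#' superposition computed on the residues *outside* the region, then the Ca
#' trace inside the region is taken from the superposed donor and everything
#' outside it from the kept model (bit-for-bit). The geometry of the spliced
#' trace is checked and attached as the `geometry` attribute.
#'
#' @param keep model whose good regions are kept.
#' @param donor model donating the replacement region.
#' @param region length-2 integer vector, 1-based inclusive residue-index
#'   interval; must lie within both structures and must not cover the whole
#'   kept chain.
#' @return A [ca_structure()] with a `geometry` attribute
#'   (see [geometry_check()]).
#' @export
splice_regions <- function(keep, donor, region) {
  stopifnot(length(region) == 2L, region[1L] <= region[2L])
  inside <- function(s) s$residue_index >= region[1L] &
    s$residue_index <= region[2L]
  if (!any(inside(donor))) stop("region not present in the donor structure")
  if (all(inside(keep))) stop("region covers the whole kept chain")
  keep_out <- which(!inside(keep))
  sub <- function(s, sel) ca_structure(
    s$ca_coords[sel, , drop = FALSE],
    sequence = paste(strsplit(s$sequence, "")[[1L]][sel], collapse = ""),
    residue_index = s$residue_index[sel], target_id = s$target_id)
  sp <- score_pair(sub(donor, !inside(donor)), sub(keep, keep_out))
  rot <- sp$tm_rotation
  tr <- as.numeric(sp$tm_translation)
  donor_fit <- sweep(donor$ca_coords %*% t(rot), 2L, -tr)
  don_in <- which(inside(donor))
  idx <- c(keep$residue_index[keep_out], donor$residue_index[don_in])
  xyz <- rbind(keep$ca_coords[keep_out, , drop = FALSE],
               donor_fit[don_in, , drop = FALSE])
  seq1 <- c(strsplit(keep$sequence, "")[[1L]][keep_out],
            strsplit(donor$sequence, "")[[1L]][don_in])
  o <- order(idx)
  out <- ca_structure(xyz[o, , drop = FALSE],
                      sequence = paste(seq1[o], collapse = ""),
                      residue_index = idx[o],
                      target_id = paste0(keep$target_id, "_spliced"))
  attr(out, "geometry") <- geometry_check(out)
  out
}

#' Run the full combination protocol for one reference model
#'
#' Selects the member set, builds the consensus candidate, and applies the
#' acceptance gate.
#'
#' @inheritParams select_combination_set
#' @param acceptance_gdt GDT-TS acceptance threshold for the candidate.
#' @param preset optional [combination_preset()] name overriding the
#'   neighbour-selection parameters.
#' @return A list of class `combination_plan`: `reference_id`, `member_ids`,
#'   `acceptance` (`"accepted"`/`"rejected"`), `candidate_gdt`, `candidate`.
#' @export
combination_plan <- function(reference_id, pool, ranking, preset = NULL,
                             gdt_min = 0.7, rmsd_max = 3, top_n = 60,
                             cap = 20, acceptance_gdt = 0.9) {
  if (!is.null(preset)) {
    p <- combination_preset(preset)
    gdt_min <- p$gdt_min; rmsd_max <- p$rmsd_max
    top_n <- p$top_n; cap <- p$cap
  }
  ref <- pool$models[[reference_id]]
  members <- select_combination_set(reference_id, pool, ranking, gdt_min,
                                    rmsd_max, top_n, cap)
  candidate <- if (length(members))
    consensus_combine(ref, pool$models[members])
  else suppressWarnings(consensus_combine(ref, list()))
  verdict <- accept_candidate(candidate, ref, acceptance_gdt)
  structure(list(reference_id = reference_id, member_ids = members,
                 acceptance = as.character(verdict),
                 candidate_gdt = attr(verdict, "gdt_ts"),
                 candidate = candidate),
            class = "combination_plan")
}

#' @export
print.combination_plan <- function(x, ...) {
  cat(sprintf("<combination_plan> reference %s: %d member(s), %s (GDT-TS %.3f)\n",
              x$reference_id, length(x$member_ids), x$acceptance,
              x$candidate_gdt))
  invisible(x)
}
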
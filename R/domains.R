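#' Filter target-template alignment hits
#'
#' Discards template hits by E-value (> `evalue_max`), aligned-region length
#' (<= `min_aligned` target residues), or alignment coverage
#' (<= `min_coverage`). The survivors define the template-covered regions used
#' for domain parsing.
#'
#' @param hits data frame with columns `template_id`, `e_value`,
#'   `target_start`, `target_end`, `coverage` (and optionally `identity`).
#' @param evalue_max,min_aligned,min_coverage filter thresholds.
#' @return The retained rows as a tibble.
#' @export
filter_hits <- function(hits, evalue_max = 1, min_aligned = 40,
                        min_coverage = 0.5) {
  hits <- tibble::as_tibble(hits)
  need <- c("template_id", "e_value", "target_start", "target_end", "coverage")
  if (!all(need %in% names(hits)))
    stop("hit table must have columns: ", paste(need, collapse = ", "))
  if (any(hits$target_start > hits$target_end))
    stop("target_start must be <= target_end")
  if (any(hits$coverage < 0 | hits$coverage > 1))
    stop("coverage must lie in [0, 1]")
  alen <- hits$target_end - hits$target_start + 1L
  hits[hits$e_value <= evalue_max & alen > min_aligned &
         hits$coverage > min_coverage, , drop = FALSE]
}

#' Read / write a hit table as TSV
#' @param path file path (tab-separated, header row).
#' @return `read_hit_table()` returns a tibble.
#' @export
read_hit_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' @rdname read_hit_table
#' @param hits hit table.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# union of 1-based inclusive intervals, clipped to [1, L], sorted and merged
merge_intervals <- function(start, end, L) {
  start <- pmax(1L, as.integer(start))
  end <- pmin(L, as.integer(end))
  keep <- start <= end
  start <- start[keep]; end <- end[keep]
  if (!length(start)) return(cbind(start = integer(), end = integer()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out <- NULL
  for (k in seq_along(start)[-1L]) {
    if (start[k] <= me + 1L) me <- max(me, end[k])
    else { out <- rbind(out, c(ms, me)); ms <- start[k]; me <- end[k] }
  }
  out <- rbind(out, c(ms, me))
  colnames(out) <- c("start", "end")
  out
}

#' Parse domain segments from retained template hits
#'
#' The union of the retained hit intervals forms the template-based (TBM)
#' cover of the target. Each maximal uncovered region longer than
#' `fm_min_gap` residues becomes a template-free (FM) domain segment; shorter
#' uncovered gaps are absorbed into the flanking template-based cover (so that
#' every non-FM region is template-based). With no retained hits the whole
#' target is a single FM segment.
#'
#' @param L target sequence length.
#' @param retained hit table after [filter_hits()]; hit order is irrelevant.
#' @param fm_min_gap minimal uncovered length that counts as an FM domain.
#' @return A tibble of class `domain_segments` with columns `start`, `end`,
#'   `klass` (`"FM"`/`"TBM"`) tiling `[1, L]` without overlap.
#' @export
parse_domains <- function(L, retained, fm_min_gap = 40) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("L must be a positive integer")
  retained <- tibble::as_tibble(retained)
  if (nrow(retained) == 0L)
    return(new_domain_segments(1L, L, "FM"))
  cov <- merge_intervals(retained$target_start, retained$target_end, L)
  if (nrow(cov) == 0L) return(new_domain_segments(1L, L, "FM"))
  # uncovered gaps, including the two ends
  gs <- c(1L, cov[, "end"] + 1L)
  ge <- c(cov[, "start"] - 1L, L)
  fm <- cbind(start = gs, end = ge)[ge - gs + 1L > fm_min_gap & gs <= ge, ,
                                    drop = FALSE]
  # everything not FM is TBM (short gaps are absorbed into the cover)
  segs <- NULL
  pos <- 1L
  if (nrow(fm)) for (k in seq_len(nrow(fm))) {
    if (fm[k, "start"] > pos)
      segs <- rbind(segs, c(pos, fm[k, "start"] - 1L, 2L))
    segs <- rbind(segs, c(fm[k, "start"], fm[k, "end"], 1L))
    pos <- fm[k, "end"] + 1L
  }
  if (pos <= L) segs <- rbind(segs, c(pos, L, 2L))
  new_domain_segments(segs[, 1L], segs[, 2L],
                      c("FM", "TBM")[segs[, 3L]])
}

new_domain_segments <- function(start, end, klass) {
  out <- tibble::tibble(start = as.integer(start), end = as.integer(end),
                        klass = as.character(klass))
  class(out) <- c("domain_segments", class(out))
  out
}

#' Classify a target from its domain segments
#'
#' @param segments a [parse_domains()] result.
#' @return `"FM"` if all segments are template-free, `"TBM"` if all are
#'   template-based, `"FM_and_TBM"` otherwise.
#' @export
classify_target <- function(segments) {
  k <- unique(segments$klass)
  if (identical(k, "FM")) "FM" else if (identical(k, "TBM")) "TBM"
  else "FM_and_TBM"
}

#' Write domain segments as BED-like text
#'
#' Three columns `name start end` with the 1-based inclusive segments
#' converted to 0-based half-open coordinates on write.
#'
#' @param segments a [parse_domains()] result.
#' @param path output path.
#' @param name feature name column (the class label by default).
#' @return `path`, invisibly.
#' @export
write_domains_bed <- function(segments, path, name = segments$klass) {
  writeLines(sprintf("%s\t%d\t%d", name, segments$start - 1L, segments$end),
             path)
  invisible(path)
}
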
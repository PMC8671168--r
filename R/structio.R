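#' Ca-trace structure objects
#'
#' A `ca_structure` is the minimal representation of a protein tertiary
#' structure model used throughout the package: one Ca coordinate per residue,
#' the one-letter sequence, and 1-based residue indices (strictly increasing,
#' gaps allowed where residues were unresolved). Cb coordinates are optional;
#' wherever a Cb-based quantity is requested and Cb is absent (always true for
#' glycine), the Ca coordinate is used instead.
#'
#' @param ca_coords numeric L x 3 matrix of Ca coordinates in Angstroms.
#' @param sequence one-letter amino-acid string of length L (optional; a
#'   poly-alanine sequence is assumed when missing).
#' @param residue_index integer vector of 1-based residue numbers, strictly
#'   increasing. Defaults to `1:L`.
#' @param target_id identifier of the target the model belongs to.
#' @param cb_coords optional numeric L x 3 matrix of Cb coordinates.
#' @return An object of class `ca_structure`.
#' @export
ca_structure <- function(ca_coords, sequence = NULL, residue_index = NULL,
                         target_id = "target", cb_coords = NULL) {
  ca_coords <- as.matrix(ca_coords)
  storage.mode(ca_coords) <- "double"
  L <- nrow(ca_coords)
  if (L < 1L || ncol(ca_coords) != 3L)
    stop("ca_coords must be an L x 3 matrix with L >= 1")
  if (any(!is.finite(ca_coords))) stop("non-finite Ca coordinates")
  if (is.null(residue_index)) residue_index <- seq_len(L)
  residue_index <- as.integer(residue_index)
  if (length(residue_index) != L || any(diff(residue_index) <= 0L))
    stop("residue_index must be strictly increasing and match L")
  if (is.null(sequence)) sequence <- paste(rep("A", L), collapse = "")
  if (nchar(sequence) != L)
    stop("sequence length must equal the number of coordinate rows")
  if (!is.null(cb_coords)) {
    cb_coords <- as.matrix(cb_coords)
    storage.mode(cb_coords) <- "double"
    if (!identical(dim(cb_coords), dim(ca_coords)) || any(!is.finite(cb_coords)))
      stop("cb_coords must be a finite L x 3 matrix")
  }
  structure(
    list(target_id = target_id, sequence = sequence,
         residue_index = residue_index, ca_coords = ca_coords,
         cb_coords = cb_coords),
    class = "ca_structure")
}

#' @export
print.ca_structure <- function(x, ...) {
  cat(sprintf("<ca_structure> target %s: %d residues (index %d..%d)%s\n",
              x$target_id, length(x$residue_index), min(x$residue_index),
              max(x$residue_index),
              if (is.null(x$cb_coords)) ", Ca only" else ", Ca+Cb"))
  invisible(x)
}

#' @export
length.ca_structure <- function(x) length(x$residue_index)

#' Read a model structure from a PDB file
#'
#' Parses ATOM records via [bio3d::read.pdb()] and reduces them to a Ca trace:
#' first model, first chain (by default), first alternate location. Residues
#' lacking a Ca atom are dropped with a warning and leave a gap in
#' `residue_index`. Hetero residues are ignored.
#'
#' @param path path to a PDB file containing ATOM records.
#' @param chain chain identifier; `NULL` keeps the first chain encountered.
#' @param target_id identifier stored on the structure; defaults to the file
#'   base name.
#' @return A [ca_structure()].
#' @export
read_model <- function(path, chain = NULL, target_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(target_id))
    target_id <- sub("\\.(pdb|ent)$", "", basename(path))
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, multi = FALSE)),
                  error = function(e) stop("no parseable ATOM records in ", path))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no parseable ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain ", chain, " not present in ", path)
  # first altloc per (residue, element)
  key <- paste(at$resno, at$elety)
  at <- at[!duplicated(key), , drop = FALSE]
  resno <- sort(unique(at$resno))
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca <- ca[match(intersect(resno, ca$resno), ca$resno), , drop = FALSE]
  missing_ca <- setdiff(resno, ca$resno)
  if (length(missing_ca))
    warning(sprintf("%d residue(s) without a Ca atom dropped (index gap kept): %s",
                    length(missing_ca),
                    paste(utils::head(missing_ca, 5L), collapse = ",")))
  if (nrow(ca) == 0L) stop("zero residues with Ca atoms in ", path)
  cb <- at[at$elety == "CB", , drop = FALSE]
  cb_coords <- NULL
  if (nrow(cb) > 0L) {
    cb_coords <- as.matrix(ca[, c("x", "y", "z")])
    hit <- match(ca$resno, cb$resno)
    ok <- !is.na(hit)
    cb_coords[ok, ] <- as.matrix(cb[hit[ok], c("x", "y", "z")])
  }
  aa1 <- suppressWarnings(bio3d::aa321(ca$resid))
  aa1[is.na(aa1) | nchar(aa1) != 1L] <- "X"
  ca_structure(as.matrix(ca[, c("x", "y", "z")]),
               sequence = paste(aa1, collapse = ""),
               residue_index = ca$resno, target_id = target_id,
               cb_coords = cb_coords)
}

#' Write a Ca trace to a PDB file
#'
#' Emits one ATOM record per residue (Ca only) through [bio3d::write.pdb()],
#' with a header REMARK flagging the model as a Ca trace.
#'
#' @param s a [ca_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(s, path) {
  stopifnot(inherits(s, "ca_structure"))
  L <- length(s)
  aa3 <- bio3d::aa123(strsplit(s$sequence, "")[[1L]])
  aa3[is.na(aa3)] <- "ALA"
  bio3d::write.pdb(file = path, xyz = as.numeric(t(s$ca_coords)),
                   type = rep("ATOM", L), resno = s$residue_index,
                   resid = aa3, eleno = seq_len(L), elety = rep("CA", L),
                   chain = rep("A", L))
  header <- "REMARK  CA TRACE WRITTEN BY DISTRANK"
  txt <- readLines(path)
  writeLines(c(header, txt), path)
  invisible(path)
}

cb_or_ca <- function(s) if (is.null(s$cb_coords)) s$ca_coords else s$cb_coords

#' Inter-residue distance map of a structure
#'
#' Euclidean pairwise distance matrix over Ca (or Cb, Ca for residues without
#' one) coordinates; the in-model analogue of a predicted distance map.
#'
#' @param s a [ca_structure()].
#' @param scheme `"ca"` or `"cb"`; `"cb"` falls back to Ca where Cb is absent.
#' @return A symmetric L x L numeric matrix (Angstroms) with zero diagonal,
#'   dimnames set to `residue_index`.
#' @export
distance_map <- function(s, scheme = c("ca", "cb")) {
  scheme <- match.arg(scheme)
  xyz <- if (scheme == "ca") s$ca_coords else cb_or_ca(s)
  m <- as.matrix(stats::dist(xyz))
  diag(m) <- 0
  dimnames(m) <- list(s$residue_index, s$residue_index)
  m
}

check_distance_map <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance map must be square")
  if (any(!is.finite(m))) stop("distance map has non-finite entries")
  if (any(m < 0)) stop("distance map has negative entries")
  if (max(abs(m - t(m))) > 1e-8) stop("distance map must be symmetric")
  if (any(abs(diag(m)) > 1e-8)) stop("distance map diagonal must be zero")
  m
}

#' Read / write a distance map as whitespace-delimited text
#'
#' @param path file path; an L x L whitespace-delimited numeric matrix.
#' @return `read_distance_map()` returns the validated L x L matrix.
#' @export
read_distance_map <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  check_distance_map(m)
}

#' @rdname read_distance_map
#' @param m distance map matrix.
#' @export
write_distance_map <- function(m, path) {
  utils::write.table(format(m, trim = TRUE, digits = 6), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Sequence-separation windows (CASP convention).
separation_bounds <- function(separation_class) {
  switch(separation_class,
         short  = c(6L, 11L),
         medium = c(12L, 23L),
         long   = c(24L, .Machine$integer.max),
         any    = c(1L, .Machine$integer.max),
         stop("unknown separation class: ", separation_class))
}

new_contact_set <- function(i, j, score, separation_class) {
  out <- tibble::tibble(i = as.integer(i), j = as.integer(j),
                        score = as.numeric(score))
  if (any(out$i >= out$j)) stop("contact pairs must satisfy i < j")
  if (anyDuplicated(paste(out$i, out$j))) stop("duplicate contact pairs")
  b <- separation_bounds(separation_class)
  sep <- out$j - out$i
  if (any(sep < b[1L] | sep > b[2L]))
    stop("pair separation inconsistent with class ", separation_class)
  out <- out[order(out$i, out$j), , drop = FALSE]
  attr(out, "separation_class") <- separation_class
  class(out) <- c("contact_set", class(out))
  out
}

#' Contacts of a distance map
#'
#' Residue pairs whose map distance is at or below `threshold`, restricted to a
#' sequence-separation class (CASP windows: short 6-11, medium 12-23,
#' long 24 and above, or `any`). Scores are all 1 (observed contacts).
#'
#' @param m distance map (symmetric, zero diagonal). Row/column names, when
#'   present, are taken as residue indices.
#' @param threshold contact distance cutoff in Angstroms.
#' @param separation_class one of `"short"`, `"medium"`, `"long"`, `"any"`.
#' @return A `contact_set` tibble with columns `i`, `j`, `score`.
#' @export
contacts_from_map <- function(m, threshold = 8, separation_class = "long") {
  m <- check_distance_map(m)
  b <- separation_bounds(separation_class)
  idx <- if (is.null(rownames(m))) seq_len(nrow(m)) else
    as.integer(rownames(m))
  hit <- which(upper.tri(m) & m <= threshold, arr.ind = TRUE)
  if (nrow(hit)) {
    sep <- abs(idx[hit[, 2L]] - idx[hit[, 1L]])
    hit <- hit[sep >= b[1L] & sep <= b[2L], , drop = FALSE]
  }
  new_contact_set(idx[hit[, 1L]], idx[hit[, 2L]], rep(1, nrow(hit)),
                  separation_class)
}

#' Read / write contacts in CASP RR-style format
#'
#' Lines are `i j d1 d2 p` (1-based indices, a distance window, and a
#' probability). Comment/sequence header lines are ignored on read.
#'
#' @param path file path.
#' @param separation_class class label attached to the set; pairs outside the
#'   class window are dropped on read.
#' @return `read_rr()` returns a `contact_set` tibble.
#' @export
read_rr <- function(path, separation_class = "any") {
  ln <- readLines(path)
  ln <- ln[grepl("^\\s*\\d+\\s+\\d+\\s", ln)]
  if (!length(ln)) return(new_contact_set(integer(), integer(), numeric(),
                                          separation_class))
  fld <- do.call(rbind, lapply(strsplit(trimws(ln), "\\s+"), function(x)
    as.numeric(x[c(1L, 2L, length(x))])))
  i <- pmin(fld[, 1L], fld[, 2L]); j <- pmax(fld[, 1L], fld[, 2L])
  b <- separation_bounds(separation_class)
  keep <- (j - i) >= b[1L] & (j - i) <= b[2L] & i != j
  keep <- keep & !duplicated(paste(i, j))
  new_contact_set(i[keep], j[keep], fld[keep, 3L], separation_class)
}

#' @rdname read_rr
#' @param contacts a `contact_set` tibble.
#' @export
write_rr <- function(contacts, path) {
  writeLines(sprintf("%d %d 0 8 %.6f", contacts$i, contacts$j,
                     contacts$score), path)
  invisible(path)
}

#' Clash and chain-break diagnostics of a Ca trace
#'
#' A severe clash is any non-adjacent Ca pair closer than `clash_cut`; a broken
#' chain is any pair of residues adjacent in `residue_index` whose Ca atoms are
#' farther apart than `break_cut`.
#'
#' @param s a [ca_structure()].
#' @param clash_cut clash distance cutoff (Angstroms).
#' @param break_cut chain-break distance cutoff (Angstroms).
#' @return A list of class `geometry_report`: `clashes` (two-column matrix of
#'   residue-index pairs), `breaks` (ditto, adjacent pairs), and `clean`.
#' @export
geometry_check <- function(s, clash_cut = 1.9, break_cut = 4.5) {
  stopifnot(inherits(s, "ca_structure"))
  m <- as.matrix(stats::dist(s$ca_coords))
  idx <- s$residue_index
  L <- length(idx)
  adj <- cbind(seq_len(L - 1L), seq(2L, length.out = L - 1L))
  adj <- adj[idx[adj[, 2L]] - idx[adj[, 1L]] == 1L, , drop = FALSE]
  brk <- adj[m[adj] > break_cut, , drop = FALSE]
  cl <- which(upper.tri(m) & m < clash_cut, arr.ind = TRUE)
  if (nrow(cl))  # adjacent residues are bonded, not clashing
    cl <- cl[abs(idx[cl[, 2L]] - idx[cl[, 1L]]) > 1L, , drop = FALSE]
  clashes <- cbind(i = idx[cl[, 1L]], j = idx[cl[, 2L]])
  breaks <- cbind(i = idx[brk[, 1L]], j = idx[brk[, 2L]])
  structure(list(clashes = clashes, breaks = breaks,
                 clean = nrow(clashes) == 0L && nrow(breaks) == 0L),
            class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf("<geometry_report> %s: %d clash(es), %d break(s)\n",
              if (x$clean) "clean" else "violations",
              nrow(x$clashes), nrow(x$breaks)))
  invisible(x)
}
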
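#' Normalise a distance map to an image in \[0, 1\]
#'
#' Distances are capped (contacts live below 8 A; a 16 A cap keeps
#' near-contact contrast) and scaled linearly, giving the image representation
#' on which the structural-similarity, hash and keypoint features operate.
#'
#' @param m distance map (Angstroms).
#' @param cap saturation distance in Angstroms; entries at or above `cap` map
#'   to 1.
#' @return An L x L matrix with entries in \[0, 1\].
#' @export
normalize_map <- function(m, cap = 16) {
  if (cap <= 0) stop("cap must be positive")
  m <- check_distance_map(m)
  pmin(m, cap) / cap
}

# --- internal image helpers -------------------------------------------------

# run body with a deterministic RNG stream, restoring the caller's stream
with_local_seed <- function(seed, body) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  body()
}

# uniform w x w moving average with replicate padding, via 2D integral image
box_mean <- function(x, w) {
  h <- (w - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  ri <- c(rep(1L, h), seq_len(n), rep(n, h))
  ci <- c(rep(1L, h), seq_len(m), rep(m, h))
  p <- x[ri, ci, drop = FALSE]
  S <- rbind(0, apply(p, 2L, cumsum))
  S <- cbind(0, t(apply(S, 1L, cumsum)))
  r2 <- seq_len(n) + w; r1 <- seq_len(n)
  c2 <- seq_len(m) + w; c1 <- seq_len(m)
  (S[r2, c2] - S[r1, c2] - S[r2, c1] + S[r1, c1]) / (w * w)
}

# mean structural similarity, 7x7 uniform window, K1 = .01 / K2 = .03, range 1
ssim_index <- function(x, y, window = 7L) {
  L <- nrow(x)
  w <- min(window, if (L %% 2L == 1L) L else L - 1L)
  if (w < 1L) w <- 1L
  c1 <- 0.01^2; c2 <- 0.03^2
  mx <- box_mean(x, w); my <- box_mean(y, w)
  vx <- box_mean(x * x, w) - mx^2
  vy <- box_mean(y * y, w) - my^2
  vxy <- box_mean(x * y, w) - mx * my
  s <- ((2 * mx * my + c1) * (2 * vxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(s)
}

# 4x4 spatial grid of 8-bin gradient-orientation histograms; a lightweight
# stand-in for a Gabor-bank GIST descriptor (same grid layout, documented).
gist_descriptor <- function(x) {
  L <- nrow(x)
  gx <- x[, c(2:L, L)] - x[, c(1, 1:(L - 1))]
  gy <- x[c(2:L, L), ] - x[c(1, 1:(L - 1)), ]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi
  bin <- pmin(floor(ang / pi * 8), 7) + 1
  cell_r <- pmin(ceiling(row(x) / L * 4), 4)
  cell_c <- pmin(ceiling(col(x) / L * 4), 4)
  cell <- (cell_r - 1) * 4 + cell_c
  desc <- numeric(16 * 8)
  idx <- (cell - 1) * 8 + bin
  for (k in seq_along(idx)) desc[idx[k]] <- desc[idx[k]] + mag[k]
  desc
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  min(1, max(0, sum(a * b) / (na * nb)))
}

dct_matrix <- function(n) {
  k <- 0:(n - 1)
  d <- outer(k, k, function(p, q) cos(pi * (2 * q + 1) * p / (2 * n)))
  d * sqrt(2 / n)
}

# 32x32 resample -> 2D DCT -> top-left 8x8 -> median-threshold 64-bit hash
phash_bits <- function(x) {
  small <- EBImage::resize(x, 32, 32)
  d <- dct_matrix(32)
  coef <- (d %*% small %*% t(d))[1:8, 1:8]
  v <- as.numeric(coef)
  v > stats::median(v)
}

# --- ORB-style keypoint matching -------------------------------------------

fast_circle <- cbind(
  dr = c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3),
  dc = c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1))

brief_pattern <- local({
  # fixed 256-test sampling pattern inside a 15x15 patch
  n <- 256L
  g <- function(u) {
    s <- 12345L
    out <- integer(u)
    for (k in seq_len(u)) {
      s <- (1103515245 * s + 12345) %% 2147483648
      out[k] <- as.integer(s %% 15L) - 7L
    }
    out
  }
  matrix(g(4L * n), ncol = 4L,
         dimnames = list(NULL, c("r1", "c1", "r2", "c2")))
})

# FAST-style corners (>= 12 contiguous circle pixels all brighter or all
# darker than the centre) + BRIEF binary descriptors on the resized image.
orb_keypoints <- function(img, threshold = 0.06, max_kp = 200L,
                          margin = 16L) {
  n <- nrow(img)
  rows <- (margin + 1L):(n - margin)
  ctr <- img[rows, rows]
  diffs <- array(0, c(length(rows), length(rows), 16L))
  for (k in 1:16)
    diffs[, , k] <- img[rows + fast_circle[k, 1L], rows + fast_circle[k, 2L]] - ctr
  # circular run of >= 12 TRUEs across the 16 circle positions, computed as
  # lists of 2D masks (run12 = run8 AND run4 shifted by 8)
  run12 <- function(b) {
    m <- lapply(1:16, function(k) b[, , k])
    rot <- function(s) ((seq_len(16L) - 1L + s) %% 16L) + 1L
    comb <- function(x, s) {
      i <- rot(s)
      lapply(1:16, function(k) x[[k]] & x[[i[k]]])
    }
    r2 <- comb(m, 1L); r4 <- comb(r2, 2L); r8 <- comb(r4, 4L)
    i8 <- rot(8L)
    out <- r8[[1L]] & r4[[i8[1L]]]
    for (k in 2:16) out <- out | (r8[[k]] & r4[[i8[k]]])
    out
  }
  corner <- run12(diffs > threshold) | run12(diffs < -threshold)
  if (!any(corner)) return(NULL)
  score <- rowSums(abs(diffs), dims = 2L)
  hits <- which(corner, arr.ind = TRUE)
  ord <- order(score[corner], decreasing = TRUE)
  hits <- hits[utils::head(ord, max_kp), , drop = FALSE]
  kp <- cbind(r = hits[, 1L] + margin, c = hits[, 2L] + margin)
  desc <- matrix(FALSE, nrow(kp), nrow(brief_pattern))
  for (t in seq_len(nrow(brief_pattern))) {
    p <- brief_pattern[t, ]
    desc[, t] <- img[cbind(kp[, 1L] + p[1L], kp[, 2L] + p[2L])] >
      img[cbind(kp[, 1L] + p[3L], kp[, 2L] + p[4L])]
  }
  desc
}

orb_descriptors <- function(x) {
  orb_keypoints(EBImage::resize(x, 256, 256))
}

orb_match_score <- function(x, y, hamming_max = 64L, dx = NULL) {
  if (is.null(dx)) dx <- orb_descriptors(x)
  dy <- orb_descriptors(y)
  if (is.null(dx) || is.null(dy)) return(0)
  a <- dx * 1; b <- dy * 1
  ham <- a %*% t(1 - b) + (1 - a) %*% t(b)   # pairwise Hamming distances
  mx <- sum(apply(ham, 1L, min) <= hamming_max)  # matched keypoints of x
  my <- sum(apply(ham, 2L, min) <= hamming_max)  # matched keypoints of y
  min(mx, my) / max(nrow(a), nrow(b))
}

# --- the feature record -----------------------------------------------------

#' Distance-map matching scores
#'
#' Nine scores comparing a predicted inter-residue distance map against the
#' map computed from a model, used as 2D input features for distance-based
#' quality assessment: windowed structural similarity (`ssim`, clamped to
#' \[0,1\]), peak signal-to-noise ratio (`psnr`, capped at 100 for identical
#' maps), a grid orientation-histogram descriptor similarity (`gist`),
#' root-mean-square difference in Angstroms over off-diagonal cells (`rmse`),
#' cell-level contact `recall` and `precision` (cells at or below 8 A,
#' sequence separation >= 6, predicted vs observed), a 64-bit DCT perceptual
#' hash similarity (`phash`), the Pearson correlation over upper-triangle
#' cells with separation >= 6 (`pearson`), and an ORB-style keypoint match
#' fraction (`orb`, 0 when either image yields no keypoints). Image-space
#' scores operate on [normalize_map()] images.
#'
#' @param predicted,observed distance maps of equal size (Angstroms).
#' @param cap saturation passed to [normalize_map()].
#' @param contact_cut contact distance for the recall/precision cells.
#' @param min_separation separation band excluded from cell-level scores.
#' @param .predicted_orb precomputed ORB descriptors of the predicted map
#'   image (internal caching hook used by [feature_table()], which compares
#'   one predicted map against many models).
#' @return A one-row tibble with columns `ssim`, `psnr`, `gist`, `rmse`,
#'   `recall`, `precision`, `phash`, `pearson`, `orb`.
#' @export
map_match_scores <- function(predicted, observed, cap = 16, contact_cut = 8,
                             min_separation = 6, .predicted_orb = NULL) {
  predicted <- check_distance_map(predicted)
  observed <- check_distance_map(observed)
  if (!identical(dim(predicted), dim(observed)))
    stop("predicted and observed maps must have equal size")
  L <- nrow(predicted)
  ip <- normalize_map(predicted, cap)
  io <- normalize_map(observed, cap)

  ssim <- min(1, max(0, ssim_index(ip, io)))
  mse <- mean((ip - io)^2)
  psnr <- if (mse == 0) 100 else min(100, 10 * log10(1 / mse))
  gist <- cosine_similarity(gist_descriptor(ip), gist_descriptor(io))

  off <- !diag(TRUE, L)
  rmse <- sqrt(mean((predicted[off] - observed[off])^2))

  sep_ok <- upper.tri(predicted) & (col(predicted) - row(predicted)) >= min_separation
  p_cells <- predicted[sep_ok] <= contact_cut
  o_cells <- observed[sep_ok] <= contact_cut
  tp <- sum(p_cells & o_cells)
  precision <- if (sum(p_cells) == 0) as.numeric(sum(o_cells) == 0) else
    tp / sum(p_cells)
  recall <- if (sum(o_cells) == 0) as.numeric(sum(p_cells) == 0) else
    tp / sum(o_cells)

  ph <- 1 - mean(xor(phash_bits(ip), phash_bits(io)))
  pe_x <- predicted[sep_ok]; pe_y <- observed[sep_ok]
  pearson <- if (length(pe_x) < 2 || stats::sd(pe_x) == 0 || stats::sd(pe_y) == 0) {
    if (isTRUE(all.equal(pe_x, pe_y))) 1 else 0
  } else stats::cor(pe_x, pe_y)
  orb <- orb_match_score(ip, io, dx = .predicted_orb)

  tibble::tibble(ssim = ssim, psnr = psnr, gist = gist, rmse = rmse,
                 recall = recall, precision = precision, phash = ph,
                 pearson = pearson, orb = orb)
}

#' Top-k contacts of a scored contact set
#'
#' @param contacts a `contact_set` tibble with prediction scores.
#' @param k number of pairs to keep; when fewer candidates exist in the class
#'   all are returned with a warning.
#' @param separation_class class window applied before ranking.
#' @return A `contact_set` of at most `k` pairs, the highest-scoring first;
#'   ties broken by `(i, j)` lexicographic order.
#' @export
topk_contacts <- function(contacts, k, separation_class = "long") {
  b <- separation_bounds(separation_class)
  sep <- contacts$j - contacts$i
  cand <- contacts[sep >= b[1L] & sep <= b[2L], , drop = FALSE]
  if (nrow(cand) < k)
    warning(sprintf("only %d candidate pairs in class %s (k = %d)",
                    nrow(cand), separation_class, k))
  ord <- order(-cand$score, cand$i, cand$j)
  top <- cand[utils::head(ord, k), , drop = FALSE]
  new_contact_set(top$i, top$j, top$score, separation_class)
}

#' Precision of predicted contacts against a model's contacts
#'
#' @param predicted_topk predicted `contact_set` (typically [topk_contacts()]).
#' @param model_contacts observed `contact_set` of the model.
#' @return Fraction of predicted pairs present among the model contacts; 0
#'   (with a warning) when no pairs were predicted.
#' @export
contact_match <- function(predicted_topk, model_contacts) {
  if (nrow(predicted_topk) == 0L) {
    warning("empty predicted contact set; precision reported as 0")
    return(0)
  }
  hits <- paste(predicted_topk$i, predicted_topk$j) %in%
    paste(model_contacts$i, model_contacts$j)
  mean(hits)
}

#' Short/medium/long-range contact matching scores
#'
#' For each sequence-separation class, the precision of the top L/2 predicted
#' contacts of that class against the contacts of the model's distance map.
#' Classes with no eligible pairs (e.g. long range on very short chains) score
#' 0 and are flagged in the `flagged` attribute.
#'
#' @param predicted scored `contact_set` of predictions (any separation).
#' @param model_map distance map computed from the model.
#' @param L target sequence length (the top-k count is `floor(L / 2)`).
#' @param contact_cut contact distance cutoff for the model map.
#' @return A one-row tibble with `short_score`, `medium_score`, `long_score`.
#' @export
contact_match_record <- function(predicted, model_map, L, contact_cut = 8) {
  k <- max(0L, floor(L / 2))
  one <- function(cls) {
    mc <- contacts_from_map(model_map, contact_cut, cls)
    top <- suppressWarnings(topk_contacts(predicted, k, cls))
    if (nrow(top) == 0L) return(structure(0, flagged = TRUE))
    structure(suppressWarnings(contact_match(top, mc)), flagged = FALSE)
  }
  s <- one("short"); m <- one("medium"); l <- one("long")
  out <- tibble::tibble(short_score = as.numeric(s), medium_score = as.numeric(m),
                        long_score = as.numeric(l))
  attr(out, "flagged") <- c(short = attr(s, "flagged"),
                            medium = attr(m, "flagged"),
                            long = attr(l, "flagged"))
  out
}
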
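cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# internal-coordinate chain extension: bond length b, virtual bond angle
# theta (p2-p3-p4) and dihedral phi (p1-p2-p3-p4), angles in radians
place_next <- function(p1, p2, p3, b, theta, phi) {
  bc <- p3 - p2; bc <- bc / sqrt(sum(bc^2))
  ab <- p2 - p1
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  p3 + (-b * cos(theta)) * bc +
    (b * sin(theta) * cos(phi)) * m +
    (b * sin(theta) * sin(phi)) * n
}

# grow a compact self-avoiding trace: helical segments use ideal virtual
# angles; loop/extended steps sample several candidate dihedrals and prefer
# the one keeping the chain inside a globular radius (Rg-like target), so
# traces fold back on themselves and carry medium/long-range contacts
build_trace <- function(L, min_sep = 3.2) {
  b <- 3.8
  rg_target <- 2.5 * L^0.38
  xyz <- matrix(0, L, 3L)
  xyz[2L, ] <- c(b, 0, 0)
  xyz[3L, ] <- xyz[2L, ] + b * c(cos(pi / 3), sin(pi / 3), 0)
  helical <- stats::runif(1) < 0.6
  seg_left <- sample(5:12, 1L)
  for (i in 4:L) {
    if (seg_left == 0L) {
      helical <- !helical
      seg_left <- sample(if (helical) 6:12 else 3:8, 1L)
    }
    prev <- xyz[seq_len(i - 1L), , drop = FALSE]
    centroid <- colMeans(prev)
    cand <- if (helical) {
      cbind(theta = 91 + stats::rnorm(1L, 0, 2),
            phi = 50 + stats::rnorm(1L, 0, 5))
    } else {
      cbind(theta = stats::runif(14L, 95, 140),
            phi = stats::runif(14L, -180, 180))
    }
    pick <- NULL
    best <- Inf
    for (k in seq_len(nrow(cand))) {
      p <- place_next(xyz[i - 3L, ], xyz[i - 2L, ], xyz[i - 1L, ], b,
                      cand[k, 1L] * pi / 180, cand[k, 2L] * pi / 180)
      if (i > 3L &&
          min(sqrt(colSums((t(prev[seq_len(i - 2L), , drop = FALSE]) - p)^2))) <= min_sep)
        next
      burden <- max(0, sqrt(sum((p - centroid)^2)) - rg_target) +
        stats::runif(1L, 0, 0.5)
      if (burden < best) { best <- burden; pick <- p }
    }
    if (is.null(pick)) {
      if (helical) {   # helix step blocked: fall back to a loop step
        helical <- FALSE
        seg_left <- sample(3:8, 1L)
        for (k in 1:30) {
          p <- place_next(xyz[i - 3L, ], xyz[i - 2L, ], xyz[i - 1L, ], b,
                          stats::runif(1L, 95, 140) * pi / 180,
                          stats::runif(1L, -180, 180) * pi / 180)
          if (min(sqrt(colSums((t(prev[seq_len(i - 2L), , drop = FALSE]) - p)^2))) > min_sep) {
            pick <- p
            break
          }
        }
      }
      if (is.null(pick)) return(NULL)   # dead end: caller retries
    }
    xyz[i, ] <- pick
    seg_left <- seg_left - 1L
  }
  xyz
}

#' Deterministic synthetic native Ca trace
#'
#' Builds a self-avoiding Ca trace with 3.8 A virtual bonds from
#' internal-coordinate geometry, alternating helical and extended segments
#' (5-15 residues) with small angular jitter. Builds are retried with derived
#' sub-seeds until the trace passes [geometry_check()] with a safety margin,
#' and are bit-reproducible for a fixed seed.
#'
#' @param L chain length (>= 10).
#' @param seed integer seed.
#' @param target_id identifier for the structure.
#' @return A clean [ca_structure()] of length `L`.
#' @export
make_native <- function(L, seed = 1L, target_id = sprintf("synth%04d", seed)) {
  if (L < 10L) stop("L must be at least 10")
  with_local_seed(seed, function() {
    for (try_ in 1:200) {
      xyz <- build_trace(L)
      if (is.null(xyz)) next
      d <- as.matrix(stats::dist(xyz))
      off <- abs(row(d) - col(d)) > 1L
      if (min(d[off]) > 3.0) {
        seqchr <- sample(c("A", "D", "E", "F", "G", "H", "I", "K", "L", "N",
                           "Q", "R", "S", "T", "V", "W", "Y"), L, replace = TRUE)
        return(ca_structure(xyz, sequence = paste(seqchr, collapse = ""),
                            target_id = target_id))
      }
    }
    stop("failed to build a self-avoiding trace; try another seed")
  })
}

# chain-correlated displacement field: iid Gaussians smoothed along the chain
# with a Gaussian kernel whose rows are unit-L2-normalised, so the marginal
# per-coordinate standard deviation equals sigma while neighbouring residues
# move coherently (low-frequency deformation)
correlated_noise <- function(L, sigma, bandwidth = 5) {
  W <- exp(-outer(seq_len(L), seq_len(L), "-")^2 / (2 * bandwidth^2))
  W <- W / sqrt(rowSums(W^2))
  sigma * (W %*% matrix(stats::rnorm(L * 3L), L, 3L))
}

# deterministic largest-remainder allocation of n items to weights w
allocate_counts <- function(n, w) {
  w <- w / sum(w)
  base <- floor(n * w)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(n * w - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Generate a decoy model pool around a native structure
#'
#' Each decoy is the native Ca trace plus chain-correlated Gaussian
#' displacement at one of the noise levels. The `skew` parameter reweights how
#' many decoys receive the larger noise levels (allocation weights
#' proportional to `exp(skew * (level - 1))`): `skew = 0` spreads decoys
#' evenly, larger values emulate hard targets whose pools contain only a few
#' good models and whose quality-score distribution is positively skewed. The
#' true GDT-TS of every decoy against the native is stored on the pool.
#'
#' @param native a [make_native()] structure (or any [ca_structure()]).
#' @param n_decoys number of decoys (>= 2).
#' @param noise_levels displacement standard deviations sigma in Angstroms.
#' @param skew non-negative skew-control parameter.
#' @param seed integer seed.
#' @param bandwidth chain-smoothing bandwidth (residues) of the noise field.
#' @param shared_misfold give the decoys at the largest noise level a common
#'   pool-wide deformation component (plus smaller individual noise), so the
#'   worst models form a mutually similar cluster the way server pools
#'   concentrate on a dominant wrong conformation for hard targets. Defaults
#'   to on for mixed-level pools and off for single-level (noise-sweep)
#'   pools.
#' @return A [model_pool()] with `true_score` filled in.
#' @export
make_decoys <- function(native, n_decoys = 30L,
                        noise_levels = c(1, 1.5, 2.5, 4, 8), skew = 0,
                        seed = 1L, bandwidth = 5,
                        shared_misfold = length(noise_levels) > 1L) {
  stopifnot(n_decoys >= 2L, all(noise_levels > 0), skew >= 0)
  L <- length(native)
  K <- length(noise_levels)
  counts <- allocate_counts(n_decoys, exp(skew * (seq_len(K) - 1L)))
  sigmas <- rep(noise_levels, counts)
  sigma_top <- max(noise_levels)
  models <- with_local_seed(seed, function() {
    sigmas <<- sample(sigmas)          # interleave levels deterministically
    misfold <- if (shared_misfold)
      correlated_noise(L, sigma_top * sqrt(8 / 9), bandwidth)
    else NULL
    lapply(seq_len(n_decoys), function(k) {
      noise <- if (!is.null(misfold) && sigmas[k] == sigma_top)
        misfold + correlated_noise(L, sigma_top / 3, bandwidth)
      else correlated_noise(L, sigmas[k], bandwidth)
      ca_structure(native$ca_coords + noise, sequence = native$sequence,
                   residue_index = native$residue_index,
                   target_id = native$target_id)
    })
  })
  names(models) <- sprintf("decoy_%03d", seq_len(n_decoys))
  ts <- vapply(models, gdt_ts, numeric(1L), reference = native)
  pool <- model_pool(models, target_id = native$target_id, group = "sim",
                     true_score = ts)
  attr(pool, "sigma") <- stats::setNames(sigmas, names(models))
  pool
}

#' Synthetic predicted distance map
#'
#' The native distance map plus symmetric zero-mean Gaussian cell noise,
#' clipped at zero with the diagonal restored to zero — a stand-in for the
#' output of a learned distance predictor at a controllable error level.
#' `deform_sd > 0` additionally computes the map from a coherently deformed
#' copy of the native (chain-correlated displacement) before adding cell
#' noise: real predictors err self-consistently on hard targets, producing a
#' map of a somewhat wrong conformation rather than white noise around the
#' true one.
#'
#' @param native a [ca_structure()].
#' @param noise_sd cell-noise standard deviation in Angstroms (>= 0).
#' @param seed integer seed.
#' @param scheme distance scheme passed to [distance_map()].
#' @param deform_sd coherent conformation-error level in Angstroms (>= 0).
#' @return A valid distance map matrix.
#' @export
make_predicted_map <- function(native, noise_sd = 0, seed = 1L,
                               scheme = "cb", deform_sd = 0) {
  stopifnot(noise_sd >= 0, deform_sd >= 0)
  src <- native
  if (deform_sd > 0) {
    xyz <- native$ca_coords + with_local_seed(seed + 13L, function()
      correlated_noise(length(native), deform_sd))
    src <- ca_structure(xyz, sequence = native$sequence,
                        residue_index = native$residue_index,
                        target_id = native$target_id)
  }
  m <- distance_map(src, scheme)
  dimnames(m) <- NULL
  if (noise_sd > 0) {
    L <- nrow(m)
    e <- with_local_seed(seed, function() {
      e <- matrix(0, L, L)
      e[upper.tri(e)] <- stats::rnorm(L * (L - 1L) / 2L, 0, noise_sd)
      e + t(e)
    })
    m <- pmax(m + e, 0)
    diag(m) <- 0
  }
  m
}

#' Synthetic query-anchored MSA
#'
#' Rows are copies of a random query with per-column substitutions at
#' `mutation_rate` and gap blocks outside their coverage interval, emulating
#' alignments whose homologs cover only parts of the target.
#'
#' @param query_length number of query columns.
#' @param n_rows total rows including the query (row 1).
#' @param mutation_rate per-column substitution probability in covered
#'   regions.
#' @param coverage_blocks list of 1-based inclusive `(start, end)` intervals;
#'   each non-query row is assigned one (recycled in order). Default: full
#'   coverage.
#' @param seed integer seed.
#' @return An [msa()].
#' @export
make_msa <- function(query_length, n_rows, mutation_rate = 0.3,
                     coverage_blocks = NULL, seed = 1L) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1, n_rows >= 1L)
  if (is.null(coverage_blocks)) coverage_blocks <- list(c(1L, query_length))
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  with_local_seed(seed, function() {
    q <- sample(aas, query_length, replace = TRUE)
    rows <- character(n_rows)
    rows[1L] <- paste(q, collapse = "")
    for (r in seq_len(n_rows)[-1L]) {
      blk <- coverage_blocks[[(r - 2L) %% length(coverage_blocks) + 1L]]
      s <- q
      mut <- stats::runif(query_length) < mutation_rate
      s[mut] <- vapply(q[mut], function(a) sample(setdiff(aas, a), 1L),
                       character(1L))
      covered <- seq_len(query_length) >= blk[1L] &
        seq_len(query_length) <= blk[2L]
      s[!covered] <- "-"
      rows[r] <- paste(s, collapse = "")
    }
    msa(rows)
  })
}

#' Synthetic target-template hit table for a planned domain layout
#'
#' Emits hits whose filtered union reproduces the planned template-based
#' cover, plus one decoy hit violating each alignment filter (E-value above 1,
#' aligned length of at most 40, coverage of at most 0.5) so the filtering
#' rules are exercised. Planned TBM segments must be longer than 40 residues.
#'
#' @param L target length.
#' @param segments planned layout: data frame with `start`, `end`, `klass`
#'   (`"FM"`/`"TBM"`) tiling `[1, L]` (e.g. a [parse_domains()] result).
#' @param seed integer seed.
#' @return A hit-table tibble (see [filter_hits()]).
#' @export
make_hit_table <- function(L, segments, seed = 1L) {
  segments <- tibble::as_tibble(segments)
  tbm <- segments[segments$klass == "TBM", , drop = FALSE]
  if (nrow(tbm) && any(tbm$end - tbm$start + 1L <= 40L))
    stop("planned TBM segments must be longer than 40 residues")
  with_local_seed(seed, function() {
    rows <- list()
    k <- 0L
    for (r in seq_len(nrow(tbm))) {
      s <- tbm$start[r]; e <- tbm$end[r]
      k <- k + 1L
      rows[[k]] <- tibble::tibble(template_id = sprintf("tpl%02da", r),
                                  e_value = 10^stats::runif(1L, -60, -5),
                                  target_start = s, target_end = e,
                                  coverage = stats::runif(1L, 0.6, 0.99))
      if (e - s + 1L > 82L) {       # a partial hit nested inside the cover
        s2 <- s + sample.int(10L, 1L)
        e2 <- s2 + 41L + sample.int(e - s2 - 41L, 1L)
        k <- k + 1L
        rows[[k]] <- tibble::tibble(template_id = sprintf("tpl%02db", r),
                                    e_value = 10^stats::runif(1L, -30, -2),
                                    target_start = s2, target_end = min(e2, e),
                                    coverage = stats::runif(1L, 0.55, 0.9))
      }
    }
    span <- function(len) {
      s <- sample.int(max(1L, L - len), 1L)
      c(s, min(L, s + len - 1L))
    }
    bad_e <- span(60L); bad_len <- span(40L); bad_cov <- span(60L)
    decoys <- tibble::tibble(
      template_id = c("bad_evalue", "bad_length", "bad_coverage"),
      e_value = c(2, 1e-10, 1e-10),
      target_start = c(bad_e[1L], bad_len[1L], bad_cov[1L]),
      target_end = c(bad_e[2L], bad_len[2L], bad_cov[2L]),
      coverage = c(0.9, 0.9, 0.4))
    do.call(rbind, c(rows, list(decoys)))
  })
}

#' One complete synthetic target fixture
#'
#' Convenience wrapper generating everything one pipeline run needs: a native
#' structure, a decoy pool with true scores, a predicted distance map at the
#' requested error level, predicted contacts derived from it, an MSA, and a
#' hit table for a simple two-domain layout.
#'
#' @inheritParams make_decoys
#' @param L chain length.
#' @param map_noise_sd cell-error level of the synthetic predicted map
#'   (Angstroms).
#' @param map_deform_sd coherent conformation-error level of the predicted
#'   map (Angstroms); see [make_predicted_map()].
#' @param seed master seed; sub-generators use derived seeds.
#' @return A list: `native`, `pool`, `predicted_map`, `contacts`, `msa`,
#'   `hits`, `layout`.
#' @export
simulate_target <- function(L = 60L, n_decoys = 30L,
                            noise_levels = c(1, 1.5, 2.5, 4, 8), skew = 0,
                            map_noise_sd = 2.5, map_deform_sd = 0,
                            seed = 1L) {
  native <- make_native(L, seed)
  pool <- make_decoys(native, n_decoys, noise_levels, skew, seed + 1L)
  pm <- make_predicted_map(native, map_noise_sd, seed + 2L,
                           deform_sd = map_deform_sd)
  cs <- contacts_from_map(pm, threshold = 12, separation_class = "any")
  contacts <- new_contact_set(cs$i, cs$j, 1 - pm[cbind(cs$i, cs$j)] / 12,
                              "any")
  m <- make_msa(L, 20L, 0.3, seed = seed + 3L)
  layout <- if (L > 140L)
    new_domain_segments(c(1L, 61L, 112L), c(60L, 111L, L),
                        c("TBM", "FM", "TBM"))
  else new_domain_segments(1L, L, "TBM")
  hits <- if (L > 41L) make_hit_table(L, layout, seed + 4L) else
    tibble::tibble(template_id = character(), e_value = numeric(),
                   target_start = integer(), target_end = integer(),
                   coverage = numeric())
  list(native = native, pool = pool, predicted_map = pm, contacts = contacts,
       msa = m, hits = hits, layout = layout)
}
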
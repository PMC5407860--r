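## Genome topology from binned contact matrices: iterative-correction
## balancing, directionality indices, TAD calling with delta-Z scores,
## boundary strength and A/B compartment assignment.

#' Iterative correction (matrix balancing)
#'
#' Balances a symmetric contact matrix so that all unmasked rows have equal
#' sums, following the iterative correction algorithm: rows are repeatedly
#' divided by their relative marginal. All-zero rows are masked and left
#' untouched. Returns the balanced matrix together with the per-bin
#' multiplicative bias factors, so that
#' `corrected[i, j] = counts[i, j] / (factors[i] * factors[j])`.
#'
#' @param mat symmetric non-negative matrix.
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the maximum relative row-sum
#'   deviation.
#' @return list with `matrix`, `factors`, `masked`, `converged`,
#'   `iterations`.
#' @export
ice_correct <- function(mat, max_iter = 500L, tol = 1e-10) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (max(abs(mat - t(mat))) > 1e-8 * max(1, max(abs(mat)))) {
    stopf("ice_correct() expects a symmetric matrix")
  }
  masked <- rowSums(mat) == 0
  w <- mat
  factors <- rep(1, nrow(mat))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    s <- rowSums(w)
    s_rel <- s / mean(s[!masked])
    s_rel[masked] <- 1
    if (max(abs(s_rel[!masked] - 1)) < tol) { converged <- TRUE; break }
    factors <- factors * s_rel
    w <- w / outer(s_rel, s_rel)
  }
  if (!converged) warnf("ice_correct() did not converge in %d iterations", max_iter)
  list(matrix = w, factors = factors, masked = masked,
       converged = converged, iterations = it)
}

#' Directionality index track
#'
#' For a sliding window (width `bin_bp`, default 25 kb) advanced in
#' `step_bp` steps, contrasts the summed contacts of the window with the
#' `window_bp` (default 1 Mb) region upstream (`A`) against downstream
#' (`B`):
#' `DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)` with
#' `E = (A + B) / 2`, zero when `A = B`. Positions whose up- or downstream
#' reach is truncated below `min_window_frac` of the full window, or where
#' `A = B = 0`, are masked (`NA`).
#'
#' @param mat binned contact matrix (one chromosome).
#' @param bin_bp matrix bin size (bp); also the sliding-window width.
#' @param window_bp up/downstream window (bp).
#' @param step_bp step between evaluated positions (bp).
#' @param min_window_frac minimum available fraction of `window_bp` on each
#'   side for a position to be evaluated.
#' @return `data.table` with `position` (window start, bp) and `di_raw`.
#' @export
directionality_index <- function(mat, bin_bp = 25000, window_bp = 1e6,
                                 step_bp = 5000, min_window_frac = 0.5) {
  n <- nrow(mat)
  chrom_len <- n * bin_bp
  bin_mid <- (seq_len(n) - 0.5) * bin_bp
  positions <- seq(0, chrom_len - bin_bp, by = step_bp)
  di <- rep(NA_real_, length(positions))
  for (k in seq_along(positions)) {
    p <- positions[k]
    if ((p < window_bp * min_window_frac) ||
        (chrom_len - (p + bin_bp) < window_bp * min_window_frac)) next
    ## focal row: weighted mix of the bins overlapped by [p, p + bin_bp)
    b1 <- floor(p / bin_bp) + 1L
    b2 <- min(floor((p + bin_bp - 1) / bin_bp) + 1L, n)
    if (b1 == b2) {
      row <- mat[b1, ]
    } else {
      w2 <- (p + bin_bp - (b2 - 1L) * bin_bp) / bin_bp
      row <- (1 - w2) * mat[b1, ] + w2 * mat[b2, ]
    }
    up <- bin_mid >= (p - window_bp) & bin_mid < p
    dn <- bin_mid >= (p + bin_bp) & bin_mid < (p + bin_bp + window_bp)
    A <- sum(row[up]); B <- sum(row[dn])
    if (A == 0 && B == 0) next
    E <- (A + B) / 2
    di[k] <- if (A == B) 0 else sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
  }
  data.table::data.table(position = positions, di_raw = di)
}

#' Smooth and standardise a directionality-index track
#'
#' Applies a running average over +/- `half_window` points (default 5, i.e.
#' +/- 25 kb on a 5 kb grid, 11 points), edge-truncated and skipping masked
#' values, then standardises to zero mean and unit variance over the
#' defined positions of the chromosome.
#'
#' @param track `data.table` from [directionality_index()].
#' @param half_window half-width of the running mean in grid points.
#' @return the track with `di_smoothed` and `di_z` columns added.
#' @export
smooth_and_standardize <- function(track, half_window = 5L) {
  x <- track$di_raw
  n <- length(x)
  sm <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    w <- x[max(1L, i - half_window):min(n, i + half_window)]
    sm[i] <- mean(w, na.rm = TRUE)
  }
  out <- data.table::copy(track)
  out[, di_smoothed := sm]
  mu <- mean(sm, na.rm = TRUE)
  s <- sd(sm, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    warnf("constant directionality track; z-scores set to 0")
    out[, di_z := ifelse(is.na(sm), NA_real_, 0)]
  } else {
    out[, di_z := (sm - mu) / s]
  }
  out[]
}

## Local extrema of a (possibly NA-masked) series. Strict neighbour
## comparison; plateaus contribute their midpoint index. Candidate maxima
## must exceed `min_abs` and minima fall below `-min_abs` (positions with no
## directionality bias cannot delimit a TAD). Returns a data.table of
## (index, type) sorted by index with alternation enforced (keeps the most
## extreme of same-type runs).
local_extrema <- function(z, min_abs = 0) {
  ok <- which(!is.na(z))
  v <- z[ok]
  n <- length(v)
  if (n < 3) return(data.table::data.table(index = integer(), type = character()))
  ## collapse exact plateaus to their midpoint
  r <- rle(v)
  starts <- cumsum(c(1L, head(r$lengths, -1)))
  mids <- starts + (r$lengths - 1L) %/% 2L
  vv <- r$values
  m <- length(vv)
  if (m < 3) return(data.table::data.table(index = integer(), type = character()))
  i <- 2:(m - 1)
  is_max <- vv[i] > vv[i - 1] & vv[i] > vv[i + 1]
  is_min <- vv[i] < vv[i - 1] & vv[i] < vv[i + 1]
  ext <- data.table::data.table(
    index = ok[mids[i]],
    value = vv[i],
    type = ifelse(is_max, "max", ifelse(is_min, "min", NA_character_))
  )[!is.na(type)]
  ext <- ext[(type == "max" & value > min_abs) |
               (type == "min" & value < -min_abs)]
  if (!nrow(ext)) return(ext[, .(index, type)])
  ## enforce alternation: within a run of same-type extrema keep the extreme
  keep <- logical(nrow(ext))
  run_start <- 1L
  for (k in seq_len(nrow(ext))) {
    if (k == nrow(ext) || ext$type[k + 1] != ext$type[k]) {
      run <- run_start:k
      best <- if (ext$type[k] == "max") run[which.max(ext$value[run])]
              else run[which.min(ext$value[run])]
      keep[best] <- TRUE
      run_start <- k + 1L
    }
  }
  ext[keep, .(index, type, value)]
}

#' Call TADs from a standardised directionality-index track
#'
#' TADs are called between pairs of consecutive local maxima (TAD start) and
#' minima (TAD end) of the standardised smoothed directionality index whose
#' standard-score difference (TAD delta-Z) exceeds `delta_z_min`. Each TAD
#' end is then extended outward over the contiguous run of positions with no
#' directionality bias (`|z| < no_bias_eps`), without crossing a previously
#' called TAD.
#'
#' @param track track with `di_z` (see [smooth_and_standardize()]).
#' @param delta_z_min minimum `z(max) - z(min)` to accept a TAD.
#' @param no_bias_eps absolute z below which a position counts as having no
#'   directionality bias.
#' @param step_bp grid step of the track (bp).
#' @return object of class `tad_set`: `data.table` with `start`, `end` (bp),
#'   `tad_delta_z`, and the defining extremum positions `max_pos`,
#'   `min_pos`.
#' @export
call_tads <- function(track, delta_z_min = 2, no_bias_eps = 0.25,
                      step_bp = 5000) {
  z <- track$di_z
  pos <- track$position
  ext <- local_extrema(z, min_abs = no_bias_eps)
  tads <- data.table::data.table(start = numeric(), end = numeric(),
                                 tad_delta_z = numeric(),
                                 max_pos = numeric(), min_pos = numeric())
  if (nrow(ext) >= 2) {
    prev_end_idx <- 0L
    for (k in seq_len(nrow(ext) - 1L)) {
      if (ext$type[k] != "max" || ext$type[k + 1] != "min") next
      i <- ext$index[k]; j <- ext$index[k + 1]
      dz <- z[i] - z[j]
      if (!is.finite(dz) || dz <= delta_z_min) next
      s <- i
      while (s - 1L > prev_end_idx && !is.na(z[s - 1L]) &&
             abs(z[s - 1L]) < no_bias_eps) s <- s - 1L
      e <- j
      while (e + 1L <= length(z) && !is.na(z[e + 1L]) &&
             abs(z[e + 1L]) < no_bias_eps) e <- e + 1L
      tads <- rbind(tads, data.table::data.table(
        start = pos[s], end = pos[e] + step_bp,
        tad_delta_z = dz, max_pos = pos[i], min_pos = pos[j]))
      prev_end_idx <- e
    }
  }
  structure(tads[], class = c("tad_set", class(tads)))
}

#' Boundary strength between adjacent TADs
#'
#' For every boundary between two consecutive TADs, the TAD-boundary
#' delta-Z is the difference between the standardised smoothed
#' directionality index at the local maximum opening the following TAD and
#' at the local minimum closing the preceding TAD. Unlike the TAD delta-Z,
#' this score does not depend on the far boundary of either TAD.
#'
#' @param tads a `tad_set` (see [call_tads()]).
#' @param track the standardised track the TADs were called on.
#' @return `data.table` with `boundary_pos` (midpoint between the flanking
#'   TADs, bp) and `tadb_delta_z`.
#' @export
boundary_strength <- function(tads, track) {
  if (nrow(tads) < 2) {
    return(data.table::data.table(boundary_pos = numeric(),
                                  tadb_delta_z = numeric()))
  }
  z_at <- function(p) track$di_z[match(p, track$position)]
  k <- seq_len(nrow(tads) - 1L)
  data.table::data.table(
    boundary_pos = (tads$min_pos[k] + tads$max_pos[k + 1]) / 2,
    tadb_delta_z = z_at(tads$max_pos[k + 1]) - z_at(tads$min_pos[k])
  )
}

#' Call A/B compartments from a contact matrix
#'
#' Balances the matrix (iterative correction), divides by the mean contact
#' at each separation (distance correction), computes the Pearson
#' correlation matrix of the resulting profiles, and takes a principal
#' component (the leading eigenvector by default; per-chromosome override to
#' a later component supported for chromosomes where the first component
#' tracks arm-level structure). The component's sign is fixed so that it
#' correlates positively with an active-mark coverage track, and it is
#' scaled by the square root of its eigenvalue and normalised so that the
#' largest magnitude is 42 (`scale_mode = "normalized"`, matching the range
#' over which the +/-10 A/B cutoff is conventionally applied) or left raw.
#' Bins with value above `threshold` are labelled `A`, below `-threshold`
#' labelled `B`, and `neither` otherwise.
#'
#' @param mat binned symmetric contact matrix (one chromosome).
#' @param active_mark numeric per-bin coverage of an active mark used for
#'   sign alignment.
#' @param bin_bp bin size (bp), for output coordinates.
#' @param pc_index which principal component to use (default 1).
#' @param threshold A/B cutoff on the scaled component value.
#' @param scale_mode `"normalized"` (scaled to max |value| = 42) or
#'   `"raw"` (eigenvector times the square root of its eigenvalue).
#' @param ice balance the matrix first.
#' @return object of class `compartment_track`: `data.table` with `bin`,
#'   `start`, `end`, `pc_value`, `label`; attribute `pc_index`.
#' @export
call_compartments <- function(mat, active_mark, bin_bp = 250000,
                              pc_index = 1L, threshold = 10,
                              scale_mode = c("normalized", "raw"),
                              ice = TRUE) {
  scale_mode <- match.arg(scale_mode)
  n <- nrow(mat)
  stopifnot(length(active_mark) == n)
  if (ice) mat <- ice_correct(mat)$matrix
  ## observed / expected by diagonal
  oe <- mat
  for (d in 0:(n - 1)) {
    idx <- cbind(seq_len(n - d), seq_len(n - d) + d)
    mu <- mean(mat[idx])
    if (mu > 0) {
      oe[idx] <- mat[idx] / mu
      oe[idx[, c(2, 1), drop = FALSE]] <- oe[idx]
    }
  }
  keep <- which(apply(oe, 1, function(r) var(r) > 0))
  if (length(keep) < max(3L, pc_index + 1L)) {
    stopf("degenerate matrix: too few informative bins for compartments")
  }
  cm <- suppressWarnings(cor(oe[keep, keep]))
  cm[!is.finite(cm)] <- 0
  eg <- eigen(cm, symmetric = TRUE)
  v <- eg$vectors[, pc_index]
  lam <- max(eg$values[pc_index], 0)
  pc <- rep(NA_real_, n)
  pc[keep] <- v * sqrt(lam)
  if (!is.na(cor(pc[keep], active_mark[keep])) &&
      cor(pc[keep], active_mark[keep]) < 0) pc <- -pc
  if (scale_mode == "normalized" && any(is.finite(pc))) {
    pc <- pc * 42 / max(abs(pc), na.rm = TRUE)
  }
  out <- data.table::data.table(
    bin = seq_len(n),
    start = (seq_len(n) - 1) * bin_bp,
    end = seq_len(n) * bin_bp,
    pc_value = pc,
    label = data.table::fcase(is.na(pc), "neither",
                              pc > threshold, "A",
                              pc < -threshold, "B",
                              default = "neither")
  )
  data.table::setattr(out, "pc_index", pc_index)
  structure(out, class = c("compartment_track", class(out)))
}

#' Aggregate a fine-binned matrix to a coarser resolution
#'
#' Sums counts of `factor x factor` blocks; the trailing partial block is
#' kept. Used to derive compartment-resolution matrices from TAD-resolution
#' ones.
#'
#' @param mat square matrix.
#' @param factor integer aggregation factor.
#' @return aggregated square matrix.
#' @export
aggregate_matrix <- function(mat, factor) {
  n <- nrow(mat)
  grp <- (seq_len(n) - 1L) %/% factor + 1L
  m <- max(grp)
  agg <- matrix(0, m, m)
  for (i in seq_len(m)) {
    sel_i <- grp == i
    for (j in i:m) {
      agg[i, j] <- sum(mat[sel_i, grp == j])
      agg[j, i] <- agg[i, j]
    }
  }
  agg
}
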
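## Distance-matched permutation enrichment of PIRs for genomic features,
## promoter-PIR chromatin-state concordance, and enhancer target assignment.

#' Sample promoter-distance-matched control fragment sets
#'
#' Builds `n_perm` control sets for the PIRs of one cell type. Every PIR is
#' replaced by a random non-PIR fragment lying on the same chromosome as a
#' randomly chosen bait, at a bait distance falling in the same log10
#' distance bin as the PIR's own interaction distance (bins span the observed
#' distance range; default 20). Control sets have the size of the PIR set,
#' contain no duplicate fragments, and never contain true PIR fragments of
#' the same cell type. Empty candidate bins are widened to the adjacent bin
#' with a warning.
#'
#' @param calls significance-called interactions with distances.
#' @param fragment_map fragment map.
#' @param cell_type cell type whose PIRs are matched.
#' @param n_perm number of control sets.
#' @param n_bins number of log10 distance bins.
#' @param seed integer seed; fixed seed gives identical control sets.
#' @return object of class `distance_matched_controls`: list with `sets`
#'   (list of fragment-id vectors), `pirs`, `breaks`.
#' @export
sample_distance_matched_controls <- function(calls, fragment_map, cell_type,
                                             n_perm = 100L, n_bins = 20L,
                                             seed = 1L) {
  sig_col <- paste0("sig_", cell_type)
  check_columns(calls, c(sig_col, "is_cis", "distance"), "calls")
  cis <- calls[get(sig_col) == TRUE & is_cis == TRUE]
  if (!nrow(cis)) stopf("no significant cis interactions for %s", cell_type)
  pir_dist <- cis[, .(distance = median(distance)), by = other_end_id]
  pirs <- pir_dist$other_end_id

  fm <- data.table::copy(fragment_map)
  data.table::setorder(fm, chrom, start)
  fm[, mid := (start + end) / 2]
  chroms <- unique(fm$chrom)
  offset <- c(0L, cumsum(fm[, .N, by = chrom]$N))
  names(offset) <- c(chroms, "..end")
  mids_by_chrom <- split(fm$mid, factor(fm$chrom, levels = chroms))
  is_pir <- fm$fragment_id %in% pirs

  ld <- log10(pmax(pir_dist$distance, 1))
  rng <- range(ld)
  if (diff(rng) == 0) rng <- rng + c(-0.05, 0.05)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  pir_bin <- pmin(pmax(findInterval(ld, breaks, rightmost.closed = TRUE), 1L),
                  n_bins)

  baits <- fm[bait == TRUE]
  n_bait <- nrow(baits)
  bait_chrom_i <- match(baits$chrom, chroms)

  ## candidate row ranges (global fm rows) per (bait, bin, side)
  Ls <- Le <- Rs <- Re <- matrix(0L, n_bait, n_bins)
  for (j in seq_len(n_bait)) {
    v <- mids_by_chrom[[bait_chrom_i[j]]]
    off <- offset[[bait_chrom_i[j]]]
    m <- (baits$start[j] + baits$end[j]) / 2
    dlo <- 10^breaks[-length(breaks)]; dhi <- 10^breaks[-1]
    Ls[j, ] <- off + findInterval(m - dhi, v) + 1L
    Le[j, ] <- off + findInterval(m - dlo, v)
    Rs[j, ] <- off + findInterval(m + dlo, v) + 1L
    Re[j, ] <- off + findInterval(m + dhi, v)
  }
  nL <- pmax(Le - Ls + 1L, 0L); nR <- pmax(Re - Rs + 1L, 0L)

  widened <- FALSE
  nP <- length(pirs)
  sets <- withr::with_seed(seed, {
    lapply(seq_len(n_perm), function(p) {
      out <- integer(nP)
      pending <- seq_len(nP)
      bin <- pir_bin
      iter <- 0L
      while (length(pending) && iter < 100L) {
        iter <- iter + 1L
        j <- sample.int(n_bait, length(pending), replace = TRUE)
        ij <- cbind(j, bin[pending])
        tot <- nL[ij] + nR[ij]
        ## widen empty (bait, bin) cells to an adjacent bin
        empty <- which(tot == 0L)
        if (length(empty)) {
          widened <<- TRUE
          alt <- ifelse(bin[pending][empty] < n_bins,
                        bin[pending][empty] + 1L,
                        bin[pending][empty] - 1L)
          ij[empty, 2] <- alt
          tot <- nL[ij] + nR[ij]
        }
        ok <- which(tot > 0L)
        if (!length(ok)) next
        u <- floor(runif(length(ok)) * tot[ok]) + 1L
        left <- u <= nL[ij][ok]
        row <- ifelse(left, Ls[ij][ok] + u - 1L,
                      Rs[ij][ok] + (u - nL[ij][ok]) - 1L)
        good <- !is_pir[row] & !fm$fragment_id[row] %in% out
        ## keep control sets duplicate-free within a permutation
        first <- !duplicated(row)
        good <- good & first
        out[pending[ok][good]] <- fm$fragment_id[row[good]]
        pending <- pending[!seq_along(pending) %in% ok[good]]
      }
      if (length(pending)) {
        ## fallback: any unused non-PIR fragment (distance match abandoned
        ## for these few draws)
        pool <- fm$fragment_id[!is_pir]
        pool <- setdiff(pool, out)
        out[pending] <- pool[sample.int(length(pool), length(pending))]
      }
      out
    })
  })
  if (widened) warnf("empty distance bins encountered; widened to adjacent bins")
  structure(list(sets = sets, pirs = pirs, breaks = breaks,
                 cell_type = cell_type),
            class = "distance_matched_controls")
}

#' Permutation enrichment of PIRs for a feature set
#'
#' Counts PIR fragments overlapping at least one feature interval and
#' compares the count with the same statistic over distance-matched control
#' sets. The empirical p-value is one-sided for enrichment,
#' `(1 + #\{permuted >= observed\}) / (n_perm + 1)`; depletion shows up as a
#' negative z-score.
#'
#' @param pirs integer vector of PIR fragment ids (or a
#'   `distance_matched_controls` object's `pirs`).
#' @param controls a [sample_distance_matched_controls()] result.
#' @param features feature intervals (`data.table` with `chrom`, `start`,
#'   `end`).
#' @param fragment_map fragment map.
#' @return object of class `permutation_result`.
#' @export
feature_enrichment <- function(pirs, controls, features, fragment_map) {
  feat_gr <- as_granges(data.table::as.data.table(features))
  frag_gr <- as_granges(fragment_map)
  hit <- GenomicRanges::countOverlaps(frag_gr, feat_gr) > 0
  names(hit) <- as.character(fragment_map$fragment_id)
  count_set <- function(ids) sum(hit[as.character(ids)], na.rm = TRUE)
  observed <- count_set(pirs)
  permuted <- vapply(controls$sets, count_set, numeric(1))
  s <- sd(permuted)
  res <- list(
    observed = observed,
    permuted_mean = mean(permuted),
    ci95 = unname(quantile(permuted, c(0.025, 0.975))),
    empirical_p = (1 + sum(permuted >= observed)) / (length(permuted) + 1),
    z_score = if (s > 0) (observed - mean(permuted)) / s else NA_real_,
    n_permutations = length(permuted),
    permuted = permuted
  )
  class(res) <- "permutation_result"
  res
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation enrichment: observed %d vs %.2f expected (95%% CI %.1f-%.1f)\n  z = %s, empirical p = %.4g (%d permutations)\n",
    x$observed, x$permuted_mean, x$ci95[1], x$ci95[2],
    if (is.na(x$z_score)) "NA" else sprintf("%.2f", x$z_score),
    x$empirical_p, x$n_permutations))
  invisible(x)
}

#' Promoter-PIR chromatin state concordance
#'
#' Cross-tabulates the broad chromatin states of promoters and their PIRs
#' over significant interactions of one cell type, reports the log2 odds
#' ratio of every (promoter state, PIR state) combination against its 2x2
#' collapse (Haldane +0.5 applied to zero cells), and a Pearson chi-squared
#' test on the full contingency table. Mixed and intermediate fragments are
#' excluded on both sides.
#'
#' @param calls significance-called interactions.
#' @param states fragment states (see [fragment_states()]) for `cell_type`.
#' @param cell_type cell type label.
#' @return object of class `concordance_matrix`: list with `log2_odds`
#'   (matrix), `chi2_p`, `table`.
#' @export
state_concordance <- function(calls, states, cell_type) {
  sig_col <- paste0("sig_", cell_type)
  check_columns(calls, sig_col, "calls")
  keep_states <- c("active", "poised", "polycomb", "background")
  st <- states[, .(fragment_id, broad_state)]
  x <- calls[get(sig_col) == TRUE, .(bait_id, other_end_id)]
  x[st, on = c(bait_id = "fragment_id"), prom_state := i.broad_state]
  x[st, on = c(other_end_id = "fragment_id"), pir_state := i.broad_state]
  x <- x[prom_state %in% keep_states & pir_state %in% keep_states]
  if (!nrow(x)) stopf("no interactions with assignable states on both ends")
  tab <- table(factor(x$prom_state, keep_states),
               factor(x$pir_state, keep_states))
  lo <- matrix(NA_real_, 4, 4, dimnames = dimnames(tab))
  for (i in 1:4) for (j in 1:4) {
    a <- tab[i, j]
    b <- sum(tab[i, ]) - a
    c <- sum(tab[, j]) - a
    d <- sum(tab) - a - b - c
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
      warnf("zero margin for (%s, %s); cell dropped",
            keep_states[i], keep_states[j])
      next
    }
    lo[i, j] <- log2(odds_ratio_2x2(a, b, c, d))
  }
  chi <- suppressWarnings(chisq.test(tab))
  structure(list(log2_odds = lo, chi2_p = chi$p.value, table = tab),
            class = "concordance_matrix")
}

#' @export
print.concordance_matrix <- function(x, ...) {
  cat("Promoter x PIR chromatin-state concordance (log2 odds ratios)\n")
  print(round(x$log2_odds, 2))
  cat(sprintf("Pearson chi-squared p = %.3g\n", x$chi2_p))
  invisible(x)
}

#' Assign enhancer target genes from promoter interactions
#'
#' For every enhancer interval overlapping a PIR of the given cell type,
#' reports the genes whose baits significantly interact with that PIR, the
#' nearest gene by TSS-to-enhancer-midpoint distance (same chromosome), and
#' whether the nearest gene is among the interaction targets. Enhancers
#' overlapping no PIR are skipped.
#'
#' @param enhancers enhancer intervals (`chrom`, `start`, `end`, optional
#'   `element_id`, `tissue`).
#' @param calls significance-called interactions.
#' @param fragment_map fragment map.
#' @param tss TSS table (`gene_id`, `chrom`, `tss`).
#' @param cell_type cell type label.
#' @return `data.table` with one row per enhancer-PIR overlap:
#'   `element_id`, `pir_id`, `target_genes`, `nearest_gene`,
#'   `nearest_is_target`.
#' @export
assign_enhancer_targets <- function(enhancers, calls, fragment_map, tss,
                                    cell_type) {
  sig_col <- paste0("sig_", cell_type)
  check_columns(calls, sig_col, "calls")
  enh <- data.table::as.data.table(enhancers)
  if (!"element_id" %in% names(enh)) enh[, element_id := sprintf("EL%04d", .I)]
  pirs <- pir_fragments(calls, cell_type, cis_only = FALSE)
  pir_dt <- fragment_map[fragment_id %in% pirs]
  hits <- GenomicRanges::findOverlaps(as_granges(enh), as_granges(pir_dt))
  if (!length(hits)) return(data.table::data.table())
  sig <- calls[get(sig_col) == TRUE, .(bait_id, other_end_id)]
  genes_of_bait <- fragment_map[, .(fragment_id, gene_id)]
  out <- data.table::rbindlist(lapply(seq_along(hits), function(k) {
    e <- S4Vectors::queryHits(hits)[k]
    p <- S4Vectors::subjectHits(hits)[k]
    pid <- pir_dt$fragment_id[p]
    baits <- sig[other_end_id == pid, unique(bait_id)]
    tg <- sort(genes_of_bait[fragment_id %in% baits & !is.na(gene_id), gene_id])
    emid <- (enh$start[e] + enh$end[e]) / 2
    cand <- tss[chrom == enh$chrom[e]]
    ng <- if (nrow(cand)) cand$gene_id[which.min(abs(cand$tss - emid))]
          else NA_character_
    data.table::data.table(
      element_id = enh$element_id[e], pir_id = pid,
      target_genes = paste(tg, collapse = ";"),
      nearest_gene = ng,
      nearest_is_target = !is.na(ng) && ng %in% tg
    )
  }))
  out[]
}

#' Tissue-stratified enhancer activity enrichment
#'
#' Runs [feature_enrichment()] once per tissue label of a tissue-annotated
#' enhancer set, against the same distance-matched permutation scheme, and
#' reports a z-score per tissue.
#'
#' @param pirs PIR fragment ids.
#' @param controls a [sample_distance_matched_controls()] result.
#' @param enhancers enhancer intervals with a `tissue` column.
#' @param fragment_map fragment map.
#' @return `data.table` with `tissue`, `observed`, `permuted_mean`,
#'   `z_score`, `empirical_p`.
#' @export
tissue_activity_enrichment <- function(pirs, controls, enhancers,
                                       fragment_map) {
  enh <- data.table::as.data.table(enhancers)
  check_columns(enh, "tissue", "enhancers")
  data.table::rbindlist(lapply(sort(unique(enh$tissue)), function(tt) {
    r <- feature_enrichment(pirs, controls, enh[tissue == tt], fragment_map)
    data.table::data.table(tissue = tt, observed = r$observed,
                           permuted_mean = r$permuted_mean,
                           z_score = r$z_score, empirical_p = r$empirical_p)
  }))
}
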
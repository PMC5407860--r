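## Cis-regulatory units: construction from significant calls, spans,
## containment in topological domains with a structure-preserving
## permutation null, state-fraction clustering and state classification.

ASSIGNABLE_STATES <- c("active", "poised", "polycomb", "background")

#' Classify a CRU from its PIR states
#'
#' A CRU containing active (and possibly background) PIRs is
#' `single_active`; one containing poised and/or polycomb (and possibly
#' background) PIRs is `single_repressed`; one containing both active and
#' repressed PIRs is `dual`; one containing only background PIRs is
#' `background`. Mixed and intermediate PIRs do not contribute.
#'
#' @param states character vector of broad PIR states.
#' @return one of `single_active`, `single_repressed`, `dual`,
#'   `background`, or `NA` if no PIR has an assignable state.
#' @export
classify_cru <- function(states) {
  states <- states[states %in% ASSIGNABLE_STATES]
  if (!length(states)) return(NA_character_)
  act <- any(states == "active")
  rep_ <- any(states %in% c("poised", "polycomb"))
  if (act && rep_) return("dual")
  if (act) return("single_active")
  if (rep_) return("single_repressed")
  "background"
}

#' Build cis-regulatory units
#'
#' One CRU per protein-coding baited fragment with at least one significant
#' PIR in the given cell type: the promoter together with all of its PIRs,
#' their broad-state composition (fractions of assignable PIRs in the
#' active, poised and polycomb states; the remainder is background), the CRU
#' span (maximum minus minimum coordinate over the bait and its cis PIR
#' fragments; trans PIRs excluded, `NA` if no cis PIR) and the CRU class.
#' CRUs whose PIRs are all mixed or intermediate are excluded.
#'
#' @param calls significance-called interactions.
#' @param fragment_map fragment map.
#' @param states fragment states for `cell_type` (see [fragment_states()]).
#' @param cell_type cell type label.
#' @return `data.table` of class `cru_set` with one row per CRU:
#'   `bait_id`, `gene_id`, `pir_ids` (list), `n_pirs`, `n_assignable`,
#'   `frac_active`, `frac_poised`, `frac_polycomb`, `n_background`,
#'   `span_bp`, `class`.
#' @export
build_crus <- function(calls, fragment_map, states, cell_type) {
  sig_col <- paste0("sig_", cell_type)
  check_columns(calls, sig_col, "calls")
  fm <- fragment_map
  st <- states[, .(fragment_id, broad_state)]
  sig <- calls[get(sig_col) == TRUE]
  pc_baits <- fm[bait == TRUE & protein_coding == TRUE, fragment_id]
  sig <- sig[bait_id %in% pc_baits]
  if (!nrow(sig)) {
    empty <- data.table::data.table()
    return(structure(empty, class = c("cru_set", class(empty))))
  }
  sig[st, on = c(other_end_id = "fragment_id"), pir_state := i.broad_state]
  fm_idx <- fm[, .(fragment_id, chrom, start, end, gene_id)]
  out <- sig[, {
    pirs <- unique(other_end_id)
    stt <- pir_state[match(pirs, other_end_id)]
    assign <- stt[stt %in% ASSIGNABLE_STATES]
    bait_row <- fm_idx[fragment_id == bait_id[1]]
    cis_pirs <- fm_idx[fragment_id %in% pirs & chrom == bait_row$chrom]
    span <- if (nrow(cis_pirs)) {
      max(c(cis_pirs$end, bait_row$end)) - min(c(cis_pirs$start, bait_row$start))
    } else NA_real_
    list(
      gene_id = bait_row$gene_id,
      pir_ids = list(pirs),
      n_pirs = length(pirs),
      n_assignable = length(assign),
      frac_active = if (length(assign)) mean(assign == "active") else NA_real_,
      frac_poised = if (length(assign)) mean(assign == "poised") else NA_real_,
      frac_polycomb = if (length(assign)) mean(assign == "polycomb") else NA_real_,
      n_background = sum(assign == "background"),
      span_bp = span,
      class = classify_cru(stt)
    )
  }, by = bait_id]
  out <- out[n_assignable > 0L]   # all-mixed/intermediate CRUs excluded
  out <- out[]
  structure(out, class = c("cru_set", class(out)))
}

#' Span of one CRU
#'
#' Maximum minus minimum coordinate over the bait fragment and its cis PIR
#' fragments; trans PIRs are ignored and the span is `NA` when no cis PIR
#' exists.
#'
#' @param bait_id bait fragment id.
#' @param pir_ids PIR fragment ids.
#' @param fragment_map fragment map.
#' @return span in bp, or `NA`.
#' @export
cru_span <- function(bait_id, pir_ids, fragment_map) {
  b <- fragment_map[fragment_id == bait_id]
  p <- fragment_map[fragment_id %in% pir_ids & chrom == b$chrom]
  if (!nrow(p)) return(NA_real_)
  max(c(p$end, b$end)) - min(c(p$start, b$start))
}

#' Merge transitively overlapping domains into their hulls
#'
#' Replaces every set of transitively overlapping intervals by its convex
#' hull (union span), leaving disjoint intervals unchanged.
#'
#' @param domains `data.table` with `chrom`, `start`, `end`.
#' @return merged `data.table`, sorted.
#' @export
merge_overlapping_domains <- function(domains) {
  gr <- GenomicRanges::reduce(as_granges(data.table::as.data.table(domains)))
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )[order(chrom, start)]
}

## 12-bin containment histogram bin of a fraction in [0, 1]:
## bin 1 = exactly 0, bin 12 = exactly 1, bins 2..11 = (0, 0.1], ... (0.9, 1).
containment_bin <- function(frac) {
  ifelse(frac == 0, 1L,
         ifelse(frac == 1, 12L,
                pmin(pmax(ceiling(frac * 10) + 1L, 2L), 11L)))
}

## domain index of positions (NA when outside every domain); domains must be
## disjoint within a chromosome.
domain_of_position <- function(chrom, pos, domains) {
  out <- rep(NA_integer_, length(pos))
  for (cc in unique(chrom)) {
    d <- domains[domains$chrom == cc]
    if (!nrow(d)) next
    d <- d[order(start)]
    sel <- which(chrom == cc)
    k <- findInterval(pos[sel], d$start)
    ok <- k >= 1L & pos[sel] < d$end[pmax(k, 1L)]
    out[sel[ok]] <- which(domains$chrom == cc)[k[ok]]
  }
  out
}

#' Containment of CRUs within topological domains
#'
#' For every CRU whose bait fragment lies fully inside one domain (baits
#' overlapping a domain boundary, or outside every domain, are excluded),
#' computes the fraction of its cis PIRs falling inside the bait's domain,
#' collects the fractions into 12 bins (bin 1 holds exactly 0%, bin 12
#' exactly 100%, the rest 10% intervals) and compares the per-bin fractions
#' against `n_perm` structure-preserving permutations in which each CRU's
#' bait is relocated to a random promoter fragment while every PIR keeps its
#' offset to the bait (PIRs pushed beyond a chromosome end are dropped from
#' that permutation).
#'
#' @param crus a `cru_set` (see [build_crus()]).
#' @param domains disjoint domain intervals (pre-merge with
#'   [merge_overlapping_domains()] if needed).
#' @param fragment_map fragment map.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return object of class `containment_profile`: list with `observed`
#'   (per-bin fractions), `observed_counts`, `n_evaluated`, `permuted`
#'   (matrix `n_perm x 12`), `ci95`, `p_enrich` (per-bin
#'   `(1 + #\{perm >= obs\}) / (n_perm + 1)`), `p_deplete`, and the per-CRU
#'   fractions.
#' @export
containment_test <- function(crus, domains, fragment_map, n_perm = 1000L,
                             seed = 1L) {
  domains <- data.table::as.data.table(domains)[order(chrom, start)]
  fm <- fragment_map
  fm_mid <- (fm$start + fm$end) / 2
  chrom_len <- fm[, .(len = max(end)), by = chrom]

  ## flatten CRUs to (cru, bait, pir offsets on the bait's chromosome)
  flat <- data.table::rbindlist(lapply(seq_len(nrow(crus)), function(i) {
    b <- crus$bait_id[i]
    bi <- match(b, fm$fragment_id)
    pirs <- crus$pir_ids[[i]]
    pi <- match(pirs, fm$fragment_id)
    keep <- fm$chrom[pi] == fm$chrom[bi]
    if (!any(keep)) return(NULL)
    data.table::data.table(cru = i, bait_id = b,
                           offset = fm_mid[pi[keep]] - fm_mid[bi])
  }))
  if (is.null(flat) || !nrow(flat)) stopf("no cis PIRs to evaluate")

  bait_pool <- fm[bait == TRUE]
  bait_dom_start <- domain_of_position(bait_pool$chrom, bait_pool$start, domains)
  bait_dom_end <- domain_of_position(bait_pool$chrom, bait_pool$end - 1, domains)
  bait_dom <- ifelse(!is.na(bait_dom_start) & !is.na(bait_dom_end) &
                       bait_dom_start == bait_dom_end, bait_dom_start,
                     NA_integer_)

  eval_profile <- function(bait_rows) {
    ## bait_rows: index into bait_pool per CRU
    dom <- bait_dom[bait_rows]
    res <- rep(NA_real_, nrow(crus))
    bm <- (bait_pool$start[bait_rows] + bait_pool$end[bait_rows]) / 2
    bc <- bait_pool$chrom[bait_rows]
    clen <- chrom_len$len[match(bc, chrom_len$chrom)]
    for (i in which(!is.na(dom))) {
      off <- flat[cru == i, offset]
      if (!length(off)) next
      p <- bm[i] + off
      ok <- p >= 0 & p <= clen[i]
      if (!any(ok)) next
      d <- domains[dom[i]]
      res[i] <- mean(p[ok] >= d$start & p[ok] < d$end)
    }
    res
  }

  obs_rows <- match(crus$bait_id, bait_pool$fragment_id)
  obs_frac <- eval_profile(obs_rows)
  n_eval <- sum(!is.na(obs_frac))
  if (!n_eval) stopf("no CRU could be evaluated against the domains")
  obs_counts <- tabulate(containment_bin(obs_frac[!is.na(obs_frac)]), 12L)

  with_replacement <- nrow(bait_pool) < nrow(crus)
  if (with_replacement) {
    warnf("fewer promoter fragments than CRUs; permuting with replacement")
  }
  perm <- withr::with_seed(seed, {
    t(vapply(seq_len(n_perm), function(p) {
      rows <- sample.int(nrow(bait_pool), nrow(crus),
                         replace = with_replacement)
      f <- eval_profile(rows)
      f <- f[!is.na(f)]
      if (!length(f)) return(rep(0, 12))
      tabulate(containment_bin(f), 12L) / length(f)
    }, numeric(12)))
  })
  observed <- obs_counts / n_eval
  structure(list(
    observed = observed,
    observed_counts = obs_counts,
    n_evaluated = n_eval,
    permuted = perm,
    ci95 = apply(perm, 2, quantile, c(0.025, 0.975)),
    p_enrich = vapply(1:12, function(b)
      (1 + sum(perm[, b] >= observed[b])) / (n_perm + 1), numeric(1)),
    p_deplete = vapply(1:12, function(b)
      (1 + sum(perm[, b] <= observed[b])) / (n_perm + 1), numeric(1)),
    fractions = obs_frac
  ), class = "containment_profile")
}

#' @export
print.containment_profile <- function(x, ...) {
  cat(sprintf("CRU containment profile over %d CRUs\n", x$n_evaluated))
  cat(sprintf("  fully contained (bin 12): %.1f%% observed vs %.1f%% permuted (p = %.3g)\n",
              100 * x$observed[12], 100 * mean(x$permuted[, 12]),
              x$p_enrich[12]))
  cat(sprintf("  fully outside (bin 1): %.1f%% observed vs %.1f%% permuted\n",
              100 * x$observed[1], 100 * mean(x$permuted[, 1])))
  invisible(x)
}

#' Cluster CRUs by PIR state composition
#'
#' Hierarchical clustering of the CRU state-fraction vectors (active,
#' poised, polycomb; mixed and intermediate PIRs do not contribute) with
#' Euclidean distances and average-linkage agglomeration, cut at `k`
#' clusters.
#'
#' @param crus a `cru_set`.
#' @param k number of clusters (reduced with a warning if fewer CRUs).
#' @return list with `assignments` (integer per CRU), `hclust` (the tree),
#'   and `crus` (the input with a `cluster_id` column).
#' @export
cluster_crus <- function(crus, k = 8L) {
  check_columns(crus, c("frac_active", "frac_poised", "frac_polycomb"),
                "cru_set")
  m <- as.matrix(crus[, .(frac_active, frac_poised, frac_polycomb)])
  if (nrow(m) < 2) stopf("need at least two CRUs to cluster")
  if (nrow(m) < k) {
    warnf("only %d CRUs; reducing k from %d", nrow(m), k)
    k <- nrow(m)
  }
  hc <- hclust(dist(m, method = "euclidean"), method = "average")
  assignments <- cutree(hc, k = k)
  out <- data.table::copy(crus)
  out[, cluster_id := assignments]
  list(assignments = assignments, hclust = hc, crus = out[])
}

#' CRU class transitions between cell types and expression association
#'
#' Matches CRUs of two cell types by bait, tabulates class transitions
#' (CRUs absent in one cell type enter a `no_cru` category), computes log2
#' odds ratios of each (transition, DE direction) combination against its
#' marginal expectation (Haldane +0.5 on zero cells), and a Fisher exact
#' test on the collapsed 2x2 table of gain-of-active vs loss-of-active
#' transitions against up- vs down-regulation.
#'
#' @param crus_a,crus_b `cru_set`s for the first and second cell type.
#' @param de_table expression table with `gene_id`, `log2fc`, `padj`.
#' @param log2fc_min,padj_max DE thresholds defining up/down.
#' @return list with `transitions` (counts), `log2_odds` (matrix
#'   transition x direction), `fisher_p`, `gain_loss_table`, `table`
#'   (per-CRU detail).
#' @export
transition_matrix <- function(crus_a, crus_b, de_table, log2fc_min = 1.5,
                              padj_max = 0.05) {
  a <- crus_a[, .(bait_id, gene_id, class_a = class)]
  b <- crus_b[, .(bait_id, class_b = class)]
  m <- merge(a, b, by = "bait_id", all = TRUE)
  m[is.na(class_a), class_a := "no_cru"]
  m[is.na(class_b), class_b := "no_cru"]
  de <- data.table::as.data.table(de_table)
  m[de, on = "gene_id", `:=`(log2fc = i.log2fc, padj = i.padj)
    ][, direction := data.table::fcase(
        !is.na(log2fc) & !is.na(padj) & padj < padj_max & log2fc > log2fc_min, "up",
        !is.na(log2fc) & !is.na(padj) & padj < padj_max & log2fc < -log2fc_min, "down",
        default = "unchanged")]
  m[, transition := paste0(class_a, "->", class_b)]
  trans_counts <- m[, .N, by = .(class_a, class_b)]

  tab <- table(m$transition, factor(m$direction, c("up", "down", "unchanged")))
  lo <- matrix(NA_real_, nrow(tab), ncol(tab), dimnames = dimnames(tab))
  tot <- sum(tab)
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    aa <- tab[i, j]; bb <- sum(tab[i, ]) - aa
    cc <- sum(tab[, j]) - aa; dd <- tot - aa - bb - cc
    lo[i, j] <- log2(odds_ratio_2x2(aa, bb, cc, dd))
  }

  gain <- m$class_b == "single_active" & m$class_a != "single_active" &
    m$class_a != "no_cru" & m$class_b != "no_cru"
  loss <- m$class_a == "single_active" & m$class_b != "single_active" &
    m$class_a != "no_cru" & m$class_b != "no_cru"
  gl <- matrix(c(sum(gain & m$direction == "up"),
                 sum(gain & m$direction == "down"),
                 sum(loss & m$direction == "up"),
                 sum(loss & m$direction == "down")),
               2, 2, byrow = TRUE,
               dimnames = list(c("gain_active", "loss_active"),
                               c("up", "down")))
  fisher_p <- if (all(rowSums(gl) > 0) && all(colSums(gl) > 0)) {
    fisher.test(gl)$p.value
  } else NA_real_
  list(transitions = trans_counts[], log2_odds = lo, fisher_p = fisher_p,
       gain_loss_table = gl, table = m[])
}
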
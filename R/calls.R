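## Interaction-call handling: loading score tables against a fragment map,
## significance thresholding with the rescue band, and per-promoter PIR
## statistics.

#' Load interaction scores against a fragment map
#'
#' Resolves both fragment ids of every scored pair in the fragment map,
#' classifies pairs as cis or trans, and computes cis interaction distances
#' as the separation between fragment midpoints. Rows whose ids cannot be
#' resolved are dropped with a warning reporting the count.
#'
#' @param scores score table (`data.table` or path readable by
#'   [read_score_table()]).
#' @param fragment_map fragment map `data.table`.
#' @param cell_types the two cell-type labels expected in the score columns.
#' @return `data.table` of interaction calls with `bait_id`, `other_end_id`,
#'   score columns, `is_cis` and `distance` (`NA` for trans pairs).
#' @export
load_scores <- function(scores, fragment_map, cell_types = c("ESC", "NEC")) {
  if (is.character(scores)) scores <- read_score_table(scores, cell_types)
  scores <- data.table::as.data.table(scores)
  check_columns(scores, c("bait_id", "other_end_id"), "score table")
  for (ct in cell_types) {
    m <- paste0("merged_", ct)
    if (!m %in% names(scores)) {
      r1 <- paste0("score_rep1_", ct); r2 <- paste0("score_rep2_", ct)
      check_columns(scores, c(r1, r2), "score table")
      scores[[m]] <- (scores[[r1]] + scores[[r2]]) / 2
    }
  }
  fm <- fragment_map[, .(fragment_id, chrom, start, end, bait)]
  fm[, mid := (start + end) / 2]
  calls <- data.table::copy(scores)
  bi <- match(calls$bait_id, fm$fragment_id)
  oi <- match(calls$other_end_id, fm$fragment_id)
  bad <- is.na(bi) | is.na(oi)
  if (any(bad)) {
    warnf("%d row(s) with unresolvable fragment ids dropped", sum(bad))
    calls <- calls[!bad]; bi <- bi[!bad]; oi <- oi[!bad]
  }
  if (!nrow(calls)) {
    calls[, `:=`(bait_chrom = character(), oe_chrom = character(),
                 is_cis = logical(), distance = numeric())]
    return(calls[])
  }
  calls[, bait_chrom := fm$chrom[bi]]
  calls[, oe_chrom := fm$chrom[oi]]
  calls[, is_cis := bait_chrom == oe_chrom]
  calls[, distance := ifelse(is_cis, abs(fm$mid[oi] - fm$mid[bi]), NA_real_)]
  calls[]
}

#' Apply the significance threshold with the rescue band
#'
#' An interaction is significant in a cell type if its merged score reaches
#' the threshold (default 12), or falls in the rescue band (default
#' `[11, 12)`) while reaching the threshold in the other cell type. Rescue
#' can only add significance: the threshold-only call set is always a subset
#' of the rescued set.
#'
#' @param calls interaction calls (see [load_scores()]).
#' @param threshold significance threshold on the merged score.
#' @param rescue_low lower edge of the rescue band.
#' @param cell_types the two cell-type labels.
#' @return the calls with logical columns `sig_<cell>` added.
#' @export
call_significant <- function(calls, threshold = 12, rescue_low = 11,
                             cell_types = c("ESC", "NEC")) {
  calls <- data.table::as.data.table(calls)
  m1 <- calls[[paste0("merged_", cell_types[1])]]
  m2 <- calls[[paste0("merged_", cell_types[2])]]
  if (is.null(m1) || is.null(m2)) {
    stopf("merged scores must be present for both cell types")
  }
  calls[, (paste0("sig_", cell_types[1])) :=
          m1 >= threshold | (m1 >= rescue_low & m1 < threshold & m2 >= threshold)]
  calls[, (paste0("sig_", cell_types[2])) :=
          m2 >= threshold | (m2 >= rescue_low & m2 < threshold & m1 >= threshold)]
  calls[]
}

#' Count PIRs per promoter
#'
#' Counts the distinct other-end fragments significantly interacting with
#' each bait in one cell type. Baits present in the call table but without a
#' significant PIR are reported with `n_pirs = 0` and `interacting = FALSE`.
#'
#' @param calls significance-called interactions.
#' @param cell_type cell type whose significance flags to use.
#' @return `data.table` with `bait_id`, `n_pirs`, `interacting`.
#' @export
pirs_per_promoter <- function(calls, cell_type) {
  sig_col <- paste0("sig_", cell_type)
  check_columns(calls, sig_col, "calls")
  out <- calls[, .(n_pirs = data.table::uniqueN(other_end_id[get(sig_col)])),
               by = bait_id]
  out[, interacting := n_pirs > 0L]
  out[]
}

#' Extract the PIR fragment set of one cell type
#'
#' @param calls significance-called interactions.
#' @param cell_type cell type label.
#' @param cis_only keep only cis interactions.
#' @return integer vector of distinct PIR fragment ids.
#' @export
pir_fragments <- function(calls, cell_type, cis_only = TRUE) {
  sig_col <- paste0("sig_", cell_type)
  check_columns(calls, sig_col, "calls")
  x <- calls[get(sig_col) == TRUE]
  if (cis_only && "is_cis" %in% names(x)) x <- x[is_cis == TRUE]
  sort(unique(x$other_end_id))
}
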
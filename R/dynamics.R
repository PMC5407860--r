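## Interaction dynamics between cell states: high-confidence retained vs
## rewired interactions, PIR recolouring, and their association with each
## other and with gene expression change.

#' Classify interactions as retained, rewired or unclassified
#'
#' Retained interactions score at or above the threshold in both replicates
#' of both cell types. Candidate rewired interactions score at or above the
#' threshold in both replicates of one cell type and below it in both
#' replicates of the other; candidates are then placed into five equal-size
#' score bins per cell type and called rewired only when they fall in the
#' top bin of their high cell type and the bottom bin of the other. With the
#' default `bin_mode = "global"`, bin edges are the merged-score quintiles
#' of the full interaction table per cell type; `bin_mode = "candidates"`
#' bins the candidates alone. Ties are broken deterministically by
#' (score, bait id, other-end id). When fragment states are supplied,
#' interactions whose PIR is mixed or intermediate in either cell type are
#' set aside as `unclassified`.
#'
#' @param calls interaction calls with replicate and merged scores.
#' @param threshold replicate score threshold.
#' @param cell_types the two cell-type labels.
#' @param bin_mode `"global"` or `"candidates"` (see Details).
#' @param states_a,states_b optional [fragment_states()] tables for the two
#'   cell types, used to remove mixed/intermediate PIRs.
#' @return the calls with columns `quintile_<cell>` (integer 1-5) and
#'   `rewiring` (`retained`, `rewired_<cell>`, `unclassified`).
#' @export
filter_rewired_retained <- function(calls, threshold = 12,
                                    cell_types = c("ESC", "NEC"),
                                    bin_mode = c("global", "candidates"),
                                    states_a = NULL, states_b = NULL) {
  bin_mode <- match.arg(bin_mode)
  dyn <- data.table::copy(data.table::as.data.table(calls))
  ct <- cell_types
  r <- lapply(1:2, function(i) list(
    r1 = dyn[[paste0("score_rep1_", ct[i])]],
    r2 = dyn[[paste0("score_rep2_", ct[i])]],
    m = dyn[[paste0("merged_", ct[i])]]
  ))
  if (any(vapply(r, function(x) any(vapply(x, is.null, logical(1))),
                 logical(1)))) {
    stopf("replicate and merged scores must be present for both cell types")
  }
  conc <- lapply(r, function(x) x$r1 >= threshold & x$r2 >= threshold)
  below <- lapply(r, function(x) x$r1 < threshold & x$r2 < threshold)
  retained <- conc[[1]] & conc[[2]]
  cand1 <- conc[[1]] & below[[2]]   # high in cell type 1
  cand2 <- conc[[2]] & below[[1]]

  quint <- function(scores, subset = NULL) {
    idx <- if (is.null(subset)) seq_along(scores) else which(subset)
    n <- length(idx)
    out <- rep(NA_integer_, length(scores))
    if (n == 0) return(out)
    ord <- idx[order(scores[idx], dyn$bait_id[idx], dyn$other_end_id[idx])]
    out[ord] <- as.integer(ceiling(5 * seq_len(n) / n))
    out
  }
  if (bin_mode == "global") {
    q1 <- quint(r[[1]]$m); q2 <- quint(r[[2]]$m)
  } else {
    cand <- cand1 | cand2
    if (sum(cand) < 5L) {
      warnf("fewer than 5 rewiring candidates; rewired set is empty")
      q1 <- q2 <- rep(NA_integer_, nrow(dyn))
    } else {
      q1 <- quint(r[[1]]$m, cand); q2 <- quint(r[[2]]$m, cand)
    }
  }
  dyn[, (paste0("quintile_", ct[1])) := q1]
  dyn[, (paste0("quintile_", ct[2])) := q2]

  rew1 <- cand1 & !is.na(q1) & !is.na(q2) & q1 == 5L & q2 == 1L
  rew2 <- cand2 & !is.na(q1) & !is.na(q2) & q2 == 5L & q1 == 1L
  dyn[, rewiring := data.table::fcase(
    retained, "retained",
    rew1, paste0("rewired_", ct[1]),
    rew2, paste0("rewired_", ct[2]),
    default = "unclassified")]

  if (!is.null(states_a) && !is.null(states_b)) {
    bad_states <- c("mixed", "intermediate")
    bad_ids <- union(
      states_a[broad_state %in% bad_states, fragment_id],
      states_b[broad_state %in% bad_states, fragment_id]
    )
    dyn[other_end_id %in% bad_ids, rewiring := "unclassified"]
  }
  dyn[]
}

#' Annotate PIR recolouring
#'
#' Adds the PIR's broad chromatin state in each cell type and a
#' `recoloured` flag (state differs between cell types).
#'
#' @param dyn classified interactions (see [filter_rewired_retained()]).
#' @param states_a,states_b [fragment_states()] tables for the two cell
#'   types.
#' @param cell_types the two cell-type labels.
#' @return `dyn` with `state_<cellA>`, `state_<cellB>` and `recoloured`
#'   columns.
#' @export
classify_recolouring <- function(dyn, states_a, states_b,
                                 cell_types = c("ESC", "NEC")) {
  dyn <- data.table::copy(dyn)
  ca <- paste0("state_", cell_types[1])
  cb <- paste0("state_", cell_types[2])
  dyn[states_a, on = c(other_end_id = "fragment_id"), (ca) := i.broad_state]
  dyn[states_b, on = c(other_end_id = "fragment_id"), (cb) := i.broad_state]
  dyn[, recoloured := get(ca) != get(cb)]
  dyn[]
}

#' Fraction of retained PIRs undergoing recolouring
#'
#' @param dyn output of [classify_recolouring()].
#' @return proportion in `[0, 1]`.
#' @export
retained_recoloured_fraction <- function(dyn) {
  x <- dyn[rewiring == "retained"]
  if (!nrow(x)) return(NA_real_)
  mean(x$recoloured, na.rm = TRUE)
}

#' Association between rewiring and recolouring
#'
#' Cross-tabulates the rewiring class (retained / rewired in either cell
#' type) against the PIR state transition, reports the log2 odds ratio of
#' every cell against its marginal expectation (Haldane +0.5 on zero cells;
#' empty categories are `NA`), and a Fisher exact test on the collapsed
#' 2x2 table of rewired-vs-retained against recoloured-vs-stable.
#'
#' @param dyn output of [classify_recolouring()].
#' @param cell_types the two cell-type labels.
#' @return list with `table`, `log2_odds`, `fisher_p`,
#'   `collapsed` (the 2x2 table).
#' @export
rewiring_recolouring_association <- function(dyn,
                                             cell_types = c("ESC", "NEC")) {
  ca <- paste0("state_", cell_types[1])
  cb <- paste0("state_", cell_types[2])
  x <- dyn[rewiring != "unclassified" &
             get(ca) %in% ASSIGNABLE_STATES & get(cb) %in% ASSIGNABLE_STATES]
  if (!nrow(x)) stopf("no classified interactions with assignable states")
  x[, transition := ifelse(recoloured, paste0(get(ca), "->", get(cb)),
                           "stable")]
  tab <- table(x$rewiring, x$transition)
  tot <- sum(tab)
  lo <- matrix(NA_real_, nrow(tab), ncol(tab), dimnames = dimnames(tab))
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    a <- tab[i, j]; b <- sum(tab[i, ]) - a
    c <- sum(tab[, j]) - a; d <- tot - a - b - c
    if (sum(tab[i, ]) == 0 || sum(tab[, j]) == 0) next
    lo[i, j] <- log2(odds_ratio_2x2(a, b, c, d))
  }
  collapsed <- matrix(c(
    sum(tab[grep("^rewired", rownames(tab)), colnames(tab) != "stable"]),
    sum(tab[grep("^rewired", rownames(tab)), colnames(tab) == "stable"]),
    sum(tab[rownames(tab) == "retained", colnames(tab) != "stable"]),
    sum(tab[rownames(tab) == "retained", colnames(tab) == "stable"])
  ), 2, 2, byrow = TRUE,
  dimnames = list(c("rewired", "retained"), c("recoloured", "stable")))
  fisher_p <- if (all(rowSums(collapsed) > 0)) fisher.test(collapsed)$p.value
              else NA_real_
  list(table = tab, log2_odds = lo, fisher_p = fisher_p,
       collapsed = collapsed)
}

#' Expression change at gained vs lost active PIRs
#'
#' Two one-sided Wilcoxon rank-sum tests of the hypothesis that genes
#' gaining an active-state PIR show higher expression log2 fold changes
#' than genes losing one: once for recolouring (retained interactions whose
#' PIR switches into/out of the active state) and once for rewiring (gained
#' or lost interactions whose PIR is active in the cell type holding the
#' interaction). Events enter once per PIR; a scenario with fewer than
#' `min_n` events per arm is skipped (`p = NA`) with the sizes reported.
#'
#' @param dyn output of [classify_recolouring()].
#' @param de_table expression table with `gene_id`, `log2fc`.
#' @param fragment_map fragment map (for bait gene lookup).
#' @param cell_types the two cell-type labels; the second is the state the
#'   cells commit to.
#' @param min_n minimum events per arm.
#' @return list with elements `recolouring` and `rewiring`, each holding
#'   `n_gain`, `n_loss`, `p`, `median_gain`, `median_loss`.
#' @export
expression_association <- function(dyn, de_table, fragment_map,
                                   cell_types = c("ESC", "NEC"),
                                   min_n = 3L) {
  ca <- paste0("state_", cell_types[1])
  cb <- paste0("state_", cell_types[2])
  de <- data.table::as.data.table(de_table)
  x <- data.table::copy(dyn)
  x[fragment_map, on = c(bait_id = "fragment_id"), gene_id := i.gene_id]
  x[de, on = "gene_id", log2fc := i.log2fc]
  x <- x[!is.na(log2fc)]

  run_test <- function(gain, loss) {
    g <- x$log2fc[gain]; l <- x$log2fc[loss]
    res <- list(n_gain = length(g), n_loss = length(l), p = NA_real_,
                median_gain = median(g), median_loss = median(l))
    if (length(g) >= min_n && length(l) >= min_n) {
      res$p <- wilcox.test(g, l, alternative = "greater", exact = FALSE)$p.value
    }
    res
  }
  ret <- x$rewiring == "retained"
  reco <- list(
    gain = ret & x[[ca]] != "active" & x[[cb]] == "active",
    loss = ret & x[[ca]] == "active" & x[[cb]] != "active"
  )
  rew <- list(
    gain = x$rewiring == paste0("rewired_", cell_types[2]) &
      x[[cb]] == "active",
    loss = x$rewiring == paste0("rewired_", cell_types[1]) &
      x[[ca]] == "active"
  )
  list(recolouring = run_test(reco$gain, reco$loss),
       rewiring = run_test(rew$gain, rew$loss))
}
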
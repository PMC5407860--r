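make_states <- function(fm, states) {
  data.table::data.table(fragment_id = fm$fragment_id, cell_type = "ESC",
                         broad_state = states)
}

test_that("CRUs collect PIR state fractions over protein-coding baits", {
  fm <- toy_fragment_map(30, baits = c(3, 15))
  fm[fragment_id == 15, protein_coding := FALSE]
  sc <- rbind(score_row(3, 9, esc = c(13, 13)),
              score_row(3, 12, esc = c(14, 14)),
              score_row(3, 20, esc = c(15, 15)),
              score_row(15, 25, esc = c(15, 15)))
  calls <- call_significant(load_scores(sc, fm))
  states <- make_states(fm, "background")
  states[fragment_id %in% c(9, 12), broad_state := "active"]
  crus <- build_crus(calls, fm, states, "ESC")
  expect_equal(nrow(crus), 1)          # non-protein-coding bait: no CRU
  expect_equal(crus$bait_id, 3)
  expect_equal(crus$frac_active, 2 / 3)
  expect_equal(crus$frac_poised, 0)
  expect_equal(crus$frac_polycomb, 0)
  expect_equal(crus$n_background, 1)
  expect_equal(crus$class, "single_active")
  ## span: bait [8000,12000), PIRs up to fragment 20 [76000,80000)
  expect_equal(crus$span_bp, 80000 - 8000)
})

test_that("CRUs whose PIRs are all mixed or intermediate are excluded", {
  fm <- toy_fragment_map(30, baits = 3)
  sc <- score_row(3, 9, esc = c(13, 13))
  calls <- call_significant(load_scores(sc, fm))
  states <- make_states(fm, "background")
  states[fragment_id == 9, broad_state := "mixed"]
  expect_equal(nrow(build_crus(calls, fm, states, "ESC")), 0)
})

test_that("CRU span uses the cis hull and ignores trans PIRs", {
  fm <- rbind(toy_fragment_map(30, baits = 3),
              toy_fragment_map(5, baits = integer(), chrom = "chr2")[,
                fragment_id := fragment_id + 100L][])
  ## bait 3: [8000,12000); cis PIR 13: [48000,52000) -> span 44000
  expect_equal(cru_span(3, 13, fm), 44000)
  expect_equal(cru_span(3, c(13, 101), fm), 44000)   # trans PIR ignored
  expect_true(is.na(cru_span(3, 101, fm)))           # trans only: undefined
  ## adding a PIR inside the hull leaves the span unchanged
  expect_equal(cru_span(3, c(13, 7), fm), 44000)
})

test_that("overlapping domains merge into hulls, disjoint ones stay", {
  d <- data.table::data.table(chrom = "chr1", start = c(0, 5, 30, 18),
                              end = c(10, 20, 40, 22))
  m <- merge_overlapping_domains(d)
  expect_equal(m$start, c(0, 30))
  expect_equal(m$end, c(22, 40))    # chain 0-10, 5-20, 18-22 -> hull 0-22
  d2 <- data.table::data.table(chrom = "chr1", start = c(0, 100),
                               end = c(10, 110))
  expect_equal(merge_overlapping_domains(d2), d2)
})

test_that("containment fractions bin into the 12-bin profile correctly", {
  cb <- regwire:::containment_bin
  expect_equal(cb(0), 1L)
  expect_equal(cb(1), 12L)
  expect_equal(cb(0.75), 9L)     # (70, 80] -> bin 9
  expect_equal(cb(0.05), 2L)
  expect_equal(cb(0.95), 11L)
  expect_equal(cb(0.10), 2L)     # (0, 10] closes at bin 2
})

test_that("containment test evaluates CRUs against domains with exclusions", {
  fm <- toy_fragment_map(100, baits = c(10, 30, 60))
  domains <- data.table::data.table(chrom = "chr1",
                                    start = c(0, 120000, 260000),
                                    end = c(120000, 260000, 400000))
  ## bait 10 [36000,40000) in domain 1; PIRs 5, 20 in domain 1, 40 outside
  sc <- rbind(score_row(10, 5, esc = c(13, 13)),
              score_row(10, 20, esc = c(13, 13)),
              score_row(10, 40, esc = c(13, 13)),
              ## bait 30 [116000,120000) fully inside domain 1 (end-exclusive)
              score_row(30, 35, esc = c(13, 13)))
  calls <- call_significant(load_scores(sc, fm))
  states <- make_states(fm, "active")
  crus <- build_crus(calls, fm, states, "ESC")
  prof <- containment_test(crus, domains, fm, n_perm = 50, seed = 1)
  expect_equal(prof$n_evaluated, 2)
  ## bait 10: 2/3 inside -> bin ceiling(6.67)+1 = 8; bait 30: PIR 35 is in
  ## domain 2 while the bait is in domain 1 -> fraction 0 -> bin 1
  expect_equal(prof$observed_counts[8], 1)
  expect_equal(prof$observed_counts[1], 1)
  expect_equal(sum(prof$observed_counts), prof$n_evaluated)
  expect_equal(rowSums(prof$permuted), rep(1, 50), tolerance = 1e-12)
})

test_that("baits straddling a domain boundary are excluded from containment", {
  fm <- toy_fragment_map(50, baits = c(10, 25))
  ## boundary at 38000 cuts bait 10 ([36000,40000)) in half
  domains <- data.table::data.table(chrom = "chr1", start = c(0, 38000),
                                    end = c(38000, 200000))
  sc <- rbind(score_row(10, 5, esc = c(13, 13)),
              score_row(25, 30, esc = c(13, 13)))
  calls <- call_significant(load_scores(sc, fm))
  crus <- build_crus(calls, fm, make_states(fm, "active"), "ESC")
  prof <- containment_test(crus, domains, fm, n_perm = 20, seed = 1)
  expect_equal(prof$n_evaluated, 1)   # only bait 25 evaluated
})

test_that("CRUs planted inside TADs show full-containment enrichment", {
  st <- test_study()
  calls <- study_calls(st)
  states <- study_states(st)
  crus <- build_crus(calls, st$fragment_map, states$ESC, "ESC")
  prof <- containment_test(crus, st$manifest$tads, st$fragment_map,
                           n_perm = 200, seed = 7)
  expect_gt(prof$observed[12], mean(prof$permuted[, 12]))
  expect_lte(prof$p_enrich[12], 0.01)
})

test_that("average-linkage clustering matches a brute-force O(n^3) oracle", {
  set.seed(4)
  x <- matrix(runif(36), 12, 3)
  crus <- data.table::data.table(bait_id = 1:12, frac_active = x[, 1],
                                 frac_poised = x[, 2], frac_polycomb = x[, 3])
  cl <- cluster_crus(crus, k = 3)
  expect_equal(sort(unique(cl$assignments)), 1:3)
  oracle <- naive_average_linkage_heights(x)
  expect_equal(sort(cl$hclust$height), sort(oracle), tolerance = 1e-10)

  ## identical vectors always co-cluster; the three unit vectors split at k=3
  unitv <- data.table::data.table(bait_id = 1:6,
                                  frac_active = c(1, 1, 0, 0, 0, 0),
                                  frac_poised = c(0, 0, 1, 1, 0, 0),
                                  frac_polycomb = c(0, 0, 0, 0, 1, 1))
  clu <- cluster_crus(unitv, k = 3)
  expect_equal(clu$assignments[1], clu$assignments[2])
  expect_equal(length(unique(clu$assignments)), 3)
  expect_warning(cluster_crus(unitv[1:2], k = 8), "reducing k")
})

test_that("CRU classification matches its exhaustive truth table", {
  expect_equal(classify_cru(c("active", "background")), "single_active")
  expect_equal(classify_cru(c("poised", "polycomb")), "single_repressed")
  expect_equal(classify_cru(c("active", "poised")), "dual")
  expect_equal(classify_cru("background"), "background")
  expect_true(is.na(classify_cru(c("mixed", "intermediate"))))
  ## exhaustive: all subsets of assignable states
  sts <- c("active", "poised", "polycomb", "background")
  for (k in 1:4) for (s in combn(sts, k, simplify = FALSE)) {
    act <- "active" %in% s
    rep_ <- any(c("poised", "polycomb") %in% s)
    want <- if (act && rep_) "dual" else if (act) "single_active"
            else if (rep_) "single_repressed" else "background"
    expect_equal(classify_cru(s), want, label = paste(s, collapse = "+"))
  }
})

test_that("transition matrix counts classes and associates with expression", {
  mk_crus <- function(classes) {
    data.table::data.table(bait_id = seq_along(classes),
                           gene_id = sprintf("G%02d", seq_along(classes)),
                           class = classes)
  }
  ## all unchanged -> diagonal
  a <- mk_crus(c("single_active", "dual", "background"))
  de <- data.table::data.table(gene_id = a$gene_id, log2fc = 0, padj = 1)
  tm <- transition_matrix(a, a, de)
  expect_true(all(tm$transitions$class_a == tm$transitions$class_b))

  ## planted coupling: gains of the active state are all upregulated
  set.seed(2)
  n <- 40
  a2 <- mk_crus(rep(c("single_repressed", "single_active"), each = n / 2))
  b2 <- mk_crus(rep(c("single_active", "single_repressed"), each = n / 2))
  de2 <- data.table::data.table(
    gene_id = a2$gene_id,
    log2fc = rep(c(3, -3), each = n / 2),
    padj = 1e-6
  )
  tm2 <- transition_matrix(a2, b2, de2)
  expect_lt(tm2$fisher_p, 1e-6)
  expect_equal(unname(tm2$gain_loss_table["gain_active", "up"]), n / 2)
  ## a bait absent in one cell type lands in the no_cru category
  tm3 <- transition_matrix(a2[1:30], b2, de2)
  expect_true("no_cru" %in% tm3$table$class_a)
})
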
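test_that("replicate concordance rules classify the quoted example cases", {
  fm <- toy_fragment_map(100, baits = c(3, 15))
  sc <- rbind(
    score_row(3, 20, esc = c(13, 14), nec = c(13, 12.5)),   # retained
    score_row(3, 30, esc = c(25, 26), nec = c(1, 2)),       # rewired (ESC)
    score_row(3, 40, esc = c(13, 14), nec = c(11.5, 13)),   # unclassified
    ## filler rows so that five quantile groups exist
    data.table::rbindlist(lapply(1:20, function(i) {
      score_row(15, 40 + i, esc = c(3, 3) + i / 10, nec = c(3, 3) + i / 10)
    }))
  )
  calls <- load_scores(sc, fm)
  dyn <- filter_rewired_retained(calls)
  expect_equal(dyn$rewiring[1], "retained")
  expect_equal(dyn$rewiring[2], "rewired_ESC")
  expect_equal(dyn$rewiring[3], "unclassified")
  ## retained and rewired never intersect
  expect_equal(sum(dyn$rewiring == "retained" &
                     grepl("rewired", dyn$rewiring)), 0)
})

test_that("noiseless synthetic data is recovered exactly", {
  cfg <- synthetic_config(seed = 17, noise_sd = 0)
  st <- simulate_pchic_study(cfg, contacts = FALSE)
  calls <- load_scores(st$scores, st$fragment_map)
  dyn <- filter_rewired_retained(calls)
  man <- st$manifest$interactions
  key <- function(dt) paste(dt$bait_id, dt$other_end_id)
  expect_setequal(key(dyn[rewiring == "retained"]),
                  key(man[class == "shared"]))
  expect_setequal(key(dyn[rewiring == "rewired_ESC"]),
                  key(man[class == "esc_only"]))
  expect_setequal(key(dyn[rewiring == "rewired_NEC"]),
                  key(man[class == "nec_only"]))
})

test_that("rewired recovery stays above 0.95 precision and recall at noise 0.5", {
  st <- test_study(seed = 23, noise_sd = 0.5)
  calls <- load_scores(st$scores, st$fragment_map)
  dyn <- filter_rewired_retained(calls)
  man <- st$manifest$interactions
  key <- function(dt) paste(dt$bait_id, dt$other_end_id)
  called <- key(dyn[grepl("^rewired", rewiring)])
  planted <- key(man[class %in% c("esc_only", "nec_only")])
  expect_gte(mean(called %in% planted), 0.95)
  expect_gte(mean(planted %in% called), 0.95)
})

test_that("quintile bins are deterministic groups of near-equal size", {
  fm <- toy_fragment_map(60, baits = 3)
  sc <- data.table::rbindlist(lapply(1:23, function(i) {
    score_row(3, 3 + i, esc = c(i, i), nec = c(24 - i, 24 - i))
  }))
  calls <- load_scores(sc, fm)
  dyn <- filter_rewired_retained(calls)
  sizes <- table(dyn$quintile_ESC)
  expect_lte(max(sizes) - min(sizes), 1)
  dyn2 <- filter_rewired_retained(calls)
  expect_identical(dyn$quintile_ESC, dyn2$quintile_ESC)
  ## candidates mode warns and empties when fewer than five candidates exist
  few <- data.table::rbindlist(c(
    lapply(1:3, function(i) score_row(3, 3 + i, esc = c(13, 13), nec = c(1, 1))),
    lapply(1:10, function(i) score_row(3, 6 + i, esc = c(3, 3), nec = c(3, 3)))
  ))
  calls_few <- load_scores(few, fm)
  expect_warning(d3 <- filter_rewired_retained(calls_few,
                                               bin_mode = "candidates"),
                 "fewer than 5")
  expect_equal(sum(grepl("rewired", d3$rewiring)), 0)
})

test_that("mixed and intermediate PIRs are set aside when states are supplied", {
  st <- test_study()
  calls <- load_scores(st$scores, st$fragment_map)
  states <- study_states(st)
  dyn <- filter_rewired_retained(calls, states_a = states$ESC,
                                 states_b = states$NEC)
  bad <- union(states$ESC[broad_state %in% c("mixed", "intermediate"),
                          fragment_id],
               states$NEC[broad_state %in% c("mixed", "intermediate"),
                          fragment_id])
  expect_true(all(dyn[other_end_id %in% bad, rewiring] == "unclassified"))
})

test_that("recolouring is a broad-state change between cell types", {
  fm <- toy_fragment_map(20, baits = 3)
  sc <- score_row(3, 10, esc = c(13, 13), nec = c(13, 13))
  calls <- load_scores(sc, fm)
  dyn <- filter_rewired_retained(calls)
  sa <- data.table::data.table(fragment_id = 1:20, broad_state = "active")
  for (to in c("active", "polycomb", "background")) {
    sb <- data.table::data.table(fragment_id = 1:20, broad_state = to)
    d <- classify_recolouring(dyn, sa, sb)
    expect_equal(d$recoloured, to != "active")
  }
  ## polycomb -> active counts as recoloured too
  sp <- data.table::data.table(fragment_id = 1:20, broad_state = "polycomb")
  sact <- data.table::data.table(fragment_id = 1:20, broad_state = "active")
  expect_true(classify_recolouring(dyn, sp, sact)$recoloured)
})

test_that("the planted recolouring rate is recovered among retained PIRs", {
  st <- test_study()
  calls <- load_scores(st$scores, st$fragment_map)
  states <- study_states(st)
  dyn <- classify_recolouring(filter_rewired_retained(calls),
                              states$ESC, states$NEC)
  frac <- retained_recoloured_fraction(dyn)
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.40)   # planted rate 0.25
})

test_that("rewiring and recolouring associate when planted to co-occur", {
  st <- test_study()
  calls <- load_scores(st$scores, st$fragment_map)
  states <- study_states(st)
  dyn <- classify_recolouring(
    filter_rewired_retained(calls, states_a = states$ESC,
                            states_b = states$NEC),
    states$ESC, states$NEC)
  assoc <- rewiring_recolouring_association(dyn)
  expect_lt(assoc$fisher_p, 0.001)
  ## gained interactions recolouring into the active state: positive log2 OR
  gain_col <- grep("->active$", colnames(assoc$log2_odds), value = TRUE)
  expect_true(length(gain_col) > 0)
  expect_gt(max(assoc$log2_odds["rewired_NEC", gain_col], na.rm = TRUE), 0)
})

test_that("expression association separates active-PIR gains from losses", {
  ## fully separated groups, n = 20 each: exact rank-sum tail below 1e-6
  fm <- toy_fragment_map(100, baits = c(3, 15))
  mk <- function(oe, esc, nec) score_row(3, oe, esc = esc, nec = nec)
  sc <- data.table::rbindlist(c(
    lapply(1:20, function(i) mk(20 + i, c(13, 13), c(13, 13))),  # retained
    lapply(1:20, function(i) mk(40 + i, c(13, 13), c(13, 13)))
  ))
  calls <- load_scores(sc, fm)
  dyn <- filter_rewired_retained(calls)
  sa <- data.table::data.table(
    fragment_id = 1:100,
    broad_state = ifelse(1:100 %in% 21:40, "background", "active"))
  sb <- data.table::data.table(
    fragment_id = 1:100,
    broad_state = ifelse(1:100 %in% 21:40, "active", "background"))
  dyn <- classify_recolouring(dyn, sa, sb)
  genes <- fm[bait == TRUE, gene_id]
  de <- data.table::data.table(gene_id = genes, log2fc = c(3, -3), padj = 1e-6)
  ## gene of bait 3 gains 20 active PIRs and loses 20: split events by gene
  ## instead via two baits
  sc2 <- data.table::rbindlist(c(
    lapply(1:20, function(i) score_row(3, 20 + i, c(13, 13), c(13, 13))),
    lapply(1:20, function(i) score_row(15, 40 + i, c(13, 13), c(13, 13)))
  ))
  dyn2 <- classify_recolouring(
    filter_rewired_retained(load_scores(sc2, fm)), sa, sb)
  res <- expression_association(dyn2, de, fm)
  expect_equal(res$recolouring$n_gain, 20)
  expect_equal(res$recolouring$n_loss, 20)
  expect_lt(res$recolouring$p, 1e-6)
  ## one empty group: skipped with sizes reported
  res2 <- expression_association(dyn2[other_end_id <= 40], de, fm)
  expect_true(is.na(res2$recolouring$p))
  expect_equal(res2$recolouring$n_loss, 0)
})

test_that("planted expression coupling drives both association scenarios", {
  st <- test_study()
  calls <- load_scores(st$scores, st$fragment_map)
  states <- study_states(st)
  dyn <- classify_recolouring(
    filter_rewired_retained(calls, states_a = states$ESC,
                            states_b = states$NEC),
    states$ESC, states$NEC)
  res <- expression_association(dyn, st$expression, st$fragment_map)
  expect_lt(res$recolouring$p, 0.01)
  expect_lt(res$rewiring$p, 0.001)
})
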
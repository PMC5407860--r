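## Shared fixtures. The default synthetic study is expensive enough to build
## once per test run and reuse.

.fixture_env <- new.env(parent = emptyenv())

## small study (no contact matrices) cached across tests
test_study <- function(seed = 42L, noise_sd = 0.5) {
  key <- sprintf("study_%d_%s", seed, noise_sd)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_pchic_study(
      synthetic_config(seed = seed, noise_sd = noise_sd), contacts = FALSE)
  }
  .fixture_env[[key]]
}

study_states <- function(study) {
  key <- paste0("states_", substr(digest_config(study$config), 1, 12))
  if (is.null(.fixture_env[[key]])) {
    sts <- lapply(study$config$cell_types, function(cc) {
      suppressWarnings(fragment_states(study$fragment_map,
                                       study$segmentations[[cc]], cc))
    })
    names(sts) <- study$config$cell_types
    .fixture_env[[key]] <- sts
  }
  .fixture_env[[key]]
}

digest_config <- function(cfg) {
  paste0(cfg$seed, "_", cfg$noise_sd, "_", cfg$n_shared)
}

study_calls <- function(study) {
  call_significant(load_scores(study$scores, study$fragment_map,
                               study$config$cell_types),
                   cell_types = study$config$cell_types)
}

## tiny hand-built fragment map: one chromosome, uniform 4 kb fragments
toy_fragment_map <- function(n = 30, frag_bp = 4000, baits = c(3, 15),
                             chrom = "chr1") {
  fm <- data.table::data.table(
    fragment_id = seq_len(n),
    chrom = chrom,
    start = (seq_len(n) - 1) * frag_bp,
    end = seq_len(n) * frag_bp,
    bait = seq_len(n) %in% baits
  )
  fm[, gene_id := ifelse(bait, sprintf("G%02d", fragment_id), NA_character_)]
  fm[, protein_coding := bait]
  fm[]
}

## score-table row builder
score_row <- function(bait, oe, esc = c(0, 0), nec = c(0, 0),
                      merged_esc = mean(esc), merged_nec = mean(nec)) {
  data.table::data.table(
    bait_id = bait, other_end_id = oe,
    score_rep1_ESC = esc[1], score_rep2_ESC = esc[2],
    score_rep1_NEC = nec[1], score_rep2_NEC = nec[2],
    merged_ESC = merged_esc, merged_NEC = merged_nec
  )
}

## brute-force average-linkage agglomeration: O(n^3), returns merge heights
naive_average_linkage_heights <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
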
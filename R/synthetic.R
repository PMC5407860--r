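## Synthetic PCHi-C study generator. Plants a small two-cell-type genome with
## known TADs, compartments, interactions, chromatin states and expression,
## and records every planted truth in a manifest so each downstream stage can
## be scored against ground truth.

#' Configuration for a synthetic PCHi-C study
#'
#' Returns a validated configuration list. The defaults define the study
#' conditions used throughout the package's tests and acceptance runs: a
#' two-chromosome 6 Mb-per-chromosome genome cut into ~4 kb restriction
#' fragments, 150 promoter baits, 25 kb contact-matrix bins, eight TADs and a
#' 750 kb A/B compartment alternation per chromosome, distance decay with
#' exponent 1, planted interaction classes (shared, cell-type-specific in
#' either direction, sub-threshold, background), 25% recolouring of retained
#' PIRs, an expression coupling of 3 log2 units, and replicate score noise of
#' 0.5.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp chromosome length (bp).
#' @param mean_fragment_bp mean restriction-fragment length; lengths are
#'   exponential, clipped to `[500, 50000]` bp.
#' @param n_baits number of promoter-containing (baited) fragments.
#' @param frac_protein_coding fraction of baits flagged protein-coding.
#' @param bin_bp contact-matrix bin size (bp).
#' @param n_tads planted TADs per chromosome.
#' @param tad_enrichment within-TAD contact enrichment factor.
#' @param compartment_bin_bp compartment bin size (bp).
#' @param compartment_block_bp size of alternating A/B blocks (bp).
#' @param compartment_neutral_fraction probability that the transition bin
#'   opening each A/B block is planted as belonging to neither compartment.
#' @param compartment_strength checkerboard contact modulation in `[0, 1)`.
#' @param distance_decay_exponent exponent of the `(1 + d)^-a` contact decay.
#' @param base_contacts expected contact count at distance zero.
#' @param n_shared,n_esc_only,n_nec_only planted significant interactions per
#'   class; cell-type-specific classes are named after the default labels.
#' @param n_subthreshold,n_background planted non-significant pairs.
#' @param pirs_per_bait target number of planted PIRs per interacting bait.
#' @param tad_containment probability that a planted PIR lies inside its
#'   bait's TAD.
#' @param max_interaction_bp maximum planted bait-PIR distance (bp).
#' @param score_means named vector of class score means: `shared`,
#'   `specific_high`, `specific_low`, `subthreshold`, `background`.
#' @param recolour_fraction fraction of retained (shared) PIRs whose broad
#'   state switches between cell types; recolouring at rewired PIRs and at
#'   unplanted fragments scales with the same knob (see the methods
#'   vignette).
#' @param mixed_fraction fraction of planted PIRs forced to the mixed or
#'   intermediate state (exercises the exclusion rules).
#' @param promoter_concordance probability that a promoter's planted state
#'   matches the modal state of its PIRs.
#' @param expression_coupling_log2fc planted expression effect (log2 units)
#'   for genes gaining/losing active PIRs.
#' @param expression_noise_sd Gaussian noise on log2 fold changes.
#' @param noise_sd Gaussian noise on replicate interaction scores.
#' @param cell_types two cell-type labels; the first plays the role of the
#'   pluripotent state.
#' @param seed integer seed; together with the config it fully determines
#'   every generated record.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chromosomes = 2L,
                             chrom_length_bp = 6e6,
                             mean_fragment_bp = 4000,
                             n_baits = 150L,
                             frac_protein_coding = 0.9,
                             bin_bp = 25000,
                             n_tads = 8L,
                             tad_enrichment = 4,
                             compartment_bin_bp = 250000,
                             compartment_block_bp = 750000,
                             compartment_neutral_fraction = 1,
                             compartment_strength = 0.4,
                             distance_decay_exponent = 1,
                             base_contacts = 300,
                             n_shared = 150L,
                             n_esc_only = 75L,
                             n_nec_only = 75L,
                             n_subthreshold = 60L,
                             n_background = 1000L,
                             pirs_per_bait = 4L,
                             tad_containment = 0.85,
                             max_interaction_bp = 6e5,
                             score_means = c(shared = 20, specific_high = 30,
                                             specific_low = 1.5,
                                             subthreshold = 9, background = 3),
                             recolour_fraction = 0.25,
                             mixed_fraction = 0.05,
                             promoter_concordance = 0.7,
                             expression_coupling_log2fc = 3,
                             expression_noise_sd = 0.3,
                             noise_sd = 0.5,
                             cell_types = c("ESC", "NEC"),
                             seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_chromosomes = n_chromosomes, n_baits = n_baits,
              n_tads = n_tads, chrom_length_bp = chrom_length_bp,
              mean_fragment_bp = mean_fragment_bp, bin_bp = bin_bp)
  if (any(counts <= 0)) stopf("all counts and lengths must be > 0")
  if (length(cell_types) != 2L || anyDuplicated(cell_types)) {
    stopf("cell_types must be two distinct labels")
  }
  stopifnot(all(c("shared", "specific_high", "specific_low", "subthreshold",
                  "background") %in% names(score_means)))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a restriction-fragment map
#'
#' Tiles each chromosome with fragments of exponential length (mean
#' `mean_fragment_bp`, clipped to 500 bp-50 kb), truncating the final
#' fragment at the chromosome end so that fragments cover the chromosome
#' exactly with no gaps or overlaps. `n_baits` fragments are flagged as
#' promoter baits and given gene identifiers; a configurable fraction is
#' flagged protein-coding.
#'
#' @param config a [synthetic_config()].
#' @return `data.table` with columns `fragment_id`, `chrom`, `start`, `end`,
#'   `bait`, `gene_id`, `protein_coding` (0-based half-open coordinates,
#'   sorted, non-overlapping).
#' @export
generate_fragment_map <- function(config) {
  withr::with_seed(sub_seed(config$seed, 1L), {
    per_chrom <- lapply(seq_len(config$n_chromosomes), function(ci) {
      len <- config$chrom_length_bp
      n_guess <- ceiling(len / 500) + 10L
      lens <- pmin(pmax(round(rexp(n_guess, 1 / config$mean_fragment_bp)),
                        500), 50000)
      ends <- cumsum(lens)
      keep <- seq_len(which(ends >= len)[1])
      ends <- pmin(ends[keep], len)
      data.table::data.table(
        chrom = paste0("chr", ci),
        start = c(0, head(ends, -1)),
        end = ends
      )
    })
    fm <- data.table::rbindlist(per_chrom)
    fm[, fragment_id := .I]
    fm[, bait := FALSE]
    bait_idx <- sort(sample(nrow(fm), config$n_baits))
    fm[bait_idx, bait := TRUE]
    fm[, gene_id := NA_character_]
    fm[bait_idx, gene_id := sprintf("G%04d", seq_len(config$n_baits))]
    fm[, protein_coding := FALSE]
    fm[bait_idx, protein_coding :=
         runif(config$n_baits) < config$frac_protein_coding]
    data.table::setcolorder(fm, c("fragment_id", "chrom", "start", "end",
                                  "bait", "gene_id", "protein_coding"))
    fm[]
  })
}

## Plant TADs and compartment labels for one genome.
plant_topology <- function(config) {
  withr::with_seed(sub_seed(config$seed, 2L), {
    n_bins <- ceiling(config$chrom_length_bp / config$bin_bp)
    tads <- data.table::rbindlist(lapply(seq_len(config$n_chromosomes),
                                         function(ci) {
      ## roughly equal TADs with +/- 2 bin jitter on interior boundaries
      cuts <- round(seq(0, n_bins, length.out = config$n_tads + 1L))
      if (config$n_tads > 1L) {
        interior <- cuts[2:config$n_tads] +
          sample(-2:2, config$n_tads - 1L, replace = TRUE)
        cuts <- c(0L, sort(pmin(pmax(interior, 2L), n_bins - 2L)), n_bins)
      }
      data.table::data.table(
        chrom = paste0("chr", ci),
        start = cuts[-length(cuts)] * config$bin_bp,
        end = pmin(cuts[-1] * config$bin_bp, config$chrom_length_bp)
      )
    }))
    tads[, tad_id := .I]

    ## alternating A/B blocks; the first bin of each new block is a planted
    ## "neither" transition zone (with prob compartment_neutral_fraction) --
    ## mirrors how bins falling outside either compartment sit at A/B
    ## transitions.
    block_bins <- max(1L, round(config$compartment_block_bp /
                                config$compartment_bin_bp))
    n_cbins <- ceiling(config$chrom_length_bp / config$compartment_bin_bp)
    comps <- data.table::rbindlist(lapply(seq_len(config$n_chromosomes),
                                          function(ci) {
      block <- floor((seq_len(n_cbins) - 1L) / block_bins)
      lab <- ifelse(block %% 2L == 0L, "A", "B")
      trans <- which(diff(block) != 0L) + 1L
      neutral <- trans[runif(length(trans)) <
                         config$compartment_neutral_fraction]
      lab[neutral] <- "neither"
      data.table::data.table(
        chrom = paste0("chr", ci),
        start = (seq_len(n_cbins) - 1L) * config$compartment_bin_bp,
        end = pmin(seq_len(n_cbins) * config$compartment_bin_bp,
                   config$chrom_length_bp),
        label = lab
      )
    }))
    list(tads = tads[], compartments = comps[])
  })
}

## Plant bait-PIR pairs with interaction classes, PIR/promoter chromatin
## states per cell type, and gene-level expression coupling groups.
plant_regulation <- function(config, fragment_map, topology) {
  ct <- config$cell_types
  cls_specific <- paste0(tolower(ct), "_only")
  withr::with_seed(sub_seed(config$seed, 3L), {
    fm <- fragment_map
    fm_mid <- fragment_mid(fm)
    tads <- topology$tads
    ## TAD index of each fragment (by midpoint; NA at boundary-free edges)
    frag_tad <- rep(NA_integer_, nrow(fm))
    for (i in seq_len(nrow(tads))) {
      sel <- fm$chrom == tads$chrom[i] & fm_mid >= tads$start[i] &
        fm_mid < tads$end[i]
      frag_tad[sel] <- tads$tad_id[i]
    }

    n_sig <- config$n_shared + config$n_esc_only + config$n_nec_only
    bait_ids <- fm[bait == TRUE, fragment_id]

    pick_pirs <- function(b) {
      bi <- which(fm$fragment_id == b)
      same_chrom <- which(fm$chrom == fm$chrom[bi] & !fm$bait &
                          abs(fm_mid - fm_mid[bi]) <= config$max_interaction_bp &
                          fm$fragment_id != b)
      in_tad <- same_chrom[!is.na(frag_tad[same_chrom]) &
                           frag_tad[same_chrom] %in% frag_tad[bi]]
      out_tad <- setdiff(same_chrom, in_tad)
      k <- config$pirs_per_bait
      take_in <- min(rbinom(1, k, config$tad_containment), length(in_tad))
      chosen <- c(if (take_in > 0) sample(in_tad, take_in),
                  if (k - take_in > 0 && length(out_tad))
                    sample(out_tad, min(k - take_in, length(out_tad))))
      ## top up from whatever remains so each bait reaches its PIR target
      if (length(chosen) < k) {
        left <- setdiff(same_chrom, chosen)
        chosen <- c(chosen, sample(left, min(k - length(chosen), length(left))))
      }
      fm$fragment_id[chosen]
    }
    ## draw baits (shuffled, without replacement) until enough pairs exist
    bait_order <- sample(bait_ids)
    pairs <- data.table::data.table(bait_id = integer(),
                                    other_end_id = integer())
    for (b in bait_order) {
      if (nrow(pairs) >= n_sig) break
      pairs <- rbind(pairs, data.table::data.table(
        bait_id = b, other_end_id = pick_pirs(b)))
    }
    if (nrow(pairs) < n_sig) {
      stopf("could not plant %d significant pairs (only %d candidate pairs)",
            n_sig, nrow(pairs))
    }
    pairs <- pairs[seq_len(n_sig)]
    pairs[, class := sample(rep(c("shared", cls_specific),
                                c(config$n_shared, config$n_esc_only,
                                  config$n_nec_only)))]

    ## non-significant pairs: random cis bait-fragment pairs not already used
    n_extra <- config$n_subthreshold + config$n_background
    used <- paste(pairs$bait_id, pairs$other_end_id)
    extra <- data.table::data.table(bait_id = integer(), other_end_id = integer())
    tries <- 0L
    while (nrow(extra) < n_extra && tries < 50L) {
      tries <- tries + 1L
      b <- sample(bait_ids, n_extra, replace = TRUE)
      bi <- match(b, fm$fragment_id)
      cand <- data.table::rbindlist(lapply(seq_along(b), function(j) {
        pool <- which(fm$chrom == fm$chrom[bi[j]] &
                      abs(fm_mid - fm_mid[bi[j]]) <= config$max_interaction_bp &
                      fm$fragment_id != b[j] & !fm$bait)
        if (!length(pool)) return(NULL)
        data.table::data.table(bait_id = b[j],
                               other_end_id = fm$fragment_id[sample(pool, 1)])
      }))
      cand <- cand[!paste(bait_id, other_end_id) %in% used]
      cand <- unique(cand)
      extra <- unique(rbind(extra, cand))
      used <- c(used, paste(extra$bait_id, extra$other_end_id))
    }
    if (nrow(extra) < n_extra) {
      stopf("requested %d non-significant pairs exceed available bait-fragment pairs",
            n_extra)
    }
    extra <- extra[seq_len(n_extra)]
    extra[, class := rep(c("subthreshold", "background"),
                         c(config$n_subthreshold, config$n_background))]
    interactions <- rbind(pairs, extra)
    interactions[, pair_id := .I]

    ## ---- planted chromatin states ------------------------------------
    assignable <- c("active", "poised", "polycomb", "background")
    amb_p <- c(active = 0.45, poised = 0.10, polycomb = 0.15, background = 0.30)
    draw_state <- function(n, p = amb_p) {
      sample(names(p), n, replace = TRUE, prob = p)
    }
    sig <- interactions[class != "background" & class != "subthreshold"]
    pir_frag <- unique(sig$other_end_id)
    ps <- data.table::data.table(fragment_id = pir_frag)
    cls_of <- sig[match(pir_frag, other_end_id), class]
    s1 <- character(length(pir_frag)); s2 <- character(length(pir_frag))
    for (j in seq_along(pir_frag)) {
      cl <- cls_of[j]
      if (cl == "shared") {
        base <- draw_state(1)
        s1[j] <- base; s2[j] <- base
      } else if (cl == cls_specific[1]) {        # lost on differentiation
        s1[j] <- sample(assignable, 1, prob = c(0.80, 0.05, 0.05, 0.10))
        s2[j] <- sample(assignable, 1, prob = c(0.10, 0.15, 0.20, 0.55))
      } else {                                    # gained on differentiation
        s2[j] <- sample(assignable, 1, prob = c(0.80, 0.05, 0.05, 0.10))
        s1[j] <- sample(assignable, 1, prob = c(0.10, 0.15, 0.20, 0.55))
      }
    }
    ps[, (paste0("state_", ct[1])) := s1]
    ps[, (paste0("state_", ct[2])) := s2]
    ps[, class := cls_of]
    ps[, recoloured := FALSE]

    ## recolouring: retained PIRs switch with prob recolour_fraction; rewired
    ## PIRs keep their planted (mostly differing) states only in proportion to
    ## the same knob, so recolour_fraction = 0 freezes every PIR state.
    shared_rows <- which(ps$class == "shared")
    reco <- shared_rows[runif(length(shared_rows)) < config$recolour_fraction]
    switch_p <- c(active = 0.4, poised = 0.1, polycomb = 0.1, background = 0.4)
    for (j in reco) {
      cur <- ps[[paste0("state_", ct[1])]][j]
      pool <- switch_p[setdiff(assignable, cur)]
      ps[[paste0("state_", ct[2])]][j] <- sample(names(pool), 1,
                                                 prob = pool / sum(pool))
    }
    ps[reco, recoloured := TRUE]
    ps[shared_rows[!shared_rows %in% reco],
       (paste0("state_", ct[2])) := get(paste0("state_", ct[1]))]
    spec_rows <- which(ps$class != "shared")
    rewired_keep_prob <- min(1, config$recolour_fraction * 3.2)
    freeze <- spec_rows[runif(length(spec_rows)) >= rewired_keep_prob]
    ps[freeze, (paste0("state_", ct[2])) := get(paste0("state_", ct[1]))]
    ps[, recoloured := get(paste0("state_", ct[1])) !=
         get(paste0("state_", ct[2]))]

    ## a small fraction of PIRs carry mixed/intermediate states in both cells
    mix <- which(runif(nrow(ps)) < config$mixed_fraction)
    mix_state <- sample(c("mixed", "intermediate"), length(mix), replace = TRUE)
    ps[mix, (paste0("state_", ct[1])) := mix_state]
    ps[mix, (paste0("state_", ct[2])) := mix_state]
    ps[mix, recoloured := FALSE]

    ## promoter states follow the modal PIR state with prob promoter_concordance
    bait_states <- data.table::rbindlist(lapply(unique(sig$bait_id), function(b) {
      row <- data.table::data.table(fragment_id = b, class = "promoter",
                                    recoloured = FALSE)
      for (cc in ct) {
        st <- ps[fragment_id %in% sig[bait_id == b, other_end_id],
                 get(paste0("state_", cc))]
        st <- st[st %in% assignable]
        modal <- if (length(st)) names(sort(table(st), decreasing = TRUE))[1]
                 else draw_state(1)
        val <- if (runif(1) < config$promoter_concordance) modal else draw_state(1)
        row[, (paste0("state_", cc)) := val]
      }
      row
    }), use.names = TRUE)
    planted_states <- rbind(ps, bait_states, use.names = TRUE, fill = TRUE)

    ## ---- expression coupling ------------------------------------------
    st1 <- function(ids) ps[match(ids, fragment_id), get(paste0("state_", ct[1]))]
    st2 <- function(ids) ps[match(ids, fragment_id), get(paste0("state_", ct[2]))]
    genes <- data.table::rbindlist(lapply(bait_ids, function(b) {
      my <- sig[bait_id == b]
      gains <- 0L; losses <- 0L
      if (nrow(my)) {
        oe <- my$other_end_id
        cl <- my$class
        gains <- sum(cl == cls_specific[2] & st2(oe) == "active") +
          sum(cl == "shared" & st1(oe) != "active" & st2(oe) == "active")
        losses <- sum(cl == cls_specific[1] & st1(oe) == "active") +
          sum(cl == "shared" & st1(oe) == "active" & st2(oe) != "active")
      }
      data.table::data.table(
        gene_id = fm[fragment_id == b, gene_id], bait_id = b,
        n_gain_active = gains, n_loss_active = losses,
        coupling = if (gains > losses) "gain" else if (losses > gains) "loss"
                   else "neutral"
      )
    }))
    list(interactions = interactions[], planted_states = planted_states[],
         genes = genes[])
  })
}

#' Build the ground-truth manifest for a synthetic study
#'
#' Plants TADs, compartment labels, bait-PIR interaction classes, PIR and
#' promoter chromatin states (including recolouring), and gene-level
#' expression coupling groups. Every record later emitted by the generators
#' traces back to exactly one entry here.
#'
#' @param config a [synthetic_config()].
#' @param fragment_map output of [generate_fragment_map()].
#' @return a list of class `ground_truth_manifest` with elements `tads`,
#'   `compartments`, `interactions`, `planted_states`, `genes`,
#'   `cell_types`.
#' @export
ground_truth_manifest <- function(config, fragment_map) {
  topo <- plant_topology(config)
  reg <- plant_regulation(config, fragment_map, topo)
  out <- c(topo, reg, list(cell_types = config$cell_types))
  class(out) <- "ground_truth_manifest"
  out
}

#' Simulate a binned contact matrix with planted structure
#'
#' Low-level simulator shared by the study generator and the topology tests:
#' expected counts are a distance-decay baseline multiplied by a within-TAD
#' enrichment factor and an A/B checkerboard factor, then Poisson-sampled and
#' symmetrised.
#'
#' @param n_bins matrix dimension.
#' @param tad_bins optional `data.table` with 1-based inclusive bin ranges
#'   `from`, `to` and optional per-TAD `enrichment`.
#' @param comp_labels optional per-bin labels in `A`/`B`/`neither`.
#' @param base_contacts expected count at distance 0.
#' @param decay_exponent distance-decay exponent.
#' @param tad_enrichment default within-TAD factor.
#' @param compartment_strength checkerboard modulation in `[0, 1)`.
#' @param noise if `FALSE`, returns the expected (noise-free) matrix.
#' @param seed integer seed.
#' @return symmetric non-negative matrix.
#' @export
simulate_contact_matrix <- function(n_bins, tad_bins = NULL,
                                    comp_labels = NULL,
                                    base_contacts = 300,
                                    decay_exponent = 1,
                                    tad_enrichment = 4,
                                    compartment_strength = 0.4,
                                    noise = TRUE, seed = 1L) {
  d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  lambda <- base_contacts / (1 + d)^decay_exponent
  if (!is.null(tad_bins)) {
    tad_of <- rep(NA_integer_, n_bins)
    enr <- rep(tad_enrichment, nrow(tad_bins))
    if ("enrichment" %in% names(tad_bins)) enr <- tad_bins$enrichment
    for (i in seq_len(nrow(tad_bins))) {
      tad_of[tad_bins$from[i]:tad_bins$to[i]] <- i
    }
    same <- outer(tad_of, tad_of, function(a, b) !is.na(a) & !is.na(b) & a == b)
    fac <- matrix(1, n_bins, n_bins)
    for (i in seq_len(nrow(tad_bins))) {
      sel <- which(tad_of == i)
      fac[sel, sel] <- enr[i]
    }
    lambda <- lambda * ifelse(same, fac, 1)
  }
  if (!is.null(comp_labels)) {
    stopifnot(length(comp_labels) == n_bins)
    ab <- comp_labels %in% c("A", "B")
    samec <- outer(comp_labels, comp_labels, "==") & outer(ab, ab, "&")
    diffc <- outer(comp_labels, comp_labels, "!=") & outer(ab, ab, "&")
    lambda[samec] <- lambda[samec] * (1 + compartment_strength)
    lambda[diffc] <- lambda[diffc] * (1 - compartment_strength)
  }
  if (!noise) {
    return((lambda + t(lambda)) / 2)
  }
  withr::with_seed(seed, {
    up <- matrix(0, n_bins, n_bins)
    iu <- upper.tri(up, diag = TRUE)
    up[iu] <- rpois(sum(iu), lambda[iu])
    up + t(up) - diag(diag(up))
  })
}

#' Generate binned contact matrices for a synthetic study
#'
#' One symmetric Poisson-sampled matrix per chromosome per cell type, with
#' the manifest's planted TADs and compartment checkerboard baked into the
#' expected counts on top of a distance-decay baseline.
#'
#' @param config a [synthetic_config()].
#' @param manifest a [ground_truth_manifest()].
#' @return nested list: `matrices[[cell_type]][[chrom]]`.
#' @export
generate_contact_matrix <- function(config, manifest) {
  n_bins <- ceiling(config$chrom_length_bp / config$bin_bp)
  ratio <- config$compartment_bin_bp / config$bin_bp
  out <- list()
  k <- 10L
  for (cc in config$cell_types) {
    out[[cc]] <- list()
    for (ci in seq_len(config$n_chromosomes)) {
      chr <- paste0("chr", ci)
      tads <- manifest$tads[chrom == chr]
      tad_bins <- data.table::data.table(
        from = pmax(1L, floor(tads$start / config$bin_bp) + 1L),
        to = pmin(n_bins, ceiling(tads$end / config$bin_bp))
      )
      comp <- manifest$compartments[chrom == chr]
      cbin_of <- pmin(floor(((seq_len(n_bins) - 1L) * config$bin_bp) /
                            config$compartment_bin_bp) + 1L, nrow(comp))
      labels <- comp$label[cbin_of]
      k <- k + 1L
      out[[cc]][[chr]] <- simulate_contact_matrix(
        n_bins, tad_bins = tad_bins, comp_labels = labels,
        base_contacts = config$base_contacts,
        decay_exponent = config$distance_decay_exponent,
        tad_enrichment = config$tad_enrichment,
        compartment_strength = config$compartment_strength,
        seed = sub_seed(config$seed, k)
      )
    }
  }
  out
}

#' Generate replicate-level interaction score tables
#'
#' Emits one row per planted pair with two replicate scores per cell type
#' (class mean plus Gaussian noise, floored at zero) and merged scores (mean
#' of replicates). Shared pairs score highly in both cell types,
#' cell-type-specific pairs score in the top quintile of the high cell type's
#' merged scores and the bottom quintile of the other, sub-threshold and
#' background pairs stay below the rescue threshold.
#'
#' @param config a [synthetic_config()].
#' @param fragment_map fragment map (must contain all planted ids).
#' @param manifest a [ground_truth_manifest()].
#' @return `data.table` with `bait_id`, `other_end_id`,
#'   `score_rep[12]_<cell>` and `merged_<cell>` columns.
#' @export
generate_interaction_scores <- function(config, fragment_map, manifest) {
  ct <- config$cell_types
  cls_specific <- paste0(tolower(ct), "_only")
  sm <- config$score_means
  withr::with_seed(sub_seed(config$seed, 4L), {
    sc <- data.table::copy(manifest$interactions)
    mean_for <- function(cl, cell_idx) {
      data.table::fcase(
        cl == "shared", sm[["shared"]],
        cl == cls_specific[cell_idx], sm[["specific_high"]],
        cl == cls_specific[3L - cell_idx], sm[["specific_low"]],
        cl == "subthreshold", sm[["subthreshold"]],
        cl == "background", sm[["background"]]
      )
    }
    n <- nrow(sc)
    for (i in 1:2) {
      mu <- mean_for(sc$class, i)
      r1 <- pmax(0, mu + rnorm(n, sd = config$noise_sd))
      r2 <- pmax(0, mu + rnorm(n, sd = config$noise_sd))
      sc[, (paste0("score_rep1_", ct[i])) := r1]
      sc[, (paste0("score_rep2_", ct[i])) := r2]
      sc[, (paste0("merged_", ct[i])) := (r1 + r2) / 2]
    }
    sc[, c("class", "pair_id") := NULL]
    sc[]
  })
}

#' Generate chromatin segmentations and an expression/DE table
#'
#' Builds a 16-state segmentation per cell type (one segment per fragment,
#' with raw states drawn from the planted broad state where one exists and
#' from an ambient distribution elsewhere) and an expression table in which
#' genes whose CRUs gain active PIRs receive log2 fold changes around
#' `+expression_coupling_log2fc`, losses around the negative, and all other
#' genes around zero. The DE flag applies `|log2FC| > 1.5` and
#' `padj < 0.05`; planted DE genes carry `padj = 1e-6` and the rest draw
#' `padj` uniformly from `(0.05, 1)`.
#'
#' @param config a [synthetic_config()].
#' @param fragment_map fragment map.
#' @param manifest a [ground_truth_manifest()].
#' @return list with `segmentations` (named list of per-cell-type
#'   `data.table`s: `chrom`, `start`, `end`, `raw_state`) and `expression`
#'   (`gene_id`, `log2fc`, `padj`, `de`, `direction`).
#' @export
generate_states_and_expression <- function(config, fragment_map, manifest) {
  ct <- config$cell_types
  raw_rep <- list(active = 1:6, poised = 7:9, polycomb = 10L, mixed = 11:12,
                  intermediate = 13L, background = 14:16)
  amb_p <- c(active = 0.12, poised = 0.03, polycomb = 0.04, mixed = 0.02,
             intermediate = 0.03, background = 0.76)
  withr::with_seed(sub_seed(config$seed, 5L), {
    n <- nrow(fragment_map)
    ## ambient states are compartment-coupled: A-compartment fragments are
    ## richer in active chromatin, as H3K4me3-aligned compartments are
    frag_mid <- (fragment_map$start + fragment_map$end) / 2
    comp <- manifest$compartments
    cbin <- pmin(floor(frag_mid / config$compartment_bin_bp) + 1L,
                 ceiling(config$chrom_length_bp / config$compartment_bin_bp))
    comp_lab <- rep("neither", n)
    for (cc in unique(fragment_map$chrom)) {
      lab <- comp[chrom == cc, label]
      sel <- fragment_map$chrom == cc
      comp_lab[sel] <- lab[cbin[sel]]
    }
    active_p <- c(A = 0.20, neither = 0.10, B = 0.04)
    ambient1 <- character(n)
    for (lb in names(active_p)) {
      sel <- comp_lab == lb
      p <- amb_p
      p["active"] <- active_p[[lb]]
      p["background"] <- 1 - sum(p[setdiff(names(p), "background")])
      ambient1[sel] <- sample(names(p), sum(sel), replace = TRUE, prob = p)
    }
    ambient2 <- ambient1
    flip <- which(runif(n) < config$recolour_fraction * 0.3)
    ambient2[flip] <- sample(names(amb_p), length(flip), replace = TRUE,
                             prob = amb_p)
    broad <- list(ambient1, ambient2)
    for (i in 1:2) {
      planted <- manifest$planted_states
      col <- paste0("state_", ct[i])
      idx <- match(planted$fragment_id, fragment_map$fragment_id)
      broad[[i]][idx] <- planted[[col]]
    }
    segmentations <- lapply(1:2, function(i) {
      raw <- vapply(broad[[i]], function(b) {
        pool <- raw_rep[[b]]
        if (length(pool) == 1L) pool else sample(pool, 1L)
      }, integer(1))
      data.table::data.table(
        chrom = fragment_map$chrom, start = fragment_map$start,
        end = fragment_map$end, raw_state = raw
      )
    })
    names(segmentations) <- ct

    genes <- manifest$genes
    eff <- data.table::fcase(genes$coupling == "gain",
                             config$expression_coupling_log2fc,
                             genes$coupling == "loss",
                             -config$expression_coupling_log2fc,
                             default = 0)
    log2fc <- eff + rnorm(nrow(genes), sd = config$expression_noise_sd)
    padj <- ifelse(genes$coupling != "neutral", 1e-6,
                   runif(nrow(genes), 0.05, 1))
    de <- abs(log2fc) > 1.5 & padj < 0.05
    expression <- data.table::data.table(
      gene_id = genes$gene_id, log2fc = log2fc, padj = padj, de = de,
      direction = data.table::fcase(de & log2fc > 0, "up",
                                    de & log2fc < 0, "down",
                                    default = "unchanged")
    )
    list(segmentations = segmentations, expression = expression)
  })
}

#' Generate feature interval sets for a synthetic study
#'
#' Emits per-cell-type histone-mark-like peak sets concentrated on
#' active-state fragments, a VISTA-like enhancer annotation (tissue-labelled
#' intervals placed preferentially at active PIRs of the committed cell
#' type), and a TSS table for the bait genes.
#'
#' @param config a [synthetic_config()].
#' @param fragment_map fragment map.
#' @param manifest a [ground_truth_manifest()].
#' @param segmentations output of [generate_states_and_expression()].
#' @return list with `peaks` (per cell type), `enhancers`, `tss`.
#' @export
generate_feature_sets <- function(config, fragment_map, manifest,
                                  segmentations) {
  ct <- config$cell_types
  withr::with_seed(sub_seed(config$seed, 6L), {
    peak_for <- function(seg) {
      broad <- curate_state(seg$raw_state)
      active <- which(broad == "active")
      other <- which(broad != "active")
      sel <- c(active[runif(length(active)) < 0.7],
               other[runif(length(other)) < 0.03])
      dt <- fragment_map[sort(sel)]
      w <- (dt$end - dt$start)
      data.table::data.table(chrom = dt$chrom,
                             start = floor(dt$start + w * 0.25),
                             end = ceiling(dt$end - w * 0.25))
    }
    peaks <- lapply(segmentations$segmentations, peak_for)

    sig <- manifest$interactions[!class %in% c("subthreshold", "background")]
    st2 <- paste0("state_", ct[2])
    act2 <- manifest$planted_states[get(st2) == "active" & class != "promoter",
                                    fragment_id]
    enh_frag <- intersect(unique(sig$other_end_id), act2)
    enh_frag <- enh_frag[runif(length(enh_frag)) < 0.6]
    rnd <- sample(fragment_map[!bait & !fragment_id %in% enh_frag, fragment_id],
                  max(3L, round(length(enh_frag) * 0.5)))
    tissues <- c(sample(c("neural", "limb", "heart"), length(enh_frag),
                        replace = TRUE, prob = c(0.7, 0.15, 0.15)),
                 sample(c("neural", "limb", "heart"), length(rnd),
                        replace = TRUE))
    dt <- fragment_map[match(c(enh_frag, rnd), fragment_id)]
    w <- dt$end - dt$start
    enhancers <- data.table::data.table(
      chrom = dt$chrom, start = floor(dt$start + w * 0.3),
      end = ceiling(dt$end - w * 0.3),
      element_id = sprintf("EL%04d", seq_len(nrow(dt))),
      tissue = tissues
    )
    tss <- fragment_map[bait == TRUE,
                        .(gene_id, chrom, tss = start)]
    list(peaks = peaks, enhancers = enhancers[], tss = tss[])
  })
}

#' Simulate a complete synthetic PCHi-C study
#'
#' Runs every generator stage under one seed and returns the full study:
#' fragment map, ground-truth manifest, contact matrices, replicate score
#' table, segmentations, expression table and feature sets. Identical
#' configurations produce identical studies.
#'
#' @param config a [synthetic_config()].
#' @param contacts if `FALSE`, skip contact-matrix generation (the slowest
#'   stage) for workflows that only need interactions/states/expression.
#' @return a list of class `pchic_study`.
#' @export
simulate_pchic_study <- function(config = synthetic_config(),
                                 contacts = TRUE) {
  fm <- generate_fragment_map(config)
  manifest <- ground_truth_manifest(config, fm)
  se <- generate_states_and_expression(config, fm, manifest)
  study <- list(
    config = config,
    fragment_map = fm,
    manifest = manifest,
    contacts = if (contacts) generate_contact_matrix(config, manifest),
    scores = generate_interaction_scores(config, fm, manifest),
    segmentations = se$segmentations,
    expression = se$expression,
    features = generate_feature_sets(config, fm, manifest, se)
  )
  class(study) <- "pchic_study"
  study
}

#' Write a synthetic study to disk
#'
#' Emits the study in the pipeline's on-disk formats: fragment map BED (+bait
#' columns), per-cell-type segmentation BEDs (raw 16-state integers), dense
#' contact matrix TSVs (one per chromosome per cell type), the replicate
#' score TSV, the expression TSV, feature BEDs and the manifest JSON.
#'
#' @param study a `pchic_study`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_bed(study$fragment_map[, .(chrom, start, end, fragment_id, bait,
                                   gene_id, protein_coding)],
            p("fragments.bed"))
  for (cc in names(study$segmentations)) {
    write_bed(study$segmentations[[cc]], p(sprintf("segmentation_%s.bed", cc)))
  }
  if (!is.null(study$contacts)) {
    for (cc in names(study$contacts)) {
      for (chr in names(study$contacts[[cc]])) {
        write_dense_matrix(study$contacts[[cc]][[chr]],
                           p(sprintf("contacts_%s_%s.tsv", cc, chr)))
      }
    }
  }
  write_score_table(study$scores, p("scores.tsv"))
  data.table::fwrite(study$expression, p("expression.tsv"), sep = "\t")
  for (cc in names(study$features$peaks)) {
    write_bed(study$features$peaks[[cc]], p(sprintf("peaks_%s.bed", cc)))
  }
  write_bed(study$features$enhancers, p("enhancers.bed"))
  data.table::fwrite(study$features$tss, p("tss.tsv"), sep = "\t")
  manifest <- study$manifest
  manifest_json <- list(
    cell_types = manifest$cell_types,
    tads = manifest$tads, compartments = manifest$compartments,
    interactions = manifest$interactions,
    planted_states = manifest$planted_states, genes = manifest$genes
  )
  jsonlite::write_json(manifest_json, p("manifest.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
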
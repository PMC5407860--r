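## Chromatin-state curation: collapse a 16-state segmentation into six broad
## states and resolve one state per restriction fragment per cell type.

#' Broad chromatin state labels
#'
#' The six broad states used throughout the package, in priority-relevant
#' order: `active` (H3K4me3 and/or H3K27ac), `poised` (H3K4 methylation plus
#' H3K27me3), `polycomb` (H3K27me3 alone), `mixed` (co-occurrence of active
#' and repressive evidence), `intermediate` (H3K4me1 alone), and `background`
#' (no detectable signal).
#'
#' @export
BROAD_STATES <- c("active", "poised", "polycomb", "mixed", "intermediate",
                  "background")

## raw 16-state -> broad state lookup
.STATE16_TO_BROAD <- c(
  rep("active", 6),        # 1-6: H3K4me3 and/or H3K27ac, no H3K27me3
  rep("poised", 3),        # 7-9: H3K4 methylation + H3K27me3
  "polycomb",              # 10 : H3K27me3 without H3K4 methylation
  rep("mixed", 2),         # 11-12: H3K27ac together with H3K27me3
  "intermediate",          # 13 : H3K4me1 alone
  rep("background", 3)     # 14-16: no signal
)

#' Curate raw segmentation states into broad chromatin states
#'
#' Maps the integer states of a 16-state hidden-Markov segmentation onto the
#' six broad states: 1-6 are `active`, 7-9 `poised`, 10 `polycomb`, 11-12
#' `mixed`, 13 `intermediate`, and 14-16 `background`.
#'
#' @param raw_state integer vector of raw states in `1:16`.
#' @return character vector of broad state labels (see [BROAD_STATES]).
#' @examples
#' curate_state(c(1, 10, 13, 15))
#' @export
curate_state <- function(raw_state) {
  raw_state <- as.integer(raw_state)
  if (anyNA(raw_state) || any(raw_state < 1L | raw_state > 16L)) {
    stopf("raw_state values must be integers in 1..16")
  }
  .STATE16_TO_BROAD[raw_state]
}

#' Resolve a single broad state from the states present in a fragment
#'
#' When a fragment overlaps segments in more than one broad state, the
#' classification is resolved by priority: (i) any functional state (active,
#' poised, polycomb, intermediate, mixed) takes precedence over background;
#' (ii) active, poised and polycomb take precedence over intermediate;
#' (iii) poised takes precedence over polycomb; (iv) active co-occurring with
#' a repressed state (poised or polycomb) yields `mixed`. A fragment whose
#' segments are all background is `background`. The raw `mixed` state already
#' encodes joint active and repressive evidence, so its presence (absent a
#' resolvable pure combination) keeps the fragment `mixed`.
#'
#' @param states character vector (a multiset) of broad states present within
#'   one fragment; order and duplication are irrelevant.
#' @return a single broad state label.
#' @examples
#' assign_fragment_state(c("active", "background"))   # "active"
#' assign_fragment_state(c("poised", "polycomb"))     # "poised"
#' assign_fragment_state(c("active", "polycomb"))     # "mixed"
#' @export
assign_fragment_state <- function(states) {
  states <- unique(as.character(states))
  bad <- setdiff(states, BROAD_STATES)
  if (length(bad)) stopf("unknown broad state(s): %s", paste(bad, collapse = ", "))
  if (!length(states)) stopf("assign_fragment_state() needs at least one state")
  fun <- setdiff(states, "background")
  if (!length(fun)) return("background")
  has <- function(s) s %in% fun
  if (has("active") && (has("poised") || has("polycomb"))) return("mixed")
  if (has("mixed")) return("mixed")
  if (has("active")) return("active")
  if (has("poised")) return("poised")
  if (has("polycomb")) return("polycomb")
  "intermediate"
}

#' Active-mark coverage track from a segmentation
#'
#' Per-bin fraction of base pairs covered by active-state segments on one
#' chromosome; used to orient compartment eigenvectors (the A compartment is
#' the active-mark-aligned sign).
#'
#' @param segmentation `data.table` with `chrom`, `start`, `end` and
#'   `raw_state` or `broad_state`.
#' @param chrom chromosome to profile.
#' @param bin_bp bin size (bp).
#' @param n_bins number of bins.
#' @return numeric vector of length `n_bins`.
#' @export
active_mark_track <- function(segmentation, chrom, bin_bp, n_bins) {
  seg <- data.table::as.data.table(segmentation)
  if (!"broad_state" %in% names(seg)) seg[, broad_state := curate_state(raw_state)]
  seg <- seg[seg$chrom == chrom & broad_state == "active"]
  cov <- numeric(n_bins)
  if (!nrow(seg)) return(cov)
  for (i in seq_len(nrow(seg))) {
    b1 <- max(1L, floor(seg$start[i] / bin_bp) + 1L)
    b2 <- min(n_bins, floor((seg$end[i] - 1) / bin_bp) + 1L)
    for (b in b1:b2) {
      lo <- max(seg$start[i], (b - 1) * bin_bp)
      hi <- min(seg$end[i], b * bin_bp)
      cov[b] <- cov[b] + (hi - lo) / bin_bp
    }
  }
  cov
}

#' Assign broad chromatin states to restriction fragments
#'
#' Overlaps a segmentation with the fragment map (any overlap of >= 1 bp
#' counts as presence) and resolves one broad state per fragment with
#' [assign_fragment_state()]. Fragments covered by no segment are reported as
#' `background` with a warning, since they represent segmentation coverage
#' gaps rather than evidence of inactivity.
#'
#' @param fragment_map fragment map `data.table` (see
#'   [generate_fragment_map()]), 0-based half-open coordinates.
#' @param segmentation `data.table` with columns `chrom`, `start`, `end` and
#'   either `raw_state` (integer 1-16) or `broad_state`.
#' @param cell_type label recorded in the result.
#' @return `data.table` with columns `fragment_id`, `cell_type`,
#'   `broad_state`.
#' @export
fragment_states <- function(fragment_map, segmentation, cell_type = NA_character_) {
  check_columns(fragment_map, c("fragment_id", "chrom", "start", "end"),
                "fragment_map")
  check_columns(segmentation, c("chrom", "start", "end"), "segmentation")
  seg <- data.table::as.data.table(segmentation)
  if (!"broad_state" %in% names(seg)) {
    check_columns(seg, "raw_state", "segmentation")
    seg[, broad_state := curate_state(raw_state)]
  }
  hits <- GenomicRanges::findOverlaps(as_granges(fragment_map), as_granges(seg))
  ov <- data.table::data.table(
    frag = S4Vectors::queryHits(hits),
    broad_state = seg$broad_state[S4Vectors::subjectHits(hits)]
  )
  resolved <- ov[, .(broad_state = assign_fragment_state(broad_state)), by = frag]
  out <- data.table::data.table(
    fragment_id = fragment_map$fragment_id,
    cell_type = cell_type,
    broad_state = "background"
  )
  out[resolved$frag, broad_state := resolved$broad_state]
  n_gap <- nrow(out) - nrow(resolved)
  if (n_gap > 0) {
    warnf("%d fragment(s) had no overlapping segment; set to background", n_gap)
  }
  out[]
}
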
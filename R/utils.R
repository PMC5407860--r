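## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## data.table (chrom, start, end) -> GRanges; input is 0-based half-open.
as_granges <- function(dt) {
  GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end)
  )
}

fragment_mid <- function(dt) (dt$start + dt$end) / 2

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Deterministic sub-seed derivation: keeps everything under one user seed
## while letting each generator stage draw an independent stream. Values stay
## below 2^31 - 1.
sub_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k)
}

## Assert that a data.table has the given columns.
check_columns <- function(dt, cols, what = "table") {
  miss <- setdiff(cols, names(dt))
  if (length(miss)) {
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

## Odds ratio of a 2x2 table c(a, b, c, d) = [[a, b], [c, d]] with Haldane
## correction applied only when a zero cell would make it degenerate.
odds_ratio_2x2 <- function(a, b, c, d, haldane = TRUE) {
  if (haldane && any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}
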
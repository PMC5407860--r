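## Readers and writers for the plain-text formats the pipeline consumes and
## emits. All interval files are 0-based, half-open (BED convention); extra
## columns beyond chrom/start/end are kept verbatim.

#' Read a BED-like file
#'
#' Reads a tab-separated interval file with at least `chrom`, `start`, `end`
#' columns (0-based half-open). Files written by [write_bed()] carry a header
#' line; headerless three-plus-column BED is also accepted, in which case the
#' leading columns are named `chrom`, `start`, `end`, `name`, `score`,
#' `strand` as far as they go.
#'
#' @param path file path.
#' @return `data.table` of intervals.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("^chrom\t", first)
  dt <- data.table::fread(path, header = has_header, sep = "\t")
  if (!has_header) {
    std <- c("chrom", "start", "end", "name", "score", "strand")
    data.table::setnames(dt, seq_len(min(ncol(dt), length(std))),
                         std[seq_len(min(ncol(dt), length(std)))])
  }
  if (!is.numeric(dt$start) || !is.numeric(dt$end)) {
    bad <- which(is.na(suppressWarnings(as.numeric(dt$start))))[1]
    stopf("malformed BED line %d in %s: non-numeric coordinates",
          (bad %||% 1L) + as.integer(has_header), path)
  }
  dt[]
}

#' Write a BED-like file
#'
#' @param dt `data.table` with `chrom`, `start`, `end` and any extra columns.
#' @param path output path.
#' @export
write_bed <- function(dt, path) {
  check_columns(dt, c("chrom", "start", "end"), "interval table")
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an interaction score table
#'
#' Expects a TSV with columns `baitID`, `otherEndID`, then per cell type
#' replicate scores `score_rep1_<cell>`, `score_rep2_<cell>` and (optionally)
#' merged scores `merged_<cell>`. When a merged column is absent it is filled
#' with the mean of the two replicate scores.
#'
#' @param path file path.
#' @param cell_types character vector of the two cell-type labels.
#' @return `data.table` with columns `bait_id`, `other_end_id`, replicate and
#'   merged score columns.
#' @export
read_score_table <- function(path, cell_types = c("ESC", "NEC")) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  data.table::setnames(dt, c("baitID", "otherEndID"), c("bait_id", "other_end_id"),
                       skip_absent = TRUE)
  check_columns(dt, c("bait_id", "other_end_id"), "score table")
  for (ct in cell_types) {
    r1 <- paste0("score_rep1_", ct); r2 <- paste0("score_rep2_", ct)
    m <- paste0("merged_", ct)
    check_columns(dt, c(r1, r2), "score table")
    if (!m %in% names(dt)) dt[[m]] <- (dt[[r1]] + dt[[r2]]) / 2
  }
  dt[]
}

#' Write an interaction score table
#' @param scores `data.table` as returned by [generate_interaction_scores()].
#' @param path output path.
#' @export
write_score_table <- function(scores, path) {
  out <- data.table::copy(scores)
  data.table::setnames(out, c("bait_id", "other_end_id"),
                       c("baitID", "otherEndID"))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write significant interactions in WashU Genome Browser text format
#'
#' One line per significant interaction:
#' `chrom:start-end<TAB>chrom:start-end<TAB>score`, coordinates 0-based
#' half-open as elsewhere in the package.
#'
#' @param calls interaction calls with significance flags
#'   (see [call_significant()]).
#' @param fragment_map fragment map.
#' @param cell_type which cell type's significant interactions to export.
#' @param path output path.
#' @export
write_washu <- function(calls, fragment_map, cell_type, path) {
  sig_col <- paste0("sig_", cell_type)
  check_columns(calls, sig_col, "calls")
  fm <- fragment_map[, .(fragment_id, chrom, start, end)]
  x <- calls[calls[[sig_col]] == TRUE]
  x <- merge(x, fm, by.x = "bait_id", by.y = "fragment_id")
  data.table::setnames(x, c("chrom", "start", "end"),
                       c("b_chrom", "b_start", "b_end"))
  x <- merge(x, fm, by.x = "other_end_id", by.y = "fragment_id")
  lines <- sprintf("%s:%d-%d\t%s:%d-%d\t%g",
                   x$b_chrom, x$b_start, x$b_end,
                   x$chrom, x$start, x$end,
                   x[[paste0("merged_", cell_type)]])
  writeLines(lines, path)
  invisible(path)
}

#' Parse WashU interaction text
#' @param path file path.
#' @return `data.table` with both anchors and the score.
#' @export
read_washu <- function(path) {
  lines <- readLines(path)
  m <- regmatches(lines, regexec(
    "^([^:]+):(\\d+)-(\\d+)\t([^:]+):(\\d+)-(\\d+)\t(.+)$", lines))
  bad <- which(lengths(m) != 8L)
  if (length(bad)) stopf("malformed WashU line %d in %s", bad[1], path)
  m <- do.call(rbind, m)
  data.table::data.table(
    chrom1 = m[, 2], start1 = as.integer(m[, 3]), end1 = as.integer(m[, 4]),
    chrom2 = m[, 5], start2 = as.integer(m[, 6]), end2 = as.integer(m[, 7]),
    score = as.numeric(m[, 8])
  )
}

#' Write a dense contact matrix as TSV
#' @param mat square numeric matrix.
#' @param path output path.
#' @export
write_dense_matrix <- function(mat, path) {
  data.table::fwrite(data.table::as.data.table(mat), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read a dense contact matrix TSV
#' @param path file path.
#' @return numeric matrix.
#' @export
read_dense_matrix <- function(path) {
  as.matrix(data.table::fread(path, sep = "\t", header = FALSE))
}

#' Convert a dense matrix to sparse triplet form
#' @param mat square matrix.
#' @return `data.table` with `bin_i`, `bin_j`, `count` (1-based bins,
#'   upper triangle including the diagonal, nonzero entries only).
#' @export
dense_to_sparse <- function(mat) {
  idx <- which(mat != 0 & upper.tri(mat, diag = TRUE), arr.ind = TRUE)
  data.table::data.table(bin_i = idx[, 1], bin_j = idx[, 2],
                         count = mat[idx])
}

#' Convert sparse triplets back to a symmetric dense matrix
#' @param sp `data.table` with `bin_i`, `bin_j`, `count`.
#' @param n matrix dimension; defaults to the largest bin index present.
#' @return symmetric numeric matrix.
#' @export
sparse_to_dense <- function(sp, n = max(sp$bin_i, sp$bin_j)) {
  mat <- matrix(0, n, n)
  mat[cbind(sp$bin_i, sp$bin_j)] <- sp$count
  mat[cbind(sp$bin_j, sp$bin_i)] <- sp$count
  mat
}
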
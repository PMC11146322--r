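#' GC content of a nucleotide sequence, in percent
#'
#' `100 * (#G + #C) / (#A + #C + #G + #T)`; case-insensitive. Gaps and
#' ambiguity codes are excluded from both numerator and denominator.
#'
#' @param sequence Nucleotide string (or vector of strings, one value each).
#' @return Percent GC per input string.
#' @export
gc_content <- function(sequence) {
  vapply(sequence, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    cnt <- vapply(c("A", "C", "G", "T"), function(b)
      n - nchar(gsub(b, "", s, fixed = TRUE)), numeric(1))
    tot <- sum(cnt)
    if (tot == 0) stop("no unambiguous bases in sequence")
    100 * (cnt[["G"]] + cnt[["C"]]) / tot
  }, numeric(1), USE.NAMES = !is.null(names(sequence)))
}

#' Coverage matrix container
#'
#' @param counts Numeric sample x scaffold matrix of mapped-read sums
#'   (nonnegative); dimnames give sample and scaffold names.
#' @param scaffold_lengths Named vector of scaffold lengths in bp (> 0),
#'   aligned with the columns of `counts`.
#' @return List of class `coverage_matrix`.
#' @export
coverage_matrix <- function(counts, scaffold_lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (ncol(counts) != length(scaffold_lengths))
    stop("dimension mismatch between counts and scaffold_lengths")
  if (any(scaffold_lengths <= 0)) stop("scaffold lengths must be positive")
  if (is.null(rownames(counts))) rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- if (!is.null(names(scaffold_lengths))) names(scaffold_lengths)
                        else paste0("scaffold", seq_len(ncol(counts)))
  structure(list(samples = rownames(counts), scaffolds = colnames(counts),
                 counts = counts, scaffold_lengths = unname(scaffold_lengths)),
            class = "coverage_matrix")
}

#' Read a bedcov-style coverage table
#'
#' Tab-delimited with header: scaffold, length, then one count column per
#' sample.
#'
#' @param path TSV file.
#' @return A [coverage_matrix].
#' @export
read_coverage_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  counts <- t(as.matrix(tab[, -(1:2), drop = FALSE]))
  colnames(counts) <- tab[[1]]
  lens <- tab[[2]]; names(lens) <- tab[[1]]
  coverage_matrix(counts, lens)
}

#' Write a coverage matrix as a bedcov-style table
#' @param m A [coverage_matrix].
#' @param path Output path.
#' @export
write_coverage_tsv <- function(m, path) {
  tab <- data.frame(scaffold = m$scaffolds, length = m$scaffold_lengths,
                    t(m$counts), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize read coverage per sample and scaffold
#'
#' Each count is divided by scaffold length and by the sample's total mapped
#' reads over the analyzed scaffolds, then the whole matrix is normalized to
#' the average over all sample-scaffold pairs, which is therefore exactly 1.
#'
#' @param m A [coverage_matrix]; every sample must have total counts > 0.
#' @return List of class `normalized_coverage` with `values` (sample x
#'   scaffold) and `cv` (per-scaffold coefficient of variation across
#'   samples).
#' @export
normalize_coverage <- function(m) {
  stopifnot(inherits(m, "coverage_matrix"))
  totals <- rowSums(m$counts)
  if (any(totals == 0))
    stop("sample(s) with zero total mapped reads: ",
         paste(m$samples[totals == 0], collapse = ", "))
  raw <- sweep(m$counts, 2, m$scaffold_lengths, "/") / totals
  values <- raw / mean(raw)
  cv <- apply(values, 2, function(v) stats::sd(v) / mean(v))
  structure(list(values = values, cv = cv, samples = m$samples,
                 scaffolds = m$scaffolds),
            class = "normalized_coverage")
}

#' Flag scaffolds with X-like bimodal coverage
#'
#' A scaffold is flagged when, relative to each sample's autosomal baseline
#' (median normalized coverage over non-flagged scaffolds), at least
#' `min_frac` of samples fall in the low band and at least `min_frac` in the
#' high band, with at most `gap_frac` of samples between the bands. Two
#' passes are run so flagged scaffolds drop out of the baseline.
#'
#' @param n A `normalized_coverage` (at least 4 samples).
#' @param low_band,high_band Relative-coverage intervals for the
#'   hemizygous (~0.5x) and diploid (~1x) modes.
#' @param min_frac Minimum fraction of samples required in each band.
#' @param gap_frac Maximum tolerated fraction of samples between the bands.
#' @return Character vector of flagged scaffold names (possibly empty).
#' @export
detect_sex_linked <- function(n, low_band = c(0.35, 0.65),
                              high_band = c(0.85, 1.15),
                              min_frac = 0.2, gap_frac = 0.1) {
  stopifnot(inherits(n, "normalized_coverage"))
  if (length(n$samples) < 4) stop("at least 4 samples required")
  flagged <- character(0)
  for (pass in 1:2) {
    keep <- setdiff(n$scaffolds, flagged)
    baseline <- apply(n$values[, n$scaffolds %in% keep, drop = FALSE], 1,
                      stats::median)
    flagged <- character(0)
    for (j in seq_along(n$scaffolds)) {
      r <- n$values[, j] / baseline
      in_low <- r >= low_band[1] & r <= low_band[2]
      in_high <- r >= high_band[1] & r <= high_band[2]
      between <- r > low_band[2] & r < high_band[1]
      if (mean(in_low) >= min_frac && mean(in_high) >= min_frac &&
          mean(between) <= gap_frac)
        flagged <- c(flagged, n$scaffolds[j])
    }
  }
  flagged
}
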
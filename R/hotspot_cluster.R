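#' Cumulative proportion curves of all genes vs selection candidates
#'
#' Genes are binned by midpoint into consecutive fixed-length windows per
#' chromosome, chromosomes taken in layout order, and the cumulative
#' proportion of all genes and of candidate genes is computed over the
#' genome-wide concatenation of windows. A vertical gap between the two
#' curves localizes an excess of candidates.
#'
#' @param genes A [gene_loci] data frame.
#' @param candidates Character vector of candidate gene symbols (non-empty,
#'   all present in `genes`).
#' @param layout A [genome_layout].
#' @param window_len Window length in bp (default 1 Mb).
#' @return Data frame of class `cumulative_curves`: one row per window with
#'   `chrom`, `window_start`, `n_total`, `n_candidate`, `cum_total`,
#'   `cum_candidate` (both cumulative proportions ending at 1).
#' @export
cumulative_curves <- function(genes, candidates, layout, window_len = 1e6) {
  if (length(candidates) == 0) stop("empty candidate set rejected")
  missing <- setdiff(candidates, genes$symbol)
  if (length(missing))
    stop("candidate symbol(s) absent from genes: ", paste(missing, collapse = ", "))
  rows <- list()
  for (k in seq_len(nrow(layout))) {
    chrom <- layout$name[k]
    n_win <- max(1, ceiling(layout$length[k] / window_len))
    starts <- (seq_len(n_win) - 1) * window_len
    g <- genes[genes$chrom == chrom, ]
    bin <- pmin(floor(g$midpoint / window_len) + 1, n_win)
    rows[[k]] <- data.frame(
      chrom = chrom, window_start = starts,
      n_total = tabulate(bin, n_win),
      n_candidate = tabulate(bin[g$symbol %in% candidates], n_win),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$cum_total <- cumsum(out$n_total) / sum(out$n_total)
  out$cum_candidate <- cumsum(out$n_candidate) / sum(out$n_candidate)
  class(out) <- c("cumulative_curves", "data.frame")
  out
}

#' Count candidate genes in one genomic window
#'
#' A gene is in the window when its midpoint lies in
#' `[window_start, window_start + window_len)` (half-open).
#'
#' @param genes A [gene_loci] data frame.
#' @param candidates Candidate symbols.
#' @param chrom Chromosome name.
#' @param window_start Window start (0-based bp).
#' @param window_len Window length in bp.
#' @return Integer count.
#' @export
count_in_window <- function(genes, candidates, chrom, window_start, window_len) {
  g <- genes[genes$chrom == chrom & genes$symbol %in% candidates, ]
  sum(g$midpoint >= window_start & g$midpoint < window_start + window_len)
}

#' Permutation null for the count of candidates in a random window
#'
#' Per iteration, chromosomes are concatenated in a fresh uniform random
#' order, one window start is drawn uniformly over the integer positions
#' `[0, total_length - window_len]`, and candidate gene midpoints (recomputed
#' on the concatenated coordinate system) falling in the half-open window are
#' counted. Windows may span chromosome junctions by construction.
#'
#' @param genes A [gene_loci] data frame.
#' @param candidates Candidate symbols (subset of `genes$symbol`).
#' @param layout A [genome_layout]; total length must be at least `window_len`.
#' @param window_len Window length in bp (default 12 Mb).
#' @param n_iter Number of iterations (default 1000).
#' @param seed Integer seed; one generator drives both the concatenation
#'   order and the window draw, consumed in that order each iteration.
#' @param observed Observed candidate count for the window of interest
#'   (optional; stored for [empirical_pvalue()]).
#' @return List of class `window_count_null` with `counts`, `n_iter`,
#'   `window_len`, `seed`, `observed`.
#' @export
permutation_null <- function(genes, candidates, layout, window_len = 12e6,
                             n_iter = 1000L, seed = 1L, observed = NA_integer_) {
  total <- sum(layout$length)
  if (window_len > total) stop("window_len exceeds total genome length")
  missing <- setdiff(candidates, genes$symbol)
  if (length(missing))
    stop("candidate symbol(s) absent from genes: ", paste(missing, collapse = ", "))
  cand <- genes[genes$symbol %in% candidates, ]
  chrom_idx <- match(cand$chrom, layout$name)
  if (anyNA(chrom_idx)) stop("candidate gene on chromosome missing from layout")
  nchrom <- nrow(layout)
  counts <- integer(n_iter)
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    ord <- sample.int(nchrom)
    offsets <- cumsum(c(0, layout$length[ord]))[seq_len(nchrom)]
    pos_of_chrom <- integer(nchrom)
    pos_of_chrom[ord] <- seq_len(nchrom)
    mid <- offsets[pos_of_chrom[chrom_idx]] + cand$midpoint
    start <- sample.int(total - window_len + 1, 1) - 1
    counts[it] <- sum(mid >= start & mid < start + window_len)
  }
  structure(list(counts = counts, n_iter = n_iter, window_len = window_len,
                 seed = seed, observed = observed),
            class = "window_count_null")
}

#' Maximum candidate count over all windows of fixed length
#'
#' Scan statistic over the layout-order concatenation: the largest number of
#' candidate midpoints falling in any `window_len` window (equivalent to a
#' 1-bp-stride scan). This is a hypothesis-free observed statistic; note the
#' permutation null of a single random window is not calibrated for it.
#'
#' @inheritParams permutation_null
#' @return List with `count`, `start` (concatenated coordinate) for one
#'   maximizing window.
#' @export
max_window_count <- function(genes, candidates, layout, window_len = 12e6) {
  cand <- genes[genes$symbol %in% candidates, ]
  offsets <- cumsum(c(0, layout$length))[seq_len(nrow(layout))]
  mid <- sort(offsets[match(cand$chrom, layout$name)] + cand$midpoint)
  if (!length(mid)) return(list(count = 0L, start = 0))
  best <- 0L; best_start <- 0
  j <- 1
  for (i in seq_along(mid)) {
    while (mid[i] - mid[j] >= window_len) j <- j + 1
    if (i - j + 1 > best) { best <- i - j + 1; best_start <- mid[j] }
    # window anchored so that mid[j] is included
  }
  list(count = as.integer(best), start = best_start)
}

#' Empirical P-value of the observed window count
#'
#' Add-one permutation convention:
#' `p = (#(null counts >= observed) + 1) / (n_iter + 1)`, so p is never zero.
#'
#' @param null A `window_count_null` from [permutation_null()].
#' @param observed Observed count; defaults to the value stored in `null`.
#' @return Numeric P-value.
#' @export
empirical_pvalue <- function(null, observed = NULL) {
  stopifnot(inherits(null, "window_count_null"), null$n_iter >= 1)
  if (is.null(observed)) observed <- null$observed
  if (is.na(observed)) stop("no observed count supplied")
  (sum(null$counts >= observed) + 1) / (null$n_iter + 1)
}
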
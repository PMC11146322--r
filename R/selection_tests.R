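#' Likelihood-ratio test of branch-specific selection
#'
#' Statistic is twice the log-likelihood difference between the two-ratio
#' branch model and the one-ratio null, referred to chi-square with one
#' degree of freedom. Negative statistics (optimizer noise: the models are
#' nested, so lnL1 >= lnL0 at the true optima) are clamped to zero with a
#' warning.
#'
#' @param fit0 `model_fit` of the one-ratio model.
#' @param fit1 `model_fit` of the two-ratio branch model (same gene).
#' @param gene_id Gene identifier recorded in the result.
#' @param tolerance Allowed negative slack before the clamping warning fires.
#' @return A one-row data frame of class `branch_test_result` with `gene_id`,
#'   `lnL0`, `lnL1`, `stat`, `df`, `p_raw`, `p_adj` (NA until
#'   [bh_adjust()]-ed), `omega_background`, `omega_foreground`, `converged`.
#' @export
lrt_branch <- function(fit0, fit1, gene_id = NULL, tolerance = 1e-6) {
  stopifnot(inherits(fit0, "model_fit"), inherits(fit1, "model_fit"))
  stat <- 2 * (fit1$lnL - fit0$lnL)
  if (stat < -tolerance)
    warning(sprintf("lnL(branch) < lnL(one-ratio) by %.4g; statistic clamped to 0 (optimizer failure?)",
                    -stat / 2))
  stat <- max(stat, 0)
  p <- chisq_sf(stat, df = 1)
  structure(data.frame(
    gene_id = if (is.null(gene_id)) "gene" else gene_id,
    lnL0 = fit0$lnL, lnL1 = fit1$lnL, stat = stat, df = 1L,
    p_raw = p, p_adj = NA_real_,
    omega_background = if (is.null(fit1$params)) NA_real_ else fit1$params$omega_background,
    omega_foreground = if (is.null(fit1$params)) NA_real_ else fit1$params$omega_foreground,
    converged = isTRUE(fit0$converged) && isTRUE(fit1$converged),
    stringsAsFactors = FALSE),
    class = c("branch_test_result", "data.frame"))
}

# chi-square survival function: the regularized upper incomplete gamma
chisq_sf <- function(x, df = 1) stats::pchisq(x, df = df, lower.tail = FALSE)

#' Benjamini-Hochberg step-up adjusted P-values
#'
#' Classic step-up FDR adjustment: sort, multiply by m/rank, enforce
#' monotonicity from the largest P downward, cap at 1. The family is exactly
#' the vector passed in.
#'
#' @param p Numeric vector of raw P-values in `[0, 1]`.
#' @return Adjusted P-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Run the branch-model selection screen over a set of genes
#'
#' For each alignment fits the one-ratio and two-ratio models, forms the LRT,
#' then BH-adjusts raw P-values within exactly the set of genes whose fits
#' succeeded (failed fits are excluded from the family with a warning).
#' Candidates are genes with adjusted P below `alpha`.
#'
#' @param alignments Named list of [codon_alignment] objects.
#' @param tree A [labeled_tree] with foreground labels, or a function
#'   `function(gene_id, alignment)` returning one (to supply per-gene pruned
#'   trees).
#' @param alpha Candidate threshold on the adjusted P (default 0.01, the
#'   screen's operating point).
#' @param seed Seed forwarded to the fitters' restart machinery.
#' @param freqs_mode,gap_policy,control Forwarded to the fitters.
#' @param verbose Print per-gene progress.
#' @return List with `results` (data frame, one row per gene) and
#'   `candidates` (character vector of gene ids with `p_adj < alpha`).
#' @export
run_branch_screen <- function(alignments, tree, alpha = 0.01, seed = 1L,
                              freqs_mode = "f3x4", gap_policy = "missing",
                              control = list(), verbose = FALSE) {
  stopifnot(length(alignments) >= 1)
  if (is.null(names(alignments)))
    names(alignments) <- vapply(alignments, function(a) a$gene_id, character(1))
  rows <- list()
  for (g in names(alignments)) {
    if (verbose) message("fitting ", g)
    row <- tryCatch({
      tr <- if (is.function(tree)) tree(g, alignments[[g]]) else tree
      f0 <- fit_one_ratio(alignments[[g]], tr, freqs_mode = freqs_mode,
                          gap_policy = gap_policy, seed = seed, control = control)
      f1 <- fit_branch_model(alignments[[g]], tr, freqs_mode = freqs_mode,
                             gap_policy = gap_policy, seed = seed, control = control)
      lrt_branch(f0, f1, gene_id = g)
    }, error = function(e) {
      warning("fit failed for ", g, ": ", conditionMessage(e),
              "; excluded from FDR family")
      NULL
    })
    if (!is.null(row)) rows[[g]] <- row
  }
  if (!length(rows)) stop("all gene fits failed")
  res <- do.call(rbind, c(rows, make.row.names = FALSE))
  res$p_adj <- bh_adjust(res$p_raw)
  candidates <- res$gene_id[res$p_adj < alpha]
  list(results = res, candidates = candidates)
}

#' Write branch-screen results to TSV
#'
#' @param results The `results` data frame from [run_branch_screen()].
#' @param path Output path.
#' @export
write_screen_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
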
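.hotspotsel_env <- new.env(parent = emptyenv())

NUC <- c("A", "C", "G", "T")

#' Codon state space for a genetic code
#'
#' Enumerates the sense codons (stops excluded) of an NCBI translation table
#' and precomputes, for every ordered pair differing at exactly one position,
#' whether the change is a transition and whether it is nonsynonymous. These
#' structural facts are what the GY94-style rate matrix is built from.
#'
#' @param code_id NCBI genetic code id (only 1, the standard code, is shipped).
#' @return List with `sense_codons`, `aa` (amino acid per sense codon), and
#'   index/matrix components used by [build_rate_matrix()].
#' @export
codon_state_space <- function(code_id = 1L) {
  key <- paste0("space", code_id)
  if (!is.null(.hotspotsel_env[[key]])) return(.hotspotsel_env[[key]])
  if (code_id != 1L) stop("only the standard genetic code (table 1) is supported")
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  sense <- codons[gc != "*"]
  aa <- unname(gc[sense])
  n <- length(sense)
  cm <- do.call(rbind, strsplit(sense, ""))
  ts_pair <- function(x, y) (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
  ii <- jj <- integer(0); ts <- ns <- logical(0)
  for (pos in 1:3) {
    other <- setdiff(1:3, pos)
    same <- outer(cm[, other[1]], cm[, other[1]], "==") &
            outer(cm[, other[2]], cm[, other[2]], "==")
    diff1 <- same & outer(cm[, pos], cm[, pos], "!=")
    idx <- which(diff1, arr.ind = TRUE)
    ii <- c(ii, idx[, 1]); jj <- c(jj, idx[, 2])
    ts <- c(ts, ts_pair(cm[idx[, 1], pos], cm[idx[, 2], pos]))
    ns <- c(ns, aa[idx[, 1]] != aa[idx[, 2]])
  }
  space <- list(code_id = code_id, sense_codons = sense, aa = aa, n = n,
                pair_i = ii, pair_j = jj, is_transition = ts, is_nonsyn = ns)
  .hotspotsel_env[[key]] <- space
  space
}

#' Equilibrium codon frequencies from positional nucleotide composition (F3x4)
#'
#' @param alignment A [codon_alignment].
#' @param mode `"f3x4"` (position-specific nucleotide frequencies, the codeml
#'   default), `"f1x4"` (pooled nucleotide frequencies), or `"empirical"`
#'   (observed sense-codon frequencies with a small floor).
#' @return List of class `codon_frequencies`: `pi` over sense codons (sums to
#'   1) and `positional` (3 x 4 nucleotide frequency matrix).
#' @export
f3x4_frequencies <- function(alignment, mode = c("f3x4", "f1x4", "empirical")) {
  mode <- match.arg(mode)
  stopifnot(inherits(alignment, "codon_alignment"))
  space <- codon_state_space()
  chars <- strsplit(alignment$sequences, "")
  pos_of <- rep_len(1:3, alignment$n_codons * 3L)
  counts <- matrix(0, 3, 4, dimnames = list(NULL, NUC))
  for (s in chars) {
    for (p in 1:3) {
      cc <- s[pos_of == p]
      counts[p, ] <- counts[p, ] + tabulate(match(cc, NUC), 4L)
    }
  }
  if (mode == "f1x4") counts <- matrix(colSums(counts), 3, 4, byrow = TRUE,
                                       dimnames = list(NULL, NUC))
  if (any(rowSums(counts) == 0))
    stop("a codon position has no unambiguous nucleotides")
  pos <- counts / rowSums(counts)
  if (mode == "empirical") {
    cods <- unlist(lapply(alignment$sequences, function(s)
      substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))), use.names = FALSE)
    tab <- tabulate(match(cods, space$sense_codons), space$n)
    if (sum(tab) == 0) stop("no unambiguous sense codons observed")
    pi <- tab / sum(tab)
  } else {
    cm <- do.call(rbind, strsplit(space$sense_codons, ""))
    pi <- pos[1, cm[, 1]] * pos[2, cm[, 2]] * pos[3, cm[, 3]]
    if (sum(pi) == 0) stop("degenerate positional frequencies")
    pi <- pi / sum(pi)
  }
  # reversible-symmetrization guard: zero frequencies are floored
  if (any(pi < 1e-10)) { pi <- pmax(pi, 1e-10); pi <- pi / sum(pi) }
  names(pi) <- space$sense_codons
  structure(list(pi = pi, positional = pos, mode = mode),
            class = "codon_frequencies")
}

#' Codon model parameters
#'
#' @param kappa Transition/transversion rate ratio (bounds `[1e-3, 100]`).
#' @param omega_background dN/dS on background branches (bounds `[1e-4, 50]`).
#' @param omega_foreground dN/dS on foreground branches; defaults to the
#'   background value (the one-ratio model).
#' @param freqs A `codon_frequencies` object.
#' @return List of class `codon_model_params`.
#' @export
codon_model_params <- function(kappa, omega_background,
                               omega_foreground = omega_background, freqs) {
  if (kappa < 1e-3 || kappa > 100) stop("kappa out of bounds [1e-3, 100]")
  for (w in c(omega_background, omega_foreground))
    if (w < 1e-4 || w > 50) stop("omega out of bounds [1e-4, 50]")
  stopifnot(inherits(freqs, "codon_frequencies"))
  structure(list(kappa = kappa, omega_background = omega_background,
                 omega_foreground = omega_foreground, freqs = freqs),
            class = "codon_model_params")
}

#' GY94-style codon rate matrix
#'
#' Off-diagonal rate \eqn{q_{ij}} is zero unless codons i and j differ at
#' exactly one nucleotide and j is a sense codon; otherwise proportional to
#' \eqn{\pi_j}, multiplied by \eqn{\kappa} for transitions and \eqn{\omega}
#' for nonsynonymous changes. The matrix is scaled so the expected number of
#' substitutions per codon per unit time is 1.
#'
#' @param params A [codon_model_params].
#' @param omega_class `"background"` or `"foreground"`.
#' @return Scaled rate matrix over sense codons.
#' @export
build_rate_matrix <- function(params, omega_class = c("background", "foreground")) {
  omega_class <- match.arg(omega_class)
  space <- codon_state_space()
  pi <- params$freqs$pi
  omega <- if (omega_class == "foreground") params$omega_foreground
           else params$omega_background
  rate <- pi[space$pair_j] *
    ifelse(space$is_transition, params$kappa, 1) *
    ifelse(space$is_nonsyn, omega, 1)
  Q <- matrix(0, space$n, space$n, dimnames = list(space$sense_codons,
                                                   space$sense_codons))
  Q[cbind(space$pair_i, space$pair_j)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix")
  Q / scale
}

# Eigen-decomposition of a reversible generator via the symmetrized form.
# Returns A, B with P(t) = A diag(exp(lambda t)) B.
eigen_reversible <- function(Q, pi) {
  d <- sqrt(pi)
  S <- Q * outer(d, 1 / d)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  list(A = es$vectors / d, B = t(es$vectors) * rep(d, each = length(d)),
       lambda = es$values)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param Q Rate matrix from [build_rate_matrix()] (reversible).
#' @param t Branch length (>= 0), expected substitutions per codon.
#' @param pi Stationary frequencies of `Q`; recovered from the model if
#'   omitted (required because the fast path uses the reversible
#'   eigendecomposition).
#' @return Stochastic matrix; rows sum to 1, entries clamped at 0.
#' @export
transition_matrix <- function(Q, t, pi = NULL) {
  stopifnot(t >= 0)
  if (is.null(pi)) pi <- stationary_from_Q(Q)
  eg <- eigen_reversible(Q, pi)
  P <- (eg$A * rep(exp(eg$lambda * t), each = nrow(Q))) %*% eg$B
  P[P < 0] <- 0
  P / rowSums(P)
}

stationary_from_Q <- function(Q) {
  # reversible Q built here satisfies pi_i q_ij = pi_j q_ji; solve via null space
  ns <- Re(eigen(t(Q))$vectors[, which.min(abs(Re(eigen(t(Q))$values)))])
  ns <- abs(ns); ns / sum(ns)
}

# ---- alignment encoding ----------------------------------------------------

# Integer codon states per taxon x codon column; NA for any codon containing
# gaps, ambiguity codes, or stops (reported). Default gap policy treats these
# as missing data at that tip; "strip" drops such columns globally.
encode_alignment <- function(alignment, gap_policy = c("missing", "strip"),
                             warn_stops = TRUE) {
  gap_policy <- match.arg(gap_policy)
  space <- codon_state_space()
  n <- alignment$n_codons
  starts <- seq(1, 3 * n, 3)
  st <- vapply(alignment$sequences, function(s) {
    cods <- substring(s, starts, starts + 2)
    match(cods, space$sense_codons)
  }, integer(n))
  if (is.null(dim(st))) st <- matrix(st, nrow = n)  # 1-codon alignments
  st <- t(st)  # taxa x codons
  if (warn_stops) {
    all_cod <- unlist(lapply(alignment$sequences, function(s)
      substring(s, starts, starts + 2)), use.names = FALSE)
    stops <- setdiff(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"],
                     character(0))
    nstop <- sum(all_cod %in% stops)
    if (nstop > 0)
      warning(nstop, " stop codon(s) observed; treated as missing data")
  }
  if (gap_policy == "strip") {
    keep <- colSums(is.na(st)) == 0
    st <- st[, keep, drop = FALSE]
    if (ncol(st) == 0) stop("no complete codon columns after stripping")
  }
  st
}

# Collapse identical site columns; returns states (taxa x npat) and weights.
compress_patterns <- function(states) {
  key <- apply(states, 2, paste, collapse = ",")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  list(states = states[, first, drop = FALSE],
       weights = as.numeric(tabulate(idx, sum(first))))
}

# Tree pieces the C++ kernel needs, with rows of `edge` in postorder.
tree_for_pruning <- function(tree, taxa) {
  phy <- tree$phy
  if (!setequal(phy$tip.label, taxa))
    stop("tree tips and alignment taxa differ: ",
         paste(union(setdiff(phy$tip.label, taxa), setdiff(taxa, phy$tip.label)),
               collapse = ", "))
  po <- ape::reorder.phylo(phy, "postorder")
  key0 <- paste(phy$edge[, 1], phy$edge[, 2])
  keyp <- paste(po$edge[, 1], po$edge[, 2])
  perm <- match(keyp, key0)
  list(phy = po, edge = po$edge, edge_len = po$edge.length,
       eclass = tree$edge_labels[perm], perm = perm,
       n_node = length(po$tip.label) + po$Nnode,
       tip_order = po$tip.label)
}

codon_loglik_cpp <- function(states, weights, tr, edge_len, params, want_grad = FALSE) {
  pi <- params$freqs$pi
  Q0 <- build_rate_matrix(params, "background")
  eg0 <- eigen_reversible(Q0, pi)
  if (any(tr$eclass == 1L)) {
    Q1 <- build_rate_matrix(params, "foreground")
    eg1 <- eigen_reversible(Q1, pi)
  } else eg1 <- eg0
  st <- states; st[is.na(st)] <- 0L
  res <- cpp_codon_loglik(st, weights, tr$edge, edge_len, tr$eclass,
                          eg0$A, eg0$B, eg0$lambda,
                          eg1$A, eg1$B, eg1$lambda,
                          unname(pi), tr$n_node, want_grad)
  res
}

#' Log-likelihood of a codon alignment on a labeled tree
#'
#' Felsenstein pruning over sense-codon states. Foreground branches use the
#' foreground omega's rate matrix, background branches the background one.
#' Codons containing gaps, ambiguity codes or stops at a tip are missing data
#' at that tip under the default gap policy.
#'
#' @param alignment A [codon_alignment]; taxa must equal the tree tips.
#' @param tree A [labeled_tree] with branch lengths.
#' @param params A [codon_model_params].
#' @param gap_policy `"missing"` (default) or `"strip"` (drop any column with
#'   a missing codon in any taxon).
#' @return The log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(alignment, tree, params,
                           gap_policy = c("missing", "strip")) {
  tr <- tree_for_pruning(tree, alignment$taxa)
  states <- encode_alignment(alignment, gap_policy)
  states <- states[match(tr$tip_order, alignment$taxa), , drop = FALSE]
  cp <- compress_patterns(states)
  codon_loglik_cpp(cp$states, cp$weights, tr, tr$edge_len, params)$loglik
}

# ---- maximum-likelihood fitting --------------------------------------------

KAPPA_BOUNDS <- c(1e-3, 100)
OMEGA_BOUNDS <- c(1e-4, 50)
BLEN_BOUNDS <- c(1e-8, 50)

# Branch lengths from JC-corrected nucleotide distances (x3 for per-codon),
# least-squares-projected onto the fixed topology.
init_branch_lengths <- function(alignment, phy) {
  n <- length(phy$edge.length)
  out <- tryCatch({
    mat <- do.call(rbind, strsplit(tolower(alignment$sequences), ""))
    rownames(mat) <- alignment$taxa
    dm <- ape::dist.dna(ape::as.DNAbin(mat), model = "JC69",
                        pairwise.deletion = TRUE)
    dm <- as.matrix(dm) * 3
    bad <- !is.finite(dm)
    if (any(bad)) dm[bad] <- max(1, dm[!bad], na.rm = TRUE) * 1.5
    fit <- phangorn::nnls.tree(stats::as.dist(dm), phy, method = "unrooted")
    key <- paste(fit$edge[, 1], fit$edge[, 2])
    fit$edge.length[match(paste(phy$edge[, 1], phy$edge[, 2]), key)]
  }, error = function(e) rep(0.1, n))
  pmin(pmax(out, 0.01), 10)
}

fit_codon_model <- function(alignment, tree, n_omega,
                            freqs_mode = "f3x4",
                            gap_policy = "missing",
                            init = list(kappa = 2, omega = 0.4),
                            max_restarts = 2L, seed = 1L,
                            control = list()) {
  stopifnot(inherits(alignment, "codon_alignment"), inherits(tree, "labeled_tree"))
  tr <- tree_for_pruning(tree, alignment$taxa)
  states <- encode_alignment(alignment, gap_policy)
  states <- states[match(tr$tip_order, alignment$taxa), , drop = FALSE]
  cp <- compress_patterns(states)
  freqs <- f3x4_frequencies(alignment, mode = freqs_mode)
  has_fg <- any(tr$eclass == 1L)
  if (n_omega == 2 && !has_fg) stop("branch model requires >= 1 foreground branch")

  bl0 <- init_branch_lengths(alignment, tr$phy)
  nb <- length(bl0)
  theta0 <- c(log(init$kappa), rep(log(init$omega), n_omega), log(bl0))
  lower <- c(log(KAPPA_BOUNDS[1]), rep(log(OMEGA_BOUNDS[1]), n_omega),
             rep(log(BLEN_BOUNDS[1]), nb))
  upper <- c(log(KAPPA_BOUNDS[2]), rep(log(OMEGA_BOUNDS[2]), n_omega),
             rep(log(BLEN_BOUNDS[2]), nb))

  clamp <- function(x, b) min(max(x, b[1]), b[2])  # exp/log roundoff at bounds
  mk_params <- function(theta) {
    kappa <- clamp(exp(theta[1]), KAPPA_BOUNDS)
    wb <- clamp(exp(theta[2]), OMEGA_BOUNDS)
    wf <- if (n_omega == 2) clamp(exp(theta[3]), OMEGA_BOUNDS) else wb
    codon_model_params(kappa, wb, wf, freqs)
  }
  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta, want_grad) {
    key <- paste(signif(theta, 15), collapse = ",")
    hit <- cache$res
    if (!is.null(hit) && identical(cache$key, key) && (!want_grad || !is.null(hit$grad)))
      return(hit)
    res <- codon_loglik_cpp(cp$states, cp$weights, tr, exp(theta[-(1:(1 + n_omega))]),
                            mk_params(theta), want_grad)
    cache$key <- key; cache$res <- res
    res
  }
  fn <- function(theta) -evaluate(theta, FALSE)$loglik
  nrate <- 1 + n_omega
  gr <- function(theta) {
    res <- evaluate(theta, TRUE)
    g <- numeric(length(theta))
    # analytic branch gradients (chain rule for the log transform)
    g[-(1:nrate)] <- -res$grad * exp(theta[-(1:nrate)])
    h <- 1e-4
    for (k in seq_len(nrate)) {
      tp <- theta; tm <- theta
      tp[k] <- theta[k] + h; tm[k] <- theta[k] - h
      g[k] <- -(evaluate(tp, FALSE)$loglik - evaluate(tm, FALSE)$loglik) / (2 * h)
    }
    cache$key <- NULL  # FD evals clobbered the cache
    g
  }

  ctl <- utils::modifyList(list(maxit = 500L, factr = 1e7), control)
  best <- NULL
  set.seed(seed)
  restarts_used <- 0L
  for (attempt in 0:max_restarts) {
    th <- if (attempt == 0) theta0 else
      pmin(pmax(theta0 + stats::rnorm(length(theta0), 0, 0.5), lower), upper)
    opt <- tryCatch(
      stats::optim(th, fn, gr, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = ctl$maxit, factr = ctl$factr)),
      error = function(e) NULL)
    if (!is.null(opt)) {
      if (is.null(best) || opt$value < best$value) best <- opt
      if (opt$convergence == 0) { restarts_used <- attempt; break }
    }
    restarts_used <- attempt
  }
  if (is.null(best))
    return(structure(list(params = NULL, tree = tree, lnL = -Inf,
                          n_free_params = length(theta0), converged = FALSE,
                          n_restarts_used = restarts_used), class = "model_fit"))
  theta <- best$par
  params <- mk_params(theta)
  fitted_tree <- tree
  bl_po <- exp(theta[-(1:nrate)])
  fitted_tree$phy$edge.length[tr$perm] <- bl_po
  structure(list(params = params, tree = fitted_tree, lnL = -best$value,
                 n_free_params = length(theta0), converged = best$convergence == 0,
                 n_restarts_used = restarts_used, freqs_mode = freqs_mode),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("model_fit: optimization failed (lnL = -Inf)\n")
  } else {
    cat(sprintf("model_fit: lnL = %.4f, kappa = %.3f, omega_bg = %.4f, omega_fg = %.4f, converged = %s\n",
                x$lnL, x$params$kappa, x$params$omega_background,
                x$params$omega_foreground, x$converged))
  }
  invisible(x)
}

#' Fit the one-ratio (M0) codon model
#'
#' Jointly maximizes kappa, a single omega shared by all branches, and all
#' branch lengths. This is the null model of the branch test.
#'
#' @param alignment A [codon_alignment].
#' @param tree A [labeled_tree] (labels are ignored by this model).
#' @param freqs_mode Frequency model passed to [f3x4_frequencies()].
#' @param gap_policy See [log_likelihood()].
#' @param max_restarts Random restarts attempted if the first optimization
#'   does not converge (seeded).
#' @param seed Seed for restart jitter.
#' @param control Optimizer control overrides (`maxit`, `factr`).
#' @return A `model_fit` with elements `params`, `tree` (optimized branch
#'   lengths), `lnL`, `n_free_params`, `converged`, `n_restarts_used`.
#' @export
fit_one_ratio <- function(alignment, tree, freqs_mode = "f3x4",
                          gap_policy = "missing", max_restarts = 2L,
                          seed = 1L, control = list()) {
  tree0 <- tree
  tree0$edge_labels[] <- 0L  # single rate class
  fit_codon_model(alignment, tree0, n_omega = 1, freqs_mode = freqs_mode,
                  gap_policy = gap_policy, max_restarts = max_restarts,
                  seed = seed, control = control)
}

#' Fit the two-ratio branch model
#'
#' As [fit_one_ratio()] but with separate background and foreground omega,
#' one additional free parameter. Foreground branches are those labeled in
#' the [labeled_tree].
#'
#' @inheritParams fit_one_ratio
#' @return A `model_fit`.
#' @export
fit_branch_model <- function(alignment, tree, freqs_mode = "f3x4",
                             gap_policy = "missing", max_restarts = 2L,
                             seed = 1L, control = list()) {
  if (!any(tree$edge_labels == 1L))
    stop("branch model requires at least one foreground branch")
  fit_codon_model(alignment, tree, n_omega = 2, freqs_mode = freqs_mode,
                  gap_policy = gap_policy, max_restarts = max_restarts,
                  seed = seed, control = control)
}
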
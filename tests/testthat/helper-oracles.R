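# Independent oracles, kept deliberately naive.

# Exhaustive-enumeration likelihood: sums over all internal-node state
# assignments. Only feasible for <= 4-taxon trees with a trifurcating root.
oracle_loglik <- function(aln, tree, params) {
  space <- codon_state_space()
  phy <- ape::reorder.phylo(tree$phy, "postorder")
  key0 <- paste(tree$phy$edge[, 1], tree$phy$edge[, 2])
  ecl <- tree$edge_labels[match(paste(phy$edge[, 1], phy$edge[, 2]), key0)]
  pi <- params$freqs$pi
  P <- lapply(seq_len(nrow(phy$edge)), function(e)
    transition_matrix(
      build_rate_matrix(params, if (ecl[e] == 1) "foreground" else "background"),
      phy$edge.length[e], pi))
  ntip <- length(phy$tip.label)
  st <- t(sapply(aln$sequences[phy$tip.label], function(s)
    match(substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)),
          space$sense_codons)))
  grid <- as.matrix(expand.grid(rep(list(seq_len(space$n)), phy$Nnode)))
  lnL <- 0
  for (col in seq_len(ncol(st))) {
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      state <- function(node) if (node <= ntip) st[node, col] else grid[g, node - ntip]
      pr <- pi[grid[g, 1]]
      for (e in seq_len(nrow(phy$edge))) {
        b <- state(phy$edge[e, 2])
        if (is.na(b)) next  # missing tip codon: marginalized out
        pr <- pr * P[[e]][state(phy$edge[e, 1]), b]
      }
      tot <- tot + pr
    }
    lnL <- lnL + log(tot)
  }
  unname(lnL)
}

# Naive BH step-up: adj_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# chi-square(1) survival via the normal closed form (erfc route),
# independent of pchisq's incomplete-gamma path.
oracle_chisq1_sf <- function(x) 2 * stats::pnorm(-sqrt(x))

# Exact null distribution of the window count on a single-chromosome toy
# genome with integer-uniform window starts.
oracle_window_null <- function(midpoints, chrom_len, window_len) {
  starts <- 0:(chrom_len - window_len)
  counts <- vapply(starts, function(s)
    sum(midpoints >= s & midpoints < s + window_len), integer(1))
  table(factor(counts, levels = 0:length(midpoints))) / length(starts)
}

# All signed arrangements of n landmarks on one linkage group.
enumerate_signed_instances <- function(landmarks) {
  n <- length(landmarks)
  perms <- if (n <= 1) list(seq_len(n)) else {
    res <- list()
    rec <- function(head, rest) {
      if (!length(rest)) { res[[length(res) + 1]] <<- head; return() }
      for (k in seq_along(rest)) rec(c(head, rest[k]), rest[-k])
    }
    rec(integer(0), seq_len(n)); res
  }
  signs <- as.matrix(expand.grid(rep(list(c("+", "-")), n)))
  out <- list()
  for (p in perms) for (r in seq_len(nrow(signs))) {
    ann <- gene_loci(landmarks[p], "chr1",
                     (seq_len(n) - 1) * 1e6, (seq_len(n) - 1) * 1e6 + 1e4,
                     strand = unname(signs[r, ]))
    out[[length(out) + 1]] <- extract_block(ann, block_def("b", landmarks))
  }
  out
}
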
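#' Default simulation tree: 8-tip pectinate with one foreground terminal
#'
#' Branch lengths 0.05-0.3 expected substitutions per codon; the foreground
#' tip `t8` sits on the longest terminal branch (0.3), emulating a fast,
#' well-separated focal lineage.
#'
#' @param foreground Tip(s) to label foreground (default `"t8"`).
#' @return A [labeled_tree].
#' @export
default_sim_tree <- function(foreground = "t8") {
  txt <- "((((((t1:0.15,t2:0.10):0.05,t3:0.12):0.05,t4:0.15):0.06,t5:0.20):0.07,t6:0.25):0.08,t7:0.15,t8:0.30);"
  labeled_tree(ape::read.tree(text = txt), foreground = foreground)
}

#' Uniform codon frequencies (1/61 per sense codon)
#' @return A `codon_frequencies` object with uniform pi.
#' @export
uniform_codon_frequencies <- function() {
  space <- codon_state_space()
  pi <- rep(1 / space$n, space$n)
  names(pi) <- space$sense_codons
  structure(list(pi = pi,
                 positional = matrix(0.25, 3, 4, dimnames = list(NULL, NUC)),
                 mode = "uniform"),
            class = "codon_frequencies")
}

#' Simulate a codon alignment under the branch model
#'
#' The root codon is drawn from the stationary distribution and evolved along
#' each branch with the transition matrix of that branch's omega class —
#' the same rate-matrix and matrix-exponential code the fitters use, so
#' simulation and inference share one model definition.
#'
#' @param tree A [labeled_tree]; foreground branches evolve under
#'   `omega_foreground`.
#' @param n_codons Number of codon sites (>= 1).
#' @param kappa,omega_background,omega_foreground Model parameters.
#' @param freqs A `codon_frequencies`; default uniform.
#' @param seed Integer seed (byte-identical output for equal seeds).
#' @param gene_id Identifier for the returned alignment.
#' @return A [codon_alignment] over the tree's tips.
#' @export
simulate_codon_alignment <- function(tree, n_codons,
                                     kappa = 2, omega_background = 0.2,
                                     omega_foreground = omega_background,
                                     freqs = uniform_codon_frequencies(),
                                     seed = 1L, gene_id = "sim") {
  stopifnot(inherits(tree, "labeled_tree"), n_codons >= 1)
  params <- codon_model_params(kappa, omega_background, omega_foreground, freqs)
  space <- codon_state_space()
  pi <- params$freqs$pi
  P_of <- list(
    background = function(t) transition_matrix(build_rate_matrix(params, "background"), t, pi),
    foreground = function(t) transition_matrix(build_rate_matrix(params, "foreground"), t, pi))
  phy <- ape::reorder.phylo(tree$phy, "postorder")
  key0 <- paste(tree$phy$edge[, 1], tree$phy$edge[, 2])
  eclass <- tree$edge_labels[match(paste(phy$edge[, 1], phy$edge[, 2]), key0)]
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  set.seed(seed)
  states <- matrix(NA_integer_, ntip + phy$Nnode, n_codons)
  states[root, ] <- sample.int(space$n, n_codons, replace = TRUE, prob = pi)
  Pcache <- list()
  for (e in rev(seq_len(nrow(phy$edge)))) {  # preorder
    p <- phy$edge[e, 1]; c <- phy$edge[e, 2]
    ckey <- paste(eclass[e], signif(phy$edge.length[e], 12))
    if (is.null(Pcache[[ckey]]))
      Pcache[[ckey]] <- (if (eclass[e] == 1L) P_of$foreground else P_of$background)(phy$edge.length[e])
    P <- Pcache[[ckey]]
    parent <- states[p, ]
    child <- integer(n_codons)
    for (s in unique(parent)) {
      idx <- which(parent == s)
      child[idx] <- sample.int(space$n, length(idx), replace = TRUE, prob = P[s, ])
    }
    states[c, ] <- child
  }
  seqs <- vapply(seq_len(ntip), function(i)
    paste(space$sense_codons[states[i, ]], collapse = ""), character(1))
  names(seqs) <- phy$tip.label
  codon_alignment(seqs[tree$phy$tip.label], gene_id = gene_id)
}

#' Default 14-chromosome layout (~2.1 Gb total)
#'
#' Mimics a bat-like chromosome-level assembly: 14 major scaffolds with a
#' broad length range summing to about 2.1 Gb.
#'
#' @return A [genome_layout].
#' @export
default_sim_layout <- function() {
  lens <- c(320, 280, 250, 220, 190, 170, 150, 130, 110, 90, 70, 50, 40, 30) * 1e6
  genome_layout(paste0("chr", seq_along(lens)), lens)
}

#' Simulate a genome annotation with a planted candidate cluster
#'
#' Non-candidate genes are placed uniformly over the genome; `n_inside`
#' candidates uniformly within the planted cluster window; remaining
#' candidates uniformly outside it.
#'
#' @param layout A [genome_layout] (default [default_sim_layout()]).
#' @param n_genes Total number of genes (> 0).
#' @param n_candidates Number of candidate genes (<= `n_genes`).
#' @param cluster List `(chrom, start, width, n_inside)` describing the
#'   planted cluster; `n_inside = 0` (or `NULL` cluster) plants nothing.
#' @param gene_width Gene footprint in bp.
#' @param seed Integer seed.
#' @return List with `genes` ([gene_loci]), `candidates` (symbols), `layout`.
#' @export
simulate_genome_annotation <- function(layout = default_sim_layout(),
                                       n_genes = 5000, n_candidates = 12,
                                       cluster = list(chrom = "chr5", start = 50e6,
                                                      width = 12e6, n_inside = 10),
                                       gene_width = 2e4, seed = 1L) {
  if (n_genes <= 0) stop("n_genes must be positive")
  if (n_candidates > n_genes) stop("more candidates than genes")
  if (is.null(cluster)) cluster <- list(n_inside = 0)
  n_in <- cluster$n_inside
  if (n_in > n_candidates) stop("planted candidates exceed total candidates")
  if (n_in > 0) {
    ci <- match(cluster$chrom, layout$name)
    if (is.na(ci) || cluster$start < 0 ||
        cluster$start + cluster$width > layout$length[ci])
      stop("infeasible placement: cluster outside chromosome")
  }
  set.seed(seed)
  total <- sum(layout$length)
  offsets <- cumsum(c(0, layout$length))[seq_len(nrow(layout))]
  to_chrom <- function(pos) {
    k <- findInterval(pos, offsets)
    list(chrom = layout$name[k], start = pos - offsets[k])
  }
  draw_uniform <- function(n, exclude_window = FALSE) {
    got <- numeric(0)
    while (length(got) < n) {
      pos <- stats::runif(n, 0, total - gene_width)
      if (exclude_window && n_in > 0) {
        ci <- match(cluster$chrom, layout$name)
        w0 <- offsets[ci] + cluster$start
        pos <- pos[pos + gene_width <= w0 | pos >= w0 + cluster$width]
      }
      got <- c(got, pos)
    }
    floor(got[seq_len(n)])
  }
  n_out <- n_candidates - n_in
  pos_bg <- draw_uniform(n_genes - n_candidates)
  pos_out <- draw_uniform(n_out, exclude_window = TRUE)
  pos_in <- if (n_in > 0) {
    ci <- match(cluster$chrom, layout$name)
    floor(offsets[ci] + cluster$start +
            stats::runif(n_in, 0, cluster$width - gene_width))
  } else numeric(0)
  pos <- c(pos_bg, pos_out, pos_in)
  loc <- to_chrom(pos)
  sym <- sprintf("g%05d", seq_along(pos))
  genes <- gene_loci(symbol = sym, chrom = loc$chrom, start = loc$start,
                     end = loc$start + gene_width,
                     strand = sample(c("+", "-"), length(pos), replace = TRUE))
  candidates <- sym[(n_genes - n_candidates + 1):n_genes]
  list(genes = genes, candidates = candidates, layout = layout)
}

#' Reference block instance with evenly spaced landmarks
#'
#' Convenience constructor for rearrangement simulations: landmarks laid out
#' in order on one linkage group, all on the plus strand.
#'
#' @param landmarks Ordered landmark symbols.
#' @param chrom Linkage group name.
#' @param spacing Distance between landmark starts (bp).
#' @param gene_width Landmark footprint (bp).
#' @param species,block Labels for the instance.
#' @return A `block_instance`.
#' @export
block_instance <- function(landmarks, chrom = "chr1", spacing = 1e6,
                           gene_width = 1e4, species = "reference",
                           block = "block") {
  ann <- gene_loci(symbol = landmarks, chrom = chrom,
                   start = (seq_along(landmarks) - 1) * spacing,
                   end = (seq_along(landmarks) - 1) * spacing + gene_width,
                   strand = "+")
  extract_block(ann, block_def(block, landmarks), species = species)
}

#' Apply gene-order rearrangements to a block instance
#'
#' Operations are applied left to right to the arrangement of present
#' landmarks (positions index the current order of linkage group 1):
#' `inversion(i, j)` reverses the segment and flips its signs;
#' `transposition(i, j, k)` moves segment `i..j` to after position `k`;
#' `fission(i)` moves the suffix from position `i` onward to a new linkage
#' group; `deletion(i)` marks the landmark absent.
#'
#' @param block A `block_instance` (typically from [block_instance()]).
#' @param operations List of lists, each with `type` and indices `i`, `j`,
#'   `k` as required.
#' @param spacing,gene_width Coordinates regenerated for the rearranged
#'   arrangement.
#' @return List with `instance` (rearranged `block_instance`) and `log`
#'   (data frame of applied operations).
#' @export
simulate_rearrangements <- function(block, operations, spacing = 1e6,
                                    gene_width = 1e4) {
  stopifnot(inherits(block, "block_instance"))
  pres <- block[block$present, ]
  pres <- pres[order(pres$chrom, pres$start), ]
  arr <- list(data.frame(landmark = pres$landmark,
                         sign = ifelse(pres$strand == "-", -1L, 1L),
                         stringsAsFactors = FALSE))
  deleted <- character(0)
  log_rows <- list()
  chk <- function(ok, op) if (!ok) stop("invalid index in operation '", op, "'")
  for (op in operations) {
    g1 <- arr[[1]]
    n <- nrow(g1)
    if (op$type == "inversion") {
      chk(op$i >= 1 && op$j <= n && op$i <= op$j, "inversion")
      seg <- g1[op$i:op$j, ]
      seg <- seg[rev(seq_len(nrow(seg))), ]
      seg$sign <- -seg$sign
      g1[op$i:op$j, ] <- seg
      arr[[1]] <- g1
    } else if (op$type == "transposition") {
      chk(op$i >= 1 && op$j <= n && op$i <= op$j &&
            op$k >= 0 && op$k <= n && (op$k <= op$i - 1 || op$k >= op$j),
          "transposition")
      seg <- g1[op$i:op$j, ]
      rest <- g1[-(op$i:op$j), ]
      k2 <- op$k - if (op$k > op$j) (op$j - op$i + 1) else 0
      arr[[1]] <- rbind(rest[seq_len(k2), , drop = FALSE], seg,
                        rest[setdiff(seq_len(nrow(rest)), seq_len(k2)), , drop = FALSE])
    } else if (op$type == "fission") {
      chk(op$i >= 2 && op$i <= n, "fission")
      arr[[length(arr) + 1]] <- g1[op$i:n, , drop = FALSE]
      arr[[1]] <- g1[seq_len(op$i - 1), , drop = FALSE]
    } else if (op$type == "deletion") {
      chk(op$i >= 1 && op$i <= n, "deletion")
      deleted <- c(deleted, g1$landmark[op$i])
      arr[[1]] <- g1[-op$i, , drop = FALSE]
    } else stop("unknown operation type: ", op$type)
    log_rows[[length(log_rows) + 1]] <-
      data.frame(type = op$type,
                 i = op$i, j = if (is.null(op$j)) NA else op$j,
                 k = if (is.null(op$k)) NA else op$k, stringsAsFactors = FALSE)
  }
  # rebuild an annotation for the rearranged state
  ann_rows <- list()
  for (gidx in seq_along(arr)) {
    g <- arr[[gidx]]
    if (!nrow(g)) next
    ann_rows[[gidx]] <- data.frame(
      symbol = g$landmark, chrom = paste0("grp", gidx),
      start = (seq_len(nrow(g)) - 1) * spacing,
      end = (seq_len(nrow(g)) - 1) * spacing + gene_width,
      strand = ifelse(g$sign < 0, "-", "+"), stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, c(ann_rows, make.row.names = FALSE))
  ann <- gene_loci(ann$symbol, ann$chrom, ann$start, ann$end, ann$strand)
  def <- block_def(attr(block, "block"), block$landmark)
  inst <- extract_block(ann, def, species = paste0(attr(block, "species"), "_rearr"))
  list(instance = inst,
       log = if (length(log_rows)) do.call(rbind, c(log_rows, make.row.names = FALSE))
             else data.frame(type = character(0), i = integer(0),
                             j = integer(0), k = integer(0)))
}

#' Simulate a sample x scaffold coverage matrix with an X-like scaffold
#'
#' Autosomal expected counts are proportional to scaffold length; a chosen
#' fraction of samples receives a 0.5x dose on the X-like scaffold
#' (hemizygous individuals); multiplicative lognormal noise on every cell.
#'
#' @param n_samples Number of samples.
#' @param scaffold_lengths Named vector of scaffold lengths (bp).
#' @param x_scaffold Name of the X-like scaffold (`NULL` for none).
#' @param frac_half_dose Fraction of samples at 0.5x dose on `x_scaffold`.
#' @param noise_sigma Lognormal sigma of the multiplicative noise.
#' @param reads_per_sample Expected total reads per sample.
#' @param seed Integer seed.
#' @return A [coverage_matrix].
#' @export
simulate_coverage <- function(n_samples, scaffold_lengths, x_scaffold = NULL,
                              frac_half_dose = 0.5, noise_sigma = 0.05,
                              reads_per_sample = 1e6, seed = 1L) {
  stopifnot(frac_half_dose >= 0, frac_half_dose <= 1)
  set.seed(seed)
  ns <- length(scaffold_lengths)
  base <- reads_per_sample * scaffold_lengths / sum(scaffold_lengths)
  counts <- matrix(rep(base, each = n_samples), n_samples, ns)
  if (!is.null(x_scaffold)) {
    j <- match(x_scaffold, names(scaffold_lengths))
    if (is.na(j)) stop("x_scaffold not in scaffold_lengths")
    n_half <- round(frac_half_dose * n_samples)
    if (n_half > 0) counts[seq_len(n_half), j] <- counts[seq_len(n_half), j] * 0.5
  }
  if (noise_sigma > 0)
    counts <- counts * matrix(stats::rlnorm(n_samples * ns, 0, noise_sigma),
                              n_samples, ns)
  rownames(counts) <- sprintf("s%02d", seq_len(n_samples))
  colnames(counts) <- names(scaffold_lengths)
  coverage_matrix(counts, scaffold_lengths)
}
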
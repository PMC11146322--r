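# Small fixtures built in code.

quartet_tree <- function(foreground = "A") {
  labeled_tree(ape::read.tree(text = "((A:0.1,B:0.2):0.05,C:0.15,D:0.3);"),
               foreground = foreground)
}

toy_alignment <- function() {
  codon_alignment(c(A = "ATGAAA", B = "ATGAAG"), gene_id = "toy")
}

# annotation with 6 genes on 2 chromosomes
toy_genes <- function() {
  gene_loci(symbol = paste0("g", 1:6),
            chrom = c("c1", "c1", "c1", "c2", "c2", "c2"),
            start = c(0, 100, 220, 10, 150, 300),
            end = c(50, 180, 300, 90, 260, 380),
            strand = c("+", "-", "+", "+", "-", "+"))
}

toy_layout <- function() genome_layout(c("c1", "c2"), c(400, 400))

# a model_fit shell for LRT plumbing tests
fake_fit <- function(lnL, omega_bg = 0.2, omega_fg = 0.5) {
  structure(list(params = list(kappa = 2, omega_background = omega_bg,
                               omega_foreground = omega_fg),
                 lnL = lnL, converged = TRUE, n_restarts_used = 0L),
            class = "model_fit")
}
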
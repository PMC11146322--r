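#' In-frame codon alignment
#'
#' Container for a curated coding-sequence alignment: one nucleotide string
#' per taxon, all of equal length divisible by three. This is the unit on
#' which selection is tested.
#'
#' @param sequences Named character vector of aligned nucleotide sequences.
#' @param gene_id Gene symbol or identifier.
#' @return An object of class `codon_alignment` with elements `gene_id`,
#'   `taxa`, `sequences` (upper-cased, named) and `n_codons`.
#' @export
codon_alignment <- function(sequences, gene_id = "gene") {
  if (is.null(names(sequences)) || anyNA(names(sequences)) || any(names(sequences) == ""))
    stop("sequences must be named by taxon")
  if (anyDuplicated(names(sequences)))
    stop("format error: duplicate taxon names: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]), collapse = ", "))
  sequences <- toupper(sequences)
  len <- unique(nchar(sequences))
  if (length(len) != 1L)
    stop("format error: sequences differ in length")
  if (len %% 3L != 0L)
    stop("frame error: alignment length ", len, " is not divisible by 3")
  bad <- grepl("[^ACGTUMRWSYKVHDBN-]", sequences)
  if (any(bad))
    stop("format error: non-nucleotide characters in taxa: ",
         paste(names(sequences)[bad], collapse = ", "))
  structure(list(gene_id = gene_id, taxa = names(sequences),
                 sequences = sequences, n_codons = len %/% 3L),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment '%s': %d taxa x %d codons\n",
              x$gene_id, length(x$taxa), x$n_codons))
  invisible(x)
}

#' Read an in-frame codon alignment from FASTA
#'
#' @param path Path to a FASTA file of aligned CDS sequences.
#' @param gene_id Gene identifier; defaults to the file name without extension.
#' @return A [codon_alignment].
#' @export
read_codon_alignment <- function(path, gene_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (is.null(gene_id)) gene_id <- sub("\\.[^.]*$", "", basename(path))
  codon_alignment(seqs, gene_id = gene_id)
}

#' Write a codon alignment to FASTA
#'
#' @param aln A [codon_alignment].
#' @param path Output path.
#' @export
write_codon_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$sequences), path)
  invisible(path)
}

#' Phylogeny with foreground/background branch labels
#'
#' Wraps an `ape::phylo` tree with a per-edge label marking the branches on
#' which a separate dN/dS ratio is fitted (the "foreground", PAML's `#1`
#' convention); all other branches are background.
#'
#' @param phy An `ape::phylo` object (branch lengths in expected
#'   substitutions per codon; missing lengths are set to 0).
#' @param foreground Character vector of tip labels and/or internal node
#'   labels; the branch subtending each is labeled foreground.
#' @param edge_labels Optional explicit integer vector (0 = background,
#'   1 = foreground), one per row of `phy$edge`; overrides `foreground`.
#' @return An object of class `labeled_tree` with elements `phy` and
#'   `edge_labels`.
#' @export
labeled_tree <- function(phy, foreground = character(), edge_labels = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (anyDuplicated(phy$tip.label)) stop("tip names must be unique")
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0, nrow(phy$edge))
  if (any(phy$edge.length < 0)) stop("branch lengths must be nonnegative")
  if (is.null(edge_labels)) {
    edge_labels <- integer(nrow(phy$edge))
    for (tag in foreground) {
      node <- match(tag, phy$tip.label)
      if (is.na(node) && !is.null(phy$node.label)) {
        hit <- match(tag, phy$node.label)
        if (!is.na(hit)) node <- length(phy$tip.label) + hit
      }
      if (is.na(node))
        stop("lookup error: foreground tag '", tag, "' not found in tree")
      edge_labels[phy$edge[, 2] == node] <- 1L
    }
  }
  stopifnot(length(edge_labels) == nrow(phy$edge))
  if (all(edge_labels == 1L)) stop("at least one background branch required")
  structure(list(phy = phy, edge_labels = as.integer(edge_labels)),
            class = "labeled_tree")
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat(sprintf("labeled_tree: %d tips, %d foreground branch(es)\n",
              length(x$phy$tip.label), sum(x$edge_labels)))
  invisible(x)
}

#' Read a newick tree with optional PAML-style #1 foreground tags
#'
#' Accepts both the `#1` tag dialect (`Lasiurus #1`, `(A,B) #1`) and an
#' explicit list of tip/clade names to label as foreground.
#'
#' @param path Newick file.
#' @param foreground Character vector of tip or internal-node labels to mark
#'   foreground (in addition to any `#1` tags in the file).
#' @return A [labeled_tree].
#' @export
read_labeled_tree <- function(path, foreground = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  read_labeled_tree_text(txt, foreground)
}

read_labeled_tree_text <- function(txt, foreground = character()) {
  # fold PAML branch tags ("name #1", ") #1") into labels ape can carry
  txt <- gsub("[ \t]*#[ \t]*([0-9]+)", "@@\\1", txt)
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) stop("format error: unparseable newick")
  tagged <- integer(0)
  strip <- function(labs) sub("@@[0-9]+$", "", labs)
  is_tag <- function(labs) grepl("@@[1-9][0-9]*$", labs)
  ntip <- length(phy$tip.label)
  tagged <- which(is_tag(phy$tip.label))
  phy$tip.label <- strip(phy$tip.label)
  if (!is.null(phy$node.label)) {
    tagged <- c(tagged, ntip + which(is_tag(phy$node.label)))
    phy$node.label <- strip(phy$node.label)
  }
  edge_labels <- integer(nrow(phy$edge))
  edge_labels[phy$edge[, 2] %in% tagged] <- 1L
  lt <- labeled_tree(phy, edge_labels = edge_labels)
  if (length(foreground)) {
    extra <- labeled_tree(lt$phy, foreground = foreground)
    lt$edge_labels <- pmax(lt$edge_labels, extra$edge_labels)
  }
  lt
}

#' Write a labeled tree as newick with #1 foreground tags
#'
#' @param tree A [labeled_tree].
#' @param path Output path.
#' @export
write_labeled_tree <- function(tree, path) {
  stopifnot(inherits(tree, "labeled_tree"))
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  fg_nodes <- phy$edge[tree$edge_labels == 1L, 2]
  tip_fg <- fg_nodes[fg_nodes <= ntip]
  phy$tip.label[tip_fg] <- paste0(phy$tip.label[tip_fg], "@@1")
  node_fg <- fg_nodes[fg_nodes > ntip]
  if (length(node_fg)) {
    if (is.null(phy$node.label)) phy$node.label <- rep("", phy$Nnode)
    phy$node.label[node_fg - ntip] <- paste0(phy$node.label[node_fg - ntip], "@@1")
  }
  txt <- ape::write.tree(phy)
  txt <- gsub("@@([0-9]+)", " #\\1", txt)
  writeLines(txt, path)
  invisible(path)
}

#' Drop taxa from a labeled tree, preserving foreground labels
#'
#' @param tree A [labeled_tree].
#' @param taxa Tip labels to remove.
#' @return A [labeled_tree] on the remaining taxa. Foreground status is kept
#'   for surviving branches (a foreground tip that is dropped simply vanishes).
#' @export
prune_labeled_tree <- function(tree, taxa) {
  stopifnot(inherits(tree, "labeled_tree"))
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  # carry edge labels through drop.tip via temporary node/tip tagging
  fg_nodes <- phy$edge[tree$edge_labels == 1L, 2]
  tag <- "@@fg"
  phy$tip.label[fg_nodes[fg_nodes <= ntip]] <-
    paste0(phy$tip.label[fg_nodes[fg_nodes <= ntip]], tag)
  nl <- if (is.null(phy$node.label)) rep("", phy$Nnode) else phy$node.label
  nl[fg_nodes[fg_nodes > ntip] - ntip] <- paste0(nl[fg_nodes[fg_nodes > ntip] - ntip], tag)
  phy$node.label <- nl
  drop_labs <- phy$tip.label[sub("@@fg$", "", phy$tip.label) %in% taxa]
  phy2 <- ape::drop.tip(phy, drop_labs)
  if (is.null(phy2) || length(phy2$tip.label) < 2)
    stop("pruning would leave fewer than 2 taxa")
  ntip2 <- length(phy2$tip.label)
  tagged <- which(endsWith(phy2$tip.label, tag))
  phy2$tip.label <- sub("@@fg$", "", phy2$tip.label)
  if (!is.null(phy2$node.label)) {
    tagged <- c(tagged, ntip2 + which(endsWith(phy2$node.label, tag)))
    phy2$node.label <- sub("@@fg$", "", phy2$node.label)
  }
  el <- integer(nrow(phy2$edge))
  el[phy2$edge[, 2] %in% tagged] <- 1L
  labeled_tree(phy2, edge_labels = el)
}

#' Genome layout: ordered chromosomes and their lengths
#'
#' @param name Character vector of chromosome/scaffold names (unique).
#' @param length Integer-valued vector of lengths in bp (> 0).
#' @return A data frame of class `genome_layout`.
#' @export
genome_layout <- function(name, length) {
  if (anyDuplicated(name)) stop("chromosome names must be unique")
  if (any(length <= 0)) stop("chromosome lengths must be positive")
  structure(data.frame(name = as.character(name), length = as.numeric(length),
                       stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

#' Gene loci table
#'
#' Internal coordinates are 0-based half-open; `midpoint = floor((start+end)/2)`.
#'
#' @param symbol,chrom,start,end,strand Vectors describing one gene per element.
#' @return A data frame of class `gene_loci` with a `midpoint` column.
#' @export
gene_loci <- function(symbol, chrom, start, end, strand = "+") {
  if (any(start < 0) || any(end <= start))
    stop("require 0 <= start < end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  structure(data.frame(symbol = as.character(symbol), chrom = as.character(chrom),
                       start = as.numeric(start), end = as.numeric(end),
                       strand = rep_len(as.character(strand), length(symbol)),
                       midpoint = floor((as.numeric(start) + as.numeric(end)) / 2),
                       stringsAsFactors = FALSE),
            class = c("gene_loci", "data.frame"))
}

#' Read gene loci from a GFF3 file
#'
#' Extracts `gene` features, takes the symbol from the `Name` attribute
#' (falling back to `ID`), and converts GFF 1-based inclusive coordinates to
#' the internal 0-based half-open convention. Gene records with no usable
#' symbol are skipped with a warning.
#'
#' @param path GFF3 file.
#' @param feature_type Feature type to extract (default `"gene"`).
#' @return A [gene_loci] data frame (empty if the file holds no genes).
#' @export
read_gff_genes <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) GenomicRanges::GRanges())
  if (length(gr)) gr <- gr[S4Vectors::mcols(gr)$type %in% feature_type]
  if (!length(gr))
    return(gene_loci(character(0), character(0), numeric(0), numeric(0) + 1)[0, ])
  mc <- S4Vectors::mcols(gr)
  sym <- if ("Name" %in% names(mc)) as.character(mc$Name) else rep(NA_character_, length(gr))
  if ("ID" %in% names(mc)) {
    id <- as.character(mc$ID)
    sym[is.na(sym) | sym == ""] <- id[is.na(sym) | sym == ""]
  }
  drop <- is.na(sym) | sym == ""
  if (any(drop))
    warning(sum(drop), " gene record(s) without Name/ID attribute skipped")
  gr <- gr[!drop]; sym <- sym[!drop]
  gene_loci(symbol = sym,
            chrom = as.character(GenomicRanges::seqnames(gr)),
            start = GenomicRanges::start(gr) - 1,   # 1-based incl -> 0-based half-open
            end = GenomicRanges::end(gr),
            strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"))
}

#' Write gene loci to GFF3
#'
#' Converts internal 0-based half-open coordinates back to GFF 1-based
#' inclusive, so read/write round-trips restore the original file coordinates.
#'
#' @param genes A [gene_loci] data frame.
#' @param path Output path.
#' @param source Value for the GFF source column.
#' @export
write_gff_genes <- function(genes, path, source = "hotspotsel") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     genes$chrom, source, as.integer(genes$start) + 1L,
                     as.integer(genes$end), genes$strand, genes$symbol, genes$symbol))
  writeLines(lines, path)
  invisible(path)
}

#' Completeness filter for ortholog alignment sets
#'
#' A gene missing at most `max_missing` of the required taxa is kept, with the
#' missing taxa to be pruned from its guide tree; a gene missing more is
#' dropped from the analysis entirely.
#'
#' @param sets Named list of [codon_alignment] objects (one per gene).
#' @param required_taxa Character vector of taxa expected in every alignment.
#' @param max_missing Maximum number of required taxa a kept gene may lack
#'   (default 1).
#' @return A list with `kept` (the surviving alignments), `prune` (named list:
#'   per kept gene, the taxa to drop from its guide tree) and `report` (data
#'   frame of every prune/drop action).
#' @export
filter_ortholog_sets <- function(sets, required_taxa, max_missing = 1L) {
  stopifnot(max_missing >= 0)
  report <- list(); kept <- list(); prune <- list()
  for (g in names(sets)) {
    missing <- setdiff(required_taxa, sets[[g]]$taxa)
    if (length(missing) > max_missing) {
      report[[g]] <- data.frame(gene = g, taxon = missing, action = "dropped",
                                stringsAsFactors = FALSE)
    } else {
      kept[[g]] <- sets[[g]]
      prune[[g]] <- missing
      if (length(missing))
        report[[g]] <- data.frame(gene = g, taxon = missing, action = "pruned",
                                  stringsAsFactors = FALSE)
    }
  }
  report <- if (length(report)) do.call(rbind, c(report, make.row.names = FALSE))
            else data.frame(gene = character(0), taxon = character(0),
                            action = character(0), stringsAsFactors = FALSE)
  list(kept = kept, prune = prune, report = report)
}
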
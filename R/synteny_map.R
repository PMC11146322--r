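#' Synteny block definition
#'
#' A named, ordered list of landmark gene symbols in reference (human) order;
#' intervening non-landmark genes are ignored when instances are extracted.
#'
#' @param name Block name (e.g. `"NF"`, `"CE"`).
#' @param landmarks Ordered character vector of unique gene symbols.
#' @param reference_species Species whose gene order defines the reference.
#' @return List of class `block_def`.
#' @export
block_def <- function(name, landmarks, reference_species = "human") {
  if (anyDuplicated(landmarks)) stop("landmark symbols must be unique")
  structure(list(name = name, landmarks = as.character(landmarks),
                 reference_species = reference_species),
            class = "block_def")
}

#' Extract a synteny block instance from an annotation
#'
#' For each landmark records presence, coordinates, orientation sign (GFF
#' strand) and the within-species order index (rank by chromosome then start
#' among present landmarks). Unannotated landmarks are flagged absent.
#'
#' @param annotation A [gene_loci] data frame for one species.
#' @param def A [block_def].
#' @param species Species label stored on the instance.
#' @return Data frame of class `block_instance`: one row per landmark with
#'   `landmark`, `ref_index`, `present`, `chrom`, `start`, `end`, `strand`,
#'   `order_index`.
#' @export
extract_block <- function(annotation, def, species = "species") {
  stopifnot(inherits(def, "block_def"))
  n <- length(def$landmarks)
  hits <- lapply(def$landmarks, function(s) which(annotation$symbol == s))
  dup <- def$landmarks[vapply(hits, length, 1L) > 1]
  if (length(dup))
    stop("ambiguity error: duplicated symbol(s) in annotation: ",
         paste(dup, collapse = ", "))
  idx <- vapply(hits, function(h) if (length(h)) h else NA_integer_, 1L)
  out <- data.frame(
    landmark = def$landmarks, ref_index = seq_len(n), present = !is.na(idx),
    chrom = ifelse(is.na(idx), NA_character_, annotation$chrom[idx]),
    start = ifelse(is.na(idx), NA_real_, annotation$start[idx]),
    end = ifelse(is.na(idx), NA_real_, annotation$end[idx]),
    strand = ifelse(is.na(idx), NA_character_, annotation$strand[idx]),
    stringsAsFactors = FALSE)
  out$order_index <- NA_integer_
  pres <- which(out$present)
  if (length(pres))
    out$order_index[pres] <- order(order(out$chrom[pres], out$start[pres]))
  attr(out, "species") <- species
  attr(out, "block") <- def$name
  class(out) <- c("block_instance", "data.frame")
  out
}

present_extent <- function(x) {
  if (inherits(x, "block_instance")) x <- x[x$present, ]
  if (nrow(x) == 0) stop("no present landmarks")
  split(x[, c("chrom", "start", "end")], x$chrom)
}

#' Classify linkage between two blocks (or genes)
#'
#' `unlinked` when the two occupy disjoint sequence sets; otherwise the gap is
#' the edge-to-edge distance between the nearest landmark boundaries on a
#' shared sequence: `linked` when the gap is at most `gap_threshold`
#' (default 10 Mb), `same-group-distant` otherwise.
#'
#' @param a,b `block_instance` objects or [gene_loci] rows.
#' @param gap_threshold Gap threshold in bp.
#' @return List of class `linkage_call` with `category` and `gap` (NA when
#'   unlinked).
#' @export
classify_linkage <- function(a, b, gap_threshold = 10e6) {
  ea <- present_extent(a); eb <- present_extent(b)
  shared <- intersect(names(ea), names(eb))
  if (!length(shared))
    return(structure(list(category = "unlinked", gap = NA_real_),
                     class = "linkage_call"))
  gap <- Inf
  for (ch in shared) {
    sa <- ea[[ch]]; sb <- eb[[ch]]
    d <- max(0, max(min(sa$start), min(sb$start)) -
                min(max(sa$end), max(sb$end)))
    gap <- min(gap, d)
  }
  structure(list(category = if (gap <= gap_threshold) "linked"
                            else "same-group-distant", gap = gap),
            class = "linkage_call")
}

signed_adjacencies <- function(inst, shared) {
  x <- inst[inst$present & inst$landmark %in% shared, ]
  x <- x[order(x$chrom, x$start), ]
  sgn <- ifelse(x$strand == "-", -1L, 1L)
  adj <- character(0)
  if (nrow(x) >= 2) {
    for (k in seq_len(nrow(x) - 1)) {
      if (x$chrom[k] != x$chrom[k + 1]) next
      r1 <- c(x$landmark[k], sgn[k], x$landmark[k + 1], sgn[k + 1])
      r2 <- c(x$landmark[k + 1], -sgn[k + 1], x$landmark[k], -sgn[k])
      s1 <- paste(r1, collapse = "|"); s2 <- paste(r2, collapse = "|")
      adj <- c(adj, if (s1 <= s2) s1 else s2)  # reading-direction symmetric
    }
  }
  adj
}

#' Breakpoint distance between two block instances
#'
#' Number of signed gene adjacencies (consecutive shared-landmark pairs with
#' consistent relative orientation, read in either direction) present in `a`
#' but absent in `b`, computed on the restriction to landmarks present in
#' both. Zero iff the signed orders agree up to whole-group reversal.
#'
#' @param a,b `block_instance` objects sharing at least two present landmarks.
#' @return Integer distance.
#' @export
breakpoint_distance <- function(a, b) {
  shared <- intersect(a$landmark[a$present], b$landmark[b$present])
  if (length(shared) < 2) stop("instances share fewer than 2 present landmarks")
  aa <- signed_adjacencies(a, shared)
  bb <- signed_adjacencies(b, shared)
  sum(!(aa %in% bb))
}

#' Machine-readable comparison table of block instances
#'
#' One row per species x landmark: chromosome, start, orientation sign,
#' species order index, reference order index, presence — the tabular
#' analogue of the block ideograms.
#'
#' @param instances List of `block_instance` objects.
#' @param calls Optional list of `linkage_call` objects appended as an
#'   attribute.
#' @return Data frame (header-only when `instances` is empty).
#' @export
render_comparison_table <- function(instances, calls = NULL) {
  cols <- c("species", "block", "landmark", "ref_index", "present", "chrom",
            "start", "strand", "order_index")
  if (!length(instances)) {
    out <- data.frame(species = character(0), block = character(0),
                      landmark = character(0), ref_index = integer(0),
                      present = logical(0), chrom = character(0),
                      start = numeric(0), strand = character(0),
                      order_index = integer(0), stringsAsFactors = FALSE)
    return(out)
  }
  rows <- lapply(instances, function(x) {
    data.frame(species = attr(x, "species"), block = attr(x, "block"),
               landmark = x$landmark, ref_index = x$ref_index,
               present = x$present, chrom = x$chrom, start = x$start,
               strand = x$strand, order_index = x$order_index,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))[, cols]
  if (!is.null(calls)) attr(out, "linkage") <- calls
  out
}
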
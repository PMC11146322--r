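ref6 <- function() block_instance(paste0("L", 1:6), species = "ref", block = "NF")

test_that("block extraction: identity, absence, duplicates, record order", {
  inst <- ref6()
  expect_equal(inst$order_index, 1:6)
  expect_true(all(inst$present))

  ann <- gene_loci(paste0("L", c(1, 2, 4, 5, 6)), "chrA",
                   c(5, 1, 3, 2, 4) * 1e6, c(5, 1, 3, 2, 4) * 1e6 + 1e4)
  got <- extract_block(ann, block_def("NF", paste0("L", 1:6)), "sp")
  expect_false(got$present[3])
  expect_true(is.na(got$order_index[3]))
  expect_equal(got$order_index[got$landmark == "L2"], 1L)
  expect_equal(got$order_index[got$landmark == "L1"], 5L)

  # record order in the annotation must not matter
  got2 <- extract_block(ann[sample(nrow(ann)), ], block_def("NF", paste0("L", 1:6)), "sp")
  expect_equal(got2$order_index, got$order_index)

  dup <- rbind(ann, ann[1, ])
  expect_error(extract_block(dup, block_def("NF", paste0("L", 1:6))), "ambiguity")
})

test_that("linkage classification follows the 10-Mb gap rule", {
  a <- block_instance(c("A1", "A2"), chrom = "s1")
  # b starts 2 Mb after a's last landmark end
  mk_at <- function(start, chrom) {
    ann <- gene_loci(c("B1", "B2"), chrom, c(start, start + 1e6),
                     c(start, start + 1e6) + 1e4)
    extract_block(ann, block_def("B", c("B1", "B2")), "sp")
  }
  a_end <- max(a$end)
  lk <- classify_linkage(a, mk_at(a_end + 2e6, "s1"))
  expect_equal(lk$category, "linked")
  expect_equal(lk$gap, 2e6)
  far <- classify_linkage(a, mk_at(a_end + 12e6, "s1"))
  expect_equal(far$category, "same-group-distant")
  expect_equal(far$gap, 12e6)
  off <- classify_linkage(a, mk_at(0, "s2"))
  expect_equal(off$category, "unlinked")
  expect_true(is.na(off$gap))
  # boundary: exactly 10 Mb is linked
  expect_equal(classify_linkage(a, mk_at(a_end + 10e6, "s1"))$category, "linked")
})

test_that("breakpoint distance: identity, reversal, single inversion", {
  a <- ref6()
  expect_equal(breakpoint_distance(a, a), 0L)

  # full reversal: order and all signs flipped -> distance 0
  rev_ann <- gene_loci(paste0("L", 6:1), "chrX",
                       (0:5) * 1e6, (0:5) * 1e6 + 1e4, strand = "-")
  b <- extract_block(rev_ann, block_def("NF", paste0("L", 1:6)), "rev")
  expect_equal(breakpoint_distance(a, b), 0L)
  expect_equal(breakpoint_distance(b, a), 0L)

  inv <- simulate_rearrangements(a, list(list(type = "inversion", i = 3, j = 5)))
  expect_equal(inv$instance$order_index,
               c(1L, 2L, 5L, 4L, 3L, 6L))
  expect_equal(inv$instance$strand[3:5], rep("-", 3))
  expect_equal(breakpoint_distance(a, inv$instance), 2L)
  expect_equal(breakpoint_distance(inv$instance, a), 2L)

  short <- block_instance("L1")
  expect_error(breakpoint_distance(a, short), "fewer than 2")
})

test_that("breakpoint distance is a reversal-invariant metric on small cases", {
  insts <- enumerate_signed_instances(c("x", "y", "z"))
  set.seed(13)
  for (rep in 1:400) {
    k <- sample(length(insts), 3, replace = TRUE)
    dab <- breakpoint_distance(insts[[k[1]]], insts[[k[2]]])
    dba <- breakpoint_distance(insts[[k[2]]], insts[[k[1]]])
    dbc <- breakpoint_distance(insts[[k[2]]], insts[[k[3]]])
    dac <- breakpoint_distance(insts[[k[1]]], insts[[k[3]]])
    expect_identical(dab, dba)
    expect_lte(dac, dab + dbc)                      # triangle inequality
  }
})

test_that("inversion count bounds breakpoint distance on simulated histories", {
  a <- block_instance(paste0("G", 1:7))
  set.seed(4)
  for (rep in 1:20) {
    nops <- sample(1:3, 1)
    ops <- lapply(seq_len(nops), function(.) {
      ij <- sort(sample(7, 2))
      list(type = "inversion", i = ij[1], j = ij[2])
    })
    out <- simulate_rearrangements(a, ops)
    expect_lte(breakpoint_distance(a, out$instance), 2 * nops)
  }
})

test_that("rearrangement operations: identity, fission, deletion, transposition", {
  a <- ref6()
  ident <- simulate_rearrangements(a, list())
  expect_equal(breakpoint_distance(a, ident$instance), 0L)
  expect_equal(nrow(ident$log), 0L)

  fis <- simulate_rearrangements(a, list(list(type = "fission", i = 4)))
  inst <- fis$instance
  expect_equal(length(unique(inst$chrom[inst$present])), 2L)
  part1 <- inst[inst$landmark %in% paste0("L", 1:3), ]
  part2 <- inst[inst$landmark %in% paste0("L", 4:6), ]
  expect_equal(classify_linkage(part1, part2)$category, "unlinked")

  del <- simulate_rearrangements(a, list(list(type = "deletion", i = 2)))
  expect_false(del$instance$present[del$instance$landmark == "L2"])
  expect_equal(sum(del$instance$present), 5L)

  tp <- simulate_rearrangements(a, list(list(type = "transposition",
                                             i = 2, j = 3, k = 5)))
  expect_equal(tp$instance$order_index,
               c(1L, 4L, 5L, 2L, 3L, 6L))
  expect_error(simulate_rearrangements(a, list(list(type = "inversion", i = 0, j = 9))),
               "invalid index")
})

test_that("comparison table renders one row per species x landmark", {
  a <- ref6()
  b <- simulate_rearrangements(a, list(list(type = "inversion", i = 1, j = 2)))$instance
  tab <- render_comparison_table(list(a, b))
  expect_equal(nrow(tab), 12L)
  expect_setequal(unique(tab$species), c("ref", "ref_rearr"))
  expect_true(all(c("order_index", "ref_index", "strand", "present") %in% names(tab)))
  empty <- render_comparison_table(list())
  expect_equal(nrow(empty), 0L)
  expect_true("landmark" %in% names(empty))
})
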
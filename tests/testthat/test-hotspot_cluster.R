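test_that("window counting uses half-open midpoint containment", {
  genes <- gene_loci(c("a", "b"), "c1", c(1, 15), c(2, 16))  # midpoints 1, 15
  expect_equal(count_in_window(genes, c("a", "b"), "c1", 0, 12), 1L)
  expect_equal(count_in_window(genes, character(0), "c1", 0, 12), 0L)
  expect_equal(count_in_window(genes, c("a", "b"), "c1", 4, 12), 1L)
  # midpoint exactly at start + window_len is excluded
  expect_equal(count_in_window(genes, "b", "c1", 3, 12), 0L)
  expect_equal(count_in_window(genes, "b", "c1", 3.5, 12), 1L)
})

test_that("cumulative curves: validation, monotonicity, identity case", {
  genes <- toy_genes()
  layout <- toy_layout()
  expect_error(cumulative_curves(genes, character(0), layout), "empty candidate")
  expect_error(cumulative_curves(genes, c("g1", "zz"), layout), "zz")

  cc <- cumulative_curves(genes, genes$symbol, layout, window_len = 100)
  expect_equal(cc$cum_total, cc$cum_candidate)
  expect_equal(cc$cum_total[nrow(cc)], 1)
  expect_true(all(diff(cc$cum_total) >= 0))

  cc2 <- cumulative_curves(genes, c("g4", "g5"), layout, window_len = 100)
  expect_true(all(diff(cc2$cum_candidate) >= 0))
  expect_equal(cc2$cum_candidate[nrow(cc2)], 1)
})

test_that("planted cluster shows its excess inside the planted region", {
  sim <- simulate_genome_annotation(
    layout = genome_layout(paste0("c", 1:3), c(60e6, 60e6, 60e6)),
    n_genes = 400, n_candidates = 10,
    cluster = list(chrom = "c2", start = 20e6, width = 12e6, n_inside = 10),
    seed = 11)
  cc <- cumulative_curves(sim$genes, sim$candidates, sim$layout)
  gap <- cc$cum_candidate - cc$cum_total
  peak <- which.max(gap)
  expect_equal(cc$chrom[peak], "c2")
  expect_gte(cc$window_start[peak], 20e6)
  expect_lte(cc$window_start[peak], 32e6)
})

test_that("permutation null matches the exhaustive start-enumeration oracle", {
  genes <- gene_loci(c("a", "b"), "c1", c(1, 15), c(2, 16))  # midpoints 1, 15
  layout <- genome_layout("c1", 20)
  exact <- oracle_window_null(c(1, 15), 20, 12)
  expect_equal(unname(exact[["0"]]), 2 / 9)
  expect_equal(unname(exact[["1"]]), 7 / 9)
  null <- permutation_null(genes, c("a", "b"), layout, window_len = 12,
                           n_iter = 10000, seed = 3)
  emp <- tabulate(null$counts + 1L, 3L) / null$n_iter
  mc <- 4 * sqrt(0.25 / null$n_iter)
  expect_lt(abs(emp[1] - 2 / 9), mc)
  expect_lt(abs(emp[2] - 7 / 9), mc)
  expect_equal(emp[3], 0)
})

test_that("null is reproducible by seed and invariant in law to layout order", {
  sim <- simulate_genome_annotation(
    layout = genome_layout(paste0("c", 1:4), rep(40e6, 4)),
    n_genes = 300, n_candidates = 8,
    cluster = list(chrom = "c1", start = 0, width = 12e6, n_inside = 4),
    seed = 5)
  n1 <- permutation_null(sim$genes, sim$candidates, sim$layout,
                         n_iter = 400, seed = 9)
  n2 <- permutation_null(sim$genes, sim$candidates, sim$layout,
                         n_iter = 400, seed = 9)
  expect_identical(n1$counts, n2$counts)

  shuffled <- sim$layout[c(3, 1, 4, 2), ]
  n3 <- permutation_null(sim$genes, sim$candidates,
                         genome_layout(shuffled$name, shuffled$length),
                         n_iter = 2000, seed = 10)
  n4 <- permutation_null(sim$genes, sim$candidates, sim$layout,
                         n_iter = 2000, seed = 11)
  ks <- suppressWarnings(stats::ks.test(n3$counts, n4$counts))
  expect_gt(ks$p.value, 0.001)

  # empty candidate set: every draw counts zero
  n0 <- permutation_null(sim$genes, character(0), sim$layout,
                         n_iter = 50, seed = 1)
  expect_true(all(n0$counts == 0))
})

test_that("tiling windows conserve the total candidate count", {
  genes <- toy_genes()
  layout <- toy_layout()
  cand <- c("g1", "g3", "g5")
  wlen <- 100
  total <- 0
  for (k in seq_len(nrow(layout)))
    for (s in seq(0, layout$length[k] - 1, by = wlen))
      total <- total + count_in_window(genes, cand, layout$name[k], s, wlen)
  expect_equal(total, length(cand))
})

test_that("empirical p-value follows the add-one convention", {
  mk <- function(counts, obs) structure(
    list(counts = counts, n_iter = length(counts), window_len = 12,
         seed = 1, observed = obs), class = "window_count_null")
  expect_equal(empirical_pvalue(mk(rep(0, 1000), 5)), 1 / 1001)
  expect_equal(empirical_pvalue(mk(c(3, 1, 2), 0)), 1)
  expect_equal(empirical_pvalue(mk(c(0, 0, 5), 5)), 0.5)
  expect_error(permutation_null(toy_genes(), "g1", toy_layout(),
                                window_len = 1e9), "exceeds")
})

test_that("max_window_count finds the densest window", {
  genes <- gene_loci(paste0("g", 1:5), "c1",
                     c(0, 10, 1e6, 1.2e6, 1.4e6), c(2, 12, 1e6 + 2, 1.2e6 + 2, 1.4e6 + 2))
  layout <- genome_layout("c1", 2e6)
  res <- max_window_count(genes, genes$symbol, layout, window_len = 5e5)
  expect_equal(res$count, 3L)
})
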
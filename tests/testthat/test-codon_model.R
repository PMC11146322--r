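space <- codon_state_space()

test_that("F3x4 frequencies: uniformity, normalization, degenerate input", {
  # every nucleotide equally frequent at every position -> uniform pi
  all64 <- paste(names(Biostrings::GENETIC_CODE), collapse = "")
  aln <- codon_alignment(c(A = all64, B = all64), "uniform")
  fr <- f3x4_frequencies(aln)
  expect_equal(unname(fr$pi), rep(1 / 61, 61), tolerance = 1e-12)

  set.seed(1)
  rnd <- simulate_codon_alignment(quartet_tree(), 500, seed = 3)
  expect_equal(sum(f3x4_frequencies(rnd)$pi), 1, tolerance = 1e-12)
  expect_equal(sum(f3x4_frequencies(rnd, "f1x4")$pi), 1, tolerance = 1e-12)
  expect_equal(sum(f3x4_frequencies(rnd, "empirical")$pi), 1, tolerance = 1e-12)

  # all-AAA alignment: frequencies collapse onto the K codon
  aaa <- codon_alignment(c(A = "AAAAAA", B = "AAAAAA"), "aaa")
  fr2 <- f3x4_frequencies(aaa)
  expect_gt(fr2$pi[["AAA"]], 0.99)
  expect_true(all(fr2$pi > 0))
})

test_that("rate matrix obeys single-step structure, conservation and scaling", {
  fr <- uniform_codon_frequencies()
  params <- codon_model_params(1, 1, 1, fr)
  Q <- build_rate_matrix(params)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_equal(Q["AAA", "GGA"], 0)          # two differences
  expect_false("TAA" %in% colnames(Q))      # stops excluded from the state space
  # omega=1, kappa=1, uniform pi: detailed balance reduces to symmetry
  expect_lt(max(abs(Q - t(Q))), 1e-12)

  set.seed(7)
  for (k in 1:5) {
    aln <- simulate_codon_alignment(quartet_tree(), 300, seed = k)
    p <- codon_model_params(runif(1, 0.5, 8), runif(1, 0.01, 3),
                            runif(1, 0.01, 3), f3x4_frequencies(aln))
    for (cls in c("background", "foreground")) {
      Qk <- build_rate_matrix(p, cls)
      expect_lt(max(abs(rowSums(Qk))), 1e-10)
      expect_equal(-sum(p$freqs$pi * diag(Qk)), 1, tolerance = 1e-10)
    }
  }
})

test_that("transition matrix: identity at t=0, stochastic, ergodic limit", {
  aln <- simulate_codon_alignment(quartet_tree(), 200, seed = 5)
  fr <- f3x4_frequencies(aln)
  params <- codon_model_params(2.5, 0.4, 0.4, fr)
  Q <- build_rate_matrix(params)
  expect_equal(transition_matrix(Q, 0, fr$pi), diag(61), tolerance = 1e-10,
               ignore_attr = TRUE)
  P <- transition_matrix(Q, 0.1, fr$pi)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  expect_true(all(P >= 0))
  Pinf <- transition_matrix(Q, 100, fr$pi)
  expect_lt(max(abs(sweep(Pinf, 2, fr$pi))), 1e-6)
})

test_that("pruning equals exhaustive enumeration on 4-taxon toys", {
  tr <- quartet_tree("A")
  for (seed in 1:3) {
    aln <- simulate_codon_alignment(tr, 5, kappa = 2.5, omega_background = 0.3,
                                    omega_foreground = 1.5, seed = seed)
    params <- codon_model_params(1.7, 0.35, 1.4, f3x4_frequencies(aln))
    expect_equal(log_likelihood(aln, tr, params),
                 oracle_loglik(aln, tr, params), tolerance = 1e-10)
  }
  # gapped codons are marginalized as missing data
  aln <- simulate_codon_alignment(tr, 5, seed = 9)
  s <- aln$sequences
  substr(s[["A"]], 1, 3) <- "---"
  substr(s[["C"]], 7, 9) <- "NNN"
  galn <- codon_alignment(s, "gapped")
  params <- codon_model_params(2, 0.5, 0.5, f3x4_frequencies(aln))
  expect_equal(log_likelihood(galn, tr, params),
               oracle_loglik(galn, tr, params), tolerance = 1e-10)
})

test_that("zero-distance limit gives ln pi of the observed codon", {
  phy <- ape::read.tree(text = "(A:0,B:0);")
  lt <- labeled_tree(phy)
  aln <- codon_alignment(c(A = "ATG", B = "ATG"), "one")
  fr <- uniform_codon_frequencies()
  params <- codon_model_params(2, 0.4, 0.4, fr)
  expect_equal(log_likelihood(aln, lt, params), log(1 / 61), tolerance = 1e-9)
})

test_that("sites are i.i.d.: doubling columns doubles the log-likelihood", {
  tr <- quartet_tree()
  aln <- simulate_codon_alignment(tr, 20, seed = 2)
  params <- codon_model_params(2, 0.4, 0.4, f3x4_frequencies(aln))
  doubled <- codon_alignment(
    stats::setNames(paste0(aln$sequences, aln$sequences), aln$taxa), "x2")
  expect_equal(log_likelihood(doubled, tr, params),
               2 * log_likelihood(aln, tr, params), tolerance = 1e-8)
})

test_that("likelihood is invariant to taxon order in the alignment", {
  tr <- quartet_tree()
  aln <- simulate_codon_alignment(tr, 50, seed = 4)
  params <- codon_model_params(2, 0.4, 0.4, f3x4_frequencies(aln))
  shuf <- codon_alignment(aln$sequences[c("D", "B", "A", "C")], "shuf")
  expect_equal(log_likelihood(shuf, tr, params),
               log_likelihood(aln, tr, params), tolerance = 1e-10)
})

test_that("degenerate labeling: all-foreground tree equals one-ratio at omega_fg", {
  # background confined to one zero-length branch: the branch-model
  # likelihood at (omega_fg = w) equals the one-ratio likelihood at w
  phy <- ape::read.tree(text = "((A:0.1,B:0.2):0.0,C:0.15,D:0.3);")
  el <- integer(nrow(phy$edge))
  zero_edge <- which(phy$edge.length == 0)[1]
  el[-zero_edge] <- 1L
  lt <- labeled_tree(phy, edge_labels = el)
  aln <- simulate_codon_alignment(lt, 40, seed = 6)
  fr <- f3x4_frequencies(aln)
  two <- codon_model_params(2, 0.1, 0.9, fr)   # bg omega is unidentifiable here
  one <- codon_model_params(2, 0.9, 0.9, fr)
  lt_all_bg <- labeled_tree(phy)
  expect_equal(log_likelihood(aln, lt, two),
               log_likelihood(aln, lt_all_bg, one), tolerance = 1e-9)
})

test_that("ML fitting: fixed point, nesting, stop-codon handling", {
  tr <- default_sim_tree()
  aln <- simulate_codon_alignment(tr, 300, kappa = 2, omega_background = 0.3,
                                  seed = 21)
  f0 <- fit_one_ratio(aln, tr)
  expect_true(f0$converged)
  expect_equal(f0$n_free_params, 2 + length(tr$phy$edge.length))
  # refit from the returned optimum: lnL unchanged within tolerance
  refit <- log_likelihood(aln, f0$tree, f0$params)
  expect_equal(refit, f0$lnL, tolerance = 1e-6)
  f1 <- fit_branch_model(aln, tr)
  expect_equal(f1$n_free_params, f0$n_free_params + 1)
  expect_gte(f1$lnL, f0$lnL - 1e-4)          # nesting
  # plausible recovery at modest length
  expect_gt(f0$params$omega_background, 0.15)
  expect_lt(f0$params$omega_background, 0.55)

  s <- aln$sequences
  substr(s[["t1"]], 1, 3) <- "TAA"            # stop codon becomes missing
  expect_warning(hotspotsel:::encode_alignment(codon_alignment(s, "stp")),
                 "stop codon")
})

test_that("strict gap policy drops incomplete columns globally", {
  tr <- quartet_tree()
  aln <- simulate_codon_alignment(tr, 10, seed = 8)
  s <- aln$sequences
  substr(s[["B"]], 4, 6) <- "---"
  ga <- codon_alignment(s, "g")
  st <- hotspotsel:::encode_alignment(ga, "strip")
  expect_equal(ncol(st), 9L)
  expect_false(anyNA(st))
})
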
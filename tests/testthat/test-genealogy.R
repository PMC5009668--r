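# Coalescent trees: simulation moments, Newick I/O, site and repeat
# evolution on trees, haplotype shuffling.

test_that("simulated trees satisfy the structural invariants", {
  set.seed(301)
  for (n in c(2L, 5L, 24L)) {
    tr <- simulate_coalescent_tree(n)
    expect_silent(validate_coalescent_tree(tr))
    expect_equal(tr$n_leaf, n)
    expect_equal(sum(!is.na(tr$parent)), 2L * n - 2L)
  }
  tr2 <- simulate_coalescent_tree(2)
  expect_equal(max(tr2$time), tr2$time[3])  # single coalescence defines depth
})

test_that("TMRCA moments match the Kingman closed forms", {
  set.seed(302)
  t2 <- replicate(1e4, max(simulate_coalescent_tree(2)$time))
  expect_lt(abs(mean(t2) / 2 - 1), 0.05)             # pair: mean 2 Ne-units
  t10 <- replicate(1e4, max(simulate_coalescent_tree(10)$time))
  expect_lt(abs(mean(t10) / 3.6 - 1), 0.05)          # 4 (1 - 1/10)
})

test_that("newick round-trips and validates", {
  txt <- "((1_1:1.0,1_2:1.0):0.5,(2_1:0.8,2_2:0.8):0.7);"
  tr <- read_newick(txt)
  expect_equal(tr$n_leaf, 4L)
  expect_equal(max(tr$time), 1.5)
  expect_setequal(tr$labels, c("1_1", "1_2", "2_1", "2_2"))
  set.seed(303)
  sim <- simulate_coalescent_tree(8)
  rt <- read_newick(write_newick(sim))
  expect_setequal(rt$labels, sim$labels)
  expect_equal(sort(rt$time), sort(sim$time), tolerance = 1e-9)
  # same topology: identical leaf-pair coalescence times
  d1 <- ape::cophenetic.phylo(as_phylo(sim))
  d2 <- ape::cophenetic.phylo(as_phylo(rt))
  expect_equal(d1[sim$labels, sim$labels], d2[sim$labels, sim$labels],
               tolerance = 1e-9)
})

test_that("malformed or non-ultrametric newick is rejected", {
  expect_error(read_newick("(A:1.0,B:2.0);"), "not ultrametric")
  expect_error(read_newick("((A:1,B:1):1,C:2,D:2);"), "not strictly binary")
  expect_error(suppressWarnings(read_newick("((A:1,B:1")), "malformed|parse")
  expect_error(read_newick("((A,B),C);"), "branch length")
})

test_that("tree ensembles round-trip through one-newick-per-line files", {
  set.seed(304)
  trees <- replicate(3, simulate_coalescent_tree(6), simplify = FALSE)
  path <- tempfile(fileext = ".nwk")
  write_tree_ensemble(trees, path)
  back <- read_tree_ensemble(path)
  expect_length(back, 3L)
  expect_equal(max(back[[2]]$time), max(trees[[2]]$time), tolerance = 1e-9)
})

test_that("site mutation honors zero rates and branch structure", {
  set.seed(305)
  tr <- simulate_coalescent_tree(6)
  pan0 <- mutate_sites_on_tree(tr, 1:50, 0, 0)
  expect_true(all(pan0$alleles == 0L))
  expect_equal(ncol(pan0$alleles), 50L)              # monomorphic retained
  expect_equal(nrow(pan0$alleles), 6L)
})

test_that("pairwise divergence matches 4 Ne mu for a sample of two", {
  set.seed(306)
  params <- mutation_params(1e-3, 10400)
  rate <- 6.7e-8
  diff_frac <- replicate(250, {
    tr <- simulate_coalescent_tree(2, labels = c("a_1", "a_2"))
    pan <- mutate_sites_on_tree(tr, seq_len(1e4), rate, 0, params)
    mean(pan$alleles[1, ] != pan$alleles[2, ])
  })
  expect_lt(abs(mean(diff_frac) / (4 * 10400 * rate) - 1), 0.1)
})

test_that("repeat evolution down a tree has the stepwise variance", {
  params <- mutation_params(1e-3, 10400)
  set.seed(307)
  # fixed pair tree, both branches t = 1.0 Ne-units
  tr <- simulate_coalescent_tree(2, labels = c("a_1", "a_2"))
  tr$time[3] <- 1.0
  devs <- replicate(1e4, {
    r <- simulate_repeat_numbers(tr, 25, params)
    r[1] - 25
  })
  expect_lt(abs(stats::var(devs) / 10.4 - 1), 0.1)   # Ne mu t = 10.4
  expect_lt(abs(mean(devs)), 0.12)
  # mu = 0 keeps everything at the root value
  r0 <- simulate_repeat_numbers(tr, 25, mutation_params(0, 10400))
  expect_true(all(r0 == 25L))
})

test_that("sibling leaf deviations are conditionally independent", {
  params <- mutation_params(1e-3, 10400)
  set.seed(308)
  tr <- simulate_coalescent_tree(2, labels = c("a_1", "a_2"))
  tr$time[3] <- 0.5
  reps <- replicate(4000, {
    r <- simulate_repeat_numbers(tr, 25, params)
    c(r[1], r[2])
  })
  cc <- stats::cor(reps[1, ], reps[2, ])             # deviations share no branch
  expect_lt(abs(cc), 0.05)
})

test_that("haplotype shuffling permutes rows and preserves content", {
  set.seed(309)
  tr <- simulate_coalescent_tree(8)
  pan <- mutate_sites_on_tree(tr, 1:40, 5e-5, 1e-5)
  shuf <- shuffle_haplotypes(pan)
  expect_identical(rownames(shuf$alleles), rownames(pan$alleles))
  key <- function(m) sort(unname(apply(m, 1, paste, collapse = "")))
  expect_identical(key(shuf$alleles), key(pan$alleles))
  expect_equal(colSums(shuf$alleles), colSums(pan$alleles),
               ignore_attr = TRUE)
})

test_that("panels round-trip through phased VCF", {
  set.seed(310)
  tr <- simulate_coalescent_tree(6)
  pan <- mutate_sites_on_tree(tr, seq(1000, 1490, by = 10), 5e-5, 1e-5)
  path <- tempfile(fileext = ".vcf")
  write_panel_vcf(pan, path)
  back <- read_panel_vcf(path)
  expect_equal(back$positions, pan$positions)
  expect_equal(unname(back$alleles[rownames(pan$alleles), ]),
               unname(pan$alleles))
})
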
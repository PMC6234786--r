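# Regional divergence statistics: assignment, binning, accumulation,
# exponential fits, lineage density, synchrony.

test_that("single-region data assign every node, nothing excluded", {
  tr <- small_fixture()$trees[[1]]
  rg <- region_table(tr$tip.label, rep("B", ape::Ntip(tr)))
  asg <- assign_node_regions(tr, rg)
  a <- asg$assignments[[1]]
  expect_true(all(a$region == "B"))
  expect_equal(nrow(a), ape::Ntip(tr) - 1L)
})

test_that("widespread or tied nodes are excluded; counts are conserved", {
  fx <- small_fixture()
  asg <- assign_node_regions(fx$trees, fx$regions)
  n_excl_tips <- sum(fx$regions$multi)
  expect_equal(length(asg$excluded_tips), n_excl_tips)
  ntip <- ape::Ntip(asg$trees[[1]])
  expect_equal(ntip, ape::Ntip(fx$trees[[1]]) - n_excl_tips)
  for (a in asg$assignments) {
    expect_equal(nrow(a), ntip - 1L)     # every internal node accounted for
    expect_true(all(is.na(a$region) | nchar(a$region) == 1L))
  }
  # the alternative tip-descendant route agrees on the easy nodes
  asg2 <- assign_node_regions(fx$trees[[1]], fx$regions,
                              method = "tip_descendant")
  expect_equal(nrow(asg2$assignments[[1]]), ntip - 1L)
})

test_that("assignments recover most true node regions on simulated histories", {
  set.seed(4)
  hits <- n_tot <- 0
  for (i in 1:10) {
    sim <- simulate_bd_tree(40, 0.12, 0, rho = 1, seed = sample.int(1e6, 1))
    rr <- simulate_ranges(sim$tree, 0.004, 0.002, seed = sample.int(1e6, 1))
    asg <- assign_node_regions(sim$tree, rr$regions)
    tr <- asg$trees[[1]]
    a <- asg$assignments[[1]]
    keys_full <- drydiv:::clade_keys(sim$tree)
    truth_int <- rr$truth$node_range[(ape::Ntip(sim$tree) + 1L):
                                       length(rr$truth$node_range)]
    keys_sub <- drydiv:::clade_keys(tr)
    pos <- match(keys_sub, keys_full)     # pruning may drop/rename clades
    ok <- !is.na(a$region) & !is.na(pos)
    hits <- hits + sum(a$region[ok] == truth_int[pos[ok]])
    n_tot <- n_tot + sum(ok)
  }
  expect_gte(hits / n_tot, 0.8)
})

test_that("divergence series is conservative and partition-exact", {
  fx <- small_fixture()
  asg <- assign_node_regions(fx$trees, fx$regions)
  ser <- divergence_series(asg, bin_width = 5)
  raw <- attr(ser, "raw")
  ntip <- ape::Ntip(asg$trees[[1]])
  per_tree <- apply(raw, 1, sum)
  expect_true(all(per_tree == ntip - 1L))          # regions+excluded = n-1
  expect_true(all(ser$q25 <= ser$median & ser$median <= ser$q75))
  expect_true(all(ser$min <= ser$q25 & ser$q75 <= ser$max))
  # random age sets: binning never double-counts or drops
  set.seed(5)
  for (i in 1:20) {
    ages <- runif(50, 0, 61)
    bins <- floor(ages / 5)
    expect_equal(sum(table(bins)), 50L)
  }
  # single tree: IQR and span collapse to the observed counts
  asg1 <- assign_node_regions(fx$trees[[1]], fx$regions)
  s1 <- divergence_series(asg1)
  expect_true(all(s1$min == s1$max & s1$median == s1$min))
  # zero age noise: spans are zero-width across the sample
  tr <- asg$trees[[1]]
  ts0 <- pseudo_posterior(tr, 6, age_cv = 0, seed = 1)
  asg0 <- assign_node_regions(ts0, fx$regions)
  s0 <- divergence_series(asg0)
  expect_true(all(s0$min == s0$max))
})

test_that("cumulative accumulation counts up to each region's node total", {
  fx <- small_fixture()
  asg <- assign_node_regions(fx$trees[[1]], fx$regions)
  cum <- cumulative_accumulation(asg)
  a <- asg$assignments[[1]]
  for (r in unique(stats::na.omit(a$region))) {
    d <- cum[cum$region == r, ]
    expect_equal(max(d$cumulative), sum(a$region == r & !is.na(a$region)))
    expect_true(all(diff(d$cumulative) >= 0))
    expect_true(all(diff(d$age) <= 0))             # toward the present
  }
  g <- cum[cum$region == "all", ]
  expect_equal(max(g$cumulative), nrow(a))         # n - 1 at the present
})

test_that("exponential fits are exact on log-linear data and flag sparse input", {
  tau <- seq(0, 40, length.out = 20)
  cum <- data.frame(region = "all", age = 40 - tau,
                    cumulative = 2 * exp(0.1 * tau))
  attr(cum, "crown_age") <- 40
  f <- fit_exponential(cum)
  expect_equal(f$b, 0.1, tolerance = 1e-6)
  expect_equal(f$a, 2, tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)
  cum2 <- data.frame(region = "all", age = 40 - tau, cumulative = 7)
  attr(cum2, "crown_age") <- 40
  expect_equal(fit_exponential(cum2)$b, 0, tolerance = 1e-12)
  sparse <- data.frame(region = c("A", "A"), age = c(10, 5),
                       cumulative = c(1, 2))
  attr(sparse, "crown_age") <- 10
  expect_false(fit_exponential(sparse)$ok)
  degen <- data.frame(region = "A", age = c(5, 5), cumulative = c(1, 2))
  expect_error(fit_exponential(degen), class = "drydiv_degenerate_fit")
})

test_that("pure-birth cumulative curves recover the growth rate", {
  set.seed(6)
  bs <- replicate(40, {
    sim <- simulate_bd_tree(30, 0.1, rho = 1, seed = sample.int(1e6, 1))
    rg <- region_table(sim$tree$tip.label, rep("A", ape::Ntip(sim$tree)))
    cum <- cumulative_accumulation(assign_node_regions(sim$tree, rg))
    f <- fit_exponential(cum)
    f$b[f$region == "all"]
  })
  expect_lt(abs(stats::median(bs) / 0.1 - 1), 0.15)
})

test_that("lineage density matches the brute-force recount and its reductions", {
  fx <- small_fixture()
  asg <- assign_node_regions(fx$trees[[1]], fx$regions)
  ld <- lineage_density(asg)
  expect_true(all(ld$density >= 1))                # own lineage always counts
  brute <- oracle_lineage_density(asg$trees[[1]], asg$assignments[[1]],
                                  asg$regions)
  expect_equal(ld$density, brute)
  # single-region tree: density equals the lineage count just before t
  tr <- fx$trees[[2]]
  rg1 <- region_table(tr$tip.label, rep("A", ape::Ntip(tr)))
  asg1 <- assign_node_regions(tr, rg1)
  ld1 <- lineage_density(asg1)
  bt <- extract_branching_times(tr)
  expect_equal(ld1$density,
               vapply(ld1$age, function(t) 1 + sum(bt > t + 1e-9), numeric(1)))
  # a region's first divergence has density 1
  first_b <- ld1[which.max(ld1$age), ]
  expect_equal(first_b$density, 1)
})

test_that("synchrony table does exact interval arithmetic", {
  ca <- data.frame(clade = c("x", "y", "z"), mean = c(15, 3, 12.5),
                   lo = c(12, 1, 11), hi = c(20, 5, 14))
  sy <- synchrony_table(ca, window = c(15, 10))
  expect_equal(sy$overlap, c(3, 0, 3))
  expect_equal(sy$overlaps, c(TRUE, FALSE, TRUE))
  expect_equal(attr(sy, "fraction_overlapping"), 2 / 3)
  bad <- data.frame(clade = "w", mean = 10, lo = 12, hi = 14)
  expect_error(synchrony_table(bad), class = "drydiv_bad_interval")
})
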
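# DIVA dynamic program, S-DIVA averaging, dispersal extraction.

test_that("uniform tips reconstruct trivially", {
  f <- diva_reconstruct(balanced4(), regions4(rep("A", 4)))
  expect_equal(f$min_cost, 0)
  expect_equal(f$total_mprs, 1)
  expect_equal(f$root_states, "A")
  ids <- 5:7
  expect_true(all(f$marginal[ids, "A"] == 1))
})

test_that("the 4-tip one-dispersal case has cost 1 and root set {A, AB}", {
  # a={A}, b={B}, c={A}, d={A}: verified against exhaustive enumeration
  f <- diva_reconstruct(balanced4(), regions4(c("A", "B", "A", "A")))
  orc <- oracle_diva(balanced4(), c(1L, 2L, 1L, 1L), 2L)
  expect_equal(f$min_cost, 1)
  expect_equal(orc$min_cost, 1)
  expect_setequal(f$root_states, c("A", "AB"))
  expect_equal(sort(orc$root_masks), c(1L, 3L))
  expect_equal(f$total_mprs, 2)
  expect_true("A" %in% f$root_states)
})

test_that("DP equals the brute-force oracle on random trees", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(4:6, 1)
    tr <- random_test_tree(n)
    nA <- sample(2:3, 1)
    masks <- sample(seq_len(2^nA - 1L), n, replace = TRUE)
    alph <- LETTERS[1:nA]
    rg <- region_table(tr$tip.label, drydiv:::mask_to_label(masks, alph), alph)
    fit <- diva_reconstruct(tr, rg)
    orc <- oracle_diva(tr, masks, nA)
    expect_equal(fit$min_cost, orc$min_cost)
    dp_masks <- sort(fit$states$masks[match(fit$root_states,
                                            fit$state_labels)])
    expect_equal(as.integer(dp_masks), as.integer(orc$root_masks))
  }
})

test_that("marginal MPR proportions are a distribution at every node", {
  fx <- small_fixture()
  tr <- fx$trees[[1]]
  fit <- diva_reconstruct(tr, fx$regions)
  ids <- (ape::Ntip(tr) + 1L):(ape::Ntip(tr) + tr$Nnode)
  expect_equal(rowSums(fit$marginal[ids, ]), rep(1, length(ids)),
               tolerance = 1e-9)
})

test_that("dispersal cost monotonicity and area-permutation symmetry", {
  set.seed(23)
  perm <- c(2L, 3L, 1L)            # A->B, B->C, C->A
  for (i in 1:20) {
    tr <- random_test_tree(5)
    masks <- sample(1:7, 5, replace = TRUE)
    rg <- region_table(tr$tip.label, drydiv:::mask_to_label(masks, LETTERS[1:3]),
                       LETTERS[1:3])
    f1 <- diva_reconstruct(tr, rg)
    f2 <- diva_reconstruct(tr, rg, diva_cost_model(dispersal = 2))
    expect_gte(f2$min_cost + 1e-12, f1$min_cost)
    # permute areas: costs identical, marginals permuted
    pmask <- vapply(masks, function(m) {
      bits <- which(bitwAnd(m, bitwShiftL(1L, 0:2)) > 0L)
      Reduce(bitwOr, bitwShiftL(1L, perm[bits] - 1L))
    }, integer(1))
    rgp <- region_table(tr$tip.label,
                        drydiv:::mask_to_label(pmask, LETTERS[1:3]),
                        LETTERS[1:3])
    fp <- diva_reconstruct(tr, rgp)
    expect_equal(fp$min_cost, f1$min_cost)
    expect_equal(fp$total_mprs, f1$total_mprs)
    # the permuted root-state set matches
    permute_label <- function(lab) {
      vapply(lab, function(s) {
        paste(sort(LETTERS[1:3][perm[match(strsplit(s, "")[[1]],
                                           LETTERS[1:3])]]), collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    expect_setequal(fp$root_states, permute_label(f1$root_states))
  }
})

test_that("S-DIVA over copies of one tree reduces to its MPR proportions", {
  fx <- small_fixture()
  tr <- fx$trees[[1]]
  fit <- diva_reconstruct(tr, fx$regions)
  ts <- tree_sample(rep(list(tr), 10), representative = tr, validate = FALSE)
  s <- sdiva(ts, fx$regions)
  ids <- (ape::Ntip(tr) + 1L):(ape::Ntip(tr) + tr$Nnode)
  expect_equal(unname(s$prob), unname(fit$marginal[ids, ]), tolerance = 1e-12)
  expect_true(all(s$coverage == 1))
  expect_equal(rowSums(s$prob), rep(1, nrow(s$prob)), tolerance = 1e-9)
  expect_error(sdiva(structure(list(), class = "multiPhylo"), fx$regions,
                     tr), class = "drydiv_empty_sample")
})

test_that("dispersal extraction follows the inheritance-aware definition", {
  tr <- ape::read.tree(text = "((a:20,b:20):10,c:30);")
  rg <- region_table(c("a", "b", "c"), c("D", "D", "A"))
  st <- drydiv:::.diva_states(4L, diva_cost_model())
  labels <- drydiv:::mask_to_label(st$masks, c("A", "B", "C", "D"))
  prob <- matrix(0, 2, length(labels), dimnames = list(NULL, labels))
  prob[1, "A"] <- 1      # root resolved to {A}
  prob[2, "D"] <- 1      # (a,b) ancestor resolved to {D}
  nrf <- structure(list(tree = tr, prob = prob, coverage = c(1, 1),
                        state_labels = labels, alphabet = c("A", "B", "C", "D"),
                        node_keys = drydiv:::clade_keys(tr), n_trees = 1L),
                   class = "node_range_freq")
  ev <- extract_dispersals(nrf, rule = "modal", regions = rg)
  expect_equal(nrow(ev), 1L)              # A -> A edges yield nothing
  expect_equal(ev$area, "D")
  expect_equal(ev$stem_age, 30)
  expect_equal(ev$crown_age, 20)
  expect_equal(unname(attr(ev, "region_counts")["D"]), 1)
})

test_that("all-MPR extraction recovers most true gain events", {
  set.seed(1)
  rates <- numeric(0)
  for (i in 1:12) {
    sim <- simulate_bd_tree(40, 0.12, 0, rho = 1, seed = sample.int(1e6, 1))
    rr <- simulate_ranges(sim$tree, 0.004, 0.002, seed = sample.int(1e6, 1))
    gains <- rr$truth$events[rr$truth$events$type == "gain", ]
    if (nrow(gains) == 0L) next
    fit <- diva_reconstruct(sim$tree, rr$regions)
    d <- extract_dispersals(fit, rule = "all_mpr")
    hits <- mapply(function(nd, ar) any(d$child == nd & d$area == ar),
                   gains$node, gains$area)
    rates <- c(rates, mean(hits))
  }
  expect_gte(mean(rates), 0.7)
})
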
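# Tree and table I/O: parsing, validation, round-trips, subsampling.

test_that("read_chronogram computes node ages and enforces ultrametricity", {
  tf <- write_tmp("((a:1,b:1):1,c:2);")
  tr <- read_chronogram(tf)
  expect_equal(crown_age(tr), 2)
  ages <- node_ages(tr)
  expect_equal(unname(ages[1:3]), c(0, 0, 0))
  expect_equal(sort(unname(ages[4:5])), c(1, 2))

  bad <- write_tmp("((a:1,b:2):1,c:2);")
  err <- expect_error(read_chronogram(bad), class = "drydiv_not_ultrametric")
  expect_match(conditionMessage(err), "'b'")

  nolen <- write_tmp("((a,b),c);")
  expect_error(read_chronogram(nolen), class = "drydiv_missing_lengths")
})

test_that("write/read round-trip preserves topology, labels and ages", {
  tr <- small_fixture()$trees[[2]]
  tf <- tempfile(fileext = ".nwk")
  write_chronogram(tr, tf)
  tr2 <- read_chronogram(tf)
  expect_true(ape::all.equal.phylo(tr, tr2))
  expect_lt(max(abs(sort(node_ages(tr)) - sort(node_ages(tr2)))), 1e-9)
  expect_identical(drydiv:::clade_keys(tr2)[1], drydiv:::clade_keys(tr)[1])
})

test_that("polytomies are rejected by default and resolvable on request", {
  tf <- write_tmp("(a:2,b:2,c:2);")
  expect_error(read_chronogram(tf), class = "drydiv_polytomy")
  tr <- read_chronogram(tf, resolve_polytomies = TRUE, seed = 1)
  expect_true(ape::is.binary(tr))
  expect_equal(crown_age(tr), 2)
})

test_that("read_tree_sample keeps order, subsamples under seed, checks tips", {
  trees <- lapply(1:5, function(i) {
    tr <- balanced4()
    tr$edge.length <- tr$edge.length * i
    tr
  })
  tf <- tempfile(fileext = ".nwk")
  ape::write.tree(structure(trees, class = "multiPhylo"), file = tf)
  ts <- read_tree_sample(tf)
  expect_length(ts, 5L)
  expect_equal(crown_age(ts[[3]]), 3 * crown_age(trees[[1]]))

  s1 <- read_tree_sample(tf, max_trees = 2, seed = 99)
  s2 <- read_tree_sample(tf, max_trees = 2, seed = 99)
  expect_length(s1, 2L)
  expect_identical(ape::write.tree(s1[[1]]), ape::write.tree(s2[[1]]))
  expect_identical(ape::write.tree(s1[[2]]), ape::write.tree(s2[[2]]))

  other <- balanced4()
  other$tip.label <- c("a", "b", "c", "zzz")
  err <- expect_error(tree_sample(c(trees, list(other))),
                      class = "drydiv_tipset_mismatch")
  expect_match(conditionMessage(err), "zzz")
  expect_error(tree_sample(list()), class = "drydiv_empty_sample")
})

test_that("region tables parse compound codes, flag multi-area, reject junk", {
  tf <- write_tmp(c("sp1\tA", "sp2\tAD", "sp3\tB,C"), ext = ".tsv")
  rg <- read_region_table(tf)
  expect_equal(rg$range, c("A", "AD", "BC"))
  expect_equal(rg$multi, c(FALSE, TRUE, TRUE))
  expect_equal(unname(attr(rg, "mask")), c(1L, 9L, 6L))

  bad <- write_tmp(c("sp1\tA", "sp2\tE"), ext = ".tsv")
  expect_error(read_region_table(bad), class = "drydiv_unknown_area")
  dup <- write_tmp(c("sp1\tA", "sp1\tB"), ext = ".tsv")
  expect_error(read_region_table(dup), class = "drydiv_duplicate_tip")
  # configurable alphabet
  rg2 <- read_region_table(write_tmp("sp1\tE", ext = ".tsv"),
                           alphabet = LETTERS[1:5])
  expect_equal(rg2$range, "E")
})

test_that("clade richness tables are validated", {
  ok <- read_clade_richness(write_tmp(c("clade\tsampled\tdescribed",
                                        "all\t157\t285"), ext = ".tsv"))
  expect_equal(ok$described, 285L)
  expect_error(
    read_clade_richness(write_tmp("all\t300\t285", ext = ".tsv")),
    class = "drydiv_richness_invalid")
})

test_that("branching times are descending internal ages, length n - 1", {
  expect_equal(extract_branching_times(caterpillar3()), c(2, 1))
  expect_equal(extract_branching_times(balanced4()), c(2, 1.5, 1))
  tr <- small_fixture()$trees[[1]]
  bt <- extract_branching_times(tr)
  expect_length(bt, ape::Ntip(tr) - 1L)
  expect_true(all(diff(bt) <= 0))
  expect_equal(bt[1], crown_age(tr))
})
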
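# Tree and table input/output: the structural contracts every downstream
# stage assumes.  Trees are plain ape "phylo" objects that have passed
# validate_chronogram(); tree samples are "multiPhylo" objects carrying a
# provenance attribute and (optionally) a designated representative tree.

#' Node ages of a dated tree
#'
#' Ages are measured backward from the present in Myr: tips are at 0 and the
#' root carries the crown age.  Works for any rooted tree with branch
#' lengths; for non-ultrametric trees the age of a node is the crown age
#' minus its distance from the root.
#'
#' @param phy a rooted `phylo` with branch lengths.
#' @return numeric vector of ages indexed like ape nodes
#'   (`1..Ntip` tips, then internals starting at `Ntip + 1`).
#' @export
node_ages <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) {
    stop_drydiv("drydiv_missing_lengths", "tree has no branch lengths")
  }
  depth <- ape::node.depth.edgelength(phy)
  max(depth[seq_len(ape::Ntip(phy))]) - depth
}

#' Crown age (root age) of a chronogram, in Ma
#' @param phy a rooted `phylo` with branch lengths.
#' @export
crown_age <- function(phy) {
  node_ages(phy)[ape::Ntip(phy) + 1L]
}

#' Validate the chronogram contract
#'
#' Checks that `phy` is rooted, binary (unless `resolve_polytomies`), has
#' branch lengths, non-negative edges, and is ultrametric within a relative
#' tolerance (default 1e-6 of the crown age).  Polytomies are rejected by
#' default; `resolve_polytomies = TRUE` breaks them randomly with
#' zero-length branches (seeded), the convention birth-death likelihoods
#' expect.
#'
#' @param phy a `phylo` object.
#' @param ultrametric_tol relative tolerance on root-to-tip path lengths.
#' @param resolve_polytomies break polytomies randomly (zero-length edges)?
#' @param seed RNG seed for the random resolution.
#' @return the validated (possibly resolved) `phylo`, invisibly classed as
#'   before; errors are signalled with class `drydiv_*`.
#' @export
validate_chronogram <- function(phy, ultrametric_tol = 1e-6,
                                resolve_polytomies = FALSE, seed = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) {
    stop_drydiv("drydiv_missing_lengths", "tree has no branch lengths")
  }
  # a basal trifurcation reads as "binary but unrooted"; treat it as a
  # root polytomy
  if (!ape::is.binary(phy) || !ape::is.rooted(phy)) {
    if (!resolve_polytomies) {
      stop_drydiv("drydiv_polytomy",
                  "tree contains polytomies (or an unrooted basal trifurcation); rerun with resolve_polytomies = TRUE")
    }
    phy <- with_seed(seed, ape::multi2di(phy, random = TRUE))
    if (!ape::is.rooted(phy) || !ape::is.binary(phy)) {
      stop_drydiv("drydiv_unrooted", "tree could not be rooted")
    }
  }
  if (any(phy$edge.length < -1e-9)) {
    stop_drydiv("drydiv_negative_edge", "tree has negative branch lengths")
  }
  depth <- ape::node.depth.edgelength(phy)
  ntip <- ape::Ntip(phy)
  tipd <- depth[seq_len(ntip)]
  ca <- max(tipd)
  # deviation against the median tip depth, so the minority tip is the one
  # named in the error
  ref <- stats::median(tipd)
  dev <- abs(tipd - ref) / ca
  if (any(dev > ultrametric_tol)) {
    worst <- which.max(dev)
    stop_drydiv("drydiv_not_ultrametric",
                "tree is not ultrametric: tip '%s' root-to-tip length %.6g vs reference depth %.6g (relative deviation %.3g > %.3g)",
                phy$tip.label[worst], tipd[worst], ref, dev[worst],
                ultrametric_tol)
  }
  phy
}

#' Read a chronogram from newick or nexus
#'
#' @param path file path.
#' @param format `"newick"`, `"nexus"`, or `"auto"` (guess from extension,
#'   falling back to newick).
#' @inheritParams validate_chronogram
#' @return a validated `phylo` chronogram.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((a:1,b:1):1,c:2);", tf)
#' tr <- read_chronogram(tf)
#' crown_age(tr)   # 2
#' @export
read_chronogram <- function(path, format = c("auto", "newick", "nexus"),
                            ultrametric_tol = 1e-6,
                            resolve_polytomies = FALSE, seed = NULL) {
  format <- match.arg(format)
  phy <- .read_trees_raw(path, format)
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L) {
      stop_drydiv("drydiv_multiple_trees",
                  "file contains %d trees; use read_tree_sample()", length(phy))
    }
    phy <- phy[[1L]]
  }
  validate_chronogram(phy, ultrametric_tol, resolve_polytomies, seed)
}

.read_trees_raw <- function(path, format) {
  if (!file.exists(path)) {
    stop_drydiv("drydiv_io", "file not found: %s", path)
  }
  if (format == "auto") {
    format <- if (grepl("\\.(nex|nexus|trees?)$", path, ignore.case = TRUE) &&
                  grepl("^#NEXUS", toupper(readLines(path, n = 1L)))) {
      "nexus"
    } else if (grepl("^#NEXUS", toupper(readLines(path, n = 1L)))) {
      "nexus"
    } else "newick"
  }
  if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path)
}

#' Write a chronogram (newick)
#'
#' @param phy a `phylo`.
#' @param path output path.
#' @param digits digits written per branch length; the default preserves
#'   node ages to well within 1e-9 on Myr-scale trees.
#' @export
write_chronogram <- function(phy, path, digits = 12L) {
  ape::write.tree(phy, file = path, digits = digits)
  invisible(path)
}

#' Bundle trees into a tree sample
#'
#' A tree sample is an ordered collection of chronograms over an identical
#' tip-label set (e.g. a posterior sample), with a provenance tag and an
#' optional designated representative (MCC-role) tree.
#'
#' @param trees a list of `phylo` or a `multiPhylo`.
#' @param representative optional `phylo` sharing the same tip set.
#' @param provenance one of `"mcc"`, `"posterior_draw"`, `"synthetic"`,
#'   `"unknown"`.
#' @param validate validate each member as a chronogram?
#' @return a `multiPhylo` with class `tree_sample` and attributes
#'   `provenance` and `representative`.
#' @export
tree_sample <- function(trees, representative = NULL,
                        provenance = c("unknown", "mcc", "posterior_draw",
                                       "synthetic"),
                        validate = TRUE) {
  provenance <- match.arg(provenance)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0L) {
    stop_drydiv("drydiv_empty_sample", "tree sample is empty")
  }
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    tl <- sort(trees[[i]]$tip.label)
    if (!identical(tl, ref)) {
      sd <- union(setdiff(tl, ref), setdiff(ref, tl))
      stop_drydiv("drydiv_tipset_mismatch",
                  "tree %d has a different tip set (symmetric difference: %s)",
                  i, paste(sd, collapse = ", "))
    }
    if (validate) trees[[i]] <- validate_chronogram(trees[[i]])
  }
  if (!is.null(representative)) {
    if (!identical(sort(representative$tip.label), ref)) {
      stop_drydiv("drydiv_tipset_mismatch",
                  "representative tree has a different tip set")
    }
    if (validate) representative <- validate_chronogram(representative)
  }
  structure(trees, class = c("tree_sample", "multiPhylo"),
            provenance = provenance, representative = representative)
}

#' @export
print.tree_sample <- function(x, ...) {
  cat(sprintf("Tree sample: %d chronograms, %d tips, provenance '%s'%s\n",
              length(x), ape::Ntip(x[[1L]]), attr(x, "provenance"),
              if (is.null(attr(x, "representative"))) "" else
                ", with representative tree"))
  invisible(x)
}

#' Read a multi-tree file as a tree sample
#'
#' Optionally subsamples `max_trees` trees uniformly without replacement,
#' reproducibly under `seed`.  All trees must share one tip-label set.
#'
#' @inheritParams read_chronogram
#' @param max_trees keep at most this many trees (uniform subsample when
#'   fewer than available); `NULL` keeps all, in file order.
#' @param seed RNG seed for the subsample.
#' @param provenance provenance tag recorded on the sample.
#' @return a [tree_sample()].
#' @export
read_tree_sample <- function(path, format = c("auto", "newick", "nexus"),
                             max_trees = NULL, seed = NULL,
                             provenance = "posterior_draw") {
  format <- match.arg(format)
  trees <- .read_trees_raw(path, format)
  if (inherits(trees, "phylo")) trees <- structure(list(trees),
                                                   class = "multiPhylo")
  trees <- unclass(trees)
  if (!is.null(max_trees) && max_trees < length(trees)) {
    keep <- with_seed(seed, sort(sample.int(length(trees), max_trees)))
    trees <- trees[keep]
  }
  tree_sample(trees, provenance = provenance)
}

#' Read a tip-to-region table (TSV)
#'
#' Two tab-separated columns: tip label and compound-coded areas (`"A"`,
#' `"AD"`, or `"A,D"`).  A header line whose first field is `tip` is
#' skipped.  Multi-area tips are flagged (`multi`), which downstream
#' regional analyses use for the exclusion rule.
#'
#' @param path TSV path.
#' @param alphabet ordered area codes (single characters), default the four
#'   continental dryland regions A (Africa), B (Asia), C (Australia),
#'   D (New World).
#' @return a `region_table` data.frame with columns `tip`, `range`, `multi`
#'   and attributes `alphabet` and `mask` (named integer bitmasks).
#' @export
read_region_table <- function(path, alphabet = c("A", "B", "C", "D")) {
  if (!file.exists(path)) stop_drydiv("drydiv_io", "file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", comment.char = "#",
                          quote = "", blank.lines.skip = TRUE)
  if (ncol(df) < 2L) {
    stop_drydiv("drydiv_region_parse", "region table needs two TSV columns")
  }
  if (tolower(df[1L, 1L]) %in% c("tip", "taxon", "species")) {
    df <- df[-1L, , drop = FALSE]
  }
  region_table(df[[1L]], df[[2L]], alphabet)
}

#' Construct a region table from vectors
#'
#' @param tips character tip labels (unique).
#' @param codes compound area codes per tip (e.g. `"AD"`).
#' @inheritParams read_region_table
#' @export
region_table <- function(tips, codes, alphabet = c("A", "B", "C", "D")) {
  tips <- as.character(tips); codes <- as.character(codes)
  stopifnot(length(tips) == length(codes))
  if (anyDuplicated(tips)) {
    stop_drydiv("drydiv_duplicate_tip", "duplicate tip(s) in region table: %s",
                paste(unique(tips[duplicated(tips)]), collapse = ", "))
  }
  mask <- label_to_mask(codes, alphabet)
  if (anyNA(mask)) {
    bad <- tips[is.na(mask)][1L]
    stop_drydiv("drydiv_unknown_area",
                "tip '%s' has area code '%s' outside alphabet {%s}",
                bad, codes[is.na(mask)][1L], paste(alphabet, collapse = ","))
  }
  out <- data.frame(tip = tips,
                    range = mask_to_label(mask, alphabet),
                    multi = popcount(mask) > 1L,
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  attr(out, "mask") <- stats::setNames(mask, tips)
  class(out) <- c("region_table", "data.frame")
  out
}

# Bitmasks of the regions for an exact tip set, erroring on missing tips.
region_masks_for <- function(regions, tips) {
  mask <- attr(regions, "mask")
  missing <- setdiff(tips, names(mask))
  if (length(missing) > 0L) {
    stop_drydiv("drydiv_missing_region",
                "tips missing from the region table: %s",
                paste(missing, collapse = ", "))
  }
  mask[tips]
}

#' Write a region table (TSV)
#' @param regions a `region_table`.
#' @param path output path.
#' @export
write_region_table <- function(regions, path) {
  utils::write.table(regions[, c("tip", "range")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = c("tip", "areas"))
  invisible(path)
}

#' Read a clade-richness table (TSV)
#'
#' Columns: clade label, sampled species count, described species count.
#' Used by the missing-taxa diagnostic; clades absent from the table are
#' treated as fully sampled.
#'
#' @param path TSV path (header line optional).
#' @return data.frame with columns `clade`, `sampled`, `described`.
#' @export
read_clade_richness <- function(path) {
  if (!file.exists(path)) stop_drydiv("drydiv_io", "file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", comment.char = "#")
  if (tolower(df[1L, 1L]) %in% c("clade", "label")) df <- df[-1L, ,
                                                            drop = FALSE]
  out <- data.frame(clade = df[[1L]],
                    sampled = as.integer(df[[2L]]),
                    described = as.integer(df[[3L]]),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$sampled)) || any(is.na(out$described))) {
    stop_drydiv("drydiv_richness_parse", "non-integer counts in richness table")
  }
  if (any(out$described < 1L) || any(out$sampled > out$described)) {
    stop_drydiv("drydiv_richness_invalid",
                "need 1 <= sampled <= described per clade")
  }
  out
}

#' Branching times of a chronogram
#'
#' Internal-node ages sorted descending; `x[1]` is the crown age and the
#' vector has `Ntip - 1` entries.  These are the sufficient statistics for
#' the birth-death likelihoods.
#'
#' @param phy a binary, ultrametric `phylo`.
#' @return numeric vector of ages (Ma), descending.
#' @export
extract_branching_times <- function(phy) {
  if (!ape::is.binary(phy)) {
    stop_drydiv("drydiv_polytomy", "branching times require a binary tree")
  }
  ages <- node_ages(phy)
  sort(ages[(ape::Ntip(phy) + 1L):(ape::Ntip(phy) + phy$Nnode)],
       decreasing = TRUE)
}
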
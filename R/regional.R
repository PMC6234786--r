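# Region-specific divergence accumulation: per-tree node-to-region
# assignment from ancestral-range reconstructions, binned divergence series
# over a tree sample, cumulative accumulation curves with exponential fits,
# nodal lineage density, and the cross-clade synchrony table.

#' Assign internal nodes to single regions across a tree sample
#'
#' Multi-area tips are excluded (pruned) before reconstruction, matching
#' the exclusion rule for regional analyses.  Under `method = "ancestral"`
#' each internal node takes the single region of its modal DIVA range when
#' that range has size one and is untied; widespread or tied nodes are
#' excluded (`NA`).  `method = "tip_descendant"` instead uses the majority
#' region among descendant tips (sensitivity check).
#'
#' @param trees a [tree_sample()], list of `phylo`, or single `phylo`.
#' @param regions a [region_table()].
#' @param method `"ancestral"` or `"tip_descendant"`.
#' @param cost_model cost model for the DIVA route.
#' @return a `node_region_assignments` list: `assignments` (per tree, a
#'   data.frame `node`, `age`, `region` with `NA` = excluded), `trees`
#'   (pruned), `regions` (pruned), `excluded_tips`, `method`.
#' @export
assign_node_regions <- function(trees, regions,
                                method = c("ancestral", "tip_descendant"),
                                cost_model = diva_cost_model()) {
  method <- match.arg(method)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  excl <- regions$tip[regions$multi]
  alphabet <- attr(regions, "alphabet")
  pruned <- lapply(trees, function(tr) {
    if (length(intersect(excl, tr$tip.label)) > 0L) {
      kept <- setdiff(tr$tip.label, excl)
      if (length(kept) < 2L) {
        stop_drydiv("drydiv_all_excluded",
                    "fewer than two single-area tips remain after exclusion")
      }
      ape::keep.tip(tr, kept)
    } else tr
  })
  keep_rows <- !regions$multi & regions$tip %in% pruned[[1L]]$tip.label
  regions2 <- region_table(regions$tip[keep_rows], regions$range[keep_rows],
                           alphabet)
  assignments <- lapply(pruned, function(tr) {
    ntip <- ape::Ntip(tr)
    ages <- node_ages(tr)
    ids <- (ntip + 1L):(ntip + tr$Nnode)
    if (method == "ancestral") {
      fit <- diva_reconstruct(tr, regions2, cost_model)
      res <- .modal_ranges(fit$marginal[ids, , drop = FALSE],
                           fit$state_labels)
      lab <- fit$state_labels[res$state]
      region <- ifelse(nchar(lab) == 1L & !res$tied, lab, NA_character_)
    } else {
      mask <- region_masks_for(regions2, tr$tip.label)
      reg_tip <- mask_to_label(mask, alphabet)
      po <- ape::reorder.phylo(tr, "postorder")
      tab <- matrix(0L, ntip + tr$Nnode, length(alphabet),
                    dimnames = list(NULL, alphabet))
      tab[cbind(seq_len(ntip), match(reg_tip, alphabet))] <- 1L
      for (j in seq_len(nrow(po$edge))) {
        tab[po$edge[j, 1L], ] <- tab[po$edge[j, 1L], ] + tab[po$edge[j, 2L], ]
      }
      region <- apply(tab[ids, , drop = FALSE], 1L, function(z) {
        w <- which(z == max(z))
        if (length(w) == 1L) alphabet[w] else NA_character_
      })
    }
    data.frame(node = ids, age = ages[ids], region = region,
               stringsAsFactors = FALSE)
  })
  structure(list(assignments = assignments, trees = pruned,
                 regions = regions2, excluded_tips = excl, method = method,
                 alphabet = alphabet),
            class = "node_region_assignments")
}

#' Binned regional divergence series over a tree sample
#'
#' Internal-node ages are histogrammed per region into half-open age bins
#' `[0, w), [w, 2w), ...` anchored at the present; excluded (widespread or
#' tied) nodes form their own category so counts are conserved.  Across
#' trees each (region, bin) cell is summarized by the median, the 25-75%
#' interquartile range (type-7 quantiles) and the full span.
#'
#' @param assign a [assign_node_regions()] result.
#' @param bin_width bin width in Myr (default 5).
#' @return data.frame `region`, `bin_lo`, `bin_hi`, `median`, `q25`, `q75`,
#'   `min`, `max`; attribute `raw` holds the trees x categories x bins
#'   count array.
#' @export
divergence_series <- function(assign, bin_width = 5) {
  stopifnot(inherits(assign, "node_region_assignments"), bin_width > 0)
  cats <- c(assign$alphabet, "excluded")
  maxage <- max(vapply(assign$assignments, function(a) max(a$age),
                       numeric(1L)))
  nbins <- floor(maxage / bin_width) + 1L
  raw <- array(0L, dim = c(length(assign$assignments), length(cats), nbins),
               dimnames = list(NULL, cats, NULL))
  for (i in seq_along(assign$assignments)) {
    a <- assign$assignments[[i]]
    cat_i <- ifelse(is.na(a$region), "excluded", a$region)
    bin_i <- pmin(floor(a$age / bin_width) + 1L, nbins)
    for (j in seq_len(nrow(a))) {
      raw[i, cat_i[j], bin_i[j]] <- raw[i, cat_i[j], bin_i[j]] + 1L
    }
  }
  rows <- expand.grid(region = cats, bin = seq_len(nbins),
                      stringsAsFactors = FALSE)
  stat <- t(apply(rows, 1L, function(rw) {
    v <- raw[, rw[["region"]], as.integer(rw[["bin"]])]
    c(stats::median(v), stats::quantile(v, c(0.25, 0.75), type = 7,
                                        names = FALSE), min(v), max(v))
  }))
  out <- data.frame(region = rows$region,
                    bin_lo = (rows$bin - 1L) * bin_width,
                    bin_hi = rows$bin * bin_width,
                    median = stat[, 1L], q25 = stat[, 2L], q75 = stat[, 3L],
                    min = stat[, 4L], max = stat[, 5L],
                    stringsAsFactors = FALSE)
  attr(out, "raw") <- raw
  out
}

#' Cumulative divergence accumulation per region
#'
#' For one assigned tree (by default the first, i.e. the representative),
#' returns per region the node ages in descending order with the running
#' count of divergences, plus a pooled `"all"` curve over every internal
#' node (excluded ones included in `"all"` only).
#'
#' @param assign a [assign_node_regions()] result.
#' @param index which tree of the sample to use.
#' @return data.frame `region`, `age`, `cumulative`; attribute `crown_age`.
#' @export
cumulative_accumulation <- function(assign, index = 1L) {
  a <- assign$assignments[[index]]
  out <- list()
  for (r in assign$alphabet) {
    ages <- sort(a$age[!is.na(a$region) & a$region == r], decreasing = TRUE)
    if (length(ages) > 0L) {
      out[[r]] <- data.frame(region = r, age = ages,
                             cumulative = seq_along(ages),
                             stringsAsFactors = FALSE)
    }
  }
  ages <- sort(a$age, decreasing = TRUE)
  out[["all"]] <- data.frame(region = "all", age = ages,
                             cumulative = seq_along(ages),
                             stringsAsFactors = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "crown_age") <- max(a$age)
  res
}

#' Exponential fit to cumulative divergence curves
#'
#' Log-linear least squares of `ln N = ln a + b * tau` on the cumulative
#' step function evaluated at its node times, with `tau` the time elapsed
#' since the crown age.  Deterministic and closed-form; regions with fewer
#' than three distinct time points are flagged rather than fitted.
#'
#' @param cum output of [cumulative_accumulation()].
#' @return data.frame `region`, `a`, `b` (per Myr), `rss`, `n_points`,
#'   `ok`.
#' @export
fit_exponential <- function(cum) {
  crown <- attr(cum, "crown_age")
  if (is.null(crown)) crown <- max(cum$age)
  if (length(unique(cum$age)) < 2L) {
    stop_drydiv("drydiv_degenerate_fit",
                "cumulative curve has a single divergence time")
  }
  res <- lapply(split(cum, cum$region), function(d) {
    d <- d[d$cumulative > 0, , drop = FALSE]
    tau <- crown - d$age
    if (length(unique(tau)) < 3L) {   # too sparse: refuse, don't fit
      return(data.frame(region = d$region[1L], a = NA_real_, b = NA_real_,
                        rss = NA_real_, n_points = nrow(d), ok = FALSE,
                        stringsAsFactors = FALSE))
    }
    fit <- stats::lm(log(d$cumulative) ~ tau)
    data.frame(region = d$region[1L], a = exp(unname(stats::coef(fit)[1L])),
               b = unname(stats::coef(fit)[2L]),
               rss = sum(stats::residuals(fit)^2), n_points = nrow(d),
               ok = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Nodal lineage density
#'
#' For every internal node assigned a region R at age t: the number of
#' branches alive at t (parent age > t >= child age) whose child node is
#' assigned R (tips count with their observed single region).  The root,
#' which has no subtending branch, contributes itself.  This is a
#' per-region lineages-through-time curve evaluated at the region's own
#' divergence times, reflecting both in-situ diversification and
#' immigration.
#'
#' @param assign a [assign_node_regions()] result.
#' @param index which tree of the sample to use.
#' @return data.frame `node`, `region`, `age`, `density`.
#' @export
lineage_density <- function(assign, index = 1L) {
  tr <- assign$trees[[index]]
  a <- assign$assignments[[index]]
  ntip <- ape::Ntip(tr)
  ages <- node_ages(tr)
  mask <- region_masks_for(assign$regions, tr$tip.label)
  tip_region <- mask_to_label(mask, assign$alphabet)
  node_region <- c(tip_region, a$region[match((ntip + 1L):(ntip + tr$Nnode),
                                              a$node)])
  pa <- ages[tr$edge[, 1L]]
  ca <- ages[tr$edge[, 2L]]
  creg <- node_region[tr$edge[, 2L]]
  root <- ntip + 1L
  keep <- !is.na(a$region)
  dens <- vapply(which(keep), function(i) {
    t <- a$age[i]; R <- a$region[i]
    alive <- pa > t + 1e-9 & ca <= t + 1e-9 & !is.na(creg) & creg == R
    sum(alive) + as.integer(a$node[i] == root)
  }, numeric(1L))
  data.frame(node = a$node[keep], region = a$region[keep],
             age = a$age[keep], density = dens, stringsAsFactors = FALSE)
}

#' Cross-clade diversification synchrony table
#'
#' Interval arithmetic on clade crown-age estimates: for each clade the
#' overlap of its credible interval `[lo, hi]` (Ma) with a query window
#' (default the mid-late Miocene, 15-10 Ma) and a boolean overlap flag;
#' the attribute `fraction_overlapping` summarizes across clades.
#'
#' @param clade_ages data.frame with columns `clade`, `mean`, `lo`, `hi`
#'   (and optionally `region`).
#' @param window numeric length-2 window in Ma, older bound first.
#' @return the input with `overlap` (Myr) and `overlaps` (flag) appended.
#' @export
synchrony_table <- function(clade_ages, window = c(15, 10)) {
  stopifnot(all(c("clade", "mean", "lo", "hi") %in% names(clade_ages)),
            length(window) == 2L)
  w_hi <- max(window); w_lo <- min(window)
  bad <- clade_ages$lo > clade_ages$mean | clade_ages$mean > clade_ages$hi
  if (any(bad)) {
    stop_drydiv("drydiv_bad_interval",
                "malformed interval for clade(s): %s",
                paste(clade_ages$clade[bad], collapse = ", "))
  }
  out <- clade_ages
  out$overlap <- pmax(0, pmin(out$hi, w_hi) - pmax(out$lo, w_lo))
  out$overlaps <- out$overlap > 0
  attr(out, "window") <- c(w_hi, w_lo)
  attr(out, "fraction_overlapping") <- mean(out$overlaps)
  out
}

#' Read a clade-age table (TSV)
#'
#' Columns: clade, mean age, interval low, interval high, and optionally a
#' region code.  Input to [synchrony_table()].
#' @param path TSV path (header optional).
#' @export
read_clade_ages <- function(path) {
  if (!file.exists(path)) stop_drydiv("drydiv_io", "file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", comment.char = "#")
  if (tolower(df[1L, 1L]) %in% c("clade", "label")) df <- df[-1L, ,
                                                            drop = FALSE]
  out <- data.frame(clade = df[[1L]], mean = as.numeric(df[[2L]]),
                    lo = as.numeric(df[[3L]]), hi = as.numeric(df[[4L]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 5L) out$region <- df[[5L]]
  out
}
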
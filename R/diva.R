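# Dispersal-vicariance ancestral-range reconstruction (DIVA) by exact
# dynamic programming over bitmask range states, statistical averaging over
# a tree sample onto a representative tree (S-DIVA), and extraction of
# timed dispersal events.
#
# Event costs follow the classic parsimony scheme: vicariance (any
# bipartition of a widespread range into two non-empty disjoint covering
# subsets) and within-area duplication are free; every area gained along a
# branch costs `dispersal`, every area lost costs `extinction`.  The DP is
# a Sankoff-style two-pass algorithm over the (2^A - 1, size-capped) range
# states, with most-parsimonious-reconstruction (MPR) counting so per-node
# marginal MPR proportions are exact.

#' DIVA event cost model
#'
#' @param dispersal cost per area gained along a branch (default 1).
#' @param extinction cost per area lost along a branch (default 1).
#' @param max_areas cap on ancestral range size; `NULL` means the full
#'   alphabet size (RASP-style analyses often cap at 2).
#' @param strict_vicariance restrict vicariance to bipartitions where one
#'   side is a single area (the stricter DIVA variant)?
#' @return a `diva_cost_model` list.
#' @export
diva_cost_model <- function(dispersal = 1, extinction = 1, max_areas = NULL,
                            strict_vicariance = FALSE) {
  stopifnot(dispersal >= 0, extinction >= 0,
            is.null(max_areas) || max_areas >= 1)
  structure(list(dispersal = dispersal, extinction = extinction,
                 max_areas = max_areas,
                 strict_vicariance = strict_vicariance),
            class = "diva_cost_model")
}

# Range-state machinery for an alphabet of nA areas capped at max_areas.
.diva_states <- function(nA, cost_model) {
  max_areas <- cost_model$max_areas %||% nA
  masks <- seq_len(2^nA - 1L)
  masks <- masks[popcount(masks) <= max_areas]
  S <- length(masks)
  idx <- integer(2^nA - 1L)
  idx[masks] <- seq_len(S)
  size <- popcount(masks)
  gains <- outer(masks, masks, function(i, d) popcount(bitwAnd(d, bitwNot(i))))
  losses <- outer(masks, masks, function(i, d) popcount(bitwAnd(i, bitwNot(d))))
  trans <- cost_model$dispersal * gains + cost_model$extinction * losses
  outcomes <- vector("list", S)
  for (p in seq_len(S)) {
    if (size[p] == 1L) {
      outcomes[[p]] <- cbind(p, p)
    } else {
      subs <- .proper_submasks(masks[p])
      comp <- bitwAnd(masks[p], bitwNot(subs))
      if (cost_model$strict_vicariance) {
        keep <- popcount(subs) == 1L | popcount(comp) == 1L
        subs <- subs[keep]; comp <- comp[keep]
      }
      outcomes[[p]] <- cbind(idx[subs], idx[comp])
    }
  }
  list(masks = masks, idx = idx, size = size, trans = trans,
       outcomes = outcomes, max_areas = max_areas)
}

# Sorted-tip-label key per internal node (bipartition-stable clade id).
clade_keys <- function(phy) {
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")
  lst <- vector("list", nn)
  lst[seq_len(ntip)] <- as.list(phy$tip.label)
  for (j in seq_len(nrow(po$edge))) {
    u <- po$edge[j, 1L]; v <- po$edge[j, 2L]
    lst[[u]] <- c(lst[[u]], lst[[v]])
  }
  vapply((ntip + 1L):nn, function(u) paste(sort(lst[[u]]), collapse = ";"),
         character(1L))
}

#' Exact DIVA reconstruction on one tree
#'
#' Two-pass dynamic program returning, for every node, the minimum subtree
#' cost per range state and exact MPR counts, from which per-node marginal
#' MPR proportions and the optimal root-range set are derived.
#'
#' @param phy a binary rooted chronogram (`phylo`).
#' @param regions a [region_table()] covering every tip (multi-area tips
#'   participate with their observed range fixed).
#' @param cost_model a [diva_cost_model()].
#' @return a `diva_result` list: `min_cost`, `total_mprs`, `root_states`
#'   (labels of optimal root ranges), `marginal` (nodes x states matrix of
#'   MPR proportions; tip rows are point masses on the observed range),
#'   `state_labels`, plus the DP tables used by [extract_dispersals()].
#' @export
diva_reconstruct <- function(phy, regions,
                             cost_model = diva_cost_model()) {
  if (!ape::is.binary(phy)) {
    stop_drydiv("drydiv_polytomy", "DIVA requires a binary tree")
  }
  alphabet <- attr(regions, "alphabet")
  nA <- length(alphabet)
  tipmask <- region_masks_for(regions, phy$tip.label)
  st <- .diva_states(nA, cost_model)
  if (any(popcount(tipmask) > st$max_areas)) {
    stop_drydiv("drydiv_max_areas",
                "max_areas (%d) smaller than the largest observed tip range",
                st$max_areas)
  }
  S <- length(st$masks)
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  root <- ntip + 1L
  tol <- 1e-9

  C <- matrix(Inf, nn, S)          # min subtree cost given node state
  M <- matrix(0, nn, S)            # MPR count of the subtree
  G <- matrix(Inf, nn, S)          # min cost below, given inherited state
  cntG <- matrix(0, nn, S)
  for (i in seq_len(ntip)) {
    C[i, st$idx[tipmask[i]]] <- 0
    M[i, st$idx[tipmask[i]]] <- 1
  }
  po <- ape::reorder.phylo(phy, "postorder")
  kids_of <- vector("list", nn)
  for (j in seq_len(nrow(po$edge))) {
    u <- po$edge[j, 1L]
    kids_of[[u]] <- c(kids_of[[u]], po$edge[j, 2L])
  }
  int_post <- unique(po$edge[, 1L])       # children before parents
  for (u in int_post) {
    kids <- kids_of[[u]]
    for (v in kids) {
      TC <- st$trans + matrix(C[v, ], S, S, byrow = TRUE)
      G[v, ] <- apply(TC, 1L, min)
      att <- abs(TC - G[v, ]) < tol
      cntG[v, ] <- as.vector(att %*% M[v, ])
    }
    k1 <- kids[1L]; k2 <- kids[2L]
    for (p in seq_len(S)) {
      o <- st$outcomes[[p]]
      vals <- G[k1, o[, 1L]] + G[k2, o[, 2L]]
      m <- min(vals)
      C[u, p] <- m
      if (is.finite(m)) {
        a <- abs(vals - m) < tol
        M[u, p] <- sum(cntG[k1, o[a, 1L]] * cntG[k2, o[a, 2L]])
      }
    }
  }
  min_cost <- min(C[root, ])
  root_att <- abs(C[root, ] - min_cost) < tol
  total_mprs <- sum(M[root, root_att])

  # Up pass: min cost / count of everything outside the subtree of v, given
  # the state at v (out, outM), then marginal MPR proportions.
  OUT <- matrix(Inf, nn, S)
  outM <- matrix(0, nn, S)
  OUT[root, ] <- 0
  outM[root, ] <- 1
  for (u in rev(int_post)) {              # parents before children
    kids <- kids_of[[u]]
    for (j in 1:2) {
      v <- kids[j]; s <- kids[3L - j]
      A <- rep.int(Inf, S)
      cntA <- rep.int(0, S)
      for (p in seq_len(S)) {
        if (!is.finite(OUT[u, p])) next
        o <- st$outcomes[[p]]
        iv <- o[, j]; is_ <- o[, 3L - j]
        vals <- OUT[u, p] + G[s, is_]
        cnts <- outM[u, p] * cntG[s, is_]
        for (r in seq_along(iv)) {
          I <- iv[r]
          if (vals[r] < A[I] - tol) {
            A[I] <- vals[r]; cntA[I] <- cnts[r]
          } else if (vals[r] < A[I] + tol) {
            cntA[I] <- cntA[I] + cnts[r]
          }
        }
      }
      AT <- A + st$trans                  # rows I, cols D
      OUT[v, ] <- apply(AT, 2L, min)
      att <- abs(sweep(AT, 2L, OUT[v, ])) < tol
      outM[v, ] <- as.vector(t(att) %*% cntA)
    }
  }
  marg <- matrix(0, nn, S)
  tot <- C + OUT
  in_mpr <- abs(tot - min_cost) < tol
  marg[in_mpr] <- (M * outM)[in_mpr]
  marg <- marg / total_mprs
  labels <- mask_to_label(st$masks, alphabet)
  colnames(marg) <- labels
  structure(list(tree = phy, alphabet = alphabet, states = st,
                 state_labels = labels, cost = C, count = M, G = G,
                 cntG = cntG, out = OUT, outM = outM, marginal = marg,
                 min_cost = min_cost, total_mprs = total_mprs,
                 root_states = labels[root_att],
                 node_keys = clade_keys(phy)),
            class = "diva_result")
}

#' @export
print.diva_result <- function(x, ...) {
  cat(sprintf("DIVA reconstruction: %d tips, min cost %g, %g MPR(s)\n",
              ape::Ntip(x$tree), x$min_cost, x$total_mprs))
  cat("optimal root range(s):", paste(x$root_states, collapse = ", "), "\n")
  invisible(x)
}

#' Statistical DIVA over a tree sample (S-DIVA)
#'
#' Runs [diva_reconstruct()] on every tree of the sample; each internal
#' node of the representative tree (identified by its tip set) then
#' receives, from every sampled tree containing that clade, the fraction of
#' that tree's MPRs assigning each range to the clade's ancestor, averaged
#' over the contributing trees.  Clades found in no sampled tree get
#' coverage 0 and are reported unresolved (`NA` probabilities).
#'
#' @param trees a [tree_sample()] (or list of `phylo`) sharing the
#'   representative's tip set.
#' @param regions a [region_table()].
#' @param representative the representative (MCC-role) tree; defaults to
#'   the sample's `representative` attribute.
#' @param cost_model a [diva_cost_model()].
#' @return a `node_range_freq` list: `prob` (internal nodes x states, rows
#'   summing to 1 where covered), `coverage`, `tree`, `state_labels`.
#' @export
sdiva <- function(trees, regions, representative = NULL,
                  cost_model = diva_cost_model()) {
  representative <- representative %||% attr(trees, "representative")
  if (is.null(representative)) {
    stop_drydiv("drydiv_no_representative",
                "no representative tree given or attached to the sample")
  }
  trees <- unclass(trees)
  if (length(trees) == 0L) {
    stop_drydiv("drydiv_empty_sample", "empty tree sample")
  }
  rep_keys <- clade_keys(representative)
  ntip <- ape::Ntip(representative)
  ref_fit <- diva_reconstruct(representative, regions, cost_model)
  S <- length(ref_fit$state_labels)
  acc <- matrix(0, length(rep_keys), S)
  hits <- integer(length(rep_keys))
  for (tr in trees) {
    fit <- diva_reconstruct(tr, regions, cost_model)
    nt <- ape::Ntip(tr)
    pos <- match(fit$node_keys, rep_keys)
    found <- which(!is.na(pos))
    for (f in found) {
      r <- pos[f]
      acc[r, ] <- acc[r, ] + fit$marginal[nt + f, ]
      hits[r] <- hits[r] + 1L
    }
  }
  prob <- acc / ifelse(hits > 0L, hits, NA_real_)
  colnames(prob) <- ref_fit$state_labels
  structure(list(tree = representative, prob = prob,
                 coverage = hits / length(trees),
                 state_labels = ref_fit$state_labels,
                 alphabet = ref_fit$alphabet,
                 node_keys = rep_keys, n_trees = length(trees)),
            class = "node_range_freq")
}

#' @export
print.node_range_freq <- function(x, ...) {
  cat(sprintf("S-DIVA node-range frequencies: %d internal nodes over %d trees (mean coverage %.2f)\n",
              nrow(x$prob), x$n_trees, mean(x$coverage)))
  invisible(x)
}

# Modal range per internal node from a probability/marginal matrix.
# Ties broken lexicographically by state label and flagged.
.modal_ranges <- function(prob, labels) {
  ord <- order(labels)             # lexicographic preference order
  n <- nrow(prob)
  modal <- integer(n)
  tied <- logical(n)
  for (i in seq_len(n)) {
    row <- prob[i, ]
    if (anyNA(row)) { modal[i] <- NA_integer_; next }
    m <- max(row)
    att <- which(row > m - 1e-9)
    tied[i] <- length(att) > 1L
    modal[i] <- att[which.min(match(att, ord))]
  }
  list(state = modal, tied = tied)
}

#' Extract timed dispersal events from resolved ancestral ranges
#'
#' For every edge, each area present in the child's range but absent from
#' the side of the parent's range the child inherited (vicariance or
#' duplication accounted for) yields one dispersal event stamped with the
#' edge's stem age (parent) and crown age (child).
#'
#' Under `rule = "modal"` every internal node is resolved to its modal
#' range (ties broken lexicographically and flagged); under
#' `rule = "all_mpr"` (available when `node_ranges` is a `diva_result`)
#' events are counted across all MPRs exactly, each reported with the
#' fraction of MPRs supporting it.
#'
#' @param phy the tree the ranges refer to; defaults to the one stored in
#'   `node_ranges`.
#' @param node_ranges a `diva_result` or `node_range_freq`.
#' @param rule `"modal"` or `"all_mpr"`.
#' @param regions tip ranges; required when `node_ranges` is a
#'   `node_range_freq` (tips are not stored there).
#' @return data.frame of events: `parent`, `child` (ape node ids), `area`,
#'   `region` (destination), `stem_age`, `crown_age`, `support`, sorted by
#'   stem age descending; attribute `region_counts` holds per-destination
#'   totals and attribute `ties` the ids of tie-broken nodes.
#' @export
extract_dispersals <- function(node_ranges, rule = c("modal", "all_mpr"),
                               phy = NULL, regions = NULL) {
  rule <- match.arg(rule)
  is_diva <- inherits(node_ranges, "diva_result")
  phy <- phy %||% node_ranges$tree
  alphabet <- node_ranges$alphabet
  nA <- length(alphabet)
  ntip <- ape::Ntip(phy)
  ages <- node_ages(phy)
  st <- if (is_diva) node_ranges$states else
    .diva_states(nA, diva_cost_model())
  if (is_diva) {
    tipstate <- apply(node_ranges$cost[seq_len(ntip), , drop = FALSE], 1L,
                      which.min)
    prob_int <- node_ranges$marginal[(ntip + 1L):(ntip + phy$Nnode), ,
                                     drop = FALSE]
  } else {
    if (is.null(regions)) {
      stop_drydiv("drydiv_missing_region",
                  "regions= is required with node_range_freq input")
    }
    tipstate <- st$idx[region_masks_for(regions, phy$tip.label)]
    prob_int <- node_ranges$prob
  }
  if (rule == "all_mpr" && !is_diva) {
    stop_drydiv("drydiv_rule",
                "rule = 'all_mpr' needs a diva_result (exact MPR counts)")
  }

  ev <- list()
  if (rule == "modal") {
    res <- .modal_ranges(prob_int, node_ranges$state_labels)
    if (anyNA(res$state)) {
      stop_drydiv("drydiv_unresolved",
                  "unresolved internal node(s) (coverage 0) under rule = 'modal'")
    }
    state <- c(tipstate, res$state)
    kids_of <- split(phy$edge[, 2L], phy$edge[, 1L])
    for (u in (ntip + 1L):(ntip + phy$Nnode)) {
      kids <- kids_of[[as.character(u)]]
      pmask <- st$masks[state[u]]
      r1 <- st$masks[state[kids[1L]]]; r2 <- st$masks[state[kids[2L]]]
      o <- st$outcomes[[state[u]]]
      costs <- st$trans[cbind(o[, 1L], state[kids[1L]])] +
        st$trans[cbind(o[, 2L], state[kids[2L]])]
      pick <- o[which.min(costs), ]
      for (j in 1:2) {
        gained <- bitwAnd(st$masks[state[kids[j]]],
                          bitwNot(st$masks[pick[j]]))
        if (gained > 0L) {
          for (b in which(bitwAnd(gained, bitwShiftL(1L, 0:(nA - 1L))) > 0L)) {
            ev[[length(ev) + 1L]] <- data.frame(
              parent = u, child = kids[j], area = alphabet[b],
              stem_age = ages[u], crown_age = ages[kids[j]], support = 1,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    ties <- which(res$tied) + ntip
  } else {
    # exact per-edge, per-area MPR fractions from the DP tables
    x <- node_ranges
    S <- length(st$masks)
    tol <- 1e-9
    best <- x$min_cost
    area_bit <- bitwShiftL(1L, 0:(nA - 1L))
    # W[[v]][I, a]: MPR-weighted count of optimal child states containing
    # area a not in inherited state I
    kids_of <- split(phy$edge[, 2L], phy$edge[, 1L])
    for (u in (ntip + 1L):(ntip + phy$Nnode)) {
      kids <- kids_of[[as.character(u)]]
      for (j in 1:2) {
        v <- kids[j]; s <- kids[3L - j]
        W <- matrix(0, S, nA)
        for (I in seq_len(S)) {
          opt <- which(abs(st$trans[I, ] + x$cost[v, ] - x$G[v, I]) < tol)
          for (D in opt) {
            gained <- bitwAnd(st$masks[D], bitwNot(st$masks[I]))
            if (gained > 0L) {
              hit <- bitwAnd(gained, area_bit) > 0L
              W[I, hit] <- W[I, hit] + x$count[v, D]
            }
          }
        }
        gaincnt <- numeric(nA)
        for (p in seq_len(S)) {
          if (!is.finite(x$out[u, p])) next
          o <- st$outcomes[[p]]
          iv <- o[, j]; is_ <- o[, 3L - j]
          okr <- abs(x$out[u, p] + x$G[v, iv] + x$G[s, is_] - best) < tol
          for (r in which(okr)) {
            gaincnt <- gaincnt +
              x$outM[u, p] * x$cntG[s, is_[r]] * W[iv[r], ]
          }
        }
        for (b in which(gaincnt > 0)) {
          ev[[length(ev) + 1L]] <- data.frame(
            parent = u, child = v, area = alphabet[b],
            stem_age = ages[u], crown_age = ages[v],
            support = gaincnt[b] / x$total_mprs, stringsAsFactors = FALSE)
        }
      }
    }
    ties <- integer(0)
  }
  out <- if (length(ev) > 0L) do.call(rbind, ev) else
    data.frame(parent = integer(0), child = integer(0),
               area = character(0), stem_age = numeric(0),
               crown_age = numeric(0), support = numeric(0),
               stringsAsFactors = FALSE)
  out$region <- out$area
  out <- out[order(-out$stem_age), , drop = FALSE]
  rownames(out) <- NULL
  counts <- stats::setNames(vapply(alphabet, function(a)
    sum(out$area == a), numeric(1L)), alphabet)
  attr(out, "region_counts") <- counts
  attr(out, "ties") <- ties
  out
}
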
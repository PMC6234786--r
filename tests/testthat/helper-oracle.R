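# Independent brute-force oracles used by the test suite.  These stay
# deliberately naive: enumeration over all assignments, never the DP path.

# Enumerate all non-empty subsets (bitmasks) of nA areas.
oracle_states <- function(nA) seq_len(2^nA - 1L)

oracle_popcount <- function(x) {
  vapply(x, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:15)) > 0L),
         numeric(1L))
}

# Per-node event cost table NC[p, l, r]: minimal cost of a speciation with
# parent state p and daughter states l, r, minimizing over inheritance
# (duplication for single-area p, any ordered bipartition otherwise), with
# unit dispersal/extinction transition costs on the daughter branches.
oracle_node_cost <- function(nA, dc = 1, ec = 1) {
  S <- 2^nA - 1L
  trans <- outer(seq_len(S), seq_len(S), function(i, d)
    dc * oracle_popcount(bitwAnd(d, bitwNot(i))) +
      ec * oracle_popcount(bitwAnd(i, bitwNot(d))))
  NC <- array(Inf, dim = c(S, S, S))
  for (p in seq_len(S)) {
    if (oracle_popcount(p) == 1L) {
      pairs <- matrix(c(p, p), ncol = 2L)
    } else {
      subs <- which(vapply(seq_len(S), function(s)
        bitwAnd(s, p) == s && s != p, logical(1L)))
      pairs <- cbind(subs, p - subs)   # complement within p, non-empty
    }
    for (l in seq_len(S)) for (r in seq_len(S)) {
      NC[p, l, r] <- min(trans[pairs[, 1L], l] + trans[pairs[, 2L], r])
    }
  }
  NC
}

# Exhaustive minimum DIVA cost and the set of optimal root states, by
# enumerating every assignment of states to internal nodes.
oracle_diva <- function(phy, tip_masks, nA, dc = 1, ec = 1) {
  NC <- oracle_node_cost(nA, dc, ec)
  S <- 2^nA - 1L
  ntip <- ape::Ntip(phy)
  nint <- phy$Nnode
  root <- ntip + 1L
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), nint)))
  state_of <- function(v) {
    ifelse(v <= ntip, tip_masks[v], NA_integer_)
  }
  total <- numeric(nrow(grid))
  for (u in (ntip + 1L):(ntip + nint)) {
    ch <- kids[[as.character(u)]]
    pu <- grid[, u - ntip]
    l <- if (ch[1L] <= ntip) rep.int(tip_masks[ch[1L]], nrow(grid)) else
      grid[, ch[1L] - ntip]
    r <- if (ch[2L] <= ntip) rep.int(tip_masks[ch[2L]], nrow(grid)) else
      grid[, ch[2L] - ntip]
    total <- total + NC[cbind(pu, l, r)]
  }
  best <- min(total)
  root_states <- sort(unique(grid[abs(total - best) < 1e-9, 1L]))
  list(min_cost = best, root_masks = root_states)
}

# Random binary ultrametric tree with n tips (coalescent shape is fine for
# parsimony tests; ages are irrelevant to DIVA costs).
random_test_tree <- function(n) {
  tr <- ape::rcoal(n, tip.label = paste0("t", seq_len(n)))
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}

# Brute-force lineage density recount: explicit double loop over nodes and
# edges, independent of the vectorized implementation.
oracle_lineage_density <- function(tr, assignment, regions) {
  ntip <- ape::Ntip(tr)
  ages <- drydiv::node_ages(tr)
  mask <- attr(regions, "mask")[tr$tip.label]
  alphabet <- attr(regions, "alphabet")
  tip_region <- vapply(mask, function(m) alphabet[which(
    bitwAnd(m, bitwShiftL(1L, seq_along(alphabet) - 1L)) > 0L)][1L],
    character(1L))
  node_region <- c(tip_region,
                   assignment$region[match((ntip + 1L):(ntip + tr$Nnode),
                                           assignment$node)])
  out <- numeric(0)
  for (i in seq_len(nrow(assignment))) {
    if (is.na(assignment$region[i])) next
    t <- assignment$age[i]; R <- assignment$region[i]
    cnt <- 0L
    for (j in seq_len(nrow(tr$edge))) {
      u <- tr$edge[j, 1L]; v <- tr$edge[j, 2L]
      if (ages[u] > t + 1e-9 && ages[v] <= t + 1e-9 &&
          !is.na(node_region[v]) && node_region[v] == R) cnt <- cnt + 1L
    }
    if (assignment$node[i] == ntip + 1L) cnt <- cnt + 1L
    out <- c(out, cnt)
  }
  out
}
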
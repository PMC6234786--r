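# Synthetic-data generators: crown-conditioned birth-death chronograms with
# piecewise-constant rates and incomplete sampling, continuous-time
# biogeographic histories with recorded truth, pseudo-posterior node-age
# perturbation, and a bundled fixture shaped like a ~60-Myr, 4-region
# dryland radiation with a Miocene rate shift.
#
# Conventions: rate vectors are youngest-epoch first; `shift_times` are
# strictly increasing ages (Ma) so epoch i covers [s_{i-1}, s_i).

# Epoch index containing age `a` (age 0 = present). Boundaries c(0, shifts).
.epoch_of <- function(a, shift_times) {
  findInterval(a, c(0, shift_times))
}

# One piecewise-exponential event age walking from age `a` toward 0.
# Returns -Inf when the lineage reaches the present without an event.
.draw_event_age <- function(a, bnd, rate) {
  i <- findInterval(a, bnd)
  repeat {
    lo <- bnd[i]
    if (rate[i] <= 0) {
      if (i == 1L) return(-Inf)
      a <- lo; i <- i - 1L
      next
    }
    cand <- a - stats::rexp(1L, rate[i])
    if (cand >= lo) return(if (i == 1L && cand <= 0) -Inf else cand)
    if (i == 1L) return(-Inf)
    a <- lo; i <- i - 1L
  }
}

#' Simulate a crown-conditioned birth-death chronogram
#'
#' Forward (simple-sampling) simulation from two lineages at the crown age
#' under piecewise-constant speciation/extinction rates; extinct lineages
#' are pruned and each surviving tip is retained independently with
#' probability `rho`.  The simulation is repeated until each crown subtree
#' retains at least `min_tips_per_side` sampled tips (the default, 1, is
#' plain crown survival, under which the pure-birth expectation
#' `E[N] = 2 exp(lambda * T)` holds exactly).
#'
#' @param crown_age crown age in Ma.
#' @param lambda speciation rates per lineage/Myr, youngest epoch first.
#' @param mu extinction rates, recycled to match `lambda`.
#' @param shift_times strictly increasing epoch boundaries (Ma);
#'   `length(lambda) - 1` of them.
#' @param rho sampling fraction in (0, 1].
#' @param min_tips_per_side conditioning: minimum sampled tips per crown
#'   subtree (>= 1 keeps the crown age of the pruned tree equal to
#'   `crown_age`).
#' @param max_attempts resimulation budget before an error.
#' @param seed RNG seed.
#' @return a list with elements `tree` (pruned sampled chronogram, `phylo`),
#'   and `truth` (complete/extant/sampled tip counts, the rate epochs, and
#'   the number of attempts used).
#' @export
simulate_bd_tree <- function(crown_age, lambda, mu = 0,
                             shift_times = numeric(), rho = 1,
                             min_tips_per_side = 1L, max_attempts = 1000L,
                             seed = NULL) {
  k <- length(shift_times)
  lambda <- rep_len(lambda, k + 1L)
  mu <- rep_len(mu, k + 1L)
  stopifnot(crown_age > 0, all(lambda > 0), all(mu >= 0),
            rho > 0, rho <= 1, min_tips_per_side >= 1L)
  if (k > 0L && (any(diff(shift_times) <= 0) || any(shift_times <= 0) ||
                 any(shift_times >= crown_age))) {
    stop_drydiv("drydiv_bad_epochs",
                "shift_times must be strictly increasing inside (0, crown_age)")
  }
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      sim <- .sim_bd_once(crown_age, lambda, mu, shift_times, rho,
                          min_tips_per_side)
      if (!is.null(sim)) {
        sim$truth$attempts <- attempt
        return(sim)
      }
    }
    stop_drydiv("drydiv_conditioning",
                "conditioning not met in %d attempts", max_attempts)
  })
}

.sim_bd_once <- function(crown_age, lambda, mu, shift_times, rho,
                         min_side) {
  bnd <- c(0, shift_times)
  rate_tot <- lambda + mu
  pspec <- lambda / rate_tot
  cap <- 256L
  birth <- end <- numeric(cap)
  type <- parent <- c1 <- c2 <- side <- integer(cap)  # type 1 tip, 2 dead, 3 split
  nlin <- 2L
  birth[1:2] <- crown_age; parent[1:2] <- 0L; side[1:2] <- 1:2
  stack <- c(1L, 2L)
  while (length(stack) > 0L) {
    id <- stack[length(stack)]; stack <- stack[-length(stack)]
    ev <- .draw_event_age(birth[id], bnd, rate_tot)
    if (ev == -Inf) {                      # reaches the present
      type[id] <- 1L; end[id] <- 0
    } else {
      ep <- .epoch_of(ev, shift_times)
      if (stats::runif(1L) < pspec[ep]) {  # speciation
        if (nlin + 2L > cap) {
          cap <- cap * 2L
          length(birth) <- cap; length(end) <- cap; length(type) <- cap
          length(parent) <- cap; length(c1) <- cap; length(c2) <- cap
          length(side) <- cap
          birth[is.na(birth)] <- 0; end[is.na(end)] <- 0
          type[is.na(type)] <- 0L; parent[is.na(parent)] <- 0L
          c1[is.na(c1)] <- 0L; c2[is.na(c2)] <- 0L; side[is.na(side)] <- 0L
        }
        type[id] <- 3L; end[id] <- ev
        kid <- nlin + 1:2
        birth[kid] <- ev; parent[kid] <- id; side[kid] <- side[id]
        c1[id] <- kid[1L]; c2[id] <- kid[2L]
        nlin <- nlin + 2L
        stack <- c(stack, kid)
        if (nlin > 2e5L) {
          stop_drydiv("drydiv_explosion",
                      "simulated tree exceeded 2e5 lineages; lower the rates")
        }
      } else {                             # extinction
        type[id] <- 2L; end[id] <- ev
      }
    }
  }
  idx <- seq_len(nlin)
  term <- idx[type[idx] %in% c(1L, 2L)]
  extant <- idx[type[idx] == 1L]
  if (length(extant) == 0L) return(NULL)
  sampled <- extant[stats::runif(length(extant)) < rho]
  for (s in 1:2) {
    if (sum(side[sampled] == s) < min_side) return(NULL)
  }
  # Assemble the complete phylo, then keep only sampled extant tips.
  ntip <- length(term)
  nnode <- sum(type[idx] == 3L) + 1L
  node_of <- integer(nlin)
  node_of[term] <- seq_len(ntip)
  splits <- idx[type[idx] == 3L]
  node_of[splits] <- ntip + 1L + seq_along(splits)
  edge <- matrix(0L, nlin, 2L)
  elen <- numeric(nlin)
  for (j in idx) {
    pn <- if (parent[j] == 0L) ntip + 1L else node_of[parent[j]]
    edge[j, ] <- c(pn, node_of[j])
    elen[j] <- birth[j] - end[j]
  }
  labels <- paste0("t", term)
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = labels, Nnode = nnode),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  keep <- paste0("t", sampled)
  tree <- if (length(keep) < ntip) ape::keep.tip(phy, keep) else phy
  list(tree = tree,
       truth = list(n_complete = ntip,
                    n_extant = length(extant),
                    n_sampled = length(sampled),
                    lambda = lambda, mu = mu, shift_times = shift_times,
                    rho = rho, crown_age = crown_age))
}

#' Count sampled present-day descendants of a single lineage (forward simulation)
#'
#' Monte-Carlo oracle for the birth-death survival/sampling probability
#' `p0`: simulates `n` independent lineages starting at age `t0` under
#' piecewise-constant rates, and returns, for each, the number of
#' descendants alive at the present that pass `rho`-sampling.  Fully
#' vectorized across replicates.
#'
#' @inheritParams simulate_bd_tree
#' @param t0 starting age of the lineage (Ma).
#' @param n number of replicate lineages.
#' @return integer vector of length `n`; `mean(out == 0)` estimates `p0(t0)`.
#' @export
simulate_sampled_descendants <- function(t0, lambda, mu = 0,
                                         shift_times = numeric(), rho = 1,
                                         n = 10000L, seed = NULL) {
  k <- length(shift_times)
  lambda <- rep_len(lambda, k + 1L)
  mu <- rep_len(mu, k + 1L)
  bnd <- c(0, shift_times)
  rate_tot <- lambda + mu
  pspec <- lambda / rate_tot
  with_seed(seed, {
    counts <- integer(n)
    age <- rep.int(t0, n)
    rep_id <- seq_len(n)
    while (length(age) > 0L) {
      m <- length(age)
      ev <- rep.int(NA_real_, m)
      cur <- age
      idx <- findInterval(cur, bnd)
      open <- rep.int(TRUE, m)
      while (any(open)) {
        pos <- which(open)
        r <- rate_tot[idx[pos]]
        w <- ifelse(r > 0, stats::rexp(length(pos), pmax(r, 1e-300)), Inf)
        cand <- cur[pos] - w
        lo <- bnd[idx[pos]]
        hit <- cand >= lo & !(idx[pos] == 1L & cand <= 0)
        ev[pos[hit]] <- cand[hit]
        open[pos[hit]] <- FALSE
        deeper <- !hit & idx[pos] > 1L
        cur[pos[deeper]] <- lo[deeper]
        idx[pos[deeper]] <- idx[pos[deeper]] - 1L
        open[pos[!hit & !deeper]] <- FALSE  # reached the present
      }
      surv <- is.na(ev)
      if (any(surv)) {
        keep_s <- stats::runif(sum(surv)) < rho
        tab <- tabulate(rep_id[surv][keep_s], nbins = n)
        counts <- counts + tab
      }
      evp <- which(!surv)
      if (length(evp) > 0L) {
        ep <- .epoch_of(ev[evp], shift_times)
        spec <- stats::runif(length(evp)) < pspec[ep]
        born <- evp[spec]
        age <- rep(ev[born], each = 2L)
        rep_id <- rep(rep_id[born], each = 2L)
      } else {
        age <- numeric(0); rep_id <- integer(0)
      }
    }
    counts
  })
}

# All non-empty proper submasks of a bitmask.
.proper_submasks <- function(mask) {
  bits <- which(bitwAnd(mask, bitwShiftL(1L, 0:15)) > 0L) - 1L
  nb <- length(bits)
  if (nb < 2L) return(integer(0))
  subs <- integer(2^nb - 2L)
  j <- 0L
  for (s in 1:(2^nb - 2L)) {
    m <- 0L
    for (b in seq_len(nb)) {
      if (bitwAnd(s, bitwShiftL(1L, b - 1L)) > 0L) {
        m <- bitwOr(m, bitwShiftL(1L, bits[b]))
      }
    }
    j <- j + 1L
    subs[j] <- m
  }
  subs
}

#' Simulate a biogeographic history along a chronogram
#'
#' Continuous-time gain/loss of areas along branches: each absent area is
#' gained at rate `dispersal` and each present area lost at rate
#' `extirpation` (loss forbidden when the range has size one).  At each
#' speciation a single-area range is duplicated into both daughters; a
#' widespread range is split by a uniformly random bipartition into two
#' non-empty disjoint subsets (vicariance).  Returns observed tip ranges
#' plus the full true history.
#'
#' @param phy a chronogram (`phylo`).
#' @param dispersal per-absent-area gain rate (events/lineage/Myr).
#' @param extirpation per-present-area loss rate.
#' @param alphabet area codes.
#' @param root_range compound code of the range at the root (e.g. `"A"`).
#' @param seed RNG seed.
#' @return list with `regions` (a [region_table()]), and `truth`:
#'   `node_range` (compound code per ape node id, tips included),
#'   `events` (data.frame: `node` = child node of the branch, `age`, `area`,
#'   `type` gain/loss), and the configuration.
#' @export
simulate_ranges <- function(phy, dispersal = 0.002, extirpation = 0.001,
                            alphabet = c("A", "B", "C", "D"),
                            root_range = "A", seed = NULL) {
  stopifnot(dispersal >= 0, extirpation >= 0)
  phy <- validate_chronogram(phy)
  root_mask <- label_to_mask(root_range, alphabet)
  if (is.na(root_mask)) {
    stop_drydiv("drydiv_unknown_area", "root_range outside the alphabet")
  }
  nA <- length(alphabet)
  full <- bitwShiftL(1L, nA) - 1L
  ntip <- ape::Ntip(phy)
  ages <- node_ages(phy)
  phy <- ape::reorder.phylo(phy, "cladewise")
  nnode <- ntip + phy$Nnode
  state <- integer(nnode)
  root <- ntip + 1L
  state[root] <- root_mask
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  ev_node <- integer(0); ev_age <- numeric(0); ev_area <- character(0)
  ev_type <- character(0)
  with_seed(seed, {
    # preorder over internal nodes (cladewise parents precede children)
    ord <- unique(phy$edge[, 1L])
    for (u in ord) {
      eidx <- children[[as.character(u)]]
      kids <- phy$edge[eidx, 2L]
      pmask <- state[u]
      if (popcount(pmask) == 1L) {
        inherit <- c(pmask, pmask)
      } else {
        subs <- .proper_submasks(pmask)
        s <- subs[sample.int(length(subs), 1L)]
        inherit <- c(s, bitwAnd(pmask, bitwNot(s)))
      }
      for (j in seq_along(kids)) {
        v <- kids[j]
        cur <- inherit[j]
        a <- ages[u]
        tgt <- ages[v]
        repeat {
          npres <- popcount(cur)
          rg <- dispersal * (nA - npres)
          rl <- if (npres >= 2L) extirpation * npres else 0
          tot <- rg + rl
          if (tot <= 0) break
          a <- a - stats::rexp(1L, tot)
          if (a <= tgt) break
          if (stats::runif(1L) < rg / tot) {  # gain
            absent <- which(bitwAnd(full, bitwNot(cur)) %/%
                              bitwShiftL(1L, 0:(nA - 1L)) %% 2L == 1L)
            pick <- absent[sample.int(length(absent), 1L)]
            cur <- bitwOr(cur, bitwShiftL(1L, pick - 1L))
            ev_node <- c(ev_node, v); ev_age <- c(ev_age, a)
            ev_area <- c(ev_area, alphabet[pick]); ev_type <- c(ev_type, "gain")
          } else {                            # loss
            present <- which(cur %/% bitwShiftL(1L, 0:(nA - 1L)) %% 2L == 1L)
            pick <- present[sample.int(length(present), 1L)]
            cur <- bitwAnd(cur, bitwNot(bitwShiftL(1L, pick - 1L)))
            ev_node <- c(ev_node, v); ev_age <- c(ev_age, a)
            ev_area <- c(ev_area, alphabet[pick]); ev_type <- c(ev_type, "loss")
          }
        }
        state[v] <- cur
      }
    }
  })
  regions <- region_table(phy$tip.label,
                          mask_to_label(state[seq_len(ntip)], alphabet),
                          alphabet)
  list(regions = regions,
       truth = list(node_range = mask_to_label(state, alphabet),
                    events = data.frame(node = ev_node, age = ev_age,
                                        area = ev_area, type = ev_type,
                                        stringsAsFactors = FALSE),
                    dispersal = dispersal, extirpation = extirpation,
                    root_range = root_range, alphabet = alphabet))
}

#' Pseudo-posterior tree sample by node-age perturbation
#'
#' Stands in for a Bayesian posterior: each replicate multiplies every
#' internal-node age by independent mean-one lognormal noise with relative
#' SD `age_cv`, then repairs monotonicity top-down so every parent stays
#' older than its children.  Topology is unchanged; branch lengths are
#' recomputed from the repaired ages so trees stay ultrametric.
#'
#' @param phy the template chronogram.
#' @param n number of replicate trees.
#' @param age_cv relative SD of the age noise, in [0, 0.5).
#' @param seed RNG seed.
#' @return a [tree_sample()] with `phy` as representative, provenance
#'   `"synthetic"`.
#' @export
pseudo_posterior <- function(phy, n, age_cv = 0.1, seed = NULL) {
  stopifnot(n >= 1, age_cv >= 0, age_cv < 0.5)
  phy <- validate_chronogram(phy)
  ntip <- ape::Ntip(phy)
  ages <- node_ages(phy)
  phy <- ape::reorder.phylo(phy, "cladewise")
  sdlog <- sqrt(log(1 + age_cv^2))
  trees <- with_seed(seed, lapply(seq_len(n), function(i) {
    a <- ages
    noise <- stats::rlnorm(phy$Nnode, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    a[(ntip + 1L):(ntip + phy$Nnode)] <-
      a[(ntip + 1L):(ntip + phy$Nnode)] * noise
    # top-down repair: parent must stay strictly older than child
    for (j in seq_len(nrow(phy$edge))) {
      u <- phy$edge[j, 1L]; v <- phy$edge[j, 2L]
      if (v > ntip && a[v] >= a[u]) a[v] <- a[u] * (1 - 1e-9)
    }
    if (any(a[(ntip + 1L):(ntip + phy$Nnode)] <= 0)) {
      stop_drydiv("drydiv_degenerate_ages", "age repair failed (non-positive age)")
    }
    out <- phy
    out$edge.length <- a[phy$edge[, 1L]] - a[phy$edge[, 2L]]
    out
  }))
  tree_sample(trees, representative = phy, provenance = "synthetic",
              validate = FALSE)
}

#' Bundled synthetic fixture: a 4-region dryland-like radiation
#'
#' One seeded call produces the whole data bundle the pipeline consumes: a
#' representative (MCC-role) chronogram with ~60 Ma crown age simulated
#' under a one-shift pure-birth model (net rate 0.053 -> 0.142 species/Myr
#' at 10.4 Ma), 55% uniform tip sampling, a biogeographic history rooted in
#' region A, a pseudo-posterior sample, a one-row clade-richness table from
#' the known complete species count, and the full simulation truth.
#'
#' @param seed RNG seed (drives every stage).
#' @param dir if non-NULL, write `mcc.nwk`, `posterior.nwk`, `regions.tsv`,
#'   `richness.tsv`, `truth.json` there (byte-identical under the same
#'   seed).
#' @param n_posterior number of pseudo-posterior trees.
#' @param crown_age,lambda,mu,shift_times,rho birth-death world; defaults
#'   follow the fitted one-shift model of the motivating dryland clade.
#' @param dispersal,extirpation,root_range biogeographic world.
#' @param age_cv pseudo-posterior age noise.
#' @return list with `trees` (a [tree_sample()], representative attached),
#'   `regions`, `richness`, `truth`.
#' @export
dryland_fixture <- function(seed = 1L, dir = NULL, n_posterior = 100L,
                            crown_age = 59.89, lambda = c(0.142, 0.053),
                            mu = 0, shift_times = 10.4, rho = 0.55,
                            dispersal = 0.002, extirpation = 0.001,
                            root_range = "A", age_cv = 0.1) {
  alphabet <- c("A", "B", "C", "D")
  bd <- simulate_bd_tree(crown_age, lambda, mu, shift_times, rho,
                         min_tips_per_side = 2L,
                         seed = derive_seed(seed, 1L))
  rg <- simulate_ranges(bd$tree, dispersal, extirpation, alphabet,
                        root_range, seed = derive_seed(seed, 2L))
  trees <- pseudo_posterior(bd$tree, n_posterior, age_cv,
                            seed = derive_seed(seed, 3L))
  richness <- data.frame(clade = "all",
                         sampled = ape::Ntip(bd$tree),
                         described = bd$truth$n_extant,
                         stringsAsFactors = FALSE)
  truth <- list(bd = bd$truth, ranges = rg$truth)
  out <- list(trees = trees, regions = rg$regions, richness = richness,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_chronogram(bd$tree, file.path(dir, "mcc.nwk"))
    ape::write.tree(structure(unclass(trees), class = "multiPhylo"),
                    file = file.path(dir, "posterior.nwk"))
    write_region_table(rg$regions, file.path(dir, "regions.tsv"))
    utils::write.table(richness, file.path(dir, "richness.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
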
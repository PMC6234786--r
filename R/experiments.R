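# Bookkeeping and simulation-recovery experiments used by the validation
# suite and the acceptance report.

#' Taxon-sampling bookkeeping
#'
#' @param n_sampled species included in the tree.
#' @param n_described species described for the clade.
#' @param n_outgroups outgroup taxa added to the matrix.
#' @return list: `percent_sampled` (100 * sampled / described), `rho`
#'   (fraction), `n_taxa` (sampled + outgroups).
#' @examples
#' sampling_summary(157, 285, 7)  # 55% sampling, 164 taxa
#' @export
sampling_summary <- function(n_sampled, n_described, n_outgroups = 0L) {
  stopifnot(n_sampled >= 1, n_described >= n_sampled, n_outgroups >= 0)
  list(percent_sampled = 100 * n_sampled / n_described,
       rho = n_sampled / n_described,
       n_taxa = n_sampled + n_outgroups)
}

#' Shift-model parameter-recovery experiment
#'
#' Simulates `n_trees` crown-conditioned birth-death trees under a known
#' one-shift model with uniform tip sampling, fits the one-shift model to
#' each by grid search ([fit_shifts()]), and summarizes the recovered
#' pre-shift (older-epoch) rate, post-shift (younger-epoch) rate and shift
#' time by their medians across replicates.
#'
#' @param n_trees number of replicate trees.
#' @param crown_age true crown age (Ma).
#' @param lambda,mu,shift_times true rates (youngest epoch first) and shift
#'   age.
#' @param rho sampling fraction applied uniformly to tips.
#' @param grid_step,start,end grid passed to [fit_shifts()]; `end` defaults
#'   to the crown age.
#' @param turnover passed to [fit_shifts()].
#' @param min_tips_per_side simulation conditioning: each crown subtree
#'   must retain at least this many sampled tips (the generator's
#'   resimulation rule for analysis-grade trees).
#' @param seed master seed; replicate r uses a seed derived from it.
#' @return list: `median_pre_rate`, `median_post_rate`,
#'   `median_shift_time`, and `replicates` (per-tree data.frame with tips,
#'   recovered rates and shift time).
#' @export
shift_recovery_experiment <- function(n_trees = 50L, crown_age = 59.89,
                                      lambda = c(0.142, 0.053), mu = 0,
                                      shift_times = 10.4, rho = 0.55,
                                      grid_step = 0.1, start = 8.7,
                                      end = NULL, turnover = "fixed",
                                      min_tips_per_side = 4L, seed = 1L) {
  end <- end %||% crown_age
  rows <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    sim <- simulate_bd_tree(crown_age, lambda, mu, shift_times, rho,
                            min_tips_per_side = min_tips_per_side,
                            seed = derive_seed(seed, i))
    bt <- extract_branching_times(sim$tree)
    fit <- fit_shifts(bt, kmax = 1L, grid_step = grid_step, start = start,
                      end = min(end, bt[1L] - grid_step), rho = rho,
                      turnover = turnover,
                      seed = derive_seed(seed, n_trees + i))
    f1 <- fit$fits[[2L]]
    rows[[i]] <- data.frame(rep = i, n_tips = length(bt) + 1L,
                            r_young = f1$r[1L], r_old = f1$r[2L],
                            shift_time = f1$shift_times[1L],
                            loglik = f1$loglik,
                            selected_k = fit$selected)
  }
  reps <- do.call(rbind, rows)
  list(median_pre_rate = stats::median(reps$r_old),
       median_post_rate = stats::median(reps$r_young),
       median_shift_time = stats::median(reps$shift_time),
       replicates = reps)
}
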
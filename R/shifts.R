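# Piecewise-constant birth-death likelihood on branching times with
# incomplete uniform sampling, grid search over shift times, and sequential
# likelihood-ratio model selection; plus the missing-taxa time-cutoff
# diagnostic.
#
# Model: a reconstructed tree of n sampled tips is conditioned on the crown
# age x1 and survival (>= 1 sampled descendant) of both crown lineages.
# p0(t) is the probability that a lineage alive at age t leaves no sampled
# descendant at the present; p1(t) the density companion.  Within a
# constant-rate epoch both have closed forms; across epochs they are
# propagated backward in time, continuity supplying the younger-boundary
# initial condition (the sampling fraction rho enters only at the present).
# logL = sum_{i>=2} [ln lambda(x_i) + ln p1(x_i)]
#        + 2 ln p1(x1) - 2 ln(1 - p0(x1)).

# One constant-rate epoch step: propagate (p0, p1) from the epoch's lower
# boundary across time increments dt (vector).  The Riccati solution is
# written with decaying exponentials only, so large r*t cannot overflow.
.bd_step <- function(dt, lam, mu, ps, p1s) {
  cdiff <- lam - mu
  if (abs(cdiff) * (max(dt, 0) + 1) < 1e-8) {   # lambda ~= mu: series limit
    lm <- (lam + mu) / 2
    if (1 - ps < 1e-15) return(list(p0 = rep.int(1, length(dt)),
                                    p1 = rep.int(0, length(dt))))
    D <- 1 / (1 - ps)
    return(list(p0 = 1 - 1 / (D + lm * dt),
                p1 = p1s * (D / (D + lm * dt))^2))
  }
  r2 <- mu / lam
  denom <- ps - r2
  if (abs(denom) < 1e-14) {                     # sitting on the fixed point
    return(list(p0 = rep.int(r2, length(dt)), p1 = p1s * exp(-cdiff * dt)))
  }
  ys <- (ps - 1) / denom
  if (cdiff > 0) {
    E <- exp(-cdiff * dt)
    list(p0 = (E - r2 * ys) / (E - ys),
         p1 = p1s * (1 - ys)^2 * E / (E - ys)^2)
  } else {
    E <- exp(cdiff * dt)
    yt <- ys * E
    list(p0 = (1 - r2 * yt) / (1 - yt),
         p1 = p1s * E * ((1 - ys) / (1 - yt))^2)
  }
}

# Piecewise p0/p1 at arbitrary ages t >= 0.  Rates youngest-epoch first.
.bd_pfuns <- function(t, lambda, mu, rho, shift_times = numeric()) {
  k <- length(shift_times)
  lambda <- rep_len(lambda, k + 1L)
  mu <- rep_len(mu, k + 1L)
  stopifnot(all(lambda > 0), all(mu >= 0), rho > 0, rho <= 1, all(t >= 0))
  bnd <- c(0, shift_times)
  p0 <- p1 <- numeric(length(t))
  ps <- 1 - rho
  p1s <- rho
  for (i in seq_len(k + 1L)) {
    upper <- if (i <= k) shift_times[i] else Inf
    sel <- t >= bnd[i] & t < upper
    if (i == k + 1L) sel <- t >= bnd[i]
    if (any(sel)) {
      stp <- .bd_step(t[sel] - bnd[i], lambda[i], mu[i], ps, p1s)
      p0[sel] <- stp$p0
      p1[sel] <- stp$p1
    }
    if (i <= k) {
      stp <- .bd_step(upper - bnd[i], lambda[i], mu[i], ps, p1s)
      ps <- stp$p0
      p1s <- stp$p1
    }
  }
  list(p0 = p0, p1 = p1)
}

#' Birth-death no-sampled-descendant probability p0(t)
#'
#' Probability that a lineage alive at age `t` leaves no sampled descendant
#' at the present, under piecewise-constant rates (youngest epoch first)
#' and uniform sampling fraction `rho`.  With a single epoch this is the
#' classical
#' `p0(t) = 1 - rho (lambda - mu) / (rho lambda + (lambda(1-rho) - mu) e^{-(lambda-mu) t})`;
#' the `lambda -> mu` limit is handled by a series guard.
#'
#' @param t age(s), Ma.
#' @param lambda,mu per-epoch rates (youngest first), recycled.
#' @param rho sampling fraction in (0, 1].
#' @param shift_times strictly increasing epoch boundaries (Ma).
#' @return numeric vector of probabilities.
#' @export
bd_p0 <- function(t, lambda, mu = 0, rho = 1, shift_times = numeric()) {
  .bd_pfuns(t, lambda, mu, rho, shift_times)$p0
}

#' Birth-death reconstructed-lineage density companion p1(t)
#'
#' With one epoch,
#' `p1(t) = rho (lambda-mu)^2 e^{-(lambda-mu) t} / (rho lambda + (lambda(1-rho) - mu) e^{-(lambda-mu) t})^2`;
#' across epochs it is propagated by continuity like [bd_p0()].
#'
#' @inheritParams bd_p0
#' @export
bd_p1 <- function(t, lambda, mu = 0, rho = 1, shift_times = numeric()) {
  .bd_pfuns(t, lambda, mu, rho, shift_times)$p1
}

.check_bt <- function(bt) {
  bt <- sort(as.numeric(bt), decreasing = TRUE)
  if (length(bt) < 1L || any(bt <= 0) || any(!is.finite(bt))) {
    stop_drydiv("drydiv_bad_bt", "branching times must be positive and finite")
  }
  bt
}

#' Constant-rate sampled birth-death log-likelihood
#'
#' Closed-form constant-rate density of the branching times, conditioned on
#' the crown age and on both crown lineages leaving sampled descendants.
#' Kept as a separate code path from [loglik_piecewise()] so the two can
#' cross-check each other.
#'
#' @param bt branching times (any order; sorted internally).
#' @inheritParams bd_p0
#' @return log-likelihood (may be `-Inf` when the data are impossible).
#' @export
loglik_constant <- function(bt, lambda, mu = 0, rho = 1) {
  stopifnot(length(lambda) == 1L, length(mu) == 1L, lambda > 0, mu >= 0,
            rho > 0, rho <= 1)
  bt <- .check_bt(bt)
  cdiff <- lambda - mu
  x1 <- bt[1L]
  if (abs(cdiff) * (x1 + 1) < 1e-8) {
    lm <- (lambda + mu) / 2
    p0 <- 1 - rho / (1 + rho * lm * bt)
    p1 <- rho / (1 + rho * lm * bt)^2
  } else {
    E <- exp(-cdiff * bt)
    den <- rho * lambda + (lambda * (1 - rho) - mu) * E
    p0 <- 1 - rho * cdiff / den
    p1 <- rho * cdiff^2 * E / den^2
  }
  ll <- sum(log(lambda) + log(p1[-1L])) + 2 * log(p1[1L]) -
    2 * log1p(-p0[1L])
  if (is.nan(ll)) {
    stop_drydiv("drydiv_loglik_nan",
                "non-finite likelihood at lambda=%g mu=%g rho=%g", lambda,
                mu, rho)
  }
  ll
}

#' Piecewise-constant birth-death log-likelihood
#'
#' @inheritParams loglik_constant
#' @param shift_times strictly increasing shift ages inside (0, crown age).
#' @param lambda,mu per-epoch rates, youngest epoch first
#'   (`length(shift_times) + 1` of each, recycled).
#' @return log-likelihood; identical to [loglik_constant()] when all epochs
#'   share one rate pair.
#' @export
loglik_piecewise <- function(bt, lambda, mu = 0, rho = 1,
                             shift_times = numeric()) {
  bt <- .check_bt(bt)
  x1 <- bt[1L]
  if (length(shift_times) > 0L &&
      (any(shift_times >= x1) || any(shift_times <= 0) ||
       any(diff(shift_times) <= 0))) {
    stop_drydiv("drydiv_bad_epochs",
                "shift times must be strictly increasing inside (0, crown age)")
  }
  pf <- .bd_pfuns(bt, lambda, mu, rho, shift_times)
  k <- length(shift_times)
  lam_at <- rep_len(lambda, k + 1L)[findInterval(bt, c(0, shift_times))]
  ll <- sum(log(lam_at[-1L]) + log(pf$p1[-1L])) + 2 * log(pf$p1[1L]) -
    2 * log1p(-pf$p0[1L])
  if (is.nan(ll)) {
    stop_drydiv("drydiv_loglik_nan",
                "non-finite likelihood at lambda=%s mu=%s rho=%g",
                paste(lambda, collapse = ","), paste(mu, collapse = ","), rho)
  }
  ll
}

# Fast likelihood evaluator for the optimizer: `bt` sorted descending and
# the epoch partition of the branching times precomputed once per set of
# shift times.  Identical arithmetic to loglik_piecewise() (same .bd_step),
# minus per-call validation.
.loglik_factory <- function(bt, rho, shift_times) {
  k <- length(shift_times)
  bnd <- c(0, shift_times)
  groups <- lapply(seq_len(k + 1L), function(i) {
    upper <- if (i <= k) shift_times[i] else Inf
    which(bt >= bnd[i] & bt < upper)
  })
  dts <- lapply(seq_len(k + 1L), function(i) bt[groups[[i]]] - bnd[i])
  lam_idx <- findInterval(bt, bnd)
  sum_logp1 <- function(lambda, mu) {
    p1 <- numeric(length(bt))
    p0_x1 <- NA_real_
    ps <- 1 - rho; p1s <- rho
    for (i in seq_len(k + 1L)) {
      g <- groups[[i]]
      if (length(g) > 0L) {
        stp <- .bd_step(dts[[i]], lambda[i], mu[i], ps, p1s)
        p1[g] <- stp$p1
        if (1L %in% g) p0_x1 <- stp$p0[match(1L, g)]
      }
      if (i <= k) {
        stp <- .bd_step(shift_times[i] - bnd[i], lambda[i], mu[i], ps, p1s)
        ps <- stp$p0; p1s <- stp$p1
      }
    }
    list(p1 = p1, p0_x1 = p0_x1)
  }
  function(lambda, mu) {
    pp <- sum_logp1(lambda, mu)
    sum(log(lambda[lam_idx[-1L]]) + log(pp$p1[-1L])) +
      2 * log(pp$p1[1L]) - 2 * log1p(-pp$p0_x1)
  }
}

# Inner MLE for fixed shift times, parameterized as (net rate r_i,
# turnover eps_i) per epoch: lambda = r/(1-eps), mu = lambda*eps.
# starts: matrix, one start per row.  Returns par, loglik, convergence.
.fit_epochs <- function(bt, shift_times, rho, starts, turnover_free = TRUE,
                        turnover_value = 0, r_bounds = c(1e-4, 5),
                        maxit = 300L) {
  m <- length(shift_times) + 1L
  llfun <- .loglik_factory(bt, rho, shift_times)
  negll <- function(par) {
    r <- par[seq_len(m)]
    eps <- if (turnover_free) par[m + seq_len(m)] else rep.int(turnover_value, m)
    lam <- r / (1 - eps)
    ll <- llfun(lam, lam * eps)
    if (is.na(ll) || !is.finite(ll)) 1e12 else -ll
  }
  lower <- c(rep.int(r_bounds[1L], m), if (turnover_free) rep.int(0, m))
  upper <- c(rep.int(r_bounds[2L], m), if (turnover_free) rep.int(0.999, m))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(starts[i, ], lower), upper), negll,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    return(list(par = starts[1L, ], loglik = -Inf, convergence = 99L))
  }
  r <- best$par[seq_len(m)]
  eps <- if (turnover_free) best$par[m + seq_len(m)] else
    rep.int(turnover_value, m)
  list(par = best$par, r = r, eps = eps, lambda = r / (1 - eps),
       mu = r * eps / (1 - eps), loglik = -best$value,
       convergence = best$convergence)
}

.moment_start <- function(bt, rho, m, turnover_free) {
  n <- length(bt) + 1L
  r0 <- max(log(max(n / rho, 3) / 2) / bt[1L], 2e-4)
  c(rep.int(r0, m), if (turnover_free) rep.int(0.1, m))
}

#' Grid-search rate-shift detection with sequential LRT selection
#'
#' Fits piecewise-constant birth-death models with k = 0, 1, ... `kmax`
#' shifts.  Shift times are searched on a regular age grid (exhaustive for
#' k = 1, warm-started along the grid; greedy placement plus
#' coordinate-wise grid refinement for k >= 2).  Per-epoch rates are
#' profiled by bounded quasi-Newton optimization in the (net rate,
#' turnover) parameterization from multiple starts.  Nested models are
#' compared by sequential likelihood-ratio tests against a chi-square with
#' `df_per_shift` degrees of freedom per added shift (default 3: two rates
#' plus one time; p-values under the df = 2 convention are reported
#' alongside), stopping at the first non-significant step.
#'
#' @param x a chronogram (`phylo`) or a numeric vector of branching times.
#' @param kmax maximum number of shifts to consider.
#' @param grid_step shift-time grid resolution, Ma.
#' @param start youngest candidate shift age (e.g. a missing-taxa cutoff);
#'   default `grid_step`.
#' @param end oldest candidate shift age; default just below the crown age.
#' @param rho sampling fraction.
#' @param df_per_shift degrees of freedom charged per shift (3 or 2).
#' @param alpha LRT significance level.
#' @param n_starts optimizer starts for k = 0 and for polishing the best
#'   grid placement (grid points themselves use a warm start plus a
#'   moment-based start).
#' @param turnover `"free"` (estimate per-epoch extinction) or `"fixed"`.
#' @param turnover_value turnover used when `turnover = "fixed"`.
#' @param seed seed for the random optimizer starts.
#' @return a `shift_model_comparison`: `table` (one row per k with logL,
#'   LRT statistic, p-values under both df conventions, selection flag),
#'   `fits` (full per-k parameter sets), `selected` (chosen k).
#' @export
fit_shifts <- function(x, kmax = 1L, grid_step = 0.1, start = NULL,
                       end = NULL, rho = 1, df_per_shift = 3L, alpha = 0.05,
                       n_starts = 5L, turnover = c("free", "fixed"),
                       turnover_value = 0, seed = NULL) {
  turnover <- match.arg(turnover)
  tf <- turnover == "free"
  bt <- if (inherits(x, "phylo")) extract_branching_times(x) else .check_bt(x)
  x1 <- bt[1L]
  start <- start %||% grid_step
  end <- end %||% (x1 - grid_step)
  stopifnot(kmax >= 0L, grid_step > 0, start < end, end <= x1)
  grid <- seq(start, min(end, x1 - grid_step / 2), by = grid_step)
  if (kmax >= 1L && length(grid) == 0L) {
    stop_drydiv("drydiv_bad_grid", "no candidate shift times on the grid")
  }

  rand_starts <- function(m) {
    with_seed(seed, {
      rs <- matrix(stats::runif((n_starts - 1L) * m, 0.005, 1), ncol = m)
      if (tf) cbind(rs, matrix(stats::runif((n_starts - 1L) * m, 0, 0.8),
                               ncol = m)) else rs
    })
  }
  fits <- vector("list", kmax + 1L)

  # k = 0
  m <- 1L
  starts0 <- rbind(.moment_start(bt, rho, m, tf), rand_starts(m))
  f0 <- .fit_epochs(bt, numeric(), rho, starts0, tf, turnover_value)
  f0$k <- 0L; f0$shift_times <- numeric()
  fits[[1L]] <- f0

  k <- 1L
  while (k <= kmax) {
    prev <- fits[[k]]
    if (k == 1L) {
      best <- NULL
      # inherit the (k-1)-model rates as the cold start for the first grid
      # point; afterwards warm-start from the neighbouring placement
      warm <- NULL
      inherit <- matrix(c(rep(prev$r, 2L)[1:2],
                          if (tf) rep(prev$eps, 2L)[1:2]), nrow = 1L)
      for (s in grid) {
        st <- if (is.null(warm)) inherit else warm
        f <- .fit_epochs(bt, s, rho, st, tf, turnover_value)
        warm <- matrix(f$par, nrow = 1L)
        if (is.null(best) || f$loglik > best$loglik) {
          best <- f; best$shift_times <- s
        }
      }
      # polish the winning placement with the full multistart
      st <- rbind(matrix(best$par, nrow = 1L),
                  .moment_start(bt, rho, 2L, tf), rand_starts(2L))
      f <- .fit_epochs(bt, best$shift_times, rho, st, tf, turnover_value)
      if (f$loglik >= best$loglik) {
        f$shift_times <- best$shift_times
        best <- f
      }
    } else {
      # greedy: add one shift to the previous set, then refine each
      # coordinate over the grid
      base <- prev$shift_times
      best <- NULL
      warm <- NULL
      for (s in grid) {
        if (any(abs(s - base) < grid_step / 2)) next
        sh <- sort(c(base, s))
        st <- rbind(.moment_start(bt, rho, k + 1L, tf))
        if (!is.null(warm)) st <- rbind(warm, st)
        f <- .fit_epochs(bt, sh, rho, st, tf, turnover_value)
        warm <- matrix(f$par, nrow = 1L)
        if (is.null(best) || f$loglik > best$loglik) {
          best <- f; best$shift_times <- sh
        }
      }
      if (is.null(best)) break
      for (ci in seq_len(k)) {   # one sweep of coordinate refinement
        for (s in grid) {
          sh <- best$shift_times
          if (any(abs(s - sh[-ci]) < grid_step / 2)) next
          sh[ci] <- s
          sh <- sort(sh)
          f <- .fit_epochs(bt, sh, rho, matrix(best$par, nrow = 1L), tf,
                           turnover_value)
          if (f$loglik > best$loglik) { best <- f; best$shift_times <- sh }
        }
      }
    }
    best$k <- k
    fits[[k + 1L]] <- best
    # nesting guard: k shifts can always reproduce k-1
    if (best$loglik < prev$loglik - 1e-6) {
      best$loglik <- prev$loglik
      best$r <- rep_len(prev$r, k + 1L); best$eps <- rep_len(prev$eps, k + 1L)
      fits[[k + 1L]] <- best
    }
    lrt <- 2 * (best$loglik - prev$loglik)
    if (stats::pchisq(lrt, df_per_shift, lower.tail = FALSE) >= alpha) break
    k <- k + 1L
  }
  fits <- fits[!vapply(fits, is.null, logical(1L))]

  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    lrt <- if (i == 1L) NA_real_ else 2 * (f$loglik - fits[[i - 1L]]$loglik)
    data.frame(k = f$k,
               shift_times = paste(round(f$shift_times, 6), collapse = ","),
               loglik = f$loglik,
               lrt = lrt,
               df = if (i == 1L) NA_integer_ else df_per_shift,
               p = if (i == 1L) NA_real_ else
                 stats::pchisq(lrt, df_per_shift, lower.tail = FALSE),
               p_df2 = if (i == 1L) NA_real_ else
                 stats::pchisq(lrt, 2L * (f$k - fits[[i - 1L]]$k),
                               lower.tail = FALSE),
               converged = f$convergence == 0L,
               stringsAsFactors = FALSE)
  }))
  selected <- 0L
  for (i in seq_len(nrow(tab))[-1L]) {
    if (!is.na(tab$p[i]) && tab$p[i] < alpha) selected <- tab$k[i] else break
  }
  tab$selected <- tab$k == selected
  structure(list(table = tab, fits = fits, selected = selected,
                 rho = rho, alpha = alpha, df_per_shift = df_per_shift,
                 grid = grid, branching_times = bt),
            class = "shift_model_comparison")
}

#' @export
print.shift_model_comparison <- function(x, ...) {
  cat(sprintf("Birth-death shift-model comparison (rho = %g, alpha = %g, df/shift = %d)\n",
              x$rho, x$alpha, x$df_per_shift))
  print(x$table, row.names = FALSE)
  f <- x$fits[[x$selected + 1L]]
  cat(sprintf("selected: %d shift(s)%s; net rates (young -> old): %s\n",
              x$selected,
              if (x$selected > 0L)
                sprintf(" at %s Ma", paste(round(f$shift_times, 2),
                                           collapse = ", ")) else "",
              paste(signif(f$r, 4), collapse = " | ")))
  invisible(x)
}

#' Missing-taxa time-cutoff diagnostic
#'
#' Heuristic profile of the fraction of lineages missing from the
#' reconstructed tree as a function of age: the observed lineage count
#' L(t) (from the tree's LTT) is compared with a crown-conditioned
#' constant-rate expectation `E(t) = N_total exp(-r t)` with
#' `r = ln(N_total / 2) / x1`, where `N_total` comes from the clade
#' richness table (unlisted tips are assumed fully sampled).  The reported
#' jump time is the youngest grid age at which the missing fraction rises
#' by more than `jump_threshold` toward the present between adjacent grid
#' points.  This is a documented surrogate diagnostic, not a fitted model.
#'
#' @param phy the chronogram.
#' @param richness a clade-richness data.frame (`clade`, `sampled`,
#'   `described`), or `NULL` for a fully sampled tree.
#' @param grid_step profile resolution, Ma.
#' @param jump_threshold minimal per-step increase flagged as the cutoff.
#' @return data.frame `t`, `expected`, `observed`, `missing` with
#'   attributes `jump_time`, `r_hat`, `N_total`.
#' @export
missing_fraction_profile <- function(phy, richness = NULL, grid_step = 0.1,
                                     jump_threshold = 0.05) {
  bt <- extract_branching_times(phy)
  n <- ape::Ntip(phy)
  N_total <- if (is.null(richness)) n else
    sum(richness$described) + (n - sum(richness$sampled))
  if (N_total < n) {
    stop_drydiv("drydiv_richness_invalid",
                "described total (%d) below sampled tip count (%d)", N_total, n)
  }
  x1 <- bt[1L]
  tg <- seq(0, x1, by = grid_step)
  r_hat <- log(N_total / 2) / x1
  expected <- N_total * exp(-r_hat * tg)
  observed <- 1 + vapply(tg, function(t) sum(bt >= t), numeric(1L))
  missing <- pmax(0, 1 - observed / expected)
  jump <- NA_real_
  if (length(tg) > 1L) {
    inc <- missing[-length(missing)] - missing[-1L]  # younger minus older
    hit <- which(inc > jump_threshold)
    if (length(hit) > 0L) jump <- tg[min(hit)]
  }
  out <- data.frame(t = tg, expected = expected, observed = observed,
                    missing = missing)
  attr(out, "jump_time") <- jump
  attr(out, "r_hat") <- r_hat
  attr(out, "N_total") <- N_total
  out
}
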
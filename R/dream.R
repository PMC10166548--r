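## Multi-chain differential-evolution MCMC with a past-state archive
## (DREAM(ZS) family): proposals are scaled difference vectors of two states
## sampled from an archive of past states, with subspace (crossover)
## sampling whose selection probabilities adapt during burn-in only, a
## discrete set of jump-size levels, and occasional unit jumps (gamma = 1)
## that allow mode swaps.  Optional snooker updates are implemented but off
## by default.

#' Sampler configuration
#'
#' @param n_chains number of parallel chains (>= 3 so that the Gelman-Rubin
#'   statistic is defined; default 4).
#' @param n_cr number of crossover values (CR = m / n_cr, m = 1..n_cr;
#'   default 25).
#' @param adaptive_gamma adapt the jump-size-level selection probabilities
#'   during burn-in (default `TRUE`).
#' @param p_gamma_unity probability of a gamma = 1 jump (default 0.10).
#' @param gamma_levels number of discrete jump-size levels (default 8).
#' @param burn_in iterations during which crossover (and jump-level)
#'   weights adapt; adaptation is frozen afterwards to preserve detailed
#'   balance.
#' @param max_steps maximum iterations per chain.
#' @param seed integer seed; the whole run is reproducible given the seed.
#' @param snooker_prob probability of a snooker update (default 0, i.e.
#'   archive-difference proposals only).
#' @param archive_thin append current states to the archive every this many
#'   iterations.
#' @param check_interval how often (iterations) convergence is checked in
#'   [run_until_converged()].
#' @param gr_threshold Gelman-Rubin stopping threshold (default 1.2).
#' @return An object of class `mm_sampler_config`.
#' @export
sampler_config <- function(n_chains = 4, n_cr = 25, adaptive_gamma = TRUE,
                           p_gamma_unity = 0.10, gamma_levels = 8,
                           burn_in = 1000, max_steps = 5000, seed = 1,
                           snooker_prob = 0, archive_thin = 10,
                           check_interval = 500, gr_threshold = 1.2) {
  stopifnot(n_chains >= 3, burn_in < max_steps, n_cr >= 1, gamma_levels >= 1,
            p_gamma_unity >= 0, p_gamma_unity <= 1)
  structure(list(n_chains = n_chains, n_cr = n_cr,
                 adaptive_gamma = adaptive_gamma,
                 p_gamma_unity = p_gamma_unity, gamma_levels = gamma_levels,
                 burn_in = burn_in, max_steps = max_steps, seed = seed,
                 snooker_prob = snooker_prob, archive_thin = archive_thin,
                 check_interval = check_interval, gr_threshold = gr_threshold),
            class = "mm_sampler_config")
}

#' Sample a posterior with archive-based differential-evolution MCMC
#'
#' @param logpost function of a parameter vector returning the log
#'   posterior density (may return `-Inf` for infeasible vectors).
#' @param priors prior specification (list of `mm_prior`, see [log_prior()]);
#'   used to initialize chains and seed the archive.
#' @param config an [sampler_config()].
#' @param par_names optional parameter names.
#' @param converge_stop stop early once the Gelman-Rubin statistic on the
#'   latter half of the traces is below `config$gr_threshold` for every
#'   parameter (checked every `config$check_interval` iterations after
#'   burn-in).
#' @param init optional matrix of initial states (chains by parameters).
#' @return An object of class `mm_chains`: list with `draws` (array
#'   iterations x parameters x chains), `logpost` (iterations x chains),
#'   `archive`, `burn_in`, `converged`, `gelman_rubin` (at termination) and
#'   the configuration.
#' @export
dream_sample <- function(logpost, priors, config = sampler_config(),
                         par_names = NULL, converge_stop = FALSE,
                         init = NULL) {
  d <- length(priors)
  N <- config$n_chains
  set.seed(config$seed)
  if (is.null(par_names)) par_names <- paste0("par", seq_len(d))

  ## archive seeded from the prior
  m0 <- max(50L, 10L * d)
  Z <- sample_prior(m0, priors)
  if (d == 1) Z <- matrix(Z, ncol = 1)

  ## initial states: prior draws with finite posterior (bounded retries)
  X <- matrix(NA_real_, N, d)
  lp <- rep(-Inf, N)
  if (!is.null(init)) {
    stopifnot(nrow(init) == N, ncol(init) == d)
    X <- init
    lp <- apply(X, 1, logpost)
    if (all(lp == -Inf)) stop("all supplied initial states are infeasible")
  } else {
    for (i in seq_len(N)) {
      for (try in 1:200) {
        x <- sample_prior(1, priors)
        v <- logpost(x)
        if (is.finite(v)) { X[i, ] <- x; lp[i] <- v; break }
      }
      if (!is.finite(lp[i]))
        stop("chain initialization failed: no feasible prior draw in 200 tries")
    }
  }

  T_ <- config$max_steps
  draws <- array(NA_real_, c(T_, d, N), dimnames = list(NULL, par_names, NULL))
  lptrace <- matrix(NA_real_, T_, N)

  ## crossover / jump-level selection weights (adapted during burn-in)
  nCR <- config$n_cr
  pCR <- rep(1 / nCR, nCR)
  dCR <- rep(0, nCR); nuse_CR <- rep(1e-6, nCR)
  nG <- config$gamma_levels
  pG <- rep(1 / nG, nG)
  dG <- rep(0, nG); nuse_G <- rep(1e-6, nG)

  converged <- FALSE; gr_final <- NULL; t_done <- T_
  for (t in seq_len(T_)) {
    sdX <- pmax(apply(X, 2, sd), 1e-12)
    for (i in seq_len(N)) {
      snooker <- runif(1) < config$snooker_prob
      if (snooker) {
        zi <- sample.int(nrow(Z), 3)
        z <- Z[zi[1], ]; za <- Z[zi[2], ]; zb <- Z[zi[3], ]
        dir <- X[i, ] - z
        nrm <- sum(dir * dir)
        if (nrm < 1e-300) next
        proj <- function(v) sum(v * dir) / nrm * dir
        gam <- runif(1, 1.2, 2.2)
        xp <- X[i, ] + gam * (proj(za) - proj(zb))
        lfwd <- (d - 1) / 2 * (log(sum((xp - z)^2)) - log(nrm))
        lpp <- logpost(xp)
        if (is.finite(lpp) && log(runif(1)) < lpp - lp[i] + lfwd) {
          X[i, ] <- xp; lp[i] <- lpp
        }
      } else {
        zi <- sample.int(nrow(Z), 2)
        diffz <- Z[zi[1], ] - Z[zi[2], ]
        mcr <- sample.int(nCR, 1, prob = pCR)
        mask <- runif(d) < mcr / nCR
        if (!any(mask)) mask[sample.int(d, 1)] <- TRUE
        dprime <- sum(mask)
        unity <- runif(1) < config$p_gamma_unity
        lev <- 1L
        if (unity) {
          gam <- 1
        } else {
          lev <- sample.int(nG, 1, prob = pG)
          gam <- 2.38 / sqrt(2 * dprime) / lev
        }
        e <- runif(1, -0.1, 0.1)
        jump <- numeric(d)
        jump[mask] <- (1 + e) * gam * diffz[mask] + rnorm(dprime, 0, 1e-6)
        xp <- X[i, ] + jump
        lpp <- logpost(xp)
        acc <- is.finite(lpp) && log(runif(1)) < lpp - lp[i]
        if (acc) {
          if (t <= config$burn_in) {
            jd <- sum(((xp - X[i, ]) / sdX)^2)
            dCR[mcr] <- dCR[mcr] + jd
            if (config$adaptive_gamma && !unity) dG[lev] <- dG[lev] + jd
          }
          X[i, ] <- xp; lp[i] <- lpp
        }
        if (t <= config$burn_in) {
          nuse_CR[mcr] <- nuse_CR[mcr] + 1
          if (config$adaptive_gamma && !unity) nuse_G[lev] <- nuse_G[lev] + 1
        }
      }
    }
    ## adapt selection weights during burn-in only
    if (t <= config$burn_in && t %% 10 == 0) {
      if (sum(dCR) > 0) {
        w <- dCR / nuse_CR
        pCR <- pmax(w / sum(w), 0.01 / nCR); pCR <- pCR / sum(pCR)
      }
      if (config$adaptive_gamma && sum(dG) > 0) {
        w <- dG / nuse_G
        pG <- pmax(w / sum(w), 0.01 / nG); pG <- pG / sum(pG)
      }
    }
    if (t %% config$archive_thin == 0) Z <- rbind(Z, X)
    draws[t, , ] <- t(X)
    lptrace[t, ] <- lp

    if (converge_stop && t > config$burn_in &&
        t %% config$check_interval == 0) {
      gr <- gelman_rubin(draws[seq_len(t), , , drop = FALSE])
      if (all(is.finite(gr)) && all(gr <= config$gr_threshold)) {
        converged <- TRUE; gr_final <- gr; t_done <- t
        break
      }
    }
  }
  draws <- draws[seq_len(t_done), , , drop = FALSE]
  lptrace <- lptrace[seq_len(t_done), , drop = FALSE]
  if (is.null(gr_final))
    gr_final <- gelman_rubin(draws)
  structure(list(draws = draws, logpost = lptrace, archive = Z,
                 burn_in = config$burn_in, par_names = par_names,
                 converged = converged, gelman_rubin = gr_final,
                 config = config),
            class = "mm_chains")
}

#' @export
print.mm_chains <- function(x, ...) {
  cat("MCMC archive:", dim(x$draws)[1], "iterations x", dim(x$draws)[2],
      "parameters x", dim(x$draws)[3], "chains\n")
  cat("  converged:", x$converged,
      " max Gelman-Rubin:", round(max(x$gelman_rubin), 3), "\n")
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computed per parameter on the latter `fraction` of each chain's trace:
#' with `W` the mean within-chain variance and `B/n` the between-chain
#' variance of the chain means, the statistic is
#' `sqrt(((n - 1)/n * W + B/n) / W)`.  Parameters with zero within-chain
#' variance are degenerate and reported as `NA`.
#'
#' @param x an `mm_chains` object or a 3-d array (iterations x parameters x
#'   chains, >= 2 chains).
#' @param fraction latter fraction of the trace to use (default 0.5).
#' @return Named numeric vector of statistics, one per parameter.
#' @export
gelman_rubin <- function(x, fraction = 0.5) {
  a <- if (inherits(x, "mm_chains")) x$draws else x
  stopifnot(length(dim(a)) == 3, dim(a)[3] >= 2)
  T_ <- dim(a)[1]
  keep <- seq.int(floor(T_ * (1 - fraction)) + 1L, T_)
  if (length(keep) < 10) stop("need at least 10 retained samples per chain")
  n <- length(keep)
  out <- numeric(dim(a)[2])
  for (p in seq_len(dim(a)[2])) {
    ch <- a[keep, p, , drop = TRUE]
    if (is.null(dim(ch))) ch <- matrix(ch, ncol = dim(a)[3])
    W <- mean(apply(ch, 2, var))
    B_over_n <- var(colMeans(ch))
    if (!is.finite(W) || W <= 0) { out[p] <- NA_real_; next }
    out[p] <- sqrt(((n - 1) / n * W + B_over_n) / W)
  }
  names(out) <- dimnames(a)[[2]]
  out
}

#' Run a calibration until the convergence criterion is met
#'
#' Alternates sampling blocks with Gelman-Rubin checks on the latter half of
#' the traces and stops when the statistic is at or below the threshold
#' (default 1.2) for every free parameter, or when `max_steps` is reached
#' (in which case the archive is returned with `converged = FALSE`, not an
#' error).
#'
#' @param problem a [calibration_problem()] (or any list with elements
#'   `logpost` and `priors`, plus optional `par_names`).
#' @param config an [sampler_config()].
#' @return An `mm_chains` archive with a convergence report (`converged`,
#'   `gelman_rubin` listing every free parameter once).
#' @export
run_until_converged <- function(problem, config = sampler_config()) {
  dream_sample(problem$logpost, problem$priors, config,
               par_names = problem$par_names %||% NULL,
               converge_stop = TRUE)
}

#' Posterior draws pooled from the latter portion of all chains
#'
#' @param chains an `mm_chains` object.
#' @param n_draws number of draws (with replacement only if fewer are
#'   retained, with a warning).
#' @param fraction latter fraction of each trace to pool (default 0.5).
#' @return Matrix `n_draws` by parameters.
#' @export
posterior_draws <- function(chains, n_draws = 1000, fraction = 0.5) {
  a <- chains$draws
  T_ <- dim(a)[1]
  keep <- seq.int(floor(T_ * (1 - fraction)) + 1L, T_)
  pool <- do.call(rbind, lapply(seq_len(dim(a)[3]), function(c)
    a[keep, , c, drop = TRUE]))
  if (dim(a)[2] == 1) pool <- matrix(pool, ncol = 1)
  colnames(pool) <- chains$par_names
  if (nrow(pool) < n_draws) {
    warning("fewer retained samples than requested draws; sampling with replacement")
    idx <- sample.int(nrow(pool), n_draws, replace = TRUE)
  } else {
    idx <- sample.int(nrow(pool), n_draws)
  }
  pool[idx, , drop = FALSE]
}

#' Save / load a chain archive as plain text
#'
#' The draws are written as CSV (iteration, chain, one column per
#' parameter, log-posterior) together with a JSON metadata header; the pair
#' round-trips through [load_chains()].
#'
#' @param chains an `mm_chains` object.
#' @param path base path; `<path>.csv` and `<path>.json` are written.
#' @return Base path, invisibly.
#' @export
save_chains <- function(chains, path) {
  a <- chains$draws
  T_ <- dim(a)[1]; d <- dim(a)[2]; N <- dim(a)[3]
  flat <- do.call(rbind, lapply(seq_len(N), function(c)
    data.frame(iteration = seq_len(T_), chain = c,
               a[, , c, drop = TRUE],
               logpost = chains$logpost[, c])))
  colnames(flat) <- c("iteration", "chain", chains$par_names, "logpost")
  write.csv(flat, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(par_names = chains$par_names, burn_in = chains$burn_in,
         converged = chains$converged,
         gelman_rubin = as.list(setNames(chains$gelman_rubin, chains$par_names)),
         n_chains = N, n_iterations = T_),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_chains
#' @export
load_chains <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- read.csv(paste0(path, ".csv"), check.names = FALSE)
  d <- length(meta$par_names); N <- meta$n_chains; T_ <- meta$n_iterations
  draws <- array(NA_real_, c(T_, d, N),
                 dimnames = list(NULL, meta$par_names, NULL))
  lptrace <- matrix(NA_real_, T_, N)
  for (c in seq_len(N)) {
    sub <- flat[flat$chain == c, , drop = FALSE]
    draws[, , c] <- as.matrix(sub[, meta$par_names, drop = FALSE])
    lptrace[, c] <- sub$logpost
  }
  structure(list(draws = draws, logpost = lptrace, archive = NULL,
                 burn_in = meta$burn_in, par_names = meta$par_names,
                 converged = meta$converged,
                 gelman_rubin = unlist(meta$gelman_rubin),
                 config = NULL),
            class = "mm_chains")
}
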
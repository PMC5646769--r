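#' MCMC run configuration
#'
#' Defaults are a desk-scale protocol (3 chains of 6000 iterations, 1000
#' burn-in, thinning 5).  The full protocol used for the published-scale
#' analysis is 3 chains of 24000 iterations, 4000 burn-in, thinning 10:
#' `mcmc_config(n_iter = 24000, n_burn = 4000, thin = 10, seed = ...)`.
#'
#' @param n_iter Iterations per chain (including burn-in).
#' @param n_burn Burn-in iterations discarded; proposal adaptation happens
#'   only during burn-in, so detailed balance holds for kept draws.
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param n_chains Number of parallel chains (run sequentially).
#' @param seed Integer seed; required — randomized fitting without an
#'   explicit seed is an error, not silent nondeterminism.
#' @param prior_sd Standard deviation of the vague normal prior on all
#'   location parameters (intercept, trend, covariate coefficients).
#' @param sd_bound Upper bound of the uniform priors on the site random
#'   effect standard deviation and on the square root of the residual
#'   log-scale variance `v`.
#' @param sigma_site_bound Upper bound of the uniform prior on the site sd
#'   alone (defaults to `sd_bound`); shrinking it towards zero forces the
#'   random effects to zero.
#' @param joint_block Add a joint adaptive (Haario-style) proposal over all
#'   fixed effects each iteration, in addition to the componentwise sweep.
#' @param rhat_warn Warn after fitting if any parameter's Gelman-Rubin
#'   statistic exceeds this value.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 6000, n_burn = 1000, thin = 5, n_chains = 3,
                        seed, prior_sd = 1000, sd_bound = 10,
                        sigma_site_bound = sd_bound,
                        joint_block = TRUE, rhat_warn = 1.05) {
  if (missing(seed) || is.null(seed)) abort("mcmc_config requires an explicit `seed`")
  if (n_burn >= n_iter) abort("n_burn must be < n_iter")
  structure(list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed), prior_sd = prior_sd,
                 sd_bound = sd_bound, sigma_site_bound = sigma_site_bound,
                 joint_block = isTRUE(joint_block),
                 rhat_warn = rhat_warn),
            class = "mcmc_config")
}

#' Fit the biomass observation model by MCMC
#'
#' Samples the posterior of the interval-aggregated catch model: catch mass
#' is normal about the sum over exposure days of latent daily biomass
#' `z = exp(y)`, with `y` a linear predictor in the design columns plus a
#' site random intercept, and the daily variance given by the log-normal
#' method-of-moments formula.  The sampler is an adaptive
#' Metropolis-within-Gibbs: componentwise random-walk updates (plus an
#' optional joint block with proposal covariance learned during burn-in) for
#' the fixed effects on an internally centered design, per-site
#' random-effect updates, and random-walk updates for the two variance
#' components.  Priors: Normal(0, `prior_sd`²) on location parameters,
#' Uniform(0, `sd_bound`) on the site sd and on sqrt(`v`).
#'
#' @param samples Samples tibble (see [read_samples()]).
#' @param sites Sites tibble.
#' @param spec A [model_spec()] (or its name as a string).
#' @param daily,site_year Covariate tables as in [build_design()].
#' @param config An [mcmc_config()]; must carry a seed.
#' @param year_coding Passed to [build_design()].
#' @param design Optionally a prebuilt [build_design()] object (overrides
#'   `samples`/`sites`/`spec`/covariates).
#' @return A `biomass_fit` object; see [tidy.biomass_fit()],
#'   [glance.biomass_fit()], [psrf()], [dic()], [project_season()].
#' @export
fit_mcmc <- function(samples = NULL, sites = NULL, spec = NULL, daily = NULL,
                     site_year = NULL, config, year_coding = "calendar",
                     design = NULL) {
  stopifnot(inherits(config, "mcmc_config"))
  if (is.null(design)) {
    if (is.character(spec)) spec <- model_spec(spec)
    design <- build_design(samples, sites, spec, daily = daily,
                           site_year = site_year, year_coding = year_coding)
  }
  stopifnot(inherits(design, "biomass_design"))

  t0 <- proc.time()[["elapsed"]]
  chains <- vector("list", config$n_chains)
  accept <- NULL
  mu_sum <- 0
  for (ch in seq_len(config$n_chains)) {
    res <- run_chain(design, config, chain_seed = config$seed + 1000L * (ch - 1L))
    chains[[ch]] <- res$draws
    accept <- if (is.null(accept)) res$accept else accept + res$accept
    mu_sum <- mu_sum + res$mu_sum
  }
  accept <- accept / config$n_chains
  n_kept_total <- sum(vapply(chains, nrow, integer(1)))

  fit <- structure(list(
    chains = chains,
    parameters = colnames(chains[[1]]),
    spec = design$spec,
    design = design,
    record = design$record,
    config = config,
    acceptance = accept,
    posterior_mu = mu_sum / n_kept_total,
    runtime_s = proc.time()[["elapsed"]] - t0
  ), class = "biomass_fit")

  rh <- psrf(fit)
  fit$rhat <- rh
  bad <- rh$parameter[is.finite(rh$rhat) & rh$rhat > config$rhat_warn]
  if (length(bad)) {
    warn(sprintf("R-hat above %.3g for: %s", config$rhat_warn,
                 paste(head(bad, 8), collapse = ", ")))
  }
  fit
}

#' @export
print.biomass_fit <- function(x, ...) {
  cat("<biomass_fit> spec:", x$spec$name, "|", x$design$n_samples, "samples,",
      length(x$design$site_levels), "sites\n")
  cat(sprintf("  %d chains x %d kept draws (iter %d, burn %d, thin %d), %.1f s\n",
              length(x$chains), nrow(x$chains[[1]]), x$config$n_iter,
              x$config$n_burn, x$config$thin, x$runtime_s))
  cat(sprintf("  max R-hat %.4f\n", max(x$rhat$rhat, na.rm = TRUE)))
  fx <- tidy(x)
  print(fx, n = min(nrow(fx), 12))
  invisible(x)
}

# one chain of the adaptive Metropolis-within-Gibbs sampler
run_chain <- function(design, config, chain_seed) {
  set.seed(chain_seed)
  X <- design$X
  p <- ncol(X)
  m <- design$mass
  len <- design$sample_len
  ends <- design$sample_ends
  site_of_sample <- design$sample_site
  n_sites <- length(design$site_levels)
  col_mu <- colMeans(X)
  Xc <- sweep(X, 2, col_mu)
  prior_sd <- config$prior_sd
  sd_bound <- config$sd_bound
  # constant design columns (e.g. a cluster dummy with no such site) do not
  # enter the likelihood: their conditional posterior is the prior, sampled
  # directly instead of by random walk
  dead <- c(FALSE, apply(Xc, 2, function(x) all(abs(x) < 1e-12)))

  # per-site aggregation of per-sample quantities
  site_groups <- split(seq_along(site_of_sample), site_of_sample)
  site_ids_present <- as.integer(names(site_groups))
  sum_by_site <- function(x) {
    out <- numeric(n_sites)
    out[site_ids_present] <- vapply(site_groups, function(ix) sum(x[ix]), numeric(1))
    out
  }

  # state
  theta <- c(log(mean(m / len)) + rnorm(1, 0, 0.3), rnorm(p, 0, 0.05))
  u <- rep(0, n_sites)
  sigma_site <- runif(1, 0.1, 0.6)
  if (sigma_site >= config$sigma_site_bound) sigma_site <- config$sigma_site_bound / 2
  w <- runif(1, 0.7, 1.3) # sqrt(v)

  eta <- theta[1] + drop(Xc %*% theta[-1])
  ez <- exp(eta)
  A1 <- sample_sums(ez, ends)
  A2 <- sample_sums(ez * ez, ends)

  loglik_vec <- function(A1, A2, u, w) {
    v <- w * w
    eu <- exp(u[site_of_sample])
    dnorm(m, eu * A1, sqrt(exp(v) * (exp(v) - 1) * eu * eu * A2), log = TRUE)
  }
  reported_c <- function(theta) theta[1] - sum(theta[-1] * col_mu)
  prior_theta <- function(theta) {
    sum(dnorm(c(reported_c(theta), theta[-1]), 0, prior_sd, log = TRUE))
  }

  llv <- loglik_vec(A1, A2, u, w)
  ll <- sum(llv)
  lp <- prior_theta(theta)

  # adaptation state
  d <- p + 1L
  ls_comp <- rep(log(0.1), d)
  ls_joint <- log(1)
  ls_u <- log(0.5)
  ls_sig <- log(0.5)
  ls_w <- log(0.1)
  acc_comp <- int_comp <- rep(0, d)
  acc_joint <- int_joint <- 0
  acc_u <- int_u <- 0
  acc_sig <- int_sig <- 0
  acc_w <- int_w <- 0
  burn_hist <- matrix(NA_real_, config$n_burn, d)
  joint_chol <- NULL

  n_kept <- (config$n_iter - config$n_burn) %/% config$thin
  par_names <- c("c", colnames(X),
                 paste0("u_", design$site_levels), "sigma_site", "v", "deviance")
  draws <- matrix(NA_real_, n_kept, length(par_names),
                  dimnames = list(NULL, par_names))
  kept <- 0L
  mu_sum <- 0

  adapt <- function(ls, acc, int, target, iter) {
    if (int == 0) return(ls)
    step <- min(0.25, 3 / sqrt(iter))
    ls + step * ((acc / int) - target)
  }

  for (iter in seq_len(config$n_iter)) {
    adapting <- iter <= config$n_burn

    # componentwise fixed-effect updates
    for (j in seq_len(d)) {
      if (dead[j]) {
        theta[j] <- rnorm(1, 0, prior_sd)
        lp <- prior_theta(theta)
        next
      }
      delta <- rnorm(1, 0, exp(ls_comp[j]))
      theta_new <- theta
      theta_new[j] <- theta[j] + delta
      eta_new <- if (j == 1L) eta + delta else eta + Xc[, j - 1L] * delta
      ez_new <- exp(eta_new)
      A1n <- sample_sums(ez_new, ends)
      A2n <- sample_sums(ez_new * ez_new, ends)
      llv_new <- loglik_vec(A1n, A2n, u, w)
      ll_new <- sum(llv_new)
      lp_new <- prior_theta(theta_new)
      int_comp[j] <- int_comp[j] + 1
      if (is.finite(ll_new) &&
          log(runif(1)) < (ll_new + lp_new) - (ll + lp)) {
        theta <- theta_new; eta <- eta_new
        A1 <- A1n; A2 <- A2n; llv <- llv_new; ll <- ll_new; lp <- lp_new
        acc_comp[j] <- acc_comp[j] + 1
      }
      if (adapting && iter %% 50 == 0) {
        ls_comp[j] <- adapt(ls_comp[j], acc_comp[j], int_comp[j], 0.44, iter)
        acc_comp[j] <- 0; int_comp[j] <- 0
      }
    }

    # joint fixed-effect block with learned covariance
    if (config$joint_block && !is.null(joint_chol)) {
      step <- exp(ls_joint) * (2.38 / sqrt(d)) *
        drop(rnorm(d) %*% joint_chol)
      step[dead] <- 0
      theta_new <- theta + step
      eta_new <- theta_new[1] + drop(Xc %*% theta_new[-1])
      ez_new <- exp(eta_new)
      A1n <- sample_sums(ez_new, ends)
      A2n <- sample_sums(ez_new * ez_new, ends)
      llv_new <- loglik_vec(A1n, A2n, u, w)
      ll_new <- sum(llv_new)
      lp_new <- prior_theta(theta_new)
      int_joint <- int_joint + 1
      if (is.finite(ll_new) &&
          log(runif(1)) < (ll_new + lp_new) - (ll + lp)) {
        theta <- theta_new; eta <- eta_new
        A1 <- A1n; A2 <- A2n; llv <- llv_new; ll <- ll_new; lp <- lp_new
        acc_joint <- acc_joint + 1
      }
      if (adapting && iter %% 50 == 0) {
        ls_joint <- adapt(ls_joint, acc_joint, int_joint, 0.25, iter)
        acc_joint <- 0; int_joint <- 0
      }
    }
    if (adapting) {
      burn_hist[iter, ] <- theta
      if (config$joint_block && iter >= 400 && iter %% 200 == 0) {
        cv <- stats::cov(burn_hist[max(1, iter - 1000):iter, , drop = FALSE])
        joint_chol <- tryCatch(chol(cv + diag(1e-10, d)), error = function(e) NULL)
      }
    }

    # site random effects, all sites proposed at once, accepted per site
    u_prop <- u + rnorm(n_sites, 0, exp(ls_u))
    llv_new <- loglik_vec(A1, A2, u_prop, w)
    dll_site <- sum_by_site(llv_new - llv)
    log_acc <- dll_site +
      dnorm(u_prop, 0, sigma_site, log = TRUE) -
      dnorm(u, 0, sigma_site, log = TRUE)
    take <- log(runif(n_sites)) < log_acc & is.finite(log_acc)
    if (any(take)) {
      u[take] <- u_prop[take]
      llv <- loglik_vec(A1, A2, u, w)
      ll <- sum(llv)
    }
    int_u <- int_u + 1; acc_u <- acc_u + mean(take)
    if (adapting && iter %% 50 == 0) {
      ls_u <- adapt(ls_u, acc_u, int_u, 0.44, iter)
      acc_u <- 0; int_u <- 0
    }

    # site sd, random walk on log scale (uniform prior on sd, Jacobian sigma)
    sig_prop <- sigma_site * exp(rnorm(1, 0, exp(ls_sig)))
    int_sig <- int_sig + 1
    if (sig_prop < config$sigma_site_bound) {
      lr <- sum(dnorm(u, 0, sig_prop, log = TRUE)) -
        sum(dnorm(u, 0, sigma_site, log = TRUE)) +
        log(sig_prop) - log(sigma_site)
      if (is.finite(lr) && log(runif(1)) < lr) {
        sigma_site <- sig_prop
        acc_sig <- acc_sig + 1
      }
    }
    if (adapting && iter %% 50 == 0) {
      ls_sig <- adapt(ls_sig, acc_sig, int_sig, 0.44, iter)
      acc_sig <- 0; int_sig <- 0
    }

    # residual log-scale sd sqrt(v), random walk with uniform prior
    w_prop <- w + rnorm(1, 0, exp(ls_w))
    int_w <- int_w + 1
    if (w_prop > 0 && w_prop < sd_bound) {
      llv_new <- loglik_vec(A1, A2, u, w_prop)
      ll_new <- sum(llv_new)
      if (is.finite(ll_new) && log(runif(1)) < ll_new - ll) {
        w <- w_prop; llv <- llv_new; ll <- ll_new
        acc_w <- acc_w + 1
      }
    }
    if (adapting && iter %% 50 == 0) {
      ls_w <- adapt(ls_w, acc_w, int_w, 0.44, iter)
      acc_w <- 0; int_w <- 0
    }

    if (!adapting && (iter - config$n_burn) %% config$thin == 0 && kept < n_kept) {
      kept <- kept + 1L
      draws[kept, ] <- c(reported_c(theta), theta[-1], u, sigma_site, w * w,
                         -2 * ll)
      mu_sum <- mu_sum + exp(u[site_of_sample]) * A1
    }
  }

  list(draws = draws[seq_len(kept), , drop = FALSE],
       accept = c(fixed = mean(acc_comp / pmax(int_comp, 1)),
                  joint = if (int_joint > 0) acc_joint / int_joint else NA_real_,
                  u = acc_u / max(int_u, 1),
                  sigma_site = acc_sig / max(int_sig, 1),
                  v = acc_w / max(int_w, 1)),
       mu_sum = mu_sum)
}

#' Stacked matrix of posterior draws over all chains
#'
#' @param fit A `biomass_fit`.
#' @param parameter Optional parameter name(s) to select columns.
#' @return Numeric matrix, kept draws (all chains stacked) x parameters.
#' @export
draws_matrix <- function(fit, parameter = NULL) {
  M <- do.call(rbind, fit$chains)
  if (is.null(parameter)) M else {
    missing <- setdiff(parameter, colnames(M))
    if (length(missing)) abort(sprintf("unknown parameter(s): %s",
                                       paste(missing, collapse = ", ")))
    M[, parameter, drop = FALSE]
  }
}

#' Posterior draws as a tidy tibble
#'
#' @param fit A `biomass_fit`.
#' @return Tibble with columns `chain, iter, parameter, value`.
#' @export
draws_tibble <- function(fit) {
  purrr::imap_dfr(fit$chains, function(M, ch) {
    tibble::tibble(
      chain = as.integer(ch),
      iter = rep(seq_len(nrow(M)), ncol(M)),
      parameter = rep(colnames(M), each = nrow(M)),
      value = as.vector(M)
    )
  })
}

#' Extract posterior mean parameters as a `model_params` object
#'
#' @param fit A `biomass_fit`.
#' @return A [model_params()] at the posterior means.
#' @export
posterior_mean_params <- function(fit) {
  mns <- colMeans(draws_matrix(fit))
  cols <- colnames(fit$design$X)
  beta <- mns[setdiff(cols, "year")]
  u <- mns[paste0("u_", fit$design$site_levels)]
  names(u) <- fit$design$site_levels
  model_params(
    c = unname(mns["c"]),
    log_lambda = if ("year" %in% cols) unname(mns["year"]) else 0,
    beta = beta,
    u = u,
    sigma2_site = unname(mns["sigma_site"])^2,
    v = unname(mns["v"])
  )
}
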
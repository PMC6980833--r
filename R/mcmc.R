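#' Fit the hierarchical detection model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs sampler for the Bernoulli-logit
#' detection model. Every scalar coefficient is updated with a Gaussian
#' random-walk proposal whose step size adapts toward 30-45% acceptance
#' during burn-in and is frozen afterwards; hyper-means are updated by
#' conjugate Gibbs draws; SD parameters are updated on the log scale (with
#' Jacobian) with proposals reflected at log(10), so the sampler never
#' leaves the Uniform(0, 10) prior support. Chains start from independent
#' moderately overdispersed draws (distinct per-chain seeds derived from
#' `seed`).
#'
#' `n_iter` is the total number of iterations per chain; the first
#' `n_burnin` are discarded, so `n_iter - n_burnin` draws are stored per
#' chain.
#'
#' @param input A [build_model_input()] object.
#' @param n_chains Number of chains (default 3).
#' @param n_iter Total iterations per chain (default 20000); must exceed
#'   `n_burnin`.
#' @param n_burnin Burn-in iterations discarded per chain (default 5000).
#' @param seed Integer seed; chain `j` uses `seed + j - 1`.
#' @param thin Keep every `thin`-th post-burn-in draw (default 1, as no
#'   thinning is applied by default).
#' @param hierarchical Pool the species-indexed coefficient families
#'   beta0..beta4 under Normal(mu_k, sigma_k) with diffuse hyperpriors
#'   (default). If `FALSE` each coefficient gets a Normal(0, variance 100)
#'   prior directly (reduced variant for sampler validation).
#' @param random_effect Include the per-scat random intercept (default
#'   `TRUE`).
#' @param monitor_alpha Also store the per-scat random effects (off by
#'   default to bound memory).
#' @param adapt_interval Iterations between step-size adaptations during
#'   burn-in (default 50).
#' @param max_init_retries Re-draw an initialization whose posterior
#'   density is non-finite up to this many times before erroring.
#' @return An object of class `"posterior_draws"`: per-chain draw matrices
#'   with named columns plus run metadata.
#' @export
run_mcmc <- function(input, n_chains = 3L, n_iter = 20000L,
                     n_burnin = 5000L, seed = 1L, thin = 1L,
                     hierarchical = TRUE, random_effect = TRUE,
                     monitor_alpha = FALSE, adapt_interval = 50L,
                     max_init_retries = 20L) {
  stopifnot(inherits(input, "model_input"))
  if (input$n_rows == 0L) stop("`input` has no rows", call. = FALSE)
  if (n_burnin < 0L || n_iter <= n_burnin)
    stop("need n_iter > n_burnin >= 0", call. = FALSE)
  if (n_chains < 1L) stop("need at least one chain", call. = FALSE)
  if (thin < 1L) stop("`thin` must be >= 1", call. = FALSE)

  d <- input$data
  S <- input$n_species
  N <- input$n_scats
  PR <- as.matrix(d[, c("pr0", "pr1", "pr2", "pr3")])

  par_names <- c(
    as.vector(t(outer(0:4, input$species,
                      function(k, s) sprintf("beta%d[%s]", k, s)))),
    "beta5", "beta6",
    if (hierarchical) c(paste0("mu_beta", 0:4), paste0("sigma_beta", 0:4)),
    if (random_effect) "sigma_alpha",
    if (monitor_alpha) sprintf("alpha[%s]", input$scats))

  draw_init <- function() {
    mu <- stats::rnorm(5, 0, 2.5)
    sigma <- stats::runif(5, 0.5, 2)
    beta <- matrix(0, 5, S)
    for (k in 1:5) beta[k, ] <- if (hierarchical)
      stats::rnorm(S, mu[k], sigma[k]) else stats::rnorm(S, 0, 2.5)
    sigma_alpha <- stats::runif(1, 0.5, 2)
    alpha <- if (random_effect) stats::rnorm(N, 0, sigma_alpha) else
      rep(0, N)
    list(beta = beta, beta5 = stats::rnorm(1, 0, 1),
         beta6 = stats::rnorm(1, 0, 1), alpha = alpha, mu = mu,
         sigma = sigma, sigma_alpha = sigma_alpha)
  }

  init_state <- function(init) {
    parameter_state(input$species, N,
                    beta0 = init$beta[1, ], beta1 = init$beta[2, ],
                    beta2 = init$beta[3, ], beta3 = init$beta[4, ],
                    beta4 = init$beta[5, ], beta5 = init$beta5,
                    beta6 = init$beta6, alpha = init$alpha, mu = init$mu,
                    sigma = init$sigma, sigma_alpha = init$sigma_alpha)
  }

  chains <- vector("list", n_chains)
  acc <- numeric(n_chains)
  for (j in seq_len(n_chains)) {
    set.seed(as.integer(seed) + j - 1L)
    init <- draw_init()
    tries <- 0L
    while (!is.finite(log_likelihood(init_state(init), input) +
                      log_prior(init_state(init), hierarchical,
                                random_effect))) {
      tries <- tries + 1L
      if (tries > max_init_retries)
        stop("could not find an initialization with finite posterior ",
             "density", call. = FALSE)
      init <- draw_init()
    }
    res <- run_chain_cpp(
      y = as.integer(d$y), sp = as.integer(d$species_index - 1L),
      scat = as.integer(d$scat_index - 1L), PR = PR,
      deg = as.numeric(d$degradation_day), ind = as.numeric(d$individual),
      S = S, nScat = N, nIter = as.integer(n_iter),
      nBurn = as.integer(n_burnin), thin = as.integer(thin), init = init,
      hierarchical = hierarchical, randomEffect = random_effect,
      monitorAlpha = monitor_alpha,
      adaptInterval = as.integer(adapt_interval))
    m <- res$draws
    colnames(m) <- par_names
    chains[[j]] <- m
    acc[j] <- res$acceptance_rate
  }

  structure(list(chains = chains, parameters = par_names,
                 n_chains = n_chains, n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), acceptance_rates = acc,
                 species = input$species, scats = input$scats,
                 individuals = input$individuals,
                 hierarchical = hierarchical,
                 random_effect = random_effect,
                 monitor_alpha = monitor_alpha),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws:", x$n_chains, "chains x",
      nrow(x$chains[[1]]), "stored iterations (",
      x$n_iter, "total,", x$n_burnin, "burn-in, thin", x$thin, ")\n")
  cat(length(x$parameters), "monitored parameters; mean acceptance rate",
      sprintf("%.2f", mean(x$acceptance_rates)), "\n")
  invisible(x)
}

#' Pool posterior draws across chains into one matrix
#'
#' @param draws A `posterior_draws` object.
#' @return A numeric matrix, rows = pooled post-burn-in draws, columns =
#'   monitored parameters.
#' @export
as_draws_matrix <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  do.call(rbind, draws$chains)
}

# Geyer initial-positive-sequence effective sample size from a list of
# per-chain draw vectors
ess_scalar <- function(xs) {
  m <- length(xs)
  n <- length(xs[[1]])
  max_lag <- min(n - 1L, 1000L)
  acfs <- lapply(xs, function(x) {
    if (stats::var(x) == 0) return(rep(0, max_lag + 1L))
    as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                          demean = TRUE)$acf)
  })
  rho <- Reduce(`+`, acfs) / m
  # sum consecutive pairs while positive (Geyer initial positive sequence)
  s <- 0
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t + 1L] + if (t + 2L <= length(rho)) rho[t + 2L] else 0
    if (pair <= 0) break
    s <- s + pair
    t <- t + 2L
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}

#' Gelman-Rubin convergence diagnostic
#'
#' For every monitored scalar computes the potential scale reduction factor
#' `Rhat = sqrt(((n - 1) / n * W + B / n) / W)` with `W` the mean
#' within-chain variance and `B` the between-chain variance, plus an
#' effective sample size. Chains with zero within-chain variance and
#' identical means (a degenerate but well-defined case) are reported as
#' `Rhat = 1` with a warning. `converged` is `TRUE` when every Rhat is
#' below `threshold`.
#'
#' @param draws A `posterior_draws` object (>= 2 chains, >= 10 stored draws
#'   each), or a list of draw matrices with common column names.
#' @param threshold Convergence threshold (default 1.1).
#' @param split Split each chain in half before computing the diagnostic
#'   (allows a single-chain diagnostic and detects within-chain drift).
#' @return A list of class `"convergence_report"`: `rhat` (named vector),
#'   `ess` (named vector), `converged`, `threshold`.
#' @export
gelman_rubin <- function(draws, threshold = 1.1, split = FALSE) {
  chains <- if (inherits(draws, "posterior_draws")) draws$chains else draws
  stopifnot(is.list(chains), length(chains) >= 1L)
  if (split) {
    chains <- unlist(lapply(chains, function(m) {
      n <- nrow(m)
      h <- n %/% 2L
      list(m[seq_len(h), , drop = FALSE],
           m[(n - h + 1L):n, , drop = FALSE])
    }), recursive = FALSE)
  }
  if (length(chains) < 2L)
    stop("Gelman-Rubin diagnostic needs >= 2 chains (or split = TRUE)",
         call. = FALSE)
  n <- nrow(chains[[1]])
  if (n < 10L) stop("need >= 10 stored draws per chain", call. = FALSE)
  if (length(unique(vapply(chains, nrow, integer(1)))) != 1L)
    stop("all chains must have equal length", call. = FALSE)
  params <- colnames(chains[[1]])
  m <- length(chains)

  means <- sapply(chains, colMeans)                     # P x m
  vars <- sapply(chains, function(x) apply(x, 2, stats::var))
  if (is.null(dim(means))) {                            # single parameter
    means <- matrix(means, nrow = 1)
    vars <- matrix(vars, nrow = 1)
  }
  W <- rowMeans(vars)
  B <- n * apply(means, 1, stats::var)
  rhat <- sqrt(((n - 1) / n * W + B / n) / W)
  degenerate <- W == 0
  if (any(degenerate)) {
    same_mean <- apply(means, 1, function(x) max(x) - min(x) == 0)
    rhat[degenerate & same_mean] <- 1.0
    rhat[degenerate & !same_mean] <- Inf
    warning("zero within-chain variance for: ",
            paste(params[degenerate], collapse = ", "),
            "; Rhat reported as 1 where chains agree exactly")
  }
  # variance-ratio floor: sqrt((n-1)/n) < 1 can occur when B ~ 0
  rhat <- pmax(rhat, 1.0)
  names(rhat) <- params

  ess <- vapply(params, function(p)
    ess_scalar(lapply(chains, function(x) x[, p])), numeric(1))

  structure(list(rhat = rhat, ess = ess,
                 converged = all(rhat < threshold),
                 threshold = threshold),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Gelman-Rubin diagnostic: max Rhat =",
      sprintf("%.4f", max(x$rhat)), "(threshold", x$threshold, ")\n")
  cat(if (x$converged) "All parameters converged.\n" else
    paste0("NOT converged: ",
           paste(names(x$rhat)[x$rhat >= x$threshold], collapse = ", "),
           "\n"))
  invisible(x)
}

#' Posterior summary of all monitored parameters
#'
#' Pools chains after burn-in and reports, per parameter, the posterior
#' mean, SD and the 2.5/25/50/75/97.5% quantiles (linear interpolation).
#'
#' @param draws A `posterior_draws` object.
#' @return A `data.frame` with one row per monitored parameter.
#' @export
summarize_posterior <- function(draws) {
  m <- as_draws_matrix(draws)
  if (nrow(m) == 0L) stop("no stored draws", call. = FALSE)
  qs <- t(apply(m, 2, stats::quantile,
                probs = c(0.025, 0.25, 0.5, 0.75, 0.975), type = 7))
  out <- data.frame(parameter = colnames(m),
                    mean = colMeans(m),
                    sd = apply(m, 2, stats::sd),
                    q2.5 = qs[, 1], q25 = qs[, 2], q50 = qs[, 3],
                    q75 = qs[, 4], q97.5 = qs[, 5],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Headline posterior summary (species-averaged effects)
#'
#' The compact report of the model's main effects: the hyper-means of the
#' four lag-proportion slope families, labelled `Day 0/pr fed` ..
#' `Day 3/pr fed` (the species-averaged effect of the proportion fed 0-3
#' days before defecation), plus the degradation-day and individual
#' coefficients.
#'
#' @param draws A `posterior_draws` object from a hierarchical fit.
#' @return A `data.frame` with columns `parameter`, `mean`, `sd`, `q2.5`,
#'   `q97.5`.
#' @export
main_effect_summary <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (!draws$hierarchical)
    stop("main-effect summary needs a hierarchical fit", call. = FALSE)
  full <- summarize_posterior(draws)
  pick <- c("mu_beta1", "mu_beta2", "mu_beta3", "mu_beta4",
            "beta5", "beta6")
  labels <- c("Day 0/pr fed", "Day 1/pr fed", "Day 2/pr fed",
              "Day 3/pr fed", "Degradation", "Cheetah")
  out <- full[match(pick, full$parameter),
              c("parameter", "mean", "sd", "q2.5", "q97.5")]
  out$parameter <- labels
  rownames(out) <- NULL
  out
}
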
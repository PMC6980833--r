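# numerically stable log(1 + exp(x)); exact for |x| up to ~700
log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Construct a parameter state for the detection model
#'
#' @param species Prey species labels (length S).
#' @param n_scats Number of scats (length of `alpha`).
#' @param beta0,beta1,beta2,beta3,beta4 Per-species coefficient vectors
#'   (recycled from length 1).
#' @param beta5 Degradation-day coefficient.
#' @param beta6 Individual coefficient.
#' @param alpha Per-scat random effects (recycled from length 1).
#' @param mu,sigma Hyper-means and hyper-SDs of the five species-indexed
#'   coefficient families (length 5, order beta0..beta4).
#' @param sigma_alpha Random-effect SD.
#' @return A list of class `"parameter_state"`.
#' @export
parameter_state <- function(species, n_scats, beta0 = 0, beta1 = 0,
                            beta2 = 0, beta3 = 0, beta4 = 0, beta5 = 0,
                            beta6 = 0, alpha = 0, mu = rep(0, 5),
                            sigma = rep(1, 5), sigma_alpha = 1) {
  S <- length(species)
  rec <- function(x, n) if (length(x) == 1L) rep(x, n) else x
  st <- list(beta = rbind(rec(beta0, S), rec(beta1, S), rec(beta2, S),
                          rec(beta3, S), rec(beta4, S)),
             beta5 = beta5, beta6 = beta6,
             alpha = rec(alpha, n_scats),
             mu = mu, sigma = sigma, sigma_alpha = sigma_alpha,
             species = species)
  if (ncol(st$beta) != S || any(lengths(list(mu, sigma)) != 5L))
    stop("parameter dimensions inconsistent", call. = FALSE)
  class(st) <- "parameter_state"
  st
}

# linear predictor for every row of a model_input under a parameter state
linear_predictor <- function(state, input) {
  d <- input$data
  s <- d$species_index
  state$beta[1, s] + state$beta[2, s] * d$pr0 + state$beta[3, s] * d$pr1 +
    state$beta[4, s] * d$pr2 + state$beta[5, s] * d$pr3 +
    state$beta5 * d$degradation_day + state$beta6 * d$individual +
    state$alpha[d$scat_index]
}

#' Bernoulli-logit log-likelihood of the detection model
#'
#' Sum over rows of `y * log(p) + (1 - y) * log(1 - p)` with
#' `logit(p)` the detection model's linear predictor. Computed in the
#' stable form `y * eta - log(1 + exp(eta))`, finite for |eta| up to
#' several hundred.
#'
#' @param state A [parameter_state()].
#' @param input A [build_model_input()] object.
#' @return A single numeric log-likelihood.
#' @export
log_likelihood <- function(state, input) {
  stopifnot(inherits(input, "model_input"))
  if (ncol(state$beta) != input$n_species ||
      length(state$alpha) != input$n_scats)
    stop("parameter state dimensions do not match the data", call. = FALSE)
  eta <- linear_predictor(state, input)
  sum(input$data$y * eta - log1pexp(eta))
}

#' Log prior density of the detection model's parameters
#'
#' Hierarchical prior: each species-indexed coefficient family
#' beta0..beta4 is drawn Normal(mu_k, sigma_k^2); the hyper-means get
#' diffuse Normal(0, variance 100) priors and the hyper-SDs Uniform(0, 10)
#' priors. Scat random effects are Normal(0, sigma_alpha^2) with
#' sigma_alpha ~ Uniform(0, 10). The degradation and individual
#' coefficients get Normal(0, variance 100) directly (they are single
#' values, not species-indexed, so there is nothing to pool). Returns
#' `-Inf` outside the support (any SD outside (0, 10)).
#'
#' @param state A [parameter_state()].
#' @param hierarchical If `FALSE`, the species-indexed coefficients get
#'   Normal(0, variance 100) priors directly and the hyperparameters are
#'   ignored (reduced model variant used for sampler validation).
#' @param random_effect If `FALSE`, the alpha / sigma_alpha terms are
#'   omitted.
#' @return A single numeric log prior density (possibly `-Inf`).
#' @export
log_prior <- function(state, hierarchical = TRUE, random_effect = TRUE) {
  lp <- stats::dnorm(state$beta5, 0, 10, log = TRUE) +
    stats::dnorm(state$beta6, 0, 10, log = TRUE)
  if (hierarchical) {
    if (any(state$sigma <= 0 | state$sigma > 10)) return(-Inf)
    lp <- lp + sum(stats::dnorm(state$mu, 0, 10, log = TRUE)) +
      5 * log(1 / 10)
    for (k in 1:5)
      lp <- lp + sum(stats::dnorm(state$beta[k, ], state$mu[k],
                                  state$sigma[k], log = TRUE))
  } else {
    lp <- lp + sum(stats::dnorm(state$beta, 0, 10, log = TRUE))
  }
  if (random_effect) {
    if (state$sigma_alpha <= 0 || state$sigma_alpha > 10) return(-Inf)
    lp <- lp + log(1 / 10) +
      sum(stats::dnorm(state$alpha, 0, state$sigma_alpha, log = TRUE))
  }
  lp
}
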
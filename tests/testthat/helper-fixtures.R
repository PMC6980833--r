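# shared fixture builders: everything is generated in code at test time

five_species <- paste0("sp", 1:5)

# a small two-animal schedule with full coverage of every day
tiny_schedule <- function(n_days = 20, seed = 11) {
  generate_feeding_schedule(n_days, c("A", "B"), five_species, 3,
                            seed = seed)
}

# the synthetic study conditions: 26 scats (2 individuals x 13 days),
# subsampled on 16 degradation days, 5 species -> 2080 rows
study_true_params <- function(seed = 99, sigma_alpha = 0.5) {
  mu <- c(-2, 0.01, 4.43, 1.82, 1.04)
  set.seed(seed)
  true_parameters(five_species,
                  beta0 = mu[1] + stats::rnorm(5),
                  beta1 = mu[2] + stats::rnorm(5),
                  beta2 = mu[3] + stats::rnorm(5),
                  beta3 = mu[4] + stats::rnorm(5),
                  beta4 = mu[5] + stats::rnorm(5),
                  beta5 = -0.16, beta6 = -1.19,
                  sigma_alpha = sigma_alpha)
}

study_synthetic <- function(seed = 1) {
  sched <- tiny_schedule(seed = seed)
  params <- study_true_params(seed = seed + 1)
  det <- simulate_detections(sched, params,
                             as.Date("2017-11-03") + 3:15, 0:15,
                             seed = seed + 2)
  list(schedule = sched, params = params, detections = det)
}

# hand-built posterior draws object (one chain unless given more)
fake_draws <- function(mat, species = "sp1", n_chains = 1,
                       hierarchical = TRUE, random_effect = TRUE) {
  chains <- if (is.matrix(mat)) list(mat) else mat
  structure(list(chains = chains, parameters = colnames(chains[[1]]),
                 n_chains = length(chains), n_iter = nrow(chains[[1]]),
                 n_burnin = 0L, thin = 1L, seed = 1L,
                 acceptance_rates = rep(NA_real_, length(chains)),
                 species = species, scats = "s1", individuals = c("A", "B"),
                 hierarchical = hierarchical,
                 random_effect = random_effect, monitor_alpha = FALSE),
            class = "posterior_draws")
}

# draw matrix with named columns for a 1-species model
draw_matrix <- function(n, species = "sp1", beta0 = 0, beta1 = 0,
                        beta2 = 0, beta3 = 0, beta4 = 0, beta5 = 0,
                        beta6 = 0, sigma_alpha = 0.5) {
  cols <- c(sprintf("beta%d[%s]", 0:4, species), "beta5", "beta6",
            paste0("mu_beta", 0:4), paste0("sigma_beta", 0:4),
            "sigma_alpha")
  m <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  fill <- function(col, v) m[, col] <<- rep(v, length.out = n)
  fill(cols[1], beta0); fill(cols[2], beta1); fill(cols[3], beta2)
  fill(cols[4], beta3); fill(cols[5], beta4)
  fill("beta5", beta5); fill("beta6", beta6)
  fill("mu_beta0", beta0); fill("mu_beta1", beta1)
  fill("mu_beta2", beta2); fill("mu_beta3", beta3)
  fill("mu_beta4", beta4)
  for (k in 0:4) fill(paste0("sigma_beta", k), 1)
  fill("sigma_alpha", sigma_alpha)
  m
}

# flat single-intercept dataset: k successes out of n, one species,
# all covariates zero
intercept_only_input <- function(n = 100, k = 50) {
  model_input_from_rows(data.frame(
    y = rep(c(1L, 0L), c(k, n - k)), species = "sp1", scat_id = "s1",
    pr0 = 0, pr1 = 0, pr2 = 0, pr3 = 0, degradation_day = 0,
    individual = 0))
}

# deterministic 1-D grid posterior for the single-intercept reduction:
# prior N(0, sd 10), likelihood Binomial(k of n) on inverse-logit scale
grid_intercept_posterior <- function(n = 100, k = 50,
                                     grid = seq(-8, 8, length.out = 40001)) {
  lp <- stats::dnorm(grid, 0, 10, log = TRUE) + k * grid -
    n * log1p(exp(grid))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  mean <- sum(w * grid)
  list(mean = mean, sd = sqrt(sum(w * grid^2) - mean^2))
}
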
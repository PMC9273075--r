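#' Genetic-algorithm settings
#'
#' Defaults are the published search settings: a population of 500 cost
#' vectors initialised from N(1, 1), truncation selection of the best 250 as
#' parents, elitism carrying the best 50 unchanged, crossover, a 20% chance
#' per child of mutating one parameter by a standard-normal perturbation,
#' and 20 generations.
#'
#' @param pop_size population size (kept constant across generations).
#' @param n_parents number of best individuals eligible to reproduce.
#' @param n_elite number of best individuals copied unchanged.
#' @param p_mutation probability, per child, of one mutation.
#' @param n_generations number of generations.
#' @param init_mu,init_sigma mean and sd of the initial gene distribution.
#' @param clamp_floor minimum admissible cost; genes are clamped here after
#'   initialisation and after mutation (a non-positive friction would mean
#'   infinite local speed).
#' @param seed optional integer seed making the whole run reproducible.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 500, n_parents = 250, n_elite = 50,
                      p_mutation = 0.2, n_generations = 20,
                      init_mu = 1, init_sigma = 1, clamp_floor = 0.01,
                      seed = NULL) {
  stopifnot(n_elite <= n_parents, n_parents <= pop_size, n_parents >= 2,
            p_mutation >= 0, p_mutation <= 1, init_sigma > 0,
            n_generations >= 1, clamp_floor > 0)
  structure(list(pop_size = as.integer(pop_size),
                 n_parents = as.integer(n_parents),
                 n_elite = as.integer(n_elite),
                 p_mutation = p_mutation,
                 n_generations = as.integer(n_generations),
                 init_mu = init_mu, init_sigma = init_sigma,
                 clamp_floor = clamp_floor, seed = seed),
            class = "ga_config")
}

#' Initialise a GA population
#'
#' Every gene (one friction cost per terrain class) is drawn from
#' N(init_mu, init_sigma^2) and clamped to the floor.  Uses the current RNG
#' state; seed beforehand (or via `run_ga`) for reproducibility.
#'
#' @param cfg a [ga_config()].
#' @param K number of terrain classes (genes per individual).
#' @return numeric matrix `pop_size x K` of cost vectors.
#' @export
init_population <- function(cfg, K) {
  stopifnot(inherits(cfg, "ga_config"), K >= 1)
  pop <- matrix(rnorm(cfg$pop_size * K, cfg$init_mu, cfg$init_sigma),
                cfg$pop_size, K)
  pmax(pop, cfg$clamp_floor)
}

#' Breed the next GA generation
#'
#' Sorts the population by fitness (stable, so ties keep their insertion
#' order), copies the best `n_elite` unchanged, and fills the population
#' back up with children: each child's parents are a pair drawn uniformly
#' without replacement from the best `n_parents`, genes are inherited by
#' uniform crossover (each gene from either parent with probability 1/2),
#' and with probability `p_mutation` one uniformly chosen gene gets a
#' standard-normal perturbation.  All genes are clamped to the floor.
#'
#' @param pop numeric matrix of individuals (rows) by genes (columns).
#' @param fitness numeric vector of evaluated fitnesses (RMSE, years); any
#'   `NA` is an error — breed only evaluated populations.
#' @param cfg a [ga_config()].
#' @return matrix of the same shape; rows `1:n_elite` are the elites in
#'   fitness order.
#' @export
breed <- function(pop, fitness, cfg) {
  stopifnot(inherits(cfg, "ga_config"), nrow(pop) == cfg$pop_size,
            length(fitness) == nrow(pop))
  if (anyNA(fitness)) stop("cannot breed: population contains unevaluated individuals")
  K <- ncol(pop)
  pop <- pop[order(fitness), , drop = FALSE]   # stable for ties
  n_child <- cfg$pop_size - cfg$n_elite
  nxt <- matrix(NA_real_, cfg$pop_size, K)
  nxt[seq_len(cfg$n_elite), ] <- pop[seq_len(cfg$n_elite), ]
  if (n_child > 0L) {
    p1 <- sample.int(cfg$n_parents, n_child, replace = TRUE)
    p2 <- sample.int(cfg$n_parents - 1L, n_child, replace = TRUE)
    p2 <- p2 + (p2 >= p1)                      # distinct second parent
    from1 <- matrix(runif(n_child * K) < 0.5, n_child, K)
    kids <- pop[p1, , drop = FALSE]
    g2 <- pop[p2, , drop = FALSE]
    kids[!from1] <- g2[!from1]
    mut <- runif(n_child) < cfg$p_mutation
    if (any(mut)) {
      w <- which(mut)
      gene <- sample.int(K, length(w), replace = TRUE)
      kids[cbind(w, gene)] <- kids[cbind(w, gene)] + rnorm(length(w))
    }
    nxt[cfg$n_elite + seq_len(n_child), ] <- pmax(kids, cfg$clamp_floor)
  }
  nxt
}

#' Fit per-class friction costs with the genetic algorithm
#'
#' Runs the full search: every individual (a per-class cost vector) is
#' scored each generation by the arrival-model RMSE against the observed
#' site dates, and the population is bred forward with truncation selection,
#' elitism, uniform crossover and mutation.  Elitism guarantees the
#' best-RMSE trajectory never increases.
#'
#' @param raster a [class_raster()].
#' @param sites data.frame with `x`, `y`, `observed_cal_bp` (and optionally
#'   `site`); see [score()].
#' @param config a [sim_config()] (origin, t0, base speed).
#' @param ga a [ga_config()].
#' @param verbose print per-generation progress.
#' @return object of class `ga_fit`: list with `best_costs`, `best_speeds`
#'   (`v0 / cost`), `best_rmse` (years), `trace` (data.frame `generation,
#'   best_rmse, mean_rmse`), `best_per_gen` (matrix of the best individual
#'   each generation), `fit` (the [score()] of the best individual, with
#'   per-site residuals), plus the configs used.
#' @examples
#' \donttest{
#' spec <- synth_spec(n_rows = 20, n_cols = 40, K = 2, n_sites = 12,
#'                    true_speeds = c(0.8, 1.6), seed = 1)
#' r <- make_banded_raster(spec)
#' sites <- simulate_sites(r, spec)
#' cfg <- sim_config(spec$t0, spec$v0, origin = spec$origin)
#' fit <- run_ga(r, sites, cfg, ga_config(n_generations = 5, seed = 1))
#' fit$best_speeds
#' }
#' @export
run_ga <- function(raster, sites, config, ga = ga_config(), verbose = FALSE) {
  stopifnot(inherits(raster, "class_raster"), inherits(config, "sim_config"),
            inherits(ga, "ga_config"))
  if (!is.null(ga$seed)) set.seed(ga$seed)
  K <- raster$K
  prep <- prepare_sites(raster, sites, config)

  # reachability is governed by nodata topology only (costs are bounded away
  # from zero), so it can be resolved once, with unit costs
  D1 <- accumulate_cost(raster, rep(1, K), origin = prep$origin,
                        targets = prep$targets, clamp_floor = ga$clamp_floor)
  reach <- is.finite(D1)
  if (any(!reach))
    warning(sum(!reach), " site(s) unreachable from the origin; excluded")
  if (!any(reach)) stop("no usable sites: none reachable from the origin")
  targets <- prep$targets[reach, , drop = FALSE]
  obs <- prep$observed[reach]
  t0 <- config$t0; v0 <- config$v0

  rmse_of <- function(costs) {
    D <- accumulate_cost(raster, costs, origin = prep$origin,
                         targets = targets, clamp_floor = ga$clamp_floor)
    sqrt(mean((t0 - D / v0 - obs)^2))
  }

  pop <- init_population(ga, K)
  trace <- data.frame(generation = seq_len(ga$n_generations),
                      best_rmse = NA_real_, mean_rmse = NA_real_)
  best_per_gen <- matrix(NA_real_, ga$n_generations, K)
  best_rmse <- Inf; best_costs <- NULL
  for (gen in seq_len(ga$n_generations)) {
    fit <- vapply(seq_len(ga$pop_size), function(i) rmse_of(pop[i, ]),
                  numeric(1))
    i_best <- which.min(fit)
    trace$best_rmse[gen] <- fit[i_best]
    trace$mean_rmse[gen] <- mean(fit)
    best_per_gen[gen, ] <- pop[i_best, ]
    if (fit[i_best] < best_rmse) {
      best_rmse <- fit[i_best]
      best_costs <- pop[i_best, ]
    }
    if (verbose)
      message(sprintf("generation %2d: best RMSE %.1f yr, mean %.1f yr",
                      gen, fit[i_best], mean(fit)))
    if (gen < ga$n_generations) pop <- breed(pop, fit, ga)
  }
  structure(list(best_costs = best_costs,
                 best_speeds = speeds_from_costs(best_costs, v0),
                 best_rmse = best_rmse,
                 trace = trace,
                 best_per_gen = best_per_gen,
                 fit = score(best_costs, raster, sites, config,
                             clamp_floor = ga$clamp_floor),
                 config = config, ga = ga),
            class = "ga_fit")
}

#' @export
print.ga_fit <- function(x, ...) {
  cat("ga_fit:", x$ga$n_generations, "generations, best RMSE",
      round(x$best_rmse, 1), "yr\n")
  cat("per-class speeds (km/yr):",
      paste(round(x$best_speeds, 3), collapse = ", "), "\n")
  invisible(x)
}
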
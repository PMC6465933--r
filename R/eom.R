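## Ensemble optimization against scattering data: a genetic algorithm
## selects fixed-size multisets of conformers from a precomputed pool so
## that the ensemble-average curve fits a target curve; the selected vs
## pool Rg/Dmax distributions report on chain flexibility and extension.

#' Genetic-algorithm configuration for ensemble selection
#'
#' @param ensemble_size conformers per ensemble (multiset; repeats allowed).
#' @param population GA population size.
#' @param generations GA generations per repeat.
#' @param mutation_rate per-member probability of random replacement.
#' @param crossover_rate probability a child is built by member-swap
#'   crossover rather than cloning.
#' @param elitism number of best individuals copied unchanged.
#' @param repeats independent GA runs aggregated in the result.
#' @param seed optional integer seed for full determinism.
#' @return Object of class `eom_config`.
#' @export
eom_config <- function(ensemble_size = 20L, population = 50L,
                       generations = 200L, mutation_rate = 0.1,
                       crossover_rate = 0.5, elitism = 2L,
                       repeats = 10L, seed = NULL) {
  counts <- c(ensemble_size = ensemble_size, population = population,
              generations = generations, elitism = elitism,
              repeats = repeats)
  if (any(counts < 1) || any(counts != round(counts)))
    stop_invalid("ensemble_size, population, generations, elitism, repeats must be integers >= 1")
  if (elitism >= population)
    stop_invalid("elitism must be smaller than population")
  rates <- c(mutation_rate, crossover_rate)
  if (any(rates < 0) || any(rates > 1))
    stop_invalid("mutation_rate and crossover_rate must lie in [0, 1]")
  structure(list(ensemble_size = as.integer(ensemble_size),
                 population = as.integer(population),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 elitism = as.integer(elitism),
                 repeats = as.integer(repeats),
                 seed = seed),
            class = "eom_config")
}

#' Precompute a conformer pool for ensemble selection
#'
#' Evaluates the Debye curve, Rg and Dmax of every pool conformer on a
#' fixed s grid, so the GA only averages precomputed curves.
#'
#' @param conformers list of [bead_conformer()] objects.
#' @param s_grid momentum-transfer grid in inverse Å.
#' @return Object of class `eom_pool`: `s`, `curves` (matrix, one column
#'   per conformer), `rg`, `dmax`, `n`.
#' @export
eom_pool <- function(conformers, s_grid) {
  conformers <- as_conformer_list(conformers)
  s_grid <- as.numeric(s_grid)
  curves <- vapply(conformers, debye_one, numeric(length(s_grid)), s = s_grid)
  structure(list(s = s_grid,
                 curves = curves,
                 rg = vapply(conformers, conformer_rg, numeric(1)),
                 dmax = vapply(conformers, conformer_dmax, numeric(1)),
                 n = length(conformers)),
            class = "eom_pool")
}

#' Reduced chi-square between two scattering curves
#'
#' \eqn{\chi^2 = \frac{1}{M-1}\sum_k \left(\frac{c I_{model,k} -
#' I_{target,k}}{\sigma_k}\right)^2} with the scale factor `c` that
#' minimizes it applied in closed form, so the statistic is invariant to
#' overall intensity scaling of the model.
#'
#' @param model a [scattering_curve()] or a numeric intensity vector on the
#'   target's grid.
#' @param target a [scattering_curve()] carrying `sigma`.
#' @return List with `chi2` and the fitted scale `c`.
#' @export
chi2_curves <- function(model, target) {
  stopifnot(inherits(target, "saxs_curve"))
  if (is.null(target$sigma))
    stop_invalid("target curve must carry sigma")
  if (inherits(model, "saxs_curve")) {
    if (length(model$s) != length(target$s) ||
        any(abs(model$s - target$s) > 1e-9))
      stop_invalid("model and target must share the same s grid")
    Im <- model$intensity
  } else {
    Im <- as.numeric(model)
    if (length(Im) != length(target$s))
      stop_invalid("model intensity length must match the target grid")
  }
  It <- target$intensity; sg <- target$sigma
  cc <- sum(Im * It / sg^2) / sum(Im^2 / sg^2)
  chi2 <- sum(((cc * Im - It) / sg)^2) / (length(It) - 1)
  list(chi2 = chi2, c = cc)
}

## chi2 for every column of an intensity matrix at once
chi2_matrix <- function(Im, It, sg) {
  w <- 1 / sg^2
  cc <- as.numeric(crossprod(Im, It * w)) / colSums(Im^2 * w)
  resid <- sweep(Im, 2L, cc, `*`) - It
  colSums(resid^2 * w) / (length(It) - 1)
}

## evaluate a population: columns of `pop` are index multisets
eval_population <- function(pop, pool_curves, It, sg) {
  E <- nrow(pop); npop <- ncol(pop)
  X <- pool_curves[, as.vector(pop), drop = FALSE]
  avg <- t(rowsum(t(X), group = rep(seq_len(npop), each = E))) / E
  chi2_matrix(avg, It, sg)
}

run_ga_once <- function(pool, It, sg, cfg) {
  P <- pool$n; E <- cfg$ensemble_size
  npop <- cfg$population; nel <- cfg$elitism
  pop <- matrix(sample.int(P, E * npop, replace = TRUE), E, npop)
  fit <- eval_population(pop, pool$curves, It, sg)
  trace_best <- numeric(cfg$generations)
  for (gen in seq_len(cfg$generations)) {
    ord <- order(fit)
    elite <- pop[, ord[seq_len(nel)], drop = FALSE]
    nchild <- npop - nel
    ## tournament selection (size 3)
    pick_parent <- function() {
      cand <- matrix(sample.int(npop, 3L * nchild, replace = TRUE), 3L)
      cand[cbind(apply(matrix(fit[cand], 3L), 2L, which.min),
                 seq_len(nchild))]
    }
    p1 <- pop[, pick_parent(), drop = FALSE]
    p2 <- pop[, pick_parent(), drop = FALSE]
    ## member-swap crossover: each slot from either parent
    cross <- runif(nchild) < cfg$crossover_rate
    take2 <- matrix(runif(E * nchild) < 0.5, E) &
      matrix(cross, E, nchild, byrow = TRUE)
    children <- p1
    children[take2] <- p2[take2]
    ## random-replacement mutation
    mut <- matrix(runif(E * nchild) < cfg$mutation_rate, E)
    nmut <- sum(mut)
    if (nmut > 0) children[mut] <- sample.int(P, nmut, replace = TRUE)
    pop <- cbind(elite, children)
    fit <- c(fit[ord[seq_len(nel)]],
             eval_population(children, pool$curves, It, sg))
    trace_best[gen] <- min(fit)
  }
  best <- which.min(fit)
  list(indices = sort(pop[, best]), chi2 = fit[best], trace = trace_best)
}

#' Select conformer ensembles that fit a target scattering curve
#'
#' Runs `cfg$repeats` independent genetic-algorithm searches (tournament
#' selection of size 3, member-swap crossover, random-replacement mutation,
#' elitism), each minimizing the scale-invariant [chi2_curves()] of the
#' ensemble-average curve against `target`. Ensembles are multisets, so a
#' conformer may carry multiplicity. Results aggregate the best ensemble of
#' every repeat; Rg/Dmax histograms use shared Freedman-Diaconis bins
#' computed on the pool.
#'
#' @param pool an [eom_pool()] (or list of conformers, converted on the
#'   target's grid).
#' @param target a [scattering_curve()] with `sigma`, on the pool's grid.
#' @param cfg an [eom_config()].
#' @return Object of class `eom_result` with `selected_indices` (list per
#'   repeat), `chi2` (per repeat), `fitness_trace` (best chi2 per
#'   generation, per repeat), and normalized histograms
#'   `rg_distribution_selected` / `rg_distribution_pool` /
#'   `dmax_distribution_selected` / `dmax_distribution_pool` (data frames
#'   with `mid` and `mass`, masses summing to 1).
#' @export
select_ensemble <- function(pool, target, cfg = eom_config()) {
  stopifnot(inherits(cfg, "eom_config"), inherits(target, "saxs_curve"))
  if (!inherits(pool, "eom_pool")) pool <- eom_pool(pool, target$s)
  if (length(pool$s) != length(target$s) ||
      any(abs(pool$s - target$s) > 1e-9))
    stop_invalid("pool and target must share the same s grid")
  if (is.null(target$sigma)) stop_invalid("target curve must carry sigma")
  if (pool$n < cfg$ensemble_size)
    stop_invalid("pool size (", pool$n, ") smaller than ensemble_size (",
                 cfg$ensemble_size, ")")
  runs <- with_seed_or_current(cfg$seed,
    lapply(seq_len(cfg$repeats), function(r)
      run_ga_once(pool, target$intensity, target$sigma, cfg)))
  sel_idx <- lapply(runs, `[[`, "indices")
  sel_all <- unlist(sel_idx)
  hist_pair <- function(pool_vals, sel_vals) {
    bw <- 2 * IQR(pool_vals) / pool$n^(1 / 3)
    if (bw <= 0) bw <- diff(range(pool_vals)) / 10 + 1e-6
    lo <- min(pool_vals, sel_vals); hi <- max(pool_vals, sel_vals)
    breaks <- seq(lo - bw / 2, hi + bw, by = bw)
    mk <- function(v) {
      h <- graphics::hist(v, breaks = breaks, plot = FALSE)
      data.frame(mid = h$mids, mass = h$counts / sum(h$counts))
    }
    list(pool = mk(pool_vals), selected = mk(sel_vals))
  }
  hr <- hist_pair(pool$rg, pool$rg[sel_all])
  hd <- hist_pair(pool$dmax, pool$dmax[sel_all])
  structure(list(selected_indices = sel_idx,
                 chi2 = vapply(runs, `[[`, numeric(1), "chi2"),
                 fitness_trace = lapply(runs, `[[`, "trace"),
                 rg_selected = pool$rg[sel_all],
                 rg_distribution_selected = hr$selected,
                 rg_distribution_pool = hr$pool,
                 dmax_distribution_selected = hd$selected,
                 dmax_distribution_pool = hd$pool),
            class = "eom_result")
}

#' @export
print.eom_result <- function(x, ...) {
  cat(sprintf("Ensemble optimization: %d repeats, best chi2 = %.4g (median %.4g)\n",
              length(x$chi2), min(x$chi2), median(x$chi2)))
  cat(sprintf("  selected mean Rg = %.1f Å vs pool mean Rg = %.1f Å\n",
              sum(x$rg_distribution_selected$mid *
                  x$rg_distribution_selected$mass),
              sum(x$rg_distribution_pool$mid * x$rg_distribution_pool$mass)))
  invisible(x)
}
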
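#' Multi-protocol fitting problem
#'
#' Bundles observed per-AP quantal contents with their protocols, the
#' starting/fixed parameter set, the calcium parameters (always held fixed
#' during fitting) and the free-parameter mask. EPSC amplitude data should be
#' converted to quantal content (amplitude / quantal size) before fitting;
#' residuals are computed on per-site release fractions
#' (quanta / `n_sites`).
#'
#' @param data named list of numeric vectors: per-AP quantal contents, one
#'   entry per protocol, lengths matching the protocols' AP counts.
#' @param protocols named list of [build_train()] protocols covering
#'   `names(data)`.
#' @param start a [priming_params()] object: starting values for free
#'   parameters and fixed values for the rest.
#' @param cap a [calcium_params()] object (fixed during fitting).
#' @param free character vector of free parameter names among
#'   `r paste(fittable_params(), collapse = ", ")`, or `"k2_scale"` for the
#'   shared scaling-factor parametrization (see [scaled_fit()]).
#' @return An object of class \code{"fit_problem"}.
#' @export
fit_problem <- function(data, protocols, start = fsin_params(),
                        cap = calcium_params(),
                        free = c("k2_0", "s2", "p_fusion")) {
  stopifnot(is.list(data), length(data) >= 1, !is.null(names(data)))
  missing <- setdiff(names(data), names(protocols))
  if (length(missing))
    stop("no protocol supplied for dataset(s): ",
         paste(missing, collapse = ", "))
  protocols <- protocols[names(data)]
  for (nm in names(data)) {
    if (length(data[[nm]]) != length(protocols[[nm]]$ap_times))
      stop(sprintf("dataset '%s' has %d values but its protocol has %d APs",
                   nm, length(data[[nm]]), length(protocols[[nm]]$ap_times)))
    if (any(!is.finite(data[[nm]])) || any(data[[nm]] < 0))
      stop(sprintf("dataset '%s' must be non-negative and finite", nm))
  }
  bad <- setdiff(free, c(fittable_params(), "k2_scale"))
  if (length(bad))
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  if ("k2_scale" %in% free && any(c("k2_0", "s2") %in% free))
    stop("'k2_scale' cannot be combined with free 'k2_0' or 's2'")
  structure(list(data = data, protocols = protocols, start = start,
                 cap = cap, free = free), class = "fit_problem")
}

# precompute grid geometry and Ca2+ traces once per problem (they do not
# depend on the priming parameters)
prep_grids <- function(protocols, cap, dt) {
  lapply(protocols, function(pr) {
    ap_steps <- as.integer(round(pr$ap_times / dt))
    list(ap_steps = ap_steps,
         ca = ca_grid(ap_steps, ap_steps[length(ap_steps)], dt, cap))
  })
}

sim_released <- function(grid, p, cap, dt) {
  s0 <- resting_state(p, cap)
  sim_core_cpp(grid$ap_steps, grid$ca, dt,
               p$b1, p$k1_max, p$K_M, p$k2_0, p$s2, p$b2, p$b3,
               p$f_tsl, p$p_fusion, cap$ca_rest, unclass(s0))$released
}

#' Root-mean-square deviation between model and data
#'
#' The fitting objective: the square root of the mean squared residual
#' between model per-site release fractions and observed ones
#' (quanta / `n_sites`), pooled over all APs of all protocols with equal
#' weight per AP.
#'
#' @param params a [priming_params()] object.
#' @param data,protocols as in [fit_problem()] (a `fit_problem` can be given
#'   as `data`).
#' @param cap a [calcium_params()] object.
#' @param dt integration step, s.
#' @return The pooled rmsd (dimensionless, per-site release scale).
#' @export
#' @examples
#' p <- fsin_params()
#' prot <- standard_protocols()["train_20hz_6"]
#' d <- list(train_20hz_6 = simulate_protocol(prot[[1]], p)$quanta)
#' rmsd_objective(p, d, prot)  # ~0: model evaluated at generating values
rmsd_objective <- function(params, data, protocols = NULL,
                           cap = calcium_params(), dt = 1e-4) {
  if (inherits(data, "fit_problem")) {
    protocols <- data$protocols; cap <- data$cap; data <- data$data
  }
  grids <- prep_grids(protocols[names(data)], cap, dt)
  res <- unlist(lapply(names(data), function(nm) {
    sim_released(grids[[nm]], params, cap, dt) -
      data[[nm]] / params$n_sites
  }))
  sqrt(mean(res^2))
}

theta_pack <- function(free, params, base, bounds) {
  log_scaled <- c("b1", "k1_max", "K_M", "k2_0", "s2", "b2", "b3", "k2_scale")
  val <- vapply(free, function(nm) {
    if (nm == "k2_scale") return(params$k2_0 / base$k2_0)
    params[[nm]]
  }, numeric(1))
  lo <- bounds$lower[free]; hi <- bounds$upper[free]
  is_log <- free %in% log_scaled
  theta <- ifelse(is_log, log(pmin(pmax(val, lo), hi)), val)
  list(theta = theta,
       lower = ifelse(is_log, log(lo), lo),
       upper = ifelse(is_log, log(hi), hi),
       is_log = is_log)
}

theta_unpack <- function(theta, free, is_log, base) {
  p <- unclass(base)
  for (i in seq_along(free)) {
    v <- if (is_log[i]) exp(theta[i]) else theta[i]
    if (free[i] == "k2_scale") {
      p$k2_0 <- v * base$k2_0
      p$s2 <- v * base$s2
    } else {
      p[[free[i]]] <- v
    }
  }
  structure(p, class = "priming_params")
}

#' Fit the two-step priming model to amplitude-train data
#'
#' Joint bounded least-squares fitting of the model to per-AP quantal
#' contents from one or more protocols, minimizing the pooled
#' [rmsd_objective()] by multi-start local optimization ([stats::nlminb()]
#' over log-transformed rates). The first start is the supplied starting
#' parameter set; remaining starts are drawn log-uniformly (rates) or
#' uniformly (fractions) within the bounds under the given seed, so fits are
#' reproducible. Site count, quantal size and all calcium parameters stay
#' fixed.
#'
#' @param data a [fit_problem()], or a named list of per-AP quantal content
#'   vectors.
#' @param protocols,start,cap,free as in [fit_problem()] (ignored when
#'   `data` is already a problem, except `free` which overrides when given).
#' @param bounds box bounds, see [priming_bounds()].
#' @param n_starts number of optimization starts (>= 1).
#' @param seed integer seed for the random starts.
#' @param dt integration step, s.
#' @param extra_starts optional list of [priming_params()] used as
#'   additional warm starts (e.g. a solution of a nested fit).
#' @param control passed to [stats::nlminb()].
#' @return An object of class \code{"priming_fit"}: fitted parameters,
#'   pooled and per-protocol rmsd, derived quantities (resting tight-state
#'   fraction, vesicular release probability `pv`, resting docking rate
#'   `k1_0`), per-start diagnostics and the problem definition. With zero
#'   free parameters the start is returned with its rmsd (no optimization).
#' @seealso [scaled_fit()], [subset_ladder()], [rmsd_objective()]
#' @export
#' @examples
#' \donttest{
#' p <- olm_params()
#' prots <- standard_protocols()[c("train_20hz_6", "complex_rec110")]
#' obs <- lapply(prots, function(pr) simulate_protocol(pr, p)$quanta)
#' fit <- fit_priming(obs, prots, start = fsin_params(),
#'                    free = c("k2_0", "s2", "p_fusion"), n_starts = 4)
#' coef(fit)
#' }
fit_priming <- function(data, protocols = NULL, start = fsin_params(),
                        cap = calcium_params(),
                        free = c("k2_0", "s2", "p_fusion"),
                        bounds = priming_bounds(), n_starts = 10, seed = 1,
                        dt = 1e-4, extra_starts = list(),
                        control = list(eval.max = 4000, iter.max = 1000)) {
  if (inherits(data, "fit_problem")) {
    problem <- data
    if (!missing(free)) problem$free <- free
  } else {
    problem <- fit_problem(data, protocols, start, cap, free)
  }
  data <- problem$data; protocols <- problem$protocols
  start <- problem$start; cap <- problem$cap; free <- problem$free

  obs_frac <- lapply(data, function(d) d / start$n_sites)
  grids <- prep_grids(protocols, cap, dt)

  objective_of <- function(p) {
    res <- unlist(lapply(names(data), function(nm)
      sim_released(grids[[nm]], p, cap, dt) - obs_frac[[nm]]))
    sqrt(mean(res^2))
  }

  if (length(free) == 0L) {
    fit <- make_fit(start, free, problem, objective_of, dt,
                    starts = data.frame(start = 1L, objective = NA_real_,
                                        convergence = NA_integer_),
                    seed = seed, k2_scale = NA_real_, base = start)
    return(fit)
  }

  pk <- theta_pack(free, start, start, bounds)
  start_thetas <- list(pk$theta)
  for (es in extra_starts) {
    start_thetas <- c(start_thetas,
                      list(theta_pack(free, es, start, bounds)$theta))
  }
  n_random <- max(0L, n_starts - length(start_thetas))
  if (n_random > 0) {
    set.seed(seed)
    for (i in seq_len(n_random)) {
      start_thetas <- c(start_thetas, list(
        pk$lower + runif(length(free)) * (pk$upper - pk$lower)))
    }
  }

  obj_theta <- function(theta) {
    p <- theta_unpack(theta, free, pk$is_log, start)
    v <- tryCatch(objective_of(p), error = function(e) NA_real_)
    if (!is.finite(v)) 1e6 else v
  }

  results <- vector("list", length(start_thetas))
  diag <- data.frame(start = seq_along(start_thetas),
                     objective = NA_real_, convergence = NA_integer_)
  for (i in seq_along(start_thetas)) {
    ans <- tryCatch(
      nlminb(start_thetas[[i]], obj_theta, lower = pk$lower,
             upper = pk$upper, control = control),
      error = function(e) NULL)
    if (!is.null(ans)) {
      results[[i]] <- ans
      diag$objective[i] <- ans$objective
      diag$convergence[i] <- ans$convergence
    }
  }
  ok <- which(!vapply(results, is.null, logical(1)) &
                is.finite(diag$objective))
  if (!length(ok))
    stop("optimization failed from every start; diagnostics:\n",
         paste(utils::capture.output(print(diag)), collapse = "\n"))
  best <- ok[which.min(diag$objective[ok])]
  theta_hat <- results[[best]]$par
  params_hat <- theta_unpack(theta_hat, free, pk$is_log, start)
  k2_scale <- if ("k2_scale" %in% free) {
    v <- theta_hat[which(free == "k2_scale")]
    exp(v)
  } else NA_real_

  make_fit(params_hat, free, problem, objective_of, dt, starts = diag,
           seed = seed, k2_scale = k2_scale, base = start,
           best_start = best)
}

make_fit <- function(params, free, problem, objective_of, dt, starts, seed,
                     k2_scale, base, best_start = NA_integer_) {
  # rmsd is always re-evaluated on the returned parameters
  rmsd <- objective_of(params)
  cap <- problem$cap
  grids <- prep_grids(problem$protocols, cap, dt)
  per_prot <- vapply(names(problem$data), function(nm) {
    res <- sim_released(grids[[nm]], params, cap, dt) -
      problem$data[[nm]] / params$n_sites
    sqrt(mean(res^2))
  }, numeric(1))
  rest <- resting_state(params, cap)
  derived <- list(ts_fraction = ts_fraction(rest),
                  pv = params$p_fusion * ts_fraction(rest),
                  k1_0 = k1_rate(cap$ca_rest, params))
  structure(list(params = params, free = free, rmsd = rmsd,
                 per_protocol_rmsd = per_prot, derived = derived,
                 data = problem$data, protocols = problem$protocols,
                 cap = cap, base = base, dt = dt, starts = starts,
                 best_start = best_start, k2_scale = k2_scale, seed = seed),
            class = "priming_fit")
}

#' Shared scaling-factor fit of the calcium-dependent priming step
#'
#' Constrained two-parameter refit in which `k2_0` and `s2` move together:
#' `k2_0 = g * k2_0(base)`, `s2 = g * s2(base)`, with the scaling factor `g`
#' and the fusion probability free and everything else fixed at the base
#' parameter set. Used to ask whether a single joint change of the second
#' priming step (plus fusion probability) converts one release phenotype
#' into the other.
#'
#' @param data,protocols,base,cap,n_starts,seed,dt,... as in
#'   [fit_priming()]; `base` plays the role of `start`.
#' @return A [fit_priming()] result whose `k2_scale` element holds the
#'   fitted scaling factor.
#' @export
scaled_fit <- function(data, protocols = NULL, base = fsin_params(),
                       cap = calcium_params(), n_starts = 10, seed = 1,
                       dt = 1e-4, ...) {
  fit_priming(data, protocols, start = base, cap = cap,
              free = c("k2_scale", "p_fusion"), n_starts = n_starts,
              seed = seed, dt = dt, ...)
}

#' Exhaustive parameter-subset ladder
#'
#' Refits every subset of `sizes` parameters from `pool`, starting from a
#' base parameter set, and ranks the subsets by fitted rmsd. This is the
#' search used to ask how many (and which) parameters must change to convert
#' a depressing release phenotype into a facilitating one. With
#' `warm_start = TRUE` each fit whose free set contains the best
#' smaller-subset solution also starts from that solution, so best rmsd is
#' non-increasing in subset size.
#'
#' @param data,protocols,base,cap,dt as in [fit_priming()].
#' @param sizes subset sizes to scan.
#' @param pool candidate parameter names.
#' @param n_starts optimization starts per subset.
#' @param seed seed for the random starts.
#' @param warm_start seed larger subsets with nested best solutions.
#' @return An object of class \code{"priming_ladder"}: a ranked table
#'   (`$table`: size, subset, rmsd) and the best [fit_priming()] result per
#'   size (`$best`).
#' @export
subset_ladder <- function(data, protocols = NULL, base = fsin_params(),
                          cap = calcium_params(), sizes = 1:3,
                          pool = fittable_params(), n_starts = 3, seed = 1,
                          dt = 1e-4, warm_start = TRUE) {
  rows <- list()
  best <- list()
  prev_best <- NULL
  for (s in sort(sizes)) {
    subsets <- utils::combn(pool, s, simplify = FALSE)
    fits <- vector("list", length(subsets))
    for (j in seq_along(subsets)) {
      sub <- subsets[[j]]
      extra <- list()
      if (warm_start && !is.null(prev_best) &&
          all(prev_best$free %in% sub))
        extra <- list(prev_best$params)
      fits[[j]] <- fit_priming(data, protocols, start = base, cap = cap,
                               free = sub, n_starts = n_starts,
                               seed = seed + j, dt = dt,
                               extra_starts = extra)
    }
    rmsds <- vapply(fits, `[[`, numeric(1), "rmsd")
    ord <- order(rmsds)
    rows[[as.character(s)]] <- data.frame(
      size = s,
      subset = vapply(subsets[ord], paste, character(1), collapse = "+"),
      rmsd = rmsds[ord], stringsAsFactors = FALSE)
    best[[as.character(s)]] <- fits[[ord[1]]]
    prev_best <- fits[[ord[1]]]
  }
  structure(list(table = do.call(rbind, rows), best = best,
                 sizes = sort(sizes)),
            class = "priming_ladder")
}

#' @export
print.priming_ladder <- function(x, n = 3, ...) {
  cat("Parameter-subset ladder (top", n, "per size)\n")
  for (s in x$sizes) {
    tab <- x$table[x$table$size == s, , drop = FALSE]
    cat(sprintf(" size %d:\n", s))
    for (i in seq_len(min(n, nrow(tab))))
      cat(sprintf("   %-28s rmsd = %.6g\n", tab$subset[i], tab$rmsd[i]))
  }
  invisible(x)
}

# ---- priming_fit methods ----------------------------------------------------

#' @export
print.priming_fit <- function(x, ...) {
  cat("Two-step priming model fit\n")
  cat(sprintf("  protocols : %s\n", paste(names(x$data), collapse = ", ")))
  cat(sprintf("  free      : %s\n",
              if (length(x$free)) paste(x$free, collapse = ", ") else "(none)"))
  if (length(x$free)) {
    cf <- coef(x)
    cat("  estimates :",
        paste(sprintf("%s = %.4g", names(cf), cf), collapse = ", "), "\n")
  }
  cat(sprintf("  rmsd      : %.6g (per-site release fraction)\n", x$rmsd))
  cat(sprintf("  derived   : TS fraction %.3f, Pv %.3f, k1_0 %.3g /s\n",
              x$derived$ts_fraction, x$derived$pv, x$derived$k1_0))
  invisible(x)
}

#' @export
coef.priming_fit <- function(object, all = FALSE, ...) {
  if (all) return(unlist(unclass(object$params)))
  if (!length(object$free)) return(numeric(0))
  vapply(object$free, function(nm) {
    if (nm == "k2_scale") object$k2_scale else object$params[[nm]]
  }, numeric(1))
}

#' @export
summary.priming_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.priming_fit")
}

#' @export
print.summary.priming_fit <- function(x, ...) {
  print(x$fit)
  cat("  per-protocol rmsd:\n")
  for (nm in names(x$fit$per_protocol_rmsd))
    cat(sprintf("    %-24s %.6g\n", nm, x$fit$per_protocol_rmsd[nm]))
  cat("  starts:\n")
  print(x$fit$starts, row.names = FALSE)
  invisible(x)
}

#' Model predictions for protocols
#'
#' Simulates the fitted model. By default returns per-AP quantal contents
#' for the fitted protocols; pass `protocols` to predict unseen ones.
#'
#' @param object a [fit_priming()] result.
#' @param protocols optional named list of protocols.
#' @param type `"quanta"`, `"epsc"` (pA) or `"fraction"` (per site).
#' @param ... unused.
#' @return Named list of numeric per-AP predictions.
#' @export
predict.priming_fit <- function(object, protocols = NULL,
                                type = c("quanta", "epsc", "fraction"), ...) {
  type <- match.arg(type)
  if (is.null(protocols)) protocols <- object$protocols
  lapply(protocols, function(pr) {
    sim <- simulate_protocol(pr, object$params, object$cap, dt = object$dt)
    switch(type, quanta = sim$quanta, epsc = sim$epsc_pa,
           fraction = sim$released_fraction)
  })
}

#' @export
fitted.priming_fit <- function(object, ...) predict(object)

#' @export
residuals.priming_fit <- function(object, ...) {
  pred <- predict(object, type = "fraction")
  unlist(lapply(names(object$data), function(nm)
    object$data[[nm]] / object$params$n_sites - pred[[nm]]))
}

#' @export
plot.priming_fit <- function(x, ...) {
  nms <- names(x$data)
  old <- par(mfrow = grDevices::n2mfrow(length(nms)),
             mar = c(4, 4, 2, 1))
  on.exit(par(old))
  pred <- predict(x)
  for (nm in nms) {
    tt <- x$protocols[[nm]]$ap_times
    plot(tt, x$data[[nm]], pch = 16, xlab = "time (s)", ylab = "quanta",
         main = nm, ...)
    lines(tt, pred[[nm]], col = "red3")
  }
  invisible(x)
}

#' Simulate synthetic paired recordings from a fitted model
#'
#' Draws `nsim` synthetic pairs from the fitted parameter set using the
#' package's paired-recording generator and returns the long-format
#' amplitude table.
#'
#' @param object a [fit_priming()] result.
#' @param nsim number of synthetic pairs.
#' @param seed master seed.
#' @param ... passed to [generator_config()] (e.g. `cv`, `noise_sd_pa`).
#' @return A [generate_dataset()] result.
#' @export
simulate.priming_fit <- function(object, nsim = 1, seed = 1, ...) {
  cfg <- generator_config(params = object$params, cap = object$cap,
                          n_pairs = nsim, seed = seed, ...)
  generate_dataset(cfg, object$protocols)
}
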
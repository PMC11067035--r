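#' Configuration of the synthetic paired-recording generator
#'
#' The generator emulates the structure of paired whole-cell recordings:
#' each synthetic pair carries a multiplicative strength factor (lognormal
#' with mean 1 and the given coefficient of variation, emulating
#' pair-to-pair variability in synapse number and size), each trial adds
#' Gaussian baseline noise, and (optionally) quantal release is sampled
#' binomially with `n_sites` trials per AP so that transmission failures
#' emerge naturally at low release probability. Amplitudes are floored at 0.
#' The recorded first-EPSC variability across pairs (CV about 0.76 at
#' pyramidal-cell to fast-spiking interneuron connections) is the default
#' strength CV.
#'
#' @param params generating [priming_params()].
#' @param cap generating [calcium_params()].
#' @param n_pairs number of synthetic pairs.
#' @param cv coefficient of variation of the lognormal pair-strength factor.
#' @param noise_sd_pa per-trial additive noise SD, pA.
#' @param n_trials trials per pair per protocol.
#' @param binomial sample quantal release binomially (otherwise the
#'   deterministic expectation is used).
#' @param seed master seed; per-pair substreams are derived from it.
#' @return An object of class \code{"generator_config"}.
#' @export
generator_config <- function(params = fsin_params(), cap = calcium_params(),
                             n_pairs = 25, cv = 0.76, noise_sd_pa = 2,
                             n_trials = 20, binomial = TRUE, seed = 1) {
  stopifnot(n_pairs >= 1, cv >= 0, noise_sd_pa >= 0, n_trials >= 1)
  structure(list(params = params, cap = cap, n_pairs = as.integer(n_pairs),
                 cv = cv, noise_sd_pa = noise_sd_pa,
                 n_trials = as.integer(n_trials), binomial = binomial,
                 seed = as.integer(seed)),
            class = "generator_config")
}

pair_seed <- function(master, pair_index) {
  as.integer((as.numeric(master) * 48271 + pair_index * 104729) %%
               2147483647)
}

# lognormal with mean 1 and coefficient of variation cv
rlnorm_mean1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate one synthetic pair
#'
#' Simulates the deterministic model response to `protocol` under the
#' generating parameters, then draws `n_trials` noisy trials for pair
#' `pair_index`: \code{amplitude = scale_pair * k_i * q + noise}, where
#' `k_i` is either the deterministic quantal content or a binomial draw
#' with `n_sites` trials and the per-site release fraction as success
#' probability. Reproducible: the pair's random substream is derived from
#' the master seed and the pair index.
#'
#' @param config a [generator_config()].
#' @param protocol a [build_train()] protocol.
#' @param pair_index positive integer identifying the pair.
#' @param sim optional precomputed [simulate_protocol()] result for this
#'   protocol (saves recomputation across pairs).
#' @return A numeric matrix `n_trials x n_ap` of amplitudes (pA) with the
#'   pair strength factor as attribute `"scale"`.
#' @export
generate_pair <- function(config, protocol, pair_index, sim = NULL) {
  stopifnot(inherits(config, "generator_config"), pair_index >= 1)
  if (is.null(sim))
    sim <- simulate_protocol(protocol, config$params, config$cap)
  n_ap <- length(sim$quanta)
  p <- config$params
  set.seed(pair_seed(config$seed, pair_index))
  scale <- rlnorm_mean1(1, config$cv)
  n_tr <- config$n_trials
  if (config$binomial) {
    k <- matrix(rbinom(n_tr * n_ap, size = round(p$n_sites),
                       prob = rep(pmin(1, sim$released_fraction),
                                  each = n_tr)),
                n_tr, n_ap)
  } else {
    k <- matrix(rep(sim$quanta, each = n_tr), n_tr, n_ap)
  }
  amp <- scale * k * p$q +
    matrix(rnorm(n_tr * n_ap, sd = config$noise_sd_pa), n_tr, n_ap)
  amp <- pmax(amp, 0)
  attr(amp, "scale") <- scale
  amp
}

#' Generate a full synthetic paired-recording dataset
#'
#' Applies [generate_pair()] to every pair and protocol and returns a
#' long-format table of trial amplitudes, one row per
#' (pair, protocol, trial, AP).
#'
#' @param config a [generator_config()].
#' @param protocols named list of protocols.
#' @return An object of class \code{"paired_dataset"}: list with
#'   `amplitudes` (data.frame: pair_id, protocol, trial, ap_index,
#'   amplitude_pa), `pair_scales` and `config`.
#' @export
#' @examples
#' cfg <- generator_config(n_pairs = 3, n_trials = 5)
#' d <- generate_dataset(cfg, standard_protocols()["train_20hz_6"])
#' head(d$amplitudes)
generate_dataset <- function(config, protocols) {
  rows <- list()
  scales <- numeric(config$n_pairs)
  for (nm in names(protocols)) {
    sim <- simulate_protocol(protocols[[nm]], config$params, config$cap)
    n_ap <- length(sim$quanta)
    for (i in seq_len(config$n_pairs)) {
      amp <- generate_pair(config, protocols[[nm]], i, sim = sim)
      scales[i] <- attr(amp, "scale")
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = i, protocol = nm,
        trial = rep(seq_len(config$n_trials), times = n_ap),
        ap_index = rep(seq_len(n_ap), each = config$n_trials),
        amplitude_pa = as.vector(amp), stringsAsFactors = FALSE)
    }
  }
  structure(list(amplitudes = do.call(rbind, rows), pair_scales = scales,
                 config = config), class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic paired-recording dataset: %d pairs x %d trials, protocols: %s\n",
    x$config$n_pairs, x$config$n_trials,
    paste(unique(x$amplitudes$protocol), collapse = ", ")))
  invisible(x)
}

#' Grand-total-average amplitude train
#'
#' The unweighted mean across pairs of the per-pair mean amplitude trains:
#' the "GTA" trace used to summarize paired recordings before fitting. Input
#' is either a [generate_dataset()] result (with a protocol name), a
#' long-format amplitude data.frame, or a list/matrix of per-pair mean
#' trains.
#'
#' @param x dataset, data.frame, matrix (pairs in rows) or list of per-pair
#'   mean trains.
#' @param protocol protocol name to extract when `x` covers several.
#' @return Numeric per-AP GTA amplitude train (pA).
#' @export
grand_total_average <- function(x, protocol = NULL) {
  if (inherits(x, "paired_dataset")) x <- x$amplitudes
  if (is.data.frame(x)) {
    if (!is.null(protocol)) x <- x[x$protocol == protocol, , drop = FALSE]
    if (!nrow(x)) stop("no rows for protocol '", protocol, "'")
    per_pair <- aggregate(amplitude_pa ~ ap_index + pair_id, data = x,
                          FUN = mean)
    gta <- aggregate(amplitude_pa ~ ap_index, data = per_pair, FUN = mean)
    return(gta$amplitude_pa[order(gta$ap_index)])
  }
  if (is.list(x)) x <- do.call(rbind, x)
  if (!is.matrix(x)) stop("cannot interpret 'x' as per-pair mean trains")
  colMeans(x)
}

#' GTA quantal contents for every protocol in a dataset
#'
#' Converts the grand-total-average amplitude trains of a synthetic dataset
#' to quantal content, the input expected by [fit_priming()]. By default
#' amplitudes are divided by the quantal size. When `initial_quanta` is
#' given, every train is instead rescaled so that the first response of the
#' first protocol equals that quantal content — the conversion used for the
#' recorded connections, whose initial release was anchored at 5 quanta
#' (pyramidal cell to fast-spiking interneuron; 160 pA at a 32 pA quantal
#' size) and 0.5 quanta (O-LM, estimated at 1/10th). Anchoring removes the
#' across-pair amplitude-scale sampling error from the grand average; the
#' common factor is preserved across protocols so relative amplitudes are
#' untouched.
#'
#' @param dataset a [generate_dataset()] result.
#' @param q quantal size, pA; defaults to the generating value.
#' @param initial_quanta optional quantal content assigned to the first
#'   response of the first protocol.
#' @return Named list of per-AP quantal content vectors.
#' @export
gta_quanta <- function(dataset, q = dataset$config$params$q,
                       initial_quanta = NULL) {
  prots <- unique(dataset$amplitudes$protocol)
  gta <- setNames(lapply(prots, function(nm)
    grand_total_average(dataset, nm)), prots)
  if (is.null(initial_quanta)) {
    scale <- 1 / q
  } else {
    a1 <- gta[[1]][1]
    if (a1 <= 0) stop("cannot anchor: first GTA amplitude is not positive")
    scale <- initial_quanta / a1
  }
  lapply(gta, function(a) a * scale)
}

#' Choose a site count yielding a target first response
#'
#' Returns the integer docking-site count for which the deterministic first
#' response of the model equals `target_quanta` as closely as possible
#' (e.g. 5 quanta for the pyramidal-cell to fast-spiking interneuron
#' connection, 0.5 for the O-LM connection).
#'
#' @param params a [priming_params()] object.
#' @param target_quanta desired first-AP quantal content.
#' @param cap a [calcium_params()] object.
#' @return Integer site count (at least 1).
#' @export
calibrate_sites <- function(params, target_quanta, cap = calcium_params()) {
  rel1 <- apply_ap(resting_state(params, cap), params)$released
  max(1L, as.integer(round(target_quanta / rel1)))
}
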
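#' Short-term plasticity metrics
#'
#' Summary statistics computed from per-AP amplitude trains (measured,
#' synthetic or simulated). All ratio metrics are invariant under scaling
#' the whole train by a positive constant.
#'
#' `paired_pulse_ratio()` is the ratio of the `i`-th to the `j`-th amplitude
#' (default: second over first, PPR 2/1). `steady_state_ratio()` is the mean
#' of the last `k_last` amplitudes over the first, quantifying steady-state
#' depression/facilitation at the end of a train. `fold_change()` is a plain
#' ratio used for drug effects on fitted parameters.
#'
#' @param train numeric per-AP amplitude train, or a
#'   [simulate_protocol()] result.
#' @param i,j numerator and denominator AP indices.
#' @return A single ratio.
#' @export
#' @examples
#' paired_pulse_ratio(c(100, 70))        # 0.7, depression
#' paired_pulse_ratio(c(50, 155))        # 3.1, facilitation
#' steady_state_ratio(c(10, 8, 6, 5, 5, 5))
paired_pulse_ratio <- function(train, i = 2, j = 1) {
  train <- amplitudes_of(train)
  stopifnot(length(train) >= max(i, j))
  if (train[j] <= 0) stop("undefined paired-pulse ratio: reference is not positive")
  train[i] / train[j]
}

#' @param k_last number of trailing amplitudes averaged for the steady
#'   state.
#' @rdname paired_pulse_ratio
#' @export
steady_state_ratio <- function(train, k_last = 3) {
  train <- amplitudes_of(train)
  stopifnot(length(train) > k_last)
  if (train[1] <= 0) stop("undefined ratio: first amplitude is not positive")
  mean(tail(train, k_last)) / train[1]
}

#' @param a,b values compared (e.g. a fitted parameter under drug and in
#'   control).
#' @rdname paired_pulse_ratio
#' @export
fold_change <- function(a, b) {
  if (b <= 0) stop("undefined fold change: denominator is not positive")
  a / b
}

amplitudes_of <- function(x) {
  if (inherits(x, "priming_sim")) x$epsc_pa else as.numeric(x)
}

#' Recovery ratio after a conditioning train
#'
#' The first amplitude of the recovery segment divided by a reference
#' amplitude: either the first EPSC of the first (conditioning) train or the
#' first EPSC of the preconditioning train, matching the two normalizations
#' used for simple and complex protocols respectively.
#'
#' @param x a [simulate_protocol()] result, or a numeric amplitude train
#'   (then `labels` is required).
#' @param reference which amplitude to normalize by.
#' @param labels per-AP segment labels when `x` is a bare numeric train.
#' @return A single ratio.
#' @export
recovery_ratio <- function(x,
                           reference = c("first_of_first_train",
                                         "first_of_preconditioning"),
                           labels = NULL) {
  reference <- match.arg(reference)
  if (inherits(x, "priming_sim")) {
    labels <- x$protocol$labels
    a <- x$epsc_pa
  } else {
    a <- as.numeric(x)
  }
  if (is.null(labels) || length(labels) != length(a))
    stop("per-AP segment labels are required")
  rec <- which(labels == "recovery")
  if (!length(rec)) stop("no 'recovery' segment in labels")
  ref_idx <- if (reference == "first_of_preconditioning") {
    idx <- which(labels == "preconditioning")
    if (!length(idx)) stop("no 'preconditioning' segment in labels")
    idx[1]
  } else {
    which(labels == "train")[1]
  }
  if (is.na(ref_idx)) stop("no 'train' segment in labels")
  if (a[ref_idx] <= 0) stop("undefined recovery ratio: reference is not positive")
  a[rec[1]] / a[ref_idx]
}

#' Vesicular release probability
#'
#' The per-site, per-AP probability that a docked vesicle is released:
#' the product of the fusion probability of fusion-competent vesicles and
#' the resting tight-state fraction, \code{Pv = p_fusion * ts_fraction}.
#' With the fitted values this gives 0.6 x 0.44 = 0.26 for the
#' pyramidal-cell to fast-spiking interneuron connection and
#' 0.36 x 0.07 = 0.025 for the O-LM connection.
#'
#' @param p_fusion fusion probability in \[0, 1\].
#' @param ts_fraction resting tight-state fraction in \[0, 1\].
#' @return The release probability.
#' @export
#' @examples
#' pv(0.6, 0.44)
#' signif(pv(0.36, 0.07), 2)
pv <- function(p_fusion, ts_fraction) {
  stopifnot(p_fusion >= 0, p_fusion <= 1, ts_fraction >= 0, ts_fraction <= 1)
  p_fusion * ts_fraction
}
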
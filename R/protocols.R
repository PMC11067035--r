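#' Stimulation protocols
#'
#' A protocol is an ordered list of action potential times built from
#' segments, each a regular train (`n_ap` APs at `freq_hz`) preceded by a
#' gap. Gaps are measured from the last AP of the previous segment to the
#' first AP of the next. Each AP carries a segment label
#' (`"preconditioning"`, `"train"` or `"recovery"`) used by the metric
#' extractors.
#'
#' @param n_ap number of action potentials (>= 1).
#' @param freq_hz stimulation frequency, Hz (> 0).
#' @param t0 time of the first AP, s.
#' @param label segment label for every AP of this train.
#' @param name protocol name.
#' @return An object of class \code{"stim_protocol"} with elements `name`,
#'   `segments`, `ap_times` (s) and `labels`.
#' @export
#' @examples
#' build_train(15, 5)$ap_times            # 0 .. 2.8 s
#' p <- concat_with_gap(build_train(15, 100), 0.11,
#'                      build_train(6, 100, label = "recovery"))
#' p$ap_times[16] - p$ap_times[15]        # the 110 ms recovery gap
build_train <- function(n_ap, freq_hz, t0 = 0, label = "train", name = NULL) {
  stopifnot(n_ap >= 1, freq_hz > 0, t0 >= 0)
  label <- match.arg(label, c("preconditioning", "train", "recovery"))
  if (is.null(name)) name <- sprintf("%gx%gHz", n_ap, freq_hz)
  seg <- list(list(n_ap = as.integer(n_ap), freq_hz = freq_hz,
                   gap_before_s = t0, label = label))
  new_protocol(name, seg)
}

new_protocol <- function(name, segments) {
  times <- numeric(0)
  labels <- character(0)
  t_last <- NULL
  for (seg in segments) {
    start <- if (is.null(t_last)) seg$gap_before_s else t_last + seg$gap_before_s
    tt <- start + (seq_len(seg$n_ap) - 1) / seg$freq_hz
    times <- c(times, tt)
    labels <- c(labels, rep(seg$label, seg$n_ap))
    t_last <- tt[length(tt)]
  }
  if (any(diff(times) <= 0))
    stop("protocol AP times must be strictly increasing")
  structure(list(name = name, segments = segments, ap_times = times,
                 labels = labels), class = "stim_protocol")
}

#' @param a,b protocols to join.
#' @param gap time between the last AP of `a` and the first AP of `b`, s
#'   (> 0).
#' @rdname build_train
#' @export
concat_with_gap <- function(a, gap, b, name = NULL) {
  stopifnot(inherits(a, "stim_protocol"), inherits(b, "stim_protocol"),
            gap > 0)
  segs_b <- b$segments
  segs_b[[1]]$gap_before_s <- gap
  if (is.null(name)) name <- paste(a$name, b$name, sep = "+")
  new_protocol(name, c(a$segments, segs_b))
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("Stimulation protocol '%s': %d APs, span %.3f s\n",
              x$name, length(x$ap_times), diff(range(x$ap_times))))
  for (seg in x$segments)
    cat(sprintf("  %-15s %2d APs at %4g Hz (gap before: %g s)\n",
                seg$label, seg$n_ap, seg$freq_hz, seg$gap_before_s))
  invisible(x)
}

#' The seven standard paired-recording protocols
#'
#' Three simple trains (15 APs at 5 Hz, 6 APs at 20 Hz, 15 APs at 100 Hz
#' followed by a 6-AP recovery test at 110 ms), two short 100 Hz trains in
#' sequence (6 + 6 APs, recovery at 110 ms or 1.5 s), and two complex
#' protocols (a 6-AP 20 Hz preconditioning train immediately followed by
#' 15 APs at 100 Hz, then a 6-AP 100 Hz recovery test at 110 ms or 1.5 s).
#' Recovery gaps are measured last-AP-to-first-AP. The transition from the
#' 20 Hz preconditioning train to the 100 Hz train keeps the 20 Hz interval
#' (50 ms) by default.
#'
#' @param complex_gap interval between the last preconditioning AP and the
#'   first AP of the 100 Hz train in the complex protocols, s.
#' @return A named list of seven [build_train()] protocols.
#' @export
#' @examples
#' names(standard_protocols())
#' length(standard_protocols()$complex_rec110$ap_times)  # 6 + 15 + 6
standard_protocols <- function(complex_gap = 0.05) {
  rec6 <- function() build_train(6, 100, label = "recovery")
  precond <- build_train(6, 20, label = "preconditioning")
  complex_core <- concat_with_gap(precond, complex_gap, build_train(15, 100))
  p <- list(
    train_5hz_15 = build_train(15, 5, name = "train_5hz_15"),
    train_20hz_6 = build_train(6, 20, name = "train_20hz_6"),
    train_100hz_15_rec110 = concat_with_gap(
      build_train(15, 100), 0.11, rec6(), name = "train_100hz_15_rec110"),
    train_100hz_6_rec110 = concat_with_gap(
      build_train(6, 100), 0.11, rec6(), name = "train_100hz_6_rec110"),
    train_100hz_6_rec1500 = concat_with_gap(
      build_train(6, 100), 1.5, rec6(), name = "train_100hz_6_rec1500"),
    complex_rec110 = concat_with_gap(
      complex_core, 0.11, rec6(), name = "complex_rec110"),
    complex_rec1500 = concat_with_gap(
      complex_core, 1.5, rec6(), name = "complex_rec1500"))
  p
}

#' Read and write protocol JSON files
#'
#' Protocols serialize as \code{\{name, segments: \[\{n_ap, freq_hz,
#' gap_before_s, label\}\]\}}. AP times are recomputed from the segments on
#' read, so a round trip reproduces them bit-exactly.
#'
#' @param protocol a [build_train()] protocol.
#' @param path file path.
#' @return `read_protocol_json()` returns a protocol;
#'   `write_protocol_json()` returns `path` invisibly.
#' @export
write_protocol_json <- function(protocol, path) {
  stopifnot(inherits(protocol, "stim_protocol"))
  jsonlite::write_json(list(name = protocol$name,
                            segments = protocol$segments),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  segs <- lapply(x$segments, function(s)
    list(n_ap = as.integer(s$n_ap), freq_hz = as.numeric(s$freq_hz),
         gap_before_s = as.numeric(s$gap_before_s), label = s$label))
  new_protocol(x$name, segs)
}
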
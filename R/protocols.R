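#' Acquisition protocols
#'
#' Constructors for the two pulse-sequence protocols used in low-field
#' time-domain 1H NMR relaxometry of starch pastes: inversion recovery
#' (pi - t - pi/2) for the spin-lattice relaxation time T1, and the
#' Carr-Purcell-Meiboom-Gill (CPMG) echo train for the spin-spin relaxation
#' time T2. Defaults mirror a typical 15 MHz benchtop protocol: inversion
#' delays 100-1000 ms at a 20 s repetition time; CPMG echo spacing TE = 2 ms,
#' 100 echoes, 15 s repetition time, three signal accumulations.
#'
#' @param delays_ms Inter-pulse delays t for inversion recovery, ms. Must be
#'   positive and strictly increasing.
#' @param te_ms CPMG echo spacing TE, ms (time between successive pi pulses;
#'   echoes are sampled at k * TE, k = 1..n_echoes).
#' @param n_echoes Number of spin echoes acquired (>= 2).
#' @param frequency_mhz Proton Larmor frequency of the spectrometer, MHz.
#' @param repetition_s Repetition (recycle) time between scans, s.
#' @param n_accumulations Number of accumulated (averaged) signal acquisitions;
#'   noise in simulated curves is averaged over this many independent
#'   realizations.
#'
#' @return An object of class `acquisition_protocol` (a list with a
#'   `sequence_kind` field of `"inversion_recovery"` or `"cpmg"`).
#' @examples
#' ir_protocol()
#' cpmg_protocol(n_echoes = 1024)
#' @name protocols
NULL

#' @rdname protocols
#' @export
ir_protocol <- function(delays_ms = seq(100, 1000, by = 100),
                        frequency_mhz = 15,
                        repetition_s = 20,
                        n_accumulations = 1L) {
  stopifnot(length(delays_ms) >= 1, is.numeric(delays_ms))
  if (any(delays_ms <= 0) || any(diff(delays_ms) <= 0)) {
    stop("`delays_ms` must be positive and strictly increasing", call. = FALSE)
  }
  new_protocol(
    sequence_kind = "inversion_recovery",
    delays_ms = as.numeric(delays_ms),
    frequency_mhz = frequency_mhz,
    repetition_s = repetition_s,
    n_accumulations = n_accumulations
  )
}

#' @rdname protocols
#' @export
cpmg_protocol <- function(te_ms = 2,
                          n_echoes = 100L,
                          frequency_mhz = 15,
                          repetition_s = 15,
                          n_accumulations = 3L) {
  stopifnot(is.numeric(te_ms), length(te_ms) == 1)
  if (te_ms <= 0) stop("`te_ms` must be > 0", call. = FALSE)
  if (n_echoes < 2) stop("`n_echoes` must be >= 2", call. = FALSE)
  new_protocol(
    sequence_kind = "cpmg",
    te_ms = as.numeric(te_ms),
    n_echoes = as.integer(n_echoes),
    frequency_mhz = frequency_mhz,
    repetition_s = repetition_s,
    n_accumulations = n_accumulations
  )
}

new_protocol <- function(sequence_kind, ..., frequency_mhz, repetition_s,
                         n_accumulations) {
  if (!is.numeric(frequency_mhz) || frequency_mhz <= 0) {
    stop("`frequency_mhz` must be > 0", call. = FALSE)
  }
  if (!is.numeric(repetition_s) || repetition_s <= 0) {
    stop("`repetition_s` must be > 0", call. = FALSE)
  }
  n_accumulations <- as.integer(n_accumulations)
  if (is.na(n_accumulations) || n_accumulations < 1) {
    stop("`n_accumulations` must be a positive integer", call. = FALSE)
  }
  structure(
    list(
      sequence_kind = sequence_kind,
      ...,
      frequency_mhz = as.numeric(frequency_mhz),
      repetition_s = as.numeric(repetition_s),
      n_accumulations = n_accumulations
    ),
    class = "acquisition_protocol"
  )
}

#' Sampling times of a protocol
#'
#' @param protocol An `acquisition_protocol`.
#' @return Numeric vector of acquisition times in ms: the inversion delays, or
#'   the echo times k * TE for CPMG.
#' @export
protocol_times <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  switch(protocol$sequence_kind,
    inversion_recovery = protocol$delays_ms,
    cpmg = seq_len(protocol$n_echoes) * protocol$te_ms,
    stop("unknown sequence kind", call. = FALSE)
  )
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  if (x$sequence_kind == "inversion_recovery") {
    cat(sprintf(
      "<inversion-recovery protocol> %d delays %.0f-%.0f ms, %.0f MHz, TR %.0f s\n",
      length(x$delays_ms), min(x$delays_ms), max(x$delays_ms),
      x$frequency_mhz, x$repetition_s
    ))
  } else {
    cat(sprintf(
      "<CPMG protocol> TE %.3g ms x %d echoes, %.0f MHz, TR %.0f s, %d accumulations\n",
      x$te_ms, x$n_echoes, x$frequency_mhz, x$repetition_s, x$n_accumulations
    ))
  }
  invisible(x)
}
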
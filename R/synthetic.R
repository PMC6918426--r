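#' Ground-truth parameter set for a simulated acquisition
#'
#' Bundles the generating parameters of a synthetic relaxation decay: the
#' equilibrium amplitude M0, the spin-lattice time T1, one or more spin-spin
#' components (T2i, p_i), and the amplitude noise level.
#'
#' @param m0 Equilibrium magnetization amplitude, arbitrary units (> 0).
#' @param t1_ms Spin-lattice relaxation time, ms (required for inversion
#'   recovery).
#' @param t2_ms Numeric vector of spin-spin relaxation times, ms (required for
#'   CPMG).
#' @param fractions Proton fractions p_i matching `t2_ms`; must be
#'   non-negative and sum to 1 (within 1e-9). Defaults to a single fraction of
#'   1 when one T2 is given.
#' @param noise_sd Standard deviation of additive zero-mean Gaussian amplitude
#'   noise, same units as `m0` (>= 0). Interpreted per accumulated trace; the
#'   generators average `n_accumulations` independent noisy realizations.
#'
#' @return An object of class `synthetic_truth`.
#' @examples
#' synthetic_truth(m0 = 100, t1_ms = 1663, t2_ms = 471)
#' synthetic_truth(m0 = 100, t2_ms = c(220, 785), fractions = c(0.3, 0.7))
#' @export
synthetic_truth <- function(m0 = 100, t1_ms = NULL, t2_ms = NULL,
                            fractions = NULL, noise_sd = 0) {
  stopifnot(is.numeric(m0), length(m0) == 1)
  if (m0 <= 0) stop("`m0` must be > 0", call. = FALSE)
  if (!is.null(t1_ms)) {
    if (!is.numeric(t1_ms) || length(t1_ms) != 1 || t1_ms <= 0) {
      stop("`t1_ms` must be a single positive number", call. = FALSE)
    }
  }
  if (!is.null(t2_ms)) {
    if (!is.numeric(t2_ms) || any(t2_ms <= 0)) {
      stop("all `t2_ms` must be > 0", call. = FALSE)
    }
    if (is.null(fractions)) {
      if (length(t2_ms) != 1) {
        stop("`fractions` required when more than one T2 component is given",
             call. = FALSE)
      }
      fractions <- 1
    }
    if (length(fractions) != length(t2_ms)) {
      stop("`fractions` and `t2_ms` must have the same length", call. = FALSE)
    }
    if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
      stop("`fractions` must be non-negative and sum to 1", call. = FALSE)
    }
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    stop("`noise_sd` must be a single number >= 0", call. = FALSE)
  }
  structure(
    list(m0 = as.numeric(m0), t1_ms = t1_ms, t2_ms = t2_ms,
         fractions = fractions, noise_sd = as.numeric(noise_sd)),
    class = "synthetic_truth"
  )
}

#' Sampled relaxation decay curve
#'
#' A decay curve is the sampled magnetization amplitude of one acquisition:
#' Mz(t) for inversion recovery, echo amplitudes Mxy(k TE) for CPMG.
#'
#' @param times_ms Sampling times, ms; strictly increasing, length >= 2.
#' @param amplitudes Amplitudes at `times_ms`, arbitrary units.
#' @param protocol Optional `acquisition_protocol` the curve was acquired with.
#' @param truth Optional `synthetic_truth` carrying the generating parameters.
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(times_ms, amplitudes, protocol = NULL, truth = NULL) {
  stopifnot(is.numeric(times_ms), is.numeric(amplitudes))
  if (length(times_ms) != length(amplitudes) || length(times_ms) < 2) {
    stop("`times_ms` and `amplitudes` must have equal length >= 2",
         call. = FALSE)
  }
  if (any(diff(times_ms) <= 0)) {
    stop("`times_ms` must be strictly increasing", call. = FALSE)
  }
  if (!is.null(protocol)) stopifnot(inherits(protocol, "acquisition_protocol"))
  if (!is.null(truth)) stopifnot(inherits(truth, "synthetic_truth"))
  structure(
    list(times_ms = as.numeric(times_ms), amplitudes = as.numeric(amplitudes),
         protocol = protocol, truth = truth),
    class = "decay_curve"
  )
}

#' @export
print.decay_curve <- function(x, ...) {
  kind <- if (is.null(x$protocol)) "decay" else x$protocol$sequence_kind
  cat(sprintf("<decay_curve> %s, %d points, t = %.3g..%.3g ms\n",
              kind, length(x$times_ms), min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

#' @export
as.data.frame.decay_curve <- function(x, ...) {
  data.frame(time_ms = x$times_ms, amplitude = x$amplitudes)
}

# Evaluate an expression with a temporary RNG state; the caller's stream is
# untouched and the result depends only on `seed`.
run_seeded <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  fn()
}

# Additive noise averaged over n independent accumulations.
accumulated_noise <- function(n_points, noise_sd, n_accumulations) {
  if (noise_sd == 0) return(rep(0, n_points))
  rowMeans(matrix(stats::rnorm(n_points * n_accumulations, sd = noise_sd),
                  nrow = n_points))
}

#' Closed-form decay models
#'
#' The two noiseless signal models: inversion recovery
#' `Mz(t) = M0 (1 - 2 exp(-t/T1))` and the multiexponential CPMG echo train
#' `Mxy(t) = M0 sum_i p_i exp(-t/T2i)` sampled at echo times t = k TE.
#'
#' @param t_ms Times, ms.
#' @param m0 Equilibrium amplitude.
#' @param t1_ms Spin-lattice relaxation time, ms.
#' @param t2_ms Spin-spin relaxation time(s), ms.
#' @param fractions Proton fractions p_i (same length as `t2_ms`, sum 1).
#' @return Numeric vector of amplitudes at `t_ms`.
#' @name decay_models
NULL

#' @rdname decay_models
#' @export
inversion_recovery_model <- function(t_ms, m0, t1_ms) {
  m0 * (1 - 2 * exp(-t_ms / t1_ms))
}

#' @rdname decay_models
#' @export
cpmg_model <- function(t_ms, m0, t2_ms, fractions) {
  drop(exp(-outer(t_ms, 1 / t2_ms)) %*% (m0 * fractions))
}

#' Simulate an inversion-recovery curve
#'
#' Evaluates `Mz(t) = M0 (1 - 2 exp(-t/T1))` at the protocol's inversion
#' delays and adds i.i.d. zero-mean Gaussian amplitude noise (averaged over
#' the protocol's accumulations). At t = 0 the model gives exactly -M0.
#'
#' @param truth A [synthetic_truth()] with a positive `t1_ms`.
#' @param protocol An inversion-recovery [ir_protocol()].
#' @param seed Optional integer seed; the same seed reproduces the curve
#'   exactly and the caller's RNG state is left untouched.
#' @return A [decay_curve()] carrying the protocol and the truth.
#' @examples
#' generate_inversion_recovery(synthetic_truth(m0 = 100, t1_ms = 1663))
#' @export
generate_inversion_recovery <- function(truth, protocol = ir_protocol(),
                                        seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(protocol, "acquisition_protocol"))
  if (protocol$sequence_kind != "inversion_recovery") {
    stop("`protocol` must be an inversion-recovery protocol", call. = FALSE)
  }
  if (is.null(truth$t1_ms) || truth$t1_ms <= 0) {
    stop("truth must carry a positive `t1_ms`", call. = FALSE)
  }
  t <- protocol_times(protocol)
  clean <- inversion_recovery_model(t, truth$m0, truth$t1_ms)
  amp <- clean + run_seeded(seed, function() {
    accumulated_noise(length(t), truth$noise_sd, protocol$n_accumulations)
  })
  decay_curve(t, amp, protocol = protocol, truth = truth)
}

#' Simulate a CPMG echo train
#'
#' Evaluates `Mxy(k TE) = M0 sum_i p_i exp(-k TE / T2i)` at the echo times
#' k = 1..n_echoes and adds accumulated Gaussian amplitude noise.
#'
#' @inheritParams generate_inversion_recovery
#' @param truth A [synthetic_truth()] with `t2_ms` components whose fractions
#'   sum to 1 (within 1e-9).
#' @param protocol A CPMG [cpmg_protocol()].
#' @return A [decay_curve()] carrying the protocol and the truth.
#' @examples
#' generate_cpmg_train(synthetic_truth(m0 = 100, t2_ms = 471))
#' @export
generate_cpmg_train <- function(truth, protocol = cpmg_protocol(),
                                seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(protocol, "acquisition_protocol"))
  if (protocol$sequence_kind != "cpmg") {
    stop("`protocol` must be a CPMG protocol", call. = FALSE)
  }
  if (is.null(truth$t2_ms)) {
    stop("truth must carry `t2_ms` components", call. = FALSE)
  }
  if (abs(sum(truth$fractions) - 1) > 1e-9) {
    stop("component fractions must sum to 1", call. = FALSE)
  }
  t <- protocol_times(protocol)
  clean <- cpmg_model(t, truth$m0, truth$t2_ms, truth$fractions)
  amp <- clean + run_seeded(seed, function() {
    accumulated_noise(length(t), truth$noise_sd, protocol$n_accumulations)
  })
  decay_curve(t, amp, protocol = protocol, truth = truth)
}

#' Simulate a whole storage study
#'
#' Generates one inversion-recovery curve and one CPMG train per design row
#' (sample x storage day, optionally replicated), with the design supplying
#' the generating parameters per cell. Per-row seeds are derived
#' deterministically from `seed`, so a fixed seed reproduces every amplitude
#' bit for bit.
#'
#' @param design A data frame with columns `starch`, `hydrocolloid`, `day`,
#'   `m0`, `t1_ms`, a list-column `t2_components` (each element a data frame
#'   with `time_ms` and `fraction`), `noise_sd`, and optionally `replicate`.
#'   See [design_from_reference()] for the standard constructor.
#' @param ir An inversion-recovery protocol.
#' @param cpmg A CPMG protocol. The default uses 1024 echoes: starch-paste
#'   bulk-water T2 of 500-1000 ms is far longer than the 200 ms span of a
#'   100-echo, 2 ms train, so recovery fixtures extend the train rather than
#'   the spacing.
#' @param seed Optional integer master seed.
#' @return A tibble: the design columns plus list-columns `ir_curve` and
#'   `cpmg_curve` holding [decay_curve()] objects.
#' @examples
#' d <- design_from_reference(hydrocolloids = "none", snr = Inf)
#' sim <- generate_storage_series(d, seed = 1)
#' nrow(sim) # 15 curve pairs: 3 starches x 5 days
#' @export
generate_storage_series <- function(design,
                                    ir = ir_protocol(),
                                    cpmg = cpmg_protocol(n_echoes = 1024L),
                                    seed = NULL) {
  design <- tibble::as_tibble(design)
  if (nrow(design) == 0) {
    return(tibble::tibble(
      starch = character(), hydrocolloid = character(), day = numeric(),
      replicate = integer(), m0 = numeric(), t1_ms = numeric(),
      t2_components = list(), noise_sd = numeric(),
      ir_curve = list(), cpmg_curve = list()
    ))
  }
  needed <- c("starch", "hydrocolloid", "day", "m0", "t1_ms",
              "t2_components", "noise_sd")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols)) {
    stop("design lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"replicate" %in% names(design)) design$replicate <- 1L
  key <- paste(design$starch, design$hydrocolloid, design$day,
               design$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (starch, hydrocolloid, day, replicate) keys in design",
         call. = FALSE)
  }
  row_seeds <- if (is.null(seed)) {
    vector("list", nrow(design))
  } else {
    as.list(run_seeded(seed, function() {
      sample.int(.Machine$integer.max - 1L, nrow(design))
    }))
  }
  design$ir_curve <- vector("list", nrow(design))
  design$cpmg_curve <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    comps <- design$t2_components[[i]]
    tr_ir <- synthetic_truth(m0 = design$m0[i], t1_ms = design$t1_ms[i],
                             noise_sd = design$noise_sd[i])
    tr_t2 <- synthetic_truth(m0 = design$m0[i], t2_ms = comps$time_ms,
                             fractions = comps$fraction,
                             noise_sd = design$noise_sd[i])
    s <- row_seeds[[i]]
    design$ir_curve[[i]] <- generate_inversion_recovery(tr_ir, ir, seed = s)
    design$cpmg_curve[[i]] <- generate_cpmg_train(
      tr_t2, cpmg, seed = if (is.null(s)) NULL else s + 1L
    )
  }
  design
}
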
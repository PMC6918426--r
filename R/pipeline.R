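STORAGE_DAYS <- c(1, 2, 10, 30, 90)

#' Fit every curve of a simulated storage study
#'
#' Runs the T1 fitter on each inversion-recovery curve and spin-grouping
#' component selection on each CPMG train of a [generate_storage_series()]
#' table, labels the resulting water fractions, and returns one tidy row per
#' fitted component.
#'
#' @param sim A tibble from [generate_storage_series()].
#' @param max_components Upper limit for the spin-grouping search.
#' @return A tibble with columns `starch`, `hydrocolloid`, `day`, `replicate`,
#'   `kind` (`"T1"`/`"T2"`), `component`, `label`, `time_ms`, `time_sd`,
#'   `fraction`, `fraction_sd`, `m0`, `converged`.
#' @export
fit_storage_series <- function(sim, max_components = 2L) {
  rows <- lapply(seq_len(nrow(sim)), function(i) {
    f1 <- fit_t1_inversion_recovery(sim$ir_curve[[i]])
    f2 <- select_component_count(sim$cpmg_curve[[i]], max_components)
    lab <- label_water_fractions(f2)
    base <- tibble::tibble(starch = sim$starch[i],
                           hydrocolloid = sim$hydrocolloid[i],
                           day = sim$day[i], replicate = sim$replicate[i])
    dplyr::bind_rows(
      dplyr::bind_cols(base, tibble::tibble(
        kind = "T1", component = 1L, label = NA_character_,
        time_ms = f1$components$time_ms, time_sd = f1$components$time_sd,
        fraction = 1, fraction_sd = 0, m0 = f1$m0, converged = f1$converged
      )),
      dplyr::bind_cols(base[rep(1, f2$n_components), ], tibble::tibble(
        kind = "T2", component = seq_len(f2$n_components),
        label = lab$label,
        time_ms = f2$components$time_ms, time_sd = f2$components$time_sd,
        fraction = f2$components$fraction,
        fraction_sd = f2$components$fraction_sd,
        m0 = f2$m0, converged = f2$converged
      ))
    )
  })
  dplyr::bind_rows(rows)
}

#' Correlation times for a fitted study
#'
#' Pairs each sample/day/replicate's fitted T1 with each of its T2 water
#' fractions and inverts the BPP ratio for every pair, so a two-pool (HCS
#' style) sample yields a bound-water and a bulk-water correlation time per
#' day.
#'
#' @param fits Tidy fit table from [fit_storage_series()] (or an equivalent
#'   table of measured values).
#' @param constants A [bpp_constants()].
#' @return A tibble keyed by `starch`, `hydrocolloid`, `day`, `replicate`,
#'   `label` with `t1_ms`, `t2_ms`, `tau_c_s`, interval bounds, coupling and
#'   regime columns.
#' @export
tauc_from_fits <- function(fits, constants = bpp_constants()) {
  t1 <- fits[fits$kind == "T1",
             c("starch", "hydrocolloid", "day", "replicate",
               "time_ms", "time_sd")]
  names(t1)[names(t1) == "time_ms"] <- "t1_ms"
  names(t1)[names(t1) == "time_sd"] <- "t1_sd"
  t2 <- fits[fits$kind == "T2",
             c("starch", "hydrocolloid", "day", "replicate", "label",
               "time_ms", "time_sd", "fraction")]
  names(t2)[names(t2) == "time_ms"] <- "t2_ms"
  names(t2)[names(t2) == "time_sd"] <- "t2_sd"
  joined <- dplyr::inner_join(
    t1, t2, by = c("starch", "hydrocolloid", "day", "replicate"))
  tauc_table(joined, constants)
}

#' Assemble a per-sample storage series
#'
#' Joins the fitted relaxation parameters and the recovered correlation times
#' of one sample into a day-ordered series, reporting (never silently
#' dropping) missing storage days.
#'
#' @param fits Tidy fit rows for a single (starch, hydrocolloid) sample.
#' @param tau_results Optional matching rows from [tauc_from_fits()].
#' @param expected_days Days the design calls for.
#' @return An object of class `storage_series`: a list with `sample_id`,
#'   `data` (day-sorted tibble), `days`, `missing_days`, `complete`.
#' @export
build_series <- function(fits, tau_results = NULL,
                         expected_days = STORAGE_DAYS) {
  fits <- tibble::as_tibble(fits)
  ids <- unique(fits[, c("starch", "hydrocolloid")])
  if (nrow(ids) != 1) {
    stop("`build_series()` expects fits from exactly one sample; got ",
         nrow(ids), call. = FALSE)
  }
  key <- c("starch", "hydrocolloid", "day", "replicate", "kind", "component")
  if (anyDuplicated(fits[, intersect(key, names(fits))])) {
    stop("conflicting duplicate fit records for the same sample/day/component",
         call. = FALSE)
  }
  data <- fits
  if (!is.null(tau_results)) {
    tau <- tibble::as_tibble(tau_results)
    tau <- tau[, intersect(
      c("starch", "hydrocolloid", "day", "replicate", "label",
        "tau_c_s", "tau_c_lo", "tau_c_hi", "coupling_constant", "regime",
        "degenerate"),
      names(tau))]
    data <- dplyr::left_join(
      data, tau,
      by = intersect(c("starch", "hydrocolloid", "day", "replicate", "label"),
                     intersect(names(data), names(tau))))
  }
  data <- data[order(data$day, data$kind, data$component), ]
  days <- sort(unique(data$day))
  missing_days <- setdiff(expected_days, days)
  structure(
    list(sample_id = ids, data = data, days = days,
         missing_days = missing_days, complete = length(missing_days) == 0),
    class = "storage_series"
  )
}

#' @export
print.storage_series <- function(x, ...) {
  cat(sprintf("<storage_series> %s + %s, days %s%s\n",
              x$sample_id$starch, x$sample_id$hydrocolloid,
              paste(x$days, collapse = ", "),
              if (x$complete) "" else sprintf(" (missing: %s)",
                                              paste(x$missing_days,
                                                    collapse = ", "))))
  invisible(x)
}

#' Percent change of a quantity over storage
#'
#' The storage-trend statistic: `100 * (value_b - value_a) / value_a` between
#' two storage days, computed per water-fraction track (so a two-pool sample
#' reports bound and bulk changes separately). By default the change is taken
#' on the mean correlation time; any numeric column of the series (e.g.
#' `time_ms`) can be requested instead.
#'
#' @param series A `storage_series` from [build_series()].
#' @param quantity Column to difference (default `"tau_c_s"`).
#' @param day_a,day_b Baseline and comparison days (both must be present).
#' @param kind Which relaxation kind the quantity lives on (`"T2"` tracks by
#'   default; use `"T1"` for the spin-lattice series).
#' @return A tibble with `starch`, `hydrocolloid`, `label`, `day_a`, `day_b`,
#'   `value_a`, `value_b`, `percent_change`.
#' @export
percent_change <- function(series, quantity = "tau_c_s", day_a = 1,
                           day_b = 90, kind = "T2") {
  stopifnot(inherits(series, "storage_series"))
  d <- series$data
  d <- d[d$kind == kind, ]
  if (!quantity %in% names(d)) {
    stop("quantity `", quantity, "` not found in series", call. = FALSE)
  }
  if (!all(c(day_a, day_b) %in% d$day)) {
    stop("both days must be present in the series", call. = FALSE)
  }
  if (!"label" %in% names(d) || all(is.na(d$label))) d$label <- "all"
  tracks <- unique(d$label)
  rows <- lapply(tracks, function(lb) {
    ya <- d[[quantity]][d$label == lb & d$day == day_a]
    yb <- d[[quantity]][d$label == lb & d$day == day_b]
    if (length(ya) == 0 || length(yb) == 0 || all(is.na(ya)) ||
        all(is.na(yb))) {
      warning(sprintf("track `%s` missing at day %s; skipped", lb,
                      if (length(ya) == 0 || all(is.na(ya))) day_a else day_b),
              call. = FALSE)
      return(NULL)
    }
    va <- mean(ya, na.rm = TRUE)
    vb <- mean(yb, na.rm = TRUE)
    if (!is.finite(va) || va == 0) {
      stop("zero or undefined baseline at day ", day_a, call. = FALSE)
    }
    tibble::tibble(starch = series$sample_id$starch,
                   hydrocolloid = series$sample_id$hydrocolloid,
                   label = lb, day_a = day_a, day_b = day_b,
                   value_a = va, value_b = vb,
                   percent_change = 100 * (vb - va) / va)
  })
  dplyr::bind_rows(rows)
}

# Compact letter display by insertion-absorption over the significance graph:
# start from one column containing every level; for each significantly
# different pair still sharing a column, split that column; absorb columns
# that became subsets of others. Letters follow column creation order, ties
# resolved by level order.
compact_letters <- function(levels, pmat, alpha = 0.05) {
  k <- length(levels)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      if (is.na(pmat[i, j]) || pmat[i, j] > alpha) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {
          a <- col; a[i] <- FALSE
          b <- col; b[j] <- FALSE
          cols[[ci]] <- a
          cols[[length(cols) + 1]] <- b
        }
      }
      # absorb duplicated or contained columns
      keep <- rep(TRUE, length(cols))
      for (ci in seq_along(cols)) {
        for (cj in seq_along(cols)) {
          if (ci == cj || !keep[ci]) next
          if (all(cols[[ci]] <= cols[[cj]]) &&
              (any(cols[[ci]] < cols[[cj]]) || ci > cj)) {
            keep[ci] <- FALSE
            break
          }
        }
      }
      cols <- cols[keep]
    }
  }
  letter_of <- letters[seq_along(cols)]
  vapply(seq_len(k), function(i) {
    paste0(letter_of[vapply(cols, `[`, logical(1), i)], collapse = "")
  }, character(1))
}

#' One-way ANOVA with Tukey HSD homogeneous subsets
#'
#' The storage study's significance machinery: a one-way analysis of variance
#' on replicate measurements across factor levels (storage days by default),
#' followed by all-pairs Tukey honest-significant-difference comparisons at
#' `alpha`, with homogeneous subsets rendered as compact letters — two levels
#' share a letter exactly when their Tukey-adjusted p exceeds `alpha`.
#'
#' @param df Data frame of replicate measurements.
#' @param value Name of the numeric response column.
#' @param group Name of the factor column (e.g. `"day"`).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `group_comparison`: a list with `table`
#'   (level, n, mean, sd, letters), `f_statistic`, `p_value`, `tukey`
#'   (pairwise tibble), `alpha`, `factor`.
#' @examples
#' df <- data.frame(day = rep(c(1, 2, 10), each = 3),
#'                  value = c(10, 11, 10, 10.5, 11, 10.2, 30, 31, 30.4))
#' compare_groups(df, "value", "day")
#' @export
compare_groups <- function(df, value = "value", group = "day", alpha = 0.05) {
  df <- as.data.frame(df)
  stopifnot(value %in% names(df), group %in% names(df))
  g_raw <- df[[group]]
  lev <- if (is.numeric(g_raw)) as.character(sort(unique(g_raw)))
         else unique(as.character(g_raw))
  g <- factor(as.character(g_raw), levels = lev)
  y <- df[[value]]
  counts <- table(g)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("need >= 2 levels with >= 2 replicates each", call. = FALSE)
  }
  within_var <- tapply(y, g, stats::var)
  if (all(within_var == 0)) {
    stop("zero within-group variance everywhere; ANOVA is degenerate",
         call. = FALSE)
  }
  fit <- stats::aov(y ~ g, data = data.frame(y = y, g = g))
  an <- summary(fit)[[1]]
  f_stat <- an[["F value"]][1]
  p_val <- an[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pmat <- matrix(NA_real_, length(lev), length(lev),
                 dimnames = list(lev, lev))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (r in seq_along(pairs)) {
    a <- pairs[[r]][1]; b <- pairs[[r]][2]
    pmat[a, b] <- pmat[b, a] <- tk[r, "p adj"]
  }
  lets <- compact_letters(lev, pmat, alpha)
  tab <- tibble::tibble(
    level = lev,
    n = as.integer(counts[lev]),
    mean = as.numeric(tapply(y, g, mean)[lev]),
    sd = as.numeric(tapply(y, g, stats::sd)[lev]),
    letters = lets
  )
  structure(
    list(table = tab, f_statistic = f_stat, p_value = p_val,
         tukey = tibble::tibble(pair = rownames(tk),
                                diff = tk[, "diff"], p_adj = tk[, "p adj"]),
         alpha = alpha, factor = group),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> one-way ANOVA on `%s`: F = %.3g, p = %.3g\n",
              x$factor, x$f_statistic, x$p_value))
  print(x$table)
  invisible(x)
}

#' Summarize a study as mean +/- SD tables with significance letters
#'
#' Produces the conventional storage-table layout: one row per storage day,
#' one column per relaxation parameter (T1 and T2 for one-pool starches; T1,
#' T2s and T2l for two-pool starches), each cell a `mean +/- sd` string
#' carrying the Tukey homogeneous-subset letter for that column's day-wise
#' comparison.
#'
#' @param measurements Tidy replicate table with columns `starch`,
#'   `hydrocolloid`, `day`, `parameter`, `value`.
#' @param alpha Significance level for the letters.
#' @param digits Decimal places in the formatted cells.
#' @return A tibble: `starch`, `hydrocolloid`, `day`, then one character
#'   column per parameter. Empty input yields an empty tibble.
#' @export
summarize_table <- function(measurements, alpha = 0.05, digits = 0) {
  measurements <- tibble::as_tibble(measurements)
  if (nrow(measurements) == 0) return(tibble::tibble())
  stopifnot(all(c("starch", "hydrocolloid", "day", "parameter", "value")
                %in% names(measurements)))
  param_order <- c("T1", "T2", "T2s", "T2l", "tau_c_s", "tau_c_l", "tau_c")
  fmt <- function(x) formatC(round(x, digits), format = "f", digits = digits)
  groups <- unique(measurements[, c("starch", "hydrocolloid")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    m <- measurements[measurements$starch == groups$starch[i] &
                        measurements$hydrocolloid == groups$hydrocolloid[i], ]
    params <- unique(m$parameter)
    params <- c(intersect(param_order, params), setdiff(params, param_order))
    days <- sort(unique(m$day))
    cells <- tibble::tibble(starch = groups$starch[i],
                            hydrocolloid = groups$hydrocolloid[i], day = days)
    for (p in params) {
      mp <- m[m$parameter == p, ]
      cmp <- compare_groups(mp, "value", "day", alpha)
      cell <- stats::setNames(
        sprintf("%s ± %s %s", fmt(cmp$table$mean), fmt(cmp$table$sd),
                cmp$table$letters),
        cmp$table$level)
      cells[[p]] <- unname(cell[as.character(days)])
    }
    cells
  })
  dplyr::bind_rows(out)
}
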
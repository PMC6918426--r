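#' Reference relaxation times of stored corn starch pastes
#'
#' Published low-field (15 MHz) 1H NMR relaxation times for 5% pastes of
#' normal (NCS, ~20% amylose), waxy (WCS, ~1% amylose) and Hylon (HCS, ~50%
#' amylose) corn starch, alone and blended with 0.2% Arabic (AG), guar (GG)
#' or xanthan (XG) gum, measured after 1, 2, 10, 30 and 90 days of storage at
#' 5 C. NCS and WCS pastes relax with a single T1 and a single T2; HCS pastes
#' show one T1 but two T2 pools — a short "bound water" component (T2s) and a
#' long "bulk water" component (T2l). Values are means +/- SD in ms.
#'
#' This table is the ground truth driving the package's synthetic studies:
#' every simulated storage series draws its generating T1/T2 from these rows.
#'
#' @param hydrocolloids Subset of `c("none", "AG", "GG", "XG")` to return.
#' @return A tibble with columns `starch`, `hydrocolloid`, `day`, `parameter`
#'   (`"T1"`, `"T2"`, `"T2s"`, `"T2l"`), `value_ms`, `sd_ms`.
#' @examples
#' corn_starch_relaxation("none")
#' @export
corn_starch_relaxation <- function(hydrocolloids = c("none", "AG", "GG", "XG")) {
  hydrocolloids <- match.arg(hydrocolloids, several.ok = TRUE)
  days <- c(1, 2, 10, 30, 90)
  rec <- function(starch, hydrocolloid, parameter, value, sd) {
    tibble::tibble(starch = starch, hydrocolloid = hydrocolloid, day = days,
                   parameter = parameter, value_ms = value, sd_ms = sd)
  }
  tab <- dplyr::bind_rows(
    # plain starch pastes
    rec("NCS", "none", "T1", c(1663, 1569, 1557, 1559, 1280), c(5, 4, 8, 7, 6)),
    rec("NCS", "none", "T2", c(471, 467, 468, 253, 186), c(3, 5, 4, 3, 3)),
    rec("WCS", "none", "T1", c(1612, 1650, 1687, 1697, 1614), c(5, 4, 8, 4, 4)),
    rec("WCS", "none", "T2", c(935, 864, 876, 874, 563), c(5, 4, 6, 3, 8)),
    rec("HCS", "none", "T1", c(1401, 1257, 1404, 1385, 1411), c(4, 3, 4, 4, 8)),
    rec("HCS", "none", "T2s", c(220, 239, 172, 146, 156), c(1, 4, 3, 2, 5)),
    rec("HCS", "none", "T2l", c(785, 966, 896, 922, 1010), c(7, 2, 4, 9, 2)),
    # + Arabic gum
    rec("NCS", "AG", "T1", c(1507, 1511, 1483, 1458, 1365), c(4, 2, 4, 5, 1)),
    rec("NCS", "AG", "T2", c(438, 455, 419, 277, 224), c(4, 5, 5, 4, 7)),
    rec("WCS", "AG", "T1", c(1621, 1613, 1608, 1635, 1549), c(4, 4, 5, 2, 3)),
    rec("WCS", "AG", "T2", c(840, 904, 871, 843, 790), c(5, 5, 4, 5, 3)),
    rec("HCS", "AG", "T1", c(1296, 1256, 1339, 1292, 1260), c(2, 2, 1, 4, 2)),
    rec("HCS", "AG", "T2s", c(257, 162, 225, 129, 165), c(4, 4, 3, 4, 5)),
    rec("HCS", "AG", "T2l", c(1204, 808, 1138, 849, 1018), c(4, 5, 5, 4, 7)),
    # + guar gum
    rec("NCS", "GG", "T1", c(1522, 1415, 1379, 1462, 1367), c(2, 2, 4, 2, 1)),
    rec("NCS", "GG", "T2", c(470, 443, 446, 355, 267), c(4, 5, 7, 7, 5)),
    rec("WCS", "GG", "T1", c(1700, 1709, 1690, 1666, 1596), c(3, 3, 4, 3, 3)),
    rec("WCS", "GG", "T2", c(871, 811, 840, 692, 499), c(5, 5, 7, 5, 6)),
    rec("HCS", "GG", "T1", c(1228, 1194, 1298, 1346, 1300), c(2, 2, 4, 3, 3)),
    rec("HCS", "GG", "T2s", c(246, 136, 218, 136, 145), c(5, 5, 7, 8, 5)),
    rec("HCS", "GG", "T2l", c(1142, 778, 989, 1017, 994), c(4, 5, 4, 4, 2)),
    # + xanthan gum
    rec("NCS", "XG", "T1", c(1558, 1587, 1642, 1657, 1542), c(4, 4, 5, 4, 7)),
    rec("NCS", "XG", "T2", c(869, 839, 877, 710, 698), c(5, 4, 4, 6, 5)),
    rec("WCS", "XG", "T1", c(1574, 1597, 1612, 1677, 1582), c(2, 2, 4, 2, 3)),
    rec("WCS", "XG", "T2", c(871, 877, 865, 842, 653), c(4, 5, 4, 4, 5)),
    rec("HCS", "XG", "T1", c(1362, 1225, 1337, 1388, 1225), c(2, 2, 1, 4, 4)),
    rec("HCS", "XG", "T2s", c(358, 298, 225, 153, 183), c(2, 3, 2, 5, 2)),
    rec("HCS", "XG", "T2l", c(497, 459, 801, 617, 472), c(6, 5, 5, 4, 5))
  )
  tab[tab$hydrocolloid %in% hydrocolloids, ]
}

#' Build a simulation design from the reference table
#'
#' Turns the [corn_starch_relaxation()] table (or a compatible subset) into a
#' per-cell simulation design for [generate_storage_series()]. NCS/WCS cells
#' get a single T2 component (fraction 1); HCS cells get the (T2s, T2l) pair
#' with a fixed bound/bulk fraction split — the published work never prints
#' the fractions, so a 0.3/0.7 convention is used and stated as such.
#'
#' @param reference A table shaped like [corn_starch_relaxation()] output.
#' @param hydrocolloids Which hydrocolloid series to include.
#' @param m0 Equilibrium amplitude given to every simulated curve.
#' @param hcs_fractions Length-2 bound/bulk fraction split for two-pool cells.
#' @param snr Signal-to-noise ratio M0 / noise_sd; `Inf` gives noise-free
#'   curves. Default 200, a realistic benchtop figure.
#' @param n_replicates Replicate acquisitions per cell.
#' @return A design tibble accepted by [generate_storage_series()].
#' @export
design_from_reference <- function(reference = corn_starch_relaxation(),
                                  hydrocolloids = c("none", "AG", "GG", "XG"),
                                  m0 = 100,
                                  hcs_fractions = c(0.3, 0.7),
                                  snr = 200,
                                  n_replicates = 1L) {
  stopifnot(length(hcs_fractions) == 2, abs(sum(hcs_fractions) - 1) < 1e-9)
  reference <- reference[reference$hydrocolloid %in% hydrocolloids, ]
  noise_sd <- if (is.infinite(snr)) 0 else m0 / snr
  cells <- unique(reference[, c("starch", "hydrocolloid", "day")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- reference[reference$starch == cells$starch[i] &
                        reference$hydrocolloid == cells$hydrocolloid[i] &
                        reference$day == cells$day[i], ]
    t1 <- cell$value_ms[cell$parameter == "T1"]
    if (length(t1) != 1) {
      stop("each design cell needs exactly one T1 row", call. = FALSE)
    }
    if ("T2" %in% cell$parameter) {
      comps <- tibble::tibble(time_ms = cell$value_ms[cell$parameter == "T2"],
                              fraction = 1)
    } else {
      comps <- tibble::tibble(
        time_ms = c(cell$value_ms[cell$parameter == "T2s"],
                    cell$value_ms[cell$parameter == "T2l"]),
        fraction = hcs_fractions
      )
    }
    tibble::tibble(
      starch = cells$starch[i], hydrocolloid = cells$hydrocolloid[i],
      day = cells$day[i], m0 = m0, t1_ms = t1,
      t2_components = list(comps), noise_sd = noise_sd
    )
  })
  design <- dplyr::bind_rows(rows)
  design <- design[rep(seq_len(nrow(design)), each = n_replicates), ]
  design$replicate <- rep(seq_len(n_replicates), length.out = nrow(design))
  design
}
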
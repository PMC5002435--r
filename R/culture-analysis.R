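# Growth rates, strain ratios, specific GG consumption rates and
# intracellular concentrations from batch-culture measurements.

#' Read a culture time-series table
#'
#' Expects columns `strain`, `condition`, `replicate`, `time_days`, `od730`
#' and optionally `glycerol_mM`. Separator is guessed from the extension
#' (TSV for `.tsv`, otherwise CSV).
#'
#' @param path CSV/TSV file path.
#' @return A tibble sorted by strain, condition, replicate and time.
#' @export
read_culture_csv <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("strain", "condition", "replicate", "time_days", "od730")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("culture table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"glycerol_mM" %in% names(df)) df$glycerol_mM <- NA_real_
  out <- tibble::as_tibble(df)
  dplyr::arrange(out, .data$strain, .data$condition, .data$replicate,
                 .data$time_days)
}

check_series <- function(data) {
  stopifnot(all(c("time_days", "od730") %in% names(data)))
  for (col in c("strain", "condition", "replicate")) {
    if (!col %in% names(data)) data[[col]] <- "1"
  }
  if (!"glycerol_mM" %in% names(data)) data$glycerol_mM <- NA_real_
  grp <- dplyr::group_by(tibble::as_tibble(data), .data$strain,
                         .data$condition, .data$replicate)
  bad <- dplyr::summarise(grp,
                          unordered = is.unsorted(.data$time_days,
                                                  strictly = TRUE),
                          .groups = "drop")
  if (any(bad$unordered)) {
    stop("sample times must be strictly increasing within each replicate")
  }
  grp
}

# log-linear interpolation of OD at time t within one replicate
od_at <- function(time, od, t) {
  if (t < min(time) - 1e-9 || t > max(time) + 1e-9) {
    stop("interval endpoint ", t, " outside sampled range [",
         min(time), ", ", max(time), "]")
  }
  if (any(od <= 0)) stop("non-positive OD in series")
  exp(stats::approx(time, log(od), xout = t, rule = 2)$y)
}

value_at <- function(time, x, t) {
  stats::approx(time, x, xout = t, rule = 2)$y
}

#' Specific growth rate over an interval
#'
#' `mu = ln(OD(t1)/OD(t0)) / (t1 - t0)`, per replicate. Endpoints not
#' sampled exactly are log-linearly interpolated. Negative rates (declining
#' OD) are returned as-is: they are meaningful as data even though a
#' growth-only model cannot reproduce them.
#'
#' @param data Culture measurements: columns `time_days`, `od730` and
#'   (optionally) `strain`, `condition`, `replicate`.
#' @param interval Numeric `c(t0, t1)` in days, `t0 < t1`.
#' @return A tibble with one row per (strain, condition, replicate):
#'   columns `strain`, `condition`, `replicate`, `t0`, `t1`, `mu_per_day`.
#' @examples
#' d <- tibble::tibble(time_days = c(0, 2), od730 = c(0.1, 0.4))
#' growth_rate(d, c(0, 2))$mu_per_day # log(4)/2
#' @export
growth_rate <- function(data, interval) {
  stopifnot(length(interval) == 2, interval[1] < interval[2])
  grp <- check_series(data)
  out <- dplyr::summarise(
    grp,
    t0 = interval[1], t1 = interval[2],
    mu_per_day = {
      od0 <- od_at(.data$time_days, .data$od730, interval[1])
      od1 <- od_at(.data$time_days, .data$od730, interval[2])
      log(od1 / od0) / (interval[2] - interval[1])
    },
    .groups = "drop"
  )
  out
}

#' Growth-rate ratio to a reference strain
#'
#' `100 * mu_strain / mu_reference` over an interval. The ratio is computed
#' for every pairing of a strain replicate with a reference replicate and
#' summarised as mean plus/minus standard deviation, so replicate scatter in
#' both strains propagates into the uncertainty.
#'
#' @param data Culture measurements for all strains (see [growth_rate()]).
#' @param reference Reference strain name (default the cleavage-deficient
#'   mutant `"dslr1670"`).
#' @param interval Numeric `c(t0, t1)` in days.
#' @return A tibble per (strain, condition): `ratio_percent` (mean over
#'   pairings), `sd`, `n_pairs`. Negative ratios are reported as-is and
#'   flagged `nonphysical = TRUE` (a growth model cannot match them).
#' @export
growth_ratio <- function(data, reference = "dslr1670", interval) {
  mus <- growth_rate(data, interval)
  if (!reference %in% mus$strain) {
    stop("reference strain not in data: ", reference)
  }
  ref <- mus[mus$strain == reference, ]
  qry <- mus[mus$strain != reference, ]
  out <- dplyr::group_by(qry, .data$strain, .data$condition)
  out <- dplyr::summarise(
    out,
    t0 = interval[1], t1 = interval[2],
    ratio_percent = {
      rmu <- ref$mu_per_day[ref$condition == .data$condition[1]]
      if (any(abs(rmu) < 1e-12)) stop("reference growth rate is zero")
      pairs <- as.vector(outer(.data$mu_per_day, rmu, "/")) * 100
      mean(pairs)
    },
    sd = {
      rmu <- ref$mu_per_day[ref$condition == .data$condition[1]]
      pairs <- as.vector(outer(.data$mu_per_day, rmu, "/")) * 100
      if (length(pairs) > 1) stats::sd(pairs) else 0
    },
    n_pairs = {
      rmu <- ref$mu_per_day[ref$condition == .data$condition[1]]
      length(.data$mu_per_day) * length(rmu)
    },
    .groups = "drop"
  )
  out$nonphysical <- out$ratio_percent < 0
  out
}

#' Specific GG consumption rate from extracellular glycerol accumulation
#'
#' In a synthesis-deficient strain fed exogenous GG, every extracellular
#' glycerol molecule stems from the cleavage of one GG (the cleavage
#' stoichiometry releases one glycerol per GG), so
#' `qGG = d[glycerol] / (biomass_avg * dt)` with the glycerol change in
#' mmol/L, time in hours, and the mean biomass concentration in gDW/L
#' obtained from OD via `dw_per_od`. The biomass average is the
#' time-weighted (trapezoidal) mean OD over the interval; `"endpoint"`
#' averages only the two endpoint ODs.
#'
#' @param data Culture measurements with `glycerol_mM` (see [growth_rate()]).
#' @param interval Numeric `c(t0, t1)` in days.
#' @param dw_per_od Dry weight per OD730 unit, g/L (default 0.2).
#' @param method `"trapezoid"` (default) or `"endpoint"` biomass averaging.
#' @return A tibble per (strain, condition, replicate) with
#'   `qGG` (mmol gDW^-1 h^-1) and `flag` (`"ok"` or
#'   `"decreasing_glycerol"`; re-uptake is not modelled, so a glycerol
#'   decrease yields `qGG = 0` with a warning).
#' @examples
#' d <- tibble::tibble(time_days = c(0, 2), od730 = c(1, 1),
#'                     glycerol_mM = c(0, 0.1))
#' estimate_qGG(d, c(0, 2))$qGG # 0.1 / (0.2 * 48)
#' @export
estimate_qGG <- function(data, interval, dw_per_od = 0.2,
                         method = c("trapezoid", "endpoint")) {
  method <- match.arg(method)
  stopifnot(length(interval) == 2, interval[1] < interval[2])
  grp <- check_series(data)
  out <- dplyr::summarise(
    grp,
    t0 = interval[1], t1 = interval[2],
    dglyc_mM = {
      if (anyNA(.data$glycerol_mM)) stop("glycerol_mM missing in series")
      value_at(.data$time_days, .data$glycerol_mM, interval[2]) -
        value_at(.data$time_days, .data$glycerol_mM, interval[1])
    },
    od_mean = if (method == "endpoint") {
      (od_at(.data$time_days, .data$od730, interval[1]) +
         od_at(.data$time_days, .data$od730, interval[2])) / 2
    } else {
      inside <- .data$time_days > interval[1] & .data$time_days < interval[2]
      tt <- c(interval[1], .data$time_days[inside], interval[2])
      oo <- c(od_at(.data$time_days, .data$od730, interval[1]),
              .data$od730[inside],
              od_at(.data$time_days, .data$od730, interval[2]))
      sum(diff(tt) * (utils::head(oo, -1) + utils::tail(oo, -1)) / 2) /
        (interval[2] - interval[1])
    },
    .groups = "drop"
  )
  dt_h <- (interval[2] - interval[1]) * 24
  out$qGG <- pmax(out$dglyc_mM, 0) / (dw_per_od * out$od_mean * dt_h)
  out$flag <- ifelse(out$dglyc_mM < 0, "decreasing_glycerol", "ok")
  out$qGG[out$dglyc_mM < 0] <- 0
  if (any(out$dglyc_mM < 0)) {
    warning("glycerol decreases over the interval for ",
            sum(out$dglyc_mM < 0), " replicate(s); returning qGG = 0 ",
            "(re-uptake not modelled)")
  }
  out[, c("strain", "condition", "replicate", "t0", "t1", "qGG", "flag")]
}

#' Intracellular concentration from an extracted amount
#'
#' Converts a measured amount of an intracellular compound into a
#' cytoplasmic concentration, assuming a culture at OD730 of 1 contains
#' `dw_per_od` g dry weight per liter and 1 mg dry weight corresponds to
#' `ul_per_mg_dw` microliter of intracellular volume.
#'
#' @param amount_umol Extracted amount, micromol.
#' @param sample_volume_L Culture volume extracted, liters.
#' @param od730 Optical density of the culture (> 0).
#' @param dw_per_od Dry weight per OD unit, g/L (default 0.2).
#' @param ul_per_mg_dw Intracellular volume per dry weight, uL/mg (default 1).
#' @return Intracellular concentration in mmol/L.
#' @examples
#' intracellular_concentration(0.12, 1e-3, 6) # 100 mmol/L
#' @export
intracellular_concentration <- function(amount_umol, sample_volume_L, od730,
                                        dw_per_od = 0.2, ul_per_mg_dw = 1) {
  stopifnot(all(amount_umol > 0), all(sample_volume_L > 0),
            dw_per_od > 0, ul_per_mg_dw > 0)
  if (any(od730 <= 0)) stop("OD730 must be positive")
  dw_mg <- sample_volume_L * od730 * dw_per_od * 1000 # g/L * L -> g -> mg
  volume_L <- dw_mg * ul_per_mg_dw * 1e-6
  amount_umol / volume_L / 1000 # umol/L -> mmol/L
}
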
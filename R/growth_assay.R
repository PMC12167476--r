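#' Mixed-cell competition assay time series
#'
#' One knockdown (or control) line: mCherry-positive, sgRNA-bearing
#' cells mixed 1:1 with unmarked cells at day 0, with the marker-positive
#' fraction measured by flow cytometry over time. The marker fraction is
#' the only quantity needed -- relative growth is read out from how the
#' odds of being marker-positive change.
#'
#' @param line_id cell line identifier.
#' @param sgrna_id sgRNA identifier.
#' @param is_control logical; `TRUE` for negative-control sgRNA lines.
#' @param day numeric vector of measurement days, strictly increasing
#'   and starting at 0.
#' @param cherry_fraction marker-positive fraction per day, strictly
#'   inside (0, 1).
#' @return An `assay_series` data.frame.
#' @export
assay_series <- function(line_id, sgrna_id, is_control, day,
                         cherry_fraction) {
  if (length(day) != length(cherry_fraction) || length(day) < 1L) {
    stop_("`day` and `cherry_fraction` must have equal positive length")
  }
  if (day[1L] != 0) stop_("timepoints must start at day 0")
  if (any(diff(day) <= 0)) stop_("timepoints must be strictly increasing")
  if (any(cherry_fraction <= 0 | cherry_fraction >= 1)) {
    stop_("cherry fractions must lie strictly inside (0, 1)")
  }
  structure(data.frame(line_id = line_id, sgrna_id = sgrna_id,
                       is_control = isTRUE(is_control), day = day,
                       cherry_fraction = cherry_fraction,
                       stringsAsFactors = FALSE),
            class = c("assay_series", "data.frame"))
}

odds <- function(f) f / (1 - f)

#' mCherry enrichment at a timepoint
#'
#' `E(t) = [f(t)/(1-f(t))] / [f(0)/(1-f(0))]`: the odds of being
#' marker-positive, normalized to day 0. Under constant relative growth
#' rates the odds evolve exponentially, so E is the natural readout:
#' E = 1 means the knockdown line grows like the unmarked competitor,
#' E < 1 slower, E > 1 faster. E depends only on fractions, never on
#' total cell numbers.
#'
#' @param series an [assay_series()].
#' @param t day at which to evaluate (must be a measured timepoint;
#'   default: the last).
#' @return Enrichment E(t), a positive number.
#' @examples
#' s <- assay_series("kd", "sg1", FALSE, c(0, 21), c(0.5, 0.2))
#' enrichment(s, 21)  # 0.25
#' @export
enrichment <- function(series, t = max(series$day)) {
  stopifnot(inherits(series, "assay_series"))
  i <- match(t, series$day)
  if (is.na(i)) {
    stop_("day ", t, " was not measured for line ", series$line_id[1L])
  }
  f0 <- series$cherry_fraction[series$day == 0]
  unname(odds(series$cherry_fraction[i]) / odds(f0))
}

#' Percent growth change of a knockdown line vs control lines
#'
#' `100 * (1 - E_target(t) / median(E_controls(t)))`; positive values
#' mean decreased growth of the knockdown line. Controls are summarized
#' by their median enrichment, robust to one aberrant control line.
#'
#' @param target the knockdown [assay_series()].
#' @param controls list of control [assay_series()] (>= 1).
#' @param t evaluation day (default 21); must be measured in the target
#'   and every control.
#' @return Percent decreased growth (negative = increased growth).
#' @examples
#' kd <- assay_series("kd", "sg1", FALSE, c(0, 21), c(0.5, 0.2))
#' ctl <- list(assay_series("c1", "neg", TRUE, c(0, 21), c(0.5, 0.5)))
#' percent_growth_change(kd, ctl, 21)  # 75
#' @export
percent_growth_change <- function(target, controls, t = 21) {
  if (inherits(controls, "assay_series")) controls <- list(controls)
  if (length(controls) < 1L) stop_("need at least one control series")
  e_t <- enrichment(target, t)
  e_c <- vapply(controls, enrichment, numeric(1L), t = t)
  100 * (1 - e_t / stats::median(e_c))
}

#' Simulate a competition-assay time series
#'
#' Deterministic trajectory in the odds domain: with growth-rate deficit
#' `d` and doubling time `Td`, the marker-positive odds follow
#' `odds(t) = odds(0) * 2^(-t * d / Td)`, i.e. enrichment
#' `E(t) = 2^(-t d / Td)`. Measured fractions are perturbed by
#' multiplicative log-normal noise with coefficient of variation
#' `measurement_cv` (flow-cytometry gating noise), then clamped inside
#' (0, 1).
#'
#' @param deficit fractional growth-rate deficit in `[0, 1]`.
#' @param days measurement days (default every other day for 21 days).
#' @param doubling_time doubling time of unperturbed cells in days.
#' @param measurement_cv multiplicative noise CV on fractions (default 0).
#' @param seed integer seed for the noise.
#' @param f0 day-0 marker-positive fraction (default 0.5, the 1:1 mix).
#' @param line_id,sgrna_id,is_control series metadata.
#' @return An [assay_series()].
#' @export
simulate_assay <- function(deficit, days = seq(0, 21, by = 2),
                           doubling_time = 1, measurement_cv = 0,
                           seed = 1L, f0 = 0.5, line_id = "sim",
                           sgrna_id = "sim_sg", is_control = deficit == 0) {
  stopifnot(is_number(deficit), deficit >= 0, deficit <= 1,
            is_number(doubling_time), doubling_time > 0,
            is_number(measurement_cv), measurement_cv >= 0,
            is_number(f0), f0 > 0, f0 < 1)
  o <- odds(f0) * 2^(-days * deficit / doubling_time)
  f <- o / (1 + o)
  if (measurement_cv > 0) {
    noise <- with_seed(seed, exp(stats::rnorm(length(f), 0, measurement_cv)))
    f <- pmin(pmax(f * noise, 1e-6), 1 - 1e-6)
  }
  assay_series(line_id, sgrna_id, is_control, days, f)
}

#' Estimate the growth-rate deficit from an assay series
#'
#' Inverts the odds model by regressing `log2` enrichment on time
#' through the origin: `log2 E(t) = -(d / Td) t`, so
#' `d = -slope * Td`. Exact on noiseless simulated series.
#'
#' @param series an [assay_series()].
#' @param doubling_time doubling time in days (default 1).
#' @return Estimated deficit (unitless fraction).
#' @export
fit_deficit <- function(series, doubling_time = 1) {
  stopifnot(inherits(series, "assay_series"))
  t <- series$day[-1L]
  y <- vapply(t, function(tt) log2(enrichment(series, tt)), numeric(1L))
  fit <- stats::lm(y ~ 0 + t)
  unname(-stats::coef(fit)[1L] * doubling_time)
}

#' Read / write competition-assay measurements as CSV
#'
#' Long format with columns `line_id`, `sgrna_id`, `is_control`, `day`,
#' `cherry_fraction`; one [assay_series()] per line id.
#'
#' @param path CSV file.
#' @return [read_assay_csv()] returns a named list of [assay_series()].
#' @export
read_assay_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("line_id", "sgrna_id", "is_control", "day", "cherry_fraction")
  if (!all(required %in% names(df))) {
    stop_("assay CSV needs columns ", paste(required, collapse = ", "))
  }
  lapply(split(df, df$line_id), function(d) {
    d <- d[order(d$day), ]
    assay_series(d$line_id[1L], d$sgrna_id[1L],
                 as.logical(d$is_control[1L]), d$day, d$cherry_fraction)
  })
}

#' @rdname read_assay_csv
#' @param series a list of [assay_series()] (or a single one).
#' @export
write_assay_csv <- function(series, path) {
  if (inherits(series, "assay_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
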
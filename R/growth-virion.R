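#' Doubling time from two cell counts
#'
#' `g = t / (3.3 * log10(b / B))`, with `B` the count at the start and `b`
#' the count at the end of a time interval `t` (hours); 3.3 is
#' `~1/log10(2)`, so one doubling over `t` hours gives `g ~ t`.
#'
#' @param B cell count at the start of the interval (> 0).
#' @param b cell count at the end of the interval (> B).
#' @param t interval length in hours (> 0).
#' @return Doubling time in hours.
#' @export
doubling_time <- function(B, b, t) {
  if (any(B <= 0) || any(t <= 0)) stopf("need B > 0 and t > 0")
  if (any(b <= B)) stopf("no growth: end count b must exceed start count B")
  t / (3.3 * log10(b / B))
}

#' PLP-to-bacterium ratio series
#'
#' The ratio of phage-like particles to cells at each timepoint, averaged
#' across replicates after the per-replicate ratio is computed; the
#' maximum ratio and the time it occurs are reported. Timepoints missing
#' in a replicate are skipped, not imputed.
#'
#' @param series a `count_series` tibble: `time_h`, `cells_per_ml`,
#'   `plp_per_ml`, optional `replicate`.
#' @return List: `ratios` tibble (`time_h`, `ratio`, `n_replicates`),
#'   `max_ratio`, `t_max`.
#' @export
plp_ratio_series <- function(series) {
  if (any(series$cells_per_ml <= 0)) {
    stopf("zero cell count at t = %s h", series$time_h[series$cells_per_ml <= 0][1L])
  }
  r <- series$plp_per_ml / series$cells_per_ml
  agg <- tapply(r, series$time_h, mean)
  nrep <- tapply(r, series$time_h, length)
  ratios <- tibble::tibble(
    time_h = as.numeric(names(agg)),
    ratio = as.numeric(agg),
    n_replicates = as.integer(nrep))
  ratios <- ratios[order(ratios$time_h), ]
  i <- which.max(ratios$ratio)
  list(ratios = ratios, max_ratio = ratios$ratio[i], t_max = ratios$time_h[i])
}

#' Capsid volume from diameter
#'
#' Sphere volume `V = (4/3) * pi * (d/2)^3`, full precision; summaries
#' print it to two significant figures (see [format_sig2()]).
#'
#' @param d capsid diameter in nm (> 0).
#' @return Volume in nm^3.
#' @export
capsid_volume <- function(d) {
  if (any(d <= 0)) stopf("capsid diameter must be > 0")
  (4 / 3) * pi * (d / 2)^3
}

#' Two-significant-figure scientific notation (reporting convention)
#'
#' @param x numeric vector.
#' @return Strings like `"1.8E5"`.
#' @export
format_sig2 <- function(x) {
  ex <- floor(log10(abs(x)))
  mant <- signif(x / 10^ex, 2)
  carried <- mant >= 10  # e.g. 9.96 -> "10" -> bump the exponent
  mant[carried] <- mant[carried] / 10
  ex[carried] <- ex[carried] + 1
  sprintf("%.1fE%d", mant, ex)
}

#' Phage genome size range from capsid diameter
#'
#' Genome size is the capsid volume times a DNA packing density. The
#' default density range of 0.40-0.53 bp/nm^3 is calibrated so a 60-nm
#' capsid implies roughly 45-60 kb of packaged dsDNA, the classic
#' tailed-phage regime.
#'
#' @param d capsid diameter in nm (> 0).
#' @param rho packing density range, bp/nm^3 (length-1 or length-2,
#'   positive).
#' @return Named numeric vector in kb (`lower`/`upper`, or a single
#'   `estimate` for a point density).
#' @export
genome_size_from_capsid <- function(d, rho = c(0.40, 0.53)) {
  if (any(d <= 0)) stopf("capsid diameter must be > 0")
  if (any(rho <= 0) || !length(rho) %in% 1:2) {
    stopf("rho must be one or two positive densities (bp/nm^3)")
  }
  v <- capsid_volume(d)
  kb <- sort(v * rho) / 1000
  if (length(kb) == 1L) setNames(kb, "estimate") else setNames(kb, c("lower", "upper"))
}

#' Culture-kinetics simulation parameters
#'
#' Defaults emulate a moderately fast-growing soybean bradyrhizobium
#' lysogen sampled over 48 h: exponential growth at a 7.1-h doubling time,
#' spontaneous induction accumulating phage-like particles at
#' `induction_yield` PLPs per cell per hour against a small first-order
#' decay, and duplicate cultures with lognormal counting noise.
#'
#' @param initial_cells B0, cells/mL at t = 0.
#' @param doubling_time g, hours.
#' @param induction_yield PLPs produced per cell per hour.
#' @param phage_decay first-order PLP decay rate, per hour.
#' @param initial_plps PLPs/mL at t = 0.
#' @param carrying_capacity optional cells/mL cap on growth.
#' @param timepoints sampling times in hours, strictly increasing from 0.
#' @param n_replicates number of duplicate cultures.
#' @param noise `"lognormal"`, `"poisson"` (on counts) or `"none"`.
#' @param noise_sd lognormal sigma on the natural-log scale.
#' @param seed integer seed.
#' @return A `growth_params` list.
#' @export
growth_params <- function(initial_cells = 5e6, doubling_time = 7.1,
                          induction_yield = 0.35, phage_decay = 0.01,
                          initial_plps = 5e5, carrying_capacity = NULL,
                          timepoints = c(0, 6, 12, 24, 36, 48),
                          n_replicates = 2,
                          noise = c("lognormal", "poisson", "none"),
                          noise_sd = 0.1, seed = 1) {
  noise <- match.arg(noise)
  if (initial_cells <= 0 || doubling_time <= 0) {
    stopf("initial_cells and doubling_time must be > 0")
  }
  if (induction_yield < 0 || phage_decay < 0 || initial_plps < 0) {
    stopf("rates and initial PLPs must be >= 0")
  }
  if (timepoints[1L] != 0 || any(diff(timepoints) <= 0)) {
    stopf("timepoints must be strictly increasing and start at 0")
  }
  list(initial_cells = initial_cells, doubling_time = doubling_time,
       induction_yield = induction_yield, phage_decay = phage_decay,
       initial_plps = initial_plps, carrying_capacity = carrying_capacity,
       timepoints = timepoints, n_replicates = as.integer(n_replicates),
       noise = noise, noise_sd = noise_sd, seed = as.integer(seed))
}

## deterministic kinetics: exponential (optionally capped) cells and the
## linear PLP balance dP/dt = y*B(t) - delta*P. Without a cap the ODE has
## a closed form; with a cap it is integrated on a fine grid with the
## exact per-step update for the linear equation.
growth_expected <- function(params, times) {
  r <- log(2) / params$doubling_time
  y <- params$induction_yield
  d <- params$phage_decay
  B0 <- params$initial_cells
  P0 <- params$initial_plps
  K <- params$carrying_capacity
  B <- B0 * exp(r * times)
  if (!is.null(K)) B <- pmin(B, K)
  if (is.null(K)) {
    P <- if (r + d > 0) {
      P0 * exp(-d * times) + y * B0 * (exp(r * times) - exp(-d * times)) / (r + d)
    } else {
      P0 + y * B0 * times
    }
  } else {
    grid <- seq(0, max(times), by = min(0.01, max(times) / 1000))
    Bg <- pmin(B0 * exp(r * grid), K)
    P <- numeric(length(grid))
    P[1L] <- P0
    dt <- diff(grid)
    for (i in seq_along(dt)) {
      if (d > 0) {
        P[i + 1L] <- P[i] * exp(-d * dt[i]) + y * Bg[i] * (1 - exp(-d * dt[i])) / d
      } else {
        P[i + 1L] <- P[i] + y * Bg[i] * dt[i]
      }
    }
    P <- stats::approx(grid, P, xout = times)$y
  }
  list(cells = B, plps = P)
}

#' Simulate culture cell and phage-like-particle counts
#'
#' Cells grow exponentially at the given doubling time (optionally capped
#' at a carrying capacity); PLPs accumulate at `induction_yield` per cell
#' per hour against first-order decay; observed counts are perturbed with
#' the configured noise. Deterministic for a fixed seed.
#'
#' @param params a [growth_params()].
#' @return A `count_series` tibble: `time_h`, `cells_per_ml`,
#'   `plp_per_ml`, `replicate`.
#' @export
simulate_growth_counts <- function(params) {
  set.seed(params$seed)
  exp_vals <- growth_expected(params, params$timepoints)
  rows <- lapply(seq_len(params$n_replicates), function(rep_i) {
    B <- exp_vals$cells
    P <- exp_vals$plps
    if (params$noise == "lognormal") {
      B <- B * rlnorm(length(B), 0, params$noise_sd)
      P <- P * rlnorm(length(P), 0, params$noise_sd)
    } else if (params$noise == "poisson") {
      B <- rpois(length(B), B)
      P <- rpois(length(P), P)
    }
    tibble::tibble(time_h = params$timepoints, cells_per_ml = B,
                   plp_per_ml = P, replicate = rep_i)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("count_series", class(out)))
}

#' Read a count series from TSV
#'
#' Expected columns: `time_h`, `cells_per_ml`, `plp_per_ml`, optional
#' `replicate`.
#'
#' @param path TSV file.
#' @return A `count_series` tibble.
#' @export
read_count_series <- function(path) {
  df <- utils::read.delim(path)
  need <- c("time_h", "cells_per_ml", "plp_per_ml")
  if (!all(need %in% names(df))) {
    stopf("count table must have columns %s", paste(need, collapse = ", "))
  }
  out <- tibble::as_tibble(df)
  structure(out, class = c("count_series", class(out)))
}
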
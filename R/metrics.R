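# Per-frame observables: instance counts by majority colour, instance
# sizes, per-species mass totals over instance members, and mean colour
# values per (majority colour, species) combination.

.METRIC_COLS <- c(
  "time_s", "n_all", "n_red", "n_blue", "size_min", "size_mean", "size_max",
  "mass_beta", "mass_gamma", "mass_instances",
  "c_red_gamma", "c_red_beta", "c_blue_gamma", "c_blue_beta"
)

#' Observables of one sampled frame
#'
#' Computes, over the viable instances of a frame: the instance counts
#' `n_all` (every viable instance, ties included), `n_red` and `n_blue`
#' (majority-colour counts); minimum, mean and maximum instance size in
#' particles; the beta, gamma and total mass summed over instance
#' members; and the mean colour values `c_<x>_<y>` for majority colour
#' `x` and species `y`. Colour means are computed per instance (mean of
#' the +1/-1 colour values of that instance's species-`y` members) and
#' then averaged without weighting across the instances of majority `x`;
#' set `pooled_colors = TRUE` to instead pool all species-`y` particles
#' of majority-`x` instances into one average. Categories with no
#' members yield `NA`.
#'
#' @param x A `sim_state` or trajectory frame.
#' @param instances Optional precomputed [viable_instances()] table.
#' @param pooled_colors Use the pooled-particle colour average instead of
#'   the per-instance-then-across-instances average.
#' @return A one-row data frame with columns `time_s`, `n_all`, `n_red`,
#'   `n_blue`, `size_min`, `size_mean`, `size_max`, `mass_beta`,
#'   `mass_gamma`, `mass_instances`, `c_red_gamma`, `c_red_beta`,
#'   `c_blue_gamma`, `c_blue_beta`.
#' @export
frame_metrics <- function(x, instances = viable_instances(x),
                          pooled_colors = FALSE) {
  t_s <- if (!is.null(x$t)) x$t else x$step * x$dt
  color_mean <- function(maj, nred, nblue) {
    sel <- instances$majority == maj
    nr <- instances[[nred]][sel]
    nb <- instances[[nblue]][sel]
    tot <- nr + nb
    if (!any(tot > 0)) {
      return(NA_real_)
    }
    if (pooled_colors) {
      sum(nr - nb) / sum(tot)
    } else {
      mean(((nr - nb) / tot)[tot > 0])
    }
  }
  n <- nrow(instances)
  out <- data.frame(
    time_s = t_s,
    n_all = n,
    n_red = sum(instances$majority == "red"),
    n_blue = sum(instances$majority == "blue"),
    size_min = if (n) min(instances$size) else NA_real_,
    size_mean = if (n) mean(instances$size) else NA_real_,
    size_max = if (n) max(instances$size) else NA_real_,
    mass_beta = sum(instances$mass_beta),
    mass_gamma = sum(instances$mass_gamma),
    mass_instances = sum(instances$mass),
    c_red_gamma = color_mean("red", "n_gamma_red", "n_gamma_blue"),
    c_red_beta = color_mean("red", "n_beta_red", "n_beta_blue"),
    c_blue_gamma = color_mean("blue", "n_gamma_red", "n_gamma_blue"),
    c_blue_beta = color_mean("blue", "n_beta_red", "n_beta_blue"),
    stringsAsFactors = FALSE
  )
  out[.METRIC_COLS]
}

#' Metric time series over sampled frames
#'
#' Applies [frame_metrics()] to every frame of a trajectory (as returned
#' by [run_simulation()] or [read_trajectory()]).
#'
#' @param frames List of trajectory frames.
#' @inheritParams frame_metrics
#' @return A data frame, one row per frame, in frame order.
#' @export
metrics_series <- function(frames, pooled_colors = FALSE) {
  do.call(rbind, lapply(frames, frame_metrics, pooled_colors = pooled_colors))
}

#' Steady-state summary over the final window of a run
#'
#' Mean and standard deviation of every metric over the final `window_s`
#' seconds of the run: the last `window_s / sample_interval` sampled
#' frames, with the interval inferred from the series. The standard
#' deviation is the population form (divisor `n`).
#'
#' @param series Metric data frame from [metrics_series()].
#' @param window_s Averaging window in seconds.
#' @return A data frame with columns `metric`, `mean`, `sd`.
#' @export
steady_state_summary <- function(series, window_s = 60) {
  interval <- if (nrow(series) > 1) stats::median(diff(series$time_s)) else 1
  n_tail <- round(window_s / interval)
  if (n_tail < 1 || n_tail > nrow(series)) {
    stop("summary window (", window_s, " s) exceeds the sampled series")
  }
  tail_rows <- series[seq(nrow(series) - n_tail + 1, nrow(series)), , drop = FALSE]
  cols <- setdiff(names(series), "time_s")
  pop_sd <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) {
      return(NA_real_)
    }
    sqrt(mean((v - mean(v))^2))
  }
  data.frame(
    metric = cols,
    mean = vapply(tail_rows[cols], function(v) mean(v, na.rm = TRUE), numeric(1)),
    sd = vapply(tail_rows[cols], pop_sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write a metric series as CSV
#'
#' Fixed column order (`time_s`, instance counts, sizes, masses, colour
#' means); missing values are written as empty fields.
#'
#' @param series Metric data frame from [metrics_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(series, path) {
  write.csv(series[.METRIC_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}
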
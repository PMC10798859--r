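#' Run and pause duration statistics
#'
#' Per-kind (minus run, plus run, pause) mean +/- SD durations and normalized
#' duration distributions; undetermined stretches are excluded. Requires at
#' least one run and one pause.
#'
#' @param segments Segment data frame from [segment_tracks()].
#' @param bin_width Histogram bin width for the distributions, s.
#' @return An object of class `run_pause_stats`: `summary` (data frame:
#'   `kind`, `n`, `mean_s`, `sd_s`) and `distributions` (named list of
#'   histograms).
#' @export
run_pause_stats <- function(segments, bin_width = 0.25) {
  keep <- segments[segments$kind %in% c("run_minus", "run_plus", "pause"), ]
  if (!any(keep$kind %in% c("run_minus", "run_plus")) ||
      !any(keep$kind == "pause")) {
    stop("need at least one run and one pause segment")
  }
  summ <- do.call(rbind, lapply(split(keep, keep$kind), function(d) {
    data.frame(kind = d$kind[1], n = nrow(d), mean_s = mean(d$duration_s),
               sd_s = if (nrow(d) > 1) sd(d$duration_s) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  dists <- lapply(split(keep, keep$kind), function(d) {
    brk <- seq(0, max(d$duration_s) + bin_width, by = bin_width)
    hist(d$duration_s, breaks = brk, plot = FALSE)
  })
  structure(list(summary = summ, distributions = dists),
            class = "run_pause_stats")
}

#' @export
print.run_pause_stats <- function(x, ...) {
  cat("Run/pause durations:\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-10s n = %4d  %.2f +/- %.2f s\n", x$summary$kind[i],
                x$summary$n[i], x$summary$mean_s[i], x$summary$sd_s[i]))
  }
  invisible(x)
}

#' Fraction of tracks exceeding a net displacement
#'
#' Counts tracks whose absolute net axial displacement within the (optional)
#' time window exceeds the threshold -- the "motile fraction" of a vesicle
#' population (e.g. 65/196 dextran and 92/214 EGF vesicles moving > 1 um).
#' Printed counts can be supplied directly via `counts`.
#'
#' @param trajectories Long trajectory data frame (ignored when `counts`
#'   given).
#' @param nucleus A [nucleus_ref()].
#' @param threshold Displacement threshold, um.
#' @param window Time window, s (`NULL` = whole track).
#' @param counts Optional `c(k, n)` of pre-tabulated counts.
#' @return List: `k`, `n`, `fraction`, `percent` (raw) and
#'   `percent_rounded`.
#' @export
fraction_over_displacement <- function(trajectories = NULL, nucleus = NULL,
                                       threshold = 1, window = NULL,
                                       counts = NULL) {
  if (!is.null(counts)) {
    k <- counts[1]; n <- counts[2]
  } else {
    if (is.null(trajectories) || !nrow(trajectories)) {
      stop("no trajectories supplied")
    }
    tracks <- split_tracks(trajectories)
    nets <- vapply(tracks, function(tr) {
      if (!is.null(window)) tr <- tr[tr$t_s <= tr$t_s[1] + window, ]
      if (nrow(tr) < 2) return(NA_real_)
      s <- axial_displacement(tr, nucleus)
      abs(s[length(s)])
    }, numeric(1))
    nets <- nets[!is.na(nets)]
    if (!length(nets)) stop("no usable tracks")
    k <- sum(nets > threshold); n <- length(nets)
  }
  if (n <= 0) stop("empty population")
  list(k = k, n = n, fraction = k / n, percent = 100 * k / n,
       percent_rounded = round(100 * k / n))
}

#' Net transport speed per track
#'
#' Absolute net axial displacement over a fixed window, converted to um/min
#' ("net distance moved in 1 min"). Tracks shorter than the window are
#' excluded and counted.
#'
#' @param trajectories Long trajectory data frame.
#' @param nucleus A [nucleus_ref()].
#' @param window Window, s (default 60).
#' @param signed If `TRUE`, keep the minus-ward sign instead of the absolute
#'   value.
#' @return List: `per_track` (data frame `track_id`,
#'   `net_speed_um_min`), `mean`, `sd`, `n`, `n_excluded`.
#' @export
net_speed <- function(trajectories, nucleus, window = 60, signed = FALSE) {
  tracks <- split_tracks(trajectories)
  vals <- lapply(tracks, function(tr) {
    if (max(tr$t_s) - min(tr$t_s) < window) return(NA_real_)
    tr <- tr[tr$t_s <= tr$t_s[1] + window, ]
    s <- axial_displacement(tr, nucleus)
    net <- s[length(s)] * 60 / window
    if (signed) net else abs(net)
  })
  v <- unlist(vals)
  keep <- !is.na(v)
  if (!any(keep)) stop("no tracks span the requested window")
  per <- data.frame(track_id = names(tracks)[keep],
                    net_speed_um_min = unname(v[keep]),
                    stringsAsFactors = FALSE)
  list(per_track = per, mean = mean(per$net_speed_um_min),
       sd = if (nrow(per) > 1) sd(per$net_speed_um_min) else 0,
       n = nrow(per), n_excluded = sum(!keep))
}

#' Expected delivery time to a target
#'
#' Time for a cargo at the cell periphery to reach its target (default a
#' lysosome 10 um away) at the measured net speed: 0.2 um/min gives 50 min,
#' 0.5 um/min gives 20 min.
#'
#' @param net_speed_um_min Net speed, um/min.
#' @param distance_um Distance to target, um.
#' @return Time in minutes (`Inf` with a warning for zero speed).
#' @export
time_to_target <- function(net_speed_um_min, distance_um = 10) {
  if (any(net_speed_um_min < 0)) stop("net speed must be >= 0")
  out <- distance_um / net_speed_um_min
  if (any(net_speed_um_min == 0)) {
    warning("zero net speed: delivery time is infinite")
  }
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by summing hypergeometric probabilities of all
#' tables (with the observed margins) no more probable than the observed
#' one, and the sample odds ratio `ad/bc`. A zero margin gives p = 1,
#' flagged.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List: `p_value`, `odds_ratio`, `flagged_zero_margin`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) {
    stop("`table` must be 2x2; see `freeman_halton()` for larger tables")
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  N <- m1 + m2
  if (m1 == 0 || m2 == 0 || n1 == 0 || (b + d) == 0) {
    return(list(p_value = 1, odds_ratio = NaN, flagged_zero_margin = TRUE))
  }
  support <- max(0, n1 - m2):min(n1, m1)
  probs <- dhyper(support, m1, m2, n1)
  p_obs <- dhyper(a, m1, m2, n1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (a * d) / (b * c)
  list(p_value = min(1, p), odds_ratio = or, flagged_zero_margin = FALSE)
}

#' Freeman-Halton exact test for an r x c table
#'
#' Convenience wrapper around the standard exact-test routine for tables
#' larger than 2x2 (e.g. the full stationary/minus/plus by condition table).
#'
#' @param table Matrix of non-negative integer counts.
#' @return List with `p_value`.
#' @export
freeman_halton <- function(table) {
  list(p_value = stats::fisher.test(as.matrix(table))$p.value)
}

#' Consolidated analysis report
#'
#' Collects the outputs of the pipeline stages into one bundle and optionally
#' writes JSON/CSV tables and summary plots (survival curve, intensity
#' histogram with fit, run/pause distributions, class proportions). Missing
#' stages are omitted with a note.
#'
#' @param stages Named list; recognized names: `residence_fit`
#'   (`survival_fit`), `intensity_fit` (`mixture_fit`), `proportions`
#'   (`proportions_table`), `run_pause` (`run_pause_stats`), `msd_fit`,
#'   `bleach_fit`, `cooccurrence` (summary list), `transport` (list).
#' @param output_dir Optional directory for JSON/CSV/PNG output.
#' @return A list of class `pipeline_report` (the consolidated summary),
#'   invisibly when writing.
#' @export
pipeline_report <- function(stages, output_dir = NULL) {
  if (!length(stages)) {
    stages <- list()
  }
  known <- c("residence_fit", "intensity_fit", "proportions", "run_pause",
             "msd_fit", "bleach_fit", "cooccurrence", "transport")
  notes <- paste("missing stage:", setdiff(known, names(stages)))
  out <- list(notes = notes)
  if (!is.null(stages$residence_fit)) {
    f <- stages$residence_fit
    out$residence <- list(off_rate_per_s = f$rate,
                          mean_residence_s = f$mean_residence,
                          mean_ci_s = f$mean_ci, n = f$n)
  }
  if (!is.null(stages$intensity_fit)) {
    f <- stages$intensity_fit
    out$intensity <- list(mu1 = f$mu1, mu2 = f$mu2, sigma = f$sigma,
                          weight1 = f$weight, mean_ratio = f$mu2 / f$mu1,
                          r_squared = f$r_squared)
  }
  if (!is.null(stages$proportions)) {
    p <- stages$proportions
    out$proportions <- as.data.frame(p)
  }
  if (!is.null(stages$run_pause)) {
    out$run_pause <- stages$run_pause$summary
  }
  if (!is.null(stages$msd_fit)) {
    f <- stages$msd_fit
    out$msd <- list(D_um2_s = f$D, intercept_um2 = f$intercept)
  }
  if (!is.null(stages$bleach_fit)) {
    f <- stages$bleach_fit
    out$bleach <- list(rate_per_s = f$rate, time_constant_s = f$time_constant)
  }
  if (!is.null(stages$cooccurrence)) out$cooccurrence <- stages$cooccurrence
  if (!is.null(stages$transport)) out$transport <- stages$transport
  class(out) <- "pipeline_report"
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(out[setdiff(names(out), "notes")],
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (!is.null(out$proportions)) {
      write.csv(out$proportions, file.path(output_dir, "class_proportions.csv"),
                row.names = FALSE)
    }
    if (!is.null(out$run_pause)) {
      write.csv(out$run_pause, file.path(output_dir, "run_pause.csv"),
                row.names = FALSE)
    }
    report_plots(stages, output_dir)
    return(invisible(out))
  }
  out
}

# summary PNGs for the report bundle
report_plots <- function(stages, output_dir) {
  if (!is.null(stages$residence_fit) && !is.null(stages$residence_durations)) {
    png(file.path(output_dir, "residence_survival.png"), 600, 450)
    x <- sort(stages$residence_durations)
    n <- length(x)
    surv <- (n - seq_len(n)) / n
    keep <- surv > 0  # survival hits zero at the last event; log axis
    plot(x[keep], surv[keep], pch = 16, cex = 0.5, log = "y",
         xlab = "residence time (s)", ylab = "P(tau)",
         main = "Residence-time survival")
    lines(x, exp(-stages$residence_fit$rate * x), col = "grey40", lwd = 2)
    dev.off()
  }
  if (!is.null(stages$intensity_fit)) {
    f <- stages$intensity_fit
    png(file.path(output_dir, "intensity_histogram.png"), 600, 450)
    plot(f$histogram, freq = FALSE, main = "Spot intensity",
         xlab = "intensity (a.u.)")
    xs <- seq(min(f$histogram$breaks), max(f$histogram$breaks), length.out = 200)
    lines(xs, f$weight * dnorm(xs, f$mu1, f$sigma) +
            (1 - f$weight) * dnorm(xs, f$mu2, f$sigma), col = "grey40", lwd = 2)
    dev.off()
  }
  if (!is.null(stages$run_pause)) {
    png(file.path(output_dir, "run_pause_distributions.png"), 800, 400)
    dists <- stages$run_pause$distributions
    par(mfrow = c(1, length(dists)))
    for (nm in names(dists)) {
      plot(dists[[nm]], freq = FALSE, main = nm, xlab = "duration (s)")
    }
    dev.off()
  }
  if (!is.null(stages$proportions)) {
    png(file.path(output_dir, "class_proportions.png"), 500, 450)
    p <- stages$proportions
    barplot(p$percent, names.arg = p$label, ylab = "percent of tracks",
            main = "Track classes")
    dev.off()
  }
  invisible(NULL)
}
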
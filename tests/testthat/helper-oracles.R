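# Independent oracles used across the test files. These deliberately use
# different code paths from the package implementation.

# brute-force run/pause segmentation: explicit scan over maximal
# same-symbol stretches, classifying each stretch by its length
oracle_segment_symbols <- function(symbols, min_run = 4, min_pause = 2) {
  n <- length(symbols)
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && symbols[j + 1L] == symbols[i]) j <- j + 1L
    len <- j - i + 1L
    kind <- if (symbols[i] == "0") {
      if (len >= min_pause) "pause" else "undetermined"
    } else if (len >= min_run) {
      if (symbols[i] == "+") "run_minus" else "run_plus"
    } else "undetermined"
    out[[length(out) + 1L]] <- data.frame(kind = kind, start_step = i,
                                          end_step = j,
                                          stringsAsFactors = FALSE)
    i <- j + 1L
  }
  do.call(rbind, out)
}

# build a trajectory whose axial (toward-nucleus) steps realize the symbols;
# nucleus at the origin, motion along +x so axial displacement = -(dx)
trajectory_from_symbols <- function(symbols, dt = 0.125,
                                    directed_step = 0.05, zero_step = 0.005) {
  steps_axial <- vapply(symbols, function(s) {
    switch(s, "+" = directed_step, "-" = -directed_step,
           "0" = zero_step * sample(c(-1, 1), 1))
  }, numeric(1))
  x <- 20 - cumsum(c(0, steps_axial))
  data.frame(track_id = 1L, frame = seq_along(x) - 1L,
             t_s = (seq_along(x) - 1L) * dt, x_um = x, y_um = 0)
}

# exhaustive-enumeration Fisher p-value for a 2x2 table: all tables with the
# observed margins, probabilities from explicit binomial coefficients
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  N <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(xs, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(N, c1))
  }, numeric(1))
  p_obs <- pr[match(a, xs)]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
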
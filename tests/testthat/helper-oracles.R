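# Independent oracles used across the suite.

# Four-parameter logistic in log10 dose (duplicated here on purpose so the
# tests do not lean on the package's internal curve).
oracle_sigmoid <- function(I, top, bottom, ec50, hill) {
  bottom + (top - bottom) / (1 + 10^((log10(ec50) - log10(I)) * hill))
}

# Brute-force nested-loop version of the negative-feedback recursion,
# written as the literal packet bookkeeping: packet s drives pupil size
# 1 - depth_s * w(lag) at times s..s+L; retinal lux at t is environmental
# lux attenuated by the single deepest constriction from packets before t;
# the reported pupil size at t is the deepest constriction from packets up
# to and including t.
oracle_feedback <- function(alpha, weights, env, horizon) {
  L <- length(weights) - 1
  depth <- numeric(horizon)
  lux <- numeric(horizon)
  for (t in seq_len(horizon)) {
    C <- 0
    if (t > 1) {
      for (s in 1:(t - 1)) {
        lag <- t - s
        if (lag <= L) C <- max(C, depth[s] * weights[lag + 1])
      }
    }
    lux[t] <- (1 - C) * env
    depth[t] <- 1 - alpha(lux[t])
  }
  rpa <- numeric(horizon)
  for (t in seq_len(horizon)) {
    best <- 0
    for (s in 1:t) {
      lag <- t - s
      if (lag <= L) best <- max(best, depth[s] * weights[lag + 1])
    }
    rpa[t] <- 1 - best
  }
  list(rpa = rpa, lux = lux)
}

# Iteratively refined grid search for the least-squares sigmoid
# (top fixed at 1); independent of the package's optimizer.
oracle_sigmoid_grid <- function(li, rpa, bottom_hi = 0.10, n_iter = 8) {
  rng <- list(log_ec50 = c(min(li) - 1, max(li) + 1),
              hill = c(-4, -0.1), bottom = c(0, bottom_hi))
  best <- NULL
  for (it in seq_len(n_iter)) {
    g <- expand.grid(
      log_ec50 = seq(rng$log_ec50[1], rng$log_ec50[2], length.out = 15),
      hill = seq(rng$hill[1], rng$hill[2], length.out = 15),
      bottom = seq(rng$bottom[1], rng$bottom[2], length.out = 9))
    rss <- apply(g, 1, function(p)
      sum((rpa - (p[3] + (1 - p[3]) /
                    (1 + 10^((p[1] - li) * p[2]))))^2))
    b <- g[which.min(rss), ]
    best <- c(as.numeric(b), min(rss))
    shrink <- function(r, center) {
      w <- diff(r) / 6
      c(max(r[1], center - w), min(r[2], center + w))
    }
    rng$log_ec50 <- shrink(rng$log_ec50, b$log_ec50)
    rng$hill <- shrink(rng$hill, b$hill)
    rng$bottom <- shrink(rng$bottom, b$bottom)
  }
  names(best) <- c("log_ec50", "hill", "bottom", "rss")
  best
}

# Grid-refined fit of the decay-rate sigmoid (top/bottom fixed).
oracle_decay_rate_grid <- function(r1, r10, r100, n_iter = 7) {
  rng <- list(mid = c(0, 2), slope = c(0.05, 20))
  best <- NULL
  for (it in seq_len(n_iter)) {
    g <- expand.grid(mid = seq(rng$mid[1], rng$mid[2], length.out = 40),
                     slope = seq(rng$slope[1], rng$slope[2], length.out = 40))
    rss <- apply(g, 1, function(p) {
      pred <- r100 + (r1 - r100) / (1 + 10^((c(0, 1, 2) - p[1]) * p[2]))
      sum((pred - c(r1, r10, r100))^2)
    })
    b <- g[which.min(rss), ]
    best <- list(mid = b$mid, slope = b$slope, rss = min(rss))
    shrink <- function(r, center) {
      w <- diff(r) / 10
      c(max(r[1], center - w), min(r[2], center + w))
    }
    rng$mid <- shrink(rng$mid, b$mid)
    rng$slope <- shrink(rng$slope, b$slope)
  }
  best
}

# Small CSV fixture written at test time.
write_trace_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

default_sweep_intensities <- function() 10^seq(-4, 4)
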
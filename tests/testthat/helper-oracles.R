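# Independent oracles, coded separately from the package implementations.

# gas-exchange equations, transcribed term by term as printed
oracle_vo2 <- function(fr_i, fi_o2, fe_o2, fi_co2, fe_co2, m) {
  num <- (fi_o2 - fe_o2) - fe_o2 * (fe_co2 - fi_co2)
  fr_i * num / ((1 - fe_o2) * m)
}
oracle_vco2 <- function(fr_i, fi_o2, fe_o2, fi_co2, fe_co2, m) {
  # positive orientation: excurrent minus incurrent CO2
  num <- (fe_co2 - fi_co2) - fe_co2 * (fi_o2 - fe_o2)
  fr_i * num / ((1 - fe_co2) * m)
}

# exhaustive optimal-partition dynamic program (no pruning); returns the
# changepoint positions minimising sum of segment RSS + penalty per segment
oracle_segment <- function(x, penalty, min_seg_len = 3) {
  n <- length(x)
  rss <- function(a, b) {
    seg <- x[a:b]
    sum((seg - mean(seg))^2)
  }
  best <- rep(Inf, n + 1)
  best[1] <- 0
  prev <- integer(n + 1)
  for (t in seq_len(n)) {
    if (t < min_seg_len) next
    for (a in 0:(t - min_seg_len)) {
      cand <- best[a + 1] + rss(a + 1, t) + penalty
      if (cand < best[t + 1] - 1e-12) {
        best[t + 1] <- cand
        prev[t + 1] <- a
      }
    }
  }
  cps <- integer(0)
  t <- n
  while (t > 0 && prev[t + 1] > 0) {
    t <- prev[t + 1]
    cps <- c(t, cps)
  }
  list(cps = cps, cost = best[n + 1])
}

# signed-rank two-sided p by explicit bitmask enumeration of sign patterns
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^m - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0])
  }, numeric(1))
  lo <- mean(ws <= w_obs + 1e-9)
  hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# rank-sum two-sided p by recursive enumeration over which pooled ranks
# fall in group 1 (depth-first, no combn)
oracle_rank_sum_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  w_obs <- sum(r[seq_along(x)])
  sums <- c()
  recurse <- function(start, left, acc) {
    if (left == 0) {
      sums <<- c(sums, acc)
      return(invisible())
    }
    for (i in start:(length(r) - left + 1)) {
      recurse(i + 1, left - 1, acc + r[i])
    }
  }
  recurse(1, n1, 0)
  lo <- mean(sums <= w_obs + 1e-9)
  hi <- mean(sums >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# quick builder for a triplicate-phase flux well
make_well <- function(baseline, oligo, fccp, ecar_base = rep(10, 3),
                      ecar_oligo = rep(12, 3), ecar_fccp = rep(35, 3)) {
  tibble::tibble(
    phase = rep(c("baseline", "oligomycin", "fccp"), each = 3),
    cycle_index = 1:9,
    ocr = c(baseline, oligo, fccp),
    ecar = c(ecar_base, ecar_oligo, ecar_fccp)
  )
}

# minimal synthetic gas trace at given per-sample target rates
make_trace <- function(vo2, rer, mass_kg = 0.1, fr_i = 30000,
                       interval_min = 10, animal_id = "A1",
                       start = as.POSIXct("2024-06-01 17:00:00", tz = "UTC")) {
  fi_o2 <- 0.2095
  fi_co2 <- 0.0004
  vco2 <- rer * vo2
  v <- vo2 * mass_kg / fr_i
  cc <- vco2 * mass_kg / fr_i
  feo2 <- fi_o2 - v
  feco2 <- fi_co2 + cc
  for (i in 1:40) {
    feo2 <- (fi_o2 - v) / (1 + (feco2 - fi_co2) - v)
    feco2 <- (cc + fi_co2) / (1 + cc - (fi_o2 - feo2))
  }
  tibble::tibble(
    animal_id = animal_id,
    time = start + 60 * interval_min * (seq_along(vo2) - 1),
    fi_o2 = fi_o2, fe_o2 = feo2, fi_co2 = fi_co2, fe_co2 = feco2,
    fr_i = fr_i, body_mass_kg = mass_kg
  )
}
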
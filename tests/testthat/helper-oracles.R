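# Independent oracles used across the suite.

# Method-of-steps closed form for y'(t) = -y(t - 1), y == 1 for t <= 0:
# propagate polynomial coefficients segment by segment (independent of the
# package's Runge-Kutta path).
poly_dde_oracle <- function(n_segments = 4) {
  polyval <- function(cf, x) {
    s <- 0
    for (c in rev(cf)) s <- s * x + c
    s
  }
  shift_poly <- function(cf) {  # coefficients of p(t - 1)
    n <- length(cf)
    out <- numeric(n)
    for (i in seq_len(n)) {
      bin <- choose(i - 1, 0:(i - 1)) * (-1)^((i - 1):0)
      out[1:i] <- out[1:i] + cf[i] * bin
    }
    out
  }
  segs <- vector("list", n_segments)
  cur <- c(1)
  y0 <- 1
  for (k in seq_len(n_segments) - 1) {
    dp <- -shift_poly(cur)
    ip <- c(0, dp / seq_along(dp))
    ip[1] <- y0 - polyval(ip, k)
    segs[[k + 1]] <- ip
    y0 <- polyval(ip, k + 1)
    cur <- ip
  }
  function(t) vapply(t, function(s) {
    if (s <= 0) return(1)
    k <- min(floor(s), n_segments - 1)
    polyval(segs[[k + 1]], s)
  }, numeric(1))
}

# Deliberately naive full scan: score every offset on both strands with
# per-window lookups (independent of the vectorized column-sweep path).
brute_force_scan_count <- function(seq, pwm, threshold = 0.85) {
  codes <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  L <- pwm$length
  n <- length(codes)
  if (n < L) return(0L)
  rng <- pwm$max_score - pwm$min_score
  count <- 0L
  comp <- c(4L, 3L, 2L, 1L)
  for (o in 0:(n - L)) {
    win <- codes[(o + 1):(o + L)]
    if (anyNA(win)) next
    s_fwd <- sum(pwm$lods[cbind(win, 1:L)])
    rc <- comp[rev(win)]
    s_rev <- sum(pwm$lods[cbind(rc, 1:L)])
    if ((s_fwd - pwm$min_score) / rng >= threshold) count <- count + 1L
    if ((s_rev - pwm$min_score) / rng >= threshold) count <- count + 1L
  }
  count
}

# small noise-free two-tissue CCG scenario reused by several tests
make_core <- local({
  cache <- new.env()
  function(tissue = "All-tissues", duration = 120) {
    key <- paste(tissue, duration)
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_core_clock(clock_params(tissue),
                                          duration = duration)
    cache[[key]]
  }
})
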
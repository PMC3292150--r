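# Shared fixtures and independent brute-force oracles.

FS <- 2000

# a short synthetic world for fast tests: 40 s, NF 16 / TF 14 / F 10
short_config <- function(seed = 1, ...) {
  synthetic_config(duration_s = 40, t_tf = 16, t_f = 30, seed = seed, ...)
}

# trial whose channel-1 sEMG is an arbitrary signal (gonio held at 90)
signal_trial <- function(x, fs = FS, ...) {
  new_trial(cbind(x, x), rep(90, length(x)), fs_emg = fs, fs_gonio = fs, ...)
}

sine <- function(freq, dur_s, fs = FS, amp = 1) {
  amp * sin(2 * pi * freq * seq(0, dur_s - 1 / fs, by = 1 / fs))
}

# trapezoid integral of a psd list (independent of the package trapz)
trapz_ <- function(psd) {
  f <- psd$freqs; p <- psd$power
  sum(diff(f) * (p[-1] + p[-length(p)])) / 2
}

# brute-force per-second majority with tie toward the more severe class
oracle_majority <- function(labels, fs) {
  n_sec <- floor(length(labels) / fs)
  sapply(seq_len(n_sec), function(i) {
    blk <- labels[seq((i - 1) * fs + 1, i * fs)]
    cnt <- sapply(FATIGUE_LEVELS, function(l) sum(blk == l))
    winners <- FATIGUE_LEVELS[cnt == max(cnt)]
    winners[length(winners)]   # FATIGUE_LEVELS is severity-ordered
  })
}

# naive loop implementation of the separability index
oracle_dbi <- function(g1, g2) {
  spread <- function(g) {
    m <- as.matrix(g)
    cen <- colMeans(m)
    d <- numeric(nrow(m))
    for (i in seq_len(nrow(m))) d[i] <- sqrt(sum((m[i, ] - cen)^2))
    if (length(d) > 1) sd(d) else 0
  }
  c1 <- colMeans(as.matrix(g1)); c2 <- colMeans(as.matrix(g2))
  (spread(g1) + spread(g2)) / sqrt(sum((c1 - c2)^2))
}

# closed-form Fisher direction for two classes
oracle_fisher_direction <- function(X, y) {
  cls <- sort(unique(y))
  X1 <- X[y == cls[1], , drop = FALSE]; X2 <- X[y == cls[2], , drop = FALSE]
  Sw <- (crossprod(sweep(X1, 2, colMeans(X1))) +
           crossprod(sweep(X2, 2, colMeans(X2)))) / (nrow(X) - 2)
  solve(Sw, colMeans(X2) - colMeans(X1))
}

angle_between <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(abs(cosang), -1), 1))
}

# per-second phase of a ground-truth label series at given feature times
phase_at <- function(labels, times) {
  as.character(labels$labels)[match(round(times), round(label_times(labels)))]
}
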
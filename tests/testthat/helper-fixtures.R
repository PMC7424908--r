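# Shared fixtures built in code.

# flat series with optional pupil override
flat_series <- function(n = 2000, pupil = 500, rate = 1000, gx = 512, gy = 384) {
  sample_series((seq_len(n) - 1) * 1000 / rate, rep(gx, n), rep(gy, n),
                rep_len(pupil, n), rate)
}

# a quiet trace with one artificial blink: pupil drops to 0 in [on, off] and
# an optional constant-magnitude derivative artifact rides on [off, off+tail]
blinky_series <- function(n = 20000, on = 8000, off = 8200, tail = 0,
                          base = 1000, art_step = 300) {
  p <- rep(base, n)
  p[(on + 1):(off + 1)] <- 0
  if (tail > 0) {
    idx <- (off + 2):(off + 1 + tail)
    p[idx] <- base + art_step * rep_len(c(1, -1), length(idx))
  }
  sample_series(seq_len(n) - 1, rep(0, n), rep(0, n), p, 1000)
}

one_blink <- function(on = 8000, off = 8200) {
  data.frame(onset_ms = on, offset_ms = off)
}

# minimal valid trial record(s)
mk_trials <- function(n = 1, n_targets = 1, onset = 6000, dur = 8000,
                      self_term = FALSE, press = NA_real_, correct = TRUE,
                      subject = "s01", session = "a") {
  resp <- ifelse(correct, n_targets, (n_targets + 1) %% 4)
  data.frame(trial_id = sprintf("t%02d", seq_len(n)),
             n_targets = rep_len(n_targets, n),
             search_onset_ms = rep_len(onset, n),
             search_offset_ms = rep_len(onset + dur, n),
             self_terminated = rep_len(self_term, n),
             press_time_ms = rep_len(press, n),
             response = rep_len(resp, n),
             correct = rep_len(correct, n),
             session_id = session, subject_id = subject)
}

mk_fix <- function(trial_id, onset, duration, x, y) {
  data.frame(trial_id = trial_id, onset_ms = onset,
             offset_ms = onset + duration, duration_ms = duration,
             x_px = x, y_px = y, item_id = NA_integer_, item_class = "none",
             visit_type = "unassigned", discovery_order = NA_integer_)
}

# independent brute-force enumeration oracle for the sign-flip cluster test
brute_cluster_p <- function(d, alpha = 0.05) {
  n <- nrow(d)
  thr <- qt(1 - alpha / 2, n - 1)
  tser <- function(m) {
    mu <- colMeans(m)
    s <- apply(m, 2, sd)
    tt <- mu / (s / sqrt(n))
    tt[s == 0 & mu == 0] <- 0
    tt
  }
  scan <- function(tt) {
    lab <- ifelse(tt > thr, 1, ifelse(tt < -thr, -1, 0))
    res <- list()
    i <- 1
    while (i <= length(tt)) {
      if (lab[i] != 0) {
        j <- i
        while (j < length(tt) && lab[j + 1] == lab[i]) j <- j + 1
        res[[length(res) + 1]] <- sum(tt[i:j])
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
    res
  }
  obs <- scan(tser(d))
  nulls <- numeric(2^n)
  for (k in 0:(2^n - 1)) {
    s <- ifelse(bitwAnd(k, 2^(0:(n - 1))) > 0, -1, 1)
    cls <- scan(tser(s * d))
    nulls[k + 1] <- if (length(cls)) max(abs(unlist(cls))) else 0
  }
  vapply(obs, function(m) (1 + sum(nulls >= abs(m))) / (1 + 2^n), numeric(1))
}
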
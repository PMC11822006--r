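# Shared fixture builders (all generated in code; no stored data).

unit_square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

make_bouts <- function(t_novel, t_familiar, t0 = 50, gap = 30) {
  rows <- list()
  if (t_novel > 0) {
    rows <- c(rows, list(data.frame(start_s = t0, end_s = t0 + t_novel,
                                    object_id = "A", object_class = "novel")))
  }
  if (t_familiar > 0) {
    rows <- c(rows, list(data.frame(start_s = t0 + t_novel + gap,
                                    end_s = t0 + t_novel + gap + t_familiar,
                                    object_id = "B",
                                    object_class = "familiar")))
  }
  do.call(rbind, rows)
}

make_line_track <- function(n = 11, fs = 1, step_cm = 1) {
  behavior_track(t_s = (seq_len(n) - 1) / fs,
                 x_cm = (seq_len(n) - 1) * step_cm - (n - 1) * step_cm / 2,
                 y_cm = rep(0, n), fs = fs)
}

# naive double-loop mutual information oracle (bits)
mi_oracle <- function(joint) {
  p <- joint / sum(joint)
  px <- rowSums(p); pk <- colSums(p)
  acc <- 0
  for (i in seq_len(nrow(p))) {
    for (k in seq_len(ncol(p))) {
      if (p[i, k] > 0) {
        acc <- acc + p[i, k] * log2(p[i, k] / (px[i] * pk[k]))
      }
    }
  }
  acc
}

# step-response trace of an RC membrane (for trace_metrics tests)
make_rc_trace <- function(i_pa, r_mohm = 200, tau_ms = 20, v_rest = -70,
                          delay_ms = 100, dur_ms = 500, dt_ms = 1,
                          total_ms = 800) {
  t <- seq(0, total_ms, by = dt_ms)
  dv_inf <- i_pa * r_mohm / 1000  # mV
  v <- rep(v_rest, length(t))
  during <- t > delay_ms & t <= delay_ms + dur_ms
  v[during] <- v_rest + dv_inf * (1 - exp(-(t[during] - delay_ms) / tau_ms))
  after <- t > delay_ms + dur_ms
  v_end <- v_rest + dv_inf * (1 - exp(-dur_ms / tau_ms))
  v[after] <- v_rest + (v_end - v_rest) * exp(-(t[after] - delay_ms - dur_ms) / tau_ms)
  voltage_trace(t, v, i_pa, delay_ms, dur_ms)
}
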
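# Shared builders for binary test signals.

# Combined signal from run lengths: runs of alternating value starting at
# `first`, e.g. mk_cs(c(3, 2, 4), 1) -> 1 1 1 0 0 1 1 1 1.
mk_cs <- function(runs, first = 1L, foot = "left", Fs = 32, t0 = 0) {
  vals <- rep(c(first, 1L - first), length.out = length(runs))
  combine_signal(rep(vals, runs), foot = foot, sampling_rate = Fs, t0 = t0)
}

# Random gait-like bit vector: alternating runs with geometric-ish lengths.
rand_runs_bits <- function(n, min_run = 1, max_run = 12) {
  bits <- integer(0)
  v <- sample(0:1, 1)
  while (length(bits) < n) {
    bits <- c(bits, rep(v, sample(min_run:max_run, 1)))
    v <- 1L - v
  }
  bits[seq_len(n)]
}

rand_recording <- function(n = 400, Fs = 32, min_run = 1, max_run = 12) {
  fog_recording(
    left = combine_signal(rand_runs_bits(n, min_run, max_run), foot = "left",
                          sampling_rate = Fs),
    right = combine_signal(rand_runs_bits(n, min_run, max_run), foot = "right",
                           sampling_rate = Fs)
  )
}

# Transition-scan oracle for FS/FO events.
scan_events_oracle <- function(bits, Fs = 32) {
  out <- NULL
  for (i in 2:length(bits)) {
    if (bits[i] != bits[i - 1]) {
      out <- rbind(out, data.frame(
        kind = if (bits[i] == 1) "FS" else "FO",
        sample = i - 1L, time_s = (i - 1L) / Fs))
    }
  }
  out
}
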
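# Exhaustive enumeration oracle for constrained sequence alignment:
# minimum path cost over all monotone paths from (1,1) to (m,n) with steps
# {(1,0),(0,1),(1,1)} on a given local-cost matrix. Recursion with a
# running-sum bound (costs are non-negative, so pruning is exact).
dtw_enumerate <- function(cost) {
  m <- nrow(cost)
  n <- ncol(cost)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + cost[i, j]
    if (acc >= best) return(invisible())
    if (i == m && j == n) {
      best <<- acc
      return(invisible())
    }
    if (i < m && j < n) rec(i + 1, j + 1, acc)
    if (i < m) rec(i + 1, j, acc)
    if (j < n) rec(i, j + 1, acc)
  }
  rec(1, 1, 0)
  best
}

sq_cost <- function(x, y) outer(x, y, function(a, b) (a - b)^2)

# Minimal stimulation trial object for operation-level tests: snippet on a
# -5..+25 ms time base with onset at t = 0.
make_trial <- function(snippet, current = 50, fs = 24400) {
  if (is.vector(snippet)) snippet <- matrix(snippet, ncol = 1)
  pre_n <- round(5 * fs / 1000)
  structure(
    list(snippet = snippet, current = current, polarity = "cathodic-first",
         fs = fs, onset_index = pre_n + 1,
         t_ms = (seq_len(nrow(snippet)) - pre_n - 1) / fs * 1000),
    class = "stim_trial"
  )
}

# Recruitment-curve object from explicit bin values (bypasses trial
# binning so fitting can be tested in isolation).
make_curve <- function(bin_center, mean_vpp, n_trials = 1L) {
  structure(
    data.frame(bin_center = bin_center, mean_vpp = mean_vpp,
               n_trials = as.integer(n_trials)),
    class = c("recruitment_curve", "data.frame"),
    bin_width = if (length(bin_center) > 1) diff(bin_center[1:2]) else 5
  )
}

# Align a list of motif renditions to a given template: one renditions x
# bins matrix per channel.
align_sets <- function(rnd, tpl, n_channels) {
  aligned <- lapply(rnd, function(r) {
    apply_warp(r$neural, dtw_align(r$feature, tpl))
  })
  lapply(seq_len(n_channels), function(ch) {
    t(vapply(aligned, function(a) a[, ch], numeric(length(tpl$feature))))
  })
}

# Template-aligned envelope sets for one simulated chronic session: the
# full preprocessing + alignment pipeline, returning one renditions x bins
# matrix per channel.
aligned_env_sets <- function(scenario, day = 1, seed = 1, template_n = 10) {
  ses <- gen_chronic_session(scenario, day = day, seed = seed)
  rnd <- motif_renditions(ses)
  tpl <- build_template(lapply(rnd, `[[`, "feature"), n = template_n)
  aligned <- lapply(rnd, function(r) {
    apply_warp(r$neural, dtw_align(r$feature, tpl))
  })
  lapply(seq_len(scenario$n_channels), function(ch) {
    t(vapply(aligned, function(a) a[, ch], numeric(length(tpl$feature))))
  })
}
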
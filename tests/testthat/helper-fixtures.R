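# Shared fixtures, built once per test run and memoised.

.fix_env <- new.env()

get_fixtures <- function() {
  if (is.null(.fix_env$fx)) .fix_env$fx <- make_fixtures(seed = 42)
  .fix_env$fx
}

# One simulated LR acquisition of the fixture flow's peak frame, with an
# alias-free smallest-above VENC and mid-range noise.
get_lr_frame <- function(frame = NULL, snr_db = 16, seed = 77) {
  fx <- get_fixtures()
  flow <- fx$flow
  if (is.null(frame)) frame <- which.max(flow$envelope)
  ms <- flow_max_speed(flow, frame)
  venc <- vapply(ms, function(m) min(venc_grid()[venc_grid() > m]),
                 numeric(1))
  set.seed(seed)
  list(flow = flow, frame = frame,
       hr = flow_frame(flow, frame),
       lr = simulate_lr(flow_frame(flow, frame), flow$mask,
                        acquisition(venc, snr_db = snr_db, intensity = 150),
                        4, flow$domain))
}

# Random velocity patch [n,n,n,3] with reproducible content.
random_patch <- function(n = 5, seed = 1, scale = 1) {
  set.seed(seed)
  array(rnorm(n^3 * 3, sd = scale), c(n, n, n, 3))
}
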
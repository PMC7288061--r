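# shared fixtures: tiny deterministic trials so individual tests stay fast

fix_model <- function() build_default_skeleton()

# short clean squat (2 reps at 30 Hz = 240 frames)
fix_squat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gt <- generate_task(task_script("squat_lateral_arms", reps = 2))
      cache <<- list(gt = gt, clean = render_jcp(gt))
    }
    cache
  }
})

# random in-limit posture for property tests
random_pose <- function(model, scale = 0.4) {
  lo <- model$limit_lo; hi <- model$limit_hi
  mid <- (lo + hi) / 2
  mid + (hi - lo) / 2 * scale * stats::runif(model$n_joints, -1, 1)
}

# minimal cross product for hand-rotation oracles
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

init_state_near_rest <- function(mod, angle_sd = 0.1) {
  th <- stats::rnorm(22, 0, angle_sd)
  th <- pmin(pmax(th, mod$limit_lo + 0.02), mod$limit_hi - 0.02)
  make_filter_state(mod, theta = th, root = c(0, 1.2, 0),
                    P = diag(84) * 0.05)
}

.st_list <- function(st, lay) {
  list(theta = st$x[lay$theta], lengths = st$x[lay$lengths],
       root = st$x[lay$root])
}

st_theta <- function(x, lay) x[lay$theta]

init_len_bounds <- function(ini) {
  list(lo = 0.8 * ini$lengths, hi = 1.2 * ini$lengths)
}

expect_psd <- function(P, tol = 1e-9) {
  ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -tol)
}
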
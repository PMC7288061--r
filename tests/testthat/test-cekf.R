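# constrained filter: transition, prediction, restricted update, full runs

test_that("transition matrix propagates the kinematic blocks exactly", {
  dt <- 1 / 30
  F_ <- build_transition(dt)
  expect_equal(dim(F_), c(84L, 84L))
  mod <- fix_model()
  lay <- state_layout(mod)
  # one joint with velocity 0.3 rad/s, zero acceleration: +0.01 rad
  x <- numeric(84L)
  x[lay$theta[5]] <- 0.2; x[lay$theta_dot[5]] <- 0.3
  x1 <- as.vector(F_ %*% x)
  expect_equal(x1[lay$theta[5]], 0.2 + 0.3 * dt)
  expect_equal(x1[lay$theta[5]] - 0.2, 0.01)
  # zero velocity and acceleration: angles and lengths unchanged
  x <- numeric(84L)
  x[lay$theta] <- stats::runif(22); x[lay$lengths] <- stats::runif(12) + 0.1
  x1 <- as.vector(F_ %*% x)
  expect_identical(x1[lay$theta], x[lay$theta])
  expect_identical(x1[lay$lengths], x[lay$lengths])
  # n-step propagation matches the constant-acceleration closed form
  x <- numeric(84L)
  th0 <- 0.1; v0 <- 0.5; a0 <- -0.8
  x[lay$theta[1]] <- th0; x[lay$theta_dot[1]] <- v0; x[lay$theta_ddot[1]] <- a0
  n <- 90L
  xn <- x
  for (k in seq_len(n)) xn <- as.vector(F_ %*% xn)
  tt <- n * dt
  expect_equal(xn[lay$theta[1]], th0 + tt * v0 + tt^2 / 2 * a0,
               tolerance = 1e-9)
})

test_that("prediction propagates covariance as F P F' + Q and stays PSD", {
  mod <- fix_model()
  F_ <- build_transition(1 / 30)
  lay <- state_layout(mod)
  # Q = 0, P = 0: deterministic propagation
  st <- make_filter_state(mod, P = matrix(0, 84, 84))
  pr <- cekf_predict(st, F_, matrix(0, 84, 84))
  expect_true(all(pr$P == 0))
  # zero process noise on lengths: length covariance block unchanged
  set.seed(5)
  A <- matrix(stats::rnorm(84 * 84, sd = 0.1), 84)
  P <- crossprod(A)
  Q <- assemble_Q(mod, grouped_sigma2(mod, stats::runif(11, 0.1, 10)), 1 / 30)
  st <- make_filter_state(mod, P = P)
  pr <- cekf_predict(st, F_, Q)
  expect_equal(pr$P[lay$lengths, lay$lengths], P[lay$lengths, lay$lengths],
               tolerance = 1e-12)
  # PSD closure over random PSD P, Q
  for (rep in 1:5) {
    A <- matrix(stats::rnorm(84 * 84, sd = 0.3), 84)
    P <- crossprod(A)
    st <- make_filter_state(mod, P = P)
    pr <- cekf_predict(st, F_, Q)
    expect_psd(pr$P, tol = 1e-10)
  }
})

# --- scalar/toy systems exercised through a 1-DOF linear analogue ----------
# The restricted update is checked against hand-computed Kalman algebra on
# toy systems by calling the low-level pieces directly on a 1-D problem
# embedded via a custom C/d row set. We emulate the scalar case with the
# full machinery by linearizing around the zero pose of one joint whose
# center is directly observed; for exact scalar checks we use the
# standalone formulas below.

kalman_scalar <- function(x, P, z, h, H, R) {
  S <- H * P * H + R
  K <- P * H / S
  xn <- x + K * (z - h)
  Pn <- (1 - K * H) * P
  list(x = xn, P = Pn, K = K)
}

test_that("unconstrained restricted update reduces to the textbook EKF", {
  mod <- fix_model()
  cons <- build_constraints(mod)
  lay <- state_layout(mod)
  set.seed(21)
  st <- init_state_near_rest(mod)
  z <- forward_kinematics(mod, st$x[lay$theta], st$x[lay$lengths],
                          st$x[lay$root]) + stats::rnorm(45, 0, 0.005)
  R <- assemble_R(0.0052)
  up <- restricted_update(st$x, st$P, z, mod, R, cons)
  # oracle: plain EKF update computed independently here
  H <- measurement_jacobian(mod, .st_list(st, lay))
  h <- forward_kinematics(mod, st$x[lay$theta], st$x[lay$lengths],
                          st$x[lay$root])
  S <- H %*% st$P %*% t(H) + R
  K <- st$P %*% t(H) %*% solve(S)
  x_ref <- st$x + as.vector(K %*% (z - h))
  active_ref <- which(cons$sign * x_ref[cons$idx] > cons$d - 1e-9)
  skip_if(length(active_ref) > 0, "random draw activated a constraint")
  expect_equal(up$x, x_ref, tolerance = 1e-10)
  expect_length(up$active, 0L)
})

test_that("violated bounds are restored exactly by the restricted gain", {
  mod <- fix_model()
  lay <- state_layout(mod)
  cons <- build_constraints(mod)
  # push the prior of the right knee below its lower bound and present a
  # measurement pulling it further down
  st <- init_state_near_rest(mod)
  kj <- match("r_knee", mod$joint_names)
  th <- st$x[lay$theta]
  th[kj] <- mod$limit_lo[kj] + 0.01
  z <- forward_kinematics(mod, th, st$x[lay$lengths], st$x[lay$root])
  th_meas <- th; th_meas[kj] <- mod$limit_lo[kj] - 0.3
  z <- forward_kinematics(mod, th_meas, st$x[lay$lengths], st$x[lay$root])
  st$x[lay$theta] <- th
  up <- restricted_update(st$x, st$P, z, mod, assemble_R(1e-6), cons)
  expect_gt(length(up$active), 0L)
  expect_lte(st_theta(up$x, lay)[kj], mod$limit_lo[kj] + 1e-9)
  expect_gte(st_theta(up$x, lay)[kj], mod$limit_lo[kj] - 1e-12)
  # all constraints satisfied
  expect_true(all(cons$sign * up$x[cons$idx] <= cons$d + 1e-9))
})

test_that("restricted gain agrees with the covariance-projection oracle up to
          the documented metric difference", {
  # The gain-corrected posterior places active components exactly on their
  # bounds (like the QP projection) but corrects *only* those components,
  # whereas the minimum-variance projection in the P metric also shifts
  # correlated components. Both must satisfy the constraints; their
  # difference is bounded by the projection's own correction size.
  mod <- fix_model()
  lay <- state_layout(mod)
  cons <- build_constraints(mod)
  set.seed(33)
  n_checked <- 0L
  for (rep in 1:50) {
    st <- init_state_near_rest(mod, angle_sd = 0.25)
    th_meas <- st$x[lay$theta] + stats::rnorm(22, 0, 0.3)
    z <- forward_kinematics(mod, th_meas, st$x[lay$lengths], st$x[lay$root])
    R <- assemble_R(1e-4)
    up <- restricted_update(st$x, st$P, z, mod, R, cons)
    expect_true(all(cons$sign * up$x[cons$idx] <= cons$d + 1e-9))
    if (length(up$active) == 0L || length(up$clamped) > 0L) next
    n_checked <- n_checked + 1L
    # QP oracle: minimum-variance equality projection of the unconstrained
    # posterior onto the active bounds in the posterior-P metric
    H <- measurement_jacobian(mod, .st_list(st, lay))
    h <- forward_kinematics(mod, st$x[lay$theta], st$x[lay$lengths],
                            st$x[lay$root])
    S <- H %*% st$P %*% t(H) + R
    K <- st$P %*% t(H) %*% solve(S)
    x_unc <- st$x + as.vector(K %*% (z - h))
    P_post <- (diag(84) - K %*% H) %*% st$P
    act <- up$active
    C <- matrix(0, length(act), 84L)
    for (i in seq_along(act)) C[i, cons$idx[act[i]]] <- cons$sign[act[i]]
    d <- cons$d[act]
    viol <- as.vector(C %*% x_unc - d)
    x_qp <- x_unc - as.vector(P_post %*% t(C) %*%
                                solve(C %*% P_post %*% t(C), viol))
    # both satisfy the active bounds exactly
    expect_equal(as.vector(C %*% up$x), d, tolerance = 1e-8)
    expect_equal(as.vector(C %*% x_qp), d, tolerance = 1e-8)
    # documented discrepancy: the two differ only through the QP's extra
    # correlated shift, which is bounded by the projection correction norm
    shift <- sqrt(sum((x_qp - x_unc)^2))
    expect_lte(sqrt(sum((up$x - x_qp)^2)), shift + 1e-8)
  }
  expect_gte(n_checked, 5L)
})

test_that("degenerate zero innovation with active constraints falls back to
          clamping", {
  mod <- fix_model()
  lay <- state_layout(mod)
  cons <- build_constraints(mod)
  st <- init_state_near_rest(mod)
  kj <- match("l_knee", mod$joint_names)
  st$x[lay$theta[kj]] <- mod$limit_lo[kj] - 0.05   # prior already violating
  z <- forward_kinematics(mod, st$x[lay$theta], st$x[lay$lengths],
                          st$x[lay$root])          # zero innovation
  st$P <- diag(84) * 1e-12                          # gain ~ 0: x_unc = prior
  up <- restricted_update(st$x, st$P, z, mod, assemble_R(0.0052), cons)
  expect_true(up$nu_degenerate || length(up$clamped) > 0L)
  expect_gte(st_theta(up$x, lay)[kj], mod$limit_lo[kj] - 1e-12)
})

test_that("filter tracks a zero-noise squat to sub-degree accuracy", {
  mod <- fix_model()
  fx <- fix_squat()
  gt <- fx$gt; clean <- fx$clean
  st <- make_filter_state(mod, theta = gt$theta[1, ], lengths = gt$lengths,
                          root = gt$root[1, ], P = diag(84) * 1e-4)
  cons <- build_constraints(mod)
  cfg <- tuning_config(mod, grouped_sigma2(mod, rep(1, 11)),
                       assemble_R(1e-6), 1 / 30)
  res <- run_filter(clean, mod, filter_matrices(mod, cfg), cons, st)
  burn <- res$t > 1
  err <- rad2deg(res$theta[burn, ] - gt$theta[burn, ])
  # observable DOFs track tightly; axial rotations are excluded (their
  # near-unobservability from joint centers is a property of the problem)
  axial <- match(c("r_hip_rot", "l_hip_rot", "r_sh_rot", "l_sh_rot"),
                 mod$joint_names)
  expect_lt(sqrt(mean(err[, -axial]^2)), 0.5)
  # constraints hold everywhere, lengths strictly positive
  expect_true(all(sweep(res$theta, 2, mod$limit_hi, "<=") |
                    abs(sweep(res$theta, 2, mod$limit_hi, "-")) < 1e-9))
  expect_true(all(res$lengths > 0))
})

test_that("length estimates converge under zero length process noise", {
  mod <- fix_model()
  # static standing pose repeated for 4 s, noisy initial lengths
  true_lengths <- mod$default_lengths
  z0 <- forward_kinematics(mod, rep(0, 22), true_lengths, c(0, 1.2, 0))
  nT <- 120L
  clean <- measurement_series(seq(0, by = 1 / 30, length.out = nT),
                              matrix(z0, nT, 45L, byrow = TRUE))
  set.seed(9)
  bad_lengths <- true_lengths * stats::runif(12, 0.92, 1.08)
  st <- make_filter_state(mod, theta = rep(0, 22), lengths = bad_lengths,
                          root = c(0, 1.2, 0))
  cons <- build_constraints(mod, 0.8 * bad_lengths, 1.2 * bad_lengths)
  gt <- list(lengths = true_lengths)
  cfg <- tuning_config(mod, grouped_sigma2(mod, rep(1, 11)),
                       assemble_R(0.0052), 1 / 30)
  res <- run_filter(clean, mod, filter_matrices(mod, cfg), cons, st)
  # length error variance decreases and ends below its start
  expect_true(all(res$P_len_diag[nrow(res$P_len_diag), ] <
                    res$P_len_diag[1L, ]))
  # monotone decrease of the total length variance
  tot <- rowSums(res$P_len_diag)
  expect_true(all(diff(tot) <= 1e-12))
  # estimates moved toward the true lengths
  e0 <- abs(bad_lengths - gt$lengths)
  e1 <- abs(res$lengths[nrow(res$lengths), ] - gt$lengths)
  expect_lt(mean(e1), mean(e0))
})

test_that("missing frames are handled by prediction-only steps", {
  mod <- fix_model()
  fx <- fix_squat()
  meas <- corrupt(fx$clean, noise_model(pooled = TRUE), seed = 4)
  meas$validity[10:12, ] <- FALSE
  ini <- init_from_measurements(meas, mod)
  cfg <- tuning_config(mod, grouped_sigma2(mod, rep(1, 11)),
                       assemble_R(0.0052), 1 / 30)
  res <- run_filter(meas, mod, filter_matrices(mod, cfg), ini$constraints,
                    ini$state)
  expect_identical(which(res$prediction_only), 10:12)
  expect_true(all(is.na(res$innovations[10, ])))
  expect_true(all(is.finite(res$theta)))
})

test_that("covariance stays symmetric PSD and all outputs respect bounds on
          a noisy run", {
  mod <- fix_model()
  fx <- fix_squat()
  meas <- corrupt(fx$clean, noise_model(), seed = 8)   # per-axis biased noise
  ini <- init_from_measurements(meas, mod)
  cfg <- tuning_config(mod, grouped_sigma2(mod, rep(10, 11)),
                       assemble_R(0.0052), 1 / 30)
  res <- run_filter(meas, mod, filter_matrices(mod, cfg), ini$constraints,
                    ini$state)
  expect_equal(res$P, t(res$P), tolerance = 1e-12)
  expect_psd(res$P, tol = 1e-9)
  lo <- matrix(mod$limit_lo, nrow(res$theta), 22, byrow = TRUE)
  hi <- matrix(mod$limit_hi, nrow(res$theta), 22, byrow = TRUE)
  expect_true(all(res$theta >= lo - 1e-9 & res$theta <= hi + 1e-9))
  Lb <- init_len_bounds(ini)
  expect_true(all(sweep(res$lengths, 2, Lb$lo, ">=") |
                    abs(sweep(res$lengths, 2, Lb$lo, "-")) < 1e-9))
  expect_true(all(sweep(res$lengths, 2, Lb$hi, "<=") |
                    abs(sweep(res$lengths, 2, Lb$hi, "-")) < 1e-9))
})
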
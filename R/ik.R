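#' Estimate segment lengths from the first frames of a trial
#'
#' Each of the 12 segment lengths is estimated from the inter-center
#' distances of its joint-center pair over the first `n_frames` frames
#' where both ends are valid (the shared clavicle and pelvis offsets pool
#' both sides). Independent isotropic noise of per-axis variance
#' sigma^2 on each center inflates the expected squared distance by
#' 6 sigma^2; the estimator removes this bias using a pooled noise
#' variance obtained from the frame-to-frame fluctuation of the distances
#' (Var(d) ~ 2 sigma^2 for segments much longer than the noise), so clean
#' input reproduces the true lengths exactly. Also returns the +/-20%
#' bounds used to constrain the filtered lengths.
#'
#' @param frames a `measurement_series` (or T x 45 matrix).
#' @param model a `skeleton_model`.
#' @param n_frames number of leading frames to average over (default 30).
#' @return list with `lengths` (named, m), `length_lo`, `length_hi`
#'   (0.8 / 1.2 times the estimate), `noise_var` (pooled per-axis
#'   variance estimate, m^2).
#' @export
estimate_initial_lengths <- function(frames, model, n_frames = 30L) {
  if (inherits(frames, "measurement_series")) {
    pos <- frames$pos; validity <- frames$validity
  } else {
    pos <- as.matrix(frames); validity <- matrix(TRUE, nrow(pos), 15L)
  }
  stopifnot(nrow(pos) >= 1L)
  n <- min(n_frames, nrow(pos))
  pos <- pos[seq_len(n), , drop = FALSE]
  validity <- validity[seq_len(n), , drop = FALSE]
  dists <- vector("list", model$n_lengths)
  for (li in seq_len(model$n_lengths)) {
    prs <- model$length_pairs[[li]]
    d <- c()
    for (r in seq_len(nrow(prs))) {
      a <- prs[r, 1L]; b <- prs[r, 2L]
      ok <- validity[, a] & validity[, b]
      if (!any(ok)) next
      pa <- pos[ok, (3L * a - 2L):(3L * a), drop = FALSE]
      pb <- pos[ok, (3L * b - 2L):(3L * b), drop = FALSE]
      d <- c(d, sqrt(rowSums((pa - pb)^2)))
    }
    if (!length(d))
      stop("cannot estimate length '", model$length_names[li],
           "': its joint centers are invalid in all supplied frames")
    dists[[li]] <- d
  }
  # pooled per-axis noise variance from the distance fluctuations
  vs <- vapply(dists, function(d)
    if (length(d) >= 3L) stats::var(d) else NA_real_, numeric(1))
  noise_var <- max(mean(vs, na.rm = TRUE) / 2, 0)
  if (!is.finite(noise_var)) noise_var <- 0
  lengths <- vapply(dists, function(d)
    sqrt(max(mean(d^2) - 6 * noise_var, (0.25 * mean(d))^2)), numeric(1))
  names(lengths) <- model$length_names
  list(lengths = lengths, length_lo = 0.8 * lengths,
       length_hi = 1.2 * lengths, noise_var = noise_var)
}

#' Per-frame least-squares inverse kinematics
#'
#' Bounded nonlinear least squares fitting the chain's joint angles and
#' root translation to one frame of measured joint centers, with the
#' segment lengths held fixed. A tiny quadratic pull (weight `reg`) toward
#' `theta_init` makes the solution unique for degrees of freedom that are
#' unobservable from joint centers alone (e.g. hip axial rotation with a
#' straight knee). The solution never has a larger residual than the
#' initial point.
#'
#' @param model a `skeleton_model`.
#' @param z numeric 45, measured joint centers (m).
#' @param lengths numeric 12, fixed segment lengths (m).
#' @param theta_init numeric 22, initial angles (rad).
#' @param root_init numeric 3, initial root translation (m); default the
#'   measured spine-base position.
#' @param valid logical 15; invalid centers are dropped from the fit
#'   (at least 6 valid joints required).
#' @param limits clip the solution to the physiological limits (bounds of
#'   the optimizer); set `FALSE` for unbounded fits.
#' @param reg regularization weight toward `theta_init`.
#' @return object of class `ik_result`: `theta` (rad), `root` (m),
#'   `residual` (RMS point distance, m), `converged` flag.
#' @export
ik_frame <- function(model, z, lengths, theta_init = rep(0, 22L),
                     root_init = NULL, valid = rep(TRUE, 15L),
                     limits = TRUE, reg = 1e-6) {
  stopifnot(length(z) == 45L, length(theta_init) == model$n_joints)
  if (sum(valid) < 6L) stop("need at least 6 valid joint centers")
  if (is.null(root_init)) {
    sb <- which(model$jcp_names == "spine_base")
    root_init <- if (valid[sb]) z[(3L * sb - 2L):(3L * sb)] else c(0, 0, 0)
  }
  rows <- which(rep(valid, each = 3L))
  nt <- model$n_joints
  obj <- function(p) {
    th <- p[seq_len(nt)]; rt <- p[nt + 1:3]
    r <- forward_kinematics(model, th, lengths, rt)[rows] - z[rows]
    sum(r^2) + reg * sum((th - theta_init)^2)
  }
  grad <- function(p) {
    th <- p[seq_len(nt)]; rt <- p[nt + 1:3]
    r <- forward_kinematics(model, th, lengths, rt)[rows] - z[rows]
    J <- jac_pose(model, th, lengths, rt)[rows, c(seq_len(nt), nt + 12L + 1:3),
                                          drop = FALSE]
    g <- 2 * as.vector(crossprod(J, r))
    g[seq_len(nt)] <- g[seq_len(nt)] + 2 * reg * (th - theta_init)
    g
  }
  lo <- c(if (limits) model$limit_lo else rep(-Inf, nt), rep(-Inf, 3L))
  hi <- c(if (limits) model$limit_hi else rep(Inf, nt), rep(Inf, 3L))
  p0 <- c(pmin(pmax(theta_init, lo[seq_len(nt)]), hi[seq_len(nt)]), root_init)
  fit <- tryCatch(
    stats::optim(p0, obj, grad, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = 200L, factr = 1e4)),
    error = function(e) NULL)
  if (is.null(fit) || fit$value > obj(p0)) {
    p <- p0; converged <- FALSE
  } else {
    p <- fit$par; converged <- fit$convergence == 0L
  }
  # projected Levenberg-Marquardt polish: quasi-Newton often stops a few
  # 1e-4 m short of the least-squares solution
  lambda <- 1e-6
  fp <- obj(p)
  polished <- FALSE
  for (it in 1:15) {
    th <- p[seq_len(nt)]; rt <- p[nt + 1:3]
    r <- forward_kinematics(model, th, lengths, rt)[rows] - z[rows]
    J <- jac_pose(model, th, lengths, rt)[rows,
                                          c(seq_len(nt), nt + 12L + 1:3),
                                          drop = FALSE]
    A <- crossprod(J)
    diag(A)[seq_len(nt)] <- diag(A)[seq_len(nt)] + reg
    g <- as.vector(crossprod(J, r)) +
      c(reg * (th - theta_init), numeric(3L))
    step <- tryCatch(solve(A + diag(nrow(A)) * lambda, g),
                     error = function(e) NULL)
    if (is.null(step)) break
    cand <- pmin(pmax(p - step, lo), hi)
    fc <- obj(cand)
    if (fc < fp - 1e-16) {
      p <- cand; fp <- fc; lambda <- max(lambda / 4, 1e-9)
      if (sqrt(sum(step^2)) < 1e-8) { polished <- TRUE; break }
    } else {
      lambda <- lambda * 10
      if (lambda > 1e4) { polished <- TRUE; break }   # no descent: at a min
    }
  }
  converged <- converged || polished
  th <- p[seq_len(nt)]; rt <- p[nt + 1:3]
  res <- forward_kinematics(model, th, lengths, rt)[rows] - z[rows]
  rms <- sqrt(mean(rowSums(matrix(res, ncol = 3L, byrow = TRUE)^2)))
  structure(list(theta = th, root = rt, residual = rms,
                 converged = converged), class = "ik_result")
}

#' @export
print.ik_result <- function(x, ...) {
  cat(sprintf("IK solution: residual %.2e m (%sconverged)\n", x$residual,
              if (x$converged) "" else "not "))
  invisible(x)
}

#' Reference joint angles by per-frame inverse kinematics
#'
#' Stand-in for a full multibody kinematic optimization: per-frame bounded
#' least squares over the same 15 joint centers, warm-started from the
#' previous frame's solution, with the segment lengths held fixed over the
#' whole trial (so the implied skeleton is rigid, unlike the raw tracker
#' output).
#'
#' @param series a `measurement_series`.
#' @param model a `skeleton_model`.
#' @param lengths fixed segment lengths (m); default estimated from the
#'   leading frames via [estimate_initial_lengths()].
#' @param theta0 initial angles for the first frame (rad).
#' @return list (class `angle_series`): `t`, `theta` (T x 22 rad), `root`
#'   (T x 3), `residual` (T), `converged` (T logical).
#' @export
mko_reference <- function(series, model,
                          lengths = estimate_initial_lengths(series, model)$lengths,
                          theta0 = rep(0, 22L)) {
  stopifnot(inherits(series, "measurement_series"))
  nT <- length(series$t)
  theta <- matrix(NA_real_, nT, model$n_joints)
  root <- matrix(NA_real_, nT, 3L)
  residual <- rep(NA_real_, nT)
  converged <- logical(nT)
  th <- theta0; rt <- NULL
  for (k in seq_len(nT)) {
    valid <- series$validity[k, ]
    if (sum(valid) < 6L) { converged[k] <- FALSE; theta[k, ] <- th; next }
    fit <- ik_frame(model, series$pos[k, ], lengths, theta_init = th,
                    root_init = rt, valid = valid)
    th <- fit$theta; rt <- fit$root
    theta[k, ] <- th; root[k, ] <- rt
    residual[k] <- fit$residual; converged[k] <- fit$converged
  }
  structure(list(t = series$t, theta = theta, root = root,
                 residual = residual, converged = converged),
            class = "angle_series")
}

#' Initialize the filter state from the first frames of a trial
#'
#' Mirrors the published initialization: segment lengths from the leading
#' frames (30 by default), joint angles and root from inverse kinematics,
#' zero velocities and accelerations, P0 = identity, and the +/-20% length
#' bounds folded into the constraint set. The IK is solved on the average
#' of the leading frames rather than the first frame alone: with
#' white measurement noise of several centimeters a single-frame fit can
#' land in a mirrored arm/leg configuration that the filter cannot leave,
#' while averaging reduces the noise by sqrt(n) (trials start at rest, so
#' the average is a valid posture).
#'
#' @param series a `measurement_series`.
#' @param model a `skeleton_model`.
#' @param n_frames frames used for length averaging and the IK average.
#' @param p0 `"rest"` (default): identity on the angle, length and root
#'   position blocks, but variance 1e-4 on the velocity and acceleration
#'   blocks — trials start in a resting posture, and encoding that known
#'   stillness prevents the velocity states of weakly observable degrees
#'   of freedom (the axial rotations) from absorbing the initial noise
#'   transient and running away under the constant-acceleration model.
#'   `"identity"` gives the plain identity initialization.
#' @return list: `state` (a `filter_state`), `lengths`, `constraints`
#'   (a `constraint_set` with the length bounds).
#' @export
init_from_measurements <- function(series, model, n_frames = 30L,
                                   p0 = c("rest", "identity")) {
  p0 <- match.arg(p0)
  est <- estimate_initial_lengths(series, model, n_frames)
  n <- min(n_frames, nrow(series$pos))
  lead <- series$pos[seq_len(n), , drop = FALSE]
  lead_valid <- series$validity[seq_len(n), , drop = FALSE]
  zbar <- vapply(seq_len(45L), function(cix) {
    j <- (cix + 2L) %/% 3L
    ok <- lead_valid[, j]
    if (any(ok)) mean(lead[ok, cix]) else NA_real_
  }, numeric(1))
  valid <- colSums(lead_valid) > 0
  fit <- ik_frame(model, zbar, est$lengths, valid = valid)
  P0 <- diag(state_layout(model)$n)
  if (p0 == "rest") {
    lay <- state_layout(model)
    rest_idx <- c(lay$theta_dot, lay$theta_ddot, lay$root_vel)
    diag(P0)[rest_idx] <- 1e-4
  }
  state <- make_filter_state(model, theta = fit$theta, lengths = est$lengths,
                             root = fit$root, P = P0)
  constraints <- build_constraints(model, length_lo = est$length_lo,
                                   length_hi = est$length_hi)
  list(state = state, lengths = est$lengths, constraints = constraints,
       ik = fit)
}
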
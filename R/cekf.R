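#' State-vector layout of the constrained filter
#'
#' The tracked state stacks 22 joint angles, 22 velocities, 22 accelerations,
#' 12 segment lengths, the 3-D root (pelvis) translation and its velocity:
#' 84 components in total. Measurements are expressed in the camera frame,
#' so the root translation is tracked with a constant-velocity model while
#' the base-link orientation is carried by three of the 22 revolute joints.
#'
#' @param model a `skeleton_model`.
#' @return list of index vectors `theta`, `theta_dot`, `theta_ddot`,
#'   `lengths`, `root`, `root_vel` and total dimension `n`.
#' @export
state_layout <- function(model) {
  nt <- model$n_joints; nl <- model$n_lengths
  list(
    theta = seq_len(nt),
    theta_dot = nt + seq_len(nt),
    theta_ddot = 2L * nt + seq_len(nt),
    lengths = 3L * nt + seq_len(nl),
    root = 3L * nt + nl + seq_len(3L),
    root_vel = 3L * nt + nl + 3L + seq_len(3L),
    n = 3L * nt + nl + 6L
  )
}

#' Construct a filter state
#'
#' @param model a `skeleton_model`.
#' @param theta joint angles (rad), length 22.
#' @param theta_dot,theta_ddot joint velocities / accelerations, default 0.
#' @param lengths segment lengths (m), default the model anthropometry.
#' @param root root translation (m), default origin.
#' @param root_vel root velocity (m/s), default 0.
#' @param P error covariance (84 x 84); default identity, the conventional
#'   uninformative initialization giving the same weight to all components.
#' @return object of class `filter_state` with fields `x` (84-vector), `P`,
#'   and accessors `theta`, `lengths`, `root` as list elements.
#' @export
make_filter_state <- function(model, theta = rep(0, model$n_joints),
                              theta_dot = rep(0, model$n_joints),
                              theta_ddot = rep(0, model$n_joints),
                              lengths = model$default_lengths,
                              root = c(0, 0, 0), root_vel = c(0, 0, 0),
                              P = NULL) {
  lay <- state_layout(model)
  x <- numeric(lay$n)
  x[lay$theta] <- theta; x[lay$theta_dot] <- theta_dot
  x[lay$theta_ddot] <- theta_ddot
  x[lay$lengths] <- lengths; x[lay$root] <- root; x[lay$root_vel] <- root_vel
  if (is.null(P)) P <- diag(lay$n)
  stopifnot(nrow(P) == lay$n, ncol(P) == lay$n)
  structure(list(x = x, P = P, layout = lay,
                 theta = theta, lengths = lengths, root = root),
            class = "filter_state")
}

.state_from_x <- function(x, P, lay) {
  structure(list(x = x, P = P, layout = lay,
                 theta = x[lay$theta], lengths = x[lay$lengths],
                 root = x[lay$root]),
            class = "filter_state")
}

#' Linear state-transition matrix
#'
#' Block-structured transition: angles evolve as theta + dt theta_dot +
#' dt^2/2 theta_ddot, velocities as theta_dot + dt theta_ddot, accelerations
#' and segment lengths are constant, and the root translation follows a
#' constant-velocity model.
#'
#' @param dt sample time (s), > 0.
#' @param n_theta,n_lengths,n_root state block sizes (defaults 22, 12, 3).
#' @return transition matrix F of size (3 n_theta + n_lengths + 2 n_root).
#' @export
#' @examples
#' F <- build_transition(1 / 30)
#' dim(F)
build_transition <- function(dt, n_theta = 22L, n_lengths = 12L, n_root = 3L) {
  stopifnot(dt > 0)
  n <- 3L * n_theta + n_lengths + 2L * n_root
  F_ <- diag(n)
  it <- seq_len(n_theta)
  F_[it, n_theta + it] <- diag(n_theta) * dt
  F_[it, 2L * n_theta + it] <- diag(n_theta) * dt^2 / 2
  F_[n_theta + it, 2L * n_theta + it] <- diag(n_theta) * dt
  ir <- 3L * n_theta + n_lengths + seq_len(n_root)
  F_[ir, ir + n_root] <- diag(n_root) * dt
  F_
}

#' Inequality-constraint set for a skeleton
#'
#' Builds the row set of the linear inequality C x <= d: two rows per joint
#' angle (physiological limits) and two per segment length (+/-20% of the
#' initial estimate by default, set via `length_lo` / `length_hi`). Each row
#' has exactly one nonzero entry (+/-1); rows are stored compactly as
#' (state index, sign, bound).
#'
#' @param model a `skeleton_model`.
#' @param length_lo,length_hi lower/upper segment-length bounds (m); default
#'   +/-20% of the model's anthropometry.
#' @return object of class `constraint_set`: data.frame with columns `idx`,
#'   `sign`, `d` and one row per scalar inequality sign * x[idx] <= d.
#' @export
build_constraints <- function(model,
                              length_lo = 0.8 * model$default_lengths,
                              length_hi = 1.2 * model$default_lengths) {
  stopifnot(all(length_lo > 0), all(length_lo < length_hi))
  lay <- state_layout(model)
  df <- rbind(
    data.frame(idx = lay$theta, sign = -1, d = -model$limit_lo),
    data.frame(idx = lay$theta, sign = +1, d = model$limit_hi),
    data.frame(idx = lay$lengths, sign = -1, d = -length_lo),
    data.frame(idx = lay$lengths, sign = +1, d = length_hi)
  )
  rownames(df) <- NULL
  structure(df, class = c("constraint_set", "data.frame"))
}

#' Prediction step of the filter
#'
#' A-priori propagation: x- = F x, P- = F P F' + Q (then symmetrized).
#'
#' @param state a `filter_state`.
#' @param F_ transition matrix from [build_transition()].
#' @param Q process-noise covariance (zero rows/columns for the segment
#'   lengths force their convergence to a constant).
#' @return a `filter_state` holding the a-priori estimate.
#' @export
cekf_predict <- function(state, F_, Q) {
  x <- as.vector(F_ %*% state$x)
  P <- F_ %*% state$P %*% t(F_) + Q
  P <- (P + t(P)) / 2
  .state_from_x(x, P, state$layout)
}

# violations of the compact constraint set: returns indices of rows with
# sign * x[idx] > d - tol
.active_rows <- function(constraints, x, tol = 1e-9) {
  which(constraints$sign * x[constraints$idx] > constraints$d - tol)
}

# clamp components of x onto the bounds of the given (violated) rows
.clamp_rows <- function(constraints, x, rows) {
  for (r in rows) x[constraints$idx[r]] <- constraints$sign[r] * constraints$d[r]
  x
}

#' Constrained (restricted-gain) measurement update
#'
#' Computes the innovation covariance S = H P- H' + R and the standard
#' Kalman gain; if the unconstrained posterior violates no joint-limit or
#' length bound the update is the textbook EKF update. Otherwise the gain is
#' corrected using only the active constraint rows,
#' \deqn{K_R = K - C'(CC')^{-1} (C \hat x^- - d) (\nu' S^{-1} \nu)^{-1} \nu' S^{-1},}
#' where \eqn{\nu} is the innovation and the violation term \eqn{C\hat x - d}
#' is evaluated, by default, at the unconstrained posterior — the only
#' reading for which the corrected estimate lands exactly on the active
#' bounds (`gain_violation = "prior"` gives the literal a-priori form,
#' which only meets the bound up to the prior-to-posterior drift). The
#' corrected posterior is re-checked once with the enlarged active set and
#' any residual violation is clamped onto its bound as a safety net
#' (flagged in the result).
#'
#' @param x_prior,P_prior a-priori state (84) and covariance.
#' @param z measurement vector (45: stacked x, y, z per joint center).
#' @param model a `skeleton_model`.
#' @param R measurement-noise covariance (45 x 45).
#' @param constraints a `constraint_set`.
#' @param valid logical 15, per-joint validity; invalid rows are dropped from
#'   h, H and R rather than imputed.
#' @param p_form covariance update: Joseph-stabilized form with the applied
#'   gain (default) or the plain `(I - K H) P-` form.
#' @param gain_violation point at which the violation term of the gain
#'   correction is evaluated, see Details.
#' @return list with posterior `x`, `P`, `innovation` (45, NA where
#'   invalid), `active` (row indices of engaged constraints), `clamped`
#'   (row indices needing the safety-net clamp), `nu_degenerate` flag.
#' @export
restricted_update <- function(x_prior, P_prior, z, model, R, constraints,
                              valid = rep(TRUE, model$n_jcp),
                              p_form = c("joseph", "simple"),
                              gain_violation = c("posterior", "prior")) {
  p_form <- match.arg(p_form)
  gain_violation <- match.arg(gain_violation)
  lay <- state_layout(model)
  st <- .state_from_x(x_prior, P_prior, lay)
  fr <- fk_frames(model, st$theta, st$lengths, st$root)
  Jp <- jac_pose(model, st$theta, st$lengths, st$root, frames = fr)
  H <- matrix(0, nrow(Jp), lay$n)
  H[, lay$theta] <- Jp[, seq_len(model$n_joints)]
  H[, lay$lengths] <- Jp[, model$n_joints + seq_len(model$n_lengths)]
  H[, lay$root] <- Jp[, model$n_joints + model$n_lengths + seq_len(3L)]
  h <- .fk_from_frames(model, fr, st$lengths)
  rows <- which(rep(valid, each = 3L))
  H <- H[rows, , drop = FALSE]
  Rv <- R[rows, rows, drop = FALSE]
  nu <- z[rows] - h[rows]
  S <- H %*% P_prior %*% t(H) + Rv
  S <- (S + t(S)) / 2
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular innovation covariance; regularizing with jitter")
    S <- S + diag(nrow(S)) * (1e-9 * sum(diag(S)) / nrow(S))
    ch <- chol(S)
  }
  Sinv_Ht <- chol2inv(ch)                      # S^-1
  K <- P_prior %*% t(H) %*% Sinv_Ht            # standard gain
  x_unc <- x_prior + as.vector(K %*% nu)

  active <- .active_rows(constraints, x_unc)
  clamped <- integer()
  nu_degenerate <- FALSE
  if (length(active) == 0L) {
    x_post <- x_unc
    K_used <- K
  } else {
    wS <- as.vector(Sinv_Ht %*% nu)            # S^-1 nu
    quad <- sum(nu * wS)                       # nu' S^-1 nu
    if (!is.finite(quad) || quad < 1e-300) {
      # zero innovation with active constraints: the (nu' S^-1 nu)^-1 factor
      # is undefined; fall back to clamping the unconstrained posterior
      nu_degenerate <- TRUE
      x_post <- .clamp_rows(constraints, x_unc, active)
      clamped <- active
      K_used <- K
    } else {
      x_at <- if (gain_violation == "posterior") x_unc else x_prior
      apply_restriction <- function(act) {
        m <- length(act)
        Ct <- matrix(0, length(x_prior), m)    # C' with one +/-1 per row
        for (k in seq_len(m))
          Ct[constraints$idx[act[k]], k] <- constraints$sign[act[k]]
        CCt <- crossprod(Ct)                   # C C'
        viol <- constraints$sign[act] * x_at[constraints$idx[act]] -
          constraints$d[act]                   # C x - d at the chosen point
        corr <- Ct %*% solve(CCt, viol)        # C'(CC')^-1 (C x - d)
        K - (corr %*% t(wS)) / quad
      }
      K_used <- apply_restriction(active)
      x_post <- x_prior + as.vector(K_used %*% nu)
      # re-check once with the enlarged active set, then clamp what remains
      still <- .active_rows(constraints, x_post, tol = 0)
      if (length(setdiff(still, active))) {
        active <- sort(union(active, still))
        K_used <- apply_restriction(active)
        x_post <- x_prior + as.vector(K_used %*% nu)
      }
      resid <- .active_rows(constraints, x_post, tol = 0)
      if (length(resid)) {
        x_post <- .clamp_rows(constraints, x_post, resid)
        clamped <- resid
      }
    }
  }

  if (p_form == "joseph") {
    IKH <- diag(length(x_prior)) - K_used %*% H
    P_post <- IKH %*% P_prior %*% t(IKH) + K_used %*% Rv %*% t(K_used)
  } else {
    P_post <- (diag(length(x_prior)) - K_used %*% H) %*% P_prior
  }
  P_post <- (P_post + t(P_post)) / 2

  innovation <- rep(NA_real_, 3L * model$n_jcp)
  innovation[rows] <- nu
  list(x = x_post, P = P_post, innovation = innovation, active = active,
       clamped = clamped, nu_degenerate = nu_degenerate)
}

#' Measurement series container
#'
#' @param t numeric time stamps (s), strictly increasing.
#' @param pos T x 45 matrix of stacked joint-center coordinates (m).
#' @param validity T x 15 logical matrix (default all valid).
#' @return object of class `measurement_series`.
#' @export
measurement_series <- function(t, pos, validity = NULL) {
  pos <- as.matrix(pos)
  stopifnot(length(t) == nrow(pos), ncol(pos) == 45L, !is.unsorted(t))
  if (is.null(validity)) validity <- matrix(TRUE, nrow(pos), 15L)
  stopifnot(nrow(validity) == nrow(pos), ncol(validity) == 15L)
  fin <- vapply(seq_len(15L), function(j)
    rowSums(is.finite(pos[, (3L * j - 2L):(3L * j), drop = FALSE])) == 3L,
    logical(nrow(pos)))
  if (any(validity & !fin))
    stop("non-finite positions on frames/joints flagged valid")
  structure(list(t = t, pos = pos, validity = validity),
            class = "measurement_series")
}

#' @export
print.measurement_series <- function(x, ...) {
  cat(sprintf("Measurement series: %d frames, %.1f s, %d joint centers\n",
              length(x$t), diff(range(x$t)), ncol(x$validity)))
  cat(sprintf("  valid joints: %.1f%%\n", 100 * mean(x$validity)))
  invisible(x)
}

#' Run the constrained filter over a full trial
#'
#' Single causal pass: prediction + restricted update per frame. Frames with
#' no valid joint are propagated by prediction only (flagged). The segment
#' lengths carry zero process noise, so their estimates (and covariance)
#' converge to a constant; all reported angles satisfy the joint limits and
#' all lengths the +/-20% bounds.
#'
#' @param measurements a `measurement_series` with uniform sampling (within
#'   1%).
#' @param model a `skeleton_model`.
#' @param matrices list with elements `F_` (transition), `Q` (process
#'   covariance), `R` (45 x 45 measurement covariance), `dt`; see
#'   [build_transition()] and [assemble_Q()].
#' @param constraints a `constraint_set`.
#' @param init a `filter_state` (see [init_from_measurements()]).
#' @param p_form covariance update form, see [restricted_update()].
#' @param gain_violation gain-correction variant, see
#'   [restricted_update()].
#' @return object of class `filter_result`: matrices `theta` (T x 22, rad),
#'   `theta_dot`, `lengths` (T x 12), `root` (T x 3), `innovations`
#'   (T x 45), `P_len_diag` (T x 12 length error variances),
#'   `constraint_active` / `clamped` per-frame counts, `prediction_only`
#'   flags, final covariance `P`, and `t`.
#' @export
run_filter <- function(measurements, model, matrices, constraints, init,
                       p_form = c("joseph", "simple"),
                       gain_violation = c("posterior", "prior")) {
  p_form <- match.arg(p_form)
  gain_violation <- match.arg(gain_violation)
  stopifnot(inherits(measurements, "measurement_series"),
            inherits(init, "filter_state"))
  t <- measurements$t
  nT <- length(t)
  if (nT >= 2L) {
    dts <- diff(t)
    if (max(abs(dts - matrices$dt)) > 0.01 * matrices$dt)
      stop("measurement time base is not uniform at the stated dt (1% tol)")
  }
  lay <- init$layout
  F_ <- matrices$F_; Q <- matrices$Q; R <- matrices$R
  x <- init$x; P <- init$P
  theta <- matrix(NA_real_, nT, model$n_joints)
  theta_dot <- matrix(NA_real_, nT, model$n_joints)
  lengths <- matrix(NA_real_, nT, model$n_lengths)
  root <- matrix(NA_real_, nT, 3L)
  innovations <- matrix(NA_real_, nT, 3L * model$n_jcp)
  P_len_diag <- matrix(NA_real_, nT, model$n_lengths)
  n_active <- integer(nT); n_clamped <- integer(nT)
  pred_only <- logical(nT)
  for (k in seq_len(nT)) {
    x <- as.vector(F_ %*% x)
    P <- F_ %*% P %*% t(F_) + Q
    P <- (P + t(P)) / 2
    valid <- measurements$validity[k, ]
    if (!any(valid)) {
      pred_only[k] <- TRUE
    } else {
      up <- restricted_update(x, P, measurements$pos[k, ], model, R,
                              constraints, valid = valid, p_form = p_form,
                              gain_violation = gain_violation)
      x <- up$x; P <- up$P
      innovations[k, ] <- up$innovation
      n_active[k] <- length(up$active)
      n_clamped[k] <- length(up$clamped)
    }
    theta[k, ] <- x[lay$theta]
    theta_dot[k, ] <- x[lay$theta_dot]
    lengths[k, ] <- x[lay$lengths]
    root[k, ] <- x[lay$root]
    P_len_diag[k, ] <- diag(P)[lay$lengths]
  }
  colnames(theta) <- model$joint_names
  colnames(lengths) <- model$length_names
  structure(list(t = t, theta = theta, theta_dot = theta_dot,
                 lengths = lengths, root = root, innovations = innovations,
                 P_len_diag = P_len_diag, constraint_active = n_active,
                 clamped = n_clamped, prediction_only = pred_only,
                 P = P, model_joint_names = model$joint_names),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("CEKF result: %d frames, %.1f s\n", length(x$t),
              diff(range(x$t))))
  cat(sprintf("  frames with active constraints: %d; safety-net clamps: %d\n",
              sum(x$constraint_active > 0), sum(x$clamped > 0)))
  cat(sprintf("  prediction-only frames: %d\n", sum(x$prediction_only)))
  fin <- x$lengths[nrow(x$lengths), ]
  cat("  final segment lengths (m):",
      paste(sprintf("%.3f", fin), collapse = " "), "\n")
  invisible(x)
}
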
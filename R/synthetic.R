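#' Task identifiers of the synthetic motion generator
#' @return character vector of the four rehabilitation tasks.
#' @export
task_ids <- function() c("squat_lateral_arms", "stepping",
                         "trunk_tilt_sagittal", "trunk_tilt_frontal")

#' Angles of interest per task
#'
#' The per-task subsets of model degrees of freedom conventionally
#' evaluated: both legs plus both arms for the squat, both legs for
#' stepping, hips (flexion and abduction) plus trunk for the two tilts.
#'
#' @param task_id one of [task_ids()].
#' @return integer vector of joint indices (theta numbering).
#' @export
angles_of_interest <- function(task_id) {
  switch(match.arg(task_id, task_ids()),
         squat_lateral_arms = c(4:11, 14:17, 19:22),
         stepping = 4:11,
         trunk_tilt_sagittal = c(4, 5, 8, 9, 12),
         trunk_tilt_frontal = c(4, 5, 8, 9, 12))
}

# per-rep amplitude profiles. Each trial is `reps` consecutive repetitions
# of a raised-cosine bump, C1-smooth and returning exactly to the resting
# posture at every repetition boundary:
#   full : one bump spanning the repetition
#   half1/half2 : a bump compressed into the first/second half (stepping
#                 alternates legs, tilts alternate sides)
#   alt  : half1 minus half2 (sign alternation within one repetition)
.profile_fun <- function(kind) {
  bump <- function(u) 0.5 * (1 - cos(2 * pi * u))
  dbump <- function(u) pi * sin(2 * pi * u)
  ddbump <- function(u) 2 * pi^2 * cos(2 * pi * u)
  switch(kind,
    full = function(u) cbind(bump(u), dbump(u), ddbump(u)),
    half1 = function(u) {
      on <- u < 0.5; v <- pmin(2 * u, 1)
      cbind(ifelse(on, bump(v), 0), ifelse(on, 2 * dbump(v), 0),
            ifelse(on, 4 * ddbump(v), 0))
    },
    half2 = function(u) {
      on <- u >= 0.5; v <- pmax(2 * u - 1, 0)
      cbind(ifelse(on, bump(v), 0), ifelse(on, 2 * dbump(v), 0),
            ifelse(on, 4 * ddbump(v), 0))
    },
    alt = function(u) {
      h1 <- .profile_fun("half1")(u); h2 <- .profile_fun("half2")(u)
      h1 - h2
    },
    stop("unknown profile kind: ", kind))
}

# task tables: joint name, amplitude (deg), profile kind
.task_table <- function(task_id) {
  A <- function(...) {
    m <- matrix(c(...), ncol = 3L, byrow = TRUE)
    data.frame(joint = m[, 1L], amp_deg = as.numeric(m[, 2L]),
               profile = m[, 3L], stringsAsFactors = FALSE)
  }
  switch(task_id,
    squat_lateral_arms = A(
      "r_hip_flex", 50, "full",  "l_hip_flex", 50, "full",
      "r_hip_abd",  12, "full",  "l_hip_abd",  12, "full",
      "r_hip_rot",   8, "full",  "l_hip_rot",   8, "full",
      "r_knee",    100, "full",  "l_knee",    100, "full",
      "trunk_flex", 15, "full",  "base_pitch",  5, "full",
      "r_clav",      8, "full",  "l_clav",      8, "full",
      "r_sh_flex",  15, "full",  "l_sh_flex",  15, "full",
      "r_sh_abd",   85, "full",  "l_sh_abd",   85, "full",
      "r_sh_rot",   10, "full",  "l_sh_rot",   10, "full",
      "r_elbow",    12, "full",  "l_elbow",    12, "full"),
    stepping = A(
      "r_hip_flex", 60, "half1", "l_hip_flex", 60, "half2",
      "r_hip_abd",   5, "half1", "l_hip_abd",   5, "half2",
      "r_hip_rot",   5, "half1", "l_hip_rot",   5, "half2",
      "r_knee",     70, "half1", "l_knee",     70, "half2",
      "base_roll",   4, "alt",   "trunk_flex",  3, "full",
      "l_sh_flex",   8, "half1", "r_sh_flex",   8, "half2",
      "l_elbow",     8, "half1", "r_elbow",     8, "half2"),
    trunk_tilt_sagittal = A(
      "trunk_flex", 35, "full",  "base_pitch",  8, "full",
      "r_hip_flex", 15, "full",  "l_hip_flex", 15, "full",
      "r_hip_abd",   4, "full",  "l_hip_abd",   4, "full",
      "r_knee",      5, "full",  "l_knee",      5, "full"),
    trunk_tilt_frontal = A(
      "base_roll",  15, "alt",
      "r_hip_abd",  -6, "alt",   "l_hip_abd",   6, "alt",
      "trunk_flex",  8, "full",
      "r_hip_flex",  6, "full",  "l_hip_flex",  6, "full"),
    stop("unknown task id: ", task_id))
}

#' Script of a synthetic rehabilitation task
#'
#' The four tasks of the validation protocol: a deep squat with lateral arm
#' extensions, stepping in place (left and right), and trunk tilts in the
#' sagittal and frontal planes. Each trial is `reps` consecutive
#' repetitions starting and ending in the resting posture (standing, arms
#' along the body, facing the camera). Amplitudes are expressed in degrees
#' and can be overridden; the exact experimental amplitudes and cadences
#' were not published, so these are package defaults chosen to be
#' physiologically plausible.
#'
#' @param task_id one of [task_ids()].
#' @param reps repetitions per trial (default 10).
#' @param period seconds per repetition (default 4, 6 for the frontal
#'   tilt).
#' @param amplitudes optional named numeric (deg) overriding per-joint
#'   amplitudes.
#' @return object of class `task_script`.
#' @export
task_script <- function(task_id = task_ids(), reps = 10L, period = NULL,
                        amplitudes = NULL) {
  task_id <- match.arg(task_id)
  if (is.null(period))
    period <- if (task_id == "trunk_tilt_frontal") 6 else 4
  tab <- .task_table(task_id)
  if (!is.null(amplitudes)) {
    stopifnot(!is.null(names(amplitudes)))
    for (nm in names(amplitudes)) {
      i <- match(nm, tab$joint)
      if (is.na(i)) tab <- rbind(tab, data.frame(joint = nm,
                                                 amp_deg = amplitudes[[nm]],
                                                 profile = "full"))
      else tab$amp_deg[i] <- amplitudes[[nm]]
    }
  }
  structure(list(task_id = task_id, reps = as.integer(reps),
                 period = period, table = tab),
            class = "task_script")
}

#' @export
print.task_script <- function(x, ...) {
  cat(sprintf("Task script '%s': %d reps x %.1f s\n", x$task_id, x$reps,
              x$period))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Generate ground-truth whole-body motion for a task
#'
#' Builds C1-smooth joint-angle trajectories (plus analytic velocities and
#' accelerations) for the scripted task, a consistent pelvis translation
#' (vertical drop during squatting computed from the hip/knee flexion and
#' the leg lengths), and the fixed segment lengths of the subject.
#' Generation is deterministic: all randomness lives in [corrupt()].
#'
#' @param script a `task_script`.
#' @param anthropometry named numeric 12-vector of segment lengths (m).
#' @param dt sample time (s), default 1/30 (the RGB-D tracker rate).
#' @param seed accepted for interface symmetry with [corrupt()] and
#'   ignored: generation is deterministic.
#' @return object of class `ground_truth`: `t`, `theta` (T x 22 rad),
#'   `theta_dot`, `theta_ddot`, `root` (T x 3 m), `root_vel`, `lengths`,
#'   `rep_boundaries` (first sample index of each repetition), `script`.
#' @export
generate_task <- function(script, anthropometry = default_anthropometry(),
                          dt = 1 / 30, seed = NULL) {
  stopifnot(inherits(script, "task_script"), dt > 0)
  model <- build_default_skeleton(anthropometry)
  total <- script$reps * script$period
  t <- seq(0, total - dt, by = dt)
  u <- (t %% script$period) / script$period
  nT <- length(t)
  nt <- model$n_joints
  theta <- matrix(0, nT, nt); dtheta <- matrix(0, nT, nt)
  ddtheta <- matrix(0, nT, nt)
  for (r in seq_len(nrow(script$table))) {
    j <- match(script$table$joint[r], model$joint_names)
    if (is.na(j)) stop("unknown joint in script: ", script$table$joint[r])
    amp <- deg2rad(script$table$amp_deg[r])
    pr <- .profile_fun(script$table$profile[r])(u)
    theta[, j] <- theta[, j] + amp * pr[, 1L]
    dtheta[, j] <- dtheta[, j] + amp * pr[, 2L] / script$period
    ddtheta[, j] <- ddtheta[, j] + amp * pr[, 3L] / script$period^2
  }
  viol <- which(colSums(sweep(theta, 2L, model$limit_hi, ">") |
                          sweep(theta, 2L, model$limit_lo, "<")) > 0)
  if (length(viol))
    stop("scripted amplitudes exceed joint limits for: ",
         paste(model$joint_names[viol], collapse = ", "))
  # pelvis trajectory: standing height minus the squat drop implied by the
  # right-leg hip and knee flexion (flat-foot geometry)
  L <- model$default_lengths; names(L) <- model$length_names
  y0 <- unname(L["th_r"] + L["sh_r"] + 0.08)
  hj <- match("r_hip_flex", model$joint_names)
  kj <- match("r_knee", model$joint_names)
  h <- theta[, hj]; k <- theta[, kj]
  drop <- L[["th_r"]] * (1 - cos(h)) + L[["sh_r"]] * (1 - cos(k - h))
  ddrop <- L[["th_r"]] * sin(h) * dtheta[, hj] +
    L[["sh_r"]] * sin(k - h) * (dtheta[, kj] - dtheta[, hj])
  root <- cbind(0, y0 - drop, 0)
  root_vel <- cbind(0, -ddrop, 0)
  rep_boundaries <- round(seq(0, script$reps - 1L) * script$period / dt) + 1L
  colnames(theta) <- model$joint_names
  structure(list(t = t, theta = theta, theta_dot = dtheta,
                 theta_ddot = ddtheta, root = root, root_vel = root_vel,
                 lengths = model$default_lengths,
                 rep_boundaries = rep_boundaries, script = script,
                 task_id = script$task_id),
            class = c("ground_truth", "angle_series"))
}

#' Render a ground-truth motion to clean joint-center measurements
#'
#' Forward kinematics of every frame: the noise-free measurement stream.
#'
#' @param gt a `ground_truth` from [generate_task()].
#' @param model matching `skeleton_model` (defaults to one rebuilt from
#'   the ground truth's segment lengths).
#' @return a `measurement_series` satisfying segment rigidity exactly.
#' @export
render_jcp <- function(gt, model = build_default_skeleton(gt$lengths)) {
  nT <- length(gt$t)
  pos <- matrix(NA_real_, nT, 45L)
  for (k in seq_len(nT))
    pos[k, ] <- forward_kinematics(model, gt$theta[k, ], gt$lengths,
                                   gt$root[k, ])
  measurement_series(gt$t, pos)
}

#' Depth-camera measurement-noise model
#'
#' Per-axis Gaussian noise with the biases and variances measured for the
#' RGB-D tracker against a stereophotogrammetric reference — defaults
#' (m, m^2): x (-0.06, 0.0019), y (0.06, 0.0050), z (-0.003, 0.0009) — or
#' the isotropic pooled model (0, 0.0052) with `pooled = TRUE`. Optional
#' outliers (0.3 m jumps in a random direction) and dropouts (validity set
#' to FALSE) approximate the structured part of real tracker error.
#'
#' @param bias,var numeric 3 (x, y, z): bias (m) and variance (m^2).
#' @param pooled use the isotropic pooled model.
#' @param outlier_rate,dropout_rate per joint-frame probabilities in
#'   `[0, 1]`.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(bias = c(-0.06, 0.06, -0.003),
                        var = c(0.0019, 0.0050, 0.0009),
                        pooled = FALSE, outlier_rate = 0, dropout_rate = 0) {
  if (pooled) { bias <- c(0, 0, 0); var <- rep(0.0052, 3L) }
  stopifnot(length(bias) == 3L, length(var) == 3L, all(var >= 0),
            outlier_rate >= 0, outlier_rate <= 1,
            dropout_rate >= 0, dropout_rate <= 1)
  structure(list(bias = bias, var = var, outlier_rate = outlier_rate,
                 dropout_rate = dropout_rate), class = "noise_model")
}

#' Corrupt a clean measurement stream with tracker noise
#'
#' Adds independent per-axis Gaussian noise (bias + variance of the noise
#' model) to every joint center, then injects outliers and dropouts at the
#' configured rates. With zero variance and bias the input is returned
#' bit-exactly. Reproducible given `seed`.
#'
#' @param clean a `measurement_series` (e.g. from [render_jcp()]).
#' @param noise a `noise_model`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a corrupted `measurement_series`.
#' @export
corrupt <- function(clean, noise = noise_model(), seed = NULL) {
  stopifnot(inherits(clean, "measurement_series"),
            inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  pos <- clean$pos
  nT <- nrow(pos)
  if (all(noise$var == 0) && all(noise$bias == 0) &&
      noise$outlier_rate == 0 && noise$dropout_rate == 0)
    return(clean)
  for (a in 1:3) {
    cols <- seq(a, 45L, 3L)
    pos[, cols] <- pos[, cols] + noise$bias[a] +
      matrix(stats::rnorm(nT * 15L, 0, sqrt(noise$var[a])), nT, 15L)
  }
  validity <- clean$validity
  if (noise$outlier_rate > 0) {
    hit <- matrix(stats::runif(nT * 15L) < noise$outlier_rate, nT, 15L)
    for (j in seq_len(15L)) {
      kk <- which(hit[, j])
      for (k in kk) {
        dir <- stats::rnorm(3L); dir <- dir / sqrt(sum(dir^2))
        pos[k, (3L * j - 2L):(3L * j)] <-
          pos[k, (3L * j - 2L):(3L * j)] + 0.3 * dir
      }
    }
  }
  if (noise$dropout_rate > 0)
    validity <- validity &
      matrix(stats::runif(nT * 15L) >= noise$dropout_rate, nT, 15L)
  measurement_series(clean$t, pos, validity)
}
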
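deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary unit axis
#'
#' Rodrigues' formula. Used for all revolute-joint rotations; every joint
#' rotates about its own local Z axis, which is stored here as a unit vector
#' expressed in the parent frame.
#'
#' @param u unit 3-vector, rotation axis.
#' @param ang angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_axis <- function(u, ang) {
  c_ <- cos(ang); s <- sin(ang); v <- 1 - c_
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(
    c_ + ux * ux * v,      ux * uy * v - uz * s,  ux * uz * v + uy * s,
    uy * ux * v + uz * s,  c_ + uy * uy * v,      uy * uz * v - ux * s,
    uz * ux * v - uy * s,  uz * uy * v + ux * s,  c_ + uz * uz * v
  ), 3L, 3L, byrow = TRUE)
}

#' Default anthropometry (12 segment lengths, meters)
#'
#' Segment lengths for an average adult scaled linearly from stature
#' (default 1.77 m, the cohort mean of the validation experiments).
#' Lengths are: trunk (spine base to spine shoulder), head (spine shoulder
#' to head center), clavicle and pelvis half-width (shared left/right),
#' and per-side upper arm, forearm, thigh and shank.
#'
#' @param stature standing height in meters.
#' @return named numeric vector of 12 segment lengths (m).
#' @export
#' @examples
#' default_anthropometry()
default_anthropometry <- function(stature = 1.77) {
  stopifnot(is.numeric(stature), stature > 0)
  base <- c(
    trunk = 0.500, head = 0.250, clav = 0.170, pelv = 0.140,
    ua_r = 0.300, ua_l = 0.300, fa_r = 0.260, fa_l = 0.260,
    th_r = 0.420, th_l = 0.420, sh_r = 0.410, sh_l = 0.410
  )
  base * (stature / 1.77)
}

#' Draw a random anthropometry for a synthetic subject
#'
#' Global stature factor of +/-7% and independent per-segment factors of
#' +/-4%, around [default_anthropometry()]. Uses the current RNG state.
#'
#' @param stature nominal stature (m).
#' @return named numeric vector of 12 segment lengths (m).
#' @export
sample_anthropometry <- function(stature = 1.77) {
  lens <- default_anthropometry(stature)
  global <- stats::runif(1L, 0.93, 1.07)
  per <- stats::runif(length(lens), 0.96, 1.04)
  out <- lens * global * per
  # keep the shared left/right structural offsets shared
  out
}

.len_names <- c("trunk", "head", "clav", "pelv", "ua_r", "ua_l",
                "fa_r", "fa_l", "th_r", "th_l", "sh_r", "sh_l")

.jcp_names <- c("spine_base", "spine_shoulder", "head",
                "r_shoulder", "r_elbow", "r_wrist",
                "l_shoulder", "l_elbow", "l_wrist",
                "r_hip", "r_knee", "r_ankle",
                "l_hip", "l_knee", "l_ankle")

# One row per joint of the default 22-DOF chain. Axes are unit vectors in the
# parent frame; the sign conventions make flexion / abduction / elevation
# positive on both sides. trans_len/trans_dir give the length-scaled fixed
# translation from the parent frame origin.
.default_joint_table <- function() {
  j <- function(name, parent, axis, trans_len, trans_dir, lo, hi, group, qgroup)
    list(name = name, parent = parent, axis = axis, trans_len = trans_len,
         trans_dir = trans_dir, lo = lo, hi = hi, group = group, qgroup = qgroup)
  X <- c(1, 0, 0); Y <- c(0, 1, 0); Z <- c(0, 0, 1); O <- c(0, 0, 0)
  # hip centers sit below-lateral of the pelvis origin; the vertical drop
  # keeps the hip flexion axis off the base-pitch axis (identifiability)
  hipR <- c(-sqrt(0.5), -sqrt(0.5), 0); hipL <- c(sqrt(0.5), -sqrt(0.5), 0)
  list(
    j("base_yaw",   0L, Y,  NA, O, -180, 180, "base", "base_rot"),
    j("base_pitch", 1L, X,  NA, O,  -60,  60, "base", "base_rot"),
    j("base_roll",  2L, Z,  NA, O,  -60,  60, "base", "base_rot"),
    j("r_hip_flex", 3L, -X, "pelv", hipR, -30, 130, "leg", "leg_hip_flex"),
    j("r_hip_abd",  4L, -Z, NA, O, -30, 50, "leg", "leg_hip_abd"),
    j("r_hip_rot",  5L, Y,  NA, O, -45, 45, "leg", "leg_hip_rot"),
    j("r_knee",     6L, X,  "th_r", -Y, -5, 150, "leg", "leg_knee"),
    j("l_hip_flex", 3L, -X, "pelv", hipL, -30, 130, "leg", "leg_hip_flex"),
    j("l_hip_abd",  8L, Z,  NA, O, -30, 50, "leg", "leg_hip_abd"),
    j("l_hip_rot",  9L, Y,  NA, O, -45, 45, "leg", "leg_hip_rot"),
    j("l_knee",    10L, X,  "th_l", -Y, -5, 150, "leg", "leg_knee"),
    j("trunk_flex", 3L, X,  NA, O, -30, 90, "trunk", "trunk"),
    # shoulders are abduction-first: the axial-rotation axis then aligns
    # with the abduction axis only at 90 deg flexion, which the scripted
    # tasks never approach (abduction-last locks at the lateral raise)
    j("r_clav",    12L, -Z, "trunk", Y, -10, 45, "trunk", "trunk"),
    j("r_sh_abd",  13L, -Z, "clav", -X, -30, 180, "arm", "arm_sh_abd"),
    j("r_sh_flex", 14L, -X, NA, O, -60, 180, "arm", "arm_sh_flex"),
    j("r_sh_rot",  15L, Y,  NA, O, -90, 90, "arm", "arm_sh_rot"),
    j("r_elbow",   16L, -X, "ua_r", -Y, -5, 150, "arm", "arm_elbow"),
    j("l_clav",    12L, Z,  "trunk", Y, -10, 45, "trunk", "trunk"),
    j("l_sh_abd",  18L, Z,  "clav", X, -30, 180, "arm", "arm_sh_abd"),
    j("l_sh_flex", 19L, -X, NA, O, -60, 180, "arm", "arm_sh_flex"),
    j("l_sh_rot",  20L, Y,  NA, O, -90, 90, "arm", "arm_sh_rot"),
    j("l_elbow",   21L, -X, "ua_l", -Y, -5, 150, "arm", "arm_elbow")
  )
}

# jcp -> (frame, offset). Offsets are linear in the segment lengths:
# off = sum_k dir_k * L[len_k].
.default_jcp_table <- function() {
  e <- function(name, frame, lens = character(), dirs = list())
    list(name = name, frame = frame, lens = lens, dirs = dirs)
  X <- c(1, 0, 0); Y <- c(0, 1, 0)
  list(
    e("spine_base", 3L),
    e("spine_shoulder", 12L, "trunk", list(Y)),
    e("head", 12L, c("trunk", "head"), list(Y, Y)),
    e("r_shoulder", 14L),
    e("r_elbow", 17L),
    e("r_wrist", 17L, "fa_r", list(-Y)),
    e("l_shoulder", 19L),
    e("l_elbow", 22L),
    e("l_wrist", 22L, "fa_l", list(-Y)),
    e("r_hip", 4L),
    e("r_knee", 7L),
    e("r_ankle", 7L, "sh_r", list(-Y)),
    e("l_hip", 8L),
    e("l_knee", 11L),
    e("l_ankle", 11L, "sh_l", list(-Y))
  )
}

# jcp index pairs spanned by each segment length (used for rigidity checks
# and initial length estimation). Shared lengths list both sides.
.default_length_pairs <- function() {
  p <- function(...) matrix(match(c(...), .jcp_names), ncol = 2L, byrow = TRUE)
  list(
    trunk = p("spine_base", "spine_shoulder"),
    head  = p("spine_shoulder", "head"),
    clav  = p("spine_shoulder", "r_shoulder", "spine_shoulder", "l_shoulder"),
    pelv  = p("spine_base", "r_hip", "spine_base", "l_hip"),
    ua_r  = p("r_shoulder", "r_elbow"),
    ua_l  = p("l_shoulder", "l_elbow"),
    fa_r  = p("r_elbow", "r_wrist"),
    fa_l  = p("l_elbow", "l_wrist"),
    th_r  = p("r_hip", "r_knee"),
    th_l  = p("l_hip", "l_knee"),
    sh_r  = p("r_knee", "r_ankle"),
    sh_l  = p("l_knee", "l_ankle")
  )
}

.assemble_skeleton <- function(joints, jcps, lengths, length_pairs) {
  nj <- length(joints); nl <- length(lengths); nc <- length(jcps)
  len_names <- names(lengths)
  parent <- vapply(joints, `[[`, integer(1), "parent")
  axis <- t(vapply(joints, function(x) x$axis / sqrt(sum(x$axis^2)), numeric(3)))
  tmat <- array(0, c(3L, nl, nj))
  for (i in seq_len(nj)) {
    tl <- joints[[i]]$trans_len
    if (!is.na(tl)) tmat[, match(tl, len_names), i] <- joints[[i]]$trans_dir
  }
  omat <- array(0, c(3L, nl, nc))
  for (i in seq_len(nc)) {
    e <- jcps[[i]]
    for (k in seq_along(e$lens))
      omat[, match(e$lens[k], len_names), i] <-
        omat[, match(e$lens[k], len_names), i] + e$dirs[[k]]
  }
  ancestors <- vector("list", nj)
  for (i in seq_len(nj)) {
    ch <- integer(); k <- i
    while (k > 0L) { ch <- c(k, ch); k <- parent[k] }
    ancestors[[i]] <- ch
  }
  # sparse views of the length-scaled translations (hot path of FK/Jacobian)
  sparsify <- function(m) {
    cols <- which(colSums(abs(m)) > 0)
    list(cols = cols, vecs = m[, cols, drop = FALSE])
  }
  trans_sparse <- lapply(seq_len(nj), function(i) sparsify(tmat[, , i]))
  jcp_sparse <- lapply(seq_len(nc), function(i) sparsify(omat[, , i]))
  model <- structure(list(
    n_joints = nj, n_lengths = nl, n_jcp = nc,
    joint_names = vapply(joints, `[[`, character(1), "name"),
    parent = parent, axis = axis, tmat = tmat,
    limit_lo = deg2rad(vapply(joints, `[[`, numeric(1), "lo")),
    limit_hi = deg2rad(vapply(joints, `[[`, numeric(1), "hi")),
    group = vapply(joints, `[[`, character(1), "group"),
    qgroup = vapply(joints, `[[`, character(1), "qgroup"),
    jcp_names = vapply(jcps, `[[`, character(1), "name"),
    jcp_frame = vapply(jcps, `[[`, integer(1), "frame"),
    jcp_omat = omat,
    length_names = len_names,
    default_lengths = unname(lengths),
    length_pairs = length_pairs,
    ancestors = ancestors,
    trans_sparse = trans_sparse,
    jcp_sparse = jcp_sparse
  ), class = "skeleton_model")
  validate_skeleton(model)
  model
}

#' Validate a skeleton model
#'
#' Checks the structural invariants of the chain: 22 revolute joints, 12
#' segment lengths, 15 mapped joint centers, topological parent ordering,
#' finite ordered joint limits, and that every segment length is referenced
#' by the chain (a joint translation or a joint-center offset).
#'
#' @param model a `skeleton_model`.
#' @return `model`, invisibly; errors if an invariant is violated.
#' @export
validate_skeleton <- function(model) {
  stopifnot(inherits(model, "skeleton_model"))
  if (model$n_joints != 22L) stop("skeleton must have exactly 22 revolute joints")
  if (model$n_lengths != 12L) stop("skeleton must carry exactly 12 segment lengths")
  if (model$n_jcp != 15L) stop("skeleton must map exactly 15 joint centers")
  if (any(model$parent >= seq_len(model$n_joints)))
    stop("joint parents must precede their children (topological order)")
  if (any(!is.finite(model$limit_lo)) || any(!is.finite(model$limit_hi)) ||
      any(model$limit_lo >= model$limit_hi))
    stop("joint limits must be finite with limit_lo < limit_hi")
  used <- colSums(abs(apply(model$tmat, 2L, rbind))) +
    colSums(abs(apply(model$jcp_omat, 2L, rbind)))
  if (any(used == 0))
    stop("unreferenced segment length(s): ",
         paste(model$length_names[used == 0], collapse = ", "))
  if (any(model$jcp_frame < 1L | model$jcp_frame > model$n_joints))
    stop("jcp_map frame out of range")
  invisible(model)
}

#' Build the default 22-DOF whole-body skeleton
#'
#' Constructs the kinematic chain used throughout the package: a tree rooted
#' at the pelvis (spine base) with 3 base-link rotations, per-side 3-DOF hips
#' and 1-DOF knees, a 1-DOF trunk, per-side 1-DOF clavicle elevations, 3-DOF
#' shoulders and 1-DOF elbows — 22 revolute joints, 12 segment lengths and a
#' map to the 15 tracked joint centers. Every joint rotates about its local
#' Z axis (stored as a unit vector in the parent frame) following an
#' anatomical flexion / abduction / axial-rotation sequence; the zero pose is
#' the reference posture: standing, arms along the body, facing the camera
#' (+Z anterior, +Y up, +X to the subject's left).
#'
#' Joint indices follow the conventional theta-numbering: 1-3 base link,
#' 4-7 right leg (hip flexion, abduction, axial rotation, knee flexion),
#' 8-11 left leg, 12 trunk flexion, 13 right clavicle elevation, 14-17 right
#' arm (shoulder flexion, abduction, axial rotation, elbow flexion), 18 left
#' clavicle, 19-22 left arm. Default physiological limits (degrees) are
#' documented in [joint_table()].
#'
#' @param anthropometry named numeric vector of 12 segment lengths (m), see
#'   [default_anthropometry()]. Order: trunk, head, clav, pelv, ua_r, ua_l,
#'   fa_r, fa_l, th_r, th_l, sh_r, sh_l.
#' @return object of class `skeleton_model`.
#' @export
#' @examples
#' mod <- build_default_skeleton()
#' joint_table(mod)
build_default_skeleton <- function(anthropometry = default_anthropometry()) {
  if (is.null(names(anthropometry))) names(anthropometry) <- .len_names
  anthropometry <- anthropometry[.len_names]
  if (any(is.na(anthropometry)))
    stop("anthropometry must name all 12 segments: ",
         paste(.len_names, collapse = ", "))
  bad <- which(!(anthropometry > 0))
  if (length(bad))
    stop("non-positive segment length: ",
         paste(.len_names[bad], collapse = ", "))
  .assemble_skeleton(.default_joint_table(), .default_jcp_table(),
                     anthropometry, .default_length_pairs())
}

#' Joint table of a skeleton model
#'
#' One row per revolute joint: index (theta1..theta22), name, parent frame,
#' group (base / leg / trunk / arm), shared process-noise group, and
#' physiological limits in degrees.
#'
#' @param model a `skeleton_model`.
#' @return data.frame with 22 rows.
#' @export
joint_table <- function(model) {
  validate_skeleton(model)
  data.frame(
    theta = paste0("theta", seq_len(model$n_joints)),
    name = model$joint_names,
    parent = model$parent,
    group = model$group,
    qgroup = model$qgroup,
    limit_lo_deg = round(rad2deg(model$limit_lo), 6),
    limit_hi_deg = round(rad2deg(model$limit_hi), 6),
    stringsAsFactors = FALSE
  )
}

#' @export
print.skeleton_model <- function(x, ...) {
  cat("Whole-body skeleton model\n")
  cat(sprintf("  %d revolute joints, %d segment lengths, %d tracked joint centers\n",
              x$n_joints, x$n_lengths, x$n_jcp))
  tab <- table(x$group)
  cat("  joints per group:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  process-noise groups:",
      length(unique(x$qgroup)) + 1L,
      "(incl. base translation)\n")
  invisible(x)
}

# Frame-by-frame forward pass: world rotation R (3x3xN), origin o (Nx3) and
# world joint axis w (Nx3) for every joint frame.
fk_frames <- function(model, theta, lengths, root) {
  nj <- model$n_joints
  parent <- model$parent; axis <- model$axis; ts <- model$trans_sparse
  R <- vector("list", nj)
  o <- matrix(0, nj, 3L)
  w <- matrix(0, nj, 3L)
  I3 <- diag(3)
  for (i in seq_len(nj)) {
    p <- parent[i]
    if (p == 0L) { Rp <- I3; op <- root }
    else { Rp <- R[[p]]; op <- o[p, ] }
    sp <- ts[[i]]
    if (length(sp$cols)) {
      tl <- sp$vecs %*% lengths[sp$cols]
      o[i, ] <- op + Rp %*% tl
    } else o[i, ] <- op
    w[i, ] <- Rp %*% axis[i, ]
    R[[i]] <- Rp %*% rot_axis(axis[i, ], theta[i])
  }
  list(R = R, o = o, w = w)
}

#' Forward kinematics: joint-center positions from a posture
#'
#' The measurement model h of the filter: maps 22 joint angles, 12 segment
#' lengths and the 3-D root translation to the 15 tracked joint centers,
#' stacked (x, y, z) per center in the fixed jcp order.
#'
#' @param model a `skeleton_model`.
#' @param theta numeric 22, joint angles (rad).
#' @param lengths numeric 12, segment lengths (m); defaults to the model's
#'   build-time anthropometry.
#' @param root numeric 3, world position of the pelvis origin (m).
#' @return named numeric vector of length 45 (x, y, z per joint center, m).
#' @export
#' @examples
#' mod <- build_default_skeleton()
#' z <- forward_kinematics(mod, rep(0, 22))
#' jcp_matrix(z)
forward_kinematics <- function(model, theta, lengths = model$default_lengths,
                               root = c(0, 0, 0)) {
  stopifnot(length(theta) == model$n_joints, all(is.finite(theta)),
            length(lengths) == model$n_lengths, all(lengths > 0),
            length(root) == 3L)
  fr <- fk_frames(model, theta, lengths, root)
  out <- numeric(3L * model$n_jcp)
  for (c_ in seq_len(model$n_jcp)) {
    f <- model$jcp_frame[c_]
    sp <- model$jcp_sparse[[c_]]
    p <- fr$o[f, ]
    if (length(sp$cols))
      p <- p + fr$R[[f]] %*% (sp$vecs %*% lengths[sp$cols])
    out[(3L * c_ - 2L):(3L * c_)] <- p
  }
  names(out) <- paste(rep(model$jcp_names, each = 3L), c("x", "y", "z"),
                      sep = "_")
  out
}

# joint-center positions from an existing frames pass (hot path)
.fk_from_frames <- function(model, fr, lengths) {
  out <- numeric(3L * model$n_jcp)
  for (c_ in seq_len(model$n_jcp)) {
    f <- model$jcp_frame[c_]
    sp <- model$jcp_sparse[[c_]]
    p <- fr$o[f, ]
    if (length(sp$cols))
      p <- p + fr$R[[f]] %*% (sp$vecs %*% lengths[sp$cols])
    out[(3L * c_ - 2L):(3L * c_)] <- p
  }
  out
}

#' Reshape a 45-vector of stacked joint centers to a 15 x 3 matrix
#'
#' @param z numeric 45 (or T x 45 matrix), stacked (x, y, z) per center.
#' @return 15 x 3 matrix (single frame input only).
#' @export
jcp_matrix <- function(z) {
  stopifnot(length(z) == 45L)
  m <- matrix(z, ncol = 3L, byrow = TRUE)
  rownames(m) <- .jcp_names
  colnames(m) <- c("x", "y", "z")
  m
}

# Analytic Jacobian of the 45-vector of joint centers with respect to
# (theta, lengths, root): 45 x 37. Revolute columns are w x (p - o) for
# joints on the center's ancestor chain; length columns accumulate the
# length-scaled translations along the chain; root columns are identity.
jac_pose <- function(model, theta, lengths, root, frames = NULL) {
  fr <- if (is.null(frames)) fk_frames(model, theta, lengths, root) else frames
  nj <- model$n_joints; nl <- model$n_lengths; nc <- model$n_jcp
  I3 <- diag(3)
  J <- matrix(0, 3L * nc, nj + nl + 3L)
  for (c_ in seq_len(nc)) {
    f <- model$jcp_frame[c_]
    rows <- (3L * c_ - 2L):(3L * c_)
    Rf <- fr$R[[f]]
    sp <- model$jcp_sparse[[c_]]
    p <- fr$o[f, ]
    if (length(sp$cols)) p <- p + Rf %*% (sp$vecs %*% lengths[sp$cols])
    chain <- model$ancestors[[f]]
    for (j in chain) {
      v <- p - fr$o[j, ]
      wj <- fr$w[j, ]
      J[rows, j] <- c(wj[2L] * v[3L] - wj[3L] * v[2L],
                      wj[3L] * v[1L] - wj[1L] * v[3L],
                      wj[1L] * v[2L] - wj[2L] * v[1L])
    }
    # length derivatives: translations along the chain + the center offset
    L <- matrix(0, 3L, nl)
    for (j in chain) {
      tsj <- model$trans_sparse[[j]]
      if (!length(tsj$cols)) next
      pj <- model$parent[j]
      Rp <- if (pj == 0L) I3 else fr$R[[pj]]
      L[, tsj$cols] <- L[, tsj$cols] + Rp %*% tsj$vecs
    }
    if (length(sp$cols)) L[, sp$cols] <- L[, sp$cols] + Rf %*% sp$vecs
    J[rows, nj + seq_len(nl)] <- L
    J[rows, nj + nl + seq_len(3L)] <- I3
  }
  J
}

#' Measurement Jacobian of the forward-kinematics model
#'
#' Analytic Jacobian H of the 45-dimensional measurement model with respect
#' to the full filter state. Columns for joint velocities, accelerations and
#' the root velocity are identically zero (the measurement depends only on
#' angles, lengths and the root position).
#'
#' @param model a `skeleton_model`.
#' @param state a `filter_state` (see [make_filter_state()]), or a list with
#'   elements `theta`, `lengths`, `root`.
#' @return 45 x 84 matrix (full state layout), or 45 x 37 if
#'   `full = FALSE` (pose components theta, lengths, root only).
#' @param full return columns for the full 84-dim state layout (default) or
#'   only the 37 pose components.
#' @export
measurement_jacobian <- function(model, state, full = TRUE) {
  theta <- state$theta; lengths <- state$lengths; root <- state$root
  stopifnot(length(theta) == model$n_joints,
            length(lengths) == model$n_lengths, length(root) == 3L)
  Jp <- jac_pose(model, theta, lengths, root)
  if (!full) return(Jp)
  lay <- state_layout(model)
  H <- matrix(0, nrow(Jp), lay$n)
  H[, lay$theta] <- Jp[, seq_len(model$n_joints)]
  H[, lay$lengths] <- Jp[, model$n_joints + seq_len(model$n_lengths)]
  H[, lay$root] <- Jp[, model$n_joints + model$n_lengths + seq_len(3L)]
  H
}
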
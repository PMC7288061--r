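#' Root-mean-square difference between two angle series
#'
#' @param a,b numeric vectors of equal length (same units; degrees when
#'   reporting accuracy).
#' @return nonnegative scalar in the units of the inputs.
#' @export
rmsd <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  sqrt(mean((a - b)^2))
}

#' Pearson correlation coefficient between two angle series
#'
#' Returns `NA` (a flagged missing value, not 0) when either input is
#' constant, for which the coefficient is undefined.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return correlation in `[-1, 1]`, or `NA` for constant input.
#' @export
cc <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Cut a trajectory into time-normalized movement cycles
#'
#' Each repetition is resampled by linear interpolation to a fixed number
#' of nodes (101 by default: 0-100% of the movement cycle), yielding
#' curves comparable across repetitions and subjects. Repetitions shorter
#' than 3 samples are skipped with a warning.
#'
#' @param trajectory numeric vector (one angle over a full trial).
#' @param rep_boundaries integer indices of the first sample of each
#'   repetition (>= 2 boundaries; the last repetition extends to the end).
#' @param n_nodes nodes per normalized cycle.
#' @return object of class `cycle_set`: an n_reps x n_nodes matrix.
#' @export
segment_cycles <- function(trajectory, rep_boundaries, n_nodes = 101L) {
  stopifnot(length(rep_boundaries) >= 2L)
  b <- c(sort(rep_boundaries), length(trajectory) + 1L)
  out <- list()
  for (i in seq_len(length(b) - 1L)) {
    seg <- trajectory[b[i]:(b[i + 1L] - 1L)]
    if (length(seg) < 3L) {
      warning("repetition ", i, " shorter than 3 samples; skipped")
      next
    }
    out[[length(out) + 1L]] <-
      stats::approx(seq_along(seg), seg, n = n_nodes)$y
  }
  m <- do.call(rbind, out)
  class(m) <- c("cycle_set", class(m))
  m
}

# expected Euler-characteristic tail of a 1D t field: 0D component plus the
# 1D resel count times the EC density of the t field (Worsley's formulation)
.rft_tail <- function(u, df, resels) {
  stats::pt(u, df, lower.tail = FALSE) +
    resels * sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / df)^(-(df - 1) / 2)
}

# FWHM of the residual field estimated from the normalized gradient
# (Kiebel-style): fwhm = sqrt(4 log 2 / mean squared gradient)
.estimate_fwhm <- function(resid) {
  v <- sqrt(colMeans(resid^2))
  v[v == 0] <- 1
  rn <- sweep(resid, 2L, v, "/")
  g <- t(diff(t(rn)))              # node-to-node gradient per curve
  msg <- mean(g^2)
  if (msg <= 0) return(ncol(resid))
  sqrt(4 * log(2) / msg)
}

#' One-dimensional SPM paired t-test over movement cycles
#'
#' Node-wise paired t statistic on the difference of two sets of
#' time-normalized curves, with family-wise control of the supra-threshold
#' probability at `alpha` by either 1D random-field theory (smoothness
#' estimated from the residual curves, Euler-characteristic threshold) or
#' a max-|t| sign-flip permutation test (exhaustive when 2^n <= `n_perm`,
#' sampled otherwise). Inference is two-sided; a positive cluster means
#' the first error set exceeds the second there (i.e. method B is better
#' over that part of the cycle). Cluster p-values are peak-level: the
#' family-wise probability of a field reaching the cluster's maximum |t|.
#'
#' @param errA,errB `cycle_set` matrices (n curves x nodes), paired by
#'   row; n >= 3.
#' @param alpha significance level (default 0.05).
#' @param method `"permutation"` (default, exact under exchangeability) or
#'   `"rft"`.
#' @param n_perm permutation budget (default 10000).
#' @param seed seed for sampled permutations.
#' @return object of class `spm_result`: `t` (t continuum), `t_star`
#'   (critical threshold), `clusters` (data.frame: start_pct, end_pct,
#'   sign, p), `alpha`, `method`, `df`, `fwhm`.
#' @export
spm_paired_t <- function(errA, errB, alpha = 0.05,
                         method = c("permutation", "rft"),
                         n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  errA <- unclass(errA); errB <- unclass(errB)
  stopifnot(is.matrix(errA), is.matrix(errB), all(dim(errA) == dim(errB)))
  n <- nrow(errA); Qn <- ncol(errA)
  if (n < 3L) stop("paired SPM needs at least 3 curve pairs")
  D <- errA - errB
  mu <- colMeans(D)
  sdv <- apply(D, 2L, stats::sd)
  se <- sdv / sqrt(n)
  traw <- ifelse(se == 0, ifelse(mu == 0, 0, sign(mu) * Inf), mu / se)
  if (any(abs(traw) > 1e6))
    warning("zero/near-zero-variance node(s) with nonzero difference: ",
            "t capped")
  tval <- pmin(pmax(traw, -1e6), 1e6)
  df <- n - 1L
  resid <- sweep(D, 2L, mu)
  fwhm <- .estimate_fwhm(resid)

  if (method == "rft") {
    resels <- (Qn - 1L) / fwhm
    f <- function(u) 2 * .rft_tail(u, df, resels) - alpha
    t_star <- stats::uniroot(f, c(1e-3, 1e3), tol = 1e-10)$root
    p_of_peak <- function(tmax) min(1, 2 * .rft_tail(tmax, df, resels))
  } else {
    exhaustive <- 2^n <= n_perm
    if (exhaustive) {
      S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    } else {
      set.seed(seed)
      S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    }
    # max-|t| under sign flips: colSums of D^2 are flip-invariant
    ssq <- colSums(D^2)
    M <- S %*% D / n                          # flipped means, n_perm x Q
    varf <- sweep(-M^2, 2L, ssq / n, "+") * n / df
    varf[varf < 0] <- 0
    sef <- sqrt(varf / n)
    Tf <- abs(M) / sef
    Tf[sef == 0] <- 0
    maxT <- apply(Tf, 1L, max)
    t_star <- unname(stats::quantile(maxT, 1 - alpha, type = 1L))
    p_of_peak <- function(tmax) max(mean(maxT >= tmax), 1 / length(maxT))
  }

  above <- abs(tval) > t_star
  clusters <- data.frame(start_pct = numeric(), end_pct = numeric(),
                         sign = integer(), p = numeric())
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      idx <- starts[i]:ends[i]
      pk <- max(abs(tval[idx]))
      clusters <- rbind(clusters, data.frame(
        start_pct = 100 * (starts[i] - 1L) / (Qn - 1L),
        end_pct = 100 * (ends[i] - 1L) / (Qn - 1L),
        sign = as.integer(sign(tval[idx][which.max(abs(tval[idx]))])),
        p = p_of_peak(pk)))
    }
  }
  structure(list(t = tval, t_star = t_star, clusters = clusters,
                 alpha = alpha, method = method, df = df, fwhm = fwhm),
            class = "spm_result")
}

#' Format a p-value in the reporting style of the evaluation tables
#' @param p p-value(s).
#' @return character: three decimals, or `"<0.0001"` below resolution.
#' @export
format_pval <- function(p) ifelse(p < 1e-4, "<0.0001", sprintf("%.3f", p))

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("1D SPM paired t-test (%s): df = %d, t* = %.3f (alpha = %g)\n",
              x$method, x$df, x$t_star, x$alpha))
  cat(sprintf("  residual smoothness FWHM = %.1f nodes\n", x$fwhm))
  if (nrow(x$clusters) == 0L) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster %d: %.0f-%.0f%% of cycle, sign %+d, p = %s\n",
                  i, x$clusters$start_pct[i], x$clusters$end_pct[i],
                  x$clusters$sign[i], format_pval(x$clusters$p[i])))
  }
  invisible(x)
}

#' @export
plot.spm_result <- function(x, ...) {
  q <- seq(0, 100, length.out = length(x$t))
  graphics::plot(q, x$t, type = "l", lwd = 2, xlab = "movement cycle (%)",
                 ylab = "SPM{t}", ...)
  graphics::abline(h = c(-x$t_star, x$t_star), col = "red", lty = 2)
  graphics::abline(h = 0, col = "grey")
  if (nrow(x$clusters)) {
    for (i in seq_len(nrow(x$clusters))) {
      idx <- q >= x$clusters$start_pct[i] & q <= x$clusters$end_pct[i]
      graphics::polygon(c(q[idx], rev(q[idx])),
                        c(x$t[idx], rep(sign(x$clusters$sign[i]) * x$t_star,
                                        sum(idx))),
                        col = grDevices::adjustcolor("grey", 0.6),
                        border = NA)
    }
  }
  invisible(x)
}

#' Per-angle accuracy table (RMSD and correlation)
#'
#' Accuracy of estimated against reference joint-angle trajectories for a
#' set of angles of interest, reported in degrees.
#'
#' @param est,ref T x 22 matrices of angles (rad).
#' @param joints integer subset of angles to report.
#' @param joint_names optional labels.
#' @return data.frame: `joint`, `rmsd_deg`, `cc`.
#' @export
accuracy_table <- function(est, ref, joints = seq_len(ncol(est)),
                           joint_names = colnames(est)) {
  if (is.null(joint_names)) joint_names <- paste0("theta", seq_len(ncol(est)))
  data.frame(
    joint = joint_names[joints],
    theta = paste0("theta", joints),
    rmsd_deg = vapply(joints, function(j)
      rmsd(rad2deg(est[, j]), rad2deg(ref[, j])), numeric(1)),
    cc = vapply(joints, function(j) cc(est[, j], ref[, j]), numeric(1)),
    row.names = NULL)
}

#' Compare the two tuning methods with per-angle SPM tests
#'
#' Runs the constrained filter under two tuning configurations on
#' identical corrupted synthetic trials for several subjects, computes the
#' absolute angle-error curves of every repetition against the ground
#' truth, and applies a paired 1D SPM t-test per angle of interest
#' (pairing repetitions across subjects). A positive supra-threshold
#' cluster means configuration A has larger error there, i.e. favors
#' configuration B.
#'
#' @param script a `task_script`.
#' @param config_a,config_b `tuning_config`s to compare (conventionally
#'   a = data-driven, b = optimized, so positive clusters favor the
#'   optimized tuning).
#' @param n_subjects synthetic subjects (anthropometry draws).
#' @param noise a `noise_model`.
#' @param seed base seed: subject s uses seed + s for its anthropometry
#'   and noise stream.
#' @param alpha significance level.
#' @param method SPM inference method.
#' @return list (class `tuning_comparison`): `table` (per-angle summary:
#'   n clusters, min p, direction), `spm` (per-angle `spm_result`s),
#'   `frac_favoring_b`.
#' @export
compare_tunings <- function(script, config_a, config_b, n_subjects = 6L,
                            noise = noise_model(pooled = TRUE), seed = 1L,
                            alpha = 0.05, method = "permutation") {
  joints <- angles_of_interest(script$task_id)
  errA <- vector("list", length(joints)); errB <- vector("list", length(joints))
  for (s in seq_len(n_subjects)) {
    set.seed(seed + s)
    anth <- sample_anthropometry()
    gt <- generate_task(script, anth, dt = config_a$dt)
    model <- build_default_skeleton(anth)
    meas <- corrupt(render_jcp(gt, model), noise, seed = seed + 1000L + s)
    ini <- init_from_measurements(meas, model)
    resA <- run_filter(meas, model, filter_matrices(model, config_a),
                       ini$constraints, ini$state)
    resB <- run_filter(meas, model, filter_matrices(model, config_b),
                       ini$constraints, ini$state)
    for (ji in seq_along(joints)) {
      j <- joints[ji]
      ea <- abs(rad2deg(resA$theta[, j] - gt$theta[, j]))
      eb <- abs(rad2deg(resB$theta[, j] - gt$theta[, j]))
      errA[[ji]] <- rbind(errA[[ji]],
                          segment_cycles(ea, gt$rep_boundaries))
      errB[[ji]] <- rbind(errB[[ji]],
                          segment_cycles(eb, gt$rep_boundaries))
    }
  }
  spm <- vector("list", length(joints))
  tab <- data.frame()
  for (ji in seq_along(joints)) {
    sp <- spm_paired_t(errA[[ji]], errB[[ji]], alpha = alpha,
                       method = method)
    spm[[ji]] <- sp
    ncl <- nrow(sp$clusters)
    dir <- if (ncl == 0L) "none"
      else if (all(sp$clusters$sign > 0)) "favors_b"
      else if (all(sp$clusters$sign < 0)) "favors_a"
      else "mixed"
    tab <- rbind(tab, data.frame(
      theta = paste0("theta", joints[ji]), n_clusters = ncl,
      min_p = if (ncl) format_pval(min(sp$clusters$p)) else "",
      direction = dir))
  }
  names(spm) <- tab$theta
  structure(list(table = tab, spm = spm,
                 frac_favoring_b = mean(tab$direction == "favors_b")),
            class = "tuning_comparison")
}

#' @export
print.tuning_comparison <- function(x, ...) {
  cat("Tuning comparison (per-angle 1D SPM paired t-tests)\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("fraction of angles favoring configuration B: %.2f\n",
              x$frac_favoring_b))
  invisible(x)
}
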
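# Columnar text interchange (comma-separated, header row; meters and
# degrees at the file boundary, radians internally).

#' Write / read a measurement series
#'
#' Columns: `t` (s), 45 joint-center coordinates (m) named
#' `<joint>_<axis>`, and 15 validity flags `valid_<joint>` (0/1).
#'
#' @param series a `measurement_series`.
#' @param path file path.
#' @return `path` (write) or a `measurement_series` (read).
#' @export
write_measurements <- function(series, path) {
  stopifnot(inherits(series, "measurement_series"))
  jn <- .jcp_names
  df <- data.frame(t = series$t, series$pos, series$validity * 1L)
  names(df) <- c("t", paste(rep(jn, each = 3L), c("x", "y", "z"), sep = "_"),
                 paste0("valid_", jn))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("cannot parse '", path, "': ",
                                          conditionMessage(e)))
  need <- 1L + 45L + 15L
  if (ncol(df) < need)
    stop("'", path, "': expected ", need, " columns, found ", ncol(df))
  measurement_series(df[[1L]], as.matrix(df[, 2:46]),
                     as.matrix(df[, 47:61]) > 0)
}

#' Write / read joint-angle output
#'
#' Filter or reference output as columnar text: `t` (s), 22 angles
#' (degrees, `theta1..theta22`), 12 segment lengths (m), and a per-frame
#' constraint-activity count plus prediction-only flag when available.
#'
#' @param result a `filter_result` or `angle_series`.
#' @param path file path.
#' @return `path` (write); a list with `t`, `theta` (rad), `lengths`
#'   (read).
#' @export
write_angles <- function(result, path) {
  df <- data.frame(t = result$t, rad2deg(result$theta))
  names(df) <- c("t", paste0("theta", seq_len(ncol(result$theta))))
  if (!is.null(result$lengths) && is.matrix(result$lengths)) {
    L <- result$lengths
    colnames(L) <- paste0("L_", seq_len(ncol(L)))
    df <- cbind(df, L)
  }
  if (!is.null(result$constraint_active))
    df$constraint_active <- result$constraint_active
  if (!is.null(result$prediction_only))
    df$prediction_only <- result$prediction_only * 1L
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_angles
#' @export
read_angles <- function(path) {
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("cannot parse '", path, "': ",
                                          conditionMessage(e)))
  tc <- grep("^theta", names(df))
  lc <- grep("^L_", names(df))
  out <- list(t = df$t, theta = deg2rad(as.matrix(df[, tc])))
  if (length(lc)) out$lengths <- as.matrix(df[, lc])
  out
}

#' Write / read a tuning configuration
#'
#' Key-value text: the 11 grouped process-noise factors, measurement
#' variance, sample time, bounds and the spectral-rule variant tag.
#'
#' @param config a `tuning_config`.
#' @param path file path.
#' @param model a `skeleton_model` (read; validates group names).
#' @return `path` (write) or a `tuning_config` (read).
#' @export
write_tuning_config <- function(config, path) {
  stopifnot(inherits(config, "tuning_config"))
  lines <- c(
    "# CEKF tuning configuration",
    sprintf("dt = %.10g", config$dt),
    sprintf("r_var = %.10g", config$R[1L, 1L]),
    sprintf("bounds = %.10g %.10g", config$bounds[1L], config$bounds[2L]),
    sprintf("eq7_variant = %s", config$eq7_variant),
    sprintf("sigma2.%s = %.10g", names(config$sigma2), config$sigma2))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_tuning_config
#' @export
read_tuning_config <- function(path, model = build_default_skeleton()) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  get1 <- function(k) vals[match(k, keys)]
  sig <- grepl("^sigma2\\.", keys)
  sigma2 <- stats::setNames(as.numeric(vals[sig]),
                            sub("^sigma2\\.", "", keys[sig]))
  bounds <- as.numeric(strsplit(get1("bounds"), "\\s+")[[1L]])
  tuning_config(model, sigma2, assemble_R(as.numeric(get1("r_var"))),
                dt = as.numeric(get1("dt")), bounds = bounds,
                eq7_variant = get1("eq7_variant"))
}

#' Write / read a skeleton definition file
#'
#' Key-value text, one section per joint (rotation axis, parent,
#' length-scaled translation, limits in degrees, group labels) plus the
#' joint-center map and segment-length names, sufficient to rebuild the
#' model exactly (given its anthropometry).
#'
#' @param model a `skeleton_model`.
#' @param path file path.
#' @return `path` (write) or a `skeleton_model` (read).
#' @export
write_skeleton_config <- function(model, path) {
  validate_skeleton(model)
  num <- function(x) paste(sprintf("%.10g", x), collapse = " ")
  lines <- c("# skeleton definition",
             paste0("lengths = ", paste(model$length_names, collapse = ",")),
             paste0("anthropometry = ", num(model$default_lengths)))
  for (i in seq_len(model$n_joints)) {
    lines <- c(lines,
      sprintf("[joint %d]", i),
      sprintf("name = %s", model$joint_names[i]),
      sprintf("parent = %d", model$parent[i]),
      sprintf("axis = %s", num(model$axis[i, ])),
      sprintf("limits_deg = %s",
              num(rad2deg(c(model$limit_lo[i], model$limit_hi[i])))),
      sprintf("group = %s", model$group[i]),
      sprintf("qgroup = %s", model$qgroup[i]))
    for (m in seq_len(model$n_lengths))
      if (any(model$tmat[, m, i] != 0))
        lines <- c(lines, sprintf("trans.%s = %s", model$length_names[m],
                                  num(model$tmat[, m, i])))
  }
  for (c_ in seq_len(model$n_jcp)) {
    lines <- c(lines,
      sprintf("[jcp %d]", c_),
      sprintf("name = %s", model$jcp_names[c_]),
      sprintf("frame = %d", model$jcp_frame[c_]))
    for (m in seq_len(model$n_lengths))
      if (any(model$jcp_omat[, m, c_] != 0))
        lines <- c(lines, sprintf("offset.%s = %s", model$length_names[m],
                                  num(model$jcp_omat[, m, c_])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_skeleton_config
#' @export
read_skeleton_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  sec <- 0L
  sections <- list(); header <- character()
  cur <- NULL; cur_name <- NULL
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      if (!is.null(cur)) sections[[length(sections) + 1L]] <-
          list(kind = cur_name, kv = cur)
      cur <- character(); cur_name <- gsub("\\[|\\]", "", ln)
    } else if (is.null(cur)) header <- c(header, ln)
    else cur <- c(cur, ln)
  }
  if (!is.null(cur)) sections[[length(sections) + 1L]] <-
      list(kind = cur_name, kv = cur)
  parse_kv <- function(x) {
    kv <- strsplit(x, "\\s*=\\s*")
    stats::setNames(vapply(kv, `[`, character(1), 2L),
                    vapply(kv, `[`, character(1), 1L))
  }
  hdr <- parse_kv(header)
  len_names <- strsplit(hdr[["lengths"]], ",")[[1L]]
  anth <- as.numeric(strsplit(hdr[["anthropometry"]], "\\s+")[[1L]])
  names(anth) <- len_names
  nums <- function(s) as.numeric(strsplit(s, "\\s+")[[1L]])
  joints <- list(); jcps <- list()
  for (s in sections) {
    kv <- parse_kv(s$kv)
    if (grepl("^joint", s$kind)) {
      trans_keys <- grep("^trans\\.", names(kv), value = TRUE)
      tl <- NA_character_; tdirs <- list(); tlens <- character()
      for (tk in trans_keys) {
        tlens <- c(tlens, sub("^trans\\.", "", tk))
        tdirs[[length(tdirs) + 1L]] <- nums(kv[[tk]])
      }
      lim <- nums(kv[["limits_deg"]])
      joints[[length(joints) + 1L]] <- list(
        name = kv[["name"]], parent = as.integer(kv[["parent"]]),
        axis = nums(kv[["axis"]]),
        trans_len = if (length(tlens)) tlens[1L] else NA,
        trans_dir = if (length(tdirs)) tdirs[[1L]] else c(0, 0, 0),
        lo = lim[1L], hi = lim[2L],
        group = kv[["group"]], qgroup = kv[["qgroup"]])
    } else {
      off_keys <- grep("^offset\\.", names(kv), value = TRUE)
      jcps[[length(jcps) + 1L]] <- list(
        name = kv[["name"]], frame = as.integer(kv[["frame"]]),
        lens = sub("^offset\\.", "", off_keys),
        dirs = lapply(off_keys, function(k) nums(kv[[k]])))
    }
  }
  .assemble_skeleton(joints, jcps, anth, .default_length_pairs())
}

#' Write a run manifest
#'
#' Records command, seeds, parameters, written artifacts and their md5
#' checksums so a run can be replayed exactly.
#'
#' @param path manifest file path.
#' @param command command name.
#' @param params named list of parameters/seeds.
#' @param artifacts character vector of file paths written by the run.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, params, artifacts) {
  sums <- tools::md5sum(artifacts)
  lines <- c(sprintf("command = %s", command),
             sprintf("timestamp = %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             sprintf("package_version = %s",
                     as.character(utils::packageVersion("bodycekf"))),
             vapply(names(params), function(k)
               sprintf("param.%s = %s", k,
                       paste(format(params[[k]]), collapse = " ")),
               character(1)),
             sprintf("artifact = %s md5:%s", names(sums), unname(sums)))
  writeLines(lines, path)
  invisible(path)
}
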
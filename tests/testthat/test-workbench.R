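# file formats, manifests and the pipeline shell

test_that("measurement series round-trip through the columnar format", {
  fx <- fix_squat()
  meas <- corrupt(fx$clean, noise_model(dropout_rate = 0.03), seed = 14)
  path <- tempfile(fileext = ".csv")
  write_measurements(meas, path)
  back <- read_measurements(path)
  expect_equal(back$t, meas$t, tolerance = 1e-9)
  expect_equal(back$pos, meas$pos, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(unname(as.matrix(back$validity)),
                   unname(as.matrix(meas$validity)))
  unlink(path)
  expect_error(suppressWarnings(read_measurements(tempfile())),
               "cannot|parse|no")
})

test_that("angle output round-trips with degrees at the file boundary", {
  mod <- fix_model()
  fx <- fix_squat()
  meas <- corrupt(fx$clean, noise_model(pooled = TRUE), seed = 15)
  ini <- init_from_measurements(meas, mod)
  cfg <- tuning_config(mod, grouped_sigma2(mod, rep(10, 11)),
                       assemble_R(0.0052), 1 / 30)
  res <- run_filter(meas, mod, filter_matrices(mod, cfg), ini$constraints,
                    ini$state)
  path <- tempfile(fileext = ".csv")
  write_angles(res, path)
  hdr <- names(utils::read.csv(path, nrows = 1))
  expect_equal(hdr[2:23], paste0("theta", 1:22))   # schema: t, theta1..22
  back <- read_angles(path)
  expect_equal(back$theta, unname(res$theta), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(dim(back$lengths), dim(res$lengths))
  unlink(path)
})

test_that("skeleton definitions round-trip through the config file", {
  mod <- build_default_skeleton(sample_anthropometry())
  path <- tempfile(fileext = ".cfg")
  write_skeleton_config(mod, path)
  back <- read_skeleton_config(path)
  expect_equal(back$parent, mod$parent)
  expect_equal(back$axis, mod$axis, tolerance = 1e-9)
  expect_equal(back$limit_lo, mod$limit_lo, tolerance = 1e-9)
  expect_equal(back$limit_hi, mod$limit_hi, tolerance = 1e-9)
  expect_equal(back$default_lengths, mod$default_lengths, tolerance = 1e-9)
  expect_equal(back$qgroup, mod$qgroup)
  # identical forward kinematics
  set.seed(19)
  th <- random_pose(mod)
  expect_equal(forward_kinematics(back, th, root = c(0, 1.2, 0)),
               forward_kinematics(mod, th, root = c(0, 1.2, 0)),
               tolerance = 1e-9)
  unlink(path)
  # the shipped definition file reproduces the built-in chain
  shipped <- system.file("extdata", "default_skeleton.cfg",
                         package = "bodycekf")
  expect_true(nzchar(shipped))
  ref <- build_default_skeleton()
  got <- read_skeleton_config(shipped)
  expect_equal(got$axis, ref$axis, tolerance = 1e-9)
  expect_equal(got$default_lengths, ref$default_lengths, tolerance = 1e-9)
})

test_that("simulate writes replayable artifacts with a manifest", {
  out1 <- file.path(tempdir(), "sim1"); out2 <- file.path(tempdir(), "sim2")
  a <- run_simulate("stepping", out1, noise = "pooled", seed = 7, reps = 2)
  b <- run_simulate("stepping", out2, noise = "pooled", seed = 7, reps = 2)
  expect_true(file.exists(a$truth))
  expect_true(file.exists(a$measurements))
  expect_true(file.exists(a$manifest))
  # same seed: byte-identical measurement files
  expect_identical(readLines(a$measurements), readLines(b$measurements))
  # manifest lists the artifacts and the seed
  man <- readLines(a$manifest)
  expect_true(any(grepl("param.seed = 7", man, fixed = TRUE)))
  expect_true(any(grepl(basename(a$measurements), man, fixed = TRUE)))
  # pooled preset recorded with the isotropic variance
  expect_true(any(grepl("0.0052", man, fixed = TRUE)))
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("track produces a schema-correct, deterministic output with
          flagged gaps", {
  outd <- file.path(tempdir(), "trk")
  sim <- run_simulate("squat_lateral_arms", outd, noise = "pooled",
                      seed = 3, reps = 2)
  # knock out three frames entirely
  meas <- read_measurements(sim$measurements)
  meas$validity[40:42, ] <- FALSE
  gap_file <- file.path(outd, "gappy.csv")
  write_measurements(meas, gap_file)
  t1 <- run_track(gap_file, outd)
  t2 <- run_track(gap_file, outd)
  expect_identical(readLines(t1$angles), readLines(t2$angles))
  df <- utils::read.csv(t1$angles)
  expect_equal(names(df)[2:23], paste0("theta", 1:22))
  expect_equal(which(df$prediction_only == 1), 40:42)
  unlink(outd, recursive = TRUE)
})

test_that("tune writes a loadable config in both modes", {
  outd <- file.path(tempdir(), "tun")
  sim <- run_simulate("trunk_tilt_sagittal", outd, noise = "pooled",
                      seed = 5, reps = 1)
  cfg_file <- file.path(outd, "dd.cfg")
  cfg <- run_tune(sim$measurements, sim$truth, cfg_file,
                  mode = "data_driven")
  expect_s3_class(cfg, "tuning_config")
  back <- read_tuning_config(cfg_file)
  expect_equal(back$sigma2, cfg$sigma2, tolerance = 1e-9)
  # rerun is idempotent
  run_tune(sim$measurements, sim$truth, cfg_file, mode = "data_driven")
  expect_equal(read_tuning_config(cfg_file)$sigma2, back$sigma2,
               tolerance = 1e-12)
  unlink(outd, recursive = TRUE)
})

test_that("evaluate emits the per-angle accuracy table layout", {
  outd <- file.path(tempdir(), "evl")
  sim <- run_simulate("squat_lateral_arms", outd, noise = "pooled",
                      seed = 2, reps = 2)
  trk <- run_track(sim$measurements, outd)
  rep_file <- file.path(outd, "report.csv")
  tab <- run_evaluate(trk$angles, sim$truth, rep_file,
                      boundaries = sim$gt$rep_boundaries,
                      joints = angles_of_interest("squat_lateral_arms"))
  expect_true(file.exists(rep_file))
  expect_equal(names(tab),
               c("theta", "rmsd_mean", "rmsd_sd", "cc_mean", "cc_sd"))
  expect_equal(tab$theta, paste0("theta",
                                 angles_of_interest("squat_lateral_arms")))
  expect_true(all(tab$rmsd_mean >= 0))
  # no overlap is an input error
  short <- read_angles(trk$angles)
  expect_error(run_evaluate(trk$angles,
                            {p <- file.path(outd, "empty.csv")
                             utils::write.csv(
                               utils::read.csv(sim$truth)[0, ], p,
                               row.names = FALSE); p},
                            rep_file), "overlap|samples")
  unlink(outd, recursive = TRUE)
})

test_that("the command-line entry point completes a small pipeline", {
  cli <- system.file("cli", "bodycekf.R", package = "bodycekf")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  outd <- file.path(tempdir(), "cli_out")
  st <- system2(rscript, c(cli, "simulate", "--task", "stepping",
                           "--seed", "7", "--reps", "1", "--noise",
                           "pooled", "--out", outd),
                stdout = TRUE, stderr = TRUE)
  expect_identical(attr(st, "status"), NULL)   # exit 0
  meas <- file.path(outd, "stepping_measurements.csv")
  expect_true(file.exists(meas))
  st2 <- system2(rscript, c(cli, "track", "--measurements", meas,
                            "--out", outd), stdout = TRUE, stderr = TRUE)
  expect_identical(attr(st2, "status"), NULL)
  expect_true(file.exists(file.path(outd,
                                    "stepping_measurements_angles.csv")))
  # unknown task: input-error exit code 2
  st3 <- suppressWarnings(system2(rscript, c(cli, "simulate", "--task",
                                             "nope", "--out", outd),
                                  stdout = TRUE, stderr = TRUE))
  expect_identical(attr(st3, "status"), 2L)
  unlink(outd, recursive = TRUE)
})
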
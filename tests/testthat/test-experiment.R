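test_that("control files parse with defaults, ordering and error contracts", {
  spec <- parse_control_file(example_control_lines(), text = TRUE)
  expect_equal(spec$method, "ml")
  expect_equal(spec$precision, 2.5)
  expect_equal(spec$fixed, list(d = 0, zr = 0.5, szr = 0, sv = 0))
  expect_equal(spec$depends, list(v = c("stimulus", "difficulty")))
  expect_equal(spec$format, c("RESPONSE", "TIME", "stimulus", "difficulty"))
  expect_equal(spec$load, "data_*.dat")
  expect_equal(spec$save, "parameters_*.dat")
  expect_equal(spec$log, "experiment.log")

  # defaults: method ks, precision 3
  minimal <- parse_control_file(c("format RESPONSE TIME", "load a.dat",
                                  "log out.log"), text = TRUE)
  expect_equal(minimal$method, "ks")
  expect_equal(minimal$precision, 3)

  expect_error(parse_control_file(character(), text = TRUE), "format")
  expect_error(parse_control_file(c("format RESPONSE TIME", "log x"),
                                  text = TRUE), "load")
  expect_error(parse_control_file(c("format RESPONSE TIME", "load a.dat"),
                                  text = TRUE), "save/log")
  expect_error(parse_control_file(c("frobnicate 1", "format RESPONSE TIME",
                                    "load a.dat", "log x"), text = TRUE),
               "unknown command")
  # a depends label absent from format aborts
  expect_error(parse_control_file(c("depends t0 block", "format RESPONSE TIME",
                                    "load a.dat", "log x"), text = TRUE),
               "block")
  # command ordering is enforced
  expect_error(parse_control_file(c("format RESPONSE TIME", "set d 0",
                                    "load a.dat", "log x"), text = TRUE),
               "precede")
  expect_error(parse_control_file(c("load a.dat", "format RESPONSE TIME",
                                    "log x"), text = TRUE), "follow")
  # wildcard load requires a wildcard save
  expect_error(parse_control_file(c("format RESPONSE TIME", "load a_*.dat",
                                    "save out.dat"), text = TRUE), "save")
  # RESPONSE/TIME are mandatory; a parameter cannot be set and depend
  expect_error(parse_control_file(c("format RESPONSE stim", "load a.dat",
                                    "log x"), text = TRUE), "TIME")
  expect_error(parse_control_file(c("set v 1", "depends v stim",
                                    "format RESPONSE TIME stim", "load a.dat",
                                    "log x"), text = TRUE), "both")
})

test_that("round-trip: generated control files parse back to their source", {
  set.seed(101)
  params <- dm_param_names <- c("v", "a", "zr", "t0", "d", "sv", "szr", "st0")
  for (i in 1:200) {
    n_cond <- sample(0:3, 1)
    conds <- if (n_cond) paste0("cond", seq_len(n_cond)) else character()
    fixed_pars <- sample(params, sample(0:3, 1))
    dep_pars <- if (n_cond) {
      sample(setdiff(params, fixed_pars), sample(0:2, 1))
    } else character()
    lines <- c(
      sample(c(paste("method", sample(c("ml", "ks", "cs"), 1)),
               paste("precision", sample(c(2, 2.5, 3, 4), 1)))),
      vapply(fixed_pars, function(p) paste("set", p, round(runif(1), 3)),
             character(1)),
      vapply(dep_pars, function(p) {
        paste("depends", p, paste(sample(conds, sample(seq_along(conds), 1)),
                                  collapse = " "))
      }, character(1)),
      paste("format RESPONSE TIME", paste(conds, collapse = " ")),
      "load data_*.dat", "save out_*.dat", "log all.log")
    spec <- parse_control_file(trimws(lines), text = TRUE)
    expect_setequal(as.character(names(spec$fixed)), fixed_pars)
    expect_setequal(as.character(names(spec$depends)), dep_pars)
    expect_equal(spec$format, c("RESPONSE", "TIME", conds))
  }
})

test_that("data files read per the declared column format", {
  f <- withr::local_tempfile(lines = c(
    "# a comment line",
    "1 0.512 word easy",
    "0\t0.734\tnonword\thard",
    "1   0.401   word   hard"))
  d <- read_data_file(f, c("RESPONSE", "TIME", "stimulus", "difficulty"))
  expect_equal(nrow(d), 3)
  expect_equal(d$response, c(1L, 0L, 1L))
  expect_equal(d$rt, c(0.512, 0.734, 0.401))
  expect_equal(d$stimulus, c("word", "nonword", "word"))
  # tabs and repeated blanks are the same dialect
  f2 <- withr::local_tempfile(lines = c("1\t0.512\tword\teasy",
                                        "0 0.734 nonword hard",
                                        "1 0.401 word hard"))
  d2 <- read_data_file(f2, c("RESPONSE", "TIME", "stimulus", "difficulty"))
  expect_equal(d2$rt[1], d$rt[1])
  expect_equal(d2$stimulus, d$stimulus)

  # '*' columns are present but ignored
  d3 <- read_data_file(f, c("RESPONSE", "TIME", "*", "*"))
  expect_false("stimulus" %in% names(d3))
  expect_equal(names(d3), c("response", "rt"))

  # comments-only file yields an empty dataset, which downstream rejects
  f4 <- withr::local_tempfile(lines = c("# only", "# comments"))
  d4 <- read_data_file(f4, c("RESPONSE", "TIME"))
  expect_equal(nrow(d4), 0)
  expect_error(log_likelihood(d4, dm_params()), "empty")

  # malformed lines are reported with their line number
  fbad <- withr::local_tempfile(lines = c("1 0.5", "2 0.6"))
  expect_error(read_data_file(fbad, c("RESPONSE", "TIME")), "line 2")
  fbad2 <- withr::local_tempfile(lines = c("1 0.5", "0 fast"))
  expect_error(read_data_file(fbad2, c("RESPONSE", "TIME")), "line 2")
  fbad3 <- withr::local_tempfile(lines = c("1 0.5 x"))
  expect_error(read_data_file(fbad3, c("RESPONSE", "TIME")), "line 1")
})

test_that("wildcards expand deterministically and drive save naming", {
  dir <- withr::local_tempdir()
  for (nm in c("participant_2.dat", "participant_1.dat", "other.txt")) {
    writeLines("1 0.5", file.path(dir, nm))
  }
  hits <- expand_wildcards(file.path(dir, "participant_*.dat"))
  expect_equal(basename(hits$path), c("participant_1.dat", "participant_2.dat"))
  expect_equal(hits$fragment, c("1", "2"))
  lit <- expand_wildcards(file.path(dir, "other.txt"))
  expect_equal(lit$fragment, "")
  expect_error(expand_wildcards(file.path(dir, "nope_*.dat")), "match")
  expect_error(expand_wildcards(file.path(dir, "gone.txt")), "not found")
  expect_error(expand_wildcards("a_*_*.dat"), "one")
})

test_that("trial minimums gate the estimation as printed", {
  nine <- tibble::tibble(response = rep(1L, 9), rt = seq(0.3, 0.7, length.out = 9))
  expect_false(check_trial_minimums(nine, "ks")$ok)
  expect_false(check_trial_minimums(nine, "ml")$ok)
  ten <- tibble::tibble(response = rep(c(0L, 1L), 5), rt = seq(0.3, 0.7, length.out = 10))
  expect_true(check_trial_minimums(ten, "ks")$ok)
  # 20 trials with 10 responses at each threshold cannot be analyzed with cs
  twenty <- tibble::tibble(response = rep(c(0L, 1L), 10),
                           rt = seq(0.3, 0.9, length.out = 20))
  expect_false(check_trial_minimums(twenty, "cs")$ok)
  # 12 trials all at the upper threshold are fine for cs
  twelve <- tibble::tibble(response = rep(1L, 12),
                           rt = seq(0.3, 0.9, length.out = 12))
  expect_true(check_trial_minimums(twelve, "cs")$ok)
  # and the fit entry point surfaces the abort
  expect_error(dm_fit(nine, method = "ks"), "estimation stopped")
})

test_that("the parameter table expands condition dependencies", {
  spec <- parse_control_file(example_control_lines(), text = TRUE)
  data <- crossed_data(5)
  pt <- build_parameter_table(spec, data)
  expect_equal(nrow(pt$cells), 4)
  v_slots <- pt$slots$slot[pt$slots$param == "v"]
  expect_length(v_slots, 4)
  expect_equal(pt$P, 7)  # 4 drifts + shared a, t0, st0
  expect_setequal(pt$slots$param, c("v", "a", "t0", "st0"))

  # no depends: one cell, P = 8 - number of fixed parameters
  s2 <- dm_spec(method = "ml", fixed = list(d = 0, zr = 0.5),
                format = c("RESPONSE", "TIME"))
  pt2 <- build_parameter_table(s2, tibble::tibble(response = 1L, rt = 0.5))
  expect_equal(nrow(pt2$cells), 1)
  expect_equal(pt2$P, 6)

  # one 3-level label on v adds two free parameters
  d3 <- tibble::tibble(response = rep(1L, 6), rt = rep(0.5, 6),
                       block = rep(c("b1", "b2", "b3"), 2))
  s3a <- dm_spec(format = c("RESPONSE", "TIME", "block"))
  s3b <- dm_spec(depends = list(v = "block"),
                 format = c("RESPONSE", "TIME", "block"))
  expect_equal(build_parameter_table(s3b, d3)$P,
               build_parameter_table(s3a, d3)$P + 2)

  # every cell resolves all eight parameters
  for (m in pt$cell_map) expect_setequal(names(m), dm_param_names())
})

test_that("outputs carry the expanded names, fit index and penalty flag", {
  set.seed(71)
  d <- two_condition_data(c(easy = 1.5, hard = 0.5), 40)
  f <- dm_fit(d, method = "ml",
              fixed = list(zr = 0.5, d = 0, sv = 0, szr = 0, st0 = 0),
              depends = list(v = "stimulus"))
  spec <- f$spec
  dir <- withr::local_tempdir()
  log_path <- file.path(dir, "all.log")
  save_path <- file.path(dir, "out_1.dat")
  tbl <- write_outputs(list(p1.dat = f), spec, save_paths = save_path,
                       log_path = log_path)
  # log: header + one row; columns = dataset + P + fit + penalized
  lines <- readLines(log_path)
  expect_length(lines, 2)
  header <- strsplit(lines[1], "\t")[[1]]
  expect_equal(header, c("dataset", "v_easy", "v_hard", "a", "t0", "fit",
                         "penalized"))
  expect_length(strsplit(lines[2], "\t")[[1]], length(header))
  # save file names depends-indexed parameters
  saved <- readLines(save_path)
  expect_true(any(grepl("^v_easy = ", saved)))
  expect_true(any(grepl("^v_hard = ", saved)))
  expect_true(any(grepl("^zr = 0.5 \\(fixed\\)", saved)))

  # a penalized result writes the penalty value in place of the fit index
  fpen <- f
  fpen$index <- aggregate_objective("ml", numeric(0), penalty = 1.25)
  tbl2 <- write_outputs(list(p1.dat = fpen), spec, save_paths = save_path,
                        log_path = log_path)
  expect_equal(tbl2$fit, 1.25)
  expect_equal(tbl2$penalized, 1L)
  expect_true(any(grepl("penalty: 1.25", readLines(save_path))))
})

test_that("a control-file run fits every matching data file and logs results", {
  set.seed(83)
  dir <- withr::local_tempdir()
  for (i in 1:2) {
    d <- sample_dataset(dm_params(v = 1.2, a = 1, t0 = 0.3), 60, 3)
    writeLines(paste(d$response, formatC(d$rt, digits = 5, format = "f")),
               file.path(dir, sprintf("p%d.dat", i)))
  }
  writeLines(c("method ml", "precision 2.5",
               "set zr 0.5", "set d 0", "set sv 0", "set szr 0", "set st0 0",
               "format RESPONSE TIME",
               "load p*.dat", "save est_*.dat", "log all.log"),
             file.path(dir, "experiment.ctl"))
  res <- run_experiment(file.path(dir, "experiment.ctl"), quiet = TRUE)
  expect_equal(nrow(res), 2)
  expect_true(file.exists(file.path(dir, "est_1.dat")))
  expect_true(file.exists(file.path(dir, "est_2.dat")))
  expect_length(readLines(file.path(dir, "all.log")), 3)
  expect_true(all(abs(res$v - 1.2) < 0.8))
})
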
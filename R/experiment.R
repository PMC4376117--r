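## Control-file driven batch interface: a plain-text control file selects the
## fit criterion and precision, fixes parameters, declares condition
## dependencies and the data-file column layout, and names input and output
## files. Each data file (usually one participant) is fitted independently.

dm_methods <- c("ml", "ks", "cs")

#' Construct an experiment specification
#'
#' The programmatic equivalent of a control file. `parse_control_file()`
#' produces the same object from text.
#'
#' @param method Fit criterion: `"ks"` (default), `"cs"` or `"ml"`.
#' @param precision Positive real precision value (default 3).
#' @param fixed Named list of parameters fixed to values (`set` commands).
#' @param depends Named list mapping parameters to condition-column labels
#'   (`depends` commands).
#' @param format Character vector of data-file column labels; must contain
#'   `RESPONSE` and `TIME`; `"*"` marks ignored columns.
#' @param load Character vector of data-file name patterns (may contain one
#'   `*` wildcard).
#' @param save Output file pattern for per-dataset save files.
#' @param log Common output (log) file path.
#' @return An object of class `dm_spec`.
#' @export
dm_spec <- function(method = "ks", precision = 3, fixed = list(),
                    depends = list(), format = c("RESPONSE", "TIME"),
                    load = NULL, save = NULL, log = NULL) {
  method <- match.arg(method, dm_methods)
  stopifnot(is.numeric(precision), precision > 0)
  bad <- setdiff(names(fixed), dm_param_names())
  if (length(bad)) stop("unknown parameter in 'set': ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(names(depends), dm_param_names())
  if (length(bad)) stop("unknown parameter in 'depends': ",
                        paste(bad, collapse = ", "), call. = FALSE)
  both <- intersect(names(fixed), names(depends))
  if (length(both)) stop("parameter both set and depends: ",
                         paste(both, collapse = ", "), call. = FALSE)
  if (!all(c("RESPONSE", "TIME") %in% format)) {
    stop("format must contain the RESPONSE and TIME columns", call. = FALSE)
  }
  cond_cols <- setdiff(format, c("RESPONSE", "TIME", "*"))
  for (par in names(depends)) {
    missing_lab <- setdiff(depends[[par]], cond_cols)
    if (length(missing_lab)) {
      stop("depends label(s) not defined in format: ",
           paste(missing_lab, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(method = method, precision = precision, fixed = fixed,
                 depends = depends, format = format, load = load,
                 save = save, log = log),
            class = "dm_spec")
}

#' Parse a control file
#'
#' Reads the plain-text command file driving a batch estimation. Lines
#' starting with `#` are comments. Commands: `method`, `precision`,
#' `set PARAMETER VALUE`, `depends PARAMETER LABEL...`,
#' `format LABEL...`, `load PATTERN`, `save PATTERN`, `log FILE`.
#' `set`/`depends` must precede `format`; `load`/`save`/`log` must follow it.
#' Defaults: `method ks`, `precision 3`. A `load` command and at least one of
#' `save`/`log` are required.
#'
#' @param path Path to the control file, or a character vector of lines when
#'   `text = TRUE`.
#' @param text If `TRUE`, `path` is treated as the file content itself.
#' @return A [dm_spec()] object.
#' @export
parse_control_file <- function(path, text = FALSE) {
  lines <- if (text) path else readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  method <- NULL; precision <- NULL
  fixed <- list(); depends <- list()
  format <- NULL; load <- character(); save <- NULL; log <- NULL
  for (ln in lines) {
    tok <- strsplit(ln, "[ \t]+")[[1]]
    cmd <- tok[1]; args <- tok[-1]
    before_format <- is.null(format)
    switch(cmd,
      method = {
        if (length(args) != 1 || !args %in% dm_methods)
          stop("control file: invalid method command: ", ln, call. = FALSE)
        method <- args
      },
      precision = {
        val <- suppressWarnings(as.numeric(args[1]))
        if (length(args) != 1 || is.na(val) || val <= 0)
          stop("control file: invalid precision command: ", ln, call. = FALSE)
        precision <- val
      },
      set = {
        if (!before_format)
          stop("control file: 'set' must precede 'format'", call. = FALSE)
        val <- suppressWarnings(as.numeric(args[2]))
        if (length(args) != 2 || is.na(val))
          stop("control file: invalid set command: ", ln, call. = FALSE)
        fixed[[args[1]]] <- val
      },
      depends = {
        if (!before_format)
          stop("control file: 'depends' must precede 'format'", call. = FALSE)
        if (length(args) < 2)
          stop("control file: invalid depends command: ", ln, call. = FALSE)
        depends[[args[1]]] <- args[-1]
      },
      format = {
        if (!before_format)
          stop("control file: duplicate format command", call. = FALSE)
        if (!length(args))
          stop("control file: empty format command", call. = FALSE)
        format <- args
      },
      load = {
        if (before_format)
          stop("control file: 'load' must follow 'format'", call. = FALSE)
        if (length(args) != 1)
          stop("control file: invalid load command: ", ln, call. = FALSE)
        load <- c(load, args)
      },
      save = {
        if (before_format)
          stop("control file: 'save' must follow 'format'", call. = FALSE)
        save <- args[1]
      },
      log = {
        if (before_format)
          stop("control file: 'log' must follow 'format'", call. = FALSE)
        log <- args[1]
      },
      stop("control file: unknown command '", cmd, "'", call. = FALSE)
    )
  }
  if (is.null(format)) stop("control file: missing format command", call. = FALSE)
  if (!length(load)) stop("control file: missing load command", call. = FALSE)
  if (is.null(save) && is.null(log)) {
    stop("control file: at least one of save/log is required", call. = FALSE)
  }
  if (any(grepl("\\*", load)) && !is.null(save) && !grepl("\\*", save)) {
    stop("control file: load pattern contains '*' so the save pattern needs one too",
         call. = FALSE)
  }
  dm_spec(method = if (is.null(method)) "ks" else method,
          precision = if (is.null(precision)) 3 else precision,
          fixed = fixed, depends = depends, format = format,
          load = load, save = save, log = log)
}

#' Read a trial data file
#'
#' Whitespace-delimited plain text, one trial per line; `#` lines are
#' comments. Columns are mapped by the `format` labels: `RESPONSE` must be 0
#' (lower threshold) or 1 (upper threshold); `TIME` is the response time in
#' seconds; `*` columns are skipped; any other label becomes a condition
#' column kept as character.
#'
#' @param path Path to the data file.
#' @param format Character vector of column labels.
#' @return A tibble with columns `response`, `rt` and one character column per
#'   named condition label.
#' @export
read_data_file <- function(path, format) {
  stopifnot(all(c("RESPONSE", "TIME") %in% format))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  rows <- strsplit(trimws(lines[keep]), "[ \t]+")
  nc <- length(format)
  out_cols <- setdiff(format, "*")
  vals <- vector("list", length(out_cols))
  names(vals) <- out_cols
  for (v in out_cols) vals[[v]] <- character(length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != nc) {
      stop(sprintf("%s line %d: expected %d columns, found %d",
                   path, keep[i], nc, length(r)), call. = FALSE)
    }
    for (j in seq_len(nc)) {
      if (format[j] != "*") vals[[format[j]]][i] <- r[j]
    }
  }
  resp <- vals[["RESPONSE"]]
  if (!all(resp %in% c("0", "1"))) {
    bad <- keep[which(!resp %in% c("0", "1"))[1]]
    stop(sprintf("%s line %d: RESPONSE must be 0 or 1", path, bad), call. = FALSE)
  }
  rt <- suppressWarnings(as.numeric(vals[["TIME"]]))
  if (anyNA(rt)) {
    bad <- keep[which(is.na(rt))[1]]
    stop(sprintf("%s line %d: TIME is not numeric", path, bad), call. = FALSE)
  }
  cond <- setdiff(out_cols, c("RESPONSE", "TIME"))
  out <- tibble::tibble(response = as.integer(resp), rt = rt)
  for (v in cond) out[[v]] <- vals[[v]]
  out
}

#' Expand a file-name wildcard pattern
#'
#' A single `*` matches any run of characters. Matches are returned in
#' deterministic lexicographic (C locale) order together with the fragment the
#' asterisk matched, which is substituted into save-file patterns.
#'
#' @param pattern File name or pattern with at most one `*`.
#' @return A tibble with columns `path` and `fragment` (`""` for literal
#'   names).
#' @export
expand_wildcards <- function(pattern) {
  n_star <- lengths(regmatches(pattern, gregexpr("\\*", pattern)))
  if (n_star > 1) stop("at most one '*' is supported in a file pattern",
                       call. = FALSE)
  if (n_star == 0) {
    if (!file.exists(pattern)) stop("file not found: ", pattern, call. = FALSE)
    return(tibble::tibble(path = pattern, fragment = ""))
  }
  dir <- dirname(pattern)
  base <- basename(pattern)
  rx <- paste0("^", gsub("\\*", "(.*)",
                         gsub("([.\\\\+?^$(){}\\[\\]|])", "\\\\\\1", base)), "$")
  files <- sort(list.files(dir, full.names = FALSE), method = "radix")
  hit <- grepl(rx, files)
  if (!any(hit)) stop("no files match pattern: ", pattern, call. = FALSE)
  files <- files[hit]
  frag <- sub(rx, "\\1", files)
  tibble::tibble(path = file.path(dir, files), fragment = frag)
}

#' Check the per-condition trial minimums
#'
#' ML and KS require at least 10 trials per experimental condition; CS
#' requires, in every condition, at least one response given in 12 or more
#' trials (the quantile bin borders are unreliable below that).
#'
#' @param data A trials tibble (with a `cell` column, or one implicit cell).
#' @param method `"ml"`, `"ks"` or `"cs"`.
#' @return A list with `ok` (logical) and `messages` (character vector
#'   describing each violation).
#' @export
check_trial_minimums <- function(data, method = c("ks", "cs", "ml")) {
  method <- match.arg(method)
  data <- normalize_trials(data)
  msgs <- character()
  for (cl in unique(data$cell)) {
    d <- data[data$cell == cl, ]
    if (method %in% c("ml", "ks")) {
      if (nrow(d) < 10L) {
        msgs <- c(msgs, sprintf(
          "condition '%s' has %d trials; at least 10 are required for %s",
          cl, nrow(d), method))
      }
    } else {
      n1 <- sum(d$response == 1); n0 <- nrow(d) - n1
      if (max(n0, n1) < 12L) {
        msgs <- c(msgs, sprintf(
          "condition '%s' has no response given in at least 12 trials (%d/%d); cs cannot be used",
          cl, n0, n1))
      }
    }
  }
  list(ok = length(msgs) == 0L, messages = msgs)
}

# attach the condition-cell id implied by the depends labels
assign_cells <- function(data, spec) {
  data <- normalize_trials(data)
  labels <- depends_labels(spec)
  if (!length(labels)) { data$cell <- "all"; return(data) }
  missing_col <- setdiff(labels, names(data))
  if (length(missing_col)) {
    stop("data lacks condition column(s): ", paste(missing_col, collapse = ", "),
         call. = FALSE)
  }
  data$cell <- apply(as.data.frame(lapply(data[labels], as.character)), 1,
                     paste, collapse = "_")
  data
}

# all labels used in any depends command, in format order
depends_labels <- function(spec) {
  labs <- unique(unlist(spec$depends, use.names = FALSE))
  labs[order(match(labs, spec$format))]
}

#' Expand the free-parameter table of an experiment
#'
#' Condition cells are the Cartesian product of the observed level sets
#' (sorted, C locale) of every condition label named in any `depends` command.
#' Each model parameter resolves, per cell, to a fixed value, a shared free
#' slot, or a condition-specific free slot named
#' `parameter_label1value_label2value...`; the number of free slots is the
#' free-parameter count P.
#'
#' @param spec A [dm_spec()] object.
#' @param data A trials tibble containing the condition columns.
#' @return An object of class `dm_ptable`: `cells` (tibble of cell ids and
#'   label values), `slots` (tibble of free slots: `slot`, `param`, `cells`),
#'   `cell_map` (per-cell parameter resolution), `P` (free-parameter count).
#' @export
build_parameter_table <- function(spec, data) {
  data <- assign_cells(data, spec)
  labels <- depends_labels(spec)
  if (length(labels)) {
    levels <- lapply(labels, function(l) sort(unique(as.character(data[[l]])),
                                              method = "radix"))
    names(levels) <- labels
    cells <- rev(expand.grid(rev(levels), stringsAsFactors = FALSE,
                             KEEP.OUT.ATTRS = FALSE))
    cells <- tibble::as_tibble(cells)
    cells$cell <- apply(cells, 1, paste, collapse = "_")
  } else {
    levels <- list()
    cells <- tibble::tibble(cell = "all")
  }

  slots <- list()
  cell_map <- lapply(seq_len(nrow(cells)), function(i) list())
  for (par in dm_param_names()) {
    if (par %in% names(spec$fixed)) {
      for (i in seq_len(nrow(cells))) {
        cell_map[[i]][[par]] <- list(type = "fixed", value = spec$fixed[[par]])
      }
    } else if (par %in% names(spec$depends)) {
      labs <- spec$depends[[par]]
      labs <- labs[order(match(labs, spec$format))]
      combos <- rev(expand.grid(rev(levels[labs]), stringsAsFactors = FALSE,
                                KEEP.OUT.ATTRS = FALSE))
      combo_id <- apply(combos, 1, paste, collapse = "_")
      for (k in seq_along(combo_id)) {
        slot_name <- paste(par, combo_id[k], sep = "_")
        member <- vapply(seq_len(nrow(cells)), function(i) {
          all(vapply(labs, function(l) cells[[l]][i] == combos[[l]][k], logical(1)))
        }, logical(1))
        slots[[length(slots) + 1L]] <- tibble::tibble(
          slot = slot_name, param = par,
          cells = paste(cells$cell[member], collapse = "\r"))
        for (i in which(member)) {
          cell_map[[i]][[par]] <- list(type = "free", slot = slot_name)
        }
      }
    } else {
      slots[[length(slots) + 1L]] <- tibble::tibble(slot = par, param = par,
                                                    cells = NA_character_)
      for (i in seq_len(nrow(cells))) {
        cell_map[[i]][[par]] <- list(type = "free", slot = par)
      }
    }
  }
  slots <- dplyr::bind_rows(slots)
  structure(list(cells = cells, slots = slots, cell_map = cell_map,
                 P = nrow(slots)),
            class = "dm_ptable")
}

#' @export
print.dm_ptable <- function(x, ...) {
  cat("<dm_ptable>", nrow(x$cells), "condition cell(s),", x$P,
      "free parameter(s)\n")
  cat("free slots:", paste(x$slots$slot, collapse = ", "), "\n")
  invisible(x)
}

fmt6 <- function(x) trimws(formatC(x, digits = 6, format = "g"))

#' Write estimation outputs
#'
#' Writes one save file per fitted dataset (a short plain-text report:
#' method, precision, parameter estimates, the three run fit values and the
#' penalty state) and/or one common tab-separated log file with a header row
#' (`dataset`, one column per free parameter, `fit`, `penalized`) and one row
#' per dataset. Numbers carry 6 significant digits.
#'
#' @param fits Named list of `dm_fit` objects (names = dataset identifiers).
#' @param spec The [dm_spec()] used.
#' @param save_paths Optional character vector of save-file paths (one per
#'   fit) or `NULL`.
#' @param log_path Optional path of the common log file or `NULL`.
#' @return Invisibly, the log table as a tibble.
#' @export
write_outputs <- function(fits, spec, save_paths = NULL, log_path = NULL) {
  stopifnot(length(fits) >= 1)
  slots <- fits[[1]]$ptable$slots$slot
  if (!is.null(save_paths)) {
    stopifnot(length(save_paths) == length(fits))
    for (i in seq_along(fits)) {
      f <- fits[[i]]
      lines <- c(
        paste("method:", f$method),
        paste("precision:", fmt6(f$precision)),
        paste("format:", paste(spec$format, collapse = " ")),
        paste("dataset:", names(fits)[i]),
        vapply(seq_along(f$estimates), function(j) {
          paste(names(f$estimates)[j], "=", fmt6(f$estimates[j]))
        }, character(1)),
        vapply(names(spec$fixed), function(par) {
          paste(par, "=", fmt6(spec$fixed[[par]]), "(fixed)")
        }, character(1)),
        paste("fit values:", paste(fmt6(f$runs$fit_value), collapse = " ")),
        if (f$index$penalized) {
          paste("penalty:", fmt6(f$index$penalty))
        } else {
          paste(switch(f$method, ml = "-LL", cs = "CS", ks = "p"), "=",
                fmt6(f$index$value))
        })
      writeLines(lines, save_paths[i])
    }
  }
  log_tbl <- dplyr::bind_rows(lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    row <- tibble::as_tibble(as.list(f$estimates))
    row <- tibble::add_column(row, dataset = names(fits)[i], .before = 1)
    row$fit <- if (f$index$penalized) f$index$penalty else f$index$value
    row$penalized <- as.integer(f$index$penalized)
    row
  }))
  if (!is.null(log_path)) {
    txt <- vapply(seq_len(nrow(log_tbl)), function(i) {
      paste(c(log_tbl$dataset[i], fmt6(unlist(log_tbl[i, slots])),
              fmt6(log_tbl$fit[i]), log_tbl$penalized[i]), collapse = "\t")
    }, character(1))
    writeLines(c(paste(c("dataset", slots, "fit", "penalized"),
                       collapse = "\t"), txt), log_path)
  }
  invisible(log_tbl)
}

#' Run a full control-file driven estimation
#'
#' Parses the control file, expands the load pattern, fits every data set and
#' writes the save/log outputs, mirroring the console report of the original
#' command-line workflow. Data sets violating the trial minimums are skipped
#' with a warning.
#'
#' @param control_file Path to the control file (default `experiment.ctl` in
#'   `dir`).
#' @param dir Directory against which relative file names are resolved
#'   (default: the control file's directory).
#' @param seed Optional integer seed for reproducibility of any stochastic
#'   internals.
#' @param quiet Suppress console output.
#' @return Invisibly, a tibble with one row per fitted dataset (the log
#'   table).
#' @export
run_experiment <- function(control_file = "experiment.ctl",
                           dir = dirname(control_file), seed = NULL,
                           quiet = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  t_start <- Sys.time()
  spec <- parse_control_file(control_file)
  say <- function(...) if (!quiet) cat(..., "\n", sep = "")
  say("control file: ", control_file)
  say("precision: ", fmt6(spec$precision), ";  method: ", spec$method)
  say("format: ", paste(spec$format, collapse = " "))
  if (length(spec$fixed)) {
    say("fixed: ", paste(names(spec$fixed), "=",
                         vapply(spec$fixed, fmt6, character(1)), collapse = ", "))
  }
  files <- dplyr::bind_rows(lapply(spec$load, function(pat) {
    expand_wildcards(file.path(dir, pat))
  }))
  fits <- list()
  save_paths <- character()
  for (i in seq_len(nrow(files))) {
    ds <- basename(files$path[i])
    say("\ndataset ", ds)
    data <- read_data_file(files$path[i], spec$format)
    res <- tryCatch(fit_spec(data, spec), error = function(e) e)
    if (inherits(res, "error")) {
      warning("dataset ", ds, ": ", conditionMessage(res), call. = FALSE)
      say("  skipped: ", conditionMessage(res))
      next
    }
    counts <- res$cell_counts
    for (j in seq_len(nrow(counts))) {
      say("  condition ", counts$cell[j], ": ",
          counts$resp_0[j], " lower / ", counts$resp_1[j], " upper responses")
    }
    say("  fit values (3 runs): ", paste(fmt6(res$runs$fit_value), collapse = "  "))
    for (j in seq_along(res$estimates)) {
      say("  ", names(res$estimates)[j], " = ", fmt6(res$estimates[j]))
    }
    fits[[ds]] <- res
    if (!is.null(spec$save)) {
      save_paths <- c(save_paths,
                      file.path(dir, sub("*", files$fragment[i], spec$save,
                                         fixed = TRUE)))
    }
  }
  if (!length(fits)) stop("no dataset could be fitted", call. = FALSE)
  log_tbl <- write_outputs(fits, spec,
                           save_paths = if (!is.null(spec$save)) save_paths,
                           log_path = if (!is.null(spec$log)) file.path(dir, spec$log))
  say("\nprocessed ", length(fits), " dataset(s) in ",
      fmt6(as.numeric(difftime(Sys.time(), t_start, units = "secs"))), " s")
  invisible(log_tbl)
}
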
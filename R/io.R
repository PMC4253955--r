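#' Readers and writers for time-series tables
#'
#' OpenSim storage (`.sto`/`.mot`) and plain CSV dialects of the same
#' column-labeled time-series table: first column `time`, one column per
#' labeled series.
#'
#' @name storage_io
#' @keywords internal
NULL

#' Read a time-series table (OpenSim storage or CSV)
#'
#' Storage files have free-form header lines terminated by `endheader`,
#' optionally declaring `nRows=`/`nColumns=` (validated against the body),
#' followed by a tab/whitespace-delimited body whose first column is
#' `time`. Files not containing an `endheader` line are parsed as CSV with
#' a header row.
#'
#' @param path File path.
#' @param kind Optional label (`"moments"`, `"lengths"`, `"arms"`,
#'   `"controls"`) recorded on the result.
#' @return A `data.frame` with a `time` column, attribute `kind`.
#' @export
read_storage <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  end <- grep("^\\s*endheader\\s*$", lines)
  if (length(end) >= 1) {
    header <- lines[seq_len(end[1] - 1)]
    body <- lines[-seq_len(end[1])]
    body <- body[nzchar(trimws(body))]
    cols <- strsplit(trimws(body[1]), "[\t ]+")[[1]]
    dat <- utils::read.table(text = paste(body[-1], collapse = "\n"),
                             col.names = cols, check.names = FALSE)
    nrows <- .header_int(header, "nRows")
    ncols <- .header_int(header, "nColumns")
    if (!is.na(nrows) && nrows != nrow(dat))
      stop("storage header declares nRows=", nrows, " but body has ",
           nrow(dat), " rows")
    if (!is.na(ncols) && ncols != ncol(dat))
      stop("storage header declares nColumns=", ncols, " but body has ",
           ncol(dat), " columns")
  } else {
    dat <- utils::read.csv(path, check.names = FALSE)
  }
  names(dat)[1] <- sub("^Time$", "time", names(dat)[1])
  if (names(dat)[1] != "time") stop("first column must be 'time'")
  if (anyDuplicated(names(dat))) stop("duplicate column names")
  if (any(diff(dat$time) <= 0)) stop("non-monotonic time column")
  attr(dat, "kind") <- kind
  dat
}

.header_int <- function(header, key) {
  hit <- grep(paste0("^\\s*", key, "\\s*="), header, value = TRUE)
  if (length(hit) == 0) return(NA_integer_)
  as.integer(sub(".*=\\s*", "", hit[1]))
}

#' Write a time-series table (OpenSim storage or CSV)
#'
#' Deterministic formatting with 17 significant digits.
#'
#' @param table A `data.frame` whose first column is `time`.
#' @param path Output path.
#' @param dialect `"storage"` or `"csv"`.
#' @param name Name written into the storage header.
#' @return `path`, invisibly.
#' @export
write_storage <- function(table, path, dialect = c("storage", "csv"),
                          name = "syntorq") {
  dialect <- match.arg(dialect)
  stopifnot(is.data.frame(table), names(table)[1] == "time")
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  if (dialect == "csv") {
    out <- vapply(table, fmt, character(nrow(table)))
    utils::write.table(rbind(names(table), out), path, sep = ",",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(name,
                 "version=1",
                 paste0("nRows=", nrow(table)),
                 paste0("nColumns=", ncol(table)),
                 "inDegrees=no",
                 "endheader",
                 paste(names(table), collapse = "\t")), con)
    body <- apply(vapply(table, fmt, character(nrow(table))), 1, paste,
                  collapse = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

# ---- trial and structure bundles -----------------------------------------

#' Write a trial to a directory of storage/CSV files
#'
#' One moments file, one muscle-tendon-lengths file, one moment-arm file
#' per DOF (columns = muscles), plus a JSON sidecar with the condition
#' label and cycle boundaries.
#'
#' @param trial A [trial_data()].
#' @param dir Output directory (created if needed).
#' @param dialect `"storage"` or `"csv"`.
#' @return The directory, invisibly.
#' @export
write_trial <- function(trial, dir, dialect = "storage") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (dialect == "csv") ".csv" else ".sto"
  pre <- file.path(dir, trial$condition)
  df <- function(mat) data.frame(time = trial$time, mat, check.names = FALSE)
  write_storage(df(trial$moments), paste0(pre, "_moments", ext), dialect)
  write_storage(df(trial$mt_lengths), paste0(pre, "_lengths", ext), dialect)
  dofs <- colnames(trial$moments)
  for (j in seq_along(dofs))
    write_storage(df(trial$moment_arms[, , j]),
                  paste0(pre, "_arms_", dofs[j], ext), dialect)
  jsonlite::write_json(list(condition = trial$condition,
                            cycles = trial$cycles, dofs = dofs,
                            muscles = colnames(trial$mt_lengths)),
                       paste0(pre, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a trial written by [write_trial()]
#'
#' @param dir Directory containing the bundle.
#' @param condition Condition label (file prefix).
#' @return A [trial_data()].
#' @export
read_trial <- function(dir, condition) {
  meta <- jsonlite::read_json(file.path(dir, paste0(condition,
                                                    "_meta.json")),
                              simplifyVector = TRUE)
  find1 <- function(stem) {
    for (ext in c(".sto", ".csv")) {
      p <- file.path(dir, paste0(condition, "_", stem, ext))
      if (file.exists(p)) return(p)
    }
    stop("missing trial file: ", stem, " for condition ", condition)
  }
  mom <- read_storage(find1("moments"), "moments")
  len <- read_storage(find1("lengths"), "lengths")
  tt <- mom$time
  arms <- array(0, c(length(tt), length(meta$muscles), length(meta$dofs)),
                dimnames = list(NULL, meta$muscles, meta$dofs))
  for (j in seq_along(meta$dofs)) {
    a <- read_storage(find1(paste0("arms_", meta$dofs[j])), "arms")
    arms[, , j] <- as.matrix(a[meta$muscles])
  }
  trial_data(meta$condition, tt, as.matrix(mom[meta$dofs]),
             as.matrix(len[meta$muscles]), arms, meta$cycles)
}

#' Write a synergy structure as a CSV bundle
#'
#' One weightings file (`weightings.csv`, rows = muscles) and one controls
#' file per condition with a time column.
#'
#' @param structure A [synergy_structure()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_structure_csv <- function(structure, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  W <- structure$W
  wdf <- data.frame(muscle = rownames(W) %||% paste0("m", seq_len(nrow(W))),
                    W, check.names = FALSE)
  names(wdf)[-1] <- paste0("syn", seq_len(ncol(W)))
  utils::write.csv(wdf, file.path(dir, "weightings.csv"), row.names = FALSE)
  for (s in seq_along(structure$H)) {
    hdf <- data.frame(time = structure$time[[s]], t(structure$H[[s]]))
    names(hdf)[-1] <- paste0("syn", seq_len(ncol(W)))
    write_storage(hdf,
                  file.path(dir, paste0("controls_",
                                        structure$conditions[s], ".csv")),
                  dialect = "csv")
  }
  jsonlite::write_json(list(conditions = structure$conditions,
                            cycles = structure$cycles),
                       file.path(dir, "structure_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synergy structure bundle written by [write_structure_csv()]
#' @param dir Directory containing the bundle.
#' @return A [synergy_structure()].
#' @export
read_structure_csv <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "structure_meta.json"),
                              simplifyVector = TRUE)
  wdf <- utils::read.csv(file.path(dir, "weightings.csv"),
                         check.names = FALSE)
  W <- as.matrix(wdf[, -1, drop = FALSE])
  rownames(W) <- wdf$muscle
  H <- list(); tt <- list()
  for (s in seq_along(meta$conditions)) {
    hdf <- read_storage(file.path(dir, paste0("controls_",
                                              meta$conditions[s], ".csv")))
    tt[[s]] <- hdf$time
    H[[s]] <- t(as.matrix(hdf[, -1, drop = FALSE]))
  }
  cycles <- meta$cycles
  if (is.matrix(cycles)) cycles <- asplit(cycles, 2)
  synergy_structure(W, H, tt, cycles, meta$conditions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- configuration -------------------------------------------------------

config_defaults <- function() {
  list(
    seed = 1L,
    plant = list(n_muscles = 8L, n_dofs = 3L, noise = 0,
                 conditions = list(list(period = 1.1, n_cycles = 1L),
                                   list(period = 0.85, n_cycles = 1L))),
    grid = list(points = 36L),
    solver = list(restarts = 1L, maxit = 2000L, factr = 1e4,
                  tol_feas = 1e-8, hinge_weight = 1000,
                  name = "reduced-lbfgsb"),
    sweep = list(n_syn_range = c(3L, 7L), n_starts = 15L,
                 k_grid = seq(0, 500, by = 100)),
    comparison = list(n_points = 30L, cycle_average = TRUE)
  )
}

#' Load and validate a run configuration
#'
#' YAML configuration with sections `plant`, `grid`, `solver`, `sweep`,
#' `comparison` and a top-level `seed`. Missing fields take documented
#' defaults (see `config_defaults`, returned when `path` is `NULL`);
#' unknown keys are rejected with a field-level message.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Nested configuration list.
#' @export
load_config <- function(path = NULL) {
  defs <- config_defaults()
  if (is.null(path)) return(defs)
  usr <- yaml::read_yaml(path)
  merge_cfg <- function(d, u, where) {
    unknown <- setdiff(names(u), names(d))
    if (length(unknown) > 0)
      stop("unknown configuration key", if (length(unknown) > 1) "s",
           " at ", where, ": ", paste(unknown, collapse = ", "))
    for (k in names(u)) {
      if (is.list(d[[k]]) && !is.null(names(d[[k]]))) {
        d[[k]] <- merge_cfg(d[[k]], u[[k]], paste0(where, "$", k))
      } else {
        d[[k]] <- u[[k]]
      }
    }
    d
  }
  cfg <- merge_cfg(defs, usr, "config")
  if (!is.numeric(cfg$seed)) stop("config$seed must be an integer")
  if (cfg$plant$n_muscles <= cfg$plant$n_dofs)
    stop("config$plant: n_muscles must exceed n_dofs")
  cfg
}

#' Write a configuration to YAML
#' @param cfg Configuration list.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
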
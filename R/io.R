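#' Load a simulation configuration file
#'
#' Reads a plain-text INI-style file with `[simulation]` and `[community]`
#' sections of `key = value` pairs (a tiny dialect parsed here directly; no
#' quoting, `#` comments allowed).  Recognised simulation keys: `mode`
#' (required), `P` (required), `L`, `steps`, `seed`, `initial_occupancy`,
#' `record_every`.  Community keys: either `file = path.csv` (read with
#' [read_community()]) or generator parameters `N`, `pivot_P`, `pivot_b`,
#' `b0`, `mortality`.  Unknown keys are rejected; omitted keys take the
#' documented defaults.
#'
#' @param path Path to the config file.
#' @return A list with elements `config` (a [sim_config()]) and `community`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  kv <- list(simulation = list(), community = list())
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!section %in% names(kv))
        stop("unknown config section [", section, "]", call. = FALSE)
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (!nzchar(section))
        stop("key outside any section: ", ln, call. = FALSE)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      kv[[section]][[key]] <- val
    } else stop("unparseable config line: ", ln, call. = FALSE)
  }
  sim <- kv$simulation
  sim_keys <- c("mode", "P", "L", "steps", "seed", "initial_occupancy",
                "record_every")
  bad <- setdiff(names(sim), sim_keys)
  if (length(bad))
    stop("unknown [simulation] key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (req in c("mode", "P"))
    if (is.null(sim[[req]]))
      stop("missing required [simulation] key: ", req, call. = FALSE)
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  cfg_args <- list(mode = sim$mode, P = as.numeric(sim$P))
  for (k in c("L", "steps", "seed", "initial_occupancy", "record_every"))
    if (!is.null(sim[[k]])) cfg_args[[k]] <- num(sim[[k]])
  cfg <- do.call(sim_config, cfg_args)

  com <- kv$community
  com_keys <- c("file", "N", "pivot_P", "pivot_b", "b0", "mortality")
  bad <- setdiff(names(com), com_keys)
  if (length(bad))
    stop("unknown [community] key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  community <- if (!is.null(com$file)) {
    read_community(file.path(dirname(path), com$file))
  } else {
    args <- list()
    if (!is.null(com$N)) args$N <- as.integer(com$N)
    for (k in c("pivot_P", "pivot_b", "b0", "mortality"))
      if (!is.null(com[[k]])) args[[k]] <- as.numeric(com[[k]])
    do.call(default_community, args)
  }
  list(config = cfg, community = community)
}

#' Write the default configuration to a file
#'
#' Emits a config file that [load_config()] round-trips to the documented
#' defaults.
#'
#' @param path Output path.
#' @param cfg A [sim_config()] to echo (defaults used if omitted).
#' @param N Community size written to the `[community]` section.
#' @return `path`, invisibly.
#' @export
write_config <- function(path, cfg = sim_config(), N = 10) {
  lines <- c(
    "[simulation]",
    paste("mode =", cfg$mode),
    paste("P =", format(cfg$P)),
    paste("L =", cfg$L),
    paste("steps =", cfg$steps),
    paste("seed =", cfg$seed),
    paste("initial_occupancy =", format(cfg$initial_occupancy)),
    paste("record_every =", cfg$record_every),
    "",
    "[community]",
    paste("N =", N))
  writeLines(lines, path)
  invisible(path)
}

#' Write a density time series as CSV
#'
#' Header `step,x_1,...,x_N,e`; one row per record.
#'
#' @param series The `series` tibble of a `lattice_sim` (or the sim itself).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_time_series <- function(series, path) {
  if (inherits(series, "lattice_sim")) series <- series$series
  readr::write_csv(series, path)
  invisible(path)
}

#' Write a lattice snapshot
#'
#' `write_snapshot_csv()` writes the raw integer grid, one lattice row per
#' CSV line (no header).  `write_snapshot_pgm()` writes a binary PGM (P5)
#' image with gray level `floor(255 * id / N)` (empty = 0 = black), viewable
#' in any image tool without extra dependencies.
#'
#' @param state A `lattice_state` or integer matrix.
#' @param path Output path.
#' @param N Number of species used for gray scaling (defaults to the maximum
#'   id present).
#' @return `path`, invisibly.
#' @export
write_snapshot_csv <- function(state, path) {
  grid <- if (inherits(state, "lattice_state")) state$grid else state
  utils::write.table(grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_snapshot_csv
#' @export
write_snapshot_pgm <- function(state, path, N = NULL) {
  grid <- if (inherits(state, "lattice_state")) state$grid else state
  if (is.null(N)) N <- max(1L, max(grid))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(grid), nrow(grid)), con,
            eos = NULL)
  # PGM is row-major: write the transpose so image rows match lattice rows
  writeBin(as.raw(floor(255 * t(grid) / N)), con)
  invisible(path)
}

#' Write a sweep result as CSV
#'
#' Header `P,richness,total_density,x_1..x_N`.
#'
#' @param sweep A `sweep_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(sweep)), path)
  invisible(path)
}

#' Write all outputs of a run plus a JSON manifest
#'
#' Writes whichever of time series, final snapshot (CSV and PGM) and sweep
#' table are supplied, under `out_prefix`, then a JSON manifest listing the
#' configuration echo, seed and every file written.  All writers are
#' deterministic: identical inputs give byte-identical files.
#'
#' @param out_prefix Path prefix for all files (directories are created).
#' @param series,state,sweep Optional objects to write.
#' @param cfg The [sim_config()] echoed into the manifest.
#' @param community_path Optional path to a community CSV to reference.
#' @return Character vector of files written (manifest last), invisibly.
#' @export
write_outputs <- function(out_prefix, series = NULL, state = NULL,
                          sweep = NULL, cfg = NULL, community_path = NULL) {
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  files <- character()
  if (!is.null(series)) {
    f <- paste0(out_prefix, "_series.csv")
    write_time_series(series, f)
    files <- c(files, f)
  }
  if (!is.null(state)) {
    f1 <- paste0(out_prefix, "_snapshot.csv")
    f2 <- paste0(out_prefix, "_snapshot.pgm")
    write_snapshot_csv(state, f1)
    write_snapshot_pgm(state, f2)
    files <- c(files, f1, f2)
  }
  if (!is.null(sweep)) {
    f <- paste0(out_prefix, "_sweep.csv")
    write_sweep(sweep, f)
    files <- c(files, f)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("lvlattice")),
    config = if (is.null(cfg)) NULL else unclass(cfg),
    community_file = community_path,
    seed = if (is.null(cfg)) NULL else cfg$seed,
    outputs = as.list(files),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  mf <- paste0(out_prefix, "_manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  files <- c(files, mf)
  stopifnot(all(file.exists(files)))
  invisible(files)
}
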
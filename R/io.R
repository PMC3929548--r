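# Plain-text formats: whitespace-delimited tables with '#'-prefixed metadata
# headers carrying a format-version tag.  Neuron indices are 1-based in
# files; times are milliseconds; voltages are in normalized units.

TS_FORMAT <- "ifgc-timeseries-1"
SPK_FORMAT <- "ifgc-spikes-1"

read_header <- function(path) {
  lines <- readLines(path, n = 50, warn = FALSE)
  if (length(lines) == 0) stop("empty input file: ", path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*(\\S+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- trimws(m[3])
  }
  kv
}

#' Write / read a multichannel time-series table
#'
#' Whitespace-delimited text: a metadata header (`# key = value` lines with
#' a format-version tag and the sampling rate), then one row per sample with
#' the time in ms in the first column and one column per channel.
#'
#' @param set a `ts_set` (or matrix; `fs` then taken as 1 kHz).
#' @param path file path.
#' @return `read_timeseries` returns a `ts_set`; `write_timeseries` its
#'   input, invisibly.
#' @export
write_timeseries <- function(set, path) {
  s <- as_ts_set(set)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# format = ", TS_FORMAT),
               paste0("# fs_khz = ", format(s$fs, digits = 17)),
               paste0("# channels = ", paste(s$labels, collapse = " "))), con)
  tab <- cbind(time_ms = seq_len(nrow(s$data)) / s$fs, s$data)
  write.table(format(tab, digits = 17, trim = TRUE, scientific = TRUE),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(set)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  kv <- read_header(path)
  if (!identical(kv$format, TS_FORMAT))
    stop("unknown or missing time-series format tag in ", path)
  fs <- as.numeric(kv$fs_khz)
  if (!is.finite(fs)) stop("missing sampling rate header in ", path)
  tab <- tryCatch(
    read.table(path, comment.char = "#", colClasses = "numeric"),
    error = function(e) stop("non-numeric or ragged data in ", path, ": ",
                             conditionMessage(e)))
  if (nrow(tab) == 0) stop("no data rows in ", path)
  tm <- tab[[1]]
  if (any(diff(tm) <= 0)) {
    bad <- which(diff(tm) <= 0)[1] + 1
    stop("non-monotone time column at row ", bad, " of ", path)
  }
  labels <- if (!is.null(kv$channels)) strsplit(kv$channels, "\\s+")[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(m) <- NULL
  ts_set(m, fs = fs, labels = labels)
}

#' Write / read spike event lists
#'
#' Text format: metadata header, then one `neuron_index spike_time_ms` line
#' per event, times nondecreasing within each neuron.
#'
#' @param spikes list of per-neuron spike-time vectors (1-based neuron
#'   indices in the file).
#' @param path file path.
#' @param n_neurons declared neuron count (for index validation on read).
#' @return `read_spikes` returns a list of per-neuron spike-time vectors.
#' @export
write_spikes <- function(spikes, path) {
  if (inherits(spikes, "simulation_record")) spikes <- spikes$spikes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# format = ", SPK_FORMAT),
               paste0("# n_neurons = ", length(spikes))), con)
  for (i in seq_along(spikes)) {
    v <- spikes[[i]]
    if (length(v))
      writeLines(paste(i, format(v, digits = 17, trim = TRUE)), con)
  }
  invisible(spikes)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path, n_neurons = NULL) {
  kv <- read_header(path)
  if (!identical(kv$format, SPK_FORMAT))
    stop("unknown or missing spike-list format tag in ", path)
  n <- n_neurons %||% as.integer(kv$n_neurons)
  if (!is.finite(n)) stop("missing neuron count in ", path)
  first <- readLines(path, warn = FALSE)
  first <- first[!grepl("^#", first) & nzchar(first)]
  if (length(first) == 0) return(rep(list(numeric(0)), n))
  tab <- read.table(text = first, colClasses = "numeric")
  idx <- tab[[1]]; tms <- tab[[2]]
  if (any(idx != floor(idx) | idx < 1 | idx > n))
    stop("neuron index out of range 1..", n, " in ", path)
  if (any(tms < 0)) stop("negative spike time in ", path)
  out <- lapply(seq_len(n), function(i) sort(tms[idx == i]))
  out
}

#' Read a run configuration file
#'
#' YAML with nested sections `network`, `params`, `drive`, `run`, `gc`,
#' `pipeline`; unknown keys are rejected.  The adjacency may be given inline
#' (list of rows), as a path to a dense 0/1 matrix file, or as a path to an
#' edge list (`src dst` per line, 1-based).
#'
#' @param path YAML config path.
#' @return a list with `network` (`network_spec`), `params`
#'   (`neuron_params`), `drive` (`drive_spec`), and validated `run`, `gc`,
#'   `pipeline` sections.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("network", "params", "drive", "run", "gc", "pipeline")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown config section(s): ",
                          paste(extra, collapse = ", "))
  check_keys <- function(sec, allowed, name) {
    bad <- setdiff(names(sec), allowed)
    if (length(bad)) stop("unknown key(s) in ", name, ": ",
                          paste(bad, collapse = ", "))
    sec
  }
  net <- check_keys(cfg$network %||% list(),
                    c("n_exc", "n_inh", "density", "adjacency",
                      "adjacency_file", "edge_list_file", "S_ee", "S_ie",
                      "S_ei", "S_ii", "model_kind", "seed"), "network")
  A <- NULL
  if (!is.null(net$adjacency)) {
    A <- do.call(rbind, net$adjacency)
  } else if (!is.null(net$adjacency_file)) {
    A <- as.matrix(read.table(file.path(dirname(path), net$adjacency_file)))
  } else if (!is.null(net$edge_list_file)) {
    el <- read.table(file.path(dirname(path), net$edge_list_file))
    n <- (net$n_exc %||% 0) + (net$n_inh %||% 0)
    A <- matrix(0L, n, n)
    A[cbind(el[[1]], el[[2]])] <- 1L
  }
  scls <- c("S_ee", "S_ie", "S_ei", "S_ii")
  sargs <- net[intersect(names(net), c(scls, "model_kind"))]
  network <- if (!is.null(A)) {
    do.call(network_spec, c(list(adjacency = A,
                                 n_exc = net$n_exc %||% nrow(A),
                                 n_inh = net$n_inh %||% 0), sargs))
  } else {
    do.call(generate_random_network,
            c(list(n_exc = net$n_exc, n_inh = net$n_inh %||% 0,
                   density = net$density %||% 0.05,
                   seed = net$seed %||% 1), sargs))
  }
  pkeys <- names(formals(neuron_params))
  params <- do.call(neuron_params,
                    check_keys(cfg$params %||% list(), pkeys, "params"))
  drive <- do.call(drive_spec,
                   check_keys(cfg$drive %||% list(),
                              names(formals(drive_spec)), "drive"))
  run <- check_keys(cfg$run %||% list(),
                    c("duration", "dt", "fs", "seed"), "run")
  gcc <- check_keys(cfg$gc %||% list(),
                    c("max_order", "order", "alpha", "mode", "bonferroni"),
                    "gc")
  pip <- check_keys(cfg$pipeline %||% list(),
                    c("threshold", "partitions", "fs_bin"), "pipeline")
  list(network = network, params = params, drive = drive,
       run = run, gc = gcc, pipeline = pip)
}
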
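#' Loop files, configuration and scenarios
#'
#' Loop collections use JSON lines (one loop object per line, keys in
#' fixed order, loops in canonical order) so diffs are stable. Matrices
#' and traces use CSV; configuration and scenario scripts use YAML (JSON
#' accepted by extension).
#'
#' @name io
NULL

.loop_json <- function(loop) {
  sprintf('{"direction":%d,"n":%d,"ops":[%s],"start":"%s"}',
          loop$direction, loop$n, paste(loop$ops, collapse = ","),
          perm_to_string(loop$start))
}

#' Write Hamilton loops to a JSON-lines file
#'
#' Serialization is deterministic: keys in fixed order, loops sorted by
#' directed canonical key when all are valid (structural order otherwise),
#' so identical collections produce byte-identical files.
#'
#' @param loops a `hamilton_loop` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_loops <- function(loops, path) {
  if (inherits(loops, "hamilton_loop")) loops <- list(loops)
  stopifnot(all(vapply(loops, inherits, logical(1L), "hamilton_loop")))
  keys <- vapply(loops, function(lp) {
    v <- verify_loop(lp)
    if (v$valid) canonicalize_loop(lp, "directed") else
      sprintf("invalid:%s", .loop_json(lp))
  }, character(1L))
  loops <- loops[order(keys)]
  writeLines(vapply(loops, .loop_json, character(1L)), path)
  invisible(path)
}

#' Read Hamilton loops from a JSON-lines file
#'
#' Each line must parse to an object with fields `n`, `start`, `ops` and
#' optionally `direction`. Loops are validated structurally (ops length
#' n!, indices in range); Hamiltonicity is a separate step
#' ([verify_loop()]). All loops in one file must share the same n.
#'
#' @param path a JSON-lines loop file.
#' @param semantics operator semantics to attach to the loops.
#' @return a list of `hamilton_loop` objects (empty for an empty file).
#' @export
read_loops <- function(path, semantics = c("value", "position")) {
  semantics <- match.arg(semantics)
  if (!file.exists(path)) stop("no such loop file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  loops <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[k]),
                    error = function(e) NULL)
    if (is.null(obj) || is.null(obj$n) || is.null(obj$start) ||
        is.null(obj$ops))
      stop(sprintf("parse error in %s at line %d: expected {n, start, ops}",
                   path, k), call. = FALSE)
    loops[[k]] <- tryCatch(
      hamilton_loop(as.character(obj$start), obj$ops,
                    direction = if (is.null(obj$direction)) 1L else
                      as.integer(obj$direction),
                    semantics = semantics),
      error = function(e)
        stop(sprintf("parse error in %s at line %d: %s",
                     path, k, conditionMessage(e)), call. = FALSE))
  }
  ns <- vapply(loops, `[[`, integer(1L), "n")
  if (length(unique(ns)) > 1L)
    stop(sprintf("inconsistent valuedness in %s: found n = {%s}",
                 path, paste(sort(unique(ns)), collapse = ", ")),
         call. = FALSE)
  loops
}

#' Write a Günther matrix as CSV
#'
#' Columns are permutation ranks 1..n!, rows are start choices.
#'
#' @param gm a `guenther_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_guenther_csv <- function(gm, path) {
  stopifnot(inherits(gm, "guenther_matrix"))
  df <- as.data.frame(unclass(gm))
  names(df) <- paste0("perm_", seq_len(ncol(gm)))
  df <- cbind(start_rank = seq_len(nrow(gm)), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.default_config <- function() {
  list(semantics = "value", max_n = 8L, counting = "undirected",
       half_life_h = 2.5, functional_fraction = 0.10,
       plaque_lifetime_h = 4.0, channel_count = 1000L,
       dwell_mean = 1, seed = 1L, log_level = "info")
}

#' Read a run configuration
#'
#' YAML or JSON (by extension); unknown keys are rejected, known keys are
#' validated, missing keys take their defaults.
#'
#' @param path config file, or `NULL` for pure defaults.
#' @return a named list of validated configuration values.
#' @export
read_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    user <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path) else
      yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop("unknown config keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg[names(user)] <- user
  }
  if (!cfg$semantics %in% c("value", "position"))
    stop("config `semantics` must be 'value' or 'position'", call. = FALSE)
  if (!cfg$counting %in% c("undirected", "directed"))
    stop("config `counting` must be 'undirected' or 'directed'",
         call. = FALSE)
  for (key in c("half_life_h", "plaque_lifetime_h"))
    if (cfg[[key]] <= 0) stop("config `", key, "` must be positive",
                              call. = FALSE)
  if (cfg$functional_fraction < 0 || cfg$functional_fraction > 1)
    stop("config `functional_fraction` must lie in [0, 1]", call. = FALSE)
  if (cfg$channel_count < 1) stop("config `channel_count` must be >= 1",
                                  call. = FALSE)
  cfg
}

#' Read a scenario script
#'
#' A scenario is a YAML (or JSON) list of timed environment signals, each
#' with `time`, optional `evidence` (map mode -> weight), `priority` and
#' `programs` (requested program sequence).
#'
#' @param path scenario file.
#' @return a list of `environment_signal` objects sorted by time.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("no such scenario file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path))
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE) else
      yaml::read_yaml(path)
  sigs <- lapply(raw, function(s) {
    environment_signal(
      time = if (is.null(s$time)) 0 else s$time,
      evidence = if (is.null(s$evidence)) numeric(0) else unlist(s$evidence),
      priority = if (is.null(s$priority)) 0 else s$priority,
      program_sequence = if (is.null(s$programs)) character(0) else
        as.character(s$programs))
  })
  sigs[order(vapply(sigs, `[[`, numeric(1L), "time"))]
}
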
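#' Reticular-formation simulator
#'
#' The architecture mirrors the brainstem reticular formation as a command
#' system: perception/relation computers condense environmental input into
#' weighted evidence; a command computer abductively selects the
#' behavior-mode program whose evidence is strongest (redundancy of
#' potential command: any program can rule the system for a time); an
#' executive computer traverses the selected Hamilton loop step by step
#' under a timing unit; higher-priority signals interrupt and replace the
#' program queue. Each program attempt is classified into one of six
#' realization outcomes, and repeated activation imprints a program into
#' memory (a minimal form of learning).
#'
#' @name reticular_sim
NULL

.outcome_levels <- c("ERROR_NO_CYCLE", "CYCLE_NOT_REINFORCED",
                     "CYCLE_ACTIVATED", "REJECTED_BY_PRIORITY",
                     "NOVEL_CYCLE", "IMPRINTED")

#' Construct a behavior-mode repertoire
#'
#' @param modes a data.frame with columns `name` (unique), `percent`
#'   (>= 0) and optionally `loop_id`.
#' @param cycle_length_weeks nominal cycle the percents refer to
#'   (default 4).
#' @param tolerance_pct acceptable deviation of the percent total from
#'   100 (default 20, i.e. totals in \[80, 120\] are accepted).
#' @return an object of class `mode_repertoire`.
#' @export
mode_repertoire <- function(modes, cycle_length_weeks = 4,
                            tolerance_pct = 20) {
  stopifnot(is.data.frame(modes), all(c("name", "percent") %in% names(modes)))
  if (nrow(modes) == 0L) stop("empty mode repertoire", call. = FALSE)
  if (anyDuplicated(modes$name))
    stop("mode names must be unique", call. = FALSE)
  if (any(modes$percent < 0) || anyNA(modes$percent))
    stop("mode percents must be non-negative", call. = FALSE)
  total <- sum(modes$percent)
  if (abs(total - 100) > tolerance_pct)
    stop(sprintf("mode percents sum to %.1f, outside 100 +/- %g",
                 total, tolerance_pct), call. = FALSE)
  if (is.null(modes$loop_id)) modes$loop_id <- seq_len(nrow(modes))
  rownames(modes) <- NULL
  structure(list(modes = modes, cycle_length_weeks = cycle_length_weeks,
                 tolerance_pct = tolerance_pct),
            class = "mode_repertoire")
}

#' @export
print.mode_repertoire <- function(x, ...) {
  cat(sprintf("<mode repertoire> %d behavior modes, %g%% total over a %g-week cycle\n",
              nrow(x$modes), sum(x$modes$percent), x$cycle_length_weeks))
  invisible(x)
}

#' The packaged default behavior-mode table
#'
#' Twenty modes of behavior (sleeps, eats, works, ...) with their percent
#' time shares over an approximately 4-week cycle, summing to exactly
#' 100. Loops are bound to rows in canonical enumeration order by default
#' (loop_id 1..20); rebind by editing the `loop_id` column.
#'
#' @return a `mode_repertoire` with 20 modes.
#' @examples
#' rep <- load_default_modes()
#' subset(rep$modes, name == "Sleeps")$percent  # 30
#' @export
load_default_modes <- function() {
  path <- system.file("extdata", "behavior_modes.csv", package = "permutoglia",
                      mustWork = TRUE)
  modes <- utils::read.csv(path, check.names = FALSE)
  mode_repertoire(modes)
}

#' Construct an environment signal
#'
#' @param time simulation clock time of the signal.
#' @param evidence named non-negative numeric vector: weight of support
#'   for each mode/program name (missing names count as zero).
#' @param priority numeric priority used by [interrupt_reprioritize()].
#' @param program_sequence optional character vector: the program sequence
#'   this signal requests (e.g. retreat, look, forward).
#' @return an object of class `environment_signal`.
#' @export
environment_signal <- function(time = 0, evidence = numeric(0), priority = 0,
                               program_sequence = character(0)) {
  evidence <- unlist(evidence)
  if (length(evidence) && (is.null(names(evidence)) || any(evidence < 0)))
    stop("evidence must be a named vector of non-negative weights",
         call. = FALSE)
  structure(list(time = time, evidence = evidence, priority = priority,
                 program_sequence = as.character(program_sequence)),
            class = "environment_signal")
}

#' Construct a command state
#'
#' @param programs named list of `hamilton_loop` programs known to the
#'   executive computer.
#' @return an object of class `command_state`: active program (or NA), its
#'   priority, the pending queue, the clock, the outcome log and the
#'   per-program activation memory.
#' @export
command_state <- function(programs = list()) {
  stopifnot(is.list(programs))
  if (length(programs) && is.null(names(programs)))
    stop("programs must be a named list", call. = FALSE)
  structure(
    list(programs = programs, active = NA_character_, active_priority = -Inf,
         step = 0L, queue = character(0), clock = 0,
         outcome_log = data.frame(time = numeric(0), program = character(0),
                                  outcome = character(0)),
         memory = integer(0)),
    class = "command_state"
  )
}

.log_outcome <- function(state, program, outcome) {
  outcome <- match.arg(outcome, .outcome_levels)
  state$outcome_log <- rbind(
    state$outcome_log,
    data.frame(time = state$clock, program = program, outcome = outcome))
  state
}

#' Abductive program selection
#'
#' Selects from the repertoire the mode whose weighted evidence is
#' maximal (evidence times per-mode gain, default gain 1); ties are broken
#' by the mode's prior percent share, then by name order. With all-zero
#' evidence the highest-prior mode wins (by default, "Sleeps" at 30 %).
#'
#' @param signal an `environment_signal`.
#' @param repertoire a `mode_repertoire`.
#' @param state optional `command_state` (unused by the default rule but
#'   part of the command interface).
#' @param gains optional named numeric vector of per-mode gains.
#' @return the selected mode name (with its score as attribute `score`).
#' @export
abductive_select <- function(signal, repertoire, state = NULL, gains = NULL) {
  stopifnot(inherits(signal, "environment_signal"),
            inherits(repertoire, "mode_repertoire"))
  modes <- repertoire$modes
  if (nrow(modes) == 0L) stop("empty mode repertoire", call. = FALSE)
  ev <- signal$evidence[modes$name]
  ev[is.na(ev)] <- 0
  gn <- rep(1, nrow(modes))
  if (!is.null(gains)) {
    g <- gains[modes$name]
    gn <- ifelse(is.na(g), 1, g)
  }
  score <- as.numeric(ev) * gn
  ord <- order(-score, -modes$percent, modes$name)
  sel <- modes$name[ord[1L]]
  attr(sel, "score") <- score[ord[1L]]
  sel
}

#' Activate a program on the command computer
#'
#' @param state a `command_state`.
#' @param program name of a known program.
#' @param priority priority of the commanding request.
#' @return the updated state.
#' @export
activate_program <- function(state, program, priority = 0) {
  stopifnot(inherits(state, "command_state"))
  if (!program %in% names(state$programs))
    stop("unknown program: ", program, call. = FALSE)
  state$active <- program
  state$active_priority <- priority
  state$step <- 0L
  state
}

#' Execute a sequence of loop programs
#'
#' The executive computer traverses each program step by step (n! negation
#' steps per loop), the timing unit advancing the clock by one per step.
#' An invalid loop is logged as ERROR_NO_CYCLE and skipped; completed
#' programs are logged CYCLE_ACTIVATED and counted in memory, and a
#' program completing its `imprint_after`-th activation is additionally
#' logged IMPRINTED.
#'
#' @param state a `command_state` whose `programs` contains every name in
#'   `program_names`.
#' @param program_names character vector, the ordered program sequence.
#' @param imprint_after number of activations after which a program is
#'   imprinted (default 3).
#' @return a list: `state` (updated) and `trace`, a data.frame
#'   `(time, program, vertex)` with one row per executed step.
#' @export
execute_program_sequence <- function(state, program_names, imprint_after = 3L) {
  stopifnot(inherits(state, "command_state"))
  unknown <- setdiff(program_names, names(state$programs))
  if (length(unknown))
    stop("unknown programs in sequence: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  trace <- list()
  for (nm in program_names) {
    loop <- state$programs[[nm]]
    v <- verify_loop(loop)
    if (!v$valid) {
      state <- .log_outcome(state, nm, "ERROR_NO_CYCLE")
      next
    }
    m <- length(v$visits)
    vertices <- c(v$visits[-1L], v$visits[1L])  # vertex after each step
    times <- state$clock + seq_len(m)
    state$clock <- state$clock + m
    trace[[length(trace) + 1L]] <-
      data.frame(time = times, program = nm, vertex = vertices)
    state$memory[nm] <- if (nm %in% names(state$memory))
      state$memory[[nm]] + 1L else 1L
    state <- .log_outcome(state, nm, "CYCLE_ACTIVATED")
    if (state$memory[[nm]] == imprint_after)
      state <- .log_outcome(state, nm, "IMPRINTED")
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(time = numeric(0), program = character(0), vertex = integer(0))
  rownames(trace) <- NULL
  list(state = state, trace = trace)
}

#' Interrupt-driven reprioritization
#'
#' If the signal's priority exceeds the active program's, the relation
#' computer preempts the command computer: the active program is logged
#' REJECTED_BY_PRIORITY and the queue is replaced by the signal's program
#' sequence. Otherwise the state is unchanged.
#'
#' @param state a `command_state` with an active program.
#' @param signal an `environment_signal` carrying a `program_sequence`.
#' @return the updated state.
#' @export
interrupt_reprioritize <- function(state, signal) {
  stopifnot(inherits(state, "command_state"),
            inherits(signal, "environment_signal"))
  if (is.na(state$active))
    stop("no active program to interrupt", call. = FALSE)
  if (signal$priority > state$active_priority) {
    state <- .log_outcome(state, state$active, "REJECTED_BY_PRIORITY")
    state$queue <- signal$program_sequence
    state$active <- if (length(signal$program_sequence))
      signal$program_sequence[1L] else NA_character_
    state$active_priority <- signal$priority
    state$step <- 0L
  }
  state
}

#' Classify a program attempt into a realization outcome
#'
#' The six possibilities for the realization of an intentional program:
#' an erroneous operator sequence finds no cycle; a valid cycle goes
#' unreinforced by sensory evidence; a reinforced cycle is activated; a
#' feasible cycle is rejected because another program has priority; a
#' valid cycle not yet in the repertoire is novel; and a repeatedly
#' activated cycle is imprinted (learning).
#'
#' @param program program name (used only for error messages).
#' @param verify_result result of [verify_loop()] on the program's loop.
#' @param evidence total sensory evidence supporting the program (>= 0).
#' @param priority_result `"won"` or `"outranked"`.
#' @param activations how many times this program has been activated
#'   (from `command_state$memory`).
#' @param known logical: is the program already in the repertoire?
#' @param imprint_after activation count at which a program is imprinted.
#' @return one of the outcome labels as a character scalar.
#' @export
classify_outcome <- function(program, verify_result, evidence = 0,
                             priority_result = c("won", "outranked"),
                             activations = 0L, known = TRUE,
                             imprint_after = 3L) {
  priority_result <- match.arg(priority_result)
  if (!verify_result$valid) {
    if (evidence > 0)
      stop(sprintf("inconsistent outcome inputs for '%s': reinforced but no cycle",
                   program), call. = FALSE)
    return("ERROR_NO_CYCLE")
  }
  if (priority_result == "outranked") return("REJECTED_BY_PRIORITY")
  if (!known) return("NOVEL_CYCLE")
  if (evidence <= 0) return("CYCLE_NOT_REINFORCED")
  if (activations + 1L >= imprint_after) return("IMPRINTED")
  "CYCLE_ACTIVATED"
}

#' Stochastic behavior-mode schedule
#'
#' Draws a mode sequence whose expected time shares equal the repertoire
#' percents: at each switch a mode is drawn with probability proportional
#' to its percent and held for a geometric dwell time (default mean 1
#' step, i.e. independent draws every step; equal dwell means keep the
#' stationary shares at the percents).
#'
#' @param repertoire a `mode_repertoire`.
#' @param duration total number of steps (> 0).
#' @param seed integer seed; identical seeds give identical sequences.
#' @param dwell_mean mean dwell time in steps (>= 1).
#' @return a data.frame `(mode, expected_pct, empirical_pct)`, one row per
#'   mode in repertoire order, empirical percents summing to 100; the
#'   drawn sequence is attached as attribute `"sequence"`.
#' @export
run_schedule <- function(repertoire, duration, seed = NULL, dwell_mean = 1) {
  stopifnot(inherits(repertoire, "mode_repertoire"))
  if (!is.numeric(duration) || length(duration) != 1L || duration < 1)
    stop("duration must be a positive number of steps", call. = FALSE)
  if (dwell_mean < 1) stop("dwell_mean must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  duration <- as.integer(duration)
  modes <- repertoire$modes
  prob <- modes$percent / sum(modes$percent)
  seq_out <- character(duration)
  filled <- 0L
  while (filled < duration) {
    m <- sample(modes$name, 1L, prob = prob)
    d <- if (dwell_mean == 1) 1L else
      stats::rgeom(1L, 1 / dwell_mean) + 1L
    d <- min(d, duration - filled)
    seq_out[(filled + 1L):(filled + d)] <- m
    filled <- filled + d
  }
  counts <- table(factor(seq_out, levels = modes$name))
  summary <- data.frame(
    mode = modes$name,
    expected_pct = 100 * prob,
    empirical_pct = 100 * as.numeric(counts) / duration)
  attr(summary, "sequence") <- seq_out
  summary
}
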
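#' Gap-junctional plaques
#'
#' A plaque is modeled as a container of Hamilton-loop programs plus a
#' population of unit gap-junction channels, each functional or
#' nonfunctional. The biology supplies three numbers: connexin half-life
#' of 1.5-3.5 h (default 2.5 h, mid-range), roughly 10 % functional
#' channels at any time, and plaque dissolution/reassembly on a timescale
#' of about 4 h. No kinetic law is given, so turnover follows the simplest
#' memoryless birth-death process honoring those numbers: per step of
#' length dt each functional channel survives with probability
#' \eqn{2^{-dt/t_{1/2}}} and nonfunctional channels convert at the
#' balancing rate that pins the expected functional fraction at the
#' target. Loop storage is closed under reversal: behavior modes come in
#' opposed pairs (wakefulness-sleeping), a loop and its reverse run.
#'
#' @name plaque
NULL

#' Build a gap-junctional plaque
#'
#' Input loops are deduplicated by undirected canonical key; each surviving
#' loop is stored together with its reversal, so the directed program count
#' is twice the undirected input count (44 undirected loops in, the full
#' 88-program network out).
#'
#' @param loops a list of valid `hamilton_loop` objects (undirected
#'   representatives), or a single loop.
#' @param channel_count number of unit channels (>= 1).
#' @param half_life_h connexin half-life in hours (default 2.5).
#' @param functional_fraction target fraction of functional channels
#'   (default 0.10).
#' @param plaque_lifetime_h dissolution/reassembly period in hours
#'   (default 4).
#' @return an object of class `gj_plaque` with `programs` (named list of
#'   directed loops keyed by directed canonical key), `channels` (logical
#'   vector, TRUE = functional) and `params`.
#' @examples
#' p <- build_plaque(construct_loop(4), channel_count = 100)
#' length(p$programs)       # 2: the loop and its reversal
#' functional_fraction(p)   # 0.10
#' @export
build_plaque <- function(loops, channel_count = 1000L,
                         half_life_h = 2.5, functional_fraction = 0.10,
                         plaque_lifetime_h = 4.0) {
  if (inherits(loops, "hamilton_loop")) loops <- list(loops)
  if (!is.list(loops) || length(loops) == 0L)
    stop("a plaque needs at least one Hamilton loop", call. = FALSE)
  if (channel_count < 1L)
    stop("channel_count must be >= 1", call. = FALSE)
  if (functional_fraction < 0 || functional_fraction > 1)
    stop("functional_fraction must lie in [0, 1]", call. = FALSE)
  for (lp in loops) {
    if (!inherits(lp, "hamilton_loop"))
      stop("loops must be hamilton_loop objects", call. = FALSE)
    v <- verify_loop(lp)
    if (!v$valid)
      stop(sprintf("invalid loop in plaque input (%s at step %d)",
                   v$kind, v$step), call. = FALSE)
  }
  ukeys <- vapply(loops, canonicalize_loop, character(1L),
                  counting = "undirected")
  loops <- loops[!duplicated(ukeys)]
  programs <- list()
  for (lp in loops) {
    fwd <- rotate_to_rank1(lp)
    bwd <- rotate_to_rank1(reverse_loop(lp))
    programs[[canonicalize_loop(fwd, "directed")]] <- fwd
    programs[[canonicalize_loop(bwd, "directed")]] <- bwd
  }
  programs <- programs[order(names(programs))]
  n_fun <- round(channel_count * functional_fraction)
  channels <- c(rep(TRUE, n_fun), rep(FALSE, channel_count - n_fun))
  structure(
    list(programs = programs, channels = channels,
         params = list(half_life_h = half_life_h,
                       functional_fraction = functional_fraction,
                       plaque_lifetime_h = plaque_lifetime_h)),
    class = "gj_plaque"
  )
}

#' @export
print.gj_plaque <- function(x, ...) {
  cat(sprintf(
    "<gap-junction plaque> %d directed loop programs, %d channels (%.1f%% functional)\n",
    length(x$programs), length(x$channels), 100 * functional_fraction(x)))
  invisible(x)
}

#' Functional channel fraction of a plaque
#'
#' @param p a `gj_plaque`.
#' @return fraction of functional channels in \[0, 1\].
#' @export
functional_fraction <- function(p) {
  stopifnot(inherits(p, "gj_plaque"))
  mean(p$channels)
}

#' One stochastic turnover step
#'
#' Each functional channel survives the step with probability
#' \eqn{2^{-dt/t_{1/2}}}; with `renewal = TRUE` nonfunctional channels
#' convert to functional with the balancing probability
#' \eqn{r = f (1 - s) / (1 - f)} (f = target fraction, s = survival), so
#' the expected functional fraction is held at the target. Channel count
#' is conserved. Seeding makes trajectories reproducible.
#'
#' @param p a `gj_plaque`.
#' @param dt step length in hours (> 0).
#' @param renewal logical; disable to watch pure exponential decay.
#' @param seed optional integer seed; identical seeds give identical
#'   trajectories.
#' @return the plaque with updated channel states.
#' @export
step_turnover <- function(p, dt, renewal = TRUE, seed = NULL) {
  stopifnot(inherits(p, "gj_plaque"))
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0)
    stop("dt must be a positive number of hours", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  s <- 2^(-dt / p$params$half_life_h)
  f <- p$params$functional_fraction
  r <- if (f >= 1) 1 else min(1, f * (1 - s) / (1 - f))
  ch <- p$channels
  fun <- which(ch)
  non <- which(!ch)
  if (length(fun)) ch[fun] <- stats::runif(length(fun)) < s
  if (renewal && length(non)) ch[non] <- stats::runif(length(non)) < r
  p$channels <- ch
  p
}

#' Simulate plaque channel turnover over time
#'
#' Runs repeated turnover steps; every `plaque_lifetime_h` hours the
#' plaque dissolves and reassembles (channels reset to the target
#' functional fraction) while the loop programs persist — the embodiment
#' of the loops is redundant and survives plaque turnover.
#'
#' @param p a `gj_plaque`.
#' @param hours total simulated time.
#' @param dt step length in hours.
#' @param renewal logical, passed to [step_turnover()].
#' @param seed optional integer seed for the whole trajectory.
#' @return a data.frame `time_h`, `functional_fraction` (the state after
#'   each step, with time 0 prepended).
#' @export
simulate_plaque <- function(p, hours, dt = 0.1, renewal = TRUE, seed = NULL) {
  stopifnot(inherits(p, "gj_plaque"))
  if (hours <= 0 || dt <= 0) stop("hours and dt must be positive",
                                  call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  steps <- ceiling(hours / dt)
  life <- p$params$plaque_lifetime_h
  n_fun0 <- round(length(p$channels) * p$params$functional_fraction)
  reset <- c(rep(TRUE, n_fun0), rep(FALSE, length(p$channels) - n_fun0))
  out_t <- numeric(steps + 1L)
  out_f <- numeric(steps + 1L)
  out_f[1L] <- functional_fraction(p)
  next_dissolution <- life
  t <- 0
  for (k in seq_len(steps)) {
    p <- step_turnover(p, dt, renewal = renewal)
    t <- t + dt
    if (is.finite(life) && t >= next_dissolution - 1e-9) {
      p$channels <- reset
      next_dissolution <- next_dissolution + life
    }
    out_t[k + 1L] <- t
    out_f[k + 1L] <- functional_fraction(p)
  }
  data.frame(time_h = out_t, functional_fraction = out_f)
}
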
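test_that("the packaged mode table matches the canonical 20-mode repertoire", {
  rep <- load_default_modes()
  expect_equal(nrow(rep$modes), 20)
  expect_equal(sum(rep$modes$percent), 100)
  pct <- function(nm) rep$modes$percent[rep$modes$name == nm]
  expect_equal(pct("Sleeps"), 30)
  expect_equal(pct("Works"), 25)
  expect_equal(pct("Interpersonal attends"), 8)
  expect_false(anyDuplicated(rep$modes$name) > 0)
})

test_that("mode_repertoire validates totals within the 100 +/- 20 band", {
  df <- data.frame(name = c("a", "b"), percent = c(60, 50))
  expect_s3_class(mode_repertoire(df), "mode_repertoire")   # 110, in band
  expect_error(mode_repertoire(data.frame(name = "a", percent = 130)),
               "outside")
  expect_error(mode_repertoire(data.frame(name = c("a", "a"),
                                          percent = c(50, 50))), "unique")
  expect_error(mode_repertoire(data.frame(name = "a", percent = -100)),
               "non-negative")
})

test_that("abductive selection is argmax with prior and name tie-breaks", {
  rep <- load_default_modes()
  sel <- abductive_select(environment_signal(
    evidence = c(Eats = 0.9, Sleeps = 0.1)), rep)
  expect_equal(as.character(sel), "Eats")
  # all-zero evidence: the highest-prior mode commands
  expect_equal(as.character(abductive_select(environment_signal(), rep)),
               "Sleeps")
  # equal evidence between two modes: higher prior wins (Works 25 > Talks 5)
  sel2 <- abductive_select(environment_signal(
    evidence = c(Works = 0.5, Talks = 0.5)), rep)
  expect_equal(as.character(sel2), "Works")
  # equal evidence and equal prior: name order (Drinks 1% vs Voids 1%)
  sel3 <- abductive_select(environment_signal(
    evidence = c(Voids = 0.5, Drinks = 0.5)), rep)
  expect_equal(as.character(sel3), "Drinks")
  # per-mode gains reweight the evidence
  sel4 <- abductive_select(environment_signal(
    evidence = c(Eats = 0.5, Talks = 0.4)), rep,
    gains = c(Talks = 2))
  expect_equal(as.character(sel4), "Talks")
  # single-mode repertoire: that mode regardless of evidence
  solo <- mode_repertoire(data.frame(name = "Works", percent = 100))
  expect_equal(as.character(abductive_select(environment_signal(
    evidence = c(Sleeps = 9)), solo)), "Works")
})

test_that("the selected program always has maximal evidence", {
  rep <- load_default_modes()
  set.seed(123)
  for (k in 1:25) {
    ev <- stats::runif(5)
    names(ev) <- sample(rep$modes$name, 5)
    sel <- abductive_select(environment_signal(evidence = ev), rep)
    expect_equal(unname(ev[as.character(sel)]), max(ev))
  }
})

test_that("execute_program_sequence traces n! steps per loop", {
  programs <- list(HL1 = construct_loop(4),
                   HL2 = rotate_to_rank1(reverse_loop(construct_loop(4))),
                   HL3 = hamilton_loop(1:4, fig_loop_ops),
                   HL4 = rotate_to_rank1(reverse_loop(
                     hamilton_loop(1:4, fig_loop_ops))))
  st <- command_state(programs)
  res <- execute_program_sequence(st, "HL1")
  expect_equal(nrow(res$trace), 24)
  expect_equal(res$state$clock, 24)
  expect_setequal(res$trace$vertex, 1:24)
  res4 <- execute_program_sequence(st, c("HL1", "HL2", "HL3", "HL4"))
  expect_equal(nrow(res4$trace), 96)
  expect_equal(unique(res4$trace$program), c("HL1", "HL2", "HL3", "HL4"))
  expect_equal(res4$trace$time, 1:96)   # timing unit advances per step
  expect_error(execute_program_sequence(st, "HL9"), "unknown programs")
})

test_that("invalid programs are logged ERROR_NO_CYCLE and skipped", {
  programs <- list(good = construct_loop(3),
                   broken = hamilton_loop(1:3, rep(1L, 6)),
                   also_good = rotate_to_rank1(reverse_loop(
                     construct_loop(3))))
  st <- command_state(programs)
  res <- execute_program_sequence(st, c("good", "broken", "also_good"))
  expect_equal(nrow(res$trace), 12)     # the two valid loops still ran
  log <- res$state$outcome_log
  expect_equal(log$outcome[log$program == "broken"], "ERROR_NO_CYCLE")
  expect_equal(sum(log$outcome == "CYCLE_ACTIVATED"), 2)
})

test_that("repeated activation imprints a program", {
  st <- command_state(list(HL1 = construct_loop(3)))
  res <- execute_program_sequence(st, rep("HL1", 3))
  log <- res$state$outcome_log
  expect_equal(sum(log$outcome == "IMPRINTED"), 1)
  expect_equal(unname(res$state$memory["HL1"]), 3)
})

test_that("interrupts preempt only on higher priority and keep a log", {
  programs <- list(look = construct_loop(3),
                   forward = rotate_to_rank1(reverse_loop(construct_loop(3))),
                   stop = hamilton_loop(1:3, c(1, 2, 1, 2, 1, 2)),
                   retreat = hamilton_loop(1:3, c(2, 1, 2, 1, 2, 1)))
  st <- activate_program(command_state(programs), "forward", priority = 1)
  # obstacle: higher-priority request for retreat -> look -> forward
  obstacle <- environment_signal(priority = 5,
                                 program_sequence = c("retreat", "look",
                                                      "forward"))
  st2 <- interrupt_reprioritize(st, obstacle)
  expect_equal(st2$queue, c("retreat", "look", "forward"))
  expect_equal(st2$active, "retreat")
  expect_equal(st2$outcome_log$outcome, "REJECTED_BY_PRIORITY")
  expect_equal(st2$outcome_log$program, "forward")
  # lower priority: unchanged
  st3 <- interrupt_reprioritize(st, environment_signal(priority = 0.5))
  expect_equal(st3$active, "forward")
  expect_equal(nrow(st3$outcome_log), 0)
  expect_error(interrupt_reprioritize(command_state(programs),
                                      environment_signal()), "no active")
})

test_that("classify_outcome maps the six realization possibilities", {
  good <- verify_loop(construct_loop(3))
  bad <- verify_loop(hamilton_loop(1:3, rep(1L, 6)))
  expect_equal(classify_outcome("p", bad), "ERROR_NO_CYCLE")
  expect_equal(classify_outcome("p", good, evidence = 0),
               "CYCLE_NOT_REINFORCED")
  expect_equal(classify_outcome("p", good, evidence = 1),
               "CYCLE_ACTIVATED")
  expect_equal(classify_outcome("p", good, evidence = 1,
                                priority_result = "outranked"),
               "REJECTED_BY_PRIORITY")
  expect_equal(classify_outcome("p", good, evidence = 1, known = FALSE),
               "NOVEL_CYCLE")
  expect_equal(classify_outcome("p", good, evidence = 1, activations = 2,
                                imprint_after = 3), "IMPRINTED")
  expect_error(classify_outcome("p", bad, evidence = 1), "inconsistent")
})

test_that("run_schedule recovers the configured shares and conserves time", {
  rep <- load_default_modes()
  s <- run_schedule(rep, duration = 20000, seed = 4L)
  expect_equal(sum(s$empirical_pct), 100)
  expect_equal(s$expected_pct[s$mode == "Sleeps"], 30)
  tol <- 3 * sqrt(0.3 * 0.7 / 20000) * 100
  expect_lt(abs(s$empirical_pct[s$mode == "Sleeps"] - 30), tol)
  # every mode's share near its percent (loose 5-sigma guard per mode)
  for (r in seq_len(nrow(s))) {
    p <- s$expected_pct[r] / 100
    expect_lt(abs(s$empirical_pct[r] - s$expected_pct[r]),
              5 * sqrt(p * (1 - p) / 20000) * 100 + 1e-9)
  }
  # determinism and degenerate cases
  expect_identical(run_schedule(rep, 1000, seed = 8L),
                   run_schedule(rep, 1000, seed = 8L))
  solo <- mode_repertoire(data.frame(name = "Works", percent = 100))
  expect_equal(run_schedule(solo, 50, seed = 1L)$empirical_pct, 100)
  expect_error(run_schedule(rep, 0), "positive")
  # dwell > 1 still fills the whole duration
  s2 <- run_schedule(rep, 500, seed = 2L, dwell_mean = 4)
  expect_equal(sum(s2$empirical_pct), 100)
  expect_length(attr(s2, "sequence"), 500)
})
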
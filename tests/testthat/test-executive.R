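test_that("round sampling reproduces the printed stimulus contingencies", {
  rng <- rng_stream(17, "exec.contingency")
  n <- 10000L
  congr <- logical(n); neutral <- logical(n); green <- logical(n)
  for (i in seq_len(n)) {
    r <- sample_training_round(rng)
    congr[i] <- r$congruency == "congruent"
    neutral[i] <- r$image_valence == "neutral"
    green[i] <- r$circle_color == "green"
  }
  ci99 <- function(p, m) 2.576 * sqrt(p * (1 - p) / m)
  expect_lt(abs(mean(congr) - 0.5), ci99(0.5, n))
  expect_lt(abs(mean(green) - 0.5), ci99(0.5, n))
  expect_lt(abs(mean(neutral[congr]) - 0.8), ci99(0.8, sum(congr)))
  expect_lt(abs(mean(neutral[!congr]) - 0.2), ci99(0.2, sum(!congr)))
  # joint table approx {0.4, 0.1, 0.1, 0.4}
  joint <- c(mean(congr & neutral), mean(congr & !neutral),
             mean(!congr & neutral), mean(!congr & !neutral))
  target <- c(0.4, 0.1, 0.1, 0.4)
  expect_true(all(abs(joint - target) < mapply(ci99, target,
                                               MoreArgs = list(m = n))))
  # marginal P(negative image) = 0.5 by construction
  expect_lt(abs(mean(!neutral) - 0.5), ci99(0.5, n))
})

test_that("congruent rounds have uniform arrows; incongruent flip the flankers", {
  rng <- rng_stream(3, "exec.arrows")
  for (i in 1:50) {
    r <- sample_training_round(rng)
    center <- r$arrows[3]
    expect_identical(center, r$center_direction)
    flankers <- r$arrows[-3]
    if (r$congruency == "congruent") {
      expect_true(all(flankers == center))
    } else {
      expect_true(all(flankers != center))
    }
  }
})

test_that("a round is correct only when both stages are right and in-window", {
  rng <- rng_stream(4, "exec.eval")
  r <- sample_training_round(rng)
  good <- list(flanker_key = r$center_direction, flanker_rt_ms = 500,
               circle_key = if (r$circle_color == "green") "up" else "down",
               circle_rt_ms = 900)
  expect_identical(evaluate_round(r, good), "correct")
  bad_circle <- good; bad_circle$circle_key <- setdiff(c("up", "down"),
                                                       good$circle_key)
  expect_identical(evaluate_round(r, bad_circle), "incorrect")
  timeout <- good; timeout$flanker_key <- NA; timeout$flanker_rt_ms <- 1000
  expect_identical(evaluate_round(r, timeout), "incorrect")
  late <- good; late$circle_rt_ms <- 2500
  expect_identical(evaluate_round(r, late), "incorrect")
  # pure: same inputs, same output
  expect_identical(evaluate_round(r, good), evaluate_round(r, good))
})

test_that("training batches run exactly 3 rounds with the printed timeline", {
  perfect <- agent_profile(skill = 1)
  log <- event_log()
  res <- run_training_batch(rng_stream(6, "exec.batch"), perfect,
                            economy_state(lives = 3, free_double_jumps = 5),
                            log = log)
  expect_length(res$outcomes, 3L)
  expect_true(all(res$outcomes == "correct"))
  expect_identical(res$cumulative_correct, 3L)
  ev <- log_events(log)
  kinds <- vapply(ev, `[[`, "", "kind")
  expect_identical(sum(kinds == "instructions_shown"), 3L)
  # within each round: image onset -> +100 ms offset -> +50 ms circle onset
  img_on <- vapply(ev[kinds == "image_onset"], `[[`, 1L, "ts_ms")
  img_off <- vapply(ev[kinds == "image_offset"], `[[`, 1L, "ts_ms")
  circ_on <- vapply(ev[kinds == "circle_onset"], `[[`, 1L, "ts_ms")
  expect_identical(img_off - img_on, rep(100L, 3L))
  expect_identical(circ_on - img_off, rep(50L, 3L))
})

test_that("correct responses earn badges at 6, 15 and 39", {
  perfect <- agent_profile(skill = 1)
  eco <- economy_state(lives = 3, free_double_jumps = 5)
  log <- event_log()
  cum <- 0L; t <- 0L; phase <- "double_jump"
  rng <- rng_stream(8, "exec.badges")
  for (b in 1:13) { # 39 rounds
    res <- run_training_batch(rng, perfect, eco, cumulative_correct = cum,
                              log = log, t0_ms = t, reward_phase = phase)
    eco <- res$economy; cum <- res$cumulative_correct
    t <- res$t_ms; phase <- res$reward_phase
  }
  badge_ev <- log_events(log, "badge_awarded")
  counts <- vapply(badge_ev, function(e) e$payload$count, 1L)
  tiers <- vapply(badge_ev, function(e) e$payload$tier, "")
  expect_identical(counts[tiers == "bronze"], 6L)
  expect_identical(counts[tiers == "silver"], 15L)
  expect_identical(counts[tiers == "gold"], 39L)
  # alternating rewards: 39 correct rounds split between jumps and lives
  expect_identical(eco$free_double_jumps, 5L + 20L)
  expect_identical(eco$lives, 3L + 19L)
})

test_that("the platformer starts with 3 lives and 5 free double jumps and punishes misses", {
  st <- platformer_start()
  expect_identical(st$economy$lives, 3L)
  expect_identical(st$economy$free_double_jumps, 5L)
  ok <- step_platformer(st, "jump", obstacle = "pit_single")
  expect_true(ok$alive)
  expect_gt(ok$distance, 0L)
  miss <- step_platformer(st, "run", obstacle = "pit_single")
  expect_identical(miss$economy$lives, 2L)
  # speed ramps and caps
  st2 <- platformer_start()
  for (i in 1:100) st2 <- step_platformer(st2, "run", dt_ms = 10000L)
  expect_identical(st2$speed, 3.0)
})
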
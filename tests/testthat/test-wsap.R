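bank <- load_wsap_bank()

test_that("the bundled bank has 42 items and honors the decoy contract", {
  expect_length(bank, 42L)
  for (it in bank) {
    if (it$is_decoy) {
      expect_identical(it$correct_answer,
                       if (it$probe_valence == "negative") "yes" else "no")
    } else {
      expect_identical(it$correct_answer,
                       if (it$probe_valence == "positive") "yes" else "no")
    }
  }
  # difficulty ordering: (word count, longest word) non-decreasing
  wc <- vapply(bank, function(it) length(it$words), 1L)
  expect_true(all(diff(wc) >= 0L))
})

test_that("grid placements spell their words along straight paths", {
  rng <- rng_stream(5, "test.grid")
  for (ix in c(1L, 7L, 20L, 42L)) {
    item <- bank[[ix]]
    grid <- build_letter_grid(item, rng = rng)
    expect_setequal(names(grid$placements), item$words)
    for (w in item$words) {
      path <- grid$placements[[w]]
      expect_identical(read_path(grid, path), w)
      # straight line: constant unit step in one of 8 directions
      if (nrow(path) > 1L) {
        dr <- diff(path[, 1]); dc <- diff(path[, 2])
        expect_true(all(dr == dr[1]) && all(dc == dc[1]))
        expect_identical(max(abs(c(dr[1], dc[1]))), 1L)
      }
    }
  }
})

test_that("grid layout is reproducible for a fixed seed and errors when a word cannot fit", {
  item <- bank[[3]]
  g1 <- build_letter_grid(item, rng = rng_stream(21, "x"))
  g2 <- build_letter_grid(item, rng = rng_stream(21, "x"))
  expect_identical(g1$cells, g2$cells)
  long_item <- sentence_item("I was absolutely overwhelmed", "tired",
                             "negative")
  expect_error(build_letter_grid(long_item, dims = c(8, 8),
                                 rng = rng_stream(1, "y")),
               "cannot fit")
})

test_that("the sentence is revealed exactly when half the words are found", {
  rng <- rng_stream(9, "reveal")
  for (ix in c(1L, 15L, 33L)) {
    item <- bank[[ix]]
    grid <- build_letter_grid(item, rng = rng)
    state <- wsap_level_start(item, 0)
    n <- length(item$words)
    threshold <- ceiling(n / 2)
    for (k in seq_len(n)) {
      res <- submit_path(state, grid, grid$placements[[item$words[k]]])
      state <- res$state
      expect_identical(res$outcome, "sentence_word")
      expect_identical(state$sentence_revealed, k >= threshold)
    }
    expect_identical(state$phase, "probe")
  }
})

test_that("bonus words score and junk paths are rejected without state change", {
  item <- sentence_item("My mom called me to tell me the news", "exciting",
                        "positive")
  grid <- build_letter_grid(item, rng = rng_stream(2, "bonus"))
  state <- wsap_level_start(item, 0)
  dict <- load_bonus_dictionary()
  # overwrite a straight run of cells with a dictionary word not in the sentence
  grid$cells[1, 1:3] <- c("S", "U", "N")
  res <- submit_path(state, grid, cbind(1L, 1:3), dictionary = dict)
  if (!"SUN" %in% item$words) {
    expect_identical(res$outcome, "bonus_word")
    expect_gt(res$state$points, state$points)
  }
  # duplicate bonus submission does not double-score
  res2 <- submit_path(res$state, grid, cbind(1L, 1:3), dictionary = dict)
  expect_identical(res2$outcome, "rejected")
  # L-shaped path rejected
  lpath <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 2L))
  res3 <- submit_path(state, grid, lpath, dictionary = dict)
  expect_identical(res3$outcome, "rejected")
  expect_identical(res3$state$points, state$points)
})

test_that("display duration is 100 + 20 per character", {
  expect_identical(display_duration_ms(strrep("a", 50)), 1100L)
  expect_identical(display_duration_ms("a"), 120L)
  expect_identical(display_duration_ms(strrep("a", 100)), 2100L)
  expect_error(display_duration_ms(""), "non-empty")
})

test_that("probe scoring rewards speed, floors at 1 and zeroes errors", {
  item <- bank[[which(!vapply(bank, `[[`, TRUE, "is_decoy") &
                      vapply(bank, `[[`, "", "probe_valence") == "positive")[1]]]
  expect_identical(score_probe(item, "yes", 0), 10L)
  expect_identical(score_probe(item, "no", 0), 0L)
  expect_identical(score_probe(item, "yes", 6000), 0L)  # timeout
  # monotone non-increasing in rt, strictly positive in-window
  rts <- seq(0, 5000, by = 250)
  pts <- vapply(rts, function(rt) score_probe(item, "yes", rt), 1L)
  expect_true(all(diff(pts) <= 0L))
  expect_true(all(pts >= 1L))
  # decoy with related negative word: yes is correct and pays
  decoy <- bank[[which(vapply(bank, `[[`, TRUE, "is_decoy") &
                       vapply(bank, `[[`, "", "probe_valence") == "negative")[1]]]
  expect_gt(score_probe(decoy, "yes", 1000), 0L)
  expect_identical(score_probe(decoy, "no", 1000), 0L)
})

test_that("the 42-level loop wraps and the tutorial schedule matches", {
  expect_identical(next_level(0), 1L)
  expect_identical(next_level(41), 0L)
  expect_identical(next_level(3), 4L)
  expect_identical(wsap_level_schedule(0)$allotted_ms, 150000L)
  expect_identical(wsap_level_schedule(1)$allotted_ms, 150000L)
  expect_identical(wsap_level_schedule(2)$allotted_ms, 120000L)
  expect_identical(wsap_level_schedule(3)$allotted_ms, 120000L)
  expect_true(wsap_level_schedule(3)$words_jumbled_visible)
  expect_false(wsap_level_schedule(4)$words_jumbled_visible)
})
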
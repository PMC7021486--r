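test_that("the cluster layout partitions 100 neurons with the stated sizes", {
  layout <- make_layout()
  expect_equal(layout$n_neurons, 100L)
  sizes <- lengths(layout[c("context_a", "context_b", "tone", "shock",
                            "non_shock", "background")])
  expect_equal(unname(sizes), c(6L, 6L, 2L, 10L, 10L, 66L))
  all_idx <- unlist(layout[c("context_a", "context_b", "tone", "shock",
                             "non_shock", "background")], use.names = FALSE)
  expect_equal(sort(all_idx), 1:100)       # disjoint and exhaustive
  expect_length(intersect(layout$shock, layout$non_shock), 0)
})

test_that("the training pattern excites the fear memory and inhibits the rest", {
  layout <- make_layout()
  cue <- training_pattern(layout)
  expect_true(all(cue$I[layout$shock] == 5))
  expect_true(all(cue$I[c(layout$context_a, layout$tone)] == 5))
  expect_true(all(cue$I[layout$non_shock] == -5))
  expect_true(all(cue$I[layout$context_b] == -5))
  expect_equal(sum(cue$I == 5), 18)
})

test_that("reexposure patterns differ only in the shock / non-shock inputs", {
  layout <- make_layout()
  amps <- list(no_footshock = c(-5, 5),
               footshock = c(-2.31, 2.31),
               reconsolidation = c(3.80, -3.80))
  for (group in names(amps)) {
    cue <- reexposure_pattern(layout, group)
    expect_true(all(cue$I[c(layout$context_b, layout$tone)] == 5))
    expect_true(all(cue$I[c(layout$context_a,
                            layout$background)] == -5))
    expect_true(all(cue$I[layout$shock] == amps[[group]][1]))
    expect_true(all(cue$I[layout$non_shock] == amps[[group]][2]))
  }
  expect_error(reexposure_pattern(layout, "massed"), "arg")
})

test_that("retrieval cues drive context plus tone at 1.5 and nothing else", {
  layout <- make_layout()
  test_cue <- retrieval_cue(layout, "B")
  expect_equal(sum(test_cue$I != 0), 8)
  expect_true(all(test_cue$I[c(layout$context_b, layout$tone)] == 1.5))
  expect_true(all(test_cue$I[layout$shock] == 0))

  renewal <- retrieval_cue(layout, "A")
  expect_true(all(renewal$I[c(layout$context_a, layout$tone)] == 1.5))
  expect_true(all(renewal$I[layout$context_b] == 0))
})

test_that("the background memory shares no active neuron with task clusters", {
  layout <- make_layout()
  cue <- background_pattern(layout)
  active <- which(cue$I > 0)
  expect_length(active, 10)
  task <- unlist(layout[c("context_a", "context_b", "tone", "shock",
                          "non_shock")], use.names = FALSE)
  expect_length(intersect(active, task), 0)
  expect_true(all(cue$I[layout$context_a] == -5))
})

test_that("learning cues take only the protocol amplitudes, retrieval cues {0, 1.5}", {
  layout <- make_layout()
  learning <- c(training_pattern(layout)$I,
                background_pattern(layout)$I,
                reexposure_pattern(layout, "no_footshock")$I,
                reexposure_pattern(layout, "footshock")$I,
                reexposure_pattern(layout, "reconsolidation")$I)
  expect_true(all(learning %in% c(-5, -3.80, -2.31, 2.31, 3.80, 5)))
  retrieval <- c(retrieval_cue(layout, "A")$I, retrieval_cue(layout, "B")$I)
  expect_true(all(retrieval %in% c(0, 1.5)))
  # construction is deterministic given the layout
  expect_identical(reexposure_pattern(layout, "footshock"),
                   reexposure_pattern(layout, "footshock"))
})

test_that("weight noise is uniform on [-0.05, 0.05] and seed-reproducible", {
  W1 <- initial_weight_noise(100, seed = 5)
  W2 <- initial_weight_noise(100, seed = 5)
  expect_identical(W1, W2)
  expect_true(all(W1 >= -0.05 & W1 <= 0.05))
  # symmetric distribution: mean of 10^4 entries within 3 standard errors
  se <- (0.1 / sqrt(12)) / sqrt(length(W1))
  expect_lt(abs(mean(W1)), 3 * se)
})

test_that("activity noise lies in [0, 0.1] and fresh draws differ", {
  u1 <- initial_activity_noise(100, seed = 9)
  expect_true(all(u1 >= 0 & u1 <= 0.1))
  withr::with_seed(13, {
    a <- initial_activity_noise(100)
    b <- initial_activity_noise(100)
    expect_false(identical(a, b))
  })
})

test_that("patterns_table lays every cue against the cluster labels", {
  tbl <- patterns_table(make_layout())
  expect_s3_class(tbl, "tbl_df")
  expect_equal(nrow(tbl), 7 * 100)
  expect_setequal(unique(tbl$cluster),
                  c("context_a", "context_b", "tone", "shock", "non_shock",
                    "background"))
  fs <- tbl[tbl$pattern == "footshock_reexposure" & tbl$cluster == "shock", ]
  expect_true(all(fs$input == -2.31))
})
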
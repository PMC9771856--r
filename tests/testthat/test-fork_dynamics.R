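test_that("dna-mode fork positions follow the constant-genomic-speed closed form", {
  m <- default_model()
  # origin at the left edge of the first interband (100 kbp)
  tr <- fork_trajectory(m, 100, 0, "right", speed = 2)
  expect_equal(fork_position(tr, 1), 102)       # 2 kbp in 1 min
  expect_equal(fork_position(tr, 0), 100)       # no elapsed time, no move
  expect_error(fork_position(tr, -0.1), "activation")
  # activation offsets shift the whole trajectory
  tr2 <- fork_trajectory(m, 100, 5, "right", speed = 2)
  expect_equal(fork_position(tr2, 6), 102)
  # left fork mirrors
  trl <- fork_trajectory(m, 100, 0, "left", speed = 2)
  expect_equal(fork_position(trl, 10), 80)
  # clamped at the model end, stop_time = distance / speed
  expect_equal(trl$stop_time, 50)
  expect_equal(fork_position(trl, 120), 0)
  # full closed form on random cases
  set.seed(21)
  g0 <- runif(100, 0, 252); tt <- runif(100, 0, 80)
  got <- mapply(function(g, t)
    fork_position(fork_trajectory(m, g, 0, "right"), t), g0, tt)
  expect_equal(got, dna_fork_closed(m, g0, tt, +1), tolerance = 1e-12)
})

test_that("stated-mode axial speed is V in interbands with V/5, V/20, V/50 in bands", {
  m <- build_default_int(speed_mode = "stated")
  # half a minute inside an interband: 0.5 width units of axial travel
  tr <- fork_trajectory(m, 100, 0, "right", speed = 2)
  x0 <- genomic_to_axial(m, 100)
  expect_equal(genomic_to_axial(m, fork_position(tr, 0.5)) - x0, 0.5)
  # a gray band (unit width) takes 5 min at V/5; it follows the 1-min interband
  expect_equal(genomic_to_axial(m, fork_position(tr, 1 + 5)) - x0, 2)
  # middle gray: 20 min for its unit width
  expect_equal(genomic_to_axial(m, fork_position(tr, 1 + 5 + 1 + 5 + 1 + 20)),
               genomic_to_axial(m, m$g_breaks[8]))
  # black: 50 min per 50-kbp-per-width unit; the 2-width 100-kbp flank = 100 min
  trl <- fork_trajectory(m, 100, 0, "left", speed = 2)
  expect_equal(trl$stop_time, 100)
})

test_that("event-driven positions match the time-stepping oracle", {
  set.seed(77)
  for (mode in c("dna", "stated")) {
    m <- build_default_int(speed_mode = mode)
    n <- 250  # x2 modes = 500 cases
    g0 <- runif(n, 0, total_genomic(m))
    tt <- runif(n, 0, 30)
    dirs <- sample(c("left", "right"), n, replace = TRUE)
    for (d in c("left", "right")) {
      sel <- dirs == d
      # shared elapsed time per direction batch keeps the stepper vectorized
      e <- round(mean(tt[sel]), 2)
      closed <- vapply(g0[sel], function(g)
        fork_position(fork_trajectory(m, g, 0, d), e), numeric(1))
      stepped <- fork_position_stepped(m, g0[sel], e, d, dt = 1e-3)
      expect_lt(max(abs(closed - stepped)), 2e-3)
    }
  }
})

test_that("INT completion times follow the two-fork maximum formula", {
  m <- default_model()
  # origin at the INT genomic center, 26 kbp in: both forks need 13 min
  rec <- chromatid_records(m, 126, 0, speed = 2)
  expect_equal(rec$int_completion_min, 13)
  # worst case: origin at an INT edge -> 52/2 = 26 min
  expect_equal(chromatid_records(m, 100, 0, 2)$int_completion_min, 26)
  expect_equal(chromatid_records(m, 152, 0, 2)$int_completion_min, 26)
  # the 26-min bound is the exact maximum over any origin placement
  grid <- chromatid_records(m, seq(100, 152, by = 0.25), 0, 2)
  expect_equal(max(grid$int_completion_min), 26)
  expect_true(all(grid$int_completion_min >= 13))
})

test_that("simulate_replication is deterministic and bounded", {
  m <- default_model()
  a <- simulate_replication(m, initiation_scenario(60), 1024, 2, seed = 4)
  b <- simulate_replication(m, initiation_scenario(60), 1024, 2, seed = 4)
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_true(all(is.finite(a$int_completion_min)))
  # activation bound + worst-case traversal bound
  expect_true(all(a$int_completion_min <= 60 + 26))
  expect_identical(nrow(a), 1024L)
})

test_that("completion_time handles regions, degenerate intervals and errors", {
  m <- default_model()
  rec <- chromatid_records(m, 126, 3, speed = 2)
  expect_equal(completion_time(rec, c(126, 126)), 3)
  expect_equal(completion_time(rec, c(100, 152)), 3 + 13)
  # monotone: enlarging the region never decreases completion time
  widths <- seq(0, 26, by = 2)
  ct <- vapply(widths, function(w)
    completion_time(rec, c(126 - w, 126 + w)), numeric(1))
  expect_true(all(diff(ct) >= 0))
  expect_error(completion_time(rec, c(140, 152)), "does not contain")
})

test_that("pulse intervals cover exactly the DNA replicated in the window", {
  m <- default_model()
  rec <- chromatid_records(m, 126, 0, speed = 2)
  # pulse before activation is empty
  late <- chromatid_records(m, 126, 50, speed = 2)
  expect_equal(nrow(edu_pulse_intervals(late, 0, 10)), 0L)
  # synchronous pulse [0, 10]: two 20-kbp intervals flanking the origin
  iv <- edu_pulse_intervals(rec, 0, 10)
  expect_equal(nrow(iv), 2L)
  expect_equal(iv$end - iv$start, c(20, 20))
  expect_equal(sort(c(iv$start, iv$end)), c(106, 126, 126, 146))
  # additivity: a partition of [0, T] tiles the total replicated interval
  T <- 24; cuts <- c(0, 3, 7.5, 11, 18, T)
  pieces <- do.call(rbind, lapply(seq_len(length(cuts) - 1), function(i)
    edu_pulse_intervals(rec, cuts[i], cuts[i + 1] - cuts[i])))
  whole <- edu_pulse_intervals(rec, 0, T)
  for (f in c("left", "right")) {
    p <- pieces[pieces$fork == f, ]
    p <- p[order(p$start), ]
    expect_equal(p$start[-1], p$end[-nrow(p)])  # contiguous tiling
    w <- whole[whole$fork == f, ]
    expect_equal(c(min(p$start), max(p$end)), c(w$start, w$end))
  }
})

test_that("replicated length conservation holds in dna mode", {
  m <- default_model()
  set.seed(31)
  g0 <- runif(50, m$int_span[1], m$int_span[2])
  rec <- chromatid_records(m, g0, 0, speed = 2)
  for (t in c(1, 7, 19, 40, 90)) {
    iv <- do.call(rbind, lapply(seq_len(50), function(i)
      edu_pulse_intervals(rec, 0, t, which_row = i)))
    got <- sum(iv$end - iv$start)
    want <- sum(pmin(2 * t, g0) + pmin(2 * t, total_genomic(m) - g0))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("mirrored models yield mirrored trajectories", {
  for (mode in c("dna", "stated")) {
    m <- build_default_int(speed_mode = mode)
    mm <- mirror_model(m)
    G <- total_genomic(m)
    set.seed(13)
    g0 <- runif(30, 0, G); tt <- runif(30, 0, 40)
    right <- mapply(function(g, t)
      fork_position(fork_trajectory(m, g, 0, "right"), t), g0, tt)
    left_mirror <- mapply(function(g, t)
      fork_position(fork_trajectory(mm, G - g, 0, "left"), t), g0, tt)
    expect_equal(right, G - left_mirror, tolerance = 1e-9)
  }
})
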
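# Relative axial fork speeds per segment kind used in "stated" speed mode,
# in units of V (the interband axial speed).
STATED_REL_SPEED <- c(interband = 1, gray = 1 / 5, middle_gray = 1 / 20,
                      black = 1 / 50)

# Per-segment genomic fork speed (kbp/min).
#  dna mode:    constant speed_kbp_per_min everywhere; axial speed then
#               scales inversely with local compaction.
#  stated mode: axial speed is V in interbands and V/5, V/20, V/50 in gray,
#               middle-gray and black segments, with V defined relative to a
#               canonical 2-kbp unit-width interband (V = speed/2 width/min,
#               i.e. V = 1 interband/min at the default 2 kbp/min); the
#               genomic speed is the axial speed times the local density.
segment_genomic_speeds <- function(model, speed_kbp_per_min) {
  if (!is.numeric(speed_kbp_per_min) || speed_kbp_per_min <= 0)
    stop("fork speed must be > 0")
  if (model$speed_mode == "dna") {
    rep(speed_kbp_per_min, nrow(model$segments))
  } else {
    V <- speed_kbp_per_min / 2  # width units / min
    density <- model$segments$dna_kbp / model$segments$axial_width
    V * STATED_REL_SPEED[model$segments$kind] * density
  }
}

# Cumulative one-way traversal time (min) from the model's left end to each
# genomic break, at the model's per-segment speeds.  tg() is a strictly
# increasing piecewise-linear "time potential": the time for a fork to move
# from genomic a to b (a < b) is tg(b) - tg(a), in either direction.
traversal_schedule <- function(model, speed_kbp_per_min) {
  v <- unname(segment_genomic_speeds(model, speed_kbp_per_min))
  t_breaks <- c(0, cumsum(model$segments$dna_kbp / v))
  list(v = v, t_breaks = t_breaks,
       g_breaks = model$g_breaks, n = nrow(model$segments))
}

sched_tg <- function(sched, g) {
  i <- pmin(findInterval(g, sched$g_breaks), sched$n)
  sched$t_breaks[i] + (g - sched$g_breaks[i]) / sched$v[i]
}

sched_tg_inv <- function(sched, tt) {
  tt <- pmin(pmax(tt, 0), sched$t_breaks[sched$n + 1L])
  i <- pmin(findInterval(tt, sched$t_breaks), sched$n)
  sched$g_breaks[i] + (tt - sched$t_breaks[i]) * sched$v[i]
}

# Vectorized genomic fork positions at elapsed times e >= 0 (clamped at the
# model ends).  `dir` is +1 (right) or -1 (left).
fork_pos_elapsed <- function(sched, origin_g, e, dir) {
  sched_tg_inv(sched, sched_tg(sched, origin_g) + dir * e)
}

#' Build one fork trajectory
#'
#' Each fired origin emits two divergent forks.  A fork's motion is
#' event-driven: within a segment it moves at a constant genomic speed
#' (see `speed_mode` in [chromosome_model()]), and its segment-boundary
#' crossing times are computed in closed form.  The fork stops (and is no
#' longer rendered as a dot) when it reaches the outer end of the model.
#'
#' @param model a [chromosome_model()]
#' @param origin_kbp genomic origin position, kbp
#' @param activation_time activation time, minutes
#' @param direction `"left"` or `"right"`
#' @param speed fork speed in kbp/min (genomic units); default 2
#' @return an object of class `fork_trajectory` with elements
#'   `segment_exit_times` (absolute times at which the fork crosses each
#'   segment boundary ahead of it) and `stop_time`.
#' @export
fork_trajectory <- function(model, origin_kbp, activation_time = 0,
                            direction = c("right", "left"), speed = 2) {
  direction <- match.arg(direction)
  stopifnot(length(origin_kbp) == 1L, length(activation_time) == 1L)
  segment_index_genomic(model, origin_kbp)  # range check
  sched <- traversal_schedule(model, speed)
  t0 <- sched_tg(sched, origin_kbp)
  if (direction == "right") {
    ahead <- sched$t_breaks[sched$t_breaks > t0]
    exits <- activation_time + (ahead - t0)
  } else {
    ahead <- sched$t_breaks[sched$t_breaks < t0]
    exits <- activation_time + (t0 - rev(ahead))
  }
  structure(
    list(origin_kbp = origin_kbp, activation_time = activation_time,
         direction = direction, speed_kbp_per_min = speed,
         segment_exit_times = exits,
         stop_time = if (length(exits)) exits[length(exits)]
                     else activation_time,
         sched = sched),
    class = "fork_trajectory"
  )
}

#' Fork position at a time point
#'
#' Closed-form genomic position of a fork at absolute time `t`, clamped at
#' the model ends.  Errors if the fork does not yet exist (`t` before its
#' activation time).
#'
#' @param trajectory a [fork_trajectory()]
#' @param t absolute time(s), minutes
#' @return genomic position(s), kbp
#' @export
fork_position <- function(trajectory, t) {
  stopifnot(inherits(trajectory, "fork_trajectory"))
  if (any(t < trajectory$activation_time))
    stop("fork does not exist before its activation time (",
         trajectory$activation_time, " min)")
  dir <- if (trajectory$direction == "right") 1 else -1
  fork_pos_elapsed(trajectory$sched, trajectory$origin_kbp,
                   t - trajectory$activation_time, dir)
}

#' Brute-force time-stepping fork integrator
#'
#' Independent reference for [fork_position()]: advances the fork with an
#' explicit stepper of step `dt`, moving at the genomic speed of the
#' segment currently occupied and splitting a step at each segment boundary
#' so the boundary is honored exactly.  Vectorized over origins.
#'
#' @inheritParams fork_trajectory
#' @param elapsed time since activation, minutes (scalar)
#' @param dt step size, minutes
#' @return genomic position(s) after `elapsed` minutes, kbp
#' @export
fork_position_stepped <- function(model, origin_kbp, elapsed,
                                  direction = c("right", "left"),
                                  speed = 2, dt = 1e-3) {
  direction <- match.arg(direction)
  stopifnot(length(elapsed) == 1L, elapsed >= 0, dt > 0)
  segment_index_genomic(model, origin_kbp)
  dirs <- if (direction == "right") 1 else -1
  v_seg <- unname(segment_genomic_speeds(model, speed))
  gb <- model$g_breaks
  nseg <- nrow(model$segments)
  G <- total_genomic(model)
  x <- origin_kbp
  n_steps <- floor(elapsed / dt + 1e-9)
  rem_last <- elapsed - n_steps * dt
  step_once <- function(x, h) {
    # within one step, walk segment by segment so speed changes exactly at
    # the boundary rather than one step late
    remaining <- rep(h, length(x))
    repeat {
      live <- remaining > 0 &
        ((dirs > 0 & x < G) | (dirs < 0 & x > 0))
      if (!any(live)) break
      i <- pmin(findInterval(x, gb), nseg)
      # moving left from an exact boundary means we are in the segment on
      # the left of it
      if (dirs < 0) i <- ifelse(x == gb[i] & i > 1L, i - 1L, i)
      v <- v_seg[i]
      bound <- if (dirs > 0) gb[i + 1L] else gb[i]
      t_to_bound <- abs(bound - x) / v
      adv <- pmin(remaining, t_to_bound)
      x <- ifelse(live, x + dirs * v * adv, x)
      remaining <- ifelse(live, remaining - adv, 0)
      # clamp at model ends: fork stops there
      remaining[x <= 0 | x >= G] <- 0
      if (all(remaining <= 1e-15)) break
    }
    x
  }
  if (n_steps > 0) for (s in seq_len(n_steps)) x <- step_once(x, dt)
  if (rem_last > 1e-12) x <- step_once(x, rem_last)
  x
}

#' Simulate replication across all chromatids
#'
#' Samples one origin per chromatid (see [sample_origins()]) and resolves
#' both forks' dynamics in closed form.  Returns one record per chromatid
#' with the origin, activation time, the times each fork reaches the model
#' ends, and the time the whole INT finishes replicating on that chromatid
#' (the later of the two forks reaching the INT edges).
#'
#' @inheritParams sample_origins
#' @param speed fork speed, kbp/min
#' @return a data.frame of class `chromatid_records` with columns
#'   `chromatid_id`, `origin_kbp`, `activation_min`, `left_stop_min`,
#'   `right_stop_min`, `int_completion_min`; the model, scenario and speed
#'   are attached as attributes.
#' @export
simulate_replication <- function(model, scenario, n_chromatids = 1024,
                                 speed = 2, seed = 1L) {
  origins <- sample_origins(model, scenario, n_chromatids, seed)
  recs <- chromatid_records(model, origins$genomic_pos,
                            origins$activation_time, speed)
  recs$chromatid_id <- origins$chromatid_id
  attr(recs, "scenario") <- scenario
  recs
}

#' Closed-form chromatid records for given origins
#'
#' Lower-level companion of [simulate_replication()] that takes explicit
#' origin positions and activation times (any position in the model, not
#' only interbands), used for analytic checks and custom placements.
#'
#' @inheritParams simulate_replication
#' @param origin_kbp vector of genomic origin positions, kbp
#' @param activation_min vector (or scalar) of activation times, minutes
#' @return see [simulate_replication()]
#' @export
chromatid_records <- function(model, origin_kbp, activation_min = 0,
                              speed = 2) {
  segment_index_genomic(model, origin_kbp)  # range check
  n <- length(origin_kbp)
  a <- rep_len(activation_min, n)
  sched <- traversal_schedule(model, speed)
  t0 <- sched_tg(sched, origin_kbp)
  t_end <- sched$t_breaks[sched$n + 1L]
  t_int_l <- sched_tg(sched, model$int_span[1])
  t_int_r <- sched_tg(sched, model$int_span[2])
  recs <- data.frame(
    chromatid_id = seq_len(n) - 1L,
    origin_kbp = origin_kbp,
    activation_min = a,
    left_stop_min = a + t0,
    right_stop_min = a + (t_end - t0),
    int_completion_min = a + pmax(t0 - t_int_l, t_int_r - t0)
  )
  class(recs) <- c("chromatid_records", "data.frame")
  attr(recs, "model") <- model
  attr(recs, "speed") <- speed
  recs
}

records_model <- function(records) {
  m <- attr(records, "model")
  if (is.null(m)) stop("records carry no model attribute")
  m
}

records_speed <- function(records) {
  s <- attr(records, "speed")
  if (is.null(s)) stop("records carry no speed attribute")
  s
}

#' Completion time of a genomic region on one chromatid
#'
#' Earliest time at which the whole region `[region[1], region[2]]` is
#' replicated on the given chromatid.  With a single origin per chromatid
#' the region must contain the origin; a region strictly excluding it can
#' never be replicated from inside on this chromatid.
#'
#' @param record a one-row subset of [simulate_replication()] output (or
#'   the full object plus `which_row`)
#' @param region numeric length-2 genomic interval, kbp
#' @param which_row row index into `record`, default 1
#' @return completion time in minutes
#' @export
completion_time <- function(record, region, which_row = 1L) {
  model <- records_model(record)
  stopifnot(length(region) == 2L, region[1] <= region[2])
  segment_index_genomic(model, region)  # range check
  r <- record[which_row, ]
  if (r$origin_kbp < region[1] || r$origin_kbp > region[2])
    stop("region [", region[1], ", ", region[2], "] does not contain the ",
         "origin at ", r$origin_kbp, " kbp")
  sched <- traversal_schedule(model, records_speed(record))
  t0 <- sched_tg(sched, r$origin_kbp)
  r$activation_min + max(t0 - sched_tg(sched, region[1]),
                         sched_tg(sched, region[2]) - t0)
}

#' Genomic intervals replicated during a labeling pulse
#'
#' Models a nucleotide-analog (EdU-style) pulse: the genomic stretch each
#' fork synthesizes during `[t_start, t_start + duration]` on one
#' chromatid.  Returns up to two intervals (one per fork), which touch at
#' the origin when activation falls inside the pulse; an interval is empty
#' (dropped) when its fork was already stopped before the pulse or the
#' chromatid activates after it.
#'
#' @inheritParams completion_time
#' @param t_start pulse start, minutes
#' @param duration pulse length, minutes (> 0)
#' @return data.frame with columns `fork` (`"left"`/`"right"`), `start`,
#'   `end` (kbp); zero rows if nothing was synthesized.
#' @export
edu_pulse_intervals <- function(record, t_start, duration, which_row = 1L) {
  stopifnot(duration > 0, t_start >= 0)
  model <- records_model(record)
  r <- record[which_row, ]
  t1 <- max(t_start, r$activation_min)
  t2 <- t_start + duration
  if (t1 >= t2) {
    return(data.frame(fork = character(), start = numeric(),
                      end = numeric()))
  }
  sched <- traversal_schedule(model, records_speed(record))
  e1 <- t1 - r$activation_min
  e2 <- t2 - r$activation_min
  right <- c(fork_pos_elapsed(sched, r$origin_kbp, e1, 1),
             fork_pos_elapsed(sched, r$origin_kbp, e2, 1))
  left <- c(fork_pos_elapsed(sched, r$origin_kbp, e2, -1),
            fork_pos_elapsed(sched, r$origin_kbp, e1, -1))
  out <- data.frame(fork = c("left", "right"),
                    start = c(left[1], right[1]),
                    end = c(left[2], right[2]))
  out[out$end > out$start, , drop = FALSE]
}
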
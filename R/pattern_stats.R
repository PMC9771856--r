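#' Snapshot of active replication forks ("red dots")
#'
#' Evaluates every fork at time `t` and returns the dots a microscope-style
#' rendering would show: one dot per active fork, with genomic and axial
#' positions and the kind of segment currently occupied.  A fork is active
#' when its chromatid has fired (`activation <= t`) and it has not yet
#' reached the model end (`t < stop time`), so dot counts obey
#' `dots(t) = 2 * activated(t) - stopped(t)`.
#'
#' The figure-style snapshot time set is 4 s then 1, 5, 20, 30, 60 and 120
#' min; see [default_snapshot_times()].
#'
#' @param records output of [simulate_replication()]
#' @param t time, minutes (scalar)
#' @return a data.frame of class `replication_snapshot` with columns
#'   `chromatid_id`, `direction`, `genomic_pos`, `axial_pos`,
#'   `segment_kind`; attributes `time_min`, `n_chromatids`, `model`.
#' @export
snapshot <- function(records, t) {
  stopifnot(length(t) == 1L, t >= 0)
  model <- records_model(records)
  sched <- traversal_schedule(model, records_speed(records))
  parts <- lapply(c(right = 1, left = -1), function(dir) {
    stop_min <- if (dir > 0) records$right_stop_min else records$left_stop_min
    act <- records$activation_min <= t & t < stop_min
    if (!any(act)) return(NULL)
    g <- fork_pos_elapsed(sched, records$origin_kbp[act],
                          t - records$activation_min[act], dir)
    data.frame(chromatid_id = records$chromatid_id[act],
               direction = if (dir > 0) "right" else "left",
               genomic_pos = g)
  })
  dots <- do.call(rbind, parts)
  if (is.null(dots))
    dots <- data.frame(chromatid_id = integer(), direction = character(),
                       genomic_pos = numeric())
  dots$axial_pos <- genomic_to_axial(model, dots$genomic_pos)
  dots$segment_kind <- segment_kind_at(model, dots$genomic_pos)
  rownames(dots) <- NULL
  class(dots) <- c("replication_snapshot", "data.frame")
  attr(dots, "time_min") <- t
  attr(dots, "n_chromatids") <- nrow(records)
  attr(dots, "model") <- model
  dots
}

#' Canonical snapshot times (minutes)
#'
#' 4 seconds, then 1, 5, 20, 30, 60 and 120 minutes.
#' @return numeric vector of length 7
#' @export
default_snapshot_times <- function() c(4 / 60, 1, 5, 20, 30, 60, 120)

#' Axial dot-density profile
#'
#' Bins a snapshot's dots along the chromosome axis into fixed-width bins
#' spanning `[0, total_axial(model)]`; a dot exactly on a bin boundary goes
#' to the right-hand bin (the last bin is closed on the right).
#'
#' @param snap a [snapshot()]
#' @param bin_width bin width in axial width units (default 0.1)
#' @return an object of class `density_profile`: a list with `bin_edges`,
#'   `counts`, `time_min`, `n_chromatids`.
#' @export
density_profile <- function(snap, bin_width = 0.1) {
  stopifnot(inherits(snap, "replication_snapshot"), bin_width > 0)
  model <- attr(snap, "model")
  W <- total_axial(model)
  n_bins <- ceiling(W / bin_width - 1e-9)
  edges <- c(bin_width * seq_len(n_bins - 1L), W)
  edges <- c(0, edges)
  idx <- pmin(floor(snap$axial_pos / bin_width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(
    list(bin_edges = edges, counts = counts,
         time_min = attr(snap, "time_min"),
         n_chromatids = attr(snap, "n_chromatids")),
    class = "density_profile"
  )
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> t = %g min, %d bins, %d dots\n",
              x$time_min, length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Edge-concentration index
#'
#' Fraction of snapshot dots that sit inside the flanking black rb-bands
#' within `margin_kbp` (genomic) of the black/INT boundary — the
#' operational reading of replication signals "concentrating at the edges
#' of the condensed bands".  Returns 0 for an empty snapshot.
#'
#' The default margin of 30 kbp covers the first 15 minutes of black-band
#' transit at 2 kbp/min; it must exceed the typical transit depth at the
#' observation time, or forks have already passed the margin and the index
#' collapses to zero (which is exactly what happens at late times — the
#' index is unimodal in time).
#'
#' @param snap a [snapshot()]
#' @param margin_kbp genomic margin, kbp (default 30)
#' @return a fraction in `[0, 1]`
#' @export
edge_concentration_index <- function(snap, margin_kbp = 30) {
  stopifnot(inherits(snap, "replication_snapshot"), margin_kbp >= 0)
  if (nrow(snap) == 0L) return(0)
  model <- attr(snap, "model")
  left_edge <- model$int_span[1]   # right edge of the left black band
  right_edge <- model$int_span[2]  # left edge of the right black band
  g <- snap$genomic_pos
  in_left <- g < left_edge & g >= left_edge - margin_kbp
  in_right <- g >= right_edge & g <= right_edge + margin_kbp
  mean(in_left | in_right)
}

#' Fraction of chromatids that have initiated replication by time t
#'
#' @param records output of [simulate_replication()]
#' @param t time, minutes
#' @return fraction in `[0, 1]`
#' @export
fraction_initiated <- function(records, t) {
  stopifnot(t >= 0)
  mean(records$activation_min <= t)
}

# Per-capacity normalization: counts / (2 * n_chromatids), i.e. dots per
# fork slot.  The chromatid count cancels between observed and reference
# patterns, but — unlike dividing by the dot total — the fraction of
# chromatids already fired is retained.  That fraction is the only signal
# separating activation windows longer than the last snapshot time
# (conditional on firing, fork ages are identically distributed under any
# uniform window that has not closed yet), so sum-normalization would make
# e.g. 30- and 60-min windows indistinguishable at snapshots up to 30 min.
normalize_profile <- function(profile) {
  n <- profile$n_chromatids
  if (is.null(n) || !is.finite(n) || n < 1)
    stop("profile lacks a usable n_chromatids for normalization")
  profile$counts / (2 * n)
}

#' Classify which initiation scenario generated an observed pattern
#'
#' For each candidate scenario, simulates `n_reference_sims` replicate
#' fragments, averages their normalized axial density profiles per time
#' point, and scores the observed pattern by the Euclidean distance between
#' observed and reference normalized profiles, summed over time points.
#' The candidate with the smallest summed distance wins.  Deterministic
#' given `seed`.
#'
#' @param observed an `observed_pattern` (see [make_labeled_dataset()]), or
#'   any list with elements `time_points` and `profiles` (a list of
#'   [density_profile()]s sharing bin edges)
#' @param candidates named list of [initiation_scenario()]s (>= 2)
#' @param model a [chromosome_model()]
#' @param n_reference_sims reference replicates per candidate (default 5)
#' @param seed integer master seed for the reference simulations
#' @param n_chromatids,speed simulation parameters for the references
#' @return a list with `best` (name of the winning candidate) and
#'   `distances` (named numeric vector, one per candidate)
#' @export
classify_scenario <- function(observed, candidates, model,
                              n_reference_sims = 5, seed = 1L,
                              n_chromatids = 1024, speed = 2) {
  if (length(candidates) < 2L) stop("need at least 2 candidate scenarios")
  if (is.null(names(candidates)) || any(names(candidates) == ""))
    names(candidates) <- paste0("scenario", seq_along(candidates))
  times <- observed$time_points
  profs <- observed$profiles
  if (length(profs) != length(times))
    stop("observed pattern must have one profile per time point")
  edges <- profs[[1]]$bin_edges
  for (p in profs) {
    if (length(p$bin_edges) != length(edges) ||
        max(abs(p$bin_edges - edges)) > 1e-9)
      stop("observed profiles do not share bin edges")
  }
  bin_width <- edges[2] - edges[1]
  obs_mat <- vapply(profs, normalize_profile, numeric(length(edges) - 1L))

  ref_seeds <- with_seed(seed,
    matrix(sample.int(.Machine$integer.max, length(candidates) *
                        n_reference_sims),
           nrow = length(candidates)))
  distances <- vapply(seq_along(candidates), function(ci) {
    ref_acc <- matrix(0, nrow(obs_mat), ncol(obs_mat))
    for (r in seq_len(n_reference_sims)) {
      recs <- simulate_replication(model, candidates[[ci]], n_chromatids,
                                   speed, seed = ref_seeds[ci, r])
      for (ti in seq_along(times)) {
        pr <- density_profile(snapshot(recs, times[ti]), bin_width)
        if (length(pr$counts) != nrow(obs_mat))
          stop("bin mismatch between observed and reference profiles")
        ref_acc[, ti] <- ref_acc[, ti] + normalize_profile(pr)
      }
    }
    ref_mean <- ref_acc / n_reference_sims
    sum(sqrt(colSums((obs_mat - ref_mean)^2)))
  }, numeric(1))
  names(distances) <- names(candidates)
  list(best = names(candidates)[which.min(distances)],
       distances = distances)
}
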
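#' Microscope-level noise model
#'
#' Emulates the two dominant degradations between simulated fork positions
#' and a super-resolution dot readout: incomplete detection (each dot is
#' seen with probability `p_detect`) and axial localization jitter
#' (Gaussian error on the axial coordinate — where the optical error
#' physically arises — clamped to the chromosome extent).
#'
#' @param p_detect per-dot detection probability in `(0, 1]` (default 0.8)
#' @param jitter_sd_axial localization error SD in axial width units
#'   (default 0.05)
#' @param seed optional integer; when set, [degrade()] is reproducible on
#'   its own, otherwise it consumes the caller's RNG stream
#' @return an object of class `noise_model`
#' @export
noise_model <- function(p_detect = 0.8, jitter_sd_axial = 0.05,
                        seed = NULL) {
  if (!is.numeric(p_detect) || p_detect <= 0 || p_detect > 1)
    stop("p_detect must be in (0, 1]")
  if (!is.numeric(jitter_sd_axial) || jitter_sd_axial < 0)
    stop("jitter_sd_axial must be >= 0")
  structure(list(p_detect = p_detect, jitter_sd_axial = jitter_sd_axial,
                 seed = seed),
            class = "noise_model")
}

#' Degrade a snapshot into a synthetic observation
#'
#' Applies the noise model dot-wise: each dot survives with probability
#' `p_detect`; surviving dots get Gaussian axial jitter, are clamped to
#' `[0, total_axial(model)]`, and their genomic position and segment kind
#' are recomputed from the perturbed axial position.  With `p_detect = 1`
#' and zero jitter this is the identity.
#'
#' @param snap a [snapshot()]
#' @param noise a [noise_model()]
#' @return a `replication_snapshot` (same attributes as the input)
#' @export
degrade <- function(snap, noise) {
  stopifnot(inherits(snap, "replication_snapshot"),
            inherits(noise, "noise_model"))
  run <- function() {
    keep <- if (noise$p_detect >= 1) rep(TRUE, nrow(snap))
            else stats::runif(nrow(snap)) < noise$p_detect
    out <- snap[keep, , drop = FALSE]
    if (noise$jitter_sd_axial > 0 && nrow(out) > 0) {
      model <- attr(snap, "model")
      x <- out$axial_pos + stats::rnorm(nrow(out), 0, noise$jitter_sd_axial)
      x <- pmin(pmax(x, 0), total_axial(model))
      out$axial_pos <- x
      out$genomic_pos <- axial_to_genomic(model, x)
      out$segment_kind <- segment_kind_at(model, out$genomic_pos)
    }
    rownames(out) <- NULL
    class(out) <- class(snap)
    attr(out, "time_min") <- attr(snap, "time_min")
    attr(out, "n_chromatids") <- attr(snap, "n_chromatids")
    attr(out, "model") <- attr(snap, "model")
    out
  }
  if (is.null(noise$seed)) run() else with_seed(noise$seed, run())
}

#' Generate a labeled dataset of synthetic observed patterns
#'
#' For each scenario, simulates `n_patterns_per_scenario` independent
#' fragments, snapshots them at `times`, degrades each snapshot with the
#' noise model, and bins the result into axial density profiles.  The
#' generating scenario name is recorded as `provenance` (for recovery
#' experiments only — the classifier never sees it).
#'
#' @inheritParams classify_scenario
#' @param scenarios named list of [initiation_scenario()]s
#' @param n_patterns_per_scenario patterns per scenario
#' @param noise a [noise_model()]; its own `seed` field is ignored here
#'   (per-pattern sub-seeds come from `seed`)
#' @param times snapshot times used for the profiles, minutes; the default
#'   `c(1, 5, 20, 30)` covers the window where the regimes differ most
#' @param bin_width axial bin width
#' @return a list of `observed_pattern` objects, each a list with
#'   `time_points`, `profiles` and `provenance`
#' @export
make_labeled_dataset <- function(model, scenarios, n_patterns_per_scenario,
                                 noise = noise_model(), seed = 1L,
                                 times = c(1, 5, 20, 30), bin_width = 0.1,
                                 n_chromatids = 1024, speed = 2) {
  if (length(scenarios) < 1L) stop("need at least one scenario")
  if (is.null(names(scenarios)) || any(names(scenarios) == ""))
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  total <- length(scenarios) * n_patterns_per_scenario
  seeds <- with_seed(seed,
    matrix(sample.int(.Machine$integer.max, 2L * total), ncol = 2L))
  out <- vector("list", total)
  k <- 0L
  for (sc in names(scenarios)) {
    for (r in seq_len(n_patterns_per_scenario)) {
      k <- k + 1L
      recs <- simulate_replication(model, scenarios[[sc]], n_chromatids,
                                   speed, seed = seeds[k, 1L])
      nm <- noise_model(noise$p_detect, noise$jitter_sd_axial,
                        seed = seeds[k, 2L])
      profs <- lapply(times, function(t)
        density_profile(degrade(snapshot(recs, t), nm), bin_width))
      out[[k]] <- structure(
        list(time_points = times, profiles = profs, provenance = sc),
        class = "observed_pattern")
    }
  }
  out
}
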
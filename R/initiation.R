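# Evaluate an expression with a temporarily seeded RNG, restoring the
# caller's RNG state afterwards, so seeded API calls do not perturb user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Define an origin-initiation scenario
#'
#' Each chromatid fires exactly one origin.  The temporal law is either
#' synchronous (all origins fire at t = 0) or a uniform activation window:
#' activation times i.i.d. uniform on `[0, window_min]` minutes.  The
#' spatial law is either `dispersed` (the origin position is uniform over
#' the pooled interband DNA of the INT, so each interband is hit in
#' proportion to its DNA content) or `fixed_locus` (every chromatid fires
#' at the same genomic position, emulating one very efficient origin).
#'
#' @param window_min activation window in minutes; `0` means synchronous.
#'   The four canonical regimes use 0, 10, 30 and 60 min.
#' @param spatial `"dispersed"` or `"fixed_locus"`
#' @param locus_kbp genomic position (kbp, model coordinates) of the fixed
#'   locus; required (and must lie inside an interband) when
#'   `spatial = "fixed_locus"`.
#' @return an object of class `initiation_scenario`
#' @export
initiation_scenario <- function(window_min = 0,
                                spatial = c("dispersed", "fixed_locus"),
                                locus_kbp = NULL) {
  spatial <- match.arg(spatial)
  if (!is.numeric(window_min) || length(window_min) != 1L ||
      !is.finite(window_min) || window_min < 0)
    stop("window_min must be a single number >= 0")
  if (spatial == "fixed_locus" && is.null(locus_kbp))
    stop("fixed_locus scenarios need locus_kbp")
  structure(
    list(
      temporal_mode = if (window_min == 0) "synchronous" else "uniform_window",
      window_min = window_min,
      spatial_mode = spatial,
      locus_kbp = locus_kbp
    ),
    class = "initiation_scenario"
  )
}

#' @export
print.initiation_scenario <- function(x, ...) {
  cat(sprintf("<initiation_scenario> %s (window %g min), %s%s\n",
              x$temporal_mode, x$window_min, x$spatial_mode,
              if (x$spatial_mode == "fixed_locus")
                sprintf(" @ %g kbp", x$locus_kbp) else ""))
  invisible(x)
}

#' The four canonical temporal regimes
#'
#' Synchronous firing plus uniform activation windows of 10, 30 and 60
#' minutes, all with dispersed origin placement.
#' @return a named list of [initiation_scenario()] objects
#' @export
default_scenarios <- function() {
  list(sync   = initiation_scenario(0),
       win10  = initiation_scenario(10),
       win30  = initiation_scenario(30),
       win60  = initiation_scenario(60))
}

# interband segments of the INT (all interbands; blacks are flanks by
# construction and interbands cannot be black)
interband_rows <- function(model) which(model$segments$kind == "interband")

#' Sample per-chromatid origin events
#'
#' Draws one origin event per chromatid: a genomic position and an
#' activation time, following the scenario's spatial and temporal laws.
#' In dispersed mode the position is uniform over the concatenated
#' interband DNA, i.e. each interband is selected with probability
#' proportional to its DNA content and the position is uniform within it.
#' All draws come from a single seeded stream in chromatid order, so the
#' result is reproducible and independent of any parallel evaluation.
#'
#' @param model a [chromosome_model()]
#' @param scenario an [initiation_scenario()]
#' @param n_chromatids number of chromatids (DNA strands); the canonical
#'   polytene value is 1024.
#' @param seed integer master seed
#' @return a data.frame of class `origin_events` with columns
#'   `chromatid_id` (0-based), `genomic_pos` (kbp) and `activation_time`
#'   (min).
#' @export
sample_origins <- function(model, scenario, n_chromatids = 1024, seed = 1L) {
  stopifnot(inherits(model, "chromosome_model"),
            inherits(scenario, "initiation_scenario"))
  if (!is.numeric(n_chromatids) || n_chromatids < 1)
    stop("n_chromatids must be >= 1")
  n <- as.integer(n_chromatids)

  if (scenario$spatial_mode == "fixed_locus") {
    if (segment_kind_at(model, scenario$locus_kbp) != "interband")
      stop("fixed_locus position ", scenario$locus_kbp,
           " kbp is not inside an interband")
  }

  res <- with_seed(seed, {
    pos <- if (scenario$spatial_mode == "fixed_locus") {
      rep(scenario$locus_kbp, n)
    } else {
      ib <- interband_rows(model)
      lens <- model$segments$dna_kbp[ib]
      starts <- model$g_breaks[ib]
      # uniform over pooled interband DNA: one draw per chromatid on the
      # concatenated length, then unfolded onto the owning interband
      u <- stats::runif(n, 0, sum(lens))
      cum <- c(0, cumsum(lens))
      k <- findInterval(u, cum, rightmost.closed = TRUE)
      k <- pmin(k, length(lens))
      starts[k] + (u - cum[k])
    }
    act <- if (scenario$temporal_mode == "synchronous") rep(0, n)
           else stats::runif(n, 0, scenario$window_min)
    data.frame(chromatid_id = seq_len(n) - 1L,
               genomic_pos = pos,
               activation_time = act)
  })
  class(res) <- c("origin_events", "data.frame")
  res
}
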
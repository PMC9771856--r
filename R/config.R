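# All times are minutes (enter 4 s as 0.0667), all genomic lengths kbp,
# all axial quantities in width units: one unit system everywhere.

run_config_defaults <- function() {
  list(
    model = "builtin",          # "builtin" or a segment-table path
    black_flank_kbp = 100,
    speed_mode = "dna",
    window_min = 0,
    spatial = "dispersed",
    locus_kbp = NA_real_,
    n_chromatids = 1024,
    speed = 2,
    snapshot_times = default_snapshot_times(),
    bin_width = 0.1,
    p_detect = 0.8,
    jitter_sd = 0.05,
    seed = 1
  )
}

#' Build a run configuration
#'
#' A flat, fully explicit description of one simulation run.  Defaults
#' reproduce the canonical setup: the built-in 52-kbp INT, synchronous
#' initiation, 1024 chromatids, 2 kbp/min forks, snapshots at 4 s and 1,
#' 5, 20, 30, 60, 120 min.  Configurations round-trip losslessly through
#' their file form ([write_run_config()] / [read_run_config()]), a flat
#' `key: value` text format (a YAML-compatible subset).
#'
#' @param ... overrides of the default fields (see
#'   `polyrepsim:::run_config_defaults()`)
#' @return an object of class `run_config`
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (!cfg$speed_mode %in% c("dna", "stated"))
    stop("speed_mode must be 'dna' or 'stated'")
  if (!cfg$spatial %in% c("dispersed", "fixed_locus"))
    stop("spatial must be 'dispersed' or 'fixed_locus'")
  if (cfg$spatial == "fixed_locus" && is.na(cfg$locus_kbp))
    stop("fixed_locus runs need locus_kbp")
  if (cfg$n_chromatids < 1) stop("n_chromatids must be >= 1")
  if (cfg$speed <= 0) stop("speed must be > 0")
  if (cfg$bin_width <= 0) stop("bin_width must be > 0")
  if (cfg$window_min < 0) stop("window_min must be >= 0")
  if (any(cfg$snapshot_times < 0)) stop("snapshot_times must be >= 0")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`
#' @param path file path
#' @export
write_run_config <- function(cfg, path) {
  fmt <- function(v) {
    if (is.character(v)) v
    else paste(vapply(v, function(x) {
      if (is.na(x)) "NA" else format(x, digits = 17, scientific = FALSE)
    }, character(1)), collapse = ", ")
  }
  lines <- vapply(names(cfg), function(k) paste0(k, ": ", fmt(cfg[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  defaults <- run_config_defaults()
  cfg <- defaults
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([A-Za-z_]+):\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3L)
      stop(path, " line ", i, ": expected 'key: value', got ",
           sQuote(lines[i]))
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(defaults))
      stop(path, " line ", i, ": unknown config key ", sQuote(key))
    cfg[[key]] <- if (is.character(defaults[[key]])) val
                  else {
                    parts <- trimws(strsplit(val, ",")[[1]])
                    nums <- suppressWarnings(as.numeric(parts))
                    if (any(is.na(nums) & parts != "NA"))
                      stop(path, " line ", i, ": non-numeric value ",
                           sQuote(val), " for key ", sQuote(key))
                    nums
                  }
  }
  validate_run_config(cfg)
}

config_model <- function(cfg) {
  if (identical(cfg$model, "builtin"))
    build_default_int(cfg$black_flank_kbp, cfg$speed_mode)
  else read_model(cfg$model, cfg$speed_mode)
}

config_scenario <- function(cfg) {
  initiation_scenario(cfg$window_min, cfg$spatial,
                      if (is.na(cfg$locus_kbp)) NULL else cfg$locus_kbp)
}
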
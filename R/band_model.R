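SEGMENT_KINDS <- c("interband", "gray", "middle_gray", "black")

#' Construct a band/interband chromosome-fragment model
#'
#' A chromosome fragment is an ordered run of chromatin segments, each with a
#' DNA content (kbp) and an axial width (abstract width units along the
#' chromosome axis).  The ratio `dna_kbp / axial_width` is the local DNA
#' compaction density.  Genomic and axial coordinates are both 0-based with
#' half-open segment intervals `[start, end)`: a point exactly on a boundary
#' belongs to the right-hand segment.
#'
#' The first and last segments must be `black` (the flanking ruby-chromatin
#' rb-bands); all segments in between form the INT, the early replication
#' initiation zone.  Interior segments may not be `black`.
#'
#' @param segments data.frame with columns `name`, `kind` (one of
#'   `"interband"`, `"gray"`, `"middle_gray"`, `"black"`), `dna_kbp` (> 0)
#'   and `axial_width` (> 0).
#' @param speed_mode `"dna"` (forks move at constant genomic speed) or
#'   `"stated"` (forks move at a fixed axial speed per segment kind); see
#'   [fork_trajectory()].
#' @return An object of class `chromosome_model`.
#' @seealso [build_default_int()], [genomic_to_axial()], [read_model()]
#' @export
chromosome_model <- function(segments, speed_mode = c("dna", "stated")) {
  speed_mode <- match.arg(speed_mode)
  req <- c("name", "kind", "dna_kbp", "axial_width")
  if (!is.data.frame(segments) || !all(req %in% names(segments)))
    stop("`segments` must be a data.frame with columns ",
         paste(req, collapse = ", "))
  segments <- as.data.frame(segments)[, req]
  segments$name <- as.character(segments$name)
  segments$kind <- as.character(segments$kind)
  n <- nrow(segments)
  if (n < 3L) stop("a model needs at least 3 segments (black, ..., black)")
  bad <- which(!segments$kind %in% SEGMENT_KINDS)
  if (length(bad))
    stop("unknown segment kind ", sQuote(segments$kind[bad[1]]),
         " in segment ", bad[1])
  if (any(!is.finite(segments$dna_kbp) | segments$dna_kbp <= 0))
    stop("all dna_kbp must be finite and > 0")
  if (any(!is.finite(segments$axial_width) | segments$axial_width <= 0))
    stop("all axial_width must be finite and > 0")
  if (segments$kind[1] != "black" || segments$kind[n] != "black")
    stop("first and last segments must be 'black' (flanking rb-bands)")
  if (any(segments$kind[-c(1L, n)] == "black"))
    stop("interior 'black' segments are not supported: the INT is the run ",
         "of non-black segments between the two flanking rb-bands")

  g_breaks <- c(0, cumsum(segments$dna_kbp))
  x_breaks <- c(0, cumsum(segments$axial_width))
  structure(
    list(
      segments = segments,
      g_breaks = g_breaks,
      x_breaks = x_breaks,
      # INT = everything strictly between the flanking black bands
      int_span = c(g_breaks[2L], g_breaks[n]),
      speed_mode = speed_mode
    ),
    class = "chromosome_model"
  )
}

#' @export
print.chromosome_model <- function(x, ...) {
  cat(sprintf(
    "<chromosome_model> %d segments, %.6g kbp / %.6g width units, INT %.6g kbp, speed_mode=%s\n",
    nrow(x$segments), total_genomic(x), total_axial(x),
    diff(x$int_span), x$speed_mode))
  print(x$segments, ...)
  invisible(x)
}

#' @export
format.chromosome_model <- function(x, ...) {
  sprintf("<chromosome_model: %d segments, %g kbp>",
          nrow(x$segments), total_genomic(x))
}

#' Total genomic length (kbp) and total axial width of a model
#' @param model a [chromosome_model()]
#' @return a scalar
#' @export
total_genomic <- function(model) model$g_breaks[length(model$g_breaks)]

#' @rdname total_genomic
#' @export
total_axial <- function(model) model$x_breaks[length(model$x_breaks)]

#' Built-in 52-kbp INT model
#'
#' The default fragment is a 52-kbp initiation zone (INT) flanked by two
#' black rb-bands: the segment run
#' black, I, G, I, G, I, MG, I, G, I, G, I, black, where each interband (I)
#' carries 2 kbp, each gray band (G) 5 kbp and the middle gray band (MG)
#' 20 kbp, so the INT totals 6 x 2 + 4 x 5 + 20 = 52 kbp.  All INT segments
#' are drawn with equal axial width 1; the black flanks get width
#' `dna / 50` (a 50 kbp-per-width compaction, consistent with the 1/50
#' relative axial fork speed used in `"stated"` mode).
#'
#' @param black_flank_kbp DNA content of each flanking black band, kbp.
#'   Intercalary-heterochromatin bands range up to >200 kbp; the default
#'   100 kbp keeps late snapshots informative.
#' @param speed_mode passed to [chromosome_model()].
#' @return a `chromosome_model` with 13 segments.
#' @examples
#' m <- build_default_int()
#' diff(m$int_span)  # 52
#' @export
build_default_int <- function(black_flank_kbp = 100,
                              speed_mode = c("dna", "stated")) {
  speed_mode <- match.arg(speed_mode)
  if (!is.numeric(black_flank_kbp) || length(black_flank_kbp) != 1L ||
      !is.finite(black_flank_kbp) || black_flank_kbp <= 0)
    stop("black_flank_kbp must be a single positive number")
  int_kinds <- c("interband", "gray", "interband", "gray", "interband",
                 "middle_gray",
                 "interband", "gray", "interband", "gray", "interband")
  int_dna <- c(2, 5, 2, 5, 2, 20, 2, 5, 2, 5, 2)
  segs <- data.frame(
    name = c("black_L",
             paste0(ifelse(int_kinds == "interband", "I", "G"),
                    seq_along(int_kinds)),
             "black_R"),
    kind = c("black", int_kinds, "black"),
    dna_kbp = c(black_flank_kbp, int_dna, black_flank_kbp),
    axial_width = c(black_flank_kbp / 50, rep(1, 11L), black_flank_kbp / 50),
    stringsAsFactors = FALSE
  )
  chromosome_model(segs, speed_mode)
}

# segment index containing each genomic position (half-open intervals;
# the total length itself belongs to the last segment)
segment_index_genomic <- function(model, g) {
  G <- total_genomic(model)
  if (any(!is.finite(g) | g < 0 | g > G))
    stop("genomic position out of range [0, ", G, "]")
  pmin(findInterval(g, model$g_breaks), nrow(model$segments))
}

segment_index_axial <- function(model, x) {
  W <- total_axial(model)
  if (any(!is.finite(x) | x < 0 | x > W))
    stop("axial position out of range [0, ", W, "]")
  pmin(findInterval(x, model$x_breaks), nrow(model$segments))
}

#' Map between genomic (kbp) and axial (width-unit) coordinates
#'
#' The map is piecewise linear: within each segment the axial position
#' interpolates proportionally to the genomic offset, so it is continuous,
#' strictly increasing, and exactly invertible.  This realizes the drawing
#' convention in which bands of very different DNA content occupy comparable
#' axial extents on the chromosome.
#'
#' @param model a [chromosome_model()]
#' @param g genomic position(s), kbp, in `[0, total_genomic(model)]`
#' @param x axial position(s), width units, in `[0, total_axial(model)]`
#' @return numeric vector of mapped coordinates
#' @export
genomic_to_axial <- function(model, g) {
  i <- segment_index_genomic(model, g)
  frac <- (g - model$g_breaks[i]) / model$segments$dna_kbp[i]
  model$x_breaks[i] + frac * model$segments$axial_width[i]
}

#' @rdname genomic_to_axial
#' @export
axial_to_genomic <- function(model, x) {
  i <- segment_index_axial(model, x)
  frac <- (x - model$x_breaks[i]) / model$segments$axial_width[i]
  model$g_breaks[i] + frac * model$segments$dna_kbp[i]
}

#' Segment kind at genomic positions
#' @inheritParams genomic_to_axial
#' @return character vector of segment kinds
#' @export
segment_kind_at <- function(model, g) {
  model$segments$kind[segment_index_genomic(model, g)]
}

#' Mirror a model end-to-end
#'
#' Reverses the segment order.  For any genomic position `g`,
#' `genomic_to_axial(model, g) + genomic_to_axial(mirror_model(model),
#' total_genomic(model) - g)` equals the total axial width.
#' @inheritParams genomic_to_axial
#' @return a `chromosome_model`
#' @export
mirror_model <- function(model) {
  chromosome_model(model$segments[rev(seq_len(nrow(model$segments))), ],
                   model$speed_mode)
}

#' Read / write a segment table
#'
#' The on-disk form is a BED-like tab-separated table with a header and the
#' columns `name`, `kind`, `dna_kbp`, `axial_width`.  Genomic and axial
#' breaks are derived on read, never stored.  `read_model(write_model(m))`
#' is the identity; malformed rows are rejected with line-numbered errors.
#'
#' @param path file path
#' @param speed_mode stored on the model (not serialized in the table)
#' @param model a [chromosome_model()]
#' @return `read_model`: a `chromosome_model`; `write_model`: `path`,
#'   invisibly.
#' @export
read_model <- function(path, speed_mode = c("dna", "stated")) {
  speed_mode <- match.arg(speed_mode)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("name", "kind", "dna_kbp", "axial_width")
  if (!all(req %in% names(tab)))
    stop("segment table ", path, " must have header columns ",
         paste(req, collapse = ", "))
  # data line i is physical line i + 1 (header)
  line_of <- function(i) i + 1L
  for (i in seq_len(nrow(tab))) {
    if (!tab$kind[i] %in% SEGMENT_KINDS)
      stop(path, " line ", line_of(i), ": unknown kind ", sQuote(tab$kind[i]))
    if (!is.numeric(tab$dna_kbp[i]) || !is.finite(tab$dna_kbp[i]) ||
        tab$dna_kbp[i] <= 0)
      stop(path, " line ", line_of(i), ": dna_kbp must be > 0, got ",
           tab$dna_kbp[i])
    if (!is.numeric(tab$axial_width[i]) || !is.finite(tab$axial_width[i]) ||
        tab$axial_width[i] <= 0)
      stop(path, " line ", line_of(i), ": axial_width must be > 0, got ",
           tab$axial_width[i])
  }
  chromosome_model(tab, speed_mode)
}

#' @rdname read_model
#' @export
write_model <- function(model, path) {
  utils::write.table(model$segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
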
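#' Average the two segments of each named wall
#'
#' The six-segment short-axis division is reduced to a free-wall and a
#' septal trace by pointwise averaging of the two segments mapped to each
#' wall; the two intermediate segments are discarded.
#'
#' @param curves A `strain_curves` set (see [synth_strain()] or
#'   [read_strain()]).
#' @return A list of class `wall_traces`: `time_ms`, `walls` (samples x 2
#'   matrix with columns `freewall`, `septum`), `ref_time_ms`, `fs_hz`.
#' @export
wall_average <- function(curves) {
  stopifnot(inherits(curves, "strain_curves"))
  seg <- curves$segments
  walls <- matrix(NA_real_, nrow(curves$strain), 2L,
                  dimnames = list(NULL, c("freewall", "septum")))
  for (w in c("freewall", "septum")) {
    idx <- which(seg$wall == w)
    if (length(idx) != 2L)
      stop(sprintf("wall '%s' must map exactly two segments (found %d)",
                   w, length(idx)), call. = FALSE)
    if (any(!is.finite(curves$strain[, idx])))
      stop(sprintf("missing samples in segments of wall '%s'", w),
           call. = FALSE)
    walls[, w] <- rowMeans(curves$strain[, idx, drop = FALSE])
  }
  structure(list(time_ms = curves$time_ms, walls = walls,
                 ref_time_ms = curves$ref_time_ms, fs_hz = curves$fs_hz),
            class = "wall_traces")
}

#' Radial-strain features of one wall trace
#'
#' Peak strain (PS) is the trace maximum (sub-sample refined by quadratic
#' interpolation on smooth peaks; discrete ties resolve to the earliest
#' time); time-to-peak (TTP) is the peak time minus the reference time;
#' onset is the first crossing of 10% of PS that is sustained for at least
#' 20 ms (interpolated between samples), a fractional threshold that is
#' invariant to amplitude scaling.
#'
#' @param trace Numeric strain trace (percent) or a `wall_traces` object
#'   with `wall` naming the column.
#' @param time_ms Sample times (ms); taken from the object when given one.
#' @param ref_time_ms Reference time (QRS-onset equivalent).
#' @param wall Column to use when `trace` is a `wall_traces` object.
#' @param sustain_ms Minimum time above threshold for the onset crossing.
#' @return A list: `ps_pct`, `onset_ms`, `ttp_ms`, `valid` (FALSE with NA
#'   features when the trace has non-positive peak strain).
#' @export
strain_features <- function(trace, time_ms = NULL, ref_time_ms = 0,
                            wall = NULL, sustain_ms = 20) {
  if (inherits(trace, "wall_traces")) {
    time_ms <- trace$time_ms
    ref_time_ms <- trace$ref_time_ms
    trace <- trace$walls[, wall]
  }
  if (is.null(time_ms)) stop("`time_ms` is required", call. = FALSE)
  y <- as.numeric(trace)
  ps_raw <- max(y)
  if (!is.finite(ps_raw) || ps_raw <= 0)
    return(list(ps_pct = NA_real_, onset_ms = NA_real_, ttp_ms = NA_real_,
                valid = FALSE))
  i <- which.max(y)                       # earliest index on plateaus
  pk <- if (i > 1L && i < length(y) && y[i - 1L] < y[i] && y[i + 1L] < y[i])
    refine_peak(time_ms, y, i) else c(time_ms[i], y[i])
  ps <- pk[2L]
  thr <- 0.1 * ps
  dt <- time_ms[2L] - time_ms[1L]
  need <- max(1L, round(sustain_ms / dt))
  up <- y >= thr
  r <- rle(up)
  ends <- cumsum(r$lengths)
  cand <- which(r$values & r$lengths >= need)
  if (!length(cand))
    return(list(ps_pct = ps, onset_ms = NA_real_, ttp_ms = pk[1L] - ref_time_ms,
                valid = FALSE))
  j <- ends[cand[1L]] - r$lengths[cand[1L]] + 1L   # first sustained sample
  onset <- if (j == 1L) time_ms[1L] else interp_cross(time_ms, y, j - 1L, thr)
  list(ps_pct = ps, onset_ms = onset - ref_time_ms,
       ttp_ms = pk[1L] - ref_time_ms, valid = TRUE)
}

#' Free-wall minus septum strain deltas
#'
#' `dPS`, `dOnset` and `dTTP` are computed as free-wall value minus septal
#' value, the sign convention in which a positive `dTTP` means the free
#' wall peaks later than the septum.
#'
#' @param fw,sep Feature sets for free wall and septum: results of
#'   [strain_features()] or named lists/vectors with any of `ps_pct`/`ps`,
#'   `onset_ms`/`onset`, `ttp_ms`/`ttp`.
#' @return Named numeric vector with `d_ps_pct`, `d_onset_ms`, `d_ttp_ms`
#'   (NA for fields absent from either wall).
#' @export
strain_deltas <- function(fw, sep) {
  get1 <- function(x, keys) {
    x <- as.list(x)
    for (k in keys) if (!is.null(x[[k]])) return(as.numeric(x[[k]]))
    NA_real_
  }
  c(d_ps_pct = get1(fw, c("ps_pct", "ps")) - get1(sep, c("ps_pct", "ps")),
    d_onset_ms = get1(fw, c("onset_ms", "onset")) -
      get1(sep, c("onset_ms", "onset")),
    d_ttp_ms = get1(fw, c("ttp_ms", "ttp")) - get1(sep, c("ttp_ms", "ttp")))
}

#' Wall features and dyssynchrony deltas for a strain curve set
#'
#' Convenience wrapper: [wall_average()], [strain_features()] per wall,
#' [strain_deltas()].
#'
#' @param curves A `strain_curves` set.
#' @return One-row data.frame with per-wall PS/onset/TTP and the deltas.
#' @export
strain_metrics <- function(curves) {
  wt <- wall_average(curves)
  fw <- strain_features(wt, wall = "freewall")
  sp <- strain_features(wt, wall = "septum")
  d <- strain_deltas(fw, sp)
  data.frame(fw_ps_pct = fw$ps_pct, fw_onset_ms = fw$onset_ms,
             fw_ttp_ms = fw$ttp_ms, sep_ps_pct = sp$ps_pct,
             sep_onset_ms = sp$onset_ms, sep_ttp_ms = sp$ttp_ms,
             d_ps_pct = unname(d["d_ps_pct"]),
             d_onset_ms = unname(d["d_onset_ms"]),
             d_ttp_ms = unname(d["d_ttp_ms"]),
             valid = fw$valid && sp$valid)
}
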
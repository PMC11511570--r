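# Linear temperature-programmed retention index (LTPRI) computation and
# minimal peak handling for chromatograms stored as two-column
# time/intensity tables.

#' n-Alkane reference ladder
#'
#' @param carbon integer carbon numbers, strictly increasing.
#' @param retention_time retention times in minutes, strictly increasing.
#' @return A data.frame of class `alkane_ladder`.
#' @export
alkane_ladder <- function(carbon, retention_time) {
  stopifnot(length(carbon) == length(retention_time), length(carbon) >= 2)
  carbon <- as.integer(carbon)
  if (any(diff(carbon) <= 0)) {
    stop("carbon numbers must be strictly increasing", call. = FALSE)
  }
  if (any(diff(retention_time) <= 0)) {
    stop("retention times must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(carbon = carbon, retention_time = retention_time),
            class = c("alkane_ladder", "data.frame"))
}

#' Bracketing alkanes for an analyte retention time
#'
#' Finds the ladder entry eluting immediately before the analyte and the
#' next entry, requiring consecutive carbon numbers. An analyte eluting
#' exactly at a ladder time is assigned to the lower bracket.
#'
#' @param ladder an [alkane_ladder()].
#' @param t analyte retention time, minutes.
#' @return List with `carbon` (lower carbon number c), `t_lower`
#'   (T_R(c)) and `t_upper` (T_R(c+1)).
#' @export
bracketing_alkanes <- function(ladder, t) {
  stopifnot(inherits(ladder, "alkane_ladder"))
  rt <- ladder$retention_time
  if (t < rt[1] || t > rt[length(rt)]) {
    stop("retention time ", t, " min is outside the alkane ladder span [",
         rt[1], ", ", rt[length(rt)], "]", call. = FALSE)
  }
  i <- findInterval(t, rt, rightmost.closed = TRUE)
  if (i >= length(rt)) i <- length(rt) - 1L
  # exact hit on an alkane time -> lower bracket (tie-break)
  if (ladder$carbon[i + 1L] - ladder$carbon[i] != 1L) {
    stop("alkane ladder gap: bracketing carbons ", ladder$carbon[i],
         " and ", ladder$carbon[i + 1L], " are not consecutive",
         call. = FALSE)
  }
  list(carbon = ladder$carbon[i], t_lower = rt[i], t_upper = rt[i + 1L])
}

#' Linear temperature-programmed retention index
#'
#' LTPRI = 100 (T_R(A) - T_R(c)) / (T_R(c+1) - T_R(c)) + 100 c, linear
#' interpolation of the analyte's retention time between the alkanes
#' eluting immediately before and after it.
#'
#' @param t_analyte analyte retention time, minutes.
#' @param t_c retention time of the alkane with `c` carbons (before).
#' @param t_c1 retention time of the alkane with `c + 1` carbons (after).
#' @param c carbon number of the earlier alkane.
#' @return Retention index in index units, in `[100 c, 100 (c + 1)]`.
#' @export
ltpri <- function(t_analyte, t_c, t_c1, c) {
  if (t_c1 <= t_c) stop("zero or negative alkane spacing", call. = FALSE)
  if (t_analyte < t_c || t_analyte > t_c1) {
    stop("analyte retention time is not inside the bracket", call. = FALSE)
  }
  100 * (t_analyte - t_c) / (t_c1 - t_c) + 100 * c
}

#' Retention index directly from a ladder
#'
#' Convenience wrapper: brackets `t` on the ladder and applies [ltpri()].
#'
#' @param ladder an [alkane_ladder()].
#' @param t analyte retention time, minutes.
#' @return Retention index in index units.
#' @export
ltpri_from_ladder <- function(ladder, t) {
  b <- bracketing_alkanes(ladder, t)
  ltpri(t, b$t_lower, b$t_upper, b$carbon)
}

#' Detect and integrate one peak in a chromatogram window
#'
#' The apex is the maximum intensity inside the window; the baseline is
#' the median intensity of the window; the area is the trapezoidal
#' integral of the baseline-subtracted signal, floored at zero.
#'
#' @param chromatogram data.frame with columns `time` (min) and
#'   `intensity`.
#' @param window numeric length-2, the time window to search.
#' @param label optional peak label.
#' @param ion optional m/z channel annotation.
#' @return A one-row data.frame of class `peak` with columns `label`,
#'   `retention_time`, `area`, `height`, `ion`.
#' @export
detect_and_integrate <- function(chromatogram, window, label = NA_character_,
                                 ion = NA_real_) {
  stopifnot(is.data.frame(chromatogram),
            all(c("time", "intensity") %in% names(chromatogram)),
            length(window) == 2, window[1] < window[2])
  sel <- chromatogram$time >= window[1] & chromatogram$time <= window[2]
  if (sum(sel) < 3) stop("window contains fewer than 3 points", call. = FALSE)
  tt <- chromatogram$time[sel]
  yy <- chromatogram$intensity[sel]
  baseline <- stats::median(yy)
  apex <- which.max(yy)
  area <- max(0, pracma::trapz(tt, yy - baseline))
  structure(
    data.frame(label = label, retention_time = tt[apex],
               area = area, height = yy[apex] - baseline, ion = ion),
    class = c("peak", "data.frame")
  )
}

#' Assemble peaks into a peak table sorted by retention time
#'
#' @param ... `peak` rows (or data.frames with the same columns).
#' @param source free-text provenance tag.
#' @return A data.frame of class `peak_table`.
#' @export
peak_table <- function(..., source = "") {
  tbl <- do.call(rbind, lapply(list(...), as.data.frame))
  tbl <- tbl[order(tbl$retention_time), , drop = FALSE]
  rownames(tbl) <- NULL
  structure(tbl, class = c("peak_table", "data.frame"), source = source)
}

#' Read / write chromatograms and peak tables as delimited text
#'
#' Chromatograms are 2-column CSV (`time`, `intensity`); peak tables are
#' CSV with header `label, retention_time, area, height, ion`.
#'
#' @param path file path.
#' @name chromatogram-io
NULL

#' @rdname chromatogram-io
#' @export
read_chromatogram <- function(path) {
  x <- utils::read.csv(path)
  stopifnot(all(c("time", "intensity") %in% names(x)))
  x
}

#' @rdname chromatogram-io
#' @param chromatogram data.frame with `time` and `intensity` columns.
#' @export
write_chromatogram <- function(chromatogram, path) {
  utils::write.csv(chromatogram[, c("time", "intensity")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname chromatogram-io
#' @export
read_peak_table <- function(path) {
  x <- utils::read.csv(path)
  structure(x[order(x$retention_time), , drop = FALSE],
            class = c("peak_table", "data.frame"))
}

#' @rdname chromatogram-io
#' @param peaks a `peak_table`.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks), path, row.names = FALSE)
  invisible(path)
}
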
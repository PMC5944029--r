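# Cardiac/ECMO flow-interface localisation. In a femoral VA-ECMO run the
# retrograde cannula stream meets the antegrade cardiac stream somewhere
# along the aorta; on the 1D model the meeting point is where the signed
# sectional trunk flow crosses from antegrade (positive, away from the
# root) to retrograde (negative).

trunk_profile <- function(solution) {
  sel <- which(!is.na(solution$stations$arc_mm))
  if (!length(sel))
    stopf("solution has no trunk arc-length stations; was the network built with a trunk?")
  ord <- sel[order(solution$stations$arc_mm[sel])]
  list(idx = ord, arc = solution$stations$arc_mm[ord])
}

#' Locate the cardiac/ECMO flow interface at one time sample
#'
#' Scans the signed flow along the aortic trunk (proximal to distal) for the
#' most proximal antegrade-to-retrograde sign change and interpolates the
#' zero crossing linearly between the bracketing stations. Two boundary
#' cases clamp the watershed to the ends of the path rather than losing it:
#' when the trunk is already retrograde at its proximal end the watershed
#' has been pushed to the root (proximal-end position, attribute
#' `fully_retrograde = TRUE`); when flow is antegrade along the whole trunk
#' while the source at the distal trunk node is actively injecting, the
#' antegrade stream has pushed the watershed onto the cannula orifice
#' (distal-end position, attribute `at_cannula = TRUE`). `NA` means no
#' interface exists (fully antegrade flow with no opposing source, e.g. a
#' cardiac-only run). Additional crossings, if any, are recorded in the
#' `n_crossings` attribute.
#'
#' @param solution a [reconstruct_cycle()] result.
#' @param time_index sample index in `1..length(solution$times)`.
#' @return interface position in mm from the aortic root, or `NA`.
#' @export
locate_interface <- function(solution, time_index) {
  i <- as.integer(time_index)
  if (i < 1L || i > length(solution$times))
    stopf("time_index out of range")
  tr <- trunk_profile(solution)
  q <- solution$station_flow_mL_s[i, tr$idx]
  x <- tr$arc
  # flows below solver noise count as stagnant, not directed
  q[abs(q) < 1e-9 * max(1, max(abs(q)))] <- 0
  # count strict antegrade-to-retrograde sign transitions (zeros skipped)
  s <- sign(q)[sign(q) != 0]
  n_down <- if (length(s) > 1L)
    sum(s[-length(s)] > 0 & s[-1L] < 0) else 0L
  neg <- which(q < 0)
  if (!length(neg)) {
    # no retrograde region: watershed at the cannula if its source is
    # actively injecting, otherwise absent
    last_seg <- solution$network$trunk[length(solution$network$trunk)]
    distal_node <- solution$network$segments[[last_seg]]$to
    src <- solution$network$sources[[distal_node]]
    if (!is.null(src) && abs(src$values[i]) > 1e-9) {
      pos <- x[length(x)]
      attr(pos, "at_cannula") <- TRUE
      attr(pos, "n_crossings") <- 0L
      return(pos)
    }
    return(NA_real_)
  }
  j <- neg[1L]
  ante <- which(q[seq_len(j - 1L)] > 0)
  if (!length(ante)) {
    # no antegrade-perfused proximal region at all: watershed at the root
    pos <- x[1L]
    attr(pos, "fully_retrograde") <- TRUE
    attr(pos, "n_crossings") <- n_down
    return(pos)
  }
  # interpolate the zero crossing just distal to the last antegrade station
  # (a zero plateau between the streams reports its proximal edge)
  a <- ante[length(ante)]
  pos <- x[a] + q[a] * (x[a + 1L] - x[a]) / (q[a] - q[a + 1L])
  attr(pos, "fully_retrograde") <- FALSE
  attr(pos, "n_crossings") <- max(n_down, 1L)
  pos
}

#' Track the flow interface over one cardiac cycle
#'
#' Applies [locate_interface()] at every sample and summarises: the cycle
#' mean over samples where an interface exists, the positional range, and
#' the fraction of the cycle during which an interface is present.
#'
#' @param solution a [reconstruct_cycle()] result.
#' @return an object of class `interface_track` with fields `times`,
#'   `position_mm` (NA where absent), `exists`, `fully_retrograde`,
#'   `cycle_mean_position_mm` (NA when never present), `cycle_range_mm`,
#'   `existence_fraction`.
#' @export
track_interface <- function(solution) {
  nt <- length(solution$times)
  pos <- rep(NA_real_, nt)
  fr <- rep(FALSE, nt)
  ac <- rep(FALSE, nt)
  for (i in seq_len(nt)) {
    p <- locate_interface(solution, i)
    pos[i] <- as.numeric(p)
    fr[i] <- isTRUE(attr(p, "fully_retrograde"))
    ac[i] <- isTRUE(attr(p, "at_cannula"))
  }
  exists <- !is.na(pos)
  structure(list(
    times = solution$times, position_mm = pos, exists = exists,
    fully_retrograde = fr, at_cannula = ac,
    cycle_mean_position_mm = if (any(exists)) mean(pos[exists]) else NA_real_,
    cycle_range_mm = if (any(exists)) diff(range(pos[exists])) else 0,
    existence_fraction = mean(exists)), class = "interface_track")
}

#' @export
print.interface_track <- function(x, ...) {
  cat(sprintf(
    "<interface_track> present %.0f%% of cycle; mean position %s mm from root (range %.1f mm)\n",
    100 * x$existence_fraction,
    if (is.na(x$cycle_mean_position_mm)) "-" else
      sprintf("%.1f", x$cycle_mean_position_mm),
    x$cycle_range_mm))
  invisible(x)
}

#' Write an interface track to CSV (`time_s,position_mm,exists`)
#'
#' @param track an [track_interface()] result.
#' @param path output file path.
#' @export
write_interface_csv <- function(track, path) {
  utils::write.csv(data.frame(time_s = track$times,
                              position_mm = track$position_mm,
                              exists = track$exists),
                   path, row.names = FALSE)
  invisible(path)
}
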
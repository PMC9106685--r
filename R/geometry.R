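# Closed-form imaging geometry for an object moving directly along the line
# of sight: vergence-defined binocular disparity, angular subtense, and the
# changing-disparity (CD) and changing-size (CS) signals they generate.
#
# Conventions used throughout the package:
#   * distances in mm, angles in arcmin at the user-facing interface
#   * distance moved m is positive toward the observer; m = 0 is fixation
#   * crossed (nearer-than-fixation) disparities are negative, so an
#     approaching object produces CD < 0 and CS > 1

RAD_TO_ARCMIN <- 60 * 180 / pi

#' Viewing geometry
#'
#' Bundles the interocular separation and viewing distance that define the
#' binocular imaging equations.
#'
#' @param interocular Interocular separation i in mm. Defaults to 65 mm,
#'   the adult population mean.
#' @param distance Viewing distance v in mm (distance to the fixation
#'   plane). Defaults to 764 mm, a typical stereoscope viewing distance.
#' @return An object of class `viewing_geometry`.
#' @examples
#' geom <- viewing_geometry()
#' geom$distance
#' @export
viewing_geometry <- function(interocular = 65, distance = 764) {
  stopifnot(is.numeric(interocular), length(interocular) == 1L, interocular > 0,
            is.numeric(distance), length(distance) == 1L, distance > 0)
  structure(list(interocular = interocular, distance = distance),
            class = "viewing_geometry")
}

#' @export
print.viewing_geometry <- function(x, ...) {
  cat(sprintf("viewing_geometry: i = %.1f mm, v = %.1f mm\n",
              x$interocular, x$distance))
  invisible(x)
}

#' Binocular disparity (vergence angle) of a point
#'
#' The vergence-defined disparity angle `2 atan((i/2) / v)` of a point at
#' distance `v`, in arcmin. This is the building block of the CD signal:
#' the disparity of an object relative to fixation is the difference of
#' two such angles.
#'
#' @param v Distance to the point in mm (> 0). Vectorised.
#' @param i Interocular separation in mm (> 0).
#' @return Disparity angle in arcmin; strictly decreasing in `v`.
#' @examples
#' binocular_disparity(764)
#' @export
binocular_disparity <- function(v, i = 65) {
  if (any(!is.finite(v)) || any(v <= 0)) stop("`v` must be finite and > 0")
  if (any(!is.finite(i)) || any(i <= 0)) stop("`i` must be finite and > 0")
  2 * atan((i / 2) / v) * RAD_TO_ARCMIN
}

#' Changing-disparity (CD) signal of a linear motion
#'
#' Disparity change, in arcmin, produced by a motion from the fixation
#' plane at distance `v` to `v - m`:
#' `CD = 2 atan((i/2)/v) - 2 atan((i/2)/(v - m))`.
#' The subtraction order keeps crossed disparities negative, so approach
#' (`m > 0`) yields `CD < 0`.
#'
#' @param v Viewing distance in mm (> 0). Vectorised.
#' @param m Distance moved in mm, positive toward the observer; must
#'   satisfy `v - m > 0`.
#' @param i Interocular separation in mm.
#' @return CD in arcmin.
#' @examples
#' cd_signal(764, 80)   # approach -> negative
#' @export
cd_signal <- function(v, m, i = 65) {
  if (any(!is.finite(v)) || any(v <= 0)) stop("`v` must be finite and > 0")
  if (any(!is.finite(m))) stop("`m` must be finite")
  if (any(v - m <= 0)) stop("`v - m` must be > 0 (object in front of the eyes)")
  binocular_disparity(v, i) - binocular_disparity(v - m, i)
}

#' Angular size of a fronto-parallel extent
#'
#' Full angular subtense, in arcmin, of a fronto-parallel extent `s`
#' viewed at distance `v`: `2 atan((s/2)/v)`.
#'
#' @param s Physical extent in mm (> 0). Vectorised.
#' @param v Viewing distance in mm (> 0).
#' @return Angular size in arcmin.
#' @examples
#' angular_size(10, 764)   # ~45 arcmin
#' angular_size(40, 764)   # ~180 arcmin
#' @export
angular_size <- function(s, v) {
  if (any(!is.finite(s)) || any(s <= 0)) stop("`s` must be finite and > 0")
  if (any(!is.finite(v)) || any(v <= 0)) stop("`v` must be finite and > 0")
  2 * atan((s / 2) / v) * RAD_TO_ARCMIN
}

#' Changing-size (CS) signal of a linear motion
#'
#' Ratio of angular sizes before and after a motion from `v` to `v - m`:
#' `CS = atan((s/2)/(v - m)) / atan((s/2)/v)`. Ratios above 1 indicate an
#' expanding (approaching) image. The dependence on the physical size `s`
#' is weak for small `s` (small-angle regime), where `CS -> v / (v - m)`.
#'
#' @param v Viewing distance in mm (> 0). Vectorised.
#' @param m Distance moved in mm (toward observer positive); `v - m > 0`.
#' @param s Physical surface size in mm (> 0).
#' @return Dimensionless size ratio.
#' @examples
#' cs_signal(764, 80, 40)   # approach -> > 1
#' @export
cs_signal <- function(v, m, s) {
  if (any(!is.finite(s)) || any(s <= 0)) stop("`s` must be finite and > 0")
  if (any(!is.finite(v)) || any(v <= 0)) stop("`v` must be finite and > 0")
  if (any(v - m <= 0)) stop("`v - m` must be > 0 (object in front of the eyes)")
  atan((s / 2) / (v - m)) / atan((s / 2) / v)
}

#' Equivalent physical surface size implied by conflicting cues
#'
#' Given a cue-conflict stimulus where the CD cue places the object at
#' `v - m_cd` while the CS cue corresponds to a surface of physical size
#' `s_cs` at `v - m_cs`, returns the physical size the surface would need
#' to have at the CD-defined position to produce the CS-defined image:
#' `s_cd = 2 (v - m_cd) tan(theta)` with
#' `theta = atan((s_cs/2) / (v - m_cs))`.
#' When the two cues agree (`m_cd == m_cs`) this returns `s_cs` exactly.
#'
#' @param v Viewing distance in mm. Vectorised.
#' @param m_cd Distance moved according to the CD cue, mm.
#' @param m_cs Distance moved according to the CS cue, mm.
#' @param s_cs Simulated physical surface size in mm.
#' @return Equivalent surface size `s_cd` in mm.
#' @export
equivalent_surface_size <- function(v, m_cd, m_cs, s_cs) {
  if (any(!is.finite(v)) || any(v <= 0)) stop("`v` must be finite and > 0")
  if (any(v - m_cd <= 0) || any(v - m_cs <= 0))
    stop("degenerate distances: `v - m` must be > 0 for both cues")
  if (any(s_cs <= 0)) stop("`s_cs` must be > 0")
  theta <- atan((s_cs / 2) / (v - m_cs))
  2 * (v - m_cd) * tan(theta)
}

# Unit-period triangular wave through 0, +1, 0, -1, 0.
triangle_wave <- function(u) {
  u <- u %% 1
  ifelse(u < 0.25, 4 * u, ifelse(u < 0.75, 2 - 4 * u, 4 * u - 4))
}

#' Triangular motion-in-depth trajectory
#'
#' One (or a fraction/multiple of one) full triangular oscillation in
#' depth: the object moves from the fixation plane to `+amplitude`
#' (toward the observer), through fixation to `-amplitude`, and back.
#' Speed in depth is constant at `4 * amplitude * cycles / duration`;
#' the defaults (80 mm amplitude, 1.5 s) give the 213 mm/s baseline speed
#' used throughout.
#'
#' Positions are sampled at the `round(duration * frame_rate)` display
#' frame boundaries plus the final frame offset, so `m` has
#' `n_frames + 1` samples with `m[1] = m[end] = 0` for whole cycles.
#'
#' @param amplitude Peak displacement in mm (> 0).
#' @param duration Presentation duration in s (> 0).
#' @param frame_rate Display frame rate in Hz.
#' @param cycles Number of oscillation cycles within `duration`
#'   (default 1; fractional values slow the oscillation, as used for
#'   frequency conflicts).
#' @param phase Phase offset in radians (a shift of `phase / (2 pi)` of a
#'   cycle, wrapped), used for phase conflicts.
#' @return An object of class `trajectory` with elements `times` (s),
#'   `m` (mm), `frame_rate`, `duration`, `amplitude`, `cycles`, `phase`,
#'   and `n_frames`.
#' @examples
#' tr <- triangular_trajectory(80, 1.5, 60)
#' max(abs(tr$m))
#' @export
triangular_trajectory <- function(amplitude = 80, duration = 1.5,
                                  frame_rate = 60, cycles = 1, phase = 0) {
  stopifnot(amplitude > 0, duration > 0, frame_rate > 0, cycles > 0)
  n_frames <- round(duration * frame_rate)
  if (n_frames < 1) stop("duration too short for one frame")
  times <- (0:n_frames) / frame_rate
  u <- (times / duration) * cycles + phase / (2 * pi)
  structure(list(times = times,
                 m = amplitude * triangle_wave(u),
                 frame_rate = frame_rate, duration = duration,
                 amplitude = amplitude, cycles = cycles, phase = phase,
                 n_frames = n_frames),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: %d frames @ %g Hz, amplitude %.1f mm, %.3g cycle(s), speed %.1f mm/s\n",
    x$n_frames, x$frame_rate, x$amplitude, x$cycles,
    4 * x$amplitude * x$cycles / x$duration))
  invisible(x)
}

#' Conflict specification
#'
#' @param type One of `"amplitude"`, `"frequency"`, `"phase"`.
#' @param level Conflict level: log2 units for amplitude and frequency
#'   (frequency levels in `[-2, 0]`), radians in `[0, pi]` for phase.
#' @return An object of class `conflict_spec`.
#' @export
conflict_spec <- function(type = c("amplitude", "frequency", "phase"),
                          level = 0) {
  type <- match.arg(type)
  stopifnot(is.numeric(level), length(level) == 1L, is.finite(level))
  if (type == "phase" && (level < 0 || level > pi))
    stop("phase conflict level must lie in [0, pi] radians")
  if (type == "frequency" && (level < -2 || level > 0))
    stop("frequency conflict level must lie in [-2, 0] log2 units")
  structure(list(type = type, level = level), class = "conflict_spec")
}

#' Cue stimulus: paired CD and CS depth trajectories
#'
#' A motion-in-depth stimulus carries one depth trajectory per cue so the
#' cues can be put into conflict; a consistent stimulus has identical
#' trajectories.
#'
#' @param cd,cs `trajectory` objects driving the disparity and image-size
#'   cues respectively; must share `frame_rate` and `duration`.
#' @param surface_size Simulated physical surface size in mm.
#' @param geometry A [viewing_geometry()].
#' @return An object of class `cue_stimulus`.
#' @export
cue_stimulus <- function(cd, cs, surface_size, geometry = viewing_geometry()) {
  stopifnot(inherits(cd, "trajectory"), inherits(cs, "trajectory"),
            inherits(geometry, "viewing_geometry"),
            surface_size > 0)
  if (cd$frame_rate != cs$frame_rate || abs(cd$duration - cs$duration) > 1e-12)
    stop("CD and CS trajectories must share frame rate and duration")
  if (max(abs(cd$m)) >= geometry$distance || max(abs(cs$m)) >= geometry$distance)
    stop("trajectory passes behind the observer: |m| must stay below v")
  structure(list(cd = cd, cs = cs, surface_size = surface_size,
                 geometry = geometry),
            class = "cue_stimulus")
}

#' Consistent-cue stimulus
#'
#' Convenience constructor for a stimulus whose CD and CS trajectories are
#' identical.
#'
#' @inheritParams cue_stimulus
#' @param trajectory A `trajectory` used for both cues.
#' @export
consistent_stimulus <- function(trajectory, surface_size,
                                geometry = viewing_geometry()) {
  cue_stimulus(trajectory, trajectory, surface_size, geometry)
}

#' Apply a cue conflict to a base trajectory
#'
#' Builds a `cue_stimulus` in which one cue (or both, counterbalanced)
#' deviates from the base triangular waveform. Amplitude conflicts scale
#' the target cue's amplitude by `2^level`; frequency conflicts scale its
#' oscillation frequency by `2^level`; phase conflicts shift its waveform
#' by `level` radians. With `target = "both"` (amplitude only, as in the
#' perturbation-analysis design) the CS amplitude is scaled by `2^level`
#' and the CD amplitude by `2^-level`, keeping their geometric mean at the
#' standard amplitude.
#'
#' @param base A `trajectory`, the consistent-cue waveform.
#' @param spec A [conflict_spec()].
#' @param target `"cs"`, `"cd"`, or `"both"` (counterbalanced).
#' @param surface_size Surface size in mm.
#' @param geometry A [viewing_geometry()].
#' @return A `cue_stimulus`.
#' @export
apply_conflict <- function(base, spec, target = c("cs", "cd", "both"),
                           surface_size, geometry = viewing_geometry()) {
  stopifnot(inherits(base, "trajectory"), inherits(spec, "conflict_spec"))
  target <- match.arg(target)
  modify <- function(traj, level) {
    switch(spec$type,
      amplitude = triangular_trajectory(traj$amplitude * 2^level,
                                        traj$duration, traj$frame_rate,
                                        traj$cycles, traj$phase),
      frequency = triangular_trajectory(traj$amplitude, traj$duration,
                                        traj$frame_rate,
                                        traj$cycles * 2^level, traj$phase),
      phase = triangular_trajectory(traj$amplitude, traj$duration,
                                    traj$frame_rate, traj$cycles,
                                    traj$phase + level))
  }
  if (target == "both") {
    if (spec$type == "phase")
      stop("counterbalanced phase conflicts are not defined")
    cd <- modify(base, -spec$level)
    cs <- modify(base, +spec$level)
  } else if (target == "cs") {
    cd <- base
    cs <- modify(base, spec$level)
  } else {
    cd <- modify(base, spec$level)
    cs <- base
  }
  cue_stimulus(cd, cs, surface_size, geometry)
}
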
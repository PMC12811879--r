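#' Stimulus geometry specification
#'
#' Describes the dichoptic display geometry in degrees of visual angle:
#' a square fusion box centred on fixation containing two vertically stacked
#' rivalrous disks, each surrounded by a dark annulus. Coordinates use the
#' convention of origin at fixation with the vertical axis positive upward.
#'
#' @param box_side Side of the square fusion box, degrees (default 4.5).
#' @param disk_diameter Diameter of each rivalrous disk, degrees (default 1.5).
#' @param annulus_outer_diameter Outer diameter of the dark annulus that
#'   surrounds each disk, degrees (default 1.75).
#' @param disk_center_offsets Signed vertical offsets of the two disk centres
#'   from fixation, degrees (default `c(1.5, -1.5)`: one disk above and one
#'   below fixation).
#' @param raster_resolution Pixels per degree used when rasterising
#'   (default 40). Must be at least 1.
#'
#' @return An object of class `geometry_spec`.
#' @examples
#' geom <- geometry_spec()
#' geom$disk_diameter
#' @export
geometry_spec <- function(box_side = 4.5,
                          disk_diameter = 1.5,
                          annulus_outer_diameter = 1.75,
                          disk_center_offsets = c(1.5, -1.5),
                          raster_resolution = 40) {
  g <- structure(
    list(
      box_side = as.numeric(box_side),
      disk_diameter = as.numeric(disk_diameter),
      annulus_outer_diameter = as.numeric(annulus_outer_diameter),
      disk_center_offsets = as.numeric(disk_center_offsets),
      raster_resolution = as.numeric(raster_resolution)
    ),
    class = "geometry_spec"
  )
  validate_geometry_spec(g)
}

validate_geometry_spec <- function(g) {
  stopifnot(inherits(g, "geometry_spec"))
  if (!(g$disk_diameter > 0)) {
    stop("geometry: disk_diameter must be positive", call. = FALSE)
  }
  if (!(g$annulus_outer_diameter >= g$disk_diameter)) {
    stop("geometry: annulus_outer_diameter must be >= disk_diameter",
         call. = FALSE)
  }
  if (!(g$box_side > g$annulus_outer_diameter)) {
    stop("geometry: box_side must exceed annulus_outer_diameter", call. = FALSE)
  }
  if (length(g$disk_center_offsets) != 2) {
    stop("geometry: exactly two disk_center_offsets are required", call. = FALSE)
  }
  # the rivalrous disks must fit inside the box; the dark annulus may abut
  # (or be clipped by) the box edge, as in the default display where the top
  # disk edge is flush with the box half-side
  r_disk <- g$disk_diameter / 2
  half <- g$box_side / 2
  for (i in seq_along(g$disk_center_offsets)) {
    off <- g$disk_center_offsets[i]
    if (abs(off) + r_disk > half + 1e-9) {
      stop(sprintf(
        "geometry: disk %d (offset %+.3f deg) extends outside the fusion box",
        i, off), call. = FALSE)
    }
  }
  if (abs(g$disk_center_offsets[1] - g$disk_center_offsets[2]) <
      g$annulus_outer_diameter) {
    stop("geometry: disks (with annuli) overlap each other", call. = FALSE)
  }
  if (!(g$raster_resolution >= 1)) {
    stop("geometry: raster_resolution must be >= 1", call. = FALSE)
  }
  g
}

#' @export
print.geometry_spec <- function(x, ...) {
  cat("<geometry_spec>\n")
  cat(sprintf("  fusion box : %.3g x %.3g deg\n", x$box_side, x$box_side))
  cat(sprintf("  disks      : %.3g deg diameter at %s deg from fixation\n",
              x$disk_diameter,
              paste(sprintf("%+.3g", x$disk_center_offsets), collapse = ", ")))
  cat(sprintf("  annuli     : to %.3g deg outer diameter\n",
              x$annulus_outer_diameter))
  cat(sprintf("  raster     : %g px/deg\n", x$raster_resolution))
  invisible(x)
}

#' Chromatic channel definitions
#'
#' The three stimulus chromaticities, given as MacLeod-Boynton coordinates
#' `[L/(L+M), S/(L+M)]` at moderate photopic luminance. The coordinates are
#' metadata: the model operates on channel identity (which pixels carry which
#' chromatic label), not on the coordinates themselves. Gray is achromatic
#' furniture and never contributes to a chromatic pool.
#'
#' @return A data.frame with columns `label`, `lm` (L/(L+M)), `s` (S/(L+M)),
#'   and `luminance_cdm2`.
#' @examples
#' chromatic_channels()
#' @export
chromatic_channels <- function() {
  data.frame(
    label = c("red", "green", "gray"),
    lm = c(0.71, 0.62, 0.665),
    s = c(0.30, 0.30, 1.0),
    luminance_cdm2 = c(15, 15, 15),
    stringsAsFactors = FALSE
  )
}

.chromatic_labels <- c("red", "green")

#' Dichoptic condition specification
#'
#' Describes one experimental condition: the background type, the per-eye
#' assignment of chromatic disk labels (patchwork by default: within every eye
#' the two disks carry different colors), the interocular swap rate, and trial
#' timing. Under interocular-switch rivalry (ISR) the two eyes' assignments
#' swap at `swap_rate`; because all pooling in the model is binocular, the
#' swap is a provable no-op for the channel sums and is represented
#' symbolically rather than rendered frame by frame.
#'
#' @param experiment `"exp1"` (stable backgrounds) or `"exp2"` (rivalrous
#'   backgrounds).
#' @param background One of `"green"`, `"red"`, `"gray"`, or `"rivalrous"`.
#'   `"rivalrous"` is only valid for `experiment = "exp2"` (and is its only
#'   valid background).
#' @param disk_assignment Named list with entries `L` and `R`, each a character
#'   vector `c(top = , bottom = )` of chromatic labels. Defaults to the
#'   patchwork arrangement: left eye top red / bottom green, right eye the
#'   reverse.
#' @param channels Character vector giving the two competing chromatic labels
#'   in a fixed order. The order fixes the random-draw order inside trials
#'   (first listed channel draws first), which is what makes label-relabelling
#'   an exact symmetry under a shared seed.
#' @param swap_rate ISR swap rate in Hz (default 3.75 cycles/s).
#' @param trial_duration Simulated trial length, seconds (default 70).
#' @param settle_duration Initial settling time discarded from all measures,
#'   seconds (default 10), leaving a 60-s measured window.
#' @param geometry A [geometry_spec()].
#'
#' @return An object of class `condition_spec`.
#' @examples
#' cond <- condition_spec("exp1", background = "green")
#' cond
#' @export
condition_spec <- function(experiment = c("exp1", "exp2"),
                           background = c("gray", "green", "red", "rivalrous"),
                           disk_assignment = NULL,
                           channels = c("red", "green"),
                           swap_rate = 3.75,
                           trial_duration = 70,
                           settle_duration = 10,
                           geometry = geometry_spec()) {
  experiment <- match.arg(experiment)
  background <- match.arg(background)
  if (is.null(disk_assignment)) {
    disk_assignment <- list(
      L = c(top = channels[1], bottom = channels[2]),
      R = c(top = channels[2], bottom = channels[1])
    )
  }
  cond <- structure(
    list(
      experiment = experiment,
      background = background,
      disk_assignment = disk_assignment,
      channels = channels,
      swap_rate = as.numeric(swap_rate),
      trial_duration = as.numeric(trial_duration),
      settle_duration = as.numeric(settle_duration),
      geometry = geometry
    ),
    class = "condition_spec"
  )
  validate_condition_spec(cond)
}

validate_condition_spec <- function(cond) {
  stopifnot(inherits(cond, "condition_spec"))
  validate_geometry_spec(cond$geometry)
  if (length(cond$channels) != 2 || anyDuplicated(cond$channels) ||
      !all(cond$channels %in% .chromatic_labels)) {
    stop("condition: channels must be two distinct chromatic labels",
         call. = FALSE)
  }
  if ((cond$background == "rivalrous") != (cond$experiment == "exp2")) {
    stop("condition: background 'rivalrous' is required for, and restricted to, exp2",
         call. = FALSE)
  }
  if (!setequal(names(cond$disk_assignment), c("L", "R"))) {
    stop("condition: disk_assignment needs entries for eyes 'L' and 'R'",
         call. = FALSE)
  }
  for (eye in c("L", "R")) {
    a <- cond$disk_assignment[[eye]]
    if (!setequal(names(a), c("top", "bottom"))) {
      stop(sprintf("condition: eye %s needs 'top' and 'bottom' disk labels", eye),
           call. = FALSE)
    }
    if (a[["top"]] == a[["bottom"]]) {
      stop(sprintf(
        "condition: eye %s violates the patchwork invariant (both disks '%s')",
        eye, a[["top"]]), call. = FALSE)
    }
    if (!all(a %in% .chromatic_labels)) {
      stop(sprintf("condition: eye %s carries a non-chromatic disk label", eye),
           call. = FALSE)
    }
  }
  if (!(cond$swap_rate > 0)) {
    stop("condition: swap_rate must be positive", call. = FALSE)
  }
  if (!(cond$trial_duration > cond$settle_duration) ||
      !(cond$settle_duration >= 0)) {
    stop("condition: trial_duration must exceed settle_duration (>= 0)",
         call. = FALSE)
  }
  cond
}

#' Background channel per eye for a condition
#'
#' Stable backgrounds show the same chromatic label to both eyes (or none, for
#' gray); the rivalrous background of exp2 shows one competing color to each
#' eye, in the condition's channel order.
#'
#' @param cond A [condition_spec()].
#' @return Named character vector (`L`, `R`); `NA` where the background
#'   carries no chromatic signal.
#' @keywords internal
background_channels <- function(cond) {
  switch(cond$background,
    gray = c(L = NA_character_, R = NA_character_),
    green = c(L = "green", R = "green"),
    red = c(L = "red", R = "red"),
    rivalrous = if (isTRUE(cond$.bg_swapped)) {
      c(L = cond$channels[2], R = cond$channels[1])
    } else {
      c(L = cond$channels[1], R = cond$channels[2])
    }
  )
}

#' @export
print.condition_spec <- function(x, ...) {
  cat("<condition_spec>\n")
  cat(sprintf("  experiment : %s\n", x$experiment))
  cat(sprintf("  background : %s\n", x$background))
  for (eye in c("L", "R")) {
    a <- x$disk_assignment[[eye]]
    cat(sprintf("  eye %s      : top %s, bottom %s\n", eye,
                a[["top"]], a[["bottom"]]))
  }
  cat(sprintf("  ISR swap   : %.3g Hz\n", x$swap_rate))
  cat(sprintf("  trial      : %.3g s (%.3g s settling discarded)\n",
              x$trial_duration, x$settle_duration))
  invisible(x)
}

#' Swap the two eyes' disk assignments
#'
#' Applies one ISR eye swap to a condition. Channel sums pooled over both eyes
#' are invariant under this operation.
#'
#' @param cond A [condition_spec()].
#' @return The condition with eyes' disk assignments exchanged.
#' @examples
#' swap_eyes(condition_spec("exp1", "gray"))
#' @export
swap_eyes <- function(cond) {
  stopifnot(inherits(cond, "condition_spec"))
  tmp <- cond$disk_assignment$L
  cond$disk_assignment$L <- cond$disk_assignment$R
  cond$disk_assignment$R <- tmp
  if (cond$background == "rivalrous") {
    # the rivalrous background also swaps between eyes; track with a flag so
    # the declared channel (draw) order is untouched
    cond$.bg_swapped <- !isTRUE(cond$.bg_swapped)
  }
  cond
}

#' Relabel the two chromatic channels of a condition
#'
#' Exchanges "red" and "green" everywhere (background and disk assignments)
#' while keeping each channel's position in the declared draw order. Running
#' the relabelled condition with the same seed therefore yields the mirrored
#' trajectory exactly.
#'
#' @param cond A [condition_spec()].
#' @return The relabelled condition.
#' @examples
#' mirror_condition(condition_spec("exp1", "green"))$background
#' @export
mirror_condition <- function(cond) {
  stopifnot(inherits(cond, "condition_spec"))
  flip <- function(x) {
    out <- x
    out[x == "red"] <- "green"
    out[x == "green"] <- "red"
    out
  }
  cond$background <- flip(cond$background)
  for (eye in c("L", "R")) {
    a <- cond$disk_assignment[[eye]]
    cond$disk_assignment[[eye]] <- stats::setNames(flip(unname(a)), names(a))
  }
  cond$channels <- flip(cond$channels)
  cond
}
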
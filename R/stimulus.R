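#' Normalization-pool accounting flags
#'
#' Controls how the divisive-normalization denominator (the channel's pool)
#' counts the background signal. The numerator is always the channel's signal
#' inside the rivalrous regions, pooled binocularly; the denominator adds a
#' background term whose extent is set here.
#'
#' `background_extent` options, per eye whose background carries the channel:
#' \describe{
#'   \item{`"full_box_plus_swap"`}{(calibrated default) The background field is
#'     counted over the full fusion-box interior, and each rivalrous region is
#'     additionally counted once because under interocular-switch rivalry every
#'     region carries the background-matched color during one of the two swap
#'     phases in each eye. This is the accounting frozen to reproduce the
#'     published worked example for the green-background stimulus (green
#'     multiplier 0.069).}
#'   \item{`"full_box"`}{Background counted over the full box interior.}
#'   \item{`"annulus_holes"`}{Plain geometric reading: box interior minus the
#'     two annulus-bounded holes (outer diameter 1.75 deg by default).}
#'   \item{`"disk_holes"`}{Box interior minus the two disk interiors only
#'     (the dark annuli counted as if background).}
#' }
#'
#' @param background_extent One of the options above.
#' @param eyes `"both"` (binocular pooling, default) or `"single"`: whether
#'   numerator and background term sum over both eyes or one. The drive ratio
#'   is unchanged for stable backgrounds (everything scales by two) but the
#'   raw sums differ.
#' @return An object of class `pool_accounting`.
#' @examples
#' pool_accounting()
#' pool_accounting("annulus_holes")
#' @export
pool_accounting <- function(background_extent = c("full_box_plus_swap",
                                                  "full_box",
                                                  "annulus_holes",
                                                  "disk_holes"),
                            eyes = c("both", "single")) {
  structure(
    list(
      background_extent = match.arg(background_extent),
      eyes = match.arg(eyes)
    ),
    class = "pool_accounting"
  )
}

#' @export
print.pool_accounting <- function(x, ...) {
  cat(sprintf("<pool_accounting> background_extent = %s, eyes = %s\n",
              x$background_extent, x$eyes))
  invisible(x)
}

# pixel-centre coordinates of the raster grid covering the fusion box
raster_grid <- function(geometry) {
  n <- max(1L, as.integer(round(geometry$box_side * geometry$raster_resolution)))
  half <- geometry$box_side / 2
  coord <- (seq_len(n) - 0.5) / geometry$raster_resolution - half
  list(n = n, x = coord, y = coord)
}

# n x n indicator of a disk centred at (0, cy) with diameter d
disk_indicator <- function(grid, cy, d) {
  r2 <- (d / 2)^2
  # rows follow the vertical coordinate: distance^2 from pixel centre
  # (x = grid$x[j], y = grid$y[i]) to the disk centre (0, cy)
  outer((grid$y - cy)^2, grid$x^2, `+`) <= r2
}

#' Render per-eye, per-channel stimulus fields
#'
#' Turns a condition into nonnegative indicator fields `S_C(x)` per eye and
#' chromatic channel. In `"raster"` mode each field is a pixel matrix over the
#' fusion box (pixel-centre sampling); in `"analytic"` mode the equivalent
#' exact areas are stored instead, which removes pixelisation noise from the
#' normalization ratio. Annuli, Nonius lines, fixation point and fusion-box
#' edges are achromatic furniture and carry zero in every chromatic channel.
#'
#' @param condition A [condition_spec()].
#' @param mode `"analytic"` (default) or `"raster"`.
#' @return An object of class `rendered_stimulus`: for raster mode, per-eye
#'   named lists of pixel matrices (one per chromatic channel) plus the grid;
#'   for analytic mode, per-eye tables of exact disk and background areas.
#' @examples
#' stim <- render_fields(condition_spec("exp1", "green"))
#' stim$areas$L
#' @export
render_fields <- function(condition, mode = c("analytic", "raster")) {
  mode <- match.arg(mode)
  validate_condition_spec(condition)
  geom <- condition$geometry
  bg <- background_channels(condition)
  a_disk <- pi * (geom$disk_diameter / 2)^2
  a_hole <- pi * (geom$annulus_outer_diameter / 2)^2
  a_box <- geom$box_side^2

  if (mode == "analytic") {
    areas <- lapply(c(L = "L", R = "R"), function(eye) {
      assign <- condition$disk_assignment[[eye]]
      disk_area <- stats::setNames(numeric(2), .chromatic_labels)
      for (pos in c("top", "bottom")) {
        lab <- assign[[pos]]
        disk_area[lab] <- disk_area[lab] + a_disk
      }
      list(
        disk_area = disk_area,
        background_channel = bg[[eye]],
        box_area = a_box,
        hole_area = 2 * a_hole,
        disk_total_area = 2 * a_disk
      )
    })
    out <- list(mode = "analytic", condition = condition, areas = areas)
  } else {
    grid <- raster_grid(geom)
    offs <- geom$disk_center_offsets
    disk_top <- disk_indicator(grid, offs[1], geom$disk_diameter)
    disk_bot <- disk_indicator(grid, offs[2], geom$disk_diameter)
    hole_top <- disk_indicator(grid, offs[1], geom$annulus_outer_diameter)
    hole_bot <- disk_indicator(grid, offs[2], geom$annulus_outer_diameter)
    bg_field <- !(hole_top | hole_bot)
    eyes <- lapply(c(L = "L", R = "R"), function(eye) {
      assign <- condition$disk_assignment[[eye]]
      fields <- stats::setNames(
        rep(list(matrix(0, grid$n, grid$n)), length(.chromatic_labels)),
        .chromatic_labels
      )
      fields[[assign[["top"]]]] <- fields[[assign[["top"]]]] + disk_top
      fields[[assign[["bottom"]]]] <- fields[[assign[["bottom"]]]] + disk_bot
      if (!is.na(bg[[eye]])) {
        fields[[bg[[eye]]]] <- fields[[bg[[eye]]]] + bg_field
      }
      lapply(fields, function(m) m * 1)
    })
    out <- list(mode = "raster", condition = condition, grid = grid,
                eyes = eyes,
                parts = list(disks = (disk_top | disk_bot) * 1,
                             background = bg_field * 1))
  }
  class(out) <- "rendered_stimulus"
  out
}

#' @export
print.rendered_stimulus <- function(x, ...) {
  cat(sprintf("<rendered_stimulus> mode = %s, background = %s\n",
              x$mode, x$condition$background))
  if (x$mode == "raster") {
    cat(sprintf("  grid: %d x %d px (%g px/deg)\n", x$grid$n, x$grid$n,
                x$condition$geometry$raster_resolution))
  }
  invisible(x)
}

#' Rivalry mask f(x)
#'
#' The binary spatial filter that isolates the rivalrous regions: weight 1
#' inside the two disk interiors, 0 elsewhere (annuli excluded). The mask is
#' identical for both eyes. A graded (non-binary) matrix of weights in `[0,1]`
#' on the same grid may be supplied wherever a mask is accepted.
#'
#' @param geometry A [geometry_spec()].
#' @param mode `"analytic"` (stores the exact support area) or `"raster"`.
#' @return An object of class `rivalry_mask`.
#' @examples
#' m <- rivalry_mask(geometry_spec())
#' m$area
#' @export
rivalry_mask <- function(geometry, mode = c("analytic", "raster")) {
  mode <- match.arg(mode)
  validate_geometry_spec(geometry)
  a_disk <- pi * (geometry$disk_diameter / 2)^2
  if (mode == "analytic") {
    out <- list(mode = "analytic", geometry = geometry, area = 2 * a_disk)
  } else {
    grid <- raster_grid(geometry)
    offs <- geometry$disk_center_offsets
    m <- (disk_indicator(grid, offs[1], geometry$disk_diameter) |
          disk_indicator(grid, offs[2], geometry$disk_diameter)) * 1
    out <- list(mode = "raster", geometry = geometry, grid = grid,
                weights = m, area = sum(m) / geometry$raster_resolution^2)
  }
  class(out) <- "rivalry_mask"
  out
}

#' Evaluate a mask at a point
#'
#' @param mask A [rivalry_mask()].
#' @param x,y Coordinates in degrees (origin at fixation).
#' @return Mask weight at the point (0 or 1 for the binary default).
#' @examples
#' mask_at(rivalry_mask(geometry_spec()), 0, 0) # fixation lies between disks
#' @export
mask_at <- function(mask, x, y) {
  stopifnot(inherits(mask, "rivalry_mask"))
  g <- mask$geometry
  r2 <- (g$disk_diameter / 2)^2
  inside <- any((x^2 + (y - g$disk_center_offsets)^2) <= r2)
  as.numeric(inside)
}

#' Per-channel masked and total signal sums
#'
#' Computes, for each chromatic channel, the numerator and denominator of the
#' normalized-drive ratio: `masked_sum` is the channel's signal inside the
#' rivalrous regions pooled binocularly, and `total_sum` adds the channel's
#' background pool, whose extent is set by the [pool_accounting()] flags.
#' Both sums are invariant under the ISR eye swap because pooling is
#' binocular.
#'
#' @param stim A [render_fields()] result.
#' @param mask A [rivalry_mask()] on the same grid (and mode). If `NULL`, the
#'   default binary mask for the stimulus geometry is used.
#' @param accounting A [pool_accounting()].
#' @return An object of class `channel_sums`: a data.frame with columns
#'   `channel`, `masked_sum`, `total_sum` (areas in squared degrees).
#' @examples
#' s <- channel_sums(render_fields(condition_spec("exp1", "green")))
#' s
#' @export
channel_sums <- function(stim, mask = NULL,
                         accounting = pool_accounting()) {
  stopifnot(inherits(stim, "rendered_stimulus"),
            inherits(accounting, "pool_accounting"))
  if (is.null(mask)) {
    mask <- rivalry_mask(stim$condition$geometry, mode = stim$mode)
  }
  stopifnot(inherits(mask, "rivalry_mask"))
  eyes <- if (accounting$eyes == "both") c("L", "R") else "L"

  masked <- stats::setNames(numeric(length(.chromatic_labels)),
                            .chromatic_labels)
  bgpool <- masked

  if (stim$mode == "analytic") {
    if (mask$mode != "analytic") {
      stop("channel_sums: mask and stimulus must share the same mode",
           call. = FALSE)
    }
    for (eye in eyes) {
      a <- stim$areas[[eye]]
      masked <- masked + a$disk_area
      bgc <- a$background_channel
      if (!is.na(bgc)) {
        bgpool[bgc] <- bgpool[bgc] + switch(
          pool_accounting_match(accounting),
          full_box_plus_swap = a$box_area + a$disk_total_area,
          full_box = a$box_area,
          annulus_holes = a$box_area - a$hole_area,
          disk_holes = a$box_area - a$disk_total_area
        )
      }
    }
  } else {
    if (mask$mode != "raster" ||
        !all(dim(mask$weights) == c(stim$grid$n, stim$grid$n))) {
      stop("channel_sums: mask grid does not match the stimulus grid",
           call. = FALSE)
    }
    px <- stim$condition$geometry$raster_resolution^2
    bg_counts <- list(
      full_box_plus_swap = (stim$grid$n^2 + sum(stim$parts$disks)) / px,
      full_box = stim$grid$n^2 / px,
      annulus_holes = sum(stim$parts$background) / px,
      disk_holes = (stim$grid$n^2 - sum(stim$parts$disks)) / px
    )
    bgch <- background_channels(stim$condition)
    for (eye in eyes) {
      for (ch in .chromatic_labels) {
        field <- stim$eyes[[eye]][[ch]]
        # background pixels lie outside the mask support, so the masked sum
        # picks up disk signal only
        masked[ch] <- masked[ch] + sum(mask$weights * field) / px
      }
      bgc <- bgch[[eye]]
      if (!is.na(bgc)) {
        bgpool[bgc] <- bgpool[bgc] +
          bg_counts[[pool_accounting_match(accounting)]]
      }
    }
  }

  out <- data.frame(
    channel = .chromatic_labels,
    masked_sum = unname(masked),
    total_sum = unname(masked + bgpool),
    stringsAsFactors = FALSE
  )
  class(out) <- c("channel_sums", "data.frame")
  out
}

pool_accounting_match <- function(accounting) accounting$background_extent
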
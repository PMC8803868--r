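# Zebrin band geometry and the mediolateral coordinate frame.
#
# Seven parasagittal bands tile the mediolateral axis of lobules III-V:
# P2- contra, P2+ contra, P1- contra, P1+, P1- ipsi, P2+ ipsi, P2- ipsi.
# The coordinate origin is the centre of the P1+ band (the midline);
# ipsilateral positions are positive.

#' Printed mean zebrin band widths
#'
#' Mean and standard deviation of the seven zebrin band widths (um) in
#' lobules III/IV/V of adult mice, ordered from the contralateral P2- band
#' to the ipsilateral P2- band, together with the recorded Purkinje cell
#' position statistics. These parameterise [generate_zebrin_geometry()].
#'
#' @format A list with elements `mean_widths`, `sd_widths` (named numeric
#'   vectors of length 7), `pc_mean` and `pc_sd` (scalars, um).
#' @export
zebrin_reference <- list(
  mean_widths = c(
    "P2-_contra" = 416.6, "P2+_contra" = 71.56, "P1-_contra" = 320.516,
    "P1+" = 34.63, "P1-_ipsi" = 320.46, "P2+_ipsi" = 69.75,
    "P2-_ipsi" = 438.04
  ),
  sd_widths = c(
    "P2-_contra" = 70.72, "P2+_contra" = 24.59, "P1-_contra" = 62.94,
    "P1+" = 16.18, "P1-_ipsi" = 60.54, "P2+_ipsi" = 22.53,
    "P2-_ipsi" = 64.25
  ),
  pc_mean = 52.42,
  pc_sd = 29.8
)

.zebrin_band_names <- names(zebrin_reference$mean_widths)

#' Construct a zebrin geometry
#'
#' A zebrin geometry fixes the widths of the seven zebrin bands and the
#' position of the recorded Purkinje cell, and thereby the mediolateral
#' coordinate frame of a map: the origin sits at the centre of the P1+
#' band and ipsilateral positions are positive.
#'
#' @param band_widths numeric vector of 7 positive band widths (um),
#'   ordered contralateral P2- to ipsilateral P2-.
#' @param pc_position signed distance of the recorded Purkinje cell from
#'   the midline (um, ipsilateral positive). Must lie within +/-130 um,
#'   the recording inclusion criterion.
#' @param midline_position coordinate assigned to the midline (um).
#' @return An object of class `zebrin_geometry` with fields `band_widths`,
#'   `pc_position`, `midline_position`.
#' @export
zebrin_geometry <- function(band_widths, pc_position = 0,
                            midline_position = 0) {
  band_widths <- as.numeric(band_widths)
  if (length(band_widths) != 7L) {
    stop("`band_widths` must contain exactly 7 widths")
  }
  if (any(!is.finite(band_widths)) || any(band_widths <= 0)) {
    stop("all band widths must be finite and > 0")
  }
  if (abs(pc_position) > 130) {
    stop("`pc_position` must lie within +/-130 um of the midline")
  }
  names(band_widths) <- .zebrin_band_names
  structure(
    list(band_widths = band_widths, pc_position = pc_position,
         midline_position = midline_position),
    class = "zebrin_geometry"
  )
}

#' @export
print.zebrin_geometry <- function(x, ...) {
  cat("Zebrin geometry (", round(sum(x$band_widths), 1), " um across 7 bands)\n",
      sep = "")
  print(round(x$band_widths, 2))
  cat("PC position:", round(x$pc_position, 2), "um from midline\n")
  invisible(x)
}

#' Band ranges of a zebrin geometry
#'
#' Lower and upper mediolateral bounds (um) of each band. Bands tile the
#' axis outward from the midline, which is the centre of the P1+ band.
#'
#' @param geometry a [zebrin_geometry()].
#' @return data.frame with columns `band`, `lower`, `upper` (um).
#' @export
band_ranges <- function(geometry) {
  stopifnot(inherits(geometry, "zebrin_geometry"))
  w <- geometry$band_widths
  # left edge of the tiling: midline - half P1+ - contralateral bands
  left <- geometry$midline_position - w[["P1+"]] / 2 -
    sum(w[c("P2-_contra", "P2+_contra", "P1-_contra")])
  bounds <- left + cumsum(c(0, unname(w)))
  data.frame(
    band = .zebrin_band_names,
    lower = bounds[1:7],
    upper = bounds[2:8],
    stringsAsFactors = FALSE
  )
}

#' Sample a zebrin geometry from the printed band statistics
#'
#' Draws each band width from a Normal distribution with the printed mean
#' and SD, truncated at a positive floor, and the Purkinje-cell position
#' from its printed distribution clipped to the recording criterion
#' \[0, 130\] um.
#'
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param mean_widths,sd_widths length-7 numeric vectors (um); default the
#'   printed adult values in [zebrin_reference].
#' @param pc_mean,pc_sd Purkinje-cell position statistics (um).
#' @param truncate if `TRUE` (default) widths are resampled (and finally
#'   clamped) to stay above `floor`.
#' @param floor positive lower bound for widths (um).
#' @return A [zebrin_geometry()].
#' @export
generate_zebrin_geometry <- function(seed = NULL,
                                     mean_widths = zebrin_reference$mean_widths,
                                     sd_widths = zebrin_reference$sd_widths,
                                     pc_mean = zebrin_reference$pc_mean,
                                     pc_sd = zebrin_reference$pc_sd,
                                     truncate = TRUE, floor = 1) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(mean_widths) == 7L, length(sd_widths) == 7L, floor > 0)
  widths <- stats::rnorm(7, mean_widths, sd_widths)
  if (truncate) {
    for (i in seq_len(7)) {
      tries <- 0L
      while (widths[i] <= floor && tries < 50L) {
        widths[i] <- stats::rnorm(1, mean_widths[i], sd_widths[i])
        tries <- tries + 1L
      }
      if (widths[i] <= floor) widths[i] <- floor
    }
  }
  pc <- stats::rnorm(1, pc_mean, pc_sd)
  pc <- min(max(pc, 0), 130)
  zebrin_geometry(widths, pc_position = pc)
}

#' Normalise mediolateral positions to the ipsilateral P1- band width
#'
#' Positions (um from the midline) are expressed as a percentage of the
#' width of the ipsilateral P1- band, the alignment unit used to pool maps
#' across animals. Sign is preserved (contralateral negative).
#'
#' @param positions numeric vector of positions (um).
#' @param geometry a [zebrin_geometry()].
#' @return numeric vector, percent of the ipsilateral P1- band width.
#' @export
align_to_zebrin <- function(positions, geometry) {
  stopifnot(inherits(geometry, "zebrin_geometry"))
  w <- geometry$band_widths[["P1-_ipsi"]]
  if (w <= 0) stop("ipsilateral P1- band width must be > 0")
  100 * (positions - geometry$midline_position) / w
}

#' Label positions by anatomical microzone
#'
#' Assigns each mediolateral position the zebrin band (structural
#' microzone) containing it. A position exactly on a boundary belongs to
#' the band on its ipsilateral (right) side. Positions outside the tiled
#' extent are clamped to the outermost band with a warning.
#'
#' @param positions numeric vector of positions (um).
#' @param geometry a [zebrin_geometry()].
#' @param template `"bands7"` uses the seven printed bands; `"bands8"`
#'   additionally splits the ipsilateral P1- band at its midpoint into
#'   medial and lateral halves, giving eight structural microzones.
#'   Alternatively a data.frame with columns `band`, `lower`, `upper`.
#' @return An object of class `zone_labeling`: a character vector of band
#'   labels with attribute `kind = "structural"`.
#' @export
structural_zones <- function(positions, geometry,
                             template = c("bands7", "bands8")) {
  ranges <- if (is.data.frame(template)) {
    template
  } else {
    template <- match.arg(template)
    r <- band_ranges(geometry)
    if (template == "bands8") {
      i <- which(r$band == "P1-_ipsi")
      mid <- (r$lower[i] + r$upper[i]) / 2
      med <- r[i, ]; med$band <- "P1-_ipsi_medial"; med$upper <- mid
      lat <- r[i, ]; lat$band <- "P1-_ipsi_lateral"; lat$lower <- mid
      r <- rbind(r[seq_len(i - 1L), ], med, lat,
                 r[seq(i + 1L, nrow(r)), ])
    }
    r
  }
  lo <- min(ranges$lower); hi <- max(ranges$upper)
  if (any(positions < lo | positions > hi)) {
    warning("positions outside the zebrin extent were clamped to the ",
            "outermost band")
    positions <- pmin(pmax(positions, lo), hi)
  }
  # boundary tie rule: a position on a boundary joins the band on its
  # ipsilateral side, i.e. intervals are [lower, upper)
  idx <- findInterval(positions, ranges$lower, left.open = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(ranges)] <- nrow(ranges)
  structure(ranges$band[idx], kind = "structural", class = "zone_labeling")
}
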
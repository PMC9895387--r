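#' Idealized spherical 10-10 electrode montage
#'
#' Builds a 32-electrode montage on the unit sphere using the geometric
#' construction of the extended international 10-10 system: midline positions
#' are spaced along the nasion-inion meridian, the outer ring runs through
#' Fp1/Fp2, T7/T8 and O1/O2 at 72 degrees of inclination from the vertex, and
#' intermediate electrodes are placed by spherical interpolation between the
#' midline and the ring along their coronal arcs.
#'
#' Coordinates use a right-handed frame with +x through the right preauricular
#' point, +y through the nasion and +z through the vertex; all positions have
#' unit norm (scalp radius 1).
#'
#' @param channels Optional character vector of labels to keep (subset of the
#'   default 32-channel roster), in the requested order.
#' @return A data frame with columns `name`, `x`, `y`, `z`.
#' @examples
#' m <- montage_1010()
#' nrow(m)              # 32
#' rowSums(m[, 2:4]^2)  # all 1
#' @export
montage_1010 <- function(channels = NULL) {
  deg <- pi / 180
  ## position at inclination `incl` from vertex, azimuth `az` measured from
  ## +y (nasion) toward +x (right ear): negative az = left hemisphere
  pos <- function(incl, az) {
    c(sin(incl * deg) * sin(az * deg),
      sin(incl * deg) * cos(az * deg),
      cos(incl * deg))
  }
  ## outer ring (incl 72): ring angle psi from nasion, left negative
  ring <- function(psi) pos(72, psi)

  p <- list(
    Fz  = pos(36, 0), FCz = pos(18, 0), Cz = pos(0, 0),
    CPz = pos(18, 180), Pz = pos(36, 180), Oz = pos(72, 180),
    Fp1 = ring(-18), Fp2 = ring(18),
    F7  = ring(-54), F8  = ring(54),
    T7  = ring(-90), T8  = ring(90),
    P7  = ring(-126), P8 = ring(126),
    O1  = ring(-162), O2 = ring(162),
    FT7 = ring(-72), FT8 = ring(72),
    TP7 = ring(-108), TP8 = ring(108)
  )
  ## intermediate electrodes: halfway along the arc joining midline and ring
  p$F3  <- slerp(p$Fz,  p$F7,  0.5); p$F4  <- slerp(p$Fz,  p$F8,  0.5)
  p$FC3 <- slerp(p$FCz, p$FT7, 0.5); p$FC4 <- slerp(p$FCz, p$FT8, 0.5)
  p$C3  <- slerp(p$Cz,  p$T7,  0.5); p$C4  <- slerp(p$Cz,  p$T8,  0.5)
  p$CP3 <- slerp(p$CPz, p$TP7, 0.5); p$CP4 <- slerp(p$CPz, p$TP8, 0.5)
  p$P3  <- slerp(p$Pz,  p$P7,  0.5); p$P4  <- slerp(p$Pz,  p$P8,  0.5)
  p$AF3 <- slerp(p$Fp1, p$F3,  0.5); p$AF4 <- slerp(p$Fp2, p$F4,  0.5)

  order32 <- c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
               "FT7", "FC3", "FCz", "FC4", "FT8", "T7", "C3", "Cz", "C4",
               "T8", "TP7", "CP3", "CPz", "CP4", "TP8", "P7", "P3", "Pz",
               "P4", "P8", "O1", "Oz", "O2")
  if (is.null(channels)) channels <- order32
  stop_if(!all(channels %in% names(p)), "unknown channel label(s): %s",
          paste(setdiff(channels, names(p)), collapse = ", "))
  xyz <- t(vapply(p[channels], identity, numeric(3)))
  data.frame(name = channels, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}
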
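#' Calibrated 4D stack
#'
#' Thin container for a 4D grayscale array with physical calibration.
#' `data` has dim `c(ny, nx, nz, nt)`; intensities are in `[0, 1]`.
#'
#' @param data 4D numeric array, dim `c(ny, nx, nz, nt)`.
#' @param pixel_size um per pixel (lateral).
#' @param z_step um between optical sections.
#' @param t_step minutes between timepoints.
#' @param times optional timepoint vector (minutes).
#' @return A `calibrated_stack` object.
#' @export
calibrated_stack <- function(data, pixel_size, z_step, t_step,
                             times = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4)
  assert_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  assert_scalar_num(z_step, "z_step", positive = TRUE)
  assert_scalar_num(t_step, "t_step", positive = TRUE)
  nt <- dim(data)[4]
  if (is.null(times)) times <- seq(0, by = t_step, length.out = nt)
  structure(list(data = data, pixel_size = pixel_size, z_step = z_step,
                 t_step = t_step, times = times),
            class = "calibrated_stack")
}

#' @export
print.calibrated_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<calibrated_stack> %d x %d px, %d z-slices, %d timepoints\n",
    d[2], d[1], d[3], d[4]))
  cat(sprintf("  calibration: %.3g um/px, %.3g um z-step, %.3g min/frame\n",
              x$pixel_size, x$z_step, x$t_step))
  invisible(x)
}

#' @export
dim.calibrated_stack <- function(x) dim(x$data)

# stylized in-focus DIC appearance of one slice: bipolar shear rim along the
# object boundary plus granular interior texture (drives local variance)
render_slice <- function(mask, rim_amp, texture_amp, background) {
  m <- (mask > 0) * 1
  if (!any(m > 0)) return(matrix(background, nrow(mask), ncol(mask)))
  ms <- EBImage::gblur(m, sigma = 0.8)
  shear <- shift_edge(ms, 1, 1) - shift_edge(ms, -1, -1)
  tex <- matrix(runif(length(m), -1, 1), nrow(m), ncol(m)) * m
  background + rim_amp * shear + texture_amp * tex
}

#' Render a scripted scene as a DIC-like calibrated stack
#'
#' Produces a stylized DIC appearance, not a physical optics model: slices
#' cutting through an object carry a bright/dark shear rim at the boundary and
#' granular interior texture (both give the high local intensity variance that
#' in-focus DIC structures show), slices at axial distance `d` from the object
#' receive only a defocused ghost blurred with a Gaussian of width
#' `blur_gain * d` pixels and attenuated with distance, and the whole stack
#' gets additive Gaussian noise. Deterministic given the script seed.
#'
#' @param truth a [build_scene()] result.
#' @param noise_sd additive Gaussian noise standard deviation (>= 0),
#'   intensity units.
#' @param blur_gain defocus kernel gain, px of Gaussian sigma per um of axial
#'   distance (>= 0).
#' @param rim_amp amplitude of the shear rim.
#' @param texture_amp amplitude of the interior granular texture.
#' @param background background intensity.
#' @param ghost_slices how many empty slices above/below an object still show
#'   a defocused ghost.
#' @return A [calibrated_stack()].
#' @export
render_dic <- function(truth, noise_sd = 0.02, blur_gain = 0.3,
                       rim_amp = 0.4, texture_amp = 0.25,
                       background = 0.5, ghost_slices = 2) {
  stopifnot(inherits(truth, "ground_truth"))
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  assert_scalar_num(blur_gain, "blur_gain", nonneg = TRUE)
  sc <- truth$script
  d <- truth$dim
  nt <- length(truth$times)
  out <- array(background, c(d[1], d[2], d[3], nt))
  with_seed(sc$seed + 1L, {
    for (ti in seq_len(nt)) {
      lab <- truth$masks[[ti]]
      nonempty <- which(apply(lab > 0, 3, any))
      sharp <- list()
      for (k in nonempty) {
        sl <- render_slice(lab[, , k], rim_amp, texture_amp, background)
        sharp[[as.character(k)]] <- sl
        out[, , k, ti] <- sl
      }
      if (length(nonempty) && ghost_slices > 0) {
        for (k in setdiff(seq_len(d[3]), nonempty)) {
          dz <- min(abs(k - nonempty))
          if (dz > ghost_slices) next
          src <- nonempty[which.min(abs(k - nonempty))]
          dist_um <- dz * sc$z_step
          sig <- max(blur_gain * dist_um, 0.5)
          ghost <- EBImage::gblur(sharp[[as.character(src)]] - background,
                                  sigma = sig)
          out[, , k, ti] <- background + ghost * 0.45^dz
        }
      }
      if (noise_sd > 0) {
        out[, , , ti] <- out[, , , ti] +
          rnorm(prod(d), sd = noise_sd)
      }
    }
  })
  calibrated_stack(out, sc$pixel_size, sc$z_step, sc$t_step,
                   times = truth$times)
}
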
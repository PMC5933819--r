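# Random-dot-motion stimulus engine. A proportion of dots (the coherence)
# steps in a common direction each frame; the rest step in independent
# random directions. Dots live for a fixed number of frames and then
# re-spawn uniformly inside the circular aperture; dots that leave the
# aperture wrap around to the opposite side.

#' Random-dot-motion stimulus parameters
#'
#' Defaults follow the display used in the decision-redecision paradigm:
#' roughly 300 dots of radius 0.08 degrees in a 3-degree aperture, moving at
#' 8 degrees/s with a 3-frame lifetime at 60 Hz. The printed dot "density"
#' of such displays is dimensionally ambiguous, so the dot count is the
#' primitive here and density is derived metadata.
#'
#' @param coherence Percentage of coherently moving dots, in (0, 100].
#' @param direction One of `"left"`, `"right"`, `"up"`, `"down"`.
#' @param n_dots Number of dots.
#' @param dot_radius Dot radius in degrees of visual angle.
#' @param aperture_radius Aperture radius in degrees.
#' @param speed Dot speed in degrees/s.
#' @param lifetime Dot lifetime in frames (re-spawn afterwards).
#' @param frame_rate Display refresh rate in Hz.
#' @return A list of class `rdm_params`.
#' @export
rdm_params <- function(coherence, direction = c("left", "right", "up", "down"),
                       n_dots = 300L, dot_radius = 0.08, aperture_radius = 3,
                       speed = 8.0, lifetime = 3L, frame_rate = 60) {
  direction <- match.arg(direction)
  stopifnot(coherence > 0, coherence <= 100, n_dots > 0, lifetime >= 1,
            dot_radius > 0, aperture_radius > 0, speed > 0, frame_rate > 0)
  structure(
    list(coherence = coherence, direction = direction, n_dots = as.integer(n_dots),
         dot_radius = dot_radius, aperture_radius = aperture_radius,
         speed = speed, lifetime = as.integer(lifetime), frame_rate = frame_rate,
         density = n_dots * dot_radius^2 / aperture_radius^2),
    class = "rdm_params"
  )
}

#' Coherence ladder for the 10 difficulty levels
#'
#' Log-spaced between 51.2% (level 1, easiest) and 1.6% (level 10,
#' hardest); level 0 is the reserved control level at 100% coherence.
#'
#' @param level Integer level(s) in 0..10.
#' @return Coherence percentage(s).
#' @examples
#' coherence_for_level(1) # 51.2
#' coherence_for_level(10) # 1.6
#' @export
coherence_for_level <- function(level) {
  if (!all(level %in% 0:10)) {
    abort("RDM difficulty level must be in 0..10 (0 = control).",
          class = "redecide_domain_error")
  }
  out <- 51.2 * (1.6 / 51.2)^((level - 1) / 9)
  out[level == 0] <- 100
  out
}

.rdm_dir_vec <- list(left = c(-1, 0), right = c(1, 0), up = c(0, 1), down = c(0, -1))

rdm_spawn <- function(n, radius) {
  # uniform in the disc
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Generate random-dot-motion frames
#'
#' @param params An [rdm_params()] object.
#' @param n_frames Number of frames to generate.
#' @param seed Integer seed.
#' @return A tibble with one row per dot per frame: `frame`, `dot`, `x`,
#'   `y`, `coherent` (flag) and `age` (frames since spawn).
#' @export
generate_rdm_frames <- function(params, n_frames, seed) {
  stopifnot(inherits(params, "rdm_params"), n_frames >= 1)
  n <- params$n_dots
  n_coh <- round(params$coherence / 100 * n)
  step <- params$speed / params$frame_rate
  dirv <- .rdm_dir_vec[[params$direction]]
  with_seed_(seed, {
    pos <- rdm_spawn(n, params$aperture_radius)
    age <- rep_len(seq_len(params$lifetime) - 1L, n) # staggered respawn
    coh <- seq_len(n) <= n_coh
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      frames[[f]] <- tibble::tibble(
        frame = f, dot = seq_len(n),
        x = pos[, 1], y = pos[, 2], coherent = coh, age = age
      )
      # advance to next frame
      theta <- runif(n, 0, 2 * pi)
      dx <- ifelse(coh, dirv[1] * step, cos(theta) * step)
      dy <- ifelse(coh, dirv[2] * step, sin(theta) * step)
      pos <- pos + cbind(dx, dy)
      # wrap-around re-entry through the opposite side of the aperture
      rr <- sqrt(rowSums(pos^2))
      out <- rr > params$aperture_radius
      if (any(out)) {
        pos[out, ] <- -pos[out, ] * (2 * params$aperture_radius / rr[out] - 1)
      }
      age <- age + 1L
      expired <- age >= params$lifetime
      if (any(expired)) {
        pos[expired, ] <- rdm_spawn(sum(expired), params$aperture_radius)
        age[expired] <- 0L
      }
    }
    dplyr::bind_rows(frames)
  })
}
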
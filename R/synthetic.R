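#' Specification of a synthetic AS-OCT iris phantom
#'
#' Describes a B-scan-like scene: a bright, roughly horizontal iris band over
#' a dark speckled background, split by a central pupil gap into a nasal
#' (left) and a temporal (right) side. The anterior border of each side
#' follows a parametric crypt curve whose arc length — hence the true
#' smoothness index — is known analytically.
#'
#' Defaults mirror the native analysis frame (629 x 1102 after cropping) and
#' a crypt geometry that lands the analytic SI in the clinically reported
#' range (roughly 0.80-1.00 over amplitudes 0-14 px at 8 crypts/side).
#'
#' @param width,height image size in pixels.
#' @param side_span horizontal extent of each iris half (pixels).
#' @param baseline_row mean border height (row of the crypt-free border).
#' @param crypt_amplitude peak crypt depth in pixels (0 = perfectly smooth).
#' @param crypt_frequency number of crypts per side.
#' @param crypt_profile `"sinusoid"` or `"gaussians"` (sum of Gaussian pits).
#' @param iris_thickness band thickness below the border (pixels).
#' @param tissue_level,background_level mean 8-bit intensities.
#' @param speckle_sigma SD of multiplicative log-normal speckle (0 = none).
#' @param blur_sigma Gaussian PSF width in pixels (0 = none).
#' @param pupil_gap width of the central gap separating the sides (pixels).
#' @param seed RNG seed; the crypt phase and the noise are drawn from it, so
#'   identical specs render byte-identical images.
#' @return an object of class `synthetic_iris_spec`.
#' @export
synthetic_iris_spec <- function(width = 1102L, height = 629L,
                                side_span = 420L, baseline_row = 260L,
                                crypt_amplitude = 6, crypt_frequency = 8,
                                crypt_profile = c("sinusoid", "gaussians"),
                                iris_thickness = 60L,
                                tissue_level = 180, background_level = 30,
                                speckle_sigma = 0.10, blur_sigma = 1,
                                pupil_gap = 180L, seed = 1L) {
  crypt_profile <- match.arg(crypt_profile)
  if (crypt_amplitude < 0) stop("crypt_amplitude must be >= 0")
  if (speckle_sigma < 0) stop("speckle_sigma must be >= 0")
  if (blur_sigma < 0) stop("blur_sigma must be >= 0")
  if (tissue_level < 0 || tissue_level > 255 ||
      background_level < 0 || background_level > 255)
    stop("intensity levels must lie in [0, 255]")
  if (2L * side_span + pupil_gap >= width)
    stop("sides and pupil gap exceed the image width")
  if (baseline_row + crypt_amplitude + iris_thickness >= height ||
      baseline_row < 1)
    stop("iris band out of frame")
  structure(as.list(environment()), class = "synthetic_iris_spec")
}

# crypt shape on t in [0,1]: returns list(f, fprime) in units of one
# amplitude (f in [0,1], crypts dip downward i.e. toward larger rows)
crypt_curve_fun <- function(profile, k, phase) {
  if (profile == "sinusoid") {
    f <- function(t) (1 + sin(2 * pi * k * t + phase)) / 2
    fp <- function(t) pi * k * cos(2 * pi * k * t + phase)
  } else {
    centers <- ((seq_len(k) - 0.5) / k + phase / (2 * pi * k)) %% 1
    w <- 1 / (6 * k)
    f <- function(t) {
      s <- 0
      for (c0 in centers) s <- s + exp(-(t - c0)^2 / (2 * w^2))
      s
    }
    fp <- function(t) {
      s <- 0
      for (c0 in centers) s <- s - (t - c0) / w^2 * exp(-(t - c0)^2 / (2 * w^2))
      s
    }
  }
  list(f = f, fprime = fp)
}

#' Analytic smoothness index of a continuous border curve
#'
#' SI = chord length / arc length for `row = f(col)` over `[a, b]`:
#' chord `= sqrt((sx (b-a))^2 + (sy (f(b)-f(a)))^2)`, arc
#' `= integral of sqrt(sx^2 + sy^2 f'(x)^2) dx`, evaluated by adaptive
#' quadrature to 1e-8 relative tolerance.
#'
#' @param f vectorized function giving the border row at column `x`.
#' @param a,b column interval, `a < b`.
#' @param fprime vectorized derivative of `f`; if `NULL`, a central
#'   difference with step `1e-5 (b-a)` is used.
#' @param spacing length-2 `(sy, sx)` pixel spacing.
#' @return the SI, a number in `(0, 1]`.
#' @export
analytic_si <- function(f, a, b, fprime = NULL, spacing = c(1, 1)) {
  if (!(a < b)) stop("need a < b")
  if (is.null(fprime)) {
    h <- 1e-5 * (b - a)
    fprime <- function(x) (f(x + h) - f(x - h)) / (2 * h)
  }
  sy <- spacing[1]; sx <- spacing[2]
  fa <- f(a); fb <- f(b)
  if (!all(is.finite(c(fa, fb)))) stop("border curve is not finite on [a, b]")
  chord <- sqrt((sx * (b - a))^2 + (sy * (fb - fa))^2)
  arc <- integrate_piecewise(function(x) sqrt(sx^2 + (sy * fprime(x))^2), a, b)
  chord / arc
}

# adaptive quadrature summed over subintervals; robust for the oscillatory
# arc-length integrand of multi-crypt curves
integrate_piecewise <- function(fun, a, b, pieces = 32L) {
  brk <- seq(a, b, length.out = pieces + 1L)
  s <- 0
  for (i in seq_len(pieces))
    s <- s + stats::integrate(fun, brk[i], brk[i + 1L], rel.tol = 1e-8,
                              subdivisions = 200L)$value
  s
}

# side geometry: column interval and curve for one side of a spec, with the
# side's phase. Returns f, fprime on absolute column coordinates.
side_geometry <- function(spec, side, phase) {
  margin <- (spec$width - 2L * spec$side_span - spec$pupil_gap) %/% 2L
  if (side == "nasal") {
    a <- margin; b <- margin + spec$side_span
  } else {
    b <- spec$width - 1L - margin; a <- b - spec$side_span
  }
  cc <- crypt_curve_fun(spec$crypt_profile, spec$crypt_frequency, phase)
  span <- b - a
  f <- function(x) spec$baseline_row + spec$crypt_amplitude * cc$f((x - a) / span)
  fp <- function(x) spec$crypt_amplitude / span * cc$fprime((x - a) / span)
  list(a = a, b = b, f = f, fprime = fp)
}

#' Render a synthetic iris phantom
#'
#' Draws the iris band under the crypt curves, applies multiplicative
#' log-normal speckle and Gaussian blur, and quantizes to 8-bit. The returned
#' truth carries the continuous curves, the analytic per-side and overall SI,
#' and the exact landmark positions (curve endpoints). Rendering is fully
#' deterministic in `(spec, spec$seed)`.
#'
#' @param spec a [synthetic_iris_spec].
#' @return a list with elements `image` ([gray_image]), `truth` (list with
#'   `true_si_nasal`, `true_si_temporal`, `true_si_overall`, `nasal`,
#'   `temporal` side geometries), and `landmarks` ([landmark_set]).
#' @export
render_iris <- function(spec) {
  stopifnot(inherits(spec, "synthetic_iris_spec"))
  rng <- local_rng(spec$seed)
  phase_n <- stats::runif(1, 0, 2 * pi)
  phase_t <- stats::runif(1, 0, 2 * pi)
  geo_n <- side_geometry(spec, "nasal", phase_n)
  geo_t <- side_geometry(spec, "temporal", phase_t)

  px <- matrix(spec$background_level, spec$height, spec$width)
  for (geo in list(geo_n, geo_t)) {
    cols <- geo$a:geo$b
    top <- round(geo$f(cols))
    bot <- pmin(top + spec$iris_thickness - 1L, spec$height - 1L)
    for (i in seq_along(cols))
      px[(top[i] + 1L):(bot[i] + 1L), cols[i] + 1L] <- spec$tissue_level
  }
  if (spec$speckle_sigma > 0) {
    noise <- exp(stats::rnorm(length(px), -spec$speckle_sigma^2 / 2,
                              spec$speckle_sigma))
    px <- px * noise
  }
  if (spec$blur_sigma > 0) px <- blur_gaussian(px, spec$blur_sigma)
  px <- round(pmin(pmax(px, 0), 255))
  restore_rng(rng)

  truth <- synthetic_truth(spec, geo_n, geo_t)
  lm <- landmark_set(
    nasal_peripheral = c(geo_n$f(geo_n$a), geo_n$a),
    nasal_central = c(geo_n$f(geo_n$b), geo_n$b),
    temporal_peripheral = c(geo_t$f(geo_t$b), geo_t$b),
    temporal_central = c(geo_t$f(geo_t$a), geo_t$a))
  list(image = gray_image(px, provenance = sprintf("synthetic(seed=%d)", spec$seed)),
       truth = truth, landmarks = lm)
}

synthetic_truth <- function(spec, geo_n, geo_t) {
  si_n <- analytic_si(geo_n$f, geo_n$a, geo_n$b, geo_n$fprime)
  si_t <- analytic_si(geo_t$f, geo_t$a, geo_t$b, geo_t$fprime)
  arc <- function(g) integrate_piecewise(function(x) sqrt(1 + g$fprime(x)^2),
                                         g$a, g$b)
  chord <- function(g) sqrt((g$b - g$a)^2 + (g$f(g$b) - g$f(g$a))^2)
  overall <- (chord(geo_n) + chord(geo_t)) / (arc(geo_n) + arc(geo_t))
  list(true_si_nasal = si_n, true_si_temporal = si_t,
       true_si_overall = overall, nasal = geo_n, temporal = geo_t)
}

# push/pop .Random.seed so generators are deterministic without clobbering
# the caller's RNG stream
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}

# separable Gaussian blur with edge replication
blur_gaussian <- function(px, sigma) {
  r <- as.integer(ceiling(3 * sigma))
  if (r < 1L) return(px)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  px <- convolve_axis(px, k, axis = 1L)
  convolve_axis(px, k, axis = 2L)
}

convolve_axis <- function(m, k, axis) {
  r <- (length(k) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) {
    off <- i - r - 1L
    out <- out + k[i] * shift_replicate(m, if (axis == 1L) off else 0L,
                                        if (axis == 2L) off else 0L)
  }
  out
}

shift_replicate <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

#' Solve the crypt amplitude that yields a target analytic overall SI
#'
#' Monotone in amplitude, solved by bisection (`uniroot`) on `[0, max_amp]`.
#'
#' @param target_si desired analytic overall SI in `(0, 1]`.
#' @param spec a [synthetic_iris_spec] whose other fields fix the geometry.
#' @param max_amp upper bracket for the amplitude (pixels).
#' @return amplitude in pixels.
#' @export
amplitude_for_si <- function(target_si, spec = synthetic_iris_spec(),
                             max_amp = 40) {
  stopifnot(target_si > 0, target_si <= 1)
  truth_at <- function(A) {
    s <- spec; s$crypt_amplitude <- A
    rng <- local_rng(s$seed)
    phase_n <- stats::runif(1, 0, 2 * pi)
    phase_t <- stats::runif(1, 0, 2 * pi)
    restore_rng(rng)
    synthetic_truth(s, side_geometry(s, "nasal", phase_n),
                    side_geometry(s, "temporal", phase_t))$true_si_overall
  }
  if (target_si >= 1) return(0)
  lo_si <- truth_at(max_amp)
  if (target_si < lo_si)
    stop(sprintf("target SI %.3f not reachable with amplitude <= %g (floor %.3f)",
                 target_si, max_amp, lo_si))
  stats::uniroot(function(A) truth_at(A) - target_si, c(0, max_amp),
                 tol = 1e-4)$root
}

#' Generate a two-group synthetic cohort
#'
#' Emulates the study design: `n_subjects` subjects with unilateral disease
#' (one affected eye whose analytic overall SI is shifted by `fu_effect`
#' relative to the fellow eye) and `n_subjects` healthy controls, two eyes
#' each. Per-eye base SIs are drawn around 0.85 (SD 0.02) with an eye-level
#' jitter of SD 0.0106 — calibrated so the control group's expected absolute
#' inter-eye difference matches the reported 0.012 — and converted to crypt
#' amplitudes by [amplitude_for_si()].
#'
#' @param n_subjects subjects per group (>= 2).
#' @param fu_effect analytic overall-SI shift for affected eyes, in `[0, 1)`.
#' @param seed RNG seed; fixed seed gives identical cohorts.
#' @param dir optional directory: if given, PNG images, `truth.csv` and
#'   `manifest.csv` are written there.
#' @param image_params named list overriding [synthetic_iris_spec()] fields
#'   (e.g. smaller `width`/`height` for fast tests).
#' @return a list with `truth` (data.frame: subject, group, eye, affected,
#'   seed, amplitude, true SI columns, landmark columns) and `specs` (list of
#'   [synthetic_iris_spec], one per eye, named as `truth$image`).
#' @export
generate_cohort <- function(n_subjects = 11L, fu_effect = 0.03, seed = 1L,
                            dir = NULL, image_params = list()) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  if (fu_effect < 0 || fu_effect >= 1) stop("fu_effect must be in [0, 1)")
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))

  base_spec <- do.call(synthetic_iris_spec, image_params)
  rows <- list(); specs <- list()
  eye_jitter <- 0.0106
  subj_id <- 0L
  for (group in c("FU", "control")) {
    for (s in seq_len(n_subjects)) {
      subj_id <- subj_id + 1L
      base_si <- min(max(stats::rnorm(1, 0.85, 0.02), 0.80), 0.92)
      affected_eye <- sample(c("OD", "OS"), 1)
      for (eye in c("OD", "OS")) {
        affected <- group == "FU" && eye == affected_eye
        target <- base_si - if (affected) fu_effect else 0
        target <- target + stats::rnorm(1, 0, eye_jitter)
        target <- min(max(target, 0.75), 0.999)
        eye_seed <- (seed * 1000L + subj_id * 10L +
                     if (eye == "OD") 1L else 2L) %% .Machine$integer.max
        sp <- base_spec
        sp$seed <- as.integer(eye_seed)
        sp$crypt_amplitude <- amplitude_for_si(target, sp)
        img_name <- sprintf("subj%02d_%s_%s.png", subj_id, group, eye)
        tr <- render_truth_only(sp)
        rows[[length(rows) + 1L]] <- data.frame(
          image = img_name, subject = subj_id, group = group, eye = eye,
          affected = affected, seed = sp$seed,
          crypt_amplitude = sp$crypt_amplitude,
          true_si_nasal = tr$true_si_nasal,
          true_si_temporal = tr$true_si_temporal,
          true_si_overall = tr$true_si_overall,
          stringsAsFactors = FALSE)
        specs[[img_name]] <- sp
      }
    }
  }
  truth <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- truth[, c("image", "subject", "eye", "group")]
    lm_cols <- NULL
    for (i in seq_len(nrow(truth))) {
      r <- render_iris(specs[[truth$image[i]]])
      write_image(r$image, file.path(dir, truth$image[i]))
      lm <- r$landmarks
      lm_cols <- rbind(lm_cols, data.frame(
        points = paste(vapply(unclass(lm), function(p)
          sprintf("%.1f,%.1f", p[1], p[2]), character(1)), collapse = " ")))
    }
    manifest$points <- lm_cols$points
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(truth = truth, specs = specs)
}

# analytic truth of a spec without rasterizing the image
render_truth_only <- function(spec) {
  rng <- local_rng(spec$seed)
  phase_n <- stats::runif(1, 0, 2 * pi)
  phase_t <- stats::runif(1, 0, 2 * pi)
  restore_rng(rng)
  synthetic_truth(spec, side_geometry(spec, "nasal", phase_n),
                  side_geometry(spec, "temporal", phase_t))
}
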
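#' Synthetic MEG sensor array over a single-sphere head model
#'
#' A stand-in for a whole-head axial MEG system: `n_channels` radial
#' magnetometers placed quasi-uniformly (Fibonacci lattice) on the upper
#' hemisphere of a shell of radius `array_radius_m`, around a conducting
#' sphere of radius `sphere_radius_m`. Gradiometers are approximated as
#' radial magnetometers. The head frame has its origin at the sphere centre;
#' "MNI-like" mm coordinates map into it by the fixed rigid translation
#' `sphere_center_mni_mm` (and mm-to-m scaling). All group-level distances
#' are computed in the same mm space, so this choice cancels in hit/miss
#' classification.
#'
#' @param n_channels number of sensors.
#' @param array_radius_m sensor shell radius (m).
#' @param sphere_radius_m conducting sphere radius (m).
#' @param sphere_center_mni_mm mm coordinates of the sphere centre in the
#'   MNI-like world space.
#' @return An object of class `sensor_array` with fields `positions` (S x 3,
#'   m, head frame), `orientations` (S x 3 radial unit vectors),
#'   `sphere_radius_m`, `sphere_center_mni_mm`.
#' @export
meg_sensor_array <- function(n_channels = 275, array_radius_m = 0.12,
                             sphere_radius_m = 0.09,
                             sphere_center_mni_mm = c(0, -25, 15)) {
  i <- seq_len(n_channels)
  z <- (i - 0.5) / n_channels             # upper hemisphere, z in (0, 1)
  phi <- i * pi * (3 - sqrt(5))           # golden angle
  rho <- sqrt(1 - z^2)
  u <- cbind(rho * cos(phi), rho * sin(phi), z)
  structure(list(positions = u * array_radius_m,
                 orientations = u,
                 n_channels = n_channels,
                 array_radius_m = array_radius_m,
                 sphere_radius_m = sphere_radius_m,
                 sphere_center_mni_mm = as.numeric(sphere_center_mni_mm)),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf(
    "Sensor array: %d radial magnetometers at %.0f mm, sphere radius %.0f mm\n",
    x$n_channels, 1000 * x$array_radius_m, 1000 * x$sphere_radius_m))
  invisible(x)
}

# MNI-like mm -> head-frame metres (sphere centre at the origin)
mni_to_head <- function(loc_mm, sensors) {
  (as.numeric(loc_mm) - sensors$sphere_center_mni_mm) / 1000
}

head_to_mni <- function(loc_m, sensors) {
  as.numeric(loc_m) * 1000 + sensors$sphere_center_mni_mm
}

#' Magnetic field of a current dipole in a conducting sphere
#'
#' Field of an equivalent current dipole inside a homogeneous conducting
#' sphere, measured along each sensor's orientation, by the closed-form
#' conducting-sphere solution
#' `B(r) = mu0 / (4 pi F^2) * (F Q x r0 - (Q x r0 . r) grad F)` with
#' `F = a (R a + R^2 - r0 . r)`. A dipole at the sphere centre, or the
#' radial component of any dipole, produces no external field.
#'
#' @param r0_m dipole location, head-frame metres (origin = sphere centre).
#' @param q_am dipole moment vector (A m).
#' @param sensors a [meg_sensor_array()].
#' @return Numeric vector of projected fields (Tesla), one per channel.
#' @export
sarvas_field <- function(r0_m, q_am, sensors) {
  mu0 <- 4e-7 * pi
  r <- sensors$positions                       # S x 3
  r0 <- as.numeric(r0_m)
  q <- as.numeric(q_am)
  a_vec <- sweep(r, 2, r0)                     # r - r0
  a <- sqrt(rowSums(a_vec^2))
  R <- sqrt(rowSums(r^2))
  r0_dot_r <- as.numeric(r %*% r0)
  a_dot_r <- rowSums(a_vec * r)
  F <- a * (R * a + R^2 - r0_dot_r)
  cF1 <- a^2 / R + a_dot_r / a + 2 * a + 2 * R
  cF2 <- a + 2 * R + a_dot_r / a
  gradF <- cF1 * r - cF2 * matrix(r0, nrow(r), 3, byrow = TRUE)
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  if (all(qxr0 == 0)) return(numeric(sensors$n_channels))
  qxr0_dot_r <- as.numeric(r %*% qxr0)
  B <- (mu0 / (4 * pi * F^2)) *
    (F * matrix(qxr0, nrow(r), 3, byrow = TRUE) - qxr0_dot_r * gradF)
  rowSums(B * sensors$orientations)
}

#' Tangential lead field of a dipole location
#'
#' The forward solution for the two effective (tangential) components of an
#' equivalent current dipole in the conducting sphere: an S x 2 gain matrix
#' in Tesla per nAm, whose columns are the projected fields of unit dipoles
#' along an orthonormal tangential basis at the location (the radial
#' component is externally silent). The basis is attached as attribute
#' `"basis"` (3 x 2).
#'
#' @param loc_mm dipole location in MNI-like mm; must be strictly inside the
#'   sphere and away from its centre.
#' @param sensors a [meg_sensor_array()].
#' @return S x 2 numeric gain matrix (T / nAm), attribute `basis`.
#' @export
sphere_leadfield <- function(loc_mm, sensors) {
  r0 <- mni_to_head(loc_mm, sensors)
  d <- sqrt(sum(r0^2))
  if (d >= sensors$sphere_radius_m)
    stop("dipole location outside the conducting sphere")
  if (d < 1e-9)
    stop("dipole at the sphere centre: tangential basis undefined")
  u <- r0 / d
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(u[2] * ref[3] - u[3] * ref[2],
          u[3] * ref[1] - u[1] * ref[3],
          u[1] * ref[2] - u[2] * ref[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  g <- cbind(sarvas_field(r0, 1e-9 * e1, sensors),
             sarvas_field(r0, 1e-9 * e2, sensors))
  attr(g, "basis") <- cbind(e1, e2)
  g
}

#' Simulation configuration
#'
#' Bundles all parameters of the single-dipole group simulation. Defaults
#' reproduce the study conditions: per participant, the dipole location is
#' drawn from an isotropic Gaussian of SD 5 mm centred on (52, -29, 13) mm;
#' the source is a 40 Hz sinusoid lasting 200 ms at 200 Hz sampling, active
#' in 30 of 60 epochs; channel white noise has density 10 fT/sqrt(Hz) over
#' an 80 Hz bandwidth (per-sample SD `10 * sqrt(80)` = 89.44 fT).
#'
#' @param seed_mni_mm centre of the source-location distribution (mm).
#' @param jitter_sd_mm isotropic SD of the per-participant location jitter.
#' @param moment_nAm dipole moment amplitude (nAm).
#' @param freq_hz,duration_s,fs_hz source frequency, epoch length, sampling
#'   rate.
#' @param n_epochs,n_active total epochs and number of source-active epochs
#'   (the first `n_active` epochs are labelled active).
#' @param noise_density_fT,bandwidth_hz white-noise density (fT/sqrt(Hz))
#'   and bandwidth; the per-sample noise SD is their product
#'   `noise_density * sqrt(bandwidth)` fT.
#' @param reference_normal_mni fixed reference orientation from which each
#'   participant's dipole orientation is derived (see
#'   [simulate_participant()]).
#' @param orientation_scale_mm jitter-to-orientation coupling length: the
#'   participant's mm location jitter divided by this length perturbs the
#'   reference normal, so a 5 mm jitter tilts the orientation by roughly 11
#'   degrees.
#' @param sensors a [meg_sensor_array()].
#' @return An object of class `sim_config` (a list of the above).
#' @export
sim_config <- function(seed_mni_mm = c(52, -29, 13), jitter_sd_mm = 5,
                       moment_nAm = 20, freq_hz = 40, duration_s = 0.2,
                       fs_hz = 200, n_epochs = 60, n_active = 30,
                       noise_density_fT = 10, bandwidth_hz = 80,
                       reference_normal_mni = c(0.62, -0.4, 0.67),
                       orientation_scale_mm = 25,
                       sensors = meg_sensor_array()) {
  cfg <- list(seed_mni_mm = as.numeric(seed_mni_mm),
              jitter_sd_mm = jitter_sd_mm, moment_nAm = moment_nAm,
              freq_hz = freq_hz, duration_s = duration_s, fs_hz = fs_hz,
              n_epochs = n_epochs, n_active = n_active,
              noise_density_fT = noise_density_fT,
              bandwidth_hz = bandwidth_hz,
              reference_normal_mni = as.numeric(reference_normal_mni),
              orientation_scale_mm = orientation_scale_mm,
              sensors = sensors)
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from YAML
#'
#' Fields present in the file override [sim_config()] defaults; sensor-array
#' fields go under a `sensors:` block.
#'
#' @param path YAML file.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  sens_args <- y$sensors
  y$sensors <- NULL
  base <- formals(sim_config)
  unknown <- setdiff(names(y), names(base))
  if (length(unknown))
    stop("unknown simulation config fields: ", paste(unknown, collapse = ", "))
  if (!is.null(sens_args)) y$sensors <- do.call(meg_sensor_array, sens_args)
  do.call(sim_config, y)
}

# per-sample channel noise SD in Tesla
noise_sd_T <- function(cfg) cfg$noise_density_fT * 1e-15 * sqrt(cfg$bandwidth_hz)

#' Simulate one participant's epoched MEG recording
#'
#' Draws the participant's dipole location from the configured Gaussian,
#' derives its orientation by perturbing the fixed reference normal with the
#' location jitter (scaled by `orientation_scale_mm`) and projecting out the
#' radial component (radial dipoles are externally silent in a sphere, so a
#' near-radial draw is re-projected), then adds the sinusoidal source field
#' to the active epochs and i.i.d. Gaussian white noise everywhere. A zero
#' moment yields pure noise; with the RNG state fixed, the noise realization
#' is identical whatever the moment, so passive epochs carry exactly no
#' source contribution.
#'
#' @param cfg a [sim_config()].
#' @param participant identifier.
#' @return An object of class `meg_epochs`: `data` (epochs x channels x
#'   samples, Tesla), `labels` ("active"/"passive"), `fs_hz`,
#'   `true_location_mm`, `orientation` (unit 3-vector), `participant`.
#' @export
simulate_participant <- function(cfg, participant = "p1") {
  stopifnot(inherits(cfg, "sim_config"))
  sens <- cfg$sensors
  jitter <- rnorm(3, 0, cfg$jitter_sd_mm)
  loc_mm <- cfg$seed_mni_mm + jitter
  # orientation: reference normal tilted consistently with the location
  # jitter, then made tangential (non-radial) at the realized location
  ori <- cfg$reference_normal_mni + jitter / cfg$orientation_scale_mm
  ori <- ori / sqrt(sum(ori^2))
  u <- mni_to_head(loc_mm, sens)
  u <- u / sqrt(sum(u^2))
  tang <- ori - sum(ori * u) * u
  if (sqrt(sum(tang^2)) < 1e-6) {            # near-radial draw: pick any tangent
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    tang <- ref - sum(ref * u) * u
  }
  ori <- tang / sqrt(sum(tang^2))

  ns <- round(cfg$duration_s * cfg$fs_hz)
  tt <- (seq_len(ns) - 1) / cfg$fs_hz
  wave <- sin(2 * pi * cfg$freq_hz * tt)
  field <- sarvas_field(mni_to_head(loc_mm, sens),
                        cfg$moment_nAm * 1e-9 * ori, sens)   # S-vector, T
  sig <- outer(field, wave)                                  # S x ns

  labels <- rep(c("active", "passive"), c(cfg$n_active,
                                          cfg$n_epochs - cfg$n_active))
  dat <- array(rnorm(cfg$n_epochs * sens$n_channels * ns, 0, noise_sd_T(cfg)),
               dim = c(cfg$n_epochs, sens$n_channels, ns))
  for (e in which(labels == "active"))
    dat[e, , ] <- dat[e, , ] + sig
  structure(list(data = dat, labels = labels, fs_hz = cfg$fs_hz,
                 true_location_mm = loc_mm, orientation = ori,
                 participant = as.character(participant)),
            class = "meg_epochs")
}

#' Simulate a group of participants
#'
#' Independent location jitter, orientation and noise per participant;
#' sensors and sphere are shared across the group.
#'
#' @param cfg a [sim_config()].
#' @param n_participants group size.
#' @param seed optional integer seed.
#' @return An object of class `meg_group`: list with `participants` (list of
#'   [simulate_participant()] results, named p01, p02, ...) and `cfg`.
#' @export
simulate_group <- function(cfg, n_participants = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("p%02d", seq_len(n_participants))
  parts <- lapply(ids, function(id) simulate_participant(cfg, id))
  names(parts) <- ids
  structure(list(participants = parts, cfg = cfg), class = "meg_group")
}

#' @export
print.meg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "MEG epochs '%s': %d epochs x %d channels x %d samples (%d active)\n",
    x$participant, d[1], d[2], d[3], sum(x$labels == "active")))
  cat(sprintf("  true source (%.1f, %.1f, %.1f) mm\n",
              x$true_location_mm[1], x$true_location_mm[2],
              x$true_location_mm[3]))
  invisible(x)
}
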
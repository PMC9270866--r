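#' Configuration of the deforming half-ellipsoid phantom
#'
#' The phantom stands in for an instrumented ovine right ventricle:
#' crystals are material points on a half-ellipsoid shell (base at
#' z = 0, apex at z = -c0) deforming through an affine systolic map,
#' with an annular crystal ring at the base, simultaneous pressure and
#' ECG channels, and two recording states (Baseline and TRA with the
#' ring scaled down). An affine deformation is chosen deliberately:
#' every downstream strain then has a closed form, so the whole
#' pipeline can be checked against analytic truth.
#'
#' Defaults are sized to produce magnitudes typical of a dilated ovine
#' RV: annular ring circumradius 19.58 mm (hexagon area ~996 mm^2),
#' heart rate 106 beats/min, systolic circumferential/longitudinal
#' stretches 0.92/0.95 (mid-single-digit-percent strains), TRA ring
#' area scale 0.53, LVP/RVP/CVP around 87/42/12 mmHg.
#'
#' @param a0,b0,c0 half-ellipsoid semi-axes in mm.
#' @param annular_radius circumradius of the 6-crystal annular ring, mm.
#' @param heart_rate beats/min.
#' @param sample_rate Hz.
#' @param n_cycles complete cardiac cycles in the recording.
#' @param lambda_c,lambda_l systolic stretch ratios (circumferential =
#'   x/y axes, longitudinal = z axis) reached at end-systole.
#' @param es_phase end-systole as a fraction of the cycle (0-1).
#' @param relax_end cycle fraction at which relaxation completes.
#' @param tra_ring_scale linear ring scale of the TRA state (area
#'   scales as its square); default `sqrt(0.53)`.
#' @param tra_wall_affine optional 3x3 matrix applied to every TRA
#'   rest position (models an interventional shape change with exact
#'   ground truth); `NULL` for identity.
#' @param noise_sd iid Gaussian noise SD per coordinate, mm.
#' @param rigid_motion optional list with elements `baseline` and/or
#'   `tra`, each `list(R = 3x3 rotation, t = length-3 translation)`
#'   applied to that state's coordinates at all times.
#' @param lvp_peak,rvp_peak,cvp_mean pressure scales in mmHg.
#' @param lead_in seconds before the first R wave.
#' @param layout the `crystal_layout` to instrument.
#' @param seed integer RNG seed (`NULL` leaves the RNG state alone).
#' @return a validated list of class `phantom_config`.
#' @export
phantom_config <- function(a0 = 42, b0 = 42, c0 = 85,
                           annular_radius = 19.58,
                           heart_rate = 106, sample_rate = 128,
                           n_cycles = 6,
                           lambda_c = 0.92, lambda_l = 0.95,
                           es_phase = 0.4, relax_end = 0.75,
                           tra_ring_scale = sqrt(0.53),
                           tra_wall_affine = NULL,
                           noise_sd = 0, rigid_motion = NULL,
                           lvp_peak = 87, rvp_peak = 42, cvp_mean = 12,
                           lead_in = 0.25,
                           layout = crystal_layout(), seed = NULL) {
  cfg <- as.list(environment())
  for (f in c("a0", "b0", "c0", "annular_radius", "heart_rate"))
    if (cfg[[f]] <= 0) stopf("phantom config field '%s' must be > 0", f)
  for (f in c("lambda_c", "lambda_l"))
    if (cfg[[f]] <= 0 || cfg[[f]] > 1.2)
      stopf("phantom config field '%s' must be in (0, 1.2]", f)
  if (tra_ring_scale <= 0 || tra_ring_scale > 1)
    stopf("phantom config field 'tra_ring_scale' must be in (0, 1]")
  if (es_phase <= 0.05 || es_phase >= relax_end || relax_end >= 1)
    stopf("need 0.05 < es_phase < relax_end < 1")
  if (noise_sd < 0) stopf("phantom config field 'noise_sd' must be >= 0")
  structure(cfg, class = "phantom_config")
}

# Rest positions of all crystals (layout order) on the half-ellipsoid.
phantom_rest_positions <- function(cfg) {
  lay <- cfg$layout
  ring_angles <- 2 * pi * (seq_len(6) - 1) / 6
  ring <- cbind(cfg$annular_radius * cos(ring_angles),
                cfg$annular_radius * sin(ring_angles), 0)
  z_frac <- c(basal = 0.30, mid = 0.55, lower = 0.80)
  wall <- NULL
  for (row in names(lay$parallels)) {
    k <- length(lay$parallels[[row]])
    # stagger alternate rows half a step for a well-shaped triangulation
    off <- if (row == "mid") pi / k else 0
    th <- 2 * pi * (seq_len(k) - 1) / k + off
    zf <- z_frac[[row]]
    rho <- sqrt(1 - zf^2)
    wall <- rbind(wall, cbind(cfg$a0 * rho * cos(th), cfg$b0 * rho * sin(th),
                              -zf * cfg$c0))
  }
  pos <- rbind(ring, wall, c(0, 0, -cfg$c0))
  rownames(pos) <- layout_labels(lay)
  pos
}

# Activation waveform on cycle phase in [0,1): 0 at ED, 1 at es_phase,
# back to 0 at relax_end (raised-cosine limbs).
activation_w <- function(phi, es_phase, relax_end) {
  w <- numeric(length(phi))
  up <- phi >= 0 & phi <= es_phase
  dn <- phi > es_phase & phi <= relax_end
  w[up] <- 0.5 * (1 - cos(pi * phi[up] / es_phase))
  w[dn] <- 0.5 * (1 + cos(pi * (phi[dn] - es_phase) / (relax_end - es_phase)))
  w
}

# Raised-cosine pressure bump whose steepest descent is at es_phase.
pressure_h <- function(phi, es_phase) {
  width <- 0.5
  start <- es_phase - 0.75 * width
  u <- phi - start
  h <- numeric(length(phi))
  inside <- u >= 0 & u <= width
  h[inside] <- 0.5 * (1 - cos(2 * pi * u[inside] / width))
  h
}

#' Generate a Baseline/TRA phantom recording pair with ground truth
#'
#' Emits two synchronized synthetic recordings that exercise the whole
#' pipeline. The free wall deforms by
#' `A(t) = diag(1 + (lambda_c - 1) w, 1 + (lambda_c - 1) w,
#' 1 + (lambda_l - 1) w)` with the raised-cosine activation `w(t)`
#' peaking at end-systole; the TRA state scales the annular ring by
#' `tra_ring_scale` in its plane (and optionally applies
#' `tra_wall_affine` everywhere). The ECG is a train of Gaussian R
#' spikes at the cycle starts; LVP is a smooth pulse whose maximum
#' negative derivative falls exactly at the configured ES phase.
#' Identical seeds give bitwise-identical output.
#'
#' @param cfg a `phantom_config`.
#' @return list with `baseline` and `tra` (`channel_recording`s) and
#'   `truth`: true ED/ES sample indices per complete cycle, the rest
#'   positions, the affine `A_at(phase)` function, true annular areas
#'   per state, the TRA ring scale, the half-ellipsoid hull-volume
#'   upper bound (ml), and the systolic stretches.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  if (!inherits(cfg, "phantom_config")) stopf("cfg must be a phantom_config")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fs <- cfg$sample_rate
  period <- 60 / cfg$heart_rate
  dur <- cfg$lead_in + (cfg$n_cycles + 0.5) * period
  n <- as.integer(round(dur * fs))
  t <- (seq_len(n) - 1) / fs
  ed_times <- cfg$lead_in + period * (0:cfg$n_cycles)
  # cycle phase (0 before the first ED)
  phi <- (t - cfg$lead_in) / period
  phase <- ifelse(phi < 0, 0, phi - floor(phi))
  w <- activation_w(phase, cfg$es_phase, cfg$relax_end)
  w[t < cfg$lead_in] <- 0

  alpha <- 1 + (cfg$lambda_c - 1) * w
  gamma <- 1 + (cfg$lambda_l - 1) * w

  rest <- phantom_rest_positions(cfg)
  lay <- cfg$layout
  labels <- layout_labels(lay)
  ann <- match(lay$annular, labels)

  make_state <- function(state_tag) {
    pos0 <- rest
    if (state_tag == "TRA") {
      s <- cfg$tra_ring_scale
      pos0[ann, 1:2] <- pos0[ann, 1:2] * s
      if (!is.null(cfg$tra_wall_affine))
        pos0 <- pos0 %*% t(cfg$tra_wall_affine)
    }
    rm <- cfg$rigid_motion[[tolower(state_tag)]]
    crystals <- vector("list", length(labels))
    names(crystals) <- labels
    for (i in seq_along(labels)) {
      p <- pos0[i, ]
      traj <- cbind(alpha * p[1], alpha * p[2], gamma * p[3])
      if (!is.null(rm)) traj <- sweep(traj %*% t(rm$R), 2, rm$t, `+`)
      if (cfg$noise_sd > 0)
        traj <- traj + matrix(stats::rnorm(3 * n, 0, cfg$noise_sd), n, 3)
      crystals[[i]] <- traj
    }
    h <- pressure_h(phase, cfg$es_phase)
    h[t < cfg$lead_in] <- 0
    lvp <- 8 + (cfg$lvp_peak - 8) * h
    rvp <- 5 + (cfg$rvp_peak - 5) * h
    cvp <- cfg$cvp_mean + 0.5 * sin(2 * pi * phase)
    ecg <- rowSums(vapply(ed_times, function(et)
      exp(-(t - et)^2 / (2 * 0.012^2)), numeric(n)))
    channel_recording(crystals, lvp, rvp, cvp, ecg, sample_rate = fs,
                      state_tag = state_tag)
  }
  baseline <- make_state("Baseline")
  tra <- make_state("TRA")

  full_eds <- ed_times[ed_times + period <= dur + 1e-9]
  ed_idx <- as.integer(round(full_eds * fs)) + 1L
  es_idx <- as.integer(round((full_eds + cfg$es_phase * period) * fs)) + 1L
  keep <- seq_len(min(length(ed_idx), cfg$n_cycles))

  hex_area <- function(r) (3 * sqrt(3) / 2) * r^2
  A_at <- function(phase) {
    wv <- activation_w(phase, cfg$es_phase, cfg$relax_end)
    diag(c(1 + (cfg$lambda_c - 1) * wv, 1 + (cfg$lambda_c - 1) * wv,
           1 + (cfg$lambda_l - 1) * wv))
  }
  truth <- list(
    ed_index = ed_idx[keep], es_index = es_idx[keep],
    period_samples = period * fs,
    rest_positions = rest, A_at = A_at,
    taa_baseline = hex_area(cfg$annular_radius),
    taa_tra = hex_area(cfg$annular_radius * cfg$tra_ring_scale) *
      if (is.null(cfg$tra_wall_affine)) 1 else
        abs(det(cfg$tra_wall_affine[1:2, 1:2])),
    ring_scale = cfg$tra_ring_scale,
    hull_bound_ml = (2 / 3) * pi * cfg$a0 * cfg$b0 * cfg$c0 / 1000,
    lambda_c = cfg$lambda_c, lambda_l = cfg$lambda_l,
    es_phase = cfg$es_phase)
  list(baseline = baseline, tra = tra, truth = truth)
}

#' Closed-form strain ground truth for an affine phantom deformation
#'
#' For the phantom's affine deformation `A`, the stretch of a material
#' direction `d` is `|A d|`, giving normal strain `(|A d|^2 - 1) / 2`,
#' and each triangle's areal strain is the exact area ratio of its
#' `A`-mapped edges minus one. Evaluated on the same reference mesh
#' and material directions the pipeline uses, this is the analytic
#' value the measured strain field should reproduce.
#'
#' @param truth the `truth` element of [generate_phantom()] (or any
#'   list with `A_at`).
#' @param mesh reference `surface_mesh` (as used by the pipeline).
#' @param dirs [material_directions()] of that mesh.
#' @param phase cycle phase in [0, 1) at which to evaluate.
#' @return data.frame per face: `region`, `E_cc`, `E_ll`, `areal`.
#' @export
analytic_truth <- function(truth, mesh, dirs, phase) {
  A <- truth$A_at(phase)
  stretch_sq <- function(D3) rowSums((D3 %*% t(A))^2)
  p1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  p2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  p3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  area <- function(P1, P2, P3)
    row_norms(rowwise_cross(P2 - P1, P3 - P1)) / 2
  a0 <- area(p1, p2, p3)
  a1 <- area(p1 %*% t(A), p2 %*% t(A), p3 %*% t(A))
  data.frame(region = mesh$face_region,
             E_cc = (stretch_sq(dirs$circ) - 1) / 2,
             E_ll = (stretch_sq(dirs$long) - 1) / 2,
             areal = a1 / a0 - 1)
}
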
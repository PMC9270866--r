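# Shared fixtures: small, fast phantom configurations.

# Heart rate 120 at 128 Hz gives an integer 64-sample cycle, so all
# noise-free beats are sample-aligned (averaging identities are exact).
quick_config <- function(heart_rate = 120, n_cycles = 5, ...) {
  phantom_config(heart_rate = heart_rate, n_cycles = n_cycles, ...)
}

default_layout <- crystal_layout()

# Reference-area-weighted regional means of a per-face vector.
region_mean <- function(values, regions, areas, region) {
  in_r <- regions == region
  sum(values[in_r] * areas[in_r]) / sum(areas[in_r])
}

row_norms_t <- function(A) sqrt(rowSums(A^2))

random_rigid <- function() {
  list(R = rotation_matrix(stats::rnorm(3), stats::runif(1, 0.2, 2 * pi)),
       t = stats::rnorm(3, sd = 40))
}

# All-crystal coordinate frame of an averaged beat at end-diastole.
beat_frame_all <- function(beat, layout = default_layout) {
  labs <- layout_labels(layout)
  t(vapply(labs, function(l) beat$crystals[[l]][1, ], numeric(3)))
}

# Apply one rigid motion to every crystal of a recording.
transform_recording <- function(rec, rm) {
  rec$crystals <- lapply(rec$crystals, function(m)
    sweep(m %*% t(rm$R), 2, rm$t, `+`))
  rec
}
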
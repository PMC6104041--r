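# Shared builders for the test suite. All fixtures are generated in code.

# Wrap a channels x samples matrix as a continuous_eeg object.
make_eeg <- function(signal, rate = 500, labels = NULL, events = NULL) {
  labels <- labels %||% paste0("ch", seq_len(nrow(signal)))
  events <- events %||% data.frame(sample = integer(0), trial = integer(0),
                                   code = character(0))
  structure(list(signal = signal, rate = rate, labels = labels,
                 events = events, unit = "uV"),
            class = "continuous_eeg")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build an epoch_set directly from an array (trials x channels x samples).
make_epochs <- function(data, times, labels = NULL, condition = NULL,
                        unit = "potential", rate = 500) {
  labels <- labels %||% paste0("ch", seq_len(dim(data)[2]))
  structure(list(data = data, times = times, rate = rate, labels = labels,
                 condition = condition %||% rep("A", dim(data)[1]),
                 trial = seq_len(dim(data)[1]), unit = unit,
                 baseline = c(-500, 0), dropped = data.frame()),
            class = "epoch_set")
}

# Smooth random 100 Hz trajectory that leaves the start circle, crosses 8 cm
# and slows down; used against the brute-force bound oracles.
random_trajectory <- function(n = 120, rate = 100) {
  tt <- seq(0, by = 1000 / rate, length.out = n)
  mt <- sample(40:70, 1)                       # movement samples
  onset <- sample(10:25, 1)
  tau <- pmin(pmax((seq_len(n) - onset) / mt, 0), 1)
  dist <- runif(1, 8.6, 10)
  s <- dist * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  ang <- runif(1, 0, 2 * pi) + cumsum(rnorm(n, 0, 0.004))
  data.frame(t = tt, x = s * cos(ang), y = s * sin(ang))
}

# Independent Legendre polynomial evaluation via the Laplace integral
# P_n(x) = (1/pi) Int_0^pi Re[(x + i sqrt(1-x^2) cos t)^n] dt (trapezoid),
# numerically stable at high order, unlike naive explicit formulas.
laplace_pn <- function(n, x) {
  th <- seq(0, pi, length.out = 20001)
  f <- Re((x + 1i * sqrt(max(0, 1 - x^2)) * cos(th))^n)
  (sum(f) - (f[1] + f[length(f)]) / 2) * diff(th[1:2]) / pi
}

# Literal sample-by-sample implementation of the onset/termination rules.
oracle_bounds <- function(traj, geometry = task_geometry(),
                          pixel_pitch = 0.035, velocity_threshold = 1.5) {
  r <- sqrt(traj$x^2 + traj$y^2)
  speed <- reachpe:::trajectory_speed(traj)
  onset <- NA_integer_
  for (i in seq_along(r)) if (r[i] > geometry$start_radius) { onset <- i; break }
  if (is.na(onset)) return(list(onset = NA, termination = NA, error = "NO_ONSET"))
  past <- NA_integer_
  for (i in seq_along(r)) if (r[i] > geometry$feedback_cutoff_radius) { past <- i; break }
  if (is.na(past)) return(list(onset = onset, termination = NA, error = "NO_TERMINATION"))
  term <- NA_integer_
  for (i in past:length(r)) {
    if (speed[i] <= velocity_threshold * pixel_pitch) { term <- i; break }
  }
  if (is.na(term)) return(list(onset = onset, termination = NA, error = "NO_TERMINATION"))
  list(onset = onset, termination = term, error = NULL)
}
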
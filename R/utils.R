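# Small internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Elementary rotations (right-handed, column convention).
rot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0,
           0, c, -s,
           0, s, c), 3, 3, byrow = TRUE)
}

rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, -s, 0,
           s, c, 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

abort_trackcal <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("trackcal_error_", class), "trackcal_error"), ...)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Normalise an angle to [0, 180) degrees (undirected image line).
angle_mod180 <- function(a) {
  a <- a %% 180
  a[a < 0] <- a[a < 0] + 180
  a
}

# Circular distance between undirected line angles, degrees in [0, 90].
angle_gap180 <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
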
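# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# state; seed = NULL uses the current stream.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1)
  withr::with_seed(as.integer(seed), force(code))
}

check_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (strict_min && x <= min) abort(sprintf("`%s` must be > %g.", name, min))
  if (!strict_min && x < min) abort(sprintf("`%s` must be >= %g.", name, min))
  invisible(x)
}

check_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2 || anyNA(x)) {
    abort(sprintf("`%s` must be a numeric pair c(min, max).", name))
  }
  if (x[1] <= 0) abort(sprintf("`%s` must be positive.", name))
  if (x[1] > x[2]) abort(sprintf("`%s` must satisfy min <= max.", name))
  invisible(x)
}

# Population (divisor n) standard deviation: the package-wide RSD convention.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

pop_rsd <- function(x) {
  m <- mean(x)
  if (m == 0) return(NA_real_)
  100 * pop_sd(x) / m
}

# Distance from points (px, py) to the segment a--b. Vectorised over points.
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

# Minimum distance between two segments p1--p2 and q1--q2 (scalars).
segment_segment_distance <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1
  d2 <- q2 - q1
  r <- p1 - q1
  a <- sum(d1 * d1)
  e <- sum(d2 * d2)
  f <- sum(d2 * r)
  if (a == 0 && e == 0) return(sqrt(sum(r * r)))
  if (a == 0) {
    t <- min(1, max(0, f / e))
    return(sqrt(sum((p1 - (q1 + t * d2))^2)))
  }
  c1 <- sum(d1 * r)
  if (e == 0) {
    s <- min(1, max(0, -c1 / a))
    return(sqrt(sum((p1 + s * d1 - q1)^2)))
  }
  b <- sum(d1 * d2)
  denom <- a * e - b * b
  s <- if (denom != 0) min(1, max(0, (b * f - c1 * e) / denom)) else 0
  t <- (b * s + f) / e
  if (t < 0) {
    t <- 0
    s <- min(1, max(0, -c1 / a))
  } else if (t > 1) {
    t <- 1
    s <- min(1, max(0, (b - c1) / a))
  }
  sqrt(sum((p1 + s * d1 - (q1 + t * d2))^2))
}

# Axis endpoints of the capsule core segment for a fibre record (length L,
# width W, centre, orientation): segment of length max(L - W, 0).
fibre_segment <- function(x, y, length, width, orientation) {
  half <- pmax(length - width, 0) / 2
  ux <- cos(orientation)
  uy <- sin(orientation)
  list(
    ax = x - half * ux, ay = y - half * uy,
    bx = x + half * ux, by = y + half * uy
  )
}

# Union-find over 1..n.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
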
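## Shared fixtures and independent oracles used across the suite.

## Analytic two-membrane density used by the generators, rebuilt here
## independently for oracle computations.
membrane_density <- function(x, sep, shape, w, peak = 1, valley = 0,
                             window = 100) {
  c1 <- window / 2 - sep / 2
  c2 <- window / 2 + sep / 2
  s <- if (shape == "triangular") {
    pmax(0, pmax(1 - abs(x - c1) / w, 1 - abs(x - c2) / w))
  } else {
    exp(-(x - c1)^2 / (2 * w^2)) + exp(-(x - c2)^2 / (2 * w^2))
  }
  valley + (peak - valley) * s
}

## Root-finding oracle for the drop rule on the analytic profile:
## peak positions by optimize() on each half-window, valley by
## optimize() between the peaks, boundaries by uniroot() of
## f(x) - threshold. Independent of the package's grid-walking code.
drop_rule_oracle <- function(sep, shape, w, peak = 1, valley = 0,
                             window = 100, drop = 0.10) {
  f <- function(x) membrane_density(x, sep, shape, w, peak, valley, window)
  p_pre <- stats::optimize(f, c(0, window / 2), maximum = TRUE)$maximum
  p_post <- stats::optimize(f, c(window / 2, window), maximum = TRUE)$maximum
  v <- stats::optimize(f, c(p_pre, p_post))$objective
  thr_pre <- f(p_pre) - drop * (f(p_pre) - v)
  thr_post <- f(p_post) - drop * (f(p_post) - v)
  vx <- stats::optimize(f, c(p_pre, p_post))$minimum
  b_pre <- stats::uniroot(function(x) f(x) - thr_pre, c(p_pre, vx),
                          tol = 1e-10)$root
  b_post <- stats::uniroot(function(x) f(x) - thr_post, c(vx, p_post),
                           tol = 1e-10)$root
  list(width = b_post - b_pre, pre = b_pre, post = b_post)
}

## A flat test stack with a single bright voxel at index (i, j, k).
one_voxel_stack <- function(i, j, k, dims = c(5, 5, 3),
                            spacing = c(0.01, 0.01, 0.4)) {
  vox <- array(0, dim = dims)
  vox[i, j, k] <- 1
  image_stack(vox, spacing = spacing, unit = "um")
}

## Brute-force vesicle classification oracle: plain geometry, no shared
## code with classify_vesicles().
classify_oracle <- function(p1, p2, side, centers, radius, dock = 10) {
  if (nrow(centers) == 0) return(list(docked = 0L, vicinity = 0L))
  L <- sqrt(sum((p2 - p1)^2))
  mid <- (p1 + p2) / 2
  docked <- 0L; vicinity <- 0L
  for (i in seq_len(nrow(centers))) {
    v <- centers[i, ]
    cr <- (p2[1] - p1[1]) * (v[2] - p1[2]) - (p2[2] - p1[2]) * (v[1] - p1[1])
    on_presyn <- side * cr > 0
    in_half_disc <- on_presyn && sum((v - mid)^2) <= (L / 2)^2
    ## perpendicular distance and lateral position along the chord
    u <- (p2 - p1) / L
    t <- sum((v - p1) * u)
    perp <- abs((v[1] - p1[1]) * (-u[2]) + (v[2] - p1[2]) * u[1])
    is_docked <- on_presyn && (perp - radius) < dock &&
      t >= 0 && t <= L && in_half_disc
    if (in_half_disc) vicinity <- vicinity + 1L
    if (is_docked) docked <- docked + 1L
  }
  list(docked = docked, vicinity = vicinity)
}
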
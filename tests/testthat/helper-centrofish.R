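# shared fixtures and small utilities built in code

# one-to-one greedy matching of true to detected spots within a radius (um);
# truth rows are visited in order of their closest detection so unambiguous
# pairs claim their detection first
match_spots <- function(truth, detected, radius = 0.5) {
  nt <- nrow(truth); nd <- nrow(detected)
  match_of <- rep(NA_integer_, nt)
  if (nt == 0 || nd == 0) {
    return(list(match_of = match_of, recall = 0, precision = 0,
                n_matched = 0L))
  }
  dm <- outer(seq_len(nt), seq_len(nd), function(i, j) {
    sqrt((truth$z_um[i] - detected$z_um[j])^2 +
           (truth$y_um[i] - detected$y_um[j])^2 +
           (truth$x_um[i] - detected$x_um[j])^2)
  })
  used <- rep(FALSE, nd)
  for (i in order(apply(dm, 1, min))) {
    j <- which.min(ifelse(used, Inf, dm[i, ]))
    if (is.finite(dm[i, j]) && dm[i, j] <= radius) {
      match_of[i] <- j
      used[j] <- TRUE
    }
  }
  n_matched <- sum(!is.na(match_of))
  list(match_of = match_of, recall = n_matched / nt,
       precision = n_matched / nd, n_matched = n_matched)
}

# a small, quickly rendered single-centrosome parameter set for unit tests
tiny_params <- function(...) {
  args <- utils::modifyList(
    list(image_shape = c(16L, 48L, 48L), n_centrosomes = 1L, n_spots = 10L),
    list(...))
  do.call(generator_params, args)
}

# mean of the truncated exponential-shell radial law r^2 exp(-r/lambda) on
# [0, r_max], by numerical quadrature (the generator-independent oracle)
truncated_shell_mean <- function(lambda, r_max) {
  num <- stats::integrate(function(r) r^3 * exp(-r / lambda), 0, r_max)$value
  den <- stats::integrate(function(r) r^2 * exp(-r / lambda), 0, r_max)$value
  num / den
}

# analytic probability mass of bins [a, b) under the same truncated law
truncated_shell_bin_mass <- function(lambda, r_max, edges) {
  den <- stats::integrate(function(r) r^2 * exp(-r / lambda), 0, r_max)$value
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  mass <- vapply(seq_along(lo), function(i) {
    a <- min(lo[i], r_max); b <- min(hi[i], r_max)
    if (b <= a) return(0)
    stats::integrate(function(r) r^2 * exp(-r / lambda), a, b)$value / den
  }, numeric(1))
  c(mass, 1 - sum(mass))  # final element = overflow mass
}

# build a bare spot table (positions in um) for statistics-level tests
make_spots <- function(z, y, x, intensity = 1) {
  data.frame(z_um = z, y_um = y, x_um = x, intensity = intensity)
}
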
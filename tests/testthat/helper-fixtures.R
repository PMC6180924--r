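# Small in-code fixtures shared across tests.

vol1d <- function(values, spacing = c(1, 1, 1)) {
  image_volume(array(values, c(length(values), 1, 1)), spacing_mm = spacing)
}

full_mask <- function(dims, spacing = c(1, 1, 1)) {
  voi_mask(array(TRUE, dims), spacing_mm = spacing)
}

# quantized VOI straight from an integer level array (0 = outside the mask);
# bypasses min-max rescaling so arbitrary level layouts can be posed
qvoi_from_levels <- function(lev, B = max(lev)) {
  structure(
    list(level_array = array(as.integer(lev), dim(lev)), mask = lev > 0,
         B = as.integer(B), vmin = 0, vmax = 1, spacing_mm = c(1, 1, 1),
         n_voxels = sum(lev > 0)),
    class = "quantized_voi"
  )
}

# simulate an exponential cohort with a given risk coefficient on one feature
sim_survival <- function(n, beta = 0, censor_frac = 0.2, seed = 1,
                         base_rate = 0.05) {
  set.seed(seed)
  x <- rnorm(n)
  t_event <- rexp(n, rate = base_rate * exp(beta * x))
  if (censor_frac > 0) {
    f <- function(u) mean(pmin(t_event / u, 1)) - censor_frac
    u <- uniroot(f, c(min(t_event) * 1e-4, max(t_event) * 1e4))$root
    t_cens <- runif(n, 0, u)
    data.frame(x = x, time_months = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens))
  } else {
    data.frame(x = x, time_months = t_event, event = 1L)
  }
}
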
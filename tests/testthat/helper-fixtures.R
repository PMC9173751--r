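# Shared fixtures, built in code at test time.

# a minimal two-event session with one short trace
tiny_session <- function(seed = 1) {
  set.seed(seed)
  tr <- fus_trace(rnorm(2000, 0, 5), 20000, t0 = 0, id = "t1")
  ev <- fus_events(onset = c(0.01, 0.06), modality = "fus",
                   trace_id = "t1", fiber_id = "f1",
                   intensity = c(155, 340), duration = 0.75,
                   validate = FALSE)
  fb <- fus_fibers("f1", class_label = "AbRA", cv = 15,
                   conduction_distance = 20)
  fus_session(list(t1 = tr), ev, fb,
              provenance = list(seed = seed, generator = "test"))
}

# brute-force Pearson correlation straight from the definition
cor_bruteforce <- function(x, y) {
  n <- length(x)
  sum((x - sum(x) / n) * (y - sum(y) / n)) /
    sqrt(sum((x - sum(x) / n)^2) * sum((y - sum(y) / n)^2))
}

# brute-force threshold scan: walk doses in ascending order and return the
# first whose response fraction strictly exceeds one half
threshold_scan <- function(dose, n_stim, n_spk) {
  o <- order(dose)
  for (i in o)
    if (n_spk[i] / n_stim[i] > 0.5) return(dose[i])
  NA_real_
}

# exact signed-rank two-sided p by explicit enumeration of all sign vectors
wilcoxon_enumerate <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  W_all <- as.matrix(signs) %*% r
  p_le <- mean(W_all <= W_obs + 1e-9)
  p_ge <- mean(W_all >= W_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
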
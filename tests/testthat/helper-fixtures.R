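# shared fixture builders for the test suite

# a random feasible toy-system spec; regime cycles with the seed
random_toy_spec <- function(seed, max_spatial = 4, complete_ion = FALSE) {
  set.seed(seed * 7919)
  n_sp <- sample(2:max_spatial, 1)
  n_el <- sample(2:min(4, 2 * n_sp), 1)
  toy_system_spec(
    n_spatial = n_sp, n_electrons = n_el,
    n_source_terms = sample(2:5, 1), n_ion_terms = sample(2:4, 1),
    n_ion_states = 2, complete_ion = complete_ion,
    regime = c("identical", "rotated", "random-spd")[1 + seed %% 3],
    seed = seed)
}

# a valid random genealogical coupling vector for n_open shells
random_coupling <- function(n_open) {
  steps <- integer(n_open)
  two_s <- 0L
  for (k in seq_len(n_open)) {
    steps[k] <- if (two_s == 0L) 1L else sample(c(-1L, 1L), 1)
    two_s <- two_s + steps[k]
  }
  steps
}

# tiny two-state ensemble for TRPES unit tests: deterministic weights
toy_trajectory <- function(id = "t1", pathway = "OOP", tautomer = "enol",
                           times = seq(0, 100, 5), hop = 40, stop_t = Inf,
                           dE = c(a = 4.0, b = 4.5, gs = 9.0),
                           norm = c(a = 0.8, b = 0.6, gs = 0.9)) {
  nt <- length(times)
  w <- matrix(0, nt, 3, dimnames = list(NULL, c("a", "b", "gs")))
  w[, "a"] <- as.numeric(times < hop & times < stop_t)
  w[, "b"] <- as.numeric(times >= hop & times < stop_t)
  w[, "gs"] <- as.numeric(times >= stop_t)
  en <- matrix(0, nt, 3, dimnames = list(NULL, c("a", "b", "gs")))
  channels <- lapply(c("a", "b", "gs"), function(s)
    list(source = s, ion = "D0", energy_ion = dE[[s]], norm = norm[[s]]))
  trajectory_record(id, tautomer, pathway, times, w, en, channels)
}
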
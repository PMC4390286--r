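# Independent one-line transcriptions of the three base height-age
# functions, used as oracles for the package's vectorized implementations.
oracle_cr <- function(a0, a1, a2, t) 1.3 + a0 * (1 - exp(a1 * t))^a2
oracle_hiv <- function(b0, b1, b2, t) 1.3 + (b0 * t^b1 / (b2 + t^(b1 - 1)))^(1 / 3)
oracle_sch <- function(c0, c1, c2, t) 1.3 + exp(c0 + c1 * t^c2)

# small, fast simulated datasets for unit tests
sim_small <- function(parameterization = "gada", family = "CR", n_trees = 12,
                      seed = 1, sigma2 = NULL, age_range = c(70, 120)) {
  simulate_trees(sim_config(n_trees = n_trees, family = family,
                            parameterization = parameterization,
                            sigma2 = sigma2, age_range = age_range),
                 seed = seed)
}

fast_ctrl <- function(...) si_control(n_starts = 1, ...)

# representative published-scale global parameter sets used across tests
tbl_gada <- list(
  CR  = gada_globals("CR", a1 = -0.00955, a20 = -1.7580, a21 = 11.6209),
  HIV = gada_globals("HIV", b00 = 59.67, b1 = 3.5702, b20 = 44542000),
  SCH = gada_globals("SCH", c10 = -158.87, c11 = 28.7682, c2 = -0.3878)
)
tbl_opt <- list(
  CR  = ggada_globals("CR", "optimal", a1 = -0.00921, a20 = -9.6725,
                      a21 = 6.7925, a22 = -1.0247),
  HIV = ggada_globals("HIV", "optimal", b10 = 3.2877, b11 = 0.0003071,
                      b20 = 306100, b21 = -604.5),
  SCH = ggada_globals("SCH", "optimal", c00 = 3.1159, c01 = -2.1849,
                      c1 = -11.7934)
)
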
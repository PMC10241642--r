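## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

## desk-scale packings reused across structure/transport tests
glass_cv10_050 <- function() fixture("glass_cv10_050", function()
  generate_packing(glass_recipe(n_particles = 500, sigma1 = 31,
                                target_fill = 0.50, quench_steps = 15000,
                                seed = 42)))

glass_cv03_045 <- function() fixture("glass_cv03_045", function()
  generate_packing(glass_recipe(n_particles = 500, sigma1 = 1,
                                target_fill = 0.45, quench_steps = 15000,
                                seed = 43)))

glass_cv03_050 <- function() fixture("glass_cv03_050", function()
  generate_packing(glass_recipe(n_particles = 500, sigma1 = 1,
                                target_fill = 0.50, quench_steps = 15000,
                                seed = 51)))

te_calibration <- function() fixture("te_calibration", function()
  calibration_curve(diameter = 430, n_r_fixed = 1.50))

## synthetic configurations with prescribed geometry
make_config <- function(positions, box, diameters) {
  structure(list(box = box, positions = positions,
                 diameters = rep_len(diameters, nrow(positions))),
            class = "particle_configuration")
}

poisson_config <- function(n, box, diameter, seed = 1) {
  set.seed(seed)
  make_config(matrix(runif(3 * n, 0, box), ncol = 3), box, diameter)
}

sc_config <- function(cells = 6, a = 350, diameter = 305) {
  g <- (as.matrix(expand.grid(seq_len(cells), seq_len(cells),
                              seq_len(cells))) - 0.5) * a
  make_config(g, cells * a, diameter)
}

fcc_config <- function(cells = 4, nn_dist = 305, diameter = 305) {
  a <- nn_dist * sqrt(2)
  base <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  g <- as.matrix(expand.grid(0:(cells - 1), 0:(cells - 1), 0:(cells - 1)))
  pos <- do.call(rbind, lapply(seq_len(nrow(g)), function(i)
    sweep(base, 2, g[i, ], "+"))) * a
  make_config(pos, cells * a, diameter)
}
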
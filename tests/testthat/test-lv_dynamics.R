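mixed_community <- function(alpha = 0.5, model = "freqdep") {
  default_community(alphas = interaction_matrix(alpha, alpha, alpha,
                                                alpha, alpha, alpha),
                    model = model)
}

test_that("classic derivatives match the hand-evaluated formulas", {
  comm <- mixed_community(0.5, model = "classic")
  got <- derivatives_classic(c(N_E = 1e7, N_Y = 1e7, N_B = 1e7), comm)
  # values evaluated by hand from the three rate equations:
  # E: 1e7*0.7*(1 - 2e7/1e9) = 6.86e6; Y: 1e7*0.35*(1 - 2e7/1e8) = 2.8e6;
  # B: 1e7*0.6*(1 - 2e7/1e9) = 5.88e6
  expect_equal(unname(got), c(6.86e6, 2.80e6, 5.88e6), tolerance = 1e-12)
  # logistic limit: all alpha = 0 and N at K/2 gives rK/4
  comm0 <- mixed_community(0)
  half <- c(N_E = 5e8, N_Y = 5e7, N_B = 5e8)
  expect_equal(unname(derivatives_classic(half, comm0)),
               c(0.7 * 1e9 / 4, 0.35 * 1e8 / 4, 0.6 * 1e9 / 4))
  # equilibrium at carrying capacity
  expect_equal(unname(derivatives_classic(c(N_E = 1e9, N_Y = 1e8, N_B = 1e9),
                                          comm0)), c(0, 0, 0))
})

test_that("frequency-dependent derivatives match the hand-evaluated formulas", {
  comm <- mixed_community(0.5)
  got <- derivatives_freqdep(c(N_E = 1e7, N_Y = 1e7, N_B = 1e7), comm)
  # equal abundances give frequency weights of 1/3:
  # E: 7e6*(1 - (1e7 + 2*0.5*(1/3)*1e7)/1e9) = 7e6*74/75
  # Y: 3.5e6*(1 - (1e7 + 2*0.5*(1/3)*1e7)/1e8) = 3.5e6*13/15
  # B: 6e6*74/75
  expect_equal(unname(got),
               c(7e6 * 74 / 75, 3.5e6 * 13 / 15, 6e6 * 74 / 75),
               tolerance = 1e-12)
  # agreement with independent transcription at random states
  set.seed(3)
  for (i in 1:20) {
    N <- 10^runif(3, 3, 9)
    state <- c(N_E = N[1], N_Y = N[2], N_B = N[3])
    expect_equal(unname(derivatives_freqdep(state, comm)),
                 unname(oracle_rates_freqdep(N, c(0.7, 0.35, 0.6),
                                             c(1e9, 1e8, 1e9),
                                             oracle_alphas(0.5))))
    expect_equal(unname(derivatives_classic(state, comm)),
                 unname(oracle_rates_classic(N, c(0.7, 0.35, 0.6),
                                             c(1e9, 1e8, 1e9),
                                             oracle_alphas(0.5))))
  }
})

test_that("the two models coincide when interactions vanish or B is absent", {
  comm0 <- mixed_community(0)
  set.seed(4)
  for (i in 1:10) {
    state <- c(N_E = 10^runif(1, 3, 9), N_Y = 10^runif(1, 3, 8),
               N_B = 10^runif(1, 3, 9))
    expect_equal(derivatives_freqdep(state, comm0),
                 derivatives_classic(state, comm0))
  }
  # N_B = 0: B terms vanish, E and Y follow the two-species freq-dep model
  comm <- mixed_community(0.3)
  state <- c(N_E = 2e8, N_Y = 3e7, N_B = 0)
  got <- derivatives_freqdep(state, comm)
  tot <- 2e8 + 3e7
  expect_equal(unname(got["N_E"]),
               2e8 * 0.7 * (1 - (2e8 + 0.3 * (3e7 / tot) * 3e7) / 1e9))
  expect_equal(unname(got["N_Y"]),
               3e7 * 0.35 * (1 - (3e7 + 0.3 * (2e8 / tot) * 2e8) / 1e8))
  expect_equal(unname(got["N_B"]), 0)
  # zero total population: all rates zero
  expect_equal(unname(derivatives_freqdep(c(N_E = 0, N_Y = 0, N_B = 0), comm)),
               c(0, 0, 0))
})

test_that("batch integration reproduces the logistic closed form when alpha = 0", {
  for (model in c("classic", "freqdep")) {
    comm <- mixed_community(0, model = model)
    traj <- integrate_batch(comm, t_end = 24)
    df <- as.data.frame(traj)
    expect_equal(df$N_E, oracle_logistic(df$time_h, 1e9, 0.7, 1e7),
                 tolerance = 1e-6)
    expect_equal(df$N_Y, oracle_logistic(df$time_h, 1e8, 0.35, 1e7),
                 tolerance = 1e-6)
    expect_equal(df$N_B, oracle_logistic(df$time_h, 1e9, 0.6, 1e7),
                 tolerance = 1e-6)
  }
})

test_that("integrator endpoints agree with a fine-step RK4 oracle", {
  set.seed(9)
  for (i in 1:4) {
    r <- runif(3, 0.2, 1.0); K <- 10^runif(3, 7.5, 9.5); N0 <- 10^runif(3, 5, 7)
    a <- setNames(runif(6, 0, 2), names(oracle_alphas()))
    comm <- lv_community(
      E = species_params("E", r[1], K[1], N0[1]),
      Y = species_params("Y", r[2], K[2], N0[2]),
      B = species_params("B", r[3], K[3], N0[3]),
      alphas = do.call(interaction_matrix, as.list(a)), model = "freqdep")
    got <- final_state(integrate_batch(comm, t_end = 24, grid = c(0, 24)))
    want <- oracle_rk4(N0, r, K, a, t_end = 24)
    expect_equal(unname(got), unname(want), tolerance = 1e-4)
  }
})

test_that("an absent species stays exactly absent and populations stay bounded", {
  comm <- lv_community(
    E = species_params("E", 0.7, 1e9, 1e7),
    Y = species_params("Y", 0.35, 1e8, 1e7),
    B = species_params("B", 0.6, 1e9, 0),
    alphas = interaction_matrix(0.4, 0.4, 0.4, 0.4, 0.4, 0.4))
  df <- as.data.frame(integrate_batch(comm))
  expect_true(all(df$N_B == 0))
  # non-negativity / boundedness across a seeded battery
  set.seed(12)
  for (i in 1:5) {
    a <- setNames(runif(6, 0, 3), names(oracle_alphas()))
    comm <- default_community(alphas = do.call(interaction_matrix, as.list(a)))
    df <- as.data.frame(integrate_batch(comm))
    for (col in c("N_E", "N_Y", "N_B")) expect_true(all(df[[col]] >= 0))
    expect_true(all(df$N_E <= max(1e7, 1e9) * (1 + 1e-6)))
    expect_true(all(df$N_Y <= max(1e7, 1e8) * (1 + 1e-6)))
    expect_true(all(df$N_B <= max(1e7, 1e9) * (1 + 1e-6)))
  }
})

test_that("serial transfer applies exact dilution at cycle boundaries", {
  comm <- mixed_community(0.01)
  traj <- simulate_serial_transfer(comm, n_cycles = 3, dilution_factor = 2^-10)
  df <- as.data.frame(traj)
  for (k in 1:2) {
    end_k <- df[df$cycle == k, ][sum(df$cycle == k), ]
    start_k1 <- df[df$cycle == k + 1, ][1, ]
    for (col in c("N_E", "N_Y", "N_B"))
      expect_identical(start_k1[[col]], end_k[[col]] * 2^-10)
  }
  # dilution_factor = 1: populations continuous across the boundary
  traj1 <- simulate_serial_transfer(comm, n_cycles = 2, dilution_factor = 1)
  df1 <- as.data.frame(traj1)
  end1 <- df1[df1$cycle == 1, ][sum(df1$cycle == 1), ]
  start2 <- df1[df1$cycle == 2, ][1, ]
  expect_equal(unlist(start2[c("N_E", "N_Y", "N_B")]),
               unlist(end1[c("N_E", "N_Y", "N_B")]))
})

test_that("a lone species regrows to carrying capacity every cycle", {
  comm <- lv_community(
    E = species_params("E", 0.7, 1e9, 1e7),
    Y = species_params("Y", 0.35, 1e8, 0),
    B = species_params("B", 0.6, 1e9, 0),
    alphas = interaction_matrix(0, 0, 0, 0, 0, 0))
  df <- as.data.frame(simulate_serial_transfer(comm, n_cycles = 4))
  ends <- sapply(split(df, df$cycle), function(x) x$N_E[nrow(x)])
  expect_true(all(ends > 0.99e9))
  # 10 doublings per cycle at the default two-step 1:2^5 protocol
  expect_equal(log2(1 / 2^-10), 10)
})

test_that("two-species equilibrium frequency is independent of starting ratio", {
  run_from <- function(NE0, NY0) {
    comm <- lv_community(
      E = species_params("E", 0.7, 1e9, NE0),
      Y = species_params("Y", 0.35, 1e8, NY0),
      B = species_params("B", 0.6, 1e9, 0),
      alphas = interaction_matrix(0.01, 0.01, 0.01, 0.01, 0.01, 0.01))
    df <- as.data.frame(simulate_serial_transfer(comm, n_cycles = 7))
    fs <- unlist(df[nrow(df), c("N_E", "N_Y")])
    fs["N_E"] / sum(fs)
  }
  f_low <- run_from(1e6, 1e7)   # E rare, 1:10
  f_high <- run_from(1e7, 1e6)  # E common, 10:1
  expect_lt(abs(f_low - f_high), 0.01)
  expect_gt(f_low, 0.5)  # E. coli is the majority partner at equilibrium
})

test_that("invasion protocol equilibrates the pair before introducing the competitor", {
  comm <- mixed_community(0.01)
  traj <- simulate_invasion(comm, equilibration_cycles = 3, total_cycles = 6)
  df <- as.data.frame(traj)
  expect_identical(attr(traj, "introduction_cycle"), 4L)
  expect_true(all(df$N_B[df$cycle <= 3] == 0))
  expect_identical(df$N_B[which(df$cycle == 4)[1]], comm$B$N0)
  # null invasion: introducing at density 0 equals the pair-only transfer
  null_inv <- simulate_invasion(comm, invader_N0 = 0, equilibration_cycles = 3,
                                total_cycles = 6)
  pair <- simulate_serial_transfer(comm, n_cycles = 6,
                                   state = c(N_E = 1e7, N_Y = 1e7, N_B = 0))
  expect_equal(as.data.frame(null_inv), as.data.frame(pair))
  # equilibration_cycles = 0 equals a three-species serial transfer
  inv0 <- simulate_invasion(comm, equilibration_cycles = 0, total_cycles = 4)
  st <- simulate_serial_transfer(comm, n_cycles = 4)
  expect_equal(as.data.frame(inv0), as.data.frame(st))
})

test_that("a strongly suppressed invader is driven extinct within two cycles", {
  comm <- default_community(
    alphas = interaction_matrix(alpha_EY = 0.01, alpha_EB = 0.01,
                                alpha_YB = 0.01, alpha_YE = 0.01,
                                alpha_BY = 0.01, alpha_BE = 3))
  traj <- simulate_invasion(comm, equilibration_cycles = 3, total_cycles = 5)
  df <- as.data.frame(traj)
  end5 <- df[df$cycle == 5, ][sum(df$cycle == 5), ]
  label <- classify_simulation(unlist(end5[c("N_E", "N_Y", "N_B")]))
  expect_identical(label$category, "competitor_extinct")
})

test_that("protocol arithmetic and the extinction rationale reproduce the stated figures", {
  expect_identical(protocol_generations(7, 2^-10), 70)
  expect_identical(protocol_generations(1, 2^-10), 10)
  # a threshold-sized population under daily 1000x dilution and tenfold
  # suppressed regrowth: 10^4 -> 100 after one day, gone on the second
  expect_identical(extinction_rationale(1e4), c(100, 0))
})
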
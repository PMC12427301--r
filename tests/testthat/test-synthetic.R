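true_allM_karyotype <- function(cfg, ci = 43) {
  karyotype("true", data.frame(
    index = seq_len(cfg$n_pairs), rl_mean = cfg$rl_profile, rl_sd = 0,
    ci_mean = rep(ci, cfg$n_pairs), ci_sd = 0, shape = "M",
    stringsAsFactors = FALSE))
}

test_that("sim_config validates its stated world", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(1, rl_profile = c(10, 20, 70)), "decreasing")
  expect_error(sim_config(1, rl_sd = -1), "non-negative")
  cfg <- sim_config(1)
  expect_equal(sum(cfg$rl_profile), 100, tolerance = 1e-9)
  expect_equal(cfg$n_replicates, 5L)  # five metaphase plates
})

test_that("measurement simulation: zero noise returns truth; fixed seed
          reruns identically; rl stays normalized", {
  cfg0 <- sim_config(seed = 3, rl_sd = 0, ci_sd = 0)
  k0 <- simulate_measurements(true_allM_karyotype(cfg0), cfg0)
  expect_equal(k0$pairs$rl_mean, cfg0$rl_profile, tolerance = 1e-12)
  expect_equal(unique(k0$pairs$rl_sd), 0)
  expect_equal(unique(k0$pairs$ci_mean), 43)
  cfg <- sim_config(seed = 4)
  k1 <- simulate_measurements(true_allM_karyotype(cfg), cfg)
  k2 <- simulate_measurements(true_allM_karyotype(cfg), cfg)
  expect_identical(k1, k2)
  expect_equal(sum(k1$pairs$rl_mean), 100, tolerance = 1e-9)
  expect_true(all(k1$pairs$ci_mean >= 0 & k1$pairs$ci_mean <= 50))
})

test_that("classification recovers nearly all true shapes at table-scale
          noise when true values sit clear of the boundaries", {
  # true ci values at least 2 SD (= 4 points) from any class boundary
  classes <- rep(c("M", "sM", "sT", "T"), each = 6)
  ci_true <- rep(c(44, 31, 19, 6), each = 6)
  rl <- 100 * seq(7.5, 1.9, length.out = 24) / sum(seq(7.5, 1.9,
                                                       length.out = 24))
  truth <- karyotype("truth", data.frame(
    index = 1:24, rl_mean = rl, rl_sd = 0, ci_mean = ci_true, ci_sd = 0,
    shape = classes, stringsAsFactors = FALSE))
  hits <- vapply(1:200, function(s) {
    cfg <- sim_config(seed = s, rl_sd = 0.5, ci_sd = 2)
    meas <- simulate_measurements(truth, cfg)
    sum(classify_shape(meas$pairs$ci_mean) == classes)
  }, 0)
  expect_true(all(hits >= 22))
  expect_gt(mean(hits), 23.5)
})

test_that("evolution simulation: zero rates copy the root everywhere", {
  cfg <- sim_config(seed = 5, tree = "((A,B),(C,D));", inversion_rate = 0,
                    translocation_rate = 0)
  sim <- simulate_karyotype_evolution(cfg)
  expect_equal(nrow(sim$events), 0L)
  for (k in sim$karyotypes) {
    expect_equal(k$pairs$shape, rep("M", cfg$n_pairs))
    expect_equal(k$pairs$rl_mean, cfg$rl_profile)
  }
})

test_that("evolution simulation is seed-deterministic and events match the
          leaf states they claim to produce", {
  cfg <- sim_config(seed = 11, tree = "((A,B),(C,D));",
                    inversion_rate = 0.8, translocation_rate = 0.2)
  s1 <- simulate_karyotype_evolution(cfg)
  s2 <- simulate_karyotype_evolution(cfg)
  expect_identical(s1$karyotypes, s2$karyotypes)
  expect_identical(s1$events, s2$events)
  expect_equal(unname(s1$totals),
               unname(c(sum(s1$events$kind == "inversion"),
                        sum(s1$events$kind == "translocation"))))
  # every fusion drops the diploid number of the subtree below it by 2
  for (k in s1$karyotypes) {
    expect_equal(k$diploid_number %% 2L, 0L)
    expect_lte(k$diploid_number, 2L * cfg$n_pairs)
  }
})

test_that("leaf shapes always agree with their centromeric indices", {
  for (s in 1:10) {
    cfg <- sim_config(seed = s, tree = "((A,B),(C,D));",
                      inversion_rate = 1)
    sim <- simulate_karyotype_evolution(cfg)
    for (k in sim$karyotypes) {
      expect_equal(classify_shape(k$pairs$ci_mean), k$pairs$shape)
    }
  }
})

test_that("JC simulation: zero rate keeps all leaves identical; two-leaf
          p-distance matches the closed form", {
  cfg0 <- sim_config(seed = 6, tree = "(a,b,c);", subst_rate = 0,
                     n_sites = 100)
  aln0 <- simulate_alignment_jc(cfg0)
  expect_equal(p_distance(aln0$mat[1, ], aln0$mat[2, ]), 0)
  expect_equal(p_distance(aln0$mat[1, ], aln0$mat[3, ]), 0)
  # E[p] = 3/4 (1 - exp(-4 d / 3)) at total path length d
  d <- 0.3
  cfg <- sim_config(seed = 7, tree = sprintf("(a:%f,b:%f);", d / 2, d / 2),
                    n_sites = 10000)
  aln <- simulate_alignment_jc(cfg)
  p_obs <- p_distance(aln$mat[1, ], aln$mat[2, ])
  p_exp <- 0.75 * (1 - exp(-4 * d / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 4 * se)
})

test_that("generators are pure functions of (config, seed) and do not
          disturb the caller's RNG", {
  set.seed(123)
  before <- .Random.seed
  cfg <- sim_config(seed = 8, tree = "(a:0.1,b:0.1);", n_sites = 50)
  invisible(simulate_alignment_jc(cfg))
  expect_identical(.Random.seed, before)
})
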
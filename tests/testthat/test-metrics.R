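test_that("plug-in entropy: degenerate, uniform, and near-asymptotic cases", {
  expect_equal(entropy_bits(rep("a", 4)), 0)
  expect_equal(entropy_bits(c("a", "b", "a", "b")), 1)
  set.seed(31)
  x <- sample(1:8, 1000, replace = TRUE)
  expect_lt(abs(entropy_bits(x) - 3), 0.05)
  expect_error(entropy_bits(numeric(0)), "empty")
})

test_that("plug-in MI: identity and independence are exact, bounds hold", {
  x <- rep(1:4, 250)
  expect_equal(mutual_information(x, x), 2)  # uniform identity channel

  grid <- expand.grid(x = 1:3, y = 1:5)      # exact factorial joint
  expect_equal(mutual_information(grid$x, grid$y), 0)

  set.seed(37)
  for (i in 1:5) {
    a <- sample(1:6, 400, replace = TRUE)
    b <- sample(1:3, 400, replace = TRUE)
    mi <- mutual_information(a, b)
    expect_gte(mi, 0)
    expect_lte(mi, min(entropy_bits(a), entropy_bits(b)) + 1e-12)
  }
})

test_that("plug-in MI converges to the exact double-sum on an analytic binomial channel", {
  exact <- mi_from_joint(binom_channel_joint(10, 0.2, 0.8))
  set.seed(41)
  draw <- function(n) {
    x <- stats::rbinom(n, 1, 0.5)
    y <- stats::rbinom(n, 10, ifelse(x == 0, 0.2, 0.8))
    mutual_information(x, y)
  }
  coarse <- draw(1000)
  fine <- draw(100000)
  expect_lt(abs(fine - exact), 0.02)
  # consistency: the estimate tightens with sample size
  expect_lt(abs(fine - exact), abs(coarse - exact) + 0.02)
})

test_that("conditional entropy and the chain-rule identity", {
  x <- rep(1:4, 100)
  expect_equal(conditional_entropy(x, x), 0)
  expect_equal(conditional_entropy(x, rep(1, 400)), entropy_bits(x))
  set.seed(43)
  for (i in 1:5) {
    a <- sample(1:5, 500, replace = TRUE)
    b <- sample(1:4, 500, replace = TRUE)
    expect_equal(entropy_bits(a) - conditional_entropy(a, b),
                 mutual_information(a, b), tolerance = 1e-12)
  }
})

test_that("equal-width binning discretizes continuous inputs", {
  set.seed(47)
  x <- runif(2000)
  b <- binning_spec("width", n_bins = 8)
  expect_lt(abs(entropy_bits(x, b) - 3), 0.05)   # ~uniform over 8 bins
  expect_equal(entropy_bits(rep(0.5, 10), b), 0) # constant sample, one bin
  expect_error(binning_spec("width", n_bins = 1), "n_bins")
})

test_that("per-cell MI is the four-channel sum over the allocation group", {
  # scripted toy log: AR a noiseless binary channel (1 bit), AL constant
  # input (0 bits), BR an input-independent output (0 bits), BL identity
  # over four symbols (2 bits)
  ins <- rep(c(1, 3), each = 4)
  log <- data.frame(t = rep(1:4, 2), atot = 200,
                    in_ar = ins, out_ar = ins * 10,
                    in_al = 2, out_al = rep(c(0, 1), 4),
                    in_br = ins, out_br = 7,
                    in_bl = rep(1:4, 2), out_bl = rep(1:4, 2))
  tab <- channel_mi(log, min_group_n = 1)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$mi_ar, 1)
  expect_equal(tab$mi_al, 0)
  expect_equal(tab$mi_br, 0)
  expect_equal(tab$mi_bl, 2)
  expect_equal(tab$mi_cell, 3)
  expect_equal(mi_cell(log, 200, min_group_n = 1), 3)
  # cross-check against the independent double-sum oracle per channel
  oracle <- mi_from_joint(table(log$in_ar, log$out_ar)) +
    mi_from_joint(table(log$in_al, log$out_al)) +
    mi_from_joint(table(log$in_br, log$out_br)) +
    mi_from_joint(table(log$in_bl, log$out_bl))
  expect_equal(tab$mi_cell, oracle, tolerance = 1e-12)
})

test_that("population averages weight every (cell, t) occurrence equally", {
  # two allocation groups with per-cell MI 4 and 0, equally occupied
  g1 <- data.frame(t = rep(1:5, each = 2), atot = 100,
                   in_ar = rep(1:2, 5), out_ar = rep(1:2, 5),
                   in_al = rep(1:2, 5), out_al = rep(1:2, 5),
                   in_br = rep(1:2, 5), out_br = rep(1:2, 5),
                   in_bl = rep(1:2, 5), out_bl = rep(1:2, 5))
  g2 <- g1
  g2$atot <- 300
  g2[, c("out_ar", "out_al", "out_br", "out_bl")] <- 9  # constant outputs
  log <- rbind(g1, g2)
  expect_equal(mi_average(log, min_group_n = 1), 2)  # (4 + 0) / 2
  # SI: every step sees one cell of each kind -> population sd of {4, 0} = 2
  expect_equal(subjective_information(log, min_group_n = 1), 2)
  # a lone cell at an extra step contributes zero spread (the extra row joins
  # the constant-output group, whose MI stays 0)
  extra <- g2[1, ]
  extra$t <- 6
  expect_equal(subjective_information(rbind(log, extra), min_group_n = 1),
               mean(c(rep(2, 5), 0)))
  expect_error(mi_average(log[0, ]), "empty")
})

test_that("sparse allocation groups merge into their nearest neighbour", {
  base <- data.frame(t = 1, atot = 200,
                     in_ar = 1, out_ar = 1, in_al = 1, out_al = 1,
                     in_br = 1, out_br = 1, in_bl = 1, out_bl = 1)
  log <- do.call(rbind, c(replicate(12, base, simplify = FALSE),
                          list(transform(base, atot = 210)),
                          list(transform(base, atot = 390))))
  tab <- channel_mi(log, min_group_n = 10)
  expect_equal(tab$group, 200)           # singletons absorbed by the big key
  expect_equal(tab$n, 14)
})

test_that("growth rate: doublings, plateaus, rescaling invariance, extinction", {
  expect_equal(growth_rate(c(100, 200, 400, 800)), 1)
  expect_equal(growth_rate(rep(42, 10)), 0)
  expect_equal(growth_rate(c(100, 200, 100, 200, 100)), 0)  # telescoping mean
  set.seed(53)
  p <- cumprod(c(100, runif(20, 0.8, 2.5)))
  expect_equal(growth_rate(p), growth_rate(7.3 * p))        # multiplier-proof
  expect_equal(growth_rate(p, transient = 5),
               mean(log2(p[-1] / p[-21])[6:20]))
  expect_true(is.na(growth_rate(c(100, 50, 0, 0))))
  expect_error(growth_rate(c(100, 200), transient = 1), "transient")
})

test_that("cell stress is the break-even concentration S / k", {
  expect_equal(cell_stress(1, 1), 1)
  expect_equal(cell_stress(1, 5), 0.2)
  expect_equal(cell_stress(5, 5), 1)
  expect_error(cell_stress(1, 0), "k")
})

test_that("run-level metrics: a single allocation group collapses the averages", {
  sim <- run_simulation(small_config(strategy = "equal"))
  m <- compute_metrics(sim)
  expect_identical(m$SI, 0)                       # one group, zero spread
  expect_equal(nrow(m$groups), 1)
  expect_equal(m$MI_T, m$groups$mi_cell)          # MI(T) = the group estimate
  expect_equal(m$H_X - m$H_XgY, m$MI_T, tolerance = 1e-12)
  expect_equal(m$c_star, 1)
  # growth metric matches a direct computation on the stored series
  expect_equal(m$GT, growth_rate(sim$real_counts, transient = sim$transient_steps))
})
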
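test_that("pair error counts unordered-pair mismatches", {
  t <- worked_truth()
  expect_equal(pair_error(t, t), 0)
  swapped <- lapply(t, function(p) p[, 2:1])
  expect_equal(pair_error(t, swapped), 0)
  i2 <- t
  i2[[1]] <- flip_haplotypes(t[[1]], 1L)  # a single flipped SNP mis-infers
  expect_equal(pair_error(t, i2), 1 / 3)
  i3 <- t
  i3[[2]] <- cbind(c(1, 1, 1), c(1, 0, 1))
  expect_equal(pair_error(t[1:2], i3[1:2]), 0.5)
})

test_that("switch error rate uses orientation-minimizing het mismatches", {
  t <- list(cbind(c(0, 0, 0, 0), c(1, 1, 1, 1)))
  expect_equal(switch_error(t, t), 0)
  expect_equal(switch_error(t, list(t[[1]][, 2:1])), 0)  # wholesale swap
  i <- list(cbind(c(0, 0, 1, 1), c(1, 1, 0, 0)))
  expect_equal(switch_error(t, i), 1)  # 2 mismatches over worst case 4/2
  # all-homozygous truth: denominator is empty, rate defined as 0
  th <- list(cbind(c(0, 0), c(0, 0)))
  expect_equal(switch_error(th, list(cbind(c(1, 1), c(1, 1)))), 0)
})

test_that("prediction error scores hidden-homozygous sites", {
  t <- worked_truth()
  expect_equal(prediction_error(t, t), 0)
  # flipping locus 1 (homozygous in all three) mis-predicts it everywhere
  i <- lapply(t, flip_haplotypes, S = 1L)
  chi <- c(1, 1, 2)
  expect_equal(prediction_error(t, i), 3 / sum(3 - chi))
  expect_equal(switch_error(t, i), 0)  # flips do not touch het phasing
})

test_that("diversity ratio counts distinct haplotypes in use", {
  fit <- xhsd(worked_example())
  expect_equal(diversity_ratio(fit), 1)
  shared <- replicate(4, cbind(c(0, 1), c(0, 1)), simplify = FALSE)
  expect_equal(diversity_ratio(shared), 1 / 4)
  private <- list(cbind(c(0, 0), c(1, 1)), cbind(c(0, 1), c(1, 0)))
  expect_equal(diversity_ratio(private), 2)
})

test_that("metrics are invariant to within-pair swaps", {
  set.seed(151)
  pool <- gen_pool(4, 6, seed = 152)
  sim <- gen_population(pool, 8, seed = 153)
  fit <- xhsd(sim$data, max_block = 6)
  t <- truth_pairs(sim)
  i <- haplotype_pairs(fit)
  iswap <- lapply(i, function(p) p[, 2:1])
  tswap <- lapply(t, function(p) p[, 2:1])
  expect_equal(switch_error(t, i), switch_error(tswap, iswap))
  expect_equal(prediction_error(t, i), prediction_error(t, iswap))
  expect_equal(pair_error(t, i), pair_error(tswap, iswap))
})

test_that("best-flip search recovers a planted flip exactly", {
  set.seed(161)
  for (r in 1:5) {
    pool <- gen_pool(4, 7, seed = 160 + r)
    sim <- gen_population(pool, 6, seed = 170 + r)
    t <- truth_pairs(sim)
    S <- sample(7, sample(1:4, 1))
    i <- lapply(t, flip_haplotypes, S = S)
    m <- best_flip_evaluate(t, i)
    expect_equal(m$P_e, 0)
    expect_equal(m$swr, 0)
    expect_equal(m$err_p, 0)
    expect_equal(m$flip_mode, "best_exhaustive")
  }
})

test_that("best-flip evaluation never reports worse totals than unflipped", {
  pool <- gen_pool(4, 7, seed = 181)
  sim <- gen_population(pool, 10, alpha = 2, seed = 182)
  fit <- xhsd(sim$data, max_block = 7)
  t <- truth_pairs(sim)
  tot <- function(m) sum(m$per_individual$miss_het + m$per_individual$miss_hom)
  plain <- phasing_metrics(t, fit)
  ex <- best_flip_evaluate(t, fit)
  expect_lte(tot(ex), tot(plain))
  # coordinate descent is valid but never beats the exhaustive optimum
  cd <- best_flip_evaluate(t, fit, L_max_exact = 0, seed = 3)
  expect_equal(cd$flip_mode, "best_search")
  expect_gte(tot(cd), tot(ex))
  expect_lte(tot(cd), tot(plain))
})

test_that("metrics reports carry all four statistics and serialize to JSON", {
  fit <- xhsd(worked_example())
  m <- phasing_metrics(worked_truth(), fit)
  expect_s3_class(m, "xhsd_metrics")
  expect_true(all(c(m$P_e, m$swr, m$err_p) >= 0))
  expect_true(m$rho > 0 && m$rho <= 2)
  expect_output(print(m), "switch error")
  path <- tempfile(fileext = ".json")
  write_metrics(m, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$P_e, m$P_e)
  expect_equal(js$rho, m$rho)
})
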
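test_that("frequency tallies come from the indicator multiplicities", {
  ind <- list(list(support = 7L, mult = 2L))
  expect_equal(block_frequencies(ind, 1), c(`7` = 1))
  ind2 <- list(list(support = c(2L, 9L), mult = c(1L, 1L)),
               list(support = c(2L, 9L), mult = c(1L, 1L)))
  expect_equal(block_frequencies(ind2, 2), c(`2` = 0.5, `9` = 0.5))
  # worked example: each of the three haplotypes is used twice
  fit <- xhsd(worked_example())
  expect_equal(unname(fit$frequencies), rep(1 / 3, 3))
  expect_equal(sum(fit$frequencies), 1)
  usage <- tabulate(as.vector(fit$pairs), ncol(fit$haplotypes))
  expect_equal(unname(fit$frequencies), usage / 6)
})

test_that("block entropy is the natural-log Shannon entropy", {
  expect_equal(block_entropy(1), 0)
  expect_equal(block_entropy(c(0.5, 0.5)), log(2))
  expect_equal(round(block_entropy(c(0.5, 0.25, 0.25)), 4), 1.0397)
  expect_error(block_entropy(c(0.5, 0.4)), "sum to 1")
  expect_error(block_entropy(c(1.2, -0.2)), "positive")
})

test_that("short sequences yield a single block; zero-entropy ties split at W", {
  d <- random_pop(N = 5, L = 4, seed = 61)
  p <- partition_blocks(d, W = 6)
  expect_equal(nrow(p$blocks), 1L)
  expect_equal(c(p$blocks$l, p$blocks$m), c(1L, 4L))
  # identical all-homozygous individuals: every tiling has zero entropy
  d0 <- xhsd_data(matrix(0L, nrow = 6, ncol = 4))
  p0 <- partition_blocks(d0, W = 3)
  expect_equal(p0$total_entropy, 0)
  expect_equal(p0$blocks$l, c(1L, 4L))
  expect_equal(p0$blocks$m, c(3L, 6L))
})

test_that("the partition DP attains the exhaustive tiling minimum", {
  for (seed in 1:3) {
    pool <- gen_pool(3, 6, seed = 70 + seed)
    sim <- gen_population(pool, 6, alpha = 2, seed = 80 + seed)
    p <- partition_blocks(sim$data, W = 3)
    # structural invariants: contiguous cover, width capped
    expect_equal(p$blocks$l[1], 1L)
    expect_equal(p$blocks$m[nrow(p$blocks)], sim$data$L)
    if (nrow(p$blocks) > 1) {
      expect_equal(p$blocks$l[-1], p$blocks$m[-nrow(p$blocks)] + 1L)
    }
    expect_true(all(p$blocks$m - p$blocks$l + 1 <= 3))
    best <- min(vapply(all_tilings(sim$data$L, 3), function(w) {
      tiling_entropy(sim$data, w)
    }, numeric(1)))
    expect_equal(p$total_entropy, best, tolerance = 1e-9)
  }
})

test_that("ligation preserves per-individual xor reconstruction", {
  pool <- gen_pool(4, 12, seed = 91)
  sim <- gen_population(pool, 10, alpha = 2, seed = 92)
  fit <- xhsd(sim$data, max_block = 6)
  expect_false(is.null(fit$partition))
  expect_equal(predict(fit, "xor"), sim$data$values)
  expect_lte(ncol(fit$haplotypes), 2L * sim$data$N)
  # with missing sites, reconstruction must hold on observed loci
  dm <- inject_missing(sim$data, 0.1, seed = 93)
  fitm <- xhsd(dm, max_block = 6)
  obs <- !is.na(dm$values)
  expect_equal(predict(fitm, "xor")[obs], dm$values[obs])
})

test_that("greedy ligation matches the exhaustive join minimum on a toy", {
  # two individuals with identical block pairs across two blocks
  pool <- cbind(c(0, 0, 1, 1), c(1, 1, 0, 0))
  X <- vapply(1:2, function(i) xor_compose(pool[, 1], pool[, 2]),
              integer(4))
  d <- xhsd_data(X)
  ctrl <- xhsd_control(max_block = 2)
  part <- partition_blocks(d, W = 2, control = ctrl)
  greedy <- ligate(d, part, ctrl)
  exact <- ligate(d, part, ctrl, method = "exhaustive")
  expect_equal(ncol(greedy$haplotypes), ncol(exact$haplotypes))
  expect_lte(ncol(greedy$haplotypes), 2L)
  # forced junction: a block-homozygous individual has identical block pairs
  dz <- xhsd_data(matrix(c(1, 0, 0, 0, 1, 0, 0, 0), nrow = 4,
                         dimnames = list(NULL, c("a", "b"))))
  fitz <- xhsd(dz, max_block = 2)
  expect_equal(predict(fitz, "xor"), dz$values)
})
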
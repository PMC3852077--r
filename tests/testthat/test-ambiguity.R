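test_that("informative-set search finds minimal empty-intersection sets", {
  # an all-homozygous xor-genotype has an empty het set: singleton answer
  X <- cbind(c(1, 1, 0), c(0, 0, 0), c(0, 1, 1))
  m <- mti(X)
  expect_equal(m$individuals, 2L)
  expect_true(m$empty)
  # two individuals whose het sets intersect at locus 2
  X2 <- cbind(c(1, 1, 0), c(0, 1, 1))
  m2 <- mti(X2)
  expect_false(m2$empty)
  expect_equal(m2$residual_intersection, 2L)
  # adding 101: brute force says the minimum empty-intersection set has size 3
  X3 <- cbind(X2, c(1, 0, 1))
  hets <- lapply(1:3, function(i) which(X3[, i] == 1))
  expect_equal(oracle_min_informative(hets), 3L)
  m3 <- mti(X3)
  expect_true(m3$empty)
  expect_equal(m3$size, 3L)
})

test_that("informative-set size equals the brute-force minimum", {
  set.seed(31)
  for (r in 1:15) {
    N <- sample(4:10, 1)
    L <- sample(4:8, 1)
    X <- matrix(as.integer(runif(N * L) < 0.5), nrow = L)
    m <- mti(X, max_exact = N)
    hets <- lapply(seq_len(N), function(i) which(X[, i] == 1))
    want <- oracle_min_informative(hets)
    if (is.na(want)) {
      expect_false(m$empty)
    } else {
      expect_true(m$empty)
      expect_equal(m$size, want)
    }
    # covered loci: homozygous in at least one member
    hom <- X[, m$individuals, drop = FALSE] == 0
    expect_equal(m$covered_loci, which(rowSums(hom) > 0))
  }
})

test_that("repeated runs cover a target fraction with disjoint sets", {
  set.seed(37)
  X <- matrix(as.integer(runif(40 * 12) < 0.5), nrow = 12)
  sets <- mti_multi(X, 0.25)
  u <- attr(sets, "union")
  expect_gte(length(u), ceiling(0.25 * 40))
  members <- lapply(sets, `[[`, "individuals")
  expect_equal(anyDuplicated(unlist(members)), 0L)
  one <- mti_multi(X, 0.01)
  expect_length(one, 1L)
})

test_that("augmentation replaces observations and checks consistency", {
  d <- worked_example()
  G <- sapply(worked_truth(), function(p) p[, 1] + p[, 2])
  d2 <- augment(d, c(1, 2), G)
  expect_equal(d2$N, 3L)
  expect_equal(d2$kind, c("regular", "regular", "xor"))
  expect_equal(d2$bias, c(4, 4, 1))
  expect_equal(d2$values[, 1], G[, 1])
  expect_identical(augment(d, integer(0), G), d)
  Gbad <- G
  Gbad[3, 1] <- 0L  # het in xor, homozygous in the genotype
  expect_error(augment(d, 1, Gbad), "inconsisten")
})

test_that("locus flips are involutions that preserve xor-genotypes", {
  set.seed(41)
  H <- matrix(as.integer(runif(24) < 0.5), nrow = 6)
  S <- c(2L, 5L)
  expect_equal(flip_haplotypes(flip_haplotypes(H, S), S), H)
  expect_equal(flip_haplotypes(H, integer(0)), H)
  for (r in 1:10) {
    S <- sample(6, sample(0:6, 1))
    Hf <- flip_haplotypes(H, S)
    for (a in 1:3) for (b in 1:4) {
      expect_equal(xor_compose(Hf[, a], Hf[, b]), xor_compose(H[, a], H[, b]))
    }
  }
  expect_error(flip_haplotypes(H, 9L), "range")
})

test_that("the flip-equivalence class has 2^L - 1 nontrivial members", {
  expect_equal(count_equivalents(3), 7)
  expect_equal(count_equivalents(1), 1)
  # enumeration: flips of a singleton set are pairwise distinct
  for (L in 2:4) {
    H <- matrix(0L, nrow = L, ncol = 1)
    seen <- vapply(seq_len(2^L - 1), function(s) {
      S <- which(bitwAnd(bitwShiftR(s, 0:(L - 1)), 1L) == 1L)
      paste(flip_haplotypes(H, S), collapse = "")
    }, character(1))
    expect_equal(length(unique(seen)), 2^L - 1)
    expect_false(paste(H, collapse = "") %in% seen)
  }
})

test_that("set equivalence agrees with brute force over all flips", {
  set.seed(43)
  for (r in 1:20) {
    L <- sample(2:5, 1)
    K <- sample(1:4, 1)
    H <- matrix(as.integer(runif(L * K) < 0.5), nrow = L)
    S <- sample(L, sample(0:L, 1))
    eq <- set_equivalent(H, flip_haplotypes(H, S))
    expect_true(as.logical(eq))
    # random second set, answer checked exhaustively
    H2 <- matrix(as.integer(runif(L * K) < 0.5), nrow = L)
    brute <- any(vapply(0:(2^L - 1), function(s) {
      Sf <- which(bitwAnd(bitwShiftR(s, 0:(L - 1)), 1L) == 1L)
      setequal(apply(flip_haplotypes(H, Sf), 2, paste, collapse = ""),
               apply(H2, 2, paste, collapse = ""))
    }, logical(1)))
    expect_equal(as.logical(set_equivalent(H, H2)), brute)
  }
  expect_true(as.logical(set_equivalent(matrix(c(0, 0, 0)),
                                        matrix(c(0, 1, 1)))))
  expect_false(set_equivalent(cbind(c(0, 0, 0), c(0, 0, 1)),
                              cbind(c(0, 0, 0), c(0, 1, 0))))
})

test_that("post-processing flip votes recover an anchored solution", {
  d <- worked_example()
  truth <- worked_truth()
  G <- sapply(truth, function(p) p[, 1] + p[, 2])
  fit <- xhsd(d)
  before <- predict(fit, "xor")
  rf <- resolve_flips(fit, G)
  expect_equal(predict(rf$solution, "xor"), before)  # flip invariance
  m <- phasing_metrics(truth, rf$solution)
  expect_equal(m$err_p, 0)  # every homozygous allele agrees with the voters
  expect_true(all(rf$status[1:2] %in% c("forced", "voted")))
  # a deliberately flipped solution is voted back
  fit2 <- fit
  fit2$haplotypes <- flip_haplotypes(fit2$haplotypes, c(1L, 2L))
  rf2 <- resolve_flips(fit2, G)
  expect_equal(phasing_metrics(truth, rf2$solution)$err_p, 0)
  expect_true(set_equivalent(rf2$solution$haplotypes, rf$solution$haplotypes))
})

test_that("pre-processing augmentation anchors every covered locus", {
  w <- augmented_sim(4, 7, 15, alpha = 3, pool_seed = 51, pop_seed = 52,
                     fraction = 0.3)
  fit <- xhsd(w$data, max_block = 7)
  covered <- which(rowSums(
    !is.na(w$data$values[, w$data$kind == "regular", drop = FALSE]) &
      w$data$values[, w$data$kind == "regular", drop = FALSE] != 1L) > 0)
  expect_equal(which(fit$flip_status == "forced"), covered)
  expect_equal(fit$unresolved_loci, setdiff(seq_len(w$data$L), covered))
})
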
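# Shared fixtures and independent brute-force oracles.

# The three-individual, three-SNP xor population used throughout: 001, 010,
# 011 (loci in rows, individuals in columns).
worked_example <- function() {
  xhsd_data(matrix(c(0, 0, 1, 0, 1, 0, 0, 1, 1), nrow = 3))
}

# A haplotype-pair truth consistent with the worked example's xor-genotypes.
worked_truth <- function() {
  list(ind1 = cbind(c(0, 0, 0), c(0, 0, 1)),
       ind2 = cbind(c(0, 0, 0), c(0, 1, 0)),
       ind3 = cbind(c(0, 0, 1), c(0, 1, 0)))
}

# Independent support search: enumerate every support (singleton doubled or
# pair) with direct reconstruction arithmetic, no calls into the scoring path.
oracle_best_support <- function(values, kind, D) {
  L <- length(values)
  obs <- !is.na(values)
  D <- sort(unique(D))
  supports <- list()
  for (a in seq_along(D)) {
    supports[[length(supports) + 1L]] <- D[a]
    if (a < length(D)) for (b in (a + 1L):length(D)) {
      supports[[length(supports) + 1L]] <- c(D[a], D[b])
    }
  }
  best <- list(support = integer(0), residual = Inf)
  for (A in supports) {
    cols <- vapply(A, hap_column, integer(L), L = L)
    if (kind == "regular") {
      ok <- all(apply(cols, 2, function(z) {
        all((values[obs] - z[obs]) %in% c(0L, 1L))
      }))
      if (!ok) next
      recon <- if (length(A) == 1L) 2L * cols[, 1] else cols[, 1] + cols[, 2]
    } else {
      recon <- if (length(A) == 1L) rep(0L, L) else (cols[, 1] + cols[, 2]) %% 2L
    }
    r <- sum((values[obs] - recon[obs])^2)
    if (r < best$residual) best <- list(support = A, residual = r)
  }
  best
}

# Does a column subset explain every individual exactly?  Direct arithmetic.
oracle_explains_all <- function(data, subset) {
  L <- data$L
  cols <- vapply(subset, hap_column, integer(L), L = L)
  for (i in seq_len(data$N)) {
    v <- data$values[, i]
    obs <- !is.na(v)
    hit <- FALSE
    for (a in seq_along(subset)) {
      for (b in a:length(subset)) {
        recon <- if (data$kind[i] == "xor") (cols[, a] + cols[, b]) %% 2L
                 else cols[, a] + cols[, b]
        if (all(recon[obs] == v[obs])) {
          hit <- TRUE
          break
        }
      }
      if (hit) break
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

# Exhaustive minimum dictionary size by subset enumeration.
oracle_min_dict <- function(data) {
  M <- 2L^data$L
  for (s in 1:M) {
    combos <- utils::combn(M, s)
    for (ci in seq_len(ncol(combos))) {
      if (oracle_explains_all(data, combos[, ci])) return(s)
    }
  }
  stop("no explaining subset found")
}

# Exhaustive minimal informative-set size (empty het intersection).
oracle_min_informative <- function(hets) {
  N <- length(hets)
  for (s in 1:N) {
    combos <- utils::combn(N, s)
    for (ci in seq_len(ncol(combos))) {
      if (length(Reduce(intersect, hets[combos[, ci]])) == 0L) return(s)
    }
  }
  NA_integer_
}

# All contiguous tilings of 1..L with block width <= W, as lists of widths.
all_tilings <- function(L, W) {
  if (L == 0L) return(list(integer(0)))
  out <- list()
  for (w in seq_len(min(W, L))) {
    for (rest in all_tilings(L - w, W)) {
      out[[length(out) + 1L]] <- c(w, rest)
    }
  }
  out
}

# Total block entropy of a tiling, each block solved through the public
# surface (greedy fit + frequency tally).
tiling_entropy <- function(data, widths) {
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  sum(vapply(seq_along(widths), function(q) {
    bd <- xhsd_data(data$values[starts[q]:ends[q], , drop = FALSE],
                    kind = data$kind, ids = data$ids)
    f <- xhsd(bd, max_block = widths[q])$frequencies
    block_entropy(f[f > 0])
  }, numeric(1)))
}

# Simulate and apply the partial-genotyping workflow used by the recovery
# tests: select informative individuals until `fraction` of the population is
# covered, then replace their xor-genotypes by regular genotypes.
augmented_sim <- function(K, L, N, alpha, pool_seed, pop_seed,
                          fraction = 0.3) {
  pool <- gen_pool(K, L, seed = pool_seed)
  sim <- gen_population(pool, N, alpha = alpha, seed = pop_seed)
  aug <- attr(mti_multi(sim$data, fraction), "union")
  G <- truth_genotypes(sim)
  colnames(G) <- sim$data$ids
  list(sim = sim, aug = aug, G = G,
       data = augment(sim$data, aug, G))
}

# A-priori exact-recovery conditions: every pool haplotype used twice, all
# pairwise pool xors distinct and realized among the individuals, every
# all-homozygous individual genotyped, empty global het intersection.  Under
# these any K-column exact explanation is the pool up to a global flip, and
# the genotypes anchor the flip.
is_recoverable <- function(sim, aug_idx) {
  K <- ncol(sim$truth$pool)
  L <- sim$truth$L
  if (any(tabulate(as.vector(sim$truth$pairs), K) < 2L)) return(FALSE)
  codes <- apply(sim$truth$pool, 2, function(h) sum(h * 2^(seq_along(h) - 1)))
  px <- c()
  for (a in 1:(K - 1)) for (b in (a + 1):K) {
    px <- c(px, bitwXor(codes[a], codes[b]))
  }
  if (anyDuplicated(px)) return(FALSE)
  xc <- apply(sim$data$values, 2, function(v) sum(v * 2^(0:(L - 1))))
  if (!all(px %in% xc)) return(FALSE)
  if (!all(which(xc == 0) %in% aug_idx)) return(FALSE)
  hets <- lapply(seq_len(sim$truth$N),
                 function(i) which(sim$data$values[, i] == 1L))
  length(Reduce(intersect, hets)) == 0L
}

random_pop <- function(N, L, seed, p = 0.4) {
  set.seed(seed)
  xhsd_data(matrix(as.integer(stats::runif(N * L) < p), nrow = L))
}
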
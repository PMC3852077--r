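# Synthetic population generator: haplotype pool, random pairing,
# xor-genotyping, missing-site and typing-error injection.

#' Generate a haplotype pool
#'
#' Draws per-site minor-allele probabilities uniformly in [0.1, 0.9], samples
#' \code{K} sitewise-independent haplotypes, then applies \code{r}
#' crossover events, each recombining a random pair of pool members at a
#' random breakpoint (emulating recombination-driven mosaicism).  Pool
#' members are kept distinct (duplicates are re-sampled, bounded retries).
#'
#' @param K pool size (distinct haplotypes), \code{K <= 2^L}.
#' @param L locus count.
#' @param r number of crossover events.
#' @param seed RNG seed.
#' @return L x K 0/1 matrix with attributes \code{maf} and \code{seed}.
#' @export
gen_pool <- function(K, L, r = 0L, seed = NULL) {
  if (K < 1L || L < 1L) stop("K and L must be >= 1")
  if (K > 2^L) stop("cannot draw ", K, " distinct haplotypes of length ", L)
  with_seed(seed, {
    maf <- stats::runif(L, 0.1, 0.9)
    draw <- function() as.integer(stats::rbinom(L, 1L, maf))
    pool <- matrix(0L, L, K)
    keys <- character(0)
    for (j in seq_len(K)) {
      for (try in 1:1000) {
        h <- draw()
        key <- paste(h, collapse = "")
        if (!key %in% keys) break
      }
      if (key %in% keys) stop("failed to draw distinct pool haplotypes")
      pool[, j] <- h
      keys <- c(keys, key)
    }
    if (r > 0L && K >= 2L && L >= 2L) for (e in seq_len(r)) {
      for (try in 1:100) {
        ij <- sample.int(K, 2L)
        b <- sample.int(L - 1L, 1L)
        rec <- c(pool[1:b, ij[1]], pool[(b + 1L):L, ij[2]])
        key <- paste(rec, collapse = "")
        if (!key %in% keys[-ij[1]]) {
          keys[ij[1]] <- key
          pool[, ij[1]] <- rec
          break
        }
      }
    }
    attr(pool, "maf") <- maf
    attr(pool, "seed") <- seed
    pool
  })
}

#' Generate a population by random pairing from a haplotype pool
#'
#' Pool sampling weights are drawn from a symmetric Dirichlet(\code{alpha});
#' each individual is two independent draws, and its xor-genotype is the XOR
#' of the drawn pair.  The full truth (pool, weights, pairs) is retained for
#' evaluation.
#'
#' @param pool L x K haplotype matrix (see [gen_pool()]).
#' @param N number of individuals.
#' @param alpha Dirichlet concentration; smaller values concentrate sampling
#'   on fewer haplotypes (lower diversity); \code{Inf} gives uniform pairing.
#' @param seed RNG seed.
#' @return an object of class \code{xhsd_sim}: \code{data} (the xor
#'   [xhsd_data()]) and \code{truth} (class \code{xhsd_truth}: \code{pool},
#'   \code{freqs}, \code{pairs} (N x 2 pool indices), \code{L}, \code{N}).
#' @export
gen_population <- function(pool, N, alpha = 1, seed = NULL) {
  pool <- as.matrix(pool)
  K <- ncol(pool)
  if (K < 1L) stop("empty pool")
  if (N < 1L) stop("N must be >= 1")
  with_seed(seed, {
    w <- if (is.finite(alpha)) stats::rgamma(K, shape = alpha) else rep(1, K)
    if (all(w == 0)) w <- rep(1, K)
    w <- w / sum(w)
    pairs <- matrix(sample.int(K, 2L * N, replace = TRUE, prob = w), ncol = 2)
    X <- vapply(seq_len(N), function(i) {
      as.integer((pool[, pairs[i, 1]] + pool[, pairs[i, 2]]) %% 2L)
    }, integer(nrow(pool)))
    truth <- structure(list(pool = pool, freqs = w, pairs = pairs,
                            L = nrow(pool), N = N, seed = seed,
                            alpha = alpha),
                       class = "xhsd_truth")
    structure(list(data = xhsd_data(X, seed = seed), truth = truth),
              class = "xhsd_sim")
  })
}

#' @export
print.xhsd_sim <- function(x, ...) {
  cat("Simulated population: N = ", x$truth$N, ", L = ", x$truth$L,
      ", pool K = ", ncol(x$truth$pool), "\n", sep = "")
  invisible(x)
}

#' True haplotype pairs / regular genotypes of a simulated population
#'
#' @param truth an \code{xhsd_truth} (or \code{xhsd_sim}) object.
#' @return \code{truth_pairs}: list of L x 2 allele matrices;
#'   \code{truth_genotypes}: L x N regular genotype matrix.
#' @export
truth_pairs <- function(truth) {
  if (inherits(truth, "xhsd_sim")) truth <- truth$truth
  lapply(seq_len(truth$N), function(i) {
    truth$pool[, truth$pairs[i, ], drop = FALSE]
  })
}

#' @rdname truth_pairs
#' @export
truth_genotypes <- function(truth) {
  if (inherits(truth, "xhsd_sim")) truth <- truth$truth
  vapply(seq_len(truth$N), function(i) {
    as.integer(truth$pool[, truth$pairs[i, 1]] + truth$pool[, truth$pairs[i, 2]])
  }, integer(truth$L))
}

#' Inject missing sites
#'
#' Each observed site is independently masked with probability \code{p_miss}.
#'
#' @param data an [xhsd_data()].
#' @param p_miss per-site missingness probability in [0, 1].
#' @param seed RNG seed.
#' @return a new [xhsd_data()] with additional \code{NA} entries.
#' @export
inject_missing <- function(data, p_miss, seed = NULL) {
  stopifnot(inherits(data, "xhsd_data"))
  if (p_miss < 0 || p_miss > 1) stop("p_miss must be in [0, 1]")
  with_seed(seed, {
    vals <- data$values
    mask <- matrix(stats::runif(length(vals)) < p_miss, nrow(vals))
    vals[mask] <- NA_integer_
    xhsd_data(vals, kind = data$kind, ids = data$ids, bias = max(data$bias),
              seed = data$seed, params = data$params)
  })
}

#' Inject typing errors into xor-genotypes
#'
#' Each observed site is independently flagged erroneous with probability
#' \code{p_err}; a flagged site is re-typed as homozygous or heterozygous
#' with equal probability (so the expected changed-bit fraction is
#' \code{p_err / 2}).
#'
#' @param data an [xhsd_data()] containing only xor-kind observations.
#' @param p_err per-site error probability in [0, 1].
#' @param seed RNG seed.
#' @return a new [xhsd_data()].
#' @export
inject_errors <- function(data, p_err, seed = NULL) {
  stopifnot(inherits(data, "xhsd_data"))
  if (any(data$kind != "xor")) {
    stop("typing-error injection is only defined for xor-genotype data")
  }
  if (p_err < 0 || p_err > 1) stop("p_err must be in [0, 1]")
  with_seed(seed, {
    vals <- data$values
    hit <- matrix(stats::runif(length(vals)) < p_err, nrow(vals)) & !is.na(vals)
    vals[hit] <- as.integer(stats::runif(sum(hit)) < 0.5)
    xhsd_data(vals, kind = data$kind, ids = data$ids,
              seed = data$seed, params = data$params)
  })
}
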
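# Entropy-minimizing block partition and ligation for long sequences.

#' Haplotype usage frequencies from indicator vectors
#'
#' Each individual contributes its pair multiplicities (one column doubled or
#' two columns once each); frequencies are the multiplicity totals divided by
#' \code{2N} and sum to 1.
#'
#' @param indicators list with one element per individual, each a list with
#'   \code{support} (candidate column indices) and \code{mult}
#'   (multiplicities summing to 2), as produced by the greedy solver.
#' @param N number of individuals.
#' @return named numeric vector of frequencies over the distinct selected
#'   columns (names are candidate column indices).
#' @export
block_frequencies <- function(indicators, N) {
  if (N == 0L) stop("empty population")
  counts <- new.env(parent = emptyenv())
  for (a in indicators) {
    m <- a$mult %||% (if (length(a$support) == 1L) 2L else c(1L, 1L))
    if (sum(m) != 2L) stop("indicator multiplicities must sum to 2")
    for (j in seq_along(a$support)) {
      key <- as.character(a$support[j])
      counts[[key]] <- (counts[[key]] %||% 0) + m[j]
    }
  }
  keys <- ls(counts)
  f <- vapply(keys, function(k) counts[[k]], numeric(1)) / (2 * N)
  f[order(as.integer(keys))]
}

#' Shannon entropy of a haplotype frequency vector
#'
#' Natural-log entropy; the block-diversity score minimized by the partition.
#'
#' @param f frequency vector with positive entries summing to 1 (tolerance
#'   1e-9).
#' @return nonnegative scalar (nats).
#' @examples
#' block_entropy(c(0.5, 0.5))        # log(2)
#' block_entropy(c(0.5, 0.25, 0.25)) # 1.0397
#' @export
block_entropy <- function(f) {
  f <- as.numeric(f)
  if (any(f <= 0) || abs(sum(f) - 1) > 1e-9) {
    stop("frequencies must be positive and sum to 1")
  }
  -sum(f * log(f))
}

#' Entropy-minimizing block partition of a long sequence
#'
#' Splits loci \code{1..L} into contiguous blocks of width at most \code{W},
#' minimizing the total Shannon entropy of the per-block haplotype usage
#' frequencies.  Each candidate block is solved with the greedy dictionary
#' search to obtain its frequencies; the optimal tiling is found by dynamic
#' programming over ending loci, with ties broken toward the smallest block
#' start (longest final block).
#'
#' @param data an [xhsd_data()].
#' @param W maximum block width.
#' @param control an [xhsd_control()].
#' @return an object of class \code{xhsd_partition}: \code{blocks}
#'   (data.frame with \code{l}, \code{m}, \code{entropy}),
#'   \code{total_entropy}, and the per-block solved results.
#' @export
partition_blocks <- function(data, W = 8L, control = xhsd_control()) {
  stopifnot(inherits(data, "xhsd_data"))
  W <- as.integer(W)
  if (W < 1L) stop("W must be >= 1")
  L <- data$L
  cache <- new.env(parent = emptyenv())
  solve_block <- function(l, m) {
    key <- paste0(l, ":", m)
    if (is.null(cache[[key]])) {
      bd <- slice_data(data, l, m)
      gp <- greedy_phase(bd, control)
      f <- block_frequencies(gp$assignments, bd$N)
      cache[[key]] <- list(l = l, m = m, gp = gp, data = bd,
                           entropy = block_entropy(f))
    }
    cache[[key]]
  }
  # E*(m) = min over l of E*(l-1) + E(l, m), block width <= W
  Estar <- c(0, rep(Inf, L))
  back <- integer(L)
  for (m in seq_len(L)) {
    for (l in seq(max(1L, m - W + 1L), m)) {
      e <- Estar[l] + solve_block(l, m)$entropy
      if (e < Estar[m + 1L] - 1e-12) {
        Estar[m + 1L] <- e
        back[m] <- l
      }
    }
  }
  blocks <- list()
  m <- L
  while (m >= 1L) {
    l <- back[m]
    blocks[[length(blocks) + 1L]] <- solve_block(l, m)
    m <- l - 1L
  }
  blocks <- rev(blocks)
  structure(list(blocks = data.frame(
                   l = vapply(blocks, `[[`, integer(1), "l"),
                   m = vapply(blocks, `[[`, integer(1), "m"),
                   entropy = vapply(blocks, `[[`, numeric(1), "entropy")),
                 total_entropy = Estar[L + 1L],
                 solutions = blocks),
            class = "xhsd_partition")
}

#' @export
print.xhsd_partition <- function(x, ...) {
  cat("Block partition: ", nrow(x$blocks), " blocks, total entropy ",
      format(round(x$total_entropy, 4)), "\n", sep = "")
  print(x$blocks)
  invisible(x)
}

# Block-level haplotype pair (alleles) for individual i in a solved block.
block_pair_alleles <- function(bl, i) {
  a <- bl$gp$assignments[[i]]
  L <- bl$data$L
  if (length(a$support) == 1L) {
    h <- hap_column(a$support, L)
    cbind(h, h, deparse.level = 0)
  } else {
    cbind(hap_column(a$support[1], L), hap_column(a$support[2], L),
          deparse.level = 0)
  }
}

#' Ligate block solutions into full-length haplotypes
#'
#' Stitches the per-block haplotype pairs left to right.  At each block
#' junction an individual's pair can be joined straight or crossed; the
#' default greedy rule prefers the join whose two resulting prefixes already
#' exist in the running set of prefixes (both known beats one beats none;
#' remaining ties take the straight join), which keeps the ligated haplotype
#' set parsimonious.  \code{method = "exhaustive"} enumerates all join
#' combinations and returns one minimizing the number of distinct full-length
#' haplotypes (only feasible for a handful of junction choices; used as a
#' test oracle).
#'
#' @param data the full-length [xhsd_data()].
#' @param part an [partition_blocks()] result with solved blocks.
#' @param control an [xhsd_control()].
#' @param method \code{"greedy"} or \code{"exhaustive"}.
#' @return a solution core (haplotypes, pairs, frequencies, partition info)
#'   as stored inside an \code{xhsd} fit.
#' @export
ligate <- function(data, part, control = xhsd_control(),
                   method = c("greedy", "exhaustive")) {
  method <- match.arg(method)
  stopifnot(inherits(part, "xhsd_partition"))
  N <- data$N
  Q <- length(part$solutions)
  bp <- lapply(part$solutions, function(bl) {
    lapply(seq_len(N), function(i) block_pair_alleles(bl, i))
  })
  assemble <- function(choices) {
    # choices: N x (Q-1) logical, TRUE = cross at that junction
    pairs <- lapply(seq_len(N), function(i) bp[[1]][[i]])
    if (Q > 1L) for (q in 2L:Q) {
      for (i in seq_len(N)) {
        nxt <- bp[[q]][[i]]
        if (Q > 1L && choices[i, q - 1L]) nxt <- nxt[, 2:1, drop = FALSE]
        pairs[[i]] <- rbind(pairs[[i]], nxt)
      }
    }
    pairs
  }
  if (method == "greedy") {
    prefixes <- lapply(seq_len(N), function(i) bp[[1]][[i]])
    if (Q > 1L) for (q in 2L:Q) {
      new_seen <- character(0)
      for (i in seq_len(N)) {
        nxt <- bp[[q]][[i]]
        straight <- cbind(c(prefixes[[i]][, 1], nxt[, 1]),
                          c(prefixes[[i]][, 2], nxt[, 2]))
        crossed <- cbind(c(prefixes[[i]][, 1], nxt[, 2]),
                         c(prefixes[[i]][, 2], nxt[, 1]))
        score <- function(p) {
          sum(c(paste(p[, 1], collapse = ""),
                paste(p[, 2], collapse = "")) %in% new_seen)
        }
        prefixes[[i]] <- if (score(crossed) > score(straight)) crossed
                         else straight
        new_seen <- unique(c(new_seen,
                             paste(prefixes[[i]][, 1], collapse = ""),
                             paste(prefixes[[i]][, 2], collapse = "")))
      }
    }
    pairs_alleles <- prefixes
  } else {
    nj <- N * max(0L, Q - 1L)
    if (nj > 12L) stop("exhaustive ligation limited to <= 12 junction choices")
    best <- NULL
    best_count <- Inf
    for (mask in 0:(2^nj - 1L)) {
      ch <- matrix(as.logical(bitwAnd(bitwShiftR(mask, seq_len(nj) - 1L), 1L)),
                   nrow = N)
      pl <- assemble(ch)
      cnt <- length(unique(unlist(lapply(pl, function(p) {
        c(paste(p[, 1], collapse = ""), paste(p[, 2], collapse = ""))
      }))))
      if (cnt < best_count) {
        best_count <- cnt
        best <- pl
      }
    }
    pairs_alleles <- best
  }
  keys <- lapply(pairs_alleles, function(p) {
    c(paste(p[, 1], collapse = ""), paste(p[, 2], collapse = ""))
  })
  uniq <- unique(unlist(keys))
  H <- vapply(uniq, function(k) as.integer(strsplit(k, "")[[1]]),
              integer(data$L))
  colnames(H) <- paste0("h", seq_along(uniq))
  pairs <- t(vapply(keys, function(k) match(k, uniq), integer(2)))
  rownames(pairs) <- data$ids
  usage <- tabulate(as.vector(pairs), nbins = length(uniq))
  f <- usage / (2 * N)
  names(f) <- colnames(H)
  list(haplotypes = H, pairs = pairs, frequencies = f,
       dictionary = NULL,
       traces = lapply(part$solutions, function(bl) bl$gp$traces),
       iterations = sum(vapply(part$solutions, function(bl) bl$gp$iterations,
                               numeric(1))),
       fitness = NA_real_,
       partition = list(blocks = part$blocks,
                        total_entropy = part$total_entropy))
}
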
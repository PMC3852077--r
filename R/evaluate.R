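# Phasing accuracy metrics and the exhaustive best-flip evaluation.

# Any accepted pair representation -> list of L x 2 allele matrices.
as_pair_list <- function(x) {
  if (inherits(x, "xhsd")) return(haplotype_pairs(x))
  if (inherits(x, "xhsd_sim") || inherits(x, "xhsd_truth")) {
    return(truth_pairs(x))
  }
  if (is.list(x) && all(vapply(x, is.matrix, logical(1)))) return(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    return(lapply(seq_len(dim(x)[3]), function(i) x[, , i]))
  }
  stop("cannot interpret haplotype pairs: supply a fitted xhsd object, a ",
       "simulation truth, or a list of L x 2 matrices")
}

check_pairs <- function(truth, inferred) {
  t <- as_pair_list(truth)
  i <- as_pair_list(inferred)
  if (length(t) != length(i)) stop("individual counts differ")
  if (nrow(t[[1]]) != nrow(i[[1]])) stop("locus counts differ")
  list(truth = t, inferred = i)
}

# Per-individual error counts between two pair lists.
#   miss_het: orientation-minimizing count of heterozygous truth loci with the
#             wrong allele assignment
#   miss_hom: homozygous truth loci where the inferred shared allele differs
#   chi:      heterozygous truth loci count
#   wrong:    unordered pair differs at any scored locus
pair_counts <- function(tp, ip) {
  L <- nrow(tp)
  obs <- !is.na(tp[, 1]) & !is.na(tp[, 2])
  het <- obs & tp[, 1] != tp[, 2]
  hom <- obs & tp[, 1] == tp[, 2]
  mA <- sum(het & ip[, 1] != tp[, 1])
  mB <- sum(het & ip[, 1] != tp[, 2])
  miss_het <- min(mA, mB)
  miss_hom <- sum(hom & !(ip[, 1] == tp[, 1] & ip[, 2] == tp[, 1]))
  same <- (all(ip[obs, 1] == tp[obs, 1]) && all(ip[obs, 2] == tp[obs, 2])) ||
          (all(ip[obs, 1] == tp[obs, 2]) && all(ip[obs, 2] == tp[obs, 1]))
  c(miss_het = miss_het, miss_hom = miss_hom, chi = sum(het),
    hom = sum(hom), wrong = as.integer(!same))
}

counts_table <- function(truth, inferred) {
  p <- check_pairs(truth, inferred)
  t(vapply(seq_along(p$truth), function(i) pair_counts(p$truth[[i]],
                                                       p$inferred[[i]]),
           numeric(5)))
}

#' Phasing accuracy metrics
#'
#' \code{pair_error} is the fraction of individuals whose inferred unordered
#' haplotype pair differs from the true pair at any locus (a single flipped
#' SNP counts as a mis-inference).  \code{switch_error} is the total
#' orientation-minimizing count of wrongly assigned heterozygous loci divided
#' by the worst case, half the total heterozygous-locus count.
#' \code{prediction_error} is the fraction of hidden-homozygous sites whose
#' inferred shared allele is wrong.  Truth-missing loci are excluded
#' throughout.
#'
#' @param truth,inferred haplotype pairs in any form accepted internally: a
#'   fitted \code{xhsd} object, a simulation result, or a list of L x 2
#'   matrices.
#' @return a fraction in [0, 1].
#' @examples
#' t <- list(cbind(c(0,0,0,0), c(1,1,1,1)))
#' i <- list(cbind(c(0,0,1,1), c(1,1,0,0)))
#' switch_error(t, i)  # 1: two switches out of a worst case of two
#' @export
pair_error <- function(truth, inferred) {
  ct <- counts_table(truth, inferred)
  mean(ct[, "wrong"])
}

#' @rdname pair_error
#' @export
switch_error <- function(truth, inferred) {
  ct <- counts_table(truth, inferred)
  denom <- sum(ct[, "chi"]) / 2
  if (denom == 0) return(0)
  sum(ct[, "miss_het"]) / denom
}

#' @rdname pair_error
#' @export
prediction_error <- function(truth, inferred) {
  ct <- counts_table(truth, inferred)
  denom <- sum(ct[, "hom"])
  if (denom == 0) return(0)
  sum(ct[, "miss_hom"]) / denom
}

#' Haplotype diversity ratio
#'
#' The number of distinct haplotypes actually used to explain the population,
#' divided by the number of individuals.  Low values indicate parsimonious
#' (low-diversity) solutions.
#'
#' @param x a fitted \code{xhsd} object, or any pair representation.
#' @param N number of individuals (inferred from \code{x} when omitted).
#' @return positive ratio (at most 2).
#' @export
diversity_ratio <- function(x, N = NULL) {
  if (inherits(x, "xhsd")) {
    N <- N %||% x$data$N
    return(sum(x$frequencies > 0) / N)
  }
  p <- as_pair_list(x)
  N <- N %||% length(p)
  keys <- unlist(lapply(p, function(m) {
    c(paste(m[, 1], collapse = ""), paste(m[, 2], collapse = ""))
  }))
  length(unique(keys)) / N
}

# Apply a locus flip set to every pair in a list.
flip_pairs <- function(pairs, S) {
  if (length(S) == 0L) return(pairs)
  lapply(pairs, function(p) flip_haplotypes(p, S))
}

#' Metrics after searching for the best bit flip
#'
#' For xor-only benchmarking the inferred solution is one of up to
#' \code{2^L - 1} flip-equivalent sets; this evaluation searches the flip
#' subset bringing the inference closest to the truth (minimizing the total
#' mis-inferred loci, heterozygous plus homozygous, then the number of
#' mis-paired individuals) and reports the metrics there.  Exhaustive over
#' all \code{2^L} subsets for \code{L <= L_max_exact}; seeded
#' coordinate-descent with restarts otherwise.
#'
#' @inheritParams pair_error
#' @param L_max_exact largest L for exhaustive search (default 16).
#' @param seed RNG seed for the coordinate-descent restarts.
#' @param restarts number of random restarts in descent mode.
#' @return an object of class \code{xhsd_metrics} with fields \code{P_e},
#'   \code{swr}, \code{err_p}, \code{rho}, \code{flip_mode}, \code{flips}
#'   and the per-individual count table.
#' @export
best_flip_evaluate <- function(truth, inferred, L_max_exact = 16L,
                               seed = NULL, restarts = 5L) {
  p <- check_pairs(truth, inferred)
  L <- nrow(p$truth[[1]])
  objective <- function(S) {
    ct <- counts_table(p$truth, flip_pairs(p$inferred, S))
    c(sum(ct[, "miss_het"]) + sum(ct[, "miss_hom"]), sum(ct[, "wrong"]))
  }
  better <- function(a, b) a[1] < b[1] || (a[1] == b[1] && a[2] < b[2])
  if (L <= L_max_exact) {
    best_S <- integer(0)
    best_v <- objective(integer(0))
    for (s in seq_len(2^L - 1L)) {
      S <- which(bitwAnd(bitwShiftR(s, 0:(L - 1L)), 1L) == 1L)
      v <- objective(S)
      if (better(v, best_v)) {
        best_v <- v
        best_S <- S
      }
    }
    mode <- "best_exhaustive"
  } else {
    descend <- function(S) {
      v <- objective(S)
      repeat {
        improved <- FALSE
        for (l in seq_len(L)) {
          S2 <- if (l %in% S) setdiff(S, l) else sort(c(S, l))
          v2 <- objective(S2)
          if (better(v2, v)) {
            S <- S2; v <- v2; improved <- TRUE
          }
        }
        if (!improved) break
      }
      list(S = S, v = v)
    }
    best <- descend(integer(0))
    with_seed(seed, {
      for (r in seq_len(restarts)) {
        S0 <- which(stats::runif(L) < 0.5)
        cand <- descend(S0)
        if (better(cand$v, best$v)) best <- cand
      }
    })
    best_S <- best$S
    best_v <- best$v
    mode <- "best_search"
  }
  out <- phasing_metrics(p$truth, flip_pairs(p$inferred, best_S),
                         flip_mode = mode)
  out$flips <- best_S
  out
}

#' Full metrics report
#'
#' @inheritParams pair_error
#' @param flip_mode label recording how the bit-flip freedom was handled.
#' @return an object of class \code{xhsd_metrics}.
#' @export
phasing_metrics <- function(truth, inferred, flip_mode = "none") {
  p <- check_pairs(truth, inferred)
  ct <- counts_table(p$truth, p$inferred)
  denom_het <- sum(ct[, "chi"]) / 2
  denom_hom <- sum(ct[, "hom"])
  structure(list(
    P_e = mean(ct[, "wrong"]),
    swr = if (denom_het == 0) 0 else sum(ct[, "miss_het"]) / denom_het,
    err_p = if (denom_hom == 0) 0 else sum(ct[, "miss_hom"]) / denom_hom,
    rho = diversity_ratio(p$inferred),
    flip_mode = flip_mode,
    flips = integer(0),
    per_individual = as.data.frame(ct)),
    class = "xhsd_metrics")
}

#' @export
print.xhsd_metrics <- function(x, ...) {
  cat("Phasing accuracy (flip mode: ", x$flip_mode, ")\n", sep = "")
  cat(sprintf("  pair error P_e:        %.4f\n", x$P_e))
  cat(sprintf("  switch error rate:     %.4f\n", x$swr))
  cat(sprintf("  prediction error:      %.4f\n", x$err_p))
  cat(sprintf("  diversity ratio rho:   %.4f\n", x$rho))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param metrics an \code{xhsd_metrics} object.
#' @param path output file.
#' @export
write_metrics <- function(metrics, path) {
  stopifnot(inherits(metrics, "xhsd_metrics"))
  jsonlite::write_json(
    list(P_e = metrics$P_e, swr = metrics$swr, err_p = metrics$err_p,
         rho = metrics$rho, flip_mode = metrics$flip_mode,
         flips = metrics$flips),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
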
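#' Maximum-parsimony haplotype phasing from xor-genotypes
#'
#' Fits the sparse-dictionary phasing model: starting from an empty dictionary,
#' candidate haplotypes are added greedily, each step picking the column whose
#' addition maximizes the average dictionary fitness over the population,
#' until every individual's observation is exactly reconstructed by a pair of
#' dictionary haplotypes (or one haplotype doubled).  Sequences longer than
#' \code{max_block} SNPs are partitioned into low-entropy blocks which are
#' solved independently and ligated.
#'
#' When regular genotypes are supplied, the bit-flip degree of freedom (any
#' set of loci may be inverted across all haplotypes without changing any
#' xor-genotype) is resolved.  With \code{resolve = "pre"} (the default when
#' genotypes are given) a minimal set of individuals whose heterozygous-locus
#' sets have empty intersection is found by [mti()] and their xor-genotypes
#' are replaced by regular genotypes before fitting, anchoring the homozygous
#' alleles during the search.  With \code{resolve = "post"} the model is fitted
#' on xor data only and the genotypes afterwards vote on per-locus flips
#' ([resolve_flips()]).
#'
#' @param x an [xhsd_data()], or an integer matrix with loci in rows and
#'   individuals in columns (xor coding 0/1, \code{NA} = missing).
#' @param genotypes optional regular genotypes: an L x N matrix (\code{NA}
#'   where unavailable) or an L x k matrix whose column names are individual
#'   ids.  Coding 0/1/2.
#' @param resolve ambiguity-resolution pathway: \code{"auto"} (pre if
#'   genotypes are given, else none), \code{"pre"}, \code{"post"} or
#'   \code{"none"}.
#' @param mode,bias,weight_missing,tie_break,seed,max_block see
#'   [xhsd_control()].
#' @param mti_max_exact exhaustive-search cap for the informative-set search.
#' @param init optional initial dictionary column indices (single-block runs
#'   only).
#' @param control an [xhsd_control()]; overrides the individual arguments.
#' @return an object of class \code{xhsd}: a list with the inferred
#'   \code{haplotypes} (L x H 0/1 matrix), per-individual \code{pairs}
#'   (N x 2 indices into the haplotype columns), usage \code{frequencies},
#'   greedy \code{traces}, \code{iterations}, final \code{fitness},
#'   \code{unresolved_loci}, per-locus \code{flip_status}, the \code{data},
#'   block \code{partition} info (long sequences), and the matched call.
#' @examples
#' X <- matrix(c(0,0,1, 0,1,0, 0,1,1), nrow = 3)
#' fit <- xhsd(X)
#' fit
#' coef(fit)
#' @export
xhsd <- function(x, genotypes = NULL,
                 resolve = c("auto", "pre", "post", "none"),
                 mode = c("indicator", "residual"), bias = 4,
                 weight_missing = FALSE,
                 tie_break = c("lowest", "random"), seed = NULL,
                 max_block = 8L, mti_max_exact = 4L, init = NULL,
                 control = NULL) {
  cl <- match.call()
  resolve <- match.arg(resolve)
  if (is.null(control)) {
    control <- xhsd_control(mode = match.arg(mode), bias = bias,
                            weight_missing = weight_missing,
                            tie_break = match.arg(tie_break), seed = seed,
                            max_block = max_block)
  }
  data <- if (inherits(x, "xhsd_data")) x else xhsd_data(x, bias = control$bias)
  G <- if (!is.null(genotypes)) normalize_genotypes(genotypes, data) else NULL
  if (resolve == "auto") resolve <- if (is.null(G)) "none" else "pre"
  if (resolve %in% c("pre", "post") && is.null(G)) {
    stop("resolve = '", resolve, "' requires regular genotypes")
  }

  mti_set <- NULL
  fit_data <- data
  if (resolve == "pre" || resolve == "post") {
    mti_set <- mti(data, max_exact = mti_max_exact)
    avail <- mti_set$individuals[colSums(!is.na(G[, mti_set$individuals,
                                                  drop = FALSE])) > 0L]
    if (length(avail) < length(mti_set$individuals)) {
      warning("regular genotypes missing for some informative individuals; ",
              "using the available subset")
    }
    mti_set$individuals <- avail
    if (resolve == "pre" && length(avail)) {
      fit_data <- augment(data, avail, G, bias = control$bias)
    }
  }

  core <- with_seed(control$seed, {
    if (fit_data$L <= control$max_block) {
      gp <- greedy_phase(fit_data, control, init = init)
      core_from_phase(fit_data, gp)
    } else {
      if (!is.null(init)) stop("init is only supported for single-block runs")
      part <- partition_blocks(fit_data, W = control$max_block,
                               control = control)
      ligate(fit_data, part, control)
    }
  })

  fit <- structure(c(core, list(data = fit_data, control = control,
                                resolve = resolve, mti = mti_set,
                                call = cl)),
                   class = "xhsd")
  fit$flip_status <- flip_status_from_data(fit)
  if (resolve == "post" && length(mti_set$individuals)) {
    rf <- resolve_flips(fit, G)
    fit <- rf$solution
  }
  fit$unresolved_loci <- which(fit$flip_status == "unresolved")
  fit
}

# Genotype matrix in any accepted shape -> full L x N matrix with NA columns
# for individuals without a regular genotype.
normalize_genotypes <- function(genotypes, data) {
  G <- as.matrix(genotypes)
  storage.mode(G) <- "integer"
  if (nrow(G) != data$L) stop_data("genotypes must have L = ", data$L, " rows")
  if (!all(G %in% c(0L, 1L, 2L) | is.na(G))) {
    stop_data("genotype entries must be 0, 1, 2 or NA")
  }
  if (ncol(G) == data$N && is.null(colnames(G))) {
    colnames(G) <- data$ids
    return(G)
  }
  if (is.null(colnames(G))) stop_data("genotype columns must be named by id")
  bad <- setdiff(colnames(G), data$ids)
  if (length(bad)) stop_data("unknown individual ids: ",
                             paste(bad, collapse = ", "))
  full <- matrix(NA_integer_, data$L, data$N, dimnames = list(NULL, data$ids))
  full[, colnames(G)] <- G
  full
}

# Solution core from a single-block greedy result.
core_from_phase <- function(data, gp) {
  L <- data$L
  H <- matrix(vapply(gp$D, hap_column, integer(L), L = L), nrow = L)
  colnames(H) <- paste0("h", seq_along(gp$D))
  pairs <- t(vapply(gp$assignments, function(a) {
    p <- match(a$support, gp$D)
    if (length(p) == 1L) c(p, p) else p
  }, integer(2)))
  rownames(pairs) <- data$ids
  freq <- block_frequencies(gp$assignments, data$N)
  f <- numeric(length(gp$D))
  f[match(as.integer(names(freq)), gp$D)] <- freq
  names(f) <- colnames(H)
  list(haplotypes = H, pairs = pairs, frequencies = f,
       dictionary = gp$D, traces = gp$traces, iterations = gp$iterations,
       fitness = gp$fitness, partition = NULL)
}

# Per-locus flip status implied by the fitted data: a locus is anchored
# ("forced") when some regular-genotype individual is observed homozygous
# there; otherwise the bit-flip freedom remains.
flip_status_from_data <- function(fit) {
  status <- rep("unresolved", fit$data$L)
  reg <- which(fit$data$kind == "regular")
  for (i in reg) {
    g <- fit$data$values[, i]
    status[!is.na(g) & g != 1L] <- "forced"
  }
  status
}

#' @export
print.xhsd <- function(x, ...) {
  used <- sum(x$frequencies > 0)
  cat("Maximum-parsimony xor-haplotype phasing (greedy dictionary selection)\n")
  cat("  individuals: ", x$data$N, "   loci: ", x$data$L,
      if (!is.null(x$partition)) paste0("   blocks: ", nrow(x$partition$blocks)),
      "\n", sep = "")
  cat("  haplotypes: ", ncol(x$haplotypes), " selected, ", used, " in use",
      " (diversity ratio ", format(round(used / x$data$N, 3)), ")\n", sep = "")
  if (is.null(x$partition)) {
    cat("  converged after ", x$iterations, " iterations; fitness ",
        format(round(x$fitness, 4)), "\n", sep = "")
  } else {
    cat("  total block entropy ", format(round(x$partition$total_entropy, 4)),
        "\n", sep = "")
  }
  nun <- length(x$unresolved_loci)
  cat("  bit-flip status: ", x$data$L - nun, "/", x$data$L,
      " loci resolved\n", sep = "")
  invisible(x)
}

#' @export
summary.xhsd <- function(object, ...) {
  hp <- haplotype_pairs(object)
  het <- vapply(seq_len(object$data$N), function(i) {
    length(het_loci(object$data$values[, i]))
  }, integer(1))
  out <- list(fit = object,
              diversity = diversity_ratio(object),
              freq = sort(object$frequencies[object$frequencies > 0],
                          decreasing = TRUE),
              het_per_ind = het)
  class(out) <- "summary.xhsd"
  out
}

#' @export
print.summary.xhsd <- function(x, ...) {
  print(x$fit)
  cat("\nHaplotype usage frequencies:\n")
  H <- x$fit$haplotypes
  for (nm in names(x$freq)) {
    cat("  ", paste(H[, nm], collapse = ""), "  ",
        format(round(x$freq[[nm]], 4)), "\n", sep = "")
  }
  cat("\nHeterozygous loci per individual: median ",
      stats::median(x$het_per_ind), " (range ", min(x$het_per_ind), "-",
      max(x$het_per_ind), ")\n", sep = "")
  if (length(x$fit$unresolved_loci)) {
    cat("Unresolved (flip-ambiguous) loci: ",
        paste(x$fit$unresolved_loci, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.xhsd <- function(object, ...) object$haplotypes

#' Inferred haplotype pairs
#'
#' @param fit a fitted \code{xhsd} object.
#' @return a named list with one L x 2 0/1 matrix per individual.
#' @export
haplotype_pairs <- function(fit) {
  stopifnot(inherits(fit, "xhsd"))
  out <- lapply(seq_len(fit$data$N), function(i) {
    fit$haplotypes[, fit$pairs[i, ], drop = FALSE]
  })
  names(out) <- fit$data$ids
  out
}

#' @export
predict.xhsd <- function(object, type = c("haplotypes", "xor", "genotype"),
                         ...) {
  type <- match.arg(type)
  if (type == "haplotypes") return(haplotype_pairs(object))
  H <- object$haplotypes
  out <- vapply(seq_len(object$data$N), function(i) {
    p <- object$pairs[i, ]
    s <- H[, p[1]] + H[, p[2]]
    if (type == "xor") s %% 2L else s
  }, integer(object$data$L))
  colnames(out) <- object$data$ids
  out
}

#' @export
fitted.xhsd <- function(object, ...) {
  xr <- predict(object, "xor")
  gr <- predict(object, "genotype")
  out <- xr
  reg <- object$data$kind == "regular"
  out[, reg] <- gr[, reg]
  out
}

#' @export
residuals.xhsd <- function(object, ...) {
  r <- object$data$values - fitted(object)
  rownames(r) <- NULL
  r
}

#' @export
plot.xhsd <- function(x, ...) {
  if (is.null(x$partition)) {
    g <- vapply(x$traces, function(t) t$max_gain, numeric(1))
    graphics::plot(seq_along(g), g, type = "b", pch = 19,
                   xlab = "greedy iteration", ylab = "maximal marginal gain",
                   main = "Dictionary growth", ...)
    graphics::abline(h = x$fitness, lty = 2, col = "grey40")
  } else {
    b <- x$partition$blocks
    graphics::barplot(b$entropy,
                      names.arg = paste0(b$l, "-", b$m),
                      xlab = "block (loci)", ylab = "Shannon entropy (nats)",
                      main = "Entropy-minimizing block partition", ...)
  }
  invisible(x)
}

#' @export
simulate.xhsd <- function(object, nsim = 1, seed = NULL, N = NULL, ...) {
  N <- N %||% object$data$N
  keep <- object$frequencies > 0
  H <- object$haplotypes[, keep, drop = FALSE]
  f <- object$frequencies[keep] / sum(object$frequencies[keep])
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      idx <- matrix(sample.int(ncol(H), 2L * N, replace = TRUE, prob = f),
                    ncol = 2)
      X <- vapply(seq_len(N), function(i) {
        as.integer((H[, idx[i, 1]] + H[, idx[i, 2]]) %% 2L)
      }, integer(nrow(H)))
      xhsd_data(X)
    })
  })
}
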
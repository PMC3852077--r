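# Bit-flip ambiguity machinery: informative-set (MTI-style) selection,
# flip equivalence, and both resolution workflows.

#' Minimal informative set of individuals
#'
#' Finds the smallest subset of individuals whose heterozygous-locus sets have
#' empty intersection.  Regular genotypes of such a set reveal the homozygous
#' allele at every locus (each locus is homozygous in at least one member),
#' which removes the bit-flip degree of freedom.  The search is exhaustive
#' over subset sizes \code{1..max_exact} (lexicographically first minimal set
#' is returned); beyond that a greedy intersection-reduction pass is used.
#' When even the whole population's heterozygous loci intersect, the
#' best-achievable set is returned with the residual intersection flagged.
#'
#' @param x an [xhsd_data()], a 0/1 matrix (loci x individuals), or a list of
#'   xor-genotype vectors.
#' @param max_exact largest subset size searched exhaustively (default 4).
#' @return an object of class \code{xhsd_mti}: \code{individuals} (indices),
#'   \code{ids}, \code{size}, \code{empty} (did the intersection reach
#'   empty?), \code{residual_intersection} (loci still heterozygous in every
#'   member), \code{covered_loci} (loci homozygous in some member).
#' @examples
#' X <- matrix(c(1,1,0, 0,1,1, 1,0,1), nrow = 3)
#' mti(X)
#' @export
mti <- function(x, max_exact = 4L) {
  hets <- het_matrix(x)
  N <- ncol(hets)
  ids <- colnames(hets) %||% paste0("ind", seq_len(N))
  found <- NULL
  for (s in seq_len(min(max_exact, N))) {
    combos <- utils::combn(N, s)
    for (ci in seq_len(ncol(combos))) {
      sel <- combos[, ci]
      v <- hets[, sel[1]]
      for (j in sel[-1]) v <- v & hets[, j]
      if (!any(v)) {
        found <- sel
        break
      }
    }
    if (!is.null(found)) break
  }
  if (is.null(found)) {
    # greedy reduction: grow the set while the intersection strictly shrinks
    sizes <- colSums(hets)
    found <- which.min(sizes)
    v <- hets[, found]
    repeat {
      if (!any(v)) break
      shrink <- vapply(seq_len(N), function(j) {
        if (j %in% found) Inf else sum(v & hets[, j])
      }, numeric(1))
      j <- which.min(shrink)
      if (shrink[j] >= sum(v)) break
      found <- c(found, j)
      v <- v & hets[, j]
    }
  }
  v <- hets[, found[1]]
  for (j in found[-1]) v <- v & hets[, j]
  cov <- covered_loci(x, found)
  structure(list(individuals = sort(found), ids = ids[sort(found)],
                 size = length(found), empty = !any(v),
                 residual_intersection = which(v),
                 covered_loci = cov),
            class = "xhsd_mti")
}

#' @export
print.xhsd_mti <- function(x, ...) {
  cat("Informative set: ", length(x$individuals), " individual(s): ",
      paste(x$ids, collapse = ", "), "\n", sep = "")
  if (!x$empty) {
    cat("  residual heterozygous intersection at loci: ",
        paste(x$residual_intersection, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Heterozygosity indicator matrix (L x N logical) from any accepted input.
het_matrix <- function(x) {
  if (inherits(x, "xhsd_data")) {
    m <- !is.na(x$values) & x$values == 1L
    colnames(m) <- x$ids
    return(m)
  }
  if (is.list(x) && !is.data.frame(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  !is.na(x) & x == 1L
}

covered_loci <- function(x, sel) {
  v <- if (inherits(x, "xhsd_data")) x$values else as.matrix(x)
  hom <- !is.na(v[, sel, drop = FALSE]) & v[, sel, drop = FALSE] == 0L
  which(rowSums(hom) > 0L)
}

#' Repeated informative-set selection to cover a target fraction
#'
#' Runs [mti()] repeatedly, excluding previously selected individuals, until
#' the union of selected individuals reaches
#' \code{ceiling(target_fraction * N)} distinct members or \code{max_runs}
#' is reached.
#'
#' @inheritParams mti
#' @param target_fraction fraction of the population to genotype, in (0, 1].
#' @param max_runs cap on the number of runs.
#' @return list of \code{xhsd_mti} objects with attribute \code{union} (the
#'   selected individual indices).
#' @export
mti_multi <- function(x, target_fraction, max_runs = 25L, max_exact = 4L) {
  if (target_fraction <= 0 || target_fraction > 1) {
    stop("target_fraction must be in (0, 1]")
  }
  hets <- het_matrix(x)
  N <- ncol(hets)
  target <- ceiling(target_fraction * N)
  sets <- list()
  union_idx <- integer(0)
  remaining <- seq_len(N)
  while (length(union_idx) < target && length(sets) < max_runs &&
         length(remaining) > 0L) {
    sub <- hets[, remaining, drop = FALSE]
    m <- mti(sub * 1L, max_exact = max_exact)
    m$individuals <- remaining[m$individuals]
    m$ids <- (colnames(hets) %||% paste0("ind", seq_len(N)))[m$individuals]
    sets[[length(sets) + 1L]] <- m
    union_idx <- union(union_idx, m$individuals)
    remaining <- setdiff(remaining, m$individuals)
  }
  attr(sets, "union") <- sort(union_idx)
  sets
}

#' Replace xor-genotypes with regular genotypes for selected individuals
#'
#' The pre-processing resolution pathway: the selected individuals'
#' observations become regular-genotype observations (carrying the bias
#' weight), anchoring homozygous alleles during the dictionary search.
#'
#' @param data an [xhsd_data()].
#' @param individuals indices (or ids) of individuals to replace.
#' @param genotypes regular genotypes, any shape accepted by [xhsd()].
#' @param bias priority weight for the replaced individuals.
#' @return a new [xhsd_data()] with mixed observation kinds.
#' @export
augment <- function(data, individuals, genotypes, bias = 4) {
  stopifnot(inherits(data, "xhsd_data"))
  if (is.character(individuals)) individuals <- match(individuals, data$ids)
  if (anyNA(individuals)) stop_data("unknown individual id in augment()")
  if (length(individuals) == 0L) return(data)
  G <- normalize_genotypes(genotypes, data)
  vals <- data$values
  kind <- data$kind
  for (i in individuals) {
    g <- G[, i]
    if (all(is.na(g))) stop_data("no regular genotype available for ",
                                 data$ids[i])
    x <- vals[, i]
    both <- !is.na(g) & !is.na(x)
    if (any((g[both] == 1L) != (x[both] == 1L))) {
      stop_data("genotype/xor inconsistency for ", data$ids[i],
                ": heterozygosity patterns disagree")
    }
    vals[, i] <- g
    kind[i] <- "regular"
  }
  xhsd_data(vals, kind = kind, ids = data$ids, bias = bias,
            seed = data$seed, params = data$params)
}

#' Invert alleles at a set of loci across a haplotype set
#'
#' Flipping any locus set across all haplotypes leaves every xor-genotype
#' they generate unchanged (both members of each pair flip), which is the
#' bit-flip degree of freedom.  Applying the same flip twice is the identity.
#'
#' @param H 0/1 matrix of haplotypes (loci x haplotypes) or a single
#'   haplotype vector.
#' @param S integer set of 1-based loci to invert.
#' @return object of the same shape as \code{H}.
#' @export
flip_haplotypes <- function(H, S) {
  vec <- is.null(dim(H))
  Hm <- if (vec) matrix(H, ncol = 1) else H
  S <- as.integer(S)
  if (any(S < 1L | S > nrow(Hm))) stop("flip loci out of range")
  Hm[S, ] <- 1L - Hm[S, ]
  if (vec) Hm[, 1] else Hm
}

#' Number of flip-equivalent solution sets
#'
#' Every nonempty locus subset gives a distinct flip, so a solution over
#' \code{L} loci has at most \code{2^L - 1} set-equivalent alternatives.
#'
#' @param L locus count, \code{L >= 1}.
#' @return numeric count.
#' @export
count_equivalents <- function(L) {
  if (L < 1) stop("L must be >= 1")
  2^L - 1
}

#' Are two haplotype sets flip-equivalent?
#'
#' True when some locus-subset flip maps one set onto the other (as unordered
#' sets of distinct haplotypes).  The candidate flips are exactly those
#' sending the first column of \code{H1} to some column of \code{H2}, so the
#' check costs O(K^2) set comparisons.
#'
#' @param H1,H2 0/1 haplotype matrices (loci x haplotypes); column multisets
#'   are compared as sets of distinct columns.
#' @return \code{TRUE} or \code{FALSE}, with attribute \code{flips} (the
#'   mapping locus set) when \code{TRUE}.
#' @export
set_equivalent <- function(H1, H2) {
  H1 <- as.matrix(H1); H2 <- as.matrix(H2)
  if (nrow(H1) != nrow(H2)) stop("haplotype sets have different L")
  L <- nrow(H1)
  if (L > 30L) stop("set_equivalent supports L <= 30")
  codes <- function(H) sort(unique(vapply(seq_len(ncol(H)), function(j) {
    as.integer(bit_code(H[, j]))
  }, integer(1))))
  c1 <- codes(H1); c2 <- codes(H2)
  if (length(c1) != length(c2)) return(FALSE)
  for (s in bitwXor(c1[1], c2)) {
    if (identical(sort(bitwXor(c1, s)), c2)) {
      out <- TRUE
      attr(out, "flips") <- which(bitwAnd(bitwShiftR(s, 0:(L - 1L)), 1L) == 1L)
      return(out)
    }
  }
  FALSE
}

#' Post-processing bit-flip resolution from regular genotypes
#'
#' The voting workflow: for each locus, every informative individual whose
#' regular genotype is homozygous there compares its inferred shared allele
#' with the genotype's allele (0 = major, 2 = minor) and votes to flip on
#' disagreement.  The majority decides; ties keep the unflipped state (status
#' \code{"voted"}, with a warning); loci without any homozygous voter remain
#' \code{"unresolved"}; unanimous loci are \code{"forced"}.  Winning flips are
#' applied to all haplotypes (and hence all pair assignments), which never
#' changes any individual's xor reconstruction.
#'
#' @param fit a fitted \code{xhsd} object.
#' @param genotypes regular genotypes for the voting individuals, any shape
#'   accepted by [xhsd()] (columns that are all \code{NA} do not vote).
#' @return list with \code{solution} (the flipped fit), \code{flips} (loci
#'   inverted) and \code{status} (per-locus \code{forced}/\code{voted}/
#'   \code{unresolved}).
#' @export
resolve_flips <- function(fit, genotypes) {
  stopifnot(inherits(fit, "xhsd"))
  G <- normalize_genotypes(genotypes, fit$data)
  L <- fit$data$L
  voters <- which(colSums(!is.na(G)) > 0L)
  status <- rep("unresolved", L)
  flips <- integer(0)
  tie_warned <- FALSE
  for (l in seq_len(L)) {
    vote_flip <- 0L
    vote_keep <- 0L
    for (i in voters) {
      g <- G[l, i]
      if (is.na(g) || g == 1L) next
      a <- fit$haplotypes[l, fit$pairs[i, ]]
      if (a[1] != a[2]) next  # inferred heterozygous: genotype cannot anchor
      want <- if (g == 2L) 1L else 0L
      if (a[1] == want) vote_keep <- vote_keep + 1L
      else vote_flip <- vote_flip + 1L
    }
    total <- vote_flip + vote_keep
    if (total == 0L) next
    if (vote_flip > vote_keep) flips <- c(flips, l)
    if (vote_flip == vote_keep) {
      status[l] <- "voted"
      tie_warned <- TRUE
    } else {
      status[l] <- if (min(vote_flip, vote_keep) == 0L) "forced" else "voted"
    }
  }
  if (tie_warned) warning("tied flip votes at some loci; kept unflipped state")
  fit$haplotypes <- flip_haplotypes(fit$haplotypes, flips)
  fit$flip_status <- status
  fit$unresolved_loci <- which(status == "unresolved")
  list(solution = fit, flips = flips, status = status)
}
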
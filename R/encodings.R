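#' Candidate haplotype at a given column index
#'
#' The candidate set for an L-SNP xor-genotype is the implicit ordered set of
#' all \code{2^L} binary columns.  Column \code{k} is the binary expansion of
#' \code{k - 1} with SNP 1 as the least-significant bit, so for \code{L = 3}
#' column 1 is \code{000}, column 3 is \code{010} and column 5 is \code{001}.
#' The set is never materialized as a matrix; this function is the
#' index-to-haplotype map.
#'
#' @param k column index, \code{1 <= k <= 2^L}.
#' @param L number of SNP loci.
#' @return integer vector of 0/1 alleles of length \code{L}
#'   (0 = major allele, 1 = minor allele).
#' @seealso [hap_index()] for the inverse map.
#' @examples
#' hap_column(5, 3)  # 0 0 1
#' hap_column(1, 3)  # 0 0 0
#' @export
hap_column <- function(k, L) {
  k <- as.integer(k)
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  if (is.na(k) || k < 1L || k > 2^L) {
    stop("column index k must lie in 1..2^L (k = ", k, ", L = ", L, ")")
  }
  bitwAnd(bitwShiftR(k - 1L, 0:(L - 1L)), 1L)
}

#' @rdname hap_column
#' @param h a 0/1 haplotype vector.
#' @return \code{hap_index} returns the column index of \code{h}.
#' @export
hap_index <- function(h) {
  check_hap(h)
  as.integer(bit_code(h) + 1)
}

# All 2^L candidate columns as an L x 2^L matrix (internal fast path; only
# built for block-sized L).
cand_matrix <- function(L) {
  L <- as.integer(L)
  M <- 2L^L
  matrix(vapply(1:M, hap_column, integer(L), L = L), nrow = L)
}

check_hap <- function(h, L = NULL) {
  if (anyNA(h) || !all(h %in% c(0L, 1L))) {
    stop("haplotype entries must all be 0 or 1")
  }
  if (!is.null(L) && length(h) != L) {
    stop("haplotype has length ", length(h), ", expected ", L)
  }
  invisible(as.integer(h))
}

#' Compose two haplotypes into an xor-genotype or a regular genotype
#'
#' An xor-genotype is the entrywise XOR of the two haplotypes: 1 marks a
#' heterozygous site, 0 a homozygous site with the allele type hidden.  A
#' regular genotype is the entrywise sum: 0 = major-homozygous,
#' 1 = heterozygous, 2 = minor-homozygous.
#'
#' @param h1,h2 0/1 haplotype vectors of equal length.
#' @return integer vector of length \code{L}: over \{0,1\} for
#'   \code{xor_compose}, over \{0,1,2\} for \code{genotype_compose}.
#' @examples
#' xor_compose(c(0, 0, 1), c(0, 1, 0))       # 0 1 1
#' genotype_compose(c(0, 1), c(0, 1))        # 0 2
#' @export
xor_compose <- function(h1, h2) {
  if (length(h1) != length(h2)) stop("haplotype lengths differ")
  check_hap(h1); check_hap(h2)
  as.integer((h1 + h2) %% 2L)
}

#' @rdname xor_compose
#' @export
genotype_compose <- function(h1, h2) {
  if (length(h1) != length(h2)) stop("haplotype lengths differ")
  check_hap(h1); check_hap(h2)
  as.integer(h1 + h2)
}

#' Compatibility of a haplotype with a regular genotype
#'
#' A haplotype \code{z} is compatible with a regular genotype \code{g} when
#' \code{g - z} is itself a valid haplotype, i.e. every entry of the
#' difference is 0 or 1.  Comparison is restricted to the observed (non-NA)
#' loci of \code{g}.  Any haplotype is compatible with any xor-genotype, so
#' no such predicate exists for xor data.
#'
#' @param z 0/1 haplotype vector.
#' @param g regular genotype vector over \{0,1,2\}, \code{NA} = missing.
#' @return \code{TRUE} or \code{FALSE}.
#' @examples
#' hap_compatible(c(0, 1), c(0, 2))  # TRUE:  g - z = 0 1
#' hap_compatible(c(1, 0), c(0, 2))  # FALSE: g - z has a -1
#' @export
hap_compatible <- function(z, g) {
  if (length(z) != length(g)) stop("haplotype and genotype lengths differ")
  check_hap(z)
  obs <- !is.na(g)
  d <- g[obs] - z[obs]
  all(d %in% c(0L, 1L))
}

#' Heterozygous loci of an xor-genotype
#'
#' @param x xor-genotype vector over \{0,1\}, \code{NA} = missing.
#' @return 1-based integer indices of observed loci equal to 1.
#' @examples
#' het_loci(c(0, 1, 1))  # 2 3
#' @export
het_loci <- function(x) {
  if (inherits(x, "xhsd_obs")) x <- x$values
  which(!is.na(x) & x == 1L)
}

#' Reconstruct an observation from selected candidate columns
#'
#' Forms the multiplicity-weighted sum of the candidate columns indexed by
#' \code{support}: modulo 2 for the xor kind (the XOR of the selected pair),
#' plain sum for the regular kind.  Multiplicities always total 2 — either a
#' single column doubled or two distinct columns once each.
#'
#' @param support integer vector of 1 or 2 candidate column indices.
#' @param L number of SNP loci.
#' @param kind \code{"xor"} or \code{"regular"}.
#' @param mult optional multiplicities on the support (defaults to 2 for a
#'   single column, c(1, 1) for a pair).
#' @return integer vector of length \code{L}.
#' @examples
#' hap_reconstruct(c(5, 3), 3)                    # 0 1 1
#' hap_reconstruct(5, 3)                          # 0 0 0 (doubled, mod 2)
#' hap_reconstruct(c(5, 3), 3, kind = "regular")  # 0 1 1
#' @export
hap_reconstruct <- function(support, L, kind = c("xor", "regular"), mult = NULL) {
  kind <- match.arg(kind)
  support <- as.integer(support)
  if (length(support) < 1L || length(support) > 2L) {
    stop("support must contain 1 or 2 column indices")
  }
  if (is.null(mult)) mult <- if (length(support) == 1L) 2L else c(1L, 1L)
  if (sum(mult) != 2L || any(mult < 1L)) {
    stop("multiplicities must be positive and sum to 2")
  }
  cols <- vapply(support, hap_column, integer(L), L = L)
  s <- as.integer(cols %*% mult)
  if (kind == "xor") s %% 2L else s
}
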
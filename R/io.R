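# Plain-text data formats.
#
#   XGT: "#XGT v1" header, then one "id<TAB>string" record per individual,
#        string over {0,1,?} ('?' = missing site), all of length L.
#   GT:  "#GT v1", alphabet {0,1,2,?}.
#   HAP: "#HAP v1", records "id<TAB>hap1<TAB>hap2" over {0,1}.
#   DICT: "#DICT v1", records "haplotype<TAB>frequency", frequencies sum to 1.
#
# All writers are byte-deterministic given identical inputs.

fmt_header <- function(tag, N, L, seed) {
  c(paste0("#", tag, " v1"),
    sprintf("#N=%d L=%d seed=%s", N, L,
            if (is.null(seed) || is.na(seed)) "NA" else format(seed)))
}

read_records <- function(path, tag, alphabet) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop_data(path, ": empty file (line 1)")
  if (lines[1] != paste0("#", tag, " v1")) {
    stop_data(path, ": line 1: expected header '#", tag, " v1'")
  }
  seed <- NA
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  h2 <- grep("^#N=", lines, value = TRUE)
  if (length(h2)) {
    m <- regmatches(h2[1], regexec("seed=([-0-9A-Za-z.]+)", h2[1]))[[1]]
    if (length(m) == 2L && m[2] != "NA") seed <- as.integer(m[2])
  }
  if (length(body) == 0L) stop_data(path, ": no records (line ",
                                    length(lines), ")")
  ids <- character(0)
  vals <- list()
  L <- NULL
  for (ln in body) {
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop_data(path, ": line ", ln, ": expected 'id<TAB>genotypes'")
    }
    chars <- strsplit(parts[2], "")[[1]]
    if (!all(chars %in% c(alphabet, "?"))) {
      stop_data(path, ": line ", ln, ": invalid symbol (alphabet ",
                paste(alphabet, collapse = ""), "?)")
    }
    if (is.null(L)) L <- length(chars)
    if (length(chars) != L) {
      stop_data(path, ": line ", ln, ": record length ", length(chars),
                " differs from L = ", L)
    }
    if (parts[1] %in% ids) {
      stop_data(path, ": line ", ln, ": duplicate id '", parts[1], "'")
    }
    ids <- c(ids, parts[1])
    v <- suppressWarnings(as.integer(chars))
    vals[[length(vals) + 1L]] <- v
  }
  list(m = do.call(cbind, vals), ids = ids, seed = seed)
}

#' Read and write xor-genotype (XGT) and regular-genotype (GT) files
#'
#' Tab-separated text with a \code{#XGT v1} (or \code{#GT v1}) header line and
#' one \code{id<TAB>string} record per individual; \code{?} marks a missing
#' site.  Round-trips are byte-exact.
#'
#' @param path file path.
#' @param data an [xhsd_data()].
#' @return readers return an [xhsd_data()]; writers return \code{path}
#'   invisibly.
#' @export
read_xgt <- function(path) {
  r <- read_records(path, "XGT", c("0", "1"))
  xhsd_data(r$m, kind = "xor", ids = r$ids, seed = r$seed)
}

#' @rdname read_xgt
#' @export
write_xgt <- function(data, path) {
  stopifnot(inherits(data, "xhsd_data"))
  if (any(data$kind != "xor")) stop_data("write_xgt expects xor-kind data")
  write_genotype_file(data, path, "XGT")
}

#' @rdname read_xgt
#' @export
read_gt <- function(path) {
  r <- read_records(path, "GT", c("0", "1", "2"))
  xhsd_data(r$m, kind = "regular", ids = r$ids, seed = r$seed)
}

#' @rdname read_xgt
#' @export
write_gt <- function(data, path) {
  stopifnot(inherits(data, "xhsd_data"))
  write_genotype_file(data, path, "GT")
}

write_genotype_file <- function(data, path, tag) {
  chr <- apply(data$values, 2, function(v) {
    s <- as.character(v)
    s[is.na(v)] <- "?"
    paste(s, collapse = "")
  })
  writeLines(c(fmt_header(tag, data$N, data$L, data$seed),
               paste(data$ids, chr, sep = "\t")), path)
  invisible(path)
}

#' Read and write phased haplotype-pair (HAP) files
#'
#' \code{#HAP v1} header, then \code{id<TAB>hap1<TAB>hap2} per individual.
#'
#' @param path file path.
#' @param x a fitted \code{xhsd} object, or a named list of L x 2 haplotype
#'   matrices.
#' @return \code{read_hap} returns a named list of L x 2 matrices;
#'   \code{write_hap} returns \code{path} invisibly.
#' @export
read_hap <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1] != "#HAP v1") {
    stop_data(path, ": line 1: expected header '#HAP v1'")
  }
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(body) == 0L) stop_data(path, ": no records")
  out <- list()
  L <- NULL
  for (ln in body) {
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3L) {
      stop_data(path, ": line ", ln, ": expected 'id<TAB>hap1<TAB>hap2'")
    }
    h <- lapply(parts[2:3], function(s) {
      ch <- strsplit(s, "")[[1]]
      if (!all(ch %in% c("0", "1"))) {
        stop_data(path, ": line ", ln, ": haplotypes must be over {0,1}")
      }
      as.integer(ch)
    })
    if (is.null(L)) L <- length(h[[1]])
    if (any(lengths(h) != L)) {
      stop_data(path, ": line ", ln, ": haplotype length differs from L = ", L)
    }
    if (parts[1] %in% names(out)) {
      stop_data(path, ": line ", ln, ": duplicate id '", parts[1], "'")
    }
    out[[parts[1]]] <- cbind(h[[1]], h[[2]], deparse.level = 0)
  }
  out
}

#' @rdname read_hap
#' @export
write_hap <- function(x, path) {
  pairs <- as_pair_list(x)
  ids <- names(pairs) %||% paste0("ind", seq_along(pairs))
  L <- nrow(pairs[[1]])
  recs <- vapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    paste(ids[i], paste(p[, 1], collapse = ""), paste(p[, 2], collapse = ""),
          sep = "\t")
  }, character(1))
  writeLines(c(fmt_header("HAP", length(pairs), L, NULL), recs), path)
  invisible(path)
}

#' Write the inferred haplotype dictionary with usage frequencies
#'
#' One \code{haplotype<TAB>frequency} record per haplotype in use; the
#' frequency column sums to 1.
#'
#' @param fit a fitted \code{xhsd} object.
#' @param path file path.
#' @export
write_dict <- function(fit, path) {
  stopifnot(inherits(fit, "xhsd"))
  keep <- fit$frequencies > 0
  H <- fit$haplotypes[, keep, drop = FALSE]
  f <- fit$frequencies[keep]
  recs <- vapply(seq_len(ncol(H)), function(j) {
    paste(paste(H[, j], collapse = ""), sprintf("%.12g", f[j]), sep = "\t")
  }, character(1))
  writeLines(c(paste0("#DICT v1"), recs), path)
  invisible(path)
}

#' Export a phased solution as minimal VCF
#'
#' Writes VCFv4.2 with one synthetic contig, positions \code{1..L},
#' placeholder alleles REF=A (major) / ALT=T (minor) and phased \code{GT}
#' fields.  Loci where the bit-flip degree of freedom is unresolved carry the
#' \code{XFLIP} FILTER flag.
#'
#' @param fit a fitted \code{xhsd} object.
#' @param path output file path.
#' @export
export_vcf <- function(fit, path) {
  stopifnot(inherits(fit, "xhsd"))
  L <- fit$data$L
  hp <- haplotype_pairs(fit)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=xhsd",
    sprintf("##contig=<ID=chrSim,length=%d>", L),
    "##FILTER=<ID=XFLIP,Description=\"Bit-flip ambiguity unresolved\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", fit$data$ids), collapse = "\t"))
  rows <- vapply(seq_len(L), function(l) {
    gt <- vapply(hp, function(p) paste0(p[l, 1], "|", p[l, 2]), character(1))
    filt <- if (l %in% fit$unresolved_loci) "XFLIP" else "PASS"
    paste(c("chrSim", l, paste0("snp", l), "A", "T", ".", filt, ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
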
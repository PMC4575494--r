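# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Build an allele-count vector
#'
#' Conditioning sets and contributor allele loads are represented throughout
#' the package as named numeric vectors mapping allele label to copy number.
#' This coerces `NULL` (empty), a character vector of allele labels (counted
#' with multiplicity), or an existing named numeric vector.
#'
#' @param x `NULL`, a character vector of allele labels, or a named numeric
#'   vector of non-negative counts.
#' @return Named numeric vector of counts (possibly empty).
#' @keywords internal
#' @noRd
as_counts <- function(x) {
  if (is.null(x)) return(stats::setNames(numeric(0), character(0)))
  if (is.character(x)) {
    if (length(x) == 0) return(stats::setNames(numeric(0), character(0)))
    tab <- table(x)
    return(stats::setNames(as.numeric(tab), names(tab)))
  }
  if (is.numeric(x)) {
    if (length(x) > 0 && is.null(names(x)))
      stop("count vectors must be named by allele label")
    if (any(x < 0)) stop("allele counts must be non-negative")
    return(x[x > 0])
  }
  stop("cannot interpret allele counts of class ", class(x)[1])
}

# add one copy of each allele in `alleles` (character, with multiplicity)
add_counts <- function(counts, alleles) {
  for (a in alleles) {
    i <- match(a, names(counts))
    if (is.na(i)) counts[[a]] <- 1 else counts[[i]] <- counts[[i]] + 1
  }
  counts
}

# all unordered genotypes constructible from an allele universe
all_genotypes <- function(alleles) {
  n <- length(alleles)
  out <- vector("list", n * (n + 1L) / 2L)
  k <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      k <- k + 1L
      out[[k]] <- genotype(alleles[i], alleles[j])
    }
  }
  out
}

is_probability <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
}

# full-precision numeric formatting for CSV output ("inf" for infinities)
format_lr <- function(x) {
  vapply(x, function(v) {
    if (is.infinite(v)) return(if (v > 0) "inf" else "-inf")
    formatC(v, digits = 17, format = "g")
  }, character(1))
}
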
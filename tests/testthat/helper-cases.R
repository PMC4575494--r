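# shared fixtures: everything is built in code at test time

# normalized random locus frequencies with STR-style labels
random_locus_freqs <- function(n_alleles, shape = 1.5) {
  x <- stats::rgamma(n_alleles, shape = shape)
  stats::setNames(x / sum(x), as.character(seq(8L, length.out = n_alleles)))
}

# one randomized engine case for DP-vs-enumeration comparisons; draws from
# the caller's RNG stream
random_engine_case <- function(allow_relative = TRUE) {
  n_alleles <- sample(2:8, 1)
  n_unknown <- sample(0:3, 1)
  # keep the enumeration oracle affordable at the largest sizes
  if (n_unknown == 3 && n_alleles > 5) n_alleles <- sample(2:5, 1)
  fr <- random_locus_freqs(n_alleles)
  params <- lr_params(p_dropout = sample(c(0, 0.05, 0.3, 0.7), 1),
                      p_dropin = sample(c(0, 0.01, 0.05), 1),
                      theta = sample(c(0, 0.01, 0.03), 1),
                      alpha = 0.5)
  detected <- names(fr)[stats::runif(n_alleles) < 0.5]
  fixed <- if (stats::runif(1) < 0.5)
    sample(names(fr), 2, replace = TRUE) else NULL
  base_cond <- if (stats::runif(1) < 0.5)
    sample(names(fr), 2, replace = TRUE) else NULL
  mask <- if (length(detected) && stats::runif(1) < 0.3)
    detected[1] else character()
  relative <- NULL
  if (allow_relative && n_unknown >= 1 && stats::runif(1) < 0.3)
    relative <- list(ibd = ibd_triple(0.25, 0.5, 0.25),
                     suspect_g = genotype(sample(names(fr), 1),
                                          sample(names(fr), 1)))
  list(freqs = fr, params = params, n_unknown = n_unknown,
       detected = detected, fixed = fixed, base_cond = base_cond,
       mask = mask, relative = relative)
}

# single-suspect vs one-unknown hypothesis pair (the canonical LR)
suspect_vs_unknown <- function()
  hypothesis_pair(hypothesis(TRUE, 0L), hypothesis(FALSE, 1L))

# write a profile CSV for a set of samples: rows = list(sample, marker,
# alleles, heights or NULL)
write_profile_csv <- function(rows, path, sample_header = "Sample Name",
                              sep = ",") {
  n <- max(vapply(rows, function(r) length(r$alleles), integer(1)))
  has_h <- any(vapply(rows, function(r) !is.null(r$heights), logical(1)))
  hdr <- c(sample_header, "Marker", paste("Allele", seq_len(n)),
           if (has_h) paste("Height", seq_len(n)))
  lines <- paste(hdr, collapse = sep)
  for (r in rows) {
    al <- c(r$alleles, rep("", n - length(r$alleles)))
    ht <- if (has_h) {
      h <- r$heights %||% rep(NA_real_, length(r$alleles))
      h <- c(h, rep(NA_real_, n - length(h)))
      ifelse(is.na(h), "", as.character(h))
    }
    lines <- c(lines, paste(c(r$sample, r$marker, al, ht), collapse = sep))
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# every unordered genotype constructible from a locus
all_genotypes_of <- function(freqs) {
  al <- names(freqs)
  out <- list()
  for (i in seq_along(al))
    for (j in i:length(al))
      out[[length(out) + 1L]] <- genotype(al[i], al[j])
  out
}

write_freq_csv <- function(table, path) {
  lines <- "Marker,Allele,Frequency"
  for (m in names(table$freqs)) {
    f <- table$freqs[[m]]
    lines <- c(lines, sprintf("%s,%s,%.17g", m, names(f), f))
  }
  writeLines(lines, path)
  path
}
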
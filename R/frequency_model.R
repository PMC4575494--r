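# Allele-frequency adjustment and theta-corrected conditional sampling.
#
# The coancestry correction is applied at the allelic level: rather than
# adjusting whole-genotype probabilities, each allele draw is conditioned on
# the alleles already "sampled" (suspect, assumed contributors, previously
# drawn unknown alleles) through the Balding-Nichols conditional formula
#   P(a | m_a copies seen among m total) =
#       (m_a * theta + (1 - theta) * p_a) / (1 + (m - 1) * theta).

#' Apply the 5/2n minimum-frequency floor
#'
#' Any allele that appears in the suspected contributor's profile or in the
#' evidence profile ("flagged" alleles) whose database frequency is below
#' 5/(2n) is raised to 5/(2n), where `n` is the number of individuals in the
#' frequency database. Flagged alleles absent from the table altogether are
#' inserted at 5/(2n). Unflagged alleles are untouched and frequencies are
#' never renormalized, so a floored locus may sum to slightly more than 1.
#'
#' @param table A [frequency_table()].
#' @param flagged Named list (marker -> character vector of allele labels).
#' @return A new [frequency_table()] with the floor applied; idempotent.
#' @export
apply_min_frequency <- function(table, flagged) {
  if (!inherits(table, "frequency_table")) stop("table must be a frequency_table")
  floor_f <- 5 / (2 * table$n_individuals)
  freqs <- table$freqs
  for (m in names(flagged)) {
    f <- freqs[[m]] %||% stats::setNames(numeric(0), character(0))
    for (a in unique(trimws(flagged[[m]]))) {
      if (!nzchar(a)) next
      i <- match(a, names(f))
      cur <- if (is.na(i)) 0 else f[[i]]
      if (cur < floor_f) f[[a]] <- floor_f
    }
    freqs[[m]] <- f
  }
  out <- table
  out$freqs <- freqs
  out$floored <- TRUE
  out
}

#' Conditional probability of sampling one more allele
#'
#' Balding-Nichols single-allele sampling formula. With no conditioning
#' (`cond` empty) this is the raw frequency `p_a`.
#'
#' @param allele Allele label.
#' @param cond Conditioning counts: named numeric vector (allele -> copies
#'   already sampled), or a character vector of allele labels, or `NULL`.
#' @param theta Coancestry coefficient in \[0, 1).
#' @param locus_freqs Named numeric vector of (post-floor) allele frequencies
#'   for the locus.
#' @return Probability of drawing `allele` next.
#' @export
conditional_allele_prob <- function(allele, cond, theta, locus_freqs) {
  cond <- as_counts(cond)
  i <- match(allele, names(locus_freqs))
  if (is.na(i))
    stop("allele '", allele, "' has no frequency; was the 5/2n floor applied?")
  p <- locus_freqs[[i]]
  j <- match(allele, names(cond))
  m_a <- if (is.na(j)) 0 else cond[[j]]
  m <- sum(cond)
  (m_a * theta + (1 - theta) * p) / (1 + (m - 1) * theta)
}

#' Conditional genotype probability
#'
#' Draws the two alleles of `g` sequentially with
#' [conditional_allele_prob()], adding the first allele to the conditioning
#' counts before the second draw; heterozygotes are multiplied by 2. The
#' result is invariant to the internal draw order. At theta = 0 with empty
#' conditioning this is the Hardy-Weinberg genotype probability.
#'
#' @param g A [genotype()].
#' @inheritParams conditional_allele_prob
#' @return Probability of genotype `g`.
#' @export
genotype_prob <- function(g, cond, theta, locus_freqs) {
  cond <- as_counts(cond)
  p1 <- conditional_allele_prob(g[1], cond, theta, locus_freqs)
  p2 <- conditional_allele_prob(g[2], add_counts(cond, g[1]), theta, locus_freqs)
  p <- p1 * p2
  if (g[1] != g[2]) p <- 2 * p
  p
}

# probability that a relative shares exactly one allele IBD and ends up with
# genotype g: the shared allele is one of the suspect's (uniformly for a
# heterozygote), the other allele is a fresh theta-conditional draw
p1_given_shared <- function(g, suspect_g, cond, theta, locus_freqs) {
  shared <- if (suspect_g[1] == suspect_g[2]) suspect_g[1] else suspect_g
  w <- 1 / length(shared)
  tot <- 0
  for (s in shared) {
    if (g[1] == s) {
      tot <- tot + w * conditional_allele_prob(g[2], cond, theta, locus_freqs)
    } else if (g[2] == s) {
      tot <- tot + w * conditional_allele_prob(g[1], cond, theta, locus_freqs)
    }
  }
  tot
}

#' Genotype probability for a relative of the suspected contributor
#'
#' Mixture over identity-by-descent states:
#' `k2 * 1{g == suspect_g} + k1 * P1(g | suspect_g) + k0 * genotype_prob(g)`,
#' where in the one-allele-IBD term the shared allele is chosen uniformly
#' among the suspect's alleles and the non-shared allele is drawn with the
#' same theta-conditional sampling as an unrelated unknown's allele.
#'
#' @param g Candidate [genotype()] for the relative.
#' @param suspect_g The suspected contributor's [genotype()] at this locus.
#' @param ibd An [ibd_triple()].
#' @inheritParams conditional_allele_prob
#' @return Probability of the relative having genotype `g`.
#' @export
relative_genotype_prob <- function(g, suspect_g, ibd, cond, theta, locus_freqs) {
  if (!inherits(ibd, "ibd_triple")) stop("ibd must be an ibd_triple()")
  cond <- as_counts(cond)
  p <- 0
  if (ibd$k2 > 0 && identical(genotype(g[1], g[2]), genotype(suspect_g[1], suspect_g[2])))
    p <- p + ibd$k2
  if (ibd$k1 > 0)
    p <- p + ibd$k1 * p1_given_shared(g, suspect_g, cond, theta, locus_freqs)
  if (ibd$k0 > 0)
    p <- p + ibd$k0 * genotype_prob(g, cond, theta, locus_freqs)
  p
}
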